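# Reading, writing and validating Boolean logical models in the community
# "targets, factors" rule-file dialect.

# Walk a rule AST and error on anything outside the grammar:
# identifiers, constants 0/1, and the operators ! & | ( ).
.checkRuleAst <- function(e) {
  if (is.symbol(e)) {
    if (!grepl(.NODE_NAME_RE, as.character(e)))
      stop("invalid node name '", as.character(e), "' in rule expression")
    return(invisible(TRUE))
  }
  if (is.numeric(e)) {
    if (!(length(e) == 1L && e %in% c(0, 1)))
      stop("numeric constants in rules must be 0 or 1")
    return(invisible(TRUE))
  }
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (op == "(") return(.checkRuleAst(e[[2L]]))
    if (op == "!") return(.checkRuleAst(e[[2L]]))
    if (op %in% c("&", "|")) {
      .checkRuleAst(e[[2L]])
      .checkRuleAst(e[[3L]])
      return(invisible(TRUE))
    }
    stop("operator '", op, "' is not part of the rule grammar (use !, &, |)")
  }
  stop("unparseable element in rule expression")
}

# All variables syntactically present in a rule expression.
.exprVars <- function(e) {
  if (is.symbol(e)) return(as.character(e))
  if (is.call(e)) {
    args <- as.list(e)[-1L]
    return(unique(unlist(lapply(args, .exprVars), use.names = FALSE)))
  }
  character(0)
}

# (regulator, sign) pairs with sign from negation parity.
.exprLiterals <- function(e, neg = FALSE) {
  if (is.symbol(e)) {
    return(data.frame(regulator = as.character(e),
                      sign = if (neg) "-" else "+",
                      stringsAsFactors = FALSE))
  }
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (op == "(") return(.exprLiterals(e[[2L]], neg))
    if (op == "!") return(.exprLiterals(e[[2L]], !neg))
    return(rbind(.exprLiterals(e[[2L]], neg), .exprLiterals(e[[3L]], neg)))
  }
  data.frame(regulator = character(0), sign = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a single logic rule
#'
#' @param target Node name the rule updates.
#' @param expression Rule formula as a string, e.g. `"(A & !B) | C"`.
#' @return A [LogicRule-class] object.
#' @examples
#' logicRule("C", "(A & !B) | C")
#' @export
logicRule <- function(target, expression) {
  expr <- tryCatch(str2lang(expression),
                   error = function(e) stop("cannot parse rule for '", target,
                                            "': ", conditionMessage(e),
                                            call. = FALSE))
  if (!(is.symbol(expr) || is.numeric(expr) || is.call(expr)))
    stop("cannot parse rule for '", target, "'")
  r <- new("LogicRule", target = as.character(target), expr = expr)
  validObject(r)
  r
}

#' Signed literals of a rule
#'
#' Returns the set of regulators syntactically present in a rule, each
#' annotated `"+"` if it appears under an even number of negations and `"-"`
#' if odd. A regulator occurring with both parities yields two rows.
#'
#' @param rule A [LogicRule-class].
#' @return data.frame with columns `regulator`, `sign`.
#' @examples
#' ruleLiterals(logicRule("C", "(A & !B) | C"))
#' @export
ruleLiterals <- function(rule) {
  stopifnot(is(rule, "LogicRule"))
  unique(.exprLiterals(rule@expr))
}

#' Construct a Boolean network from rules
#'
#' @param rules A list of [LogicRule-class] objects, one per node; node order
#'   follows the list order.
#' @param pathways Optional named character vector mapping nodes to pathway
#'   labels. Entries for nodes absent from the network are dropped with a
#'   warning.
#' @return A validated [BooleanNetwork-class].
#' @export
booleanNetwork <- function(rules, pathways = character(0)) {
  targets <- unname(vapply(rules, function(r) r@target, character(1)))
  dup <- targets[duplicated(targets)]
  if (length(dup))
    stop("duplicate rule for node '", dup[1L], "'")
  names(rules) <- targets
  if (length(pathways)) {
    unknown <- setdiff(names(pathways), targets)
    if (length(unknown)) {
      warning("pathway map entries for unknown nodes dropped: ",
              paste(unknown, collapse = ", "))
      pathways <- pathways[setdiff(names(pathways), unknown)]
    }
  }
  net <- new("BooleanNetwork", nodes = targets, rules = rules,
             pathways = pathways)
  validObject(net)
  net
}

#' Parse a rule file into a BooleanNetwork
#'
#' Accepts the plain-text "targets, factors" dialect: an optional header line
#' `targets, factors`, then one comma-separated `target, formula` line per
#' node. Blank lines and lines starting with `#` are ignored. Node order
#' follows file order.
#'
#' @param text Character scalar (entire file content) or character vector of
#'   lines.
#' @param pathways Optional named character vector of pathway labels.
#' @return A [BooleanNetwork-class].
#' @examples
#' net <- parseRules("A, B\nB, !A")
#' influenceGraph(net)
#' @seealso [readRules()] to read from a file, [writeRules()] for the inverse.
#' @export
parseRules <- function(text, pathways = character(0)) {
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lineno <- seq_along(text)
  keep <- !grepl("^\\s*(#|$)", text)
  text <- text[keep]; lineno <- lineno[keep]
  if (!length(text)) stop("rule file contains no rules")
  if (grepl("^\\s*targets?\\s*,\\s*factors?\\s*$", text[1L],
            ignore.case = TRUE)) {
    text <- text[-1L]; lineno <- lineno[-1L]
  }
  if (!length(text)) stop("rule file contains no rules")
  rules <- vector("list", length(text))
  for (i in seq_along(text)) {
    line <- text[i]
    cpos <- regexpr(",", line, fixed = TRUE)
    if (cpos < 0)
      stop("line ", lineno[i], ": expected 'target, formula'")
    target <- trimws(substr(line, 1L, cpos - 1L))
    body <- trimws(substr(line, cpos + 1L, nchar(line)))
    if (!grepl(.NODE_NAME_RE, target))
      stop("line ", lineno[i], ": invalid target name '", target, "'")
    rules[[i]] <- tryCatch(logicRule(target, body),
      error = function(e) stop("line ", lineno[i], ": ",
                               conditionMessage(e), call. = FALSE))
  }
  booleanNetwork(rules, pathways)
}

#' Read a rule file (and optional pathway map) from disk
#'
#' @param path Path to a "targets, factors" rule file.
#' @param pathwayFile Optional path to a two-column TSV (node, pathway).
#' @return A [BooleanNetwork-class].
#' @export
readRules <- function(path, pathwayFile = NULL) {
  pw <- character(0)
  if (!is.null(pathwayFile)) {
    tab <- read.delim(pathwayFile, header = TRUE, stringsAsFactors = FALSE)
    pw <- setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
  }
  parseRules(readLines(path), pathways = pw)
}

#' Serialize a BooleanNetwork to rule-file text
#'
#' Writes the "targets, factors" dialect; re-parsing the output yields a
#' network with identical nodes and truth tables. Output is byte-stable
#' across runs.
#'
#' @param network A [BooleanNetwork-class].
#' @param path Optional file path; when given the text is also written there.
#' @return The rule-file content as a single string (invisibly when `path`
#'   is given).
#' @export
writeRules <- function(network, path = NULL) {
  stopifnot(is(network, "BooleanNetwork"))
  body <- vapply(network@rules,
                 function(r) paste(deparse(r@expr, width.cutoff = 500L),
                                   collapse = " "),
                 character(1))
  txt <- paste0("targets, factors\n",
                paste0(network@nodes, ", ", body, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", txt), path)
    return(invisible(txt))
  }
  txt
}

#' Write a pathway map TSV
#'
#' @param network A [BooleanNetwork-class] with non-empty pathway groups.
#' @param path Output TSV path (columns `node`, `pathway`).
#' @return Invisibly, the data.frame written.
#' @export
writePathwayMap <- function(network, path) {
  pw <- pathwayGroups(network)
  df <- data.frame(node = names(pw), pathway = unname(pw),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Evaluate a rule under a network state
#'
#' @param rule A [LogicRule-class].
#' @param state Named vector of 0/1 values covering every variable the rule
#'   references.
#' @return 0 or 1 (integer).
#' @examples
#' evaluateRule(logicRule("A", "!B"), c(B = 1))
#' @export
evaluateRule <- function(rule, state) {
  stopifnot(is(rule, "LogicRule"))
  vars <- .exprVars(rule@expr)
  missing <- setdiff(vars, names(state))
  if (length(missing))
    stop("state is missing variable(s): ", paste(missing, collapse = ", "))
  if (length(state) && !all(state %in% c(0, 1)))
    stop("state values must be 0/1")
  env <- as.list(as.numeric(state))
  names(env) <- names(state)
  as.integer(as.logical(eval(rule@expr, envir = env)))
}

#' Signed influence graph of a network
#'
#' One directed edge `(from, to, sign)` for every signed literal of every
#' rule; a regulator appearing with both parities in one rule contributes two
#' edges. Edge order is deterministic (target order, then literal order).
#'
#' @param network A [BooleanNetwork-class].
#' @return data.frame with columns `from`, `to`, `sign`.
#' @export
influenceGraph <- function(network) {
  stopifnot(is(network, "BooleanNetwork"))
  parts <- lapply(network@nodes, function(v) {
    lits <- ruleLiterals(network@rules[[v]])
    if (!nrow(lits)) return(NULL)
    data.frame(from = lits$regulator, to = v, sign = lits$sign,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(from = character(0), to = character(0),
                      sign = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Regulators of a node in network-node order (deterministic tt layout).
.ruleRegulators <- function(network, v) {
  intersect(network@nodes, .exprVars(network@rules[[v]]@expr))
}

# Truth table of a rule over its regulators: entry 1 + sum(b_j * 2^(j-1))
# holds the rule value when regulator j has value b_j.
.ruleTruthTable <- function(network, v) {
  regs <- .ruleRegulators(network, v)
  k <- length(regs)
  if (k > 16L) stop("rule for '", v, "' has more than 16 regulators")
  tt <- integer(2^k)
  for (idx in seq_len(2^k)) {
    bits <- as.integer(bitwAnd(bitwShiftR(idx - 1L, 0:(max(k, 1) - 1L)), 1L))
    st <- setNames(bits[seq_len(k)], regs)
    tt[idx] <- evaluateRule(network@rules[[v]], st)
  }
  list(regulators = regs, table = tt)
}

#' Semantic regulator dependencies of every node
#'
#' A node `v` depends semantically on `u` when flipping `u` changes `v`'s
#' rule output for some assignment of the other regulators (determined by
#' exhaustive truth-table enumeration). Syntactic literals are always a
#' superset of these; rules without vacuous literals make the two coincide.
#'
#' @param network A [BooleanNetwork-class].
#' @return data.frame with columns `from`, `to`.
#' @export
semanticDependencies <- function(network) {
  parts <- lapply(network@nodes, function(v) {
    tt <- .ruleTruthTable(network, v)
    k <- length(tt$regulators)
    dep <- vapply(seq_len(k), function(j) {
      idx <- 0:(2^k - 1L)
      any(tt$table[idx + 1L] != tt$table[bitwXor(idx, bitwShiftL(1L, j - 1L)) + 1L])
    }, logical(1))
    if (!any(dep)) return(NULL)
    data.frame(from = tt$regulators[dep], to = v, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Nodes reachable from a set of source nodes in the influence graph
#'
#' @param network A [BooleanNetwork-class].
#' @param from Character vector of source nodes.
#' @param includeSelf Count the sources themselves as reached?
#' @return Character vector of reachable node names.
#' @export
reachableNodes <- function(network, from, includeSelf = TRUE) {
  ig <- influenceGraph(network)
  seen <- unique(from)
  frontier <- seen
  while (length(frontier)) {
    nxt <- unique(ig$to[ig$from %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- union(seen, frontier)
  }
  if (!includeSelf) seen <- setdiff(seen, from)
  seen
}
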