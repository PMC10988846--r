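# Shared fixtures and independent brute-force oracles used across the suite.

# Build a PersonalizedModel directly with hand-chosen parameters.
makeModel <- function(net, forced = integer(0), up = NULL, down = NULL,
                      init = NULL) {
  nn <- nodes(net)
  free <- setdiff(nn, names(forced))
  if (is.null(up)) up <- setNames(rep(0.5, length(free)), free)
  if (is.null(down)) down <- setNames(rep(0.5, length(free)), free)
  if (is.null(init)) init <- setNames(rep(0.5, length(nn)), nn)
  if (length(forced)) init[names(forced)] <- as.numeric(forced)
  new("PersonalizedModel", network = net,
      forcings = setNames(as.integer(forced), names(forced)),
      upRates = up[free], downRates = down[free], initialP = init[nn])
}

neutralProfile <- function(id = "neutral", group = "none") {
  patientProfile(id, group)
}

# Truth table of a network rule by direct enumeration (independent of the
# package's own truth-table code path).
bruteTruthTable <- function(net, node) {
  r <- rules(net)[[node]]
  vars <- sort(unique(ruleLiterals(r)$regulator))
  k <- length(vars)
  if (k == 0) return(evaluateRule(r, setNames(integer(0), character(0))))
  grid <- expand.grid(rep(list(0:1), k))
  names(grid) <- vars
  apply(grid, 1L, function(row) evaluateRule(r, row))
}

# Exact two-sided Mann-Whitney p by full enumeration of group labelings.
mwEnumOracle <- function(a, b) {
  pooled <- c(a, b)
  nA <- length(a); nB <- length(b)
  r <- rank(pooled)
  uOf <- function(idx) sum(r[idx]) - nA * (nA + 1) / 2
  obs <- uOf(seq_len(nA))
  us <- combn(length(pooled), nA, uOf)
  pl <- mean(us <= obs + 1e-9)
  pg <- mean(us >= obs - 1e-9)
  list(U = obs, p = min(1, 2 * min(pl, pg)))
}

# All permutations of 1..n (for the Spearman enumeration oracle).
permEnum <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permEnum(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, sub + (sub >= k))))
}

# Exact two-sided Spearman p by enumeration over all permutations.
spearPermOracle <- function(x, y) {
  perms <- permEnum(length(x))
  obs <- cor(x, y, method = "spearman")
  rhos <- apply(perms, 1L, function(p) cor(x, y[p], method = "spearman"))
  pl <- mean(rhos <= obs + 1e-12)
  pg <- mean(rhos >= obs - 1e-12)
  list(rho = obs, p = min(1, 2 * min(pl, pg)))
}

# Hand-computed BH step-up adjustment (min over the tail of p*m/rank).
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  adj[o] <- rev(cummin(rev(sorted)))
  pmin(adj, 1)
}
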