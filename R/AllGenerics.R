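#' @name accessors
#' @title Accessors for PatientBoolNet objects
#'
#' @description Accessor generics for the core S4 classes: node names, rules
#' and pathway groups of a [BooleanNetwork-class]; forcings, transition rates
#' and initial ON-probabilities of a [PersonalizedModel-class]; activity
#' matrix, time grid and Monte Carlo standard errors of an
#' [ActivityCurveSet-class].
#'
#' @param x An object of the appropriate class.
#' @return `nodes()`, a character vector; `rules()`, a named list of
#'   [LogicRule-class]; `pathwayGroups()`, a named character vector (possibly
#'   empty); `forcings()`, a named integer vector; `transitionRates()`, a list
#'   with elements `up` and `down`; `initialProbabilities()`, a named numeric
#'   vector; `activityMatrix()` and `mcStderr()`, numeric matrices;
#'   `curveTimes()`, a numeric vector.
NULL

#' @rdname accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))
#' @rdname accessors
#' @export
setGeneric("rules", function(x) standardGeneric("rules"))
#' @rdname accessors
#' @export
setGeneric("pathwayGroups", function(x) standardGeneric("pathwayGroups"))
#' @rdname accessors
#' @export
setGeneric("forcings", function(x) standardGeneric("forcings"))
#' @rdname accessors
#' @export
setGeneric("transitionRates", function(x) standardGeneric("transitionRates"))
#' @rdname accessors
#' @export
setGeneric("initialProbabilities",
           function(x) standardGeneric("initialProbabilities"))
#' @rdname accessors
#' @export
setGeneric("activityMatrix", function(x) standardGeneric("activityMatrix"))
#' @rdname accessors
#' @export
setGeneric("curveTimes", function(x) standardGeneric("curveTimes"))
#' @rdname accessors
#' @export
setGeneric("mcStderr", function(x) standardGeneric("mcStderr"))

#' @rdname accessors
setMethod("nodes", "BooleanNetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("rules", "BooleanNetwork", function(x) x@rules)
#' @rdname accessors
setMethod("pathwayGroups", "BooleanNetwork", function(x) x@pathways)
#' @rdname accessors
setMethod("nodes", "PersonalizedModel", function(x) x@network@nodes)
#' @rdname accessors
setMethod("forcings", "PersonalizedModel", function(x) x@forcings)
#' @rdname accessors
setMethod("transitionRates", "PersonalizedModel",
          function(x) list(up = x@upRates, down = x@downRates))
#' @rdname accessors
setMethod("initialProbabilities", "PersonalizedModel", function(x) x@initialP)
#' @rdname accessors
setMethod("activityMatrix", "ActivityCurveSet", function(x) x@activity)
#' @rdname accessors
setMethod("curveTimes", "ActivityCurveSet", function(x) x@times)
#' @rdname accessors
setMethod("mcStderr", "ActivityCurveSet", function(x) x@stderr)
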