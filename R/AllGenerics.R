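#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' Small accessor generics so downstream code never touches slots
#' directly.
#'
#' @param object a package object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("birdId", function(object) standardGeneric("birdId"))
#' @rdname accessors
#' @export
setGeneric("fixes", function(object) standardGeneric("fixes"))
#' @rdname accessors
#' @export
setGeneric("dives", function(object) standardGeneric("dives"))
#' @rdname accessors
#' @export
setGeneric("stateLabels", function(object) standardGeneric("stateLabels"))
#' @rdname accessors
#' @export
setGeneric("seqLogLik", function(object) standardGeneric("seqLogLik"))
#' @rdname accessors
#' @export
setGeneric("udDensity", function(object) standardGeneric("udDensity"))
#' @rdname accessors
#' @export
setGeneric("udCellM", function(object) standardGeneric("udCellM"))
#' @rdname accessors
#' @export
setGeneric("pcaLoadings", function(object) standardGeneric("pcaLoadings"))
#' @rdname accessors
#' @export
setGeneric("pcaEigenvalues",
           function(object) standardGeneric("pcaEigenvalues"))
#' @rdname accessors
#' @export
setGeneric("pcaScoreMatrix",
           function(object) standardGeneric("pcaScoreMatrix"))

#' @rdname accessors
#' @export
setMethod("birdId", "MurreDeployment", function(object) object@birdId)
#' @rdname accessors
#' @export
setMethod("fixes", "MurreDeployment", function(object) object@fixes)
#' @rdname accessors
#' @export
setMethod("dives", "MurreDeployment", function(object) object@dives)
#' @rdname accessors
#' @export
setMethod("stateLabels", "BehaviorSequence", function(object) object@states)
#' @rdname accessors
#' @export
setMethod("stateLabels", "HMMSpec", function(object) object@states)
#' @rdname accessors
#' @export
setMethod("seqLogLik", "BehaviorSequence", function(object) object@logLik)
#' @rdname accessors
#' @export
setMethod("udDensity", "UtilizationDistribution",
          function(object) object@density)
#' @rdname accessors
#' @export
setMethod("udCellM", "UtilizationDistribution",
          function(object) object@cellM)
#' @rdname accessors
#' @export
setMethod("pcaLoadings", "PCAResult", function(object) object@loadings)
#' @rdname accessors
#' @export
setMethod("pcaEigenvalues", "PCAResult", function(object) object@eigenvalues)
#' @rdname accessors
#' @export
setMethod("pcaScoreMatrix", "PCAResult", function(object) object@scores)

setMethod("show", "MurreDeployment", function(object) {
  cat(sprintf(
    "MurreDeployment %s (%s, %s)\n  %d fixes, %s to %s\n  %d dives\n",
    object@birdId, object@sex, object@stage, nrow(object@fixes),
    format(object@startT, "%Y-%m-%d %H:%M", tz = "UTC"),
    format(object@endT, "%Y-%m-%d %H:%M", tz = "UTC"),
    nrow(object@dives)))
})

setMethod("show", "HMMSpec", function(object) {
  cat(sprintf("HMMSpec with %d states: %s\n", length(object@states),
              paste(object@states, collapse = ", ")))
  cat("Transition matrix:\n")
  print(round(object@trans, 3))
})

setMethod("show", "BehaviorSequence", function(object) {
  tab <- table(factor(object@states, levels = object@spec@states))
  cat(sprintf("BehaviorSequence for %s: %d fixes, logLik %.2f\n",
              object@deploymentId, length(object@states), object@logLik))
  print(tab)
})

setMethod("show", "UtilizationDistribution", function(object) {
  cat(sprintf(
    "UtilizationDistribution: %d x %d cells of %.0f m (%s)\n",
    length(object@x), length(object@y), object@cellM, object@crsNote))
})

setMethod("show", "PCAResult", function(object) {
  cat(sprintf(
    "PCAResult: %d variables, %d retained (%s), %.1f%% variance\n",
    length(object@variables), ncol(object@loadings),
    if (object@rotated) "varimax rotated" else "unrotated",
    object@varExplainedPct))
})

setMethod("show", "EnvField", function(object) {
  cat(sprintf("EnvField %s [%s]: %d x %d cells, %d days (%s to %s)\n",
              object@variable, object@units, length(object@lon),
              length(object@lat), length(object@times),
              min(object@times), max(object@times)))
})
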