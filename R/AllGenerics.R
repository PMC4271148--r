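#' Accessors for estimate objects
#'
#' \code{sHat} and \code{uHat} return the estimated per-allele sensitivity
#' and specificity of a \linkS4class{PerformanceEstimate};
#' \code{nSites} the number of observations behind the fit;
#' \code{sMedian}, \code{uMedian}, \code{sCI}, \code{uCI} and
#' \code{perSetEstimates} the aggregated quantities of an
#' \linkS4class{EstimateSummary}; \code{individualId} the sample label of a
#' \linkS4class{CallSet}.
#'
#' @param object a \linkS4class{PerformanceEstimate},
#'   \linkS4class{EstimateSummary} or \linkS4class{CallSet}.
#' @return A numeric scalar (or numeric(2) for the interval accessors), an
#'   integer count, a character label, or a \code{data.frame} of per-set
#'   estimates, depending on the accessor.
#' @name estimate-accessors
#' @aliases sHat uHat nSites sMedian uMedian sCI uCI perSetEstimates
#'   individualId
NULL

#' @rdname estimate-accessors
#' @export
setGeneric("sHat", function(object) standardGeneric("sHat"))
#' @rdname estimate-accessors
#' @export
setGeneric("uHat", function(object) standardGeneric("uHat"))
#' @rdname estimate-accessors
#' @export
setGeneric("nSites", function(object) standardGeneric("nSites"))
#' @rdname estimate-accessors
#' @export
setGeneric("sMedian", function(object) standardGeneric("sMedian"))
#' @rdname estimate-accessors
#' @export
setGeneric("uMedian", function(object) standardGeneric("uMedian"))
#' @rdname estimate-accessors
#' @export
setGeneric("sCI", function(object) standardGeneric("sCI"))
#' @rdname estimate-accessors
#' @export
setGeneric("uCI", function(object) standardGeneric("uCI"))
#' @rdname estimate-accessors
#' @export
setGeneric("perSetEstimates",
           function(object) standardGeneric("perSetEstimates"))
#' @rdname estimate-accessors
#' @export
setGeneric("individualId", function(object) standardGeneric("individualId"))

setMethod("sHat", "PerformanceEstimate", function(object) object@sHat)
setMethod("uHat", "PerformanceEstimate", function(object) object@uHat)
setMethod("nSites", "PerformanceEstimate", function(object) object@nSites)
setMethod("sMedian", "EstimateSummary", function(object) object@sMedian)
setMethod("uMedian", "EstimateSummary", function(object) object@uMedian)
setMethod("sCI", "EstimateSummary", function(object) object@sCI)
setMethod("uCI", "EstimateSummary", function(object) object@uCI)
setMethod("perSetEstimates", "EstimateSummary",
          function(object) object@estimates)
setMethod("individualId", "CallSet", function(object) object@individualId)

#' @describeIn estimate-accessors log-likelihood at the fitted optimum.
#' @importFrom stats logLik
#' @export
logLik.PerformanceEstimate <- function(object, ...) {
    structure(object@logLik, df = 2L, nobs = object@nSites,
              class = "logLik")
}

setMethod("show", "PerformanceEstimate", function(object) {
    cat("PerformanceEstimate\n")
    cat(sprintf("  sensitivity (s): %.6f\n", object@sHat))
    cat(sprintf("  specificity (u): %.6f\n", object@uHat))
    cat(sprintf("  sites: %d   log-likelihood: %.4f\n",
                object@nSites, object@logLik))
    if (!is.na(object@siteSetSeed))
        cat(sprintf("  site-set seed: %d\n", object@siteSetSeed))
})

setMethod("show", "EstimateSummary", function(object) {
    cat(sprintf("EstimateSummary over %d site set(s)\n", object@nReplicates))
    cat(sprintf("  median s: %.6f  (CI %.6f-%.6f)\n",
                object@sMedian, object@sCI[1L], object@sCI[2L]))
    cat(sprintf("  median u: %.6f  (CI %.6f-%.6f)\n",
                object@uMedian, object@uCI[1L], object@uCI[2L]))
})

setMethod("show", "CallSet", function(object) {
    cat(sprintf("CallSet for individual '%s': %d called position(s)\n",
                object@individualId, length(object)))
    if (length(object)) methods::callNextMethod()
})
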