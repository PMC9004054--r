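#' Line identifiers of an object
#'
#' @param x a \code{MarkerMatrix}, \code{KinshipMatrix}, \code{BlueTable} or
#'   \code{PosteriorSummary}.
#' @return character vector of line (genotype) identifiers, in object order.
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))

#' Marker identifiers of a marker matrix
#'
#' @param x a \code{MarkerMatrix}.
#' @return character vector of marker identifiers.
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' Trait names carried by an object
#'
#' @param x a \code{TrialTable}, \code{BlueTable}, \code{SimTruth} or
#'   \code{PosteriorSummary}.
#' @return character vector of trait names.
#' @export
setGeneric("traitNames", function(x) standardGeneric("traitNames"))

#' Posterior-mean genomic estimated breeding values
#'
#' @param x a \code{PosteriorSummary}.
#' @return numeric matrix, lines x traits, of posterior-mean genetic values.
#' @export
setGeneric("gebv", function(x) standardGeneric("gebv"))

#' Posterior-mean genetic covariance between traits
#'
#' @param x a \code{PosteriorSummary} from a multi-trait fit.
#' @return symmetric traits x traits matrix (\eqn{\Sigma}).
#' @export
setGeneric("sigmaHat", function(x) standardGeneric("sigmaHat"))

#' Posterior-mean residual covariance (diagonal) between traits
#'
#' @param x a \code{PosteriorSummary} from a multi-trait fit.
#' @return diagonal traits x traits matrix (R).
#' @export
setGeneric("residualMatrix", function(x) standardGeneric("residualMatrix"))

#' Mean predictive ability of a cross-validation result
#'
#' @param x a \code{CvResult}.
#' @return mean Pearson correlation over valid replicates.
#' @export
setGeneric("meanPredictiveAbility", function(x) standardGeneric("meanPredictiveAbility"))
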