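## Marker imputation and the VanRaden additive relationship matrix.

#' Impute missing marker codes
#'
#' Two imputation rules for \{-1, 0, +1\} coded markers:
#' \describe{
#'   \item{mean}{fill each missing cell with the marker's observed mean
#'     (fractional values, kept as-is for downstream kinship).}
#'   \item{knn}{fill from the \code{k} nearest lines (Euclidean distance over
#'     jointly observed markers), averaging their codes at the missing marker
#'     and rounding to the nearest code in \{-1, 0, +1\}.}
#' }
#' Observed cells are never changed; a matrix with no missing cells is
#' returned unchanged.
#'
#' @param markers a \code{MarkerMatrix}.
#' @param method "mean" (default) or "knn".
#' @param k neighbours for \code{method = "knn"}.
#' @return a \code{MarkerMatrix} with no missing cells (\code{imputed = TRUE}
#'   when anything was filled).
#' @examples
#' m <- matrix(c(-1, NA, 1, 0, 0, 0), nrow = 3,
#'             dimnames = list(paste0("L", 1:3), c("m1", "m2")))
#' as.matrix(imputeMissing(MarkerMatrix(m)))
#' @export
imputeMissing <- function(markers, method = c("mean", "knn"), k = 5) {
  stopifnot(is(markers, "MarkerMatrix"))
  method <- match.arg(method)
  m <- as.matrix(markers)
  if (!anyNA(m)) return(markers)

  all_missing <- colSums(!is.na(m)) == 0
  if (any(all_missing))
    stop("marker(s) with no observed value: ",
         paste(colnames(m)[all_missing], collapse = ", "))

  if (method == "mean") {
    mu <- colMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mu[idx[, 2]]
  } else {
    k <- min(k, nrow(m) - 1)
    filled <- m
    need <- which(rowSums(is.na(m)) > 0)
    for (i in need) {
      ## distances to all other lines over jointly observed markers
      d <- vapply(seq_len(nrow(m)), function(j) {
        if (j == i) return(Inf)
        ok <- !is.na(m[i, ]) & !is.na(m[j, ])
        if (!any(ok)) return(Inf)
        sqrt(mean((m[i, ok] - m[j, ok])^2))
      }, numeric(1))
      nb <- order(d)[seq_len(k)]
      for (jm in which(is.na(m[i, ]))) {
        v <- m[nb, jm]
        v <- v[!is.na(v)]
        filled[i, jm] <- if (length(v)) round(mean(v)) else
          round(mean(m[, jm], na.rm = TRUE))
      }
    }
    m <- filled
  }
  MarkerMatrix(m, imputed = TRUE)
}

#' Additive genomic relationship matrix (VanRaden)
#'
#' \eqn{K = W W^T / c} where W is the column-centered code matrix and
#' \eqn{c = \sum_j 2 f_j (1 - f_j)} with \eqn{f_j} the allele frequency of
#' marker j. For \{-1, 0, +1\} codes, \eqn{f_j = (\bar{x}_j + 1)/2}. This is
#' the same centering and scaling as the classic A.mat computation (no MAF
#' filter, no shrinkage); an optional minimum-MAF filter can be switched on.
#' If the smallest eigenvalue falls below \code{-1e-8}, a ridge
#' \eqn{(|\lambda_{min}| + 10^{-6}) I} is added and the event is reported via
#' \code{message()} and recorded in the returned object.
#'
#' @param markers a \code{MarkerMatrix} with no missing cells (run
#'   \code{\link{imputeMissing}} first).
#' @param minMaf optional minimum minor allele frequency; markers below it are
#'   dropped before computing K (default 0 = keep all polymorphic markers).
#' @return a \code{\linkS4class{KinshipMatrix}}.
#' @examples
#' mk <- simulateMarkers(10, 100, seed = 2)
#' additiveRelationship(mk)
#' @export
additiveRelationship <- function(markers, minMaf = 0) {
  stopifnot(is(markers, "MarkerMatrix"))
  m <- as.matrix(markers)
  if (anyNA(m)) stop("markers contain missing cells; run imputeMissing() first")

  f <- (colMeans(m) + 1) / 2          # frequency of the +1 allele
  keep <- f > 0 & f < 1               # drop monomorphic markers (no information)
  if (minMaf > 0) keep <- keep & pmin(f, 1 - f) >= minMaf
  if (!any(keep))
    stop("degenerate marker set: no polymorphic markers left, c = 0")
  W <- sweep(m[, keep, drop = FALSE], 2, colMeans(m[, keep, drop = FALSE]))
  c_scale <- sum(2 * f[keep] * (1 - f[keep]))
  K <- tcrossprod(W) / c_scale
  K <- (K + t(K)) / 2

  lmin <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  stabilized <- FALSE; eps <- 0
  if (lmin < -1e-8) {
    eps <- abs(lmin) + 1e-6
    K <- K + diag(eps, nrow(K))
    stabilized <- TRUE
    message(sprintf("kinship stabilized: added %.3g to the diagonal (min eigenvalue %.3g)",
                    eps, lmin))
  }
  KinshipMatrix(K, stabilized = stabilized, epsilon = eps)
}

#' Subset a kinship matrix to a set of lines
#'
#' @param kinship a \code{KinshipMatrix}.
#' @param ids line identifiers to keep, in the requested order.
#' @return a \code{KinshipMatrix} over \code{ids}.
#' @export
subsetKinship <- function(kinship, ids) {
  stopifnot(is(kinship, "KinshipMatrix"))
  missing_ids <- setdiff(ids, lineIds(kinship))
  if (length(missing_ids))
    stop("unknown line id(s): ", paste(head(missing_ids, 5), collapse = ", "))
  KinshipMatrix(as.matrix(kinship)[ids, ids, drop = FALSE],
                stabilized = kinship@stabilized, epsilon = kinship@epsilon)
}
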