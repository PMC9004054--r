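## Bayesian genomic prediction: single-trait GBLUP with alpha ~ N(0, K s2g)
## and multi-trait GBLUP with alpha ~ MVN(0, Sigma (x) K), eps ~ MVN(0, R (x) I),
## Sigma unstructured and R diagonal. Sampling is done in C++ (src/gibbs.cpp)
## under R's RNG; these wrappers set priors, align inputs to the kinship
## matrix, and package the output.

## scaled-inverse-chi-square scale with prior mode = half the sample variance
.prior_scale <- function(vy, nu) vy * (nu + 2) / (2 * nu)

#' Effective sample size of a chain
#'
#' Initial-positive-sequence estimate from the empirical autocorrelations.
#'
#' @param x numeric chain.
#' @return estimated effective sample size.
#' @export
effectiveSampleSize <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(1000, n %/% 2), plot = FALSE)$acf[-1]
  neg <- which(ac < 0)
  if (length(neg)) ac <- ac[seq_len(neg[1] - 1)]
  n / (1 + 2 * sum(ac))
}

#' Geweke-style stationarity z-score
#'
#' Compares the mean of the first \code{frac1} of a chain with the mean of the
#' last \code{frac2}, with standard errors based on effective sample sizes.
#' |z| well above 3 indicates a trend (poor convergence).
#'
#' @param x numeric chain.
#' @param frac1,frac2 fractions taken from the start and end.
#' @return z-score (0 for a constant chain).
#' @export
gewekeZ <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(max(2, floor(frac1 * n)))]
  b <- x[seq.int(n - max(2, floor(frac2 * n)) + 1, n)]
  va <- var(a) / effectiveSampleSize(a)
  vb <- var(b) / effectiveSampleSize(b)
  if (va + vb == 0) return(0)
  (mean(a) - mean(b)) / sqrt(va + vb)
}

.warn_mixing <- function(chains, what) {
  for (nm in names(chains)) {
    x <- chains[[nm]]
    if (!is.numeric(x) || is.matrix(x)) next
    z <- gewekeZ(x)
    if (abs(z) > 4)
      warning(sprintf("%s: poor mixing for %s (Geweke z = %.1f, ESS = %.0f)",
                      what, nm, z, effectiveSampleSize(x)), call. = FALSE)
  }
}

.align_kinship <- function(kinship, ids) {
  if (!is(kinship, "KinshipMatrix"))
    stop("kinship must be a KinshipMatrix (run additiveRelationship(); ",
         "its stabilization guarantees the PSD K the sampler requires)")
  if (!all(ids %in% lineIds(kinship)))
    stop("phenotype genotypes missing from K: ",
         paste(head(setdiff(ids, lineIds(kinship)), 5), collapse = ", "))
  as.matrix(subsetKinship(kinship, ids))
}

#' Single-trait Bayesian genomic prediction (Gibbs sampler)
#'
#' Model: \eqn{y = \mu + \alpha + \varepsilon} with
#' \eqn{\alpha \sim N(0, K\sigma^2_g)} and
#' \eqn{\varepsilon \sim N(0, I\sigma^2_e)}. The Gibbs cycle updates
#' \eqn{\mu}, \eqn{\alpha} (diagonally, in the eigenbasis of K),
#' \eqn{\sigma^2_g} and \eqn{\sigma^2_e} (scaled-inverse-chi-square
#' conditionals), and augments missing phenotypes from their conditional
#' normal, so GEBVs and predictions are produced for every genotype in
#' \code{y} including unphenotyped ones. Defaults follow the study protocol
#' (2000 burn-in / 12,000 iterations).
#'
#' @param y named numeric vector of adjusted means (BLUEs) for one trait;
#'   \code{NA} marks genotypes to predict. Needs >= 10 observed values.
#' @param kinship a \code{KinshipMatrix} covering \code{names(y)}.
#' @param config a \code{\link{gibbsConfig}}.
#' @param trait trait label carried into the output.
#' @param fixSigma2G,fixSigma2E fix a variance component at a known value
#'   instead of sampling it (testing hook; \code{NA} = sample).
#' @param keepGebvChain retain the full genetic-value chain (for Monte-Carlo
#'   error assessment).
#' @return a \code{\linkS4class{PosteriorSummary}}.
#' @examples
#' mk <- simulateMarkers(30, 300, seed = 1)
#' K <- additiveRelationship(mk)
#' y <- setNames(rnorm(30), lineIds(mk)); y[1:5] <- NA
#' fit <- fitSingleTrait(y, K, gibbsConfig(burnIn = 100, nIter = 600, seed = 1))
#' head(gebv(fit))
#' @export
fitSingleTrait <- function(y, kinship, config = gibbsConfig(), trait = "trait",
                           fixSigma2G = NA, fixSigma2E = NA,
                           keepGebvChain = FALSE) {
  stopifnot(is(config, "GibbsConfig"))
  if (is.null(names(y))) stop("y must carry genotype names")
  if (sum(!is.na(y)) < 10) stop("need >= 10 observed phenotypes")
  K <- .align_kinship(kinship, names(y))

  e <- eigen(K, symmetric = TRUE)
  d <- pmax(e$values, 0)
  obs <- !is.na(y)
  vy <- var(y[obs])
  nu0 <- config@priorDfVariance
  s0 <- .prior_scale(vy, nu0)

  yc <- y; yc[!obs] <- 0
  res <- local_seed(config@seed,
    .gibbs_st_cpp(yc, as.integer(obs), e$vectors, d,
                  as.integer(config@burnIn), as.integer(config@nIter),
                  as.integer(config@thin), nu0, s0, s0,
                  ifelse(is.na(fixSigma2G), -1, fixSigma2G),
                  ifelse(is.na(fixSigma2E), -1, fixSigma2E),
                  keepGebvChain))
  .warn_mixing(res$chains[c("sigma2_g", "sigma2_e")], "fitSingleTrait")

  n <- length(y)
  gm <- matrix(res$alpha_hat, n, 1, dimnames = list(names(y), trait))
  yp <- matrix(ifelse(obs, NA_real_, res$pred_hat), n, 1,
               dimnames = list(names(y), trait))
  new("PosteriorSummary", model = "ST",
      muHat = setNames(res$mu_hat, trait),
      gebvValues = gm, yPred = yp,
      observed = matrix(obs, n, 1, dimnames = list(names(y), trait)),
      sigma2G = setNames(res$sigma2_g_hat, trait),
      sigma2E = setNames(res$sigma2_e_hat, trait),
      SigmaHat = matrix(numeric(0), 0, 0), RHat = matrix(numeric(0), 0, 0),
      chains = res$chains)
}

#' Multi-trait Bayesian genomic prediction (Gibbs sampler)
#'
#' Model: stacked \eqn{y_j = \mu_j + \alpha_j + \varepsilon_j} with
#' \eqn{\alpha \sim MVN(0, \Sigma \otimes K)} and
#' \eqn{\varepsilon \sim MVN(0, R \otimes I)}, \eqn{\Sigma} unstructured
#' (inverse-Wishart full conditional) and R diagonal (scaled-inverse-
#' chi-square conditionals). Genetic values are updated per eigen-coordinate
#' of K as t x t multivariate-normal solves; arbitrary missing phenotype cells
#' are data-augmented each iteration, which is what allows CV2-style partially
#' observed genotypes.
#'
#' @param Y numeric matrix, genotypes x traits, with rownames and colnames;
#'   arbitrary \code{NA} pattern, but every trait needs >= 2 observed values.
#' @param kinship a \code{KinshipMatrix} covering \code{rownames(Y)}.
#' @param config a \code{\link{gibbsConfig}}; \code{priorDfWishart = NA}
#'   resolves to t + 3.
#' @param keepSigmaChain retain the \eqn{\Sigma} chain (kept x t^2).
#' @return a \code{\linkS4class{PosteriorSummary}} with \code{sigmaHat} and
#'   \code{residualMatrix} filled.
#' @examples
#' mk <- simulateMarkers(30, 300, seed = 2)
#' K <- additiveRelationship(mk)
#' Y <- matrix(rnorm(60), 30, 2, dimnames = list(lineIds(mk), c("A", "B")))
#' fit <- fitMultiTrait(Y, K, gibbsConfig(burnIn = 100, nIter = 600, seed = 1))
#' sigmaHat(fit)
#' @export
fitMultiTrait <- function(Y, kinship, config = gibbsConfig(),
                          keepSigmaChain = TRUE) {
  stopifnot(is(config, "GibbsConfig"))
  if (is.null(rownames(Y)) || is.null(colnames(Y)))
    stop("Y must carry genotype rownames and trait colnames")
  nobs <- colSums(!is.na(Y))
  if (any(nobs < 2))
    stop("trait(s) with < 2 observations: ",
         paste(colnames(Y)[nobs < 2], collapse = ", "))
  K <- .align_kinship(kinship, rownames(Y))

  e <- eigen(K, symmetric = TRUE)
  d <- pmax(e$values, 0)
  t <- ncol(Y)
  obs <- !is.na(Y)
  vy <- apply(Y, 2, var, na.rm = TRUE)
  nuR <- config@priorDfVariance
  s0R <- .prior_scale(vy, nuR)
  nuS <- if (is.na(config@priorDfWishart)) t + 3 else config@priorDfWishart
  ## scale set so the prior MODE of each Sigma diagonal (Psi/(nu + t + 1)) is
  ## half the sample variance -- the same mode the scalar variance priors use,
  ## keeping the t = 1 multi-trait model consistent with the single-trait one
  S0 <- diag((nuS + t + 1) * 0.5 * vy, t)

  Yc <- Y; Yc[!obs] <- 0
  res <- local_seed(config@seed,
    .gibbs_mt_cpp(Yc, matrix(as.integer(obs), nrow(Y), t), e$vectors, d,
                  as.integer(config@burnIn), as.integer(config@nIter),
                  as.integer(config@thin), nuR, s0R, nuS, S0,
                  keepSigmaChain))
  if (res$n_jitter > 0)
    message(sprintf("fitMultiTrait: Sigma update jittered to PD in %d iteration(s)",
                    res$n_jitter))
  chR <- res$chains$R
  colnames(chR) <- colnames(Y)
  diag_chains <- lapply(seq_len(t), function(j) chR[, j])
  names(diag_chains) <- paste0("R_", colnames(Y))
  .warn_mixing(diag_chains, "fitMultiTrait")

  Sh <- (res$Sigma_hat + t(res$Sigma_hat)) / 2
  dimnames(Sh) <- list(colnames(Y), colnames(Y))
  Rh <- diag(as.numeric(res$R_hat), t)
  dimnames(Rh) <- dimnames(Sh)
  gm <- res$A_hat; dimnames(gm) <- dimnames(Y)
  yp <- ifelse(obs, NA_real_, res$pred_hat); dimnames(yp) <- dimnames(Y)
  new("PosteriorSummary", model = "MT",
      muHat = setNames(as.numeric(res$mu_hat), colnames(Y)),
      gebvValues = gm, yPred = yp, observed = obs,
      sigma2G = setNames(diag(Sh), colnames(Y)),
      sigma2E = setNames(diag(Rh), colnames(Y)),
      SigmaHat = Sh, RHat = Rh, chains = res$chains)
}

#' Predictions from a fitted model
#'
#' Posterior-mean prediction \eqn{\hat\mu_j + \widehat{gebv}_{ij}} for the
#' requested genotypes and trait: for cells that were missing in the input
#' this equals the data-augmentation posterior mean, and for never-phenotyped
#' genotypes it is GEBV plus intercept.
#'
#' @param object a \code{PosteriorSummary}.
#' @param ids genotype identifiers (default: all fitted).
#' @param trait trait name (default: first fitted trait).
#' @param ... ignored.
#' @return named numeric vector of predictions.
#' @export
setMethod("predict", "PosteriorSummary", function(object, ids = NULL,
                                                  trait = NULL, ...) {
  if (is.null(ids)) ids <- lineIds(object)
  if (is.null(trait)) trait <- traitNames(object)[1]
  if (!trait %in% traitNames(object)) stop("unknown trait: ", trait)
  unknown <- setdiff(ids, lineIds(object))
  if (length(unknown))
    stop("unknown genotype id(s): ", paste(head(unknown, 5), collapse = ", "))
  object@muHat[trait] + setNames(object@gebvValues[ids, trait], ids)
})
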