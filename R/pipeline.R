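#' @include simulate.R
NULL

## End-to-end orchestration: simulate (or load) -> kinship -> BLUEs ->
## ANOVA / summary / correlations -> CV comparison -> report. Every stage
## writes plain CSV into the run directory and appends to run.log, and can be
## re-run individually against files already present there.

#' RunConfig: everything a pipeline run needs
#'
#' @slot outDir output directory for CSVs and the log.
#' @slot seed global seed; stage and replicate seeds derive from it.
#' @slot profile \code{"demo"} (reduced problem sizes, labelled scaled-down in
#'   outputs) or \code{"paper-scale"} (27,466 markers, 100 CV replicates,
#'   2000/12,000 Gibbs iterations).
#' @slot markerFile,trialFile optional CSV inputs; empty string = simulate.
#' @slot design a \code{\linkS4class{DesignSpec}}.
#' @slot simPar parameter list from \code{\link{simParams}}.
#' @slot nMarkers marker count when simulating.
#' @slot primaryTraits,secondaryTraits trait designations; defaults are the
#'   five primary agronomic traits and the two physiological secondary traits
#'   (CT, NDVI).
#' @slot datasets which BLUE datasets to build ("combined" and/or environment
#'   labels).
#' @slot cvTraits primary traits to cross-validate.
#' @slot gibbs a \code{\linkS4class{GibbsConfig}}.
#' @slot nReps CV replicates.
#' @export
setClass("RunConfig",
  representation(outDir = "character", seed = "numeric", profile = "character",
                 markerFile = "character", trialFile = "character",
                 design = "DesignSpec", simPar = "list", nMarkers = "numeric",
                 primaryTraits = "character", secondaryTraits = "character",
                 datasets = "character", cvTraits = "character",
                 gibbs = "GibbsConfig", nReps = "numeric")
)

setValidity("RunConfig", function(object) {
  if (!object@profile %in% c("demo", "paper-scale"))
    return("profile must be 'demo' or 'paper-scale'")
  if (any(object@secondaryTraits %in% object@primaryTraits))
    return("a trait cannot be both primary and secondary")
  if (!all(object@cvTraits %in% object@primaryTraits))
    return("cvTraits must be primary traits")
  TRUE
})

#' Construct a RunConfig
#'
#' The demo profile runs at reduced problem size (2,000 markers, 20 CV
#' replicates, 500/3,000 Gibbs iterations) and its outputs are labelled
#' scaled-down; paper-scale uses 27,466 markers, 100 replicates and
#' 2000/12,000 iterations.
#'
#' @param outDir output directory.
#' @param seed global seed.
#' @param profile "demo" or "paper-scale".
#' @param markerFile,trialFile optional input CSVs (see
#'   \code{\link{readMarkerCSV}}, \code{\link{readTrialCSV}}); omit to
#'   simulate.
#' @param design a \code{\link{designSpec}}.
#' @param simPar simulation parameters; defaults to
#'   \code{\link{defaultSimParams}} for the design.
#' @param nMarkers,nReps,gibbs override the profile's problem sizes.
#' @param primaryTraits,secondaryTraits,datasets,cvTraits see
#'   \code{\linkS4class{RunConfig}}.
#' @return a \code{RunConfig}.
#' @export
runConfig <- function(outDir, seed = 1, profile = c("demo", "paper-scale"),
                      markerFile = "", trialFile = "",
                      design = designSpec(), simPar = NULL,
                      nMarkers = NULL, nReps = NULL, gibbs = NULL,
                      primaryTraits = c("HI", "GY", "GN", "SPI", "FE"),
                      secondaryTraits = c("CT", "NDVI"),
                      datasets = "combined", cvTraits = primaryTraits) {
  profile <- match.arg(profile)
  if (is.null(simPar))
    simPar <- defaultSimParams(nEnv = length(design@environments),
                               nRep = design@nRep)
  if (is.null(nMarkers)) nMarkers <- if (profile == "demo") 2000 else 27466
  if (is.null(nReps)) nReps <- if (profile == "demo") 20 else 100
  if (is.null(gibbs)) {
    gibbs <- if (profile == "demo")
      gibbsConfig(burnIn = 500, nIter = 3000, seed = seed)
    else gibbsConfig(seed = seed)
  }
  new("RunConfig", outDir = outDir, seed = seed, profile = profile,
      markerFile = markerFile, trialFile = trialFile, design = design,
      simPar = simPar, nMarkers = nMarkers, primaryTraits = primaryTraits,
      secondaryTraits = secondaryTraits, datasets = datasets,
      cvTraits = cvTraits, gibbs = gibbs, nReps = nReps)
}

.log_line <- function(outDir, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  paste0(...))
  cat(line, "\n", file = file.path(outDir, "run.log"), append = TRUE, sep = "")
}

.sig_code <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "c", ifelse(p < 0.005, "b",
                                                     ifelse(p < 0.05, "a", ""))))
}

#' Run the full analysis pipeline
#'
#' Stages (any subset, in this order): \code{simulate} writes markers, trial
#' and ground truth; \code{kinship} imputes markers and writes K;
#' \code{blues} writes one BLUE table per requested dataset plus the
#' ANOVA-mean-squares, summary-with-heritability and trait-correlation CSVs;
#' \code{cv} runs ST-CV1 / MT-CV1 / MT-CV2 on shared splits for every CV
#' trait and dataset and writes the predictive-ability table (with percent
#' increase from ST-CV1 to MT-CV2), the per-replicate long table and a
#' bar-chart-ready per-scheme summary. Later stages read their inputs from
#' \code{outDir}, so a partial run is resumable. Identical configurations
#' give bit-identical outputs.
#'
#' @param config a \code{\link{runConfig}}.
#' @param stages character subset of
#'   \code{c("simulate", "kinship", "blues", "cv")} or \code{"all"}.
#' @return invisibly, a named list of the files written.
#' @export
runPipeline <- function(config, stages = "all") {
  stopifnot(is(config, "RunConfig"))
  all_stages <- c("simulate", "kinship", "blues", "cv")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  out <- config@outDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  pf <- function(name) file.path(out, name)
  .log_line(out, "pipeline start; profile=", config@profile,
            " seed=", config@seed, " stages=", paste(stages, collapse = ","),
            " (R ", getRversion(), ")")

  ds <- config@design
  ids <- c(sprintf("L%03d", seq_len(ds@nLines)),
           if (ds@nChecks > 0) sprintf("CHK%d", seq_len(ds@nChecks)))

  if ("simulate" %in% stages) {
    if (nzchar(config@markerFile)) {
      markers <- readMarkerCSV(config@markerFile)
      .log_line(out, "markers loaded from ", config@markerFile)
    } else {
      markers <- simulateMarkers(length(ids), config@nMarkers,
                                 seed = config@seed, lineIds = ids)
      .log_line(out, "markers simulated: ", length(ids), " x ", config@nMarkers)
    }
    files$markers <- writeMarkerCSV(markers, pf("markers.csv"))
    if (nzchar(config@trialFile)) {
      trial <- readTrialCSV(config@trialFile)
      .log_line(out, "trial loaded from ", config@trialFile)
    } else {
      sim <- simulateTrial(markers, ds, config@simPar, seed = config@seed + 1)
      trial <- sim$trial
      files$truth <- writeSimTruth(sim$truth, pf("sim_truth.yaml"))
      .log_line(out, "trial simulated: ", nrow(as.data.frame(trial)), " plots; ",
                "target h2 = ", paste(sprintf("%.2f", sim$truth@heritabilities),
                                      collapse = ","))
    }
    files$trial <- writeTrialCSV(trial, pf("trial.csv"))
  }

  if ("kinship" %in% stages) {
    markers <- readMarkerCSV(pf("markers.csv"))
    imp <- imputeMissing(markers)
    if (!identical(as.matrix(imp), as.matrix(markers)))
      .log_line(out, "imputation: per-marker-mean filled ",
                sum(is.na(as.matrix(markers))), " cells ",
                "(study pipeline used LD-KNNi in external software; ",
                "mean imputation is this package's default)")
    K <- additiveRelationship(imp)
    if (K@stabilized)
      .log_line(out, "kinship stabilized: epsilon = ", format(K@epsilon))
    files$kinship <- writeKinshipCSV(K, pf("kinship.csv"))
    .log_line(out, "kinship written: mean diagonal ",
              sprintf("%.3f", mean(diag(as.matrix(K)))))
  }

  if ("blues" %in% stages) {
    trial <- readTrialCSV(pf("trial.csv"))
    tn <- traitNames(trial)
    envs <- unique(as.data.frame(trial)$env)
    for (dset in config@datasets) {
      blues <- computeBlues(trial, dataset = dset)
      files[[paste0("blues_", dset)]] <-
        writeBlueCSV(blues, pf(sprintf("blues_%s.csv", dset)))
      corr <- traitCorrelations(blues)
      idx <- which(upper.tri(corr$r), arr.ind = TRUE)
      cor_df <- data.frame(trait1 = rownames(corr$r)[idx[, 1]],
                           trait2 = colnames(corr$r)[idx[, 2]],
                           r = corr$r[idx], p = corr$p[idx],
                           n = corr$n[idx])
      write.csv(cor_df, pf(sprintf("correlations_%s.csv", dset)),
                row.names = FALSE)
    }
    ## ANOVA mean squares (combined; needs >= 2 environments)
    if (length(envs) >= 2) {
      an <- do.call(rbind, lapply(tn, function(tr) {
        a <- anovaMeanSquares(trial, tr)
        data.frame(trait = tr,
                   MS_G = a$mean_sq[1], sig_G = .sig_code(a$p[1]),
                   MS_E = a$mean_sq[2], sig_E = .sig_code(a$p[2]),
                   MS_GxE = a$mean_sq[3], sig_GxE = .sig_code(a$p[3]))
      }))
      write.csv(an, pf("anova_mean_squares.csv"), row.names = FALSE)
      files$anova <- pf("anova_mean_squares.csv")
    }
    ## summary with heritability
    summ <- do.call(rbind, lapply(config@datasets, function(dset) {
      b <- as.matrix(readBlueCSV(pf(sprintf("blues_%s.csv", dset)), dset))
      do.call(rbind, lapply(colnames(b), function(tr) {
        h2 <- tryCatch(
          broadSenseHeritability(estimateVarianceComponents(trial, tr)),
          error = function(e) NA_real_)
        data.frame(dataset = dset, trait = tr,
                   mean = mean(b[, tr], na.rm = TRUE),
                   min = min(b[, tr], na.rm = TRUE),
                   max = max(b[, tr], na.rm = TRUE),
                   sd = sd(b[, tr], na.rm = TRUE), H2 = h2)
      }))
    }))
    write.csv(summ, pf("summary_heritability.csv"), row.names = FALSE)
    files$summary <- pf("summary_heritability.csv")
    .log_line(out, "blues written for: ", paste(config@datasets, collapse = ", "))
  }

  if ("cv" %in% stages) {
    K <- readKinshipCSV(pf("kinship.csv"))
    gcfg <- config@gibbs
    .log_line(out, "cv: ", config@nReps, " reps, chains ", gcfg@burnIn, "/",
              gcfg@nIter, ", priors: variance df ", gcfg@priorDfVariance,
              ", Wishart df ", ifelse(is.na(gcfg@priorDfWishart), "t+3",
                                      gcfg@priorDfWishart),
              if (config@profile == "demo") " [scaled-down demo profile]" else "")
    tab4 <- NULL; long <- NULL; fig <- NULL
    for (dset in config@datasets) {
      blues <- readBlueCSV(pf(sprintf("blues_%s.csv", dset)), dset)
      panel <- lineIds(blues)  # checks are excluded from GS by construction
      splits <- makeSplits(panel, trainFraction = ds@trainFraction,
                           nReps = config@nReps, seed = config@seed + 17)
      for (tr in config@cvTraits) {
        res <- lapply(c("ST-CV1", "MT-CV1", "MT-CV2"), function(sch) {
          runScheme(blues, K, maskSpec(sch, tr, config@secondaryTraits),
                    splits, gcfg)
        })
        names(res) <- c("ST-CV1", "MT-CV1", "MT-CV2")
        pct <- suppressWarnings(percentIncrease(res[["ST-CV1"]], res[["MT-CV2"]]))
        tab4 <- rbind(tab4, data.frame(
          dataset = dset, trait = tr, profile = config@profile,
          ST_CV1 = res[["ST-CV1"]]@meanR, MT_CV1 = res[["MT-CV1"]]@meanR,
          MT_CV2 = res[["MT-CV2"]]@meanR, pct_increase = pct))
        for (sch in names(res)) {
          r <- res[[sch]]
          fig <- rbind(fig, data.frame(dataset = dset, trait = tr, scheme = sch,
                                       mean_r = r@meanR, se_r = r@seR,
                                       n_valid = r@nValidReps,
                                       profile = config@profile))
          long <- rbind(long, data.frame(dataset = dset, trait = tr,
                                         scheme = sch,
                                         rep = seq_along(r@perRepR),
                                         r = r@perRepR))
        }
        .log_line(out, sprintf("cv %s/%s: ST-CV1 %.3f MT-CV1 %.3f MT-CV2 %.3f (+%.1f%%)",
                               dset, tr, res[["ST-CV1"]]@meanR,
                               res[["MT-CV1"]]@meanR, res[["MT-CV2"]]@meanR, pct))
      }
    }
    write.csv(tab4, pf("predictive_ability.csv"), row.names = FALSE)
    write.csv(long, pf("predictive_ability_reps.csv"), row.names = FALSE)
    write.csv(fig, pf("predictive_ability_summary.csv"), row.names = FALSE)
    files$cv <- pf("predictive_ability.csv")
  }

  .log_line(out, "pipeline done")
  invisible(files)
}
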