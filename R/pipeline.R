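## End-to-end in-silico study: generate a cohort of synthetic animals,
## fit T1 maps pre/post contrast, segment plaque on the anatomy scans,
## quantify TPV and delta-R1, and run the group statistics.

## Group calibration ladders: nominal per-week plaque delta-R1 (s^-1) and
## MRI-scale plaque volume (mm^3) used to size the synthetic lesions.
.ladders <- list(
  progression = list(weeks = c(9, 13, 17, 21),
                     deltaR1 = c(0.28, 0.5, 1.06, 3.29),
                     tpv = c(0.44, 0.63, 1.36, 1.91)),
  regression = list(weeks = c(13, 19, 25),
                    deltaR1 = c(0.49, 0.58, 1.33),
                    tpv = c(1.04, 1.25, 1.45)),
  wildtype = list(weeks = c(9, 13, 17, 21),
                  deltaR1 = c(0, 0, 0, 0),
                  tpv = c(0, 0, 0, 0))
)

## en-face analog scalings: area per MRI-scale volume (mm^2 / mm^3) and
## the volume shrinkage of the ex vivo preparation relative to MRI
.kTPA <- 71.2e-3 / 1.91
.kEnface <- 0.46 / 1.91

#' Phantom preset for a study group and week
#'
#' Builds a [PhantomSpec] whose plaque load follows the group's
#' calibration ladder: the plaque Gd concentration is `deltaR1 / r1` for
#' the week's nominal delta-R1, and one wall-attached ellipsoidal lesion
#' is sized to the week's nominal volume.  Per-animal lognormal
#' variability (coefficient of variation `variability`) and the lesion's
#' angular position are drawn reproducibly from `seed`.
#'
#' @param group `"progression"`, `"regression"` or `"wildtype"`.
#' @param week time point; must be one of the group's scheduled weeks
#'   (progression 9/13/17/21 on diet, regression 13/19/25 after the diet
#'   switch).
#' @param seed integer seed for this animal.
#' @param variability lognormal CV of per-animal plaque size and uptake.
#' @param noiseSigma SR magnitude-noise fraction.
#' @param gridShape,voxelSize grid geometry.
#' @param r1Agent agent relaxivity, L mmol^-1 s^-1.
#' @return A [PhantomSpec].
#' @export
#' @examples
#' phantomPreset("progression", 21, seed = 7)
phantomPreset <- function(group = c("progression", "regression", "wildtype"),
                          week, seed, variability = 0.25, noiseSigma = 0.02,
                          gridShape = c(32L, 32L, 10L),
                          voxelSize = c(0.18, 0.18, 0.22), r1Agent = 18) {
  group <- match.arg(group)
  lad <- .ladders[[group]]
  iw <- match(week, lad$weeks)
  if (is.na(iw))
    stop(sprintf("week %s is not scheduled for the %s group (%s)",
                 week, group, paste(lad$weeks, collapse = ", ")))
  set.seed(seed)
  theta <- stats::runif(1, 0, 2 * pi)
  sdlog <- sqrt(log(1 + variability^2))
  volScale <- stats::rlnorm(1, -sdlog^2 / 2, sdlog)
  uptScale <- stats::rlnorm(1, -sdlog^2 / 2, sdlog)

  lumenRadius <- 0.55; wallThickness <- 0.2
  center <- c(0, 0) + (gridShape[1:2] - 1) / 2 * voxelSize[1:2]
  zc <- (gridShape[3] - 1) / 2 * voxelSize[3]

  vol <- lad$tpv[iw] * volScale
  plaques <- if (group == "wildtype" || vol <= 0) {
    data.frame(cx = numeric(), cy = numeric(), cz = numeric(),
               ax = numeric(), ay = numeric(), az = numeric())
  } else {
    ## one ellipsoid a = b in-plane, c = 0.7 a axially, centred on the
    ## outer wall surface; 4/3 pi a^2 c = vol
    a <- (vol / (4 / 3 * pi * 0.7))^(1 / 3)
    rad <- lumenRadius + wallThickness
    data.frame(cx = center[1] + rad * cos(theta),
               cy = center[2] + rad * sin(theta),
               cz = zc, ax = a, ay = a, az = 0.7 * a)
  }
  cGd <- lad$deltaR1[iw] / r1Agent * uptScale
  phantomSpec(gridShape = gridShape, voxelSize = voxelSize,
              plaques = plaques,
              gdConcentration = c(background = 0, blood = 0, wall = 0,
                                  plaque = cGd),
              r1Agent = r1Agent, noiseSigma = noiseSigma, seed = seed)
}

#' Study configuration
#'
#' @slot animals data.frame with one synthetic animal per row: `case`,
#'   `group`, `week`.
#' @slot seed global seed; per-case seeds are derived by a counter scheme
#'   so adding cases does not perturb existing ones.
#' @slot delays,tr SR protocol (ms).
#' @slot anatomyTI,anatomyTR anatomy protocol (ms).
#' @slot passes,smoothRadius T1-fit settings.
#' @slot hiResFactor,anatomyShift,anatomyNoiseSigma anatomy settings.
#' @slot noiseSigma SR noise fraction.
#' @slot thresholdPolicy `"difference"` (threshold the post - pre anatomy
#'   difference at `thresholdK` robust noise SDs) or `"fixed"` (use
#'   `thresholdValue` on the post anatomy).
#' @slot thresholdK,thresholdValue,minComponent segmentation settings.
#' @slot variability per-animal lognormal CV.
#' @slot gridShape,voxelSize phantom grid.
#' @slot outputDir optional directory for per-case NIfTI output
#'   (length-0 character to skip).
#' @export
setClass("StudyConfig", representation(
  animals = "data.frame", seed = "integer",
  delays = "numeric", tr = "numeric",
  anatomyTI = "numeric", anatomyTR = "numeric",
  passes = "integer", smoothRadius = "integer",
  hiResFactor = "integer", anatomyShift = "numeric",
  anatomyNoiseSigma = "numeric", noiseSigma = "numeric",
  thresholdPolicy = "character", thresholdK = "numeric",
  thresholdValue = "numeric", minComponent = "integer",
  variability = "numeric", gridShape = "integer", voxelSize = "numeric",
  outputDir = "character"
))

setValidity("StudyConfig", function(object) {
  msg <- character()
  if (!all(c("case", "group", "week") %in% names(object@animals)))
    msg <- c(msg, "animals needs columns case, group, week")
  if (!all(object@animals$group %in% names(.ladders)))
    msg <- c(msg, "groups must be progression, regression or wildtype")
  if (!object@thresholdPolicy %in% c("difference", "fixed"))
    msg <- c(msg, "thresholdPolicy must be 'difference' or 'fixed'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "StudyConfig", function(object) {
  cat("StudyConfig:", nrow(object@animals), "synthetic animals (",
      paste(sprintf("%s=%d", names(table(object@animals$group)),
                    as.integer(table(object@animals$group))), collapse = ", "),
      "), seed", object@seed, "\n")
  cat("  SR delays (ms):", paste(object@delays, collapse = ", "),
      "| TR", object@tr, "| passes", object@passes, "\n")
})

#' Default study configuration
#'
#' The study design: 5 animals per group and time point, progression
#' imaged at 9/13/17/21 weeks on diet (20 animals) and regression at
#' 13/19/25 weeks after the diet switch (15 animals); each (animal,
#' week) is one independent synthetic case.
#'
#' @param seed global seed.
#' @param nPerGroup animals per group and time point.
#' @param groups subset of `"progression"`, `"regression"`, `"wildtype"`.
#' @param ... overrides for any [StudyConfig] slot.
#' @return A [StudyConfig].
#' @export
#' @examples
#' defaultStudyConfig(seed = 1)
defaultStudyConfig <- function(seed = 1L, nPerGroup = 5L,
                               groups = c("progression", "regression"),
                               ...) {
  rows <- do.call(rbind, lapply(groups, function(g) {
    wk <- .ladders[[g]]$weeks
    expand.grid(animal = seq_len(nPerGroup), week = wk, group = g,
                stringsAsFactors = FALSE)
  }))
  animals <- data.frame(case = seq_len(nrow(rows)), group = rows$group,
                        week = rows$week)
  cfg <- new("StudyConfig", animals = animals, seed = as.integer(seed),
             delays = c(77, 200, 350, 500, 1200), tr = 1500,
             anatomyTI = 250, anatomyTR = 650,
             passes = 3L, smoothRadius = 1L,
             hiResFactor = 1L, anatomyShift = c(0.09, 0.09, 0),
             anatomyNoiseSigma = 0.01, noiseSigma = 0.02,
             thresholdPolicy = "difference", thresholdK = 3,
             thresholdValue = NA_real_, minComponent = 5L,
             variability = 0.25, gridShape = c(32L, 32L, 10L),
             voxelSize = c(0.18, 0.18, 0.22), outputDir = character())
  dots <- list(...)
  for (nm in names(dots)) slot(cfg, nm) <- dots[[nm]]
  validObject(cfg)
  cfg
}

#' Read a study configuration from YAML
#'
#' Expects a top-level `schema: plaqueR1-study/1` key; all other keys
#' override [defaultStudyConfig()] arguments or slots.
#'
#' @param path YAML file path.
#' @return A [StudyConfig].
#' @export
readStudyConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$schema) || !identical(y$schema, "plaqueR1-study/1"))
    stop("config must declare schema: plaqueR1-study/1")
  y$schema <- NULL
  args <- y[names(y) %in% c("seed", "nPerGroup", "groups")]
  slots <- y[!names(y) %in% names(args)]
  slotTypes <- getSlots("StudyConfig")
  for (nm in names(slots)) {
    if (!nm %in% names(slotTypes)) stop("unknown config key: ", nm)
    slots[[nm]] <- switch(slotTypes[[nm]],
                          integer = as.integer(slots[[nm]]),
                          numeric = as.numeric(slots[[nm]]),
                          slots[[nm]])
  }
  do.call(defaultStudyConfig, c(args, slots))
}

## counter-based per-case seed fan-out (kept below 2^31)
.caseSeed <- function(globalSeed, case) {
  as.integer((as.numeric(globalSeed) * 97 + 7919 * as.numeric(case)) %%
               2147483587)
}

## intensity mask for T1 fitting: voxels with appreciable signal
.signalMask <- function(series, frac = 0.15) {
  mx <- apply(series@volumes, 1:3, max)
  mx > frac * max(mx)
}

## robust per-channel noise SD from the darkest voxels of the shortest
## delay volume.  The MAD (rather than the median) is insensitive to the
## weak true signal those voxels carry; for Rayleigh-distributed noise
## mad(x) = 0.6657 sigma.
.noiseFloorSd <- function(series, mask) {
  i <- which.min(series@delays)
  bg <- series@volumes[, , , i][!mask]
  if (!length(bg)) return(0)
  stats::mad(bg) / 0.6657
}

## segmentation of one case's anatomy per the configured policy.
## "difference": the agent accumulates only in plaque, so the post - pre
## anatomy difference is plaque-specific; it is smoothed in-plane (3x3)
## and thresholded at the larger of k robust-noise SDs and half the peak
## difference (full-width-half-maximum rule, compensating the smoothing
## blur at the lesion boundary).
.segmentCase <- function(study, cfg) {
  if (cfg@thresholdPolicy == "difference") {
    dif <- study@anatomyPost@volumes[, , , 1] - study@anatomyPre@volumes[, , , 1]
    if (stats::mad(dif) > 1e-9 * max(abs(dif), 1)) {
      ## noisy data: smooth in-plane before thresholding
      dif <- .boxMeanMasked(dif, array(TRUE, dim(dif)), 1L, inPlane = TRUE)
      thr <- max(cfg@thresholdK * stats::mad(dif), 0.5 * max(dif))
    } else {
      ## no measurable noise: any positive difference is enhancement
      thr <- 0.5 * max(dif)
    }
    thresholdSegment(dif, thr, cfg@minComponent,
                     voxelSize = study@anatomyPost@voxelSize,
                     fovOrigin = study@anatomyPost@fovOrigin)
  } else {
    thresholdSegment(study@anatomyPost, cfg@thresholdValue, cfg@minComponent)
  }
}

#' Study report
#'
#' @slot table per-case measurements and ground truth.
#' @slot trajectories per-measure group trajectories
#'   (see [groupTrajectory()]).
#' @slot correlations pairwise Pearson correlations among the measures.
#' @slot interobserver interobserver TPV correlation, or NULL-like empty
#'   list when skipped.
#' @slot provenance config echo, seed and package version.
#' @export
setClass("StudyReport", representation(
  table = "data.frame", trajectories = "list", correlations = "data.frame",
  interobserver = "list", provenance = "list"
))

setMethod("show", "StudyReport", function(object) {
  cat("StudyReport:", nrow(object@table), "cases\n")
  if (nrow(object@correlations)) {
    cat("  correlations:\n")
    for (i in seq_len(nrow(object@correlations)))
      cat(sprintf("    %s ~ %s: r = %.3f (%s), p = %.3g\n",
                  object@correlations$x[i], object@correlations$y[i],
                  object@correlations$r[i], object@correlations$category[i],
                  object@correlations$p[i]))
  }
  if (length(object@interobserver))
    cat(sprintf("  interobserver TPV r = %.3f (p = %.3g)\n",
                object@interobserver$r, object@interobserver$p))
})

## process one animal; returns a one-row data.frame of measures + truth
.runCase <- function(case, group, week, cfg, verbose = FALSE) {
  seed <- .caseSeed(cfg@seed, case)
  spec <- phantomPreset(group, week, seed, cfg@variability, cfg@noiseSigma,
                        cfg@gridShape, cfg@voxelSize)
  outDir <- if (length(cfg@outputDir))
    file.path(cfg@outputDir, sprintf("case%03d", case)) else NULL
  study <- makePairedStudy(spec, cfg@delays, cfg@tr, cfg@anatomyTI,
                           cfg@anatomyTR, cfg@hiResFactor, cfg@anatomyShift,
                           cfg@anatomyNoiseSigma, outDir = outDir)
  truth <- study@truth

  ## volumetry on the anatomy grid
  roisA <- .segmentCase(study, cfg)
  tpvMRI <- totalPlaqueVolume(roisA)@tpv
  roisB <- perturbROIs(roisA, seed + 31L)
  tpvB <- totalPlaqueVolume(roisB)@tpv

  ## relaxometry on the SR grid, with the Rician noise floor estimated
  ## from the background and removed before fitting
  mask <- .signalMask(study@pre)
  sdHat <- .noiseFloorSd(study@pre, mask)
  preMap <- fitMap(study@pre, cfg@passes, cfg@smoothRadius, mask,
                   noiseSd = sdHat)
  ## the B1 profile is a session constant: reuse the pre-contrast B field
  ## for the post map, which also cancels correlated B errors in delta-R1
  postMap <- fitMap(study@post, cfg@passes, cfg@smoothRadius, mask,
                    noiseSd = .noiseFloorSd(study@post, mask),
                    bField = bMap(preMap))
  dmap <- deltaR1(preMap, postMap)
  roisT1 <- transferROIs(roisA, dmap)
  dR1 <- if (any(roisT1@mask & dmap@mask)) roiMeanDeltaR1(dmap, roisT1) else 0

  ## fit accuracy against truth: pre-contrast T1 in the vessel wall and
  ## plaque (the tissue the method is about)
  m <- preMap@mask & (truth@labels == 2L | truth@labels == 3L)
  t1err <- if (any(m))
    stats::median(abs(preMap@t1Map[m] - truth@t1Pre[m]) / truth@t1Pre[m])
  else NA_real_

  ## en-face analogs from ground-truth geometry with measurement noise
  set.seed(seed + 41L)
  mnoise <- function() stats::rlnorm(1, -0.15^2 / 2, 0.15)
  tpa <- truth@plaqueVolume * .kTPA * mnoise()
  tpvEF <- truth@plaqueVolume * .kEnface * mnoise()

  cPlq <- spec@gdConcentration[["plaque"]]
  if (verbose)
    message(sprintf("case %d (%s w%s): TPV %.3f (truth %.3f), dR1 %.3f (truth %.3f)",
                    case, group, week, tpvMRI, truth@plaqueVolume, dR1,
                    spec@r1Agent * cPlq))
  data.frame(case = case, group = group, week = week, seed = seed,
             tpa_mm2 = tpa, tpv_enface_mm3 = tpvEF, tpv_mri_mm3 = tpvMRI,
             delta_r1_s1 = dR1, tpv_reader_b_mm3 = tpvB,
             truth_tpv_mm3 = truth@plaqueVolume,
             truth_delta_r1_s1 = spec@r1Agent * cPlq,
             t1_med_rel_err = t1err)
}

#' Run the full in-silico study
#'
#' For each synthetic animal: generate the paired pre/post study, fit
#' pre- and post-contrast T1 maps, compute the delta-R1 map, segment
#' plaque on the anatomy scans, transfer the ROIs to the map grid,
#' quantify TPV and mean plaque delta-R1, then summarize group
#' trajectories, cross-measure correlations and interobserver agreement.
#' Fully deterministic given the config seed.
#'
#' @param config a [StudyConfig].
#' @param verbose log per-case progress.
#' @return A [StudyReport].
#' @export
runStudy <- function(config, verbose = FALSE) {
  validObject(config)
  an <- config@animals
  rows <- vector("list", nrow(an))
  for (i in seq_len(nrow(an))) {
    rows[[i]] <- tryCatch(
      .runCase(an$case[i], an$group[i], an$week[i], config, verbose),
      error = function(e) stop(sprintf("case %d (stage failure): %s",
                                       an$case[i], conditionMessage(e))))
  }
  tab <- do.call(rbind, rows)

  measures <- c("tpa_mm2", "tpv_enface_mm3", "tpv_mri_mm3", "delta_r1_s1")
  plaqueTab <- tab[tab$group != "wildtype", , drop = FALSE]

  traj <- lapply(stats::setNames(measures, measures), function(m) {
    tryCatch(groupTrajectory(tab, m), error = function(e) NULL)
  })

  cors <- data.frame()
  inter <- list()
  if (nrow(plaqueTab) >= 3 && any(plaqueTab$truth_tpv_mm3 > 0)) {
    prs <- utils::combn(measures, 2)
    cors <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
      cr <- pearsonCorrelation(plaqueTab[[prs[1, j]]], plaqueTab[[prs[2, j]]])
      data.frame(x = prs[1, j], y = prs[2, j], r = cr@r, p = cr@p,
                 n = cr@n, category = cr@category)
    }))
    if (stats::sd(plaqueTab$tpv_mri_mm3) > 0 &&
        stats::sd(plaqueTab$tpv_reader_b_mm3) > 0) {
      cr <- pearsonCorrelation(plaqueTab$tpv_mri_mm3,
                               plaqueTab$tpv_reader_b_mm3)
      inter <- list(r = cr@r, p = cr@p, n = cr@n, category = cr@category)
    }
  } else {
    message("correlations skipped: no plaque-bearing cases with nonzero measures")
  }

  new("StudyReport", table = tab, trajectories = traj, correlations = cors,
      interobserver = inter,
      provenance = list(
        seed = config@seed, n_cases = nrow(an),
        delays_ms = config@delays, tr_ms = config@tr,
        passes = config@passes, threshold_policy = config@thresholdPolicy,
        package_version = as.character(utils::packageVersion("plaqueR1"))))
}

#' Estimate-versus-truth recovery benchmark
#'
#' Per-case comparison of the pipeline's estimates with the generator's
#' ground truth for TPV, plaque delta-R1 and pre-contrast T1, with
#' aggregate bias, RMSE and Pearson correlation.
#'
#' @param config a [StudyConfig], or an existing [StudyReport] from
#'   [runStudy()] to avoid recomputation.
#' @return List with `cases` (per-case truth/estimate/relative error)
#'   and `summary` (per-measure bias, RMSE, Pearson r).
#' @export
recoveryBenchmark <- function(config) {
  rep_ <- if (is(config, "StudyReport")) config else runStudy(config)
  tab <- rep_@table
  cases <- data.frame(
    case = tab$case, group = tab$group, week = tab$week,
    tpv_truth = tab$truth_tpv_mm3, tpv_est = tab$tpv_mri_mm3,
    tpv_rel_err = ifelse(tab$truth_tpv_mm3 > 0,
                         (tab$tpv_mri_mm3 - tab$truth_tpv_mm3) /
                           tab$truth_tpv_mm3, NA_real_),
    dr1_truth = tab$truth_delta_r1_s1, dr1_est = tab$delta_r1_s1,
    dr1_rel_err = ifelse(tab$truth_delta_r1_s1 > 0,
                         (tab$delta_r1_s1 - tab$truth_delta_r1_s1) /
                           tab$truth_delta_r1_s1, NA_real_),
    t1_med_rel_err = tab$t1_med_rel_err)
  summarize <- function(truth, est) {
    ok <- is.finite(truth) & is.finite(est)
    r <- if (sum(ok) >= 3 && stats::sd(truth[ok]) > 0 &&
             stats::sd(est[ok]) > 0)
      pearsonCorrelation(truth[ok], est[ok])@r else NA_real_
    c(bias = mean(est[ok] - truth[ok]),
      rmse = sqrt(mean((est[ok] - truth[ok])^2)), pearson_r = r)
  }
  list(cases = cases,
       summary = rbind(tpv = summarize(cases$tpv_truth, cases$tpv_est),
                       delta_r1 = summarize(cases$dr1_truth, cases$dr1_est)),
       t1_median_rel_err = stats::median(cases$t1_med_rel_err, na.rm = TRUE))
}
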