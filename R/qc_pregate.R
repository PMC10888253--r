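# Stage-1/stage-2 event cleanup: acquisition-time signal QC, doublet
# exclusion by a robust FSC-A/FSC-H linear separator, and low-scatter
# debris removal.

#' Acquisition-time signal quality control
#'
#' Events are split into `n_bins` equal-count time bins.  A bin is dropped
#' when its acquisition rate (bin duration) or any channel's level (bin
#' mean on the analysis scale) departs from the cross-bin median by more
#' than `mad_k` robust (MAD-scaled) deviations; this targets abrupt
#' fluctuations in flow, voltage or staining conditions rather than slow
#' trends.  Bin means rather than medians are compared because the median
#' of a bimodal channel flaps between modes under per-bin composition
#' noise.  Samples without a time channel pass through with a warning.
#'
#' @param sample a `cg_sample` (conventionally transformed, so fluorescence
#'   shifts are additive).
#' @param n_bins number of equal-count time bins (default 50).
#' @param mad_k robust deviation multiplier (default 5).
#' @param min_events_required minimum acquisition size for the panel
#'   (default 100000).
#' @return a `cg_qc` result: logical keep `mask`, `bins_dropped` table,
#'   `pass_min_events` flag.
#' @export
time_qc <- function(sample, n_bins = 50, mad_k = 5, min_events_required = 100000) {
  n <- n_events(sample)
  pass_min <- n >= min_events_required
  if (is.null(sample$time)) {
    warning("sample has no time channel; time QC is a pass-through")
    return(structure(list(
      mask = rep(TRUE, n), bins_dropped = data.frame(),
      min_events_required = min_events_required, pass_min_events = pass_min
    ), class = "cg_qc"))
  }
  if (n < n_bins * 20)
    cg_stop("cg_data_error", "time QC needs at least %d events (got %d)",
            n_bins * 20, n)
  stopifnot(!is.unsorted(sample$time))

  bin <- as.integer(cut(seq_len(n), breaks = n_bins, labels = FALSE))
  tsplit <- split(sample$time, bin)
  dur <- vapply(tsplit, function(t) diff(range(t)), 1)

  robust_out <- function(x) {
    med <- median(x)
    s <- mad(x)
    abs(x - med) > mad_k * s + 1e-9
  }
  drop_rate <- robust_out(dur)

  # per-channel binned medians (exclude the time channel itself)
  chan <- which(gsub("[^A-Z0-9]", "", toupper(colnames(sample$events))) != "TIME")
  drop_level <- rep(FALSE, n_bins)
  for (j in chan) {
    lev_j <- vapply(split(sample$events[, j], bin), mean, 1)
    drop_level <- drop_level | robust_out(lev_j)
  }

  dropped <- drop_rate | drop_level
  if (all(dropped))
    cg_stop("cg_sample_rejected", "time QC dropped every bin; sample rejected")
  mask <- !dropped[bin]
  bins_dropped <- data.frame(
    bin = which(dropped),
    t_lo = vapply(tsplit[dropped], min, 1),
    t_hi = vapply(tsplit[dropped], max, 1),
    reason = ifelse(drop_rate[dropped], "rate", "level")
  )
  structure(list(
    mask = mask, bins_dropped = bins_dropped,
    min_events_required = min_events_required, pass_min_events = pass_min
  ), class = "cg_qc")
}

#' Fit the singlet ridge in FSC-A/FSC-H
#'
#' Robust (iteratively reweighted, bisquare) linear regression of FSC-H on
#' FSC-A.  Single cells fall on a tight line; doublets carry excess area
#' relative to height and are down-weighted by the robust fit.
#'
#' @param fsc_a,fsc_h per-event forward-scatter area and height.
#' @param ratio_threshold allowed relative FSC-A excess over the ridge
#'   prediction before an event is called a doublet (default 0.25).
#' @return a `cg_doublet_model` with `slope`, `intercept`,
#'   `ratio_threshold`.
#' @export
fit_doublet_model <- function(fsc_a, fsc_h, ratio_threshold = 0.25) {
  if (length(fsc_a) < 100)
    cg_stop("cg_data_error", "doublet model needs at least 100 events")
  if (sd(fsc_a) == 0 || sd(fsc_h) == 0)
    cg_stop("cg_fit_error", "degenerate scatter: zero variance in FSC-A or FSC-H")
  fit <- suppressWarnings(
    MASS::rlm(fsc_h ~ fsc_a, psi = MASS::psi.bisquare, maxit = 100)
  )
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    cg_stop("cg_fit_error", "doublet ridge fit failed (slope %.3g)", slope)
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 ratio_threshold = ratio_threshold),
            class = "cg_doublet_model")
}

#' Doublet exclusion mask
#'
#' An event is a doublet when its FSC-A exceeds the ridge-predicted area
#' `(FSC-H - intercept) / slope` by more than the model's relative
#' threshold.  The rule is invariant to rescaling both scatter axes by a
#' common factor.
#'
#' @param fsc_a,fsc_h per-event scatter values.
#' @param model a [fit_doublet_model()] result.
#' @return logical keep mask (`FALSE` = doublet).
#' @export
remove_doublets <- function(fsc_a, fsc_h, model) {
  stopifnot(inherits(model, "cg_doublet_model"))
  pred_a <- (fsc_h - model$intercept) / model$slope
  !(fsc_a > pred_a * (1 + model$ratio_threshold))
}

# Find the density valley between a low-intensity mode and the main mass;
# NA when no distinct low mode exists.
valley_cut <- function(v, min_peak_frac = 0.01) {
  d <- density(v, n = 512)
  y <- d$y; x <- d$x
  k <- length(y)
  is_peak <- c(FALSE, y[2:(k - 1)] > y[1:(k - 2)] & y[2:(k - 1)] >= y[3:k], FALSE)
  peaks <- which(is_peak & y >= min_peak_frac * max(y))
  if (length(peaks) < 2) return(NA_real_)
  p1 <- peaks[1]; p2 <- peaks[2]
  # a "low mode" must be clearly below the bulk of the data
  if (x[p1] > quantile(v, 0.35)) return(NA_real_)
  valley <- p1 + which.min(y[(p1 + 1):(p2 - 1)])
  min(x[valley], median(v))
}

#' Debris removal by low FSC-A / low SSC-A
#'
#' Debris (subcellular fragments) sits in a joint low-scatter mode.  On
#' each axis the cut is placed at the density valley between the lowest
#' mode and the leukocyte modes; when no distinct low mode exists the cut
#' falls back to the configured quantile floor.  An event is dropped only
#' when *both* FSC-A and SSC-A are below their cuts.
#'
#' @param fsc_a,ssc_a per-event scatter values (linear scale).
#' @param fsc_quantile,ssc_quantile fallback quantile floors (default 0.02).
#' @return logical keep mask (`FALSE` = debris).
#' @export
remove_debris <- function(fsc_a, ssc_a, fsc_quantile = 0.02, ssc_quantile = 0.02) {
  cut_f <- valley_cut(fsc_a)
  cut_s <- valley_cut(ssc_a)
  if (is.na(cut_f)) cut_f <- quantile(fsc_a, fsc_quantile, names = FALSE)
  if (is.na(cut_s)) cut_s <- quantile(ssc_a, ssc_quantile, names = FALSE)
  !(fsc_a < cut_f & ssc_a < cut_s)
}

#' Full pre-gating: time QC, then doublets, then debris
#'
#' Runs the stage-1/stage-2 cleanup in fixed order on a matched,
#' transformed sample.  Each event is attributed to the first stage that
#' drops it.  The viability proxy is the fraction of events surviving
#' doublet and debris removal among events that passed time QC; the panel
#' carries no viability dye, so this is a scatter-based proxy, not a dye
#' measurement.
#'
#' @param sample a transformed, tube-matched `cg_sample`.
#' @param tube the `cg_tube` the sample was matched to.
#' @param params optional overrides: `n_bins`, `mad_k`,
#'   `min_events_required`, `ratio_threshold`, `fsc_quantile`,
#'   `ssc_quantile`, `min_surviving` (default 500).
#' @return a `cg_clean` object: filtered `sample`, cumulative keep `mask`,
#'   per-event `stage` attribution, `qc`, `doublet_model`,
#'   `fractions_removed`, `viability_proxy`.
#' @export
pregate <- function(sample, tube, params = list()) {
  p <- modifyList(list(n_bins = 50, mad_k = 5, min_events_required = 100000,
                       ratio_threshold = 0.25, fsc_quantile = 0.02,
                       ssc_quantile = 0.02, min_surviving = 500), params)
  n <- n_events(sample)
  if (n == 0) cg_stop("cg_sample_rejected", "empty sample")

  qc <- time_qc(sample, n_bins = p$n_bins, mad_k = p$mad_k,
                min_events_required = p$min_events_required)
  stage <- rep("kept", n)
  stage[!qc$mask] <- "time_qc"

  sc <- scatter_columns(sample, tube)
  alive <- qc$mask
  model <- fit_doublet_model(sc[alive, "fsc_a"], sc[alive, "fsc_h"],
                             ratio_threshold = p$ratio_threshold)
  keep_d <- remove_doublets(sc[, "fsc_a"], sc[, "fsc_h"], model)
  stage[alive & !keep_d] <- "doublet"
  alive <- alive & keep_d

  keep_db <- rep(TRUE, n)
  keep_db[alive] <- remove_debris(sc[alive, "fsc_a"], sc[alive, "ssc_a"],
                                  fsc_quantile = p$fsc_quantile,
                                  ssc_quantile = p$ssc_quantile)
  stage[alive & !keep_db] <- "debris"
  alive <- alive & keep_db

  if (sum(alive) < p$min_surviving)
    cg_stop("cg_sample_rejected",
            "only %d events survive pre-gating (< %d); sample rejected",
            sum(alive), p$min_surviving)

  n_postqc <- sum(qc$mask)
  fractions <- c(time_qc = mean(stage == "time_qc"),
                 doublets = mean(stage == "doublet"),
                 debris = mean(stage == "debris"))
  clean_sample <- sample
  clean_sample$events <- sample$events[alive, , drop = FALSE]
  if (!is.null(sample$time)) clean_sample$time <- sample$time[alive]

  structure(list(
    sample = clean_sample,
    mask = alive,
    stage = stage,
    qc = qc,
    doublet_model = model,
    fractions_removed = fractions,
    viability_proxy = sum(alive) / max(1L, n_postqc)
  ), class = "cg_clean")
}
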