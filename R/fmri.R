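# Functional-run preprocessing into trial patterns, ROI extraction in common
# space, and supervised cross-subject t-score voxel selection.

#' A functional (task) run
#'
#' Wraps a time-by-voxel signal matrix (TR units) with its trial event table.
#' The event table has one row per phase per trial with columns `trial`,
#' `phase` (`Rest` / `Control` / `Attention`), `onset` and `duration`
#' (seconds from run start) and `side` (`left` / `right`, meaningful for the
#' Attention phase). Each trial must contain exactly one Attention phase and
#' all events must lie within the run.
#'
#' @param signal numeric matrix, time (rows, TRs) by voxel (columns).
#' @param events event data frame as above.
#' @param subject,run identifiers.
#' @param grid `list(dim, affine, mask)` describing the voxel grid; `voxels`
#'   gives the linear grid index of each signal column (defaults to all
#'   voxels).
#' @param voxels linear grid indices of the signal columns.
#' @param tr repetition time in seconds (default 2).
#' @return an object of class `functional_run`.
#' @export
functional_run <- function(signal, events, subject = "sub01", run = 1L,
                           grid = NULL, voxels = NULL, tr = 2) {
  signal <- as.matrix(signal)
  stopifnot(is.data.frame(events),
            all(c("trial", "phase", "onset", "duration") %in% names(events)))
  dur <- nrow(signal) * tr
  if (any(events$onset + events$duration > dur + 1e-9))
    stop("events extend beyond the run duration")
  att <- events[events$phase == "Attention", ]
  if (any(table(att$trial) != 1) || !setequal(att$trial, unique(events$trial)))
    stop("each trial must have exactly one Attention phase")
  if (is.null(voxels)) voxels <- seq_len(ncol(signal))
  structure(list(signal = signal, events = events, subject = subject,
                 run = run, grid = grid, voxels = as.integer(voxels), tr = tr),
            class = "functional_run")
}

#' Preprocessing configuration for functional runs
#'
#' @param drop_initial initial volumes discarded (T1-equilibration; default 5).
#' @param hemodynamic_delay label shift in TRs applied to phase windows
#'   (default 2 TRs = 4 s).
#' @param detrend per-voxel linear detrending.
#' @param winsor_mad winsorize samples beyond this many MADs from the voxel
#'   median (`Inf` disables; default 4).
#' @param baseline subtract the same trial's Control-phase mean.
#' @param zscore z-score each voxel across the run's trials.
#' @return a list of class `prep_config`.
#' @export
prep_config <- function(drop_initial = 5, hemodynamic_delay = 2,
                        detrend = TRUE, winsor_mad = 4, baseline = TRUE,
                        zscore = TRUE) {
  structure(list(drop_initial = drop_initial,
                 hemodynamic_delay = hemodynamic_delay, detrend = detrend,
                 winsor_mad = winsor_mad, baseline = baseline,
                 zscore = zscore), class = "prep_config")
}

# TR indices (1-based, original timeline) covered by [onset, onset+duration)
phase_volumes <- function(onset, duration, tr) {
  t0 <- floor(onset / tr + 1e-9) + 1
  t1 <- floor((onset + duration) / tr + 1e-9)
  if (t1 < t0) integer(0) else seq.int(t0, t1)
}

#' Preprocess a functional run into trial patterns
#'
#' Pipeline, in order: (1) drop the first `drop_initial` volumes; (2) shift
#' the phase windows by the hemodynamic delay; (3) per-voxel linear detrend;
#' (4) winsorize temporal outliers beyond `winsor_mad` MADs from the voxel
#' median; (5) average volumes within each Attention phase; (6) subtract the
#' same trial's Control-phase mean; (7) z-score each voxel across the run's
#' trials. Trials truncated by the run end are dropped with a warning;
#' zero-variance voxels at step (7) yield 0 and are flagged.
#'
#' @param run a [functional_run()].
#' @param config a [prep_config()].
#' @return a `trial_patterns` object: matrix `X` (trials by voxels, z-units),
#'   `labels` (+1 attend-left / -1 attend-right), `runs`, `subject`, `grid`,
#'   `voxels`, and `flagged` (zero-variance voxel columns).
#' @export
preprocess_run <- function(run, config = prep_config()) {
  stopifnot(inherits(run, "functional_run"))
  cf <- config
  X <- run$signal
  Tn <- nrow(X)
  keep <- seq.int(cf$drop_initial + 1, Tn)
  shift <- cf$hemodynamic_delay

  if (cf$detrend) {
    tt <- keep
    B <- cbind(1, tt - mean(tt))
    X[keep, ] <- X[keep, , drop = FALSE] -
      B %*% qr.coef(qr(B), X[keep, , drop = FALSE])
  }
  if (is.finite(cf$winsor_mad)) {
    med <- apply(X[keep, , drop = FALSE], 2, median)
    md <- apply(X[keep, , drop = FALSE], 2, mad)
    hi <- med + cf$winsor_mad * md
    lo <- med - cf$winsor_mad * md
    X[keep, ] <- pmin(pmax(X[keep, , drop = FALSE],
                           matrix(lo, length(keep), ncol(X), byrow = TRUE)),
                      matrix(hi, length(keep), ncol(X), byrow = TRUE))
  }

  trials <- sort(unique(run$events$trial))
  feats <- list()
  labels <- integer(0)
  dropped <- 0
  for (tri in trials) {
    ev <- run$events[run$events$trial == tri, ]
    att <- ev[ev$phase == "Attention", ]
    ctl <- ev[ev$phase == "Control", ]
    idx_att <- phase_volumes(att$onset, att$duration, run$tr) + shift
    idx_ctl <- if (nrow(ctl)) phase_volumes(ctl$onset, ctl$duration, run$tr) + shift
               else integer(0)
    if (length(idx_att) == 0 || max(idx_att) > Tn ||
        min(idx_att) <= cf$drop_initial) {
      dropped <- dropped + 1
      next
    }
    f <- colMeans(X[idx_att, , drop = FALSE])
    if (cf$baseline && length(idx_ctl) > 0 && max(idx_ctl) <= Tn)
      f <- f - colMeans(X[idx_ctl, , drop = FALSE])
    feats[[length(feats) + 1]] <- f
    labels <- c(labels, if (identical(att$side, "left")) 1L else -1L)
  }
  if (dropped > 0)
    warning(dropped, " trial(s) truncated by the run end; dropped")
  if (length(feats) == 0) stop("no usable trials in run")
  M <- do.call(rbind, feats)

  flagged <- integer(0)
  if (cf$zscore) {
    mu <- colMeans(M)
    sdv <- apply(M, 2, sd)
    flagged <- which(sdv < 1e-12)
    sdv[flagged] <- 1
    M <- sweep(sweep(M, 2, mu), 2, sdv, "/")
    M[, flagged] <- 0
  }
  structure(list(X = M, labels = labels,
                 runs = rep(run$run, nrow(M)), subject = run$subject,
                 grid = run$grid, voxels = run$voxels, flagged = flagged),
            class = "trial_patterns")
}

#' @export
print.trial_patterns <- function(x, ...) {
  cat("Trial patterns:", nrow(x$X), "trials x", ncol(x$X), "voxels | subject",
      x$subject, "| labels +1:", sum(x$labels == 1), "-1:", sum(x$labels == -1),
      "\n")
  invisible(x)
}

#' Combine trial patterns from several runs of one subject
#'
#' @param patterns list of `trial_patterns` with identical voxel sets.
#' @return a single `trial_patterns` with concatenated trials.
#' @export
combine_patterns <- function(patterns) {
  stopifnot(length(patterns) >= 1)
  v <- patterns[[1]]$voxels
  for (p in patterns[-1]) stopifnot(identical(p$voxels, v))
  structure(list(X = do.call(rbind, lapply(patterns, `[[`, "X")),
                 labels = unlist(lapply(patterns, `[[`, "labels")),
                 runs = unlist(lapply(patterns, `[[`, "runs")),
                 subject = patterns[[1]]$subject,
                 grid = patterns[[1]]$grid,
                 voxels = v,
                 flagged = unique(unlist(lapply(patterns, `[[`, "flagged")))),
            class = "trial_patterns")
}

#' Project trial patterns onto common coordinates and restrict to an ROI
#'
#' Each trial's feature image is warped onto the common grid through the
#' subject transform `Phi_s` (trilinear pull-back) and indexed at the mask's
#' voxels, in ascending voxel order — identical across subjects, so features
#' line up for pooled decoding.
#'
#' @param patterns a `trial_patterns` on the subject grid.
#' @param mask an ROI as a [scalar_volume()] with logical/0-1 data on the
#'   common grid.
#' @param phi transform mapping common-grid world coordinates onto the
#'   subject (e.g. from [build_common_space()]); `NULL` for identity.
#' @return a `trial_patterns` on the common grid.
#' @export
extract_roi <- function(patterns, mask, phi = NULL) {
  stopifnot(inherits(patterns, "trial_patterns"), inherits(mask, "scalar_volume"))
  roi_idx <- which(mask$data > 0)
  if (length(roi_idx) == 0) stop("empty ROI mask")
  g <- patterns$grid
  stopifnot(!is.null(g))
  X <- grid_world_coords(mask, roi_idx)
  Y <- if (is.null(phi)) X else transform_points(phi, X)
  w2v <- solve(g$affine)
  full <- array(0, g$dim)
  n_tr <- nrow(patterns$X)
  out <- matrix(0, n_tr, length(roi_idx))
  inside_any <- FALSE
  for (t in seq_len(n_tr)) {
    full[] <- 0
    full[patterns$voxels] <- patterns$X[t, ]
    res <- cpp_sample_scalar(full, g$dim, numeric(0), w2v, Y, FALSE)
    out[t, ] <- res$value
    if (any(res$inside)) inside_any <- TRUE
  }
  if (!inside_any) stop("ROI does not intersect the subject's data field")
  structure(list(X = out, labels = patterns$labels, runs = patterns$runs,
                 subject = patterns$subject,
                 grid = list(dim = dim(mask$data), affine = mask$affine),
                 voxels = as.integer(roi_idx), flagged = integer(0)),
            class = "trial_patterns")
}

#' Supervised cross-subject voxel selection by summed absolute t-scores
#'
#' For every reference subject a Welch two-sample t statistic (attend-left
#' vs attend-right trials) is computed per voxel; voxels are ranked by the
#' sum of absolute t values over the reference subjects and the top
#' `ceiling(fraction * n)` are kept (ties broken by ascending voxel index).
#' The target subject's data must not be passed in — selection is part of
#' the transfer protocol.
#'
#' @param reference_patterns list of `trial_patterns` (common grid, aligned
#'   voxel columns), one per reference subject.
#' @param fraction fraction of voxels to keep, in (0, 1]; 1 keeps all.
#' @return integer vector of selected column positions (ascending); the
#'   summed score is attached as `attr(, "score")`.
#' @export
select_voxels <- function(reference_patterns, fraction = 1) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  stopifnot(length(reference_patterns) >= 1)
  nv <- ncol(reference_patterns[[1]]$X)
  score <- numeric(nv)
  for (p in reference_patterns) {
    stopifnot(ncol(p$X) == nv)
    a <- p$X[p$labels == 1, , drop = FALSE]
    b <- p$X[p$labels == -1, , drop = FALSE]
    if (nrow(a) < 2 || nrow(b) < 2)
      stop("each reference subject needs >= 2 trials per class")
    se2 <- apply(a, 2, var) / nrow(a) + apply(b, 2, var) / nrow(b)
    t <- (colMeans(a) - colMeans(b)) / sqrt(se2)
    t[is.nan(t)] <- 0  # 0/0: no signal, no variance
    score <- score + abs(t)
  }
  m <- ceiling(fraction * nv)
  ord <- order(-score, seq_len(nv))
  sel <- sort(ord[seq_len(m)])
  attr(sel, "score") <- score
  sel
}
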