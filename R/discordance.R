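# Voxel-wise discordance between two registration routes of FA maps,
# tissue stratification, and exponential tail fitting.

#' FA map of a subject registered onto the common grid
#'
#' Computes FA in the subject's native space and warps it through the
#' registration transform (trilinear pull-back).
#'
#' @param x the subject's [tensor_volume()].
#' @param phi transform mapping common-grid world coordinates onto the
#'   subject, or `NULL` for identity.
#' @param out_grid the common grid (volume or `list(dim, affine)`).
#' @return a [scalar_volume()] on the common grid.
#' @export
registered_fa <- function(x, phi = NULL, out_grid = x) {
  stopifnot(inherits(x, "tensor_volume"))
  native <- fa_map(x)
  if (is.null(phi)) {
    g <- as_grid(out_grid)
    if (all(g$dim == grid_dim(x)) && max(abs(g$affine - x$affine)) < 1e-9)
      return(native)
    phi <- affine_transform()
  }
  apply_transform_scalar(native, phi, out_grid, interpolation = "trilinear")
}

#' Discordance map between two registration routes
#'
#' For each subject, the FA map registered through route B is subtracted from
#' the FA map registered through route A (the per-subject subtraction maps
#' are retained); the discordance map is the voxel-wise mean of their
#' absolute values over subjects.
#'
#' @param fa_a,fa_b paired lists of registered FA [scalar_volume()]s on the
#'   same grid (e.g. tensor-metric route and scalar-baseline route).
#' @return a `discordance_map`: `map` (a [scalar_volume()], values >= 0),
#'   `l_diff` (per-subject signed subtraction maps), `n_subjects`.
#' @export
discordance_map <- function(fa_a, fa_b) {
  if (length(fa_a) != length(fa_b)) stop("paired lists of equal length required")
  if (length(fa_a) == 0) stop("no subjects")
  l_diff <- vector("list", length(fa_a))
  acc <- 0
  for (i in seq_along(fa_a)) {
    if (!same_grid(fa_a[[i]], fa_b[[i]]) || !same_grid(fa_a[[i]], fa_a[[1]]))
      stop("all maps must share one grid")
    l_diff[[i]] <- fa_a[[i]]$data - fa_b[[i]]$data
    acc <- acc + abs(l_diff[[i]])
  }
  structure(list(map = scalar_volume(acc / length(fa_a),
                                     affine = fa_a[[1]]$affine,
                                     mask = fa_a[[1]]$mask),
                 l_diff = l_diff, n_subjects = length(fa_a)),
            class = "discordance_map")
}

#' @export
print.discordance_map <- function(x, ...) {
  v <- x$map$data[x$map$mask]
  cat(sprintf("Discordance map over %d subjects | median %.4g | mean %.4g\n",
              x$n_subjects, median(v), mean(v)))
  invisible(x)
}

# logical 6-neighbour dilation
adjacent6 <- function(mask) {
  out <- array(FALSE, dim(mask))
  n <- dim(mask)
  out[-1, , ] <- out[-1, , ] | mask[-n[1], , ]
  out[-n[1], , ] <- out[-n[1], , ] | mask[-1, , ]
  out[, -1, ] <- out[, -1, ] | mask[, -n[2], ]
  out[, -n[2], ] <- out[, -n[2], ] | mask[, -1, ]
  out[, , -1] <- out[, , -1] | mask[, , -n[3]]
  out[, , -n[3]] <- out[, , -n[3]] | mask[, , -1]
  out
}

#' FA-threshold tissue masks (white matter, gray matter, edge of gray matter)
#'
#' Operationalizes the tissue classes on the template: white matter is
#' FA >= `fa_wm` inside the brain mask; gray matter is the rest of the brain;
#' the edge of gray matter is the gray-matter voxels 6-adjacent to white
#' matter. The returned gray-matter class excludes its edge, so the three
#' classes are pairwise disjoint.
#'
#' @param template a [tensor_volume()] with meaningful FA contrast (its mask
#'   is the brain mask).
#' @param fa_wm FA threshold for white matter (default 0.25).
#' @return a `tissue_masks` list of three logical arrays: `wm`, `gm`
#'   (interior), `edge`.
#' @export
tissue_masks <- function(template, fa_wm = 0.25) {
  stopifnot(inherits(template, "tensor_volume"))
  FA <- fa_map(template)$data
  brain <- template$mask
  wm <- brain & (FA >= fa_wm)
  if (!any(wm)) stop("empty tissue class: white matter (no FA >= ", fa_wm, ")")
  gm_all <- brain & !wm
  if (!any(gm_all)) stop("empty tissue class: gray matter")
  edge <- gm_all & adjacent6(wm)
  if (!any(edge)) stop("empty tissue class: edge of gray matter")
  gm <- gm_all & !edge
  structure(list(wm = wm, gm = gm, edge = edge), class = "tissue_masks")
}

#' Exponential tail fit of a value distribution
#'
#' Fits `exp(-a x)` to the right tail: the maximum-likelihood rate for the
#' exceedances over a threshold is `a = 1 / mean(value - threshold)`. The
#' threshold defaults to the `threshold_quantile` quantile of the values. A
#' bootstrap standard error over the exceedances is attached.
#'
#' @param values numeric vector.
#' @param threshold_quantile quantile defining the tail (default 0.5, the
#'   median).
#' @param threshold explicit threshold overriding the quantile.
#' @param n_boot bootstrap resamples for the standard error.
#' @param seed RNG seed for the bootstrap.
#' @return list with `rate`, `se`, `threshold`, `n_exceed`.
#' @export
tail_fit <- function(values, threshold_quantile = 0.5, threshold = NULL,
                     n_boot = 1000, seed = 1L) {
  if (is.null(threshold))
    threshold <- as.numeric(quantile(values, threshold_quantile))
  exceed <- values[values > threshold] - threshold
  if (length(exceed) < 30)
    stop("too few exceedances above the threshold (", length(exceed), " < 30)")
  rate <- 1 / mean(exceed)
  se <- with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i)
      1 / mean(sample(exceed, replace = TRUE)), numeric(1))
    sd(reps)
  })
  list(rate = rate, se = se, threshold = threshold, n_exceed = length(exceed))
}

#' Tissue-stratified summary of a discordance map
#'
#' Median, mean and exponential tail rate of the discordance values within
#' each tissue class.
#'
#' @param map a `discordance_map` (or a [scalar_volume()]).
#' @param masks a `tissue_masks` on the same grid.
#' @param ... passed to [tail_fit()].
#' @return data frame with one row per tissue class (`tissue`, `n`, `median`,
#'   `mean`, `tail_rate`, `tail_se`); empty classes yield `NA` rows.
#' @export
stratified_summary <- function(map, masks, ...) {
  vol <- if (inherits(map, "discordance_map")) map$map else map
  stopifnot(inherits(vol, "scalar_volume"), inherits(masks, "tissue_masks"))
  rows <- lapply(c("gm", "edge", "wm"), function(cls) {
    m <- masks[[cls]]
    if (!any(m))
      return(data.frame(tissue = cls, n = 0L, median = NA_real_,
                        mean = NA_real_, tail_rate = NA_real_,
                        tail_se = NA_real_))
    v <- vol$data[m]
    tf <- tryCatch(tail_fit(v, ...), error = function(e) NULL)
    data.frame(tissue = cls, n = length(v), median = median(v), mean = mean(v),
               tail_rate = if (is.null(tf)) NA_real_ else tf$rate,
               tail_se = if (is.null(tf)) NA_real_ else tf$se)
  })
  do.call(rbind, rows)
}
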