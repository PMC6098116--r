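# Synthetic multi-subject phantom cohorts: a tensor-brain template (curved
# white-matter tract wrapped in a gray-matter band), per-subject ground-truth
# piecewise-affine deformations, 30-direction diffusion-weighted signals, and
# task-fMRI runs whose informative voxels sit at the gray/white boundary and
# follow each subject's anatomy.

#' Quasi-uniform unit directions on the sphere (Fibonacci lattice)
#'
#' @param n number of directions.
#' @return `n x 3` matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(1 - z^2, 0))
  ang <- i * pi * (3 - sqrt(5))
  cbind(r * cos(ang), r * sin(ang), z)
}

#' Specification of a synthetic phantom cohort
#'
#' Defaults emulate the acquisition protocol the pipeline targets: 1 b0 +
#' 30 diffusion directions at b = 1000 s/mm^2 acquired twice and averaged,
#' TR = 2 s task runs of Rest (8-16 s) / Control (4 s) / Attention (8 s)
#' trials, and literature-typical tissue eigenvalues. Deformation magnitudes
#' produce inter-subject anatomical variability of a few voxels; the fMRI
#' effect is expressed in units of the fMRI noise SD (z-units).
#'
#' @param grid grid shape (>= 16 per axis).
#' @param voxel voxel dimensions in mm.
#' @param curves list of `n x 3` world-coordinate polylines (tract
#'   centrelines); default a single coronal arc.
#' @param tract_radius white-matter tube radius (mm).
#' @param gm_thickness gray-matter band thickness around the tract (mm).
#' @param evals_wm,evals_gm,evals_csf tissue eigenvalues (mm^2/s).
#' @param s0 b0 signal level; `dwi_noise` Gaussian noise SD on the signals;
#'   `n_dirs` diffusion directions; `bvalue` in s/mm^2;
#'   `n_acquisitions` repeated acquisitions; `average_acquisitions` average
#'   them in signal space (otherwise volumes are concatenated).
#' @param translation,rotation,scale,block_jitter ground-truth deformation
#'   magnitudes: max |translation| per axis (mm), max rotation per axis
#'   (degrees), max relative scale deviation, per-block translation jitter
#'   (mm).
#' @param effect fMRI effect size in noise-SD units; `fmri_noise` noise SD;
#'   `drift_max` max linear drift per TR (noise-SD units).
#' @param trials_per_run,runs_per_subject,tr task layout; `rest_range`
#'   Rest duration range (s), `control_dur` and `attention_dur` in s;
#'   `hemodynamic_delay` of the simulated response in TRs.
#' @param rician use Rician (magnitude) instead of Gaussian DWI noise.
#' @param seed cohort seed.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(32, 32, 32), voxel = c(2, 2, 2),
                         curves = NULL, tract_radius = 4, gm_thickness = 6,
                         evals_wm = c(1.7, 0.3, 0.3) * 1e-3,
                         evals_gm = c(0.9, 0.7, 0.7) * 1e-3,
                         evals_csf = c(3, 3, 3) * 1e-3,
                         s0 = 1000, dwi_noise = 20, n_dirs = 30, bvalue = 1000,
                         n_acquisitions = 2, average_acquisitions = TRUE,
                         translation = 6, rotation = 8, scale = 0.08,
                         block_jitter = 2,
                         effect = 0.5, fmri_noise = 1, drift_max = 0.02,
                         trials_per_run = 10, runs_per_subject = 5, tr = 2,
                         rest_range = c(8, 16), control_dur = 4,
                         attention_dur = 8, hemodynamic_delay = 2,
                         rician = FALSE, seed = 1L) {
  stopifnot(all(grid >= 16), all(voxel > 0), tract_radius > 0,
            gm_thickness >= 0, translation >= 0, rotation >= 0, scale >= 0,
            block_jitter >= 0, effect >= 0, fmri_noise >= 0,
            trials_per_run %% 2 == 0)
  if (is.null(curves)) {
    theta <- seq(-60, 60, length.out = 200) * pi / 180
    R <- 20
    curves <- list(cbind(R * sin(theta), 0, R * cos(theta) - R + 4))
  }
  structure(as.list(environment()), class = "phantom_spec")
}

centered_affine <- function(grid, voxel) {
  aff <- diag(4)
  diag(aff)[1:3] <- voxel
  aff[1:3, 4] <- -(grid - 1) / 2 * voxel
  aff
}

# nearest point and tangent on the sampled centrelines for each query point
nearest_on_curves <- function(X, curves) {
  best_d2 <- rep(Inf, nrow(X))
  best_p <- matrix(0, nrow(X), 3)
  best_t <- matrix(0, nrow(X), 3)
  for (cv in curves) {
    tangent <- rbind(cv[2, ] - cv[1, ], (cv[-1, , drop = FALSE] -
                       cv[-nrow(cv), , drop = FALSE]))
    tangent <- tangent / sqrt(rowSums(tangent^2))
    for (s in seq_len(nrow(cv))) {
      d2 <- (X[, 1] - cv[s, 1])^2 + (X[, 2] - cv[s, 2])^2 + (X[, 3] - cv[s, 3])^2
      upd <- d2 < best_d2
      if (any(upd)) {
        best_d2[upd] <- d2[upd]
        best_p[upd, ] <- matrix(cv[s, ], sum(upd), 3, byrow = TRUE)
        best_t[upd, ] <- matrix(tangent[s, ], sum(upd), 3, byrow = TRUE)
      }
    }
  }
  list(dist = sqrt(best_d2), point = best_p, tangent = best_t)
}

#' Build the phantom template tensor brain
#'
#' White-matter voxels (within `tract_radius` of a centreline) are strongly
#' anisotropic with the principal axis along the local tract tangent; the
#' gray-matter band is weakly anisotropic with a radial principal axis;
#' everything else is background (zero tensor, outside the mask).
#' Deterministic: no randomness enters the template.
#'
#' The returned volume carries attributes: `labels` (0 background, 1 GM,
#' 2 WM), `informative` (0 / +1 left / -1 right; the GM voxels 6-adjacent to
#' WM, lateralized by world x), and `t1` (a noise-free pseudo-T1 intensity
#' array: WM 1.0, GM 0.6).
#'
#' @param spec a [phantom_spec()].
#' @return a [tensor_volume()].
#' @export
make_template <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  aff <- centered_affine(spec$grid, spec$voxel)
  dom <- grid_domain(list(dim = spec$grid, affine = aff))
  tube <- spec$tract_radius + spec$gm_thickness
  for (cv in spec$curves) {
    if (any(sweep(cv, 2, dom$lo) < tube) || any(sweep(-cv, 2, -dom$hi) < tube))
      stop("tract (including the gray-matter band) extends outside the grid")
  }
  X <- grid_world_coords(list(dim = spec$grid, affine = aff))
  nc <- nearest_on_curves(X, spec$curves)
  wm <- nc$dist <= spec$tract_radius
  gm <- !wm & nc$dist <= spec$tract_radius + spec$gm_thickness
  labels <- array(0L, spec$grid)
  labels[wm] <- 2L
  labels[gm] <- 1L

  comp <- array(0, c(spec$grid, 6))
  fill <- function(sel, evals, axis) {
    # D = l2 I + (l1 - l2) a a'   (axially symmetric tensor)
    l1 <- evals[1]; l2 <- mean(evals[2:3])
    ax <- axis[sel, , drop = FALSE]
    comp[, , , 1][sel] <<- l2 + (l1 - l2) * ax[, 1]^2
    comp[, , , 2][sel] <<- (l1 - l2) * ax[, 1] * ax[, 2]
    comp[, , , 3][sel] <<- l2 + (l1 - l2) * ax[, 2]^2
    comp[, , , 4][sel] <<- (l1 - l2) * ax[, 1] * ax[, 3]
    comp[, , , 5][sel] <<- (l1 - l2) * ax[, 2] * ax[, 3]
    comp[, , , 6][sel] <<- l2 + (l1 - l2) * ax[, 3]^2
  }
  if (any(wm)) fill(wm, spec$evals_wm, nc$tangent)
  if (any(gm)) {
    radial <- X - nc$point
    nrm <- sqrt(rowSums(radial^2))
    nrm[nrm == 0] <- 1
    fill(gm, spec$evals_gm, radial / nrm)
  }
  mask <- array(wm | gm, spec$grid)
  tv <- tensor_volume(comp, affine = aff, mask = mask)

  gm_arr <- array(gm, spec$grid)
  wm_arr <- array(wm, spec$grid)
  edge <- gm_arr & adjacent6(wm_arr)
  informative <- array(0L, spec$grid)
  informative[edge] <- ifelse(X[edge, 1] < 0, 1L, -1L)
  t1 <- array(0, spec$grid)
  t1[wm_arr] <- 1
  t1[gm_arr] <- 0.6
  attr(tv, "labels") <- labels
  attr(tv, "informative") <- informative
  attr(tv, "t1") <- t1
  tv
}

random_truth_transform <- function(spec, domain) {
  for (attempt in 1:10) {
    ang <- runif(3, -spec$rotation, spec$rotation) * pi / 180
    Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
                c(0, sin(ang[1]), cos(ang[1])))
    Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
                c(-sin(ang[2]), 0, cos(ang[2])))
    Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
                c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
    A <- Rz %*% Ry %*% Rx %*% diag(runif(3, 1 - spec$scale, 1 + spec$scale))
    t0 <- runif(3, -spec$translation, spec$translation)
    counts <- c(2, 2, 2)
    nb <- prod(counts)
    params <- matrix(rep(c(t(A), t0), each = nb), nb, 12)
    params[, 10:12] <- params[, 10:12] +
      matrix(runif(3 * nb, -spec$block_jitter, spec$block_jitter), nb, 3)
    phi <- piecewise_affine(params, counts, domain$lo,
                            (domain$hi - domain$lo) / counts)
    jd <- jacobian_map(phi, list(dim = spec$grid,
                                 affine = centered_affine(spec$grid, spec$voxel)))
    if (min(jd$data) > 0.05) return(phi)
  }
  stop("could not sample an invertible ground-truth deformation in 10 tries")
}

simulate_dwi <- function(tensors, spec) {
  dirs <- fibonacci_directions(spec$n_dirs)
  bvals <- c(0, rep(spec$bvalue, spec$n_dirs))
  bvecs <- rbind(c(0, 0, 0), dirs)
  dm <- grid_dim(tensors)
  d <- tensors$data
  one_acq <- function() {
    S <- array(0, c(dm, spec$n_dirs + 1))
    S[, , , 1] <- spec$s0
    for (k in seq_len(spec$n_dirs)) {
      g <- dirs[k, ]
      q <- g[1]^2 * d[, , , 1] + 2 * g[1] * g[2] * d[, , , 2] +
        g[2]^2 * d[, , , 3] + 2 * g[1] * g[3] * d[, , , 4] +
        2 * g[2] * g[3] * d[, , , 5] + g[3]^2 * d[, , , 6]
      S[, , , k + 1] <- spec$s0 * exp(-spec$bvalue * q)
    }
    if (spec$dwi_noise > 0) {
      noise <- array(rnorm(length(S), sd = spec$dwi_noise), dim(S))
      if (spec$rician) {
        noise2 <- array(rnorm(length(S), sd = spec$dwi_noise), dim(S))
        S <- sqrt((S + noise)^2 + noise2^2)
      } else S <- S + noise
    }
    S[array(!tensors$mask, c(dm, spec$n_dirs + 1))] <- 0
    S
  }
  acqs <- lapply(seq_len(spec$n_acquisitions), function(i) one_acq())
  if (spec$average_acquisitions || spec$n_acquisitions == 1) {
    S <- Reduce(`+`, acqs) / length(acqs)
  } else {
    S <- array(0, c(dm, (spec$n_dirs + 1) * spec$n_acquisitions))
    for (i in seq_along(acqs))
      S[, , , (i - 1) * (spec$n_dirs + 1) + seq_len(spec$n_dirs + 1)] <- acqs[[i]]
    bvals <- rep(bvals, spec$n_acquisitions)
    bvecs <- do.call(rbind, rep(list(bvecs), spec$n_acquisitions))
  }
  list(data = S, scheme = gradient_scheme(bvals, bvecs))
}

simulate_run <- function(subject_mask, informative, spec, aff, run_id, subject_id) {
  vox <- which(subject_mask)
  info_val <- informative[vox]
  n_tr <- spec$trials_per_run
  sides <- sample(rep(c("left", "right"), n_tr / 2))
  rest_choices <- seq(spec$rest_range[1], spec$rest_range[2], by = spec$tr)
  onset <- 5 * spec$tr  # dummy volumes discarded in preprocessing
  ev <- list()
  for (k in seq_len(n_tr)) {
    rest <- sample(rest_choices, 1)
    ev[[length(ev) + 1]] <- data.frame(
      trial = k,
      phase = c("Rest", "Control", "Attention"),
      onset = c(onset, onset + rest, onset + rest + spec$control_dur),
      duration = c(rest, spec$control_dur, spec$attention_dur),
      side = c(NA, NA, sides[k]))
    onset <- onset + rest + spec$control_dur + spec$attention_dur
  }
  events <- do.call(rbind, ev)
  n_vol <- ceiling(onset / spec$tr) + spec$hemodynamic_delay + 2
  # effect is expressed in noise-SD units; at zero noise the unit is 1
  amp <- spec$effect * (if (spec$fmri_noise > 0) spec$fmri_noise else 1)
  sig <- matrix(100, n_vol, length(vox))
  drift <- runif(length(vox), -spec$drift_max, spec$drift_max) * spec$fmri_noise
  sig <- sig + outer(seq_len(n_vol), drift)
  if (spec$fmri_noise > 0)
    sig <- sig + matrix(rnorm(length(sig), sd = spec$fmri_noise),
                        n_vol, length(vox))
  add_box <- function(sig, onset, duration, pattern) {
    idx <- phase_volumes(onset, duration, spec$tr) + spec$hemodynamic_delay
    idx <- idx[idx <= n_vol]
    sig[idx, ] <- sig[idx, ] + matrix(pattern, length(idx), length(vox),
                                      byrow = TRUE)
    sig
  }
  for (k in seq_len(n_tr)) {
    evk <- events[events$trial == k, ]
    lab <- if (sides[k] == "left") 1 else -1
    ctl <- evk[evk$phase == "Control", ]
    att <- evk[evk$phase == "Attention", ]
    sig <- add_box(sig, ctl$onset, ctl$duration, 0.5 * amp * abs(info_val))
    sig <- add_box(sig, att$onset, att$duration, lab * amp * info_val)
  }
  functional_run(sig, events, subject = subject_id, run = run_id,
                 grid = list(dim = dim(subject_mask), affine = aff,
                             mask = subject_mask),
                 voxels = vox, tr = spec$tr)
}

#' Simulate one cohort subject from the template
#'
#' Samples a ground-truth piecewise-affine deformation within the spec
#' magnitudes (resampled up to 10 times if it folds), warps the template
#' (with tensor reorientation) onto the subject, simulates the
#' diffusion-weighted acquisition(s) and fits the subject's tensor volume
#' from them, renders the pseudo-T1, and simulates the task runs: each
#' trial's Attention phase adds the side-dependent response (+/- effect,
#' lateralized) at the subject's warped boundary voxels, the Control phase a
#' symmetric response, plus per-voxel linear drift and Gaussian noise.
#'
#' @param template from [make_template()].
#' @param spec the [phantom_spec()].
#' @param subject_seed RNG seed for this subject.
#' @param subject_id identifier string.
#' @param is_template if `TRUE` the ground-truth deformation is the identity
#'   (the template subject's own acquisition).
#' @return a list: `truth` (subject-to-template [piecewise_affine()]),
#'   `tensors` (DWI-fitted [tensor_volume()]), `dwi`, `scheme`, `t1`
#'   ([scalar_volume()]), `runs`, `informative` (array), `labels`, `id`.
#' @export
make_subject <- function(template, spec, subject_seed, subject_id = "sub01",
                         is_template = FALSE) {
  stopifnot(inherits(template, "tensor_volume"), inherits(spec, "phantom_spec"))
  dom <- grid_domain(template)
  aff <- template$affine
  with_seed(subject_seed, {
    truth <- if (is_template) pa_identity(dom, c(2, 2, 2))
             else random_truth_transform(spec, dom)
    warped <- apply_transform_tensor(template, truth, template)
    labels <- array(as.integer(round(apply_transform_scalar(
      scalar_volume(array(as.numeric(attr(template, "labels")), grid_dim(template)),
                    affine = aff),
      truth, template, interpolation = "nearest")$data)), grid_dim(template))
    informative <- array(as.integer(round(apply_transform_scalar(
      scalar_volume(array(as.numeric(attr(template, "informative")),
                          grid_dim(template)), affine = aff),
      truth, template, interpolation = "nearest")$data)), grid_dim(template))
    informative[!warped$mask] <- 0L
    dwi <- simulate_dwi(warped, spec)
    tensors <- suppressWarnings(
      fit_tensor(dwi$data, dwi$scheme, mask = warped$mask, affine = aff))
    t1dat <- apply_transform_scalar(
      scalar_volume(attr(template, "t1"), affine = aff), truth, template)$data
    t1 <- scalar_volume(t1dat + array(rnorm(length(t1dat), sd = 0.02),
                                      dim(t1dat)),
                        affine = aff, mask = warped$mask)
    runs <- lapply(seq_len(spec$runs_per_subject), function(r)
      simulate_run(warped$mask, informative, spec, aff, r, subject_id))
    list(id = subject_id, truth = truth, tensors = tensors,
         tensors_true = warped, dwi = dwi$data, scheme = dwi$scheme, t1 = t1,
         runs = runs, informative = informative, labels = labels)
  })
}

#' Simulate a full phantom cohort
#'
#' Subject 1 is the template subject (identity deformation; conventionally
#' excluded from decoding analyses, as the common coordinates are anchored on
#' it); subjects 2..n are deformed. Deterministic for a fixed spec seed.
#'
#' @param n_subjects total subjects including the template subject (>= 3).
#' @param spec a [phantom_spec()].
#' @param dir optional directory; if given, the cohort is also written to
#'   disk via [write_cohort()].
#' @return a `synthetic_cohort`: `template`, `subjects` (list), `spec`.
#' @export
make_cohort <- function(n_subjects, spec = phantom_spec(), dir = NULL) {
  if (n_subjects < 3) stop("need at least 3 subjects (template + 2)")
  template <- make_template(spec)
  base <- (spec$seed %% 100000L) * 1000L
  subjects <- lapply(seq_len(n_subjects), function(s)
    make_subject(template, spec, subject_seed = base + s,
                 subject_id = sprintf("sub-%02d", s - 1),
                 is_template = (s == 1)))
  cohort <- structure(list(template = template, subjects = subjects,
                           spec = spec), class = "synthetic_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$subjects), "subjects (1 template +",
      length(x$subjects) - 1, "analysis) on a",
      paste(x$spec$grid, collapse = "x"), "grid\n")
  invisible(x)
}
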