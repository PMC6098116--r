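# Registration of tensor volumes under the deviatoric tensor metric, and of
# scalar volumes under SSD (the T1-style baseline). Multi-resolution,
# global-affine-then-block-wise, derivative-free pattern search.

#' Apply a transform to a tensor volume (pull-back resampling)
#'
#' For each output voxel the source tensor is sampled at `phi(x)`
#' (component-wise trilinear interpolation) and reoriented by the
#' finite-strain rotation of the local linear part of `phi`, so that fibre
#' orientations stay anatomically consistent. Samples falling outside the
#' source field yield the zero tensor and are excluded from the output mask.
#'
#' @param v a [tensor_volume()] (the source).
#' @param phi a transform mapping output-space world coordinates to source
#'   world coordinates.
#' @param out_grid output geometry: a volume or `list(dim, affine)`.
#' @param reorient apply finite-strain tensor reorientation (default `TRUE`).
#' @return a [tensor_volume()] on `out_grid`.
#' @export
apply_transform_tensor <- function(v, phi, out_grid = v, reorient = TRUE) {
  stopifnot(inherits(v, "tensor_volume"))
  g <- as_grid(out_grid)
  X <- grid_world_coords(g)
  Y <- transform_points(phi, X)
  A <- if (reorient) local_jacobian(phi, X) else matrix(0, 0, 9)
  res <- cpp_sample_tensor(v$data, grid_dim(v), as.numeric(v$mask),
                           solve(v$affine), Y, A)
  comp <- array(res$comp, c(g$dim, 6))
  mask <- array(res$inside & res$mask >= 0.5, g$dim)
  comp[!array(res$inside, g$dim)] <- 0  # guard (already zeroed in C++)
  tensor_volume(comp, affine = g$affine, mask = mask)
}

#' Apply a transform to a scalar volume (pull-back resampling)
#'
#' @param v a [scalar_volume()].
#' @inheritParams apply_transform_tensor
#' @param interpolation `"trilinear"` (default, for EPI and FA maps) or
#'   `"nearest"` (for label volumes).
#' @return a [scalar_volume()] on `out_grid`.
#' @export
apply_transform_scalar <- function(v, phi, out_grid = v,
                                   interpolation = c("trilinear", "nearest")) {
  stopifnot(inherits(v, "scalar_volume"))
  interpolation <- match.arg(interpolation)
  g <- as_grid(out_grid)
  X <- grid_world_coords(g)
  Y <- transform_points(phi, X)
  res <- cpp_sample_scalar(v$data, grid_dim(v), as.numeric(v$mask),
                           solve(v$affine), Y, interpolation == "nearest")
  val <- array(res$value, g$dim)
  mask <- array(res$inside & res$mask >= 0.5, g$dim)
  scalar_volume(val, affine = g$affine, mask = mask)
}

#' Registration configuration
#'
#' Coarse-to-fine schedule: at pyramid level `i` the volumes are downsampled
#' by `pyramid[i]` and the block lattice has `blocks[[i]]` blocks per axis.
#' The default (3 levels; global affine, then 2x2x2, then 4x4x4 blocks)
#' suits brain-sized grids; small phantoms converge well with two levels.
#'
#' @param pyramid integer downsampling factors, coarsest first.
#' @param blocks list of per-axis block counts, same length as `pyramid`.
#' @param max_sweeps sweep cap per level.
#' @param tol relative objective decrease under which (over `tol_sweeps`
#'   sweeps) the step sizes are halved and, once exhausted, the level stops.
#' @param tol_sweeps window (in sweeps) for the convergence test.
#' @param step_linear initial step for the 9 linear-part entries
#'   (dimensionless).
#' @param step_trans initial translation step in mm; default one voxel of the
#'   current pyramid level.
#' @param halvings number of step halvings before a level is declared
#'   converged.
#' @param min_support blocks influencing fewer foreground voxels than this
#'   are left at their inherited affine (too little evidence to optimize).
#' @param oob_weight weight of the penalty for sampling outside the source
#'   foreground, as a multiple of the mean target signal power; keeps the
#'   search from trading noisy tissue match for empty background.
#' @param trans_search half-range (in coarsest-level voxels) of the
#'   exhaustive global-translation initialization at the first pyramid
#'   level; 0 disables it.
#' @return a list of class `reg_config`.
#' @export
reg_config <- function(pyramid = c(4, 2, 1),
                       blocks = list(c(1, 1, 1), c(2, 2, 2), c(4, 4, 4)),
                       max_sweeps = 50, tol = 1e-4, tol_sweeps = 3,
                       step_linear = 0.05, step_trans = NULL, halvings = 4,
                       min_support = 20, oob_weight = 0.3, trans_search = 2) {
  stopifnot(length(pyramid) == length(blocks))
  structure(list(pyramid = pyramid, blocks = blocks, max_sweeps = max_sweeps,
                 tol = tol, tol_sweeps = tol_sweeps, step_linear = step_linear,
                 step_trans = step_trans, halvings = halvings,
                 min_support = min_support, oob_weight = oob_weight,
                 trans_search = trans_search),
            class = "reg_config")
}

# block-mean downsampling by integer factor
downsample_volume <- function(v, f) {
  if (f == 1) return(v)
  dm <- grid_dim(v)
  n2 <- dm %/% f
  stopifnot(all(n2 >= 1))
  blockmean <- function(a) {
    a <- a[seq_len(n2[1] * f), seq_len(n2[2] * f), seq_len(n2[3] * f), drop = FALSE]
    dim(a) <- c(f, n2[1], f, n2[2], f, n2[3])
    a <- aperm(a, c(1, 3, 5, 2, 4, 6))
    dim(a) <- c(f^3, prod(n2))
    array(colMeans(a), n2)
  }
  S <- rbind(cbind(diag(3) * f, (f - 1) / 2), c(0, 0, 0, 1))
  aff <- v$affine %*% S
  maskf <- blockmean(array(as.numeric(v$mask), dm)) > 0.5
  if (inherits(v, "tensor_volume")) {
    comp <- array(0, c(n2, 6))
    for (c6 in 1:6) comp[, , , c6] <- blockmean(v$data[, , , c6])
    tensor_volume(comp, affine = aff, mask = maskf)
  } else {
    scalar_volume(blockmean(v$data), affine = aff, mask = maskf)
  }
}

# initialize a block lattice from an existing transform: local affine at each
# new block centre
resample_pa <- function(phi, counts, domain) {
  sp <- (domain$hi - domain$lo) / counts
  centres <- as.matrix(expand.grid(
    domain$lo[1] + (seq_len(counts[1]) - 0.5) * sp[1],
    domain$lo[2] + (seq_len(counts[2]) - 0.5) * sp[2],
    domain$lo[3] + (seq_len(counts[3]) - 0.5) * sp[3]))
  Y <- transform_points(phi, centres)
  J <- local_jacobian(phi, centres)
  params <- matrix(0, nrow(centres), 12)
  params[, 1:9] <- J
  for (r in 1:3) {
    params[, 9 + r] <- Y[, r] -
      (J[, 3 * (r - 1) + 1] * centres[, 1] +
       J[, 3 * (r - 1) + 2] * centres[, 2] +
       J[, 3 * (r - 1) + 3] * centres[, 3])
  }
  piecewise_affine(params, counts, domain$lo, sp)
}

# voxels (0-based linear indices) influenced by each block
block_support <- function(grid, counts, lo, sp, subset_all) {
  X <- grid_world_coords(grid, subset_all + 1L)
  m <- counts
  i0 <- vector("list", 3)
  for (d in 1:3) {
    if (m[d] == 1) i0[[d]] <- rep(0L, nrow(X))
    else {
      u <- (X[, d] - lo[d]) / sp[d] - 0.5
      i0[[d]] <- as.integer(pmin(pmax(floor(u), 0), m[d] - 2))
    }
  }
  support <- rep(list(integer(0)), prod(m))
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    ii <- pmin(i0[[1]] + cx, m[1] - 1L)
    jj <- pmin(i0[[2]] + cy, m[2] - 1L)
    kk <- pmin(i0[[3]] + cz, m[3] - 1L)
    bid <- ii + m[1] * (jj + m[2] * kk) + 1L
    parts <- split(subset_all, bid)
    for (nm in names(parts)) {
      b <- as.integer(nm)
      support[[b]] <- c(support[[b]], parts[[nm]])
    }
  }
  lapply(support, function(s) sort(unique(s)))
}

# derivative-free coordinate-wise pattern search over block parameters
pattern_search <- function(objfun, params, support, subset_all, config,
                           step_trans) {
  steps <- c(rep(config$step_linear, 9), rep(step_trans, 3))
  total <- objfun(params, subset_all)
  traj <- total
  halvings <- 0
  converged <- FALSE
  sweep <- 0
  nb <- nrow(params)
  while (sweep < config$max_sweeps) {
    sweep <- sweep + 1
    improved <- FALSE
    for (b in seq_len(nb)) {
      sub <- support[[b]]
      if (length(sub) < config$min_support) next  # too little evidence
      base <- objfun(params, sub)
      for (j in 1:12) {
        for (sgn in c(1, -1)) {
          moved <- FALSE
          repeat {
            trial <- params
            trial[b, j] <- params[b, j] + sgn * steps[j]
            if (j <= 9) {
              # keep every block orientation-preserving and well-conditioned
              A <- matrix(trial[b, 1:9], 3, 3, byrow = TRUE)
              dA <- det(A)
              if (dA < 0.1 || dA > 10) break
            }
            val <- objfun(trial, sub)
            if (val < base * (1 - 1e-12) - 1e-300) {
              params <- trial
              base <- val
              improved <- TRUE
              moved <- TRUE
            } else break
          }
          if (moved) break
        }
      }
    }
    total <- objfun(params, subset_all)
    traj <- c(traj, min(total, traj[length(traj)]))
    small_gain <- length(traj) > config$tol_sweeps &&
      (traj[length(traj) - config$tol_sweeps] - total) <=
        config$tol * max(traj[length(traj) - config$tol_sweeps], 1e-300)
    if (!improved || small_gain) {
      if (halvings >= config$halvings) {
        converged <- TRUE
        break
      }
      steps <- steps / 2
      halvings <- halvings + 1
    }
  }
  list(params = params, trajectory = traj, converged = converged)
}

register_volumes <- function(source, target, config, reorient) {
  tensor <- inherits(source, "tensor_volume")
  if (sum(source$mask) == 0 || sum(target$mask) == 0)
    stop("empty mask: nothing to register")
  domain <- grid_domain(target)
  phi <- NULL
  trace <- list()
  converged <- FALSE
  traj_final <- NULL
  for (lvl in seq_along(config$pyramid)) {
    f <- config$pyramid[lvl]
    counts <- config$blocks[[lvl]]
    ds <- downsample_volume(source, f)
    dt <- downsample_volume(target, f)
    sp <- (domain$hi - domain$lo) / counts
    pa <- if (is.null(phi)) pa_identity(domain, counts)
          else resample_pa(phi, counts, domain)
    subset_all <- which(dt$mask) - 1L
    if (length(subset_all) == 0) stop("empty mask overlap at pyramid level ", lvl)
    support <- block_support(dt, counts, domain$lo, sp, subset_all)
    sdim <- grid_dim(ds)
    odim <- grid_dim(dt)
    sw2v <- solve(ds$affine)
    ov2w <- dt$affine
    smask <- as.numeric(ds$mask)
    # out-of-field samples are penalized (beyond their zero-value mismatch)
    # so blocks cannot profit from pushing foreground voxels off the field
    oob <- if (tensor) {
      d <- dt$data
      f2 <- d[, , , 1]^2 + d[, , , 3]^2 + d[, , , 6]^2 +
        2 * (d[, , , 2]^2 + d[, , , 4]^2 + d[, , , 5]^2)
      tr <- d[, , , 1] + d[, , , 3] + d[, , , 6]
      config$oob_weight * mean(pmax(METRIC_SCALE * (f2 - tr^2 / 3), 0)[dt$mask])
    } else {
      config$oob_weight * mean(dt$data[dt$mask]^2)
    }
    objfun <- if (tensor) {
      function(params, subset) {
        cpp_tensor_obj(ds$data, sdim, smask, sw2v, dt$data, odim, ov2w,
                       params, counts, domain$lo, sp, as.integer(subset),
                       reorient, oob)
      }
    } else {
      function(params, subset) {
        cpp_scalar_obj(ds$data, sdim, smask, sw2v, dt$data, odim, ov2w,
                       params, counts, domain$lo, sp, as.integer(subset), oob)
      }
    }
    st <- if (is.null(config$step_trans)) max(voxel_size(dt$affine))
          else config$step_trans
    if (lvl == 1 && config$trans_search > 0) {
      # exhaustive global-translation initialization at the coarsest level:
      # lands the search in the right basin before local refinement
      vs <- max(voxel_size(dt$affine))
      offs <- seq(-config$trans_search * vs, config$trans_search * vs,
                  by = vs / 2)
      best <- objfun(pa$params, subset_all)
      best_t <- c(0, 0, 0)
      for (ox in offs) for (oy in offs) for (oz in offs) {
        trial <- pa$params
        trial[, 10:12] <- sweep(trial[, 10:12, drop = FALSE], 2,
                                -c(ox, oy, oz))
        val <- objfun(trial, subset_all)
        if (val < best) {
          best <- val
          best_t <- c(ox, oy, oz)
        }
      }
      pa$params[, 10:12] <- sweep(pa$params[, 10:12, drop = FALSE], 2, -best_t)
    }
    res <- pattern_search(objfun, pa$params, support, subset_all, config, st)
    phi <- piecewise_affine(res$params, counts, domain$lo, sp)
    trace[[lvl]] <- res$trajectory
    converged <- res$converged
    traj_final <- res$trajectory
  }
  structure(list(transform = phi, objective = traj_final, trace = trace,
                 converged = converged),
            class = "registration_result")
}

#' Register a tensor volume to a target under the deviatoric metric
#'
#' Minimizes the masked sum of squared deviatoric tensor distances between
#' the warped source and the target, over a global affine followed by
#' per-block affines (coarse to fine), by a derivative-free coordinate-wise
#' pattern search. Tensors are reoriented (finite strain) during warping.
#' The recorded objective trajectory is non-increasing; `converged` is
#' `FALSE` when the final level exhausted its sweep cap while still
#' improving.
#'
#' @param source,target [tensor_volume()]s (masked).
#' @param config a [reg_config()].
#' @return a `registration_result`: `transform` (a [piecewise_affine()]
#'   mapping target world coordinates onto the source), `objective` (final
#'   level trajectory), `trace` (per-level trajectories), `converged`.
#' @export
register_tensor <- function(source, target, config = reg_config()) {
  stopifnot(inherits(source, "tensor_volume"), inherits(target, "tensor_volume"))
  register_volumes(source, target, config, reorient = TRUE)
}

#' Register a scalar volume to a target by sum-of-squared differences
#'
#' The scalar-image analogue of [register_tensor()] (the T1-style baseline
#' route): same transform model and optimizer, objective replaced by the
#' masked sum of squared intensity differences, no reorientation.
#'
#' @param source,target [scalar_volume()]s.
#' @inheritParams register_tensor
#' @return a `registration_result`.
#' @export
register_scalar <- function(source, target, config = reg_config()) {
  stopifnot(inherits(source, "scalar_volume"), inherits(target, "scalar_volume"))
  register_volumes(source, target, config, reorient = FALSE)
}

#' @export
print.registration_result <- function(x, ...) {
  cat("Registration:", paste(x$transform$counts, collapse = "x"),
      "blocks | objective", signif(x$objective[1], 5), "->",
      signif(x$objective[length(x$objective)], 5),
      if (x$converged) "| converged\n" else "| NOT converged\n")
  invisible(x)
}

#' Build common anatomical coordinates for a cohort
#'
#' Mirrors the template-then-average construction: (1) every non-template
#' subject is registered to the designated template subject and warped onto
#' its grid; (2) the warped volumes are averaged into the mean template that
#' defines the common coordinates; (3) each original subject volume is
#' re-registered to the mean, giving the per-subject transform `Phi_s` that
#' maps common-space coordinates onto that subject.
#'
#' @param subjects list of [tensor_volume()]s (or [scalar_volume()]s for the
#'   scalar baseline), at least 2.
#' @param template_id index of the fixed template subject (conventionally
#'   excluded from downstream analyses).
#' @param config a [reg_config()].
#' @param transforms_for indices of the subjects for which `Phi_s` is
#'   computed in step (3); defaults to all.
#' @return a `common_space`: `template` (mean volume), `transforms` (list of
#'   [piecewise_affine()] per requested subject), `template_id`, and the
#'   per-subject `registrations`.
#' @export
build_common_space <- function(subjects, template_id = 1,
                               config = reg_config(),
                               transforms_for = seq_along(subjects)) {
  n <- length(subjects)
  if (n < 2) stop("need at least 2 subjects")
  stopifnot(template_id >= 1, template_id <= n)
  tensor <- inherits(subjects[[template_id]], "tensor_volume")
  regfun <- if (tensor) register_tensor else register_scalar
  tmpl <- subjects[[template_id]]
  warped <- list()
  for (s in setdiff(seq_len(n), template_id)) {
    res <- tryCatch(regfun(subjects[[s]], tmpl, config),
                    error = function(e)
                      stop("registration to template failed for subject ", s,
                           ": ", conditionMessage(e)))
    warped[[length(warped) + 1]] <-
      if (tensor) apply_transform_tensor(subjects[[s]], res$transform, tmpl)
      else apply_transform_scalar(subjects[[s]], res$transform, tmpl)
  }
  mean_tmpl <- if (tensor) average_tensor_volumes(warped)
               else average_scalar_volumes(warped)
  transforms <- list()
  registrations <- list()
  for (s in transforms_for) {
    res <- tryCatch(regfun(subjects[[s]], mean_tmpl, config),
                    error = function(e)
                      stop("registration to mean template failed for subject ",
                           s, ": ", conditionMessage(e)))
    transforms[[as.character(s)]] <- res$transform
    registrations[[as.character(s)]] <- res
  }
  structure(list(template = mean_tmpl, transforms = transforms,
                 template_id = template_id, registrations = registrations),
            class = "common_space")
}

average_scalar_volumes <- function(volumes) {
  if (length(volumes) == 0) stop("cannot average an empty list of volumes")
  acc <- volumes[[1]]$data
  msk <- volumes[[1]]$mask
  for (v in volumes[-1]) {
    if (!same_grid(volumes[[1]], v)) stop("volumes are not on the same grid")
    acc <- acc + v$data
    msk <- msk & v$mask
  }
  scalar_volume(acc / length(volumes), affine = volumes[[1]]$affine, mask = msk)
}

#' @export
print.common_space <- function(x, ...) {
  cat("Common space: mean template of class", class(x$template)[1], "|",
      length(x$transforms), "subject transform(s) | template subject",
      x$template_id, "\n")
  invisible(x)
}

#' Jacobian-determinant map of a transform
#'
#' Voxel-wise determinant of the local linear part (analytic derivative of
#' the blended block-affine map) on a grid: the local volume-change factor
#' of the deformation.
#'
#' @param phi a transform.
#' @param grid a volume or `list(dim, affine)`.
#' @return a [scalar_volume()].
#' @export
jacobian_map <- function(phi, grid) {
  g <- as_grid(grid)
  X <- grid_world_coords(g)
  J <- local_jacobian(phi, X)
  det <- J[, 1] * (J[, 5] * J[, 9] - J[, 6] * J[, 8]) -
         J[, 2] * (J[, 4] * J[, 9] - J[, 6] * J[, 7]) +
         J[, 3] * (J[, 4] * J[, 8] - J[, 5] * J[, 7])
  scalar_volume(array(det, g$dim), affine = g$affine,
                mask = if (is.null(g$mask)) NULL else g$mask)
}

#' Per-parcel means of a Jacobian map
#'
#' @param jac a [scalar_volume()] (e.g. from [jacobian_map()]).
#' @param parcellation a [scalar_volume()] of non-negative integer labels on
#'   the same grid (0 = background).
#' @param labels the labels to summarize, ascending; defaults to all positive
#'   labels present. A requested label with no voxels yields `NA` with a
#'   warning.
#' @return named numeric vector of per-parcel means, labels ascending.
#' @export
parcel_jacobian_features <- function(jac, parcellation, labels = NULL) {
  stopifnot(inherits(jac, "scalar_volume"), inherits(parcellation, "scalar_volume"))
  if (!same_grid(jac, parcellation)) stop("parcellation not on the jacobian grid")
  lab <- as.integer(round(parcellation$data))
  if (is.null(labels)) labels <- sort(unique(lab[lab > 0]))
  out <- vapply(labels, function(L) {
    sel <- lab == L
    if (!any(sel)) return(NA_real_)
    mean(jac$data[sel])
  }, numeric(1))
  if (anyNA(out)) warning("empty parcel(s): ", paste(labels[is.na(out)], collapse = ", "))
  names(out) <- labels
  out
}

#' Mean displacement error between a transform and a ground-truth map
#'
#' Evaluates `truth(phi(x))` over the masked voxels of `grid` and reports the
#' mean distance to `x`, in voxel units. With `truth = NULL` the error of
#' `phi` against the identity is reported. Used to validate recovery of
#' known deformations (`phi` maps template space onto the subject; `truth`
#' maps the subject back onto the template).
#'
#' @param phi transform under test (template -> subject world coordinates).
#' @param truth ground-truth subject -> template transform, or `NULL`.
#' @param grid a volume (its mask defines the evaluation points).
#' @return mean displacement in voxels.
#' @export
mean_displacement_error <- function(phi, truth, grid) {
  g <- as_grid(grid)
  subset <- if (is.null(g$mask)) seq_len(prod(g$dim)) else which(g$mask)
  X <- grid_world_coords(g, subset)
  Y <- transform_points(phi, X)
  Z <- if (is.null(truth)) Y else transform_points(truth, Y)
  mean(sqrt(rowSums((Z - X)^2))) / mean(voxel_size(g$affine))
}
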