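# Diffusion-tensor data model and the deviatoric tensor metric.
#
# A tensor is stored as its six unique components in lower-triangular order
# (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz), the common NIfTI symmetric-matrix
# convention; units mm^2/s.

TENSOR_COMPONENTS <- c("xx", "xy", "yy", "xz", "yz", "zz")
.DIAG6 <- c(1L, 3L, 6L)   # positions of Dxx, Dyy, Dzz
.OFF6 <- c(2L, 4L, 5L)    # positions of Dxy, Dxz, Dyz
METRIC_SCALE <- 8 * pi / 15

#' Convert between 3x3 symmetric matrices and 6-component tensors
#'
#' @param D a symmetric 3x3 matrix, or a numeric vector of the six unique
#'   components in the order Dxx, Dxy, Dyy, Dxz, Dyz, Dzz.
#' @return `as_tensor6()` returns the length-6 component vector;
#'   `tensor_matrix()` returns the full symmetric 3x3 matrix.
#' @export
as_tensor6 <- function(D) {
  if (is.matrix(D)) {
    stopifnot(all(dim(D) == c(3, 3)))
    if (max(abs(D - t(D))) > 1e-8 * max(1, max(abs(D))))
      stop("tensor matrix must be symmetric")
    c(D[1, 1], D[1, 2], D[2, 2], D[1, 3], D[2, 3], D[3, 3])
  } else {
    stopifnot(length(D) == 6)
    as.numeric(D)
  }
}

#' @rdname as_tensor6
#' @export
tensor_matrix <- function(D) {
  v <- as_tensor6(D)
  matrix(c(v[1], v[2], v[4],
           v[2], v[3], v[5],
           v[4], v[5], v[6]), 3, 3)
}

frobenius6 <- function(v) {
  sqrt(sum(v[.DIAG6]^2) + 2 * sum(v[.OFF6]^2))
}

#' Deviatoric (anisotropy-only) part of a diffusion tensor
#'
#' Subtracts the isotropic part: `D - (trace(D)/3) * I`. The result is
#' trace-free and carries only the directional (anisotropic) information of
#' the tensor.
#'
#' @inheritParams as_tensor6
#' @return the deviatoric tensor, in the same representation as the input.
#' @export
deviatoric <- function(D) {
  mat_in <- is.matrix(D)
  v <- as_tensor6(D)
  tr3 <- sum(v[.DIAG6]) / 3
  v[.DIAG6] <- v[.DIAG6] - tr3
  if (mat_in) tensor_matrix(v) else v
}

#' Deviatoric tensor distance
#'
#' The non-Euclidean similarity used for tensor registration:
#' `sqrt(8*pi/15) * ||dev(D1) - dev(D2)||_F`, where `dev` removes the
#' isotropic part. Equivalently (closed form)
#' `sqrt(8*pi/15 * (||D1 - D2||_F^2 - Tr(D1 - D2)^2 / 3))`. Differences that
#' are purely isotropic have distance zero, so this is a pseudometric.
#'
#' @param D1,D2 tensors (3x3 symmetric matrices or 6-component vectors).
#' @param method `"deviatoric"` evaluates the definition through the
#'   deviatoric parts; `"closed"` evaluates the algebraically equivalent
#'   closed form on the raw difference. Both agree to rounding error.
#' @return a non-negative scalar.
#' @export
tensor_distance <- function(D1, D2, method = c("deviatoric", "closed")) {
  method <- match.arg(method)
  v1 <- as_tensor6(D1)
  v2 <- as_tensor6(D2)
  if (method == "deviatoric") {
    d <- deviatoric(v1) - deviatoric(v2)
    dn <- frobenius6(d)
    # a difference that is isotropic to working precision is distance 0
    scale <- frobenius6(v1) + frobenius6(v2) + frobenius6(v1 - v2)
    if (dn <= 1e-13 * scale) return(0)
    sqrt(METRIC_SCALE) * dn
  } else {
    d <- v1 - v2
    f2 <- sum(d[.DIAG6]^2) + 2 * sum(d[.OFF6]^2)
    tr <- sum(d[.DIAG6])
    rel <- f2 - tr^2 / 3
    # a difference that is isotropic to working precision is distance 0:
    # the first term absorbs the cancellation error of f2 - tr^2/3, the
    # second the rounding of the subtraction relative to the input scale
    floor_ <- 1e-13 * f2 + (1e-13 * (frobenius6(v1) + frobenius6(v2)))^2
    if (rel <= floor_) return(0)
    sqrt(max(0, METRIC_SCALE * rel))
  }
}

#' Fractional anisotropy of a tensor
#'
#' `FA = sqrt(3/2) * ||dev(D)||_F / ||D||_F`, clamped to \[0, 1\]; the zero
#' tensor maps to 0 by convention. This Frobenius form needs no
#' eigendecomposition, so tensors with small negative eigenvalues (as arise
#' from least-squares fitting of noisy data) are handled without clipping.
#'
#' @inheritParams as_tensor6
#' @return FA in \[0, 1\].
#' @export
fa <- function(D) {
  v <- as_tensor6(D)
  nrm <- frobenius6(v)
  if (nrm == 0) return(0)
  val <- sqrt(1.5) * frobenius6(deviatoric(v)) / nrm
  min(max(val, 0), 1)
}

#' Diffusion gradient scheme
#'
#' One direction and b-value per diffusion-weighted volume. Directions of
#' non-b0 volumes must be unit vectors; at least six distinct non-b0
#' directions plus one b0 volume are needed to fit a tensor.
#'
#' @param bvals numeric vector of b-values (s/mm^2), 0 for b0 volumes.
#' @param bvecs matrix of gradient directions, one row per volume.
#' @return an object of class `gradient_scheme`.
#' @export
gradient_scheme <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3) stop("bvecs must have 3 columns")
  if (nrow(bvecs) != length(bvals)) stop("one direction per b-value required")
  dwi <- bvals > 0
  if (any(dwi)) {
    nrm <- sqrt(rowSums(bvecs[dwi, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6))
      stop("non-b0 gradient directions must have unit norm (tol 1e-6)")
  }
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat("Gradient scheme:", sum(x$bvals == 0), "b0 +", sum(x$bvals > 0),
      "diffusion-weighted volumes, b =",
      paste(unique(x$bvals[x$bvals > 0]), collapse = "/"), "s/mm^2\n")
  invisible(x)
}

#' Tensor and scalar volumes
#'
#' `tensor_volume()` wraps a 3D lattice of diffusion tensors: a
#' `nx x ny x nz x 6` array of components (lower-triangular order), a 4x4
#' voxel-to-world affine (mm, 0-based voxel indices), and a logical
#' foreground mask. `scalar_volume()` is the analogous 3D scalar container
#' (FA maps, registered EPI volumes, parcellations).
#'
#' @param data the component array (`4D` with 6 components for tensors, `3D`
#'   for scalars).
#' @param affine 4x4 voxel-to-world matrix; must be invertible.
#' @param mask logical array matching the grid; defaults to all `TRUE`.
#' @return an object of class `tensor_volume` or `scalar_volume`.
#' @export
tensor_volume <- function(data, affine = diag(4), mask = NULL) {
  stopifnot(length(dim(data)) == 4, dim(data)[4] == 6)
  check_affine(affine)
  dm <- dim(data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dm)
  stopifnot(all(dim(mask) == dm))
  structure(list(data = data, affine = affine, mask = array(as.logical(mask), dm)),
            class = "tensor_volume")
}

#' @rdname tensor_volume
#' @export
scalar_volume <- function(data, affine = diag(4), mask = NULL) {
  stopifnot(length(dim(data)) == 3)
  check_affine(affine)
  dm <- dim(data)
  if (is.null(mask)) mask <- array(TRUE, dm)
  stopifnot(all(dim(mask) == dm))
  structure(list(data = data, affine = affine, mask = array(as.logical(mask), dm)),
            class = "scalar_volume")
}

check_affine <- function(affine) {
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
  if (abs(det(affine[1:3, 1:3])) < 1e-12) stop("affine must be invertible")
  invisible(affine)
}

grid_dim <- function(v) {
  if (inherits(v, "tensor_volume")) dim(v$data)[1:3] else dim(v$data)
}

same_grid <- function(a, b, tol = 1e-6) {
  all(grid_dim(a) == grid_dim(b)) && max(abs(a$affine - b$affine)) < tol
}

#' @export
print.tensor_volume <- function(x, ...) {
  dm <- grid_dim(x)
  cat("Tensor volume", paste(dm, collapse = " x "), "|",
      sum(x$mask), "foreground voxels | voxel size",
      paste(signif(voxel_size(x$affine), 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' @export
print.scalar_volume <- function(x, ...) {
  dm <- grid_dim(x)
  cat("Scalar volume", paste(dm, collapse = " x "), "|",
      sum(x$mask), "foreground voxels\n")
  invisible(x)
}

voxel_size <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' Fit diffusion tensors to a DWI stack by log-linear least squares
#'
#' Per voxel, solves `log S = log S0 - b g' D g` for the six tensor
#' components and log S0 in one linear least-squares fit. Voxels outside the
#' mask get the zero tensor; voxels with non-positive signal inside the mask
#' are flagged, zeroed, and reported in a warning.
#'
#' @param dwi 4D array (`nx x ny x nz x nvol`) of diffusion-weighted signals.
#' @param scheme a [gradient_scheme()] with one entry per volume.
#' @param mask optional logical array of voxels to fit.
#' @param affine voxel-to-world matrix carried to the output.
#' @return a [tensor_volume()]; flagged voxel indices (if any) are in
#'   `attr(, "flagged")`.
#' @export
fit_tensor <- function(dwi, scheme, mask = NULL, affine = diag(4)) {
  stopifnot(inherits(scheme, "gradient_scheme"), length(dim(dwi)) == 4)
  nvol <- dim(dwi)[4]
  if (nvol != length(scheme$bvals)) stop("scheme does not match DWI volume count")
  b <- scheme$bvals
  if (sum(b == 0) < 1) stop("at least one b0 volume is required")
  dirs <- scheme$bvecs[b > 0, , drop = FALSE]
  if (nrow(unique(round(dirs, 8))) < 6)
    stop("invalid scheme: fewer than 6 distinct non-b0 directions")

  dm <- dim(dwi)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dm)
  g <- scheme$bvecs
  # design: log S0 intercept + the six quadratic-form weights
  X <- cbind(1,
             -b * g[, 1]^2, -b * 2 * g[, 1] * g[, 2], -b * g[, 2]^2,
             -b * 2 * g[, 1] * g[, 3], -b * 2 * g[, 2] * g[, 3], -b * g[, 3]^2)
  idx <- which(mask)
  S <- matrix(aperm(dwi, c(4, 1, 2, 3)), nrow = nvol)[, idx, drop = FALSE]
  bad <- colSums(S <= 0) > 0
  comp <- array(0, c(dm, 6))
  if (any(!bad)) {
    beta <- qr.coef(qr(X), log(S[, !bad, drop = FALSE]))
    compflat <- matrix(0, length(idx), 6)
    compflat[!bad, ] <- t(beta[2:7, , drop = FALSE])
    for (c6 in 1:6) {
      plane <- array(0, dm)
      plane[idx] <- compflat[, c6]
      comp[, , , c6] <- plane
    }
  }
  if (any(bad)) {
    warning(sum(bad), " voxel(s) with non-positive signal inside mask; zeroed")
  }
  out <- tensor_volume(comp, affine = affine, mask = mask)
  attr(out, "flagged") <- idx[bad]
  out
}

#' Voxel-wise FA map of a tensor volume
#'
#' @param tv a [tensor_volume()].
#' @return a [scalar_volume()] of fractional anisotropy, 0 outside the mask.
#' @export
fa_map <- function(tv) {
  stopifnot(inherits(tv, "tensor_volume"))
  d <- tv$data
  f2 <- d[, , , 1]^2 + d[, , , 3]^2 + d[, , , 6]^2 +
    2 * (d[, , , 2]^2 + d[, , , 4]^2 + d[, , , 5]^2)
  tr <- d[, , , 1] + d[, , , 3] + d[, , , 6]
  dev2 <- pmax(f2 - tr^2 / 3, 0)
  out <- array(0, grid_dim(tv))
  nz <- f2 > 0
  out[nz] <- pmin(pmax(sqrt(1.5 * dev2[nz] / f2[nz]), 0), 1)
  out[!tv$mask] <- 0
  scalar_volume(out, affine = tv$affine, mask = tv$mask)
}

#' Squared-metric distance between two tensor volumes
#'
#' Sum over masked voxels of the squared deviatoric tensor distance; this is
#' the registration objective evaluated at identity alignment.
#'
#' @param v1,v2 [tensor_volume()]s on the same grid.
#' @param mask optional logical array; defaults to the intersection of the
#'   two volume masks.
#' @return a non-negative scalar.
#' @export
volume_distance <- function(v1, v2, mask = NULL) {
  stopifnot(inherits(v1, "tensor_volume"), inherits(v2, "tensor_volume"))
  if (!same_grid(v1, v2)) stop("volumes are not on the same grid")
  if (is.null(mask)) mask <- v1$mask & v2$mask
  d <- v1$data - v2$data
  f2 <- d[, , , 1]^2 + d[, , , 3]^2 + d[, , , 6]^2 +
    2 * (d[, , , 2]^2 + d[, , , 4]^2 + d[, , , 5]^2)
  tr <- d[, , , 1] + d[, , , 3] + d[, , , 6]
  d2 <- pmax(METRIC_SCALE * (f2 - tr^2 / 3), 0)
  sum(d2[mask])
}

#' Component-wise (Euclidean) mean of tensor volumes
#'
#' @param volumes a list of [tensor_volume()]s on identical grids.
#' @return a [tensor_volume()] whose mask is the intersection of the input
#'   masks.
#' @export
average_tensor_volumes <- function(volumes) {
  if (length(volumes) == 0) stop("cannot average an empty list of volumes")
  stopifnot(all(vapply(volumes, inherits, logical(1), "tensor_volume")))
  for (v in volumes[-1]) {
    if (!same_grid(volumes[[1]], v)) stop("volumes are not on the same grid")
  }
  acc <- volumes[[1]]$data
  msk <- volumes[[1]]$mask
  for (v in volumes[-1]) {
    acc <- acc + v$data
    msk <- msk & v$mask
  }
  tensor_volume(acc / length(volumes), affine = volumes[[1]]$affine, mask = msk)
}
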