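# Spatial transforms. All transforms act on world (mm) coordinates and are
# used in pull-back fashion: a transform attached to a registration maps
# points of the *output* (template) space to the *source* (subject) space.

#' Affine world-coordinate transform
#'
#' `y = A x + t` with `det(A) > 0`.
#'
#' @param A 3x3 linear part.
#' @param t length-3 translation (mm).
#' @return an object of class `affine_transform`.
#' @export
affine_transform <- function(A = diag(3), t = c(0, 0, 0)) {
  A <- as.matrix(A)
  stopifnot(all(dim(A) == c(3, 3)), length(t) == 3)
  if (det(A) <= 0) stop("affine linear part must have positive determinant")
  structure(list(A = A, t = as.numeric(t)), class = "affine_transform")
}

#' Piecewise-affine transform on a regular block lattice
#'
#' One affine map per block of a regular partition of the template domain,
#' blended with trilinear weights between the 8 nearest block centres so that
#' the overall map is continuous; beyond the centre lattice the weights clamp,
#' extending the map affinely.
#'
#' @param params `nb x 12` matrix, one row per block in x-fastest order:
#'   the row-major 3x3 linear part followed by the translation (mm).
#' @param counts integer block counts per axis, `nb = prod(counts)`.
#' @param lo lower corner of the covered domain (world mm).
#' @param spacing block width per axis (mm); block centre `i` (0-based) sits
#'   at `lo + (i + 0.5) * spacing`.
#' @return an object of class `piecewise_affine`.
#' @export
piecewise_affine <- function(params, counts, lo, spacing) {
  params <- as.matrix(params)
  counts <- as.integer(counts)
  stopifnot(length(counts) == 3, ncol(params) == 12,
            nrow(params) == prod(counts),
            length(lo) == 3, length(spacing) == 3, all(spacing > 0))
  structure(list(params = params, counts = counts,
                 lo = as.numeric(lo), spacing = as.numeric(spacing)),
            class = "piecewise_affine")
}

#' @export
print.piecewise_affine <- function(x, ...) {
  cat("Piecewise-affine transform:", paste(x$counts, collapse = " x "),
      "blocks over [", paste(signif(x$lo, 4), collapse = ", "), "] +",
      paste(signif(x$counts * x$spacing, 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' Domain (axis-aligned bounding box) of a volume's grid in world coordinates
#'
#' @param v a volume or a `list(dim, affine)` grid descriptor.
#' @return `list(lo, hi)` in mm, covering the full voxel extent.
#' @export
grid_domain <- function(v) {
  g <- as_grid(v)
  n <- g$dim
  corners <- as.matrix(expand.grid(c(-0.5, n[1] - 0.5),
                                   c(-0.5, n[2] - 0.5),
                                   c(-0.5, n[3] - 0.5)))
  w <- corners %*% t(g$affine[1:3, 1:3]) +
    matrix(g$affine[1:3, 4], nrow(corners), 3, byrow = TRUE)
  list(lo = apply(w, 2, min), hi = apply(w, 2, max))
}

as_grid <- function(v) {
  if (inherits(v, c("tensor_volume", "scalar_volume")))
    list(dim = grid_dim(v), affine = v$affine, mask = v$mask)
  else if (is.list(v) && !is.null(v$dim) && !is.null(v$affine))
    list(dim = as.integer(v$dim), affine = v$affine, mask = v$mask)
  else stop("expected a volume or a list(dim, affine)")
}

#' Construct a piecewise-affine transform from a single affine
#'
#' Every block receives the same affine, so the blended map equals the
#' affine exactly. `pa_identity()` is the identity special case.
#'
#' @param af an [affine_transform()].
#' @param domain a `list(lo, hi)` as from [grid_domain()], or a volume.
#' @param counts block counts per axis.
#' @return a [piecewise_affine()].
#' @export
pa_from_affine <- function(af, domain, counts = c(1, 1, 1)) {
  stopifnot(inherits(af, "affine_transform"))
  if (!is.list(domain) || is.null(domain$lo)) domain <- grid_domain(domain)
  nb <- prod(counts)
  row <- c(t(af$A), af$t)
  piecewise_affine(matrix(row, nb, 12, byrow = TRUE), counts,
                   domain$lo, (domain$hi - domain$lo) / counts)
}

#' @rdname pa_from_affine
#' @export
pa_identity <- function(domain, counts = c(1, 1, 1)) {
  pa_from_affine(affine_transform(), domain, counts)
}

#' Map world points through a transform
#'
#' @param phi a transform (`affine_transform`, `piecewise_affine`, or a
#'   composition from [compose_transforms()]).
#' @param X `n x 3` matrix of world coordinates (mm).
#' @return `n x 3` matrix of mapped coordinates.
#' @export
transform_points <- function(phi, X) UseMethod("transform_points")

#' @export
transform_points.affine_transform <- function(phi, X) {
  X %*% t(phi$A) + matrix(phi$t, nrow(X), 3, byrow = TRUE)
}

#' @export
transform_points.piecewise_affine <- function(phi, X) {
  cpp_pa_points(phi$params, phi$counts, phi$lo, phi$spacing, as.matrix(X))
}

#' Local Jacobian matrices of a transform
#'
#' The full analytic derivative of the blended map, including the
#' blend-weight gradient term (the map is differentiable away from the
#' centre-lattice cell faces).
#'
#' @inheritParams transform_points
#' @return `n x 9` matrix of row-major 3x3 Jacobians.
#' @export
local_jacobian <- function(phi, X) UseMethod("local_jacobian")

#' @export
local_jacobian.affine_transform <- function(phi, X) {
  matrix(c(t(phi$A)), nrow(X), 9, byrow = TRUE)
}

#' @export
local_jacobian.piecewise_affine <- function(phi, X) {
  cpp_pa_jacobian(phi$params, phi$counts, phi$lo, phi$spacing, as.matrix(X))
}

#' Compose two transforms
#'
#' Returns the transform `x -> outer(inner(x))`. Under pull-back resampling,
#' warping a volume by `inner` and the result by `outer` equals (up to
#' interpolation) a single warp by `compose_transforms(inner, outer)`:
#' the second warp samples at `inner(outer(x))`.
#'
#' @param outer,inner transforms.
#' @return an object of class `composed_transform`.
#' @export
compose_transforms <- function(outer, inner) {
  structure(list(outer = outer, inner = inner), class = "composed_transform")
}

#' @export
transform_points.composed_transform <- function(phi, X) {
  transform_points(phi$outer, transform_points(phi$inner, X))
}

#' @export
local_jacobian.composed_transform <- function(phi, X) {
  Ji <- local_jacobian(phi$inner, X)
  Jo <- local_jacobian(phi$outer, transform_points(phi$inner, X))
  out <- matrix(0, nrow(X), 9)
  for (r in 1:3) for (cc in 1:3) {
    # (Jo %*% Ji)[r,cc] per point, row-major layout
    out[, 3 * (r - 1) + cc] <-
      Jo[, 3 * (r - 1) + 1] * Ji[, cc] +
      Jo[, 3 * (r - 1) + 2] * Ji[, 3 + cc] +
      Jo[, 3 * (r - 1) + 3] * Ji[, 6 + cc]
  }
  out
}

# world coordinates of every voxel (0-based indices), n x 3
grid_world_coords <- function(grid, subset = NULL) {
  g <- as_grid(grid)
  n <- g$dim
  if (is.null(subset)) subset <- seq_len(prod(n))
  lin0 <- subset - 1L
  i <- lin0 %% n[1]
  j <- (lin0 %/% n[1]) %% n[2]
  k <- lin0 %/% (n[1] * n[2])
  V <- cbind(i, j, k)
  V %*% t(g$affine[1:3, 1:3]) +
    matrix(g$affine[1:3, 4], length(subset), 3, byrow = TRUE)
}

#' Serialize transforms to and from JSON
#'
#' Stores the block lattice geometry and the 12 parameters per block.
#'
#' @param phi a [piecewise_affine()] transform.
#' @param path file path.
#' @return `read_transform()` returns the transform, invisibly `path` for
#'   the writer.
#' @export
write_transform <- function(phi, path) {
  stopifnot(inherits(phi, "piecewise_affine"))
  obj <- list(type = "piecewise_affine", counts = phi$counts,
              lo = phi$lo, spacing = phi$spacing, params = phi$params)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "piecewise_affine")) stop("unknown transform type")
  piecewise_affine(obj$params, obj$counts, obj$lo, obj$spacing)
}
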