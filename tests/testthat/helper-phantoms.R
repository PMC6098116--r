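# shared fixtures, built in code and memoized within the test session

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a compact straight-tract spec for 16^3 unit-test phantoms
small_spec <- function(...) {
  args <- list(...)
  defaults <- list(grid = c(16, 16, 16), voxel = c(2, 2, 2),
                   curves = list(cbind(seq(-5, 5, length.out = 60), 0, 0)),
                   tract_radius = 3, gm_thickness = 4)
  do.call(phantom_spec, modifyList(defaults, args))
}

# the standard 32^3 arc template (deterministic, no RNG)
std_template <- function() {
  cached("std_template", make_template(phantom_spec()))
}

# random symmetric 3x3 tensor with entries of order `scale`
random_tensor <- function(scale = 1) {
  M <- matrix(rnorm(9, sd = scale), 3, 3)
  (M + t(M)) / 2
}

random_rotation <- function() {
  qr_res <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# forward-simulate noiseless DWI signals from one tensor on a small grid
simulate_signals <- function(D, dims, scheme, s0 = 1000) {
  v6 <- as_tensor6(D)
  nvol <- length(scheme$bvals)
  S <- array(0, c(dims, nvol))
  for (k in seq_len(nvol)) {
    g <- scheme$bvecs[k, ]
    q <- g[1]^2 * v6[1] + 2 * g[1] * g[2] * v6[2] + g[2]^2 * v6[3] +
      2 * g[1] * g[3] * v6[4] + 2 * g[2] * g[3] * v6[5] + g[3]^2 * v6[6]
    S[, , , k] <- s0 * exp(-scheme$bvals[k] * q)
  }
  S
}

std_scheme <- function(n_dirs = 30, b = 1000) {
  dirs <- fibonacci_directions(n_dirs)
  gradient_scheme(c(0, rep(b, n_dirs)), rbind(c(0, 0, 0), dirs))
}

# small affine helper for recovery tests
rigid_affine <- function(angles_deg = c(0, 0, 0), scale = c(1, 1, 1),
                         t = c(0, 0, 0)) {
  a <- angles_deg * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  affine_transform(Rz %*% Ry %*% Rx %*% diag(scale), t)
}

# fast registration schedule used throughout the phantom tests
fast_cfg <- function(...) {
  reg_config(pyramid = c(2, 1), blocks = list(c(1, 1, 1), c(1, 1, 1)), ...)
}
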