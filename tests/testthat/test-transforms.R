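# piecewise-affine transforms, warping, Jacobian maps, parcel features

test_that("a one-block lattice reproduces its affine exactly", {
  dom <- list(lo = c(-32, -32, -32), hi = c(32, 32, 32))
  af <- rigid_affine(c(5, -3, 8), c(1.05, 0.95, 1), c(4, -2, 1))
  phi <- pa_from_affine(af, dom)
  set.seed(11)
  X <- matrix(runif(300, -40, 40), 100, 3)  # incl. points outside the domain
  expect_equal(transform_points(phi, X), transform_points(af, X),
               tolerance = 1e-12)
  expect_equal(local_jacobian(phi, X), local_jacobian(af, X),
               tolerance = 1e-12)
})

test_that("blended map is continuous and its Jacobian matches finite differences", {
  dom <- list(lo = c(-30, -30, -30), hi = c(30, 30, 30))
  counts <- c(3, 2, 2)
  set.seed(12)
  nb <- prod(counts)
  params <- matrix(0, nb, 12)
  for (b in seq_len(nb)) {
    A <- diag(3) + matrix(runif(9, -0.1, 0.1), 3, 3)
    params[b, ] <- c(t(A), runif(3, -4, 4))
  }
  phi <- piecewise_affine(params, counts, dom$lo,
                          (dom$hi - dom$lo) / counts)
  # continuity: tiny steps produce tiny output changes across the volume
  X <- matrix(runif(600, -29, 29), 200, 3)
  h <- 1e-5
  for (d in 1:3) {
    Xh <- X; Xh[, d] <- Xh[, d] + h
    expect_lt(max(abs(transform_points(phi, Xh) - transform_points(phi, X))),
              1e-3)
  }
  # analytic Jacobian vs central differences at cell-interior points
  Xi <- matrix(runif(150, -25, 25), 50, 3)
  J <- local_jacobian(phi, Xi)
  h <- 1e-4
  for (d in 1:3) {
    Xp <- Xi; Xp[, d] <- Xp[, d] + h
    Xm <- Xi; Xm[, d] <- Xm[, d] - h
    num <- (transform_points(phi, Xp) - transform_points(phi, Xm)) / (2 * h)
    for (r in 1:3)
      expect_lt(max(abs(J[, 3 * (r - 1) + d] - num[, r])), 1e-3)
  }
})

test_that("identity warp leaves tensor volumes unchanged", {
  tmpl <- std_template()
  w <- apply_transform_tensor(tmpl, pa_identity(grid_domain(tmpl)), tmpl)
  expect_equal(w$data, tmpl$data, tolerance = 1e-12)
  expect_equal(w$mask, tmpl$mask)
})

test_that("rigid rotation preserves FA and rotates principal directions", {
  # piecewise-constant phantom: two constant-tensor half-spaces split at x=0,
  # rotated about the x axis so no blending occurs across the interface
  dm <- c(16, 16, 16)
  aff <- diag(4); aff[1:3, 4] <- -(dm - 1) / 2
  comp <- array(0, c(dm, 6))
  DA <- as_tensor6(diag(c(1.7, 0.3, 0.3)) * 1e-3)
  DB <- as_tensor6(diag(c(0.9, 0.7, 0.7)) * 1e-3)
  for (c6 in 1:6) {
    comp[1:8, , , c6] <- DA[c6]
    comp[9:16, , , c6] <- DB[c6]
  }
  v <- tensor_volume(comp, affine = aff)
  af <- rigid_affine(c(10, 0, 0))
  phi <- pa_from_affine(af, v)
  w <- apply_transform_tensor(v, phi, v)
  fa_in <- fa_map(v)$data
  fa_out <- fa_map(w)$data
  expect_lt(mean(abs(fa_out[w$mask] - fa_in[w$mask])), 0.02)
  # principal direction of a warped interior voxel equals R^T e1 (pull-back)
  Dw <- tensor_matrix(w$data[4, 8, 8, ])
  e_w <- eigen(Dw, symmetric = TRUE)$vectors[, 1]
  e_expected <- t(af$A) %*% c(1, 0, 0)
  expect_gt(abs(sum(e_w * e_expected)), 0.99)
})

test_that("warp composition matches the composed transform", {
  tmpl <- std_template()
  phi1 <- pa_from_affine(rigid_affine(c(0, 0, 6), t = c(2, 0, 0)), tmpl)
  phi2 <- pa_from_affine(rigid_affine(c(4, 0, 0), t = c(0, -2, 1)), tmpl)
  two_step <- apply_transform_tensor(apply_transform_tensor(tmpl, phi1, tmpl),
                                     phi2, tmpl)
  one_step <- apply_transform_tensor(tmpl, compose_transforms(phi1, phi2), tmpl)
  both <- two_step$mask & one_step$mask
  expect_lt(mean(abs(two_step$data - one_step$data)[array(both, c(dim(both), 6))]),
            2e-5)
})

test_that("scalar warping: exact shifts and exact linear ramps", {
  dm <- c(10, 10, 10)
  aff <- diag(4)
  ramp <- array(0, dm)
  for (i in 1:10) ramp[i, , ] <- i - 1  # linear in x (world = voxel here)
  v <- scalar_volume(ramp, affine = aff)
  dom <- grid_domain(v)
  # integer translation + nearest -> exact shift
  phi <- pa_from_affine(affine_transform(t = c(2, 0, 0)), dom)
  w <- apply_transform_scalar(v, phi, v, interpolation = "nearest")
  expect_equal(w$data[1:8, , ], ramp[3:10, , ])
  # half-voxel shift + trilinear on a linear field -> exact ramp values
  phi_h <- pa_from_affine(affine_transform(t = c(0.5, 0, 0)), dom)
  wh <- apply_transform_scalar(v, phi_h, v)
  inside <- wh$inside
  expect_equal(wh$data[2:9, 2:9, 2:9],
               ramp[2:9, 2:9, 2:9] + 0.5, tolerance = 1e-12)
  # out-of-field voxels are zero and mask-excluded
  expect_true(all(wh$data[10, , ] == 0))
  expect_true(all(!wh$mask[10, , ]))
})

test_that("jacobian map: identity, uniform scaling, and a numeric oracle", {
  grid <- list(dim = c(8, 8, 8), affine = diag(4))
  dom <- grid_domain(grid)
  expect_equal(unique(c(jacobian_map(pa_identity(dom), grid)$data)), 1)
  s <- 1.3
  phi_s <- pa_from_affine(affine_transform(diag(3) * s), dom)
  expect_equal(unique(round(c(jacobian_map(phi_s, grid)$data), 10)), s^3)
  # arbitrary piecewise transform vs central finite differences
  set.seed(13)
  params <- matrix(0, 8, 12)
  for (b in 1:8) params[b, ] <- c(t(diag(3) + matrix(runif(9, -0.08, 0.08), 3, 3)),
                                  runif(3, -1, 1))
  phi <- piecewise_affine(params, c(2, 2, 2), dom$lo, (dom$hi - dom$lo) / 2)
  jm <- jacobian_map(phi, grid)
  X <- grid_world_coords(grid)
  h <- 1e-4
  Jnum <- matrix(0, nrow(X), 9)
  for (d in 1:3) {
    Xp <- X; Xp[, d] <- Xp[, d] + h
    Xm <- X; Xm[, d] <- Xm[, d] - h
    num <- (transform_points(phi, Xp) - transform_points(phi, Xm)) / (2 * h)
    for (r in 1:3) Jnum[, 3 * (r - 1) + d] <- num[, r]
  }
  detnum <- Jnum[, 1] * (Jnum[, 5] * Jnum[, 9] - Jnum[, 6] * Jnum[, 8]) -
    Jnum[, 2] * (Jnum[, 4] * Jnum[, 9] - Jnum[, 6] * Jnum[, 7]) +
    Jnum[, 3] * (Jnum[, 4] * Jnum[, 8] - Jnum[, 5] * Jnum[, 7])
  expect_lt(max(abs(c(jm$data) - detnum)), 1e-3)
})

test_that("parcel Jacobian features equal group-by means", {
  grid <- list(dim = c(6, 6, 6), affine = diag(4))
  dom <- grid_domain(grid)
  phi <- pa_identity(dom)
  lab <- array(sample(0:3, 216, replace = TRUE), c(6, 6, 6))
  parc <- scalar_volume(lab * 1, affine = diag(4))
  f <- parcel_jacobian_features(jacobian_map(phi, grid), parc)
  expect_equal(unname(f), rep(1, 3))
  # known values in a two-parcel volume
  jd <- array(0, c(6, 6, 6))
  jd[lab == 1] <- 2.5
  jd[lab == 2] <- 0.5
  f2 <- parcel_jacobian_features(scalar_volume(jd, affine = diag(4)), parc,
                                 labels = c(1, 2))
  expect_equal(unname(f2), c(2.5, 0.5))
  # random field vs brute-force tapply
  jr <- scalar_volume(array(rnorm(216), c(6, 6, 6)), affine = diag(4))
  f3 <- parcel_jacobian_features(jr, parc)
  brute <- tapply(jr$data[lab > 0], lab[lab > 0], mean)
  expect_equal(unname(f3), unname(c(brute)))
  # empty requested parcel yields NA with a warning
  expect_warning(f4 <- parcel_jacobian_features(jr, parc, labels = c(1, 9)),
                 "empty")
  expect_true(is.na(f4["9"]))
})

test_that("transforms serialize to JSON and back", {
  dom <- list(lo = c(-10, -12, -8), hi = c(10, 12, 8))
  set.seed(14)
  params <- matrix(rnorm(8 * 12), 8, 12)
  phi <- piecewise_affine(params, c(2, 2, 2), dom$lo, (dom$hi - dom$lo) / 2)
  path <- tempfile(fileext = ".json")
  write_transform(phi, path)
  phi2 <- read_transform(path)
  expect_equal(phi2$params, phi$params)
  expect_equal(phi2$counts, phi$counts)
  expect_equal(phi2$lo, phi$lo)
  expect_equal(phi2$spacing, phi$spacing)
})
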