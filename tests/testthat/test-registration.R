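# registration: identity, known-transform recovery, common-space construction

test_that("registering a volume to itself stays at identity", {
  tmpl <- std_template()
  res <- register_tensor(tmpl, tmpl, fast_cfg())
  err <- mean_displacement_error(res$transform, NULL, tmpl)
  expect_lt(err, 0.05)
  expect_true(all(diff(res$objective) <= 1e-9 * max(res$objective[1], 1)))
  expect_lt(res$objective[length(res$objective)], 1e-10)
})

test_that("a two-voxel translation is recovered below half a voxel", {
  tmpl <- std_template()
  truth <- pa_from_affine(affine_transform(t = c(4, -4, 0)), tmpl)
  moved <- apply_transform_tensor(tmpl, truth, tmpl)
  res <- register_tensor(moved, tmpl, fast_cfg())
  expect_lt(mean_displacement_error(res$transform, truth, tmpl), 0.5)
})

test_that("a 10-degree rotation is recovered and FA distributions match", {
  tmpl <- std_template()
  truth <- pa_from_affine(rigid_affine(c(0, 0, 10)), tmpl)
  moved <- apply_transform_tensor(tmpl, truth, tmpl)
  res <- register_tensor(moved, tmpl, fast_cfg())
  expect_lt(mean_displacement_error(res$transform, truth, tmpl), 0.5)
})

test_that("registering back a rotated volume preserves the FA histogram", {
  # fat piecewise-constant phantom: interpolation affects few voxels, so the
  # FA distribution of the registered-back volume matches the target closely
  dm <- c(16, 16, 16)
  aff <- diag(4); aff[1:3, 4] <- -(dm - 1) / 2
  comp <- array(0, c(dm, 6))
  DA <- as_tensor6(diag(c(1.7, 0.3, 0.3)) * 1e-3)
  DB <- as_tensor6(diag(c(0.9, 0.7, 0.7)) * 1e-3)
  for (c6 in 1:6) {
    comp[, , 1:8, c6] <- DA[c6]
    comp[, , 9:16, c6] <- DB[c6]
  }
  v <- tensor_volume(comp, affine = aff)
  truth <- pa_from_affine(rigid_affine(c(0, 0, 10)), v)
  moved <- apply_transform_tensor(v, truth, v)
  res <- register_tensor(moved, v, fast_cfg())
  back <- apply_transform_tensor(moved, res$transform, v)
  core <- back$mask & v$mask
  br <- seq(0, 1, by = 0.1)
  h1 <- hist(fa_map(v)$data[core], breaks = br, plot = FALSE)$counts
  h2 <- hist(fa_map(back)$data[core], breaks = br, plot = FALSE)$counts
  expect_lt(sum(abs(h1 / sum(h1) - h2 / sum(h2))), 0.02 * 2)
})

test_that("scalar registration recovers a known translation and survives noise", {
  tmpl <- std_template()
  t1 <- scalar_volume(attr(tmpl, "t1"), affine = tmpl$affine, mask = tmpl$mask)
  truth <- pa_from_affine(affine_transform(t = c(-4, 2, 2)), tmpl)
  moved <- apply_transform_scalar(t1, truth, t1)
  res <- register_scalar(moved, t1, fast_cfg())
  expect_lt(mean_displacement_error(res$transform, truth, tmpl), 0.5)
  # pure-noise source: must not crash; returns a usable result object
  set.seed(20)
  noise <- scalar_volume(array(rnorm(prod(grid_dim(tmpl))), grid_dim(tmpl)),
                         affine = tmpl$affine, mask = tmpl$mask)
  resn <- register_scalar(noise, t1, fast_cfg(max_sweeps = 10))
  expect_s3_class(resn, "registration_result")
  expect_true(is.logical(resn$converged))
  expect_true(all(diff(resn$objective) <= 1e-9 * max(resn$objective[1], 1)))
})

test_that("objective trajectories are non-increasing at every level", {
  spec <- phantom_spec(seed = 31)
  coh <- make_cohort(3, spec)
  res <- register_tensor(coh$subjects[[2]]$tensors, coh$template, fast_cfg())
  for (traj in res$trace)
    expect_true(all(diff(traj) <= 1e-9 * max(traj[1], 1)))
})

test_that("empty masks are rejected", {
  tmpl <- std_template()
  empty <- tmpl
  empty$mask[] <- FALSE
  expect_error(register_tensor(empty, tmpl, fast_cfg()), "empty mask")
})

test_that("identical subjects give a common space fixed at identity", {
  spec <- small_spec()
  tmpl <- make_template(spec)
  cs <- build_common_space(list(tmpl, tmpl, tmpl), template_id = 1,
                           config = fast_cfg())
  expect_equal(length(cs$transforms), 3)
  expect_lt(max(abs(cs$template$data - tmpl$data)), 1e-10)
  for (phi in cs$transforms)
    expect_lt(mean_displacement_error(phi, NULL, tmpl), 0.1)
})

test_that("two translated subjects re-register onto a centred mean", {
  tmpl <- std_template()
  dom <- grid_domain(tmpl)
  mk <- function(t) apply_transform_tensor(
    tmpl, pa_from_affine(affine_transform(t = t), dom), tmpl)
  s2 <- mk(c(4, 0, 0))
  s3 <- mk(c(-4, 0, 0))
  cs <- build_common_space(list(tmpl, s2, s3), template_id = 1,
                           config = fast_cfg())
  # residual metric after registration far below the unregistered one
  subs <- list(`2` = s2, `3` = s3)
  for (s in c("2", "3")) {
    pre <- volume_distance(subs[[s]], cs$template, mask = cs$template$mask)
    warped <- apply_transform_tensor(subs[[s]], cs$transforms[[s]], cs$template)
    post <- volume_distance(warped, cs$template, mask = cs$template$mask)
    expect_lt(post, 0.1 * pre)
  }
})

test_that("common space is stable under permutation of non-template subjects", {
  spec <- small_spec(seed = 7)
  tmpl <- make_template(spec)
  s2 <- make_subject(tmpl, spec, 1001, "a")
  s3 <- make_subject(tmpl, spec, 1002, "b")
  cs1 <- build_common_space(list(tmpl, s2$tensors, s3$tensors),
                            template_id = 1, config = fast_cfg(),
                            transforms_for = 2:3)
  cs2 <- build_common_space(list(tmpl, s3$tensors, s2$tensors),
                            template_id = 1, config = fast_cfg(),
                            transforms_for = 2:3)
  expect_equal(cs1$template$data, cs2$template$data, tolerance = 1e-10)
  expect_equal(cs1$transforms[["2"]]$params, cs2$transforms[["3"]]$params,
               tolerance = 1e-8)
})

test_that("registration halves the displacement error of a known deformation", {
  spec <- phantom_spec(seed = 33)
  tmpl <- make_template(spec)
  s <- make_subject(tmpl, spec, 4242, "sub-x")
  err0 <- mean_displacement_error(pa_identity(grid_domain(tmpl)), s$truth, tmpl)
  res <- register_tensor(s$tensors, tmpl, fast_cfg())
  err <- mean_displacement_error(res$transform, s$truth, tmpl)
  expect_lt(err, 0.5 * err0)
})
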