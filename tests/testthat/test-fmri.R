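# functional-run preprocessing, ROI extraction, supervised voxel selection

# three-trial toy run: fixed 8 s Rest / 4 s Control / 8 s Attention at TR 2
toy_events <- function(n_trials = 3, sides = c("left", "right", "left")) {
  onset <- 10  # after the 5 discarded dummy volumes
  ev <- list()
  for (k in seq_len(n_trials)) {
    ev[[k]] <- data.frame(trial = k, phase = c("Rest", "Control", "Attention"),
                          onset = onset + c(0, 8, 12),
                          duration = c(8, 4, 8), side = c(NA, NA, sides[k]))
    onset <- onset + 20
  }
  do.call(rbind, ev)
}

toy_run <- function(signal, ...) {
  functional_run(signal, toy_events(), subject = "s1", run = 1L, ...)
}

no_shift <- function(...) prep_config(hemodynamic_delay = 0, ...)

test_that("phase averaging and baseline subtraction match a hand computation", {
  ev <- toy_events()
  Tn <- 40
  sig <- matrix(0, Tn, 2)
  # voxel 1: deterministic values; compute expected phase means by hand
  sig[, 1] <- seq_len(Tn)
  # trial k Attention covers TRs (onset/2+1):(onset+8)/2, Control likewise
  cfg <- prep_config(hemodynamic_delay = 0, detrend = FALSE,
                     winsor_mad = Inf, zscore = FALSE)
  pats <- preprocess_run(toy_run(sig), cfg)
  expected <- vapply(1:3, function(k) {
    att <- ev[ev$trial == k & ev$phase == "Attention", ]
    ctl <- ev[ev$trial == k & ev$phase == "Control", ]
    att_idx <- (att$onset / 2 + 1):((att$onset + att$duration) / 2)
    ctl_idx <- (ctl$onset / 2 + 1):((ctl$onset + ctl$duration) / 2)
    mean(sig[att_idx, 1]) - mean(sig[ctl_idx, 1])
  }, numeric(1))
  expect_equal(unname(pats$X[, 1]), expected)
  expect_equal(pats$labels, c(1L, -1L, 1L))
})

test_that("a pure linear trend yields all-zero features", {
  sig <- outer(seq_len(40), c(0.5, -1.2, 3))  # per-voxel linear trends
  pats <- preprocess_run(toy_run(sig), no_shift())
  expect_lt(max(abs(pats$X)), 1e-8)
  expect_equal(sort(pats$flagged), 1:3)  # zero variance after detrend
})

test_that("preprocessing is invariant to constant offsets and added trends", {
  set.seed(40)
  sig <- matrix(rnorm(40 * 5), 40, 5)
  base <- preprocess_run(toy_run(sig), no_shift())
  shifted <- sig + matrix(rep(c(10, -3, 5, 0, 100), each = 40), 40, 5) +
    outer(seq_len(40), c(1, 2, -1, 0.5, 0))
  again <- preprocess_run(toy_run(shifted), no_shift())
  expect_equal(base$X, again$X, tolerance = 1e-8)
})

test_that("z-scored features have zero mean and unit variance per voxel", {
  set.seed(41)
  ev <- toy_events(6, rep(c("left", "right"), 3))
  onset <- 10
  sig <- matrix(rnorm(80 * 4), 80, 4)
  run <- functional_run(sig, ev, subject = "s", run = 1L)
  pats <- preprocess_run(run, no_shift())
  expect_lt(max(abs(colMeans(pats$X))), 1e-10)
  expect_lt(max(abs(apply(pats$X, 2, sd) - 1)), 1e-10)
})

test_that("a noiseless lateralized boxcar is perfectly separable", {
  ev <- toy_events(4, c("left", "right", "left", "right"))
  Tn <- 95
  sig <- matrix(0, Tn, 2)
  for (k in 1:4) {
    att <- ev[ev$trial == k & ev$phase == "Attention", ]
    idx <- (att$onset / 2 + 1):((att$onset + att$duration) / 2)
    s <- if (att$side == "left") 1 else -1
    sig[idx, 1] <- s
    sig[idx, 2] <- -s
  }
  run <- functional_run(sig, ev, subject = "s", run = 1L)
  pats <- preprocess_run(run, no_shift())
  expect_true(all(pats$X[pats$labels == 1, 1] > 0))
  expect_true(all(pats$X[pats$labels == -1, 1] < 0))
  expect_true(all(pats$X[pats$labels == 1, 2] < 0))
})

test_that("trials truncated by the run end are dropped with a warning", {
  # events fit the run, but the hemodynamic shift pushes the last Attention
  # window past the final volume
  sig <- matrix(rnorm(36 * 2), 36, 2)
  expect_warning(pats <- preprocess_run(toy_run(sig),
                                        prep_config(hemodynamic_delay = 2)),
                 "truncated")
  expect_equal(nrow(pats$X), 2)
})

test_that("ROI extraction warps patterns into common space in fixed order", {
  dm <- c(8, 8, 8)
  grid <- list(dim = dm, affine = diag(4), mask = array(TRUE, dm))
  set.seed(42)
  X <- matrix(rnorm(3 * prod(dm)), 3, prod(dm))
  pats <- structure(list(X = X, labels = c(1L, -1L, 1L), runs = rep(1L, 3),
                         subject = "s", grid = grid,
                         voxels = seq_len(prod(dm)), flagged = integer(0)),
                    class = "trial_patterns")
  full_mask <- scalar_volume(array(1, dm), affine = diag(4))
  out <- extract_roi(pats, full_mask, NULL)
  expect_equal(out$X, X)
  # a 10-voxel ROI gives 10 features in ascending voxel order
  m10 <- array(0, dm); m10[sample(prod(dm), 10)] <- 1
  roi10 <- scalar_volume(m10, affine = diag(4))
  out10 <- extract_roi(pats, roi10, NULL)
  expect_equal(ncol(out10$X), 10)
  expect_equal(out10$voxels, which(m10 > 0))
  expect_equal(out10$X, X[, which(m10 > 0)])
  # known integer shift: equals warping each trial image then indexing
  phi <- pa_from_affine(affine_transform(t = c(1, 0, 0)), grid_domain(full_mask))
  outw <- extract_roi(pats, roi10, phi)
  img <- array(X[2, ], dm)
  wimg <- apply_transform_scalar(scalar_volume(img, affine = diag(4)), phi,
                                 full_mask)
  expect_equal(outw$X[2, ], wimg$data[which(m10 > 0)])
})

test_that("voxel selection ranks by summed absolute Welch t and respects ties", {
  set.seed(43)
  mkpat <- function(effect_voxel = 3, effect = 3, nv = 20, nt = 20) {
    X <- matrix(rnorm(nt * nv), nt, nv)
    labels <- rep(c(1L, -1L), nt / 2)
    X[labels == 1, effect_voxel] <- X[labels == 1, effect_voxel] + effect
    structure(list(X = X, labels = labels, runs = rep(1L, nt), subject = "r",
                   grid = NULL, voxels = seq_len(nv), flagged = integer(0)),
              class = "trial_patterns")
  }
  refs <- list(mkpat(), mkpat(), mkpat())
  sel_all <- select_voxels(refs, 1)
  expect_equal(as.integer(sel_all), 1:20)
  hits <- 0
  for (i in 1:100) {
    refs_i <- list(mkpat(), mkpat(), mkpat())
    if (identical(as.integer(select_voxels(refs_i, 0.05)), 3L)) hits <- hits + 1
  }
  expect_gte(hits, 95)
  # permutation symmetry and doubling a subject keeps the ranking
  s1 <- attr(select_voxels(refs, 0.5), "score")
  s2 <- attr(select_voxels(rev(refs), 0.5), "score")
  expect_equal(s1, s2)
  sdup <- attr(select_voxels(c(refs, refs[1]), 0.5), "score")
  expect_equal(order(-sdup)[1], order(-s1)[1])
  expect_error(select_voxels(refs, 0), "fraction")
  expect_error(select_voxels(refs, 1.2), "fraction")
})
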