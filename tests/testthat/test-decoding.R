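# linear SVM, conjunction / voting / self decoders, cross-validation hygiene

mkpats <- function(X, labels, subject = "s", runs = NULL) {
  structure(list(X = X, labels = as.integer(labels),
                 runs = if (is.null(runs)) rep(1L, nrow(X)) else runs,
                 subject = subject, grid = NULL, voxels = seq_len(ncol(X)),
                 flagged = integer(0)),
            class = "trial_patterns")
}

# pooled cohort of noisy lateralized patterns with a fixed informative voxel
sim_subject <- function(n_trials = 20, nv = 10, effect = 2, seed = 1,
                        subject = "s", runs_of = NULL) {
  set.seed(seed)
  labels <- rep(c(1L, -1L), n_trials / 2)
  X <- matrix(rnorm(n_trials * nv), n_trials, nv)
  X[, 1] <- X[, 1] + effect * labels
  mkpats(X, labels, subject, runs_of)
}

test_that("the linear SVM separates trivially separable data", {
  X <- rbind(c(1, 0), c(-1, 0))
  clf <- train_svm(X, c(1, -1))
  p <- predict(clf, X)
  expect_equal(as.integer(p), c(1L, -1L))
  # label flip negates the decision function
  clf2 <- train_svm(X, c(-1, 1))
  expect_equal(attr(predict(clf2, X), "decision"),
               -attr(predict(clf, X), "decision"), tolerance = 1e-6)
  expect_error(train_svm(X, c(1, 1)), "single class")
})

test_that("the SVM primal objective matches an independent optimizer", {
  set.seed(50)
  n <- 40
  y <- rep(c(1, -1), each = n / 2)
  X <- cbind(rnorm(n) + 2.2 * y, rnorm(n))
  clf <- train_svm(X, y, C = 1)
  primal <- function(wb) {
    w <- wb[1:2]; b <- wb[3]
    0.5 * sum(w^2) + sum(pmax(0, 1 - y * (X %*% w + b)))
  }
  ours <- primal(c(clf$w, clf$b))
  # independent oracle: direct minimization of the primal from many starts
  best <- Inf
  for (s in 1:5) {
    set.seed(s)
    o <- optim(c(clf$w, clf$b) * 0 + rnorm(3, sd = 0.5), primal,
               method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
    o2 <- optim(o$par, primal, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-14))
    best <- min(best, o2$value)
  }
  expect_lt(abs(ours - best), 1e-4 * max(1, best))
  expect_lte(best, ours + 1e-6)  # libSVM should not beat the optimum
})

test_that("conjunction decoding: perfect on a noiseless clone, folds honest", {
  base <- sim_subject(effect = 50, seed = 2, subject = "a")
  pats <- list(base,
               mkpats(base$X, base$labels, "b"),
               mkpats(base$X, base$labels, "c"))
  res <- conjunction_decode(pats, target = 3)
  expect_equal(res$accuracy, 100)
  # three subjects -> exactly three LOSO folds, each excluding its target
  tab <- transfer_decode(pats, "conjunction")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$subject, c("a", "b", "c"))
})

test_that("shuffled reference labels put transfer accuracy near chance", {
  set.seed(51)
  pats <- lapply(1:3, function(i) sim_subject(40, effect = 2, seed = 100 + i,
                                              subject = paste0("s", i)))
  shuffled <- lapply(pats[1:2], function(p) {
    p$labels <- sample(p$labels)
    p
  })
  res <- conjunction_decode(c(shuffled, pats[3]), target = 3)
  expect_gte(res$accuracy, 100 * qbinom(0.005, 40, 0.5) / 40)
  expect_lte(res$accuracy, 100 * qbinom(0.995, 40, 0.5) / 40)
})

test_that("voting: majority wins, exact ties are misses", {
  # construct 20 reference classifiers via duplicated perfect/inverted subjects
  good <- sim_subject(effect = 50, seed = 3, subject = "g")
  bad <- mkpats(good$X, -good$labels, "b")
  target <- mkpats(good$X, good$labels, "t")
  # 10 vs 10 votes: every trial is an exact tie -> all scored incorrect
  refs <- c(rep(list(good), 10), rep(list(bad), 10))
  res <- voting_decode(c(refs, list(target)), target = 21)
  expect_equal(res$accuracy, 0)
  expect_true(all(res$votes == 0))
  # 11 vs 9: the majority side prevails on every trial
  refs2 <- c(rep(list(good), 11), rep(list(bad), 9))
  res2 <- voting_decode(c(refs2, list(target)), target = 21)
  expect_equal(res2$accuracy, 100)
  # all classifiers identical -> voting equals the single classifier
  refs3 <- rep(list(good), 20)
  res3 <- voting_decode(c(refs3, list(target)), target = 21)
  single <- conjunction_decode(list(good, target), target = 2)
  expect_equal(res3$accuracy, single$accuracy)
})

test_that("self-decoding: five folds, perfect when separable, chance at zero effect", {
  runs <- rep(1:5, each = 10)
  pat <- sim_subject(50, effect = 50, seed = 4, runs_of = runs)
  res <- self_decode(pat)
  expect_length(res$folds, 5)
  expect_equal(res$accuracy, 100)
  accs <- vapply(1:20, function(s) {
    self_decode(sim_subject(50, effect = 0, seed = 200 + s,
                            runs_of = runs))$accuracy
  }, numeric(1))
  # mean of 20 null accuracies stays inside a generous binomial band
  expect_gt(mean(accs), 30)
  expect_lt(mean(accs), 70)
})

test_that("no information leaks from the target into transfer training", {
  pats <- lapply(1:4, function(i) sim_subject(20, effect = 2, seed = 300 + i,
                                              subject = paste0("s", i)))
  res1 <- conjunction_decode(pats, target = 4)
  # replacing the target's data entirely must not change the fold's training
  pats2 <- pats
  pats2[[4]]$X <- pats2[[4]]$X * 0 + 7
  refs <- setdiff(seq_along(pats), 4)
  clf1 <- train_svm(do.call(rbind, lapply(pats[refs], `[[`, "X")),
                    unlist(lapply(pats[refs], `[[`, "labels")))
  clf2 <- train_svm(do.call(rbind, lapply(pats2[refs], `[[`, "X")),
                    unlist(lapply(pats2[refs], `[[`, "labels")))
  expect_identical(clf1$w, clf2$w)
  expect_identical(clf1$b, clf2$b)
})

test_that("accuracy is invariant under a consistent feature permutation", {
  pats <- lapply(1:3, function(i) sim_subject(20, effect = 1.5, seed = 400 + i,
                                              subject = paste0("s", i)))
  perm <- sample(ncol(pats[[1]]$X))
  permed <- lapply(pats, function(p) {
    p$X <- p$X[, perm]
    p
  })
  for (tgt in 1:3) {
    expect_equal(conjunction_decode(permed, tgt)$accuracy,
                 conjunction_decode(pats, tgt)$accuracy)
    expect_equal(voting_decode(permed, tgt)$accuracy,
                 voting_decode(pats, tgt)$accuracy)
  }
})
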