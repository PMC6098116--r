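# Statistical comparisons: paired Wilcoxon, the jackknife
# area-under-regression test, the surrogate pairwise-distance test on
# deformation features, and PCA embedding.

#' Paired Wilcoxon signed-rank test on accuracy pairs
#'
#' Exact-distribution signed-rank test for up to 25 non-zero differences
#' (normal approximation above, or in the presence of ties); zero differences
#' are dropped, as in the standard signed-rank procedure. If every difference
#' is zero the test is degenerate and `p = 1` is returned with
#' `degenerate = TRUE`.
#'
#' @param a,b paired accuracy vectors (percent), same length.
#' @return list with `p_two_sided`, `p_greater` (one-sided, `a > b`),
#'   `n_nonzero`, `degenerate`.
#' @export
wilcoxon_paired <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  nz <- sum(d != 0)
  if (nz == 0)
    return(list(p_two_sided = 1, p_greater = 1, n_nonzero = 0L,
                degenerate = TRUE))
  if (nz < 6) stop("need at least 6 non-zero differences")
  exact <- nz <= 25 && !any(duplicated(abs(d[d != 0])))
  two <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = exact,
                                      correct = !exact))$p.value
  gr <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = exact,
                                     correct = !exact,
                                     alternative = "greater"))$p.value
  list(p_two_sided = two, p_greater = gr, n_nonzero = as.integer(nz),
       degenerate = FALSE)
}

area_under_line <- function(fit, x1, x2) {
  cf <- coef(fit)
  cf[1] * (x2 - x1) + cf[2] * (x2^2 - x1^2) / 2
}

#' Jackknife comparison of areas under two regression lines
#'
#' For scatter data (self-accuracy on x, transfer-accuracy on y) from two
#' methods A and B over the same subjects: each subject is deleted in turn,
#' ordinary least-squares lines are fitted to the remaining points of A and
#' B, and the signed difference (A - B) of the areas under the two lines over
#' the observed x-range of the retained points is recorded. The one-sided
#' p-value that the A line lies above the B line comes from a jackknife
#' t-statistic on the leave-one-out differences (the raw differences are
#' returned so other constructions can be applied).
#'
#' @param A,B data frames with columns `x` (self accuracy) and `y` (transfer
#'   accuracy), same subjects in the same order, `n >= 5`.
#' @return list with `differences` (one per left-out subject), `estimate`
#'   (their mean), `se` (jackknife standard error), `t`, `p` (one-sided,
#'   mean difference > 0), `n`.
#' @export
jackknife_area_test <- function(A, B) {
  stopifnot(is.data.frame(A), is.data.frame(B),
            all(c("x", "y") %in% names(A)), all(c("x", "y") %in% names(B)),
            nrow(A) == nrow(B))
  n <- nrow(A)
  if (n < 5) stop("need at least 5 subjects")
  if (diff(range(c(A$x, B$x))) <= 0) stop("degenerate x-range (all equal)")
  d <- vapply(seq_len(n), function(i) {
    Ai <- A[-i, ]
    Bi <- B[-i, ]
    xr <- range(c(Ai$x, Bi$x))
    if (diff(xr) <= 0) stop("degenerate x-range after deletion")
    area_under_line(lm(y ~ x, Ai), xr[1], xr[2]) -
      area_under_line(lm(y ~ x, Bi), xr[1], xr[2])
  }, numeric(1))
  est <- mean(d)
  se <- sqrt((n - 1) / n * sum((d - est)^2))
  if (se == 0) {
    p <- if (est > 0) 0 else 1
    t <- if (est == 0) 0 else sign(est) * Inf
  } else {
    t <- est / se
    p <- pt(t, df = n - 1, lower.tail = FALSE)
  }
  list(differences = d, estimate = est, se = se, t = t, p = p, n = n)
}

#' Surrogate test on the mean pairwise distance of a subject subset
#'
#' Observed statistic: the mean pairwise Euclidean distance among the
#' selected subjects in the original feature space (e.g. parcel-wise
#' Jacobian-determinant features). Surrogates: the same statistic on subsets
#' of the same size drawn uniformly (without replacement within a draw) from
#' all subjects. Small distances are significant;
#' `p = (1 + #\{surrogate <= observed\}) / (1 + n_surrogates)`.
#'
#' @param features subjects-by-features matrix.
#' @param selected indices of the selected subjects (>= 2).
#' @param n_surrogates number of surrogate draws (>= 99; default 10000).
#' @param seed RNG seed for the draws.
#' @return list with `observed`, `surrogates`, `p`, `n_surrogates`.
#' @export
surrogate_distance_test <- function(features, selected, n_surrogates = 10000,
                                    seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  k <- length(selected)
  if (k < 2) stop("need at least 2 selected subjects")
  if (k > n) stop("subset size exceeds the number of subjects")
  if (n_surrogates < 99) stop("need at least 99 surrogates")
  meandist <- function(idx) mean(dist(features[idx, , drop = FALSE]))
  obs <- meandist(selected)
  sur <- with_seed(seed, vapply(seq_len(n_surrogates), function(i)
    meandist(sample.int(n, k)), numeric(1)))
  p <- (1 + sum(sur <= obs)) / (1 + n_surrogates)
  structure(list(observed = obs, surrogates = sur, p = p,
                 n_surrogates = as.integer(n_surrogates)),
            class = "surrogate_test")
}

#' @export
print.surrogate_test <- function(x, ...) {
  cat(sprintf("Surrogate distance test: observed %.4g | p = %.4g (%d surrogates)\n",
              x$observed, x$p, x$n_surrogates))
  invisible(x)
}

#' PCA embedding of deformation features
#'
#' Mean-centred principal-component projection onto `k` dimensions,
#' components ordered by decreasing variance. Sign convention: within each
#' component the loading of largest magnitude is positive, so embeddings are
#' reproducible across platforms.
#'
#' @param features subjects-by-features matrix (at least `k + 1` subjects).
#' @param k embedding dimension (default 3).
#' @return list with `scores` (subjects x k), `explained` (variance ratios,
#'   length k), `rotation`.
#' @export
pca_embed <- function(features, k = 3) {
  features <- as.matrix(features)
  if (nrow(features) < k + 1) stop("need at least k + 1 subjects")
  pc <- prcomp(features, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-8)
  if (k > rank) stop("k exceeds the rank of the centred feature matrix")
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  rotation <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, "*")
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, explained = evr[seq_len(k)], rotation = rotation)
}
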