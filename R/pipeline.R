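# End-to-end cohort analysis: common-space construction, trial-pattern
# projection, and the transfer/self decoding battery on a synthetic cohort.

#' Run the subject-transfer decoding pipeline on a synthetic cohort
#'
#' Builds common coordinates from the cohort's anatomy (tensor volumes under
#' the deviatoric metric for `registration = "dti"`, pseudo-T1 volumes under
#' SSD for `"t1"`, or no registration at all for `"none"`), preprocesses
#' every analysis subject's task runs into trial patterns, projects them onto
#' the common grid restricted to the brain ROI, and evaluates conjunction,
#' naive-voting and self decoders.
#'
#' Subject 1 is the template subject and is excluded from decoding.
#'
#' @param cohort a `synthetic_cohort` from [make_cohort()].
#' @param registration `"dti"`, `"t1"` or `"none"`.
#' @param config a [reg_config()]; the default two-level global-affine
#'   chain (half then full resolution) is accurate and fast on the 32-voxel
#'   phantom grids, where coarser pyramids lose the thin tissue band and
#'   fine block lattices overfit acquisition noise.
#' @param fraction voxel fraction for within-fold supervised selection
#'   (1 = use the whole ROI).
#' @param schemes which decoders to run.
#' @param prep a [prep_config()].
#' @return list with `conjunction`, `voting`, `self` accuracy tables (percent
#'   per analysis subject), the `roi` size, `registration` tag, the
#'   common-space `transforms` and mean `template`.
#' @export
cohort_pipeline <- function(cohort,
                            registration = c("dti", "t1", "none"),
                            config = reg_config(pyramid = c(2, 1),
                                                blocks = list(c(1, 1, 1),
                                                              c(1, 1, 1))),
                            fraction = 1,
                            schemes = c("conjunction", "voting", "self"),
                            prep = prep_config()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  registration <- match.arg(registration)
  n <- length(cohort$subjects)
  analysis <- seq.int(2, n)

  if (registration == "dti") {
    vols <- lapply(cohort$subjects, `[[`, "tensors")
    cs <- build_common_space(vols, template_id = 1, config = config,
                             transforms_for = analysis)
    roi_mask <- cs$template$mask
    common <- cs$template
    transforms <- cs$transforms
  } else if (registration == "t1") {
    vols <- lapply(cohort$subjects, `[[`, "t1")
    cs <- build_common_space(vols, template_id = 1, config = config,
                             transforms_for = analysis)
    roi_mask <- cs$template$mask
    common <- cs$template
    transforms <- cs$transforms
  } else {
    masks <- lapply(cohort$subjects[analysis], function(s) s$tensors$mask)
    roi_mask <- Reduce(`&`, masks)
    common <- cohort$subjects[[1]]$tensors
    transforms <- NULL
  }
  roi <- scalar_volume(array(as.numeric(roi_mask), dim(roi_mask)),
                       affine = common$affine)

  patterns <- lapply(analysis, function(s) {
    subj <- cohort$subjects[[s]]
    pats <- combine_patterns(lapply(subj$runs, preprocess_run, config = prep))
    phi <- if (is.null(transforms)) NULL else transforms[[as.character(s)]]
    extract_roi(pats, roi, phi)
  })

  out <- list(registration = registration, roi_size = sum(roi_mask > 0),
              transforms = transforms, template = common)
  if ("conjunction" %in% schemes)
    out$conjunction <- transfer_decode(patterns, "conjunction", fraction)
  if ("voting" %in% schemes)
    out$voting <- transfer_decode(patterns, "voting", fraction)
  if ("self" %in% schemes)
    out$self <- data.frame(
      subject = vapply(patterns, function(p) as.character(p$subject), character(1)),
      accuracy = vapply(patterns, function(p) self_decode(p)$accuracy, numeric(1)))
  out
}

#' Synthetic parcellation of a brain mask
#'
#' Partitions the masked voxels into `n_parcels` spatially compact parcels by
#' k-means on world coordinates (seeded, deterministic). Stands in for an
#' anatomical parcellation when summarizing deformation (Jacobian) features.
#'
#' @param volume a volume whose mask is parcellated.
#' @param n_parcels number of parcels (default 28).
#' @param seed RNG seed for k-means initialization.
#' @return a [scalar_volume()] of integer labels (0 outside the mask).
#' @export
synthetic_parcellation <- function(volume, n_parcels = 28, seed = 1L) {
  g <- as_grid(volume)
  idx <- which(g$mask)
  stopifnot(length(idx) >= n_parcels)
  X <- grid_world_coords(g, idx)
  km <- with_seed(seed, kmeans(X, centers = n_parcels, nstart = 3,
                               iter.max = 50))
  lab <- array(0, g$dim)
  lab[idx] <- km$cluster
  scalar_volume(lab, affine = g$affine, mask = g$mask)
}

#' Parcel-wise Jacobian deformation features for a set of transforms
#'
#' For each subject transform, computes the Jacobian-determinant map on the
#' common grid and averages it within each parcel, yielding one
#' subjects-by-parcels feature matrix for deformation-similarity analyses
#' (PCA embedding, surrogate distance tests).
#'
#' @param transforms list of transforms (e.g. from [build_common_space()]).
#' @param parcellation a label [scalar_volume()] on the common grid.
#' @return matrix, subjects by parcels.
#' @export
deformation_features <- function(transforms, parcellation) {
  feats <- lapply(transforms, function(phi) {
    jac <- jacobian_map(phi, parcellation)
    parcel_jacobian_features(jac, parcellation)
  })
  do.call(rbind, feats)
}
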