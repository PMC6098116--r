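# NIfTI and table I/O. Tensor volumes are stored as 4D NIfTI with the six
# components in lower-triangular order (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz);
# gradient schemes as plain-text bval/bvec tables with one row per volume.

#' Read and write volumes as NIfTI
#'
#' @param v the volume; `path` the file path (`.nii` or `.nii.gz`).
#' @param mask_path optional path for the foreground mask (written/read as a
#'   0/1 volume); if `NULL` on read, all voxels are foreground.
#' @return the volume (readers) or `path`, invisibly (writers).
#' @export
write_tensor_volume <- function(v, path, mask_path = NULL) {
  stopifnot(inherits(v, "tensor_volume"))
  img <- RNifti::asNifti(v$data)
  img <- RNifti::`sform<-`(img, structure(v$affine, code = 2L))
  RNifti::writeNifti(img, path)
  if (!is.null(mask_path)) write_scalar_volume(mask_volume(v), mask_path)
  invisible(path)
}

#' @rdname write_tensor_volume
#' @export
read_tensor_volume <- function(path, mask_path = NULL) {
  img <- RNifti::readNifti(path)
  stopifnot(length(dim(img)) == 4, dim(img)[4] == 6)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  mask <- if (is.null(mask_path)) NULL else read_scalar_volume(mask_path)$data > 0.5
  tensor_volume(array(as.numeric(img), dim(img)), affine = aff, mask = mask)
}

#' @rdname write_tensor_volume
#' @export
write_scalar_volume <- function(v, path) {
  stopifnot(inherits(v, "scalar_volume"))
  img <- RNifti::asNifti(v$data)
  img <- RNifti::`sform<-`(img, structure(v$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_tensor_volume
#' @export
read_scalar_volume <- function(path) {
  img <- RNifti::readNifti(path)
  stopifnot(length(dim(img)) == 3)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  scalar_volume(array(as.numeric(img), dim(img)), affine = aff)
}

mask_volume <- function(v) {
  scalar_volume(array(as.numeric(v$mask), grid_dim(v)), affine = v$affine)
}

#' Read and write gradient schemes as bval/bvec text tables
#'
#' One row per volume: the bval file holds one b-value per line; the bvec
#' file three whitespace-separated direction components per line.
#'
#' @param scheme a [gradient_scheme()].
#' @param bval_path,bvec_path file paths.
#' @return the scheme (reader) or invisibly the paths (writer).
#' @export
write_gradient_scheme <- function(scheme, bval_path, bvec_path) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  writeLines(format(scheme$bvals, trim = TRUE), bval_path)
  write.table(scheme$bvecs, bvec_path, row.names = FALSE, col.names = FALSE)
  invisible(c(bval_path, bvec_path))
}

#' @rdname write_gradient_scheme
#' @export
read_gradient_scheme <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- as.matrix(read.table(bvec_path))
  gradient_scheme(bvals, bvecs)
}

#' Read and write trial event tables as TSV
#'
#' Columns: `trial`, `phase`, `onset`, `duration`, `side`.
#'
#' @param events event data frame; `path` file path.
#' @return the events (reader) or invisibly `path` (writer).
#' @export
write_events <- function(events, path) {
  write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to a BIDS-like directory tree
#'
#' Layout: `sub-XX/dwi/dwi.nii` + `dwi.bval`/`dwi.bvec`,
#' `sub-XX/func/run-Y.nii` + `run-Y_events.tsv`,
#' `sub-XX/anat/pseudo-t1.nii`, and `truth/` with the template, the
#' ground-truth deformations (JSON) and the informative-voxel masks.
#' Volumes are written uncompressed so identical cohorts yield identical
#' trees.
#'
#' @param cohort a `synthetic_cohort` from [make_cohort()].
#' @param dir output directory.
#' @return invisibly `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth_dir <- file.path(dir, "truth")
  dir.create(truth_dir, showWarnings = FALSE)
  write_tensor_volume(cohort$template, file.path(truth_dir, "template.nii"),
                      file.path(truth_dir, "template-mask.nii"))
  aff <- cohort$template$affine
  for (s in cohort$subjects) {
    sd <- file.path(dir, s$id)
    for (sub in c("dwi", "func", "anat"))
      dir.create(file.path(sd, sub), recursive = TRUE, showWarnings = FALSE)
    img <- RNifti::asNifti(s$dwi)
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    RNifti::writeNifti(img, file.path(sd, "dwi", "dwi.nii"))
    write_gradient_scheme(s$scheme, file.path(sd, "dwi", "dwi.bval"),
                          file.path(sd, "dwi", "dwi.bvec"))
    write_scalar_volume(s$t1, file.path(sd, "anat", "pseudo-t1.nii"))
    for (r in seq_along(s$runs)) {
      run <- s$runs[[r]]
      full <- array(0, c(run$grid$dim, nrow(run$signal)))
      for (t in seq_len(nrow(run$signal))) {
        vol <- array(0, run$grid$dim)
        vol[run$voxels] <- run$signal[t, ]
        full[, , , t] <- vol
      }
      img <- RNifti::asNifti(full)
      img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
      RNifti::writeNifti(img, file.path(sd, "func", sprintf("run-%d.nii", r)))
      write_events(run$events, file.path(sd, "func",
                                         sprintf("run-%d_events.tsv", r)))
    }
    write_transform(s$truth, file.path(truth_dir,
                                       sprintf("%s-deformation.json", s$id)))
    write_scalar_volume(
      scalar_volume(array(as.numeric(s$informative), dim(s$informative)),
                    affine = aff),
      file.path(truth_dir, sprintf("%s-informative.nii", s$id)))
  }
  invisible(dir)
}
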