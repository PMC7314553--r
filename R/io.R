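#' Write a synthetic run to disk
#'
#' Writes the 4D functional volumes as NIfTI-1 (columns x depths x 1 x
#' volumes, double precision so re-reading is bit-exact), the run schedule as
#' a BIDS-style events TSV, the truth tables (observed laminar amplitudes and
#' leakage matrix) as TSV, and a manifest JSON recording the seed and
#' geometry.
#'
#' @param run a [simulate_run()] result
#' @param out_dir output directory (created if needed)
#' @param prefix file-name prefix (default the run condition)
#' @return invisibly, the named list of written paths
#' @export
write_dataset <- function(run, out_dir, prefix = run$condition) {
  stopifnot(inherits(run, "synthetic_run"))
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory: ", out_dir)
  n_col <- max(run$voxels$column)
  n_depth <- max(run$voxels$depth_index)
  n_vol <- nrow(run$data)
  vol4d <- array(t(run$data), c(n_col, n_depth, 1, n_vol))

  paths <- list(
    bold = file.path(out_dir, paste0(prefix, "_bold.nii")),
    events = file.path(out_dir, paste0(prefix, "_events.tsv")),
    truth_sustained = file.path(out_dir, paste0(prefix, "_truth_sustained.tsv")),
    truth_transient = file.path(out_dir, paste0(prefix, "_truth_transient.tsv")),
    leakage = file.path(out_dir, paste0(prefix, "_leakage.tsv")),
    voxels = file.path(out_dir, paste0(prefix, "_voxels.tsv")),
    manifest = file.path(out_dir, paste0(prefix, "_manifest.json")))

  img <- RNifti::asNifti(vol4d, datatype = "double")
  RNifti::writeNifti(img, paths$bold, compression = 0)
  write_events_tsv(run$schedule, paths$events)
  utils::write.table(run$truth$sustained_observed, paths$truth_sustained,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(run$truth$transient_observed, paths$truth_transient,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(run$truth$leakage, paths$leakage, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(run$voxels, paths$voxels, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(condition = run$condition, seed = run$seed,
         n_columns = n_col, n_depths = n_depth, n_volumes = n_vol,
         tr = run$schedule$tr,
         subject_scale = run$truth$subject_scale),
    paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read back a synthetic run written by [write_dataset()]
#'
#' @param out_dir directory holding the files
#' @param prefix file-name prefix used at write time
#' @return list: `data` (volumes x voxels), `voxels`, `events`, `truth`
#'   (sustained/transient/leakage matrices), `manifest`
#' @export
read_dataset <- function(out_dir, prefix) {
  img <- RNifti::readNifti(file.path(out_dir, paste0(prefix, "_bold.nii")))
  d <- dim(img)
  data <- t(matrix(img, d[1] * d[2] * d[3], d[4]))
  list(
    data = data,
    voxels = utils::read.table(
      file.path(out_dir, paste0(prefix, "_voxels.tsv")),
      header = TRUE, sep = "\t"),
    events = read_events_tsv(
      file.path(out_dir, paste0(prefix, "_events.tsv"))),
    truth = list(
      sustained_observed = as.matrix(utils::read.table(
        file.path(out_dir, paste0(prefix, "_truth_sustained.tsv")),
        sep = "\t")),
      transient_observed = as.matrix(utils::read.table(
        file.path(out_dir, paste0(prefix, "_truth_transient.tsv")),
        sep = "\t")),
      leakage = as.matrix(utils::read.table(
        file.path(out_dir, paste0(prefix, "_leakage.tsv")), sep = "\t"))),
    manifest = jsonlite::read_json(
      file.path(out_dir, paste0(prefix, "_manifest.json")),
      simplifyVector = TRUE))
}

#' Write a long-format depth-profile table
#'
#' Columns: column id, depth_fraction, value (plus any extra id columns).
#' @param profiles matrix columns x depths
#' @param depth_fractions depth fractions (from pial) naming the columns
#' @param path output TSV path
#' @export
write_profile_tsv <- function(profiles, depth_fractions, path) {
  M <- as.matrix(profiles)
  long <- data.frame(
    column = rep(seq_len(nrow(M)), times = ncol(M)),
    depth_fraction = rep(depth_fractions, each = nrow(M)),
    value = as.vector(M))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
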