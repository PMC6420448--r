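#' Read and write pipeline tables
#'
#' All tables are plain tab-separated files with a header row; all timing is
#' in seconds; seeds travel with the tables they generated.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_tsv_table` returns a data.frame.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Serialize an experiment design to a directory
#'
#' Writes `words.tsv`, `contexts.tsv` and a `design.yaml` header carrying the
#' configuration and generating seed; [read_design()] restores an equivalent
#' `experiment_design`.
#'
#' @param design an [build_design()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_design <- function(design, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_table(design$words, file.path(dir, "words.tsv"))
  write_tsv_table(design$contexts, file.path(dir, "contexts.tsv"))
  hdr <- c(unclass(design$params), list(seed = design$seed))
  yaml::write_yaml(hdr, file.path(dir, "design.yaml"))
  invisible(dir)
}

#' @rdname write_design
#' @export
read_design <- function(dir) {
  hdr <- yaml::read_yaml(file.path(dir, "design.yaml"))
  config <- design_config(hdr$n_sets, hdr$words_per_set, hdr$words_per_trial,
                          hdr$repetitions, hdr$context_style)
  structure(
    list(words = read_tsv_table(file.path(dir, "words.tsv")),
         contexts = read_tsv_table(file.path(dir, "contexts.tsv")),
         params = config, seed = hdr$seed),
    class = "experiment_design"
  )
}

#' Export / import a synthetic BOLD run as NIfTI
#'
#' Synthetic voxels have no geometry, so runs are laid out as 1 x 1 x V x T
#' volumes; the companion mask is a 1 x 1 x V binary image. Requires the
#' RNifti package.
#'
#' @param run a `bold_run`.
#' @param path output `.nii.gz` path.
#' @param mask_path optional path for an all-ones mask image.
#' @return `read_bold_nifti` returns a `bold_run`.
#' @export
write_bold_nifti <- function(run, path, mask_path = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("NIfTI export requires the RNifti package")
  }
  v <- ncol(run$signal)
  arr <- array(t(run$signal), dim = c(1L, 1L, v, nrow(run$signal)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1, run$tr)
  RNifti::writeNifti(img, path)
  if (!is.null(mask_path)) {
    RNifti::writeNifti(RNifti::asNifti(array(1, dim = c(1L, 1L, v))),
                       mask_path)
  }
  invisible(path)
}

#' @rdname write_bold_nifti
#' @param mask_path path to a binary mask image selecting voxels (any
#'   spatial layout; voxels are flattened in array order).
#' @param tr_seconds sampling interval override; defaults to the file pixdim.
#' @param label run label.
#' @export
read_bold_nifti <- function(path, mask_path = NULL, tr_seconds = NULL,
                            label = "run") {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("NIfTI import requires the RNifti package")
  }
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) != 4L) stop("expected a 4-D NIfTI volume")
  n_t <- d[4L]
  flat <- matrix(arr, ncol = n_t)   # voxels x T in array order
  if (!is.null(mask_path)) {
    mask <- as.array(RNifti::readNifti(mask_path))
    if (!all(dim(mask) == d[1:3])) {
      stop("mask dimensions do not match the functional volume")
    }
    flat <- flat[as.logical(mask != 0), , drop = FALSE]
  }
  if (is.null(tr_seconds)) {
    pd <- RNifti::pixdim(img)
    tr_seconds <- if (length(pd) >= 4L && pd[4L] > 0) pd[4L] else 1
  }
  new_bold_run(t(flat), tr_seconds, label)
}
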