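#' Write an examination to the exam-directory layout
#'
#' Layout: `dir/meta.json` (pixel spacing per view, labels in mmHg / Wood
#' units, exam id) plus one NIfTI file per phase under
#' `dir/<view>/phase_###.nii.gz`, and optional chamber masks as
#' `dir/<view>/mask_<chamber>.nii.gz` (one 3D volume, phases stacked).
#'
#' @param exam A [cine_exam()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_exam_dir <- function(exam, dir) {
  stopifnot(inherits(exam, "cine_exam"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(id = exam$id,
               labels = as.list(exam$labels),
               views = lapply(exam$series, function(s)
                 list(pixel_spacing = s$pixel_spacing,
                      n_phases = n_phases(s))))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (v in names(exam$series)) {
    vd <- file.path(dir, v)
    dir.create(vd, showWarnings = FALSE)
    s <- exam$series[[v]]
    for (p in seq_len(n_phases(s))) {
      RNifti::writeNifti(s$frames[, , p],
                         file.path(vd, sprintf("phase_%03d.nii.gz", p)))
    }
    if (!is.null(exam$masks[[v]])) {
      for (ch in names(exam$masks[[v]])) {
        RNifti::writeNifti(exam$masks[[v]][[ch]] * 1,
                           file.path(vd, sprintf("mask_%s.nii.gz", ch)))
      }
    }
  }
  invisible(dir)
}

#' Read an examination from the exam-directory layout
#'
#' @param dir Directory written by [write_exam_dir()] (or assembled by
#'   hand in the same layout).
#' @return A [cine_exam()].
#' @export
read_exam_dir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  views <- intersect(CINE_VIEWS, names(meta$views))
  series <- lapply(setNames(views, views), function(v) {
    files <- sort(list.files(file.path(dir, v), pattern = "^phase_\\d+\\.nii",
                             full.names = TRUE))
    if (!length(files)) abort(sprintf("no phase files for view %s", v))
    frames <- vapply(files, function(f) as.matrix(RNifti::readNifti(f)),
                     matrix(0, nrow(RNifti::readNifti(files[1])),
                            ncol(RNifti::readNifti(files[1]))))
    dimnames(frames) <- NULL
    cine_series(frames, meta$views[[v]]$pixel_spacing, v)
  })
  masks <- NULL
  for (v in views) {
    mf <- list.files(file.path(dir, v), pattern = "^mask_.*\\.nii",
                     full.names = TRUE)
    for (f in mf) {
      ch <- sub("^mask_(.*)\\.nii(\\.gz)?$", "\\1", basename(f))
      mk <- as.array(RNifti::readNifti(f))
      attributes(mk) <- list(dim = dim(mk))
      masks[[v]][[ch]] <- mk
    }
  }
  labels <- if (length(meta$labels)) unlist(meta$labels)
  cine_exam(series, labels = labels, masks = masks, id = meta$id)
}
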