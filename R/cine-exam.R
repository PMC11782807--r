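#' Construct a cine series
#'
#' A cine series is one temporally ordered stack of 2D grayscale frames
#' covering a cardiac cycle in a single imaging plane, with isotropic
#' pixel-spacing metadata.
#'
#' @param frames Numeric array `H x W x n_phases` (or a single `H x W`
#'   matrix), nonnegative intensities. All frames share one shape.
#' @param pixel_spacing Isotropic spacing in mm per pixel (> 0).
#' @param view_id One of `"2CH"`, `"4CH"`, `"RVLA"`, `"SAX"`.
#' @return An object of class `cine_series`.
#' @export
cine_series <- function(frames, pixel_spacing, view_id) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (dim(frames)[3] < 1L) abort("a cine series needs at least one frame")
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L ||
      !is.finite(pixel_spacing) || pixel_spacing <= 0) {
    abort("`pixel_spacing` must be a single positive number (mm/pixel)")
  }
  view_id <- match.arg(view_id, CINE_VIEWS)
  structure(
    list(frames = frames, pixel_spacing = pixel_spacing, view_id = view_id),
    class = "cine_series"
  )
}

#' @export
print.cine_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cine_series> view %s: %d frames of %dx%d at %.3g mm/px\n",
              x$view_id, d[3], d[1], d[2], x$pixel_spacing))
  invisible(x)
}

n_phases <- function(series) dim(series$frames)[3]

#' Construct a multi-view examination
#'
#' Bundles one cine series per view with optional right-heart-catheter
#' labels (mPAP mmHg, PAWP mmHg, PVR Wood units) and optional per-view
#' binary chamber masks.
#'
#' @param series Named list of [cine_series()] objects; names must be the
#'   view ids.
#' @param labels Optional named numeric vector with elements `mPAP`, `PAWP`,
#'   `PVR` (any subset).
#' @param masks Optional nested list `masks[[view]][[chamber]]`, each a
#'   logical/0-1 array matching that view's frames (`H x W x n_phases`) or a
#'   single `H x W` mask applied to every phase.
#' @param id Optional examination identifier.
#' @return An object of class `cine_exam`.
#' @export
cine_exam <- function(series, labels = NULL, masks = NULL, id = NULL) {
  stopifnot(is.list(series), length(series) >= 1L)
  if (is.null(names(series)) || any(!names(series) %in% CINE_VIEWS)) {
    abort("`series` must be a named list keyed by view id (2CH/4CH/RVLA/SAX)")
  }
  for (s in series) stopifnot(inherits(s, "cine_series"))
  if (!is.null(labels)) {
    bad <- setdiff(names(labels), c("mPAP", "PAWP", "PVR"))
    if (length(bad)) abort(paste0("unknown label(s): ", paste(bad, collapse = ", ")))
  }
  if (!is.null(masks)) {
    bad <- setdiff(names(masks), names(series))
    if (length(bad)) abort("masks refer to views absent from the exam")
    for (v in names(masks)) {
      allowed <- CHAMBERS_BY_VIEW[[v]]
      bad <- setdiff(names(masks[[v]]), allowed)
      if (length(bad)) {
        abort(sprintf("chamber(s) %s not present in view %s",
                      paste(bad, collapse = ", "), v))
      }
    }
  }
  structure(list(series = series, labels = labels, masks = masks, id = id),
            class = "cine_exam")
}

#' @export
print.cine_exam <- function(x, ...) {
  cat(sprintf("<cine_exam>%s %d view(s): %s\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              length(x$series), paste(names(x$series), collapse = ", ")))
  if (!is.null(x$labels)) {
    cat("  labels:", paste(sprintf("%s=%.3g", names(x$labels), x$labels),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

# Expand a single H x W mask to H x W x n, or pass a 3D mask through;
# validates alignment with the frames it will be applied to.
align_mask <- function(mask, frame_dim) {
  if (is.matrix(mask)) mask <- array(mask, c(dim(mask), 1L))
  md <- dim(mask)
  if (!all(md[1:2] == frame_dim[1:2])) {
    abort("mask spatial size does not match the frames")
  }
  if (md[3] == 1L && frame_dim[3] > 1L) {
    mask <- array(mask, frame_dim)  # one mask propagated to all phases
  } else if (md[3] != frame_dim[3]) {
    abort("mask has neither 1 frame nor one mask per phase")
  }
  storage.mode(mask) <- "double"
  if (!all(mask %in% c(0, 1))) abort("masks must be binary")
  mask
}
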