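#' Percentile intensity normalisation
#'
#' Clips intensities at the series-wide 3rd and 97th percentile and affinely
#' maps the clipped range to `[0, 1]`. Percentiles are taken over all pixels
#' of the whole series (not per frame) so inter-frame intensity relations are
#' preserved.
#'
#' @param frames Numeric array of frames (`H x W x n` or a matrix).
#' @param probs Lower/upper clipping percentiles as probabilities.
#' @return Array of the same shape with values in `[0, 1]`. A degenerate
#'   series (lower percentile equal to upper) maps to all zeros with a
#'   warning.
#' @export
normalize_intensity <- function(frames, probs = c(0.03, 0.97)) {
  stopifnot(is.numeric(frames), length(frames) >= 1L)
  q <- quantile(frames, probs = probs, names = FALSE)
  if (q[1] >= q[2]) {
    warn("degenerate cine series (flat intensity range); returning zeros")
    out <- frames
    out[] <- 0
    return(out)
  }
  out <- pmin(pmax(frames, q[1]), q[2])
  rng <- range(out)
  out <- (out - rng[1]) / (rng[2] - rng[1])
  out
}

#' Resample a cine series to a target pixel spacing
#'
#' Rescales every frame with bilinear interpolation so the output spacing is
#' `target_spacing` mm/pixel. Output size is
#' `round(src_dim * src_spacing / target_spacing)`.
#'
#' @param series A [cine_series()].
#' @param target_spacing Target spacing in mm/pixel (default 0.94).
#' @return A [cine_series()] at the target spacing.
#' @export
resample_to_spacing <- function(series, target_spacing = 0.94) {
  stopifnot(inherits(series, "cine_series"))
  if (!is.numeric(target_spacing) || target_spacing <= 0) {
    abort("`target_spacing` must be positive")
  }
  d <- dim(series$frames)
  if (isTRUE(all.equal(series$pixel_spacing, target_spacing))) {
    series$pixel_spacing <- target_spacing
    return(series)
  }
  new_d <- as.integer(round(d[1:2] * series$pixel_spacing / target_spacing))
  out <- EBImage::resize(series$frames, w = new_d[1], h = new_d[2],
                         filter = "bilinear")
  cine_series(array(out, c(new_d, d[3])), target_spacing, series$view_id)
}

#' Centre-crop or zero-pad a cine series to a square matrix size
#'
#' Frames larger than `size` are cropped to the central `size x size`
#' window; smaller dimensions are symmetrically zero-padded. Offsets are
#' identical across all frames of the series.
#'
#' @param series A [cine_series()].
#' @param size Target square size in pixels (default 256).
#' @param center_offset Integer `(row, col)` shift of the crop window away
#'   from the geometric centre.
#' @return A [cine_series()] with `size x size` frames.
#' @export
crop_or_pad <- function(series, size = 256L, center_offset = c(0L, 0L)) {
  stopifnot(inherits(series, "cine_series"), size >= 1L)
  d <- dim(series$frames)
  out <- array(0, c(size, size, d[3]))
  # source window and destination window per dimension
  win <- function(n) {
    if (n >= size) {
      s0 <- floor((n - size) / 2)
      list(src = seq_len(size) + s0, dst = seq_len(size), off = s0)
    } else {
      d0 <- floor((size - n) / 2)
      list(src = seq_len(n), dst = seq_len(n) + d0, off = -d0)
    }
  }
  wr <- win(d[1]); wc <- win(d[2])
  sr <- wr$src; dr <- wr$dst
  if (d[1] >= size) sr <- pmin(pmax(sr + center_offset[1], 1L), d[1])
  sc <- wc$src; dc <- wc$dst
  if (d[2] >= size) sc <- pmin(pmax(sc + center_offset[2], 1L), d[2])
  out[dr, dc, ] <- series$frames[sr, sc, ]
  cine_series(out, series$pixel_spacing, series$view_id)
}

#' Preprocess a cine series to the model's tensor layout
#'
#' Intensity-normalises (3rd/97th percentile clip, map to `[0, 1]`),
#' resamples to `spacing` mm/pixel with bilinear interpolation, and
#' centre-crops/zero-pads to `size x size`. The result is the fixed layout
#' the network consumes: `n_phases` frames of `size x size` in `[0, 1]` at
#' `spacing` mm/pixel (defaults: 20 x 256 x 256 at 0.94 mm, i.e. a
#' 240 x 240 mm field of view).
#'
#' @inheritParams crop_or_pad
#' @param spacing Target pixel spacing, mm/pixel.
#' @param n_phases_expected Required number of cardiac phases (default 20).
#' @return A `preprocessed_cine_series` (also a [cine_series()]).
#' @export
preprocess_series <- function(series, spacing = 0.94, size = 256L,
                              n_phases_expected = 20L,
                              center_offset = c(0L, 0L)) {
  stopifnot(inherits(series, "cine_series"))
  if (n_phases(series) != n_phases_expected) {
    abort(sprintf("expected %d phases, got %d",
                  n_phases_expected, n_phases(series)))
  }
  series$frames <- normalize_intensity(series$frames)
  series <- resample_to_spacing(series, spacing)
  series$frames <- pmin(pmax(series$frames, 0), 1)  # guard interpolation
  series <- crop_or_pad(series, size, center_offset)
  class(series) <- c("preprocessed_cine_series", class(series))
  series
}

#' Preprocess every view of an examination
#'
#' @param exam A [cine_exam()].
#' @inheritParams preprocess_series
#' @return A [cine_exam()] whose series are preprocessed. Masks, if present,
#'   are passed through untouched (they are assumed to live in the
#'   preprocessed geometry).
#' @export
preprocess_exam <- function(exam, spacing = 0.94, size = 256L,
                            n_phases_expected = 20L) {
  stopifnot(inherits(exam, "cine_exam"))
  exam$series <- lapply(exam$series, preprocess_series, spacing = spacing,
                        size = size, n_phases_expected = n_phases_expected)
  exam
}

#' Augmentation parameters
#'
#' Random horizontal flip, shift, isotropic scale, and in-plane rotation.
#' One transform is sampled per cine series and applied identically to all
#' of its frames, preserving temporal coherence. Magnitudes default to mild
#' values that preserve cardiac anatomy.
#'
#' @param flip_prob Probability of a horizontal mirror.
#' @param max_shift_px Maximum |shift| in pixels (each axis, uniform).
#' @param scale_range Length-2 range of isotropic scale factors.
#' @param max_rotation_deg Maximum |rotation| in degrees (uniform).
#' @param share_across_views If `TRUE`, the four views of one exam share a
#'   single sampled transform; by default each series draws its own.
#' @param seed Optional integer for reproducible draws.
#' @return An `augmentation_params` list.
#' @export
augmentation_params <- function(flip_prob = 0.5, max_shift_px = 16,
                                scale_range = c(0.9, 1.1),
                                max_rotation_deg = 15,
                                share_across_views = FALSE, seed = NULL) {
  stopifnot(flip_prob >= 0, flip_prob <= 1, max_shift_px >= 0,
            length(scale_range) == 2L, all(scale_range > 0),
            max_rotation_deg >= 0)
  structure(list(flip_prob = flip_prob, max_shift_px = max_shift_px,
                 scale_range = sort(scale_range),
                 max_rotation_deg = max_rotation_deg,
                 share_across_views = share_across_views, seed = seed),
            class = "augmentation_params")
}

draw_transform <- function(p) {
  list(flip  = runif(1) < p$flip_prob,
       shift = runif(2, -p$max_shift_px, p$max_shift_px),
       scale = runif(1, p$scale_range[1], p$scale_range[2]),
       angle = runif(1, -p$max_rotation_deg, p$max_rotation_deg) * pi / 180)
}

is_identity_transform <- function(tr) {
  !tr$flip && all(tr$shift == 0) && tr$scale == 1 && tr$angle == 0
}

# Apply one sampled affine (flip -> scale -> rotate, about the image
# centre, then shift) to every frame of a series with bilinear
# interpolation; background fills with 0.
apply_transform <- function(frames, tr) {
  if (is_identity_transform(tr)) return(frames)
  d <- dim(frames)
  ctr <- d[1:2] / 2  # EBImage affine coordinates are 0-based
  Fm <- diag(c(1, if (tr$flip) -1 else 1))
  R  <- matrix(c(cos(tr$angle), -sin(tr$angle),
                 sin(tr$angle),  cos(tr$angle)), 2, 2, byrow = TRUE)
  A  <- tr$scale * R %*% Fm
  tv <- ctr - A %*% ctr + tr$shift
  m  <- rbind(t(A), as.numeric(tv))
  out <- EBImage::affine(frames, m, filter = "bilinear",
                         output.dim = d[1:2], bg.col = 0)
  array(pmin(pmax(as.numeric(out), 0), 1), d)
}

#' Augment an examination (training-time only)
#'
#' Samples one affine transform per cine series (or one shared transform for
#' the whole exam) and applies it to all 20 frames of that series. Values
#' are re-clipped to `[0, 1]`. Deterministic given `params$seed`.
#'
#' @param exam A [cine_exam()] of preprocessed series.
#' @param params An [augmentation_params()] object.
#' @return The augmented [cine_exam()].
#' @export
augment_exam <- function(exam, params = augmentation_params()) {
  stopifnot(inherits(exam, "cine_exam"),
            inherits(params, "augmentation_params"))
  run <- function() {
    shared <- if (params$share_across_views) draw_transform(params) else NULL
    exam$series <- lapply(exam$series, function(s) {
      tr <- shared %||% draw_transform(params)
      s$frames <- apply_transform(s$frames, tr)
      s
    })
    exam
  }
  if (is.null(params$seed)) run() else with_local_seed(params$seed, run())
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
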