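#' Phantom generator configuration
#'
#' Configures the synthetic multi-view cardiac cine phantom: four views
#' (2CH, 4CH, RVLA, SAX) of 20-phase 256x256 series at 0.94 mm/pixel, each
#' view showing its anatomically available chambers as soft-edged ellipses
#' (with a myocardial ring around the ventricles) over a noisy background.
#' Chamber areas follow a cyclic contraction profile with end-systole at
#' phase 9, and the area of chambers named in `signal_map` additionally
#' scales with the hemodynamic target, planting a target-correlated
#' morphological signal at chosen (view, chamber) locations.
#'
#' The target (mPAP) distribution defaults to a truncated normal with mean
#' 39.7 and SD 14.5 mmHg, matching a referral pulmonary-hypertension cohort;
#' PVR is linked linearly to mPAP (`PVR = 0.25 mPAP - 3 + noise`) and PAWP
#' is drawn independently (12.9 +/- 5.4 mmHg), so the precapillary decision
#' rule sees both classes.
#'
#' @param target Name of the label carrying the planted image signal.
#' @param target_mean,target_sd Mean/SD of the mPAP distribution (mmHg).
#' @param signal_map Data frame with columns `view`, `chamber`, `coef`;
#'   fractional area change per SD of the target. Default: 0.35 on
#'   (SAX, RV) only.
#' @param contraction_frac Fractional area reduction of the ventricles at
#'   end-systole; atria use `atrial_frac` half a cycle out of phase.
#' @param atrial_frac Fractional area reduction of the atria.
#' @param es_phase Phase index (1-20) of end-systole (minimum ventricular
#'   area).
#' @param noise_sd Pixel-wise Gaussian noise SD (intensity units).
#' @param background Mean background intensity.
#' @param jitter_shift_px,jitter_rot_deg,jitter_gain Per-series pose/gain
#'   jitter half-ranges (uniform).
#' @param image_size,spacing,n_phases Native raster geometry.
#' @param pvr_slope,pvr_intercept,pvr_noise_sd PVR-mPAP link.
#' @param pawp_mean,pawp_sd PAWP distribution (mmHg).
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(target = "mPAP",
                           target_mean = 39.7, target_sd = 14.5,
                           signal_map = NULL,
                           contraction_frac = 0.35, atrial_frac = 0.25,
                           es_phase = 9, noise_sd = 0.05, background = 0.12,
                           jitter_shift_px = 4, jitter_rot_deg = 5,
                           jitter_gain = 0.1,
                           image_size = 256L, spacing = 0.94,
                           n_phases = 20L,
                           pvr_slope = 0.25, pvr_intercept = -3,
                           pvr_noise_sd = 1.2,
                           pawp_mean = 12.9, pawp_sd = 5.4) {
  if (is.null(signal_map)) {
    signal_map <- tibble::tibble(view = "SAX", chamber = "RV", coef = 0.35)
  }
  signal_map <- tibble::as_tibble(signal_map)
  stopifnot(all(c("view", "chamber", "coef") %in% names(signal_map)))
  for (i in seq_len(nrow(signal_map))) {
    v <- signal_map$view[i]; ch <- signal_map$chamber[i]
    if (!v %in% CINE_VIEWS || !ch %in% CHAMBERS_BY_VIEW[[v]]) {
      abort(sprintf("signal_map entry (%s, %s) is not a valid view-chamber pair", v, ch))
    }
  }
  stopifnot(target_sd > 0, noise_sd >= 0, contraction_frac >= 0,
            contraction_frac < 1, atrial_frac >= 0, atrial_frac < 1,
            es_phase >= 1, es_phase <= n_phases, n_phases >= 1,
            image_size >= 32, spacing > 0)
  structure(as.list(environment()), class = "phantom_config")
}

# Base end-diastole chamber geometry per view, in pixels on the 256 grid:
# centre (row, col), semi-axes (a = row axis, b = col axis), orientation
# (rad), blood-pool intensity, and for ventricles a myocardial ring
# (outer axes = ring * inner, mid intensity).
phantom_geometry <- function() {
  ch <- function(cr, cc, a, b, ang, int, ring = NA) {
    list(centre = c(cr, cc), a = a, b = b, angle = ang,
         intensity = int, ring = ring)
  }
  list(
    `2CH` = list(LV = ch(100, 128, 40, 26, 0.10, 0.85, ring = 1.35),
                 LA = ch(178, 132, 26, 22, 0.00, 0.72)),
    `4CH` = list(LV = ch(90, 160, 34, 24, -0.20, 0.85, ring = 1.30),
                 RV = ch(92, 96, 36, 22, 0.15, 0.80, ring = 1.22),
                 LA = ch(170, 162, 26, 22, 0.00, 0.72),
                 RA = ch(168, 98, 27, 23, 0.00, 0.70)),
    RVLA  = list(RV = ch(100, 120, 40, 26, 0.20, 0.80, ring = 1.25),
                 RA = ch(175, 140, 28, 23, 0.00, 0.70)),
    SAX   = list(LV = ch(130, 150, 27, 27, 0.00, 0.85, ring = 1.45),
                 RV = ch(122, 84, 34, 24, 0.10, 0.80, ring = 1.22))
  )
}

# Cyclic contraction profile: area multiplier per phase. A circular
# von-Mises-style bump centred on the end-systole phase gives a smooth,
# periodic cycle whose minimum falls exactly at `es_phase`.
contraction_profile <- function(n_phases, es_phase, frac, kappa = 2) {
  p <- seq_len(n_phases)
  bump <- exp(kappa * (cos(2 * pi * (p - es_phase) / n_phases) - 1))
  1 - frac * bump
}

signal_coef <- function(config, view, chamber) {
  i <- which(config$signal_map$view == view & config$signal_map$chamber == chamber)
  if (length(i)) config$signal_map$coef[i[1]] else 0
}

# Analytic chamber area (mm^2) at a given target value and phase; pose
# jitter is area-preserving so this is exact for rendered phantoms.
#' Analytic phantom chamber area
#'
#' Area (mm^2) of a phantom chamber at a given target value and phase,
#' computed from the generative geometry. Useful as a noise-free oracle
#' regressor input.
#'
#' @param config A [phantom_config()].
#' @param target Scalar value of the signal-carrying label.
#' @param view,chamber Location of the chamber.
#' @param phase Phase index (1-based).
#' @return Area in mm^2.
#' @export
phantom_chamber_area <- function(config, target, view, chamber, phase) {
  g <- phantom_geometry()[[view]][[chamber]]
  if (is.null(g)) abort(sprintf("chamber %s not present in view %s", chamber, view))
  frac <- if (chamber %in% c("LV", "RV")) config$contraction_frac else config$atrial_frac
  es   <- if (chamber %in% c("LV", "RV")) config$es_phase
          else ((config$es_phase - 1 + config$n_phases / 2) %% config$n_phases) + 1
  k <- contraction_profile(config$n_phases, es, frac)[phase]
  z <- (target - config$target_mean) / config$target_sd
  s <- pmin(pmax(1 + signal_coef(config, view, chamber) * z, 0.2), 2)
  pi * g$a * g$b * k * s * config$spacing^2
}

# Render one view series plus its chamber masks. All randomness must come
# from the caller's RNG state.
render_view <- function(config, view, target, with_masks = TRUE) {
  sz <- config$image_size
  npz <- config$n_phases
  geo <- phantom_geometry()[[view]]
  z <- (target - config$target_mean) / config$target_sd
  # per-series pose/gain jitter
  dshift <- runif(2, -config$jitter_shift_px, config$jitter_shift_px)
  psi    <- runif(1, -config$jitter_rot_deg, config$jitter_rot_deg) * pi / 180
  gain   <- runif(1, 1 - config$jitter_gain, 1 + config$jitter_gain)
  ctr    <- (sz + 1) / 2
  prof_v <- contraction_profile(npz, config$es_phase, config$contraction_frac)
  es_a   <- ((config$es_phase - 1 + npz / 2) %% npz) + 1
  prof_a <- contraction_profile(npz, es_a, config$atrial_frac)

  frames <- array(rnorm(sz * sz * npz, mean = config$background,
                        sd = config$noise_sd), c(sz, sz, npz))
  masks <- if (with_masks) lapply(geo, function(g) array(FALSE, c(sz, sz, npz)))

  for (p in seq_len(npz)) {
    # myocardium rings first, blood pools after, so pools are never covered
    for (pass in c("ring", "pool")) {
      for (nm in names(geo)) {
        g <- geo[[nm]]
        if (pass == "ring" && is.na(g$ring)) next
        frac_prof <- if (nm %in% c("LV", "RV")) prof_v else prof_a
        s <- pmin(pmax(1 + signal_coef(config, view, nm) * z, 0.2), 2)
        ax_scale <- sqrt(frac_prof[p] * s)
        a <- g$a * ax_scale; b <- g$b * ax_scale
        # jittered pose: rotate centre offset about image centre, add shift
        off <- g$centre - ctr
        Rj <- matrix(c(cos(psi), -sin(psi), sin(psi), cos(psi)), 2, 2,
                     byrow = TRUE)
        cen <- ctr + as.numeric(Rj %*% off) + dshift
        ang <- g$angle + psi
        ext <- max(a, b) * (if (pass == "ring") g$ring else 1) + 2
        rows <- max(1, floor(cen[1] - ext)):min(sz, ceiling(cen[1] + ext))
        cols <- max(1, floor(cen[2] - ext)):min(sz, ceiling(cen[2] + ext))
        u <- rows - cen[1]
        v <- cols - cen[2]
        cu <- cos(ang); su <- sin(ang)
        U <- outer(u, rep(1, length(v))); V <- outer(rep(1, length(u)), v)
        q <- ((U * cu + V * su) / a)^2 + ((-U * su + V * cu) / b)^2
        blk <- frames[rows, cols, p]
        if (pass == "ring") {
          sel <- q > 1 & q <= g$ring^2
          blk[sel] <- blk[sel] + 0.35 * gain
        } else {
          sel <- q <= 1
          # soft interior edge: full intensity in the core, fading towards
          # the boundary; support is exactly the ellipse interior
          edge <- 1 - 0.45 * pmin(pmax((q - 0.7) / 0.3, 0), 1)
          blk[sel] <- config$background + (g$intensity * gain - config$background) *
            edge[sel] + rnorm(sum(sel), sd = config$noise_sd)
          if (with_masks) {
            mblk <- masks[[nm]][rows, cols, p]
            mblk[sel] <- TRUE
            masks[[nm]][rows, cols, p] <- mblk
          }
        }
        frames[rows, cols, p] <- blk
      }
    }
  }
  frames[frames < 0] <- 0
  list(series = cine_series(frames, config$spacing, view), masks = masks)
}

#' Generate one synthetic examination
#'
#' Renders all four views of a phantom exam for a given hemodynamic label
#' triple. Chamber regions before dilation match the returned masks
#' pixel-exactly. Deterministic given `seed`.
#'
#' @param config A [phantom_config()].
#' @param labels Named numeric vector with `mPAP`, `PAWP`, `PVR`.
#' @param seed Integer seed for this exam's pose jitter and noise.
#' @param masks If `TRUE` (default), attach per-phase binary chamber masks.
#' @param id Optional exam identifier.
#' @return A [cine_exam()] with raw `cine_series`, labels, and masks.
#' @export
generate_exam <- function(config, labels, seed = 1L, masks = TRUE, id = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (!all(c("mPAP", "PAWP", "PVR") %in% names(labels))) {
    abort("`labels` must contain mPAP, PAWP, and PVR")
  }
  target <- labels[[config$target]]
  with_local_seed(seed, {
    rendered <- lapply(CINE_VIEWS,
                       function(v) render_view(config, v, target, with_masks = masks))
    names(rendered) <- CINE_VIEWS
    series <- lapply(rendered, `[[`, "series")
    mk <- if (masks) lapply(rendered, `[[`, "masks") else NULL
    cine_exam(series, labels = labels[c("mPAP", "PAWP", "PVR")],
              masks = mk, id = id)
  })
}

#' Sample hemodynamic label triples
#'
#' mPAP is truncated normal (> 0); PVR follows the linear link to mPAP plus
#' noise (floored at 0.1 Wood units); PAWP is independent normal clipped to
#' a physiologic band.
#'
#' @param n Number of triples.
#' @param config A [phantom_config()].
#' @return A tibble with columns `mPAP`, `PAWP`, `PVR`.
#' @export
sample_hemodynamics <- function(n, config = phantom_config()) {
  mpap <- rnorm(n, config$target_mean, config$target_sd)
  while (any(bad <- mpap <= 0)) {
    mpap[bad] <- rnorm(sum(bad), config$target_mean, config$target_sd)
  }
  pvr <- pmax(config$pvr_slope * mpap + config$pvr_intercept +
                rnorm(n, sd = config$pvr_noise_sd), 0.1)
  pawp <- pmin(pmax(rnorm(n, config$pawp_mean, config$pawp_sd), 2), 35)
  tibble::tibble(mPAP = mpap, PAWP = pawp, PVR = pvr)
}

#' Generate a labelled phantom dataset with patient-level splits
#'
#' Draws label triples and per-exam render seeds, and assigns disjoint
#' train/validation/test splits. Exams are rendered lazily through
#' [materialize_exam()], so arbitrarily large datasets stay cheap to hold.
#'
#' @param config A [phantom_config()].
#' @param n_train,n_val,n_test Split sizes (default ratio 65/15/20 of 400).
#' @param seed Integer master seed; per-exam seeds derive from it.
#' @return A `phantom_dataset`: the config plus an exam tibble
#'   (`id`, `split`, `seed`, `mPAP`, `PAWP`, `PVR`).
#' @export
generate_dataset <- function(config = phantom_config(),
                             n_train = 260L, n_val = 60L, n_test = 80L,
                             seed = 1L) {
  stopifnot(n_train >= 1L, n_val >= 0L, n_test >= 0L)
  n <- n_train + n_val + n_test
  with_local_seed(seed, {
    labels <- sample_hemodynamics(n, config)
    exams <- tibble::tibble(
      id = sprintf("exam_%04d", seq_len(n)),
      split = rep(c("train", "val", "test"), c(n_train, n_val, n_test)),
      seed = sample.int(.Machine$integer.max - 1L, n),
      mPAP = labels$mPAP, PAWP = labels$PAWP, PVR = labels$PVR
    )
    structure(list(config = config, exams = exams), class = "phantom_dataset")
  })
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %d exams (%s)\n", nrow(x$exams),
              paste(sprintf("%s=%d", names(table(x$exams$split)),
                            as.integer(table(x$exams$split))), collapse = ", ")))
  invisible(x)
}

#' Render one exam of a phantom dataset
#'
#' @param dataset A `phantom_dataset` from [generate_dataset()].
#' @param id Exam id (or integer row index).
#' @param masks Attach chamber masks?
#' @return A [cine_exam()].
#' @export
materialize_exam <- function(dataset, id, masks = FALSE) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  row <- if (is.numeric(id)) dataset$exams[id, ] else
    dataset$exams[dataset$exams$id == id, ]
  if (nrow(row) != 1L) abort("exam id not found")
  generate_exam(dataset$config,
                labels = c(mPAP = row$mPAP, PAWP = row$PAWP, PVR = row$PVR),
                seed = row$seed, masks = masks, id = row$id)
}
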