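# ---- trace collection over a dataset ------------------------------------

# Run the fusion forward pass over every exam of a split, collecting the
# 105 per-feature predictions and all attention weights.
collect_traces <- function(model, features, split = NULL) {
  if (inherits(features, "phantom_dataset")) {
    features <- encode_dataset(features, model$config)
  }
  stopifnot(inherits(features, "cine_features"))
  keep <- if (is.null(split)) seq_len(nrow(features$exams))
          else which(features$exams$split %in% split)
  if (!length(keep)) abort("no exams in the requested split")
  cfg <- model$config
  nv <- length(cfg$views); np <- cfg$n_phases; nf <- nv * np
  P <- cfg$pool_grid^2
  groups <- fusion_groups(cfg)
  n <- length(keep)
  preds <- matrix(0, n, nf + np + nv + 1L)
  w_view <- array(0, c(n, np, nv))
  w_phase <- array(0, c(n, nv, np))
  w_final <- matrix(0, n, np + nv)
  for (i in seq_len(n)) {
    Xe <- matrix(features$X[keep[i], , ], nf, P)
    He <- encode_pooled(model$params, cfg$activation, Xe)
    fw <- fuse_forward(cfg, model$params, He, groups)
    feats <- rbind(He, fw$S, fw$Tm, matrix(fw$g, 1))
    preds[i, ] <- as.numeric(feats %*% model$params$w_r) + model$params$b_r
    for (p in seq_len(np)) w_view[i, p, ] <- fw$A_vw[[p]]
    for (v in seq_len(nv)) w_phase[i, v, ] <- fw$A_pw[[v]]
    w_final[i, ] <- fw$a2
  }
  preds <- preds * model$target_scale + model$target_center
  idx <- frame_index(cfg)
  feature_id <- tibble::tibble(
    level = c(rep("frame", nf), rep("spatial_summary", np),
              rep("temporal_summary", nv), "final"),
    view = c(idx$view, rep(NA_character_, np), cfg$views, NA_character_),
    phase = c(idx$phase, seq_len(np), rep(NA_integer_, nv), NA_integer_)
  )
  list(preds = preds, feature_id = feature_id,
       weights = list(view_wise = w_view, phase_wise = w_phase,
                      final = w_final),
       truth = features$exams[[cfg$target]][keep],
       ids = features$exams$id[keep], config = cfg)
}

#' Per-feature predictive performance
#'
#' Because the fusion is dimension-preserving, every component feature (80
#' frames), intermediate summary (20 spatial + 4 temporal), and the final
#' feature can be passed through the shared regression layer and scored
#' against the labels. Rows also carry the feature's mean normalised
#' attention weight in each fusion group it takes part in.
#'
#' @param model A `cinefuse_model` (an untrained model is accepted but
#'   flagged with a warning).
#' @param features `cine_features` or `phantom_dataset` with labels.
#' @param split Which split to evaluate (default `"test"`).
#' @return A `feature_importance` tibble with one row per feature (105 for
#'   the full 4-view, 20-phase model): identity (`level`, `view`, `phase`),
#'   `mae`/`pcc`/`r2` of its prediction, and mean attention weights
#'   (`weight_view_fusion`, `weight_phase_fusion`, `weight_final`, `NA`
#'   where not applicable).
#' @export
per_feature_performance <- function(model, features, split = "test") {
  if (!model$trained) warn("model is untrained; importance reflects random weights")
  tr <- collect_traces(model, features, split)
  perf <- purrr::map_dfr(seq_len(ncol(tr$preds)), function(j) {
    regression_report(tr$truth, tr$preds[, j])
  })
  mw <- mean_attention_weights(model, features, split, .traces = tr)
  cfg <- tr$config
  np <- cfg$n_phases; nv <- length(cfg$views)
  out <- dplyr::bind_cols(tr$feature_id, perf[c("mae", "pcc", "r2")])
  out$weight_view_fusion <- NA_real_
  out$weight_phase_fusion <- NA_real_
  out$weight_final <- NA_real_
  for (r in seq_len(nrow(out))) {
    lv <- out$level[r]
    if (lv == "frame") {
      v <- match(out$view[r], cfg$views); p <- out$phase[r]
      out$weight_view_fusion[r] <- mw$mean$view_wise[p, v]
      out$weight_phase_fusion[r] <- mw$mean$phase_wise[v, p]
    } else if (lv == "spatial_summary") {
      out$weight_final[r] <- mw$mean$final[out$phase[r]]
    } else if (lv == "temporal_summary") {
      out$weight_final[r] <- mw$mean$final[np + match(out$view[r], cfg$views)]
    }
  }
  class(out) <- c("feature_importance", class(out))
  out
}

#' Mean normalised attention weights per fusion group
#'
#' Averages each exam's (already normalised) attention weights over the
#' dataset, separately per fusion group. Groups are never renormalised
#' against each other; within every group the means still sum to one.
#'
#' @inheritParams per_feature_performance
#' @param .traces Internal: precollected traces.
#' @return An `attention_summary`: a tidy tibble (`fusion`, `group`,
#'   `component`, `mean_weight`) plus the raw group means in `$mean` --
#'   `view_wise` (phase x view), `phase_wise` (view x phase), `final`
#'   (length 24).
#' @export
mean_attention_weights <- function(model, features, split = "test",
                                   .traces = NULL) {
  tr <- .traces %||% collect_traces(model, features, split)
  cfg <- tr$config
  np <- cfg$n_phases; nv <- length(cfg$views)
  m_view <- apply(tr$weights$view_wise, c(2, 3), mean)   # phase x view
  m_phase <- apply(tr$weights$phase_wise, c(2, 3), mean) # view x phase
  m_final <- colMeans(tr$weights$final)
  dimnames(m_view) <- list(sprintf("phase_%02d", seq_len(np)), cfg$views)
  dimnames(m_phase) <- list(cfg$views, sprintf("phase_%02d", seq_len(np)))
  names(m_final) <- c(sprintf("phase_%02d", seq_len(np)), cfg$views)
  tbl <- dplyr::bind_rows(
    tidyr::expand_grid(phase = seq_len(np), view = cfg$views) |>
      dplyr::mutate(fusion = "view_wise",
                    group = sprintf("phase_%02d", .data$phase),
                    component = .data$view,
                    mean_weight = m_view[cbind(.data$phase,
                                               match(.data$view, cfg$views))]) |>
      dplyr::select("fusion", "group", "component", "mean_weight"),
    tidyr::expand_grid(view = cfg$views, phase = seq_len(np)) |>
      dplyr::mutate(fusion = "phase_wise", group = .data$view,
                    component = sprintf("phase_%02d", .data$phase),
                    mean_weight = m_phase[cbind(match(.data$view, cfg$views),
                                                .data$phase)]) |>
      dplyr::select("fusion", "group", "component", "mean_weight"),
    tibble::tibble(fusion = "final", group = "final",
                   component = names(m_final), mean_weight = m_final)
  )
  structure(list(table = tbl,
                 mean = list(view_wise = m_view, phase_wise = m_phase,
                             final = m_final)),
            class = "attention_summary")
}

#' @export
print.attention_summary <- function(x, ...) {
  cat("<attention_summary> mean normalised weights per fusion group\n")
  print(x$table, n = 10)
  invisible(x)
}

# ---- mask dilation and pixel perturbation -------------------------------

# Cache of banded Gaussian operators keyed by (n, sigma, radius).
.gauss_ops <- new.env(parent = emptyenv())

gauss_band <- function(n, sigma, radius) {
  key <- paste(n, sigma, radius, sep = "_")
  op <- .gauss_ops[[key]]
  if (is.null(op)) {
    k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
    k <- k / sum(k)
    op <- matrix(0, n, n)
    for (d in seq(-radius, radius)) {
      i <- seq_len(n)
      j <- i + d
      ok <- j >= 1 & j <= n
      op[cbind(i[ok], j[ok])] <- k[d + radius + 1]
    }
    .gauss_ops[[key]] <- op
  }
  op
}

#' Dilate a binary mask with a truncated Gaussian filter
#'
#' Convolves the 0/1 mask with a separable Gaussian kernel (SD `sigma`
#' pixels, truncated at `radius` pixels) and thresholds strictly above
#' zero. The result is a superset of the input support extended by up to
#' `radius` pixels along each axis, hiding the exact area and boundary
#' shape of the original region.
#'
#' @param mask Binary (0/1 or logical) matrix.
#' @param sigma Gaussian SD in pixels (default 4).
#' @param radius Kernel truncation radius in pixels (default 16).
#' @return Logical matrix of the same size.
#' @export
dilate_mask <- function(mask, sigma = 4, radius = 16) {
  if (is.logical(mask)) mask <- mask * 1
  if (!is.matrix(mask) || !all(mask %in% c(0, 1))) {
    abort("`mask` must be a binary matrix")
  }
  n1 <- nrow(mask); n2 <- ncol(mask)
  filt <- gauss_band(n1, sigma, radius) %*% mask %*% t(gauss_band(n2, sigma, radius))
  filt > 0
}

check_perturb_masks <- function(exam, masks) {
  stopifnot(inherits(exam, "cine_exam"), is.list(masks))
  bad <- setdiff(names(masks), names(exam$series))
  if (length(bad)) abort("masks refer to views absent from the exam")
  lapply(setNames(names(masks), names(masks)), function(v) {
    align_mask(masks[[v]], dim(exam$series[[v]]$frames))
  })
}

#' Mask out a region of selected views
#'
#' Sets pixels inside the mask to 0 (the black-canvas value) on the
#' selected views, across all frames; other views are untouched.
#'
#' @param exam A [cine_exam()].
#' @param masks Named list `view -> mask`, each a binary `H x W` matrix
#'   (propagated to every phase) or `H x W x n_phases` array aligned with
#'   that view's frames.
#' @return The perturbed [cine_exam()].
#' @seealso [apply_paste()] for the complementary perturbation; for any
#'   mask, `mask + paste` reconstructs the exam pixel-exactly.
#' @export
apply_mask <- function(exam, masks) {
  am <- check_perturb_masks(exam, masks)
  for (v in names(am)) {
    exam$series[[v]]$frames <- exam$series[[v]]$frames * (1 - am[[v]])
  }
  exam
}

#' Paste a region of selected views onto a black canvas
#'
#' Every view becomes a black (all-zero) series except that, within the
#' views named in `masks`, pixels inside the mask keep their original
#' intensities. Complementary to [apply_mask()].
#'
#' @inheritParams apply_mask
#' @return The perturbed [cine_exam()].
#' @export
apply_paste <- function(exam, masks) {
  am <- check_perturb_masks(exam, masks)
  for (v in names(exam$series)) {
    if (v %in% names(am)) {
      exam$series[[v]]$frames <- exam$series[[v]]$frames * am[[v]]
    } else {
      exam$series[[v]]$frames[] <- 0
    }
  }
  exam
}

#' Chamber importance via mask/paste perturbation
#'
#' For every mode (mask, paste), chamber, and location (each single view
#' where the chamber is visible, plus an "All views" cell perturbing the
#' chamber in every view showing it), perturbs every test exam with the
#' Gaussian-dilated chamber mask, re-runs the frozen model, and reports the
#' resulting test-set Pearson correlation. The intact (unperturbed) PCC is
#' attached for reference.
#'
#' @param model A trained `cinefuse_model`.
#' @param dataset A `phantom_dataset` (masks are rendered with each exam)
#'   or a list of [cine_exam()] objects carrying masks.
#' @param split Split to evaluate (phantom datasets; default `"test"`).
#' @param sigma,radius Dilation parameters, see [dilate_mask()].
#' @return A `perturbation_grid` tibble (`mode`, `view`, `chamber`, `pcc`,
#'   `n`), with the intact PCC in `attr(, "intact_pcc")`. Cells whose
#'   perturbed predictions are degenerate (e.g. constant) report `NA`.
#' @export
chamber_importance <- function(model, dataset, split = "test",
                               sigma = 4, radius = 16) {
  cfg <- model$config
  P <- cfg$pool_grid^2
  nv <- length(cfg$views); np <- cfg$n_phases; nf <- nv * np
  pool <- pooling_operator(cfg$image_size, cfg$pool_grid)
  if (inherits(dataset, "phantom_dataset")) {
    idx <- which(dataset$exams$split %in% split)
    if (!length(idx)) abort("no exams in the requested split")
    get_exam <- function(k) materialize_exam(dataset, idx[k], masks = TRUE)
    n <- length(idx)
    truth <- dataset$exams[[cfg$target]][idx]
  } else {
    stopifnot(is.list(dataset))
    n <- length(dataset)
    get_exam <- function(k) dataset[[k]]
    truth <- vapply(dataset, function(e) e$labels[[cfg$target]], numeric(1))
  }
  # all valid single-view cells, in a fixed chamber-major order
  cells <- purrr::map_dfr(c("LV", "LA", "RV", "RA"), function(ch) {
    vs <- cfg$views[vapply(cfg$views, function(v) ch %in% CHAMBERS_BY_VIEW[[v]],
                           logical(1))]
    if (!length(vs)) return(NULL)
    tibble::tibble(chamber = ch, view = c(vs, "All views"))
  })
  modes <- c("mask", "paste")
  pred <- array(NA_real_, c(n, nrow(cells), length(modes)))
  pred_intact <- numeric(n)
  groups <- fusion_groups(cfg)
  view_rows <- lapply(seq_len(nv), function(v) (v - 1L) * np + seq_len(np))
  names(view_rows) <- cfg$views
  for (k in seq_len(n)) {
    exam <- preprocess_exam(get_exam(k), size = cfg$image_size,
                            n_phases_expected = np)
    if (is.null(exam$masks)) abort("exam carries no chamber masks")
    X0 <- matrix(0, nf, P)
    for (v in cfg$views) {
      fr <- exam$series[[v]]$frames
      for (p in seq_len(np)) {
        X0[view_rows[[v]][p], ] <- as.numeric(crossprod(pool, fr[, , p]) %*% pool)
      }
    }
    # pooled content of each dilated chamber region, per view
    pm <- list()
    for (v in names(exam$masks)) {
      fr <- exam$series[[v]]$frames
      for (ch in names(exam$masks[[v]])) {
        mk <- align_mask(exam$masks[[v]][[ch]], dim(fr))
        Xm <- matrix(0, np, P)
        for (p in seq_len(np)) {
          dm <- dilate_mask(mk[, , p], sigma, radius)
          Xm[p, ] <- as.numeric(crossprod(pool, fr[, , p] * dm) %*% pool)
        }
        pm[[v]][[ch]] <- Xm
      }
    }
    run <- function(X) {
      He <- encode_pooled(model$params, cfg$activation, X)
      fuse_forward(cfg, model$params, He, groups)$pred *
        model$target_scale + model$target_center
    }
    pred_intact[k] <- run(X0)
    for (ci in seq_len(nrow(cells))) {
      ch <- cells$chamber[ci]; vw <- cells$view[ci]
      vs <- if (vw == "All views") {
        names(pm)[vapply(names(pm), function(v) ch %in% names(pm[[v]]),
                         logical(1))]
      } else vw
      if (!length(vs) || !all(vapply(vs, function(v) ch %in% names(pm[[v]]),
                                     logical(1)))) next
      for (mi in seq_along(modes)) {
        X <- if (modes[mi] == "mask") X0 else matrix(0, nf, P)
        for (v in vs) {
          X[view_rows[[v]], ] <- if (modes[mi] == "mask") {
            X0[view_rows[[v]], ] - pm[[v]][[ch]]
          } else {
            pm[[v]][[ch]]
          }
        }
        pred[k, ci, mi] <- run(X)
      }
    }
  }
  grid <- purrr::map_dfr(seq_along(modes), function(mi) {
    dplyr::mutate(cells, mode = modes[mi],
                  pcc = vapply(seq_len(nrow(cells)), function(ci) {
                    p <- pred[, ci, mi]
                    if (anyNA(p) || sd(p) == 0) {
                      warn(sprintf("degenerate predictions for %s/%s (%s); PCC undefined",
                                   cells$view[ci], cells$chamber[ci], modes[mi]))
                      return(NA_real_)
                    }
                    pearson_corr(truth, p)
                  }, numeric(1)),
                  n = n)
  })
  grid <- dplyr::select(grid, "mode", "view", "chamber", "pcc", "n")
  attr(grid, "intact_pcc") <- pearson_corr(truth, pred_intact)
  class(grid) <- c("perturbation_grid", class(grid))
  grid
}
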