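#' Model configuration
#'
#' Configures the multi-view cine regression network: a shared frame
#' encoder maps each 256x256 frame to a D-dimensional feature; a single
#' shared Attention Feature Fusion Block (AFFB) fuses the 80 frame features
#' in two stages (view-wise per phase -> 20 spatial summaries, phase-wise
#' per view -> 4 temporal summaries, then all 24 into the final feature);
#' a shared affine regression layer maps any feature to a scalar.
#'
#' The encoder is a compact design suited to CPU training: a fixed
#' `pool_grid x pool_grid` patch-average pooling of the frame followed by a
#' learned affine map and elementwise nonlinearity. Because encoder, AFFB,
#' and regression layer are each shared, the trainable parameter count is
#' independent of the number of views and phases.
#'
#' @param views Character vector of view ids (default all four).
#' @param n_phases Phases per cine series (default 20).
#' @param image_size Input frame size in pixels (square).
#' @param pool_grid Pooling grid; `image_size` must be divisible by it.
#' @param feature_dim Feature dimension D (default 64, the small profile).
#' @param activation Encoder nonlinearity: `"relu"`, `"tanh"`, or
#'   `"identity"`.
#' @param target Which label the model predicts (`mPAP`, `PAWP`, `PVR`).
#' @param shared_affb Use one AFFB for all 25 fusion calls (default TRUE);
#'   `FALSE` gives each stage its own scorer, for ablation.
#' @return A `cinefuse_config` list.
#' @export
cinefuse_config <- function(views = CINE_VIEWS, n_phases = 20L,
                            image_size = 256L, pool_grid = 16L,
                            feature_dim = 64L,
                            activation = c("relu", "tanh", "identity"),
                            target = c("mPAP", "PAWP", "PVR"),
                            shared_affb = TRUE) {
  activation <- match.arg(activation)
  target <- match.arg(target)
  stopifnot(length(views) >= 1L, all(views %in% CINE_VIEWS),
            n_phases >= 1L, feature_dim >= 1L,
            image_size %% pool_grid == 0L)
  structure(list(views = views, n_phases = as.integer(n_phases),
                 image_size = as.integer(image_size),
                 pool_grid = as.integer(pool_grid),
                 feature_dim = as.integer(feature_dim),
                 activation = activation, target = target,
                 shared_affb = shared_affb),
            class = "cinefuse_config")
}

# Block-average pooling operator: image_size x pool_grid matrix M with
# M[i, j] = 1/block if row i falls in block j, so t(M) %*% frame %*% M is
# the patch-mean image.
pooling_operator <- function(image_size, pool_grid) {
  block <- image_size %/% pool_grid
  M <- matrix(0, image_size, pool_grid)
  M[cbind(seq_len(image_size), rep(seq_len(pool_grid), each = block))] <- 1 / block
  M
}

#' Initialise a multi-view cine fusion model
#'
#' Weights are drawn at random (He-scaled encoder, small attention and
#' regression heads); deterministic given `seed`.
#'
#' @param config A [cinefuse_config()].
#' @param seed Integer seed for weight initialisation.
#' @return A `cinefuse_model` object.
#' @export
cinefuse_model <- function(config = cinefuse_config(), seed = 1L) {
  stopifnot(inherits(config, "cinefuse_config"))
  P <- config$pool_grid^2
  D <- config$feature_dim
  init_scorer <- function() list(w_a = rnorm(D, sd = 0.1 / sqrt(D)), b_a = 0)
  params <- with_local_seed(seed, {
    p <- list(W1 = matrix(rnorm(P * D, sd = sqrt(2 / P)), P, D),
              b1 = rep(0, D),
              scorers = if (config$shared_affb) list(shared = init_scorer())
                        else list(view_wise = init_scorer(),
                                  phase_wise = init_scorer(),
                                  final = init_scorer()),
              w_r = rnorm(D, sd = 0.1 / sqrt(D)), b_r = 0)
    p
  })
  structure(list(config = config, params = params,
                 pool = pooling_operator(config$image_size, config$pool_grid),
                 target_center = 0, target_scale = 1,
                 trained = FALSE, history = NULL, seed = seed),
            class = "cinefuse_model")
}

#' @export
print.cinefuse_model <- function(x, ...) {
  cat(sprintf("<cinefuse_model> %s target, %d views x %d phases, D=%d (%s)%s\n",
              x$config$target, length(x$config$views), x$config$n_phases,
              x$config$feature_dim,
              if (x$trained) "trained" else "untrained",
              sprintf(", %d parameters", n_parameters(x))))
  invisible(x)
}

#' Trainable parameter count
#' @param model A `cinefuse_model`.
#' @return Integer number of trainable scalars.
#' @export
n_parameters <- function(model) {
  p <- model$params
  length(p$W1) + length(p$b1) + length(p$w_r) + 1L +
    sum(vapply(p$scorers, function(s) length(s$w_a) + 1L, integer(1)))
}

scorer_for <- function(model, stage) {
  if (model$config$shared_affb) model$params$scorers$shared
  else model$params$scorers[[stage]]
}

softmax <- function(a) {
  e <- exp(a - max(a))
  e / sum(e)
}

# Pool a frame to its patch-mean feature vector (length pool_grid^2).
pool_frame <- function(model, frame) {
  as.numeric(crossprod(model$pool, frame) %*% model$pool)
}

activate <- function(h, activation) {
  switch(activation, relu = pmax(h, 0), tanh = tanh(h), identity = h)
}

#' Encode one frame into a feature vector
#'
#' Applies the shared frame encoder (fixed patch-average pooling, then a
#' learned affine map and nonlinearity). Deterministic: the same frame
#' always yields the same feature.
#'
#' @param model A `cinefuse_model`.
#' @param frame Numeric `image_size x image_size` matrix with values in
#'   `[0, 1]`.
#' @return Numeric feature vector of length `feature_dim`.
#' @export
encode_frame <- function(model, frame) {
  stopifnot(inherits(model, "cinefuse_model"))
  sz <- model$config$image_size
  if (!is.matrix(frame) || !all(dim(frame) == c(sz, sz))) {
    abort(sprintf("frame must be a %dx%d matrix", sz, sz))
  }
  pooled <- pool_frame(model, frame)
  h <- as.numeric(crossprod(model$params$W1, pooled)) + model$params$b1
  activate(h, model$config$activation)
}

# Encode a matrix of pooled frame vectors (rows) into features (rows).
encode_pooled <- function(params, activation, X) {
  H <- X %*% params$W1
  H <- sweep(H, 2, params$b1, "+")
  activate(H, activation)
}

#' Attention feature fusion (AFFB)
#'
#' Fuses N >= 1 component features of common dimension D into one fused
#' feature of dimension D: a shared linear scorer assigns each component a
#' raw attention weight, softmax normalises the weights to sum to one, and
#' the fused feature is the weighted sum. With a single component the block
#' is the identity; with identical components it returns them unchanged.
#'
#' @param model A `cinefuse_model` (supplies the scorer parameters).
#' @param components Numeric matrix (N x D, rows are components) or a list
#'   of equal-length numeric vectors.
#' @param stage Which scorer to use when `shared_affb = FALSE`; ignored for
#'   the default shared block.
#' @return List with `fused` (length-D vector) and `weights`, a list of
#'   `raw` and `normalized` attention weights.
#' @export
affb_fuse <- function(model, components,
                      stage = c("shared", "view_wise", "phase_wise", "final")) {
  stage <- match.arg(stage)
  if (is.list(components) && !is.data.frame(components)) {
    lens <- lengths(components)
    if (length(components) == 0L) abort("cannot fuse an empty component list")
    if (length(unique(lens)) != 1L) abort("components have mixed dimensions")
    components <- do.call(rbind, components)
  }
  if (!is.matrix(components) || nrow(components) < 1L) {
    abort("cannot fuse an empty component list")
  }
  D <- model$config$feature_dim
  if (ncol(components) != D) {
    abort(sprintf("components must have dimension %d", D))
  }
  sc <- if (model$config$shared_affb) scorer_for(model, "shared")
        else scorer_for(model, if (stage == "shared") "final" else stage)
  raw <- as.numeric(components %*% sc$w_a) + sc$b_a
  alpha <- softmax(raw)
  fused <- as.numeric(crossprod(components, alpha))
  list(fused = fused, weights = list(raw = raw, normalized = alpha))
}

# Frame ordering is view-major: index (v-1) * n_phases + p.
frame_index <- function(config) {
  tibble::tibble(
    idx = seq_len(length(config$views) * config$n_phases),
    view = rep(config$views, each = config$n_phases),
    phase = rep(seq_len(config$n_phases), length(config$views))
  )
}

fusion_groups <- function(config) {
  nv <- length(config$views); np <- config$n_phases
  list(
    # one view-wise fusion per phase: the nv frames of that phase
    by_phase = lapply(seq_len(np), function(p) (seq_len(nv) - 1L) * np + p),
    # one phase-wise fusion per view: the np frames of that view
    by_view = lapply(seq_len(nv), function(v) (v - 1L) * np + seq_len(np))
  )
}

#' Two-stage attention fusion of a frame-feature grid
#'
#' Stage 1 runs one AFFB call per phase over its views (spatial summaries)
#' and one per view over its phases (temporal summaries); stage 2 fuses all
#' resulting summaries into the final feature in a single AFFB call. Every
#' feature -- the 80 frame features, 24 summaries, and the final feature --
#' is also passed through the shared regression layer, giving the
#' per-feature prediction surface.
#'
#' @param model A `cinefuse_model`.
#' @param frame_features Numeric matrix `(n_views * n_phases) x D` in
#'   view-major order (all phases of view 1, then view 2, ...).
#' @return A `fusion_trace`: frame features, spatial and temporal
#'   summaries, final feature, all attention weights, and per-feature
#'   predictions.
#' @details The complete view-by-phase grid is required; an incomplete grid
#'   is rejected. The fusion itself accepts any component count, so exams
#'   with fewer views or phases are handled by configuring a smaller grid
#'   in [cinefuse_config()] rather than by silently dropping rows.
#' @export
two_stage_fuse <- function(model, frame_features) {
  cfg <- model$config
  nv <- length(cfg$views); np <- cfg$n_phases
  if (!is.matrix(frame_features) ||
      nrow(frame_features) != nv * np ||
      ncol(frame_features) != cfg$feature_dim) {
    abort(sprintf("frame_features must be a %d x %d matrix (view-major)",
                  nv * np, cfg$feature_dim))
  }
  g <- fusion_groups(cfg)
  spatial <- matrix(0, np, cfg$feature_dim)
  w_view <- matrix(0, np, nv, dimnames = list(NULL, cfg$views))
  for (p in seq_len(np)) {
    fz <- affb_fuse(model, frame_features[g$by_phase[[p]], , drop = FALSE],
                    stage = "view_wise")
    spatial[p, ] <- fz$fused
    w_view[p, ] <- fz$weights$normalized
  }
  temporal <- matrix(0, nv, cfg$feature_dim, dimnames = list(cfg$views, NULL))
  w_phase <- matrix(0, nv, np, dimnames = list(cfg$views, NULL))
  for (v in seq_len(nv)) {
    fz <- affb_fuse(model, frame_features[g$by_view[[v]], , drop = FALSE],
                    stage = "phase_wise")
    temporal[v, ] <- fz$fused
    w_phase[v, ] <- fz$weights$normalized
  }
  stage2 <- rbind(spatial, temporal)
  fz <- affb_fuse(model, stage2, stage = "final")
  final <- fz$fused
  w_final <- setNames(fz$weights$normalized,
                      c(sprintf("phase_%02d", seq_len(np)), cfg$views))
  idx <- frame_index(cfg)
  preds <- tibble::tibble(
    level = c(rep("frame", nv * np), rep("spatial_summary", np),
              rep("temporal_summary", nv), "final"),
    view = c(idx$view, rep(NA_character_, np), cfg$views, NA_character_),
    phase = c(idx$phase, seq_len(np), rep(NA_integer_, nv), NA_integer_),
    prediction = regress(model, rbind(frame_features, spatial, temporal,
                                      matrix(final, 1)))
  )
  structure(list(frame_features = frame_features,
                 spatial_summaries = spatial,
                 temporal_summaries = temporal,
                 final_feature = final,
                 weights = list(view_wise = w_view, phase_wise = w_phase,
                                final = w_final),
                 per_feature_predictions = preds),
            class = "fusion_trace")
}

#' @export
print.fusion_trace <- function(x, ...) {
  cat(sprintf("<fusion_trace> %d frame features, %d summaries, 1 final feature (D=%d)\n",
              nrow(x$frame_features),
              nrow(x$spatial_summaries) + nrow(x$temporal_summaries),
              length(x$final_feature)))
  invisible(x)
}

#' Regression layer
#'
#' The shared affine head mapping any feature (component, summary, or
#' final) to a prediction in target units.
#'
#' @param model A `cinefuse_model`.
#' @param features Length-D vector or N x D matrix (rows are features).
#' @return Numeric vector of predictions.
#' @export
regress <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, 1)
  stopifnot(ncol(features) == model$config$feature_dim)
  std <- as.numeric(features %*% model$params$w_r) + model$params$b_r
  std * model$target_scale + model$target_center
}

#' Forward pass over one examination
#'
#' Encodes all frames of a preprocessed exam, runs the two-stage attention
#' fusion, and regresses the final feature; the complete fusion trace is
#' returned for explainability.
#'
#' @param model A `cinefuse_model`.
#' @param exam A preprocessed [cine_exam()] covering the model's views.
#' @return List with `prediction` (scalar, target units) and `trace`
#'   (a `fusion_trace`).
#' @export
predict_exam <- function(model, exam) {
  stopifnot(inherits(exam, "cine_exam"))
  cfg <- model$config
  missing_views <- setdiff(cfg$views, names(exam$series))
  if (length(missing_views)) {
    abort(paste0("exam is missing view(s): ", paste(missing_views, collapse = ", ")))
  }
  feats <- lapply(cfg$views, function(v) {
    s <- exam$series[[v]]
    if (n_phases(s) != cfg$n_phases) {
      abort(sprintf("view %s has %d phases; model expects %d",
                    v, n_phases(s), cfg$n_phases))
    }
    t(vapply(seq_len(cfg$n_phases),
             function(p) encode_frame(model, s$frames[, , p]),
             numeric(cfg$feature_dim)))
  })
  trace <- two_stage_fuse(model, do.call(rbind, feats))
  list(prediction = regress(model, trace$final_feature), trace = trace)
}
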