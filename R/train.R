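#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 1e-4 and
#' weight decay 1e-8, batch size 10, up to 1000 epochs with early stopping
#' on validation MSE (patience 50, best checkpoint restored).
#'
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty folded into the gradient.
#' @param batch_size Exams per optimisation step.
#' @param max_epochs Upper bound on epochs.
#' @param patience Early-stop patience, in epochs without validation
#'   improvement; must not exceed `max_epochs`.
#' @param seed Seed covering shuffling (and any augmentation sampling).
#' @param aux_loss_weight Optional deep-supervision weight: adds
#'   `aux_loss_weight` times the mean squared error of the 104 component
#'   predictions to the final-feature loss (0 = final-only, the default).
#' @param verbose Print a line per epoch.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 1e-8,
                         batch_size = 10L, max_epochs = 1000L,
                         patience = 50L, seed = 1L,
                         aux_loss_weight = 0, verbose = FALSE) {
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1L,
            max_epochs >= 1L, patience >= 1L, patience <= max_epochs,
            aux_loss_weight >= 0)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 aux_loss_weight = aux_loss_weight, verbose = verbose),
            class = "train_config")
}

#' Small-profile training configuration
#'
#' A CPU-friendly schedule for the compact encoder: larger steps and
#' batches, fewer epochs. Used throughout the package's own experiments.
#'
#' @param ... Overrides passed to [train_config()].
#' @export
small_train_config <- function(...) {
  defaults <- list(learning_rate = 3e-3, batch_size = 32L,
                   max_epochs = 150L, patience = 25L)
  do.call(train_config, utils::modifyList(defaults, list(...)))
}

#' Mean squared error
#'
#' @param predictions,targets Equal-length numeric vectors (n >= 1).
#' @return Mean of squared differences.
#' @export
mse_loss <- function(predictions, targets) {
  if (length(predictions) == 0L) abort("empty batch")
  if (length(predictions) != length(targets)) abort("length mismatch")
  mean((predictions - targets)^2)
}

#' Encode a phantom dataset into pooled frame features
#'
#' Streams each exam (render -> preprocess -> patch-average pooling) so the
#' full-resolution pixels of at most one exam are ever held in memory. The
#' pooled representation is the fixed front-end of the encoder; the learned
#' part of the model consumes it directly during training.
#'
#' @param dataset A `phantom_dataset` from [generate_dataset()], or a list
#'   of labelled [cine_exam()] objects.
#' @param config A [cinefuse_config()] describing the frame layout.
#' @param augment Optional [augmentation_params()]; applied per exam to the
#'   training split only (validation and test exams are never augmented),
#'   deterministic given `seed`.
#' @param seed Seed for augmentation draws.
#' @return A `cine_features` object: array `n_exams x n_frames x P` plus
#'   the exam label tibble.
#' @export
encode_dataset <- function(dataset, config = cinefuse_config(),
                           augment = NULL, seed = 1L) {
  pool <- pooling_operator(config$image_size, config$pool_grid)
  P <- config$pool_grid^2
  nf <- length(config$views) * config$n_phases
  if (inherits(dataset, "phantom_dataset")) {
    exams_tbl <- dataset$exams
    get_exam <- function(i) materialize_exam(dataset, i, masks = FALSE)
  } else {
    stopifnot(is.list(dataset), all(vapply(dataset, inherits, logical(1), "cine_exam")))
    exams_tbl <- tibble::tibble(
      id = vapply(seq_along(dataset),
                  function(i) dataset[[i]]$id %||% sprintf("exam_%04d", i),
                  character(1)),
      split = "train",
      mPAP = vapply(dataset, function(e) e$labels[["mPAP"]], numeric(1)),
      PAWP = vapply(dataset, function(e) e$labels[["PAWP"]], numeric(1)),
      PVR = vapply(dataset, function(e) e$labels[["PVR"]], numeric(1))
    )
    get_exam <- function(i) dataset[[i]]
  }
  n <- nrow(exams_tbl)
  X <- array(0, c(n, nf, P))
  aug_seeds <- if (!is.null(augment)) {
    with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  }
  for (i in seq_len(n)) {
    exam <- get_exam(i)
    exam <- preprocess_exam(exam, size = config$image_size,
                            n_phases_expected = config$n_phases)
    if (!is.null(augment) && exams_tbl$split[i] == "train") {
      augment$seed <- aug_seeds[i]
      exam <- augment_exam(exam, augment)
    }
    r <- 1L
    for (v in config$views) {
      fr <- exam$series[[v]]$frames
      for (p in seq_len(config$n_phases)) {
        X[i, r, ] <- as.numeric(crossprod(pool, fr[, , p]) %*% pool)
        r <- r + 1L
      }
    }
  }
  structure(list(X = X, exams = exams_tbl, config = config),
            class = "cine_features")
}

#' @export
print.cine_features <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf("<cine_features> %d exams x %d frames x %d pooled dims\n",
              d[1], d[2], d[3]))
  invisible(x)
}

# ---- internal forward/backward over pooled features ---------------------

act_grad <- function(H, activation) {
  switch(activation, relu = (H > 0) * 1, tanh = 1 - H^2,
         identity = array(1, dim(H)))
}

# Forward fusion for one exam's encoded frames He (nf x D); returns
# everything backward needs. Scorers resolved per stage.
fuse_forward <- function(model_cfg, params, He, groups) {
  sc <- function(stage) {
    if (model_cfg$shared_affb) params$scorers$shared else params$scorers[[stage]]
  }
  np <- model_cfg$n_phases; nv <- length(model_cfg$views)
  D <- model_cfg$feature_dim
  s_vw <- sc("view_wise"); s_pw <- sc("phase_wise"); s_fi <- sc("final")
  S <- matrix(0, np, D); A_vw <- vector("list", np)
  for (p in seq_len(np)) {
    comps <- He[groups$by_phase[[p]], , drop = FALSE]
    a <- softmax(as.numeric(comps %*% s_vw$w_a) + s_vw$b_a)
    A_vw[[p]] <- a
    S[p, ] <- as.numeric(crossprod(comps, a))
  }
  Tm <- matrix(0, nv, D); A_pw <- vector("list", nv)
  for (v in seq_len(nv)) {
    comps <- He[groups$by_view[[v]], , drop = FALSE]
    a <- softmax(as.numeric(comps %*% s_pw$w_a) + s_pw$b_a)
    A_pw[[v]] <- a
    Tm[v, ] <- as.numeric(crossprod(comps, a))
  }
  M <- rbind(S, Tm)
  a2 <- softmax(as.numeric(M %*% s_fi$w_a) + s_fi$b_a)
  g <- as.numeric(crossprod(M, a2))
  pred <- sum(g * params$w_r) + params$b_r
  list(S = S, Tm = Tm, M = M, A_vw = A_vw, A_pw = A_pw, a2 = a2,
       g = g, pred = pred)
}

# Backward through one AFFB call. comps N x D, alpha N, dfused D.
affb_backward <- function(comps, alpha, w_a, dfused) {
  dalpha <- as.numeric(comps %*% dfused)
  da <- alpha * (dalpha - sum(alpha * dalpha))
  list(dcomps = outer(alpha, dfused) + outer(da, w_a),
       dw_a = as.numeric(crossprod(comps, da)),
       db_a = sum(da))
}

zero_like <- function(params) {
  rapply(params, function(x) { x[] <- 0; x }, how = "replace")
}

# Backward for one exam; returns dHe plus parameter gradients to add.
fuse_backward <- function(model_cfg, params, He, fw, dpred, grads,
                          aux = NULL) {
  sc_name <- function(stage) if (model_cfg$shared_affb) "shared" else stage
  np <- model_cfg$n_phases; nv <- length(model_cfg$views)
  grads$w_r <- grads$w_r + dpred * fw$g
  grads$b_r <- grads$b_r + dpred
  dg <- dpred * params$w_r
  s_fi <- if (model_cfg$shared_affb) params$scorers$shared else params$scorers$final
  bw2 <- affb_backward(fw$M, fw$a2, s_fi$w_a, dg)
  nm <- sc_name("final")
  grads$scorers[[nm]]$w_a <- grads$scorers[[nm]]$w_a + bw2$dw_a
  grads$scorers[[nm]]$b_a <- grads$scorers[[nm]]$b_a + bw2$db_a
  dS <- bw2$dcomps[seq_len(np), , drop = FALSE]
  dT <- bw2$dcomps[np + seq_len(nv), , drop = FALSE]
  dHe <- matrix(0, nrow(He), ncol(He))
  if (!is.null(aux)) {
    # deep supervision on summaries: dL/dS, dL/dT terms
    dS <- dS + outer(aux$dpred_S, params$w_r)
    dT <- dT + outer(aux$dpred_T, params$w_r)
    grads$w_r <- grads$w_r +
      as.numeric(crossprod(fw$S, aux$dpred_S)) +
      as.numeric(crossprod(fw$Tm, aux$dpred_T))
    grads$b_r <- grads$b_r + sum(aux$dpred_S) + sum(aux$dpred_T)
  }
  groups <- fusion_groups(model_cfg)
  s_vw <- if (model_cfg$shared_affb) params$scorers$shared else params$scorers$view_wise
  nmv <- sc_name("view_wise")
  for (p in seq_len(np)) {
    idx <- groups$by_phase[[p]]
    bw <- affb_backward(He[idx, , drop = FALSE], fw$A_vw[[p]], s_vw$w_a, dS[p, ])
    dHe[idx, ] <- dHe[idx, ] + bw$dcomps
    grads$scorers[[nmv]]$w_a <- grads$scorers[[nmv]]$w_a + bw$dw_a
    grads$scorers[[nmv]]$b_a <- grads$scorers[[nmv]]$b_a + bw$db_a
  }
  s_pw <- if (model_cfg$shared_affb) params$scorers$shared else params$scorers$phase_wise
  nmp <- sc_name("phase_wise")
  for (v in seq_len(nv)) {
    idx <- groups$by_view[[v]]
    bw <- affb_backward(He[idx, , drop = FALSE], fw$A_pw[[v]], s_pw$w_a, dT[v, ])
    dHe[idx, ] <- dHe[idx, ] + bw$dcomps
    grads$scorers[[nmp]]$w_a <- grads$scorers[[nmp]]$w_a + bw$dw_a
    grads$scorers[[nmp]]$b_a <- grads$scorers[[nmp]]$b_a + bw$db_a
  }
  if (!is.null(aux)) {
    dHe <- dHe + outer(aux$dpred_frames, params$w_r)
    grads$w_r <- grads$w_r + as.numeric(crossprod(He, aux$dpred_frames))
    grads$b_r <- grads$b_r + sum(aux$dpred_frames)
  }
  list(dHe = dHe, grads = grads)
}

# Loss and gradients for a batch of exams. X_batch: n x nf x P; ys
# standardised targets. Returns loss (standardised units) and grads.
batch_grad <- function(model_cfg, params, X_batch, ys, aux_w = 0) {
  n <- dim(X_batch)[1]; nf <- dim(X_batch)[2]; P <- dim(X_batch)[3]
  D <- model_cfg$feature_dim
  Xf <- matrix(aperm(X_batch, c(2, 1, 3)), n * nf, P)  # frame-major within exam
  H <- encode_pooled(params, model_cfg$activation, Xf)
  groups <- fusion_groups(model_cfg)
  grads <- zero_like(params)
  dH <- matrix(0, n * nf, D)
  loss <- 0
  n_comp <- nf + model_cfg$n_phases + length(model_cfg$views)
  for (e in seq_len(n)) {
    rows <- (e - 1L) * nf + seq_len(nf)
    He <- H[rows, , drop = FALSE]
    fw <- fuse_forward(model_cfg, params, He, groups)
    resid <- fw$pred - ys[e]
    loss <- loss + resid^2 / n
    dpred <- 2 * resid / n
    aux <- NULL
    if (aux_w > 0) {
      pr_fr <- as.numeric(He %*% params$w_r) + params$b_r
      pr_S <- as.numeric(fw$S %*% params$w_r) + params$b_r
      pr_T <- as.numeric(fw$Tm %*% params$w_r) + params$b_r
      k <- aux_w * 2 / (n * (n_comp - 1))
      loss <- loss + aux_w * (sum((pr_fr - ys[e])^2) + sum((pr_S - ys[e])^2) +
                                sum((pr_T - ys[e])^2)) / (n * (n_comp - 1))
      aux <- list(dpred_frames = k * (pr_fr - ys[e]),
                  dpred_S = k * (pr_S - ys[e]),
                  dpred_T = k * (pr_T - ys[e]))
    }
    bw <- fuse_backward(model_cfg, params, He, fw, dpred, grads, aux)
    grads <- bw$grads
    dH[rows, ] <- bw$dHe
  }
  dHpre <- dH * act_grad(H, model_cfg$activation)
  grads$W1 <- grads$W1 + crossprod(Xf, dHpre)
  grads$b1 <- grads$b1 + colSums(dHpre)
  list(loss = loss, grads = grads)
}

# Predictions (standardised units) for a feature array n x nf x P.
predict_std <- function(model_cfg, params, X) {
  n <- dim(X)[1]; nf <- dim(X)[2]; P <- dim(X)[3]
  Xf <- matrix(aperm(X, c(2, 1, 3)), n * nf, P)
  H <- encode_pooled(params, model_cfg$activation, Xf)
  groups <- fusion_groups(model_cfg)
  vapply(seq_len(n), function(e) {
    He <- H[(e - 1L) * nf + seq_len(nf), , drop = FALSE]
    fuse_forward(model_cfg, params, He, groups)$pred
  }, numeric(1))
}

# ---- Adam ---------------------------------------------------------------

flatten_params <- function(p) {
  out <- list(W1 = p$W1, b1 = p$b1, w_r = p$w_r, b_r = p$b_r)
  for (nm in names(p$scorers)) {
    out[[paste0("sc_", nm, "_w")]] <- p$scorers[[nm]]$w_a
    out[[paste0("sc_", nm, "_b")]] <- p$scorers[[nm]]$b_a
  }
  out
}

unflatten_params <- function(flat, template) {
  p <- template
  p$W1 <- flat$W1; p$b1 <- flat$b1; p$w_r <- flat$w_r; p$b_r <- flat$b_r
  for (nm in names(p$scorers)) {
    p$scorers[[nm]]$w_a <- flat[[paste0("sc_", nm, "_w")]]
    p$scorers[[nm]]$b_a <- flat[[paste0("sc_", nm, "_b")]]
  }
  p
}

#' Train a cine fusion model
#'
#' Adam optimisation of the mean-squared-error between the final-feature
#' prediction and the target label, with early stopping on validation MSE
#' and restoration of the best checkpoint. Targets are internally z-scored
#' using the training split; predictions are always reported in target
#' units. Fully reproducible given `config$seed` and the model's
#' initialisation seed.
#'
#' @param features A `cine_features` object from [encode_dataset()] whose
#'   exam tibble carries `split` ("train"/"val"/"test") and the target
#'   label, or a `phantom_dataset` (encoded on the fly).
#' @param model A freshly initialised [cinefuse_model()]; its `config`
#'   fixes the target and architecture.
#' @param config A [train_config()].
#' @return The trained `cinefuse_model`, with `$history` (a tibble of
#'   per-epoch train/validation metrics) and `$best_epoch`.
#' @export
train_model <- function(features, model = cinefuse_model(),
                        config = train_config()) {
  stopifnot(inherits(model, "cinefuse_model"), inherits(config, "train_config"))
  if (inherits(features, "phantom_dataset")) {
    features <- encode_dataset(features, model$config)
  }
  stopifnot(inherits(features, "cine_features"))
  exams <- features$exams
  target <- model$config$target
  if (!target %in% names(exams)) abort(sprintf("no %s label in features", target))
  itr <- which(exams$split == "train")
  iva <- which(exams$split == "val")
  if (!length(itr)) abort("empty training split")
  if (any(duplicated(exams$id)) ||
      length(intersect(exams$id[itr], exams$id[iva]))) {
    abort("splits share examination ids")
  }
  y_tr <- exams[[target]][itr]
  mu <- mean(y_tr); sigma <- sd(y_tr)
  if (!is.finite(sigma) || sigma == 0) sigma <- 1
  ys_tr <- (y_tr - mu) / sigma
  ys_va <- if (length(iva)) (exams[[target]][iva] - mu) / sigma
  Xtr <- features$X[itr, , , drop = FALSE]
  Xva <- if (length(iva)) features$X[iva, , , drop = FALSE]

  cfg_m <- model$config
  params <- model$params
  flat <- flatten_params(params)
  m_state <- lapply(flat, function(x) { x[] <- 0; x })
  v_state <- m_state
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  best <- list(loss = Inf, flat = flat, epoch = 0L)
  hist <- vector("list", config$max_epochs)
  wait <- 0L

  with_local_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(length(itr))
      nb <- ceiling(length(ord) / config$batch_size)
      tr_loss <- 0
      for (b in seq_len(nb)) {
        sel <- ord[((b - 1L) * config$batch_size + 1L):
                     min(b * config$batch_size, length(ord))]
        params <- unflatten_params(flat, params)
        bg <- batch_grad(cfg_m, params, Xtr[sel, , , drop = FALSE],
                         ys_tr[sel], config$aux_loss_weight)
        tr_loss <- tr_loss + bg$loss * length(sel)
        gflat <- flatten_params(bg$grads)
        step <- step + 1L
        for (nm in names(flat)) {
          g <- gflat[[nm]] + config$weight_decay * flat[[nm]]
          m_state[[nm]] <- beta1 * m_state[[nm]] + (1 - beta1) * g
          v_state[[nm]] <- beta2 * v_state[[nm]] + (1 - beta2) * g^2
          mhat <- m_state[[nm]] / (1 - beta1^step)
          vhat <- v_state[[nm]] / (1 - beta2^step)
          flat[[nm]] <- flat[[nm]] - config$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      tr_loss <- tr_loss / length(itr)
      params <- unflatten_params(flat, params)
      row <- tibble::tibble(epoch = epoch,
                            train_loss = tr_loss * sigma^2,
                            val_loss = NA_real_, val_mae = NA_real_,
                            val_pcc = NA_real_, val_r2 = NA_real_)
      if (length(iva)) {
        pv <- predict_std(cfg_m, params, Xva)
        row$val_loss <- mse_loss(pv, ys_va) * sigma^2
        pv_t <- pv * sigma + mu
        yv_t <- exams[[target]][iva]
        row$val_mae <- mae(yv_t, pv_t)
        row$val_pcc <- tryCatch(pearson_corr(yv_t, pv_t), error = function(e) NA_real_)
        row$val_r2 <- tryCatch(r_squared(yv_t, pv_t), error = function(e) NA_real_)
        monitor <- row$val_loss
      } else monitor <- row$train_loss
      hist[[epoch]] <- row
      if (config$verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        row$train_loss, row$val_loss))
      }
      if (monitor < best$loss - 1e-12) {
        best <- list(loss = monitor, flat = flat, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })
  model$params <- unflatten_params(best$flat, model$params)
  model$target_center <- mu
  model$target_scale <- sigma
  model$trained <- TRUE
  model$best_epoch <- best$epoch
  model$train_config <- config
  h <- dplyr::bind_rows(hist[!vapply(hist, is.null, logical(1))])
  class(h) <- c("cinefuse_history", class(h))
  model$history <- h
  model
}

#' Predict from encoded features
#'
#' @param object A trained `cinefuse_model`.
#' @param newdata A `cine_features` object (or `phantom_dataset`).
#' @param split Optional split filter (e.g. `"test"`).
#' @param ... Unused.
#' @return Tibble with `id`, `split`, `truth`, `prediction` (target units).
#' @export
predict.cinefuse_model <- function(object, newdata, split = NULL, ...) {
  if (inherits(newdata, "phantom_dataset")) {
    newdata <- encode_dataset(newdata, object$config)
  }
  stopifnot(inherits(newdata, "cine_features"))
  keep <- if (is.null(split)) seq_len(nrow(newdata$exams))
          else which(newdata$exams$split %in% split)
  ps <- predict_std(object$config, object$params,
                    newdata$X[keep, , , drop = FALSE])
  tibble::tibble(id = newdata$exams$id[keep],
                 split = newdata$exams$split[keep],
                 truth = newdata$exams[[object$config$target]][keep],
                 prediction = ps * object$target_scale + object$target_center)
}
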