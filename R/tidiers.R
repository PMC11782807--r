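#' Tidy a cine fusion model
#'
#' One row per parameter group (encoder map, attention scorer(s),
#' regression head) with its size and Euclidean norm.
#'
#' @param x A `cinefuse_model`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `n_parameters`, `l2_norm`.
#' @method tidy cinefuse_model
#' @export
tidy.cinefuse_model <- function(x, ...) {
  p <- x$params
  groups <- c(list(encoder_weights = p$W1, encoder_bias = p$b1,
                   regression_weights = p$w_r, regression_bias = p$b_r),
              setNames(lapply(p$scorers, function(s) c(s$w_a, s$b_a)),
                       paste0("attention_scorer_", names(p$scorers))))
  tibble::tibble(
    component = names(groups),
    n_parameters = vapply(groups, length, integer(1)),
    l2_norm = vapply(groups, function(g) sqrt(sum(g^2)), numeric(1))
  )
}

#' Glance at a cine fusion model
#'
#' @param x A `cinefuse_model`.
#' @param ... Unused.
#' @return One-row tibble: architecture summary and, when trained, the
#'   best-epoch validation metrics.
#' @method glance cinefuse_model
#' @export
glance.cinefuse_model <- function(x, ...) {
  out <- tibble::tibble(
    target = x$config$target,
    n_views = length(x$config$views),
    n_phases = x$config$n_phases,
    feature_dim = x$config$feature_dim,
    n_parameters = n_parameters(x),
    trained = x$trained,
    best_epoch = NA_integer_, val_loss = NA_real_,
    val_pcc = NA_real_, val_r2 = NA_real_
  )
  if (x$trained && !is.null(x$history) && !is.null(x$best_epoch) &&
      x$best_epoch >= 1) {
    h <- x$history[x$history$epoch == x$best_epoch, ]
    out$best_epoch <- x$best_epoch
    out$val_loss <- h$val_loss
    out$val_pcc <- h$val_pcc
    out$val_r2 <- h$val_r2
  }
  out
}
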