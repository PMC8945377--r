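# Joint reconstruction-classification training.
#
# The objective is L_joint = alpha * L_rec + beta * L_ce, with the summed
# per-modality squared-error reconstruction loss and the binary cross-entropy
# classification loss, optimized jointly (autoencoder and classifier weights
# updated simultaneously) with Adam.

CE_EPS <- 1e-7

#' Summed per-modality reconstruction loss
#'
#' `sum_i ||x_i - x_i-hat||^2` over the modalities, averaged over the batch
#' samples (per-sample averaging keeps the loss on a scale independent of the
#' batch size; set `reduce = "sum"` for the raw per-sample sum).
#'
#' @param targets List of target matrices.
#' @param reconstructions List of reconstruction matrices, matching shapes.
#' @param reduce `"mean"` (default) or `"sum"` over samples.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(targets, reconstructions, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  if (length(targets) != length(reconstructions)) {
    stopf("`targets` and `reconstructions` must pair up")
  }
  total <- 0
  for (i in seq_along(targets)) {
    if (!identical(dim(targets[[i]]), dim(reconstructions[[i]]))) {
      stopf("reconstruction %d: shape mismatch (%s vs %s)", i,
            paste(dim(targets[[i]]), collapse = "x"),
            paste(dim(reconstructions[[i]]), collapse = "x"))
    }
    total <- total + sum((targets[[i]] - reconstructions[[i]])^2)
  }
  if (reduce == "mean") total / nrow(targets[[1L]]) else total
}

#' Binary cross-entropy classification loss
#'
#' Mean over samples of `-[y log y' + (1 - y) log(1 - y')]`. Predicted
#' probabilities are clamped to `[1e-7, 1 - 1e-7]` so that saturated
#' predictions yield a finite loss.
#'
#' @param y 0/1 labels.
#' @param prob Predicted positive-class probabilities in (0, 1).
#' @param pos_weight Optional weight multiplying the positive-class terms
#'   (e.g. `n_neg / n_pos` to counter imbalance); default 1.
#' @return Non-negative scalar.
#' @export
classification_loss <- function(y, prob, pos_weight = 1) {
  assert_binary(y, "y")
  if (length(y) != length(prob)) stopf("`y` and `prob` lengths differ")
  p <- pmin(pmax(prob, CE_EPS), 1 - CE_EPS)
  -mean(pos_weight * y * log(p) + (1 - y) * log(1 - p))
}

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 0.01 for
#' 100 epochs, joint-loss weights `alpha = beta = 1`, full-batch gradient
#' steps (cohorts in this setting rarely exceed a few hundred samples, so
#' full-batch removes a tuning axis; set `batch_size` for mini-batching).
#'
#' @param learning_rate Adam learning rate (default 0.01).
#' @param epochs Number of epochs (default 100).
#' @param alpha Weight of the reconstruction loss (default 1).
#' @param beta Weight of the classification loss (default 1).
#' @param batch_size Mini-batch size, or `NULL` (default) for full batch.
#' @param seed Seed controlling mini-batch shuffling.
#' @param pos_weight Weight of the positive-class cross-entropy terms
#'   (default 1, i.e. no reweighting; balanced accuracy already reports
#'   imbalance-robust performance).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.01, epochs = 100L, alpha = 1,
                         beta = 1, batch_size = NULL, seed = 1L,
                         pos_weight = 1) {
  assert_scalar_number(learning_rate, "learning_rate", 0, Inf, strict = TRUE)
  assert_scalar_number(pos_weight, "pos_weight", 0, Inf, strict = TRUE)
  if (epochs < 1L) stopf("`epochs` must be >= 1")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 alpha = alpha, beta = beta, batch_size = batch_size,
                 seed = as.integer(seed), pos_weight = pos_weight),
            class = "train_config")
}

# One joint gradient step on a batch. Returns updated model and the losses.
train_step <- function(model, inputs, targets, y, config, state, t) {
  fw <- fusion_forward(model, inputs, training = TRUE)
  model <- fw$model
  n <- length(y)
  tgt <- lapply(model$threads, function(th) targets[[th$target]])
  w <- config$pos_weight %||% 1
  l_rec <- reconstruction_loss(unname(tgt), unname(fw$reconstructions[names(model$threads)]))
  l_ce <- classification_loss(y, fw$prob, pos_weight = w)
  l_joint <- config$alpha * l_rec + config$beta * l_ce
  if (!is.finite(l_joint)) return(list(model = model, losses = c(l_rec, l_ce, l_joint)))

  # classifier head: d L_ce / d logit = (p - y) / n, scaled by beta (and by
  # pos_weight on the positive-class terms).
  p <- pmin(pmax(fw$prob, CE_EPS), 1 - CE_EPS)
  wy <- ifelse(y == 1, w, 1)
  dprob <- config$beta * wy * (p - y) / n / (p * (1 - p))  # chain through the clamp
  dprob <- matrix(dprob, ncol = 1L)
  bk_clf <- mlp_backward(model$clf, fw$caches$clf, dprob)
  model$clf <- adam_update_mlp(state, "clf", model$clf, bk_clf$grads,
                               config$learning_rate, t)
  dZ <- bk_clf$dX

  if (!is.null(model$fusion)) {
    bk_fus <- mlp_backward(model$fusion, fw$caches$fusion, dZ)
    model$fusion <- adam_update_mlp(state, "fusion", model$fusion, bk_fus$grads,
                                    config$learning_rate, t)
    dZin <- bk_fus$dX
  } else {
    dZin <- dZ
  }

  # split the fused gradient back onto the thread latents
  hs <- vapply(model$threads, `[[`, numeric(1L), "h")
  dz <- list()
  if (model$spec$fusion_rule == "concat") {
    off <- 0L
    for (nm in names(model$threads)) {
      dz[[nm]] <- dZin[, off + seq_len(hs[[nm]]), drop = FALSE]
      off <- off + hs[[nm]]
    }
  } else {
    for (nm in names(model$threads)) dz[[nm]] <- dZin / length(model$threads)
  }

  for (nm in names(model$threads)) {
    th <- model$threads[[nm]]
    dRecon <- config$alpha * 2 * (fw$reconstructions[[nm]] - targets[[th$target]]) / n
    bk_dec <- mlp_backward(th$dec, fw$caches$dec[[nm]], dRecon)
    model$threads[[nm]]$dec <- adam_update_mlp(state, paste0("dec.", nm),
                                               th$dec, bk_dec$grads,
                                               config$learning_rate, t)
    bk_enc <- mlp_backward(th$enc, fw$caches$enc[[nm]], bk_dec$dX + dz[[nm]])
    model$threads[[nm]]$enc <- adam_update_mlp(state, paste0("enc.", nm),
                                               th$enc, bk_enc$grads,
                                               config$learning_rate, t)
  }
  list(model = model, losses = c(l_rec, l_ce, l_joint))
}

#' Train a fusion model on a reference dataset
#'
#' Joint optimization of the reconstruction and classification losses; the
#' autoencoder and classifier weights are updated simultaneously. For the IFA
#' variant the reference dataset must contain the unshared modality, which
#' supervises the surrogate decoder.
#'
#' @param model A `fusion_model` from [build_cfa()], [build_ifa()] or
#'   [build_sma()].
#' @param reference A labeled [multiomics()] dataset containing every modality
#'   the variant reads or reconstructs.
#' @param config A [train_config()].
#' @return List with `model` (trained) and `history`, a data frame with one
#'   row per epoch (`epoch`, `l_rec`, `l_ce`, `l_joint`).
#' @export
train_fusion <- function(model, reference, config = train_config()) {
  if (is.null(reference$labels)) stopf("reference dataset must be labeled")
  need <- unique(c(vapply(model$threads, `[[`, character(1L), "input"),
                   vapply(model$threads, `[[`, character(1L), "target")))
  miss <- setdiff(need, names(reference$modalities))
  if (length(miss)) {
    stopf("training %s requires modality '%s' in the reference data",
          model$variant, miss[1L])
  }
  mats <- lapply(reference$modalities[need], unclass)
  y <- as.numeric(reference$labels)
  n <- length(y)
  state <- adam_state_new()
  hist <- matrix(NA_real_, config$epochs, 3L)
  t <- 0L
  batches <- if (is.null(config$batch_size)) list(seq_len(n)) else NULL
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      if (!is.null(config$batch_size)) {
        ord <- sample(n)
        batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      }
      ep_losses <- c(0, 0, 0)
      for (b in batches) {
        t <- t + 1L
        inputs <- lapply(mats, function(m) m[b, , drop = FALSE])
        step <- train_step(model, inputs, inputs, y[b], config, state, t)
        model <- step$model
        if (!all(is.finite(step$losses))) {
          stopf("training diverged: non-finite loss at epoch %d", epoch)
        }
        ep_losses <- ep_losses + step$losses * length(b)
      }
      hist[epoch, ] <- ep_losses / n
    }
  })
  history <- data.frame(epoch = seq_len(config$epochs), l_rec = hist[, 1L],
                        l_ce = hist[, 2L], l_joint = hist[, 3L])
  list(model = model, history = history)
}
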