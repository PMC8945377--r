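# The three fusion architectures: CFA, IFA and SMA.
#
# Each model is a set of per-modality "threads" (encoder + decoder), an
# optional fusion encoder over the concatenated (or averaged) thread latents,
# and a classification head (dense layer + sigmoid). A thread records which
# modality it reads (`input`) and which it reconstructs (`target`); in the
# incomplete architecture (IFA) the surrogate thread reads the shared modality
# m1 but reconstructs the unshared m2, which is how a completely missing
# modality still contributes a latent at inference time.

#' Encoder architecture specification
#'
#' Defaults reproduce the reference backbone used for the full-size TCGA
#' matrices: two-layer encoders of widths 1024/256 for the two wide modalities,
#' a 64-unit encoder for miRNA, and a 36-unit fusion encoder over the
#' 256+256+64 = 576-wide concatenated latent.
#'
#' @param encoder_widths Named list of per-modality hidden width vectors. The
#'   last width of a modality's encoder is that modality's latent size `h_i`.
#' @param fusion_width Hidden width(s) of the fusion encoder applied to the
#'   fused thread latents.
#' @param batchnorm Apply 1-D batch normalization after each dense layer in
#'   the encoders (before the rectifier). Default `TRUE`.
#' @param fusion_rule `"concat"` (default; the 576-wide fusion input of the
#'   reference backbone is only consistent with concatenation) or `"average"`,
#'   which requires all thread latents to share one width.
#' @param decoder `"mirrored"` (default; decoder widths reverse the encoder's)
#'   or `"single"` (one dense layer from latent back to the input dimension).
#' @param decoder_activation Activation of the final decoder layer: `"relu"`
#'   (default; note this forces non-negative reconstructions, so z-scored
#'   targets can only be matched on their positive part) or `"linear"`.
#' @return An `encoder_spec` list.
#' @export
encoder_spec <- function(encoder_widths = list(m1 = c(1024L, 256L),
                                               m2 = c(1024L, 256L),
                                               m3 = 64L),
                         fusion_width = 36L,
                         batchnorm = TRUE,
                         fusion_rule = c("concat", "average"),
                         decoder = c("mirrored", "single"),
                         decoder_activation = c("relu", "linear")) {
  fusion_rule <- match.arg(fusion_rule)
  decoder <- match.arg(decoder)
  decoder_activation <- match.arg(decoder_activation)
  if (any(unlist(encoder_widths) < 1L) || any(fusion_width < 1L)) {
    stopf("all layer widths must be >= 1")
  }
  structure(list(encoder_widths = encoder_widths, fusion_width = fusion_width,
                 batchnorm = batchnorm, fusion_rule = fusion_rule,
                 decoder = decoder, decoder_activation = decoder_activation),
            class = "encoder_spec")
}

#' Desk-scale encoder specification for the shipped simulation preset
#'
#' Scales the reference backbone's compression ratios (roughly 8x then 4x per
#' encoder layer) down to the preset's 500/800/50 feature counts. Decoders use
#' linear outputs: the preset pipeline reconstructs z-scored (signed) targets,
#' which a rectifier output could only match on their positive part.
#'
#' @return An `encoder_spec`.
#' @export
preset_encoder_spec <- function() {
  encoder_spec(encoder_widths = list(m1 = c(64L, 16L), m2 = c(64L, 16L),
                                     m3 = 16L),
               fusion_width = 16L, decoder_activation = "linear")
}

spec_widths_for <- function(spec, name, pos) {
  w <- spec$encoder_widths
  if (!is.null(names(w)) && name %in% names(w)) return(w[[name]])
  if (pos <= length(w)) return(w[[pos]])
  stopf("no encoder widths for modality '%s' in spec", name)
}

make_thread <- function(input, target, d_in, d_out, widths, spec) {
  enc <- init_mlp(d_in, widths, batchnorm = spec$batchnorm)
  dec_widths <- if (spec$decoder == "mirrored") c(rev(widths[-length(widths)]), d_out)
                else d_out
  dec <- init_mlp(widths[length(widths)], dec_widths, batchnorm = FALSE,
                  activation = "relu",
                  final_activation = spec$decoder_activation)
  list(input = input, target = target, enc = enc, dec = dec,
       h = widths[length(widths)], d_in = d_in, d_out = d_out)
}

finish_model <- function(variant, threads, spec, with_fusion = TRUE) {
  hs <- vapply(threads, `[[`, numeric(1L), "h")
  if (spec$fusion_rule == "average" && length(unique(hs)) != 1L) {
    stopf("average fusion requires equal thread latent widths (got %s)",
          paste(hs, collapse = ", "))
  }
  fusion_in <- as.integer(if (spec$fusion_rule == "concat") sum(hs) else hs[[1L]])
  fusion <- NULL
  if (with_fusion) {
    fusion <- init_mlp(fusion_in, spec$fusion_width, batchnorm = spec$batchnorm)
    z_width <- as.integer(spec$fusion_width[length(spec$fusion_width)])
  } else {
    z_width <- fusion_in
  }
  clf <- init_mlp(z_width, 1L, batchnorm = FALSE, activation = "sigmoid")
  structure(
    list(variant = variant, threads = threads, fusion = fusion, clf = clf,
         spec = spec, fusion_input_width = fusion_in, latent_width = z_width),
    class = "fusion_model"
  )
}

#' Build a complete fusion autoencoder (CFA)
#'
#' One encoder/decoder thread per modality; the thread latents are fused
#' (concatenated by default) and compressed by a fusion encoder into the joint
#' latent `Z` used by the classification head. Reconstructions come from the
#' per-modality latents. Built on two modalities this is the CFA-2M ablation
#' baseline.
#'
#' @param dims Named integer vector of per-modality feature counts
#'   (e.g. `c(m1 = 500, m2 = 800, m3 = 50)`).
#' @param spec An [encoder_spec()].
#' @param seed Seed for the (fan-in scaled) weight initialization.
#' @return A `fusion_model`.
#' @export
build_cfa <- function(dims, spec = encoder_spec(), seed = 1L) {
  if (any(dims < 1L)) stopf("all dims must be positive")
  if (is.null(names(dims))) names(dims) <- paste0("m", seq_along(dims))
  with_seed(seed, {
    threads <- lapply(seq_along(dims), function(i) {
      nm <- names(dims)[i]
      make_thread(nm, nm, dims[[i]], dims[[i]],
                  spec_widths_for(spec, nm, i), spec)
    })
    names(threads) <- names(dims)
    finish_model(if (length(dims) == 2L) "CFA-2M" else "CFA", threads, spec)
  })
}

#' Build an incomplete fusion autoencoder (IFA)
#'
#' Like the CFA, except that the thread of the unshared modality (m2) is a
#' surrogate: its encoder consumes the shared modality x1 and its decoder is
#' supervised to reconstruct x2 from the reference source, learning the
#' mapping `x1 -> z_{2|1} -> x2-hat`. At inference the model therefore needs
#' only x1 and x3, yet still contributes a latent (and a reconstruction) for
#' the missing modality.
#'
#' @param dims Named integer feature counts of the modalities available at
#'   inference (e.g. `c(m1 = 500, m3 = 50)`).
#' @param d2 Feature count of the unshared modality, known from the reference
#'   source.
#' @param spec An [encoder_spec()].
#' @param seed Seed for weight initialization.
#' @param missing_name Name of the unshared modality (default `"m2"`).
#' @param shared_name Modality feeding the surrogate encoder (default the
#'   first entry of `dims`).
#' @return A `fusion_model`.
#' @export
build_ifa <- function(dims, d2, spec = encoder_spec(), seed = 1L,
                      missing_name = "m2", shared_name = names(dims)[1L]) {
  if (d2 < 1L) stopf("`d2` must be positive")
  if (any(dims < 1L)) stopf("all dims must be positive")
  if (is.null(names(dims))) {
    stopf("`dims` must be named (modalities available at inference)")
  }
  d1 <- dims[[shared_name]]
  with_seed(seed, {
    threads <- list()
    threads[[shared_name]] <- make_thread(
      shared_name, shared_name, d1, d1,
      spec_widths_for(spec, shared_name, 1L), spec)
    threads[[missing_name]] <- make_thread(
      shared_name, missing_name, d1, d2,
      spec_widths_for(spec, missing_name, 2L), spec)
    for (nm in setdiff(names(dims), shared_name)) {
      threads[[nm]] <- make_thread(nm, nm, dims[[nm]], dims[[nm]],
                                   spec_widths_for(spec, nm, 3L), spec)
    }
    finish_model("IFA", threads, spec)
  })
}

#' Build a single-modal autoencoder (SMA) baseline
#'
#' A standard autoencoder on one modality whose latent feeds the
#' classification head directly (no fusion encoder).
#'
#' @param d Feature count of the modality.
#' @param spec An [encoder_spec()].
#' @param seed Seed for weight initialization.
#' @param name Modality name (default `"m1"`); used to look up encoder widths
#'   in `spec` and to select the input at forward time.
#' @return A `fusion_model`.
#' @export
build_sma <- function(d, spec = encoder_spec(), seed = 1L, name = "m1") {
  if (d < 1L) stopf("`d` must be >= 1")
  with_seed(seed, {
    threads <- list()
    threads[[name]] <- make_thread(name, name, d, d,
                                   spec_widths_for(spec, name, 1L), spec)
    finish_model(paste0("SMA-", name), threads, spec, with_fusion = FALSE)
  })
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model %s> %d thread(s), fused latent width %d\n",
              x$variant, length(x$threads), x$latent_width))
  for (th in x$threads) {
    cat(sprintf("  %s -> h=%d -> %s-hat (d_in=%d, d_out=%d)\n",
                th$input, th$h, th$target, th$d_in, th$d_out))
  }
  np <- n_parameters(x)
  cat(sprintf("  parameters: %d\n", sum(np)))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model A `fusion_model`.
#' @param include_batchnorm Count batch-norm scale/shift parameters too
#'   (default `TRUE`; set `FALSE` to count dense weights and biases only).
#' @return Named integer vector with one entry per component
#'   (`enc_<mod>`, `dec_<mod>`, `fusion`, `classifier`).
#' @export
n_parameters <- function(model, include_batchnorm = TRUE) {
  out <- integer(0L)
  for (nm in names(model$threads)) {
    th <- model$threads[[nm]]
    out[paste0("enc_", nm)] <- mlp_param_count(th$enc, include_batchnorm)
    out[paste0("dec_", nm)] <- mlp_param_count(th$dec, include_batchnorm)
  }
  if (!is.null(model$fusion)) {
    out["fusion"] <- mlp_param_count(model$fusion, include_batchnorm)
  }
  out["classifier"] <- mlp_param_count(model$clf, include_batchnorm)
  out
}

required_inputs <- function(model) unique(vapply(model$threads, `[[`,
                                                 character(1L), "input"))

# Full forward pass. `inputs` is a named list of samples-in-rows matrices
# covering required_inputs(model). Returns reconstructions, thread latents,
# fused latent Z, predicted probability, and (for training) all caches plus
# the model with updated batch-norm running statistics.
fusion_forward <- function(model, inputs, training = FALSE) {
  need <- required_inputs(model)
  miss <- setdiff(need, names(inputs))
  if (length(miss)) {
    stopf("forward pass of %s requires modality '%s', which was not supplied",
          model$variant, miss[1L])
  }
  nref <- nrow(inputs[[need[1L]]])
  z <- list(); recon <- list(); enc_caches <- list(); dec_caches <- list()
  for (nm in names(model$threads)) {
    th <- model$threads[[nm]]
    X <- inputs[[th$input]]
    if (nrow(X) != nref) stopf("modality '%s': inconsistent sample count", th$input)
    fe <- mlp_forward(th$enc, X, training)
    model$threads[[nm]]$enc <- fe$mlp
    z[[nm]] <- fe$out
    enc_caches[[nm]] <- fe$caches
    fd <- mlp_forward(th$dec, fe$out, training)
    model$threads[[nm]]$dec <- fd$mlp
    recon[[nm]] <- fd$out
    dec_caches[[nm]] <- fd$caches
  }
  if (model$spec$fusion_rule == "concat") {
    Zin <- do.call(cbind, unname(z))
  } else {
    Zin <- Reduce(`+`, z) / length(z)
  }
  fus_cache <- NULL
  if (!is.null(model$fusion)) {
    ff <- mlp_forward(model$fusion, Zin, training)
    model$fusion <- ff$mlp
    Z <- ff$out
    fus_cache <- ff$caches
  } else {
    Z <- Zin
  }
  fc <- mlp_forward(model$clf, Z, training)
  model$clf <- fc$mlp
  list(model = model, z = z, fusion_input = Zin, latent = Z,
       prob = as.numeric(fc$out), reconstructions = recon,
       caches = list(enc = enc_caches, dec = dec_caches, fusion = fus_cache,
                     clf = fc$caches))
}

#' Run a trained model on a dataset
#'
#' Evaluation-mode forward pass (batch norm uses running statistics, so the
#' prediction for a sample does not depend on which batch it sits in).
#'
#' @param object A `fusion_model`.
#' @param dataset A [multiomics()] object (or named list of matrices)
#'   containing the modalities the variant reads.
#' @param ... Unused.
#' @return List with `prob` (predicted positive-class probability per sample),
#'   `class` (0/1 at threshold 0.5), `latent` (fused latent matrix `Z`), and
#'   `reconstructions`.
#' @export
predict.fusion_model <- function(object, dataset, ...) {
  inputs <- if (inherits(dataset, "multiomics")) {
    lapply(dataset$modalities, unclass)
  } else {
    dataset
  }
  fw <- fusion_forward(object, inputs, training = FALSE)
  list(prob = fw$prob, class = as.integer(fw$prob >= 0.5), latent = fw$latent,
       reconstructions = fw$reconstructions)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the trained parameters, the architecture spec,
#' variant tag and the fitted normalization statistics, and round-trips
#' exactly.
#'
#' @param model A `fusion_model`.
#' @param path File path.
#' @param norm_stats Optional `"norm_stats"` attribute from
#'   [zscore_normalize()].
#' @return `path` (for `save_checkpoint`) or the checkpoint list (for
#'   `load_checkpoint`) with elements `model` and `norm_stats`.
#' @export
save_checkpoint <- function(model, path, norm_stats = NULL) {
  saveRDS(list(model = model, norm_stats = norm_stats, version = 1L), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$model) || !inherits(ck$model, "fusion_model")) {
    stopf("'%s' is not a modalfuse checkpoint", path)
  }
  ck
}
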