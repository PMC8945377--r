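# Shared fixture builders. All fixtures are generated in code, seeded.

# A tiny labeled three-modality dataset with a strong class signal, for fast
# pipeline tests.
tiny_dataset <- function(n = 60L, dims = c(m1 = 12L, m2 = 18L, m3 = 6L),
                         class_effect = c(2, 3, 1), seed = 42L) {
  cfg <- simulation_config(n, dims, latent_dim = 2L,
                           loadings_scale = c(1, 1, 0.5),
                           noise_sd = c(1, 1, 1),
                           class_effect = class_effect,
                           prevalence = 0.5, seed = seed)
  simulate_multiomics(cfg)
}

# A tiny encoder spec matched to tiny_dataset dims.
tiny_spec <- function(decoder_activation = "linear") {
  encoder_spec(encoder_widths = list(m1 = 6L, m2 = 6L, m3 = 3L),
               fusion_width = 4L, decoder_activation = decoder_activation)
}

# Write a small modality matrix to a temp TSV and return the path.
write_temp_modality <- function(values, ids, features, name = "m1",
                                ext = ".tsv") {
  m <- modality_matrix(name, matrix(values, length(ids), length(features),
                                    dimnames = list(ids, features)))
  path <- tempfile(fileext = ext)
  write_modality(m, path)
  path
}

# Brute-force pairwise-concordance (Mann-Whitney) AUC with ties counted 1/2.
concordance_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  grid <- outer(pos, neg, `-`)
  (sum(grid > 0) + 0.5 * sum(grid == 0)) / (length(pos) * length(neg))
}
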