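# Small benchmark configurations shared across test files. Sizes are kept
# deliberately small so unit tests stay fast; the full-scale study
# conditions live in the acceptance tests.

tiny_config <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(
      n_proteins = 6, ligands_per_protein = 8, n_background_ligands = 60,
      n_bits = 96, n_desc = 24, n_signature_bits = 10, n_signature_desc = 4,
      size_jitter = 3, seed = seed
    ),
    list(...)
  )
  do.call(wes_benchmark_config, args)
}

tiny_benchmark <- function(seed = 7, ...) {
  generate_benchmark(tiny_config(seed = seed, ...))
}

tiny_model_config <- function(seed = 7, ...) {
  wes_config(seed = seed, ...)
}

# random 0/1 vector
rbits <- function(n, p = 0.5) stats::rbinom(n, 1L, p)
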