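# Shared fixtures: built in code at test time, cached per session.

# Small, fast library for unit tests (full-scale runs live in the
# acceptance suite).
small_library <- local({
  cache <- new.env(parent = emptyenv())
  function(separability = 2, n_pairs = 400L, seed = 7L) {
    key <- paste(separability, n_pairs, seed, sep = "_")
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_library(generator_config(
        n_api = 20L, n_coformer = 50L, n_pairs = n_pairs,
        separability = separability, seed = seed))
    }
    cache[[key]]
  }
})

# Cleaned descriptor matrix + split for a library (single call used by
# several tests).
prepare_library <- function(lib, split_seed = 1L, test_fraction = 0.2) {
  dmat <- descriptor_matrix(lib$molecules, external = lib$descriptors)
  sp <- split_dataset(lib$pairs, test_fraction, split_seed)
  train_ids <- unique(c(sp$train$api_id, sp$train$coformer_id))
  cl <- clean_and_standardize(dmat, train_ids)
  list(lib = lib, split = sp, dmat = cl$matrix, clean = cl$report)
}

# Three-row molecule table used across molecule/descriptor tests.
example_molecules <- function() {
  molecule_table(data.frame(
    id = c("VPZ", "RES", "GAL"),
    name = c("vonoprazan", "resorcinol", "pyrogallol"),
    role = c("api", "coformer", "coformer"),
    group = c("base", "phenol", "phenol"),
    smiles = NA_character_,
    formula = c("C17H16FN3O2S", "C6H6O2", "C6H6O3"),
    pka_acid = c(NA, 9.57, 9.1),
    pka_base = c(9.4, NA, NA),
    stringsAsFactors = FALSE))
}
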