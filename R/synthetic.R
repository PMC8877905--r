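# Seeded generator of labeled API-coformer pair libraries.
#
# The generative model plants a hydrogen-bond-style complementarity
# signal: every molecule carries latent donor and acceptor strengths
# (Gamma(2, 1)) plus standard-normal nuisance factors. A pair scores
# s = donor_api * acceptor_cof + donor_cof * acceptor_api, and the
# cocrystal label is Bernoulli(logistic(separability * (s - s0))) with
# s0 the empirical score quantile that centres the expected positive
# fraction. The model pipeline never sees the latents - only noisy
# random linear mixtures of them (the "external descriptors") plus
# archetype-consistent formulas and pKa values - so classifier accuracy
# is bounded above by the Bayes accuracy of the latent rule.

# archetype formula pools (small pharmaceutically plausible molecules)
ARCHETYPE_FORMULAS <- list(
  acid = c("C7H6O2", "C4H6O4", "C5H7NO3", "C7H6O3", "C5H5NO2",
           "C2H3NO3", "C7H5NO3S", "C4H4O4", "C6H8O7"),
  phenol = c("C6H6O2", "C6H6O3", "C7H8O2", "C7H8O", "C8H10O2"),
  amide = c("C2H5NO", "C2H5NO2", "C7H7NO", "C6H6N2O", "CH4N2O", "C3H7NO"),
  base = c("C4H10N2", "C5H5N", "C6H8N2", "C5H11N", "C6H12N2"),
  api = c("C17H16FN3O2S", "C13H18N2O2", "C16H14N2O3", "C14H11ClN2O2",
          "C15H17N3O2", "C18H20FN3O")
)

# archetype pKa samplers; ranges bracket the published screening table
.sample_archetype_pka <- function(archetype, n) {
  switch(archetype,
    acid = list(pka_acid = stats::runif(n, 1.5, 5), pka_base = rep(NA_real_, n)),
    phenol = list(pka_acid = stats::runif(n, 8.5, 10.5), pka_base = rep(NA_real_, n)),
    amide = list(pka_acid = stats::runif(n, 13, 17), pka_base = rep(NA_real_, n)),
    base = list(pka_acid = rep(NA_real_, n), pka_base = stats::runif(n, 8, 11)),
    api = list(pka_acid = rep(NA_real_, n), pka_base = stats::runif(n, 8, 11))
  )
}

#' Configuration for the synthetic pair-library generator
#'
#' Defaults emulate the published training corpus scale: 1476 labeled
#' API-coformer pairs, balanced classes, separability 2.0 (pinned so
#' the Bayes accuracy of the latent rule falls in [0.90, 0.95]).
#'
#' @param n_api,n_coformer Numbers of API and coformer molecules.
#' @param n_pairs Number of distinct labeled pairs (<= n_api * n_coformer).
#' @param positive_fraction Expected fraction of positive labels, in (0, 1).
#' @param n_latent_nuisance Nuisance latent dimensions per molecule.
#' @param separability Logistic slope of the label rule (>= 0); 0 means
#'   labels carry no signal.
#' @param descriptor_noise_sd Gaussian noise on observed descriptors.
#' @param n_observed Number of observed (mixed) descriptor columns.
#' @param pka_profiles Mixture weights over coformer archetypes
#'   (`acid`, `phenol`, `amide`, `base`); normalized internally.
#' @param seed Integer seed; the library is fully reproducible from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_api = 60L, n_coformer = 150L,
                             n_pairs = 1476L, positive_fraction = 0.5,
                             n_latent_nuisance = 6L, separability = 2.0,
                             descriptor_noise_sd = 0.3, n_observed = 32L,
                             pka_profiles = c(acid = 0.45, phenol = 0.2,
                                              amide = 0.2, base = 0.15),
                             seed = 42L) {
  if (n_pairs > n_api * n_coformer) {
    stop("n_pairs exceeds n_api * n_coformer", call. = FALSE)
  }
  if (positive_fraction <= 0 || positive_fraction >= 1) {
    stop("`positive_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (separability < 0) stop("`separability` must be >= 0", call. = FALSE)
  stopifnot(all(c("acid", "phenol", "amide", "base") %in% names(pka_profiles)))
  structure(list(n_api = as.integer(n_api),
                 n_coformer = as.integer(n_coformer),
                 n_pairs = as.integer(n_pairs),
                 positive_fraction = positive_fraction,
                 n_latent_nuisance = as.integer(n_latent_nuisance),
                 separability = separability,
                 descriptor_noise_sd = descriptor_noise_sd,
                 n_observed = as.integer(n_observed),
                 pka_profiles = pka_profiles / sum(pka_profiles),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Sample molecules of the given archetypes with latents and identities.
.sample_molecules <- function(ids, names_prefix, role, archetypes, config) {
  n <- length(ids)
  donor <- stats::rgamma(n, 2, 1)
  acceptor <- stats::rgamma(n, 2, 1)
  nuis <- matrix(stats::rnorm(n * config$n_latent_nuisance), n,
                 config$n_latent_nuisance)
  formula <- vapply(archetypes, function(a) {
    sample(ARCHETYPE_FORMULAS[[a]], 1L)
  }, character(1))
  pka_acid <- numeric(n); pka_base <- numeric(n)
  for (a in unique(archetypes)) {
    idx <- which(archetypes == a)
    pk <- .sample_archetype_pka(a, length(idx))
    pka_acid[idx] <- pk$pka_acid
    pka_base[idx] <- pk$pka_base
  }
  mol <- molecule_table(data.frame(
    id = ids, name = paste0(names_prefix, seq_len(n)), role = role,
    group = archetypes, smiles = NA_character_, formula = formula,
    pka_acid = pka_acid, pka_base = pka_base, stringsAsFactors = FALSE))
  latents <- cbind(donor = donor, acceptor = acceptor, nuis)
  colnames(latents) <- c("donor", "acceptor",
                         paste0("nuisance_", seq_len(config$n_latent_nuisance)))
  rownames(latents) <- ids
  list(molecules = mol, latents = latents)
}

# Empirical score quantile fixing the expected positive fraction.
# Computed on the library's own pair scores: molecules are reused across
# pairs, so thresholding an independent population sample would leave a
# library-level offset in the realized label fraction.
.score_threshold <- function(scores, positive_fraction) {
  unname(stats::quantile(scores, probs = 1 - positive_fraction))
}

.pair_score <- function(lat_api, lat_cof) {
  lat_api[, "donor"] * lat_cof[, "acceptor"] +
    lat_cof[, "donor"] * lat_api[, "acceptor"]
}

#' Generate a labeled synthetic pair library
#'
#' Fully reproducible from `config$seed`. The returned object bundles
#' the molecule table, external (mixed, noisy) descriptor table, the
#' labeled pair table, and - hidden from the modelling pipeline, for
#' oracle use only - the latent donor/acceptor/nuisance matrix, the
#' score threshold `s0` and the mixing matrix.
#'
#' @param config A `generator_config`.
#' @return An object of class `pair_library`.
#' @export
generate_library <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    api_ids <- sprintf("API%03d", seq_len(config$n_api))
    cof_ids <- sprintf("CF%03d", seq_len(config$n_coformer))
    arch_names <- names(config$pka_profiles)
    cof_arch <- sample(arch_names, config$n_coformer, replace = TRUE,
                       prob = config$pka_profiles)
    # guarantee every archetype is represented
    for (i in seq_along(arch_names)) {
      if (!arch_names[i] %in% cof_arch) cof_arch[i] <- arch_names[i]
    }
    apis <- .sample_molecules(api_ids, "Api-", "api",
                              rep("api", config$n_api), config)
    cofs <- .sample_molecules(cof_ids, "Coformer-", "coformer",
                              cof_arch, config)
    molecules <- molecule_table(rbind(as.data.frame(apis$molecules),
                                      as.data.frame(cofs$molecules)))
    latents <- rbind(apis$latents, cofs$latents)

    # observed descriptors: fixed random linear mixing + noise
    d_latent <- ncol(latents)
    mixing <- matrix(stats::rnorm(d_latent * config$n_observed,
                                  0, 1 / sqrt(d_latent)),
                     d_latent, config$n_observed)
    obs <- latents %*% mixing +
      matrix(stats::rnorm(nrow(latents) * config$n_observed,
                          0, config$descriptor_noise_sd),
             nrow(latents), config$n_observed)
    colnames(obs) <- sprintf("d%02d", seq_len(config$n_observed))
    descriptors <- data.frame(id = rownames(obs), obs,
                              stringsAsFactors = FALSE, row.names = NULL)

    combo <- sample.int(config$n_api * config$n_coformer, config$n_pairs)
    ai <- ((combo - 1L) %% config$n_api) + 1L
    ci <- ((combo - 1L) %/% config$n_api) + 1L
    s <- .pair_score(latents[api_ids[ai], , drop = FALSE],
                     latents[cof_ids[ci], , drop = FALSE])
    s0 <- .score_threshold(s, config$positive_fraction)
    p <- stats::plogis(config$separability * (s - s0))
    label <- stats::rbinom(config$n_pairs, 1L, p)
    pairs <- pair_table(data.frame(api_id = api_ids[ai],
                                   coformer_id = cof_ids[ci],
                                   label = label, stringsAsFactors = FALSE))

    structure(list(molecules = molecules, descriptors = descriptors,
                   pairs = pairs, latents = latents, mixing = mixing,
                   s0 = s0, config = config),
              class = "pair_library")
  })
}

#' @export
print.pair_library <- function(x, ...) {
  cat("Synthetic cocrystal pair library\n")
  cat(sprintf("  %d APIs x %d coformers, %d labeled pairs (%d positive)\n",
              x$config$n_api, x$config$n_coformer, nrow(x$pairs),
              sum(x$pairs$label)))
  cat(sprintf("  separability %.2f, seed %d\n",
              x$config$separability, x$config$seed))
  invisible(x)
}

#' Bayes accuracy of the generator's latent rule
#'
#' Monte-Carlo accuracy of the Bayes-optimal classifier (threshold the
#' true label probability at 0.5) on freshly generated pairs from the
#' library's configuration - the ceiling no trained model can beat
#' except by chance.
#'
#' @param library A `pair_library` (latents must be present).
#' @param n_eval Number of fresh pairs to simulate.
#' @param seed Seed for the evaluation draw (defaults to the library
#'   seed + 1).
#' @return Estimated Bayes accuracy in [0, 1].
#' @export
bayes_accuracy <- function(library, n_eval = 1e5,
                           seed = library$config$seed + 1L) {
  stopifnot(inherits(library, "pair_library"))
  if (is.null(library$latents) || is.null(library$s0)) {
    stop("library lacks latent annotations", call. = FALSE)
  }
  cfg <- library$config
  with_seed(seed, {
    s <- stats::rgamma(n_eval, 2, 1) * stats::rgamma(n_eval, 2, 1) +
      stats::rgamma(n_eval, 2, 1) * stats::rgamma(n_eval, 2, 1)
    p <- stats::plogis(cfg$separability * (s - library$s0))
    label <- stats::rbinom(n_eval, 1L, p)
    pred <- as.integer(p >= 0.5)
    mean(pred == label)
  })
}

#' Generate an unlabeled screening panel with hidden truth
#'
#' Emulates a prospective coformer screen: one new API plus `n_panel`
#' coformers spanning all archetypes (at least one of each), with
#' observed descriptors produced by the library's frozen mixing matrix.
#' The true labels, drawn from the same latent rule, are returned in a
#' separate `truth` table and never enter the panel tables.
#'
#' @param library A `pair_library` (provides the mixing matrix, score
#'   threshold and configuration).
#' @param n_panel Number of coformers in the panel.
#' @param seed Seed for the panel draw (defaults to library seed + 2).
#' @return List with `api` (single-row molecule table), `molecules`
#'   (panel coformers), `descriptors` (API + coformers), and `truth`
#'   (data.frame coformer_id, p_true, label).
#' @export
generate_screening_panel <- function(library, n_panel = 51L,
                                     seed = library$config$seed + 2L) {
  stopifnot(inherits(library, "pair_library"))
  if (n_panel < 1L) stop("`n_panel` must be >= 1", call. = FALSE)
  cfg <- library$config
  with_seed(seed, {
    arch_names <- names(cfg$pka_profiles)
    arch <- sample(arch_names, n_panel, replace = TRUE,
                   prob = cfg$pka_profiles)
    for (i in seq_along(arch_names)) {
      if (i <= n_panel && !arch_names[i] %in% arch) arch[i] <- arch_names[i]
    }
    api <- .sample_molecules("PANAPI", "PanelApi-", "api", "api", cfg)
    cofs <- .sample_molecules(sprintf("PAN%03d", seq_len(n_panel)),
                              "Panel-", "coformer", arch, cfg)
    latents <- rbind(api$latents, cofs$latents)
    obs <- latents %*% library$mixing +
      matrix(stats::rnorm(nrow(latents) * cfg$n_observed,
                          0, cfg$descriptor_noise_sd),
             nrow(latents), cfg$n_observed)
    colnames(obs) <- sprintf("d%02d", seq_len(cfg$n_observed))
    descriptors <- data.frame(id = rownames(obs), obs,
                              stringsAsFactors = FALSE, row.names = NULL)

    s <- .pair_score(latents[rep("PANAPI", n_panel), , drop = FALSE],
                     cofs$latents)
    p <- stats::plogis(cfg$separability * (s - library$s0))
    label <- stats::rbinom(n_panel, 1L, p)
    truth <- data.frame(coformer_id = cofs$molecules$id, p_true = p,
                        label = label, stringsAsFactors = FALSE)
    list(api = api$molecules, molecules = cofs$molecules,
         descriptors = descriptors, truth = truth)
  })
}

#' Write a pair library to CSV files
#'
#' Writes `molecules.csv`, `descriptors.csv` and `pairs.csv` (the files
#' the modelling pipeline consumes), the hidden truth as
#' `latents.truth.csv`, and a `manifest.json` recording the
#' configuration, seed and score threshold. Identical configurations
#' produce byte-identical trees.
#'
#' @param library A `pair_library`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_library <- function(library, dir) {
  stopifnot(inherits(library, "pair_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_molecule_table(library$molecules, file.path(dir, "molecules.csv"))
  utils::write.csv(library$descriptors, file.path(dir, "descriptors.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(as.data.frame(library$pairs), file.path(dir, "pairs.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  lat <- data.frame(id = rownames(library$latents), library$latents,
                    stringsAsFactors = FALSE, row.names = NULL)
  utils::write.csv(lat, file.path(dir, "latents.truth.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  cfg <- unclass(library$config)
  cfg$pka_profiles <- as.list(cfg$pka_profiles)
  jsonlite::write_json(
    list(config = cfg, s0 = library$s0,
         config_hash = config_hash(cfg)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a pair library back from CSV files
#'
#' Restores a library written by [write_library()], including the
#' hidden-truth latents if present.
#'
#' @param dir Directory written by [write_library()].
#' @return A `pair_library` (without the mixing matrix, which is not
#'   serialized; regenerate from the manifest config when needed).
#' @export
read_library <- function(dir) {
  molecules <- read_molecule_table(file.path(dir, "molecules.csv"))
  descriptors <- utils::read.csv(file.path(dir, "descriptors.csv"),
                                 stringsAsFactors = FALSE,
                                 fileEncoding = "UTF-8")
  pairs <- read_pair_table(file.path(dir, "pairs.csv"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  lat_path <- file.path(dir, "latents.truth.csv")
  latents <- NULL
  if (file.exists(lat_path)) {
    lt <- utils::read.csv(lat_path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    latents <- as.matrix(lt[, -1L, drop = FALSE])
    rownames(latents) <- lt$id
  }
  cfg <- manifest$config
  config <- generator_config(cfg$n_api, cfg$n_coformer, cfg$n_pairs,
                             cfg$positive_fraction, cfg$n_latent_nuisance,
                             cfg$separability, cfg$descriptor_noise_sd,
                             cfg$n_observed, unlist(cfg$pka_profiles),
                             cfg$seed)
  structure(list(molecules = molecules, descriptors = descriptors,
                 pairs = pairs, latents = latents, mixing = NULL,
                 s0 = manifest$s0, config = config),
            class = "pair_library")
}
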