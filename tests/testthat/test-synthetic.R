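# Synthetic pair-library generator: determinism, calibration, oracle.

test_that("the same seed reproduces a byte-identical library tree", {
  cfg <- generator_config(n_api = 15L, n_coformer = 40L, n_pairs = 200L,
                          seed = 31L)
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  write_library(generate_library(cfg), d1)
  write_library(generate_library(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), info = f)
  }
  # and a different seed changes the pairs
  cfg2 <- generator_config(n_api = 15L, n_coformer = 40L, n_pairs = 200L,
                           seed = 32L)
  expect_false(identical(generate_library(cfg2)$pairs$label,
                         generate_library(cfg)$pairs$label))
})

test_that("libraries respect their configuration and validate structurally", {
  lib <- small_library()
  cfg <- lib$config
  expect_equal(nrow(lib$pairs), cfg$n_pairs)
  expect_equal(nrow(lib$molecules), cfg$n_api + cfg$n_coformer)
  expect_s3_class(lib$molecules, "molecule_table")
  expect_s3_class(lib$pairs, "pair_table")
  # every archetype represented among coformers
  cof <- lib$molecules[lib$molecules$role == "coformer", ]
  expect_setequal(unique(cof$group), c("acid", "phenol", "amide", "base"))
  # base coformers carry only a basic pKa
  expect_true(all(is.na(cof$pka_acid[cof$group == "base"])))
  expect_true(all(!is.na(cof$pka_base[cof$group == "base"])))
  expect_true(all(!is.na(cof$pka_acid[cof$group != "base"])))
  # infeasible pair count rejected
  expect_error(generator_config(n_api = 3, n_coformer = 4, n_pairs = 20),
               "exceeds")
})

test_that("generated positive fraction is calibrated to the configured value", {
  # binomial bound over 20 seeds at reduced pair count
  n <- 400L
  p <- 0.5
  bound <- 3 * sqrt(n * p * (1 - p))  # ~30 pairs
  for (seed in 1:20) {
    lib <- generate_library(generator_config(
      n_api = 20L, n_coformer = 50L, n_pairs = n, seed = seed))
    expect_lt(abs(sum(lib$pairs$label) - n * p), bound)
  }
})

test_that("Bayes accuracy hits the no-signal and deterministic limits and is monotone", {
  libs <- lapply(c(0, 0.5, 1, 2, 4, 50), function(s)
    small_library(separability = s, n_pairs = 50L))
  acc <- vapply(libs, bayes_accuracy, numeric(1), n_eval = 1e5)
  expect_equal(acc[1], 0.5, tolerance = 0.02)   # no signal
  expect_gte(acc[6], 0.99)                      # near-deterministic labels
  expect_true(all(diff(acc) >= -0.005))         # monotone up to MC noise
})

test_that("at zero separability labels are independent of the descriptors", {
  lib <- small_library(separability = 0, n_pairs = 1000L)
  pr <- prepare_library(lib)
  m <- train_classifier(pr$split$train, pr$dmat,
                        model_config("random_forest", seed = 1))
  acc <- evaluate(m, pr$split$test, pr$dmat)$accuracy
  expect_lt(abs(acc - 0.5), 0.07)
})

test_that("screening panels span all archetypes and carry hidden truth separately", {
  lib <- small_library()
  panel <- generate_screening_panel(lib, n_panel = 51L)
  expect_equal(nrow(panel$molecules), 51L)
  expect_setequal(unique(panel$molecules$group),
                  c("acid", "phenol", "amide", "base"))
  base_rows <- panel$molecules$group == "base"
  expect_true(all(is.na(panel$molecules$pka_acid[base_rows])))
  expect_equal(nrow(panel$truth), 51L)
  expect_true(all(panel$truth$label %in% 0:1))
  # the panel tables themselves never contain the truth columns
  expect_false(any(c("label", "p_true") %in% names(panel$molecules)))
  expect_error(generate_screening_panel(lib, n_panel = 0L), "n_panel")
})

test_that("a library round-trips through its CSV directory", {
  lib <- small_library(n_pairs = 150L)
  dir <- withr::local_tempdir()
  write_library(lib, dir)
  back <- read_library(dir)
  expect_equal(as.data.frame(back$pairs), as.data.frame(lib$pairs))
  expect_equal(as.data.frame(back$molecules), as.data.frame(lib$molecules),
               tolerance = 1e-12)
  expect_equal(back$s0, lib$s0, tolerance = 1e-12)
  expect_equal(back$latents, lib$latents, tolerance = 1e-12)
  expect_equal(back$config$separability, lib$config$separability)
})
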