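# Formula-level descriptors and matrix cleaning/standardization.

test_that("degree of unsaturation follows the ring-and-double-bond formula", {
  dbe <- function(f) {
    formula_descriptors(list(formula = f, pka_acid = NA, pka_base = NA))[["dbe"]]
  }
  expect_equal(dbe("H2O"), 0)        # saturated, acyclic
  expect_equal(dbe("C6H6"), 4)       # benzene: ring + 3 double bonds
  expect_equal(dbe("C17H16FN3O2S"), 11)
  expect_equal(dbe("C6H6O2"), 4)
})

test_that("descriptor vector has the documented schema and encodes absent pKa", {
  mols <- example_molecules()
  v <- formula_descriptors(mols[1, ])  # API: basic only
  expect_named(v, coscreen:::FORMULA_DESCRIPTOR_NAMES)
  expect_equal(v[["pka_acid"]], 0)
  expect_equal(v[["pka_acid_present"]], 0)
  expect_equal(v[["pka_base"]], 9.4)
  expect_equal(v[["pka_base_present"]], 1)
  expect_equal(v[["n_halogen"]], 1)
  expect_equal(v[["n_NO"]], 5)

  # pure function: identical input -> identical vector
  expect_identical(v, formula_descriptors(mols[1, ]))
})

test_that("external descriptor tables merge by id with strict coverage", {
  mols <- example_molecules()
  ext <- data.frame(id = c("VPZ", "RES", "GAL"),
                    a = c(1, 2, 3), b = c(0.5, -0.5, 0))
  m <- descriptor_matrix(mols, external = ext)
  expect_equal(dim(m), c(3L, 16L + 2L))
  expect_true(all(c("ext_a", "ext_b") %in% colnames(m)))
  expect_equal(m["RES", "ext_a"], 2)

  expect_error(attach_external_descriptors(mols, ext[-2, ]), "RES")
  ext_bad <- rbind(ext, data.frame(id = "XXX", a = 1, b = 1))
  expect_error(attach_external_descriptors(mols, ext_bad), "XXX")

  ext$b <- c("0.5", "oops", "0")
  expect_warning(m2 <- attach_external_descriptors(mols, ext), "ext_b|b")
  expect_false("ext_b" %in% colnames(m2))
  expect_true("ext_a" %in% colnames(m2))
})

test_that("cleaning drops non-finite and constant columns and z-scores on train rows", {
  set.seed(11)
  m <- cbind(good1 = rnorm(10), good2 = runif(10),
             const = rep(3, 10), withna = c(NA, rnorm(9)))
  rownames(m) <- paste0("M", 1:10)
  train <- paste0("M", 1:6)
  out <- clean_and_standardize(m, train)

  expect_setequal(out$report$kept, c("good1", "good2"))
  expect_equal(out$report$dropped_constant, "const")
  expect_equal(out$report$dropped_nonfinite, "withna")
  # train-row moments after transform
  expect_equal(colMeans(out$matrix[train, ]), c(good1 = 0, good2 = 0),
               tolerance = 1e-9)
  expect_equal(apply(out$matrix[train, ], 2, sd), c(good1 = 1, good2 = 1),
               tolerance = 1e-9)

  # idempotent up to the variance tolerance
  again <- clean_and_standardize(out$matrix, train)
  expect_equal(length(again$report$dropped_constant), 0L)
  expect_equal(length(again$report$dropped_nonfinite), 0L)

  # all-dropped input errors
  expect_error(clean_and_standardize(m[, c("const", "withna")], train),
               "dropped")
})

test_that("the fitted transform depends only on training rows", {
  set.seed(12)
  m <- matrix(rnorm(60), 12, 5,
              dimnames = list(paste0("M", 1:12), paste0("d", 1:5)))
  train <- paste0("M", 1:6)
  ref <- clean_and_standardize(m, train)
  perm <- m[c(train, sample(paste0("M", 7:12))), ]
  out <- clean_and_standardize(perm, train)
  expect_equal(out$report$center, ref$report$center)
  expect_equal(out$report$scale, ref$report$scale)
  # and apply_cleaning replays the frozen transform on new rows
  expect_equal(apply_cleaning(ref$report, m), ref$matrix)
})
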