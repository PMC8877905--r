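# Delta-pKa rule: computation, boundaries, reference-table regression.

test_that("delta-pKa is pKa(base) minus pKa(acid)", {
  expect_equal(delta_pka(9.4, 9.64), -0.24)
  expect_equal(delta_pka(9.4, 9.4), 0)
  expect_equal(delta_pka(9.4, 3.86), 5.54)
  expect_error(delta_pka(NA, 3), "both")
})

test_that("classification thresholds assign closed boundaries to the definite classes", {
  expect_equal(classify_delta(-0.24), "cocrystal")
  expect_equal(classify_delta(0.3), "continuum")
  expect_equal(classify_delta(0), "cocrystal")
  expect_equal(classify_delta(3), "salt")
  expect_equal(classify_delta(5.54), "salt")
  expect_error(classify_delta(NaN), "finite")
})

test_that("category is a monotone step function of delta", {
  set.seed(99)
  d <- sort(runif(1e6, -12, 12))
  lv <- c(cocrystal = 1L, continuum = 2L, salt = 3L)
  codes <- lv[classify_delta(d)]
  expect_true(all(diff(codes) >= 0L))
  # boundaries appear exactly at 0 and 3
  expect_equal(classify_delta(c(-1e-12, 1e-12, 3 - 1e-12, 3 + 1e-12)),
               c("cocrystal", "continuum", "continuum", "salt"))
})

test_that("the published vonoprazan screen is reproduced row-by-row", {
  tab <- vpz_coformer_table()
  expect_equal(nrow(tab), 19L)
  api <- list(id = "VPZ", pka_base = 9.4)
  for (i in seq_len(nrow(tab))) {
    cf <- list(id = tab$name[i], pka_acid = tab$pka_acid[i])
    res <- classify_pair(api, cf)
    if (is.na(tab$pka_acid[i])) {
      expect_equal(res$category, "not_applicable", info = tab$name[i])
      expect_true(is.na(res$delta))
    } else {
      expect_equal(res$delta, tab$delta_pka_reported[i], tolerance = 0.011,
                   info = tab$name[i])
      expect_equal(res$category, tab$prediction_reported[i],
                   info = tab$name[i])
    }
  }
})

test_that("classify_pair handles absent pKa and agrees with classify_delta", {
  api <- list(id = "VPZ", pka_base = 9.4)
  res <- classify_pair(api, list(id = "piperazine", pka_acid = NA))
  expect_equal(res$category, "not_applicable")

  expect_error(classify_pair(list(id = "X", pka_base = NA),
                             list(id = "Y", pka_acid = 4)), "pka_base")

  set.seed(7)
  for (pka in runif(20, -5, 20)) {
    res <- classify_pair(api, list(id = "cf", pka_acid = pka))
    expect_equal(res$category, classify_delta(delta_pka(9.4, pka)))
  }
})

test_that("dpka_screen emits the conventional screening-table columns", {
  mols <- example_molecules()
  out <- dpka_screen(mols[1, ], mols[2:3, ])
  expect_equal(names(out), c("coformer_id", "name", "group", "pka_acid",
                             "delta_pka", "prediction"))
  expect_equal(out$delta_pka, c(9.4 - 9.57, 9.4 - 9.1))
  expect_equal(out$prediction, c("cocrystal", "continuum"))
})
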