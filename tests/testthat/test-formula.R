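# Molecular formula parsing, molar mass and stoichiometry.

test_that("formulas parse to element counts, including groups and hydrates", {
  expect_equal(unclass(parse_formula("H2O")), c(H = 2L, O = 1L))
  expect_equal(unclass(parse_formula("C17H16FN3O2S")),
               c(C = 17L, H = 16L, F = 1L, N = 3L, O = 2L, S = 1L))
  expect_equal(unclass(parse_formula("C6H6O2")), c(C = 6L, H = 6L, O = 2L))
  # parenthesized groups with multiplier
  expect_equal(unclass(parse_formula("C(CH3)4")), c(C = 5L, H = 12L))
  expect_equal(unclass(parse_formula("K2(SO4)")), c(K = 2L, S = 1L, O = 4L))
  # hydrate suffix, both middle-dot and ASCII period
  expect_equal(unclass(parse_formula("C4H4O4·2H2O")),
               c(C = 4L, H = 8L, O = 6L))
  expect_equal(unclass(parse_formula("C4H4O4.H2O")),
               c(C = 4L, H = 6L, O = 5L))
})

test_that("malformed or unsupported formulas fail with the offending token", {
  expect_error(parse_formula("CaSO4"), "Ca")
  expect_error(parse_formula("C6H6O2)"), "unexpected token")
  expect_error(parse_formula("(C6H6O2"), "unbalanced")
  expect_error(parse_formula(""), "non-empty")
  expect_error(parse_formula("c6h6"), "unexpected token")
})

test_that("molar masses match the pinned atomic weight table", {
  expect_equal(molar_mass("H2O"), 18.02)
  expect_equal(molar_mass("C6H6O2"), 110.11)
  expect_equal(molar_mass("C6H6O3"), 126.11)
  expect_equal(molar_mass("C17H16FN3O2S"), 345.39)
})

test_that("molar mass is additive over merged element counts", {
  a <- parse_formula("C6H6O2")
  b <- parse_formula("C17H16FN3O2S")
  merged <- coscreen:::.merge_counts(a, b)
  expect_equal(coscreen:::.molar_mass_exact(merged),
               coscreen:::.molar_mass_exact(a) + coscreen:::.molar_mass_exact(b))
})

test_that("batch masses reproduce reaction-crystallization amounts", {
  # resorcinol, 10 mmol -> ~1.1 g; pyrogallol 10 mmol -> ~1.26 g;
  # vonoprazan 5 mmol -> ~1.73 g, 1 mmol -> ~345 mg
  expect_equal(mass_for_amount("C6H6O2", 10), 1.10112, tolerance = 1e-8)
  expect_equal(mass_for_amount("C6H6O3", 10, signif_digits = 3), 1.26)
  expect_equal(mass_for_amount("C17H16FN3O2S", 5, signif_digits = 3), 1.73)
  expect_equal(round(mass_for_amount("C17H16FN3O2S", 1) * 1000), 345)
  expect_equal(mass_for_amount("C6H6O2", 0), 0)
  expect_error(mass_for_amount("C6H6O2", -1), "non-negative")
})

test_that("mass is linear in amount", {
  for (f in c("H2O", "C6H6O2", "C17H16FN3O2S")) {
    x <- mass_for_amount(f, 3.7)
    expect_equal(mass_for_amount(f, 7.4), 2 * x, tolerance = 1e-12)
  }
})

test_that("batch_spec tabulates formula, amount and mass", {
  bs <- batch_spec(c("C6H6O2", "C17H16FN3O2S"), c(10, 5))
  expect_equal(names(bs), c("formula", "mmol", "g"))
  expect_equal(bs$g, c(1.10112, 1.726960), tolerance = 1e-6)
})
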