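# Molecular-formula chemistry: parsing, molar mass, batch stoichiometry.

# IUPAC standard atomic weights, pinned (3 decimals or the IUPAC
# abridged value where the standard weight is an interval).
ATOMIC_WEIGHTS <- c(
  C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06,
  F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904, P = 30.974,
  Na = 22.990, K = 39.098
)

HALOGENS <- c("F", "Cl", "Br", "I")

#' Parse a molecular formula into element counts
#'
#' Accepts Hill-notation formulas over the supported element set
#' (C, H, N, O, S, F, Cl, Br, I, P, Na, K) with optional integer counts,
#' parenthesized groups with a trailing multiplier, and a hydrate suffix
#' written as `"·nH2O"` (an ASCII `"."` is accepted in place of the
#' middle dot). Isotopes and charges are not part of the grammar.
#'
#' @param formula A single formula string, e.g. `"C17H16FN3O2S"` or
#'   `"CuSO4·5H2O"` (copper is not supported; shown for syntax only).
#' @return A named integer vector of element counts (class
#'   `"element_counts"`), names drawn from the supported element set.
#' @examples
#' parse_formula("H2O")
#' parse_formula("C6H6O2")         # resorcinol / catechol / hydroquinone
#' parse_formula("C17H16FN3O2S")   # vonoprazan free base
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(trimws(formula))) {
    stop("`formula` must be a single non-empty string", call. = FALSE)
  }
  s <- trimws(formula)
  s <- gsub("\u00b7|\u22c5", ".", s)  # middle-dot variants -> '.'

  # split off a hydrate suffix ".nH2O"
  hydrate <- 0L
  hm <- regmatches(s, regexec("^(.*)\\.([0-9]*)H2O$", s))[[1]]
  if (length(hm) == 3L) {
    s <- hm[2]
    hydrate <- if (nzchar(hm[3])) as.integer(hm[3]) else 1L
    if (!nzchar(s)) stop("malformed formula: hydrate suffix with no parent in '",
                         formula, "'", call. = FALSE)
  } else if (grepl(".", s, fixed = TRUE)) {
    stop("malformed formula '", formula,
         "': only a '·nH2O' hydrate suffix is supported after '·'",
         call. = FALSE)
  }

  counts <- .parse_formula_group(s, formula)
  if (hydrate > 0L) {
    counts <- .merge_counts(counts, c(H = 2L * hydrate, O = hydrate))
  }
  structure(counts, class = "element_counts")
}

# Recursive-descent parse of a (sub)formula with no hydrate suffix.
.parse_formula_group <- function(s, original) {
  counts <- integer(0)
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "(") {
      depth <- 1L
      j <- i
      while (depth > 0L) {
        j <- j + 1L
        if (j > n) stop("malformed formula '", original,
                        "': unbalanced '('", call. = FALSE)
        cj <- substr(s, j, j)
        if (cj == "(") depth <- depth + 1L
        if (cj == ")") depth <- depth - 1L
      }
      inner <- .parse_formula_group(substr(s, i + 1L, j - 1L), original)
      i <- j + 1L
      mult <- .take_count(s, i)
      inner <- inner * mult$count
      counts <- .merge_counts(counts, inner)
      i <- mult$i
    } else if (grepl("^[A-Z]$", ch)) {
      sym <- ch
      if (i < n && grepl("^[a-z]$", substr(s, i + 1L, i + 1L))) {
        sym <- substr(s, i, i + 1L)
        i <- i + 1L
      }
      if (!sym %in% names(ATOMIC_WEIGHTS)) {
        stop("unsupported element '", sym, "' in formula '", original, "'",
             call. = FALSE)
      }
      i <- i + 1L
      cnt <- .take_count(s, i)
      add <- stats::setNames(cnt$count, sym)
      counts <- .merge_counts(counts, add)
      i <- cnt$i
    } else {
      stop("malformed formula '", original, "': unexpected token '", ch, "'",
           call. = FALSE)
    }
  }
  if (length(counts) == 0L) {
    stop("malformed formula '", original, "': empty group", call. = FALSE)
  }
  counts
}

.take_count <- function(s, i) {
  m <- regmatches(substr(s, i, nchar(s)),
                  regexpr("^[0-9]+", substr(s, i, nchar(s))))
  if (length(m) == 1L && nzchar(m)) {
    cnt <- as.integer(m)
    if (cnt < 1L) stop("malformed formula: zero count", call. = FALSE)
    list(count = cnt, i = i + nchar(m))
  } else {
    list(count = 1L, i = i)
  }
}

.merge_counts <- function(a, b) {
  for (sym in names(b)) {
    if (sym %in% names(a)) a[[sym]] <- a[[sym]] + b[[sym]] else a[[sym]] <- b[[sym]]
  }
  a
}

#' Molar mass of a formula or element-count vector
#'
#' Sums pinned standard atomic weights over the element counts. The value
#' is reported to two decimal places (g/mol), the precision of the
#' internal weight table.
#'
#' @param x An `element_counts` vector from [parse_formula()], or a
#'   formula string which is parsed first.
#' @return Molar mass in g/mol, rounded to 2 decimals.
#' @examples
#' molar_mass("H2O")            # 18.02
#' molar_mass("C17H16FN3O2S")   # 345.39 (vonoprazan)
#' @export
molar_mass <- function(x) {
  round(.molar_mass_exact(x), 2)
}

.molar_mass_exact <- function(x) {
  if (is.character(x)) x <- parse_formula(x)
  syms <- names(x)
  missing <- setdiff(syms, names(ATOMIC_WEIGHTS))
  if (length(missing) > 0L) {
    stop("no atomic weight for element(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sum(ATOMIC_WEIGHTS[syms] * as.numeric(x))
}

#' Mass required for a molar amount
#'
#' Converts a molar amount in mmol into grams of substance using the
#' unrounded molar mass, e.g. for weighing out a reaction-crystallization
#' batch. Display rounding is the caller's choice via `signif_digits`.
#'
#' @param formula Molecular formula string.
#' @param amount_mmol Amount of substance in mmol (must be >= 0).
#' @param signif_digits Optional number of significant digits for the
#'   returned value; `NULL` (default) returns the unrounded mass.
#' @return Mass in grams.
#' @examples
#' mass_for_amount("C6H6O2", 10)            # 1.10112 g of resorcinol
#' mass_for_amount("C17H16FN3O2S", 5, 3)    # 1.73 g of vonoprazan
#' @export
mass_for_amount <- function(formula, amount_mmol, signif_digits = NULL) {
  if (!is.numeric(amount_mmol) || length(amount_mmol) != 1L ||
      is.na(amount_mmol) || amount_mmol < 0) {
    stop("`amount_mmol` must be a single non-negative number", call. = FALSE)
  }
  g <- .molar_mass_exact(formula) * amount_mmol / 1000
  if (!is.null(signif_digits)) g <- signif(g, signif_digits)
  g
}

#' Batch stoichiometry table
#'
#' Computes the mass in grams for each (formula, mmol) row, the report
#' used when weighing out components for a synthesis batch.
#'
#' @param formula Character vector of molecular formulas.
#' @param amount_mmol Numeric vector of amounts in mmol (recycled if
#'   length 1).
#' @return A data.frame with columns `formula`, `mmol`, `g`.
#' @export
batch_spec <- function(formula, amount_mmol) {
  n <- max(length(formula), length(amount_mmol))
  formula <- rep_len(formula, n)
  amount_mmol <- rep_len(amount_mmol, n)
  g <- vapply(seq_len(n), function(i) {
    mass_for_amount(formula[i], amount_mmol[i])
  }, numeric(1))
  data.frame(formula = formula, mmol = amount_mmol, g = g,
             stringsAsFactors = FALSE)
}
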