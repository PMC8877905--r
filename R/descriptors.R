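# Per-molecule numeric descriptors and matrix cleaning/standardization.
#
# The built-in set is deliberately formula-derivable only, so the core
# pipeline runs without any structure-perception engine; richer
# topological/electronic descriptors (e.g. a Mordred export) enter via
# the external-table adapter and are treated identically downstream.

FORMULA_DESCRIPTOR_NAMES <- c(
  "molar_mass", "n_C", "n_H", "n_N", "n_O", "n_S", "n_halogen",
  "hetero_fraction", "n_NO", "dbe", "n_heavy", "h_per_heavy",
  "pka_acid", "pka_acid_present", "pka_base", "pka_base_present"
)

#' Formula-level descriptors for one molecule
#'
#' Computes the built-in descriptor set from the molecular formula and
#' the pKa fields: molar mass; C/H/N/O/S/halogen counts; heteroatom
#' fraction; N+O count (hydrogen-bond-acceptor proxy); degree of
#' unsaturation (DBE = C + 1 + (N - H - X)/2, halogens X counted like
#' H); heavy-atom count; H-per-heavy-atom ratio; and the two pKa
#' channels. An absent pKa is encoded as a (0, 0) value/presence pair
#' rather than imputed, because absence is chemically informative (e.g.
#' no acidic proton at all).
#'
#' @param molecule A single-row `molecule_table`, or a list with fields
#'   `formula` and optionally `pka_acid`, `pka_base`.
#' @return Named numeric vector of length 16 (14 descriptors, the two
#'   pKa channels carrying an extra presence flag each).
#' @export
formula_descriptors <- function(molecule) {
  counts <- parse_formula(molecule$formula)
  g <- function(sym) if (sym %in% names(counts)) as.numeric(counts[[sym]]) else 0
  n_c <- g("C"); n_h <- g("H"); n_n <- g("N"); n_o <- g("O"); n_s <- g("S")
  n_x <- sum(vapply(HALOGENS, g, numeric(1)))
  total <- sum(as.numeric(counts))
  n_heavy <- total - n_h
  hetero <- total - n_c - n_h
  dbe <- n_c + 1 + (n_n - n_h - n_x) / 2

  pka_a <- molecule$pka_acid
  pka_b <- molecule$pka_base
  pka_a <- if (is.null(pka_a) || is.na(pka_a)) NA_real_ else as.numeric(pka_a)
  pka_b <- if (is.null(pka_b) || is.na(pka_b)) NA_real_ else as.numeric(pka_b)

  v <- c(
    molar_mass = .molar_mass_exact(counts),
    n_C = n_c, n_H = n_h, n_N = n_n, n_O = n_o, n_S = n_s, n_halogen = n_x,
    hetero_fraction = if (total > 0) hetero / total else 0,
    n_NO = n_n + n_o,
    dbe = dbe,
    n_heavy = n_heavy,
    h_per_heavy = if (n_heavy > 0) n_h / n_heavy else 0,
    pka_acid = if (is.na(pka_a)) 0 else pka_a,
    pka_acid_present = as.numeric(!is.na(pka_a)),
    pka_base = if (is.na(pka_b)) 0 else pka_b,
    pka_base_present = as.numeric(!is.na(pka_b))
  )
  v[FORMULA_DESCRIPTOR_NAMES]
}

#' Descriptor matrix for a molecule table
#'
#' One row per molecule (rownames = molecule ids), built-in formula
#' descriptors in the leading columns, optionally merged with an
#' external descriptor table via [attach_external_descriptors()].
#'
#' @param molecules A `molecule_table`.
#' @param external Optional external descriptor data.frame or CSV path
#'   (first column = molecule id, remaining columns numeric).
#' @return Numeric matrix, rows = molecules, columns = descriptors.
#' @export
descriptor_matrix <- function(molecules, external = NULL) {
  stopifnot(inherits(molecules, "molecule_table"))
  rows <- lapply(seq_len(nrow(molecules)), function(i) {
    formula_descriptors(molecules[i, , drop = FALSE])
  })
  m <- do.call(rbind, rows)
  rownames(m) <- molecules$id
  if (!is.null(external)) m <- attach_external_descriptors(molecules, external, builtin = m)
  m
}

#' Merge an external descriptor table into the built-in matrix
#'
#' Adapter contract for descriptor generators outside this package (any
#' tool producing one numeric row per molecule, e.g. a Mordred export):
#' the table is keyed by molecule id, external column names are prefixed
#' with `"ext_"` to avoid collisions, and columns containing any
#' non-numeric cell are reported and dropped.
#'
#' @param molecules A `molecule_table`.
#' @param table Data.frame or CSV path; first column molecule id.
#' @param builtin Optional precomputed built-in matrix (internal use).
#' @return Numeric matrix of built-in + external columns.
#' @export
attach_external_descriptors <- function(molecules, table, builtin = NULL) {
  stopifnot(inherits(molecules, "molecule_table"))
  if (is.character(table) && length(table) == 1L) {
    table <- utils::read.csv(table, check.names = FALSE, colClasses = "character",
                             fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(table), ncol(table) >= 2L)
  ids <- as.character(table[[1L]])
  unknown <- setdiff(ids, molecules$id)
  if (length(unknown) > 0L) {
    stop("external descriptor table has id(s) with no molecule: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(molecules$id, ids)
  if (length(absent) > 0L) {
    stop("molecule id(s) missing from external descriptor table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate id(s) in external descriptor table", call. = FALSE)
  }

  vals <- table[, -1L, drop = FALSE]
  keep <- vapply(vals, function(col) {
    col <- normalize_minus(as.character(col))
    !anyNA(suppressWarnings(as.numeric(col)))
  }, logical(1))
  if (any(!keep)) {
    warning("dropping non-numeric external descriptor column(s): ",
            paste(names(vals)[!keep], collapse = ", "), call. = FALSE)
  }
  vals <- vals[, keep, drop = FALSE]
  if (ncol(vals) == 0L) stop("no numeric external descriptor columns", call. = FALSE)
  ext <- vapply(vals, function(col) as.numeric(normalize_minus(as.character(col))),
                numeric(nrow(vals)))
  ext <- matrix(ext, nrow = nrow(vals),
                dimnames = list(ids, paste0("ext_", names(vals))))
  ext <- ext[molecules$id, , drop = FALSE]

  if (is.null(builtin)) builtin <- descriptor_matrix(molecules)
  cbind(builtin, ext)
}

#' Clean and standardize a descriptor matrix
#'
#' Drops columns with any non-finite value, then columns whose variance
#' over the training rows is below `1e-12`, then z-scores every kept
#' column using mean and standard deviation fitted on the training rows
#' only; the same affine transform is applied to all other rows. The
#' fitted transform is returned as a `clean_report` so it can be frozen
#' inside a trained model and replayed on screening panels.
#'
#' @param m Numeric descriptor matrix (rownames = molecule ids).
#' @param train_ids Character vector of row ids to fit on.
#' @return List with elements `matrix` (transformed, kept columns only)
#'   and `report` (a `clean_report`: dropped/kept names, center, scale).
#' @export
clean_and_standardize <- function(m, train_ids) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  train_ids <- unique(as.character(train_ids))
  if (length(train_ids) == 0L) stop("`train_ids` must be non-empty", call. = FALSE)
  if (!all(train_ids %in% rownames(m))) {
    stop("train_ids not in matrix: ",
         paste(setdiff(train_ids, rownames(m)), collapse = ", "), call. = FALSE)
  }

  nonfinite <- colnames(m)[apply(m, 2, function(x) any(!is.finite(x)))]
  rest <- setdiff(colnames(m), nonfinite)
  tr <- m[train_ids, rest, drop = FALSE]
  v <- apply(tr, 2, stats::var)
  constant <- rest[is.na(v) | v < 1e-12]
  kept <- setdiff(rest, constant)
  if (length(kept) == 0L) {
    stop("all descriptor columns dropped during cleaning", call. = FALSE)
  }

  center <- colMeans(m[train_ids, kept, drop = FALSE])
  scale <- apply(m[train_ids, kept, drop = FALSE], 2, stats::sd)
  report <- structure(
    list(dropped_nonfinite = nonfinite, dropped_constant = constant,
         kept = kept, center = center, scale = scale,
         train_ids = train_ids),
    class = "clean_report"
  )
  list(matrix = apply_cleaning(report, m), report = report)
}

#' Apply a fitted cleaning transform to new rows
#'
#' @param report A `clean_report` from [clean_and_standardize()].
#' @param m Descriptor matrix containing at least the kept columns.
#' @return Transformed matrix restricted to the kept columns.
#' @export
apply_cleaning <- function(report, m) {
  stopifnot(inherits(report, "clean_report"))
  missing_cols <- setdiff(report$kept, colnames(m))
  if (length(missing_cols) > 0L) {
    stop("matrix lacks cleaned descriptor column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- m[, report$kept, drop = FALSE]
  sweep(sweep(x, 2, report$center, "-"), 2, report$scale, "/")
}

#' @export
print.clean_report <- function(x, ...) {
  cat("Descriptor cleaning report\n")
  cat("  kept:             ", length(x$kept), "columns\n")
  cat("  dropped nonfinite:", length(x$dropped_nonfinite), "\n")
  cat("  dropped constant: ", length(x$dropped_constant), "\n")
  invisible(x)
}

#' Serialize a clean report to JSON
#'
#' @param report A `clean_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clean_report <- function(report, path) {
  stopifnot(inherits(report, "clean_report"))
  jsonlite::write_json(
    list(dropped_nonfinite = report$dropped_nonfinite,
         dropped_constant = report$dropped_constant,
         kept = report$kept,
         center = as.list(report$center),
         scale = as.list(report$scale)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
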