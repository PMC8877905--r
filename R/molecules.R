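# Molecule table ingestion, validation and round-trip CSV I/O.

MOLECULE_REQUIRED <- c("id", "name", "role", "formula")
MOLECULE_OPTIONAL <- c("group", "smiles", "pka_acid", "pka_base")
MOLECULE_COLUMNS <- c("id", "name", "role", "group", "smiles", "formula",
                      "pka_acid", "pka_base")

#' Build a validated molecule table
#'
#' A molecule table holds one chemical entity per row: identity, role
#' (`"api"` or `"coformer"`), a free-text functional-group label, an
#' optional SMILES string (carried through, never interpreted), a
#' Hill-notation molecular formula, and optional acid/base pKa values
#' (most acidic proton and most basic site respectively). Validation
#' enforces unique ids, parseable formulas, legal roles and pKa values
#' within [-5, 20].
#'
#' @param df A data.frame with columns `id`, `name`, `role`, `formula`
#'   and optionally `group`, `smiles`, `pka_acid`, `pka_base`.
#' @return A data.frame of class `molecule_table` with the full column
#'   set in canonical order; missing optional fields are `NA`.
#' @export
molecule_table <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(MOLECULE_REQUIRED, names(df))
  if (length(missing_cols) > 0L) {
    stop("molecule table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(MOLECULE_OPTIONAL, names(df))) df[[col]] <- NA
  out <- df[, MOLECULE_COLUMNS]
  for (col in c("id", "name", "role", "group", "smiles", "formula")) {
    out[[col]] <- as.character(out[[col]])
    out[[col]][!is.na(out[[col]]) & !nzchar(out[[col]])] <- NA_character_
  }
  for (col in c("pka_acid", "pka_base")) {
    out[[col]] <- parse_numeric_field(out[[col]], what = col)
  }

  dup <- out$id[duplicated(out$id)]
  if (length(dup) > 0L) {
    stop("duplicate molecule id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_role <- !out$role %in% c("api", "coformer")
  if (any(bad_role)) {
    stop("invalid role for id(s) ",
         paste(out$id[bad_role], collapse = ", "),
         " (must be 'api' or 'coformer')", call. = FALSE)
  }
  for (i in seq_len(nrow(out))) {
    tryCatch(parse_formula(out$formula[i]), error = function(e) {
      stop("row '", out$id[i], "': ", conditionMessage(e), call. = FALSE)
    })
  }
  for (col in c("pka_acid", "pka_base")) {
    v <- out[[col]]
    bad <- !is.na(v) & (v < -5 | v > 20)
    if (any(bad)) {
      stop(col, " out of range [-5, 20] for id(s): ",
           paste(out$id[bad], collapse = ", "), call. = FALSE)
    }
  }
  rownames(out) <- NULL
  class(out) <- c("molecule_table", "data.frame")
  out
}

#' Read a molecule table from CSV
#'
#' CSV dialect: UTF-8, comma separated, mandatory header, `.` decimal
#' mark. Numeric pKa fields accept both the ASCII hyphen-minus and the
#' typographic minus U+2212 (as printed in many tables).
#'
#' @param path Path to the CSV file.
#' @return A `molecule_table` (see [molecule_table()]).
#' @export
read_molecule_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = TRUE,
                        fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  molecule_table(df)
}

#' Write a molecule table to CSV
#'
#' Inverse of [read_molecule_table()]: a table written and re-read
#' compares equal field-by-field.
#'
#' @param molecules A `molecule_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_molecule_table <- function(molecules, path) {
  stopifnot(inherits(molecules, "molecule_table"))
  out <- as.data.frame(molecules)
  for (col in c("pka_acid", "pka_base")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "", as.character(out[[col]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

# Fetch one molecule row by id, erroring on absence.
molecule_by_id <- function(molecules, id) {
  i <- match(id, molecules$id)
  if (is.na(i)) stop("no molecule with id '", id, "'", call. = FALSE)
  molecules[i, , drop = FALSE]
}
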