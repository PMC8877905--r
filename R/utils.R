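# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`,
#' restoring the previous RNG state afterwards so library calls never
#' perturb a caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Normalize minus signs: tables in the literature often use U+2212 rather
# than the ASCII hyphen-minus; both must parse as negative numbers.
normalize_minus <- function(x) {
  gsub("\u2212", "-", x)
}

# Parse a numeric field that may use U+2212, returning NA for blank cells.
parse_numeric_field <- function(x, what = "value", where = NULL) {
  x <- trimws(normalize_minus(as.character(x)))
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & nzchar(x) & is.na(out)
  if (any(bad)) {
    ctx <- if (is.null(where)) "" else paste0(" in ", where)
    stop(sprintf("non-numeric %s%s: %s", what, ctx,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  out[!nzchar(x) | is.na(x)] <- NA_real_
  out
}

# Stable short hash of an R object (config fingerprinting for manifests).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  # polynomial rolling hash over the deparsed text; stable across sessions
  v <- utf8ToInt(s)
  h <- 0
  for (i in seq_along(v)) h <- (h * 31 + v[i]) %% 2147483647
  sprintf("%08x", h)
}
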