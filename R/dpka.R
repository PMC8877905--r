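# Delta-pKa salt / cocrystal / continuum arbitration.
#
# For a basic API and an acidic coformer, dpKa = pKa(base) - pKa(acid)
# predicts proton transfer: dpKa >= 3 a salt, dpKa <= 0 a cocrystal,
# the open interval (0, 3) the much less predictable "salt-cocrystal
# continuum". Closed boundaries are assigned to the definite classes so
# the classification is a total step function of dpKa.

DPKA_CATEGORIES <- c("cocrystal", "continuum", "salt", "not_applicable")

#' Delta-pKa of an API-coformer pair
#'
#' @param pka_base_api Most basic site pKa of the API.
#' @param pka_acid_coformer Most acidic proton pKa of the coformer.
#' @return `pka_base_api - pka_acid_coformer` (vectorized, unrounded;
#'   round to 2 decimals for display).
#' @examples
#' delta_pka(9.4, 9.64)   # -0.24, vonoprazan-pyrocatechol
#' delta_pka(9.4, 3.86)   #  5.54, vonoprazan-succinic acid
#' @export
delta_pka <- function(pka_base_api, pka_acid_coformer) {
  if (anyNA(pka_base_api) || anyNA(pka_acid_coformer)) {
    stop("delta_pka requires both pKa values; use classify_pair() for ",
         "molecules with absent pKa", call. = FALSE)
  }
  pka_base_api - pka_acid_coformer
}

#' Classify a delta-pKa value
#'
#' @param delta Finite numeric vector of delta-pKa values.
#' @return Character vector: `"cocrystal"` (delta <= 0), `"salt"`
#'   (delta >= 3), `"continuum"` otherwise.
#' @export
classify_delta <- function(delta) {
  if (any(!is.finite(delta))) stop("`delta` must be finite", call. = FALSE)
  ifelse(delta <= 0, "cocrystal", ifelse(delta >= 3, "salt", "continuum"))
}

#' Classify one API-coformer pair by the delta-pKa rule
#'
#' The API must carry a basic pKa. A coformer with no acidic proton
#' (a pure base such as piperazine) yields category `"not_applicable"`
#' with no delta, mirroring the "-" entries of screening tables.
#'
#' @param api Single-row `molecule_table` (or list) with `pka_base`.
#' @param coformer Single-row `molecule_table` (or list), `pka_acid`
#'   optional.
#' @return Data.frame of class `delta_pka_result`: `api_id`,
#'   `coformer_id`, `delta`, `category`.
#' @export
classify_pair <- function(api, coformer) {
  pb <- api$pka_base
  if (is.null(pb) || is.na(pb)) {
    stop("API '", api$id, "' has no pka_base; the delta-pKa rule needs a ",
         "basic API", call. = FALSE)
  }
  pa <- coformer$pka_acid
  if (is.null(pa) || is.na(pa)) {
    delta <- NA_real_
    category <- "not_applicable"
  } else {
    delta <- delta_pka(pb, pa)
    category <- classify_delta(delta)
  }
  structure(data.frame(api_id = as.character(api$id),
                       coformer_id = as.character(coformer$id),
                       delta = delta, category = category,
                       stringsAsFactors = FALSE),
            class = c("delta_pka_result", "data.frame"))
}

#' Delta-pKa screen of a coformer panel
#'
#' Applies [classify_pair()] row-wise and returns a screening table in
#' the conventional column order (coformer, group, pKa, delta-pKa,
#' prediction).
#'
#' @param api Single-row `molecule_table` with `pka_base`.
#' @param coformers `molecule_table` of coformers.
#' @return Data.frame with columns `coformer_id`, `name`, `group`,
#'   `pka_acid`, `delta_pka`, `prediction`.
#' @export
dpka_screen <- function(api, coformers) {
  rows <- lapply(seq_len(nrow(coformers)), function(i) {
    cf <- coformers[i, , drop = FALSE]
    res <- classify_pair(api, cf)
    data.frame(coformer_id = cf$id, name = cf$name,
               group = cf$group, pka_acid = cf$pka_acid,
               delta_pka = res$delta, prediction = res$category,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reference coformer screen for vonoprazan
#'
#' The published 20-coformer screening table for the vonoprazan free
#' base (API basic pKa 9.4): coformer name, functional-group block,
#' ChemAxon-calculated pKa, the reported delta-pKa and salt/cocrystal
#' prediction, and the liquid-assisted-grinding outcome. Shipped as
#' plain CSV in `extdata`; used as a regression fixture for the
#' delta-pKa rule.
#'
#' @return Data.frame with columns `name`, `group`, `lag_result`,
#'   `pka_acid`, `pka_base`, `delta_pka_reported`,
#'   `prediction_reported`.
#' @export
vpz_coformer_table <- function() {
  path <- system.file("extdata", "vpz_coformers.csv", package = "coscreen")
  df <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8",
                        stringsAsFactors = FALSE)
  for (col in c("pka_acid", "pka_base", "delta_pka_reported")) {
    df[[col]] <- parse_numeric_field(df[[col]], what = col)
  }
  df
}
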