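# Ideal solubility from melting data (van't Hoff form) and ranking.
#
# ln x = -(dHfus / R) * (1/T - 1/Tmelt); x is the ideal mole-fraction
# solubility of the crystalline solid at temperature T. The heat-capacity
# correction of the full ideal-solubility equation is omitted (fusion
# enthalpy and onset temperature are the only inputs available from a
# routine DSC run), so values are comparative, not absolute.

GAS_CONSTANT <- 8.314  # J/(mol K)

#' Ideal mole-fraction solubility from melting data
#'
#' @param t_melt_K Melting onset temperature in K (> 0).
#' @param dh_fus_J Enthalpy of fusion in J/mol (> 0).
#' @param temperature_K Solution temperature in K (> 0); default 310.15
#'   (37 C, physiological).
#' @return Ideal mole fraction in (0, 1]; 1 when `temperature_K >=
#'   t_melt_K` (above the melt there is no lattice to dissolve).
#' @examples
#' ideal_solubility(366.15, 38000)   # ~0.105
#' @export
ideal_solubility <- function(t_melt_K, dh_fus_J, temperature_K = 310.15) {
  if (any(t_melt_K <= 0) || any(dh_fus_J <= 0) || any(temperature_K <= 0)) {
    stop("temperatures and fusion enthalpy must be positive", call. = FALSE)
  }
  x <- exp(-(dh_fus_J / GAS_CONSTANT) * (1 / temperature_K - 1 / t_melt_K))
  pmin(x, 1)
}

#' Rank solid forms by ideal solubility
#'
#' Evaluates [ideal_solubility()] for each thermal record and orders
#' the forms by descending ideal mole fraction; ties break
#' lexicographically by `form_id`.
#'
#' @param records Data.frame with columns `form_id`, `t_melt_C`
#'   (melting onset, Celsius) and `dH_kJ_per_mol` (fusion enthalpy,
#'   kJ/mol).
#' @param temperature_K Solution temperature in K.
#' @return `records` with added columns `t_melt_K`, `dh_fus_J`,
#'   `ideal_x` and `rank`, ordered best-first.
#' @export
rank_forms <- function(records, temperature_K = 310.15) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  need <- c("form_id", "t_melt_C", "dH_kJ_per_mol")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0L) {
    stop("thermal table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- records
  out$t_melt_K <- out$t_melt_C + 273.15
  out$dh_fus_J <- out$dH_kJ_per_mol * 1000
  out$ideal_x <- ideal_solubility(out$t_melt_K, out$dh_fus_J, temperature_K)
  ord <- order(-out$ideal_x, out$form_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Read a thermal-record table from CSV
#'
#' @param path CSV with columns `form_id`, `t_melt_C`, `dH_kJ_per_mol`.
#' @return Data.frame of thermal records.
#' @export
read_thermal_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("form_id", "t_melt_C", "dH_kJ_per_mol")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("thermal table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' Reference thermal records for the vonoprazan cocrystals
#'
#' DSC melting onsets and fusion enthalpies reported for the three
#' phase-pure vonoprazan cocrystals (with resorcinol, catechol and
#' pyrogallol). Shipped as plain CSV in `extdata`.
#'
#' @return Data.frame with columns `form_id`, `t_melt_C`,
#'   `dH_kJ_per_mol`.
#' @export
vpz_thermal_table <- function() {
  read_thermal_table(system.file("extdata", "vpz_cocrystal_thermal.csv",
                                 package = "coscreen"))
}
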