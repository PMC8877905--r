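# End-to-end screening orchestration: model predictions on a coformer
# panel, row-wise delta-pKa arbitration, composite ranking.

DPKA_PRIORITY <- c(cocrystal = 1L, continuum = 2L, salt = 3L,
                   not_applicable = 4L)

#' Screen a coformer panel against one API
#'
#' Computes descriptors for the panel (built-in formula set plus any
#' external table), replays the model's frozen cleaning transform,
#' predicts cocrystal probabilities for every API-coformer pair, and
#' applies the delta-pKa rule to every row (not only model positives,
#' so the report subsumes a screening table; `model_label` marks the
#' subset a virtual screen would carry into the laboratory). Rows are
#' ordered by a composite rank: model positives first, then delta-pKa
#' category (cocrystal > continuum > salt > not applicable), then
#' probability.
#'
#' With `model = NULL` the classifier stage is bypassed and
#' `forced_labels` (a single 0/1 or one per coformer) stands in for the
#' model call - useful for re-deriving the rule columns of a published
#' screen.
#'
#' @param api Single-row `molecule_table` with `pka_base`.
#' @param coformers `molecule_table` of panel coformers.
#' @param model A `cocrystal_model`, or `NULL` to bypass.
#' @param external Optional external descriptor table (data.frame or
#'   CSV path) covering API and coformers; required if the model was
#'   trained with external descriptors.
#' @param forced_labels 0/1 labels used when `model` is `NULL`.
#' @param rank If `FALSE`, keep the input row order.
#' @return Data.frame of class `screening_report` with columns
#'   `coformer_id`, `name`, `group`, `model_probability`, `model_label`,
#'   `delta_pka`, `dpka_category`, `composite_rank`, and a `manifest`
#'   attribute (model config hash and seed).
#' @export
run_screen <- function(api, coformers, model = NULL, external = NULL,
                       forced_labels = NULL, rank = TRUE) {
  stopifnot(inherits(api, "molecule_table"), nrow(api) == 1L,
            inherits(coformers, "molecule_table"))

  if (!is.null(model)) {
    panel <- molecule_table(rbind(as.data.frame(api), as.data.frame(coformers)))
    dmat <- descriptor_matrix(panel, external = external)
    if (!is.null(model$clean)) dmat <- apply_cleaning(model$clean, dmat)
    pairs <- pair_table(data.frame(api_id = api$id,
                                   coformer_id = coformers$id,
                                   stringsAsFactors = FALSE))
    pred <- predict_pairs(model, pairs, dmat)
    probability <- pred$probability
    label <- pred$predicted
  } else {
    if (is.null(forced_labels)) {
      stop("either `model` or `forced_labels` must be supplied", call. = FALSE)
    }
    label <- as.integer(rep_len(forced_labels, nrow(coformers)))
    probability <- rep(NA_real_, nrow(coformers))
  }

  dp <- dpka_screen(api, coformers)
  out <- data.frame(coformer_id = coformers$id, name = coformers$name,
                    group = coformers$group,
                    model_probability = probability,
                    model_label = label,
                    delta_pka = dp$delta_pka,
                    dpka_category = dp$prediction,
                    stringsAsFactors = FALSE)
  if (rank) {
    prob_key <- ifelse(is.na(out$model_probability), -Inf,
                       out$model_probability)
    ord <- order(-out$model_label, DPKA_PRIORITY[out$dpka_category],
                 -prob_key, out$coformer_id)
    out <- out[ord, , drop = FALSE]
  }
  out$composite_rank <- seq_len(nrow(out))
  rownames(out) <- NULL

  manifest <- list(
    api_id = api$id,
    model = if (is.null(model)) "bypassed" else model$config$algorithm,
    config_hash = if (is.null(model)) NA_character_ else
      config_hash(unclass(model$config)),
    seed = if (is.null(model)) NA_integer_ else model$config$seed,
    n_panel = nrow(coformers),
    n_model_positive = sum(out$model_label == 1L)
  )
  attr(out, "manifest") <- manifest
  class(out) <- c("screening_report", "data.frame")
  out
}

#' Write a screening report and its manifest
#'
#' @param report A `screening_report`.
#' @param dir Output directory; writes `report.csv` and
#'   `manifest.json`.
#' @return `dir`, invisibly.
#' @export
write_screening_report <- function(report, dir) {
  stopifnot(inherits(report, "screening_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(report), file.path(dir, "report.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(attr(report, "manifest"),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
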