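# API-coformer pair records: validation, featurization, splitting.

#' Build a validated pair table
#'
#' @param df Data.frame with columns `api_id`, `coformer_id` and
#'   optionally `label` (0/1).
#' @return Data.frame of class `pair_table`.
#' @export
pair_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("api_id", "coformer_id")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("pair table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$api_id <- as.character(df$api_id)
  df$coformer_id <- as.character(df$coformer_id)
  if (any(df$api_id == df$coformer_id)) {
    stop("pair with identical api_id and coformer_id", call. = FALSE)
  }
  key <- paste(pmin(df$api_id, df$coformer_id), pmax(df$api_id, df$coformer_id))
  if (anyDuplicated(key)) {
    stop("duplicate pair(s): ", paste(unique(key[duplicated(key)]), collapse = "; "),
         call. = FALSE)
  }
  if ("label" %in% names(df)) {
    lab <- df$label
    if (!all(is.na(lab) | lab %in% c(0, 1))) {
      stop("labels must be 0, 1 or NA", call. = FALSE)
    }
    df$label <- as.integer(lab)
  }
  rownames(df) <- NULL
  class(df) <- c("pair_table", "data.frame")
  df
}

#' Read a labeled pair table from CSV
#' @param path CSV with columns api_id, coformer_id and optionally label.
#' @return A `pair_table`.
#' @export
read_pair_table <- function(path) {
  pair_table(utils::read.csv(path, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8"))
}

#' Featurize one API-coformer pair
#'
#' Combines the two cleaned descriptor vectors into a single model input.
#' `"concat"` (default) is the ordered concatenation with the API block
#' first, matching the convention that a pair is always framed as
#' API-coformer; `"symmetric"` uses order-invariant (sum, absolute
#' difference) blocks.
#'
#' @param api_vec,cof_vec Named numeric vectors sharing the same
#'   descriptor schema.
#' @param mode `"concat"` or `"symmetric"`.
#' @return Named numeric feature vector.
#' @export
featurize_pair <- function(api_vec, cof_vec, mode = c("concat", "symmetric")) {
  mode <- match.arg(mode)
  if (!identical(names(api_vec), names(cof_vec))) {
    diff <- union(setdiff(names(api_vec), names(cof_vec)),
                  setdiff(names(cof_vec), names(api_vec)))
    stop("descriptor schema mismatch between pair members: ",
         paste(diff, collapse = ", "), call. = FALSE)
  }
  if (mode == "concat") {
    stats::setNames(c(api_vec, cof_vec),
                    c(paste0("api_", names(api_vec)), paste0("cof_", names(cof_vec))))
  } else {
    stats::setNames(c(api_vec + cof_vec, abs(api_vec - cof_vec)),
                    c(paste0("sum_", names(api_vec)), paste0("dif_", names(api_vec))))
  }
}

# Vectorized featurization of a pair table against a descriptor matrix.
featurize_pairs <- function(pairs, dmat, mode = c("concat", "symmetric")) {
  mode <- match.arg(mode)
  missing_ids <- setdiff(unique(c(pairs$api_id, pairs$coformer_id)), rownames(dmat))
  if (length(missing_ids) > 0L) {
    stop("descriptor matrix lacks molecule id(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  a <- dmat[pairs$api_id, , drop = FALSE]
  b <- dmat[pairs$coformer_id, , drop = FALSE]
  x <- if (mode == "concat") {
    cbind(a, b)
  } else {
    cbind(a + b, abs(a - b))
  }
  colnames(x) <- if (mode == "concat") {
    c(paste0("api_", colnames(dmat)), paste0("cof_", colnames(dmat)))
  } else {
    c(paste0("sum_", colnames(dmat)), paste0("dif_", colnames(dmat)))
  }
  rownames(x) <- NULL
  x
}

#' Stratified train/test split of a labeled pair table
#'
#' Splits by label so class proportions are preserved (test counts per
#' class within one of the target), disjointly and exhaustively, fully
#' determined by `seed`.
#'
#' @param pairs Labeled `pair_table`.
#' @param test_fraction Fraction held out, in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` pair tables.
#' @export
split_dataset <- function(pairs, test_fraction = 0.2, seed = 1) {
  if (!"label" %in% names(pairs) || anyNA(pairs$label)) {
    stop("split_dataset requires fully labeled pairs", call. = FALSE)
  }
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must be in (0, 1)", call. = FALSE)
  }
  tab <- table(pairs$label)
  if (any(tab < 2L)) {
    stop("each class needs at least 2 members to split", call. = FALSE)
  }
  test_idx <- with_seed(seed, {
    unlist(lapply(sort(unique(pairs$label)), function(cl) {
      idx <- which(pairs$label == cl)
      n_test <- max(1L, round(test_fraction * length(idx)))
      sample(idx, n_test)
    }), use.names = FALSE)
  })
  test_idx <- sort(test_idx)
  train <- pairs[-test_idx, , drop = FALSE]
  test <- pairs[test_idx, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  class(train) <- class(test) <- c("pair_table", "data.frame")
  list(train = train, test = test)
}
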