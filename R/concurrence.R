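#' Remove slides with an 'other' diagnosis from each stratum
#'
#' A diagnosis of 'other' cannot be scored against a reference diagnosis
#' (the reference never contains 'other'), so within each condition x medium
#' stratum every slide for which any rater chose 'other' is removed from that
#' stratum before concurrence is computed. Dropping the whole slide, rather
#' than only the offending rater's record, keeps the rater panel balanced.
#'
#' @param table A [rating_table()].
#' @param reference A [reference_table()] (used only for validation that rated
#'   slides are covered).
#' @return The filtered `rating_table`; the attribute `"removed"` is a
#'   data.frame logging, per stratum, how many slides were removed.
#' @export
remove_other <- function(table, reference = NULL) {
  if (!is.null(reference)) check_reference_covers(table, reference)
  strata <- unique(table[, c("condition", "medium")])
  keep <- rep(TRUE, nrow(table))
  log <- list()
  for (i in seq_len(nrow(strata))) {
    cond <- strata$condition[i]
    med <- strata$medium[i]
    in_stratum <- table$condition == cond & table$medium == med
    bad_slides <- unique(table$slide_id[in_stratum &
                                          !is.na(table$diagnosis) &
                                          table$diagnosis == "other"])
    drop <- in_stratum & table$slide_id %in% bad_slides
    if (all(!in_stratum | drop)) {
      stop(sprintf(
        "every slide in stratum (%s, %s) has an 'other' diagnosis; nothing left to score",
        cond, med), call. = FALSE)
    }
    keep[drop] <- FALSE
    log[[i]] <- data.frame(condition = cond, medium = med,
                           slides_removed = length(bad_slides),
                           stringsAsFactors = FALSE)
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(table)
  attr(out, "removed") <- do.call(rbind, log)
  out
}

check_reference_covers <- function(table, reference) {
  missing_ref <- setdiff(unique(table$slide_id), reference$slide_id)
  if (length(missing_ref) > 0) {
    stop("rated slide(s) absent from the reference table: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Concurrence of rater diagnoses with the reference diagnosis
#'
#' Accuracy of the pooled rater diagnoses against the reference: the
#' proportion of slide x rater (x condition x medium) pairs whose diagnosis
#' matches the reference, with exact Clopper-Pearson confidence limits, a
#' one-sided exact binomial p-value against the no-information rate (the
#' largest reference-class share among the retained pairs), and an unweighted
#' Cohen kappa of the pooled (rating, reference) pairs.
#'
#' 'Other' diagnoses must already be removed ([remove_other()]) and no
#' missing diagnoses may remain.
#'
#' @param table A [rating_table()] (any subset of strata; pairs are pooled
#'   over everything present).
#' @param reference A [reference_table()] covering every rated slide.
#' @param level Confidence level for the exact limits, default 0.95.
#' @return An object of class `concurrence_result`: list with `proportion`,
#'   `lcl`, `ucl`, `p`, `kappa_vs_reference` (a `kappa_result`), `n_pairs`,
#'   `matches`, `nir`.
#' @export
concurrence <- function(table, reference, level = 0.95) {
  check_reference_covers(table, reference)
  if (nrow(table) == 0) stop("no rating pairs to score", call. = FALSE)
  if (anyNA(table$diagnosis)) {
    stop("missing diagnoses present; impute or drop them before scoring concurrence",
         call. = FALSE)
  }
  if (any(table$diagnosis == "other")) {
    stop("'other' diagnoses present; apply remove_other() first", call. = FALSE)
  }
  ref <- reference$diagnosis[match(table$slide_id, reference$slide_id)]
  n_pairs <- nrow(table)
  matches <- sum(table$diagnosis == ref)
  nir <- max(table(ref)) / n_pairs
  bt_ci <- stats::binom.test(matches, n_pairs, conf.level = level)
  bt_p <- stats::binom.test(matches, n_pairs, p = nir, alternative = "greater")
  structure(
    list(proportion = matches / n_pairs,
         lcl = bt_ci$conf.int[1], ucl = bt_ci$conf.int[2],
         p = bt_p$p.value,
         kappa_vs_reference = cohen_kappa(table$diagnosis, ref),
         n_pairs = n_pairs, matches = matches, nir = nir, level = level),
    class = "concurrence_result"
  )
}

#' @export
print.concurrence_result <- function(x, ...) {
  cat(sprintf(
    "concurrence = %.3f [%.3f, %.3f] (%d/%d pairs), p = %.4g vs no-information rate %.3f\n",
    x$proportion, x$lcl, x$ucl, x$matches, x$n_pairs, x$p, x$nir))
  cat(sprintf("kappa vs reference = %.3f (p = %.4g)\n",
              x$kappa_vs_reference$kappa, x$kappa_vs_reference$p))
  invisible(x)
}

#' One-vs-rest sensitivity and specificity against the reference
#'
#' For each diagnosis category, pooled slide x rater pairs are scored
#' one-vs-rest: sensitivity is the share of reference-positive pairs called
#' positive (`tp / (tp + fn)`), specificity the share of reference-negative
#' pairs called negative (`tn / (tn + fp)`). A zero denominator yields `NA`,
#' never zero.
#'
#' @inheritParams concurrence
#' @param categories Categories to score; defaults to the four reference
#'   diagnoses.
#' @return A data.frame of class `category_metrics` with columns `category`,
#'   `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`.
#' @export
sensitivity_specificity <- function(table, reference,
                                    categories = setdiff(diagnosis_levels(), "other")) {
  check_reference_covers(table, reference)
  if (anyNA(table$diagnosis)) {
    stop("missing diagnoses present; impute or drop them first", call. = FALSE)
  }
  ref <- reference$diagnosis[match(table$slide_id, reference$slide_id)]
  rated <- table$diagnosis
  out <- lapply(categories, function(cat) {
    tp <- sum(ref == cat & rated == cat)
    fn <- sum(ref == cat & rated != cat)
    fp <- sum(ref != cat & rated == cat)
    tn <- sum(ref != cat & rated != cat)
    data.frame(category = cat, tp = tp, fp = fp, tn = tn, fn = fn,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("category_metrics", "data.frame")
  out
}
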