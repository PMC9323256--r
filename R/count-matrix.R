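#' Subject-by-category count matrix
#'
#' The input shape of the Fleiss kappa statistic: an `n` subjects by `k`
#' categories integer matrix whose entry `n_ij` counts the raters that
#' assigned subject `i` to category `j`, with a constant row sum `m` (raters
#' per subject).
#'
#' @param counts Integer matrix (subjects x categories); dimnames optional.
#' @return An object of class `subject_category_counts` (a matrix with an `m`
#'   attribute).
#' @export
subject_category_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("need at least 2 subjects and 2 categories", call. = FALSE)
  }
  rs <- rowSums(counts)
  if (length(unique(rs)) != 1) {
    stop("unequal row sums: every subject must receive the same number of ratings",
         call. = FALSE)
  }
  m <- rs[[1]]
  if (m < 2) stop("need at least 2 ratings per subject", call. = FALSE)
  storage.mode(counts) <- "integer"
  structure(counts, m = as.integer(m), class = c("subject_category_counts", "matrix"))
}

#' Build the Fleiss input for one stratum
#'
#' Counts, per slide, how many raters assigned each of the five diagnosis
#' categories within one condition x medium stratum. The stratum must be
#' complete: a missing diagnosis must first be imputed (see
#' [impute_ratings()]) or the slide dropped.
#'
#' @param table A [rating_table()].
#' @param condition One of [condition_levels()].
#' @param medium One of [medium_levels()].
#' @param categories Category set (columns); defaults to the five diagnoses.
#' @return A [subject_category_counts()] matrix with slide ids as row names.
#' @export
to_count_matrix <- function(table, condition, medium,
                            categories = diagnosis_levels()) {
  condition <- match.arg(condition, condition_levels())
  medium <- match.arg(medium, medium_levels())
  sub <- table[table$condition == condition & table$medium == medium, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop(sprintf("no records in stratum (%s, %s)", condition, medium), call. = FALSE)
  }
  if (anyNA(sub$diagnosis)) {
    bad <- sub[is.na(sub$diagnosis), , drop = FALSE]
    stop(sprintf(
      paste0("stratum (%s, %s) has %d missing diagnosis cell(s) (e.g. slide %s, ",
             "rater %s); impute them or remove the slides first"),
      condition, medium, nrow(bad), bad$slide_id[1], bad$rater_id[1]),
      call. = FALSE)
  }
  tab <- table(factor(sub$slide_id, levels = sort(unique(sub$slide_id))),
               factor(sub$diagnosis, levels = categories))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), categories))
  subject_category_counts(counts)
}

#' Per-rater, per-condition, per-category marginal counts
#'
#' The count layout of the study's published count tables: for one medium, how
#' many slides each rater assigned to each diagnosis under each condition,
#' plus a `total` row counting that rater's non-missing diagnoses.
#'
#' @param table A [rating_table()].
#' @param medium One of [medium_levels()].
#' @param raters Rater ids (columns); defaults to those present, sorted.
#' @return A 3-d array `[diagnosis + total, rater, condition]` of counts.
#' @export
marginal_counts <- function(table, medium, raters = NULL) {
  medium <- match.arg(medium, medium_levels())
  sub <- table[table$medium == medium, , drop = FALSE]
  if (is.null(raters)) raters <- sort(unique(sub$rater_id))
  cats <- diagnosis_levels()
  out <- array(0L, dim = c(length(cats) + 1L, length(raters), 3L),
               dimnames = list(c(cats, "total"), raters, condition_levels()))
  if (nrow(sub) == 0 || length(raters) == 0) return(out)
  keep <- !is.na(sub$diagnosis) & sub$rater_id %in% raters
  sub <- sub[keep, , drop = FALSE]
  tab <- table(factor(sub$diagnosis, levels = cats),
               factor(sub$rater_id, levels = raters),
               factor(sub$condition, levels = condition_levels()))
  out[cats, , ] <- as.integer(tab)
  out["total", , ] <- apply(out[cats, , , drop = FALSE], c(2, 3), sum)
  out
}
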