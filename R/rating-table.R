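#' Construct a validated rating table
#'
#' A rating table holds one diagnosis per slide x rater x condition x medium
#' cell, in long format. The diagnosis may be missing (`NA`) where a rater
#' could not read a slide; every other field is required. Extra columns (for
#' example the histological feature answers recorded alongside each read) are
#' carried through untouched.
#'
#' @param df A data.frame with columns `slide_id`, `species`, `rater_id`,
#'   `condition`, `medium`, `diagnosis`. Labels are canonicalized to lower
#'   case; an empty string or `NA` diagnosis marks a missing rating.
#' @return An object of class `rating_table` (a data.frame).
#' @export
rating_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("slide_id", "species", "rater_id", "condition", "medium", "diagnosis")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("rating table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$slide_id <- as.character(df$slide_id)
  df$rater_id <- as.character(df$rater_id)
  df$species <- canonical_label(df$species, species_levels(), "species")
  df$condition <- canonical_label(df$condition, condition_levels(), "condition")
  df$medium <- canonical_label(df$medium, medium_levels(), "medium")
  df$diagnosis <- canonical_label(df$diagnosis, diagnosis_levels(), "diagnosis",
                                  allow_missing = TRUE)
  key <- paste(df$slide_id, df$rater_id, df$condition, df$medium, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    k <- strsplit(key[dup][1], "\r", fixed = TRUE)[[1]]
    stop(sprintf(
      "duplicate rating for (slide_id=%s, rater_id=%s, condition=%s, medium=%s)",
      k[1], k[2], k[3], k[4]), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("rating_table", "data.frame")
  df
}

#' @export
print.rating_table <- function(x, ...) {
  cat(sprintf(
    "<rating_table> %d records: %d slides, %d raters, %d conditions, media: %s; %d missing diagnoses\n",
    nrow(x), length(unique(x$slide_id)), length(unique(x$rater_id)),
    length(unique(x$condition)), paste(sort(unique(x$medium)), collapse = "/"),
    sum(is.na(x$diagnosis))))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

#' Construct a validated reference-diagnosis table
#'
#' The reference (gold-standard) diagnosis per slide. A reference diagnosis is
#' never 'other': the study design only includes slides with a definite
#' reference class.
#'
#' @param df A data.frame with columns `slide_id`, `species`, `diagnosis`.
#' @return An object of class `reference_table` (a data.frame).
#' @export
reference_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("slide_id", "species", "diagnosis")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("reference table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$slide_id <- as.character(df$slide_id)
  df$species <- canonical_label(df$species, species_levels(), "species")
  df$diagnosis <- canonical_label(df$diagnosis,
                                  setdiff(diagnosis_levels(), "other"),
                                  "reference diagnosis")
  if (anyDuplicated(df$slide_id)) {
    stop("duplicate slide_id in reference table: ",
         df$slide_id[duplicated(df$slide_id)][1], call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("reference_table", "data.frame")
  df
}

#' Read and write rating / reference tables
#'
#' Long-format CSV with a header, UTF-8. Lines starting with `#` are comments
#' (fixture files carry a provenance comment). An empty diagnosis cell encodes
#' a missing rating.
#'
#' @param path Path to a CSV file.
#' @return `read_ratings()` a [rating_table()]; `read_reference()` a
#'   [reference_table()].
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", colClasses = "character",
                        na.strings = character())
  rating_table(df)
}

#' @rdname read_ratings
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", colClasses = "character",
                        na.strings = character())
  reference_table(df)
}

#' @rdname read_ratings
#' @param x A `rating_table` or `reference_table`.
#' @param comment Optional comment line(s) written at the top of the file.
#' @export
write_ratings <- function(x, path, comment = NULL) {
  df <- as.data.frame(x)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_ratings
#' @export
write_reference <- function(x, path, comment = NULL) {
  write_ratings(x, path, comment)
}
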