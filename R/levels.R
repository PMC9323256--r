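#' Canonical label sets
#'
#' The five etiological diagnosis labels offered to each rater, the three
#' sequential reading conditions (in study order), the two viewing media, and
#' the two species. All labels are canonically lower case; readers accept any
#' case on input.
#'
#' @return A character vector of canonical labels.
#' @name labels
NULL

#' @rdname labels
#' @export
diagnosis_levels <- function() {
  c("cystitis", "neoplasia", "urolithiasis", "normal", "other")
}

#' @rdname labels
#' @export
condition_levels <- function() {
  c("no_info", "signalment_history", "predictive_tool")
}

#' @rdname labels
#' @export
medium_levels <- function() {
  c("wsi", "glass")
}

#' @rdname labels
#' @export
species_levels <- function() {
  c("canine", "feline")
}

# Canonicalize a label vector against a valid set; "" becomes NA when
# allow_missing, anything else unknown is an error listing the valid labels.
canonical_label <- function(x, valid, what, allow_missing = FALSE) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("", "na")] <- NA_character_
  bad <- !is.na(x) & !(x %in% valid)
  if (any(bad)) {
    stop(sprintf(
      "unknown %s label(s): %s; valid labels are: %s",
      what, paste(unique(x[bad]), collapse = ", "),
      paste(valid, collapse = ", ")
    ), call. = FALSE)
  }
  if (!allow_missing && anyNA(x)) {
    stop(sprintf("missing %s label not allowed here", what), call. = FALSE)
  }
  x
}
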