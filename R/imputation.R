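#' Chained-equation imputation of missing categorical ratings
#'
#' Fills missing diagnosis cells by chained polytomous (multinomial logistic)
#' regression, the standard treatment for unordered categorical missing data:
#' the table is pivoted wide by rater (one row per slide x condition x
#' medium), and for each incomplete rater column a multinomial model of that
#' column on the other raters' observed-or-currently-imputed diagnoses plus
#' condition indicators is fitted, then each missing cell is drawn from its
#' predicted category distribution. The fit-and-draw sweep over incomplete
#' columns is repeated `maxit` times, and `m` independent chains (with seeds
#' derived from `seed`) give `m` completed tables.
#'
#' By default each component fit uses a bootstrap resample of the complete
#' rows as an approximate draw from the parameter distribution, making the
#' imputation "proper"; `proper = FALSE` fits by plain maximum likelihood.
#' When a component design is degenerate (rank deficiency, a single observed
#' category, or a failed fit) the draw falls back to the column's observed
#' empirical distribution and the fallback is logged.
#'
#' Originally observed cells are never modified.
#'
#' @param table A [rating_table()]; missingness must be confined to the
#'   diagnosis column.
#' @param m Number of completed datasets (>= 1), default 5.
#' @param maxit Chained sweeps per dataset (>= 1), default 10.
#' @param seed Integer seed; chain `i` uses `seed + i`.
#' @param proper Use the bootstrap parameter draw (default `TRUE`).
#' @return A list of `m` completed [rating_table()]s; attribute `"log"`
#'   records fallback events, attribute `"spec"` the settings used.
#' @export
impute_ratings <- function(table, m = 5L, maxit = 10L, seed = 1L, proper = TRUE) {
  if (m < 1 || maxit < 1) stop("m and maxit must be >= 1", call. = FALSE)
  if (!anyNA(table$diagnosis)) {
    out <- lapply(seq_len(m), function(i) table)
  } else {
    wide <- stats::reshape(
      as.data.frame(table)[, c("slide_id", "condition", "medium", "rater_id", "diagnosis")],
      idvar = c("slide_id", "condition", "medium"),
      timevar = "rater_id", direction = "wide")
    rater_cols <- grep("^diagnosis\\.", names(wide), value = TRUE)
    raters <- sub("^diagnosis\\.", "", rater_cols)
    entirely_missing <- raters[vapply(rater_cols,
                                      function(cc) all(is.na(wide[[cc]])),
                                      logical(1))]
    if (length(entirely_missing) > 0) {
      stop("rater column(s) entirely missing, nothing to learn from: ",
           paste(entirely_missing, collapse = ", "), call. = FALSE)
    }
    log_events <- character()
    completed <- lapply(seq_len(m), function(chain) {
      res <- with_seed(seed + chain, impute_chain(wide, rater_cols, maxit, proper))
      log_events <<- c(log_events, res$log)
      res$wide
    })
    out <- lapply(completed, function(w) {
      filled <- table
      for (cc in rater_cols) {
        r <- sub("^diagnosis\\.", "", cc)
        idx <- match(paste(filled$slide_id, filled$condition, filled$medium),
                     paste(w$slide_id, w$condition, w$medium))
        fill <- filled$rater_id == r & is.na(filled$diagnosis)
        filled$diagnosis[fill] <- w[[cc]][idx[fill]]
      }
      filled
    })
    attr(out, "log") <- log_events
  }
  attr(out, "spec") <- list(m = m, maxit = maxit, seed = seed, proper = proper)
  out
}

# one chained-imputation pass over a wide table; assumes RNG already seeded
impute_chain <- function(wide, rater_cols, maxit, proper) {
  log_events <- character()
  miss <- lapply(rater_cols, function(cc) which(is.na(wide[[cc]])))
  names(miss) <- rater_cols
  incomplete <- rater_cols[vapply(miss, length, integer(1)) > 0]
  # initialize missing cells from the observed empirical distribution
  for (cc in incomplete) {
    obs <- wide[[cc]][!is.na(wide[[cc]])]
    wide[[cc]][miss[[cc]]] <- sample(obs, length(miss[[cc]]), replace = TRUE)
  }
  for (it in seq_len(maxit)) {
    for (cc in incomplete) {
      target_miss <- miss[[cc]]
      obs_rows <- setdiff(seq_len(nrow(wide)), target_miss)
      preds <- c(setdiff(rater_cols, cc), "condition")
      fml <- stats::as.formula(paste0("`", cc, "` ~ ",
                                      paste0("`", preds, "`", collapse = " + ")))
      fit_rows <- if (proper) {
        sample(obs_rows, length(obs_rows), replace = TRUE)
      } else obs_rows
      # fixed factor levels so prediction rows never carry unseen levels
      as_pred_factors <- function(df) {
        for (p in setdiff(rater_cols, cc)) {
          df[[p]] <- factor(df[[p]], levels = diagnosis_levels())
        }
        df$condition <- factor(df$condition, levels = condition_levels())
        df
      }
      train <- as_pred_factors(wide[fit_rows, , drop = FALSE])
      train[[cc]] <- factor(train[[cc]], levels = diagnosis_levels())
      train[[cc]] <- droplevels(train[[cc]])
      draw <- NULL
      if (nlevels(train[[cc]]) >= 2) {
        fit <- tryCatch(
          nnet::multinom(fml, data = train, trace = FALSE, maxit = 200),
          error = function(e) NULL, warning = function(w) NULL)
        if (!is.null(fit)) {
          pr <- tryCatch(
            stats::predict(fit, newdata = as_pred_factors(wide[target_miss, , drop = FALSE]),
                           type = "probs"),
            error = function(e) NULL)
          if (!is.null(pr)) {
            if (is.null(dim(pr)) && nlevels(train[[cc]]) == 2) {
              # two observed levels: predict() returns P(second level)
              lv <- fit$lev
              pr <- cbind(1 - pr, pr)
              colnames(pr) <- lv
            } else if (is.null(dim(pr))) {
              # single prediction row: named probability vector
              pr <- matrix(pr, nrow = 1, dimnames = list(NULL, names(pr)))
            }
            draw <- apply(pr, 1, function(p) {
              sample(colnames(pr), 1, prob = pmax(p, 0))
            })
          }
        }
      }
      if (is.null(draw)) {
        obs <- wide[[cc]][obs_rows]
        draw <- sample(obs, length(target_miss), replace = TRUE)
        log_events <- c(log_events, sprintf(
          "fallback to empirical draw for %s (sweep %d): degenerate component model",
          sub("^diagnosis\\.", "", cc), it))
      }
      wide[[cc]][target_miss] <- draw
    }
  }
  list(wide = wide, log = unique(log_events))
}

#' Pool kappa estimates across imputations (Rubin's rules)
#'
#' Point estimate is the mean of the per-imputation kappas; the total variance
#' is the mean within-imputation variance plus `(1 + 1/m)` times the
#' between-imputation variance.
#'
#' @param kappas Numeric vector of kappa estimates, or a list of
#'   `kappa_result`s.
#' @param variances Within-imputation variances (squared standard errors);
#'   extracted from `kappa_result`s when omitted.
#' @return A list with `kappa`, `variance`, `within`, `between`, `m`.
#' @export
pool_kappa <- function(kappas, variances = NULL) {
  if (is.list(kappas) && all(vapply(kappas, inherits, logical(1), "kappa_result"))) {
    if (is.null(variances)) variances <- vapply(kappas, function(k) k$se0^2, numeric(1))
    kappas <- vapply(kappas, function(k) k$kappa, numeric(1))
  }
  if (length(kappas) == 0) stop("no kappa results to pool", call. = FALSE)
  m <- length(kappas)
  if (is.null(variances)) variances <- rep(NA_real_, m)
  if (length(variances) != m) stop("variances must match kappas", call. = FALSE)
  within <- mean(variances)
  between <- if (m > 1) stats::var(kappas) else 0
  list(kappa = mean(kappas),
       variance = within + (1 + 1 / m) * between,
       within = within, between = between, m = m)
}
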