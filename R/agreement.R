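#' Fleiss kappa for multiple raters, with per-category detail
#'
#' Chance-corrected agreement for a fixed panel of `m` raters assigning each
#' of `n` subjects to one of `k` unordered categories. With
#' `p_j = sum_i n_ij / (n m)` the marginal share of category `j`,
#' `P_i = (sum_j n_ij^2 - m) / (m (m - 1))` the observed pairwise agreement on
#' subject `i`, `P_bar = mean_i P_i` and `P_e = sum_j p_j^2` the chance
#' agreement, the overall statistic is
#' `kappa = (P_bar - P_e) / (1 - P_e)`.
#'
#' Per category, `kappa_j = 1 - sum_i n_ij (m - n_ij) / (n m (m-1) p_j q_j)`
#' with `q_j = 1 - p_j`; a category used never or always (`p_j` of 0 or 1) has
#' no defined kappa and is reported as `NA`. Standard errors are the
#' large-sample null (`kappa = 0`) forms, so `z = kappa / se0` and the
#' two-sided normal p-value test the hypothesis of purely chance agreement:
#' `se0_j = sqrt(2 / (n m (m-1)))` per category, and overall
#' `se0 = sqrt(2) / (S sqrt(n m (m-1))) * sqrt(S^2 - sum_j p_j q_j (q_j - p_j))`
#' where `S = sum_j p_j q_j`.
#'
#' @param counts A [subject_category_counts()] matrix (or a plain matrix with
#'   constant row sums).
#' @return An object of class `kappa_result`: a list with `kappa`, `se0`, `z`,
#'   `p`, `band` (see [interpret_kappa()]), `n`, `m`, `k`, and a
#'   `per_category` data.frame with columns `category`, `kappa`, `se0`, `z`,
#'   `p`.
#' @seealso [interpret_kappa()], [bootstrap_kappa_ci()], [to_count_matrix()]
#' @export
fleiss_kappa <- function(counts) {
  counts <- as_counts(counts)
  m <- attr(counts, "m")
  n <- nrow(counts)
  k <- ncol(counts)
  nm <- n * m
  p_j <- colSums(counts) / nm
  P_e <- sum(p_j^2)
  if (1 - P_e <= .Machine$double.eps * k) {
    stop("kappa is undefined: all ratings fall in a single category (chance agreement = 1)",
         call. = FALSE)
  }
  P_i <- (rowSums(counts^2) - m) / (m * (m - 1))
  P_bar <- mean(P_i)
  kappa <- (P_bar - P_e) / (1 - P_e)

  q_j <- 1 - p_j
  S <- sum(p_j * q_j)
  se0 <- sqrt(2) / (S * sqrt(nm * (m - 1))) *
    sqrt(S^2 - sum(p_j * q_j * (q_j - p_j)))
  z <- kappa / se0
  p <- 2 * stats::pnorm(-abs(z))

  denom_j <- nm * (m - 1) * p_j * q_j
  kappa_j <- ifelse(p_j <= 0 | p_j >= 1, NA_real_,
                    1 - colSums(counts * (m - counts)) / denom_j)
  se0_j <- rep(sqrt(2 / (nm * (m - 1))), k)
  z_j <- kappa_j / se0_j
  per_category <- data.frame(
    category = colnames(counts) %||% paste0("cat", seq_len(k)),
    kappa = as.numeric(kappa_j),
    se0 = se0_j,
    z = as.numeric(z_j),
    p = 2 * stats::pnorm(-abs(as.numeric(z_j))),
    row.names = NULL, stringsAsFactors = FALSE
  )

  structure(
    list(kappa = kappa, se0 = se0, z = z, p = p,
         band = interpret_kappa(kappa), per_category = per_category,
         n = n, m = m, k = k, statistic = "fleiss"),
    class = "kappa_result"
  )
}

as_counts <- function(counts) {
  if (inherits(counts, "subject_category_counts")) return(counts)
  subject_category_counts(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Interpretation band for a kappa value
#'
#' The conventional banding for chance-corrected agreement: values below 0.40
#' represent poor agreement beyond chance, values from 0.40 to 0.75 fair to
#' good agreement, and values above 0.75 excellent agreement. Both boundaries
#' are inclusive to the middle band.
#'
#' @param kappa A kappa value in `[-1, 1]`.
#' @return One of `"poor"`, `"fair_to_good"`, `"excellent"`.
#' @export
interpret_kappa <- function(kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1 || is.na(kappa) ||
      kappa < -1 || kappa > 1) {
    stop("kappa must be a single value in [-1, 1]", call. = FALSE)
  }
  if (kappa < 0.40) "poor" else if (kappa <= 0.75) "fair_to_good" else "excellent"
}

#' Cohen kappa for two rating sequences
#'
#' Unweighted chance-corrected agreement between two paired categorical
#' sequences: `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the observed
#' agreement proportion and `p_e = sum_j row_j col_j` the marginal chance
#' agreement. The standard error is the large-sample null form of Fleiss,
#' Cohen and Everitt, so `z` and the two-sided `p` test chance agreement.
#'
#' @param ratings_a,ratings_b Equal-length category vectors (length >= 2).
#' @param categories Optional shared category set; defaults to the union of
#'   observed values.
#' @return A `kappa_result` (without per-category detail).
#' @export
cohen_kappa <- function(ratings_a, ratings_b, categories = NULL) {
  ratings_a <- as.character(ratings_a)
  ratings_b <- as.character(ratings_b)
  if (length(ratings_a) != length(ratings_b)) {
    stop("rating sequences must have equal length", call. = FALSE)
  }
  n <- length(ratings_a)
  if (n < 2) stop("need at least 2 paired ratings", call. = FALSE)
  if (anyNA(ratings_a) || anyNA(ratings_b)) {
    stop("missing values are not allowed; impute or drop them first", call. = FALSE)
  }
  if (is.null(categories)) categories <- sort(unique(c(ratings_a, ratings_b)))
  tab <- table(factor(ratings_a, levels = categories),
               factor(ratings_b, levels = categories)) / n
  p_o <- sum(diag(tab))
  row_m <- rowSums(tab)
  col_m <- colSums(tab)
  p_e <- sum(row_m * col_m)
  if (1 - p_e <= .Machine$double.eps) {
    stop("kappa is undefined: marginal chance agreement equals 1", call. = FALSE)
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  var0 <- (p_e + p_e^2 - sum(row_m * col_m * (row_m + col_m))) / (n * (1 - p_e)^2)
  se0 <- sqrt(max(var0, 0))
  z <- if (se0 > 0) kappa / se0 else NA_real_
  structure(
    list(kappa = kappa, se0 = se0, z = z,
         p = 2 * stats::pnorm(-abs(z)),
         band = interpret_kappa(kappa), per_category = NULL,
         n = n, m = 2L, k = length(categories), statistic = "cohen"),
    class = "kappa_result"
  )
}

#' Subject-level percentile bootstrap interval for the overall Fleiss kappa
#'
#' Resamples subjects (rows of the count matrix) with replacement, recomputes
#' the overall kappa per resample, and returns the percentile interval.
#' Degenerate resamples (all ratings in one category, kappa undefined) are
#' skipped and counted; more than half skipped is an error.
#'
#' @inheritParams fleiss_kappa
#' @param replicates Number of bootstrap resamples (>= 200).
#' @param level Confidence level, default 0.95.
#' @param seed Integer seed; the interval is reproducible under a fixed seed.
#' @return An object of class `kappa_interval`: list with `level`, `lower`,
#'   `upper`, `kappa` (point estimate), `replicates`, `skipped`.
#' @export
bootstrap_kappa_ci <- function(counts, replicates = 2000, level = 0.95, seed = 1L) {
  counts <- as_counts(counts)
  if (replicates < 200) stop("need at least 200 bootstrap replicates", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  point <- fleiss_kappa(counts)$kappa
  n <- nrow(counts)
  m <- attr(counts, "m")
  kap <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * replicates, replace = TRUE), nrow = n)
    apply(idx, 2, function(i) fleiss_kappa_value(counts[i, , drop = FALSE], m))
  })
  skipped <- sum(is.na(kap))
  if (skipped > replicates / 2) {
    stop(sprintf("%d of %d bootstrap resamples were degenerate (kappa undefined)",
                 skipped, replicates), call. = FALSE)
  }
  kap <- kap[!is.na(kap)]
  qs <- stats::quantile(kap, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(
    list(level = level, lower = max(qs[1], -1), upper = min(qs[2], 1),
         kappa = point, replicates = replicates, skipped = skipped),
    class = "kappa_interval"
  )
}

# bare-metal overall kappa used inside the bootstrap loop; NA when degenerate
fleiss_kappa_value <- function(counts, m) {
  n <- nrow(counts)
  nm <- n * m
  p_j <- colSums(counts) / nm
  P_e <- sum(p_j^2)
  if (1 - P_e <= .Machine$double.eps * length(p_j)) return(NA_real_)
  P_bar <- mean((rowSums(counts^2) - m) / (m * (m - 1)))
  (P_bar - P_e) / (1 - P_e)
}

# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("%s kappa = %.4f (band: %s), z = %.3f, p = %.4g [n=%d, m=%d, k=%d]\n",
              x$statistic, x$kappa, x$band, x$z, x$p,
              x$n, x$m, x$k))
  if (!is.null(x$per_category)) {
    cat("per-category:\n")
    print(x$per_category, digits = 4)
  }
  invisible(x)
}

#' @export
print.kappa_interval <- function(x, ...) {
  cat(sprintf("kappa = %.4f, %d%% percentile bootstrap CI [%.4f, %.4f] (%d replicates, %d skipped)\n",
              x$kappa, round(100 * x$level), x$lower, x$upper,
              x$replicates, x$skipped))
  invisible(x)
}
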