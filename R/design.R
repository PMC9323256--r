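#' Kappa-based sample size for an agreement study
#'
#' Returns the smallest number of subjects `n` such that the expected lower
#' one-sided `100(1 - alpha)%` confidence limit of the kappa estimate,
#' `kappa0 - z_(1-alpha) * sqrt(Var(kappa_hat))`, is at least `kappaL`, by
#' incrementing `n` from 2. `kappa0` is the anticipated agreement, `kappaL`
#' the lowest agreement the study must be able to assure, and the variance is
#' evaluated at `kappa0` for a binary trait with the given prevalence.
#'
#' Two variance models are available:
#' \describe{
#'   \item{`"pairwise"` (default)}{the classic large-sample variance of the
#'     binary intraclass kappa (Bloch-Kraemer / Donner-Eliasziw form),
#'     `Var = (1 - k) * ((1 - k)(1 - 2k) + k(2 - k) / (2 p q)) / n`.
#'     It plans on the agreement information carried by rater pairs and is
#'     deliberately conservative for panels of more than two raters, whose
#'     count enters as a design descriptor and feasibility check only.}
#'   \item{`"information"`}{the inverse expected Fisher information of
#'     `(prevalence, kappa)` under the Dirichlet-multinomial (common
#'     correlation) model for `raters` ratings per subject; it decreases as
#'     raters are added and gives smaller, anticonservative study sizes.}
#' }
#'
#' @param kappa0 Anticipated agreement, in `(kappaL, 1]`.
#' @param kappaL Lower limit of agreement to assure, `> -1`.
#' @param raters Number of raters per subject (>= 2).
#' @param alpha One-sided type-I level, default 0.05.
#' @param prevalence Assumed binary-trait prevalence, in (0, 1), default 0.5.
#' @param method Variance model, `"pairwise"` or `"information"`.
#' @param n_max Search cap, default `1e6`.
#' @return The required number of subjects (integer).
#' @export
kappa_sample_size <- function(kappa0, kappaL, raters, alpha = 0.05,
                              prevalence = 0.5,
                              method = c("pairwise", "information"),
                              n_max = 1e6) {
  method <- match.arg(method)
  if (!(kappaL > -1 && kappaL < kappa0 && kappa0 <= 1)) {
    stop("need -1 < kappaL < kappa0 <= 1", call. = FALSE)
  }
  if (raters < 2 || raters != round(raters)) {
    stop("raters must be an integer >= 2", call. = FALSE)
  }
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)", call. = FALSE)
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must be in (0, 0.5)", call. = FALSE)
  z <- stats::qnorm(1 - alpha)
  v1 <- switch(method,
    pairwise = pairwise_kappa_var1(kappa0, prevalence),
    information = information_kappa_var1(kappa0, prevalence, raters)
  )
  n <- 2
  while (kappa0 - z * sqrt(v1 / n) < kappaL) {
    n <- n + 1
    if (n > n_max) {
      stop("required sample size exceeds n_max; agreement goal unattainable",
           call. = FALSE)
    }
  }
  as.integer(n)
}

# per-subject variance factor of the binary intraclass kappa estimator
pairwise_kappa_var1 <- function(kappa, prevalence) {
  p <- prevalence
  q <- 1 - p
  (1 - kappa) * ((1 - kappa) * (1 - 2 * kappa) + kappa * (2 - kappa) / (2 * p * q))
}

# Dirichlet-multinomial (Polya) probability of x successes among m ratings
polya_logp <- function(x, m, prevalence, kappa) {
  a <- prevalence * (1 - kappa)
  b <- (1 - prevalence) * (1 - kappa)
  num1 <- if (x > 0) sum(log(a + (0:(x - 1)) * kappa)) else 0
  num2 <- if (m - x > 0) sum(log(b + (0:(m - x - 1)) * kappa)) else 0
  den <- sum(log((1 - kappa) + (0:(m - 1)) * kappa))
  lchoose(m, x) + num1 + num2 - den
}

# per-subject variance factor from inverse expected Fisher information
information_kappa_var1 <- function(kappa, prevalence, m, h = 1e-5) {
  info <- matrix(0, 2, 2)
  for (x in 0:m) {
    p <- exp(polya_logp(x, m, prevalence, kappa))
    g <- c(
      (polya_logp(x, m, prevalence + h, kappa) -
         polya_logp(x, m, prevalence - h, kappa)) / (2 * h),
      (polya_logp(x, m, prevalence, kappa + h) -
         polya_logp(x, m, prevalence, kappa - h)) / (2 * h)
    )
    info <- info + p * (g %o% g)
  }
  solve(info)[2, 2]
}
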