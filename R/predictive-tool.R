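#' Feature encoding for the predictive tool
#'
#' The tool scores five histological features per slide: four yes/no features
#' (urothelial ulceration, submucosal lymphoid aggregates, neutrophilic
#' submucosal inflammation, urothelial inflammation) and the amount of
#' submucosal hemorrhage on an ordered level set, by default
#' mild/moderate/severe. The design encoding is an intercept, one 0/1
#' indicator per binary feature, and treatment-coded hemorrhage indicators
#' with the lowest level as baseline. A 4-level hemorrhage set including
#' "none" can be configured for designs that record absent hemorrhage
#' explicitly.
#'
#' @param hemorrhage_levels Ordered hemorrhage level set; the first level is
#'   the encoding baseline.
#' @return An object of class `feature_encoding`.
#' @export
feature_encoding <- function(hemorrhage_levels = c("mild", "moderate", "severe")) {
  hemorrhage_levels <- tolower(hemorrhage_levels)
  if (length(hemorrhage_levels) < 2 || anyDuplicated(hemorrhage_levels)) {
    stop("hemorrhage_levels must be >= 2 distinct levels", call. = FALSE)
  }
  structure(
    list(binary = c("urothelial_ulceration", "submucosal_lymphoid_aggregates",
                    "neutrophilic_submucosal_inflammation", "urothelial_inflammation"),
         hemorrhage_levels = hemorrhage_levels),
    class = "feature_encoding"
  )
}

#' Outcome classes of the predictive tool
#'
#' The tool predicts cystitis, neoplasia and urolithiasis against a combined
#' baseline class `normal_other` (normal and 'other' pooled, reflecting the
#' low case numbers in both).
#'
#' @return Character vector, baseline class first.
#' @export
tool_classes <- function() {
  c("normal_other", "cystitis", "neoplasia", "urolithiasis")
}

#' Collapse raw diagnoses to the tool's outcome classes
#'
#' @param diagnosis Character vector of diagnosis labels.
#' @return Character vector over [tool_classes()].
#' @export
collapse_diagnosis <- function(diagnosis) {
  d <- canonical_label(diagnosis, c(diagnosis_levels(), "normal_other"), "diagnosis")
  ifelse(d %in% c("normal", "other"), "normal_other", d)
}

yesno_to01 <- function(x, field) {
  if (is.logical(x)) return(as.numeric(x))
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stop("invalid value for ", field, call. = FALSE)
    return(as.numeric(x))
  }
  x <- tolower(trimws(as.character(x)))
  if (!all(x %in% c("yes", "no", "true", "false", "1", "0"))) {
    stop("invalid yes/no value for ", field, ": ",
         paste(setdiff(unique(x), c("yes", "no")), collapse = ", "), call. = FALSE)
  }
  as.numeric(x %in% c("yes", "true", "1"))
}

#' Encode feature vectors into the tool's design matrix
#'
#' @param v A data.frame (one row per case) or list with the four binary
#'   feature fields and `submucosal_hemorrhage`; binary values may be
#'   yes/no, TRUE/FALSE or 0/1.
#' @param encoding A [feature_encoding()].
#' @return A numeric design matrix: `intercept`, four 0/1 indicators, and
#'   `L - 1` hemorrhage level indicators.
#' @export
encode_features <- function(v, encoding = feature_encoding()) {
  v <- as.data.frame(v, stringsAsFactors = FALSE)
  need <- c(encoding$binary, "submucosal_hemorrhage")
  miss <- setdiff(need, names(v))
  if (length(miss) > 0) {
    stop("feature field(s) missing: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- nrow(v)
  X <- matrix(0, nrow = n, ncol = 1 + length(encoding$binary) +
                length(encoding$hemorrhage_levels) - 1)
  lev <- encoding$hemorrhage_levels
  colnames(X) <- c("intercept", encoding$binary,
                   paste0("hemorrhage_", lev[-1]))
  X[, "intercept"] <- 1
  for (b in encoding$binary) X[, b] <- yesno_to01(v[[b]], b)
  hem <- tolower(trimws(as.character(v$submucosal_hemorrhage)))
  bad <- !(hem %in% lev)
  if (any(bad)) {
    stop("unknown hemorrhage level(s): ", paste(unique(hem[bad]), collapse = ", "),
         "; configured levels: ", paste(lev, collapse = ", "), call. = FALSE)
  }
  for (l in lev[-1]) X[, paste0("hemorrhage_", l)] <- as.numeric(hem == l)
  X
}

# multinomial log-likelihood pieces; beta is (k-1) x p, baseline row omitted.
multinom_probs <- function(X, beta) {
  eta <- X %*% t(beta)                      # n x (k-1)
  eta <- cbind(0, eta)                      # baseline
  eta <- eta - apply(eta, 1, max)           # overflow guard
  num <- exp(eta)
  num / rowSums(num)
}

multinom_loglik <- function(X, Y, beta, ridge = 0) {
  P <- multinom_probs(X, beta)
  sum(log(pmax(P[cbind(seq_len(nrow(X)), Y)], 1e-300))) - 0.5 * ridge * sum(beta^2)
}

# gradient and observed information of the (penalized) multinomial loglik
multinom_score <- function(X, Yind, beta, ridge) {
  p <- ncol(X)
  nc <- nrow(beta)
  P <- multinom_probs(X, beta)
  grad <- numeric(nc * p)
  info <- matrix(0, nc * p, nc * p)
  for (c in seq_len(nc)) {
    idx_c <- (c - 1) * p + seq_len(p)
    grad[idx_c] <- crossprod(X, Yind[, c] - P[, c + 1]) - ridge * beta[c, ]
    for (d in seq_len(c)) {
      idx_d <- (d - 1) * p + seq_len(p)
      w <- P[, c + 1] * ((c == d) - P[, d + 1])
      blk <- crossprod(X, X * w)
      info[idx_c, idx_d] <- blk
      info[idx_d, idx_c] <- t(blk)
    }
  }
  diag(info) <- diag(info) + ridge
  list(grad = grad, info = info)
}

# Newton-Raphson fit; Y integer class index 1..k (1 = baseline).
multinom_newton <- function(X, Y, k, ridge = 0, max_iter = 100, tol = 1e-10) {
  p <- ncol(X)
  nc <- k - 1
  beta <- matrix(0, nrow = nc, ncol = p)
  Yind <- matrix(0, nrow = nrow(X), ncol = nc)
  for (c in seq_len(nc)) Yind[, c] <- as.numeric(Y == c + 1)
  ll <- multinom_loglik(X, Y, beta, ridge)
  converged <- FALSE
  diverged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    sc <- multinom_score(X, Yind, beta, ridge)
    step <- tryCatch(solve(sc$info, sc$grad), error = function(e) NULL)
    if (is.null(step)) { diverged <- TRUE; break }
    # step-halving to keep the (penalized) log-likelihood non-decreasing
    alpha <- 1
    repeat {
      cand <- beta + alpha * matrix(step, nrow = nc, ncol = p, byrow = TRUE)
      ll_new <- multinom_loglik(X, Y, cand, ridge)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-8) break
    }
    beta <- cand
    moved <- ll_new - ll
    ll <- ll_new
    if (max(abs(beta)) > 15 && ridge == 0) { diverged <- TRUE; break }
    if (max(abs(sc$grad)) < 1e-6 && abs(moved) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
  }
  info <- multinom_score(X, Yind, beta, ridge)$info
  list(beta = beta, loglik = multinom_loglik(X, Y, beta, 0),
       penalized_loglik = ll, info = info,
       converged = converged, diverged = diverged, iterations = iter)
}

#' Fit the multinomial-logistic predictive model
#'
#' Maximizes the multinomial log-likelihood of the collapsed diagnosis
#' (baseline `normal_other`) on the encoded histological features by Newton
#' iteration, with `P(y = c | x) = exp(x b_c) / (1 + sum_c' exp(x b_c'))`.
#' If the fit shows quasi-separation (diverging coefficients or failure to
#' converge), it is refit with a small ridge penalty (default `1e-4`) and the
#' penalty is recorded. The coefficient covariance is the inverse observed
#' information at the optimum.
#'
#' Species is handled either as an additional 0/1 indicator column in one
#' joint model (default; fewer parameters at small n) or as two independent
#' per-species fits (`species = "stratified"`).
#'
#' @param cases A data.frame with `species`, the five feature fields of
#'   [feature_encoding()], and `diagnosis` (raw or already collapsed).
#' @param encoding A [feature_encoding()].
#' @param species `"indicator"` or `"stratified"`.
#' @param ridge Ridge penalty applied from the start (0 = plain ML).
#' @param auto_ridge Penalty used for the automatic refit on separation.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `tool_model`: coefficients `beta` (one row per
#'   non-baseline class), `covariance`, `encoding`, `classes`, `loglik`,
#'   `null_loglik`, `iterations`, `converged`, `penalty`; stratified fits
#'   carry one such model per species in `$models`.
#' @export
fit_diagnosis_model <- function(cases, encoding = feature_encoding(),
                                species = c("indicator", "stratified"),
                                ridge = 0, auto_ridge = 1e-4, max_iter = 100) {
  species <- match.arg(species)
  cases <- as.data.frame(cases, stringsAsFactors = FALSE)
  cases$species <- canonical_label(cases$species, species_levels(), "species")
  y <- collapse_diagnosis(cases$diagnosis)
  cls <- tool_classes()
  absent <- setdiff(cls, unique(y))
  if (length(absent) > 0) {
    stop("no cases in outcome class(es): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (species == "stratified") {
    models <- lapply(species_levels(), function(sp) {
      sub <- cases[cases$species == sp, , drop = FALSE]
      sub_absent <- setdiff(cls, unique(collapse_diagnosis(sub$diagnosis)))
      if (length(sub_absent) > 0) {
        stop(sprintf("species %s has no cases in outcome class(es): %s",
                     sp, paste(sub_absent, collapse = ", ")), call. = FALSE)
      }
      fit_tool_fitted(encode_features(sub, encoding),
                      collapse_diagnosis(sub$diagnosis), cls, encoding,
                      ridge, auto_ridge, max_iter)
    })
    names(models) <- species_levels()
    return(structure(list(models = models, encoding = encoding,
                          classes = cls, species = "stratified"),
                     class = "tool_model"))
  }
  X <- cbind(encode_features(cases, encoding),
             species_feline = as.numeric(cases$species == "feline"))
  fit_tool_fitted(X, y, cls, encoding, ridge, auto_ridge, max_iter)
}

# core fit on an explicit design matrix; used for both joint and stratified fits
fit_tool_fitted <- function(X, y, cls, encoding, ridge, auto_ridge, max_iter) {
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient after encoding", call. = FALSE)
  }
  Y <- match(y, cls)
  fit <- multinom_newton(X, Y, k = length(cls), ridge = ridge,
                         max_iter = max_iter)
  penalty <- ridge
  if (!fit$converged) {
    penalty <- if (ridge > 0) ridge else auto_ridge
    fit <- multinom_newton(X, Y, k = length(cls), ridge = penalty,
                           max_iter = max_iter)
    if (!fit$converged) {
      stop(sprintf(
        "multinomial fit did not converge after %d iterations (ridge %.2g, max |beta| %.2f)",
        fit$iterations, penalty, max(abs(fit$beta))), call. = FALSE)
    }
  }
  covariance <- tryCatch(solve(fit$info), error = function(e) {
    stop("observed information is singular at the optimum", call. = FALSE)
  })
  covariance <- (covariance + t(covariance)) / 2
  cn <- colnames(X)
  dimnames(fit$beta) <- list(cls[-1], cn)
  theta_names <- as.vector(vapply(cls[-1], function(c) paste(c, cn, sep = ":"),
                                  character(length(cn))))
  dimnames(covariance) <- list(theta_names, theta_names)
  tab <- table(factor(y, levels = cls))
  null_loglik <- sum(tab * log(tab / sum(tab)))
  structure(
    list(beta = fit$beta, covariance = covariance, encoding = encoding,
         classes = cls,
         species = if ("species_feline" %in% cn) "indicator" else "single",
         loglik = fit$loglik,
         null_loglik = null_loglik, iterations = fit$iterations,
         converged = fit$converged, penalty = penalty, n = nrow(X)),
    class = "tool_model"
  )
}

#' @export
print.tool_model <- function(x, ...) {
  if (identical(x$species, "stratified")) {
    cat("<tool_model> stratified by species\n")
    for (sp in names(x$models)) {
      cat("--", sp, "--\n")
      print(x$models[[sp]])
    }
    return(invisible(x))
  }
  cat(sprintf(
    "<tool_model> multinomial logit, baseline %s; n = %d, logLik = %.2f (null %.2f), %d iterations%s\n",
    x$classes[1], x$n, x$loglik, x$null_loglik, x$iterations,
    if (x$penalty > 0) sprintf(", ridge penalty %.2g", x$penalty) else ""))
  print(round(x$beta, 3))
  invisible(x)
}

model_design_row <- function(model, v) {
  x <- encode_features(v, model$encoding)
  if ("species_feline" %in% colnames(model$beta)) {
    x <- cbind(x, species_feline = as.numeric(
      canonical_label(v$species, species_levels(), "species") == "feline"))
  }
  x
}

#' Predict per-disease probabilities with delta-method confidence limits
#'
#' Softmax probabilities over the four outcome classes for one feature
#' vector, with normal-theory confidence limits propagated from the
#' coefficient covariance by the delta method: for each class probability the
#' gradient `g` with respect to the full coefficient vector gives variance
#' `g' Sigma g`; limits are clipped to `[0, 1]`.
#'
#' @param model A [fit_diagnosis_model()] result.
#' @param v A one-row data.frame (or list) with `species` and the five
#'   feature fields.
#' @param level Confidence level, default 0.95.
#' @return A data.frame of class `disease_probabilities` with columns
#'   `class`, `probability`, `lower`, `upper` (diseases first, baseline
#'   `normal_other` last).
#' @export
predict_probs <- function(model, v, level = 0.95) {
  v <- as.data.frame(v, stringsAsFactors = FALSE)
  if (nrow(v) != 1) stop("predict_probs takes a single feature vector", call. = FALSE)
  if (identical(model$species, "stratified")) {
    sp <- canonical_label(v$species, species_levels(), "species")
    return(predict_probs(model$models[[sp]], v, level = level))
  }
  x <- drop(model_design_row(model, v))
  if (length(x) != ncol(model$beta)) {
    stop("feature vector does not match the model encoding", call. = FALSE)
  }
  cls <- model$classes
  nc <- length(cls) - 1
  p_len <- ncol(model$beta)
  eta <- c(0, drop(model$beta %*% x))
  eta <- eta - max(eta)
  probs <- exp(eta) / sum(exp(eta))        # baseline first
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- lapply(seq_along(cls), function(ci) {
    p_c <- probs[ci]
    g <- numeric(nc * p_len)
    for (cp in seq_len(nc)) {
      delta <- as.numeric(ci == cp + 1)
      g[(cp - 1) * p_len + seq_len(p_len)] <- p_c * (delta - probs[cp + 1]) * x
    }
    se <- sqrt(max(drop(t(g) %*% model$covariance %*% g), 0))
    data.frame(class = cls[ci], probability = p_c,
               lower = max(p_c - z * se, 0), upper = min(p_c + z * se, 1),
               se = se, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[c(2:nrow(out), 1), ]          # diseases first, baseline last
  rownames(out) <- NULL
  attr(out, "level") <- level
  class(out) <- c("disease_probabilities", "data.frame")
  out
}

#' Enumerate the exhaustive per-species probability lookup table
#'
#' One row per feature combination (2^4 binary combinations times the
#' hemorrhage levels; 48 rows under the default encoding), each carrying the
#' [predict_probs()] probabilities and confidence limits for the given
#' species. Rows are ordered deterministically: binary features
#' most-significant-first, hemorrhage level last (fastest varying). This is
#' the table a spreadsheet front end would hide behind the rater's answers.
#'
#' @inheritParams predict_probs
#' @param species `"canine"` or `"feline"`.
#' @return A data.frame of class `lookup_table`: feature columns followed by
#'   `<class>_prob`, `<class>_lower`, `<class>_upper` per outcome class.
#' @export
enumerate_lookup <- function(model, species, level = 0.95) {
  species <- match.arg(species, species_levels())
  enc <- model$encoding
  b <- enc$binary
  grid <- expand.grid(
    submucosal_hemorrhage = enc$hemorrhage_levels,
    rev4 = c("no", "yes"), rev3 = c("no", "yes"),
    rev2 = c("no", "yes"), rev1 = c("no", "yes"),
    stringsAsFactors = FALSE
  )
  names(grid)[2:5] <- rev(b)
  grid <- grid[, c(b, "submucosal_hemorrhage")]
  rownames(grid) <- NULL
  cls <- c(setdiff(tool_classes(), "normal_other"), "normal_other")
  prob_cols <- lapply(seq_len(nrow(grid)), function(i) {
    v <- cbind(species = species, grid[i, , drop = FALSE])
    pp <- predict_probs(model, v, level = level)
    stats::setNames(
      as.numeric(t(as.matrix(pp[match(cls, pp$class), c("probability", "lower", "upper")]))),
      as.vector(t(outer(cls, c("prob", "lower", "upper"), paste, sep = "_"))))
  })
  out <- cbind(species = species, grid,
               as.data.frame(do.call(rbind, prob_cols)))
  rownames(out) <- NULL
  attr(out, "level") <- level
  class(out) <- c("lookup_table", "data.frame")
  out
}

#' Write a lookup table to CSV or JSON
#'
#' @param lookup An [enumerate_lookup()] result.
#' @param path Output file.
#' @param format `"csv"` or `"json"`.
#' @export
write_lookup <- function(lookup, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(lookup), path, row.names = FALSE)
  } else {
    jsonlite::write_json(as.data.frame(lookup), path, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Simulate cases from a known coefficient matrix
#'
#' Draws feature vectors (independent balanced binary features, uniform
#' hemorrhage levels, Bernoulli species) and samples the collapsed diagnosis
#' from the multinomial-logit probabilities implied by `beta`. Used to
#' validate parameter and probability recovery of [fit_diagnosis_model()].
#'
#' @param n Number of cases.
#' @param beta Coefficient matrix, 3 rows (cystitis, neoplasia, urolithiasis)
#'   by `p` design columns (intercept, 4 binaries, hemorrhage indicators,
#'   species indicator last).
#' @param encoding A [feature_encoding()].
#' @param seed Integer seed.
#' @return A case data.frame suitable for [fit_diagnosis_model()].
#' @export
simulate_cases <- function(n, beta, encoding = feature_encoding(), seed = 1L) {
  with_seed(seed, {
    b <- encoding$binary
    v <- data.frame(
      species = sample(species_levels(), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    for (f in b) v[[f]] <- sample(c("no", "yes"), n, replace = TRUE)
    v$submucosal_hemorrhage <- sample(encoding$hemorrhage_levels, n, replace = TRUE)
    X <- cbind(encode_features(v, encoding),
               species_feline = as.numeric(v$species == "feline"))
    P <- multinom_probs(X, beta)
    cls <- tool_classes()
    v$diagnosis <- vapply(seq_len(n),
                          function(i) sample(cls, 1, prob = P[i, ]),
                          character(1))
    v
  })
}
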