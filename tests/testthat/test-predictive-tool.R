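# committed "moderate effects" generator used across tool tests
tool_beta <- rbind(
  cystitis     = c(-0.5, 1.0, 0.5, 1.2, 1.0, 0.4, 0.8, 0.3),
  neoplasia    = c(-1.0, 1.5, -0.8, -0.5, 0.0, 0.5, 0.9, -0.2),
  urolithiasis = c(-0.8, 1.2, 0.0, 0.3, 0.2, 0.8, 1.2, 0.5))

baseline_case <- function(...) {
  v <- data.frame(species = "canine", urothelial_ulceration = "no",
                  submucosal_lymphoid_aggregates = "no",
                  neutrophilic_submucosal_inflammation = "no",
                  urothelial_inflammation = "no",
                  submucosal_hemorrhage = "mild", stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) v[[nm]] <- mods[[nm]]
  v
}

test_that("feature encoding produces the documented design columns", {
  x <- encode_features(baseline_case())
  expect_equal(unname(drop(x)), c(1, 0, 0, 0, 0, 0, 0))
  x2 <- drop(encode_features(baseline_case(urothelial_ulceration = "yes",
                                           submucosal_hemorrhage = "severe")))
  expect_equal(x2[["intercept"]], 1)
  expect_equal(x2[["urothelial_ulceration"]], 1)
  expect_equal(x2[["hemorrhage_severe"]], 1)
  expect_equal(sum(x2), 3)

  expect_error(encode_features(baseline_case(submucosal_hemorrhage = "none")),
               "unknown hemorrhage level")
  enc4 <- feature_encoding(c("none", "mild", "moderate", "severe"))
  expect_equal(ncol(encode_features(baseline_case(submucosal_hemorrhage = "none"), enc4)), 8)
})

test_that("the Newton fit agrees with an independent multinomial fitter", {
  cases <- simulate_cases(800, tool_beta, seed = 3)
  mod <- fit_diagnosis_model(cases)
  df <- cases
  df$y <- factor(collapse_diagnosis(df$diagnosis), levels = tool_classes())
  df$hem <- factor(df$submucosal_hemorrhage, levels = c("mild", "moderate", "severe"))
  nn <- nnet::multinom(
    y ~ urothelial_ulceration + submucosal_lymphoid_aggregates +
      neutrophilic_submucosal_inflammation + urothelial_inflammation + hem + species,
    data = df, trace = FALSE, maxit = 500, reltol = 1e-12)
  expect_equal(unname(mod$beta), unname(coef(nn)), tolerance = 1e-4)
  expect_equal(mod$loglik, as.numeric(stats::logLik(nn)), tolerance = 1e-6)
})

test_that("null data give near-uniform fitted probabilities and loglik dominates the null", {
  cases <- simulate_cases(2000, matrix(0, 3, 8), seed = 9)
  mod <- fit_diagnosis_model(cases)
  freq <- as.numeric(table(factor(collapse_diagnosis(cases$diagnosis),
                                  levels = tool_classes()))) / nrow(cases)
  for (v in list(baseline_case(),
                 baseline_case(species = "feline", urothelial_ulceration = "yes",
                               submucosal_hemorrhage = "severe"))) {
    pp <- predict_probs(mod, v)
    got <- pp$probability[match(tool_classes(), pp$class)]
    # recovery within sampling error: 4 delta-method SEs at this design point
    expect_lt(max(abs(got - freq) / pp$se[match(tool_classes(), pp$class)]), 4)
  }
  expect_gte(mod$loglik, mod$null_loglik)
})

test_that("a perfectly separating feature triggers the recorded ridge path", {
  cases <- simulate_cases(300, tool_beta, seed = 5)
  cases$urothelial_ulceration <-
    ifelse(collapse_diagnosis(cases$diagnosis) == "neoplasia", "yes", "no")
  mod <- fit_diagnosis_model(cases)
  expect_true(mod$converged)
  expect_gt(mod$penalty, 0)
})

test_that("single-class data and rank-deficient designs are errors", {
  cases <- simulate_cases(50, tool_beta, seed = 2)
  cases$diagnosis <- "cystitis"
  expect_error(fit_diagnosis_model(cases), "no cases in outcome class")
})

test_that("all-zero coefficients predict 0.25 per class and probabilities always sum to 1", {
  cases <- simulate_cases(400, tool_beta, seed = 4)
  mod <- fit_diagnosis_model(cases)
  zero <- mod
  zero$beta[] <- 0
  pp <- predict_probs(zero, baseline_case(species = "feline"))
  expect_equal(pp$probability, rep(0.25, 4))
  pp2 <- predict_probs(mod, baseline_case(submucosal_hemorrhage = "moderate"))
  expect_equal(sum(pp2$probability), 1, tolerance = 1e-12)
  expect_true(all(pp2$lower <= pp2$probability & pp2$probability <= pp2$upper))
  expect_true(all(pp2$lower >= 0 & pp2$upper <= 1))
})

test_that("increasing a coefficient increases the class probability when the feature is on", {
  cases <- simulate_cases(400, tool_beta, seed = 6)
  mod <- fit_diagnosis_model(cases)
  v <- baseline_case(urothelial_ulceration = "yes")
  p0 <- predict_probs(mod, v)
  bumped <- mod
  bumped$beta["cystitis", "urothelial_ulceration"] <-
    bumped$beta["cystitis", "urothelial_ulceration"] + 0.5
  p1 <- predict_probs(bumped, v)
  expect_gt(p1$probability[p1$class == "cystitis"],
            p0$probability[p0$class == "cystitis"])
})

test_that("the lookup table enumerates every combination once and matches predict_probs", {
  cases <- simulate_cases(600, tool_beta, seed = 8)
  mod <- fit_diagnosis_model(cases)
  lk <- enumerate_lookup(mod, "feline")
  expect_equal(nrow(lk), 48)
  feat_cols <- c(feature_encoding()$binary, "submucosal_hemorrhage")
  expect_false(any(duplicated(lk[, feat_cols])))
  probs <- as.matrix(lk[, paste0(tool_classes(), "_prob")])
  expect_lt(max(abs(rowSums(probs) - 1)), 1e-10)
  i <- 17
  pp <- predict_probs(mod, cbind(species = "feline", lk[i, feat_cols]))
  expect_equal(lk$cystitis_prob[i], pp$probability[pp$class == "cystitis"])
  expect_equal(lk$normal_other_upper[i], pp$upper[pp$class == "normal_other"])
})

test_that("stratified species fits predict from the matching per-species model", {
  cases <- simulate_cases(1200, tool_beta, seed = 10)
  mod <- fit_diagnosis_model(cases, species = "stratified")
  expect_named(mod$models, species_levels())
  v <- baseline_case(species = "feline", urothelial_inflammation = "yes")
  joint <- predict_probs(mod$models$feline, v)
  via_wrapper <- predict_probs(mod, v)
  expect_equal(via_wrapper, joint)
})
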