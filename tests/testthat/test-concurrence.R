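ref4 <- reference_table(data.frame(
  slide_id = c("s1", "s2", "s3", "s4"), species = "canine",
  diagnosis = c("cystitis", "cystitis", "normal", "neoplasia")))

test_that("remove_other drops whole slides within a stratum and is idempotent", {
  tab <- make_ratings(slides = paste0("s", 1:4), raters = paste0("P", 1:4),
                      diagnoses = c("cystitis", "cystitis", "other", "cystitis",
                                    rep("cystitis", 4),
                                    rep("normal", 4),
                                    rep("neoplasia", 4)))
  out <- remove_other(tab, ref4)
  expect_false("s1" %in% out$slide_id)  # P3 chose 'other' on s1
  expect_equal(sort(unique(out$slide_id)), c("s2", "s3", "s4"))
  expect_equal(attr(out, "removed")$slides_removed, 1)
  strip <- function(x) {
    attr(x, "removed") <- NULL
    as.data.frame(x)
  }
  again <- remove_other(out, ref4)
  expect_equal(strip(again), strip(out))

  clean <- make_ratings(slides = "s2", raters = paste0("P", 1:4),
                        diagnoses = rep("cystitis", 4))
  expect_equal(strip(remove_other(clean)), as.data.frame(clean))

  all_other <- make_ratings(slides = c("s1", "s2"), raters = c("P1", "P2"),
                            diagnoses = c("other", "cystitis", "cystitis", "other"))
  expect_error(remove_other(all_other), "every slide in stratum")
})

test_that("'other' removal is stratum-local: a slide survives in clean strata", {
  two_cond <- rbind(
    data.frame(slide_id = "s1", species = "canine", rater_id = c("P1", "P2"),
               condition = "no_info", medium = "wsi",
               diagnosis = c("other", "cystitis")),
    data.frame(slide_id = c("s1", "s2"), species = "canine",
               rater_id = rep(c("P1", "P2"), each = 2),
               condition = "predictive_tool", medium = "wsi",
               diagnosis = "cystitis"),
    data.frame(slide_id = "s2", species = "canine", rater_id = c("P1", "P2"),
               condition = "no_info", medium = "wsi", diagnosis = "normal"))
  out <- remove_other(rating_table(two_cond))
  expect_false(any(out$slide_id == "s1" & out$condition == "no_info"))
  expect_true(any(out$slide_id == "s1" & out$condition == "predictive_tool"))
})

test_that("concurrence proportion, exact limits and errors behave as specified", {
  tab <- make_ratings(slides = paste0("s", 1:4), raters = "P1",
                      diagnoses = c("cystitis", "cystitis", "normal", "urolithiasis"))
  res <- concurrence(tab, ref4)
  expect_equal(res$proportion, 0.75)
  expect_equal(res$n_pairs, 4)
  ok <- stats::binom.test(3, 4)$conf.int
  expect_equal(c(res$lcl, res$ucl), as.numeric(ok))

  perfect <- make_ratings(slides = paste0("s", 1:4), raters = paste0("P", 1:5),
                          diagnoses = rep(c("cystitis", "cystitis", "normal", "neoplasia"),
                                          each = 5))
  pres <- concurrence(perfect, ref4)
  expect_equal(pres$proportion, 1)
  expect_equal(pres$ucl, 1)

  orphan <- make_ratings(slides = "sX", raters = "P1", diagnoses = "cystitis")
  expect_error(concurrence(orphan, ref4), "absent from the reference")
})

test_that("concurrence pools per-rater accuracies weighted by pair counts", {
  fx <- fixture_study("glass")
  tab <- fx$ratings[fx$ratings$condition == "no_info", ]
  class(tab) <- class(fx$ratings)
  tab <- remove_other(tab, fx$reference)
  overall <- concurrence(tab, fx$reference)
  per_rater <- vapply(unique(tab$rater_id), function(r) {
    sub <- tab[tab$rater_id == r, ]
    class(sub) <- class(tab)
    res <- concurrence(sub, fx$reference)
    c(res$matches, res$n_pairs)
  }, numeric(2))
  expect_equal(overall$proportion, sum(per_rater[1, ]) / sum(per_rater[2, ]))
})

test_that("one-vs-rest sensitivity and specificity follow confusion-count arithmetic", {
  # 10 pairs: reference 4 cystitis, 6 normal; rater gets 3 cystitis right,
  # calls one cystitis normal, and one normal cystitis
  ref10 <- reference_table(data.frame(
    slide_id = paste0("s", 1:10), species = "canine",
    diagnosis = c(rep("cystitis", 4), rep("normal", 6))))
  calls <- c("cystitis", "cystitis", "cystitis", "normal",
             "cystitis", rep("normal", 5))
  tab <- make_ratings(slides = paste0("s", 1:10), raters = "P1", diagnoses = calls)
  met <- sensitivity_specificity(tab, ref10)
  expect_equal(met$sensitivity[met$category == "cystitis"], 0.75)
  expect_equal(met$specificity[met$category == "cystitis"], 5 / 6)
  # categories absent from the reference have undefined sensitivity
  expect_true(is.na(met$sensitivity[met$category == "neoplasia"]))
  expect_equal(met$specificity[met$category == "neoplasia"], 1)

  perfect <- make_ratings(slides = paste0("s", 1:10), raters = "P1",
                          diagnoses = ref10$diagnosis)
  pm <- sensitivity_specificity(perfect, ref10)
  expect_true(all(pm$sensitivity[!is.na(pm$sensitivity)] == 1))
  expect_true(all(pm$specificity == 1))
})

test_that("for two categories the metrics equal the brute-force 2x2 table", {
  set.seed(11)
  for (i in 1:20) {
    n <- 30
    ref <- sample(c("cystitis", "normal"), n, replace = TRUE, prob = c(0.4, 0.6))
    call <- ifelse(runif(n) < 0.7, ref, sample(c("cystitis", "normal"), n, replace = TRUE))
    if (length(unique(ref)) < 2) next
    rt <- reference_table(data.frame(slide_id = paste0("s", 1:n),
                                     species = "canine", diagnosis = ref))
    tab <- make_ratings(slides = paste0("s", 1:n), raters = "P1", diagnoses = call)
    met <- sensitivity_specificity(tab, rt, categories = "cystitis")
    tp <- sum(ref == "cystitis" & call == "cystitis")
    fn <- sum(ref == "cystitis" & call != "cystitis")
    tn <- sum(ref != "cystitis" & call != "cystitis")
    fp <- sum(ref != "cystitis" & call == "cystitis")
    expect_equal(met$sensitivity, tp / (tp + fn))
    expect_equal(met$specificity, tn / (tn + fp))
  }
})
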