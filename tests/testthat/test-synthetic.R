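test_that("zero-noise kernels reproduce the reference exactly", {
  noiseless <- lapply(stats::setNames(nm = paste0("P", 1:4)), function(r) {
    lapply(stats::setNames(nm = condition_levels()), function(cc) {
      make_confusion_kernel(1, other_rate = 0, neoplasia_bonus = 0)
    })
  })
  cfg <- sim_config(rater_profiles = noiseless, feature_flip = 0,
                    missing = NULL, media = "wsi", seed = 3)
  s <- simulate_study(cfg)
  ref <- s$reference$diagnosis[match(s$ratings$slide_id, s$reference$slide_id)]
  expect_identical(s$ratings$diagnosis, ref)
  expect_equal(fleiss_kappa(to_count_matrix(s$ratings, "no_info", "wsi"))$kappa, 1)
  expect_equal(concurrence(s$ratings, s$reference)$proportion, 1)
})

test_that("simulation is byte-identical under the same config and seed", {
  a <- simulate_study(sim_config(seed = 21))
  b <- simulate_study(sim_config(seed = 21))
  expect_identical(lapply(a, as.data.frame), lapply(b, as.data.frame))
  c <- simulate_study(sim_config(seed = 22))
  expect_false(identical(as.data.frame(a$ratings), as.data.frame(c$ratings)))
})

test_that("reference class sizes, species mix, media and missingness follow the design", {
  s <- simulate_study(sim_config(seed = 4))
  tab <- table(s$reference$diagnosis)
  expect_equal(as.numeric(tab[c("cystitis", "neoplasia", "urolithiasis", "normal")]),
               c(7, 6, 6, 6))
  expect_false("other" %in% s$reference$diagnosis)
  expect_equal(sum(s$reference$species == "canine"), 2 + 3 + 4 + 4)
  expect_equal(length(unique(s$ratings$slide_id[s$ratings$medium == "glass"])), 22)
  # missingness confined to the configured rater and medium
  na_rows <- s$ratings[is.na(s$ratings$diagnosis), ]
  expect_true(all(na_rows$rater_id == "P4"))
  expect_true(all(na_rows$medium == "wsi"))
})

test_that("invalid confusion kernels are rejected", {
  bad <- default_rater_profiles()
  bad$P1$no_info[1, 1] <- 2
  expect_error(sim_config(rater_profiles = bad), "probability vectors")
})

test_that("more kernel diagonal mass yields higher expected concurrence", {
  mean_conc <- function(acc) {
    prof <- lapply(stats::setNames(nm = paste0("P", 1:4)), function(r) {
      lapply(stats::setNames(nm = condition_levels()), function(cc) {
        make_confusion_kernel(acc, other_rate = 0.02)
      })
    })
    vals <- vapply(1:30, function(i) {
      s <- simulate_study(sim_config(rater_profiles = prof, missing = NULL,
                                     media = "wsi", seed = 400 + i))
      scored <- remove_other(s$ratings, s$reference)
      concurrence(scored, s$reference)$proportion
    }, numeric(1))
    mean(vals)
  }
  accs <- c(0.4, 0.6, 0.8)
  res <- vapply(accs, mean_conc, numeric(1))
  expect_true(all(diff(res) > 0))
})

test_that("fixture marginal counts equal the published tables cell for cell", {
  expected <- pathagree:::fixture_marginals()
  for (med in medium_levels()) {
    fx <- fixture_study(med)
    m <- marginal_counts(fx$ratings, med)
    for (cond in condition_levels()) {
      for (r in paste0("P", 1:4)) {
        expect_equal(unname(m[diagnosis_levels(), r, cond]),
                     unname(expected[[med]][[cond]][r, ]),
                     label = sprintf("%s/%s/%s", med, cond, r))
      }
    }
  }
})

test_that("fixture missing cells sit where the published totals say", {
  wsi <- fixture_study("wsi")$ratings
  m <- marginal_counts(wsi, "wsi")
  expect_equal(unname(m["total", "P4", ]), c(19, 21, 19))
  expect_equal(unname(m["total", "P1", ]), c(25, 25, 25))
  glass <- fixture_study("glass")$ratings
  mg <- marginal_counts(glass, "glass")
  expect_equal(unname(mg["total", "P1", ]), c(22, 21, 22))
  expect_equal(sum(is.na(glass$diagnosis)), 1)
})

test_that("a YAML config round-trips into an equivalent simulation", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 12",
    "feature_flip: 0.05",
    "media: [wsi]",
    "missing: ~",
    "accuracies: {no_info: 0.5, signalment_history: 0.6, predictive_tool: 0.7}",
    "rater_offsets: {P1: 0.0, P2: 0.0, P3: 0.0, P4: 0.0}"), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_null(cfg$missing)
  direct <- sim_config(
    rater_profiles = default_rater_profiles(
      accuracies = c(no_info = 0.5, signalment_history = 0.6, predictive_tool = 0.7),
      rater_offsets = c(P1 = 0, P2 = 0, P3 = 0, P4 = 0)),
    feature_flip = 0.05, missing = NULL, media = "wsi", seed = 12)
  expect_identical(as.data.frame(simulate_study(cfg)$ratings),
                   as.data.frame(simulate_study(direct)$ratings))
})
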