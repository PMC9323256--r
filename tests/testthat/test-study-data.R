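test_that("labels are canonicalized case-insensitively and unknown labels are rejected", {
  tab <- rating_table(data.frame(
    slide_id = "s1", species = "Canine", rater_id = "P1",
    condition = "No_Info", medium = "WSI", diagnosis = "Cystitis"))
  expect_equal(tab$diagnosis, "cystitis")
  expect_equal(tab$species, "canine")
  expect_equal(tab$condition, "no_info")

  expect_error(
    rating_table(data.frame(slide_id = "s1", species = "canine", rater_id = "P1",
                            condition = "no_info", medium = "wsi",
                            diagnosis = "carcinoma")),
    "valid labels.*cystitis")
})

test_that("duplicate (slide, rater, condition, medium) cells are rejected by name", {
  df <- data.frame(slide_id = c("s1", "s1"), species = "canine",
                   rater_id = "P1", condition = "no_info", medium = "wsi",
                   diagnosis = c("cystitis", "normal"))
  expect_error(rating_table(df), "duplicate rating.*slide_id=s1.*rater_id=P1")
})

test_that("rating tables round-trip through CSV, preserving missing cells", {
  fx <- fixture_study("wsi")
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratings(fx$ratings, path, comment = "round-trip check")
  back <- read_ratings(path)
  expect_equal(as.data.frame(back), as.data.frame(fx$ratings))

  rpath <- withr::local_tempfile(fileext = ".csv")
  write_reference(fx$reference, rpath)
  expect_equal(as.data.frame(read_reference(rpath)), as.data.frame(fx$reference))
})

test_that("bundled fixture files load to the full slide x rater x condition grid", {
  wsi <- read_ratings(system.file("extdata", "fixture_wsi_ratings.csv",
                                  package = "pathagree"))
  expect_equal(nrow(wsi), 25 * 4 * 3)
  expect_equal(as.data.frame(wsi), as.data.frame(fixture_study("wsi")$ratings))

  glass <- read_ratings(system.file("extdata", "fixture_glass_ratings.csv",
                                    package = "pathagree"))
  expect_equal(length(unique(glass$slide_id)), 22)
  expect_equal(nrow(glass), 22 * 4 * 3)
})

test_that("to_count_matrix counts raters per category and enforces completeness", {
  tab <- make_ratings(slides = c("s1", "s2"), raters = c("r1", "r2"),
                      diagnoses = c("cystitis", "cystitis", "cystitis", "normal"))
  cm <- to_count_matrix(tab, "no_info", "wsi")
  expect_equal(unname(cm["s1", ]), c(2, 0, 0, 0, 0))
  expect_equal(unname(cm["s2", ]), c(1, 0, 0, 1, 0))
  expect_equal(attr(cm, "m"), 2L)

  tab$diagnosis[4] <- NA
  expect_error(to_count_matrix(tab, "no_info", "wsi"), "impute")

  glass <- fixture_study("glass")$ratings
  cm <- to_count_matrix(glass, "no_info", "glass")
  expect_equal(dim(cm), c(22L, 5L))
  expect_true(all(rowSums(cm) == 4))
})

test_that("marginal counts reproduce the published digital no-information column set", {
  fx <- fixture_study("wsi")
  m <- marginal_counts(fx$ratings, "wsi")
  expect_equal(unname(m["cystitis", , "no_info"]), c(7, 14, 17, 6))
  expect_equal(unname(m["total", "P4", "no_info"]), 19)
  # empty table gives all-zero counts
  empty <- fx$ratings[0, , drop = FALSE]
  class(empty) <- class(fx$ratings)
  expect_equal(sum(marginal_counts(empty, "wsi")), 0)
})

test_that("marginal counts summed over categories equal the non-missing cell count", {
  for (med in medium_levels()) {
    fx <- fixture_study(med)
    m <- marginal_counts(fx$ratings, med)
    cats <- diagnosis_levels()
    for (r in dimnames(m)[[2]]) {
      for (cond in condition_levels()) {
        nonmiss <- sum(fx$ratings$rater_id == r & fx$ratings$condition == cond &
                         fx$ratings$medium == med & !is.na(fx$ratings$diagnosis))
        expect_equal(sum(m[cats, r, cond]), nonmiss)
        expect_equal(m["total", r, cond], sum(m[cats, r, cond]))
      }
    }
  }
})

test_that("count-matrix column sums yield a probability vector over categories", {
  set.seed(42)
  for (i in 1:20) {
    cm <- panel_to_counts(random_panel(sample(2:8, 1), sample(2:5, 1), 4), 4)
    p <- colSums(cm) / sum(cm)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(sum(p), 1)
  }
})
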