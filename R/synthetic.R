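#' Build a rater confusion kernel
#'
#' A confusion kernel gives, per true (reference) diagnosis, the probability
#' of each reported diagnosis including 'other'. The default shape reflects
#' how bladder histology is actually confused: neoplasia is recognised well,
#' while cystitis, urolithiasis and normal tissue are confused among each
#' other (their histological pictures overlap), and a small mass goes to
#' 'other'.
#'
#' @param accuracy Diagonal (correct-report) probability for cystitis,
#'   urolithiasis and normal.
#' @param other_rate Probability of reporting 'other' for any true class.
#' @param neoplasia_bonus Added to `accuracy` for true neoplasia (capped at
#'   `0.97`).
#' @return A 4 x 5 row-stochastic matrix, rows cystitis/neoplasia/
#'   urolithiasis/normal, columns [diagnosis_levels()].
#' @export
make_confusion_kernel <- function(accuracy, other_rate = 0.05,
                                  neoplasia_bonus = 0.2) {
  if (accuracy < 0 || other_rate < 0 || accuracy + other_rate > 1) {
    stop("need accuracy >= 0, other_rate >= 0, accuracy + other_rate <= 1",
         call. = FALSE)
  }
  cats <- diagnosis_levels()
  true_cls <- setdiff(cats, "other")
  confusable <- c("cystitis", "urolithiasis", "normal")
  Q <- matrix(0, nrow = 4, ncol = 5, dimnames = list(true_cls, cats))
  for (t in true_cls) {
    acc <- if (t == "neoplasia") min(accuracy + neoplasia_bonus, 1 - other_rate) else accuracy
    oth <- min(other_rate, 1 - acc)
    Q[t, t] <- acc
    Q[t, "other"] <- oth
    rest <- 1 - acc - oth
    spread <- if (t == "neoplasia") confusable else setdiff(confusable, t)
    Q[t, spread] <- Q[t, spread] + rest / length(spread)
  }
  Q
}

default_feature_dists <- function(hemorrhage_levels = c("mild", "moderate", "severe")) {
  # per-class Bernoulli probabilities for the four binary features and
  # categorical weights over hemorrhage levels; shaped so inflamed bladders
  # carry inflammation features and normal bladders are mostly clean
  list(
    cystitis = list(urothelial_ulceration = 0.5, submucosal_lymphoid_aggregates = 0.6,
                    neutrophilic_submucosal_inflammation = 0.7,
                    urothelial_inflammation = 0.8,
                    hemorrhage = c(0.5, 0.3, 0.2)),
    neoplasia = list(urothelial_ulceration = 0.6, submucosal_lymphoid_aggregates = 0.2,
                     neutrophilic_submucosal_inflammation = 0.3,
                     urothelial_inflammation = 0.4,
                     hemorrhage = c(0.4, 0.4, 0.2)),
    urolithiasis = list(urothelial_ulceration = 0.7, submucosal_lymphoid_aggregates = 0.3,
                        neutrophilic_submucosal_inflammation = 0.5,
                        urothelial_inflammation = 0.5,
                        hemorrhage = c(0.3, 0.4, 0.3)),
    normal = list(urothelial_ulceration = 0.05, submucosal_lymphoid_aggregates = 0.05,
                  neutrophilic_submucosal_inflammation = 0.05,
                  urothelial_inflammation = 0.1,
                  hemorrhage = c(0.9, 0.08, 0.02))
  )
}

#' Default rater confusion profiles
#'
#' One kernel per rater and condition. The condition base accuracies are
#' ordered no-information < signalment/history < predictive tool, the
#' qualitative pattern the sequential reading design is meant to produce;
#' small per-rater offsets make the panel heterogeneous.
#'
#' @param accuracies Named base accuracy per condition.
#' @param rater_offsets Named per-rater accuracy offsets.
#' @param other_rate Passed to [make_confusion_kernel()].
#' @return Nested list: `profiles[[rater]][[condition]]` is a kernel.
#' @export
default_rater_profiles <- function(accuracies = c(no_info = 0.55,
                                                  signalment_history = 0.65,
                                                  predictive_tool = 0.75),
                                   rater_offsets = c(P1 = 0.02, P2 = -0.04,
                                                     P3 = 0, P4 = 0.02),
                                   other_rate = 0.05) {
  stopifnot(all(condition_levels() %in% names(accuracies)))
  lapply(stats::setNames(nm = names(rater_offsets)), function(r) {
    lapply(stats::setNames(nm = condition_levels()), function(cond) {
      make_confusion_kernel(
        min(max(accuracies[[cond]] + rater_offsets[[r]], 0), 0.95 - other_rate),
        other_rate = other_rate)
    })
  })
}

#' Configuration of a synthetic agreement study
#'
#' The defaults emulate the study design the package is built around:
#' 25 slides (7 cystitis, 6 neoplasia, 6 urolithiasis, 6 normal) with the
#' published canine/feline mix per class, four raters reading under three
#' sequential conditions on two media (all 25 slides as whole-slide images;
#' 22 on glass, three neoplasia blocks being unavailable), confusion
#' concentrated among cystitis/urolithiasis/normal, and one rater (P4) with
#' partial missingness on the digital medium.
#'
#' @param class_sizes Named slide counts per reference diagnosis.
#' @param species_canine Named fraction of canine slides per class.
#' @param feature_dists Per-class feature distributions (see
#'   `default_feature_dists`).
#' @param rater_profiles Nested kernel list from [default_rater_profiles()].
#' @param feature_flip Per-rater per-feature flip/resample probability for
#'   the perceived feature answers.
#' @param missing List `(rater, medium, conditions, rate)` describing the
#'   incomplete rater, or `NULL` for a complete study.
#' @param media Media to generate.
#' @param glass_unavailable Number of neoplasia slides absent from the glass
#'   medium.
#' @param seed Integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(class_sizes = c(cystitis = 7, neoplasia = 6,
                                       urolithiasis = 6, normal = 6),
                       species_canine = c(cystitis = 2 / 7, neoplasia = 3 / 6,
                                          urolithiasis = 4 / 6, normal = 4 / 6),
                       feature_dists = default_feature_dists(),
                       rater_profiles = default_rater_profiles(),
                       feature_flip = 0.1,
                       missing = list(rater = "P4", medium = "wsi",
                                      conditions = condition_levels(),
                                      rate = 0.2),
                       media = medium_levels(),
                       glass_unavailable = 3,
                       seed = 1L) {
  true_cls <- setdiff(diagnosis_levels(), "other")
  stopifnot(all(true_cls %in% names(class_sizes)),
            all(true_cls %in% names(species_canine)),
            all(class_sizes >= 0))
  for (r in names(rater_profiles)) {
    for (cond in names(rater_profiles[[r]])) {
      Q <- rater_profiles[[r]][[cond]]
      if (!is.matrix(Q) || any(Q < 0) ||
          any(abs(rowSums(Q) - 1) > 1e-8) ||
          !identical(dim(Q), c(4L, 5L))) {
        stop(sprintf("invalid confusion kernel for rater %s, condition %s: rows must be 4x5 probability vectors",
                     r, cond), call. = FALSE)
      }
    }
  }
  if (!is.null(missing)) {
    stopifnot(missing$rate >= 0, missing$rate <= 1,
              missing$rater %in% names(rater_profiles))
  }
  structure(
    list(class_sizes = class_sizes, species_canine = species_canine,
         feature_dists = feature_dists, rater_profiles = rater_profiles,
         feature_flip = feature_flip, missing = missing, media = media,
         glass_unavailable = glass_unavailable, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar fields (`class_sizes`, `accuracies`, `rater_offsets`, `other_rate`,
#' `feature_flip`, `missing`, `media`, `glass_unavailable`, `seed`) are read
#' from YAML; kernels are rebuilt from the accuracies.
#'
#' @param path YAML file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$class_sizes)) args$class_sizes <- unlist(y$class_sizes)
  if (!is.null(y$species_canine)) args$species_canine <- unlist(y$species_canine)
  prof_args <- list()
  if (!is.null(y$accuracies)) prof_args$accuracies <- unlist(y$accuracies)
  if (!is.null(y$rater_offsets)) prof_args$rater_offsets <- unlist(y$rater_offsets)
  if (!is.null(y$other_rate)) prof_args$other_rate <- y$other_rate
  if (length(prof_args) > 0) {
    args$rater_profiles <- do.call(default_rater_profiles, prof_args)
  }
  for (f in c("feature_flip", "media", "glass_unavailable", "seed")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  if ("missing" %in% names(y)) {
    args["missing"] <- list(if (is.list(y$missing)) y$missing else NULL)
  }
  do.call(sim_config, args)
}

# deterministic slide frame: ids, reference class, species
slide_frame <- function(class_sizes, species_canine) {
  true_cls <- c("cystitis", "neoplasia", "urolithiasis", "normal")
  ref <- rep(true_cls, times = class_sizes[true_cls])
  n <- length(ref)
  species <- character(n)
  for (cl in true_cls) {
    idx <- which(ref == cl)
    n_can <- round(species_canine[[cl]] * length(idx))
    species[idx] <- c(rep("canine", n_can),
                      rep("feline", length(idx) - n_can))
  }
  data.frame(slide_id = sprintf("S%02d", seq_len(n)), diagnosis = ref,
             species = species, stringsAsFactors = FALSE)
}

medium_slides <- function(slides, medium, glass_unavailable) {
  if (medium == "glass" && glass_unavailable > 0) {
    neo <- which(slides$diagnosis == "neoplasia")
    drop <- utils::tail(neo, glass_unavailable)
    slides <- slides[-drop, , drop = FALSE]
  }
  slides
}

#' Simulate a complete synthetic agreement study
#'
#' Draws slides and their histological features per reference class, then for
#' each medium, rater and condition draws the reported diagnosis from that
#' rater's confusion kernel given the true diagnosis; perceived feature
#' answers are the true features with flip noise; missingness is applied
#' last. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with `ratings` (a [rating_table()] with feature-answer
#'   columns), `cases` (true features + reference diagnosis, for
#'   [fit_diagnosis_model()]), and `reference` (a [reference_table()]).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    slides <- slide_frame(config$class_sizes, config$species_canine)
    hem_levels <- c("mild", "moderate", "severe")
    feats <- lapply(seq_len(nrow(slides)), function(i) {
      d <- config$feature_dists[[slides$diagnosis[i]]]
      bf <- vapply(c("urothelial_ulceration", "submucosal_lymphoid_aggregates",
                     "neutrophilic_submucosal_inflammation", "urothelial_inflammation"),
                   function(f) stats::rbinom(1, 1, d[[f]]), numeric(1))
      c(as.list(ifelse(bf == 1, "yes", "no")),
        submucosal_hemorrhage = sample(hem_levels, 1, prob = d$hemorrhage))
    })
    feats <- do.call(rbind, lapply(feats, as.data.frame, stringsAsFactors = FALSE))
    cases <- cbind(slides[, c("slide_id", "species")], feats,
                   diagnosis = slides$diagnosis, stringsAsFactors = FALSE)
    reference <- reference_table(slides[, c("slide_id", "species", "diagnosis")])

    raters <- names(config$rater_profiles)
    feature_names <- names(feats)
    recs <- list()
    for (med in config$media) {
      ms <- medium_slides(slides, med, config$glass_unavailable)
      midx <- match(ms$slide_id, slides$slide_id)
      for (r in raters) {
        for (cond in condition_levels()) {
          Q <- config$rater_profiles[[r]][[cond]]
          diag_rep <- vapply(ms$diagnosis, function(truth) {
            sample(colnames(Q), 1, prob = Q[truth, ])
          }, character(1), USE.NAMES = FALSE)
          perceived <- feats[midx, , drop = FALSE]
          for (f in feature_names) {
            flip <- stats::runif(nrow(perceived)) < config$feature_flip
            if (f == "submucosal_hemorrhage") {
              perceived[[f]][flip] <- sample(hem_levels, sum(flip), replace = TRUE)
            } else {
              perceived[[f]][flip] <- ifelse(perceived[[f]][flip] == "yes", "no", "yes")
            }
          }
          recs[[length(recs) + 1]] <- cbind(
            data.frame(slide_id = ms$slide_id, species = ms$species,
                       rater_id = r, condition = cond, medium = med,
                       diagnosis = diag_rep, stringsAsFactors = FALSE),
            perceived)
        }
      }
    }
    ratings <- do.call(rbind, recs)
    mi <- config$missing
    if (!is.null(mi) && mi$rate > 0) {
      hit <- ratings$rater_id == mi$rater & ratings$medium == mi$medium &
        ratings$condition %in% mi$conditions
      ratings$diagnosis[hit & stats::runif(nrow(ratings)) < mi$rate] <- NA
    }
    list(ratings = rating_table(ratings), cases = cases, reference = reference)
  })
}
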