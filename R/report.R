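#' Run the full agreement / concurrence analysis
#'
#' Orchestrates the study pipeline per medium: (1) impute missing ratings if
#' any ([impute_ratings()]; kappas are pooled over the completed datasets by
#' Rubin's rules); (2) per condition, overall and per-category Fleiss kappa
#' with interpretation bands and a subject-level bootstrap interval; (3)
#' apply the 'other'-removal rule, then concurrence and one-vs-rest
#' sensitivity/specificity per condition, per medium and overall; (4)
#' marginal count tables. Concurrence and sensitivity/specificity are
#' computed on the first completed dataset (point estimates are insensitive
#' to which completed set is used; the kappas, the primary endpoint, are
#' pooled over all of them).
#'
#' @param ratings A [rating_table()].
#' @param reference A [reference_table()] covering every rated slide.
#' @param m Completed datasets for imputation (used only when missing cells
#'   are present).
#' @param maxit Chained-imputation sweeps.
#' @param bootstrap_replicates Bootstrap resamples per kappa interval.
#' @param level Confidence level for intervals.
#' @param seed Integer seed driving imputation and bootstrap.
#' @return An object of class `report_bundle`: list with `kappa` (data.frame:
#'   medium, condition, scope, kappa, z, p, band, ci bounds, pooled variance),
#'   `concurrence` (data.frame over condition/medium/overall groupings),
#'   `sensitivity_specificity`, `marginals` (per-medium arrays), `removed`
#'   ('other'-rule log), `imputation_log`, and `provenance`.
#' @export
run_report <- function(ratings, reference, m = 5L, maxit = 10L,
                       bootstrap_replicates = 500L, level = 0.95, seed = 1L) {
  check_reference_covers(ratings, reference)
  media <- sort(unique(ratings$medium))
  kappa_rows <- list()
  marginals <- list()
  imputation_log <- character()
  completed_first <- list()

  for (med in media) {
    med_tab <- ratings[ratings$medium == med, , drop = FALSE]
    class(med_tab) <- class(ratings)
    completed <- if (anyNA(med_tab$diagnosis)) {
      sets <- impute_ratings(med_tab, m = m, maxit = maxit, seed = seed)
      imputation_log <- c(imputation_log, attr(sets, "log"))
      sets
    } else {
      list(med_tab)
    }
    completed_first[[med]] <- completed[[1]]
    marginals[[med]] <- marginal_counts(med_tab, med)

    for (cond in intersect(condition_levels(), unique(med_tab$condition))) {
      fits <- lapply(completed, function(tab) {
        fleiss_kappa(to_count_matrix(tab, cond, med))
      })
      pooled <- pool_kappa(fits)
      ci <- bootstrap_kappa_ci(to_count_matrix(completed[[1]], cond, med),
                               replicates = bootstrap_replicates,
                               level = level, seed = seed)
      z <- pooled$kappa / sqrt(pooled$variance)
      kappa_rows[[length(kappa_rows) + 1]] <- data.frame(
        medium = med, condition = cond, scope = "overall", category = NA,
        kappa = pooled$kappa, z = z, p = 2 * stats::pnorm(-abs(z)),
        band = interpret_kappa(pooled$kappa),
        ci_lower = ci$lower, ci_upper = ci$upper,
        variance = pooled$variance, stringsAsFactors = FALSE)
      for (cat in diagnosis_levels()) {
        per <- lapply(fits, function(f) {
          f$per_category[f$per_category$category == cat, ]
        })
        kap_j <- vapply(per, function(x) x$kappa, numeric(1))
        if (all(is.na(kap_j))) next  # category unused: kappa undefined
        pooled_j <- pool_kappa(kap_j[!is.na(kap_j)],
                               vapply(per, function(x) x$se0^2, numeric(1))[!is.na(kap_j)])
        z_j <- pooled_j$kappa / sqrt(pooled_j$variance)
        kappa_rows[[length(kappa_rows) + 1]] <- data.frame(
          medium = med, condition = cond, scope = "category", category = cat,
          kappa = pooled_j$kappa, z = z_j, p = 2 * stats::pnorm(-abs(z_j)),
          band = interpret_kappa(pooled_j$kappa),
          ci_lower = NA_real_, ci_upper = NA_real_,
          variance = pooled_j$variance, stringsAsFactors = FALSE)
      }
    }
  }

  scored <- do.call(rbind, lapply(completed_first, as.data.frame))
  class(scored) <- class(ratings)
  scored <- remove_other(scored, reference)
  removed_log <- attr(scored, "removed")
  groupings <- c(
    list(list(label = "all", rows = rep(TRUE, nrow(scored)))),
    lapply(intersect(condition_levels(), unique(scored$condition)), function(cond) {
      list(label = paste0("condition:", cond), rows = scored$condition == cond)
    }),
    lapply(media, function(med) {
      list(label = paste0("medium:", med), rows = scored$medium == med)
    })
  )
  conc_rows <- list()
  ss_rows <- list()
  for (g in groupings) {
    sub <- scored[g$rows, , drop = FALSE]
    class(sub) <- class(ratings)
    cr <- concurrence(sub, reference, level = level)
    conc_rows[[length(conc_rows) + 1]] <- data.frame(
      grouping = g$label, proportion = cr$proportion, lcl = cr$lcl,
      ucl = cr$ucl, p = cr$p, kappa = cr$kappa_vs_reference$kappa,
      kappa_p = cr$kappa_vs_reference$p, n_pairs = cr$n_pairs,
      stringsAsFactors = FALSE)
    ss <- sensitivity_specificity(sub, reference)
    ss$grouping <- g$label
    ss_rows[[length(ss_rows) + 1]] <- as.data.frame(ss)
  }

  structure(
    list(kappa = do.call(rbind, kappa_rows),
         concurrence = do.call(rbind, conc_rows),
         sensitivity_specificity = do.call(rbind, ss_rows),
         marginals = marginals,
         removed = removed_log,
         imputation_log = imputation_log,
         provenance = list(
           seed = seed, m = m, maxit = maxit,
           bootstrap_replicates = bootstrap_replicates, level = level,
           media = media,
           n_records = nrow(ratings),
           package_version = as.character(utils::packageVersion("pathagree")))),
    class = "report_bundle"
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n== Fleiss kappa ==\n")
  print(x$kappa, digits = 3)
  cat("== Concurrence with reference ==\n")
  print(x$concurrence, digits = 3)
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Writes `kappa.csv`, `concurrence.csv`, `sensitivity_specificity.csv`,
#' per-medium `marginals_<medium>.csv` and `provenance.json`.
#'
#' @param bundle A [run_report()] result.
#' @param dir Output directory (created if needed).
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$kappa, file.path(dir, "kappa.csv"), row.names = FALSE)
  utils::write.csv(bundle$concurrence, file.path(dir, "concurrence.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$sensitivity_specificity,
                   file.path(dir, "sensitivity_specificity.csv"), row.names = FALSE)
  for (med in names(bundle$marginals)) {
    m <- bundle$marginals[[med]]
    flat <- as.data.frame.table(m, responseName = "count")
    names(flat)[1:3] <- c("diagnosis", "rater_id", "condition")
    utils::write.csv(flat, file.path(dir, paste0("marginals_", med, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
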