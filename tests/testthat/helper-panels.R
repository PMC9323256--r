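# random rater-assignment panel: n subjects x m raters, categories 1..k
random_panel <- function(n, m, k) {
  matrix(sample.int(k, n * m, replace = TRUE), nrow = n)
}

panel_to_counts <- function(panel, k) {
  cnt <- t(apply(panel, 1, tabulate, nbins = k))
  colnames(cnt) <- paste0("cat", seq_len(k))
  subject_category_counts(cnt)
}

# independent oracle: overall Fleiss kappa by brute-force enumeration of all
# m(m-1)/2 rater pairs per subject (agreement-proportion form)
oracle_fleiss <- function(panel) {
  n <- nrow(panel)
  m <- ncol(panel)
  agree <- numeric(n)
  for (i in seq_len(n)) {
    hits <- 0
    for (a in seq_len(m - 1)) {
      for (b in (a + 1):m) {
        hits <- hits + (panel[i, a] == panel[i, b])
      }
    }
    agree[i] <- hits / (m * (m - 1) / 2)
  }
  p_j <- as.vector(table(factor(panel, levels = sort(unique(as.vector(panel)))))) /
    (n * m)
  # include categories never used: they contribute 0 to P_e
  P_e <- sum(p_j^2)
  (mean(agree) - P_e) / (1 - P_e)
}

# minimal complete rating table builder for concurrence / kappa tests
make_ratings <- function(slides, raters, diagnoses,
                         condition = "no_info", medium = "wsi",
                         species = "canine") {
  grid <- expand.grid(rater_id = raters, slide_id = slides,
                      stringsAsFactors = FALSE)
  rating_table(data.frame(
    slide_id = grid$slide_id, species = species, rater_id = grid$rater_id,
    condition = condition, medium = medium, diagnosis = diagnoses,
    stringsAsFactors = FALSE))
}
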