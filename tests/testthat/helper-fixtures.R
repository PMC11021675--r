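# Fixtures built in code: the figure-panel census table and a brute-force
# histogram-count oracle.

# Per-row counts of the combined-panel breakdown (component set -> panels).
table1_combos <- function() {
  list(
    list(components = c("boxplot", "univariate_scatter"), panels = 28L),
    list(components = c("boxplot", "stacked_dot"), panels = 6L),
    list(components = c("boxplot", "histogram"), panels = 4L),
    list(components = c("dot_whisker", "stacked_dot"), panels = 3L),
    list(components = c("density", "boxplot"), panels = 2L),
    list(components = c("density", "dotplot"), panels = 1L)
  )
}

# The 270-panel census: 84 bar, 79 dot-whisker, 60 boxplot, combined panels
# per the breakdown rows above (44), remainder density. 50 panels in total
# show the underlying distribution and/or raw data.
survey_fixture_df <- function() {
  combos <- table1_combos()
  n_combined <- sum(vapply(combos, `[[`, integer(1), "panels"))
  n_density <- 270L - 84L - 79L - 60L - n_combined
  rows <- list()
  add <- function(type, k, components = "", dist = FALSE) {
    if (k == 0L) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      plot_type = rep(type, k),
      combined_components = rep(components, k),
      shows_distribution = rep(dist, k),
      stringsAsFactors = FALSE)
  }
  add("bar", 84L)
  add("dot_whisker", 79L)
  # 3 of the boxplot panels counted as showing the distribution, so that
  # combined (44) + density + boxplot-subset = 50 panels showing
  # distribution and/or raw data
  add("boxplot", 57L)
  add("boxplot", 3L, dist = TRUE)
  add("density", n_density, dist = TRUE)
  for (cmb in combos) {
    add("combined", cmb$panels,
        components = paste(cmb$components, collapse = ";"), dist = TRUE)
  }
  df <- do.call(rbind, rows)
  df$journal <- "J"
  df$article_id <- sprintf("a%03d", seq_len(nrow(df)))
  df$panel_id <- sprintf("p%03d", seq_len(nrow(df)))
  df$shows_raw <- FALSE
  df[, c("journal", "article_id", "panel_id", "plot_type",
         "combined_components", "shows_distribution", "shows_raw")]
}

write_survey_fixture <- function(path = tempfile(fileext = ".csv")) {
  write.csv(survey_fixture_df(), path, row.names = FALSE, quote = FALSE)
  path
}

# Independent per-value loop oracle for histogram counting: bin i is
# [edges[i], edges[i+1]) except the last, which is closed above.
brute_force_counts <- function(values, edges) {
  nbin <- length(edges) - 1L
  counts <- integer(nbin)
  for (v in values) {
    for (i in seq_len(nbin)) {
      hi_ok <- if (i == nbin) v <= edges[i + 1L] else v < edges[i + 1L]
      if (v >= edges[i] && hi_ok) {
        counts[i] <- counts[i] + 1L
        break
      }
    }
  }
  counts
}

random_panel_df <- function(n, seed) {
  set.seed(seed)
  types <- sample(c("bar", "dot_whisker", "boxplot", "density", "combined",
                    "other"), n, replace = TRUE)
  comps <- vapply(types, function(t) {
    if (t != "combined") return("")
    k <- sample(1:3, 1)
    paste(sample(c("boxplot", "univariate_scatter", "stacked_dot",
                   "histogram", "density"), k), collapse = ";")
  }, character(1))
  data.frame(
    journal = "J", article_id = sprintf("a%d", seq_len(n)),
    panel_id = sprintf("p%d", seq_len(n)), plot_type = types,
    combined_components = comps,
    shows_distribution = sample(c(TRUE, FALSE), n, replace = TRUE),
    shows_raw = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE)
}
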