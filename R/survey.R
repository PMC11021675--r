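# Figure-type census arithmetic: validate a coded figure-panel table,
# tally plot types with integer percentages, and break down combined
# panels by their component layers.

PLOT_TYPES <- c("bar", "dot_whisker", "boxplot", "density", "combined",
                "other")
COMBINED_COMPONENTS <- c("boxplot", "univariate_scatter", "stacked_dot",
                         "histogram", "dot_whisker", "density", "dotplot")

parse_flag <- function(x) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Read and validate a coded figure-panel table
#'
#' The machine format for a figure-panel census: one row per panel, CSV
#' with header and columns `journal`, `article_id`, `panel_id`,
#' `plot_type` (one of bar, dot_whisker, boxplot, density, combined,
#' other), `combined_components` (semicolon-separated subset of boxplot,
#' univariate_scatter, stacked_dot, histogram, dot_whisker, density,
#' dotplot; non-empty iff `plot_type` is combined), `shows_distribution`
#' and `shows_raw` (logical flags). Malformed rows are reported with their
#' line numbers.
#'
#' @param path CSV file path.
#' @return A data.frame of validated panel records (class `panel_records`);
#'   `combined_components` holds a list column of character vectors.
#' @export
read_panel_table <- function(path) {
  if (!file.exists(path)) stop("panel table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("journal", "article_id", "panel_id", "plot_type",
                "combined_components", "shows_distribution", "shows_raw")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("panel table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) return(validate_panel_records(df))
  df$plot_type <- trimws(df$plot_type)
  df$combined_components <- trimws(df$combined_components)
  validate_panel_records(df)
}

# Shared validation for records read from file or built in code.
# Line numbers reported are CSV line numbers (header = line 1).
validate_panel_records <- function(df) {
  problems <- character(0)
  comp_list <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    line <- i + 1L
    pt <- df$plot_type[i]
    if (!pt %in% PLOT_TYPES) {
      problems <- c(problems, sprintf(
        "line %d: unknown plot_type '%s' (expected one of %s)",
        line, pt, paste(PLOT_TYPES, collapse = ", ")))
      next
    }
    comps <- df$combined_components[i]
    comps <- if (is.na(comps) || comps == "") character(0)
             else trimws(strsplit(comps, ";", fixed = TRUE)[[1]])
    bad <- setdiff(comps, COMBINED_COMPONENTS)
    if (length(bad) > 0L) {
      problems <- c(problems, sprintf(
        "line %d: unknown combined component(s): %s", line,
        paste(bad, collapse = ", ")))
    }
    if (pt == "combined" && length(comps) == 0L) {
      problems <- c(problems, sprintf(
        "line %d: plot_type 'combined' requires combined_components", line))
    }
    if (pt != "combined" && length(comps) > 0L) {
      problems <- c(problems, sprintf(
        "line %d: combined_components given for non-combined plot_type '%s'",
        line, pt))
    }
    comp_list[[i]] <- comps
  }
  for (col in c("shows_distribution", "shows_raw")) {
    flags <- parse_flag(df[[col]])
    bad <- which(is.na(flags))
    if (length(bad) > 0L) {
      problems <- c(problems, sprintf(
        "line %d: %s must be a logical flag", bad + 1L, col))
    }
    df[[col]] <- flags
  }
  if (length(problems) > 0L) {
    stop("invalid panel table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  df$combined_components <- comp_list
  class(df) <- c("panel_records", "data.frame")
  df
}

#' Integer percentage, rounding half away from zero
#'
#' `round()` in R rounds half to even; survey percentages instead round
#' half away from zero (e.g. 50/270 is 18.52 -> 19), which is the
#' convention these census figures use.
#'
#' @param count Numerator, `0 <= count <= total`.
#' @param total Positive denominator.
#' @return Integer percent.
#' @examples
#' percent(84, 270) # 31
#' @export
percent <- function(count, total) {
  stopifnot(is.numeric(count), is.numeric(total))
  if (any(total <= 0)) stop("total must be positive", call. = FALSE)
  if (any(count < 0) || any(count > total)) {
    stop("count must lie in [0, total]", call. = FALSE)
  }
  as.integer(floor(100 * count / total + 0.5))
}

#' Tally a figure-panel census
#'
#' Aggregates validated panel records into the census summary: counts and
#' integer percentages per plot type (of all univariate panels), and the
#' count of panels showing the underlying distribution and/or the raw data
#' (either-or-both semantics).
#'
#' @param records A [read_panel_table()] result (or any data.frame passing
#'   the same validation).
#' @return An object of class `survey_summary`: list with
#'   `univariate_panels`, `counts` (named integer vector over plot types),
#'   `percents` (same names), `distribution_or_raw` and
#'   `distribution_or_raw_percent`.
#' @export
tally <- function(records) {
  stopifnot(is.data.frame(records))
  if (!inherits(records, "panel_records")) {
    records <- validate_panel_records(records)
  }
  total <- nrow(records)
  if (total == 0L) stop("no panel records to tally", call. = FALSE)
  counts <- vapply(PLOT_TYPES,
                   function(t) sum(records$plot_type == t), integer(1))
  percents <- vapply(PLOT_TYPES, function(t) percent(counts[[t]], total),
                     integer(1))
  either <- sum(records$shows_distribution | records$shows_raw)
  structure(list(
    univariate_panels = total,
    counts = counts,
    percents = percents,
    distribution_or_raw = either,
    distribution_or_raw_percent = percent(either, total)
  ), class = "survey_summary")
}

#' @export
print.survey_summary <- function(x, ...) {
  cat(sprintf("<survey_summary: %d univariate panels>\n",
              x$univariate_panels))
  for (t in names(x$counts)) {
    cat(sprintf("  %-12s %4d (%d%%)\n", t, x$counts[[t]], x$percents[[t]]))
  }
  cat(sprintf("  showing distribution and/or raw data: %d (%d%%)\n",
              x$distribution_or_raw, x$distribution_or_raw_percent))
  invisible(x)
}

canonical_combo <- function(comps) {
  paste(sort(unique(comps)), collapse = "+")
}

#' Break down combined panels by component combination
#'
#' @param records A [read_panel_table()] result.
#' @return A list with `combos` (data.frame of `combo` label and `panels`
#'   count, sorted by decreasing count) and `boxplot_containing` (number of
#'   combined panels whose combination includes a boxplot layer). Empty
#'   breakdown (zero rows) when no panel is combined.
#' @export
combined_breakdown <- function(records) {
  stopifnot(is.data.frame(records))
  if (!inherits(records, "panel_records")) {
    records <- validate_panel_records(records)
  }
  comb <- records[records$plot_type == "combined", , drop = FALSE]
  if (nrow(comb) == 0L) {
    return(list(combos = data.frame(combo = character(0),
                                    panels = integer(0)),
                boxplot_containing = 0L))
  }
  keys <- vapply(comb$combined_components, canonical_combo, character(1))
  tab <- sort(table(keys), decreasing = TRUE)
  combos <- data.frame(combo = names(tab), panels = as.integer(tab))
  has_box <- vapply(comb$combined_components,
                    function(x) "boxplot" %in% x, logical(1))
  list(combos = combos, boxplot_containing = sum(has_box))
}

#' Write a survey summary to CSV
#'
#' One row per plot type with count and integer percentage, then one row
#' for the distribution-and/or-raw-data tally, then one row per combined
#' combination.
#'
#' @param summary A [tally()] result.
#' @param breakdown A [combined_breakdown()] result (optional).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_survey_csv <- function(summary, path, breakdown = NULL) {
  stopifnot(inherits(summary, "survey_summary"))
  rows <- data.frame(
    section = "plot_type",
    category = names(summary$counts),
    panels = as.integer(summary$counts),
    percent = as.integer(summary$percents))
  rows <- rbind(rows, data.frame(
    section = "feature", category = "shows_distribution_or_raw",
    panels = summary$distribution_or_raw,
    percent = summary$distribution_or_raw_percent))
  if (!is.null(breakdown) && nrow(breakdown$combos) > 0L) {
    rows <- rbind(rows, data.frame(
      section = "combined_breakdown",
      category = breakdown$combos$combo,
      panels = breakdown$combos$panels,
      percent = NA_integer_))
    rows <- rbind(rows, data.frame(
      section = "combined_breakdown", category = "contains_boxplot",
      panels = breakdown$boxplot_containing, percent = NA_integer_))
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
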