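# Seeded generators for the four benchmark distributions used throughout
# the package: normal, zero-inflated, positively skewed with outliers, and
# bimodal. All four presets are constrained so their POPULATION mean equals
# a common target (default 10), which makes them a sharp test bed for any
# display claiming to show both the summary and the shape of the data: the
# overlaid means agree while the shapes differ radically.
#
# Every generator seeds the global RNG stream explicitly via a local
# set.seed() call and restores the caller's RNG state afterwards, so calls
# are reproducible and leave no hidden state behind.

with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate normally distributed values
#'
#' @param n Number of draws (>= 1).
#' @param mean,sd Normal parameters; `sd > 0`.
#' @param seed Integer seed; identical seeds give identical vectors.
#' @return Numeric vector of length `n`.
#' @export
gen_normal <- function(n, mean = 10, sd = 2, seed = 1) {
  stopifnot(n >= 1, sd > 0)
  with_seed(seed, stats::rnorm(n, mean = mean, sd = sd))
}

# Mean of a normal(mu, sd) truncated to [0, Inf), computed on the log
# scale (Mills ratio) so it stays finite for very negative mu.
truncnorm_mean <- function(mu, sd) {
  a <- (0 - mu) / sd
  mills <- exp(stats::dnorm(a, log = TRUE) -
                 stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
  mu + sd * mills
}

# Solve for the location mu such that the [0, Inf)-truncated normal with
# scale sd has the requested mean. The truncated mean is increasing in mu,
# so a bracketed root always exists for target > 0.
solve_truncnorm_mu <- function(target_mean, sd) {
  stopifnot(target_mean > 0, sd > 0)
  f <- function(mu) truncnorm_mean(mu, sd) - target_mean
  lo <- target_mean - 10 * sd
  hi <- target_mean + sd
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Generate zero-inflated values
#'
#' Each value is exactly 0 with probability `p_zero`, otherwise a draw from
#' a normal distribution truncated at 0 whose location is solved (by root
#' finding on the truncated-normal mean) so that the non-zero component has
#' mean exactly `nonzero_mean`. The population mean of the mixture is then
#' `(1 - p_zero) * nonzero_mean`. When `target_mean` is supplied (preset
#' mode) that constraint is enforced: `nonzero_mean` defaults to
#' `target_mean / (1 - p_zero)` and a conflicting explicit value is an
#' error.
#'
#' @param n Number of draws.
#' @param p_zero Probability of an exact zero, in (0, 1).
#' @param nonzero_mean Mean of the positive component (data units).
#' @param nonzero_sd Scale of the positive component before truncation.
#' @param seed Integer seed.
#' @param target_mean Optional population mean to enforce (preset mode).
#' @return Numeric vector of length `n`; zeros are exact.
#' @export
gen_zero_inflated <- function(n, p_zero = 0.4, nonzero_mean = NULL,
                              nonzero_sd = 5, seed = 1, target_mean = NULL) {
  stopifnot(n >= 1, p_zero > 0, p_zero < 1, nonzero_sd > 0)
  if (!is.null(target_mean)) {
    implied <- target_mean / (1 - p_zero)
    if (is.null(nonzero_mean)) {
      nonzero_mean <- implied
    } else if (abs((1 - p_zero) * nonzero_mean - target_mean) > 1e-8) {
      stop(sprintf(paste0(
        "preset constraint violated: (1 - p_zero) * nonzero_mean = %.6g ",
        "but target_mean = %.6g"), (1 - p_zero) * nonzero_mean, target_mean),
        call. = FALSE)
    }
  }
  if (is.null(nonzero_mean)) nonzero_mean <- 10 / (1 - p_zero)
  stopifnot(nonzero_mean > 0)
  mu <- solve_truncnorm_mu(nonzero_mean, nonzero_sd)
  p_lo <- stats::pnorm(0, mean = mu, sd = nonzero_sd)
  with_seed(seed, {
    is_zero <- stats::runif(n) < p_zero
    out <- numeric(n)
    k <- sum(!is_zero)
    if (k > 0L) {
      # inverse-CDF draw from the truncated normal: exact and seed-stable
      u <- stats::runif(k, min = p_lo, max = 1)
      out[!is_zero] <- stats::qnorm(u, mean = mu, sd = nonzero_sd)
    }
    out
  })
}

#' Generate positively skewed values with far-right outliers
#'
#' A two-component mixture: with probability `1 - outlier_frac` a lognormal
#' body (median < mean, positive skew), with probability `outlier_frac` a
#' lognormal outlier component centred at `outlier_mean`. The body's
#' log-scale location is solved so the mixture mean equals `target_mean`
#' exactly: `body_mean = (target_mean - outlier_frac * outlier_mean) /
#' (1 - outlier_frac)`, which must be positive (otherwise the constraint is
#' infeasible and an error is raised).
#'
#' @param n Number of draws.
#' @param body_scale Log-scale SD of the lognormal body (> 0).
#' @param outlier_frac Fraction of outlier draws, in \[0, 0.2\].
#' @param outlier_mean Mean of the outlier component (data units).
#' @param seed Integer seed.
#' @param target_mean Population mean of the mixture.
#' @return Numeric vector of length `n`, all values > 0.
#' @export
gen_skewed_outliers <- function(n, body_scale = 0.5, outlier_frac = 0.05,
                                outlier_mean = 40, seed = 1,
                                target_mean = 10) {
  stopifnot(n >= 1, body_scale > 0, outlier_frac >= 0, outlier_frac <= 0.2,
            outlier_mean > 0, target_mean > 0)
  body_mean <- (target_mean - outlier_frac * outlier_mean) / (1 - outlier_frac)
  if (body_mean <= 0) {
    stop(sprintf(paste0(
      "infeasible mean constraint: outlier_frac * outlier_mean = %.3g ",
      "already exceeds target_mean = %.3g"),
      outlier_frac * outlier_mean, target_mean), call. = FALSE)
  }
  meanlog_body <- log(body_mean) - body_scale^2 / 2
  outlier_sdlog <- 0.2
  meanlog_out <- log(outlier_mean) - outlier_sdlog^2 / 2
  with_seed(seed, {
    is_out <- stats::runif(n) < outlier_frac
    out <- numeric(n)
    out[!is_out] <- stats::rlnorm(sum(!is_out), meanlog_body, body_scale)
    out[is_out] <- stats::rlnorm(sum(is_out), meanlog_out, outlier_sdlog)
    out
  })
}

#' Generate bimodal values
#'
#' An equal mixture of two normals centred at `target_mean +/- separation/2`
#' with common SD `component_sd`; the population mean equals `target_mean`
#' exactly by symmetry. The modes must be distinguishable:
#' `separation > 4 * component_sd`.
#'
#' @param n Number of draws.
#' @param separation Distance between the two component means (> 4 SD).
#' @param component_sd Common SD of the components.
#' @param seed Integer seed.
#' @param target_mean Centre of symmetry (the population mean).
#' @return Numeric vector of length `n`.
#' @export
gen_bimodal <- function(n, separation = 10, component_sd = 1, seed = 1,
                        target_mean = 10) {
  stopifnot(n >= 1, component_sd > 0)
  if (separation <= 4 * component_sd) {
    stop("separation must exceed 4 * component_sd for distinguishable modes",
         call. = FALSE)
  }
  lo <- target_mean - separation / 2
  hi <- target_mean + separation / 2
  with_seed(seed, {
    upper <- stats::runif(n) < 0.5
    centre <- ifelse(upper, hi, lo)
    stats::rnorm(n, mean = centre, sd = component_sd)
  })
}

#' The four-group benchmark data set
#'
#' Generates the four benchmark distributions (normal, zero-inflated,
#' positively skewed with outliers, bimodal) as one list of
#' [data_group()]s, each of size `n` and each constrained to the same
#' intended population mean: the standard stress test for a grouped
#' univariate display, since every group's overlaid mean agrees while the
#' shapes differ radically. Per-group seeds are derived from `seed` by
#' fixed small offsets so the groups are independent but jointly
#' reproducible.
#'
#' @param seed Integer seed.
#' @param n Per-group sample size (default 50).
#' @param target_mean Intended population mean of all four groups
#'   (default 10).
#' @return Named list of four `data_group` objects: `normal`,
#'   `zero_inflated`, `skewed_outliers`, `bimodal`.
#' @examples
#' groups <- figure1_groups(seed = 1)
#' vapply(groups, `[[`, numeric(1), "n")
#' @export
figure1_groups <- function(seed = 1, n = 50, target_mean = 10) {
  stopifnot(n >= 1)
  seed <- as.integer(seed)
  list(
    normal = data_group("normal",
      gen_normal(n, mean = target_mean, sd = 2, seed = seed)),
    zero_inflated = data_group("zero_inflated",
      gen_zero_inflated(n, p_zero = 0.4, nonzero_sd = 5, seed = seed + 1L,
                        target_mean = target_mean)),
    skewed_outliers = data_group("skewed_outliers",
      gen_skewed_outliers(n, body_scale = 0.5, outlier_frac = 0.05,
                          outlier_mean = 40, seed = seed + 2L,
                          target_mean = target_mean)),
    bimodal = data_group("bimodal",
      gen_bimodal(n, separation = 10, component_sd = 1, seed = seed + 3L,
                  target_mean = target_mean))
  )
}

#' Write data groups to a long-format CSV
#'
#' Two columns, `group` and `value`, one row per measurement — the format
#' the CLI's plot command reads back.
#'
#' @param groups List of [data_group()] objects.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_groups_csv <- function(groups, path) {
  stopifnot(is.list(groups),
            all(vapply(groups, inherits, logical(1), "data_group")))
  df <- do.call(rbind, lapply(groups, function(g) {
    data.frame(group = g$label, value = g$values)
  }))
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read data groups from a long-format table
#'
#' @param path CSV/TSV file with one group column and one numeric value
#'   column (separator inferred from the file extension: `.tsv` reads as
#'   tab-separated).
#' @param group_col,value_col Column names (defaults `"group"`, `"value"`).
#' @return Named list of [data_group()] objects in order of first
#'   appearance.
#' @export
read_groups_csv <- function(path, group_col = "group", value_col = "value") {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  for (col in c(group_col, value_col)) {
    if (!col %in% names(df)) {
      stop(sprintf("column '%s' not found in %s", col, path), call. = FALSE)
    }
  }
  labels <- unique(as.character(df[[group_col]]))
  groups <- lapply(labels, function(lab) {
    data_group(lab, as.numeric(df[[value_col]][df[[group_col]] == lab]))
  })
  names(groups) <- labels
  groups
}
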