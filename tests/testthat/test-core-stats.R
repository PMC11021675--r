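test_that("summary statistics match hand-computed and textbook-formula values", {
  s <- summarise_values(c(0, 10, 20))
  expect_equal(s$mean, 10)
  expect_equal(s$sd, 10) # sample variance (100 + 0 + 100) / 2
  expect_equal(s$median, 10)

  s <- summarise_values(c(5, 5, 5, 5))
  expect_equal(s$mean, 5)
  expect_equal(s$sd, 0)
  expect_equal(s$q1, 5)
  expect_equal(s$q3, 5)

  # two-pass textbook formulas as an independent oracle on a large sample
  x <- gen_normal(10000, mean = 10, sd = 2, seed = 42)
  s <- summarise_values(x)
  m_oracle <- sum(x) / length(x)
  sd_oracle <- sqrt(sum((x - m_oracle)^2) / (length(x) - 1))
  expect_equal(s$mean, m_oracle, tolerance = 1e-12)
  expect_equal(s$sd, sd_oracle, tolerance = 1e-12)
  expect_true(s$q1 <= s$median && s$median <= s$q3)
  expect_true(all(c(s$mean, s$median, s$q1, s$q3) >= min(x)))
  expect_true(all(c(s$mean, s$median, s$q1, s$q3) <= max(x)))
})

test_that("summarise drops missing values and errors on empty groups", {
  s <- summarise_values(c(1, NA, 3))
  expect_equal(s$n, 2)
  expect_error(summarise_values(c(NA_real_, NA_real_)), "cannot be plotted")
  expect_warning(s1 <- summarise_values(7), "size 1")
  expect_equal(s1$sd, 0)
})

test_that("location shift moves location statistics and leaves sd unchanged", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(50, mean = runif(1, -5, 5), sd = runif(1, 0.1, 3))
    cc <- runif(1, -100, 100)
    a <- summarise_values(x)
    b <- summarise_values(x + cc)
    expect_equal(b$mean, a$mean + cc, tolerance = 1e-10)
    expect_equal(b$median, a$median + cc, tolerance = 1e-10)
    expect_equal(b$q1, a$q1 + cc, tolerance = 1e-10)
    expect_equal(b$q3, a$q3 + cc, tolerance = 1e-10)
    expect_equal(b$sd, a$sd, tolerance = 1e-10)
  }
})

test_that("bin-width rules evaluate their formulas on the pooled sample", {
  expect_equal(select_bin_width(rnorm(10), bin_rule("fixed", width = 1)), 1)
  expect_error(bin_rule("fixed", width = -2), "positive width")
  expect_error(bin_rule("fixed"), "positive width")

  # hand-evaluated Freedman-Diaconis on 1..100 with type-7 quartiles:
  # IQR = 75.25 - 25.75 = 49.5, width = 2 * 49.5 * 100^(-1/3)
  expect_equal(select_bin_width(1:100, bin_rule("freedman_diaconis")),
               2 * 49.5 * 100^(-1 / 3), tolerance = 1e-12)
  expect_equal(select_bin_width(1:100, bin_rule("scott")),
               3.49 * sd(1:100) * 100^(-1 / 3), tolerance = 1e-12)
  expect_equal(select_bin_width(1:100, bin_rule("sturges")),
               99 / (1 + log2(100)), tolerance = 1e-12)
})

test_that("degenerate samples fall back: zero IQR to Scott, zero spread to unit bin", {
  # heavy central mass: IQR = 0 but sd > 0 -> Scott fallback
  x <- c(rep(5, 50), 0, 10)
  expect_equal(select_bin_width(x, bin_rule("freedman_diaconis")),
               3.49 * sd(x) * length(x)^(-1 / 3))
  # constant data -> single unit-width bin centred on the value
  x <- rep(7, 20)
  for (kind in c("freedman_diaconis", "scott", "sturges")) {
    w <- select_bin_width(x, bin_rule(kind))
    expect_equal(w, 1)
  }
  expect_equal(make_edges(7, 7, 1), c(6.5, 7.5))
})

test_that("adaptive widths scale as n^(-1/3) under duplication", {
  set.seed(3)
  x <- rnorm(500)
  for (kind in c("freedman_diaconis", "scott")) {
    w1 <- select_bin_width(x, bin_rule(kind))
    w2 <- select_bin_width(c(x, x), bin_rule(kind))
    # duplication doubles n but leaves IQR/sd essentially unchanged
    expect_equal(w2 / w1, 2^(-1 / 3), tolerance = 0.01)
  }
})

test_that("bin edges are anchored at multiples of the width", {
  expect_equal(make_edges(0.3, 2.2, 1), c(0, 1, 2, 3))
  expect_equal(make_edges(0, 3, 1), c(0, 1, 2, 3)) # max on edge retained
  e <- make_edges(-0.5, 0.5, 0.25)
  expect_equal(e[1], -0.5)
  expect_equal(e, seq(-0.5, 0.5, by = 0.25))
  expect_error(make_edges(1, 0, 1), "global_min")
  expect_error(make_edges(0, 1, 0), "positive")

  set.seed(7)
  for (i in 1:50) {
    lo <- runif(1, -50, 50); hi <- lo + runif(1, 0, 100)
    w <- runif(1, 0.01, 10)
    e <- make_edges(lo, hi, w)
    expect_true(e[1] <= lo)
    expect_true(e[length(e)] >= hi)
    expect_equal(e[1] / w, round(e[1] / w), tolerance = 1e-9)
    expect_equal(max(abs(diff(e) - w)) / w, 0, tolerance = 1e-9)
    # last edge is the SMALLEST anchored multiple >= hi
    expect_true(e[length(e)] - w < hi)
  }
})

test_that("bin counting is half-open with a closed last bin and conserves n", {
  expect_equal(bin_counts(c(0, 0, 0, 5), 0:6), c(3, 0, 0, 0, 0, 1))
  expect_equal(bin_counts(1, c(0, 1, 2)), c(0, 1)) # 1.0 goes to [1, 2)
  expect_equal(bin_counts(2, c(0, 1, 2)), c(0, 1)) # max lands in last bin
  expect_error(bin_counts(c(0, 7), 0:6), "outside")

  x <- gen_normal(1000, 0, 1, seed = 9)
  x <- pmin(pmax(x, -4), 4)
  e <- make_edges(-4, 4, 0.5)
  expect_identical(bin_counts(x, e), brute_force_counts(x, e))
  expect_equal(sum(bin_counts(x, e)), length(x))
})

test_that("shared histograms conserve every group's n", {
  set.seed(21)
  for (i in 1:25) {
    groups <- lapply(seq_len(sample(1:4, 1)), function(j) {
      data_group(paste0("g", j), runif(sample(5:200, 1), -10, 10))
    })
    h <- build_histogram(groups, bin_rule("freedman_diaconis"))
    for (g in groups) {
      expect_equal(sum(h$counts[[g$label]]), g$n)
    }
    expect_equal(max(abs(diff(diff(h$edges)))), 0, tolerance = 1e-9)
  }
})

test_that("small-sample advisory triggers exactly below n = 20", {
  expect_warning(flag <- check_sample_size(19), "below the recommended")
  expect_true(flag)
  expect_no_warning(flag <- check_sample_size(20))
  expect_false(flag)
  expect_no_warning(flag <- check_sample_size(50))
  expect_false(flag)
})
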