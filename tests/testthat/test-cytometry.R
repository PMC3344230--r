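# Simulated two-peak histogram with Gaussian peaks at given channel means.
gauss_hist <- function(means, cv = 0.03, n = 5000, channels = 1:1024,
                       heights = rep(1, length(means)), id = "s") {
  counts <- numeric(length(channels))
  for (i in seq_along(means)) {
    draws <- rnorm(round(n * heights[i]), means[i], cv * means[i])
    bins <- pmin(pmax(round(draws), 1L), max(channels))
    counts <- counts + tabulate(bins, length(channels))
  }
  fluorescence_histogram(id, channels, counts)
}

test_that("peak detection recovers well-separated G1 peaks", {
  set.seed(11)
  h <- gauss_hist(c(200, 240))
  pk <- detect_g1_peaks(h)
  expect_length(pk, 2)
  expect_lt(abs(pk[1] - 200), 1)
  expect_lt(abs(pk[2] - 240), 1)
})

test_that("a single peak is an unresolvable histogram", {
  set.seed(12)
  h <- gauss_hist(300)
  expect_error(detect_g1_peaks(h), "unresolvable")
})

test_that("sub-prominence G2 doublet peaks are suppressed", {
  set.seed(13)
  h <- gauss_hist(c(200, 240, 480), heights = c(1, 1, 0.4))
  pk <- detect_g1_peaks(h, min_prominence_fraction = 0.5)
  expect_length(pk, 2)
  expect_lt(abs(pk[2] - 240), 1)
})

test_that("reference ratios give the published genome sizes and ploidies", {
  for (case in list(list(r = 1.2, p = 2L, pg = 24.096),
                    list(r = 1.8, p = 3L, pg = 36.144),
                    list(r = 2.4, p = 4L, pg = 48.192))) {
    pc <- call_ploidy(100 * case$r, 100)
    expect_equal(pc$ratio, case$r)
    expect_equal(pc$ploidy, case$p)
    expect_equal(pc$genome_size_pg, case$pg, tolerance = 1e-12)
    expect_equal(round(pc$genome_size_pg), round(case$pg))
  }
})

test_that("ratios outside tolerance are uncalled; bad peaks are errors", {
  pc <- call_ploidy(100, 100)  # ratio 1.0, distance 0.2 > 0.15
  expect_true(is.na(pc$ploidy))
  expect_equal(pc$ratio, 1)
  expect_error(call_ploidy(-1, 100), "positive")
  expect_error(call_ploidy(100, 0), "positive")
})

test_that("genome size is exactly ratio times the standard size", {
  set.seed(14)
  for (i in 1:50) {
    sp <- runif(1, 50, 900); st <- runif(1, 50, 900)
    pc <- call_ploidy(sp, st)
    expect_equal(pc$genome_size_pg, (sp / st) * 20.08,
                 tolerance = 1e-9)
  }
})

test_that("scaling all channels leaves ratio, ploidy and genome size unchanged", {
  set.seed(15)
  h <- gauss_hist(c(200, 360))
  base <- call_ploidy_histogram(h)
  for (k in c(0.5, 2, 3.7)) {
    h2 <- fluorescence_histogram("s", h$channels * k, h$counts)
    sc <- call_ploidy_histogram(h2)
    expect_equal(sc$ratio, base$ratio, tolerance = 1e-6)
    expect_equal(sc$ploidy, base$ploidy)
    expect_equal(sc$genome_size_pg, base$genome_size_pg, tolerance = 1e-4)
  }
})

test_that("simulated histograms at CV <= 5% call the latent ploidy reliably", {
  set.seed(16)
  n_ok <- 0
  n_rep <- 1000
  for (i in seq_len(n_rep)) {
    p <- sample(2:4, 1)
    cv <- runif(1, 0.01, 0.05)
    h <- gauss_hist(c(200, 200 * 0.6 * p), cv = cv, n = 3000)
    call <- tryCatch(call_ploidy_histogram(h)$ploidy, error = function(e) NA)
    if (isTRUE(call == p)) n_ok <- n_ok + 1
  }
  expect_gte(n_ok / n_rep, 0.99)
})

test_that("spore-count classification follows the 32/64 rule", {
  expect_equal(classify_reproduction(c(32, 32, 32, 32, 32))$mode, "apogamous")
  expect_equal(classify_reproduction(c(16, 28, 32, 32, 32))$mode, "apogamous")
  expect_equal(classify_reproduction(rep(64, 5))$mode, "sexual")
  expect_equal(classify_reproduction(rep(48, 5))$mode, "indeterminate")
  expect_equal(classify_reproduction(c(64, 64, 32, 32, 48))$mode, "indeterminate")
  expect_error(classify_reproduction(integer(0)), "empty")
})

test_that("reproduction mode is invariant to sporangium order", {
  set.seed(17)
  for (i in 1:25) {
    counts <- sample(c(16, 28, 32, 48, 64), 5, replace = TRUE)
    m0 <- classify_reproduction(counts)$mode
    for (j in 1:5)
      expect_equal(classify_reproduction(sample(counts))$mode, m0)
  }
})

test_that("histogram CSV round-trips through the reader", {
  set.seed(18)
  h <- gauss_hist(c(200, 240), id = "roundtrip")
  f <- tempfile(fileext = ".csv")
  write_histogram_csv(h, f)
  h2 <- read_histogram_csv(f, sample_id = "roundtrip")
  expect_equal(h2$counts, h$counts)
  expect_equal(h2$channels, h$channels)
  expect_equal(cytometry_table(list(h2))$ploidy, call_ploidy_histogram(h)$ploidy)
})
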