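test_that("MRE and SMSE reproduce the zero-variate simplifications", {
  df <- tibble::tibble(set = "Li", data = 1, pred = 1.2, weight = 1)
  fm <- fit_metrics(df)
  expect_equal(fm$RE, 0.2)
  expect_equal(attr(fm, "MRE"), 0.2)

  # p/d = 3: SSE = (3-1)^2 / (1 + 3^2) = 0.4
  df3 <- tibble::tibble(set = "Li", data = 1, pred = 3, weight = 1)
  expect_equal(fit_metrics(df3)$SSE, 0.4)

  # perfect fit
  dfp <- tibble::tibble(
    set = rep(c("a", "b"), c(2, 4)), data = c(1, 2, 3, 4, 5, 6),
    pred = c(1, 2, 3, 4, 5, 6), weight = 1
  )
  fm <- fit_metrics(dfp)
  expect_equal(attr(fm, "MRE"), 0)
  expect_equal(attr(fm, "SMSE"), 0)
})

test_that("metrics match an independently hand-coded evaluation", {
  set.seed(3)
  df <- tibble::tibble(
    set = rep(c("a", "b", "c"), c(3, 4, 1)),
    data = runif(8, 0.5, 4), pred = runif(8, 0.5, 4),
    weight = runif(8, 0.1, 2)
  )
  fm <- fit_metrics(df)
  # oracle: explicit loops over the defining formulas
  REs <- SSEs <- numeric(0)
  for (s in unique(df$set)) {
    d <- df$data[df$set == s]
    p <- df$pred[df$set == s]
    w <- df$weight[df$set == s]
    wi <- sum(w)
    REs[s] <- sum(w / wi * abs(p - d)) / abs(mean(d))
    SSEs[s] <- sum(w * (p - d)^2) / sum(w * (d^2 + p^2))
  }
  expect_equal(fm$RE, unname(REs[fm$set]), tolerance = 1e-12)
  expect_equal(fm$SSE, unname(SSEs[fm$set]), tolerance = 1e-12)
  expect_equal(attr(fm, "MRE"), mean(REs), tolerance = 1e-12)
  expect_equal(attr(fm, "SMSE"), mean(SSEs), tolerance = 1e-12)
})

test_that("zero-weight datasets are excluded from n-prime", {
  df <- tibble::tibble(
    set = c("a", "b"), data = c(1, 1), pred = c(2, 1.5), weight = c(1, 0)
  )
  fm <- fit_metrics(df)
  expect_equal(attr(fm, "n_sets"), 1)
  expect_equal(attr(fm, "MRE"), 1) # only set a counts
  dfz <- df
  dfz$weight <- 0
  expect_error(fit_metrics(dfz), "zero")
})

test_that("SMSE is bounded by one and approaches it for extreme ratios", {
  # zero-variate expression over extreme prediction/data ratios
  r <- 10^seq(-6, 6, length.out = 200)
  sse <- (r - 1)^2 / (1 + r^2)
  expect_true(all(sse <= 1))
  expect_gt(max(sse), 1 - 1e-5)
  # randomized multi-point datasets
  set.seed(4)
  for (i in 1:500) {
    n <- sample(1:6, 1)
    df <- tibble::tibble(
      set = "s", data = exp(runif(n, -8, 8)), pred = exp(runif(n, -8, 8)),
      weight = runif(n, 0.01, 1)
    )
    expect_lte(fit_metrics(df)$SSE, 1)
  }
})

test_that("rescaling all weights within a dataset leaves RE and SSE unchanged", {
  set.seed(5)
  df <- tibble::tibble(
    set = rep("a", 5), data = runif(5, 1, 3), pred = runif(5, 1, 3),
    weight = runif(5)
  )
  df2 <- df
  df2$weight <- df$weight * 2
  expect_equal(fit_metrics(df)$RE, fit_metrics(df2)$RE, tolerance = 1e-13)
  expect_equal(fit_metrics(df)$SSE, fit_metrics(df2)$SSE, tolerance = 1e-13)
})

test_that("minimizing the sb loss does not minimize MRE", {
  # two-point counterexample: one scalar dataset d = 1 with two candidate
  # predictions; sb ranks them differently from MRE because its denominator
  # grows with the prediction
  d <- 1
  p1 <- 1.8
  p2 <- 0.55
  sb <- function(p) (d - p)^2 / (d^2 + p^2)
  mre <- function(p) abs(p / d - 1)
  expect_lt(sb(p1), sb(p2)) # sb prefers the overestimate
  expect_gt(mre(p1), mre(p2)) # MRE prefers the underestimate
})

test_that("completeness rises with data coverage and stays on the 1-10 scale", {
  mk <- function(zlabs, uni = list()) {
    deb_entry(
      species = "t",
      zero_variate = tibble::tibble(
        label = zlabs, value = 1,
        units = unname(debfit:::label_units()[zlabs]), temp_K = 293.15
      ),
      uni_variate = uni
    )
  }
  weight_only <- mk("Wwi")
  expect_equal(completeness_score(weight_only), 1.5) # minimal rubric level
  more <- mk(c("Wwi", "ab", "ap", "Lb", "Lp", "Ri"))
  expect_gt(completeness_score(more), completeness_score(weight_only))
  uni <- list(
    list(
      label = "tL", x = 0:5, y = rep(0.5, 6), units_x = "d", units_y = "cm",
      temp_K = 293.15, f = 1, weight = 1
    ),
    list(
      label = "LN", x = rep(0.5, 3), y = rep(2, 3), units_x = "cm",
      units_y = "1/d", temp_K = 293.15, f = 1, weight = 1
    )
  )
  most <- mk(c("Wwi", "ab", "ap", "Lb", "Lp", "Ri"), uni)
  expect_gt(completeness_score(most), completeness_score(more))
  expect_lte(completeness_score(most), 10)
  expect_gte(completeness_score(weight_only), 1)
})
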