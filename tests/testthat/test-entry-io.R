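test_that("entry files round-trip through YAML", {
  e <- generate_synthetic_entry(abj_params(), deb_model("abj"), cv = 0.05, seed = 3)
  fp <- withr::local_tempfile(fileext = ".yaml")
  write_entry(e, fp)
  e2 <- read_entry(fp)
  expect_equal(e2$species, e$species)
  expect_equal(e2$model$label, "abj")
  expect_equal(e2$zero_variate$value, e$zero_variate$value, tolerance = 1e-12)
  expect_equal(e2$uni_variate[[1]]$y, e$uni_variate[[1]]$y, tolerance = 1e-12)
  expect_equal(
    unlist(unclass(e2$params)), unlist(unclass(e$params)),
    tolerance = 1e-12
  )
  expect_equal(attr(e2$params, "free"), attr(e$params, "free"))
  expect_equal(e2$options$loss, e$options$loss)
})

test_that("unit corruption fails loudly before any computation", {
  e <- generate_synthetic_entry(gen_params(), cv = 0, seed = 1)
  fp <- withr::local_tempfile(fileext = ".yaml")
  write_entry(e, fp)
  txt <- readLines(fp)
  txt <- sub("units: cm$", "units: mm", txt)
  writeLines(txt, fp)
  expect_error(read_entry(fp), "unit mismatch")
})

test_that("a uni-variate dataset without temperature is refused by name", {
  expect_error(
    deb_entry(
      species = "t",
      uni_variate = list(list(
        label = "tL", x = 1:3, y = c(1, 2, 3) / 10, units_x = "d",
        units_y = "cm", temp_K = NA, f = 1, weight = 1
      ))
    ),
    "tL.*temperature"
  )
  expect_error(
    deb_entry(species = "t", zero_variate = tibble::tibble(
      label = "Lq", value = 1, units = "cm", temp_K = 293.15
    )),
    "unknown zero-variate label"
  )
})

test_that("a zero weight multiplier silences a dataset in the metrics", {
  e <- generate_synthetic_entry(gen_params(), cv = 0.1, seed = 5)
  e$uni_variate[[1]]$weight <- 0
  df <- predict_entry(e, e$params)
  fm <- fit_metrics(df[, c("set", "data", "pred", "weight")])
  expect_equal(attr(fm, "n_sets"), nrow(e$zero_variate))
  expect_true(is.na(fm$RE[fm$set == "tL"]) || fm$w_i[fm$set == "tL"] == 0)
})

test_that("synthetic entries are deterministic under a seed", {
  e1 <- generate_synthetic_entry(gen_params(), cv = 0.05, seed = 9)
  e2 <- generate_synthetic_entry(gen_params(), cv = 0.05, seed = 9)
  f1 <- withr::local_tempfile(fileext = ".yaml")
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_entry(e1, f1)
  write_entry(e2, f2)
  expect_identical(readLines(f1), readLines(f2)) # byte-for-byte
  e3 <- generate_synthetic_entry(gen_params(), cv = 0.05, seed = 10)
  expect_false(identical(e1$zero_variate$value, e3$zero_variate$value))
})

test_that("noise-free synthetic data equal the model's own predictions", {
  e <- generate_synthetic_entry(gen_params(), cv = 0, seed = 1)
  df <- predict_entry(e, e$params)
  expect_equal(df$pred, df$data, tolerance = 1e-12)
})

test_that("age-at-birth predictions at two temperatures differ by the Arrhenius factor", {
  p <- gen_params()
  mk <- function(temp) {
    deb_entry(
      species = "t", params = p,
      zero_variate = tibble::tibble(
        label = "ab", value = 15, units = "d", temp_K = temp
      )
    )
  }
  p1 <- predict_entry(mk(293.15), p)$pred
  p2 <- predict_entry(mk(303.15), p)$pred
  expect_equal(p1 / p2, temp_correction(303.15, p) / temp_correction(293.15, p),
    tolerance = 1e-9
  )
})

test_that("time-length predictions equal the von Bertalanffy closed form", {
  p <- gen_params()
  cmp <- compound_parameters(p)
  x <- seq(0, 1500, length.out = 12)
  e <- deb_entry(
    species = "t", params = p,
    uni_variate = list(list(
      label = "tL", x = x, y = rep(0.5, 12), units_x = "d", units_y = "cm",
      temp_K = p$T_ref, f = 1, weight = 1
    ))
  )
  pred <- predict_entry(e, p)$pred
  ir <- initial_reserve(p, f = 1)
  rB <- cmp$k_M / 3 / (1 + 1 / cmp$g)
  Lvb <- cmp$L_m - (cmp$L_m - ir$L_b) * exp(-rB * x)
  expect_equal(pred, Lvb, tolerance = 1e-5)
})

test_that("an unregistered dataset label is refused at estimation", {
  e <- generate_synthetic_entry(gen_params(), cv = 0, seed = 1)
  e$uni_variate[[1]]$label <- "tL_x"
  names(e$uni_variate) <- NULL
  e$uni_variate[[1]]$label <- "tL_x"
  df <- predict_entry(e, e$params) # suffixed labels dispatch on the base
  expect_equal(nrow(df[df$set == "tL_x", ]), 30)
})

test_that("reports carry the four mandated sections deterministically", {
  e <- generate_synthetic_entry(gen_params(), cv = 0.02, seed = 2)
  r1 <- render_report(e)
  r2 <- render_report(e)
  expect_identical(r1, r2)
  for (sec in c(
    "## Metadata", "## Predictions", "## Parameters",
    "## Implied properties"
  )) {
    expect_true(any(startsWith(r1, sec)), info = sec)
  }
  expect_true(any(grepl("MRE", r1)))
  expect_true(any(grepl("completeness", r1)))
})
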