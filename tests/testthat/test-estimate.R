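test_that("the loss trace is non-increasing across continuation rounds", {
  e <- generate_synthetic_entry(gen_params(), cv = 0.05, seed = 21)
  init <- perturb_params(gen_params(), c("p_Am", "v", "kap"), amount = 0.15)
  fit <- estimate(e, init = init, options = quick_options(steps = 40, continuations = 3))
  expect_true(all(diff(fit$trace$loss) <= 1e-12))
  expect_lte(fit$loss, fit$trace$loss[1])
})

test_that("a zero weight multiplier is equivalent to omitting the dataset", {
  e_with <- generate_synthetic_entry(gen_params(), cv = 0.05, seed = 22)
  e_zero <- e_with
  e_zero$uni_variate[[1]]$weight <- 0
  e_none <- e_with
  e_none$uni_variate <- list()

  # equal objective values at arbitrary parameter sets (up to solver noise:
  # the silenced dataset still requests output times from the integrator)
  for (mult in c(0.9, 1, 1.1)) {
    p <- gen_params(p_Am = 22.5 * mult)
    dfz <- predict_entry(e_zero, p)
    dfn <- predict_entry(e_none, p)
    expect_equal(
      deb_loss(dfz[, c("set", "data", "pred", "weight")], "sb"),
      deb_loss(dfn[, c("set", "data", "pred", "weight")], "sb"),
      tolerance = 1e-6
    )
  }
  # and hence matching estimates under the same deterministic search
  init <- perturb_params(gen_params(), c("p_Am", "kap"), amount = 0.1)
  opts <- quick_options(steps = 30)
  fz <- estimate(e_zero, init = init, options = opts)
  fn <- estimate(e_none, init = init, options = opts)
  expect_equal(unlist(unclass(fz$params)), unlist(unclass(fn$params)),
    tolerance = 1e-3
  )
})

test_that("an infeasible initial set is refused", {
  e <- generate_synthetic_entry(gen_params(), cv = 0, seed = 1)
  bad <- gen_params(kap = 1.5)
  attr(bad, "free") <- "kap"
  expect_error(estimate(e, init = bad), "filter")
})

test_that("pseudo-data hardly move kappa when growth and reproduction data are present", {
  e <- generate_synthetic_entry(gen_params(), cv = 0, seed = 23)
  init <- perturb_params(gen_params(), c("p_Am", "v", "kap", "p_M"), amount = 0.12)
  opts <- quick_options(steps = 150, continuations = 2)
  f_with <- estimate(e, init = init, options = opts)
  e$pseudo <- FALSE
  f_without <- estimate(e, init = init, options = opts)
  expect_lt(
    abs(f_with$params$kap / f_without$params$kap - 1),
    0.01
  )
})

test_that("estimation results persist and restart as a new seed", {
  e <- generate_synthetic_entry(gen_params(), cv = 0.05, seed = 24)
  init <- perturb_params(gen_params(), c("p_Am", "kap"), amount = 0.1)
  fit <- estimate(e, init = init, options = quick_options(steps = 30))
  fp <- withr::local_tempfile(fileext = ".yaml")
  write_fit(fit, fp)
  seed2 <- read_fit_params(fp)
  expect_equal(unlist(unclass(seed2)), unlist(unclass(fit$params)), tolerance = 1e-12)
  expect_equal(attr(seed2, "free"), attr(fit$params, "free"))
  expect_true(filter_check(seed2, e$model)$pass)
  refit <- estimate(e, init = seed2, options = quick_options(steps = 10))
  expect_lte(refit$loss, fit$loss * (1 + 1e-9))
})

test_that("tidy and glance summarise a fit", {
  e <- generate_synthetic_entry(gen_params(), cv = 0.05, seed = 25)
  init <- perturb_params(gen_params(), c("p_Am", "kap"), amount = 0.05)
  fit <- estimate(e, init = init, options = quick_options(steps = 20))
  td <- tidy(fit)
  expect_true(all(c("parameter", "init", "estimate", "free") %in% names(td)))
  expect_equal(sum(td$free), 2)
  gl <- glance(fit)
  expect_true(all(c("loss", "MRE", "SMSE", "n_obj") %in% names(gl)))
  expect_gte(gl$MRE, 0)
})

test_that("auto-initialization recovers the scale of a known parameter set", {
  truth <- deb_params(z = 1.4)
  e <- generate_synthetic_entry(truth, cv = 0, seed = 26)
  init <- auto_init_9(e$zero_variate, deb_model("std"), steps = 250)
  expect_true(filter_check(init, deb_model("std"))$pass)
  # implied properties of the init reproduce the nine observations within 30%
  preds <- predict_entry(
    deb_entry(species = "chk", params = init, zero_variate = e$zero_variate),
    init
  )
  expect_true(all(abs(preds$pred / preds$data - 1) < 0.3))
})

test_that("the all-noisy design's intrinsic error floor exceeds five percent", {
  # linear error propagation through the prediction Jacobian at the default
  # weights: with 5% noise on every datum, the one-sigma relative errors of
  # p_Am, v and p_M are above 5% even with only the four core parameters
  # free — recovery experiments must keep the zero-variate observations exact
  truth <- gen_params()
  entry <- generate_synthetic_entry(truth,
    design = synthetic_design(tL = list(n = 30)), cv = 0, seed = 1
  )
  free <- c("p_Am", "v", "kap", "p_M")
  base <- predict_entry(entry, truth)
  J <- matrix(0, nrow(base), length(free))
  for (j in seq_along(free)) {
    p2 <- truth
    p2[[free[j]]] <- truth[[free[j]]] * 1.001
    J[, j] <- (log(predict_entry(entry, p2)$pred) - log(base$pred)) / 0.001
  }
  Cov <- solve(t(J) %*% diag(base$weight) %*% J) * 0.05^2
  sig <- sqrt(diag(Cov))
  names(sig) <- free
  expect_gt(sig[["p_Am"]], 0.05)
  expect_gt(sig[["v"]], 0.05)
  expect_gt(sig[["p_M"]], 0.05)
  expect_lt(sig[["kap"]], 0.05) # kappa itself is well determined
})

test_that("auto-initialization falls back to the zoom-scaled generalized set", {
  zv <- tibble::tibble(
    label = c("Li", "ab"), value = c(2.3, 20), units = c("cm", "d"),
    temp_K = 293.15, weight = 1, f = 1
  )
  init <- auto_init_9(zv, deb_model("std"))
  expect_true(filter_check(init, deb_model("std"))$pass)
  expect_equal(compound_parameters(init)$L_m, 2.3, tolerance = 1e-9)
})
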