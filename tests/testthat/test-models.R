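test_that("model labels map to the three families", {
  fam <- c(
    std = "s", stf = "s", stx = "s", ssj = "s", sbp = "s",
    abj = "a", asj = "a", abp = "a", hep = "h", hex = "h"
  )
  for (lbl in names(fam)) expect_equal(deb_model(lbl)$family, unname(fam[lbl]))
  expect_error(deb_model("xyz"), "unknown model label")
})

test_that("shape correction is 1 for s-models and tracks the window for a-models", {
  p <- abj_params()
  std <- deb_model("std")
  abj <- deb_model("abj")
  expect_equal(shape_correction(std, EH = 50, L = 0.7, p = p), 1)
  # start of acceleration: continuity at sM = 1
  expect_equal(shape_correction(abj, EH = p$E_Hb, L = 0.1, p = p, L_b = 0.1), 1)
  # during: L / L_b
  expect_equal(shape_correction(abj, EH = 1, L = 0.15, p = p, L_b = 0.1), 1.5)
  # after metamorphosis with L_j = 2 L_b: frozen at 2
  expect_equal(
    shape_correction(abj, EH = p$E_Hj, L = 0.5, p = p, L_b = 0.1, L_j = 0.2), 2
  )
  expect_error(
    shape_correction(abj, EH = 1, L = 0.15, p = p),
    "not yet realized"
  )
})

test_that("acceleration factor is the after/before length ratio", {
  p <- gen_params()
  tr <- integrate_life_cycle(p, deb_model("std"), f = 1)
  expect_equal(acceleration_factor(tr, deb_model("std"))$factor, 1)

  # degenerate window
  p0 <- gen_params(E_Hj = gen_params()$E_Hb)
  tr0 <- integrate_life_cycle(p0, deb_model("abj"), f = 1)
  expect_equal(acceleration_factor(tr0, deb_model("abj"))$factor, 1, tolerance = 1e-9)

  # against a refined-tolerance integration of the same system
  p8 <- gen_params(E_Hj = 8 * 0.275)
  a1 <- acceleration_factor(
    integrate_life_cycle(p8, deb_model("abj"), f = 1), deb_model("abj")
  )$factor
  a2 <- acceleration_factor(
    integrate_life_cycle(p8, deb_model("abj"), f = 1, rtol = 1e-11, atol = 1e-13),
    deb_model("abj")
  )$factor
  expect_gt(a1, 1.5)
  expect_equal(a1, a2, tolerance = 1e-6)

  # missing events yield an absent value with a reason
  short <- integrate_life_cycle(p8, deb_model("abj"), f = 1, horizon = 30)
  af <- acceleration_factor(short, deb_model("abj"))
  expect_true(is.na(af$factor))
  expect_match(af$reason, "not realized")
})

test_that("degenerate extensions collapse to their parent models", {
  p <- gen_params()
  probe <- c(50, 300, 1200, 5000)
  run <- function(p, lbl) {
    as.data.frame(states_at(
      integrate_life_cycle(p, deb_model(lbl), f = 1, times = probe),
      probe
    ))[, c("E", "L", "EH", "ER")]
  }
  base_std <- run(p, "std")
  expect_equal(run(gen_params(E_Hj = p$E_Hb), "abj"), base_std, tolerance = 1e-7)
  expect_equal(run(gen_params(E_Hs = p$E_Hb + 1e-9, t_sj = 0), "ssj"), base_std,
    tolerance = 1e-7
  )
  base_stf <- run(p, "stf")
  expect_equal(run(gen_params(t_0 = 0, E_Hx = p$E_Hb + 1e-9), "stx"), base_stf,
    tolerance = 1e-7
  )
  base_abj <- run(abj_params(), "abj")
  expect_equal(run(abj_params(E_Hs = p$E_Hb + 1e-9), "asj"), base_abj,
    tolerance = 1e-6
  )
})

test_that("the ssj non-feeding stage shrinks structure, more so for longer stages", {
  lost <- vapply(c(5, 20, 60), function(tsj) {
    p <- gen_params(E_Hs = 1, t_sj = tsj)
    tr <- integrate_life_cycle(p, deb_model("ssj"), f = 1)
    shr <- tr[tr$stage == "shrink", ]
    expect_true(all(diff(shr$L) <= 1e-12)) # non-increasing during the stage
    head(shr$L, 1) - tail(shr$L, 1)
  }, numeric(1))
  expect_true(all(diff(lost) > 0))
})

test_that("growth ceases at puberty for sbp and abp", {
  p <- gen_params()
  tr <- integrate_life_cycle(p, deb_model("sbp"), f = 1)
  ad <- tr[tr$stage == "adult", ]
  expect_lt(diff(range(ad$L)), 1e-12)
  # reproduction claims the whole mobilized flux beyond maintenance
  i <- nrow(ad) - 1
  expect_equal(ad$pC[i] - ad$pS[i] - ad$pJ[i],
    (ad$ER[i + 1] - ad$ER[i]) / (ad$t[i + 1] - ad$t[i]),
    tolerance = 1e-3
  )
  expect_gte(
    ad$pC[i] - ad$pS[i] - ad$pJ[i],
    (1 - p$kap) * ad$pC[i] - ad$pJ[i]
  )

  pab <- abj_params()
  trp <- integrate_life_cycle(pab, deb_model("abp"), f = 1)
  sch <- attr(trp, "schedule")
  Lb <- sch$L[sch$event == "b"]
  Lp <- sch$L[sch$event == "p"]
  adp <- trp[trp$stage == "adult", ]
  expect_lt(diff(range(adp$L)), 1e-12)
  expect_equal(unique(adp$sM), Lp / Lb, tolerance = 1e-9)
})

test_that("stx delays fetal growth by t_0 and stf grows linearly before birth", {
  p <- gen_params(t_0 = 5, E_Hx = 1.5)
  tr <- integrate_life_cycle(p, deb_model("stx"), f = 1)
  early <- tr[tr$t < 5 - 1e-6, ]
  expect_true(all(early$L <= 1e-4)) # still at the starting speck
  sch <- attr(tr, "schedule")
  expect_true(all(c("g", "b", "x", "p") %in% sch$event[sch$reached]))

  trf <- integrate_life_cycle(gen_params(), deb_model("stf"), f = 1)
  fet <- trf[trf$stage == "fetus" & trf$t > 0.1, ]
  slope <- (fet$L - fet$L[1]) / (fet$t - fet$t[1])
  expect_equal(slope[-1], rep(gen_params()$v / 3, nrow(fet) - 1), tolerance = 1e-6)
})

test_that("hex converts larval structure to pupal reserve and conserves the buffer", {
  p <- gen_params(E_Hp = 0.5, E_Rj = 500)
  tr <- integrate_life_cycle(p, deb_model("hex"), f = 1)
  sch <- attr(tr, "schedule")
  expect_true(all(c("b", "j", "e") %in% sch$event[sch$reached]))
  larva <- tr[tr$stage == "larva", ]
  pupa <- tr[tr$stage == "pupa", ]
  # buffer unchanged across pupation
  expect_equal(tail(larva$ER, 1), head(pupa$ER, 1), tolerance = 1e-9)
  # energy bookkeeping of the structure -> reserve conversion
  E_before <- tail(larva$E, 1) + p$E_G * tail(larva$L, 1)^3
  E_after <- head(pupa$E, 1) + p$E_G * head(pupa$L, 1)^3
  expect_equal(E_before - E_after, (1 - p$kap_V) * p$E_G * tail(larva$L, 1)^3,
    tolerance = 1e-6
  )
  # larval maturity is frozen; buffer accumulates pre-puberty
  expect_lt(diff(range(larva$EH)), 1e-9)
  expect_gt(tail(larva$ER, 1), 0)
  # imago neither grows nor allocates to reproduction
  im <- tr[tr$stage == "imago", ]
  expect_lt(diff(range(im$L)), 1e-12)
  expect_lt(diff(range(im$ER)), 1e-12)
  expect_true(all(diff(im$E) < 0))
})

test_that("hep emerges at the reproduction-buffer density threshold", {
  p <- gen_params(E_Hp = 20, E_Rj = 50)
  tr <- integrate_life_cycle(p, deb_model("hep"), f = 1)
  sch <- attr(tr, "schedule")
  expect_true(all(c("b", "p", "e") %in% sch$event[sch$reached]))
  i_e <- which(sch$event == "e")
  st <- states_at(tr, sch$age[i_e])
  expect_equal(st$ER / st$L^3, 50, tolerance = 1e-4)
  im <- tr[tr$stage == "imago", ]
  expect_lt(diff(range(im$L)), 1e-12)
})

test_that("every model type yields a finite, invariant-respecting trajectory", {
  cases <- list(
    std = gen_params(), stf = gen_params(),
    stx = gen_params(t_0 = 5, E_Hx = 1.5),
    ssj = gen_params(E_Hs = 1, t_sj = 10),
    sbp = gen_params(), abj = abj_params(),
    asj = gen_params(E_Hs = 0.5, E_Hj = 2.75), abp = abj_params(),
    hep = gen_params(E_Hp = 20, E_Rj = 50),
    hex = gen_params(E_Hp = 0.5, E_Rj = 500)
  )
  set.seed(11)
  for (lbl in names(cases)) {
    p <- cases[[lbl]]
    # jitter the core rates within a filter-passing neighbourhood
    for (nm in c("p_Am", "v", "p_M")) p[[nm]] <- p[[nm]] * runif(1, 0.9, 1.1)
    tr <- integrate_life_cycle(p, deb_model(lbl), f = 1)
    expect_true(all(is.finite(tr$E)), info = lbl)
    expect_true(all(is.finite(tr$L)), info = lbl)
    expect_true(all(tr$S >= 0 & tr$S <= 1), info = lbl)
    expect_true(all(tr$sM >= 1), info = lbl)
    # sM never decreases along the trajectory
    expect_true(all(diff(tr$sM) >= -1e-9), info = lbl)
  }
})
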