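test_that("noiseless single-cycle trace returns the true rate constants", {
  tr <- simulate_spr_trace(ka = 2e5, kd = 0.06, Rmax = 100, noise = 0)
  fit <- fit_spr_1to1(tr)
  expect_equal(fit$ka, 2e5, tolerance = 0.01)
  expect_equal(fit$kd, 0.06, tolerance = 0.01)
  expect_equal(fit$Rmax, 100, tolerance = 0.01)
  expect_equal(fit$KD, 300e-9, tolerance = 0.01)
})

test_that("K_D is recovered within 10% from noisy traces", {
  kds <- vapply(1:25, function(s)
    fit_spr_1to1(simulate_spr_trace(noise = 1, seed = s))$KD, numeric(1))
  expect_true(all(abs(kds - 300e-9) / 300e-9 < 0.1))
})

test_that("saturating concentrations trigger an identifiability warning", {
  tr <- simulate_spr_trace(ka = 2e5, kd = 0.06, Rmax = 100,
                           concentrations = c(5e-5, 1e-4), noise = 0.5,
                           seed = 2)
  expect_warning(fit <- fit_spr_1to1(tr), "correlated")
  expect_false(fit$identifiable)
  expect_equal(fit$Rmax, 100, tolerance = 0.05)
})

test_that("SPR fit is invariant under uniform response rescaling", {
  tr <- simulate_spr_trace(noise = 0.5, seed = 3)
  f1 <- fit_spr_1to1(tr)
  tr2 <- tr; tr2$R <- 3.7 * tr$R
  f2 <- fit_spr_1to1(tr2)
  expect_equal(f2$ka, f1$ka, tolerance = 1e-3)
  expect_equal(f2$kd, f1$kd, tolerance = 1e-3)
  expect_equal(f2$Rmax, 3.7 * f1$Rmax, tolerance = 1e-3)
})

test_that("fitted parameters reproduce the equilibrium plateaus", {
  tr <- simulate_spr_trace(ka = 2e5, kd = 0.06, Rmax = 100,
                           concentrations = 400e-9, t_assoc = 400,
                           t_dissoc = 30, noise = 0.3, seed = 5)
  fit <- fit_spr_1to1(tr)
  Req <- fit$Rmax * 400e-9 / (400e-9 + fit$KD)
  plateau <- max(tr$R[tr$conc > 0])
  expect_lt(abs(Req - plateau), 5 * fit$rmse + 1)
})

test_that("Tm is read off a noiseless sigmoid at grid accuracy", {
  mc <- simulate_melt_curve(tm = 67, noise = 0)
  expect_equal(compute_tm(mc), 67, tolerance = 0.26)
})

test_that("a 2-degree stability difference is resolved to 0.2 degrees", {
  d <- vapply(1:25, function(s)
    compute_tm(simulate_melt_curve(tm = 69, seed = s)) -
      compute_tm(simulate_melt_curve(tm = 67, seed = s + 500)),
    numeric(1))
  expect_lt(abs(mean(d) - 2), 0.2)
})

test_that("Tm is invariant under affine transforms of the signal", {
  mc <- simulate_melt_curve(tm = 64, noise = 0.002, seed = 9)
  t1 <- compute_tm(mc)
  mc2 <- mc; mc2$signal <- -5 * mc$signal + 11
  expect_equal(compute_tm(mc2), t1, tolerance = 1e-9)
})

test_that("degenerate melt curves are rejected", {
  Tg <- seq(15, 90, by = 0.5)
  expect_error(compute_tm(list(temperature = Tg, signal = rep(1, length(Tg)))),
               "flat")
  expect_error(compute_tm(list(temperature = Tg, signal = 0.01 * Tg + 2)),
               "Tm undefined")
})

test_that("rising and falling transitions give the same Tm", {
  mc_fall <- simulate_melt_curve(tm = 70, amplitude = -0.6, noise = 0)
  mc_rise <- simulate_melt_curve(tm = 70, amplitude = 0.6, noise = 0)
  expect_equal(compute_tm(mc_fall), compute_tm(mc_rise), tolerance = 0.3)
})
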