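test_that("Guinier fit inverts an exact Guinier curve", {
  q <- default_q_grid(300, 0.005, 0.2)
  g <- guinier_fit(scattering_profile(q, 100 * exp(-q^2 * 48^2 / 3)))
  expect_equal(g$Rg, 48, tolerance = 1e-6)
  expect_equal(g$I0, 100, tolerance = 1e-6)
  expect_lte(g$qRg_max, 1.5)
})

test_that("Guinier Rg of the bead sphere matches sqrt(3/5) R", {
  # the Guinier regime of a uniform sphere ends near q Rg ~ 1.3
  g <- guinier_fit(fx_sphere_profile(), qRg_limit = 1.3)
  expect_equal(g$Rg, sqrt(3 / 5) * 50, tolerance = 0.02)
})

test_that("Guinier fit flags unusable input", {
  q <- default_q_grid(50)
  expect_error(guinier_fit(scattering_profile(q, -abs(sin(q * 10)) - 1)),
               "no positive")
})

test_that("IFT reconstructs the sphere pair distribution", {
  truth <- mixture_truth(conformers = "s", weights = 1, noise = 0.01,
                         q_min = 0.005, q_max = 0.25)
  pe <- simulate_experiment(truth, list(fx_sphere_profile()), seed = 3)
  pr <- ift_pr(pe, 110)
  R <- 50
  pth <- pr$r^2 * (1 - 3 * pr$r / (4 * R) + pr$r^3 / (16 * R^3))
  pth[pr$r > 2 * R] <- 0
  expect_lt(max(abs(pr$p_norm - pth / max(pth))), 0.03)
  expect_equal(pr$Rg, sqrt(3 / 5) * R, tolerance = 0.01)
  # p(r) integral is proportional to I(0): cross-check against Debye
  expect_equal(pr$I0, nrow(fx_sphere()$beads)^2, tolerance = 0.05)
  expect_lt(pr$chi2, 2)
})

test_that("two-bead profile yields a single p(r) peak at the distance", {
  d <- 30
  q <- seq(0.005, 0.45, length.out = 300)
  m2 <- toy_model(rbind(c(0, 0, 0), c(d, 0, 0)))
  pm <- pr_from_model(m2, bin_width = 1)
  expect_equal(pm$r[which.max(pm$p)], d, tolerance = 1)
})

test_that("increasing regularization increases data misfit monotonically", {
  truth <- mixture_truth(conformers = "s", weights = 1, noise = 0.01,
                         q_min = 0.005, q_max = 0.25)
  pe <- simulate_experiment(truth, list(fx_sphere_profile()), seed = 8)
  alphas <- 10^seq(-4, 2, by = 2)
  chis <- vapply(alphas, function(a)
    suppressWarnings(ift_pr(pe, 110, alpha = a))$chi2, numeric(1))
  expect_true(all(diff(chis) >= -1e-8))
})

test_that("too small a Dmax is flagged as a systematic misfit", {
  truth <- mixture_truth(conformers = "s", weights = 1, noise = 0.01,
                         q_min = 0.005, q_max = 0.25)
  pe <- simulate_experiment(truth, list(fx_sphere_profile()), seed = 3)
  expect_warning(ift_pr(pe, 60), "too small")
})

test_that("Dmax scan finds the sphere diameter", {
  truth <- mixture_truth(conformers = "s", weights = 1, noise = 0.01,
                         q_min = 0.005, q_max = 0.25)
  pe <- simulate_experiment(truth, list(fx_sphere_profile()), seed = 3)
  ds <- dmax_scan(pe, c(60, 150), step = 10)
  expect_equal(ds$dmax, 100, tolerance = 0.05)
  expect_false(ds$degenerate)
})

test_that("Dmax of a thin rod is near its length (known upward bias)", {
  L <- 120
  n <- 60
  rod <- toy_model(cbind(seq(0, L, length.out = n), 0, 0))
  q <- seq(0.005, 0.25, length.out = 150)
  pr_rod <- debye_profile(rod, q, method = "exact")
  truth <- mixture_truth(conformers = "r", weights = 1, noise = 0.01,
                         q_min = 0.005, q_max = 0.25)
  pe <- simulate_experiment(truth, list(pr_rod), seed = 4)
  ds <- dmax_scan(pe, c(60, 200), step = 10)
  expect_gte(ds$dmax, L)
  expect_lte(ds$dmax, 1.2 * L)
})

test_that("Guinier and P(r) Rg agree on a compact body", {
  g <- guinier_fit(fx_sphere_profile(), qRg_limit = 1.3)
  truth <- mixture_truth(conformers = "s", weights = 1, noise = 0.01,
                         q_min = 0.005, q_max = 0.25)
  pr <- ift_pr(simulate_experiment(truth, list(fx_sphere_profile()), seed = 3),
               110)
  expect_lt(abs(g$Rg - pr$Rg) / pr$Rg, 0.03)
})

test_that("dimensionless Kratky of a pure Guinier curve peaks at sqrt(3)", {
  q <- default_q_grid(400, 0.005, 0.2)
  rg <- 45
  prof <- scattering_profile(q, 50 * exp(-q^2 * rg^2 / 3))
  g <- guinier_fit(prof)
  k <- kratky_dimensionless(prof, g)
  peak <- k$features[k$features$type == "peak", ]
  expect_equal(peak$x[1], sqrt(3), tolerance = 0.03)
  expect_equal(peak$y[1], 3 / exp(1), tolerance = 0.02)
})

test_that("mixture Guinier Rg lands in the experimental window", {
  # calibration check on the noiseless mixture; noisy draws scatter
  # around it by a few tenths of an Angstrom
  p0 <- simulate_experiment(mixture_truth(noise = 0),
                            list(fx_profile_closed(), fx_profile_open()))
  g0 <- guinier_fit(p0)
  expect_gt(g0$Rg, 48)
  expect_lt(g0$Rg, 49)
  g1 <- guinier_fit(fx_mixture_exp(seed = 1))
  expect_lt(abs(g1$Rg - g0$Rg), 1.5)
})

test_that("mixture Dmax is in the 160-170 A window at low noise", {
  pe <- fx_mixture_exp(seed = 1, noise = 0.005)
  ds <- dmax_scan(pe, c(120, 220), step = 10)
  expect_gte(ds$dmax, 160)
  expect_lte(ds$dmax, 170)
})

test_that("buffer subtraction removes the background within noise", {
  pc <- fx_profile_closed(); po <- fx_profile_open()
  truth <- mixture_truth(noise = 0.02)
  fs <- simulate_secsaxs_frames(truth, list(pc, po), n_buffer = 10,
                                n_peak = 16, seed = 6)
  sub <- subtract_buffer(fs)
  z_buf <- sub$I[, sub$is_buffer] / sub$sigma[, sub$is_buffer]
  expect_lt(abs(mean(z_buf)), 0.15)
  # single buffer frame still defined, with a larger sigma
  sub1 <- subtract_buffer(fs, buffer_idx = 1L)
  expect_true(all(sub1$sigma >= fs$sigma))
})

test_that("merging a single selected frame returns that frame", {
  pc <- fx_profile_closed(); po <- fx_profile_open()
  truth <- mixture_truth(noise = 0.02)
  fs <- simulate_secsaxs_frames(truth, list(pc, po), n_buffer = 6,
                                n_peak = 10, elution_width = 0.5, seed = 6)
  sub <- subtract_buffer(fs)
  merged <- merge_frames(sub, ratio_min = 0.9)
  keep <- attr(merged, "frames")
  if (length(keep) == 1L)
    expect_equal(merged$I, sub$I[, keep], ignore_attr = TRUE)
  expect_true(all(!fs$is_buffer[keep]))
})

test_that("reductions are deterministic for fixed input", {
  pe <- fx_mixture_exp(seed = 1)
  expect_identical(guinier_fit(pe)$Rg, guinier_fit(pe)$Rg)
  expect_identical(ift_pr(pe, 160)$p, ift_pr(pe, 160)$p)
})
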