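test_that("Debye profile reproduces closed forms", {
  q <- seq(0, 0.4, by = 0.01)
  # single bead: flat I = f^2
  p1 <- debye_profile(toy_model(c(0, 0, 0)), q)
  expect_equal(p1$I, rep(1, length(q)))
  # two beads at distance d: I = 2 + 2 sin(qd)/(qd), I(0) = 4
  d <- 30
  p2 <- debye_profile(toy_model(rbind(c(0, 0, 0), c(d, 0, 0))), q,
                      method = "exact")
  expect_equal(p2$I[1], 4)
  qq <- q[-1]
  expect_equal(p2$I[-1], 2 + 2 * sin(qq * d) / (qq * d), tolerance = 1e-12)
})

test_that("Debye profile of a bead sphere matches the analytic form factor", {
  sph <- fx_sphere()
  n <- nrow(sph$beads)
  q <- seq(0.002, 0.1, length.out = 60)
  p <- debye_profile(sph, q)
  ff <- function(x) (3 * (sin(x) - x * cos(x)) / x^3)^2
  I_th <- n^2 * ff(q * 50)
  # relative agreement away from the form-factor zero, normalized
  # agreement (in units of I(0)) across the whole qR <= 5 range
  keep <- q * 50 <= 5 & ff(q * 50) > 0.01
  expect_lt(max(abs(p$I[keep] - I_th[keep]) / I_th[keep]), 0.02)
  expect_lt(max(abs(p$I[q * 50 <= 5] - I_th[q * 50 <= 5])) / n^2, 0.02)
})

test_that("I(0) equals the squared total weight exactly", {
  m <- fx_closed()
  p <- debye_profile(m, c(0, 0.01))
  expect_equal(p$I[1], sum(m$beads$f)^2, tolerance = 1e-12)
})

test_that("binned acceleration stays within 0.5% of the exact double sum", {
  m <- fx_closed()
  q <- default_q_grid(60)
  pb <- debye_profile(m, q)
  pe <- debye_profile(m, q, method = "exact")
  expect_lt(max(abs(pb$I - pe$I) / pe$I), 0.005)
})

test_that("chi2 recovers scale and vanishes for proportional profiles", {
  q <- default_q_grid(80)
  theo <- debye_profile(fx_closed(), q)
  exp1 <- scattering_profile(q, theo$I, sigma = 0.01 * theo$I)
  r1 <- chi2(exp1, theo)
  expect_equal(r1$chi2, 0, tolerance = 1e-20)
  expect_equal(r1$c, 1)
  exp2 <- scattering_profile(q, 2 * theo$I, sigma = 0.01 * theo$I)
  r2 <- chi2(exp2, theo)
  expect_equal(r2$chi2, 0, tolerance = 1e-18)
  expect_equal(r2$c, 2)
})

test_that("chi2 is invariant under rescaling experiment and sigma together", {
  q <- default_q_grid(80)
  theo <- debye_profile(fx_closed(), q)
  exp1 <- simulate_experiment(mixture_truth(conformers = "x", weights = 1),
                              list(theo), seed = 4)
  r1 <- chi2(exp1, theo)
  exp2 <- scattering_profile(q, 7.3 * exp1$I, sigma = 7.3 * exp1$sigma)
  r2 <- chi2(exp2, theo)
  expect_equal(r2$chi2, r1$chi2, tolerance = 1e-10)
  expect_equal(r2$c, 7.3 * r1$c, tolerance = 1e-10)
})

test_that("noisy chi2 against the true profile is near one", {
  q <- default_q_grid(500)
  theo <- debye_profile(fx_closed(), q)
  truth <- mixture_truth(conformers = "x", weights = 1, noise = 0.02)
  chis <- vapply(1:100, function(s)
    chi2(simulate_experiment(truth, list(theo), seed = s), theo)$chi2,
    numeric(1))
  expect_gt(mean(chis), 0.9)
  expect_lt(mean(chis), 1.1)
})

test_that("profile text round trip preserves data", {
  p <- fx_mixture_exp(seed = 2)
  f <- withr::local_tempfile(fileext = ".dat")
  write_profile(p, f)
  p2 <- read_profile(f)
  expect_equal(p2$q, p$q, tolerance = 1e-7)
  expect_equal(p2$I, p$I, tolerance = 1e-8)
  expect_equal(p2$sigma, p$sigma, tolerance = 1e-8)
})
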