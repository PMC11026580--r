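test_that("simulate_experiment with zero noise is the exact weighted sum", {
  pc <- fx_profile_closed(); po <- fx_profile_open()
  truth <- mixture_truth(weights = c(0.6, 0.4), noise = 0)
  p <- simulate_experiment(truth, list(pc, po), seed = 1)
  expect_equal(p$I, 0.6 * pc$I + 0.4 * po$I, tolerance = 1e-14)
})

test_that("a degenerate one-component mixture returns that profile", {
  pc <- fx_profile_closed(); po <- fx_profile_open()
  truth <- mixture_truth(weights = c(1, 0), noise = 0.02)
  p <- simulate_experiment(truth, list(pc, po), seed = 1)
  expect_lt(max(abs(p$I - pc$I) / p$sigma), 5)
  expect_equal(p$sigma, 0.02 * pc$I * (1 + 5 * pc$q), tolerance = 1e-12)
})

test_that("mixture weights must be a distribution", {
  expect_error(mixture_truth(weights = c(0.7, 0.4)), "sum to 1")
  expect_error(mixture_truth(weights = c(1.2, -0.2)), "non-negative")
})

test_that("SEC-SAXS frames behave like an elution", {
  pc <- fx_profile_closed(); po <- fx_profile_open()
  truth <- mixture_truth(noise = 0.02)
  fs <- simulate_secsaxs_frames(truth, list(pc, po), n_buffer = 8,
                                n_peak = 20, seed = 3)
  expect_equal(sum(fs$is_buffer), 8L)
  # zero concentration everywhere -> frames statistically match buffer
  fs0 <- simulate_secsaxs_frames(truth, list(pc, po), n_buffer = 8,
                                 n_peak = 20, peak_frac = 0, seed = 3)
  sub0 <- subtract_buffer(fs0)
  z <- sub0$I[, !sub0$is_buffer] / sub0$sigma[, !sub0$is_buffer]
  expect_lt(abs(mean(z)), 0.1)
  expect_lt(max(abs(z)), 6)
  # apex frame has the largest integral ratio to background
  sub <- subtract_buffer(fs)
  ratios <- colSums(abs(sub$I)) / sum(sub$background)
  apex_true <- which.max(fs$truth_concentration)
  expect_equal(which.max(ratios), apex_true)
})

test_that("merged elution frames recover the mixture Rg", {
  pc <- fx_profile_closed(); po <- fx_profile_open()
  truth <- mixture_truth(noise = 0.01)
  fs <- simulate_secsaxs_frames(truth, list(pc, po), n_buffer = 8,
                                n_peak = 24, peak_frac = 4, seed = 5)
  merged <- merge_frames(subtract_buffer(fs))
  rg_merged <- guinier_fit(merged)$Rg
  rg_ref <- guinier_fit(simulate_experiment(mixture_truth(noise = 0.005),
                                            list(pc, po), seed = 1))$Rg
  expect_lt(abs(rg_merged - rg_ref) / rg_ref, 0.02)
})

test_that("SPR trace follows the 1:1 closed forms", {
  # zero concentration -> zero response
  tr0 <- simulate_spr_trace(concentrations = 0, noise = 0)
  expect_true(all(tr0$R == 0))
  # one long association reaches the Langmuir plateau
  tr <- simulate_spr_trace(ka = 2e5, kd = 0.06, Rmax = 100,
                           concentrations = 1e-6, t_assoc = 600,
                           t_dissoc = 10, noise = 0)
  KD <- 0.06 / 2e5
  expect_equal(max(tr$R), 100 * 1e-6 / (1e-6 + KD), tolerance = 1e-4)
  expect_equal(tr$truth$KD, 300e-9)
  expect_error(simulate_spr_trace(ka = -1), "> 0")
})

test_that("melt curve generator hits its target Tm", {
  mc <- simulate_melt_curve(tm = 67, noise = 0)
  expect_equal(compute_tm(mc), 67, tolerance = 0.26)
  expect_error(simulate_melt_curve(tm = 5), "inside")
})

test_that("generators are bit-reproducible under a fixed seed", {
  pc <- fx_profile_closed(); po <- fx_profile_open()
  truth <- mixture_truth(noise = 0.02)
  expect_identical(simulate_experiment(truth, list(pc, po), seed = 11)$I,
                   simulate_experiment(truth, list(pc, po), seed = 11)$I)
  expect_identical(simulate_spr_trace(seed = 4)$R, simulate_spr_trace(seed = 4)$R)
  expect_identical(simulate_melt_curve(seed = 4)$signal,
                   simulate_melt_curve(seed = 4)$signal)
  f1 <- simulate_secsaxs_frames(truth, list(pc, po), seed = 9)
  f2 <- simulate_secsaxs_frames(truth, list(pc, po), seed = 9)
  expect_identical(f1$I, f2$I)
})

test_that("ground truth sidecar writes the mixture definition", {
  truth <- mixture_truth(weights = c(0.6, 0.4), noise = 0.02)
  f <- withr::local_tempfile(fileext = ".txt")
  write_truth(truth, f)
  lines <- readLines(f)
  expect_true(any(grepl("^weights=0.6,0.4$", lines)))
  expect_true(any(grepl("^conformers=closed,open$", lines)))
})
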