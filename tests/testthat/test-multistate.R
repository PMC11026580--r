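test_that("fit_weights recovers an exact two-state mixture", {
  pc <- fx_profile_closed(); po <- fx_profile_open()
  truth <- mixture_truth(weights = c(0.6, 0.4), noise = 0)
  pe <- simulate_experiment(truth, list(pc, po), seed = 1)
  fit <- fit_weights(pe, list(pc, po), ids = c("closed", "open"))
  expect_equal(fit$weights, c(0.6, 0.4), tolerance = 1e-8)
  expect_lt(fit$chi2, 1e-6)
  expect_equal(fit$scale, 1, tolerance = 1e-8)
})

test_that("k = 1 fit reduces to the plain chi2 statistic", {
  pc <- fx_profile_closed()
  pe <- fx_mixture_exp(seed = 3)
  fit <- fit_weights(pe, list(pc))
  ref <- chi2(pe, pc)
  expect_equal(fit$weights, 1)
  expect_equal(fit$chi2, ref$chi2, tolerance = 1e-10)
  expect_equal(fit$scale, ref$c, tolerance = 1e-10)
})

test_that("weights are recovered within 0.05 at 2% noise", {
  pc <- fx_profile_closed(); po <- fx_profile_open()
  truth <- mixture_truth(weights = c(0.6, 0.4), noise = 0.02)
  w1 <- vapply(1:100, function(s) {
    pe <- simulate_experiment(truth, list(pc, po), seed = s)
    fit_weights(pe, list(pc, po))$weights[1]
  }, numeric(1))
  expect_lt(abs(mean(w1) - 0.6), 0.05)
  expect_lt(max(abs(w1 - 0.6)), 0.12)
  chis <- vapply(1:50, function(s) {
    pe <- simulate_experiment(truth, list(pc, po), seed = s)
    fit_weights(pe, list(pc, po))$chi2
  }, numeric(1))
  expect_gt(mean(chis), 0.85)
  expect_lt(mean(chis), 1.15)
})

test_that("weight vectors lie on the simplex", {
  pe <- fx_mixture_exp(seed = 5)
  ens <- fx_ensemble_small()
  sr <- multistate_search(pe, ens, k_max = 3, top_n = 20, beam_width = 15)
  for (k in 2:3) {
    tab <- sr$results[[as.character(k)]]
    for (i in seq_len(nrow(tab))) {
      w <- as.numeric(strsplit(tab$weights[i], ";")[[1]])
      expect_true(all(w >= -1e-9))
      expect_equal(sum(w), 1, tolerance = 1e-6)
    }
  }
})

test_that("best chi2 is non-increasing in k", {
  pe <- fx_mixture_exp(seed = 5)
  ens <- fx_ensemble_small()
  sr <- multistate_search(pe, ens, k_max = 3, top_n = 20, beam_width = 15)
  chis <- vapply(sr$best, `[[`, numeric(1), "chi2")
  expect_true(all(diff(chis) <= 1e-9))
})

test_that("a pool containing the truth gives an exact noiseless k=2 fit", {
  pc <- fx_profile_closed(); po <- fx_profile_open()
  truth <- mixture_truth(weights = c(0.6, 0.4), noise = 0)
  pe <- simulate_experiment(truth, list(pc, po), seed = 1)
  ens <- fx_ensemble_small()
  profs <- cbind(ens$profiles[, 1:10], closed = pc$I, open = po$I)
  colnames(profs) <- c(sprintf("c%04d", 1:10), "closed", "open")
  pool <- list(profiles = profs,
               rg = c(ens$rg[1:10], model_rg(fx_closed()), model_rg(fx_open())))
  sr <- multistate_search(pe, pool, k_max = 2, top_n = 10, beam_width = 12)
  expect_equal(sort(sr$best[["2"]]$ids), c("closed", "open"))
  expect_lt(sr$best[["2"]]$chi2, 1e-8)
  w <- sr$best[["2"]]$weights[order(sr$best[["2"]]$ids)]
  expect_equal(w, c(0.6, 0.4), tolerance = 1e-6)
})

test_that("beam search equals exhaustive enumeration on a 30-conformer pool", {
  pe <- fx_mixture_exp(seed = 7)
  ens <- fx_ensemble_small()   # 30 conformers
  sr <- multistate_search(pe, ens, k_max = 3, top_n = 50, beam_width = 100)
  for (k in 2:3) {
    ex <- multistate_exhaustive(pe, ens, k = k, top_n = 50)
    got <- sr$results[[as.character(k)]]
    expect_equal(got$ids, ex$ids)
    expect_equal(got$chi2, ex$chi2, tolerance = 1e-10)
  }
})

test_that("single-state data show no overfitting signal at k = 2", {
  pc <- fx_profile_closed()
  truth <- mixture_truth(conformers = "closed", weights = 1, noise = 0.02)
  pe <- simulate_experiment(truth, list(pc), seed = 9)
  ens <- fx_ensemble_small()
  profs <- cbind(ens$profiles, closed = pc$I)
  pool <- list(profiles = profs, rg = c(ens$rg, model_rg(fx_closed())))
  sr <- multistate_search(pe, pool, k_max = 2, top_n = 10, beam_width = 31)
  chi1 <- sr$best[["1"]]$chi2
  chi2_ <- sr$best[["2"]]$chi2
  expect_lt(chi1, 1.3)           # truth in pool: k = 1 fits well
  expect_gt(chi2_, 0.9 * chi1)   # k = 2 improves by < 10%
})

test_that("state counting localizes a synthetic two-state truth", {
  pc <- fx_profile_closed(); po <- fx_profile_open()
  truth <- mixture_truth(weights = c(0.5, 0.5), noise = 0.02)
  pe <- simulate_experiment(truth, list(pc, po), seed = 2)
  ens <- fx_ensemble_small()
  profs <- cbind(ens$profiles, closed = pc$I, open = po$I)
  pool <- list(profiles = profs,
               rg = c(ens$rg, model_rg(fx_closed()), model_rg(fx_open())))
  sr <- multistate_search(pe, pool, k_max = 2, top_n = 30, beam_width = 32)
  states <- state_count(sr, k = 2)
  expect_gte(states$n_states, 2)
  expect_equal(sum(states$peaks$mass), 1, tolerance = 1e-6)
  # the two dominant peaks bracket the truth conformer Rg values
  top2 <- states$peaks[order(-states$peaks$mass), ][1:2, ]
  expect_lt(min(abs(top2$rg - model_rg(fx_closed()))), 3)
  expect_lt(min(abs(top2$rg - model_rg(fx_open()))), 3)
})

test_that("fits pooled over one conformer give one state", {
  pc <- fx_profile_closed()
  sr <- list(results = list("2" = data.frame(
    chi2 = rep(1, 5), scale = 1, mean_rg = 45,
    ids = "a;a", weights = "0.5;0.5", stringsAsFactors = FALSE)),
    rg = 45.5, ids = "a")
  st <- state_count(sr, k = 2)
  expect_equal(st$n_states, 1L)
})
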