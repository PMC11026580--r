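test_that("glycan occupancy and chain length control the bead count", {
  sites_full <- default_glycan_sites()
  sites_full$occupancy <- 1
  m_full <- make_toy_antibody(antibody_spec(glycan_sites = sites_full))
  # 5 sites x 2 heavy chains, 9 beads each
  expect_length(m_full$glycans, 10L)
  expect_equal(sum(m_full$beads$kind == "glycan"), 90L)

  sites_none <- sites_full
  sites_none$length <- 0L
  m_none <- make_toy_antibody(antibody_spec(glycan_sites = sites_none))
  spec <- antibody_spec()
  n_protein <- 2L * spec$n_res_fab + spec$n_res_fc +
    2L * (diff(spec$hinge_range) + 1L) + 2L * (diff(spec$tail_range) + 1L)
  expect_equal(nrow(m_none$beads), n_protein)
})

test_that("spec validation rejects invalid inputs", {
  bad <- default_glycan_sites()
  bad$occupancy[1] <- 1.2
  expect_error(antibody_spec(glycan_sites = bad), "occupancy")
  expect_error(antibody_spec(glycan_weight_ratio = 0.8), "ratio")
  expect_error(antibody_spec(hinge_range = c(228, 235), tail_range = c(230, 240)),
               "overlap")
})

test_that("conformer modes land in their Rg windows", {
  m <- fx_antibody()
  rg_closed <- vapply(1:3, function(s)
    model_rg(make_conformer(m, "closed", seed = s)), numeric(1))
  rg_open <- vapply(1:3, function(s)
    model_rg(make_conformer(m, "open", seed = s)), numeric(1))
  rg_ext <- vapply(1:3, function(s)
    model_rg(make_conformer(m, "extended", seed = s)), numeric(1))
  expect_true(all(rg_closed > 43 & rg_closed < 47))
  expect_true(all(rg_open > 52 & rg_open < 54))
  expect_true(all(rg_ext > 63 & rg_ext < 66))
  expect_error(make_conformer(m, "sideways"))
})

test_that("builder and conformers are seed-reproducible", {
  m1 <- make_toy_antibody(antibody_spec(seed = 7))
  m2 <- make_toy_antibody(antibody_spec(seed = 7))
  expect_identical(model_xyz(m1), model_xyz(m2))
  c1 <- make_conformer(m1, "closed", seed = 3)
  c2 <- make_conformer(m1, "closed", seed = 3)
  expect_identical(model_xyz(c1), model_xyz(c2))
  c3 <- make_conformer(m1, "closed", seed = 4)
  expect_false(identical(model_xyz(c1), model_xyz(c3)))
})

test_that("make_conformer preserves rigid-body internal geometry", {
  m <- fx_antibody()
  cf <- make_conformer(m, "extended", seed = 2)
  for (b in names(m$bodies)) {
    idx <- m$bodies[[b]][seq(1, length(m$bodies[[b]]), by = 7)]
    d0 <- dist(model_xyz(m)[idx, ])
    d1 <- dist(model_xyz(cf)[idx, ])
    expect_lt(max(abs(d0 - d1)), 1e-6)
  }
})

test_that("domain dimensions are immunoglobulin-like", {
  m <- fx_antibody()
  for (b in c("Fab1", "Fab2", "Fc")) {
    idx <- m$bodies[[b]]
    sub <- structure_model(m$beads[idx, ], bodies = list(all = seq_along(idx)))
    rg <- model_rg(sub)
    expect_gt(rg, 20)
    expect_lt(rg, 28)
  }
})
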