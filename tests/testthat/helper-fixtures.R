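# memoized fixtures shared across test files (built once per run)
.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_antibody <- function() fx("antibody", function() make_toy_antibody())

fx_closed <- function() fx("closed", function()
  make_conformer(fx_antibody(), "closed", seed = 1))

fx_open <- function() fx("open", function()
  make_conformer(fx_antibody(), "open", seed = 1))

fx_extended <- function() fx("extended", function()
  make_conformer(fx_antibody(), "extended", seed = 1))

fx_q <- function() default_q_grid(150)

fx_profile_closed <- function() fx("p_closed", function()
  debye_profile(fx_closed(), fx_q()))

fx_profile_open <- function() fx("p_open", function()
  debye_profile(fx_open(), fx_q()))

fx_sphere <- function() fx("sphere", function() sphere_model(50, 2000))

fx_sphere_profile <- function() fx("p_sphere", function()
  debye_profile(fx_sphere(), seq(0.005, 0.25, length.out = 150)))

# noisy mixture experiment at the demo settings (equal closed/open split)
fx_mixture_exp <- function(seed = 1, noise = 0.02, weights = c(0.5, 0.5)) {
  truth <- mixture_truth(weights = weights, noise = noise)
  simulate_experiment(truth, list(fx_profile_closed(), fx_profile_open()),
                      seed = seed)
}

# small deterministic ensemble reused by the multistate tests
fx_ensemble_small <- function() fx("ens_small", function()
  sample_ensemble(fx_antibody(), n = 30, q = fx_q(), seed = 42))

# bead model helper for hand-built fixtures
toy_model <- function(xyz, f = 1) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  beads <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      f = rep_len(f, n), kind = "protein", chain = "A",
                      resno = seq_len(n), region = "all",
                      stringsAsFactors = FALSE)
  structure_model(beads, bodies = list(all = seq_len(n)))
}
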