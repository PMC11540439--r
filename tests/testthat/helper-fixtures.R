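# Shared fixtures, built in code.

# the packaged published grid, loaded once
ref_grid <- load_reference_grid(mvsref_example_grid())
ref_params <- derive_gaussian_params(ref_grid)
ref_chart <- chart_from_params(ref_params)

# a small config with spec'd reference parameters; monotone = "none" keeps the
# per-milestone marginals exactly Gaussian for calibration checks
sim_config <- function(n, seed, rho = 0.5, monotone = "none", ...) {
  simulation_config(n_embryos = n, seed = seed, rho = rho,
                    monotone = monotone, ...)
}

# synthetic parameters with constant sigma, handy for recovery tests; means
# are shifted upward so a wide constant sigma cannot produce negative times
flat_sigma_params <- function(sigma = 5) {
  p <- ref_params
  p$mu <- p$mu + 40
  p$sigma <- rep(sigma, nrow(p))
  p
}

# brute-force AUC by pair enumeration, ties worth 0.5 (independent oracle)
brute_auc <- function(score, y) {
  pos <- score[y == 1]
  neg <- score[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
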