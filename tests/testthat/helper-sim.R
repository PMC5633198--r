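# Shared fixtures: full-pipeline simulations and model fits are cached per
# seed so that multiple test files (and the acceptance suite) reuse them.

.pipeline_cache <- new.env(parent = emptyenv())

# a small, fast configuration for unit tests
tiny_cfg <- function(seed = 1, n_sites = 400, ...) {
  sim_config(n_sites = n_sites, genome_length = 2e7, seed = seed, ...)
}

# full default-scale simulation plus the standard downstream fits
pipeline_fit <- function(seed) {
  key <- paste0("s", seed)
  if (!is.null(.pipeline_cache[[key]])) return(.pipeline_cache[[key]])
  cfg <- sim_config(seed = seed)
  sim <- simulate_diallel(cfg)
  fb <- fit_blues(sim$phenotypes)
  b <- fb$blues[fb$blues$trait == "YLD", ]
  y <- stats::setNames(b$blue, b$genotype)[sim$crosses$hybrid]
  se2 <- mean(stats::setNames(b$se, b$genotype)[sim$crosses$hybrid]^2)
  keep <- sim$track$site[sim$track$gerp > 0 & !sim$truth$sites$monomorphic]
  enc <- encode_ad(sim$f1[sim$crosses$hybrid, keep])
  fit <- fit_gblup(y, enc, sigma_e = se2)
  eff <- backsolve_effects(fit, sim$track)
  blocks <- build_blocks(sim$ibd, attr(sim$track, "genome"), track = sim$track)
  out <- list(cfg = cfg, sim = sim, fb = fb, y = y, se2 = se2, enc = enc,
              fit = fit, eff = eff, blocks = blocks)
  .pipeline_cache[[key]] <- out
  out
}

# deleterious-allele dominance for block scoring, from backsolved k
k_del_from_effects <- function(eff) {
  stats::setNames(clamp_unit(-eff$k), eff$site)
}

clamp_unit <- function(x) pmin(pmax(x, -1), 1)
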