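test_that("generators are bit-identical under a fixed seed", {
  cfg <- tiny_cfg(seed = 2)
  t1 <- simulate_gerp_track(cfg, seed = 7)
  t2 <- simulate_gerp_track(cfg, seed = 7)
  expect_identical(t1, t2)
  s1 <- simulate_diallel(cfg)
  s2 <- simulate_diallel(cfg)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$ibd, s2$ibd)
})

test_that("score mixture and genic fraction behave as configured", {
  # degenerate mixture: no positive tail, hence no GERP-SNPs
  cfg0 <- tiny_cfg(pos_weight = 0)
  tr0 <- simulate_gerp_track(cfg0, seed = 1)
  expect_true(all(tr0$gerp <= 0))
  expect_error(sim_config(pos_weight = 1.5), "mixture")
  # genic fraction: binomial count around the expectation
  cfg <- sim_config(n_sites = 5000, genic_fraction = 0.64)
  tr <- simulate_gerp_track(cfg, seed = 3)
  exp_genic <- 5000 * 0.64
  tol <- 3 * sqrt(5000 * 0.64 * 0.36)
  expect_lt(abs(sum(tr$genic) - exp_genic), tol)
  # positive-score mean decreases with recombination (built-in enrichment)
  pos <- tr$gerp > 0
  expect_lt(stats::cor(tr$gerp[pos], tr$recomb[pos], method = "spearman"), 0)
})

test_that("parents are fully inbred and the strong-selection limit empties the panel", {
  cfg <- tiny_cfg(seed = 3)
  sim <- simulate_diallel(cfg)
  expect_true(all(sim$genotypes %in% c(0L, 2L)))
  # unconditioned sampling with overwhelming selection: every site fixed for
  # the conserved allele
  cfg_s <- tiny_cfg(ascertain = FALSE,
                    sel_coef_law = function(g) rep(50, length(g)))
  fg <- simulate_frequencies_and_genotypes(simulate_gerp_track(cfg_s, seed = 2),
                                           cfg_s, seed = 2)
  pos_sites <- which(!is.na(fg$truth$s))
  expect_true(all(fg$genotypes[, pos_sites] == 0L))
})

test_that("recessive deleterious alleles segregate at higher frequencies than additive ones", {
  # analytic: p = sqrt(mu/s) (k = 1) exceeds p = 2 mu / s (k = 0) for mu << s;
  # check the sampled panel frequencies agree within binomial error
  base <- list(n_sites = 2000, genome_length = 2e7, ascertain = FALSE, mu = 1e-4,
               sel_coef_law = function(g) rep(0.01, length(g)))
  cfg_rec <- do.call(sim_config, c(base, list(dominance_law = function(g, n = length(g)) rep(1, n))))
  cfg_add <- do.call(sim_config, c(base, list(dominance_law = function(g, n = length(g)) rep(0, n))))
  p_rec <- sqrt(1e-4 / 0.01); p_add <- 2 * 1e-4 / 0.01
  expect_gt(p_rec, p_add)
  fr <- function(cfg) {
    tr <- simulate_gerp_track(cfg, seed = 5)
    fg <- simulate_frequencies_and_genotypes(tr, cfg, seed = 5)
    pos <- tr$gerp > 0
    c(mean(fg$truth$p[pos]), mean(fg$truth$freq[pos]))
  }
  rec <- fr(cfg_rec); add <- fr(cfg_add)
  expect_equal(rec[1], p_rec, tolerance = 1e-8)
  expect_equal(add[1], p_add, tolerance = 1e-8)
  expect_gt(rec[2], add[2])  # realized frequencies preserve the ordering
})

test_that("panel frequencies decline with conservation score", {
  pf <- pipeline_fit(1)
  pos <- pf$sim$track$gerp > 0
  rho <- stats::cor(pf$sim$truth$sites$freq[pos], pf$sim$track$gerp[pos],
                    method = "spearman")
  expect_lt(rho, 0)
})

test_that("IBD segments force genotype identity and respect bounds", {
  cfg <- tiny_cfg(seed = 6)
  sim <- simulate_diallel(cfg)
  segs <- sim$ibd
  expect_true(all(segs$start < segs$end))
  expect_true(all(segs$start >= 0 & segs$end <= cfg$genome_length))
  for (i in seq_len(min(nrow(segs), 40))) {
    inseg <- sim$track$pos >= segs$start[i] & sim$track$pos < segs$end[i]
    if (!any(inseg)) next
    expect_identical(sim$genotypes[segs$parent_a[i], inseg],
                     sim$genotypes[segs$parent_b[i], inseg])
  }
  # zero mean length produces no segments
  cfg0 <- tiny_cfg(ibd_mean_len = 0)
  expect_equal(nrow(simulate_ibd_segments(cfg0, seed = 1)), 0)
  # doubling segment density increases the number of haplotype blocks
  nblocks <- function(frac, sd) {
    cfg <- tiny_cfg(seed = sd, ibd_frac = frac)
    segs <- simulate_ibd_segments(cfg, seed = sd)
    nrow(build_blocks(segs, c("1" = cfg$genome_length)))
  }
  more <- vapply(1:3, function(sd) nblocks(0.16, sd) > nblocks(0.08, sd), logical(1))
  expect_true(all(more))
})

test_that("true effects carry the configured score relationships", {
  cfg <- tiny_cfg(seed = 8)
  tr <- simulate_gerp_track(cfg, seed = 8)
  # zero dominance law: a purely additive trait
  cfg0 <- tiny_cfg(dominance_law = function(g, n = length(g)) rep(0, n))
  e0 <- simulate_effects(tr, cfg0, seed = 1)
  expect_true(all(e0$d == 0))
  eff <- simulate_effects(tr, cfg, seed = 9)
  y <- eff[eff$trait == "YLD" & eff$gerp > 0, ]
  # conserved-allele dominance increases with score (deleterious allele more
  # recessive), so k_del = -k decreases
  expect_lt(stats::coef(stats::lm(-y$k ~ y$gerp))[2], 0)
  expect_gt(stats::coef(stats::lm(y$a ~ y$gerp))[2], 0)
  # flowering-like trait is additive and score-free
  f <- eff[eff$trait == "FT", ]
  expect_true(all(f$d == 0))
  # calibration: realized hybrid dominance-variance share hits the target
  pf <- pipeline_fit(1)
  expect_lt(abs(pf$sim$truth$dom_share - 0.24), 0.05)
  # independent recomputation of the calibrated share from truth effects
  sim <- pf$sim
  keep <- colnames(pf$enc$X)
  et <- sim$effects[sim$effects$trait == "YLD", ]
  av <- stats::setNames(et$a, et$site)[keep]
  dv <- stats::setNames(et$d, et$site)[keep]
  alpha <- av - (1 - 2 * pf$enc$p) * dv
  uA <- drop(pf$enc$X %*% alpha)
  uD <- drop(pf$enc$W %*% dv)
  expect_lt(abs(stats::var(uD) / (stats::var(uA) + stats::var(uD)) - 0.24), 0.05)
})

test_that("true breeding values equal the per-site Falconer sum", {
  cfg <- tiny_cfg(seed = 10)
  sim <- simulate_diallel(cfg)
  eff <- sim$effects[sim$effects$trait == "YLD", ]
  a <- stats::setNames(eff$a, eff$site)
  d <- stats::setNames(eff$d, eff$site)
  gv <- genetic_value(sim$f1, eff)
  for (h in sample(rownames(sim$f1), 3)) {
    total <- 0
    for (s in colnames(sim$f1)) {
      x <- sim$f1[h, s]
      total <- total + switch(as.character(x), "0" = a[[s]], "1" = d[[s]], "2" = -a[[s]])
    }
    expect_equal(unname(gv[h]), total)
  }
  # the stored genetic values are the Falconer sums plus the trait baseline
  G <- sim$truth$genetic_values
  shift <- G[rownames(sim$f1), "YLD"] - gv
  expect_lt(diff(range(shift)), 1e-9)
})

test_that("phenotype generation responds to the heritability target", {
  # more residual variance lowers fitted heritability
  h2s <- c(0.45, 0.95)
  fitted <- vapply(h2s, function(h2) {
    cfg <- tiny_cfg(seed = 12, h2 = c(YLD = 0.9, FT = h2), gxe_ratio = 0)
    sim <- simulate_diallel(cfg)
    fb <- fit_blues(sim$phenotypes)
    fb$varcomp$H2[fb$varcomp$trait == "FT"]
  }, numeric(1))
  expect_lt(fitted[1], fitted[2])
  expect_error(simulate_diallel(tiny_cfg(gxe_ratio = 10)), "unattainable")
  cfg <- tiny_cfg(seed = 13)
  sim <- simulate_diallel(cfg)
  expect_error(
    simulate_diallel_phenotypes(sim$genotypes, sim$effects,
                                data.frame(hybrid = "x", parent1 = "P01", parent2 = "QQ"),
                                cfg),
    "unknown parent")
})

test_that("heterosis of the yield-like trait is strong and positive for flowering-like it is absent", {
  pf <- pipeline_fit(1)
  mph <- compute_mph(pf$fb$blues, pf$sim$crosses)
  expect_gt(mean(mph$mph_pct[mph$trait == "YLD"]), 25)
  expect_lt(abs(mean(mph$mph_pct[mph$trait == "FT"])), 2)
})
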