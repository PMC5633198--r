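perm_track <- function(n = 7) {
  data.frame(site = sprintf("s%d", 1:n), chrom = "1", pos = seq_len(n) * 10,
             end = seq_len(n) * 10 + 1, gerp = seq_len(n) / 10,
             genic = rep(c(TRUE, FALSE), length.out = n), recomb = 1,
             stringsAsFactors = FALSE)
}

test_that("circular permutation rotates scores within windows and preserves multisets", {
  tr <- perm_track(7)
  tr$gerp <- c(1, 2, 3, 4, 5, 6, 7)  # a..g
  # window of 3, offset 1 per window: (a,b,c | d,e,f | g) -> (c,a,b | f,d,e | g)
  out <- circular_permutation(tr, window_snps = 3, n_shuffles = 1,
                              offsets = list(c(1, 1, 1)))[[1]]
  expect_equal(out$gerp, c(3, 1, 2, 6, 4, 5, 7))
  # offset 0 leaves the track unchanged
  out0 <- circular_permutation(tr, window_snps = 3, n_shuffles = 1,
                               offsets = list(c(0, 0, 0)))[[1]]
  expect_equal(out0$gerp, tr$gerp)
  # random rotations preserve the per-window score multiset
  set.seed(2)
  big <- perm_track(100)
  big$gerp <- stats::rnorm(100)
  for (p in circular_permutation(big, window_snps = 30, n_shuffles = 5)) {
    for (w in list(1:30, 31:60, 61:90, 91:100)) {
      expect_equal(sort(p$gerp[w]), sort(big$gerp[w]))
    }
  }
  # genic-only permutation leaves intergenic scores in place
  set.seed(3)
  pg <- circular_permutation(big, window_snps = 10, n_shuffles = 3,
                             genic_only = TRUE)
  for (p in pg) expect_equal(p$gerp[!big$genic], big$gerp[!big$genic])
  expect_error(circular_permutation(big[sample(100), ], 10), "sorted")
})

test_that("with all blocks included, posterior means approach ridge regression", {
  set.seed(14)
  n <- 20; m <- 10
  X <- matrix(stats::rnorm(n * m), n, m, dimnames = list(NULL, paste0("b", 1:m)))
  beta <- stats::rnorm(m, 0, 1)
  y <- drop(X %*% beta) + stats::rnorm(n, 0, 0.5)
  set.seed(15)
  fit <- bayesc_fit(X, y, bayesc_config(n_iter = 20000, burn_in = 2000, pi = 0))
  lambda <- fit$s2e / fit$s2b
  ridge <- ridge_oracle(X, y, lambda)
  expect_gt(stats::cor(fit$beta, ridge), 0.99)
  expect_true(all(fit$inclusion == 1))
})

test_that("BayesC recovers sparse block effects and is seed-reproducible", {
  # sparse architecture (10% of 200 blocks causal), 66 records, h2 = 0.7,
  # prior exclusion probability set to the generative sparsity
  set.seed(77)
  X <- matrix(stats::rnorm(66 * 200), 66, 200,
              dimnames = list(NULL, paste0("b", 1:200)))
  cors <- vapply(1:10, function(sd) {
    set.seed(500 + sd)
    r <- stats::rnorm(200) * stats::rbinom(200, 1, 0.1)
    g <- drop(X %*% r)
    y <- g + stats::rnorm(66, 0, stats::sd(g) * sqrt(3 / 7))
    fit <- bayesc_fit(X, y, bayesc_config(pi = 0.9))
    stats::cor(fit$beta, r)
  }, numeric(1))
  expect_true(all(cors > 0.5))
  # bit-reproducibility under a fixed seed, on real block scores
  pf <- pipeline_fit(1)
  sc <- score_blocks(pf$sim$f1, pf$blocks, pf$sim$track, model = "additive")
  y <- drop(sc %*% stats::rnorm(ncol(sc), 0, 0.2)) + stats::rnorm(nrow(sc))
  set.seed(99); f1 <- bayesc_fit(sc, y, bayesc_config(n_iter = 500, burn_in = 50))
  set.seed(99); f2 <- bayesc_fit(sc, y, bayesc_config(n_iter = 500, burn_in = 50))
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$pve, f2$pve)
  expect_error(bayesc_fit(sc, rep(1, nrow(sc))), "zero-variance")
})

test_that("cross-validation accuracy is near one for deterministic signal and near zero for noise", {
  pf <- pipeline_fit(1)
  sc <- score_blocks(pf$sim$f1, pf$blocks, pf$sim$track, model = "additive")
  set.seed(23)
  r <- stats::rnorm(ncol(sc), 0, 1)
  y_det <- drop(sc %*% r)
  cv <- cross_validate(sc, y_det, bayesc_config(), n_splits = 5)
  expect_gt(cv$mean_accuracy, 0.9)
  y_noise <- stats::rnorm(nrow(sc))
  cvn <- cross_validate(sc, y_noise, bayesc_config(), n_splits = 10)
  expect_lt(abs(cvn$mean_accuracy), 0.25)
  # identical seeds give identical split assignments and accuracies
  set.seed(31); cv1 <- cross_validate(sc, y_det, bayesc_config(), n_splits = 3)
  set.seed(31); cv2 <- cross_validate(sc, y_det, bayesc_config(), n_splits = 3)
  expect_identical(cv1$splits, cv2$splits)
  expect_identical(cv1$accuracy, cv2$accuracy)
})

test_that("real-vs-permuted comparison flags only genuine differences", {
  set.seed(41)
  acc <- stats::rnorm(30, 0.5, 0.05)
  pm <- matrix(stats::rnorm(90, 0.5, 0.05), 30, 3)
  r_null <- compare_real_vs_permuted(list(GY = acc), list(GY = pm))
  expect_false(r_null$significant)
  r_shift <- compare_real_vs_permuted(list(GY = acc + 0.5), list(GY = pm))
  expect_true(r_shift$significant)
  expect_lt(r_shift$p_value, 1e-6)
  expect_error(compare_real_vs_permuted(list(GY = acc[1:10]), list(GY = pm)),
               "mismatched")
  # Benjamini-Hochberg across traits
  r2 <- compare_real_vs_permuted(list(A = acc + 0.5, B = acc),
                                 list(A = pm, B = pm))
  expect_equal(r2$fdr, stats::p.adjust(r2$p_value, "BH"))
})

test_that("combining-ability model comparison detects genomically captured structure", {
  pf <- pipeline_fit(1)
  crosses <- pf$sim$crosses
  y <- pf$y
  blues <- data.frame(genotype = names(y), trait = "YLD", blue = unname(y))
  # null: a noise breeding value neither helps the fit nor lowers AIC much
  set.seed(13)
  g_noise <- stats::setNames(stats::rnorm(length(y)), names(y))
  r0 <- gca_model_comparison(blues, crosses, list(YLD = g_noise))
  expect_gt(r0$f_p_value, 0.01)
  # additive block scores decompose into parental contributions, so an
  # additive-model breeding value is exactly collinear with the GCA design —
  # flagged, not an error
  sc_add <- score_blocks(pf$sim$f1, pf$blocks, pf$sim$track, model = "additive")
  set.seed(14)
  fa <- bayesc_fit(sc_add[names(y), ], y, bayesc_config())
  ra <- gca_model_comparison(blues, crosses, list(YLD = stats::setNames(fa$fitted, names(y))))
  expect_true(ra$collinear)
  # a dominance-aware breeding value carries cross-specific (SCA-like)
  # signal beyond combining abilities and lowers AIC
  eff <- pf$eff
  k_del <- k_del_from_effects(eff)
  sc_inc <- score_blocks(pf$sim$f1, pf$blocks, pf$sim$track,
                         k_del = k_del, model = "incomplete")
  set.seed(15)
  fi <- bayesc_fit(sc_inc[names(y), ], y, bayesc_config())
  r1 <- gca_model_comparison(blues, crosses, list(YLD = stats::setNames(fi$fitted, names(y))))
  expect_false(r1$collinear)
  expect_lt(r1$delta_aic, 0)
  expect_lt(r1$f_p_value, 0.05)
})

test_that("triploid dosage interpolation reduces to the diploid scheme and breaks AAB/ABB symmetry", {
  gm <- rbind(A = c(0L, 2L, 0L), B = c(2L, 2L, 0L))
  colnames(gm) <- c("s1", "s2", "s3")
  w <- c(s1 = 1.5, s2 = 2, s3 = 1)
  crosses <- data.frame(hybrid = "AxB", parent1 = "A", parent2 = "B")
  # fully recessive deleterious allele: a single copy in three is fully masked
  tp <- triploid_projection(gm, crosses, w, k_del = c(s1 = -1, s2 = -1, s3 = -1))
  # s1: A conserved, B deleterious -> AAB dosage 1 scores 1.5 * 1 * (1 - 1) = 0
  #     ABB dosage 2 scores 1.5 * 2 * (1 - 1/2) = 1.5; s2: fixed deleterious,
  #     dosage 3 scores 2 * 3 * (1 + k * 0) = 6 in both triploids
  expect_equal(tp$aab, 0 + 6 + 0)
  expect_equal(tp$abb, 1.5 + 6 + 0)
  # diploid F1: s1 het -> 0 under full recessivity; s2 hom -> 2 * 2
  expect_equal(tp$diploid, 0 + 4 + 0)
  # identical parents: triploid load is 1.5x the diploid load (dosage scaling)
  ci <- data.frame(hybrid = "AxA", parent1 = "A", parent2 = "A")
  ti <- triploid_projection(gm, ci, w, k_del = c(s1 = -0.4, s2 = -0.4, s3 = -0.4))
  expect_equal(ti$aab, ti$abb)
  expect_equal(ti$aab, 1.5 * ti$diploid)
  # asymmetry whenever the parents differ at a weighted site
  expect_true(tp$aab != tp$abb)
  expect_error(triploid_projection(gm, crosses, c(s1 = 0, s2 = 0, s3 = 0)),
               "positively weighted")
})
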