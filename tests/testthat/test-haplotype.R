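seg_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(parent_a = r[[1]], parent_b = r[[2]], chrom = "1",
               start = as.numeric(r[[3]]), end = as.numeric(r[[4]]),
               stringsAsFactors = FALSE)
  }))
}

test_that("haplotype blocks tile the chromosome between IBD breakpoints", {
  genome <- c("1" = 10000)
  # no segments: whole chromosome is one block
  b0 <- build_blocks(NULL, genome)
  expect_equal(nrow(b0), 1)
  expect_equal(c(b0$start, b0$end), c(0, 10000))
  # a single segment introduces its endpoints as breakpoints
  b1 <- build_blocks(seg_df(list("P1", "P2", 2000, 5000)), genome)
  expect_equal(b1$start, c(0, 2000, 5000))
  expect_equal(b1$end, c(2000, 5000, 10000))
  # short inter-breakpoint gaps are dropped by the length filter
  b2 <- build_blocks(seg_df(list("P1", "P2", 2000, 2500),
                            list("P1", "P3", 2500, 5000)),
                     genome, min_len = 1000)
  expect_false(any(b2$end - b2$start < 1000))
  expect_equal(nrow(b2), 3)  # [0,2000) [2500,5000) [5000,10000)
  b3 <- build_blocks(seg_df(list("P1", "P2", 2000, 2500)), genome, min_len = 100)
  expect_equal(nrow(b3), 3)
  expect_error(build_blocks(seg_df(list("P1", "P2", 500, 500)), genome), "start < end")
})

test_that("member SNPs are assigned by half-open containment and blocks partition them", {
  genome <- c("1" = 1000)
  track <- data.frame(site = c("a", "b", "c", "d"), chrom = "1",
                      pos = c(50, 199, 200, 999), end = c(51, 200, 201, 1000),
                      gerp = c(1, -1, 2, 0.5), genic = TRUE, recomb = 1)
  b <- build_blocks(seg_df(list("P1", "P2", 200, 800)), genome,
                    track = track, min_len = 10)
  expect_equal(b$sites[[1]], c("a", "b"))   # [0, 200): pos 199 included
  expect_equal(b$sites[[2]], "c")           # [200, 800): pos 200 included
  expect_equal(b$sites[[3]], "d")
  expect_equal(b$n_gerp_snps, c(1L, 1L, 1L))
  # memberships are disjoint and cover all sites
  expect_equal(sort(unlist(b$sites)), sort(track$site))
})

test_that("F1 projection equals brute-force allele addition for all 66 crosses", {
  expect_equal(unname(project_f1(rbind(A = 0L, B = 0L),
                                 data.frame(hybrid = "AxB", parent1 = "A", parent2 = "B"))[1, 1]), 0L)
  pf <- pipeline_fit(1)
  gm <- pf$sim$genotypes
  crosses <- pf$sim$crosses
  f1 <- pf$sim$f1
  idx <- sample(ncol(gm), 50)
  for (i in sample(nrow(crosses), 10)) {
    g1 <- gm[crosses$parent1[i], idx]
    g2 <- gm[crosses$parent2[i], idx]
    expect_equal(unname(f1[crosses$hybrid[i], idx]),
                 as.integer((g1 + g2) / 2))
  }
  # missing and heterozygous parents propagate
  gmh <- rbind(A = c(2L, 1L, NA), B = c(0L, 0L, 2L))
  colnames(gmh) <- c("x", "y", "z")
  expect_warning(
    f1h <- project_f1(gmh, data.frame(hybrid = "AxB", parent1 = "A", parent2 = "B")),
    "heterozygous")
  expect_equal(unname(f1h[1, ]), c(1L, NA, NA))
  expect_error(project_f1(gmh, data.frame(hybrid = "q", parent1 = "A", parent2 = "Q")),
               "unknown parent")
})

single_block_fixture <- function(g = 2) {
  genome <- c("1" = 1000)
  track <- data.frame(site = "s1", chrom = "1", pos = 100, end = 101,
                      gerp = g, genic = TRUE, recomb = 1)
  blocks <- build_blocks(NULL, genome, track = track, min_len = 10)
  f1 <- matrix(c(0L, 1L, 2L), 3, 1, dimnames = list(c("h0", "h1", "h2"), "s1"))
  list(track = track, blocks = blocks, f1 = f1)
}

test_that("per-SNP block scores follow the 0 / (1+k)g / 2g assignment", {
  fx <- single_block_fixture(g = 2)
  sc_add <- score_blocks(fx$f1, fx$blocks, fx$track, model = "additive")
  expect_equal(unname(sc_add[, 1]), c(0, 2, 4))       # k_het = 0
  sc_dom <- score_blocks(fx$f1, fx$blocks, fx$track, model = "dominance")
  expect_equal(unname(sc_dom[, 1]), c(0, 0, 4))       # full complementation
  sc_inc <- score_blocks(fx$f1, fx$blocks, fx$track,
                         k_del = c(s1 = 0.5), model = "incomplete")
  expect_equal(unname(sc_inc[, 1]), c(0, 3, 4))       # (1 + 0.5) * 2
  expect_error(score_blocks(fx$f1, fx$blocks, fx$track, model = "incomplete"),
               "k_del")
})

test_that("block scores equal the per-SNP brute-force oracle on random instances", {
  set.seed(77)
  for (trial in 1:50) {
    n_snps <- 10; n_hyb <- 6
    genome <- c("1" = 10000)
    pos <- sort(sample(0:9999, n_snps))
    track <- data.frame(site = sprintf("s%02d", 1:n_snps), chrom = "1",
                        pos = pos, end = pos + 1,
                        gerp = round(stats::runif(n_snps, -1, 3), 2),
                        genic = TRUE, recomb = 1)
    cuts <- sort(sample(500:9500, 4))
    segs <- seg_df(list("P1", "P2", cuts[1], cuts[2]),
                   list("P1", "P3", cuts[3], cuts[4]))
    blocks <- build_blocks(segs, genome, track = track, min_len = 1)
    f1 <- matrix(sample(c(0L, 1L, 2L, NA), n_hyb * n_snps, replace = TRUE,
                        prob = c(0.4, 0.3, 0.25, 0.05)),
                 n_hyb, n_snps,
                 dimnames = list(paste0("h", 1:n_hyb), track$site))
    k_del <- stats::setNames(stats::runif(n_snps, -1.5, 1.5), track$site)
    for (mm in c("additive", "dominance", "incomplete")) {
      got <- score_blocks(f1, blocks, track, k_del = k_del, model = mm)
      want <- score_blocks_oracle(f1, blocks, track, clamp_unit(k_del), mm)
      expect_equal(got, want, ignore_attr = TRUE)
    }
  }
})

test_that("incomplete-dominance scoring interpolates the additive and dominance models", {
  pf <- pipeline_fit(1)
  sim <- pf$sim
  sites <- colnames(sim$f1)
  k0 <- stats::setNames(rep(0, length(sites)), sites)
  km1 <- stats::setNames(rep(-1, length(sites)), sites)
  sc_add <- score_blocks(sim$f1, pf$blocks, sim$track, model = "additive")
  sc_dom <- score_blocks(sim$f1, pf$blocks, sim$track, model = "dominance")
  expect_equal(score_blocks(sim$f1, pf$blocks, sim$track, k_del = k0,
                            model = "incomplete"), sc_add, ignore_attr = TRUE)
  expect_equal(score_blocks(sim$f1, pf$blocks, sim$track, k_del = km1,
                            model = "incomplete"), sc_dom, ignore_attr = TRUE)
})

test_that("replacing a heterozygote by the deleterious homozygote never lowers a block score", {
  fx <- single_block_fixture(g = 1.3)
  for (kd in c(-1, -0.3, 0, 0.6, 1)) {
    sc <- score_blocks(fx$f1, fx$blocks, fx$track,
                       k_del = c(s1 = kd), model = "incomplete")
    expect_lte(sc["h1", 1], sc["h2", 1])
    expect_equal(unname(sc["h0", 1]), 0)  # all-conserved hybrid scores zero
  }
})

test_that("naive IBD caller finds long runs of genotype identity", {
  n <- 200
  pos <- seq(0, by = 1000, length.out = n)
  track <- data.frame(site = sprintf("s%03d", 1:n), chrom = "1",
                      pos = pos, end = pos + 1, gerp = 1, genic = TRUE, recomb = 1)
  set.seed(5)
  g1 <- 2L * stats::rbinom(n, 1, 0.3)
  g2 <- 2L * stats::rbinom(n, 1, 0.3)
  g2[51:150] <- g1[51:150]  # shared segment of 100 consecutive sites
  g2[1:50][g1[1:50] == g2[1:50]] <- 2L - g1[1:50][g1[1:50] == g2[1:50]]
  g2[151:200][g1[151:200] == g2[151:200]] <- 2L - g1[151:200][g1[151:200] == g2[151:200]]
  gm <- rbind(A = g1, B = g2)
  colnames(gm) <- track$site
  segs <- call_ibd_naive(gm, track, min_snps = 50)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start, pos[51])
  expect_equal(segs$end, pos[150] + 1)
})
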