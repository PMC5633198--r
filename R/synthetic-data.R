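#' Simulate a per-site conservation-score track
#'
#' Draws site positions uniformly on a single linear chromosome and assigns
#' each site a GERP-like conservation score from a two-part mixture: with
#' probability `pos_weight` a positive (constrained) score, otherwise a
#' non-positive score (point mass at 0 with a small negative tail). The
#' positive tail is exponential with mean decreasing in the local
#' recombination rate, so that constrained sites are enriched in
#' low-recombination regions; the recombination landscape itself dips in the
#' chromosome centre, mimicking a pericentromeric region. A genic indicator
#' is drawn with probability `genic_fraction` per site.
#'
#' @param config A [sim_config()] object.
#' @param seed Optional seed; when NULL the current RNG stream is used.
#' @return A `gerp_track` data frame with columns `site`, `chrom`, `pos`
#'   (0-based), `end`, `gerp`, `genic`, `recomb` (cM/Mb), sorted by position,
#'   with attribute `genome` (named chromosome-length vector).
#' @export
simulate_gerp_track <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_sites
  L <- config$genome_length
  pos <- sort(sample.int(L, n)) - 1
  rel <- pos / L
  # recombination landscape: high at chromosome arms, low near the centre
  recomb <- 0.1 + 4 * (2 * abs(rel - 0.5))^2 + stats::rgamma(n, shape = 2, rate = 4)
  is_pos <- stats::runif(n) < config$pos_weight
  gerp <- numeric(n)
  npos <- sum(is_pos)
  if (npos) {
    mean_g <- 1.8 / (1 + 0.5 * recomb[is_pos])
    gerp[is_pos] <- stats::rexp(npos, rate = 1 / mean_g)
  }
  nneg <- sum(!is_pos)
  if (nneg) {
    tail <- stats::runif(nneg) < 0.3
    gerp[!is_pos][tail] <- -stats::rexp(sum(tail), rate = 2)
  }
  genic <- stats::runif(n) < config$genic_fraction
  track <- data.frame(site = sprintf("s%05d", seq_len(n)), chrom = "1",
                      pos = pos, end = pos + 1, gerp = gerp, genic = genic,
                      recomb = recomb, stringsAsFactors = FALSE)
  attr(track, "genome") <- c("1" = L)
  class(track) <- c("gerp_track", "data.frame")
  track
}

#' Simulate equilibrium frequencies and inbred-panel genotypes
#'
#' For each positively scored site, the deleterious-allele frequency is the
#' mutation-selection-balance equilibrium from [equilibrium_frequency()],
#' with the selection coefficient and dominance drawn from the configured
#' laws; non-positive-score sites receive neutral-like frequencies from a
#' scaled Beta distribution. Each fully inbred parent then carries the
#' deleterious allele homozygously with probability equal to the site
#' frequency, so genotypes are strictly 0 or 2. Sites monomorphic across the
#' panel are flagged.
#'
#' By default sites are ascertained as segregating variants (SNPs): the panel
#' carrier count is drawn from the binomial conditioned on polymorphism
#' (0 < count < n), mirroring the fact that an observed SNP set contains only
#' sites that happen to segregate in the sequenced panel. With
#' `ascertain = FALSE` in the configuration, unconditioned binomial sampling
#' is used and most strongly selected sites come out monomorphic.
#'
#' @inheritParams simulate_gerp_track
#' @param track Track from [simulate_gerp_track()].
#' @return List with `genotypes` (parents x sites integer matrix of
#'   deleterious-allele dosages), and `truth` — a data frame per site with
#'   equilibrium frequency `p`, fitness dominance `k_fit`, selection
#'   coefficient `s`, realized panel frequency `freq`, and `monomorphic`
#'   flag. The number of frequencies clamped into `[0, 0.5]` is in attribute
#'   `n_clamped` of `truth`.
#' @export
simulate_frequencies_and_genotypes <- function(track, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(track)
  np <- config$n_parents
  pos <- track$gerp > 0
  p <- numeric(n); s <- rep(NA_real_, n); kf <- rep(NA_real_, n)
  if (any(pos)) {
    s[pos] <- config$sel_coef_law(track$gerp[pos])
    if (any(!is.finite(s[pos])) || any(s[pos] <= 0)) {
      stop("sel_coef_law must return positive finite values for positive scores")
    }
    kf[pos] <- config$dominance_law(track$gerp[pos])
    pp <- equilibrium_frequency(config$mu, s[pos], kf[pos])
    n_clamped <- attr(pp, "n_clamped")
    p[pos] <- as.numeric(pp)
  } else {
    n_clamped <- 0L
  }
  if (any(!pos)) p[!pos] <- 0.5 * stats::rbeta(sum(!pos), 0.8, 2)
  ascertain <- config$ascertain %||% TRUE
  if (ascertain) {
    # carrier count | segregation: truncated Binomial(np, p) on 1..np-1
    cnt <- vapply(p, function(pj) {
      pr <- stats::dbinom(seq_len(np - 1), np, max(pj, 1e-12))
      if (sum(pr) <= 0) return(1L)
      sample.int(np - 1, 1, prob = pr)
    }, integer(1))
    gm <- matrix(0L, np, n, dimnames = list(config$parents, track$site))
    for (j in seq_len(n)) gm[sample.int(np, cnt[j]), j] <- 2L
  } else {
    gm <- matrix(2L * stats::rbinom(np * n, 1L, rep(p, each = np)),
                 nrow = np, dimnames = list(config$parents, track$site))
  }
  truth <- data.frame(site = track$site, p = p, k_fit = kf, s = s,
                      freq = colMeans(gm) / 2,
                      monomorphic = apply(gm, 2, function(x) length(unique(x[!is.na(x)])) < 2),
                      stringsAsFactors = FALSE)
  attr(truth, "n_clamped") <- n_clamped
  list(genotypes = gm, truth = truth)
}

#' Simulate pairwise IBD segments
#'
#' For each unordered pair of parents, draws a Poisson number of
#' identity-by-descent segments whose expected total length covers
#' `ibd_frac` of the genome, with exponentially distributed lengths of mean
#' `ibd_mean_len`; overlapping segments within a pair are merged. Segments
#' respect chromosome bounds. Use [force_ibd_identity()] to make genotypes
#' consistent with the emitted segments.
#'
#' @inheritParams simulate_gerp_track
#' @return Data frame `parent_a`, `parent_b`, `chrom`, `start`, `end`
#'   (0-based half-open), possibly with zero rows.
#' @export
simulate_ibd_segments <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- config$genome_length
  empty <- data.frame(parent_a = character(0), parent_b = character(0),
                      chrom = character(0), start = numeric(0), end = numeric(0),
                      stringsAsFactors = FALSE)
  if (config$ibd_mean_len <= 0 || config$ibd_frac <= 0) return(empty)
  pairs <- utils::combn(config$parents, 2)
  lambda <- config$ibd_frac * L / config$ibd_mean_len
  out <- list()
  for (q in seq_len(ncol(pairs))) {
    m <- stats::rpois(1, lambda)
    if (m == 0) next
    start <- floor(stats::runif(m, 0, L))
    len <- pmax(1, stats::rexp(m, rate = 1 / config$ibd_mean_len))
    end <- pmin(L, start + len)
    o <- order(start)
    start <- start[o]; end <- end[o]
    # merge overlaps within the pair
    ms <- start[1]; me <- end[1]; merged <- list()
    if (m > 1) {
      for (i in 2:m) {
        if (start[i] <= me) me <- max(me, end[i]) else {
          merged[[length(merged) + 1]] <- c(ms, me); ms <- start[i]; me <- end[i]
        }
      }
    }
    merged[[length(merged) + 1]] <- c(ms, me)
    mm <- do.call(rbind, merged)
    out[[length(out) + 1]] <- data.frame(
      parent_a = pairs[1, q], parent_b = pairs[2, q], chrom = "1",
      start = mm[, 1], end = mm[, 2], stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Force genotype identity inside IBD segments
#'
#' Makes a parent genotype matrix consistent with a set of pairwise IBD
#' segments: at every site covered by a segment, the two parents of the pair
#' must be identical. Because pairwise constraints are transitive at a site,
#' parents are grouped per site by label propagation over all covering
#' segments and every group member receives the genotype of its
#' lowest-indexed member.
#'
#' @param gm Parent genotype matrix (parents x sites).
#' @param segments IBD segment data frame from [simulate_ibd_segments()].
#' @param track Site track giving the coordinate of each `gm` column.
#' @return The modified genotype matrix.
#' @export
force_ibd_identity <- function(gm, segments, track) {
  if (is.null(segments) || nrow(segments) == 0) return(gm)
  parents <- rownames(gm)
  n <- ncol(gm)
  lab <- matrix(rep(seq_along(parents), n), nrow = length(parents))
  cover <- lapply(seq_len(nrow(segments)), function(i) {
    which(track$chrom == segments$chrom[i] &
            track$pos >= segments$start[i] & track$pos < segments$end[i])
  })
  ia <- match(segments$parent_a, parents)
  ib <- match(segments$parent_b, parents)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(segments))) {
      idx <- cover[[i]]
      if (!length(idx)) next
      m <- pmin(lab[ia[i], idx], lab[ib[i], idx])
      if (any(lab[ia[i], idx] != m) || any(lab[ib[i], idx] != m)) {
        lab[ia[i], idx] <- m
        lab[ib[i], idx] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  for (j in seq_len(n)) {
    lj <- lab[, j]
    if (all(lj == seq_along(parents))) next
    # each IBD group shares the genotype of a randomly chosen member, which
    # preserves the marginal allele frequency of the site
    for (cl in unique(lj)) {
      members <- which(lj == cl)
      if (length(members) > 1) {
        gm[members, j] <- gm[members[sample.int(length(members), 1)], j]
      }
    }
  }
  gm
}

#' Simulate true per-SNP trait effects
#'
#' Generates the ground-truth effect table for two traits. For the yield-like
#' trait `YLD`, the additive effect of the conserved allele, `a`, increases in
#' expectation with conservation score (so the deleterious allele decreases
#' yield), and the conserved-allele dominance `k` also increases with score
#' (more damaging alleles are more recessive); the dominance deviation is
#' `d = k * a`. For the flowering-like trait `FT`, effects are independent of
#' conservation score and purely additive (`d = 0`).
#'
#' When realized allele frequencies are supplied, dominance deviations of the
#' yield-like trait are rescaled by a single global factor (found by root
#' search, with `d <= a` enforced) so that the dominance-variance share
#' `V_D / (V_A + V_D)` matches `config$dom_share`. When the hybrid genotype
#' matrix `f1` is also supplied, the share is measured on the realized
#' additive and dominance variance components of the hybrid population
#' (`var(X alpha)` and `var(W d)` with the orthogonal encodings of
#' [encode_ad()]), which accounts for linkage between sites in the
#' 12-haplotype panel; otherwise the independent-sites single-locus sums are
#' used: `V_A = 2 f (1 - f) alpha^2` with `alpha = a - d (1 - 2 f)` and
#' `V_D = (2 f (1 - f) d)^2`, where `f` is the deleterious-allele frequency.
#'
#' @inheritParams simulate_frequencies_and_genotypes
#' @param freqs Optional named per-site realized deleterious-allele
#'   frequencies (e.g. `truth$freq` from
#'   [simulate_frequencies_and_genotypes()]) used for calibration.
#' @param f1 Optional hybrid genotype matrix (hybrids x sites, deleterious
#'   dosage) for realized-variance calibration.
#' @return Data frame with one row per site and trait: `site`, `trait`,
#'   `gerp`, `a`, `d`, `k`, `alpha`, `va`, `vd` (the latter three NA when
#'   `freqs` is NULL). Attribute `lambda` records the calibration factor and
#'   attribute `realized_dom_share` the calibrated hybrid-variance share
#'   (when `f1` is given).
#' @export
simulate_effects <- function(track, config, freqs = NULL, f1 = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(track)
  pos <- track$gerp > 0
  ## yield-like trait
  a_y <- numeric(n)
  a_y[pos] <- config$effect_law(track$gerp[pos])
  a_y[!pos] <- abs(stats::rnorm(sum(!pos), 0, 0.005))
  k_y <- numeric(n)
  k_y[pos] <- config$dominance_law(track$gerp[pos])
  d_y <- k_y * a_y
  lambda <- 1
  realized_share <- NA_real_
  if (!is.null(freqs)) {
    f <- freqs[track$site]
    segp <- pos & f > 0 & f < 1
    if (is.null(f1)) {
      share <- function(lam) {
        d <- pmin(lam * d_y[segp], a_y[segp])
        alpha <- a_y[segp] - d * (1 - 2 * f[segp])
        va <- 2 * f[segp] * (1 - f[segp]) * alpha^2
        vd <- (2 * f[segp] * (1 - f[segp]) * d)^2
        sum(vd) / (sum(va) + sum(vd))
      }
    } else {
      # realized hybrid-population variances under the orthogonal encodings
      sites <- track$site[segp]
      fh <- colMeans(f1[, sites, drop = FALSE]) / 2
      use <- fh > 0 & fh < 1
      sites <- sites[use]
      fh <- fh[use]
      x <- f1[, sites, drop = FALSE]
      Xm <- matrix(rep(2 * fh, each = nrow(f1)), nrow(f1)) - x
      Wm <- matrix(0, nrow(f1), length(sites))
      Wm[x == 0L] <- matrix(rep(-2 * fh^2, each = nrow(f1)), nrow(f1))[x == 0L]
      Wm[x == 1L] <- matrix(rep(2 * fh * (1 - fh), each = nrow(f1)), nrow(f1))[x == 1L]
      Wm[x == 2L] <- matrix(rep(-2 * (1 - fh)^2, each = nrow(f1)), nrow(f1))[x == 2L]
      a_seg <- a_y[match(sites, track$site)]
      d_seg <- d_y[match(sites, track$site)]
      share <- function(lam) {
        d <- pmin(lam * d_seg, a_seg)
        alpha <- a_seg - d * (1 - 2 * fh)
        va <- stats::var(drop(Xm %*% alpha))
        vd <- stats::var(drop(Wm %*% d))
        vd / (va + vd)
      }
    }
    if (sum(segp) >= 2 && config$dom_share > 0) {
      lo <- share(0); hi <- share(8)
      if (hi <= config$dom_share) {
        lambda <- 8
        warning("dominance-variance share target unattainable; using maximal rescaling")
      } else if (lo >= config$dom_share) {
        lambda <- 0
      } else {
        lambda <- stats::uniroot(function(l) share(l) - config$dom_share,
                                 c(0, 8), tol = 1e-6)$root
      }
    }
    realized_share <- share(lambda)
    d_y <- pmin(lambda * d_y, a_y)
    k_y <- ifelse(a_y > 0, d_y / a_y, 0)
  }
  ## flowering-like trait: additive, unlinked to conservation
  a_f <- abs(stats::rnorm(n, 0, 0.03))
  eff <- rbind(
    data.frame(site = track$site, trait = "YLD", gerp = track$gerp,
               a = a_y, d = d_y, k = k_y, stringsAsFactors = FALSE),
    data.frame(site = track$site, trait = "FT", gerp = track$gerp,
               a = a_f, d = 0, k = 0, stringsAsFactors = FALSE))
  if (!is.null(freqs)) {
    f <- freqs[eff$site]
    eff$alpha <- eff$a - eff$d * (1 - 2 * f)
    eff$va <- 2 * f * (1 - f) * eff$alpha^2
    eff$vd <- (2 * f * (1 - f) * eff$d)^2
  } else {
    eff$alpha <- eff$va <- eff$vd <- NA_real_
  }
  attr(eff, "lambda") <- lambda
  attr(eff, "realized_dom_share") <- realized_share
  eff
}

#' True genetic value of genotypes given per-site effects
#'
#' Sums the single-locus genotype values over sites: a genotype with 0, 1 or
#' 2 copies of the deleterious allele contributes `+a`, `d`, `-a`
#' respectively. Missing genotypes contribute 0.
#'
#' @param gm Genotype matrix (individuals x sites, deleterious dosage 0/1/2).
#' @param effects Effect table from [simulate_effects()] filtered to one
#'   trait.
#' @return Named numeric vector of genetic values.
#' @export
genetic_value <- function(gm, effects) {
  stopifnot(length(unique(effects$trait)) == 1)
  a <- stats::setNames(effects$a, effects$site)[colnames(gm)]
  d <- stats::setNames(effects$d, effects$site)[colnames(gm)]
  X <- gm
  X[is.na(X)] <- NA
  hom0 <- X == 0L; het <- X == 1L; hom2 <- X == 2L
  hom0[is.na(hom0)] <- FALSE; het[is.na(het)] <- FALSE; hom2[is.na(hom2)] <- FALSE
  drop(hom0 %*% a + het %*% d - hom2 %*% a)
}

#' Simulate plot-level diallel phenotypes
#'
#' Generates the multi-year replicated field trial: for every phenotyped
#' genotype (all hybrids of the cross list plus the inbred parents), plot
#' values are `mu + G + year + rep(year) + block(rep) + GxE + residual`.
#' Genotypes are re-randomized into incomplete blocks within every replicate
#' (a resolvable design), so genotype effects are estimable free of block
#' confounding. Non-genetic variances are set from the target broad-sense
#' heritability via `H2 = V_G / (V_G + V_GxE / i + V_E / (i j))` with
#' `V_GxE = gxe_ratio * V_G`, where `V_G` is the genetic variance of the
#' hybrid population (the material the genomic analyses model). For a trait
#' with directional dominance the inbred-hybrid gap inflates the all-entries
#' genetic variance, so the all-entries heritability implied by the chosen
#' components (`H2_implied` in the returned `varcomp`) exceeds the
#' hybrid-level target; [compute_H2()] on the full trial recovers
#' `H2_implied`, and recovers the target itself for a purely additive trait
#' (no gap).
#'
#' @param genotypes Parent genotype matrix (parents x sites).
#' @param effects Effect table from [simulate_effects()].
#' @param crosses Cross list (see [diallel_crosses()]); a subset is allowed.
#' @param config A [sim_config()].
#' @param seed Optional seed.
#' @return List with `plots` (data frame `genotype`, `year`, `rep`, `block`,
#'   `trait`, `value`), `genetic_values` (genotype x trait matrix of true
#'   values including the trait baseline), and `varcomp` (per-trait V_G,
#'   V_GxE, V_E used).
#' @export
simulate_diallel_phenotypes <- function(genotypes, effects, crosses, config,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  unknown <- setdiff(unique(c(crosses$parent1, crosses$parent2)), rownames(genotypes))
  if (length(unknown)) stop("unknown parent(s) in cross list: ", paste(unknown, collapse = ", "))
  f1 <- suppressWarnings(project_f1(genotypes, crosses))
  all_gm <- rbind(genotypes, f1)
  traits <- unique(effects$trait)
  ids <- rownames(all_gm)
  is_inbred <- ids %in% rownames(genotypes)
  ni <- config$n_years; nj <- config$n_reps
  G <- matrix(NA_real_, length(ids), length(traits),
              dimnames = list(ids, traits))
  varcomp <- list(); plots <- list()
  for (tr in traits) {
    h2 <- config$h2[[tr]] %||% stop("no h2 configured for trait ", tr)
    g <- genetic_value(all_gm, effects[effects$trait == tr, ])
    vg_all <- stats::var(g)
    # the heritability target is calibrated on the hybrid population (the
    # material the genomic analyses model); for a trait with dominance the
    # inbred-hybrid gap inflates the all-entries genetic variance, so the
    # all-entries H2 implied by these components is reported alongside
    vg <- stats::var(g[!is_inbred])
    if (h2 >= 1) {
      vgxe <- 0; ve <- 0
    } else {
      vgxe <- config$gxe_ratio * vg
      ve <- ni * nj * (vg * (1 / h2 - 1) - vgxe / ni)
      if (ve < 0) stop("h2 target unattainable with configured gxe_ratio")
    }
    if (tr == "YLD") {
      # anchor the yield intercept so hybrids exceed the mid-parent mean by
      # the configured heterosis ratio (strong hybrid vigour, as observed
      # for yield in elite maize diallels); floored so every mid-parent BLUE
      # stays well above zero and percent heterosis is stable
      t_mph <- config$mph_target %||% 1.82
      b_anchor <- (mean(g[!is_inbred]) - (1 + t_mph) * mean(g[is_inbred])) / t_mph
      mids <- (g[crosses$parent1] + g[crosses$parent2]) / 2
      noise_mid <- sqrt((ve / (ni * nj) + vgxe / ni) / 2)
      b_safe <- -min(mids) + 4 * noise_mid + 0.15 * (mean(mids) - min(mids))
      b <- max(b_anchor, b_safe)
    } else {
      b <- 70
    }
    G[, tr] <- g + b
    varcomp[[tr]] <- c(V_G = vg_all, V_G_hyb = vg, V_GxE = vgxe, V_E = ve,
                       H2_implied = if (h2 >= 1) 1 else
                         vg_all / (vg_all + vgxe / ni + ve / (ni * nj)),
                       H2_hyb = h2)
    year_eff <- if (ve == 0 && vgxe == 0) rep(0, ni) else
      stats::rnorm(ni, 0, sqrt(0.5 * vg))
    gxe <- matrix(stats::rnorm(length(ids) * ni, 0, sqrt(vgxe)), length(ids), ni)
    for (i in seq_len(ni)) {
      for (j in seq_len(nj)) {
        rep_eff <- stats::rnorm(1, 0, sqrt(0.2 * ve))
        # resolvable design: block membership re-randomized every replicate,
        # so genotype effects are estimable free of block confounding
        blocks <- sample(rep(c("B1", "B2", "B3"), length.out = length(ids)))
        blk_lv <- unique(blocks)
        blk_eff <- stats::setNames(stats::rnorm(length(blk_lv), 0, sqrt(0.2 * ve)), blk_lv)
        val <- G[, tr] + year_eff[i] + rep_eff + blk_eff[blocks] + gxe[, i] +
          stats::rnorm(length(ids), 0, sqrt(ve))
        plots[[length(plots) + 1]] <- data.frame(
          genotype = ids, year = i, rep = j, block = blocks, trait = tr,
          value = unname(val), stringsAsFactors = FALSE)
      }
    }
  }
  list(plots = do.call(rbind, plots), genetic_values = G,
       varcomp = do.call(rbind, varcomp))
}

#' Run the full synthetic-diallel generator
#'
#' Orchestrates the generators under a single seed: conservation track,
#' equilibrium frequencies and panel genotypes, IBD segments (with genotype
#' identity enforced inside segments), true effects (calibrated to the
#' configured dominance-variance share), F1 projection, and plot-level
#' phenotypes, together with ground-truth records for parameter-recovery
#' tests.
#'
#' @param config A [sim_config()].
#' @return List with `config`, `track`, `genotypes`, `ibd`, `crosses`, `f1`,
#'   `effects`, `phenotypes` (plot data frame), and `truth` (site truth table,
#'   true genetic values, variance components, calibration factor).
#' @export
simulate_diallel <- function(config = sim_config()) {
  set.seed(config$seed)
  track <- simulate_gerp_track(config)
  fg <- simulate_frequencies_and_genotypes(track, config)
  ibd <- simulate_ibd_segments(config)
  gm <- force_ibd_identity(fg$genotypes, ibd, track)
  fg$truth$freq <- colMeans(gm) / 2
  fg$truth$monomorphic <- apply(gm, 2, function(x) length(unique(x[!is.na(x)])) < 2)
  crosses <- diallel_crosses(config$parents)
  f1 <- project_f1(gm, crosses)
  effects <- simulate_effects(track, config,
                              freqs = stats::setNames(fg$truth$freq, fg$truth$site),
                              f1 = f1)
  ph <- simulate_diallel_phenotypes(gm, effects, crosses, config)
  list(config = config, track = track, genotypes = gm, ibd = ibd,
       crosses = crosses, f1 = f1, effects = effects,
       phenotypes = ph$plots,
       truth = list(sites = fg$truth, genetic_values = ph$genetic_values,
                    varcomp = ph$varcomp,
                    dom_lambda = attr(effects, "lambda"),
                    dom_share = attr(effects, "realized_dom_share")))
}
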