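#' Configuration for the BayesC block-regression sampler
#'
#' @param n_iter Total Gibbs iterations (default 4,100 for routine use; set
#'   41,000 with `burn_in = 1000` for a long chain).
#' @param burn_in Iterations discarded as burn-in (default 100).
#' @param pi Fixed prior exclusion probability of a block; `NULL` (default)
#'   estimates pi with a Beta prior.
#' @param pi_prior Beta prior (a, b) on the exclusion probability when
#'   estimated (default Beta(1, 9)).
#' @param nu_b,nu_e Prior degrees of freedom for the slab and residual
#'   variances (scaled inverse-chi-square).
#' @param r2 Fraction of phenotypic variance attributed a priori to the
#'   blocks; sets the slab scale (default 0.5).
#' @return List of class `bayesc_config`.
#' @export
bayesc_config <- function(n_iter = 4100, burn_in = 100, pi = NULL,
                          pi_prior = c(1, 9), nu_b = 4, nu_e = 4, r2 = 0.5) {
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (!is.null(pi) && (pi < 0 || pi > 1)) stop("pi must lie in [0, 1]")
  structure(list(n_iter = n_iter, burn_in = burn_in, pi = pi,
                 pi_prior = pi_prior, nu_b = nu_b, nu_e = nu_e, r2 = r2),
            class = "bayesc_config")
}

#' BayesC fit of phenotypes on haplotype-block scores
#'
#' Bayesian variable-selection regression of a phenotype (BLUEs or
#' mid-parent heterosis) on block complementation scores,
#' `y_i = mu + sum_j r_j I_ij + e`, with a spike-and-slab prior on the block
#' coefficients (common slab variance, exclusion probability pi estimated by
#' default). Gibbs sampling runs in compiled code using R's RNG, so results
#' are reproducible with `set.seed()`.
#'
#' @param scores Block-score matrix (individuals x blocks), rows aligned to
#'   `y`.
#' @param y Numeric phenotype vector.
#' @param config A [bayesc_config()].
#' @return List of class `bayesc_fit`: posterior means `mu`, `beta` (named by
#'   block), `inclusion`, `pi`, `s2b`, `s2e`; `fitted` values; and `pve`, the
#'   posterior variance explained (squared correlation of fitted and
#'   observed).
#' @export
bayesc_fit <- function(scores, y, config = bayesc_config()) {
  scores <- as.matrix(scores)
  if (nrow(scores) != length(y)) stop("rows of `scores` must align with `y`")
  if (ncol(scores) < 2) stop("need >= 2 blocks")
  if (any(!is.finite(scores))) stop("non-finite block scores")
  if (stats::var(y) == 0) stop("zero-variance phenotype")
  vy <- stats::var(y)
  mean_x2 <- mean(colMeans(scores^2))
  pi0 <- config$pi %||% (config$pi_prior[1] / sum(config$pi_prior))
  m_in <- max(1, ncol(scores) * (1 - pi0))
  target_s2b <- config$r2 * vy / (m_in * max(mean_x2, 1e-12))
  scale_b <- target_s2b * max(config$nu_b - 2, 0.5) / config$nu_b
  scale_e <- (1 - config$r2) * vy * max(config$nu_e - 2, 0.5) / config$nu_e
  res <- .bayesc_gibbs(scores, y,
                       as.integer(config$n_iter), as.integer(config$burn_in),
                       pi_init = pi0, estimate_pi = is.null(config$pi),
                       pi_a = config$pi_prior[1], pi_b = config$pi_prior[2],
                       nu_b = config$nu_b, scale_b = scale_b,
                       nu_e = config$nu_e, scale_e = scale_e)
  beta <- stats::setNames(as.numeric(res$beta), colnames(scores))
  fitted <- drop(res$mu + scores %*% beta)
  pve <- if (stats::sd(fitted) == 0) 0 else stats::cor(fitted, y)^2
  structure(list(mu = res$mu, beta = beta,
                 inclusion = stats::setNames(as.numeric(res$inclusion),
                                             colnames(scores)),
                 pi = res$pi, s2b = res$s2b, s2e = res$s2e,
                 fitted = fitted, pve = pve, config = config),
            class = "bayesc_fit")
}

#' Predict from a BayesC fit
#' @param object A `bayesc_fit`.
#' @param newdata Block-score matrix with the same columns.
#' @param ... Ignored.
#' @export
predict.bayesc_fit <- function(object, newdata, ...) {
  drop(object$mu + as.matrix(newdata)[, names(object$beta), drop = FALSE] %*%
         object$beta)
}

#' Cross-validated prediction accuracy of the block model
#'
#' Repeated random 80/20 splits (the hold-out fraction of a 5-fold scheme):
#' for each split the model is trained on 80% of individuals and accuracy is
#' the Pearson correlation between predicted and observed values on the
#' remaining 20%. Split assignments are generated from the current RNG state
#' (seed with `set.seed()`), or supplied explicitly via `splits` so that
#' competing models and permutation nulls can share identical training and
#' validation sets.
#'
#' @inheritParams bayesc_fit
#' @param n_splits Number of random splits (default 100).
#' @param folds Hold-out is `1/folds` of the data (default 5).
#' @param splits Optional list of validation-index vectors to reuse.
#' @param method Accuracy correlation method (`"pearson"` default).
#' @return List with `accuracy` (per-split vector), `mean_accuracy`, and
#'   `splits` (the validation-index list).
#' @export
cross_validate <- function(scores, y, config = bayesc_config(),
                           n_splits = 100, folds = 5, splits = NULL,
                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- length(y)
  if (n < 10) stop("need >= 10 records")
  n_val <- max(1, round(n / folds))
  if (is.null(splits)) {
    splits <- vector("list", n_splits)
    for (s in seq_len(n_splits)) {
      repeat {
        v <- sort(sample.int(n, n_val))
        if (length(v) >= 3 && stats::sd(y[v]) > 0 && (n - length(v)) >= 5) break
      }
      splits[[s]] <- v
    }
  }
  acc <- vapply(seq_along(splits), function(s) {
    v <- splits[[s]]
    fit <- bayesc_fit(scores[-v, , drop = FALSE], y[-v], config)
    pred <- predict(fit, scores[v, , drop = FALSE])
    if (stats::sd(pred) == 0) return(0)
    stats::cor(pred, y[v], method = method)
  }, numeric(1))
  list(accuracy = acc, mean_accuracy = mean(acc), splits = splits)
}

#' Circularly permute conservation scores along the genome
#'
#' Produces null score tracks that preserve the local score distribution and
#' coordinates but break the score-to-site assignment: sites are ordered by
#' coordinate and partitioned into consecutive windows of `window_snps`
#' sites; within each window the score vector is rotated by a random offset
#' (each window and shuffle independently). Optionally only genic sites are
#' rotated (the non-genic scores stay in place), controlling for
#' genic/intergenic score differences.
#'
#' @param track Site track sorted by coordinate.
#' @param window_snps Sites per window (default 50,000; a window larger than
#'   the site count means one whole-track rotation).
#' @param n_shuffles Number of permuted tracks (default 10).
#' @param genic_only Rotate only genic sites.
#' @param offsets Optional list (length `n_shuffles`) of integer offset
#'   vectors, one per window, for deterministic rotation.
#' @return List of `n_shuffles` tracks with permuted `gerp` columns.
#' @export
circular_permutation <- function(track, window_snps = 50000, n_shuffles = 10,
                                 genic_only = FALSE, offsets = NULL) {
  ord <- order(track$chrom, track$pos)
  if (any(ord != seq_len(nrow(track)))) stop("track must be sorted by coordinate")
  idx <- if (genic_only) which(track$genic) else seq_len(nrow(track))
  nw <- max(1, ceiling(length(idx) / window_snps))
  win_of <- rep(seq_len(nw), each = window_snps, length.out = length(idx))
  lapply(seq_len(n_shuffles), function(s) {
    newg <- track$gerp
    for (w in seq_len(nw)) {
      wi <- idx[win_of == w]
      len <- length(wi)
      if (len < 2) next
      off <- if (!is.null(offsets)) offsets[[s]][w] %% len
             else sample.int(len, 1) - 1L
      if (off == 0) next
      rot <- c(newg[wi][(len - off + 1):len], newg[wi][1:(len - off)])
      newg[wi] <- rot
    }
    tr <- track
    tr$gerp <- newg
    tr
  })
}

#' Compare real and permuted cross-validation accuracies
#'
#' One-sided paired test (real > permuted), per trait, of cross-validation
#' accuracies across shared splits, with the permuted accuracy per split
#' averaged over shuffles; p-values are Benjamini-Hochberg adjusted across
#' traits.
#'
#' @param real Named list (by trait) of per-split accuracy vectors.
#' @param perm Named list (by trait) of matrices, rows = the same splits,
#'   columns = shuffles.
#' @param fdr_level Significance threshold on the adjusted p-value.
#' @return Data frame `trait`, `mean_real`, `mean_perm`, `diff`, `p_value`,
#'   `fdr`, `significant`.
#' @export
compare_real_vs_permuted <- function(real, perm, fdr_level = 0.05) {
  stopifnot(identical(sort(names(real)), sort(names(perm))))
  rows <- lapply(names(real), function(tr) {
    r <- real[[tr]]
    pm <- as.matrix(perm[[tr]])
    if (nrow(pm) != length(r)) stop("mismatched split sets for trait ", tr)
    pbar <- rowMeans(pm)
    dif <- r - pbar
    p <- if (stats::sd(dif) == 0) {
      if (mean(dif) > 0) 0 else 1
    } else {
      stats::t.test(r, pbar, paired = TRUE, alternative = "greater")$p.value
    }
    data.frame(trait = tr, mean_real = mean(r), mean_perm = mean(pbar),
               diff = mean(dif), p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$fdr < fdr_level
  out
}

#' Compare the genomic prediction model with a combining-ability model
#'
#' Least-squares fits of `Y_ij = mu + GCA_i + GCA_j + e` and
#' `Y_ij = mu + GCA_i + GCA_j + G_ij + e`, where `G_ij` is the breeding
#' value of the hybrid from the genomic prediction model; reports the
#' nested-model F-test and the AIC difference (model with G minus GCA-only;
#' negative favours the genomic model), Benjamini-Hochberg adjusted across
#' traits.
#'
#' @param blues Hybrid BLUE data frame (`genotype`, `trait`, `blue`).
#' @param crosses Cross list (`hybrid`, `parent1`, `parent2`).
#' @param gebv Named list (by trait) of named hybrid breeding-value vectors.
#' @return Data frame `trait`, `f_p_value`, `fdr`, `delta_aic`, `collinear`.
#' @export
gca_model_comparison <- function(blues, crosses, gebv) {
  parents <- sort(unique(c(crosses$parent1, crosses$parent2)))
  Z <- matrix(0, nrow(crosses), length(parents),
              dimnames = list(crosses$hybrid, parents))
  for (i in seq_len(nrow(crosses))) {
    Z[i, crosses$parent1[i]] <- 1
    Z[i, crosses$parent2[i]] <- 1
  }
  rows <- lapply(names(gebv), function(tr) {
    b <- blues[blues$trait == tr, ]
    y <- stats::setNames(b$blue, b$genotype)[crosses$hybrid]
    g <- gebv[[tr]][crosses$hybrid]
    if (anyNA(y) || anyNA(g)) stop("missing BLUE or breeding value for trait ", tr)
    m1 <- stats::lm(y ~ Z)
    m2 <- stats::lm(y ~ Z + g)
    collinear <- any(is.na(stats::coef(m2)["g"]))
    pf <- if (collinear) NA_real_ else stats::anova(m1, m2)[2, "Pr(>F)"]
    data.frame(trait = tr, f_p_value = pf,
               delta_aic = stats::AIC(m2) - stats::AIC(m1),
               collinear = collinear, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$f_p_value, method = "BH")
  out[, c("trait", "f_p_value", "fdr", "delta_aic", "collinear")]
}

#' Project triploid hybrid load scores from diploid parents
#'
#' Predicts GERP-weighted load for simulated triploids with unbalanced
#' genome composition (AAB: two copies of parent 1's genome; ABB: two of
#' parent 2's), to contrast with the diploid F1 and the parents. Per site
#' the deleterious-allele dosage in a ploidy-`m` genotype is
#' `x in 0..m`, and the site score is the dosage interpolation
#' `w * x * (1 + k_del * (m - x) / (m - 1))`, which at `m = 2` reduces to
#' the diploid 0 / (1 + k_del) w / 2 w scheme of [score_blocks()]. Values
#' are summed over positively weighted sites; larger scores mean a larger
#' expressed deleterious load (i.e. a lower predicted breeding value).
#'
#' @param gm Parent genotype matrix (deleterious dosage 0/2).
#' @param crosses Cross list.
#' @param weights Named per-site positive weights (conservation score `g`,
#'   or an effect-size magnitude).
#' @param k_del Named per-SNP deleterious-allele dominance in `[-1, 1]`
#'   (-1 fully recessive, 0 additive, +1 fully dominant); missing sites
#'   default to 0.
#' @return Data frame `hybrid`, `parent1`, `parent2`, `diploid`, `aab`,
#'   `abb`, `parent1_self`, `parent2_self` (per-genotype summed load
#'   scores).
#' @export
triploid_projection <- function(gm, crosses, weights, k_del = NULL) {
  sites <- intersect(colnames(gm), names(weights)[weights > 0])
  if (!length(sites)) stop("no positively weighted sites")
  w <- weights[sites]
  kd <- rep(0, length(sites))
  names(kd) <- sites
  if (!is.null(k_del)) {
    kk <- clamp(k_del[sites], -1, 1)
    kd[!is.na(kk)] <- kk[!is.na(kk)]
  }
  load_m <- function(x, m) sum(w * x * (1 + kd * (m - x) / (m - 1)), na.rm = TRUE)
  res <- lapply(seq_len(nrow(crosses)), function(i) {
    gA <- gm[crosses$parent1[i], sites] / 2  # 0/1 haplotype carrier state
    gB <- gm[crosses$parent2[i], sites] / 2
    data.frame(hybrid = crosses$hybrid[i], parent1 = crosses$parent1[i],
               parent2 = crosses$parent2[i],
               diploid = load_m(gA + gB, 2),
               aab = load_m(2 * gA + gB, 3),
               abb = load_m(gA + 2 * gB, 3),
               parent1_self = load_m(2 * gA, 2),
               parent2_self = load_m(2 * gB, 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
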