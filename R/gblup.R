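#' Additive and dominance genotype encodings
#'
#' Encodes hybrid genotypes with the centred parameterisation that makes
#' additive and dominance effects orthogonal at a locus under Hardy-Weinberg
#' proportions. With `x` the number of copies of the counted (deleterious,
#' A2) allele and `p` its frequency, the additive codes for genotypes
#' A1A1 / A1A2 / A2A2 are `X = 2p - x = {2p, 2p - 1, 2p - 2}` and the
#' dominance codes `W = {-2p^2, 2p(1 - p), -2(1 - p)^2}`; both have zero
#' expectation under Hardy-Weinberg proportions. Monomorphic sites (p = 0 or
#' 1) are dropped. Genomic relationship matrices are
#' `G_A = X X' / sum(2 p (1 - p))` and `G_D = W W' / sum((2 p (1 - p))^2)`.
#'
#' @param gm Genotype matrix (individuals x sites) coded as copies of the
#'   deleterious (A2) allele, 0/1/2, NA allowed (mean-imputed in the codes).
#' @param freqs Optional named frequencies of the *deleterious* allele used
#'   for the encoding; by default estimated from `gm` itself (the hybrid
#'   sample).
#' @return List with matrices `X`, `W` (individuals x retained sites), `p`
#'   (counted deleterious-allele frequency per retained site), `sumA`,
#'   `sumD` (denominators), and relationship matrices `GA`, `GD`. Dropped
#'   sites are listed in `dropped`.
#' @export
encode_ad <- function(gm, freqs = NULL) {
  if (is.null(freqs)) {
    fdel <- colMeans(gm, na.rm = TRUE) / 2
  } else {
    fdel <- freqs[colnames(gm)]
  }
  p <- fdel  # frequency of the counted (deleterious) allele
  keep <- which(!is.na(p) & p > 0 & p < 1)
  dropped <- colnames(gm)[setdiff(seq_along(p), keep)]
  gm <- gm[, keep, drop = FALSE]
  p <- p[keep]
  n <- nrow(gm)
  dos <- gm  # copies of A2 (deleterious)
  X <- matrix(rep(2 * p, each = n), n) - dos
  q <- 1 - p
  W <- matrix(NA_real_, n, length(p), dimnames = dimnames(gm))
  W[dos == 0L] <- matrix(rep(-2 * p^2, each = n), n)[dos == 0L]
  W[dos == 1L] <- matrix(rep(2 * p * q, each = n), n)[dos == 1L]
  W[dos == 2L] <- matrix(rep(-2 * q^2, each = n), n)[dos == 2L]
  for (M in c("X", "W")) {
    m <- get(M)
    if (anyNA(m)) {
      cm <- colMeans(m, na.rm = TRUE)
      idx <- which(is.na(m), arr.ind = TRUE)
      m[idx] <- cm[idx[, 2]]
      assign(M, m)
    }
  }
  dimnames(X) <- dimnames(W) <- dimnames(gm)
  sumA <- sum(2 * p * q)
  sumD <- sum((2 * p * q)^2)
  list(X = X, W = W, p = p, sumA = sumA, sumD = sumD,
       GA = tcrossprod(X) / sumA, GD = tcrossprod(W) / sumD,
       dropped = dropped)
}

reml_loglik <- function(y, Vlist, sigma2, Xf) {
  V <- Reduce(`+`, Map(`*`, Vlist, sigma2))
  n <- length(y)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-1e10)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi <- chol2inv(ch)
  XtVi <- crossprod(Xf, Vi)
  XtViX <- XtVi %*% Xf
  chX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chX)) return(-1e10)
  logdetX <- 2 * sum(log(diag(chX)))
  beta <- chol2inv(chX) %*% XtVi %*% y
  r <- y - Xf %*% beta
  -0.5 * (logdetV + logdetX + drop(crossprod(r, Vi %*% r)))
}

#' REML fit of the additive + dominance GBLUP model
#'
#' Fits `y = mu + u_A + u_D + e` with `u_A ~ N(0, G_A sigma2_A)`,
#' `u_D ~ N(0, G_D sigma2_D)` by restricted maximum likelihood, maximising
#' the REML log-likelihood directly over log-variances with a quasi-Newton
#' optimiser (variances floored at 1e-10 times the phenotypic variance).
#' Constrained fits of complete additivity (`model = "additive"`, d = 0) and
#' complete dominance (`model = "dominance"`, alpha = 0) are supported.
#'
#' When the phenotypes are stage-one BLUEs, their error variance is known
#' from the trial fit (`V_E / (i j) + V_GxE / i`); passing it as `sigma_e`
#' fixes the residual variance at that value instead of estimating it, which
#' stabilises the additive/dominance split — with few genotypes and rare
#' alleles the dominance relationship matrix is diagonal-heavy and competes
#' with the residual.
#'
#' @param y Named numeric vector of genotype BLUEs (aligned to the rows of
#'   the encodings).
#' @param enc Encodings from [encode_ad()].
#' @param model `"ad"` (default), `"additive"`, or `"dominance"`.
#' @param sigma_e Optional known residual (BLUE error) variance; when given,
#'   sigma2_E is fixed at this value rather than estimated.
#' @return Object of class `gblup_fit`: list with `sigma2`
#'   (named A/D/E variance estimates), `proportions` (of phenotypic
#'   variance), `loglik`, `converged`, `mu`, `y`, `model`, and the fitted
#'   total genetic values `fitted`.
#' @export
fit_gblup <- function(y, enc, model = c("ad", "additive", "dominance"),
                      sigma_e = NULL) {
  model <- match.arg(model)
  n <- length(y)
  if (n < 10) stop("need >= 10 records")
  stopifnot(nrow(enc$GA) == n)
  Xf <- matrix(1, n, 1)
  vy <- stats::var(y)
  if (vy == 0) {
    s2 <- c(A = 0, D = 0, E = 0)
    return(structure(list(sigma2 = s2, proportions = s2, loglik = NA_real_,
                          converged = TRUE, mu = mean(y), y = y, model = model,
                          fitted = rep(mean(y), n), enc = enc),
                     class = "gblup_fit"))
  }
  comp <- switch(model,
                 ad = list(A = enc$GA, D = enc$GD, E = diag(n)),
                 additive = list(A = enc$GA, E = diag(n)),
                 dominance = list(D = enc$GD, E = diag(n)))
  free <- names(comp)
  if (!is.null(sigma_e)) free <- setdiff(free, "E")
  k <- length(free)
  lo <- log(1e-10 * vy); hi <- log(1e3 * vy)
  obj <- function(theta) {
    s2 <- stats::setNames(numeric(length(comp)), names(comp))
    s2[free] <- exp(theta)
    if (!is.null(sigma_e)) s2["E"] <- sigma_e
    -reml_loglik(y, comp, s2, Xf)
  }
  init <- rep(log(vy / (k + 1)), k)
  opt <- stats::optim(init, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                      control = list(maxit = 200))
  s2 <- stats::setNames(numeric(length(comp)), names(comp))
  s2[free] <- exp(opt$par)
  if (!is.null(sigma_e)) s2["E"] <- sigma_e
  sigma2 <- c(A = unname(s2["A"]), D = unname(s2["D"]), E = unname(s2["E"]))
  sigma2[is.na(sigma2)] <- 0
  V <- Reduce(`+`, Map(`*`, comp, s2))
  Vi <- chol2inv(chol(V))
  mu <- drop(crossprod(rep(1, n), Vi) %*% y) / sum(Vi)
  resid <- y - mu
  uA <- if (!is.na(s2["A"])) drop(s2[["A"]] * enc$GA %*% Vi %*% resid) else rep(0, n)
  uD <- if (!is.na(s2["D"])) drop(s2[["D"]] * enc$GD %*% Vi %*% resid) else rep(0, n)
  structure(list(sigma2 = sigma2,
                 proportions = sigma2 / sum(sigma2),
                 loglik = -opt$value,
                 converged = opt$convergence == 0,
                 mu = mu, y = y, model = model,
                 u_A = uA, u_D = uD, fitted = mu + uA + uD, enc = enc),
            class = "gblup_fit")
}

#' Backsolve per-SNP effects from a GBLUP fit
#'
#' Converts the genomic BLUPs to per-SNP allele-substitution effects
#' `alpha = (sigma2_A / sumA) X' V^{-1} (y - mu)` and dominance deviations
#' `d = (sigma2_D / sumD) W' V^{-1} (y - mu)` (the standard marker-BLUP
#' backsolution against the realized relationship matrices), then derives
#' the additive effect and degree of dominance of the conserved allele,
#' per-SNP variances `V_A = 2 p (1 - p) alpha^2` and
#' `V_D = (2 p (1 - p) d)^2`, and a flag for SNPs whose summed variance
#' exceeds the genome-wide per-SNP mean.
#'
#' Because `alpha` here is the average substitution effect under the centred
#' coding, the additive (homozygote half-difference) effect follows the
#' classical relation `a = alpha + (1 - 2 p) d` with `p` the
#' deleterious-allele frequency; the degree of dominance is `k = d / a`,
#' clamped to `[-2, 2]`. Positive `k` means the conserved allele is dominant
#' (the deleterious allele recessive); `k = +1` is complete dominance. The
#' alternative extraction `a_printed = alpha - 2 p (1 - p) d` used by some
#' GBLUP software output conventions is reported alongside with its ratio
#' `k_printed`.
#'
#' @param fit A `gblup_fit` from [fit_gblup()].
#' @param track Optional site track contributing `gerp` (and `recomb`)
#'   columns to the output.
#' @return Data frame (class `snp_effects`): `site`, `p` (deleterious-allele
#'   frequency), `alpha`, `d`, `a`, `k`, `a_printed`, `k_printed`, `va`,
#'   `vd`, `pass_filter`, plus `gerp`/`recomb` when `track` is supplied.
#'   Sites with `a = 0` have NA `k` (count in attribute `n_k_undefined`).
#' @export
backsolve_effects <- function(fit, track = NULL) {
  enc <- fit$enc
  n <- length(fit$y)
  comp <- list(enc$GA * fit$sigma2[["A"]], enc$GD * fit$sigma2[["D"]],
               diag(n) * fit$sigma2[["E"]])
  V <- Reduce(`+`, comp)
  Vi <- chol2inv(chol(V))
  r <- Vi %*% (fit$y - fit$mu)
  alpha <- drop((fit$sigma2[["A"]] / enc$sumA) * crossprod(enc$X, r))
  d <- drop((fit$sigma2[["D"]] / enc$sumD) * crossprod(enc$W, r))
  p <- enc$p
  tpq <- 2 * p * (1 - p)
  a <- alpha + (1 - 2 * p) * d
  k <- clamp(ifelse(a == 0, NA_real_, d / a), -2, 2)
  a_printed <- alpha - tpq * d
  k_printed <- clamp(ifelse(a_printed == 0, NA_real_, d / a_printed), -2, 2)
  out <- data.frame(site = colnames(enc$X), p = unname(p),
                    alpha = unname(alpha), d = unname(d), a = unname(a),
                    k = unname(k), a_printed = unname(a_printed),
                    k_printed = unname(k_printed),
                    va = unname(tpq * alpha^2), vd = unname((tpq * d)^2),
                    stringsAsFactors = FALSE)
  out$pass_filter <- (out$va + out$vd) > mean(out$va + out$vd)
  if (!is.null(track)) {
    m <- match(out$site, track$site)
    out$gerp <- track$gerp[m]
    if (!is.null(track$recomb)) out$recomb <- track$recomb[m]
  }
  attr(out, "n_k_undefined") <- sum(is.na(out$k))
  class(out) <- c("snp_effects", "data.frame")
  out
}

#' Regress backsolved SNP effects on conservation score
#'
#' Ordinary least-squares regressions of |a| (additive-effect magnitude), d
#' (dominance deviation) and k (degree of dominance of the conserved allele)
#' on the conservation score, restricted to SNPs passing the per-SNP variance
#' filter. Optionally drops SNPs in the lowest recombination quartile as a
#' linked-selection robustness check.
#'
#' @param effects A `snp_effects` table from [backsolve_effects()] carrying a
#'   `gerp` column.
#' @param drop_low_recomb Drop sites in the lowest recombination-rate
#'   quartile (requires a `recomb` column).
#' @param min_sites Minimum number of filter-passing sites (default 20).
#' @return Data frame `response`, `slope`, `ci_lo`, `ci_hi`, `p_value`, `n`.
#' @export
regress_on_gerp <- function(effects, drop_low_recomb = FALSE, min_sites = 20) {
  if (is.null(effects$gerp)) stop("effects table lacks a `gerp` column")
  d <- effects[effects$pass_filter, , drop = FALSE]
  if (drop_low_recomb) {
    if (is.null(d$recomb)) stop("no `recomb` column for the low-recombination filter")
    d <- d[d$recomb > stats::quantile(d$recomb, 0.25), , drop = FALSE]
  }
  if (nrow(d) < min_sites) stop("too few filter-passing sites (", nrow(d), ")")
  resp <- list(abs_a = abs(d$a), d = d$d, k = d$k)
  out <- lapply(names(resp), function(nm) {
    yv <- resp[[nm]]
    ok <- !is.na(yv)
    fit <- stats::lm(yv[ok] ~ d$gerp[ok])
    ci <- stats::confint(fit)[2, ]
    data.frame(response = nm, slope = unname(stats::coef(fit)[2]),
               ci_lo = ci[1], ci_hi = ci[2],
               p_value = suppressWarnings(summary(fit))$coefficients[2, 4], n = sum(ok),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Frequency- and recombination-matched random SNP sets
#'
#' Draws control sets of random sites (including non-positively scored ones)
#' matched to a target set's joint histogram over allele-frequency bins of
#' 10% and recombination-rate quartiles (quartile breaks from the candidate
#' pool). Sampling is without replacement within a set; a stratum with too
#' few candidates is sampled with replacement (flagged).
#'
#' @param track Site track (`site`, `gerp`, `recomb`).
#' @param freqs Named per-site allele frequencies.
#' @param target_sites Character vector of target site ids (default: all
#'   positively scored segregating sites).
#' @param n_sets Number of control sets (default 10).
#' @return List of `n_sets` character vectors of site ids; attributes
#'   `target_histogram` (stratum counts) and `with_replacement` (strata that
#'   required replacement).
#' @export
matched_random_sample <- function(track, freqs, target_sites = NULL, n_sets = 10) {
  f <- freqs[track$site]
  ok <- !is.na(f)
  pool <- track$site[ok]
  f <- f[ok]
  rec <- track$recomb[ok]
  if (is.null(target_sites)) {
    target_sites <- track$site[ok & track$gerp > 0 & f > 0 & f < 1]
  }
  fbin <- pmin(floor(f * 10), 9)
  rq <- stats::quantile(rec, c(0.25, 0.5, 0.75))
  rbin <- findInterval(rec, rq)
  stratum <- paste(fbin, rbin, sep = ":")
  names(stratum) <- pool
  tgt <- table(stratum[target_sites])
  wr <- character(0)
  sets <- lapply(seq_len(n_sets), function(s) {
    picks <- lapply(names(tgt), function(st) {
      cand <- pool[stratum == st]
      need <- tgt[[st]]
      if (length(cand) >= need) {
        sample(cand, need)
      } else {
        wr <<- union(wr, st)
        sample(cand, need, replace = TRUE)
      }
    })
    unlist(picks, use.names = FALSE)
  })
  attr(sets, "target_histogram") <- tgt
  attr(sets, "with_replacement") <- wr
  sets
}

#' Shuffled-dominance null for block-model explained variance
#'
#' Randomly permutes the per-SNP degrees of dominance across sites (keeping
#' additive weights fixed), rebuilds the incomplete-dominance block scores,
#' refits the Bayesian block model, and compares the posterior variance
#' explained under the observed dominance values with the permuted null
#' distribution.
#'
#' @param f1,blocks,track As for [score_blocks()].
#' @param k Named per-SNP degree of dominance in the conserved-allele
#'   convention of [backsolve_effects()] (converted internally to the
#'   heterozygote-scoring convention `k_del = -k`).
#' @param y Named phenotype vector aligned to the rows of `f1`.
#' @param n_shuffles Number of permutations (default 10).
#' @param config [bayesc_config()] for the block-model fits.
#' @return List with `observed` (posterior variance explained), `null`
#'   (numeric vector of length `n_shuffles`), and `exceeds` (observed >= max
#'   null).
#' @export
shuffled_k_control <- function(f1, blocks, track, k, y, n_shuffles = 10,
                               config = bayesc_config()) {
  k_del <- clamp(-k, -1, 1)
  pve <- function(kd) {
    sc <- score_blocks(f1, blocks, track, k_del = kd, model = "incomplete")
    fit <- bayesc_fit(sc[names(y), , drop = FALSE], y, config)
    fit$pve
  }
  observed <- pve(k_del)
  null <- vapply(seq_len(n_shuffles), function(i) {
    # permute values across the same site ids
    kp <- stats::setNames(as.numeric(sample(unname(k_del))), names(k_del))
    pve(kp)
  }, numeric(1))
  list(observed = observed, null = null, exceeds = observed >= max(null))
}
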