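#' Best linear unbiased estimates of genotype values from plot data
#'
#' Fits, per trait, the trial mixed model
#' `value = mu + year + rep(year) + block(year:rep) + genotype + genotype:year + e`
#' with year and genotype fixed and replicate-in-year, block-in-replicate and
#' genotype-by-year random, and returns one BLUE per genotype. Variance
#' components for [compute_H2()] (V_G, V_GxE, V_E) come from a companion fit
#' with genotype random. Estimation uses REML via \pkg{lme4}; with a single
#' year the interaction is dropped and V_GxE is fixed at 0. When the
#' non-genetic variance is numerically zero (noise-free data) the mixed model
#' degenerates and BLUEs are the plot means.
#'
#' @param records Plot-level data frame with columns `genotype`, `year`,
#'   `rep`, `block`, `trait`, `value`.
#' @return List with `blues` (data frame `genotype`, `trait`, `blue`, `se` —
#'   the BLUE and its standard error from the fixed-effect covariance) and
#'   `varcomp` (data frame `trait`, `V_G`, `V_GxE`, `V_E`, `i`, `j`, `H2`).
#' @export
fit_blues <- function(records) {
  need <- c("genotype", "year", "rep", "block", "trait", "value")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "))
  }
  blues <- list(); vcs <- list()
  for (tr in unique(records$trait)) {
    d <- records[records$trait == tr & is.finite(records$value), , drop = FALSE]
    if (!nrow(d)) {
      warning("trait ", tr, " has no non-missing records; skipped")
      next
    }
    d$genotype <- factor(d$genotype)
    d$year <- factor(d$year)
    d$yrep <- interaction(d$year, d$rep, drop = TRUE)
    d$yblk <- interaction(d$yrep, d$block, drop = TRUE)
    ni <- nlevels(d$year)
    nj <- length(unique(d$rep))
    one_year <- ni < 2
    gmeans <- tapply(d$value, d$genotype, mean)
    # residual spread around genotype x year cell means; ~0 => noise-free
    cellm <- stats::ave(d$value, interaction(d$genotype, d$year, d$rep, drop = TRUE))
    noise_free <- stats::sd(d$value - cellm) < 1e-10 &&
      stats::sd(d$value - stats::ave(d$value, d$genotype)) < 1e-10
    if (noise_free) {
      blue <- gmeans
      blue_se <- stats::setNames(rep(0, length(gmeans)), names(gmeans))
      vc <- c(V_G = stats::var(as.numeric(gmeans)), V_GxE = 0, V_E = 0)
    } else {
      fixed_form <- if (one_year) {
        value ~ 0 + genotype + (1 | yrep) + (1 | yblk)
      } else {
        value ~ 0 + genotype + year + (1 | yrep) + (1 | yblk) + (1 | genotype:year)
      }
      fit <- tryCatch(
        suppressMessages(suppressWarnings(
          lme4::lmer(fixed_form, data = d,
                     control = lme4::lmerControl(check.conv.singular = "ignore")))),
        error = function(e) stop("mixed-model fit failed for trait ", tr, ": ",
                                 conditionMessage(e)))
      cf <- lme4::fixef(fit)
      gsel <- grep("^genotype", names(cf))
      gcoef <- cf[gsel]
      names(gcoef) <- sub("^genotype", "", names(gcoef))
      # centre year effects so BLUEs are on the mean-year scale
      ycf <- cf[grep("^year", names(cf))]
      yadj <- if (length(ycf)) mean(c(0, unname(ycf))) else 0
      blue <- gcoef + yadj
      blue_se <- sqrt(diag(as.matrix(stats::vcov(fit)))[gsel])
      names(blue_se) <- names(gcoef)
      rand_form <- if (one_year) {
        value ~ 1 + (1 | genotype) + (1 | yrep) + (1 | yblk)
      } else {
        value ~ 1 + year + (1 | genotype) + (1 | yrep) + (1 | yblk) + (1 | genotype:year)
      }
      rfit <- suppressMessages(suppressWarnings(
        lme4::lmer(rand_form, data = d,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))))
      vcs_tab <- as.data.frame(lme4::VarCorr(rfit))
      getv <- function(g) {
        v <- vcs_tab$vcov[vcs_tab$grp == g]
        if (length(v)) v[1] else 0
      }
      vc <- c(V_G = getv("genotype"),
              V_GxE = if (one_year) 0 else getv("genotype:year"),
              V_E = getv("Residual"))
    }
    blues[[tr]] <- data.frame(genotype = names(blue), trait = tr,
                              blue = unname(as.numeric(blue)),
                              se = unname(as.numeric(blue_se[names(blue)])),
                              stringsAsFactors = FALSE)
    h2 <- tryCatch(compute_H2(vc["V_G"], vc["V_GxE"], vc["V_E"], i = ni, j = nj),
                   error = function(e) NA_real_)
    vcs[[tr]] <- data.frame(trait = tr, V_G = vc[["V_G"]], V_GxE = vc[["V_GxE"]],
                            V_E = vc[["V_E"]], i = ni, j = nj, H2 = h2,
                            stringsAsFactors = FALSE)
  }
  list(blues = do.call(rbind, c(blues, list(make.row.names = FALSE))),
       varcomp = do.call(rbind, c(vcs, list(make.row.names = FALSE))))
}

#' Broad-sense heritability on an entry-mean basis
#'
#' `H2 = V_G / (V_G + V_GxE / i + V_E / (i * j))` with `i` years and `j`
#' replicates per year.
#'
#' @param V_G,V_GxE,V_E Genetic, genotype-by-year and residual variance
#'   components (>= 0).
#' @param i Number of years; `j` number of replicates per year.
#' @param j See `i`.
#' @return Heritability in `[0, 1]`.
#' @examples
#' compute_H2(1, 3, 9, i = 3, j = 3)  # 1/3
#' @export
compute_H2 <- function(V_G, V_GxE, V_E, i = 3, j = 3) {
  if (any(c(V_G, V_GxE, V_E) < 0)) stop("variance components must be >= 0")
  if (i < 1 || j < 1) stop("i and j must be >= 1")
  denom <- V_G + V_GxE / i + V_E / (i * j)
  if (denom == 0) stop("all variance components are zero; H2 undefined")
  unname(V_G / denom)
}

#' Mid-parent heterosis from genotype BLUEs
#'
#' For each cross, absolute mid-parent heterosis is the hybrid BLUE minus the
#' mean of its two parents' BLUEs, and percent heterosis is 100 times the
#' absolute value divided by the mid-parent mean. A mid-parent mean of zero
#' leaves percent heterosis undefined (NA, flagged in `pct_undefined`).
#'
#' @param blues BLUE data frame (`genotype`, `trait`, `blue`) containing both
#'   hybrids and parents.
#' @param crosses Cross list (`hybrid`, `parent1`, `parent2`).
#' @return Data frame `hybrid`, `parent1`, `parent2`, `trait`, `blue`,
#'   `mid_parent`, `mph_abs`, `mph_pct`, `pct_undefined`.
#' @export
compute_mph <- function(blues, crosses) {
  out <- list()
  for (tr in unique(blues$trait)) {
    b <- blues[blues$trait == tr, ]
    v <- stats::setNames(b$blue, b$genotype)
    miss <- setdiff(unique(c(crosses$hybrid, crosses$parent1, crosses$parent2)),
                    names(v))
    if (length(miss)) stop("BLUEs missing for: ", paste(miss, collapse = ", "))
    mid <- (v[crosses$parent1] + v[crosses$parent2]) / 2
    hyb <- v[crosses$hybrid]
    mph <- hyb - mid
    pct <- ifelse(mid == 0, NA_real_, 100 * mph / mid)
    out[[tr]] <- data.frame(hybrid = crosses$hybrid, parent1 = crosses$parent1,
                            parent2 = crosses$parent2, trait = tr,
                            blue = unname(hyb), mid_parent = unname(mid),
                            mph_abs = unname(mph), mph_pct = unname(pct),
                            pct_undefined = mid == 0, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' General and specific combining abilities
#'
#' GCA of a parent is the mean BLUE of the hybrids involving that parent
#' minus the overall hybrid mean; SCA of a cross is its hybrid BLUE minus the
#' overall mean and both parental GCAs. GCAs are centred across parents.
#'
#' @inheritParams compute_mph
#' @return List with `gca` (`parent`, `trait`, `gca`) and `sca` (`hybrid`,
#'   `trait`, `sca`), plus per-trait overall hybrid means in `mu`.
#' @export
compute_gca_sca <- function(blues, crosses) {
  gca_out <- list(); sca_out <- list(); mu_out <- list()
  parents <- unique(c(crosses$parent1, crosses$parent2))
  for (tr in unique(blues$trait)) {
    b <- blues[blues$trait == tr, ]
    v <- stats::setNames(b$blue, b$genotype)
    hyb <- v[crosses$hybrid]
    if (anyNA(hyb)) stop("hybrid BLUEs missing for trait ", tr)
    mu <- mean(hyb)
    gca <- vapply(parents, function(p) {
      inx <- crosses$parent1 == p | crosses$parent2 == p
      if (!any(inx)) return(NA_real_)
      mean(hyb[inx]) - mu
    }, numeric(1))
    gca <- gca[!is.na(gca)]
    gca <- gca - mean(gca)  # centred
    sca <- hyb - mu - gca[crosses$parent1] - gca[crosses$parent2]
    gca_out[[tr]] <- data.frame(parent = names(gca), trait = tr,
                                gca = unname(gca), stringsAsFactors = FALSE)
    sca_out[[tr]] <- data.frame(hybrid = crosses$hybrid, trait = tr,
                                sca = unname(sca), stringsAsFactors = FALSE)
    mu_out[[tr]] <- mu
  }
  g <- do.call(rbind, gca_out); rownames(g) <- NULL
  s <- do.call(rbind, sca_out); rownames(s) <- NULL
  list(gca = g, sca = s, mu = unlist(mu_out))
}

#' Recompute heterosis statistics from a published hybrid BLUE table
#'
#' Validation against a supplied supplementary-style table of hybrid and
#' parent BLUEs: recomputes percent mid-parent heterosis per cross and the
#' Spearman correlation between two (typically highly correlated) traits'
#' hybrid BLUEs. The expected file layout is a CSV with columns `hybrid`,
#' `parent1`, `parent2`, then one column per trait of hybrid BLUEs and
#' `<trait>_P1` / `<trait>_P2` columns of parental BLUEs.
#'
#' @param path CSV file path.
#' @param yield_trait Trait column used for the heterosis summary
#'   (default `"GY"`).
#' @param cor_traits Length-2 character vector of trait columns to correlate
#'   (default `c("DTS", "DTP")`).
#' @return List with `mean_mph_pct`, `sd_mph_pct`, `spearman`, `n_hybrids`,
#'   and the per-cross table `mph`.
#' @export
check_s1_table <- function(path, yield_trait = "GY",
                           cor_traits = c("DTS", "DTP")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(yield_trait, paste0(yield_trait, c("_P1", "_P2")), cor_traits)
  if (!all(need %in% names(tab))) {
    stop("table lacks required columns: ", paste(setdiff(need, names(tab)), collapse = ", "))
  }
  mid <- (tab[[paste0(yield_trait, "_P1")]] + tab[[paste0(yield_trait, "_P2")]]) / 2
  mph_pct <- 100 * (tab[[yield_trait]] - mid) / mid
  list(mean_mph_pct = mean(mph_pct, na.rm = TRUE),
       sd_mph_pct = stats::sd(mph_pct, na.rm = TRUE),
       spearman = stats::cor(tab[[cor_traits[1]]], tab[[cor_traits[2]]],
                             method = "spearman", use = "complete.obs"),
       n_hybrids = nrow(tab),
       mph = data.frame(hybrid = tab$hybrid %||% seq_len(nrow(tab)),
                        mph_pct = mph_pct))
}
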