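#' Per-line deleterious-allele burden
#'
#' Counts, for each line, the number of positively scored sites (GERP > 0) at
#' which it carries the putatively deleterious allele, divided by its number
#' of non-missing such sites (the burden ratio). The default "presence"
#' convention counts a site once whether the line is heterozygous or
#' homozygous for the deleterious allele; the alternative `"dosage"`
#' convention counts allele copies (0/1/2) and divides by twice the
#' non-missing site count. Sites are also partitioned, across the line set,
#' into fixed (deleterious allele carried by every line with data) and
#' segregating (carried by some but not all).
#'
#' @param gm Genotype matrix (lines x sites, deleterious-allele dosage
#'   0/1/2/NA).
#' @param track Site track with `site` and `gerp` columns matching `gm`.
#' @param convention `"presence"` (default) or `"dosage"`.
#' @return List with `per_line` (data frame `line`, `n_deleterious`,
#'   `n_nonmissing`, `burden`) and `partition` (`n_fixed`, `n_segregating`,
#'   `n_absent`, `n_gerp_snps`).
#' @export
per_line_burden <- function(gm, track, convention = c("presence", "dosage")) {
  convention <- match.arg(convention)
  keep <- track$site[track$gerp > 0]
  keep <- intersect(colnames(gm), keep)
  if (!length(keep)) {
    warning("no positively scored sites; empty burden report")
    return(list(per_line = data.frame(line = rownames(gm), n_deleterious = 0L,
                                      n_nonmissing = 0L, burden = NA_real_),
                partition = c(n_fixed = 0L, n_segregating = 0L, n_absent = 0L,
                              n_gerp_snps = 0L)))
  }
  g <- gm[, keep, drop = FALSE]
  nonmiss <- rowSums(!is.na(g))
  if (convention == "presence") {
    cnt <- rowSums(g >= 1L, na.rm = TRUE)
    burden <- cnt / nonmiss
  } else {
    cnt <- rowSums(g, na.rm = TRUE)
    burden <- cnt / (2 * nonmiss)
  }
  carrier_frac <- apply(g, 2, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    mean(x >= 1L)
  })
  partition <- c(n_fixed = sum(carrier_frac == 1, na.rm = TRUE),
                 n_segregating = sum(carrier_frac > 0 & carrier_frac < 1, na.rm = TRUE),
                 n_absent = sum(carrier_frac == 0, na.rm = TRUE),
                 n_gerp_snps = length(keep))
  list(per_line = data.frame(line = rownames(gm), n_deleterious = as.integer(cnt),
                             n_nonmissing = as.integer(nonmiss),
                             burden = as.numeric(burden), stringsAsFactors = FALSE),
       partition = partition)
}

#' Complementation and homozygous deleterious load per hybrid
#'
#' For each cross of two homozygous parents, classifies every positively
#' scored site with complete parental data: `n_hom_deleterious` counts sites
#' at which both parents carry the deleterious allele (the hybrid is
#' homozygous deleterious) and `n_complemented` counts sites at which exactly
#' one parent carries it (the hybrid is heterozygous, so a recessive
#' deleterious allele is masked).
#'
#' @inheritParams per_line_burden
#' @param crosses Cross list (`hybrid`, `parent1`, `parent2`).
#' @return Data frame `hybrid`, `parent1`, `parent2`, `n_hom_deleterious`,
#'   `n_complemented`, `n_sites_used`.
#' @export
hybrid_complementation <- function(gm, track, crosses) {
  miss <- setdiff(unique(c(crosses$parent1, crosses$parent2)), rownames(gm))
  if (length(miss)) stop("unknown parent(s) in cross list: ", paste(miss, collapse = ", "))
  keep <- intersect(colnames(gm), track$site[track$gerp > 0])
  g <- gm[, keep, drop = FALSE]
  res <- lapply(seq_len(nrow(crosses)), function(i) {
    g1 <- g[crosses$parent1[i], ]
    g2 <- g[crosses$parent2[i], ]
    ok <- !is.na(g1) & !is.na(g2) & g1 != 1L & g2 != 1L
    c1 <- g1[ok] == 2L
    c2 <- g2[ok] == 2L
    data.frame(hybrid = crosses$hybrid[i], parent1 = crosses$parent1[i],
               parent2 = crosses$parent2[i],
               n_hom_deleterious = sum(c1 & c2),
               n_complemented = sum(xor(c1, c2)),
               n_sites_used = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Regression of allele frequency on conservation score
#'
#' Bins sites (including those with non-positive scores) by conservation
#' score in bins of `bin_width`, averages the deleterious-allele frequency
#' per bin, and regresses the bin means on the bin mid-points by least
#' squares weighted by bin occupancy (sparsely occupied tail bins carry
#' high-variance means and would otherwise dominate the fit); also reports
#' the per-site Spearman correlation.
#'
#' @param freqs Named per-site allele frequencies (the 12-parent sample or an
#'   external panel).
#' @param track Site track (`site`, `gerp`).
#' @param bin_width Score bin width (default 0.01).
#' @return List with `slope`, `ci` (95% band), `p_value`, `spearman`,
#'   `n_bins`, and the binned table `bins` (`bin`, `mean_freq`, `n`).
#' @export
correlate_freq_gerp <- function(freqs, track, bin_width = 0.01) {
  f <- freqs[track$site]
  ok <- !is.na(f)
  g <- track$gerp[ok]; f <- f[ok]
  bin <- floor(g / bin_width) * bin_width
  agg <- stats::aggregate(f, list(bin = bin), mean)
  names(agg) <- c("bin", "mean_freq")
  agg$n <- as.integer(table(bin)[as.character(agg$bin)])
  if (nrow(agg) < 2) stop("need >= 2 occupied score bins")
  fit <- stats::lm(mean_freq ~ bin, data = agg, weights = agg$n)
  list(slope = unname(stats::coef(fit)[2]),
       ci = unname(stats::confint(fit)[2, ]),
       p_value = suppressWarnings(summary(fit))$coefficients[2, 4],
       spearman = stats::cor(f, g, method = "spearman"),
       n_bins = nrow(agg), bins = agg)
}

#' Regression of mean positive conservation score on recombination rate
#'
#' Averages, per genomic window, the conservation score of positively scored
#' sites and the recombination rate of all sites in the window, and fits an
#' ordinary least-squares regression of window mean score on window mean
#' recombination rate. Windows containing no positively scored site are
#' omitted.
#'
#' @param track Site track (`chrom`, `pos`, `gerp`, `recomb`).
#' @param window Window size in bp (default 1 Mb).
#' @return List with `slope`, `ci`, `p_value`, `n_windows`, and the
#'   per-window table `windows`.
#' @export
correlate_recomb_gerp <- function(track, window = 1e6) {
  if (window <= 0) stop("window must be > 0")
  win <- paste(track$chrom, floor(track$pos / window), sep = ":")
  splitg <- split(seq_len(nrow(track)), win)
  rows <- lapply(splitg, function(idx) {
    pos <- idx[track$gerp[idx] > 0]
    if (!length(pos)) return(NULL)
    data.frame(mean_gerp = mean(track$gerp[pos]),
               mean_recomb = mean(track$recomb[idx]),
               n_gerp_snps = length(pos))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0) stop("no window contains a positively scored site")
  if (nrow(rows) < 2) stop("need >= 2 informative windows")
  fit <- stats::lm(mean_gerp ~ mean_recomb, data = rows)
  list(slope = unname(stats::coef(fit)[2]),
       ci = unname(stats::confint(fit)[2, ]),
       p_value = suppressWarnings(summary(fit))$coefficients[2, 4],
       n_windows = nrow(rows), windows = rows)
}

#' Correlation of homozygous deleterious load with hybrid phenotypes
#'
#' Spearman correlation, per trait, between the per-hybrid count of
#' homozygous deleterious sites (from [hybrid_complementation()]) and the
#' hybrid BLUE.
#'
#' @param comp Output of [hybrid_complementation()].
#' @param blues BLUE data frame (`genotype`, `trait`, `blue`).
#' @return Data frame `trait`, `rho`, `p_value`, `n`, `undefined`.
#' @export
correlate_burden_phenotype <- function(comp, blues) {
  if (nrow(comp) < 5) stop("need >= 5 hybrids")
  out <- list()
  for (tr in unique(blues$trait)) {
    b <- blues[blues$trait == tr, ]
    v <- stats::setNames(b$blue, b$genotype)[comp$hybrid]
    ok <- !is.na(v)
    x <- comp$n_hom_deleterious[ok]
    if (stats::sd(x) == 0) {
      out[[tr]] <- data.frame(trait = tr, rho = NA_real_, p_value = NA_real_,
                              n = sum(ok), undefined = TRUE)
      next
    }
    ct <- suppressWarnings(stats::cor.test(x, v[ok], method = "spearman"))
    out[[tr]] <- data.frame(trait = tr, rho = unname(ct$estimate),
                            p_value = ct$p.value, n = sum(ok), undefined = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
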