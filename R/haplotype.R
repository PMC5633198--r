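#' Build haplotype blocks from pairwise IBD segments
#'
#' Haplotype blocks are the contiguous genomic intervals within which there is
#' no identity-by-descent (IBD) breakpoint in any pairwise comparison of the
#' parental lines: every segment start and end position, pooled across all
#' pairs, is a breakpoint, and blocks tile the chromosome between consecutive
#' breakpoints (plus the chromosome ends). Blocks shorter than `min_len` are
#' discarded. All coordinates are 0-based half-open.
#'
#' @param segments Data frame of IBD segments with columns `parent_a`,
#'   `parent_b`, `chrom`, `start`, `end` (may have zero rows).
#' @param genome Named numeric vector of chromosome lengths (names are
#'   chromosome ids).
#' @param track Optional site track (see [simulate_gerp_track()]) with columns
#'   `site`, `chrom`, `pos`, `gerp`; when supplied, member SNPs are assigned
#'   to blocks by half-open coordinate containment and a positive-GERP SNP
#'   count is recorded per block.
#' @param min_len Minimum retained block length in bp (default 1000).
#' @return Data frame with columns `block`, `chrom`, `start`, `end`, and (when
#'   `track` is given) `n_snps`, `n_gerp_snps`; the per-block member site ids
#'   are stored in the list-column `sites`.
#' @export
build_blocks <- function(segments, genome, track = NULL, min_len = 1000) {
  stopifnot(is.numeric(genome), !is.null(names(genome)))
  if (nrow(segments %||% data.frame())) {
    bad <- segments$start >= segments$end
    if (any(bad)) stop("IBD segments must satisfy start < end")
  }
  out <- list()
  for (chr in names(genome)) {
    L <- genome[[chr]]
    bp <- c(0, L)
    if (!is.null(segments) && nrow(segments)) {
      seg <- segments[segments$chrom == chr, , drop = FALSE]
      bp <- c(bp, seg$start, seg$end)
    }
    bp <- sort(unique(clamp(bp, 0, L)))
    blk <- data.frame(chrom = chr, start = bp[-length(bp)], end = bp[-1])
    blk <- blk[blk$end - blk$start >= min_len, , drop = FALSE]
    out[[chr]] <- blk
  }
  blocks <- do.call(rbind, out)
  rownames(blocks) <- NULL
  if (nrow(blocks) == 0) return(cbind(blocks, block = character(0)))
  blocks$block <- sprintf("b%04d", seq_len(nrow(blocks)))
  blocks <- blocks[, c("block", "chrom", "start", "end")]
  if (!is.null(track)) {
    sites <- vector("list", nrow(blocks))
    n_gerp <- integer(nrow(blocks))
    for (i in seq_len(nrow(blocks))) {
      inb <- track$chrom == blocks$chrom[i] &
        track$pos >= blocks$start[i] & track$pos < blocks$end[i]
      sites[[i]] <- track$site[inb]
      n_gerp[i] <- sum(track$gerp[inb] > 0)
    }
    blocks$n_snps <- lengths(sites)
    blocks$n_gerp_snps <- n_gerp
    blocks$sites <- sites
  }
  blocks
}

#' Project F1 diploid genotypes from homozygous parents
#'
#' Because fully inbred parents carry no heterozygosity, the diploid genotype
#' of every F1 is determined exactly: each parent contributes one allele per
#' site. Genotypes are coded as copies of the deleterious allele, so parents
#' are 0 or 2 and the F1 is `(g1 + g2) / 2` in \{0, 1, 2\}. A site that is
#' missing in either parent is missing in the F1; a site at which a parent is
#' heterozygous is set to missing for all hybrids (with a warning).
#'
#' @param gm Parent genotype matrix (parents x sites, codes 0/1/2/NA), rows
#'   named by parent id.
#' @param crosses Data frame with columns `hybrid`, `parent1`, `parent2`.
#' @return Integer matrix hybrids x sites of F1 deleterious-allele dosages.
#' @export
project_f1 <- function(gm, crosses) {
  miss <- setdiff(unique(c(crosses$parent1, crosses$parent2)), rownames(gm))
  if (length(miss)) stop("unknown parent(s) in cross list: ", paste(miss, collapse = ", "))
  het_sites <- which(apply(gm == 1L, 2, any, na.rm = TRUE))
  if (length(het_sites)) {
    warning(length(het_sites), " site(s) heterozygous in a parent; set to missing in all F1s")
  }
  f1 <- (gm[crosses$parent1, , drop = FALSE] + gm[crosses$parent2, , drop = FALSE]) / 2L
  if (length(het_sites)) f1[, het_sites] <- NA
  rownames(f1) <- crosses$hybrid
  storage.mode(f1) <- "integer"
  f1
}

#' GERP-weighted haplotype-block complementation scores
#'
#' For each hybrid and haplotype block, sums per-SNP scores over the block's
#' positive-GERP member SNPs. A SNP with conservation score `g > 0` scores 0
#' when the hybrid is homozygous for the conserved (major) allele, `2 * g`
#' when homozygous for the putatively deleterious allele, and
#' `(1 + k_het) * g` when heterozygous, where `k_het` is the dominance of the
#' deleterious allele in the heterozygote: 0 under the `"additive"` model,
#' -1 under the `"dominance"` model (full complementation, heterozygote
#' scores 0), or the per-SNP estimate `k_del` clamped to `[-1, 1]` under the
#' `"incomplete"` model. Missing genotypes contribute 0. Blocks containing no
#' positive-GERP SNP are excluded.
#'
#' Note the sign bridge from GBLUP dominance: [backsolve_effects()] reports
#' `k = d / a` for the conserved allele (k = +1 means the deleterious allele
#' is fully recessive); use `k_del = -k` here, so that a fully recessive
#' deleterious allele is fully complemented in the heterozygote.
#'
#' @param f1 Hybrid genotype matrix (hybrids x sites, deleterious-allele
#'   dosage 0/1/2, NA allowed), columns named by site id.
#' @param blocks Block table from [build_blocks()] (must carry the `sites`
#'   list-column).
#' @param track Site track with columns `site`, `gerp`.
#' @param k_del Named numeric vector of per-SNP deleterious-allele dominance
#'   (required for `model = "incomplete"`); values outside `[-1, 1]` are
#'   clamped (count reported via attribute `n_clamped`). Sites absent from
#'   `k_del` fall back to 0 (additive).
#' @param model One of `"additive"`, `"dominance"`, `"incomplete"`.
#' @return Numeric matrix hybrids x retained blocks of summed block scores,
#'   with attribute `model`.
#' @export
score_blocks <- function(f1, blocks, track, k_del = NULL,
                         model = c("additive", "dominance", "incomplete")) {
  model <- match.arg(model)
  if (is.null(blocks$sites)) stop("`blocks` must carry member sites; rebuild with a track")
  gerp <- stats::setNames(track$gerp, track$site)
  n_clamped <- 0L
  site_k <- function(ids) {
    switch(model,
      additive = rep(0, length(ids)),
      dominance = rep(-1, length(ids)),
      incomplete = {
        if (is.null(k_del)) stop("`k_del` required for the incomplete-dominance model")
        k <- k_del[ids]
        k[is.na(k)] <- 0
        n_clamped <<- n_clamped + sum(k < -1 | k > 1)
        clamp(k, -1, 1)
      })
  }
  keep <- which((blocks$n_gerp_snps %||% 0L) > 0)
  scores <- matrix(0, nrow(f1), length(keep),
                   dimnames = list(rownames(f1), blocks$block[keep]))
  for (j in seq_along(keep)) {
    ids <- blocks$sites[[keep[j]]]
    g <- gerp[ids]
    ids <- ids[g > 0]
    g <- g[g > 0]
    k <- site_k(ids)
    X <- f1[, ids, drop = FALSE]
    # per-SNP score: 0 / (1 + k) g / 2 g for dosage 0 / 1 / 2; missing -> 0
    hom <- X == 2L
    het <- X == 1L
    hom[is.na(hom)] <- FALSE
    het[is.na(het)] <- FALSE
    scores[, j] <- hom %*% (2 * g) + het %*% ((1 + k) * g)
  }
  attr(scores, "model") <- model
  attr(scores, "n_clamped") <- n_clamped
  scores
}

#' Naive IBD segment caller from genotype identity
#'
#' A deliberately simple fallback for real data when externally inferred IBD
#' segments are unavailable: for each pair of lines it scans for runs of at
#' least `min_snps` consecutive sites with identical non-missing genotypes and
#' emits the spanned interval. This is not equivalent to model-based IBD
#' inference (no LD model, no error tolerance) and is intended only to make
#' the block machinery usable without external calls.
#'
#' @param gm Parent genotype matrix (parents x sites).
#' @param track Site track with `site`, `chrom`, `pos` matching `gm` columns.
#' @param min_snps Minimum run length in SNPs (default 50).
#' @return IBD segment data frame (`parent_a`, `parent_b`, `chrom`, `start`,
#'   `end`).
#' @export
call_ibd_naive <- function(gm, track, min_snps = 50) {
  stopifnot(ncol(gm) == nrow(track))
  ord <- order(track$chrom, track$pos)
  track <- track[ord, ]
  gm <- gm[, ord, drop = FALSE]
  parents <- rownames(gm)
  out <- list()
  for (i in seq_len(length(parents) - 1)) {
    for (j in seq(i + 1, length(parents))) {
      same <- gm[i, ] == gm[j, ] & !is.na(gm[i, ]) & !is.na(gm[j, ])
      for (chr in unique(track$chrom)) {
        idx <- which(track$chrom == chr)
        r <- rle(as.logical(same[idx]))
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        run <- which(r$values & r$lengths >= min_snps)
        for (k in run) {
          lo <- idx[starts[k]]; hi <- idx[ends[k]]
          out[[length(out) + 1]] <- data.frame(
            parent_a = parents[i], parent_b = parents[j], chrom = chr,
            start = track$pos[lo], end = track$pos[hi] + 1)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(parent_a = character(0), parent_b = character(0),
                      chrom = character(0), start = numeric(0), end = numeric(0)))
  }
  do.call(rbind, out)
}
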