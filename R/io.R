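#' Write a parent genotype matrix as VCF
#'
#' Emits one biallelic record per site, REF = conserved allele ("A"),
#' ALT = deleterious allele ("T"), one sample column per parent with
#' genotypes 0/0, 0/1, 1/1 or ./. for missing. Positions are written 1-based
#' per the VCF convention (the in-memory track is 0-based).
#'
#' @param gm Genotype matrix (parents x sites, deleterious dosage 0/1/2/NA).
#' @param track Site track (`site`, `chrom`, `pos`).
#' @param path Output file path (plain-text `.vcf`).
#' @export
write_genotypes_vcf <- function(gm, track, path) {
  stopifnot(all(colnames(gm) %in% track$site))
  m <- match(colnames(gm), track$site)
  gt_map <- c("0" = "0/0", "1" = "0/1", "2" = "1/1")
  gt <- apply(gm, 1, function(x) {
    out <- gt_map[as.character(x)]
    out[is.na(out)] <- "./."
    out
  })
  hdr <- c("##fileformat=VCFv4.2",
           "##source=gerphet",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(gm)), collapse = "\t"))
  body <- cbind(track$chrom[m], track$pos[m] + 1, colnames(gm), "A", "T",
                ".", "PASS", ".", "GT", gt)
  writeLines(c(hdr, apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read a parent genotype matrix from VCF
#'
#' Reads a VCF (via \pkg{vcfR}) and returns the deleterious-allele (ALT)
#' dosage matrix, samples x sites.
#'
#' @param path VCF file path.
#' @return Integer matrix (samples x sites, 0/1/2/NA) with site ids from the
#'   ID column and an attribute `positions` (data frame `site`, `chrom`,
#'   `pos` 0-based).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("package 'vcfR' is required to read VCF files")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, 2, function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x == "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x == "1/1"] <- 2L
    out
  })
  rownames(dos) <- v@fix[, "ID"]
  res <- t(dos)
  attr(res, "positions") <- data.frame(
    site = v@fix[, "ID"], chrom = v@fix[, "CHROM"],
    pos = as.numeric(v@fix[, "POS"]) - 1, stringsAsFactors = FALSE)
  res
}

#' Write / read a conservation-score track as BED-like TSV
#'
#' Columns: chrom, start (0-based), end, score, genic flag, recombination
#' rate; tab-separated with a header.
#'
#' @param track Track data frame.
#' @param path File path.
#' @export
write_gerp_track <- function(track, path) {
  utils::write.table(
    track[, c("chrom", "pos", "end", "gerp", "genic", "recomb", "site")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gerp_track
#' @param genome_length Genome length recorded on the returned track.
#' @export
read_gerp_track <- function(path, genome_length = NA) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  track <- data.frame(site = d$site, chrom = as.character(d$chrom),
                      pos = d$pos, end = d$end, gerp = d$gerp,
                      genic = as.logical(d$genic), recomb = d$recomb,
                      stringsAsFactors = FALSE)
  if (!is.na(genome_length)) attr(track, "genome") <- c("1" = genome_length)
  class(track) <- c("gerp_track", "data.frame")
  track
}

#' Write / read IBD segments as TSV
#'
#' Columns parent_a, parent_b, chrom, start, end. Coordinates are 0-based
#' half-open in memory; files declared 1-based inclusive are converted on
#' read with `one_based = TRUE`.
#'
#' @param segments IBD segment data frame.
#' @param path File path.
#' @export
write_ibd_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ibd_segments
#' @param one_based Input coordinates are 1-based inclusive.
#' @export
read_ibd_segments <- function(path, one_based = FALSE) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  d$chrom <- as.character(d$chrom)
  if (one_based) {
    d$start <- d$start - 1
  }
  d
}
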