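#' Configuration for the synthetic diallel generator
#'
#' Bundles the generative assumptions of the synthetic data: panel size,
#' number of scored sites, the conservation-score mixture, the laws mapping
#' conservation score to selection coefficient, dominance and effect size,
#' target heritabilities and the field-trial design. Defaults emulate an
#' elite-maize partial diallel: 12 fully inbred parents, a 66-hybrid diallel
#' phenotyped over 3 years x 3 replicates, a yield-like trait (`YLD`) with
#' GERP-linked, incompletely dominant deleterious effects and a
#' dominance-variance share of 0.24, and a flowering-like trait (`FT`) that
#' is purely additive and unlinked to conservation score.
#'
#' The dominance convention throughout is `k`, the degree of dominance of the
#' conserved (major) allele in `[0, 1]`: `k = 1` means the deleterious allele
#' is fully recessive.
#'
#' @param n_parents Number of inbred parents (>= 2).
#' @param n_sites Number of biallelic scored sites.
#' @param genome_length Genome length in bp (single linear chromosome "1").
#' @param mu Effective per-site mutation rate feeding
#'   [equilibrium_frequency()]. The default (1e-4) is chosen so that
#'   equilibrium frequencies yield realistic numbers of segregating sites in
#'   a 12-line panel rather than a literal per-generation point-mutation rate.
#' @param pos_weight Mixture weight of the positive (conserved) score tail.
#' @param genic_fraction Expected fraction of sites flagged genic.
#' @param sel_coef_law Function g -> selection coefficient s (> 0).
#' @param dominance_law Function (g, n) -> n draws of conserved-allele
#'   dominance k in `[0, 1]` (noisy, increasing in g by default).
#' @param effect_law Function (g, n) -> n draws of the positive additive
#'   effect |a| of the conserved allele on the yield-like trait.
#' @param dom_share Target dominance-variance share V_D / (V_A + V_D) for the
#'   yield-like trait, calibrated by a global rescaling of dominance
#'   deviations (see [simulate_effects()]).
#' @param mph_target Ratio by which mean hybrid yield exceeds the mean
#'   mid-parent yield (default 1.82, i.e. 182% mid-parent heterosis); fixes
#'   the otherwise arbitrary yield intercept.
#' @param h2 Named vector of target broad-sense heritabilities per trait.
#' @param gxe_ratio V_GxE as a fraction of V_G.
#' @param n_years,n_reps Trial design (default 3 x 3).
#' @param ascertain Condition panel sampling on segregation, so sites are
#'   observed SNPs (default TRUE); see
#'   [simulate_frequencies_and_genotypes()].
#' @param ibd_mean_len Mean IBD segment length in bp.
#' @param ibd_frac Expected fraction of the genome covered by IBD per pair.
#' @param seed RNG seed used by [simulate_diallel()].
#' @return Object of class `sim_config` (a list).
#' @export
sim_config <- function(n_parents = 12,
                       n_sites = 5000,
                       genome_length = 1e8,
                       mu = 1e-4,
                       pos_weight = 0.5,
                       genic_fraction = 0.64,
                       sel_coef_law = function(g) 0.005 + 0.012 * pmax(g, 0),
                       dominance_law = function(g, n = length(g))
                         clamp(0.15 + 0.22 * pmax(g, 0) + stats::rnorm(n, 0, 0.05), 0, 1),
                       effect_law = function(g, n = length(g))
                         0.25 * pmax(g, 0) + abs(stats::rnorm(n, 0, 0.03)),
                       dom_share = 0.24,
                       mph_target = 1.82,
                       h2 = c(YLD = 0.7, FT = 0.9),
                       gxe_ratio = 0.25,
                       n_years = 3,
                       n_reps = 3,
                       ascertain = TRUE,
                       ibd_mean_len = 2e6,
                       ibd_frac = 0.08,
                       seed = 1L) {
  if (n_parents < 2) stop("n_parents must be >= 2")
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (mu <= 0) stop("mutation_rate must be > 0")
  if (pos_weight < 0 || pos_weight > 1) stop("invalid mixture weight pos_weight")
  if (genic_fraction < 0 || genic_fraction > 1) stop("invalid genic_fraction")
  if (any(h2 <= 0 | h2 > 1)) stop("h2 must lie in (0, 1]")
  if (dom_share < 0 || dom_share >= 1) stop("dom_share must lie in [0, 1)")
  cfg <- list(n_parents = n_parents, n_sites = n_sites,
              genome_length = genome_length, mu = mu,
              pos_weight = pos_weight, genic_fraction = genic_fraction,
              sel_coef_law = sel_coef_law, dominance_law = dominance_law,
              effect_law = effect_law, dom_share = dom_share,
              mph_target = mph_target, h2 = h2, ascertain = ascertain,
              gxe_ratio = gxe_ratio, n_years = n_years, n_reps = n_reps,
              ibd_mean_len = ibd_mean_len, ibd_frac = ibd_frac,
              seed = as.integer(seed),
              parents = sprintf("P%02d", seq_len(n_parents)))
  class(cfg) <- "sim_config"
  cfg
}
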