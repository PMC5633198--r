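#' Equilibrium frequency of a deleterious allele under mutation-selection balance
#'
#' Computes the classical deterministic equilibrium frequency of a deleterious
#' allele maintained by recurrent mutation (rate `mu`) and removed by selection
#' of strength `s` against the deleterious homozygote. Dominance is
#' parameterised by `k`, the degree of dominance of the *fitness-increasing*
#' (conserved) allele on a 0..1 scale: `k = 1` means the deleterious allele is
#' fully recessive, `k = 0` means additive gene action. In terms of the usual
#' dominance coefficient of the deleterious allele, `h = (1 - k) / 2`.
#'
#' Two closed forms are used, switching at `k = 0.98`:
#' near-complete recessivity (`k > 0.98`) gives `p = sqrt(mu / s)`, while
#' partial dominance (`k <= 0.98`) gives `p = 2 * mu / (s * (1 - k))`
#' (equivalently `mu / (h * s)`). The partial-dominance form diverges as
#' `k -> 1`, which is why the recessive form takes over near that boundary.
#' Results are clamped to `[0, 0.5]`; the deleterious allele is by definition
#' the minor allele, so equilibria implying a frequency above one half are
#' truncated (the number clamped is recorded in the `"n_clamped"` attribute).
#'
#' @param mu Per-site, per-generation mutation rate towards the deleterious
#'   allele. Must be positive.
#' @param s Selection coefficient against the deleterious homozygote
#'   (fitness `1 - s`). Must be positive.
#' @param k Degree of dominance of the conserved allele, in `[0, 1]`.
#'   Vectorised over `mu`, `s` and `k`.
#' @return Numeric vector of equilibrium deleterious-allele frequencies in
#'   `[0, 0.5]`, with attribute `n_clamped`.
#' @examples
#' equilibrium_frequency(1e-6, 0.01, k = 1)   # sqrt(1e-4) = 0.01
#' equilibrium_frequency(1e-6, 0.01, k = 0)   # 2e-6 / 0.01 = 2e-4
#' @export
equilibrium_frequency <- function(mu, s, k) {
  n <- max(length(mu), length(s), length(k))
  mu <- rep_len(mu, n); s <- rep_len(s, n); k <- rep_len(k, n)
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("`mu` must be positive and finite")
  if (any(!is.finite(s)) || any(s <= 0)) stop("`s` must be positive and finite")
  if (any(!is.finite(k)) || any(k < 0) || any(k > 1)) stop("`k` must lie in [0, 1]")
  p <- ifelse(k > 0.98, sqrt(mu / s), 2 * mu / (s * (1 - k)))
  clamped <- p > 0.5 | p < 0
  p <- pmin(pmax(p, 0), 0.5)
  attr(p, "n_clamped") <- sum(clamped)
  p
}

#' Sample the deleterious-allele count in a panel of fully inbred lines
#'
#' Each inbred line carries the deleterious allele (homozygously) with
#' probability equal to the population frequency `p`, so the panel count is
#' Binomial(`n`, `p`). A site is segregating in the panel iff the count is
#' strictly between 0 and `n`.
#'
#' @param p Allele frequency (vectorised; each element gives one site).
#' @param n Panel size (number of inbred lines), default 12.
#' @return Integer vector of panel allele counts, with logical attribute
#'   `segregating`.
#' @export
sample_inbred_panel <- function(p, n = 12) {
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]")
  cnt <- stats::rbinom(length(p), size = n, prob = p)
  attr(cnt, "segregating") <- cnt > 0L & cnt < n
  cnt
}

#' Mutation-selection-balance panel-ascertainment experiment
#'
#' Tests whether ascertaining segregating sites in a small panel of inbreds
#' induces a spurious association between dominance and conservation score
#' when, in truth, dominance is independent of conservation. Per site a
#' conservation score `g` is drawn from a standard-exponential positive tail,
#' a dominance value `k ~ Uniform(0, 1)` is drawn independently of `g`, the
#' selection coefficient is `s = gerp_to_s(g)`, the equilibrium frequency
#' follows [equilibrium_frequency()], and a panel of `n_panel` inbreds is
#' sampled. The regression of `k` on `g` among panel-segregating sites is
#' returned; under the null of independence its slope confidence interval
#' should cover zero.
#'
#' The default mutation rate keeps equilibrium frequencies small enough that
#' the panel segregation probability is ~linear in frequency; it then
#' factorises into separate functions of score and dominance, which is what
#' makes the null exact. At much larger rates the segregation probability
#' saturates and a weak spurious slope appears.
#'
#' @param n_sites Number of simulated sites.
#' @param mu Mutation rate passed to [equilibrium_frequency()].
#' @param gerp_to_s Function mapping a conservation score to a selection
#'   coefficient; default `0.005 + 0.01 * g`.
#' @param k_law Function mapping conservation scores to dominance values in
#'   `[0, 1]`; the default ignores the score (`Uniform(0, 1)`, the null).
#'   Supplying a score-dependent law provides a positive control.
#' @param n_panel Panel size (default 12 inbred lines).
#' @param conf Confidence level for the slope interval.
#' @return List with elements `slope`, `ci` (length-2), `p_value`,
#'   `n_segregating`, and the per-site data frame `sites`
#'   (columns `gerp`, `k`, `s`, `p`, `count`, `segregating`).
#' @export
run_msb_experiment <- function(n_sites = 5000, mu = 3e-6,
                               gerp_to_s = function(g) 0.005 + 0.01 * g,
                               k_law = NULL, n_panel = 12, conf = 0.95) {
  stopifnot(n_sites >= 1)
  g <- stats::rexp(n_sites, rate = 1)
  k <- if (is.null(k_law)) stats::runif(n_sites) else k_law(g)
  if (any(k < 0 | k > 1)) stop("k_law must return values in [0, 1]")
  s <- gerp_to_s(g)
  if (any(!is.finite(s)) || any(s <= 0)) stop("gerp_to_s must return positive finite values")
  p <- equilibrium_frequency(mu, s, k)
  cnt <- sample_inbred_panel(as.numeric(p), n = n_panel)
  seg <- attr(cnt, "segregating")
  if (sum(seg) < 20) stop("fewer than 20 segregating sites; increase n_sites or mu")
  fit <- stats::lm(k[seg] ~ g[seg])
  ci <- stats::confint(fit, level = conf)[2L, ]
  list(slope = unname(stats::coef(fit)[2L]),
       ci = unname(ci),
       p_value = summary(fit)$coefficients[2L, 4L],
       n_segregating = sum(seg),
       sites = data.frame(gerp = g, k = k, s = s, p = as.numeric(p),
                          count = as.integer(cnt), segregating = seg))
}
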