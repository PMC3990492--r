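#' Admixture-weighted mean alternate-allele frequency
#'
#' `pbar_i = sum_k theta_k * p_ki`: the expected alt frequency at site i in
#' an admixed individual with proportions theta.
#'
#' @param freq_by_group sites x groups matrix of per-group alt frequencies.
#' @param theta admixture proportions (simplex), ordered like the columns.
#' @return per-site weighted frequency in [0, 1].
#' @export
weighted_freq <- function(freq_by_group, theta) {
  theta <- unlist(theta)
  if (abs(sum(theta) - 1) > 1e-8 || any(theta < 0))
    stop("theta must be a simplex")
  freq_by_group <- as.matrix(freq_by_group)
  if (ncol(freq_by_group) != length(theta))
    stop("theta length must match frequency columns")
  as.vector(freq_by_group %*% theta)
}

#' Posterior-mean genotype dosage from read counts
#'
#' The genotype prior is Hardy-Weinberg at the admixture-weighted alt
#' frequency `pbar`: ((1-pbar)^2, 2 pbar (1-pbar), pbar^2). The read
#' likelihood is binomial in the alt count with per-read alt probability
#' `eps_s`, 0.5, `1 - eps_s` for genotypes 0, 1, 2. The dosage is the
#' posterior mean alt-allele count; with zero reads it equals the prior
#' mean `2 * pbar` exactly.
#'
#' @param ref_count,alt_count non-negative read counts (vectorized).
#' @param pbar weighted alt frequency per site (recycled).
#' @param eps_s sequencing error in (0, 0.5).
#' @return dosage in [0, 2], monotone non-decreasing in `alt_count` at
#'   fixed depth.
#' @export
genotype_dosage <- function(ref_count, alt_count, pbar, eps_s = 0.01) {
  stopifnot(eps_s > 0, eps_s < 0.5)
  if (any(pbar < 0 | pbar > 1, na.rm = TRUE)) stop("pbar must lie in [0, 1]")
  n <- pmax(length(ref_count), length(alt_count), length(pbar))
  ref_count <- rep_len(ref_count, n)
  alt_count <- rep_len(alt_count, n)
  pbar <- rep_len(pbar, n)
  if (any(ref_count < 0 | alt_count < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  q <- c(eps_s, 0.5, 1 - eps_s)
  prior <- cbind((1 - pbar)^2, 2 * pbar * (1 - pbar), pbar^2)
  # binomial kernels share the depth; the choose() factor cancels
  lik <- vapply(1:3, function(gi)
    q[gi]^alt_count * (1 - q[gi])^ref_count, numeric(n))
  if (n == 1) lik <- matrix(lik, nrow = 1)
  post <- prior * lik
  d <- (post[, 2] + 2 * post[, 3]) / rowSums(post)
  # no reads: the posterior is the prior and the dosage its mean, exactly
  none <- (ref_count + alt_count) == 0
  d[none] <- 2 * pbar[none]
  d
}

#' Call presence of an allele from dosage
#'
#' The alternate allele is considered present when the dosage exceeds
#' `tau`. The default 0.6 keeps the false-positive rate of observing a
#' specific variant in a non-carrier below 0.0025 and the false discovery
#' rate below 0.2 at 1x coverage and above.
#'
#' @param dosage dosage vector from [genotype_dosage()].
#' @param tau presence threshold (default 0.6).
#' @return logical vector.
#' @export
call_presence <- function(dosage, tau = 0.6) {
  dosage > tau
}

# Pseudo-genotypes from dosage presence flags, shaped for observe_csvs():
# alt present & ref present -> 1; alt only -> 2; ref only -> 0; neither or
# missing counts -> NA. Ref presence is the mirrored threshold (2 - d) > tau.
dosage_pseudo_genotypes <- function(read_counts, pbar, eps_s = 0.01,
                                    tau = 0.6) {
  n_ind <- ncol(read_counts$alt)
  g <- matrix(NA_integer_, nrow(read_counts$alt), n_ind)
  for (i in seq_len(n_ind)) {
    d <- genotype_dosage(read_counts$ref[, i], read_counts$alt[, i],
                         pbar, eps_s)
    alt_p <- call_presence(d, tau)
    ref_p <- call_presence(2 - d, tau)
    gi <- rep(NA_integer_, length(d))
    gi[alt_p & ref_p] <- 1L
    gi[alt_p & !ref_p] <- 2L
    gi[!alt_p & ref_p] <- 0L
    gi[is.na(d)] <- NA_integer_
    g[, i] <- gi
  }
  g
}

#' Genotype probabilities under the Wahlund effect vs pooled HWE
#'
#' For a specific allele at frequency `f` in one population admixing at
#' proportion `admix_prop` with a population where the allele is absent:
#' the unmixed mixture of the two Hardy-Weinberg populations versus a
#' single pooled Hardy-Weinberg population at frequency
#' `admix_prop * f`. The gap between the two triples bounds the error made
#' by assuming pooled HWE in the dosage prior.
#'
#' @param f allele frequency in the carrier population, in [0, 1].
#' @param admix_prop admixture proportion of the carrier population.
#' @return list with `unmixed` and `pooled` genotype probability triples
#'   (g = 0, 1, 2) and `max_abs_diff`.
#' @export
wahlund_probs <- function(f, admix_prop) {
  stopifnot(f >= 0, f <= 1, admix_prop >= 0, admix_prop <= 1)
  hwe <- function(p) c(`0` = (1 - p)^2, `1` = 2 * p * (1 - p), `2` = p^2)
  unmixed <- admix_prop * hwe(f) + (1 - admix_prop) * hwe(0)
  pooled <- hwe(admix_prop * f)
  list(unmixed = unmixed, pooled = pooled,
       max_abs_diff = max(abs(unmixed - pooled)))
}

#' Draw specific-variant weighted allele frequencies
#'
#' Log-uniform (density proportional to 1/f) on `[fmin, fmax]`: specific
#' variants are dominated by rare alleles -- 5% is the upper tail of their
#' frequency spectrum, not a typical value. The default lower bound is a
#' singleton frequency in a ~200-haplotype panel (~0.005) scaled by a small
#' admixture weight (0.1).
#'
#' @param n number of draws.
#' @param fmin,fmax frequency bounds, 0 < fmin <= fmax <= 1.
#' @return vector of frequencies.
#' @export
r_csv_weighted_freq <- function(n, fmin = 5e-4, fmax = 0.05) {
  stopifnot(fmin > 0, fmax >= fmin, fmax <= 1)
  exp(stats::runif(n, log(fmin), log(fmax)))
}

#' Monte-Carlo false-positive rate of dosage presence calling
#'
#' Simulates non-carrier (genotype 0) site-individual pairs at specific-
#' variant-range weighted frequencies, generates reads (Poisson depth,
#' binomial alt reads at error `eps_s`), computes dosages under the HWE
#' prior and reports the fraction called present at threshold `tau`.
#'
#' @param coverage mean read depth.
#' @param n_pairs number of simulated site-individual pairs.
#' @param eps_s sequencing error.
#' @param tau presence threshold.
#' @param fmin,fmax weighted-frequency bounds passed to
#'   [r_csv_weighted_freq()].
#' @param seed RNG seed.
#' @return list with `fpr`, `n_pairs`, `coverage`.
#' @export
presence_fpr <- function(coverage, n_pairs = 1e5, eps_s = 0.01, tau = 0.6,
                         fmin = 5e-4, fmax = 0.05, seed = 1L) {
  set.seed(seed)
  pbar <- r_csv_weighted_freq(n_pairs, fmin, fmax)
  depth <- stats::rpois(n_pairs, coverage)
  alt <- stats::rbinom(n_pairs, depth, eps_s)   # true genotype is 0
  d <- genotype_dosage(depth - alt, alt, pbar, eps_s)
  list(fpr = mean(call_presence(d, tau)), n_pairs = n_pairs,
       coverage = coverage)
}
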