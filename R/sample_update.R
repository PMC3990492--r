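#' Ancestry state of tracks at given site positions
#'
#' @param tracks an [ancestry_track()].
#' @param positions site positions (bp, same chromosome/coordinate system).
#' @param individuals individual ids to extract (default: those present).
#' @return list of two character matrices `anc1`, `anc2`
#'   (individuals x sites); positions not covered by any segment are `NA`.
#' @export
tracks_to_states <- function(tracks, positions, individuals = NULL) {
  df <- as.data.frame(tracks)
  if (is.null(individuals)) individuals <- unique(df$individual)
  n <- length(positions)
  a1 <- matrix(NA_character_, length(individuals), n,
               dimnames = list(individuals, NULL))
  a2 <- a1
  for (i in seq_along(individuals)) {
    seg <- df[df$individual == individuals[i], , drop = FALSE]
    if (nrow(seg) == 0) next
    seg <- seg[order(seg$start), , drop = FALSE]
    idx <- findInterval(positions, seg$start)
    ok <- idx >= 1 & positions <= seg$end[pmax(idx, 1)]
    a1[i, ok] <- seg$anc1[idx[ok]]
    a2[i, ok] <- seg$anc2[idx[ok]]
  }
  list(anc1 = a1, anc2 = a2)
}

# site indices excluded by the transition buffer for one individual's
# per-site state vector (NA-safe; a change to/from NA also counts as a
# transition since coverage edges are low-confidence too).
buffer_mask <- function(state, buffer) {
  n <- length(state)
  if (n <= 1) return(rep(FALSE, n))
  s <- ifelse(is.na(state), "\r.na", state)
  tr <- which(s[-1] != s[-n]) + 1L   # transition between tr-1 and tr
  excl <- rep(FALSE, n)
  for (t in tr) {
    lo <- max(1L, t - buffer)
    hi <- min(n, t + buffer - 1L)
    if (hi >= lo) excl[lo:hi] <- TRUE
  }
  excl
}

#' Sample allele frequencies from homozygous-ancestry calls
#'
#' For each site, sums alternate-allele counts over individuals whose
#' extended diploid track is homozygous for `group` at that site, excluding
#' sites within `buffer` SNPs (in the analysis site order) of an ancestry
#' transition of that individual (those calls are less confident). The
#' frequency is the summed count divided by twice the number of eligible
#' calls; sites with no eligible call are `NA` (undefined).
#'
#' @param genotypes a [genotype_matrix()].
#' @param tracks diploid [ancestry_track()] covering the genotype sites.
#' @param group group whose frequency is estimated.
#' @param buffer number of SNPs around a transition to exclude (default 10).
#' @return list with `p_alt` (per-site frequency, `NA` where undefined) and
#'   `n_calls` (eligible homozygous calls per site).
#' @export
sample_frequencies <- function(genotypes, tracks, group, buffer = 10L) {
  pos <- genotypes$sites$pos
  st <- tracks_to_states(tracks, pos, genotypes$individuals)
  n_site <- length(pos)
  num <- numeric(n_site)
  den <- integer(n_site)
  for (i in seq_along(genotypes$individuals)) {
    state <- paste(st$anc1[i, ], st$anc2[i, ], sep = "\r")
    state[is.na(st$anc1[i, ])] <- NA
    hom <- !is.na(st$anc1[i, ]) & st$anc1[i, ] == group & st$anc2[i, ] == group
    excl <- buffer_mask(state, buffer)
    g <- genotypes$genotypes[, i]
    ok <- hom & !excl & !is.na(g)
    num[ok] <- num[ok] + g[ok]
    den[ok] <- den[ok] + 1L
  }
  p <- ifelse(den > 0, num / (2 * den), NA_real_)
  list(p_alt = p, n_calls = den)
}

#' Max-update of reference frequencies with sample frequencies
#'
#' Element-wise maximum; undefined (`NA`) sample entries pass the reference
#' through. Frequencies act as presence indicators for specific-variant
#' calling, so evidence of presence in the sample can only be added, never
#' erased: absence in the sample does not overwrite reference presence.
#'
#' @param ref reference frequencies (vector or matrix).
#' @param sample sample frequencies of the same shape, `NA` = undefined.
#' @return updated frequencies, `>= ref` everywhere.
#' @export
max_update <- function(ref, sample) {
  out <- pmax(ref, sample)
  out[is.na(sample)] <- ref[is.na(sample)]
  out
}

# One round of frequency updating from called tracks, for all groups and
# both alleles. freqs: list(alt, ref, groups) of sites x groups matrices.
update_frequencies <- function(genotypes, tracks, freqs, buffer = 10L) {
  for (k in seq_along(freqs$groups)) {
    sf <- sample_frequencies(genotypes, tracks, freqs$groups[k], buffer)
    freqs$alt[, k] <- max_update(freqs$alt[, k], sf$p_alt)
    freqs$ref[, k] <- max_update(freqs$ref[, k],
                                 ifelse(is.na(sf$p_alt), NA, 1 - sf$p_alt))
  }
  freqs
}

csv_key <- function(tab) paste(tab$site, tab$csv_allele)

# Decode every individual against a csv table; returns combined track.
decode_cohort <- function(genotypes, tab, spec, pseudo_geno = NULL) {
  pos <- genotypes$sites$pos
  chrom <- genotypes$sites$chrom[1]
  g <- if (is.null(pseudo_geno)) genotypes$genotypes else pseudo_geno
  segs <- vector("list", length(genotypes$individuals))
  prior_state <- which.max(initial_distribution(spec))
  for (i in seq_along(genotypes$individuals)) {
    obs <- observe_csvs(g[, i], tab)
    id <- genotypes$individuals[i]
    if (nrow(obs) == 0) {
      # no informative variant observed: fall back to the prior mode
      segs[[i]] <- data.frame(
        chrom = chrom, start = min(pos), end = max(pos), individual = id,
        anc1 = spec$groups[spec$states[1, prior_state]],
        anc2 = spec$groups[spec$states[2, prior_state]])
    } else {
      dec <- posterior_decode(obs, spec)
      segs[[i]] <- as.data.frame(extend_calls(dec$calls, pos, chrom, id))
    }
  }
  ancestry_track(do.call(rbind, segs))
}

#' Sample-aware iterative local ancestry inference
#'
#' The full inference loop: call specific variants from the current
#' frequencies, observe them in each individual, posterior-decode, extend
#' calls to all sites, then re-estimate per-group frequencies from
#' confidently called homozygous-ancestry segments of the cohort itself and
#' max-update the frequency matrices. `n_iter` refinement rounds follow the
#' initial reference-panel-only decode (`n_iter = 0` is the plain pipeline).
#' Iteration stops early when the specific-variant set no longer changes.
#'
#' @param genotypes a [genotype_matrix()], site-harmonized with the source
#'   of `freqs`.
#' @param spec an [hmm_spec()].
#' @param freqs list(alt, ref, groups) of per-group allele frequency
#'   matrices, from [panel_frequencies()]; alternatively pass `panel`.
#' @param panel optional [haplotype_panel()] used to compute `freqs`.
#' @param level grouping level when `panel` is given.
#' @param n_iter number of refinement iterations (default 4; accuracy gains
#'   are typically negligible past the 3rd-4th).
#' @param buffer transition buffer in SNPs for [sample_frequencies()].
#' @param read_counts optional read counts (list with `ref`/`alt` matrices)
#'   for low-coverage mode: observations are then made from genotype
#'   dosages thresholded at `tau` instead of hard genotypes.
#' @param eps_s sequencing error used in dosage computation.
#' @param tau dosage presence threshold.
#' @param keep_history if TRUE, tracks from every iteration are returned.
#' @return list with `tracks` (final calls), `csv_table`, `freqs`,
#'   `diagnostics` (per-iteration data.frame: iteration, n_csv, added,
#'   removed), and optionally `history`.
#' @export
infer_ancestry <- function(genotypes, spec, freqs = NULL, panel = NULL,
                           level = c("continental", "population"),
                           n_iter = 4L, buffer = 10L,
                           read_counts = NULL, eps_s = 0.01, tau = 0.6,
                           keep_history = FALSE) {
  level <- match.arg(level)
  if (is.null(freqs)) {
    if (is.null(panel)) stop("supply either freqs or panel")
    freqs <- panel_frequencies(panel, level)
  }
  if (!all(spec$groups %in% freqs$groups))
    stop("spec groups absent from frequency matrices")
  sites <- genotypes$sites
  if (nrow(freqs$alt) != nrow(sites))
    stop("frequency matrices not aligned with genotype sites")
  if (n_iter < 0) stop("n_iter must be >= 0")

  pseudo <- NULL
  make_pseudo <- function(freqs) {
    if (is.null(read_counts)) return(NULL)
    pbar <- weighted_freq(freqs$alt[, spec$groups, drop = FALSE], spec$theta)
    dosage_pseudo_genotypes(read_counts, pbar, eps_s, tau)
  }

  diagnostics <- data.frame(iteration = integer(), n_csv = integer(),
                            added = integer(), removed = integer())
  history <- list()
  tab <- csvs_from_freqs(sites, freqs$alt, freqs$ref, freqs$groups, level)
  prev_key <- csv_key(tab)
  pseudo <- make_pseudo(freqs)
  tracks <- decode_cohort(genotypes, tab, spec, pseudo)
  diagnostics[1, ] <- list(0L, nrow(tab), NA_integer_, NA_integer_)
  if (keep_history) history[[1]] <- tracks

  it <- 0L
  while (it < n_iter) {
    it <- it + 1L
    freqs <- update_frequencies(genotypes, tracks, freqs, buffer)
    tab <- csvs_from_freqs(sites, freqs$alt, freqs$ref, freqs$groups, level)
    key <- csv_key(tab)
    added <- sum(!(key %in% prev_key))
    removed <- sum(!(prev_key %in% key))
    diagnostics[it + 1L, ] <- list(it, nrow(tab), added, removed)
    if (added == 0L && removed == 0L) break
    prev_key <- key
    pseudo <- make_pseudo(freqs)
    tracks <- decode_cohort(genotypes, tab, spec, pseudo)
    if (keep_history) history[[it + 1L]] <- tracks
  }
  out <- list(tracks = tracks, csv_table = tab, freqs = freqs,
              diagnostics = diagnostics)
  if (keep_history) out$history <- history
  out
}

#' One-shot frequency update from externally supplied ancestry tracks
#'
#' Re-estimates per-group frequencies from the homozygous-ancestry regions
#' of user-provided tracks (e.g. consensus calls from other methods),
#' max-updates the reference frequencies and re-calls specific variants.
#'
#' @param genotypes a [genotype_matrix()].
#' @param tracks externally provided diploid [ancestry_track()].
#' @param panel reference [haplotype_panel()].
#' @param level grouping level.
#' @param buffer transition buffer in SNPs.
#' @return list with the updated `csv_table` and `freqs`.
#' @export
update_from_provided_tracks <- function(genotypes, tracks, panel,
                                        level = c("continental", "population"),
                                        buffer = 10L) {
  level <- match.arg(level)
  freqs <- panel_frequencies(panel, level)
  if (nrow(freqs$alt) != nrow(genotypes$sites))
    stop("panel and genotype site sets differ; harmonize first")
  freqs <- update_frequencies(genotypes, tracks, freqs, buffer)
  tab <- csvs_from_freqs(genotypes$sites, freqs$alt, freqs$ref,
                         freqs$groups, level)
  list(csv_table = tab, freqs = freqs)
}
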