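#' Admixture model parameters
#'
#' @param theta named numeric simplex of admixture proportions per
#'   continental group.
#' @param G integer > 0, generations since admixture.
#' @param lambda crossover rate per bp per generation (biological scale,
#'   default 1e-8).
#' @return object of class `admixture_model`.
#' @export
admixture_model <- function(theta, G, lambda = 1e-8) {
  theta <- unlist(theta)
  if (is.null(names(theta))) stop("theta must be named by group")
  if (any(theta < 0) || abs(sum(theta) - 1) > 1e-8)
    stop("theta must be a simplex (non-negative, summing to 1)")
  if (G < 1 || G != round(G)) stop("G must be a positive integer")
  if (lambda <= 0) stop("lambda must be positive")
  structure(list(theta = theta, G = as.integer(G), lambda = lambda),
            class = "admixture_model")
}

#' Simulation presets for common admixed American populations
#'
#' Admixture proportions (European, Native American, African) and
#' generations since admixture: African-American 0.2/0.0/0.8 with G = 6;
#' Mexican 0.45/0.5/0.05 and Puerto Rican 0.67/0.13/0.2, both with G = 15.
#'
#' @param name `"AA"`, `"MEX"` or `"PUR"`.
#' @param groups names for the three groups, in (European, Native American,
#'   African) order.
#' @return an [admixture_model()].
#' @export
admix_preset <- function(name = c("AA", "MEX", "PUR"),
                         groups = c("EUR", "NAM", "AFR")) {
  name <- match.arg(name)
  p <- switch(name,
              AA  = list(theta = c(0.2, 0.0, 0.8), G = 6L),
              MEX = list(theta = c(0.45, 0.5, 0.05), G = 15L),
              PUR = list(theta = c(0.67, 0.13, 0.2), G = 15L))
  admixture_model(stats::setNames(p$theta, groups), p$G)
}

#' Specification of a synthetic ancestral reference panel
#'
#' Describes K ancestral groups over one chromosome: shared variants (drawn
#' in every group) plus group-private variants at controlled per-megabase
#' densities. Private variants are the ground-truth specific variants the
#' generator knows by construction.
#'
#' @param groups character vector of group names (K >= 2).
#' @param length_bp chromosome length in bp.
#' @param n_hap haplotypes per group (recycled to K).
#' @param shared_per_mb density of shared variants per Mb (Poisson mean).
#' @param shared_freq_range per-group alt frequencies of shared variants
#'   are drawn i.i.d. uniform from this range.
#' @param private_per_mb per-group density of private variants per Mb
#'   (recycled to K).
#' @param private_freq_range alt frequency range of a private allele in its
#'   own group (uniform draw); frequency is exactly 0 elsewhere.
#' @param spurious_fraction fraction of each group's private sites that are
#'   only apparently private: their allele also segregates in the other
#'   groups (at a frequency from `private_freq_range`), but reference
#'   panels sampled with `mask_spurious = TRUE` force those carriers
#'   absent, emulating specific variants spuriously called from a finite
#'   panel. Cohort-source panels sampled with `mask_spurious = FALSE` carry
#'   the allele everywhere it truly segregates.
#' @param chrom chromosome name.
#' @return object of class `synthetic_panel_spec`.
#' @export
synthetic_panel_spec <- function(groups, length_bp, n_hap = 50,
                                 shared_per_mb = 100,
                                 shared_freq_range = c(0.05, 0.95),
                                 private_per_mb = 50,
                                 private_freq_range = c(0.02, 0.2),
                                 spurious_fraction = 0,
                                 chrom = "chr1") {
  K <- length(groups)
  stopifnot(K >= 2, length_bp >= 1, all(n_hap >= 1),
            shared_per_mb >= 0, all(private_per_mb >= 0),
            spurious_fraction >= 0, spurious_fraction <= 1)
  rng_ok <- function(r) length(r) == 2 && r[1] > 0 && r[2] <= 1 && r[1] <= r[2]
  if (!rng_ok(shared_freq_range) || !rng_ok(private_freq_range))
    stop("frequency ranges must lie in (0, 1]")
  structure(list(groups = groups, length_bp = as.numeric(length_bp),
                 n_hap = rep_len(n_hap, K),
                 shared_per_mb = shared_per_mb,
                 shared_freq_range = shared_freq_range,
                 private_per_mb = rep_len(private_per_mb, K),
                 private_freq_range = private_freq_range,
                 spurious_fraction = spurious_fraction,
                 chrom = chrom),
            class = "synthetic_panel_spec")
}

# Draw the generative truth (site positions, types and per-group allele
# frequencies) for a spec. Shared between reference and cohort sampling so
# both panels are views of one underlying population.
synthetic_truth <- function(spec, seed) {
  set.seed(seed)
  K <- length(spec$groups)
  mb <- spec$length_bp / 1e6
  n_shared <- stats::rpois(1, spec$shared_per_mb * mb)
  n_priv <- stats::rpois(K, spec$private_per_mb * mb)
  n_tot <- n_shared + sum(n_priv)
  type <- c(rep("shared", n_shared),
            rep(spec$groups, n_priv))
  pos <- sort(sample.int(spec$length_bp, n_tot, replace = FALSE))
  # assign types randomly to positions so private sites interleave
  type <- sample(type)
  freq <- matrix(0, n_tot, K, dimnames = list(NULL, spec$groups))
  sh <- type == "shared"
  freq[sh, ] <- matrix(stats::runif(sum(sh) * K, spec$shared_freq_range[1],
                                    spec$shared_freq_range[2]),
                       ncol = K)
  spurious <- rep(FALSE, n_tot)
  for (k in seq_len(K)) {
    pk <- type == spec$groups[k]
    freq[pk, k] <- stats::runif(sum(pk), spec$private_freq_range[1],
                                spec$private_freq_range[2])
    if (spec$spurious_fraction > 0) {
      idx <- which(pk)
      n_sp <- round(spec$spurious_fraction * length(idx))
      if (n_sp > 0) {
        sp <- sample(idx, n_sp)
        spurious[sp] <- TRUE
        others <- setdiff(seq_len(K), k)
        freq[sp, others] <- matrix(
          stats::runif(n_sp * (K - 1), spec$private_freq_range[1],
                       spec$private_freq_range[2]), ncol = K - 1)
      }
    }
  }
  list(pos = pos, type = type, freq = freq, spurious = spurious)
}

#' Generate a synthetic labeled reference panel
#'
#' Sites are placed uniformly along the chromosome; haplotype alleles are
#' sampled independently per site from the generative per-group
#' frequencies (no linkage disequilibrium). The generative truth (site
#' type, true per-group frequencies, spurious flag) is attached as
#' `attr(panel, "truth")` for parameter-recovery checks.
#'
#' @param spec a [synthetic_panel_spec()].
#' @param seed RNG seed; output is deterministic given (spec, seed).
#' @param truth optional pre-drawn truth (from a previous call's
#'   attribute), so a reference panel and a cohort-source panel can be
#'   sampled from the same underlying population.
#' @param mask_spurious if TRUE, carriers of a spurious-flagged allele are
#'   forced absent outside its designated group (finite-panel artifact);
#'   if FALSE the allele is sampled at its true frequencies everywhere.
#' @return a [haplotype_panel()] with a `truth` attribute.
#' @export
generate_synthetic_panel <- function(spec, seed = 1L, truth = NULL,
                                     mask_spurious = TRUE) {
  if (is.null(truth)) truth <- synthetic_truth(spec, seed)
  set.seed(seed + 1L)
  K <- length(spec$groups)
  freq <- truth$freq
  if (mask_spurious && any(truth$spurious)) {
    for (k in seq_len(K)) {
      sp <- truth$spurious & truth$type == spec$groups[k]
      freq[sp, -k] <- 0
    }
  }
  haps <- matrix(0L, length(truth$pos), sum(spec$n_hap))
  labels <- rep(spec$groups, spec$n_hap)
  col0 <- 0L
  for (k in seq_len(K)) {
    nk <- spec$n_hap[k]
    haps[, col0 + seq_len(nk)] <-
      (matrix(stats::runif(length(truth$pos) * nk), ncol = nk) <
         freq[, k]) * 1L
    col0 <- col0 + nk
  }
  # ref/alt letters drawn from unambiguous strand pairs
  pairs <- matrix(c("A", "C", "A", "G", "C", "T", "G", "T"), ncol = 2,
                  byrow = TRUE)
  pick <- ((seq_along(truth$pos) - 1L) %% 4L) + 1L
  sites <- data.frame(chrom = spec$chrom, pos = truth$pos,
                      ref = pairs[pick, 1], alt = pairs[pick, 2])
  panel <- haplotype_panel(sites, haps, labels)
  attr(panel, "truth") <- truth
  panel
}

#' Simulate admixed diploids by a random walk over panel haplotypes
#'
#' Each simulated haploid is built segment by segment: the distance to the
#' next crossover is exponential with mean `1/(lambda * G)` bp, and at each
#' crossover an ancestry is drawn from `theta` and a source haplotype
#' uniformly from that group (redrawing may pick the same ancestry, so not
#' every crossover is an ancestry switch). Haploids are paired into
#' diploids, each simulated haploid used exactly once.
#'
#' @param panel source [haplotype_panel()]; every group with positive
#'   `theta` needs at least one haplotype.
#' @param model an [admixture_model()] (theta named by the panel's
#'   continental groups).
#' @param n_genotypes number of diploid individuals to simulate.
#' @param seed RNG seed (bit-for-bit reproducible).
#' @return list with `genotypes` (a [genotype_matrix()]), `truth_diploid`
#'   and `truth_haploid` ([ancestry_track()]s; haploid individual ids are
#'   `<ind>_1`, `<ind>_2`), and `crossover_lengths` (the exact exponential
#'   crossover-distance draws in bp, for distributional checks; on the
#'   track each haploid's final segment is right-censored at the
#'   chromosome end).
#' @export
simulate_admixed <- function(panel, model, n_genotypes, seed = 1L) {
  set.seed(seed)
  theta <- model$theta
  grp <- panel_groups(panel, "continental")
  used <- names(theta)[theta > 0]
  if (!all(used %in% grp))
    stop("theta has positive mass on group(s) without panel haplotypes: ",
         paste(setdiff(used, grp), collapse = ", "))
  by_group <- split(seq_along(grp), grp)
  pos <- panel$sites$pos
  chrom <- panel$sites$chrom[1]
  lo <- min(pos); hi <- max(pos)
  mean_seg <- 1 / (model$lambda * model$G)
  n_hap <- 2L * n_genotypes
  hap_alleles <- matrix(0L, nrow(panel$sites), n_hap)
  seg_list <- vector("list", n_hap)
  xlen <- vector("list", n_hap)
  for (h in seq_len(n_hap)) {
    cur <- lo
    starts <- integer(0); ends <- integer(0); ancs <- character(0)
    draws <- numeric(0)
    while (cur <= hi) {
      anc <- sample(names(theta), 1L, prob = theta)
      src <- by_group[[anc]]
      src <- if (length(src) == 1L) src else src[sample.int(length(src), 1L)]
      len <- stats::rexp(1, rate = 1 / mean_seg)
      seg_end <- min(hi, floor(cur + len))
      idx <- which(pos >= cur & pos <= seg_end)
      if (length(idx) > 0) hap_alleles[idx, h] <- panel$haplotypes[idx, src]
      starts <- c(starts, cur); ends <- c(ends, seg_end); ancs <- c(ancs, anc)
      draws <- c(draws, len)
      cur <- seg_end + 1L
    }
    # the raw draws, not the track segments: segments are right-censored at
    # the chromosome end (and keeping only the complete ones would be
    # length-biased), while the draws are exact Exp(1/(lambda G)) samples
    xlen[[h]] <- draws
    # merge adjacent same-ancestry segments for the truth track
    run <- cumsum(c(TRUE, ancs[-1] != ancs[-length(ancs)]))
    seg_list[[h]] <- data.frame(
      chrom = chrom,
      start = as.integer(tapply(starts, run, min)),
      end = as.integer(tapply(ends, run, max)),
      anc = as.character(tapply(ancs, run, `[`, 1L)))
  }
  inds <- sprintf("sim%03d", seq_len(n_genotypes))
  hap_ids <- paste(rep(inds, each = 2), 1:2, sep = "_")
  truth_hap <- do.call(rbind, lapply(seq_len(n_hap), function(h)
    cbind(seg_list[[h]], individual = hap_ids[h])))
  truth_hap <- ancestry_track(data.frame(
    chrom = truth_hap$chrom, start = truth_hap$start, end = truth_hap$end,
    individual = truth_hap$individual, anc1 = truth_hap$anc,
    anc2 = NA_character_))
  # diploid truth: overlay the two haploid tracks of each individual
  dip <- vector("list", n_genotypes)
  for (i in seq_len(n_genotypes)) {
    s1 <- seg_list[[2 * i - 1]]; s2 <- seg_list[[2 * i]]
    cuts <- sort(unique(c(s1$start, s1$end + 1L, s2$start, s2$end + 1L)))
    st <- cuts[-length(cuts)]; en <- cuts[-1] - 1L
    a1 <- s1$anc[findInterval(st, s1$start)]
    a2 <- s2$anc[findInterval(st, s2$start)]
    lo_a <- pmin(a1, a2); hi_a <- pmax(a1, a2)
    run <- cumsum(c(TRUE, lo_a[-1] != lo_a[-length(lo_a)] |
                          hi_a[-1] != hi_a[-length(hi_a)]))
    dip[[i]] <- data.frame(
      chrom = chrom,
      start = as.integer(tapply(st, run, min)),
      end = as.integer(tapply(en, run, max)),
      individual = inds[i],
      anc1 = as.character(tapply(lo_a, run, `[`, 1L)),
      anc2 = as.character(tapply(hi_a, run, `[`, 1L)))
  }
  truth_dip <- ancestry_track(do.call(rbind, dip))
  geno <- hap_alleles[, seq(1, n_hap, 2)] + hap_alleles[, seq(2, n_hap, 2)]
  list(genotypes = genotype_matrix(panel$sites, geno, inds),
       truth_diploid = truth_dip,
       truth_haploid = truth_hap,
       crossover_lengths = unlist(xlen))
}

#' Simulate per-site read counts at a given mean coverage
#'
#' Depth at each (site, individual) is Poisson with mean `coverage`; the
#' alternate-read count is binomial with success probability `eps_s`, 0.5
#' or `1 - eps_s` for genotypes 0, 1 and 2 (sequencing error `eps_s` on
#' homozygous sites).
#'
#' @param genotypes a [genotype_matrix()]; missing genotypes get depth but
#'   alt reads drawn as for genotype 0 with probability proportional to
#'   nothing -- they are returned with NA counts and should be skipped.
#' @param coverage mean read depth (>= 0).
#' @param eps_s per-read sequencing error in (0, 0.5).
#' @param seed RNG seed.
#' @return list with `sites`, `individuals`, `ref` and `alt` count
#'   matrices (sites x individuals).
#' @export
simulate_reads <- function(genotypes, coverage, eps_s = 0.01, seed = 1L) {
  stopifnot(coverage >= 0, eps_s > 0, eps_s < 0.5)
  set.seed(seed)
  g <- genotypes$genotypes
  n <- length(g)
  depth <- matrix(stats::rpois(n, coverage), nrow = nrow(g))
  q <- matrix(NA_real_, nrow = nrow(g), ncol = ncol(g))
  q[!is.na(g)] <- c(eps_s, 0.5, 1 - eps_s)[g[!is.na(g)] + 1L]
  alt <- matrix(NA_integer_, nrow = nrow(g), ncol = ncol(g))
  ok <- !is.na(q)
  alt[ok] <- stats::rbinom(sum(ok), depth[ok], q[ok])
  ref <- depth - alt
  list(sites = genotypes$sites, individuals = genotypes$individuals,
       ref = ref, alt = alt)
}
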