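#' Mean squared correlation between true and inferred ancestry
#'
#' At each evaluation SNP and each ancestry k, the diploid dosage of k
#' (0/1/2 copies) is formed for truth and calls across individuals and the
#' squared Pearson correlation computed; values are averaged over
#' ancestries (those with positive theta when `theta` is given), then over
#' SNPs. SNP-ancestry cells with zero variance in truth or calls are
#' excluded and counted.
#'
#' @param truth,calls diploid [ancestry_track()]s for the same individuals.
#' @param positions evaluation SNP positions (bp).
#' @param groups ancestry labels to evaluate.
#' @param theta optional admixture proportions; ancestries with zero mass
#'   are skipped.
#' @param individuals ids to evaluate (default: those in `truth`).
#' @param mask optional logical/integer mask over `positions`.
#' @return list with `mean_r2`, `per_ancestry` (named), `n_excluded`
#'   (zero-variance cells) and `n_evaluated`.
#' @export
r2_metric <- function(truth, calls, positions, groups, theta = NULL,
                      individuals = NULL, mask = NULL) {
  if (!is.null(mask)) positions <- positions[mask]
  if (is.null(individuals)) individuals <- unique(as.data.frame(truth)$individual)
  ts <- tracks_to_states(truth, positions, individuals)
  cs <- tracks_to_states(calls, positions, individuals)
  if (all(is.na(cs$anc1))) stop("call tracks cover none of the evaluation sites")
  if (!is.null(theta)) groups <- groups[theta[groups] > 0]
  r2 <- matrix(NA_real_, length(groups), length(positions))
  n_excl <- 0L
  for (ki in seq_along(groups)) {
    k <- groups[ki]
    td <- (ts$anc1 == k) + (ts$anc2 == k)
    cd <- (cs$anc1 == k) + (cs$anc2 == k)
    for (s in seq_along(positions)) {
      x <- td[, s]; y <- cd[, s]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 2 || stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
        n_excl <- n_excl + 1L
        next
      }
      r2[ki, s] <- stats::cor(x[ok], y[ok])^2
    }
  }
  per_snp <- colMeans(r2, na.rm = TRUE)
  per_anc <- rowMeans(r2, na.rm = TRUE)
  mean_r2 <- mean(per_snp[!is.nan(per_snp)])
  list(mean_r2 = mean_r2,
       per_ancestry = stats::setNames(per_anc, groups),
       n_excluded = n_excl,
       n_evaluated = sum(!is.na(r2)))
}

#' Haploid and diploid ancestry accuracy
#'
#' Diploid accuracy: fraction of (SNP, individual) cells where the
#' unordered inferred pair equals the unordered true pair. Haploid
#' accuracy: fraction of allele slots matched under the best pairing of
#' inferred to true labels per cell (cell score 0, 0.5 or 1). Haploid
#' accuracy is always >= diploid accuracy.
#'
#' @inheritParams r2_metric
#' @return named numeric vector `c(haploid =, diploid =)`.
#' @export
haploid_diploid_accuracy <- function(truth, calls, positions,
                                     individuals = NULL, mask = NULL) {
  if (!is.null(mask)) positions <- positions[mask]
  if (is.null(individuals)) individuals <- unique(as.data.frame(truth)$individual)
  ts <- tracks_to_states(truth, positions, individuals)
  cs <- tracks_to_states(calls, positions, individuals)
  ok <- !is.na(ts$anc1) & !is.na(cs$anc1)
  t1 <- ts$anc1[ok]; t2 <- ts$anc2[ok]
  c1 <- cs$anc1[ok]; c2 <- cs$anc2[ok]
  dip <- mean(t1 == c1 & t2 == c2)
  perm1 <- (t1 == c1) + (t2 == c2)
  perm2 <- (t1 == c2) + (t2 == c1)
  hap <- mean(pmax(perm1, perm2) / 2)
  c(haploid = hap, diploid = dip)
}

track_switch_positions <- function(track, individual) {
  seg <- as.data.frame(track)
  seg <- seg[seg$individual == individual, , drop = FALSE]
  seg <- seg[order(seg$start), , drop = FALSE]
  if (nrow(seg) <= 1) return(integer(0))
  seg$start[-1]
}

#' Distance from true to nearest inferred ancestry switch points
#'
#' For every switch of the true diploid state, the distance in bp to the
#' nearest inferred switch of the same individual; true switches with no
#' inferred switch within `window` are excluded and counted.
#'
#' @param truth,calls diploid [ancestry_track()]s on a shared coordinate
#'   system.
#' @param window maximum distance considered (default 500 kb).
#' @return list with `distances`, `mean` (`NA` when no switch qualifies),
#'   `sd`, `n_excluded`.
#' @export
switch_resolution <- function(truth, calls, window = 5e5) {
  inds <- unique(as.data.frame(truth)$individual)
  dists <- numeric(0)
  n_excl <- 0L
  for (id in inds) {
    tsw <- track_switch_positions(truth, id)
    csw <- track_switch_positions(calls, id)
    for (p in tsw) {
      if (length(csw) == 0) { n_excl <- n_excl + 1L; next }
      d <- min(abs(csw - p))
      if (d <= window) dists <- c(dists, d) else n_excl <- n_excl + 1L
    }
  }
  list(distances = dists,
       mean = if (length(dists)) mean(dists) else NA_real_,
       sd = if (length(dists) > 1) stats::sd(dists) else NA_real_,
       n_excluded = n_excl)
}

#' Run one simulate-infer-evaluate scenario
#'
#' Convenience harness used by [accuracy_sweep()] and the demo pipeline:
#' simulates an admixed cohort from a panel, optionally simulates reads at
#' a given coverage, runs [infer_ancestry()] and scores against the truth.
#'
#' @param panel source and reference [haplotype_panel()] (or a list with
#'   `reference` and `cohort` panels sampled from one truth).
#' @param model an [admixture_model()].
#' @param n_genotypes cohort size.
#' @param n_iter refinement iterations.
#' @param coverage `NA` for hard genotypes, otherwise mean read depth.
#' @param eps_csv,lambda_hmm,eps_s,tau HMM and dosage parameters.
#' @param seed RNG seed.
#' @param keep_history passed to [infer_ancestry()].
#' @return list with `r2`, `accuracy` (haploid/diploid), `fit` (full
#'   [infer_ancestry()] output), `sim`, and `spec`.
#' @export
run_scenario <- function(panel, model, n_genotypes, n_iter = 0L,
                         coverage = NA, eps_csv = 1e-5, lambda_hmm = 1e-15,
                         eps_s = 0.01, tau = 0.6, seed = 1L,
                         keep_history = FALSE) {
  ref_panel <- if (is.list(panel) && !inherits(panel, "haplotype_panel"))
    panel$reference else panel
  cohort_panel <- if (is.list(panel) && !inherits(panel, "haplotype_panel"))
    panel$cohort else panel
  sim <- simulate_admixed(cohort_panel, model, n_genotypes, seed = seed)
  dens <- estimate_density(ref_panel, "continental")
  groups <- names(model$theta)
  N <- dens$N[groups]
  N[is.na(N) | N <= 0] <- 1e-3   # zero-theta groups need a placeholder
  spec <- hmm_spec(groups, model$theta, model$G, lambda = lambda_hmm,
                   eps_csv = eps_csv, N = N)
  rc <- NULL
  if (!is.na(coverage))
    rc <- simulate_reads(sim$genotypes, coverage, eps_s, seed = seed + 1L)
  fit <- infer_ancestry(sim$genotypes, spec,
                        freqs = panel_frequencies(ref_panel, "continental"),
                        n_iter = n_iter, read_counts = rc, eps_s = eps_s,
                        tau = tau, keep_history = keep_history)
  pos <- sim$genotypes$sites$pos
  r2 <- r2_metric(sim$truth_diploid, fit$tracks, pos, groups,
                  theta = model$theta)
  acc <- haploid_diploid_accuracy(sim$truth_diploid, fit$tracks, pos)
  list(r2 = r2, accuracy = acc, fit = fit, sim = sim, spec = spec)
}

#' Accuracy sweep over coverage, cohort size or iteration count
#'
#' Runs the full pipeline at every grid point with fixed seeds and returns
#' a tidy results table.
#'
#' @param kind `"coverage"`, `"cohort_size"` or `"iterations"`.
#' @param grid numeric grid values.
#' @param panel,model as in [run_scenario()].
#' @param base list of baseline arguments overriding [run_scenario()]
#'   defaults (`n_genotypes`, `n_iter`, `coverage`, ...).
#' @param seeds one or more replicate seeds.
#' @return data.frame (grid value, seed, r2, haploid, diploid).
#' @export
accuracy_sweep <- function(kind = c("coverage", "cohort_size", "iterations"),
                           grid, panel, model, base = list(), seeds = 1L) {
  kind <- match.arg(kind)
  rows <- list()
  for (v in grid) {
    for (s in seeds) {
      args <- utils::modifyList(
        list(panel = panel, model = model, n_genotypes = 20L,
             n_iter = 0L, coverage = NA, seed = s), base)
      args[[switch(kind, coverage = "coverage",
                   cohort_size = "n_genotypes",
                   iterations = "n_iter")]] <- v
      res <- do.call(run_scenario, args)
      rows[[length(rows) + 1L]] <- data.frame(
        value = v, seed = s, r2 = res$r2$mean_r2,
        haploid = res$accuracy["haploid"],
        diploid = res$accuracy["diploid"])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
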