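# Hand-built panels and independent oracles shared across tests.

# 3-group toy panel with known allele sharing patterns:
#   site 1: alt carried only by group A (2 copies)     -> alt CSV of A
#   site 2: alt in A and B                             -> no CSV
#   site 3: A fixed ref, B and C fixed alt             -> ref CSV of A only
#   site 4: alt absent everywhere                      -> ref in all, no CSV
#   site 5: alt only in C (1 copy)                     -> alt CSV of C
toy_panel <- function() {
  haps <- rbind(
    c(1, 1, 0, 0, 0, 0),   # site 1
    c(1, 0, 1, 0, 0, 0),   # site 2
    c(0, 0, 1, 1, 1, 1),   # site 3
    c(0, 0, 0, 0, 0, 0),   # site 4
    c(0, 0, 0, 0, 1, 0))   # site 5
  sites <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L, 400L, 500L),
                      ref = "A", alt = "G")
  haplotype_panel(sites, haps, labels = c("A", "A", "B", "B", "C", "C"))
}

# Unordered state index of an ordered pair (a, b) in the (i <= j) listing.
pair_to_state <- function(a, b, states) {
  lo <- min(a, b); hi <- max(a, b)
  which(states[1, ] == lo & states[2, ] == hi)
}

# Independent brute-force posterior: enumerates every ordered diploid path
# (K^2 ordered states per step) with haploid kernels written out directly,
# then collapses to unordered pairs. Shares no code with the package's
# forward-backward or transition construction.
brute_force_posterior <- function(obs_groups, d, theta, G, lambda, E,
                                  states) {
  K <- length(theta)
  L <- length(obs_groups)
  S_ord <- K * K
  ord_a <- rep(seq_len(K), each = K)
  ord_b <- rep(seq_len(K), times = K)
  map <- vapply(seq_len(S_ord),
                function(s) pair_to_state(ord_a[s], ord_b[s], states), 0L)
  e_ord <- E[map, , drop = FALSE]   # emission by ordered state
  init <- theta[ord_a] * theta[ord_b]
  r <- 1 - exp(-d * G * lambda)
  Th <- function(rj) (1 - rj) * diag(K) + rj * matrix(theta, K, K,
                                                      byrow = TRUE)
  Tord <- lapply(r, function(rj) {
    Tm <- Th(rj)
    out <- matrix(0, S_ord, S_ord)
    for (u in seq_len(S_ord))
      for (v in seq_len(S_ord))
        out[u, v] <- Tm[ord_a[u], ord_a[v]] * Tm[ord_b[u], ord_b[v]]
    out
  })
  paths <- as.matrix(expand.grid(rep(list(seq_len(S_ord)), L)))
  prob <- init[paths[, 1]] * e_ord[cbind(paths[, 1], obs_groups[1])]
  if (L > 1) {
    for (j in 2:L) {
      prob <- prob * Tord[[j - 1]][cbind(paths[, j - 1], paths[, j])] *
        e_ord[cbind(paths[, j], obs_groups[j])]
    }
  }
  total <- sum(prob)
  post <- matrix(0, L, ncol(states))
  for (j in seq_len(L)) {
    agg <- tapply(prob, map[paths[, j]], sum)
    post[j, as.integer(names(agg))] <- agg / total
  }
  list(posterior = post, loglik = log(total))
}

# Reference/cohort panel pair drawn from one generative truth, with
# spurious specific variants masked out of the reference only.
spurious_panel_pair <- function(pspec, seed) {
  truth <- lancsv:::synthetic_truth(pspec, seed)
  list(reference = generate_synthetic_panel(pspec, seed = seed,
                                            truth = truth,
                                            mask_spurious = TRUE),
       cohort = generate_synthetic_panel(pspec, seed = seed + 1000L,
                                         truth = truth,
                                         mask_spurious = FALSE),
       truth = truth)
}

# Small phased VCF text for panel-reader tests.
write_test_vcf <- function(path, records,
                           samples = c("S1", "S2")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

vcf_rec <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}
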