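# cohort where sample frequency arithmetic can be done by hand: 3
# individuals, all homozygous group "A" along the whole chromosome
hand_cohort <- function() {
  sites <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                      ref = "A", alt = "G")
  g <- cbind(c(0L, 0L, 1L), c(1L, NA, 1L), c(2L, 0L, 0L))
  gm <- genotype_matrix(sites, g, c("i1", "i2", "i3"))
  tr <- ancestry_track(data.frame(chrom = "chr1", start = 1L, end = 400L,
                                  individual = c("i1", "i2", "i3"),
                                  anc1 = "A", anc2 = "A"))
  list(gm = gm, tr = tr)
}

test_that("sample frequencies sum alt counts over homozygous calls", {
  hc <- hand_cohort()
  sf <- sample_frequencies(hc$gm, hc$tr, "A", buffer = 0L)
  expect_equal(sf$p_alt, c((0 + 1 + 2) / 6, (0 + 0) / 4, (1 + 1 + 0) / 6))
  expect_equal(sf$n_calls, c(3L, 2L, 3L))   # missing genotype not counted
  # no homozygous-B calls anywhere: all undefined
  sfb <- sample_frequencies(hc$gm, hc$tr, "B", buffer = 0L)
  expect_true(all(is.na(sfb$p_alt)))
})

test_that("sites near an ancestry transition are excluded by the buffer", {
  sites <- data.frame(chrom = "chr1", pos = seq(100L, 3000L, by = 100L),
                      ref = "A", alt = "G")
  n <- nrow(sites)
  gm <- genotype_matrix(sites, matrix(2L, n, 1), "i1")
  # transition at 1550: sites 1-15 hom A, 16-30 hom B
  tr <- ancestry_track(data.frame(
    chrom = "chr1", start = c(1L, 1550L), end = c(1549L, 3100L),
    individual = "i1", anc1 = c("A", "B"), anc2 = c("A", "B")))
  sf <- sample_frequencies(gm, tr, "A", buffer = 5L)
  # transition is between site 15 and 16: sites 11..20 are buffered
  expect_true(all(!is.na(sf$p_alt[1:10])))
  expect_true(all(is.na(sf$p_alt[11:30])))
  sf0 <- sample_frequencies(gm, tr, "A", buffer = 0L)
  expect_true(all(!is.na(sf0$p_alt[1:15])))
})

test_that("max-update adds presence evidence but never erases it", {
  ref <- c(0, 0.02, 0, 0.5)
  smp <- c(0.05, 0, NA, 0.6)
  out <- max_update(ref, smp)
  expect_equal(out, c(0.05, 0.02, 0, 0.6))
  # matrix form dominates the reference element-wise
  set.seed(1)
  R <- matrix(runif(30), 10); S <- matrix(runif(30), 10)
  S[sample(30, 8)] <- NA
  expect_true(all(max_update(R, S) >= R))
})

test_that("zero refinement iterations equal the plain decode pipeline", {
  pspec <- synthetic_panel_spec(c("A", "B"), 5e6, n_hap = 30,
                                shared_per_mb = 20, private_per_mb = 80,
                                private_freq_range = c(0.1, 0.4))
  panel <- generate_synthetic_panel(pspec, seed = 2)
  model <- admixture_model(c(A = 0.3, B = 0.7), G = 6)
  sim <- simulate_admixed(panel, model, 5, seed = 4)
  dens <- estimate_density(panel)
  spec <- hmm_spec(c("A", "B"), model$theta, model$G, N = dens$N)
  freqs <- panel_frequencies(panel)
  fit0 <- infer_ancestry(sim$genotypes, spec, freqs = freqs, n_iter = 0)
  # manual pipeline: call, observe, decode, extend
  tab <- call_csvs(panel)
  manual <- lapply(seq_along(sim$genotypes$individuals), function(i) {
    obs <- observe_csvs(sim$genotypes$genotypes[, i], tab)
    dec <- posterior_decode(obs, spec)
    as.data.frame(extend_calls(dec$calls, panel$sites$pos, "chr1",
                               sim$genotypes$individuals[i]))
  })
  manual <- ancestry_track(do.call(rbind, manual))
  expect_equal(as.data.frame(fit0$tracks), as.data.frame(manual))
  expect_equal(fit0$diagnostics$iteration, 0L)
})

test_that("updated frequencies dominate the reference at every iteration", {
  pp <- spurious_panel_pair(
    synthetic_panel_spec(c("A", "B"), 5e6, n_hap = 30, shared_per_mb = 20,
                         private_per_mb = 60,
                         private_freq_range = c(0.1, 0.4),
                         spurious_fraction = 0.05), seed = 6)
  model <- admixture_model(c(A = 0.4, B = 0.6), G = 6)
  sim <- simulate_admixed(pp$cohort, model, 10, seed = 7)
  dens <- estimate_density(pp$reference)
  spec <- hmm_spec(c("A", "B"), model$theta, model$G, N = dens$N)
  ref_freqs <- panel_frequencies(pp$reference)
  fit <- infer_ancestry(sim$genotypes, spec, freqs = ref_freqs, n_iter = 3)
  expect_true(all(fit$freqs$alt >= ref_freqs$alt))
  expect_true(all(fit$freqs$ref >= ref_freqs$ref))
  expect_true(all(fit$diagnostics$n_csv >= 0))
})

test_that("perfect tracks converge the variant set to the sample truth", {
  pp <- spurious_panel_pair(
    synthetic_panel_spec(c("A", "B"), 5e6, n_hap = 40, shared_per_mb = 10,
                         private_per_mb = 60,
                         private_freq_range = c(0.15, 0.5),
                         spurious_fraction = 0.1), seed = 12)
  model <- admixture_model(c(A = 0.5, B = 0.5), G = 6)
  sim <- simulate_admixed(pp$cohort, model, 40, seed = 13)
  upd <- update_from_provided_tracks(sim$genotypes, sim$truth_diploid,
                                     pp$reference)
  ref_tab <- call_csvs(pp$reference)
  # every spurious reference record whose allele is carried by some cohort
  # individual inside a homozygous discordant region must be gone
  truth <- pp$truth
  st <- tracks_to_states(sim$truth_diploid, sim$genotypes$sites$pos,
                         sim$genotypes$individuals)
  spur <- which(truth$spurious[ref_tab$site] & ref_tab$csv_allele == "alt")
  upd_key <- paste(upd$csv_table$site, upd$csv_table$csv_allele)
  removed <- 0L; observable <- 0L
  for (rix in spur) {
    s <- ref_tab$site[rix]
    carr <- !is.na(sim$genotypes$genotypes[s, ]) &
      sim$genotypes$genotypes[s, ] >= 1
    hom_other <- st$anc1[, s] == st$anc2[, s] &
      st$anc1[, s] != ref_tab$group[rix]
    if (any(carr & hom_other, na.rm = TRUE)) {
      observable <- observable + 1L
      key <- paste(s, "alt")
      if (!(key %in% upd_key)) removed <- removed + 1L
    }
  }
  expect_gt(observable, 10)
  # buffer exclusion can shield a transition-adjacent carrier, so demand a
  # high removal fraction rather than totality
  expect_gt(removed / observable, 0.9)
})

test_that("one-shot updates from external tracks behave at the edges", {
  hc <- hand_cohort()
  # tiny explicit panel over the same 3 sites
  panel <- haplotype_panel(hc$gm$sites,
                           cbind(c(1L, 0L, 0L), c(0L, 0L, 0L),
                                 c(0L, 1L, 0L), c(0L, 0L, 0L)),
                           c("A", "A", "B", "B"))
  ref_tab <- call_csvs(panel)
  # empty track set: output equals the reference table
  empty <- ancestry_track(data.frame(chrom = character(), start = integer(),
                                     end = integer(),
                                     individual = character(),
                                     anc1 = character(),
                                     anc2 = character()))
  upd0 <- update_from_provided_tracks(hc$gm, empty, panel)
  expect_equal(as.data.frame(upd0$csv_table), as.data.frame(ref_tab))
  # tracks covering only group A: only A's frequencies can change
  ref_freqs <- panel_frequencies(panel)
  upd <- update_from_provided_tracks(hc$gm, hc$tr, panel)
  expect_equal(upd$freqs$alt[, "B"], ref_freqs$alt[, "B"])
  expect_false(all(upd$freqs$alt[, "A"] == ref_freqs$alt[, "A"]))
})
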