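test_that("specificity rule: present in exactly one group, absent elsewhere", {
  tab <- call_csvs(toy_panel())
  key <- paste(tab$site, tab$csv_allele)
  # site 1: alt carried by 2 group-A haplotypes only
  expect_true("1 alt" %in% key)
  expect_equal(tab$group[key == "1 alt"], "A")
  # site 2: alt in A and B -> no alt record
  expect_false("2 alt" %in% key)
  # site 3 fixed difference: ref is specific to A, alt present in B and C
  expect_true("3 ref" %in% key)
  expect_equal(tab$group[key == "3 ref"], "A")
  expect_false("3 alt" %in% key)
  # site 4: ref present everywhere, alt nowhere -> nothing
  expect_false(any(tab$site == 4))
  # site 5: singleton alt in C
  expect_equal(tab$group[key == "5 alt"], "C")
  # frequency invariant: specific allele has positive frequency in exactly
  # the source group
  fr <- attr(tab, "freqs")
  for (i in seq_len(nrow(tab))) {
    expect_true(fr[i, tab$group[i]] > 0)
    expect_true(all(fr[i, setdiff(colnames(fr), tab$group[i])] == 0))
  }
})

test_that("zero-haplotype groups and single-group panels are errors", {
  p <- toy_panel()
  expect_error(call_csvs(subset_sites(p, 1:5)), NA)
  one_group <- haplotype_panel(p$sites, p$haplotypes,
                               labels = rep("A", 6))
  expect_error(call_csvs(one_group), "at least 2 groups")
  expect_error(estimate_density(one_group), "at least 2 groups")
})

test_that("noise-free synthetic private variants are recovered exactly", {
  pspec <- synthetic_panel_spec(c("A", "B", "C"), 2e6, n_hap = 30,
                                shared_per_mb = 0, private_per_mb = 80,
                                private_freq_range = c(0.2, 0.6))
  panel <- generate_synthetic_panel(pspec, seed = 5)
  truth <- attr(panel, "truth")
  tab <- call_csvs(panel)
  alt_tab <- tab[tab$csv_allele == "alt", ]
  sampled <- which(rowSums(panel$haplotypes) > 0)   # allele drawn into >=1 hap
  expect_setequal(alt_tab$site, sampled)
  expect_equal(alt_tab$group, truth$type[alt_tab$site])
})

test_that("enlarging another group's panel only shrinks foreign CSV sets", {
  set.seed(42)
  pspec <- synthetic_panel_spec(c("A", "B"), 1e6, n_hap = c(10, 4),
                                shared_per_mb = 200, private_per_mb = 50,
                                private_freq_range = c(0.05, 0.5))
  panel <- generate_synthetic_panel(pspec, seed = 9)
  tab_small <- call_csvs(panel)
  a_csvs <- paste(tab_small$site, tab_small$csv_allele)[tab_small$group == "A"]
  # enlarge group B by resampling extra haplotypes from the same truth
  truth <- attr(panel, "truth")
  extra <- (matrix(runif(length(truth$pos) * 20), ncol = 20) <
              truth$freq[, "B"]) * 1L
  big <- haplotype_panel(panel$sites,
                         cbind(panel$haplotypes, extra),
                         c(panel$labels, rep("B", 20)))
  tab_big <- call_csvs(big)
  a_csvs_big <- paste(tab_big$site, tab_big$csv_allele)[tab_big$group == "A"]
  expect_true(all(a_csvs_big %in% a_csvs))
})

test_that("density estimation matches the D * E[f] carriage expectation", {
  # private alt variants at density D/Mb, each at frequency ~f: a held-out
  # haplotype carries each with probability f, so N ~ D * f
  D <- 200; f <- 0.3
  pspec <- synthetic_panel_spec(c("A", "B"), 5e6, n_hap = 60,
                                shared_per_mb = 0, private_per_mb = D,
                                private_freq_range = c(f, f))
  panel <- generate_synthetic_panel(pspec, seed = 31)
  dens <- estimate_density(panel, span_bp = 5e6)
  expected <- D * f
  se <- sqrt(D * 5 * f * (1 - f)) / 5   # binomial carriage over the span
  expect_lt(abs(dens$N["A"] - expected), 4 * se)
  expect_lt(abs(dens$N["B"] - expected), 4 * se)
  # diagonal dominance: own-group density far above spurious rate
  expect_gt(dens$N["A"], 10 * max(dens$spurious_rate["A"], 1e-9))
})

test_that("density with a disjoint target panel counts carriage on targets", {
  pspec <- synthetic_panel_spec(c("A", "B"), 2e6, n_hap = 40,
                                shared_per_mb = 50, private_per_mb = 100,
                                private_freq_range = c(0.1, 0.4))
  truth <- lancsv:::synthetic_truth(pspec, 3)
  train <- generate_synthetic_panel(pspec, seed = 3, truth = truth)
  target <- generate_synthetic_panel(pspec, seed = 77, truth = truth)
  dens <- estimate_density(train, target = target)
  expect_equal(rownames(dens$counts), c("A", "B"))
  expect_gt(dens$N["A"], dens$counts["A", "B"])
  expect_gt(dens$N["B"], dens$counts["B", "A"])
  expect_error(estimate_density(train, span_bp = 0), "span")
})

test_that("observation sequences follow carriage of the specific allele", {
  panel <- toy_panel()
  tab <- call_csvs(panel)
  # sites: 1 = alt CSV of A, 3 = ref CSV of A, 5 = alt CSV of C
  g <- c(0L, 0L, 2L, 0L, 0L)     # hom alt at the fixed-difference site
  expect_equal(nrow(observe_csvs(g, tab)), 0)   # carries no specific allele
  g2 <- c(1L, 0L, 1L, 0L, 2L)
  obs <- observe_csvs(g2, tab)
  # het at site 3 carries the ref allele -> one observation of A
  expect_equal(obs$site, c(1L, 3L, 5L))
  expect_equal(obs$group, c("A", "A", "C"))
  expect_false(is.unsorted(obs$pos))
  # copy number collapses: genotype 2 at site 1 is a single observation,
  # and genotype 0 at the ref-specific site 3 carries the ref allele
  g3 <- c(2L, 0L, 0L, 0L, 0L)
  obs3 <- observe_csvs(g3, tab)
  expect_equal(obs3$site, c(1L, 3L))
  expect_equal(sum(obs3$site == 1L), 1)
})

test_that("missing genotypes and haploid inputs are handled", {
  panel <- toy_panel()
  tab <- call_csvs(panel)
  g <- c(NA_integer_, 0L, 0L, 0L, 1L)
  obs <- observe_csvs(g, tab)
  expect_false(1L %in% obs$site)      # missing -> no observation
  expect_true(5L %in% obs$site)
  # haploid: allele 1 at a ref-specific site is NOT carriage of ref
  hap <- c(0L, 0L, 1L, 0L, 0L)
  obs_h <- observe_csvs(hap, tab, ploidy = 1L)
  expect_false(3L %in% obs_h$site)
  hap2 <- c(0L, 0L, 0L, 0L, 0L)
  expect_true(3L %in% observe_csvs(hap2, tab, ploidy = 1L)$site)
})
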