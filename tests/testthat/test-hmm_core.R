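test_that("crossover probability follows the Poisson closed form", {
  expect_equal(crossover_prob(0, 15, 1e-15), 0)
  expect_equal(crossover_prob(1e6, 15, 1e-15), 1 - exp(-1.5e-8))
  expect_lt(abs(crossover_prob(1e6, 15, 1e-15) - 1.5e-8), 1e-12)
  expect_equal(crossover_prob(1e30, 15, 1e-15), 1)   # d -> Inf limit
  d <- sort(runif(20, 0, 1e8))
  expect_false(is.unsorted(crossover_prob(d, 10, 1e-9)))
  expect_error(crossover_prob(-1, 10, 1e-8), "non-negative")
})

test_that("transition matrix limits: identity at r = 0, pairing at r = 1", {
  th <- c(0.5, 0.5)
  expect_equal(transition_matrix(0, th), diag(3))
  T1 <- transition_matrix(1, th)
  for (row in 1:3) expect_equal(unname(T1[row, ]), c(0.25, 0.5, 0.25))
})

test_that("unordered collapse matches ordered-pair enumeration", {
  # K = 3 spot check: P((A1,A1) -> (A2,A3)) = 2 (r theta2)(r theta3)
  th <- c(0.3, 0.2, 0.5)
  r <- 0.37
  Tm <- transition_matrix(r, th)
  states <- hmm_states(3)
  from <- pair_to_state(1, 1, states)
  to <- pair_to_state(2, 3, states)
  expect_equal(Tm[from, to], 2 * (r * th[2]) * (r * th[3]))
  # full-matrix oracle over random draws
  set.seed(7)
  for (rep in 1:20) {
    K <- sample(2:4, 1)
    th <- as.numeric(rgamma(K, 1)); th <- th / sum(th)
    r <- runif(1)
    states <- hmm_states(K)
    Tm <- transition_matrix(r, th)
    Th <- (1 - r) * diag(K) + r * matrix(th, K, K, byrow = TRUE)
    S <- ncol(states)
    oracle <- matrix(0, S, S)
    for (u in seq_len(S)) {
      a <- states[1, u]; b <- states[2, u]
      for (cc in seq_len(K)) for (dd in seq_len(K)) {
        v <- pair_to_state(cc, dd, states)
        oracle[u, v] <- oracle[u, v] + Th[a, cc] * Th[b, dd]
      }
    }
    expect_equal(Tm, oracle, tolerance = 1e-12)
  }
})

test_that("emission rows are distributions with the stated structure", {
  N <- c(EUR = 15.70, NAM = 10.75, AFR = 123.48)
  spec <- hmm_spec(names(N), c(EUR = 0.2, NAM = 0.1, AFR = 0.7), G = 6,
                   eps_csv = 1e-5, N = N)
  E <- emission_matrix(spec)
  expect_equal(unname(rowSums(E)), rep(1, 6))
  # homozygous EUR row: (1 - 2 eps, eps, eps)
  hom <- pair_to_state(1, 1, spec$states)
  expect_equal(unname(E[hom, ]), c(1 - 2e-5, 1e-5, 1e-5))
  # heterozygous EUR/AFR: in-state mass split by informative densities
  het <- pair_to_state(1, 3, spec$states)
  expect_equal(unname(E[het, "EUR"] / E[het, "AFR"]), 15.70 / 123.48)
  expect_equal(unname(E[het, "NAM"]), 1e-5)
  # K = 2: no out-of-state group, pure density ratio
  spec2 <- hmm_spec(c("A", "B"), c(A = 0.4, B = 0.6), G = 10,
                    N = c(A = 3, B = 1))
  E2 <- emission_matrix(spec2)
  het2 <- pair_to_state(1, 2, spec2$states)
  expect_equal(unname(E2[het2, ]), c(0.75, 0.25))
})

test_that("invalid HMM parameters are rejected", {
  expect_error(hmm_spec(c("A", "B"), c(A = 0.6, B = 0.6), 5,
                        N = c(A = 1, B = 1)), "simplex")
  expect_error(hmm_spec(c("A", "B"), c(A = 0.5, B = 0.5), 5, eps_csv = 0.6,
                        N = c(A = 1, B = 1)), "eps_csv")
  expect_error(hmm_spec(c("A", "B"), c(A = 0.5, B = 0.5), 5,
                        N = c(A = 0, B = 1)), "positive")
})

test_that("single-observation posterior is the Bayes update of the prior", {
  spec <- hmm_spec(c("A", "B"), c(A = 0.5, B = 0.5), G = 6,
                   N = c(A = 2, B = 6))
  obs <- data.frame(site = 1L, pos = 1000L, group = "A")
  dec <- posterior_decode(obs, spec)
  pi0 <- initial_distribution(spec)
  E <- emission_matrix(spec)
  expected <- pi0 * E[, "A"]
  expected <- expected / sum(expected)
  expect_equal(unname(dec$posterior[1, ]), unname(expected), tolerance = 1e-12)
  expect_equal(dec$loglik, log(sum(pi0 * E[, "A"])), tolerance = 1e-12)
})

test_that("forward-backward equals brute-force path enumeration", {
  set.seed(11)
  for (rep in 1:12) {
    K <- sample(2:3, 1)
    L <- sample(1:6, 1)
    th <- as.numeric(rgamma(K, 1)) + 0.05; th <- th / sum(th)
    groups <- LETTERS[seq_len(K)]
    N <- stats::setNames(runif(K, 1, 100), groups)
    G <- sample(c(6, 15), 1)
    lambda <- 10^runif(1, -9, -7)     # large enough that r is non-trivial
    spec <- hmm_spec(groups, stats::setNames(th, groups), G,
                     lambda = lambda, eps_csv = 1e-4, N = N)
    pos <- sort(sample.int(5e7, L))
    og <- sample.int(K, L, replace = TRUE)
    obs <- data.frame(site = seq_len(L), pos = pos, group = groups[og])
    dec <- posterior_decode(obs, spec)
    bf <- brute_force_posterior(og, diff(pos), th, G, lambda,
                                emission_matrix(spec), spec$states)
    expect_equal(dec$loglik, bf$loglik, tolerance = 1e-10)
    expect_lt(max(abs(dec$posterior - bf$posterior)), 1e-10)
  }
})

test_that("decoding stays finite and normalized for very long sequences", {
  spec <- hmm_spec(c("A", "B"), c(A = 0.2, B = 0.8), G = 6,
                   N = c(A = 16, B = 123))
  L <- 1e5
  set.seed(3)
  obs <- data.frame(site = seq_len(L),
                    pos = sort(sample.int(2.4e8, L)),
                    group = sample(c("A", "B"), L, replace = TRUE,
                                   prob = c(0.2, 0.8)))
  dec <- posterior_decode(obs, spec)
  expect_true(is.finite(dec$loglik))
  expect_true(all(is.finite(dec$posterior)))
  expect_lt(max(abs(rowSums(dec$posterior) - 1)), 1e-9)
})

test_that("zero-probability ancestries never appear in calls", {
  spec <- hmm_spec(c("A", "B", "C"), c(A = 0.2, B = 0, C = 0.8), G = 6,
                   N = c(A = 16, B = 1e-3, C = 123))
  set.seed(4)
  obs <- data.frame(site = 1:50, pos = sort(sample.int(1e7, 50)),
                    group = sample(c("A", "C"), 50, replace = TRUE))
  dec <- posterior_decode(obs, spec)
  expect_false(any(dec$calls$anc1 == "B" | dec$calls$anc2 == "B"))
})

test_that("calls extend forward to the next observation", {
  calls <- data.frame(pos = c(100L, 900L),
                      anc1 = c("A", "A"), anc2 = c("A", "B"))
  positions <- c(50L, 100L, 500L, 900L, 1200L)
  tr <- extend_calls(calls, positions, "chr1", "i1")
  st <- tracks_to_states(tr, positions)
  expect_equal(unname(st$anc2[1, ]), c("A", "A", "A", "B", "B"))
  # pos 500 takes the preceding call, pos 50 the first call
  expect_equal(unname(st$anc1[1, 3]), "A")
  expect_equal(unname(st$anc1[1, 1]), "A")
  # single observation covers the whole span as one segment
  tr1 <- extend_calls(calls[1, ], positions, "chr1", "i1")
  expect_equal(nrow(tr1), 1)
  expect_equal(tr1$start, 50L)
  expect_equal(tr1$end, 1200L)
})
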