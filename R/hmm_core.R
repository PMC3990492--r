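#' HMM parameters for diploid local ancestry decoding
#'
#' The hidden states are all unordered pairs of ancestral groups
#' \{A_i, A_j\}, i <= j (K(K+1)/2 states). Emissions are the source groups
#' of observed group-specific variants; transitions depend on the physical
#' distance between consecutive observations.
#'
#' @param groups character vector of K group names.
#' @param theta named admixture proportions (simplex over `groups`).
#' @param G generations since admixture.
#' @param lambda per-bp per-generation recombination rate used in the
#'   transition kernel. The default 1e-15 is intentionally far below the
#'   biological 1e-8: nearby specific variants are strongly linked and a
#'   damped rate stops runs of linked variants from forcing state switches.
#' @param eps_csv spurious-variant emission rate per non-compatible group
#'   (default 1e-5); must lie in (0, 1/K).
#' @param N named informative densities (expected group-k variants per
#'   group-k haplotype per Mb), e.g. from [estimate_density()]. Must be
#'   positive for every group with positive `theta`.
#' @return object of class `hmm_spec`.
#' @export
hmm_spec <- function(groups, theta, G, lambda = 1e-15, eps_csv = 1e-5, N) {
  K <- length(groups)
  stopifnot(K >= 2)
  theta <- theta[groups]
  if (any(is.na(theta)) || any(theta < 0) || abs(sum(theta) - 1) > 1e-8)
    stop("theta must be a simplex named by the groups")
  if (eps_csv <= 0 || eps_csv >= 1 / K)
    stop("eps_csv must lie in (0, 1/K)")
  N <- N[groups]
  if (any(is.na(N)) || any(N < 0))
    stop("N must be non-negative and named by the groups")
  if (any(theta > 0 & N <= 0))
    stop("N must be positive for every group with positive theta")
  if (G < 1) stop("G must be >= 1")
  if (lambda <= 0) stop("lambda must be positive")
  structure(list(groups = groups, K = K, theta = theta, G = G,
                 lambda = lambda, eps_csv = eps_csv, N = N,
                 states = hmm_states(K)),
            class = "hmm_spec")
}

#' Unordered diploid state space
#'
#' @param K number of groups.
#' @return 2 x K(K+1)/2 integer matrix; column s holds the (i, j) group
#'   indices (i <= j) of state s, enumerated (1,1), (1,2), ..., (K,K).
#' @export
hmm_states <- function(K) {
  i <- rep(seq_len(K), times = K - seq_len(K) + 1)
  j <- unlist(lapply(seq_len(K), function(a) a:K))
  rbind(i, j)
}

#' Probability of at least one crossover over a physical distance
#'
#' Recombination between consecutive observations is a Poisson process
#' with rate `d * G * lambda`, so `r = 1 - exp(-d G lambda)`.
#'
#' @param d distance in bp (>= 0).
#' @param G generations since admixture.
#' @param lambda per-bp per-generation rate.
#' @return r in [0, 1), monotone in `d`.
#' @export
crossover_prob <- function(d, G, lambda) {
  if (any(d < 0)) stop("distances must be non-negative")
  1 - exp(-d * G * lambda)
}

# Constant components of the unordered-pair transition matrix:
# T(r) = (1-r)^2 I + r(1-r) B + r^2 C.
transition_components <- function(theta, states = NULL) {
  K <- length(theta)
  if (is.null(states)) states <- hmm_states(K)
  S <- ncol(states)
  B <- matrix(0, S, S)
  C <- matrix(0, S, S)
  for (u in seq_len(S)) {
    a <- states[1, u]; b <- states[2, u]
    for (v in seq_len(S)) {
      cc <- states[1, v]; dd <- states[2, v]
      if (cc == dd) {
        B[u, v] <- theta[cc] * ((a == cc) + (b == cc))
        C[u, v] <- theta[cc]^2
      } else {
        B[u, v] <- theta[dd] * ((a == cc) + (b == cc)) +
                   theta[cc] * ((a == dd) + (b == dd))
        C[u, v] <- 2 * theta[cc] * theta[dd]
      }
    }
  }
  list(B = B, C = C)
}

#' Diploid transition matrix for a given recombination probability
#'
#' Built from two independent haploid kernels
#' `T(a -> b) = (1-r) 1[a = b] + r theta_b` (at a crossover the new
#' ancestry is drawn from the admixture proportions), multiplied over the
#' two chromosomes and collapsed to unordered pairs; an off-diagonal target
#' receives the mass of both ordered realizations.
#'
#' @param r probability of one or more recombinations, in [0, 1].
#' @param theta admixture proportions (simplex).
#' @return row-stochastic K(K+1)/2 square matrix; `r = 0` gives the
#'   identity, `r = 1` makes every row the random-pairing distribution of
#'   `theta`.
#' @export
transition_matrix <- function(r, theta) {
  stopifnot(r >= 0, r <= 1)
  tc <- transition_components(theta)
  diag(ncol(tc$B)) * (1 - r)^2 + r * (1 - r) * tc$B + r^2 * tc$C
}

#' Emission matrix over observed variant source groups
#'
#' In a homozygous state \{A_k, A_k\} the observation is A_k with
#' probability `1 - (K-1) eps` and any other group with probability `eps`
#' each. In a heterozygous state \{A_i, A_j\} the in-state mass
#' `1 - (K-2) eps` is split between A_i and A_j proportional to their
#' informative densities `N_i : N_j`, and each out-of-state group gets
#' `eps`. Every row sums to 1.
#'
#' @param spec an [hmm_spec()].
#' @return K(K+1)/2 x K matrix, rows = states, columns = observed group.
#' @export
emission_matrix <- function(spec) {
  K <- spec$K; eps <- spec$eps_csv; N <- spec$N
  states <- spec$states
  S <- ncol(states)
  E <- matrix(eps, S, K, dimnames = list(NULL, spec$groups))
  for (s in seq_len(S)) {
    i <- states[1, s]; j <- states[2, s]
    if (i == j) {
      E[s, i] <- 1 - (K - 1) * eps
    } else {
      if (N[i] + N[j] <= 0)
        stop("heterozygous state with zero total informative density")
      inmass <- 1 - (K - 2) * eps
      E[s, i] <- inmass * N[i] / (N[i] + N[j])
      E[s, j] <- inmass * N[j] / (N[i] + N[j])
    }
  }
  E
}

#' Initial distribution over unordered ancestry pairs
#'
#' Random pairing (Hardy-Weinberg in theta): theta_i^2 for homozygous
#' states and 2 theta_i theta_j for heterozygous ones. The HMM's start
#' state is silent; this distribution applies at the first observation.
#'
#' @param spec an [hmm_spec()].
#' @return probability vector over the state space.
#' @export
initial_distribution <- function(spec) {
  states <- spec$states
  th <- spec$theta
  vapply(seq_len(ncol(states)), function(s) {
    i <- states[1, s]; j <- states[2, s]
    if (i == j) th[i]^2 else 2 * th[i] * th[j]
  }, 0)
}

#' Posterior decoding of one individual's observation sequence
#'
#' Runs scaled forward-backward over the diploid ancestry-pair states and
#' assigns each observation the pair with maximal posterior (ties broken
#' deterministically toward the lower state index).
#'
#' @param obs a `csv_observations` data.frame from [observe_csvs()] (columns
#'   `pos`, `group`), L >= 1; every observed group must be in the spec.
#' @param spec an [hmm_spec()].
#' @return list with `posterior` (L x S matrix, rows sum to 1), `calls`
#'   (data.frame pos, state, anc1, anc2), `loglik`, and `states`.
#' @export
posterior_decode <- function(obs, spec) {
  if (nrow(obs) < 1) stop("need at least one observation")
  o <- match(obs$group, spec$groups)
  if (any(is.na(o)))
    stop("observed group(s) absent from spec: ",
         paste(unique(obs$group[is.na(o)]), collapse = ", "))
  if (is.unsorted(obs$pos)) stop("observations must be position-sorted")
  d <- diff(obs$pos)
  r <- crossover_prob(d, spec$G, spec$lambda)
  E <- emission_matrix(spec)
  eobs <- E[, o, drop = FALSE]           # S x L
  tc <- transition_components(spec$theta, spec$states)
  pi0 <- initial_distribution(spec)
  res <- .fb_decode(pi0, tc$B, tc$C, r, eobs)
  gamma <- res$gamma
  gamma <- gamma / rowSums(gamma)
  call_idx <- max.col(gamma, ties.method = "first")
  states <- spec$states
  list(posterior = gamma,
       calls = data.frame(pos = obs$pos, state = call_idx,
                          anc1 = spec$groups[states[1, call_idx]],
                          anc2 = spec$groups[states[2, call_idx]]),
       loglik = res$loglik,
       states = states)
}

#' Extend per-observation ancestry calls to all variants
#'
#' Every site at or after observation j and before observation j+1 takes
#' call j; sites before the first observation take the first call. The
#' result tiles the span of `positions` as a diploid track.
#'
#' @param calls data.frame with `pos`, `anc1`, `anc2` (from
#'   [posterior_decode()]).
#' @param positions positions of all sites to cover (bp).
#' @param chrom chromosome name.
#' @param individual individual id for the track.
#' @return an [ancestry_track()].
#' @export
extend_calls <- function(calls, positions, chrom, individual) {
  if (nrow(calls) < 1) stop("need at least one call")
  span <- range(positions)
  state <- paste(calls$anc1, calls$anc2, sep = "\r")
  run <- cumsum(c(TRUE, state[-1] != state[-length(state)]))
  first <- !duplicated(run)
  starts <- calls$pos[first]
  anc1 <- calls$anc1[first]; anc2 <- calls$anc2[first]
  starts[1] <- min(span[1], starts[1])
  ends <- c(starts[-1] - 1L, max(span[2], calls$pos[nrow(calls)]))
  ancestry_track(data.frame(chrom = chrom, start = starts, end = ends,
                            individual = individual,
                            anc1 = anc1, anc2 = anc2))
}
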