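---
title: "Local ancestry from continent-specific variants: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local ancestry from continent-specific variants: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lancsv)
```

# The problem

Recently admixed genomes (African Americans, Mexicans, Puerto Ricans, ...)
are mosaics of chromosomal segments inherited from distinct continental
ancestries. Assigning an ancestry pair to every locus — local ancestry
inference — underlies admixture mapping, recombination-rate estimation and
demographic inference. Haplotype-copying methods are accurate but scale
poorly to fully sequenced cohorts. Sequencing, however, surfaces a signal
that genotyping arrays mostly miss: large numbers of rare variants whose
minor allele is observed in exactly one continental group. `lancsv` calls
these continent-specific variants (CSVs) from labeled reference panels and
decodes local ancestry directly from the sequence of CSVs an individual
carries. Only allele frequencies per group are needed from the reference —
no phased haplotype copying, and runtime is linear in the number of
observed CSVs per individual.

# Calling specific variants

For every site and both alleles, an allele is a CSV of group $k$ when its
observed count is at least one in group $k$ and zero in every other group
at the chosen level (`call_csvs()`, level `"continental"`; the same rule at
level `"population"` defines sub-continental population-specific variants,
sCSVs). Consequences we enforce and test:

* both alleles at a site can qualify independently (a fixed difference
  yields a ref-allele record for one group while the alt allele, present in
  the remaining groups, yields none);
* records are per allele, so at most one record per (site, allele);
* a group with zero haplotypes is a hard error — absence cannot be
  asserted from nothing;
* the presence threshold is count $\ge 1$ by definition; `min_count` is
  exposed for robustness experiments only.

Because panels are finite, some alleles are called specific although a
larger sample would reveal them elsewhere — *spurious* CSVs. Their rate is
measured by `estimate_density()`: each haplotype of group $k$ is held out
in turn, variants are re-called, and the carried group-$j$ alleles are
counted per megabase. The diagonal of the resulting matrix is the
informative density $N_k$ (expected own-group CSVs per haplotype per Mb),
the off-diagonal mass the spurious rate. When a disjoint evaluation panel
is available it is used instead of leave-one-out; leave-one-out is the
self-contained default.

# The hidden Markov model

Each individual is decoded independently. Hidden states are the unordered
ancestry pairs $\{A_i, A_j\}$, $i \le j$ — $K(K+1)/2$ states for $K$
groups. The observation sequence (`observe_csvs()`) is the position-ordered
list of sites where the individual carries at least one copy of a specific
allele, each tagged with the allele's source group. Carriage is collapsed
to one observation regardless of copy number: the emission model is
defined over the identity of the observed variant, and a diploid
homozygous carrier gives no extra information about *which* chromosome
carries it. Missing genotypes yield no observation.

**Transitions.** Recombination between consecutive observations separated
by $d$ bp is a Poisson process with intensity $d\,G\,\lambda$, so the
probability of at least one crossover is $r = 1 - e^{-dG\lambda}$
(`crossover_prob()`). Each chromosome switches independently with kernel
$T(a \to b) = (1-r)\,\mathbf{1}[a=b] + r\,\theta_b$ — at a crossover the
new ancestry is drawn from the admixture proportions $\theta$, so a
crossover is not necessarily an ancestry switch. The diploid transition
matrix is the product of two haploid kernels collapsed to unordered pairs
(off-diagonal targets receive both ordered realizations); we generate it
as $T(r) = (1-r)^2 I + r(1-r)B + r^2 C$ with constant matrices $B$, $C$
precomputed from $\theta$, and verify it in tests against an exhaustive
enumeration of ordered pairs rather than transcribing per-cell formulas.

The default $\lambda$ is $10^{-15}$ per bp per generation — deliberately
seven orders of magnitude below the biological $10^{-8}$ used by the
simulator. Nearby CSVs are strongly linked; with a biological switching
rate a short run of linked discordant variants can force a state change.
The damped rate prices a switch at roughly three consistent discordant
observations, which suppresses linkage artifacts while long ancestry
tracts still supply overwhelming evidence. Both rates are exposed
(`lambda_hmm`, `lambda_sim`) and deliberately distinct.

**Emissions** are constant per state. In a homozygous state
$\{A_k, A_k\}$ the observation is $A_k$ with probability
$1-(K-1)\varepsilon$ and any other group with probability $\varepsilon$
each, the spurious-CSV rate ($\varepsilon = 10^{-5}$ by default). In a
heterozygous state $\{A_i, A_j\}$ the in-state mass $1-(K-2)\varepsilon$
is split as $N_i : N_j$ — with both ancestries present, own-group CSVs
arrive in proportion to the informative densities. We apply
$\varepsilon$ *per non-compatible group* (so the homozygous match mass is
$1-(K-1)\varepsilon$); fixing instead the total mismatch mass at
$\varepsilon$ differs at $O(\varepsilon)$ and would change nothing at the
default magnitude.

**Decoding.** The start state is silent; the first observation is emitted
from the random-pairing (Hardy–Weinberg in $\theta$) distribution
$\theta_i^2$, $2\theta_i\theta_j$. We run scaled forward–backward (in
C++), which is underflow-free by construction — the per-step scale factors
sum to the log-likelihood — and is exercised in tests at $10^5$
observations. Each observation gets the posterior-mode pair; ties break
deterministically toward the lower state index. Calls are extended to all
variants by inheriting the preceding observation's call (sites before the
first observation take the first call), giving a diploid track that tiles
the chromosome (`extend_calls()`). An individual with zero observations
falls back to the prior-mode state for the whole span. Viterbi decoding is
intentionally not provided; the posterior-marginal criterion is the one
the accuracy metrics score.

# Sample-aware refinement

Spurious CSVs come from finite panels; the admixed cohort itself is the
cheapest source of additional chromosomes. After decoding, for each group
$k$ and site $i$, the sample frequency $p_{ki}$ is the summed alternate
count over individuals whose extended track is homozygous $k$ at $i$,
divided by twice the number of such calls — excluding sites within 10 SNPs
(in analysis-site order, on the harmonized site set) of an ancestry
transition, where calls are least confident. Reference frequencies are
then updated by the element-wise maximum (`max_update()`): frequencies act
as presence indicators, so sample evidence can create presence (killing a
spurious record of another group, or adding a new specific allele) but
absence in the sample never erases reference presence. Undefined sample
frequencies (no eligible homozygous call) pass the reference through. We
track both alleles' frequency matrices so ref-allele records update
symmetrically.

Variants are re-called from the updated frequencies and the cohort is
re-decoded; `n_iter = 4` rounds by default, matching the point at which
accuracy gains become negligible, with an early stop when the variant set
stops changing. There is deliberately no convergence tolerance on the
frequencies themselves — the iteration count is the contract. Hard calls
(not posterior-weighted) feed the update; `update_from_provided_tracks()`
runs a single update from externally supplied tracks (e.g. consensus calls
of other methods) for held-out-cohort designs.

# Low-coverage sequencing

With read counts $(\mathrm{ref}_i, \mathrm{alt}_i)$ instead of genotypes,
presence of an allele is decided by the posterior-mean genotype dosage
(`genotype_dosage()`). The prior is Hardy–Weinberg at the
admixture-weighted frequency $\bar p_i = \sum_k \theta_k p_{ki}$
(`weighted_freq()`, using current-iteration frequencies so low-coverage
mode composes with refinement); the likelihood is binomial with per-read
alt probability $\varepsilon_s$, $0.5$, $1-\varepsilon_s$ for $g = 0, 1,
2$ and $\varepsilon_s = 0.01$ by default. With zero reads the dosage is
exactly $2\bar p_i$. The alternate allele is called present when
$d_i > \tau$ with $\tau = 0.6$; ref-allele presence uses the mirrored
threshold $2 - d_i > \tau$. Observations then proceed exactly as with hard
genotypes.

Using pooled Hardy–Weinberg as the prior ignores the Wahlund effect
(sub-populations at different frequencies reduce heterozygosity relative
to the pooled expectation). `wahlund_probs()` quantifies the worst case:
for an allele at 5% in one population and absent in the other at 50%
admixture, the heterozygote probability is 0.0475 unmixed versus 0.04875
pooled — a gap of 0.00125, negligible against the binomial read noise, and
CSV frequencies are almost always far below 5%.

**Threshold calibration.** The false-positive rate (presence called in a
true non-carrier) is measured by Monte Carlo (`presence_fpr()`): weighted
frequencies are drawn log-uniformly (density $\propto 1/f$) on
$[5\times10^{-4}, 0.05]$. We chose this spectrum, rather than a uniform
draw, because specific variants are overwhelmingly rare — 5% is the upper
tail of their frequency distribution, not a typical value; the lower bound
is a singleton frequency in a panel of ~200 haplotypes scaled by a small
admixture weight. Under these conditions the FPR at $\tau = 0.6$ stays
below 0.0025 at every coverage from 1× to 30× (worst near 1–2×, where a
single error read at the rare-allele ceiling can clear the threshold). The
companion false-discovery rate (fraction of presence calls from
non-carriers) falls steeply with coverage and is below 0.2 from 2× up; at
exactly 1× it measures ≈0.21 under this stand-in spectrum — the quantity
is sensitive to the assumed frequency distribution, and the FPR bound is
the one we treat as the contract. Both rates can be recomputed per-site or
per-observation from the returned flags.

# Sub-continental ancestry

sCSVs are called with the same rule at population level, so sCSV sets are
pairwise disjoint by allele, and any continental CSV whose group contains
a single population is also that population's sCSV. `loo_profile()`
produces the held-out carriage matrix (row-max-normalized for display);
`segment_sweep()` assigns random held-out segments of 0.05–30 Mb to the
population with the strictly maximal sCSV count. Ties and zero-count
segments are scored "unassigned" and count as errors, with their fraction
reported separately — with ten populations, random guessing scores 10%, so
unassigned-as-error keeps the baseline honest. (The upper end of published
segment ranges for this design varies between 0.05 and 0.1 Mb at the
short end; the default here is 0.05 Mb and both are one `min_mb` argument
away.) Continental accuracy is computed by rolling assignments up through
the population→group map, and is never below population accuracy on the
same segments. Diploid sub-continental decoding needs no separate engine:
a population-level table feeds `infer_ancestry()` unchanged.
`enrichment_counts()` counts sCSV carriage per Mb per haplotype inside
homozygous continental regions of an admixed cohort, the design used to
localize which source population an admixture component resembles.

# The simulator and what passing tests mean

`generate_synthetic_panel()` draws site positions uniformly on one
chromosome; private sites carry their allele only in the designated group
at a frequency uniform in a configured range, shared sites draw
independent per-group frequencies. Haplotypes are sampled independently
per site: there is **no linkage disequilibrium** by design. The generative
truth (site types, true frequencies, spurious flags) rides along as an
attribute, so parameter-recovery tests compare against construction, not
against a second inference. A `spurious_fraction` marks private sites
whose allele truly segregates in other groups; reference panels are
sampled with those carriers masked (the finite-panel artifact made
explicit) while cohort panels sample the full truth — this is how the
refinement tests know exactly which records are spurious and which
individuals can expose them.

`simulate_admixed()` builds each haploid by a random walk: exponential
inter-crossover distances with mean $1/(\lambda G)$ bp ($\lambda =
10^{-8}$), ancestry redrawn from $\theta$ at each crossover, a source
haplotype drawn uniformly from that group; haploids are paired into
diploids, each haploid used exactly once. Crossovers are laid down on
physical distance at constant rate — no genetic map, no interference. The
raw exponential draws are returned for distributional checks because the
track segments are right-censored at the chromosome end (and keeping only
complete segments would be length-biased). Reads are Poisson depth with
binomial alt counts as above. Everything is bit-reproducible from (spec,
seed).

Default study conditions used across the test suite: admixture presets
$\theta_{EUR:NAM:AFR}$ = 0.2/0.0/0.8 with $G=6$ (African-American),
0.45/0.5/0.05 and 0.67/0.13/0.2 with $G=15$ (Mexican, Puerto Rican);
informative densities in the recovery scenario tuned to ≈(16, 11, 123)
variants/Mb/haplotype for EUR/NAM/AFR — the magnitudes seen between
continental panels, African diversity dominating — via site densities
$D_k = N_k / \mathbb{E}[f]$ with $f \sim U(0.05, 0.25)$. The end-to-end
scenarios run 50 diploids over 20 Mb (recovery) and 30 diploids over 10 Mb
(refinement); these sizes give stable metrics while keeping the whole
suite around a minute, and scale linearly for users who want more.

Because the generator has no LD, no genotyping error and no panel
mis-specification beyond the injected spurious fraction, passing tests
demonstrate correctness of the machinery (calling rule, HMM arithmetic,
update logic, metrics) and calibration under the stated generative model —
they do not by themselves establish accuracy on real cohorts, where LD
between CSVs is the main known error source and reference-panel match
matters more than panel size.

# Numerical and design notes

* Coordinates are 1-based inclusive internally (VCF convention); all
  interval output is 0-based half-open (BED convention); round trips are
  lossless.
* Site harmonization is keyed on (chrom, pos, ref, alt); allele-swapped
  records are flipped ($g \to 2-g$) or dropped per `on_swap`,
  deterministically. Sites absent from the reference are dropped — they
  cannot be specific variants under the panel and carry no signal in this
  model. A/T and C/G sites are strand-ambiguous and filtered.
* Missing genotypes are a distinct state: no observation, never zero.
* Forward–backward is scaled linear-space; posterior rows renormalize to 1
  within $10^{-9}$ (asserted), and the brute-force path-enumeration oracle
  agrees to $10^{-10}$ on all small instances.
* Argmax ties (posterior and segment assignment) break to the lower index
  / "unassigned" respectively, so runs are deterministic.
* $p\bar{}=0$ sites pose no 0/0 hazard: the dosage denominator always has
  prior mass on some genotype.
* Metrics: the scalar $r^2$ for $K$-way ancestry is the squared Pearson
  correlation of per-ancestry diploid dosages across individuals, averaged
  over ancestries with $\theta_k > 0$ and then over SNPs — for $K > 2$ a
  scalar correlation is otherwise undefined, and correlating the ancestry-
  pair index was rejected as non-ordinal. Zero-variance SNP-ancestry cells
  are excluded and counted, not scored 1. Haploid accuracy scores each
  cell by the best pairing of called to true labels (0, 0.5, 1), so it
  never falls below diploid exact-pair accuracy.
* Switch resolution reports, for each true diploid-state switch, the
  distance to the nearest inferred switch within 500 kb; unmatched
  switches are excluded and counted.

# Known limitations

LD between specific variants is not modeled (the damped $\lambda$ is a
mitigation, not a model); the spurious-emission rate $\varepsilon$ is
uniform across ancestries although spurious rates differ by an order of
magnitude between groups; the simulator's no-LD panels make synthetic
accuracy optimistic; phasing, imputation, liftover and indels are out of
scope; and read counts are the low-coverage contract — BAMs and external
genotype likelihoods are not parsed.
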