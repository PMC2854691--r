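---
title: "Equivalent length, k-mer fluctuation statistics, and the RSD growth model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivalent length, k-mer fluctuation statistics, and the RSD growth model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqlen)
```

## The problem

Counting the occurrences of all $4^k$ DNA words of length $k$ in a whole
chromosome gives an alignment-free global summary of the sequence. Its raw
variance, however, mixes two very different things. A sequence whose AT
fraction $p$ is far from 0.5 necessarily has some words much more frequent
than others — that spread is fixed by composition and carries no
information about how "random" the sequence is. The statistical signal is
what remains after composition is accounted for.

This package implements the stratification that separates the two. Every
k-mer type is assigned to the **m-set** $K_m$ of words containing exactly
$m$ letters from $\{A, T\}$; there are $n_m = \binom{k}{m} 2^k$ types in
$K_m$ and $\sum_m n_m = 4^k$. In a long random sequence obeying intrastrand
parity (A$\approx$T, C$\approx$G — which shuffled genomes satisfy by
construction) every word in $K_m$ has the same expected frequency
$L\,(p/2)^m (q/2)^{k-m}$, so the m-sets are exactly the strata within which
all remaining spread is statistical.

## Variance decomposition and equivalent length

Writing $N_i$ for the count of type $i$, $\bar N = W/4^k$ for the global
mean ($W$ = number of valid windows), and $\bar N_m$ for the mean within
$K_m$, the squared coefficient of variation splits exactly (a parallel-axis
identity):

$$ M^2 = M_{nf}^2 + M_f^2, \qquad
   M_{nf}^2 = \frac{\sum_m n_m (\bar N_m - \bar N)^2}{4^k \bar N^2}, \qquad
   M_f^2 = \frac{\sum_m \sum_{i \in K_m} (N_i - \bar N_m)^2}{4^k \bar N^2}. $$

`decompose_cv()` computes all three; the identity is property-tested to
$10^{-12}$ relative against a brute-force oracle. The *non-fluctuating*
part $M_{nf}^2$ converges with length to a closed-form composition
background (`nf_variance_limit()`) that vanishes at $p = 0.5$; the
*fluctuating* part of a random sequence is nearly Poisson,
$M_f^2 \approx 4^k/L$. The length at which the background overtakes the
Poisson part is the crossover length `crossover_length()`
($4^k$ divided by the background limit): at $p = 0.7$ it is only 316 b for
$k = 4$ and about 2852 b for $k = 6$, far shorter than any chromosome —
which is why biased-composition sequences must never be compared on raw
variances.

Inverting the Poisson relation defines the **equivalent length**

$$ L_e = \gamma \frac{4^k}{M_f^2}, $$

the length of a random sequence with the same fluctuation statistics.
Shuffled controls give $L_e \approx L$; genomes give $L_e$ orders of
magnitude below $L$.

### The factor $\gamma$ and its policies

Because each m-set mean is *estimated* from the same spectrum, the expected
within-set sum of squares under independent-letter sampling is exactly
$(n_m - 1) W \pi_m$ with $\pi_m = (p/2)^m (q/2)^{k-m}$ — one degree of
freedom is spent per m-set. Summing over $m$:

$$ E[M_f^2] = \gamma \frac{4^k}{L}, \qquad
   \gamma = \sum_m (n_m - 1)\,\pi_m = 1 - \sum_{m=0}^{k} \pi_m , $$

which reduces to $1 - (k+1)/4^k$ at $p = 0.5$. This is the package's
`analytic` policy. It deliberately replaces the naive multinomial factor
$1 - \sum_i \pi_i^2$: simulation (300 replicates per condition) shows the
naive factor misses the mean of $L\,M_f^2/4^k$ by 20–25% at $k = 2$, while
the degrees-of-freedom form is within the residual window-overlap
covariance (a few percent at $k = 2$, negligible by $k = 6$).

Two further policies exist. `unity` sets $\gamma = 1$; it is used whenever
equivalent lengths are mapped onto the universal curve, where the factor is
conventionally absorbed. `montecarlo` calibrates $\gamma$ as the mean of
$L\,M_f^2/4^k$ over seeded exact-composition shuffles of the same $(L, p)$.
The Monte-Carlo route matters because the matching-random null is an exact
permutation: its letter counts are frozen, which depresses $M_f^2$ below
any independent-letter theory (at $k = 2$ the mean factor drops from
$\approx 0.74$ to $\approx 0.48$). No closed form for the permutation
factor is attempted; calibration on the null itself forces
$L_e(\text{random}) \approx L$ by construction.

### Estimator variance at small k

The within-m-set sum of squares has roughly $4^k - k - 1$ degrees of
freedom, so the relative SD of a single sequence's $M_f^2$ is about 50% at
$k = 2$, 13% at $k = 4$ and 3% at $k = 6$ — an irreducible property of the
statistic, visible equally in published tables of 50 kb random-sequence
equivalent lengths, whose $k = 2$ SDs are comparable to the means. All
claims of the form "$L_e$ tracks $L$" are therefore tested on the
ensemble-pooled estimate $\gamma 4^k / \overline{M_f^2}$ over seeded
replicates, never on a single draw at $k = 2$.

## The universal curve, $\sigma_f$, and $\chi^2$

Across genomes, equivalent lengths cluster around an exponential law
$L_e^{uc}(k) = A e^{\beta k}$ with $\beta = 0.92$. The package calibrates
$A$ from two anchor values (310 b at $k = 2$, 194 kb at $k = 9$); the two
anchors agree in $\ln A$ to about 0.1%, and `universality_model()` warns
beyond 0.5%. A residual composition correction is known to exist but its
functional form is not recoverable from the published account; the model
therefore exposes it only as a stored parameter (`tau`) and computes on the
$p = 0.5$ curve. The curve is not extended beyond $k = 10$, where
$L_e^{uc}$ approaches usable sequence lengths.

Through the $L_e$ definition (with $\gamma \approx 1$) the curve converts
into a universal SD of the fluctuating part,
$\sigma_f = L / \sqrt{4^k L_e^{uc}(k)}$, against the random-sequence
reference $\sqrt{L/4^k}$ (`universal_sigma_f()`). Modeling deviations as
Gaussian with SD $\sigma_f$ yields the expected fraction of k-mer types
beyond $n_\sigma$ random-sequence SDs (`pvalue_fraction()`); this
reproduces the published fraction table to its printed precision at every
cell except two, which disagree with the same model that fits the rest and
are treated as misprints.

Deviation from the curve is measured by
$\chi^2 = \text{mean}\left[\ln L_e - \ln L_e^{uc}(k)\right]^2$
(`chi_square()`); $e^{\sqrt{\chi^2}}$ is the typical multiplicative
deviation, so 0.18 means agreement within a factor of ~1.6 and 0.43 within
a factor of ~2. The log form is the only one consistent with both published
glosses of those two values.

## The similarity index

For two equal-length windows (or concatenates) the index

$$ \Delta = \frac{1}{4^k} \sum_m \sum_{i \in K_m}
   \frac{(N_i^a - N_i^b)^2}{s_m^2(a) + s_m^2(b)} $$

is computed after scaling both spectra to a common window total. Its
defining calibration: $\Delta = 0$ for identical windows, $\Delta \approx 1$
for independent random windows of the same composition (each squared
difference averages the pooled variance), $\Delta \gg 1$ for
composition-divergent pairs. The published formula is only partially
recoverable, so this normalization — per-m pooled variances, averaged over
all types — is the package's reconstruction, chosen to pin those three
calibration points; it is the largest single reconstruction in the
package. Two numerical choices follow from the calibration: the $s_m^2$ are
*unbiased* ($n_m - 1$) variances, because at $k = 2$ the m-sets hold only
4–8 types and the population form inflates the independent-random mean to
~1.3 (unbiased: ~1.07); and m-sets with zero pooled variance are skipped,
renormalizing by the contributing types (they arise only in degenerate toy
inputs). `similarity_matrix()` applies the index over sliding windows
(defaults: width 25 kb, slide 10 kb, $k = 2$, the published plotting
conventions), and `summarize_similarity()` reports off-diagonal means and a
Welch t test against a reference matrix.

## The RSD growth model

`rsd_simulate()` generates genome-like sequences in three stages:

1. **Init** — `L0` (default 64) iid bases with $P(A) = P(T) = p/2$.
2. **Growth** — repeat: draw segment length $\ell$ uniform on
   $[1, 2\langle d\rangle]$ (capped at the current length $L$), copy the
   segment starting at a uniform position with the whole segment inside the
   sequence (no wrap-around), insert the copy at a uniform site in
   $[0, L]$; stop the first time the length reaches the target. The final
   length therefore lies in $[L_{target}, L_{target} + 2\langle d\rangle)$.
3. **Mutation** — administer exactly $\text{round}(r L)$ substitutions at
   sites drawn uniformly *with replacement*, replacement bases drawn from
   the $p$-biased distribution independently of the original base. A
   replacement may be silent: $r$ counts administered events per site
   (cumulative density), and sampling with replacement matches that
   per-site semantics. Mutations are applied only after growth is complete;
   $r$ summarizes the lifetime mutational load, not a time course.

Growth runs in C++ (the only hot loop: ~2000 string insertions of $O(L)$
each to reach 2 Mb) but draws from R's RNG, so a single seed makes the
whole pipeline bit-reproducible; an R-level replay of the event log is the
test oracle for the C++ path. Tandem duplications receive no special
treatment and deletions, inversions and interleaved mutation are out of
scope by design.

Defaults are the best-fitting parameter set for reproducing the universal
curve with 2 Mb, $p = 0.5$ sequences: `L0 = 64`, `d_mean = 1000`,
`r = 0.73`. Generated equivalent lengths are insensitive to the final
length beyond about 0.5 Mb.

### Batch $\chi^2$ and the ensemble convention

For an ensemble of model sequences, `simulate_batch()` measures $L_e(k)$
per sequence (with $\gamma = 1$) and reports two statistics. The headline
`chi2` first averages $\ln L_e$ over replicates at each $k$ and then
applies `chi_square()` to the five ensemble values — this is the statistic
appropriate to results *averaged over model sequences*, and the one whose
best-parameter value is $\approx 0.18$. `chi2_per_sequence` instead treats
every (sequence, k) pair as a term, additionally absorbing the
replicate-to-replicate dispersion of $L_e$ (dominated by the $k = 2$
estimator noise discussed above); at the best parameters it is roughly
0.29, and it is the analogue of the all-chromosome genomic average, where
each chromosome contributes its own terms. Both are returned so that either
convention can be inspected.

`scan_r()` profiles the ensemble $\chi^2$ over a grid of $r$ at fixed
$(L_0, \langle d\rangle)$. Because mutation happens after growth, the grown
skeletons are independent of $r$: the same seeded skeletons (and the same
mutation seed streams) are reused across the grid — common random numbers,
which cancel skeleton-level noise out of the comparison and sharpen the
argmin at fixed compute. The basin is broad ($\chi^2$ within a factor ~2 of
its minimum for $r \approx 0.65$–0.80) with a clear interior minimum at
$r \approx 0.70$–0.75 for the default grid and 12–20 replicates per point.

### Problem sizes used

The shipped tests and the acceptance script use: 50 replicates of 2 Mb for
the best-set $\chi^2$ (Monte-Carlo SE about 0.02 on the ensemble value);
20 (script) or 12 (tests) replicates per grid point for the $r$ scan over
$r = 0.55, 0.60, \ldots, 0.90$; 20 shuffles per $(L, p)$ condition for the
length-tracking bands at $L \in \{0.1, 0.5, 2\}$ Mb and
$p \in \{0.5, 0.7\}$; and 10 calibration shuffles per Monte-Carlo $\gamma$.
These sizes put every stochastic check at 2 or more standard errors from
its acceptance boundary while keeping the full suite in the minutes range.

## Mutation-rate algebra

Under exponential growth $dL/dt = \lambda L$, `growth_rate()` returns
$\lambda = \ln(L/L_0)/t$ (per Mya). With growth purely by segmental
duplication of mean length $\langle d\rangle$, the per-base SD event rate
is $\rho = \lambda/\langle d\rangle$. Because duplication copies previously
mutated sites (doubling the cumulative count of mutated positions, in
expectation, over the naive integral), the cumulative density relates to
the per-site rate by $\mu = r\lambda/2$; `cumulative_mutations()` closes
the triple via $n_{mut} = (\mu/\lambda) L$ and the round trip
$r = 2 n_{mut}/L$ is exact. Units are fixed to bases and Mya throughout —
mixed Mb/Gb/Gya unit slips are the main practical failure mode of these
formulas.

Scenario values for orientation: a genome growing from 0.2 Mb to 3 Gb over
3.4 Gya gives $\lambda \approx 2.8\times10^{-3}$/Mya; with
$\langle d\rangle = 2$ kb, $\rho \approx 1.35$/Mb/Mya; with $r = 0.73$,
$\mu \approx 0.99\times10^{-3}$/site/Mya — all inside the ranges estimated
independently from sequence comparison.

## What the synthetic data does and does not emulate

The generators provide: iid and exact-composition random sequences
(the matching-random null), planted-duplication composites, and RSD model
sequences. They emulate the global statistical structure that the methods
target — composition bias, duplication-driven fluctuation excess,
homogeneity along the sequence — and they are what all stochastic tests
run on. They do **not** emulate long-range correlations requiring tandem
duplication structure, repeat families, coding constraint, GC isochores, or
real annotation geometry; passing tests demonstrate correctness of the
statistics and the model's internal claims, not biological fidelity of any
particular genome. Survey-scale results over hundreds of real chromosomes
require genome downloads and are out of scope; the tests instead assert
their simulation analogues (duplication shortens $L_e$; $\Delta \approx 1$
for independent shuffles; intra-sequence similarity of model chromosomes
exceeds that of random pairs).

## Degenerate inputs and edge conventions

Non-ACGT characters become N; N-containing windows are skipped and do not
count toward $W$; an all-N sequence has no composition and is an error.
Coordinates are 0-based half-open; concatenates splice in ascending order
without reverse-complementing minus-strand features, and overlapping
annotations are merged before splicing (so no base is double-counted — the
one normalization choice the published account leaves open). A constant
spectrum has $M_f^2 = 0$ and no equivalent length (error, not Inf).
`le_profile()` refuses segment lengths below four times the asymptotic
$L_e$ only when the sequence is actually in the saturating regime (full
$L_e < L/4$); random-like sequences, whose $L_e$ grows with segment length,
are exempt — without that distinction no segment length would ever be
admissible for a random sequence. Growth stops at the first length
$\ge$ target (the alternative strict-inequality reading differs by at most
one segment, immaterial at $\langle d\rangle \ll L$).

## Known limitations

* The m-set stratification assumes intrastrand parity
  ($P(A) \approx P(T)$, $P(C) \approx P(G)$). Real chromosomes satisfy it
  closely, but RSD sequences grown from a very short seed can amplify the
  seed's A/T imbalance (growth is clonal; only mutation restores parity),
  and for such sequences part of the within-m-set spread is compositional
  rather than statistical — their matching shuffles then show
  $L_e < L$. This is a property of the statistic, not a bug; the
  parity-symmetric `exact_composition_sequence()` null is provided for
  controls where exact parity is wanted.
* The $k = 2$ equivalent length is a high-variance statistic everywhere —
  single-sequence values at $k = 2$ should never be interpreted without
  replicates.
* The analytic $\gamma$ ignores window-overlap covariance (a few percent
  at $k = 2$) and does not apply to exact permutations; use the
  Monte-Carlo policy when $L_e(\text{random}) = L$ must hold tightly.
* The similarity normalization is a reconstruction pinned by calibration
  points, not a transcription of the original formula.
* The universal curve's residual composition dependence is exposed but not
  modeled; computations use the $p = 0.5$ curve.
* Canonical (strand-collapsed) counting, RNA/protein alphabets, and
  streaming counting for $k > 12$ are out of scope.
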