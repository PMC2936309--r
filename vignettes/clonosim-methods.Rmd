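---
title: "Modelling karyotype diploidization and admixture in Clonopsis stick insects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling karyotype diploidization and admixture in Clonopsis stick insects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonosim)
```

## The biological problem

The Moroccan stick-insect genus *Clonopsis* is a numerically polyploid
series on the haploid number n = 18: the bisexual *C. felicitatis*
(cn = 36/35, XX/X0), the parthenogenetic *C. gallica* (cn = 54) and
*C. soumiae* (cn = 72), plus two clonal strains of ameiotic, androgenetic
males with cn = 35 and cn = 53. The puzzle is that all these karyotypes
*look* diploid — chromosomes come in morphological pairs — despite being
numerically triploid or tetraploid. `clonosim` implements a quantitative
model of the fast-diploidization hypothesis that explains this: an
"intermediate triploid female" with altered meiosis whose trivalents
segregate 2⇔1, followed by anaphasic restitution of the egg. The package
couples that cytogenetic model to a synthetic generator of dominant AFLP
(Amplified Fragment Length Polymorphism) data and an admixture-inference
stage, so the population-genetic signature the hypothesis predicts
(parental populations plus admixed hybrids) can be studied end to end on
data of known truth.

## The meiosis model

A triploid oocyte I forms 18 trivalents. Each trivalent independently
sends two chromosomes to one pole and one to the other, with either
orientation equally likely — the model's single mechanistic assumption;
nothing in the system suggests an orientation bias, and the exact
probabilities below follow only under fairness and independence. If m of
the n trivalents deliver their doubled complement to the oocyte-II pole,

* m follows Binomial(n, 1/2) (`exact_m_distribution()`),
* the oocyte II carries n + m chromosomes (`segregate()`),
* anaphasic restitution — retention of the second polar body — doubles
  every chromosome, giving an egg with cn = 2(n + m) whose chromosomes
  are all in pairs, hence the diploid look (`apply_restitution()`).

Three egg classes matter (`classify_egg()`):

* **m = 18** (scheme A): cn = 72, uniformly ×4 — the *C. soumiae* class.
  Probability 2·(1/2)¹⁸ ≈ 7.63×10⁻⁴ % counting both concordant
  orientations, since an m = 0 meiosis places the doubled series in the
  other product of the division.
* **m = 9** (scheme B): cn = 54 with 9 groups ×4 and 9 groups ×2 — the
  *C. gallica* class. Probability dbinom(9, 18, 1/2) ≈ 18.5 %, common
  enough that every new triploid female is a credible founder of a new
  strain.
* **m = 0**: cn = 36 uniformly ×2, a diploid-like egg. The source
  hypothesis is silent on this class; we classify it (`"diploid_like"`)
  rather than discard it, and likewise keep all aneuploid classes —
  viability filtering is a reporting decision, not a mechanistic one.

Androgenetic males derive in three ways (`derive_androgen()`): accidental
X loss from a cn = 54 genome (→ cn = 53, always odd, source cn − 1);
mis-segregation of the X trivalent during an otherwise concordant
scheme-A meiosis I with **no** restitution (17 autosomes ×2 + one X →
cn = 35); or direct hybridization producing a diploid X0 male (cn = 35).
The no-restitution reading of the cn = 35 route is an implementation
decision: it is the only arithmetic on n = 18 that yields an odd 35 from
the triploid female.

`simulate_eggs()` draws independent uniformly random segregation patterns
per egg; with the default n = 18 the Monte-Carlo class frequencies are
checked against the exact binomial by a chi-square goodness-of-fit test
(tail bins pooled so expected counts exceed 5).

## Origin scenarios

`make_diploid_hybrid()`, `make_gamete()`, `fuse()` and
`make_triploid_female()` assemble the individuals that feed the meiosis
model, tracking two bookkeeping invariants:

* **mtDNA is strictly maternal.** Every descendant's `mtdna_label` equals
  the founding egg mother's label — including under androgenesis, where
  the egg pronucleus contributes nothing nuclear. This is the signature
  that lets a clade share mtDNA while embodying foreign nuclear genomes.
* **cn arithmetic is conservative.** Syngamy sums the gamete complements;
  single-sperm androgenesis doubles the sperm head (a
  `double_single_sperm = FALSE` switch takes an unreduced diploid sperm
  as-is); multi-sperm androgenesis (stick-insect eggs are polyspermic)
  sums the sperm only.

Pre-, intra- and post-meiotic restitution are deliberately not
distinguished mechanistically: all three produce the same unreduced
diploid gamete, which is the only property downstream code consumes.
Parental genomes are opaque string labels; species- versus race-level
hybridity is expressed only through label distinctness plus the
generator's divergence parameter. Whether the triploid founder arose by
syngamy or androgenesis cannot be decided from the available data, so
both modes are first-class and no default is asserted.

## The synthetic AFLP generator

`sample_parental_frequencies()` draws, per marker, an ancestral
presence-allele frequency from Uniform(0.05, 0.95) and per-population
frequencies from the Balding–Nichols Beta distribution
Beta(p(1−F)/F, (1−p)(1−F)/F), with F the `divergence` parameter.
Defaults mirror the real study's shape: K = 4 parental populations,
195 retained markers, 27–40 diploid-scored individuals, ≤5 % missing
data per retained marker. F = 0.25 encodes well-differentiated but
related populations — the regime the admixture analysis assumes; the
pre-filter missingness of 2 % is our own choice (the study never states
its raw missing rate) picked as typical of scored AFLP gels.

`simulate_matrix()` gives individual i at marker l its `ploidy_scored`
(default 2) allele copies, each of ancestry k with probability
Q_true[i,k] and a presence allele with probability p[k,l]; the dominant
band is seen iff any copy carries presence, so a pure diploid shows the
band with probability 1 − (1 − p)². Scoring everyone as diploid — even
individuals the scenario made triploid or tetraploid — mirrors the
karyotype-based scoring decision of the real analysis; passing
`copy_number` through `true_ancestry()` enables 1 − (1 − p)^c banding
for sensitivity analysis. Markers are unlinked and at linkage
equilibrium; missingness (`inject_missing()`) is completely at random.
What the generator does **not** emulate: fragment-length homoplasy of
co-migrating bands, primer-combination effects, gel-scoring error, and
linkage — so passing recovery tests here demonstrates correctness of the
inference machinery under the model's own assumptions, not robustness of
AFLP practice.

`apply_fragment_elimination()` models unidirectional fragment loss in
allopolyploids by zeroing the eliminated parent's presence frequency at a
random `fraction` of markers (up to 14 % of loci in a single generation
is documented in allopolyploids). `filter_markers()` implements the
dataset rule: markers with **more than** 5 % missing cells are removed —
exactly 5 % is retained.

## Admixture inference

`fit_admixture()` maximizes the admixture likelihood for dominant
diploid-scored data:

$$\log L = \sum_{i,l} \log P(y_{il} \mid Q, p), \qquad
  P(y_{il}=1) = 1 - (1 - \pi_{il})^2, \qquad
  \pi_{il} = \sum_k Q_{ik}\, p_{kl},$$

by EM over the latent per-copy (ancestry, allele) states. With
$a_k = Q_{ik} p_{kl}$, $b_k = Q_{ik}(1-p_{kl})$ and $B = \sum_k b_k$, a
band-absent cell contributes expected ancestry-k copy counts $2b_k/B$; a
band-present cell contributes $2[a_k/(1-B^2) + b_k/(1+B)]$ copies of
which $2a_k/(1-B^2)$ carry presence. Both M-steps are closed-form, so the
log-likelihood is monotone (asserted every iteration). Missing cells are
skipped. Convergence: relative log-likelihood change below 10⁻⁸ or 2000
iterations; `n_init` random starts, winner by log-likelihood, ties by
seed order. Starts use Dirichlet(1) membership rows and allele
frequencies anchored on the pooled closed-form estimate
p = 1 − √(1 − f) (the exact K = 1 MLE, which also serves as an analytic
oracle in the tests) perturbed by ±0.3 per cluster; frequencies are kept
in [10⁻⁹, 1 − 10⁻⁹] for numerical safety. This replaces the original
Bayesian MCMC machinery with a deterministic-per-seed, desk-scale
estimator of the same inference target (Q, p); replicate counts (5 per
K, 10 at the forced K = 2) are retained as independent random starts.

**Selecting K** (`select_K()`). Two rules are computed and compared:

* *Plateau rule on the adjusted likelihood.* The raw maximized
  log-likelihood is non-decreasing in K (the models are nested), so
  "the K maximizing the probability of the data" is only meaningful on a
  complexity-adjusted surface. We subtract the free-parameter count
  d_K = N(K−1) + KL (an AIC-type adjustment, playing the role the
  implicit complexity penalty plays in the Bayesian estimated probability
  of data) and choose the smallest K whose adjusted mean across
  replicates lies within one standard error of the maximum.
* *Evanno's deltaK*: |L(K+1) − 2L(K) + L(K−1)| / sd(L(K)) across
  replicates, defined only at interior grid values; note a linear-in-K
  adjustment cancels in the second difference, so deltaK is identical on
  the raw and adjusted surfaces.

On synthetic data with four well-separated parental populations both
rules recover K = 4. When the two rules disagree — which happens at
small sample sizes, where the likelihood-level plateau is noisy —
`chosen_K` follows deltaK: the second difference is immune to the
monotone rise of the maximized likelihood in K, which is precisely what
defeats likelihood-level rules.

**Assignment.** `assign_individuals()` applies the q ≥ 0.80 rule,
inclusive at the boundary: an individual reaching 80 % membership in its
arg-max cluster is assigned; anything lower is flagged admixed.
`forced_K2_analysis()` reproduces the two-parental-pools re-analysis:
drop a dominating outgroup, fit K = 2 with 10 aligned replicates
(`align_labels()` resolves label switching by minimum-L1 matching of the
allele-frequency tables, exhaustively for K ≤ 8), average the aligned Q,
then assign.

## Pipeline, seeds and problem sizes

`run_pipeline()` chains meiosis → generation → filtering → K selection →
fit → assignment → Jaccard distances, writing CSV/JSON plus a run log.
One master seed drives everything; each stage derives a deterministic
31-bit sub-stream seed, so identical configurations give byte-identical
outputs and stages can be re-run in isolation. Default problem sizes are
the study-shaped ones (27–40 individuals, ~195 markers, K grid 1–8 with
5 replicates, 10⁵ Monte-Carlo eggs); the test suite uses the same shapes
with smaller grids where a property does not need the full design.

## Known limitations

* Orientation bias, chiasma placement, recombination and the 55–57
  chromosome European *C. gallica* variants are not modelled.
* The meiotic-like two-division apomixis described for European
  *C. gallica* is mechanistically unspecified and excluded.
* The EM estimator gives point estimates only — no posterior uncertainty
  on Q, unlike the MCMC it stands in for. Because no prior shrinks Q,
  the maximum-likelihood membership of a truly pure individual has
  appreciable sampling spread at the ~195-dominant-marker scale: a small
  fraction of pure individuals land below the q ≥ 0.80 cutoff and are
  then conservatively labelled admixed. Doubling or tripling the marker
  count removes the effect entirely in our recovery experiments.
* The m = 0 diploid-like egg's biological viability is unknown; it is
  reported, never filtered.
* Tree building, ordination and mitochondrial sequence analysis are out
  of scope.
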