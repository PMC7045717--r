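---
title: "Models and methods behind admixrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind admixrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem

Several admixed populations derive from hybridisation between the same pair
of diverged lineages — some produced by human transport into ports, some by
natural contact, some in the laboratory. Each population has its own overall
ancestry proportions, so allele frequencies cannot be compared directly
across populations. The concordance approach removes the genome-wide
component: a locus is interesting only insofar as its frequency departs from
what the population's *mean* ancestry predicts, and admixture events are
compared through the correlation of those departures. This vignette explains
each model in the package, the defaults, and the choices made where the
design was genuinely open.

# Reference panels and their simulation

The inference operates on biallelic ancestry-informative SNPs with reference
allele frequencies per source lineage, organised in a three-level hierarchy
(species; allopatric lineage; locally introgressed subpopulation). The
simulator generates such panels under the Balding–Nichols model: an
ancestral frequency drawn uniformly on (0.05, 0.95) and, along every branch
of a user-specified lineage tree with divergence parameter F ∈ [0, 1), a
Beta-distributed descendant frequency with the parent's mean and variance
F·p(1−p). Loci are ascertained by rejection until the allele-frequency
difference (AFD) between two designated focal lineages reaches a threshold —
this mirrors how empirical ancestry-informative panels are built, and it is
why F~ST~ computed on such panels is intentionally inflated relative to
genome-wide values. Panels meant to resolve several contrasts at once (as in
the analysis workflow) are unions of pair-ascertained subsets.

Allele orientation is fixed once, before any analysis: at every locus the
counted allele is the one more frequent in the designated focal lineage,
with exact ties broken towards the lexicographically smaller allele label
and flagged. Orientation is applied identically to genotypes and panel, so
re-orientation is a no-op. All downstream quantities (distortions, LD) are
sign-stable only because orientation happens first.

# The forward hybrid-swarm simulator

Hybrid swarms are simulated forward in time with explicit ancestry tracts:

* **Founding.** Each of N diploid founders receives two haplotypes whose
  source lineages are drawn independently from the founding mixture q0;
  haplotype alleles are Bernoulli draws from the source's panel frequency.
  Generation g = 0 returns the founders themselves.
* **Mating.** Discrete generations; monoecious random mating with selfing
  excluded; population size constant at N. The default N = 500 is an
  arbitrary, configurable choice — effective sizes of port populations are
  unknown.
* **Recombination.** Per linkage group, gametes receive a
  Poisson(map length in Morgans) number of crossovers at uniform positions
  — the Haldane no-interference model, consistent with the Haldane mapping
  function used for map construction. Markers without map positions become
  zero-length pseudo-groups, which under this model segregate independently
  (50% recombination), the intended behaviour for "unlinked" markers.
* **Tracts.** Every chromosome copy is a list of tracts labelled by founder
  haplotype, tiling [0, L] without gaps; the label also carries the source
  lineage, so junction counts (ancestry switches) and tract-length-weighted
  true ancestries are exact by construction, and genotypes are read off the
  founder haplotypes — drift and identity-by-descent are therefore fully
  realistic, not approximated by frequency draws.
* **Selection.** Optional per-locus viability coefficients: fitness 1,
  1 + s/2, 1 + s by dosage of the counted allele, multiplicative across
  loci, acting through the probability of being drawn as a parent.
* **Migration.** An optional per-generation fraction of individuals is
  replaced by fresh pure-source migrants (new founder haplotypes), emulating
  continued input from a native lineage.
* **Mitochondria.** One haploid marker inherited from the dam; two-sex
  genetics beyond this maternal marker is out of scope.

The per-generation meiosis is implemented in C++ (the one loop where R-level
overhead dominates) but uses R's RNG throughout, so a fixed seed gives
bit-identical results.

Laboratory crosses reuse the same machinery: F1 = pure × pure; F2 = one F1
dam × five F1 sires (the classic design, with the sire count configurable);
backcrosses in both reciprocal directions. F1 parent genotypes are attached
to cross outputs because the map filters need them.

# Supervised ancestry estimation

Individual ancestries Q are estimated by maximum likelihood with the
reference frequencies held fixed: each non-missing allele copy contributes
log Σ~k~ q~k~ f~k~(allele), and EM with copy-wise responsibilities maximises
this exactly (the log-likelihood is asserted non-decreasing at every
iteration in the tests). This replaces Bayesian admixture clustering with
MCMC for a deliberate reason: with references fixed, the likelihood is the
same, the optimisation is deterministic and fast, and replicate merging
becomes unnecessary. What is lost is the propagation of reference-frequency
uncertainty and the linkage-aware model; dating consequently moves to
admixture-LD decay (below). Reference frequencies exactly at 0 or 1 are
clamped to [10⁻³, 1 − 10⁻³] and flagged so that no genotype has infinite
negative log-likelihood. Individuals whose typed loci cannot distinguish
the sources are returned as uniform Q with a flat-likelihood flag.

Classification without admixture (for assigning individuals to clusters
rather than estimating fractions) is a hard-assignment EM under
Hardy–Weinberg within clusters, with add-½ pseudocounts and deterministic
fixed-point iteration from a given initialisation; emptied clusters are
re-seeded with the worst-fitting individual and flagged.

Hybrid-class posteriors use the fixed expected ancestry-pair proportions of
the six early-generation classes over (AA, AB, BB) per locus, mixing
Bernoulli draws from the two parental frequency vectors. Parental
frequencies are treated as known — their sampling uncertainty is *not*
integrated over, a flagged simplification relative to full Bayesian hybrid
classification; with diagnostic-grade panels the posteriors are sharp
regardless.

Reference sets are purified before panel frequencies are recomputed:
candidates with less than 85% ancestry in their putative cluster are
dropped (removing migrants and recent hybrids), and individuals with more
than 10% ancestry from an excluded sympatric source are removed from the
reduced data set. Both thresholds are arguments.

# Distortions and their comparison

For an admixture event with bound source frequencies f~k~ and mean
ancestries Q̄~k~ (composite ancestries are sums of Q components), the
expected frequency is f_exp = Σ~k~ f~k~·Q̄~k~ and the distortion
D = f_obs − f_exp, with f_obs computed from admixed individuals only and
the mitochondrial marker counted haploid. If the admixed individuals are
draws from the mixture implied by Q̄, E[D] = 0 locus by locus — the null the
tests calibrate against.

Correlations of D between events use Pearson's r over shared non-missing
loci and a two-sided permutation test that shuffles the locus pairing of
one table, with the add-one rule (p is never exactly zero). With eight or
fewer shared loci the permutation distribution is enumerated exhaustively
and the p-value is exact. Two-sidedness is a choice: both positive and
negative correlations are scientifically meaningful (same-direction versus
reversed sorting).

Class-level evidence combines the pairwise p-values with the Empirical
Brown's Method. Fisher's −2Σlog p is calibrated against a scaled
chi-square whose variance is estimated from per-test data vectors pushed
through their empirical CDFs; the data vector chosen for a correlation test
is the element-wise product of the two events' standardised D vectors over
the loci shared by the whole class — the per-locus contribution to that
pair's statistic, which carries the dependence created when one event
appears in several pairs. Under independence the method reduces to Fisher;
under net negative estimated dependence the Fisher scaling is retained, as
in the reference formulation. One property worth knowing: for perfectly
duplicated tests the combined p sits a few percent *below* the single p,
because the finite-sample variance of −2 log(ECDF) undershoots its
asymptotic value of 4; the method prevents double counting but is not
exactly conservative at that corner.

# Geography: least-cost distances and clines

Distances between coastal sites are shortest water paths on a raster of
water (conductance 1) and land (blocked) cells, under 8-neighbour adjacency
with √2-weighted diagonals. A 16-neighbour stencil would reduce
discretisation bias slightly; 8-neighbour was chosen for simplicity, and the
bias is immaterial for the metric properties and toy-geometry checks the
package makes. Sites are snapped to the nearest water cell with the snap
distance recorded and a configurable cap. Transect assembly (which sites,
the inward origin, per-site exclusions) is configuration, not inference.

Clines are fitted in the Szymura–Barton family: a central sigmoid
y = (1 + tanh(2(x−c)/w))/2 with width w the inverse maximum slope, optional
independent exponential tails starting δ away from the centre with
steepness τ, and free scaling to [pmin, pmax]. One subtlety of this
parameterisation: the tail expression governs *everything* beyond c ± δ, so
δ = 0 does not mean "no tail" — a plain sigmoid is an explicit no-tails
variant, which is also the fitting default (tails are fitted on request).
The likelihood is binomial for allele counts and Gaussian on site means for
ancestry clines (SE = sd/√n, pooled sd where n < 3). The MLE uses
multi-start bounded L-BFGS-B on transformed parameters (20 starts by
default), fitting both orientations and keeping the better likelihood;
credible intervals come from random-walk Metropolis (default burn-in 10⁴,
chain 10⁵, proposal scales tuned to 20–40% acceptance during burn-in).

# Linkage map and admixture dating

Map construction is classical two-point F2 mapping. Markers are admitted
only if heterozygous in every F1 parent, with parental AFD ≥ 0.2 and F2
missingness ≤ 10%; Mendelian 1:2:1 segregation is then tested per admitted
marker with Holm step-down control. Recombination fractions come from EM
over the double-heterozygote phase ambiguity (coupling phase is guaranteed
by construction from oriented pure lines), with a LOD against r = 0.5.
Groups are single-linkage components at LOD ≥ 3 and r ≤ 0.35 — conventional
defaults, configurable — ordered exhaustively up to 7 markers and by greedy
seriation with 2-opt refinement beyond, with Haldane positions
d = −½·ln(1−2r) cumulated along the order.

Admixture age is estimated from the decay of admixture LD with map
distance. The composite (Burrows) disequilibrium Δ = cov(X, Y)/2 between
dosage vectors is phase-free and robust to departures from Hardy–Weinberg.
Under a single admixture pulse followed by random mating, the LD between a
pair at recombination fraction c decays by (1 − c) per generation, so
Δ(d) = D0·(1 − c(d))^g with c(d) the Haldane fraction. The package fits
this by least squares (a profile grid over g with the conditionally optimal
D0 in closed form, refined by bounded quasi-Newton), with bootstrap
confidence intervals over individuals. The frequently seen form
D0·e^(−g·d) is the small-distance limit of the same model; it is available
as an option, but over maps extending to a Morgan it underestimates the
retention of LD at large distances and biases g low by roughly 10%, which
is why the Haldane kernel is the default. Fits use signed Δ on oriented
data; an option fits |Δ| instead, which makes the estimate invariant to
per-locus allele flips at the cost of a small positive bias where the
signal is below the noise floor.

This estimator replaces linkage-model-based dating inside a Bayesian
clustering framework: both measure the same quantity — the accumulation of
ancestry junctions per Morgan since admixture — and on simulations with
known age the ALD estimate recovers the truth (coverage is checked at
g = 10 and the fresh-admixture limit at g = 0). Dating assumes neutrality
and no ongoing gene flow; continued migrant input or selection against
recombinants biases the estimate towards more recent times, so field
estimates are lower bounds in that sense.

# Numerical choices

* Permutation p-values use the add-one rule everywhere; exhaustive
  enumeration replaces sampling at ≤ 8 shared loci.
* Reference-frequency clamp ε = 10⁻³; no-admixture cluster frequencies use
  add-½ pseudocounts.
* Orientation ties break towards the lexicographically smaller allele label
  and are flagged; re-orientation is idempotent.
* Missing-data filtering is loci first (10%), then individuals (30%) over
  retained loci; the order is fixed and documented, and the filter commutes
  with row/column permutations.
* Monomorphic loci: HWE p = 1 (flagged); F~ST~ loci with zero
  denominator components are excluded from the ratio of sums.
* r estimates are clamped to [10⁻⁶, 0.5]; Haldane transforms cap r at 0.49
  to keep positions finite.
* Bootstrap CIs are percentile-based and widened, if necessary, to contain
  the point estimate.

# What the simulations do and do not show

The generator reproduces the *mechanics* of replicated admixture: shared
founding history (one pool sampled into several populations), independent
admixture on different backgrounds, recombination-driven decay of LD and of
hybrid-class structure, maternal mitochondrial transmission, viability
selection at chosen loci. Validation on it therefore demonstrates that the
estimators recover known ancestries, ages, cline geometries, map partitions
and selection targets under the stated conditions, and that the null
calibrations (distortion means, permutation and HWE p-values) are correct.

It does not emulate: selection arising from intrinsic incompatibilities or
local adaptation (so positive distortion correlations between *independent*
simulated events — the field signature of parallel selection — have no
synthetic counterpart; only shared-history correlation is generated);
genotyping error; ascertainment from a finite real SNP discovery panel;
age-structured, overlapping generations; real coastal geometry. Passing
tests consequently validate the machinery and its calibration, not any
biological claim about real populations.

Validation problem sizes were chosen to make truth recovery measurable at
desk scale: swarms of N = 500–1000 for 8–10 generations with 76-locus
panels, 100-replicate null calibrations, 50-replicate power and coverage
checks, 114-offspring F2 designs on five 50-cM linkage groups (dense enough
that marker admission filters leave no gaps larger than the grouping
threshold), and 15-site transects with 50 individuals per site. Map-partition
recovery is validated on fully informative intercross markers — the
convention of linkage-simulation tools — which isolates grouping and
ordering from panel informativeness; the admission filters that handle
partially informative markers are validated separately.

# Known limitations

* Supervised EM treats reference frequencies as exact; with small reference
  samples the Q estimates are overconfident.
* The hybrid-class posterior shares that simplification and considers only
  the six two-generation classes.
* Single-linkage grouping can merge linkage groups through one spurious
  low-r̂ pair at small sample sizes; at n = 114 this occurs in a few percent
  of replicates.
* ALD dating assumes a single pulse; continuous admixture yields an
  effective (more recent) age.
* The cline tail parameterisation matches the standard family in shape, but
  exact numerical equivalence with any particular fitting package's
  internal transforms is not attempted; the model is validated on its own
  simulated data.
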