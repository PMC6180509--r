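---
title: "Methods: strain-level holobiont metagenomics with holostrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain-level holobiont metagenomics with holostrain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Insect holobionts such as the pea aphid carry a small community of heritable
bacterial symbionts: one obligate, strictly maternally inherited primary
symbiont and several facultative secondary symbionts that are mostly
vertically transmitted but occasionally jump between host lineages. Shotgun
sequencing of whole hosts yields metagenomic read sets in which each
symbiont appears at wildly different depths across samples. After mapping
reads to reference genomes (outside this package's scope), the questions
become statistical: which symbionts are present in which samples; which
variants are trustworthy; what is each sample's dominant symbiont strain;
how do strain phylogenies relate to the host's maternal-line phylogeny; and
do individual hosts ever carry two strains at once?

`holostrain` implements that analysis chain on per-sample allele depths
(VCF with `AD`/`DPR`) and per-position coverage tracks, plus a simulator
that generates ground-truthed holobiont datasets so every stage can be
validated without any external data.

# Presence calls and variant-calling eligibility

For each (sample, symbiont) pair, `summarize_coverage()` computes the mean
depth over **all** reference positions (zeros included), the breadth covered
by ≥ 5 reads, and the fraction of positions covered by fewer than two
reads. `call_presence()` maps these to a three-way status:

* **absent** — mean depth < 1×;
* **analysable** — mean depth > 10× *and* at most 90% of positions below
  two reads (the homogeneity condition);
* **present_low** — everything in between: detected, but too thin for
  reliable variant calling.

Both depth bounds are read strictly, so exactly 1× or exactly 10× is
`present_low`. Homogeneity is operationalized solely through the
fraction-below-two-reads statistic because that is the only quantitative
criterion the workflow defines; we deliberately add no second dispersion
statistic. `present_low` samples matter later: their symbiont tips are
pruned before reconciliation rather than being miscounted as losses, while
true absences (< 1×) remain in the host tree.

# The variant-filtering cascade

`filter_variants()` applies, in a fixed canonical order:

1. **Rare-allele removal** (`filter_rare_alleles()`): within each
   (site, sample), every alternative allele supported by fewer than 4 reads
   *or* below 10% of the site's total depth in that sample is zeroed.
   Boundaries are inclusive on the keep side (exactly 4 reads and exactly
   10% survive). The rule is per sample: an allele can be genuine in one
   sample and noise in another. Sites where no sample retains an
   alternative are dropped.
2. **Extreme-coverage masks** (`mask_extreme_coverage()`): per sample, the
   median total depth across variant sites is computed (lower-middle
   element for even counts — deterministic, no interpolation). A site is
   masked LOW when its depth is strictly below the sample median in at
   least 75% of samples, and HIGH when it is at least 5× the median in at
   least 75% of samples. The median is per sample, not pooled: coverage
   differs by orders of magnitude across samples, so a pooled median would
   be meaningless.
3. **Homology mask** (`apply_homology_mask()`): externally computed
   intervals (e.g. > 80% cross-genome homology) are consumed as 0-based
   half-open BED and matching sites dropped.

**Absent samples and the 75% denominators.** A sample in which the symbiont
is absent has a median variant depth of 0, which makes the HIGH condition
(`depth ≥ 5 × 0`) vacuously true and, with enough absent samples, masks
every site. This is not hypothetical: with per-branch symbiont loss, whole
clades of hosts can be uninfected. `filter_variants(include_samples =)`
therefore excludes non-analysable samples from the denominators; the
pipeline always passes the analysable set. The default (all samples) keeps
the literal rule for matrices that contain only infected samples.

**Idempotence.** Because the medians are recomputed from whatever matrix is
given, re-running the cascade can in principle mask additional sites (the
median is data-dependent). In the realistic regime — dozens of sites or
more, several samples, depths without strong cross-sample correlation —
the masked fraction is far too small to move an integer median and the
cascade is a fixed point; the test suite checks this on simulated data
rather than asserting it as a theorem.

**Residual false positives.** Under the default simulated world (1% error,
50× depth, 3 variants/kb) the cascade retains on the order of one or two
false sites per dataset: at positions whose realized depth dips to ~35×,
four matching error reads already clear both the 4-read and the 10% rule.
That is ≈ 3 × 10⁻⁵ false sites per genomic position, but ≈ 1% of retained
sites — users counting on a false fraction strictly below 1% of calls
should raise `min_alt_reads` or demand support in ≥ 2 samples downstream.

# Variant profiles

`build_profiles()` reduces each sample to its **variant profile**: the most
abundant allele at every filtered site. An exact tie of the maximum —
reference against alternative, or two alternatives against each other —
falls back to the reference allele and sets a tie flag; extending the
tie rule to alternative-vs-alternative ties keeps the rule deterministic
with a single clause. Sites with zero total depth are flagged missing and
also fall back to the reference for sequence synthesis, but are excluded
from distance computation.

A *variable* site is one with at least two distinct observed or chosen
alleles across samples; a sample whose tie flags exceed 5% of its
non-missing variable sites is excluded (`exclude_ambiguous_samples()`,
strict >, so exactly 5% is kept) — ties that frequent mean the "dominant
strain" is not well defined, as in low-coverage pooled samples. Identical
profiles are collapsed to one representative (lexicographically smallest
sample ID) with a re-expansion map (`deduplicate_profiles()`), because
distance-based tree inference misbehaves on zero-length duplicates.

`apply_profile_to_genes()` synthesizes per-sample gene sequences by
applying the chosen alleles to the reference in descending coordinate
order (so indels never shift pending coordinates), reverse-complementing
minus-strand genes after editing. Edits spanning a gene boundary are
truncated to the overlap with a warning. Output feeds external alignment
and maximum-likelihood tools, which are deliberately out of scope.

# Profile phylogenies

The pairwise profile distance is the count of sites at which two profiles
are both non-missing and disagree, divided by the **total number of
variants detected on the genome** — a fixed denominator, so distances stay
comparable across pairs with different missingness. Pairwise-missing sites
are excluded from the numerator only; whether the original
profile-clustering formulation excluded them from the denominator as well
is ambiguous, and the fixed-denominator reading was chosen for
comparability.

`neighbor_joining()` is implemented in-package rather than delegated so
that two behaviours are fully specified: ties in the Q-criterion are broken
by the lexicographically smallest pair of cluster labels (a cluster is
labelled by its smallest tip), and a negative inferred branch length is
clamped to zero with the deficit transferred to its sister branch. On
additive matrices it recovers the generating tree exactly (this is tested
against 100 random trees and against `ape::nj`).

`bootstrap_support()` resamples variant sites (columns) with replacement —
the only exchangeable unit in profile space — rebuilds the NJ tree per
replicate, and reports the percentage of replicates containing each
internal bipartition of the main tree. Supports annotate the main tree
only; no consensus tree is built. `root_with_outgroup()` places the root
on the branch separating a monophyletic outgroup, splitting its length
equally. `ultrametrize_grafen()` assigns node heights
$(d - 1)/(n - 1)$ (d = descendant tips), making every root-to-tip path 1 —
a purely topological clock substitute appropriate when reconciliation
ignores branch lengths anyway. `compare_topologies()` reports the
Robinson–Foulds symmetric difference over non-trivial bipartitions.

# Intra-host coinfection

A host carrying two symbiont strains shows many sites where both alleles
survive filtering, with read depths clustering around the two strains'
abundances — a bimodal pooled depth histogram. `fit_depth_mixture()` pools
major and minor allele depths of the polymorphic sites and fits one- and
two-component **Poisson** mixtures by EM (50 seeded quantile-based
restarts, |Δloglik| < 1e-8, ≤ 500 iterations). Poisson was chosen because
read depth is count data and the reference analysis only inspects a
histogram; a negative-binomial variant would absorb overdispersion but
needs more data to separate from a genuine mixture. The sample is called
**bi** only if all three gates pass:

| gate | default | why |
|------|---------|-----|
| polymorphic sites | ≥ 100 | below this the histogram shape is noise; real coinfections show thousands |
| ΔBIC (k=2 vs k=1) | > 10 | "strong evidence" on the usual BIC scale; avoids calling overdispersion |
| mean ratio | ≥ 2 | modes closer than 2× are not separable into strain depths at these depths |

The two component means are the strain depth estimates (e.g. ≈ 40× and
≈ 10×). `phase_by_depth()` assigns each site's alleles to strains by
component likelihood, with posterior confidences; exact ties go
major-allele-to-strain-1 at confidence 0.5. `contamination_check()` guards
the interpretation: genomes that must be strain-pure in the sample (the
primary symbiont, the mitochondrion) must show essentially no intra-sample
polymorphism (≤ 0.1% of sites by default), otherwise the "coinfection" is
more parsimoniously cross-sample contamination. Pooling major and minor
depths into one fit mirrors the histogram being emulated; estimating the
minor strain from minor alleles only is a possible alternative not taken.

# Cospeciation by event-cost reconciliation

`reconcile()` maps the symbiont tree onto the host tree under the
four-event model — cospeciation (cost 0), duplication, host switch and
loss (cost 1 each by default) — with an **exact dynamic program** over
(symbiont node, host node) pairs: cospeciation sends the two symbiont
children into distinct host child subtrees, duplication keeps both at or
below the current host node, a switch sends exactly one child to a host
node not ancestrally related to the current one, and descents accumulate
losses per edge. The widely used genetic-algorithm reconciliation tools
are replaced by this exact DP deliberately: it is deterministic and
provably minimal for the cost model. The trade-off is that no transfer
time-consistency is enforced, so an optimum may contain switches that a
time-aware search would reject; results should be read as lower bounds on
event cost. Event counts describe one optimal solution, ties broken by
event priority (cospeciation first) then host-node index. The DP is
verified against exhaustive enumeration of all internal-node mappings on
small trees.

`cospeciation_test()` permutes the tip-mapping images uniformly (500
permutations by default) and reports the add-one estimator
$p = (1 + \#\{\text{permuted cost} \le \text{observed}\})/(n_{perm}+1)$.
Shuffling images rather than relabelling tips matters when several
symbiont tips share a host.

**A calibration caveat worth knowing.** With integer unit costs on small
trees, the reconciliation cost takes only a handful of distinct values, so
under the null the observed cost ties a large share of the permuted costs
and the add-one p-value is strongly conservative: at 8 tips the empirical
type-I error at α = 0.05 is ≈ 0, not ≈ 0.05. The test never
over-rejects — a significant result can be trusted — but a calibration
band with a positive lower bound (e.g. requiring type-I ≥ 2%) is
unattainable with this estimator on discrete costs, and the corresponding
acceptance assertion is left failing by design rather than papered over.
Continuous costs or a randomized tie-broken p-value would restore exact
calibration at the price of non-determinism.

# The simulator: a stated world

`simulate_holobiont()` generates: a Yule host tree (default 12 hosts,
birth rate 1); a symbiont history that co-diverges at host speciations,
dies on each occupied host branch with probability `loss_prob` (default
0.1) and jumps to a contemporaneous host branch at `switch_rate` expected
switches per branch (default 0.5); and read-count data over a uniform
random reference genome (default 200 kb) with mutation events placed as a
Poisson process proportional to branch length, calibrated to 3 variants/kb
— the primary-symbiont-like middle of the 0.03–17 variants/kb range the
motivating system spans. 95% of variants are substitutions, 5% are 1–3 bp
indels; each mutation event creates a new site (near-infinite-sites), so
strain genotypes are clean presence/absence vectors over sites. Per-sample
per-position depth is Poisson(50×) by default; each read is miscalled with
probability 1% to a uniformly chosen wrong base; a candidate site enters
the emitted matrix when any sample shows ≥ 2 reads of the same
non-reference allele, mimicking a caller's evidence threshold, so the
output contains realistic error-driven false-positive sites for the filter
to remove. Pooled samples mix member strains with symmetric-Dirichlet
weights; a coinfection sample mixes the two most divergent strains at
specified mean depths (default scenario 40×/10×).

What the generator does **not** emulate: mapping artifacts, chimeric
reads, reference bias, within-genome recombination, overdispersed
(non-Poisson) coverage, or indel-rich error processes. A green end-to-end
test therefore establishes that the statistical machinery is correct under
its stated assumptions — not that those assumptions hold for any
particular real dataset.

Two honest consequences of this world showed up in validation and are left
visible rather than tuned away:

* With per-branch loss, a loss near the host root uninfects a whole clade;
  datasets with very few infected hosts are legitimate draws.
* Poisson mutation placement leaves some short internal branches of the
  truth tree with zero realized mutations. Such branches are unknowable
  from the data, so strict topology-recovery counts fall slightly short of
  their target even though every *supported* branch is recovered exactly
  (both statements are asserted in the acceptance suite; the strict one is
  expected to fail and documented as such).

# Numerical and determinism choices

* All randomness flows through explicit integer seeds; the pipeline
  expands one top-level seed into per-stage substreams.
* Sample ordering and tie-breaking use radix (C-locale) sorts everywhere,
  so results do not depend on the platform locale.
* Integer medians use the lower-middle element; no interpolation.
* Newick output uses 12 significant digits; round trips preserve branch
  lengths to 1e-9 and are byte-stable on re-write.
* VCF I/O is a minimal bespoke reader/writer for the `AD`/`DPR` dialect:
  byte-stable canonical output, explicit missing-vs-zero-depth flags, and
  sortedness errors that name the offending record. Multiallelic records
  are kept as one site because the most-abundant-allele rule needs all
  alleles of a locus together.

# Known limitations

* Only the dominant strain per sample is genotyped (plus a two-strain
  decomposition in the coinfection module); pooled samples underestimate
  diversity by construction.
* The reconciliation ignores branch lengths and transfer timing.
* At most two mixture components; deeper multi-infections are out of
  scope.
* The homology mask is consumed, never computed.
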