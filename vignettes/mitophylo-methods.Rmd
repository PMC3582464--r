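---
title: "Methods and design of mitophylo"
author: "mitophylo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of mitophylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitophylo)
```

## Scope and scientific setting

`mitophylo` implements the desk-side analysis workflow used in
phylogeographic studies of human mitochondrial DNA, organised around the
North African haplogroups M1 and U6. The mitochondrial genome is a
16,569-bp, effectively haploid, non-recombining molecule; its matrilineal
genealogy can therefore be reconstructed from shared derived mutations,
dated with a molecular clock, and compared across geographic regions and
language families. The package covers: a reference model with per-site
mutation classes; the variant nomenclature used on published haplogroup
trees; median-joining networks and rooted clade trees; rho-based
coalescent dating; regional frequency tables; FST / geography / language
Mantel tests; classical skyline reconstruction of effective population
size; and a coalescent simulator that generates all the inputs needed to
validate the rest.

## The reference model

All coordinates are 1-based positions on the standard (rCRS) coordinate
frame. The control region spans positions 16024–16569 and 1–576, with the
first hypervariable segment (HVS-I) at 16024–16400 and HVS-II taken as
57–372. The gene annotation (13 protein genes, 22 tRNAs, 2 rRNAs,
including the light-strand genes and the known overlaps such as
ATP8/ATP6 and ND4L/ND4) is shipped as a plain TSV and can be overridden.
Overlapping positions are classified by the first annotated record, and
the one or two positions of incomplete terminal codons (completed by
polyadenylation in vivo) are conservatively treated as non-synonymous.

The packaged reference *sequence* is synthetic: a fixed, seeded random
sequence on the true coordinate frame, clearly labelled as such in its
FASTA header and filename. All operations — codon extraction, synonymous
versus non-synonymous calls, site pools for the simulator — are computed
from the packaged sequence at run time, so exchanging it for a real rCRS
FASTA via `loadMtReference(fasta = ...)` changes nothing structurally.
What the synthetic sequence cannot provide is agreement with published
per-site classifications of real polymorphisms; tests therefore verify
classification against an independent whole-gene translation oracle
rather than against published site lists.

Every substitution maps to exactly one of four classes: `control`,
`rna_gene`, `synonymous`, `nonsynonymous`. Published trees colour sites
with a three-way scheme in which control and RNA-gene changes are jointly
"non-coding"; the package keeps them distinct because the synonymous
clock must count strictly coding synonymous changes, and folds them
together only for display.

## Variant nomenclature

Tokens follow the convention of published haplogroup trees scored against
a reference: bare positions are transitions (`16126`), a trailing capital
letter marks a transversion (`16182C`), `+index` marks insertions
(`309+2C`), `d` deletions, `!`/`!!` reversals to the ancestral state, and
IUB letters heteroplasmic calls. Parsing is strict (malformed tokens are
reported by name) and formatting is canonical, so parse–format
round-trips are exact. Heteroplasmic calls are stored but excluded from
every count — an ambiguous state cannot be scored as a mutation.

Homopolymeric C-tract positions (303–315, 16180–16195, and the 514–524
AC repeat) are conventionally unreliable: the package drops indels and
run-extending transversions (the `16182C`, `16193C`, `309+2C` family)
inside these windows, but keeps ordinary transitions such as 16189,
which published trees do score. The mask is a config-exposed default
because published legends list examples rather than exact windows.

For population comparisons, `buildAnalysisHaplotypes()` reduces each
sample to coding-region variants plus HVS-I, drops HVS-II (not uniformly
sequenced across studies, so absence there is not informative), and
treats untyped positions as reference-identical — the convention that
makes partially genotyped samples comparable with fully sequenced ones.

## Networks and clade trees

`buildMJNetwork()` implements the median-joining algorithm: the
epsilon-relaxed minimum spanning network over observed haplotypes is
augmented iteratively with quasi-median vectors of linked triplets whose
connection cost is within `epsilon` of the minimum, and superfluous
median vectors (latent nodes of degree at most two, which lie on a
geodesic rather than at a branch point) are pruned. The default
`epsilon = 0` is the common default of network software and reproduces
the perfect phylogeny on compatible data; hypermutable positions
(defaults 150, 152, 195, 16189) receive weight 0.5 so that homoplasy
concentrates where it is biologically expected. Both the weight values
and the site list are exposed because published weighting schemes are
rarely specified precisely.

Reticulations (cycles) represent homoplasy. `resolveReticulation()`
breaks each cycle at the position with the highest background recurrence
count — the network analogue of resolving a loop "on the more frequent
occurrence" of a known recurrent mutation — duplicating that change in
the resulting tree. Ties are broken deterministically towards the lower
position number, with a warning, so outputs are reproducible.

`rootAndLabel()` orients the network away from a chosen root haplotype
and labels every node with the deepest clade whose defining variants are
all present in the node's reference-relative state. Matching against the
absolute state (rather than the root-relative path) keeps labels correct
when the tree is rooted at a non-reference haplotype such as L3.
`assignCladeFromMarkers()` places partially typed samples: a clade must
be consistent with every typed defining position and positively supported
by at least one typed marker of its own stem; deeper clades excluded only
by missing coverage form the ambiguity set, and samples derived for
markers of incompatible branches are rejected as unplaceable.

## Coalescent dating

The rho statistic of a clade is the mean number of mutations from the
clade's root haplotype to each of its samples; its standard error uses
the branch decomposition

\[ \sigma^2 = n^{-2} \sum_{b} n_b^2\, m_b, \]

where \(n_b\) is the number of samples subtended by branch \(b\) and
\(m_b\) its (class-filtered) mutation count. Back mutations count as
events. Two clocks convert rho to years:

* **Synonymous linear clock.** Counts only synonymous coding-region
  changes. The calibration constant is not printed in the source
  material; the package recovers it by a least-squares fit through the
  origin of the packaged published (rho, age) pairs, giving
  `r format(defaultSynonymousClock()@yearsPerSub, digits = 6)` years per
  synonymous substitution, and exposes it for overriding.
* **Corrected whole-molecule clock.** Whole-molecule rates are
  time-dependent because purifying selection progressively removes
  mildly deleterious (mostly non-synonymous) variation. The packaged
  calibration fits a monotone curve through the origin,
  \(\mathrm{age} = a\rho + b\rho^2\) with \(a, b \ge 0\), to the
  published corrected-age pairs; it was validated leave-one-out against
  each published pair. With the correction disabled the clock reduces to
  the long-term rate 1.695e-8 substitutions/site/year over 16,569 sites.
  The quadratic form was chosen over an isotonic fit because the pairs
  are near-linear with ~3% scatter and a two-parameter monotone curve
  extrapolates stably at the deep end of the calibrated range; rho
  outside that range triggers an extrapolation warning.

Confidence intervals apply the clock to \(\rho \pm 1.96\sigma\) (floored
at zero), which brackets the point estimate because both clocks are
monotone. Ages are reported rounded to the nearest 100 years, the
convention of published age tables.

## Population statistics

Frequency tables nest counts by the haplogroup hierarchy (letter/digit
alternation: M1a1 is inside M1a and M1, M10 is not inside M1), with
region rows as sums of member populations and percentages of row sample
size to one decimal.

Pairwise FST is distance-based (a Phi-statistic): an AMOVA variance
decomposition of haplotype mismatch counts over the analysis-haplotype
positions, linearised as FST/(1−FST). The distance-based flavour was
chosen because the haplotypes are sequences; a haplotype-frequency
flavour would discard the mutational distances the data carry. Negative
variance-component estimates truncate to zero; FST = 1 has no finite
linearisation and flags the matrix cell as `NA`.

Geographic distances are great circles on a sphere of radius 6371 km;
language distances are binary (0 within a language family, 1 between),
because the families involved are too divergent to rank. The Mantel test
correlates upper-triangle entries with a one-sided permutation p-value
(sign-matched, with the +1 correction) under simultaneous row/column
permutation, with a seedable permutation stream. Published Mantel
coefficients for these data are not reproducible without the authors'
population coordinates, which were never printed; the package therefore
validates the machinery by calibration (uniform null p-values, exact
identity cases) rather than by matching coefficients.

## Skyline estimation

The classical skyline estimator converts each coalescent interval with
\(i\) lineages and duration \(t_i\) into \(\hat N_e = i(i-1)t_i/2\)
(haploid units, as appropriate for mtDNA — all Ne values in this package
are haploid and would be halved under a diploid convention). The
generalized variant pools consecutive intervals per step, trading
resolution for variance. Bayesian skyline inference (MCMC over sequence
likelihoods) is deliberately out of scope; this module operates on known
simulated genealogies or rho-dated clade trees, which is sufficient to
study estimator behaviour. The published plots' time axes were produced
by pushing rho through the purifying-selection calculator;
`rescaleTime()` reproduces that intent by mapping the genealogy's
mutational depth through the corrected clock so the root rho lands on
the corrected age, with intermediate times mapped proportionally in rho.
A generation time of 25 years converts generations to years.

## The synthetic-data generator

The simulator draws Kingman coalescent genealogies under piecewise
demographies (constant or exponentially growing epochs, haploid Ne) and
drops class-partitioned Poisson mutations on branches, with positions
drawn from the reference's per-class site pools; recurrent hits on a
lineage revert the site, reproducing the "!"-style back mutations of
real trees. Default per-generation genome-wide rates are chosen to match
the clocks the package ships: synonymous 25/7995 per generation (so the
synonymous clock is exactly matched at a 25-year generation),
non-synonymous 0.63 times that (the non-synonymous-to-synonymous ratio
the M1/U6 data show), RNA genes 1.2e-3, and control region 8e-3 (the
hypervariable segments dominate real control-region variation). An
optional purifying-selection knob removes non-synonymous mutations older
than a threshold (default 400 generations, i.e. 10 KYA) with a
configurable probability, reproducing the inflation of apparent rates in
young clades that motivates the corrected clock.

Scenario presets encode the study-shaped situations: `founder_star`
(default 20 lineages radiating from a founder 10,000 years ago, the
pattern of a founder-effect sub-clade), `two_phase_expansion` (Ne 500
beyond 880 generations ≈ 22 KYA, 5,000 to 400 generations ≈ 10 KYA,
50,000 since — two expansion phases bracketing the end of the Last
Glacial Maximum and the Holocene transition), `two_pop_divergence`, and
`null_language`. Each bundle carries a machine-readable truth record.

What the simulator does **not** emulate: heteroplasmy, sequencing error,
C-tract artefacts, rate heterogeneity within a class, population
structure beyond the two-deme scenario, and sampling biases of real
surveys. Passing tests therefore demonstrate correctness of the
estimators under the stated model, not robustness to every property of
real data.

## Problem sizes and numerical choices

The validation suite uses problem sizes chosen to give stable Monte
Carlo behaviour at interactive runtimes: 10,000 replicates for
closed-form coalescent checks, 5,000 × 999 permutations for the Mantel
null calibration, 500 replicates for TMRCA recovery and skyline
recovery (n = 50 tips), and 1,000 replicates for Saillard-interval
coverage. Distance comparisons in the network code use an absolute
tolerance of 1e-9 to keep half-integer site weights exact; median
expansion at fully tied multistate sites is capped at 27 combinations;
deterministic tie-breaks (lowest position, lexicographic edge order,
creation-order median names `mv1, mv2, ...`) make every output
reproducible under a fixed seed.

## Known limitations

* The packaged reference sequence is synthetic; synonymous/non-synonymous
  calls on real data require substituting a real rCRS/RSRS FASTA.
* The corrected clock is an empirical monotone interpolation of
  published pairs, not a mechanistic selection model; outside its
  calibrated rho range it extrapolates with a warning.
* The median-joining implementation targets desk-scale data (hundreds of
  haplotypes); it is not optimised for genome-wide panels.
* Mantel results depend on the grouping and coordinates supplied by the
  user; the package ships no coordinates of its own.
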