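---
title: "Discovering and validating structured mRNA leaders with leaderscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and validating structured mRNA leaders with leaderscout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leaderscout)
```

## The problem

Bacteria commonly regulate ribosomal protein synthesis autogenously: when
a ribosomal protein such as S15 accumulates beyond what ribosome assembly
consumes, the excess protein binds a structured RNA element in the 5'
leader of its own mRNA (`rpsO`) and shuts down further expression.  These
leader structures are astonishingly diverse -- unrelated architectures
have evolved independently in different phyla to solve the same
regulatory problem -- and most bacterial lineages have no characterised
S15 regulator at all.  Finding new ones is therefore a comparative
exercise: harvest the 5' regions upstream of the gene across many
genomes, look for conserved secondary structure supported by
compensatory (covarying) substitutions, refine the candidate against
transcriptomic evidence, and finally validate a representative by
quantitative binding and reporter assays.

`leaderscout` implements that workflow at desk scale, end to end, with a
synthetic-data generator standing in for genome databases and raw
experimental data so that every stage is testable offline.

## The discovery pipeline

### Harvesting leaders

For each genome, the target gene is located in the annotation (with a
six-frame translated Smith-Waterman fallback for unannotated genomes,
BLOSUM62, gap open 11 / extend 1).  The harvested leader spans up to 500
nt 5' of the translation start -- truncated at the 3' end of the nearest
annotated gene on either strand, a deliberately strand-agnostic reading
of "the previous gene", since operon boundaries upstream are
strand-independent in practice -- plus the first 25 nt of the coding
region, reverse-complemented to mRNA sense for minus-strand genes.

Redundant sequences (>90% identity over >70% of the shorter sequence,
from a free-end-gap global alignment scored +1/-1/-2) are removed by a
greedy, order-stable filter, and the survivors are clustered by taxonomy
into groups of at most 100, splitting oversized groups rank by rank.
The identity denominator is aligned columns inside the overlapped
region, and coverage is measured against the shorter sequence -- the
conservative reading of a redundancy rule that is usually stated
ambiguously.

### Structure inference by covariation

Each cluster is aligned progressively (UPGMA guide tree over pairwise
identity distances; profile-profile Needleman-Wunsch merges), and rows
are weighted by the Gerstein-Sonnhammer-Chothia scheme so that clades of
near-duplicates do not dominate the statistics.

The evidence for base pairing is covariation.  For columns $i < j$ with
canonical pairs $\{AU, UA, CG, GC, GU, UG\}$, the pair score is

$$ s(i,j) \;=\; \sum_{a,b} w_a w_b \, h_{ab} \;-\;
   \phi \cdot \Pr_w[\text{gap or non-canonical}], $$

where $h_{ab} \in \{0,1,2\}$ counts the positions at which the canonical
pair types of rows $a$ and $b$ differ, and $\phi$ (default 1.0) charges
rows inconsistent with pairing.  Column pairs are also annotated with
weighted mutual information (0--2 bits) and a class: *covarying* (two
canonical types differing at both positions), *compatible* (types
differing at one), *conserved* (one invariant canonical type carrying at
least 75% of the weight), or *rejected*.  A Nussinov-style dynamic
program then maximises the total score over non-crossing pairs with
hairpin loops of at least 3 columns, admitting only pairs with
$s \ge \tau$ (default 0.05); stacked runs shorter than `min_helix`
(default 2) are pruned, and helices are named `H0, H1, ...` 5' to 3'.
Pseudoknots are handled the way curators handle them: two individually
nested structures can be merged with `merge_pseudoknot()`, which keeps
crossing pairs on an explicit second annotation tier rather than
discarding them.

This folding engine is a deliberate stand-in for covariance-model
induction (CMfinder-style EM): it exercises the same comparative
evidence while remaining small enough to verify exhaustively -- the test
suite checks it against brute-force enumeration of all non-crossing
pairings on hundreds of small alignments.  It uses no thermodynamic
energy model, so a helix with no substitution evidence (perfectly
conserved in every row) scores 0 and is invisible; that is a feature for
comparative discovery and a known limitation for single-sequence
folding.

### Homology expansion with empirical E-values

A curated alignment is summarised as a motif profile: pseudocounted
weighted nucleotide frequencies per column, a gap frequency, and a
joint frequency table over the six canonical pair types for every
consensus pair.  Scanning is glocal -- the profile must match end to
end, the genome is local -- with log-odds match scores, gap-frequency
derived deletion penalties, a flat 2-bit insertion penalty, and a pair
bonus for hits whose nucleotides preserve canonical pairing.

Significance is calibrated empirically: each genome is shuffled
preserving dinucleotide counts (an Eulerian-walk shuffle), the shuffles
are scanned, and a Gumbel distribution is fitted to the null scores by
the method of moments ($\lambda = \pi/(\sigma\sqrt{6})$,
$\mu = m - \gamma/\lambda$).  E-values are
$E(s) = N_\mathrm{eff} \, e^{-\lambda (s - \mu)}$ with
$N_\mathrm{eff}$ the searched positions per profile length.  The null
pool is all reported hit scores from the shuffles, not only per-shuffle
maxima; with that convention a planted true motif scores $E \ll 1$
while the best shuffled-genome hits land at $E$ of order 1, which is
what a lenient acceptance cut of $E \le 1$ is designed against.
`expand_iterate()` repeats scan--calibrate--accept--realign for up to 4
rounds (the acceptance threshold, rounds, and shuffle count are all
configurable), stopping early at a fixed point and recording the round
in which every row was recruited.

### Transcript boundaries

Comparative evidence can predict helices that are never transcribed.
`call_tss()` places a single change-point in a per-base coverage window
under a Poisson model: the breakpoint maximising the two-segment
log-likelihood gain, accepted only if the downstream mean is at least
3-fold the upstream mean (floored at 0.5) and at least 5 reads deep --
defaults chosen to be robust at toy scale, with ties broken 5'-most.
One boundary per gene is modelled deliberately; multi-TSS calling is out
of scope because the upstream evidence that would discriminate primary
from secondary starts is not part of the inputs.  The call position is
invariant to uniform depth scaling, and on noiseless steps it is exact.

`truncate_to_transcript()` maps the called TSS into alignment columns
through a member sequence with known genomic coordinates and flags each
helix: `unsupported` (entirely 5' of the TSS), `conflicted`
(straddling), or `supported`.  Pairs are never deleted -- the flags are
curation evidence, and helix names are kept stable so that discarding an
untranscribed 5' helix does not rename the rest.  Positions reported to
users follow the field convention for leaders: +1 is the A of the start
codon, -1 the base immediately 5' of it, with no position 0.

### Reporting

`report_consensus()` renders a family as annotated Stockholm: `SS_cons`
with a second bracket tier (`Aa`) for pseudoknots, a four-class
conservation line (uppercase majority nucleotide at >=97% weighted
identity, lowercase at >=90%, `:` at >=75%, `.` otherwise -- the
conventional diagram thresholds), a pair-class line (`C`/`c`/`=`/`x`
for covarying/compatible/conserved/rejected), and per-helix records
including transcript support.  Text is the entire reporting surface; no
graphics are produced.

## Validation analytics

Filter-binding assays partition bound from free radiolabelled RNA, so
the fraction bound is $F_b = N/(N+Y)$ over nitrocellulose and nylon
counts, and titrations follow the one-site isotherm

$$ F_b \;=\; \frac{\mathrm{Max\%} \cdot [S15]}{[S15] + K_D}. $$

`fit_binding()` minimises least squares over $(K_D, \mathrm{Max\%})$.
Because the conditional optimum of Max% at fixed $K_D$ is closed-form,
the fit profiles the residual sum of squares over a logarithmic $K_D$
grid and refines the grid optimum with a bounded one-dimensional
minimisation -- deterministic, derivative-free, and exact on noiseless
data, replacing the spreadsheet solver such fits are traditionally done
with.  A fit is *censored* when the fitted $K_D$ exceeds the maximum
assayed concentration, reported as ">max" -- the convention for weak
binders whose titrations never approach saturation.  Replicates are
aggregated as mean +/- sample SD over uncensored fits, with any censored
replicate censoring the aggregate.

One property of this regime deserves emphasis.  When the true $K_D$
lies well beyond the assayed ceiling (for example 2000 nM against a
500 nM top concentration), the titration is nearly linear and carries
little information about $K_D$; with Gaussian noise of SD 0.03 on the
fraction bound, the least-squares estimate scatters over orders of
magnitude and roughly a quarter of replicate fits land *below* the
ceiling.  The package measures this directly in its acceptance test: at
those settings about 70% of replicates censor, and driving that above
95% would require noise below roughly 0.015.  Censoring is therefore
reported per replicate and aggregated conservatively, rather than
treated as near-certain.

Reporter regulation is quantified as GFP/OD600 per replicate,
fold change = mean(uninduced)/mean(induced), and a two-sided Welch
t-test with `*` for p < 0.01 and `**` for p < 0.001.  Welch was chosen
over Student's t because induced and repressed cultures have very
different variance scales; at n = 3 its effective degrees of freedom are
low (about 2), so even a clean 10-fold repression with 10% noise reaches
p < 0.01 in only about 90% of simulated experiments -- the package's
power simulation pins that number, and it is worth knowing before
designing a 3-replicate assay.

## The synthetic-data generator

All tests run against generated data whose statistical structure
matches what the analysis assumes:

* `evolve_family()` evolves a 136 nt root leader (111 nt 5' region with
  three planted helices and a Shine-Dalgarno sequence, plus a fixed
  25 nt coding tail) down a random rooted tree rescaled to mean depth 1.
  Substitutions are uniform over the three alternative nucleotides
  (Jukes-Cantor-like, no transition bias) at 0.3 expected substitutions
  per site per unit depth -- typical leader divergence within an order.
  The single covariation knob is the compensation probability `rho`
  (default 0.9): a substitution in a paired site is complemented in its
  partner with that probability.  Only deletions are simulated
  (`indel_rate`, default 0), so the true alignment stays indexed by
  root positions and recovery can be scored exactly.
* `plant_genomes()` embeds each leaf 5' of a fixed rpsO-like ORF in a
  uniform-background 3 kb genome, on a random strand, optionally behind
  a decoy "previous gene" whose 3' end bounds the harvest at a
  configurable gap.
* `simulate_coverage()` draws Poisson depths around a step (default
  means 2 before, 40 after), and `simulate_binding()` draws titrations
  from the one-site model with additive Gaussian noise clipped to
  [0, 1].

What the generator does *not* emulate -- realistic genome composition,
insertion-rich alignments, variable-length helices, multi-TSS
transcription, count overdispersion -- bounds what passing tests show:
they demonstrate that the algorithms recover what was planted under the
stated model, not that the pipeline matches any particular external
tool on real genomes.

## Problem sizes and numerical choices

The shipped tests and demonstration use families of 8-20 taxa on the
136 nt leader, genomes of 3 kb, 200-replicate binding simulations,
1000-window TSS sweeps, and 500-case exhaustive folding comparisons.
These sizes were chosen so the full pattern of evidence -- planted-helix
recovery above 80%, TSS calls within 3 nt in over 95% of windows, mean
K_D recovery within a few percent across the 5-221 nM regime -- is
reproducible in minutes on a laptop.

Determinism is treated as a design requirement: all generators are pure
functions of their spec and seed, dynamic-programming tracebacks break
ties by fixed rules (5'-most pairing partner, diagonal before gaps),
dedup keeps first occurrences, and the pipeline fans one seed out to
its stages, so reruns are byte-identical.  Degenerate inputs resolve
conservatively rather than erroring where the workflow has a natural
continuation: a flat coverage window is a no-call, an alignment with no
qualifying pairs folds to an empty structure, a leader whose upstream
gap is zero is returned as a flagged coding-tail stub, and zero-variance
reporter data yield an NA p-value rather than false certainty.

```{r demo, eval = FALSE}
# the end-to-end synthetic walkthrough
res <- run_demo(seed = 7)
res$planted_flags
#>            H0            H1            H2
#> "unsupported"   "supported"   "supported"
```

The pre-TSS helix H0 is recovered by comparative folding but flagged
`unsupported` by the coverage change-point -- the computational form of
the curation step in which transcriptomic evidence trims a
comparative-genomics prediction down to the biologically plausible RNA.
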