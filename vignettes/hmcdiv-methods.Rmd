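---
title: "Methods: domain-wise hemocyanin divergence and D3 SNP analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain-wise hemocyanin divergence and D3 SNP analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmcdiv)
```

## The scientific question

Crustacean hemocyanin subunits carry three conserved domains: D1 (an
all-alpha N-terminal domain, residues roughly 20–148 of the small
subunit), D2 (the copper-binding oxygen-transport core, 150–407) and D3
(the C-terminal domain, 413–657), which folds like an immunoglobulin
beta-sandwich. If hemocyanin moonlights as an innate-immune recognition
molecule, two signatures are expected: the D3 domain should diverge
faster than D1 and D2 across species, and it should be unusually
variable within an individual's clone libraries, much like an
immunoglobulin variable region. `hmcdiv` implements the computational
machinery to test both signatures — between-species divergence metrics,
a consensus-unit aligner that scores the Ig-likeness of D3, and a
clone-library SNP caller — together with seeded generators that produce
every input synthetically.

## Maximum-likelihood distances under JTT

Between-species divergence is measured per domain as a pairwise
maximum-likelihood distance under the Jones–Taylor–Thornton (1992)
empirical amino-acid model. The model is embedded as the published
exchangeability counts $s_{ij}$ and equilibrium frequencies $\pi_j$; the
generator is $Q_{ij} = s_{ij}\pi_j$ with rows summing to zero, scaled so
that $-\sum_i \pi_i Q_{ii} = 1$. One unit of time therefore equals one
expected substitution per site — the model gives no natural unit, and
expected substitutions/site is the community convention. For an aligned
pair the log-likelihood at time $t$ is

$$\ell(t) = \sum_{\text{columns}} \log\left(\pi_x\,
[e^{Qt}]_{xy}\right),$$

summed over columns with a standard residue in both rows (gaps and
ambiguity codes are excluded pairwise). `jtt_ml_distance()` maximizes
$\ell$ on $t \in [10^{-6}, 10]$ with Brent's method to an absolute
tolerance of $10^{-6}$; identical sequences short-circuit to exactly 0,
and a pair whose optimum pins at the upper bound is reported as 10 with
a `saturated` flag. The symmetrized generator is eigendecomposed once
per model object so $P(t)$ costs a 20×20 reconstruction per evaluation.

Pairs are aligned with exact Needleman–Wunsch global alignment
(BLOSUM62, gap open 10, gap extend 1 by default; a gap of length $L$
costs $\mathrm{open} + L\cdot\mathrm{ext}$) rather than a multiple
alignment projected to pairs: pairwise statistics then need no guide
tree and are reproducible without alignment-order artifacts. "Identity"
is the fraction of identical columns among columns with a residue in
both rows — terminal gaps therefore never dilute a self-comparison —
and "similarity" (often called homology in BLAST/BioEdit output) is the
fraction of columns with a positive substitution score, identities
included.

`domain_distance_summary()` computes all $n(n-1)/2$ pairwise distances
for one domain and their mean; `domain_divergence_tests()` compares two
domains' distance samples with a Mann–Whitney U test
(`mann_whitney_u()`, exact for small tie-free samples, normal
approximation with tie and continuity corrections otherwise). The
pairwise distances of a fixed taxon set are not independent samples, so
these p-values are descriptive summaries of a divergence contrast, not
calibrated error rates; they are reproduced in this form because that
is how domain contrasts are conventionally reported. p-values below
0.0005 print as "< 0.0005", never as zero.

## Ka and Ks by Li's method

Coding-level divergence uses Li's (1993) unbiased estimator.  Every
position of every sense codon is classed by degeneracy: nondegenerate
(no synonymous alternative), twofold (one or two), fourfold (all
three); class totals $L_0, L_2, L_4$ are averaged over the two
sequences. Differences are classed the same way, a change at a site
whose class differs between the two codons counting half in each.
Codons differing at more than one position are resolved over all
minimal pathways with equal weights, discarding pathways through stop
codons; if every pathway is blocked the codon pair is skipped with a
warning. At twofold sites a change counts as "transitional" exactly
when it is synonymous — Li's interchange rule, which handles the
arginine (CGA/AGA, CGG/AGG first positions) and isoleucine (ATA third
position) families where the synonymous partner is reached by
transversion. With proportions $P_i$ (transitions) and $Q_i$
(transversions),

$$A_i = \tfrac12\ln\tfrac{1}{1-2P_i-Q_i} -
\tfrac14\ln\tfrac{1}{1-2Q_i},\qquad
B_i = \tfrac12\ln\tfrac{1}{1-2Q_i},$$

$$K_s = \frac{L_2A_2 + L_4A_4}{L_2+L_4} + B_4, \qquad
K_a = A_0 + \frac{L_0B_0 + L_2B_2}{L_0+L_2}.$$

A non-positive logarithm argument marks the affected rate as saturated
(`NA`) rather than silently clamping. One deliberate difference from
the 1985 Li–Wu–Luo weighting: multi-hit pathways here are averaged with
*equal* weights (and verified against exhaustive small-codon oracles),
whereas Li's original code weights pathways by amino-acid interchange
likelihoods; on single-hit codons the two coincide exactly, which is
how the implementation is cross-checked against an independent port of
Li's code.

## Consensus-unit matching

The Ig-likeness evidence for D3 rests on aligning the domain against a
conserved-domain consensus written as ordered "units": one or more
conserved residues followed by a bracketed count or range of variable
spacer residues, e.g. `C[2-4]`, `{FYW}[1]`, `Y[0-*]`. `match_units()`
maximizes the number of units placed in pattern order at increasing
query positions, subject to length budgets: between two consecutively
matched units the query gap must lie within the sum of the traversed
spacer ranges, and a skipped unit still consumes its conserved length
plus its spacer budget. Skipping therefore forgives residue identity
but not geometry, so matched units remain positionally plausible within
the consensus. The optimizer is a dynamic program over (unit, anchor)
states; ties break toward the lexicographically smallest anchor vector,
making results order-robust and deterministic. A `greedy = TRUE`
first-fit scan is available for comparison with simpler
scan-in-turn implementations; it can only ever match fewer units.
Matched counts and longest consecutive runs are reported as percentages
of the unit total at one decimal, rounding half up.

The exact 34-unit inventory of the Ig consensus (NCBI CDD Cd00096, as
transcribed at the time of the original analyses) cannot be
reconstructed from published figures alone, so the shipped benchmark is
a synthetic 34-unit pattern planted with 26 matched units containing a
15-run — the same summary structure — and users supply their own
transcription for real consensi (`parse_unit_pattern()` documents the
format).

## Clone-library SNP calling

Within-individual variability is measured from plasmid clone libraries
of a PCR-amplified D3 region (96 clones per library is one microtitre
plate). Each clone is globally aligned to the subunit's reference D3
(match +2, mismatch −3, gap open 5, gap extend 2); clones covering less
than 80% of the reference are rejected with a reason. Only substitution
columns count — indels are ignored, and any non-ACGT base is missing
data. A SNP is a (position, alternative base) pair observed at least
twice (`min_recurrence = 2`) in the pooling scope, the minimal filter
that discounts singleton PCR/sequencing artifacts; positions are
reported in accession coordinates via the domain annotation (the small
subunit's D3 is representable both as 1741–2528 and as the 1752–2528
amplicon — both are plain annotations, neither is hard-coded).
Pooling defaults to (subunit, level) across libraries, reproducing
per-level genomic/cDNA catalogs, and is configurable to per-library.
Negative-control libraries (e.g. beta-actin clones) warn if they yield
any SNP. Site frequencies divide recurrence by the subunit's pooled
clone total by default — with 1,157 clones the smallest reportable
frequency is $100 \times 2/1157 = 0.17\%$ — and print at two decimals,
half-up. `compare_catalogs()` performs the cross-library set algebra
(sizes, pairwise and k-way intersections, union, shared position
lists), keyed by position+allele internally and by bare position for
accession-style lists; inclusion–exclusion consistency is
property-tested. Catalogs export to VCF 4.2 with recurrence and
frequency in INFO.

At the default error model (0.1% per base), roughly one spurious
recurrence-2 site per 96-clone library is expected from error
collisions alone; the recurrence filter is therefore validated as an
*exact* filter (catalog = direct-diff counts thresholded at 2), not as
a guarantee that every catalog entry is biological.

## The synthetic-data generators

The generators exist so that every analysis above can be exercised and
validated without downloads, and their defaults encode the study
conditions the pipeline targets:

* `simulate_protein_family()` — a star tree (pairwise distances are the
  object of interest, and star branches give direct control of the true
  pairwise divergence: two branches of $t/2$ make every pair exactly
  $t$ apart). The root is drawn from JTT equilibrium; defaults are six
  taxa and per-domain divergences 0.447528 (D1, 129 aa), 0.226219 (D2,
  258 aa) and 0.666782 (D3, 245 aa) — the reported domain means, so the
  planted ordering D3 > D1 > D2 is the condition under test.
* `simulate_clone_library()` — 96 clones; planted (position, alt,
  frequency) sites carried per clone by Bernoulli draws (or exactly
  `round(f·n)` carriers with `carrier_mode = "exact"`, used where a
  catalog of an exact size is the condition); iid per-base errors at
  0.1%, uniform over the three alternative bases — the simplest null
  that exercises the recurrence filter. Planted frequencies in the
  0.17–20% band mirror the reported range.
* `simulate_codon_alignment()` — plants one change per mutated codon at
  a site of requested degeneracy class and substitution type, so
  Li-method class counts are known exactly by construction.
* `simulate_unit_fixture()` — instantiates a chosen flag vector; with
  rigid (exact) spacers the pattern geometry fixes every unit's
  position given one anchor, so corrupted units (written with a filler
  residue excluded from all conserved positions) cannot match and the
  planted flags are the optimum.

All generators are deterministic given a seed. What they do *not*
emulate: among-site rate heterogeneity, alignment uncertainty (clones
and family members are generated already homologous end-to-end), PCR
chimeras and recombination, and indel processes beyond what the aligner
must tolerate. Green tests therefore demonstrate correctness of the
estimators and filters under their own model assumptions, not
robustness to real-data misalignment or rate variation.

## Numerical choices and scale

* ML distance search interval $[10^{-6}, 10]$, tolerance $10^{-6}$;
  estimates validated against an independent grid search (step
  $2\times10^{-4}$) to within $5\times10^{-4}$, and against a second
  ML-distance implementation to $10^{-4}$.
* Parameter recovery uses 1,000-site pairs at $t \in \{0.1, 0.3,
  0.7\}$ with 50 replicates (median error under 10%).
* Recurrence-filter fuzzing uses 100 seeded 96-clone libraries over a
  300 nt region, and the benchmark set-algebra catalogs use the
  777 nt amplicon; these sizes make the full suite run in about two
  minutes while leaving every count assertion exact.
* Rounding is half-up at the reporting boundary only (two decimals for
  frequencies, one for unit percentages); internal values stay
  unrounded.
* Tie-breaks: alignment traceback is delegated to the alignment
  engine (deterministic); unit matching prefers the smallest anchors.

## A worked mini-example

```{r example}
model <- jtt_model()
fam <- simulate_protein_family(6, hmc_domain_plan(), model, seed = 1)
means <- vapply(c("D1", "D2", "D3"), function(d)
  domain_distance_summary(fam$sequences[[d]], model,
                          domain_name = d)$mean, 0)
round(means, 4)

fx <- simulate_unit_fixture(unit_benchmark_flags(), rigid = TRUE,
                            seed = 1)
match_units(fx$query, fx$pattern)
```

## Known limitations

* No tree inference, bootstrap or gamma rate heterogeneity; distances
  are strictly pairwise.
* Ka/Ks is Li's counting method only — no codon substitution models,
  no maximum-likelihood dN/dS.
* The unit matcher scores presence/absence against a consensus, not a
  PSSM or profile HMM; residue classes carry no weights.
* SNP calling cannot distinguish allelic polymorphism, somatic
  variation and RNA-level editing — that interpretation needs the
  experimental design around the catalogs, not the catalogs alone.
* Real-accession benchmarks (subunit identity, domain means, the
  Cd00096 match) depend on database sequences and a manual consensus
  transcription; the package ships synthetic stand-ins with the same
  summary structure instead of bundling third-party data.
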