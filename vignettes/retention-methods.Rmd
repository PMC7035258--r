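---
title: "Methods: gene retention after polyploidy, from collinearity to network robustness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene retention after polyploidy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyret)
```

## The model

`polyret` asks a population-of-genes question: after recursive
polyploidizations, does a focal gene class keep its duplicate copies more
often than the genome-wide average? The observable is collinearity — a
duplicate retained since a whole-genome event still sits in a block of
conserved ancestral gene order, whereas tandem, proximal and dispersed
duplicates arise by local or ectopic mechanisms and do not. The package
therefore treats "gene is in a significant collinear block" as the proxy
for "gene descends from a polyploidy event", tests class enrichment on that
status, dates blocks with a Ks clock, and follows the retained copies into
interaction-network space.

## Collinear block detection

Anchors are homologous gene pairs surviving a loose similarity filter
(E-value < 1e-5, top five matches per query — loose because duplicates born
at ancient events are highly diverged). Blocks are chains of anchors whose
order ranks increase on both chromosomes (or increase/decrease for inverted
segments) with at most `max_gap = 50` intervening genes on each genome, the
classic gap bound for plant paleogenomics. Chaining maximises anchor count
by dynamic programming, extracts the best chain, removes it, and repeats —
with a total tie order (score; then total gap; then lexicographic anchor
sequence; then orientation) so results are bit-reproducible. An exhaustive
enumeration oracle in the test suite verifies the DP on hundreds of random
instances.

Block significance is a permutation test: the observed anchors of a
chromosome pair are redrawn uniformly on the rank grid, the best chain
score recorded, and `p = (1 + #{null ≥ observed}) / (1 + n_permutations)`.
We chose a permutation null because the analytic distribution of gap-bounded
chains has no convenient closed form and the add-one estimator is exact at
the achievable p floor. The null is computed once per (chromosome pair,
anchor count) and shared by that pair's blocks. The default
`n_permutations = 1000` resolves p down to ~0.001; analyses gating only at
p < 0.05 (as all built-in reports do) are equally served by 200
permutations, which the examples and acceptance runs use for speed at their
stated problem sizes (1000–2000 ancestral genes).

One guard matters on self-comparisons: anchors at rank distance ≤ 1 on the
same chromosome are excluded from chaining, otherwise the main diagonal of
a self dot plot chains into one giant spurious "block". Those same adjacent
pairs are exactly what the tandem classifier needs, so the classifier
receives anchors built *without* that exclusion
(`anchors_from_hits(..., exclude_tandem_adjacent = FALSE)`).

## Duplicate classification and enrichment

Each gene gets exactly one of five types with precedence
wgd > tandem > proximal > dispersed > singleton. The windows default to
tandem = adjacent ranks (0 intervening genes) and proximal ≤ 10 intervening
genes, the conventional classifier windows; both are parameters of
`classifier_params()`.

Enrichment is a Pearson chi-squared on the 2×2 of (focal, background) ×
(in-category, not), 1 df, no continuity correction by default (counts in
scope are in the hundreds to tens of thousands). The status call is
**I**/**D** when p < α (default 0.05) with the focal proportion above/below
background, else **U**. Two backgrounds are offered: `all_genes` mirrors
the layout of published collinearity tables (the focal row is compared
against the whole-genome row, focal genes included), while `non_focal`
uses the complement and is the statistically clean choice when the focal
set is a non-trivial fraction of the genome. No multiple-testing correction
is applied by default, matching how such per-species tables are usually
reported; a Bonferroni option would be a one-liner on the returned
p-values.

## Event attribution and the recounting rule

Blocks are dated by the median Ks of their anchor pairs against half-open
Ks windows `[ks_min, ks_max)` supplied by the analyst (a density-valley
suggester exists but is never auto-applied — silent misattribution is worse
than asking). Median-of-anchors is robust to a minority of mis-paired
anchors inside a block; a median outside all windows leaves the block
unassigned rather than force-fitted. Gene counts per event follow the
recounting rule: a gene whose blocks are labelled with several events
contributes to each of them, because a gene retained through an old event
and reduplicated in a young one is genuinely part of both events' legacies.
Venn-style exact event-set counts are reported alongside so the overlap is
visible rather than hidden in double counting.

## Network projection and robustness

The "equivalent replacement" rule projects a reference interaction network
through an ortholog map: reference edge (a, b) yields target edge (x, y)
for every x ∈ orth(a), y ∈ orth(b), x ≠ y, deduplicated, no self-loops.
The map is deliberately many-to-many (reciprocal best hits plus co-orthologs
within 0.9× of the best bitscore): a one-to-one map cannot grow a network
after duplication, which would contradict the phenomenon under study —
this is why projection is monotone in ortholog-set size, a property the
tests assert directly.

Robustness is R = C/(N − Nr): remove Nr nodes uniformly at random, take the
largest connected component fraction of what remains, average over 100
draws. Fractional schemes resolve as Nr = round-half-up(f·N) clamped to
[1, N − 1]; rounding half *up* avoids the no-op Nr = 0 on small networks,
and the clamp keeps the statistic defined. Removal is uniform, not
degree-targeted — the protocol models random failure, not attack.

## Ka/Ks (Nei–Gojobori 1986)

Synonymous/nonsynonymous site counts assign each codon position the
fraction of its three possible changes that are synonymous (changes into a
stop codon count as nonsynonymous, keeping S + N = 3 per codon exactly).
Differences between codon pairs average over all minimal mutational
pathways; pathways through stop codons are excluded and the rest
reweighted equally — if every pathway is blocked (a rare corner), all are
used. Proportions are Jukes–Cantor corrected, erroring at the p ≥ 0.75
saturation boundary rather than returning a fiction. ω = Ka/Ks is `NA`
(undefined), not infinity, when Ks = 0; positive selection is flagged only
for defined ω > 1. Gapped codon columns are dropped pairwise. Only the
standard genetic code is supported — the organisms in scope are plants.
An independent brute-force enumerator (separate code path, hard-coded
translation string) checks every field to 1e-10 on random pairs.

## The synthetic genome generator

The generator is the package's experimental apparatus, not a fixture. It
emulates:

* **Recursive polyploidy**: each event appends whole chromosome copies
  (multiplicity 2 or 3), so within-copy collinearity is exact, as in real
  paleo-blocks; each new copy then survives per-gene with a class-dependent
  retention probability (defaults 0.8 focal vs 0.4 background — the biased
  regime under study; the pre-event copy always survives, so genes never go
  extinct).
* **A Ks clock**: every surviving homologous pair draws
  Ks ~ Normal(age of its lineage-split event, `ks_noise_sd`), truncated at
  zero (implemented as censoring; at the default ages ≥ 0.2 and sd = 0.05
  the boundary is never touched). The default history — WGT at Ks 1.6, WGDs
  at 0.8 and 0.2 — gives modes separated by ≥ 4 sd, the regime where
  nearest-mode dating is reliable.
* **Single-gene modes**: tandem inserts at the adjacent rank, proximal at
  2–10 intervening genes, dispersed on another chromosome (rates 2%, 1%,
  3% per gene by default). Their pairs carry a young Ks
  (mean `sgd_ks = 0.1`), a value the package chooses since single-copy
  duplications have no event age.
* **Erosion**: random segment inversions (2–25 genes) shuffle gene order,
  fragmenting chains exactly as real rearrangements erode collinearity.
* **Observables**: a similarity table with identity = 100·exp(−0.3·Ks) plus
  bounded noise (so identity falls with pair age and the family thresholds
  remain meaningful), E-values monotone in identity, self-hits ranked
  first; and a preferential-attachment reference interaction network over
  the ancestral focal genes.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: sequence-level homoplasy and alignment
error, gene deaths, chromosome fusion/fission, transposed duplications,
rate variation across lineages, and incomplete genome assemblies. Pairs are
emitted only between true homologs, so detection specificity against
spurious similarity is exercised only through the permutation null, not
through a realistic noise floor.

## Calibration choices

Two design points deserve explicit statement.

*Unit of replication.* Retention bias is a property of ancestral genes
(does this gene keep a duplicate?), and a retained duplicate contributes
**two** correlated copies to the emitted genome. A 2×2 built over emitted
genes is therefore overdispersed under the null — empirically ~10%
rejection at α = 0.05 — while the same test over ancestral genes with the
non-overlapping background rejects at 5–6%, as a calibrated test should.
The calibration experiments consequently count ancestral genes with
`background_mode = "non_focal"`; the per-copy table remains the right
object for describing an observed genome (it is what published collinearity
tables print), just not for type-I calibration.

*Calibration bypasses detection.* The null/power calibration runs use the
generator's truth to mark retained genes rather than re-running block
detection hundreds of times: under label-exchangeable nulls, detection adds
no class-specific bias, and the chi-squared sampling behaviour is the thing
being calibrated. Detection fidelity is measured separately where it is the
question — classifier recovery (≥ 95% agreement with truth at zero
inversions, degrading monotonically with erosion, confusion concentrated in
wgd↔dispersed) and event-attribution recovery (≥ 90% of blocks correctly
dated at sd 0.05) both run the full chaining path at 1000–2000 ancestral
genes.

## Numerical conventions and degenerate inputs

Percentages in every report are round-half-up to two decimals
(`format_percent(353, 420)` is `"84.05"`). All randomness flows from one
integer seed; pipeline stages draw stable derived seeds so a stage re-run
in isolation reproduces its in-pipeline behaviour. Degenerate cases are
contracts, not surprises: empty anchor sets yield empty block objects;
zero-marginal 2×2 tables are skipped with status U and a warning (the test
is undefined there); robustness schemes that would empty a network are
reported not-applicable; readers reject malformed lines with their line
number rather than repairing silently.

## Limitations

The permutation null assumes anchors are exchangeable across the rank grid,
which slightly overstates significance when anchor density varies strongly
along a chromosome. Ks dating inherits the usual saturation and
rate-constancy caveats; windows must be chosen by the analyst. The
co-ortholog 0.9× bitscore window is a pragmatic surrogate for proper
orthogroup inference and will over-merge recent tandem arrays. None of the
statistics separate WGD remnants from old segmental duplications — both are
reported as "wgd", and collinearity-based counts are best read as lower
bounds under erosion.
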