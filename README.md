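# polyret

Testing whether a gene class is preferentially retained in
polyploidy-derived, collinear genomic regions — and what that retention does
to the class's regulatory network.

## The problem

Paleopolyploidy (whole-genome duplication, WGD, and triplication, WGT)
leaves behind *collinear* chromosomal segments: runs of homologous genes
that preserve ancestral gene order. After each event most duplicate copies
are lost again (fractionation), but losses are not uniform across functional
categories. For stress-response families — cold-related genes are the
motivating example — duplicates are retained far more often than the
genome-wide average, and the retained copies enlarge the family's
protein–protein interaction network, making it more robust to node loss.

`polyret` implements that inference chain as composable, tested R functions:

1. **Family identification** from all-vs-all similarity tables
   (E-value < 1e-10, identity > 60%, strict inequalities).
2. **Anchor filtering** (E-value < 1e-5, top five matches per query) and
   **collinear block detection** by gap-constrained chaining
   (≤ 50 intervening genes on each genome) with a permutation null for
   block significance (p < 0.05).
3. **Five-way duplicate classification** per gene, with the precedence
   wgd > tandem > proximal > dispersed > singleton.
4. **Event attribution**: blocks are dated by the median synonymous
   distance (Ks) of their anchor pairs against user-supplied Ks windows;
   genes reduplicated in a younger event are *recounted* in every event
   that touched them.
5. **Enrichment**: Pearson chi-squared on the 2×2 of class × collinearity
   status (or duplication type), with an Increase / Unchanged / Decrease
   call.
6. **Network projection** ("equivalent replacement"): a reference
   interaction network is carried onto another genome through a
   many-to-many ortholog map, so duplicate-rich genomes grow larger
   networks.
7. **Robustness** R = C/(N − Nr): the largest-connected-component fraction
   after removing Nr random nodes, averaged over 100 draws, profiled over
   the protocol (5, 10 nodes; 5%, 10%, 20%, 50%).
8. **Ka/Ks screening** by Nei–Gojobori (1986) with Jukes–Cantor correction;
   ω > 1 flags candidate positive selection.

A synthetic-genome module generates recursive tetra/hexaploid histories
with class-biased retention, single-gene duplications, Ks clocks and
inversion erosion — with a per-gene truth table, so every stage above is
verifiable against known ground truth without any downloads.

## Worked example

```r
library(polyret)

# a genome shaped by a WGT ("gamma", Ks ~1.6) and two WGDs ("beta" 0.8,
# "alpha" 0.2), with focal genes retained at 0.8 vs background 0.4
sim   <- simulate_genome(sim_params(n_genes = 300, n_chroms = 3, seed = 11),
                         default_events())
hits  <- emit_similarity_table(sim, seed = 2)
an    <- anchors_from_hits(filter_anchors(hits), sim$genes)
blocks <- find_collinear_blocks(an, sim$genes,
                                collinearity_params(n_permutations = 200,
                                                    seed = 3))
glance(blocks)
#> # A tibble: 1 × 4
#>   n_blocks n_significant n_anchors median_block_size
#>      <int>         <int>     <int>             <int>
#> 1      179           179      3231                15

focal <- sim$genes$gene_id[sim$genes$class_tag == "focal"]
enrichment_row(focal, colinear_gene_set(blocks), sim$genes$gene_id)
#> <polyret_enrichment> focal 836/867 (96.42%) vs background 1485/1582
#> (93.87%): chi2 = 7.386, p = 0.00657, status I
```

179 significant blocks tile the simulated chromosomes; 96.4% of focal genes
sit in at least one of them against 93.9% genome-wide, and the chi-squared
call is **I** — the focal class is significantly over-retained in collinear
regions, which is exactly the bias the generator planted (0.8 vs 0.4
retention). `run_pipeline()` chains all stages (classification, event
attribution, network projection, robustness) behind one seeded, fully
deterministic call configured in R or YAML.

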