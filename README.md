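# reptype

Degenerate primer design and in-silico PCR for plasmid replicon typing.

Catabolic plasmids of the IncP-1, IncP-7 and IncP-9 incompatibility groups
carry much of the machinery bacteria use to degrade pesticides and aromatic
pollutants, and environmental surveys detect them culture-independently by
PCR against their replication loci (*oriV*, *rep*, *trfA*). `reptype` is a
toolkit for building and auditing such detection systems. It covers the
full computational workflow around a replicon-typing PCR:

1. **Design.** Given replicon reference sequences grouped into subgroups,
   the package aligns them (Needleman–Wunsch pairwise, NJ-guide-tree
   progressive alignment), profiles per-column conservation, and
   enumerates degenerate primer windows under explicit constraints:
   primer length *L* (default 21 nt), degeneracy
   `prod_i |expansion(p_i)| <= 8`, a perfect 3′-terminal anchor of
   ≥ 12 bp on **every** target, at most 4 mismatches (all 5′ of the
   anchor), indel-free windows, a Wallace-rule melting window
   (`Tm = 2(A+T) + 4(G+C)`, averaged over expansions), and a per-target
   product size inside a configurable window (default 610–637 bp).
2. **In-silico PCR.** Degenerate matching follows the subset rule: a
   (possibly ambiguous) template base matches a primer base only when its
   whole expansion is covered. Binding sites on both strands, predicted
   amplicons (`length = rev_end − fwd_start + 1`), and target/non-target
   specificity screens.
3. **Classification.** Amplicon sequences are co-aligned with labelled
   references, assigned the subgroup of the nearest reference by
   Jukes–Cantor distance (`d = −3/4 · ln(1 − 4p/3)` on pairwise-deleted
   columns), with `unaffiliated` beyond a distance threshold
   `tau = 0.10`, bootstrap support over column resampling, and a
   neighbor-joining tree (Saitou–Nei with the Studier–Keppler Q
   criterion) written as Newick.
4. **Synthetic panels.** A seeded generator produces nine-subgroup
   replicon panels with planted primer sites, spacer-length variation,
   decoy non-targets and query "clone libraries" with full ground truth,
   so every stage above is testable without any download.

The package ships the published degenerate IncP-9 *oriV-rep* primer pair
(`incp9_primers()`) and the accession lists of its 28-sequence reference
panels (`incp9_accessions()`). Other systems (e.g. *trfA*, IncP-7 *rep*)
are supported through a user-supplied primer registry file.

## A worked example

```r
library(reptype)

panel <- simulate_panel(sim_config(seed = 7))
panel
#> <replicon_panel>
#>   27 targets in 9 subgroups; 6 non-targets; seed 7
#>   expected amplicons: 612-636 bp

design <- design_primers(panel$targets)
design
#> <primer_design>
#>   alignment: 27 rows x 946 columns
#>   candidates: 9 forward, 9 reverse; 14 valid pairs
#>   best pair: F GAGGGTTTGGAGATCATWAGA (cols 73-93) / R GGTCTGTATCCAGTTRTGCTT (cols 730-750)
#>   amplicons: 612-636 bp across 27 targets
```

The designer rediscovers, from sequence data alone, exactly the planted
degenerate 21-mers — the published IncP-9 pair (`W` = A/T, `R` = A/G) —
at the planted coordinates, with every per-target product inside the
610–637 bp window.

```r
screen <- specificity_screen("GAGGGTTTGGAGATCATWAGA", "GGTCTGTATCCAGTTRTGCTT",
                             panel$targets, panel$nontargets)
screen
#> <specificity_report>
#>   targets amplified: 27/27; non-targets amplified: 0/6
#>   target product lengths: 612-636 bp
#>   fully specific: TRUE

queries <- simulate_queries(panel, n_per_subgroup = 2, divergence = 0.02)
refs <- amplicon_sequences(
  predict_amplicons("GAGGGTTTGGAGATCATWAGA", "GGTCTGTATCCAGTTRTGCTT",
                    panel$targets),
  panel$targets)
cls <- classify_amplicons(queries, refs, n_reps = 100, seed = 11)
glance(cls)
#> # A tibble: 1 × 8
#>   n_queries n_unaffiliated n_labels mean_distance mean_support   tau n_reps  seed
#>       <int>          <int>    <int>         <dbl>        <dbl> <dbl>  <dbl> <dbl>
#> 1        18              0        9        0.0212          100   0.1    100    11
```

All 18 simulated clones (2 % diverged) classify back to their true
subgroup with distance well under `tau` and full bootstrap support.
`tidy()` / `glance()` give tabular views of every result object and
`autoplot()` draws the conservation profile, the specificity screen and
the assignment map.

A command-line entry point wraps the same functions
(`inst/exec/reptype`): `reptype simulate | design | ispcr | classify`,
each writing TSV/FASTA/Newick outputs plus a manifest with input digests
and the seed, so identical commands reproduce identical outputs.

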