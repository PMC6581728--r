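# splicevol

Comparative evolution of alternative splicing (AS) from splice-junction
evidence.

Plant transcriptomes splice the same orthologous genes differently: most AS
events are gained or lost along lineages rather than conserved, events that
introduce premature termination codons (PTCs, degraded by nonsense-mediated
decay) behave differently from ordinary events, and a handful of intronic
sequence determinants — the distance between the authentic splice site and
its nearest alternative site or internal GT/AG, junction size,
polypyrimidine/UA tracts, branch sites — explain much of which junctions are
alternatively spliced and which events survive between species. `splicevol`
implements that comparative analysis as a tested, reusable R pipeline that
runs entirely from junction-level evidence tables plus genome/annotation
files — no read mapping required.

## What it computes

* **Event detection and PSI** — intron retention (IR), alternative donor
  (AltD), alternative acceptor (AltA) and exon skipping (ES) from filtered
  junctions (overhang ≥ 13 bp, intron length in [41, 50000] bp), with
  `PSI = inclusion / (inclusion + exclusion)` defined only at ≥ 10
  supporting reads.
* **Conserved exon–exon junctions (EEJs)** — reciprocal-best translated
  alignment of 100+100 bp exonic flanks within one-to-one ortholog pairs
  (≥ 3 aa aligned per flank, ≥ 60 bp coverage, significance ≤ 1e-3), AS
  conservation calls (conserved / lost / gained / type switch) and the 5×5
  AS transition spectrum.
* **PTC / NMD annotation** — longest-ORF scanning and the 50-nt rule (stop
  codon ≥ 50 nt upstream of the final exon–exon boundary), with event-level
  AS+PTC / AS−PTC classes and Fisher-exact conservation contrasts.
* **Splice-site determinants** — 12-mer splice-site PWMs with log2-odds
  match scores (> 2 cutoff), alternative-site and inter-GT/AG distances
  with frame flags, polypyrimidine/UA tract and branch-site detection,
  log2-odds-ratio effect sizes, and hexamer enhancer/silencer enrichment.
* **Splicing-code and AS-conservation classifiers** — balanced (1:1 or
  1:1:1) datasets, stratified 60/20/20 splits, a seeded feed-forward
  network selected by validation AUC, rank-based AUC, permutation
  importance, and best-of-10 repeated fitting for the conservation model.
* **Profiles and clustering** — PSI (0.05 < PSI < 0.95 filter, Spearman)
  and binary AS presence (asymmetric binary distance) profiles with
  feature-bootstrap UPGMA clustering and per-node support.
* **Synthetic cohorts** — `cohort_config()` / `generate_cohort()` build
  seeded multi-species worlds (GT..AG introns, planted events with known
  PSI, engineered PTC isoforms, controlled divergence and conservation
  labels, planted determinant signals) so every stage is testable offline.

## Worked example

```r
library(splicevol)

cfg    <- cohort_config(n_genes = 30, seed = 7, as_fraction = 0.3, depth = 100)
cohort <- generate_cohort(cfg)

sp1    <- cohort$species$sp1
junc   <- load_junctions(sp1$junctions)
events <- classify_as_events(junc, sp1, sample_id = "sp1_t1")
table(events$type)
#> AltA AltD   ES   IR
#>    6    5    1   14
head(events[, c("event_id", "type", "inclusion_reads", "exclusion_reads", "psi")], 4)
#>                  event_id type inclusion_reads exclusion_reads       psi
#> 1 sp1_g001:AltD:1385-1470 AltD              37              12 0.7551020
#> 2 sp1_g002:AltA:2593-2726 AltA              24              95 0.2016807
#> 3   sp1_g003:IR:3363-3480   IR              47              60 0.4392523
#> 4 sp1_g004:AltA:4925-5264 AltA              62              32 0.6595745
```

Each row is one AS event in one sample: `psi` is the inclusion-isoform
fraction (e.g. the first AltD event's shorter-intron isoform carries 37 of
49 reads, PSI ≈ 0.76). Cross-species conservation for the same cohort:

```r
sp2    <- cohort$species$sp2
orth   <- find_orthologs(sp1$proteins, sp2$proteins)   # 30 one-to-one pairs
mm     <- match_eejs(build_eej_table(sp1), build_eej_table(sp2), orth)
ev1    <- classify_as_events(junc, sp1, sample_id = unique(sp1$junctions$sample_id))
ev2    <- classify_as_events(load_junctions(sp2$junctions), sp2,
                             sample_id = unique(sp2$junctions$sample_id))
labels <- call_conservation(mm, ev1, ev2)
transition_spectrum(labels)
#>      none AltA AltD ES IR
#> none  111    6    1  4  3
#> AltA    3    3    0  0  0
#> AltD    3    0    2  0  0
#> ES      2    0    0  0  0
#> IR     11    0    0  0  3
```

Diagonal cells are conserved events; the `none` row/column are gains and
losses — here 8 conserved events against 19 losses and 14 gains, the
species-specific pattern the analysis is built to quantify. PTC classes for
the first species' events:

```r
table(event_ptc_classes(sp1)$class)
#> AS_minus_PTC  AS_plus_PTC
#>           25            1
```

A command-line interface wraps the same steps
(`inst/cli/splicevol.R simulate|detect|conserve|ptc|features|profile`).

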