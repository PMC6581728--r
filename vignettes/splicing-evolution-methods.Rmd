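---
title: "Methods: comparative evolution of alternative splicing from junction evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative evolution of alternative splicing from junction evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Alternative pre-mRNA splicing (AS) produces multiple mature transcripts from
one gene by differential intron removal or splice-site choice. Comparing AS
across related plant species asks three questions: how conserved are
individual AS events at orthologous exon–exon junctions (EEJs); whether AS
events that introduce premature termination codons (PTCs, the substrate of
nonsense-mediated decay, NMD) are more or less conserved than other events;
and which sequence determinants near the splice sites explain why a junction
is alternatively rather than constitutively spliced — and why that state is
gained or lost between species.

`splicevol` implements this comparative pipeline end to end on junction-level
evidence (not raw reads): event detection and percent-spliced-in (PSI)
quantification, cross-species EEJ matching, PTC annotation under the 50-nt
rule, splice-site determinant extraction, classifier training, and profile
clustering. A seeded multi-species cohort generator makes every stage
testable without external sequencing data.

## Event detection and PSI

Junction evidence is a table of intron-spanning alignments
(0-based half-open intron intervals, strand, supporting reads, minimum
overhang, optional intronic coverage). Two filters mirror standard practice
for removing alignment artefacts: overhang ≥ 13 bp, and intron length within
[41, 50000] bp (the mapping bounds; sub-60-bp plant introns are rare enough
that no further floor is applied). Within a gene:

* **AltD** — two junctions sharing the acceptor and differing at the donor
  (strand-aware: the donor is the 5′ intron end on the sense strand);
* **AltA** — sharing the donor, differing at the acceptor;
* **ES** — a junction spanning an annotated exon that a pair of junctions
  includes; all three junctions must survive filtering;
* **IR** — a junction with both spliced reads and intronic coverage
  (coverage arrives as a single aggregate count; per-base contiguity is not
  checked).

PSI = inclusion/(inclusion + exclusion), defined only when total support is
at least 10 reads. For AltD/AltA the inclusion isoform is the junction with
the shorter intron (more exonic sequence); for ES the inclusion count is the
*sum* of the two inclusion-junction counts; for IR inclusion is the intronic
coverage and exclusion the spliced reads, so that total support is the sum
of junction and intron-region reads. A triple of junctions recognised as ES
suppresses the AltD/AltA calls its exclusion junction would otherwise
generate.

## Conserved EEJs and AS transitions

Each supported junction is represented by up to 100 bp of flanking exonic
sequence per side (truncated at exon boundaries, sense strand). Within
one-to-one ortholog gene pairs (reciprocal best protein hits, e-value
≤ 1e-6, ties excluded), EEJ sequences are compared by translated local
alignment (BLOSUM62, affine gaps, all sense-frame combinations). A match is
accepted when it is reciprocal best by score, at least 3 amino acids align
in each flank, aligned coverage is ≥ 60 bp, and the significance proxy is
below 1e-3. The proxy is a Karlin–Altschul e-value
(`E = K·m·n·exp(−λS)`, gapped BLOSUM62 constants λ = 0.267, K = 0.041);
this replaces BLAST's statistics on desk-scale data — thresholds are
exposed and the mapping is monotone in score, which is what the filters
need.

An AS event is *conserved* when the same AS type occurs at both matched
EEJs; *lost*/*gained* are reported relative to the first species;
differing types are a *type switch*; EEJs carrying more than one AS type
are excluded. Counting matched pairs over the five states
\{none, AltA, AltD, ES, IR\} per side gives the 5×5 transition spectrum,
whose grand total is the number of labeled pairs.

## PTC annotation (50-nt rule)

The longest ATG-initiated ORF of each mature isoform is found on the
forward strand (ties → 5′-most; candidate ORFs containing N are discarded).
A transcript is PTC+ when its stop codon ends at least 50 nt upstream of
the **final** exon–exon boundary, in mature coordinates. The rule is
ambiguous in its usual phrasing ("an exon–exon boundary"); the final
junction is the standard NMD convention and is the default, with
`rule = "any"` exposed. An event receives a PTC class only when it maps to
exactly two transcripts whose sole structural difference is the AS region
and at least one lacks a PTC; two PTC+ transcripts are treated as
annotation artefacts and left unassigned. Conservation × PTC class is
compared with a two-sided Fisher exact test; the reported odds ratio is the
sample odds ratio ad/bc.

## Determinant features

Splice-site models are 12-mer position weight matrices (5 bp exonic +
GT/AG + 5 bp intronic; Laplace pseudocount 1) against the base composition
of internal GT/AG decoy windows; the match score is the summed per-position
log2 odds, and candidate sites must score > 2 (the published cutoff is
applied on this reconstructed scale, since the original scale is not
recoverable). Distance features per junction: junction size (intron
length), distance from the authentic site to the nearest internal GT/AG
and to the nearest PWM-passing candidate site, with frame flags
(`distance %% 3 != 0`) and explicit absent states (absent distances are
encoded as 150, beyond the largest plantable distance, with a presence
flag — classifiers see both).

Polypyrimidine and UA tracts: within the 50 intronic bases preceding the
acceptor AG (the terminal AG itself is excluded from the window), the
longest substring of length ≥ 5 with C+T (or A+T) composition strictly
> 0.85; polypyrimidine tracts must end within the last 10 bases of the
intron (as printed, the 10-base rule applies to polypyrimidine tracts
only); length ties break to the 3′-most hit. Branch sites: the last 100
intronic bases are scanned for heptamers matching NNYTRAY, NNCTYAC,
NNRTAAC or NNCTAAA (IUPAC), scored by mismatches to TACTAAC, and an intron
is reported only when its most downstream hit is (tied-)best — a
false-positive control that intentionally discards ambiguous introns.
Effect sizes are log2 odds ratios of AS frequency with vs without a
motif/tract, with a +0.5 pseudocount on all four cells only when a zero
cell occurs (so the printed example reproduces exactly). Hexamer
enrichment compares per-window presence between alternative and
constitutive 50-bp windows by hypergeometric test in both directions
(BH-adjusted), with backgrounds subsampled to 10,000 windows, seeded.

The feature matrix for one side (AltD or AltA) has one row per eligible
EEJ in genes carrying that event type: junctions with mean support below 5
reads, or carrying multiple AS types, or carrying a different single type,
are excluded. The minor (alternative-site) junction of an event is a
coordinate shadow of the authentic EEJ and is not an independent row.

## Classifiers

The splicing-code model is a binary classifier (alternative vs
constitutive) trained on the feature matrix after balancing: all
alternative rows are kept and constitutive rows are subsampled (seeded) to
the same count, so chance precision is 50%. Data are split 60/20/20
(stratified, sizes within one row per class); hyperparameters from a small
declared grid are selected by validation AUC and the winning configuration
is refit on the union of training and validation data. The reference
learner is a small feed-forward network (three hidden tanh layers, softmax
output, full-batch Adam, L2 penalty) — deterministic given the seed, which
is the contract the tests rely on; early stopping halts when the best
validation logloss has improved by less than 1% over the last ten
evaluation rounds. AUC is the rank-based (Mann–Whitney) estimate with ties
counting 0.5; multiclass AUC is the macro average of one-vs-rest AUCs.
Variable importance is permutation importance: the mean AUC drop over 20
seeded permutations per feature on held-out data.

The conservation model is the three-class analogue
(conserved/lost/gained, chance precision 33.3%) trained on cross-species
feature *differences* (first minus second species) plus flank similarity —
`(alignment length − gaps − mismatches)/alignment length` from a global
alignment of the combined flanks — and GC-content change. Because
conserved events are scarce, the 1:1:1 subsample is redrawn and the model
refit ten times; the repeat with the highest complete-dataset AUC is kept.

## Profiles and clustering

PSI profiles over conserved events are filtered to rows with
0.05 < PSI < 0.95 in at least one sample, correlated by Spearman
(pairwise-complete; pairs with fewer than 3 complete observations are
undefined), and clustered by average linkage (UPGMA) on 1 − ρ. The
machinery for presence/absence profiles uses the asymmetric binary
(Jaccard) distance over one-to-one orthologs after dropping genes with no
AS anywhere. Node support is the fraction of feature-bootstrap replicates
reproducing a node's leaf set; this replaces approximately-unbiased
p-values because the object under test is the topology (species- vs
tissue-level grouping), not the AU correction. Expression profiles use
Pearson on log2(TPM+1) after an expressed-gene filter (TPM > 5 in ≥ 1
sample); GC%/TMM normalisation is out of scope and documented as such.

## The synthetic world

`cohort_config()` states the world; `generate_cohort()` realises it
deterministically from one seed (stage-local streams derive from it by
fixed offsets). Genes are exon/intron mosaics with GT..AG introns, a
designed ATG→stop reading frame whose stop codon lies in the final exon,
splice-site consensus contexts written with 15% per-base noise on the
intron side of every authentic and planted alternative site, a planted
polypyrimidine tract (probability 0.8) ending within the last 10 intronic
bases, and a TACTAAC branch heptamer (probability 0.7) 20–32 bases
upstream of the acceptor. Defaults follow what the analysis assumes for a
plant cohort: 4–8 exons of 80–200 bp, introns 80–400 bp (inside the
mapping bounds), IR and AltA as the dominant planted types, PSI in
(0.1, 0.9), mean junction depth 50, two species at 2%/site divergence, AS
mostly species-specific (20% conserved), 12% of events PTC-coupled, and a
lognormal per-gene expression multiplier (sd 0.7) because homogeneous
depth would make read support a spurious label determinant.

Species are derived from a common ancestral gene by i.i.d. substitution —
codon-level (never creating stops) inside reading frames and planted
insert regions, base-level elsewhere, with splice dinucleotides, planted
alternative sites, consensus contexts and planted stop codons protected.
Events are planted per junction; when `determinant_signal` s > 0 the
planting probability is logistic in the alternative-site distance
(`plogis(qlogis(as_fraction) + s·(33 − d)/16)`), which reproduces the
distance-decay shape seen in real junctions and gives the classifiers a
recoverable signal. PTC+ minor isoforms carry an engineered in-frame stop
inside the inserted segment, placed so that ≥ one downstream exon
guarantees the 50-nt margin; every intent is verified post hoc with an ORF
scanner written independently of the ptc module, and the recorded truth is
the verified state. ES minor isoforms are always PTC− (a fusion-codon
construction was judged too fragile to guarantee; see the ledgered
limitation). In species where an event is absent (lost/gained), the
alternative-site dinucleotide is destroyed — this is what makes
cross-species presence/distance differences informative for the
conservation model.

What the generator does **not** emulate: raw reads and mapping noise,
indels (coordinates stay comparable across species), splice-graph
complexity beyond the four event types, NAGNAG acceptors, expression-AS
coupling, polymorphism. A green test therefore establishes that the
pipeline recovers what was planted under the stated statistical model —
not that the biology of any real cohort satisfies that model.

## Numerical choices and degenerate inputs

Probability vectors must sum to 1 within 1e-9. AS-carrying introns need
≥ 47 bp (41-bp minimum for the shorter isoform + 6-bp minimum alternative
distance); smaller lower bounds raise an infeasible-geometry error.
Duplicate junction rows merge by summing reads. Empty inputs yield empty,
headered outputs. Classifier features must be finite; the offending column
is named. All randomised procedures (subsampling, splits, permutations,
bootstrap, network initialisation) take explicit seeds and restore the
caller's RNG state.

## Known limitations

IR detection uses aggregate intronic coverage, so partially covered
introns and exitron-like cases are indistinguishable. The feature registry
implements the determinants named in the analysis (~13 distance/tract/
support features per side); the full supplementary feature lists are not
printed, so the registry is intentionally extensible. The e-value proxy is
calibrated for ranking, not for absolute BLAST-comparable significance.
The conservation model's signal in synthetic data comes from site
presence/distance differences; real lost/gained events may carry subtler
signals the generator does not emulate.
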