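---
title: "Methods: multi-factor neoantigen prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-factor neoantigen prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(truneo)
```

# Overview

`truneo` ranks candidate tumor neoantigens by integrating the steps of
the HLA class-I presentation pathway rather than binding affinity alone.
The pipeline consumes annotated somatic variants with per-read metric
summaries, HLA genotype calls from two callers in two samples, gene-level
TPM with per-variant RNA mutant-read counts, paired tumor/normal HLA
allele coverage, a reference proteome, and predictor scores for each
(peptide, allele) pair. It emits a ranked candidate table and a
high-confidence subset. This vignette documents the model, the defaults,
the numerical conventions, and what the synthetic tests do and do not
establish.

# Somatic variant filters

SNVs pass five conjunctive criteria: (1) tumor depth ≥ 10× with tumor
VAF ≥ 5% and normal VAF < 2%; (2) no other candidate SNV within 10 bp on
the same chromosome (strictly greater than 10 bp passes, computed among
raw pre-filter candidates); (3) median mutant-read mapping quality ≥ 30;
(4) median mutant-read base quality ≥ 20; (5) mutant reads not enriched
near the read ends. Criteria 3–5 additionally carry a Wilcoxon rank-sum
test at printed p cutoffs of 0.2, 0.05 and 0.1.

The printed criteria pair each threshold with a p cutoff but state
neither the comparison groups nor the direction. We compare
mutant-supporting against reference-supporting reads with the one-sided
alternative "mutant worse" (lower quality; smaller distance to the read
end) and *fail* a variant when the test is significant at the cutoff —
the reading under which the test screens out artifacts, mirroring
standard false-positive filtering practice (e.g. the VarScan/fpfilter
family). The "within 5 bp of the read end" phrasing is folded into the
definition of the distance-to-nearer-end metric; the test carries the
decision. InDels pass on depth ≥ 10×, tumor VAF strictly > 10% and
normal VAF strictly < 2%; the local-realignment step of the published
InDel protocol needs BAM access and is out of scope. Fusions are called
from RNA and carry no DNA-level filter.

The rank-sum p-value uses midranks for ties; for combined sample sizes
up to 25 the exact permutation distribution is computed by dynamic
programming over doubled midranks (so tied data remain exact), above
that the normal approximation with tie correction and continuity
correction. The exact path is verified in the tests against brute-force
enumeration of all rank assignments.

# HLA consensus and loss of heterozygosity

Genotypes are resolved per gene (A, B, C independently; the published
decision tree says "genotype" without granularity, and caller
discordance is typically gene-local): caller 1 agreeing between tumor
and normal wins; else caller 2 agreeing; else the two callers agreeing
on the normal sample; else caller 1's normal-sample call, flagged low
confidence.

LOH is tested per gene on shared polymorphic sites: the per-site, per-
allele coverage log-ratio r(a, s) = log2(tumor_unique / normal_unique)
is compared between the two alleles by a paired t-test; LOH is called at
p < 0.0002 and the lost allele is the one with the smaller mean ratio.
The test is two-sided ("allelic imbalance" does not specify a
direction); what constitutes a "site" is left abstract — sites are
paired observations. Sites with any zero count are dropped (a +0.5
pseudocount is available via `loh_pseudocount`); at least two usable
sites are required. Degenerate zero-variance differences are mapped to
p = 1 when all differences are zero and to p = 0 (with a warning) for a
constant non-zero shift. A homozygous gene yields `not_applicable`.

# Peptide enumeration

Missense substitutions yield a 21-mer context centred on the mutated
residue (truncated at protein ends); frameshifts yield 10 upstream
wild-type residues plus the full novel tail to the first stop (neoORF;
an immediate stop yields no candidates); in-frame indels 10 residues
each side of the altered segment; fusions 10 residues each side of the
protein-space junction. All 8–11-mer windows containing at least one
mutant residue are crossed with the patient's distinct alleles.

Fusion windows count as mutant only when they span the junction bond —
a window lying wholly inside one partner is that partner's wild-type
sequence. The published text does not state fusion scanning semantics;
this convention extends the 21-mer scan by analogy while keeping
wild-type windows out.

Candidates are filtered on (1) RNA expression of the mutation (mutant
reads ≥ 1), (2) self-homology — implemented as exact substring match of
the mutant peptide against the reference proteome, chosen for
determinism since the published criterion ("homologous to self") does
not define a similarity threshold; a near-match option is deliberately
deferred — and (3) predicted IC50, dropping peptides strictly above
500 nM (exactly 500 is retained, since only "larger than 500 nM" is
filtered).

Anchor-residue changes are substitutions at P2 or the C-terminal
position, the canonical class-I anchors, for all alleles; per-allele
anchor maps are a configuration extension point.

# Scoring

The composite score multiplies the combined processing score, the
expression score, the tumor VAF and the peptide weight (see the README
for the formulas). Numerical conventions worth recording:

* Expression quartiles are taken over genes with TPM > 0 in the tumor
  (configurable to all genes); the published strict inequalities leave
  boundary TPM values undefined, so values exactly at a quartile land in
  the middle band (0.66).
* The epitope taxonomy splits at 150 nM with exactly 150 assigned to the
  low-affinity classes; class weights are 1 / 0.6 / 0.5 / 0.25 / 0.15 /
  0.125. In-frame indel candidates, which the taxonomy does not name,
  are classed as non-anchor substitution-like (classes 3/6).
* The deep-learning weight's "MHC bindscore < 100" is read as IC50 <
  100 nM, consistent with the high-confidence filter; equality gaps
  (TPM exactly 15, IC50 exactly 100) fall through to the 0.125 branch;
  the presentation rank is computed within the patient's candidate set.
* VAF enters the product directly as the clonality term — the formula
  exposes nothing else.
* Ranking is by descending score with ties broken by ascending affinity
  then lexicographic peptide, making output order fully deterministic.
  Ranks are per (peptide, allele) pair; `collapse_by_variant()` keeps
  each variant's best candidate, which is the ranking used for top-k
  variant selection.
* High-confidence: VAF > 0.1, IC50 < 100 nM, TPM > 15 and the
  presenting allele not LOH-lost — all strict.

# Predictor adapters and the surrogate network

External predictors are consumed through a flat score table per
(peptide, allele); the shipped backends are a deterministic hash-seeded
mock (a pure function of peptide, allele and seed, supporting fixture
injection) and a fixture reader. The pipeline depends only on the score
table, never on the backend — an invariant the tests enforce by
replaying a run with the mock's output re-supplied as a fixture.

A toy surrogate of the learned presentation model is included: one-hot
peptide encoding padded to 11 positions, fully connected layers of 256
and 74 relu units, and a 74-wide per-allele embedding that gates the
output through a dot product and sigmoid, trained with binary
cross-entropy, a 10% validation split and early stopping when the
validation loss stops decreasing. The published architecture sentence is
ambiguous about what "74" counts; we use it for both the second layer
and the embedding width as written. The surrogate demonstrates the
architecture at desk scale on synthetic, separable data only; it is not
trained on mass-spectrometry data and makes no accuracy claim for real
pMHC presentation.

# Evaluation metrics

`recall_at_k` sums labeled-immunogenic candidates within each patient's
top k and divides by the cohort denominator (e.g. 19), matching the
published "true positives / 19" with per-patient top-10 lists; a
per-patient-mean variant exists behind a flag but is not the headline
metric. Unlabeled candidates occupy ranked slots. The random baseline is
the cohort positive fraction. The Elispot true-positive rate is
true / (true + false) over the validated top-k list. The TPM-threshold
sweep drops candidates below a minimal TPM and moves survivors up by the
number of dropped higher-ranked candidates in the same patient, so a
zero threshold is exactly a no-op.

The TCR expansion test is a one-sided Fisher's exact test (hypergeometric
tail) of each clone's post- vs pre-stimulation counts, with
Benjamini–Hochberg correction applied within each peptide culture (the
published text does not state the family; clones-within-culture is the
natural unit of one screening experiment). A clone is expanded when
q < 0.05, the unconditional sample odds ratio exceeds 1 (the reporting
style of the published clone table, not the conditional MLE), and the
clone is not significant in any other peptide culture. Percentages are
reported half-up to 2 decimals, matching the published precision.

# The synthetic generator: what green tests establish

`generate_synthetic_bundle(n, k, seed)` emulates the full input universe
at desk scale: variants with per-read metric vectors, expression,
RNA mutant reads, four-way HLA calls, LOH coverage, a proteome and a
predictor fixture. The k planted variants are drawn inside the published
high-confidence operating region (VAF 0.15–0.6, TPM 40–200, designed
IC50 20–80 nM, strong cleavage/TAP/presentation scores, no LOH); the
n − k decoys cycle through seven failure modes — sub-threshold VAF and
TPM, silent consequence, depth failure, base-quality failure, RNA
non-expression, a low-VAF indel, a low-expression fusion. Read-level
metrics of passing variants draw mutant reads slightly *better* than
reference reads, so the one-sided "mutant worse" tests are never
significant by construction. The generator chooses these values once as
a realistic stated world (depths of 50–300× reflect exome practice;
mock affinities are log-uniform over 10–10000 nM as IC50s are
log-distributed); they are not tuned against test outcomes.

Because planted and decoy score regions are separated by construction, a
green planted-recovery test establishes that the plumbing — filters,
enumeration, joins, score arithmetic, ranking, LOH exclusion — is
correct end to end. It does *not* establish predictive accuracy on real
tumors: real predictor scores are not fully separated, real proteomes
contain near-homologs, expression and clonality are correlated, and the
published patient-level filter counts (451 → 313 → 254 → 116 → 10)
depend on raw sequencing data and external predictor binaries that are
out of scope here.

# Known limitations

* Class-II (15-mer+) neoantigens are not scored.
* Homology is exact-substring; similarity-based self-filtering is not
  implemented.
* The LOH test operates on abstract paired sites without purity/ploidy
  adjustment.
* The published interchange format between pipeline stages is not
  specified; the TSV/VCF dialect here is an artifact convention, and the
  configuration document is JSON.
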