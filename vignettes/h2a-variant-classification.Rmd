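---
title: "Classifying histone H2A variants from sequence signatures"
author: "h2avariants maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying histone H2A variants from sequence signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(h2avariants)
```

## The problem

Histone H2A is the most variable of the core histones. Beyond the
replication-coupled (RC) form, eukaryotes carry replication-independent
variants — H2A.X (marked by a terminal SQ[D/E][F/Y] motif whose serine is
phosphorylated at DNA double-strand breaks), H2A.Z (a LEYLTAEVLELAGNA
signature in the α2 helix, an L1 loop one residue longer, a docking domain
one residue shorter), the plant variants H2A.W (RY[A/S][Q/K] L1 loop,
terminal KSPKK) and H2A.M (RYA[Q/K] L1 loop), and macroH2A (a long
macro-domain C-terminal extension). Algal genomes additionally carry three
recently described classes: H2A.N (an N-terminal tail extended by roughly
30 residues, with a divergent QSLRA αN helix and a PLRP tail motif), H2A.O
(an H2A.Z-type α2 helix combined with a lysine/glycine-rich N-tail and a
terminal SQDY), and H2A.E (the H2A.Z-type α2 helix without those extras,
typically encoded intronless inside histone gene clusters).

Because expression-based classification (S-phase coupling) is not available
for most algae, classification must rest on protein sequence signatures
plus corroborating genomic and expression evidence. This package implements
that programme as a reusable, testable pipeline:

1. **Fold anatomy** — locate the histone fold and delimit the regions
   (N-tail, αN, α1, L1, α2, L2, α3, docking domain, C-tail) on which all
   features are defined.
2. **Feature extraction** — the seven classification features: motif
   analysis of the αN helix, L1 loop, α2 helix, acidic patch and C-terminal
   ending, plus the lengths of the L1 loop and docking domain; auxiliary
   tail-composition statistics complete the vector.
3. **Classification** — an explicit rule cascade with a full evidence
   trace per call.
4. **Evidence layers** — consensus/conservation profiles, gene context
   (introns, histone clusters, anchored micro-synteny), expression
   specificity, PTM-peptide assignment, and a neighbor-joining monophyly
   check.
5. **Synthetic data** — generators that plant all of the above structure,
   so each stage is validated against known truth.

## Fold anatomy by profile anchoring

Regions are delimited by aligning each mature protein (initial methionine
stripped) to a reference position-frequency profile covering αN through the
docking domain. The alignment is *global over the profile* and *local over
the sequence*: every profile column must be matched or explicitly deleted,
while unaligned sequence ends are free and become the N- and C-tails.
Scoring is log-odds, `log2(freq(residue, column) + 1e-3) − log2(0.05)`,
with affine gap costs (open 11, extend 1, the BLAST defaults). `X` residues
score zero everywhere. Dynamic programming is exact; an independently
written naive implementation is used as an oracle in the tests.

The shipped profile is built by stacking the fold regions of the nine class
templates (shorter regions right-padded) and converting residue counts to
frequencies with a pseudocount of 0.02. Columns where classes agree are
sharply peaked; genuinely divergent columns are flat and therefore penalize
no class unduly. The fold is called detected when the alignment score
reaches 0.6 × the profile-consensus self-score — a scale-free threshold
that all nine templates clear with a worst-case margin of about 30%, while
random sequences of the same length fall far below it. Sequences shorter
than 60 residues are never assigned a fold.

Two conventions deserve note. First, where the αN helix begins relative to
the N-tail differs between variants and is not uniquely defined by
alignment; the profile's αN interval is a documented convention. Second,
region lengths are measured on the query after alignment, so a terminal
region that is one residue shorter than the profile (the H2A.Z docking
domain) can be absorbed into the adjacent free tail when the flanking
residue is compatible with the final profile column; the classifier
therefore relies on the docking histidine count and acidic-patch
composition — which map through the alignment — rather than on a ±1 length
difference.

## The classifier

The decision cascade mirrors how the signatures are combined in practice:

1. *fold missing* → `unclassified`;
2. C-tail ≥ 100 residues → `macroH2A` (macro-domain detection by length
   only; no homology model);
3. α2 helix within 2 mismatches of LEYLTAEVLELAGNA → **Z family**:
   `H2A.O` if the N-tail is K/G-rich *and* the sequence ends SQDY;
   `H2A.Z` on a 2-of-3 vote over {two docking histidines, acidic patch
   opening with G, terminal KKRI}; otherwise `H2A.E`;
4. otherwise: terminal SQ[D/E][F/Y] (or SQDY) → `H2A.X`; terminal KSPKK
   with a W/M-type L1 → `H2A.W`; RYA[Q/K] L1 → `H2A.M`; QSLRA αN within
   1 mismatch *and* N-tail ≥ 45 residues → `H2A.N`; a VLLPKK docking
   ending or a lysine-rich C-tail (K fraction ≥ 0.3) → `RC_H2A`;
   `unclassified` as the fallback.

Rule order encodes structural-family membership first (the α2 helix), then
the C-terminal / L1 / αN specializations, with RC H2A as the residual.
Testing SQDY before the general SQ[D/E][F/Y] is what keeps H2A.O — which
carries the H2A.X-type ending without being its orthologue — from ever
being called H2A.X. "K/G-rich" is operationalized as a longest K/G run ≥ 6
or a K+G fraction ≥ 0.5 over an N-tail of at least 10 residues; "at the
very end" means exactly the last 4 residues (5 for KSPKK), with no offset
allowance. All thresholds are `classifierConfig()` parameters. Every rule
evaluated is recorded in an ordered evidence trace, and each call carries a
tier: `strong` when every defining rule fired, `weak` when it rested on a
single rule. A hook for subtyping H2A.E is deliberately left open: the
class is known to split into several subtypes by αN/L1 consensus, but the
sub-consensus sequences are not modelled here.

## Synthetic data: what it emulates, and what it does not

The generator ships one hand-built template per class (≈115–155 residues;
macroH2A ≈ 217 with a 112-residue C-tail; H2A.N ≈ 155 with a 48-residue
N-tail). Published descriptions of these classes specify consensus motifs
and qualitative region properties, not full-length template sequences, so
the templates are a modelling choice: each is assembled region by region so
that its diagnostic signatures are planted verbatim and its non-signature
positions are plausible histone-like sequence. One deliberate departure
from nature: real RC H2A differs from the H2A.Z α2 signature by a single
residue, which would make the 2-mismatch family split meaningless; the
templates place all non-Z-family α2 blocks at Hamming distance 4 so the
family decision is well-posed. Conclusions about the classifier's behaviour
on real proteins near the α2 tolerance boundary cannot be drawn from these
simulations.

The mutation model is i.i.d. substitution (uniform over the 19 alternative
residues) outside signature positions, plus length-1 indels at region
junctions only. Masking signature positions keeps the planted class truth
well-defined at any substitution rate — so recovery experiments measure the
pipeline's behaviour under background divergence, not signature decay.
Benchmark conditions used throughout the tests: substitution rate 0.05,
indel rate 0.05, 50 sequences per class for recovery, 5 per class for the
monophyly check.

Gene neighborhoods are generated with an anchor gene, four conserved
flankers per side, and optional planted perturbations: intercalated
novel-orthogroup genes between flankers, and contig breaks that move a
suffix of the downstream flankers to a second contig. The contig cut and
the intercalations are planted in disjoint inter-flanker gaps so every
planted break is individually recoverable (the detector reports one break
per gap). Histone cluster layouts plant intronless clustered genes with a
tandem H2A–H2B pair, against intron-bearing isolated variant genes on
separate contigs.

Expression tables are log-normal: expressed cells around TPM 50 (log-sd
0.25), silent cells around TPM 0.3, so the planted patterns separate
cleanly around the filter threshold of 2 (strictly greater than, applied to
group means — "above 2 in at least one condition"). Condition-responsive
genes carry a 4-standard-deviation shift on the log scale in the target
group. Real RNA-seq has heavier tails, correlated replicates and
compositional constraints; passing these tests demonstrates the logic of
the filters, not robustness to real-data noise.

## Consensus and conservation

`buildConsensus()` reports, per alignment column, the modal residue over
non-gap symbols and a conservation class: *conserved* when the modal
frequency is at least 0.9, *semi-conserved* when one residue property group
(KRH, DE, ST, FYW, ILVM, AG, NQ, C, P) reaches 0.9, *variable* otherwise.
The thresholds and the grouping are documented conventions — the thresholds
behind published black/red consensus lettering are not stated anywhere.
Gaps are excluded from the denominator, with per-column occupancy reported
separately; logo matrices (`columnFrequencies()`) therefore have columns
summing to exactly 1 unless a column is all-gap, in which case it is
emitted as a flagged zero column.

The bundled multiple aligner exists so tests need no external MSA engine.
It is a center-star procedure (center = maximal total pairwise score,
pairwise Needleman–Wunsch under BLOSUM62, merged by the
once-a-gap-always-a-gap rule) rather than a guide-tree progressive aligner:
for within-class sets at the benchmark noise levels the two give equivalent
column structure, and center-star is considerably simpler to verify. For
cross-class distance matrices the package instead uses per-pair global
alignments (`classMonophyly()`), which are robust to the highly divergent
tails that defeat any single reference row.

## Gene context and micro-synteny

Intron counts come straight from GFF3 exon rows (`exon_count − 1`).
Cluster detection chains histone-family genes along a contig with a maximum
inter-gene gap of 20 kb and calls a chain a cluster when it spans at least
two distinct histone families; both values are conventions (co-localization
on a contig is the only published definition) and are arguments. Tandem
H2A–H2B adjacency is flagged within clusters.

`compareNeighborhoods()` takes orthogroups as *input* (any orthology
pipeline can supply the map; genes without a mapping become singleton
orthogroups). For each target genome it locates the anchor orthogroup,
flips the neighborhood when the anchor strand differs from the reference
(so upstream/downstream remain comparable), finds each reference flanker
genome-wide (nearest copy to the anchor when several exist), and annotates
breaks between consecutive shared flankers: *intercalated* when non-member
genes sit between them on one contig, *contig* when they lie on different
contigs. `order_score` is the longest-common-subsequence length of the
reference flanker order against the target's anchor-contig gene order,
divided by the number of reference flankers — flankers dispersed to other
contigs therefore depress the score, which is exactly the dispersal
phenotype of interest. Multi-copy anchors are compared against every copy
and the best order score is reported with a `multi_copy` flag. No
quantitative assembly-quality exclusion is applied; per-genome flanker
coverage is reported and exclusion is left to the user.

## Expression logic

The filter keeps a gene when its group-mean TPM strictly exceeds 2 in at
least one group; a gene at exactly 2.0 is removed. Specificity calls follow
from the same per-group means. The two-condition comparison is a two-sided
equal-variance Student's t test on raw TPM replicates with a significance
star at p < 0.05 and no multiple-testing correction of the star itself — a
Benjamini–Hochberg column is emitted as supplementary output. Genes with
zero variance in both groups and equal means return t = 0, p = 1. The
threshold is absolute (TPM units), so rescaling the matrix changes the
calls by design. Under the generator's null the star fires at a rate
statistically indistinguishable from 0.05 (within three binomial standard
deviations over 10,000 genes), which the acceptance suite verifies.

## Clade sanity layer

The phylogenetic layer is deliberately lightweight: p-distances,
neighbor-joining (negative branch lengths clamped to zero), rooting on the
H2A.Z leaves, and exact monophyly testing. It recovers additive distance
matrices exactly and, at benchmark noise, every planted class forms a
clade. It is a distance-based sanity check for synthetic data — not a
substitute for maximum-likelihood inference with bootstrap support, which
is out of scope here, and no support values are produced.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; 1-based inclusive only in
  GFF3 and exported region tables.
* Motif scoring windows: the α2 signature is scanned over the region ±3
  residues, the αN motif over the region ±2; a region too short for a full
  window scores the maximal distance (15 and 5 respectively).
* Empty tails give zero-valued composition statistics and `cterm_class`
  `none`.
* Neighbor-joining ties and alignment-score ties are resolved
  deterministically (first-maximum), so every result is reproducible; all
  generators derive independent RNG streams from one master seed by stable
  hashing, and identical configuration plus seed gives byte-identical
  outputs, verified by manifest MD5 comparison.
* Problem sizes used by the validation suite (chosen to exercise each
  property at meaningful scale): 1,000 random sequences per signature
  pattern, 450 sequences for noisy recovery, 100 random instances each for
  the alignment/synteny/cluster/tree oracles, 10,000 genes for null
  calibration.

## Known limitations

* Orthology inference, homolog discovery, MSA engines, ML phylogenies,
  structure prediction and de-novo PTM prediction are all out of scope;
  the package consumes their outputs where relevant.
* The classifier's tolerances were chosen for well-separated synthetic
  classes; on real proteins the α2 tolerance in particular interacts with
  the RC/H2A.Z single-residue difference noted above and should be tuned
  with an expert eye.
* macroH2A detection is length-only and will mislabel any H2A fused to a
  long non-macro C-terminal extension.
* Synteny comparison assumes the orthogroup map is correct; mapping errors
  surface as spurious intercalation breaks.

## A worked example

```{r example, eval = FALSE}
set <- makeBenchmarkSet(syntheticSpec(
  stats::setNames(rep(5L, 9), h2aClasses()),
  substitution_rate = 0.05, indel_rate = 0.05, seed = 1))
fvs <- extractFeatureTable(set)
res <- classifyBatch(fvs)
confusionMatrix(res$calls, truthLabels(set))
```
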