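# h2avariants

Signature-based classification and characterization of histone H2A variants.

## The problem

Histone H2A is the most variable core histone. Besides the
replication-coupled (RC) form, genomes carry replication-independent
variants with diagnostic sequence signatures: H2A.X ends in SQ[D/E][F/Y]
(the serine is phosphorylated at DNA double-strand breaks); H2A.Z carries a
LEYLTAEVLELAGNA signature in the α2 helix, a one-residue-longer L1 loop and
a shorter docking domain; plant H2A.W and H2A.M are marked by RY[A/S][Q/K]
and RYA[Q/K] L1 loops; macroH2A carries a long macro-domain C-tail. Algal
genomes additionally harbor H2A.N (an N-tail extended by ~30 residues with
QSLRA/PLRP motifs), H2A.O (H2A.Z-type α2 plus a K/G-rich N-tail and
terminal SQDY) and H2A.E (H2A.Z-type α2 without those extras, encoded in
histone gene clusters). Where expression timing cannot be measured,
classification must rest on protein signatures plus genomic and expression
evidence — this package implements that programme end to end:

* **fold anatomy** — profile-anchored delimitation of N-tail, αN, α1, L1,
  α2, L2, α3, docking domain and C-tail (affine-gap DP, global on the
  profile, local on the sequence);
* **features** — the seven classification features (αN, L1, α2, acidic
  patch and C-terminal ending motifs; L1 and docking lengths) plus tail
  composition statistics and PTM-peptide assignment;
* **classifier** — an auditable rule cascade over the feature vector with
  a full evidence trace per call;
* **evidence layers** — Jalview-style consensus/conservation profiles,
  intron counts, histone-cluster detection, anchored micro-synteny with
  break annotation, TPM expression filtering and specificity calls,
  neighbor-joining monophyly checks;
* **synthetic data** — generators that plant all of the above structure
  (labelled protein sets, gene neighborhoods with planted breaks,
  expression matrices with planted patterns) so every stage is testable
  without external data.

## A worked example

```r
library(h2avariants)

set <- makeBenchmarkSet(syntheticSpec(
  stats::setNames(rep(5L, 9), h2aClasses()),
  substitution_rate = 0.05, indel_rate = 0.05, seed = 1))
res <- classifyBatch(extractFeatureTable(set))
res$counts
#>       RC_H2A        H2A.X        H2A.Z        H2A.E        H2A.O        H2A.N
#>            5            5            5            5            5            5
#>        H2A.W        H2A.M     macroH2A unclassified
#>            5            5            5            0
```

Every call carries its evidence trace:

```r
res$evidence$H2AO_001
#>               rule fired        observed
#> 1    fold_detected  TRUE           FALSE
#> 2      macro_ctail FALSE              11
#> 3 alpha2_signature  TRUE               0
#> 4    kg_rich_ntail  TRUE run=13,frac=0.7
#> 5      cterm_O_end  TRUE           O_end
```

The 45 noisy proteins (5% substitutions outside signature positions, 5%
junction indels) are all recovered into their planted classes; the trace
shows *why*: here the α2 helix matched the H2A.Z signature exactly
(0 mismatches), the N-tail carried a 13-residue K/G run, and the sequence
ended in SQDY — the combination that defines H2A.O and keeps it from being
mistaken for H2A.X despite the shared C-terminal motif.

A thin CLI over the same functions is provided in `inst/scripts/h2a.R`
(subcommands `synth`, `anatomy`, `classify`, `run`).

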