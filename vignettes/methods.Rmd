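---
title: "Methods: discovering RRNPPA peptide quorum-sensing systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering RRNPPA peptide quorum-sensing systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Firmicutes regulate sporulation, competence, virulence and phage
lysis-lysogeny decisions through cytoplasmic quorum-sensing (QS) receptors of
the RRNPPA family — Rap, Rgg, NprR, PlcR, PrgX, AimR and ComR. Each receptor
binds a short peptide pheromone matured from a precursor (propeptide) gene
that typically sits immediately up- or downstream of the receptor gene. The
subfamilies share low sequence identity, the propeptide genes are tiny and
usually unannotated, and many systems live on mobile genetic elements (MGEs):
plasmids, prophages and phage-plasmids. `rrnppa` packages the discovery and
classification workflow for such systems:

1. **Receptor search** — per-subfamily profile models scanned over a
   proteome, with coverage and E-value gates and family disambiguation rules.
2. **Propeptide calling** — small-ORF detection in the receptor gene flanks,
   a heuristic export-signal score, and known-peptide fallbacks for the
   SHP-class families.
3. **Architecture analysis** — propeptide length outliers, mature-peptide
   (pseudo)repeats, sibling gene comparison.
4. **Context and role** — chromosome/prophage/plasmid/phage-plasmid
   assignment and eavesdropper/single/chatterer/multi-message classification.
5. **Structure comparison** — Kabsch superposition of conserved TPR blocks,
   RMSD matrices, interaction networks, UPGMA/NJ dendrograms.

A synthetic-genome generator with planted ground truth replaces the
genome-database survey, so the whole pipeline is exercised and measured
without external data.

# Receptor models and calibration

Seed alignments are condensed into position-specific scoring models:
columns whose gap fraction exceeds 0.5 are dropped and the log-odds of
residue $a$ at a retained column is

$$ s(a) = \log \frac{p_a + w\,b_a}{(1 + w)\, b_a} $$

with $p_a$ the observed (weight-normalized) frequency, $b_a$ a fixed
background (Robinson–Robinson-style composition) and pseudocount weight
$w = 1$. Proteins are scored by local dynamic programming with uniform
affine gap penalties (open 11, extend 1 in log-odds units). This is a
deliberate simplification of a profile HMM — there are no position-specific
insert/delete states — and the difference is absorbed by an explicit
calibration: the best scores of 500 i.i.d. background decoys are fitted with
a Gumbel distribution by maximum likelihood, and E-values are
$P(S \ge s) \times N$ for database size $N$. Coverage is the fraction of
model columns consumed by match states on the optimal local path.

Default gates are E-value $\le 10^{-5}$ and coverage $\ge 0.6$, identical for
every family and overridable per family. The per-family numeric thresholds of
the original survey are not published; coverage is used as the primary gate
because hit classes separate most sharply on it.

Two disambiguation rules mirror the family structure. Rap and NprR share
their 3HB/TPR core, so the Rap model also matches NprR proteins while the
NprR model (which additionally spans the HTH block missing from Rap) does not
match Rap above the coverage gate: any protein passing both gates is classed
NprR and flagged `reassigned_from = "Rap"`. The Rgg model also matches
MutR/GadR-like regulators that have no QS function, so an Rgg assignment is
kept only when a QS propeptide is confirmed next to the gene.

# Propeptide calling

For each receptor gene the 50 terminal bases are concatenated with 1,000
additional bases beyond the gene, in the transcription direction, on both
sides (windows truncate at linear replicon ends and wrap on circular ones).
All six frames of each window are scanned for ORFs of 20–120 aa starting at
ATG/GTG/TTG, keeping the longest ORF per stop codon. Both window strands are
searched (the original procedure does not state this; searching both is the
more conservative choice and is the package's decision). Candidate ORFs
overlapping the receptor gene beyond the shared 50 nt are discarded.

Each ORF is scored by a documented heuristic standing in for the neural
signal-peptide predictors, over the classic n/h/c architecture:

* **n-region** (weight 0.4): a KK duplet within the first 12 residues.
* **h-region** (weight 0.4): the maximum 8-residue Kyte–Doolittle window
  mean, gated at 3.0 and saturating at 4.0. The gate is deliberately strict:
  ORFs translated from random DNA are hydrophobic-rich (about a third of
  sense codons encode F/L/I/V/M/A), and a softer gate floods eavesdropper
  flanks with spurious calls. Strongly hydrophobic h-regions (Leu/Ile runs)
  sit well above it; weakly hydrophobic real signals would be missed — a
  sensitivity/precision trade this package resolves toward precision.
* **c-region** (weight 0.2): a small–X–small (A/G/S) motif within 10
  residues after the h-region; the cleavage point is placed after it. A
  lipobox (`[LVI][ASTG][GA]C`) around the h-region end overrides to the SPII
  (lipoprotein) pathway with cleavage before the invariant Cys.

ORFs at score $\ge 0.6$ are primary calls; if a window pair yields none, the
fallback cutoff 0.25 is applied, mirroring the secondary-predictor cutoff of
the original procedure (the numeric value carries over; the score scale is
this package's own). The mature peptide defaults to the C-terminal 7 residues
unless repeat analysis refines it.

The SHP-class families (Rgg, ComR, PrgX) encode short peptides with no
canonical signal. For them a known-peptide route always runs **in addition**
to the signal cascade — upstream six-frame translation for Rgg/ComR, and the
whole plasmid for PrgX (whose pheromone genes are usually far from the
receptor gene): peptides longer than 10 aa between stop codons are aligned to
each known mature peptide by exact dynamic programming and kept at identity
> 80% over > 85% coverage of the known peptide. Running this route
unconditionally (rather than only when the signal cascade is empty) is a
deliberate deviation: a spurious fallback ORF call must not mask a real
signal-less pheromone.

# Repeats, roles and context

The mature-peptide repeat detector takes the C-terminal 5-mer as seed and
scans the propeptide greedily left-to-right for non-overlapping occurrences
with at most 1 mismatch (the field describes "pseudorepetition" without a
numeric similarity; 1-of-5 is the package default). Length outliers per
family use Tukey fences on type-7 quartiles; the quartile method matters for
the fences and is therefore fixed and documented. Group length differences
use a tie-corrected Kruskal–Wallis test.

Roles are a total function of the mature-peptide copies of a system's calls:
no call → *eavesdropper*; at least two identical copies (within one
propeptide or across sibling genes) → *chatterer*, which takes precedence;
at least two distinct matures → *multi-message*; otherwise *single*.
Context is *plasmid*/*phage-plasmid* from replicon-level labels, *prophage*
when the gene is **fully contained** in a prophage interval (boundary
handling is unstated in the field; full containment is the package's rule,
and a gene straddling a boundary is chromosome), else *chromosome*.
Genus-normalized summaries weight each genus equally; the exact normalization
used in published distribution plots is unstated, so the mode is selectable
and labelled in the output.

# Structure comparison

Conserved TPR blocks are compared as CA-only coordinate selections (atom
sets beyond CA are not needed for backbone RMSD and are not parsed).
Superposition is the closed-form Kabsch solution (proper rotation enforced);
the RMSD matrix feeds a thresholded interaction network (default threshold:
the median off-diagonal distance, always reported) and UPGMA or
neighbor-joining dendrograms with optional midpoint rooting. Labels are
sorted before clustering so ties break deterministically and results are
invariant to input order. Greedy identity/coverage clustering (default
0.95/0.95, longest-first) provides the de-redundancy step used before
sequence analyses.

# The synthetic world

`sim_config()` fixes the simulation defaults, which are the package's stated
world rather than tunable dials:

* 7 families × 20 systems, receptor mutation rate 0.1 vs fixed toy consensus
  sequences (~290–430 aa) with a shared Rap/NprR core block reproducing the
  one-way model confusion.
* 20% eavesdroppers (never Rgg, whose family definition requires a
  pheromone); 10% sibling propeptide gene pairs (second gene on the opposite
  flank, mature differing at position 5 or 6 in most pairs); 30% of
  propeptides multi-copy with up to 6 tandem mature copies, 30% of those
  carrying one single-mismatch pseudorepeat copy; 10% SPII export.
* 15% of systems on plasmids (PrgX always; a quarter of plasmid draws
  labelled phage-plasmid), 20% of chromosomal systems inside planted
  prophage intervals — roughly the MGE share reported for real surveys.
* Background DNA i.i.d. uniform over ACGT (the simplest null for E-value
  calibration); coordinates 0-based half-open; propeptide ORFs are planted
  with an in-frame stop immediately before their start codon so the
  longest-ORF-per-stop rule recovers exactly the planted coordinates;
  receptor DNA uses a fixed codon per amino acid.
* Mature peptides are drawn from a polar-biased alphabet (max Kyte–Doolittle
  1.8) so that a mature region can never outscore a planted h-region; SHP
  peptides get a polar body and no KK duplet, emulating "no canonical
  signal". The SHP gene model (short, upstream, weak signal) is a stand-in:
  the real architecture of these genes is not described beyond being small
  and differently exported.

What a green test does establish: the pipeline recovers planted receptors,
propeptide coordinates, pathways, contexts and roles from sequence alone at
the stated rates, and its statistics (E-values, Kruskal–Wallis, chi-square,
Kabsch RMSD) are calibrated against independent oracles. What it does not
establish: performance on real genomes — real seed alignments, codon usage,
gene density, overlapping features, diverged propeptides and real
signal-peptide variability are all outside the synthetic world, and the
signal heuristic is not a substitute for the neural predictors it stands in
for.

# Numerical choices and edge cases

* Gumbel calibration by maximum likelihood (profile likelihood in the scale
  parameter, solved by bisection); calibration refuses degenerate decoy
  score variance and fewer than 500 decoys.
* Ties in family assignment break by (E-value, family name); ties in
  clustering by (length, name); dendrogram label order is pre-sorted.
* `kruskal_wallis()` defines H = 0, p = 1 when all values are identical.
* Quartiles are type 7 (linear interpolation); families with fewer than 4
  propeptides get undefined fences and contribute no outliers.
* Genes shorter than 50 nt contribute their whole length to the flank window
  (with a warning); windows on circular replicons wrap; replicons are linear
  unless marked circular.
* Proteins shorter than 15 aa never score as signals; shorter than 10 aa are
  rejected by the repeat detector.

# A worked example

```{r, eval = FALSE}
library(rrnppa)
bundle <- generate_genome(sim_config(systems_per_family = 3, seed = 11))
res <- run_qs_pipeline(bundle, seed = 5)
head(res$systems)
summarize_systems(res$systems)
```

The acceptance criteria for this pipeline (exact enrichment chi-square,
ORF-finder equivalence with a brute-force oracle, planted-system recovery
rates, Rap/NprR disambiguation, repeat-detector exactness, Kabsch and
dendrogram exactness, and statistical calibration) are implemented one-to-one
in `tests/testthat/test-acceptance.R`.
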