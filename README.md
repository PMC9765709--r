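# rrnppa

Discovery and classification of RRNPPA peptide quorum-sensing systems in
Firmicutes-like genomes.

## The problem

Firmicutes control sporulation, competence, virulence and phage
lysis-lysogeny decisions through cytoplasmic quorum-sensing receptors of the
RRNPPA family — **Rap, Rgg, NprR, PlcR, PrgX, AimR, ComR**. Each receptor
binds a short peptide pheromone cut from a precursor (propeptide) whose gene
usually sits immediately up- or downstream of the receptor gene. Finding
these systems is hard: the subfamilies share little sequence identity, the
propeptide genes are tiny (20–120 aa) and typically unannotated, and many
systems ride on mobile genetic elements (plasmids, prophages,
phage-plasmids). Some systems carry several copies of their mature peptide
("chatterers"); others carry none and respond to peptides made elsewhere
("eavesdroppers").

`rrnppa` implements this discovery workflow for bioinformaticians studying
peptide QS:

* **Receptor search** — per-subfamily position-specific scoring models
  (log-odds `log((p_a + w b_a)/((1+w) b_a))` per column), local alignment
  with affine gaps, Gumbel-calibrated E-values (`E = P(S >= s) * N`),
  coverage/E-value gates, and the family disambiguation rules (Rap+NprR →
  NprR; Rgg requires a confirmed propeptide).
* **Propeptide calling** — 50 + 1,000 nt strand-aware flank windows,
  six-frame small-ORF detection with alternative starts (ATG/GTG/TTG), a
  heuristic n/h/c signal-peptide score with SPI/SPII (lipobox) assignment, a
  0.25 fallback cutoff, and known-peptide searches for the signal-less
  SHP-class families (six-frame upstream for Rgg/ComR, plasmid-wide for
  PrgX).
* **Architecture** — Tukey-fence length outliers, C-terminal 5-mer
  pseudorepeat detection with 1 mismatch tolerance, sibling propeptide
  comparison, tie-corrected Kruskal–Wallis tests.
* **Context & role** — chromosome / prophage / plasmid / phage-plasmid
  assignment (full containment for prophages) and eavesdropper / single /
  chatterer / multi-message classification; the 1-df MGE-enrichment
  chi-square.
* **Structure** — Kabsch superposition of conserved TPR blocks, RMSD
  matrices, threshold networks, UPGMA/NJ dendrograms with midpoint rooting,
  and greedy 95/95 identity/coverage sequence clustering.
* **Synthetic genomes** — a generator that plants complete systems
  (receptors from family consensus models, propeptides with KK-duplet
  n-regions, hydrophobic h-regions, AQA or lipobox cleavage sites, tandem
  mature copies, sibling genes, eavesdroppers, prophage/plasmid context)
  with full ground truth, so every stage is testable without external data.

## Worked example

```r
library(rrnppa)
bundle <- generate_genome(sim_config(systems_per_family = 3, seed = 11))
res <- run_qs_pipeline(bundle, seed = 5)
head(res$systems[, c("receptor_id","family","context","role","n_propeptides")])
#>   receptor_id family    context         role n_propeptides
#> 1    cds_0002   AimR chromosome eavesdropper             0
#> 2    cds_0004   AimR   prophage    chatterer             1
#> 3    cds_0008   AimR   prophage       single             1
#> 4    cds_0014   NprR chromosome    chatterer             1
#> 5    cds_0015   NprR chromosome    chatterer             1
#> 6    cds_0018   NprR chromosome eavesdropper             0
```

Each row is one discovered receptor with its genomic context and signaling
role: `cds_0002` is an AimR receptor with no detectable pheromone gene (an
eavesdropper), while `cds_0004` sits in a prophage and makes multiple
identical copies of its mature peptide (a chatterer).

Propeptide architecture is inspectable directly:

```r
pp <- generate_propeptide("NprR", n_copies = 3, variant_position = 5,
                          pathway = "SPI", seed = 8)
pp$protein
#> [1] "MKKTSQIIILILLLGAQANNDQKQKNNDQYQKNNDQYQK"
detect_repeats(pp$protein)[c("copy_count", "classification")]
#> $copy_count
#> [1] 3
#> $classification
#> [1] "pseudorepeated"
```

The protein reads like a real precursor: `MKK` n-region, Leu/Ile h-region, a
conserved Gly, an `AQA` cleavage motif, then three tandem mature copies, one
carrying a single substitution (a pseudorepeat). The enrichment test used for
SPII propeptides in mobile elements:

```r
r <- enrichment_chi_square(59, 211, 0.14)   # 59 of 211 SPII calls in MGEs vs 14% expected
sprintf("chi2 = %.2f, p = %.2e", r$chi2, r$p)
#> [1] "chi2 = 34.16, p = 5.07e-09"
```

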