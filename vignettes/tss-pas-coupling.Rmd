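---
title: "Quantifying TSS-PAS coupling from full-length long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying TSS-PAS coupling from full-length long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isocoupler)
library(data.table)
```

## The model

A full-length cDNA read reports one transcript's complete anatomy: its
transcription start site (TSS), its exon-junction chain, and its
cleavage/polyadenylation site (PAS). For a gene with $r$ TSSs and $c$
PASs, the full-length reads form a joint count table $O \in
\mathbb{N}^{r \times c}$. Under the null hypothesis that promoter choice
and 3′ end choice are independent, the expected counts conditional on
the margins are $E_{ij} = O_{i\cdot} O_{\cdot j} / N$, and departures
are measured by

$$X^2 = \sum_{ij} \frac{(O_{ij} - E_{ij})^2}{E_{ij}}, \qquad
  r_{ij} = \frac{O_{ij} - E_{ij}}{\sqrt{E_{ij}}}.$$

Because per-gene tables are small and sparse, the $\chi^2$ asymptotics
are unreliable; significance is assessed by Monte Carlo. The null
distribution samples tables *uniformly with both margins fixed*
(Patefield's algorithm, `stats::r2dtable`), and the estimate is

$$\hat p = \frac{1 + \#\{X^2_{(b)} \ge X^2_{\mathrm{obs}}\}}{B + 1},$$

which is never zero and is biased upward by at most $1/(B+1)$.
Benjamini–Hochberg correction is applied across genes. Conditioning on
both margins is the standard Monte-Carlo chi-squared convention; a
multinomial null drawn from $E/N$ (fixing only $N$) is available via
`test_tss_bias(..., null = "multinomial")` because the original
analysis does not state which was used — on our fixtures the two agree
to within Monte-Carlo error, and fixed margins is the default as the
more conservative, exactly-enumerable choice (the acceptance oracle
enumerates fixed-margin tables).

A cell is a **dominant promoter** pair when three conditions hold: the
gene is transcriptionally biased (adjusted $p < \alpha$), the TSS
contribution $O_{ij}/O_{\cdot j}$ strictly exceeds 0.20, and the PAS
contribution $O_{ij}/O_{i\cdot}$ strictly exceeds 0.60. The strictness
follows the wording "exceeded"; the gene-level dominance score is
$\max_{ij} |r_{ij}|$.

The splicing-link engine (LASER) reuses the same machinery on
TSS × junction and junction × PAS tables. Its linkage score is
$\sum_{ij} r_{ij}^2$, which equals $X^2$ identically — the package
asserts this identity on every tested matrix rather than computing the
two quantities through separate code paths and hoping. Junctions whose
flanking exon is an alternative first or last exon are excluded so that
the splicing axis is not confounded with the 5′/3′ axes being tested.

## Parameters that matter

All thresholds live in `default_config()` and mirror the analysis they
implement. Distances are nucleotides on the genome.

| parameter | default | role |
|---|---|---|
| `tss_window` / `pas_window` | 50 / 150 | read-to-site assignment windows; a read matching both is "full-length" |
| `pas_cluster_window`, `pas_min_support` | 20, 2 | PAS database clustering and support |
| `filter_overlap_window` | 100 | 3′-end filter window against the database |
| `last_bin_cover_frac` | 0.10 | last-3′UTR-bin coverage above which an end is corrected to the distal PAS |
| `merge_tol_3p` / `merge_tol_5p` / `merge_tol_exon` | 150 / 50 / 10 | isoform merge tolerances (strict `<`) |
| `ip_a_frac`, `ip_window`, `ip_tes_exempt` | 0.70, 10, 250 | internal-priming blacklist: strictly more than 70% A in the 10-bp upstream window, exempt near annotated ends |
| `alpha_fly` / `alpha_human` | 0.1 / 0.01 | BH cutoffs; the human preset is stricter because organoid data carry fewer reads per gene |
| `tss_contrib_min`, `pas_contrib_min` | 0.20, 0.60 | dominance contribution cutoffs (strict) |
| `residual_bias_cut` | 0.7 | biased feature-pair cutoff on raw Pearson residuals |
| `signal_window_scan` / `signal_window_pas` | 20 / 50 | poly(A)-signal scan windows (QC vs PAS-usage analyses) |
| `mc_reps` | 2000 | Monte-Carlo replicates; resolution of $\hat p$ is $1/(B+1)$ |
| `max_tx_len` | 10000 | spans above this lack full-length coverage and are excluded |
| `proximal_frac` | 0.20 | proximal/distal 3′UTR boundary (boundary value classified proximal) |
| `msa_row_occ`, `msa_max_ident` | 0.4, 0.98 | alignment row refinement |
| `peak_min_height/distance/width` | 0.2, 2, 2 | co-evolution peak finding |
| `coevo_percentile` | 0.50 | top fraction of TSS scores called co-evolving |

## What the generator emulates — and what it does not

`simulate_gene_models()` builds genes with alternative TSSs ≥ 151 nt
apart and alternative PASs ≥ 601 nt apart — strictly more than twice
the assignment windows, so site assignment on artifact-free reads is
provably unambiguous and recovery tests can demand 100%. Real genes do
not offer this guarantee; `ambiguous = TRUE` removes it for
tie-breaking tests. Each gene carries a shared internal exon chain with
an optional cassette exon whose inclusion probability may depend on the
TSS (`p_inc`), giving LASER planted or null splicing links. The genome
sequence plants, per PAS, a canonical AATAAA 14–19 nt upstream and an
A-free 10-mer immediately upstream (so no true PAS can trip the
blacklist), and one A₁₀ tract per gene in the middle of the last 3′UTR
bin, > 250 bp from every annotated end (so the blacklist is *allowed*
to flag it).

`simulate_reads()` draws per-gene (TSS, PAS) labels multinomially from
the coupling matrix (default 100 reads/gene, the order of per-gene
coverage at which the dominance analysis operates). Artifacts modify
but never drop reads: 5′ truncation moves the 5′ end 51–350 nt into
the gene body while avoiding ± 50 nt of every other TSS (truncated
reads are unassignable, not misassigned); internal priming re-anchors
the 3′ end on the planted A-tract and leaves the tail flag set, since
that is precisely what the artifact looks like; `p_tailless` clears
only the tail flag. Default artifact rates in the CLI preset (0.1 /
0.05 / 0.3) are plausible for ONT cDNA libraries; tests state their own
rates explicitly.

`simulate_msa()` uses a star phylogeny over A/C/G/T with no gaps and no
branch lengths — adequate because the analysis uses only column-wise
co-occurrence, not tree structure. Planted pairs link a promoter-1
column to a 3′UTR column through a two-state bijection honored with
probability $\rho$; promoter 2 receives the same number of
*independent* two-state columns. This composition matching matters:
background MI noise between independent columns grows with alphabet
size, so an unmatched 4-state control promoter scores systematically
differently even at $\rho = 0$ — an early version of the generator
failed the no-coupling criterion for exactly this reason, and the fix
was matching the control's column composition, not adjusting any
threshold.

Consequences for interpretation: a green suite establishes that the
statistical engine, filters, and recovery logic are correct on data
whose generative process is known and favorable. It does not establish
robustness to mapping error, cleavage-site heterogeneity beyond the
clustering window, degradation-induced 3′ bias, or phylogenetic
non-independence — all properties of real data the generator
deliberately omits.

## Numerical and procedural choices

* **Coordinates.** Everything internal is 0-based half-open
  (BED-native); GTF is converted exactly once at each boundary. Site
  positions use the terminus convention (+ strand: exclusive end;
  − strand: inclusive start), so `|terminus − site|` is the assignment
  distance on either strand.
* **Clustering** is single-linkage chaining on sorted positions
  (deterministic, order-independent); the representative is the modal
  member position, ties resolved 3′-most, matching the "confident 3′
  end" intent. An all-pairs brute-force oracle checks it exactly on
  every instance up to n = 15.
* **Assignment ties**: nearest site wins; exact distance ties go to the
  5′-most TSS and 3′-most PAS. Reads whose TSS and PAS match different
  genes are dropped with a logged reason rather than guessed.
* **3′-end correction order**: an end strictly inside the last 3′UTR
  bin obeys the 10% rule even when it also lies within the snap window
  of the proximal PAS — the worked semantics of the correction demand
  it (an end covering 12% of the bin moves distal, not back). Ends
  failing the 10% rule snap to the bin's proximal PAS, the conservative
  completion of a rule stated only for the > 10% branch. Ends outside
  the last bin snap to a cluster within 100 nt or stay put.
* **Merging** uses union-find transitive closure over the pairwise
  mergeable relation; chains of pairwise-mergeable isoforms therefore
  collapse even when the endpoints differ by more than a tolerance.
  This affects counts and is tested against a connected-components
  oracle.
* **Degenerate genes** (zero-span 3′UTR) are flagged with `NA` class
  and a warning instead of aborting; the flag is the error record, and
  cohort runs survive one pathological gene.
* **MI** is base-2, computed on pairwise-complete rows, with pairs
  having < 3 complete rows scored 0. Base only scales scores and the
  classification is rank-based, so it changes no labels. The APC
  correction $\mathrm{MI}_c(i,j) = \mathrm{MI}(i,j) - \bar m_i \bar m_j
  / \bar m$ uses diagonal-free means; negatives are floored at 0.
* **Peak finding** declares a peak at a local maximum (plateaus counted
  once) with height ≥ 0.2 whose base span — the distance between the
  flanking local minima — is at least 2 columns; peaks closer than 2
  positions merge keeping the higher. An edge maximum with a
  single-column fall has base span 1 and is rejected. The 1-D profile
  fed to the peak finder is, per 3′UTR column, the maximum corrected MI
  against the promoter region — the minimal faithful reduction of a 2-D
  comparison to the stated 1-D peak search; column-max gives the same
  ranks on our fixtures.
* **Fisher exact** (2×2, two-sided) sums hypergeometric probabilities
  ≤ the observed table's with the customary $1 + 10^{-7}$ relative
  slack, matching `stats::fisher.test` to 12 digits while keeping the
  implementation and the oracle on separate routes.
* **Determinism.** Every stochastic operation takes an explicit seed;
  the CLI derives per-stage seeds (kept below $2^{31}$) from the single
  `--seed`. Identical seed and config give byte-identical outputs for
  every subcommand.

## Known limitations

Assembly itself (splice-graph correction/collapse), differential
isoform usage between conditions, single-cell counting, structural
isoform categories, and raw-signal tail-length estimation are out of
scope. The blacklist scans the genome exhaustively, which is fine for
megabase-scale simulated genomes but would want an indexed
implementation for mammalian genomes. The junction exclusion rule
identifies alternative first/last exons from the annotation provided;
incomplete annotations weaken it. TPM here is read-proportion TPM over
full-length reads (each read is one transcript, so no length
normalization) — appropriate for the gene filter it implements, not a
general-purpose expression estimate.
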