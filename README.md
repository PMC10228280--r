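# isocoupler

Coupling between transcription start sites (TSSs) and polyadenylation
sites (PASs) from full-length long-read transcriptomes.

## The problem

Genes with several promoters (alternative TSS usage, ATSS) frequently
also use several cleavage/polyadenylation sites (alternative
polyadenylation, APA). Because a full-length cDNA read covers one
transcript from its 5′ cap to its poly(A) tail, each read observes a
*joint* (TSS, PAS) choice — something short-read data cannot give. This
package implements, for bulk and single-cell long-read data, the
analysis chain needed to ask whether a gene's promoter choice biases its
3′ end choice:

1. **PAS database** — confident 3′ ends from poly(A)-tail-anchored
   reads: single-nucleotide cleavage sites clustered in 20-nt windows,
   clusters with ≥ 2 reads kept; internal-priming blacklist (positions
   with > 70% A in the 10-bp upstream window, exempting ± 250 bp around
   annotated transcript ends); ranked poly(A)-signal scan (AATAAA …
   TTTAAA); nucleotide profiles, tail-length summaries, 5′ pile-ups.
2. **Transcript curation** — 3′ ends filtered against the database
   (100-nt window, or distal ends inside the reference annotation with
   an AATAAA), corrected through 3′UTR bins (> 10% coverage of the last
   bin → distal PAS), and merged under 150/50/10-nt tolerances with
   transitive closure.
3. **LATER** — reads assigned to a TSS (± 50 nt) and PAS (± 150 nt) are
   full-length; per gene, the TSS × PAS count matrix
   O is tested against independence with the chi-squared statistic
   X² = Σ (O−E)²/E, E = (row × col)/N, using Monte-Carlo sampling of
   tables with fixed margins (Patefield), p = (1 + #{X²* ≥ X²})/(B+1),
   BH-corrected across genes. A cell (i, j) is a **dominant promoter**
   pair iff the gene is biased (adj. p < α; 0.1 fly / 0.01 human
   presets), TSS contribution O_ij/col_j > 20% and PAS contribution
   O_ij/row_i > 60%.
4. **LASER** — the same engine on TSS × exon-junction and
   junction × PAS matrices (junctions touching alternative first/last
   exons excluded); linkage score = Σ r_ij² (= X²) with Pearson
   residuals r_ij = (O−E)/√E, pairs with |r| > 0.7 flagged biased.
5. **Downstream statistics** — Shannon/Simpson diversity of end usage,
   proximal (≤ 20% of the 3′UTR) vs distal PAS classes, and
   poly(A)-signal skipping 2×2 tables with two-sided Fisher exact p.
6. **Co-evolution** — promoter–3′UTR covariation from species
   alignments: refineMSA-style row filtering (occupancy ≥ 0.4, identity
   ≤ 0.98), pairwise mutual information (bits) with average product
   correction, peak-based region scores (findpeaks parameters 0.2/2/2),
   genes in the top 50th percentile called co-evolving.

A first-class synthetic-data module simulates multi-TSS/multi-PAS gene
models on a synthetic genome (planted poly(A) signals and internal-
priming A₁₀ tracts), full-length reads with 5′-truncation /
internal-priming / tailless artifacts, and species alignments with
planted promoter–3′UTR covariation — so the whole pipeline is testable
without downloads.

## Worked example

```r
library(isocoupler)

models <- simulate_gene_models(40, sim_preset("mixed"), seed = 7)
sim <- simulate_reads(models,
                      rates = list(p_truncate_5p = 0.1,
                                   p_internal_prime = 0.05,
                                   p_tailless = 0.3), seed = 8)

tailed <- sim$reads[sim$reads$has_polya, ]
db <- apply_blacklist(build_pas_database(tailed),
                      internal_priming_mask(models$genome, models$txs))
pas_db <- annotate_clusters(db, models$txs)

asn   <- assign_full_length_reads(sim$reads, models$tss, pas_db)
mats  <- build_coupling_matrices(asn)
tests <- test_tss_bias(mats, B = 2000, alpha = 0.1, seed = 9)
dom   <- call_promoter_dominance(tests, mats)
```

Output (seeds as above):

```
PAS database: 80 clusters (80 true sites)
full-length reads: 3399 / 4000 (85.0%)
genes tested: 40; transcriptionally biased: 20
dominant (TSS, PAS) pairs: 40
   gene_id       X2         p_mc        p_adj biased dominance_score
1:   g0002 60.81429 0.0004997501 0.0009995002   TRUE        4.132998
2:   g0004 63.82350 0.0004997501 0.0009995002   TRUE        4.087376
3:   g0006 59.51697 0.0004997501 0.0009995002   TRUE        4.127402

     pas1 pas2        # coupling matrix of g0002
tss1   41    4
tss2    2   36
```

Reading this: the "mixed" preset alternates independent-coupling genes
with diagonally coupled ones (odds ratio 81), 100 reads each. The
database recovers exactly the 80 true PASs (internal-priming clusters
are blacklisted); 85% of reads are full-length (the rest carry planted
5′/3′ artifacts); exactly the 20 planted-coupling genes are called
transcriptionally biased, each contributing its two diagonal dominant
(TSS, PAS) pairs — e.g. in g0002, tss1 contributes 41/43 of pas1's
reads (TSS contribution 0.95) and 41/45 of its own reads go to pas1
(PAS contribution 0.91).

## Command line

```
isocoupler simulate --n-genes 20 --preset mixed --out sim/ --seed 1
isocoupler pasdb    --reads sim/reads.bed12 --polya sim/polya.tsv \
                    --genome sim/genome.fasta --gtf sim/annotation.gtf \
                    --tss sim/tss.bed --out db/
isocoupler filter   --gtf sim/annotation.gtf --pasdb db/pas_db.bed \
                    --reference sim/annotation.gtf --genome sim/genome.fasta \
                    --out cia/
isocoupler quantify --reads sim/reads.bed12 --polya sim/polya.tsv \
                    --tss sim/tss.bed --pasdb db/pas_db.bed --out quant/
isocoupler dominance --assignments quant/assignments.tsv --preset fly \
                     --seed 1 --out dom/
isocoupler laser    --reads sim/reads.bed12 --polya sim/polya.tsv \
                    --tss sim/tss.bed --pasdb db/pas_db.bed \
                    --gtf sim/annotation.gtf --seed 1 --out laser/
isocoupler stats    --assignments quant/assignments.tsv --pasdb db/pas_db.bed \
                    --gtf sim/annotation.gtf --genome sim/genome.fasta \
                    --dominance dom/dominance.tsv --out stats/
isocoupler coevolve --msa sim/msa.fasta --regions sim/regions.bed --out coev/
```

`exec/isocoupler` is the Rscript wrapper; every subcommand accepts
`--config <file>` (flat `key = value`, see `default_config()`) and
`--seed`, and is byte-identical across runs with the same seed.

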