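# bhlhscan

Genome-wide identification and phylogenetic classification of basic
helix-loop-helix (bHLH) transcription-factor genes.

bHLH proteins regulate neurogenesis, myogenesis, sex determination and
many other developmental programs through a ~60-residue domain (basic
region, helix 1, loop, helix 2). Animal bHLH proteins form 45
orthologous families in six higher-order groups (A–F). Surveys of a
newly sequenced genome answer three questions: *which loci encode bHLH
domains*, *which family does each belong to*, and *how is the domain's
coding region organised* (introns, their lengths and positions).
`bhlhscan` implements the complete desk procedure for all three, for
researchers cataloguing transcription-factor repertoires in newly
assembled genomes:

1. **Search** — six-frame conceptual translation scanned against a
   reference panel of annotated bHLH motifs by Smith–Waterman local
   alignment (PAM250, affine gaps 11/1), with exon chaining for
   intron-split motifs, locus deduplication (same contig, frame and
   coding region → keep one), and a conserved-site filter: a candidate
   must match ≥ 10 of the 19 diagnostic motif columns (the two most
   conserved sit at motif positions 24 and 51).
2. **Classify** — in-group phylogenetic analysis per candidate:
   neighbor-joining (1000 bootstrap replicates), maximum-parsimony (100)
   and maximum-likelihood (JTT, 100) trees of the candidate with the
   reference members of its higher-order group; a reference that is the
   candidate's sister in a tree with bootstrap support exceeding 50 is
   its ortholog, graded into confidence tiers (`full` > `nj_mp` >
   `single_method` > `cross_species` > `family_only`), with automatic
   gene naming (`Mist1`/`Mist2`-style suffixes under a species prefix).
3. **Annotate introns** — introns interrupting the motif's coding region
   are mapped to motif subregions (basic/helix 1/loop/helix 2) with
   genomic lengths, phases and summary statistics.

A synthetic-data module generates reference panels and genomes with
implanted, mutated, optionally intron-split motifs plus shuffled decoys
and complete ground truth, so the whole pipeline is testable end to end.

## Worked example

```r
library(bhlhscan)

# a small simulated survey (a few minutes; the package defaults run the
# full 50-implant validation genome)
cfg <- simulation_config(n_contigs = 4, contig_length = 12000,
                         n_implants = 6, decoy_count = 10, seed = 7)
pnl <- generate_panel(cfg)
sim <- implant_genome(pnl, cfg)

gff <- tempfile(fileext = ".gff3")
write_gff3(sim$gff, gff)
res <- run_pipeline(sim$genome, pnl$panel, gene_models = gff,
                    species_prefix = "Syn", seed = 7)

head(res$calls[, c("name", "family", "group", "tier",
                   "nj_support", "mp_support", "ml_support")])
score_against_truth(res$calls, sim$truth, res$introns)[1:5]
res$summary$introns[c("members_with_introns", "total_introns",
                      "longest_bp", "mean_bp")]
```

which prints (seed 7):

```
         name family group        tier nj_support mp_support ml_support
122  SynFam01  Fam01     A family_only         NA         NA         NA
188  SynFam04  Fam04     D        full         99         98         90
241  SynFam03  Fam03     C        full         92         96         66
378 SynFam07a  Fam07     A        full         73        100         96
381  SynFam05  Fam05     E        full         77         99         88
463 SynFam07b  Fam07     A        full         73        100         91

$precision        [1] 0.8571429
$recall           [1] 1
$family_accuracy  [1] 1
$decoy_rejection  [1] 1
$intron_recovery  [1] 1

$members_with_introns [1] 2
$total_introns        [1] 4
$longest_bp           [1] 3240
$mean_bp              [1] 1753
```

Each call names the candidate's ortholog in the reference panel, its
family and group, the confidence tier of the decision rule, and the
bootstrap support of the candidate–ortholog clade in each of the three
trees (two recovered Fam07 paralogs get the `a`/`b` suffixes; one
intron-fragmented candidate only reaches the family-level vote). The
truth scoring shows that every implanted gene is recovered with the
correct family, all shuffled decoys are rejected by the conserved-site
filter, and every implanted intron is reported with its exact genomic
length and motif subregion.

A command-line wrapper with the same stages
(`simulate`, `scan`, `filter`, `classify`, `introns`, `report`, `all`)
is installed at `inst/cli/bhlhscan`:

```sh
Rscript inst/cli/bhlhscan simulate --seed 7 --out sim/
Rscript inst/cli/bhlhscan all --genome sim/genome.fasta \
    --panel sim/panel.fasta --panel-meta sim/panel_meta.tsv \
    --gff sim/truth.gff3 --prefix Syn --seed 7 --out run/
```

## Reference data

`inst/extdata/` ships a *synthetic* stand-in reference panel (59
generated motifs covering the 45 animal families and groups A–F, 19
invariant columns anchored at motif positions 24 and 51) plus the
family → group map. Real species panels are supplied as FASTA +
metadata TSV (`id`, `species`, `family`, `group`) via
`load_reference_panel()`; fallback panels for cross-species
classification are passed the same way.

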