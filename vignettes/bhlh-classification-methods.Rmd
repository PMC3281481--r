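---
title: "Genome-wide bHLH identification and orthology classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide bHLH identification and orthology classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Basic helix-loop-helix (bHLH) proteins are a superfamily of transcription
factors built around a ~60-residue domain: a DNA-binding basic region and
two helices separated by a variable loop. Animal bHLH proteins fall into
45 orthologous families, grouped into six higher-order groups A–F by
DNA-binding behaviour (A/B bind E-box variants, C are bHLH–PAS proteins,
D lack the basic region, E bind N-boxes, F carry the COE domain).
Genome-wide surveys of this family follow a standard recipe: search the
genome with a panel of annotated motifs from a reference species, filter
candidates by conservation at the domain's diagnostic sites, and then
decide each candidate's family by *in-group phylogenetic analysis* —
placing the candidate among the known members of its higher-order group
and asking whether it forms a supported two-leaf clade with one of them.
`bhlhscan` implements that recipe as a reusable, tested pipeline, together
with a synthetic-genome simulator that provides ground truth for
validating every stage.

## Motif search

The genome is conceptually translated in all six frames (`N` → `X`, stop
codons kept as `*`); each frame is scanned with every panel motif by
Smith–Waterman local alignment under PAM250 with affine gap costs
(opening 11, extension 1, so a length-*k* gap costs 11 + *k*). In place of
an E-value cut-off the search is deliberately permissive: candidate
segments need only reach a raw score of 25, and a candidate is retained
when its (possibly chained, see below) score reaches `min_score = 40`.
Both thresholds are configurable (`search_config()`); selectivity comes
not from the score but from the conserved-site filter.

Because one query has at most one optimal local alignment per sequence,
the scanner works in two stages. *Discovery*: all queries are aligned
against the frame translation, found regions are masked, and the pass is
repeated (up to `max_candidates_per_contig` rounds) so that multiple
copies of a motif in one frame are all found. *Refinement*: every query is
then re-aligned against each discovered locus (with small flanks), so
each query obtains its own segment coordinates regardless of which query
discovered the locus. Without the refinement stage, a region found first
by one family's query is invisible to the query that actually matches it
— which loses exon segments of intron-split genes.

Genes whose motif is interrupted by introns appear as partial segments in
different frames. Segments of the same query on one contig and strand are
chained by a best-path search over a DAG whose edges require the
downstream segment to continue the query (query-coordinate gap in
[-1, 15] residues) within `max_chain_gap = 50` kb of genomic distance.
The chain score is the sum of segment scores minus a gap penalty of
0.01 per bridged bp (10 points/kb): without the penalty, a segment
happily joins a distant paralog's segment instead of its true partner
one intron away. A final locus pass drops partial single-frame hits
whose exons are already covered (≥ 70%) by a more complete candidate at
the same locus, mirroring the one-gene-per-locus manual curation such
surveys apply; the classical duplicate rule — same contig, same frame,
overlapping coding region, keep the best score — is applied in
`dedupe_hits()`, with overlap measured on exon intervals so that a
multi-exon chain does not swallow a distinct gene lying inside one of
its introns.

## Conserved-site filter

Nineteen diagnostic motif columns carry the family-wide conservation
signal of the bHLH domain; the two strongest sit at motif columns 24
and 51. The package derives its site specification from the reference
panel itself: `calibrate_conserved_sites()` picks the modal-frequency
threshold at which exactly 19 alignment columns qualify and checks that
columns 24 and 51 are among them; each site's allowed residue set
contains every residue reaching a 10% column frequency. A candidate
peptide is aligned to the panel consensus (ends-free), its residues at
the 19 sites are compared with the allowed sets, and it is kept iff at
least 10 sites match; peptides covering less than half of the motif are
rejected as truncated. The keep-at-10 boundary follows the operative
discard rule of the protocol (fewer than ten conservations → discard).

## Phylogenetic machinery

* **Alignment** — a simplified progressive aligner: pairwise global
  alignment identities give a guide tree (by neighbor joining), profiles
  are merged along it by global dynamic programming with sum-of-pairs
  PAM250 scoring and a linear gap penalty of 8 per column. It is
  deterministic and adequate for the near-equal-length motif sets this
  pipeline aligns; it does not reproduce ClustalW column-for-column.
* **Distances** — similarity-to-cost conversion
  `cost(a,b) = (S(a,a)+S(b,b))/2 − S(a,b)` applied to PAM250, averaged
  over shared non-gap columns (pairwise deletion). The historical step
  matrix this emulates is not published; the conversion is configurable.
* **Neighbor joining** — standard Saitou–Nei agglomeration; ties in the
  Q-criterion break on the smallest index pair, negative branch lengths
  clamp to zero. On additive matrices the generating tree is recovered
  exactly (this is asserted in the tests).
* **Parsimony** — Fitch counting with gaps as missing data (full state
  sets). Searches enumerate all topologies up to 8 taxa and otherwise
  hill-climb by nearest-neighbor interchange from the NJ tree with two
  seeded random restarts.
* **Likelihood** — Felsenstein pruning under the empirical JTT model
  (published exchangeabilities and frequencies, rate-normalized so branch
  lengths are substitutions per site), gaps as missing data. Transition
  matrices come from a cached symmetric eigendecomposition. The topology
  search screens candidates with least-squares branch lengths fitted to
  the step-distance matrix (converted to substitutions per site through
  the stationary expected substitution cost with a Poisson multiple-hit
  correction; one likelihood evaluation each) and then optimizes the
  best three screened topologies by per-edge Brent search (bounded,
  tolerance 1e-4, two sweeps), keeping the higher-screened topology on
  near-ties. Screening trades a guarantee of per-topology optimality
  for a ~50-fold smaller search cost; with the short, strongly
  structured in-group alignments this pipeline sees, the screened
  ranking and the fully optimized ranking agree at the top.
* **Bootstrap** — alignment columns are resampled with replacement; the
  support of an internal edge is the percentage of replicate trees
  containing its bipartition, attached as node labels of the point
  estimate. One master seed drives sequential replicate draws, making
  every support value bit-reproducible. Replicate MP/ML searches use the
  NNI quick variant: support depends only on replicate topologies, so
  the expensive branch-length refinement is skipped there.

## The decision rule

For each filtered candidate, the panel members of the best-hitting
reference's higher-order group form the in-group (capped at the 8
best-scoring members; the protocol's own worked example used seven), and
the best-scoring member of a *different* group is the outgroup. NJ
(1000 bootstrap replicates), MP (100) and ML (100) trees are built for
candidate + in-group + outgroup. In each tree the candidate's sister is
inspected: a single-leaf sister that is not the outgroup is a candidate
ortholog, and its support is the fraction of replicates in which exactly
that two-leaf split occurs. Tiers:

| tier | condition |
|------|-----------|
| `full` | same ortholog in all three methods, every support > 50 |
| `nj_mp` | NJ and MP agree with support > 50, ML disagrees or is unresolved |
| `single_method` | exactly one method supported |
| `cross_species` | a fallback species panel produced one of the above |
| `family_only` | majority family among the top-5 alignment hits |
| `unassigned` | none of the above |

"Exceeds 50" is strict inequality, applied uniformly; ML support is
bootstrap support of the ML builder (quartet-puzzling reliability
values, sometimes used in this role, are a different statistic and are
deliberately not emulated — one support semantics across methods keeps
the rule coherent).
The tier order is total, and raising the threshold can only demote a
call (asserted as a property test). Names are the species prefix plus
the ortholog or family stem; stems claimed by several candidates are
numbered (`Mist1`, `Mist2`), stems already ending in a digit take letter
suffixes (`Stich1a`, `Stich1b`), and family-only calls continue their
family's numeric series.

## Intron annotation

Gene models arrive as GFF3 (`gene`/`mRNA`/`CDS`; for simulated data, the
emitted truth): splice-site prediction is outside this package's scope.
For each classified candidate the overlapping model's CDS intervals are
walked in transcription order; each inter-exon gap becomes one intron
record with its genomic length (donor GT through acceptor AG inclusive),
phase (coding offset within the interrupted codon) and the motif
subregion of the interrupted codon. The default subregion boundaries
(1-based motif columns) are basic = [1,16), helix 1 = [16,31),
loop = [31,46), helix 2 = [46,60]; the domain literature gives no single
canonical coordinate set, so these are configurable
(`subregion_scheme()`), chosen so that site 24 falls in helix 1 and
site 51 in helix 2. An intron falling exactly on a boundary belongs to
the subregion of the codon 5′ of the junction — a deterministic tie rule.
Gaps shorter than 4 bp are rejected as implausible introns.

## The simulator

`simulation_config()` defaults describe the validation conditions: 10
families × 2 reference members (real panels average ~1.3 motifs per
family), motif length 60. All families descend from one shared domain
ancestor at a between-family divergence of 0.35 per site (~45%
inter-family identity — the relatedness regime of real bHLH panels;
independently random family sequences would create absurdly long
inter-family branches and the long-branch artifacts that go with them),
and members diverge from their family ancestor at 0.10 per site, with
the 19 designated conserved columns (including 24 and 51) protected.
The genome is 10 contigs × 30 kb of uniform random background carrying
50 implants and 100 decoys. Implants re-mutate a random panel member, back-translate with
uniform synonymous codons, and are placed without overlap on a random
strand; half are split by one GT..AG intron (a second intron in 30% of
those), with log-normal lengths (median ≈ 1 kb, meanlog = log 1000,
sdlog = 1) capped at 20 kb — a heavy-tailed regime of the kind seen in
insect genomes with transposon-inflated introns, without asserting any
particular species' statistics. Decoys are
composition-preserving shuffles of panel motifs: they carry the same
residue composition but scramble the 19 sites, so they probe exactly
what the conserved-site filter is supposed to reject.

What the simulator does *not* emulate: codon bias, repetitive or GC-
structured background, pseudogenes, alternative splicing, sequencing
gaps, and assembly fragmentation of single genes across contigs. Passing
the planted-recovery checks therefore demonstrates the pipeline's
internal coherence — search, chaining, filtering, classification and
intron bookkeeping are mutually consistent — not its performance on a
real assembly, where sensitivity is bounded by assembly quality and the
realism of the reference panel.

## Numerical and reproducibility choices

All stochastic steps flow from one integer seed: the simulator uses it
directly, each candidate derives a child seed (`seed + 13·i`), and each
method's bootstrap offsets it again. Genomic coordinates are 1-based
inclusive on the forward strand in every file (GFF3 convention); frame
signs carry strand. Distances use pairwise deletion; parsimony and
likelihood treat gaps as missing. Degenerate inputs fail loudly: an
alignment pair with no shared non-gap column, exons out of order, a
sub-4-bp intron gap, a candidate with no positive-scoring panel hit.

Problem sizes in the shipped tests and acceptance script — 4–6-taxon
oracle comparisons (200 matrices for NJ, 100 alignments for parsimony,
50 branch lengths for likelihood), the full 50-implant planted genome,
and 1000-replicate bootstrap checks — were chosen as the smallest sizes
at which each claim is meaningfully exercised.

## Known limitations

* The bundled 59-motif reference panel is synthetic (generated, clearly
  labelled); real species panels must be supplied by the user as
  FASTA + TSV. Conclusions about real genomes require real panels.
* The ML search is heuristic beyond 8 taxa and screened below that; it
  can in principle return a slightly sub-optimal topology, though never
  one worse than its NJ start.
* Chaining assumes exon segments of one gene lie within 50 kb on one
  contig; split assemblies break this.
* The progressive aligner is intentionally simple; for long or highly
  gapped motifs an external aligner's result can be imported as aligned
  FASTA instead.
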