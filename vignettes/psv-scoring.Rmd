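---
title: "Phenotype-aware structural variant prioritization: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-aware structural variant prioritization: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psvrank)
```

## The model

`psvrank` ranks structural variants (SVs) for Mendelian-disease diagnosis
by combining, per variant, a sequence-level deleteriousness score with a
phenotype-level relevance score:

$$PSV(Q, G, D) = \sum_{g \in G} \delta(g)\, e^{\phi(Q, D_g)}$$

where $G$ is the set of genes affected by the variant, $\delta(g) \ge 0$
is a per-gene heuristic for the predicted damage to gene function or
dosage, $Q$ is the proband's set of Human Phenotype Ontology (HPO) terms,
and $D_g$ is the gene-associated disease model maximizing the symmetric
Resnik similarity $\phi$. The exponential weighting means a perfect
phenotype match can lift a moderately damaging variant far above
phenotypically irrelevant but equally damaging ones, while a gene with no
disease association still contributes $\delta(g) \cdot e^0 = \delta(g)$:
sequence evidence is never silenced, only amplified.

The assumptions are deliberately coarse. $\delta$ is a rule table, not a
trained model: it encodes qualitative molecular reasoning (a frameshift is
worse than an in-frame change; removing half a UTR is worse than removing
a tenth; an inversion that merely relocates an intact transcript is
harmless) with a handful of constants. This favours interpretability —
every score decomposes into per-gene, per-transcript rule hits — over
calibration. The score is additive over genes and unbounded above; it is a
ranking statistic, not a pathogenicity probability.

### The deleteriousness rules

For each transcript of each affected gene the variant is classified by
relationship (variant contains transcript / partial overlap / variant
within an element) and by the most deleterious element class it touches,
with precedence coding-or-splice > TSS > UTR > promoter > intron. The
gene score is the maximum over its transcripts — the damage to the most
damaged isoform. The per-class rules:

| class | contains transcript | partial overlap | coding/splice | UTR | intron | promoter |
|-------|--------------------|-----------------|---------------|-----|--------|----------|
| DEL | 1 | by element hit | 1 (frameshift), 0.8 (in-frame) | $\min(2\,len_{SV}/len_{UTR}, 1)$ | 0 | 0.4 |
| DUP/CNV | copy gain | 0 (tandem past a terminus) | 1 / 0.8 by frame | as DEL | 0 | 0.4 |
| INV | 0 | 1 | 1 | as DEL | 0 | 0.4 |
| INS | — | — | 0.9 (frameshift), 0.2 (in-frame) | $\min(len_{INS}/len_{UTR}, 1)$ | 0 | 0.4 |
| BND | — | — | 1 | 1 | 1 | 0.4 |

Additional rules: loss of the transcription start site by a deletion is
scored 1 (as deleterious as a coding hit); an inversion wholly inside one
intron is 0 and one that fully contains the transcript is 0 (the primary
sequence is unchanged); a whole-gene duplication scores its copy-number
gain, so a triplication (two extra copies) scores 2; both breakends of a
translocation are scored and the larger value used per transcript, with
each record treated as one adjacency (no event grouping).

Reading-frame logic: the frame effect of a deletion or duplication is the
total affected coding length modulo 3, *except* that disrupting the splice
region of an exon that is not itself removed outright is
frameshift-equivalent (score 1). This makes a clean whole-exon in-frame
deletion score 0.8 even though it removes the exon's own splice sites,
while a 3-bp deletion straddling an acceptor site scores 1 — both match
the intended biology.

Where the source rules were ambiguous we resolved as follows, as package
design choices:

* Coding duplications are frame-sensitive ({0.8, 1}) rather than a flat 1,
  mirroring the deletion rule; a frameshifting intra-exonic duplication
  still scores 1.
* The UTR formulas use the length of the intersection of the variant with
  the UTR (not the full variant length) when the variant extends past the
  UTR; otherwise the coding rules would already dominate via precedence.
* 5' and 3' UTRs are scored identically; when both are hit the larger
  relative loss is used.
* An insertion landing exactly on a splice boundary is treated as a
  splice-disrupting frameshift (0.9) regardless of its length modulo 3.
* A duplication that partially overlaps a transcript — i.e. extends beyond
  its 5' or 3' terminus — is neutral (0): the duplicated copy lies outside
  the primary linear transcript sequence. This takes precedence over the
  TSS rule for duplications.

### Phenotype similarity

Term information content is corpus-based: $IC(t) = -\ln(n_t / N)$ in nats,
where $n_t$ counts the diseases annotated (after propagating annotations
to ancestors) with $t$ and $N$ is the corpus size. Natural logs are used
because the priority score exponentiates $\phi$ with base $e$, making
$e^{\phi}$ interpretable against corpus frequencies. Unannotated terms
receive a pseudo-count of 1 ($IC = \ln N$) so queries mentioning them stay
finite; this is configurable. One-sided similarity averages, over the
iterated side's *own* terms, the best $IC(MICA(\cdot,\cdot))$ against the
other side, and $\phi$ is the mean of the two directions — the standard
symmetric Resnik reading. Pairwise MICA values are memoized (and can be
precomputed in bulk), which is exact, not approximate.

Note $\phi(Q,Q) \ge \phi(Q,D)$ is *not* guaranteed by best-match
averaging; the invariant tested instead is $\phi \le \max_t IC(t)$.
Unknown query terms are a fatal error listing the offenders; obsolete and
alternative ids are resolved through the ontology's alias map.

## Tunable parameters

| parameter | default | units | why |
|-----------|---------|-------|-----|
| frequency threshold | 0.01 | allele fraction | variants in more than 1 % of the population are treated as common; strict `>` |
| reciprocal-overlap threshold | 0.80 | fraction | a call matches a panel SV only above 80 % reciprocal overlap; strict `>` |
| insertion anchor padding | 100 | bp | insertions have zero-length anchors, so interval overlap is degenerate; matching uses anchor distance plus length ratio above the overlap threshold |
| minimum ALT reads | 3 | reads | calls supported by fewer than 3 reads are dropped; unknown depth is kept, since depth reporting is caller-specific |
| promoter length | 2000 | bp | promoters are taken as the 2 kb upstream of each transcript's TSS, clipped at contig bounds; derived per transcript, with the gene taking the max across transcripts |
| splice-region width | 2 | bp | the two intronic bases flanking each exon (canonical donor/acceptor) |
| caller dialect | auto | — | pbsv reads FORMAT `AD`; sniffles FORMAT `DV` (INFO `RE` fallback); SVIM INFO `SUPPORT` (FORMAT `AD` fallback); `auto` probes in that order. The mapping is configurable because depth conventions drift between caller versions |

Coordinates are 0-based half-open on the + strand internally; VCF and
GFF3 conversion happens only at the I/O boundary. For symbolic alleles,
POS is interpreted as the base before the event and END as its last base
(the affected region is `[POS, END)` 0-based), which makes the sequence
and symbolic notations of the same deletion produce identical internal
regions and exact round-trips. CNV records derive the copy-number gain
from INFO `CN` assuming a diploid baseline (`gain = max(1, CN - 2)`);
plain `<DUP>` records default to gain 1.

## Degenerate inputs and numerical choices

Zero-length regions have reciprocal overlap 0 by definition. An empty
gene set gives PSV 0 (the variant is still reported). A coding transcript
with a zero-length UTR hit cannot arise (a UTR hit requires positive
intersection), but the UTR formula guards `len_UTR = 0` by returning the
cap. Ranking ties are broken deterministically by (contig, start, id),
and a tie-aware group-median rank is reported alongside the positional
rank, mirroring the convention of ranking a variant as the middle of its
tied group. The pipeline is deterministic end to end: two runs on the
same inputs produce byte-identical TSV output.

Multi-allelic records are processed on their first ALT with a warning;
records that cannot be decoded (symbolic allele without END and SVLEN,
malformed breakend ALT, no net length change) are skipped with a logged
warning and counted, so parsed = scored + skipped + filtered always
reconciles.

## What the synthetic fixtures emulate — and what they do not

The fixture generator builds a two-contig genome with eight genes chosen
to realize every scoring cell: plus- and minus-strand genes, coding and
non-coding transcripts, a multi-transcript gene, a 144-bp fully-coding
middle exon (deletable in frame), a gene with 300-bp and 200-bp UTRs for
the UTR formulas, and compact genes for whole-gene events; a ~30-term
rooted DAG ontology with one multi-parent term and an alias; eight
disease models over that ontology; and a common-SV panel. The background
VCF generator emits records in all five SV classes and all three VCF
notations, placed intergenically, intronically, or as copies of panel
entries — neutral *by construction*.

The spike-in harness appends causal case records (allelic depth 5:5, so
the depth filter cannot remove them) to seeded background files, runs the
full pipeline per file, and reports each case's median rank across files.
Because backgrounds are neutral by construction, any causal variant with
positive δ in a phenotype-matched gene ranks first; the suite runs 20
such cases across all five classes against three 120-variant backgrounds.
These sizes keep the whole suite in the minutes range on one core and are
sufficient because every discriminating rule is exercised directly by
unit fixtures; the spike-in adds an end-to-end integration check, not
statistical power.

Passing these tests therefore shows the machinery is correct, not that
the method's ranking performance transfers to real data: real long-read
call sets have tens of thousands of variants whose scores populate the
whole range (UTR fractions, promoter hits, partially matching
phenotypes), real HPO term sets are noisy and incomplete, and real
transcript annotation has overlapping genes and many isoforms. Absolute
$\phi$ values — and hence absolute PSV scores — depend on the disease
corpus and ontology release used to compute information content, so
published per-case scores are reproducible only in their arithmetic, not
their inputs; the acceptance script accordingly fixes the published
$\phi$ values as inputs when verifying the two published score
aggregations.

## Known limitations

* No nucleotide-level consequence calling (HGVS), splice-strength or
  regulatory models; enhancer/repeat/dosage tracks are carried as
  annotations only and never affect scores.
* No mode-of-inheritance or genotype-aware filtering, no
  compound-heterozygote pairing, no per-population allele-frequency
  stratification.
* Only the first ALT allele of multi-allelic records is analyzed.
* Breakends are analyzed as independent adjacencies; complex events split
  across records are not reassembled.

## A minimal run

```{r example, eval = FALSE}
ann <- make_toy_annotation("toyann")
make_background_vcf(50, seed = 1, path = "bg.vcf", assembly = ann$assembly)
res <- run_prioritize(
  vcf = "bg.vcf", transcripts = ann$transcripts, panels = ann$panel,
  obo = ann$obo, disease_annotations = ann$disease_annotations,
  gene_diseases = ann$gene_diseases, hpo_terms = "HP:0001250",
  out_prefix = "run")
head(res$table)
```
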