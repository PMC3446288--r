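---
title: "Methods: junction-level splicing analysis with PTC prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction-level splicing analysis with PTC prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`splicejudge` analyses alternative splicing (AS) and its coupling to
nonsense-mediated mRNA decay (NMD) from single-end RNA-seq of two
conditions — a wild-type (WT) sample and an NMD-deficient knock-out
(KO) sample.  The pipeline works at the resolution of individual
exon–exon junctions rather than assembled transcripts:

1. **Combinatorial junction database.**  For every gene, exon models
   from any number of annotation sources are merged into a
   non-redundant exon union, and a junction is enumerated for *every*
   ordered pair of non-overlapping union exons in transcription
   order.  This represents both annotated and unannotated (in silico
   predicted) splice products: skipping any run of exons, and any
   alternative 5'/3' boundary variant present in the union.  NMD
   substrates are systematically depleted from transcript
   repositories, so restricting the search to annotated junctions
   would bias a study of NMD exactly against its targets; the
   combinatorial database removes that bias at the cost of a larger
   mapping index.
2. **Junction mapping.**  Reads are assigned by exact match either to
   a junction window (`flank_len` bases each side of the boundary,
   default 70 for 75-nt reads) or to the genome, with junction
   precedence and a unique-mapping policy.  Reads spanning three or
   more exons match no single window; they are rescued by trimming 10
   bases from the 3' end and remapping, iteratively.
3. **Quantification.**  Junction counts, junction and gene RPKM,
   between-sample normalization (upper-quartile or TMM), and a
   fold-change classification of junctions into upregulated (≥ 2-fold
   up in KO), downregulated, unregulated, or below a 3-read cutoff.
4. **PTC prediction.**  Each junction is spliced into the gene's
   backbone isoform and the resulting transcript is translated; a
   stop codon at least 50 nt upstream of the final exon–exon boundary
   marks the junction PTC+ (the 50-nt rule).
5. **Event classification.**  Seven AS event classes are inferred
   from motifs on the expressed-junction graph (SES, MES, A5SS, A3SS,
   MXE, AFE, ALE), each quantified with percent spliced in (PSI) and
   ΔPSI between conditions.
6. **Conservation analyses.**  Per-base conservation meta-profiles
   around regulated cassette exons and around PTC positions, and the
   identity distribution of regulated stop codons with Fisher's exact
   tests.

# The 50-nt rule implementation

For a junction *j* of gene *g* the spliced transcript is built on the
**backbone**: the longest CDS-bearing isoform of *g*.  All exonic
sequence between *j*'s donor and acceptor is removed and the flanking
exons are clipped to *j*'s boundaries; backbone exons wholly inside
the spliced-out interval are dropped.  When *j*'s donor or acceptor
exon is not part of the backbone (a poison exon, an alternative
boundary variant, an alternative terminal exon), that exon is taken
from the exon union and the chain continues with the backbone exons
beyond it — the *splice-through* policy.  This is a junction-local
model: it asks what one junction does to the backbone's coding
potential, not what full isoform the cell actually made, which is the
appropriate question when the only evidence is junction-spanning
reads.

Translation starts at the backbone's annotated start codon, mapped
through the new chain via its genomic position (calls where the
junction removes the start codon are flagged and reported `NA`).  The
first in-frame stop is located and its distance measured from the
stop's 3' end to the transcript's **last** exon–exon boundary.  The
junction is PTC+ when

* distance ≥ `ptc_min_dist` (default 50 nt, **inclusive**: a stop at
  exactly 50 nt is PTC+, at 49 nt is not), and
* the stop is not the backbone's own annotated stop (normal stops are
  immune regardless of downstream junctions).

Stops in the last exon have non-positive distance and are therefore
never PTC.  Transcripts with no stop are flagged `no_stop_found` and
called PTC−.  Junctions of genes without any CDS-bearing isoform are
`NA` and excluded from PTC+/PTC− denominators; event-level ALE labels
are likewise `NA`, since with two alternative last exons the rule has
no meaningful reference boundary.

Only the exon-junction positional rule is modelled.
Poly(A)-binding-protein proximity effects, uORFs, and selenocysteine
recoding are out of scope.

# Event motifs and PSI

A junction is *expressed* for event finding when it has ≥ 1 read in
any sample.  Motifs on the per-gene graph of expressed junctions:

* **SES/MES**: a skip junction i→k together with an expressed chain
  of inclusion junctions i→j₁→…→jₘ→k across m ≥ 1 intervening,
  mutually non-overlapping exons; m = 1 is SES, m ≥ 2 MES.  Every
  distinct chain under a skip is reported as its own event with a
  shared locus, so complex regions surface once per motif instance.
* **A5SS/A3SS**: two junctions sharing an acceptor (donor) whose
  donor (acceptor) exons are genomically overlapping boundary
  variants.  The *inclusion* side is the junction retaining more
  exonic sequence (the extended variant).
* **MXE**: exons j, k (j 5' of k, non-overlapping) with i→j, j→m,
  i→k, k→m all expressed and **no** expressed j→k junction.  The
  stringency is deliberate: a single read on j→k destroys the call,
  and with both inclusion paths active the region surfaces as
  skipping events instead — the double-inclusion pattern expected
  when NMD normally polices the mutually exclusive pair.
* **AFE/ALE**: junctions from two non-overlapping terminal exons
  (never downstream/upstream of any expressed junction of the gene)
  converging on one acceptor / diverging from one donor.  The
  proximal alternative exon is the inclusion side; this choice is a
  labelling convention and ΔPSI magnitudes are unaffected.

PSI = 100 · I/(I + E) where I and E are the **mean** counts over the
inclusion and exclusion junction sets.  The mean (not the sum)
prevents a cassette's two inclusion junctions from double-weighting
against its single skip junction.  ΔPSI = PSI(KO) − PSI(WT); events
beyond ±20 percentage points are called increased inclusion /
exclusion, and an event is *supported* when PSI is defined in both
samples with ≥ `min_event_reads` (default 10) summed reads per
sample — chosen as the order of magnitude at which a binomial PSI
estimate has a standard error below ~15 points.

# Mapping policy and parameters

The internal mapper is exact-match (a Biostrings `PDict` over the
junction index concatenation and the genome, both strands).  Junction
hits require ≥ `anchor_min` (default 5) bases on each side of the
boundary.  A read matching two distinct junction windows — or,
failing a junction hit, two genomic loci — is unmapped; junction hits
take precedence over genomic ones, so junction reads are never also
counted as exonic.  Mismatch-tolerant alignment at scale is the job
of external aligners: `import_sam()` accepts alignments against the
genome and/or the exported junction-index FASTA (reference names
`gene|chrom|strand|donor|acceptor`), decoding N-gapped genome
alignments back to database junctions.  Truncation rescue trims
`trunc_step` = 10 nt from the 3' end per round (3' because base
quality decays there on short-read platforms), stopping at
`trunc_min_len` = 25 nt = 5 · anchor_min.

Normalization: upper-quartile factors equalize the 75th percentile of
nonzero counts; TMM (via edgeR, 30% M / 5% A trim, reference = first
sample) composes the trimmed mean of M-values with library size so
that factors multiply raw counts directly.  Fold changes use
normalized counts with a 0.5 pseudocount, making junctions absent
from WT but passing the 3-read cutoff upregulated by construction.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline
is validated.  Each simulated gene carries one designed event: a
clean, CDS-bearing backbone isoform A and an alternative isoform B
realising the event, with B annotated *without* CDS records — as NMD
isoforms typically are in curated repositories — so the PTC backbone
is always the clean isoform.  Designed exonic sequence uses the
{A, C, G} alphabet; stop codons therefore exist exactly where planted
(start codons, annotated stops, poison/frame-shift stops), in any
reading frame, and every designed junction's PTC status is
re-verified through `call_ptc()` before the simulation is emitted.
Introns and intergenic space use all four bases.

Default conditions: 50 genes spread over all seven classes; 75-nt
single-end reads; 3000 reads per gene per condition (giving designed
minor-isoform junctions a few tens of spanning reads — enough that a
true ~3-fold change is reliably called at the 2-fold threshold);
minor-isoform abundance 0.1; KO stabilization factor 4 on PTC+
isoforms followed by renormalization (so a 90/10 mixture becomes
69.2/30.8); splice-noise rate 0.2 random unannotated junctions per
gene at ~2 reads, reproducing the low-expression PTC+ enrichment
regime; planted PTC stop identities biased 70% TGA.  Reads are
error-free with uniform starts, abundance × effective-positions
weighted; an optional SAM route exists for external aligners.

What the generator does **not** emulate: sequencing errors and
quality decay, GC/positional coverage bias, paired ends, overlapping
genes, intron retention, biological replicate variability, and
realistic exon/intron length distributions (lengths are drawn from
narrow ranges chosen so every designed stop can satisfy the 50-nt
geometry).  Passing the recovery suites therefore demonstrates
algorithmic correctness under known truth — not robustness to
real-library noise, which enters only through the external-aligner
import path.  One further artefact: because designed exons are
T-free on the sense strand, the exonic background for the stop-codon
identity analysis is sparse in simulation (only planted stops exist);
the intronic and intergenic backgrounds are fully informative.

The conservation track generator plants elevated scores (0.9 vs a
0.35 baseline) in the 75-nt intron flanks of regulated cassette exons
and around designed PTC positions (±10 nt at 0.85), giving the
meta-profile contrasts a known truth.

# Numerical and design choices

* Coordinates are 0-based half-open throughout; GTF is converted at
  the boundary.  Junction identity is `(chrom, strand, donor,
  acceptor)` genome-wide, first gene wins; boundary variants sharing
  a coordinate pair therefore collapse to one junction record.
* Gene identity across repositories: exact id match first, then
  single-linkage clustering by ≥ 1 bp exonic overlap on the same
  strand; opposite-strand overlaps never merge.
* Ties in `longest_isoform` break toward the lexicographically
  smallest id; ambiguous exon-boundary resolution prefers the longest
  union variant.
* Conservation windows are anchored at splice-site boundaries;
  exons/introns shorter than the window contribute their available
  positions (`NA` padding on the far side), and means are per
  position over anchors with data.  Missing track data is `NA`,
  never 0.  The PTC profile is clipped at the stop's exon boundaries
  and baseline-subtracted against a seeded (default 1729) random
  sample of expressed exons, 4000 by default.  Smoothing (a cubic
  spline in figure renderings) is never applied to stored values.
* Fisher's exact tests use `stats::fisher.test`, switching to a
  seeded simulated p-value above 1000 total counts; the test suite
  checks exact agreement with hypergeometric enumeration on small
  tables.
* Per-gene AS/PTC slopes use least squares **through the origin** (a
  gene with zero junctions has zero AS junctions by definition).
* The canonical-isoform correction
  `gene_fc · (1 − ptc_ko)/(1 − ptc_wt)` is a reconstruction of the
  splice-factor correction idea and is flagged unreliable when either
  PTC fraction exceeds 0.9; raw inputs are always available
  alongside.
* Problem sizes in the validation suite (500 genes for the PTC
  oracle, 50-gene end-to-end runs at 3000 reads/gene, motif graphs up
  to 8 exons) were chosen as the smallest scales at which the
  statistical criteria are well powered on a single CPU.

# Known limitations

* PTC prediction is junction-local against one backbone; compound
  isoforms using several non-canonical junctions at once are not
  modelled (their individual junctions are each assessed
  separately).
* The pipeline pools one library per condition, as in pooled-RNA
  designs; replicate-aware dispersion modelling and differential
  tests are out of scope.
* Intron retention is not among the event classes.
* De novo junction discovery is delegated to external spliced
  aligners; imported novel exons participate in motif finding only
  through junctions whose boundaries resolve in the exon union.
* AFE events keep the backbone's annotated start codon under the
  splice-through policy; when alternative promoters truly shift the
  start codon, those PTC calls are lower-confidence (flagged via the
  novel-donor-exon flag).
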