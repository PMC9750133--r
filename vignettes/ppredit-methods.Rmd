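---
title: "Detecting PPR off-target editing sites: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting PPR off-target editing sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppredit)
```

## The problem

C-to-U RNA editing in plant chloroplasts and mitochondria converts specific
cytidines to uridines post-transcriptionally, usually restoring conserved
codons. Each edited cytidine is selected by a pentatricopeptide repeat (PPR)
protein that reads the RNA sequence upstream of the site, one repeat per
nucleotide. When a PPR editing factor is expressed outside its native
nuclear-organellar context, or overexpressed, it can deaminate cytidines it
would normally never touch. `ppredit` implements the computational workflow
for finding and characterizing such off-target sites from strand-specific
RNA-seq, together with the surrounding analyses: PPR-code scoring of
cis-elements, context-similarity profiles, splice-ratio and expression
quantification, and cross-species allele genotyping. A synthetic-data module
generates genomes and reads with known ground truth so that every stage can
be tested without external data.

In cDNA reads, editing shows up as an apparent C-to-T substitution on the
transcript strand; for a transcript on the minus strand of the reference it
appears as G-to-A in plus-strand genome coordinates. Every call made by this
package is therefore canonically C-to-U on its transcript, and strand
bookkeeping is the pipeline's main source of subtlety.

## Reference preparation

Two transformations make the mapping reference fair and unambiguous:

* **Y/R masking** (`mask_known_sites()`). Known editing positions are
  replaced by the IUPAC codes Y (C or T; plus-strand transcripts) or R (A or
  G; minus-strand transcripts). The aligner treats a masked base as matching
  both constituent bases with no penalty, so edited and unedited reads map
  equally well — without masking, heavily edited reads would be penalized
  and efficiencies biased downward. Masking is idempotent and exactly
  invertible given the site list (`unmask_known_sites()`).
* **Inverted-repeat collapse** (`collapse_inverted_repeat()`). Plastid
  genomes carry a large duplicated inverted repeat; mapping against both
  copies makes every IR read multi-mapping. One copy is removed except for
  75 nt at each border (so junction-spanning reads still align), and feature
  coordinates are shifted. Which copy to remove is taken as input; features
  straddling a cut border are truncated and flagged, since there is no
  principled way to reassign them.

Coordinates are 1-based inclusive in every file and report; the I/O layer
converts to 0-based half-open formats (BED) at the boundary.

## The built-in aligner

Discovery only needs substitution signal, so the aligner is deliberately
minimal: exact k-mer seeds (k = 15, one seed per 15 nt of read plus a final
flush seed) propose ungapped placements, each scored as matches over aligned
length on both strands; ties go to the leftmost start, then the plus strand.
Identity is matches/aligned-length, and the aligned fraction is
aligned-length/read-length. Indels and spliced alignment are out of scope —
junction analysis uses explicit junction references instead. The benefit of
this design is that the aligner is deterministic and small enough to verify
against a brute-force sliding-window oracle, which the test suite does on
sub-kilobase genomes with up to 5 substitutions per read.

Reads with equal best identity at more than one locus are flagged
multi-mapping and excluded from pileups; IR collapse removes the dominant
source of such ambiguity beforehand.

Pair selection follows the organellar enrichment rule: both mates strictly
longer than 100 nt, and at least one mate aligned with at least 85% identity
over more than half its length. The strand of a fragment is inferred from
the library chemistry: mate 1 carries the transcript sense; mate 2 reports
the opposite alignment strand.

## Site discovery and its filters

Pileups count bases per position, in plus-strand orientation, separately per
transcript strand. SNP calling then applies, per (position, strand):

* a minimum strand coverage (default 20 reads; the source protocol does not
  state one, so it is exposed as a parameter),
* a minimum rate of the most frequent non-reference base, **inclusive** at
  5% of total strand coverage,
* a type filter keeping only C-to-T (plus strand) and G-to-A (minus strand)
  calls,
* exclusion of known editing sites and of tRNA/rRNA genes, whose
  hypermodified residues produce reverse-transcription artifacts unrelated
  to mRNA editing.

Editing efficiency is reported as `100 * T/(T + C)` (equivalently A/(A+G)).
The phrase "T/C ratio" in the field's protocols is read as this two-allele
fraction, not a literal quotient: control sites are routinely printed as
100%, which only the fraction can produce. The 5% cutoff is applied to both
the SNP rate (all-base denominator) and the two-allele efficiency; both
numbers are reported per record, since published protocols use both
phrasings interchangeably.

An off-target site is retained when it reaches the threshold in at least one
mutant library while the wild type stays below 1%. The wild-type cutoff is
not exactly zero because a deep pileup virtually always contains a few
errored bases; 1% sits two orders of magnitude below the discovery threshold
and one above the expected error contribution at the default error rate.

High- versus low-affinity classification partitions the libraries:
a site edited at threshold in at least one moderate-expression library is
high-affinity; a site edited only upon overexpression is low-affinity.
Codon impact for CDS sites is computed by translating the reference and
edited codon under the standard genetic code (`"S->L"`, `"Q->STOP"`,
`"synonymous"`, or `"-"` outside coding regions).

## PPR-code scoring

The code table is configuration, not hard-coded truth: a TSV of rules
mapping (motif class, amino acids 2/5/last) to a preferred nucleotide set,
with wildcards, shipped with the generic two-amino-acid rules
(TN→A, TD→G, SN→A, SD→G, ND→U, NS→C, NN→C/U) plus the class-specific rules
relevant to this factor (VN in L1 → A/U; TD in SS → G). Combinations without
a rule are "n.p." (not predictable). A three-amino-acid variant using
position 2 is supported as a second scoring pass; the headline mismatch
totals use the two-amino-acid pass.

Anchoring places the last motif at position −4 relative to the edited C, so
a 15-motif array faces −18..−4. Within the footprint each position scores
match or mismatch against the predicted set; n.p. positions and positions
outside the footprint (−20, −19, −3..+5) are never counted as mismatches.
Per-site and per-motif mismatch totals are marginals of the same verdict
matrix, and the test suite asserts their consistency. The packaged motif
annotation for the studied factor
(`inst/extdata/qed1_motifs_synthetic.tsv`) carries the full 15-motif class
string but amino acids only for the two motifs whose identities are public
(motif 7: V/N; motif 9: T/D); the remaining entries are deliberately NA and
score n.p. — it is a partial, synthetic stand-in, not a database export.

The frequency matrix and degenerate consensus follow directly: per-position
base frequencies over aligned windows, and the IUPAC code of all bases above
an inclusion threshold. The threshold that generated the published
consensus string is not stated anywhere, so it is an exposed parameter
(default 0.2) and no test asserts a particular consensus.

## Context similarity

For the windowed similarity profile, sequences spanning −50..+50 around each
site are compared pairwise: per window of 14 nt (sliding, step 1), the
fraction of identical positions, averaged over all unordered pairs. The
editing site itself (position 0; "[C]" mode) or positions −1..+1 ("[nCn]"
mode) are removed from numerator and denominator, so the guaranteed C match
cannot inflate similarity around the anchor. The original tool's exact
normalization is not published; fraction-identical per window is the natural
reading and is what the brute-force oracle in the tests recomputes.
Ambiguity codes count as non-identical (conservative). Values are reported
at the window's left edge; centered reporting is a parameter, since the
figure-axis convention cannot be recovered from text.

## Quantification

* **Splice ratio**: reads are assigned to spliced (exon1–exon2) or unspliced
  (exon1–intron, intron–exon2) junction references when they cross the
  junction with at least 10 nt on both sides (the protocol is silent on the
  overhang; 10 nt makes a spurious exon-only assignment across the junction
  essentially impossible at the default identity threshold). A read counts
  at most once, ties between spliced and unspliced hits are discarded, and a
  read spanning both intron borders counts once. Counts are normalized to
  total mapped organellar reads; the ratio is normalized spliced over
  normalized unspliced and the spliced fraction is `spliced/(spliced +
  unspliced)`, so `ratio = f/(1 - f)` whenever both are defined.
* **RPKM**: `1e9 * reads / (length * library_total)`.
* **ΔΔCt**: technical replicates averaged; ΔCt against the reference gene;
  calibrator either given or auto-selected as the highest-ΔCt (lowest
  expression) sample, in which case the minimum fold change is exactly 1.

## Allele genotyping across species

The published search for genomic C versus pre-edited T alleles used relaxed
BLAST against external databases; this package replaces it with exact scans
over user-supplied FASTA, which keeps every call oracle-checkable: 31-mers
centered on the site (C and T versions, both strands) for nucleotide
genotyping, and an exact six-frame peptide scan for the pre-edited
19-residue peptide. Approximate matching is deliberately out of scope. A
sequence matching both allele versions is flagged ambiguous rather than
resolved; species-level calls require all sequences of a species to agree.
Editotype statuses follow the standard vocabulary (edited / unedited C /
C with unknown editing status / genomic T / no data).

## The synthetic-data module

`simulate_reads()` emulates the study's library design: strand-specific
paired-end 2 × 150 nt reads with 250 bp mean insert, per-molecule Bernoulli
editing at designated sites, per-intron splicing probability, optional
antisense transcription, and a uniform per-base substitution error rate
(default 0.001, a typical post-filter Illumina value). Base qualities are
constant high quality, coverage is uniform along transcripts (no 3' bias)
and there is no PCR-duplicate, GC-bias or indel model — the discovery
filters are coverage-agnostic and substitution-based, so these refinements
would not change what the tests can demonstrate. Consequently, passing
simulations show correctness of the pipeline's bookkeeping and estimators
under the stated model, not robustness to every artifact of real libraries
(mapping bias at paralogs, position-dependent error, coverage dips).

Simulation scale in the tests and acceptance script was chosen so that
binomial noise is well below the quantities checked: per-site coverage of
roughly 2,200–2,500x (three binomial standard errors at 2,000x and an
efficiency near 90% are about 1.9 percentage points) and 5,000 junction
reads for the splice fraction (three standard errors are about 1.9 points).
Toy genomes are 1.2–2.5 kb with 500-nt genes; each simulated library is a
few thousand pairs, which the aligner maps in seconds.

## Pipeline orchestration

`run_pipeline()` chains reference preparation, mapping, pileup, SNP calling,
filtering and wild-type-subtracted discovery, writing every intermediate and
the resolved configuration to the output directory; identical configuration
and seeds give byte-identical outputs. Efficiencies are quantified on
uncollapsed pileups; identical-read collapsing, used in the original
protocol's discovery step, is exposed as an option
(`collapse_duplicates`) because collapsing deep data down to unique
sequences is correct for deciding *whether* a site exists but distorts *how
much* it is edited. There is no shell entry point: the exported functions,
the acceptance script and this vignette are the interface.

## Known limitations

* Ungapped alignment: the trans-spliced rps12 intron and any
  indel-containing read are outside the aligner's scope.
* The aligner's k-mer seeding can miss a placement when substitutions
  disrupt every seed; with seeds every 15 nt this requires pathological
  error placement at the identity thresholds used.
* The PPR code table ships with the public two-amino-acid rules only; motif
  classes without published rules score n.p. rather than guessing.
* Statistical testing of differential editing between libraries is not
  implemented; the workflow applies plain thresholds, as its source does.
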