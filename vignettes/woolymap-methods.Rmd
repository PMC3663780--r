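---
title: "Methods: backcross fine-mapping and splice-consequence prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: backcross fine-mapping and splice-consequence prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woolymap)
```

`woolymap` models the complete desk side of a positional-candidate study of
a recessive mouse coat mutation: simulating and analyzing a testcross
panel, refining a critical interval with recombinant-only genotyping,
triaging candidate genes, detecting a coisogenic deletion, and predicting
its splicing and protein consequences. This vignette is the package's
account of the underlying models, the tunable parameters, the synthetic
data it generates, and the choices made where the design was genuinely
open.

## The cross and the meiosis model

The design is an intraspecific testcross: an (A × N)F1 female, carrying
the recessive mutation on her N-derived chromosome, is bred to
homozygous-mutant N males. Only the dam's meiosis is informative — the sire
transmits the same mutant N haplotype to every offspring — so each progeny's
genotype directly reads out one maternal gamete, and the phenotype reads
out the allele transmitted at the trait locus itself. `simulate_backcross()`
therefore simulates a single chromatid per progeny.

Crossovers follow the Haldane model: counts per interval are Poisson with
mean equal to the genetic length in Morgans, without interference. Rather
than drawing crossover points, the simulator walks the ordered loci
(markers plus the trait) as a Markov chain, switching parental origin
across each interval with probability

$$ r = \tfrac{1}{2}\left(1 - e^{-2d}\right), $$

the Haldane map function of the interval length $d$. For a Poisson process
this is exact, not an approximation. Interference is deliberately out of
scope: over the few-cM intervals this design resolves, interference changes
double-recombinant rates that the analysis flags but never relies on.

Tunable parameters and their defaults:

* `n` — panel size. The replica panel uses 1,679, the size at which a
  recombination fraction of ~0.5% still yields ~10 recombinants.
* `penetrance` (default 1.0) — probability that a homozygous-mutant
  genotype shows the mutant phenotype; applied as a Bernoulli mask to the
  transmitted-allele truth, so reduced penetrance produces normal-looking
  mutants (apparent double recombinants), which the localization flags.
* `genotyping_error` (default 0) — per-genotype flip probability.
* `cm_per_mb` (default 0.5) — linear physical-to-genetic conversion, the
  genome-wide mouse average; used when a map is built from physical
  positions alone.
* `seed` — always an explicit argument; the global RNG state is saved and
  restored, so no function depends on or perturbs ambient randomness.

## Localization by minimal crossovers

`localize_trait()` treats the trait as a pseudo-locus whose dam allele is
implied by phenotype (mutant ⇒ mutant-carrying N allele, normal ⇒ A
allele) and places it in the inter-marker slot minimizing the total number
of crossovers implied across all progeny. Slots tied at the minimum are
merged: a marker that never recombines with the trait makes its two
adjacent slots indistinguishable, so such markers end up *inside* the
reported interval, exactly as a zero-recombinant marker should. The flanks
are the markers bounding the merged run — equivalently, the nearest markers
whose trait-marker recombinants place the trait on the other side. If one
side shows no recombinant at all, the outermost typed marker is used and a
warning recorded.

Missing genotypes make a progeny uninformative for the affected
comparisons only; it is never dropped globally. Progeny whose flanking
alleles both disagree with the trait allele (requiring a double crossover
inside the interval, or reflecting phenotyping/genotyping error) are
flagged and retained.

The second mapping stage, `refine_interval()`, mirrors the recombinant-only
genotyping strategy: new markers strictly inside the current interval are
typed only on the interval's recombinants, and every other progeny is
imputed as parental across the interval (its flanking alleles agree, and
that shared allele is copied onto the new markers). Localization is re-run
over the union of loci; by construction the result can never widen, and
the implementation asserts this.

Recombination fractions are recombinant counts over informative meioses
with the binomial standard error $\sqrt{\hat r(1-\hat r)/n}$. No multipoint
likelihood, LOD scores or map-function inversion is used anywhere: the
method of the analysis is pure recombinant counting, and the package keeps
that property so every reported number can be audited against the
haplotype table.

## The replica panel

The packaged panel (`replica_backcross_panel()`) is deterministic, not
simulated. It encodes exactly the totals the study design states: 1,679
progeny splitting 840 mutant : 839 normal (χ² = 1/1679 ≈ 0.0006, P ≈
0.98); 11 recombinants between the proximal flanking microsatellite and
the trait; 19 between the trait and the distal flank; an interior marker
with zero trait recombinants; all remaining progeny parental. The
refinement stage's SNP genotypes place two crossovers between SNP2 and the
trait and one between the trait and SNP6, with SNP3-5 never separated from
it. Where the source gives only totals, the sub-splits (how the 11
proximal crossovers distribute among sub-intervals, which phenotypes carry
them) are fixed constants chosen once; they affect nothing the analysis
reports beyond the per-subinterval crossover counts.

Physical positions sit on a local 0-based frame chosen once: flank-to-flank
4.8 Mb, SNP2-SNP6 0.75 Mb, trait at 3.30 Mb. Only marker names that the
underlying study names are used.

## Candidate triage

`triage()` applies three exclusion rules with a fixed precedence —
`outside_interval` over `knockout_normal_coat` over `no_skin_role` — so
input order cannot change membership or reasons. Genes are interval
members under any-overlap, half-open semantics. Exclusion requires
positive evidence: a gene with unknown knockout phenotype and unknown
expression stays in as a weak candidate rather than being silently
dropped. The packaged table (`replica_interval_genes()`) marks the
collectively described genes with generic names (`predicted_gene_*`,
`skin_silent_*`), since the source does not name them individually; its
coordinates are synthetic.

## Coisogenic deletion detection

Two coisogenic strains differ, by definition, only at the mutated locus,
so `find_deletion()` refuses anything that is not a single contiguous
deletion instead of aligning around it: with longest common prefix $P$ and
suffix $S$, a valid pair satisfies $P + S \ge |mutant|$, and every
placement $s \in [\,|mutant|-S,\ P\,]$ is equivalent. The reported call is
the smallest such $s$ (left alignment, the standard indel normalization)
with `ambiguity_span` recording how many equivalent left shifts were
absorbed. VCF output uses the 1-based anchor-base convention (REF carries
the preceding base plus the deleted block).

Annotation against gene models is interval arithmetic, strand-aware, with
transcription-order ordinals. A splice acceptor is defined structurally as
the last two intronic nucleotides plus the first exonic one; a donor as
the last exonic nucleotide plus the first two intronic ones; losing any
part of a site counts as losing the site. No motif scoring, branch-point
or splicing-strength model is involved — the biological inference this
package reproduces rests on physical removal of the acceptor, and the
tests check the annotation against a per-base brute-force oracle.

## Exon skipping, frame rule, and consequences

`predict_mutant_model()` drops every exon whose acceptor is lost. Donor
loss triggers skipping symmetrically: the skipping rule is isolated in one
place and purely structural, and the symmetric choice is the natural
extension where only acceptor loss is ever exercised by the replica.
Exons partially deleted but with both sites intact keep their remaining
sequence; deletions strictly internal to an intron leave the spliced
transcript unchanged (verified base-for-base for the overlapping gene in
the replica). A deletion that removes the CDS start codon is outside the
rule's domain and raises an error rather than guessing at re-initiation.

Downstream quantities follow from the mutant model:

* **Amplicons** (`predict_amplicon()`): the spliced distance from the
  first base of the forward primer site to the last base of the reverse
  site, inclusive — the convention in which gel product sizes are read.
  Primer sites are addressed by exon ordinal, so a skipped exon raises
  "primer site lost" instead of silently mismeasuring.
* **Translation** (`translate_cds()`): standard nuclear code only,
  hard-coded in the package; translation runs to the first stop and flags
  a missing in-frame stop. The test suite checks it against Biostrings'
  translator on random sequences — two independent routes to the same
  table.
* **Frameshift**: reported in the consequence report by the frame rule —
  a shift occurs iff the removed coding length is not a multiple of 3.
  The prefix-based comparison (`compare_proteins()`) still reports where
  the proteins diverge; the two are distinct because an in-frame skip also
  diverges at the junction without shifting frame.
* **Domains**: retention is the fraction of a domain's residue span inside
  the identical prefix; anything below 1 is listed as truncated. Proteins
  are compared by common prefix, not alignment, which is exactly right for
  single-junction events and deliberately wrong for anything more complex.

## The replica locus fixture

`replica_locus_fixture()` builds a 10-kb genomic sequence carrying two
overlapping genes: a five-exon plus-strand gene whose exon 3 has 125 nt
and whose CDS totals 2,439 nt (812 codons plus stop), and a thirteen-exon
minus-strand gene laid out so that one of its introns (intron 10-11 in
transcription order) fully contains the 955-bp deletion. The deletion
removes the final 830 bp of the plus-strand gene's intron 2-3 together
with all of exon 3 — taking the exon-3 acceptor with it while remaining
strictly intronic for the other gene. The nested primer pair on exons 1
and 4 gives a 484-bp spliced wild-type product, hence 359 bp after the
125-nt skip. The exon 2/3 junction is placed inside codon 272, and the
shifted frame in exon 4 meets a planted out-of-frame stop after 24 novel
residues, truncating the 812-residue protein to 295.

These anchors are design properties — exon lengths, CDS bounds, primer
offsets, a T-free stretch at the start of exon 4 so the shifted frame
meets no premature stop before the planted one — while everything else
(UTRs, introns, non-anchored codons) is drawn from a seeded RNG. The
anchored quantities are therefore invariant to the seed, and the tests
assert this. Intron boundaries carry canonical GT/AG dinucleotides
(strand-aware) for realism, although no code reads them. Deletion
boundary bases are patched so the call has zero ambiguity.

What the fixture does *not* emulate: real exon/intron lengths of the
actual genes (not published), real genomic coordinates, sequence homology,
SNP-level strain variation, or repetitive context around the deletion. A
green test on the fixture establishes that the pipeline's arithmetic and
rules are correct on a locus with the published structure — not that the
published sequence itself was re-analyzed.

Note on the published numbers: the source's frameshift bookkeeping is
internally inconsistent (divergence "after codon 224" cannot be reconciled
with a codon spanning the exon 2/3 boundary at residue 272, 24 novel
residues, and a 524-residue product). The fixture anchors only the
mutually consistent quantities — 812 residues, 484/359-bp products, the
125-nt exon — and reports what its own structure yields: divergence after
codon 271, 24 novel residues, a 295-residue mutant protein.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open internally; GFF3 and VCF output are
  1-based inclusive; all printed text is 1-based.
* Genotype codes are `H` (dam transmitted the A-derived allele), `N`
  (N-derived), `-` (missing) in TSV.
* Maps are single-chromosome; equal marker positions are rejected at
  construction, so "nearest marker" ties cannot arise downstream.
* A panel with all trait alleles unknown localizes to the whole map with
  warnings on both sides rather than erroring.
* Zero-length deletions are identity operations in `apply_deletion()` and
  invalid as comparator output (`find_deletion()` requires the mutant to
  be strictly shorter).
* The chi-square test uses no continuity correction; at the panel sizes
  involved the correction is immaterial, and the uncorrected statistic is
  the one whose null distribution the tests verify for uniformity.

## Known limitations

Intercross (F2) designs, sex linkage, quantitative traits, interference
models, multipoint likelihood mapping, read-based variant calling, SNP
calling, splicing-strength or NMD prediction, and protein structure are
all out of scope. The CLI surface of a standalone tool is intentionally
absent: the exported functions compose in a few lines of R (see the
README's worked example), and the acceptance script shows the end-to-end
invocation.
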