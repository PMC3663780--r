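# woolymap

Positional-candidate analysis tools for a fully penetrant recessive coat
mutation in the mouse — the wooly (*wly*) locus on proximal chromosome 11 —
from testcross fine-mapping through candidate triage to the molecular
consequence call on the overlapping *Slc5a10*/*Fam83g* locus.

## The problem and who this is for

A spontaneous recessive coat mutation segregating in an inbred colony can
be assigned to a gene without any sequencing of the whole genome: cross a
carrier F1 female to homozygous-mutant males, count recombinants between
the trait and ordered markers, shrink the critical interval in two stages,
rule genes in or out on published functional evidence, and compare
coisogenic wild-type and mutant sequence over the survivors. `woolymap`
implements each of those steps as composable, tested R functions, plus a
synthetic-data module that generates backcross panels and genomic fixtures
with the statistical and structural properties the analysis assumes — so
the whole pipeline is testable without any external data.

It is written for geneticists doing positional cloning in experimental
crosses, and for anyone who wants a worked, reproducible model of the
classic recombinant-counting approach.

## The quantities at its core

* **Segregation**: a testcross segregates 1:1;
  χ² = Σ (Oᵢ − E)²/E with E = n/2, df = 1.
* **Recombination fraction** between loci *a*, *b*:
  r̂ = n_rec / n_inf with SE = √(r̂(1−r̂)/n_inf). Meiosis is simulated
  under the Haldane map function r = (1 − e^(−2d))/2 (d in Morgans, no
  interference).
* **Trait localization**: the trait pseudo-locus (phenotype read back as
  the dam-transmitted allele) is placed in the inter-marker slot that
  minimizes total crossovers across the panel; tied slots merge into one
  critical interval whose bounding markers are the flanks.
* **Deletion detection**: for coisogenic sequences differing by one
  contiguous deletion, the longest common prefix P and suffix S satisfy
  P + S ≥ |mutant|; the call is left-aligned with its ambiguity recorded.
* **Splice consequence**: an exon whose acceptor (or donor) is lost is
  skipped; a skip of L nt shifts the reading frame iff L ≢ 0 (mod 3);
  RT-PCR products shorten by exactly the skipped length when the primers
  flank the skip.

## Worked example

```r
library(woolymap)

# Stage 1: the 1,679-progeny replica testcross panel
panel <- replica_backcross_panel()
glance(test_segregation(panel))
#>   n_mutant n_normal     chi2    df p_value
#> 1      840      839 0.000596     1   0.981

haps <- infer_transmitted_haplotypes(panel)
loc <- localize_trait(haps)
loc
#> <trait_localization> wly in (D11Mit208, D11Mit242): 11 proximal + 19 distal
#> recombinants, 4,800,000 bp
#>   not separated from the trait: D11Mit260

# Stage 2: SNPs typed only on the 30 recombinants
refined <- refine_interval(loc, panel, replica_snp_genotypes(), replica_snp_map())
refined
#> <trait_localization> wly in (SNP2, SNP6): 2 proximal + 1 distal
#> recombinants, 750,000 bp
#>   not separated from the trait: D11Mit260, SNP3, SNP4, SNP5

# Candidate triage over the interval gene table
triage(replica_interval_genes(), replica_critical_interval())
#> <triage_result> 16 gene(s): 2 primary, 14 excluded
#>   primary: Slc5a10, Fam83g

# Coisogenic sequence comparison on the replica locus fixture
fx <- replica_locus_fixture(seed = 1)
call <- find_deletion(fx$genome, fx$mutant_genome, chrom = fx$chrom)
call
#> <deletion_call> replica_locus:3284-4239 (0-based), 955 bp deleted, ambiguity 0

# Splice-consequence prediction for the exon-overlapping gene
rep <- predict_consequence(fx$genes$Fam83g_like, fx$genome, call,
                           fx$primers$fam_nested$pair)
rep
#> <consequence_report> Fam83g_like
#>   skipped exon(s): 3
#>   RT-PCR product: 484 bp wild type, 359 bp mutant
#>   frameshift: after codon 271; 24 novel residue(s)
#>   protein: 812 aa wild type -> 295 aa mutant
#>   truncated domains: DUF1669-like (94% retained); PLD-like-N (95% retained);
#>   proline-rich (0% retained)
```

Reading the output: the panel segregates 1:1 (P ≈ 0.98), the trait maps
between the flanking microsatellites with 11 + 19 recombinants, and
recombinant-only SNP typing shrinks the interval to 0.75 Mb containing four
markers never separated from the trait. Triage leaves the two overlapping
skin-expressed genes. The comparator finds a single 955-bp deletion that is
intronic for one gene but removes the other's exon-3 acceptor, so exon 3
(125 nt) is skipped: the nested RT-PCR product drops from 484 to 359 bp,
the frame shifts at the exon 2/4 junction, and the 812-residue protein
truncates after a short run of novel residues, removing the annotated
C-terminal domains.

The same gene on the intronic side is unaffected:

```r
mut_a <- predict_mutant_model(fx$genes$Slc5a10_like, call)
identical(splice(mut_a, fx$mutant_genome),
          splice(fx$genes$Slc5a10_like, fx$genome))
#> [1] TRUE
```

## Acceptance script

`scripts/acceptance.R` rebuilds the replica fixture from scratch, runs the
deletion comparator, the exon-skipping predictor and the translator, and
writes the recomputed quantities (mutant amplicon length, called deletion
length, wild-type protein length) as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The seed controls the fixture's random background (introns, UTRs,
non-anchored codons); the reported quantities are structural properties of
the locus design and are recomputed, not stored.

## More

The methods vignette (`vignettes/woolymap-methods.Rmd`) describes the
meiosis model, the localization algorithm, the fixture design and its
deliberate limitations, and the numerical conventions (0-based internal
coordinates, 1-based GFF3/VCF output, left-aligned indels).
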