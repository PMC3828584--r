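---
title: "Family-based recessive variant prioritization in quad pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based recessive variant prioritization in quad pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

In a nuclear family with two unaffected parents and two (or more) children
affected by an autosomal recessive disorder, the causal genotype must follow
one of two patterns at the causal gene, under full penetrance:

* **shared homozygous** — every affected child carries the same variant on
  both haplotypes and each parent is a heterozygous carrier; or
* **compound heterozygous in trans** — the children carry two different
  damaging variants in the same gene, one inherited from each parent, so
  both copies of the gene are disrupted.

`quadrec` implements the filtering cascade that exploits this: classify every
exome variant by its predicted consequence on a transcript, keep only
putatively damaging classes, remove everything already catalogued in
reference site databases (a novel severe recessive allele is expected to be
absent from them), scan the remaining variants gene by gene for the two
segregation patterns, and finally intersect the surviving genes with a list
of genes already implicated in the phenotype.

The quad design is what gives the scan its power. With unphased genotypes, a
single proband cannot distinguish two variants in trans (one per haplotype)
from two in cis (same haplotype, one intact gene copy). With both parents
genotyped, phase is inferred by transmission: if the mother carries exactly
one of the pair and the father exactly the other, the pair must be in trans
in the children. When *both* parents carry the same variant its origin is
ambiguous; such variants are reported with the candidate as "unphased
extras" but never count toward the trans requirement. A variant carried by
*neither* parent is inconsistent with transmission (possible de novo call or
genotyping error) and is excluded from candidacy. An unaffected parent who
is homozygous for the alternate allele contradicts the full-penetrance
recessive model, and the variant is excluded.

Missing genotypes **fail closed**: a variant with any missing genotype in
the pedigree cannot qualify. This trades sensitivity for reproducibility —
a candidate list should not depend on what was *not* observed.

## Consequence classification and coordinates

Each gene is represented by one canonical transcript: ordered genomic exons,
the CDS bounds, and the spliced, strand-corrected coding sequence. Coding
SNVs are classified by mutating the affected codon and translating both
codons with the standard genetic code (no initiation-codon special cases, no
alternative codes): identical residues are `synonymous`, a new stop is
`stop_gain`, otherwise `nonsynonymous`. A substitution that destroys the
reference stop codon is reported as `nonsynonymous` (the category set has no
separate stop-loss class). Indels in the CDS are `frameshift_indel` when the
allele-length difference is not a multiple of 3, else `inframe_indel`;
indels straddling an exon/intron junction are conservatively retained as
`splice_region`.

Intronic positions are expressed as intron number (in transcript order) plus
a signed offset: positive from the donor (5′) side, negative from the
acceptor (3′) side, whichever is nearer, with ties resolved to the donor
side. Positions within **10 bases** of a junction are `splice_region`; the
window is inclusive at the boundary (|offset| ≤ 10). The damaging-class
filter keeps `nonsynonymous`, `stop_gain`, `splice_region`, and
`frameshift_indel`; UTR-exonic variants are classified `utr` and dropped.

Coordinates follow VCF conventions externally (1-based, indels anchored on a
shared first base) and the CDS arithmetic is the standard one: CDS position
*p* lies in codon ⌊(*p*−1)/3⌋+1 at offset ((*p*−1) mod 3)+1. Names are
rendered as HGVS coding (`c.8375T>C`) and protein (`p.V2792A`) strings, and
intronic variants in the legacy intervening-sequence notation
(`IVS25+3G>A`), which remains common in the clinical deafness literature.

Site-database exclusion is **presence/absence on the exact
(chrom, pos, ref, alt) key**, not an allele-frequency threshold: matching by
position alone would discard novel alleles arising at previously catalogued
sites, which is precisely the class of allele the cascade is built to find.

## Protein-level interpretation

Candidate missense changes are mapped onto a protein domain table (closed
residue intervals, overlapping entries allowed and preserved — the bundled
myosin XVa table keeps the published overlap between the first FERM domain,
residues 2687–2867, and the putative SH3 domain, 2865–2959). Conservation
is assessed on a user-supplied protein alignment: the ungapped reference
position is mapped to its alignment column, the identity fraction is the
proportion of non-gap residues in that column equal to the reference
residue, and a residue is "mammal conserved" when it is invariant across a
declared mammal panel (default: human, chimpanzee, macaque, cow, dog,
mouse, rat — the outgroups chicken and zebrafish are excluded). A gap in a
mammal row counts as not conserved but leaves the identity-fraction
denominator.

## What the simulator emulates — and what it does not

The synthetic generator produces a complete, self-contained quad dataset:
toy multi-exon genes (one pseudo-chromosome each, both strands, canonical
GT..AG introns, valid CDS: start codon, no internal stop, length divisible
by 3), background variants segregating under Mendelian transmission from
random parental genotypes, two site databases, a disease-gene list, a
nine-species alignment of the planted gene's protein, and the planted
causal signal. Defaults: 200 genes, 2000 background draws, a 20-gene list,
and a compound-het plant — a paternal coding nonsynonymous SNV plus a
maternal intronic SNV at donor offset +3, the carrier split observed in the
motivating family.

Database membership is drawn per background variant (90% by default) and
the allele frequency is conditioned on it: catalogued sites are common
(MAF 0.05–0.5), novel sites rare (MAF 0.001–0.02). That is what membership
in a large site catalogue means for a segregating site, and it reproduces
the qualitative behaviour of real exomes, where database exclusion is the
single most powerful filter and chance recessive patterns among novel
variants are rare. Near-miss decoys are planted deliberately: cis-only
pairs (both variants from one parent), single-carrier homozygous lookalikes
(deliberately non-Mendelian, emulating a genotyping error — these are
excluded from the Mendelian audit, which covers the random background), and
perfect trans pairs that are catalogued in the databases.

Everything flows from one seeded RNG stream in a documented order, so a
config is a complete recipe: identical configs give byte-identical
datasets. Missingness is applied last by thresholding a per-genotype
uniform draw that does not depend on the rate, so the missing sets are
nested as the rate rises and per-seed recovery of the planted gene is
monotone non-increasing by construction — the robustness analysis in
`analysis/04_robustness.R` measures how quickly the fail-closed policy
loses the candidate (at 10% missingness roughly half the seeds already
lose it, since a compound-het candidate needs eight intact genotypes plus
informative parental homozygous-reference calls).

What the simulator does **not** emulate: read-level error, linkage
disequilibrium between background sites (the cascade uses no LD), allele
frequencies tied to real populations, multi-transcript genes, and real
genome coordinates. Passing the end-to-end tests therefore demonstrates the
correctness of the *filtering logic* under the stated genetic model, not
calling accuracy on real sequence data.

## Numerical and design choices

* Splice window 10 bases, boundary-inclusive; the window's inclusivity at
  exactly 10 is this package's call (the convention the tallies imply does
  not fix the boundary).
* Intron numbering counts introns of the whole transcript in transcript
  order, so "IVS25" is the intron after exon 25 — the conventional reading
  of the legacy notation.
* Domain intervals are closed on both ends, as printed tables of domain
  boundaries conventionally are.
* Equidistant intronic positions (exact middle of an even-length intron)
  take the donor-side positive offset.
* One candidate per gene: a gene qualifying as both shared-homozygous and
  compound-het is reported once, as homozygous, with a dual-mode flag,
  avoiding double counting.
* Genes are evaluated independently; a variant inside two overlapping gene
  models is considered for each gene separately.
* Multi-allelic VCF rows are split into biallelic records on read, each
  sample's dosage recoded as the count of that alternate allele; phase
  separators are accepted and ignored (phase is inferred from parents, not
  from the VCF).
* No genotype-quality or depth filtering is implemented: the input is
  treated as called genotypes, and quality control is upstream of this
  package.
* Desk-scale problem sizes throughout (hundreds of genes, thousands of
  variants, 20-seed grids) — chosen so the full property suites, including
  the exhaustive oracle comparisons, run in minutes on one CPU while still
  exercising every code path.

## Known limitations

One canonical transcript per gene (no consequence aggregation across
isoforms); no splice-strength scoring beyond the distance window; no
X-linked, dominant, or de novo models; no penetrance or population
allele-frequency modelling; SNV-centric protein annotation (indel protein
consequences are classified but not named at the protein level).
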