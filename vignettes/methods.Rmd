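---
title: "Methods: cohort variant mining, consequence annotation and flock genetics with ovmx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort variant mining, consequence annotation and flock genetics with ovmx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovmx)
```

`ovmx` implements the computational workflow for mining sequence variants
in the ovine Mx genes from cohort read pileups, annotating their coding
consequences, and analysing the population genetics of the resulting
genotypes. This vignette is the package's account of the underlying
models, the tunable parameters and their defaults, the design choices that
were genuinely open, and what the synthetic cohorts do — and do not — say
about real data.

## Coordinate model

All coordinates are 1-based and inclusive: genomic positions, CDS
positions (c.1 is the A of the start ATG) and codon numbers (codon *k*
spans c.(3k−2)..3k). Conversion to 0-based half-open coordinates happens
only inside file writers. Minus-strand genes are reverse-complemented at
splice time, so all downstream CDS arithmetic is strand-agnostic; this
matches the transcript-oriented c. notation used throughout variant
reporting. `genomic_to_cds()` assigns every position of a locus exactly
one label (CDS location, 5'UTR, intron, 3'UTR, upstream, downstream) —
the partition is property-tested against a brute-force enumeration of the
spliced transcript.

`map_transcript_to_genome()` chains maximal exact matches greedily from
left to right, taking at each step the longest prefix of the remaining
transcript found downstream of the previous block (ties broken by the
smallest genomic start). This mirrors manual 100%-identity exon mapping of
a transcript (e.g. a multi-exon 5'UTR) onto an assembly; it performs no
gapped or mismatched alignment, which is a deliberate non-goal. The
default minimum block of 15 nt is conservative relative to the ≥ 32-nt
exact matches such manual mappings rest on; blocks shorter than the
minimum produce an explicit "no mapping" result naming the untiled
interval. Greedy chaining can fail on transcripts whose exon boundaries
sit inside long genomic repeats; the round-trip property test therefore
asserts correctness of every returned mapping rather than success on
pathological inputs.

## Genotype calling and the cohort filter

A genotype is called per (individual, site) from the two most frequent
alleles over \{A, C, G, T, −\}, where "−" is a single-base deletion (gap)
read. With read depth *d* and minor-allele fraction *m* over the top two
alleles:

| parameter           | default | meaning                                        |
|---------------------|--------:|------------------------------------------------|
| `min_depth`         |      10 | below this the call is `missing`               |
| `hom_max_minor`     |    0.10 | *m* ≤ this → homozygous                        |
| `het_min_minor`     |    0.25 | *m* ≥ this → heterozygous                      |
| third-allele bound  |    0.10 | a 3rd allele above 10% of depth → `ambiguous`  |

The depth-10 floor and the criteria thresholds below are fixed by the
workflow being implemented; the 0.10/0.25 genotype band is a package
design decision: at depth ≥ 10 a true heterozygote concentrates near
*m* = 0.5 while sequencing error stays below a few percent, so the band
(0.10, 0.25) is an explicit "ambiguous" buffer rather than a hard
boundary — mirroring how sires with unclear chromatograms are treated as
having an ambiguous genotype rather than forced into a class. Multiallelic
evidence fails safe to `ambiguous` because the workflow's acceptance rules
are defined for biallelic sites only.

A candidate site becomes an accepted variant iff four criteria hold:
(i) the variant is observed in at least one individual at ≥ 10-fold
coverage; (ii) some individual's minor-allele read fraction exceeds 0.45
(strict); (iii) every homozygote carries one of the two alleles seen in
the heterozygotes, or all homozygotes are homozygous non-reference;
(iv) at least two heterozygotes exist and all show the same change —
ambiguous calls are excluded from (iii) and (iv). In addition the site
must lie in a *suitable coverage region*: summed depth over individuals
with depth ≥ 10 strictly exceeds 99 reads. Pooled read counts and f(alt)
use only individuals with depth ≥ 10 at the site, consistent with
criterion (i). f(alt) is reported rounded to two decimals; all
computation retains full precision. The criteria implementation is
property-tested against an independent brute-force transcription of the
rule text on 500 randomized small cohorts.

Single-base deletions are carried through the pileup as a gap allele at
the deleted position and converted to left-anchored REF/ALT (previous
reference base) only in the VCF writer, per VCFv4.2.

## Consequence annotation

Substitutions are annotated via the standard genetic code (the code table
is injectable for testing): synonymous, missense, nonsense (new stop) or
stop-lost. Codon-1 changes are classified missense but flagged
`start_lost_candidate`, because loci with several in-frame ATGs can leave
the functional start ambiguous. A single-base deletion is translated
codon-by-codon in the shifted frame from the first affected codon until a
stop; the novel peptide (`fs_peptide`, length `fs_len`) excludes the stop,
and `stop_offset = fs_len + 1` counts the stop as an altered codon. Two
label conventions exist for frameshifts: the package default `fsN*` counts
the *novel residues before the stop* (so a deletion with seven novel
residues and a stop at the eighth altered codon is `fs7*`), while standard
HGVS counts the stop position (`fsTer8`); both numbers are stored and
either label can be emitted. If no stop is reached before the sequence
ends, the class is `stop_lost` with an explicit `no_stop_found` note. The
frameshift walk is property-tested against full re-translation of the
edited sequence with Biostrings.

The packaged *MX1*/*MX2* coding-variant tables give codon numbers, the
nucleotide change and the amino-acid change, but not intra-codon offsets.
`build_variant_cds()` therefore reconstructs a fixture CDS by exhaustive
search over the (codon, offset) pairs consistent with each printed row —
the search is deterministic (smallest offset, then alphabetical codon) and
fails loudly if a row admits no consistent codon. The frameshift context
(codons 329–337) is pinned so that deleting c.985 reproduces the published
novel peptide Ser.Arg.Ile.Ser.Pro.Thr.Ser followed by a stop.

## Population genetics

Hardy–Weinberg conformance uses the Pearson chi-square against
(p², 2pq, q²)·n with df = 1 — three genotype classes minus one minus one
estimated allele frequency. This is the standard large-sample test; an
exact test is a non-goal. Monomorphic samples return an explicit
"undefined" result rather than p = 1. Flock contrasts are 2×2 Pearson
chi-squares on allele counts with df = 1; the continuity correction is off
by default and available by flag, since which variant was used in the
original analyses is not stated. Significance defaults to α = 0.05 (the
methods text this implements prints "α = 0.5", an evident typo for 0.05
given that conformance was reported as p > 0.05), and no multiple-testing
correction is applied, deliberately, for these small datasets.

Sire inference evaluates, for each candidate sire genotype, the product
over progeny of the Mendelian probability of the observed offspring
genotype, with each dam modelled by her known genotype or by a random
allele at the population frequency. The maximum-likelihood genotype is
reported as "likely" only when it beats the runner-up by at least 20:1 —
a package choice calibrated to reproduce the qualitative "likely
homozygote" verdicts that 17-progeny sire groups support; the threshold is
configurable. A trio impossible under every sire genotype (e.g. a hom-alt
offspring of a hom-ref dam) raises a pedigree-inconsistency error naming
the trio.

Haplotype enumeration over *h* heterozygous linked sites returns all
2^(h−1) phase configurations (one when h ≤ 1); phase is unambiguous iff at
most one site is heterozygous. Relative expression follows 2^−ΔΔCt with
replicate Ct values averaged before differencing.

When genotype counts are reconstructed from a reported allele frequency
and sample size (`genotype_counts_from_frequency()`), rounding is checked
against allele conservation and a warning is raised when the reported
frequency is not representable (e.g. f = 0.5 over 33 animals implies an
odd allele count). One published flock table prints n = 2 for a row where
every parallel row has n = 20; the packaged fixtures use 20.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure of a diploid WGS
cohort over a candidate locus:

* genotypes at each planted variant are two independent Bernoulli(f)
  draws per individual (Hardy–Weinberg by construction; verified by a
  goodness-of-fit test at n = 10,000);
* depth per (individual, site) is i.i.d. Poisson with mean 20 by default,
  the middle of the 10–30× range typical of the cohorts this workflow
  targets;
* reads are drawn from the genotype's allele mix (alt fraction 0, 0.5, 1)
  and corrupted at a per-base error rate of 0.005 by default (Sanger/
  Illumina-scale), substituting uniformly among the other three
  nucleotides. A true gap read (deletion allele) is reported as a gap:
  substitution error is modelled for base calls only.

Randomness is organised as one master seed from which per-individual
substream seeds are drawn once, so enlarging a cohort never perturbs
previously generated individuals, and the same seed is bit-reproducible.
The generator deliberately omits coverage autocorrelation, mapping error
and multi-base indels: the acceptance criteria are strictly per-site, so
these features cannot change which calls the criteria make, but their
absence means a clean pass on synthetic cohorts does not certify
performance on real alignments with alignment artefacts.

`simulate_pedigree()` draws parental genotypes from the allele frequency
and transmits alleles Mendelianly. `simulate_closed_flock()` iterates
Wright–Fisher binomial resampling of 2N alleles with viability selection
(fitness 1, 1, 1−s against alternative homozygotes); the deterministic
mode iterates the infinite-population recurrence, which for a recessive
lethal is f′ = f/(1+f) — the stochastic and deterministic modes are tested
against neutral mean-preservation and that closed form respectively.
Closed-flock simulations use a breeding population of ~90 (80–100 ewes
plus sires, as in the research flocks this models).

## Numerical and degenerate-input choices

* Tie-breaks in genotype calling follow the fixed allele order
  A, C, G, T, − so calls are deterministic.
* The alternative allele of a record is the most frequent pooled non-ref
  allele among qualified individuals.
* Empty pileups yield empty region lists and empty record frames, not
  errors; malformed inputs (negative counts, unknown alleles, length
  mismatches) are rejected at construction.
* Pipeline outputs contain no timestamps, so re-running on identical
  inputs is byte-identical; the JSON manifest records version, seed,
  thresholds and a hash of the analysis parameters.
* Problem sizes in the test suite are chosen for desk-scale validation:
  criteria oracle agreement on 500 cohorts of ≤ 5×20, exact recovery on a
  600-bp locus with 24 animals, a 50-kb × 8-animal error-only screen for
  false accepts, 200 simulated sire groups, and 500 neutral 20-generation
  flock replicates.

## Known limitations

* The miner starts from allele counts: alignment, base-quality
  recalibration and BAM handling are out of scope.
* Only biallelic SNPs and single-base deletions are modelled; multi-base
  indels and true multiallelic segregation are not.
* The Hardy–Weinberg test is asymptotic and unreliable for very small
  expected counts; the package reports it regardless, as the workflow it
  implements did, and leaves exact tests to specialised software.
* Transcript-to-genome mapping is exact-match only and can fail on
  repetitive loci; failures are explicit, never silent.
* The 2×2 flock contrast treats alleles as independent draws (2n alleles
  from n animals), the conventional approximation for genotype data.
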