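# ovmx — variant mining and population genetics for ovine Mx genes

Sheep carry two interferon-induced Mx genes, *MX1* and *MX2*, adjacent on
chromosome 1. Both encode dynamin-like GTPases of the innate antiviral
defence, and both segregate loss-of-function alleles in commercial and
research flocks — most notably a stop-gain in *MX2* (c.497G>A; p.W166\*)
and a single-base deletion that shifts the reading frame (c.985del;
p.Q329Sfs7\*). `ovmx` is an R package for the computational workflow behind
such findings. It is written for geneticists and bioinformaticians who
start from per-individual allele read counts (pileups) over a candidate
locus and want to

1. **mine variants** across a cohort with explicit, reproducible filter
   criteria,
2. **annotate** each variant's codon-level consequence, including
   frameshift translation to the next stop, and
3. **analyse the population genetics** of the resulting genotypes:
   allele/genotype frequencies, Hardy–Weinberg conformance, flock
   contrasts, sire genotype inference from progeny, haplotype phase
   enumeration and qPCR relative expression.

A seedable synthetic-cohort generator reproduces the statistical structure
of a diploid whole-genome cohort (Poisson read depth, per-base sequencing
error, Hardy–Weinberg genotypes at planted variant sites) so the entire
pipeline can be exercised and validated at desk scale.

## The core rules and statistics

**Genotype calling.** At each site a genotype is called from the two most
frequent alleles when depth ≥ 10; with minor-allele read fraction *m*, the
call is homozygous if *m* ≤ 0.10, heterozygous if *m* ≥ 0.25, and
ambiguous in between (a third allele above 10% of depth also marks the
call ambiguous). Sites below depth 10 are missing.

**Cohort acceptance criteria.** A candidate variant is accepted iff
(i) it is observed in at least one individual at ≥ 10-fold coverage;
(ii) some individual shows a minor-allele read fraction > 0.45;
(iii) every homozygote carries one of the two alleles seen in the
heterozygotes, or all homozygotes are homozygous non-reference; and
(iv) at least two heterozygotes exist and all heterozygotes show the same
change — and the site lies in a *suitable coverage region*, where the
summed depth over individuals with ≥ 10-fold coverage exceeds 99 reads.

**Consequences.** Substitutions are classed as transitions/transversions
and synonymous/missense/nonsense via the standard genetic code. A
single-base deletion is translated in the shifted frame from the first
affected codon to the next stop: for a deletion with novel peptide of
length *N*, the label is `p.<ref><codon><new>fsN*` (the stop is the
(*N*+1)-th altered codon; standard HGVS `fsTer` notation is available).

**Population genetics.** For genotype counts (n₀, n₁, n₂) at a biallelic
locus, f(alt) = (2n₂+n₁)/2n; Hardy–Weinberg conformance is a Pearson
chi-square against (p², 2pq, q²)·n with df = 1; flock contrasts are 2×2
chi-squares on allele counts (optional Yates correction); sire genotypes
are inferred by maximising the Mendelian transmission likelihood over
progeny (verdict "likely" at a ≥ 20:1 likelihood ratio); closed-flock
allele trajectories follow Wright–Fisher resampling with viability
selection (fitness 1, 1, 1−s), which for a recessive lethal reduces to
f′ = f/(1+f); relative expression uses the 2^−ΔΔCt method.

## Worked example

```r
library(ovmx)

# a 300-bp reference with a planted SNP (f = 0.35) and a planted
# single-base deletion (f = 0.25)
set.seed(1)
reference <- paste(sample(c("A","C","G","T"), 300, TRUE), collapse = "")
planted <- data.frame(position = c(90, 210),
                      ref = substring(reference, c(90, 210), c(90, 210)),
                      alt = c("C", "-"), freq = c(0.35, 0.25),
                      type = c("SNP", "deletion"))
cfg <- sim_config(n_individuals = 16, planted_variants = planted,
                  mean_depth = 25, error_rate = 0.005, seed = 42)
sim <- simulate_cohort(cfg, reference)
records <- mine_variants(sim$pileup)
records[, c("position","ref","alt","variant_class",
            "pooled_variant_reads","pooled_total_reads",
            "n_carriers","n_genotyped","accepted")]
#>   position ref alt variant_class pooled_variant_reads pooled_total_reads
#> 1        3   G   A        SNP_Ts                    2                461
#> 2       90   T   C        SNP_Ts                   97                403
#> 3      210   G   -         INDEL                   60                408
#>   n_carriers n_genotyped accepted
#> 1          0          15    FALSE
#> 2          7          16     TRUE
#> 3          4          16    FALSE
```

The planted SNP is accepted: 7 of 16 animals carry it and 97/403 pooled
reads support it. Position 3 is a sequencing-error artefact — it never
reaches a heterozygous minor fraction, so criteria (ii) and (iv) reject
it. The deletion is genuinely polymorphic (4 carriers) but in this draw no
single heterozygote reached a minor read fraction above 0.45, so criterion
(ii) leaves it unaccepted — the criteria demand strong within-individual
evidence, and rare variants at modest depth can miss the cut.

Consequence annotation of the two *MX2* null alleles:

```r
annotate_snp(w166_fixture_cds(), 497, "A")
#> c.497G>A p.W166* (nonsense)
annotate_deletion(q329_fixture_cds(), 985)
#> c.985del p.Q329Sfs7* (frameshift) novel peptide
#>   Ser.Arg.Ile.Ser.Pro.Thr.Ser, stop at altered codon 8
```

Genotype statistics for a 68-animal cohort with 13 alternative homozygotes
and 24 heterozygotes:

```r
g <- genotype_counts(31, 24, 13)
carriers(g)                        #> 37
round(allele_frequency(g)[["f_alt"]], 3)  #> 0.368
hwe_test(g)
#> Hardy-Weinberg chi-square: X-squared = 3.947, df = 1, p = 0.04695
```

A thin command-line wrapper over the same functions lives in
`inst/cli/ovmx.R` (`simulate`, `mine`, `annotate`,
`stats {hwe,compare,sire,haplotypes,ddct}`, `run`).

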