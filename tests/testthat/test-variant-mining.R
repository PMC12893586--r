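# Genotype calling, the cohort filter criteria and variant mining.

test_that("call_genotype applies depth and minor-fraction rules", {
  het <- call_genotype(c(A = 10, G = 10), ref = "A")
  expect_identical(het$state, "het")
  expect_setequal(het$alleles, c("A", "G"))
  expect_equal(het$minor_fraction, 0.5)

  hom <- call_genotype(c(A = 20), ref = "A")
  expect_identical(hom$state, "hom_ref")
  expect_identical(hom$alleles, "A")

  expect_identical(call_genotype(c(A = 5, G = 4), ref = "A")$state, "missing")

  # boundary: 6/24 = 0.25 is called het (threshold inclusive)
  b <- call_genotype(c(A = 18, G = 6), ref = "A")
  expect_identical(b$state, "het")
  expect_equal(b$minor_fraction, 0.25)

  # the ambiguous band between hom and het thresholds
  expect_identical(call_genotype(c(A = 17, G = 3), ref = "A")$state,
                   "ambiguous")
  # hom-alt and the gap allele
  expect_identical(call_genotype(c(G = 30), ref = "A")$state, "hom_alt")
  expect_identical(call_genotype(c(A = 12, `-` = 12), ref = "A")$state, "het")
  # a third allele above 10% of depth fails safe
  expect_identical(call_genotype(c(A = 12, G = 12, C = 4), ref = "A")$state,
                   "ambiguous")
  expect_error(call_genotype(c(A = -1), ref = "A"), "non-negative")
  expect_error(call_genotype(c(A = 10), ref = "A", hom_max_minor = 0.3,
                             het_min_minor = 0.25), "hom_max_minor")
})

test_that("suitable_coverage_regions applies the two-part pooled rule", {
  mk <- function(depths) {  # depths: individuals x positions (all ref A)
    ni <- nrow(depths); np <- ncol(depths)
    counts <- array(0L, dim = c(ni, np, 5L))
    counts[, , 1L] <- depths
    cohort_pileup(sprintf("i%d", 1:ni), 1:np, rep("A", np), counts)
  }
  # 5 x depth 20 = 100 > 99: in; 5 x depth 10 = 50: out
  r <- suitable_coverage_regions(mk(cbind(rep(20L, 5), rep(10L, 5))))
  expect_equal(r, data.frame(start = 1L, end = 1L))
  # 10 x depth 10 + 1 x depth 9: the 9 contributes nothing, sum 100: in
  r2 <- suitable_coverage_regions(mk(matrix(c(rep(10L, 10), 9L), ncol = 1)))
  expect_equal(nrow(r2), 1)
  # maximal intervals merge consecutive qualifying positions
  d <- cbind(rep(20L, 6), rep(20L, 6), rep(5L, 6), rep(20L, 6))
  r3 <- suitable_coverage_regions(mk(d))
  expect_equal(r3, data.frame(start = c(1L, 4L), end = c(2L, 4L)))
  # empty pileup
  empty <- mk(matrix(0L, 2, 3))
  expect_equal(nrow(suitable_coverage_regions(empty)), 0)
})

test_that("apply_cohort_criteria matches the worked examples", {
  het <- function(a, b, mf = 0.5)
    list(state = "het", alleles = c(a, b), minor_fraction = mf)
  hom <- function(a, ref = "A")
    list(state = if (a == ref) "hom_ref" else "hom_alt", alleles = a,
         minor_fraction = 0.02)
  # two hets at 0.5 plus a hom ref: all four criteria pass
  flags <- apply_cohort_criteria(list(het("A", "G"), het("A", "G"),
                                      hom("A")), ref = "A")
  expect_true(all(flags))
  # a single het fails (iv)
  flags1 <- apply_cohort_criteria(list(het("A", "G"), hom("A"), hom("A")),
                                  ref = "A")
  expect_false(flags1[["iv"]])
  expect_true(flags1[["i"]] && flags1[["ii"]] && flags1[["iii"]])
  # two hets with different alternative alleles fail (iv)
  flags2 <- apply_cohort_criteria(list(het("A", "G"), het("A", "C")),
                                  ref = "A")
  expect_false(flags2[["iv"]])
  # a homozygote outside the het pair fails (iii) unless all homs non-ref
  flags3 <- apply_cohort_criteria(list(het("A", "G"), het("A", "G"),
                                      hom("C")), ref = "A")
  expect_true(flags3[["iii"]])  # C is non-ref: second clause holds
  flags4 <- apply_cohort_criteria(list(het("C", "G"), het("C", "G"),
                                      hom("A")), ref = "A")
  expect_false(flags4[["iii"]])
})

test_that("criteria flags agree with the brute-force oracle on random cohorts", {
  set.seed(9157)
  n_checked <- 0L
  for (case in 1:500) {
    pu <- random_pileup(sample(2:5, 1), sample(3:20, 1))
    rec <- mine_variants(pu, region_sum_min = 0L)
    gts <- attr(rec, "genotypes")
    for (k in seq_len(nrow(rec))) {
      j <- match(rec$position[k], pu$positions)
      calls <- lapply(pu$individuals, function(id)
        call_genotype(site_counts_of(pu, id, j), ref = pu$ref[j]))
      expected <- oracle_criteria(calls, pu$ref[j])
      got <- c(i = rec$crit_i[k], ii = rec$crit_ii[k],
               iii = rec$crit_iii[k], iv = rec$crit_iv[k])
      expect_identical(got, expected)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 500)  # the random cohorts actually produced variants
})

test_that("mine_variants pools reads over qualified individuals and reports f_alt", {
  # pooled 254/551 built from hets and homozygotes
  counts <- array(0L, dim = c(5L, 1L, 5L))
  counts[1, 1, ] <- c(49L, 0L, 51L, 0L, 0L)   # het A/G
  counts[2, 1, ] <- c(50L, 0L, 50L, 0L, 0L)   # het A/G
  counts[3, 1, ] <- c(51L, 0L, 49L, 0L, 0L)   # het A/G
  counts[4, 1, ] <- c(0L, 0L, 104L, 0L, 0L)   # hom alt
  counts[5, 1, ] <- c(147L, 0L, 0L, 0L, 0L)   # hom ref
  pu <- cohort_pileup(sprintf("i%d", 1:5), 1L, "A", counts)
  rec <- mine_variants(pu, region_sum_min = 99L)
  expect_equal(rec$pooled_variant_reads, 254L)
  expect_equal(rec$pooled_total_reads, 551L)
  expect_identical(format_f_alt(rec$f_alt), "0.46")
  expect_true(rec$accepted)
  expect_equal(rec$n_carriers, 4L)
  expect_equal(rec$n_genotyped, 5L)

  # an individual below depth 10 is excluded from the pool
  counts[5, 1, ] <- c(9L, 0L, 0L, 0L, 0L)
  pu2 <- cohort_pileup(sprintf("i%d", 1:5), 1L, "A", counts)
  rec2 <- mine_variants(pu2)
  expect_equal(rec2$pooled_total_reads, 404L)
  expect_equal(rec2$n_genotyped, 4L)
})

test_that("an error-free homozygous-reference cohort yields no records", {
  counts <- array(0L, dim = c(4L, 20L, 5L))
  counts[, , 2L] <- 30L
  pu <- cohort_pileup(sprintf("i%d", 1:4), 1:20, rep("C", 20), counts)
  rec <- mine_variants(pu)
  expect_equal(nrow(rec), 0)
})

test_that("table and VCF writers handle cohorts with no accepted variants", {
  counts <- array(0L, dim = c(4L, 10L, 5L))
  counts[, , 2L] <- 30L
  counts[1, 3, 2L] <- 26L; counts[1, 3, 1L] <- 4L  # error-like minor allele
  pu <- cohort_pileup(sprintf("i%d", 1:4), 1:10, rep("C", 10), counts)
  rec <- mine_variants(pu)
  expect_equal(sum(rec$accepted), 0)
  f_tab <- tempfile(fileext = ".tsv")
  df <- write_variant_table(rec, f_tab)
  expect_equal(nrow(df), 0)
  expect_equal(length(readLines(f_tab)), 1)  # header only
  f_vcf <- tempfile(fileext = ".vcf")
  write_vcf(rec, paste(pu$ref, collapse = ""), f_vcf)
  expect_length(grep("^[^#]", readLines(f_vcf)), 0)
})

test_that("per-site genotype states conserve the cohort size", {
  set.seed(42)
  pu <- random_pileup(5, 15)
  rec <- mine_variants(pu, region_sum_min = 0L)
  gts <- attr(rec, "genotypes")
  for (k in seq_len(ncol(gts)))
    expect_equal(sum(table(factor(gts[, k],
      levels = c("hom_ref", "het", "hom_alt", "ambiguous", "missing")))), 5)
})

test_that("adding alt-supporting reads never decreases f_alt", {
  set.seed(5)
  counts <- array(0L, dim = c(3L, 1L, 5L))
  counts[1, 1, ] <- c(20L, 20L, 0L, 0L, 0L)
  counts[2, 1, ] <- c(30L, 0L, 0L, 0L, 0L)
  counts[3, 1, ] <- c(18L, 22L, 0L, 0L, 0L)
  prev <- -1
  for (extra in c(0L, 5L, 20L, 100L)) {
    c2 <- counts
    c2[2, 1, 2L] <- c2[2, 1, 2L] + extra
    pu <- cohort_pileup(c("a", "b", "c"), 1L, "A", c2)
    rec <- mine_variants(pu, region_sum_min = 0L)
    expect_gte(rec$f_alt, prev)
    prev <- rec$f_alt
  }
})

test_that("pileup TSV round-trips the cohort exactly", {
  set.seed(3)
  pu <- random_pileup(3, 8)
  f <- tempfile(fileext = ".tsv")
  write_pileup_tsv(pu, f)
  expect_identical(readLines(f, n = 1L), "#ovmx_pileup v1")
  pu2 <- read_pileup_tsv(f)
  expect_identical(pu2$counts, pu$counts)
  expect_identical(pu2$ref, pu$ref)
  expect_identical(pu2$individuals, pu$individuals)
  bad <- tempfile()
  writeLines("individual_id\tposition", bad)
  expect_error(read_pileup_tsv(bad), "header")
})
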