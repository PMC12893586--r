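# Allele frequencies, chi-square tests, sire inference, haplotypes, ddCt.

test_that("allele_frequency and carriers follow the genotype arithmetic", {
  expect_equal(allele_frequency(genotype_counts(0, 0, 10))[["f_alt"]], 1)
  expect_equal(allele_frequency(genotype_counts(5, 10, 5))[["f_alt"]], 0.5)
  g <- genotype_counts(31, 24, 13)  # 68-animal cohort at the M1V site
  f <- allele_frequency(g)
  expect_equal(f[["f_alt"]], 50 / 136)
  expect_equal(sum(f), 1)
  expect_equal(carriers(g), 37)
  expect_equal(carriers(genotype_counts(10, 0, 0)), 0)
  expect_equal(carriers(genotype_counts(7, 14, 10)), 24)  # lamb cohort
  expect_error(genotype_counts(-1, 0, 0), "non-negative")
})

test_that("genotype counts reconstruct from frequency and n with conservation check", {
  g <- genotype_counts_from_frequency(0.25, 20)
  expect_equal(g$n, 20)
  expect_equal(2 * g$n_alt_hom + g$n_het, round(2 * 20 * 0.25))
  expect_warning(genotype_counts_from_frequency(0.5, 33), "conserve")
})

test_that("hwe_test matches hand-computed Pearson statistics", {
  # exact HWE proportions: statistic 0, p = 1
  h0 <- hwe_test(genotype_counts(25, 50, 25))
  expect_equal(h0$statistic, 0)
  expect_equal(h0$p.value, 1)
  # (3, 10, 31): expected (1.4545, 13.0909, 29.4545), X2 ~ 2.453
  h1 <- hwe_test(genotype_counts(3, 10, 31))
  expect_equal(h1$statistic, 2.4531, tolerance = 1e-4)
  expect_equal(h1$p.value, 0.1173, tolerance = 1e-3)
  expect_equal(unname(h1$expected),
               c(1.4545, 13.0909, 29.4545), tolerance = 1e-4)
  # complete heterozygote deficit at p = q = 0.5, n = 20: X2 = n
  h2 <- hwe_test(genotype_counts(10, 0, 10))
  expect_equal(h2$statistic, 20)
  expect_lt(h2$p.value, 0.001)
  # monomorphic input is explicitly undefined
  hm <- hwe_test(genotype_counts(12, 0, 0))
  expect_true(hm$undefined)
  expect_true(is.na(hm$p.value))
})

test_that("hwe_test is invariant under swapping the allele labels", {
  set.seed(77)
  for (rep in 1:50) {
    x <- as.list(sample(0:30, 3, replace = TRUE))
    if (sum(unlist(x)) == 0) next
    a <- do.call(genotype_counts, x)
    b <- genotype_counts(x[[3]], x[[2]], x[[1]])
    ha <- hwe_test(a); hb <- hwe_test(b)
    expect_identical(ha$undefined, hb$undefined)
    if (!ha$undefined) expect_equal(ha$statistic, hb$statistic)
  }
})

test_that("hwe statistic vanishes for counts at exact HWE proportions", {
  for (p in c(0.1, 0.2, 0.5)) {
    n <- 1000
    g <- genotype_counts(round(p^2 * n), round(2 * p * (1 - p) * n),
                         round((1 - p)^2 * n))
    expect_lt(hwe_test(g)$statistic, 1e-2)
  }
})

test_that("flock_compare matches chisq.test and is symmetric", {
  # HSFR: f_alt 0.5 over 33 animals (33/33 alleles); TSFR: 40/0
  hsfr <- genotype_counts(8, 17, 8)
  tsfr <- genotype_counts(20, 0, 0)
  tab <- rbind(c(33, 40), c(33, 0))
  plain <- flock_compare(hsfr, tsfr)
  expect_equal(plain$statistic,
               unname(stats::chisq.test(tab, correct = FALSE)$statistic))
  yates <- flock_compare(hsfr, tsfr, yates = TRUE)
  expect_equal(yates$statistic,
               unname(stats::chisq.test(tab, correct = TRUE)$statistic))
  expect_equal(yates$statistic, 26.76, tolerance = 1e-2)
  expect_lt(plain$p.value, 1e-6)
  # symmetry
  expect_equal(flock_compare(tsfr, hsfr)$statistic, plain$statistic)
  # identical flocks: statistic 0, p = 1
  same <- flock_compare(hsfr, hsfr)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # one allele absent in one flock but present in the other: finite test
  a <- genotype_counts(3, 0, 0); b <- genotype_counts(1, 2, 1)
  r <- flock_compare(a, b)
  expect_false(r$undefined)
  expect_true(is.finite(r$statistic))
  expect_equal(r$statistic,
               unname(suppressWarnings(
                 stats::chisq.test(rbind(c(6, 4), c(0, 4)),
                                   correct = FALSE))$statistic))
  # an allele absent from both flocks is undefined
  expect_true(flock_compare(genotype_counts(5, 0, 0),
                            genotype_counts(9, 0, 0))$undefined)
})

test_that("sire genotype inference follows Mendelian likelihoods", {
  # all progeny hom_ref from hom_ref dams
  r <- infer_sire_genotype(rep("hom_ref", 8), rep("hom_ref", 8))
  expect_identical(r$ml_genotype, "hom_ref")
  expect_equal(r$likelihood[["hom_alt"]], 0)
  expect_gt(r$likelihood[["het"]], 0)
  expect_gt(r$likelihood[["hom_ref"]], r$likelihood[["het"]])
  # a het offspring of a hom_ref dam must have got alt from the sire
  r2 <- infer_sire_genotype(c("het", "het"), c("hom_ref", "hom_ref"))
  expect_equal(r2$likelihood[["hom_ref"]], 0)
  # a hom_alt offspring of a hom_ref dam is impossible for any sire
  expect_error(infer_sire_genotype("hom_alt", "hom_ref"),
               "pedigree inconsistency")
  # 17 progeny all carrying alt from the sire, dams at f_alt = 0.25
  r3 <- infer_sire_genotype(rep("hom_alt", 17), dam_freq = 0.25)
  expect_identical(r3$ml_genotype, "hom_alt")
  expect_identical(r3$verdict, "likely")
  expect_gt(r3$lr, 20)
  # impossible pedigree errors out naming a trio
  expect_error(infer_sire_genotype("hom_alt", "hom_ref"),
               "pedigree inconsistency")
  # few uninformative progeny give an ambiguous verdict
  r4 <- infer_sire_genotype(c("het", "het"), dam_freq = 0.5)
  expect_identical(r4$verdict, "ambiguous")
})

test_that("sire inference recovers the true genotype on simulated pedigrees", {
  cfg <- sim_config(1, seed = 4242,
                    pedigree = list(n_sires = 200, progeny_per_sire = 12,
                                    f_alt = 0.3))
  ped <- simulate_pedigree(cfg)
  hits <- 0L; total <- 0L
  for (sid in unique(ped$sire_id)) {
    sub <- ped[ped$sire_id == sid, ]
    est <- infer_sire_genotype(sub$offspring_gt, sub$dam_gt)
    total <- total + 1L
    if (est$ml_genotype == sub$sire_gt[1]) hits <- hits + 1L
  }
  expect_equal(total, 200L)
  expect_gt(hits / total, 0.95)
})

test_that("haplotype enumeration counts phase configurations", {
  # 1 het among 3 sites: single, unambiguous configuration
  r1 <- enumerate_haplotypes(list(c("A", "A"), c("A", "A"), c("G", "A")))
  expect_length(r1$pairs, 1)
  expect_true(r1$unambiguous)
  expect_setequal(r1$pairs[[1]], c("AAG", "AAA"))
  # 2 het sites: 2 configurations, ambiguous
  r2 <- enumerate_haplotypes(list(c("A", "G"), c("C", "T")))
  expect_length(r2$pairs, 2)
  expect_false(r2$unambiguous)
  expect_setequal(lapply(r2$pairs, sort),
                  list(c("AC", "GT"), c("AT", "GC")))
  # size is exactly max(1, 2^(h-1)) for h = 0..4
  set.seed(12)
  for (h in 0:4) {
    gts <- c(replicate(h, c("A", "G"), simplify = FALSE),
             replicate(5 - h, c("C", "C"), simplify = FALSE))
    gts <- sample(gts)
    expect_length(enumerate_haplotypes(gts)$pairs, max(1, 2^(h - 1)))
  }
})

test_that("ddct computes 2^-ddCt fold changes", {
  expect_equal(ddct(list(target_treated = 20, reference_treated = 20,
                         target_control = 20, reference_control = 20))$fold, 1)
  expect_equal(ddct(list(target_treated = 21, reference_treated = 20,
                         target_control = 20, reference_control = 20))$fold, 0.5)
  expect_equal(ddct(list(target_treated = 18, reference_treated = 21,
                         target_control = 20, reference_control = 20))$fold, 8)
  r <- ddct(list(target_treated = 22, reference_treated = 20,
                 target_control = 26, reference_control = 20))
  expect_equal(r$ddct, -4)
  expect_equal(r$fold, 16)
  # replicates averaged; data.frame interface
  df <- data.frame(gene = rep(c("target", "reference"), each = 4),
                   condition = rep(c("treated", "control"), 4),
                   ct = c(22, 26, 22, 26, 20, 20, 20, 20))
  expect_equal(ddct(df)$fold, 16)
  expect_error(ddct(list(target_treated = 22)), "missing")
  df_bad <- df; df_bad$ct[1] <- NA
  expect_error(ddct(df_bad), "non-positive|missing")
})
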