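# Allele/genotype frequencies, Hardy-Weinberg and between-flock chi-square
# tests, sire genotype inference from progeny under Mendelian transmission,
# haplotype enumeration over linked sites, and 2^-ddCt relative expression.
# Chi-square tests are Pearson tests with p-values from the chi-square
# distribution; no multiple-testing correction is applied (small datasets).

#' Genotype counts at a biallelic locus
#'
#' @param n_ref_hom,n_het,n_alt_hom Non-negative integer counts of
#'   reference homozygotes, heterozygotes and alternative homozygotes.
#' @return An object of class `genotype_counts` with the three counts and
#'   `n`, their sum.
#' @export
genotype_counts <- function(n_ref_hom, n_het, n_alt_hom) {
  x <- c(n_ref_hom = n_ref_hom, n_het = n_het, n_alt_hom = n_alt_hom)
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  structure(as.list(c(x, n = sum(x))), class = "genotype_counts")
}

#' Genotype counts from an allele frequency and sample size
#'
#' Reconstructs integer genotype counts from a reported alternative-allele
#' frequency and the number of animals genotyped, assuming Hardy-Weinberg
#' proportions, with rounding and an allele-conservation check (the
#' reconstructed allele count must equal `round(2 n f_alt)`).
#'
#' @param f_alt Alternative-allele frequency in `[0, 1]`.
#' @param n Number of animals.
#' @return A [genotype_counts()].
#' @export
genotype_counts_from_frequency <- function(f_alt, n) {
  stopifnot(f_alt >= 0, f_alt <= 1, n >= 1)
  n_alt_hom <- round(f_alt^2 * n)
  n_het <- round(2 * f_alt * (1 - f_alt) * n)
  n_ref_hom <- n - n_alt_hom - n_het
  g <- genotype_counts(n_ref_hom, n_het, n_alt_hom)
  if (2 * g$n_alt_hom + g$n_het != round(2 * n * f_alt))
    warning("rounded genotype counts do not conserve the allele count")
  g
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("genotype_counts: %d ref hom / %d het / %d alt hom (n = %d)\n",
              x$n_ref_hom, x$n_het, x$n_alt_hom, x$n))
  invisible(x)
}

#' Allele frequencies from genotype counts
#' @param counts A [genotype_counts()].
#' @return Named numeric vector `c(f_ref, f_alt)`.
#' @export
allele_frequency <- function(counts) {
  if (counts$n < 1) stop("empty counts")
  f_alt <- (2 * counts$n_alt_hom + counts$n_het) / (2 * counts$n)
  c(f_ref = 1 - f_alt, f_alt = f_alt)
}

#' Number of carriers of the alternative allele
#' @param counts A [genotype_counts()].
#' @return `n_het + n_alt_hom`.
#' @export
carriers <- function(counts) counts$n_het + counts$n_alt_hom

chisq_result <- function(statistic, df, expected, method, undefined = FALSE,
                         reason = NULL) {
  structure(list(statistic = statistic, df = df,
                 p.value = if (undefined) NA_real_
                           else stats::pchisq(statistic, df, lower.tail = FALSE),
                 expected = expected, method = method,
                 undefined = undefined, reason = reason),
            class = "ovmx_chisq")
}

#' @export
print.ovmx_chisq <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("%s: test undefined (%s)\n", x$method, x$reason))
  } else {
    cat(sprintf("%s: X-squared = %.4g, df = %d, p = %.4g\n",
                x$method, x$statistic, x$df, x$p.value))
  }
  invisible(x)
}

#' Hardy-Weinberg conformance test
#'
#' Pearson chi-square of observed genotype counts against the
#' Hardy-Weinberg proportions `p^2, 2pq, q^2` computed from the observed
#' allele frequencies; df = 1 (three genotype classes, one estimated
#' allele frequency). A monomorphic sample yields an explicit undefined
#' result rather than a silent p = 1.
#'
#' @param counts A [genotype_counts()].
#' @return An `ovmx_chisq` result with `statistic`, `df`, `p.value` and the
#'   expected counts.
#' @export
hwe_test <- function(counts) {
  if (counts$n < 1) stop("empty counts")
  f <- allele_frequency(counts)
  if (f[["f_alt"]] == 0 || f[["f_alt"]] == 1)
    return(chisq_result(NA_real_, 1L, NULL, "Hardy-Weinberg chi-square",
                        undefined = TRUE, reason = "monomorphic sample"))
  p <- f[["f_ref"]]; q <- f[["f_alt"]]
  expected <- c(n_ref_hom = p^2, n_het = 2 * p * q, n_alt_hom = q^2) * counts$n
  observed <- c(counts$n_ref_hom, counts$n_het, counts$n_alt_hom)
  stat <- sum((observed - expected)^2 / expected)
  chisq_result(stat, 1L, expected, "Hardy-Weinberg chi-square")
}

#' Compare allele frequencies between two flocks
#'
#' 2x2 Pearson chi-square on allele counts (reference/alternative x
#' flock), df = 1, with optional Yates continuity correction.
#'
#' @param a,b [genotype_counts()] for the two flocks.
#' @param yates Apply the continuity correction (default FALSE).
#' @return An `ovmx_chisq` result.
#' @export
flock_compare <- function(a, b, yates = FALSE) {
  if (a$n < 1 || b$n < 1) stop("both flocks must be non-empty")
  alt <- c(2 * a$n_alt_hom + a$n_het, 2 * b$n_alt_hom + b$n_het)
  ref <- c(2 * a$n, 2 * b$n) - alt
  tab <- rbind(ref = ref, alt = alt)
  if (any(rowSums(tab) == 0))
    return(chisq_result(NA_real_, 1L, NULL, "flock allele chi-square",
                        undefined = TRUE,
                        reason = "an allele is absent from both flocks"))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  dev <- abs(tab - expected)
  if (yates) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  chisq_result(stat, 1L, expected,
               paste0("flock allele chi-square",
                      if (yates) " (Yates-corrected)" else ""))
}

# Probability that a parent of given genotype transmits the alternative
# allele; "unknown" falls back to the population allele frequency f.
transmit_alt <- function(genotype, f = NA_real_) {
  switch(genotype,
         hom_ref = 0, het = 0.5, hom_alt = 1,
         unknown = {
           if (is.na(f)) stop("dam genotype unknown and no allele frequency given")
           f
         },
         stop("unknown genotype label: ", genotype))
}

#' Infer a sire's genotype from progeny genotypes
#'
#' For each candidate sire genotype the likelihood is the product over
#' progeny of the Mendelian transmission probability of the observed
#' offspring genotype, with the dam modelled either by her known genotype
#' or by the population allele frequency (a random allele with probability
#' `dam_freq` of being the alternative). The maximum-likelihood genotype is
#' labelled `likely` when it beats the runner-up by at least
#' `lr_threshold` (default 20:1), otherwise `ambiguous`.
#'
#' @param offspring Character vector of progeny genotypes (`hom_ref`,
#'   `het`, `hom_alt`).
#' @param dams Optional character vector of dam genotypes (same length;
#'   `unknown` entries use `dam_freq`).
#' @param dam_freq Population alternative-allele frequency used for
#'   unknown dams.
#' @param lr_threshold Likelihood ratio required for a `likely` verdict.
#' @return List with `likelihood` (named numeric over the three sire
#'   genotypes), `ml_genotype`, `verdict` (`"likely"` or `"ambiguous"`)
#'   and `lr` (ratio of best to runner-up likelihood).
#' @export
infer_sire_genotype <- function(offspring, dams = NULL, dam_freq = NA_real_,
                                lr_threshold = 20) {
  if (length(offspring) < 1L) stop("need at least one progeny genotype")
  if (is.null(dams)) dams <- rep("unknown", length(offspring))
  stopifnot(length(dams) == length(offspring))
  sire_gts <- c("hom_ref", "het", "hom_alt")
  lik <- stats::setNames(numeric(3), sire_gts)
  for (sg in sire_gts) {
    s <- transmit_alt(sg)
    lik[sg] <- prod(vapply(seq_along(offspring), function(k) {
      d <- transmit_alt(dams[k], dam_freq)
      switch(offspring[k],
             hom_alt = s * d,
             hom_ref = (1 - s) * (1 - d),
             het = s * (1 - d) + (1 - s) * d,
             stop("unknown offspring genotype: ", offspring[k]))
    }, numeric(1)))
  }
  if (all(lik == 0))
    stop("pedigree inconsistency: no sire genotype can produce trio ",
         which.min(vapply(seq_along(offspring), function(k) {
           d <- transmit_alt(dams[k], dam_freq)
           max(vapply(c(0, 0.5, 1), function(s) switch(offspring[k],
               hom_alt = s * d, hom_ref = (1 - s) * (1 - d),
               het = s * (1 - d) + (1 - s) * d), numeric(1)))
         }, numeric(1))))
  ord <- order(lik, decreasing = TRUE)
  lr <- if (lik[ord[2]] == 0) Inf else lik[ord[1]] / lik[ord[2]]
  list(likelihood = lik,
       ml_genotype = sire_gts[ord[1]],
       verdict = if (lr >= lr_threshold) "likely" else "ambiguous",
       lr = lr)
}

#' Enumerate haplotype pairs consistent with multi-site genotypes
#'
#' With `h` heterozygous sites there are `2^(h-1)` phase configurations
#' (one when `h <= 1`); the genotype is phase-unambiguous iff `h <= 1`.
#'
#' @param genotypes List of length-2 character vectors, the two alleles at
#'   each site, ordered by position.
#' @return List with `pairs` (list of 2-element character vectors, each a
#'   haplotype pair as allele strings), `n_het` and `unambiguous`.
#' @examples
#' # hom A / hom A / het G|A: single configuration {AAG, AAA}
#' enumerate_haplotypes(list(c("A", "A"), c("A", "A"), c("G", "A")))
#' @export
enumerate_haplotypes <- function(genotypes) {
  stopifnot(all(vapply(genotypes, length, integer(1)) == 2L))
  het <- vapply(genotypes, function(g) g[1] != g[2], logical(1))
  h <- sum(het)
  het_idx <- which(het)
  n_cfg <- max(1L, 2L^(h - 1L))
  # phase of the first het site is fixed; others take both orientations
  free <- if (h >= 2L) het_idx[-1L] else integer(0)
  pairs <- vector("list", n_cfg)
  for (cfg in seq_len(n_cfg) - 1L) {
    flip <- if (length(free)) as.logical(bitwAnd(cfg, 2L^(seq_along(free) - 1L)))
            else logical(0)
    h1 <- vapply(genotypes, `[`, character(1), 1L)
    h2 <- vapply(genotypes, `[`, character(1), 2L)
    for (m in seq_along(free)) if (flip[m]) {
      i <- free[m]
      tmp <- h1[i]; h1[i] <- h2[i]; h2[i] <- tmp
    }
    pairs[[cfg + 1L]] <- sort(c(paste(h1, collapse = ""),
                                paste(h2, collapse = "")))
  }
  list(pairs = pairs, n_het = h, unambiguous = h <= 1L)
}

#' Relative expression by the 2^-ddCt method
#'
#' Replicate Ct values are averaged per gene/condition; the fold change is
#' `2^-((Ct_target,treated - Ct_ref,treated) - (Ct_target,control -
#' Ct_ref,control))`.
#'
#' @param ct Data frame with columns `gene` (`"target"` or `"reference"`),
#'   `condition` (`"treated"` or `"control"`) and `ct` (positive, finite);
#'   or a named list/vector with elements `target_treated`,
#'   `reference_treated`, `target_control`, `reference_control` (each may
#'   hold replicate values).
#' @return List with `ddct` and `fold`.
#' @export
ddct <- function(ct) {
  if (is.data.frame(ct)) {
    need <- c("gene", "condition", "ct")
    if (!all(need %in% names(ct)))
      stop("Ct table needs columns: ", paste(need, collapse = ", "))
    get <- function(g, cond) ct$ct[ct$gene == g & ct$condition == cond]
    vals <- list(target_treated = get("target", "treated"),
                 reference_treated = get("reference", "treated"),
                 target_control = get("target", "control"),
                 reference_control = get("reference", "control"))
  } else {
    vals <- as.list(ct)
  }
  need <- c("target_treated", "reference_treated",
            "target_control", "reference_control")
  for (nm in need) {
    v <- vals[[nm]]
    if (is.null(v) || length(v) == 0L || any(!is.finite(v)) || any(v <= 0))
      stop("missing or non-positive Ct values for ", nm)
  }
  m <- vapply(vals[need], mean, numeric(1))
  dd <- (m[["target_treated"]] - m[["reference_treated"]]) -
    (m[["target_control"]] - m[["reference_control"]])
  list(ddct = unname(dd), fold = unname(2^(-dd)))
}

#' Read a Ct table from TSV
#' @param path TSV with columns `gene`, `condition`, `ct`.
#' @return Data frame suitable for [ddct()].
#' @export
read_ct_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read genotype tables and pedigree records from TSV
#'
#' Expected columns: `animal_id`, `sire_id`, `dam_id`, `genotype`
#' (`hom_ref`, `het`, `hom_alt`, `unknown`); additional columns pass
#' through.
#'
#' @param path TSV path.
#' @return Data frame of pedigree records.
#' @export
read_pedigree_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("animal_id", "sire_id", "dam_id", "genotype")
  if (!all(need %in% names(df)))
    stop("pedigree TSV must have columns: ", paste(need, collapse = ", "))
  df
}
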