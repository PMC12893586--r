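# Per-individual genotype calling from allele read counts and cohort-level
# variant acceptance: criteria (i)-(iv) plus the suitable-coverage-region
# rule. Genotypes are called from the two most frequent alleles at a site;
# the minor-allele read fraction separates homozygotes (sequencing error)
# from heterozygotes (~0.5), with an explicit ambiguous band in between.

#' Call a genotype from allele read counts at one site
#'
#' A site with depth below `min_depth` is `missing`. Otherwise, over the two
#' most frequent alleles with minor fraction `m`: homozygous if
#' `m <= hom_max_minor`, heterozygous if `m >= het_min_minor`, ambiguous in
#' between. A third allele exceeding 10% of depth also marks the call
#' ambiguous (multi-allelic sites fail safe).
#'
#' @param counts Named non-negative counts over alleles `A,C,G,T,-` (missing
#'   names count as zero).
#' @param ref Reference allele at the site.
#' @param hom_max_minor,het_min_minor Minor-fraction thresholds
#'   (`0 <= hom_max_minor < het_min_minor <= 0.5`); defaults 0.10 / 0.25.
#' @param min_depth Minimum read depth for a call (default 10).
#' @return A list with `state` (`hom_ref`, `het`, `hom_alt`, `ambiguous`,
#'   `missing`), `alleles` (major first), `minor_fraction` and `depth`.
#' @examples
#' call_genotype(c(A = 18, G = 6), ref = "A")  # het, minor fraction 0.25
#' @export
call_genotype <- function(counts, ref, hom_max_minor = 0.10,
                          het_min_minor = 0.25, min_depth = 10L) {
  if (!(hom_max_minor >= 0 && hom_max_minor < het_min_minor &&
        het_min_minor <= 0.5))
    stop("need 0 <= hom_max_minor < het_min_minor <= 0.5")
  if (any(counts < 0)) stop("read counts must be non-negative")
  if (!all(names(counts) %in% OVMX_ALLELES))
    stop("count names must be among ", paste(OVMX_ALLELES, collapse = ","))
  full <- stats::setNames(rep(0, 5L), OVMX_ALLELES)
  full[names(counts)] <- counts
  cnt <- array(as.integer(full), dim = c(1L, 1L, 5L))
  g <- call_genotypes_matrix(cnt, ref, hom_max_minor, het_min_minor, min_depth)
  list(state = g$state[1, 1],
       alleles = if (g$state[1, 1] == "missing") NULL
                 else if (g$state[1, 1] %in% c("het", "ambiguous"))
                   c(g$allele1[1, 1], g$allele2[1, 1])
                 else g$allele1[1, 1],
       minor_fraction = if (g$state[1, 1] == "missing") NA_real_
                        else g$minor[1, 1],
       depth = g$depth[1, 1])
}

# Vectorised genotype calling over an (individual x position x allele) count
# array. Returns matrices: state, allele1 (major), allele2 (second), minor
# (minor fraction over top two), depth. allele2 is NA for homozygous calls'
# reporting but retained internally for candidate detection of ambiguous
# calls; here we always keep the top-two alleles.
call_genotypes_matrix <- function(counts, ref, hom_max_minor = 0.10,
                                  het_min_minor = 0.25, min_depth = 10L) {
  ni <- dim(counts)[1]; np <- dim(counts)[2]
  m1 <- matrix(-1L, ni, np); m2 <- matrix(-1L, ni, np); m3 <- matrix(-1L, ni, np)
  i1 <- matrix(1L, ni, np); i2 <- matrix(1L, ni, np)
  depth <- matrix(0L, ni, np)
  for (k in 1:5) {
    ck <- matrix(counts[, , k], ni, np)
    depth <- depth + ck
    gt1 <- ck > m1
    gt2 <- !gt1 & ck > m2
    # shift down
    m3[gt2] <- m2[gt2]
    m3[gt1] <- m2[gt1]
    m2[gt1] <- m1[gt1]; i2[gt1] <- i1[gt1]
    m1[gt1] <- ck[gt1]; i1[gt1] <- k
    m2[gt2] <- ck[gt2]; i2[gt2] <- k
    gt3 <- !gt1 & !gt2 & ck > m3
    m3[gt3] <- ck[gt3]
  }
  minor <- ifelse(m1 + m2 > 0, m2 / (m1 + m2), 0)
  refidx <- match(ref, OVMX_ALLELES)
  refm <- matrix(rep(refidx, each = ni), ni, np)
  state <- matrix("ambiguous", ni, np)
  hom <- minor <= hom_max_minor
  het <- minor >= het_min_minor
  state[hom & i1 == refm] <- "hom_ref"
  state[hom & i1 != refm] <- "hom_alt"
  state[het] <- "het"
  # a third allele above 10% of depth -> ambiguous (fail safe)
  state[m3 > 0.10 * depth] <- "ambiguous"
  state[depth < min_depth] <- "missing"
  list(state = state,
       allele1 = matrix(OVMX_ALLELES[i1], ni, np),
       allele2 = matrix(ifelse(m2 > 0L, OVMX_ALLELES[i2], NA_character_), ni, np),
       minor = minor, depth = depth)
}

#' Suitable coverage regions of a cohort pileup
#'
#' Maximal intervals of consecutive positions where the summed depth over
#' individuals with depth >= `min_depth` exceeds `region_sum_min` reads
#' (individuals below `min_depth` contribute nothing).
#'
#' @param pileup A [cohort_pileup()].
#' @param min_depth Per-individual qualifying depth (default 10).
#' @param region_sum_min Pooled-depth threshold, strict `>` (default 99).
#' @return Data frame with columns `start`, `end` (genomic positions).
#' @export
suitable_coverage_regions <- function(pileup, min_depth = 10L,
                                      region_sum_min = 99L) {
  d <- pileup_depth(pileup)
  pooled <- colSums(d * (d >= min_depth))
  ok <- pooled > region_sum_min
  if (!any(ok)) return(data.frame(start = integer(0), end = integer(0)))
  pos <- pileup$positions
  # break runs on either condition change or non-consecutive positions
  grp <- cumsum(c(TRUE, diff(pos) != 1L | diff(ok) != 0L))
  keep <- tapply(ok, grp, `[`, 1L)
  starts <- tapply(pos, grp, min)[keep]
  ends <- tapply(pos, grp, max)[keep]
  data.frame(start = as.integer(starts), end = as.integer(ends),
             row.names = NULL)
}

#' Cohort acceptance criteria for a candidate variant site
#'
#' Evaluates the four filter criteria on a set of per-individual genotype
#' calls: (i) the variant is seen in at least one non-missing individual
#' (calls are only made at depth >= 10); (ii) some individual's minor-allele
#' read fraction exceeds 0.45; (iii) every homozygote carries one of the two
#' alleles seen in the heterozygotes, or all homozygotes are homozygous
#' non-reference; (iv) at least two heterozygotes exist and all
#' heterozygotes show the same allele pair. Ambiguous calls are excluded
#' from (iii) and (iv).
#'
#' @param calls List of genotype calls as returned by [call_genotype()].
#' @param ref Reference allele at the site.
#' @param minor_fraction_crit Threshold for criterion (ii), strict `>`
#'   (default 0.45).
#' @return Named logical vector with elements `i`, `ii`, `iii`, `iv`.
#' @export
apply_cohort_criteria <- function(calls, ref, minor_fraction_crit = 0.45) {
  states <- vapply(calls, function(x) x$state, character(1))
  nonmiss <- states != "missing"
  shows_variant <- vapply(calls, function(x)
    x$state != "missing" && any(x$alleles != ref), logical(1))
  crit_i <- any(shows_variant)
  mf <- vapply(calls, function(x)
    if (x$state == "missing") NA_real_ else x$minor_fraction, numeric(1))
  crit_ii <- any(mf > minor_fraction_crit, na.rm = TRUE)
  hets <- calls[states == "het"]
  homs <- calls[states %in% c("hom_ref", "hom_alt")]
  het_pairs <- lapply(hets, function(x) sort(x$alleles))
  if (length(hets) > 0L) {
    het_alleles <- unique(unlist(het_pairs))
    crit_iii <- all(vapply(homs, function(x) x$alleles %in% het_alleles,
                           logical(1))) ||
      all(vapply(homs, function(x) x$alleles != ref, logical(1)))
  } else {
    # no heterozygotes: only the all-hom-non-reference clause can hold
    crit_iii <- length(homs) == 0L ||
      all(vapply(homs, function(x) x$alleles != ref, logical(1)))
  }
  crit_iv <- length(hets) >= 2L &&
    all(vapply(het_pairs, identical, logical(1), y = het_pairs[[1]]))
  c(i = crit_i, ii = crit_ii, iii = crit_iii, iv = crit_iv)
}

#' Mine variants from a cohort pileup
#'
#' Calls genotypes for every individual at every position, then emits one
#' record per position where any qualified call contains a non-reference
#' allele. Pooled read counts use only individuals with depth >=
#' `min_depth`. A record is accepted when criteria (i)-(iv) all pass and
#' the position lies in a suitable coverage region.
#'
#' @param pileup A [cohort_pileup()].
#' @param hom_max_minor,het_min_minor,min_depth See [call_genotype()].
#' @param region_sum_min,minor_fraction_crit See
#'   [suitable_coverage_regions()] and [apply_cohort_criteria()].
#' @return Data frame of variant records (position, ref, alt,
#'   variant_class, pooled counts, `f_alt`, carrier/genotyped counts,
#'   criteria flags, `in_region`, `accepted`), sorted by position, with a
#'   `genotypes` attribute: a character matrix (individual x record) of
#'   per-animal genotype states.
#' @export
mine_variants <- function(pileup, hom_max_minor = 0.10, het_min_minor = 0.25,
                          min_depth = 10L, region_sum_min = 99L,
                          minor_fraction_crit = 0.45) {
  g <- call_genotypes_matrix(pileup$counts, pileup$ref,
                             hom_max_minor, het_min_minor, min_depth)
  ni <- length(pileup$individuals); np <- length(pileup$positions)
  refm <- matrix(rep(pileup$ref, each = ni), ni, np)
  nonmiss <- g$state != "missing"
  shows <- nonmiss & (g$allele1 != refm |
                        (!is.na(g$allele2) & g$allele2 != refm &
                           g$state %in% c("het", "ambiguous")))
  cand <- which(colSums(shows) > 0L)
  regions <- suitable_coverage_regions(pileup, min_depth, region_sum_min)
  in_region_vec <- rep(FALSE, np)
  for (r in seq_len(nrow(regions)))
    in_region_vec[pileup$positions >= regions$start[r] &
                    pileup$positions <= regions$end[r]] <- TRUE
  rows <- vector("list", length(cand))
  gts <- matrix(character(0), nrow = ni, ncol = 0)
  if (length(cand))
    gts <- matrix(NA_character_, ni, length(cand),
                  dimnames = list(pileup$individuals, NULL))
  for (k in seq_along(cand)) {
    j <- cand[k]
    ref <- pileup$ref[j]
    calls <- lapply(seq_len(ni), function(i) list(
      state = g$state[i, j],
      alleles = if (g$state[i, j] == "missing") NULL
                else if (g$state[i, j] %in% c("het", "ambiguous") &&
                         !is.na(g$allele2[i, j]))
                  c(g$allele1[i, j], g$allele2[i, j])
                else g$allele1[i, j],
      minor_fraction = if (g$state[i, j] == "missing") NA_real_
                       else g$minor[i, j]))
    qual <- g$depth[, j] >= min_depth
    pooled_counts <- colSums(matrix(pileup$counts[qual, j, ],
                                    ncol = 5L,
                                    dimnames = list(NULL, OVMX_ALLELES)))
    nonref <- pooled_counts[setdiff(OVMX_ALLELES, ref)]
    alt <- names(nonref)[which.max(nonref)]
    pooled_total <- sum(pooled_counts)
    pooled_variant <- pooled_counts[[alt]]
    states <- vapply(calls, function(x) x$state, character(1))
    carrier <- vapply(calls, function(x)
      x$state %in% c("het", "hom_alt") && alt %in% x$alleles, logical(1))
    flags <- apply_cohort_criteria(calls, ref, minor_fraction_crit)
    vclass <- if (alt == "-" || ref == "-") "INDEL"
              else paste0("SNP_", classify_substitution(ref, alt))
    rows[[k]] <- data.frame(
      position = pileup$positions[j], ref = ref, alt = alt,
      variant_class = vclass,
      pooled_variant_reads = pooled_variant,
      pooled_total_reads = pooled_total,
      f_alt = if (pooled_total > 0) pooled_variant / pooled_total else NA_real_,
      n_carriers = sum(carrier),
      n_genotyped = sum(states %in% c("hom_ref", "het", "hom_alt")),
      crit_i = flags[["i"]], crit_ii = flags[["ii"]],
      crit_iii = flags[["iii"]], crit_iv = flags[["iv"]],
      in_region = in_region_vec[j])
    gts[, k] <- states
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(position = integer(0), ref = character(0),
                         alt = character(0), variant_class = character(0),
                         pooled_variant_reads = integer(0),
                         pooled_total_reads = integer(0), f_alt = numeric(0),
                         n_carriers = integer(0), n_genotyped = integer(0),
                         crit_i = logical(0), crit_ii = logical(0),
                         crit_iii = logical(0), crit_iv = logical(0),
                         in_region = logical(0))
  out$accepted <- out$crit_i & out$crit_ii & out$crit_iii & out$crit_iv &
    out$in_region
  ord <- order(out$position)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "genotypes") <- gts[, ord, drop = FALSE]
  out
}

#' Format a pooled alternative-allele read frequency for reporting
#'
#' Reporting rounds to two decimals; computation elsewhere keeps full
#' precision.
#'
#' @param f_alt Numeric vector of pooled alt-read fractions.
#' @return Character vector, two decimal places.
#' @export
format_f_alt <- function(f_alt) sprintf("%.2f", round(f_alt, 2))

#' Write accepted variants as a summary table
#'
#' One row per variant with position, change, type, pooled read counts,
#' f(alt) rounded to two decimals, and carrier/genotyped animal counts.
#'
#' @param records Data frame from [mine_variants()].
#' @param path Output TSV path.
#' @param accepted_only Write only accepted records (default TRUE).
#' @export
write_variant_table <- function(records, path, accepted_only = TRUE) {
  r <- if (accepted_only) records[records$accepted, , drop = FALSE] else records
  df <- data.frame(
    position = r$position,
    change = if (nrow(r)) paste0(r$ref, ">", r$alt) else character(0),
    type = unname(c(SNP_Ts = "SNP (Ts)", SNP_Tv = "SNP (Tv)",
                    INDEL = "INDEL")[r$variant_class]),
    reads = if (nrow(r)) paste0(r$pooled_variant_reads, "/",
                                r$pooled_total_reads) else character(0),
    f_alt = format_f_alt(r$f_alt),
    animals = if (nrow(r)) paste0(r$n_carriers, "/", r$n_genotyped)
              else character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
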