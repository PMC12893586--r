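# Load the sequence machinery up front so per-test timings reflect the
# computation, not namespace loading.
invisible(Biostrings::GENETIC_CODE)

# Independent brute-force oracles used by the property tests. These follow
# the filtering rules and coordinate definitions naively (loops and direct
# enumeration) and share no code with the package implementation.

# Criteria (i)-(iv) written directly from the rule text, one clause at a
# time, over a list of genotype calls.
oracle_criteria <- function(calls, ref, crit = 0.45) {
  f_i <- FALSE
  for (cl in calls) {
    if (cl$state == "missing") next
    for (a in cl$alleles) if (a != ref) f_i <- TRUE
  }
  f_ii <- FALSE
  for (cl in calls) {
    if (cl$state == "missing") next
    if (!is.na(cl$minor_fraction) && cl$minor_fraction > crit) f_ii <- TRUE
  }
  het_pairs <- list()
  hom_alleles <- character(0)
  for (cl in calls) {
    if (cl$state == "het") het_pairs[[length(het_pairs) + 1L]] <- sort(cl$alleles)
    if (cl$state %in% c("hom_ref", "hom_alt"))
      hom_alleles <- c(hom_alleles, cl$alleles)
  }
  if (length(het_pairs) > 0L) {
    seen <- unique(unlist(het_pairs))
    all_in_pair <- TRUE
    for (a in hom_alleles) if (!(a %in% seen)) all_in_pair <- FALSE
    all_nonref <- TRUE
    for (a in hom_alleles) if (a == ref) all_nonref <- FALSE
    f_iii <- all_in_pair || all_nonref
  } else {
    f_iii <- TRUE
    for (a in hom_alleles) if (a == ref) f_iii <- FALSE
    if (length(hom_alleles) == 0L) f_iii <- TRUE
  }
  f_iv <- FALSE
  if (length(het_pairs) >= 2L) {
    f_iv <- TRUE
    for (p in het_pairs) if (!identical(p, het_pairs[[1]])) f_iv <- FALSE
  }
  c(i = f_i, ii = f_ii, iii = f_iii, iv = f_iv)
}

# Random small cohort pileup: counts concentrated on one or two alleles so
# that all genotype states (and ambiguous/missing) actually occur.
random_pileup <- function(n_ind, n_pos) {
  counts <- array(0L, dim = c(n_ind, n_pos, 5L))
  ref <- sample(c("A", "C", "G", "T"), n_pos, replace = TRUE)
  for (i in seq_len(n_ind)) for (j in seq_len(n_pos)) {
    depth <- sample(0:40, 1L)
    k1 <- sample.int(5L, 1L)
    k2 <- sample.int(5L, 1L)
    split <- stats::runif(1)
    a <- round(depth * split)
    counts[i, j, k1] <- counts[i, j, k1] + a
    counts[i, j, k2] <- counts[i, j, k2] + depth - a
    if (stats::runif(1) < 0.1) {  # occasional third allele
      k3 <- sample.int(5L, 1L)
      counts[i, j, k3] <- counts[i, j, k3] + sample(0:5, 1L)
    }
  }
  cohort_pileup(sprintf("i%02d", seq_len(n_ind)), seq_len(n_pos), ref, counts)
}

# Enumerate the CDS by walking exon positions one base at a time in
# transcript orientation; returns the genomic positions of c.1..c.L in
# order.
oracle_cds_positions <- function(exons, strand, cds_start, cds_end) {
  tx_positions <- integer(0)
  for (r in seq_len(nrow(exons))) {
    pos <- if (strand == "+") exons[r, 1]:exons[r, 2] else exons[r, 2]:exons[r, 1]
    tx_positions <- c(tx_positions, pos)
  }
  i1 <- which(tx_positions == cds_start)
  i2 <- which(tx_positions == cds_end)
  tx_positions[i1:i2]
}

# Frameshift oracle: delete the base, re-translate the whole edited
# sequence with Biostrings, and diff from the first altered codon.
oracle_frameshift <- function(cds, cds_pos) {
  edited <- paste0(substr(cds, 1, cds_pos - 1), substr(cds, cds_pos + 1, nchar(cds)))
  usable <- nchar(edited) - nchar(edited) %% 3
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(substr(edited, 1, usable)))))
  first_codon <- ceiling(cds_pos / 3)
  tail_aa <- substr(aa, first_codon, nchar(aa))
  stop_at <- regexpr("*", tail_aa, fixed = TRUE)
  if (stop_at < 0) return(list(found_stop = FALSE, peptide = tail_aa))
  list(found_stop = TRUE,
       peptide = substr(tail_aa, 1, stop_at - 1),
       stop_offset = as.integer(stop_at))
}

# Random stop-free coding sequence of n codons (for annotation properties).
random_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(n_codons)
  for (k in seq_len(n_codons)) {
    repeat {
      cd <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                  collapse = "")
      if (!(cd %in% stops)) break
    }
    codons[k] <- cd
  }
  paste(codons, collapse = "")
}

# Raw counts for one (individual, position-index) pair of a pileup.
site_counts_of <- function(pu, id, j) {
  stats::setNames(pu$counts[match(id, pu$individuals), j, ],
                  c("A", "C", "G", "T", "-"))
}

# Tiny deterministic toy cohort: 3 individuals, two sites that pass all
# criteria (two hets at ~0.5 plus a hom), padded so the region rule holds.
toy_passing_pileup <- function(n_pad = 30L) {
  ref <- rep("A", n_pad)
  ref[10L] <- "G"
  counts <- array(0L, dim = c(3L, n_pad, 5L))
  counts[, , 1L] <- 40L  # deep hom-ref A everywhere
  # site 5: A>T, two hets + one hom ref
  counts[1, 5, 1L] <- 20L; counts[1, 5, 4L] <- 20L
  counts[2, 5, 1L] <- 19L; counts[2, 5, 4L] <- 21L
  # site 10 (ref G): G>C, two hets + one hom alt
  counts[, 10, 1L] <- 0L
  counts[1, 10, 3L] <- 20L; counts[1, 10, 2L] <- 20L
  counts[2, 10, 3L] <- 18L; counts[2, 10, 2L] <- 22L
  counts[3, 10, 2L] <- 40L
  cohort_pileup(c("s1", "s2", "s3"), seq_len(n_pad), ref, counts)
}
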