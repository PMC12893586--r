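# Seedable generator of synthetic diploid cohorts: read pileups with
# Poisson depth and per-base sequencing error, pedigrees under Mendelian
# transmission, and closed-flock allele trajectories under Wright-Fisher
# drift with viability selection. One explicit seed drives everything; each
# individual draws from its own substream so that enlarging the cohort does
# not perturb previously generated individuals.

#' Configuration of a synthetic cohort
#'
#' @param n_individuals Number of diploid individuals.
#' @param planted_variants Data frame with columns `position`, `ref`, `alt`
#'   (`"-"` for a single-base deletion), `freq` (population alternative
#'   allele frequency) and `type` (`"SNP"` or `"deletion"`); may be NULL.
#' @param mean_depth Mean of the per-(individual, site) Poisson read depth.
#' @param error_rate Per-base sequencing error probability (<= 0.1); an
#'   erroneous base is replaced uniformly by one of the other three
#'   nucleotides. Gap reads (deletion allele) are not subject to
#'   substitution error.
#' @param seed Integer seed (mandatory).
#' @param pedigree Optional list `list(n_sires, progeny_per_sire, f_alt)`
#'   for [simulate_pedigree()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals, planted_variants = NULL,
                       mean_depth = 20, error_rate = 0.005, seed,
                       pedigree = NULL) {
  if (missing(seed) || is.null(seed) || is.na(seed)) stop("seed is mandatory")
  stopifnot(n_individuals >= 1, mean_depth > 0,
            error_rate >= 0, error_rate <= 0.1)
  if (!is.null(planted_variants)) {
    need <- c("position", "ref", "alt", "freq", "type")
    if (!all(need %in% names(planted_variants)))
      stop("planted_variants needs columns: ", paste(need, collapse = ", "))
    stopifnot(all(planted_variants$freq >= 0), all(planted_variants$freq <= 1),
              all(planted_variants$type %in% c("SNP", "deletion")))
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 planted_variants = planted_variants,
                 mean_depth = mean_depth, error_rate = error_rate,
                 seed = as.integer(seed), pedigree = pedigree),
            class = "sim_config")
}

# Run fn() under a given RNG seed without disturbing the caller's stream.
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# Independent substream seeds keyed by the master seed: the first
# n_individuals draws are per-individual seeds, so extending the cohort
# leaves earlier individuals' streams unchanged.
substream_seeds <- function(seed, n) {
  with_seed(seed, function() sample.int(.Machine$integer.max - 1L, n))
}

#' Simulate a diploid cohort read pileup
#'
#' Genotypes at each planted variant are two independent Bernoulli(`freq`)
#' allele draws per individual; depth at every (individual, site) is
#' Poisson(`mean_depth`); reads are drawn from the genotype's allele mix
#' (alt fraction 0, 0.5 or 1) and nucleotide reads are corrupted at
#' `error_rate`, substituting uniformly among the other three nucleotides.
#' Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param reference Reference sequence (character string, A/C/G/T).
#' @return List with `pileup` (a [cohort_pileup()]) and `truth`: the matrix
#'   of true alternative-allele copy numbers (individual x planted variant)
#'   and the planted variant table.
#' @export
simulate_cohort <- function(cfg, reference) {
  reference <- toupper(as.character(reference))
  refv <- strsplit(reference, "")[[1]]
  np <- length(refv)
  pv <- cfg$planted_variants
  if (!is.null(pv)) {
    if (any(pv$position < 1L | pv$position > np))
      stop("planted variant position outside the reference")
    bad <- refv[pv$position] != toupper(pv$ref)
    if (any(bad))
      stop("planted variant ref mismatch at position ",
           pv$position[which(bad)[1]])
  }
  ni <- cfg$n_individuals
  nv <- if (is.null(pv)) 0L else nrow(pv)
  ids <- sprintf("ind%03d", seq_len(ni))
  seeds <- substream_seeds(cfg$seed, ni)
  counts <- array(0L, dim = c(ni, np, 5L))
  geno <- matrix(0L, ni, nv, dimnames = list(ids, NULL))
  ref_idx <- match(refv, OVMX_ALLELES)
  e <- cfg$error_rate
  for (i in seq_len(ni)) {
    with_seed(seeds[i], function() {
      # true alternative-allele fraction per site for this individual
      alt_frac <- rep(0, np)
      alt_idx <- ref_idx
      if (nv > 0L) {
        g <- stats::rbinom(nv, 2L, pv$freq)
        geno[i, ] <<- g
        alt_frac[pv$position] <- g / 2
        alt_idx[pv$position] <- match(toupper(pv$alt), OVMX_ALLELES)
      }
      depth <- stats::rpois(np, cfg$mean_depth)
      alt_reads <- stats::rbinom(np, depth, alt_frac)
      ref_reads <- depth - alt_reads
      # substitution errors on nucleotide reads only
      err_ref <- if (e > 0) stats::rbinom(np, ref_reads, e) else rep(0L, np)
      is_gap_alt <- OVMX_ALLELES[alt_idx] == "-"
      err_alt <- if (e > 0)
        stats::rbinom(np, ifelse(is_gap_alt, 0L, alt_reads), e)
      else rep(0L, np)
      counts[cbind(i, seq_len(np), ref_idx)] <<-
        counts[cbind(i, seq_len(np), ref_idx)] + ref_reads - err_ref
      counts[cbind(i, seq_len(np), alt_idx)] <<-
        counts[cbind(i, seq_len(np), alt_idx)] + alt_reads - err_alt
      for (j in which(err_ref + err_alt > 0L)) {
        spread_err <- function(n_err, true_idx) {
          if (n_err == 0L) return()
          others <- setdiff(1:4, true_idx)  # errors land on nucleotides
          add <- stats::rmultinom(1L, n_err, rep(1 / length(others),
                                                 length(others)))[, 1]
          counts[i, j, others] <<- counts[i, j, others] + add
        }
        spread_err(err_ref[j], ref_idx[j])
        spread_err(err_alt[j], alt_idx[j])
      }
    })
  }
  pileup <- cohort_pileup(ids, seq_len(np), refv, counts)
  list(pileup = pileup,
       truth = list(genotypes = geno, planted_variants = pv))
}

#' Simulate a pedigree with true genotypes
#'
#' Sires and dams draw two alleles each from the population frequency;
#' offspring receive one allele from each parent under Mendelian
#' transmission. Reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()] with a `pedigree` spec
#'   (`n_sires`, `progeny_per_sire`, `f_alt`).
#' @return Data frame of trios: `offspring_id`, `sire_id`, `dam_id`,
#'   `sire_gt`, `dam_gt`, `offspring_gt` (genotype labels).
#' @export
simulate_pedigree <- function(cfg) {
  ped <- cfg$pedigree
  if (is.null(ped) || is.null(ped$n_sires) || is.null(ped$progeny_per_sire) ||
      is.null(ped$f_alt))
    stop("cfg$pedigree must provide n_sires, progeny_per_sire and f_alt")
  gt_label <- function(k) c("hom_ref", "het", "hom_alt")[k + 1L]
  with_seed(cfg$seed, function() {
    rows <- list()
    for (s in seq_len(ped$n_sires)) {
      sire_g <- sum(stats::rbinom(2L, 1L, ped$f_alt))
      for (o in seq_len(ped$progeny_per_sire)) {
        dam_g <- sum(stats::rbinom(2L, 1L, ped$f_alt))
        from_sire <- stats::rbinom(1L, 1L, sire_g / 2)
        from_dam <- stats::rbinom(1L, 1L, dam_g / 2)
        rows[[length(rows) + 1L]] <- data.frame(
          offspring_id = sprintf("s%02d_o%03d", s, o),
          sire_id = sprintf("sire%02d", s),
          dam_id = sprintf("s%02d_dam%03d", s, o),
          sire_gt = gt_label(sire_g), dam_gt = gt_label(dam_g),
          offspring_gt = gt_label(from_sire + from_dam))
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate a closed flock under drift and viability selection
#'
#' Wright-Fisher binomial resampling of `2 * n_breeding` alleles each
#' generation with viability selection against alternative homozygotes
#' (fitness 1, 1, `1 - s`). With `deterministic = TRUE` the
#' infinite-population recurrence is followed instead (no seed needed);
#' for a recessive lethal (`s = 1`) this reduces to
#' `f' = f / (1 + f)`.
#'
#' @param n_breeding Breeding population size (>= 2).
#' @param generations Number of generations to simulate.
#' @param f0 Initial alternative-allele frequency.
#' @param s Selection coefficient against alternative homozygotes, in
#'   `[0, 1]`.
#' @param seed Integer seed (required unless `deterministic`).
#' @param deterministic Follow the infinite-population recurrence.
#' @return Numeric vector of allele frequencies, length `generations + 1`
#'   (starting at `f0`).
#' @export
simulate_closed_flock <- function(n_breeding, generations, f0, s = 0,
                                  seed = NULL, deterministic = FALSE) {
  stopifnot(n_breeding >= 2, generations >= 0, f0 >= 0, f0 <= 1,
            s >= 0, s <= 1)
  step <- function(f) {
    # random mating then viability selection on genotypes
    w_mean <- 1 - s * f^2
    if (w_mean == 0) return(0)  # only lethal homozygotes remain
    (f * (1 - f) + (1 - s) * f^2) / w_mean
  }
  traj <- numeric(generations + 1L)
  traj[1L] <- f0
  if (deterministic) {
    for (t in seq_len(generations)) traj[t + 1L] <- step(traj[t])
    return(traj)
  }
  if (is.null(seed)) stop("seed is required for the stochastic simulation")
  with_seed(seed, function() {
    for (t in seq_len(generations)) {
      fs <- step(traj[t])
      traj[t + 1L] <<- stats::rbinom(1L, 2L * n_breeding, fs) / (2 * n_breeding)
    }
  })
  traj
}

#' Write a truth-genotype table as TSV
#' @param truth The `truth` element returned by [simulate_cohort()].
#' @param path Output path.
#' @export
write_truth_tsv <- function(truth, path) {
  g <- truth$genotypes
  if (is.null(truth$planted_variants) || ncol(g) == 0L) {
    utils::write.table(data.frame(individual_id = rownames(g)), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  df <- data.frame(individual_id = rep(rownames(g), times = ncol(g)),
                   position = rep(truth$planted_variants$position,
                                  each = nrow(g)),
                   alt_copies = as.vector(g))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
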