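# Cohort pileup container: per-individual, per-position allele read counts.
# Internally a 3-d integer array (individual x position x allele) for speed;
# the on-disk format is a long TSV dialect (one row per individual-position).

# Allele alphabet; "-" is a single-base deletion (gap) call at that position.
OVMX_ALLELES <- c("A", "C", "G", "T", "-")
PILEUP_HEADER <- "#ovmx_pileup v1"

#' Construct a cohort pileup
#'
#' @param individuals Character vector of individual identifiers.
#' @param positions Integer vector of genomic positions (sorted, 1-based).
#' @param ref Character vector of reference bases, one per position.
#' @param counts Integer array of dim `(n_individuals, n_positions, 5)` with
#'   allele slices ordered A, C, G, T, `-`. Missing data are zero-depth.
#' @return An object of class `cohort_pileup`.
#' @export
cohort_pileup <- function(individuals, positions, ref, counts) {
  individuals <- as.character(individuals)
  positions <- as.integer(positions)
  ref <- toupper(as.character(ref))
  stopifnot(length(ref) == length(positions),
            all(ref %in% OVMX_ALLELES),
            !is.unsorted(positions, strictly = TRUE))
  counts <- array(as.integer(counts),
                  dim = c(length(individuals), length(positions), 5L),
                  dimnames = list(individuals, NULL, OVMX_ALLELES))
  if (any(counts < 0L, na.rm = TRUE)) stop("read counts must be non-negative")
  counts[is.na(counts)] <- 0L
  structure(list(individuals = individuals, positions = positions,
                 ref = ref, counts = counts),
            class = "cohort_pileup")
}

#' @export
print.cohort_pileup <- function(x, ...) {
  cat(sprintf("cohort_pileup: %d individuals x %d positions (mean depth %.1f)\n",
              length(x$individuals), length(x$positions),
              mean(pileup_depth(x))))
  invisible(x)
}

#' Per-individual, per-position read depth
#' @param pileup A [cohort_pileup()].
#' @return Integer matrix (individual x position).
#' @export
pileup_depth <- function(pileup) {
  d <- pileup$counts[, , 1L, drop = FALSE]
  for (k in 2:5) d <- d + pileup$counts[, , k, drop = FALSE]
  array(d, dim = dim(pileup$counts)[1:2],
        dimnames = list(pileup$individuals, NULL))
}

# Counts for one (individual, position): named integer vector over alleles.
site_counts <- function(pileup, individual, position) {
  j <- match(position, pileup$positions)
  i <- match(individual, pileup$individuals)
  if (is.na(i) || is.na(j)) stop("unknown individual or position")
  stats::setNames(pileup$counts[i, j, ], OVMX_ALLELES)
}

#' Build a cohort pileup from a long data.frame
#'
#' @param df Data frame with columns `individual_id`, `position`, `ref`,
#'   `countA`, `countC`, `countG`, `countT`, `countGap`. Pairs not listed
#'   get zero depth.
#' @return A [cohort_pileup()].
#' @export
as_cohort_pileup <- function(df) {
  need <- c("individual_id", "position", "ref",
            "countA", "countC", "countG", "countT", "countGap")
  if (!all(need %in% names(df)))
    stop("pileup table must have columns: ", paste(need, collapse = ", "))
  inds <- unique(as.character(df$individual_id))
  pos <- sort(unique(as.integer(df$position)))
  ref <- character(length(pos))
  ref[match(as.integer(df$position), pos)] <- toupper(as.character(df$ref))
  cnt <- array(0L, dim = c(length(inds), length(pos), 5L))
  i <- match(as.character(df$individual_id), inds)
  j <- match(as.integer(df$position), pos)
  cols <- c("countA", "countC", "countG", "countT", "countGap")
  for (k in 1:5)
    cnt[cbind(i, j, k)] <- as.integer(df[[cols[k]]])
  cohort_pileup(inds, pos, ref, cnt)
}

#' Write a cohort pileup in the package's TSV dialect
#'
#' Long format with a versioned header line (`#ovmx_pileup v1`) followed by
#' the column header `individual_id position ref countA countC countG
#' countT countGap` (tab-separated).
#'
#' @param pileup A [cohort_pileup()].
#' @param path Output path.
#' @export
write_pileup_tsv <- function(pileup, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(PILEUP_HEADER, con)
  ni <- length(pileup$individuals); np <- length(pileup$positions)
  df <- data.frame(
    individual_id = rep(pileup$individuals, times = np),
    position = rep(pileup$positions, each = ni),
    ref = rep(pileup$ref, each = ni),
    countA = as.vector(pileup$counts[, , 1L]),
    countC = as.vector(pileup$counts[, , 2L]),
    countG = as.vector(pileup$counts[, , 3L]),
    countT = as.vector(pileup$counts[, , 4L]),
    countGap = as.vector(pileup$counts[, , 5L]))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort pileup from the package's TSV dialect
#' @param path Path to a file written by [write_pileup_tsv()].
#' @return A [cohort_pileup()].
#' @export
read_pileup_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!identical(first, PILEUP_HEADER))
    stop("not an ovmx pileup TSV (missing '", PILEUP_HEADER, "' header)")
  df <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  as_cohort_pileup(df)
}
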