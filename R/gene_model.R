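# Gene structure representation and coordinate conversions between genomic,
# CDS (c.) and codon space. Coordinates are 1-based inclusive throughout;
# conversion to 0-based half-open happens only inside file writers.

#' Construct a gene model
#'
#' A gene model anchors all coordinate math of the package: the exon/intron
#' structure of a locus, its strand, and the genomic positions of the first
#' and last coding nucleotide. Exons are stored 5'->3' in transcript
#' orientation, so for a minus-strand gene the first exon has the largest
#' genomic coordinates.
#'
#' @param gene_id Character label for the gene (e.g. `"MX2"`).
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column integer matrix (or data.frame) of genomic
#'   `start`/`end` pairs, 1-based inclusive, non-overlapping, ordered 5'->3'
#'   in transcript orientation. Within a row `start <= end` (genomic order).
#' @param cds_start,cds_end Genomic positions of the first and last coding
#'   nucleotide (first/last in *transcript* orientation: for a minus-strand
#'   gene `cds_start` is the genomically larger coordinate).
#' @return An object of class `gene_model`.
#' @examples
#' gm <- gene_model("toy", "+", cbind(c(1, 16), c(12, 30)), 3, 23)
#' @export
gene_model <- function(gene_id, strand, exons, cds_start, cds_end) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"))
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  if (ncol(exons) != 2L || any(exons[, 1] > exons[, 2]))
    stop("exons must be a 2-column matrix of start <= end pairs")
  colnames(exons) <- c("start", "end")
  # non-overlap + ordering in transcript orientation
  if (nrow(exons) > 1L) {
    ok <- if (strand == "+") all(exons[-1, 1] > exons[-nrow(exons), 2])
          else all(exons[-1, 2] < exons[-nrow(exons), 1])
    if (!ok)
      stop("exons must be non-overlapping and ordered 5'->3' in transcript orientation")
  }
  obj <- structure(list(gene_id = gene_id, strand = strand, exons = exons,
                        cds_start = as.integer(cds_start),
                        cds_end = as.integer(cds_end)),
                   class = "gene_model")
  # cds anchors must fall inside exons, and CDS length must be a codon multiple
  for (p in c(obj$cds_start, obj$cds_end))
    if (!any(p >= exons[, 1] & p <= exons[, 2]))
      stop("cds_start/cds_end must fall inside an exon")
  len <- cds_length(obj)
  if (len <= 0L || len %% 3L != 0L)
    stop("total CDS length must be a positive multiple of 3 (got ", len, ")")
  obj
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s strand): %d exon(s), CDS %d nt (%d codons)\n",
              x$gene_id, x$strand, nrow(x$exons), cds_length(x),
              cds_length(x) %/% 3L))
  invisible(x)
}

# Transcript coordinate of a genomic position (NA if intronic/outside).
# Exons are 5'->3' in transcript orientation; within a minus-strand exon the
# transcript runs from the genomic end down to the genomic start.
transcript_pos <- function(model, genomic_pos) {
  ex <- model$exons
  lens <- ex[, 2] - ex[, 1] + 1L
  offs <- c(0L, cumsum(lens))
  for (i in seq_len(nrow(ex))) {
    if (genomic_pos >= ex[i, 1] && genomic_pos <= ex[i, 2]) {
      within <- if (model$strand == "+") genomic_pos - ex[i, 1] + 1L
                else ex[i, 2] - genomic_pos + 1L
      return(unname(offs[i] + within))
    }
  }
  NA_integer_
}

# Genomic position of a transcript coordinate.
genomic_pos_of <- function(model, tpos) {
  ex <- model$exons
  lens <- ex[, 2] - ex[, 1] + 1L
  offs <- c(0L, cumsum(lens))
  i <- findInterval(tpos - 1L, offs, rightmost.closed = FALSE)
  if (tpos < 1L || tpos > sum(lens)) stop("transcript position out of range")
  within <- tpos - offs[i]
  unname(if (model$strand == "+") ex[i, 1] + within - 1L
         else ex[i, 2] - within + 1L)
}

#' Total coding-sequence length of a gene model
#' @param model A [gene_model()].
#' @return Integer CDS length in nucleotides.
#' @export
cds_length <- function(model) {
  transcript_pos(model, model$cds_end) - transcript_pos(model, model$cds_start) + 1L
}

#' Convert a CDS position to codon number and intra-codon offset
#'
#' c.1 is the A of the start ATG; codon 1 spans c.1-c.3.
#'
#' @param cds_pos Positive integer position within the coding sequence.
#' @return A list with `cds_pos`, `codon_number` and `codon_offset` (1-3).
#' @examples
#' cds_to_codon(497)  # codon 166, offset 2 (the W166* site of ovine MX2)
#' @export
cds_to_codon <- function(cds_pos) {
  cds_pos <- as.integer(cds_pos)
  if (length(cds_pos) != 1L || is.na(cds_pos) || cds_pos < 1L)
    stop("cds_pos must be a positive integer")
  codon <- (cds_pos + 2L) %/% 3L
  list(cds_pos = cds_pos, codon_number = codon,
       codon_offset = cds_pos - 3L * (codon - 1L))
}

#' Inverse of [cds_to_codon()]
#' @param codon_number,codon_offset Codon index (1-based) and offset (1-3).
#' @return The CDS position.
#' @export
codon_to_cds <- function(codon_number, codon_offset) {
  stopifnot(codon_number >= 1, codon_offset %in% 1:3)
  as.integer(3L * (codon_number - 1L) + codon_offset)
}

#' Locate a genomic position within a gene model
#'
#' Coding positions return a CDS location (as [cds_to_codon()]); every other
#' position gets exactly one non-coding label.
#'
#' @param model A [gene_model()].
#' @param genomic_pos Genomic position (1-based).
#' @return For coding positions, a list with `label = "CDS"`, `cds_pos`,
#'   `codon_number`, `codon_offset`; otherwise a list with `label` one of
#'   `"5'UTR"`, `"intron"`, `"3'UTR"`, `"upstream"`, `"downstream"`.
#' @export
genomic_to_cds <- function(model, genomic_pos) {
  genomic_pos <- as.integer(genomic_pos)
  ex <- model$exons
  lo <- min(ex[, 1]); hi <- max(ex[, 2])
  if (genomic_pos < lo || genomic_pos > hi) {
    before <- genomic_pos < lo  # genomically before the locus
    lab <- if (model$strand == "+") {
      if (before) "upstream" else "downstream"
    } else {
      if (before) "downstream" else "upstream"
    }
    return(list(label = lab))
  }
  tp <- transcript_pos(model, genomic_pos)
  if (is.na(tp)) return(list(label = "intron"))
  t_cds_start <- transcript_pos(model, model$cds_start)
  t_cds_end <- transcript_pos(model, model$cds_end)
  if (tp < t_cds_start) return(list(label = "5'UTR"))
  if (tp > t_cds_end) return(list(label = "3'UTR"))
  loc <- cds_to_codon(tp - t_cds_start + 1L)
  c(list(label = "CDS"), loc)
}

#' Genomic position of a CDS coordinate
#' @param model A [gene_model()].
#' @param cds_pos 1-based position within the coding sequence.
#' @return Genomic position (integer); inverse of [genomic_to_cds()] on
#'   coding positions.
#' @export
cds_to_genomic <- function(model, cds_pos) {
  cds_pos <- as.integer(cds_pos)
  if (cds_pos < 1L || cds_pos > cds_length(model))
    stop("cds_pos outside 1..CDS length")
  genomic_pos_of(model, transcript_pos(model, model$cds_start) + cds_pos - 1L)
}

#' Splice a transcript out of a genome sequence
#'
#' Concatenates the exon subsequences in transcript orientation;
#' minus-strand genes are reverse-complemented.
#'
#' @param model A [gene_model()].
#' @param genome_seq Genome sequence as a character string (A/C/G/T).
#' @return The spliced transcript as an uppercase character string.
#' @export
spliced_transcript <- function(model, genome_seq) {
  genome_seq <- toupper(as.character(genome_seq))
  n <- nchar(genome_seq)
  ex <- model$exons
  if (any(ex[, 1] < 1L) || any(ex[, 2] > n))
    stop("exon exceeds genome sequence bounds")
  pieces <- substring(genome_seq, ex[, 1], ex[, 2])
  if (model$strand == "-")
    pieces <- vapply(pieces, revcomp, character(1), USE.NAMES = FALSE)
  paste0(pieces, collapse = "")
}

#' Coding sequence of a gene model
#' @param model A [gene_model()].
#' @param genome_seq Genome sequence (character string).
#' @return The concatenated CDS (start codon to stop codon, inclusive).
#' @export
coding_sequence <- function(model, genome_seq) {
  tx <- spliced_transcript(model, genome_seq)
  substr(tx, transcript_pos(model, model$cds_start),
         transcript_pos(model, model$cds_end))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Map a transcript onto a genome by greedy exact matching
#'
#' Chains maximal exact matches left to right: at each step the longest
#' prefix of the remaining transcript that occurs in the genome downstream
#' of the previous block is taken as the next block (ties broken by the
#' smallest genomic start). This mirrors manual 100%-identity exon mapping,
#' as used for multi-exon 5'UTRs; it performs no gapped or mismatched
#' alignment.
#'
#' @param transcript,genome Nucleotide sequences (character strings).
#' @param min_block Minimum accepted block length (default 15; must be >= 8).
#' @return A list with `mapped` (logical); on success `blocks`, a data.frame
#'   with `t_start`, `t_end`, `g_start`, `g_end`; on failure `unmapped`, the
#'   transcript interval that could not be placed.
#' @export
map_transcript_to_genome <- function(transcript, genome, min_block = 15L) {
  transcript <- toupper(as.character(transcript))
  genome <- toupper(as.character(genome))
  if (nchar(transcript) == 0L || nchar(genome) == 0L)
    stop("sequences must be non-empty")
  if (min_block < 8L) stop("min_block must be >= 8")
  tch <- strsplit(transcript, "")[[1]]
  gch <- strsplit(genome, "")[[1]]
  nt <- length(tch); ng <- length(gch)
  blocks <- list()
  t0 <- 1L; gmin <- 1L
  while (t0 <= nt) {
    best_len <- 0L; best_g <- NA_integer_
    starts <- which(gch == tch[t0])
    starts <- starts[starts >= gmin]
    for (g in starts) {
      len <- 1L
      while (t0 + len <= nt && g + len <= ng && tch[t0 + len] == gch[g + len])
        len <- len + 1L
      if (len > best_len) { best_len <- len; best_g <- g }  # ties keep smaller g
    }
    remaining <- nt - t0 + 1L
    if (best_len < min(min_block, remaining) || best_len == 0L)
      return(list(mapped = FALSE,
                  unmapped = c(t_start = t0, t_end = nt),
                  blocks = do.call(rbind.data.frame, blocks)))
    blocks[[length(blocks) + 1L]] <-
      data.frame(t_start = t0, t_end = t0 + best_len - 1L,
                 g_start = best_g, g_end = best_g + best_len - 1L)
    t0 <- t0 + best_len
    gmin <- best_g + best_len  # genomic intervals strictly increase
  }
  list(mapped = TRUE, blocks = do.call(rbind, blocks))
}

#' Read a gene model from a minimal BED12-like TSV
#'
#' Expected columns: `gene_id`, `strand`, `exon_starts`, `exon_ends`
#' (comma-separated genomic coordinates, transcript order), `cds_start`,
#' `cds_end`. One gene per line; lines beginning `#` are ignored.
#'
#' @param path Path to the TSV file.
#' @return A [gene_model()] (first line) or a list of them if several.
#' @export
read_gene_model <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene_id", "strand", "exon_starts", "exon_ends",
            "cds_start", "cds_end")
  if (!all(need %in% names(df)))
    stop("gene model TSV must have columns: ", paste(need, collapse = ", "))
  models <- lapply(seq_len(nrow(df)), function(i) {
    s <- as.integer(strsplit(df$exon_starts[i], ",")[[1]])
    e <- as.integer(strsplit(df$exon_ends[i], ",")[[1]])
    gene_model(df$gene_id[i], df$strand[i], cbind(s, e),
               df$cds_start[i], df$cds_end[i])
  })
  if (length(models) == 1L) models[[1]] else models
}

#' Write a gene model as GFF3
#'
#' Emits `gene`, `exon` and `CDS` features (1-based inclusive, per GFF3).
#'
#' @param model A [gene_model()].
#' @param path Output file path.
#' @param seqid Sequence identifier for column 1 (default `"chr"`).
#' @export
write_gff3 <- function(model, path, seqid = "chr") {
  ex <- model$exons
  lo <- min(ex[, 1]); hi <- max(ex[, 2])
  att <- function(id, parent = NULL) {
    a <- paste0("ID=", id)
    if (!is.null(parent)) a <- paste0(a, ";Parent=", parent)
    a
  }
  lines <- c("##gff-version 3",
             paste(seqid, "ovmx", "gene", lo, hi, ".", model$strand, ".",
                   att(model$gene_id), sep = "\t"))
  # exon rows in genomic order for readability
  ord <- order(ex[, 1])
  for (k in seq_along(ord)) {
    i <- ord[k]
    lines <- c(lines,
               paste(seqid, "ovmx", "exon", ex[i, 1], ex[i, 2], ".",
                     model$strand, ".",
                     att(paste0(model$gene_id, ":exon", k), model$gene_id),
                     sep = "\t"))
  }
  # CDS rows: intersect exons with the genomic CDS span
  span <- sort(c(model$cds_start, model$cds_end))
  for (k in seq_along(ord)) {
    i <- ord[k]
    s <- max(ex[i, 1], span[1]); e <- min(ex[i, 2], span[2])
    if (s <= e)
      lines <- c(lines,
                 paste(seqid, "ovmx", "CDS", s, e, ".", model$strand, ".",
                       att(paste0(model$gene_id, ":cds", k), model$gene_id),
                       sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from a FASTA file
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(toupper(seqs)), path)
  invisible(path)
}
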