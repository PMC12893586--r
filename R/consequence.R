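# Codon-level consequence annotation of SNPs and single-nucleotide
# deletions. Frameshifts are translated codon-by-codon in the shifted frame
# until the next stop; labels follow the c./p. convention, with the
# frameshift suffix fsN* counting the novel residues before the stop
# (standard HGVS fsTer notation, which counts the stop itself, is available
# via `hgvs_standard = TRUE`).

# Three-letter amino-acid names used in reports (incl. stop).
AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "STOP")

# Codon -> one-letter amino acid under an injectable code table
# (default: the standard genetic code).
translate_codon <- function(codon, code = Biostrings::GENETIC_CODE) {
  aa <- unname(code[codon])
  if (is.na(aa)) stop("cannot translate codon: ", codon)
  aa
}

#' Classify a nucleotide substitution as transition or transversion
#'
#' Transitions (Ts) exchange purines (A<->G) or pyrimidines (C<->T);
#' transversions (Tv) cross the two classes.
#'
#' @param ref,alt Distinct single nucleotides in `A,C,G,T`.
#' @return `"Ts"` or `"Tv"`.
#' @examples
#' classify_substitution("G", "A")  # Ts
#' classify_substitution("C", "G")  # Tv
#' @export
classify_substitution <- function(ref, alt) {
  nts <- c("A", "C", "G", "T")
  if (!(ref %in% nts) || !(alt %in% nts)) stop("ref and alt must be A/C/G/T")
  if (ref == alt) stop("ref and alt must differ")
  pur <- c("A", "G")
  if ((ref %in% pur) == (alt %in% pur)) "Ts" else "Tv"
}

#' Annotate a single-nucleotide substitution on a coding sequence
#'
#' @param cds Coding sequence (character string, length a multiple of 3,
#'   first codon = codon 1).
#' @param cds_pos 1-based position of the substitution within the CDS.
#' @param alt Alternative nucleotide (must differ from the reference base).
#' @param code Genetic code table (named codon->amino-acid vector).
#' @return A `consequence` list: `cds_pos`, `codon_number`, `ref_codon`,
#'   `alt_codon`, `ref_aa`, `alt_aa` (one-letter, `*` = stop),
#'   `consequence_class` (`synonymous`, `missense`, `nonsense`,
#'   `stop_lost`), `hgvs_c`, `hgvs_p`, and `note` (e.g.
#'   `start_lost_candidate` for codon-1 changes, since which of several
#'   in-frame ATGs initiates translation can be ambiguous).
#' @examples
#' cds <- paste(rep("GCT", 200), collapse = "")
#' substr(cds, 496, 498) <- "TGG"
#' annotate_snp(cds, 497, "A")  # p.W166*, nonsense
#' @export
annotate_snp <- function(cds, cds_pos, alt, code = Biostrings::GENETIC_CODE) {
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("cds length must be a multiple of 3")
  if (cds_pos < 1L || cds_pos > n) stop("cds_pos out of range")
  alt <- toupper(alt)
  ref <- substr(cds, cds_pos, cds_pos)
  if (ref == alt) stop("alt equals the reference base at cds_pos")
  loc <- cds_to_codon(cds_pos)
  cstart <- 3L * (loc$codon_number - 1L) + 1L
  ref_codon <- substr(cds, cstart, cstart + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, loc$codon_offset, loc$codon_offset) <- alt
  ref_aa <- translate_codon(ref_codon, code)
  alt_aa <- translate_codon(alt_codon, code)
  class <- if (ref_aa == alt_aa) "synonymous"
           else if (alt_aa == "*") "nonsense"
           else if (ref_aa == "*") "stop_lost"
           else "missense"
  note <- if (loc$codon_number == 1L && class != "synonymous")
    "start_lost_candidate" else NA_character_
  hgvs_p <- if (class == "synonymous")
    sprintf("p.%s%d=", ref_aa, loc$codon_number)
  else sprintf("p.%s%d%s", ref_aa, loc$codon_number, alt_aa)
  structure(list(cds_pos = as.integer(cds_pos),
                 codon_number = loc$codon_number,
                 ref_codon = ref_codon, alt_codon = alt_codon,
                 ref_aa = ref_aa, alt_aa = alt_aa,
                 consequence_class = class,
                 fs_peptide = NA_character_, fs_len = NA_integer_,
                 stop_offset = NA_integer_,
                 hgvs_c = sprintf("c.%d%s>%s", cds_pos, ref, alt),
                 hgvs_p = hgvs_p, note = note),
            class = "consequence")
}

#' Annotate a single-nucleotide deletion on a coding sequence
#'
#' Deletes one base, then translates from the first affected codon in the
#' shifted frame until a stop codon. `fs_peptide` holds the novel residues
#' up to but excluding the stop, `fs_len` their count, and `stop_offset`
#' the ordinal position of the stop counting the first altered codon as 1
#' (so `stop_offset = fs_len + 1`). If the edited sequence ends before a
#' stop is reached the class is `stop_lost` and the record carries a
#' `no_stop_found` note.
#'
#' @param cds Coding sequence (character string).
#' @param cds_pos 1-based position of the deleted base.
#' @param code Genetic code table.
#' @param hgvs_standard Use standard HGVS `fsTer<N>` (counting the stop)
#'   instead of the default `fs<N>*` (counting the novel residues).
#' @return A `consequence` list (see [annotate_snp()]) with the frameshift
#'   fields populated.
#' @export
annotate_deletion <- function(cds, cds_pos, code = Biostrings::GENETIC_CODE,
                              hgvs_standard = FALSE) {
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (cds_pos < 1L || cds_pos > n) stop("cds_pos out of range")
  loc <- cds_to_codon(cds_pos)
  cstart <- 3L * (loc$codon_number - 1L) + 1L
  ref_codon <- substr(cds, cstart, cstart + 2L)
  ref_aa <- translate_codon(ref_codon, code)
  edited <- paste0(substr(cds, 1L, cds_pos - 1L), substr(cds, cds_pos + 1L, n))
  # walk the shifted frame codon-by-codon from the first affected codon
  peptide <- character(0)
  stop_offset <- NA_integer_
  k <- 0L
  repeat {
    s <- cstart + 3L * k
    if (s + 2L > nchar(edited)) break  # ran off the sequence: no stop
    aa <- translate_codon(substr(edited, s, s + 2L), code)
    k <- k + 1L
    if (aa == "*") { stop_offset <- k; break }
    peptide <- c(peptide, aa)
  }
  found_stop <- !is.na(stop_offset)
  fs_len <- length(peptide)
  first_new <- if (fs_len >= 1L) peptide[1L] else "*"
  hgvs_p <- if (!found_stop) {
    sprintf("p.%s%d%sfs*?", ref_aa, loc$codon_number, first_new)
  } else if (hgvs_standard) {
    sprintf("p.%s%d%sfsTer%d", ref_aa, loc$codon_number, first_new, stop_offset)
  } else if (fs_len == 0L) {
    # the first altered codon is itself a stop: effectively nonsense
    sprintf("p.%s%d*", ref_aa, loc$codon_number)
  } else {
    sprintf("p.%s%d%sfs%d*", ref_aa, loc$codon_number, first_new, fs_len)
  }
  structure(list(cds_pos = as.integer(cds_pos),
                 codon_number = loc$codon_number,
                 ref_codon = ref_codon, alt_codon = NA_character_,
                 ref_aa = ref_aa,
                 alt_aa = if (fs_len >= 1L) first_new else "*",
                 consequence_class = if (found_stop) "frameshift" else "stop_lost",
                 fs_peptide = if (fs_len) paste(peptide, collapse = "") else "",
                 fs_len = fs_len,
                 stop_offset = stop_offset,
                 hgvs_c = sprintf("c.%ddel", cds_pos),
                 hgvs_p = hgvs_p,
                 note = if (found_stop) NA_character_ else "no_stop_found"),
            class = "consequence")
}

#' @export
print.consequence <- function(x, ...) {
  cat(sprintf("%s %s (%s)", x$hgvs_c, x$hgvs_p, x$consequence_class))
  if (!is.na(x$fs_len) && x$consequence_class == "frameshift")
    cat(sprintf(" novel peptide %s, stop at altered codon %d",
                paste(AA3[strsplit(x$fs_peptide, "")[[1]]], collapse = "."),
                x$stop_offset))
  if (!is.na(x$note)) cat(" [", x$note, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Parse a coding-change label back to its components
#'
#' Inverse of the `hgvs_c` labels emitted by [annotate_snp()] and
#' [annotate_deletion()].
#'
#' @param hgvs_c Label such as `"c.497G>A"` or `"c.985del"`.
#' @return List with `cds_pos` and, for substitutions, `ref` and `alt`;
#'   deletions have `type = "del"`.
#' @export
parse_hgvs_c <- function(hgvs_c) {
  m <- regmatches(hgvs_c, regexec("^c\\.([0-9]+)([ACGT])>([ACGT])$", hgvs_c))[[1]]
  if (length(m) == 4L)
    return(list(type = "sub", cds_pos = as.integer(m[2]), ref = m[3], alt = m[4]))
  m <- regmatches(hgvs_c, regexec("^c\\.([0-9]+)del$", hgvs_c))[[1]]
  if (length(m) == 2L)
    return(list(type = "del", cds_pos = as.integer(m[2])))
  stop("cannot parse coding-change label: ", hgvs_c)
}

#' Count protein-altering consequences
#'
#' @param records List of `consequence` objects.
#' @return Number of records whose class is not `synonymous`.
#' @export
count_protein_altering <- function(records) {
  sum(vapply(records, function(x) x$consequence_class != "synonymous",
             logical(1)))
}

#' Write consequence annotations as a TSV
#'
#' @param records List of `consequence` objects.
#' @param path Output path.
#' @param positions Optional genomic positions, one per record.
#' @export
write_consequence_tsv <- function(records, path, positions = NULL) {
  df <- data.frame(
    position = if (is.null(positions)) vapply(records, `[[`, integer(1), "cds_pos")
               else positions,
    hgvs_c = vapply(records, `[[`, character(1), "hgvs_c"),
    hgvs_p = vapply(records, `[[`, character(1), "hgvs_p"),
    class = vapply(records, `[[`, character(1), "consequence_class"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
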