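# Worked-example data: the coding variants observed in ovine MX1 and MX2
# across a 68-animal whole-genome cohort, given as (codon number, ref>alt
# nucleotide, reference amino acid, amino-acid change). Published variant
# lists give codon numbers but not intra-codon offsets, so a fixture CDS is
# reconstructed by exhaustive search: for each row the unique codon and
# offset consistent with the printed reference amino acid and amino-acid
# change is placed at that codon.

#' Coding variants of ovine MX1 (11 SNPs)
#'
#' Columns: `codon`, `ref_nt`, `alt_nt`, `ref_aa` (three-letter),
#' `change` (three-letter alternative amino acid, `"no"` for synonymous),
#' `type` (`"SNP"`).
#'
#' @return A data.frame with one row per coding variant.
#' @export
mx1_coding_variants <- function() {
  data.frame(
    codon = c(16L, 17L, 30L, 80L, 125L, 288L, 323L, 390L, 452L, 575L, 579L),
    ref_nt = c("C", "G", "T", "T", "G", "C", "C", "C", "A", "G", "A"),
    alt_nt = c("T", "A", "C", "C", "A", "T", "G", "T", "G", "A", "G"),
    ref_aa = c("Ser", "Gly", "Met", "Ser", "Glu", "Asp", "Thr", "Leu",
               "Ile", "Ala", "Glu"),
    change = c("no", "Ser", "Thr", "no", "no", "no", "no", "no",
               "Val", "no", "no"),
    type = "SNP")
}

#' Coding variants of ovine MX2 (16 SNPs and one single-base deletion)
#'
#' Same columns as [mx1_coding_variants()]; the codon-329 row is the
#' single-nucleotide deletion (`type = "deletion"`, `change =
#' "Frameshift"`), and the codon-166 row is the stop-gain (W166*).
#'
#' @return A data.frame with one row per coding variant.
#' @export
mx2_coding_variants <- function() {
  data.frame(
    codon = c(1L, 28L, 64L, 85L, 166L, 175L, 329L, 376L, 378L, 422L,
              561L, 584L, 598L, 608L, 616L, 697L, 713L),
    ref_nt = c("A", "T", "A", "C", "G", "G", "C", "G", "T", "T",
               "G", "C", "C", "A", "G", "C", "G"),
    alt_nt = c("G", "C", "C", "T", "A", "A", NA, "A", "C", "C",
               "A", "T", "T", "G", "A", "A", "A"),
    ref_aa = c("Met", "Phe", "Asn", "Pro", "Trp", "Val", "Gln", "Glu",
               "Ile", "Ile", "Ala", "Tyr", "Ser", "Ser", "Gln", "Arg",
               "Gly"),
    change = c("Val", "no", "His", "Ser", "STOP", "no", "Frameshift",
               "no", "no", "no", "no", "no", "no", "no", "no", "no",
               "Ser"),
    type = c(rep("SNP", 6), "deletion", rep("SNP", 10)))
}

# Codons of the frameshift context: the original reading of codons 329-336
# is Gln.Gln.Asp.Ile.Thr.Asn.Lys.Leu; deleting the first base of codon 329
# shifts the frame to Ser.Arg.Ile.Ser.Pro.Thr.Ser.STOP. Codon 337 must
# begin with A for the shifted frame to terminate at the eighth altered
# codon.
frameshift_context_codons <- function() {
  list(`329` = "CAG", `330` = "CAG", `331` = "GAT", `332` = "ATC",
       `333` = "ACC", `334` = "AAC", `335` = "AAG", `336` = "CTG",
       `337` = "AAA")
}

# Find a codon and intra-codon offset consistent with a printed variant
# row: the codon encodes ref_aa, carries ref_nt at the offset, and the
# substituted codon encodes the printed change ("no" = same amino acid,
# "STOP" = termination). Deterministic: smallest offset, then alphabetical
# codon order.
codon_for_change <- function(ref_aa3, ref_nt, alt_nt, change3,
                             code = Biostrings::GENETIC_CODE) {
  aa1 <- names(AA3)[match(ref_aa3, AA3)]
  if (is.na(aa1)) stop("unknown amino acid: ", ref_aa3)
  want <- if (change3 == "no") aa1
          else if (change3 == "STOP") "*"
          else names(AA3)[match(change3, AA3)]
  codons <- sort(names(code)[code == aa1])
  for (off in 1:3) {
    for (cd in codons) {
      if (substr(cd, off, off) != ref_nt) next
      mut <- cd
      substr(mut, off, off) <- alt_nt
      if (unname(code[mut]) == want) return(list(codon = cd, offset = off))
    }
  }
  stop("no codon consistent with ", ref_aa3, " ", ref_nt, ">", alt_nt,
       " -> ", change3)
}

#' Build a fixture coding sequence realising a variant table
#'
#' Constructs a CDS in which every SNP row sits at a codon/offset consistent
#' with its printed reference amino acid and amino-acid change, a deletion
#' row is embedded in the frameshift context of
#' `frameshift_context_codons()`, unused codons are filled with `GCT`
#' (Ala), codon 1 is `ATG` unless a row dictates otherwise, and a terminal
#' `TAA` closes the frame.
#'
#' @param rows Variant table in the format of [mx1_coding_variants()].
#' @param n_codons Number of codons before the terminal stop (default:
#'   enough to hold every row plus the frameshift context).
#' @return List with `cds` (character string) and `rows` (the input table
#'   augmented with `cds_pos`, the 1-based CDS position of each change).
#' @export
build_variant_cds <- function(rows, n_codons = NULL) {
  fsctx <- frameshift_context_codons()
  need <- max(rows$codon, if (any(rows$type == "deletion"))
    max(as.integer(names(fsctx))) else 0L) + 3L
  if (is.null(n_codons)) n_codons <- need
  stopifnot(n_codons >= need - 3L)
  codons <- rep("GCT", n_codons)
  codons[1L] <- "ATG"
  if (any(rows$type == "deletion"))
    codons[as.integer(names(fsctx))] <- unlist(fsctx)
  cds_pos <- integer(nrow(rows))
  for (r in seq_len(nrow(rows))) {
    if (rows$type[r] == "deletion") {
      # deletion of the first base of its codon, inside the planted context
      off <- 1L
      if (codons[rows$codon[r]] != fsctx[[as.character(rows$codon[r])]] ||
          substr(codons[rows$codon[r]], 1L, 1L) != rows$ref_nt[r])
        stop("deletion row inconsistent with frameshift context")
    } else {
      hit <- codon_for_change(rows$ref_aa[r], rows$ref_nt[r],
                              rows$alt_nt[r], rows$change[r])
      codons[rows$codon[r]] <- hit$codon
      off <- hit$offset
    }
    cds_pos[r] <- codon_to_cds(rows$codon[r], off)
  }
  rows$cds_pos <- cds_pos
  list(cds = paste(c(codons, "TAA"), collapse = ""), rows = rows)
}

#' Annotate every row of a variant table on its fixture CDS
#'
#' @param rows Variant table ([mx1_coding_variants()] format).
#' @return List of `consequence` objects, one per row.
#' @export
annotate_variant_table <- function(rows) {
  fx <- build_variant_cds(rows)
  lapply(seq_len(nrow(fx$rows)), function(r) {
    if (fx$rows$type[r] == "deletion")
      annotate_deletion(fx$cds, fx$rows$cds_pos[r])
    else
      annotate_snp(fx$cds, fx$rows$cds_pos[r], fx$rows$alt_nt[r])
  })
}

#' Fixture CDS for the W166* stop-gain
#'
#' A coding sequence whose codon 166 is `TGG` (Trp), so the substitution
#' `c.497G>A` creates the amber stop `TAG`.
#'
#' @param n_codons CDS length in codons before the terminal stop.
#' @return Character string CDS.
#' @export
w166_fixture_cds <- function(n_codons = 200L) {
  stopifnot(n_codons >= 166L)
  codons <- rep("GCT", n_codons)
  codons[1L] <- "ATG"
  codons[166L] <- "TGG"
  paste(c(codons, "TAA"), collapse = "")
}

#' Fixture CDS for the Q329Sfs7* frameshift
#'
#' A coding sequence embedding the frameshift context at codons 329-337, so
#' the single-base deletion `c.985del` shifts the frame to read
#' Ser.Arg.Ile.Ser.Pro.Thr.Ser.STOP.
#'
#' @param n_codons CDS length in codons before the terminal stop.
#' @return Character string CDS.
#' @export
q329_fixture_cds <- function(n_codons = 340L) {
  fsctx <- frameshift_context_codons()
  stopifnot(n_codons >= 337L)
  codons <- rep("GCT", n_codons)
  codons[1L] <- "ATG"
  codons[as.integer(names(fsctx))] <- unlist(fsctx)
  paste(c(codons, "TAA"), collapse = "")
}
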