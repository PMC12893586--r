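# Pipeline orchestration and the remaining external formats: VCFv4.2
# output (1-based POS; single-base deletions left-anchored on the preceding
# reference base), a JSON run manifest, and a simple key-value config file
# with CLI-flag-style overrides (precedence: overrides > file > defaults).

ovmx_version <- function() {
  as.character(utils::packageVersion("ovmx"))
}

# Stable hash of the configuration for output headers/manifest.
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  flat <- cfg[order(names(cfg))]
  writeLines(paste(names(flat), vapply(flat, function(x)
    paste(format(x), collapse = ","), character(1)), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

#' Pipeline configuration
#'
#' Thresholds default to the mining rules: per-individual qualifying depth
#' 10, pooled-region threshold 99 (strict `>`), heterozygote evidence
#' threshold 0.45 (strict `>`), genotype minor-fraction bands 0.10/0.25.
#'
#' @param pileup Path to a pileup TSV, or a [cohort_pileup()] object.
#' @param reference Path to a FASTA file, or a reference sequence string.
#' @param gene_model Optional [gene_model()] (or gene-model TSV path) used
#'   to annotate coding consequences of accepted variants.
#' @param simulate Optional [sim_config()]; when given, the pileup is
#'   generated rather than read and `reference` must be a sequence/FASTA.
#' @param out_dir Output directory for the VCF, variant table, annotation
#'   and stats TSVs and the JSON manifest.
#' @param coverage_min,region_sum_min,minor_fraction_crit,hom_max_minor,het_min_minor
#'   Mining thresholds (see [mine_variants()]).
#' @param seed Seed recorded in the manifest (and used by `simulate`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(pileup = NULL, reference = NULL,
                            gene_model = NULL, simulate = NULL,
                            out_dir = ".", coverage_min = 10L,
                            region_sum_min = 99L,
                            minor_fraction_crit = 0.45,
                            hom_max_minor = 0.10, het_min_minor = 0.25,
                            seed = 1L) {
  if (!(hom_max_minor >= 0 && hom_max_minor < het_min_minor &&
        het_min_minor <= 0.5))
    stop("config invalid: need 0 <= hom_max_minor < het_min_minor <= 0.5")
  if (coverage_min < 1L || region_sum_min < 0L ||
      minor_fraction_crit <= 0 || minor_fraction_crit >= 1)
    stop("config invalid: thresholds out of range")
  if (is.null(simulate) && is.null(pileup))
    stop("config invalid: need either a pileup or a simulate config")
  structure(list(pileup = pileup, reference = reference,
                 gene_model = gene_model, simulate = simulate,
                 out_dir = out_dir, coverage_min = as.integer(coverage_min),
                 region_sum_min = as.integer(region_sum_min),
                 minor_fraction_crit = minor_fraction_crit,
                 hom_max_minor = hom_max_minor,
                 het_min_minor = het_min_minor, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a key=value config file with overrides
#'
#' Lines of the form `key = value` (comments `#`). Values in `overrides`
#' take precedence over the file, which takes precedence over the
#' [pipeline_config()] defaults.
#'
#' @param path Config file path (may be NULL).
#' @param overrides Named list of override values.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    lines <- grep("^\\s*(#|$)", readLines(path), value = TRUE, invert = TRUE)
    kv <- strsplit(lines, "\\s*=\\s*")
    for (p in kv) {
      if (length(p) != 2L) stop("bad config line: ", paste(p, collapse = "="))
      vals[[trimws(p[1])]] <- utils::type.convert(trimws(p[2]), as.is = TRUE)
    }
  }
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Write accepted variants as VCFv4.2
#'
#' SNPs are written at their position; a single-base deletion (gap allele)
#' at position `p` is left-anchored: `POS = p - 1`, `REF` the two bases at
#' `p-1..p`, `ALT` the base at `p-1`. INFO carries `FALT`,
#' `VREADS`/`TREADS` (pooled), `NCARRIER`/`NGENO` and, when annotation is
#' available, `CSQ_CLASS`, `HGVS_C`, `HGVS_P`. The header records the tool
#' version and config hash.
#'
#' @param records Data frame from [mine_variants()] (accepted rows are
#'   written).
#' @param reference Reference sequence (character string).
#' @param path Output path.
#' @param chrom Chromosome name for column 1.
#' @param annotations Optional list of `consequence` objects parallel to
#'   the accepted rows.
#' @param config_hash Optional config hash string for the header.
#' @export
write_vcf <- function(records, reference, path, chrom = "chr1",
                      annotations = NULL, config_hash = NULL) {
  reference <- toupper(as.character(reference))
  acc <- records[records$accepted, , drop = FALSE]
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=ovmx-", ovmx_version()),
           if (!is.null(config_hash)) paste0("##ovmx_config_hash=", config_hash),
           "##INFO=<ID=FALT,Number=1,Type=Float,Description=\"Pooled alternative-allele read fraction\">",
           "##INFO=<ID=VREADS,Number=1,Type=Integer,Description=\"Pooled variant-supporting reads\">",
           "##INFO=<ID=TREADS,Number=1,Type=Integer,Description=\"Pooled total reads\">",
           "##INFO=<ID=NCARRIER,Number=1,Type=Integer,Description=\"Animals carrying the variant\">",
           "##INFO=<ID=NGENO,Number=1,Type=Integer,Description=\"Animals genotyped\">",
           "##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description=\"Coding consequence class\">",
           "##INFO=<ID=HGVS_C,Number=1,Type=String,Description=\"Coding-level change\">",
           "##INFO=<ID=HGVS_P,Number=1,Type=String,Description=\"Protein-level change\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  rows <- character(nrow(acc))
  for (k in seq_len(nrow(acc))) {
    p <- acc$position[k]
    if (acc$alt[k] == "-") {
      if (p < 2L) stop("cannot left-anchor a deletion at position 1")
      pos <- p - 1L
      ref <- substr(reference, p - 1L, p)
      alt <- substr(reference, p - 1L, p - 1L)
    } else {
      pos <- p
      ref <- acc$ref[k]
      alt <- acc$alt[k]
    }
    info <- sprintf("FALT=%.6g;VREADS=%d;TREADS=%d;NCARRIER=%d;NGENO=%d",
                    acc$f_alt[k], acc$pooled_variant_reads[k],
                    acc$pooled_total_reads[k], acc$n_carriers[k],
                    acc$n_genotyped[k])
    if (!is.null(annotations) && !is.null(annotations[[k]])) {
      a <- annotations[[k]]
      info <- paste0(info, sprintf(";CSQ_CLASS=%s;HGVS_C=%s;HGVS_P=%s",
                                   a$consequence_class, a$hgvs_c, a$hgvs_p))
    }
    rows[k] <- paste(chrom, pos, ".", ref, alt, ".", "PASS", info, sep = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Stages: (optional) simulate -> mine -> annotate -> stats. Writes
#' `variants.vcf`, `variants.tsv`, `consequences.tsv`, `stats.tsv` and
#' `manifest.json` into `cfg$out_dir`. Any stage failure removes partial
#' outputs and aborts with a stage-named diagnostic. Outputs contain no
#' timestamps, so re-running on identical inputs is byte-identical.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the mined records, annotations, per-site
#'   genotype-count stats and output paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outs <- file.path(cfg$out_dir, c("variants.vcf", "variants.tsv",
                                   "consequences.tsv", "stats.tsv",
                                   "manifest.json"))
  names(outs) <- c("vcf", "table", "csq", "stats", "manifest")
  stage <- "setup"
  tryCatch({
    stage <- "input"
    reference <- if (is.null(cfg$reference)) NULL
      else if (file.exists(as.character(cfg$reference)[1]) &&
               !grepl("^[ACGTacgt]+$", cfg$reference))
        read_fasta(cfg$reference)[[1]]
      else toupper(as.character(cfg$reference))
    gm <- cfg$gene_model
    if (is.character(gm) && length(gm) == 1L && file.exists(gm))
      gm <- read_gene_model(gm)
    if (!is.null(cfg$simulate)) {
      stage <- "simulate"
      sim <- simulate_cohort(cfg$simulate, reference)
      pu <- sim$pileup
    } else {
      pu <- if (inherits(cfg$pileup, "cohort_pileup")) cfg$pileup
            else read_pileup_tsv(cfg$pileup)
      if (is.null(reference)) reference <- paste(pu$ref, collapse = "")
    }
    stage <- "mine"
    rec <- mine_variants(pu, hom_max_minor = cfg$hom_max_minor,
                         het_min_minor = cfg$het_min_minor,
                         min_depth = cfg$coverage_min,
                         region_sum_min = cfg$region_sum_min,
                         minor_fraction_crit = cfg$minor_fraction_crit)
    stage <- "annotate"
    acc <- rec[rec$accepted, , drop = FALSE]
    ann <- vector("list", nrow(acc))
    if (!is.null(gm)) {
      cds <- coding_sequence(gm, reference)
      for (k in seq_len(nrow(acc))) {
        loc <- genomic_to_cds(gm, acc$position[k])
        if (loc$label == "CDS") {
          ann[[k]] <- if (acc$alt[k] == "-")
            annotate_deletion(cds, loc$cds_pos)
          else annotate_snp(cds, loc$cds_pos, acc$alt[k])
        }
      }
    }
    stage <- "stats"
    gts <- attr(rec, "genotypes")[, rec$accepted, drop = FALSE]
    stats_df <- do.call(rbind, lapply(seq_len(nrow(acc)), function(k) {
      gc <- genotype_counts(sum(gts[, k] == "hom_ref"),
                            sum(gts[, k] == "het"),
                            sum(gts[, k] == "hom_alt"))
      hw <- hwe_test(gc)
      data.frame(position = acc$position[k],
                 n_ref_hom = gc$n_ref_hom, n_het = gc$n_het,
                 n_alt_hom = gc$n_alt_hom,
                 f_alt_genotypic = unname(allele_frequency(gc)["f_alt"]),
                 hwe_chisq = if (hw$undefined) NA_real_ else hw$statistic,
                 hwe_p = if (hw$undefined) NA_real_ else hw$p.value)
    }))
    if (is.null(stats_df))
      stats_df <- data.frame(position = integer(0))
    stage <- "write"
    # hash only the analysis parameters, not file-system locations
    h <- config_hash(cfg[c("coverage_min", "region_sum_min",
                           "minor_fraction_crit", "hom_max_minor",
                           "het_min_minor", "seed")])
    write_vcf(rec, reference, outs[["vcf"]],
              annotations = ann, config_hash = h)
    write_variant_table(rec, outs[["table"]])
    keep <- !vapply(ann, is.null, logical(1))
    write_consequence_tsv(ann[keep], outs[["csq"]],
                          positions = acc$position[keep])
    utils::write.table(stats_df, outs[["stats"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- list(tool = "ovmx", version = ovmx_version(),
                     seed = cfg$seed, config_hash = h,
                     thresholds = list(
                       coverage_min = cfg$coverage_min,
                       region_sum_min = cfg$region_sum_min,
                       minor_fraction_crit = cfg$minor_fraction_crit,
                       hom_max_minor = cfg$hom_max_minor,
                       het_min_minor = cfg$het_min_minor),
                     n_individuals = length(pu$individuals),
                     n_positions = length(pu$positions),
                     n_candidates = nrow(rec),
                     n_accepted = sum(rec$accepted),
                     outputs = as.list(basename(outs)))
    jsonlite::write_json(manifest, outs[["manifest"]], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    invisible(list(records = rec, annotations = ann, stats = stats_df,
                   outputs = outs))
  }, error = function(e) {
    unlink(outs)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}
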