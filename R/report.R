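#' Export CNV calls as VCF 4.2
#'
#' One data line per (merged) call, with symbolic `<DEL>`/`<DUP>` alleles:
#' POS is the start of the first supporting amplicon, INFO/END the end of
#' the last one (both 1-based inclusive). REF is `N` (no reference genome
#' is available to the tool) and the single genotype column holds the
#' placeholder `./1` (amplicon depth cannot phase). A merged region spanning
#' any number of amplicons therefore exports as exactly one line.
#'
#' @param calls calls data frame (one sample's, merged and sorted).
#' @param design the [amplicon_design()] (supplies the contig lines).
#' @param sample_id name of the VCF genotype column.
#' @param path optional output path.
#' @return Character vector of VCF lines, invisibly if written to `path`.
#' @export
to_vcf <- function(calls, design, sample_id = "sample", path = NULL) {
  contigs <- unique(design$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=panelcnv-", as.character(utils::packageVersion("panelcnv"))),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=AMPLICONS,Number=1,Type=Integer,Description=\"Number of supporting amplicons\">",
    "##INFO=<ID=MEANNRC,Number=1,Type=Float,Description=\"Mean normalized read count over the region\">",
    sprintf("##contig=<ID=%s>", contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t"))
  body <- character(0)
  if (nrow(calls)) {
    o <- order(match(calls$chrom, contigs), calls$start)
    cc <- calls[o, , drop = FALSE]
    body <- sprintf(
      "%s\t%d\t.\tN\t<%s>\t.\t.\tSVTYPE=%s;END=%d;AMPLICONS=%d;MEANNRC=%.4f\tGT\t./1",
      cc$chrom, cc$start, cc$direction, cc$direction, cc$end,
      cc$n_amplicons, cc$mean_nrc)
  }
  lines <- c(header, body)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Export calls and per-amplicon evidence as TSV
#'
#' @param calls calls data frame (any number of samples).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  out <- calls[, c("sample", "chrom", "start", "end", "direction",
                   "n_amplicons", "mean_nrc", "merged")]
  out$amplicons <- vapply(calls$amplicons, paste, "", collapse = ",")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$amplicons <- I(strsplit(as.character(df$amplicons), ","))
  df
}

#' Per-amplicon evidence table
#'
#' One row per non-missing (sample, amplicon) cell: NRC, z, one-tailed p
#' and state, as produced by the detection pass.
#'
#' @param result a `"cnv_result"` from [two_stage_detect()].
#' @param path optional output path.
#' @return The table (invisibly when written).
#' @export
amplicon_table <- function(result, path = NULL) {
  rows <- lapply(names(result$statuses), function(s) {
    st <- result$statuses[[s]]
    st <- st[st$state != "MISSING", , drop = FALSE]
    data.frame(sample = s, amplicon = st$id, nrc = st$nrc, z = st$z,
               p = st$p, state = st$state, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
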