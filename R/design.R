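#' Amplicon panel designs
#'
#' An amplicon design is the ordered catalogue of the panel's amplicons:
#' one row per amplicon with its genomic interval (1-based, inclusive),
#' gene label and primer-pool index. Rows are sorted by (chromosome, start);
#' "successive" amplicons throughout the package means adjacent rows of this
#' ordering restricted to one chromosome.
#'
#' @param id character vector of unique amplicon labels.
#' @param chrom chromosome names (non-empty).
#' @param start,end 1-based inclusive genomic coordinates, `start <= end`.
#' @param gene gene labels; defaults to the amplicon id prefix before the
#'   last underscore.
#' @param pool primer-pool indices (integer >= 1); defaults to 1.
#' @return A data frame of class `"amplicon_design"` sorted by
#'   (chromosome, start, end, id), with columns `id`, `chrom`, `start`,
#'   `end`, `gene`, `pool`.
#' @export
amplicon_design <- function(id, chrom, start, end, gene = NULL, pool = NULL) {
  id <- as.character(id)
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  n <- length(id)
  if (length(chrom) != n || length(start) != n || length(end) != n)
    stop("id, chrom, start, end must have equal length")
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate amplicon id: ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(chrom)) || anyNA(chrom)) stop("chromosome must be non-empty")
  if (anyNA(start) || anyNA(end) || any(start > end))
    stop("amplicon coordinates must satisfy start <= end")
  if (is.null(gene)) gene <- sub("_[^_]*$", "", id)
  if (is.null(pool)) pool <- rep(1L, n)
  pool <- as.integer(pool)
  if (anyNA(pool) || any(pool < 1L)) stop("pool must be an integer >= 1")
  df <- data.frame(id = id, chrom = chrom, start = start, end = end,
                   gene = as.character(gene), pool = pool,
                   stringsAsFactors = FALSE)
  o <- order(chrom_rank(df$chrom), df$start, df$end, df$id)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("amplicon_design", "data.frame")
  df
}

# Natural chromosome order: chr1..chr22 numerically, then X, Y, M(T),
# then anything else lexicographically. Used for sorting and VCF contigs.
chrom_rank <- function(chrom) {
  base <- sub("^chr", "", chrom, ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(base))
  rank <- ifelse(!is.na(num), num,
                 ifelse(toupper(base) == "X", 100,
                        ifelse(toupper(base) == "Y", 101,
                               ifelse(toupper(base) %in% c("M", "MT"), 102, 103))))
  # distinct unknown names keep a stable lexicographic order
  rank + match(chrom, sort(unique(chrom))) / (length(unique(chrom)) + 1) * 1e-3
}

#' @export
print.amplicon_design <- function(x, ...) {
  cat(sprintf("amplicon_design: %d amplicons, %d genes, %d chromosomes, %d pool(s)\n",
              nrow(x), length(unique(x$gene)), length(unique(x$chrom)),
              length(unique(x$pool))))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Read an amplicon design from BED or TSV
#'
#' Two dialects are accepted. `"bed0"` is standard BED: 0-based half-open
#' coordinates, whitespace-separated columns chrom/start/end/name with
#' optional gene and pool columns 5-6; coordinates are converted to the
#' internal 1-based inclusive convention (`start + 1`). `"tsv1"` is a
#' headered TSV with columns `chrom`, `start`, `end`, `amplicon`, and
#' optional `gene`, `pool`, already 1-based inclusive.
#'
#' @param path path to the design file.
#' @param dialect `"bed0"` or `"tsv1"`.
#' @return An [amplicon_design()].
#' @export
read_design <- function(path, dialect = c("tsv1", "bed0")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("design file not found: ", path)
  if (dialect == "bed0") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    lines <- lines[!grepl("^(track|browser|#)", lines)]
    fields <- strsplit(trimws(lines), "[ \t]+")
    nf <- vapply(fields, length, 1L)
    bad <- which(nf < 4L)
    if (length(bad))
      stop("unparseable design row at line ", bad[1], ": need >= 4 fields")
    starts <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
    ends <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
    if (anyNA(starts) || anyNA(ends)) {
      bad <- which(is.na(starts) | is.na(ends))[1]
      stop("unparseable design row at line ", bad, ": non-integer coordinates")
    }
    gene <- ifelse(nf >= 5L, vapply(fields, function(f) f[5], ""), NA)
    pool <- ifelse(nf >= 6L, vapply(fields, function(f) f[6], ""), NA)
    amplicon_design(
      id = vapply(fields, `[`, "", 4L),
      chrom = vapply(fields, `[`, "", 1L),
      start = starts + 1L, end = ends,
      gene = if (all(is.na(gene))) NULL else
        ifelse(is.na(gene), sub("_[^_]*$", "", vapply(fields, `[`, "", 4L)), gene),
      pool = if (all(is.na(pool))) NULL else
        as.integer(ifelse(is.na(pool), 1L, pool)))
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "amplicon")
    if (!all(need %in% names(df)))
      stop("tsv1 design needs columns: ", paste(need, collapse = ", "))
    amplicon_design(id = df$amplicon, chrom = df$chrom,
                    start = df$start, end = df$end,
                    gene = if ("gene" %in% names(df)) df$gene else NULL,
                    pool = if ("pool" %in% names(df)) df$pool else NULL)
  }
}

#' Write an amplicon design as tsv1
#'
#' @param design an [amplicon_design()].
#' @param path output path.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "amplicon_design"))
  out <- data.frame(chrom = design$chrom, start = design$start,
                    end = design$end, amplicon = design$id,
                    gene = design$gene, pool = design$pool)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample coverage file
#'
#' A two-column TSV `(amplicon_id, total_reads)` with or without a header.
#' Amplicons of the design absent from the file come back as `NA` (missing).
#'
#' @param path coverage TSV path.
#' @param design the panel [amplicon_design()].
#' @return Numeric vector aligned to the design order, `NA` where missing.
#' @export
read_coverage <- function(path, design) {
  stopifnot(inherits(design, "amplicon_design"))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, header = FALSE)
  if (nrow(df) && is.na(suppressWarnings(as.numeric(df[1, 2]))))
    df <- df[-1, , drop = FALSE]  # header row
  ids <- as.character(df[[1]])
  counts <- suppressWarnings(as.numeric(df[[2]]))
  unknown <- setdiff(ids, design$id)
  if (length(unknown))
    stop("coverage file contains unknown amplicon id: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  if (anyNA(counts)) stop("non-numeric read count in ", path)
  if (any(counts < 0)) stop("negative read count in ", path)
  v <- rep(NA_real_, nrow(design))
  v[match(ids, design$id)] <- counts
  v
}

#' Assemble per-sample count vectors into a run matrix
#'
#' A run matrix couples the design with an amplicons x samples matrix of raw
#' integer read counts and a missing mask. Masked cells are excluded from
#' every downstream mean, median, SD and z-score.
#'
#' @param design an [amplicon_design()].
#' @param vectors named list of count vectors (names = sample ids), each
#'   aligned to the design order; `NA` marks a missing cell.
#' @return A list of class `"run_matrix"` with elements `design`,
#'   `sample_ids`, `counts` (numeric matrix, missing cells hold `NA`) and
#'   `missing` (logical matrix).
#' @export
assemble_run <- function(design, vectors) {
  stopifnot(inherits(design, "amplicon_design"), length(vectors) >= 1)
  ids <- names(vectors)
  if (is.null(ids) || any(!nzchar(ids))) stop("vectors must be named by sample id")
  if (anyDuplicated(ids))
    stop("duplicate sample id: ", unique(ids[duplicated(ids)])[1])
  n <- nrow(design)
  bad <- which(vapply(vectors, length, 1L) != n)
  if (length(bad)) stop("count vector length mismatch for sample ", ids[bad[1]])
  counts <- matrix(unlist(vectors, use.names = FALSE), nrow = n,
                   dimnames = list(design$id, ids))
  if (any(counts < 0, na.rm = TRUE)) stop("negative read count")
  structure(list(design = design, sample_ids = ids, counts = counts,
                 missing = is.na(counts)),
            class = "run_matrix")
}

#' Read a combined coverage matrix
#'
#' First column `amplicon_id`, one column of raw counts per sample.
#' Empty fields are missing.
#'
#' @param path matrix TSV path.
#' @param design the panel [amplicon_design()].
#' @return A `"run_matrix"`.
#' @export
read_count_matrix <- function(path, design) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  unknown <- setdiff(ids, design$id)
  if (length(unknown))
    stop("matrix contains unknown amplicon id: ", unknown[1])
  vectors <- lapply(df[-1], function(col) {
    v <- rep(NA_real_, nrow(design))
    v[match(ids, design$id)] <- suppressWarnings(as.numeric(col))
    v
  })
  assemble_run(design, vectors)
}

#' @export
print.run_matrix <- function(x, ...) {
  cat(sprintf("run_matrix: %d amplicons x %d samples (%d missing cells)\n",
              nrow(x$counts), ncol(x$counts), sum(x$missing)))
  invisible(x)
}

#' Write a run matrix as a combined coverage TSV
#' @param run a `"run_matrix"`.
#' @param path output path.
#' @export
write_count_matrix <- function(run, path) {
  m <- run$counts
  m[run$missing] <- NA
  out <- data.frame(amplicon_id = rownames(m), m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
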