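#' Normalization configuration
#'
#' Collects the knobs of the normalization chain that turns raw amplicon
#' read counts into normalized read counts (NRC) with theoretical value 1
#' at two copies, 0.5 at a heterozygous deletion and 1.5 at a duplication.
#'
#' @param min_raw_reads raw counts below this are deleted (masked);
#'   default 20.
#' @param reference_fraction fraction of eligible amplicons retained as the
#'   stable reference set (lowest coefficient of variation across samples);
#'   default 0.10, at least one amplicon is always kept.
#' @param forced_reference_ids optional amplicon ids to use as the reference
#'   set instead of the automatic selection.
#' @param excluded_ids optional amplicon ids never used as references.
#' @param control_sample_ids optional sample ids of CNV-free controls; when
#'   given, median-ratio denominators come from the controls only.
#' @param include_self logical; include the sample itself in the cross-sample
#'   median denominator (default `TRUE`). With five or more samples the
#'   difference from self-exclusion is at most one rank.
#' @return A list of class `"normalization_config"`.
#' @export
normalization_config <- function(min_raw_reads = 20L,
                                 reference_fraction = 0.10,
                                 forced_reference_ids = NULL,
                                 excluded_ids = NULL,
                                 control_sample_ids = NULL,
                                 include_self = TRUE) {
  stopifnot(min_raw_reads >= 0, reference_fraction > 0, reference_fraction <= 1)
  if (length(intersect(forced_reference_ids, excluded_ids)))
    stop("forced_reference_ids and excluded_ids must be disjoint")
  structure(list(min_raw_reads = as.integer(min_raw_reads),
                 reference_fraction = reference_fraction,
                 forced_reference_ids = forced_reference_ids,
                 excluded_ids = excluded_ids,
                 control_sample_ids = control_sample_ids,
                 include_self = isTRUE(include_self)),
            class = "normalization_config")
}

#' Mask low-coverage cells
#'
#' Cells with raw counts below `min_raw_reads` are added to the missing
#' mask (counts themselves are unchanged). An amplicon missing in a strict
#' majority of the samples is then masked in all samples, so that
#' cross-sample medians stay meaningful.
#'
#' @param run a `"run_matrix"`.
#' @param min_raw_reads non-negative threshold; default 20.
#' @return The filtered `"run_matrix"`.
#' @export
filter_low_coverage <- function(run, min_raw_reads = 20L) {
  stopifnot(inherits(run, "run_matrix"), min_raw_reads >= 0)
  miss <- run$missing | (!is.na(run$counts) & run$counts < min_raw_reads)
  dropped <- rowMeans(miss) > 0.5
  miss[dropped, ] <- TRUE
  run$missing <- miss
  run
}

#' Primer-pool share normalization
#'
#' Each count becomes its share of the sample's total within the same
#' primer pool, removing library-size and pool-loading differences:
#' within every (sample, pool), the non-missing outputs sum to 1.
#'
#' @param run a `"run_matrix"` (typically after [filter_low_coverage()]).
#' @return Numeric matrix of pool shares, `NA` at missing cells.
#' @export
pool_normalize <- function(run) {
  stopifnot(inherits(run, "run_matrix"))
  counts <- run$counts
  counts[run$missing] <- NA
  out <- counts
  for (p in unique(run$design$pool)) {
    rows <- run$design$pool == p
    tot <- colSums(counts[rows, , drop = FALSE], na.rm = TRUE)
    nval <- colSums(!is.na(counts[rows, , drop = FALSE]))
    if (any(nval == 0))
      stop("all amplicons missing for sample ",
           run$sample_ids[which(nval == 0)[1]], " in pool ", p)
    if (any(tot <= 0))
      stop("zero total coverage for sample ",
           run$sample_ids[which(tot <= 0)[1]], " in pool ", p)
    out[rows, ] <- sweep(counts[rows, , drop = FALSE], 2, tot, `/`)
  }
  out
}

#' Select stable reference amplicons
#'
#' References are the amplicons most stable across the samples of a run:
#' the `reference_fraction` proportion (at least one) with the lowest
#' coefficient of variation (SD/mean across samples) of the pool-normalized
#' values, among amplicons non-missing in every sample and not excluded.
#' User-forced references short-circuit the selection.
#'
#' @param values pool-normalized matrix (from [pool_normalize()]).
#' @param design the [amplicon_design()].
#' @param cfg a [normalization_config()].
#' @return Character vector of reference amplicon ids.
#' @export
select_reference_amplicons <- function(values, design, cfg = normalization_config()) {
  if (!is.null(cfg$forced_reference_ids)) {
    bad <- setdiff(cfg$forced_reference_ids, design$id)
    if (length(bad)) stop("forced reference amplicon not in design: ", bad[1])
    return(setdiff(cfg$forced_reference_ids, cfg$excluded_ids))
  }
  if (ncol(values) < 2) stop("reference selection needs >= 2 samples")
  complete <- rowSums(is.na(values)) == 0
  eligible <- complete & !(design$id %in% cfg$excluded_ids)
  if (!any(eligible))
    stop("no amplicon is non-missing in every sample and unexcluded")
  v <- values[eligible, , drop = FALSE]
  cv <- apply(v, 1, stats::sd) / rowMeans(v)
  k <- max(1L, ceiling(cfg$reference_fraction * sum(eligible)))
  design$id[eligible][order(cv)[seq_len(k)]]
}

#' Scale each sample by its reference amplicons
#'
#' Divides every sample's column by the mean of that sample's reference
#' values, so that the per-sample mean over the references is exactly 1.
#'
#' @param values pool-normalized matrix.
#' @param design the [amplicon_design()].
#' @param refs reference amplicon ids (non-missing in every sample).
#' @return Rescaled matrix.
#' @export
reference_scale <- function(values, design, refs) {
  if (!length(refs)) stop("empty reference set")
  rows <- match(refs, design$id)
  if (anyNA(rows)) stop("reference amplicon not in design: ",
                        refs[which(is.na(rows))[1]])
  refv <- values[rows, , drop = FALSE]
  if (anyNA(refv)) {
    j <- which(colSums(is.na(refv)) > 0)[1]
    stop("reference amplicon missing in sample ", colnames(values)[j])
  }
  sweep(values, 2, colMeans(refv), `/`)
}

#' Cross-sample median ratio
#'
#' The last normalization step: each amplicon value is divided by the
#' median of the same amplicon across the run. Without controls the median
#' is taken over all samples whose cell is non-missing and whose exclusion
#' set (the two-stage mechanism) does not contain the amplicon; with
#' controls it is taken over the control samples only. Cells whose
#' denominator pool is empty, or whose denominator is zero, are masked.
#'
#' @param values reference-scaled matrix.
#' @param design the [amplicon_design()].
#' @param cfg a [normalization_config()].
#' @param exclusions optional named list (sample id -> amplicon ids removed
#'   from that sample's contribution to denominators).
#' @return A list of class `"nrc_matrix"`: `design`, `sample_ids`, `nrc`
#'   (matrix, `NA` at missing) and `missing`.
#' @export
median_ratio <- function(values, design, cfg = normalization_config(),
                         exclusions = NULL) {
  samples <- colnames(values)
  med_row <- function(x) if (any(ok <- !is.na(x))) stats::median(x[ok]) else NA_real_
  if (!is.null(cfg$control_sample_ids)) {
    bad <- setdiff(cfg$control_sample_ids, samples)
    if (length(bad)) stop("control sample not in run: ", bad[1])
    denom <- apply(values[, cfg$control_sample_ids, drop = FALSE], 1, med_row)
    nrc <- sweep(values, 1, denom, `/`)
  } else {
    if (ncol(values) < 2) stop("median ratio needs >= 2 samples (or controls)")
    pool <- values
    if (!is.null(exclusions)) {
      for (s in names(exclusions)) {
        rows <- match(intersect(exclusions[[s]], design$id), design$id)
        if (length(rows)) pool[rows, s] <- NA
      }
    }
    if (cfg$include_self) {
      denom <- apply(pool, 1, med_row)
      nrc <- sweep(values, 1, denom, `/`)
    } else {
      nrc <- values
      for (j in seq_along(samples)) {
        denom_j <- apply(pool[, -j, drop = FALSE], 1, med_row)
        nrc[, j] <- values[, j] / denom_j
      }
    }
  }
  nrc[!is.finite(nrc)] <- NA
  structure(list(design = design, sample_ids = samples, nrc = nrc,
                 missing = is.na(nrc)),
            class = "nrc_matrix")
}

#' @export
print.nrc_matrix <- function(x, ...) {
  cat(sprintf("nrc_matrix: %d amplicons x %d samples, median NRC %.3f\n",
              nrow(x$nrc), ncol(x$nrc), stats::median(x$nrc, na.rm = TRUE)))
  invisible(x)
}

#' Run the full normalization chain
#'
#' Low-coverage filtering, pool-share normalization, stable-reference
#' scaling, then the cross-sample median ratio. On a noiseless run with no
#' CNVs the resulting NRC is identically 1.
#'
#' @param run a `"run_matrix"`.
#' @param cfg a [normalization_config()].
#' @param exclusions optional per-sample exclusion list for the median
#'   ratio (see [median_ratio()]).
#' @return An `"nrc_matrix"` with attribute `"refs"` (the reference ids)
#'   and `"scaled"` (the pre-ratio matrix, reused by the two-stage caller).
#' @export
normalize_run <- function(run, cfg = normalization_config(), exclusions = NULL) {
  filtered <- filter_low_coverage(run, cfg$min_raw_reads)
  shares <- pool_normalize(filtered)
  refs <- select_reference_amplicons(shares, run$design, cfg)
  scaled <- reference_scale(shares, run$design, refs)
  out <- median_ratio(scaled, run$design, cfg, exclusions)
  attr(out, "refs") <- refs
  attr(out, "scaled") <- scaled
  out
}

#' Export / import an NRC matrix as TSV
#' @param nrc an `"nrc_matrix"`.
#' @param path output path; missing cells are written as empty fields.
#' @export
write_nrc <- function(nrc, path) {
  out <- data.frame(amplicon_id = rownames(nrc$nrc), nrc$nrc,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_nrc
#' @param design the matching [amplicon_design()].
#' @export
read_nrc <- function(path, design) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  m <- m[match(design$id, rownames(m)), , drop = FALSE]
  structure(list(design = design, sample_ids = colnames(m), nrc = m,
                 missing = is.na(m)),
            class = "nrc_matrix")
}
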