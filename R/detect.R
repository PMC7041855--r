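#' Detection configuration
#'
#' @param alpha one-tailed significance level for calling an amplicon
#'   deleted/duplicated (default 0.01; the z threshold is the standard
#'   normal quantile, about 2.326).
#' @param alpha_relax relaxed level applied to a single non-significant
#'   amplicon flanked by two CNV areas (default 0.05).
#' @param min_amplicons minimum number of successive significant amplicons
#'   on one chromosome required to call a CNV (default 3).
#' @param max_merge_distance optional maximum genomic gap in base pairs
#'   below which two same-direction CNVs are merged; unset by default
#'   (single-gap rule only).
#' @param two_stage recompute the median ratio excluding first-pass CNV
#'   amplicons before the final detection (default `TRUE`).
#' @return A list of class `"detection_config"`.
#' @export
detection_config <- function(alpha = 0.01, alpha_relax = 0.05,
                             min_amplicons = 3L, max_merge_distance = NULL,
                             two_stage = TRUE) {
  stopifnot(alpha > 0, alpha < alpha_relax, alpha_relax < 1, min_amplicons >= 1)
  structure(list(alpha = alpha, alpha_relax = alpha_relax,
                 min_amplicons = as.integer(min_amplicons),
                 max_merge_distance = max_merge_distance,
                 two_stage = isTRUE(two_stage)),
            class = "detection_config")
}

#' Per-sample z-scores
#'
#' Standardizes a sample's NRC values against the sample's own genome-wide
#' mean and population standard deviation: z_i = (NRC_i - mu_p) / sigma_p.
#' The non-missing output has mean 0 and population SD 1 exactly.
#'
#' @param x numeric NRC vector for one sample (`NA` = missing).
#' @return z vector of the same length; `NA` propagates.
#' @export
z_scores <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("z-scores need >= 2 non-missing values")
  mu <- mean(x[ok])
  sigma <- sqrt(mean((x[ok] - mu)^2))  # population SD
  if (sigma == 0) stop("zero variance sample")
  (x - mu) / sigma
}

#' Classify amplicons from z-scores
#'
#' One-tailed test against the standard normal: an amplicon is DEL when
#' `z <= qnorm(alpha)`, DUP when `z >= qnorm(1 - alpha)` (ties count as
#' significant), otherwise NEUTRAL; missing z gives MISSING.
#'
#' @param z z-score vector (`NA` = missing).
#' @param alpha one-tailed significance level in (0, 1).
#' @return Character vector of states `DEL`/`DUP`/`NEUTRAL`/`MISSING`.
#' @export
classify <- function(z, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  p <- stats::pnorm(-abs(z))  # tail probability in the sign's direction
  ifelse(is.na(z), "MISSING",
         ifelse(p <= alpha & z < 0, "DEL",
                ifelse(p <= alpha & z > 0, "DUP", "NEUTRAL")))
}

#' Per-amplicon status table for one sample
#'
#' @param design the [amplicon_design()].
#' @param nrc_row the sample's NRC vector aligned to the design.
#' @param alpha one-tailed significance level.
#' @return Data frame with columns `id`, `chrom`, `nrc`, `z`, `p`
#'   (one-tailed, in the z sign's direction), `state`.
#' @export
amplicon_status <- function(design, nrc_row, alpha = 0.01) {
  z <- z_scores(nrc_row)
  data.frame(id = design$id, chrom = design$chrom, nrc = nrc_row,
             z = z, p = stats::pnorm(-abs(z)), state = classify(z, alpha),
             stringsAsFactors = FALSE)
}

empty_calls <- function() {
  df <- data.frame(sample = character(), chrom = character(),
                   start = integer(), end = integer(),
                   direction = character(), n_amplicons = integer(),
                   mean_nrc = numeric(), merged = logical(),
                   stringsAsFactors = FALSE)
  df$amplicons <- list()
  df
}

make_call <- function(sample, design, idx, direction, merged, nrc_row) {
  data.frame(sample = sample, chrom = design$chrom[idx[1]],
             start = min(design$start[idx]), end = max(design$end[idx]),
             direction = direction, n_amplicons = length(idx),
             mean_nrc = mean(nrc_row[idx], na.rm = TRUE),
             merged = merged, amplicons = I(list(design$id[idx])),
             stringsAsFactors = FALSE)
}

#' Segment significant amplicons into CNV calls
#'
#' Maximal runs of successive same-direction significant amplicons on one
#' chromosome, of length at least `min_amplicons`, become calls. MISSING
#' amplicons are skipped transparently (they neither break a run nor count
#' toward its length); runs never span chromosomes.
#'
#' @param status an [amplicon_status()] table aligned to the design.
#' @param design the [amplicon_design()].
#' @param cfg a [detection_config()].
#' @param sample_id label recorded in the calls.
#' @return Calls data frame (one row per CNV; `amplicons` is a list column
#'   of supporting ids in design order).
#' @export
call_segments <- function(status, design, cfg = detection_config(),
                          sample_id = "sample") {
  calls <- empty_calls()
  for (ch in unique(design$chrom)) {
    idx <- which(design$chrom == ch & status$state != "MISSING")
    if (!length(idx)) next
    st <- status$state[idx]
    r <- rle(st)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] %in% c("DEL", "DUP") && r$lengths[k] >= cfg$min_amplicons) {
        calls <- rbind(calls,
                       make_call(sample_id, design, idx[starts[k]:ends[k]],
                                 r$values[k], FALSE, status$nrc))
      }
    }
  }
  rownames(calls) <- NULL
  calls
}

# one-tailed p of z in the call's direction
p_in_direction <- function(z, direction) {
  if (is.na(z)) return(NA_real_)
  if (direction == "DEL") stats::pnorm(z) else stats::pnorm(-z)
}

#' Merge CNV calls across single false-negative gaps
#'
#' Two same-direction calls on one chromosome disjointed by exactly one
#' non-missing amplicon are merged when that amplicon is significant in the
#' same direction at the relaxed level `alpha_relax`; the gap amplicon
#' joins the call with state `MERGED_GAP` (its display state stays
#' neutral). If `max_merge_distance` is set, same-direction calls whose
#' genomic gap does not exceed it are additionally merged. Both rules are
#' applied repeatedly until a fixed point.
#'
#' @param calls calls data frame from [call_segments()].
#' @param status the sample's [amplicon_status()] table.
#' @param design the [amplicon_design()].
#' @param cfg a [detection_config()].
#' @return A list: `calls` (merged) and `status` (with `MERGED_GAP`
#'   annotations).
#' @export
merge_segments <- function(calls, status, design, cfg = detection_config()) {
  repeat {
    if (nrow(calls) < 2) break
    o <- order(chrom_rank(calls$chrom), calls$start)
    calls <- calls[o, , drop = FALSE]
    merged_any <- FALSE
    for (i in seq_len(nrow(calls) - 1)) {
      a <- calls[i, ]; b <- calls[i + 1, ]
      if (a$chrom != b$chrom || a$direction != b$direction) next
      pos1 <- max(match(a$amplicons[[1]], design$id))
      pos2 <- min(match(b$amplicons[[1]], design$id))
      if (pos2 <= pos1) next
      between <- setdiff(seq(pos1, pos2), c(pos1, pos2))
      between <- between[status$state[between] != "MISSING"]
      gap_ok <- length(between) == 1 &&
        isTRUE(p_in_direction(status$z[between], a$direction) <= cfg$alpha_relax)
      dist_ok <- !is.null(cfg$max_merge_distance) &&
        (b$start - a$end - 1L) <= cfg$max_merge_distance
      if (gap_ok || dist_ok) {
        neutral <- between[!(status$state[between] %in% c("DEL", "DUP"))]
        status$state[neutral] <- "MERGED_GAP"
        idx <- sort(c(match(a$amplicons[[1]], design$id), between,
                      match(b$amplicons[[1]], design$id)))
        merged_call <- make_call(a$sample, design, idx, a$direction, TRUE,
                                 status$nrc)
        calls <- rbind(calls[-c(i, i + 1), , drop = FALSE], merged_call)
        merged_any <- TRUE
        break
      }
    }
    if (!merged_any) break
  }
  o <- order(chrom_rank(calls$chrom), calls$start)
  calls <- calls[o, , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls, status = status)
}

# full single-sample detection: z-scores, classification, segmentation, merge
detect_sample <- function(design, nrc_row, dcfg, sample_id) {
  status <- amplicon_status(design, nrc_row, dcfg$alpha)
  calls <- call_segments(status, design, dcfg, sample_id)
  merge_segments(calls, status, design, dcfg)
}

detect_all <- function(nrc, dcfg) {
  statuses <- list()
  calls <- empty_calls()
  for (j in seq_along(nrc$sample_ids)) {
    s <- nrc$sample_ids[j]
    res <- detect_sample(nrc$design, nrc$nrc[, j], dcfg, s)
    statuses[[s]] <- res$status
    calls <- rbind(calls, res$calls)
  }
  rownames(calls) <- NULL
  list(calls = calls, statuses = statuses)
}

#' Two-stage CNV detection on a run
#'
#' Stage 1 runs the full normalization chain and detection with empty
#' exclusions. The amplicons inside each sample's first-pass calls
#' (including merged gaps) are then removed from that sample's contribution
#' to the median-ratio denominators, the ratio is recomputed, and detection
#' runs once more (exactly two stages). This de-biases regions where many
#' samples of the run share the same event. In control mode the
#' denominators already come from CNV-free controls only, so stage 2 is
#' skipped.
#'
#' @param run a `"run_matrix"`.
#' @param ncfg a [normalization_config()].
#' @param dcfg a [detection_config()].
#' @return A list of class `"cnv_result"`: `calls` (all samples), `statuses`
#'   (named list of per-sample status tables), `nrc` (final
#'   `"nrc_matrix"`), and `stage1` (first-pass calls, for inspection).
#' @export
two_stage_detect <- function(run, ncfg = normalization_config(),
                             dcfg = detection_config()) {
  nrc1 <- normalize_run(run, ncfg)
  det1 <- detect_all(nrc1, dcfg)
  skip2 <- !dcfg$two_stage || !is.null(ncfg$control_sample_ids)
  if (skip2) {
    out <- list(calls = det1$calls, statuses = det1$statuses, nrc = nrc1,
                stage1 = det1$calls)
    class(out) <- "cnv_result"
    return(out)
  }
  exclusions <- lapply(split(det1$calls, det1$calls$sample),
                       function(d) unique(unlist(d$amplicons)))
  nrc2 <- median_ratio(attr(nrc1, "scaled"), run$design, ncfg, exclusions)
  det2 <- detect_all(nrc2, dcfg)
  out <- list(calls = det2$calls, statuses = det2$statuses, nrc = nrc2,
              stage1 = det1$calls)
  class(out) <- "cnv_result"
  out
}

#' @export
print.cnv_result <- function(x, ...) {
  cat(sprintf("cnv_result: %d call(s) in %d sample(s)\n",
              nrow(x$calls), length(x$statuses)))
  if (nrow(x$calls))
    print(x$calls[, c("sample", "chrom", "start", "end", "direction",
                      "n_amplicons", "mean_nrc", "merged")], ...)
  invisible(x)
}
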