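#' CUSUM diagnostic track
#'
#' Cumulative-sum control chart of a sample's NRC values, highlighting
#' sustained small shifts (subclonal CNVs, mosaicism) that individual
#' z-scores miss. With xbar and sigma the mean and population SD over all
#' the patient's non-missing amplicons (genome-wide, the same moments as
#' the z-scores), each chromosome accumulates
#' \deqn{S^+_n = \max(0, S^+_{n-1} + x_n - (\bar x + \sigma))}
#' \deqn{S^-_n = \min(0, S^-_{n-1} + x_n - (\bar x - \sigma))}
#' starting from 0 at the chromosome's first amplicon; missing amplicons
#' are skipped. A sustained negative `s_minus` excursion marks a candidate
#' deletion; a sustained positive `s_plus` marks a duplication. The track
#' is a pure diagnostic output and never feeds the automated caller.
#'
#' @param nrc_row the sample's NRC vector aligned to the design.
#' @param design the [amplicon_design()].
#' @return Data frame (class `"cusum_track"`) over the non-missing
#'   amplicons: `id`, `chrom`, `pos` (amplicon start), `s_plus`, `s_minus`.
#' @export
cusum_track <- function(nrc_row, design) {
  ok <- !is.na(nrc_row)
  if (sum(ok) < 2) stop("CUSUM needs >= 2 non-missing amplicons")
  xbar <- mean(nrc_row[ok])
  sigma <- sqrt(mean((nrc_row[ok] - xbar)^2))
  if (sigma == 0) stop("zero variance sample")
  out <- data.frame(id = design$id[ok], chrom = design$chrom[ok],
                    pos = design$start[ok], s_plus = 0, s_minus = 0,
                    stringsAsFactors = FALSE)
  x <- nrc_row[ok]
  for (ch in unique(out$chrom)) {
    i <- which(out$chrom == ch)
    sp <- 0; sm <- 0
    for (k in seq_along(i)) {
      sp <- max(0, sp + x[i[k]] - (xbar + sigma))
      sm <- min(0, sm + x[i[k]] - (xbar - sigma))
      out$s_plus[i[k]] <- sp
      out$s_minus[i[k]] <- sm
    }
  }
  class(out) <- c("cusum_track", "data.frame")
  out
}

#' Loess diagnostic track
#'
#' Locally weighted linear regression (tricube weights, degree 1, a single
#' pass with no robustness iterations) of values against genomic position,
#' evaluated at each input position. The bandwidth is the fraction of the
#' points entering each local window; the span is clamped from below so
#' that every window holds at least three points.
#'
#' @param positions numeric genomic positions of one chromosome's
#'   non-missing amplicons.
#' @param values NRC values at those positions.
#' @param bandwidth span in (0, 1]; default 0.25.
#' @return Data frame (class `"loess_track"`) with `pos` and `fitted`, or
#'   `NULL` with a warning when fewer than three points are given.
#' @export
loess_track <- function(positions, values, bandwidth = 0.25) {
  stopifnot(bandwidth > 0, bandwidth <= 1)
  ok <- !is.na(values) & !is.na(positions)
  positions <- positions[ok]; values <- values[ok]
  n <- length(positions)
  if (n < 3) {
    warning("fewer than 3 points; Loess track omitted")
    return(NULL)
  }
  span <- max(bandwidth, min(1, 3 / n))
  fit <- stats::loess(values ~ positions, degree = 1, span = span,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  out <- data.frame(pos = positions, fitted = stats::predict(fit))
  attr(out, "bandwidth") <- bandwidth
  class(out) <- c("loess_track", "data.frame")
  out
}

#' Per-sample diagnostic track table
#'
#' Assembles, for one sample, the NRC, per-chromosome Loess fit and CUSUM
#' series into a single table, matching the `tracks` export layout.
#'
#' @param nrc an `"nrc_matrix"`.
#' @param sample_id sample to extract.
#' @param bandwidth Loess bandwidth (default 0.25).
#' @return Data frame: `amplicon_id`, `chromosome`, `position`, `nrc`,
#'   `loess`, `s_plus`, `s_minus` (non-missing amplicons only).
#' @export
sample_tracks <- function(nrc, sample_id, bandwidth = 0.25) {
  j <- match(sample_id, nrc$sample_ids)
  if (is.na(j)) stop("unknown sample: ", sample_id)
  x <- nrc$nrc[, j]
  cus <- cusum_track(x, nrc$design)
  out <- data.frame(amplicon_id = cus$id, chromosome = cus$chrom,
                    position = cus$pos, nrc = x[!is.na(x)],
                    loess = NA_real_, s_plus = cus$s_plus,
                    s_minus = cus$s_minus, stringsAsFactors = FALSE)
  for (ch in unique(out$chromosome)) {
    i <- which(out$chromosome == ch)
    lt <- tryCatch(loess_track(out$position[i], out$nrc[i], bandwidth),
                   warning = function(w) NULL)
    if (!is.null(lt)) out$loess[i] <- lt$fitted
  }
  out
}
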