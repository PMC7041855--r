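# Desk-scale validation experiments: synthetic reconstructions of the
# benchmark layouts the caller is expected to reproduce. Shared by the
# acceptance test suite and scripts/acceptance.R.

#' The 22 positive-control CNV profiles of the germline benchmark
#'
#' Per-event amplicon counts, carrier sample and direction of the 22
#' validated germline CNVs (gains and losses over genes covered by 4 to 98
#' amplicons), distributed over 11 sequencing runs of 16 samples. Used to
#' rebuild the germline sensitivity experiment on synthetic runs.
#'
#' @return Data frame with columns `run` (1--11), `sample` (e.g. "S03"),
#'   `n_amplicons`, `type` ("Gain"/"Loss"). 461 amplicons in total.
#' @export
germline_validation_events <- function() {
  df <- data.frame(
    run = c(1, 1, 1, 2, 2, 3, 4, 4, 5, 5, 5, 6, 6, 7, 7, 8, 9, 10, 10, 11, 11, 11),
    sample = sprintf("S%02d", c(3, 8, 9, 2, 15, 3, 4, 12, 3, 15, 16, 2, 9, 2,
                                6, 8, 6, 10, 16, 8, 14, 15)),
    n_amplicons = c(10L, 58L, 98L, 25L, 25L, 58L, 4L, 58L, 25L, 10L, 10L, 10L,
                    4L, 4L, 10L, 10L, 10L, 7L, 4L, 10L, 4L, 7L),
    type = c("Gain", "Gain", "Gain", "Gain", "Loss", "Gain", "Gain", "Gain",
             "Gain", "Gain", "Loss", "Gain", "Gain", "Gain", "Gain", "Loss",
             "Loss", "Gain", "Gain", "Gain", "Gain", "Gain"),
    stringsAsFactors = FALSE)
  stopifnot(sum(df$n_amplicons) == 461L)
  df
}

#' Low-cell-fraction dilution experiment
#'
#' One 16-sample, 2,394-amplicon synthetic run (noise CV 5%); an
#' 80-amplicon gene is fully deleted in one sample at the given
#' cancer-cell fraction via the dilution model, and the default two-stage
#' pipeline is run. Reports how many of the gene's amplicons come out in
#' state DEL for the carrier.
#'
#' @param seed integer seed for the synthetic run.
#' @param fraction cancer-cell fraction (default 0.60).
#' @return List: `n_flagged`, `n_region` (80), `called` (any overlapping
#'   DEL call).
#' @export
experiment_dilution <- function(seed = 1L, fraction = 0.60) {
  design <- sim_design()
  run <- simulate_run(simulation_spec(n_samples = 16L, design = design,
                                      noise_cv = 0.05, seed = seed))
  region <- gene_amplicons(design, genes_with_size(design, 80)[1])
  carrier <- "S01"
  run <- apply_cnv(run, cnv_event(carrier, region, 1L, fraction))
  res <- two_stage_detect(run)
  st <- res$statuses[[carrier]]
  rows <- match(region, design$id)
  calls <- res$calls
  list(n_flagged = sum(st$state[rows] == "DEL"),
       n_region = length(region),
       called = any(calls$sample == carrier & calls$direction == "DEL" &
                      calls$chrom == design$chrom[rows[1]] &
                      calls$start <= max(design$end[rows]) &
                      calls$end >= min(design$start[rows])))
}

#' Null-cohort specificity experiment
#'
#' A synthetic cohort with no CNVs (2,394 amplicons, noise CV 5%),
#' processed in 16-sample batches through the default pipeline. Over a
#' designated 10-amplicon gene, the fraction of (amplicon, sample) cells
#' not inside any call is the per-amplicon specificity.
#'
#' @param seed integer master seed; each batch derives its own.
#' @param n_total cohort size (default 456 samples).
#' @param batch_size samples per run (default 16).
#' @return List: `specificity`, `n_cells`, `false_cells`.
#' @export
experiment_null_specificity <- function(seed = 1L, n_total = 456L,
                                        batch_size = 16L) {
  design <- sim_design()
  gene <- genes_with_size(design, 10)[1]
  region <- gene_amplicons(design, gene)
  rows <- match(region, design$id)
  lo <- min(design$start[rows]); hi <- max(design$end[rows])
  chrom <- design$chrom[rows[1]]
  sizes <- rep(batch_size, n_total %/% batch_size)
  if (n_total %% batch_size) sizes <- c(sizes, n_total %% batch_size)
  false_cells <- 0L
  for (b in seq_along(sizes)) {
    run <- simulate_run(simulation_spec(n_samples = sizes[b], design = design,
                                        noise_cv = 0.05,
                                        seed = seed * 1000L + b))
    res <- two_stage_detect(run)
    calls <- res$calls
    overlapping <- calls[calls$chrom == chrom & calls$start <= hi &
                           calls$end >= lo, , drop = FALSE]
    if (nrow(overlapping))
      for (k in seq_len(nrow(overlapping)))
        false_cells <- false_cells +
          sum(overlapping$amplicons[[k]] %in% region)
  }
  n_cells <- length(region) * n_total
  list(specificity = (n_cells - false_cells) / n_cells,
       n_cells = n_cells, false_cells = false_cells)
}

#' Germline sensitivity experiment
#'
#' Rebuilds the 22-event germline benchmark on synthetic data: 11
#' simulated 16-sample runs (2,394 amplicons, noise CV 5%) carrying the
#' [germline_validation_events()] at germline ratios (copy number 1 for a
#' loss, 3 for a gain, fraction 1), each event on a gene with the matching
#' amplicon count. The default two-stage pipeline is run
#' per run; amplicon-level sensitivity pools correct-direction flagged
#' amplicons over all events.
#'
#' @param seed integer master seed; each run derives its own.
#' @return List: `sensitivity`, `n_amplicons` (461), `detected_amplicons`,
#'   `events_detected` (events overlapped by a correct-direction call),
#'   `n_events` (22).
#' @export
experiment_germline <- function(seed = 1L) {
  design <- sim_design()
  events <- germline_validation_events()
  events$gene <- vapply(events$n_amplicons,
                        function(k) genes_with_size(design, k)[1], "")
  detected <- 0L
  events_hit <- 0L
  for (r in unique(events$run)) {
    ev <- events[events$run == r, , drop = FALSE]
    run <- simulate_run(simulation_spec(n_samples = 16L, design = design,
                                        noise_cv = 0.05,
                                        seed = seed * 100L + r))
    for (k in seq_len(nrow(ev)))
      run <- apply_cnv(run, cnv_event(ev$sample[k],
                                      gene_amplicons(design, ev$gene[k]),
                                      if (ev$type[k] == "Gain") 3L else 1L, 1))
    res <- two_stage_detect(run)
    for (k in seq_len(nrow(ev))) {
      region <- gene_amplicons(design, ev$gene[k])
      rows <- match(region, design$id)
      want <- if (ev$type[k] == "Gain") "DUP" else "DEL"
      st <- res$statuses[[ev$sample[k]]]
      detected <- detected + sum(st$state[rows] == want)
      calls <- res$calls
      hit <- any(calls$sample == ev$sample[k] & calls$direction == want &
                   calls$chrom == design$chrom[rows[1]] &
                   calls$start <= max(design$end[rows]) &
                   calls$end >= min(design$start[rows]))
      events_hit <- events_hit + hit
    }
  }
  n <- sum(events$n_amplicons)
  list(sensitivity = detected / n, n_amplicons = n,
       detected_amplicons = detected, events_detected = events_hit,
       n_events = nrow(events))
}
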