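#' Synthetic panel design
#'
#' Builds a deterministic amplicon design that mimics a multiplex amplicon
#' panel: genes of the given sizes laid out contiguously, spread over
#' chromosomes, amplicons alternating between two primer pools, 250 bp
#' amplicons spaced 1 kb apart.
#'
#' @param gene_sizes integer vector: amplicons per gene, in gene order.
#'   The default, [default_gene_sizes()], mirrors a 2,394-amplicon,
#'   89-gene clinical panel and contains one gene of each size needed by
#'   the validation experiments (98, 80, 58, 25, 10, 7, 4).
#' @param n_chrom number of chromosomes the genes are spread over
#'   (default 23: chr1..chr22 and chrX, which receives the last genes).
#' @param n_pools number of primer pools (default 2, alternating).
#' @return An [amplicon_design()].
#' @export
sim_design <- function(gene_sizes = default_gene_sizes(), n_chrom = 23L,
                       n_pools = 2L) {
  stopifnot(all(gene_sizes >= 1), n_chrom >= 1, n_pools >= 1)
  g <- length(gene_sizes)
  chrom_names <- c(paste0("chr", 1:22), "chrX", "chrY")[seq_len(n_chrom)]
  gene_chrom <- chrom_names[ceiling(seq_len(g) / ceiling(g / n_chrom))]
  id <- character(0); chrom <- character(0); start <- integer(0)
  gene <- character(0); pool <- integer(0)
  offset <- stats::setNames(rep(0L, n_chrom), chrom_names)
  for (k in seq_len(g)) {
    nk <- gene_sizes[k]
    ch <- gene_chrom[k]
    gname <- sprintf("GENE%03d", k)
    s <- offset[ch] + 10000L + (seq_len(nk) - 1L) * 1000L
    offset[ch] <- offset[ch] + 10000L + nk * 1000L
    id <- c(id, sprintf("%s_a%02d", gname, seq_len(nk)))
    chrom <- c(chrom, rep(ch, nk)); start <- c(start, s)
    gene <- c(gene, rep(gname, nk))
    pool <- c(pool, (seq_along(s) - 1L) %% n_pools + 1L)
  }
  amplicon_design(id, chrom, start, start + 249L, gene, pool)
}

#' @rdname sim_design
#' @export
default_gene_sizes <- function() {
  special <- c(4L, 7L, 10L, 25L, 58L, 80L)
  filler <- c(rep(26L, 62), rep(25L, 20))
  # interleave the specials among the fillers; the 98-amplicon gene goes
  # last so it lands on chrX (a whole-chromosome-X duplication target)
  chunk <- cut(seq_along(filler), 6, labels = FALSE)
  sizes <- integer(0)
  for (k in 1:6) sizes <- c(sizes, special[k], filler[chunk == k])
  sizes <- c(sizes, 98L)
  stopifnot(sum(sizes) == 2394L, length(sizes) == 89L)
  sizes
}

#' Simulation specification
#'
#' The stated world of the synthetic generator: per-sample library sizes,
#' shared per-amplicon efficiencies, multiplicative cell-level noise and
#' optional Poisson count sampling.
#'
#' @param n_samples number of samples in the run (default 16, the size of
#'   the germline panel runs being emulated).
#' @param design an [amplicon_design()]; default [sim_design()].
#' @param library_size_range range of the per-sample mean amplicon depth,
#'   drawn uniformly (default 500--2000 reads).
#' @param amplicon_efficiency_sd log-scale SD of the per-amplicon
#'   multiplicative efficiency, shared across samples (default 0.5;
#'   amplification efficiency in multiplex PCR varies several-fold).
#' @param noise_cv per-cell multiplicative coefficient of variation
#'   (log-normal; default 0.05).
#' @param count_noise `"none"` (default) or `"poisson"` for an additional
#'   Poisson sampling layer.
#' @param seed RNG seed; identical spec + seed gives identical matrices.
#' @return A list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_samples = 16L, design = sim_design(),
                            library_size_range = c(500, 2000),
                            amplicon_efficiency_sd = 0.5,
                            noise_cv = 0.05,
                            count_noise = c("none", "poisson"),
                            seed = 1L) {
  stopifnot(n_samples >= 1, noise_cv >= 0, amplicon_efficiency_sd >= 0,
            all(library_size_range > 0))
  structure(list(n_samples = as.integer(n_samples), design = design,
                 library_size_range = library_size_range,
                 amplicon_efficiency_sd = amplicon_efficiency_sd,
                 noise_cv = noise_cv,
                 count_noise = match.arg(count_noise),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a sequencing run
#'
#' Counts are `round(library_size_j * efficiency_i * noise_ij)` with
#' mean-one log-normal noise of the requested CV, optionally followed by
#' Poisson sampling. With all noise off, every column is proportional to a
#' constant vector, so the normalization chain returns NRC identically 1.
#'
#' @param spec a [simulation_spec()].
#' @return A `"run_matrix"`.
#' @export
simulate_run <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- nrow(spec$design); s <- spec$n_samples
  eff <- exp(stats::rnorm(n, 0, spec$amplicon_efficiency_sd))
  lib <- stats::runif(s, spec$library_size_range[1], spec$library_size_range[2])
  mu <- outer(eff, lib)
  if (spec$noise_cv > 0) {
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    mu <- mu * matrix(stats::rlnorm(n * s, -sdlog^2 / 2, sdlog), n, s)
  }
  counts <- if (spec$count_noise == "poisson")
    matrix(stats::rpois(n * s, mu), n, s) else round(mu)
  dimnames(counts) <- list(spec$design$id, sprintf("S%02d", seq_len(s)))
  structure(list(design = spec$design, sample_ids = colnames(counts),
                 counts = counts, missing = matrix(FALSE, n, s,
                   dimnames = dimnames(counts))),
            class = "run_matrix")
}

#' A CNV event to inject
#'
#' @param sample_id carrier sample.
#' @param amplicon_ids contiguous amplicon ids of the region, all on one
#'   chromosome.
#' @param copy_number integer total copy number (not 2; 1 = heterozygous
#'   deletion, 3 = duplication, 0 = homozygous loss).
#' @param fraction cancer-cell fraction in [0, 1]; 1 is the germline /
#'   clonal case.
#' @return A list of class `"cnv_event"`.
#' @export
cnv_event <- function(sample_id, amplicon_ids, copy_number, fraction = 1) {
  stopifnot(length(amplicon_ids) >= 1, copy_number >= 0, copy_number != 2,
            fraction >= 0, fraction <= 1)
  structure(list(sample_id = sample_id,
                 amplicon_ids = as.character(amplicon_ids),
                 copy_number = as.integer(copy_number), fraction = fraction),
            class = "cnv_event")
}

#' Inject a CNV into a run by the cell-fraction dilution model
#'
#' Each raw count in the region becomes the simulated read count
#' `SRC = RRC * (1 - f) + RRC * (c/2) * f`, rounded half-up to an integer:
#' a mixture of normal cells (two copies) and a fraction f of cells at
#' copy number c. `f = 1` gives the germline case (counts scaled by c/2).
#' Counts outside the region are untouched.
#'
#' @param run a `"run_matrix"`.
#' @param event a [cnv_event()].
#' @return The modified `"run_matrix"`.
#' @export
apply_cnv <- function(run, event) {
  stopifnot(inherits(run, "run_matrix"), inherits(event, "cnv_event"))
  rows <- match(event$amplicon_ids, run$design$id)
  if (anyNA(rows)) stop("event amplicon not in design: ",
                        event$amplicon_ids[which(is.na(rows))[1]])
  if (length(unique(run$design$chrom[rows])) > 1)
    stop("event region crosses chromosomes")
  j <- match(event$sample_id, run$sample_ids)
  if (is.na(j)) stop("unknown sample: ", event$sample_id)
  f <- event$fraction
  factor <- (1 - f) + (event$copy_number / 2) * f
  run$counts[rows, j] <- floor(run$counts[rows, j] * factor + 0.5)
  run
}

#' Helper: amplicon ids of a gene
#' @param design an [amplicon_design()].
#' @param gene gene label.
#' @return Character vector of the gene's amplicon ids in design order.
#' @export
gene_amplicons <- function(design, gene) {
  ids <- design$id[design$gene == gene]
  if (!length(ids)) stop("unknown gene: ", gene)
  ids
}

#' Helper: genes with exactly k amplicons
#' @param design an [amplicon_design()].
#' @param k amplicon count.
#' @return Character vector of gene labels (design order).
#' @export
genes_with_size <- function(design, k) {
  tab <- table(design$gene)[unique(design$gene)]
  names(tab)[tab == k]
}

#' Cancer-cell-fraction dilution sweep
#'
#' Emulates the minimum-detectable-fraction experiment: for each fraction,
#' a single-copy deletion of the region is injected into a copy of the run
#' at that cancer-cell fraction, the full two-stage pipeline is run, and
#' detection evidence is summarised.
#'
#' @param run the baseline `"run_matrix"` (no CNV in the region).
#' @param region amplicon ids of the deleted gene.
#' @param sample_id carrier sample.
#' @param fractions cancer-cell fractions; default 0 to 1 in steps of 0.05.
#' @param ncfg,dcfg pipeline configuration.
#' @return Data frame with one row per fraction: `fraction`,
#'   `n_del_amplicons` (region amplicons in state DEL for the carrier),
#'   `called` (any DEL call overlapping the region), `max_s_minus`
#'   (maximum |S-| of the carrier's CUSUM over the region).
#' @export
dilution_sweep <- function(run, region, sample_id,
                           fractions = seq(0, 1, by = 0.05),
                           ncfg = normalization_config(),
                           dcfg = detection_config()) {
  rows <- match(region, run$design$id)
  chrom <- unique(run$design$chrom[rows])
  lo <- min(run$design$start[rows]); hi <- max(run$design$end[rows])
  out <- data.frame(fraction = fractions, n_del_amplicons = NA_integer_,
                    called = NA, max_s_minus = NA_real_)
  for (r in seq_along(fractions)) {
    f <- fractions[r]
    run_f <- if (f > 0)
      apply_cnv(run, cnv_event(sample_id, region, 1L, f)) else run
    res <- two_stage_detect(run_f, ncfg, dcfg)
    st <- res$statuses[[sample_id]]
    out$n_del_amplicons[r] <- sum(st$state[rows] == "DEL", na.rm = TRUE)
    cc <- res$calls
    out$called[r] <- any(cc$sample == sample_id & cc$direction == "DEL" &
                           cc$chrom == chrom & cc$start <= hi & cc$end >= lo)
    cus <- cusum_track(res$nrc$nrc[, sample_id], run$design)
    inside <- cus$id %in% region
    out$max_s_minus[r] <- if (any(inside)) max(abs(cus$s_minus[inside])) else 0
  }
  out
}
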