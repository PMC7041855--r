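test_that("z_scores standardizes with the population SD", {
  z <- z_scores(c(0.8, 1.2))
  expect_equal(z, c(-1, 1))                     # mu = 1, popSD = 0.2
  expect_error(z_scores(rep(1, 5)), "zero variance")
  expect_error(z_scores(c(1, NA)), ">= 2 non-missing")

  # standardization identity on arbitrary input, NA propagation
  set.seed(2)
  x <- rlnorm(50); x[c(3, 17)] <- NA
  z <- z_scores(x)
  expect_true(all(is.na(z[c(3, 17)])))
  ok <- !is.na(z)
  expect_equal(mean(z[ok]), 0)
  expect_equal(sqrt(mean(z[ok]^2)), 1)
})

test_that("classify applies the one-tailed threshold in the z sign direction", {
  # qnorm(0.99) = 2.3263 < 2.40; qnorm(0.999) = 3.09 > 2.40
  expect_equal(classify(-2.40, 0.01), "DEL")
  expect_equal(classify(-2.40, 0.001), "NEUTRAL")
  expect_equal(classify(2.40, 0.01), "DUP")
  expect_equal(classify(0, 0.49), "NEUTRAL")
  expect_equal(classify(NA_real_), "MISSING")
  # the threshold itself is significant (<=, up to floating point)
  expect_equal(classify(stats::qnorm(0.01) - 1e-9, 0.01), "DEL")
  expect_equal(classify(stats::qnorm(0.01) + 1e-6, 0.01), "NEUTRAL")
})

test_that("call_segments keeps runs of min length on one chromosome", {
  d3 <- tiny_design(3)
  cfg <- detection_config()
  st <- status_from_states(d3, rep("DEL", 3))
  calls <- call_segments(st, d3, cfg, "s")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$direction, "DEL")
  expect_equal(calls$n_amplicons, 3L)
  expect_equal(calls$start, d3$start[1])
  expect_equal(calls$end, d3$end[3])

  st2 <- status_from_states(d3, c("DEL", "DEL", "NEUTRAL"))
  expect_equal(nrow(call_segments(st2, d3, cfg, "s")), 0)

  # same states split over chromosomes never form one call
  dsplit <- multi_design(c(1, 1, 1), chroms = c("chr1", "chr2", "chr1"))
  st3 <- status_from_states(dsplit, rep("DEL", 3))
  expect_equal(nrow(call_segments(st3, dsplit, cfg, "s")), 0)

  # MISSING amplicons are skipped transparently
  d5 <- tiny_design(5)
  st4 <- status_from_states(d5, c("DEL", "MISSING", "DEL", "MISSING", "DEL"))
  calls4 <- call_segments(st4, d5, cfg, "s")
  expect_equal(nrow(calls4), 1)
  expect_equal(calls4$n_amplicons, 3L)
  expect_equal(calls4$amplicons[[1]], d5$id[c(1, 3, 5)])
})

test_that("call_segments agrees with the brute-force window oracle", {
  set.seed(31)
  cfg <- detection_config(min_amplicons = 3)
  for (rep in 1:25) {
    n <- sample(10:60, 1)
    d <- multi_design(c(ceiling(n / 2), floor(n / 2)))
    states <- sample(c("DEL", "DUP", "NEUTRAL", "MISSING"), n, replace = TRUE,
                     prob = c(0.3, 0.3, 0.3, 0.1))
    st <- status_from_states(d, states)
    got <- call_segments(st, d, cfg, "s")
    want <- oracle_segments(states, d$chrom, cfg$min_amplicons)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      want_ids <- lapply(want, function(w) d$id[w$ids])
      got_ids <- got$amplicons
      expect_setequal(vapply(got_ids, paste, "", collapse = ","),
                      vapply(want_ids, paste, "", collapse = ","))
    }
  }
})

test_that("merge_segments bridges a single relaxed-significant gap", {
  d <- tiny_design(7)
  cfg <- detection_config()
  mk <- function(zgap) {
    states <- c(rep("DEL", 3), "NEUTRAL", rep("DEL", 3))
    z <- c(rep(-3, 3), zgap, rep(-3, 3))
    st <- status_from_states(d, states, z)
    calls <- call_segments(st, d, cfg, "s")
    merge_segments(calls, st, d, cfg)
  }
  # p = pnorm(-1.8) = 0.036 <= 0.05 -> merged into one 7-amplicon call
  res <- mk(-1.8)
  expect_equal(nrow(res$calls), 1)
  expect_equal(res$calls$n_amplicons, 7L)
  expect_true(res$calls$merged)
  expect_equal(res$status$state[4], "MERGED_GAP")

  # p = pnorm(-1.0) = 0.159 > 0.05 -> stays two calls
  res2 <- mk(-1.0)
  expect_equal(nrow(res2$calls), 2)
  expect_false(any(res2$calls$merged))

  # a gap significant in the WRONG direction never merges
  res3 <- mk(+3)
  expect_equal(nrow(res3$calls), 2)
})

test_that("merge_segments never merges opposite directions, honors distance", {
  d <- tiny_design(7)
  cfg <- detection_config()
  states <- c(rep("DEL", 3), "NEUTRAL", rep("DUP", 3))
  z <- c(rep(-3, 3), -1.8, rep(3, 3))
  st <- status_from_states(d, states, z)
  calls <- call_segments(st, d, cfg, "s")
  expect_equal(nrow(merge_segments(calls, st, d, cfg)$calls), 2)

  # distance rule: gap amplicon not significant, but calls within range
  cfg_d <- detection_config(max_merge_distance = 10000)
  states2 <- c(rep("DEL", 3), "NEUTRAL", rep("DEL", 3))
  z2 <- c(rep(-3, 3), 0, rep(-3, 3))
  st2 <- status_from_states(d, states2, z2)
  calls2 <- call_segments(st2, d, cfg_d, "s")
  res <- merge_segments(calls2, st2, d, cfg_d)
  expect_equal(nrow(res$calls), 1)
  expect_true(res$calls$merged)
})

test_that("merging reaches a fixed point over chains of calls", {
  # DEL(3) gap DEL(3) gap DEL(3): both gaps relaxed-significant -> one call
  d <- tiny_design(11)
  cfg <- detection_config()
  states <- c(rep("DEL", 3), "NEUTRAL", rep("DEL", 3), "NEUTRAL", rep("DEL", 3))
  z <- ifelse(states == "DEL", -3, -2)          # pnorm(-2) = 0.023 <= 0.05
  st <- status_from_states(d, states, z)
  calls <- call_segments(st, d, cfg, "s")
  expect_equal(nrow(calls), 3)
  res <- merge_segments(calls, st, d, cfg)
  expect_equal(nrow(res$calls), 1)
  expect_equal(res$calls$n_amplicons, 11L)

  # random property: merging never increases the call count, never mixes
  # directions, and a second application changes nothing (fixed point)
  set.seed(77)
  for (rep in 1:20) {
    n <- 40
    dr <- tiny_design(n)
    z <- rnorm(n, 0, 2)
    stt <- status_from_states(dr, classify(z, 0.01), z)
    cl <- call_segments(stt, dr, cfg, "s")
    m1 <- merge_segments(cl, stt, dr, cfg)
    expect_lte(nrow(m1$calls), max(nrow(cl), 0))
    expect_true(all(!duplicated(unlist(m1$calls$amplicons))))
    m2 <- merge_segments(m1$calls, m1$status, dr, cfg)
    expect_equal(nrow(m2$calls), nrow(m1$calls))
    expect_equal(m2$calls$start, m1$calls$start)
  }
})

test_that("two_stage_detect removes shared-event bias (stage-2 contract)", {
  # 7 samples, 39 of 120 amplicons deleted in 3 of them: stage 1 biases the
  # median at those amplicons; stage 2 must clear non-carrier duplications
  # and keep a deletion call in every carrier
  d <- multi_design(c(39, 150, 150, 150),
                    chroms = c("chr13", "chr1", "chr2", "chr3"))
  spec <- simulation_spec(n_samples = 7, design = d, noise_cv = 0.05, seed = 13)
  run <- simulate_run(spec)
  region <- gene_amplicons(d, "G1")
  carriers <- c("S01", "S02", "S03")
  for (s in carriers) run <- apply_cnv(run, cnv_event(s, region, 1L, 1))
  res <- two_stage_detect(run, normalization_config(), detection_config())
  calls <- res$calls
  non_carrier_dup <- calls[calls$direction == "DUP" &
                             !(calls$sample %in% carriers) &
                             calls$chrom == "chr13", ]
  expect_equal(nrow(non_carrier_dup), 0)
  for (s in carriers)
    expect_true(any(calls$sample == s & calls$direction == "DEL" &
                      calls$chrom == "chr13"))
})

test_that("two_stage is a no-op without CNVs and for a lone carrier", {
  d <- multi_design(c(100, 100), chroms = c("chr1", "chr2"))
  spec <- simulation_spec(n_samples = 8, design = d, noise_cv = 0.05, seed = 4)
  run <- simulate_run(spec)
  res <- two_stage_detect(run)
  expect_equal(nrow(res$calls), nrow(res$stage1))

  # one carrier among 8: the median over >= 7 clean samples is unchanged by
  # excluding the carrier, so both stages call identically
  region <- gene_amplicons(d, "G2")[1:10]
  run2 <- apply_cnv(run, cnv_event("S05", region, 1L, 1))
  res2 <- two_stage_detect(run2)
  key <- function(df) df[order(df$sample, df$chrom, df$start),
                         c("sample", "chrom", "start", "end", "direction")]
  expect_equal(key(res2$calls), key(res2$stage1), ignore_attr = TRUE)
  expect_true(any(res2$calls$sample == "S05" & res2$calls$direction == "DEL"))
})

test_that("control mode uses control denominators and skips stage 2", {
  d <- multi_design(c(20, 60, 60, 60),
                    chroms = c("chr1", "chr2", "chr3", "chr4"))
  spec <- simulation_spec(n_samples = 7, design = d, noise_cv = 0.05, seed = 19)
  run <- simulate_run(spec)
  region <- gene_amplicons(d, "G1")
  # 4 of 7 carry the deletion; only 3 controls are clean
  for (s in c("S01", "S02", "S03", "S04"))
    run <- apply_cnv(run, cnv_event(s, region, 1L, 1))
  ncfg <- normalization_config(control_sample_ids = c("S05", "S06", "S07"))
  res <- two_stage_detect(run, ncfg, detection_config())
  for (s in c("S01", "S02", "S03", "S04"))
    expect_true(any(res$calls$sample == s & res$calls$direction == "DEL" &
                      res$calls$chrom == "chr1"))
  expect_false(any(res$calls$sample %in% c("S05", "S06", "S07") &
                     res$calls$direction == "DUP"))
})
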