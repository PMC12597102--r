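# Length-signal construction, circular binary segmentation against an
# exhaustive oracle, peak-rule delineation, and the normal-capsid fallback
# window.

test_that("length signals tally reads exactly, zero bins included", {
  sig <- length_signal(c(100, 100, 250), bin_width = 1, range = c(1, 300))
  expect_equal(length(sig$counts), 300L)
  expect_equal(sig$counts[100], 2L)
  expect_equal(sig$counts[250], 1L)
  expect_equal(sum(sig$counts), 3L)
  # conservation at scale
  set.seed(1)
  lens <- sample(1000:50000, 20000, replace = TRUE)
  sig2 <- length_signal(lens, bin_width = 10, range = c(1000, 50000))
  expect_equal(sum(sig2$counts), 20000L)
  # brute-force histogram oracle at bin width 10
  brute <- table(cut(lens, breaks = seq(1000, 50010, by = 10),
                     right = FALSE))
  expect_equal(as.integer(sig2$counts), as.integer(brute))
  # empty input is a valid empty signal
  expect_equal(length(length_signal(numeric())$counts), 0L)
})

test_that("a constant signal yields a single segment", {
  sig <- signal_from_counts(rep(3L, 30))
  segs <- cbs_segment(sig, cbs_params(nperm = 500))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$mean_count, 3)
  expect_equal(segs$n_markers, 30L)
})

test_that("a clean step is split exactly at the exhaustive max-t location", {
  x <- c(rep(0L, 10), rep(10L, 10))
  sig <- signal_from_counts(x)
  segs <- cbs_segment(sig, cbs_params(alpha = 0.01, nperm = 1000, seed = 1))
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$last_bin[1], 10L)
  or <- oracle_max_arc(as.numeric(x))
  # the oracle's arc boundary matches the accepted change point
  expect_true(10L %in% c(or$i, or$j))
})

test_that("accepted change points equal exhaustive max-t locations on step signals", {
  set.seed(99)
  for (case in 1:15) {
    n <- sample(20:50, 1)
    cp <- sample(5:(n - 5), 1)
    lvl <- sample(5:15, 1)
    x <- c(rnorm(cp, 0, 0.3), rnorm(n - cp, lvl, 0.3))
    x <- round(pmax(x, 0), 3)
    arc <- virionseq:::.cbs_max_arc(x, 2L)
    or <- oracle_max_arc(x)
    expect_equal(arc$stat, or$stat, tolerance = 1e-10)
    # an arc and its complement carry the same statistic and imply the same
    # cuts; compare the implied change-point sets
    cuts <- function(a) setdiff(c(a$i, a$j), c(0L, n))
    expect_setequal(cuts(arc), cuts(or))
    segs <- cbs_segment(signal_from_counts(round(x * 1000)),
                        cbs_params(nperm = 500, seed = 1))
    expect_true(cp %in% segs$last_bin)
  }
})

test_that("segments always partition the bin axis", {
  set.seed(7)
  for (case in 1:8) {
    x <- rpois(60, lambda = sample(c(1, 5, 20), 60, replace = TRUE))
    segs <- cbs_segment(signal_from_counts(x), cbs_params(nperm = 300))
    expect_equal(segs$first_bin[1], 1L)
    expect_equal(segs$last_bin[nrow(segs)], 60L)
    if (nrow(segs) > 1)
      expect_equal(segs$first_bin[-1L], segs$last_bin[-nrow(segs)] + 1L)
    expect_equal(sum(segs$n_markers), 60L)
  }
})

test_that("lowering alpha never increases the number of segments", {
  set.seed(11)
  for (case in 1:5) {
    x <- c(rpois(15, 2), rpois(15, 8), rpois(15, 3), rpois(15, 12))
    sig <- signal_from_counts(x)
    ns <- vapply(c(0.001, 0.01, 0.05, 0.2), function(a)
      nrow(cbs_segment(sig, cbs_params(alpha = a, nperm = 500, seed = 1))),
      integer(1))
    expect_true(all(diff(ns) >= 0))
  }
})

test_that("the peak rule selects the contiguous run of segments with mean >= 2", {
  # segment means along the window: 0.2, 8, 2.5, 0.1 -> segments 2-3 only
  segs <- data.frame(first_bin = c(1L, 11L, 21L, 31L),
                     last_bin = c(10L, 20L, 30L, 40L),
                     n_markers = rep(10L, 4),
                     mean_count = c(0.2, 8, 2.5, 0.1),
                     start_length = c(1L, 11L, 21L, 31L),
                     end_length = c(10L, 20L, 30L, 40L))
  class(segs) <- c("cbs_segments", "data.frame")
  reads <- c(rep(15, 80), rep(25, 25), rep(35, 1))
  rng <- delineate_range(segs, c(1, 40), reads, capsid = "small")
  expect_equal(rng$min_length, 11L)
  expect_equal(rng$max_length, 30L)
  expect_false(rng$fallback)
  expect_equal(rng$n_reads, 105L)
  expect_true(rng$p5_length <= rng$median_length &
                rng$median_length <= rng$p95_length)
  # all means < 2: fallback to the single highest-mean segment
  segs$mean_count <- c(0.2, 1.4, 0.9, 0.1)
  rng2 <- delineate_range(segs, c(1, 40), reads, capsid = "normal")
  expect_true(rng2$fallback)
  expect_equal(c(rng2$min_length, rng2$max_length), c(11L, 20L))
  # a single qualifying segment spans itself
  segs$mean_count <- c(0.2, 8, 0.4, 0.1)
  rng3 <- delineate_range(segs, c(1, 40), reads, capsid = "small")
  expect_equal(c(rng3$min_length, rng3$max_length), c(11L, 20L))
  expect_error(delineate_range(segs, c(500, 600), reads, capsid = "small"),
               "no segment")
})

test_that("the 25-46 kb fallback window keeps inclusive bounds and drops outliers", {
  lens <- c(15900, 25000, 30000, 44000, 46000, 46001, 60000)
  kept <- normal_fallback_filter(lens)
  expect_equal(kept, c(25000, 30000, 44000, 46000))
  expect_equal(normal_fallback_filter(numeric()), numeric())
  expect_equal(normal_fallback_filter(c(15900, 30000, 44000, 60000)),
               c(30000, 44000))
  expect_error(normal_fallback_filter(lens, low = 50000, high = 40000),
               "low")
})

test_that("delineated medians recover configured capacities on the infection preset", {
  # moderate-scale parameter recovery (full-scale run lives in acceptance)
  cfg <- scenario_preset("infection_E72m5", n_series_phage = 150L,
                         n_series_pici = 120L, n_lateral = 40L,
                         n_plasmid = 3L)
  ds <- emit_dataset(cfg, seed = 21, with_sequences = FALSE)
  sig <- length_signal(ds$reads$length, bin_width = 100,
                       range = c(1000, 60000))
  segs <- cbs_segment(sig, cbs_params(nperm = 2000, seed = 1))
  small <- delineate_range(segs, c(10000, 25000), ds$reads,
                           min_mean = 200, capsid = "small")
  normal <- delineate_range(segs, c(25000, 50000), ds$reads,
                            min_mean = 200, capsid = "normal")
  expect_equal(small$median_length, 16500, tolerance = 0.02)
  expect_equal(normal$median_length, 45300, tolerance = 0.02)
  # disjoint ranges
  expect_lt(small$max_length, normal$min_length)
})
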