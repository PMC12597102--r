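# Headful-packaging simulator: concatemer arithmetic, series structure,
# lateral coverage decay, fragmentation statistics, dataset determinism.

test_that("concatemer construction and coordinate map follow modular arithmetic", {
  u <- make_pici()
  cc <- build_concatemer(u, 3L)
  expect_equal(cc$length, 44400L)
  expect_equal(concat_to_unit(cc, 29600), 0)
  expect_equal(concat_to_unit(cc, c(0, 14800, 14801)), c(0, 0, 1))
  expect_equal(build_concatemer(u, 1L)$length, 14800L)
  expect_equal(build_concatemer(unit_genome("p", 44200L, category = "phage"),
                                5L)$length, 221000L)
  expect_error(build_concatemer(u, 0L), "n_units")
})

test_that("headful starts are contiguous and follow closed-form positions without noise", {
  u <- make_phage(pac = 2000L)
  cc <- build_concatemer(u, 5L)
  # all-normal capsids, capacity 1.03 x unit, zero jitter and CV
  cap <- round(1.03 * u$length)
  cm <- capsid_model(1000, cap, capacity_cv = 0, pac_offset_sd = 0,
                     p_small = 0, p_switch = 0)
  g <- simulate_headful_series(cc, cm, seed = 1)
  expect_equal(g$start, 2000 + (seq_len(nrow(g)) - 1L) * cap)
  # contiguity: each genophore starts where the previous ended
  expect_equal(g$start[-1L], g$end[-nrow(g)])
  # conservation: total packaged DNA fits in the concatemer
  expect_lte(sum(g$length), cc$length)
})

test_that("a small first headful shifts the next normal genophore one small capacity downstream", {
  u <- make_phage()
  cc <- build_concatemer(u, 5L)
  small_cap <- round(0.374 * u$length)
  g <- NULL
  for (s in 1:50) {
    cand <- simulate_headful_series(
      cc, capsid_model(small_cap, round(1.03 * u$length), capacity_cv = 0,
                       pac_offset_sd = 0, p_small = 0.5, p_switch = 1),
      seed = s)
    if (nrow(cand) >= 2 && cand$capsid[1] == "small" &&
        cand$capsid[2] == "normal") { g <- cand; break }
  }
  expect_false(is.null(g))
  expect_equal(g$start[2] - u$pac_position, small_cap)
})

test_that("degenerate and extreme capsid probabilities behave as declared", {
  u <- make_pici()
  short <- build_concatemer(u, 1L)
  cm <- rigid_capsid(small = 16500, normal = 45300, p_small = 1)
  # concatemer (14.8 kb) shorter than the small capacity (16.5 kb)
  expect_equal(nrow(simulate_headful_series(short, cm, seed = 1)), 0L)
  cc <- build_concatemer(u, 20L)
  all_small <- simulate_headful_series(
    cc, capsid_model(16500, 45300, p_small = 1, p_switch = 0.5), seed = 2)
  expect_true(all(all_small$capsid == "small"))
  all_normal <- simulate_headful_series(
    cc, capsid_model(16500, 45300, p_small = 0, p_switch = 0.5), seed = 3)
  expect_true(all(all_normal$capsid == "normal"))
})

test_that("series conservation and contiguity hold across random models", {
  u <- make_phage()
  cc <- build_concatemer(u, 8L)
  for (s in 1:20) {
    cm <- capsid_model(16500, 45300, p_small = 0.65, p_switch = 0.3)
    g <- simulate_headful_series(cc, cm, seed = s)
    if (nrow(g) < 2) next
    expect_equal(g$start[-1L], g$end[-nrow(g)])
    expect_lte(sum(g$length), cc$length)
    expect_true(all(g$length > 0))
  }
})

test_that("lateral coverage decays with distance as the series-length survival function", {
  chr <- unit_genome("chr", 600000L, category = "chromosome",
                     circular = FALSE)
  el <- list(start = 100000L, end = 114800L, pac = 100500L,
             direction = "forward")
  cap <- 16500
  cm <- rigid_capsid(small = cap, normal = 45300, p_small = 1)
  lm_ <- lateral_model(series_min = 2L, series_max = 12L)
  n_init <- 10000L
  g <- simulate_lateral(chr, el, lm_, cm, n_initiations = n_init, seed = 42)
  cov <- coverage_profile(g, ref_length = chr$length)
  # closed form: position pac + d covered iff series length m >= ceil(d/cap)
  for (d in c(20000, 60000, 120000, 180000)) {
    m_needed <- ceiling(d / cap)
    p_cover <- mean(2:12 >= m_needed)
    emp <- cov[el$pac + d] / n_init
    tol <- 4 * sqrt(p_cover * (1 - p_cover) / n_init) + 1e-9
    expect_lt(abs(emp - p_cover), max(tol, 0.02))
  }
  # monotone non-increasing expected coverage (binomial noise allowed):
  # check on 10-kb bin means
  downstream <- cov[(el$end + 1):(el$end + 180000)]
  bins <- colMeans(matrix(downstream, nrow = 10000))
  expect_true(all(diff(bins) < 0.02 * n_init))
})

test_that("a single-headful lateral series stays within element plus terminal redundancy", {
  chr <- unit_genome("chr", 400000L, category = "chromosome",
                     circular = FALSE)
  el <- list(start = 100000L, end = 114800L, pac = 100500L,
             direction = "forward")
  cm <- rigid_capsid(small = 16500, normal = 45300, p_small = 1)
  g <- simulate_lateral(chr, el, lateral_model(series_min = 1L,
                                               series_max = 1L),
                        cm, n_initiations = 50, seed = 7)
  expect_true(all(g$headful == 1L))
  expect_true(all(g$end <= el$pac + 16500))
  expect_error(
    simulate_lateral(chr, list(start = -5L, end = 10L, pac = 0L,
                               direction = "forward"),
                     lateral_model(), cm, 1, seed = 1),
    "outside")
})

test_that("fragmentation preserves molecules at the Poisson zero-class rate", {
  g <- data.frame(length = rep(45000L, 4000))
  frag <- fragmentation_model(2e-5, min_emitted_length = 500L)
  out <- simulate_fragmentation(g, frag, seed = 9)
  intact <- sum(out$intact)
  expect_equal(intact / 4000, exp(-0.9), tolerance = 0.08)
  # break_rate 0 keeps everything intact
  out0 <- simulate_fragmentation(g, fragmentation_model(0), seed = 1)
  expect_true(all(out0$intact))
  expect_equal(nrow(out0), 4000L)
  # pieces are labelled fragment and respect the emission floor
  gg <- data.frame(length = rep(45000L, 50), capsid = "normal")
  pieces <- simulate_fragmentation(gg, fragmentation_model(1e-4), seed = 2)
  expect_true(all(pieces$capsid[!pieces$intact] == "fragment"))
  expect_true(all(pieces$length >= 500L))
})

test_that("emitted datasets are deterministic and carry coherent truth labels", {
  cfg <- scenario_preset("infection_E72m5", n_series_phage = 4L,
                         n_series_pici = 4L, n_lateral = 4L, n_plasmid = 2L)
  d1 <- withr::with_tempdir({
    emit_dataset(cfg, seed = 3, out_dir = "a")
    list(fq = readLines(file.path("a", "reads.fastq")),
         tr = readLines(file.path("a", "truth.tsv")))
  })
  d2 <- withr::with_tempdir({
    emit_dataset(cfg, seed = 3, out_dir = "b")
    list(fq = readLines(file.path("b", "reads.fastq")),
         tr = readLines(file.path("b", "truth.tsv")))
  })
  expect_identical(d1$fq, d2$fq)
  expect_identical(d1$tr, d2$tr)

  ds <- emit_dataset(cfg, seed = 3, with_sequences = FALSE)
  tr <- ds$reads
  # fragments never claim full-length capsid status
  expect_true(all(tr$capsid[!tr$intact] == "fragment"))
  # plasmid monomer emission: single headfuls of a small capsid
  pl <- tr[tr$origin == "plasmid" & tr$intact, ]
  expect_true(all(abs(pl$unit_copies - 16500 / 15000) < 0.15))
  # truth median of small intact genophores tracks the configured capacity
  sm <- tr$length[tr$capsid == "small"]
  expect_equal(median(sm), 16500, tolerance = 0.01)
})

test_that("emitted FASTQ agrees with the truth TSV", {
  cfg <- scenario_preset("infection_E72m5", n_series_phage = 3L,
                         n_series_pici = 3L, n_lateral = 2L, n_plasmid = 1L)
  withr::with_tempdir({
    ds <- emit_dataset(cfg, seed = 8, out_dir = "d")
    reads <- read_reads(file.path("d", "reads.fastq"))
    truth <- read.table(file.path("d", "truth.tsv"), header = TRUE,
                        sep = "\t")
    expect_setequal(reads$read_id, truth$read_id)
    m <- merge(reads, truth, by = "read_id")
    expect_equal(m$length.x, m$length.y)
    # references round-trip
    refs <- read_reference_set(file.path("d", "refs.fasta"),
                               file.path("d", "refs_meta.tsv"))
    expect_equal(refs[["SeCI_SE48"]]$pac_position, 500L)
    expect_equal(refs[["SeCI_SE48"]]$category, "pici")
  })
})
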