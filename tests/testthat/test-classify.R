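# Origin assignment: the exact tiler, per-read classification, unit-copy
# counting over doubled circular references, and pac-offset statistics.

# small labelled dataset shared by several blocks
.classify_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- scenario_preset("infection_E72m5", n_series_phage = 12L,
                             n_series_pici = 12L, n_lateral = 12L,
                             n_plasmid = 2L)
      ds <- emit_dataset(cfg, seed = 31)
      hits <- align_exact(ds$sequences, ds$refs)
      cache <<- list(ds = ds, hits = hits,
                     asg = classify_reads(hits, ds$refs))
    }
    cache
  }
})

test_that("tandem multimers count exact unit copies for k = 1..4", {
  set.seed(5)
  unit_seq <- random_dna(14800)
  u <- unit_genome("SeCI_SE48", 14800L, pac_position = 500L,
                   category = "pici", sequence = unit_seq)
  refs <- reference_set(u)
  for (k in 1:4) {
    read <- Biostrings::DNAStringSet(strrep(unit_seq, k))
    names(read) <- sprintf("tandem_%d", k)
    hits <- align_exact(read, refs)
    expect_equal(count_unit_copies(hits, 14800L), k)
  }
  # a circularly permuted 15.9-kb genophore on the 14.8-kb unit: ~1.07 copies
  full <- strrep(unit_seq, 2L)
  read <- Biostrings::DNAStringSet(substr(full, 2001, 2000 + 15900))
  names(read) <- "permuted"
  hits <- align_exact(read, refs)
  expect_equal(count_unit_copies(hits, 14800L), 15900 / 14800,
               tolerance = 1e-6)
})

test_that("reverse-strand reads tile and classify like forward ones", {
  set.seed(6)
  unit_seq <- random_dna(14800)
  u <- unit_genome("SeCI_SE48", 14800L, pac_position = 500L,
                   category = "pici", sequence = unit_seq)
  refs <- reference_set(u)
  fwd <- substr(strrep(unit_seq, 2L), 1001, 1000 + 15900)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  reads <- Biostrings::DNAStringSet(c(f = fwd, r = rc))
  hits <- align_exact(reads, refs)
  asg <- classify_reads(hits, refs)
  expect_equal(asg$origin, c("pici", "pici"))
  expect_equal(asg$unit_copies[1], asg$unit_copies[2], tolerance = 1e-6)
})

test_that("classification recovers truth labels on a labelled dataset", {
  fx <- .classify_fixture()
  truth <- fx$ds$reads
  truth$origin[truth$origin == "hybrid"] <- "hybrid_lateral"
  m <- merge(fx$asg, truth[, c("read_id", "origin")], by = "read_id",
             suffixes = c("_pred", "_true"))
  tab <- table(m$origin_pred, m$origin_true)
  for (cat in c("phage", "pici", "chromosome")) {
    expect_gte(tab[cat, cat] / sum(tab[cat, ]), 0.95)  # precision
    expect_gte(tab[cat, cat] / sum(tab[, cat]), 0.95)  # recall
  }
  hl <- "hybrid_lateral"
  if (hl %in% colnames(tab))
    expect_gte(tab[hl, hl] / sum(tab[, hl]), 0.9)
})

test_that("a 1.5-unit PICI multimer with 10 kb of flank through attB is hybrid_lateral", {
  set.seed(41)
  pici_seq <- random_dna(14800)
  backbone <- random_dna(120000)
  attB <- 60000L
  u_pici <- unit_genome("SeCI_SE48", 14800L, pac_position = 500L,
                        category = "pici", sequence = pici_seq, attB = attB)
  u_chr <- unit_genome("chromosome", 120000L, category = "chromosome",
                       sequence = backbone, circular = FALSE)
  refs <- reference_set(u_pici, u_chr)
  read <- Biostrings::DNAStringSet(paste0(
    substr(strrep(pici_seq, 2L), 1L, 22200L),
    substr(backbone, attB + 1L, attB + 10000L)))
  names(read) <- "multimer_hybrid"
  hits <- align_exact(read, refs)
  asg <- classify_reads(hits, refs)
  expect_equal(asg$origin, "hybrid_lateral")
  expect_equal(asg$unit_copies, 22200 / 14800, tolerance = 1e-6)
  # the fold switch reports it as chromosomal
  folded <- classify_reads(hits, refs, fold_hybrid_into_chromosome = TRUE)
  expect_equal(folded$origin, "chromosome")
})

test_that("lateral hybrids in the labelled dataset are recovered", {
  fx <- .classify_fixture()
  truth <- fx$ds$reads
  hybrids <- truth$read_id[truth$origin == "hybrid"]
  got <- fx$asg[fx$asg$read_id %in% hybrids, ]
  expect_gt(nrow(got), 0)
  expect_gte(mean(got$origin == "hybrid_lateral"), 0.9)
})

test_that("no hits yields an ambiguous assignment with zero coverage", {
  asg <- classify_reads(virionseq:::.empty_hits(),
                        reference_set(make_pici()))
  expect_equal(nrow(asg), 0L)
})

test_that("capsid labels follow the delineated ranges", {
  asg <- data.frame(read_id = c("a", "b", "c"),
                    read_length = c(16400L, 45000L, 8000L))
  small <- list(min_length = 15500, max_length = 17500)
  normal <- list(min_length = 43000, max_length = 47000)
  out <- assign_capsid(asg, small, normal)
  expect_equal(out$capsid, c("small", "normal", "fragment"))
})

test_that("pac-offset statistics recover the initiation jitter from single headfuls", {
  set.seed(77)
  unit_seq <- random_dna(14800)
  u <- unit_genome("SeCI_SE48", 14800L, pac_position = 500L,
                   category = "pici", sequence = unit_seq)
  refs <- reference_set(u)
  cc <- build_concatemer(u, 3L)
  cm <- capsid_model(16500, 45300, capacity_cv = 0, pac_offset_sd = 200,
                     p_small = 1, p_switch = 0)
  g <- do.call(rbind, lapply(1:400, function(i)
    simulate_headful_series(cc, cm, max_headfuls = 1L)))
  seqs <- Biostrings::DNAStringSet(
    substr(rep(cc$sequence, nrow(g)), g$start + 1L, g$end))
  names(seqs) <- sprintf("r%04d", seq_len(nrow(g)))
  hits <- align_exact(seqs, refs)
  asg <- classify_reads(hits, refs)
  ps <- pac_offset_stats(asg, hits, refs, origin = "pici")
  expect_equal(ps$offset_sd, 200, tolerance = 0.1)
  expect_lt(abs(ps$offset_median), 50)
  # terminal redundancy of a 16.5-kb genophore on a 14.8-kb unit: ~11.5%
  expect_equal(ps$redundancy_median, 16500 / 14800 - 1, tolerance = 0.02)
})

test_that("reads starting exactly at pac with unit length have offset and redundancy zero", {
  set.seed(12)
  unit_seq <- random_dna(10000)
  u <- unit_genome("u", 10000L, pac_position = 800L, category = "pici",
                   sequence = unit_seq)
  refs <- reference_set(u)
  full <- strrep(unit_seq, 2L)
  read <- Biostrings::DNAStringSet(substr(full, 801, 800 + 10000))
  names(read) <- "exact"
  hits <- align_exact(read, refs)
  asg <- classify_reads(hits, refs)
  ps <- pac_offset_stats(asg, hits, refs, origin = "pici")
  expect_equal(ps$offsets, 0)
  expect_equal(ps$redundancy_median, 0)
})

test_that("PAF round-trips through write and read", {
  fx <- .classify_fixture()
  h <- head(fx$hits, 20)
  tf <- tempfile(fileext = ".paf")
  write_paf(h, tf)
  back <- read_paf(tf, mapq_floor = 0)
  expect_equal(back$read_id, h$read_id)
  expect_equal(back$read_start, h$read_start)
  expect_equal(back$ref_end, h$ref_end)
  expect_equal(back$strand, h$strand)
  # malformed lines carry a line number
  writeLines(c(readLines(tf), "broken\tline"), tf)
  expect_error(read_paf(tf), "line 21")
})

test_that("SAM input is accepted through Rsamtools", {
  skip_if_not_installed("Rsamtools")
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:unitA\tLN:10000",
    paste("r1", 0, "unitA", 101, 60, "500M", "*", 0, 0,
          paste(rep("A", 500), collapse = ""),
          paste(rep("I", 500), collapse = ""), sep = "\t"),
    paste("r2", 16, "unitA", 1001, 5, "300M", "*", 0, 0,
          paste(rep("C", 300), collapse = ""),
          paste(rep("I", 300), collapse = ""), sep = "\t")),
    sam)
  hits <- read_sam(sam, mapq_floor = 10)
  expect_equal(nrow(hits), 1L)  # r2 filtered by mapq
  expect_equal(hits$ref_start, 100L)
  expect_equal(hits$ref_end, 600L)
  expect_equal(hits$strand, "+")
})
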