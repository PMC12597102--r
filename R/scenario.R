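# Scenario presets and end-to-end dataset emission for the simulator.

#' Simulation scenario presets
#'
#' Each preset describes one experimental system as a parameter bundle:
#' helper-phage and satellite unit genomes, capsid capacities and switching,
#' lateral-packaging behaviour, fragmentation intensity and the mix of
#' packaging substrates. Presets mirror the study conditions of the
#' corresponding systems: infection lysates show low fragmentation, antibiotic
#' induction shows heavier fragmentation and more small-headed particles, and
#' mitomycin-like induction shifts packaging toward the satellite.
#'
#' @param name one of `"infection_E72m5"`, `"infection_48"`,
#'   `"induction_cipro"`, `"induction_mitomycin"`, `"spontaneous"`.
#' @param ... named overrides applied on top of the preset (e.g.
#'   `n_series_phage`).
#' @return a scenario config list understood by [emit_dataset()].
#' @export
scenario_preset <- function(name = c("infection_E72m5", "infection_48",
                                     "induction_cipro", "induction_mitomycin",
                                     "spontaneous"), ...) {
  name <- match.arg(name)
  e72 <- list(name = "phage_E72m5", length = 44200L, pac = 2000L)
  p48 <- list(name = "phage_48", length = 42500L, pac = 2000L)
  base <- list(
    name = name,
    phage = e72,
    pici = list(name = "SeCI_SE48", length = 14800L, pac = 500L),
    plasmid = list(name = "p1457", length = 15000L),
    chromosome_backbone = 800000L,
    attB_phage = 250000L,           # prophage packages forward (toward pici)
    attB_pici = 450000L,            # pici packages reverse (toward prophage)
    capsid = capsid_model(16500, 45300, p_small = 0.65, p_switch = 0.3),
    lateral = lateral_model(p_in_situ = 0.2),
    frag = fragmentation_model(2e-6),
    n_units = 8L,
    n_series_phage = 60L,
    n_series_pici = 60L,
    n_lateral = 30L,
    n_plasmid = 3L,
    p_reverse_strand = 0.5)
  preset <- switch(
    name,
    infection_E72m5 = base,
    infection_48 = utils::modifyList(base, list(
      phage = p48,
      capsid = capsid_model(15900, 43800, p_small = 0.45, p_switch = 0.3))),
    induction_cipro = utils::modifyList(base, list(
      capsid = capsid_model(16500, 45300, p_small = 0.75, p_switch = 0.3),
      lateral = lateral_model(p_in_situ = 0.35),
      frag = fragmentation_model(8e-6),
      n_lateral = 60L, n_plasmid = 8L)),
    induction_mitomycin = utils::modifyList(base, list(
      capsid = capsid_model(16500, 45300, p_small = 0.8, p_switch = 0.3),
      lateral = lateral_model(p_in_situ = 0.35),
      frag = fragmentation_model(1e-5),
      n_series_phage = 30L, n_series_pici = 120L, n_lateral = 60L)),
    spontaneous = utils::modifyList(base, list(
      capsid = capsid_model(16500, 45300, p_small = 0.7, p_switch = 0.3),
      frag = fragmentation_model(5e-6),
      n_lateral = 40L)))
  utils::modifyList(preset, list(...))
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Assemble the element-containing chromosome: backbone with the prophage
# inserted (forward orientation) at attB_phage and the satellite inserted in
# reverse orientation at attB_pici, packaging directions toward each other.
.integrated_chromosome <- function(config, phage_seq, pici_seq, backbone_seq) {
  stopifnot(config$attB_phage < config$attB_pici)
  Lp <- config$phage$length; Li <- config$pici$length
  a1 <- config$attB_phage; a2 <- config$attB_pici
  seq <- NULL
  if (!is.null(backbone_seq)) {
    seq <- paste0(substr(backbone_seq, 1L, a1),
                  phage_seq,
                  substr(backbone_seq, a1 + 1L, a2),
                  .revcomp_chr(pici_seq),
                  substr(backbone_seq, a2 + 1L, config$chromosome_backbone))
  }
  phage_el <- list(start = a1, end = a1 + Lp,
                   pac = a1 + config$phage$pac, direction = "forward")
  # reverse-oriented insert: unit position p maps to chromosome coordinate
  # start + (Li - 1 - p); packaging proceeds leftward on the chromosome
  pici_start <- a2 + Lp
  pici_el <- list(start = pici_start, end = pici_start + Li,
                  pac = pici_start + (Li - 1L - config$pici$pac),
                  direction = "reverse")
  list(sequence = seq,
       length = config$chromosome_backbone + Lp + Li,
       phage_element = phage_el, pici_element = pici_el)
}

.overlap_len <- function(s, e, el) pmax(0L, pmin(e, el$end) - pmax(s, el$start))

#' Emit a complete labelled synthetic dataset
#'
#' Runs the full generative model of one scenario under a single seed:
#' synthesises reference sequences, packages phage / satellite / plasmid
#' concatemers and in-situ (lateral) series, fragments the resulting
#' genophores, and (optionally) writes FASTQ reads, a truth TSV and the
#' reference FASTA + sidecar metadata. Deterministic given `config` and
#' `seed`.
#'
#' @param config a scenario list from [scenario_preset()].
#' @param seed integer seed; every random draw derives from it.
#' @param out_dir optional output directory; created if missing. When `NULL`,
#'   nothing is written and the dataset is only returned.
#' @param with_sequences generate nucleotide sequences (needed for
#'   classification); when `FALSE` only read lengths and truth labels are
#'   produced, which is much faster for length-distribution work.
#' @return (invisibly when writing) a list with `reads` (truth data.frame with
#'   1-based inclusive coordinates), `sequences` (a
#'   [Biostrings::DNAStringSet] or `NULL`), `refs` (a [reference_set()] when
#'   sequences were generated), `elements` (integrated element coordinates,
#'   0-based half-open), `config`, `seed` and, when `out_dir` is given,
#'   `paths`.
#' @export
emit_dataset <- function(config, seed, out_dir = NULL, with_sequences = TRUE) {
  stopifnot(is.list(config), inherits(config$capsid, "capsid_model"))
  set.seed(seed)

  phage_seq <- pici_seq <- plasmid_seq <- backbone_seq <- NULL
  if (with_sequences) {
    phage_seq <- random_dna(config$phage$length)
    pici_seq <- random_dna(config$pici$length)
    plasmid_seq <- random_dna(config$plasmid$length)
    backbone_seq <- random_dna(config$chromosome_backbone)
  }
  chrom <- .integrated_chromosome(config, phage_seq, pici_seq, backbone_seq)
  chrom_unit <- unit_genome("chromosome", chrom$length,
                            category = "chromosome", circular = FALSE)

  phage_unit <- unit_genome(config$phage$name, config$phage$length,
                            pac_position = config$phage$pac,
                            category = "phage", sequence = phage_seq,
                            attB = config$attB_phage)
  pici_unit <- unit_genome(config$pici$name, config$pici$length,
                           pac_position = config$pici$pac,
                           category = "pici", sequence = pici_seq,
                           attB = config$attB_pici)
  plasmid_unit <- unit_genome(config$plasmid$name, config$plasmid$length,
                              pac_position = 0L, category = "plasmid",
                              sequence = plasmid_seq)

  grab_series <- function(unit, n_series, n_units, origin,
                          max_headfuls = Inf) {
    if (n_series == 0L) return(NULL)
    cc <- build_concatemer(unit, n_units)
    res <- lapply(seq_len(n_series), function(i) {
      g <- simulate_headful_series(cc, config$capsid,
                                   max_headfuls = max_headfuls)
      if (nrow(g) == 0L) return(NULL)
      g$origin <- origin; g$reference <- unit$name
      g$source <- sprintf("%s_series%04d", origin, i)
      g
    })
    do.call(rbind, res)
  }

  n_lat_pici <- round(config$n_lateral * 0.7)
  n_lat_phage <- config$n_lateral - n_lat_pici

  lat <- function(el, n, tag) {
    if (n == 0L) return(NULL)
    g <- simulate_lateral(chrom_unit, el, config$lateral, config$capsid,
                          n_initiations = n)
    if (nrow(g) == 0L) return(NULL)
    g$reference <- "chromosome"
    g$source <- sprintf("%s_init%04d", tag, g$initiation)
    g[, c("start", "end", "length", "capsid", "headful", "origin",
          "reference", "source")]
  }

  pieces <- list(
    phage = grab_series(phage_unit, config$n_series_phage,
                        config$n_units, "phage"),
    pici = grab_series(pici_unit, config$n_series_pici,
                       config$n_units, "pici"),
    plasmid = grab_series(plasmid_unit, config$n_plasmid, 2L, "plasmid",
                          max_headfuls = 1L),
    lat_pici = lat(chrom$pici_element, n_lat_pici, "lat_pici"),
    lat_phage = lat(chrom$phage_element, n_lat_phage, "lat_phage"))
  keep <- c("start", "end", "length", "capsid", "headful", "origin",
            "reference", "source")
  gen <- do.call(rbind, lapply(pieces[!vapply(pieces, is.null, logical(1))],
                               function(d) d[, keep]))
  rownames(gen) <- NULL

  reads <- simulate_fragmentation(gen, config$frag)
  reads$abs_start <- reads$start + reads$piece_start
  reads$abs_end <- reads$start + reads$piece_end
  reads$length <- reads$abs_end - reads$abs_start

  # re-derive per-piece truth origin from the interval actually covered
  is_chr <- reads$reference == "chromosome"
  if (any(is_chr)) {
    s <- reads$abs_start[is_chr]; e <- reads$abs_end[is_chr]
    ovp <- .overlap_len(s, e, chrom$phage_element)
    ovi <- .overlap_len(s, e, chrom$pici_element)
    # a genophore is a hybrid when element- and host-derived content are
    # both substantial (>= 20% of its length); marginal flanks go to the
    # dominant category, matching the operational definition the classifier
    # reports
    len <- e - s
    f_el <- (ovp + ovi) / len
    el_cat <- ifelse(ovp >= ovi, "phage", "pici")
    reads$origin[is_chr] <- ifelse(
      f_el >= 0.2 & (1 - f_el) >= 0.2, "hybrid",
      ifelse(f_el > 0.5, el_cat, "chromosome"))
    reads$element_copies <- NA_real_
    reads$element_copies[is_chr] <- pmax(ovp / config$phage$length,
                                         ovi / config$pici$length)
  } else reads$element_copies <- NA_real_

  reads$unit_copies <- NA_real_
  mge <- reads$origin %in% c("phage", "pici", "plasmid") & !is_chr
  ul <- c(setNames(config$phage$length, "phage"),
          setNames(config$pici$length, "pici"),
          setNames(config$plasmid$length, "plasmid"))
  reads$unit_copies[mge] <- reads$length[mge] / ul[reads$origin[mge]]
  in_el <- is_chr & reads$origin %in% c("phage", "pici", "hybrid")
  reads$unit_copies[in_el] <- reads$element_copies[in_el]

  reads$strand <- ifelse(runif(nrow(reads)) < config$p_reverse_strand,
                         "-", "+")
  reads <- reads[sample.int(nrow(reads)), ]
  reads$read_id <- sprintf("read_%06d", seq_len(nrow(reads)))
  rownames(reads) <- NULL

  sequences <- NULL
  refs <- NULL
  if (with_sequences) {
    concat_seq <- c(
      setNames(strrep(phage_seq, config$n_units), config$phage$name),
      setNames(strrep(pici_seq, config$n_units), config$pici$name),
      setNames(strrep(plasmid_seq, 2L), config$plasmid$name),
      chromosome = chrom$sequence)
    chars <- substr(rep(concat_seq[reads$reference], 1L),
                    reads$abs_start + 1L, reads$abs_end)
    sequences <- Biostrings::DNAStringSet(chars)
    names(sequences) <- reads$read_id
    neg <- reads$strand == "-"
    if (any(neg))
      sequences[neg] <- Biostrings::reverseComplement(sequences[neg])
    refs <- reference_set(
      phage_unit, pici_unit, plasmid_unit,
      unit_genome("chromosome", config$chromosome_backbone,
                  category = "chromosome", sequence = backbone_seq,
                  circular = FALSE))
  }

  truth <- data.frame(
    read_id = reads$read_id,
    capsid = reads$capsid,
    origin = reads$origin,
    reference = reads$reference,
    start = reads$abs_start + 1L,      # 1-based inclusive in emitted reports
    end = reads$abs_end,
    strand = reads$strand,
    unit_copies = reads$unit_copies,
    length = reads$length,
    intact = reads$intact,
    source = reads$source,
    stringsAsFactors = FALSE)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    truth_path <- file.path(out_dir, "truth.tsv")
    write.table(truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(truth = truth_path)
    if (with_sequences) {
      fq <- file.path(out_dir, "reads.fastq")
      .write_fastq(sequences, fq)
      rp <- write_reference_set(refs, file.path(out_dir, "refs.fasta"),
                                file.path(out_dir, "refs_meta.tsv"))
      paths <- c(paths, fastq = fq, rp)
    }
    cfgp <- file.path(out_dir, "scenario.txt")
    writeLines(c(sprintf("name=%s", config$name),
                 sprintf("seed=%d", seed),
                 sprintf("n_units=%d", config$n_units)), cfgp)
    paths <- c(paths, config = cfgp)
  }

  invisible(list(reads = truth, sequences = sequences, refs = refs,
                 elements = chrom[c("phage_element", "pici_element")],
                 chromosome_length = chrom$length,
                 config = config, seed = seed, paths = paths))
}

# FASTQ writer for arbitrarily long reads (uniform placeholder quality).
# Biostrings' fastq writer uses a fixed-width line buffer sized for
# short-read data and crashes on genophore-length records, so the four-line
# records are emitted directly.
.write_fastq <- function(sequences, path) {
  chars <- as.character(sequences)
  qual <- vapply(nchar(chars), function(w) strrep("I", w), character(1))
  lines <- as.vector(rbind(paste0("@", names(sequences)), chars, "+", qual))
  writeLines(lines, path)
  invisible(path)
}
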