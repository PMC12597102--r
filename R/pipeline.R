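# End-to-end orchestration: reproducible pipeline over the four analysis
# stages (segment -> ambiguity -> classify -> quantify) with standard-format
# I/O and a machine-readable run manifest.

#' Read read lengths (and optionally sequences) from FASTQ/FASTA or a length
#' list
#'
#' @param path FASTQ/FASTA (optionally gzipped; detected by extension) or a
#'   plain text file with one integer length per line.
#' @param sequences also return the sequences (FASTQ/FASTA only).
#' @return data.frame with `read_id` and `length`; with `sequences = TRUE`,
#'   the [Biostrings::DNAStringSet] is attached as attribute `"sequences"`.
#' @export
read_reads <- function(path, sequences = FALSE) {
  base <- sub("\\.gz$", "", path)
  kind <- if (grepl("\\.(fastq|fq)$", base)) "fastq"
  else if (grepl("\\.(fasta|fa|fna)$", base)) "fasta"
  else "lengths"
  if (kind == "lengths") {
    lens <- suppressWarnings(as.integer(readLines(path)))
    if (anyNA(lens)) stop("malformed length list at line ",
                          which(is.na(lens))[1])
    return(data.frame(read_id = sprintf("read_%06d", seq_along(lens)),
                      length = lens, stringsAsFactors = FALSE))
  }
  dss <- Biostrings::readDNAStringSet(path, format = kind)
  names(dss) <- sub("\\s.*$", "", names(dss))
  out <- data.frame(read_id = names(dss),
                    length = Biostrings::width(dss),
                    stringsAsFactors = FALSE)
  if (sequences) attr(out, "sequences") <- dss
  out
}

#' Write a coverage track as bedGraph
#'
#' @param coverage per-base coverage vector.
#' @param ref_name reference name for column 1.
#' @param path output path.
#' @export
write_bedgraph <- function(coverage, ref_name, path) {
  r <- rle(coverage)
  ends <- cumsum(r$lengths)
  starts <- c(0L, head(ends, -1L))
  keep <- r$values != 0
  lines <- sprintf("%s\t%d\t%d\t%g", ref_name, starts[keep], ends[keep],
                   r$values[keep])
  writeLines(lines, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param reads path to reads (FASTQ/FASTA/length list).
#' @param out_dir output directory.
#' @param alignments optional PAF or SAM path; when absent and `refs_fasta`
#'   is given, the exact tiler aligns the reads itself.
#' @param refs_fasta,refs_meta reference FASTA and sidecar metadata (as
#'   written by [write_reference_set()]).
#' @param bin_width histogram bin width in nt.
#' @param cbs segmentation parameters ([cbs_params()]).
#' @param small_window,normal_window search windows (nt) for the two capsid
#'   peaks.
#' @param fit_domain background-fit domain (nt).
#' @param min_mean_per_nt peak-rule threshold expressed per nt of bin width:
#'   a peak segment must average at least `min_mean_per_nt * bin_width` reads
#'   per bin (default 2, the rule's value at 1-nt markers).
#' @param min_primary,min_component,mapq_floor classification thresholds.
#' @param seed global seed, recorded in the manifest.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(reads, out_dir, alignments = NULL,
                            refs_fasta = NULL, refs_meta = NULL,
                            bin_width = 100L, cbs = cbs_params(),
                            small_window = c(10000, 25000),
                            normal_window = c(25000, 50000),
                            fit_domain = c(1000, 40000),
                            min_mean_per_nt = 2,
                            min_primary = 0.8, min_component = 0.2,
                            mapq_floor = 10, seed = 1L) {
  structure(list(reads = reads, out_dir = out_dir, alignments = alignments,
                 refs_fasta = refs_fasta, refs_meta = refs_meta,
                 bin_width = as.integer(bin_width), cbs = cbs,
                 small_window = small_window, normal_window = normal_window,
                 fit_domain = fit_domain, min_mean_per_nt = min_mean_per_nt,
                 min_primary = min_primary,
                 min_component = min_component, mapq_floor = mapq_floor,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes segment -> ambiguity -> classify -> quantify on one sample and
#' writes, under `config$out_dir`: `segments.tsv`, `ranges.json`,
#' `ambiguity.json`, `assignments.tsv`, `abundance.json`, per-reference
#' coverage bedGraphs, and a `manifest.json` with parameters, seed and
#' output checksums. Runs are byte-identical under a fixed config and seed
#' (no timestamps are embedded). A failure in any stage halts with a
#' stage-tagged error; outputs of completed stages remain on disk.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with `ranges`, `ambiguity`, `assignments`,
#'   `abundance`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outs <- character()

  reads <- .stage("input", read_reads(config$reads,
                                      sequences = is.null(config$alignments)))

  ## -- segment ------------------------------------------------------------
  seg_res <- .stage("segment", {
    sig <- length_signal(reads$length, bin_width = config$bin_width,
                         range = c(config$fit_domain[1],
                                   max(config$normal_window)))
    segs <- cbs_segment(sig, config$cbs)
    min_mean <- config$min_mean_per_nt * config$bin_width
    small <- delineate_range(segs, config$small_window, reads,
                             min_mean = min_mean, capsid = "small")
    normal <- tryCatch(
      delineate_range(segs, config$normal_window, reads,
                      min_mean = min_mean, capsid = "normal"),
      error = function(e) NULL)
    normal_fallback <- is.null(normal)
    if (normal_fallback) {
      sel <- normal_fallback_filter(reads)
      qs <- quantile(sel$length, c(0.05, 0.5, 0.95), names = FALSE)
      normal <- structure(list(capsid = "normal", min_length = 25000,
                               max_length = 46000, n_reads = nrow(sel),
                               median_length = qs[2], p5_length = qs[1],
                               p95_length = qs[3], fallback = TRUE),
                          class = "genophore_range")
    }
    seg_path <- file.path(config$out_dir, "segments.tsv")
    write.table(as.data.frame(segs), seg_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    rng_path <- .write_json(list(small = unclass(small),
                                 normal = unclass(normal),
                                 bin_width = config$bin_width),
                            file.path(config$out_dir, "ranges.json"))
    outs <<- c(outs, seg_path, rng_path)
    list(signal = sig, segments = segs, small = small, normal = normal)
  })

  ## -- ambiguity ----------------------------------------------------------
  amb <- .stage("ambiguity", {
    fit <- fit_background(seg_res$signal, seg_res$small,
                          fit_domain = config$fit_domain)
    obs <- sum(reads$length >= seg_res$small$min_length &
                 reads$length <= seg_res$small$max_length)
    a <- ambiguous_fraction(fit, seg_res$small, obs)
    p <- .write_json(list(a = fit$a, b = fit$b, predicted = a$predicted,
                          observed = a$observed, fraction = a$fraction),
                     file.path(config$out_dir, "ambiguity.json"))
    outs <<- c(outs, p)
    a
  })

  ## -- classify -----------------------------------------------------------
  cls <- .stage("classify", {
    refs <- NULL
    if (!is.null(config$refs_fasta))
      refs <- read_reference_set(config$refs_fasta, config$refs_meta)
    if (!is.null(config$alignments)) {
      if (!file.exists(config$alignments))
        stop("alignments path does not exist: ", config$alignments)
      hits <- if (grepl("\\.sam$", config$alignments))
        read_sam(config$alignments, config$mapq_floor)
      else read_paf(config$alignments, config$mapq_floor)
    } else {
      if (is.null(refs)) stop("need either alignments or references")
      hits <- align_exact(attr(reads, "sequences"), refs)
    }
    if (is.null(refs)) stop("need refs_fasta/refs_meta for classification")
    asg <- classify_reads(hits, refs, min_primary = config$min_primary,
                          min_component = config$min_component,
                          mapq_floor = config$mapq_floor)
    asg <- assign_capsid(asg, seg_res$small, seg_res$normal)
    p <- file.path(config$out_dir, "assignments.tsv")
    write.table(asg, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outs <<- c(outs, p)
    for (rn in unique(hits$reference)) {
      h <- hits[hits$reference == rn, , drop = FALSE]
      cov <- coverage_profile(h, ref_length = max(h$ref_end))
      bp <- file.path(config$out_dir, paste0("coverage_", rn, ".bedgraph"))
      write_bedgraph(cov, rn, bp)
      outs <<- c(outs, bp)
    }
    list(hits = hits, assignments = asg, refs = refs)
  })

  ## -- quantify -----------------------------------------------------------
  quant <- .stage("quantify", {
    ab <- abundance_table(cls$assignments)
    cov_by_ref <- vapply(split(cls$hits, cls$hits$reference), function(h)
      sum(h$ref_end - h$ref_start) /
        cls$refs[[h$reference[1]]]$length, numeric(1))
    shares <- copy_shares(cov_by_ref)
    p <- .write_json(list(abundance = ab, copy_shares = shares),
                     file.path(config$out_dir, "abundance.json"))
    outs <<- c(outs, p)
    list(abundance = ab, shares = shares)
  })

  ## -- manifest -----------------------------------------------------------
  manifest <- list(
    package = "virionseq",
    version = as.character(utils::packageVersion("virionseq")),
    seed = config$seed,
    parameters = list(bin_width = config$bin_width,
                      alpha = config$cbs$alpha,
                      min_width = config$cbs$min_width,
                      nperm = config$cbs$nperm,
                      small_window = config$small_window,
                      normal_window = config$normal_window,
                      fit_domain = config$fit_domain,
                      min_primary = config$min_primary,
                      min_component = config$min_component,
                      mapq_floor = config$mapq_floor),
    outputs = as.list(setNames(unname(tools::md5sum(outs)),
                               basename(outs))))
  mp <- .write_json(manifest, file.path(config$out_dir, "manifest.json"))

  invisible(list(ranges = seg_res[c("small", "normal")], ambiguity = amb,
                 assignments = cls$assignments, abundance = quant$abundance,
                 copy_shares = quant$shares, manifest = manifest,
                 manifest_path = mp))
}

#' Read/write a flat key=value config file
#'
#' @param path file with `key=value` lines (`#` comments allowed).
#' @return named character vector.
#' @export
read_flat_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(vapply(kv, length, integer(1)) < 2L)
  if (length(bad)) stop("malformed config line ", bad[1])
  setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)),
           vapply(kv, `[[`, character(1), 1L))
}
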