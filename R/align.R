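# Alignment input: PAF and SAM readers for externally produced alignments,
# plus a built-in exact-match tiler so that error-free synthetic reads can be
# classified without an external aligner. All in-memory coordinates are
# 0-based half-open.

#' Read alignments from a PAF file (minimap2 dialect)
#'
#' @param path PAF path (optionally gzipped).
#' @param mapq_floor drop records with mapping quality below this (default
#'   10).
#' @return data.frame of alignment hits: `read_id`, `read_length`,
#'   `read_start`, `read_end`, `strand`, `reference`, `ref_length`,
#'   `ref_start`, `ref_end`, `n_match`, `block_len`, `mapq` (coordinates
#'   0-based half-open, as in PAF).
#' @export
read_paf <- function(path, mapq_floor = 10) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(.empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 12L)
  if (length(bad))
    stop(sprintf("malformed PAF record at line %d: fewer than 12 fields",
                 bad[1]))
  m <- do.call(rbind, lapply(fields, `[`, 1:12))
  df <- data.frame(
    read_id = m[, 1], read_length = as.integer(m[, 2]),
    read_start = as.integer(m[, 3]), read_end = as.integer(m[, 4]),
    strand = m[, 5], reference = m[, 6],
    ref_length = as.integer(m[, 7]), ref_start = as.integer(m[, 8]),
    ref_end = as.integer(m[, 9]), n_match = as.integer(m[, 10]),
    block_len = as.integer(m[, 11]), mapq = as.integer(m[, 12]),
    stringsAsFactors = FALSE)
  df[df$mapq >= mapq_floor, , drop = FALSE]
}

#' Write alignment hits as PAF
#'
#' @param hits a hits data.frame as returned by [read_paf()] or
#'   [align_exact()].
#' @param path output path.
#' @export
write_paf <- function(hits, path) {
  h <- hits
  if (!"n_match" %in% names(h)) h$n_match <- h$read_end - h$read_start
  if (!"block_len" %in% names(h)) h$block_len <- h$read_end - h$read_start
  if (!"mapq" %in% names(h)) h$mapq <- 60L
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                   h$read_id, h$read_length, h$read_start, h$read_end,
                   h$strand, h$reference, h$ref_length, h$ref_start,
                   h$ref_end, h$n_match, h$block_len, h$mapq)
  writeLines(lines, path)
  invisible(path)
}

.empty_hits <- function() {
  data.frame(read_id = character(), read_length = integer(),
             read_start = integer(), read_end = integer(),
             strand = character(), reference = character(),
             ref_length = integer(), ref_start = integer(),
             ref_end = integer(), n_match = integer(),
             block_len = integer(), mapq = integer(),
             stringsAsFactors = FALSE)
}

.cigar_ref_width <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  vapply(seq_along(cigar), function(i) {
    toks <- regmatches(cigar[i], ops[i])[[1]]
    n <- as.integer(sub("[MIDNSHP=X]$", "", toks))
    op <- sub("^\\d+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}

.cigar_read_span <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  t(vapply(seq_along(cigar), function(i) {
    toks <- regmatches(cigar[i], ops[i])[[1]]
    n <- as.integer(sub("[MIDNSHP=X]$", "", toks))
    op <- sub("^\\d+", "", toks)
    lead <- if (length(op) && op[1] %in% c("S", "H")) n[1] else 0L
    trail <- if (length(op) > 1 && op[length(op)] %in% c("S", "H"))
      n[length(op)] else 0L
    aligned <- sum(n[op %in% c("M", "I", "=", "X")])
    c(lead, aligned, lead + aligned + trail)
  }, integer(3)))
}

#' Read alignments from a SAM file
#'
#' Converts through BAM with Rsamtools and returns the same hit table as
#' [read_paf()].
#'
#' @inheritParams read_paf
#' @export
read_sam <- function(path, mapq_floor = 10) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("reading SAM requires the Rsamtools package")
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar")))[[1]]
  ok <- !is.na(res$pos)
  if (!any(ok)) return(.empty_hits())
  cig <- res$cigar[ok]
  span <- .cigar_read_span(cig)
  refw <- .cigar_ref_width(cig)
  df <- data.frame(
    read_id = res$qname[ok], read_length = span[, 3],
    read_start = span[, 1], read_end = span[, 1] + span[, 2],
    strand = ifelse(bitwAnd(res$flag[ok], 16L) > 0L, "-", "+"),
    reference = as.character(res$rname[ok]),
    ref_length = NA_integer_,
    ref_start = res$pos[ok] - 1L,
    ref_end = res$pos[ok] - 1L + refw,
    n_match = span[, 2], block_len = refw,
    mapq = res$mapq[ok], stringsAsFactors = FALSE)
  df[!is.na(df$mapq) & df$mapq >= mapq_floor, , drop = FALSE]
}

# Pre-index a reference set for the exact tiler: circular units are doubled
# so circularly permuted genophores tile across the origin; both strands are
# kept so satellite segments integrated in reverse orientation still anchor.
.tiler_index <- function(refs) {
  lapply(refs, function(u) {
    if (is.null(u$sequence)) stop("tiler references must carry sequences")
    s <- if (isTRUE(u$circular)) strrep(u$sequence, 2L) else u$sequence
    fwd <- Biostrings::DNAString(s)
    list(unit = u, fwd = fwd, rev = Biostrings::reverseComplement(fwd),
         search_len = length(fwd))
  })
}

#' Exact-match tiling alignment of error-free reads
#'
#' Greedy seed-and-extend tiler for synthetic, error-free reads: anchors a
#' seed k-mer on each reference (circular references are doubled so that
#' circularly permuted genophores align contiguously; both strands are
#' searched) and extends the exact match as far as it runs, then continues
#' with the remainder of the read. Not an aligner for real, error-containing
#' reads.
#'
#' @param sequences a [Biostrings::DNAStringSet] of reads (named by read id).
#' @param refs a [reference_set()] whose units carry sequences.
#' @param k seed length in nt (default 24).
#' @param min_hit discard extensions shorter than this (default 50 nt).
#' @return a hits data.frame as from [read_paf()], with `ref_start`/`ref_end`
#'   on the (possibly doubled) search sequence and an extra `unit_start`
#'   column giving `ref_start` modulo the unit length.
#' @export
align_exact <- function(sequences, refs, k = 24L, min_hit = 50L) {
  stopifnot(inherits(refs, "reference_set"))
  idx <- .tiler_index(refs)
  ids <- names(sequences)
  out <- vector("list", length(sequences))
  last_ref <- 1L
  for (r in seq_along(sequences)) {
    read <- sequences[[r]]
    L <- length(read)
    pos <- 1L
    hits <- list(); nh <- 0L
    order_refs <- c(last_ref, setdiff(seq_along(idx), last_ref))
    while (pos + k - 1L <= L) {
      seed <- Biostrings::subseq(read, pos, pos + k - 1L)
      best <- NULL
      for (ri in order_refs) {
        ref <- idx[[ri]]
        for (strand in c("+", "-")) {
          subject <- if (strand == "+") ref$fwd else ref$rev
          mt <- Biostrings::matchPattern(seed, subject)
          st <- BiocGenerics::start(mt)
          for (s0 in st) {
            ext_max <- min(L - pos + 1L, ref$search_len - s0 + 1L)
            ext <- Biostrings::lcprefix(
              Biostrings::subseq(read, pos, pos + ext_max - 1L),
              Biostrings::subseq(subject, s0, s0 + ext_max - 1L))
            if (is.null(best) || ext > best$ext)
              best <- list(ri = ri, strand = strand, s0 = s0, ext = ext)
          }
          if (!is.null(best) && best$ext == L - pos + 1L) break
        }
        if (!is.null(best) && best$ext == L - pos + 1L) break
      }
      if (is.null(best) || best$ext < min_hit) {
        pos <- pos + k
        next
      }
      ref <- idx[[best$ri]]
      last_ref <- best$ri
      u <- ref$unit
      if (best$strand == "+") {
        rs <- best$s0 - 1L; re <- rs + best$ext
      } else {
        re <- ref$search_len - (best$s0 - 1L); rs <- re - best$ext
      }
      nh <- nh + 1L
      hits[[nh]] <- data.frame(
        read_id = ids[r], read_length = L,
        read_start = pos - 1L, read_end = pos - 1L + best$ext,
        strand = best$strand, reference = u$name,
        ref_length = u$length, ref_start = rs, ref_end = re,
        n_match = best$ext, block_len = best$ext, mapq = 60L,
        unit_start = rs %% u$length,
        stringsAsFactors = FALSE)
      pos <- pos + best$ext
    }
    out[[r]] <- if (nh) do.call(rbind, hits)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- .empty_hits(); res$unit_start <- integer()
  }
  rownames(res) <- NULL
  res
}
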