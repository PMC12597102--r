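#' Describe a unit genome
#'
#' A unit genome is one copy of a replicon as it appears in the packaging
#' substrate: a helper-phage genome, a phage-inducible chromosomal island
#' (PICI), a plasmid, or a host chromosome. Headful packaging cuts genophores
#' out of concatemers of such units, starting near the `pac_position` and
#' proceeding in `packaging_direction`.
#'
#' @param name unique reference name.
#' @param length unit length in nt (> 0).
#' @param pac_position 0-based position of the pac site on the unit.
#' @param packaging_direction `"forward"` or `"reverse"`.
#' @param category one of `"phage"`, `"pici"`, `"plasmid"`, `"chromosome"`.
#' @param sequence optional nucleotide string of length `length`. Synthetic
#'   sequences can be generated with [random_dna()].
#' @param circular logical; circular replicons are tiled over a doubled
#'   reference when counting unit copies.
#' @param attB optional 0-based chromosomal integration site (only meaningful
#'   for integrative elements).
#' @return an object of class `unit_genome`.
#' @examples
#' pici <- unit_genome("SeCI", 14800, pac_position = 500, category = "pici")
#' pici$length
#' @export
unit_genome <- function(name, length, pac_position = 0L,
                        packaging_direction = c("forward", "reverse"),
                        category = c("phage", "pici", "plasmid", "chromosome"),
                        sequence = NULL, circular = TRUE, attB = NA_integer_) {
  packaging_direction <- match.arg(packaging_direction)
  category <- match.arg(category)
  length <- as.integer(length)
  pac_position <- as.integer(pac_position)
  if (length <= 0L) stop("unit genome length must be > 0")
  if (pac_position < 0L || pac_position >= length)
    stop("pac_position must satisfy 0 <= pac_position < length")
  if (!is.null(sequence) && nchar(sequence) != length)
    stop("sequence length does not match declared unit length")
  structure(
    list(name = name, length = length, pac_position = pac_position,
         packaging_direction = packaging_direction, category = category,
         sequence = sequence, circular = circular, attB = as.integer(attB)),
    class = "unit_genome")
}

#' @export
print.unit_genome <- function(x, ...) {
  cat(sprintf("<unit_genome> %s: %s, %d nt, pac @ %d (%s)%s\n",
              x$name, x$category, x$length, x$pac_position,
              x$packaging_direction,
              if (isTRUE(x$circular)) ", circular" else ""))
  invisible(x)
}

#' Collect unit genomes into a reference set
#'
#' @param ... `unit_genome` objects (or a single list of them).
#' @return an object of class `reference_set`: a named list of unit genomes.
#' @export
reference_set <- function(...) {
  units <- list(...)
  if (length(units) == 1L && !inherits(units[[1L]], "unit_genome"))
    units <- units[[1L]]
  stopifnot(all(vapply(units, inherits, logical(1), "unit_genome")))
  nms <- vapply(units, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("reference names must be unique")
  names(units) <- nms
  structure(units, class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d references\n", length(x)))
  for (u in x) print(u)
  invisible(x)
}

#' Random nucleotide sequence
#'
#' i.i.d. uniform A/C/G/T drawn from the current R random number generator;
#' wrap in [withr::with_seed()] or call after [set.seed()] for reproducibility.
#'
#' @param n sequence length in nt.
#' @return a single character string of length `n`.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Write a reference set as FASTA plus a sidecar metadata table
#'
#' The sidecar TSV declares, per reference: category, pac position (1-based in
#' the emitted file, GenBank convention), packaging direction, circularity and
#' attB. Together the two files are sufficient to re-create the set with
#' [read_reference_set()].
#'
#' @param refs a `reference_set` whose units carry sequences.
#' @param fasta,meta output paths.
#' @export
write_reference_set <- function(refs, fasta, meta) {
  seqs <- lapply(refs, `[[`, "sequence")
  if (any(vapply(seqs, is.null, logical(1))))
    stop("all references must carry sequences to be written as FASTA")
  dss <- Biostrings::DNAStringSet(unlist(seqs))
  names(dss) <- names(refs)
  Biostrings::writeXStringSet(dss, fasta)
  df <- data.frame(
    name = names(refs),
    category = vapply(refs, `[[`, character(1), "category"),
    length = vapply(refs, `[[`, integer(1), "length"),
    pac_position = vapply(refs, `[[`, integer(1), "pac_position") + 1L,
    packaging_direction = vapply(refs, `[[`, character(1),
                                 "packaging_direction"),
    circular = vapply(refs, function(u) isTRUE(u$circular), logical(1)),
    attB = ifelse(
      is.na(vapply(refs, `[[`, integer(1), "attB")), NA_integer_,
      vapply(refs, `[[`, integer(1), "attB") + 1L),
    stringsAsFactors = FALSE)
  write.table(df, meta, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, meta = meta))
}

#' Read a reference set written by [write_reference_set()]
#'
#' @param fasta,meta paths produced by [write_reference_set()].
#' @return a `reference_set`.
#' @export
read_reference_set <- function(fasta, meta) {
  dss <- Biostrings::readDNAStringSet(fasta)
  names(dss) <- sub("\\s.*$", "", names(dss))
  df <- read.table(meta, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  units <- lapply(seq_len(nrow(df)), function(i) {
    nm <- df$name[i]
    unit_genome(nm, df$length[i], pac_position = df$pac_position[i] - 1L,
                packaging_direction = df$packaging_direction[i],
                category = df$category[i],
                sequence = as.character(dss[[nm]]),
                circular = df$circular[i],
                attB = if (is.na(df$attB[i])) NA_integer_ else df$attB[i] - 1L)
  })
  reference_set(units)
}
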