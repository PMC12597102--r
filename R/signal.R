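# Read-length signal construction: the histogram ("marker") axis that the
# segmentation operates on.

#' Bin read lengths into a length signal
#'
#' Builds the ordered per-bin read-count signal over a length axis, including
#' zero-count bins, which is the marker axis for [cbs_segment()]. With the
#' default 1-nt bins every observed length is its own marker, matching the
#' dense zero/one-abundance structure of long-read length distributions.
#'
#' @param reads numeric vector of read lengths (nt), or a data.frame with a
#'   `length` column.
#' @param bin_width bin width in nt (>= 1).
#' @param range inclusive length range `c(low, high)` to histogram; reads
#'   outside are dropped. Defaults to the observed range.
#' @return an object of class `length_signal`: list with `bin_width`,
#'   `bin_start` (ascending integer start length of each bin) and `counts`.
#' @examples
#' sig <- length_signal(c(100, 100, 250), bin_width = 1, range = c(1, 300))
#' sum(sig$counts)  # 3
#' @export
length_signal <- function(reads, bin_width = 1L, range = NULL) {
  lens <- if (is.data.frame(reads)) reads$length else reads
  lens <- as.numeric(lens)
  bin_width <- as.integer(bin_width)
  if (bin_width < 1L) stop("bin_width must be >= 1")
  if (is.null(range)) {
    if (length(lens) == 0L)
      return(structure(list(bin_width = bin_width, bin_start = integer(),
                            counts = integer()), class = "length_signal"))
    range <- c(floor(min(lens)), ceiling(max(lens)))
  }
  lens <- lens[lens >= range[1] & lens <= range[2]]
  nbin <- as.integer(floor((range[2] - range[1]) / bin_width) + 1L)
  idx <- floor((lens - range[1]) / bin_width) + 1L
  idx[idx > nbin] <- nbin
  counts <- tabulate(idx, nbins = nbin)
  structure(list(bin_width = bin_width,
                 bin_start = as.integer(range[1] + (seq_len(nbin) - 1L) *
                                          bin_width),
                 counts = counts),
            class = "length_signal")
}

#' @export
print.length_signal <- function(x, ...) {
  cat(sprintf("<length_signal> %d bins of %d nt, %d reads, range [%d, %d]\n",
              length(x$counts), x$bin_width, sum(x$counts),
              if (length(x$bin_start)) min(x$bin_start) else NA_integer_,
              if (length(x$bin_start)) max(x$bin_start) + x$bin_width - 1L
              else NA_integer_))
  invisible(x)
}

#' Fallback length window for normal-capsid genophores
#'
#' When fragmentation prevents the segmentation from isolating the
#' normal-capsid peak, reads between `low` and `high` (inclusive) are taken
#' as originating exclusively from normal capsids: the window sits above any
#' small-capsid genophore and below chimeric or error-inflated read lengths,
#' which are excluded.
#'
#' @param reads numeric read lengths (nt) or a data.frame with `length`.
#' @param low,high inclusive window bounds in nt; defaults 25000 and 46000.
#' @return the subset of `reads` with `low <= length <= high` (same type as
#'   the input).
#' @export
normal_fallback_filter <- function(reads, low = 25000, high = 46000) {
  if (low >= high) stop("low must be < high")
  lens <- if (is.data.frame(reads)) reads$length else reads
  keep <- lens >= low & lens <= high
  if (is.data.frame(reads)) reads[keep, , drop = FALSE] else reads[keep]
}
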