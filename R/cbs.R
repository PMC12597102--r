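# Circular binary segmentation of the read-length signal, and delineation of
# capsid-specific genophore length ranges from the resulting segments.

#' Segmentation parameters
#'
#' @param alpha significance level for accepting a change point by
#'   permutation test (0 < alpha < 1). Default 0.01.
#' @param min_width minimum number of markers (bins) per changed segment
#'   (>= 2). Default 2.
#' @param nperm number of permutations per test (>= 100). Default 10000.
#' @param seed integer seed for the permutation stream. Default 1.
#' @return an object of class `cbs_params`.
#' @export
cbs_params <- function(alpha = 0.01, min_width = 2L, nperm = 10000L,
                       seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, min_width >= 2, nperm >= 100)
  structure(list(alpha = alpha, min_width = as.integer(min_width),
                 nperm = as.integer(nperm), seed = as.integer(seed)),
            class = "cbs_params")
}

.perm_p <- function(x, min_width, obs, nperm, alpha) {
  # early stop: once count > ceil(alpha*(nperm+1)) - 1 the split is rejected
  max_exceed <- ceiling(alpha * (nperm + 1)) - 1
  count <- .cbs_perm_count(as.numeric(x), min_width, obs, nperm, max_exceed)
  (count + 1) / (nperm + 1)
}

#' Segment a length signal by circular binary segmentation
#'
#' Recursively splits the bin axis: at each step the arc (i, j] maximising the
#' standardised mean-difference statistic between the arc and its complement
#' is found by exhaustive scan; the split is accepted when its permutation
#' p-value (against `nperm` within-segment permutations) is below `alpha` and
#' every resulting piece holds at least `min_width` markers. Accepted splits
#' are recursed into; finally, adjacent segments whose mean difference is not
#' supported by a two-sample permutation test at `alpha` are merged. The
#' returned segments partition the bin axis.
#'
#' @param signal a [length_signal()].
#' @param params a [cbs_params()].
#' @return data.frame of class `cbs_segments` with columns `first_bin`,
#'   `last_bin` (1-based inclusive bin indices), `n_markers`, `mean_count`,
#'   `start_length`, `end_length` (inclusive nt span of the segment).
#' @export
cbs_segment <- function(signal, params = cbs_params()) {
  stopifnot(inherits(signal, "length_signal"), inherits(params, "cbs_params"))
  x <- as.numeric(signal$counts)
  n <- length(x)
  if (n < 2L) stop("need at least 2 bins to segment")
  if (n < params$min_width) {
    warning("fewer bins than min_width; returning a single segment")
    return(.segments_df(signal, c(1L, n + 1L)))
  }
  .with_seed(params$seed, {
    bounds <- sort(unique(c(1L, n + 1L,
                            .cbs_split(x, 1L, n, params))))
    bounds <- .cbs_merge(x, bounds, params)
    .segments_df(signal, bounds)
  })
}

# recursive splitter over x[lo..hi]; returns internal boundaries (1-based,
# boundary b means a segment break between bins b-1 and b)
.cbs_split <- function(x, lo, hi, params) {
  n <- hi - lo + 1L
  if (n < 2L * params$min_width) return(integer())
  seg <- x[lo:hi]
  if (max(seg) == min(seg)) return(integer())  # constant: nothing to split
  arc <- .cbs_max_arc(seg, params$min_width)
  if (is.na(arc$stat) || arc$stat < 0) return(integer())
  p <- .perm_p(seg, params$min_width, arc$stat, params$nperm, params$alpha)
  if (p >= params$alpha) return(integer())
  cuts <- integer()
  if (arc$i > 0L) cuts <- c(cuts, lo + arc$i)
  if (arc$j < n) cuts <- c(cuts, lo + arc$j)
  if (length(cuts) == 0L) return(integer())
  pieces <- cbind(c(lo, cuts), c(cuts - 1L, hi))
  out <- cuts
  for (r in seq_len(nrow(pieces)))
    out <- c(out, .cbs_split(x, pieces[r, 1L], pieces[r, 2L], params))
  out
}

# merge adjacent segments whose difference a two-sample permutation test does
# not support at alpha
.cbs_merge <- function(x, bounds, params) {
  nperm <- min(params$nperm, 2000L)
  repeat {
    if (length(bounds) <= 2L) return(bounds)
    merged <- FALSE
    for (b in seq(2L, length(bounds) - 1L)) {
      a <- x[bounds[b - 1L]:(bounds[b] - 1L)]
      c_ <- x[bounds[b]:(bounds[b + 1L] - 1L)]
      if (.perm_p2(a, c_, nperm) >= params$alpha) {
        bounds <- bounds[-b]
        merged <- TRUE
        break
      }
    }
    if (!merged) return(bounds)
  }
}

# two-sample permutation test on the absolute mean difference
.perm_p2 <- function(a, b, nperm) {
  pooled <- c(a, b)
  if (max(pooled) == min(pooled)) return(1)
  na <- length(a)
  obs <- abs(mean(a) - mean(b))
  n <- length(pooled)
  count <- 0L
  for (i in seq_len(nperm)) {
    idx <- sample.int(n, na)
    d <- abs(mean(pooled[idx]) - mean(pooled[-idx]))
    if (d >= obs) count <- count + 1L
  }
  (count + 1) / (nperm + 1)
}

.segments_df <- function(signal, bounds) {
  bounds <- sort(unique(as.integer(bounds)))
  first <- bounds[-length(bounds)]
  last <- bounds[-1L] - 1L
  df <- data.frame(
    first_bin = first, last_bin = last,
    n_markers = last - first + 1L,
    mean_count = vapply(seq_along(first), function(i)
      mean(signal$counts[first[i]:last[i]]), numeric(1)),
    start_length = signal$bin_start[first],
    end_length = signal$bin_start[last] + signal$bin_width - 1L)
  class(df) <- c("cbs_segments", "data.frame")
  df
}

#' Delineate a capsid-specific genophore length range from segments
#'
#' Applies the peak rule: the peak is the maximal run of contiguous segments,
#' containing the highest-mean segment inside the search window, whose means
#' are all at least `min_mean`; the range spans from the start of the first
#' to the end of the last such segment. If no segment in the peak reaches
#' `min_mean`, the span of the single highest-mean segment in the window is
#' used as a fallback. Median and 5th/95th percentile lengths are computed
#' from the reads inside the range (inclusive endpoints).
#'
#' @param segments a [cbs_segment()] result.
#' @param search_window inclusive nt window `c(low, high)` in which the peak
#'   is sought (e.g. `c(10000, 25000)` for small capsids, `c(25000, 50000)`
#'   for normal ones).
#' @param reads numeric read lengths (nt) or data.frame with `length`; used
#'   for the within-range summaries.
#' @param min_mean minimum average read count per retained peak segment
#'   (default 2).
#' @param capsid label stored on the result (`"small"` or `"normal"`).
#' @return an object of class `genophore_range`: list with `capsid`,
#'   `min_length`, `max_length`, `n_reads`, `median_length`, `p5_length`,
#'   `p95_length`, `fallback` (logical: highest-mean-segment rule used).
#' @export
delineate_range <- function(segments, search_window, reads, min_mean = 2,
                            capsid = c("small", "normal")) {
  capsid <- match.arg(capsid)
  stopifnot(inherits(segments, "cbs_segments"), length(search_window) == 2L)
  lens <- if (is.data.frame(reads)) reads$length else as.numeric(reads)
  inwin <- which(segments$end_length >= search_window[1] &
                   segments$start_length <= search_window[2])
  if (length(inwin) == 0L)
    stop("no segment intersects the search window; no peak found")
  anchor <- inwin[which.max(segments$mean_count[inwin])]
  fallback <- segments$mean_count[anchor] < min_mean
  if (fallback) {
    lo_seg <- hi_seg <- anchor
  } else {
    ok <- segments$mean_count >= min_mean
    lo_seg <- anchor
    while (lo_seg > 1L && ok[lo_seg - 1L]) lo_seg <- lo_seg - 1L
    hi_seg <- anchor
    while (hi_seg < nrow(segments) && ok[hi_seg + 1L]) hi_seg <- hi_seg + 1L
  }
  rng <- c(segments$start_length[lo_seg], segments$end_length[hi_seg])
  sel <- lens[lens >= rng[1] & lens <= rng[2]]
  qs <- if (length(sel)) quantile(sel, c(0.05, 0.5, 0.95), names = FALSE,
                                  type = 7)
  else rep(NA_real_, 3)
  structure(list(capsid = capsid, min_length = rng[1], max_length = rng[2],
                 n_reads = length(sel), median_length = qs[2],
                 p5_length = qs[1], p95_length = qs[3], fallback = fallback),
            class = "genophore_range")
}

#' @export
print.genophore_range <- function(x, ...) {
  cat(sprintf(
    "<genophore_range> %s capsid: [%d, %d] nt, n=%d, median %.0f (5th-95th %.0f-%.0f)%s\n",
    x$capsid, x$min_length, x$max_length, x$n_reads, x$median_length,
    x$p5_length, x$p95_length,
    if (isTRUE(x$fallback)) " [fallback: highest-mean segment]" else ""))
  invisible(x)
}
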