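# Coverage tracks and the two packaging signatures the analysis looks for:
# the capsid-switch coverage step downstream of the pac site, and the
# distance-decaying lateral-transduction gradient on the chromosome.

#' Per-base coverage from packaging intervals or alignment hits
#'
#' @param intervals data.frame with 0-based half-open `start`/`end` columns
#'   (genophore intervals on a reference or concatemer), or alignment hits
#'   with `ref_start`/`ref_end`.
#' @param ref_length reference length; defaults to the maximum end seen.
#' @return integer vector of per-base coverage (length `ref_length`).
#' @export
coverage_profile <- function(intervals, ref_length = NULL) {
  s <- if ("ref_start" %in% names(intervals)) intervals$ref_start else
    intervals$start
  e <- if ("ref_end" %in% names(intervals)) intervals$ref_end else
    intervals$end
  if (is.null(ref_length)) ref_length <- max(e)
  ir <- IRanges::IRanges(start = s + 1L, end = e)
  as.integer(IRanges::coverage(ir, width = ref_length))
}

#' Detect the capsid-switch coverage step downstream of the pac site
#'
#' When the terminase-concatemer complex fills a small prohead first, the
#' following normal-capsid genophores start one small-capacity downstream of
#' the pac site, producing a step up in concatemer coverage there. Because a
#' complete headful series tiles the concatemer contiguously, the signature
#' is visible in the coverage of normal-capsid reads (pass those intervals),
#' not in the pooled coverage of all capsid types. The step
#' is reported when mean coverage in the window
#' `[pac + small_capacity, pac + small_capacity + w)` exceeds the mean in
#' `[pac, pac + small_capacity)` by at least `min_ratio`; its location is
#' then estimated by an exhaustive single change-point (max-|t|) scan of the
#' binned track around the expected position.
#'
#' @param coverage per-base coverage (from [coverage_profile()]).
#' @param pac 0-based pac position on the track.
#' @param small_capacity small-capsid capacity in nt.
#' @param w comparison window width in nt (default 5000).
#' @param min_ratio minimum downstream/upstream mean-coverage ratio to call a
#'   step (default 1.05: with no capsid switching the ratio stays within
#'   ~1% of unity, while switching lifts it by the conditional probability
#'   that a post-small headful is normal, typically 8% and more).
#' @param bin_width track binning for the change-point scan (default 100 nt).
#' @param search_halfwidth half-width of the scan window around
#'   `pac + small_capacity` (default 10000 nt).
#' @return list with `detected`, `ratio`, `step_position` (0-based track
#'   coordinate, `NA` when not detected) and `offset_from_pac`.
#' @export
detect_capsid_step <- function(coverage, pac, small_capacity, w = 5000,
                               min_ratio = 1.05, bin_width = 100,
                               search_halfwidth = 10000) {
  n <- length(coverage)
  lo1 <- pac + 1L; hi1 <- min(pac + small_capacity, n)
  lo2 <- min(pac + small_capacity + 1L, n); hi2 <- min(pac + small_capacity + w, n)
  m1 <- mean(coverage[lo1:hi1]); m2 <- mean(coverage[lo2:hi2])
  ratio <- if (m1 > 0) m2 / m1 else Inf
  if (!is.finite(ratio) || ratio < min_ratio)
    return(list(detected = FALSE, ratio = ratio, step_position = NA_real_,
                offset_from_pac = NA_real_))
  from <- max(pac, pac + small_capacity - search_halfwidth)
  to <- min(n, pac + small_capacity + search_halfwidth)
  idx <- seq(from + 1L, to)
  nb <- floor(length(idx) / bin_width)
  track <- vapply(seq_len(nb), function(b)
    mean(coverage[idx[((b - 1L) * bin_width + 1L):(b * bin_width)]]),
    numeric(1))
  # exhaustive single change point: best prefix/suffix mean split
  best <- .best_binary_split(track)
  step <- from + (best - 1L) * bin_width + bin_width / 2
  list(detected = TRUE, ratio = ratio, step_position = step,
       offset_from_pac = step - pac)
}

# index b of the first bin of the right piece maximising the standardised
# prefix/suffix mean difference; leftmost tie wins
.best_binary_split <- function(x) {
  n <- length(x)
  S <- cumsum(x); T <- S[n]
  ks <- seq_len(n - 1L)
  z <- abs(S[ks] - ks * T / n) / sqrt(ks * (n - ks))
  which.max(z) + 1L
}

#' Lateral-transduction coverage gradient
#'
#' Bins chromosomal coverage downstream of an integrated element in its
#' packaging direction and reports a Spearman trend statistic: lateral
#' packaging makes the expected coverage decrease with distance from the
#' element.
#'
#' @param coverage per-base chromosome coverage.
#' @param element list with 0-based `start`, `end`, `direction` (as in
#'   [simulate_lateral()]).
#' @param bin_width distance bin in nt (default 5000).
#' @param max_distance how far downstream to follow (default 200000 nt).
#' @return list with `distance` (bin midpoints, nt), `coverage` (mean per
#'   bin), `rho`, `p_value`.
#' @export
lateral_gradient <- function(coverage, element, bin_width = 5000,
                             max_distance = 200000) {
  n <- length(coverage)
  fwd <- identical(element$direction, "forward")
  if (fwd) {
    from <- element$end; to <- min(n, element$end + max_distance)
    seg <- coverage[(from + 1L):to]
  } else {
    to <- element$start; from <- max(0L, element$start - max_distance)
    seg <- rev(coverage[(from + 1L):to])
  }
  nb <- floor(length(seg) / bin_width)
  if (nb < 3L) stop("not enough downstream sequence to form bins")
  mcov <- vapply(seq_len(nb), function(b)
    mean(seg[((b - 1L) * bin_width + 1L):(b * bin_width)]), numeric(1))
  dist <- (seq_len(nb) - 0.5) * bin_width
  if (all(mcov == mcov[1])) {
    rho <- 0; p <- 1
  } else {
    ct <- suppressWarnings(cor.test(dist, mcov, method = "spearman"))
    rho <- unname(ct$estimate); p <- ct$p.value
  }
  list(distance = dist, coverage = mcov, rho = rho, p_value = p)
}
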