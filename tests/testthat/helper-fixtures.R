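# Shared fixtures, built in code at test time.

make_phage <- function(length = 44200L, pac = 2000L)
  unit_genome("phage_E72m5", length, pac_position = pac, category = "phage")

make_pici <- function(length = 14800L, pac = 500L)
  unit_genome("SeCI_SE48", length, pac_position = pac, category = "pici")

# deterministic capsid model without noise, for closed-form checks
rigid_capsid <- function(small = 16500, normal = 45300, p_small = 0,
                         p_switch = 0)
  capsid_model(small, normal, capacity_cv = 0, pac_offset_sd = 0,
               p_small = p_small, p_switch = p_switch)

# a length_signal built directly from a count vector (unit bins starting at 1)
signal_from_counts <- function(counts, bin_width = 1L, start = 1L) {
  structure(list(bin_width = as.integer(bin_width),
                 bin_start = as.integer(start + (seq_along(counts) - 1L) *
                                          bin_width),
                 counts = as.integer(counts)),
            class = "length_signal")
}

# brute-force oracle for the CBS arc statistic: exhaustive O(n^2) scan in
# plain R, independent of the compiled path
oracle_max_arc <- function(x, min_width = 2L) {
  n <- length(x)
  best <- -Inf; bi <- NA; bj <- NA
  T <- sum(x)
  for (i in 0:(n - 1)) for (j in (i + 1):n) {
    k <- j - i
    if (k < min_width || n - k < min_width) next
    v <- abs(sum(x[(i + 1):j]) - k * T / n) / sqrt(k * (n - k))
    if (v > best + 1e-12) { best <- v; bi <- i; bj <- j }
  }
  list(stat = best, i = bi, j = bj)
}

# exponential-background + Gaussian-peak mixture with known contamination
make_mixture <- function(seed, n_bg = 6000, n_peak = 3600, bg_mean = 6000,
                         peak_mean = 16500, peak_sd = 660) {
  set.seed(seed)
  bg <- 1000 + rexp(n_bg, 1 / bg_mean)
  bg <- bg[bg <= 60000]
  peak <- rnorm(n_peak, peak_mean, peak_sd)
  list(lengths = c(bg, peak),
       label = c(rep("bg", length(bg)), rep("peak", n_peak)))
}
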