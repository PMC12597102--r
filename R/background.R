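# Exponential background model for the fragmented-DNA read-length
# distribution, used to estimate the fraction of reads of ambiguous capsid
# origin inside the small-capsid genophore peak.

#' Fit the exponential background model
#'
#' Fits `count = a * exp(b * length)` by least squares to the binned length
#' distribution over the fit domain (default 1000-40000 nt), excluding the
#' bins inside the small-capsid genophore range, whose counts are dominated
#' by full-length genophores rather than fragments. Zero-count bins are
#' included; the fit is initialised from a log-linear regression on the
#' positive bins. The sign of `b` is left free (decay is expected, not
#' enforced).
#'
#' @param signal a [length_signal()] at the segmentation bin width.
#' @param small_range a [delineate_range()] result for the small capsid (or
#'   any list with `min_length`/`max_length`), excluded from the fit.
#' @param fit_domain inclusive nt bounds of the fit domain.
#' @param exclusion_pad widening of the excluded interval on each side, as a
#'   multiple of the range width (default 1.5). The delineated range clips
#'   the genophore peak near its inflection points, so the peak's tails
#'   would otherwise leak into the background fit and inflate it exactly
#'   where the prediction is evaluated.
#' @return an object of class `exp_fit`: list with `a`, `b`, `fit_domain`,
#'   `excluded`, `n_bins`, `rss` and `fitted_at(x)` usable via [predict()].
#' @export
fit_background <- function(signal, small_range,
                           fit_domain = c(1000, 40000),
                           exclusion_pad = 1.5) {
  stopifnot(inherits(signal, "length_signal"))
  mid <- signal$bin_start + (signal$bin_width - 1) / 2
  pad <- exclusion_pad * (small_range$max_length - small_range$min_length)
  excl <- c(small_range$min_length - pad, small_range$max_length + pad)
  keep <- mid >= fit_domain[1] & mid <= fit_domain[2] &
    !(mid >= excl[1] & mid <= excl[2])
  x <- mid[keep]; y <- as.numeric(signal$counts[keep])
  if (sum(y > 0) < 10L) stop("degenerate data: too few non-empty bins ",
                             "remain after exclusion")
  pos <- y > 0
  init <- lm(log(y[pos]) ~ x[pos])
  a0 <- exp(unname(coef(init)[1])); b0 <- unname(coef(init)[2])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(b * x), start = list(a = a0, b = b0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    a <- a0; b <- b0
    rss <- sum((y - a * exp(b * x))^2)
  } else {
    cf <- coef(fit)
    a <- unname(cf["a"]); b <- unname(cf["b"])
    rss <- sum(residuals(fit)^2)
  }
  structure(list(a = a, b = b, fit_domain = fit_domain,
                 excluded = excl,
                 n_bins = length(x), rss = rss,
                 bin_width = signal$bin_width),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "<exp_fit> count = %.4g * exp(%.4g * length); domain [%g, %g] nt minus [%g, %g]; %d bins, RSS %.3g\n",
    x$a, x$b, x$fit_domain[1], x$fit_domain[2], x$excluded[1], x$excluded[2],
    x$n_bins, x$rss))
  invisible(x)
}

#' @export
predict.exp_fit <- function(object, newdata, ...) {
  x <- if (is.list(newdata)) newdata$length else newdata
  object$a * exp(object$b * x)
}

#' Fraction of ambiguous-origin reads in the small-capsid peak
#'
#' Predicts the background (fragmented-DNA) count expected inside the
#' small-capsid genophore range from the exponential fit, and reports it as a
#' fraction of the observed count there. Values are clipped to [0, 1]; a clip
#' at 1 is flagged with a warning because it indicates the background model
#' over-predicts the whole peak.
#'
#' @param fit an [fit_background()] result.
#' @param small_range the small-capsid [delineate_range()] result.
#' @param observed_count_in_range number of reads observed inside the range
#'   (> 0).
#' @return list with `predicted`, `observed`, `fraction`.
#' @export
ambiguous_fraction <- function(fit, small_range, observed_count_in_range) {
  stopifnot(inherits(fit, "exp_fit"), observed_count_in_range > 0)
  w <- fit$bin_width
  starts <- seq(small_range$min_length, small_range$max_length, by = w)
  mids <- starts + (w - 1) / 2
  predicted <- sum(pmax(0, predict(fit, mids)))
  fraction <- predicted / observed_count_in_range
  if (fraction > 1) {
    warning("predicted background exceeds observed peak count; ",
            "fraction clipped to 1")
    fraction <- 1
  }
  list(predicted = predicted, observed = observed_count_in_range,
       fraction = max(0, fraction))
}
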