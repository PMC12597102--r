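# Phage-antibiotic interaction scoring with the four reference models for
# two-agent combinations: Bliss independence, highest single agent (HSA),
# Loewe additivity on fitted 4-parameter log-logistic monotherapy curves,
# and a ZIP-style potency-shift score. Positive mean excess indicates
# synergy, negative antagonism.

#' Build a synergy grid
#'
#' @param conc1,conc2 dose vectors of the two agents (phage input ratio and
#'   antibiotic x MIC); zeros mark monotherapy rows/columns.
#' @param response percent response in \[0, 100\] (viability convention:
#'   100 = highest observed value).
#' @return data.frame of class `synergy_grid`.
#' @export
synergy_grid <- function(conc1, conc2, response) {
  stopifnot(length(conc1) == length(conc2),
            length(conc1) == length(response))
  if (any(response < 0 | response > 100))
    stop("responses must be percentages in [0, 100]")
  if (!any(conc1 > 0 & conc2 == 0) || !any(conc1 == 0 & conc2 > 0))
    stop("grid must include monotherapy rows/columns for both agents")
  if (!any(conc1 > 0 & conc2 > 0))
    stop("grid must include at least one combination cell")
  structure(data.frame(conc1 = conc1, conc2 = conc2, response = response),
            class = c("synergy_grid", "data.frame"))
}

# 4PL fit of response (%) vs dose; returns NULL when not enough dose levels
.fit_4pl <- function(dose, response) {
  lv <- sort(unique(dose))
  if (length(lv) < 4L) return(NULL)
  top0 <- max(response); bot0 <- min(response)
  ec0 <- stats::median(dose[dose > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ bot + (top - bot) / (1 + (dose / ec)^hill),
      start = list(top = top0, bot = bot0, ec = ec0, hill = 1),
      lower = c(top = 0, bot = 0, ec = 1e-12, hill = 0.1),
      upper = c(top = 100, bot = 100, ec = Inf, hill = 20),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  fit
}

.pl4_response <- function(fit, dose) {
  cf <- coef(fit)
  unname(cf["bot"] + (cf["top"] - cf["bot"]) /
           (1 + (dose / cf["ec"])^cf["hill"]))
}

# inverse 4PL: dose producing response E (NA outside the asymptotes)
.pl4_inverse <- function(fit, E) {
  cf <- coef(fit)
  top <- unname(cf["top"]); bot <- unname(cf["bot"])
  eps <- 1e-9
  E <- pmin(pmax(E, bot + eps), top - eps)
  unname(cf["ec"] * ((top - E) / (E - bot))^(1 / cf["hill"]))
}

#' Score a two-agent combination grid against reference models
#'
#' Responses are converted to inhibition fractions (`1 - response/100`,
#' the viability convention). For every combination cell the expected
#' inhibition under each null model is computed from the monotherapy data
#' (Bliss: `yA + yB - yA*yB`; HSA: `max(yA, yB)`; Loewe: dose equivalence on
#' fitted 4PL monotherapy curves; ZIP: Bliss expectation on the fitted,
#' potency-shifted curves) and the excess is `observed - expected`. The
#' overall score per model is the mean excess times 100.
#'
#' @param grid a [synergy_grid()].
#' @return list of class `synergy_scores`: per model a list with `score` and
#'   a per-cell data.frame `cells` (`conc1`, `conc2`, `observed`, `expected`,
#'   `excess`); Loewe and ZIP are `NULL` (with a message) when a monotherapy
#'   curve cannot be fitted from fewer than 4 dose levels.
#' @export
synergy_scores <- function(grid) {
  stopifnot(inherits(grid, "synergy_grid"))
  inh <- 1 - grid$response / 100
  monoA <- grid[grid$conc2 == 0, ]
  monoB <- grid[grid$conc1 == 0, ]
  yA <- function(d) {
    v <- vapply(d, function(x) {
      hit <- monoA$response[monoA$conc1 == x]
      if (length(hit)) 1 - mean(hit) / 100 else NA_real_
    }, numeric(1))
    v
  }
  yB <- function(d) {
    vapply(d, function(x) {
      hit <- monoB$response[monoB$conc2 == x]
      if (length(hit)) 1 - mean(hit) / 100 else NA_real_
    }, numeric(1))
  }
  comb <- grid[grid$conc1 > 0 & grid$conc2 > 0, ]
  obs <- 1 - comb$response / 100
  ya <- yA(comb$conc1); yb <- yB(comb$conc2)
  if (anyNA(ya) || anyNA(yb))
    stop("every combination dose needs a matching monotherapy measurement")

  cells <- function(expected) {
    data.frame(conc1 = comb$conc1, conc2 = comb$conc2, observed = obs,
               expected = expected, excess = obs - expected)
  }
  score <- function(cl) list(score = 100 * mean(cl$excess), cells = cl)

  out <- list(
    bliss = score(cells(ya + yb - ya * yb)),
    hsa = score(cells(pmax(ya, yb))))

  fitA <- .fit_4pl(monoA$conc1, monoA$response)
  fitB <- .fit_4pl(monoB$conc2, monoB$response)
  if (is.null(fitA) || is.null(fitB)) {
    message("monotherapy curve unfittable (fewer than 4 dose levels): ",
            "Loewe and ZIP scores unavailable")
    out$loewe <- NULL
    out$zip <- NULL
  } else {
    # Loewe: expected response E solves d1/DA(E) + d2/DB(E) = 1
    loewe_exp <- mapply(function(d1, d2) {
      f <- function(E) d1 / .pl4_inverse(fitA, E) +
        d2 / .pl4_inverse(fitB, E) - 1
      lo <- max(min(coef(fitA)["bot"], coef(fitB)["bot"])) + 1e-6
      hi <- min(max(coef(fitA)["top"], coef(fitB)["top"])) - 1e-6
      E <- tryCatch(uniroot(f, c(lo, hi), tol = 1e-8)$root,
                    error = function(e) NA_real_)
      if (is.na(E)) {
        # no crossing: additivity expectation saturates at the nearer bound
        E <- if (f(hi) > 0) hi else lo
      }
      1 - E / 100
    }, comb$conc1, comb$conc2)
    out$loewe <- score(cells(loewe_exp))
    # ZIP-style: Bliss expectation on the fitted monotherapy curves
    fa <- 1 - .pl4_response(fitA, comb$conc1) / 100
    fb <- 1 - .pl4_response(fitB, comb$conc2) / 100
    out$zip <- score(cells(fa + fb - fa * fb))
  }
  class(out) <- "synergy_scores"
  out
}

#' @export
print.synergy_scores <- function(x, ...) {
  cat("<synergy_scores> mean excess x 100 (positive = synergy):\n")
  for (m in names(x)) {
    if (is.null(x[[m]])) cat(sprintf("  %-6s unavailable\n", m))
    else cat(sprintf("  %-6s %+.2f\n", m, x[[m]]$score))
  }
  invisible(x)
}
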