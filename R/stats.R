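# Statistical toolkit for transduction experiments: effect sizes, post-hoc
# tests with a compact-letter display, limit-of-detection substitution and
# transduction metrics.

#' Cliff's delta effect size
#'
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n * m)`, computed by a
#' sorted-merge equivalent of the full pairwise comparison.
#'
#' @param x,y numeric samples (non-empty).
#' @return delta in \[-1, 1\]; positive when `x` tends to exceed `y`.
#' @examples
#' cliffs_delta(c(1, 2, 3), c(2, 3, 4))  # -5/9
#' @export
cliffs_delta <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  sy <- sort(y)
  # for each x: #{y < x} and #{y > x} via binary search on the sorted sample
  n_less <- findInterval(x, sy, left.open = TRUE)        # y_j <  x_i
  n_leq <- findInterval(x, sy)                           # y_j <= x_i
  greater <- sum(n_less)
  less <- sum(length(sy) - n_leq)
  (greater - less) / (length(x) * length(y))
}

#' Limit-of-detection substitution
#'
#' Values below the limit of detection are replaced by `lod / sqrt(2)` prior
#' to statistical testing; values at or above the LOD are unchanged.
#'
#' @param values non-negative numeric vector.
#' @param lod limit of detection (> 0), default 10.
#' @return the substituted vector.
#' @examples
#' lod_substitute(c(0, 5, 10, 50))  # 7.07, 7.07, 10, 50
#' @export
lod_substitute <- function(values, lod = 10) {
  stopifnot(lod > 0)
  if (any(values < 0)) stop("negative values are not valid counts")
  ifelse(values < lod, lod / sqrt(2), values)
}

#' Transduction metrics per replicate
#'
#' Transduction frequency is the ratio of transductant-forming units to
#' plaque-forming units (TFU/PFU) per biological replicate. TFU values below
#' the limit of detection are substituted with [lod_substitute()] first.
#'
#' @param table data.frame with columns `TFU_per_ml` and `PFU_per_ml`
#'   (optionally `treatment`, `replicate`).
#' @param lod limit of detection for TFU counts (default 10).
#' @return the input with `TFU_sub` and `frequency` columns plus a
#'   `summary` attribute (mean, sd, median of frequency per treatment).
#' @export
transduction_metrics <- function(table, lod = 10) {
  stopifnot(all(c("TFU_per_ml", "PFU_per_ml") %in% names(table)))
  if (any(table$PFU_per_ml <= 0))
    stop("PFU_per_ml must be > 0 for a defined transduction frequency")
  table$TFU_sub <- lod_substitute(table$TFU_per_ml, lod)
  table$frequency <- table$TFU_sub / table$PFU_per_ml
  grp <- if ("treatment" %in% names(table)) table$treatment else
    rep("all", nrow(table))
  sm <- do.call(rbind, lapply(split(table$frequency, grp), function(v)
    data.frame(mean = mean(v), sd = sd(v), median = median(v),
               n = length(v))))
  sm$treatment <- rownames(sm); rownames(sm) <- NULL
  attr(table, "summary") <- sm[, c("treatment", "mean", "sd", "median", "n")]
  table
}

#' Games-Howell post-hoc test
#'
#' Pairwise comparisons after a Welch-type ANOVA for groups with unequal
#' variances: the standard error of each pairwise difference uses the
#' per-group variances, degrees of freedom follow Welch-Satterthwaite, and
#' p-values refer `t * sqrt(2)` to the studentized range distribution with
#' `k` groups.
#'
#' @param values numeric response.
#' @param groups grouping factor (each group needs >= 2 observations).
#' @return data.frame with `group1`, `group2`, `diff`, `se`, `df`, `p_value`.
#' @export
games_howell <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  ns <- tapply(values, groups, length)
  if (any(ns < 2L)) stop("every group needs >= 2 observations")
  ms <- tapply(values, groups, mean)
  vs <- tapply(values, groups, var)
  k <- nlevels(groups)
  lv <- levels(groups)
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se2 <- vs[i] / ns[i] + vs[j] / ns[j]
    t <- (ms[i] - ms[j]) / sqrt(se2)
    df <- se2^2 / ((vs[i] / ns[i])^2 / (ns[i] - 1) +
                     (vs[j] / ns[j])^2 / (ns[j] - 1))
    p <- ptukey(abs(t) * sqrt(2), k, df, lower.tail = FALSE)
    data.frame(group1 = lv[i], group2 = lv[j],
               diff = unname(ms[i] - ms[j]), se = sqrt(se2),
               df = unname(df), p_value = unname(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' Pairwise rank z-tests with the tie correction, following a
#' Kruskal-Wallis test; p-values are adjusted with `p_adjust_method`.
#'
#' @param values numeric response.
#' @param groups grouping factor.
#' @param p_adjust_method multiplicity adjustment (default `"holm"`).
#' @return data.frame with `group1`, `group2`, `z`, `p_value`, `p_adj`.
#' @export
dunn_test <- function(values, groups, p_adjust_method = "holm") {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rs <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  lv <- levels(groups)
  pairs <- utils::combn(nlevels(groups), 2)
  out <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[i] + 1 / ns[j]))
    z <- (rs[i] - rs[j]) / se
    data.frame(group1 = lv[i], group2 = lv[j], z = unname(z),
               p_value = unname(2 * stats::pnorm(abs(z), lower.tail = FALSE)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$p_adj <- p.adjust(out$p_value, method = p_adjust_method)
  rownames(out) <- NULL
  out
}

#' Compact-letter display from pairwise p-values
#'
#' Groups sharing at least one letter are not significantly different at
#' `alpha` (insert-and-absorb algorithm).
#'
#' @param pairs data.frame with `group1`, `group2` and a p-value column.
#' @param groups character vector of all group names (fixes the order).
#' @param p_col name of the p-value column (default `"p_value"`).
#' @param alpha significance threshold (default 0.05).
#' @return named character vector of letter codes.
#' @export
compact_letters <- function(pairs, groups, p_col = "p_value", alpha = 0.05) {
  k <- length(groups)
  differ <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (r in seq_len(nrow(pairs))) {
    if (pairs[[p_col]][r] < alpha) {
      differ[pairs$group1[r], pairs$group2[r]] <- TRUE
      differ[pairs$group2[r], pairs$group1[r]] <- TRUE
    }
  }
  sets <- list(groups)  # start with one letter containing everyone
  for (g1 in groups) for (g2 in groups) {
    if (g1 < g2 && differ[g1, g2]) {
      for (s in seq_along(sets)) {
        if (all(c(g1, g2) %in% sets[[s]])) {
          a <- setdiff(sets[[s]], g1)
          b <- setdiff(sets[[s]], g2)
          sets[[s]] <- a
          sets <- c(sets, list(b))
        }
      }
      # absorb subsets
      keep <- rep(TRUE, length(sets))
      for (s1 in seq_along(sets)) for (s2 in seq_along(sets))
        if (s1 != s2 && keep[s1] && keep[s2] &&
            all(sets[[s1]] %in% sets[[s2]])) keep[s1] <- FALSE
      sets <- sets[keep]
    }
  }
  letters_out <- setNames(rep("", k), groups)
  for (s in seq_along(sets))
    for (g in sets[[s]])
      letters_out[g] <- paste0(letters_out[g], letters[s])
  letters_out
}

#' Group comparison dispatcher
#'
#' Runs the test battery appropriate for each data type: pairwise Welch
#' t-tests for abundance fractions; one-way ANOVA on log10-transformed
#' counts with Games-Howell pairwise comparisons (optionally excluding
#' 1.5xIQR outliers on the log scale first) for virion and viable-cell
#' counts; Kruskal-Wallis plus Dunn pairwise z-tests for zero-inflated TFU
#' data. All modes attach a compact-letter display at `alpha`.
#'
#' @param values numeric response.
#' @param groups grouping factor.
#' @param design `"welch_t"`, `"games_howell"` or `"kruskal_dunn"`.
#' @param log10_transform log-transform before testing (default `TRUE` for
#'   `games_howell`).
#' @param exclude_outliers drop observations beyond 1.5xIQR of their group on
#'   the (possibly log) scale before variance-based testing (default
#'   `FALSE`); exclusions are recorded in the result.
#' @param alpha significance level for the letter display (default 0.05).
#' @return list with `omnibus` (test statistic and p-value), `pairwise`
#'   (data.frame), `letters`, `excluded` (indices).
#' @export
group_tests <- function(values, groups,
                        design = c("games_howell", "welch_t", "kruskal_dunn"),
                        log10_transform = NULL, exclude_outliers = FALSE,
                        alpha = 0.05) {
  design <- match.arg(design)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (is.null(log10_transform)) log10_transform <- design == "games_howell"
  v <- if (log10_transform) log10(values) else values
  excluded <- integer()
  if (exclude_outliers && design != "kruskal_dunn") {
    for (lv in levels(groups)) {
      idx <- which(groups == lv)
      q <- quantile(v[idx], c(0.25, 0.75), names = FALSE)
      iqr <- q[2] - q[1]
      out <- idx[v[idx] < q[1] - 1.5 * iqr | v[idx] > q[2] + 1.5 * iqr]
      excluded <- c(excluded, out)
    }
    if (length(excluded)) {
      v <- v[-excluded]; groups <- droplevels(groups[-excluded])
    }
  }
  if (design == "kruskal_dunn") {
    om <- kruskal.test(v, groups)
    pw <- dunn_test(v, groups)
    p_col <- "p_adj"
  } else if (design == "games_howell") {
    if (any(tapply(v, groups, length) < 2L))
      stop("every group needs >= 2 observations for variance-based tests")
    om <- oneway.test(v ~ groups)      # Welch ANOVA, unequal variances
    pw <- games_howell(v, groups)
    p_col <- "p_value"
  } else {
    om <- oneway.test(v ~ groups)
    lv <- levels(groups)
    pairs <- utils::combn(length(lv), 2)
    pw <- do.call(rbind, apply(pairs, 2, function(pr) {
      a <- v[groups == lv[pr[1]]]; b <- v[groups == lv[pr[2]]]
      tt <- t.test(a, b)
      data.frame(group1 = lv[pr[1]], group2 = lv[pr[2]],
                 diff = mean(a) - mean(b), p_value = tt$p.value,
                 stringsAsFactors = FALSE)
    }))
    p_col <- "p_value"
  }
  list(omnibus = list(statistic = unname(om$statistic),
                      p_value = om$p.value, method = om$method),
       pairwise = pw,
       letters = compact_letters(pw, levels(groups), p_col = p_col,
                                 alpha = alpha),
       excluded = excluded)
}
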