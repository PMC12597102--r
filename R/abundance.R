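# Quantitative outputs: per-capsid origin abundances and genome-copy
# coverage shares.

#' Per-capsid origin abundance table
#'
#' Fractions of genophore origins within each capsid class, optionally per
#' replicate with across-replicate mean and standard deviation.
#'
#' @param assignments a [classify_reads()] result with a `capsid` column
#'   (see [assign_capsid()]); an optional `replicate` column triggers
#'   replicate aggregation.
#' @param capsids capsid classes to tabulate (default small and normal).
#' @return data.frame with `capsid`, `origin`, `count`, `fraction` (and, with
#'   replicates, `replicate`-level rows plus `mean_fraction`/`sd_fraction`
#'   summaries in the `summary` attribute). Fractions within a capsid sum
#'   to 1; an empty capsid class is flagged with a warning and dropped.
#' @export
abundance_table <- function(assignments, capsids = c("small", "normal")) {
  stopifnot("capsid" %in% names(assignments))
  has_rep <- "replicate" %in% names(assignments)
  tab_one <- function(d, rep_id = NULL) {
    rows <- lapply(capsids, function(cp) {
      dd <- d[d$capsid == cp, , drop = FALSE]
      if (nrow(dd) == 0L) {
        warning("empty capsid class: ", cp)
        return(NULL)
      }
      cnt <- table(dd$origin)
      data.frame(replicate = if (is.null(rep_id)) NA_character_ else rep_id,
                 capsid = cp, origin = names(cnt),
                 count = as.integer(cnt),
                 fraction = as.numeric(cnt) / nrow(dd),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  if (!has_rep) {
    out <- tab_one(assignments)
    out$replicate <- NULL
    return(out)
  }
  out <- do.call(rbind, lapply(split(assignments, assignments$replicate),
                               function(d) tab_one(d, d$replicate[1])))
  rownames(out) <- NULL
  agg <- stats::aggregate(fraction ~ capsid + origin, out,
                          function(v) c(mean = mean(v), sd = sd(v)))
  summary <- data.frame(capsid = agg$capsid, origin = agg$origin,
                        mean_fraction = agg$fraction[, "mean"],
                        sd_fraction = agg$fraction[, "sd"])
  attr(out, "summary") <- summary
  out
}

#' Genome-copy coverage shares
#'
#' The occurrence of each element in the total released virion pool,
#' expressed as the coverage of that reference relative to the summed
#' coverage of all references, in percent. With a replicate dimension the
#' default is to compute shares per replicate and average them; `pooled`
#' sums coverage first.
#'
#' @param coverage named numeric vector of per-reference mean coverage, or a
#'   data.frame with `reference`, `coverage` and optionally `replicate`.
#' @param mode `"per_replicate"` (default) or `"pooled"`.
#' @return data.frame with `reference`, `share_pct` (summing to 100) and,
#'   per-replicate, `sd_pct`.
#' @export
copy_shares <- function(coverage, mode = c("per_replicate", "pooled")) {
  mode <- match.arg(mode)
  if (is.numeric(coverage)) {
    if (all(coverage == 0)) stop("all-zero coverage")
    return(data.frame(reference = names(coverage),
                      share_pct = 100 * coverage / sum(coverage)))
  }
  stopifnot(all(c("reference", "coverage") %in% names(coverage)))
  if (!"replicate" %in% names(coverage) || mode == "pooled") {
    tot <- tapply(coverage$coverage, coverage$reference, sum)
    if (sum(tot) == 0) stop("all-zero coverage")
    return(data.frame(reference = names(tot),
                      share_pct = as.numeric(100 * tot / sum(tot))))
  }
  per <- lapply(split(coverage, coverage$replicate), function(d) {
    tot <- tapply(d$coverage, d$reference, sum)
    data.frame(reference = names(tot),
               share = as.numeric(tot / sum(tot)))
  })
  per <- do.call(rbind, per)
  m <- tapply(per$share, per$reference, mean)
  s <- tapply(per$share, per$reference, sd)
  data.frame(reference = names(m), share_pct = as.numeric(100 * m),
             sd_pct = as.numeric(100 * s))
}
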