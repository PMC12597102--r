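# Origin classification of delineated genophores: per-read category calls,
# unit-copy counting over doubled circular references, and pac-offset /
# terminal-redundancy statistics.

.merged_read_cov <- function(read_start, read_end) {
  ir <- IRanges::reduce(IRanges::IRanges(start = read_start + 1L,
                                         end = read_end))
  sum(IRanges::width(ir))
}

#' Classify reads by genophore origin
#'
#' For every read, the aligned fraction of the read covered by each reference
#' category is computed from merged hit intervals. A read is called
#' `hybrid_lateral` when a mobile element (phage or PICI) and the chromosome
#' each cover at least `min_component` of it and the chromosomal interval is
#' contiguous with the element's integration site (within `attB_tol` nt);
#' otherwise the single category covering at least `min_primary` is assigned;
#' anything else is `ambiguous`.
#'
#' @param hits alignment hits (from [align_exact()], [read_paf()] or
#'   [read_sam()]); records below `mapq_floor` are ignored.
#' @param refs a [reference_set()]; categories, unit lengths and (for the
#'   chromosome) integration sites are taken from it.
#' @param attB 0-based integration site(s) on the chromosome reference, as a
#'   named or unnamed integer vector; defaults to the `attB` fields of the
#'   element units in `refs`.
#' @param min_primary minimum covered fraction for a single-category call
#'   (default 0.8).
#' @param min_component minimum covered fraction per component of a hybrid
#'   call (default 0.2).
#' @param attB_tol contiguity tolerance at the integration junction in nt
#'   (default 100).
#' @param mapq_floor minimum mapping quality (default 10).
#' @param fold_hybrid_into_chromosome report hybrids as `chromosome`
#'   (default `FALSE`).
#' @return data.frame of class `origin_assignments`: `read_id`,
#'   `read_length`, `origin`, `reference`, `unit_copies`, `covered_fraction`.
#' @export
classify_reads <- function(hits, refs, attB = NULL, min_primary = 0.8,
                           min_component = 0.2, attB_tol = 100L,
                           mapq_floor = 10, fold_hybrid_into_chromosome = FALSE) {
  stopifnot(inherits(refs, "reference_set"))
  cat_of <- vapply(refs, `[[`, character(1), "category")
  unit_len <- vapply(refs, `[[`, integer(1), "length")
  if (is.null(attB)) {
    ab <- vapply(refs, `[[`, integer(1), "attB")
    attB <- ab[!is.na(ab)]
  }
  hits <- hits[hits$mapq >= mapq_floor, , drop = FALSE]
  ids <- unique(hits$read_id)
  res <- lapply(split(hits, factor(hits$read_id, levels = ids)), function(h) {
    L <- h$read_length[1]
    by_ref <- split(h, h$reference)
    cov <- vapply(by_ref, function(g)
      .merged_read_cov(g$read_start, g$read_end), numeric(1))
    frac <- cov / L
    cats <- cat_of[names(cov)]
    cat_frac <- tapply(frac, cats, sum)
    mge_cats <- intersect(c("phage", "pici"), names(cat_frac))
    origin <- "ambiguous"; reference <- NA_character_; copies <- NA_real_
    is_hybrid <- FALSE
    chr_frac <- if ("chromosome" %in% names(cat_frac))
      cat_frac[["chromosome"]] else 0
    if (length(mge_cats) && chr_frac >= min_component) {
      best_mge <- mge_cats[which.max(cat_frac[mge_cats])]
      if (cat_frac[[best_mge]] >= min_component) {
        chrom_hits <- h[cats[match(h$reference, names(cov))] == "chromosome", ,
                        drop = FALSE]
        near_attB <- any(vapply(attB, function(a)
          any(abs(chrom_hits$ref_start - a) <= attB_tol |
                abs(chrom_hits$ref_end - a) <= attB_tol), logical(1)))
        if (near_attB) {
          is_hybrid <- TRUE
          origin <- if (fold_hybrid_into_chromosome) "chromosome" else
            "hybrid_lateral"
          mge_refs <- names(cov)[cats == best_mge]
          reference <- mge_refs[which.max(cov[mge_refs])]
          copies <- sum(cov[mge_refs]) / unit_len[[reference]]
        }
      }
    }
    if (!is_hybrid) {
      top <- names(cat_frac)[which.max(cat_frac)]
      if (cat_frac[[top]] >= min_primary) {
        origin <- top
        refs_in <- names(cov)[cats == top]
        reference <- refs_in[which.max(cov[refs_in])]
        if (top %in% c("phage", "pici", "plasmid"))
          copies <- sum(cov[refs_in]) / unit_len[[reference]]
      }
    }
    data.frame(read_id = h$read_id[1], read_length = L, origin = origin,
               reference = reference, unit_copies = copies,
               covered_fraction = max(cat_frac), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(read_id = character(), read_length = integer(),
                      origin = character(), reference = character(),
                      unit_copies = numeric(), covered_fraction = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("origin_assignments", "data.frame")
  out
}

#' Count unit-genome copies in one read
#'
#' Total aligned read length attributable to a circularly permutable unit,
#' divided by the unit length. Alignments are expected to have been produced
#' against a doubled reference (as [align_exact()] does for circular units)
#' so that circular permutation does not split the tiling.
#'
#' @param hits alignment hits of a single read against the unit's reference.
#' @param unit_length the unit genome length in nt.
#' @return copies as a float (e.g. 3.0 for an exact tandem trimer).
#' @export
count_unit_copies <- function(hits, unit_length) {
  if (nrow(hits) == 0L) return(0)
  .merged_read_cov(hits$read_start, hits$read_end) / unit_length
}

#' Assign capsid labels from delineated genophore length ranges
#'
#' @param assignments an [classify_reads()] result (or any data.frame with
#'   `read_length`).
#' @param small_range,normal_range [delineate_range()] results (either may be
#'   `NULL`).
#' @return `assignments` with a `capsid` column: `"small"`, `"normal"` or
#'   `"fragment"` for reads in neither range.
#' @export
assign_capsid <- function(assignments, small_range = NULL,
                          normal_range = NULL) {
  len <- assignments$read_length
  capsid <- rep("fragment", length(len))
  if (!is.null(normal_range))
    capsid[len >= normal_range$min_length &
             len <= normal_range$max_length] <- "normal"
  if (!is.null(small_range))
    capsid[len >= small_range$min_length &
             len <= small_range$max_length] <- "small"
  assignments$capsid <- capsid
  assignments
}

#' Packaging-initiation offsets and terminal redundancy
#'
#' Recovers, per classified mobile-element read, the physical genophore start
#' in unit coordinates (for reverse-strand reads this is the alignment
#' position of the read's last base), expresses it as a signed offset from
#' the pac site along the packaging direction, and summarises terminal
#' redundancy (`unit_copies` minus its floor) as median and 5th-95th
#' percentiles.
#'
#' @param assignments a [classify_reads()] result.
#' @param hits the hits the assignments were derived from (must carry
#'   `unit_start`, i.e. come from [align_exact()], or `ref_start` within the
#'   unit).
#' @param refs a [reference_set()].
#' @param origin which origin category to summarise (default `"pici"`).
#' @return list with `offsets` (nt, signed along packaging direction),
#'   `offset_median`, `offset_sd`, `redundancy` (fraction of unit),
#'   `redundancy_median`, `redundancy_p5`, `redundancy_p95`.
#' @export
pac_offset_stats <- function(assignments, hits, refs, origin = "pici") {
  sel <- assignments[assignments$origin == origin &
                       !is.na(assignments$reference), , drop = FALSE]
  if (nrow(sel) == 0L) stop("no non-ambiguous assignments with origin ",
                            origin)
  offs <- rep(NA_real_, nrow(sel))
  for (i in seq_len(nrow(sel))) {
    u <- refs[[sel$reference[i]]]
    h <- hits[hits$read_id == sel$read_id[i] &
                hits$reference == sel$reference[i], , drop = FALSE]
    if (nrow(h) == 0L) next
    plus <- h$strand[1] == "+"
    anchor <- if (plus) h[which.min(h$read_start), , drop = FALSE]
    else h[which.max(h$read_end), , drop = FALSE]
    us <- if ("unit_start" %in% names(h)) anchor$unit_start
    else anchor$ref_start %% u$length
    d <- (us - u$pac_position) %% u$length
    if (d > u$length / 2) d <- d - u$length
    if (u$packaging_direction == "reverse") d <- -d
    offs[i] <- d
  }
  offs <- offs[!is.na(offs)]
  red <- sel$unit_copies - floor(sel$unit_copies)
  list(offsets = offs,
       offset_median = median(offs), offset_sd = sd(offs),
       redundancy = red,
       redundancy_median = median(red),
       redundancy_p5 = quantile(red, 0.05, names = FALSE),
       redundancy_p95 = quantile(red, 0.95, names = FALSE))
}
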