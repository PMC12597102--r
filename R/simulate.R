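# Headful-packaging simulator: generates labelled synthetic long reads with
# the statistical structure the downstream analysis assumes (terminally
# redundant, circularly permuted genophores cut from concatemers with
# imprecise pac initiation, two capsid capacities with switching, in-situ
# lateral packaging into the chromosome, rare plasmid packaging, and
# length-dependent fragmentation).

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  expr
}

#' Capsid capacity and switching model
#'
#' Two capsid types compete for the same terminase-concatemer complex: normal
#' phage proheads and small, satellite-remodelled proheads whose capacity is
#' roughly 37% of the normal one. Capacities are drawn per headful from a
#' Normal distribution with a per-type coefficient of variation; the complex
#' may switch capsid type between consecutive headfuls.
#'
#' @param small_capacity_mean,normal_capacity_mean mean headful capacity in nt;
#'   must satisfy `0 < small < normal`.
#' @param capacity_cv coefficient of variation of the per-headful capacity;
#'   a single value or a named vector `c(small = , normal = )`.
#' @param pac_offset_sd standard deviation (nt) of the Normal jitter of the
#'   first packaging initiation around the pac site.
#' @param p_small probability that a given headful goes into a small prohead.
#' @param p_switch probability that the capsid type is re-drawn (with
#'   probability `p_small` of being small) between consecutive headfuls.
#' @return an object of class `capsid_model`.
#' @export
capsid_model <- function(small_capacity_mean, normal_capacity_mean,
                         capacity_cv = c(small = 0.04, normal = 0.02),
                         pac_offset_sd = 300, p_small = 0.5, p_switch = 0.3) {
  if (!(small_capacity_mean > 0 && small_capacity_mean < normal_capacity_mean))
    stop("need 0 < small_capacity_mean < normal_capacity_mean")
  if (length(capacity_cv) == 1L)
    capacity_cv <- c(small = unname(capacity_cv), normal = unname(capacity_cv))
  stopifnot(all(c("small", "normal") %in% names(capacity_cv)),
            all(capacity_cv >= 0), pac_offset_sd >= 0,
            p_small >= 0, p_small <= 1, p_switch >= 0, p_switch <= 1)
  structure(list(small_capacity_mean = small_capacity_mean,
                 normal_capacity_mean = normal_capacity_mean,
                 capacity_cv = capacity_cv, pac_offset_sd = pac_offset_sd,
                 p_small = p_small, p_switch = p_switch),
            class = "capsid_model")
}

#' Lateral (in-situ) packaging model
#'
#' Lateral transduction arises when packaging initiates from the pac site of
#' an element still integrated in the chromosome: the headful series proceeds
#' from the element into flanking host DNA, so the expected chromosomal
#' coverage decays with distance from the element in the packaging direction.
#'
#' @param series_min,series_max support of the distribution of the number of
#'   consecutive headfuls per initiation (default 2-12).
#' @param series_weights optional probability weights over
#'   `series_min:series_max` (default uniform).
#' @param p_in_situ probability that a satellite packaging initiation happens
#'   before excision (i.e. in situ, on the chromosome) rather than on an
#'   excised-element concatemer.
#' @return an object of class `lateral_model`.
#' @export
lateral_model <- function(series_min = 2L, series_max = 12L,
                          series_weights = NULL, p_in_situ = 0.2) {
  series_min <- as.integer(series_min); series_max <- as.integer(series_max)
  stopifnot(series_min >= 1L, series_max >= series_min,
            p_in_situ >= 0, p_in_situ <= 1)
  support <- series_min:series_max
  if (is.null(series_weights)) series_weights <- rep(1, length(support))
  stopifnot(length(series_weights) == length(support), all(series_weights >= 0))
  structure(list(series_min = series_min, series_max = series_max,
                 series_weights = series_weights / sum(series_weights),
                 p_in_situ = p_in_situ),
            class = "lateral_model")
}

#' Length-dependent fragmentation model
#'
#' Models the background of sub-genophore reads produced by DNA breakage
#' during extraction and library preparation: each molecule receives a
#' Poisson(`break_rate` x length) number of uniformly placed breaks, so longer
#' molecules are more likely to fragment.
#'
#' @param break_rate expected breaks per nt (>= 0).
#' @param min_emitted_length pieces shorter than this are discarded (nt).
#' @return an object of class `fragmentation_model`.
#' @export
fragmentation_model <- function(break_rate, min_emitted_length = 500L) {
  stopifnot(break_rate >= 0, min_emitted_length >= 1)
  structure(list(break_rate = break_rate,
                 min_emitted_length = as.integer(min_emitted_length)),
            class = "fragmentation_model")
}

#' Build a concatemer of unit genomes
#'
#' Rolling-circle replication produces head-to-tail concatemers of the unit
#' genome; headful packaging cuts genophores out of them.
#'
#' @param unit a [unit_genome()].
#' @param n_units number of tandem copies (>= 1).
#' @return an object of class `concatemer` with elements `unit`, `n_units`,
#'   `length` and (when the unit carries one) `sequence`.
#' @examples
#' u <- unit_genome("SeCI", 14800, category = "pici")
#' cc <- build_concatemer(u, 3)
#' cc$length                    # 44400
#' concat_to_unit(cc, 29600)    # 0
#' @export
build_concatemer <- function(unit, n_units) {
  stopifnot(inherits(unit, "unit_genome"))
  n_units <- as.integer(n_units)
  if (is.na(n_units) || n_units < 1L) stop("n_units must be >= 1")
  seq <- if (!is.null(unit$sequence)) strrep(unit$sequence, n_units)
  structure(list(unit = unit, n_units = n_units,
                 length = unit$length * n_units, sequence = seq),
            class = "concatemer")
}

#' Map a concatemer position to its unit-genome position
#'
#' @param concatemer a [build_concatemer()] result.
#' @param pos 0-based position(s) on the concatemer.
#' @return 0-based position(s) on the unit genome (`pos` modulo unit length).
#' @export
concat_to_unit <- function(concatemer, pos) {
  stopifnot(all(pos >= 0), all(pos < concatemer$length))
  pos %% concatemer$unit$length
}

.draw_capsid <- function(p_small) if (runif(1) < p_small) "small" else "normal"

.draw_capacity <- function(capsid, model) {
  mu <- if (capsid == "small") model$small_capacity_mean else
    model$normal_capacity_mean
  cv <- unname(model$capacity_cv[[capsid]])
  max(1L, as.integer(round(rnorm(1, mu, cv * mu))))
}

#' Simulate one headful packaging series along a concatemer
#'
#' The first genophore starts at the unit's pac site plus Normal(0,
#' `pac_offset_sd`) jitter (truncated to the concatemer); each subsequent
#' genophore starts where the previous one ended; per-headful capacities are
#' drawn from the capsid model; the capsid type of the first headful is drawn
#' with `p_small` and subsequent headfuls are independently re-drawn with
#' probability `p_switch`, otherwise inherited. The series stops when the
#' remaining concatemer cannot hold the next capacity.
#'
#' @param concatemer a [build_concatemer()] result.
#' @param capsid a [capsid_model()].
#' @param seed optional integer seed for local reproducibility.
#' @param max_headfuls optional cap on the number of headfuls per series.
#' @return a data.frame with one row per genophore: `start`, `end` (0-based
#'   half-open concatemer coordinates), `length`, `capsid`, `headful`.
#' @export
simulate_headful_series <- function(concatemer, capsid, seed = NULL,
                                    max_headfuls = Inf) {
  stopifnot(inherits(concatemer, "concatemer"),
            inherits(capsid, "capsid_model"))
  .with_seed(seed, {
    L <- concatemer$length
    start <- concatemer$unit$pac_position +
      round(rnorm(1, 0, capsid$pac_offset_sd))
    start <- min(max(start, 0), L - 1L)
    type <- .draw_capsid(capsid$p_small)
    out <- list(); k <- 0L
    repeat {
      if (k >= max_headfuls) break
      cap <- .draw_capacity(type, capsid)
      if (start + cap > L) break
      k <- k + 1L
      out[[k]] <- data.frame(start = start, end = start + cap, length = cap,
                             capsid = type, headful = k,
                             stringsAsFactors = FALSE)
      start <- start + cap
      if (runif(1) < capsid$p_switch) type <- .draw_capsid(capsid$p_small)
    }
    if (k == 0L)
      return(data.frame(start = integer(), end = integer(),
                        length = integer(), capsid = character(),
                        headful = integer(), stringsAsFactors = FALSE))
    do.call(rbind, out)
  })
}

#' Simulate lateral (in-situ) packaging from an integrated element
#'
#' Packaging initiates at the element's pac site on the chromosome before
#' excision and proceeds in the element's packaging direction into flanking
#' host DNA; the number of consecutive headfuls per initiation is drawn from
#' the lateral model's series-length distribution.
#'
#' @param chromosome a [unit_genome()] of category `"chromosome"` describing
#'   the (element-containing) chromosome.
#' @param element a list with 0-based fields `start`, `end` (half-open
#'   interval of the integrated element on the chromosome), `pac` (chromosomal
#'   coordinate of the element's pac site) and `direction` (`"forward"` for
#'   packaging toward increasing coordinates, `"reverse"` otherwise).
#' @param lateral a [lateral_model()].
#' @param capsid a [capsid_model()].
#' @param n_initiations number of independent packaging initiations.
#' @param seed optional integer seed.
#' @return a data.frame with one row per genophore: `initiation`, `headful`,
#'   `start`, `end` (0-based half-open chromosome coordinates), `length`,
#'   `capsid`, `origin` (`"element"`, `"hybrid"` or `"chromosome"`).
#' @export
simulate_lateral <- function(chromosome, element, lateral, capsid,
                             n_initiations = 1L, seed = NULL) {
  stopifnot(inherits(chromosome, "unit_genome"),
            chromosome$category == "chromosome",
            inherits(lateral, "lateral_model"),
            inherits(capsid, "capsid_model"))
  L <- chromosome$length
  if (element$start < 0 || element$end > L || element$start >= element$end)
    stop("element interval lies outside the chromosome")
  if (element$pac < element$start || element$pac >= element$end)
    stop("element pac site must lie inside the element interval")
  fwd <- identical(element$direction, "forward")
  support <- lateral$series_min:lateral$series_max
  .with_seed(seed, {
    rows <- vector("list", n_initiations)
    for (i in seq_len(n_initiations)) {
      m <- sample(support, 1L, prob = lateral$series_weights)
      jit <- round(rnorm(1, 0, capsid$pac_offset_sd))
      pos <- element$pac + if (fwd) jit else -jit
      pos <- min(max(pos, 0), L - 1L)
      type <- .draw_capsid(capsid$p_small)
      gen <- list(); k <- 0L
      while (k < m) {
        cap <- .draw_capacity(type, capsid)
        s <- if (fwd) pos else pos - cap
        e <- if (fwd) pos + cap else pos
        if (s < 0 || e > L) break
        k <- k + 1L
        ov <- min(e, element$end) - max(s, element$start)
        origin <- if (ov <= 0) "chromosome" else
          if (s >= element$start && e <= element$end) "element" else "hybrid"
        gen[[k]] <- data.frame(initiation = i, headful = k, start = s,
                               end = e, length = cap, capsid = type,
                               origin = origin, stringsAsFactors = FALSE)
        pos <- if (fwd) e else s
        if (runif(1) < capsid$p_switch) type <- .draw_capsid(capsid$p_small)
      }
      rows[[i]] <- if (k > 0L) do.call(rbind, gen)
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(initiation = integer(), headful = integer(),
                        start = integer(), end = integer(),
                        length = integer(), capsid = character(),
                        origin = character(), stringsAsFactors = FALSE)
    out
  })
}

#' Fragment genophores into a background of sub-genophore reads
#'
#' Each genophore receives a Poisson(`break_rate` x length) number of breaks
#' at uniform positions. Unbroken genophores keep their capsid truth label;
#' emitted pieces are labelled `"fragment"` and pieces shorter than
#' `min_emitted_length` are dropped.
#'
#' @param genophores data.frame with at least a `length` column (plus any
#'   bookkeeping columns, which are carried through).
#' @param frag a [fragmentation_model()].
#' @param seed optional integer seed.
#' @return the input rows expanded into pieces, with columns `piece_start`,
#'   `piece_end` (0-based half-open offsets within the parent genophore),
#'   `length` (piece length), `intact` (logical) and `capsid` set to
#'   `"fragment"` for non-intact pieces.
#' @export
simulate_fragmentation <- function(genophores, frag, seed = NULL) {
  stopifnot(inherits(frag, "fragmentation_model"),
            is.data.frame(genophores), "length" %in% names(genophores))
  .with_seed(seed, {
    n <- nrow(genophores)
    if (n == 0L) {
      out <- genophores
      out$piece_start <- integer(); out$piece_end <- integer()
      out$intact <- logical()
      return(out)
    }
    nb <- rpois(n, frag$break_rate * genophores$length)
    pieces <- lapply(seq_len(n), function(i) {
      L <- genophores$length[i]
      row <- genophores[i, , drop = FALSE]
      if (nb[i] == 0L) {
        row$piece_start <- 0L; row$piece_end <- L; row$intact <- TRUE
        return(row)
      }
      cuts <- sort(unique(pmin(pmax(floor(runif(nb[i]) * L), 1L), L - 1L)))
      bounds <- c(0L, cuts, L)
      ps <- bounds[-length(bounds)]; pe <- bounds[-1L]
      keep <- (pe - ps) >= frag$min_emitted_length
      if (!any(keep)) return(NULL)
      out <- row[rep(1L, sum(keep)), , drop = FALSE]
      out$piece_start <- ps[keep]; out$piece_end <- pe[keep]
      out$length <- pe[keep] - ps[keep]
      if ("capsid" %in% names(out)) out$capsid <- "fragment"
      out$intact <- FALSE
      out
    })
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    out
  })
}
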