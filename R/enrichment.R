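# Distribution of disease variants along the transmembrane helices:
# per-helix counts (with or without the +/-5 flank windows), chi-square
# goodness-of-fit against a uniform M1-M4 expectation, center-relative
# histograms, and zero-coverage positions.

#' Count variants per transmembrane helix
#'
#' Each variant is assigned to at most one helix via
#' \code{\link{assign_helix}}; positions outside every helix (or in a flank
#' when \code{flank_included = FALSE}) are excluded from the counts but
#' reported.
#'
#' @param variants data frame with columns \code{protein_id} and \code{pos}.
#' @param topologies a \code{TopologyRegistry} (or named list of
#'   \code{TMTopology}); every variant's protein must be present.
#' @param flank_included count positions within the flank windows as part
#'   of the adjacent helix (default \code{TRUE} counts core only when
#'   \code{FALSE}).
#' @return list of class \code{HelixCounts}: \code{counts} (named integer
#'   vector M1..M4), \code{total}, \code{outside}, \code{flank_included}.
#' @export
count_by_helix <- function(variants, topologies, flank_included = FALSE) {
  tops <- if (inherits(topologies, "TopologyRegistry")) topologies$topologies
          else topologies
  counts <- setNames(integer(4), .HELIX_IDS)
  outside <- 0L
  for (i in seq_len(nrow(variants))) {
    top <- tops[[variants$protein_id[i]]]
    if (is.null(top))
      stop("no topology for protein '", variants$protein_id[i], "'",
           call. = FALSE)
    a <- assign_helix(top, variants$pos[i], flank_included = flank_included)
    if (a$region == "outside") outside <- outside + 1L
    else counts[a$helix] <- counts[a$helix] + 1L
  }
  structure(list(counts = counts, total = sum(counts), outside = outside,
                 flank_included = flank_included),
            class = "HelixCounts")
}

#' @export
print.HelixCounts <- function(x, ...) {
  cat(sprintf("Variants per helix (%s flanks): %s; total %d, outside %d\n",
              if (x$flank_included) "with" else "without",
              paste(names(x$counts), x$counts, sep = "=", collapse = ", "),
              x$total, x$outside))
  invisible(x)
}

#' Chi-square goodness-of-fit of the per-helix variant distribution
#'
#' Tests the observed M1--M4 counts against the distribution expected by
#' chance. The default expectation is equal counts across the four helices
#' (the default of the standard chi-square goodness-of-fit routine);
#' \code{expected = "length"} weights the expectation by helix length
#' instead. The p-value comes from the exact chi-square survival function
#' with 3 degrees of freedom.
#'
#' @param counts a \code{HelixCounts} (or named numeric vector of 4 counts).
#' @param expected \code{"equal"} or \code{"length"}.
#' @param helix_lengths named lengths of M1..M4, required for
#'   \code{expected = "length"}.
#' @return list of class \code{ChiSquareResult}: \code{statistic},
#'   \code{df}, \code{p_value}, \code{expected}.
#' @examples
#' chisquare_uniform(c(M1 = 27, M2 = 39, M3 = 16, M4 = 4))
#' @export
chisquare_uniform <- function(counts, expected = c("equal", "length"),
                              helix_lengths = NULL) {
  expected <- match.arg(expected)
  obs <- if (inherits(counts, "HelixCounts")) counts$counts else counts
  stopifnot(length(obs) == 4L)
  if (sum(obs) == 0) stop("no variants to test (total = 0)", call. = FALSE)
  p <- if (expected == "equal") rep(1 / 4, 4) else {
    if (is.null(helix_lengths))
      stop("expected = 'length' requires helix_lengths", call. = FALSE)
    helix_lengths <- helix_lengths[names(obs)]
    helix_lengths / sum(helix_lengths)
  }
  ht <- suppressWarnings(chisq.test(obs, p = p))
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = unname(ht$p.value), expected = ht$expected),
            class = "ChiSquareResult")
}

#' @export
print.ChiSquareResult <- function(x, ...) {
  cat(sprintf("chi-square = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Histogram of variant positions relative to helix centers
#'
#' Positions of variants expressed as a signed distance in residues from
#' the central residue of their helix (negative toward the extracellular
#' space, positive toward the cytosol; see \code{\link{center_offset}}).
#' Flank positions are tagged separately so they stay distinguishable from
#' core-helix counts.
#'
#' @inheritParams count_by_helix
#' @return long-format data frame: \code{helix}, \code{offset},
#'   \code{region} (\code{core}/\code{flank}), \code{count}.
#' @export
position_histogram <- function(variants, topologies) {
  tops <- if (inherits(topologies, "TopologyRegistry")) topologies$topologies
          else topologies
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    top <- tops[[variants$protein_id[i]]]
    if (is.null(top))
      stop("no topology for protein '", variants$protein_id[i], "'",
           call. = FALSE)
    a <- assign_helix(top, variants$pos[i])
    if (a$region == "outside") next
    co <- center_offset(top, variants$pos[i])
    rows[[length(rows) + 1L]] <- data.frame(helix = co$helix,
                                            offset = co$offset,
                                            region = co$region,
                                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(helix = character(), offset = integer(),
                      region = character(), count = integer(),
                      stringsAsFactors = FALSE))
  long <- do.call(rbind, rows)
  agg <- aggregate(list(count = rep(1L, nrow(long))),
                   by = long[c("helix", "offset", "region")], FUN = sum)
  agg <- agg[order(agg$helix, agg$offset, agg$region), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Number of core-helix positions with no observed disease variant
#'
#' Counts the center-relative offsets within the named helix of the
#' reference topology that carry zero variants (e.g. the observation that
#' M1 shows more uncovered positions than the pore-lining M2).
#'
#' @inheritParams count_by_helix
#' @param helix_id \code{"M1"}..\code{"M4"}.
#' @param ref_protein protein whose helix span defines the offset range;
#'   defaults to the first topology.
#' @return integer count of uncovered core offsets.
#' @export
zero_coverage_positions <- function(variants, topologies, helix_id,
                                    ref_protein = NULL) {
  tops <- if (inherits(topologies, "TopologyRegistry")) topologies$topologies
          else topologies
  stopifnot(helix_id %in% .HELIX_IDS)
  ref_protein <- ref_protein %||% names(tops)[1]
  top <- tops[[ref_protein]]
  h <- top$helices[top$helices$helix_id == helix_id, ]
  offsets <- vapply(seq(h$start, h$end),
                    function(p) center_offset(top, p)$offset, integer(1))
  hist <- position_histogram(variants, tops)
  covered <- hist$offset[hist$helix == helix_id & hist$region == "core" &
                           hist$count > 0]
  sum(!offsets %in% covered)
}
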