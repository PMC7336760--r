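# Transmembrane topology: M1-M4 helix spans, membrane orientation, M2
# prime numbering anchored at the conserved 9' leucine, and signed
# center-relative helix coordinates.
#
# Helix boundaries are configuration data (SwissProt TRANSMEM-style
# annotations are release-dependent), snapshotted in the packaged config;
# they are never computed here.

.HELIX_IDS <- c("M1", "M2", "M3", "M4")
# Cys-loop subunits cross the membrane out-in-out-in: the N-terminal side
# of M1 and M3 is extracellular, of M2 and M4 cytoplasmic.
.HELIX_NSIDE <- c(M1 = "extracellular", M2 = "cytoplasmic",
                  M3 = "extracellular", M4 = "cytoplasmic")

#' Load a transmembrane-topology registry from a YAML config
#'
#' The config lists, per protein, the four helix spans (1-based inclusive),
#' the N-terminal membrane side of each helix, the flank width used for
#' near-helix assignment, and the prime-numbering anchors. The packaged
#' config (\code{system.file("extdata", "topology_cysloop.yaml",
#' package = "cysloop")}) carries the GABA-A alpha-2 (GABRA2) entry with
#' the reference anchor Leu291 = 9'.
#'
#' @param path path to the YAML topology config; defaults to the packaged
#'   registry.
#' @return A list of class \code{TopologyRegistry} with elements
#'   \code{topologies} (named list of \code{TMTopology}: \code{protein_id},
#'   \code{helices} data frame, \code{flank}) and \code{anchors} (named list
#'   of \code{PrimeAnchor}: \code{protein_id}, \code{anchor_pos},
#'   \code{anchor_prime}).
#' @export
load_topology <- function(path = system.file("extdata", "topology_cysloop.yaml",
                                             package = "cysloop")) {
  if (!file.exists(path)) stop("topology config not found: ", path, call. = FALSE)
  cfg <- yaml::yaml.load_file(path)
  flank_default <- if (!is.null(cfg$flank)) as.integer(cfg$flank) else 5L
  if (is.na(flank_default) || flank_default < 0L)
    stop("topology config: flank must be a non-negative integer", call. = FALSE)
  if (is.null(cfg$proteins) || length(cfg$proteins) == 0L)
    stop("topology config: no proteins defined", call. = FALSE)
  topologies <- lapply(names(cfg$proteins), function(pid) {
    entry <- cfg$proteins[[pid]]
    hx <- entry$helices
    missing_hx <- setdiff(.HELIX_IDS, names(hx))
    if (length(missing_hx) > 0L)
      stop(sprintf("topology config: protein '%s' is missing helix %s",
                   pid, paste(missing_hx, collapse = ", ")), call. = FALSE)
    helices <- do.call(rbind, lapply(.HELIX_IDS, function(h) {
      start <- as.integer(hx[[h]]$start)
      end <- as.integer(hx[[h]]$end)
      side <- if (!is.null(hx[[h]]$n_term_side)) hx[[h]]$n_term_side else .HELIX_NSIDE[[h]]
      if (is.na(start) || is.na(end) || start >= end)
        stop(sprintf("topology config: protein '%s' helix %s: need start < end",
                     pid, h), call. = FALSE)
      if (!identical(side, .HELIX_NSIDE[[h]]))
        stop(sprintf(
          "topology config: protein '%s' helix %s: n_term_side '%s' breaks the alternating out/in orientation (expected '%s')",
          pid, h, side, .HELIX_NSIDE[[h]]), call. = FALSE)
      data.frame(helix_id = h, start = start, end = end,
                 n_term_side = side, stringsAsFactors = FALSE)
    }))
    for (i in 2:4) {
      if (helices$start[i] <= helices$end[i - 1L])
        stop(sprintf(
          "topology config: protein '%s': helix %s (%d-%d) overlaps or precedes %s (%d-%d)",
          pid, helices$helix_id[i], helices$start[i], helices$end[i],
          helices$helix_id[i - 1L], helices$start[i - 1L], helices$end[i - 1L]),
          call. = FALSE)
    }
    fl <- if (!is.null(entry$flank)) as.integer(entry$flank) else flank_default
    if (is.na(fl) || fl < 0L)
      stop(sprintf("topology config: protein '%s': flank must be >= 0", pid),
           call. = FALSE)
    structure(list(protein_id = pid,
                   accession = entry$accession %||% pid,
                   helices = helices, flank = fl),
              class = "TMTopology")
  })
  names(topologies) <- names(cfg$proteins)
  anchors <- list()
  if (!is.null(cfg$anchors)) {
    anchors <- lapply(names(cfg$anchors), function(pid) {
      a <- cfg$anchors[[pid]]
      anc <- structure(list(protein_id = pid,
                            anchor_pos = as.integer(a$anchor_pos),
                            anchor_prime = as.integer(a$anchor_prime)),
                       class = "PrimeAnchor")
      top <- topologies[[pid]]
      if (is.null(top))
        stop(sprintf("topology config: anchor for unknown protein '%s'", pid),
             call. = FALSE)
      m2 <- top$helices[top$helices$helix_id == "M2", ]
      if (anc$anchor_pos < m2$start - top$flank ||
          anc$anchor_pos > m2$end + top$flank)
        stop(sprintf(
          "topology config: anchor position %d of '%s' lies outside M2 +/- flank",
          anc$anchor_pos, pid), call. = FALSE)
      anc
    })
    names(anchors) <- names(cfg$anchors)
  }
  structure(list(topologies = topologies, anchors = anchors, path = path),
            class = "TopologyRegistry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign a residue position to a transmembrane helix
#'
#' A position is \code{core} when inside a helix span, \code{flank} when
#' within \code{flank} residues of a span boundary, and \code{outside}
#' otherwise. When the flank windows of two helices overlap, the position
#' is assigned to the nearer helix; an exact tie goes to the N-terminal-side
#' (earlier) helix.
#'
#' @param top a \code{TMTopology}.
#' @param pos 1-based residue index (>= 1).
#' @param flank_included when \code{FALSE}, flank positions are reported as
#'   \code{outside}.
#' @return list with \code{helix} (\code{M1}..\code{M4} or \code{NA}) and
#'   \code{region} (\code{core}, \code{flank} or \code{outside}).
#' @export
assign_helix <- function(top, pos, flank_included = TRUE) {
  stopifnot(inherits(top, "TMTopology"), pos >= 1)
  pos <- as.integer(pos)
  h <- top$helices
  inside <- pos >= h$start & pos <= h$end
  if (any(inside)) {
    return(list(helix = h$helix_id[which(inside)[1]], region = "core"))
  }
  dist <- pmax(h$start - pos, pos - h$end)  # positive outside every span
  if (flank_included && any(dist <= top$flank)) {
    cand <- which(dist <= top$flank)
    best <- cand[which.min(dist[cand])]     # tie -> earlier (N-terminal) helix
    return(list(helix = h$helix_id[best], region = "flank"))
  }
  list(helix = NA_character_, region = "outside")
}

#' M2 prime-position index of a residue
#'
#' Prime numbering is defined by anchor arithmetic from the conserved 9'
#' activation-gate leucine: \code{prime = pos - anchor_pos + anchor_prime}.
#' For the packaged GABRA2 anchor (Leu291 = 9') this places Pro280 at -2'
#' (the desensitization-gate ring), Val284 at 2' and Thr292 at 10'.
#'
#' @param anchor a \code{PrimeAnchor} (or a \code{TopologyRegistry}, whose
#'   anchor for \code{protein} is used).
#' @param pos 1-based residue index; must lie within the anchor protein's
#'   M2 span +/- flank when a topology is supplied.
#' @param topology optional \code{TMTopology} used to enforce the M2 domain
#'   of the numbering; outside it the prime index is undefined.
#' @param protein protein id used to resolve anchor/topology when
#'   \code{anchor} is a registry.
#' @return integer prime index of class \code{PrimeIndex} (printed with the
#'   prime mark, e.g. \code{-2'}).
#' @examples
#' reg <- load_topology()
#' prime_index(reg, 280, protein = "GABRA2")   # -2'
#' @export
prime_index <- function(anchor, pos, topology = NULL, protein = NULL) {
  if (inherits(anchor, "TopologyRegistry")) {
    protein <- protein %||% names(anchor$anchors)[1]
    topology <- topology %||% anchor$topologies[[protein]]
    anchor <- anchor$anchors[[protein]]
    if (is.null(anchor))
      stop("no prime anchor defined for protein '", protein, "'", call. = FALSE)
  }
  stopifnot(inherits(anchor, "PrimeAnchor"))
  pos <- as.integer(pos)
  if (!is.null(topology)) {
    m2 <- topology$helices[topology$helices$helix_id == "M2", ]
    if (pos < m2$start - topology$flank || pos > m2$end + topology$flank)
      stop(sprintf(
        "prime numbering undefined: position %d outside M2 (%d-%d) +/- %d of '%s'",
        pos, m2$start, m2$end, topology$flank, anchor$protein_id),
        call. = FALSE)
  }
  structure(pos - anchor$anchor_pos + anchor$anchor_prime,
            class = "PrimeIndex")
}

#' @export
print.PrimeIndex <- function(x, ...) {
  cat(format_prime(x), "\n")
  invisible(x)
}

#' Render a prime index with the prime mark
#' @param x integer prime index (or \code{PrimeIndex}).
#' @return character, e.g. \code{"-2'"} or \code{"9'"}.
#' @export
format_prime <- function(x) sprintf("%d'", as.integer(x))

#' Prime index of a residue in a non-reference subunit
#'
#' Composes cross-paralog position mapping with reference prime numbering:
#' the position is mapped onto the reference subunit by global pairwise
#' alignment, then indexed by the reference anchor. This is how, e.g., the
#' last beta-subunit leucine of the 9' activation-gate ring acquires the
#' same 9' label as the reference leucine.
#'
#' @param subunit \code{ProteinSequence} carrying \code{pos}.
#' @param pos 1-based residue index in \code{subunit}.
#' @param ref reference \code{ProteinSequence} (the anchor's protein).
#' @param anchor a \code{PrimeAnchor}.
#' @param topology optional reference \code{TMTopology} (domain check).
#' @return \code{PrimeIndex}.
#' @export
prime_index_foreign <- function(subunit, pos, ref, anchor, topology = NULL) {
  if (identical(subunit$id, ref$id) && identical(subunit$residues, ref$residues))
    return(prime_index(anchor, pos, topology))
  m <- map_position(align_pair(subunit, ref, mode = "global"), pos)
  if (m$unaligned)
    stop(sprintf("position %d of '%s' is unaligned to the reference '%s'",
                 pos, subunit$id, ref$id), call. = FALSE)
  prime_index(anchor, m$target_pos, topology)
}

#' Signed center-relative coordinate of a helix residue
#'
#' Distance in residues from the central residue of the assigned helix,
#' with the sign convention that negative offsets point toward the
#' extracellular space and positive offsets toward the cytosol, regardless
#' of the helix's N-terminal orientation. The center of an even-length
#' helix is \code{floor((start + end) / 2)}.
#'
#' @param top a \code{TMTopology}.
#' @param pos residue index; must be core or flank of some helix.
#' @return list with \code{helix}, \code{region} and integer \code{offset}.
#' @export
center_offset <- function(top, pos) {
  a <- assign_helix(top, pos)
  if (a$region == "outside")
    stop(sprintf("position %d is outside every helix (+/- flank) of '%s'",
                 pos, top$protein_id), call. = FALSE)
  h <- top$helices[top$helices$helix_id == a$helix, ]
  center <- (h$start + h$end) %/% 2L
  off <- as.integer(pos) - center
  if (h$n_term_side == "cytoplasmic") off <- -off
  list(helix = a$helix, region = a$region, offset = off)
}

#' Residue identities of a pore ring across subunits
#'
#' For a given prime position, reports the residue letter contributed by
#' each subunit: the prime index is converted to a reference position via
#' the anchor, then mapped onto every subunit by pairwise alignment.
#' Subunits whose equivalent position is unaligned are flagged, not
#' silently dropped.
#'
#' @param prime integer prime index (e.g. \code{-2} for the
#'   desensitization-gate ring, \code{9} for the activation gate).
#' @param subunits list of \code{ProteinSequence}.
#' @param ref reference \code{ProteinSequence}.
#' @param anchor \code{PrimeAnchor} on \code{ref}.
#' @return data frame: \code{subunit_id}, \code{pos}, \code{residue},
#'   \code{unaligned}.
#' @export
ring_identities <- function(prime, subunits, ref, anchor) {
  if (inherits(subunits, "ProteinSequence")) subunits <- list(subunits)
  ref_pos <- anchor$anchor_pos + as.integer(prime) - anchor$anchor_prime
  rows <- lapply(subunits, function(su) {
    if (identical(su$id, ref$id) && identical(su$residues, ref$residues)) {
      return(data.frame(subunit_id = su$id, pos = ref_pos,
                        residue = substr(su$residues, ref_pos, ref_pos),
                        unaligned = FALSE, stringsAsFactors = FALSE))
    }
    m <- map_position(align_pair(ref, su, mode = "global"), ref_pos)
    data.frame(subunit_id = su$id,
               pos = if (m$unaligned) NA_integer_ else m$target_pos,
               residue = if (m$unaligned) NA_character_ else m$target_aa,
               unaligned = m$unaligned, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
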