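# Synthetic generators: every stage of the pipeline gets a download-free
# test surface with recorded ground truth. Toy channels are exactly
# C5-symmetric so their pore radii are closed-form; sequence families are
# evolved with recorded substitutions and indels; variant tables are
# multinomial draws over helix categories with the truth kept alongside.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate a C5-symmetric toy channel with analytically known pore radii
#'
#' Builds concentric atom rings around the z axis (five atoms per ring by
#' default, exact C5 symmetry), standing in for the transmembrane pore of a
#' pentameric receptor. Because the geometry is exact, the pore radius at
#' each ring height is closed-form: the on-axis clearance
#' \code{min over rings j of sqrt(ring_radius_j^2 + (z_i - z_j)^2) -
#' vdW_j}, which reduces to \code{ring_radius_i - vdW_i} whenever the
#' rings are spaced widely enough not to encroach on each other. A
#' negative analytic radius marks a fully occluded (blocked) constriction.
#' Rings named in \code{mutation_mask} are narrowed by
#' \code{radius_decrement} (emulating a bulkier pore-lining side chain).
#' An optional rigid rotation/translation is applied to the atoms and to
#' the returned axis.
#'
#' @param ring_z strictly increasing ring heights (Angstrom), axis
#'   coordinates before the rigid transform.
#' @param ring_radius ring radii (recycled), each larger than the largest
#'   vdW radius used.
#' @param atoms_per_ring atoms per ring (default 5).
#' @param element element per ring (recycled, default \code{"C"}).
#' @param mutation_mask integer indices of rings to mutate.
#' @param radius_decrement radial narrowing applied to mutated rings.
#' @param rotation optional 3 x 3 rotation matrix.
#' @param translation optional length-3 translation.
#' @return list: \code{structure} (a \code{Structure3D}; chain per
#'   symmetry-related subunit position), \code{analytic} (data frame
#'   \code{ring}, \code{z}, \code{radius} -- the exact profile),
#'   \code{axis} (the transformed \code{PoreAxis}).
#' @examples
#' toy <- gen_toy_pentamer(ring_z = c(0, 6, 12), ring_radius = c(5, 3.5, 5))
#' toy$analytic
#' @export
gen_toy_pentamer <- function(ring_z, ring_radius, atoms_per_ring = 5L,
                             element = "C", mutation_mask = integer(),
                             radius_decrement = 1.0,
                             rotation = NULL, translation = c(0, 0, 0)) {
  n <- length(ring_z)
  if (n < 1L || any(diff(ring_z) <= 0))
    stop("ring_z must be strictly increasing", call. = FALSE)
  ring_radius <- rep_len(ring_radius, n)
  element <- rep_len(element, n)
  if (any(ring_radius <= max(vdw_radius(element))))
    stop("ring radii must exceed the largest vdW radius used", call. = FALSE)
  # mutation narrowing is applied after validation: a mutated ring may drop
  # below the vdW radius, which models a fully occluded (blocked) gate and
  # shows up as a negative analytic clearance
  if (length(mutation_mask) > 0L) {
    stopifnot(all(mutation_mask >= 1L), all(mutation_mask <= n),
              all(ring_radius[mutation_mask] > radius_decrement))
    ring_radius[mutation_mask] <- ring_radius[mutation_mask] - radius_decrement
  }
  ang <- 2 * pi * (seq_len(atoms_per_ring) - 1L) / atoms_per_ring
  at <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(chain = LETTERS[seq_len(atoms_per_ring)],
               resno = i, resname = "RNG",
               atom = paste0(element[i], "1"), element = element[i],
               x = ring_radius[i] * cos(ang),
               y = ring_radius[i] * sin(ang),
               z = ring_z[i], occ = 1, stringsAsFactors = FALSE)
  }))
  origin <- c(0, 0, 0); direction <- c(0, 0, 1)
  xyz <- as.matrix(at[c("x", "y", "z")])
  if (!is.null(rotation)) {
    stopifnot(all(dim(rotation) == c(3, 3)),
              abs(det(rotation) - 1) < 1e-6)
    xyz <- xyz %*% t(rotation)
    direction <- as.vector(rotation %*% direction)
  }
  xyz <- sweep(xyz, 2, translation, "+")
  origin <- origin + translation
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  structure3d <- structure(list(structure_id = "toy_pentamer", atoms = at,
                                het = at[0, ], chain_roles = NULL),
                           class = "Structure3D")
  vdw <- vdw_radius(element)
  analytic_radius <- vapply(seq_len(n), function(i)
    min(sqrt(ring_radius^2 + (ring_z[i] - ring_z)^2) - vdw), 0)
  list(structure = structure3d,
       analytic = data.frame(ring = seq_len(n), z = ring_z,
                             radius = analytic_radius),
       axis = structure(list(origin = origin, direction = direction),
                        class = "PoreAxis"))
}

#' Write a Structure3D to a PDB file
#'
#' Serialization goes through \code{bio3d::write.pdb} so the generators
#' exercise the same public file interface as real structures.
#'
#' @param s a \code{Structure3D}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_structure_pdb <- function(s, path) {
  at <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(at[c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resname, chain = at$chain,
                   elety = at$atom, o = at$occ, elesy = at$element)
  invisible(path)
}

#' Evolve a synthetic protein family with a recorded position map
#'
#' Descendants are derived from a random ancestor by per-column
#' substitution and (optionally) single-residue insertions/deletions. The
#' true descendant-to-ancestor position map and the substituted columns
#' are returned alongside the sequences, so alignment-based mapping can be
#' scored against ground truth rather than inferred from the data. Indels
#' avoid the first and last three ancestor columns to keep terminal
#' alignments stable.
#'
#' @param ancestor_length residues in the ancestor.
#' @param n_descendants number of descendant sequences.
#' @param substitution_rate per-column substitution probability in [0, 1).
#' @param indel_rate per-column probability of an indel event (split
#'   equally between insertion and deletion) in [0, 1).
#' @param seed RNG seed (same seed, byte-identical output).
#' @return list: \code{reference} (ancestor \code{ProteinSequence}),
#'   \code{descendants} (list of \code{ProteinSequence}), \code{maps}
#'   (per descendant, data frame \code{desc_pos}, \code{ref_pos}; inserted
#'   positions have \code{NA} ref), \code{substituted} (per descendant,
#'   ancestor columns carrying a substitution).
#' @export
gen_family <- function(ancestor_length = 200L, n_descendants = 5L,
                       substitution_rate = 0.05, indel_rate = 0,
                       seed = 1L) {
  stopifnot(substitution_rate >= 0, substitution_rate < 1,
            indel_rate >= 0, indel_rate < 1, ancestor_length >= 10L)
  .with_seed(seed, {
    anc <- sample(.AA_STANDARD, ancestor_length, replace = TRUE)
    descendants <- vector("list", n_descendants)
    maps <- vector("list", n_descendants)
    substituted <- vector("list", n_descendants)
    for (k in seq_len(n_descendants)) {
      res <- anc
      sub_cols <- which(runif(ancestor_length) < substitution_rate)
      for (i in sub_cols) res[i] <- sample(setdiff(.AA_STANDARD, res[i]), 1L)
      chars <- as.list(res)
      refs <- as.list(seq_len(ancestor_length))
      if (indel_rate > 0) {
        interior <- seq(4L, ancestor_length - 3L)
        ev <- runif(length(interior))
        del <- interior[ev < indel_rate / 2]
        ins <- interior[ev >= indel_rate / 2 & ev < indel_rate]
        for (i in del) { chars[[i]] <- character(0); refs[[i]] <- integer(0) }
        for (i in ins) {
          chars[[i]] <- c(chars[[i]], sample(.AA_STANDARD, 1L))
          refs[[i]] <- c(refs[[i]], NA_integer_)
        }
      }
      seq_k <- unlist(chars)
      ref_pos <- unlist(refs)
      descendants[[k]] <- protein_sequence(sprintf("desc%02d", k),
                                           paste(seq_k, collapse = ""))
      maps[[k]] <- data.frame(desc_pos = seq_along(seq_k), ref_pos = ref_pos)
      substituted[[k]] <- sub_cols
    }
    names(descendants) <- names(maps) <- names(substituted) <-
      vapply(descendants, `[[`, "", "id")
    list(reference = protein_sequence("REF", paste(anc, collapse = "")),
         descendants = descendants, maps = maps, substituted = substituted)
  })
}

#' Generate a variant table with controlled per-helix enrichment
#'
#' Variants are placed by a multinomial draw over placement categories --
#' the four helix cores, their flank windows, and the region outside --
#' with the true category of every variant recorded. Weights proportional
#' to the observed per-helix disease counts reproduce the enrichment
#' structure of the real data; uniform weights give the null.
#'
#' @param topology a \code{TMTopology} (or \code{TopologyRegistry}, first
#'   protein used).
#' @param n_variants number of variants to draw.
#' @param weights named non-negative weights over any subset of
#'   \code{M1}..\code{M4}, \code{flank}, \code{outside} (not all zero).
#' @param protein_length protein length used for the outside category
#'   (default: M4 end + 20).
#' @param seed RNG seed.
#' @return data frame of variant records (\code{protein_id}, \code{gene},
#'   \code{pos}, \code{ref_aa}, \code{alt_aa}, \code{source},
#'   \code{significance}) with ground-truth columns \code{truth_category},
#'   \code{truth_helix}, \code{truth_region}.
#' @export
gen_variant_table <- function(topology, n_variants,
                              weights = c(M1 = 1, M2 = 1, M3 = 1, M4 = 1),
                              protein_length = NULL, seed = 1L) {
  if (inherits(topology, "TopologyRegistry"))
    topology <- topology$topologies[[1]]
  stopifnot(inherits(topology, "TMTopology"),
            all(weights >= 0), sum(weights) > 0)
  h <- topology$helices
  protein_length <- protein_length %||% (max(h$end) + 20L)
  core_pos <- lapply(seq_len(4), function(i) seq(h$start[i], h$end[i]))
  names(core_pos) <- h$helix_id
  all_pos <- seq_len(protein_length)
  region_of <- vapply(all_pos, function(p)
    assign_helix(topology, p)$region, "")
  pools <- c(core_pos, list(flank = all_pos[region_of == "flank"],
                            outside = all_pos[region_of == "outside"]))
  weights <- weights[names(weights) %in% names(pools)]
  if (length(weights) == 0L) stop("no usable weight categories", call. = FALSE)
  if (n_variants == 0L) {
    return(data.frame(protein_id = character(), gene = character(),
                      pos = integer(), ref_aa = character(),
                      alt_aa = character(), source = character(),
                      significance = character(), truth_category = character(),
                      truth_helix = character(), truth_region = character(),
                      stringsAsFactors = FALSE))
  }
  .with_seed(seed, {
    cat_draw <- sample(names(weights), n_variants, replace = TRUE,
                       prob = weights / sum(weights))
    pos <- vapply(cat_draw, function(cg) {
      pool <- pools[[cg]]
      pool[sample.int(length(pool), 1L)]
    }, integer(1))
    ref <- sample(.AA_STANDARD, n_variants, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(.AA_STANDARD, r), 1L), "")
    truth <- lapply(pos, function(p) assign_helix(topology, p))
    data.frame(protein_id = topology$protein_id, gene = topology$protein_id,
               pos = as.integer(pos), ref_aa = ref, alt_aa = alt,
               source = "manual", significance = "pathogenic",
               truth_category = unname(cat_draw),
               truth_helix = vapply(truth, function(t)
                 t$helix %||% NA_character_, ""),
               truth_region = vapply(truth, `[[`, "", "region"),
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Registry of packaged fixtures
#'
#' Returns the packaged study data: the seven GABRA2 variants, the 23-row
#' published cross-receptor equivalence table, the topology config with
#' the 9'-leucine prime anchor, and the chloride ion constants.
#'
#' @return list: \code{seven_variants} (data frame),
#'   \code{table1} (data frame), \code{topology_path}, \code{registry}
#'   (loaded \code{TopologyRegistry}), \code{anchor} (GABRA2
#'   \code{PrimeAnchor}), \code{ion} (see \code{\link{ion_constants}}).
#' @export
fixtures <- function() {
  path <- function(f) {
    p <- system.file("extdata", f, package = "cysloop")
    if (!nzchar(p)) stop("packaged fixture missing: ", f, call. = FALSE)
    p
  }
  seven <- read.delim(path("gabra2_seven_variants.tsv"), comment.char = "#",
                      stringsAsFactors = FALSE)
  table1 <- read.delim(path("table1_equivalents.tsv"), comment.char = "#",
                       stringsAsFactors = FALSE)
  reg <- load_topology(path("topology_cysloop.yaml"))
  list(seven_variants = seven, table1 = table1,
       topology_path = path("topology_cysloop.yaml"),
       registry = reg, anchor = reg$anchors$GABRA2, ion = ion_constants())
}
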