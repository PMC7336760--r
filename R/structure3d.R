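# Structure I/O and pore geometry: pore-axis radius profiles in 3 Angstrom
# steps, constriction detection, chloride-passability classification,
# van der Waals / hydrogen-bond contacts, inter-residue distances and
# Kabsch least-squares superposition.

# Bondi van der Waals radii (Angstrom); hydrogens are ignored throughout.
.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
          F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
.VDW_DEFAULT <- 1.70

#' Van der Waals radius of an element
#' @param element element symbol (vectorized, case-insensitive).
#' @return numeric radius in Angstrom (Bondi set; 1.70 for unknowns).
#' @export
vdw_radius <- function(element) {
  r <- .VDW[toupper(element)]
  r[is.na(r)] <- .VDW_DEFAULT
  unname(r)
}

#' Ionic radii of chloride used for pore-passability classification
#' @return named vector: \code{cl_pauling} (1.81 A, Pauling ionic radius)
#'   and \code{cl_hydrated} (3.2 A, hydrated Cl- radius).
#' @export
ion_constants <- function() c(cl_pauling = 1.81, cl_hydrated = 3.2)

#' Read a (pentameric) structure from PDB or mmCIF
#'
#' Parsing is delegated to bio3d. Hydrogens are dropped, alternate
#' locations are resolved to the highest-occupancy atom per name, and
#' hetero/ligand atoms are separated from the polymer. Only the first
#' model of a multi-model file is used (with a warning).
#'
#' @param path path to the structure file.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or
#'   \code{"mmcif"}.
#' @param chain_roles optional named character vector mapping chain ids to
#'   subunit roles (e.g. \code{c(A = "alpha1", B = "beta3", ...)}); every
#'   name must be a chain present in the file.
#' @return An object of class \code{Structure3D}: \code{structure_id},
#'   \code{atoms} (polymer heavy atoms: \code{chain}, \code{resno},
#'   \code{resname}, \code{atom}, \code{element}, \code{x}, \code{y},
#'   \code{z}, \code{occ}), \code{het} (hetero atoms, same layout) and
#'   \code{chain_roles}.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           chain_roles = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- if (format == "mmcif") bio3d::read.cif(path) else bio3d::read.pdb(path)
  if (!is.null(dim(pdb$xyz)) && nrow(pdb$xyz) > 1L)
    warning("multi-model file; using the first model", call. = FALSE)
  at <- pdb$atom
  element <- toupper(trimws(at$elesy))
  noel <- is.na(element) | element == ""
  element[noel] <- toupper(substr(gsub("[0-9']", "", at$elety[noel]), 1, 1))
  at$element <- element
  at <- at[!at$element %in% c("H", "D"), , drop = FALSE]
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(at$chain, at$resno, at$elety, -occ)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(at[c("chain", "resno", "elety")]), , drop = FALSE]
  keep <- function(df) data.frame(chain = df$chain, resno = df$resno,
                                  resname = df$resid, atom = df$elety,
                                  element = df$element,
                                  x = df$x, y = df$y, z = df$z,
                                  occ = ifelse(is.na(df$o), 1, df$o),
                                  stringsAsFactors = FALSE)
  poly <- keep(at[at$type == "ATOM", , drop = FALSE])
  het <- keep(at[at$type != "ATOM", , drop = FALSE])
  if (!all(is.finite(as.matrix(poly[c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path, call. = FALSE)
  if (!is.null(chain_roles)) {
    unknown <- setdiff(names(chain_roles), unique(c(poly$chain, het$chain)))
    if (length(unknown) > 0L)
      stop("chain-role map names chains absent from the structure: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(structure_id = sub("\\.[^.]+$", "", basename(path)),
                 atoms = poly, het = het, chain_roles = chain_roles),
            class = "Structure3D")
}

#' @export
print.Structure3D <- function(x, ...) {
  cat(sprintf("Structure3D %s: %d polymer atoms, %d hetero atoms, chains %s\n",
              x$structure_id, nrow(x$atoms), nrow(x$het),
              paste(sort(unique(x$atoms$chain)), collapse = "")))
  invisible(x)
}

.coords <- function(atoms) as.matrix(atoms[c("x", "y", "z")])

#' Channel pore axis of a pentameric bundle
#'
#' The axis passes through the centroid of the selected transmembrane
#' C-alpha atoms along their dominant principal direction. The direction is
#' oriented extracellular-to-cytoplasmic: when \code{extracellular_ref} (a
#' point on the extracellular side) is given, the direction points away
#' from it; otherwise the sign is fixed deterministically so the largest
#' direction component is positive.
#'
#' @param s a \code{Structure3D}.
#' @param tm_selection optional data frame (\code{chain}, \code{start},
#'   \code{end}) restricting the C-alpha atoms used; default all.
#' @param extracellular_ref optional length-3 point on the extracellular
#'   side used to orient the axis.
#' @return list of class \code{PoreAxis}: \code{origin} (centroid) and
#'   unit \code{direction}.
#' @export
pore_axis <- function(s, tm_selection = NULL, extracellular_ref = NULL) {
  at <- s$atoms[s$atoms$atom == "CA", , drop = FALSE]
  if (nrow(at) == 0L) at <- s$atoms  # toy structures without backbone
  if (!is.null(tm_selection)) {
    keep <- rep(FALSE, nrow(at))
    for (i in seq_len(nrow(tm_selection))) {
      keep <- keep | (at$chain == tm_selection$chain[i] &
                        at$resno >= tm_selection$start[i] &
                        at$resno <= tm_selection$end[i])
    }
    at <- at[keep, , drop = FALSE]
  }
  if (length(unique(at$chain)) < 3L)
    stop("pore axis needs >= 3 chains with TM residues", call. = FALSE)
  xyz <- .coords(at)
  centroid <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, centroid))
  if (nrow(xyz) < 3L || sv$d[3] < 1e-6 * sv$d[1])
    stop("degenerate TM geometry (rank < 3)", call. = FALSE)
  dir <- sv$v[, 1]
  if (!is.null(extracellular_ref)) {
    if (sum(dir * (centroid - extracellular_ref)) < 0) dir <- -dir
  } else if (dir[which.max(abs(dir))] < 0) {
    dir <- -dir
  }
  structure(list(origin = centroid, direction = dir / sqrt(sum(dir^2))),
            class = "PoreAxis")
}

# Clearance of a sphere centered at point p: min over atoms of
# (distance - vdW radius). Negative means the point is inside an atom.
.clearance <- function(p, xyz, vdw) {
  d2 <- (xyz[, 1] - p[1])^2 + (xyz[, 2] - p[2])^2 + (xyz[, 3] - p[3])^2
  min(sqrt(d2) - vdw)
}

#' Pore radius profile along the channel axis
#'
#' At each step along the axis the profile records the radius of the
#' largest sphere, centered in the step plane, that avoids van der Waals
#' overlap with every atom: \code{radius = max over centers of min over
#' atoms (||center - atom|| - vdW)}. The in-plane center is refined from
#' the axis point by local hill-climbing (0.5 A moves within a small
#' neighborhood, then simplex polish), with total displacement capped at
#' \code{grid_radius}. The local search follows the connected pore the way
#' channel-profiling tools do -- it tracks tilted or kinked pores but
#' cannot tunnel through the channel wall, where the maximal-sphere
#' objective would grow without bound. Set \code{refine = FALSE} for a
#' fixed on-axis measurement. Negative clearances clamp to zero and flag
#' the step as blocked; steps with no atoms nearby are marked undefined.
#'
#' @param s a \code{Structure3D}.
#' @param axis a \code{PoreAxis}; computed via \code{\link{pore_axis}} when
#'   \code{NULL}.
#' @param step_size spacing of the profile steps in Angstrom (default 3).
#' @param s_values optional explicit axis coordinates to evaluate
#'   (overrides the regular grid).
#' @param refine refine the in-plane center (default \code{TRUE}).
#' @param grid_radius,grid_step displacement cap and hill-climb spacing
#'   (Angstrom).
#' @param slab half-width of the atom pre-filter around each step plane.
#' @return list of class \code{PoreProfile}: \code{axis}, \code{step_size},
#'   and \code{steps} -- a data frame with \code{s} (distance along the
#'   axis from the first step), \code{center_x/y/z}, \code{radius},
#'   \code{blocked}, \code{undefined}.
#' @export
pore_profile <- function(s, axis = NULL, step_size = 3, s_values = NULL,
                         refine = TRUE, grid_radius = 8, grid_step = 0.5,
                         slab = 15) {
  if (is.null(axis)) axis <- pore_axis(s)
  xyz <- .coords(s$atoms)
  vdw <- vdw_radius(s$atoms$element)
  dir <- axis$direction
  t_all <- as.vector(sweep(xyz, 2, axis$origin) %*% dir)
  if (is.null(s_values)) {
    s_values <- seq(min(t_all), max(t_all) + step_size * 0.999, by = step_size)
  }
  # orthonormal in-plane basis
  u <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- u - sum(u * dir) * dir; u <- u / sqrt(sum(u^2))
  v <- c(dir[2] * u[3] - dir[3] * u[2],
         dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])
  # local moves tried at each hill-climb iteration
  moves <- expand.grid(a = seq(-3, 3) * grid_step, b = seq(-3, 3) * grid_step)
  moves <- moves[moves$a^2 + moves$b^2 <= (3 * grid_step)^2, , drop = FALSE]
  steps <- lapply(s_values, function(sv) {
    sel <- abs(t_all - sv) <= slab
    if (!any(sel)) {
      return(data.frame(s = sv, center_x = NA_real_, center_y = NA_real_,
                        center_z = NA_real_, radius = NA_real_,
                        blocked = FALSE, undefined = TRUE))
    }
    axyz <- xyz[sel, , drop = FALSE]
    avdw <- vdw[sel]
    p0 <- axis$origin + sv * dir
    obj <- function(ab) {
      excess <- sqrt(sum(ab^2)) - grid_radius
      .clearance(p0 + ab[1] * u + ab[2] * v, axyz, avdw) -
        if (excess > 0) 1e3 * excess else 0
    }
    if (refine) {
      # greedy hill-climb from the axis point over a local move set
      ab <- c(0, 0); best <- obj(ab)
      for (it in seq_len(200)) {
        cand <- t(t(moves) + ab)
        vals <- apply(cand, 1, obj)
        k <- which.max(vals)
        if (vals[k] <= best + 1e-9) break
        ab <- as.numeric(cand[k, ]); best <- vals[k]
      }
      opt <- optim(ab, function(p) -obj(p), method = "Nelder-Mead",
                   control = list(reltol = 1e-10, maxit = 500))
      center <- p0 + opt$par[1] * u + opt$par[2] * v
      cl <- -opt$value
    } else {
      center <- p0
      cl <- .clearance(center, axyz, avdw)
    }
    data.frame(s = sv, center_x = center[1], center_y = center[2],
               center_z = center[3], radius = max(cl, 0),
               blocked = cl < 0, undefined = FALSE)
  })
  steps <- do.call(rbind, steps)
  steps$s <- steps$s - steps$s[1]  # profile coordinate starts at 0
  structure(list(axis = axis, step_size = step_size, steps = steps,
                 s_offset = s_values[1]),
            class = "PoreProfile")
}

#' @export
print.PoreProfile <- function(x, ...) {
  ok <- !x$steps$undefined
  i <- which.min(ifelse(ok, x$steps$radius, Inf))
  cat(sprintf("PoreProfile: %d steps of %.1f A; narrowest radius %.2f A at s = %.1f A\n",
              nrow(x$steps), x$step_size, x$steps$radius[i], x$steps$s[i]))
  invisible(x)
}

#' Classify a pore radius by chloride passability
#'
#' Thresholds are the Pauling ionic radius of Cl- (1.81 A) and the radius
#' of hydrated Cl- (3.2 A): a constriction narrower than 1.81 A is
#' \code{blocked}, between the two only a dehydrated ion fits, and at or
#' above 3.2 A a hydrated ion passes.
#'
#' @param radius numeric pore radii in Angstrom (>= 0).
#' @return character vector over \code{blocked},
#'   \code{dehydrated-Cl-only}, \code{hydrated-Cl-passable}.
#' @examples
#' classify_permeation(c(1.60, 1.81, 3.55))
#' @export
classify_permeation <- function(radius) {
  if (any(is.na(radius)) || any(radius < 0))
    stop("radius must be non-negative", call. = FALSE)
  ic <- ion_constants()
  ifelse(radius < ic[["cl_pauling"]], "blocked",
         ifelse(radius < ic[["cl_hydrated"]], "dehydrated-Cl-only",
                "hydrated-Cl-passable"))
}

#' Per-step radius differences between wild-type and mutant profiles
#'
#' @param wt wild-type \code{PoreProfile}.
#' @param mutants a named list of mutant \code{PoreProfile}s (or a single
#'   profile).
#' @param threshold absolute radius change (Angstrom) above which a step is
#'   flagged (default 0.1).
#' @return long-format data frame: \code{s}, \code{mutant},
#'   \code{radius_wt}, \code{radius_mut}, \code{delta}
#'   (mutant - wild-type), \code{flagged}.
#' @export
compare_profiles <- function(wt, mutants, threshold = 0.1) {
  if (inherits(mutants, "PoreProfile")) mutants <- list(mutant = mutants)
  if (is.null(names(mutants)))
    names(mutants) <- paste0("mutant", seq_along(mutants))
  out <- lapply(names(mutants), function(nm) {
    m <- mutants[[nm]]
    if (nrow(m$steps) != nrow(wt$steps) ||
        max(abs(m$steps$s - wt$steps$s)) > 1e-6)
      stop("profile steps mismatch for '", nm,
           "': same axis registration and step size required", call. = FALSE)
    delta <- m$steps$radius - wt$steps$radius
    data.frame(s = wt$steps$s, mutant = nm,
               radius_wt = wt$steps$radius, radius_mut = m$steps$radius,
               delta = delta, flagged = !is.na(delta) & abs(delta) > threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Residue-residue contacts (van der Waals and hydrogen bond)
#'
#' A residue pair is in van der Waals contact when any heavy-atom distance
#' is at most the sum of the Bondi radii plus 0.5 A, and hydrogen-bonded
#' when any N/O donor-acceptor pair lies within 3.5 A. Contacts between
#' different chains are flagged inter-subunit.
#'
#' @param s a \code{Structure3D}.
#' @param selection optional data frame (\code{chain}, \code{resno})
#'   restricting the residues considered.
#' @param vdw_slack slack added to the radius sum (default 0.5 A).
#' @param hbond_max maximum donor-acceptor distance (default 3.5 A).
#' @return data frame of class \code{ContactSet}: \code{chain_a},
#'   \code{resno_a}, \code{chain_b}, \code{resno_b}, \code{type}
#'   (\code{vdw}/\code{hbond}), \code{distance} (closest qualifying atom
#'   pair), \code{inter_subunit}.
#' @export
contacts <- function(s, selection = NULL, vdw_slack = 0.5, hbond_max = 3.5) {
  at <- s$atoms
  if (!is.null(selection)) {
    keep <- paste(at$chain, at$resno) %in%
      paste(selection$chain, selection$resno)
    at <- at[keep, , drop = FALSE]
  }
  if (nrow(at) == 0L) stop("empty selection", call. = FALSE)
  xyz <- .coords(at)
  vdw <- vdw_radius(at$element)
  res_id <- paste(at$chain, at$resno, sep = "|")
  rows <- list()
  ids <- unique(res_id)
  for (i in seq_along(ids)) {
    ai <- which(res_id == ids[i])
    for (j in seq_along(ids)) {
      if (j <= i) next
      bj <- which(res_id == ids[j])
      d <- sqrt(outer(rowSums(xyz[ai, , drop = FALSE]^2), rowSums(xyz[bj, , drop = FALSE]^2), "+") -
                  2 * xyz[ai, , drop = FALSE] %*% t(xyz[bj, , drop = FALSE]))
      lim <- outer(vdw[ai], vdw[bj], "+") + vdw_slack
      pair <- function(type, hit, dd) {
        data.frame(chain_a = at$chain[ai[1]], resno_a = at$resno[ai[1]],
                   chain_b = at$chain[bj[1]], resno_b = at$resno[bj[1]],
                   type = type, distance = min(dd[hit]),
                   inter_subunit = at$chain[ai[1]] != at$chain[bj[1]],
                   stringsAsFactors = FALSE)
      }
      if (any(d <= lim)) rows[[length(rows) + 1L]] <- pair("vdw", d <= lim, d)
      no_a <- at$element[ai] %in% c("N", "O")
      no_b <- at$element[bj] %in% c("N", "O")
      if (any(no_a) && any(no_b)) {
        dh <- d[no_a, no_b, drop = FALSE]
        if (any(dh <= hbond_max))
          rows[[length(rows) + 1L]] <- pair("hbond", dh <= hbond_max, dh)
      }
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(chain_a = character(), resno_a = integer(),
               chain_b = character(), resno_b = integer(), type = character(),
               distance = numeric(), inter_subunit = logical(),
               stringsAsFactors = FALSE)
  class(out) <- c("ContactSet", class(out))
  out
}

#' Distance between two residues
#'
#' @param s a \code{Structure3D}.
#' @param resA,resB lists with \code{chain} and \code{resno}.
#' @param convention \code{"ca"} (C-alpha to C-alpha) or \code{"min-heavy"}
#'   (minimum over heavy-atom pairs). The identical residue is 0 by
#'   convention.
#' @return distance in Angstrom.
#' @export
residue_distance <- function(s, resA, resB, convention = c("ca", "min-heavy")) {
  convention <- match.arg(convention)
  get <- function(r) {
    at <- s$atoms[s$atoms$chain == r$chain & s$atoms$resno == r$resno, ,
                  drop = FALSE]
    if (convention == "ca") at <- at[at$atom == "CA", , drop = FALSE]
    if (nrow(at) == 0L)
      stop(sprintf("missing %s atoms for residue %s/%s",
                   if (convention == "ca") "CA" else "heavy",
                   r$chain, r$resno), call. = FALSE)
    .coords(at)
  }
  if (identical(resA$chain, resB$chain) && identical(resA$resno, resB$resno))
    return(0)
  a <- get(resA); b <- get(resB)
  d <- sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b))
  min(d)
}

#' Kabsch least-squares superposition
#'
#' Optimal rigid superposition of paired coordinate sets by singular value
#' decomposition of the covariance matrix, constrained to a proper
#' rotation (determinant +1).
#'
#' @param A,B numeric n x 3 matrices of paired coordinates (n >= 3, not
#'   collinear). \code{B} is superposed onto \code{A}.
#' @return list: \code{rmsd} (Angstrom), \code{rotation} (3 x 3, applied as
#'   \code{B \%*\% rotation}), \code{translation} (length 3) such that
#'   \code{B \%*\% rotation + translation} best fits \code{A}.
#' @export
kabsch_rmsd <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(ncol(A) == 3L, ncol(B) == 3L)
  if (nrow(A) != nrow(B)) stop("coordinate sets must be paired", call. = FALSE)
  if (nrow(A) < 3L) stop("need at least 3 paired points", call. = FALSE)
  ca <- colMeans(A); cb <- colMeans(B)
  P <- sweep(A, 2, ca); Q <- sweep(B, 2, cb)
  if (svd(P)$d[2] < 1e-8 * max(svd(P)$d[1], 1) ||
      svd(Q)$d[2] < 1e-8 * max(svd(Q)$d[1], 1))
    stop("degenerate (collinear) coordinate set", call. = FALSE)
  H <- t(Q) %*% P
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- Q %*% R
  rmsd <- sqrt(mean(rowSums((fitted - P)^2)))
  list(rmsd = rmsd, rotation = R, translation = as.vector(ca - cb %*% R))
}

#' Write a pore profile (with permeation classes) as TSV
#' @param profile a \code{PoreProfile}.
#' @param path output path.
#' @param header optional comment lines (each prefixed with \code{#}).
#' @return the augmented step table, invisibly.
#' @export
write_profile_tsv <- function(profile, path, header = NULL) {
  df <- profile$steps
  df$permeation_class <- NA_character_
  ok <- !df$undefined
  df$permeation_class[ok] <- classify_permeation(df$radius[ok])
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(format(df, digits = 6, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(df)
}
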