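# Sequence I/O, pairwise alignment and cross-paralog position mapping.
#
# All residue indices are 1-based, matching UniProt/HGVS conventions.

.AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.AA_ALLOWED <- c(.AA_STANDARD, "X")

#' Construct a protein sequence object
#'
#' @param id accession or name (a single string).
#' @param residues one-letter amino-acid string; only the 20 standard codes
#'   plus \code{X} are allowed.
#' @return An object of class \code{ProteinSequence} with fields \code{id},
#'   \code{residues} and \code{length}.
#' @examples
#' protein_sequence("toy", "ACDEFGHIK")
#' @export
protein_sequence <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(as.character(residues))
  stopifnot(length(residues) == 1L)
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!chars %in% .AA_ALLOWED)
  if (length(bad) > 0L) {
    stop(sprintf("record '%s': illegal residue character '%s' at position %d",
                 id, chars[bad[1]], bad[1]), call. = FALSE)
  }
  structure(list(id = id, residues = residues, length = nchar(residues)),
            class = "ProteinSequence")
}

#' @export
print.ProteinSequence <- function(x, ...) {
  cat(sprintf("ProteinSequence %s (%d aa)\n", x$id, x$length))
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Records are returned in file order; the header token before the first
#' whitespace becomes the sequence id. Residues are validated against the
#' 20 standard one-letter codes plus \code{X}.
#'
#' @param path path to a FASTA file.
#' @return A named list of \code{\link{protein_sequence}} objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, "", 1L)
  seqs <- as.character(set)
  out <- Map(protein_sequence, ids, seqs)
  names(out) <- ids
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs a list of \code{ProteinSequence} objects.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "ProteinSequence")) seqs <- list(seqs)
  lines <- unlist(lapply(seqs, function(s) c(paste0(">", s$id), s$residues)))
  writeLines(lines, path)
  invisible(path)
}

#' Optimal pairwise alignment of two protein sequences
#'
#' Needleman-Wunsch (global) or Smith-Waterman (local) alignment under
#' BLOSUM62 with affine gap penalties (open 10, extend 0.5 per residue;
#' a gap run of length L costs 10 + 0.5 L). The dynamic programming is
#' delegated to \code{Biostrings::pairwiseAlignment}, which returns a
#' deterministic optimal alignment.
#'
#' @param a,b \code{ProteinSequence} objects (both non-empty).
#' @param mode \code{"global"} or \code{"local"}.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param matrix substitution matrix name (default \code{"BLOSUM62"}).
#' @return A \code{PairwiseAlignment} object: \code{query_id},
#'   \code{target_id}, \code{aligned_query}, \code{aligned_target} (equal
#'   length gapped strings with no gap-in-both column), \code{score},
#'   \code{mode}, and 1-based inclusive \code{query_span}/\code{target_span}.
#' @examples
#' a <- protein_sequence("s1", "ACDEFG")
#' b <- protein_sequence("s2", "ACEFG")
#' align_pair(a, b, "global")
#' @export
align_pair <- function(a, b, mode = c("global", "local"),
                       gap_open = 10, gap_extend = 0.5, matrix = "BLOSUM62") {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "ProteinSequence"), inherits(b, "ProteinSequence"))
  if (a$length == 0L || b$length == 0L)
    stop("cannot align an empty sequence", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$residues), Biostrings::AAString(b$residues),
    type = mode, substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  qa <- as.character(Biostrings::pattern(aln))
  ta <- as.character(Biostrings::subject(aln))
  qs <- c(Biostrings::start(Biostrings::pattern(aln)),
          Biostrings::end(Biostrings::pattern(aln)))
  ts <- c(Biostrings::start(Biostrings::subject(aln)),
          Biostrings::end(Biostrings::subject(aln)))
  structure(list(query_id = a$id, target_id = b$id,
                 aligned_query = qa, aligned_target = ta,
                 score = Biostrings::score(aln), mode = mode,
                 query_span = qs, target_span = ts),
            class = "PairwiseAlignment")
}

#' @export
print.PairwiseAlignment <- function(x, ...) {
  cat(sprintf("%s alignment %s vs %s  score %.1f\n", x$mode,
              x$query_id, x$target_id, x$score))
  cat(" ", x$aligned_query, "\n ", x$aligned_target, "\n")
  invisible(x)
}

# Per-column 1-based residue indices of an alignment (NA at gap columns).
.aln_columns <- function(aln) {
  q <- strsplit(aln$aligned_query, "")[[1]]
  t <- strsplit(aln$aligned_target, "")[[1]]
  stopifnot(length(q) == length(t))
  qpos <- ifelse(q == "-", NA_integer_, cumsum(q != "-") + aln$query_span[1] - 1L)
  tpos <- ifelse(t == "-", NA_integer_, cumsum(t != "-") + aln$target_span[1] - 1L)
  list(q = q, t = t, qpos = as.integer(qpos), tpos = as.integer(tpos))
}

#' Map a residue position through a pairwise alignment
#'
#' Finds the alignment column containing \code{source_pos} of the query and
#' returns the target residue index in that column. When the column is a gap
#' in the target the position is reported as unaligned, together with the
#' nearest mapped flanking positions -- never a silent nearest guess.
#'
#' @param aln a \code{PairwiseAlignment} from \code{\link{align_pair}}.
#' @param source_pos 1-based query residue index; must lie within the
#'   aligned query span.
#' @return A list of class \code{ResidueMapping}: \code{source_pos},
#'   \code{target_pos} (\code{NA} when unaligned), \code{unaligned},
#'   \code{column_identical}, and for unaligned positions
#'   \code{flank_before}/\code{flank_after} (nearest mapped target indices).
#' @export
map_position <- function(aln, source_pos) {
  stopifnot(inherits(aln, "PairwiseAlignment"))
  source_pos <- as.integer(source_pos)
  cols <- .aln_columns(aln)
  if (source_pos < aln$query_span[1] || source_pos > aln$query_span[2])
    stop(sprintf("position %d outside aligned query span [%d, %d] of '%s'",
                 source_pos, aln$query_span[1], aln$query_span[2],
                 aln$query_id), call. = FALSE)
  i <- match(source_pos, cols$qpos)
  tp <- cols$tpos[i]
  res <- list(source_pos = source_pos,
              target_pos = tp,
              unaligned = is.na(tp),
              column_identical = !is.na(tp) && cols$q[i] == cols$t[i],
              source_aa = cols$q[i],
              target_aa = if (is.na(tp)) NA_character_ else cols$t[i])
  if (is.na(tp)) {
    before <- cols$tpos[seq_len(i - 1L)]
    after <- cols$tpos[seq(i + 1L, length(cols$tpos))]
    res$flank_before <- if (any(!is.na(before))) max(before, na.rm = TRUE) else NA_integer_
    res$flank_after <- if (any(!is.na(after))) min(after, na.rm = TRUE) else NA_integer_
  }
  class(res) <- "ResidueMapping"
  res
}

#' @export
print.ResidueMapping <- function(x, ...) {
  if (x$unaligned) {
    cat(sprintf("position %d -> unaligned (nearest mapped: %s / %s)\n",
                x$source_pos, x$flank_before, x$flank_after))
  } else {
    cat(sprintf("position %d (%s) -> %d (%s)%s\n", x$source_pos, x$source_aa,
                x$target_pos, x$target_aa,
                if (x$column_identical) " identical" else ""))
  }
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' Identical columns divided by aligned (non-gap-pair) columns.
#'
#' @param aln a \code{PairwiseAlignment}.
#' @return A fraction in \code{[0, 1]}.
#' @export
percent_identity <- function(aln) {
  cols <- .aln_columns(aln)
  aligned <- cols$q != "-" & cols$t != "-"
  if (!any(aligned)) stop("alignment has zero aligned columns", call. = FALSE)
  sum(cols$q[aligned] == cols$t[aligned]) / sum(aligned)
}

#' Per-position conservation of a reference sequence across homologs
#'
#' Each homolog is globally aligned to the reference; a reference position
#' counts as conserved in that homolog when the alignment column carries the
#' identical residue. Positions aligned to a gap count as non-identical.
#'
#' @param ref reference \code{ProteinSequence}.
#' @param others list of homolog \code{ProteinSequence} objects (length >= 1).
#' @param ... passed to \code{\link{align_pair}}.
#' @return Numeric vector of length \code{ref$length}: fraction of homologs
#'   identical at each reference position.
#' @export
conservation_profile <- function(ref, others, ...) {
  if (inherits(others, "ProteinSequence")) others <- list(others)
  stopifnot(length(others) >= 1L)
  hits <- matrix(0, nrow = ref$length, ncol = length(others))
  for (j in seq_along(others)) {
    cols <- .aln_columns(align_pair(ref, others[[j]], mode = "global", ...))
    ident <- !is.na(cols$qpos) & !is.na(cols$tpos) & cols$q == cols$t
    hits[cols$qpos[ident], j] <- 1
  }
  rowMeans(hits)
}

#' Tabulate a full source-to-target residue mapping
#'
#' Runs \code{\link{map_position}} over every aligned source position and
#' returns the standard tab-delimited mapping layout.
#'
#' @param aln a \code{PairwiseAlignment}.
#' @param path optional output path; when given, the table is written as TSV.
#' @return A data frame with columns \code{source_id}, \code{source_pos},
#'   \code{source_aa}, \code{target_id}, \code{target_pos}, \code{target_aa},
#'   \code{column_identical}.
#' @export
mapping_table <- function(aln, path = NULL) {
  cols <- .aln_columns(aln)
  keep <- !is.na(cols$qpos)
  df <- data.frame(source_id = aln$query_id,
                   source_pos = cols$qpos[keep],
                   source_aa = cols$q[keep],
                   target_id = aln$target_id,
                   target_pos = cols$tpos[keep],
                   target_aa = ifelse(is.na(cols$tpos[keep]), NA, cols$t[keep]),
                   column_identical = !is.na(cols$tpos[keep]) &
                     cols$q[keep] == cols$t[keep],
                   stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
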