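# Protein-level missense variant tables: HGVS arithmetic, dialect parsing,
# merge/de-duplication across sources, and cross-receptor equivalence
# reports.

.AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
          Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
          Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
          Tyr = "Y", Val = "V")
.AA1 <- setNames(names(.AA3), unname(.AA3))

#' Convert between one- and three-letter amino-acid codes
#' @param x character vector of codes.
#' @return character vector of the converted codes.
#' @export
aa_three_to_one <- function(x) {
  out <- unname(.AA3[x])
  if (anyNA(out)) stop("unknown three-letter amino-acid code: ",
                       paste(x[is.na(out)], collapse = ", "), call. = FALSE)
  out
}

#' @rdname aa_three_to_one
#' @export
aa_one_to_three <- function(x) {
  out <- unname(.AA1[toupper(x)])
  if (anyNA(out)) stop("unknown one-letter amino-acid code: ",
                       paste(x[is.na(out)], collapse = ", "), call. = FALSE)
  out
}

#' Parse a protein-level HGVS missense description
#'
#' Accepts three-letter-code protein HGVS with or without the \code{p.}
#' prefix (e.g. \code{"p.Pro280Leu"}, \code{"Leu256Val"}). Synonymous,
#' nonsense, frameshift or otherwise non-missense notation is rejected.
#'
#' @param text a single HGVS p. string.
#' @return list with \code{pos} (1-based), \code{ref_aa}, \code{alt_aa}
#'   (one-letter codes).
#' @examples
#' parse_hgvs_p("p.Pro280Leu")
#' @export
parse_hgvs_p <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- sub("^p\\.", "", trimws(text))
  m <- regmatches(s, regexec("^([A-Z][a-z]{2})([0-9]+)([A-Za-z*=]+)$", s))[[1]]
  if (length(m) == 0L)
    stop("malformed protein HGVS: '", text, "'", call. = FALSE)
  ref3 <- m[2]; pos <- as.integer(m[3]); alt3 <- m[4]
  if (!ref3 %in% names(.AA3))
    stop("malformed protein HGVS (unknown reference residue): '", text, "'",
         call. = FALSE)
  if (!alt3 %in% names(.AA3))
    stop("not a missense change: '", text, "'", call. = FALSE)
  ref <- .AA3[[ref3]]; alt <- .AA3[[alt3]]
  if (ref == alt)
    stop("not a missense change (synonymous): '", text, "'", call. = FALSE)
  if (pos < 1L) stop("malformed protein HGVS (position < 1): '", text, "'",
                     call. = FALSE)
  list(pos = pos, ref_aa = ref, alt_aa = alt)
}

#' Residue index of a coding-nucleotide position
#'
#' HGVS c. to p. arithmetic: the residue affected by coding position
#' \code{c_pos} is codon \code{ceiling(c_pos / 3)} (e.g. c.839 falls in
#' codon 280).
#'
#' @param c_pos coding-nucleotide position(s), 1-based.
#' @param cds_length optional CDS length; positions beyond it are rejected.
#' @return integer residue index (vectorized).
#' @examples
#' codon_index(839)  # 280
#' @export
codon_index <- function(c_pos, cds_length = NULL) {
  c_pos <- as.numeric(c_pos)
  if (any(is.na(c_pos)) || any(c_pos < 1) || any(c_pos != floor(c_pos)))
    stop("coding position must be a positive integer", call. = FALSE)
  if (!is.null(cds_length) && any(c_pos > cds_length))
    stop("coding position beyond the CDS length", call. = FALSE)
  as.integer(ceiling(c_pos / 3))
}

# Normalized clinical-significance vocabulary.
.SIG_LEVELS <- c("pathogenic", "likely_pathogenic", "benign", "likely_benign",
                 "uncertain", "disease", "polymorphism", "unclassified",
                 "other")
.SIG_PATHOGENIC <- c("pathogenic", "likely_pathogenic", "disease")

#' Normalize a clinical-significance label
#'
#' Maps source vocabulary (ClinVar assertions, Humsavar categories) onto a
#' closed set: \code{pathogenic}, \code{likely_pathogenic}, \code{benign},
#' \code{likely_benign}, \code{uncertain}, \code{disease},
#' \code{polymorphism}, \code{unclassified}, \code{other}. The combined
#' assertion "Pathogenic/Likely pathogenic" normalizes to
#' \code{pathogenic}.
#'
#' @param x character vector of raw labels.
#' @return character vector over the closed vocabulary.
#' @export
normalize_significance <- function(x) {
  key <- tolower(trimws(x))
  out <- rep("other", length(key))
  out[key %in% c("pathogenic", "pathogenic/likely pathogenic",
                 "pathogenic/likely_pathogenic")] <- "pathogenic"
  out[key %in% c("likely pathogenic", "likely_pathogenic")] <- "likely_pathogenic"
  out[key == "benign"] <- "benign"
  out[key %in% c("likely benign", "likely_benign")] <- "likely_benign"
  out[key %in% c("uncertain significance", "uncertain",
                 "vus", "conflicting interpretations of pathogenicity")] <- "uncertain"
  out[key %in% c("disease", "lp/p")] <- "disease"
  out[key %in% c("polymorphism", "lb/b")] <- "polymorphism"
  out[key %in% c("unclassified", "us")] <- "unclassified"
  out
}

#' Is a normalized significance label disease-causing?
#' @param sig normalized significance labels.
#' @return logical vector.
#' @export
is_pathogenic <- function(sig) sig %in% .SIG_PATHOGENIC

#' Load a protein-level missense variant table
#'
#' Reads a tab-delimited table in one of two minimal dialects and keeps
#' missense records only, with normalized significance labels and 1-based
#' positions on the canonical protein sequence.
#'
#' Dialect \code{clinvar} expects columns \code{gene}, \code{protein_id},
#' \code{hgvs_p}, \code{significance} (optional \code{hgvs_c},
#' \code{rsid}). Dialect \code{humsavar} expects \code{gene},
#' \code{protein_id}, \code{aa_change}, \code{category} (optional
#' \code{dbsnp}). Rows that fail HGVS parsing (synonymous, nonsense,
#' frameshift, malformed) are skipped; their count is reported via a
#' message and the \code{"n_skipped"} attribute.
#'
#' @param path path to the tab-delimited file.
#' @param dialect \code{"clinvar"} or \code{"humsavar"}.
#' @return data frame of variant records with columns \code{protein_id},
#'   \code{gene}, \code{pos}, \code{ref_aa}, \code{alt_aa}, \code{source},
#'   \code{significance}, \code{hgvs_c}, \code{hgvs_p}, \code{rsid}.
#' @export
load_variants <- function(path, dialect = c("clinvar", "humsavar")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("variant table not found: ", path, call. = FALSE)
  raw <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  hgvs_col <- if (dialect == "clinvar") "hgvs_p" else "aa_change"
  sig_col <- if (dialect == "clinvar") "significance" else "category"
  need <- c("gene", "protein_id", hgvs_col, sig_col)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L)
    stop(sprintf("variant table '%s' (%s dialect) lacks columns: %s",
                 path, dialect, paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  rsid <- if (dialect == "clinvar") raw[["rsid"]] else raw[["dbsnp"]]
  if (is.null(rsid)) rsid <- rep(NA_character_, nrow(raw))
  hgvs_c <- raw[["hgvs_c"]] %||% rep(NA_character_, nrow(raw))
  rows <- vector("list", nrow(raw))
  n_skipped <- 0L
  for (i in seq_len(nrow(raw))) {
    parsed <- tryCatch(parse_hgvs_p(raw[[hgvs_col]][i]), error = function(e) NULL)
    if (is.null(parsed)) { n_skipped <- n_skipped + 1L; next }
    rows[[i]] <- data.frame(
      protein_id = raw$protein_id[i], gene = raw$gene[i],
      pos = parsed$pos, ref_aa = parsed$ref_aa, alt_aa = parsed$alt_aa,
      source = dialect,
      significance = normalize_significance(raw[[sig_col]][i]),
      hgvs_c = hgvs_c[i], hgvs_p = raw[[hgvs_col]][i], rsid = rsid[i],
      stringsAsFactors = FALSE)
  }
  if (n_skipped > 0L)
    message(sprintf("load_variants: skipped %d non-missense/unparseable row(s) in %s",
                    n_skipped, basename(path)))
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) out <- .empty_variants()
  attr(out, "n_skipped") <- n_skipped
  out
}

.empty_variants <- function() {
  data.frame(protein_id = character(), gene = character(), pos = integer(),
             ref_aa = character(), alt_aa = character(), source = character(),
             significance = character(), hgvs_c = character(),
             hgvs_p = character(), rsid = character(), stringsAsFactors = FALSE)
}

.variant_key <- function(v) paste(v$protein_id, v$pos, v$ref_aa, v$alt_aa, sep = "|")

#' Merge and de-duplicate variant sets from two sources
#'
#' Builds the merged disease-causing set used for enrichment analysis. A
#' duplicate is the same amino-acid change at the same position in the same
#' protein; duplicates across sources are counted once (source
#' \code{"both"}). A key carrying a pathogenic-class label
#' (\code{pathogenic}, \code{likely_pathogenic}, \code{disease}) in one
#' source and a non-pathogenic-class label in the other is treated as a
#' conflicting interpretation and removed entirely.
#'
#' @param a variant data frame from the first source (e.g. ClinVar dialect).
#' @param b variant data frame from the second source (e.g. Humsavar).
#' @return list with \code{variants} (merged pathogenic records, a
#'   \code{source} column in \code{clinvar}/\code{humsavar}/\code{both})
#'   and \code{counts} (\code{only_a}, \code{only_b}, \code{both},
#'   \code{conflicts_removed}).
#' @export
merge_dedupe <- function(a, b) {
  if (is.null(a)) a <- .empty_variants()
  if (is.null(b)) b <- .empty_variants()
  ka <- .variant_key(a); kb <- .variant_key(b)
  # per-key pathogenic status in each source (any pathogenic copy counts)
  path_a <- tapply(is_pathogenic(a$significance), ka, any)
  path_b <- tapply(is_pathogenic(b$significance), kb, any)
  nonpath_a <- tapply(!is_pathogenic(a$significance), ka, any)
  nonpath_b <- tapply(!is_pathogenic(b$significance), kb, any)
  shared <- intersect(names(path_a), names(path_b))
  conflict <- shared[(path_a[shared] & nonpath_b[shared] & !path_b[shared]) |
                     (path_b[shared] & nonpath_a[shared] & !path_a[shared])]
  keys_a <- setdiff(names(path_a)[path_a], conflict)
  keys_b <- setdiff(names(path_b)[path_b], conflict)
  both <- intersect(keys_a, keys_b)
  only_a <- setdiff(keys_a, keys_b)
  only_b <- setdiff(keys_b, keys_a)
  pick <- function(df, keys, key_vec) {
    df <- df[key_vec %in% keys & is_pathogenic(df$significance), , drop = FALSE]
    df[!duplicated(.variant_key(df)), , drop = FALSE]
  }
  out <- rbind(pick(a, c(only_a, both), ka), pick(b, only_b, kb))
  out <- out[order(.variant_key(out)), , drop = FALSE]
  out$source[.variant_key(out) %in% both] <- "both"
  rownames(out) <- NULL
  list(variants = out,
       counts = list(only_a = length(only_a), only_b = length(only_b),
                     both = length(both),
                     conflicts_removed = length(conflict)))
}

#' Cross-receptor equivalence report for a set of query variants
#'
#' For each query variant (on the reference protein), lists the pathogenic
#' variants in other Cys-loop receptors whose equivalent reference
#' position falls within \code{window} residues of the query position,
#' labeled \code{exact} (same position) or \code{adjacent} (offset 1).
#' Each other-receptor variant is reported once, under its nearest query
#' (an exact match beats an adjacent one; remaining ties go to the
#' lower query position).
#'
#' Equivalent positions are computed by global pairwise alignment of each
#' other-receptor sequence to the reference when \code{sequences} is
#' supplied; otherwise \code{other_variants} must already carry an
#' \code{equivalent_ref_pos} column (e.g. the packaged published table).
#' Variants whose position cannot be mapped are flagged via the
#' \code{"n_unmapped"} attribute, not silently dropped into matches.
#'
#' @param query_variants data frame of reference-protein variants
#'   (columns \code{pos}, \code{ref_aa}, \code{alt_aa}; optional
#'   \code{hgvs_p}).
#' @param other_variants data frame of other-receptor variants (columns
#'   \code{gene}, \code{protein_id}, \code{pos}, \code{hgvs_p}; optional
#'   \code{family}, \code{hgvs_c}, \code{equivalent_ref_pos}).
#' @param sequences optional named list of \code{ProteinSequence} keyed by
#'   \code{protein_id}, including the reference.
#' @param ref reference \code{ProteinSequence} (required with
#'   \code{sequences}).
#' @param window maximum reference-coordinate offset reported (default 1).
#' @return data frame of equivalence rows: \code{query_variant},
#'   \code{query_pos}, \code{other_gene}, \code{family},
#'   \code{other_variant}, \code{other_pos}, \code{equivalent_ref_pos},
#'   \code{relation}.
#' @export
build_equivalence_table <- function(query_variants, other_variants,
                                    sequences = NULL, ref = NULL, window = 1L) {
  empty <- data.frame(query_variant = character(), query_pos = integer(),
                      other_gene = character(), family = character(),
                      other_variant = character(), other_pos = integer(),
                      equivalent_ref_pos = integer(), relation = character(),
                      stringsAsFactors = FALSE)
  if (nrow(query_variants) == 0L || nrow(other_variants) == 0L) {
    attr(empty, "n_unmapped") <- 0L
    return(empty)
  }
  if (!is.null(sequences)) {
    stopifnot(!is.null(ref))
    eq <- rep(NA_integer_, nrow(other_variants))
    for (pid in unique(other_variants$protein_id)) {
      su <- sequences[[pid]]
      if (is.null(su))
        stop("no sequence supplied for protein '", pid, "'", call. = FALSE)
      aln <- align_pair(su, ref, mode = "global")
      idx <- which(other_variants$protein_id == pid)
      eq[idx] <- vapply(other_variants$pos[idx], function(p) {
        m <- tryCatch(map_position(aln, p), error = function(e) NULL)
        if (is.null(m) || m$unaligned) NA_integer_ else m$target_pos
      }, integer(1))
    }
    other_variants$equivalent_ref_pos <- eq
  } else if (is.null(other_variants$equivalent_ref_pos)) {
    stop("either supply 'sequences' or an 'equivalent_ref_pos' column",
         call. = FALSE)
  }
  n_unmapped <- sum(is.na(other_variants$equivalent_ref_pos))
  if (is.null(query_variants$hgvs_p))
    query_variants$hgvs_p <- sprintf("%s%d%s",
                                     aa_one_to_three(query_variants$ref_aa),
                                     query_variants$pos,
                                     aa_one_to_three(query_variants$alt_aa))
  fam <- other_variants$family %||% rep(NA_character_, nrow(other_variants))
  qorder <- order(query_variants$pos)
  rows <- list()
  for (j in seq_len(nrow(other_variants))) {
    eq <- other_variants$equivalent_ref_pos[j]
    if (is.na(eq)) next
    d <- abs(query_variants$pos - eq)
    if (min(d) > window) next
    i <- qorder[which.min(d[qorder])]  # nearest query; tie -> lower position
    rows[[length(rows) + 1L]] <- data.frame(
      query_variant = query_variants$hgvs_p[i],
      query_pos = query_variants$pos[i],
      other_gene = other_variants$gene[j],
      family = fam[j],
      other_variant = other_variants$hgvs_p[j],
      other_pos = other_variants$pos[j],
      equivalent_ref_pos = eq,
      relation = if (d[i] == 0L) "exact" else "adjacent",
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else empty
  out <- out[order(match(out$query_pos, sort(unique(query_variants$pos)))), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- n_unmapped
  out
}
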