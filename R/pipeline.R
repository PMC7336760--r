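# Pipeline orchestration: config loading, the map / enrich / pore commands
# behind the command-line interface (inst/cli/cysloop.R), and a thin
# optional UniProt fetch helper. Every output TSV carries a header comment
# with the tool version and the config hash so identical runs are
# byte-identical and attributable.

#' Load and validate a pipeline config
#'
#' @param path YAML config; recognized keys: \code{sequences} (FASTA),
#'   \code{variants_clinvar}, \code{variants_humsavar},
#'   \code{query_variants}, \code{equivalence_table}, \code{topology},
#'   \code{structure_wt}, \code{structure_mutants}, \code{chain_roles},
#'   \code{flank}, \code{step_size}, \code{distance_convention},
#'   \code{out_dir}, \code{seed}.
#' @return list of class \code{PipelineConfig} (with \code{config_hash}).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::yaml.load_file(path)
  for (key in c("sequences", "variants_clinvar", "variants_humsavar",
                "query_variants", "equivalence_table", "topology",
                "structure_wt")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("config: file for '", key, "' not found: ", cfg[[key]],
           call. = FALSE)
  }
  if (!is.null(cfg$step_size) && (cfg$step_size <= 0 || cfg$step_size > 10))
    stop("config: step_size must be in (0, 10] Angstrom", call. = FALSE)
  if (!is.null(cfg$flank) && cfg$flank < 0)
    stop("config: flank must be >= 0", call. = FALSE)
  cfg$topology <- cfg$topology %||%
    system.file("extdata", "topology_cysloop.yaml", package = "cysloop")
  cfg$step_size <- cfg$step_size %||% 3
  cfg$out_dir <- cfg$out_dir %||% "."
  cfg$seed <- cfg$seed %||% 1L
  cfg$config_hash <- unname(tools::md5sum(path))
  class(cfg) <- "PipelineConfig"
  cfg
}

.tsv_header <- function(cfg) {
  c(sprintf("cysloop %s", as.character(packageVersion("cysloop"))),
    sprintf("config %s", cfg$config_hash %||% "inline"))
}

.write_tsv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", .tsv_header(cfg)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-receptor equivalence command
#'
#' Builds the equivalence report for the query variants: for every query,
#' all pathogenic variants in other Cys-loop receptors whose equivalent
#' reference position lies within one residue. Runs from the packaged
#' study fixtures when the config names no inputs.
#'
#' @param cfg a \code{PipelineConfig} (or path to one); \code{NULL} uses
#'   the packaged fixtures.
#' @param out output TSV path (default \code{equivalence.tsv} under the
#'   config's \code{out_dir}).
#' @return the equivalence data frame, invisibly.
#' @export
cmd_map <- function(cfg = NULL, out = NULL) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  fx <- fixtures()
  if (is.null(cfg)) cfg <- structure(list(out_dir = "."), class = "PipelineConfig")
  query <- if (!is.null(cfg$query_variants))
    read.delim(cfg$query_variants, comment.char = "#", stringsAsFactors = FALSE)
  else fx$seven_variants
  others <- if (!is.null(cfg$equivalence_table))
    read.delim(cfg$equivalence_table, comment.char = "#", stringsAsFactors = FALSE)
  else fx$table1
  if (nrow(others) > 0L) {
    others$pos <- vapply(others$hgvs_p, function(h) parse_hgvs_p(h)$pos, 1L)
    others$protein_id <- others$protein_id %||% others$gene
  }
  sequences <- NULL; refseq <- NULL
  if (!is.null(cfg$sequences)) {
    sequences <- read_fasta(cfg$sequences)
    refseq <- sequences[[cfg$reference %||% "GABRA2"]]
  }
  eq <- build_equivalence_table(query, others, sequences = sequences,
                                ref = refseq)
  if (nrow(eq) == 0L) warning("empty equivalence report", call. = FALSE)
  out <- out %||% file.path(cfg$out_dir %||% ".", "equivalence.tsv")
  .write_tsv(eq, out, cfg)
  message(sprintf("cmd_map: %d equivalence rows (%d of %d query variants) -> %s",
                  nrow(eq), length(unique(eq$query_variant)), nrow(query), out))
  invisible(eq)
}

#' Per-helix enrichment command
#'
#' Merges and de-duplicates the two variant sources, counts disease
#' variants per transmembrane helix (with and without the flank windows),
#' tests the M1--M4 distribution against a uniform expectation, and writes
#' the counts, chi-square summary and center-relative histogram tables.
#'
#' @param cfg a \code{PipelineConfig} or path; must name
#'   \code{variants_clinvar} and/or \code{variants_humsavar}.
#' @param out_prefix path prefix of the three TSVs (default
#'   \code{enrich} under \code{out_dir}).
#' @return list with \code{counts_core}, \code{counts_flank},
#'   \code{chisq_core}, \code{chisq_flank}, \code{histogram},
#'   \code{provenance}, invisibly.
#' @export
cmd_enrich <- function(cfg, out_prefix = NULL) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  reg <- load_topology(cfg$topology)
  cv <- if (!is.null(cfg$variants_clinvar))
    load_variants(cfg$variants_clinvar, "clinvar") else .empty_variants()
  hv <- if (!is.null(cfg$variants_humsavar))
    load_variants(cfg$variants_humsavar, "humsavar") else .empty_variants()
  merged <- merge_dedupe(cv, hv)
  message(sprintf(
    "cmd_enrich: %d pathogenic variants after dedupe (%d clinvar-only, %d humsavar-only, %d both, %d conflicting removed)",
    nrow(merged$variants), merged$counts$only_a, merged$counts$only_b,
    merged$counts$both, merged$counts$conflicts_removed))
  counts_core <- count_by_helix(merged$variants, reg, flank_included = FALSE)
  counts_flank <- count_by_helix(merged$variants, reg, flank_included = TRUE)
  chi_core <- chisquare_uniform(counts_core)
  chi_flank <- chisquare_uniform(counts_flank)
  hist <- position_histogram(merged$variants, reg)
  out_prefix <- out_prefix %||% file.path(cfg$out_dir %||% ".", "enrich")
  .write_tsv(data.frame(helix = rep(names(counts_core$counts), 2),
                        flank_included = rep(c(FALSE, TRUE), each = 4),
                        count = c(counts_core$counts, counts_flank$counts)),
             paste0(out_prefix, "_counts.tsv"), cfg)
  .write_tsv(data.frame(
    scope = c("core", "core_plus_flank"),
    statistic = c(chi_core$statistic, chi_flank$statistic),
    df = c(chi_core$df, chi_flank$df),
    p_value = c(chi_core$p_value, chi_flank$p_value)),
    paste0(out_prefix, "_chisq.tsv"), cfg)
  .write_tsv(hist, paste0(out_prefix, "_histogram.tsv"), cfg)
  invisible(list(counts_core = counts_core, counts_flank = counts_flank,
                 chisq_core = chi_core, chisq_flank = chi_flank,
                 histogram = hist, provenance = merged$counts))
}

#' Pore-profile command
#'
#' Profiles the wild-type structure (and any mutant configurations) along
#' the pore axis in \code{step_size} steps, classifies each step by
#' chloride passability, and writes the per-structure profiles plus the
#' wild-type-versus-mutant delta table.
#'
#' @param cfg a \code{PipelineConfig} or path; must name
#'   \code{structure_wt}; \code{structure_mutants} is an optional named
#'   list of files sharing the wild-type's chain layout.
#' @param out_prefix path prefix for outputs (default \code{pore}).
#' @return list with \code{wt} profile, \code{mutants}, \code{deltas},
#'   invisibly.
#' @export
cmd_pore <- function(cfg, out_prefix = NULL) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  if (is.null(cfg$structure_wt))
    stop("config: structure_wt is required", call. = FALSE)
  roles <- if (!is.null(cfg$chain_roles)) unlist(cfg$chain_roles) else NULL
  wt <- read_structure(cfg$structure_wt, chain_roles = roles)
  axis <- pore_axis(wt)
  prof <- pore_profile(wt, axis, step_size = cfg$step_size %||% 3)
  out_prefix <- out_prefix %||% file.path(cfg$out_dir %||% ".", "pore")
  write_profile_tsv(prof, paste0(out_prefix, "_wt.tsv"), .tsv_header(cfg))
  mutants <- list()
  if (!is.null(cfg$structure_mutants)) {
    for (nm in names(cfg$structure_mutants)) {
      ms <- read_structure(cfg$structure_mutants[[nm]], chain_roles = roles)
      mp <- pore_profile(ms, axis, step_size = cfg$step_size %||% 3,
                         s_values = prof$steps$s + prof$s_offset)
      mutants[[nm]] <- mp
      write_profile_tsv(mp, paste0(out_prefix, "_", nm, ".tsv"),
                        .tsv_header(cfg))
    }
  }
  deltas <- NULL
  if (length(mutants) > 0L) {
    deltas <- compare_profiles(prof, mutants)
    .write_tsv(deltas, paste0(out_prefix, "_deltas.tsv"), cfg)
  }
  ok <- !prof$steps$undefined
  i <- which.min(ifelse(ok, prof$steps$radius, Inf))
  message(sprintf("cmd_pore: narrowest radius %.2f A at s = %.1f A (%s)",
                  prof$steps$radius[i], prof$steps$s[i],
                  classify_permeation(prof$steps$radius[i])))
  invisible(list(wt = prof, mutants = mutants, deltas = deltas))
}

#' Fetch canonical protein sequences from UniProt
#'
#' Thin convenience helper for the CLI layer; requires network access and
#' is never used by the core analysis functions, which accept local FASTA.
#'
#' @param accessions character vector of UniProtKB accessions.
#' @param path destination FASTA file.
#' @return \code{path}, invisibly.
#' @export
uniprot_fetch <- function(accessions, path) {
  urls <- sprintf("https://rest.uniprot.org/uniprotkb/%s.fasta", accessions)
  chunks <- vapply(urls, function(u) {
    con <- url(u)
    on.exit(close(con))
    paste(readLines(con, warn = FALSE), collapse = "\n")
  }, "")
  writeLines(chunks, path)
  invisible(path)
}
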