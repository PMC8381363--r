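#' Threshold configuration for the atlas pipeline
#'
#' All tunable thresholds used across classification, network construction,
#' novelty/annotation filtering and iBAQ quantification live in a single
#' validated configuration object, so that every rule in the pipeline is
#' driven from one place and can be overridden from a YAML file or
#' individual arguments.
#'
#' @param detect_min Detection floor in FPKM. A gene is "detected" in a
#'   tissue when its FPKM is at least this value (default 1).
#' @param fold_elevated Fold-change threshold shared by the three elevated
#'   categories (default 5): tissue enriched, group enriched, tissue
#'   enhanced.
#' @param fold_high Fold-change defining "highly" tissue-enriched genes
#'   (default 50).
#' @param group_size_min,group_size_max Allowed tissue-set sizes for the
#'   group-enriched category (defaults 2 and 7).
#' @param network_max_tissues Maximum tissue-set size for a group node to be
#'   kept in the enrichment network (default 5).
#' @param network_min_genes Minimum gene count for a group node to be kept
#'   in the enrichment network (default 3).
#' @param novel_min_length Exclusive minimum transcript length in nt for a
#'   novel candidate (default 200; retained transcripts are strictly
#'   longer).
#' @param novel_min_exons Exclusive minimum exon count (default 1; retained
#'   transcripts have more than one exon).
#' @param annot_min_bitscore,annot_min_pident,annot_max_evalue Evidence
#'   thresholds for calling a novel gene "annotated" by a database hit:
#'   bit score strictly above 500, percent identity strictly above 50,
#'   E-value strictly below 1e-20.
#' @param overlap_max_evalue,overlap_min_identity Thresholds for the
#'   cross-species proteome overlap: E-value at most 1e-5 and identity at
#'   least 30 percent (both inclusive).
#' @param ibaq_pep_len_min,ibaq_pep_len_max Length window, in amino acids,
#'   of tryptic peptides counted as observable for iBAQ (defaults 6 and
#'   30).
#' @param ibaq_missed_cleavages Missed cleavages allowed in the theoretical
#'   digest used for the observable-peptide count (default 0).
#' @param abundance_bins Increasing FPKM cut points for the per-tissue
#'   detected-gene strata (default 1, 10, 100, 1000, 10000).
#'
#' @return An object of class \code{atlas_config}: a named list of the
#'   validated threshold values.
#' @examples
#' cfg <- atlas_config()
#' cfg$fold_elevated
#' atlas_config(fold_high = 100)$fold_high
#' @export
atlas_config <- function(detect_min = 1,
                         fold_elevated = 5,
                         fold_high = 50,
                         group_size_min = 2L,
                         group_size_max = 7L,
                         network_max_tissues = 5L,
                         network_min_genes = 3L,
                         novel_min_length = 200,
                         novel_min_exons = 1L,
                         annot_min_bitscore = 500,
                         annot_min_pident = 50,
                         annot_max_evalue = 1e-20,
                         overlap_max_evalue = 1e-5,
                         overlap_min_identity = 30,
                         ibaq_pep_len_min = 6L,
                         ibaq_pep_len_max = 30L,
                         ibaq_missed_cleavages = 0L,
                         abundance_bins = c(1, 10, 100, 1000, 10000)) {
  cfg <- list(
    detect_min = as.numeric(detect_min),
    fold_elevated = as.numeric(fold_elevated),
    fold_high = as.numeric(fold_high),
    group_size_min = as.integer(group_size_min),
    group_size_max = as.integer(group_size_max),
    network_max_tissues = as.integer(network_max_tissues),
    network_min_genes = as.integer(network_min_genes),
    novel_min_length = as.numeric(novel_min_length),
    novel_min_exons = as.integer(novel_min_exons),
    annot_min_bitscore = as.numeric(annot_min_bitscore),
    annot_min_pident = as.numeric(annot_min_pident),
    annot_max_evalue = as.numeric(annot_max_evalue),
    overlap_max_evalue = as.numeric(overlap_max_evalue),
    overlap_min_identity = as.numeric(overlap_min_identity),
    ibaq_pep_len_min = as.integer(ibaq_pep_len_min),
    ibaq_pep_len_max = as.integer(ibaq_pep_len_max),
    ibaq_missed_cleavages = as.integer(ibaq_missed_cleavages),
    abundance_bins = as.numeric(abundance_bins)
  )
  class(cfg) <- "atlas_config"
  validate_config(cfg)
  cfg
}

#' Validate an atlas configuration
#'
#' Checks the structural invariants of a threshold configuration and stops
#' with an informative message on the first violation.
#'
#' @param cfg An \code{atlas_config} object (or a bare named list with the
#'   same fields).
#' @return The configuration, invisibly, when valid.
#' @export
validate_config <- function(cfg) {
  scalar_fields <- setdiff(names(cfg), "abundance_bins")
  for (f in scalar_fields) {
    v <- cfg[[f]]
    if (length(v) != 1L || !is.finite(v)) {
      stop(sprintf("config field '%s' must be a single finite number", f))
    }
    if (f == "ibaq_missed_cleavages") {
      if (v < 0) stop("ibaq_missed_cleavages must be >= 0")
    } else if (v <= 0) {
      stop(sprintf("config field '%s' must be strictly positive", f))
    }
  }
  if (cfg$group_size_min < 2L)
    stop("group_size_min must be at least 2")
  if (cfg$group_size_max < cfg$group_size_min)
    stop("group_size_max must be >= group_size_min")
  if (cfg$fold_high < cfg$fold_elevated)
    stop("fold_high must be >= fold_elevated")
  if (cfg$ibaq_pep_len_min > cfg$ibaq_pep_len_max)
    stop("ibaq_pep_len_min must be <= ibaq_pep_len_max")
  if (any(cfg$abundance_bins <= 0))
    stop("abundance_bins must be strictly positive")
  if (is.unsorted(cfg$abundance_bins, strictly = TRUE))
    stop("abundance_bins must be strictly increasing")
  invisible(cfg)
}

#' Read an atlas configuration from a file
#'
#' Accepts either a YAML mapping or a flat \code{key=value} file whose keys
#' mirror the \code{\link{atlas_config}} argument names. Keys absent from
#' the file keep their defaults; unknown keys are an error.
#'
#' @param path Path to the configuration file.
#' @return An \code{atlas_config} object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  is_flat <- all(grepl("^\\s*($|#|[A-Za-z_.]+\\s*=)", txt))
  if (is_flat && any(grepl("=", txt, fixed = TRUE))) {
    kv <- txt[grepl("=", txt, fixed = TRUE)]
    kv <- sub("#.*$", "", kv)
    keys <- trimws(sub("=.*$", "", kv))
    vals <- trimws(sub("^[^=]*=", "", kv))
    overrides <- lapply(vals, function(v) {
      parts <- strsplit(v, "[,;]\\s*|\\s+")[[1]]
      as.numeric(parts[nzchar(parts)])
    })
    names(overrides) <- keys
  } else {
    overrides <- yaml::read_yaml(path)
  }
  known <- names(formals(atlas_config))
  bad <- setdiff(names(overrides), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(atlas_config, overrides)
}

#' @export
print.atlas_config <- function(x, ...) {
  cat("atlas threshold configuration\n")
  for (f in names(x)) {
    cat(sprintf("  %-22s %s\n", f, paste(format(x[[f]]), collapse = " ")))
  }
  invisible(x)
}
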