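#' Construct an expression matrix
#'
#' A light container for a genes x samples abundance matrix with a declared
#' unit. Values must be non-negative and finite; gene and sample identifiers
#' must be unique.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param unit Either "FPKM" or "TPM".
#' @return An object of class \code{expression_matrix}.
#' @export
expression_matrix <- function(values, unit = c("FPKM", "TPM")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite (no NA/NaN/Inf)")
  if (any(values < 0))
    stop("negative expression value found; abundances must be >= 0")
  structure(list(values = values, unit = unit), class = "expression_matrix")
}

#' Construct a tissue-level profile
#'
#' Genes x tissues matrix of replicate-averaged FPKM, the sole input of the
#' specificity classifier. At least two tissues are required.
#'
#' @param values Numeric matrix with gene-id rownames and tissue colnames.
#' @return An object of class \code{tissue_profile}.
#' @export
tissue_profile <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry gene ids as rownames and tissue names as colnames")
  if (anyDuplicated(colnames(values))) stop("tissue names must be unique")
  if (anyDuplicated(rownames(values))) stop("gene ids must be unique")
  if (ncol(values) < 2L) stop("a tissue profile needs at least 2 tissues")
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0))
    stop("profile values must be finite and non-negative")
  structure(list(values = values, unit = "FPKM"), class = "tissue_profile")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @export
print.tissue_profile <- function(x, ...) {
  cat(sprintf("tissue_profile: %d genes x %d tissues [FPKM]\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a gene x sample expression table
#'
#' Expects a UTF-8 TSV whose first column is headed \code{gene_id} and whose
#' remaining columns are sample abundances. Malformed numeric cells,
#' negative values and duplicated identifiers are rejected.
#'
#' @param path Path to the TSV file.
#' @param unit Declared abundance unit, "FPKM" or "TPM".
#' @return An \code{expression_matrix}.
#' @export
read_expression_table <- function(path, unit = c("FPKM", "TPM")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("expression table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("expression table needs a gene_id column and at least one sample")
  if (names(df)[1] != "gene_id")
    stop("first column of an expression table must be headed 'gene_id'")
  gene_ids <- df[[1]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id in expression table: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  body <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("malformed numeric cell '%s' (gene %s, sample %s)",
                 body[bad[1], bad[2]], gene_ids[bad[1]], colnames(body)[bad[2]]))
  }
  dimnames(num) <- list(gene_ids, colnames(body))
  expression_matrix(num, unit)
}

#' Write an expression table
#'
#' Inverse of \code{\link{read_expression_table}}; first column
#' \code{gene_id}, tab-separated, '.' decimal separator.
#'
#' @param x An \code{expression_matrix} or \code{tissue_profile}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_expression_table <- function(x, path) {
  values <- if (inherits(x, c("expression_matrix", "tissue_profile"))) x$values else x
  df <- data.frame(gene_id = rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read sample metadata
#'
#' TSV with columns \code{sample_id}, \code{tissue}, \code{donor_id}.
#'
#' @param path Path to the metadata TSV.
#' @return A data.frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  need <- c("sample_id", "tissue", "donor_id")
  if (!all(need %in% names(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df[need]
}

#' Aggregate replicate samples to tissue-level means
#'
#' Collapses a genes x samples FPKM matrix to a genes x tissues profile by
#' taking the arithmetic mean over each tissue's replicate samples.
#' Single-replicate tissues pass through unchanged. Gene order and count
#' are preserved, and the result does not depend on sample order.
#'
#' @param matrix An \code{expression_matrix} with unit FPKM.
#' @param meta Sample metadata data.frame (columns \code{sample_id},
#'   \code{tissue}, \code{donor_id}); every sample in \code{matrix} must
#'   have exactly one row.
#' @return A \code{tissue_profile}.
#' @examples
#' m <- expression_matrix(matrix(c(4, 6), 1, 2,
#'        dimnames = list("g1", c("s1", "s2"))), "FPKM")
#' meta <- data.frame(sample_id = c("s1", "s2"),
#'                    tissue = "liver", donor_id = c("d1", "d2"))
#' aggregate_by_tissue(m, meta)$values  # liver = 5
#' @export
aggregate_by_tissue <- function(matrix, meta) {
  if (!inherits(matrix, "expression_matrix")) stop("matrix must be an expression_matrix")
  if (matrix$unit != "FPKM") stop("tissue aggregation is defined on FPKM matrices")
  samples <- colnames(matrix$values)
  missing <- setdiff(samples, meta$sample_id)
  if (length(missing))
    stop("sample(s) without metadata: ", paste(missing, collapse = ", "))
  tissue_of <- meta$tissue[match(samples, meta$sample_id)]
  tissues <- sort(unique(tissue_of))
  out <- vapply(tissues, function(tt) {
    cols <- which(tissue_of == tt)
    rowMeans(matrix$values[, cols, drop = FALSE])
  }, numeric(nrow(matrix$values)))
  if (!is.matrix(out)) out <- base::matrix(out, nrow = nrow(matrix$values),
                                           dimnames = list(rownames(matrix$values), tissues))
  dimnames(out) <- list(rownames(matrix$values), tissues)
  tissue_profile(out)
}

# shared TSV writer: deterministic column order, no quoting, '.' decimals
write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write to '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Write a classification call table
#'
#' Columns: \code{gene_id}, \code{category}, \code{elevated_tissues}
#' (';'-joined), \code{fold_change} ("inf" for unbounded folds, empty for
#' non-elevated categories), \code{highly_enriched} (true/false).
#'
#' @param calls Data frame of calls from \code{\link{classify_all}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_calls <- function(calls, path) {
  fc <- ifelse(is.na(calls$fold_change), "",
               ifelse(is.infinite(calls$fold_change), "inf",
                      format(calls$fold_change, digits = 15, trim = TRUE, scientific = FALSE)))
  out <- data.frame(gene_id = calls$gene_id,
                    category = as.character(calls$category),
                    elevated_tissues = calls$elevated_tissues,
                    fold_change = fc,
                    highly_enriched = ifelse(calls$highly_enriched, "true", "false"),
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
}

#' Read a classification call table written by \code{\link{write_calls}}
#'
#' @param path Path to the calls TSV.
#' @return A data.frame in the same shape \code{\link{classify_all}} returns.
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) stop("calls file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  fc <- suppressWarnings(ifelse(df$fold_change == "inf", Inf,
                                ifelse(df$fold_change == "", NA_real_,
                                       as.numeric(df$fold_change))))
  data.frame(gene_id = df$gene_id,
             category = factor(df$category, levels = specificity_categories()),
             elevated_tissues = df$elevated_tissues,
             fold_change = fc,
             highly_enriched = df$highly_enriched == "true",
             stringsAsFactors = FALSE)
}

#' Write an iBAQ result table
#'
#' Adds a \code{log10_ibaq} column (empty where iBAQ is 0) for
#' abundance-ranking plots.
#'
#' @param ibaq Ranked data.frame from \code{\link{compute_ibaq}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_ibaq <- function(ibaq, path) {
  l10 <- ifelse(ibaq$ibaq > 0, format(log10(ibaq$ibaq), digits = 10, trim = TRUE), "")
  out <- data.frame(accession = ibaq$accession,
                    n_observable_peptides = ibaq$n_observable_peptides,
                    ibaq = format(ibaq$ibaq, digits = 15, trim = TRUE, scientific = FALSE),
                    rank = ibaq$rank,
                    log10_ibaq = l10,
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
}

#' Read a transcript record table
#'
#' TSV with columns \code{transcript_id}, \code{gene_id}, \code{class_code},
#' \code{length}, \code{exon_count}. These columns map directly onto
#' gffcompare ".tmap" output fields (qry_id, qry_gene_id, class_code, len,
#' num_exons); this reader takes the tabular form and does not parse GTF.
#'
#' @param path Path to the TSV.
#' @return A data.frame of transcript records.
#' @export
read_transcript_table <- function(path) {
  if (!file.exists(path)) stop("transcript table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  need <- c("transcript_id", "gene_id", "class_code", "length", "exon_count")
  if (!all(need %in% names(df)))
    stop("transcript table must have columns: ", paste(need, collapse = ", "))
  df$length <- as.numeric(df$length)
  df$exon_count <- as.integer(df$exon_count)
  if (any(is.na(df$length)) || any(df$length <= 0)) stop("transcript length must be > 0")
  if (any(is.na(df$exon_count)) || any(df$exon_count < 1)) stop("exon_count must be >= 1")
  df[need]
}

#' Read an annotation / alignment hit table
#'
#' BLAST outfmt-6-like TSV with a header. Required columns are given by
#' \code{need}; extra columns are kept.
#'
#' @param path Path to the TSV.
#' @param need Character vector of required column names.
#' @return A data.frame of hits with numeric score columns.
#' @export
read_hit_table <- function(path,
                           need = c("query_id", "database", "bitscore", "pident", "evalue")) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  if (!all(need %in% names(df)))
    stop("hit table must have columns: ", paste(need, collapse = ", "))
  for (col in intersect(c("bitscore", "pident", "evalue"), names(df)))
    df[[col]] <- as.numeric(df[[col]])
  df
}
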