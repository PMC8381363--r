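#' The six expression-specificity categories
#'
#' Category labels in classification precedence order: a gene is assigned
#' the first category whose rule it satisfies, which makes the six classes
#' a partition of the gene set.
#'
#' @return Character vector of the six category names.
#' @export
specificity_categories <- function() {
  c("not_detected", "tissue_enriched", "group_enriched",
    "tissue_enhanced", "expressed_in_all", "mixed")
}

# Core rule evaluation on one per-tissue FPKM vector. Returns list(category,
# elevated [character], fold). Precedence: not_detected -> tissue_enriched ->
# group_enriched -> tissue_enhanced -> expressed_in_all -> mixed.
#
# Group search: under the mean(G) >= fold * mean(complement) criterion the
# best group of size k is always the k highest-expressing tissues, so only
# top-k prefixes (k = group_size_min..group_size_max) of the expression-sorted
# tissue list are examined; the smallest qualifying prefix is reported.
# Ties are broken by descending expression then lexicographic tissue name.
classify_vector <- function(v, tissues, config) {
  n <- length(v)
  # not detected: below the floor everywhere
  if (all(v < config$detect_min)) {
    return(list(category = "not_detected", elevated = character(0), fold = NA_real_))
  }
  ord <- order(-v, tissues, method = "radix")
  vs <- v[ord]
  ts <- tissues[ord]
  top <- vs[1]
  second <- vs[2]
  # tissue enriched: top tissue at least fold_elevated x every other tissue
  if (top >= config$detect_min && top >= config$fold_elevated * second) {
    fold <- if (second == 0) Inf else top / second
    return(list(category = "tissue_enriched", elevated = ts[1], fold = fold))
  }
  # group enriched: smallest qualifying top-k prefix
  kmax <- min(config$group_size_max, n - 1L)
  if (kmax >= config$group_size_min) {
    cums <- cumsum(vs)
    total <- cums[n]
    for (k in config$group_size_min:kmax) {
      if (vs[k] < config$detect_min) break  # no size-k set can be all-detected
      gmean <- cums[k] / k
      cmean <- (total - cums[k]) / (n - k)
      if (gmean >= config$fold_elevated * cmean) {
        fold <- if (cmean == 0) Inf else gmean / cmean
        return(list(category = "group_enriched", elevated = ts[seq_len(k)], fold = fold))
      }
    }
  }
  # tissue enhanced: top tissue at least fold_elevated x mean of the rest
  rest_mean <- (sum(v) - top) / (n - 1)
  if (top >= config$detect_min && top >= config$fold_elevated * rest_mean) {
    fold <- if (rest_mean == 0) Inf else top / rest_mean
    return(list(category = "tissue_enhanced", elevated = ts[1], fold = fold))
  }
  if (all(v >= config$detect_min)) {
    return(list(category = "expressed_in_all", elevated = character(0), fold = NA_real_))
  }
  list(category = "mixed", elevated = character(0), fold = NA_real_)
}

#' Classify one gene's per-tissue expression vector
#'
#' Assigns one of six specificity categories from a vector of
#' replicate-averaged FPKM values, applying the rules in precedence order:
#' \emph{not detected} (below \code{detect_min} everywhere), \emph{tissue
#' enriched} (top tissue at least \code{fold_elevated} times every other
#' tissue), \emph{group enriched} (a set of \code{group_size_min} to
#' \code{group_size_max} detected tissues whose mean is at least
#' \code{fold_elevated} times the mean of the remaining tissues),
#' \emph{tissue enhanced} (top tissue at least \code{fold_elevated} times
#' the mean of all other tissues), \emph{expressed in all} (at or above
#' \code{detect_min} everywhere), else \emph{mixed}.
#'
#' @param expression Named non-negative numeric vector of per-tissue FPKM
#'   (names are tissue names; length at least 2).
#' @param config An \code{\link{atlas_config}}.
#' @param gene_id Optional gene identifier carried into the result.
#' @return A list of class \code{specificity_call} with fields
#'   \code{gene_id}, \code{category}, \code{elevated_tissues},
#'   \code{fold_change} (ratio, possibly \code{Inf}; \code{NA} for
#'   non-elevated categories) and \code{highly_enriched}.
#' @examples
#' cfg <- atlas_config()
#' classify_gene(c(brain = 100, liver = 5, lung = 5, heart = 5), cfg)$category
#' @export
classify_gene <- function(expression, config = atlas_config(), gene_id = NA_character_) {
  if (length(expression) < 2L)
    stop("classification needs expression in at least 2 tissues")
  if (anyNA(expression) || any(expression < 0))
    stop("expression values must be non-negative and non-missing")
  tissues <- names(expression)
  if (is.null(tissues)) tissues <- paste0("tissue", seq_along(expression))
  res <- classify_vector(as.numeric(expression), tissues, config)
  structure(list(
    gene_id = gene_id,
    category = res$category,
    elevated_tissues = res$elevated,
    fold_change = res$fold,
    highly_enriched = identical(res$category, "tissue_enriched") &&
      res$fold >= config$fold_high
  ), class = "specificity_call")
}

#' @export
print.specificity_call <- function(x, ...) {
  cat(sprintf("%s: %s%s%s\n",
              ifelse(is.na(x$gene_id), "gene", x$gene_id), x$category,
              if (length(x$elevated_tissues))
                paste0(" [", paste(x$elevated_tissues, collapse = ";"),
                       ", fold ", format(x$fold_change, digits = 4), "]") else "",
              if (isTRUE(x$highly_enriched)) " (highly enriched)" else ""))
  invisible(x)
}

#' Classify every gene of a tissue profile
#'
#' Applies \code{\link{classify_gene}} to each row of a tissue profile and
#' builds the atlas summary (per-category counts and percentages, and
#' per-tissue enriched/elevated gene counts).
#'
#' @param profile A \code{\link{tissue_profile}}.
#' @param config An \code{\link{atlas_config}}.
#' @return A list with elements \code{calls} (data.frame with columns
#'   \code{gene_id}, \code{category}, \code{elevated_tissues} (';'-joined),
#'   \code{fold_change}, \code{highly_enriched}; the profile's tissue names
#'   are attached as \code{attr(calls, "tissues")}) and \code{summary}
#'   (see \code{\link{summarize_categories}}).
#' @export
classify_all <- function(profile, config = atlas_config()) {
  if (!inherits(profile, "tissue_profile")) stop("profile must be a tissue_profile")
  vals <- profile$values
  tissues <- colnames(vals)
  n <- nrow(vals)
  category <- character(n)
  elev <- character(n)
  fold <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    res <- tryCatch(classify_vector(vals[i, ], tissues, config),
                    error = function(e) stop("gene ", rownames(vals)[i], ": ",
                                             conditionMessage(e)))
    category[i] <- res$category
    elev[i] <- paste(sort(res$elevated), collapse = ";")
    fold[i] <- res$fold
  }
  calls <- data.frame(
    gene_id = rownames(vals),
    category = factor(category, levels = specificity_categories()),
    elevated_tissues = elev,
    fold_change = fold,
    highly_enriched = category == "tissue_enriched" & fold >= config$fold_high,
    stringsAsFactors = FALSE
  )
  attr(calls, "tissues") <- tissues
  list(calls = calls, summary = summarize_categories(calls, tissues, config))
}

#' Summarise classification calls
#'
#' Category counts with global percentages (rounded half away from zero to
#' integer percent) and per-tissue counts of tissue-enriched and elevated
#' genes (per-tissue shares to one decimal), matching the atlas reporting
#' conventions.
#'
#' @param calls Calls data.frame from \code{\link{classify_all}}.
#' @param tissues Tissue names; defaults to \code{attr(calls, "tissues")}.
#' @param config An \code{\link{atlas_config}}.
#' @return A list of class \code{category_summary}: \code{n_genes},
#'   \code{counts}, \code{percent} (named integer percentages),
#'   \code{per_tissue} (data.frame with tissue, n_enriched, pct_enriched,
#'   n_elevated).
#' @export
summarize_categories <- function(calls, tissues = attr(calls, "tissues"),
                                 config = atlas_config()) {
  if (is.null(tissues))
    tissues <- sort(unique(unlist(strsplit(calls$elevated_tissues[
      calls$elevated_tissues != ""], ";", fixed = TRUE))))
  counts <- table(factor(calls$category, levels = specificity_categories()))
  counts <- stats::setNames(as.integer(counts), specificity_categories())
  n <- nrow(calls)
  pct <- if (n > 0) round_half_up(100 * counts / n, 0) else counts * 0
  elev_cat <- c("tissue_enriched", "group_enriched", "tissue_enhanced")
  sets <- strsplit(calls$elevated_tissues, ";", fixed = TRUE)
  per_tissue <- do.call(rbind, lapply(tissues, function(tt) {
    in_set <- vapply(sets, function(s) tt %in% s, logical(1))
    n_enr <- sum(calls$category == "tissue_enriched" & in_set)
    n_elev <- sum(calls$category %in% elev_cat & in_set)
    data.frame(tissue = tt, n_enriched = n_enr,
               pct_enriched = if (n > 0) round_half_up(100 * n_enr / n, 1) else 0,
               n_elevated = n_elev, stringsAsFactors = FALSE)
  }))
  structure(list(n_genes = n, counts = counts, percent = pct,
                 per_tissue = per_tissue), class = "category_summary")
}

#' @export
print.category_summary <- function(x, ...) {
  cat(sprintf("category summary over %d genes\n", x$n_genes))
  for (cc in names(x$counts))
    cat(sprintf("  %-17s %6d  (%d%%)\n", cc, x$counts[[cc]], x$percent[[cc]]))
  invisible(x)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention of the
#' printed atlas percentages), unlike base R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(2.5)      # 3
#' round_half_up(4.05, 1)  # 4.1
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Fraction of a tissue's transcript mass encoded by its elevated genes
#'
#' For one tissue, the percentage of total FPKM contributed by genes that
#' are elevated (tissue enriched, group enriched or tissue enhanced) in
#' that tissue.
#'
#' @param profile A \code{\link{tissue_profile}}.
#' @param calls Calls data.frame from \code{\link{classify_all}}.
#' @param tissue Tissue name present in the profile.
#' @return Percentage in [0, 100] (unrounded).
#' @export
elevated_transcript_fraction <- function(profile, calls, tissue) {
  if (!tissue %in% colnames(profile$values))
    stop("tissue '", tissue, "' not in profile")
  col <- profile$values[, tissue]
  total <- sum(col)
  if (total == 0)
    stop("total FPKM in tissue '", tissue, "' is zero; fraction undefined")
  elev_cat <- c("tissue_enriched", "group_enriched", "tissue_enhanced")
  sets <- strsplit(calls$elevated_tissues, ";", fixed = TRUE)
  in_set <- vapply(sets, function(s) tissue %in% s, logical(1))
  keep <- calls$category %in% elev_cat & in_set
  idx <- match(calls$gene_id[keep], rownames(profile$values))
  100 * sum(col[idx]) / total
}

#' Detected-gene counts per tissue at increasing abundance cuts
#'
#' For each tissue, the number of genes whose FPKM is at least each cut
#' point. Counts are weakly decreasing across increasing cuts.
#'
#' @param profile A \code{\link{tissue_profile}}.
#' @param bins Strictly increasing FPKM cut points.
#' @return Integer matrix, tissues x cuts; column names are
#'   \code{">=cut"}.
#' @export
detected_gene_counts <- function(profile, bins = atlas_config()$abundance_bins) {
  if (length(bins) < 1 || is.unsorted(bins, strictly = TRUE))
    stop("bins must be strictly increasing")
  vals <- profile$values
  out <- vapply(bins, function(b) colSums(vals >= b), numeric(ncol(vals)))
  if (!is.matrix(out)) out <- matrix(out, nrow = ncol(vals))
  dimnames(out) <- list(colnames(vals), paste0(">=", format(bins, trim = TRUE)))
  storage.mode(out) <- "integer"
  out
}

#' Spearman similarity and average-linkage clustering of samples
#'
#' Computes the sample-by-sample Spearman rank correlation matrix of a TPM
#' expression matrix and clusters the samples by average linkage on the
#' distance 1 - rho. The merge tree is also serialised to Newick with
#' sample ids as leaf labels.
#'
#' @param matrix An \code{\link{expression_matrix}} with unit TPM (genes x
#'   samples) and at least two samples.
#' @return A list with \code{correlation} (symmetric matrix, unit
#'   diagonal), \code{tree} (an \code{hclust} object) and \code{newick}
#'   (character scalar).
#' @export
spearman_similarity <- function(matrix) {
  if (!inherits(matrix, "expression_matrix")) stop("matrix must be an expression_matrix")
  if (matrix$unit != "TPM")
    stop("sample similarity is computed on TPM matrices")
  vals <- matrix$values
  if (ncol(vals) < 2L) stop("need at least 2 samples")
  if (nrow(vals) < 2L) stop("need at least 2 genes to rank")
  const <- apply(vals, 2, function(x) stats::var(rank(x)) == 0)
  if (any(const))
    stop("constant-expression sample(s), Spearman undefined: ",
         paste(colnames(vals)[const], collapse = ", "))
  rho <- stats::cor(vals, method = "spearman")
  hc <- stats::hclust(stats::as.dist(1 - rho), method = "average")
  phy <- ape::as.phylo(hc)
  nwk <- ape::write.tree(phy)
  list(correlation = rho, tree = hc, newick = nwk)
}

#' Write a sample-clustering tree to a Newick file
#'
#' @param sim Result of \code{\link{spearman_similarity}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(sim, path) {
  writeLines(sim$newick, path)
  invisible(path)
}
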