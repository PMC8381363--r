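# Independent oracles used to cross-check the implementation. These are
# deliberately naive (exhaustive enumeration, manual formulas) and share no
# code with the package's own paths.

# rule-by-rule classifier with exhaustive subset enumeration for the group
# category (all tissue subsets of sizes group_size_min..group_size_max)
oracle_classify <- function(v, cfg = atlas_config()) {
  n <- length(v)
  if (all(v < cfg$detect_min)) return("not_detected")
  vs <- sort(v, decreasing = TRUE)
  if (vs[1] >= cfg$detect_min && vs[1] >= cfg$fold_elevated * vs[2])
    return("tissue_enriched")
  kmax <- min(cfg$group_size_max, n - 1)
  if (kmax >= cfg$group_size_min) {
    for (k in cfg$group_size_min:kmax) {
      for (S in utils::combn(n, k, simplify = FALSE)) {
        if (all(v[S] >= cfg$detect_min) &&
            mean(v[S]) >= cfg$fold_elevated * mean(v[-S]))
          return("group_enriched")
      }
    }
  }
  if (vs[1] >= cfg$detect_min && vs[1] >= cfg$fold_elevated * mean(vs[-1]))
    return("tissue_enhanced")
  if (all(v >= cfg$detect_min)) return("expressed_in_all")
  "mixed"
}

# vectorised version of the exhaustive oracle for whole profiles; loops over
# subsets, not genes, so large comparisons stay fast
oracle_classify_profile <- function(X, cfg = atlas_config()) {
  n <- ncol(X)
  sorted <- t(apply(X, 1, sort, decreasing = TRUE))
  det <- X >= cfg$detect_min
  not_det <- rowSums(det) == 0
  enriched <- sorted[, 1] >= cfg$detect_min &
    sorted[, 1] >= cfg$fold_elevated * sorted[, 2]
  group_any <- rep(FALSE, nrow(X))
  kmax <- min(cfg$group_size_max, n - 1)
  if (kmax >= cfg$group_size_min) {
    for (k in cfg$group_size_min:kmax) {
      for (S in utils::combn(n, k, simplify = FALSE)) {
        gm <- rowMeans(X[, S, drop = FALSE])
        cm <- rowMeans(X[, -S, drop = FALSE])
        ok <- rowSums(det[, S, drop = FALSE]) == k & gm >= cfg$fold_elevated * cm
        group_any <- group_any | ok
      }
    }
  }
  enhanced <- sorted[, 1] >= cfg$detect_min &
    sorted[, 1] >= cfg$fold_elevated * rowMeans(sorted[, -1, drop = FALSE])
  in_all <- rowSums(det) == n
  out <- rep("mixed", nrow(X))
  out[in_all] <- "expressed_in_all"
  out[enhanced] <- "tissue_enhanced"
  out[group_any] <- "group_enriched"
  out[enriched] <- "tissue_enriched"
  out[not_det] <- "not_detected"
  out
}

# random profile with zeros, low and high values; exercises every category
random_profile_matrix <- function(n_genes, n_tissues) {
  vals <- ifelse(stats::runif(n_genes * n_tissues) < 0.15, 0,
                 10^stats::runif(n_genes * n_tissues, -1, 2.3))
  matrix(vals, n_genes, n_tissues,
         dimnames = list(sprintf("g%d", seq_len(n_genes)),
                         sprintf("t%02d", seq_len(n_tissues))))
}

# Spearman rho by explicit rank transform + covariance formula
oracle_spearman <- function(x, y) {
  xr <- rank(x); yr <- rank(y)
  sum((xr - mean(xr)) * (yr - mean(yr))) /
    sqrt(sum((xr - mean(xr))^2) * sum((yr - mean(yr))^2))
}

# naive triple-predicate transcript filter
oracle_filter_transcripts <- function(records, cfg = atlas_config()) {
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    keep[i] <- records$class_code[i] == "u" &&
      records$length[i] > cfg$novel_min_length &&
      records$exon_count[i] > cfg$novel_min_exons
  }
  records[keep, , drop = FALSE]
}

# naive annotation scan: per-database passing query sets
oracle_annotation_counts <- function(hits, cfg = atlas_config()) {
  dbs <- sort(unique(hits$database))
  sets <- lapply(dbs, function(db) {
    q <- character(0)
    for (i in seq_len(nrow(hits))) {
      if (hits$database[i] == db &&
          hits$bitscore[i] > cfg$annot_min_bitscore &&
          hits$pident[i] > cfg$annot_min_pident &&
          hits$evalue[i] < cfg$annot_max_evalue)
        q <- union(q, hits$query_id[i])
    }
    sort(q)
  })
  names(sets) <- dbs
  sets
}

# all merges of up to m+1 adjacent zero-missed-cleavage fragments
oracle_missed_cleavage_peptides <- function(frags, m) {
  out <- character(0)
  for (i in seq_along(frags)) {
    for (j in i:min(i + m, length(frags))) {
      out <- c(out, paste(frags[i:j], collapse = ""))
    }
  }
  out
}

random_aa_sequence <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}
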