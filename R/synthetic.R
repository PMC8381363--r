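#' Simulation specification for a synthetic expression atlas
#'
#' Defines the study conditions the generator emulates: a tissues x genes
#' FPKM atlas with planted specificity categories, planted fold changes and
#' multiplicative log-normal replicate noise. The seed fully determines the
#' output.
#'
#' @param n_genes,n_tissues,replicates_per_tissue Atlas dimensions
#'   (defaults 1000 genes, 16 tissues, 3 replicates, the sampling depth of
#'   a multi-donor tissue panel).
#' @param category_proportions Named 6-vector of planted category shares
#'   summing to 1; the default mirrors the category mix of a mammalian
#'   tissue atlas (42\% expressed in all, 16\% tissue enriched, 10\% group
#'   enriched, 21\% tissue enhanced, 3\% not detected, 8\% mixed).
#' @param fold_range_elevated Interval the planted fold changes of tissue-
#'   and group-enriched genes are drawn from; the lower bound must be at
#'   least the classifier's fold threshold. Tissue-enhanced genes use the
#'   largest feasible fold for the tissue count instead (see
#'   \code{\link{generate_atlas}}).
#' @param baseline_fpkm_range Interval background FPKM values are drawn
#'   from.
#' @param replicate_noise_sigma Log-normal sigma of multiplicative
#'   replicate noise (0 = noiseless).
#' @param margin Factor by which planted inequalities exceed their
#'   thresholds, so noise rarely flips categories (default 1.5).
#' @param seed Integer RNG seed.
#' @return An object of class \code{atlas_sim_spec}.
#' @export
atlas_sim_spec <- function(n_genes = 1000L,
                           n_tissues = 16L,
                           replicates_per_tissue = 3L,
                           category_proportions = c(not_detected = 0.03,
                                                    tissue_enriched = 0.16,
                                                    group_enriched = 0.10,
                                                    tissue_enhanced = 0.21,
                                                    expressed_in_all = 0.42,
                                                    mixed = 0.08),
                           fold_range_elevated = c(10, 50),
                           baseline_fpkm_range = c(0.5, 10),
                           replicate_noise_sigma = 0.2,
                           margin = 1.5,
                           seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               n_tissues = as.integer(n_tissues),
               replicates_per_tissue = as.integer(replicates_per_tissue),
               category_proportions = category_proportions,
               fold_range_elevated = as.numeric(fold_range_elevated),
               baseline_fpkm_range = as.numeric(baseline_fpkm_range),
               replicate_noise_sigma = as.numeric(replicate_noise_sigma),
               margin = as.numeric(margin),
               seed = as.integer(seed))
  cats <- specificity_categories()
  if (!setequal(names(spec$category_proportions), cats))
    stop("category_proportions must be named with the six categories")
  spec$category_proportions <- spec$category_proportions[cats]
  if (abs(sum(spec$category_proportions) - 1) > 1e-9)
    stop("category_proportions must sum to 1")
  if (any(spec$category_proportions < 0)) stop("proportions must be >= 0")
  if (spec$n_genes < 1 || spec$n_tissues < 2 || spec$replicates_per_tissue < 1)
    stop("atlas dimensions must be positive (>= 2 tissues)")
  if (spec$replicate_noise_sigma < 0) stop("replicate_noise_sigma must be >= 0")
  if (spec$margin < 1) stop("margin must be >= 1")
  if (diff(spec$fold_range_elevated) < 0 || diff(spec$baseline_fpkm_range) < 0)
    stop("ranges must be ordered (lo, hi)")
  class(spec) <- "atlas_sim_spec"
  spec
}

# --- per-category mean-profile planters (unplaced: position 1 is the top) ---

plant_not_detected <- function(n, cfg, margin) {
  list(means = stats::runif(n, 0, cfg$detect_min / margin),
       elevated = integer(0), fold = NA_real_)
}

plant_enriched <- function(n, cfg, spec) {
  lo <- spec$baseline_fpkm_range[1]; hi <- spec$baseline_fpkm_range[2]
  others <- stats::runif(n - 1, max(lo, cfg$detect_min), hi)
  f <- stats::runif(1, spec$fold_range_elevated[1], spec$fold_range_elevated[2])
  top <- f * max(others)
  list(means = c(top, others), elevated = 1L, fold = f)
}

plant_group <- function(n, cfg, spec) {
  kmax <- min(cfg$group_size_max, n - 2L)
  if (kmax < cfg$group_size_min)
    stop("group category infeasible with ", n, " tissues")
  k <- if (kmax == cfg$group_size_min) kmax else
    sample(cfg$group_size_min:kmax, 1)
  lo <- spec$baseline_fpkm_range[1]; hi <- spec$baseline_fpkm_range[2]
  comp <- stats::runif(n - k, lo, hi)
  f <- stats::runif(1, spec$fold_range_elevated[1], spec$fold_range_elevated[2])
  u <- stats::runif(k, 0.85, 1.15)
  grp <- f * mean(comp) * u / mean(u)
  list(means = c(grp, comp), elevated = seq_len(k), fold = f)
}

# Tissue-enhanced profiles live in a narrow wedge: the top tissue must be at
# least fold_elevated x the mean of the others, yet below fold_elevated x the
# second tissue, and no top-k prefix may satisfy the group criterion. A shape
# (M, q x j, floor x rest) is searched over j, q and M for the best-balanced
# profile: the one maximising the smallest slack among the defining enhanced
# inequality and the distances to the enriched and group boundaries, capped
# at the requested margin. At 16 tissues the feasible enhanced fold tops out
# near 8x, so fold_range_elevated does not apply to this category.
enhanced_shape <- function(n, cfg, margin) {
  r <- cfg$detect_min
  fe <- cfg$fold_elevated
  best <- NULL
  for (j in seq_len(min(3L, n - 2L))) {
    for (q in seq(1.05, 4, by = 0.05) * r) {
      abar <- (j * q + (n - 1 - j) * r) / (n - 1)
      m_lo <- 1.02 * fe * abar
      m_hi <- 0.98 * fe * q
      if (m_lo >= m_hi) next
      for (M in seq(m_lo, m_hi, length.out = 15)) {
        v <- c(M, rep(q, j), rep(r, n - 1 - j))
        res <- classify_vector(v, paste0("t", seq_len(n)), cfg)
        if (res$category != "tissue_enhanced") next
        vs <- sort(v[-1], decreasing = TRUE)
        s_def <- M / (fe * abar)              # defining-rule margin
        s_enr <- fe * vs[1] / M               # distance below the enriched rule
        cums <- cumsum(c(M, vs)); total <- cums[n]
        ks <- cfg$group_size_min:min(cfg$group_size_max, n - 1L)
        s_grp <- min(vapply(ks, function(k)   # distance below the group rule
          fe * ((total - cums[k]) / (n - k)) / (cums[k] / k), numeric(1)))
        cand <- list(M = M, q = q, j = j, fold = M / abar,
                     slack = min(s_def, s_enr, s_grp, margin))
        if (is.null(best) || cand$slack > best$slack) best <- cand
      }
    }
  }
  if (is.null(best))
    stop("tissue_enhanced category infeasible with ", n, " tissues")
  best
}

plant_enhanced <- function(n, cfg, shape) {
  scale <- stats::runif(1, 0.8, 3)
  means <- scale * c(shape$M, rep(shape$q, shape$j), rep(cfg$detect_min, n - 1 - shape$j))
  # keep the floor detected-agnostic jitter small so the shape's margins hold
  means[-1] <- means[-1] * stats::runif(n - 1, 0.97, 1.03)
  list(means = means, elevated = 1L, fold = shape$fold)
}

plant_expressed_all <- function(n, cfg) {
  scale <- stats::runif(1, 0.6, 2)
  list(means = scale * stats::runif(n, 3 * cfg$detect_min, 12 * cfg$detect_min),
       elevated = integer(0), fold = NA_real_)
}

# Mixed profiles decay geometrically across the detection floor: gradual
# decay keeps every top-k prefix below the group criterion while leaving at
# least one tissue detected and one not. The decay rate adapts upward until
# the classification rules all fail.
plant_mixed <- function(n, cfg, margin) {
  for (rho in seq(0.1^(1 / (n - 1)), 0.97, by = 0.02)) {
    hiA <- min(6, (cfg$detect_min / margin) / rho^(n - 1))
    if (hiA <= 1.5 * cfg$detect_min) next
    A <- stats::runif(1, 1.5 * cfg$detect_min, hiA)
    means <- A * rho^(0:(n - 1))
    res <- classify_vector(means, paste0("t", seq_len(n)), cfg)
    if (res$category == "mixed")
      return(list(means = means, elevated = integer(0), fold = NA_real_))
  }
  stop("mixed category infeasible with ", n, " tissues")
}

#' Generate a synthetic tissue atlas with planted ground truth
#'
#' Plants a per-tissue mean FPKM profile for every gene that satisfies its
#' assigned category's defining inequalities with margin, then draws
#' replicate samples as mean x lognormal(0, sigma). Every planted profile
#' is verified against the classification rules before acceptance, so a
#' noiseless atlas is recovered exactly by \code{\link{classify_all}}.
#'
#' @param spec An \code{\link{atlas_sim_spec}}.
#' @param config The \code{\link{atlas_config}} whose thresholds the
#'   planted profiles must satisfy.
#' @return A list with \code{matrix} (\code{expression_matrix}, FPKM,
#'   genes x samples), \code{metadata} (sample_id, tissue, donor_id),
#'   \code{profile} (\code{tissue_profile} of the true per-tissue means)
#'   and \code{truth} (data.frame gene_id, planted_category,
#'   planted_tissues (';'-joined), planted_fold).
#' @export
generate_atlas <- function(spec, config = atlas_config()) {
  if (!inherits(spec, "atlas_sim_spec")) stop("spec must be an atlas_sim_spec")
  if (spec$fold_range_elevated[1] < config$fold_elevated)
    stop("fold_range_elevated lower bound must be >= fold_elevated")
  n <- spec$n_genes; nt <- spec$n_tissues
  props <- spec$category_proportions
  if (props[["group_enriched"]] > 0 && nt < config$group_size_min + 2L)
    stop("group category requested with too few tissues")
  set.seed(spec$seed)
  # integer category allocation: floor + largest remainders
  raw <- props * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  categories <- sample(rep(names(cnt), cnt))
  tissues <- sprintf("tissue%02d", seq_len(nt))
  shape <- if (cnt[["tissue_enhanced"]] > 0) enhanced_shape(nt, config, spec$margin)
           else NULL
  # group-enriched genes share tissue sets drawn from a small per-size pool,
  # mimicking the recurrent tissue combinations of real atlases (and giving
  # the enrichment network sets with >= several member genes)
  kmax_grp <- min(config$group_size_max, nt - 2L)
  group_pool <- if (kmax_grp >= config$group_size_min) {
    lapply(stats::setNames(config$group_size_min:kmax_grp,
                           config$group_size_min:kmax_grp),
           function(k) list(sample(nt, k), sample(nt, k)))
  } else list()
  means <- matrix(0, n, nt, dimnames = list(sprintf("gene%04d", seq_len(n)), tissues))
  planted_tissues <- character(n)
  planted_fold <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cat_i <- categories[i]
    ok <- FALSE
    for (try in 1:100) {
      p <- switch(cat_i,
                  not_detected = plant_not_detected(nt, config, spec$margin),
                  tissue_enriched = plant_enriched(nt, config, spec),
                  group_enriched = plant_group(nt, config, spec),
                  tissue_enhanced = plant_enhanced(nt, config, shape),
                  expressed_in_all = plant_expressed_all(nt, config),
                  mixed = plant_mixed(nt, config, spec$margin))
      if (cat_i == "group_enriched") {
        S <- group_pool[[as.character(length(p$elevated))]][[sample(2, 1)]]
        pos <- c(S, sample(setdiff(seq_len(nt), S)))
      } else {
        pos <- sample.int(nt)  # random tissue placement
      }
      v <- numeric(nt); v[pos] <- p$means
      res <- classify_vector(v, tissues, config)
      if (res$category == cat_i) { ok <- TRUE; break }
    }
    if (!ok) stop("could not plant category '", cat_i, "' (gene ", i, ")")
    means[i, ] <- v
    planted_tissues[i] <- paste(sort(tissues[pos[p$elevated]]), collapse = ";")
    planted_fold[i] <- p$fold
  }
  nr <- spec$replicates_per_tissue
  sample_ids <- as.vector(t(outer(tissues, seq_len(nr), function(t, r)
    sprintf("%s_rep%d", t, r))))
  meta <- data.frame(sample_id = sample_ids,
                     tissue = rep(tissues, each = nr),
                     donor_id = sprintf("donor%d", rep(seq_len(nr), times = nt)),
                     stringsAsFactors = FALSE)
  noise <- matrix(stats::rlnorm(n * nt * nr, 0, spec$replicate_noise_sigma), n, nt * nr)
  values <- means[, rep(seq_len(nt), each = nr), drop = FALSE] * noise
  dimnames(values) <- list(rownames(means), sample_ids)
  truth <- data.frame(gene_id = rownames(means),
                      planted_category = categories,
                      planted_tissues = planted_tissues,
                      planted_fold = planted_fold,
                      stringsAsFactors = FALSE)
  list(matrix = expression_matrix(values, "FPKM"),
       metadata = meta,
       profile = tissue_profile(means),
       truth = truth)
}

#' Generate synthetic transcript records for the novelty filter
#'
#' Retained records satisfy all three retention rules (class code "u",
#' length > 200 nt, more than one exon); each non-retained record violates
#' exactly one rule, chosen uniformly, so every predicate is exercised.
#'
#' @param n Number of records.
#' @param retain_fraction Probability a record is planted as retained.
#' @param seed Integer RNG seed.
#' @param config An \code{\link{atlas_config}}.
#' @return A list with \code{records} (data.frame) and \code{truth}
#'   (logical vector: planted retained flag).
#' @export
generate_transcripts <- function(n, retain_fraction = 0.5, seed = 1L,
                                 config = atlas_config()) {
  if (retain_fraction < 0 || retain_fraction > 1)
    stop("retain_fraction must be in [0, 1]")
  set.seed(seed)
  retained <- stats::runif(n) < retain_fraction
  other_codes <- c("=", "c", "j", "e", "i", "o", "p", "s", "x")
  long_len <- function(k) sample(seq(ceiling(config$novel_min_length) + 50, 8000), k,
                                 replace = TRUE)
  short_len <- function(k) sample(seq(50, floor(config$novel_min_length)), k,
                                  replace = TRUE)
  code <- ifelse(retained, "u", NA)
  len <- ifelse(retained, long_len(n), NA)
  exons <- ifelse(retained, sample(2:20, n, replace = TRUE), NA)
  idx_bad <- which(!retained)
  violated <- sample(c("code", "length", "exons"), length(idx_bad), replace = TRUE)
  for (w in seq_along(idx_bad)) {
    i <- idx_bad[w]
    code[i] <- if (violated[w] == "code") sample(other_codes, 1) else "u"
    len[i] <- if (violated[w] == "length") short_len(1) else long_len(1)
    exons[i] <- if (violated[w] == "exons") 1L else sample(2:20, 1)
  }
  records <- data.frame(transcript_id = sprintf("TX%05d", seq_len(n)),
                        gene_id = sprintf("NG%05d", seq_len(n)),
                        class_code = code,
                        length = as.numeric(len),
                        exon_count = as.integer(exons),
                        stringsAsFactors = FALSE)
  list(records = records, truth = retained)
}

# residues that never create or suppress a tryptic cleavage inside a peptide
.body_alphabet <- setdiff(AA_ALPHABET, c("K", "R"))

random_peptide <- function(len, terminal_kr, first_not_p) {
  first_pool <- if (first_not_p) setdiff(.body_alphabet, "P") else .body_alphabet
  body_len <- len - as.integer(terminal_kr)
  chars <- c(sample(first_pool, 1),
             if (body_len > 1) sample(.body_alphabet, body_len - 1, replace = TRUE))
  if (terminal_kr) chars <- c(chars, sample(c("K", "R"), 1))
  paste(chars, collapse = "")
}

#' Generate a toy proteome with known tryptic structure
#'
#' Each protein is a concatenation of peptides of known lengths whose
#' internal residues never contain K/R and which never start with P after a
#' cleavage site, so the tryptic digest of the protein is exactly the
#' construction peptide list and the observable-peptide count is known by
#' bookkeeping. Intensities are drawn log-uniform. A paired alignment hit
#' table with planted pass/fail labels (against the overlap thresholds) is
#' also produced.
#'
#' @param n Number of proteins.
#' @param seed Integer RNG seed.
#' @param pass_fraction Fraction of proteins planted with a passing
#'   overlap hit (default 0.5).
#' @param species Species label used in the hit table (default "human").
#' @param config An \code{\link{atlas_config}}.
#' @return A list with \code{proteins} (accession, sequence, intensity),
#'   \code{peptide_counts} (accession, n_observable: the planted
#'   observable-peptide count), \code{peptides} (list of construction
#'   peptide vectors), \code{hits} (query_id, species, pident, evalue),
#'   \code{pass_truth} (logical, named by accession) and \code{totals}
#'   (named species total = n).
#' @export
generate_proteome <- function(n, seed = 1L, pass_fraction = 0.5,
                              species = "human", config = atlas_config()) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  lo <- config$ibaq_pep_len_min; hi <- config$ibaq_pep_len_max
  out_pool <- c(seq(2, lo - 1), seq(hi + 1, hi + 10))
  accession <- sprintf("PROT%04d", seq_len(n))
  peptides <- vector("list", n)
  n_obs <- integer(n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    k <- sample(3:12, 1)
    lens <- ifelse(stats::runif(k) < 0.7, sample(lo:hi, k, replace = TRUE),
                   sample(out_pool, k, replace = TRUE))
    peps <- vapply(seq_len(k), function(j)
      random_peptide(lens[j], terminal_kr = j < k, first_not_p = j > 1), character(1))
    peptides[[i]] <- peps
    n_obs[i] <- sum(lens >= lo & lens <= hi)
    seqs[i] <- paste(peps, collapse = "")
  }
  proteins <- data.frame(accession = accession, sequence = seqs,
                         intensity = 10^stats::runif(n, 5, 9),
                         stringsAsFactors = FALSE)
  pass <- stats::runif(n) < pass_fraction
  pident <- ifelse(pass, stats::runif(n, config$overlap_min_identity, 100),
                   stats::runif(n, 5, config$overlap_min_identity - 1))
  evalue <- ifelse(pass, 10^stats::runif(n, -30, log10(config$overlap_max_evalue)),
                   10^stats::runif(n, log10(config$overlap_max_evalue) + 1, -1))
  # fail rows violate one threshold each; alternate which one
  flip <- !pass & seq_len(n) %% 2 == 0
  pident[flip] <- stats::runif(sum(flip), config$overlap_min_identity, 100)
  evalue[!pass & !flip] <- 10^stats::runif(sum(!pass & !flip), -30,
                                           log10(config$overlap_max_evalue))
  hits <- data.frame(query_id = accession, species = species,
                     pident = pident, evalue = evalue, stringsAsFactors = FALSE)
  # duplicate some passing rows to exercise distinct-query semantics
  dup <- which(pass)[seq_len(min(3, sum(pass)))]
  if (length(dup)) hits <- rbind(hits, hits[dup, , drop = FALSE])
  rownames(hits) <- NULL
  list(proteins = proteins,
       peptide_counts = data.frame(accession = accession, n_observable = n_obs,
                                   stringsAsFactors = FALSE),
       peptides = peptides,
       hits = hits,
       pass_truth = stats::setNames(pass, accession),
       totals = stats::setNames(n, species))
}

#' Write a toy proteome to FASTA + intensity TSV
#'
#' Emits exactly the dialects \code{\link{read_protein_entries}} reads.
#'
#' @param proteome Result of \code{\link{generate_proteome}} (or any list
#'   with a \code{proteins} data.frame).
#' @param fasta_path,intensity_path Output paths.
#' @return \code{fasta_path}, invisibly.
#' @export
write_proteome <- function(proteome, fasta_path, intensity_path) {
  pr <- proteome$proteins
  ss <- Biostrings::AAStringSet(stats::setNames(pr$sequence, pr$accession))
  Biostrings::writeXStringSet(ss, fasta_path)
  write_tsv(data.frame(accession = pr$accession,
                       intensity = format(pr$intensity, digits = 15, trim = TRUE,
                                          scientific = FALSE)),
            intensity_path)
  invisible(fasta_path)
}
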