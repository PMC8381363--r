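cfg <- atlas_config()

test_that("worked classification examples land in the documented categories", {
  cases <- list(
    list(v = c(0, 0, 0, 0), cat = "not_detected"),
    list(v = c(100, 5, 5, 5), cat = "tissue_enriched", fold = 20, high = FALSE),
    list(v = c(300, 5, 5, 5), cat = "tissue_enriched", fold = 60, high = TRUE),
    list(v = c(50, 45, 1, 1, 1, 1), cat = "group_enriched",
         tissues = c("t1", "t2"), fold = 47.5),
    list(v = c(16, 4, 4, 2, 2, 2, 2, 2), cat = "tissue_enhanced",
         fold = 16 / mean(c(4, 4, 2, 2, 2, 2, 2))),
    list(v = c(2, 2, 2, 2), cat = "expressed_in_all"),
    list(v = c(2, 2, 2, 0.5, 0.5, 0.5, 0.5, 0.5), cat = "mixed")
  )
  for (cs in cases) {
    v <- stats::setNames(cs$v, paste0("t", seq_along(cs$v)))
    call <- classify_gene(v, cfg)
    expect_equal(call$category, cs$cat, info = paste(cs$v, collapse = ","))
    expect_equal(call$category, oracle_classify(cs$v, cfg))
    if (!is.null(cs$fold)) expect_equal(call$fold_change, cs$fold)
    if (!is.null(cs$high)) expect_equal(call$highly_enriched, cs$high)
    if (!is.null(cs$tissues)) expect_setequal(call$elevated_tissues, cs$tissues)
  }
})

test_that("boundary and degenerate inputs behave as specified", {
  # exactly fivefold qualifies (inclusive reading)
  expect_equal(classify_gene(c(a = 25, b = 5, c = 1), cfg)$category, "tissue_enriched")
  # second-highest zero gives an infinite fold
  call <- classify_gene(c(a = 7, b = 0, c = 0, d = 0), cfg)
  expect_equal(call$category, "tissue_enriched")
  expect_true(is.infinite(call$fold_change))
  expect_true(call$highly_enriched)
  expect_error(classify_gene(c(a = 5), cfg), "at least 2")
  expect_error(classify_gene(c(a = -1, b = 2), cfg), "non-negative")
})

test_that("classifier matches the exhaustive-subset oracle on random profiles", {
  set.seed(101)
  for (nt in c(4, 6, 10)) {
    X <- random_profile_matrix(120, nt)
    got <- as.character(classify_all(tissue_profile(X), cfg)$calls$category)
    want <- apply(X, 1, oracle_classify, cfg = cfg)
    expect_identical(got, unname(want), label = paste(nt, "tissues"))
  }
})

test_that("reported group is the smallest qualifying top-k prefix", {
  set.seed(202)
  X <- random_profile_matrix(400, 8)
  res <- classify_all(tissue_profile(X), cfg)$calls
  grp <- which(res$category == "group_enriched")
  for (i in grp) {
    members <- strsplit(res$elevated_tissues[i], ";", fixed = TRUE)[[1]]
    k <- length(members)
    v <- X[i, ]
    ord <- order(-v, colnames(X), method = "radix")
    # the reported set is the top-k by expression
    expect_setequal(members, colnames(X)[ord[seq_len(k)]])
    # no shorter prefix qualifies
    if (k > cfg$group_size_min) {
      for (k2 in cfg$group_size_min:(k - 1)) {
        S <- ord[seq_len(k2)]
        qualifies <- all(v[S] >= cfg$detect_min) &&
          mean(v[S]) >= cfg$fold_elevated * mean(v[-S])
        expect_false(qualifies)
      }
    }
  }
})

test_that("categories partition the gene set and summaries add up", {
  set.seed(7)
  X <- random_profile_matrix(500, 8)
  res <- classify_all(tissue_profile(X), cfg)
  expect_equal(sum(res$summary$counts), 500L)
  expect_false(anyNA(res$calls$category))
  # published count structure: per-category counts sum to the atlas total
  counts <- c(6778L, 2601L, 1627L, 3331L, 502L)
  expect_equal(sum(c(counts, 16013L - sum(counts))), 16013L)
})

test_that("classification is scale- and tissue-order-invariant", {
  set.seed(11)
  X <- random_profile_matrix(200, 6)
  base <- classify_all(tissue_profile(X), cfg)$calls
  for (c_scale in c(3, 17.5)) {  # upscaling keeps detected values detected
    scaled <- classify_all(tissue_profile(X * c_scale), cfg)$calls
    same_detect <- apply(X, 1, function(v) all((v >= 1) == (v * c_scale >= 1)))
    expect_identical(scaled$category[same_detect], base$category[same_detect])
  }
  perm <- sample(ncol(X))
  permuted <- classify_all(tissue_profile(X[, perm]), cfg)$calls
  expect_identical(permuted$category, base$category)
  expect_identical(permuted$elevated_tissues, base$elevated_tissues)  # sorted sets
})

test_that("global and per-tissue percentages follow half-away-from-zero rounding", {
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(3.5), 4)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(4.05, 1), 4.1)
  # the printed atlas shares from the published counts
  expect_equal(round_half_up(100 * 6778 / 16013), 42)
  expect_equal(round_half_up(100 * 2601 / 16013), 16)
  expect_equal(round_half_up(100 * 653 / 16013, 1), 4.1)
  expect_equal(round_half_up(100 * 1048 / 16013, 1), 6.5)
})

test_that("elevated transcript fraction tracks FPKM mass bookkeeping", {
  # three genes in 2 tissues: g1 enriched in A carries 60% of A's FPKM mass
  X <- matrix(c(60, 1,
                20, 30,
                20, 30), 3, 2, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("A", "B")))
  prof <- tissue_profile(X)
  calls <- classify_all(prof, cfg)$calls
  expect_equal(as.character(calls$category[1]), "tissue_enriched")
  expect_equal(elevated_transcript_fraction(prof, calls, "A"), 60)
  # no gene elevated in B -> 0%
  expect_equal(elevated_transcript_fraction(prof, calls, "B"), 0)
  zero <- tissue_profile(matrix(c(1, 1, 0, 0), 2, 2,
                                dimnames = list(c("g1", "g2"), c("A", "B"))))
  zcalls <- classify_all(zero, cfg)$calls
  expect_error(elevated_transcript_fraction(zero, zcalls, "B"), "undefined")
})

test_that("detected-gene counts are correct and monotone in the cut", {
  X <- matrix(c(0.5, 2, 20), 3, 1, dimnames = list(paste0("g", 1:3), "A"))
  prof <- tissue_profile(cbind(A = X[, 1], B = X[, 1]))
  counts <- detected_gene_counts(prof, c(1, 10, 100))
  expect_equal(unname(counts["A", ]), c(2L, 1L, 0L))
  expect_error(detected_gene_counts(prof, c(10, 1)), "increasing")
  set.seed(5)
  Y <- random_profile_matrix(200, 4)
  cm <- detected_gene_counts(tissue_profile(Y), atlas_config()$abundance_bins)
  expect_true(all(apply(cm, 1, function(r) all(diff(r) <= 0))))
})

test_that("Spearman similarity matches a rank-then-Pearson computation", {
  set.seed(13)
  vals <- matrix(rexp(40 * 5), 40, 5,
                 dimnames = list(sprintf("g%d", 1:40), sprintf("s%d", 1:5)))
  m <- expression_matrix(vals, "TPM")
  sim <- spearman_similarity(m)
  expect_equal(unname(diag(sim$correlation)), rep(1, 5))
  expect_equal(sim$correlation, t(sim$correlation))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(sim$correlation[i, j], oracle_spearman(vals[, i], vals[, j]),
                 tolerance = 1e-12)
  }
  expect_match(sim$newick, "^\\(")
  expect_setequal(ape::read.tree(text = sim$newick)$tip.label, colnames(vals))
})

test_that("duplicated, reversed and constant samples behave as documented", {
  set.seed(14)
  base <- sort(rexp(30)) + seq(0.01, 0.3, 0.01)  # strictly increasing ranks
  vals <- cbind(s1 = base, s2 = base, s3 = rev(base), s4 = rexp(30))
  rownames(vals) <- sprintf("g%d", 1:30)
  sim <- spearman_similarity(expression_matrix(vals, "TPM"))
  expect_equal(sim$correlation["s1", "s2"], 1)
  expect_equal(sim$correlation["s1", "s3"], -1)
  # identical samples merge first (at distance ~0)
  first_pair <- sim$tree$labels[-sim$tree$merge[1, ]]
  expect_setequal(first_pair, c("s1", "s2"))
  const <- cbind(vals[, 1:2], flat = rep(2, 30))
  expect_error(spearman_similarity(expression_matrix(const, "TPM")), "flat")
  expect_error(spearman_similarity(expression_matrix(vals, "FPKM")), "TPM")
})
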