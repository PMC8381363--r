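cfg <- atlas_config()

test_that("simulation specs validate their invariants", {
  expect_s3_class(atlas_sim_spec(), "atlas_sim_spec")
  props <- c(not_detected = 0.5, tissue_enriched = 0.6, group_enriched = 0,
             tissue_enhanced = 0, expressed_in_all = 0, mixed = 0)
  expect_error(atlas_sim_spec(category_proportions = props), "sum to 1")
  expect_error(atlas_sim_spec(margin = 0.5), "margin")
  expect_error(atlas_sim_spec(n_tissues = 1), "tissues")
  expect_error(generate_atlas(atlas_sim_spec(fold_range_elevated = c(2, 4))),
               "fold_range_elevated")
  # group category with too few tissues is an infeasible spec
  props2 <- c(not_detected = 0, tissue_enriched = 0, group_enriched = 1,
              tissue_enhanced = 0, expressed_in_all = 0, mixed = 0)
  expect_error(generate_atlas(atlas_sim_spec(n_tissues = 3,
                                             category_proportions = props2)),
               "too few tissues")
})

test_that("same seed gives identical atlases; different seeds differ", {
  spec <- atlas_sim_spec(n_genes = 60, n_tissues = 8, replicates_per_tissue = 2,
                         seed = 99)
  a <- generate_atlas(spec)
  b <- generate_atlas(spec)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth, b$truth)
  spec2 <- atlas_sim_spec(n_genes = 60, n_tissues = 8, replicates_per_tissue = 2,
                          seed = 100)
  expect_false(identical(generate_atlas(spec2)$matrix$values, a$matrix$values))
})

test_that("noiseless planted atlases are recovered exactly through the pipeline", {
  spec <- atlas_sim_spec(n_genes = 250, n_tissues = 12, replicates_per_tissue = 3,
                         replicate_noise_sigma = 0, seed = 3)
  sim <- generate_atlas(spec)
  prof <- aggregate_by_tissue(sim$matrix, sim$metadata)
  expect_equal(prof$values, sim$profile$values, tolerance = 1e-12)
  calls <- classify_all(prof, cfg)$calls
  expect_identical(as.character(calls$category), sim$truth$planted_category)
})

test_that("degenerate category proportions plant exactly that category", {
  props <- c(not_detected = 0, tissue_enriched = 1, group_enriched = 0,
             tissue_enhanced = 0, expressed_in_all = 0, mixed = 0)
  sim <- generate_atlas(atlas_sim_spec(n_genes = 40, n_tissues = 6,
                                       replicates_per_tissue = 1,
                                       category_proportions = props,
                                       replicate_noise_sigma = 0, seed = 8))
  expect_true(all(sim$truth$planted_category == "tissue_enriched"))
  calls <- classify_all(sim$profile, cfg)$calls
  expect_true(all(calls$category == "tissue_enriched"))
  expect_identical(calls$elevated_tissues, sim$truth$planted_tissues)
  # planted folds come from the requested range
  expect_true(all(sim$truth$planted_fold >= 10 & sim$truth$planted_fold <= 50))
})

test_that("planted elevated folds and tissue sets agree with the classifier", {
  spec <- atlas_sim_spec(n_genes = 200, n_tissues = 16, replicates_per_tissue = 1,
                         replicate_noise_sigma = 0, seed = 21)
  sim <- generate_atlas(spec)
  calls <- classify_all(sim$profile, cfg)$calls
  enr <- sim$truth$planted_category == "tissue_enriched"
  expect_identical(calls$elevated_tissues[enr], sim$truth$planted_tissues[enr])
  expect_equal(calls$fold_change[enr], sim$truth$planted_fold[enr],
               tolerance = 1e-9)
})

test_that("transcript generator plants single-rule violations", {
  gen <- generate_transcripts(1000, retain_fraction = 0.3, seed = 9)
  expect_equal(nrow(filter_novel_transcripts(gen$records)), sum(gen$truth))
  bad <- gen$records[!gen$truth, ]
  viol <- (bad$class_code != "u") + (bad$length <= 200) + (bad$exon_count <= 1)
  expect_true(all(viol == 1L))  # each non-retained record violates exactly one rule
  expect_identical(generate_transcripts(1000, 0.3, seed = 9)$records, gen$records)
  expect_equal(nrow(filter_novel_transcripts(
    generate_transcripts(100, 1, seed = 1)$records)), 100L)
  expect_equal(nrow(filter_novel_transcripts(
    generate_transcripts(100, 0, seed = 1)$records)), 0L)
})

test_that("proteome generator is deterministic and its digests are known by construction", {
  g1 <- generate_proteome(25, seed = 12)
  g2 <- generate_proteome(25, seed = 12)
  expect_identical(g1$proteins, g2$proteins)
  expect_identical(g1$hits, g2$hits)
  for (i in seq_len(25)) {
    expect_equal(tryptic_digest(g1$proteins$sequence[i]), g1$peptides[[i]])
  }
  lens <- lapply(g1$peptides, nchar)
  known <- vapply(lens, function(l) sum(l >= 6 & l <= 30), integer(1))
  expect_equal(g1$peptide_counts$n_observable, known)
})
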