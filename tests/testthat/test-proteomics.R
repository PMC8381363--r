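cfg <- atlas_config()

test_that("tryptic digestion applies the K/R rule with proline suppression", {
  expect_equal(tryptic_digest("AAAAKGGGGGGRCCCCCCC"),
               c("AAAAK", "GGGGGGR", "CCCCCCC"))
  expect_equal(tryptic_digest("AAKPGGR"), "AAKPGGR")  # KP does not cleave
  expect_equal(tryptic_digest("AAKPGGR", suppress_proline = FALSE),
               c("AAK", "PGGR"))
  expect_equal(tryptic_digest("ACDEFGH"), "ACDEFGH")   # no site
  expect_equal(tryptic_digest("AAKR"), c("AAK", "R"))  # terminal R, no empty peptide
  expect_error(tryptic_digest("ABZ"), "invalid residue")
})

test_that("digest conserves the sequence and missed cleavages merge adjacent fragments", {
  set.seed(61)
  for (i in 1:200) {
    s <- random_aa_sequence(sample(5:120, 1))
    frags <- tryptic_digest(s)
    expect_equal(paste(frags, collapse = ""), s)
    for (m in 1:2) {
      expect_equal(sort(tryptic_digest(s, missed_cleavages = m)),
                   sort(oracle_missed_cleavage_peptides(frags, m)))
    }
  }
})

test_that("iBAQ worked example and zero-intensity ranking", {
  e <- data.frame(accession = c("P1", "P2"),
                  sequence = c("AAAAKGGGGGGRCCCCCCC", "AAAAKGGGGGGRCCCCCCC"),
                  intensity = c(10, 0))
  res <- compute_ibaq(e, cfg)
  # AAAAK is length 5, below the 6-30 window -> 2 observable peptides
  expect_equal(res$ranked$n_observable_peptides, c(2L, 2L))
  expect_equal(res$ranked$ibaq, c(5, 0))
  expect_equal(res$ranked$rank, 1:2)
  expect_equal(res$ranked$accession[2], "P2")  # zero intensity ranks last
})

test_that("proteins with no observable peptide are excluded and reported", {
  e <- data.frame(accession = c("OK", "SHORT"),
                  sequence = c("AAAAAAKGGGGGGR", "AAK"),
                  intensity = c(4, 9))
  res <- compute_ibaq(e, cfg)
  expect_equal(res$ranked$accession, "OK")
  expect_equal(res$unquantified$accession, "SHORT")
  expect_equal(res$unquantified$n_observable_peptides, 0L)
})

test_that("iBAQ equals intensity / known peptide count exactly, scaling preserves ranks", {
  gen <- generate_proteome(50, seed = 63)
  res <- compute_ibaq(gen$proteins, cfg)$ranked
  known <- gen$peptide_counts$n_observable[match(res$accession,
                                                 gen$peptide_counts$accession)]
  intens <- gen$proteins$intensity[match(res$accession, gen$proteins$accession)]
  expect_equal(res$n_observable_peptides, known)
  expect_equal(res$ibaq, intens / known)
  scaled <- gen$proteins
  scaled$intensity <- scaled$intensity * 7
  res2 <- compute_ibaq(scaled, cfg)$ranked
  expect_equal(res2$accession, res$accession)
  expect_equal(res2$ibaq, res$ibaq * 7)
})

test_that("FASTA + intensity TSV round-trip into compute_ibaq input", {
  gen <- generate_proteome(10, seed = 64)
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_proteome(gen, fa, tsv)
  entries <- read_protein_entries(fa, tsv)
  expect_equal(entries$accession, gen$proteins$accession)
  expect_equal(entries$sequence, gen$proteins$sequence)
  expect_equal(entries$intensity, gen$proteins$intensity, tolerance = 1e-12)
})

test_that("overlap analysis reproduces the published milk-proteome arithmetic", {
  # 285 distinct passing donkey-milk queries of 401 self proteins -> 71%
  hits <- data.frame(query_id = sprintf("q%03d", 1:285),
                     species = "human",
                     pident = 45, evalue = 1e-10, stringsAsFactors = FALSE)
  res <- overlap_analysis(hits, c(human = 401), cfg)
  expect_equal(res$n_overlap, 285L)
  expect_equal(res$fraction, 71)
  # duplicate hit rows do not change distinct-query counts
  res_dup <- overlap_analysis(rbind(hits, hits), c(human = 401), cfg)
  expect_equal(res_dup$n_overlap, 285L)
  # boundary: thresholds are inclusive (evalue <= 1e-5, identity >= 30)
  edge <- data.frame(query_id = "q", species = "s", pident = 30, evalue = 1e-5)
  expect_equal(overlap_analysis(edge, c(s = 1), cfg)$n_overlap, 1L)
  miss <- data.frame(query_id = "q", species = "s", pident = 29.9, evalue = 1e-5)
  expect_equal(overlap_analysis(miss, c(s = 1), cfg)$n_overlap, 0L)
  expect_error(overlap_analysis(edge, c(other = 1), cfg), "absent from totals")
  empty <- overlap_analysis(hits[0, ], c(human = 401), cfg)
  expect_equal(empty$n_overlap, 0L)
  expect_equal(empty$fraction, 0)
})

test_that("overlap counts match planted pass labels on a synthetic table", {
  gen <- generate_proteome(80, seed = 65, pass_fraction = 0.5)
  res <- overlap_analysis(gen$hits, gen$totals, cfg)
  expect_equal(res$n_overlap, sum(gen$pass_truth))
  expect_equal(res$fraction, round_half_up(100 * sum(gen$pass_truth) / 80))
})
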