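test_that("normalization applies the printed formula and conserves 1e7", {
  m <- matrix(c(100L, 300L, 600L, 1L, 1L, 0L), ncol = 2L,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  norm <- normalize_counts(m)
  expect_equal(unname(norm[, "s1"]), c(1e6, 3e6, 6e6))
  expect_equal(unname(norm[, "s2"]), c(5e6, 5e6, 0))
  expect_equal(unname(colSums(norm)), c(1e7, 1e7))

  zero <- matrix(0L, 2L, 1L, dimnames = list(c("g1", "g2"), "empty"))
  expect_error(normalize_counts(zero), "empty")
})

test_that("fold enrichment obeys the zero-denominator rule", {
  expect_identical(fold_enrichment(50, 10), 5)
  expect_identical(fold_enrichment(7, 0), 7)    # denominator 0 -> 1
  expect_identical(fold_enrichment(0, 12), 0)   # numerator never reformatted
  expect_equal(fold_enrichment(c(50, 7, 0), c(10, 0, 12)), c(5, 7, 0))
  expect_error(fold_enrichment(1:3, 1:2), "length")
})

test_that("sgRNA calls use a strict threshold across the half-library's pools", {
  lib <- toy_library(1L)  # 6 guides: 3 in A, 3 in B
  fe <- matrix(1, nrow = 6L, ncol = 4L,
               dimnames = list(lib$guide_id, c("A-1", "A-2", "B-1", "B-2")))
  g <- lib$guide_id[lib$half_library == "A"]
  fe[g[1L], c("A-1", "A-2")] <- c(6.1, 5.5)   # both above -> hit
  fe[g[2L], c("A-1", "A-2")] <- c(6.1, 4.9)   # one below -> no hit
  fe[g[3L], c("A-1", "A-2")] <- c(5.0, 8.0)   # 5.0 is not "more than 5"

  hits <- call_enriched_sgrnas(fe, lib, threshold = 5)
  expect_true(hits[g[1L]])
  expect_false(hits[g[2L]])
  expect_false(hits[g[3L]])

  hits_any <- call_enriched_sgrnas(fe, lib, threshold = 5,
                                   replicate_mode = "any")
  expect_true(hits_any[g[2L]])
  expect_true(hits_any[g[3L]])   # 8.0 > 5 in one experiment

  expect_error(call_enriched_sgrnas(fe, lib, threshold = 0), "threshold")
})

test_that("gene calls apply the dual half-library criterion", {
  lib <- toy_library(3L)
  hits <- setNames(rep(FALSE, nrow(lib)), lib$guide_id)
  genes <- unique(lib$gene)

  gA <- lib$guide_id[lib$gene == genes[1L] & lib$half_library == "A"][1L]
  gB <- lib$guide_id[lib$gene == genes[1L] & lib$half_library == "B"][1L]
  hits[c(gA, gB)] <- TRUE                       # both halves -> candidate
  gA2 <- lib$guide_id[lib$gene == genes[2L] & lib$half_library == "A"]
  hits[gA2] <- TRUE                             # A only -> partial

  rep <- call_candidate_genes(hits, lib)
  expect_equal(rep$candidate_genes, genes[1L])
  expect_equal(rep$partial_genes, genes[2L])
  expect_length(intersect(rep$candidate_genes, rep$partial_genes), 0L)
  expect_setequal(rep$supporting_guides[[genes[1L]]], c(gA, gB))

  # min_per_half = 2 demotes the single-guide candidate
  rep2 <- call_candidate_genes(hits, lib, min_per_half = 2L)
  expect_length(rep2$candidate_genes, 0L)
  expect_error(call_candidate_genes(hits, lib, min_per_half = 0L),
               "min_per_half")
})

test_that("run_screen reproduces a hand-enumerated toy screen", {
  lib <- toy_library(4L, seed = 8L)
  ss <- toy_samples()
  genes <- unique(lib$gene)
  # flat baseline of 10 reads everywhere
  counts <- matrix(10L, nrow = nrow(lib), ncol = 8L,
                   dimnames = list(lib$guide_id, ss$sample_id))
  treated <- ss$sample_id[ss$condition == "treated"]
  # engineer gene 1 as a dual-library hit: one guide per half with raw
  # treated counts 200 vs untreated 10. Hand enumeration: each treated
  # column totals 21*10 + 3*200 = 810 reads, every untreated column
  # totals 240, so FE = (200/810)/(10/240) = 5.93 > 5 for the boosted
  # guides and (10/810)/(10/240) = 0.30 for everything else.
  hitA <- lib$guide_id[lib$gene == genes[1L] & lib$half_library == "A"][1L]
  hitB <- lib$guide_id[lib$gene == genes[1L] & lib$half_library == "B"][1L]
  counts[hitA, treated] <- 200L
  counts[hitB, treated] <- 200L
  # gene 2 enriched in half A only
  pA <- lib$guide_id[lib$gene == genes[2L] & lib$half_library == "A"][1L]
  counts[pA, treated] <- 200L

  col_total <- 10L * (nrow(lib) - 3L) + 3L * 200L
  fe_hit <- (200 / col_total) / (10 / (10 * nrow(lib)))
  expect_gt(fe_hit, 5)

  res <- run_screen(counts, ss, lib)
  expect_equal(res$fe[hitA, "A-1"], fe_hit)
  expect_equal(res$report$candidate_genes, genes[1L])
  expect_equal(res$report$partial_genes, genes[2L])
  expect_equal(res$report$parameters$threshold, 5)

  # monotone limit: an unreachable threshold empties the candidate list
  res_inf <- run_screen(counts, ss, lib, threshold = 1e9)
  expect_length(res_inf$report$candidate_genes, 0L)

  # treated == untreated -> FE identically 1, nothing called
  flat <- matrix(10L, nrow(lib), 8L,
                 dimnames = list(lib$guide_id, ss$sample_id))
  res_flat <- run_screen(flat, ss, lib)
  expect_true(all(res_flat$fe == 1))
  expect_length(res_flat$report$candidate_genes, 0L)
})

test_that("calls agree with the literal-rule oracle on random screens", {
  lib <- toy_library(8L, seed = 2L)
  ss <- toy_samples()
  set.seed(101)
  for (i in 1:50) {
    counts <- random_counts(lib, ss)
    res <- run_screen(counts, ss, lib)
    oracle <- oracle_screen_calls(counts, ss, lib)
    expect_equal(res$fe, oracle$fe)
    expect_equal(res$report$sgrna_hits, oracle$hits)
    expect_equal(res$report$candidate_genes, oracle$candidates)
    expect_equal(res$report$partial_genes, oracle$partial)
  }
})

test_that("scale invariance: rescaling a sample's raw counts changes nothing", {
  lib <- toy_library(5L, seed = 13L)
  ss <- toy_samples()
  set.seed(7)
  counts <- random_counts(lib, ss)
  res <- run_screen(counts, ss, lib)
  scaled <- counts
  scaled[, 3L] <- scaled[, 3L] * 17L
  res2 <- run_screen(scaled, ss, lib)
  expect_equal(res2$normalized[, 3L], res$normalized[, 3L])
  expect_equal(res2$fe, res$fe)
  expect_equal(res2$report$candidate_genes, res$report$candidate_genes)
})

test_that("FE and threshold monotonicity hold", {
  # FE non-decreasing in treated, strictly decreasing in untreated
  tr <- seq(0, 100, by = 10)
  fe_tr <- fold_enrichment(tr, rep(10, length(tr)))
  expect_true(all(diff(fe_tr) >= 0))
  un <- seq(1, 100, by = 5)
  fe_un <- fold_enrichment(rep(50, length(un)), un)
  expect_true(all(diff(fe_un) < 0))

  # candidate set shrinks (or stays) as the threshold rises
  lib <- toy_library(8L, seed = 4L)
  ss <- toy_samples()
  set.seed(31)
  counts <- random_counts(lib, ss, max_count = 100L)
  cands <- lapply(c(1, 2, 5, 10), function(t) {
    run_screen(counts, ss, lib, threshold = t)$report$candidate_genes
  })
  for (k in 2:length(cands)) {
    expect_true(all(cands[[k]] %in% cands[[k - 1L]]))
  }
})

test_that("heatmap export is long-format and value-identical", {
  lib <- toy_library(2L)
  ss <- toy_samples()
  set.seed(5)
  counts <- random_counts(lib, ss)
  res <- run_screen(counts, ss, lib)
  genes <- unique(lib$gene)

  out <- export_heatmap_matrix(res$fe, lib, genes[1L])
  expect_equal(nrow(out), 6L * 4L)
  expect_named(out, c("gene", "guide_id", "half_library", "experiment",
                      "fold_enrichment"))

  path <- withr::local_tempfile(fileext = ".tsv")
  export_heatmap_matrix(res$fe, lib, genes, path)
  back <- utils::read.delim(path)
  for (i in seq_len(nrow(back))) {
    expect_equal(back$fold_enrichment[i],
                 res$fe[back$guide_id[i], back$experiment[i]])
  }

  empty <- export_heatmap_matrix(res$fe, lib, character(0))
  expect_equal(nrow(empty), 0L)
  expect_error(export_heatmap_matrix(res$fe, lib, "NOSUCH"), "NOSUCH")
})
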