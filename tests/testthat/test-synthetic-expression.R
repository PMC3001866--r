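# Synthetic gene maps and paired expression tables with planted truth.

test_that("gene maps are seed-reproducible with the expected density", {
  u1 <- make_gene_map(1, 10e6, genes_per_mb = 10, seed = 1)
  u2 <- make_gene_map(1, 10e6, genes_per_mb = 10, seed = 1)
  expect_identical(u1, u2)
  n_genes <- length(unique(u1$annotations$gene_symbol))
  expect_gt(n_genes, 60)   # Poisson(100), allow wide slack
  expect_lt(n_genes, 140)
  u3 <- make_gene_map(1, 10e6, genes_per_mb = 10, seed = 2)
  expect_false(identical(u1$annotations, u3$annotations))
  expect_error(make_gene_map(0, 1e6, 10, seed = 1), "chromosome")
  expect_error(make_gene_map(1, 1e6, 0, seed = 1), "genes_per_mb")
  expect_error(make_gene_map(1, -5, 10, seed = 1), "positive")
})

test_that("generated maps satisfy universe invariants", {
  u <- make_gene_map(3, c(8e6, 5e6, 3e6), genes_per_mb = 15, seed = 9)
  a <- u$annotations
  expect_true(all(a$start < a$end))
  expect_true(all(a$end <= u$chrom_sizes[a$chromosome]))
  expect_false(any(duplicated(a$probeset_id)))
  counts <- table(a$chromosome)
  expect_equal(sum(counts), nrow(a))
})

test_that("expression tables are positive, paired, and noiseless-exact", {
  u <- make_gene_map(1, 6e6, genes_per_mb = 20, seed = 3)
  tr <- make_expression_truth(u, n_de = 20, noise_sd = 0,
                              normalization_corr = 1, seed = 5)
  ex <- make_expression(u, tr)
  expect_identical(ex$variant_a, ex$variant_b)
  expect_true(all(ex$variant_a$mutant > 0 & ex$variant_a$control > 0))
  fc <- fold_change(ex$variant_a$mutant, ex$variant_a$control)
  names_by_mag <- ex$variant_a$probeset_id[order(-abs(fc$log2fc))]
  expect_setequal(head(names_by_mag, 20), tr$planted_de_probesets)
  # planted magnitudes are the stated effect, everything else is null
  planted_idx <- ex$variant_a$probeset_id %in% tr$planted_de_probesets
  expect_equal(abs(fc$log2fc[planted_idx]),
               rep(tr$effect_log2fc, 20))
  expect_equal(fc$log2fc[!planted_idx],
               rep(0, sum(!planted_idx)))
})

test_that("fold-change noise across variants correlates at the stated level", {
  u <- make_gene_map(1, 40e6, genes_per_mb = 25, seed = 6)
  for (rho in c(0.3, 0.9)) {
    tr <- make_expression_truth(u, n_de = 0, noise_sd = 0.5,
                                normalization_corr = rho, seed = 8)
    ex <- make_expression(u, tr)
    fa <- fold_change(ex$variant_a$mutant, ex$variant_a$control)$log2fc
    fb <- fold_change(ex$variant_b$mutant, ex$variant_b$control)$log2fc
    expect_lt(abs(cor(fa, fb) - rho), 0.08)
  }
  expect_error(make_expression_truth(u, 5, normalization_corr = 0), "corr")
  expect_error(make_expression_truth(u, 5, effect_log2fc = -1), "positive")
})

test_that("with no planted effects the top-k intersection behaves as noise", {
  # for two independent rankings of N items the expected top-k overlap is
  # k^2/N; oracle by direct permutation simulation
  N <- 200L
  k <- 20L
  oracle_mean <- with_seed(12, {
    mean(replicate(400, {
      length(intersect(sample.int(N, k), sample.int(N, k)))
    }))
  })
  expect_lt(abs(oracle_mean - k^2 / N), 0.25)

  u <- make_gene_map(1, 10e6, genes_per_mb = 20, seed = 14)
  n <- nrow(u$annotations)
  sizes <- vapply(1:30, function(s) {
    tr <- make_expression_truth(u, n_de = 0, noise_sd = 0.5,
                                normalization_corr = 0.01, seed = s)
    ex <- make_expression(u, tr)
    fa <- setNames(fold_change(ex$variant_a$mutant, ex$variant_a$control)$log2fc,
                   ex$variant_a$probeset_id)
    fb <- setNames(fold_change(ex$variant_b$mutant, ex$variant_b$control)$log2fc,
                   ex$variant_b$probeset_id)
    k_loc <- 20L
    length(intersect_top_k(rank_products(list(fa), "over"),
                           rank_products(list(fb), "over"), k_loc))
  }, numeric(1))
  expect_lt(abs(mean(sizes) - 20^2 / n), 1.5)
})

test_that("planted cluster members are recovered by the downstream scan", {
  u <- make_gene_map(1, 10e6, genes_per_mb = 10, seed = 20)
  rg <- list(chromosome = "1", start = 4e6, end = 4.4e6)
  tr <- make_expression_truth(u, n_de = 10, noise_sd = 0,
                              normalization_corr = 1,
                              planted_clusters = list(rg), seed = 2)
  members <- tr$planted_clusters[[1]]$probesets
  expect_gte(length(members), 1L)
  de <- collapse_to_genes(names(tr$direction)[tr$direction > 0],
                          names(tr$direction)[tr$direction < 0], u)
  cl <- merge_windows(scan_windows(u, de, scan_config()))
  member_syms <- unique(u$annotations$gene_symbol[
    u$annotations$probeset_id %in% members])
  hit <- vapply(seq_len(nrow(cl)), function(i) {
    all(member_syms %in% strsplit(cl$de_genes[i], ",")[[1]])
  }, logical(1))
  expect_true(any(hit))
})

test_that("expression TSV round trips", {
  u <- make_gene_map(1, 2e6, genes_per_mb = 10, seed = 30)
  tr <- make_expression_truth(u, n_de = 3, seed = 1)
  ex <- make_expression(u, tr)
  path <- tempfile(fileext = ".tsv")
  write_expression(ex$variant_a, path)
  back <- read_expression(path)
  expect_equal(back$probeset_id, ex$variant_a$probeset_id)
  expect_equal(back$mutant, ex$variant_a$mutant, tolerance = 1e-8)
})
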