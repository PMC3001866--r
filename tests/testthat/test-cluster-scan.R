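# Sliding-window cluster detection, merging, permutation null, empirical P.

test_that("scan_config enforces its invariants", {
  cfg <- scan_config()
  expect_equal(cfg$window_bp, 5e5)
  expect_equal(cfg$slide_bp, 1e5)
  expect_equal(cfg$density_ratio_min, 0.75)
  expect_equal(cfg$min_de_genes, 2L)
  expect_error(scan_config(slide_bp = 6e5), "slide_bp")
  expect_error(scan_config(density_ratio_min = 0))
  expect_error(scan_config(min_de_genes = 1))
})

test_that("window qualification follows the density and pair rules", {
  u <- toy_universe()
  # window [0, 5e5) on chr1 holds anchors A, B, C (gene level: 3 genes)
  w <- scan_windows(u, c("A", "B"), scan_config())
  # 2 DE of 3 chip genes = 0.67 < 0.75 -> no window from that region
  expect_false(any(w$start == 0 & w$chromosome == "1"))

  w2 <- scan_windows(u, c("A", "B", "C"), scan_config())
  q0 <- w2[w2$chromosome == "1" & w2$start == 0, ]
  expect_equal(q0$n_de, 3L)
  expect_equal(q0$n_chip, 3L)

  # M and N on chr13 sit alone in [1.0, 1.2) Mb: ratio 1 with 2 DE genes
  w3 <- scan_windows(u, c("M", "N"), scan_config())
  expect_true(any(w3$chromosome == "13"))
  # a single DE gene never qualifies, even at ratio 1
  w4 <- scan_windows(u, "O", scan_config())
  expect_equal(nrow(w4), 0L)
})

test_that("overlapping windows merge into one cluster, across-chromosome never", {
  u <- toy_universe()
  w <- scan_windows(u, c("M", "N", "A", "B", "C"), scan_config())
  cl <- merge_windows(w)
  expect_equal(nrow(cl), 2L)  # one cluster per chromosome
  expect_setequal(cl$chromosome, c("1", "13"))
  cl13 <- cl[cl$chromosome == "13", ]
  expect_setequal(strsplit(cl13$de_genes, ",")[[1]], c("M", "N"))
  # windows offset by one slide sharing the DE pair merged into one region
  expect_true(all(cl$n_windows >= 1))
  expect_equal(nrow(merge_windows(w[0, ])), 0L)
})

test_that("planted synthetic clusters are recovered exactly, matching the oracle", {
  u <- make_gene_map(2, c(10e6, 10e6), genes_per_mb = 8, seed = 21)
  # plant whole grid-aligned windows (density ratio 1 inside each) so the
  # planted regions are genuine clusters by the window rule
  regions <- list(find_plantable_window(u, "1"),
                  find_plantable_window(u, "2"))
  n_members <- sum(vapply(regions, function(rg) {
    nrow(genes_in_interval(u, rg$chromosome, rg$start, rg$end))
  }, numeric(1)))
  tr <- make_expression_truth(u, n_de = n_members, noise_sd = 0,
                              normalization_corr = 1,
                              planted_clusters = regions, seed = 4)
  de <- collapse_to_genes(names(tr$direction)[tr$direction > 0],
                          names(tr$direction)[tr$direction < 0], u)
  cl <- merge_windows(scan_windows(u, de, scan_config()))
  expect_equal(nrow(cl), cluster_count_oracle(u, de$genes$gene_symbol))
  # every planted cluster recovered, and nothing else
  expect_equal(nrow(cl), length(regions))
  for (rg in regions) {
    member_syms <- unique(genes_in_interval(u, rg$chromosome, rg$start,
                                            rg$end)$gene_symbol)
    hit <- vapply(seq_len(nrow(cl)), function(i) {
      cl$chromosome[i] == rg$chromosome &&
        all(member_syms %in% strsplit(cl$de_genes[i], ",")[[1]])
    }, logical(1))
    expect_equal(sum(hit), 1L)
  }
})

test_that("scan_windows is monotone: adding a DE gene never removes a window", {
  u <- make_gene_map(1, 8e6, genes_per_mb = 12, seed = 31)
  syms <- unique(u$annotations$gene_symbol)
  base <- with_seed(8, sample(syms, 20))
  w1 <- scan_windows(u, base, scan_config())
  extra <- setdiff(syms, base)[1:5]
  w2 <- scan_windows(u, c(base, extra), scan_config())
  key <- function(w) paste(w$chromosome, w$start)
  expect_true(all(key(w1) %in% key(w2)))
})

test_that("null distribution is reproducible and degenerates correctly", {
  u <- toy_universe()
  n1 <- null_cluster_distribution(u, list_size = 4, n_sims = 30, seed = 5)
  n2 <- null_cluster_distribution(u, list_size = 4, n_sims = 30, seed = 5)
  expect_identical(n1$counts, n2$counts)
  expect_equal(n1$mean, mean(n1$counts))
  expect_equal(n1$min, min(n1$counts))
  expect_equal(n1$max, max(n1$counts))

  # drawing the whole universe is the same as calling every gene DE
  full <- null_cluster_distribution(u, list_size = nrow(u$annotations),
                                    n_sims = 5, seed = 1)
  all_cl <- merge_windows(scan_windows(u, unique(u$annotations$gene_symbol)))
  expect_true(all(full$counts == nrow(all_cl)))
  expect_error(null_cluster_distribution(u, list_size = 100, n_sims = 2),
               "exceeds")
})

test_that("fast null path agrees with scan+merge on individual draws", {
  u <- make_gene_map(1, 10e6, genes_per_mb = 15, seed = 13)
  nd <- null_cluster_distribution(u, list_size = 30, n_sims = 20,
                                  config = scan_config(), seed = 99)
  # re-derive each simulation's count through the public scan path
  recomputed <- with_seed(99, {
    n_ps <- nrow(u$annotations)
    draws <- replicate(20, sample.int(n_ps, 30))
    apply(draws, 2, function(ix) {
      syms <- unique(u$annotations$gene_symbol[ix])
      nrow(merge_windows(scan_windows(u, syms, scan_config())))
    })
  })
  expect_equal(nd$counts, as.integer(recomputed))
})

test_that("null mean matches exhaustive enumeration on a tiny universe", {
  # 8 genes on one 1.2 Mb chromosome; every C(8,3) = 56 subset enumerated
  ann <- data.frame(
    probeset_id = paste0("p", 1:8), gene_symbol = paste0("g", 1:8),
    chromosome = "1",
    start = c(5e4, 1.2e5, 2.1e5, 3.9e5, 5.5e5, 7.4e5, 9.2e5, 1.05e6),
    end = c(5e4, 1.2e5, 2.1e5, 3.9e5, 5.5e5, 7.4e5, 9.2e5, 1.05e6) + 2e4)
  u <- chip_universe(ann, chrom_sizes = c("1" = 1.2e6))
  subsets <- combn(8, 3)
  exact_counts <- apply(subsets, 2, function(ix) {
    cluster_count_oracle(u, paste0("g", ix))
  })
  exact_mean <- mean(exact_counts)
  expect_gt(exact_mean, 0)  # the configuration must be informative
  nd <- null_cluster_distribution(u, list_size = 3, n_sims = 4000, seed = 17)
  se <- sd(exact_counts) / sqrt(4000)
  expect_lt(abs(nd$mean - exact_mean), 4 * se + 1e-9)
})

test_that("empirical_p uses the plus-one convention and renders bounds", {
  mk_null <- function(counts) {
    structure(list(counts = counts, n_sims = length(counts),
                   list_size = 1L, mean = mean(counts), min = min(counts),
                   max = max(counts), seed = 0L),
              class = "null_cluster_distribution")
  }
  p0 <- empirical_p(10, mk_null(rep(0L, 1000)))
  expect_equal(p0$p, 1 / 1001)
  expect_equal(p0$label, "<0.001")

  pmax_ <- empirical_p(0, mk_null(0:9))
  expect_equal(pmax_$p, 1)

  # uniform counts 0..9, observed 5 -> 5 exceedances (5,6,7,8,9)
  p5 <- empirical_p(5, mk_null(0:9))
  expect_equal(p5$b, 5L)
  expect_equal(p5$p, 6 / 11)

  # decreasing in observed count, always in (0, 1]
  ps <- vapply(0:10, function(o) empirical_p(o, mk_null(0:9))$p, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("cluster count tolerates coordinate translation up to grid effects", {
  u <- make_gene_map(1, 10e6, genes_per_mb = 10, seed = 55)
  syms <- with_seed(3, sample(unique(u$annotations$gene_symbol), 15))
  base <- nrow(merge_windows(scan_windows(u, syms)))
  shift <- 3e5  # a multiple of the slide
  ann <- u$annotations
  ann$start <- ann$start + shift
  ann$end <- ann$end + shift
  u2 <- chip_universe(ann, chrom_sizes = c("1" = 10e6 + shift))
  shifted <- nrow(merge_windows(scan_windows(u2, syms)))
  expect_lte(abs(shifted - base), 1)
})
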