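# Synthetic gene maps and paired expression tables with planted ground
# truth, so that ranking, intersection, cluster detection and enrichment can
# all be validated without microarray data.
#
# Expression model: each probeset has a latent log2 intensity; multiplicative
# (log-normal) noise perturbs the mutant/control ratio. The two
# "normalization variant" tables share a latent fold-change component and
# carry independent variant-specific noise, so their per-probeset fold
# changes correlate at `normalization_corr` -- the minimal structure the
# dual-normalization intersection assumes.

#' Generate a synthetic annotated gene map
#'
#' Gene starts are uniform per chromosome, gene lengths log-normal (median
#' 20 kb), gene counts Poisson at `genes_per_mb` per Mb. A fraction of genes
#' receives a second probeset to exercise probeset-to-gene collapsing.
#' Reproducible: the same seed yields an identical universe.
#'
#' @param n_chromosomes number of chromosomes (1-24, labelled 1..22, X, Y).
#' @param chrom_lengths chromosome lengths in bp (recycled).
#' @param genes_per_mb mean gene density per Mb (> 0).
#' @param seed integer seed.
#' @param multi_probeset_frac fraction of genes carrying two probesets.
#' @return a [chip_universe()].
#' @export
make_gene_map <- function(n_chromosomes, chrom_lengths, genes_per_mb, seed,
                          multi_probeset_frac = 0.1) {
  if (n_chromosomes < 1) stop("need at least one chromosome")
  if (n_chromosomes > 24) stop("at most 24 chromosomes (1-22, X, Y)")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (genes_per_mb <= 0) stop("genes_per_mb must be positive")
  chroms <- .CHROMOSOMES[seq_len(n_chromosomes)]
  lens <- rep_len(as.numeric(chrom_lengths), n_chromosomes)

  with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_chromosomes)) {
      len <- lens[i]
      n <- rpois(1L, genes_per_mb * len / 1e6)
      if (n == 0L) next
      start <- sort(floor(runif(n, 0, max(1, len - 2000))))
      glen <- pmax(1000, round(rlnorm(n, meanlog = log(2e4), sdlog = 0.8)))
      end <- pmin(start + glen, len)
      sym <- sprintf("G%s_%04d", chroms[i], seq_len(n))
      rows[[length(rows) + 1L]] <- data.frame(
        probeset_id = sprintf("PS_%s_%04d_at", chroms[i], seq_len(n)),
        gene_symbol = sym, chromosome = chroms[i],
        start = start, end = end, stringsAsFactors = FALSE)
      extra <- which(runif(n) < multi_probeset_frac)
      if (length(extra)) {
        rows[[length(rows) + 1L]] <- data.frame(
          probeset_id = sprintf("PS_%s_%04d_x_at", chroms[i], extra),
          gene_symbol = sym[extra], chromosome = chroms[i],
          start = start[extra], end = end[extra], stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) stop("no genes generated; increase genes_per_mb or lengths")
    chip_universe(do.call(rbind, rows),
                  chrom_sizes = setNames(lens, chroms))
  })
}

#' Plant a misexpression truth over a universe
#'
#' Selects the planted differentially expressed probesets: first every
#' probeset anchored inside each planted cluster region (one direction per
#' cluster), then the remainder drawn without replacement, with sampling
#' weight `1 + excess` on chromosomes listed in `chrom_enrichment`.
#'
#' @param universe a [chip_universe()].
#' @param n_de total number of planted DE probesets.
#' @param effect_log2fc planted |log2 fold change| (> 0).
#' @param noise_sd SD of the log2 fold-change noise (0 = noiseless).
#' @param normalization_corr correlation of the two variants' fold-change
#'   noise, in (0, 1].
#' @param planted_clusters list of `list(chromosome, start, end)` regions
#'   whose probesets all become DE.
#' @param chrom_enrichment named vector chromosome -> excess sampling weight.
#' @param frac_over fraction of (non-cluster) planted probesets
#'   over-expressed.
#' @param seed integer seed.
#' @return object of class `expression_truth`.
#' @export
make_expression_truth <- function(universe, n_de, effect_log2fc = 2,
                                  noise_sd = 0.25, normalization_corr = 0.9,
                                  planted_clusters = NULL,
                                  chrom_enrichment = NULL,
                                  frac_over = 0.5, seed = 1L) {
  stopifnot(inherits(universe, "chip_universe"))
  if (effect_log2fc <= 0) stop("effect_log2fc must be positive")
  if (normalization_corr <= 0 || normalization_corr > 1) {
    stop("normalization_corr must be in (0, 1]")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  a <- universe$annotations

  with_seed(seed, {
    planted <- character()
    direction <- numeric()
    clusters <- list()
    for (cl in planted_clusters) {
      g <- genes_in_interval(universe, cl$chromosome, cl$start, cl$end)
      if (nrow(g) == 0L) {
        stop("planted cluster contains no probesets: ", cl$chromosome, ":",
             cl$start, "-", cl$end)
      }
      dir_cl <- sample(c(1, -1), 1L)
      planted <- c(planted, g$probeset_id)
      direction <- c(direction, rep(dir_cl, nrow(g)))
      clusters[[length(clusters) + 1L]] <-
        list(chromosome = normalize_chromosome(cl$chromosome),
             start = cl$start, end = cl$end,
             probesets = g$probeset_id, direction = dir_cl)
    }
    planted <- unique(planted)
    direction <- direction[!duplicated(planted)]
    if (length(planted) > n_de) stop("planted clusters exceed n_de")
    pool <- setdiff(a$probeset_id, planted)
    n_rest <- n_de - length(planted)
    if (n_rest > length(pool)) stop("n_de exceeds universe size")
    if (n_rest > 0L) {
      wt <- rep(1, length(pool))
      if (!is.null(chrom_enrichment)) {
        chrom <- a$chromosome[match(pool, a$probeset_id)]
        names(chrom_enrichment) <- normalize_chromosome(names(chrom_enrichment))
        hit <- chrom %in% names(chrom_enrichment)
        wt[hit] <- 1 + chrom_enrichment[chrom[hit]]
      }
      rest <- sample(pool, n_rest, prob = wt)
      planted <- c(planted, rest)
      direction <- c(direction,
                     ifelse(runif(n_rest) < frac_over, 1, -1))
    }
    structure(list(planted_de_probesets = planted,
                   direction = setNames(direction, planted),
                   planted_clusters = clusters,
                   chrom_enrichment = chrom_enrichment,
                   effect_log2fc = effect_log2fc, noise_sd = noise_sd,
                   normalization_corr = normalization_corr,
                   seed = as.integer(seed)),
              class = "expression_truth")
  })
}

#' Generate paired expression tables from a planted truth
#'
#' Emits two tables (variants "A" and "B", the two normalization variants)
#' with columns `probeset_id`, `mutant`, `control`. All values are positive;
#' planted probesets receive `+-effect_log2fc` on the log2 scale; the noise
#' components of the two variants' fold changes correlate at
#' `normalization_corr`. With `noise_sd = 0` the tables are identical and
#' the planted probesets occupy exactly the top |log2fc| ranks.
#'
#' @param universe a [chip_universe()].
#' @param truth an [make_expression_truth()] object valid for `universe`.
#' @return list with `variant_a`, `variant_b` (data.frames) and `truth`.
#' @export
make_expression <- function(universe, truth) {
  stopifnot(inherits(universe, "chip_universe"),
            inherits(truth, "expression_truth"))
  a <- universe$annotations
  missing <- setdiff(truth$planted_de_probesets, a$probeset_id)
  if (length(missing)) {
    stop("truth references probesets absent from universe: ",
         paste(head(missing, 5L), collapse = ", "))
  }
  n <- nrow(a)
  rho <- truth$normalization_corr
  with_seed(truth$seed + 1L, {
    mu <- rnorm(n, mean = 8, sd = 1.5)
    delta <- numeric(n)
    idx <- match(truth$planted_de_probesets, a$probeset_id)
    delta[idx] <- truth$direction[truth$planted_de_probesets] * truth$effect_log2fc
    z <- rnorm(n)
    ea <- rnorm(n)
    eb <- rnorm(n)
    fc_a <- delta + truth$noise_sd * (sqrt(rho) * z + sqrt(1 - rho) * ea)
    fc_b <- delta + truth$noise_sd * (sqrt(rho) * z + sqrt(1 - rho) * eb)
    tab <- function(fc) data.frame(probeset_id = a$probeset_id,
                                   mutant = 2^(mu + fc), control = 2^mu,
                                   stringsAsFactors = FALSE)
    list(variant_a = tab(fc_a), variant_b = tab(fc_b), truth = truth)
  })
}

#' Write an expression table as TSV
#'
#' @param table data.frame with `probeset_id`, `mutant`, `control`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(table, path) {
  stopifnot(all(c("probeset_id", "mutant", "control") %in% names(table)))
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression TSV
#'
#' @param path path to a TSV with columns `probeset_id`, `mutant`, `control`.
#' @return data.frame.
#' @export
read_expression <- function(path) {
  tb <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("probeset_id", "mutant", "control"), names(tb))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  tb$probeset_id <- as.character(tb$probeset_id)
  tb
}
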