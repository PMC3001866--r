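# Two-sample comparisons from raw data and from published summary
# statistics, binary contact-fraction tests, and report assembly.
#
# Published "mean +- x" values are interpreted as standard errors of the
# mean (SEM): under that reading they reproduce the published p-values,
# whereas the SD reading does not. The choice is documented, not claimed as
# the source's intent. Welch (unequal-variance) tests are the default, with
# a pooled-variance option, and all tests are two-sided.

#' Summary statistic triple
#'
#' @param mean group mean.
#' @param sem standard error of the mean (`>= 0`).
#' @param n group size (`>= 2`).
#' @return object of class `summary_stat`.
#' @export
summary_stat <- function(mean, sem, n) {
  stopifnot(is.finite(mean), is.finite(sem), sem >= 0, n >= 2)
  structure(list(mean = mean, sem = sem, n = as.integer(n)),
            class = "summary_stat")
}

#' Two-sample t-test from summary statistics
#'
#' `t = (mean_a - mean_b) / sqrt(sem_a^2 + sem_b^2)` with
#' Welch-Satterthwaite degrees of freedom (default) or pooled variance, and
#' a two-sided p-value. Degenerate zero-variance inputs: equal means give
#' `p = 1`, unequal means give `p = 0` with `degenerate = TRUE`.
#'
#' @param a,b [summary_stat()] objects.
#' @param var.equal use the pooled-variance (classic Student) form.
#' @return list with `t`, `df`, `p.value`, `mean_a`, `mean_b`, `degenerate`.
#' @export
welch_t_from_summary <- function(a, b, var.equal = FALSE) {
  stopifnot(inherits(a, "summary_stat"), inherits(b, "summary_stat"))
  if (a$sem == 0 && b$sem == 0) {
    eq <- isTRUE(all.equal(a$mean, b$mean))
    return(list(t = if (eq) 0 else Inf * sign(a$mean - b$mean),
                df = NA_real_, p.value = if (eq) 1 else 0,
                mean_a = a$mean, mean_b = b$mean, degenerate = TRUE))
  }
  va <- a$sem^2  # variance of the mean
  vb <- b$sem^2
  if (var.equal) {
    # back out sample variances, pool, recompute the SE of the difference
    s2a <- va * a$n
    s2b <- vb * b$n
    sp2 <- ((a$n - 1) * s2a + (b$n - 1) * s2b) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  } else {
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t <- (a$mean - b$mean) / se
  list(t = t, df = df, p.value = 2 * pt(-abs(t), df),
       mean_a = a$mean, mean_b = b$mean, degenerate = FALSE)
}

#' Two-sample test of lamina-contact fractions
#'
#' Per-group contact fraction plus a two-sample t-test applied directly to
#' the 0/1 contact scores (the study's analysis of its binary data).
#'
#' @param contacts_a,contacts_b vectors of 0/1 contact scores, length >= 2.
#' @param var.equal use the pooled-variance form.
#' @return list with `fraction_a`, `fraction_b`, `t`, `df`, `p.value`.
#' @export
contact_fraction_test <- function(contacts_a, contacts_b, var.equal = FALSE) {
  chk <- function(x, nm) {
    if (length(x) < 2L) stop(nm, " needs at least 2 observations")
    if (!all(x %in% c(0, 1))) stop(nm, " must contain only 0/1 scores")
    as.numeric(x)
  }
  a <- chk(contacts_a, "contacts_a")
  b <- chk(contacts_b, "contacts_b")
  if (var(a) == 0 && var(b) == 0) {
    eq <- mean(a) == mean(b)
    return(list(fraction_a = mean(a), fraction_b = mean(b),
                t = if (eq) 0 else Inf * sign(mean(a) - mean(b)),
                df = NA_real_, p.value = if (eq) 1 else 0))
  }
  tt <- t.test(a, b, var.equal = var.equal)
  list(fraction_a = mean(a), fraction_b = mean(b),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value)
}

#' Round a percentage for display
#'
#' Stored values stay full precision everywhere; rounding happens only in
#' the report layer, to the nearest integer or a fixed number of decimals.
#'
#' @param x numeric percent values.
#' @param digits decimal places (0 = nearest integer).
#' @return rounded numeric vector.
#' @export
render_percent <- function(x, digits = 0L) round(x, digits)

#' Assemble a result report bundle
#'
#' Collects upstream results into display-ready data.frames, applying
#' rounding rules at this layer only. Missing sections are skipped with a
#' warning. When `dir` is given each section is also written as a TSV.
#'
#' @param de a `de_gene_set` or NULL.
#' @param clusters a [merge_windows()] data.frame or NULL.
#' @param null a [null_cluster_distribution()] or NULL.
#' @param enrichment a [chromosome_fractions()] /
#'   [chi_square_uniformity()] result or NULL.
#' @param shared a [shared_genes()] result or NULL.
#' @param fish a data.frame of per-nucleus FISH measurements or NULL.
#' @param percent_digits decimals for percent columns.
#' @param dir optional output directory for TSV files.
#' @return named list of data.frames (the report bundle), invisibly when
#'   writing to `dir`.
#' @export
render_report <- function(de = NULL, clusters = NULL, null = NULL,
                          enrichment = NULL, shared = NULL, fish = NULL,
                          percent_digits = 0L, dir = NULL) {
  bundle <- list()
  if (is.null(de)) warning("report: no differential-expression section")
  else {
    g <- de$genes
    bundle$de_genes <- g
    bundle$de_counts <- data.frame(
      n_genes = de$counts$n_genes, n_over = de$counts$n_over,
      n_under = de$counts$n_under, n_discordant = de$counts$n_discordant,
      n_probesets = length(de$over_probesets) + length(de$under_probesets))
  }
  if (is.null(clusters)) warning("report: no cluster section")
  else bundle$clusters <- clusters
  if (!is.null(null)) {
    bundle$null_distribution <- data.frame(sim = seq_along(null$counts),
                                           n_clusters = null$counts)
  }
  if (is.null(enrichment)) warning("report: no enrichment section")
  else {
    per <- enrichment$per_chromosome
    per$percent <- render_percent(per$percent, percent_digits)
    per$percent_raw <- enrichment$per_chromosome$percent
    bundle$enrichment <- per
    bundle$enrichment_summary <- data.frame(
      genomewide_percent = render_percent(enrichment$genomewide_percent,
                                          percent_digits),
      genomewide_percent_raw = enrichment$genomewide_percent,
      chi2 = if (is.null(enrichment$chi2)) NA_real_ else enrichment$chi2,
      df = if (is.null(enrichment$df)) NA_integer_ else enrichment$df,
      p = if (is.null(enrichment$p)) NA_real_ else enrichment$p)
  }
  if (!is.null(shared)) {
    bundle$shared_genes <- shared$genes
    per <- shared$per_chromosome
    if (!is.null(per$percent_of_chip)) {
      per$percent_of_chip <- render_percent(per$percent_of_chip, 1L)
    }
    bundle$shared_by_chromosome <- per
  }
  if (!is.null(fish)) bundle$fish_measurements <- fish
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(bundle)) {
      write.table(bundle[[nm]], file.path(dir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    return(invisible(bundle))
  }
  bundle
}
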