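# Per-chromosome misexpression percentages, the chi-square test of uniform
# distribution across chromosomes, and the cross-tissue shared-gene analysis.
#
# Expected counts come from the chip universe composition, not from genome
# gene counts: the null hypothesis is that the genome-wide misexpressed
# fraction applies to each chromosome's chip genes. X and Y are ordinary
# categories when present on the chip (24 categories on a full human chip,
# hence df = 23).

#' Per-chromosome misexpression fractions
#'
#' @param universe a [chip_universe()].
#' @param de_set a `de_gene_set` from [collapse_to_genes()], or (in probeset
#'   mode) a character vector of probeset ids.
#' @param unit count `"gene"` symbols (default; what the study reports) or
#'   `"probeset"`s.
#' @return object of class `chrom_enrichment`: `per_chromosome` data.frame
#'   (`chromosome`, `n_chip`, `n_de`, `percent`, `expected`, `chi2_contrib`),
#'   `genomewide_percent`, `n_de_total`, `n_chip_total`. Chromosomes with no
#'   chip genes are excluded (with a message). Percents are raw floats;
#'   rounding belongs to the report layer.
#' @export
chromosome_fractions <- function(universe, de_set, unit = c("gene", "probeset")) {
  unit <- match.arg(unit)
  n_chip <- chrom_feature_counts(universe, unit)
  if (unit == "gene") {
    stopifnot(inherits(de_set, "de_gene_set"))
    de_chrom <- de_set$genes$chromosome
  } else {
    ps <- if (inherits(de_set, "de_gene_set")) {
      c(de_set$over_probesets, de_set$under_probesets)
    } else {
      as.character(de_set)
    }
    a <- universe$annotations
    idx <- match(ps, a$probeset_id)
    if (anyNA(idx)) stop("probeset(s) absent from universe")
    de_chrom <- a$chromosome[idx]
  }
  n_de <- table(factor(de_chrom, levels = names(n_chip)))
  n_de <- setNames(as.integer(n_de), names(n_chip))
  if (any(drop <- n_chip == 0)) {
    message("excluding chromosome(s) with no chip genes: ",
            paste(names(n_chip)[drop], collapse = ", "))
    n_chip <- n_chip[!drop]
    n_de <- n_de[!drop]
  }
  gw <- sum(n_de) / sum(n_chip)
  per <- data.frame(chromosome = names(n_chip),
                    n_chip = unname(n_chip), n_de = unname(n_de),
                    percent = 100 * unname(n_de) / unname(n_chip),
                    expected = unname(n_chip) * gw,
                    stringsAsFactors = FALSE)
  per$chi2_contrib <- (per$n_de - per$expected)^2 / per$expected
  structure(list(per_chromosome = per,
                 genomewide_percent = 100 * gw,
                 n_de_total = sum(n_de), n_chip_total = sum(n_chip),
                 unit = unit),
            class = "chrom_enrichment")
}

#' @export
print.chrom_enrichment <- function(x, ...) {
  cat(sprintf("chrom_enrichment: %d of %d %ss misexpressed (%.2f%%) on %d chromosomes\n",
              x$n_de_total, x$n_chip_total, x$unit,
              x$genomewide_percent, nrow(x$per_chromosome)))
  if (!is.null(x$chi2)) {
    cat(sprintf("  chi-square %.3g, df %d, p %.3g\n", x$chi2, x$df, x$p))
  }
  invisible(x)
}

#' Chi-square test of uniform misexpression across chromosomes
#'
#' Goodness of fit of the observed per-chromosome misexpressed counts to the
#' expectation that each chromosome carries the genome-wide misexpressed
#' fraction of its chip genes: `chi2 = sum (obs - exp)^2 / exp`,
#' `df = categories - 1`, upper-tail p. No continuity correction.
#'
#' @param result a [chromosome_fractions()] result.
#' @return the same object with `chi2`, `df`, `p` filled in.
#' @export
chi_square_uniformity <- function(result) {
  stopifnot(inherits(result, "chrom_enrichment"))
  per <- result$per_chromosome
  if (nrow(per) < 2L) stop("need at least 2 chromosome categories")
  if (any(per$expected <= 0)) stop("expected count must be positive in every category")
  result$chi2 <- sum((per$n_de - per$expected)^2 / per$expected)
  result$df <- nrow(per) - 1L
  result$p <- pchisq(result$chi2, result$df, lower.tail = FALSE)
  result
}

#' Genes misexpressed in two tissues
#'
#' Intersection by gene symbol with a per-chromosome breakdown, and (when
#' chip composition is supplied) the shared genes as a percentage of each
#' chromosome's chip genes.
#'
#' @param de_a,de_b `de_gene_set` objects, or data.frames with columns
#'   `gene_symbol` and `chromosome` (both collapsed over the same universe).
#' @param chip_counts optional named vector of chip genes per chromosome
#'   (e.g. from [chrom_feature_counts()]).
#' @return object of class `shared_genes`: `genes` data.frame, `n_shared`,
#'   `per_chromosome` data.frame (`chromosome`, `n_shared`, and when
#'   `chip_counts` is given `n_chip`, `percent_of_chip`).
#' @export
shared_genes <- function(de_a, de_b, chip_counts = NULL) {
  tab <- function(x) {
    if (inherits(x, "de_gene_set")) x$genes[, c("gene_symbol", "chromosome")]
    else x[, c("gene_symbol", "chromosome")]
  }
  a <- tab(de_a)
  b <- tab(de_b)
  shared <- sort(intersect(unique(a$gene_symbol), unique(b$gene_symbol)))
  genes <- a[match(shared, a$gene_symbol), , drop = FALSE]
  rownames(genes) <- NULL
  counts <- table(genes$chromosome)
  per <- data.frame(chromosome = names(counts),
                    n_shared = as.integer(counts), stringsAsFactors = FALSE)
  if (!is.null(chip_counts)) {
    names(chip_counts) <- normalize_chromosome(names(chip_counts))
    per$n_chip <- as.integer(chip_counts[per$chromosome])
    per$percent_of_chip <- 100 * per$n_shared / per$n_chip
  }
  structure(list(genes = genes, n_shared = length(shared),
                 per_chromosome = per),
            class = "shared_genes")
}

#' @export
print.shared_genes <- function(x, ...) {
  cat("shared_genes:", x$n_shared, "genes on",
      nrow(x$per_chromosome), "chromosome(s)\n")
  invisible(x)
}
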