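# Fold-change computation, rank-products ranking across comparisons, top-K
# dual-normalization intersection, and probeset -> gene collapsing.
#
# The chip was measured once per condition but normalized two ways; each
# normalization variant yields one fold-change list. Rank products reduce to
# plain fold-change ordering when only one comparison is supplied, which the
# implementation makes explicit rather than hiding.

#' Signed fold change between two positive expression values
#'
#' Ratio `r = mutant/control`; the signed form is `r` when `r >= 1` and
#' `-1/r` otherwise, so magnitudes are always >= 1 and the sign encodes
#' direction (`+` over-, `-` under-expressed in the mutant). `r = 1` maps to
#' `+1` with `log2fc = 0`.
#'
#' @param mutant,control positive numeric vectors (recycled).
#' @return data.frame with columns `fc_signed` and `log2fc`.
#' @export
fold_change <- function(mutant, control) {
  if (any(!is.finite(mutant)) || any(!is.finite(control)) ||
      any(mutant <= 0) || any(control <= 0)) {
    stop("expression values must be positive and finite")
  }
  r <- mutant / control
  data.frame(fc_signed = ifelse(r >= 1, r, -1 / r), log2fc = log2(r))
}

#' Rank products across fold-change comparisons
#'
#' Each comparison ranks every probeset (rank 1 = most extreme in the stated
#' direction: largest `log2fc` for `"over"`, smallest for `"under"`); the RP
#' score is the geometric mean of a probeset's ranks across comparisons.
#' Ties in ranking and in RP score are broken by probeset id, lexicographic,
#' for determinism.
#'
#' @param fc_lists list of named numeric vectors of `log2fc`, one per
#'   comparison; all must cover the same probeset universe.
#' @param direction `"over"` or `"under"`.
#' @return data.frame (`probeset_id`, `rp`), ascending by `rp`.
#' @export
rank_products <- function(fc_lists, direction = c("over", "under")) {
  direction <- match.arg(direction)
  if (!is.list(fc_lists) || length(fc_lists) < 1L) {
    stop("need at least one comparison")
  }
  ids <- sort(names(fc_lists[[1L]]))
  if (is.null(ids) || any(!nzchar(ids))) stop("fold-change vectors must be named")
  for (fc in fc_lists) {
    if (!identical(sort(names(fc)), ids)) {
      stop("comparisons cover different probeset universes")
    }
  }
  n <- length(ids)
  logranks <- matrix(0, n, length(fc_lists))
  for (j in seq_along(fc_lists)) {
    fc <- fc_lists[[j]][ids]
    key <- if (direction == "over") -fc else fc
    ord <- order(key, ids)
    rk <- integer(n)
    rk[ord] <- seq_len(n)
    logranks[, j] <- log(rk)
  }
  rp <- exp(rowMeans(logranks))
  out <- data.frame(probeset_id = ids, rp = rp)
  out <- out[order(out$rp, out$probeset_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersection of the top k entries of two rankings
#'
#' @param ranking_a,ranking_b rankings as returned by [rank_products()]
#'   (or plain character vectors, best first) over the same universe.
#' @param k list size, `1 <= k <=` universe size.
#' @return sorted character vector of probeset ids in both top-k lists.
#' @export
intersect_top_k <- function(ranking_a, ranking_b, k) {
  ids_a <- if (is.data.frame(ranking_a)) ranking_a$probeset_id else ranking_a
  ids_b <- if (is.data.frame(ranking_b)) ranking_b$probeset_id else ranking_b
  if (!setequal(ids_a, ids_b)) stop("rankings cover different universes")
  if (k < 1 || k > length(ids_a)) {
    stop("k must be between 1 and the universe size (", length(ids_a), ")")
  }
  sort(intersect(ids_a[seq_len(k)], ids_b[seq_len(k)]))
}

#' Collapse probeset-level calls to gene-level misexpression calls
#'
#' A gene is counted once; its direction is `over`/`under` when all member
#' probesets agree and `discordant` otherwise (e.g. one probeset up, another
#' down for the same gene).
#'
#' @param over,under character vectors of probeset ids (disjoint).
#' @param universe a [chip_universe()] containing every listed probeset.
#' @return object of class `de_gene_set`: the probeset sets, a gene table
#'   (`gene_symbol`, `direction`, `chromosome`, `n_probesets`) and counts
#'   (`n_genes`, `n_over`, `n_under`, `n_discordant`).
#' @export
collapse_to_genes <- function(over, under, universe) {
  stopifnot(inherits(universe, "chip_universe"))
  over <- unique(as.character(over))
  under <- unique(as.character(under))
  both <- intersect(over, under)
  if (length(both)) {
    stop("probeset(s) in both over and under sets: ",
         paste(both, collapse = ", "))
  }
  a <- universe$annotations
  all_ps <- c(over, under)
  missing <- setdiff(all_ps, a$probeset_id)
  if (length(missing)) {
    stop("probeset(s) absent from universe: ", paste(missing, collapse = ", "))
  }
  idx <- match(all_ps, a$probeset_id)
  tab <- data.frame(probeset_id = all_ps,
                    gene_symbol = a$gene_symbol[idx],
                    chromosome = a$chromosome[idx],
                    dir = rep(c("over", "under"),
                              c(length(over), length(under))),
                    stringsAsFactors = FALSE)
  by_gene <- split(tab, tab$gene_symbol)
  genes <- do.call(rbind, lapply(by_gene, function(g) {
    d <- unique(g$dir)
    data.frame(gene_symbol = g$gene_symbol[1L],
               direction = if (length(d) == 1L) d else "discordant",
               chromosome = g$chromosome[1L],
               n_probesets = nrow(g),
               stringsAsFactors = FALSE)
  }))
  genes <- genes[order(genes$gene_symbol), , drop = FALSE]
  rownames(genes) <- NULL
  counts <- list(n_genes = nrow(genes),
                 n_over = sum(genes$direction == "over"),
                 n_under = sum(genes$direction == "under"),
                 n_discordant = sum(genes$direction == "discordant"))
  structure(list(over_probesets = sort(over), under_probesets = sort(under),
                 genes = genes, counts = counts),
            class = "de_gene_set")
}

#' @export
print.de_gene_set <- function(x, ...) {
  cat("de_gene_set:", x$counts$n_genes, "genes (",
      x$counts$n_over, "over,", x$counts$n_under, "under,",
      x$counts$n_discordant, "discordant ) from",
      length(x$over_probesets) + length(x$under_probesets), "probesets\n")
  invisible(x)
}

#' Full differential-expression call from two paired expression tables
#'
#' Convenience wrapper chaining [fold_change()], [rank_products()],
#' [intersect_top_k()] (separately for over- and under-expression) and
#' [collapse_to_genes()]: the misexpression call is the intersection of the
#' two normalization variants' top-k lists in each direction.
#'
#' @param variant_a,variant_b data.frames with columns `probeset_id`,
#'   `mutant`, `control` (one per normalization variant).
#' @param k top-list size per direction (the study used 1000).
#' @param universe a [chip_universe()].
#' @return a [collapse_to_genes()] result.
#' @export
de_from_tables <- function(variant_a, variant_b, k, universe) {
  fc_of <- function(tb) {
    setNames(fold_change(tb$mutant, tb$control)$log2fc, tb$probeset_id)
  }
  fa <- fc_of(variant_a)
  fb <- fc_of(variant_b)
  over <- intersect_top_k(rank_products(list(fa), "over"),
                          rank_products(list(fb), "over"), k)
  under <- intersect_top_k(rank_products(list(fa), "under"),
                           rank_products(list(fb), "under"), k)
  # a probeset can fall in both top lists when k exceeds half the universe;
  # resolve by the larger |log2fc| average, ties dropped from both
  both <- intersect(over, under)
  if (length(both)) {
    mean_fc <- (fa[both] + fb[both]) / 2
    over <- setdiff(over, both[mean_fc <= 0])
    under <- setdiff(under, both[mean_fc >= 0])
  }
  collapse_to_genes(over, under, universe)
}
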