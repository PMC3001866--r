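# Shared fixtures and independent brute-force oracles. Oracles deliberately
# avoid the package's own code paths: plain loops and direct definitions.

# small hand-written universe: chr1 10 Mb with 6 genes / 7 probesets,
# chr13 5 Mb with 3 genes (internal 0-based half-open coordinates)
toy_universe <- function() {
  ann <- data.frame(
    probeset_id = c("p1", "p2", "p3", "p3b", "p4", "p5", "p6",
                    "q1", "q2", "q3"),
    gene_symbol = c("A", "B", "C", "C", "D", "E", "F",
                    "M", "N", "O"),
    chromosome = c(rep("1", 7), rep("13", 3)),
    start = c(100000, 250000, 400000, 410000, 1200000, 5000000, 9000000,
              1000000, 1150000, 4000000),
    end = c(120000, 260000, 450000, 455000, 1210000, 5050000, 9100000,
            1020000, 1160000, 4100000),
    stringsAsFactors = FALSE)
  chip_universe(ann, chrom_sizes = c("1" = 10e6, "13" = 5e6))
}

write_gene_map_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# brute-force per-slice EDM: O(n^2) nearest-background search
edm_oracle <- function(mask, spacing) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0, nr, nc)
  bg <- which(!mask, arr.ind = TRUE)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    if (nrow(bg) == 0L) { out[i, j] <- Inf; next }
    out[i, j] <- sqrt(min(((i - bg[, 1]) * spacing[1])^2 +
                          ((j - bg[, 2]) * spacing[2])^2))
  }
  out
}

# brute-force 3D min distance from territory voxels to nucleus background
min_dist_3d_oracle <- function(territory, nucleus, voxel) {
  tv <- which(territory, arr.ind = TRUE)
  bg <- which(!nucleus, arr.ind = TRUE)
  if (nrow(bg) == 0L) return(Inf)
  best <- Inf
  for (k in seq_len(nrow(tv))) {
    d <- sqrt(((tv[k, 1] - bg[, 1]) * voxel[2])^2 +
              ((tv[k, 2] - bg[, 2]) * voxel[1])^2 +
              ((tv[k, 3] - bg[, 3]) * voxel[3])^2)
    best <- min(best, d)
  }
  best
}

# brute-force hybrid median with reflect-101 borders, via stats::median
hybrid_median_oracle <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ref <- function(i, n) ifelse(i < 1, 2 - i, ifelse(i > n, 2 * n - i, i))
  out <- m
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    px <- function(di, dj) m[ref(i + di, nr), ref(j + dj, nc)]
    plus <- c(px(-1, 0), px(1, 0), px(0, -1), px(0, 1), px(0, 0))
    cross <- c(px(-1, -1), px(-1, 1), px(1, -1), px(1, 1), px(0, 0))
    out[i, j] <- median(c(median(plus), median(cross), m[i, j]))
  }
  out
}

# first grid-aligned window on `chromosome` holding 2-3 chip genes; planting
# all of them makes that window's DE density exactly 1, i.e. a true cluster
find_plantable_window <- function(universe, chromosome, window = 5e5,
                                  slide = 1e5, n_genes = 2:3) {
  len <- universe$chrom_sizes[[chromosome]]
  for (ws in seq(0, len - 1, by = slide)) {
    g <- genes_in_interval(universe, chromosome, ws, min(ws + window, len))
    if (length(unique(g$gene_symbol)) %in% n_genes) {
      return(list(chromosome = chromosome, start = ws,
                  end = min(ws + window, len)))
    }
  }
  stop("no plantable window on chromosome ", chromosome)
}

# independent window-scan oracle: direct loops over a fixed grid, returning
# the merged cluster count for a set of DE gene symbols
cluster_count_oracle <- function(universe, de_symbols, window = 5e5,
                                 slide = 1e5, ratio = 0.75, min_de = 2) {
  a <- universe$annotations
  first <- !duplicated(a$gene_symbol)
  anchors <- tapply(a$start, a$gene_symbol, min)
  genes <- data.frame(sym = a$gene_symbol[first], chrom = a$chromosome[first])
  genes$anchor <- as.numeric(anchors[genes$sym])
  total <- 0L
  for (ch in names(universe$chrom_sizes)) {
    len <- universe$chrom_sizes[[ch]]
    g <- genes[genes$chrom == ch, ]
    starts <- seq(0, len - 1, by = slide)
    qual <- logical(length(starts))
    ends <- pmin(starts + window, len)
    for (k in seq_along(starts)) {
      inw <- g$anchor >= starts[k] & g$anchor < ends[k]
      n_chip <- sum(inw)
      n_de <- sum(inw & g$sym %in% de_symbols)
      qual[k] <- n_chip > 0 && n_de / n_chip >= ratio && n_de >= min_de
    }
    idx <- which(qual)
    if (length(idx)) {
      total <- total + 1L +
        sum(starts[idx[-1]] > ends[idx[-length(idx)]])
    }
  }
  total
}
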