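# Probeset/gene annotation universe: the set of loci measured by the chip,
# one row per probeset, plus per-chromosome lengths. Coordinates are stored
# 0-based half-open; annotation TSVs on disk are 1-based inclusive (UCSC
# browser style) and converted on read/write.

.CHROMOSOMES <- c(as.character(1:22), "X", "Y")

#' Normalize chromosome labels
#'
#' Accepts `"chr13"`/`"13"` synonyms (and lower-case `x`/`y`), returns the
#' bare label used internally (`"1"`..`"22"`, `"X"`, `"Y"`).
#'
#' @param x character vector of chromosome labels.
#' @return character vector of bare labels.
#' @export
normalize_chromosome <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  x <- toupper(x)
  bad <- !(x %in% .CHROMOSOMES)
  if (any(bad)) {
    stop("unknown chromosome label(s): ",
         paste(unique(x[bad]), collapse = ", "))
  }
  x
}

#' Construct a chip universe
#'
#' Bundles a validated probeset annotation table with per-chromosome lengths.
#' Annotations use 0-based half-open coordinates.
#'
#' @param annotations data.frame with columns `probeset_id`, `gene_symbol`,
#'   `chromosome`, `start`, `end` and optionally `strand`.
#' @param chrom_sizes optional named numeric vector of chromosome lengths in
#'   bp; defaults to the maximal annotation end per chromosome.
#' @return an object of class `chip_universe`.
#' @export
chip_universe <- function(annotations, chrom_sizes = NULL) {
  req <- c("probeset_id", "gene_symbol", "chromosome", "start", "end")
  miss <- setdiff(req, names(annotations))
  if (length(miss)) stop("missing annotation column(s): ",
                         paste(miss, collapse = ", "))
  ann <- as.data.frame(annotations, stringsAsFactors = FALSE)
  ann$probeset_id <- as.character(ann$probeset_id)
  ann$gene_symbol <- as.character(ann$gene_symbol)
  ann$chromosome <- normalize_chromosome(ann$chromosome)
  ann$start <- as.numeric(ann$start)
  ann$end <- as.numeric(ann$end)
  if (!"strand" %in% names(ann)) ann$strand <- NA_character_

  if (any(!nzchar(ann$probeset_id))) stop("empty probeset_id")
  dup <- ann$probeset_id[duplicated(ann$probeset_id)]
  if (length(dup)) stop("duplicated probeset_id: ",
                        paste(unique(dup), collapse = ", "))
  bad <- !is.finite(ann$start) | !is.finite(ann$end) |
    ann$start < 0 | ann$start >= ann$end
  if (any(bad)) stop("invalid interval (need 0 <= start < end) for probeset ",
                     paste(ann$probeset_id[bad], collapse = ", "))

  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(ann$end, ann$chromosome, max)
    chrom_sizes <- setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  } else {
    names(chrom_sizes) <- normalize_chromosome(names(chrom_sizes))
    over <- ann$end > chrom_sizes[ann$chromosome]
    if (any(is.na(over))) stop("annotation on chromosome missing from chrom_sizes")
    if (any(over)) stop("annotation end beyond chromosome length for probeset ",
                        paste(ann$probeset_id[over], collapse = ", "))
  }
  ord <- order(match(ann$chromosome, .CHROMOSOMES), ann$start, ann$probeset_id)
  ann <- ann[ord, req0 <- c(req, "strand")]
  rownames(ann) <- NULL
  structure(list(annotations = ann, chrom_sizes = chrom_sizes),
            class = "chip_universe")
}

#' @export
print.chip_universe <- function(x, ...) {
  cat("chip_universe:", nrow(x$annotations), "probesets,",
      length(unique(x$annotations$gene_symbol)), "genes,",
      length(x$chrom_sizes), "chromosome(s)\n")
  invisible(x)
}

#' Read a gene annotation TSV into a chip universe
#'
#' The file must be tab-delimited with a header containing `probeset_id`,
#' `gene_symbol`, `chromosome`, `start`, `end` (`strand` optional).
#' Coordinates in the file are 1-based inclusive and are converted to the
#' internal 0-based half-open representation.
#'
#' @param path path to the TSV file.
#' @param chrom_sizes optional named vector of chromosome lengths (bp).
#' @return a [chip_universe()].
#' @export
read_gene_map <- function(path, chrom_sizes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("probeset_id", "gene_symbol", "chromosome", "start", "end")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stop("missing column(s) in ", path, ": ",
                         paste(miss, collapse = ", "))
  start <- suppressWarnings(as.numeric(raw$start))
  end <- suppressWarnings(as.numeric(raw$end))
  bad <- which(!is.finite(start) | !is.finite(end) | start < 1 | start >= end)
  if (length(bad)) {
    stop("malformed coordinates at line ", bad[1] + 1L,
         " (1-based inclusive, need 1 <= start < end): ",
         raw$probeset_id[bad[1]])
  }
  raw$start <- start - 1  # to 0-based half-open
  raw$end <- end
  chip_universe(raw, chrom_sizes = chrom_sizes)
}

#' Write a chip universe back to an annotation TSV
#'
#' Inverse of [read_gene_map()]: coordinates are emitted 1-based inclusive.
#'
#' @param universe a [chip_universe()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(universe, path) {
  stopifnot(inherits(universe, "chip_universe"))
  out <- universe$annotations
  out$start <- format(out$start + 1, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a chip universe as BED6
#'
#' 0-based half-open, name column = probeset_id, score 0.
#'
#' @inheritParams write_gene_map
#' @return `path`, invisibly.
#' @export
write_gene_map_bed <- function(universe, path) {
  stopifnot(inherits(universe, "chip_universe"))
  a <- universe$annotations
  bed <- data.frame(chrom = paste0("chr", a$chromosome),
                    start = format(a$start, scientific = FALSE, trim = TRUE),
                    end = format(a$end, scientific = FALSE, trim = TRUE),
                    name = a$probeset_id, score = 0,
                    strand = ifelse(is.na(a$strand), ".", a$strand))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Annotations anchored within a genomic interval
#'
#' Membership uses each annotation's anchor coordinate (its start, the lower
#' bp of the interval, regardless of strand) and the half-open convention:
#' anchors in `[start, end)` are returned, ordered by coordinate then
#' probeset id.
#'
#' @param universe a [chip_universe()].
#' @param chromosome chromosome label (`"13"` or `"chr13"`).
#' @param start,end interval bounds, 0-based half-open, `start < end`.
#' @return data.frame of matching annotations.
#' @export
genes_in_interval <- function(universe, chromosome, start, end) {
  stopifnot(inherits(universe, "chip_universe"), start < end)
  chromosome <- normalize_chromosome(chromosome)
  if (!chromosome %in% names(universe$chrom_sizes)) {
    stop("chromosome not in universe: ", chromosome)
  }
  a <- universe$annotations
  hit <- a$chromosome == chromosome & a$start >= start & a$start < end
  out <- a[hit, , drop = FALSE]
  out <- out[order(out$start, out$probeset_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genomic separation of two loci in Mb
#'
#' @param start_a,start_b locus start coordinates in bp (non-negative).
#' @return list with `mb` (float megabases) and `mb_int` (truncated toward
#'   zero, the form used when quoting separations like "21 Mb").
#' @export
locus_separation_mb <- function(start_a, start_b) {
  stopifnot(start_a >= 0, start_b >= 0)
  mb <- abs(start_b - start_a) / 1e6
  list(mb = mb, mb_int = trunc(mb))
}

#' Per-chromosome feature counts
#'
#' "Genes on the chip per chromosome" can be counted either as deduplicated
#' gene symbols or as probesets; both modes are exposed because reported
#' chip compositions rarely state which was meant.
#'
#' @param universe a [chip_universe()].
#' @param unit `"gene"` (deduplicated symbols, default) or `"probeset"`.
#' @return named integer vector, one entry per chromosome in the universe.
#' @export
chrom_feature_counts <- function(universe, unit = c("gene", "probeset")) {
  stopifnot(inherits(universe, "chip_universe"))
  unit <- match.arg(unit)
  a <- universe$annotations
  if (unit == "gene") a <- a[!duplicated(a$gene_symbol), , drop = FALSE]
  tab <- table(factor(a$chromosome,
                      levels = intersect(.CHROMOSOMES,
                                         names(universe$chrom_sizes))))
  setNames(as.integer(tab), names(tab))
}
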