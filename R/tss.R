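#' Read a TSS annotation table
#'
#' Reads a 5-column tab-separated gene annotation (`gene_id`, `chrom`,
#' `tss`, `strand`, `biotype`) with TSS positions in 0-based coordinates.
#'
#' @param path Path to the TSV file (with header).
#' @return Tibble with columns `gene_id`, `chrom`, `tss`, `strand`,
#'   `biotype`.
#' @export
read_tss_table <- function(path) {
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(), chrom = readr::col_character(),
      tss = readr::col_integer(), strand = readr::col_character(),
      biotype = readr::col_character()
    ),
    progress = FALSE
  )
  validate_tss(x)
  x
}

validate_tss <- function(tss, arg = "tss") {
  needed <- c("gene_id", "chrom", "tss", "strand", "biotype")
  missing_cols <- setdiff(needed, names(tss))
  if (length(missing_cols) > 0) {
    abort(sprintf("`%s` is missing column(s): %s.", arg, paste(missing_cols, collapse = ", ")))
  }
  if (nrow(tss) > 0 && !all(tss$strand %in% c("+", "-"))) {
    abort(sprintf("`%s$strand` must be '+' or '-'.", arg))
  }
  if (nrow(tss) > 0 && any(tss$tss < 0)) {
    abort(sprintf("`%s$tss` must be non-negative.", arg))
  }
  invisible(tss)
}

#' Read gene TSSs from a GTF annotation
#'
#' Imports the `gene` lines of a GTF file and derives the transcription
#' start site of each gene: the 5' end on the annotated strand, converted
#' from the GTF's 1-based inclusive coordinates to 0-based positions. The
#' gene biotype is taken from the `gene_biotype` attribute.
#'
#' @param path Path to a GTF file.
#' @return Tibble with columns `gene_id`, `chrom`, `tss`, `strand`,
#'   `biotype`.
#' @export
read_tss_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  }
  mc <- S4Vectors::mcols(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  tibble(
    gene_id = as.character(mc$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    tss = ifelse(strand == "-", GenomicRanges::end(gr) - 1L, GenomicRanges::start(gr) - 1L),
    strand = strand,
    biotype = if ("gene_biotype" %in% names(mc)) as.character(mc$gene_biotype) else NA_character_
  )
}

#' Write a gene annotation as GTF
#'
#' Writes each gene as a single-base `gene` feature at its TSS (converted to
#' 1-based GTF coordinates) with `gene_id` and `gene_biotype` attributes.
#'
#' @param tss TSS tibble (`gene_id`, `chrom`, `tss`, `strand`, `biotype`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss_gtf <- function(tss, path) {
  validate_tss(tss)
  gr <- GenomicRanges::GRanges(
    seqnames = tss$chrom,
    ranges = IRanges::IRanges(start = tss$tss + 1L, width = 1L),
    strand = tss$strand
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$source <- "adacomplex"
  S4Vectors::mcols(gr)$gene_id <- tss$gene_id
  S4Vectors::mcols(gr)$gene_biotype <- tss$biotype
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Map loci to their nearest TSS
#'
#' Assigns each locus the closest TSS on the same chromosome. The distance
#' is 0 when the TSS lies inside the locus, otherwise the distance from the
#' TSS to the nearer locus edge; ties are broken by the lexicographically
#' smallest `gene_id`. Loci whose nearest TSS is farther than `max_dist`
#' (or on a chromosome with no TSS) get `NA` assignments.
#'
#' @param loci Tibble of intervals (`chrom`, `start`, `end`); extra columns
#'   are carried through.
#' @param tss TSS tibble (see [read_tss_table()]); must be non-empty.
#' @param max_dist Maximum assignment distance in bp (default 1000).
#' @return `loci` with added columns `gene_id`, `distance`, `biotype` (NA
#'   when unassigned).
#' @export
nearest_tss <- function(loci, tss, max_dist = 1000) {
  validate_intervals(loci, "loci")
  validate_tss(tss)
  if (nrow(tss) == 0) {
    abort("`tss` annotation is empty.")
  }
  assert_scalar_number(max_dist, "max_dist", positive = TRUE)
  loci$.locus <- seq_len(nrow(loci))
  cand <- dplyr::inner_join(
    loci[, c(".locus", "chrom", "start", "end")],
    tss[, c("gene_id", "chrom", "tss", "biotype")],
    by = "chrom", relationship = "many-to-many"
  )
  cand$distance <- ifelse(
    cand$tss >= cand$start & cand$tss < cand$end,
    0L,
    pmin(abs(cand$tss - cand$start), abs(cand$tss - (cand$end - 1L)))
  )
  best <- cand |>
    dplyr::filter(distance <= max_dist) |>
    dplyr::arrange(.locus, distance, gene_id) |>
    dplyr::distinct(.locus, .keep_all = TRUE)
  out <- dplyr::left_join(
    loci,
    best[, c(".locus", "gene_id", "distance", "biotype")],
    by = ".locus"
  )
  out$.locus <- NULL
  out
}

#' Fraction of assigned genes with a given biotype
#'
#' Over the unique genes assigned to a set of loci (e.g. by
#' [nearest_tss()]), the fraction whose biotype matches `biotype`.
#'
#' @param assigned Tibble with `gene_id` and `biotype` columns; rows with
#'   `NA` gene ids (unassigned loci) are ignored.
#' @param biotype Biotype label to count (default `"tRNA"`).
#' @return A single fraction in `[0, 1]`.
#' @export
biotype_fraction <- function(assigned, biotype = "tRNA") {
  if (!all(c("gene_id", "biotype") %in% names(assigned))) {
    abort("`assigned` must have `gene_id` and `biotype` columns.")
  }
  genes <- dplyr::distinct(assigned[!is.na(assigned$gene_id), c("gene_id", "biotype")])
  if (nrow(genes) == 0) {
    abort("No assigned genes: biotype fraction is undefined.")
  }
  mean(genes$biotype == biotype)
}

#' TSS-centred intensity matrix
#'
#' Builds a genes-by-position matrix of RPM coverage around TSSs, averaged
#' across the replicate tracks of one factor. Columns run from `-flank` to
#' `flank - 1` relative to the TSS; rows for minus-strand genes are flipped
#' so that positive columns are always downstream of transcription. Windows
#' truncated at chromosome edges are zero-padded and flagged in the
#' `truncated` attribute.
#'
#' @param tss TSS tibble (rows of the matrix, in order).
#' @param tracks List of `coverage_track` replicates of one factor.
#' @param flank Half-window size in bp (default 500).
#' @return Numeric matrix (class `intensity_matrix`) with `gene_id`
#'   rownames, relative-position colnames, and attributes `flank` and
#'   `truncated`.
#' @export
tss_intensity_matrix <- function(tss, tracks, flank = 500) {
  validate_tss(tss)
  if (nrow(tss) == 0) {
    abort("`tss` must be non-empty.")
  }
  assert_scalar_number(flank, "flank", positive = TRUE)
  if (!is.list(tracks) || length(tracks) == 0) {
    abort("`tracks` must be a non-empty list of coverage tracks.")
  }
  n_pos <- 2L * as.integer(flank)
  mat <- matrix(0, nrow = nrow(tss), ncol = n_pos)
  truncated <- logical(nrow(tss))
  for (tr in tracks) {
    stopifnot(inherits(tr, "coverage_track"))
    for (i in seq_len(nrow(tss))) {
      minus <- tss$strand[i] == "-"
      ## window chosen so that after strand-flipping, column r always holds
      ## the base r bp downstream of transcription (column 0 = the TSS)
      lo <- tss$tss[i] - as.integer(flank) + if (minus) 1L else 0L
      hi <- lo + n_pos
      chrom_len <- if (tss$chrom[i] %in% names(tr$cov)) length(tr$cov[[tss$chrom[i]]]) else 0L
      if (lo < 0 || hi > chrom_len) truncated[i] <- TRUE
      v <- window_counts(tr, tss$chrom[i], lo, hi) * 1e6 / tr$total_reads
      if (minus) v <- rev(v)
      mat[i, ] <- mat[i, ] + v
    }
  }
  mat <- mat / length(tracks)
  rownames(mat) <- tss$gene_id
  colnames(mat) <- as.character(seq(-as.integer(flank), as.integer(flank) - 1L))
  structure(mat, flank = as.integer(flank), truncated = truncated,
            class = c("intensity_matrix", "matrix", "array"))
}
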