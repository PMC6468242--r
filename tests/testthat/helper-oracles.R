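## Brute-force oracles used across tests. These deliberately avoid the
## package's interval machinery: everything is computed on explicit
## per-base boolean/integer vectors over small toy chromosomes.

## boolean membership vector over positions 0..chrom_len-1 for intervals on
## one chromosome (BED half-open coordinates)
base_mask <- function(starts, ends, chrom_len) {
  mask <- logical(chrom_len)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) {
      mask[(starts[i] + 1):ends[i]] <- TRUE
    }
  }
  mask
}

## per-base count of distinct replicates covering each position
replicate_count_per_base <- function(peaks, chrom_len) {
  reps <- unique(peaks$replicate)
  counts <- integer(chrom_len)
  for (r in reps) {
    pk <- peaks[peaks$replicate == r, ]
    counts <- counts + as.integer(base_mask(pk$start, pk$end, chrom_len))
  }
  counts
}

## random interval set on one toy chromosome
random_intervals <- function(n, chrom_len, max_width = 60, chrom = "toy") {
  start <- sample.int(chrom_len - max_width, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  tibble::tibble(chrom = chrom, start = start, end = start + width)
}

## interval-overlap test by direct arithmetic (half-open)
overlaps_1bp <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

## recover per-base counts from a track via single-base RPM queries
window_counts_for_test <- function(track, from, to, chrom = "toy") {
  w <- tibble::tibble(chrom = chrom, start = from:(to - 1L), end = (from + 1L):to)
  rpm_in_window(w, track) * track$total_reads / 1e6
}

## build a coverage_track directly from an explicit per-base count vector
track_from_counts <- function(counts, total_reads, chrom = "toy",
                              chip_factor = NA_character_,
                              replicate_id = NA_character_) {
  coverage_track(
    tibble::tibble(
      chrom = chrom, start = seq_along(counts) - 1L,
      end = seq_along(counts), count = counts
    ),
    total_reads = total_reads, chip_factor = chip_factor,
    replicate_id = replicate_id
  )
}
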