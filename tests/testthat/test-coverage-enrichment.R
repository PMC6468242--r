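test_that("rpm_in_window matches the unit definition and a per-base sum oracle", {
  zero <- track_from_counts(rep(0, 500), total_reads = 1e6)
  w <- tibble::tibble(chrom = "toy", start = 100L, end = 300L)
  expect_equal(rpm_in_window(w, zero), 0)

  counts <- rep(0, 500)
  counts[151:155] <- 1 # 5 reads inside [100, 300)
  tr <- track_from_counts(counts, total_reads = 1e6)
  expect_equal(rpm_in_window(w, tr), 5.0)

  withr::local_seed(17)
  counts <- rpois(5000, 2)
  tr <- track_from_counts(counts, total_reads = 25000)
  starts <- sample.int(4800, 20) - 1L
  windows <- tibble::tibble(chrom = "toy", start = starts, end = starts + 200L)
  oracle <- vapply(
    seq_len(nrow(windows)),
    function(i) sum(counts[(windows$start[i] + 1):windows$end[i]]) * 1e6 / 25000,
    numeric(1)
  )
  expect_equal(rpm_in_window(windows, tr), oracle)

  expect_error(
    rpm_in_window(tibble::tibble(chrom = "nope", start = 0L, end = 10L), tr),
    "Chromosome"
  )
})

test_that("rpm_in_window is additive over a partition of an interval", {
  withr::local_seed(19)
  counts <- rpois(1000, 3)
  tr <- track_from_counts(counts, total_reads = 5000)
  whole <- tibble::tibble(chrom = "toy", start = 100L, end = 700L)
  cuts <- sort(c(100L, sample(101:699, 4), 700L))
  parts <- tibble::tibble(chrom = "toy", start = cuts[-length(cuts)], end = cuts[-1])
  expect_equal(sum(rpm_in_window(parts, tr)), rpm_in_window(whole, tr))
})

test_that("locus_log2_enrichment recovers planted fold changes", {
  withr::local_seed(29)
  counts <- rpois(2000, 4)
  tr <- track_from_counts(counts, total_reads = sum(counts))
  loci <- tibble::tibble(chrom = "toy", start = c(100L, 900L), end = c(300L, 1100L))
  # identical chip and input: exactly 0 regardless of pseudocount
  expect_equal(locus_log2_enrichment(loci, tr, tr), c(0, 0))

  # 4x RPM ratio with signal >> pseudocount: ~2
  chip <- track_from_counts(rep(40, 1000), total_reads = 1e6)
  input <- track_from_counts(rep(10, 1000), total_reads = 1e6)
  l <- tibble::tibble(chrom = "toy", start = 0L, end = 1000L)
  expect_equal(locus_log2_enrichment(l, chip, input), 2, tolerance = 1e-3)

  # planted 8-fold enrichment under Poisson noise, both samples sequenced
  # to a designed depth of 1e6 mapped reads: mean log2 across 100 loci
  # within 0.2 of 3
  chrom_len <- 60000L
  starts <- (0:99) * 600L + 100L
  loci <- tibble::tibble(chrom = "toy", start = starts, end = starts + 200L)
  lambda0 <- 1e6 / chrom_len
  lam <- rep(lambda0, chrom_len)
  for (i in seq_len(nrow(loci))) {
    lam[(loci$start[i] + 1):loci$end[i]] <- lambda0 * 8
  }
  chip <- track_from_counts(rpois(chrom_len, lam), total_reads = 1e6)
  input <- track_from_counts(rpois(chrom_len, lambda0), total_reads = 1e6)
  l2 <- locus_log2_enrichment(loci, chip, input)
  expect_lt(abs(mean(l2) - 3), 0.2)
})

test_that("average_replicates is the arithmetic mean", {
  expect_equal(average_replicates(1.0), 1.0)
  expect_equal(average_replicates(c(1, 3)), 2)
  expect_error(average_replicates(numeric()), "non-empty")
  withr::local_seed(37)
  x <- rnorm(1000)
  expect_equal(average_replicates(x), sum(x) / length(x))
})

test_that("zscores standardise to mean 0 and population sd 1", {
  expect_equal(zscores(c(-1, 1)), c(-1, 1))
  expect_error(zscores(c(0, 0, 0)), "[Dd]egenerate")
  expect_error(zscores(3), "at least 2")

  withr::local_seed(41)
  x <- rnorm(500, mean = 2, sd = 3)
  z <- zscores(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-12)
  # population (divide-by-N) convention, not sample sd
  expect_equal(z, (x - mean(x)) / (sd(x) * sqrt(499 / 500)))
})

test_that("nearest_tss assigns by edge distance with threshold and tie-breaking", {
  tss <- tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "toy", tss = c(150L, 5000L),
    strand = c("+", "-"), biotype = c("tRNA", "protein_coding")
  )
  inside <- nearest_tss(tibble::tibble(chrom = "toy", start = 100L, end = 200L), tss)
  expect_equal(inside$gene_id, "gA")
  expect_equal(inside$distance, 0L)

  # nearest TSS exactly 1 bp beyond the threshold -> unassigned
  far <- nearest_tss(tibble::tibble(chrom = "toy", start = 1151L, end = 1200L), tss[1, ])
  expect_true(is.na(far$gene_id))
  at <- nearest_tss(tibble::tibble(chrom = "toy", start = 1150L, end = 1200L), tss[1, ])
  expect_equal(at$gene_id, "gA")
  expect_equal(at$distance, 1000L)

  # equidistant genes: lexicographically smallest id wins
  ties <- tibble::tibble(
    gene_id = c("gZ", "gB"), chrom = "toy", tss = c(90L, 210L),
    strand = "+", biotype = "protein_coding"
  )
  got <- nearest_tss(tibble::tibble(chrom = "toy", start = 100L, end = 201L), ties)
  expect_equal(got$gene_id, "gB")
})

test_that("nearest_tss matches the all-pairs minimum-distance oracle", {
  withr::local_seed(43)
  loci <- random_intervals(30, 5000)
  tss <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:50), chrom = "toy",
    tss = sample.int(5000, 50) - 1L,
    strand = sample(c("+", "-"), 50, replace = TRUE),
    biotype = "protein_coding"
  )
  got <- nearest_tss(loci, tss, max_dist = 1000)
  for (i in seq_len(nrow(loci))) {
    d <- ifelse(
      tss$tss >= loci$start[i] & tss$tss < loci$end[i], 0L,
      pmin(abs(tss$tss - loci$start[i]), abs(tss$tss - (loci$end[i] - 1L)))
    )
    if (min(d) > 1000) {
      expect_true(is.na(got$gene_id[i]))
    } else {
      best <- tss$gene_id[d == min(d)]
      expect_equal(got$gene_id[i], sort(best)[1])
      expect_equal(got$distance[i], min(d))
    }
  }
})

test_that("biotype_fraction counts unique assigned genes", {
  all_trna <- tibble::tibble(gene_id = c("a", "b"), biotype = "tRNA")
  expect_equal(biotype_fraction(all_trna), 1.0)
  none <- tibble::tibble(gene_id = c("a", "b"), biotype = "protein_coding")
  expect_equal(biotype_fraction(none), 0.0)
  expect_error(biotype_fraction(none[0, ]), "undefined")

  # 24 loci assigned to 24 genes, 12 of them tRNA; duplicated assignments
  # must not change the unique-gene fraction
  assigned <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:24),
    biotype = rep(c("tRNA", "protein_coding"), each = 12)
  )
  expect_equal(biotype_fraction(assigned), 0.5)
  expect_equal(biotype_fraction(assigned[c(1:24, 1:6), ]), 0.5)
})

test_that("tss_intensity_matrix averages replicates and respects strand orientation", {
  flat <- track_from_counts(rep(2, 3000), total_reads = 1e6)
  tss <- tibble::tibble(
    gene_id = c("plus", "minus"), chrom = "toy", tss = c(1000L, 2000L),
    strand = c("+", "-"), biotype = "protein_coding"
  )
  m <- tss_intensity_matrix(tss, list(flat), flank = 100)
  expect_equal(dim(m), c(2, 200))
  expect_true(all(abs(m - 2) < 1e-12))

  # spike at TSS+10 on the + gene and TSS-10 on the - gene: both land in
  # the downstream +10 column
  counts <- rep(0, 3000)
  counts[1000 + 10 + 1] <- 7 # position 1010 (0-based), + gene TSS 1000
  counts[2000 - 10 + 1] <- 7 # position 1990 (0-based), - gene TSS 2000
  tr <- track_from_counts(counts, total_reads = 1e6)
  m <- tss_intensity_matrix(tss, list(tr), flank = 100)
  expect_equal(m["plus", "10"], 7)
  expect_equal(m["minus", "10"], 7)
  expect_equal(sum(m), 14)
  # column 0 is the TSS itself on both strands
  counts0 <- rep(0, 3000)
  counts0[1000 + 1] <- 3
  counts0[2000 + 1] <- 5
  m0 <- tss_intensity_matrix(tss, list(track_from_counts(counts0, 1e6)), flank = 100)
  expect_equal(m0["plus", "0"], 3)
  expect_equal(m0["minus", "0"], 5)

  # replicate averaging
  m2 <- tss_intensity_matrix(tss, list(flat, track_from_counts(rep(4, 3000), 1e6)), flank = 50)
  expect_true(all(abs(m2 - 3) < 1e-12))

  # windows running off the chromosome edge are zero-padded and flagged
  edge <- tibble::tibble(gene_id = "e", chrom = "toy", tss = 20L,
                         strand = "+", biotype = "protein_coding")
  me <- tss_intensity_matrix(edge, list(flat), flank = 100)
  expect_true(attr(me, "truncated"))
  expect_equal(unname(me[1, "-100"]), 0)
})

test_that("planted TSS-proximal enrichment produces a centred profile", {
  withr::local_seed(47)
  chrom_len <- 30000L
  tss_pos <- seq(2000L, 28000L, by = 2000L)
  strand <- rep(c("+", "-"), length.out = length(tss_pos))
  lam <- rep(2, chrom_len)
  for (p in tss_pos) lam[(p - 50):(p + 50)] <- 20
  tr <- track_from_counts(rpois(chrom_len, lam), total_reads = 1e6)
  tss <- tibble::tibble(
    gene_id = sprintf("g%02d", seq_along(tss_pos)), chrom = "toy",
    tss = tss_pos, strand = strand, biotype = "protein_coding"
  )
  m <- tss_intensity_matrix(tss, list(tr), flank = 500)
  prof <- colMeans(unclass(m))
  peak_pos <- as.integer(names(prof)[which.max(prof)])
  expect_lte(abs(peak_pos), 50)
})

test_that("enrichment_table averages replicates and z-scores within factor", {
  withr::local_seed(53)
  counts1 <- rpois(2000, 3)
  counts2 <- rpois(2000, 3)
  input_c <- rpois(2000, 3)
  t1 <- track_from_counts(counts1, sum(counts1), chip_factor = "X", replicate_id = "r1")
  t2 <- track_from_counts(counts2, sum(counts2), chip_factor = "X", replicate_id = "r2")
  input <- track_from_counts(input_c, sum(input_c), chip_factor = "input")
  ref <- tibble::tibble(chrom = "toy", start = c(0L, 500L, 1000L), end = c(200L, 700L, 1200L))
  et <- enrichment_table(ref, list(t1, t2), input)
  expect_equal(nrow(et), 3)
  manual <- (locus_log2_enrichment(ref, t1, input) +
               locus_log2_enrichment(ref, t2, input)) / 2
  expect_equal(et$mean_log2, manual)
  expect_equal(et$z, zscores(manual))
})

test_that("bedGraph round-trips through write and read", {
  withr::local_seed(59)
  counts <- rpois(500, 1)
  tr <- track_from_counts(counts, total_reads = 1000, chip_factor = "X",
                          replicate_id = "r1")
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, total_reads = 1000)
  w <- tibble::tibble(chrom = "toy", start = 0L, end = 500L)
  expect_equal(rpm_in_window(w, back), rpm_in_window(w, tr))
  expect_equal(
    window_counts_for_test(back, 0L, 500L),
    as.numeric(counts)
  )
})
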