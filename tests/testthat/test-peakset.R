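test_that("read_narrowpeak parses BED fields, dedupes and reports bad lines", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")

  writeLines(character(), f)
  expect_equal(nrow(read_narrowpeak(f)), 0)

  writeLines("chr2L\t100\t200\tp1\t50", f)
  x <- read_narrowpeak(f)
  expect_equal(x$chrom, "chr2L")
  expect_equal(x$start, 100L)
  expect_equal(x$end, 200L)
  expect_equal(x$name, "p1")
  expect_equal(x$score, 50)

  # duplicates within one file collapse to one record
  writeLines(c("chr2L\t100\t200", "chr2L\t100\t200", "chr2L\t300\t400"), f)
  expect_equal(nrow(read_narrowpeak(f)), 2)

  writeLines(c("chr2L\t100\t200", "chr2L\tabc\t300"), f)
  expect_error(read_narrowpeak(f), "line 2")
  writeLines(c("chr2L\t100\t200", "chr3R\t500\t400"), f)
  expect_error(read_narrowpeak(f), "line 2")
})

test_that("narrowPeak write/read round-trips intervals", {
  withr::local_seed(11)
  pk <- random_intervals(3, 1000, chrom = "chr2L")
  pk$name <- c("a", "b", "c")
  pk$score <- c(1, 2.5, 3)
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  write_narrowpeak(pk, f)
  back <- read_narrowpeak(f)
  pk_sorted <- pk[order(pk$start), ]
  expect_equal(back$start, pk_sorted$start)
  expect_equal(back$end, pk_sorted$end)
  expect_equal(back$name, pk_sorted$name)
  expect_equal(back$score, pk_sorted$score)
})

test_that("merge_intervals matches a per-base oracle and is idempotent and order-invariant", {
  expect_equal(
    merge_intervals(tibble::tibble(chrom = "c", start = c(10L, 30L), end = c(20L, 40L))),
    tibble::tibble(chrom = "c", start = c(10L, 30L), end = c(20L, 40L))
  )
  expect_equal(
    merge_intervals(tibble::tibble(chrom = "c", start = c(0L, 5L), end = c(10L, 15L))),
    tibble::tibble(chrom = "c", start = 0L, end = 15L)
  )
  # bookended intervals merge
  expect_equal(
    merge_intervals(tibble::tibble(chrom = "c", start = c(0L, 10L), end = c(10L, 20L))),
    tibble::tibble(chrom = "c", start = 0L, end = 20L)
  )

  withr::local_seed(7)
  for (rep in 1:5) {
    x <- random_intervals(50, 1000)
    merged <- merge_intervals(x)
    # base-set equality against the boolean-array oracle
    expect_equal(
      base_mask(merged$start, merged$end, 1000),
      base_mask(x$start, x$end, 1000)
    )
    # output is sorted and pairwise disjoint (no overlap, no bookending)
    expect_true(all(diff(merged$start) > 0))
    expect_true(all(merged$start[-1] > merged$end[-nrow(merged)]))
    # idempotent and order-invariant
    expect_equal(merge_intervals(merged), merged)
    expect_equal(merge_intervals(x[sample.int(nrow(x)), ]), merged)
  }
})

test_that("reproducible_peaks honours trivial cases and argument checks", {
  one <- tibble::tibble(chrom = "c", start = c(5L, 50L), end = c(15L, 60L), replicate = "r1")
  expect_equal(reproducible_peaks(one, 1), merge_intervals(one))

  disjoint <- tibble::tibble(
    chrom = "c", start = c(0L, 100L), end = c(10L, 110L),
    replicate = c("r1", "r2")
  )
  expect_equal(nrow(reproducible_peaks(disjoint, 2)), 0)
  expect_error(reproducible_peaks(disjoint, 3), "exceeds")
})

test_that("reproducible_peaks recovers jittered true regions and matches the support-count oracle", {
  withr::local_seed(23)
  chrom_len <- 10000L
  true_start <- seq(500L, 9000L, by = 1500L)[1:6]
  true_end <- true_start + 200L
  reps <- purrr::map_dfr(1:3, function(r) {
    keep <- if (r == 2) 1:4 else 1:6 # replicate 2 misses two peaks
    jitter <- sample(-20:20, length(keep), replace = TRUE)
    tibble::tibble(
      chrom = "toy",
      start = true_start[keep] + jitter,
      end = true_end[keep] + sample(-20:20, length(keep), replace = TRUE),
      replicate = paste0("r", r)
    )
  })
  got <- reproducible_peaks(reps, 2)
  expect_equal(nrow(got), 6)
  # every true region is covered by exactly one reproducible interval
  hits <- mapply(
    function(s, e) sum(overlaps_1bp(got$start, got$end, s, e)),
    true_start, true_end
  )
  expect_true(all(hits == 1))

  # per-base check: bases supported by >=2 replicates are inside the result,
  # bases supported by <2 replicates and not in any kept peak are outside
  support <- replicate_count_per_base(reps, chrom_len)
  mask <- base_mask(got$start, got$end, chrom_len)
  expect_true(all(mask[support >= 2]))
  # peaks kept are those overlapping a >=2-support base; nothing else enters
  peak_keep <- vapply(
    seq_len(nrow(reps)),
    function(i) any(support[(reps$start[i] + 1):reps$end[i]] >= 2),
    logical(1)
  )
  oracle_mask <- base_mask(reps$start[peak_keep], reps$end[peak_keep], chrom_len)
  expect_equal(mask, oracle_mask)
})

test_that("reproducible_peaks equals pooled merge at min_support 1 and shrinks as support grows", {
  withr::local_seed(31)
  reps <- purrr::map_dfr(1:4, function(r) {
    x <- random_intervals(12, 2000)
    x$replicate <- paste0("r", r)
    x
  })
  expect_equal(reproducible_peaks(reps, 1), merge_intervals(reps))
  masks <- lapply(1:4, function(k) {
    got <- reproducible_peaks(reps, k)
    base_mask(got$start, got$end, 2000)
  })
  for (k in 2:4) {
    expect_true(all(masks[[k]] <= masks[[k - 1]]))
  }
})

test_that("classify_locus partitions the 8 support vectors per the SAGA/ADA rule", {
  grid <- expand.grid(Ada2b = c(TRUE, FALSE), Spt3 = c(TRUE, FALSE), Sgf11 = c(TRUE, FALSE))
  cls <- classify_locus(grid)
  expect_equal(sum(cls == "canonical"), 1)
  expect_equal(sum(cls == "ada2b_only"), 1)
  expect_equal(sum(cls == "other"), 6)
  expect_equal(classify_locus(c(Ada2b = TRUE, Spt3 = FALSE, Sgf11 = FALSE)), "ada2b_only")
  expect_equal(classify_locus(c(Ada2b = TRUE, Spt3 = TRUE, Sgf11 = TRUE)), "canonical")
  expect_equal(classify_locus(c(Ada2b = TRUE, Spt3 = TRUE, Sgf11 = FALSE)), "other")
  expect_error(classify_locus(c(Ada2b = TRUE, Spt3 = FALSE)), "missing")
})

test_that("build_reference_set merges across factors and classifies support", {
  # single factor: loci supported by that factor only -> ada2b_only by the rule
  solo <- build_reference_set(list(
    Ada2b = tibble::tibble(chrom = "c", start = 0L, end = 10L)
  ))
  expect_true(solo$Ada2b)
  expect_false(solo$Spt3)
  expect_false(solo$Sgf11)
  expect_equal(solo$locus_class, "ada2b_only")

  # chained overlap across three factors collapses to one canonical locus
  ref <- build_reference_set(list(
    Ada2b = tibble::tibble(chrom = "c", start = 100L, end = 200L),
    Spt3 = tibble::tibble(chrom = "c", start = 150L, end = 250L),
    Sgf11 = tibble::tibble(chrom = "c", start = 180L, end = 300L)
  ))
  expect_equal(nrow(ref), 1)
  expect_equal(ref$start, 100L)
  expect_equal(ref$end, 300L)
  expect_true(all(ref$Ada2b, ref$Spt3, ref$Sgf11))
  expect_equal(ref$locus_class, "canonical")
})

test_that("build_reference_set recovers planted locus classes exactly", {
  withr::local_seed(5)
  n_can <- 40
  n_ada <- 10
  starts <- (seq_len(n_can + n_ada) - 1L) * 1000L + 100L
  classes <- sample(c(rep("canonical", n_can), rep("ada2b_only", n_ada)))
  truth <- tibble::tibble(chrom = "toy", start = starts, end = starts + 300L, class = classes)
  per_factor <- list(
    Ada2b = truth[, 1:3],
    Spt3 = truth[truth$class == "canonical", 1:3],
    Sgf11 = truth[truth$class == "canonical", 1:3]
  )
  ref <- build_reference_set(per_factor)
  expect_equal(nrow(ref), n_can + n_ada)
  expect_equal(ref$locus_class, truth$class[order(truth$start)])
})

test_that("overlap_fraction matches the all-pairs oracle", {
  a <- tibble::tibble(chrom = "c", start = c(0L, 100L), end = c(10L, 110L))
  expect_equal(overlap_fraction(a, a), 1.0)
  b <- tibble::tibble(chrom = "other", start = 0L, end = 1000L)
  expect_equal(overlap_fraction(a, b), 0.0)
  expect_error(overlap_fraction(a[0, ], b), "empty")

  withr::local_seed(13)
  for (rep in 1:3) {
    x <- random_intervals(20, 800)
    y <- random_intervals(20, 800)
    oracle <- mean(vapply(
      seq_len(nrow(x)),
      function(i) any(overlaps_1bp(x$start[i], x$end[i], y$start, y$end)),
      logical(1)
    ))
    expect_equal(overlap_fraction(x, y), oracle)
  }
})
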