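#' Configuration for the synthetic dataset generator
#'
#' Bundles every tunable of the synthetic-data module, with defaults that
#' describe a compact two-chromosome genome carrying well-separated planted
#' binding loci, three ChIP'd factors with replicate structure matching the
#' reproducibility thresholds (Ada2b 3 of 4, Spt3/Sgf11 2 of 3), Poisson
#' read coverage with planted fold enrichment, a MudPIT-style
#' spectral-count experiment with a mock control, and a gel-filtration
#' column plus density gradient with a planted complex. All generators are
#' deterministic given `seed`. Unknown argument names are rejected.
#'
#' @param seed Integer master seed; each sub-generator derives its own
#'   stream from it.
#' @param ... Named overrides of any default listed below.
#' @return A named list of class `synthetic_config`.
#' @section Defaults:
#' Genome/loci: `chrom_sizes` (2 x 150 kb), `n_canonical` 40,
#' `n_ada2b_only` 10, `n_unbound` 10, `peak_width_mean` 400 bp,
#' `peak_width_sd` 50, `min_gap` 2000 bp.
#' Peak replicates: `factors` (Ada2b/Spt3/Sgf11), `n_replicates`
#' (4/3/3), `min_support` (3/2/2), `replicate_dropout` 0.02 each,
#' `jitter` 50 bp.
#' Coverage: `coverage_depth` 6e5 reads/sample, `fold_canonical` 8 (all
#' factors), `fold_ada2b_only` 12 for Ada2b and 1 otherwise.
#' Annotation: `n_genes` 200, `trna_fraction` 0.3,
#' `ada2b_trna_fraction` 0.5.
#' Proteomics: `n_proteins` 44, `n_complex` 4, `spectra_per_run` 2000,
#' `complex_fold` 20, `n_shared_groups` 4, `shared_fraction` 0.3.
#' Column/gradient: paper-style marker radii (8.5/6.1/4.8/2.8/2.1 nm),
#' `v0` 7.4 ml, `vt` 24 ml, linear elution model `elution_intercept` 20,
#' `elution_slope` -1.2 ml/nm, `elution_noise` 0.05 ml, `sample_rs` 7.8 nm;
#' gradient `gradient_intercept` -0.3, `gradient_slope` 0.4 S/fraction,
#' `gradient_noise` 0.05 S, `gradient_marker_fractions` (8, 14, 22),
#' `sample_s` 7.3 S, `fraction_ml` 0.5.
#' @export
synthetic_config <- function(seed = 1, ...) {
  defaults <- list(
    seed = as.integer(seed),
    ## genome and planted loci
    chrom_sizes = c(chr2L = 150000L, chr2R = 150000L),
    n_canonical = 40L,
    n_ada2b_only = 10L,
    n_unbound = 10L,
    peak_width_mean = 400,
    peak_width_sd = 50,
    min_gap = 2000,
    ## replicate peak calls
    factors = c("Ada2b", "Spt3", "Sgf11"),
    n_replicates = c(Ada2b = 4L, Spt3 = 3L, Sgf11 = 3L),
    min_support = c(Ada2b = 3L, Spt3 = 2L, Sgf11 = 2L),
    replicate_dropout = c(Ada2b = 0.02, Spt3 = 0.02, Sgf11 = 0.02),
    jitter = 50,
    ## coverage
    coverage_depth = 6e5,
    fold_canonical = c(Ada2b = 8, Spt3 = 8, Sgf11 = 8),
    fold_ada2b_only = c(Ada2b = 12, Spt3 = 1, Sgf11 = 1),
    ## gene annotation
    n_genes = 200L,
    trna_fraction = 0.3,
    ada2b_trna_fraction = 0.5,
    ## proteomics
    n_proteins = 44L,
    n_complex = 4L,
    spectra_per_run = 2000L,
    complex_fold = 20,
    n_shared_groups = 4L,
    shared_fraction = 0.3,
    ## gel filtration column and gradient
    column_markers = tibble(
      name = c("thyroglobulin", "apoferritin", "aldolase", "ovalbumin", "carbonic_anhydrase"),
      stokes_radius = c(8.5, 6.1, 4.8, 2.8, 2.1)
    ),
    v0 = 7.4,
    vt = 24,
    elution_intercept = 20,
    elution_slope = -1.2,
    elution_noise = 0.05,
    sample_rs = 7.8,
    fraction_ml = 0.5,
    gradient_intercept = -0.3,
    gradient_slope = 0.4,
    gradient_noise = 0.05,
    gradient_marker_fractions = c(8, 14, 22),
    sample_s = 7.3
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown synthetic_config field(s): %s.", paste(unknown, collapse = ", ")))
  }
  defaults[names(overrides)] <- overrides
  if (defaults$elution_slope >= 0) {
    abort("`elution_slope` must be negative: larger complexes elute earlier.")
  }
  structure(defaults, class = "synthetic_config")
}

## sub-seed per generator so stages can be regenerated independently;
## offsets keep derived seeds well under 2^31
sub_seed <- function(config, k) as.integer(config$seed) * 101L + k

#' Plant ground-truth binding loci
#'
#' Lays out non-overlapping loci of three classes (`canonical`,
#' `ada2b_only`, `unbound`) across the configured chromosomes. Loci are
#' placed on a jittered grid so that consecutive loci are separated by at
#' least `min_gap` bases, and classes are assigned at random.
#'
#' @param config A [synthetic_config()].
#' @return Tibble (`locus_id`, `chrom`, `start`, `end`, `class`).
#' @export
simulate_loci <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n_total <- config$n_canonical + config$n_ada2b_only + config$n_unbound
  if (n_total == 0) {
    return(tibble(
      locus_id = character(), chrom = character(),
      start = integer(), end = integer(), class = character()
    ))
  }
  withr::with_seed(sub_seed(config, 0L), {
    max_width <- config$peak_width_mean + 4 * config$peak_width_sd
    slot <- max_width + config$min_gap
    sizes <- config$chrom_sizes
    slots <- purrr::map_dfr(names(sizes), function(chr) {
      n_slots <- floor((sizes[[chr]] - config$min_gap) / slot)
      tibble(chrom = chr, slot_start = config$min_gap + (seq_len(n_slots) - 1) * slot)
    })
    if (nrow(slots) < n_total) {
      abort("Chromosomes too small for the requested number of loci at the configured gap.")
    }
    picked <- slots[sort(sample.int(nrow(slots), n_total)), ]
    width <- pmax(50, round(rnorm(n_total, config$peak_width_mean, config$peak_width_sd)))
    classes <- sample(c(
      rep("canonical", config$n_canonical),
      rep("ada2b_only", config$n_ada2b_only),
      rep("unbound", config$n_unbound)
    ))
    tibble(
      locus_id = sprintf("locus%03d", seq_len(n_total)),
      chrom = picked$chrom,
      start = as.integer(picked$slot_start),
      end = as.integer(picked$slot_start + width),
      class = classes
    )
  })
}

#' Generate a synthetic gene annotation
#'
#' Creates `n_genes` gene records with TSS positions, strands and biotypes.
#' Exactly `round(trna_fraction * n_genes)` genes are tRNAs. When planted
#' loci are supplied, one gene is placed at the centre of every planted
#' locus (so nearest-TSS assignment is well defined) and
#' `round(ada2b_trna_fraction * n_ada2b_only)` of the genes at ada2b-only
#' loci are tRNAs; remaining genes are placed away from all loci.
#'
#' @param config A [synthetic_config()].
#' @param loci Optional output of [simulate_loci()].
#' @return TSS tibble (`gene_id`, `chrom`, `tss`, `strand`, `biotype`).
#' @export
make_annotation <- function(config, loci = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  n_genes <- config$n_genes
  if (n_genes == 0) {
    return(tibble(
      gene_id = character(), chrom = character(), tss = integer(),
      strand = character(), biotype = character()
    ))
  }
  n_trna <- round(config$trna_fraction * n_genes)
  withr::with_seed(sub_seed(config, 1L), {
    if (!is.null(loci) && nrow(loci) > 0) {
      if (nrow(loci) > n_genes) {
        abort("`n_genes` must be at least the number of planted loci.")
      }
      at_loci <- tibble(
        chrom = loci$chrom,
        tss = as.integer(floor((loci$start + loci$end) / 2)),
        class = loci$class
      )
      n_bg <- n_genes - nrow(at_loci)
      bg <- random_gene_positions(config, n_bg, avoid = loci)
      genes <- dplyr::bind_rows(at_loci, dplyr::mutate(bg, class = "background"))
    } else {
      genes <- dplyr::mutate(random_gene_positions(config, n_genes, avoid = NULL),
                             class = "background")
    }
    ## biotype assignment: ada2b-only-proximal genes first, then background
    genes$biotype <- "protein_coding"
    is_ada <- which(genes$class == "ada2b_only")
    n_ada_trna <- min(round(config$ada2b_trna_fraction * length(is_ada)), n_trna)
    trna_idx <- if (n_ada_trna > 0) is_ada[seq_len(n_ada_trna)] else integer()
    remaining <- n_trna - length(trna_idx)
    pool <- which(genes$class == "background")
    if (remaining > length(pool)) {
      abort("`trna_fraction` too high for the number of background genes.")
    }
    if (remaining > 0) {
      trna_idx <- c(trna_idx, sample(pool, remaining))
    }
    genes$biotype[trna_idx] <- "tRNA"
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
    genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
    genes[, c("gene_id", "chrom", "tss", "strand", "biotype")]
  })
}

## sample gene positions uniformly, rejecting positions within 1.5 kb of
## any planted locus so background genes never steal a nearest-TSS call
random_gene_positions <- function(config, n, avoid = NULL) {
  if (n == 0) {
    return(tibble(chrom = character(), tss = integer()))
  }
  sizes <- config$chrom_sizes
  out <- tibble(chrom = character(), tss = integer())
  guard <- 0
  while (nrow(out) < n && guard < 50) {
    guard <- guard + 1
    chrom <- sample(names(sizes), n, replace = TRUE,
                    prob = as.numeric(sizes) / sum(as.numeric(sizes)))
    pos <- vapply(chrom, function(chr) sample.int(sizes[[chr]] - 1000L, 1L) + 500L, integer(1))
    cand <- tibble(chrom = chrom, tss = as.integer(pos))
    if (!is.null(avoid) && nrow(avoid) > 0) {
      gr_cand <- GenomicRanges::GRanges(cand$chrom, IRanges::IRanges(cand$tss + 1L, width = 1L))
      gr_avoid <- GenomicRanges::GRanges(
        avoid$chrom,
        IRanges::IRanges(pmax(avoid$start - 1500L, 0L) + 1L, avoid$end + 1500L)
      )
      cand <- cand[GenomicRanges::countOverlaps(gr_cand, gr_avoid) == 0, ]
    }
    out <- dplyr::bind_rows(out, cand)
  }
  out[seq_len(n), ]
}

#' Simulate per-factor, per-replicate peak calls
#'
#' Every replicate of a factor observes each true locus bound by that
#' factor with probability `1 - replicate_dropout`, with peak edges
#' jittered uniformly by up to `jitter` bp (truncated so that end > start).
#' Canonical loci emit peaks for all factors; ada2b-only loci only for
#' Ada2b; unbound loci never.
#'
#' @param loci Output of [simulate_loci()].
#' @param config A [synthetic_config()].
#' @return Tibble (`chip_factor`, `replicate`, `chrom`, `start`, `end`,
#'   `name`).
#' @export
simulate_replicate_peaks <- function(loci, config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(sub_seed(config, 2L), {
    purrr::map_dfr(config$factors, function(f) {
      bound <- loci[loci$class == "canonical" |
                      (loci$class == "ada2b_only" & f == "Ada2b"), ]
      n_rep <- config$n_replicates[[f]]
      dropout <- config$replicate_dropout[[f]]
      purrr::map_dfr(seq_len(n_rep), function(r) {
        keep <- runif(nrow(bound)) >= dropout
        pk <- bound[keep, ]
        if (nrow(pk) == 0) {
          return(tibble(
            chip_factor = character(), replicate = character(),
            chrom = character(), start = integer(), end = integer(),
            name = character()
          ))
        }
        j1 <- round(runif(nrow(pk), -config$jitter, config$jitter))
        j2 <- round(runif(nrow(pk), -config$jitter, config$jitter))
        start <- pmax(0L, as.integer(pk$start + j1))
        end <- as.integer(pk$end + j2)
        end <- pmax(end, start + 1L)
        tibble(
          chip_factor = f,
          replicate = sprintf("%s_rep%d", f, r),
          chrom = pk$chrom, start = start, end = end,
          name = pk$locus_id
        )
      })
    })
  })
}

#' Simulate ChIP and input coverage tracks
#'
#' Draws per-base Poisson read counts for every factor replicate and for
#' one total-chromatin input sample. The background rate is
#' `coverage_depth / genome size`; inside a planted locus the rate is
#' multiplied by the configured class- and factor-specific fold. The input
#' track carries no planted enrichment. Each track's `total_reads` equals
#' the number of reads actually simulated.
#'
#' @param loci Output of [simulate_loci()].
#' @param config A [synthetic_config()].
#' @return Named list of `coverage_track` objects (`<factor>_rep<k>` plus
#'   `"input"`).
#' @export
simulate_coverage <- function(loci, config) {
  stopifnot(inherits(config, "synthetic_config"))
  sizes <- config$chrom_sizes
  lambda0 <- config$coverage_depth / sum(as.numeric(sizes))
  fold_for <- function(f) {
    fold <- setNames(rep(1, nrow(loci)), loci$locus_id)
    fold[loci$class == "canonical"] <- config$fold_canonical[[f]]
    fold[loci$class == "ada2b_only"] <- config$fold_ada2b_only[[f]]
    fold
  }
  make_track <- function(f, rep_id, fold) {
    cov <- lapply(names(sizes), function(chr) {
      lam <- rep(lambda0, sizes[[chr]])
      on_chr <- loci[loci$chrom == chr, ]
      if (nrow(on_chr) > 0 && !is.null(fold)) {
        for (i in seq_len(nrow(on_chr))) {
          idx <- (on_chr$start[i] + 1):on_chr$end[i]
          lam[idx] <- lam[idx] * fold[[on_chr$locus_id[i]]]
        }
      }
      S4Vectors::Rle(rpois(length(lam), lam))
    })
    cov <- methods::as(setNames(cov, names(sizes)), "SimpleRleList")
    total <- sum(vapply(cov, function(r) sum(as.numeric(S4Vectors::runValue(r) *
                                                          S4Vectors::runLength(r))), numeric(1)))
    new_coverage_track(cov, max(total, 1), sample_id = paste0(f, "_", rep_id),
                       chip_factor = f, replicate_id = rep_id)
  }
  withr::with_seed(sub_seed(config, 3L), {
    tracks <- list()
    for (f in config$factors) {
      fold <- fold_for(f)
      for (r in seq_len(config$n_replicates[[f]])) {
        rep_id <- sprintf("rep%d", r)
        tracks[[sprintf("%s_%s", f, rep_id)]] <- make_track(f, rep_id, fold)
      }
    }
    tracks[["input"]] <- make_track("input", "rep1", NULL)
    tracks
  })
}

#' Simulate a MudPIT spectral-count experiment
#'
#' Draws spectral counts for two sample runs (`frac18`, `frac19`) and a
#' mock-purification control. Sampling is multinomial with probabilities
#' proportional to abundance times protein length; the planted complex
#' members have `complex_fold` times the contaminant abundance in the
#' sample runs and are absent from the mock. A configurable number of
#' contaminant paralog pairs share peptide groups: a fraction of the pair's
#' spectra is moved into a shared group with the remainder kept unique.
#'
#' @param config A [synthetic_config()].
#' @return List with `counts`, `shared` (tibbles in the formats of
#'   [read_spectral_counts()] / [read_shared_groups()]) and `truth`
#'   (planted abundances and complex membership).
#' @export
simulate_spectral_counts <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_proteins
  k <- config$n_complex
  if (n < k + 2 * config$n_shared_groups) {
    abort("`n_proteins` too small for the requested complex and shared groups.")
  }
  withr::with_seed(sub_seed(config, 4L), {
    proteins <- sprintf("P%03d", seq_len(n))
    complex_members <- proteins[seq_len(k)]
    lengths <- sample(150:1000, n, replace = TRUE)
    abundance <- rep(1, n)
    abundance[seq_len(k)] <- config$complex_fold
    contaminants <- setdiff(proteins, complex_members)
    ## paralog pairs drawn from contaminants
    pair_pool <- sample(contaminants, 2 * config$n_shared_groups)
    pairs <- matrix(pair_pool, ncol = 2)
    draw_run <- function(run_id, probs) {
      cnt <- as.integer(rmultinom(1, config$spectra_per_run, probs))
      counts <- tibble(
        protein_id = proteins, run_id = run_id,
        length = as.integer(lengths), unique_spectra = as.numeric(cnt)
      )
      shared <- tibble(
        run_id = character(), group_id = character(),
        protein_id = character(), spectra = numeric()
      )
      for (g in seq_len(nrow(pairs))) {
        members <- pairs[g, ]
        i <- match(members, counts$protein_id)
        pair_total <- sum(counts$unique_spectra[i])
        s_g <- round(config$shared_fraction * pair_total)
        if (s_g == 0) next
        ## remove shared spectra proportionally from the members' unique counts
        take <- round(s_g * counts$unique_spectra[i] / pair_total)
        take[1] <- s_g - sum(take[-1])
        counts$unique_spectra[i] <- counts$unique_spectra[i] - take
        shared <- dplyr::bind_rows(shared, tibble(
          run_id = run_id, group_id = sprintf("grp%02d", g),
          protein_id = members, spectra = s_g
        ))
      }
      list(counts = counts, shared = shared)
    }
    p_sample <- abundance * lengths / sum(abundance * lengths)
    p_mock <- ifelse(proteins %in% complex_members, 0, lengths)
    p_mock <- p_mock / sum(p_mock)
    runs <- list(
      draw_run("frac18", p_sample),
      draw_run("frac19", p_sample),
      draw_run("mock", p_mock)
    )
    list(
      counts = dplyr::bind_rows(lapply(runs, `[[`, "counts")),
      shared = dplyr::bind_rows(lapply(runs, `[[`, "shared")),
      truth = list(
        complex_members = complex_members,
        abundance = setNames(abundance, proteins),
        lengths = setNames(as.integer(lengths), proteins)
      )
    )
  })
}

#' Simulate a gel-filtration calibration and density gradient
#'
#' Generates marker elution volumes from a monotone linear model of the
#' Stokes radius plus Gaussian noise, a sample complex planted at
#' `sample_rs`, and sedimentation-gradient standards from a linear
#' s-versus-fraction model with the sample peaking at the fraction
#' corresponding to `sample_s`.
#'
#' @param config A [synthetic_config()].
#' @return List with `markers` (name, stokes_radius, elution_volume),
#'   `gradient` (fraction, s), `sample` (elution_volume, peak_fraction),
#'   `v0`, `vt` and `truth` (planted `rs` and `s`).
#' @export
simulate_gel_filtration <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(sub_seed(config, 5L), {
    mk <- config$column_markers
    ve <- config$elution_intercept + config$elution_slope * mk$stokes_radius +
      rnorm(nrow(mk), 0, config$elution_noise)
    if (is.unsorted(ve[order(-mk$stokes_radius)], strictly = TRUE)) {
      abort("Generated marker elutions are non-monotone; reduce `elution_noise` or spread the markers.")
    }
    markers <- tibble(
      name = mk$name, stokes_radius = mk$stokes_radius, elution_volume = ve
    )
    sample_ve <- config$elution_intercept + config$elution_slope * config$sample_rs +
      rnorm(1, 0, config$elution_noise)
    grad_frac <- config$gradient_marker_fractions
    gradient <- tibble(
      fraction = grad_frac,
      s = config$gradient_intercept + config$gradient_slope * grad_frac +
        rnorm(length(grad_frac), 0, config$gradient_noise)
    )
    peak_fraction <- round((config$sample_s - config$gradient_intercept) / config$gradient_slope)
    list(
      markers = markers,
      gradient = gradient,
      sample = list(elution_volume = sample_ve, peak_fraction = peak_fraction),
      v0 = config$v0,
      vt = config$vt,
      truth = list(rs = config$sample_rs, s = config$sample_s)
    )
  })
}

#' Generate the full synthetic dataset
#'
#' Runs every sub-generator under the configured seed and, optionally,
#' writes all inputs to disk in their standard text formats: narrowPeak
#' files per factor replicate, bedGraph coverage with a sidecar total-reads
#' table, a GTF and TSV gene annotation, spectral-count and shared-group
#' TSVs, gel-filtration marker and gradient TSVs, and a `truth.json`
#' manifest of the planted ground truth.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Optional directory to write the dataset to.
#' @return List with elements `loci`, `annotation`, `peaks`, `tracks`,
#'   `proteomics`, `gel_filtration` and `config`.
#' @export
simulate_ada_dataset <- function(config = synthetic_config(), out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  loci <- simulate_loci(config)
  annotation <- make_annotation(config, loci)
  peaks <- simulate_replicate_peaks(loci, config)
  tracks <- simulate_coverage(loci, config)
  proteomics <- simulate_spectral_counts(config)
  gel <- simulate_gel_filtration(config)
  data <- list(
    loci = loci, annotation = annotation, peaks = peaks, tracks = tracks,
    proteomics = proteomics, gel_filtration = gel, config = config
  )
  if (!is.null(out_dir)) {
    write_ada_dataset(data, out_dir)
  }
  data
}

write_ada_dataset <- function(data, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- data$config
  readr::write_tsv(data$loci, file.path(out_dir, "truth_loci.tsv"), progress = FALSE)
  readr::write_tsv(data$annotation, file.path(out_dir, "annotation.tsv"), progress = FALSE)
  write_tss_gtf(data$annotation, file.path(out_dir, "annotation.gtf"))
  for (rep_id in unique(data$peaks$replicate)) {
    pk <- data$peaks[data$peaks$replicate == rep_id, ]
    write_narrowpeak(pk, file.path(out_dir, sprintf("%s.narrowPeak", rep_id)))
  }
  totals <- purrr::map_dfr(names(data$tracks), function(nm) {
    tr <- data$tracks[[nm]]
    write_bedgraph(tr, file.path(out_dir, sprintf("%s.bedGraph", nm)))
    tibble(sample_id = nm, chip_factor = tr$chip_factor,
           replicate_id = tr$replicate_id, total_reads = tr$total_reads)
  })
  readr::write_tsv(totals, file.path(out_dir, "total_reads.tsv"), progress = FALSE)
  readr::write_tsv(data$proteomics$counts, file.path(out_dir, "spectral_counts.tsv"), progress = FALSE)
  readr::write_tsv(data$proteomics$shared, file.path(out_dir, "shared_groups.tsv"), progress = FALSE)
  readr::write_tsv(data$gel_filtration$markers, file.path(out_dir, "column_markers.tsv"), progress = FALSE)
  readr::write_tsv(data$gel_filtration$gradient, file.path(out_dir, "gradient_markers.tsv"), progress = FALSE)
  truth <- list(
    seed = config$seed,
    locus_classes = setNames(data$loci$class, data$loci$locus_id),
    complex_members = data$proteomics$truth$complex_members,
    rs = data$gel_filtration$truth$rs,
    s = data$gel_filtration$truth$s,
    sample_elution_volume = data$gel_filtration$sample$elution_volume,
    sample_peak_fraction = data$gel_filtration$sample$peak_fraction,
    v0 = data$gel_filtration$v0,
    vt = data$gel_filtration$vt
  )
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Load a written synthetic dataset back from disk
#'
#' Reads a directory produced by [simulate_ada_dataset()] through the
#' package's standard-format readers ([read_narrowpeak()],
#' [read_bedgraph()], [read_tss_table()], [read_spectral_counts()], ...)
#' into the same structure returned by [simulate_ada_dataset()].
#'
#' @param dir Dataset directory.
#' @param config The [synthetic_config()] the dataset was generated with
#'   (carried for stage parameters; defaults to the default config).
#' @return A dataset list, see [simulate_ada_dataset()].
#' @export
load_ada_dataset <- function(dir, config = synthetic_config()) {
  loci <- readr::read_tsv(file.path(dir, "truth_loci.tsv"),
                          col_types = "cciic", progress = FALSE)
  annotation <- read_tss_table(file.path(dir, "annotation.tsv"))
  totals <- readr::read_tsv(file.path(dir, "total_reads.tsv"),
                            col_types = "cccd", progress = FALSE)
  tracks <- lapply(seq_len(nrow(totals)), function(i) {
    read_bedgraph(
      file.path(dir, sprintf("%s.bedGraph", totals$sample_id[i])),
      total_reads = totals$total_reads[i],
      sample_id = totals$sample_id[i],
      chip_factor = totals$chip_factor[i],
      replicate_id = totals$replicate_id[i]
    )
  })
  names(tracks) <- totals$sample_id
  peak_files <- list.files(dir, pattern = "\\.narrowPeak$", full.names = TRUE)
  peaks <- purrr::map_dfr(peak_files, function(f) {
    rep_id <- sub("\\.narrowPeak$", "", basename(f))
    pk <- read_narrowpeak(f)
    pk$replicate <- rep_id
    pk$chip_factor <- sub("_rep[0-9]+$", "", rep_id)
    pk
  })
  gel <- list(
    markers = readr::read_tsv(file.path(dir, "column_markers.tsv"),
                              col_types = "cdd", progress = FALSE),
    gradient = readr::read_tsv(file.path(dir, "gradient_markers.tsv"),
                               col_types = "dd", progress = FALSE)
  )
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  gel$sample <- list(
    elution_volume = truth$sample_elution_volume,
    peak_fraction = truth$sample_peak_fraction
  )
  gel$v0 <- truth$v0
  gel$vt <- truth$vt
  gel$truth <- list(rs = truth$rs, s = truth$s)
  list(
    loci = loci, annotation = annotation, peaks = peaks, tracks = tracks,
    proteomics = list(
      counts = read_spectral_counts(file.path(dir, "spectral_counts.tsv")),
      shared = read_shared_groups(file.path(dir, "shared_groups.tsv")),
      truth = list(complex_members = truth$complex_members)
    ),
    gel_filtration = gel,
    config = config
  )
}
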