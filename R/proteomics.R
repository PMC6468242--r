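#' Read a spectral-count table
#'
#' Reads per-run protein spectral counts as tab-separated text with columns
#' `protein_id`, `run_id`, `length` (residues) and `unique_spectra` (uSpC).
#'
#' @param path Path to the TSV file (with header).
#' @return Tibble of spectral counts.
#' @export
read_spectral_counts <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      protein_id = readr::col_character(), run_id = readr::col_character(),
      length = readr::col_integer(), unique_spectra = readr::col_double()
    ),
    progress = FALSE
  )
}

#' Read a shared-peptide group table
#'
#' Reads shared spectral counts as tab-separated text with columns
#' `run_id`, `group_id`, `protein_id`, `spectra`: each row names one member
#' of a shared-peptide group, and `spectra` is the group's shared count
#' (sSpC), repeated on every member row of that group.
#'
#' @param path Path to the TSV file (with header).
#' @return Tibble of shared groups.
#' @export
read_shared_groups <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      run_id = readr::col_character(), group_id = readr::col_character(),
      protein_id = readr::col_character(), spectra = readr::col_double()
    ),
    progress = FALSE
  )
}

validate_counts <- function(counts) {
  needed <- c("protein_id", "run_id", "length", "unique_spectra")
  missing_cols <- setdiff(needed, names(counts))
  if (length(missing_cols) > 0) {
    abort(sprintf("`counts` is missing column(s): %s.", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(counts) > 0) {
    if (any(counts$length <= 0)) abort("Protein `length` must be positive.")
    if (any(counts$unique_spectra < 0)) abort("`unique_spectra` must be non-negative.")
    if (anyDuplicated(counts[, c("protein_id", "run_id")])) {
      abort("Duplicate (protein_id, run_id) rows in `counts`.")
    }
  }
  invisible(counts)
}

#' Distribute shared spectral counts among group members
#'
#' Computes distributed spectral counts (dSpC): each protein keeps its
#' unique spectra, and every shared-peptide group's count is split among its
#' member proteins in proportion to their unique spectral counts. When no
#' member of a group has unique spectra, the group's count is split equally.
#' Distribution is per run; total spectra are conserved exactly
#' (sum dSpC = sum uSpC + sum sSpC).
#'
#' @param counts Spectral-count tibble (`protein_id`, `run_id`, `length`,
#'   `unique_spectra`).
#' @param shared Optional shared-group tibble (`run_id`, `group_id`,
#'   `protein_id`, `spectra`), see [read_shared_groups()]. Groups with a
#'   single member are treated as unique spectra, with a warning.
#' @return `counts` with an added `dspc` column.
#' @export
distribute_shared_spectra <- function(counts, shared = NULL) {
  validate_counts(counts)
  counts$dspc <- as.numeric(counts$unique_spectra)
  if (is.null(shared) || nrow(shared) == 0) {
    return(counts)
  }
  needed <- c("run_id", "group_id", "protein_id", "spectra")
  if (!all(needed %in% names(shared))) {
    abort(sprintf("`shared` must have columns %s.", paste(needed, collapse = ", ")))
  }
  key <- paste(counts$protein_id, counts$run_id, sep = "\r")
  idx <- stats::setNames(seq_len(nrow(counts)), key)
  groups <- split(shared, paste(shared$run_id, shared$group_id, sep = "\r"))
  singletons <- character()
  for (g in groups) {
    sspc <- unique(g$spectra)
    if (length(sspc) != 1) {
      abort(sprintf("Group %s (run %s) has inconsistent shared counts.", g$group_id[1], g$run_id[1]))
    }
    member_idx <- idx[paste(g$protein_id, g$run_id, sep = "\r")]
    if (anyNA(member_idx)) {
      abort(sprintf(
        "Group %s (run %s) names protein(s) absent from `counts`.",
        g$group_id[1], g$run_id[1]
      ))
    }
    if (length(member_idx) == 1) {
      singletons <- c(singletons, g$group_id[1])
      counts$dspc[member_idx] <- counts$dspc[member_idx] + sspc
      next
    }
    anchors <- counts$unique_spectra[member_idx]
    w <- if (sum(anchors) > 0) anchors / sum(anchors) else rep(1 / length(anchors), length(anchors))
    counts$dspc[member_idx] <- counts$dspc[member_idx] + sspc * w
  }
  if (length(singletons) > 0) {
    warn(sprintf(
      "Shared group(s) with a single member treated as unique spectra: %s.",
      paste(unique(singletons), collapse = ", ")
    ))
  }
  counts
}

#' Distributed normalized spectral abundance factor (dNSAF)
#'
#' Quantifies relative protein abundance per MudPIT run: distributed
#' spectral counts (see [distribute_shared_spectra()]) are divided by
#' protein length and normalised so the values sum to 1 within each run:
#' `dNSAF_i = (dSpC_i / L_i) / sum_m(dSpC_m / L_m)`.
#'
#' @inheritParams distribute_shared_spectra
#' @return `counts` with added `dspc` and `dnsaf` columns.
#' @export
dnsaf <- function(counts, shared = NULL) {
  counts <- distribute_shared_spectra(counts, shared)
  out <- counts |>
    dplyr::mutate(saf = dspc / length) |>
    dplyr::group_by(run_id) |>
    dplyr::mutate(dnsaf = saf / sum(saf)) |>
    dplyr::ungroup()
  if (anyNA(out$dnsaf) | any(!is.finite(out$dnsaf))) {
    bad <- unique(out$run_id[!is.finite(out$dnsaf)])
    abort(sprintf("Run(s) with no spectra at all: %s.", paste(bad, collapse = ", ")))
  }
  out$saf <- NULL
  out
}

#' Proteins enriched above a dNSAF threshold
#'
#' Averages dNSAF across the listed runs and keeps proteins whose mean
#' exceeds `threshold`. When a mock (control purification) run is given,
#' proteins whose mock dNSAF is at least their sample mean are excluded,
#' mirroring the omission of proteins also enriched in a mock sample.
#' A protein absent from a run contributes 0 to its mean.
#'
#' @param dnsaf_tbl Output of [dnsaf()] (needs `protein_id`, `run_id`,
#'   `dnsaf`).
#' @param runs Character vector of run ids to average over.
#' @param threshold dNSAF enrichment cutoff (default 0.035).
#' @param mock_run Optional run id of the mock control.
#' @return Tibble (`protein_id`, `mean_dnsaf`) of enriched proteins, sorted
#'   by decreasing mean dNSAF (ties by id).
#' @export
enriched_proteins <- function(dnsaf_tbl, runs, threshold = 0.035, mock_run = NULL) {
  if (length(runs) == 0) {
    abort("`runs` must name at least one run.")
  }
  missing_runs <- setdiff(c(runs, mock_run), unique(dnsaf_tbl$run_id))
  if (length(missing_runs) > 0) {
    abort(sprintf("Run(s) not in the dNSAF table: %s.", paste(missing_runs, collapse = ", ")))
  }
  means <- dnsaf_tbl |>
    dplyr::filter(run_id %in% runs) |>
    dplyr::group_by(protein_id) |>
    dplyr::summarise(mean_dnsaf = sum(dnsaf) / length(runs), .groups = "drop")
  out <- dplyr::filter(means, mean_dnsaf > threshold)
  if (!is.null(mock_run)) {
    mock <- dnsaf_tbl |>
      dplyr::filter(run_id == mock_run) |>
      dplyr::select(protein_id, mock_dnsaf = dnsaf)
    out <- out |>
      dplyr::left_join(mock, by = "protein_id") |>
      dplyr::mutate(mock_dnsaf = dplyr::coalesce(.data$mock_dnsaf, 0)) |>
      dplyr::filter(.data$mock_dnsaf < mean_dnsaf) |>
      dplyr::select(-"mock_dnsaf")
  }
  dplyr::arrange(out, dplyr::desc(mean_dnsaf), protein_id)
}

#' Sorted dNSAF abundance matrix
#'
#' Spreads a dNSAF table into a proteins-by-runs matrix, adds a `mean`
#' column averaged over `average_runs`, and sorts rows by that average in
#' decreasing order (ties broken by protein id) — the layout used for
#' fraction-wise abundance heatmaps.
#'
#' @param dnsaf_tbl Output of [dnsaf()].
#' @param sample_runs Run ids to include as columns, in order.
#' @param average_runs Run ids averaged into the `mean` sorting column
#'   (default: `sample_runs`).
#' @return A tibble (class `dnsaf_matrix`) with `protein_id`, one column
#'   per run, and `mean`; missing protein/run combinations are 0.
#' @export
abundance_matrix <- function(dnsaf_tbl, sample_runs, average_runs = sample_runs) {
  missing_runs <- setdiff(c(sample_runs, average_runs), unique(dnsaf_tbl$run_id))
  if (length(missing_runs) > 0) {
    abort(sprintf("Run(s) not in the dNSAF table: %s.", paste(missing_runs, collapse = ", ")))
  }
  wide <- dnsaf_tbl |>
    dplyr::filter(run_id %in% unique(c(sample_runs, average_runs))) |>
    dplyr::select(protein_id, run_id, dnsaf) |>
    tidyr::pivot_wider(names_from = run_id, values_from = dnsaf, values_fill = 0)
  for (r in unique(c(sample_runs, average_runs))) {
    if (!r %in% names(wide)) wide[[r]] <- 0
  }
  wide$mean <- rowMeans(wide[, average_runs, drop = FALSE])
  out <- wide[order(-wide$mean, wide$protein_id), c("protein_id", sample_runs, "mean")]
  class(out) <- c("dnsaf_matrix", class(out))
  out
}
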