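#' Read a PSM table
#'
#' Reads a tab-separated table of peptide-to-spectrum matches with columns
#' `spectrum_id`, `protein`, `peptide`, `score` and optionally `is_decoy`.
#' When `is_decoy` is absent it is inferred from the accession prefix of the
#' reversed-database entries.
#'
#' @param path TSV file.
#' @param decoy_prefix accession prefix marking decoy hits (default `"REV_"`),
#'   used only when the file has no `is_decoy` column.
#' @return A data.frame of PSM records.
#' @export
read_psm_table <- function(path, decoy_prefix = "REV_") {
  psms <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("spectrum_id", "protein", "peptide", "score")
  missing <- setdiff(required, names(psms))
  if (length(missing) > 0) {
    stop("PSM table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!"is_decoy" %in% names(psms)) {
    psms$is_decoy <- startsWith(psms$protein, decoy_prefix)
  }
  psms$is_decoy <- as.logical(psms$is_decoy)
  validate_psms(psms)
  psms
}

validate_psms <- function(psms) {
  if (nrow(psms) == 0) return(invisible(psms))
  if (any(!nzchar(psms$spectrum_id))) stop("empty spectrum_id in PSM table")
  if (any(!is.finite(psms$score))) stop("non-finite score in PSM table")
  invisible(psms)
}

#' Best-scoring match per spectrum
#'
#' Reduces a PSM list (target and decoy matches mixed) to exactly one record
#' per spectrum: the match with the highest score across the standard and
#' reversed-database searches.  A score tie between a target and a decoy
#' match is resolved to the decoy, which makes the downstream FDR estimate
#' conservative.
#'
#' @param psms data.frame of PSM records (see [read_psm_table()]).
#' @return A data.frame with one row per distinct `spectrum_id`.
#' @export
best_psm_per_spectrum <- function(psms) {
  validate_psms(psms)
  if (nrow(psms) == 0) return(psms)
  # order: per spectrum, decreasing score, decoys first on ties
  ord <- order(psms$spectrum_id, -psms$score, !psms$is_decoy)
  sorted <- psms[ord, , drop = FALSE]
  best <- sorted[!duplicated(sorted$spectrum_id), , drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Target-decoy false discovery rate
#'
#' The global PSM-level FDR: the number of best matches that hit the
#' reversed (decoy) database divided by the number of best matches against
#' both databases.  The input must already be reduced to one match per
#' spectrum ([best_psm_per_spectrum()]).  An empty list has FDR 0 by
#' convention (nothing reported, nothing false).
#'
#' @param psms data.frame of best-per-spectrum PSM records.
#' @return A fraction in `[0, 1]`.
#' @export
compute_fdr <- function(psms) {
  validate_psms(psms)
  if (nrow(psms) == 0) return(0)
  sum(psms$is_decoy) / nrow(psms)
}

#' Per-run FDR report with a global aggregate
#'
#' Applies [best_psm_per_spectrum()] and [compute_fdr()] within each run and
#' aggregates decoy and total counts across runs into one global ratio.
#'
#' @param psms data.frame of PSM records with an additional `run` column.
#' @return A list with `per_run` (data.frame run/n_psms/n_decoy/fdr) and
#'   `global_fdr`.
#' @export
fdr_by_run <- function(psms) {
  if (!"run" %in% names(psms)) stop("PSM table needs a 'run' column")
  per_run <- lapply(split(psms, psms$run), function(run_psms) {
    best <- best_psm_per_spectrum(run_psms)
    data.frame(run = run_psms$run[1], n_psms = nrow(best),
               n_decoy = sum(best$is_decoy), fdr = compute_fdr(best),
               stringsAsFactors = FALSE)
  })
  per_run <- do.call(rbind, c(per_run, list(make.row.names = FALSE)))
  total <- sum(per_run$n_psms)
  list(per_run = per_run,
       global_fdr = if (total == 0) 0 else sum(per_run$n_decoy) / total)
}
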