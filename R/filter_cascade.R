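#' Control-based background removal
#'
#' Removes every protein that was identified in at least one control
#' experiment — with any nonzero spectral count, including single-count
#' identifications — from the candidate lists of all baits and both
#' conditions.  Removal is global: a protein seen in a control is treated as
#' background everywhere.  The removed accessions are stored in the
#' `"removed_proteins"` attribute of the result.
#'
#' @param x a [count_matrix()] containing at least one control column.
#' @return The `count_matrix` restricted to proteins with zero counts across
#'   all control experiments.
#' @export
control_filter <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  ctrl_cols <- x$meta$experiment_id[x$meta$role == "control_experiment"]
  if (length(ctrl_cols) == 0) {
    stop("control_filter requires at least one control experiment")
  }
  in_control <- rowSums(x$counts[, ctrl_cols, drop = FALSE]) > 0L
  out <- structure(
    list(counts = x$counts[!in_control, , drop = FALSE], meta = x$meta),
    class = "count_matrix")
  attr(out, "removed_proteins") <- rownames(x$counts)[in_control]
  out
}

strength_class <- function(summed_count, weak_value = 2L, strong_min = 3L) {
  as.character(ifelse(summed_count >= strong_min, "strong",
                      ifelse(summed_count == weak_value, "weak", "one_hit")))
}

#' Sum spectral counts over replicate groups
#'
#' For every (bait, prey, condition) triple, sums the prey's spectral counts
#' over that bait x condition's replicate experiments and assigns the
#' interaction-strength class: `one_hit` (summed count 1), `weak` (exactly
#' 2) or `strong` (3 or more).  Zero-sum triples are omitted.
#'
#' @param x a (typically control-filtered) [count_matrix()].
#' @param weak_value,strong_min class boundaries on the summed count
#'   (defaults 2 and 3).
#' @return A data.frame of candidate interactions with columns `bait`,
#'   `prey`, `condition`, `summed_count`, `strength`.
#' @export
sum_replicates <- function(x, weak_value = 2L, strong_min = 3L) {
  stopifnot(inherits(x, "count_matrix"))
  stopifnot(weak_value >= 1L, strong_min == weak_value + 1L)
  meta <- x$meta[x$meta$role == "bait_experiment", , drop = FALSE]
  groups <- unique(meta[, c("bait", "condition")])
  out <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    cols <- meta$experiment_id[meta$bait == groups$bait[i] &
                                 meta$condition == groups$condition[i]]
    sums <- rowSums(x$counts[, cols, drop = FALSE])
    nz <- sums > 0L
    if (!any(nz)) next
    out[[i]] <- data.frame(
      bait = groups$bait[i],
      prey = rownames(x$counts)[nz],
      condition = groups$condition[i],
      summed_count = as.integer(sums[nz]),
      stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  out <- if (length(out) > 0) {
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  } else {
    data.frame(bait = character(0), prey = character(0),
               condition = character(0), summed_count = integer(0),
               stringsAsFactors = FALSE)
  }
  out$strength <- strength_class(out$summed_count, weak_value, strong_min)
  out
}

#' Remove one-hit wonders
#'
#' Drops candidate pairs supported by only a single PSM.  In the default
#' (`"per_condition"`) mode a (bait, prey) pair survives iff its summed
#' count reaches `min_keep` (2) in at least one condition's replicate group;
#' for a surviving pair, a condition where the sum is 1 is kept as presence
#' evidence but stays flagged `one_hit` and never confers weak/strong
#' status.  The `"pooled"` mode instead pools the summed counts across both
#' conditions before applying the threshold (sensitivity-analysis switch).
#'
#' @param candidates data.frame from [sum_replicates()].
#' @param mode `"per_condition"` (default) or `"pooled"`.
#' @param min_keep minimal summed count that rescues a pair (default 2).
#' @return The filtered candidate data.frame.
#' @export
drop_one_hit_wonders <- function(candidates, mode = c("per_condition",
                                                      "pooled"),
                                 min_keep = 2L) {
  mode <- match.arg(mode)
  if (nrow(candidates) == 0) return(candidates)
  key <- paste(candidates$bait, candidates$prey, sep = "\r")
  support <- switch(mode,
    per_condition = tapply(candidates$summed_count, key, max),
    pooled = tapply(candidates$summed_count, key, sum)
  )
  keep <- key %in% names(support)[support >= min_keep]
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full candidate filter cascade
#'
#' Composes the three filtering stages — control-based removal, replicate
#' summation with strength classes, one-hit-wonder removal — in the fixed
#' order of the screening workflow.
#'
#' @param x a [count_matrix()].
#' @param one_hit_mode passed to [drop_one_hit_wonders()].
#' @return A list with `candidates` (the surviving candidate table),
#'   `post_control` (the control-filtered matrix) and `removed_background`
#'   (accessions removed by the control filter).
#' @export
filter_cascade <- function(x, one_hit_mode = "per_condition") {
  filtered <- control_filter(x)
  candidates <- sum_replicates(filtered)
  candidates <- drop_one_hit_wonders(candidates, mode = one_hit_mode)
  list(candidates = candidates,
       post_control = filtered,
       removed_background = attr(filtered, "removed_proteins"))
}

#' Write a candidate-interaction table as TSV
#'
#' @param candidates data.frame from the cascade.
#' @param path output file.
#' @export
write_candidates <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a candidate-interaction table from TSV
#'
#' @param path TSV with columns bait, prey, condition, summed_count, strength.
#' @return The candidate data.frame.
#' @export
read_candidates <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("bait", "prey", "condition", "summed_count", "strength")
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    stop("candidate table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  out
}
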