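#' Experiment metadata table
#'
#' Builds and validates the experiment metadata used throughout the pipeline.
#' Each row describes one LC-MS/MS run: which bait was expressed, under which
#' condition, which biological replicate it is, and whether it is a bait
#' experiment or a control (background) experiment.
#'
#' @param experiment_id character, unique label per run.
#' @param bait character, bait accession (control experiments carry their own
#'   control-bait accession, which must not be one of the study baits).
#' @param condition `"untreated"`, `"TNF"` or `"not_applicable"`.
#' @param replicate integer replicate index (>= 1).
#' @param role `"bait_experiment"` or `"control_experiment"`.
#' @return A validated `data.frame` with those five columns.
#' @export
experiment_meta <- function(experiment_id, bait, condition, replicate, role) {
  meta <- data.frame(
    experiment_id = as.character(experiment_id),
    bait = as.character(bait),
    condition = as.character(condition),
    replicate = as.integer(replicate),
    role = as.character(role),
    stringsAsFactors = FALSE
  )
  validate_experiment_meta(meta)
  meta
}

validate_experiment_meta <- function(meta) {
  required <- c("experiment_id", "bait", "condition", "replicate", "role")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(meta$experiment_id)) {
    dup <- unique(meta$experiment_id[duplicated(meta$experiment_id)])
    stop("duplicated experiment_id: ", paste(dup, collapse = ", "))
  }
  bad_cond <- setdiff(meta$condition, c("untreated", "TNF", "not_applicable"))
  if (length(bad_cond) > 0) {
    stop("unknown condition label(s): ", paste(bad_cond, collapse = ", "))
  }
  bad_role <- setdiff(meta$role, c("bait_experiment", "control_experiment"))
  if (length(bad_role) > 0) {
    stop("unknown role label(s): ", paste(bad_role, collapse = ", "))
  }
  if (any(meta$replicate < 1L)) stop("replicate indices must be >= 1")
  study_baits <- unique(meta$bait[meta$role == "bait_experiment"])
  ctrl_baits <- unique(meta$bait[meta$role == "control_experiment"])
  shared <- intersect(study_baits, ctrl_baits)
  if (length(shared) > 0) {
    stop("bait(s) used both as study bait and control bait: ",
         paste(shared, collapse = ", "))
  }
  key <- meta[meta$role == "bait_experiment",
              c("bait", "condition", "replicate")]
  if (anyDuplicated(key)) {
    stop("duplicate (bait, condition, replicate) among bait experiments")
  }
  invisible(meta)
}

#' Spectral-count matrix
#'
#' The central container of the pipeline: a nonnegative integer matrix of
#' spectral counts (proteins in rows, experiments in columns) joined to the
#' experiment metadata.  Decoy accessions must already be excluded and every
#' protein must be observed in at least one experiment.
#'
#' @param counts integer matrix, rownames = protein accessions, colnames =
#'   experiment ids.
#' @param meta experiment metadata (see [experiment_meta()]); row order need
#'   not match the column order of `counts`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (matrix, columns reordered to match `meta`) and `meta`.
#' @export
count_matrix <- function(counts, meta) {
  validate_experiment_meta(meta)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)) && nrow(counts) > 0) {
    stop("counts must have protein accessions as rownames")
  }
  if (!setequal(colnames(counts), meta$experiment_id)) {
    stop("count matrix columns and metadata experiment_ids differ: ",
         paste(union(setdiff(colnames(counts), meta$experiment_id),
                     setdiff(meta$experiment_id, colnames(counts))),
               collapse = ", "))
  }
  counts <- counts[, meta$experiment_id, drop = FALSE]
  if (any(counts < 0L)) stop("negative spectral counts are not allowed")
  if (nrow(counts) > 0 && any(rowSums(counts) == 0L)) {
    stop("protein(s) with zero counts in every experiment: ",
         paste(utils::head(rownames(counts)[rowSums(counts) == 0L], 5),
               collapse = ", "))
  }
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  n_bait <- sum(x$meta$role == "bait_experiment")
  n_ctrl <- sum(x$meta$role == "control_experiment")
  cat(sprintf(
    "count_matrix: %d proteins x %d experiments (%d bait, %d control)\n",
    nrow(x$counts), ncol(x$counts), n_bait, n_ctrl))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Assemble a count matrix from per-experiment count tables
#'
#' Takes one protein -> count table per experiment (named list or long-format
#' data.frame), forms the union of proteins, fills absent entries with zero,
#' and drops decoy accessions (reversed-database hits).  The number of decoy
#' rows dropped is stored in the `"n_decoys_dropped"` attribute.
#'
#' @param tables named list (names = experiment ids) of named integer vectors
#'   (names = protein accessions), or a long data.frame with columns
#'   `experiment_id`, `protein`, `count`.
#' @param meta experiment metadata; its experiment ids must exactly match the
#'   table names.
#' @param decoy_prefix accession prefix marking reversed-database hits
#'   (default `"REV_"`).
#' @return A [count_matrix()].
#' @export
assemble_count_matrix <- function(tables, meta, decoy_prefix = "REV_") {
  validate_experiment_meta(meta)
  if (is.data.frame(tables)) {
    required <- c("experiment_id", "protein", "count")
    if (!all(required %in% names(tables))) {
      stop("long table needs columns: ", paste(required, collapse = ", "))
    }
    tables <- split(
      stats::setNames(as.integer(tables$count), tables$protein),
      tables$experiment_id
    )
  }
  unknown <- setdiff(names(tables), meta$experiment_id)
  if (length(unknown) > 0) {
    stop("experiment_id not in metadata: ", paste(unknown, collapse = ", "))
  }
  absent <- setdiff(meta$experiment_id, names(tables))
  if (length(absent) > 0) {
    stop("metadata experiment(s) without a count table: ",
         paste(absent, collapse = ", "))
  }
  for (id in names(tables)) {
    tab <- tables[[id]]
    if (length(tab) > 0 && (is.null(names(tab)) || any(!nzchar(names(tab))))) {
      stop("count table for ", id, " has unnamed entries")
    }
    if (any(tab < 0)) stop("negative count in experiment ", id)
    if (anyDuplicated(names(tab))) {
      tables[[id]] <- tapply(tab, names(tab), sum)  # collapse duplicates
    }
  }
  proteins <- sort(unique(unlist(lapply(tables, names), use.names = FALSE)))
  is_decoy <- startsWith(proteins, decoy_prefix)
  n_decoys <- sum(is_decoy)
  proteins <- proteins[!is_decoy]
  counts <- matrix(0L, nrow = length(proteins), ncol = nrow(meta),
                   dimnames = list(proteins, meta$experiment_id))
  for (id in names(tables)) {
    tab <- tables[[id]]
    keep <- names(tab) %in% proteins
    counts[names(tab)[keep], id] <- as.integer(tab[keep])
  }
  counts <- counts[rowSums(counts) > 0L, , drop = FALSE]
  out <- count_matrix(counts, meta)
  attr(out, "n_decoys_dropped") <- n_decoys
  out
}

#' Pre-filter census of proteins and bait-prey interactions
#'
#' Counts the distinct identified proteins (matrix rows) and the distinct
#' (bait, prey) interactions: a prey counts as identified for a bait when it
#' has a nonzero spectral count in at least one of that bait's experiments
#' (either condition, any replicate).  Control experiments never contribute
#' interactions.  Bait self-identifications are retained here; self-loops are
#' only removed at the lean-network stage.
#'
#' @param x a [count_matrix()].
#' @return A list with `n_proteins` and `n_interactions`.
#' @export
census <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  meta <- x$meta
  bait_meta <- meta[meta$role == "bait_experiment", , drop = FALSE]
  n_inter <- 0L
  for (b in unique(bait_meta$bait)) {
    cols <- bait_meta$experiment_id[bait_meta$bait == b]
    sub <- x$counts[, cols, drop = FALSE]
    n_inter <- n_inter + sum(rowSums(sub) > 0L)
  }
  list(n_proteins = nrow(x$counts), n_interactions = n_inter)
}

#' Subset a count matrix to a protein set
#'
#' @param x a [count_matrix()].
#' @param proteins accessions to keep (order preserved from `x`).
#' @return A `count_matrix` restricted to those rows.
#' @keywords internal
subset_proteins <- function(x, proteins) {
  stopifnot(inherits(x, "count_matrix"))
  keep <- rownames(x$counts) %in% proteins
  structure(list(counts = x$counts[keep, , drop = FALSE], meta = x$meta),
            class = "count_matrix")
}
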