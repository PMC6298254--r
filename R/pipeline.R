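#' Pipeline configuration
#'
#' Collects the switches and thresholds of the end-to-end run: the one-hit
#' grouping mode, the lean-network order-of-operations and degree options,
#' and the weak/strong boundaries on summed spectral counts.
#'
#' @param one_hit_mode `"per_condition"` (default) or `"pooled"`; see
#'   [drop_one_hit_wonders()].
#' @param lean_order `"selfloop_before_degree"` (default) or
#'   `"degree_before_selfloop"`; see [build_lean()].
#' @param degree_scope `"strong"` (default) or `"extensive"`.
#' @param degree_threshold minimal prey degree in the lean network
#'   (default 3).
#' @param weak_value,strong_min summed-count boundaries: weak is exactly
#'   `weak_value` (default 2), strong is `>= strong_min` (default 3;
#'   must equal `weak_value + 1`).
#' @param decoy_prefix accession prefix of reversed-database hits.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(one_hit_mode = "per_condition",
                            lean_order = "selfloop_before_degree",
                            degree_scope = "strong",
                            degree_threshold = 3L,
                            weak_value = 2L,
                            strong_min = 3L,
                            decoy_prefix = "REV_") {
  if (degree_threshold < 1L) stop("degree_threshold must be >= 1")
  if (weak_value < 1L || strong_min != weak_value + 1L) {
    stop("strong_min must equal weak_value + 1 and weak_value must be >= 1")
  }
  structure(list(one_hit_mode = one_hit_mode, lean_order = lean_order,
                 degree_scope = degree_scope,
                 degree_threshold = as.integer(degree_threshold),
                 weak_value = as.integer(weak_value),
                 strong_min = as.integer(strong_min),
                 decoy_prefix = decoy_prefix),
            class = "pipeline_config")
}

#' Run the full filtering and network-construction pipeline
#'
#' Executes, in order: pre-filter census, control-based background removal,
#' replicate summation with strength classes, one-hit-wonder removal,
#' extensive-network construction, TNF dynamics classification, reference
#' annotation, and lean-network derivation.  Optionally writes every
#' intermediate table plus a machine-readable JSON report of the checkpoint
#' counts.
#'
#' @param x a [count_matrix()].
#' @param reference a [reference_set()]; defaults to an empty set (all
#'   edges novel, no rescue).
#' @param config a [pipeline_config()].
#' @param out_dir output directory for intermediate tables and the report;
#'   `NULL` (default) writes nothing.
#' @return A list with the stage outputs (`census`, `post_control`,
#'   `candidates`, `extensive`, `lean`) and `report`, the checkpoint counts.
#' @export
run_pipeline <- function(x, reference = reference_set(data.frame()),
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(x, "count_matrix"), inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  pre <- stage("census", census(x))
  filtered <- stage("control_filter", control_filter(x))
  post_control_census <- stage("census", census(filtered))
  cands <- stage("sum_replicates",
                 sum_replicates(filtered, weak_value = config$weak_value,
                                strong_min = config$strong_min))
  cands <- stage("drop_one_hit_wonders",
                 drop_one_hit_wonders(cands, mode = config$one_hit_mode))
  baits <- unique(x$meta$bait[x$meta$role == "bait_experiment"])
  extensive <- stage("build_extensive", build_extensive(cands, baits = baits))
  extensive <- stage("classify_dynamics", classify_dynamics(extensive))
  extensive <- stage("annotate_known", annotate_known(extensive, reference))
  lean <- stage("build_lean",
                build_lean(extensive,
                           degree_threshold = config$degree_threshold,
                           order = config$lean_order,
                           degree_scope = config$degree_scope))
  lean_report <- attr(lean, "lean_report")
  ext_sum <- network_summary(extensive)
  lean_sum <- network_summary(lean)
  report <- list(
    pre_filter = list(n_proteins = pre$n_proteins,
                      n_interactions = pre$n_interactions),
    post_control = list(
      n_proteins = post_control_census$n_proteins,
      n_interactions = post_control_census$n_interactions,
      n_background_removed = length(attr(filtered, "removed_proteins"))
    ),
    extensive = ext_sum,
    lean = c(lean_sum, lean_report)
  )
  out <- list(census = pre, post_control = filtered, candidates = cands,
              extensive = extensive, lean = lean, report = report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_candidates(cands, file.path(out_dir, "candidates.tsv"))
    export_network(extensive, file.path(out_dir, "extensive_edges.tsv"),
                   "edge_table")
    export_network(extensive, file.path(out_dir, "extensive_nodes.tsv"),
                   "node_table")
    if (nrow(lean$edges) > 0) {
      export_network(lean, file.path(out_dir, "lean_edges.tsv"), "edge_table")
      export_network(lean, file.path(out_dir, "lean_nodes.tsv"), "node_table")
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
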