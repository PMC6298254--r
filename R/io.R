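#' Read a wide spectral-count table with experiment metadata
#'
#' The canonical input dialect: a TSV whose first column holds protein
#' accessions and whose remaining columns are experiment ids, paired with a
#' metadata TSV (columns `experiment_id`, `bait`, `condition`, `replicate`,
#' `role`).  This mirrors deposited "spectral counts" + "experiment
#' overview" tables, which can be ingested after mapping their column names
#' onto this dialect.
#'
#' @param counts_path wide counts TSV.
#' @param meta_path metadata TSV.
#' @param decoy_prefix decoy accessions (dropped with a count recorded in
#'   the `"n_decoys_dropped"` attribute).
#' @return A [count_matrix()].
#' @export
read_counts_wide <- function(counts_path, meta_path, decoy_prefix = "REV_") {
  raw <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta <- read_experiment_meta(meta_path)
  proteins <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(mat) <- "integer"
  mat[is.na(mat)] <- 0L
  rownames(mat) <- proteins
  is_decoy <- startsWith(proteins, decoy_prefix)
  mat <- mat[!is_decoy, , drop = FALSE]
  mat <- mat[rowSums(mat) > 0L, , drop = FALSE]
  out <- count_matrix(mat, meta)
  attr(out, "n_decoys_dropped") <- sum(is_decoy)
  out
}

#' Read a long spectral-count table
#'
#' @param counts_path TSV with columns `experiment_id`, `protein`, `count`.
#' @param meta_path metadata TSV.
#' @param decoy_prefix decoy accession prefix.
#' @return A [count_matrix()].
#' @export
read_counts_long <- function(counts_path, meta_path, decoy_prefix = "REV_") {
  long <- utils::read.delim(counts_path, stringsAsFactors = FALSE)
  meta <- read_experiment_meta(meta_path)
  assemble_count_matrix(long, meta, decoy_prefix = decoy_prefix)
}

#' Read experiment metadata from TSV
#'
#' @param path metadata TSV (experiment_id, bait, condition, replicate,
#'   role).
#' @return A validated metadata data.frame.
#' @export
read_experiment_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_experiment_meta(meta)
  meta
}

#' Write a count matrix (wide TSV) and its metadata
#'
#' @param x a [count_matrix()].
#' @param counts_path,meta_path output files.
#' @export
write_counts_wide <- function(x, counts_path, meta_path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(protein = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

#' Read a two-column reference-pair TSV
#'
#' @param path TSV whose first two columns are the interactor accessions
#'   (header required, names free).
#' @param version_label provenance label stored on the set.
#' @return A [reference_set()].
#' @export
read_reference_tsv <- function(path, version_label = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("reference TSV needs at least two columns")
  reference_set(df[, 1:2], version_label = version_label)
}

#' Read a BioGRID tab-delimited subset as a reference set
#'
#' @param path BioGRID-style tab-delimited file.
#' @param col_a,col_b column names holding the two interactor identifiers
#'   (defaults match the BioGRID tab2 official-symbol columns).
#' @param version_label provenance label.
#' @return A [reference_set()].
#' @export
read_biogrid <- function(path,
                         col_a = "Official.Symbol.Interactor.A",
                         col_b = "Official.Symbol.Interactor.B",
                         version_label = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c(col_a, col_b) %in% names(df))) {
    stop("BioGRID columns not found: ", col_a, ", ", col_b,
         " (available: ", paste(names(df), collapse = ", "), ")")
  }
  reference_set(df[, c(col_a, col_b)], version_label = version_label)
}

#' Write a reference set as a two-column TSV
#'
#' @param reference a [reference_set()].
#' @param path output file.
#' @export
write_reference_tsv <- function(reference, path) {
  stopifnot(inherits(reference, "reference_set"))
  parts <- strsplit(reference$keys, "\r", fixed = TRUE)
  df <- data.frame(interactor_a = vapply(parts, `[`, "", 1),
                   interactor_b = vapply(parts, `[`, "", 2),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network
#'
#' Writes an [interaction_network()] in one of: `"SIF"` (simple interaction
#' format, topology only — documented as lossy), `"GraphML"` (all node and
#' edge attributes, typed), `"MITAB25"` (PSI-MITAB 2.5, 15 tab-separated
#' columns; strengths, dynamics and known flags are packed into the
#' confidence column so the matching reader can restore them), or
#' `"node_table"`/`"edge_table"` (TSV mirrors of the attribute frames).
#'
#' @param network an [interaction_network()].
#' @param path output file.
#' @param format one of `"SIF"`, `"GraphML"`, `"MITAB25"`, `"node_table"`,
#'   `"edge_table"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path,
                           format = c("SIF", "GraphML", "MITAB25",
                                      "node_table", "edge_table")) {
  stopifnot(inherits(network, "interaction_network"))
  format <- match.arg(format)
  switch(format,
    SIF = write_sif(network, path),
    GraphML = write_network_graphml(network, path),
    MITAB25 = write_mitab25(network, path),
    node_table = {
      utils::write.table(network$nodes, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      invisible(path)
    },
    edge_table = {
      utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      invisible(path)
    }
  )
}

write_sif <- function(network, path) {
  if (nrow(network$edges) == 0) stop("refusing to write an empty SIF file")
  lines <- paste(network$edges$bait, "interacts-with", network$edges$prey)
  writeLines(lines, path)
  invisible(path)
}

#' Read a node table + edge table pair back into a network
#'
#' @param node_path,edge_path TSV files written by [export_network()] with
#'   formats `"node_table"` and `"edge_table"`.
#' @return An [interaction_network()].
#' @export
read_network_tables <- function(node_path, edge_path) {
  nodes <- utils::read.delim(node_path, stringsAsFactors = FALSE)
  edges <- utils::read.delim(edge_path, stringsAsFactors = FALSE)
  interaction_network(nodes, edges)
}

# --- GraphML (igraph-backed) -------------------------------------------

#' Convert an interaction network to an igraph graph
#'
#' All node columns (except `id`) become vertex attributes and all edge
#' columns (except the endpoints) become edge attributes.
#'
#' @param network an [interaction_network()].
#' @return A directed `igraph` graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  igraph::graph_from_data_frame(
    d = network$edges[, c("bait", "prey",
                          setdiff(names(network$edges), c("bait", "prey"))),
                      drop = FALSE],
    directed = TRUE,
    vertices = network$nodes
  )
}

#' Convert an igraph graph back to an interaction network
#'
#' @param g a directed igraph graph carrying the attributes produced by
#'   [as_igraph()].
#' @return An [interaction_network()].
#' @export
from_igraph <- function(g) {
  nodes <- igraph::as_data_frame(g, what = "vertices")
  nodes$id <- NULL  # GraphML readers surface the raw n0/n1/... node ids here
  names(nodes)[names(nodes) == "name"] <- "id"
  edges <- igraph::as_data_frame(g, what = "edges")
  names(edges)[names(edges) == "from"] <- "bait"
  names(edges)[names(edges) == "to"] <- "prey"
  nodes$is_bait <- as.logical(nodes$is_bait)
  for (col in intersect(c("present_untreated", "present_TNF", "known"),
                        names(edges))) {
    edges[[col]] <- as.logical(edges[[col]])
  }
  rownames(nodes) <- NULL
  interaction_network(nodes, edges)
}

write_network_graphml <- function(network, path) {
  if (nrow(network$nodes) == 0) {
    stop("refusing to write an empty GraphML file")
  }
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Read a GraphML network export
#'
#' @param path GraphML file written by [export_network()].
#' @return An [interaction_network()].
#' @export
read_network_graphml <- function(path) {
  from_igraph(igraph::read_graph(path, format = "graphml"))
}

# --- PSI-MITAB 2.5 ------------------------------------------------------

mitab25_columns <- c(
  "ID(s) interactor A", "ID(s) interactor B",
  "Alt. ID(s) interactor A", "Alt. ID(s) interactor B",
  "Alias(es) interactor A", "Alias(es) interactor B",
  "Interaction detection method(s)", "Publication 1st author(s)",
  "Publication Identifier(s)", "Taxid interactor A", "Taxid interactor B",
  "Interaction type(s)", "Source database(s)",
  "Interaction identifier(s)", "Confidence value(s)"
)

write_mitab25 <- function(network, path) {
  e <- network$edges
  conf <- sprintf("spectral-strength-untreated:%s|spectral-strength-TNF:%s",
                  e$strength_untreated, e$strength_TNF)
  if ("dynamics" %in% names(e)) {
    conf <- paste0(conf, "|dynamics:", e$dynamics)
  }
  if ("known" %in% names(e)) {
    conf <- paste0(conf, "|known:", tolower(as.character(e$known)))
  }
  rows <- data.frame(
    a = paste0("local:", e$bait),
    b = paste0("local:", e$prey),
    alt_a = "-", alt_b = "-", alias_a = "-", alias_b = "-",
    method = "psi-mi:\"MI:0004\"(affinity chromatography technology)",
    author = "-", pub = "-", tax_a = "-", tax_b = "-",
    type = "psi-mi:\"MI:0914\"(association)",
    source = "local:baitprey",
    interaction_id = paste0("local:", seq_len(nrow(e))),
    confidence = conf,
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(mitab25_columns, collapse = "\t")), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a PSI-MITAB 2.5 export back into a network
#'
#' Restores the edges (with strengths, dynamics and known flags from the
#' confidence column) and infers nodes; bait status is inferred from edge
#' sources.
#'
#' @param path MITAB 2.5 file written by [export_network()].
#' @return An [interaction_network()].
#' @export
read_mitab25 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 15L)
  if (length(bad) > 0) stop("MITAB line(s) without 15 columns: ",
                            paste(utils::head(bad, 5), collapse = ", "))
  strip_ns <- function(x) sub("^[^:]*:", "", x)
  conf_get <- function(conf, key) {
    m <- regmatches(conf, regexec(paste0("(?:^|\\|)", key, ":([^|]*)"), conf))
    vapply(m, function(v) if (length(v) == 2) v[2] else NA_character_, "")
  }
  a <- strip_ns(vapply(fields, `[`, "", 1))
  b <- strip_ns(vapply(fields, `[`, "", 2))
  conf <- vapply(fields, `[`, "", 15)
  edges <- data.frame(
    bait = a, prey = b,
    strength_untreated = conf_get(conf, "spectral-strength-untreated"),
    strength_TNF = conf_get(conf, "spectral-strength-TNF"),
    stringsAsFactors = FALSE
  )
  edges$present_untreated <- edges$strength_untreated != "absent"
  edges$present_TNF <- edges$strength_TNF != "absent"
  dyn <- conf_get(conf, "dynamics")
  if (!anyNA(dyn)) edges$dynamics <- dyn
  kn <- conf_get(conf, "known")
  if (!anyNA(kn)) edges$known <- kn == "true"
  ids <- unique(c(edges$bait, edges$prey))
  nodes <- data.frame(id = ids, is_bait = ids %in% edges$bait,
                      stringsAsFactors = FALSE)
  interaction_network(nodes, edges)
}
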