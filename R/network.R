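#' Reference interaction set
#'
#' A set of known interactions as unordered protein pairs (BioGRID-style),
#' used for known/novel annotation of edges and for rescuing preys during
#' lean-network construction.
#'
#' @param pairs data.frame with two character columns (any names) giving the
#'   two interactors of each pair.
#' @param version_label free-text provenance label.
#' @return An object of class `reference_set` with a canonical unordered-pair
#'   key set.
#' @export
reference_set <- function(pairs, version_label = "") {
  if (nrow(pairs) > 0) {
    a <- as.character(pairs[[1]]); b <- as.character(pairs[[2]])
  } else {
    a <- character(0); b <- character(0)
  }
  keys <- unique(pair_key(a, b))
  structure(list(keys = keys, version_label = version_label),
            class = "reference_set")
}

# canonical unordered key: sorted endpoints
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: %d unordered pairs%s\n", length(x$keys),
              if (nzchar(x$version_label)) paste0(" [", x$version_label, "]")
              else ""))
  invisible(x)
}

#' Membership test for unordered pairs
#'
#' @param reference a [reference_set()].
#' @param a,b endpoint accessions (vectorised).
#' @return Logical vector: is the unordered pair (a, b) in the set?
#' @export
reference_contains <- function(reference, a, b) {
  stopifnot(inherits(reference, "reference_set"))
  pair_key(as.character(a), as.character(b)) %in% reference$keys
}

#' Directed bait-prey interaction network
#'
#' @param nodes data.frame with columns `id`, `is_bait` and optionally
#'   `node_class`.
#' @param edges data.frame with columns `bait`, `prey`,
#'   `strength_untreated`, `strength_TNF` (each `absent`/`one_hit`/`weak`/
#'   `strong`), `present_untreated`, `present_TNF`, and optionally
#'   `dynamics`, `known`.
#' @return An object of class `interaction_network`.
#' @export
interaction_network <- function(nodes, edges) {
  if (!"node_class" %in% names(nodes)) {
    nodes$node_class <- rep("unannotated", nrow(nodes))
  }
  strengths <- c("absent", "one_hit", "weak", "strong")
  stopifnot(all(edges$strength_untreated %in% strengths),
            all(edges$strength_TNF %in% strengths))
  if (nrow(edges) > 0) {
    if (!all(edges$present_untreated == (edges$strength_untreated != "absent")) ||
        !all(edges$present_TNF == (edges$strength_TNF != "absent"))) {
      stop("edge presence flags inconsistent with strengths")
    }
    if (any(!edges$present_untreated & !edges$present_TNF)) {
      stop("edge absent in both conditions")
    }
    if (!all(edges$bait %in% nodes$id[nodes$is_bait])) {
      stop("every edge source must be a bait node")
    }
    if (!all(edges$prey %in% nodes$id)) stop("edge prey missing from nodes")
  }
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d nodes (%d baits), %d edges\n",
              nrow(x$nodes), sum(x$nodes$is_bait), nrow(x$edges)))
  if ("dynamics" %in% names(x$edges) && nrow(x$edges) > 0) {
    tab <- table(x$edges$dynamics)
    cat("  dynamics:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Build the extensive network from filtered candidates
#'
#' Merges per-condition candidate rows into one directed edge per (bait,
#' prey) pair carrying both conditions' strengths.  Node set is the union of
#' baits and preys; a bait identified as prey of another bait remains a
#' single node with `is_bait = TRUE`.
#'
#' @param candidates post-cascade candidate data.frame (see
#'   [filter_cascade()]).
#' @param baits optional character vector declaring the full bait panel;
#'   defaults to the baits occurring in `candidates`.  A candidate whose
#'   bait is not in this panel is an error.
#' @return An [interaction_network()].
#' @export
build_extensive <- function(candidates, baits = NULL) {
  if (is.null(baits)) baits <- unique(candidates$bait)
  unknown <- setdiff(unique(candidates$bait), baits)
  if (length(unknown) > 0) {
    stop("candidate bait(s) not in the declared panel: ",
         paste(unknown, collapse = ", "))
  }
  if (nrow(candidates) == 0) {
    nodes <- data.frame(id = character(0), is_bait = logical(0),
                        stringsAsFactors = FALSE)
    edges <- data.frame(bait = character(0), prey = character(0),
                        strength_untreated = character(0),
                        strength_TNF = character(0),
                        present_untreated = logical(0),
                        present_TNF = logical(0), stringsAsFactors = FALSE)
    return(interaction_network(nodes, edges))
  }
  key <- paste(candidates$bait, candidates$prey, sep = "\r")
  pairs <- candidates[!duplicated(key), c("bait", "prey"), drop = FALSE]
  pick <- function(cond) {
    idx <- match(paste(pairs$bait, pairs$prey, cond, sep = "\r"),
                 paste(candidates$bait, candidates$prey,
                       candidates$condition, sep = "\r"))
    s <- candidates$strength[idx]
    s[is.na(s)] <- "absent"
    s
  }
  edges <- data.frame(
    bait = pairs$bait, prey = pairs$prey,
    strength_untreated = pick("untreated"),
    strength_TNF = pick("TNF"),
    stringsAsFactors = FALSE
  )
  edges$present_untreated <- edges$strength_untreated != "absent"
  edges$present_TNF <- edges$strength_TNF != "absent"
  node_ids <- union(intersect(baits, c(candidates$bait, candidates$prey)),
                    unique(c(edges$bait, edges$prey)))
  nodes <- data.frame(id = node_ids, is_bait = node_ids %in% baits,
                      stringsAsFactors = FALSE)
  interaction_network(nodes, edges)
}

#' Classify edge dynamics under TNF treatment
#'
#' Labels every edge by its presence pattern across the two conditions:
#' `appears` (TNF only), `disappears` (untreated only) or `independent`
#' (present in both).  The three labels partition all edges.
#'
#' @param network an [interaction_network()] from [build_extensive()].
#' @return The network with an edge column `dynamics`.
#' @export
classify_dynamics <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  e <- network$edges
  e$dynamics <- ifelse(e$present_TNF & !e$present_untreated, "appears",
                ifelse(e$present_untreated & !e$present_TNF, "disappears",
                       "independent"))
  network$edges <- e
  network
}

#' Annotate edges against a reference interaction set
#'
#' Marks each edge `known` when its unordered (bait, prey) pair is in the
#' reference set; the overlap counts are stored in the `"overlap"` attribute
#' (`n_known`, `n_novel`).
#'
#' @param network an [interaction_network()].
#' @param reference a [reference_set()].
#' @return The network with an edge column `known`.
#' @export
annotate_known <- function(network, reference) {
  stopifnot(inherits(network, "interaction_network"))
  e <- network$edges
  e$known <- if (nrow(e) > 0) {
    reference_contains(reference, e$bait, e$prey)
  } else logical(0)
  network$edges <- e
  attr(network, "overlap") <- list(n_known = sum(e$known),
                                   n_novel = sum(!e$known))
  network
}

edge_is_strong <- function(edges) {
  edges$strength_untreated == "strong" | edges$strength_TNF == "strong"
}

#' Derive the lean network
#'
#' Produces the visualization-grade subgraph of the extensive network by
#' applying, in order: (1) keep only edges that are strong in at least one
#' condition; (2) remove self-loops (bait interacting with itself); (3)
#' compute each non-bait node's degree in the resulting strong graph; (4)
#' retain a non-bait prey iff its degree reaches `degree_threshold` OR it
#' has at least one known (reference) edge — the latter is the rescue that
#' prevents known partners from being filtered out; bait nodes are exempt
#' from the degree filter and retained whenever they keep an edge.
#'
#' With `order = "degree_before_selfloop"` the degrees are computed before
#' self-loop removal (reproduction switch; the published node/edge totals
#' may depend on this choice).  With `degree_scope = "extensive"` degrees
#' are counted in the full extensive network instead of the strong subgraph.
#'
#' The result carries a `"lean_report"` attribute with the counts of rescued
#' nodes and edges (nodes retained only through the reference rescue, and
#' their edges) and of removed self-loops (total and known).
#'
#' @param network an [interaction_network()] with `dynamics` and `known`
#'   computed.
#' @param degree_threshold minimal degree for a non-bait prey (default 3).
#' @param order `"selfloop_before_degree"` (default) or
#'   `"degree_before_selfloop"`.
#' @param degree_scope `"strong"` (default) or `"extensive"`.
#' @return The lean [interaction_network()].
#' @export
build_lean <- function(network, degree_threshold = 3L,
                       order = c("selfloop_before_degree",
                                 "degree_before_selfloop"),
                       degree_scope = c("strong", "extensive")) {
  stopifnot(inherits(network, "interaction_network"))
  order <- match.arg(order)
  degree_scope <- match.arg(degree_scope)
  e <- network$edges
  if (!"dynamics" %in% names(e)) {
    stop("dynamics must be classified before building the lean network")
  }
  if (!"known" %in% names(e)) {
    stop("edges must be annotated against a reference before building the ",
         "lean network")
  }
  nodes <- network$nodes

  strong <- e[edge_is_strong(e), , drop = FALSE]
  self_loop <- strong$bait == strong$prey
  n_self_loops <- sum(self_loop)
  n_known_self_loops <- sum(self_loop & strong$known)
  no_self <- strong[!self_loop, , drop = FALSE]

  degree_edges <- switch(degree_scope, strong = strong, extensive = e)
  if (order == "selfloop_before_degree") {
    degree_edges <- degree_edges[degree_edges$bait != degree_edges$prey, ,
                                 drop = FALSE]
  }
  deg <- node_degrees(degree_edges, nodes$id)

  is_bait <- stats::setNames(nodes$is_bait, nodes$id)
  known_preys <- unique(no_self$prey[no_self$known])
  keep_node <- vapply(nodes$id, function(id) {
    if (is_bait[[id]]) return(TRUE)
    if (deg[[id]] >= degree_threshold) return(TRUE)
    id %in% known_preys
  }, logical(1))
  rescued_ids <- nodes$id[keep_node & !nodes$is_bait &
                            deg[nodes$id] < degree_threshold]

  keep_edge <- no_self$bait %in% nodes$id[keep_node] &
    no_self$prey %in% nodes$id[keep_node]
  lean_edges <- no_self[keep_edge, , drop = FALSE]
  n_rescued_edges <- sum(lean_edges$prey %in% rescued_ids)

  lean_ids <- unique(c(lean_edges$bait, lean_edges$prey))
  lean_nodes <- nodes[nodes$id %in% lean_ids, , drop = FALSE]
  out <- interaction_network(lean_nodes, lean_edges)
  attr(out, "lean_report") <- list(
    n_rescued_nodes = sum(rescued_ids %in% lean_ids),
    n_rescued_edges = n_rescued_edges,
    n_self_loops_removed = n_self_loops,
    n_known_self_loops_removed = n_known_self_loops
  )
  out
}

# undirected degree per node over a directed edge list (self-loops, when
# present, contribute 1; parallel (bait, prey) duplicates cannot occur)
node_degrees <- function(edges, ids) {
  ends <- c(edges$bait, edges$prey)
  if (nrow(edges) > 0) {
    loops <- edges$bait == edges$prey
    if (any(loops)) ends <- c(edges$bait[!loops], edges$prey[!loops],
                              edges$bait[loops])
  }
  tab <- table(factor(ends, levels = ids))
  stats::setNames(as.integer(tab), ids)
}

#' Summarise a network's composition
#'
#' @param network an [interaction_network()].
#' @return A list of counts: nodes, baits, edges, and (when computed) the
#'   dynamics breakdown and known/novel split.
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  e <- network$edges
  out <- list(n_nodes = nrow(network$nodes),
              n_baits = sum(network$nodes$is_bait),
              n_edges = nrow(e))
  if ("dynamics" %in% names(e)) {
    out$dynamics <- c(
      independent = sum(e$dynamics == "independent"),
      appears = sum(e$dynamics == "appears"),
      disappears = sum(e$dynamics == "disappears")
    )
  }
  if ("known" %in% names(e)) {
    out$n_known <- sum(e$known)
    out$n_novel <- sum(!e$known)
  }
  out
}
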