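# Independent brute-force oracles and small random-input generators.
# These re-derive expected results by exhaustive set operations and explicit
# loops, deliberately sharing no code with the package internals.

# -- filter cascade oracle ----------------------------------------------

# Exhaustive reimplementation of the cascade by set operations:
# returns data.frame(bait, prey, condition, summed_count, strength).
oracle_cascade <- function(x, mode = "per_condition") {
  counts <- x$counts
  meta <- x$meta
  ctrl_cols <- meta$experiment_id[meta$role == "control_experiment"]
  background <- character(0)
  for (p in rownames(counts)) {
    for (cc in ctrl_cols) if (counts[p, cc] > 0) background <- c(background, p)
  }
  kept <- setdiff(rownames(counts), background)
  rows <- list()
  bait_meta <- meta[meta$role == "bait_experiment", ]
  for (b in unique(bait_meta$bait)) {
    for (cond in unique(bait_meta$condition[bait_meta$bait == b])) {
      cols <- bait_meta$experiment_id[bait_meta$bait == b &
                                        bait_meta$condition == cond]
      for (p in kept) {
        s <- 0
        for (cc in cols) s <- s + counts[p, cc]
        if (s > 0) {
          rows[[length(rows) + 1]] <- data.frame(
            bait = b, prey = p, condition = cond, summed_count = s,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  cand <- do.call(rbind, rows)
  if (is.null(cand)) {
    return(data.frame(bait = character(0), prey = character(0),
                      condition = character(0), summed_count = integer(0),
                      strength = character(0), stringsAsFactors = FALSE))
  }
  keep_pair <- rep(FALSE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    same <- cand$bait == cand$bait[i] & cand$prey == cand$prey[i]
    support <- if (mode == "per_condition") max(cand$summed_count[same])
               else sum(cand$summed_count[same])
    keep_pair[i] <- support >= 2
  }
  cand <- cand[keep_pair, , drop = FALSE]
  cand$strength <- as.character(
    ifelse(cand$summed_count >= 3, "strong",
           ifelse(cand$summed_count == 2, "weak", "one_hit")))
  cand$summed_count <- as.integer(cand$summed_count)
  rownames(cand) <- NULL
  cand
}

# canonical sort for comparing candidate tables
sort_candidates <- function(df) {
  df <- df[order(df$bait, df$prey, df$condition), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# -- lean network oracle ------------------------------------------------

# Exhaustive application of the lean rules on an annotated extensive
# network: strong filter, self-loop removal, per-node degree, degree-or-known
# retention for non-bait preys.
oracle_lean <- function(network, degree_threshold = 3,
                        order = "selfloop_before_degree",
                        degree_scope = "strong") {
  e <- network$edges
  nodes <- network$nodes
  strong <- e[e$strength_untreated == "strong" |
                e$strength_TNF == "strong", , drop = FALSE]
  no_self <- strong[strong$bait != strong$prey, , drop = FALSE]
  deg_edges <- if (degree_scope == "strong") strong else e
  if (order == "selfloop_before_degree") {
    deg_edges <- deg_edges[deg_edges$bait != deg_edges$prey, , drop = FALSE]
  }
  deg <- sapply(nodes$id, function(id) {
    d <- 0
    for (i in seq_len(nrow(deg_edges))) {
      if (deg_edges$bait[i] == id) d <- d + 1
      if (deg_edges$prey[i] == id && deg_edges$bait[i] != id) d <- d + 1
    }
    d
  })
  retained <- character(0)
  for (i in seq_len(nrow(nodes))) {
    id <- nodes$id[i]
    if (nodes$is_bait[i]) { retained <- c(retained, id); next }
    has_known <- any(no_self$prey == id & no_self$known)
    if (deg[[id]] >= degree_threshold || has_known) retained <- c(retained, id)
  }
  keep <- no_self$bait %in% retained & no_self$prey %in% retained
  lean_edges <- no_self[keep, , drop = FALSE]
  ids <- unique(c(lean_edges$bait, lean_edges$prey))
  list(edges = sort_edges(lean_edges), node_ids = sort(ids))
}

sort_edges <- function(e) {
  e <- e[order(e$bait, e$prey), , drop = FALSE]
  rownames(e) <- NULL
  e
}

# -- random input generators --------------------------------------------

# small random count matrix with controls, for grid/property tests
random_small_matrix <- function(seed, max_proteins = 6, max_experiments = 8) {
  set.seed(seed)
  n_prot <- sample(1:max_proteins, 1)
  n_ctrl <- sample(1:2, 1)
  n_baits <- sample(1:2, 1)
  n_rep <- sample(1:2, 1)
  meta <- list()
  for (b in seq_len(n_baits)) {
    for (cond in c("untreated", "TNF")) {
      for (r in seq_len(n_rep)) {
        meta[[length(meta) + 1]] <- data.frame(
          experiment_id = sprintf("B%d_%s_r%d", b, cond, r),
          bait = sprintf("B%d", b), condition = cond, replicate = r,
          role = "bait_experiment", stringsAsFactors = FALSE)
      }
    }
  }
  for (k in seq_len(n_ctrl)) {
    meta[[length(meta) + 1]] <- data.frame(
      experiment_id = sprintf("C%d_r1", k), bait = sprintf("C%d", k),
      condition = "not_applicable", replicate = 1L,
      role = "control_experiment", stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  if (nrow(meta) > max_experiments) meta <- meta[seq_len(max_experiments), ]
  # ensure at least one control survives truncation
  if (!any(meta$role == "control_experiment")) {
    meta$role[nrow(meta)] <- "control_experiment"
    meta$bait[nrow(meta)] <- "C1"
    meta$condition[nrow(meta)] <- "not_applicable"
  }
  counts <- matrix(rbinom(n_prot * nrow(meta), size = 4, prob = 0.35),
                   nrow = n_prot,
                   dimnames = list(sprintf("P%02d", seq_len(n_prot)),
                                   meta$experiment_id))
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  if (nrow(counts) == 0) return(NULL)
  count_matrix(counts, meta)
}

# random PSM table for FDR tests
random_psms <- function(seed, n_spectra = 20, max_matches = 3) {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_spectra)) {
    k <- sample(1:max_matches, 1)
    rows[[s]] <- data.frame(
      spectrum_id = sprintf("spec%03d", s),
      protein = sprintf("P%03d", sample(1:50, k, replace = TRUE)),
      peptide = replicate(k, paste(sample(LETTERS[1:20], 6, TRUE),
                                   collapse = "")),
      score = round(runif(k, 10, 60), 2),
      is_decoy = runif(k) < 0.3,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# per-spectrum max by explicit loop (decoy wins target-decoy ties)
oracle_best_psms <- function(psms) {
  out <- list()
  for (s in unique(psms$spectrum_id)) {
    sub <- psms[psms$spectrum_id == s, , drop = FALSE]
    best <- sub[sub$score == max(sub$score), , drop = FALSE]
    if (nrow(best) > 1 && any(best$is_decoy)) {
      best <- best[best$is_decoy, , drop = FALSE]
    }
    out[[s]] <- best[1, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# random annotated extensive network for lean-oracle tests
random_toy_network <- function(seed, max_nodes = 10) {
  set.seed(seed)
  n_baits <- sample(2:3, 1)
  n_preys <- sample(2:(max_nodes - n_baits), 1)
  baits <- sprintf("B%d", seq_len(n_baits))
  preys <- sprintf("Y%d", seq_len(n_preys))
  ids <- c(baits, preys)
  strengths <- c("absent", "one_hit", "weak", "strong")
  edges <- list()
  for (b in baits) {
    targets <- sample(ids, sample(1:min(5, length(ids)), 1))
    for (t in targets) {
      su <- sample(strengths, 1)
      st <- if (su == "absent") sample(strengths[-1], 1) else
        sample(strengths, 1)
      edges[[length(edges) + 1]] <- data.frame(
        bait = b, prey = t, strength_untreated = su, strength_TNF = st,
        stringsAsFactors = FALSE)
    }
  }
  e <- unique(do.call(rbind, edges))
  e <- e[!duplicated(e[, c("bait", "prey")]), , drop = FALSE]
  e$present_untreated <- e$strength_untreated != "absent"
  e$present_TNF <- e$strength_TNF != "absent"
  node_ids <- unique(c(baits, e$prey))
  nodes <- data.frame(id = node_ids, is_bait = node_ids %in% baits,
                      stringsAsFactors = FALSE)
  net <- interaction_network(nodes, e)
  net <- classify_dynamics(net)
  # random reference over possible pairs
  all_pairs <- e[, c("bait", "prey")]
  take <- runif(nrow(all_pairs)) < 0.4
  ref <- reference_set(all_pairs[take, , drop = FALSE])
  list(network = annotate_known(net, ref), reference = ref)
}
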