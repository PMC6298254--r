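edge_is_strong_for_test <- function(e) {
  e$strength_untreated == "strong" | e$strength_TNF == "strong"
}

toy_candidates <- function() {
  data.frame(
    bait = c("B1", "B1", "B2"),
    prey = c("P1", "P1", "P1"),
    condition = c("untreated", "TNF", "TNF"),
    summed_count = c(2L, 5L, 3L),
    strength = c("weak", "strong", "strong"),
    stringsAsFactors = FALSE
  )
}

test_that("extensive network merges per-condition candidates into one edge", {
  net <- build_extensive(toy_candidates())
  e <- net$edges[net$edges$bait == "B1", ]
  expect_equal(nrow(e), 1)
  expect_equal(e$strength_untreated, "weak")
  expect_equal(e$strength_TNF, "strong")
  e2 <- net$edges[net$edges$bait == "B2", ]
  expect_equal(e2$strength_untreated, "absent")
  expect_false(e2$present_untreated)

  empty <- build_extensive(toy_candidates()[0, ])
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(empty$nodes), 0)

  expect_error(build_extensive(toy_candidates(), baits = "B1"), "B2")
})

test_that("extensive edge count equals distinct surviving pairs on synthetic data", {
  d <- simulate_dataset(synthetic_config(seed = 41, n_baits = 5))
  res <- filter_cascade(d$matrix)
  net <- build_extensive(res$candidates)
  expect_equal(nrow(net$edges),
               length(unique(paste(res$candidates$bait,
                                   res$candidates$prey))))
  expect_true(all(net$edges$bait %in% net$nodes$id[net$nodes$is_bait]))
})

test_that("dynamics labels follow the presence pattern and partition edges", {
  net <- classify_dynamics(build_extensive(toy_candidates()))
  e <- net$edges
  expect_equal(e$dynamics[e$bait == "B2"], "appears")
  expect_equal(e$dynamics[e$bait == "B1"], "independent")

  d <- simulate_dataset(synthetic_config(seed = 42))
  res <- filter_cascade(d$matrix)
  dyn <- classify_dynamics(build_extensive(res$candidates))$edges$dynamics
  expect_true(all(dyn %in% c("appears", "disappears", "independent")))
})

test_that("reference annotation is order-blind on the pair", {
  net <- classify_dynamics(build_extensive(toy_candidates()))
  ref <- reference_set(data.frame(a = "P1", b = "B1"))  # swapped order
  ann <- annotate_known(net, ref)
  expect_true(ann$edges$known[ann$edges$bait == "B1"])
  expect_false(ann$edges$known[ann$edges$bait == "B2"])

  none <- annotate_known(net, reference_set(data.frame()))
  expect_false(any(none$edges$known))
  expect_equal(attr(none, "overlap")$n_novel, nrow(none$edges))
})

test_that("known-edge fraction among recovered planted pairs tracks coverage", {
  d <- simulate_dataset(synthetic_config(seed = 43, one_hit_rate = 0))
  ref <- simulate_reference_set(d$truth, coverage = 0.5, seed = 43)
  res <- filter_cascade(d$matrix)
  net <- annotate_known(classify_dynamics(build_extensive(res$candidates)),
                        ref)
  planted_keys <- paste(d$truth$planted$bait, d$truth$planted$prey)
  e <- net$edges[paste(net$edges$bait, net$edges$prey) %in% planted_keys, ]
  frac <- mean(e$known)
  expect_gt(frac, 0.35)
  expect_lt(frac, 0.65)
})

# a small worked lean example, checked by hand:
#   B1->Y1 strong, B1->Y2 strong, B2->Y1 strong, B3->Y1 strong,
#   B1->B1 strong self-loop, B2->Y3 weak, B3->Y4 strong (known)
# Y1 has degree 3 (kept), Y2 degree 1 (dropped), Y3 weak (dropped with edge),
# Y4 degree 1 but known (rescued).
lean_toy <- function() {
  e <- data.frame(
    bait = c("B1", "B1", "B2", "B3", "B1", "B2", "B3"),
    prey = c("Y1", "Y2", "Y1", "Y1", "B1", "Y3", "Y4"),
    strength_untreated = c("strong", "strong", "strong", "strong", "strong",
                           "weak", "absent"),
    strength_TNF = c("weak", "absent", "strong", "strong", "strong", "weak",
                     "strong"),
    stringsAsFactors = FALSE
  )
  e$present_untreated <- e$strength_untreated != "absent"
  e$present_TNF <- e$strength_TNF != "absent"
  ids <- unique(c(e$bait, e$prey))
  nodes <- data.frame(id = ids, is_bait = ids %in% c("B1", "B2", "B3"),
                      stringsAsFactors = FALSE)
  net <- classify_dynamics(interaction_network(nodes, e))
  annotate_known(net, reference_set(data.frame(a = c("B3", "B9"),
                                               b = c("Y4", "Y9"))))
}

test_that("the lean filter applies strong/self-loop/degree/rescue rules in order", {
  lean <- build_lean(lean_toy())
  keys <- paste(lean$edges$bait, lean$edges$prey)
  expect_setequal(keys, c("B1 Y1", "B2 Y1", "B3 Y1", "B3 Y4"))
  expect_setequal(lean$nodes$id, c("B1", "B2", "B3", "Y1", "Y4"))
  rep <- attr(lean, "lean_report")
  expect_equal(rep$n_rescued_nodes, 1)       # Y4, known partner of B3
  expect_equal(rep$n_rescued_edges, 1)
  expect_equal(rep$n_self_loops_removed, 1)  # B1 -> B1
  expect_equal(rep$n_known_self_loops_removed, 0)
})

test_that("lean construction requires dynamics and known annotations", {
  net <- build_extensive(toy_candidates())
  expect_error(build_lean(net), "dynamics")
  expect_error(build_lean(classify_dynamics(net)), "reference")
})

test_that("weak-only edges never reach the lean network", {
  lean <- build_lean(lean_toy())
  expect_false("Y3" %in% lean$nodes$id)
  expect_true(all(lean$edges$strength_untreated == "strong" |
                    lean$edges$strength_TNF == "strong"))
})

test_that("build_lean equals the exhaustive rule oracle on random toy graphs", {
  for (seed in 1:60) {
    toy <- random_toy_network(seed)
    for (ord in c("selfloop_before_degree", "degree_before_selfloop")) {
      lean <- build_lean(toy$network, order = ord)
      want <- oracle_lean(toy$network, order = ord)
      expect_equal(sort_edges(lean$edges), want$edges,
                   info = sprintf("seed %d order %s", seed, ord))
      expect_setequal(lean$nodes$id, want$node_ids)
    }
  }
})

test_that("with empty reference and threshold 1 the lean net is the strong non-self-loop subgraph", {
  for (seed in 61:75) {
    toy <- random_toy_network(seed)
    net <- annotate_known(toy$network, reference_set(data.frame()))
    lean <- build_lean(net, degree_threshold = 1)
    e <- net$edges
    want <- e[(e$strength_untreated == "strong" | e$strength_TNF == "strong") &
                e$bait != e$prey, , drop = FALSE]
    expect_equal(sort_edges(lean$edges[, names(want)]), sort_edges(want))
  }
})

test_that("the lean network is a subgraph of the extensive network and rescue stays inside the reference", {
  for (seed in 76:90) {
    toy <- random_toy_network(seed)
    lean <- build_lean(toy$network)
    ext_keys <- paste(toy$network$edges$bait, toy$network$edges$prey)
    expect_true(all(paste(lean$edges$bait, lean$edges$prey) %in% ext_keys))
    expect_true(all(lean$nodes$id %in% toy$network$nodes$id))
    # any prey kept with degree < 3 must be covered by a known (reference) edge
    rep <- attr(lean, "lean_report")
    if (rep$n_rescued_edges > 0) {
      strong <- toy$network$edges[edge_is_strong_for_test(toy$network$edges), ]
      deg <- table(c(strong$bait[strong$bait != strong$prey],
                     strong$prey[strong$bait != strong$prey]))
      low <- lean$nodes$id[!lean$nodes$is_bait &
                             sapply(lean$nodes$id, function(i)
                               sum(deg[names(deg) == i]) < 3)]
      for (id in low) {
        inc <- lean$edges[lean$edges$prey == id, ]
        expect_true(any(reference_contains(toy$reference, inc$bait, inc$prey)))
      }
    }
    # dynamics labels and known/novel split partition the lean edges
    s <- network_summary(lean)
    expect_equal(sum(s$dynamics), s$n_edges)
    expect_equal(s$n_known + s$n_novel, s$n_edges)
  }
})
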