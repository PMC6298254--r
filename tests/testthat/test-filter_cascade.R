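cascade_meta <- function(n_rep = 3) {
  rbind(
    expand.grid(replicate = seq_len(n_rep), condition = c("untreated", "TNF"),
                bait = "B1", stringsAsFactors = FALSE) |>
      (\(g) data.frame(experiment_id = sprintf("B1_%s_r%d", g$condition,
                                               g$replicate),
                       bait = g$bait, condition = g$condition,
                       replicate = g$replicate, role = "bait_experiment",
                       stringsAsFactors = FALSE))(),
    data.frame(experiment_id = "c1", bait = "CTRL1",
               condition = "not_applicable", replicate = 1L,
               role = "control_experiment", stringsAsFactors = FALSE)
  )
}

test_that("a single control identification removes a protein everywhere", {
  meta <- cascade_meta()
  counts <- rbind(P1 = c(50L, 50L, 50L, 50L, 50L, 50L, 1L),  # 1 in control
                  P2 = c(2L, 0L, 1L, 0L, 0L, 0L, 0L))
  colnames(counts) <- meta$experiment_id
  filtered <- control_filter(count_matrix(counts, meta))
  expect_identical(rownames(filtered$counts), "P2")
  expect_identical(attr(filtered, "removed_proteins"), "P1")
})

test_that("the control filter needs control columns", {
  meta <- cascade_meta()
  meta <- meta[meta$role == "bait_experiment", ]
  counts <- matrix(1L, 1, nrow(meta),
                   dimnames = list("P1", meta$experiment_id))
  expect_error(control_filter(count_matrix(counts, meta)), "control")
})

test_that("replicate sums define the strength classes", {
  meta <- cascade_meta()
  counts <- rbind(P1 = c(1L, 1L, 0L, 0L, 0L, 0L, 0L),   # untreated sum 2
                  P2 = c(0L, 0L, 0L, 2L, 1L, 1L, 0L),   # TNF sum 4
                  P3 = c(1L, 0L, 0L, 0L, 0L, 0L, 0L))   # untreated sum 1
  colnames(counts) <- meta$experiment_id
  cands <- sum_replicates(count_matrix(counts, meta))
  get <- function(p, cond) cands[cands$prey == p & cands$condition == cond, ]
  expect_equal(get("P1", "untreated")$summed_count, 2)
  expect_equal(get("P1", "untreated")$strength, "weak")
  expect_equal(nrow(get("P1", "TNF")), 0)  # zero-sum triple omitted
  expect_equal(get("P2", "TNF")$strength, "strong")
  expect_equal(get("P3", "untreated")$strength, "one_hit")
})

test_that("one-hit wonders are dropped pairwise but kept as presence evidence", {
  cands <- data.frame(
    bait = "B1", prey = c("P1", "P2", "P2"),
    condition = c("untreated", "untreated", "TNF"),
    summed_count = c(1L, 1L, 4L),
    strength = c("one_hit", "one_hit", "strong"),
    stringsAsFactors = FALSE
  )
  out <- drop_one_hit_wonders(cands)
  expect_false("P1" %in% out$prey)              # sum 1 / absent: removed
  expect_equal(nrow(out[out$prey == "P2", ]), 2)  # both conditions kept
  expect_equal(out$strength[out$prey == "P2" & out$condition == "untreated"],
               "one_hit")
  expect_equal(nrow(drop_one_hit_wonders(cands[0, ])), 0)
})

test_that("pooled one-hit mode sums evidence across conditions", {
  cands <- data.frame(
    bait = "B1", prey = "P1", condition = c("untreated", "TNF"),
    summed_count = c(1L, 1L), strength = "one_hit",
    stringsAsFactors = FALSE
  )
  expect_equal(nrow(drop_one_hit_wonders(cands, mode = "per_condition")), 0)
  expect_equal(nrow(drop_one_hit_wonders(cands, mode = "pooled")), 2)
})

test_that("the cascade shrinks the protein and pair sets at every stage", {
  d <- simulate_dataset(synthetic_config(seed = 31, n_baits = 4,
                                         n_background = 60))
  res <- filter_cascade(d$matrix)
  pre <- census(d$matrix)
  post <- census(res$post_control)
  expect_lt(post$n_proteins, pre$n_proteins)
  expect_lte(post$n_interactions, pre$n_interactions)
  surviving_pairs <- unique(paste(res$candidates$bait, res$candidates$prey))
  expect_lte(length(surviving_pairs), post$n_interactions)
})

test_that("the composed cascade equals the exhaustive set-operation oracle", {
  for (seed in 1:60) {
    m <- random_small_matrix(seed)
    if (is.null(m)) next
    for (mode in c("per_condition", "pooled")) {
      got <- sort_candidates(filter_cascade(m, one_hit_mode = mode)$candidates)
      want <- sort_candidates(oracle_cascade(m, mode = mode))
      expect_equal(got, want, info = sprintf("seed %d mode %s", seed, mode))
    }
  }
})

test_that("on planted data the cascade removes background and keeps strong pairs", {
  d <- simulate_dataset(synthetic_config(seed = 33, n_baits = 2,
                                         interactors_per_bait = 5,
                                         n_background = 50,
                                         background_detect_prob = 0.9,
                                         one_hit_rate = 0,
                                         profile_mix = c(constitutive = 1,
                                                         TNF_induced = 0,
                                                         TNF_lost = 0)))
  res <- filter_cascade(d$matrix)
  recovered <- unique(res$candidates[, c("bait", "prey")])
  recovered_keys <- paste(recovered$bait, recovered$prey)
  truth <- d$truth$planted
  strong <- truth[truth$expected_strength == "strong", ]
  expect_true(all(paste(strong$bait, strong$prey) %in% recovered_keys))
  expect_length(intersect(recovered$prey, d$truth$background), 0)
})
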