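#' Configuration for the synthetic spectral-count generator
#'
#' Describes a simulated Virotrap-style screen: a panel of baits each run in
#' two conditions with biological replicates, a set of control experiments
#' with unrelated baits, a shared pool of background contaminants detected
#' across bait and control runs, and bait-specific planted interactors whose
#' presence may depend on TNF treatment.
#'
#' Spectral counts of detected proteins follow an overdispersed (negative
#' binomial) law; condition-dependent interactors are structural zeros in
#' their off condition unless `leaky_prob > 0`.
#'
#' @param n_baits number of study baits.
#' @param n_controls number of control experiments.
#' @param n_replicates biological replicates per bait x condition.
#' @param conditions condition labels (first = untreated/reference).
#' @param n_background size of the shared contaminant pool.
#' @param background_detect_prob probability that a background protein is
#'   observed in any given experiment (bait or control).
#' @param interactors_per_bait planted interactors per bait.
#' @param profile_mix named proportions over `constitutive`, `TNF_induced`,
#'   `TNF_lost`; must sum to 1.
#' @param count_mean,count_dispersion mean and dispersion (negative binomial
#'   `size`) of the count law for detected proteins.
#' @param one_hit_rate fraction of planted interactors forced to a summed
#'   count of exactly 1 within each replicate group where they occur
#'   (deliberate one-hit wonders).
#' @param interactor_detect_prob per-replicate detection probability of a
#'   planted (non one-hit) interactor in its active condition.
#' @param leaky_prob per-replicate probability that a condition-dependent
#'   interactor leaks a count into its off condition (stress-test knob;
#'   default 0 = structural zeros).
#' @param bait_self_count summed per-replicate count the bait protein itself
#'   receives in its own experiments (0 disables bait self-detection).
#' @param reference_coverage fraction of planted pairs included when a
#'   reference set is simulated from the ground truth.
#' @param seed integer seed; identical (config, seed) pairs reproduce
#'   identical datasets.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_baits = 12,
                             n_controls = 15,
                             n_replicates = 3,
                             conditions = c("untreated", "TNF"),
                             n_background = 150,
                             background_detect_prob = 0.8,
                             interactors_per_bait = 10,
                             profile_mix = c(constitutive = 0.5,
                                             TNF_induced = 0.25,
                                             TNF_lost = 0.25),
                             count_mean = 6,
                             count_dispersion = 2,
                             one_hit_rate = 0.1,
                             interactor_detect_prob = 0.9,
                             leaky_prob = 0,
                             bait_self_count = 10,
                             reference_coverage = 0.5,
                             seed = 1L) {
  cfg <- list(
    n_baits = as.integer(n_baits),
    n_controls = as.integer(n_controls),
    n_replicates = as.integer(n_replicates),
    conditions = as.character(conditions),
    n_background = as.integer(n_background),
    background_detect_prob = background_detect_prob,
    interactors_per_bait = as.integer(interactors_per_bait),
    profile_mix = profile_mix,
    count_mean = count_mean,
    count_dispersion = count_dispersion,
    one_hit_rate = one_hit_rate,
    interactor_detect_prob = interactor_detect_prob,
    leaky_prob = leaky_prob,
    bait_self_count = as.integer(bait_self_count),
    reference_coverage = reference_coverage,
    seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  chk_count <- function(field, min = 0L) {
    v <- cfg[[field]]
    if (length(v) != 1 || is.na(v) || v < min) {
      stop("invalid synthetic config: '", field, "' must be a count >= ", min)
    }
  }
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("invalid synthetic config: '", field, "' must lie in [0, 1]")
    }
  }
  chk_count("n_baits", 1L); chk_count("n_controls")
  chk_count("n_replicates", 1L); chk_count("n_background")
  chk_count("interactors_per_bait"); chk_count("bait_self_count")
  chk_prob("background_detect_prob"); chk_prob("one_hit_rate")
  chk_prob("interactor_detect_prob"); chk_prob("leaky_prob")
  chk_prob("reference_coverage")
  if (length(cfg$conditions) != 2 || anyDuplicated(cfg$conditions)) {
    stop("invalid synthetic config: 'conditions' must be two distinct labels")
  }
  pm <- cfg$profile_mix
  if (!setequal(names(pm), c("constitutive", "TNF_induced", "TNF_lost")) ||
      any(pm < 0) || abs(sum(pm) - 1) > 1e-8) {
    stop("invalid synthetic config: 'profile_mix' must be nonnegative ",
         "proportions over constitutive/TNF_induced/TNF_lost summing to 1")
  }
  if (cfg$count_mean <= 1 || cfg$count_dispersion <= 0) {
    stop("invalid synthetic config: 'count_mean' must exceed 1 and ",
         "'count_dispersion' must be positive")
  }
  invisible(cfg)
}

# Count of a detected protein: 1 + NB keeps detected counts >= 1 with
# mean == count_mean and overdispersion from the NB component.
rdetect <- function(n, cfg) {
  1L + stats::rnbinom(n, size = cfg$count_dispersion, mu = cfg$count_mean - 1)
}

#' Generate a synthetic spectral-count dataset with ground truth
#'
#' Emits a [count_matrix()] whose columns are `n_baits x 2 conditions x
#' n_replicates` bait experiments plus `n_controls` control experiments,
#' together with the planted ground truth.  Background contaminants
#' (`BG....`) are detected stochastically in bait and control columns alike;
#' planted interactors (`INT....`) occur only in their own bait's columns,
#' with `TNF_induced` pairs structurally absent from untreated columns and
#' `TNF_lost` pairs the reverse (unless `leaky_prob > 0`).  A fraction
#' `one_hit_rate` of planted pairs is forced to a summed count of exactly 1
#' in each replicate group where they occur, emulating one-hit wonders.
#'
#' @param config a [synthetic_config()].
#' @return A list with elements `matrix` ([count_matrix()]), `meta`
#'   (experiment metadata) and `truth` (list with data.frame `planted`
#'   columns bait/prey/profile/expected_strength, and character vector
#'   `background`).  `expected_strength` is the class the filter cascade is
#'   expected to assign given the realised counts: `one_hit`, `weak` or
#'   `strong` by the pair's best condition.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  cfg <- config
  set.seed(cfg$seed)

  cond_untreated <- cfg$conditions[1]
  cond_tnf <- cfg$conditions[2]
  baits <- sprintf("BAIT%02d", seq_len(cfg$n_baits))
  ctrl_baits <- sprintf("CTRL%02d", seq_len(cfg$n_controls))

  bait_meta <- expand.grid(replicate = seq_len(cfg$n_replicates),
                           condition = cfg$conditions,
                           bait = baits,
                           stringsAsFactors = FALSE)
  bait_meta <- data.frame(
    experiment_id = sprintf("%s_%s_r%d", bait_meta$bait, bait_meta$condition,
                            bait_meta$replicate),
    bait = bait_meta$bait,
    condition = bait_meta$condition,
    replicate = bait_meta$replicate,
    role = "bait_experiment",
    stringsAsFactors = FALSE
  )
  ctrl_meta <- data.frame(
    experiment_id = sprintf("%s_r1", ctrl_baits),
    bait = ctrl_baits,
    condition = "not_applicable",
    replicate = 1L,
    role = "control_experiment",
    stringsAsFactors = FALSE
  )
  meta <- rbind(bait_meta, ctrl_meta)
  validate_experiment_meta(meta)

  background <- if (cfg$n_background > 0) {
    sprintf("BG%04d", seq_len(cfg$n_background))
  } else character(0)

  n_int <- cfg$n_baits * cfg$interactors_per_bait
  interactors <- if (n_int > 0) sprintf("INT%04d", seq_len(n_int)) else character(0)
  profiles <- if (n_int > 0) {
    sample(names(cfg$profile_mix), n_int, replace = TRUE,
           prob = cfg$profile_mix)
  } else character(0)
  planted <- data.frame(
    bait = rep(baits, each = cfg$interactors_per_bait),
    prey = interactors,
    profile = profiles,
    stringsAsFactors = FALSE
  )
  planted$is_one_hit <- stats::runif(nrow(planted)) < cfg$one_hit_rate

  proteins <- c(if (cfg$bait_self_count > 0) baits else character(0),
                interactors, background)
  counts <- matrix(0L, nrow = length(proteins), ncol = nrow(meta),
                   dimnames = list(proteins, meta$experiment_id))

  # background pool: independent detection in every experiment
  if (length(background) > 0) {
    det <- matrix(stats::runif(length(background) * nrow(meta)) <
                    cfg$background_detect_prob,
                  nrow = length(background))
    n_det <- sum(det)
    vals <- matrix(0L, nrow = length(background), ncol = nrow(meta))
    vals[det] <- rdetect(n_det, cfg)
    counts[background, ] <- vals
  }

  # bait self-identification in its own six columns
  if (cfg$bait_self_count > 0) {
    for (b in baits) {
      cols <- meta$experiment_id[meta$role == "bait_experiment" &
                                   meta$bait == b]
      counts[b, cols] <- cfg$bait_self_count
    }
  }

  # planted interactors: only in their own bait's columns, profile-gated
  active_conditions <- function(profile) {
    switch(profile,
           constitutive = c(cond_untreated, cond_tnf),
           TNF_induced = cond_tnf,
           TNF_lost = cond_untreated)
  }
  for (i in seq_len(nrow(planted))) {
    b <- planted$bait[i]; p <- planted$prey[i]
    active <- active_conditions(planted$profile[i])
    off <- setdiff(cfg$conditions, active)
    for (cond in active) {
      cols <- meta$experiment_id[meta$role == "bait_experiment" &
                                   meta$bait == b & meta$condition == cond]
      if (planted$is_one_hit[i]) {
        # a single PSM across the whole replicate group
        counts[p, sample(cols, 1)] <- 1L
      } else {
        det <- stats::runif(length(cols)) < cfg$interactor_detect_prob
        if (!any(det)) det[sample(length(cols), 1)] <- TRUE  # always observed
        counts[p, cols[det]] <- rdetect(sum(det), cfg)
      }
    }
    if (cfg$leaky_prob > 0 && length(off) > 0) {
      for (cond in off) {
        cols <- meta$experiment_id[meta$role == "bait_experiment" &
                                     meta$bait == b & meta$condition == cond]
        leak <- stats::runif(length(cols)) < cfg$leaky_prob
        if (any(leak)) counts[p, cols[leak]] <- 1L
      }
    }
  }

  counts <- counts[rowSums(counts) > 0L, , drop = FALSE]
  mat <- count_matrix(counts, meta)

  # expected strength from the realised summed counts (best condition)
  planted$expected_strength <- vapply(seq_len(nrow(planted)), function(i) {
    if (planted$is_one_hit[i]) return("one_hit")
    b <- planted$bait[i]; p <- planted$prey[i]
    if (!p %in% rownames(counts)) return("one_hit")
    best <- max(vapply(cfg$conditions, function(cond) {
      cols <- meta$experiment_id[meta$role == "bait_experiment" &
                                   meta$bait == b & meta$condition == cond]
      sum(counts[p, cols])
    }, numeric(1)))
    if (best >= 3) "strong" else if (best == 2) "weak" else "one_hit"
  }, character(1))
  planted$is_one_hit <- NULL

  truth <- list(planted = planted, background = background)
  validate_ground_truth(truth)
  list(matrix = mat, meta = meta, truth = truth)
}

validate_ground_truth <- function(truth) {
  stopifnot(is.list(truth), is.data.frame(truth$planted))
  if (length(intersect(truth$planted$prey, truth$background)) > 0) {
    stop("ground truth invalid: planted preys overlap background identifiers")
  }
  invisible(truth)
}

#' Simulate a partial-knowledge reference interaction set
#'
#' Samples a stated fraction of the planted pairs (without replacement) into
#' an unordered-pair reference set, mimicking the partial coverage of curated
#' databases such as BioGRID, and optionally adds decoy pairs that were never
#' planted.
#'
#' @param truth ground truth from [simulate_dataset()].
#' @param coverage fraction of planted pairs to include, in `[0, 1]`.
#' @param extra_pairs number of decoy pairs (bait x `DEC....` prey) to add.
#' @param seed integer seed.
#' @return A [reference_set()] of unordered pairs.
#' @export
simulate_reference_set <- function(truth, coverage = 0.5, extra_pairs = 0,
                                   seed = 1L) {
  validate_ground_truth(truth)
  if (length(coverage) != 1 || is.na(coverage) || coverage < 0 || coverage > 1) {
    stop("coverage must lie in [0, 1]")
  }
  set.seed(as.integer(seed))
  planted <- truth$planted
  n_take <- round(coverage * nrow(planted))
  take <- if (n_take > 0) sample(nrow(planted), n_take) else integer(0)
  pairs <- planted[take, c("bait", "prey"), drop = FALSE]
  names(pairs) <- c("a", "b")
  if (extra_pairs > 0) {
    dec <- data.frame(
      a = sample(unique(planted$bait), extra_pairs, replace = TRUE),
      b = sprintf("DEC%04d", seq_len(extra_pairs)),
      stringsAsFactors = FALSE
    )
    pairs <- rbind(pairs, dec)
  }
  reference_set(pairs, version_label = sprintf(
    "synthetic coverage=%.2f extra=%d seed=%d", coverage, extra_pairs,
    as.integer(seed)))
}

#' Write simulated ground truth as TSV
#'
#' @param truth ground truth from [simulate_dataset()].
#' @param path output file.
#' @export
write_ground_truth <- function(truth, path) {
  validate_ground_truth(truth)
  utils::write.table(truth$planted, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
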