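#' @keywords internal
"_PACKAGE"

#' Published study design constants
#'
#' Design counts of the playback study the package's defaults emulate:
#' 414 gecker call units from 52 calling bouts given by 9 callers; 19 adults
#' observed for 160 proximity scans each; 145 unidirectional agonistic
#' events; 82 playback trials on 16 subjects of which 74 elicited a looking
#' response, scored over a 30-s post-playback window.
#'
#' These constants seed the synthetic-data defaults and support simple
#' summary arithmetic (e.g. mean units per bout, looking-response rate).
#'
#' @format a named list.
#' @export
study_design <- list(
  n_call_units     = 414L,
  n_bouts          = 52L,
  n_callers        = 9L,
  n_adults         = 19L,
  n_females        = 10L,
  n_matrilines     = 5L,
  scans_per_focal  = 160L,
  n_agonistic      = 145L,
  n_trials         = 82L,
  n_subjects       = 16L,
  n_looking        = 74L,
  look_window_s    = 30
)

.check_len5 <- function(x, name) {
  if (!is.numeric(x) || !(length(x) %in% c(1L, 5L)) || any(x < 0))
    stop(sprintf("`%s` must be a non-negative numeric of length 1 or 5", name),
         call. = FALSE)
  rep_len(as.numeric(x), 5L)
}

feature_names <- c("DFB1", "DFA2", "PF", "FR", "duration")

# uniform integer draw on a closed range, safe for degenerate ranges
.draw_count <- function(range) {
  if (range[1] == range[2]) return(range[1])
  sample(range[1]:range[2], 1L)
}

#' Simulation specification for caller-labelled call features
#'
#' Describes a hierarchical generator for multivariate acoustic features of
#' call units nested in calling bouts: each caller has a mean feature vector,
#' each bout adds a caller-shared random offset, and each unit adds
#' independent noise. The hierarchy mirrors repeated calls within vocal
#' episodes, where units of a bout are non-independent.
#'
#' Defaults emulate the study design: 9 callers, 6 bouts per caller, 2-12
#' units per bout (uniform), unit noise sd 1 and bout sd 0.5 per feature.
#'
#' @param n_callers number of callers (>= 2).
#' @param bouts_per_caller bouts recorded per caller.
#' @param units_per_bout integer range `c(min, max)` of units per bout,
#'   drawn uniformly; min >= 1.
#' @param feature_means optional `n_callers x 5` matrix of caller mean
#'   feature vectors; if `NULL`, caller means are drawn
#'   `N(0, between_caller_sd)` per feature.
#' @param between_caller_sd sd of caller means per feature (length 1 or 5).
#' @param within_caller_sd unit-level noise sd per feature (length 1 or 5).
#' @param bout_sd bout-level random-effect sd per feature (length 1 or 5).
#' @param seed integer seed; the generator is a pure function of the spec.
#' @return an object of class `"call_sim_spec"`.
#' @export
call_sim_spec <- function(n_callers = 9, bouts_per_caller = 6,
                          units_per_bout = c(2, 12), feature_means = NULL,
                          between_caller_sd = 1, within_caller_sd = 1,
                          bout_sd = 0.5, seed = 1) {
  if (n_callers < 2) stop("`n_callers` must be >= 2", call. = FALSE)
  if (bouts_per_caller < 1) stop("`bouts_per_caller` must be >= 1", call. = FALSE)
  units_per_bout <- as.integer(round(units_per_bout))
  if (length(units_per_bout) == 1L) units_per_bout <- rep(units_per_bout, 2L)
  if (length(units_per_bout) != 2L || units_per_bout[1] < 1 ||
      units_per_bout[2] < units_per_bout[1])
    stop("`units_per_bout` must be an integer range c(min, max) with min >= 1",
         call. = FALSE)
  if (!is.null(feature_means)) {
    feature_means <- as.matrix(feature_means)
    if (nrow(feature_means) != n_callers || ncol(feature_means) != 5L)
      stop("`feature_means` must be an n_callers x 5 matrix", call. = FALSE)
  }
  structure(list(
    n_callers = as.integer(n_callers),
    bouts_per_caller = as.integer(bouts_per_caller),
    units_per_bout = units_per_bout,
    feature_means = feature_means,
    between_caller_sd = .check_len5(between_caller_sd, "between_caller_sd"),
    within_caller_sd = .check_len5(within_caller_sd, "within_caller_sd"),
    bout_sd = .check_len5(bout_sd, "bout_sd"),
    seed = as.integer(seed)), class = "call_sim_spec")
}

#' Generate a caller-labelled call-unit feature table
#'
#' Draws a feature table from a [call_sim_spec()]: one row per call unit,
#' `unit feature = caller mean + bout effect + unit noise`, with bout ids
#' unique across callers. Deterministic given the spec's seed.
#'
#' @param spec a [call_sim_spec()].
#' @return a data.frame with columns `unit_id`, `bout_id`, `caller_id` and
#'   the five feature columns `DFB1, DFA2, PF, FR, duration` (on an abstract
#'   standardised scale).
#' @export
gen_call_features <- function(spec) {
  stopifnot(inherits(spec, "call_sim_spec"))
  set.seed(spec$seed)
  callers <- sprintf("C%02d", seq_len(spec$n_callers))
  M <- spec$feature_means
  if (is.null(M)) {
    M <- matrix(stats::rnorm(spec$n_callers * 5L), ncol = 5L) *
      rep(spec$between_caller_sd, each = spec$n_callers)
  }
  rows <- vector("list", spec$n_callers * spec$bouts_per_caller)
  bout <- 0L
  for (ci in seq_len(spec$n_callers)) {
    for (b in seq_len(spec$bouts_per_caller)) {
      bout <- bout + 1L
      n_units <- .draw_count(spec$units_per_bout)
      bout_eff <- stats::rnorm(5L, sd = spec$bout_sd)
      noise <- matrix(stats::rnorm(n_units * 5L), ncol = 5L) *
        rep(spec$within_caller_sd, each = n_units)
      feats <- matrix(M[ci, ], n_units, 5L, byrow = TRUE) +
        matrix(bout_eff, n_units, 5L, byrow = TRUE) + noise
      colnames(feats) <- feature_names
      rows[[bout]] <- data.frame(
        unit_id = NA_character_,
        bout_id = sprintf("B%03d", bout),
        caller_id = callers[ci],
        feats, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$unit_id <- sprintf("U%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Generate synthetic call-unit waveforms with planted spectra
#'
#' Writes one 44.1 kHz mono 16-bit PCM WAV per call unit, each a harmonic
#' tonal burst (fundamental plus decaying harmonics, Hann-shaped envelope)
#' whose fundamental frequency and duration are caller-specific with bout-
#' and unit-level jitter. Planted parameters are returned in the metadata so
#' feature extraction can be validated against known spectra. Emulates tonal
#' agonistic call units whose energy sits in the 2-10 kHz band.
#'
#' @param spec a [call_sim_spec()] (controls counts and nesting; the
#'   acoustic scales below control the planted spectra).
#' @param out_dir writable directory for the WAV files.
#' @param f0_range range (Hz) over which caller fundamental means are spaced.
#' @param n_harmonics number of harmonics (including the fundamental).
#' @param duration_range_ms range of unit durations (ms).
#' @param bout_jitter_hz,unit_jitter_hz sd of bout- and unit-level
#'   fundamental jitter (Hz).
#' @param rate sampling rate, Hz.
#' @return metadata data.frame with columns `unit_id, bout_id, caller_id,
#'   file, f0_hz, n_harmonics, duration_ms`.
#' @export
gen_call_waveforms <- function(spec, out_dir, f0_range = c(2000, 5000),
                               n_harmonics = 3, duration_range_ms = c(150, 400),
                               bout_jitter_hz = 30, unit_jitter_hz = 15,
                               rate = 44100) {
  stopifnot(inherits(spec, "call_sim_spec"))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
  set.seed(spec$seed)
  callers <- sprintf("C%02d", seq_len(spec$n_callers))
  f0_caller <- seq(f0_range[1], f0_range[2], length.out = spec$n_callers)
  meta <- list(); bout <- 0L; unit <- 0L
  for (ci in seq_len(spec$n_callers)) {
    for (b in seq_len(spec$bouts_per_caller)) {
      bout <- bout + 1L
      n_units <- .draw_count(spec$units_per_bout)
      f0_bout <- f0_caller[ci] + stats::rnorm(1L, sd = bout_jitter_hz)
      for (u in seq_len(n_units)) {
        unit <- unit + 1L
        f0 <- f0_bout + stats::rnorm(1L, sd = unit_jitter_hz)
        dur_ms <- stats::runif(1L, duration_range_ms[1], duration_range_ms[2])
        n <- round(dur_ms / 1000 * rate)
        t <- (seq_len(n) - 1L) / rate
        x <- rep(0, n)
        for (h in seq_len(n_harmonics))
          x <- x + (0.5 ^ (h - 1)) * sin(2 * pi * h * f0 * t)
        env <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))  # Hann
        x <- 0.8 * x * env / max(abs(x * env))
        fname <- sprintf("U%04d.wav", unit)
        write_wav(waveform(x, rate), file.path(out_dir, fname))
        meta[[unit]] <- data.frame(
          unit_id = sprintf("U%04d", unit), bout_id = sprintf("B%03d", bout),
          caller_id = callers[ci], file = fname, f0_hz = f0,
          n_harmonics = n_harmonics, duration_ms = 1000 * n / rate,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, meta)
}

#' Simulation specification for a social troop
#'
#' Describes a troop with planted social structure: dyadic affinities (the
#' probability a pair is recorded as close neighbours in any proximity
#' scan), a latent rank order driving agonistic outcomes, sexes and
#' matrilines. Defaults emulate the study group: 19 adults (10 females) in 5
#' matrilines, 160 scans per focal, 145 agonistic events.
#'
#' @param n_individuals number of adults.
#' @param n_females number of females (assigned to the first ids).
#' @param n_matrilines number of matrilines (round-robin assignment by
#'   default).
#' @param sexes optional per-individual `"F"`/`"M"` vector.
#' @param matrilines optional per-individual matriline labels.
#' @param true_ranks optional permutation; rank 1 is the top of the
#'   hierarchy. Defaults to id order.
#' @param planted_affinity optional symmetric zero-diagonal matrix of dyadic
#'   neighbour probabilities in \[0, 1\]. Default plants community structure
#'   on matrilines: within-matriline 0.30, between 0.05.
#' @param n_scans_per_focal proximity scans per focal individual.
#' @param n_conflicts number of unidirectional agonistic events.
#' @param rank_steepness probability in \[0.5, 1\] that the higher-ranked
#'   member of a dyad wins an event; 0.5 is no hierarchy signal.
#' @param seed integer seed.
#' @return an object of class `"troop_sim_spec"`.
#' @export
troop_sim_spec <- function(n_individuals = 19, n_females = 10,
                           n_matrilines = 5, sexes = NULL, matrilines = NULL,
                           true_ranks = NULL, planted_affinity = NULL,
                           n_scans_per_focal = 160, n_conflicts = 145,
                           rank_steepness = 0.9, seed = 1) {
  n <- as.integer(n_individuals)
  if (n < 3) stop("`n_individuals` must be >= 3", call. = FALSE)
  if (n_females > n || n_females < 0)
    stop("`n_females` must lie between 0 and n_individuals", call. = FALSE)
  ids <- sprintf("I%02d", seq_len(n))
  if (is.null(sexes))
    sexes <- rep(c("F", "M"), c(n_females, n - n_females))
  if (length(sexes) != n || !all(sexes %in% c("F", "M")))
    stop("`sexes` must be length n_individuals with values 'F'/'M'",
         call. = FALSE)
  if (is.null(matrilines))
    matrilines <- paste0("M", rep_len(seq_len(n_matrilines), n))
  if (length(matrilines) != n)
    stop("`matrilines` must have one label per individual", call. = FALSE)
  if (is.null(true_ranks)) true_ranks <- seq_len(n)
  if (!setequal(true_ranks, seq_len(n)))
    stop("`true_ranks` must be a permutation of 1..n_individuals",
         call. = FALSE)
  if (is.null(planted_affinity)) {
    # community structure on matrilines plus continuous dyadic
    # heterogeneity (gregariousness and dyad-specific preference), so the
    # friendship gradient is not a pure kinship indicator
    same <- outer(matrilines, matrilines, "==")
    base <- ifelse(same, 0.22, 0.06)
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed + 90000L)
    greg <- stats::runif(n, 0, 0.2)
    pref <- matrix(stats::runif(n * n, 0, 0.15), n, n)
    pref <- (pref + t(pref)) / 2
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
    planted_affinity <- pmin(base + outer(greg, greg, "+") / 2 + pref, 0.9)
    diag(planted_affinity) <- 0
  }
  planted_affinity <- as.matrix(planted_affinity)
  if (nrow(planted_affinity) != n || ncol(planted_affinity) != n)
    stop("`planted_affinity` must be n x n", call. = FALSE)
  if (max(abs(planted_affinity - t(planted_affinity))) > 1e-12 ||
      any(diag(planted_affinity) != 0))
    stop("`planted_affinity` must be symmetric with zero diagonal",
         call. = FALSE)
  if (any(planted_affinity < 0) || any(planted_affinity > 1))
    stop("`planted_affinity` entries must lie in [0, 1]", call. = FALSE)
  if (rank_steepness < 0.5 || rank_steepness > 1)
    stop("`rank_steepness` must lie in [0.5, 1]", call. = FALSE)
  structure(list(
    n_individuals = n, ids = ids, sexes = sexes, matrilines = matrilines,
    true_ranks = as.integer(true_ranks), planted_affinity = planted_affinity,
    n_scans_per_focal = as.integer(n_scans_per_focal),
    n_conflicts = as.integer(n_conflicts),
    rank_steepness = rank_steepness, seed = as.integer(seed)),
    class = "troop_sim_spec")
}

#' Generate proximity scans, agonistic events and a grooming matrix
#'
#' Draws the three observation streams of a troop with planted structure:
#' each focal's scans record each groupmate as a neighbour independently
#' with probability `planted_affinity[focal, other]`; each agonistic event
#' samples a dyad uniformly and lets the higher-ranked member win with
#' probability `rank_steepness`; the grooming matrix is a monotone noisy
#' transform of the planted affinity.
#'
#' @param spec a [troop_sim_spec()].
#' @return a list with elements `scans` (data.frame `focal_id, scan_index,
#'   neighbour_ids` with ';'-separated neighbour ids), `conflicts`
#'   (data.frame `winner_id, loser_id, order`), `grooming` (symmetric
#'   matrix), plus `ids`, `sexes`, `matrilines`, `true_ranks` carried over
#'   from the spec.
#' @export
gen_troop_observations <- function(spec) {
  stopifnot(inherits(spec, "troop_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_individuals; ids <- spec$ids
  aff <- spec$planted_affinity

  scans <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- character(spec$n_scans_per_focal)
    for (s in seq_len(spec$n_scans_per_focal)) {
      hit <- stats::runif(n) < aff[i, ]
      hit[i] <- FALSE
      nb[s] <- paste(ids[hit], collapse = ";")
    }
    scans[[i]] <- data.frame(focal_id = ids[i],
                             scan_index = seq_len(spec$n_scans_per_focal),
                             neighbour_ids = nb, stringsAsFactors = FALSE)
  }
  scans <- do.call(rbind, scans)

  rank_of <- spec$true_ranks           # rank position per id (1 = top)
  winner <- character(spec$n_conflicts); loser <- character(spec$n_conflicts)
  for (e in seq_len(spec$n_conflicts)) {
    pair <- sample.int(n, 2L)
    hi <- pair[which.min(rank_of[pair])]  # higher-ranked = smaller rank
    lo <- setdiff(pair, hi)
    if (stats::runif(1L) < spec$rank_steepness) {
      winner[e] <- ids[hi]; loser[e] <- ids[lo]
    } else {
      winner[e] <- ids[lo]; loser[e] <- ids[hi]
    }
  }
  conflicts <- data.frame(winner_id = winner, loser_id = loser,
                          order = seq_len(spec$n_conflicts),
                          stringsAsFactors = FALSE)

  groom <- matrix(0, n, n, dimnames = list(ids, ids))
  ut <- upper.tri(groom)
  groom[ut] <- pmax(0, round(200 * aff[ut] + stats::rnorm(sum(ut), sd = 2)))
  groom <- groom + t(groom)

  list(scans = scans, conflicts = conflicts, grooming = groom,
       ids = ids, sexes = stats::setNames(spec$sexes, ids),
       matrilines = stats::setNames(spec$matrilines, ids),
       true_ranks = stats::setNames(spec$true_ranks, ids))
}

#' Simulation specification for playback trials
#'
#' Describes the generator for trial-level looking times: one trial per
#' subject and condition, `look = condition mean + subject intercept +
#' order_slope * order + noise`, truncated to the \[0, 30\] s scoring
#' window. Default condition means are the study's reported per-condition
#' means (9.49, 4.30, 7.93, 5.41, 5.34, 4.39 s for conditions 1-6).
#'
#' @param n_subjects number of subjects drawn from the troop.
#' @param conditions subset of 1:6 to run.
#' @param condition_means per-condition mean look time (s), named by the
#'   full 1:6 positions.
#' @param subject_sd between-subject intercept sd (s).
#' @param residual_sd residual sd (s).
#' @param order_slope change in look time per trial position (s).
#' @param seed integer seed.
#' @return an object of class `"trial_sim_spec"`.
#' @export
trial_sim_spec <- function(n_subjects = 16, conditions = 1:6,
                           condition_means = c(9.49, 4.30, 7.93, 5.41, 5.34, 4.39),
                           subject_sd = 2, residual_sd = 4,
                           order_slope = -0.9, seed = 1) {
  if (!all(conditions %in% 1:6)) stop("`conditions` must be within 1..6",
                                      call. = FALSE)
  if (length(condition_means) != 6L || any(condition_means < 0))
    stop("`condition_means` must be 6 non-negative means (conditions 1..6)",
         call. = FALSE)
  if (subject_sd < 0 || residual_sd < 0)
    stop("`subject_sd` and `residual_sd` must be >= 0", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 conditions = as.integer(sort(unique(conditions))),
                 condition_means = as.numeric(condition_means),
                 subject_sd = subject_sd, residual_sd = residual_sd,
                 order_slope = order_slope, seed = as.integer(seed)),
            class = "trial_sim_spec")
}

#' Generate a playback trial table from troop observations
#'
#' Builds the study's derived covariates from the troop streams
#' (association matrix, Elo ratings, kinship, eigenvector centrality),
#' selects the caller dyad for every subject x condition with
#' [select_condition_dyads()], randomises condition order within subject and
#' draws looking times per the [trial_sim_spec()]. Trials whose condition
#' has no eligible dyad (e.g. conditions 3-4 for central subjects) are
#' marked skipped with `look_time = NA`.
#'
#' @param spec a [trial_sim_spec()].
#' @param troop output of [gen_troop_observations()].
#' @return a data.frame with one row per scheduled trial: `subject_id,
#'   condition, caller_A, caller_B, trial_order, conflict_intensity,
#'   friendship_between_callers, relatedness_between_callers, elo_diff,
#'   subject_centrality, look_time, skipped`.
#' @export
gen_trials <- function(spec, troop) {
  stopifnot(inherits(spec, "trial_sim_spec"))
  set.seed(spec$seed)
  assoc <- build_association_matrix(troop$scans, ids = troop$ids)
  fz <- zscore_dyadic(assoc)
  elo <- elo_ratings(troop$conflicts, ids = troop$ids)
  kin <- kinship_matrix(troop$matrilines)
  cent <- eigenvector_centrality(assoc)
  subjects <- sort(sample(troop$ids, spec$n_subjects))

  rows <- list()
  for (s in subjects) {
    conds <- sample(spec$conditions)
    subj_int <- stats::rnorm(1L, sd = spec$subject_sd)
    ord <- 0L
    for (cond in conds) {
      dyad <- select_condition_dyads(s, assoc, kin, troop$sexes, cent, cond)
      skipped <- is.null(dyad)
      if (skipped) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = s, condition = cond, caller_A = NA_character_,
          caller_B = NA_character_, trial_order = NA_integer_,
          conflict_intensity = NA_real_,
          friendship_between_callers = NA_real_,
          relatedness_between_callers = NA_real_, elo_diff = NA_real_,
          subject_centrality = unname(cent$scores[s]), look_time = NA_real_,
          skipped = TRUE, stringsAsFactors = FALSE)
        next
      }
      ord <- ord + 1L
      intensity <- min(5, max(1, round(stats::rnorm(1L, 3, 0.8))))
      y <- spec$condition_means[cond] + subj_int +
        spec$order_slope * ord + stats::rnorm(1L, sd = spec$residual_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s, condition = cond,
        caller_A = dyad[1], caller_B = dyad[2], trial_order = ord,
        conflict_intensity = intensity,
        friendship_between_callers = fz[dyad[1], dyad[2]],
        relatedness_between_callers = kin[dyad[1], dyad[2]],
        elo_diff = abs(elo$ratings[dyad[1]] - elo$ratings[dyad[2]]),
        subject_centrality = unname(cent$scores[s]),
        look_time = min(30, max(0, y)), skipped = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # z-scale the dominance covariate across conducted trials, as the study
  # scaled all friendship and dominance data
  ok <- !out$skipped
  if (sum(ok) > 1 && stats::sd(out$elo_diff[ok]) > 0)
    out$elo_diff[ok] <- as.numeric(scale(out$elo_diff[ok]))
  out
}
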