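.schemas_init <- function() list(
  scans = list(cols = c("focal_id", "scan_index", "neighbour_ids"),
               numeric = "scan_index", key = NULL),
  conflicts = list(cols = c("winner_id", "loser_id", "order"),
                   numeric = "order", key = NULL),
  matrilines = list(cols = c("individual_id", "matriline"),
                    numeric = character(0), key = "individual_id"),
  features = list(cols = c("unit_id", "bout_id", "caller_id", feature_names),
                  numeric = feature_names, key = "unit_id"),
  trials = list(cols = c("subject_id", "condition", "caller_A", "caller_B",
                         "trial_order", "conflict_intensity",
                         "friendship_between_callers",
                         "relatedness_between_callers", "elo_diff",
                         "subject_centrality", "look_time", "skipped"),
                numeric = c("condition", "trial_order", "conflict_intensity",
                            "friendship_between_callers",
                            "relatedness_between_callers", "elo_diff",
                            "subject_centrality", "look_time"),
                key = NULL))

#' Read and validate an observation table
#'
#' CSV readers for the package's table schemas (`"scans"`, `"conflicts"`,
#' `"matrilines"`, `"features"`, `"trials"`). The header must contain the
#' schema's columns; numeric columns are type-checked with row numbers in
#' the error message, and key columns must be unique.
#'
#' @param path CSV path.
#' @param schema one of the schema names above.
#' @return validated data.frame.
#' @export
read_observation_table <- function(path, schema) {
  schemas <- .schemas_init()
  if (!schema %in% names(schemas))
    stop(sprintf("unknown schema '%s'", schema), call. = FALSE)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path),
                               call. = FALSE)
  sc <- schemas[[schema]]
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(sc$cols, colnames(tab))
  if (length(missing) > 0L)
    stop(sprintf("'%s': missing column(s) for schema '%s': %s", path, schema,
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (nrow(tab) == 0L) {
    warning(sprintf("'%s' contains a header but no rows", path),
            call. = FALSE)
  }
  for (col in sc$numeric) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !(tab[[col]] %in% c("", "NA")))
    if (length(bad) > 0L)
      stop(sprintf("'%s': non-numeric values in column '%s' at row(s) %s",
                   path, col, paste(utils::head(bad, 5L), collapse = ", ")),
           call. = FALSE)
    tab[[col]] <- v
  }
  if (!is.null(sc$key)) {
    dup <- which(duplicated(tab[[sc$key]]))
    if (length(dup) > 0L)
      stop(sprintf("'%s': duplicate %s at row(s) %s", path, sc$key,
                   paste(utils::head(dup, 5L), collapse = ", ")),
           call. = FALSE)
  }
  if (schema == "trials" && "skipped" %in% colnames(tab))
    tab$skipped <- tab$skipped %in% c("TRUE", "true", "1")
  tab
}

#' Write a square dyadic matrix as CSV
#'
#' Individual ids form the header row and first column.
#' @param m matrix with dimnames.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a square dyadic matrix written by [write_matrix_csv()]
#' @param path CSV path.
#' @return matrix with dimnames.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Export an association network as an edge list
#'
#' Writes dyads with positive weight as `from,to,weight` rows (upper
#' triangle only), for external network visualisation.
#'
#' @param m association matrix.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(m, path) {
  ids <- rownames(m)
  ut <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  utils::write.csv(data.frame(from = ids[ut[, 1]], to = ids[ut[, 2]],
                              weight = m[ut]), path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects the settings of an end-to-end synthetic run: simulation specs,
#' pDFA settings, Elo constants and the output directory. All stochastic
#' stages derive their streams from `seed`.
#'
#' @param out_dir output directory for reports.
#' @param seed master integer seed.
#' @param call_spec,troop_spec,trial_spec simulation specifications; by
#'   default built from `seed` with study-design defaults.
#' @param n_perm permutations for the pDFA and Mantel tests.
#' @param pdfa_mode `"plain"` or `"cv"`.
#' @param holdout `"unit"` or `"bout"` (cross-validated pDFA only).
#' @param elo_k,elo_start Elo update constant and initial rating.
#' @param stages subset of `c("simulate", "features", "pdfa", "network",
#'   "design", "models")`.
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, seed = 1, call_spec = NULL,
                            troop_spec = NULL, trial_spec = NULL,
                            n_perm = 999, pdfa_mode = c("plain", "cv"),
                            holdout = c("unit", "bout"), elo_k = 100,
                            elo_start = 1000,
                            stages = c("simulate", "pdfa", "network",
                                       "design", "models")) {
  pdfa_mode <- match.arg(pdfa_mode)
  holdout <- match.arg(holdout)
  stopifnot(n_perm >= 1, is.numeric(seed), length(seed) == 1L)
  seed <- as.integer(seed)
  structure(list(
    out_dir = out_dir, seed = seed,
    call_spec = call_spec %||% call_sim_spec(seed = seed),
    troop_spec = troop_spec %||% troop_sim_spec(seed = seed + 1L),
    trial_spec = trial_spec %||% trial_sim_spec(seed = seed + 2L),
    n_perm = as.integer(n_perm), pdfa_mode = pdfa_mode, holdout = holdout,
    elo_k = elo_k, elo_start = elo_start, stages = stages),
    class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the end-to-end synthetic pipeline
#'
#' Executes the requested stages in order — simulate the input streams,
#' run the nested-permutation caller-identity analysis, build the social
#' metrics (association, Elo, centrality, grooming Mantel test, split-half
#' stability), select condition dyads per subject, and fit the looking-time
#' models — writing JSON reports and CSV tables under `cfg$out_dir` and
#' finally a run manifest with config echo, output checksums and per-stage
#' timings. Fails fast with the stage name on any error.
#'
#' @param cfg a [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  run_stage <- function(stage, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    .stage_log(stage, "done")
    res
  }
  out <- function(f) file.path(cfg$out_dir, f)

  features <- troop <- trials <- NULL
  if ("simulate" %in% cfg$stages) {
    run_stage("simulate", function() {
      features <<- gen_call_features(cfg$call_spec)
      troop <<- gen_troop_observations(cfg$troop_spec)
      utils::write.csv(features, out("call_features.csv"), row.names = FALSE)
      utils::write.csv(troop$scans, out("scans.csv"), row.names = FALSE)
      utils::write.csv(troop$conflicts, out("conflicts.csv"),
                       row.names = FALSE)
      write_matrix_csv(troop$grooming, out("grooming.csv"))
      utils::write.csv(data.frame(individual_id = troop$ids,
                                  matriline = unname(troop$matrilines),
                                  sex = unname(troop$sexes)),
                       out("individuals.csv"), row.names = FALSE)
    })
  }
  if ("pdfa" %in% cfg$stages) {
    if (is.null(features))
      stop("configuration error: 'pdfa' stage requires the 'simulate' stage ",
           "or a features table", call. = FALSE)
    run_stage("pdfa", function() {
      tab <- check_inclusion(normalize_features(features, log_rule = "none"))
      res <- if (cfg$pdfa_mode == "plain")
        pdfa_test(tab, n_perm = cfg$n_perm, seed = cfg$seed)
      else pdfa_crossvalidated(tab, n_perm = cfg$n_perm, seed = cfg$seed,
                               holdout = cfg$holdout)
      rep <- res[c("observed_accuracy", "p_value", "null_mean", "n_perm",
                   "seed", "mode")]
      rep$null_ci <- as.list(stats::setNames(res$null_ci,
                                             c("lo_2.5", "hi_97.5")))
      rep$per_class_accuracy <- as.list(res$per_class_accuracy)
      rep$per_class_p <- as.list(res$per_class_p)
      jsonlite::write_json(rep, out("pdfa_report.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    })
  }
  assoc <- cent <- kin <- elo <- NULL
  if (any(c("network", "design", "models") %in% cfg$stages)) {
    if (is.null(troop))
      stop("configuration error: network/design/models stages require the ",
           "'simulate' stage", call. = FALSE)
    assoc <- build_association_matrix(troop$scans, ids = troop$ids)
    cent <- eigenvector_centrality(assoc)
    kin <- kinship_matrix(troop$matrilines)
    elo <- elo_ratings(troop$conflicts, ids = troop$ids, k = cfg$elo_k,
                       start = cfg$elo_start)
  }
  if ("network" %in% cfg$stages) {
    run_stage("network", function() {
      write_matrix_csv(assoc, out("association.csv"))
      write_matrix_csv(zscore_dyadic(assoc), out("association_z.csv"))
      write_edge_list(assoc, out("network_edges.csv"))
      groom_mantel <- mantel_test(assoc, troop$grooming,
                                  n_perm = cfg$n_perm, seed = cfg$seed)
      stab50 <- stability_split(troop$scans, 0.5, ids = troop$ids,
                                n_perm = cfg$n_perm, seed = cfg$seed)
      stab95 <- stability_split(troop$scans, 0.95, ids = troop$ids,
                                n_perm = cfg$n_perm, seed = cfg$seed)
      jsonlite::write_json(list(
        elo_ratings = as.list(elo$ratings),
        centrality = as.list(cent$scores),
        central_set = cent$central_set,
        peripheral_set = cent$peripheral_set,
        grooming_mantel = unclass(groom_mantel),
        stability_split_50 = unclass(stab50),
        stability_split_95 = unclass(stab95)),
        out("network_report.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    })
  }
  if ("design" %in% cfg$stages) {
    run_stage("design", function() {
      rows <- list()
      for (s in troop$ids) for (cond in 1:6) {
        d <- select_condition_dyads(s, assoc, kin, troop$sexes, cent, cond)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = s, condition = cond,
          caller_A = if (is.null(d)) NA else d[1],
          caller_B = if (is.null(d)) NA else d[2],
          feasible = !is.null(d), stringsAsFactors = FALSE)
      }
      utils::write.csv(do.call(rbind, rows), out("condition_dyads.csv"),
                       row.names = FALSE)
    })
  }
  if ("models" %in% cfg$stages) {
    run_stage("models", function() {
      trials <<- gen_trials(cfg$trial_spec, troop)
      utils::write.csv(trials, out("trials.csv"), row.names = FALSE)
      term_block <- function(fit) {
        tt <- fit$terms; tt$term <- rownames(tt); rownames(tt) <- NULL
        tt[, c("term", "estimate", "se", "t", "p")]
      }
      reports <- list()
      for (w in 1:3) {
        cm <- fit_condition_model(trials, w)
        reports[[paste0("condition_model_", w)]] <- list(
          terms = term_block(cm$fit), lrt = unclass(cm$lrt))
      }
      rm <- fit_relationship_model(trials)
      reports$relationship_model <- list(
        terms = term_block(rm$fit), lrt = unclass(rm$lrt),
        random_effects = as.list(rm$fit$random_effects),
        singular = rm$fit$singular)
      jsonlite::write_json(reports, out("model_report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "rows")
    })
  }

  files <- setdiff(list.files(cfg$out_dir), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("callnet")),
    seed = cfg$seed, n_perm = cfg$n_perm, stages = cfg$stages,
    timings_s = timings,
    checksums = as.list(tools::md5sum(file.path(cfg$out_dir, files))) |>
      stats::setNames(files))
  tmp <- out(".manifest.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, out("manifest.json"))
  invisible(manifest)
}
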