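# End-to-end orchestration: configuration-driven runs producing feature
# tables, evaluation CSVs, importance-profile CSVs and a reproducibility
# manifest; plus cross-run profile comparison.
#
# Configurations are plain R lists, or JSON files with the same shape.
# Exactly one of `input` (recordings dir + labels + map on disk) or
# `simulate` (a synthetic_cohort_spec argument list) must be present.

#' Load a run configuration
#'
#' @param config a named list, or path to a JSON file.
#' @return The validated configuration list.
#' @export
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim)
    stop("config must contain exactly one of 'input' or 'simulate'",
         call. = FALSE)
  config$features <- utils::modifyList(
    list(sigma = 12, source_kind = "position",
         velocity_filter = "butterworth", trim = NULL),
    config$features %||% list())
  config$decoding <- utils::modifyList(
    list(targets = "gender", families = "svm", k = 5, seed = 1,
         split = "random"),
    config$decoding %||% list())
  config
}

run_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf("[kinedecode] %s", sprintf(fmt, ...)))
}

#' Run the full decoding pipeline
#'
#' Executes io -> kinematics -> features -> decoding -> joint importance
#' for every requested (target, family) pair and writes the artifacts
#' into `out_dir`: `features.tsv`, `evaluations.csv` (tidy: target,
#' family, fold, metric, value; fold 0 = mean), `profiles.csv`, and
#' `manifest.json` (seed, config hash, fold assignment).
#'
#' @param config list or JSON path accepted by [load_run_config()].
#' @param out_dir output directory; created if needed.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the dataset, evaluations, profiles and
#'   artifact paths.
#' @export
run_decoding <- function(config, out_dir = NULL, quiet = FALSE) {
  config <- load_run_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("no output directory given",
                                                   call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fo <- config$features

  if (!is.null(config$simulate)) {
    run_log(quiet, "simulating cohort")
    spec <- do.call(synthetic_cohort_spec, config$simulate)
    map <- default_joint_map()
    data <- cohort_dataset(spec, map, source_kind = fo$source_kind,
                           velocity_filter = fo$velocity_filter,
                           sigma = fo$sigma)
    dataset_tag <- sprintf("sim%d", spec$seed)
  } else {
    inp <- config$input
    map <- if (is.null(inp$map)) default_joint_map()
           else read_marker_joint_map(inp$map)
    labels <- utils::read.csv(inp$labels, stringsAsFactors = FALSE)
    files <- sort(list.files(inp$recordings, pattern = "\\.tsv$",
                             full.names = TRUE))
    if (!length(files)) stop("no .tsv recordings found", call. = FALSE)
    run_log(quiet, "extracting features from %d recordings", length(files))
    X <- NULL; part <- character(0); stim <- character(0)
    for (f in files) {
      rec <- tryCatch({
        r <- read_marker_recording(f)
        ids <- strsplit(tools::file_path_sans_ext(basename(f)), "_")[[1]]
        r$participant_id <- ids[1]
        r$stimulus_id <- paste(ids[-1], collapse = "_")
        if (!is.null(fo$trim)) r <- trim_to_window(r, fo$trim[1], fo$trim[2])
        fill_gaps(r)
      }, error = function(e)
        stop(sprintf("stage io [%s]: %s", basename(f), conditionMessage(e)),
             call. = FALSE))
      fv <- tryCatch(
        extract_features(rec, map, source_kind = fo$source_kind,
                         velocity_filter = fo$velocity_filter,
                         sigma = fo$sigma),
        error = function(e)
          stop(sprintf("stage features [%s]: %s", basename(f),
                       conditionMessage(e)), call. = FALSE))
      X <- rbind(X, fv$values)
      part <- c(part, rec$participant_id)
      stim <- c(stim, rec$stimulus_id)
    }
    data <- labeled_dataset(X, part, stim, labels)
    dataset_tag <- basename(normalizePath(inp$recordings))
  }

  write_feature_table(data, file.path(out_dir, "features.tsv"))
  dec <- config$decoding
  groups <- if (identical(dec$split, "grouped")) data$sample_ids$participant
  folds <- make_folds(nrow(data$features), k = dec$k, seed = dec$seed,
                      groups = groups)
  evals <- list(); profiles <- list()
  for (target in dec$targets) {
    for (family in dec$families) {
      if ((family == "svm") != (target == "gender")) next
      run_log(quiet, "decoding %s with %s", target, family)
      res <- crossval_experiment(data, target, family, folds)
      evals[[paste(target, family, sep = ".")]] <- res$evaluation
      ji <- joint_importance(res$models, map, target_name = target,
                             dataset_tag = dataset_tag)
      profiles <- c(profiles, unname(ji))
    }
  }
  write_evaluations(evals, file.path(out_dir, "evaluations.csv"))
  write_importance_profiles(profiles, file.path(out_dir, "profiles.csv"))

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               null = "null", force = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(seed = dec$seed, config = config,
                   config_hash = unname(tools::md5sum(tf)),
                   fold_assignment = folds$fold_index,
                   n_samples = nrow(data$features),
                   n_features = ncol(data$features),
                   package_version = as.character(utils::packageVersion("kinedecode")))
  unlink(tf)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  run_log(quiet, "artifacts written to %s", out_dir)
  invisible(list(data = data, evaluations = evals, profiles = profiles,
                 out_dir = out_dir))
}

#' Write a tidy evaluation CSV
#'
#' Long format: `target, family, fold, metric, value`; fold 0 carries the
#' cross-fold means.
#'
#' @param evals list of evaluation objects from [crossval_experiment()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_evaluations <- function(evals, path) {
  rows <- lapply(evals, function(ev) {
    if (inherits(ev, "classification_evaluation")) {
      data.frame(target = ev$target_name, family = ev$family,
                 fold = c(seq_len(ev$k), 0L), metric = "accuracy",
                 value = c(ev$per_fold_accuracy, ev$mean_accuracy))
    } else {
      data.frame(target = ev$target_name, family = ev$family,
                 fold = rep(c(seq_len(ev$k), 0L), 2),
                 metric = rep(c("r2", "rmse"), each = ev$k + 1L),
                 value = c(ev$per_fold_r2, ev$mean_r2,
                           ev$per_fold_rmse, ev$mean_rmse))
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Persist a feature dataset as TSV
#'
#' One row per (participant, stimulus); feature columns `e0001..eNNNN`.
#'
#' @param data a [labeled_dataset()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path) {
  stopifnot(inherits(data, "labeled_dataset"))
  X <- data$features
  colnames(X) <- sprintf("e%04d", seq_len(ncol(X)))
  df <- cbind(data$sample_ids, as.data.frame(X))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare importance profiles across runs
#'
#' Reads one or more `profiles.csv` files, keeps the shared granularity
#' (default `paired12`), and produces all pairwise Spearman correlations,
#' one Ward dendrogram and one 3-D classical MDS embedding. With
#' `out_dir` set, writes `spearman.csv`, `merges.csv` and
#' `mds_coordinates.csv`.
#'
#' @param profile_files character vector of CSV paths from
#'   [write_importance_profiles()].
#' @param granularity which profile granularity to compare.
#' @param out_dir optional output directory for the comparison CSVs.
#' @return A list with `set`, `spearman`, `dendrogram`, `embedding`.
#' @export
compare_profiles <- function(profile_files, granularity = "paired12",
                             out_dir = NULL) {
  profs <- list()
  for (f in profile_files) {
    ps <- read_importance_profiles(f)
    profs <- c(profs, Filter(function(p) p$granularity == granularity, ps))
  }
  if (length(profs) < 2)
    stop("need at least two profiles at the requested granularity",
         call. = FALSE)
  set <- profile_set(profs)
  sp <- profile_spearman_matrix(set)
  dd <- ward_dendrogram(set)
  em <- mds_embed(set, ndim = 3)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(sp$r, file.path(out_dir, "spearman.csv"))
    utils::write.csv(dd$merges, file.path(out_dir, "merges.csv"),
                     row.names = FALSE)
    utils::write.csv(em$coordinates, file.path(out_dir, "mds_coordinates.csv"))
  }
  list(set = set, spearman = sp, dendrogram = dd, embedding = em)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `run-all`, `decode`, `compare`. Invoked by the
#' `exec/kinedecode` script; callable directly with an argument vector
#' for testing.
#'
#' @param args character vector of command-line arguments.
#' @return Exit status, invisibly.
#' @export
kd_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: kinedecode <command> [options]",
    "  simulate --out DIR [--seed N] [--dancers N] [--stimuli N] [--duration S] [--rate HZ]",
    "  features --recordings DIR --out F.tsv [--map CFG] [--source position|velocity] [--filter butterworth|savgol] [--sigma S]",
    "  run-all  --config CFG.json [--out DIR] [--quiet]",
    "  decode   --features F.tsv --labels L.csv --target T --family F [--k K] [--seed N] [--split random|grouped] --out DIR",
    "  compare  --profiles A.csv[,B.csv...] --out DIR [--granularity G]",
    sep = "\n")
  if (!length(args)) { cat(usage, "\n"); return(invisible(1L)) }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  quiet <- isTRUE(opts$quiet)
  switch(cmd,
    simulate = {
      spec <- synthetic_cohort_spec(
        n_dancers = as.integer(opts$dancers %||% 60),
        n_stimuli = as.integer(opts$stimuli %||% 4),
        duration = as.numeric(opts$duration %||% 30),
        sampling_rate = as.numeric(opts$rate %||% 60),
        seed = as.integer(opts$seed %||% 1))
      run_log(quiet, "generating cohort into %s", opts$out)
      write_cohort(generate_cohort(spec), opts$out)
    },
    features = {
      map <- if (is.null(opts$map)) default_joint_map()
             else read_marker_joint_map(opts$map)
      files <- sort(list.files(opts$recordings, pattern = "\\.tsv$",
                               full.names = TRUE))
      if (!length(files)) stop("no .tsv recordings found", call. = FALSE)
      X <- NULL; part <- character(0); stim <- character(0)
      for (f in files) {
        rec <- read_marker_recording(f)
        ids <- strsplit(tools::file_path_sans_ext(basename(f)), "_")[[1]]
        rec$participant_id <- ids[1]
        rec$stimulus_id <- paste(ids[-1], collapse = "_")
        fv <- extract_features(
          fill_gaps(rec), map,
          source_kind = opts$source %||% "position",
          velocity_filter = opts$filter %||% "butterworth",
          sigma = as.numeric(opts$sigma %||% 12))
        X <- rbind(X, fv$values)
        part <- c(part, rec$participant_id)
        stim <- c(stim, rec$stimulus_id)
      }
      X <- as.matrix(X)
      colnames(X) <- sprintf("e%04d", seq_len(ncol(X)))
      df <- cbind(data.frame(participant = part, stimulus = stim), X)
      utils::write.table(df, opts$out, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      run_log(quiet, "wrote %d feature rows to %s", nrow(df), opts$out)
    },
    `run-all` = {
      run_decoding(opts$config, out_dir = opts$out, quiet = quiet)
    },
    decode = {
      tab <- utils::read.delim(opts$features, stringsAsFactors = FALSE)
      fcols <- grep("^e[0-9]+$", names(tab))
      data <- labeled_dataset(as.matrix(tab[, fcols]), tab$participant,
                              tab$stimulus,
                              utils::read.csv(opts$labels,
                                              stringsAsFactors = FALSE))
      groups <- if (identical(opts$split, "grouped"))
        data$sample_ids$participant
      folds <- make_folds(nrow(data$features),
                          k = as.integer(opts$k %||% 5),
                          seed = as.integer(opts$seed %||% 1),
                          groups = groups)
      res <- crossval_experiment(data, opts$target, opts$family, folds)
      dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
      write_evaluations(stats::setNames(list(res$evaluation), opts$target),
                        file.path(opts$out, "evaluations.csv"))
      ji <- joint_importance(res$models, default_joint_map(),
                             target_name = opts$target)
      write_importance_profiles(unname(ji),
                                file.path(opts$out, "profiles.csv"))
      if (!quiet) print(res$evaluation)
    },
    compare = {
      files <- strsplit(opts$profiles, ",")[[1]]
      compare_profiles(files, granularity = opts$granularity %||% "paired12",
                       out_dir = opts$out)
    },
    { cat(usage, "\n"); return(invisible(1L)) })
  invisible(0L)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop(sprintf("unexpected argument '%s'", a),
                                   call. = FALSE)
    key <- substring(a, 3)
    if (key %in% c("quiet", "verbose")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args)) stop(sprintf("--%s needs a value", key),
                                  call. = FALSE)
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}
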