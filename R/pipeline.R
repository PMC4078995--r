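#' Study configuration
#'
#' Bundles every stage's tunables for [run_pipeline()]. Exactly one input
#' source is used: a simulation spec (`simulate`), a long-form raw recording
#' (`input_long`), or a precomputed feature table (`input_features`).
#'
#' @param simulate an [fnirs_sim_spec()] (e.g. [preset_paperlike()]), or
#'   `NULL`.
#' @param input_long path to a long-form TSV (see [read_fnirs_long()]), or
#'   `NULL`.
#' @param input_features path to a feature-table TSV, or `NULL`.
#' @param preprocessing a [preproc_config()].
#' @param k outer CV folds.
#' @param C soft-margin cost.
#' @param seed root seed; every stage's randomness derives from it.
#' @param top top-K subsets retained per search.
#' @param q FDR level of the channel screen.
#' @param unit unit of analysis for the screen (`"trial"`/`"participant"`).
#' @param run_bilateral run the full D = 24 exhaustive search (2^24 - 1
#'   subsets; hours-scale). Off by default; the two D = 12 hemispheric
#'   searches always run.
#' @param positive_label see [fnirs_features()].
#' @param checkpoint_dir optional directory for search checkpoints.
#' @return a `study_config` list.
#' @export
study_config <- function(simulate = preset_paperlike(), input_long = NULL,
                         input_features = NULL,
                         preprocessing = preproc_config(), k = 5, C = 1,
                         seed = 1, top = 50, q = 0.05, unit = "trial",
                         run_bilateral = FALSE, positive_label = NULL,
                         checkpoint_dir = NULL) {
  stopifnot(k >= 2)
  structure(list(simulate = simulate, input_long = input_long,
                 input_features = input_features,
                 preprocessing = preprocessing, k = k, C = C, seed = seed,
                 top = top, q = q, unit = unit,
                 run_bilateral = run_bilateral,
                 positive_label = positive_label,
                 checkpoint_dir = checkpoint_dir),
            class = "study_config")
}

#' Run the full classification study
#'
#' End-to-end driver: obtain trials (simulate or read), preprocess to mean-Z
#' features, run the exhaustive channel-subset searches (left and right
#' hemispheres; optionally the full bilateral set), evaluate the LASSO and
#' sparse-logistic comparators on the same folds and rank them within each
#' exhaustive accuracy distribution, and run the channel-wise t-test screen.
#'
#' @param config a [study_config()].
#' @return object of class `study_report`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(study_config(simulate = preset_paperlike(), seed = 1))
#' rep$summary
#' }
#' @export
run_pipeline <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  stage <- "input"
  report <- tryCatch({
    features <- NULL
    qc <- NULL
    if (!is.null(config$input_features)) {
      features <- readr::read_tsv(config$input_features,
                                  show_col_types = FALSE)
      if (!is.null(config$positive_label) || !is.numeric(features$label)) {
        features$label <- encode_labels(features$label,
                                        config$positive_label)
      }
    } else {
      long <- if (!is.null(config$input_long)) {
        read_fnirs_long(config$input_long)
      } else if (!is.null(config$simulate)) {
        simulate_fnirs_trials(config$simulate, seed = config$seed)$trials
      } else {
        stop("study_config names no input source", call. = FALSE)
      }
      stage <- "preprocess"
      features <- fnirs_features(long, config$preprocessing,
                                 positive_label = config$positive_label)
      qc <- attr(features, "qc")
    }
    stage <- "study"
    fnirs_study(features, config = config, qc = qc)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  report
}

#' Exhaustive-search study on a ready feature table
#'
#' The analysis core behind [run_pipeline()], for when features are already
#' in hand.
#'
#' @param features_df feature table ([fnirs_features()] shape).
#' @param config a [study_config()] (input fields ignored).
#' @param qc optional QC table to embed in the report.
#' @return a `study_report`: `summary` (dataset description), `searches`
#'   (named list of `channel_search`), `optimal` / `occurrence` / `signs`
#'   tables per channel set, `comparators` tibble with percentile ranks,
#'   `screen` table, and `provenance`.
#' @export
fnirs_study <- function(features_df, config = study_config(), qc = NULL) {
  fm <- features_matrix(features_df)
  sets <- list(left = "left", right = "right")
  if (config$run_bilateral) sets$bilateral <- "bilateral"

  folds <- kfold_assign(fm$t, k = config$k, seed = config$seed)
  ckpt <- function(name) {
    if (is.null(config$checkpoint_dir)) NULL
    else file.path(config$checkpoint_dir, paste0("search-", name, ".tsv"))
  }

  searches <- lapply(names(sets), function(nm) {
    channel_search(features_df, channels = sets[[nm]], k = config$k,
                   C = config$C, folds = folds, top = config$top,
                   checkpoint = ckpt(nm))
  })
  names(searches) <- names(sets)

  comparators <- dplyr::bind_rows(lapply(names(sets), function(nm) {
    ids <- resolve_search_channels(sets[[nm]], fm$channel_ids)
    sub_df <- features_df[c("label",
                            intersect(names(features_df),
                                      sprintf("ch%02d", ids)))]
    dplyr::bind_rows(lapply(c("lasso", "slr"), function(m) {
      res <- comparator_cv(sub_df, method = m, folds = folds,
                           seed = config$seed)
      pr <- percentile_rank(res$accuracy, searches[[nm]])
      tibble::tibble(channel_set = nm, method = m,
                     accuracy = res$accuracy,
                     n_selected = length(res$selected_channels),
                     selected = list(res$selected_channels),
                     rank = pr$rank, n_subsets = pr$n,
                     top_fraction = pr$top_fraction)
    }))
  }))

  screen <- channel_screen(features_df, q = config$q, unit = config$unit)

  summary <- tibble::tibble(
    n_trials = nrow(features_df),
    n_pos = sum(fm$t == 1), n_neg = sum(fm$t == -1),
    n_channels = length(fm$channel_ids),
    n_rejected = if (is.null(qc)) NA_integer_ else sum(!qc$retained)
  )

  structure(list(
    summary = summary,
    searches = searches,
    optimal = lapply(searches, optimal_subsets),
    occurrence = lapply(searches, channel_occurrence),
    signs = lapply(searches, sign_consistency),
    comparators = comparators,
    screen = screen,
    features = features_df,
    qc = qc,
    provenance = list(seed = config$seed, k = config$k, C = config$C,
                      top = config$top, q = config$q,
                      config_hash = rlang::hash(unclass(config)),
                      package_version =
                        as.character(utils::packageVersion("fnirselect")))
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("fNIRS two-group study: N = %d trials (%d / %d), D = %d channels\n",
              s$n_trials, s$n_pos, s$n_neg, s$n_channels))
  for (nm in names(x$searches)) {
    g <- glance(x$searches[[nm]])
    cat(sprintf("  %-9s search: best %.1f%% (|A| = %d, %d co-optimal), all-channels %.1f%%\n",
                nm, g$best_accuracy, g$best_size, g$n_optimal,
                g$all_channel_accuracy))
  }
  for (i in seq_len(nrow(x$comparators))) {
    cm <- x$comparators[i, ]
    cat(sprintf("  %-9s %-5s: %.1f%% (rank %d of %d, top %.2f%%)\n",
                cm$channel_set, toupper(cm$method), cm$accuracy, cm$rank,
                cm$n_subsets, 100 * cm$top_fraction))
  }
  nsig <- sum(x$screen$significant[x$screen$test == "two_sample"])
  cat(sprintf("  channel screen: %d FDR-significant group difference(s)\n",
              nsig))
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits a JSON summary plus TSV tables (ranked subsets, top-K weight
#' matrices, occurrence/sign tables, comparator table, screen table).
#'
#' @param report a `study_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$searches)) {
    sr <- report$searches[[nm]]
    readr::write_tsv(tidy(sr), file.path(dir, paste0("ranked-", nm, ".tsv")))
    W <- tibble::as_tibble(sr$top_weights)
    readr::write_tsv(dplyr::bind_cols(sr$top[c("rank", "mask", "accuracy")], W),
                     file.path(dir, paste0("top-weights-", nm, ".tsv")))
    readr::write_tsv(report$occurrence[[nm]],
                     file.path(dir, paste0("occurrence-", nm, ".tsv")))
    readr::write_tsv(report$signs[[nm]],
                     file.path(dir, paste0("signs-", nm, ".tsv")))
  }
  readr::write_tsv(dplyr::select(report$comparators, -"selected"),
                   file.path(dir, "comparators.tsv"))
  readr::write_tsv(report$screen, file.path(dir, "screen.tsv"))
  if (!is.null(report$qc)) {
    readr::write_tsv(report$qc, file.path(dir, "qc.tsv"))
  }
  json <- list(
    summary = as.list(report$summary),
    searches = lapply(report$searches, function(s) as.list(glance(s))),
    optimal = lapply(report$optimal, function(o) {
      o$channels <- vapply(o$channels, paste, character(1), collapse = ",")
      o
    }),
    comparators = dplyr::select(report$comparators, -"selected"),
    provenance = report$provenance
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
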