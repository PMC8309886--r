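# Pattern-bank persistence and run repository.
#
# A recognition pattern is a trained model (SVM or ANFIS) together with its
# feature-pattern id and keys and creation metadata. Patterns live in the
# `patt_bank` folder of a run repository whose layout mirrors the tracking
# dataflow: `data_log` (input features), `patt_bank` (patterns), `out_log`
# (recognition output), `fig_log` (traceable-diagram data).

.BANK_FORMAT_VERSION <- 1L

#' Create (or open) a run repository
#'
#' @param root directory; the four subfolders are created if absent.
#' @return The root path, invisibly, with class `rehab_repository`.
#' @export
init_repository <- function(root) {
  for (d in c("data_log", "patt_bank", "out_log", "fig_log")) {
    dir.create(file.path(root, d), recursive = TRUE, showWarnings = FALSE)
  }
  invisible(structure(root, class = "rehab_repository"))
}

#' Build a pattern-bank entry
#'
#' @param model a trained `svm_model` or `fis`.
#' @param pattern_id feature pattern id (1..15).
#' @param subject subject tag used in the artifact name.
#' @param seed the seed the training run used.
#' @param timestamp creation time (default now, UTC).
#' @return A list of class `pattern_entry`.
#' @export
pattern_entry <- function(model, pattern_id, subject = "anon", seed = NA_integer_,
                          timestamp = format(Sys.time(), "%Y%m%d%H%M%S", tz = "UTC")) {
  model_type <- if (inherits(model, "svm_model")) "svm"
                else if (inherits(model, "fis")) "anfis"
                else stop("model must be an svm_model or a fis", call. = FALSE)
  keys <- feature_patterns()[[as.character(pattern_id)]]
  if (is.null(keys)) stop("unknown pattern_id", call. = FALSE)
  structure(list(pattern_id = as.integer(pattern_id), keys = keys,
                 model_type = model_type, model = model,
                 subject = subject, seed = seed, timestamp = timestamp,
                 version = .BANK_FORMAT_VERSION),
            class = "pattern_entry")
}

# artifact name: subject + timestamp + pattern index + model type
.entry_filename <- function(entry) {
  sprintf("%s_%s_p%02d_%s.rds", entry$subject, entry$timestamp,
          entry$pattern_id, entry$model_type)
}

#' Save / load a recognition pattern
#'
#' Patterns are serialized as a versioned single-file artifact in the
#' `patt_bank` folder; the file name embeds subject tag, timestamp, pattern
#' index and model type. Saving over an existing entry is rejected unless
#' `overwrite = TRUE`; loading validates the format version and structure.
#'
#' @param entry a [pattern_entry()].
#' @param bank_dir the `patt_bank` directory (or a repository root
#'   containing one).
#' @param overwrite allow replacing an existing file.
#' @return `save_pattern` returns the file path invisibly; `load_pattern`
#'   returns the `pattern_entry`.
#' @export
save_pattern <- function(entry, bank_dir, overwrite = FALSE) {
  stopifnot(inherits(entry, "pattern_entry"))
  if (dir.exists(file.path(bank_dir, "patt_bank"))) {
    bank_dir <- file.path(bank_dir, "patt_bank")
  }
  path <- file.path(bank_dir, .entry_filename(entry))
  if (file.exists(path) && !overwrite) {
    stop("pattern entry already exists: ", basename(path), call. = FALSE)
  }
  saveRDS(entry, path)
  invisible(path)
}

#' @rdname save_pattern
#' @param path file to load.
#' @export
load_pattern <- function(path) {
  if (!file.exists(path)) stop("no such pattern file: ", path, call. = FALSE)
  entry <- tryCatch(readRDS(path),
                    error = function(e) stop("corrupted pattern file: ", path,
                                             call. = FALSE))
  if (!inherits(entry, "pattern_entry") ||
      !identical(entry$version, .BANK_FORMAT_VERSION) ||
      is.null(entry$model)) {
    stop("invalid or incompatible pattern file: ", path, call. = FALSE)
  }
  entry
}

#' Recognize segments with a stored pattern
#'
#' Selects the entry's feature keys from a feature table and applies its
#' model.
#'
#' @param entry a [pattern_entry()].
#' @param features a [feature_table()] data.frame.
#' @return data.frame with `true` (from `ex_id`, may be `NA`), `label`,
#'   and for the ANFIS the `crisp` output.
#' @export
recognize <- function(entry, features) {
  stopifnot(inherits(entry, "pattern_entry"), is.data.frame(features))
  X <- features[, entry$keys, drop = FALSE]
  true <- if ("ex_id" %in% names(features)) features$ex_id else NA_integer_
  if (entry$model_type == "svm") {
    p <- predict_svm(entry$model, X)
    data.frame(true = true, label = p$label)
  } else {
    crisp <- suppressWarnings(predict_anfis(entry$model, X))
    lab <- rep(NA_integer_, length(crisp))
    ok <- is.finite(crisp)
    lab[ok] <- crisp_to_label(crisp[ok])
    data.frame(true = true, label = lab, crisp = crisp)
  }
}

#' Run configuration
#'
#' Reads and validates the pipeline configuration (YAML), supplying
#' defaults for any missing field.
#'
#' @param path YAML file, or `NULL` for all defaults.
#' @param overrides named list overriding file values (CLI flags).
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    sample_rate = 100,
    reference_window = 0.5,
    convention = "included",
    n_per_exercise = 65,
    pattern_id = 3,
    model = "svm",
    k_folds = 5,
    seed = 1L,
    repository = "rehab_runs",
    subject = "synthA"
  )
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg[names(overrides)] <- overrides
  stopifnot(cfg$sample_rate > 0, cfg$reference_window > 0,
            cfg$convention %in% c("included", "projected"),
            cfg$n_per_exercise >= 1,
            cfg$pattern_id %in% 1:15,
            cfg$model %in% c("svm", "anfis"),
            cfg$k_folds >= 2)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}
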