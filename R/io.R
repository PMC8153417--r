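TRIAL_LOG_COLUMNS <- c("subject_id", "session", "trial", "is_pretraining",
                       "goal", "uncertainty", "s1", "a1", "s2", "a2",
                       "s_outcome", "reward")

#' Write a trial log CSV
#'
#' One row per trial; comma-separated, UTF-8, header required; actions as
#' symbolic labels (`L`/`R`), states as string ids, numbers at full
#' precision.
#'
#' @param trials trial-log data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path) {
  miss <- setdiff(TRIAL_LOG_COLUMNS, names(trials))
  if (length(miss)) stop("trial log missing column(s): ",
                         paste(miss, collapse = ", "))
  write.csv(trials[, TRIAL_LOG_COLUMNS], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read and validate a trial log CSV
#'
#' Validates the schema, duplicate (subject, session, trial) keys, monotone
#' trial indices within each session, and -- when a graph is supplied --
#' the consistency of every logged transition with the successor map.
#' Errors name the offending row.
#'
#' @param path CSV file written by [write_trial_log()] (or produced
#'   externally in the same dialect).
#' @param graph optional `"task_graph"` for transition validation.
#' @return Trial-log data.frame ordered as on file.
#' @export
read_trial_log <- function(path, graph = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  trials <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(trials) == 0) stop("no trials in ", path)
  miss <- setdiff(TRIAL_LOG_COLUMNS, names(trials))
  if (length(miss)) stop("trial log missing column(s): ",
                         paste(miss, collapse = ", "))
  trials$is_pretraining <- as.logical(trials$is_pretraining)
  key <- paste(trials$subject_id, trials$session, trials$trial)
  if (anyDuplicated(key))
    stop("duplicate (subject, session, trial) at row ",
         which(duplicated(key))[1])
  for (grp in split(seq_len(nrow(trials)),
                    paste(trials$subject_id, trials$session))) {
    tr <- trials$trial[grp]
    if (any(diff(tr) <= 0))
      stop("non-monotone trial indices at row ", grp[which(diff(tr) <= 0)[1] + 1])
  }
  if (!is.null(graph)) {
    enc <- encode_trials(trials, graph)
    for (i in seq_len(nrow(trials))) {
      ok1 <- tryCatch({successor_index(graph, enc$s1[i], enc$a1[i], enc$s2[i]);
        TRUE}, error = function(e) FALSE)
      ok2 <- tryCatch({successor_index(graph, enc$s2[i], enc$a2[i],
                                       enc$sout[i]); TRUE},
                      error = function(e) FALSE)
      if (!ok1 || !ok2)
        stop("inconsistent transition at row ", i, ": ",
             if (!ok1) paste0(trials$s2[i], " not a successor of (",
                              trials$s1[i], ", ", trials$a1[i], ")")
             else paste0(trials$s_outcome[i], " not a successor of (",
                         trials$s2[i], ", ", trials$a2[i], ")"))
    }
  }
  trials
}

#' Read a task configuration file (YAML or JSON)
#'
#' Entries present in the file override the [task_config()] defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `"task_config"`.
#' @export
read_task_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(raw$coin_values)) raw$coin_values <- unlist(raw$coin_values)
  do.call(task_config, raw)
}

#' Write a fit result as JSON
#'
#' @param fit a `"fit_result"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  x <- unclass(fit)
  x$par <- as.list(x$par)  # keep parameter names in the JSON object
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fit result written by [write_fit_result()]
#'
#' @param path JSON file.
#' @return A `"fit_result"`.
#' @export
read_fit_result <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  x$par <- unlist(x$par)
  structure(x, class = "fit_result")
}

#' Write per-trial latent variables as JSON lines
#'
#' One JSON object per trial with the arbitration latents: `spe`, `rpe`,
#' `chi_mb`, `chi_mf`, `p_mb`, `tau`, `action_probs` (probability of the
#' right action at each decision).
#'
#' @param latents latents data.frame from [simulate_subject()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_latents_jsonl <- function(latents, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(latents))) {
    l <- latents[i, ]
    obj <- list(subject_id = l$subject_id, session = l$session,
                trial = l$trial, spe = c(l$spe1, l$spe2),
                rpe = c(l$rpe1, l$rpe2), chi_mb = l$chi_mb,
                chi_mf = l$chi_mf, p_mb = l$p_mb, tau = c(l$tau1, l$tau2),
                action_probs = c(l$p_right1, l$p_right2))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
  invisible(path)
}

#' Write structured results to a directory
#'
#' Deterministic file naming: fit results as one JSON per subject-model,
#' comparison and measure tables as CSV, plus a run-metadata JSON capturing
#' the seed and package version.
#'
#' @param results named list; supported elements: `fits` (list of
#'   `"fit_result"`), `comparison` (a `"model_comparison"`), `measures` /
#'   `manifest` (data.frames), `logs` (trial log), `latents`.
#' @param out_dir output directory (created if missing).
#' @param seed seed recorded in the metadata.
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(results, out_dir, seed = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  add <- function(p) written <<- c(written, p)
  if (!is.null(results$fits)) {
    for (f in results$fits) {
      p <- file.path(out_dir, paste0("fit_", f$subject_id, "_", f$model,
                                     ".json"))
      write_fit_result(f, p); add(p)
    }
  }
  if (!is.null(results$comparison)) {
    p <- file.path(out_dir, "model_comparison.csv")
    write.csv(results$comparison$table, p, row.names = FALSE); add(p)
  }
  for (nm in c("measures", "manifest")) {
    if (!is.null(results[[nm]])) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      write.csv(results[[nm]], p, row.names = FALSE); add(p)
    }
  }
  if (!is.null(results$logs)) {
    p <- file.path(out_dir, "trials.csv")
    write_trial_log(results$logs, p); add(p)
  }
  if (!is.null(results$latents)) {
    p <- file.path(out_dir, "latents.jsonl")
    write_latents_jsonl(results$latents, p); add(p)
  }
  meta <- list(package = "arbrl",
               version = as.character(packageVersion("arbrl")),
               seed = seed, timestamp = format(Sys.time(), tz = "UTC"))
  p <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, p, auto_unbox = TRUE); add(p)
  invisible(written)
}
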