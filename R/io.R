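# CSV trial-log serialization and configuration loading.

#' Write a trial log to CSV
#'
#' The header matches the trial-log field names exactly; session metadata is
#' stored in leading \code{#}-prefixed comment lines and restored by
#' \code{\link{read_trial_log}}.
#'
#' @param log a \code{trial_log}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trial_log <- function(log, path) {
  stopifnot(inherits(log, "trial_log"))
  meta <- attr(log, "meta")
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta))
    writeLines(paste0("# ", names(meta), ": ",
                      vapply(meta, function(v) paste(format(v), collapse = " "),
                             character(1))), con)
  utils::write.csv(as.data.frame(log), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial log from CSV
#'
#' @param path CSV file written by \code{\link{write_trial_log}} (or any CSV
#'   with the documented columns).
#' @return A \code{trial_log}; schema violations raise line-identified
#'   validation errors.
#' @export
read_trial_log <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- list()
  if (length(meta_lines)) {
    kv <- sub("^# *", "", lines[meta_lines])
    keys <- sub(":.*$", "", kv)
    vals <- sub("^[^:]*: *", "", kv)
    meta <- stats::setNames(as.list(vals), keys)
    for (k in names(meta)) {
      num <- suppressWarnings(as.numeric(meta[[k]]))
      if (!is.na(num)) meta[[k]] <- num
    }
  }
  df <- utils::read.csv(text = lines[setdiff(seq_along(lines), meta_lines)],
                        stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_log_columns, names(df))
  if (length(missing_cols))
    stop_validation(path, ": missing column(s): ",
                    paste(missing_cols, collapse = ", "))
  for (col in c("accepted", "is_choice", "rewarded", "forced"))
    df[[col]] <- as.logical(df[[col]])
  for (col in c("trial_index", "block_index", "encounter_index"))
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  bad <- which(is.na(df$trial_index) | is.na(df$block_index) |
               is.na(df$encounter_index) | is.na(df$accepted) |
               is.na(df$is_choice) | is.na(df$rewarded) | is.na(df$odor_id))
  if (length(bad))
    stop_validation(path, ": malformed value(s) at data line(s) ",
                    paste(utils::head(bad, 5L), collapse = ", "))
  trial_log(df, meta = meta)
}

config_defaults <- function() {
  list(task = list(blocks = data.frame(n_trials = 80L,
                                       p_A = c(0.8, 0.2, 0.8),
                                       p_B = c(0.2, 0.8, 0.2)),
                   baiting = TRUE, n_odors = 2L),
       rule = list(variant = "both", eta = -0.3, tau_r = 3.5, tau_s = 3.5),
       ensemble = list(n_kc = 100L, active_fraction = 0.1, overlap = 0,
                       noise_sd = 0))
}

#' Load a simulation configuration
#'
#' Reads a YAML or JSON file with optional top-level sections \code{task},
#' \code{rule}, \code{ensemble}; omitted fields take the documented defaults,
#' unknown keys are rejected.
#'
#' @param path config file (\code{.yaml}/\code{.yml}/\code{.json}); an empty
#'   or absent-section file yields the full defaults.
#' @return list with \code{task} (a \code{task_config}), \code{rule} (a
#'   \code{plasticity_rule}), \code{ensemble} (a \code{kc_ensemble}).
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  raw <- raw %||% list()
  unknown <- setdiff(names(raw), c("task", "rule", "ensemble"))
  if (length(unknown))
    stop_validation("unknown config section(s): ", paste(unknown, collapse = ", "))
  def <- config_defaults()
  merge_section <- function(section) {
    user <- raw[[section]] %||% list()
    extra <- setdiff(names(user), names(def[[section]]))
    if (length(extra))
      stop_validation("unknown key(s) in '", section, "': ",
                      paste(extra, collapse = ", "))
    utils::modifyList(def[[section]], user)
  }
  task <- merge_section("task")
  rule <- merge_section("rule")
  ens <- merge_section("ensemble")
  list(task = task_config(as.data.frame(task$blocks), task$baiting, task$n_odors),
       rule = plasticity_rule(rule$variant, rule$eta, rule$tau_r, rule$tau_s),
       ensemble = kc_ensemble(ens$n_kc, ens$active_fraction, ens$overlap,
                              ens$noise_sd))
}
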