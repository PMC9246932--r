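## Table I/O, flat config files, and the generate -> clean -> analyse ->
## report pipeline ------------------------------------------------------------

SUBJECT_COLS <- c("subject_id", "group", "age_years", "sex", "piq", "viq", "fsiq")
TRIAL_COLS <- c("subject_id", "block", "trial_idx", "condition", "isi_ms",
                "rt_ms", "n_presses")

## Column shim for externally exported tables with differing headers.
TRIAL_COL_ALIASES <- c(Subject = "subject_id", subj = "subject_id",
                       Block = "block", Trial = "trial_idx",
                       Condition = "condition", Stimulus = "condition",
                       ISI = "isi_ms", RT = "rt_ms", rt = "rt_ms",
                       presses = "n_presses")
SUBJECT_COL_ALIASES <- c(Subject = "subject_id", subj = "subject_id",
                         Group = "group", Diagnosis = "group",
                         Age = "age_years", Sex = "sex",
                         PIQ = "piq", VIQ = "viq", FSIQ = "fsiq")

apply_aliases <- function(df, aliases) {
  hit <- names(df) %in% names(aliases)
  names(df)[hit] <- aliases[names(df)[hit]]
  df
}

#' Read and validate a trial table
#'
#' Comma-separated, UTF-8, header row. Required columns: `subject_id`,
#' `block`, `trial_idx`, `condition` (A/V/AV), `isi_ms`, `rt_ms` (empty =
#' miss), `n_presses`. A small alias shim maps common export headers onto
#' this schema. Violations are rejected naming the offending row and value.
#'
#' @param path File path.
#' @return A validated data frame.
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- apply_aliases(df, TRIAL_COL_ALIASES)
  missing <- setdiff(TRIAL_COLS, names(df))
  if (length(missing)) {
    stop_invalid("trial table missing column(s): %s", paste(missing, collapse = ", "))
  }
  validate_trial_table(df[, TRIAL_COLS])
}

#' @rdname read_trial_table
#' @param trials A candidate trial table.
#' @export
validate_trial_table <- function(trials) {
  bad <- which(!trials$condition %in% CONDITIONS)
  if (length(bad)) {
    stop_invalid("unknown condition label '%s' in trial row %d",
                 trials$condition[bad[1]], bad[1])
  }
  bad <- which(!is.na(trials$isi_ms) & trials$isi_ms <= 0)
  if (length(bad)) {
    stop_invalid("non-positive ISI (%s ms) in trial row %d",
                 format(trials$isi_ms[bad[1]]), bad[1])
  }
  bad <- which(!is.na(trials$rt_ms) & trials$rt_ms <= 0)
  if (length(bad)) {
    stop_invalid("non-positive RT (%s ms) in trial row %d",
                 format(trials$rt_ms[bad[1]]), bad[1])
  }
  trials
}

#' Read and validate a subject table
#'
#' Required columns: `subject_id`, `group` (NT/ASD), `age_years`, `sex`,
#' `piq`, `viq`, `fsiq`; extra columns are preserved.
#'
#' @param path File path.
#' @return A validated data frame.
#' @export
read_subject_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- apply_aliases(df, SUBJECT_COL_ALIASES)
  missing <- setdiff(SUBJECT_COLS, names(df))
  if (length(missing)) {
    stop_invalid("subject table missing column(s): %s",
                 paste(missing, collapse = ", "))
  }
  bad <- which(!df$group %in% c("NT", "ASD"))
  if (length(bad)) {
    stop_invalid("unknown group label '%s' in subject row %d",
                 df$group[bad[1]], bad[1])
  }
  df
}

#' Write a subject or trial table
#'
#' Plain CSV with header; missing RTs are written as empty fields and read
#' back as misses.
#'
#' @param df Table to write.
#' @param path Destination path.
#' @return The path, invisibly.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read or write a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are parsed
#' as numeric where possible, comma-separated values become vectors.
#'
#' @param path File path.
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop_invalid("malformed config line: '%s'", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

#' @rdname read_config
#' @param config Named list of scalar/vector values.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    sprintf("%s = %s", k, paste(config[[k]], collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Per-subject race-model results for a cohort
#'
#' Cleans each subject's trials, builds the conditioned CDF set and runs
#' the race pipeline, returning one row per analysable subject with the
#' benefit/gain statistics and the 20 quantile differences.
#'
#' @param trials Cohort trial table.
#' @param subjects Subject table.
#' @param conditioned Use the preceding-modality-conditioned race model.
#' @param n_q Number of quantiles.
#' @return A data frame with `subject_id`, `benefit_pred`, `benefit_emp`,
#'   `gain`, `auc_pos`, `auc_neg` and `diff_1` ... `diff_<n_q>`.
#' @export
cohort_race_table <- function(trials, subjects, conditioned = TRUE, n_q = 20L) {
  rows <- lapply(subjects$subject_id, function(id) {
    tr <- trials[trials$subject_id == id, , drop = FALSE]
    ro <- try(suppressWarnings(
      race_outcome(condition_subsets(tr, n_q = n_q), conditioned = conditioned)),
      silent = TRUE)
    if (inherits(ro, "try-error")) return(NULL)
    row <- data.frame(subject_id = id, benefit_pred = ro$benefit_pred,
                      benefit_emp = ro$benefit_emp, gain = ro$gain,
                      auc_pos = ro$auc_pos, auc_neg = ro$auc_neg)
    row[paste0("diff_", seq_len(n_q))] <- as.list(ro$diff_fn)
    row
  })
  do.call(rbind, rows)
}

#' Per-subject modality switch effects for a cohort
#'
#' @param trials Cohort trial table.
#' @param subjects Subject table.
#' @return Long data frame: `subject_id`, `condition`, `mse_auc`,
#'   `degenerate`, plus per-subject `mse_uni` (mean of the two unisensory
#'   directions) merged in.
#' @export
cohort_mse_table <- function(trials, subjects) {
  rows <- lapply(subjects$subject_id, function(id) {
    tr <- trials[trials$subject_id == id, , drop = FALSE]
    m <- try(suppressWarnings(mse_by_condition(condition_subsets(tr))),
             silent = TRUE)
    if (inherits(m, "try-error")) return(NULL)
    m$subject_id <- id
    m
  })
  out <- do.call(rbind, rows)
  uni <- stats::aggregate(mse_auc ~ subject_id,
                          data = out[out$condition %in% c("V->A", "A->V"), ],
                          FUN = mean)
  names(uni)[2] <- "mse_uni"
  merge(out, uni, by = "subject_id", all.x = TRUE)
}

#' Per-subject context-variant race fits for a cohort
#'
#' @param trials Cohort trial table.
#' @param subjects Subject table.
#' @return Data frame: LATER parameters per channel, `rho`, `eta`,
#'   objective and convergence flag per analysable subject.
#' @export
cohort_context_fits <- function(trials, subjects) {
  rows <- lapply(subjects$subject_id, function(id) {
    tr <- cleaned_rts(trials[trials$subject_id == id, , drop = FALSE])
    f <- try(suppressWarnings(fit_context_race(
      tr$rt_ms[tr$condition == "A"], tr$rt_ms[tr$condition == "V"],
      tr$rt_ms[tr$condition == "AV"])), silent = TRUE)
    if (inherits(f, "try-error")) return(NULL)
    data.frame(subject_id = id, mu_a = f$mu_a, sigma_a = f$sigma_a,
               mu_v = f$mu_v, sigma_v = f$sigma_v, rho = f$rho, eta = f$eta,
               objective = f$objective, converged = f$converged)
  })
  do.call(rbind, rows)
}

## Order-independent hash of a config list (for the run manifest).
config_hash <- function(config) {
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                        digits = NA)
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Executes enabled stages in dependency order on a synthetic cohort (or
#' tables read from `subject_file`/`trial_file`): generate, clean/exclude,
#' race-model analysis, competition-model evaluation, switch effects,
#' context-race fits, and group inference. Writes per-subject and
#' group-level CSV tables plus a machine-readable JSON run manifest
#' (config hash, seed, package version, stage timings) to `out_dir`.
#'
#' @param config Named list (or path to a flat key-value file): any
#'   [cohort_config()] fields, plus logical toggles `race`, `competition`,
#'   `mse`, `context_fit`, `inference`, the counts `n_perm`, `n_boot`, a
#'   mandatory `seed`, optional `subject_file`/`trial_file`, and `out_dir`.
#' @return Invisibly, a list with the result tables and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$seed)) stop_invalid("config must carry a seed")
  toggle <- function(k, default = TRUE) {
    v <- config[[k]]
    if (is.null(v)) default else as.logical(v) %in% TRUE
  }
  out_dir <- config$out_dir %||% "results"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- expr
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    res
  }
  results <- list()

  if (!is.null(config$trial_file)) {
    trials <- read_trial_table(config$trial_file)
    subjects <- read_subject_table(config$subject_file)
  } else {
    cfg_args <- config[intersect(names(config), names(formals(cohort_config)))]
    cohort <- timed("generate", generate_cohort(do.call(cohort_config, cfg_args)))
    subjects <- cohort$subjects
    trials <- cohort$trials
    write_table_csv(subjects, file.path(out_dir, "subjects.csv"))
    write_table_csv(trials, file.path(out_dir, "trials.csv"))
  }

  excl <- timed("clean", apply_exclusions(subjects, trials))
  write_table_csv(excl, file.path(out_dir, "exclusions.csv"))
  results$exclusions <- excl
  keep <- excl$subject_id[!excl$excluded]
  subjects <- subjects[subjects$subject_id %in% keep, , drop = FALSE]
  trials <- trials[trials$subject_id %in% keep, , drop = FALSE]

  if (toggle("race")) {
    results$race <- timed("race", cohort_race_table(trials, subjects))
    write_table_csv(results$race, file.path(out_dir, "race_results.csv"))
  }
  if (toggle("competition")) {
    ben <- timed("competition_benefits",
                 cohort_model_benefits(trials, subjects))
    results$model_benefits <- ben
    grid <- timed("competition_eval",
                  evaluate_models(ben, n_perm = config$n_perm %||% 2000,
                                  seed = stage_seed(config$seed, "competition")))
    results$model_grid <- grid
    write_table_csv(grid, file.path(out_dir, "model_grid.csv"))
  }
  if (toggle("mse")) {
    results$mse <- timed("mse", cohort_mse_table(trials, subjects))
    write_table_csv(results$mse, file.path(out_dir, "mse_results.csv"))
  }
  if (toggle("context_fit")) {
    results$context <- timed("context_fit", cohort_context_fits(trials, subjects))
    write_table_csv(results$context, file.path(out_dir, "context_fits.csv"))
  }
  if (toggle("inference")) {
    if (is.null(results$race)) {
      stop_invalid("inference stage requires the race stage (no gain available)")
    }
    results$inference <- timed("inference", {
      d <- merge(results$race, subjects, by = "subject_id")
      dmat <- as.matrix(d[, grep("^diff_", names(d))])
      viol <- race_violation_test(dmat, n_perm = config$n_perm %||% 2000,
                                  seed = stage_seed(config$seed, "violation"))
      rows <- data.frame(analysis = "race_violation",
                         contrast = paste0("q", viol$quantile),
                         statistic = viol$statistic, p = viol$p_perm,
                         correction = "tmax")
      g1 <- d$gain[d$group == "ASD"]; g2 <- d$gain[d$group == "NT"]
      if (length(g1) >= 3 && length(g2) >= 3) {
        pt <- permutation_test(g1, g2, n_perm = config$n_perm %||% 2000,
                               correction = "none",
                               seed = stage_seed(config$seed, "gain_group"))
        rows <- rbind(rows, data.frame(
          analysis = "gain_group", contrast = "ASD-NT",
          statistic = pt$statistic, p = pt$p, correction = "none"))
      }
      rows
    })
    write_table_csv(results$inference, file.path(out_dir, "inference.csv"))
  }

  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   package_version = as.character(utils::packageVersion("multirace")),
                   n_subjects = nrow(subjects), timings = timings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
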