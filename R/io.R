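#' @title Plain-CSV trial-table schemas
#' @name io
#' @description
#' All tables cross the package boundary as plain CSV with fixed, documented
#' column names, so real datasets can be re-scored by the same functions
#' that consume the synthetic generators:
#' \itemize{
#'   \item vigilance: `subject, trial, onset_s, condition, rt_ms, valid`
#'     with `condition` in `{baseline, gain, loss, neutral}`;
#'   \item N-back: `subject, load, frame, trial, is_target, response,
#'     correct`;
#'   \item pupil: `time_s, diameter_mm, valid`;
#'   \item indifference: `subject, frame, effort_level, indifference`.
#' }
NULL

read_schema_csv <- function(path, required) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop_ef("%s is missing required columns: %s", path,
            paste(missing, collapse = ", "))
  x
}

#' Read a vigilance trial table
#' @param path CSV path.
#' @export
read_vigilance_csv <- function(path) {
  x <- read_schema_csv(path, c("subject", "trial", "onset_s", "condition",
                               "rt_ms"))
  if (is.null(x$valid)) x$valid <- TRUE
  x
}

#' Read an N-back trial table
#' @param path CSV path.
#' @export
read_nback_csv <- function(path) {
  x <- read_schema_csv(path, c("subject", "load", "frame", "trial",
                               "is_target", "response"))
  x$is_target <- as.logical(x$is_target)
  x$response[x$response %in% c("", "NA")] <- NA_character_
  x
}

#' Read a pupil trace
#' @param path CSV path.
#' @param unit declared diameter unit; anything but `"mm"` is accepted but
#'   flagged in the returned attribute `pupil_unit`.
#' @export
read_pupil_csv <- function(path, unit = "mm") {
  x <- read_schema_csv(path, c("time_s", "diameter_mm", "valid"))
  x$valid <- as.logical(x$valid)
  attr(x, "pupil_unit") <- unit
  x
}

#' Read an indifference table
#' @param path CSV path.
#' @export
read_indifference_csv <- function(path) {
  read_schema_csv(path, c("subject", "frame", "effort_level", "indifference"))
}

#' Write any package table as CSV
#' @param x data frame.
#' @param path destination.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Command-line entry point
#'
#' Subcommands mirror the pipeline stages:
#' `effortframe simulate --what {vigilance,pupil,nback,choices}`,
#' `staircase`, `score`, `fit`, `auc`, `pupil`, and `run`. Configuration
#' is a JSON file mirroring the config constructors; `--seed` drives all
#' randomness; `--out` is the output directory. Invoked by the
#' `inst/cli/effortframe` script; exposed as a function for testing.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly (0 = success).
#' @export
effortframe_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: effortframe <simulate|staircase|score|fit|auc|pupil|run> [options]",
    "  --config PATH   JSON config (experiment_config fields)",
    "  --seed N        master seed (default 1)",
    "  --out DIR       output directory (default '.')",
    "  --what WHAT     simulate: vigilance|pupil|nback|choices",
    "  --input PATH    input CSV for score/fit/auc/pupil", sep = "\n")
  if (length(args) == 0L) { message(usage); return(invisible(2L)) }
  cmd <- args[1L]
  opt <- list(seed = 1L, out = ".", what = "vigilance",
              config = NULL, input = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt)) stop_ef("unknown option --%s", key)
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opt$seed <- as.integer(opt$seed)
  cfg_json <- if (!is.null(opt$config)) jsonlite::read_json(opt$config) else list()
  dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)

  switch(cmd,
    simulate = {
      out <- switch(opt$what,
        vigilance = generate_vigilance_session(
          do.call(vigilance_config, cfg_json$vigilance %||% list()),
          seed = opt$seed),
        nback = generate_nback_session(
          do.call(nback_config, cfg_json$nback %||% list()),
          load = cfg_json$load %||% 2L, frame = cfg_json$frame %||% "gain",
          seed = opt$seed),
        pupil = generate_pupil_trace(
          do.call(pupil_config, cfg_json$pupil %||% list()),
          events = seq(10, 590, by = 8), duration_s = 600, seed = opt$seed),
        stop_ef("unsupported --what %s", opt$what))
      write_table_csv(out, file.path(opt$out, paste0(opt$what, ".csv")))
    },
    staircase = {
      cfg <- do.call(experiment_config,
                     c(cfg_json, list(master_seed = opt$seed)))
      agents <- sample_agents(cfg)
      ind <- do.call(rbind, lapply(agents, function(a)
        titrate_subject(a, cfg$effort_levels, cfg$amount_high,
                        cfg$reference_effort)$indifference))
      write_table_csv(ind, file.path(opt$out, "indifference.csv"))
    },
    score = {
      if (is.null(opt$input)) stop_ef("score needs --input")
      tbl <- read_nback_csv(opt$input)
      write_table_csv(score_nback(tbl), file.path(opt$out, "nback_scores.csv"))
    },
    fit = {
      if (is.null(opt$input)) stop_ef("fit needs --input")
      ch <- read_schema_csv(opt$input,
                            c("subject", "frame", "effort_low", "effort_high",
                              "amount_low", "amount_high", "choice"))
      fits_by_subject <- lapply(split(ch, ch$subject), function(g)
        fit_all_families(g, g$choice, subject_id = g$subject[1L],
                         frame = g$frame[1L]))
      cmpr <- compare_models(fits_by_subject)
      write_table_csv(cmpr$per_subject, file.path(opt$out, "fits.csv"))
      write_table_csv(cmpr$group, file.path(opt$out, "bic_group.csv"))
      jsonlite::write_json(list(group_winner = cmpr$group_winner),
                           file.path(opt$out, "fit_report.json"),
                           auto_unbox = TRUE)
    },
    auc = {
      if (is.null(opt$input)) stop_ef("auc needs --input")
      ind <- read_indifference_csv(opt$input)
      auc <- do.call(rbind, lapply(
        split(ind, list(ind$subject, ind$frame), drop = TRUE), function(g)
          data.frame(subject = g$subject[1L], frame = g$frame[1L],
                     auc = auc_from_indifference(g$effort_level,
                                                 g$indifference))))
      write_table_csv(auc, file.path(opt$out, "auc.csv"))
    },
    pupil = {
      if (is.null(opt$input)) stop_ef("pupil needs --input")
      tr <- preprocess_pupil(read_pupil_csv(opt$input))
      write_table_csv(tr, file.path(opt$out, "pupil_clean.csv"))
    },
    run = {
      cfg <- do.call(experiment_config,
                     c(cfg_json, list(master_seed = opt$seed)))
      run_experiment(cfg, out_dir = opt$out)
    },
    { message(usage); return(invisible(2L)) })
  invisible(0L)
}
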