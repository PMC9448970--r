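# One-command orchestration: detection records -> encounter histories ->
# goodness of fit / c-hat -> stepwise QAICc selection -> real-scale
# estimates, with every tabular artifact written as CSV carrying the config
# hash, plus a structured JSON-lines log.

#' Pipeline configuration
#'
#' Builds (and validates) the configuration driving [run_pipeline()].
#' Unspecified entries take the defaults below. Candidate model structures
#' are formula strings as in [model_spec()].
#'
#' @param ... configuration entries overriding the defaults:
#'   `detections_csv`, `histories_file` (`.inp` or CSV; overrides
#'   detections), `biomass_csv`, `double_marked_ids`, `multi_colony`,
#'   `years`, `min_detections` (6), `min_span` (12), `max_span` (120),
#'   `candidates` (named list of formula strings for `p`, `phi`, `psi`;
#'   empty list = no selection), `general` (general structures),
#'   `constant` (structures for the constant-model summary),
#'   `chat_floor` (floor c-hat at 1?), `n_starts`, `seed`, `out_dir`.
#' @param config optional list or path to a JSON file with the same entries
#'   (entries in `...` win).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., config = NULL) {
  defaults <- list(
    detections_csv = NULL, histories_file = NULL, biomass_csv = NULL,
    double_marked_ids = character(), multi_colony = "breeding",
    years = 2013:2020, min_detections = 6L, min_span = 12L, max_span = 120L,
    candidates = list(
      p = c("~ state * time * colony", "~ state + time * colony",
        "~ state * colony", "~ state"),
      phi = c("~ time * colony", "~ colony", "~ state + colony", "~ 1"),
      psi = c("~ state * time * colony", "~ state * colony", "~ state")),
    general = list(phi = "~ time * colony", p = "~ state * time * colony",
      psi = "~ state * time * colony"),
    constant = list(phi = "~ colony", p = "~ state * colony",
      psi = "~ state * colony"),
    chat_floor = TRUE, n_starts = 2L, seed = 1L, out_dir = "skipmark-out")
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  user <- c(list(...), config)
  user <- user[!duplicated(names(user))]
  unknown <- setdiff(names(user), names(defaults))
  .assert(length(unknown) == 0L, "unknown config entries: %s",
    paste(unknown, collapse = ", "))
  cfg <- defaults
  cfg[names(user)] <- user
  .assert(cfg$min_detections > 0 && cfg$min_span > 0 && cfg$max_span > 0,
    "rule thresholds must be positive")
  structure(cfg, class = "pipeline_config")
}

#' @noRd
.config_hash <- function(config) {
  snap <- unclass(config)
  snap$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(snap, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' @noRd
.write_csv_hashed <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @noRd
.log_event <- function(log_path, stage, event, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stage = stage, event = event), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
    file = log_path, append = TRUE, sep = "")
  message(sprintf("[%s] %s", stage, event))
}

#' Run the analysis pipeline
#'
#' Executes state assignment, goodness of fit / c-hat, stepwise model
#' selection and real-scale estimation, writing all artifacts into
#' `config$out_dir`. A failed stage aborts with an error naming the stage;
#' artifacts written up to that point are retained.
#'
#' Artifacts: `config_snapshot.json`, `exclusions.csv`, `histories.inp`,
#' `histories.csv`, `marked_tally.csv`, `gof.csv`, `chat.csv`,
#' `model_table.csv` (or a "no selection performed" note), `estimates.csv`,
#' `transitions_by_year.csv`, `constant_model_diagram.csv`, optionally
#' `predicted_survival.csv`, and `log.jsonl`.
#'
#' @param config a [pipeline_config()].
#' @param stage run a single stage: one of `"assign"`, `"gof"`, `"select"`,
#'   `"estimates"`, or `"all"` (default). Later stages re-derive what they
#'   need from the artifact directory.
#' @return the artifact directory, invisibly.
#' @export
run_pipeline <- function(config, stage = "all") {
  stage <- match.arg(stage, c("all", "assign", "gof", "select", "estimates"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  log_path <- file.path(out, "log.jsonl")
  jsonlite::write_json(c(unclass(config), list(config_hash = hash)),
    file.path(out, "config_snapshot.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  run_stage <- function(name, expr) {
    .log_event(log_path, name, "start")
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      .log_event(log_path, name, "error", message = conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
        conditionMessage(e)), call. = FALSE)
    })
    .log_event(log_path, name, "done",
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
    res
  }
  want <- function(s) stage %in% c("all", s) ||
    (stage != "assign" && s == "assign") ||
    (stage %in% c("select", "estimates") && s == "gof")

  histories <- NULL
  if (want("assign")) {
    histories <- run_stage("assign", {
      if (!is.null(config$histories_file)) {
        h <- if (grepl("\\.inp$", config$histories_file)) {
          read_inp(config$histories_file)
        } else {
          read_histories_csv(config$histories_file)
        }
        .write_csv_hashed(data.frame(individual_id = character(),
          reason = character()), file.path(out, "exclusions.csv"), hash)
        h
      } else {
        .assert(!is.null(config$detections_csv),
          "config needs detections_csv or histories_file")
        rec <- read_detections(config$detections_csv)
        filt <- apply_exclusion_filters(rec,
          double_marked_ids = config$double_marked_ids,
          multi_colony = config$multi_colony)
        .write_csv_hashed(filt$report, file.path(out, "exclusions.csv"), hash)
        bh <- build_encounter_histories(filt$records, years = config$years,
          min_detections = config$min_detections,
          min_span = config$min_span, max_span = config$max_span)
        .write_csv_hashed(bh$marked_tally, file.path(out, "marked_tally.csv"),
          hash)
        bh$histories
      }
    })
    write_inp(histories, file.path(out, "histories.inp"),
      comments = sprintf("config_hash: %s", hash))
    write_histories_csv(histories, file.path(out, "histories.csv"),
      comments = sprintf("config_hash: %s", hash))
    if (stage == "assign") return(invisible(out))
  }

  gof <- NULL
  chat <- 1
  if (want("gof")) {
    gof <- run_stage("gof", jmv_components(histories))
    chat <- if (gof$omnibus$df > 0) {
      suppressMessages(chat_from_gof(gof$omnibus$chi_square, gof$omnibus$df,
        floor_at_one = isTRUE(config$chat_floor)))
    } else 1
    .write_csv_hashed(gof_table(gof), file.path(out, "gof.csv"), hash)
    .write_csv_hashed(data.frame(chi_square = gof$omnibus$chi_square,
      df = gof$omnibus$df, chat = chat), file.path(out, "chat.csv"), hash)
    if (stage == "gof") return(invisible(out))
  }

  biomass <- if (!is.null(config$biomass_csv)) read_biomass_csv(config$biomass_csv)
  fixed <- default_fixed_params(levels(histories$colony))
  chosen <- NULL
  if (stage %in% c("all", "select", "estimates")) {
    no_cands <- length(config$candidates) == 0L ||
      all(vapply(config$candidates, length, integer(1)) == 0L)
    if (no_cands) {
      .write_csv_hashed(data.frame(note = "no selection performed"),
        file.path(out, "model_table.csv"), hash)
      .log_event(log_path, "select", "skipped", reason = "empty candidate set")
    } else {
      sel <- run_stage("select", select_stepwise(
        lapply(config$candidates, as.list), histories, chat = chat,
        general = config$general, fixed = fixed, biomass = biomass,
        n_starts = config$n_starts, seed = config$seed))
      .write_csv_hashed(sel$table, file.path(out, "model_table.csv"), hash)
      if (nrow(sel$excluded)) {
        .write_csv_hashed(sel$excluded, file.path(out, "excluded_models.csv"),
          hash)
      }
      chosen <- sel$chosen
    }
    if (stage == "select") return(invisible(out))
  }

  run_stage("estimates", {
    if (!is.null(chosen)) {
      est <- real_estimates(chosen)
      .write_csv_hashed(est, file.path(out, "estimates.csv"), hash)
      psi_t <- est[est$class == "psi" & !is.na(est$transition), , drop = FALSE]
      .write_csv_hashed(psi_t[order(psi_t$transition, psi_t$colony, psi_t$time), ],
        file.path(out, "transitions_by_year.csv"), hash)
      covs <- intersect(all.vars(chosen$spec$phi),
        c("sardine", "anchovy", "combined"))
      if (length(covs) && !is.null(biomass)) {
        v <- covs[1]
        rng <- chosen$layout$cov_range[[v]]
        grid <- expand.grid(x = seq(rng[1], rng[2], length.out = 50),
          colony = levels(histories$colony))
        names(grid)[1] <- v
        pred <- real_estimates(chosen, at = grid, class = "phi")
        .write_csv_hashed(pred, file.path(out, "predicted_survival.csv"), hash)
      }
    }
    const_spec <- model_spec(phi = config$constant$phi, p = config$constant$p,
      psi = config$constant$psi, fixed = fixed, biomass = biomass,
      label = "constant")
    cfit <- fit_msmr(const_spec, histories, n_starts = config$n_starts,
      seed = config$seed)
    cest <- real_estimates(cfit)
    .write_csv_hashed(cest, file.path(out, "constant_model_diagram.csv"), hash)
    if (is.null(chosen)) {
      .write_csv_hashed(cest, file.path(out, "estimates.csv"), hash)
    }
    NULL
  })
  invisible(out)
}

#' Summarize a pipeline artifact directory
#'
#' Collects the tabular artifacts of [run_pipeline()] into one markdown
#' document (`report.md`); every number in the report is read back from a
#' CSV, so regeneration is idempotent. A missing artifact raises an error
#' naming the file.
#'
#' @param artifact_dir directory written by [run_pipeline()].
#' @return path of the report, invisibly.
#' @export
make_report <- function(artifact_dir) {
  need <- function(f) {
    p <- file.path(artifact_dir, f)
    .assert(file.exists(p), "missing pipeline artifact: %s", f)
    p
  }
  snap <- jsonlite::read_json(need("config_snapshot.json"),
    simplifyVector = TRUE)
  gof <- read.csv(need("gof.csv"), comment.char = "#")
  chat <- read.csv(need("chat.csv"), comment.char = "#")
  mt <- read.csv(need("model_table.csv"), comment.char = "#")
  est <- read.csv(need("estimates.csv"), comment.char = "#")
  lines <- c(
    "# Multistate mark-recapture pipeline report", "",
    sprintf("Config hash: `%s`; seed: %s", snap$config_hash, snap$seed), "",
    "## Goodness of fit", "",
    knit_table(gof), "",
    sprintf("c-hat = %.3f (chi2 = %.2f on %d df)", chat$chat[1],
      chat$chi_square[1], chat$df[1]), "",
    "## Model selection", "")
  if ("note" %in% names(mt)) {
    lines <- c(lines, "no selection performed", "")
    selected <- NA_character_
  } else {
    lines <- c(lines, knit_table(mt[, c("stage", "model", "K", "QAICc",
      "delta", "weight")]), "")
    last_stage <- mt[mt$stage == "psi", , drop = FALSE]
    selected <- if (nrow(last_stage)) {
      cnd <- last_stage[last_stage$delta < 2, , drop = FALSE]
      cnd$model[order(cnd$K, cnd$QAICc)][1]
    } else NA_character_
    lines <- c(lines, sprintf("Selected model: `%s`", selected), "")
  }
  lines <- c(lines, "## Estimates (head)", "",
    knit_table(head(est[, c("class", "state", "time", "colony", "estimate",
      "se")], 20L)), "")
  out <- file.path(artifact_dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}

#' @noRd
knit_table <- function(df) {
  if (!nrow(df)) return("(empty)")
  fmt <- function(x) {
    if (is.numeric(x)) formatC(x, digits = 4, format = "g") else as.character(x)
  }
  body <- do.call(cbind, lapply(df, fmt))
  body <- rbind(colnames(df), rep("---", ncol(df)), body)
  apply(body, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
}
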