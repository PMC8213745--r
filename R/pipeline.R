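# Seeded end-to-end pipeline: generate -> design -> simulate -> score ->
# fit -> report, with plain-CSV interfaces between stages so every stage
# can be re-run in isolation or replaced by user-supplied data
# (reanalysis mode). One global seed is expanded into per-stage child
# seeds by `stage_seed()` (seed + 1000003 * stage index, mod 2^31 - 1).

PN_STAGE <- c(generate = 1L, wave1 = 2L, design = 3L, simulate = 4L)

#' Pipeline configuration
#'
#' @param generator a [generator_config()]
#' @param design a [design_spec()]
#' @param inclusion_threshold minimum classroom participation rate in (0, 1]
#' @param participation_rates optional per-classroom rates; default 1 for
#'   every generated classroom (all pupils participate)
#' @param outdir output directory for stage CSVs
#' @param seed global integer seed (mandatory for simulation modes)
#' @param verbose print one line per stage and exclusion?
#' @return list of class `pn_pipeline_config`
#' @export
pipeline_config <- function(generator = generator_config(),
                            design = design_spec(),
                            inclusion_threshold = 0.5,
                            participation_rates = NULL,
                            outdir = tempfile("peernorms_run_"),
                            seed = 1L,
                            verbose = FALSE) {
  if (!(inclusion_threshold > 0 && inclusion_threshold <= 1)) {
    stop("inclusion_threshold must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(seed)) stop("seed is mandatory", call. = FALSE)
  structure(list(generator = generator, design = design,
                 inclusion_threshold = inclusion_threshold,
                 participation_rates = participation_rates,
                 outdir = outdir, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "pn_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys: `seed` (mandatory), `outdir`,
#' `inclusion_threshold`, `participation_rates`, `generator` (fields of
#' [generator_config()]) and `design` (fields of [design_spec()]). Omitted
#' fields keep package defaults.
#'
#' @param path YAML file path
#' @param seed optional override of the file's seed
#' @return a `pn_pipeline_config`
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  gen_args <- y$generator %||% list()
  des_args <- y$design %||% list()
  gen <- do.call(generator_config, gen_args)
  des <- do.call(design_spec, des_args)
  pipeline_config(generator = gen, design = des,
                  inclusion_threshold = y$inclusion_threshold %||% 0.5,
                  participation_rates = y$participation_rates,
                  outdir = y$outdir %||% tempfile("peernorms_run_"),
                  seed = seed %||% y$seed,
                  verbose = y$verbose %||% FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drop classrooms with participation below threshold
#'
#' Classrooms where fewer than `threshold` of pupils took part are dropped
#' because their majority and popular-peer norms cannot be identified
#' robustly. Exclusions are logged (one line, machine-parsable reason).
#'
#' @param classrooms list of `pn_classroom`
#' @param participation per-classroom participation rates in \[0, 1\],
#'   recycled if length 1
#' @param threshold minimum rate, in (0, 1]
#' @param verbose print exclusion lines?
#' @return the retained classrooms (aborts if none survive)
#' @export
apply_inclusion_filter <- function(classrooms, participation,
                                   threshold = 0.5, verbose = FALSE) {
  if (!(threshold > 0 && threshold <= 1)) {
    stop("inclusion threshold must lie in (0, 1]", call. = FALSE)
  }
  participation <- rep_len(participation, length(classrooms))
  keep <- participation >= threshold
  if (verbose) {
    for (i in which(!keep)) {
      message(sprintf("EXCLUDE classroom=%s reason=participation_below_threshold rate=%.2f",
                      classrooms[[i]]$id, participation[i]))
    }
  }
  if (!any(keep)) {
    stop("all classrooms fall below the participation threshold; nothing to analyse",
         call. = FALSE)
  }
  classrooms[keep]
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  path
}

read_stage_csv <- function(path, required, name = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  check_columns(df, required, name)
  df
}

#' Run the full pipeline
#'
#' Generate classrooms, apply the classroom-participation filter, generate
#' wave-1 ratings, build the wave-2 design, simulate wave-2 responses,
#' score adjustments, fit models 1-2 and the stay/copy logistic models, and
#' write every stage table as CSV under `config$outdir`. Re-running with an
#' identical config and seed reproduces byte-identical CSVs.
#'
#' @param config a [pipeline_config()]
#' @return (invisibly) the run manifest: config hash, seed, per-stage
#'   counts, relaxation rate, output paths
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pn_pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$verbose) message(sprintf(...))
  seed <- config$seed

  say("stage generate (seed %d)", stage_seed(seed, PN_STAGE["generate"]))
  classrooms <- generate_classrooms(config$generator,
                                    seed = stage_seed(seed, PN_STAGE["generate"]))
  rates <- config$participation_rates %||% rep(1, length(classrooms))
  classrooms <- apply_inclusion_filter(classrooms, rates,
                                       config$inclusion_threshold,
                                       verbose = config$verbose)
  item_bank <- generate_item_bank(config$generator)
  participants <- bind_participants(classrooms)

  wave1 <- generate_wave1(classrooms, item_bank, config$generator,
                          seed = stage_seed(seed, PN_STAGE["wave1"]))

  designs <- lapply(seq_along(classrooms), function(k) {
    cl <- classrooms[[k]]
    build_design(cl, wave1, item_bank, popularity_ranking(cl),
                 spec = config$design,
                 seed = stage_seed(seed, PN_STAGE["design"] * 100L + k))
  })
  trials <- do.call(rbind, c(lapply(designs, `[[`, "trials"),
                             make.row.names = FALSE))
  excluded <- do.call(rbind, c(lapply(designs, `[[`, "excluded"),
                               make.row.names = FALSE))
  if (config$verbose && nrow(excluded)) {
    for (i in seq_len(nrow(excluded))) {
      message(sprintf("EXCLUDE participant=%s reason=%s",
                      excluded$participant[i], excluded$reason[i]))
    }
  }

  trials <- simulate_wave2(trials, participants, config$generator$update_policy,
                           seed = stage_seed(seed, PN_STAGE["simulate"]))

  scored <- score_trials(trials)
  scored$age_z <- participants$age_z[match(scored$participant,
                                           participants$id)]
  results <- fit_models(scored)

  paths <- c(
    participants = write_stage_csv(
      participants[c("id", "classroom", "age", "age_z", "school_year",
                     "gender")], config$outdir, "participants.csv"),
    nominations = write_stage_csv(
      do.call(rbind, c(lapply(classrooms, `[[`, "nominations"),
                       make.row.names = FALSE)),
      config$outdir, "nominations.csv"),
    wave1 = write_stage_csv(wave1, config$outdir, "wave1.csv"),
    trials = write_stage_csv(scored[, c("participant", "classroom", "item",
                                        "domain", "block", "block_order",
                                        "trial_index", "direction", "P1",
                                        "NI", "relaxed", "P2")],
                             config$outdir, "trials.csv"),
    adjustments = write_stage_csv(
      scored[, c("participant", "classroom", "item", "block", "direction",
                 "domain", "S", "round_class", "strategy", "abs_change")],
      config$outdir, "adjustments.csv"),
    summary_source = write_stage_csv(summarize_by_source(scored),
                                     config$outdir, "summary_source.csv"),
    summary_dirdom = write_stage_csv(summarize_by_direction_domain(scored),
                                     config$outdir, "summary_dirdom.csv"),
    summary_strategy = write_stage_csv(strategy_proportions(scored),
                                       config$outdir, "summary_strategy.csv"),
    summary_filler = write_stage_csv(filler_summary(scored),
                                     config$outdir, "summary_filler.csv"),
    model_results = write_stage_csv(results$model_results,
                                    config$outdir, "model_results.csv"),
    variance_components = write_stage_csv(results$variance_components,
                                          config$outdir,
                                          "variance_components.csv"),
    excluded = write_stage_csv(excluded, config$outdir,
                               "excluded_participants.csv"))

  counts <- table(scored$round_class)
  manifest <- list(
    package_version = as.character(utils::packageVersion("peernorms")),
    seed = seed,
    config_hash = config_hash(config),
    n_classrooms = length(classrooms),
    n_participants = nrow(participants),
    n_designable = length(unique(scored$participant)),
    n_undesignable = nrow(excluded),
    n_trials = nrow(scored),
    rounds = as.list(counts),
    relaxation_rate = if (any(scored$direction != "filler")) {
      mean(scored$relaxed[scored$direction != "filler"])
    } else NA_real_,
    paths = as.list(paths))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: %d participants, %d trials, relaxation %.1f%%",
      manifest$n_participants, manifest$n_trials,
      100 * (manifest$relaxation_rate %||% NA_real_))
  invisible(manifest)
}

# stable hash of the config (seed and outdir excluded so the hash names the
# design of the run, not its location)
config_hash <- function(config) {
  x <- config
  x$outdir <- NULL
  x$verbose <- NULL
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12, force = TRUE)
  # small rolling hash; avoids a digest dependency
  bytes <- utf8ToInt(as.character(json))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# fit the pre-specified model set on scored records
fit_models <- function(scored) {
  m1 <- fit_lmm(scored, model = 1)
  m2 <- fit_lmm(scored, model = 2)
  stay <- fit_logit_rim(scored, response = "stay", model = 1)
  copy <- fit_logit_rim(scored, response = "copy", model = 1)
  bind_model <- function(id, m) cbind(model = id, m$coefficients)
  model_results <- do.call(rbind, list(
    bind_model("lmm_model1", m1), bind_model("lmm_model2", m2),
    bind_model("logit_stay", stay), bind_model("logit_copy", copy)))
  vc <- rbind(cbind(model = "lmm_model1", m1$varcomp),
              cbind(model = "lmm_model2", m2$varcomp),
              data.frame(model = c("logit_stay", "logit_copy"),
                         component = "participant_intercept_sd",
                         variance = c(stay$sigma_u^2, copy$sigma_u^2)))
  list(model_results = model_results, variance_components = vc,
       fits = list(lmm_model1 = m1, lmm_model2 = m2,
                   logit_stay = stay, logit_copy = copy))
}

#' Re-analyse user-supplied trial data
#'
#' Reanalysis mode skips generation: it consumes a trials CSV (the
#' documented `trials.csv` schema, wave-2 responses in `P2`) and a
#' participants CSV (for `age_z`), scores adjustments and fits the model
#' set. Schemas are validated before any computation.
#'
#' @param trials_csv path to trials.csv
#' @param participants_csv path to participants.csv
#' @param outdir output directory
#' @return (invisibly) list with the scored records and fitted models;
#'   writes adjustments.csv, summaries and model_results.csv to `outdir`
#' @export
run_reanalysis <- function(trials_csv, participants_csv,
                           outdir = tempfile("peernorms_reanalysis_")) {
  trials <- read_stage_csv(trials_csv,
                           c("participant", "item", "domain", "block",
                             "direction", "P1", "NI", "P2"), "trials.csv")
  participants <- read_stage_csv(participants_csv, c("id", "age_z"),
                                 "participants.csv")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  scored <- score_trials(trials)
  scored$age_z <- participants$age_z[match(scored$participant,
                                           participants$id)]
  results <- fit_models(scored)
  write_stage_csv(scored, outdir, "adjustments.csv")
  write_stage_csv(summarize_by_source(scored), outdir, "summary_source.csv")
  write_stage_csv(summarize_by_direction_domain(scored), outdir,
                  "summary_dirdom.csv")
  write_stage_csv(strategy_proportions(scored), outdir,
                  "summary_strategy.csv")
  write_stage_csv(results$model_results, outdir, "model_results.csv")
  invisible(list(scored = scored, results = results, outdir = outdir))
}

#' Command-line entry point
#'
#' Subcommands: `run-all` (full pipeline), `reanalyze` (consume supplied
#' CSVs), `report` (print summaries from an existing run directory).
#' Options: `--config` (YAML, see [read_pipeline_config()]), `--seed`
#' (override), `--outdir`, and for reanalyze `--trials`/`--participants`.
#'
#' @param args character vector, defaults to the command line
#' @return exit status, invisibly
#' @export
peernorms_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    cat("usage: peernorms <run-all|reanalyze|report> [--config F] [--seed N]",
        "[--outdir D] [--trials F] [--participants F]\n")
    return(invisible(0L))
  }
  cmd <- args[1]
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = list(
      optparse::make_option("--config", type = "character", default = NULL),
      optparse::make_option("--seed", type = "integer", default = NULL),
      optparse::make_option("--outdir", type = "character", default = NULL),
      optparse::make_option("--trials", type = "character", default = NULL),
      optparse::make_option("--participants", type = "character",
                            default = NULL))),
    args = args[-1])
  if (cmd == "run-all") {
    config <- if (!is.null(opts$config)) {
      read_pipeline_config(opts$config, seed = opts$seed)
    } else {
      pipeline_config(seed = opts$seed %||% 1L, verbose = TRUE)
    }
    if (!is.null(opts$outdir)) config$outdir <- opts$outdir
    manifest <- run_pipeline(config)
    cat(sprintf("run complete: %d participants, %d trials -> %s\n",
                manifest$n_participants, manifest$n_trials, config$outdir))
  } else if (cmd == "reanalyze") {
    if (is.null(opts$trials) || is.null(opts$participants)) {
      stop("reanalyze needs --trials and --participants", call. = FALSE)
    }
    res <- run_reanalysis(opts$trials, opts$participants,
                          outdir = opts$outdir %||%
                            tempfile("peernorms_reanalysis_"))
    cat(sprintf("reanalysis complete -> %s\n", res$outdir))
  } else if (cmd == "report") {
    dir <- opts$outdir %||% "."
    for (f in c("summary_source.csv", "summary_dirdom.csv",
                "summary_strategy.csv", "model_results.csv")) {
      p <- file.path(dir, f)
      if (file.exists(p)) {
        cat("==", f, "==\n")
        print(utils::read.csv(p))
      }
    }
  } else {
    stop("unknown subcommand: ", cmd, call. = FALSE)
  }
  invisible(0L)
}
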