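#' Pipeline configuration
#'
#' Configuration of the end-to-end analysis pipeline: speciation of the
#' loading solutions, synthetic-data generation (or loading of measured CSV
#' data), kinetic fitting with model comparison, and Transwell permeability
#' with mass balance. Unit policy everywhere: concentrations uM, time min,
#' volume L, Pe cm/s.
#'
#' @param seed Integer seed forwarded to every stochastic stage.
#' @param speciation List: `total_roh`, `total_rbp`, `total_ttr`,
#'   `kd_roh_rbp`, `kd_holo_ttr` (uM).
#' @param simulation A [simulation_config()] (its seed is overridden by
#'   `seed`), or `NULL` to disable simulation.
#' @param accumulation_csv,transwell_csv Optional paths to measured data; when
#'   given they replace the simulated datasets.
#' @param alpha Significance level for the kinetic model comparison.
#' @param fit_n_starts Multistart budget for [fit_accumulation()].
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1,
                            speciation = list(total_roh = 2, total_rbp = 2,
                                              total_ttr = 4,
                                              kd_roh_rbp = 0.1,
                                              kd_holo_ttr = 0.25),
                            simulation = simulation_config(),
                            accumulation_csv = NULL,
                            transwell_csv = NULL,
                            alpha = 0.05,
                            fit_n_starts = 6) {
  if (!is.null(simulation)) simulation$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), speciation = speciation,
                 simulation = simulation,
                 accumulation_csv = accumulation_csv,
                 transwell_csv = transwell_csv, alpha = alpha,
                 fit_n_starts = fit_n_starts),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Chains speciation -> (simulate or load) -> kinetic fits and model
#' comparison -> permeability and mass balance, and assembles a JSON-ready
#' report with four sections plus a manifest (stage provenance, seed,
#' package version, unit policy).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, `report.json` and the stage
#'   CSVs are written there (a partial manifest is kept on stage failure).
#' @return The report, an invisible list with elements `speciation`,
#'   `kinetics`, `permeability`, `mass_balance`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(
    package = "retinolBBB",
    version = as.character(utils::packageVersion("retinolBBB")),
    seed = config$seed,
    units = list(concentration = "uM", time = "min", volume = "L",
                 permeability = "cm/s"),
    stages = character())
  report <- list()
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  finish_stage <- function(name) {
    manifest$stages <<- c(manifest$stages, name)
    if (!is.null(out_dir))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
  }

  # -- speciation ------------------------------------------------------------
  sp <- config$speciation
  report$speciation <- speciation_table(
    total_roh = sp$total_roh, total_rbp = sp$total_rbp,
    total_ttr = sp$total_ttr, kd_roh_rbp = sp$kd_roh_rbp,
    kd_holo_ttr = sp$kd_holo_ttr)
  finish_stage("speciation")

  # -- data ------------------------------------------------------------------
  if (!is.null(config$accumulation_csv)) {
    tcs <- read_accumulation_csv(config$accumulation_csv)
  } else {
    tcs <- simulate_accumulation(config$simulation)
    if (!is.null(out_dir))
      write_accumulation_csv(tcs, file.path(out_dir, "accumulation.csv"))
  }
  if (!is.null(config$transwell_csv)) {
    assay <- read_transwell_csv(config$transwell_csv)
  } else {
    assay <- simulate_transwell(config$simulation)
    if (!is.null(out_dir))
      write_transwell_csv(assay, file.path(out_dir, "transwell.csv"))
  }
  finish_stage("data")

  # -- kinetics --------------------------------------------------------------
  fit_bi <- fit_accumulation(tcs, model = "biphasic",
                             n_starts = config$fit_n_starts,
                             seed = config$seed)
  fit_mono <- fit_accumulation(tcs, model = "monophasic",
                               n_starts = config$fit_n_starts,
                               seed = config$seed)
  cmp <- compare_models(fit_mono, fit_bi, alpha = config$alpha)
  report$kinetics <- list(
    biphasic = c(unclass(fit_bi$params),
                 list(sse = fit_bi$sse, n_obs = fit_bi$n_obs)),
    monophasic = c(unclass(fit_mono$params)[c("Kp", "k1")],
                   list(sse = fit_mono$sse, n_obs = fit_mono$n_obs)),
    comparison = unclass(cmp))
  finish_stage("kinetics")

  # -- permeability ----------------------------------------------------------
  pe <- assay_permeability(assay)
  report$permeability <- list(per_replicate = pe,
                              summary = attr(pe, "summary"))
  report$mass_balance <- mass_balance(assay)
  finish_stage("permeability")

  report$manifest <- manifest
  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(report)
}

#' Read a speciation JSON config
#'
#' Schema: `{"total_roh_uM", "total_rbp_uM", "total_ttr_uM",
#' "kd_roh_rbp_uM", "kd_holo_ttr_uM", "variant"}` (variant one of
#' `wt|muRBP|muTTR`, default `wt`).
#'
#' @param path JSON path.
#' @return An [equilibrium_system()].
#' @export
read_speciation_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  equilibrium_system(
    total_roh = cfg$total_roh_uM, total_rbp = cfg$total_rbp_uM,
    total_ttr = cfg$total_ttr_uM,
    kd_roh_rbp = if (is.null(cfg$kd_roh_rbp_uM)) 0.1 else cfg$kd_roh_rbp_uM,
    kd_holo_ttr = if (is.null(cfg$kd_holo_ttr_uM)) 0.25
                  else cfg$kd_holo_ttr_uM,
    variant = if (is.null(cfg$variant)) "wt" else cfg$variant)
}

#' Command-line interface
#'
#' Subcommands: `speciate --config cfg.json [--table] [--out out.json]`,
#' `simulate accumulation|transwell --out dir [--seed N]`,
#' `fit-accumulation --data tc.csv [--model biphasic] [--compare]
#' [--out fit.json]`, `permeability --data assay.csv [--out pe.json]`,
#' `run [--seed N] --out dir`. Installed as `exec/retinolbbb`.
#'
#' @param args Character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly (0 on success).
#' @export
retinolbbb_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: retinolbbb <speciate|simulate|fit-accumulation|permeability|run> [options]\n")
    return(invisible(1L))
  }
  cmd <- args[1]; rest <- args[-1]
  opt <- function(flags) {
    optparse::parse_args(
      optparse::OptionParser(option_list = flags),
      args = rest, positional_arguments = TRUE)
  }
  o <- optparse::make_option
  status <- 0L
  switch(cmd,
    "speciate" = {
      p <- opt(list(
        o("--config", type = "character"),
        o("--out", type = "character", default = NULL),
        o("--table", action = "store_true", default = FALSE)))
      sys <- read_speciation_config(p$options$config)
      st <- solve_ternary(sys)
      if (p$options$table) {
        tab <- speciation_table(sys$total_roh, sys$total_rbp, sys$total_ttr,
                                sys$kd_roh_rbp,
                                if (is.finite(sys$kd_holo_ttr))
                                  sys$kd_holo_ttr else 0.25)
        dest <- if (is.null(p$options$out)) stdout() else p$options$out
        utils::write.csv(tab, dest, row.names = FALSE, quote = FALSE)
      } else {
        out <- c(as.list(as.data.frame(st)),
                 list(percent_free = fraction_free(st),
                      residuals = as.list(st$residuals)))
        if (is.null(p$options$out))
          cat(jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE,
                               digits = NA), "\n")
        else jsonlite::write_json(out, p$options$out, auto_unbox = TRUE,
                                  pretty = TRUE, digits = NA)
      }
    },
    "simulate" = {
      p <- opt(list(
        o("--seed", type = "integer", default = 1L),
        o("--noise", type = "character", default = "gaussian_cv"),
        o("--out", type = "character")))
      what <- p$args[1]
      cfg <- simulation_config(seed = p$options$seed,
                               noise_model = p$options$noise)
      if (!dir.exists(p$options$out))
        dir.create(p$options$out, recursive = TRUE)
      if (identical(what, "accumulation")) {
        write_accumulation_csv(simulate_accumulation(cfg),
                               file.path(p$options$out, "accumulation.csv"))
      } else if (identical(what, "transwell")) {
        write_transwell_csv(simulate_transwell(cfg),
                            file.path(p$options$out, "transwell.csv"))
      } else {
        message("simulate needs a positional argument: accumulation|transwell")
        status <- 1L
      }
    },
    "fit-accumulation" = {
      p <- opt(list(
        o("--data", type = "character"),
        o("--model", type = "character", default = "biphasic"),
        o("--compare", action = "store_true", default = FALSE),
        o("--seed", type = "integer", default = 1L),
        o("--out", type = "character", default = NULL)))
      tcs <- read_accumulation_csv(p$options$data)
      fit <- fit_accumulation(tcs, model = p$options$model,
                              seed = p$options$seed)
      out <- list(model = fit$model, params = unclass(fit$params),
                  se = as.list(fit$se), sse = fit$sse, n_obs = fit$n_obs,
                  converged = fit$converged)
      if (p$options$compare) {
        other <- fit_accumulation(
          tcs, model = if (fit$model == "biphasic") "monophasic"
                       else "biphasic", seed = p$options$seed)
        cmpres <- if (fit$model == "biphasic")
          compare_models(other, fit) else compare_models(fit, other)
        out$comparison <- unclass(cmpres)
      }
      if (is.null(p$options$out))
        cat(jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE,
                             digits = NA), "\n")
      else jsonlite::write_json(out, p$options$out, auto_unbox = TRUE,
                                pretty = TRUE, digits = NA)
    },
    "permeability" = {
      p <- opt(list(
        o("--data", type = "character"),
        o("--out", type = "character", default = NULL)))
      assay <- read_transwell_csv(p$options$data)
      pe <- assay_permeability(assay)
      out <- list(per_replicate = pe, summary = attr(pe, "summary"),
                  mass_balance = mass_balance(assay))
      if (is.null(p$options$out))
        cat(jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE,
                             digits = NA, dataframe = "rows"), "\n")
      else jsonlite::write_json(out, p$options$out, auto_unbox = TRUE,
                                pretty = TRUE, digits = NA,
                                dataframe = "rows")
    },
    "run" = {
      p <- opt(list(
        o("--seed", type = "integer", default = 1L),
        o("--out", type = "character")))
      run_pipeline(pipeline_config(seed = p$options$seed),
                   out_dir = p$options$out)
    },
    {
      message("unknown subcommand: ", cmd)
      status <- 1L
    })
  invisible(status)
}
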