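#' Run the full binding-analysis pipeline
#'
#' Orchestrates every analysis stage from a single configuration: load and
#' correct titrations, Stern-Volmer and double-log fits per temperature,
#' van't Hoff thermodynamics with force classification, quenching-mechanism
#' classification, IDF/Scatchard analysis across protein concentrations,
#' TCSPC lifetime fits, mean residue ellipticity, and docking-score
#' conversion. Only the stages whose inputs are present in the configuration
#' run; downstream stages consume upstream outputs (van't Hoff consumes the
#' per-temperature double-log constants; the quenching verdict consumes the
#' Stern-Volmer fits and lifetime ratios). A stage error is recorded in the
#' report and halts only that stage's dependents.
#'
#' The configuration is a named list, or the path to a YAML file with the
#' same structure:
#' \describe{
#'   \item{binding_titrations}{character vector of titration CSV paths, one
#'     per temperature (see [read_titration_table()] for the format).}
#'   \item{idf_titrations}{character vector of titration CSV paths at
#'     distinct protein concentrations, one temperature.}
#'   \item{decays}{list: `traces` (decay CSV paths in titration order),
#'     `components` (default 2), and `tau0` (ns) or `tau0_trace` (path).}
#'   \item{cd}{list: `path` (CSV with `wavelength,theta_mdeg`),
#'     `protein_conc`, `path_length`, `n_residues`.}
#'   \item{docking_scores}{numeric vector of docking energies (kcal/mol).}
#'   \item{options}{list: `bracket_denominator`, `n_levels`, `trim`,
#'     `noise_tolerance`, `ratio_threshold`, `kb_temperature`,
#'     `r2_linear_threshold`.}
#' }
#'
#' @param config Named list or YAML file path.
#' @return An object of class `analysis_report`: nested list of per-stage
#'   results, `units` metadata, `warnings`, `errors` and `provenance`.
#'   Identical configuration and inputs yield an identical report apart from
#'   the `provenance$timestamp` field.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_schema("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  opts <- config$options %||% list()
  opt <- function(name, default) opts[[name]] %||% default

  # validate referenced files before any computation
  paths <- c(unlist(config$binding_titrations),
             unlist(config$idf_titrations),
             unlist(config$decays$traces),
             config$decays$tau0_trace,
             config$cd$path)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing) > 0) {
    stop_schema("input file(s) not found: ", paste(missing, collapse = ", "))
  }

  warnings_log <- character()
  errors_log <- character()
  report <- list()

  collect <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        errors_log <<- c(errors_log, paste0(stage, ": ", conditionMessage(e)))
        NULL
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log, paste0(stage, ": ",
                                                conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  # ---- per-temperature steady-state fits -------------------------------
  sv_fits <- NULL
  if (!is.null(config$binding_titrations)) {
    series <- collect("load_binding", lapply(config$binding_titrations,
                                             read_titration_table))
    if (!is.null(series)) {
      sv_fits <- collect("stern_volmer", lapply(series, stern_volmer_fit))
      dl_fits <- collect("double_log", lapply(
        series, double_log_fit,
        bracket_denominator = opt("bracket_denominator", "F")))
      report$stern_volmer <- lapply(sv_fits, unclass)
      report$double_log <- lapply(dl_fits, unclass)

      if (!is.null(dl_fits) && length(dl_fits) >= 2) {
        vh <- collect("vant_hoff", {
          temps <- vapply(dl_fits, `[[`, numeric(1), "temperature")
          kas <- vapply(dl_fits, `[[`, numeric(1), "k_a")
          vant_hoff_fit(temps, kas)
        })
        if (!is.null(vh)) {
          report$vant_hoff <- unclass(vh)
          tr <- collect("thermo", thermo_report(vh))
          if (!is.null(tr)) {
            report$thermo <- list(table = tr$table,
                                  force_label = tr$force_label)
          }
        }
      }
    }
  }

  # ---- lifetimes --------------------------------------------------------
  ratios <- numeric()
  if (!is.null(config$decays)) {
    lt <- collect("lifetime", {
      traces <- lapply(config$decays$traces, read_decay_table)
      ncomp <- config$decays[["components"]] %||% 2
      fits <- lapply(traces, fit_multiexponential, n_components = ncomp)
      tau0 <- config$decays[["tau0"]]
      if (is.null(tau0) && !is.null(config$decays$tau0_trace)) {
        tau0 <- fit_multiexponential(
          read_decay_table(config$decays$tau0_trace),
          n_components = ncomp)$tau_avg
      }
      list(fits = fits, tau0 = tau0,
           ratios = if (!is.null(tau0)) {
             lifetime_ratio_series(tau0, fits)
           } else numeric())
    })
    if (!is.null(lt)) {
      report$lifetime <- list(tau0 = lt$tau0,
                              fits = lapply(lt$fits, unclass),
                              tau0_over_tau = lt$ratios)
      ratios <- lt$ratios
    }
  }

  # ---- quenching mechanism ---------------------------------------------
  if (!is.null(sv_fits) && length(sv_fits) >= 1) {
    verdict <- collect("classify_quenching",
                       classify_quenching(sv_fits, ratios,
                                          opt("ratio_threshold", 0.05)))
    if (!is.null(verdict)) report$quenching <- unclass(verdict)
  }

  # ---- IDF / Scatchard --------------------------------------------------
  if (!is.null(config$idf_titrations)) {
    idf <- collect("idf", {
      series <- lapply(config$idf_titrations, read_titration_table)
      idf_analysis(series,
                   n_levels = opt("n_levels", 10),
                   trim = opt("trim", 0.05),
                   noise_tolerance = opt("noise_tolerance", 2),
                   r2_linear_threshold = opt("r2_linear_threshold", 0.95))
    })
    if (!is.null(idf)) {
      report$idf <- list(points = as.data.frame(idf$points),
                         fit = unclass(idf$fit))
    }
  }

  # ---- CD ---------------------------------------------------------------
  if (!is.null(config$cd)) {
    cd <- collect("cd", {
      tab <- utils::read.csv(config$cd$path, comment.char = "#")
      data.frame(
        wavelength = tab$wavelength,
        mre = mean_residue_ellipticity(tab$theta_mdeg,
                                       config$cd$protein_conc,
                                       config$cd$path_length,
                                       config$cd$n_residues))
    })
    if (!is.null(cd)) report$cd <- cd
  }

  # ---- docking-score conversion ----------------------------------------
  if (!is.null(config$docking_scores)) {
    dk <- collect("docking", {
      tt <- opt("kb_temperature", 300)
      data.frame(delta_g_kcal = config$docking_scores,
                 k_b = kb_from_score(config$docking_scores, tt),
                 temperature = tt)
    })
    if (!is.null(dk)) report$docking <- dk
  }

  report$units <- list(
    k_sv = "1/M", k_a = "1/M", k_b = "1/M", n_sites = "unitless",
    delta_h = "J/mol", delta_s = "J/(mol K)", delta_g = "J/mol",
    t_delta_s = "J/mol", temperature = "K", ligand_free = "mol/L",
    sigma_nu = "ligand per protein", lifetimes = "ns", tau_avg = "ns",
    mre = "deg cm^2/dmol", delta_g_kcal = "kcal/mol"
  )
  report$warnings <- warnings_log
  report$errors <- errors_log
  report$provenance <- list(
    package = "quenchbind",
    version = as.character(utils::packageVersion("quenchbind")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config
  )
  structure(report, class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  stages <- setdiff(names(x), c("units", "warnings", "errors", "provenance"))
  cat(sprintf("<analysis_report> stages: %s\n",
              paste(stages, collapse = ", ")))
  if (length(x$errors)) {
    cat("  errors:\n"); for (e in x$errors) cat("   -", e, "\n")
  }
  if (length(x$warnings)) cat(sprintf("  %d warning(s)\n", length(x$warnings)))
  invisible(x)
}

#' Write an analysis report to JSON
#'
#' @param report An [run_pipeline()] result (or any list).
#' @param path Output JSON path.
#' @param strip_timestamp Drop the provenance timestamp so identical analyses
#'   produce byte-identical files. Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, strip_timestamp = FALSE) {
  if (strip_timestamp && !is.null(report$provenance)) {
    report$provenance$timestamp <- NULL
  }
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}

#' Structural validation of an analysis report
#'
#' Checks the invariants the report promises consumers: known top-level
#' sections only, units metadata present, finite numeric results in each
#' stage, and character warning/error logs. A machine-readable description
#' of the layout ships in `inst/schema/analysis-report-schema.json`.
#'
#' @param report An [run_pipeline()] result.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_report <- function(report) {
  stopifnot(inherits(report, "analysis_report") || is.list(report))
  required <- c("units", "warnings", "errors", "provenance")
  allowed <- c("stern_volmer", "double_log", "vant_hoff", "thermo",
               "quenching", "idf", "lifetime", "cd", "docking", required)
  unknown <- setdiff(names(report), allowed)
  if (length(unknown)) {
    stop_schema("unknown report section(s): ", paste(unknown, collapse = ", "))
  }
  if (!all(required %in% names(report))) {
    stop_schema("missing required section(s): ",
                paste(setdiff(required, names(report)), collapse = ", "))
  }
  if (!is.character(report$warnings) || !is.character(report$errors)) {
    stop_schema("warnings and errors must be character vectors")
  }
  if (!is.list(report$units) || is.null(report$units$k_b)) {
    stop_schema("units metadata missing")
  }
  num_ok <- function(x) is.numeric(x) && all(is.finite(x) | is.na(x))
  walk <- function(x) {
    if (is.list(x)) return(all(vapply(x, walk, logical(1))))
    if (is.numeric(x)) return(num_ok(x))
    TRUE
  }
  for (sec in setdiff(names(report), c("provenance", required))) {
    if (!walk(report[[sec]])) {
      stop_schema("non-finite numeric value in section: ", sec)
    }
  }
  invisible(TRUE)
}
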