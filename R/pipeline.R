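#' Compare local and global unfolding free energies
#'
#' Builds the per-residue stability comparison: residues whose local
#' unfolding free energy from H/D exchange strictly exceeds the global
#' unfolding free energy from chemical denaturation, and those exceeding
#' 1.5 times it — the anomalously protected core. Thresholds are also
#' expressed in protection-factor units, `logP_eq = dG / (ln(10) R T)`,
#' and are always recomputed from the inputs.
#'
#' @param local Protection table from [protection()] / [hdx_analyze()]
#'   (columns `residue`, `aa`, `dG_local`, `temperature`).
#' @param global_fit An `lem_fit` from [fit_lem()] (or a list with
#'   `dG_H2O` and `temperature`).
#' @param factor Multiplier for the upper threshold (default 1.5).
#' @return Object of class `stability_report`: `dG_global`,
#'   `threshold_1x`, `threshold_fx` (= `factor * dG_global`), their logP
#'   equivalents, residue index vectors `above_global` and
#'   `above_factor` (the latter always a subset of the former), `factor`,
#'   `temperature`, and the joined per-residue `table`.
#' @export
compare_stability <- function(local, global_fit, factor = 1.5) {
  require_columns(local, c("residue", "dG_local"), "protection table")
  dG_global <- global_fit$dG_H2O
  if (is.null(dG_global) || !is.finite(dG_global)) {
    abort("compare_stability: global fit lacks dG_H2O")
  }
  T_local <- if ("temperature" %in% names(local)) local$temperature[1] else 298.15
  T_global <- global_fit$temperature %||% T_local
  if (abs(T_local - T_global) > 1) {
    abort(sprintf("compare_stability: temperature mismatch (%.2f vs %.2f K)",
                  T_local, T_global))
  }
  thr1 <- dG_global
  thrf <- factor * dG_global
  to_logp <- function(dg) dg / (log(10) * R_KCAL * T_local)
  tbl <- mutate(as_tibble(local),
                above_global = .data$dG_local > thr1,
                above_factor = .data$dG_local > thrf)
  structure(list(
    dG_global = dG_global, factor = factor, temperature = T_local,
    threshold_1x = thr1, threshold_fx = thrf,
    logP_threshold_1x = to_logp(thr1), logP_threshold_fx = to_logp(thrf),
    above_global = tbl$residue[tbl$above_global],
    above_factor = tbl$residue[tbl$above_factor],
    table = tbl
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability comparison at %.2f K\n", x$temperature))
  cat(sprintf("  dG_global = %.3f kcal/mol (logP equivalent %.2f)\n",
              x$dG_global, x$logP_threshold_1x))
  cat(sprintf("  %.1fx threshold = %.3f kcal/mol (logP equivalent %.2f)\n",
              x$factor, x$threshold_fx, x$logP_threshold_fx))
  cat(sprintf("  residues above dG_global: %d; above %.1fx: %d\n",
              length(x$above_global), x$factor, length(x$above_factor)))
  invisible(x)
}

#' Run the analysis pipeline from a configuration file
#'
#' Orchestrates the stages end to end from a YAML configuration. Present
#' stages run; absent stages are skipped. The `hdx` and `denat` stages
#' feed the stability comparison when both are present. Outputs (CSV per
#' stage plus a JSON run manifest) are written under `out_dir`; reruns
#' with the same config are byte-identical.
#'
#' Config keys (all paths relative to the config file):
#' \describe{
#'   \item{hdx}{`file` (long CSV, minutes), `pD`, `temperature`}
#'   \item{denat}{`file` (D, y CSV), `temperature`}
#'   \item{melt}{`file` (T, y CSV), `unit` ("K"/"C")}
#'   \item{dsc}{`file` (T, Cp CSV), `unit`, `baseline`}
#'   \item{csp}{`ref`, `state` peak-list files}
#'   \item{relax}{`file` (residue, aa, tau, y CSV), `kind`}
#' }
#'
#' @param config_path YAML file.
#' @param out_dir Output directory (default `<config dir>/results`).
#' @return Named list of stage results, invisibly.
#' @export
run_pipeline <- function(config_path, out_dir = NULL) {
  cfg <- yaml::read_yaml(config_path)
  base <- dirname(normalizePath(config_path))
  out_dir <- out_dir %||% file.path(base, "results")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  resolve <- function(p) if (is.null(p)) NULL else file.path(base, p)
  results <- list()
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  if (!is.null(cfg$hdx)) {
    results$hdx <- run_stage("hdx", function() {
      df <- read_series(resolve(cfg$hdx$file), x_unit = "min")
      names(df)[names(df) == "x"] <- "t"
      hdx_analyze(df, pD = cfg$hdx$pD %||% 6.5,
                  temperature = cfg$hdx$temperature %||% 298.15)
    })
    write_scores(dplyr::transmute(results$hdx, .data$residue, .data$aa,
                                  value = .data$dG_local, error = NA_real_,
                                  flag = .data$censored),
                 file.path(out_dir, "hdx_dG_local.csv"))
  }
  if (!is.null(cfg$denat)) {
    results$denat <- run_stage("denat", function() {
      df <- readr::read_csv(resolve(cfg$denat$file), show_col_types = FALSE)
      fit_lem(df, temperature = cfg$denat$temperature %||% 298.15)
    })
    readr::write_csv(tidy(results$denat), file.path(out_dir, "denat_fit.csv"))
  }
  if (!is.null(results$hdx) || !is.null(cfg$compare)) {
    if (is.null(results$hdx) && !is.null(cfg$compare)) {
      abort("pipeline: stability comparison requested but hdx stage missing")
    }
    if (!is.null(results$hdx) && is.null(results$denat) && !is.null(cfg$compare)) {
      abort("pipeline: stability comparison requested but denat stage missing")
    }
    if (!is.null(results$hdx) && !is.null(results$denat)) {
      results$comparison <- compare_stability(results$hdx, results$denat)
      readr::write_csv(results$comparison$table,
                       file.path(out_dir, "stability_comparison.csv"))
    }
  }
  if (!is.null(cfg$melt)) {
    results$melt <- run_stage("melt", function() {
      df <- readr::read_csv(resolve(cfg$melt$file), show_col_types = FALSE)
      fit_melt(df, temperature_unit = cfg$melt$unit %||% "K")
    })
    readr::write_csv(tidy(results$melt), file.path(out_dir, "melt_fit.csv"))
  }
  if (!is.null(cfg$dsc)) {
    results$dsc <- run_stage("dsc", function() {
      df <- readr::read_csv(resolve(cfg$dsc$file), show_col_types = FALSE)
      dsc_analyze(df, baseline = cfg$dsc$baseline %||% "progress",
                  temperature_unit = cfg$dsc$unit %||% "K")
    })
    readr::write_csv(tidy(results$dsc), file.path(out_dir, "dsc_result.csv"))
  }
  if (!is.null(cfg$csp)) {
    results$csp <- run_stage("csp", function() {
      ref <- read_peaklist(resolve(cfg$csp$ref))
      st <- read_peaklist(resolve(cfg$csp$state))
      significance_flags(csp(ref, st))
    })
    write_scores(dplyr::transmute(results$csp, .data$residue, .data$aa,
                                  value = .data$dd, error = NA_real_,
                                  flag = .data$significant),
                 file.path(out_dir, "csp.csv"))
  }
  if (!is.null(cfg$relax)) {
    results$relax <- run_stage("relax", function() {
      df <- readr::read_csv(resolve(cfg$relax$file), show_col_types = FALSE)
      fit_relaxation_set(df, kind = cfg$relax$kind %||% "R2")
    })
    readr::write_csv(results$relax, file.path(out_dir, "relaxation.csv"))
  }

  manifest <- list(
    package = "acpdyn",
    version = as.character(utils::packageVersion("acpdyn")),
    config = basename(config_path),
    stages = names(results),
    seed = cfg$seed %||% NA
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
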