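#' Full societal cost-effectiveness analysis of a three-arm trial
#'
#' Runs the whole pipeline on patient-level data: multiple imputation of
#' missing follow-up data, per-patient cost and effect computation, and
#' the stratified bootstrap for the three pairwise contrasts
#' (telemonitoring vs control, telemonitoring vs telephone, telephone vs
#' control), each with remission-based and QALY-based outputs, plus
#' optional cost-driver sensitivity scenarios.
#'
#' @param patients a `cea_patients` data frame (e.g. from
#'   [read_patients()] or [generate_trial()]).
#' @param costs a `cea_unit_costs` table; defaults to the packaged rates.
#' @param m number of imputations (default 5).
#' @param B bootstrap replicates per imputation (default 1000).
#' @param seed master seed for imputation and bootstrap.
#' @param wtp_grid willingness-to-pay grid for the CEACs.
#' @param horizon_years QALY horizon in years.
#' @param scenarios optional list of [sensitivity_scenario()]s; if
#'   supplied, remission-measure CEACs are recomputed per scenario with
#'   common random numbers.
#' @return An object of class `cea_analysis`: a list with `contrasts`
#'   (three `cea_contrast` objects), `imputation` (the imputation set),
#'   `arm_summaries` (per-arm cost/effect means pooled across
#'   imputations), `sensitivity` (long data frame or `NULL`) and
#'   `manifest` (run metadata).
#' @export
run_full_analysis <- function(patients, costs = default_unit_costs(),
                              m = 5, B = 1000, seed = 1,
                              wtp_grid = seq(0, 20000, by = 500),
                              horizon_years = 0.5, scenarios = NULL) {
  patients <- validate_patients(patients)
  costs <- validate_unit_costs(costs)
  imp <- impute(patients, m = m, seed = seed)
  contrasts <- list(
    c("telemonitoring", "control"),
    c("telemonitoring", "telephone"),
    c("telephone", "control")
  )
  results <- lapply(contrasts, function(ct) {
    contrast_analysis(imp, ct[1], ct[2], B = B, seed = seed, costs = costs,
                      horizon_years = horizon_years, wtp_grid = wtp_grid)
  })
  names(results) <- vapply(contrasts, paste, character(1), collapse = "_vs_")

  arm_summaries <- .arm_summaries(imp, costs, horizon_years)

  sens <- NULL
  if (!is.null(scenarios)) {
    sens <- do.call(rbind, lapply(contrasts, function(ct) {
      s <- scenario_ceacs(imp, ct[1], ct[2], scenarios, B = B, seed = seed,
                          costs = costs, horizon_years = horizon_years,
                          wtp_grid = wtp_grid)
      s$contrast <- paste(ct, collapse = "_vs_")
      s
    }))
  }
  manifest <- list(
    package = "ceatrial",
    version = as.character(utils::packageVersion("ceatrial")),
    seed = seed, m = m, B = B,
    wtp_max = max(wtp_grid), horizon_years = horizon_years,
    n_patients = nrow(patients),
    config_hash = config_hash(list(costs = unclass(costs), m = m, B = B,
                                   seed = seed, wtp_grid = wtp_grid,
                                   horizon_years = horizon_years)),
    imputation_method = imp$method_tag,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  structure(list(contrasts = results, imputation = imp,
                 arm_summaries = arm_summaries, sensitivity = sens,
                 manifest = manifest),
            class = "cea_analysis")
}

.arm_summaries <- function(imp, costs, horizon_years) {
  per_imp <- lapply(imp$datasets, function(d) {
    cb <- total_cost(d, costs)
    ef <- effect_summary(d, horizon_years = horizon_years)
    fields <- unlist(cost_fields())
    agg <- stats::aggregate(cb[, fields], by = list(arm = cb$arm), mean)
    eagg <- data.frame(
      arm = sort(unique(ef$arm)),
      remission_w0 = tapply(ef$in_remission_w0, ef$arm, mean),
      remission_w24 = tapply(ef$in_remission_w24, ef$arm, mean),
      weeks_in_remission = tapply(ef$weeks_in_remission, ef$arm, mean),
      mean_qaly = tapply(ef$qaly, ef$arm, mean),
      median_eq5d_w0 = tapply(ef$eq5d_w0, ef$arm, stats::median),
      median_eq5d_w24 = tapply(ef$eq5d_w24, ef$arm, stats::median))
    merge(agg, eagg, by = "arm")
  })
  num <- vapply(per_imp, function(d) as.matrix(d[, -1]),
                as.matrix(per_imp[[1]][, -1]))
  pooled <- apply(num, c(1, 2), mean)
  out <- data.frame(arm = per_imp[[1]]$arm, pooled, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Hash a configuration object
#'
#' Deterministic 31-bit polynomial rolling hash of the JSON
#' serialisation, recorded in run manifests so a rerun can verify it used
#' the same configuration.
#'
#' @param x any JSON-serialisable object.
#' @return Hex string.
#' @export
config_hash <- function(x) {
  bytes <- utf8ToInt(as.character(
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write analysis outputs as delimited text plus a run manifest
#'
#' Writes, per contrast, the bootstrap draws, the ICER/quadrant summary
#' and the acceptability curves as CSV, together with the per-arm
#' cost/effect summary table, any sensitivity CEACs, and a JSON run
#' manifest (seed, configuration hash, software version). Numeric tables
#' are written at full precision, so a rerun with the same seed is
#' byte-identical.
#'
#' @param results a `cea_analysis` from [run_full_analysis()], or a bare
#'   list with a `manifest` element for partial runs.
#' @param out_dir output directory (created if needed).
#' @return Character vector of files written (the manifest lists them
#'   too), invisibly.
#' @export
write_results <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir,
                  call. = FALSE)
  }
  if (file.access(out_dir, mode = 2) != 0) {
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  }
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    files <<- c(files, name)
  }
  if (!is.null(results$arm_summaries)) {
    put(results$arm_summaries, "arm_summaries.csv")
  }
  for (nm in names(results$contrasts)) {
    ct <- results$contrasts[[nm]]
    put(as.data.frame(ct$draws), paste0("draws_", nm, ".csv"))
    summ <- do.call(rbind, lapply(c("remission", "qaly"), function(ms) {
      s <- ct[[ms]]
      data.frame(measure = ms, median_icer = s$icer$median,
                 icer_ci_low = s$icer$ci_low,
                 icer_ci_high = s$icer$ci_high,
                 n_defined = s$icer$n_defined,
                 p_NE = s$quadrants["NE"], p_SE_dominant = s$quadrants["SE"],
                 p_SW = s$quadrants["SW"], p_NW = s$quadrants["NW"],
                 pooled_delta_cost = ct$pooled$delta_cost$estimate,
                 pooled_delta_effect = ct$pooled[[
                   paste0("delta_", ms)]]$estimate,
                 row.names = NULL)
    }))
    put(summ, paste0("icer_summary_", nm, ".csv"))
    cc <- do.call(rbind, lapply(c("remission", "qaly"), function(ms) {
      data.frame(measure = ms, ct[[ms]]$ceac)
    }))
    put(cc, paste0("ceac_", nm, ".csv"))
  }
  if (!is.null(results$sensitivity)) {
    put(results$sensitivity, "sensitivity_ceacs.csv")
  }
  manifest <- results$manifest
  manifest$files <- files
  manifest_path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(files, "run_manifest.json"))
}

#' @export
print.cea_analysis <- function(x, ...) {
  cat("Societal cost-effectiveness analysis:",
      x$manifest$n_patients, "patients, m =", x$manifest$m,
      "imputations, B =", x$manifest$B, "replicates\n\n")
  for (ct in x$contrasts) print(ct)
  invisible(x)
}
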