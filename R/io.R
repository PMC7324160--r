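#' Read a unit-trial table from CSV
#'
#' Expects the long-format schema of [isn_units]: required columns
#' `session, unit_id, phase, laser_mW, trial, spike_count, window_s`,
#' optional `depth_um, width_ms`. Malformed rows (unknown phase, negative
#' counts, non-positive windows) are reported with their row numbers.
#'
#' @param path CSV file path.
#' @return An [isn_units] table; an empty file yields an empty table with a
#'   warning.
#' @export
read_unit_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("unit table '", path, "' is empty")
    for (col in setdiff(unit_required_cols, names(df))) df[[col]] <- logical(0)
    class(df) <- c("isn_units", class(df))
    return(df)
  }
  validate_units(df)
}

#' Write a unit-trial table to CSV
#'
#' @param units An [isn_units] table.
#' @param path CSV file path.
#' @export
write_unit_table <- function(units, path) {
  units <- validate_units(units)
  utils::write.csv(as.data.frame(units), path, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic-experiment analysis pipeline
#'
#' Executes, on one seed: synthetic-data generation, pharmacological unit
#' classification, per-session laser normalization (`L0` from the average
#' inhibitory response), per-unit initial slopes, population curves, the
#' global equilibrium fit on the resulting dose-response dataset, and
#' stability analysis of the fitted network. This is the integration surface
#' tying the modules together; every stage is also available separately.
#'
#' @param config An [generator_config()].
#' @param seed Integer seed; fully determines the report.
#' @param n_restarts Restarts for the global fit.
#' @param fit If `FALSE`, stop after slopes (no model fit; faster).
#' @param out_dir Optional directory: writes `units.csv`,
#'   `classification.csv`, `slopes.csv`, `fit.json` and `manifest.json`.
#' @param alpha Classification significance level.
#' @param phases Phases kept for the model fit. With fewer than all three
#'   the parameters are identifiable only up to the equilibrium rescaling
#'   family; the report carries a note.
#' @return An object of class `isn_report`: classification table, per-session
#'   `L0`, slope table, population curves, fitted parameters (if requested),
#'   ISN verdict and stability boundary, plus the generation truth.
#' @export
run_pipeline <- function(config = generator_config(), seed = 1,
                         n_restarts = 200, fit = TRUE, out_dir = NULL,
                         alpha = 0.01, phases = isn_phases) {
  gen <- generate_dataset(config, seed = seed)
  units <- gen$units
  cls <- classify_units(units, method = "pharma", alpha = alpha)
  labels <- stats::setNames(cls$label, cls$unit_id)
  ## per-session L0 from the average I response of classified units
  sessions <- unique(units$session)
  L0 <- stats::setNames(rep(NA_real_, length(sessions)), sessions)
  norms <- list()
  for (s in sessions) {
    su <- units[units$session == s, , drop = FALSE]
    curve <- population_average(su, labels, "I", phase = "intact")
    nf <- find_L0(data.frame(laser_mW = curve$laser_mW, rate = curve$mean_rate))
    norms[[s]] <- nf
    L0[s] <- nf$L0_mW
  }
  slopes <- do.call(rbind, lapply(unique(units$unit_id), function(id) {
    u <- unit_rows(units, id)
    s <- u$session[1]
    if (!is.finite(L0[s])) return(NULL)
    sl <- initial_slope(u, L0[s])
    data.frame(unit_id = id, session = s, label = labels[id],
               raw_slope = sl$raw_slope, normalized_slope = sl$normalized_slope,
               baseline_rate = sl$baseline_rate)
  }))
  curves <- list(E = population_average(units, labels, "E"),
                 I = population_average(units, labels, "I"))
  fit_res <- NULL; isn <- NA; boundary <- NA_real_; notes <- character(0)
  if (fit) {
    ds <- build_dose_response(units, labels, L0)
    ds <- dose_response_dataset(ds[ds$phase %in% phases, , drop = FALSE])
    fit_res <- withCallingHandlers(
      fit_global(ds, n_restarts = n_restarts, seed = seed),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    isn <- is_isn(fit_res$params)
    boundary <- tryCatch(stability_boundary_ratio(fit_res$params),
                         error = function(e) NA_real_)
  }
  report <- structure(
    list(seed = seed, classification = cls, L0_mW = L0,
         normalizations = norms, slopes = slopes, curves = curves,
         fit = fit_res, isn = isn, stability_boundary = boundary,
         notes = notes, truth = gen$truth),
    class = "isn_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_unit_table(units, file.path(out_dir, "units.csv"))
    utils::write.csv(cls, file.path(out_dir, "classification.csv"), row.names = FALSE)
    utils::write.csv(slopes, file.path(out_dir, "slopes.csv"), row.names = FALSE)
    if (!is.null(fit_res)) {
      write_params_json(fit_res$params, file.path(out_dir, "fit.json"))
    }
    manifest <- list(seed = seed,
                     package_version = as.character(utils::packageVersion("isnfit")),
                     n_restarts = n_restarts, alpha = alpha,
                     n_sessions = config$n_sessions,
                     units_per_session = config$units_per_session,
                     trials_per_level = config$trials_per_level,
                     laser_mW = config$laser_mW)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.isn_report <- function(x, ...) {
  cat("<isn_report> seed =", x$seed, "\n")
  tab <- table(x$classification$label)
  cat("  classified units:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  per-session L0 (mW):",
      paste(sprintf("%s=%.3g", names(x$L0_mW), x$L0_mW), collapse = ", "), "\n")
  if (!is.null(x$slopes)) {
    med <- tapply(x$slopes$normalized_slope, x$slopes$label, stats::median)
    cat("  median normalized initial slope:",
        paste(sprintf("%s=%.3g", names(med), med), collapse = ", "), "\n")
  }
  if (!is.null(x$fit)) {
    cat(sprintf("  fitted W_EE = %.3g -> %s; stability boundary tau_I/tau_E = %.3g\n",
                x$fit$params$W_EE,
                if (isTRUE(x$isn)) "ISN" else "non-ISN",
                x$stability_boundary))
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}
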