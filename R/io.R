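#' Writers for tidy CSV outputs and JSON run manifests
#'
#' All numeric outputs of the package are plain CSV (trajectories, half-time
#' tables, steady-state tables, sensitivity scans, assay time courses) plus
#' a JSON manifest recording how they were produced.
#'
#' @name io
NULL

#' @rdname io
#' @param traj trajectory data.frame from [run_timeline()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(traj, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param tab data.frame (half-time table, steady table, or scan).
#' @export
write_table_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param report a `steady_report`.
#' @export
write_steady_csv <- function(report, path) {
  stopifnot(inherits(report, "steady_report"))
  df <- data.frame(protein = c(names(report$fractions), "Total RR pool"),
                   fraction_pct = c(unname(report$fractions),
                                    report$total_pct))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param tc tidy assay time course.
#' @export
write_assay_csv <- function(tc, path) {
  utils::write.csv(tc, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_assay_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a JSON run manifest
#'
#' Records the full parameter set, the scenario applied, solver settings,
#' the seed, and the package version, so any output table can be
#' regenerated.
#'
#' @param path output file.
#' @param params the `che_params` used.
#' @param scn scenario (or `NULL`).
#' @param seed integer seed (or `NA`).
#' @param extra named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, params, scn = NULL, seed = NA_integer_,
                           extra = list()) {
  m <- c(list(
    package = "phosrelay",
    version = as.character(utils::packageVersion("phosrelay")),
    seed = seed,
    scenario = if (is.null(scn)) "wild type" else
      list(label = scn$label, knockouts = scn$knockouts,
           rates_zeroed = scn$rates_zeroed),
    solver = list(steady = list(method = "lsoda", rtol = 1e-10, atol = 1e-12,
                                newton_tol = 1e-10),
                  decay = list(method = "vode", rtol = 1e-10, atol = 1e-14)),
    parameters = unclass(params)[c(.rate_names, .totals)]),
    extra)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a fit result as JSON
#'
#' @param fit a `fit_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  out <- list(estimates = as.list(fit$estimates),
              rss = fit$rss,
              optimizer = fit$optimizer,
              agreement = fit$agreement,
              converged = fit$converged,
              per_optimizer = lapply(fit$per_optimizer, function(r)
                list(estimates = as.list(r$estimates), rss = r$rss,
                     converged = r$converged)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
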