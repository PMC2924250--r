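#' Plan a one-at-a-time sensitivity scan
#'
#' Each listed parameter (rate constant or protein total) is multiplied in
#' turn by each factor while all others stay at baseline, and a scalar
#' robustness metric is recomputed. Two metrics are supported:
#'
#' * `"cheB1P_half_time"` - the CheB1-P shut-off half-time (s) from
#'   [decay_half_times()]; probes whether the CheY6 phosphate sink keeps
#'   terminating the slowest response regulator quickly.
#' * `"cheY4P_level_at_k1_off"` - the steady CheY4-P concentration (uM)
#'   with CheA2 autophosphorylation off (`k1 = 0`) but the CheA4 input to
#'   CheA3 still active; probes whether the CheB2-mediated phosphorelay
#'   still feeds the polar-cluster response regulators.
#'
#' `k5r` is excluded from the default parameter list: its baseline value is
#' zero, so multiplicative perturbation cannot move it.
#'
#' @param factors positive multipliers (default 0.1, 0.5, 1.5, 10).
#' @param parameters names of parameters to scan; default all rates and
#'   totals except `k5r`.
#' @param metric which metric to compute.
#' @return an object of class `sensitivity_plan`.
#' @export
sensitivity_plan <- function(factors = c(0.1, 0.5, 1.5, 10),
                             parameters = NULL,
                             metric = c("cheB1P_half_time",
                                        "cheY4P_level_at_k1_off")) {
  metric <- match.arg(metric)
  if (any(factors <= 0)) stop("factors must be positive")
  excluded <- character()
  if (is.null(parameters)) {
    parameters <- setdiff(c(.rate_names, .totals), "k5r")
    excluded <- "k5r"
  } else {
    bad <- setdiff(parameters, c(.rate_names, .totals))
    if (length(bad))
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
  }
  structure(list(factors = as.numeric(factors), parameters = parameters,
                 metric = metric, excluded = excluded),
            class = "sensitivity_plan")
}

#' Run a one-at-a-time sensitivity scan
#'
#' Evaluates the plan's metric on the full factorial grid of
#' `parameters x factors`. Perturbed systems that fail to reach a steady
#' state are flagged (`converged = FALSE`, metric `NA`) rather than dropped.
#' The scan is deterministic and row order follows the plan.
#'
#' @param params baseline `che_params`.
#' @param plan a `sensitivity_plan`.
#' @param ... passed to the underlying protocol ([decay_half_times()] or
#'   [find_steady_state()]), e.g. `n_grid` to trade accuracy for speed.
#' @return data.frame with columns `parameter`, `factor`, `value` (the
#'   metric), `converged`; attributes `metric`, `baseline` (unperturbed
#'   metric value) and `excluded`.
#' @export
run_scan <- function(params, plan, ...) {
  validate_params(params)
  stopifnot(inherits(plan, "sensitivity_plan"))
  eval_metric <- function(p) {
    if (plan$metric == "cheB1P_half_time") {
      tab <- decay_half_times(p, ...)
      tab$half_time[tab$species == "CheB1-P"]
    } else {
      p_off <- p; p_off$k1 <- 0
      ss <- find_steady_state(p_off, ...)
      ss[["Y4P"]]
    }
  }
  baseline <- eval_metric(params)
  grid <- expand.grid(factor = plan$factors, parameter = plan$parameters,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("parameter", "factor")]
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p[[grid$parameter[i]]] <- p[[grid$parameter[i]]] * grid$factor[i]
    val <- tryCatch(eval_metric(p), error = function(e) NA_real_)
    data.frame(value = val, converged = !is.na(val))
  })
  out <- cbind(grid, do.call(rbind, res))
  rownames(out) <- NULL
  attr(out, "metric") <- plan$metric
  attr(out, "baseline") <- baseline
  attr(out, "excluded") <- plan$excluded
  out
}

#' Reshape a scan into a parameters-by-factors matrix
#'
#' @param scan output of [run_scan()].
#' @return data.frame, one row per parameter, one column per factor.
#' @export
scan_wide <- function(scan) {
  wide <- stats::reshape(scan[, c("parameter", "factor", "value")],
                         idvar = "parameter", timevar = "factor",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "x", names(wide))
  rownames(wide) <- NULL
  wide
}
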