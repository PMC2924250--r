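#' Define a genetic / biochemical perturbation scenario
#'
#' A scenario is a recipe for modifying a parameter set: protein knockouts
#' (total concentration set to zero), removal of the CheA3 phosphatase
#' activity (`k15a = k15b = 0`), and zeroing of individual rate constants.
#' Scenarios compose: all listed modifications are applied together by
#' [apply_scenario()].
#'
#' @param knockouts character vector of protein names to delete; any of
#'   `"CheA2", "CheA3", "CheY3", "CheY4", "CheY6", "CheB1", "CheB2"`.
#' @param rates_zeroed character vector of rate-constant names to set to
#'   zero, e.g. `"k6r"` for the reverse transfer from CheB1-P to CheA2.
#' @param phosphatase_off logical; shorthand for zeroing `k15a` and `k15b`.
#' @param label free-text label carried into output tables.
#' @return an object of class `che_scenario`.
#' @examples
#' scenario(knockouts = "CheY6")                      # sink deletion
#' scenario(phosphatase_off = TRUE, label = "no phosphatase")
#' scenario(knockouts = "CheY6", rates_zeroed = "k6r")
#' @export
scenario <- function(knockouts = character(), rates_zeroed = character(),
                     phosphatase_off = FALSE, label = NULL) {
  knockouts <- as.character(knockouts)
  rates_zeroed <- as.character(rates_zeroed)
  bad <- setdiff(knockouts, names(.proteins))
  if (length(bad))
    stop("unknown protein name(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(names(.proteins), collapse = ", "), ")")
  bad <- setdiff(rates_zeroed, .rate_names)
  if (length(bad))
    stop("unknown rate name(s): ", paste(bad, collapse = ", "))
  if (isTRUE(phosphatase_off))
    rates_zeroed <- union(rates_zeroed, c("k15a", "k15b"))
  if (is.null(label)) {
    parts <- c(if (length(knockouts)) paste0("d", knockouts),
               if (length(rates_zeroed)) paste0(rates_zeroed, "=0"))
    label <- if (length(parts)) paste(parts, collapse = "+") else "wild type"
  }
  structure(list(knockouts = knockouts, rates_zeroed = rates_zeroed,
                 label = label),
            class = "che_scenario")
}

#' @export
print.che_scenario <- function(x, ...) {
  cat("<che_scenario>", x$label, "\n")
  if (length(x$knockouts))
    cat("  knockouts:", paste(x$knockouts, collapse = ", "), "\n")
  if (length(x$rates_zeroed))
    cat("  rates zeroed:", paste(x$rates_zeroed, collapse = ", "), "\n")
  invisible(x)
}

#' Apply a scenario to a parameter set
#'
#' Returns a modified copy of `params`: each knocked-out protein's total is
#' set to zero and each listed rate constant is set to zero. An empty
#' scenario returns the parameter set unchanged.
#'
#' @param params a `che_params` object.
#' @param scn a `che_scenario` (or `NULL` for no modification).
#' @return a `che_params` object.
#' @export
apply_scenario <- function(params, scn = NULL) {
  validate_params(params)
  if (is.null(scn)) return(params)
  stopifnot(inherits(scn, "che_scenario"))
  for (pr in scn$knockouts) params[[.proteins[[pr]]]] <- 0
  for (rt in scn$rates_zeroed) params[[rt]] <- 0
  params
}
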