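#' Default model parameterization
#'
#' Builds the full parameter set of the chemotaxis phosphotransfer network:
#' kinase input rates, forward/reverse phosphotransfer constants,
#' response-regulator autodephosphorylation constants, the two CheA3
#' phosphatase constants, and the seven total protein concentrations.
#' Defaults are the experimentally determined and fitted constants for
#' *R. sphaeroides*. Second-order rate constants are given on the
#' (M s)^-1 scale (as usually reported); model code rescales them to
#' (uM s)^-1 internally so that all state variables live in uM.
#'
#' Rate-constant naming: `k3 ... k9` are forward phosphotransfer constants
#' (kinase-P to RR), `k3r ... k9r` the corresponding reverse constants
#' (RR-P back to kinase; the field writes these k_-3 ... k_-9), `k10 ... k14`
#' RR-P autodephosphorylation, and `k15a`/`k15b` CheY6-P dephosphorylation
#' catalyzed by CheA3 and CheA3-P respectively. `k5r` (reverse transfer from
#' CheY6-P to CheA2) is zero: CheY6-P does not rephosphorylate CheA2.
#'
#' @param ... named overrides of any rate or total, e.g. `k1 = 0`,
#'   `Y6T = 450`.
#' @return An object of class `che_params`: a named list of non-negative
#'   numerics with fields `k1, k2, k3..k7, k3r..k7r, k8, k9, k8r, k9r,
#'   k10..k14, k15a, k15b` and totals `A2T, A3T, Y3T, Y4T, Y6T, B1T, B2T`
#'   (uM).
#' @examples
#' p <- che_parameters()
#' p$k1              # CheA2 autophosphorylation, s^-1
#' che_parameters(Y6T = 0)$Y6T  # CheY6 knockout
#' @export
che_parameters <- function(...) {
  p <- list(
    # kinase phosphoryl input (s^-1)
    k1 = 0.12,     # CheA2 autophosphorylation
    k2 = 0.98,     # phosphorylation of CheA3 by CheA4 (CheA4 implicit)
    # forward / reverse phosphotransfer, (M s)^-1
    k3 = 6.60e3,  k3r = 1.17e4,   # CheA2-P <-> CheY3
    k4 = 8.85e5,  k4r = 2.32e5,   # CheA2-P <-> CheY4
    k5 = 1.54e3,  k5r = 0,        # CheA2-P  -> CheY6 (irreversible)
    k6 = 1.78e6,  k6r = 2.85e6,   # CheA2-P <-> CheB1
    k7 = 3.07e3,  k7r = 1.53e3,   # CheA2-P <-> CheB2
    k8 = 7.75e5,  k8r = 2.83e3,   # CheA3-P <-> CheY6
    k9 = 6.15e4,  k9r = 3.10e3,   # CheA3-P <-> CheB2
    # RR-P autodephosphorylation (s^-1)
    k10 = 1.93e-2,  # CheY3-P
    k11 = 1.82e-2,  # CheY4-P
    k12 = 1.69e-1,  # CheY6-P
    k13 = 1.73e-4,  # CheB1-P
    k14 = 1.33e-2,  # CheB2-P
    # CheA3 phosphatase acting on CheY6-P, (M s)^-1
    k15a = 5.20e3,  # catalyzed by CheA3
    k15b = 5.20e3,  # catalyzed by CheA3-P
    # total protein concentrations (uM)
    A2T = 89.9, A3T = 89.9,
    Y3T = 3.5, Y4T = 13.8, Y6T = 225, B1T = 81.2, B2T = 20.8
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad))
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  class(p) <- "che_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks that every rate constant and every total concentration is a single
#' finite non-negative number.
#'
#' @param params a `che_params` object.
#' @return `params`, invisibly; signals an error on violation.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "che_params"))
  for (nm in c(.rate_names, .totals)) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter ", nm, " must be a single finite number")
    if (v < 0)
      stop("parameter ", nm, " is negative (", v, ")")
  }
  invisible(params)
}

# Convert to internal units: uM for concentrations, s^-1 and (uM s)^-1 for
# rates. Returns a plain named numeric vector used by all solver code.
.p_internal <- function(params) {
  v <- unlist(params[c(.rate_names, .totals)])
  v[.second_order_rates] <- v[.second_order_rates] / 1e6
  v
}

#' @export
print.che_params <- function(x, ...) {
  cat("<che_params> chemotaxis network parameter set\n")
  cat("  first-order rates (s^-1):\n")
  for (nm in .first_order_rates)
    cat(sprintf("    %-5s %g\n", nm, x[[nm]]))
  cat("  second-order rates ((M s)^-1):\n")
  for (nm in .second_order_rates)
    cat(sprintf("    %-5s %g\n", nm, x[[nm]]))
  cat("  protein totals (uM):\n")
  for (nm in .totals)
    cat(sprintf("    %-5s %g\n", nm, x[[nm]]))
  invisible(x)
}

.param_comments <- c(
  k1 = "s^-1, CheA2 autophosphorylation",
  k2 = "s^-1, CheA3 phosphorylation by CheA4",
  k3 = "(M s)^-1, CheA2-P -> CheY3", k3r = "(M s)^-1, CheY3-P -> CheA2",
  k4 = "(M s)^-1, CheA2-P -> CheY4", k4r = "(M s)^-1, CheY4-P -> CheA2",
  k5 = "(M s)^-1, CheA2-P -> CheY6", k5r = "(M s)^-1, CheY6-P -> CheA2 (zero)",
  k6 = "(M s)^-1, CheA2-P -> CheB1", k6r = "(M s)^-1, CheB1-P -> CheA2",
  k7 = "(M s)^-1, CheA2-P -> CheB2", k7r = "(M s)^-1, CheB2-P -> CheA2",
  k8 = "(M s)^-1, CheA3-P -> CheY6", k8r = "(M s)^-1, CheY6-P -> CheA3",
  k9 = "(M s)^-1, CheA3-P -> CheB2", k9r = "(M s)^-1, CheB2-P -> CheA3",
  k10 = "s^-1, CheY3-P autodephosphorylation",
  k11 = "s^-1, CheY4-P autodephosphorylation",
  k12 = "s^-1, CheY6-P autodephosphorylation",
  k13 = "s^-1, CheB1-P autodephosphorylation",
  k14 = "s^-1, CheB2-P autodephosphorylation",
  k15a = "(M s)^-1, CheY6-P dephosphorylation by CheA3",
  k15b = "(M s)^-1, CheY6-P dephosphorylation by CheA3-P",
  A2T = "uM, total CheA2", A3T = "uM, total CheA3",
  Y3T = "uM, total CheY3", Y4T = "uM, total CheY4", Y6T = "uM, total CheY6",
  B1T = "uM, total CheB1", B2T = "uM, total CheB2")

#' Write a parameter set to a flat text config
#'
#' One `key: value` pair per line, units noted in a trailing comment.
#' The format round-trips exactly through [read_params()].
#'
#' @param params a `che_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  nms <- c(.rate_names, .totals)
  lines <- c("# chemotaxis phosphotransfer network parameters",
             sprintf("%s: %.15g  # %s", nms,
                     vapply(nms, function(n) params[[n]], 0),
                     .param_comments[nms]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a parameter set from a flat text config
#'
#' @param path file written by [write_params()] (or hand-edited in the same
#'   `key: value` format; `#` starts a comment).
#' @return a `che_params` object.
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- vapply(kv, length, 0L) != 2L
  if (any(bad)) stop("malformed line(s) in ", path)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[[`, "", 2L)))
  if (anyNA(vals)) stop("non-numeric value(s) in ", path)
  do.call(che_parameters, as.list(stats::setNames(vals, keys)))
}

#' Construct a network state
#'
#' A snapshot of the seven phosphoform concentrations. Unphosphorylated
#' partners are implied by conservation and can be recovered with
#' [unphosphorylated()].
#'
#' @param A2P,A3P,Y3P,Y4P,Y6P,B1P,B2P phosphoform concentrations (uM).
#' @param params optional `che_params`; when given, each phosphoform is
#'   checked against its total (0 <= XP <= XT).
#' @return named numeric vector of length 7, class `che_state`.
#' @export
network_state <- function(A2P = 0, A3P = 0, Y3P = 0, Y4P = 0, Y6P = 0,
                          B1P = 0, B2P = 0, params = NULL) {
  s <- c(A2P = A2P, A3P = A3P, Y3P = Y3P, Y4P = Y4P, Y6P = Y6P,
         B1P = B1P, B2P = B2P)
  if (!all(is.finite(s))) stop("non-finite concentration")
  if (any(s < 0)) stop("negative concentration")
  if (!is.null(params)) {
    tot <- unlist(params[.totals])[.total_of[.species]]
    if (any(s > tot + 1e-9))
      stop("phosphoform exceeds its total concentration")
  }
  class(s) <- c("che_state", "numeric")
  s
}

#' Unphosphorylated partner concentrations
#'
#' @param state named phosphoform vector (uM).
#' @param params a `che_params` object supplying the totals.
#' @return named vector `A2, A3, Y3, Y4, Y6, B1, B2` (uM), each
#'   `XT - XP`.
#' @export
unphosphorylated <- function(state, params) {
  tot <- vapply(.totals, function(n) params[[n]], 0)
  u <- tot - as.numeric(state[.species])
  names(u) <- sub("T$", "", .totals)
  u
}
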