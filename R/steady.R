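#' Steady state of the phosphotransfer network
#'
#' Integrates the network from a fully unphosphorylated initial condition
#' over a long horizon with a stiff solver, then refines the endpoint by a
#' damped Newton iteration on the algebraic system `rhs(x) = 0` (Jacobian by
#' central finite differences). Convergence requires the max-norm of the
#' right-hand side to fall below `tol`.
#'
#' The slowest relaxation mode of the network is set by CheB1-P
#' autodephosphorylation (time constant ~ 1/k13 ~ 5.8e3 s), hence the
#' default 1e5 s horizon.
#'
#' @param params a `che_params` object.
#' @param horizon integration horizon (s) for the transient phase.
#' @param init `"unphos"` (default) starts from all phosphoforms zero;
#'   `"phos"` starts from the fully phosphorylated state (used to probe
#'   uniqueness of the steady state).
#' @param refine logical; run the Newton refinement (default `TRUE`).
#' @param tol convergence tolerance on `max(abs(rhs))`, uM/s.
#' @return a `che_state` phosphoform vector with attribute `rhs_norm`.
#' @examples
#' ss <- find_steady_state(che_parameters())
#' attr(ss, "rhs_norm") < 1e-10
#' @export
find_steady_state <- function(params, horizon = 1e5, init = c("unphos", "phos"),
                              refine = TRUE, tol = 1e-10) {
  validate_params(params)
  init <- match.arg(init)
  q <- .p_internal(params)
  y0 <- if (init == "unphos") {
    stats::setNames(numeric(7), .species)
  } else {
    stats::setNames(q[.total_of[.species]], .species)
  }
  out <- deSolve::ode(y0, c(0, horizon), .ode_func, q, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12, maxsteps = 1e5)
  y <- out[nrow(out), .species]
  if (refine) y <- .newton_refine(y, q, tol)
  nrm <- max(abs(.che_rhs(y, q)))
  if (nrm >= tol)
    stop("steady state did not converge: ||rhs||_inf = ", signif(nrm, 3),
         " uM/s (tol ", tol, ")")
  # clamp tiny negative round-off and cap at totals
  y <- pmin(pmax(y, 0), q[.total_of[.species]])
  s <- network_state(y[["A2P"]], y[["A3P"]], y[["Y3P"]], y[["Y4P"]],
                     y[["Y6P"]], y[["B1P"]], y[["B2P"]])
  attr(s, "rhs_norm") <- max(abs(.che_rhs(as.numeric(s), q)))
  s
}

# damped Newton with finite-difference Jacobian on the 7-species system
.newton_refine <- function(y, q, tol, max_iter = 60) {
  f <- .che_rhs(y, q)
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < tol * 0.01) break
    J <- .fd_jacobian(y, q)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      y_new <- y + lambda * step
      # keep iterates inside the physical box
      y_new <- pmin(pmax(y_new, 0), q[.total_of[.species]])
      f_new <- .che_rhs(y_new, q)
      if (max(abs(f_new)) < max(abs(f)) || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    if (max(abs(f_new)) >= max(abs(f))) break  # no progress; keep y
    y <- y_new; f <- f_new
  }
  y
}

.fd_jacobian <- function(y, q) {
  n <- length(y)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-7 * max(1, abs(y[j]))
    yp <- y; yp[j] <- yp[j] + h
    ym <- y; ym[j] <- ym[j] - h
    J[, j] <- (.che_rhs(yp, q) - .che_rhs(ym, q)) / (2 * h)
  }
  J
}

#' Steady-state phosphorylated fractions
#'
#' Wraps [find_steady_state()] and reports, for each of the five response
#' regulators, the percentage of its pool that is phosphorylated
#' (`100 * XP / XT`), together with the concentration-weighted percentage of
#' the combined five-RR pool. Knocked-out proteins (total zero) are reported
#' as `NA` and excluded from the pool percentage.
#'
#' @param params a `che_params` object.
#' @param ... passed to [find_steady_state()].
#' @return an object of class `steady_report`: list with `fractions`
#'   (named percentage vector over CheY3, CheY4, CheY6, CheB1, CheB2),
#'   `total_pct` (pool percentage), and `state` (the steady phosphoform
#'   vector, including the kinases).
#' @examples
#' rep <- steady_fractions(che_parameters())
#' round(rep$fractions)     # ~ c(30, 75, 64, 33, 40)
#' round(rep$total_pct)     # ~ 55
#' @export
steady_fractions <- function(params, ...) {
  s <- find_steady_state(params, ...)
  rr_tot <- vapply(.total_of[.rr_species], function(n) params[[n]], 0)
  rr_p <- as.numeric(s[.rr_species])
  frac <- ifelse(rr_tot > 0, 100 * rr_p / rr_tot, NA_real_)
  names(frac) <- c("CheY3", "CheY4", "CheY6", "CheB1", "CheB2")
  total_pct <- if (sum(rr_tot) > 0) 100 * sum(rr_p) / sum(rr_tot) else NA_real_
  structure(list(fractions = frac, total_pct = total_pct, state = s),
            class = "steady_report")
}

#' @export
print.steady_report <- function(x, ...) {
  cat("<steady_report> fraction phosphorylated (%)\n")
  for (nm in names(x$fractions))
    cat(sprintf("  %-6s %s\n", nm,
                if (is.na(x$fractions[[nm]])) "absent"
                else sprintf("%.1f", x$fractions[[nm]])))
  cat(sprintf("  total RR pool: %.1f\n", x$total_pct))
  invisible(x)
}
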