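#' Signal-termination half-times after kinase shut-off
#'
#' Implements the shut-off protocol used to characterize signal
#' termination: the (possibly perturbed) network is brought to steady state
#' with both phosphoryl inputs active, then CheA2 autophosphorylation and
#' CheA4-mediated phosphorylation of CheA3 are switched off simultaneously
#' (`k1 = k2 = 0`) and each response-regulator phosphoform is followed until
#' it falls to half of its steady-state level. The decay is integrated with
#' a stiff solver on a dense logarithmic time grid and the half-level
#' crossing is located by interpolation between grid points, not by
#' nearest-neighbor lookup.
#'
#' @param params a `che_params` object (baseline parameterization).
#' @param scn optional `che_scenario` applied before equilibration
#'   (knockouts, phosphatase removal, zeroed rates).
#' @param horizon decay horizon (s). If a phosphoform has not reached half
#'   of its steady level by then, it is reported censored at the horizon.
#' @param n_grid number of logarithmically spaced sample points for the
#'   decay integration.
#' @return data.frame with one row per response regulator: `species`,
#'   `steady_level` (uM), `half_time` (s), `censored` (logical), `absent`
#'   (TRUE for knocked-out proteins, whose half-time is `NA`).
#' @examples
#' \donttest{
#' wt <- decay_half_times(che_parameters())
#' wt$half_time  # ~ (4.9, 7.3, 1.3, 4.2, 4.8) s ordering Y3,Y4,Y6,B1,B2
#' }
#' @export
decay_half_times <- function(params, scn = NULL, horizon = 1e5,
                             n_grid = 3000) {
  p <- apply_scenario(params, scn)
  if (p$k1 == 0 && p$k2 == 0)
    stop("both phosphoryl inputs are already off; the shut-off protocol ",
         "requires reactions 1 and 2 active during equilibration")
  ss <- find_steady_state(p)
  p_off <- p; p_off$k1 <- 0; p_off$k2 <- 0
  traj <- .decay_trajectory(ss, p_off, horizon, n_grid)
  species_names <- c(Y3P = "CheY3-P", Y4P = "CheY4-P", Y6P = "CheY6-P",
                     B1P = "CheB1-P", B2P = "CheB2-P")
  rows <- lapply(.rr_species, function(sp) {
    tot <- p[[.total_of[[sp]]]]
    lev <- ss[[sp]]
    if (tot <= 0) {
      return(data.frame(species = species_names[[sp]], steady_level = 0,
                        half_time = NA_real_, censored = FALSE,
                        absent = TRUE))
    }
    ht <- .first_crossing(traj$time, traj[[sp]], lev / 2)
    data.frame(species = species_names[[sp]], steady_level = lev,
               half_time = if (is.na(ht)) horizon else ht,
               censored = is.na(ht), absent = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "scenario") <- if (is.null(scn)) "wild type" else scn$label
  out
}

# dense shut-off decay, log-spaced grid from 1e-3 s to the horizon
.decay_trajectory <- function(state, params_off, horizon, n_grid) {
  q <- .p_internal(params_off)
  tt <- unique(c(0, 10^seq(-3, log10(horizon), length.out = n_grid)))
  y0 <- stats::setNames(as.numeric(state[.species]), .species)
  out <- deSolve::ode(y0, tt, .ode_func, q, method = "vode",
                      rtol = 1e-10, atol = 1e-14, maxsteps = 1e5)
  as.data.frame(out)
}

# first downward crossing of `target`, linear interpolation in the
# bracketing interval; NA when never crossed
.first_crossing <- function(times, values, target) {
  if (values[1] <= target) return(0)
  i <- which(values <= target)[1]
  if (is.na(i)) return(NA_real_)
  t0 <- times[i - 1]; t1 <- times[i]
  v0 <- values[i - 1]; v1 <- values[i]
  t0 + (target - v0) * (t1 - t0) / (v1 - v0)
}

#' CheB1-P half-time with the CheY6 sink and its escape route removed
#'
#' The combined perturbation that isolates CheB1-P autodephosphorylation:
#' CheY6 deleted (`Y6T = 0`) and the reverse phosphotransfer from CheB1-P to
#' CheA2 (`k6r`, i.e. the constant written k_-6) set to zero, so CheB1-P can
#' no longer drain through any phosphate sink. Its shut-off half-time then
#' approaches the autodephosphorylation limit `ln(2)/k13` (~4000 s), up to
#' the delay caused by rephosphorylation from residual CheA2-P.
#'
#' @param params a `che_params` object.
#' @param ... passed to [decay_half_times()].
#' @return the CheB1-P half-time (s), a single number.
#' @export
sink_ablation_half_time <- function(params, ...) {
  scn <- scenario(knockouts = "CheY6", rates_zeroed = "k6r",
                  label = "dCheY6 + k6r=0")
  tab <- decay_half_times(params, scn, ...)
  tab$half_time[tab$species == "CheB1-P"]
}

#' Autodephosphorylation half-times implied by the rate constants
#'
#' The analytic first-order half-life `ln(2)/k` for each response
#' regulator's autodephosphorylation constant. These are the values the
#' shut-off half-times collapse to when every phosphotransfer route is
#' removed.
#'
#' @param params a `che_params` object.
#' @return named vector of half-times (s) for CheY3-P, CheY4-P, CheY6-P,
#'   CheB1-P, CheB2-P.
#' @export
autodephos_half_times <- function(params = che_parameters()) {
  k <- c(params$k10, params$k11, params$k12, params$k13, params$k14)
  stats::setNames(log(2) / k,
                  c("CheY3-P", "CheY4-P", "CheY6-P", "CheB1-P", "CheB2-P"))
}
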