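#' Mass-action right-hand side of the network ODEs
#'
#' Time derivatives of the seven phosphoform concentrations under the
#' fifteen-reaction scheme: kinase phosphoryl input (reactions 1-2),
#' reversible phosphotransfer from CheA2-P to all five RRs (3-7) and from
#' CheA3-P to CheY6 and CheB2 (8-9), RR-P autodephosphorylation (10-14),
#' and catalytic dephosphorylation of CheY6-P by CheA3 / CheA3-P (15a/15b).
#' Unphosphorylated species enter as `XT - XP`, so conservation holds by
#' construction along any trajectory.
#'
#' @param state named phosphoform vector (uM), see [network_state()].
#' @param params a `che_params` object.
#' @return named numeric vector of derivatives (uM/s), one per phosphoform.
#' @examples
#' p <- che_parameters()
#' che_rhs(network_state(), p)["A2P"]  # k1 * A2T at the unphosphorylated state
#' @export
che_rhs <- function(state, params) {
  validate_params(params)
  .che_rhs(as.numeric(state[.species]), .p_internal(params))
}

# core RHS on internal-unit parameter vector; `y` ordered as .species
.che_rhs <- function(y, q) {
  A2P <- y[1]; A3P <- y[2]; Y3P <- y[3]; Y4P <- y[4]
  Y6P <- y[5]; B1P <- y[6]; B2P <- y[7]
  A2 <- q[["A2T"]] - A2P; A3 <- q[["A3T"]] - A3P
  Y3 <- q[["Y3T"]] - Y3P; Y4 <- q[["Y4T"]] - Y4P; Y6 <- q[["Y6T"]] - Y6P
  B1 <- q[["B1T"]] - B1P; B2 <- q[["B2T"]] - B2P

  dA2P <- q[["k1"]] * A2 -
    (q[["k3"]] * A2P * Y3 - q[["k3r"]] * A2 * Y3P) -
    (q[["k4"]] * A2P * Y4 - q[["k4r"]] * A2 * Y4P) -
    (q[["k5"]] * A2P * Y6 - q[["k5r"]] * A2 * Y6P) -
    (q[["k6"]] * A2P * B1 - q[["k6r"]] * A2 * B1P) -
    (q[["k7"]] * A2P * B2 - q[["k7r"]] * A2 * B2P)
  dA3P <- q[["k2"]] * A3 -
    (q[["k8"]] * A3P * Y6 - q[["k8r"]] * A3 * Y6P) -
    (q[["k9"]] * A3P * B2 - q[["k9r"]] * A3 * B2P)
  dY3P <- q[["k3"]] * A2P * Y3 - q[["k3r"]] * A2 * Y3P - q[["k10"]] * Y3P
  dY4P <- q[["k4"]] * A2P * Y4 - q[["k4r"]] * A2 * Y4P - q[["k11"]] * Y4P
  dY6P <- q[["k5"]] * A2P * Y6 - q[["k5r"]] * A2 * Y6P +
    q[["k8"]] * A3P * Y6 - q[["k8r"]] * A3 * Y6P -
    q[["k12"]] * Y6P - q[["k15a"]] * A3 * Y6P - q[["k15b"]] * A3P * Y6P
  dB1P <- q[["k6"]] * A2P * B1 - q[["k6r"]] * A2 * B1P - q[["k13"]] * B1P
  dB2P <- q[["k7"]] * A2P * B2 - q[["k7r"]] * A2 * B2P +
    q[["k9"]] * A3P * B2 - q[["k9r"]] * A3 * B2P - q[["k14"]] * B2P

  c(A2P = dA2P, A3P = dA3P, Y3P = dY3P, Y4P = dY4P, Y6P = dY6P,
    B1P = dB1P, B2P = dB2P)
}

# deSolve-compatible derivative function
.ode_func <- function(t, y, q) list(.che_rhs(y, q))

.reaction_ids <- c("r1", "r2", "r3", "r4", "r5", "r6", "r7", "r8", "r9",
                   "r10", "r11", "r12", "r13", "r14", "r15a", "r15b")

# stoichiometry: species x reaction (net, forward direction positive)
.stoich <- local({
  S <- matrix(0, nrow = 7, ncol = 16,
              dimnames = list(.species, .reaction_ids))
  S["A2P", "r1"] <- 1
  S["A3P", "r2"] <- 1
  S["A2P", "r3"] <- -1; S["Y3P", "r3"] <- 1
  S["A2P", "r4"] <- -1; S["Y4P", "r4"] <- 1
  S["A2P", "r5"] <- -1; S["Y6P", "r5"] <- 1
  S["A2P", "r6"] <- -1; S["B1P", "r6"] <- 1
  S["A2P", "r7"] <- -1; S["B2P", "r7"] <- 1
  S["A3P", "r8"] <- -1; S["Y6P", "r8"] <- 1
  S["A3P", "r9"] <- -1; S["B2P", "r9"] <- 1
  S["Y3P", "r10"] <- -1
  S["Y4P", "r11"] <- -1
  S["Y6P", "r12"] <- -1
  S["B1P", "r13"] <- -1
  S["B2P", "r14"] <- -1
  S["Y6P", "r15a"] <- -1
  S["Y6P", "r15b"] <- -1
  S
})

#' Net reaction fluxes at a state
#'
#' Signed net rate of each of the sixteen elementary reaction channels
#' (reactions 1-14 plus the two phosphatase channels 15a/15b), in uM/s.
#' Phosphotransfer fluxes are forward minus reverse, so a negative value for
#' e.g. reaction 7 means CheB2-P is donating phosphoryl groups back to CheA2.
#' `stoichiometry() %*% reaction_fluxes(...)` reproduces [che_rhs()], which
#' the test-suite uses as a bookkeeping cross-check.
#'
#' @param state named phosphoform vector (uM).
#' @param params a `che_params` object.
#' @return named numeric vector `r1 ... r15b` (uM/s).
#' @export
reaction_fluxes <- function(state, params) {
  validate_params(params)
  q <- .p_internal(params)
  y <- as.numeric(state[.species])
  A2P <- y[1]; A3P <- y[2]; Y3P <- y[3]; Y4P <- y[4]
  Y6P <- y[5]; B1P <- y[6]; B2P <- y[7]
  A2 <- q[["A2T"]] - A2P; A3 <- q[["A3T"]] - A3P
  Y3 <- q[["Y3T"]] - Y3P; Y4 <- q[["Y4T"]] - Y4P; Y6 <- q[["Y6T"]] - Y6P
  B1 <- q[["B1T"]] - B1P; B2 <- q[["B2T"]] - B2P
  c(r1 = q[["k1"]] * A2,
    r2 = q[["k2"]] * A3,
    r3 = q[["k3"]] * A2P * Y3 - q[["k3r"]] * A2 * Y3P,
    r4 = q[["k4"]] * A2P * Y4 - q[["k4r"]] * A2 * Y4P,
    r5 = q[["k5"]] * A2P * Y6 - q[["k5r"]] * A2 * Y6P,
    r6 = q[["k6"]] * A2P * B1 - q[["k6r"]] * A2 * B1P,
    r7 = q[["k7"]] * A2P * B2 - q[["k7r"]] * A2 * B2P,
    r8 = q[["k8"]] * A3P * Y6 - q[["k8r"]] * A3 * Y6P,
    r9 = q[["k9"]] * A3P * B2 - q[["k9r"]] * A3 * B2P,
    r10 = q[["k10"]] * Y3P,
    r11 = q[["k11"]] * Y4P,
    r12 = q[["k12"]] * Y6P,
    r13 = q[["k13"]] * B1P,
    r14 = q[["k14"]] * B2P,
    r15a = q[["k15a"]] * A3 * Y6P,
    r15b = q[["k15b"]] * A3P * Y6P)
}

#' Stoichiometry matrix of the reaction network
#'
#' @return 7 x 16 integer matrix (phosphoforms x reaction channels); entry
#'   (i, j) is the net change in phosphoform i per unit net flux of
#'   reaction j.
#' @export
stoichiometry <- function() .stoich

#' Per-reaction flux report
#'
#' Diagnostic that makes phosphorelay routing visible: net flux of every
#' reaction channel at a given state, plus the phosphoryl bookkeeping
#' (kinase input flux through reactions 1-2 and hydrolysis flux through
#' reactions 10-15b). At a steady state the two balance. At the steady state
#' reached with CheA2 autophosphorylation off (`k1 = 0`), the reaction-7 net
#' flux is negative: CheB2-P is running in reverse, relaying phosphoryl
#' groups from CheA3-P to CheA2.
#'
#' @param params a `che_params` object.
#' @param state phosphoform vector at which to evaluate the fluxes.
#' @return list with elements `fluxes` (named uM/s vector), `input_flux`,
#'   `hydrolysis_flux` (uM/s scalars), and `rhs` (the per-species derivative
#'   implied by the fluxes).
#' @export
phosphorelay_flux_report <- function(params, state) {
  fl <- reaction_fluxes(state, params)
  list(fluxes = fl,
       input_flux = unname(fl["r1"] + fl["r2"]),
       hydrolysis_flux = unname(sum(fl[c("r10", "r11", "r12", "r13",
                                         "r14", "r15a", "r15b")])),
       rhs = stats::setNames(as.numeric(.stoich %*% fl), .species))
}
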