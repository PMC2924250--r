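# Independent brute-force oracle for the network derivatives: walk the
# reaction table one reaction at a time, accumulating +/- propensity into
# each participating phosphoform. Kept deliberately separate from the
# package's closed-form RHS so the two can cross-validate.
oracle_rhs <- function(state, params) {
  u <- function(nm) params[[paste0(nm, "T")]] - state[[paste0(nm, "P")]]
  sp <- function(nm) state[[nm]]
  k <- function(nm) {
    v <- params[[nm]]
    # second-order constants are published on the (M s)^-1 scale
    if (nm %in% c("k3", "k3r", "k4", "k4r", "k5", "k5r", "k6", "k6r",
                  "k7", "k7r", "k8", "k8r", "k9", "k9r", "k15a", "k15b"))
      v / 1e6 else v
  }
  d <- c(A2P = 0, A3P = 0, Y3P = 0, Y4P = 0, Y6P = 0, B1P = 0, B2P = 0)
  add <- function(d, species, amount) { d[species] <- d[species] + amount; d }

  # (1) A2 -> A2P ; (2) A3 -> A3P
  d <- add(d, "A2P", k("k1") * u("A2"))
  d <- add(d, "A3P", k("k2") * u("A3"))
  # (3)-(7): A2P + RR <-> A2 + RRP
  transfer <- list(c("Y3", "k3", "k3r"), c("Y4", "k4", "k4r"),
                   c("Y6", "k5", "k5r"), c("B1", "k6", "k6r"),
                   c("B2", "k7", "k7r"))
  for (tr in transfer) {
    rr <- tr[1]; fwd <- k(tr[2]) * sp("A2P") * u(rr)
    rev <- k(tr[3]) * u("A2") * sp(paste0(rr, "P"))
    d <- add(d, "A2P", -fwd + rev)
    d <- add(d, paste0(rr, "P"), fwd - rev)
  }
  # (8)-(9): A3P + RR <-> A3 + RRP
  for (tr in list(c("Y6", "k8", "k8r"), c("B2", "k9", "k9r"))) {
    rr <- tr[1]; fwd <- k(tr[2]) * sp("A3P") * u(rr)
    rev <- k(tr[3]) * u("A3") * sp(paste0(rr, "P"))
    d <- add(d, "A3P", -fwd + rev)
    d <- add(d, paste0(rr, "P"), fwd - rev)
  }
  # (10)-(14): autodephosphorylation
  auto <- c(Y3P = "k10", Y4P = "k11", Y6P = "k12", B1P = "k13", B2P = "k14")
  for (spn in names(auto)) d <- add(d, spn, -k(auto[[spn]]) * sp(spn))
  # (15a/15b): catalytic dephosphorylation of Y6P by A3 / A3P
  d <- add(d, "Y6P", -k("k15a") * u("A3") * sp("Y6P"))
  d <- add(d, "Y6P", -k("k15b") * sp("A3P") * sp("Y6P"))
  d
}

# random valid state: each phosphoform uniform in [0, total]
rand_state <- function(params) {
  tot <- c(params$A2T, params$A3T, params$Y3T, params$Y4T, params$Y6T,
           params$B1T, params$B2T)
  s <- stats::runif(7) * tot
  names(s) <- c("A2P", "A3P", "Y3P", "Y4P", "Y6P", "B1P", "B2P")
  s
}

# default forward-assay sampling grid: log-spaced across the transient
assay_times <- signif(10^seq(-1, log10(600), length.out = 8), 3)

# published shut-off half-time and steady-fraction tables used by several
# test files (s and %, respectively)
published_halftimes <- list(
  wild_type = c("CheY3-P" = 4.9, "CheY4-P" = 7.3, "CheY6-P" = 1.3,
                "CheB1-P" = 4.2, "CheB2-P" = 4.8),
  dCheY6 = c("CheY3-P" = 296, "CheY4-P" = 543, "CheB1-P" = 309,
             "CheB2-P" = 430),
  no_phosphatase = c("CheY3-P" = 8.4, "CheY4-P" = 15.1, "CheY6-P" = 8.2,
                     "CheB1-P" = 8.1, "CheB2-P" = 6.3))
published_fractions <- list(
  wild_type = c(CheY3 = 30, CheY4 = 75, CheY6 = 64, CheB1 = 33, CheB2 = 40,
                total = 55),
  no_phosphatase = c(CheY3 = 88, CheY4 = 98, CheY6 = 99, CheB1 = 91,
                     CheB2 = 96, total = 97))
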