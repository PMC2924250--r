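#' Design a closed-system phosphotransfer assay
#'
#' Describes an in-vitro radiolabel phosphotransfer experiment of the kind
#' used to estimate transfer rate constants, in two flavours:
#'
#' * `forward_transfer`: a purified phosphorylated kinase (the donor-P) is
#'   mixed with an unphosphorylated response regulator; label moves
#'   donor-P -> RR-P, reversibly, while RR-P also autodephosphorylates.
#' * `reverse_transfer`: a phosphorylated P1 domain (e.g. CheA3P1-P) is the
#'   label source; unphosphorylated CheA2 is present as acceptor, and the
#'   added RR shuttles label from the P1 donor to CheA2. The P1 donor does
#'   not transfer label to CheA2 directly; any CheA2-P that appears has
#'   passed through the RR, so the appearance of CheA2-P reads out reverse
#'   phosphotransfer from RR-P.
#'
#' @param mode assay flavour, see above.
#' @param donor0 initial donor-P concentration (uM).
#' @param rr0 total added response regulator (uM); 0 gives a buffer control.
#' @param a2_0 total unphosphorylated CheA2 acceptor (uM); required (> 0)
#'   in `reverse_transfer` mode.
#' @param times sampling times (s), strictly increasing.
#' @param rr_name label for the response regulator (bookkeeping only).
#' @return an object of class `assay_design`.
#' @examples
#' # the classic reverse assay: 30 uM donor-P, 5 uM CheA2, 10 uM RR
#' assay_design("reverse_transfer", donor0 = 30, rr0 = 10, a2_0 = 5,
#'              times = c(10, 30, 60, 120, 300, 600, 1200, 1800))
#' @export
assay_design <- function(mode = c("forward_transfer", "reverse_transfer"),
                         donor0, rr0, a2_0 = 0, times,
                         rr_name = "RR") {
  mode <- match.arg(mode)
  if (donor0 < 0 || rr0 < 0 || a2_0 < 0) stop("concentrations must be >= 0")
  if (length(times) < 1 || any(diff(times) <= 0) || any(times < 0))
    stop("times must be non-negative and strictly increasing")
  if (mode == "reverse_transfer" && a2_0 <= 0)
    stop("reverse_transfer mode requires a CheA2 acceptor (a2_0 > 0)")
  structure(list(mode = mode, donor0 = donor0, rr0 = rr0, a2_0 = a2_0,
                 times = as.numeric(times), rr_name = rr_name),
            class = "assay_design")
}

.assay_species <- function(design) {
  if (design$mode == "reverse_transfer") c("donor_p", "rr_p", "a2_p")
  else c("donor_p", "rr_p")
}

#' Simulate a phosphotransfer assay
#'
#' Deterministic mass-action time course of the closed assay system, in the
#' same (M s)^-1 units as the published constants for second-order rates.
#'
#' @param design an [assay_design()].
#' @param rates named list of rate constants:
#'   `k_f` ((M s)^-1, kinase-P -> RR forward transfer),
#'   `k_r` ((M s)^-1, RR-P -> kinase reverse transfer),
#'   `k_d` ((M s)^-1, P1-donor -> RR transfer; reverse mode only),
#'   `k_auto` (s^-1, RR-P autodephosphorylation),
#'   `k_d_hyd` (s^-1, donor-P hydrolysis; default 0).
#' @return data.frame in tidy form: `time`, `species`
#'   (`donor_p`, `rr_p`, and in reverse mode `a2_p`), `value` (uM).
#' @export
simulate_assay <- function(design, rates) {
  stopifnot(inherits(design, "assay_design"))
  r <- .assay_rates(rates, design$mode)
  tt <- unique(c(0, design$times))
  if (design$mode == "reverse_transfer") {
    y0 <- c(donor_p = design$donor0, rr_p = 0, a2_p = 0)
    fn <- function(t, y, pr) {
      RR <- design$rr0 - y[["rr_p"]]
      A2 <- design$a2_0 - y[["a2_p"]]
      transfer_in <- pr[["k_d"]] * y[["donor_p"]] * RR
      to_a2 <- pr[["k_r"]] * A2 * y[["rr_p"]] - pr[["k_f"]] * y[["a2_p"]] * RR
      list(c(donor_p = -transfer_in - pr[["k_d_hyd"]] * y[["donor_p"]],
             rr_p = transfer_in - to_a2 - pr[["k_auto"]] * y[["rr_p"]],
             a2_p = to_a2))
    }
  } else {
    y0 <- c(donor_p = design$donor0, rr_p = 0)
    fn <- function(t, y, pr) {
      RR <- design$rr0 - y[["rr_p"]]
      D <- design$donor0 - y[["donor_p"]]
      fwd <- pr[["k_f"]] * y[["donor_p"]] * RR - pr[["k_r"]] * D * y[["rr_p"]]
      list(c(donor_p = -fwd - pr[["k_d_hyd"]] * y[["donor_p"]],
             rr_p = fwd - pr[["k_auto"]] * y[["rr_p"]]))
    }
  }
  out <- as.data.frame(deSolve::ode(y0, tt, fn, r, method = "lsoda",
                                    rtol = 1e-10, atol = 1e-12,
                                    maxsteps = 1e5))
  out <- out[out$time %in% design$times, , drop = FALSE]
  long <- stats::reshape(out, direction = "long",
                         varying = .assay_species(design),
                         v.names = "value", timevar = "species",
                         times = .assay_species(design), idvar = "time")
  long <- long[order(long$time, match(long$species, .assay_species(design))),
               c("time", "species", "value")]
  rownames(long) <- NULL
  long
}

# validate and convert second-order constants to (uM s)^-1
.assay_rates <- function(rates, mode) {
  need <- c("k_f", "k_r", "k_auto")
  if (mode == "reverse_transfer") need <- c(need, "k_d")
  miss <- setdiff(need, names(rates))
  if (length(miss)) stop("missing rate(s): ", paste(miss, collapse = ", "))
  r <- c(k_f = 0, k_r = 0, k_d = 0, k_auto = 0, k_d_hyd = 0)
  r[names(rates)] <- unlist(rates)
  if (any(r < 0)) stop("assay rates must be non-negative")
  r[c("k_f", "k_r", "k_d")] <- r[c("k_f", "k_r", "k_d")] / 1e6
  r
}

#' Multiplicative measurement-noise model
#'
#' Band intensities from phosphorimaging scale with the amount of label but
#' carry multiplicative error; this model draws independent lognormal
#' factors with unit mean and coefficient of variation `cv` for every band
#' at every time point.
#'
#' @param cv coefficient of variation (dimensionless, >= 0).
#' @param seed integer seed making draws reproducible.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(cv = 0, seed = 1L) {
  if (cv < 0) stop("cv must be >= 0")
  structure(list(cv = cv, seed = as.integer(seed)), class = "noise_model")
}

#' Generate synthetic assay data
#'
#' Runs [simulate_assay()] and corrupts every measured value with
#' independent multiplicative lognormal noise of unit mean, once per
#' replicate. With `cv = 0` the output equals the noiseless simulation.
#' Draws are isolated from the caller's RNG stream and fully determined by
#' the noise model's seed.
#'
#' @param design an [assay_design()].
#' @param rates rate list as in [simulate_assay()].
#' @param noise a [noise_model()].
#' @param replicates number of replicate time courses.
#' @return tidy data.frame: `time`, `species`, `value`, `replicate`.
#' @export
generate_synthetic_data <- function(design, rates, noise = noise_model(),
                                    replicates = 1L) {
  stopifnot(inherits(noise, "noise_model"))
  clean <- simulate_assay(design, rates)
  sdlog <- sqrt(log(1 + noise$cv^2))
  n <- nrow(clean)
  draws <- .with_seed(noise$seed, {
    matrix(stats::rlnorm(n * replicates, meanlog = -sdlog^2 / 2,
                         sdlog = sdlog), nrow = n)
  })
  out <- do.call(rbind, lapply(seq_len(replicates), function(rep) {
    d <- clean
    d$value <- d$value * draws[, rep]
    d$replicate <- rep
    d
  }))
  rownames(out) <- NULL
  out
}

# evaluate `expr` under a fixed seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
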