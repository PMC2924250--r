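#' Build a stimulation timeline schedule
#'
#' An ordered list of rate-constant switch events, each applied at a given
#' time: the standard way to emulate attractant stimulation of one receptor
#' cluster (turn a kinase input off) followed by recovery (turn it back on).
#'
#' @param time numeric vector of event times (s), strictly increasing.
#' @param rate character vector of rate-constant names, one per event.
#' @param value numeric vector of new values, one per event (use the default
#'   constant to restore a rate).
#' @return an object of class `che_schedule` (a data.frame).
#' @examples
#' p <- che_parameters()
#' # off/on stimulation of the polar cluster, then the cytoplasmic cluster
#' sched <- timeline_schedule(
#'   time  = c(100, 5100, 10100, 15100),
#'   rate  = c("k1", "k1", "k2", "k2"),
#'   value = c(0, p$k1, 0, p$k2))
#' @export
timeline_schedule <- function(time = numeric(), rate = character(),
                              value = numeric()) {
  stopifnot(length(time) == length(rate), length(rate) == length(value))
  if (length(time) > 1 && any(diff(time) <= 0))
    stop("event times must be strictly increasing")
  bad <- setdiff(rate, .rate_names)
  if (length(bad)) stop("unknown rate name(s): ", paste(bad, collapse = ", "))
  if (any(value < 0)) stop("event values must be non-negative")
  structure(data.frame(time = as.numeric(time), rate = as.character(rate),
                       value = as.numeric(value),
                       stringsAsFactors = FALSE),
            class = c("che_schedule", "data.frame"))
}

#' Simulate a stimulation timeline
#'
#' Starts at the steady state of `params` and integrates the network
#' forward, restarting the stiff solver at every scheduled rate switch so
#' the trajectory is continuous at event boundaries. With an empty schedule
#' the trajectory simply sits at the initial steady state.
#'
#' @param params a `che_params` object defining the initial (pre-stimulus)
#'   system.
#' @param schedule a `che_schedule` from [timeline_schedule()] (may be
#'   empty).
#' @param t_end end of the simulation (s); must exceed the last event time.
#' @param sample_grid optional explicit output times (s); by default each
#'   inter-event segment is sampled at `n_per_segment` equally spaced
#'   points.
#' @param n_per_segment samples per segment when `sample_grid` is `NULL`.
#' @return data.frame: `time` plus the seven phosphoform columns (uM).
#' @export
run_timeline <- function(params, schedule, t_end,
                         sample_grid = NULL, n_per_segment = 400) {
  validate_params(params)
  stopifnot(inherits(schedule, "che_schedule"))
  if (nrow(schedule) && t_end <= max(schedule$time))
    stop("t_end must exceed the last event time")
  bounds <- c(0, schedule$time, t_end)
  y <- as.numeric(find_steady_state(params)[.species])
  names(y) <- .species
  p <- params
  pieces <- list()
  for (seg in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[seg]; t1 <- bounds[seg + 1L]
    if (seg > 1L) p[[schedule$rate[seg - 1L]]] <- schedule$value[seg - 1L]
    tt <- if (is.null(sample_grid)) {
      seq(t0, t1, length.out = n_per_segment)
    } else {
      unique(c(t0, sample_grid[sample_grid >= t0 & sample_grid <= t1], t1))
    }
    out <- deSolve::ode(y, tt, .ode_func, .p_internal(p), method = "vode",
                        rtol = 1e-8, atol = 1e-12, maxsteps = 1e5)
    df <- as.data.frame(out)
    y <- unlist(df[nrow(df), .species])
    # drop the duplicated segment-start row after the first segment
    pieces[[seg]] <- if (seg == 1L) df else df[-1L, ]
  }
  traj <- do.call(rbind, pieces)
  rownames(traj) <- NULL
  traj
}

#' Four-event stimulation schedule
#'
#' The canonical off/on stimulation sequence for both receptor clusters:
#' (A) CheA2 autophosphorylation off, (B) back on, (C) CheA3
#' phosphorylation by CheA4 off, (D) back on, with each segment long enough
#' for the network to re-equilibrate.
#'
#' @param params a `che_params` object supplying the restore values.
#' @param segment duration of each segment (s). The slowest recovery mode
#'   involves CheB1-P (~1/k13); the default leaves ample margin.
#' @return a `che_schedule` with four events; attribute `t_end` gives the
#'   matching end time.
#' @export
stimulation_schedule <- function(params = che_parameters(), segment = 4e4) {
  sched <- timeline_schedule(
    time  = segment * 1:4,
    rate  = c("k1", "k1", "k2", "k2"),
    value = c(0, params$k1, 0, params$k2))
  attr(sched, "t_end") <- segment * 5
  sched
}
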