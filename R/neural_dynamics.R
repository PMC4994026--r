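#' Canonical microcircuit population labels
#'
#' The four cell populations of a canonical-microcircuit (CMC) source, in the
#' fixed state-vector order used throughout the package: spiny stellate
#' (`ss`), superficial pyramidal (`sp`), inhibitory interneuron (`ii`) and
#' deep pyramidal (`dp`).
#' @export
cmc_populations <- c("ss", "sp", "ii", "dp")

#' The ten canonical intrinsic (within-source) edges
#'
#' Each CMC source has a fixed intrinsic wiring of ten signed edges.  The
#' signs are immutable (inhibitory edges stay inhibitory); only magnitudes are
#' configurable.  The `sp->sp` self-connection is the one whose magnitude is
#' additionally multiplied by the superficial-pyramidal gain.
#' @format A data frame with columns `from`, `to`, `sign`.
#' @export
cmc_intrinsic_edges <- data.frame(
  from = c("ss", "sp", "ii", "ii", "ss", "dp", "sp", "ss", "ii", "dp"),
  to   = c("ss", "ss", "ss", "ii", "ii", "ii", "sp", "sp", "dp", "dp"),
  sign = c(-1, -1, -1, -1, +1, +1, -1, +1, -1, -1),
  stringsAsFactors = FALSE
)

#' CMC source parameters
#'
#' Biophysical constants of a single canonical-microcircuit source: synaptic
#' time constants, the ten intrinsic edge magnitudes, the firing sigmoid
#' slope, the baseline superficial-pyramidal gain, and the fixed per-component
#' extrinsic coupling gains that convert dimensionless connection strengths
#' into afferent drive.
#'
#' @param tau named numeric, synaptic time constants in ms for
#'   `ss`, `sp`, `ii`, `dp`; all strictly positive.
#' @param g numeric length 10, non-negative magnitudes of the intrinsic edges
#'   in the order of [cmc_intrinsic_edges] (per-ms units).
#' @param sigmoid_slope slope `r` of the firing sigmoid (1/mV), positive.
#' @param gain_sp baseline multiplicative gain on the `sp->sp` self-edge
#'   magnitude, positive.
#' @param ext_gain named numeric length 4: fixed per-ms coupling gains for the
#'   four extrinsic components `f_ss` (forward onto spiny stellate), `f_dp`
#'   (forward onto deep pyramidal), `b_sp`, `b_ii` (backward, inhibitory).
#'   Connection strengths in a network model are dimensionless multiples of
#'   these.
#' @return An object of class `cmc_parameters`.
#' @export
cmc_parameters <- function(tau = c(ss = 2, sp = 2, ii = 16, dp = 28),
                           g = c(0.8, 0.8, 1.6, 0.8, 0.8, 0.4, 0.8, 0.8, 0.4, 0.2),
                           sigmoid_slope = 2 / 3,
                           gain_sp = 1,
                           ext_gain = c(f_ss = 2, f_dp = 1,
                                        b_sp = 0.6, b_ii = 0.3)) {
  tau <- tau[cmc_populations]
  stopifnot(length(tau) == 4, all(is.finite(tau)), all(tau > 0))
  stopifnot(length(g) == 10, all(is.finite(g)), all(g >= 0))
  stopifnot(is.finite(sigmoid_slope), sigmoid_slope > 0)
  stopifnot(is.finite(gain_sp), gain_sp > 0)
  ext_gain <- ext_gain[c("f_ss", "f_dp", "b_sp", "b_ii")]
  stopifnot(all(is.finite(ext_gain)), all(ext_gain >= 0))
  structure(list(tau = tau, g = unname(g), sigmoid_slope = sigmoid_slope,
                 gain_sp = gain_sp, ext_gain = ext_gain),
            class = "cmc_parameters")
}

#' Population firing sigmoid
#'
#' Centred logistic transfer from membrane potential to (dimensionless)
#' firing rate, `S(v) = 1/(1 + exp(-r v)) - 1/2`.  Odd, strictly increasing,
#' bounded in (-1/2, 1/2), with `S(0) = 0` so the origin is a network fixed
#' point.
#'
#' @param v membrane potential(s); must be finite.
#' @param slope sigmoid slope `r` (> 0).
#' @return Firing rate(s), same shape as `v`.
#' @export
sigmoid_firing <- function(v, slope) {
  if (!all(is.finite(v))) stop("non-finite membrane potential")
  stopifnot(is.finite(slope), slope > 0)
  1 / (1 + exp(-slope * v)) - 0.5
}

#' Gaussian-bump stimulus
#'
#' Exogenous (subcortical volley) drive used to start network dynamics:
#' a Gaussian bump in peristimulus time.
#'
#' @param onset time of the peak (ms peristimulus).
#' @param dispersion standard deviation of the bump (ms, > 0).
#' @param amplitude base magnitude (dimensionless, >= 0); scaled per source by
#'   the input gains `C` of the network model.
#' @return An object of class `stimulus_input`.
#' @export
stimulus_input <- function(onset = 64, dispersion = 16, amplitude = 1) {
  stopifnot(is.finite(onset), is.finite(dispersion), dispersion > 0,
            is.finite(amplitude), amplitude >= 0)
  structure(list(onset = onset, dispersion = dispersion, amplitude = amplitude),
            class = "stimulus_input")
}

#' Evaluate the Gaussian bump
#'
#' @param t time(s) in ms peristimulus.
#' @param input a [stimulus_input()].
#' @return `amplitude * exp(-(t - onset)^2 / (2 dispersion^2))`.
#' @export
gaussian_bump <- function(t, input) {
  stopifnot(inherits(input, "stimulus_input"))
  input$amplitude * exp(-(t - input$onset)^2 / (2 * input$dispersion^2))
}

#' Simulation grid
#'
#' Integration window, internal step, and output sampling rate.
#'
#' @param t_start,t_end peristimulus window bounds (ms), `t_start < t_end`.
#' @param dt integration step (ms, > 0); must not exceed the output sampling
#'   interval `1000 / output_rate`.
#' @param output_rate sampling rate of the emitted series (Hz).
#' @return An object of class `simulation_grid` with the output time vector in
#'   `$times`.
#' @export
simulation_grid <- function(t_start = 1, t_end = 450, dt = 1, output_rate = 250) {
  stopifnot(t_start < t_end, dt > 0, output_rate > 0,
            dt <= 1000 / output_rate + 1e-12)
  times <- seq(t_start, t_end, by = 1000 / output_rate)
  structure(list(t_start = t_start, t_end = t_end, dt = dt,
                 output_rate = output_rate, times = times),
            class = "simulation_grid")
}

#' Time derivative of one CMC source
#'
#' Reference implementation of the second-order synaptic kernel: for each
#' population `p`, with rate constant `kappa_p = 1/tau_p`,
#' `dv_p = i_p` and `di_p = kappa_p a_p - 2 kappa_p i_p - kappa_p^2 v_p`,
#' where `a_p` is the summed presynaptic drive.  The constant-drive
#' equilibrium is `v* = a tau` (set `di = 0`, then `i = 0` gives
#' `kappa a = kappa^2 v*`).  Used as an independent oracle for the compiled
#' network integrator.
#'
#' @param state numeric length 8: voltages `v` (populations in
#'   [cmc_populations] order) then currents `i`.
#' @param afferent numeric length 4: summed presynaptic drive per population.
#' @param params a [cmc_parameters()].
#' @return numeric length 8, the state derivative.
#' @export
source_derivative <- function(state, afferent, params) {
  if (!all(is.finite(state))) stop("non-finite state")
  if (!all(is.finite(afferent))) stop("non-finite afferent drive")
  stopifnot(length(state) == 8, length(afferent) == 4,
            inherits(params, "cmc_parameters"))
  kappa <- unname(1 / params$tau)
  v <- state[1:4]; cur <- state[5:8]
  unname(c(cur, kappa * afferent - 2 * kappa * cur - kappa^2 * v))
}

#' Intrinsic afferent drive of one isolated CMC source
#'
#' The signed intrinsic wiring of [cmc_intrinsic_edges] applied to the firing
#' of the source's own populations (no delays); exposed for testing and for
#' the R-side oracle.
#'
#' @param v voltages, length 4 in [cmc_populations] order.
#' @param params a [cmc_parameters()].
#' @param gain per-source multiplier on the baseline superficial-pyramidal
#'   gain (default 1).
#' @return numeric length 4, the intrinsic afferent per population.
#' @export
intrinsic_afferent <- function(v, params, gain = 1) {
  s <- sigmoid_firing(v, params$sigmoid_slope)
  names(s) <- cmc_populations
  g <- params$g
  gsp <- params$gain_sp * gain
  c(ss = -g[1] * s["ss"] - g[2] * s["sp"] - g[3] * s["ii"],
    sp = -g[7] * gsp * s["sp"] + g[8] * s["ss"],
    ii = -g[4] * s["ii"] + g[5] * s["ss"] + g[6] * s["dp"],
    dp = -g[9] * s["ii"] - g[10] * s["dp"])
}

#' Integrate a CMC network
#'
#' Simulates the delayed neural-mass dynamics of a multi-source network driven
#' by a Gaussian-bump input, from the resting origin state.  Extrinsic drive
#' from source `j` to `i` uses presynaptic firing evaluated at `t - D[i, j]`
#' (ring-buffer history with linear interpolation); intrinsic coupling within
#' a source is delayed by that source's self delay.  Fixed-step RK4.
#'
#' @param model a [build_model()] network (possibly condition-modulated via
#'   [apply_modulation()]).
#' @param params a single [cmc_parameters()] shared by all sources, or a list
#'   of one per source.
#' @param input a [stimulus_input()].
#' @param grid a [simulation_grid()].
#' @param v_bound instability bound: any population voltage exceeding this in
#'   magnitude aborts with a diagnostic error naming the divergent source.
#' @return An object of class `cmc_simulation`: list with `times` (the output
#'   sampling times, ms), `v` (3-d array `[n_sources, 4 populations, n_times]`
#'   of membrane potentials) and `sources`.
#' @export
integrate_network <- function(model, params = cmc_parameters(),
                              input = stimulus_input(), grid = simulation_grid(),
                              v_bound = 1e3) {
  stopifnot(inherits(model, "dcm_network"), inherits(input, "stimulus_input"),
            inherits(grid, "simulation_grid"))
  n <- nrow(model$sources)
  if (inherits(params, "cmc_parameters")) params <- rep(list(params), n)
  stopifnot(length(params) == n)

  gmat   <- vapply(params, function(p) p$g, numeric(10))
  taumat <- vapply(params, function(p) p$tau, numeric(4))
  slope  <- params[[1]]$sigmoid_slope
  ext    <- params[[1]]$ext_gain
  gain   <- vapply(seq_len(n), function(s) params[[s]]$gain_sp, numeric(1)) *
    model$G

  # physical per-ms couplings = dimensionless strengths x fixed component gains
  res <- .cmc_integrate_cpp(
    n_sources = n,
    g = gmat, tau = taumat, slope = slope, gain_sp = gain,
    A_f_ss = model$A_forward$ss * ext[["f_ss"]],
    A_f_dp = model$A_forward$dp * ext[["f_dp"]],
    A_b_sp = model$A_backward$sp * ext[["b_sp"]],
    A_b_ii = model$A_backward$ii * ext[["b_ii"]],
    D = model$D, D_self = model$D_self, C = model$C,
    onset = input$onset, dispersion = input$dispersion,
    amplitude = input$amplitude,
    t0 = min(0, grid$t_start), t_end = grid$t_end, dt = grid$dt,
    v_bound = v_bound, out_times = grid$times)

  if (isTRUE(res$diverged)) {
    stop(sprintf("network integration diverged at source '%s' (t = %.1f ms): |v| > %g",
                 model$sources$name[res$source], res$time, v_bound))
  }

  nt <- length(grid$times)
  # rows of res$v are (source, population) pairs, population fastest
  v <- array(aperm(array(res$v, dim = c(4, n, nt)), c(2, 1, 3)),
             dim = c(n, 4, nt),
             dimnames = list(model$sources$name, cmc_populations, NULL))
  structure(list(times = grid$times, v = v, sources = model$sources$name),
            class = "cmc_simulation")
}
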