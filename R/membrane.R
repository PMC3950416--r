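## Single-compartment Hodgkin-Huxley membrane with conductance synapses.
## This R-level stepper is the reference path for the compiled network
## engine: both use exponential-Euler gating and forward-Euler voltage on
## start-of-step currents, so they agree step for step at equal dt.

#' Membrane parameters of a model neuron
#'
#' Single compartment (cylinder) with leak, squid-axon Na+/K+ channels and
#' AMPA/GABA conductance synapses. All cells in the network share one
#' parameter set.
#'
#' The membrane equation is
#' \deqn{C_m \frac{dV}{dt} = -\left(g_{pas}(V - e_{leak}) + i_{Na} + i_K + i_{syn}\right)}
#' with densities in mS/cm2 and synaptic point currents
#' \eqn{i_{syn} = g (V - e_{rev})} converted by the compartment area.
#'
#' Two printed source constants cannot be taken literally and are kept as
#' explicit alternatives rather than defaults: a leak reversal of 0 mV only
#' makes sense in a shifted voltage convention that is incompatible with the
#' AMPA (0 mV) and GABA (-80 mV) reversals, so the default is the absolute
#' convention with `e_leak = -65`; and a capacitance density of 10 uF/cm2
#' combined with standard squid kinetics yields at most a single spike
#' followed by depolarization block at any drive, so the default is the
#' standard 1 uF/cm2. Set `convention = "literal"` to adopt the printed
#' values anyway. See the package vignette for the full discussion.
#'
#' @param diameter_um,length_um compartment geometry (um); defaults 30 and 10.
#' @param axial_resistivity axial resistivity in Ohm cm (kept for fidelity;
#'   unused in a single compartment).
#' @param cm capacitance density, uF/cm2.
#' @param g_pas leak conductance density, mS/cm2 (0.1 mS/cm2 = 1e-4 S/cm2).
#' @param e_leak leak reversal potential, mV.
#' @param g_na,g_k maximal channel conductance densities, mS/cm2.
#' @param e_na,e_k channel reversal potentials, mV.
#' @param v_thresh spike-detection threshold, mV (upward crossing).
#' @param refractory_ms spike-detection lockout, ms.
#' @param convention `"absolute"` (default) or `"literal"`; the latter sets
#'   `e_leak = 0` and the leak to the printed 0.001 nS absolute conductance
#'   spread over the compartment area.
#' @return named list of membrane parameters, including the derived
#'   `area_cm2` (cylinder lateral surface).
#' @examples
#' p <- membraneParams()
#' p$area_cm2              # ~9.42e-6 cm2 for a 30x10 um cylinder
#' @export
membraneParams <- function(diameter_um = 30, length_um = 10,
                           axial_resistivity = 100,
                           cm = 1, g_pas = 0.1, e_leak = -65,
                           g_na = 120, g_k = 36, e_na = 50, e_k = -77,
                           v_thresh = 0, refractory_ms = 2,
                           convention = c("absolute", "literal")) {
  convention <- match.arg(convention)
  stopifnot(diameter_um > 0, length_um > 0, cm > 0,
            g_pas >= 0, g_na >= 0, g_k >= 0)
  area_cm2 <- pi * (diameter_um * 1e-4) * (length_um * 1e-4)
  if (convention == "literal") {
    e_leak <- 0
    g_pas <- 0.001e-6 / area_cm2 * 1e3   # 0.001 nS absolute -> mS/cm2
    cm <- 10
  }
  list(diameter_um = diameter_um, length_um = length_um,
       axial_resistivity = axial_resistivity, cm = cm,
       g_pas = g_pas, e_leak = e_leak,
       g_na = g_na, g_k = g_k, e_na = e_na, e_k = e_k,
       v_thresh = v_thresh, refractory_ms = refractory_ms,
       area_cm2 = area_cm2, convention = convention)
}

#' Synapse parameters
#'
#' Instantaneous-rise, exponential-decay conductance synapses: AMPA
#' (tau = 5 ms, reversal 0 mV) and GABA (tau = 10 ms, reversal -80 mV).
#'
#' @param kind `"ampa"` or `"gaba"`.
#' @param tau decay time constant, ms (defaults per kind).
#' @param e_rev reversal potential, mV (defaults per kind).
#' @return named list `(kind, tau, e_rev)`.
#' @export
synapseParams <- function(kind = c("ampa", "gaba"), tau = NULL, e_rev = NULL) {
  kind <- match.arg(kind)
  if (is.null(tau)) tau <- if (kind == "ampa") 5 else 10
  if (is.null(e_rev)) e_rev <- if (kind == "ampa") 0 else -80
  stopifnot(tau > 0)
  list(kind = kind, tau = tau, e_rev = e_rev)
}

#' Neuron state
#'
#' Membrane voltage, HH gating variables and synaptic conductances of one
#' cell. Gating defaults to steady state at the given voltage.
#'
#' @param v membrane voltage, mV.
#' @param m,h,n gating variables in `[0, 1]`; default steady state at `v`.
#' @param g_ampa,g_gaba synaptic conductances, uS.
#' @param last_spike_time time of last detected spike (ms) or `NA`.
#' @param refractory_until end of the current spike-detection lockout (ms).
#' @return named list state.
#' @export
neuronState <- function(v = -65, m = NULL, h = NULL, n = NULL,
                        g_ampa = 0, g_gaba = 0,
                        last_spike_time = NA_real_, refractory_until = -Inf) {
  r <- .hh_rates(v)
  if (is.null(m)) m <- r$am / (r$am + r$bm)
  if (is.null(h)) h <- r$ah / (r$ah + r$bh)
  if (is.null(n)) n <- r$an / (r$an + r$bn)
  stopifnot(m >= 0, m <= 1, h >= 0, h <= 1, n >= 0, n <= 1,
            g_ampa >= 0, g_gaba >= 0)
  list(v = v, m = m, h = h, n = n, g_ampa = g_ampa, g_gaba = g_gaba,
       last_spike_time = last_spike_time, refractory_until = refractory_until)
}

## squid-axon rate functions, absolute convention (rest near -65 mV)
.hh_rates <- function(v) {
  xm <- v + 40
  am <- ifelse(abs(xm) < 1e-7, 1, 0.1 * xm / (1 - exp(-xm / 10)))
  bm <- 4 * exp(-(v + 65) / 18)
  ah <- 0.07 * exp(-(v + 65) / 20)
  bh <- 1 / (1 + exp(-(v + 35) / 10))
  xn <- v + 55
  an <- ifelse(abs(xn) < 1e-7, 0.1, 0.01 * xn / (1 - exp(-xn / 10)))
  bn <- 0.125 * exp(-(v + 65) / 80)
  list(am = am, bm = bm, ah = ah, bh = bh, an = an, bn = bn)
}

## total steady-state membrane current density (uA/cm2) at voltage v
.hh_steady_current <- function(v, params) {
  r <- .hh_rates(v)
  m <- r$am / (r$am + r$bm); h <- r$ah / (r$ah + r$bh); n <- r$an / (r$an + r$bn)
  params$g_na * m^3 * h * (v - params$e_na) +
    params$g_k * n^4 * (v - params$e_k) +
    params$g_pas * (v - params$e_leak)
}

#' Resting state of the membrane
#'
#' Solves for the voltage at which the total steady-state membrane current
#' vanishes (leak + Na + K with gating at steady state) and returns the
#' corresponding quiescent [neuronState()]. This is the fixed point of the
#' dynamics in the absence of input.
#'
#' @param params membrane parameters from [membraneParams()].
#' @return a neuron state at the resting fixed point.
#' @examples
#' st <- restingState(membraneParams())
#' round(st$v, 1)   # close to -65 mV
#' @export
restingState <- function(params = membraneParams()) {
  root <- uniroot(function(v) .hh_steady_current(v, params),
                  lower = -90, upper = -40, tol = 1e-12)
  neuronState(v = root$root)
}

#' Advance one neuron by a single time step
#'
#' One fixed-step update of the single-compartment HH dynamics:
#' exponential-Euler gating toward steady state at the start-of-step
#' voltage, exact exponential conductance decay, forward-Euler voltage on
#' start-of-step currents. A spike is reported exactly when the voltage
#' crosses `v_thresh` upward outside the refractory lockout.
#'
#' @param state a [neuronState()].
#' @param params membrane parameters, [membraneParams()].
#' @param syn list with `ampa` and `gaba` entries from [synapseParams()].
#' @param dt time step, ms; must be positive and at most 0.1 ms.
#' @param injected_current injected point current, nA.
#' @param t current time (ms), used for spike bookkeeping.
#' @return list `(state, spiked)`.
#' @examples
#' st <- restingState()
#' out <- advanceNeuron(st, membraneParams(), dt = 0.025)
#' abs(out$state$v - st$v) < 1e-9   # resting state is a fixed point
#' @export
advanceNeuron <- function(state, params = membraneParams(),
                          syn = list(ampa = synapseParams("ampa"),
                                     gaba = synapseParams("gaba")),
                          dt = 0.025, injected_current = 0, t = 0) {
  stopifnot(dt > 0, dt <= 0.1)
  vals <- unlist(state[c("v", "m", "h", "n", "g_ampa", "g_gaba")])
  if (any(!is.finite(vals))) {
    bad <- names(vals)[!is.finite(vals)][1]
    stop(sprintf("integration diverged at dt = %g: non-finite state variable '%s'",
                 dt, bad))
  }
  v <- state$v
  ina <- params$g_na * state$m^3 * state$h * (v - params$e_na)
  ik  <- params$g_k * state$n^4 * (v - params$e_k)
  il  <- params$g_pas * (v - params$e_leak)
  isyn_nA <- state$g_ampa * (v - syn$ampa$e_rev) + state$g_gaba * (v - syn$gaba$e_rev)
  dens <- 1e-3 / params$area_cm2                      # nA -> uA/cm2
  dv <- (-(ina + ik + il + isyn_nA * dens) + injected_current * dens) / params$cm
  vnew <- v + dt * dv
  r <- .hh_rates(v)
  ee <- function(x, a, b) {
    inf <- a / (a + b)
    inf + (x - inf) * exp(-dt * (a + b))
  }
  out <- state
  out$m <- ee(state$m, r$am, r$bm)
  out$h <- ee(state$h, r$ah, r$bh)
  out$n <- ee(state$n, r$an, r$bn)
  out$g_ampa <- state$g_ampa * exp(-dt / syn$ampa$tau)
  out$g_gaba <- state$g_gaba * exp(-dt / syn$gaba$tau)
  tnew <- t + dt
  spiked <- vnew >= params$v_thresh && v < params$v_thresh &&
    tnew >= state$refractory_until
  if (spiked) {
    out$last_spike_time <- tnew
    out$refractory_until <- tnew + params$refractory_ms
  }
  out$v <- vnew
  list(state = out, spiked = spiked)
}

#' Deliver a synaptic event to a neuron
#'
#' Instantaneous conductance rise: the AMPA or GABA conductance is
#' incremented by the synaptic weight; everything else is untouched.
#' Weights are non-negative; the sign of the effect is carried by the
#' synapse kind through its reversal potential.
#'
#' @param state a [neuronState()].
#' @param kind `"ampa"` or `"gaba"`.
#' @param weight conductance increment, uS; must be non-negative.
#' @return the updated state.
#' @export
deliverSynapticEvent <- function(state, kind = c("ampa", "gaba"), weight) {
  kind <- match.arg(kind)
  if (!is.numeric(weight) || length(weight) != 1 || weight < 0)
    stop("synaptic weight must be a single non-negative number")
  if (kind == "ampa") state$g_ampa <- state$g_ampa + weight
  else state$g_gaba <- state$g_gaba + weight
  state
}

#' Simulate a single neuron with scheduled synaptic events
#'
#' Drives [advanceNeuron()] over a whole trial, delivering the given events
#' at their (grid-rounded) times. Used as the reference path for the
#' compiled network engine and for convergence checks at reduced dt.
#'
#' @param duration trial length, ms.
#' @param dt step, ms.
#' @param events data.frame with `time` (ms), `kind`, `weight`; may be empty.
#' @param injected_current constant injected current, nA.
#' @param params,syn as in [advanceNeuron()].
#' @param state initial state; defaults to rest.
#' @param record logical; if `TRUE` the voltage trace is returned.
#' @return list with `spike_times` (ms), final `state`, and optionally
#'   `v` + `time` traces.
#' @export
simulateNeuron <- function(duration, dt = 0.025,
                           events = data.frame(time = numeric(),
                                               kind = character(),
                                               weight = numeric()),
                           injected_current = 0,
                           params = membraneParams(),
                           syn = list(ampa = synapseParams("ampa"),
                                      gaba = synapseParams("gaba")),
                           state = NULL, record = FALSE) {
  if (is.null(state)) state <- restingState(params)
  n_steps <- round(duration / dt)
  ev_step <- pmax(1L, as.integer(round(events$time / dt)))
  spike_times <- numeric()
  vtrace <- if (record) numeric(n_steps) else NULL
  for (k in seq_len(n_steps)) {
    hit <- which(ev_step == k)
    for (e in hit)
      state <- deliverSynapticEvent(state, events$kind[e], events$weight[e])
    res <- advanceNeuron(state, params, syn, dt, injected_current, t = (k - 1) * dt)
    state <- res$state
    if (res$spiked) spike_times <- c(spike_times, k * dt)
    if (record) vtrace[k] <- state$v
  }
  out <- list(spike_times = spike_times, state = state)
  if (record) { out$v <- vtrace; out$time <- seq_len(n_steps) * dt }
  out
}
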