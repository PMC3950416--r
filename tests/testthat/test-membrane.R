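test_that("resting state is a fixed point of the dynamics", {
  p <- membraneParams()
  st <- restingState(p)
  out <- advanceNeuron(st, p, dt = 0.025)
  expect_lt(abs(out$state$v - st$v), 1e-9)
  expect_false(out$spiked)
})

test_that("quiescent neuron never spikes and gating stays in [0,1] over 1 s", {
  p <- membraneParams()
  syn <- list(ampa = synapseParams("ampa"), gaba = synapseParams("gaba"))
  st <- restingState(p)
  # strong alternating synaptic bombardment, checked every step
  set.seed(1)
  ev <- data.frame(time = sort(runif(80, 0, 1000)),
                   kind = rep(c("ampa", "gaba"), 40),
                   weight = runif(80, 0, 0.02))
  n_steps <- 40000
  ok <- TRUE
  for (k in seq_len(n_steps)) {
    hit <- which(abs(ev$time - k * 0.025) < 0.0125)
    for (e in hit) st <- deliverSynapticEvent(st, ev$kind[e], ev$weight[e])
    st <- advanceNeuron(st, p, syn, 0.025, t = (k - 1) * 0.025)$state
    if (st$m < 0 || st$m > 1 || st$h < 0 || st$h > 1 || st$n < 0 || st$n > 1) {
      ok <- FALSE; break
    }
  }
  expect_true(ok)
  # and with no input at all: silence for 1 s
  quiet <- simulateNeuron(1000, dt = 0.025)
  expect_length(quiet$spike_times, 0)
})

test_that("conductance decay between events is exactly exponential", {
  p <- membraneParams()
  syn <- list(ampa = synapseParams("ampa"), gaba = synapseParams("gaba"))
  st <- restingState(p)
  st <- deliverSynapticEvent(st, "ampa", 0.01)
  st <- deliverSynapticEvent(st, "gaba", 0.02)
  g0a <- st$g_ampa; g0g <- st$g_gaba
  for (k in 1:400) st <- advanceNeuron(st, p, syn, 0.025)$state
  expect_equal(st$g_ampa, g0a * exp(-400 * 0.025 / 5), tolerance = 1e-12)
  expect_equal(st$g_gaba, g0g * exp(-400 * 0.025 / 10), tolerance = 1e-12)
})

test_that("synaptic events sum linearly and reject negative weights", {
  st <- restingState()
  expect_identical(deliverSynapticEvent(st, "ampa", 0), st)
  one <- deliverSynapticEvent(st, "ampa", 0.004)
  two <- deliverSynapticEvent(deliverSynapticEvent(st, "ampa", 0.002),
                              "ampa", 0.002)
  expect_identical(one$g_ampa, two$g_ampa)
  expect_error(deliverSynapticEvent(st, "gaba", -1), "non-negative")
  # all other fields untouched
  expect_identical(one[setdiff(names(one), "g_ampa")],
                   st[setdiff(names(st), "g_ampa")])
})

test_that("GABA current magnitude shrinks near its reversal potential", {
  g <- 0.01
  i_at <- function(v) abs(g * (v - (-80)))
  expect_lt(i_at(-78), i_at(-50))
  # same through the state-based current expression
  syn <- synapseParams("gaba")
  expect_lt(abs(g * (-78 - syn$e_rev)), abs(g * (-50 - syn$e_rev)))
})

test_that("suprathreshold current drives periodic spiking with stable ISI", {
  p <- membraneParams()
  # ~0.1 nA over this compartment is well above rheobase
  r <- simulateNeuron(300, dt = 0.025, injected_current = 0.12, params = p)
  expect_gt(length(r$spike_times), 5)
  isi <- diff(r$spike_times)
  late <- isi[3:length(isi)]
  expect_lt(max(abs(late - mean(late))) / mean(late), 0.01)
})

test_that("halving dt changes driven spike times by less than 0.5 ms", {
  r1 <- simulateNeuron(300, dt = 0.025, injected_current = 0.12)
  r2 <- simulateNeuron(300, dt = 0.0125, injected_current = 0.12)
  n <- min(length(r1$spike_times), length(r2$spike_times))
  expect_gt(n, 3)
  # phase drift accumulates over the train: bound the drift per spike
  drift <- abs(r1$spike_times[1:n] - r2$spike_times[1:n])
  expect_lt(max(drift / seq_len(n)), 0.5)
  expect_lt(drift[1], 0.5)
})

test_that("EPSP peak depolarization grows monotonically with weight", {
  peaks <- vapply(c(0.0005, 0.001, 0.002, 0.003), function(w) {
    ev <- data.frame(time = 5, kind = "ampa", weight = w)
    max(simulateNeuron(30, events = ev, record = TRUE)$v)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("non-finite state is reported with the offending variable", {
  st <- restingState()
  st$h <- NaN
  expect_error(advanceNeuron(st), "diverged.*'h'")
})

test_that("compiled engine and R stepper agree on a driven single neuron", {
  cfg <- tiny_config()
  net <- buildNetwork(cfg)
  # drive only the L cell through its R input (weight g_lgn, delay 1 ms)
  net@synapses <- net@synapses[net@synapses$projection == "R->L", ]
  spikes_in <- data.frame(cell = 0L, time = c(5, 30, 55, 80, 105))
  sim <- colorspike:::.cs_simulate(net, spikes_in, 150, 0.025,
                                   record_cells = 3L)
  ev <- data.frame(time = spikes_in$time + 1, kind = "ampa",
                   weight = cfg$g_lgn)
  ref <- simulateNeuron(150, dt = 0.025, events = ev, record = TRUE)
  l_spikes <- sim$events$time[sim$events$layer == "L"]
  expect_equal(l_spikes, ref$spike_times)
  # engine gating uses a 0.01 mV lookup table; voltages agree to that grid
  expect_lt(max(abs(sim$vtrace[, 1] - ref$v)), 0.1)
})
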