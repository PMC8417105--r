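# Fixed-point integrate-and-fire spiking network, emulating the on-board
# FPGA engine bit-for-bit. Potentials, weights, bias strength and the firing
# threshold are signed 16-bit microvolt values; decay constants and the bias
# chance are Q16 fractions in [0, 1). Each unit keeps a fast and a slow
# leaky potential whose difference forms an alpha-like PSP; a unit fires
# when (slow - fast) strictly exceeds the threshold, resets both potentials
# to zero and enqueues a spike that reaches its targets after the global
# conduction delay. The network runs at 10,000 updates per second.

INT16_MIN <- -32768
INT16_MAX <- 32767
SNN_MAX_UNITS <- 256L
SNN_MAX_CONNECTIONS <- 2000L
SNN_MAX_DELAY_STEPS <- 35L   # 3.5 ms at 0.1 ms per step

clamp_i16 <- function(x) pmin(pmax(x, INT16_MIN), INT16_MAX)

#' Global network parameters
#'
#' @param conduction_delay_steps Spike conduction delay in 0.1 ms update
#'   steps (1--35, i.e. at most 3.5 ms).
#' @param fast_decay,slow_decay Q16 decay fractions (integers 0--65535
#'   representing 0 to 65535/65536) applied to the fast and slow potentials
#'   every step.
#' @param bias_chance Q16 probability of an independent bias spike per unit
#'   per step.
#' @param bias_strength_uv Signed 16-bit bias spike weight in uV.
#' @param threshold_uv Signed 16-bit firing threshold in uV.
#' @return An object of class `"snn_globals"`.
#' @export
snn_globals <- function(conduction_delay_steps = 1L, fast_decay, slow_decay,
                        bias_chance = 0L, bias_strength_uv = 0L,
                        threshold_uv) {
  if (conduction_delay_steps < 1L || conduction_delay_steps > SNN_MAX_DELAY_STEPS)
    stop("conduction_delay_steps must be 1-", SNN_MAX_DELAY_STEPS,
         " (3.5 ms max)", call. = FALSE)
  for (q in list(fast_decay, slow_decay, bias_chance))
    if (q < 0 || q > 65535) stop("Q16 values must be in 0-65535", call. = FALSE)
  for (v in list(bias_strength_uv, threshold_uv))
    if (v < INT16_MIN || v > INT16_MAX)
      stop("uV values must be signed 16-bit", call. = FALSE)
  structure(list(conduction_delay_steps = as.integer(conduction_delay_steps),
                 fast_decay = fast_decay, slow_decay = slow_decay,
                 bias_chance = bias_chance,
                 bias_strength_uv = bias_strength_uv,
                 threshold_uv = threshold_uv), class = "snn_globals")
}

#' Build and validate a spiking network
#'
#' Up to 256 units and 2,000 connections. Unit indices are 0-based; sources
#' -1 to -8 denote external spike inputs taken directly from the eight event
#' generators (source -(g+1) is generator g). The first eight units are the
#' network's I/O units (their output spikes can activate event generators);
#' output spikes of the first 16 units are recorded as network events.
#'
#' @param n_units Number of units (1--256).
#' @param globals An [snn_globals()].
#' @param connections Data frame with columns `source` (unit 0..n_units-1 or
#'   external -1..-8), `target` (unit 0..n_units-1) and `weight_uv` (signed
#'   16-bit uV).
#' @return An object of class `"snn_network"`.
#' @export
snn_network <- function(n_units, globals, connections) {
  n_units <- as.integer(n_units)
  if (n_units < 1L || n_units > SNN_MAX_UNITS)
    stop("n_units must be 1-", SNN_MAX_UNITS, " (got ", n_units, ")",
         call. = FALSE)
  stopifnot(inherits(globals, "snn_globals"))
  connections <- as.data.frame(connections)
  if (nrow(connections) > SNN_MAX_CONNECTIONS)
    stop("at most ", SNN_MAX_CONNECTIONS, " connections (got ",
         nrow(connections), ")", call. = FALSE)
  bad_src <- connections$source < -8 | connections$source >= n_units
  if (any(bad_src))
    stop("connection source out of range (external sources are -1..-8): ",
         paste(unique(connections$source[bad_src]), collapse = ","),
         call. = FALSE)
  if (any(connections$target < 0 | connections$target >= n_units))
    stop("connection target out of range", call. = FALSE)
  if (any(connections$weight_uv < INT16_MIN | connections$weight_uv > INT16_MAX))
    stop("connection weights must be signed 16-bit uV", call. = FALSE)
  structure(list(n_units = n_units, globals = globals,
                 connections = connections), class = "snn_network")
}

#' @export
print.snn_network <- function(x, ...) {
  cat("<snn_network> ", x$n_units, " units, ", nrow(x$connections),
      " connections, delay ", x$globals$conduction_delay_steps,
      " steps, threshold ", x$globals$threshold_uv, " uV\n", sep = "")
  invisible(x)
}

#' Q16 fixed-point decay
#'
#' Multiplies a signed 16-bit potential by a Q16 decay fraction, keeping the
#' most significant 16 bits of the 32-bit product: `floor(p * d / 2^16)`,
#' with floor toward minus infinity for negative potentials (arithmetic
#' shift semantics).
#'
#' @param p Potential(s), signed 16-bit.
#' @param d Decay constant(s), Q16 integer 0--65535.
#' @return Decayed potential(s).
#' @examples
#' decay_fixed_point(16384, 32768)  # exact halving: 8192
#' @export
decay_fixed_point <- function(p, d) {
  floor(p * d / 65536)
}

# 32-bit linear congruential stream; the top 16 bits of the state are the
# Q16 draw compared against bias_chance. Chosen as a documented, exactly
# reproducible stand-in for the unpublished hardware generator.
LCG_A <- 1664525
LCG_C <- 1013904223
LCG_M <- 4294967296  # 2^32

lcg_next <- function(s) (LCG_A * s + LCG_C) %% LCG_M
lcg_draw_q16 <- function(s) floor(s / 65536)

#' Initial runtime state for a network
#'
#' @param net An [snn_network()].
#' @param seed Integer seed for the bias-spike stream.
#' @return An object of class `"snn_state"`: fast/slow potentials (uV), the
#'   conduction-delay spike queue and the bias PRNG state.
#' @export
snn_state <- function(net, seed = 1L) {
  d <- net$globals$conduction_delay_steps
  structure(list(
    v_fast = numeric(net$n_units),
    v_slow = numeric(net$n_units),
    queue = matrix(FALSE, net$n_units, d),
    ptr = 1L,
    prng = (as.double(seed) * 2654435761 + 1) %% LCG_M,
    step = 0
  ), class = "snn_state")
}

#' Advance the network by one 0.1 ms step
#'
#' Performs the engine's four sub-steps in order: (1) both potentials of
#' every unit are decayed with [decay_fixed_point()]; (2) every delayed
#' spike due this step (internal spikes that fired `conduction_delay` steps
#' ago, and external generator spikes routed to this step) adds its
#' connection weight to the target's fast and slow potentials, saturating at
#' the signed 16-bit bounds; (3) if the bias chance is nonzero, each unit in
#' index order draws one Q16 pseudo-random value and receives the bias
#' strength on both potentials when the draw is below the bias chance;
#' (4) units whose slow minus fast potential strictly exceeds the threshold
#' enqueue a spike and reset both potentials to zero.
#'
#' @param net An [snn_network()].
#' @param state An [snn_state()].
#' @param ext_spikes Logical vector of length 8: external spikes from the
#'   event generators delivered this step (see [route_io()]).
#' @return List with the updated `state` and `fired` (0-based indices of
#'   units that fired, among all units).
#' @export
step_network <- function(net, state, ext_spikes = logical(8)) {
  g <- net$globals
  n <- net$n_units
  # (1) decay
  vf <- decay_fixed_point(state$v_fast, g$fast_decay)
  vs <- decay_fixed_point(state$v_slow, g$slow_decay)
  # (2) delayed spike delivery
  due_internal <- state$queue[, state$ptr]
  conn <- net$connections
  src <- conn$source
  due <- logical(length(src))
  int <- src >= 0
  due[int] <- due_internal[src[int] + 1L]
  due[!int] <- ext_spikes[-src[!int]]
  if (any(due)) {
    delta <- rowsum(conn$weight_uv[due], conn$target[due])
    idx <- as.integer(rownames(delta)) + 1L
    vf[idx] <- clamp_i16(vf[idx] + delta[, 1])
    vs[idx] <- clamp_i16(vs[idx] + delta[, 1])
  }
  # (3) bias spikes
  if (g$bias_chance > 0) {
    draws <- numeric(n); s <- state$prng
    for (u in seq_len(n)) { s <- lcg_next(s); draws[u] <- lcg_draw_q16(s) }
    state$prng <- s
    b <- draws < g$bias_chance
    if (any(b)) {
      vf[b] <- clamp_i16(vf[b] + g$bias_strength_uv)
      vs[b] <- clamp_i16(vs[b] + g$bias_strength_uv)
    }
  }
  # (4) threshold check, reset, enqueue
  fired <- (vs - vf) > g$threshold_uv
  vf[fired] <- 0; vs[fired] <- 0
  state$queue[, state$ptr] <- fired
  state$ptr <- state$ptr %% ncol(state$queue) + 1L
  state$v_fast <- vf; state$v_slow <- vs
  state$step <- state$step + 1
  list(state = state, fired = which(fired) - 1L)
}

#' Run a network for many steps
#'
#' Convenience driver around [step_network()]. One simulated second is
#' exactly 10,000 steps.
#'
#' @param net An [snn_network()].
#' @param n_steps Number of 0.1 ms update steps.
#' @param ext_spikes Optional logical matrix (`n_steps` x 8) of external
#'   generator spikes per step.
#' @param seed Seed for the bias stream.
#' @return List with `raster` (data frame `step` (0-based), `unit`) and the
#'   final `state`.
#' @export
run_network <- function(net, n_steps, ext_spikes = NULL, seed = 1L) {
  state <- snn_state(net, seed)
  steps <- integer(0); units <- integer(0)
  blank <- logical(8)
  for (t in seq_len(n_steps)) {
    ext <- if (is.null(ext_spikes)) blank else as.logical(ext_spikes[t, ])
    r <- step_network(net, state, ext)
    state <- r$state
    if (length(r$fired)) {
      steps <- c(steps, rep.int(t - 1L, length(r$fired)))
      units <- c(units, r$fired)
    }
  }
  list(raster = data.frame(step = steps, unit = units), state = state)
}

#' Route generator events into and network spikes out of the SNN
#'
#' Events from generator `g` become external spikes from source `-(g+1)` on
#' the next network step boundary: an event at tick `T` is delivered on step
#' `floor(T / step_ticks) + 1` (0-based steps; step `s` spans ticks
#' `[s*step_ticks, (s+1)*step_ticks)`). In the other direction, output
#' spikes of units 0--7 are returned as activations of the corresponding
#' event generators, and spikes of units 0--15 as network event records.
#'
#' @param events [event_records()] with generator sources 0--7.
#' @param n_steps Number of network steps the flags should cover.
#' @param tb A [timebase()].
#' @return Logical matrix `n_steps` x 8 of external spike flags.
#' @export
route_io <- function(events, n_steps, tb = timebase()) {
  if (nrow(events) && any(events$source < 0 | events$source > 7))
    stop("generator id out of range 0-7", call. = FALSE)
  flags <- matrix(FALSE, n_steps, 8)
  if (nrow(events)) {
    step <- floor(events$timestamp / tb$snn_step_ticks) + 1
    ok <- step < n_steps
    flags[cbind(step[ok] + 1, events$source[ok] + 1)] <- TRUE
  }
  flags
}

#' Convert a network raster to session event records
#'
#' Spikes of the first 16 units are recorded as network events, timestamped
#' at the start tick of the step on which they fired; spikes of the first 8
#' units additionally activate the corresponding event generator.
#'
#' @param raster Data frame `step` (0-based), `unit` from [run_network()].
#' @param tb A [timebase()].
#' @return List with `records` ([event_records()] of kind
#'   `"network_event"`, units 0--15) and `activations` ([event_records()]
#'   of kind `"digital_event"`, sources = generator ids 0--7).
#' @export
raster_to_records <- function(raster, tb = timebase()) {
  rec <- raster[raster$unit < 16, , drop = FALSE]
  act <- raster[raster$unit < 8, , drop = FALSE]
  list(
    records = event_records(rec$step * tb$snn_step_ticks, rec$unit,
                            "network_event"),
    activations = event_records(act$step * tb$snn_step_ticks, act$unit,
                                "digital_event")
  )
}
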