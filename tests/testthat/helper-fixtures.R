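# Shared fixture builders. Everything is generated in code; no stored data.

make_channels <- function(n, mode = "single_ended", rate = 20000) {
  lapply(seq_len(n) - 1L, function(i) channel_config(i, mode, rate))
}

# canonical 1 mA, 0.4 ms biphasic pulse (0.2 ms per phase)
canonical_waveform <- function(waveform_id = 0L, pins = c(0L, 1L),
                               delay_ticks = 0, count = 1L, ipi_ticks = 0,
                               amp_ua = 1000) {
  stim_waveform(waveform_id, delay_ticks,
                amp1_ua = amp_ua, width1_ticks = 20,
                amp2_ua = -amp_ua, width2_ticks = 20,
                count = count, ipi_ticks = ipi_ticks, pins = pins)
}

one_waveform_condition <- function(w, gen = 0L) {
  stim_condition(0L, list(w), list(list(gen = gen,
                                        waveform_ids = w$waveform_id,
                                        rules = list())))
}

# brute-force window-discriminator oracle: checks every sample directly
disc_oracle <- function(codes, period, spec, blanking = NULL) {
  n <- length(codes)
  delays <- vapply(spec$windows, `[[`, 0, "delay_ticks")
  dsamp <- delays %/% period
  out <- numeric(0)
  last <- -Inf
  for (i in 2:n) {
    t <- (i - 1) * period
    crossed <- if (spec$polarity == "rising")
      codes[i - 1] < spec$threshold && codes[i] >= spec$threshold
    else codes[i - 1] > spec$threshold && codes[i] <= spec$threshold
    if (!crossed) next
    if (!is.null(blanking) && nrow(blanking)) {
      inb <- FALSE
      for (k in seq_len(nrow(blanking)))
        if (t >= blanking[k, 1] && t < blanking[k, 2]) inb <- TRUE
      if (inb) next
    }
    if (t - last < spec$dead_time_ticks) next
    ok <- TRUE
    for (wi in seq_along(spec$windows)) {
      j <- i + dsamp[wi]
      w <- spec$windows[[wi]]
      if (j > n || codes[j] < w$amplitude_min || codes[j] > w$amplitude_max) {
        ok <- FALSE; break
      }
    }
    if (ok) { out <- c(out, t); last <- t }
  }
  out
}

# independent scalar reference implementation of the fixed-point network
# engine: explicit per-unit, per-connection loops, saturation applied at the
# defined points, and the machine's LCG stream for bias draws
snn_reference_run <- function(net, n_steps, ext = NULL, seed = 1L) {
  g <- net$globals
  n <- net$n_units
  D <- g$conduction_delay_steps
  vf <- numeric(n); vs <- numeric(n)
  queue <- matrix(FALSE, n, D); ptr <- 1L
  s <- (as.double(seed) * 2654435761 + 1) %% 2^32
  sat <- function(x) max(-32768, min(32767, x))
  conn <- net$connections
  raster <- list()
  for (t in seq_len(n_steps)) {
    for (u in seq_len(n)) {
      pd <- vf[u] * g$fast_decay
      vf[u] <- (pd - (pd %% 65536)) / 65536
      pd <- vs[u] * g$slow_decay
      vs[u] <- (pd - (pd %% 65536)) / 65536
    }
    due <- queue[, ptr]
    extt <- if (is.null(ext)) logical(8) else as.logical(ext[t, ])
    acc <- numeric(n)
    for (k in seq_len(nrow(conn))) {
      src <- conn$source[k]
      fired_src <- if (src >= 0) due[src + 1] else extt[-src]
      if (fired_src) acc[conn$target[k] + 1] <- acc[conn$target[k] + 1] +
          conn$weight_uv[k]
    }
    for (u in seq_len(n)) {
      if (acc[u] != 0) {
        vf[u] <- sat(vf[u] + acc[u])
        vs[u] <- sat(vs[u] + acc[u])
      }
    }
    if (g$bias_chance > 0) {
      for (u in seq_len(n)) {
        s <- (1664525 * s + 1013904223) %% 2^32
        if (floor(s / 65536) < g$bias_chance) {
          vf[u] <- sat(vf[u] + g$bias_strength_uv)
          vs[u] <- sat(vs[u] + g$bias_strength_uv)
        }
      }
    }
    fired <- logical(n)
    for (u in seq_len(n)) {
      if (vs[u] - vf[u] > g$threshold_uv) {
        fired[u] <- TRUE; vf[u] <- 0; vs[u] <- 0
      }
    }
    queue[, ptr] <- fired
    ptr <- ptr %% D + 1L
    if (any(fired))
      raster[[length(raster) + 1L]] <- data.frame(step = t - 1L,
                                                  unit = which(fired) - 1L)
  }
  list(raster = if (length(raster)) do.call(rbind, raster) else
         data.frame(step = integer(), unit = integer()),
       v_fast = vf, v_slow = vs)
}

# random small network for oracle comparisons
random_net <- function(n_units = 20, n_conn = 60, seed = 1,
                       bias_chance = 3000, delay = 3) {
  set.seed(seed)
  conn <- data.frame(
    source = sample(c(-(1:8), 0:(n_units - 1)), n_conn, replace = TRUE),
    target = sample(0:(n_units - 1), n_conn, replace = TRUE),
    weight_uv = sample(-2000:2000, n_conn, replace = TRUE))
  snn_network(n_units,
              snn_globals(delay, fast_decay = 45000, slow_decay = 60000,
                          bias_chance = bias_chance, bias_strength_uv = 800,
                          threshold_uv = 1200),
              conn)
}

# discriminator spec tuned to a known template rendered at a given peak
# (negative-going): threshold at half peak, one window on the trough
template_disc <- function(template_codes, period, noise_codes = 0) {
  peak_i <- which.min(template_codes)
  peak <- template_codes[peak_i]
  thr <- peak / 2
  cross_i <- which(template_codes <= thr)[1]
  d <- (peak_i - cross_i) * period
  pad <- max(4 * noise_codes, abs(peak) * 0.35)
  wins <- list(list(delay_ticks = d,
                    amplitude_min = peak - pad, amplitude_max = peak + pad))
  window_disc_spec(thr, "falling", wins, dead_time_ticks = 100)
}
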