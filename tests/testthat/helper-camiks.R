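# shared fixtures and independent oracles, built in code at test time

# independent brute-force ITC solver: free ligand by plain bisection on the
# mass balance for an arbitrary number of site classes, coded separately
# from the package's quadratic/uniroot paths
brute_itc_heats <- function(n, kd, dh, volumes, cell_conc, syringe_conc,
                            cell_volume) {
  dv <- cumsum(volumes)
  f_cell <- (1 - dv / (2 * cell_volume)) / (1 + dv / (2 * cell_volume))
  m_t <- cell_conc * f_cell
  x_t <- syringe_conc * (dv / cell_volume) / (1 + dv / (2 * cell_volume))
  q_cum <- numeric(length(volumes))
  for (i in seq_along(volumes)) {
    lo <- 0
    hi <- x_t[i]
    for (k in 1:200) {
      mid <- (lo + hi) / 2
      bound <- m_t[i] * sum(n * mid / (kd + mid))
      if (mid + bound > x_t[i]) hi <- mid else lo <- mid
    }
    l <- (lo + hi) / 2
    q_cum[i] <- m_t[i] * sum(n * dh * l / (kd + l)) * cell_volume * 1e3
  }
  q_prev <- c(0, q_cum[-length(q_cum)])
  q_cum - q_prev + (volumes / cell_volume) * (q_cum + q_prev) / 2
}

default_itc_experiment <- function(n_inj = 20) {
  itc_experiment(tibble::tibble(volume_ul = rep(2, n_inj)),
                 cell_conc = 50e-6, syringe_conc = 750e-6)
}

# idealised AP waveforms on a 0.05 ms grid; hand-derived APD50 oracles in
# the tests that use them
square_ap <- function() {
  t <- seq(0, 400, by = 0.05)
  tibble::tibble(time_ms = t,
                 v_mV = ifelse(t >= 10 & t < 110, 20, -80))
}

triangle_ap <- function() {
  t <- seq(0, 400, by = 0.05)
  v <- rep(-80, length(t))
  up <- t >= 10 & t <= 10.5
  v[up] <- -80 + (t[up] - 10) / 0.5 * 120
  down <- t > 10.5 & t <= 310.5
  v[down] <- 40 - (t[down] - 10.5) * 0.4
  tibble::tibble(time_ms = t, v_mV = v)
}

# random-but-plausible model states for derivative cross-checks
random_ord_states <- function(n, seed = 421) {
  base <- ord_initial_state()
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    s <- base
    s["v"] <- runif(1, -90, 40)
    s[2:9] <- base[2:9] * runif(8, 0.7, 1.3)
    s[10:45] <- pmin(pmax(base[10:45] + runif(36, -0.15, 0.15), 1e-6), 1)
    s
  }))
}
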