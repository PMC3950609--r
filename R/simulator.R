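#' Simulation configuration
#'
#' Numerical and recording settings for the cable solver. The default time
#' step (0.025 ms) with the implicit tree solve is stable for the stiff SOCB
#' sodium density; axial resistivity is not a measured quantity of this model
#' lineage's recordings and defaults to the customary 110 Ohm cm.
#'
#' @param dt time step, ms
#' @param axial_resistivity Ohm cm
#' @param settle_time ms simulated before t = 0 of any protocol
#' @param initial_v uniform initial potential, mV
#' @param solver `"backward_euler"` or `"crank_nicolson"`
#' @param record_sites site names to record (`"soma"`, `"socb"`,
#'   `"distal_axon"`, or a compartment id)
#' @param record_currents record per-channel current densities at the sites
#' @return a list of class `rgc_sim_config`
#' @export
simulation_config <- function(dt = 0.025, axial_resistivity = 110,
                              settle_time = 500, initial_v = -65,
                              solver = c("backward_euler", "crank_nicolson"),
                              record_sites = "soma",
                              record_currents = FALSE) {
  solver <- match.arg(solver)
  stopifnot(dt > 0, axial_resistivity > 0, settle_time >= 0)
  structure(list(dt = dt, axial_resistivity = axial_resistivity,
                 settle_time = settle_time, initial_v = initial_v,
                 solver = solver, record_sites = record_sites,
                 record_currents = record_currents),
            class = "rgc_sim_config")
}

#' Assemble a simulatable cell
#'
#' Binds a (discretized) morphology to the channel distribution and a free
#' conductance triple: resolves per-compartment densities, computes the axial
#' coupling conductances from cylinder geometry and axial resistivity, and
#' registers the named recording sites `soma`, `socb` (the SOCB compartment
#' closest to the band midpoint) and `distal_axon` (the distal end).
#'
#' @param morph an `rgc_morphology`
#' @param triple `c(g_nap, g_t, g_h)` maximal densities, S/cm2
#' @param table a [distribution_table()]
#' @param config a [simulation_config()] (axial resistivity is taken here)
#' @return a list of class `rgc_simcell`
#' @export
build_cell <- function(morph, triple, table = distribution_table(),
                       config = simulation_config()) {
  validate_morphology(morph)
  df <- as.data.frame(morph)
  n <- nrow(df)
  dens <- t(vapply(seq_len(n), function(i) {
    compartment_conductances(table, df$region[i], df$in_socb[i], triple)
  }, numeric(9)))
  colnames(dens) <- CHANNELS
  area_cm2 <- lateral_area(df) * 1e-8
  # axial: half-cylinder resistances in series, lengths/diameters in cm
  r_half <- config$axial_resistivity * (df$length * 1e-4 / 2) /
    (pi * (df$diameter * 1e-4 / 2)^2)
  g_axial <- numeric(n)
  for (i in seq_len(n)[-1]) {
    p <- df$parent_id[i]
    g_axial[i] <- 1e6 / (r_half[i] + r_half[p])
  }
  sites <- c(soma = 1L)
  if (any(df$in_socb)) {
    spec <- get_axon_spec(morph)
    mid <- spec$socb_start + spec$socb_length / 2
    socb_rows <- which(df$in_socb)
    sites["socb"] <- socb_rows[which.min(abs(df$arc_from_soma[socb_rows] - mid))]
  }
  distal <- which(df$region == "distal_axon")
  if (length(distal)) sites["distal_axon"] <- distal[which.max(df$arc_from_soma[distal])]
  structure(list(morph = morph, parent = ifelse(is.na(df$parent_id), 0L,
                                                df$parent_id) - 1L,
                 area_cm2 = area_cm2, g_axial = g_axial, dens = dens,
                 sites = sites, triple = triple, table = table,
                 n_comp = n),
            class = "rgc_simcell")
}

resolve_site <- function(cell, site) {
  if (is.numeric(site)) {
    stopifnot(site >= 1, site <= cell$n_comp)
    return(as.integer(site))
  }
  if (!site %in% names(cell$sites))
    stop("site '", site, "' not available on this cell (no standard axon?)")
  cell$sites[[site]]
}

#' Current-clamp stimulus protocols
#'
#' The named protocols used for tuning and validation: `spontaneous` (no
#' stimulus, 1.5 s), `hyp_step_200pA` (-0.2 nA for 500 ms with 1 s pre and
#' 500 ms post), `staircase_fig9` (seven increasing -0.02 nA steps of 2 s each
#' followed by one -0.2 nA step of 0.5 s), `cv_steps` (-20 pA increments to
#' -80 pA, each held for `hold_duration`), and `on_depolarize` (a sustained
#' depolarizing holding current).
#'
#' @param name protocol name
#' @param hold_duration ms per level for `cv_steps` (default 10 s) and
#'   `on_depolarize`
#' @param amplitude nA holding current for `on_depolarize` (default 0.05)
#' @param site stimulation site name or compartment id (default soma)
#' @return a data.frame of steps (`t_start`, `duration`, `amplitude`) of class
#'   `rgc_protocol`, with attributes `tstop` and `site`
#' @export
make_protocol <- function(name = c("spontaneous", "hyp_step_200pA",
                                   "staircase_fig9", "cv_steps",
                                   "on_depolarize"),
                          hold_duration = 10000, amplitude = 0.05,
                          site = "soma") {
  name <- match.arg(name)
  steps <- switch(name,
    spontaneous = data.frame(t_start = numeric(0), duration = numeric(0),
                             amplitude = numeric(0)),
    hyp_step_200pA = data.frame(t_start = 1000, duration = 500,
                                amplitude = -0.2),
    staircase_fig9 = rbind(
      data.frame(t_start = (0:6) * 2000, duration = 2000,
                 amplitude = -0.02 * (1:7)),
      data.frame(t_start = 14000, duration = 500, amplitude = -0.2)),
    cv_steps = data.frame(t_start = (0:3) * hold_duration,
                          duration = hold_duration,
                          amplitude = -0.02 * (1:4)),
    on_depolarize = data.frame(t_start = 0, duration = hold_duration,
                               amplitude = amplitude)
  )
  tstop <- switch(name,
    spontaneous = 1500,
    hyp_step_200pA = 2000,
    staircase_fig9 = 15000,
    cv_steps = 4 * hold_duration,
    on_depolarize = hold_duration
  )
  structure(steps, class = c("rgc_protocol", "data.frame"),
            tstop = tstop, site = site, name = name)
}

# a bare protocol from explicit steps
custom_protocol <- function(steps, tstop, site = "soma") {
  stopifnot(all(c("t_start", "duration", "amplitude") %in% names(steps)))
  structure(steps, class = c("rgc_protocol", "data.frame"),
            tstop = tstop, site = site, name = "custom")
}

#' Simulate a cell under a current-clamp protocol
#'
#' Integrates the coupled cable + channel + calcium system: the voltage starts
#' uniform at `initial_v` with gates at their voltage-clamp steady state and
#' calcium at the residual level, `settle_time` is simulated before protocol
#' time zero, and each step advances gates (exact exponential / implicit
#' two-state), then calcium (exact linear update), then the voltage by an
#' implicit tree solve. Output is deterministic for fixed inputs.
#'
#' @param cell an [build_cell()] result
#' @param protocol an [make_protocol()] result
#' @param config a [simulation_config()]
#' @param constants a [membrane_constants()] list
#' @return an `rgc_recording`: list with `time` (ms, protocol time), `v`
#'   (matrix, one column per recorded site), `dt`, `stim` (nA trace),
#'   `currents` (optional per-channel densities), and metadata
#' @export
simulate <- function(cell, protocol, config = simulation_config(),
                     constants = membrane_constants()) {
  stopifnot(inherits(cell, "rgc_simcell"), inherits(protocol, "rgc_protocol"))
  tstop <- attr(protocol, "tstop")
  steps_df <- as.data.frame(protocol)
  if (nrow(steps_df) && max(steps_df$t_start + steps_df$duration) > tstop)
    stop("protocol steps extend past tstop")
  n_steps <- round(tstop / config$dt)
  tgrid <- (seq_len(n_steps) - 1) * config$dt
  stim <- numeric(n_steps)
  for (k in seq_len(nrow(steps_df))) {
    on <- tgrid >= steps_df$t_start[k] &
      tgrid < steps_df$t_start[k] + steps_df$duration[k]
    stim[on] <- stim[on] + steps_df$amplitude[k]
  }
  rec_idx <- vapply(config$record_sites, function(s) resolve_site(cell, s), 1L)
  stim_comp <- resolve_site(cell, attr(protocol, "site"))
  cc <- unlist(constants[c("cm", "v_na", "v_k", "v_l", "v_h", "v_t", "ca_e",
                           "ca_diss", "ca_res", "tau_ca", "rt2f_mv",
                           "ca_drive")])
  res <- simulate_core(cell$parent, cell$area_cm2, cell$g_axial, cell$dens,
                       cc, config$dt, n_steps,
                       round(config$settle_time / config$dt), stim,
                       stim_comp - 1L, rec_idx - 1L, config$record_currents,
                       config$initial_v,
                       config$solver == "crank_nicolson")
  v <- res$v
  colnames(v) <- names(rec_idx)
  structure(list(time = seq(0, by = config$dt, length.out = n_steps + 1),
                 v = v, dt = config$dt, stim = c(stim, 0),
                 currents = res$currents, protocol = protocol,
                 sites = rec_idx, config = config,
                 metadata = list(triple = cell$triple, n_comp = cell$n_comp)),
            class = "rgc_recording")
}

#' @export
print.rgc_recording <- function(x, ...) {
  cat(sprintf("Recording: %.0f ms at dt %.3f ms, sites: %s\n",
              max(x$time), x$dt, paste(colnames(x$v), collapse = ", ")))
  invisible(x)
}
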