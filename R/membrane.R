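GATE_NAMES <- c("m", "h", "c", "n", "a", "h_A", "l", "m_T", "h_T", "d", "p")

#' Fixed membrane parameters
#'
#' The constants shared by all simulations: specific capacitance, reversal
#' potentials, the calcium shell geometry and clearance time constant, and the
#' physical constants entering the calcium Nernst potential. The temperature
#' (305.15 K = 32 C) matches the recordings the model is constrained against.
#'
#' @param ... overrides by name (e.g. `v_l = -62`)
#' @return a named list of class `rgc_constants`
#' @export
membrane_constants <- function(...) {
  const <- list(
    cm = 1,            # uF/cm2
    v_k = -70, v_l = -60, v_h = 0, v_t = 120, v_na = 35, # mV
    ca_e = 1.8e-3,     # M, extracellular calcium
    ca_diss = 1e-6,    # M, K(Ca) dissociation constant
    ca_res = 1e-7,     # M, residual intracellular calcium
    r_shell = 0.1,     # um, submembrane shell depth
    tau_ca = 1.5,      # ms, calcium clearance time constant
    r_gas = 8.314,     # J/(M K)
    faraday = 9.684e4, # C/M
    temp_k = 305.15,   # K (32 C)
    gl0 = 8e-6,        # S/cm2, unadjusted leak density
    g_kca = 5e-5       # S/cm2, K(Ca) maximal conductance scale
  )
  over <- list(...)
  bad <- setdiff(names(over), names(const))
  if (length(bad)) stop("unknown constant: ", bad[1])
  const[names(over)] <- over
  # derived: RT/2F in mV, and the Eq-3 drive term in M/ms per mA/cm2
  const$rt2f_mv <- 1000 * const$r_gas * const$temp_k / (2 * const$faraday)
  const$ca_drive <- 3e-3 / (2 * const$faraday * const$r_shell * 1e-4)
  class(const) <- c("rgc_constants", "list")
  const
}

#' Voltage-dependent gating rates
#'
#' Evaluates the transition rates alpha and beta (1/ms) for one of the eleven
#' gating variables, together with the steady state `x_inf = alpha/(alpha+beta)`
#' and time constant `tau = 1/(alpha+beta)`. Removable singularities in the
#' alpha functions (at -30, -13, -40 and -90 mV for m, c, n and a) are
#' evaluated by a second-order series; the persistent-sodium gate `p` switches
#' between its two rate branches at -40 mV.
#'
#' @param gate one of `"m"`, `"h"`, `"c"`, `"n"`, `"a"`, `"h_A"`, `"l"`,
#'   `"m_T"`, `"h_T"`, `"d"`, `"p"`
#' @param v membrane potential, mV (vectorized)
#' @return a data.frame with columns `alpha`, `beta`, `x_inf`, `tau`
#' @export
gate_kinetics <- function(gate, v) {
  idx <- match(gate, GATE_NAMES)
  if (is.na(idx)) stop("unknown gate name: ", gate)
  stopifnot(all(is.finite(v)))
  ab <- gate_rates_cpp(idx - 1L, as.numeric(v))
  data.frame(alpha = ab[, 1], beta = ab[, 2],
             x_inf = ab[, 1] / (ab[, 1] + ab[, 2]),
             tau = 1 / (ab[, 1] + ab[, 2]))
}

#' Gating state at voltage-clamp steady state
#'
#' @param v membrane potential, mV (scalar)
#' @return named numeric vector over the eleven gates; the coupled
#'   (`h_T`, `d`) pair is set to the equilibrium of its two-state system
#' @export
steady_gating <- function(v) {
  stopifnot(length(v) == 1, is.finite(v))
  setNames(drop(steady_gates_cpp(v)), GATE_NAMES)
}

#' Advance the gating state over one time step at frozen voltage
#'
#' First-order gates relax exactly (`x <- x_inf + (x - x_inf) exp(-dt/tau)`);
#' the coupled T-current inactivation pair (`h_T`, `d`) takes one implicit
#' (backward Euler) step of its linear two-state system. Outputs are clamped
#' to \[0, 1\].
#'
#' @param state named numeric vector over the eleven gates, or an n x 11 matrix
#' @param v membrane potential, mV (scalar, or length n for a matrix state)
#' @param dt time step, ms, > 0
#' @return the advanced state in the same shape
#' @export
advance_gates <- function(state, v, dt) {
  stopifnot(dt > 0)
  if (is.matrix(state)) {
    stopifnot(ncol(state) == 11)
    return(advance_gates_cpp(state, rep_len(as.numeric(v), nrow(state)), dt))
  }
  stopifnot(length(state) == 11)
  st <- state[GATE_NAMES]
  out <- advance_gates_cpp(matrix(as.numeric(st), 1), as.numeric(v), dt)
  setNames(drop(out), GATE_NAMES)
}

#' Calcium Nernst potential
#'
#' `V_Ca = (RT/2F) ln(Ca_e / Ca_i)` in mV.
#'
#' @param ca_i intracellular calcium, M, > 0 (vectorized)
#' @param constants a [membrane_constants()] list
#' @return mV
#' @export
nernst_vca <- function(ca_i, constants = membrane_constants()) {
  if (any(ca_i <= 0)) stop("ca_i must be positive")
  constants$rt2f_mv * log(constants$ca_e / ca_i)
}

#' Advance the submembrane calcium concentration
#'
#' Integrates `dCa/dt = -3 I_Ca / (2 F r) - (Ca - Ca_res)/tau_Ca` by the exact
#' linear update at frozen calcium current (inward current negative, so inward
#' flux raises the concentration).
#'
#' @param ca_i M, > 0
#' @param i_ca calcium current density, mA/cm2 (inward negative)
#' @param dt ms, > 0
#' @param constants a [membrane_constants()] list
#' @return M, always positive
#' @export
advance_calcium <- function(ca_i, i_ca, dt, constants = membrane_constants()) {
  stopifnot(dt > 0, all(ca_i > 0))
  ca_inf <- constants$ca_res - constants$ca_drive * i_ca * constants$tau_ca
  out <- ca_inf + (ca_i - ca_inf) * exp(-dt / constants$tau_ca)
  pmax(out, 1e-12)
}

#' Calcium-activated potassium conductance
#'
#' `g = g_max (Ca/Ca_diss)^2 / (1 + (Ca/Ca_diss)^2)`: half-maximal at the
#' dissociation constant, monotone in calcium, bounded by `g_max`.
#'
#' @param ca_i M (vectorized)
#' @param g_kca_max S/cm2
#' @param constants a [membrane_constants()] list
#' @return S/cm2
#' @export
kca_conductance <- function(ca_i, g_kca_max,
                            constants = membrane_constants()) {
  y <- (ca_i / constants$ca_diss)^2
  g_kca_max * y / (1 + y)
}

#' Regional channel distribution
#'
#' The per-region channel densities (S/cm2): the fixed block (Na, HVA Ca,
#' delayed-rectifier K, A-type K, K(Ca) scale, adjusted leak) and the
#' multipliers applied to the free conductance triple (NaP, T, h). SOCB-flagged
#' compartments override their region with a five-fold Na and NaP density and
#' no Ca, K, A-type or K(Ca) channels. The leak is the 15-fold adjusted value
#' everywhere except the distal axon (25-fold). The distal-axon K(Ca) scale is
#' exposed as an argument because its printed value (0.07 S/cm2) is three
#' orders of magnitude above every other region.
#'
#' @param gl0 unadjusted leak density, S/cm2
#' @param leak_multiplier leak adjustment outside the distal axon
#' @param leak_multiplier_distal leak adjustment in the distal axon
#' @param g_kca_distal distal-axon K(Ca) maximal conductance, S/cm2
#' @return a list of class `rgc_distribution`
#' @export
distribution_table <- function(gl0 = 8e-6, leak_multiplier = 15,
                               leak_multiplier_distal = 25,
                               g_kca_distal = 0.07) {
  regions <- REGIONS
  fixed <- rbind(
    na      = c(0.08,   0.025,  0.15,   0.2,    0.07),
    ca      = c(0.0015, 0.002,  0.0015, 0,      0),
    k       = c(0.018,  0.012,  0.018,  0.018,  0.018),
    ka      = c(0.054,  0.036,  0.054,  0,      0),
    kca_max = c(6.5e-5, 1e-6,   6.5e-5, 6.5e-5, g_kca_distal),
    l       = c(rep(leak_multiplier * gl0, 4), leak_multiplier_distal * gl0)
  )
  colnames(fixed) <- regions
  out <- list(
    fixed = fixed,
    socb = c(na = 5 * 0.08, ca = 0, k = 0, ka = 0, kca_max = 0),
    nap_mult = c(soma = 1, dendrite = 1, initial_segment = 0.05,
                 narrow_segment = 0.05, distal_axon = 0.05),
    t_mult = c(soma = 1, dendrite = 5, initial_segment = 1,
               narrow_segment = 1, distal_axon = 1),
    h_mult = c(soma = 1, dendrite = 1, initial_segment = 1,
               narrow_segment = 1, distal_axon = 1),
    socb_nap_mult = 5, socb_t_mult = 1, socb_h_mult = 1
  )
  class(out) <- c("rgc_distribution", "list")
  out
}

CHANNELS <- c("na", "ca", "k", "ka", "kca_max", "l", "h", "nap", "t")

#' Channel densities of one compartment
#'
#' Resolves the nine channel densities for a compartment from its region, its
#' SOCB flag, and the free conductance triple (maximal NaP, T and h densities
#' in S/cm2).
#'
#' @param table a [distribution_table()]
#' @param region region name
#' @param in_socb logical SOCB flag
#' @param triple numeric length 3: `c(g_nap, g_t, g_h)` in S/cm2, >= 0
#' @return named numeric vector over `na, ca, k, ka, kca_max, l, h, nap, t`
#' @export
compartment_conductances <- function(table, region, in_socb, triple) {
  if (!region %in% REGIONS) stop("unknown region: ", region)
  stopifnot(length(triple) == 3, all(triple >= 0))
  g <- table$fixed[, region]
  if (isTRUE(in_socb)) g[names(table$socb)] <- table$socb
  nap <- triple[1] * if (isTRUE(in_socb)) table$socb_nap_mult else
    table$nap_mult[[region]]
  gt <- triple[2] * if (isTRUE(in_socb)) table$socb_t_mult else
    table$t_mult[[region]]
  gh <- triple[3] * if (isTRUE(in_socb)) table$socb_h_mult else
    table$h_mult[[region]]
  setNames(c(g[c("na", "ca", "k", "ka", "kca_max", "l")], gh, nap, gt),
           CHANNELS)
}

#' Total membrane current density and its per-channel breakdown
#'
#' Sums the nine ionic currents `g_x * (gating product) * (V - E_x)` with the
#' gating exponents of the current-balance equation (m^3 h, c^3, n^4, a^3 h_A,
#' l, m_T^3 h_T, p); the K(Ca) conductance is the calcium-dependent
#' [kca_conductance()] with reversal `V_K`, and the HVA calcium current uses
#' the dynamic calcium Nernst potential. Outward currents are positive.
#'
#' @param v membrane potential, mV
#' @param gates named gating vector (as [steady_gating()])
#' @param ca_state list with `ca_i` (M); its Nernst potential is recomputed
#' @param densities named densities as [compartment_conductances()]
#' @param constants a [membrane_constants()] list
#' @return list with `total` (mA/cm2) and `currents` (named breakdown);
#'   `currents["ca"]` is the HVA calcium current that drives the calcium shell
#' @export
total_ionic_current <- function(v, gates, ca_state, densities,
                                constants = membrane_constants()) {
  g <- gates
  v_ca <- nernst_vca(ca_state$ca_i, constants)
  gkca <- kca_conductance(ca_state$ca_i, densities[["kca_max"]], constants)
  cur <- c(
    na = densities[["na"]] * g[["m"]]^3 * g[["h"]] * (v - constants$v_na),
    ca = densities[["ca"]] * g[["c"]]^3 * (v - v_ca),
    k = densities[["k"]] * g[["n"]]^4 * (v - constants$v_k),
    ka = densities[["ka"]] * g[["a"]]^3 * g[["h_A"]] * (v - constants$v_k),
    kca = gkca * (v - constants$v_k),
    l = densities[["l"]] * (v - constants$v_l),
    h = densities[["h"]] * g[["l"]] * (v - constants$v_h),
    nap = densities[["nap"]] * g[["p"]] * (v - constants$v_na),
    t = densities[["t"]] * g[["m_T"]]^3 * g[["h_T"]] * (v - constants$v_t)
  )
  list(total = sum(cur), currents = cur)
}
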