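#' Constraint ranges for phenotype classification
#'
#' The tuning constraints: ON cells rest in \[-70, -62\] mV with no
#' spontaneous activity, no spikes during the -0.2 nA step and no rebound;
#' OFF cells rest in \[-62, -50\] mV, fire spontaneously at 15-23 Hz
#' (transient) or 40-48 Hz (sustained), stay silent during the step, and
#' rebound at >= 2x their spontaneous rate at step offset.
#' @keywords internal
CONSTRAINTS <- list(
  on = list(rest = c(-70, -62), spont = c(0, 0)),
  off_t = list(rest = c(-62, -50), spont = c(15, 23)),
  off_s = list(rest = c(-62, -50), spont = c(40, 48))
)

#' Evaluate one conductance triple against the tuning constraints
#'
#' Runs the spontaneous protocol (resting potential and spontaneous rate over
#' the final 1 s) and the -0.2 nA / 500 ms hyperpolarizing step protocol, and
#' fills the full constraint report. Spikes are counted only if they overshoot
#' 0 mV; the C0 check fails when the soma shows fast upstrokes (dV/dt >
#' 10 mV/ms) that never reach the 0 mV threshold.
#'
#' @param morph a discretized `rgc_morphology`
#' @param triple `c(g_nap, g_t, g_h)` in S/cm2
#' @param config a [simulation_config()]
#' @param table a [distribution_table()]
#' @return a list of class `rgc_constraint_report`
#' @export
evaluate_point <- function(morph, triple, config = simulation_config(),
                           table = distribution_table()) {
  cell <- build_cell(morph, triple, table, config)
  config$record_sites <- "soma"
  spont <- simulate(cell, make_protocol("spontaneous"), config)
  tr <- get_trace(spont, "soma")
  win <- c(max(tr$time) - 1000, max(tr$time))
  train <- detect_spikes(tr$v, tr$dt)
  spont_hz <- firing_rate(train, win)
  iw <- which(tr$time >= win[1] & tr$time < win[2])
  rest <- as.numeric(mean_vm_spike_removed(tr$v[iw], tr$dt))
  # C0: every fast upstroke in the window must reach the 0 mV threshold
  up <- which(c(diff(tr$v[iw]) / tr$dt, 0) > 10)
  c0 <- TRUE
  if (length(up)) {
    w <- ceiling(2 / tr$dt)
    reached <- vapply(up, function(i) {
      any(tr$v[iw][i:min(length(iw), i + w)] >= 0)
    }, logical(1))
    c0 <- all(reached)
  }
  step_rec <- simulate(cell, make_protocol("hyp_step_200pA"), config)
  sm <- step_response_metrics(step_rec)
  report <- list(c0_pass = c0, rest_mV = rest, spont_Hz = spont_hz,
                 spikes_during_hyp = sm$spikes_during_step,
                 rebound_rate_Hz = sm$rebound_burst_rate,
                 step_metrics = sm, triple = triple)
  report$on_pass <- c0 && spont_hz == 0 &&
    rest >= CONSTRAINTS$on$rest[1] && rest <= CONSTRAINTS$on$rest[2] &&
    sm$spikes_during_step == 0 && sm$rebound_burst_rate == 0
  off_ok <- function(band) {
    c0 && spont_hz >= band[1] && spont_hz <= band[2] &&
      rest >= CONSTRAINTS$off_t$rest[1] && rest <= CONSTRAINTS$off_t$rest[2] &&
      sm$spikes_during_step == 0 && spont_hz > 0 &&
      sm$rebound_burst_rate >= 2 * spont_hz
  }
  report$offT_pass <- off_ok(CONSTRAINTS$off_t$spont)
  report$offS_pass <- off_ok(CONSTRAINTS$off_s$spont)
  class(report) <- "rgc_constraint_report"
  report
}

#' Phenotype label of a constraint report
#'
#' Pure function of the report: returns `"ON"`, `"OFF_T"`, `"OFF_S"` or
#' `"none"`. The three pass flags are mutually exclusive by construction
#' (disjoint spontaneous-rate bands; ON requires silence).
#'
#' @param report an [evaluate_point()] result
#' @return a phenotype label
#' @export
classify_point <- function(report) {
  if (isTRUE(report$on_pass)) return("ON")
  if (isTRUE(report$offT_pass)) return("OFF_T")
  if (isTRUE(report$offS_pass)) return("OFF_S")
  "none"
}

#' Grid search over the free conductance space
#'
#' Evaluates and classifies every point of the (g_NaP, g_T, g_h) lattice.
#' Individual solver failures are recorded as label `"error"` rather than
#' aborting the search; results are independent of evaluation order. An
#' environment can be supplied as a cache so interrupted searches resume.
#'
#' @param morph a discretized `rgc_morphology`
#' @param gnap,gt,gh axis values, S/cm2
#' @param config a [simulation_config()]
#' @param table a [distribution_table()]
#' @param cache optional environment keyed by triple for resumable runs
#' @return a list of class `rgc_grid` with `axes` and `points` (data.frame
#'   with indices `i, j, k`, the conductances, and `label`)
#' @export
grid_search <- function(morph, gnap, gt, gh, config = simulation_config(),
                        table = distribution_table(), cache = NULL) {
  stopifnot(all(gnap >= 0), all(gt >= 0), all(gh >= 0))
  pts <- expand.grid(i = seq_along(gnap), j = seq_along(gt),
                     k = seq_along(gh))
  pts$gnap <- gnap[pts$i]
  pts$gt <- gt[pts$j]
  pts$gh <- gh[pts$k]
  lab <- character(nrow(pts))
  for (r in seq_len(nrow(pts))) {
    key <- paste(pts$gnap[r], pts$gt[r], pts$gh[r], sep = "|")
    if (!is.null(cache) && !is.null(cache[[key]])) {
      lab[r] <- cache[[key]]
      next
    }
    lab[r] <- tryCatch(
      classify_point(evaluate_point(
        morph, c(pts$gnap[r], pts$gt[r], pts$gh[r]), config, table)),
      error = function(e) "error")
    if (!is.null(cache)) cache[[key]] <- lab[r]
  }
  pts$label <- lab
  structure(list(axes = list(gnap = gnap, gt = gt, gh = gh), points = pts),
            class = "rgc_grid")
}

#' Linear refinement axes around the labelled region of a grid
#'
#' The second pass of the two-stage search: after a coarse (typically
#' logarithmic) sweep, build linearly spaced axes spanning the bounding box
#' of all phenotype-labelled points, one coarse cell wider on each side where
#' possible. Feed the result back to [grid_search()].
#'
#' @param grid a labelled [grid_search()] result
#' @param n points per axis in the refined lattice
#' @return a list with `gnap`, `gt`, `gh` axis vectors
#' @export
refinement_axes <- function(grid, n = 5) {
  lab <- grid$points[grid$points$label %in% c("ON", "OFF_T", "OFF_S"), ,
                     drop = FALSE]
  if (!nrow(lab)) stop("no labelled points to refine around")
  one <- function(axis, idx) {
    lo <- max(min(idx) - 1L, 1L)
    hi <- min(max(idx) + 1L, length(axis))
    seq(axis[lo], axis[hi], length.out = n)
  }
  list(gnap = one(grid$axes$gnap, lab$i),
       gt = one(grid$axes$gt, lab$j),
       gh = one(grid$axes$gh, lab$k))
}

#' Connected valid sets of a labelled grid
#'
#' Extracts, per phenotype, the connected components of same-labelled lattice
#' points under face (6-neighbour) adjacency (26-neighbour available).
#' Singleton components are reported separately from multi-point sets, since
#' isolated points do not constitute a valid conductance set.
#'
#' @param grid an [grid_search()] result
#' @param adjacency 6 (faces) or 26 (faces, edges and corners)
#' @return a list per phenotype, each with `components` (list of data.frames
#'   with a `bbox` attribute) and `singletons`
#' @export
extract_valid_sets <- function(grid, adjacency = 6) {
  stopifnot(adjacency %in% c(6, 26))
  out <- list()
  for (lab in c("ON", "OFF_T", "OFF_S")) {
    pts <- grid$points[grid$points$label == lab, , drop = FALSE]
    if (!nrow(pts)) {
      out[[lab]] <- list(components = list(), singletons = pts)
      next
    }
    n <- nrow(pts)
    edges <- integer(0)
    for (a in seq_len(n)) {
      dd <- abs(pts$i - pts$i[a]) + abs(pts$j - pts$j[a]) + abs(pts$k - pts$k[a])
      mx <- pmax(abs(pts$i - pts$i[a]),
                 pmax(abs(pts$j - pts$j[a]), abs(pts$k - pts$k[a])))
      nb <- if (adjacency == 6) which(dd == 1) else which(mx == 1)
      nb <- nb[nb > a]
      if (length(nb)) edges <- c(edges, rbind(a, nb))
    }
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (length(edges)) g <- igraph::add_edges(g, edges)
    comp <- igraph::components(g)
    comps <- list()
    singles <- pts[0, ]
    for (cid in seq_len(comp$no)) {
      members <- pts[comp$membership == cid, , drop = FALSE]
      if (nrow(members) == 1) {
        singles <- rbind(singles, members)
      } else {
        attr(members, "bbox") <- rbind(
          gnap = range(members$gnap), gt = range(members$gt),
          gh = range(members$gh))
        comps[[length(comps) + 1]] <- members
      }
    }
    out[[lab]] <- list(components = comps, singletons = singles)
  }
  structure(out, class = "rgc_valid_sets")
}

#' Smallest persistent-sodium density that drives spontaneous firing
#'
#' Bisects g_NaP for the smallest value producing sustained spontaneous
#' somatic spiking (spikes overshooting 0 mV at a positive rate over the final
#' 1 s of the spontaneous protocol) at fixed g_T and g_h.
#'
#' @param morph a discretized `rgc_morphology`
#' @param g_t,g_h fixed companion densities, S/cm2
#' @param lower,upper bisection bracket, S/cm2
#' @param tol bracket width at which to stop, S/cm2
#' @param config a [simulation_config()]
#' @return S/cm2 (midpoint of the final bracket); NA if even `upper` is silent
#' @export
find_nap_threshold <- function(morph, g_t = 3e-4, g_h = 1e-9, lower = 0,
                               upper = 4e-5, tol = 1e-6,
                               config = simulation_config()) {
  spikes_at <- function(gnap) {
    cell <- build_cell(morph, c(gnap, g_t, g_h), config = config)
    rec <- simulate(cell, make_protocol("spontaneous"), config)
    tr <- get_trace(rec, "soma")
    train <- detect_spikes(tr$v, tr$dt)
    firing_rate(train, c(max(tr$time) - 1000, max(tr$time))) > 0
  }
  if (!spikes_at(upper)) return(NA_real_)
  if (spikes_at(lower)) return(lower)
  while (upper - lower > tol) {
    mid <- (upper + lower) / 2
    if (spikes_at(mid)) upper <- mid else lower <- mid
  }
  (upper + lower) / 2
}

# regime label for one staircase level (artifact definitions; the transition
# itself is the qualitative prediction)
regime_of <- function(train, window, v, dt) {
  rate <- firing_rate(train, window)
  if (rate == 0) return("silent")
  st <- train$spike_times
  st <- st[st >= window[1] & st < window[2]]
  if (length(st) < 3) return("burst")
  isi <- diff(st)
  cv <- sd(isi) / mean(isi)
  if (cv >= 0.8 && any(isi < 30) && any(isi > 200)) return("burst")
  if (cv >= 0.3) return("irregular")
  "regular"
}

#' Validate an OFF conductance point
#'
#' Runs the staircase and CV-step protocols on an OFF-classified triple and
#' reports: per-level subthreshold oscillation analysis (V1), the observed
#' regime sequence across increasing hyperpolarization (V2; regimes: regular
#' CV < 0.3, irregular CV >= 0.3, burst = clustered spikes, silent), and the
#' CV of the ISI against the spike-removed membrane potential with its fitted
#' slope (V3).
#'
#' @param morph a discretized `rgc_morphology`
#' @param triple an OFF_T- or OFF_S-classified conductance triple
#' @param config a [simulation_config()]
#' @param cv_hold_duration ms held per CV step (10 s by default)
#' @param report optionally, the precomputed [evaluate_point()] report
#' @return a list of class `rgc_validation_report` with `v1`, `v2`, `v3`
#' @export
validate_point <- function(morph, triple, config = simulation_config(),
                           cv_hold_duration = 10000, report = NULL) {
  if (is.null(report)) report <- evaluate_point(morph, triple, config)
  label <- classify_point(report)
  if (!label %in% c("OFF_T", "OFF_S"))
    stop("validation applies only to OFF-classified triples (got ", label, ")")
  cell <- build_cell(morph, triple, config = config)
  config$record_sites <- "soma"

  stair <- simulate(cell, make_protocol("staircase_fig9"), config)
  tr <- get_trace(stair, "soma")
  train <- detect_spikes(tr$v, tr$dt)
  levels7 <- as.data.frame(stair$protocol)[1:7, ]
  v2 <- character(7)
  for (k in 1:7) {
    win <- c(levels7$t_start[k], levels7$t_start[k] + levels7$duration[k])
    iw <- which(tr$time >= win[1] & tr$time < win[2])
    v2[k] <- regime_of(train, win, tr$v[iw], tr$dt)
  }
  # oscillation analysis per level on a dedicated steady hold, so onset
  # relaxation does not masquerade as slow rhythm
  v1 <- lapply(levels7$amplitude, function(amp) {
    proto <- custom_protocol(
      data.frame(t_start = 0, duration = 3000, amplitude = amp), tstop = 3000)
    hold <- simulate(cell, proto, config)
    trh <- get_trace(hold, "soma")
    oscillation_report(trh$v[trh$time >= 1000], trh$dt)
  })

  cvp <- make_protocol("cv_steps", hold_duration = cv_hold_duration)
  cvrec <- simulate(cell, cvp, config)
  trc <- get_trace(cvrec, "soma")
  steps <- as.data.frame(cvp)
  v3 <- data.frame(amplitude = steps$amplitude, mean_vm = NA_real_,
                   cv = NA_real_)
  trainc <- detect_spikes(trc$v, trc$dt)
  for (k in seq_len(nrow(steps))) {
    win <- c(steps$t_start[k], steps$t_start[k] + steps$duration[k])
    iw <- which(trc$time >= win[1] & trc$time < win[2])
    v3$mean_vm[k] <- as.numeric(mean_vm_spike_removed(
      trc$v[iw], trc$dt, min_retained = 0))
    st <- trainc$spike_times
    st <- st[st >= win[1] & st < win[2]]
    if (length(st) >= 3) v3$cv[k] <- sd(diff(st)) / mean(diff(st))
  }
  ok <- !is.na(v3$cv)
  slope <- if (sum(ok) >= 2) unname(coef(lm(cv ~ mean_vm, v3[ok, ]))[2])
           else NA_real_
  structure(list(label = label, v1 = v1, v2 = v2, v3 = v3,
                 v3_slope = slope),
            class = "rgc_validation_report")
}

#' Surface-area reduction experiment
#'
#' Re-simulates a cell with dendritic diameters, dendritic lengths, or the
#' soma shrunk by steps of 10 % down to 50 % (channel densities per area held
#' fixed), recording for every factor the spontaneous rate, the rebound burst
#' rate after the -0.2 nA step, the spike peak amplitude, and the maximal
#' dV/dt.
#'
#' @param morph a discretized `rgc_morphology` (unscaled)
#' @param triple a constraint-meeting conductance triple
#' @param config a [simulation_config()]
#' @param targets which reductions to run
#' @param factors reduction factors
#' @return a tidy data.frame: target, factor, spont_Hz, rebound_rate_Hz,
#'   spike_peak_mV, max_dvdt
#' @export
morphology_reduction_experiment <- function(
    morph, triple, config = simulation_config(),
    targets = c("dendrite_diameter", "dendrite_length", "soma"),
    factors = c(1, 0.9, 0.8, 0.7, 0.6, 0.5)) {
  rows <- list()
  for (target in targets) {
    for (f in factors) {
      m <- scale_morphology(morph, target, f)
      cell <- build_cell(m, triple, config = config)
      config$record_sites <- "soma"
      spont <- simulate(cell, make_protocol("spontaneous"), config)
      tr <- get_trace(spont, "soma")
      train <- detect_spikes(tr$v, tr$dt)
      win <- c(max(tr$time) - 1000, max(tr$time))
      srec <- simulate(cell, make_protocol("hyp_step_200pA"), config)
      sm <- step_response_metrics(srec)
      rows[[length(rows) + 1]] <- data.frame(
        target = target, factor = f,
        spont_Hz = firing_rate(train, win),
        rebound_rate_Hz = sm$rebound_burst_rate,
        spike_peak_mV = max(tr$v),
        max_dvdt = max(diff(tr$v)) / tr$dt)
    }
  }
  do.call(rbind, rows)
}
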