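get_trace <- function(rec, site = "soma") {
  if (inherits(rec, "rgc_recording")) {
    if (!site %in% colnames(rec$v)) stop("site not recorded: ", site)
    list(v = rec$v[, site], dt = rec$dt, time = rec$time)
  } else {
    stop("expected an rgc_recording")
  }
}

#' Detect spikes by threshold crossing
#'
#' A spike time is the first sample of each upward crossing of the 0 mV
#' threshold; crossings within the refractory window of the previous spike are
#' suppressed. A trace that starts at or above threshold yields a single spike
#' at its first sample.
#'
#' @param v voltage trace, mV (uniformly sampled)
#' @param dt sample interval, ms
#' @param threshold mV, default 0
#' @param refractory ms, default 1
#' @param t0 time of the first sample, ms
#' @return a list of class `rgc_spike_train` with `spike_times` (ms, strictly
#'   increasing) and the detection settings
#' @export
detect_spikes <- function(v, dt, threshold = 0, refractory = 1, t0 = 0) {
  above <- v >= threshold
  crossing <- which(above & !c(FALSE, head(above, -1)))
  if (length(above) && above[1]) crossing <- union(1L, crossing)
  times <- t0 + (crossing - 1) * dt
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  structure(list(spike_times = times[keep], detection_threshold = threshold,
                 refractory = refractory),
            class = "rgc_spike_train")
}

spike_train_of <- function(rec, site = "soma") {
  tr <- get_trace(rec, site)
  detect_spikes(tr$v, tr$dt, t0 = tr$time[1])
}

#' Mean firing rate in a window
#'
#' Spikes in `[t0, t1)` divided by the window length, in Hz (times in ms).
#'
#' @param train an `rgc_spike_train`
#' @param window `c(t0, t1)` in ms, `t1 > t0`
#' @return Hz
#' @export
firing_rate <- function(train, window) {
  stopifnot(length(window) == 2)
  if (window[2] <= window[1]) stop("empty firing-rate window")
  n <- sum(train$spike_times >= window[1] & train$spike_times < window[2])
  n / (window[2] - window[1]) * 1000
}

# indices to drop: everything within `blank` ms after a dV/dt threshold hit
spike_mask <- function(v, dt, dvdt_threshold = 10, blank = 2) {
  dv <- c(diff(v) / dt, 0)
  hits <- which(dv > dvdt_threshold)
  if (!length(hits)) return(logical(length(v)))
  drop <- logical(length(v))
  w <- ceiling(blank / dt)
  for (h in hits) drop[h:min(length(v), h + w)] <- TRUE
  drop
}

#' Mean membrane potential with spikes removed
#'
#' Excludes all samples within 2 ms after any point where dV/dt exceeds
#' 10 mV/ms (the 10 V/s criterion) and averages the remainder. If fewer than
#' `min_retained` ms of data survive, the result carries attribute
#' `warning = TRUE`.
#'
#' @param v voltage trace, mV
#' @param dt ms
#' @param dvdt_threshold mV/ms
#' @param blank ms excised after each threshold hit
#' @param min_retained ms of retained data below which the result is flagged
#' @return mV (NaN if nothing is retained), possibly with `warning` attribute
#' @export
mean_vm_spike_removed <- function(v, dt, dvdt_threshold = 10, blank = 2,
                                  min_retained = 1000) {
  drop <- spike_mask(v, dt, dvdt_threshold, blank)
  kept <- v[!drop]
  out <- mean(kept)
  if (length(kept) * dt < min_retained) attr(out, "warning") <- TRUE
  out
}

#' Coefficient of variation of the inter-spike interval
#'
#' Sample standard deviation (n - 1 denominator) of the inter-spike intervals
#' divided by their mean. Requires at least three spikes (two intervals).
#'
#' @param train an `rgc_spike_train`
#' @return dimensionless CV
#' @export
cv_isi <- function(train) {
  isi <- diff(train$spike_times)
  if (length(isi) < 2) stop("cv_isi needs at least 2 inter-spike intervals")
  sd(isi) / mean(isi)
}

# Welch power spectral density by averaged Hann-windowed segments.
# Returns data.frame(freq Hz, power) for a signal sampled at fs Hz.
welch_psd <- function(x, fs, n_segments = 3) {
  n <- length(x)
  seg <- floor(2 * n / (n_segments + 1)) # 50 % overlap
  starts <- round(seq(1, n - seg + 1, length.out = n_segments))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  acc <- 0
  for (s in starts) {
    xs <- x[s:(s + seg - 1)]
    xs <- (xs - mean(xs)) * w
    acc <- acc + Mod(fft(xs))^2
  }
  nf <- floor(seg / 2)
  data.frame(freq = (seq_len(nf)) * fs / seg,
             power = acc[2:(nf + 1)] / length(starts))
}

# fft band-pass: zero all bins outside [f_lo, f_hi] Hz
bandpass_fft <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f) # two-sided
  xf <- fft(x - mean(x))
  xf[f < f_lo | f > f_hi] <- 0
  Re(fft(xf, inverse = TRUE)) / n
}

#' Detect subthreshold membrane-potential oscillations
#'
#' De-spikes (linear interpolation over excised samples) and linearly detrends
#' the trace, decimates it to 500 Hz, and computes a Welch periodogram. An
#' oscillation is `present` when a spectral peak in the 0.5-12 Hz band carries
#' at least `peak_factor` times the spectral median; its `frequency` is the
#' peak location and `peak_to_peak` is measured on the band-passed signal. The
#' oscillation is `sustained` when the band-passed amplitude over the final
#' half of the window retains at least half of the first half's amplitude.
#' Frequencies completing fewer than three cycles in the window are treated
#' as relaxation drift and excluded from the peak search.
#'
#' @param v voltage trace, mV
#' @param dt ms
#' @param band Hz, analysis band
#' @param peak_factor presence threshold relative to the spectral median
#' @param min_amplitude mV; band-passed peak-to-peak below this never counts
#'   as an oscillation (rejects flat traces and sample noise)
#' @return a list of class `rgc_oscillation_report` with `present`,
#'   `sustained`, `frequency` (Hz), `peak_to_peak` (mV)
#' @export
oscillation_report <- function(v, dt, band = c(0.5, 12), peak_factor = 3,
                               min_amplitude = 0.1) {
  if (length(v) * dt < 2000)
    stop("oscillation analysis needs at least 2 s of data")
  drop <- spike_mask(v, dt)
  x <- v
  if (any(drop)) {
    idx <- seq_along(v)
    x[drop] <- approx(idx[!drop], v[!drop], xout = idx[drop], rule = 2)$y
  }
  x <- x - fitted(lm(x ~ seq_along(x)))
  # decimate to 500 Hz by block means
  fs0 <- 1000 / dt
  dec <- max(1L, round(fs0 / 500))
  nb <- floor(length(x) / dec)
  x <- colMeans(matrix(x[seq_len(nb * dec)], nrow = dec))
  fs <- fs0 / dec
  psd <- welch_psd(x, fs)
  # frequencies with fewer than three cycles in the window cannot be told
  # apart from slow relaxation drift; lift the band floor accordingly
  f_lo <- max(band[1], 3000 / (length(v) * dt))
  in_band <- psd$freq >= f_lo & psd$freq <= band[2]
  pk <- which.max(psd$power * in_band)
  bp <- bandpass_fft(x, fs, f_lo, band[2])
  present <- psd$power[pk] >= peak_factor * median(psd$power) && in_band[pk] &&
    diff(range(bp)) >= min_amplitude
  half <- floor(length(bp) / 2)
  amp1 <- diff(range(bp[seq_len(half)]))
  amp2 <- diff(range(bp[(half + 1):length(bp)]))
  # frequency and amplitude always report the band peak; `present` carries
  # the detection decision
  structure(list(present = present,
                 sustained = present && amp2 >= 0.5 * amp1,
                 frequency = psd$freq[pk],
                 peak_to_peak = diff(range(bp))),
            class = "rgc_oscillation_report")
}

#' Response metrics of a hyperpolarizing current step
#'
#' Measures, around one step of a recording: the pre-step resting potential
#' (spike-removed mean), the steady hyperpolarized potential (spike-removed
#' mean over the last 20 % of the step), the hyperpolarization depth, the sag
#' (early minimum relative to the steady state, reported as a nonnegative
#' magnitude), spikes during the step, the rebound burst rate over the 200 ms
#' after step offset, and the latent period from offset to the first rebound
#' spike.
#'
#' @param rec an `rgc_recording`
#' @param step list with `t_start`, `duration`, `amplitude` (defaults to the
#'   largest-amplitude step of the recording's protocol)
#' @param site recorded site
#' @return a list of class `rgc_step_metrics`
#' @export
step_response_metrics <- function(rec, step = NULL, site = "soma") {
  tr <- get_trace(rec, site)
  if (is.null(step)) {
    pr <- as.data.frame(rec$protocol)
    if (!nrow(pr)) stop("recording has no stimulus step")
    k <- which.max(abs(pr$amplitude))
    step <- as.list(pr[k, ])
  }
  t_on <- step$t_start
  t_off <- step$t_start + step$duration
  if (t_off > max(tr$time)) stop("step not contained in the recording")
  idx <- function(a, b) which(tr$time >= a & tr$time < b)
  pre <- idx(max(0, t_on - 10000), t_on)
  v_rest <- mean_vm_spike_removed(tr$v[pre], tr$dt,
                                  min_retained = min(1000, 0.8 * length(pre) * tr$dt))
  tail20 <- idx(t_off - 0.2 * step$duration, t_off)
  v_hyp <- mean_vm_spike_removed(tr$v[tail20], tr$dt, min_retained = 0)
  early <- idx(t_on, min(t_off, t_on + 200))
  sag <- max(0, v_hyp - min(tr$v[early]))
  train <- detect_spikes(tr$v, tr$dt, t0 = tr$time[1])
  st <- train$spike_times
  spikes_during <- sum(st >= t_on & st < t_off)
  rebound <- st[st >= t_off & st < t_off + 200]
  post <- st[st >= t_off]
  structure(list(v_rest = as.numeric(v_rest), v_hyp = as.numeric(v_hyp),
                 hyp_depth = as.numeric(v_rest) - as.numeric(v_hyp),
                 sag = sag, spikes_during_step = spikes_during,
                 rebound_burst_rate = length(rebound) / 0.2,
                 latent_period = if (length(post)) post[1] - t_off else NA_real_,
                 step = step),
            class = "rgc_step_metrics")
}

#' Somatic input resistance
#'
#' Primary (somatic) definition: the steady-state somatic voltage deflection
#' per unit current for a small hyperpolarizing probe step, using
#' spike-removed means over the last 500 ms of a 1000 ms baseline window and
#' of a 1000 ms probe window. The secondary (`"dendritic"`) mode probes at the
#' soma but measures the deflection at the first compartment of each primary
#' dendrite and averages the per-dendrite resistances.
#'
#' @param cell an [build_cell()] result
#' @param config a [simulation_config()]
#' @param probe probe amplitude, nA (default -0.01)
#' @param mode `"somatic"` or `"dendritic"`
#' @return MOhm
#' @export
input_resistance <- function(cell, config = simulation_config(),
                             probe = -0.01, mode = c("somatic", "dendritic")) {
  mode <- match.arg(mode)
  df <- as.data.frame(cell$morph)
  sites <- if (mode == "somatic") "soma" else {
    prim <- which(df$region == "dendrite" & df$parent_id == 1L)
    if (!length(prim)) stop("cell has no primary dendrites")
    prim
  }
  config$record_sites <- sites
  proto <- custom_protocol(data.frame(t_start = 1000, duration = 1000,
                                      amplitude = probe), tstop = 2000)
  rec <- simulate(cell, proto, config)
  r_of <- function(v) {
    i0 <- which(rec$time >= 500 & rec$time < 1000)
    i1 <- which(rec$time >= 1500 & rec$time < 2000)
    v0 <- mean_vm_spike_removed(v[i0], rec$dt, min_retained = 100)
    v1 <- mean_vm_spike_removed(v[i1], rec$dt, min_retained = 100)
    if (isTRUE(attr(v0, "warning")) || isTRUE(attr(v1, "warning")))
      stop("spike-removed measurement window too short for input resistance")
    (as.numeric(v1) - as.numeric(v0)) / probe
  }
  mean(apply(rec$v, 2, r_of))
}
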