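#' Sample a release-site layout for one active zone
#'
#' Places `n_sites` release-site centers inside a disc of radius
#' `az_radius_nm` by rejection sampling, enforcing a minimum
#' center-to-center separation. Coordinates are in nm relative to the
#' active-zone center.
#'
#' @param config a [generator_config()].
#' @param max_retries attempts before the packing is declared infeasible.
#' @return a list with `az_radius_nm` and `sites`, an `n_sites x 2`
#'   matrix of x/y coordinates in nm.
#' @export
sample_synapse_layout <- function(config, max_retries = 2000L) {
  r <- config$az_radius_nm
  k <- config$n_sites
  sep <- config$site_min_sep_nm
  for (attempt in seq_len(max_retries)) {
    ## uniform in disc via sqrt-radius transform
    u <- stats::runif(k)
    th <- stats::runif(k, 0, 2 * pi)
    pts <- cbind(x = r * sqrt(u) * cos(th), y = r * sqrt(u) * sin(th))
    if (k == 1L || min(stats::dist(pts)) >= sep)
      return(list(az_radius_nm = r, sites = pts))
  }
  stop(sprintf(paste0("infeasible release-site packing: %d sites with ",
                      "min separation %.0f nm in a disc of radius %.0f nm ",
                      "(no valid configuration in %d attempts)"),
               k, sep, r, max_retries))
}

#' Sample the stimulus-by-stimulus event schedule for one synapse
#'
#' For each of `n_stimuli` stimuli, draws at most one synchronous
#' release (probability `pr_true`), labelled MVR with probability
#' `p_mvr`, plus an independent asynchronous event with probability
#' `p_async` at a latency uniform in 0.1-0.9 of the stimulus interval.
#' Each event is assigned a release site (uniformly) and a true position
#' scattered isotropically around the site center with SD
#' `sigma_loc_nm`.
#'
#' @param config a [generator_config()].
#' @param layout output of [sample_synapse_layout()].
#' @return a data.frame with one row per event: `stim_index`, `site`,
#'   `is_mvr`, `synchronous`, `latency_s`, `t_s`, `x_true_nm`,
#'   `y_true_nm`, ordered by time. Zero rows when nothing is released.
#' @export
sample_event_schedule <- function(config, layout) {
  ns <- config$n_stimuli
  isi <- config$stim_interval_s
  sync_rel <- stats::runif(ns) < config$pr_true
  sync_mvr <- stats::runif(ns) < config$p_mvr
  async_rel <- stats::runif(ns) < config$p_async
  async_lat <- stats::runif(ns, 0.1 * isi, 0.9 * isi)

  idx_s <- which(sync_rel)
  idx_a <- which(async_rel)
  ev <- data.frame(
    stim_index = c(idx_s, idx_a),
    is_mvr = c(sync_mvr[idx_s], rep(FALSE, length(idx_a))),
    synchronous = rep(c(TRUE, FALSE), c(length(idx_s), length(idx_a))),
    latency_s = c(rep(0, length(idx_s)), async_lat[idx_a]))
  if (nrow(ev) == 0L) {
    ev$site <- integer(0); ev$t_s <- numeric(0)
    ev$x_true_nm <- numeric(0); ev$y_true_nm <- numeric(0)
    return(ev)
  }
  ev$site <- sample.int(config$n_sites, nrow(ev), replace = TRUE)
  ev$t_s <- (ev$stim_index - 1) * isi + ev$latency_s
  ev$x_true_nm <- layout$sites[ev$site, 1] +
    stats::rnorm(nrow(ev), 0, config$sigma_loc_nm)
  ev$y_true_nm <- layout$sites[ev$site, 2] +
    stats::rnorm(nrow(ev), 0, config$sigma_loc_nm)
  ev[order(ev$t_s), c("stim_index", "site", "is_mvr", "synchronous",
                      "latency_s", "t_s", "x_true_nm", "y_true_nm")]
}

## exponential truncated at `upper`, by inverse CDF (no rejection loop)
sample_trunc_exp <- function(n, mean, upper) {
  if (mean <= 0) return(rep(0, n))
  u <- stats::runif(n)
  -mean * log(1 - u * (1 - exp(-upper / mean)))
}

## normal truncated at 0 by resampling (sd << mean here, loop is rare)
rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Sample per-event kinetic ground truth
#'
#' Draws, for each scheduled event, the quantal amplitude (sum of one or
#' two quanta), the endocytic decay constant (ultrafast vs fast mode),
#' the dwell time, and the retrieval fraction with its category.
#'
#' The sampled `fraction` is the event's true retrieval fraction *as
#' measured at the end of the 1 s window*: the trace model's asymptotic
#' undershoot `f_model` is solved from it so that the noiseless trace
#' satisfies `(F(peak) - F(peak + 1 s)) / F(peak) = fraction` exactly.
#' This keeps generated category labels consistent with what the
#' analysis measures, for any decay constant and dwell time.
#'
#' @param is_mvr logical vector, one element per event.
#' @param config a [generator_config()].
#' @param window_s measurement window over which the retrieval fraction
#'   is defined (default 1 s, the inter-stimulus interval).
#' @return data.frame with columns `amplitude`, `n_quanta`, `tau_s`,
#'   `mode` ("ultrafast"/"fast"), `dwell_s`, `fraction`, `category`,
#'   `f_model`.
#' @export
sample_event_kinetics <- function(is_mvr, config, window_s = 1.0) {
  n <- length(is_mvr)
  lv <- retrieval_levels()
  if (n == 0L)
    return(data.frame(amplitude = numeric(0), n_quanta = integer(0),
                      tau_s = numeric(0), mode = character(0),
                      dwell_s = numeric(0), fraction = numeric(0),
                      category = character(0), f_model = numeric(0)))
  k <- ifelse(is_mvr, 2L, 1L)
  amp <- vapply(k, function(ki)
    sum(rnorm_pos(ki, config$q1, config$q_cv * config$q1)), 0.0)

  ultra <- stats::runif(n) < config$p_ultrafast
  tau_mean <- ifelse(ultra, config$tau_ultrafast_s, config$tau_fast_s)
  tau <- rnorm_pos(n, tau_mean, config$tau_cv * tau_mean)

  dwell <- sample_trunc_exp(n, config$dwell_mean_s, 0.5)

  iv <- retrieval_intervals()
  cat_idx <- sample.int(4L, n, replace = TRUE, prob = config$p_retrieval)
  category <- lv[cat_idx]
  lo <- vapply(category, function(cc) iv[[cc]][1], 0.0)
  hi <- vapply(category, function(cc) iv[[cc]][2], 0.0)
  fraction <- lo + stats::runif(n) * (hi - lo)
  fraction[category == "none"] <- 0

  ## attenuation of the asymptote visible within the finite window
  atten <- 1 - exp(-pmax(window_s - dwell, 0) / tau)
  f_model <- ifelse(category == "none", 0, fraction / atten)

  data.frame(amplitude = amp, n_quanta = k, tau_s = tau,
             mode = ifelse(ultra, "ultrafast", "fast"),
             dwell_s = dwell, fraction = fraction,
             category = factor(category, levels = lv),
             f_model = f_model)
}

#' Synthesize one event trace
#'
#' Noiseless model, with the event at t = 0:
#' `F(t) = 0` for `t < 0`; `F(t) = A` during the plateau
#' (`0 <= t < dwell`); afterwards
#' `F(t) = A * ((1 - f) + f * exp(-(t - dwell) / tau))`.
#' Additive Gaussian noise of SD `noise_sd` (in the same units as `A`)
#' is applied to every sample. `f > 1` drives the tail below baseline
#' (excessive retrieval); `f = 0` gives a flat plateau (no retrieval).
#'
#' @param amplitude peak amplitude `A` (> 0).
#' @param dwell_s plateau duration, seconds, in `[0, post_s)`.
#' @param tau_s decay constant, seconds (ignored when `f = 0`).
#' @param f model undershoot fraction: the asymptotic fractional drop of
#'   the decay component.
#' @param config a [generator_config()] (frame interval and noise SD).
#' @param n_pre number of baseline frames before the event.
#' @param post_s length of the post-event window, seconds (>= 1).
#' @param noise_sd overrides `config$noise_sd` when not `NULL`.
#' @return an object of class `event_trace`: list with `values`, `t_s`
#'   (time of each frame relative to the event), `frame_interval_s`,
#'   `event_index` (index of the t = 0 frame), `n_pre`.
#' @export
synthesize_trace <- function(amplitude, dwell_s, tau_s, f, config,
                             n_pre = 5L, post_s = 1.0, noise_sd = NULL) {
  if (amplitude <= 0) stop("amplitude must be > 0")
  if (post_s < 1.0 - 1e-12)
    stop("post-event window must cover at least 1 s (retrieval fraction ",
         "is defined at 1 s)")
  if (dwell_s < 0 || dwell_s >= post_s)
    stop("dwell_s must lie in [0, post_s)")
  dt <- config$frame_interval_s
  if (is.null(noise_sd)) noise_sd <- config$noise_sd
  t <- seq(-n_pre * dt, post_s + 1e-9, by = dt)
  vals <- event_model(t, amplitude, dwell_s, tau_s, f)
  if (noise_sd > 0) vals <- vals + stats::rnorm(length(vals), 0, noise_sd)
  structure(list(values = vals, t_s = t, frame_interval_s = dt,
                 event_index = n_pre + 1L, n_pre = as.integer(n_pre)),
            class = "event_trace")
}

## the noiseless plateau + exponential decay model, vectorized over t
event_model <- function(t, A, dwell, tau, f) {
  out <- numeric(length(t))
  plateau <- t >= 0 & t < dwell
  decay <- t >= dwell
  out[plateau] <- A
  if (f == 0) out[decay] <- A
  else out[decay] <- A * ((1 - f) + f * exp(-(t[decay] - dwell) / tau))
  out
}

#' @export
print.event_trace <- function(x, ...) {
  cat(sprintf("event_trace: %d frames @ %.0f ms (%d pre-event)\n",
              length(x$values), 1000 * x$frame_interval_s, x$n_pre))
  invisible(x)
}

#' Simulate a full synthetic dataset
#'
#' Composes layout, schedule, kinetics and trace synthesis over
#' `config$n_synapses` boutons. Each synapse consumes its own derived
#' RNG substream, so enlarging `n_synapses` does not perturb the
#' synapses already generated. Observed event coordinates are the true
#' positions plus isotropic Gaussian localization error
#' (`sigma_loc_nm`); observed amplitudes carry one frame's worth of
#' trace noise.
#'
#' @param config a [generator_config()].
#' @return an object of class `ph_dataset`: list with
#'   \describe{
#'     \item{events}{EventRecord table: `event_id`, `synapse_id`,
#'       `stim_index`, `t_s`, `x_nm`, `y_nm`, `amplitude`,
#'       `label_release` ("UVR"/"MVR"), `label_sync`
#'       ("synchronous"/"asynchronous").}
#'     \item{traces}{numeric matrix, one row per event, with attributes
#'       `frame_interval_s`, `event_index`, `n_pre`, `t_s`.}
#'     \item{truth}{ground-truth table aligned row-for-row with
#'       `events` (site id, true coordinates, amplitude, tau, mode,
#'       dwell, retrieval fraction/category, quanta count).}
#'     \item{layouts}{per-synapse list of site layouts.}
#'     \item{config}{the generating configuration.}
#'   }
#' @export
simulate_dataset <- function(config) {
  config <- validate_generator_config(config)
  per_syn <- vector("list", config$n_synapses)
  layouts <- vector("list", config$n_synapses)
  for (i in seq_len(config$n_synapses)) {
    set.seed(derive_seed(config$seed, i))
    layout <- sample_synapse_layout(config)
    sched <- sample_event_schedule(config, layout)
    kin <- sample_event_kinetics(sched$is_mvr, config,
                                 window_s = config$stim_interval_s)
    n <- nrow(sched)
    layouts[[i]] <- layout
    tr <- NULL
    if (n > 0) {
      tr <- t(vapply(seq_len(n), function(j) {
        synthesize_trace(kin$amplitude[j], kin$dwell_s[j], kin$tau_s[j],
                         kin$f_model[j], config)$values
      }, numeric(trace_length(config))))
    }
    obs_x <- sched$x_true_nm + stats::rnorm(n, 0, config$sigma_loc_nm)
    obs_y <- sched$y_true_nm + stats::rnorm(n, 0, config$sigma_loc_nm)
    obs_amp <- kin$amplitude + stats::rnorm(n, 0, config$noise_sd)
    per_syn[[i]] <- list(
      events = data.frame(
        synapse_id = rep(i, n), stim_index = sched$stim_index,
        t_s = sched$t_s, x_nm = obs_x, y_nm = obs_y,
        amplitude = obs_amp,
        label_release = ifelse(sched$is_mvr, "MVR", "UVR"),
        label_sync = ifelse(sched$synchronous, "synchronous",
                            "asynchronous")),
      truth = cbind(data.frame(synapse_id = rep(i, n),
                               site = sched$site,
                               x_true_nm = sched$x_true_nm,
                               y_true_nm = sched$y_true_nm,
                               latency_s = sched$latency_s),
                    kin),
      traces = tr)
  }
  events <- do.call(rbind, lapply(per_syn, `[[`, "events"))
  truth <- do.call(rbind, lapply(per_syn, `[[`, "truth"))
  traces <- do.call(rbind, lapply(per_syn, `[[`, "traces"))
  if (is.null(events)) {
    events <- data.frame(synapse_id = integer(0), stim_index = integer(0),
                         t_s = numeric(0), x_nm = numeric(0),
                         y_nm = numeric(0), amplitude = numeric(0),
                         label_release = character(0),
                         label_sync = character(0))
    truth <- truth[0, , drop = FALSE]
  }
  n_ev <- nrow(events)
  events <- cbind(data.frame(event_id = seq_len(n_ev)), events)
  rownames(events) <- rownames(truth) <- NULL
  if (is.null(traces)) traces <-
      matrix(numeric(0), 0, trace_length(config))
  dt <- config$frame_interval_s
  n_pre <- 5L
  attr(traces, "frame_interval_s") <- dt
  attr(traces, "event_index") <- n_pre + 1L
  attr(traces, "n_pre") <- n_pre
  attr(traces, "t_s") <- seq(-n_pre * dt, 1.0 + 1e-9, by = dt)
  structure(list(events = events, traces = traces, truth = truth,
                 layouts = layouts, config = config),
            class = "ph_dataset")
}

trace_length <- function(config, n_pre = 5L, post_s = 1.0) {
  length(seq(-n_pre * config$frame_interval_s, post_s + 1e-9,
             by = config$frame_interval_s))
}

#' Extract one row of a trace matrix as an `event_trace`
#'
#' @param traces trace matrix from [simulate_dataset()].
#' @param i row index.
#' @return an `event_trace`.
#' @export
trace_row <- function(traces, i) {
  if (is.null(attr(traces, "frame_interval_s")))
    stop("trace matrix lacks its metadata attributes; subset trace ",
         "matrices with subset_traces(), not `[`")
  structure(list(values = traces[i, ],
                 t_s = attr(traces, "t_s"),
                 frame_interval_s = attr(traces, "frame_interval_s"),
                 event_index = attr(traces, "event_index"),
                 n_pre = attr(traces, "n_pre")),
            class = "event_trace")
}

#' Subset a trace matrix, preserving its metadata attributes
#'
#' @param traces trace matrix from [simulate_dataset()].
#' @param idx row (event) indices or logical mask.
#' @return trace matrix with the same attributes.
#' @export
subset_traces <- function(traces, idx) {
  out <- traces[idx, , drop = FALSE]
  for (a in c("frame_interval_s", "event_index", "n_pre", "t_s"))
    attr(out, a) <- attr(traces, a)
  out
}

#' @export
print.ph_dataset <- function(x, ...) {
  cat(sprintf("ph_dataset: %d synapses, %d events (seed %d)\n",
              x$config$n_synapses, nrow(x$events), x$config$seed))
  invisible(x)
}

#' Simulate a whole-synapse train response
#'
#' Linear superposition model of the average bouton fluorescence during
#' a high-frequency action-potential train: each AP releases with
#' probability `pr_true` (independently per synapse), contributing its
#' quantal amplitude decaying with a sampled endocytic time constant.
#' The returned trace is the average over `config$n_synapses` boutons.
#' Release decisions are made by thresholding a common uniform draw
#' against `pr_true`, so traces simulated at increasing `pr_true` under
#' the same seed are coupled (common random numbers).
#'
#' @param config a [generator_config()].
#' @param rate_hz stimulation rate of the train.
#' @param n_ap number of action potentials.
#' @param post_s extra time simulated after the last AP.
#' @return list with `t_s` and `dff` (mean fluorescence, q1 units).
#' @export
simulate_train_response <- function(config, rate_hz, n_ap,
                                    post_s = 2.0) {
  stopifnot(rate_hz > 0, n_ap >= 1)
  set.seed(derive_seed(config$seed, 999983L))
  dt <- config$frame_interval_s
  ap_times <- (seq_len(n_ap) - 1) / rate_hz
  t <- seq(0, max(ap_times) + post_s, by = dt)
  acc <- numeric(length(t))
  for (s in seq_len(config$n_synapses)) {
    u_rel <- stats::runif(n_ap)
    u_mvr <- stats::runif(n_ap)
    rel <- u_rel < config$pr_true
    if (!any(rel)) next
    idx <- which(rel)
    k <- ifelse(u_mvr[idx] < config$p_mvr, 2L, 1L)
    amp <- vapply(k, function(ki)
      sum(rnorm_pos(ki, config$q1, config$q_cv * config$q1)), 0.0)
    ultra <- stats::runif(length(idx)) < config$p_ultrafast
    tm <- ifelse(ultra, config$tau_ultrafast_s, config$tau_fast_s)
    tau <- rnorm_pos(length(idx), tm, config$tau_cv * tm)
    for (j in seq_along(idx)) {
      dtj <- t - ap_times[idx[j]]
      on <- dtj >= 0
      acc[on] <- acc[on] + amp[j] * exp(-dtj[on] / tau[j])
    }
  }
  list(t_s = t, dff = acc / max(1L, config$n_synapses))
}
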