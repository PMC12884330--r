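## Integrated Gaussian PSF: expected photons per pixel for a spot of
## `photons` total at (x0, y0) (pixel-center coordinates, pixel i
## centered at i * pixel_size). Proper pixel integration via erf
## differences, so photons are conserved.
psf_pixel_counts <- function(xs_px, ys_px, x0_px, y0_px, sigma_px,
                             photons) {
  cx <- stats::pnorm(xs_px + 0.5, x0_px, sigma_px) -
    stats::pnorm(xs_px - 0.5, x0_px, sigma_px)
  cy <- stats::pnorm(ys_px + 0.5, y0_px, sigma_px) -
    stats::pnorm(ys_px - 0.5, y0_px, sigma_px)
  photons * outer(cy, cx)           # rows = y, cols = x
}

#' Render isolated fluorescent spots
#'
#' Renders `n_spots` single-frame spots (one spot per frame, centered
#' within +/- 1 pixel of the field center at a random subpixel
#' position) under the camera model of [optics_config()]: integrated
#' Gaussian PSF, Poisson shot noise on signal + background, Gaussian
#' read noise. Used for localization-precision calibration.
#'
#' @param n_spots number of spots (= frames).
#' @param optics an [optics_config()].
#' @param amplitude_quanta spot brightness in quantal units; total
#'   photons are `amplitude_quanta * photons_per_quantum`.
#' @param roi_px square field side, pixels.
#' @param poisson disable to render noiseless expectations.
#' @return list: `stack` (`roi_px x roi_px x n_spots`), `truth`
#'   data.frame with `x_nm`, `y_nm`, `photons` (0-based pixel-center
#'   coordinate convention: pixel i is centered at `i * pixel_size_nm`).
#' @export
render_spots <- function(n_spots, optics, amplitude_quanta = 1,
                         roi_px = 15L, poisson = TRUE) {
  sig_px <- optics$psf_sigma_nm / optics$pixel_size_nm
  ctr <- (roi_px - 1) / 2
  xs <- 0:(roi_px - 1)
  stack <- array(0, c(roi_px, roi_px, n_spots))
  x0 <- ctr + stats::runif(n_spots, -1, 1)
  y0 <- ctr + stats::runif(n_spots, -1, 1)
  photons <- amplitude_quanta * optics$photons_per_quantum
  for (i in seq_len(n_spots)) {
    mu <- psf_pixel_counts(xs, xs, x0[i], y0[i], sig_px, photons) +
      optics$background_photons_per_pixel
    frame <- if (poisson) {
      matrix(stats::rpois(length(mu), mu), nrow(mu))
    } else mu
    if (optics$read_noise_e > 0 && poisson)
      frame <- frame + stats::rnorm(length(mu), 0, optics$read_noise_e)
    stack[, , i] <- frame
  }
  list(stack = stack,
       truth = data.frame(x_nm = x0 * optics$pixel_size_nm,
                          y_nm = y0 * optics$pixel_size_nm,
                          photons = photons))
}

#' Render a synthetic dataset as an image stack
#'
#' Places each simulated synapse on a square grid inside the field
#' (with a 3-PSF margin) and renders every frame of the recording: a
#' constant background plus, for each event, an integrated-Gaussian PSF
#' scaled by `photons_per_quantum * F(t)` where `F(t)` is the event's
#' noiseless fluorescence model. Negative `F(t)` (the sub-baseline
#' undershoot of excessive retrieval) cannot be represented by an
#' additive photon model without a resting-fluorescence component and
#' is clipped to zero contribution. Poisson shot noise is applied to
#' signal + background, then Gaussian read noise. Values are clipped to
#' the 16-bit range with a warning when they saturate.
#'
#' @param dataset a `ph_dataset` from [simulate_dataset()].
#' @param optics an [optics_config()]; `field_px` must fit all synapses
#'   plus a 3-PSF margin.
#' @param poisson disable to render noiseless expectations.
#' @param pre_frames baseline frames rendered before the first stimulus
#'   (default 12, enough for the running-median baseline window).
#' @return list: `stack` (array, counts), `sidecar` data.frame mapping
#'   every event to its frame and pixel-truth coordinates (`event_id`,
#'   `frame`, `x_nm`, `y_nm` in field coordinates), `synapse_origins_nm`,
#'   `clipped` flag, `optics`, `frame_interval_s`.
#' @export
render_movie <- function(dataset, optics, poisson = TRUE,
                         pre_frames = 12L) {
  cfg <- dataset$config
  set.seed(derive_seed(cfg$seed, 424243L))
  px <- optics$pixel_size_nm
  sig_px <- optics$psf_sigma_nm / px
  margin_nm <- 3 * optics$psf_sigma_nm + cfg$az_radius_nm
  n_syn <- cfg$n_synapses
  grid_n <- ceiling(sqrt(max(1L, n_syn)))
  field_nm <- (optics$field_px - 1) * px
  pitch <- (field_nm - 2 * margin_nm) / max(1, grid_n - 1)
  if (grid_n > 1 && pitch < 2 * margin_nm ||
      field_nm < 2 * margin_nm)
    stop("field too small for ", n_syn, " synapses plus a 3-PSF margin; ",
         "increase optics$field_px")
  gi <- (seq_len(n_syn) - 1) %% grid_n
  gj <- (seq_len(n_syn) - 1) %/% grid_n
  ox <- margin_nm + gi * if (grid_n > 1) pitch else 0
  oy <- margin_nm + gj * if (grid_n > 1) pitch else 0

  dt <- cfg$frame_interval_s
  n_frames <- ceiling(cfg$n_stimuli * cfg$stim_interval_s / dt) + 1L +
    pre_frames
  np <- optics$field_px
  xs <- 0:(np - 1)
  ev <- dataset$events
  tru <- dataset$truth
  ex_nm <- ox[ev$synapse_id] + tru$x_true_nm
  ey_nm <- oy[ev$synapse_id] + tru$y_true_nm
  ev_frame <- floor(ev$t_s / dt + 1e-9) + 1L + pre_frames

  stack <- array(optics$background_photons_per_pixel, c(np, np, n_frames))
  half <- ceiling(4 * sig_px)
  for (k in seq_len(nrow(ev))) {
    xp <- ex_nm[k] / px
    yp <- ey_nm[k] / px
    cx <- round(xp); cy <- round(yp)
    xr <- max(0, cx - half):min(np - 1, cx + half)
    yr <- max(0, cy - half):min(np - 1, cy + half)
    t_ev <- ev$t_s[k]
    f0 <- ev_frame[k]
    f1 <- min(n_frames, f0 + ceiling(1.0 / dt))
    tt <- (seq(f0, f1) - 1 - pre_frames) * dt - t_ev
    fvals <- event_model(tt, tru$amplitude[k], tru$dwell_s[k],
                         tru$tau_s[k], tru$f_model[k])
    for (j in seq_along(tt)) {
      if (fvals[j] <= 0) next
      add <- psf_pixel_counts(xr, yr, xp, yp, sig_px,
                              optics$photons_per_quantum * fvals[j])
      stack[yr + 1, xr + 1, f0 + j - 1] <-
        stack[yr + 1, xr + 1, f0 + j - 1] + add
    }
  }
  if (poisson) {
    stack[] <- stats::rpois(length(stack), stack)
    if (optics$read_noise_e > 0)
      stack[] <- stack + stats::rnorm(length(stack), 0,
                                      optics$read_noise_e)
  }
  clipped <- any(stack > 65535)
  if (clipped) {
    warning("rendered stack saturates the 16-bit range; clipping")
    stack[stack > 65535] <- 65535
  }
  stack[stack < 0] <- 0
  list(stack = stack,
       sidecar = data.frame(event_id = ev$event_id, frame = ev_frame,
                            x_nm = ex_nm, y_nm = ey_nm,
                            amplitude = tru$amplitude),
       synapse_origins_nm = cbind(x = ox, y = oy),
       clipped = clipped, optics = optics, frame_interval_s = dt)
}
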