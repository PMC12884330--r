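#' Generator configuration for synthetic single-vesicle experiments
#'
#' Builds and validates the parameter set that defines one simulated
#' pHluorin experiment: a field of boutons stimulated at 1 Hz for 200 s,
#' imaged at 50 ms/frame, releasing single vesicles (UVR) or pairs (MVR)
#' at clustered release sites inside a disc-shaped active zone, each
#' event followed by plateau + exponential endocytic decay.
#'
#' Defaults encode the baseline ("control") condition: quantal amplitude
#' `q1 = 1` with `q2 = 2*q1` for MVR, decay constants ~100 ms
#' (ultrafast, 20% of events) and ~500 ms (fast, 80%), retrieval-
#' fraction category weights 35% partial / 38% quantal / 24% excessive /
#' 3% none, and ~20 nm localization scatter.
#'
#' @param n_synapses number of boutons to simulate.
#' @param n_stimuli number of 1-AP stimuli (default 200).
#' @param stim_interval_s inter-stimulus interval in seconds (default 1).
#' @param frame_interval_s camera frame interval in seconds (default 0.050).
#' @param pr_true per-stimulus probability of a synchronous release event.
#' @param p_mvr probability that a synchronous event is multivesicular.
#' @param q1 quantal amplitude of one vesicle, arbitrary fluorescence units.
#' @param q_cv coefficient of variation of a single quantum.
#' @param p_ultrafast probability that an event decays with the ultrafast
#'   time constant rather than the fast one.
#' @param tau_ultrafast_s,tau_fast_s mean decay constants of the two
#'   endocytic modes, seconds (defaults 0.100 and 0.500).
#' @param tau_cv relative SD of the decay constant within a mode.
#' @param dwell_mean_s mean of the exponential dwell-time (plateau)
#'   distribution, seconds; truncated at 0.5 s.
#' @param p_retrieval length-4 probability vector over retrieval
#'   categories, in the order partial, quantal, excessive, none.
#' @param sigma_loc_nm isotropic SD of event-position scatter, nm. Applied
#'   both as biological scatter around the release-site center and as
#'   localization error on the observed coordinates.
#' @param az_radius_nm radius of the disc containing the release sites.
#' @param n_sites number of release sites per active zone.
#' @param site_min_sep_nm minimum center-to-center site separation, nm.
#' @param noise_sd additive Gaussian noise SD on traces, in q1 units.
#' @param p_async probability of an asynchronous event per stimulus.
#' @param seed integer seed; every random draw in the simulation derives
#'   from it.
#' @return an object of class `generator_config` (a validated list).
#' @seealso [simulate_dataset()], [apply_condition_map()]
#' @export
generator_config <- function(n_synapses = 20L,
                             n_stimuli = 200L,
                             stim_interval_s = 1.0,
                             frame_interval_s = 0.050,
                             pr_true = 0.3,
                             p_mvr = 0.1,
                             q1 = 1.0,
                             q_cv = 0.1,
                             p_ultrafast = 0.2,
                             tau_ultrafast_s = 0.100,
                             tau_fast_s = 0.500,
                             tau_cv = 0.2,
                             dwell_mean_s = 0.100,
                             p_retrieval = c(partial = 0.35, quantal = 0.38,
                                             excessive = 0.24, none = 0.03),
                             sigma_loc_nm = 20,
                             az_radius_nm = 150,
                             n_sites = 8L,
                             site_min_sep_nm = 60,
                             noise_sd = 0.1,
                             p_async = 0.05,
                             seed = 1L) {
  cfg <- list(
    n_synapses = as.integer(n_synapses), n_stimuli = as.integer(n_stimuli),
    stim_interval_s = stim_interval_s, frame_interval_s = frame_interval_s,
    pr_true = pr_true, p_mvr = p_mvr, q1 = q1, q_cv = q_cv,
    p_ultrafast = p_ultrafast, tau_ultrafast_s = tau_ultrafast_s,
    tau_fast_s = tau_fast_s, tau_cv = tau_cv, dwell_mean_s = dwell_mean_s,
    p_retrieval = p_retrieval, sigma_loc_nm = sigma_loc_nm,
    az_radius_nm = az_radius_nm, n_sites = as.integer(n_sites),
    site_min_sep_nm = site_min_sep_nm, noise_sd = noise_sd,
    p_async = p_async, seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

#' @rdname generator_config
#' @param cfg a `generator_config` to validate.
#' @export
validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  probs <- c(pr_true = cfg$pr_true, p_mvr = cfg$p_mvr,
             p_ultrafast = cfg$p_ultrafast, p_async = cfg$p_async)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1 | !is.finite(probs)],
               collapse = ", "))
  pr <- cfg$p_retrieval
  if (length(pr) != 4L || any(pr < 0) || any(pr > 1))
    stop("p_retrieval must be a length-4 probability vector")
  if (abs(sum(pr) - 1) > 1e-9)
    stop("p_retrieval must sum to 1 (got ", format(sum(pr)), ")")
  if (is.null(names(pr))) names(cfg$p_retrieval) <-
      c("partial", "quantal", "excessive", "none")
  if (!(cfg$tau_ultrafast_s < cfg$tau_fast_s))
    stop("tau_ultrafast_s must be smaller than tau_fast_s")
  if (!(cfg$frame_interval_s < cfg$stim_interval_s))
    stop("frame_interval_s must be smaller than stim_interval_s")
  if (cfg$sigma_loc_nm < 0) stop("sigma_loc_nm must be >= 0")
  if (cfg$site_min_sep_nm <= 0) stop("site_min_sep_nm must be > 0")
  pos <- c(q1 = cfg$q1, tau_ultrafast_s = cfg$tau_ultrafast_s,
           stim_interval_s = cfg$stim_interval_s,
           frame_interval_s = cfg$frame_interval_s,
           az_radius_nm = cfg$az_radius_nm)
  if (any(pos <= 0)) stop("strictly positive required: ",
                          paste(names(pos)[pos <= 0], collapse = ", "))
  if (cfg$n_sites < 1L) stop("n_sites must be >= 1")
  if (cfg$n_synapses < 0L || cfg$n_stimuli < 1L)
    stop("n_synapses must be >= 0 and n_stimuli >= 1")
  if (cfg$q_cv < 0 || cfg$tau_cv < 0 || cfg$noise_sd < 0 ||
      cfg$dwell_mean_s < 0)
    stop("q_cv, tau_cv, noise_sd and dwell_mean_s must be >= 0")
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat("generator_config:",
      x$n_synapses, "synapses,", x$n_stimuli, "stimuli @",
      1 / x$stim_interval_s, "Hz,",
      sprintf("Pr=%.3g, p_mvr=%.3g, p_ultrafast=%.3g, seed=%d",
              x$pr_true, x$p_mvr, x$p_ultrafast, x$seed), "\n")
  invisible(x)
}

#' Optics configuration for movie rendering
#'
#' Imaging model used by [render_movie()]: a 150x/1.45NA near-TIRF
#' system with a back-illuminated EMCCD (13 um pixels, so 86.7 nm in the
#' sample plane), a Gaussian PSF, Poisson shot noise on signal plus
#' background, and additive Gaussian read noise.
#'
#' @param pixel_size_nm sample-plane pixel size (default 86.7 nm =
#'   13 um camera pixel / 150x magnification).
#' @param psf_sigma_nm Gaussian PSF standard deviation (default 130 nm).
#' @param photons_per_quantum detected photons per frame for one quantal
#'   unit of fluorescence (default 2000).
#' @param background_photons_per_pixel mean background per pixel per
#'   frame (default 50).
#' @param read_noise_e Gaussian read noise SD in counts (default 1).
#' @param field_px field width/height in pixels (square field).
#' @param n_frames number of frames when rendering a fixed-length stack.
#' @return an object of class `optics_config`.
#' @export
optics_config <- function(pixel_size_nm = 86.7,
                          psf_sigma_nm = 130,
                          photons_per_quantum = 2000,
                          background_photons_per_pixel = 50,
                          read_noise_e = 1.0,
                          field_px = 32L,
                          n_frames = 40L) {
  oc <- list(pixel_size_nm = pixel_size_nm, psf_sigma_nm = psf_sigma_nm,
             photons_per_quantum = photons_per_quantum,
             background_photons_per_pixel = background_photons_per_pixel,
             read_noise_e = read_noise_e, field_px = as.integer(field_px),
             n_frames = as.integer(n_frames))
  vals <- unlist(oc[1:5])
  if (any(!is.finite(vals)) || any(vals <= 0) && read_noise_e < 0)
    stop("optics parameters must be finite")
  if (any(unlist(oc[c(1, 2, 3, 4)]) <= 0))
    stop("optics parameters must be strictly positive")
  if (oc$read_noise_e < 0) stop("read_noise_e must be >= 0")
  if (!(oc$psf_sigma_nm > oc$pixel_size_nm / 4))
    stop("psf_sigma_nm must exceed pixel_size_nm/4 (undersampled PSF)")
  class(oc) <- "optics_config"
  oc
}

## Retrieval-fraction category intervals. Only the 0.8/1.2 cut points are
## biologically anchored; the outer limits bound the generator's draws.
retrieval_intervals <- function() {
  list(partial = c(0.3, 0.8), quantal = c(0.8, 1.2),
       excessive = c(1.2, 1.6), none = c(0, 0))
}

retrieval_levels <- function() c("partial", "quantal", "excessive", "none")

## Derive a bounded child seed from (seed, index) without consuming RNG
## state. Keeps results stable when n_synapses changes.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %%
               2147483647)
}
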