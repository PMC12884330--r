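#' Detection parameters
#'
#' @param baseline_window_frames frames used for the running-median
#'   baseline (default 10).
#' @param threshold_k detection threshold in multiples of the robust
#'   per-frame noise SD (default 5: at 4 the Gaussian tail alone yields
#'   of order 0.1 false maxima per 2k-pixel frame, i.e. tens of spurious
#'   events over a 200 s movie).
#' @param min_separation_px non-maximum suppression radius (default 3).
#' @param roi_halfwidth_px half-width of the fitting ROI (default 4).
#' @return a validated `detection_params` list.
#' @export
detection_params <- function(baseline_window_frames = 10L,
                             threshold_k = 5,
                             min_separation_px = 3L,
                             roi_halfwidth_px = 4L) {
  p <- list(baseline_window_frames = as.integer(baseline_window_frames),
            threshold_k = threshold_k,
            min_separation_px = as.integer(min_separation_px),
            roi_halfwidth_px = as.integer(roi_halfwidth_px))
  if (any(unlist(p) <= 0)) stop("all detection parameters must be positive")
  if (p$roi_halfwidth_px < 2L) stop("roi_halfwidth_px must be >= 2")
  class(p) <- "detection_params"
  p
}

#' Running-median baseline subtraction (delta-F stack)
#'
#' Each output frame is the input frame minus the per-pixel median of
#' the preceding `baseline_window_frames` frames. The first window
#' frames, which have no full baseline, are emitted as zeros and listed
#' in the `flagged_frames` attribute.
#'
#' @param stack array `height x width x frames`.
#' @param baseline_window_frames baseline window length.
#' @return delta-F array of the same dimensions, with attribute
#'   `flagged_frames`.
#' @export
compute_delta_frames <- function(stack, baseline_window_frames = 10L) {
  d <- dim(stack)
  w <- as.integer(baseline_window_frames)
  if (length(d) != 3 || d[3] <= w)
    stop("stack must have more than baseline_window_frames frames")
  out <- array(0, d)
  npix <- d[1] * d[2]
  flat <- matrix(stack, npix, d[3])
  for (f in (w + 1L):d[3]) {
    base <- matrixStats_rowMedians(flat[, (f - w):(f - 1L), drop = FALSE])
    out[, , f] <- flat[, f] - base
  }
  attr(out, "flagged_frames") <- seq_len(w)
  out
}

matrixStats_rowMedians <- function(m) {
  if (requireNamespace("matrixStats", quietly = TRUE))
    matrixStats::rowMedians(m)
  else apply(m, 1, stats::median)
}

## 2D convolution by shift-and-add with edge replication
conv2_replicate <- function(img, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  ch <- (kh + 1L) %/% 2L; cw <- (kw + 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  pad_r <- function(i) pmin(pmax(i, 1L), h)
  pad_c <- function(j) pmin(pmax(j, 1L), w)
  out <- matrix(0, h, w)
  for (a in seq_len(kh)) for (b in seq_len(kw)) {
    k <- kernel[a, b]
    if (k == 0) next
    out <- out + k * img[pad_r(seq_len(h) + a - ch),
                         pad_c(seq_len(w) + b - cw)]
  }
  out
}

## negated Laplacian-of-Gaussian kernel at the PSF scale: positive
## response on PSF-sized bright blobs
log_kernel <- function(sigma_px) {
  half <- max(3L, ceiling(3 * sigma_px))
  g <- -half:half
  xx <- outer(rep(1, length(g)), g)
  yy <- t(xx)
  r2 <- xx^2 + yy^2
  k <- -(r2 - 2 * sigma_px^2) / sigma_px^4 *
    exp(-r2 / (2 * sigma_px^2))
  k - mean(k)                       # zero-sum: flat background rejected
}

#' Detect candidate fusion events in a delta-F stack
#'
#' Band-pass filters every frame with a Laplacian-of-Gaussian kernel at
#' the PSF scale, thresholds at `threshold_k` times the per-frame robust
#' noise SD (1.4826 x MAD) of the filtered frame, keeps local maxima,
#' and applies greedy non-maximum suppression at `min_separation_px`.
#' A candidate is reported only on the first frame after its intensity
#' step: locations already above threshold in the previous filtered
#' frame are suppressed (events persist for many frames while the
#' pHluorin signal decays; they are single fusions, not tracks).
#'
#' @param delta_stack output of [compute_delta_frames()].
#' @param params a [detection_params()].
#' @param psf_sigma_px PSF sigma in pixels (filter scale).
#' @return data.frame of candidates: `frame`, `x_px`, `y_px` (0-based
#'   pixel indices), `response`.
#' @export
detect_candidates <- function(delta_stack, params = detection_params(),
                              psf_sigma_px = 1.5) {
  d <- dim(delta_stack)
  kern <- log_kernel(psf_sigma_px)
  skip <- attr(delta_stack, "flagged_frames")
  res <- list()
  prev_filt <- matrix(0, d[1], d[2])
  for (f in seq_len(d[3])) {
    if (!is.null(skip) && f %in% skip) next
    filt <- conv2_replicate(delta_stack[, , f], kern)
    noise <- stats::mad(filt)
    if (noise <= 0) { prev_filt <- filt; next }
    thr <- params$threshold_k * noise
    ## step criterion: report a fusion once, on its onset frame. The
    ## response must exceed the threshold and must have risen since the
    ## previous frame by at least half the threshold AND 40% of its own
    ## current value (shot noise on a bright plateau scales with the
    ## signal, not with the background-derived threshold)
    new_hot <- filt > thr &
      (filt - prev_filt) > pmax(thr / 2, 0.4 * filt)
    prev_filt <- filt
    cand <- which(new_hot, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    ## strict local maxima over the 8-neighborhood
    keep <- vapply(seq_len(nrow(cand)), function(i) {
      r <- cand[i, 1]; cc <- cand[i, 2]
      rr <- max(1, r - 1):min(d[1], r + 1)
      ccr <- max(1, cc - 1):min(d[2], cc + 1)
      filt[r, cc] >= max(filt[rr, ccr])
    }, TRUE)
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0) next
    vals <- filt[cand]
    ord <- order(vals, decreasing = TRUE)
    cand <- cand[ord, , drop = FALSE]
    vals <- vals[ord]
    sel <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (i == 1L) { sel[1] <- TRUE; next }
      prev <- cand[sel, , drop = FALSE]
      dist2 <- (prev[, 1] - cand[i, 1])^2 + (prev[, 2] - cand[i, 2])^2
      sel[i] <- all(dist2 >= params$min_separation_px^2)
    }
    cand <- cand[sel, , drop = FALSE]
    res[[length(res) + 1L]] <-
      data.frame(frame = f, x_px = cand[, 2] - 1L, y_px = cand[, 1] - 1L,
                 response = vals[sel])
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(frame = integer(0), x_px = integer(0),
                      y_px = integer(0), response = numeric(0))
  rownames(out) <- NULL
  out
}

#' Subpixel 2D-Gaussian localization of one spot
#'
#' Nonlinear least squares of
#' `offset + A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * sigma^2))`
#' over the ROI around a candidate, with `(x0, y0, sigma)` optimized and
#' `(A, offset)` profiled linearly. The localization precision is the
#' 1-SD parameter uncertainty from the residual-variance-scaled inverse
#' normal matrix of the full 5-parameter Jacobian, converted to nm.
#'
#' Coordinate convention: pixel `i` (0-based) is centered at
#' `i * pixel_size_nm`; `x_nm = x_px * pixel_size_nm` exactly.
#'
#' @param delta_frame 2D matrix (a delta-F frame, or a raw frame for
#'   isolated spots on a constant background).
#' @param candidate list or row with `x_px`, `y_px` (0-based).
#' @param params a [detection_params()].
#' @param pixel_size_nm sample-plane pixel size.
#' @return one-row data.frame (`spot_fit`): `x_nm`, `y_nm`, `x_px`,
#'   `y_px`, `amplitude`, `sigma_px`, `offset`, `precision_x_nm`,
#'   `precision_y_nm`, `converged`, `residual_rms`.
#' @export
fit_gaussian_spot <- function(delta_frame, candidate,
                              params = detection_params(),
                              pixel_size_nm = 86.7) {
  hw <- params$roi_halfwidth_px
  cx <- as.integer(round(candidate$x_px))
  cy <- as.integer(round(candidate$y_px))
  h <- nrow(delta_frame); w <- ncol(delta_frame)
  if (cx - hw < 0 || cy - hw < 0 || cx + hw > w - 1 || cy + hw > h - 1)
    stop("ROI extends beyond the frame edge")
  xr <- (cx - hw):(cx + hw)
  yr <- (cy - hw):(cy + hw)
  roi <- delta_frame[yr + 1, xr + 1]
  xx <- outer(rep(1, length(yr)), xr)
  yy <- outer(yr, rep(1, length(xr)))
  z <- as.vector(roi)
  xv <- as.vector(xx); yv <- as.vector(yy)

  sigma0 <- 1.5
  lin_fit <- function(e) {
    n <- length(z)
    see <- sum(e * e); se <- sum(e); sez <- sum(e * z); sz <- sum(z)
    det <- see * n - se * se
    if (abs(det) < 1e-12) return(NULL)
    A <- (n * sez - se * sz) / det
    off <- (see * sz - se * sez) / det
    list(A = A, off = off, sse = sum((z - A * e - off)^2))
  }
  obj <- function(p) {
    e <- exp(-((xv - p[1])^2 + (yv - p[2])^2) / (2 * exp(2 * p[3])))
    lf <- lin_fit(e)
    if (is.null(lf)) return(1e30)
    lf$sse
  }
  ## moment-based start refined by Nelder-Mead
  wpos <- pmax(z - stats::median(z), 0)
  if (sum(wpos) > 0) {
    x_start <- sum(wpos * xv) / sum(wpos)
    y_start <- sum(wpos * yv) / sum(wpos)
  } else { x_start <- cx; y_start <- cy }
  op <- stats::optim(c(x_start, y_start, log(sigma0)), obj,
                     method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
  x0 <- op$par[1]; y0 <- op$par[2]; sig <- exp(op$par[3])
  e <- exp(-((xv - x0)^2 + (yv - y0)^2) / (2 * sig^2))
  lf <- lin_fit(e)
  bad <- is.null(lf) || lf$A <= 0 || op$convergence != 0 ||
    sig <= 0.5 || sig >= 5 * sigma0 ||
    abs(x0 - cx) > hw || abs(y0 - cy) > hw
  prec <- c(NA_real_, NA_real_)
  rms <- NA_real_
  if (!is.null(lf)) {
    rms <- sqrt(lf$sse / length(z))
    J <- cbind(A = e,
               x0 = lf$A * e * (xv - x0) / sig^2,
               y0 = lf$A * e * (yv - y0) / sig^2,
               sig = lf$A * e * ((xv - x0)^2 + (yv - y0)^2) / sig^3,
               off = 1)
    dof <- max(1L, length(z) - 5L)
    cv <- tryCatch(solve(crossprod(J)) * lf$sse / dof,
                   error = function(err) NULL)
    if (is.null(cv)) bad <- TRUE
    else prec <- sqrt(pmax(diag(cv)[2:3], 0)) * pixel_size_nm
  }
  data.frame(x_nm = x0 * pixel_size_nm, y_nm = y0 * pixel_size_nm,
             x_px = x0, y_px = y0,
             amplitude = if (is.null(lf)) NA_real_ else lf$A,
             sigma_px = sig,
             offset = if (is.null(lf)) NA_real_ else lf$off,
             precision_x_nm = prec[1], precision_y_nm = prec[2],
             converged = !bad, residual_rms = rms)
}

#' Extract an event trace from an image stack
#'
#' Per-frame Gaussian-weighted ROI sum centered on the localized spot,
#' baseline-subtracted (median of the pre-event baseline window) and
#' optionally normalized to the detection-frame value. The weighted sum
#' of a constant background cancels after baseline subtraction, so the
#' extracted trace is proportional to the event's fluorescence model.
#'
#' @param stack raw image stack.
#' @param spot one-row `spot_fit` (needs `x_px`, `y_px`, `sigma_px`)
#'   plus a `frame` element giving the detection frame.
#' @param window_s post-event window to extract, seconds (>= 1 s needed
#'   downstream).
#' @param frame_interval_s frame interval, seconds.
#' @param params a [detection_params()] (baseline window, ROI size).
#' @param normalize divide by the detection-frame value.
#' @return an `event_trace`.
#' @export
extract_event_trace <- function(stack, spot, window_s = 1.0,
                                frame_interval_s = 0.050,
                                params = detection_params(),
                                normalize = FALSE) {
  d <- dim(stack)
  f0 <- spot$frame
  n_post <- ceiling(window_s / frame_interval_s)
  n_pre <- params$baseline_window_frames
  if (f0 + n_post > d[3])
    stop("post-event window truncated by the end of the stack")
  if (f0 - n_pre < 1)
    stop("baseline window truncated by the start of the stack")
  hw <- params$roi_halfwidth_px
  cx <- as.integer(round(spot$x_px)); cy <- as.integer(round(spot$y_px))
  xr <- max(0, cx - hw):min(d[2] - 1, cx + hw)
  yr <- max(0, cy - hw):min(d[1] - 1, cy + hw)
  wx <- exp(-((xr - spot$x_px)^2) / (2 * spot$sigma_px^2))
  wy <- exp(-((yr - spot$y_px)^2) / (2 * spot$sigma_px^2))
  wmat <- outer(wy, wx)
  wmat <- wmat / sum(wmat)
  frames <- (f0 - n_pre):(f0 + n_post)
  vals <- vapply(frames, function(f)
    sum(wmat * stack[yr + 1, xr + 1, f]), 0.0)
  base <- stats::median(vals[seq_len(n_pre)])
  vals <- vals - base
  if (normalize) {
    peak <- vals[n_pre + 1L]
    if (peak != 0) vals <- vals / peak
  }
  structure(list(values = vals,
                 t_s = (frames - f0) * frame_interval_s,
                 frame_interval_s = frame_interval_s,
                 event_index = n_pre + 1L, n_pre = as.integer(n_pre)),
            class = "event_trace")
}

#' Detect and localize all events in a stack
#'
#' Convenience composition: delta-F, candidate detection, per-candidate
#' Gaussian fits. Non-converged fits are kept in the table (flagged by
#' `converged = FALSE`) so that event counts reconcile, but should be
#' excluded from spatial statistics.
#'
#' @param stack raw image stack.
#' @param params a [detection_params()].
#' @param pixel_size_nm sample-plane pixel size.
#' @param psf_sigma_px filter scale in pixels.
#' @return data.frame: candidate columns plus the `spot_fit` columns.
#' @export
detect_events <- function(stack, params = detection_params(),
                          pixel_size_nm = 86.7, psf_sigma_px = 1.5) {
  delta <- compute_delta_frames(stack, params$baseline_window_frames)
  cands <- detect_candidates(delta, params, psf_sigma_px)
  fits <- lapply(seq_len(nrow(cands)), function(i) {
    fit <- tryCatch(
      fit_gaussian_spot(delta[, , cands$frame[i]], cands[i, ], params,
                        pixel_size_nm),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    cbind(frame = cands$frame[i], fit)
  })
  out <- do.call(rbind, fits)
  if (is.null(out))
    out <- cbind(frame = integer(0),
                 data.frame(x_nm = numeric(0), y_nm = numeric(0),
                            x_px = numeric(0), y_px = numeric(0),
                            amplitude = numeric(0), sigma_px = numeric(0),
                            offset = numeric(0),
                            precision_x_nm = numeric(0),
                            precision_y_nm = numeric(0),
                            converged = logical(0),
                            residual_rms = numeric(0)))
  rownames(out) <- NULL
  out
}
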