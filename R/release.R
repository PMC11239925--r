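## Presynaptic glutamate-release analysis.
##
## Traces come from iGluSnFR-style imaging: continuous acquisition at 20 Hz,
## evoked protocol of 20 field stimuli at 0.5 Hz. Release events are sharp
## fluorescence rises; an event is accepted when its baseline-subtracted
## amplitude exceeds k times the baseline noise SD (k = 7 by default).

#' Construct a trace set
#'
#' @param values synapse x frame numeric matrix (a.u.).
#' @param frame_rate imaging rate in Hz (> 0), default 20.
#' @param stim_frames strictly increasing 1-based stimulation frame indices,
#'   all below the number of frames.
#' @param roi_centers optional matrix of ROI centers (`x`, `y`, 0-based px).
#' @param roi_radius ROI radius in px (default 4, i.e. 700 nm).
#' @return list of class `trace_set`.
#' @export
trace_set <- function(values, frame_rate = 20, stim_frames = integer(0),
                      roi_centers = NULL, roi_radius = 4) {
  .assert(is.matrix(values), "values must be a synapse x frame matrix")
  .assert(frame_rate > 0, "frame_rate must be > 0")
  stim_frames <- as.integer(stim_frames)
  if (length(stim_frames)) {
    .assert(all(diff(stim_frames) > 0), "stim_frames must be strictly increasing")
    .assert(max(stim_frames) < ncol(values), "stim_frames must be < n_frames")
  }
  structure(list(values = values, frame_rate = frame_rate,
                 stim_frames = stim_frames, roi_centers = roi_centers,
                 roi_radius = roi_radius),
            class = "trace_set")
}

#' Detect active synapses in an image stack
#'
#' Active release sites appear as local maxima of the first temporal
#' derivative of the stack. The derivative is smoothed with a temporal
#' moving average and a spatial Gaussian, collapsed by taking the
#' per-pixel temporal maximum, and thresholded robustly
#' (median + `k_mad` * MAD); surviving strict local maxima at least
#' `roi_radius` px apart become ROI centers.
#'
#' @param stack numeric array `(frame, y, x)` with >= 2 frames.
#' @param roi_radius minimal separation of ROI centers, px.
#' @param smooth_frames temporal moving-average window (frames).
#' @param smooth_sigma_px spatial Gaussian sigma (px); 0 disables.
#' @param k_mad robust threshold multiplier.
#' @return matrix with columns `x`, `y` (0-based px), one row per ROI.
#' @export
detect_active_synapses <- function(stack, roi_radius = 4, smooth_frames = 3,
                                   smooth_sigma_px = 1, k_mad = 5) {
  dm <- dim(stack)
  .assert(length(dm) == 3, "stack must be a (frame, y, x) array")
  if (dm[1] < 2) stop("single-frame stack: temporal derivative undefined")
  nf <- dm[1] - 1; h <- dm[2]; w <- dm[3]
  d <- matrix(stack[-1, , ] - stack[-dm[1], , ], nf, h * w)
  if (smooth_frames > 1 && nf >= smooth_frames) {
    ker <- rep(1 / smooth_frames, smooth_frames)
    d <- apply(d, 2, function(v) as.numeric(stats::filter(v, ker, sides = 2)))
    d <- matrix(d, nf, h * w)
    d[is.na(d)] <- 0
  }
  if (smooth_sigma_px > 0) {
    for (f in seq_len(nf))
      d[f, ] <- as.numeric(EBImage::gblur(matrix(d[f, ], h, w),
                                          sigma = smooth_sigma_px))
  }
  m <- matrix(apply(d, 2, max), h, w)
  thr <- median(m) + k_mad * mad(m)
  # strict-ish 8-neighborhood local maxima above the threshold
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  is_max <- m > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[2:(h + 1) + dy, 2:(w + 1) + dx]
    is_max <- is_max & (m >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(cbind(x = numeric(0), y = numeric(0)))
  ord <- order(m[idx], decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(idx))) {
    if (!length(keep) ||
        all((idx[keep, 1] - idx[i, 1])^2 + (idx[keep, 2] - idx[i, 2])^2 >=
              roi_radius^2))
      keep <- c(keep, i)
  }
  cbind(x = idx[keep, 2] - 1, y = idx[keep, 1] - 1)
}

#' Extract mean-intensity ROI traces from a stack
#'
#' Each ROI is the disc of pixels whose center lies within `roi_radius` px of
#' the ROI center (49 pixels for the default radius of 4); the trace is the
#' per-frame mean over those pixels.
#'
#' @param stack numeric array `(frame, y, x)`.
#' @param roi_centers matrix of `x`, `y` 0-based pixel coordinates.
#' @param roi_radius disc radius, px; 0 gives the single center pixel.
#' @param frame_rate,stim_frames stored on the returned [trace_set()].
#' @param strict error (instead of warn + clip) when a disc crosses the
#'   image border.
#' @return a [trace_set()].
#' @export
extract_traces <- function(stack, roi_centers, roi_radius = 4,
                           frame_rate = 20, stim_frames = integer(0),
                           strict = FALSE) {
  dm <- dim(stack)
  .assert(length(dm) == 3, "stack must be a (frame, y, x) array")
  nf <- dm[1]; h <- dm[2]; w <- dm[3]
  off <- expand.grid(dx = -roi_radius:roi_radius, dy = -roi_radius:roi_radius)
  off <- off[off$dx^2 + off$dy^2 <= roi_radius^2, ]
  sm <- matrix(stack, nf)          # frames x (h * w), column-major over (y, x)
  n_roi <- nrow(roi_centers)
  values <- matrix(NA_real_, n_roi, nf)
  for (i in seq_len(n_roi)) {
    px <- roi_centers[i, 1] + off$dx
    py <- roi_centers[i, 2] + off$dy
    inside <- px >= 0 & px < w & py >= 0 & py < h
    if (!all(inside)) {
      if (strict) stop("ROI ", i, " touches the image border")
      warning("ROI ", i, " clipped at the image border")
      px <- px[inside]; py <- py[inside]
    }
    values[i, ] <- rowMeans(sm[, px * h + py + 1, drop = FALSE])
  }
  trace_set(values, frame_rate = frame_rate, stim_frames = stim_frames,
            roi_centers = roi_centers, roi_radius = roi_radius)
}

#' Detect release events in fluorescence traces
#'
#' Per trace, the baseline is a running median (window `baseline_window_s`);
#' the noise SD is the MAD (x 1.4826) of the residual, floored at a scaled
#' machine epsilon. Events are local peaks of the residual exceeding
#' `k_sigma` times the noise SD, with a one-frame refractory period.
#' Events falling exactly one frame after a stimulus are labeled
#' `"evoked-window"`, all others `"spontaneous"`.
#'
#' @param traces a [trace_set()] (or numeric matrix / vector).
#' @param k_sigma detection threshold in noise-SD units (default 7).
#' @param baseline_window_s running-median window, s.
#' @param frame_rate,stim_frames used when `traces` is a bare matrix.
#' @return data.frame of class `event_table` with columns `synapse_id`,
#'   `frame`, `amplitude`, `amplitude_sigma`, `kind`; attributes `n_frames`,
#'   `n_synapses`, `frame_rate`, `stim_frames`.
#' @export
detect_events <- function(traces, k_sigma = 7, baseline_window_s = 2,
                          frame_rate = 20, stim_frames = integer(0)) {
  .assert(k_sigma > 0, "k_sigma must be > 0")
  if (inherits(traces, "trace_set")) {
    frame_rate <- traces$frame_rate
    stim_frames <- traces$stim_frames
    traces <- traces$values
  }
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1)
  if (anyNA(traces)) stop("NaN/NA in traces")
  n <- ncol(traces)
  win <- round(baseline_window_s * frame_rate)
  win <- max(3, win + (win %% 2 == 0))       # odd running-median window
  .assert(n >= win, "trace shorter than the baseline window")
  evoked_frames <- stim_frames + 1L
  out <- vector("list", nrow(traces))
  for (s in seq_len(nrow(traces))) {
    v <- traces[s, ]
    resid <- v - stats::runmed(v, win)
    sigma <- mad(resid)
    sigma <- max(sigma, 1e3 * .Machine$double.eps * max(1, max(abs(v))))
    prev <- c(-Inf, resid[-n]); nxt <- c(resid[-1], -Inf)
    pk <- which(resid > k_sigma * sigma & resid >= prev & resid > nxt)
    if (length(pk) > 1) {                     # 1-frame refractory
      keep <- pk[1]
      for (f in pk[-1]) if (f - keep[length(keep)] > 1) keep <- c(keep, f)
      pk <- keep
    }
    if (length(pk))
      out[[s]] <- data.frame(
        synapse_id = s, frame = pk, amplitude = resid[pk],
        amplitude_sigma = resid[pk] / sigma,
        kind = ifelse(pk %in% evoked_frames, "evoked-window", "spontaneous"))
  }
  ev <- do.call(rbind, out)
  if (is.null(ev))
    ev <- data.frame(synapse_id = integer(0), frame = integer(0),
                     amplitude = numeric(0), amplitude_sigma = numeric(0),
                     kind = character(0))
  structure(ev, class = c("event_table", "data.frame"),
            n_frames = n, n_synapses = nrow(traces),
            frame_rate = frame_rate, stim_frames = stim_frames)
}

#' Per-synapse spontaneous event frequency
#'
#' Frequency is the event count divided by the acquisition duration
#' (5 min = 300 s by default). Pass a pre-filtered event table (e.g. only
#' `kind == "spontaneous"`) to exclude evoked-window events.
#'
#' @param events an `event_table` (or data.frame with `synapse_id`).
#' @param duration_s acquisition length, s (> 0).
#' @param synapse_ids synapses to report (zero-event synapses get 0 Hz);
#'   defaults to the table's `n_synapses` attribute.
#' @return data.frame `synapse_id`, `n_events`, `freq_hz`.
#' @export
spontaneous_frequency <- function(events, duration_s = 300,
                                  synapse_ids = NULL) {
  .assert(duration_s > 0, "duration_s must be > 0")
  if (is.null(synapse_ids))
    synapse_ids <- seq_len(attr(events, "n_synapses") %||%
                             max(events$synapse_id, 0))
  n <- table(factor(events$synapse_id, levels = synapse_ids))
  data.frame(synapse_id = synapse_ids, n_events = as.vector(n),
             freq_hz = as.vector(n) / duration_s)
}

#' Per-synapse evoked release probability
#'
#' A stimulus is counted as successful when at least one detected event falls
#' exactly one frame after the stimulus frame; the probability is the number
#' of successful stimuli divided by the total number of stimulations
#' (20 by default under the 20-stimuli 0.5 Hz protocol). Multiple events in
#' one window count once.
#'
#' @param events an `event_table`.
#' @param stim_frames 1-based stimulus frame indices (defaults to the
#'   table's attribute).
#' @param n_stimuli total stimulations (defaults to `length(stim_frames)`).
#' @param n_frames trace length, for window validation (defaults to the
#'   table's attribute).
#' @param synapse_ids synapses to report; defaults as in
#'   [spontaneous_frequency()].
#' @return data.frame `synapse_id`, `n_success`, `evoked_probability`.
#' @export
evoked_probability <- function(events, stim_frames = NULL, n_stimuli = NULL,
                               n_frames = NULL, synapse_ids = NULL) {
  stim_frames <- stim_frames %||% attr(events, "stim_frames")
  .assert(length(stim_frames) >= 1, "need at least one stimulus")
  n_stimuli <- n_stimuli %||% length(stim_frames)
  n_frames <- n_frames %||% attr(events, "n_frames")
  if (!is.null(n_frames) && any(stim_frames + 1 > n_frames))
    stop("stimulus at trace end: evoked window undefined")
  if (is.null(synapse_ids))
    synapse_ids <- seq_len(attr(events, "n_synapses") %||%
                             max(events$synapse_id, 0))
  inwin <- events[events$frame %in% (stim_frames + 1), , drop = FALSE]
  # one frame maps to one stimulus, so distinct frames = successful stimuli
  succ <- tapply(inwin$frame, factor(inwin$synapse_id, levels = synapse_ids),
                 function(f) length(unique(f)))
  succ[is.na(succ)] <- 0
  data.frame(synapse_id = synapse_ids, n_success = as.vector(succ),
             evoked_probability = as.vector(succ) / n_stimuli)
}

#' Gaussian kernel-density summary of a measurement distribution
#'
#' @param values >= 2 finite values with nonzero spread.
#' @param bandwidth_rule `"scott"` (default) or `"silverman"`.
#' @param n_grid evaluation grid size.
#' @return list with `x`, `y` (density grid), `bandwidth`, `integral`
#'   (trapezoidal, should be 1 within 1e-3) and `n`.
#' @export
kde_summary <- function(values, bandwidth_rule = c("scott", "silverman"),
                        n_grid = 512) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  v <- values[is.finite(values)]
  .assert(length(v) >= 2, "need >= 2 finite values")
  if (sd(v) == 0) stop("zero bandwidth: all values identical")
  bw <- if (bandwidth_rule == "scott") bw.nrd(v) else bw.nrd0(v)
  d <- density(v, bw = bw, n = n_grid)
  integral <- sum(diff(d$x) * (head(d$y, -1) + d$y[-1]) / 2)
  list(x = d$x, y = d$y, bandwidth = bw, integral = integral, n = length(v))
}

#' Fit a luminescence standard curve
#'
#' Ordinary least squares of luminescence (RLU) on concentration, as used to
#' convert secretion-assay readouts to glutamate concentrations; a log-log
#' variant is available for calibration series spanning several decades
#' (e.g. 100 uM down to 1.28e-3 uM).
#'
#' @param concentrations calibration concentrations, uM (>= 3 distinct).
#' @param rlu luminescence readouts, same length.
#' @param log_scale fit `log10(rlu) ~ log10(conc)` instead of the linear
#'   scale.
#' @return list of class `standard_curve` with `slope`, `intercept`,
#'   `r_squared`, `conc_range`, `rlu_range`, `log_scale`.
#' @export
fit_standard_curve <- function(concentrations, rlu, log_scale = FALSE) {
  .assert(length(concentrations) == length(rlu), "length mismatch")
  .assert(length(concentrations) >= 3, "need >= 3 calibration points")
  if (length(unique(concentrations)) < 2)
    stop("degenerate calibration: identical concentrations")
  xx <- if (log_scale) log10(concentrations) else concentrations
  yy <- if (log_scale) log10(rlu) else rlu
  fit <- lm(yy ~ xx)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((yy - mean(yy))^2)
  structure(list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = r2,
    conc_range = range(concentrations), rlu_range = range(rlu),
    log_scale = log_scale
  ), class = "standard_curve")
}

#' Interpolate concentrations from a standard curve
#'
#' Inverts the fitted line; values outside the calibrated RLU range are
#' returned with a warning (extrapolation).
#'
#' @param curve a [fit_standard_curve()] result.
#' @param rlu luminescence values to convert.
#' @return concentrations in uM.
#' @export
interpolate_concentration <- function(curve, rlu) {
  .assert(inherits(curve, "standard_curve"), "curve must be a standard_curve")
  outside <- rlu < curve$rlu_range[1] | rlu > curve$rlu_range[2]
  if (any(outside))
    warning(sum(outside), " value(s) outside the calibrated RLU range: extrapolating")
  if (curve$log_scale)
    10^((log10(rlu) - curve$intercept) / curve$slope)
  else
    (rlu - curve$intercept) / curve$slope
}
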