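#' Model configuration
#'
#' Collects every tunable parameter of the simulator in one list: the
#' retina pre-processing stage, the lobula orientation tuning curves and
#' edge-length scale factor, and the Kenyon-cell synaptic noise model.
#' Defaults reproduce the reference parameterization used throughout the
#' package; every experiment-level function accepts a `config` argument.
#'
#' @param binarize_threshold Green-channel cut (0--255 scale). Pixels with
#'   green value strictly below the cut are figure (black), others ground.
#' @param denoise Logical; apply a 3x3 median filter before binarization.
#' @param canny_sigma Gaussian blur sigma (pixels) for edge detection.
#' @param canny_low,canny_high Hysteresis thresholds as fractions of the
#'   maximum gradient magnitude in the image.
#' @param magnitude_threshold Weak-edge cut on Sobel gradient magnitude,
#'   computed on the 0--255 intensity scale. Edge pixels with magnitude
#'   less than or equal to the cut are discarded.
#' @param edge_filter Either `"magnitude"` (per-pixel magnitude rule,
#'   default) or `"segment"` (drop connected edge segments shorter than
#'   `segment_min_px`, the visual-acuity reading of the same rule).
#' @param segment_min_px Minimum connected segment length in pixels kept
#'   under `edge_filter = "segment"`. The default 9 px corresponds to a
#'   3 degree subtense for a 150 px pattern spanning roughly 48 degrees.
#' @param peak_A,peak_B Preferred orientations (degrees) of the type A and
#'   type B lobula neurons. Orientations live on [0, 180); 250 reduces to
#'   70.
#' @param hwhm Angular half-width at half-maximum (degrees) of the tuning
#'   curves. 45 corresponds to a full angular width at half-maximum of
#'   about 90 degrees.
#' @param rate_A,rate_B Peak firing rates (Hz) at the preferred
#'   orientation for a reference-length edge.
#' @param baseline Baseline firing rate (Hz); background rates are treated
#'   as already deducted, so the default is 0.
#' @param reference_length Edge length (pixels) at which the tuning curves
#'   are defined; the scale factor is 1 there.
#' @param scale_exponent Exponent alpha of the edge-length scale factor
#'   S(L) = (L / reference_length)^alpha. `NULL` (default) calibrates
#'   alpha in closed form from the type A curve so that a single vertical
#'   bar (600 px at 90, 200 px at 0) and a doubled pair of horizontal bars
#'   (1200 px at 0, 400 px at 90) produce exactly equal type A rates
#'   (see `length_scale`).
#' @param tuning_table Optional data frame (`degree`, `rate_A`, `rate_B`)
#'   replacing the parametric tuning curves by linear interpolation, e.g.
#'   a digitized recording.
#' @param scale_table Optional data frame (`length`, `factor`) replacing
#'   the parametric scale factor by monotone interpolation.
#' @param snr Signal-to-noise ratio of the per-synapse additive white
#'   Gaussian noise. Default 30, decibel semantics.
#' @param snr_mode `"db"` (noise sd = rate * 10^(-snr/20)) or `"linear"`
#'   (noise sd = rate / snr).
#' @param noise_mode `"collapsed"` (default; the sum of a cell's
#'   independent per-synapse draws is sampled from its exact Gaussian
#'   distribution with one draw per cell), `"synapse"` (literal
#'   independent draw per synapse), or `"shared"` (one draw per lobula
#'   neuron per trial, shared by every synapse reading it).
#' @param copies_per_config Kenyon-cell copies per wiring configuration
#'   and source region (30 gives populations of 10,320 / 5,160 cells).
#'
#' @return A list of class `"beekc_config"`.
#' @export
beekc_config <- function(binarize_threshold = 128,
                         denoise = TRUE,
                         canny_sigma = 1.0,
                         canny_low = 0.1,
                         canny_high = 0.2,
                         magnitude_threshold = 1.7,
                         edge_filter = c("magnitude", "segment"),
                         segment_min_px = 9,
                         peak_A = 115,
                         peak_B = 250,
                         hwhm = 45,
                         rate_A = 36,
                         rate_B = 36,
                         baseline = 0,
                         reference_length = 280,
                         scale_exponent = NULL,
                         tuning_table = NULL,
                         scale_table = NULL,
                         snr = 30,
                         snr_mode = c("db", "linear"),
                         noise_mode = c("collapsed", "synapse", "shared"),
                         copies_per_config = 30) {
  edge_filter <- match.arg(edge_filter)
  snr_mode <- match.arg(snr_mode)
  noise_mode <- match.arg(noise_mode)
  stopifnot(binarize_threshold >= 0, binarize_threshold <= 255,
            canny_sigma > 0, canny_low <= canny_high,
            magnitude_threshold >= 0, hwhm > 0,
            rate_A >= 0, rate_B >= 0, reference_length > 0,
            snr > 0, copies_per_config >= 1)
  cfg <- list(
    binarize_threshold = binarize_threshold,
    denoise = denoise,
    canny_sigma = canny_sigma,
    canny_low = canny_low,
    canny_high = canny_high,
    magnitude_threshold = magnitude_threshold,
    edge_filter = edge_filter,
    segment_min_px = segment_min_px,
    peak_A = peak_A %% 180,
    peak_B = peak_B %% 180,
    hwhm = hwhm,
    rate_A = rate_A,
    rate_B = rate_B,
    baseline = baseline,
    reference_length = reference_length,
    scale_exponent = scale_exponent,
    tuning_table = tuning_table,
    scale_table = scale_table,
    snr = snr,
    snr_mode = snr_mode,
    noise_mode = noise_mode,
    copies_per_config = copies_per_config
  )
  class(cfg) <- "beekc_config"
  cfg
}

#' @export
print.beekc_config <- function(x, ...) {
  cat("beekc model configuration\n")
  cat(sprintf("  tuning: A %g deg / B %g deg, HWHM %g deg, peaks %g/%g Hz\n",
              x$peak_A, x$peak_B, x$hwhm, x$rate_A, x$rate_B))
  cat(sprintf("  scale factor: S(L) = (L/%g)^%.4f\n",
              x$reference_length, scale_exponent(x)))
  cat(sprintf("  noise: SNR %g (%s), mode %s\n", x$snr, x$snr_mode,
              x$noise_mode))
  cat(sprintf("  edge filter: %s (threshold %g)\n", x$edge_filter,
              x$magnitude_threshold))
  invisible(x)
}

# Quadrant labels in canonical order (q = 1..4). Row 0 of an image is
# dorsal; columns left of the vertical midline belong to the left eye.
QUADRANTS <- c("dorsal_left", "ventral_left", "dorsal_right", "ventral_right")

# per-synapse noise standard deviation for a given firing rate
noise_sd <- function(rate, config) {
  if (config$snr_mode == "db") rate * 10^(-config$snr / 20)
  else rate / config$snr
}
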