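#' Lobula orientation-sensitive neurons (LOSNs)
#'
#' Two types of large-field lobula neuron summarise the oriented edge
#' content of each visual-field quadrant. Type A prefers 115 degrees,
#' type B 250 degrees (70 on the [0, 180) orientation axis), each with an
#' angular half-width at half-maximum of 45 degrees (a full width of
#' about 90). The response to a mixed-orientation quadrant is the
#' proportion-weighted tuning-curve response, rescaled by a sublinear
#' function of the total edge length:
#'
#'   rate(x, q) = ( sum_i  H(q,i)/sum_i H(q,i) * C(x, i) ) * S(sum_i H(q,i))
#'
#' @name lobula
NULL

# minimum angular distance on the 180-degree orientation circle
ang_dist180 <- function(a, b) {
  d <- abs((a - b) %% 180)
  pmin(d, 180 - d)
}

#' Orientation tuning curve
#'
#' Firing rate of a type A or type B lobula neuron to a reference-length
#' (280 px) edge at orientation `theta`. The default parametric form is
#' a wrapped Gaussian on the 180-degree orientation circle,
#' `baseline + peak_rate * 2^-((d / hwhm)^2)` with `d` the angular
#' distance to the preferred orientation, so the rate is exactly half the
#' peak at `hwhm` degrees away. A tabulated curve (e.g. digitized from
#' recordings) replaces the parametric form when
#' `config$tuning_table` is set.
#'
#' @param x `"A"` or `"B"`.
#' @param theta Orientation(s) in degrees; any real, reduced mod 180.
#' @param config A [beekc_config()].
#' @return Firing rate(s) in Hz.
#' @export
tuning_curve <- function(x, theta, config = beekc_config()) {
  if (!x %in% c("A", "B")) stop("unknown neuron type: ", x)
  if (!is.null(config$tuning_table)) {
    tb <- config$tuning_table
    col <- paste0("rate_", x)
    stopifnot(all(c("degree", col) %in% names(tb)))
    deg <- c(tb$degree, tb$degree[1] + 180)   # periodic closure
    val <- c(tb[[col]], tb[[col]][1])
    f <- stats::approxfun(deg, val, rule = 2)
    return(f(theta %% 180 + ifelse(theta %% 180 < deg[1], 180, 0)))
  }
  peak <- if (x == "A") config$peak_A else config$peak_B
  rate <- if (x == "A") config$rate_A else config$rate_B
  d <- ang_dist180(theta, peak)
  config$baseline + rate * 2^(-(d / config$hwhm)^2)
}

#' Edge-length scale-factor exponent
#'
#' The scale factor is `S(L) = (L / reference_length)^alpha`. When
#' `config$scale_exponent` is `NULL`, alpha is calibrated in closed form
#' from the type A tuning curve so that the reference worked example
#' holds exactly: a single vertical bar (edge content 600 px at 90
#' degrees + 200 px at 0) and a doubled pair of horizontal bars (1200 px
#' at 0 + 400 px at 90) -- identical orientation proportions, doubled
#' total length -- elicit exactly equal type A rates. That pins
#' `S(1600)/S(800)` and hence `alpha = log2` of the ratio of the two
#' proportion-weighted curve responses (about 0.812 under default
#' curves).
#'
#' @param config A [beekc_config()].
#' @return The exponent alpha.
#' @export
scale_exponent <- function(config = beekc_config()) {
  if (!is.null(config$scale_exponent)) return(config$scale_exponent)
  c0 <- tuning_curve("A", 0, config)
  c90 <- tuning_curve("A", 90, config)
  log2((0.25 * c0 + 0.75 * c90) / (0.75 * c0 + 0.25 * c90))
}

#' Edge-length scale factor S(L)
#'
#' Dimensionless multiplier applied to the proportion-weighted tuning
#' response of a quadrant: 1 at the 280 px reference length, 0 at 0,
#' monotone non-decreasing and sublinear (S(2L) < 2 S(L)), emulating the
#' saturating growth of large-field responses with edge length. A
#' tabulated curve is used when `config$scale_table` is set (values are
#' normalized to 1 at the reference length).
#'
#' @param L Total edge length(s) in pixels, >= 0.
#' @param config A [beekc_config()].
#' @return Scale factor(s).
#' @export
length_scale <- function(L, config = beekc_config()) {
  if (any(L < 0)) stop("edge length must be >= 0")
  if (!is.null(config$scale_table)) {
    tb <- config$scale_table
    stopifnot(all(c("length", "factor") %in% names(tb)))
    f <- stats::approxfun(tb$length, tb$factor, rule = 2)
    return(f(L) / f(config$reference_length))
  }
  (L / config$reference_length)^scale_exponent(config)
}

#' LOSN firing rate for one quadrant
#'
#' @param H An `edge_histogram`.
#' @param x Neuron type, `"A"` or `"B"`.
#' @param q Quadrant name (see `QUADRANTS`) or index 1--4.
#' @param config A [beekc_config()].
#' @return Firing rate in Hz (0 for an empty quadrant).
#' @export
losn_response <- function(H, x, q, config = beekc_config()) {
  stopifnot(inherits(H, "edge_histogram"))
  if (is.character(q)) q <- match(q, QUADRANTS)
  hq <- unclass(H)[q, ]
  tot <- sum(hq)
  if (tot == 0) return(0)
  curve <- tuning_curve(x, 0:179, config)
  sum(hq / tot * curve) * length_scale(tot, config)
}

#' All eight LOSN responses for a pattern
#'
#' @param H An `edge_histogram`.
#' @param config A [beekc_config()].
#' @return A 2 x 4 matrix of class `"losn_response"`; rows `A`, `B`,
#'   columns the canonical quadrants; attribute `uid` carried over from
#'   the histogram.
#' @export
losn_vector <- function(H, config = beekc_config()) {
  stopifnot(inherits(H, "edge_histogram"))
  M <- unclass(H)
  tot <- rowSums(M)
  curveA <- tuning_curve("A", 0:179, config)
  curveB <- tuning_curve("B", 0:179, config)
  S <- ifelse(tot > 0, length_scale(tot, config), 0)
  prop <- M / ifelse(tot > 0, tot, 1)
  r <- rbind(A = as.vector(prop %*% curveA) * S,
             B = as.vector(prop %*% curveB) * S)
  colnames(r) <- QUADRANTS
  structure(r, class = "losn_response", uid = attr(H, "uid"))
}

#' @export
print.losn_response <- function(x, ...) {
  cat("<losn_response", if (!is.null(attr(x, "uid")))
    paste0("'", attr(x, "uid"), "'"), "(Hz)>\n")
  print(round(unclass(x), 2))
  invisible(x)
}

#' Read / write LOSN response files
#'
#' CSV with columns `type`, `quadrant`, `rate_hz`, keyed by pattern UID.
#'
#' @param losn A `losn_response`.
#' @param path File path.
#' @export
write_losn <- function(losn, path) {
  stopifnot(inherits(losn, "losn_response"))
  df <- data.frame(type = rep(c("A", "B"), times = 4),
                   quadrant = rep(QUADRANTS, each = 2),
                   rate_hz = as.vector(unclass(losn)[, QUADRANTS]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_losn
#' @export
read_losn <- function(path) {
  df <- utils::read.csv(path)
  r <- matrix(0, 2, 4, dimnames = list(c("A", "B"), QUADRANTS))
  for (k in seq_len(nrow(df))) r[df$type[k], df$quadrant[k]] <- df$rate_hz[k]
  structure(r, class = "losn_response")
}
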