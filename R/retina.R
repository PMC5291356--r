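#' Retina pre-processing: images to edge-orientation histograms
#'
#' The six-step pipeline reduces a stimulus image to a per-quadrant
#' edge-length-by-orientation table: (1) median-filter denoising,
#' (2) green-channel binarization, (3) Canny edge detection with Sobel
#' gradient analysis, (4) weak-edge removal, (5) per-quadrant orientation
#' histograms in 1 degree bins over [0, 180), (6) caching keyed by the
#' pattern UID.
#'
#' All convolutions are computed by explicit symmetric shift-and-add so
#' that horizontally mirroring an image yields exactly the mirrored edge
#' map (bit-for-bit), a property the tests rely on.
#'
#' @name retina
NULL

# shift a matrix by (dr, dc) with replicated (clamped) borders
mshift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# separable Gaussian blur, symmetric grouping so mirroring is exact
gauss_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-(0:r)^2 / (2 * sigma^2))
  w <- w / (w[1] + 2 * sum(w[-1]))
  rowpass <- w[1] * m
  for (d in seq_len(r))
    rowpass <- rowpass + w[d + 1] * (mshift(m, -d, 0) + mshift(m, d, 0))
  out <- w[1] * rowpass
  for (d in seq_len(r))
    out <- out + w[d + 1] * (mshift(rowpass, 0, -d) + mshift(rowpass, 0, d))
  out
}

sort3 <- function(a, b, c) {
  lo <- pmin(pmin(a, b), c)
  hi <- pmax(pmax(a, b), c)
  list(lo = lo, mid = a + b + c - lo - hi, hi = hi)
}

median3 <- function(a, b, c) sort3(a, b, c)$mid

#' Denoise a stimulus image
#'
#' 3x3 median filter (per channel for RGB input); the standard removal
#' of isolated pixel noise. On noise-free hard-edged stimuli the result
#' binarizes identically to the input.
#'
#' @param img A `stimulus_image`.
#' @return The filtered `stimulus_image`.
#' @export
denoise <- function(img) {
  stopifnot(inherits(img, "stimulus_image"))
  med9 <- function(m) {
    cols <- lapply(-1:1, function(dc)
      sort3(mshift(m, -1, dc), mshift(m, 0, dc), mshift(m, 1, dc)))
    median3(pmax(cols[[1]]$lo, pmax(cols[[2]]$lo, cols[[3]]$lo)),
            median3(cols[[1]]$mid, cols[[2]]$mid, cols[[3]]$mid),
            pmin(cols[[1]]$hi, pmin(cols[[2]]$hi, cols[[3]]$hi)))
  }
  px <- img$pixels
  if (is.matrix(px)) px <- med9(px)
  else for (k in seq_len(dim(px)[3])) px[, , k] <- med9(px[, , k])
  new_stimulus(px, img$uid, img$provenance)
}

#' Binarize via the green channel
#'
#' Thresholds the green channel (the full grid for greyscale input) at
#' `config$binarize_threshold`: values strictly below the cut are figure.
#'
#' @param img A `stimulus_image` (grey matrix or RGB array).
#' @param config A [beekc_config()].
#' @return Logical matrix, `TRUE` = figure (black).
#' @export
binarize <- function(img, config = beekc_config()) {
  stopifnot(inherits(img, "stimulus_image"))
  px <- img$pixels
  g <- if (is.matrix(px)) px else px[, , 2]
  g < config$binarize_threshold
}

#' Detect oriented edges in a binary image
#'
#' Canny edge detection (Gaussian blur, Sobel gradients, non-maximum
#' suppression along the gradient, hysteresis thresholding). Each edge
#' pixel carries the Sobel gradient magnitude (on the 0--255 intensity
#' scale) and the edge orientation in degrees in [0, 180), i.e. the
#' direction perpendicular to the gradient.
#'
#' @param bin Logical matrix (`TRUE` = figure), e.g. from [binarize()].
#' @param config A [beekc_config()].
#' @return A list of class `"edge_map"`: `edge` (logical), `orientation`
#'   (degrees, `NA` off-edge), `magnitude` (`NA` off-edge).
#' @export
detect_edges <- function(bin, config = beekc_config()) {
  stopifnot(is.logical(bin), is.matrix(bin))
  m <- gauss_blur(bin * 255, config$canny_sigma)
  # grouping is chosen so a horizontally mirrored input yields the
  # bit-exact mirrored gradients: diagonal pairs are summed before the
  # axial term (IEEE addition is commutative, not associative)
  gx <- (mshift(m, -1, 1) + 2 * mshift(m, 0, 1) + mshift(m, 1, 1)) -
        (mshift(m, -1, -1) + 2 * mshift(m, 0, -1) + mshift(m, 1, -1))
  gdn <- ((mshift(m, 1, -1) + mshift(m, 1, 1)) + 2 * mshift(m, 1, 0)) -
         ((mshift(m, -1, -1) + mshift(m, -1, 1)) + 2 * mshift(m, -1, 0))
  gy <- -gdn                               # y axis points up (dorsal)
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) {
    na <- matrix(NA_real_, nrow(bin), ncol(bin))
    return(structure(list(edge = matrix(FALSE, nrow(bin), ncol(bin)),
                          orientation = na, magnitude = na),
                     class = "edge_map"))
  }
  phi <- atan2(gy, gx) * 180 / pi          # gradient direction
  # non-maximum suppression: 4 quantized gradient sectors
  sector <- round((phi %% 180) / 45) %% 4
  keep <- mag > 0
  n1 <- mag; n2 <- mag
  sel <- sector == 0                       # horizontal gradient
  n1[sel] <- mshift(mag, 0, 1)[sel];  n2[sel] <- mshift(mag, 0, -1)[sel]
  sel <- sector == 1                       # 45 deg (up-right) gradient
  n1[sel] <- mshift(mag, -1, 1)[sel]; n2[sel] <- mshift(mag, 1, -1)[sel]
  sel <- sector == 2                       # vertical gradient
  n1[sel] <- mshift(mag, -1, 0)[sel]; n2[sel] <- mshift(mag, 1, 0)[sel]
  sel <- sector == 3                       # 135 deg gradient
  n1[sel] <- mshift(mag, -1, -1)[sel]; n2[sel] <- mshift(mag, 1, 1)[sel]
  keep <- keep & mag >= n1 & mag >= n2
  # hysteresis: weak ridge pixels survive only when 8-connected to a
  # strong one
  strong <- keep & mag >= config$canny_high * max(mag)
  weak <- keep & mag >= config$canny_low * max(mag)
  edge <- strong
  repeat {
    grown <- edge
    for (dr in -1:1) for (dc in -1:1)
      if (dr || dc) grown <- grown | mshift(edge, dr, dc)
    grown <- grown & weak
    if (identical(grown, edge)) break
    edge <- grown
  }
  orientation <- (phi + 90) %% 180
  orientation[!edge] <- NA_real_
  magout <- mag
  magout[!edge] <- NA_real_
  structure(list(edge = edge, orientation = orientation,
                 magnitude = magout),
            class = "edge_map")
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf("<edge_map  %d x %d, %d edge px>\n", ncol(x$edge),
              nrow(x$edge), sum(x$edge)))
  invisible(x)
}

# 8-connected component labels of a logical matrix (label propagation)
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  big <- sum(mask) + 1L
  repeat {
    cur <- lab
    cur[!mask] <- big
    nb <- cur
    for (dr in -1:1) for (dc in -1:1)
      if (dr || dc) nb <- pmin(nb, mshift(cur, dr, dc))
    nb[!mask] <- 0L
    if (identical(nb, lab)) break
    lab <- nb
  }
  lab
}

#' Remove weak edges
#'
#' Default (`edge_filter = "magnitude"`): drop edge pixels whose Sobel
#' gradient magnitude is less than or equal to `magnitude_threshold`
#' (the literal rule; edges below a 3 degree subtense on the bee eye are
#' behaviourally invisible). Alternative (`edge_filter = "segment"`):
#' drop 8-connected edge segments shorter than `segment_min_px` pixels,
#' the contour-length reading of the same acuity limit.
#'
#' @param em An `edge_map`.
#' @param magnitude_threshold Cut on the Sobel magnitude; overrides the
#'   value in `config`.
#' @param config A [beekc_config()].
#' @return The filtered `edge_map`.
#' @export
filter_weak_edges <- function(em,
                              magnitude_threshold = config$magnitude_threshold,
                              config = beekc_config()) {
  stopifnot(inherits(em, "edge_map"))
  if (magnitude_threshold < 0) stop("magnitude threshold must be >= 0")
  drop <- if (config$edge_filter == "magnitude") {
    em$edge & !is.na(em$magnitude) & em$magnitude <= magnitude_threshold
  } else {
    lab <- label_components(em$edge)
    sizes <- tabulate(lab)
    em$edge & sizes[pmax(lab, 1L)] < config$segment_min_px
  }
  em$edge[drop] <- FALSE
  em$orientation[drop] <- NA_real_
  em$magnitude[drop] <- NA_real_
  em
}

#' Per-quadrant edge-orientation histogram
#'
#' Divides the frame into four equal quadrants at the horizontal
#' (dorsal/ventral) and vertical (left/right eye) midlines and counts
#' retained edge pixels per integer orientation bin (0--179 degrees; the
#' degenerate 180 bin folds into 0).
#'
#' @param em An `edge_map` (from a 150- or 300-px-wide frame).
#' @return A 4 x 180 matrix of class `"edge_histogram"`; rows
#'   `dorsal_left`, `ventral_left`, `dorsal_right`, `ventral_right`,
#'   columns `"0"`..`"179"`. `H[q, i]` is the edge length in pixels.
#' @export
quadrant_histogram <- function(em) {
  stopifnot(inherits(em, "edge_map"))
  h <- nrow(em$edge); w <- ncol(em$edge)
  if (!(w %in% c(TILE, FRAME)))
    stop("frame width must be 150 or 300 px")
  idx <- which(em$edge, arr.ind = TRUE)
  dorsal <- idx[, 1] <= h / 2
  left <- idx[, 2] <= w / 2
  q <- ifelse(left, ifelse(dorsal, 1L, 2L), ifelse(dorsal, 3L, 4L))
  bin <- round(em$orientation[em$edge]) %% 180
  H <- matrix(0, 4, 180, dimnames = list(QUADRANTS, 0:179))
  if (length(q))
    for (k in seq_along(q)) H[q[k], bin[k] + 1] <- H[q[k], bin[k] + 1] + 1
  structure(H, class = "edge_histogram")
}

#' @export
print.edge_histogram <- function(x, ...) {
  tot <- rowSums(unclass(x))
  cat("<edge_histogram>  edge px per quadrant:\n")
  print(tot)
  invisible(x)
}

.beekc_cache <- new.env(parent = emptyenv())

config_signature <- function(config) {
  keys <- c("binarize_threshold", "denoise", "canny_sigma", "canny_low",
            "canny_high", "magnitude_threshold", "edge_filter",
            "segment_min_px")
  paste(vapply(config[keys], function(v) paste(format(v), collapse = ","),
               character(1)), collapse = "|")
}

#' Full pre-processing pipeline
#'
#' `denoise` -> `binarize` -> `detect_edges` -> `filter_weak_edges` ->
#' `quadrant_histogram`, memoised on the pattern UID (and the retina
#' parameters) so repeated presentations of the same pattern reuse the
#' stored histogram.
#'
#' @param img A `stimulus_image`.
#' @param config A [beekc_config()].
#' @param cache Use/update the in-memory histogram cache.
#' @return An `edge_histogram` with attribute `uid`.
#' @export
preprocess <- function(img, config = beekc_config(), cache = TRUE) {
  stopifnot(inherits(img, "stimulus_image"))
  key <- paste0(img$uid, "#", config_signature(config))
  if (cache && !is.null(.beekc_cache[[key]])) return(.beekc_cache[[key]])
  x <- if (config$denoise) denoise(img) else img
  em <- detect_edges(binarize(x, config), config)
  em <- filter_weak_edges(em, config = config)
  H <- quadrant_histogram(em)
  attr(H, "uid") <- img$uid
  if (cache) .beekc_cache[[key]] <- H
  H
}

#' Empty the histogram/LOSN memo cache
#' @export
clear_cache <- function() {
  rm(list = ls(.beekc_cache), envir = .beekc_cache)
  invisible(NULL)
}

#' Read / write per-image histogram files
#'
#' Structured text (CSV) with columns `quadrant`, `orientation_deg`,
#' `length_px`; zero bins are omitted on write.
#'
#' @param H An `edge_histogram`.
#' @param path File path.
#' @return `read_histogram`: an `edge_histogram`; `write_histogram`:
#'   `path`, invisibly.
#' @export
write_histogram <- function(H, path) {
  stopifnot(inherits(H, "edge_histogram"))
  M <- unclass(H)
  idx <- which(M > 0, arr.ind = TRUE)
  df <- data.frame(quadrant = QUADRANTS[idx[, 1]],
                   orientation_deg = idx[, 2] - 1L,
                   length_px = M[idx])
  df <- df[order(df$quadrant, df$orientation_deg), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_histogram
#' @export
read_histogram <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("quadrant", "orientation_deg", "length_px") %in%
                  names(df)))
  H <- matrix(0, 4, 180, dimnames = list(QUADRANTS, 0:179))
  for (k in seq_len(nrow(df)))
    H[df$quadrant[k], df$orientation_deg[k] + 1] <- df$length_px[k]
  structure(H, class = "edge_histogram")
}

#' Build an edge histogram directly from (quadrant, orientation, length)
#' entries
#'
#' Convenience for worked examples where the histogram is specified
#' rather than measured from an image.
#'
#' @param quadrant Quadrant names (see `QUADRANTS`) or indices 1--4.
#' @param orientation_deg Integer orientations in [0, 180).
#' @param length_px Edge lengths in pixels.
#' @return An `edge_histogram`.
#' @export
edge_histogram <- function(quadrant, orientation_deg, length_px) {
  H <- matrix(0, 4, 180, dimnames = list(QUADRANTS, 0:179))
  if (is.numeric(quadrant)) quadrant <- QUADRANTS[quadrant]
  stopifnot(length(quadrant) == length(orientation_deg),
            length(orientation_deg) == length(length_px),
            all(orientation_deg >= 0 & orientation_deg < 180),
            all(length_px >= 0))
  for (k in seq_along(quadrant))
    H[quadrant[k], orientation_deg[k] + 1] <-
      H[quadrant[k], orientation_deg[k] + 1] + length_px[k]
  structure(H, class = "edge_histogram")
}
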