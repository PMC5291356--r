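#' Stimulus images and pattern recipes
#'
#' Stimuli are achromatic rasters: a black figure (grey value 0) on a
#' white ground (255). Pattern tiles are 150 x 150 px; composited fields
#' of view are 300 x 150 px (width x height is 300 x 150; matrices are
#' stored rows x columns, so `dim(pixels)` is `c(150, width)`).
#' Row 1 is the top of the image (dorsal); column 1 is the far left.
#'
#' @name stimuli
NULL

TILE <- 150L
FRAME <- 300L

new_stimulus <- function(pixels, uid, provenance = NULL) {
  stopifnot(is.matrix(pixels) || length(dim(pixels)) == 3)
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  if (h != TILE || !(w %in% c(TILE, FRAME)))
    stop("stimulus must be 150 px high and 150 or 300 px wide, got ",
         h, " x ", w)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]")
  structure(list(uid = uid, pixels = pixels, provenance = provenance),
            class = "stimulus_image")
}

#' @export
print.stimulus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<stimulus_image '%s'  %d x %d px, %d figure px>\n",
              x$uid, d[2], d[1], sum(x$pixels < 128)))
  invisible(x)
}

#' Pattern recipe
#'
#' A structured description of a generated stimulus. Supported families:
#' `bar_set`, `quadrant_bars`, `cross`, `sector_disc`, `spiral_disc`,
#' `octagon`, `checkerboard` and `mirror` (horizontal pixel mirror of a
#' base recipe). Family-specific parameters are passed through `...`;
#' angles are degrees, reduced to [0, 360), and all geometry is
#' deterministic and hard-edged (no anti-aliasing).
#'
#' @param family Pattern family name.
#' @param uid Unique identifier; derived from the parameters if omitted.
#' @param ... Family parameters, see `make_pattern`.
#' @return A list of class `"pattern_recipe"`.
#' @export
pattern_recipe <- function(family, ..., uid = NULL) {
  params <- list(...)
  families <- c("bar_set", "quadrant_bars", "cross", "sector_disc",
                "spiral_disc", "octagon", "checkerboard", "mirror")
  if (!family %in% families)
    stop("unknown pattern family: ", family)
  if (is.null(uid)) {
    flat <- vapply(params, function(p) {
      if (inherits(p, "pattern_recipe")) p$uid
      else paste(format(unlist(p), trim = TRUE), collapse = "_")
    }, character(1))
    uid <- paste0(family, "(", paste(flat, collapse = ";"), ")")
  }
  structure(list(family = family, params = params, uid = uid),
            class = "pattern_recipe")
}

# pixel-centre coordinate grids for a 150x150 tile, origin at the tile
# centre, v pointing up (dorsal positive)
tile_coords <- function() {
  u <- matrix(rep(seq_len(TILE) - 0.5 - TILE / 2, each = TILE), TILE)
  v <- matrix(rep(TILE / 2 - seq_len(TILE) + 0.5, times = TILE), TILE)
  list(u = u, v = v)
}

deg_cos <- function(a) cospi(a / 180)
deg_sin <- function(a) sinpi(a / 180)

# mask of pixels inside an oriented bar
bar_mask <- function(u, v, angle, length, width, cx = 0, cy = 0) {
  ca <- deg_cos(angle); sa <- deg_sin(angle)
  du <- u - cx; dv <- v - cy
  along <- du * ca + dv * sa
  perp <- -du * sa + dv * ca
  abs(along) <= length / 2 & abs(perp) <= width / 2
}

render <- function(mask) {
  px <- matrix(255, TILE, TILE)
  px[mask] <- 0
  px
}

#' Generate a pattern tile from a recipe
#'
#' Deterministically rasterizes a 150 x 150 px black-on-white tile.
#'
#' Family parameters:
#' \describe{
#'   \item{bar_set}{`bars`: list of `list(angle, length, width, cx, cy)`
#'     (centre offsets from the tile centre, x right / y up).}
#'   \item{quadrant_bars}{see [make_quadrant_pattern()].}
#'   \item{cross}{`rotation` (deg, default 0), `opening` (angle between
#'     the two arms, default 90), `arm_length` (140), `width` (30). At
#'     rotation 0 the default cross is a plus of two orthogonal bars.}
#'   \item{sector_disc}{`n_sectors` (even, default 4), `rotation` (0),
#'     `diameter` (150); alternating black/white angular sectors.}
#'   \item{spiral_disc}{`n_arms` (3), `twist` (total twist in degrees at
#'     the rim, default 270), `rotation` (0), `handedness` (+1 or -1),
#'     `diameter` (150).}
#'   \item{octagon}{`n_sides` (8), `rotation` (0), `outer_r` (72, the
#'     apothem), `ring_width` (15); a regular polygonal ring.}
#'   \item{checkerboard}{`check_size` (default 25).}
#'   \item{mirror}{`base`: a `pattern_recipe`; the horizontal pixel
#'     mirror of the rendered base tile.}
#' }
#'
#' @param recipe A [pattern_recipe()].
#' @return A `stimulus_image` (150 x 150).
#' @export
make_pattern <- function(recipe) {
  stopifnot(inherits(recipe, "pattern_recipe"))
  p <- recipe$params
  g <- tile_coords()
  px <- switch(recipe$family,
    bar_set = {
      if (is.null(p$bars) || !length(p$bars)) stop("bar_set needs bars")
      mask <- matrix(FALSE, TILE, TILE)
      for (b in p$bars) {
        b <- utils::modifyList(list(width = 10, cx = 0, cy = 0), b)
        if (b$width < 1) stop("bar widths must be >= 1 px")
        mask <- mask | bar_mask(g$u, g$v, b$angle %% 360, b$length,
                                b$width, b$cx, b$cy)
      }
      if (!any(mask)) stop("recipe places no figure inside the tile")
      render(mask)
    },
    quadrant_bars = do.call(quadrant_bars_pixels, p),
    cross = {
      p <- utils::modifyList(list(rotation = 0, opening = 90,
                                  arm_length = 140, width = 30), p)
      mask <- bar_mask(g$u, g$v, p$rotation %% 360, p$arm_length, p$width) |
        bar_mask(g$u, g$v, (p$rotation + p$opening) %% 360, p$arm_length,
                 p$width)
      render(mask)
    },
    sector_disc = {
      p <- utils::modifyList(list(n_sectors = 4, rotation = 0,
                                  diameter = 150), p)
      if (p$n_sectors < 2 || p$n_sectors %% 2 != 0)
        stop("n_sectors must be even and >= 2")
      r <- sqrt(g$u^2 + g$v^2)
      ang <- (atan2(g$v, g$u) * 180 / pi - p$rotation) %% 360
      w <- 360 / p$n_sectors
      render(r <= p$diameter / 2 & (floor(ang / w) %% 2 == 0))
    },
    spiral_disc = {
      p <- utils::modifyList(list(n_arms = 3, twist = 270, rotation = 0,
                                  handedness = 1, diameter = 150), p)
      R <- p$diameter / 2
      r <- sqrt(g$u^2 + g$v^2)
      ang <- atan2(g$v, g$u) * 180 / pi
      phase <- (ang - p$handedness * p$twist * r / R - p$rotation) %%
        (360 / p$n_arms)
      render(r <= R & phase < 180 / p$n_arms)
    },
    octagon = {
      p <- utils::modifyList(list(n_sides = 8, rotation = 0, outer_r = 72,
                                  ring_width = 15), p)
      inpoly <- function(apothem) {
        inside <- matrix(TRUE, TILE, TILE)
        for (k in seq_len(p$n_sides) - 1) {
          beta <- p$rotation + k * 360 / p$n_sides
          inside <- inside &
            (g$u * deg_cos(beta) + g$v * deg_sin(beta) <= apothem)
        }
        inside
      }
      render(inpoly(p$outer_r) & !inpoly(p$outer_r - p$ring_width))
    },
    checkerboard = {
      p <- utils::modifyList(list(check_size = 25), p)
      s <- p$check_size
      if (s < 1) stop("check_size must be >= 1")
      rows <- floor((seq_len(TILE) - 1) / s)
      cols <- floor((seq_len(TILE) - 1) / s)
      render(outer(rows, cols, `+`) %% 2 == 0)
    },
    mirror = {
      base <- p$base
      stopifnot(inherits(base, "pattern_recipe"))
      mirror_image(make_pattern(base))$pixels
    }
  )
  new_stimulus(px, recipe$uid, recipe)
}

quadrant_bars_pixels <- function(orientations, counts,
                                 bar_length = 56, bar_width = 10,
                                 spacing = 20) {
  stopifnot(length(orientations) == 4, length(counts) == 4,
            all(counts >= 1), bar_width >= 1)
  orientations <- orientations %% 180
  g <- tile_coords()
  centres <- list(dorsal_left = c(-37.5, 37.5),
                  ventral_left = c(-37.5, -37.5),
                  dorsal_right = c(37.5, 37.5),
                  ventral_right = c(37.5, -37.5))
  mask <- matrix(FALSE, TILE, TILE)
  for (q in 1:4) {
    th <- orientations[q]; k <- counts[q]
    cq <- centres[[q]]
    offs <- (seq_len(k) - (k + 1) / 2) * spacing
    ca <- deg_cos(th); sa <- deg_sin(th)
    for (o in offs) {
      cx <- cq[1] - o * sa; cy <- cq[2] + o * ca
      # analytic bounding box of the rotated bar, checked against the
      # quadrant rectangle so bars never bleed across the midlines
      ex <- abs(ca) * bar_length / 2 + abs(sa) * bar_width / 2
      ey <- abs(sa) * bar_length / 2 + abs(ca) * bar_width / 2
      if (cx - ex < min(0, sign(cq[1]) * 75) - 1e-9 ||
          cx + ex > max(0, sign(cq[1]) * 75) + 1e-9 ||
          cy - ey < min(0, sign(cq[2]) * 75) - 1e-9 ||
          cy + ey > max(0, sign(cq[2]) * 75) + 1e-9)
        stop("bar placement overflows quadrant bounds (quadrant ",
             QUADRANTS[q], ")")
      mask <- mask | bar_mask(g$u, g$v, th, bar_length, bar_width, cx, cy)
    }
  }
  render(mask)
}

#' Quadrant-bar patterns
#'
#' A 150 x 150 tile whose four quadrants each contain `counts[q]`
#' parallel bars at `orientations[q]` degrees. Quadrant order is
#' dorsal-left, ventral-left, dorsal-right, ventral-right (the canonical
#' quadrant order used throughout the package).
#'
#' @param orientations Four angles in [0, 180).
#' @param counts Four integers >= 1 (bars per quadrant).
#' @param bar_length,bar_width,spacing Bar geometry in pixels; bars are
#'   stacked perpendicular to their orientation, `spacing` px apart.
#' @param uid Optional identifier.
#' @return A `stimulus_image`.
#' @export
make_quadrant_pattern <- function(orientations, counts,
                                  bar_length = 56, bar_width = 10,
                                  spacing = 20, uid = NULL) {
  make_pattern(pattern_recipe("quadrant_bars",
                              orientations = orientations, counts = counts,
                              bar_length = bar_length, bar_width = bar_width,
                              spacing = spacing, uid = uid))
}

#' Horizontal pixel mirror of a stimulus
#' @param img A `stimulus_image`.
#' @return The left/right mirrored `stimulus_image` (uid prefixed
#'   `mirror()`).
#' @export
mirror_image <- function(img) {
  stopifnot(inherits(img, "stimulus_image"))
  px <- img$pixels[, rev(seq_len(ncol(img$pixels))), drop = FALSE]
  new_stimulus(px, paste0("mirror(", img$uid, ")"),
               list(mirror_of = img$uid))
}

#' Composite a tile into an offset field of view
#'
#' Places a 150 x 150 tile into a white 300 x 150 frame, shifted
#' horizontally by `offset` pixels from centre (positive = rightwards).
#' Content shifted past the frame bounds is cropped. At offset 0 the tile
#' occupies columns 76--225, half visible to each simulated eye.
#'
#' @param base 150 x 150 `stimulus_image`.
#' @param offset Signed integer, |offset| <= 200.
#' @return A 300 x 150 `stimulus_image` with uid `"<uid>@<offset>"`.
#' @export
composite_offset <- function(base, offset) {
  stopifnot(inherits(base, "stimulus_image"))
  if (ncol(base$pixels) != TILE)
    stop("base must be a 150 x 150 tile")
  offset <- as.integer(round(offset))
  if (abs(offset) > 200) stop("|offset| must be <= 200")
  frame <- matrix(255, TILE, FRAME)
  dest <- (TILE / 2 + offset) + seq_len(TILE)   # frame columns 76+o .. 225+o
  keep <- dest >= 1 & dest <= FRAME
  frame[, dest[keep]] <- base$pixels[, keep]
  new_stimulus(frame, sprintf("%s@%+d", base$uid, offset),
               list(base = base$uid, offset = offset))
}

#' The 17-frame horizontal offset series of a tile
#'
#' Offsets run from -200 to +200 px in 25 px steps, producing 17
#' composited 300 x 150 test frames.
#'
#' @param base 150 x 150 `stimulus_image`.
#' @param offsets Signed pixel shifts (default the canonical 17).
#' @return A list of class `"offset_series"` with elements `base`,
#'   `offsets`, `frames`.
#' @export
offset_series <- function(base, offsets = seq(-200L, 200L, by = 25L)) {
  if (any(offsets %% 25 != 0))
    warning("offsets are not multiples of the 25 px protocol step")
  frames <- lapply(offsets, function(o) composite_offset(base, o))
  structure(list(base = base, offsets = as.integer(offsets),
                 frames = frames),
            class = "offset_series")
}

#' Read / write stimulus PNG files
#'
#' `write_png` stores the pixel grid losslessly as an 8-bit grey PNG;
#' `read_png` accepts grey or RGB(A) PNGs (colour channels are retained
#' so that downstream binarization can use the green channel) and checks
#' the stimulus dimension contract.
#'
#' @param path File path.
#' @param uid Identifier for the read image (defaults to the file name).
#' @param img A `stimulus_image`.
#' @return `read_png`: a `stimulus_image`; `write_png`: `path`,
#'   invisibly.
#' @export
read_png <- function(path, uid = sub("\\.png$", "", basename(path))) {
  a <- png::readPNG(path)
  px <- round(a * 255)
  if (length(dim(px)) == 3 && dim(px)[3] == 4)
    px <- px[, , 1:3, drop = FALSE]   # drop alpha
  if (length(dim(px)) == 3 && dim(px)[3] == 1) px <- px[, , 1]
  new_stimulus(px, uid, list(source = path))
}

#' @rdname read_png
#' @export
write_png <- function(img, path) {
  stopifnot(inherits(img, "stimulus_image"))
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}
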