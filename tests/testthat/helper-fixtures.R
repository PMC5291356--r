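# shared fixtures: small deterministic stimuli and histograms

hbar_tile <- function(length = 60, width = 20, angle = 0, cx = 0, cy = 0,
                      uid = NULL) {
  make_pattern(pattern_recipe(
    "bar_set", bars = list(list(angle = angle, length = length,
                                width = width, cx = cx, cy = cy)),
    uid = uid))
}

# the reference worked-example histograms: one quadrant, 0/90 content
worked_example_histograms <- function(q = "dorsal_left") {
  list(cs = edge_histogram(rep(q, 2), c(0, 90), c(600, 200)),
       cor = edge_histogram(rep(q, 2), c(0, 90), c(1200, 400)),
       inc = edge_histogram(rep(q, 2), c(0, 90), c(200, 600)))
}

# random valid edge histogram (for property tests)
random_histogram <- function() {
  H <- matrix(0, 4, 180, dimnames = list(beekc:::QUADRANTS, 0:179))
  for (q in 1:4) {
    bins <- sample(0:179, sample(3:10, 1))
    H[q, bins + 1] <- sample(10:300, length(bins), replace = TRUE)
  }
  structure(H, class = "edge_histogram")
}

# a random 8-rate LOSN vector with no exact Kenyon-cell input ties
random_losn <- function() {
  r <- matrix(runif(8, 5, 40), 2, 4,
              dimnames = list(c("A", "B"), beekc:::QUADRANTS))
  structure(r, class = "losn_response")
}

nonoise <- function(...) beekc_config(snr = Inf, ...)
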