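#' Mushroom body Kenyon cells
#'
#' Kenyon cells are binary threshold units summing signed lobula inputs.
#' Each of the 86 wiring configurations pairs `nA` type-A synapses with
#' `nB` type-B synapses of opposite sign (counts drawn from
#' {1, 2, 3, 5, 7, 11, 13}; primes exclude duplicate response profiles,
#' so equal counts occur only as 1A,1B). Configurations 1--43 are
#' A-excitatory/B-inhibitory; 44--86 are their sign-flipped reciprocals,
#' which guarantees close to 50% population activation for any input.
#' All synaptic weights are fixed at +1/-1; there is no learning.
#'
#' Two wiring variants: DISTINCT cells read one visual-field quadrant
#' (86 configs x 30 copies x 4 quadrants = 10,320 cells); MERGED cells
#' read the same dorsal or ventral band of both eyes, with the
#' configuration's synapse set duplicated per eye (86 x 30 x 2 = 5,160
#' cells).
#'
#' @name mushroom_body
NULL

SYN_COUNTS <- c(1L, 2L, 3L, 5L, 7L, 11L, 13L)

#' The 86 LOSN-to-Kenyon-cell wiring configurations
#'
#' @return Data frame with columns `id` (1--86), `nA`, `nB` (synapse
#'   counts), `sign_A`, `sign_B` (+1/-1, always opposite).
#' @export
build_config_table <- function() {
  first <- do.call(rbind, lapply(SYN_COUNTS, function(nA) {
    nB <- if (nA == 1L) SYN_COUNTS else setdiff(SYN_COUNTS, nA)
    data.frame(nA = nA, nB = nB)
  }))
  stopifnot(nrow(first) == 43L)
  tab <- rbind(cbind(first, sign_A = 1L, sign_B = -1L),
               cbind(first, sign_A = -1L, sign_B = 1L))
  cbind(id = seq_len(86L), tab)
}

#' Build a Kenyon cell population
#'
#' @param variant `"DISTINCT"` or `"MERGED"` (case-insensitive).
#' @param configs Configuration table (default [build_config_table()]).
#' @param copies Copies per configuration per source region.
#' @param regions Optional subset of source regions: quadrant names for
#'   DISTINCT, `"dorsal"`/`"ventral"` for MERGED (e.g. the single-
#'   quadrant subpopulation of the worked example).
#' @return A list of class `"kc_population"`: `variant`, `cells` (one
#'   row per Kenyon cell: config id, counts, signs, `region`), `size`.
#' @export
build_population <- function(variant = c("DISTINCT", "MERGED"),
                             configs = build_config_table(),
                             copies = 30L, regions = NULL) {
  variant <- toupper(variant)
  variant <- match.arg(variant, c("DISTINCT", "MERGED"))
  all_regions <- if (variant == "DISTINCT") QUADRANTS
                 else c("dorsal", "ventral")
  if (is.null(regions)) regions <- all_regions
  stopifnot(all(regions %in% all_regions))
  cells <- do.call(rbind, lapply(regions, function(reg) {
    block <- configs[rep(seq_len(nrow(configs)), times = copies), ]
    block$region <- reg
    block
  }))
  rownames(cells) <- NULL
  structure(list(variant = variant, cells = cells,
                 copies_per_config = copies, size = nrow(cells)),
            class = "kc_population")
}

#' @export
print.kc_population <- function(x, ...) {
  cat(sprintf("<kc_population %s: %d cells (%d configs x %d copies x %d regions)>\n",
              x$variant, x$size, length(unique(x$cells$id)),
              x$copies_per_config, length(unique(x$cells$region))))
  invisible(x)
}

#' One noisy synaptic rate draw
#'
#' The firing rate carried by a synapse is the connected lobula neuron's
#' rate plus zero-mean Gaussian noise whose standard deviation follows
#' the configured SNR rule (`sd = rate * 10^(-snr/20)` for decibel
#' semantics). Draws are independent per synapse per trial.
#'
#' @param rate Firing rate(s), Hz, >= 0.
#' @param config A [beekc_config()]; `snr = Inf` disables noise.
#' @return Perturbed rate(s), Hz.
#' @export
noisy_rate <- function(rate, config = beekc_config()) {
  stopifnot(all(rate >= 0))
  if (is.infinite(config$snr)) return(rate)
  rate + stats::rnorm(length(rate), 0, noise_sd(rate, config))
}

# per-cell deterministic summed input `mu` and the sd of its total
# synaptic noise under independent per-synapse draws
cell_input_params <- function(pop, losn, config) {
  r <- unclass(losn)
  cells <- pop$cells
  k <- if (is.infinite(config$snr)) 0 else
    if (config$snr_mode == "db") 10^(-config$snr / 20) else 1 / config$snr
  if (pop$variant == "DISTINCT") {
    q <- match(cells$region, QUADRANTS)
    if (anyNA(q)) stop("population/losn region mismatch")
    rA <- r["A", q]; rB <- r["B", q]
    mu <- cells$sign_A * cells$nA * rA + cells$sign_B * cells$nB * rB
    sd <- k * sqrt(cells$nA * rA^2 + cells$nB * rB^2)
  } else {
    ql <- match(paste0(cells$region, "_left"), QUADRANTS)
    qr <- match(paste0(cells$region, "_right"), QUADRANTS)
    if (anyNA(ql) || anyNA(qr)) stop("population/losn region mismatch")
    rAl <- r["A", ql]; rAr <- r["A", qr]
    rBl <- r["B", ql]; rBr <- r["B", qr]
    mu <- cells$sign_A * cells$nA * (rAl + rAr) +
      cells$sign_B * cells$nB * (rBl + rBr)
    sd <- k * sqrt(cells$nA * (rAl^2 + rAr^2) + cells$nB * (rBl^2 + rBr^2))
  }
  list(mu = mu, sd = sd)
}

# cells x n_trials logical activation matrix
activation_matrix <- function(pop, losn, n_trials, config = beekc_config()) {
  p <- cell_input_params(pop, losn, config)
  n <- pop$size
  if (config$noise_mode == "collapsed" || is.infinite(config$snr)) {
    noise <- if (all(p$sd == 0)) 0 else
      stats::rnorm(n * n_trials) * p$sd     # sd recycles down columns
    matrix(p$mu + noise > 0, n, n_trials)
  } else if (config$noise_mode == "synapse") {
    syn <- synapse_expansion(pop, losn, config)
    out <- matrix(FALSE, n, n_trials)
    for (t in seq_len(n_trials)) {
      draw <- syn$sign * (syn$rate +
        stats::rnorm(length(syn$rate), 0, noise_sd(syn$rate, config)))
      out[, t] <- rowsum(draw, syn$cell)[, 1] > 0
    }
    out
  } else {                                  # shared per-LOSN noise
    r <- unclass(losn)
    sd8 <- noise_sd(r, config)
    out <- matrix(FALSE, n, n_trials)
    for (t in seq_len(n_trials)) {
      rn <- r + stats::rnorm(length(r)) * sd8
      pn <- cell_input_params(pop, structure(rn, class = "losn_response"),
                              within_cfg_nonoise(config))
      out[, t] <- pn$mu > 0
    }
    out
  }
}

within_cfg_nonoise <- function(config) { config$snr <- Inf; config }

# one row per synapse: owning cell index, source rate, sign
synapse_expansion <- function(pop, losn, config) {
  r <- unclass(losn)
  cells <- pop$cells
  dup <- if (pop$variant == "MERGED") c("left", "right") else ""
  cell <- integer(0); rate <- numeric(0); sign <- integer(0)
  for (side in dup) {
    qa <- if (pop$variant == "DISTINCT") match(cells$region, QUADRANTS)
          else match(paste0(cells$region, "_", side), QUADRANTS)
    cell <- c(cell,
              rep(seq_len(nrow(cells)), times = cells$nA),
              rep(seq_len(nrow(cells)), times = cells$nB))
    rate <- c(rate,
              rep(r["A", qa], times = cells$nA),
              rep(r["B", qa], times = cells$nB))
    sign <- c(sign,
              rep(cells$sign_A, times = cells$nA),
              rep(cells$sign_B, times = cells$nB))
  }
  list(cell = cell, rate = rate, sign = sign)
}

#' Binary Kenyon cell activation vector for one trial
#'
#' Each cell sums its signed, independently noise-perturbed synaptic
#' inputs; the cell fires (1) iff the sum is strictly greater than zero.
#'
#' @param pop A `kc_population`.
#' @param losn A `losn_response` (all 8 rates).
#' @param config A [beekc_config()]; set `snr = Inf` for noise-free
#'   activation.
#' @return Integer vector of 0/1, length `pop$size`.
#' @export
activate <- function(pop, losn, config = beekc_config()) {
  stopifnot(inherits(pop, "kc_population"), inherits(losn, "losn_response"))
  as.integer(activation_matrix(pop, losn, 1L, config)[, 1])
}
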