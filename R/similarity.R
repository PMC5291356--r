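#' Kenyon cell similarity ratio (KCSR)
#'
#' The behavioural read-out of the model. For a trial's three binary
#' activation vectors -- rewarded training pattern CS+, correct test
#' stimulus TS_COR and incorrect test stimulus TS_INC -- the KCSR is
#'
#'   KCSR = 1 - E(CS+, TS_COR) / (E(CS+, TS_COR) + E(CS+, TS_INC))
#'
#' with E the Euclidean distance. Values above 0.5 mean the correct test
#' stimulus evokes the more CS+-like Kenyon cell code; averaged over
#' trials and multiplied by 100 this is the simulated bee's percent
#' correct performance.
#'
#' @name similarity
NULL

#' Euclidean distance between two activation vectors
#'
#' For binary vectors this is the square root of the number of
#' disagreeing cells.
#'
#' @param a,b Equal-length numeric/integer vectors.
#' @return The distance.
#' @export
euclidean <- function(a, b) {
  if (length(a) != length(b)) stop("activation vectors differ in length")
  sqrt(sum((a - b)^2))
}

#' Kenyon cell similarity ratio of one trial
#'
#' @param cs,cor,inc Activation vectors for CS+, TS_COR, TS_INC.
#' @return A list of class `"similarity_result"`: `e_cor`, `e_inc`,
#'   `kcsr`. The degenerate case of three identical vectors (both
#'   distances zero, unreachable with noise on) returns KCSR = 0.5,
#'   i.e. indifference.
#' @export
kcsr <- function(cs, cor, inc) {
  e_cor <- euclidean(cs, cor)
  e_inc <- euclidean(cs, inc)
  ratio <- if (e_cor + e_inc > 0) 1 - e_cor / (e_cor + e_inc) else 0.5
  structure(list(e_cor = e_cor, e_inc = e_inc, kcsr = ratio),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("KCSR = %.4f  (E_cor = %.4f, E_inc = %.4f)\n",
              x$kcsr, x$e_cor, x$e_inc))
  invisible(x)
}
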