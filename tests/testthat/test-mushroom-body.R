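test_that("the 86-entry wiring table matches the reference catalogue", {
  tab <- build_config_table()
  expect_equal(nrow(tab), 86)
  expect_identical(tab$id, 1:86)
  # id 001: 1 excitatory A, 1 inhibitory B
  expect_equal(unlist(tab[tab$id == 1, c("nA", "nB", "sign_A", "sign_B")]),
               c(nA = 1, nB = 1, sign_A = 1, sign_B = -1))
  # id 046: 1 inhibitory A, 3 excitatory B
  expect_equal(unlist(tab[tab$id == 46, c("nA", "nB", "sign_A", "sign_B")]),
               c(nA = 1, nB = 3, sign_A = -1, sign_B = 1))
  # counts come from the prime set; equal counts only for 1A,1B
  expect_true(all(tab$nA %in% c(1, 2, 3, 5, 7, 11, 13)))
  expect_true(all(tab$nB %in% c(1, 2, 3, 5, 7, 11, 13)))
  expect_true(all(tab$nA == tab$nB | tab$nA != tab$nB))
  expect_equal(sum(tab$nA == tab$nB), 2)   # 001 and its reciprocal 044
  # every config k <= 43 has its sign-flipped reciprocal at k + 43
  for (k in 1:43) {
    expect_equal(tab$nA[k], tab$nA[k + 43])
    expect_equal(tab$nB[k], tab$nB[k + 43])
    expect_equal(tab$sign_A[k], -tab$sign_A[k + 43])
    expect_equal(tab$sign_B[k], -tab$sign_B[k + 43])
  }
  expect_true(all(tab$sign_A == -tab$sign_B))
})

test_that("population sizes and wiring match the two variants", {
  pop_d <- build_population("DISTINCT")
  pop_m <- build_population("MERGED")
  expect_equal(pop_d$size, 10320)
  expect_equal(pop_m$size, 5160)
  expect_setequal(unique(pop_d$cells$region), beekc:::QUADRANTS)
  expect_setequal(unique(pop_m$cells$region), c("dorsal", "ventral"))
  # MERGED wiring expansion: a config-046 dorsal cell reads 1 inhibitory
  # A and 3 excitatory B synapses from the dorsal band of EACH eye
  cell_idx <- which(pop_m$cells$id == 46 &
                      pop_m$cells$region == "dorsal")[1]
  losn <- structure(matrix(c(2, 3, 5, 7, 11, 13, 17, 19), 2, 4,
                           dimnames = list(c("A", "B"), beekc:::QUADRANTS)),
                    class = "losn_response")
  p <- beekc:::cell_input_params(pop_m, losn,
                                 beekc_config(snr = Inf))
  # dorsal_left A=2 B=3, dorsal_right A=11 B=13:
  # input = -(2 + 11) + 3*(3 + 13) = 35
  expect_equal(unname(p$mu[cell_idx]), -(2 + 11) + 3 * (3 + 13))
  # single-region subpopulation used by the worked example
  expect_equal(build_population("DISTINCT", regions = "dorsal_left")$size,
               2580)
})

test_that("noisy rates follow the configured SNR rule", {
  cfg <- beekc_config()                     # snr 30 dB
  expect_identical(noisy_rate(36, beekc_config(snr = Inf)), 36)
  set.seed(99)
  draws <- noisy_rate(rep(36, 1e5), cfg)
  sd_expect <- 36 * 10^(-30 / 20)           # ~1.14 Hz on the peak rate
  expect_lt(abs(mean(draws) - 36), 3 * sd_expect / sqrt(1e5))
  expect_equal(stats::sd(draws), sd_expect, tolerance = 0.02)
  lin <- beekc_config(snr = 30, snr_mode = "linear")
  set.seed(100)
  expect_equal(stats::sd(noisy_rate(rep(36, 1e5), lin)), 36 / 30,
               tolerance = 0.02)
})

test_that("activation applies strict-positive thresholding", {
  cfg0 <- beekc_config(snr = Inf)
  pop <- build_population("DISTINCT", regions = "dorsal_left")
  # config 001 (1A+, 1B-) with A = 10, B = 20 sums to -10: silent
  losn <- structure(matrix(c(10, 20, 0, 0, 0, 0, 0, 0), 2, 4,
                           dimnames = list(c("A", "B"), beekc:::QUADRANTS)),
                    class = "losn_response")
  a <- activate(pop, losn, cfg0)
  expect_equal(a[pop$cells$id == 1], rep(0L, 30))
  expect_equal(a[pop$cells$id == 44], rep(1L, 30))
  # a summed input of exactly zero does not fire (strict inequality)
  tie <- structure(matrix(c(10, 10, 0, 0, 0, 0, 0, 0), 2, 4,
                          dimnames = list(c("A", "B"), beekc:::QUADRANTS)),
                   class = "losn_response")
  a_tie <- activate(pop, tie, cfg0)
  expect_true(all(a_tie[pop$cells$id %in% c(1, 44)] == 0))
})

test_that("reciprocal wiring halves the population activation exactly", {
  cfg0 <- beekc_config(snr = Inf)
  set.seed(31)
  for (variant in c("DISTINCT", "MERGED")) {
    pop <- build_population(variant)
    losn <- random_losn()
    a <- activate(pop, losn, cfg0)
    expect_equal(mean(a), 0.5)
    # complementarity per reciprocal pair: sorting by (region, id) aligns
    # the copies of config k with those of config k + 43
    ids <- pop$cells$id
    ord <- order(pop$cells$region, pop$cells$id)
    a_ord <- a[ord]; id_ord <- ids[ord]
    expect_true(all(a_ord[id_ord <= 43] == 1 - a_ord[id_ord > 43]))
  }
})

test_that("MERGED summed inputs are invariant to exchanging the eyes", {
  pop <- build_population("MERGED")
  cfg <- beekc_config()
  set.seed(8)
  losn <- random_losn()
  swapped <- unclass(losn)[, c("dorsal_right", "ventral_right",
                               "dorsal_left", "ventral_left")]
  colnames(swapped) <- beekc:::QUADRANTS
  p1 <- beekc:::cell_input_params(pop, losn, cfg)
  p2 <- beekc:::cell_input_params(pop, structure(swapped,
                                                 class = "losn_response"),
                                  cfg)
  expect_identical(p1$mu, p2$mu)
  expect_identical(p1$sd, p2$sd)
})

test_that("noise draws are independent across cells sharing a lobula neuron", {
  cfg <- beekc_config()
  pop <- build_population("DISTINCT", regions = "dorsal_left")
  # configs 1 and 2 share the same A source; near-threshold input makes
  # their activations noise-driven
  losn <- structure(matrix(c(20, 20, 0, 0, 0, 0, 0, 0), 2, 4,
                           dimnames = list(c("A", "B"), beekc:::QUADRANTS)),
                    class = "losn_response")
  set.seed(17)
  am <- beekc:::activation_matrix(pop, losn, 4000, cfg)
  i <- which(pop$cells$id == 1)[1]
  j <- which(pop$cells$id == 1)[2]
  expect_lt(abs(stats::cor(am[i, ], am[j, ])), 0.05)
})

test_that("the three noise modes agree in distribution", {
  cfg_syn <- beekc_config(noise_mode = "synapse")
  cfg_col <- beekc_config(noise_mode = "collapsed")
  pop <- build_population("DISTINCT", regions = "dorsal_left")
  set.seed(23)
  losn <- random_losn()
  set.seed(51)
  a_syn <- rowMeans(beekc:::activation_matrix(pop, losn, 600, cfg_syn))
  set.seed(52)
  a_col <- rowMeans(beekc:::activation_matrix(pop, losn, 600, cfg_col))
  # per-cell firing probabilities agree within Monte-Carlo error
  expect_lt(max(abs(a_syn - a_col)), 0.08)
  # the shared mode runs and keeps the reciprocal halving on average
  cfg_sh <- beekc_config(noise_mode = "shared")
  set.seed(53)
  a_sh <- beekc:::activation_matrix(pop, losn, 200, cfg_sh)
  expect_equal(mean(a_sh), 0.5, tolerance = 0.02)
})

test_that("activation is deterministic under a fixed seed", {
  cfg <- beekc_config()
  pop <- build_population("MERGED")
  set.seed(19)
  losn <- random_losn()
  set.seed(4242); a1 <- activate(pop, losn, cfg)
  set.seed(4242); a2 <- activate(pop, losn, cfg)
  expect_identical(a1, a2)
})
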