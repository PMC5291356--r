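#' Study files and the shipped experiment suites
#'
#' A study bundles a pattern recipe library with a list of experiment
#' definitions (discrimination triplets, offset sweeps, generalization
#' tests) plus recorded honeybee percentages as side-by-side metadata.
#' Studies round-trip through YAML; the three suites used by the
#' package's reproduction runs are built programmatically by
#' [study_discrimination()], [study_generalization()] and
#' [study_crosses()].
#'
#' @name studies
NULL

recipe_to_list <- function(r) {
  p <- lapply(r$params, function(v)
    if (inherits(v, "pattern_recipe")) recipe_to_list(v) else v)
  list(family = r$family, uid = r$uid, params = p)
}

recipe_from_list <- function(l) {
  p <- l$params
  if (l$family == "mirror") p$base <- recipe_from_list(p$base)
  if (!is.null(p$bars)) p$bars <- lapply(p$bars, as.list)
  for (nm in c("orientations", "counts"))
    if (!is.null(p[[nm]])) p[[nm]] <- as.numeric(unlist(p[[nm]]))
  do.call(pattern_recipe, c(list(family = l$family, uid = l$uid), p))
}

#' Load / write a study file (YAML)
#'
#' @param path File path.
#' @param study A list of class `"study_file"` with `study_id`,
#'   `recipes` (named list of [pattern_recipe()]), `experiments` (named
#'   lists; discrimination entries carry `cs`/`cor`/`inc` and optional
#'   `offsets`, generalization entries carry `cs_set`/`reciprocal_set`).
#' @return `load_study`: the `study_file`; `write_study`: `path`,
#'   invisibly.
#' @export
load_study <- function(path) {
  y <- yaml::read_yaml(path)
  for (f in c("study_id", "experiments", "recipes"))
    if (is.null(y[[f]])) stop("study file missing field '", f, "': ", path)
  recipes <- lapply(y$recipes, recipe_from_list)
  uids <- names(recipes)
  for (k in seq_along(y$experiments)) {
    e <- y$experiments[[k]]
    refs <- unlist(e[intersect(names(e),
                               c("cs", "cor", "inc", "cs_set",
                                 "reciprocal_set", "reciprocal_cor",
                                 "reciprocal_inc"))])
    bad <- setdiff(refs, uids)
    if (length(bad))
      stop("experiment ", k, " ('", e$id, "') references unknown UID(s): ",
           paste(bad, collapse = ", "))
  }
  structure(list(study_id = y$study_id, recipes = recipes,
                 experiments = y$experiments),
            class = "study_file")
}

#' @rdname load_study
#' @export
write_study <- function(study, path) {
  stopifnot(inherits(study, "study_file"))
  y <- list(study_id = study$study_id,
            experiments = study$experiments,
            recipes = lapply(study$recipes, recipe_to_list))
  yaml::write_yaml(y, path)
  invisible(path)
}

new_study <- function(study_id, recipes, experiments) {
  names(recipes) <- vapply(recipes, `[[`, character(1), "uid")
  structure(list(study_id = study_id, recipes = recipes,
                 experiments = experiments),
            class = "study_file")
}

#' @export
print.study_file <- function(x, ...) {
  cat(sprintf("<study_file '%s': %d experiments, %d recipes>\n",
              x$study_id, length(x$experiments), length(x$recipes)))
  invisible(x)
}

#' Render every recipe of a study into a pattern library
#' @param study A `study_file`.
#' @return Named list of `stimulus_image` tiles keyed by UID.
#' @export
build_patterns <- function(study) {
  stopifnot(inherits(study, "study_file"))
  lapply(study$recipes, make_pattern)
}

#' Run every experiment of a study
#'
#' Discrimination entries run once per offset in their `offsets` field
#' (default 0); generalization entries run with full triplet
#' enumeration. Identical `(study, seed)` input reproduces the results
#' table bit for bit.
#'
#' @param study A `study_file`.
#' @param model `"DISTINCT"` or `"MERGED"`.
#' @param patterns Pattern library (default: rendered from the study).
#' @param config A [beekc_config()].
#' @param n_trials Override of each experiment's trial count (optional).
#' @param seed Base seed; experiment k / offset j derive distinct
#'   sub-seeds.
#' @return Results data frame (see [results_table()]).
#' @export
run_study <- function(study, model = "DISTINCT",
                      patterns = build_patterns(study),
                      config = beekc_config(), n_trials = NULL,
                      seed = NULL) {
  stopifnot(inherits(study, "study_file"))
  rows <- list()
  for (k in seq_along(study$experiments)) {
    e <- study$experiments[[k]]
    nt <- if (!is.null(n_trials)) n_trials else
      if (!is.null(e$n_trials)) e$n_trials else 1000L
    bee <- if (!is.null(e$bee_pct)) e$bee_pct else NA_real_
    if (!is.null(e$cs_set)) {
      res <- run_generalization(
        cs_set = e$cs_set, cor = e$cor, inc = e$inc,
        reciprocal_set = e$reciprocal_set,
        reciprocal_cor = if (!is.null(e$reciprocal_cor)) e$reciprocal_cor
                         else e$inc,
        reciprocal_inc = if (!is.null(e$reciprocal_inc)) e$reciprocal_inc
                         else e$cor,
        model = model, patterns = patterns, n_trials = nt,
        config = config,
        seed = if (is.null(seed)) NULL else seed + 1000L * k,
        id = e$id, bee_pct = bee)
      rows[[length(rows) + 1]] <- results_table(res)
    } else {
      offsets <- if (!is.null(e$offsets)) as.integer(unlist(e$offsets))
                 else 0L
      res <- run_offset_sweep(e$cs, e$cor, e$inc, model, patterns,
                              offsets = offsets, n_trials = nt,
                              config = config,
                              seed = if (is.null(seed)) NULL
                                     else seed + 1000L * k,
                              id = e$id, bee_pct = bee)
      rows[[length(rows) + 1]] <- results_table(res)
    }
  }
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------
# Shipped suites. Pattern geometry recreates the published stimuli at
# the level of their described structure (bar layouts, rotations,
# mirrorings); the exact sector/spiral/octagon proportions are only
# depicted in the source figures, so the generator defaults below are
# the package's recorded recreation (see the methods vignette).
# ---------------------------------------------------------------------

hbar_set <- function(angle, uid) {
  offs <- c(-50, 0, 50)
  bars <- lapply(offs, function(o)
    list(angle = angle, length = 140, width = 20,
         cx = -o * deg_sin(angle), cy = o * deg_cos(angle)))
  pattern_recipe("bar_set", bars = bars, uid = uid)
}

#' The discrimination suite: seven pattern pairs with offset sweeps
#'
#' Seven rewarded/rotated-or-mirrored pairs emulating the classic
#' free-flight discrimination stimuli: oriented gratings, a four-sector
#' disc, crosses, two multi-bar patterns against their left/right
#' reversals (experiments 4 and 6), mirror-image spirals, and octagonal
#' rings. Each experiment is a 17-offset sweep with TS_COR identical to
#' CS+ and TS_INC the rotated/mirrored partner. Honeybee percentages are
#' attached where the source behavioural work reports them.
#'
#' @return A `study_file`.
#' @export
study_discrimination <- function() {
  q4 <- function(uid, orientations, counts)
    pattern_recipe("quadrant_bars", orientations = orientations,
                   counts = counts, uid = uid)
  spiral <- pattern_recipe("spiral_disc", n_arms = 4, twist = 360,
                           handedness = 1, uid = "spiral_cw")
  # reversal pairs use axial (0/90 deg) bars: their pixel mirror presents
  # the same orientations in the reverse eyes, the defining property of
  # the left/right-reversed stimuli
  rev4 <- q4("bars_axial_a", c(0, 90, 90, 0), c(1, 1, 1, 1))
  rev6 <- q4("bars_axial_b", c(90, 90, 0, 0), c(2, 2, 2, 2))
  recipes <- list(
    hbar_set(0, "grating_horizontal"),
    hbar_set(90, "grating_vertical"),
    pattern_recipe("sector_disc", n_sectors = 4, rotation = 0,
                   uid = "sectors4"),
    pattern_recipe("sector_disc", n_sectors = 4, rotation = 45,
                   uid = "sectors4_rot45"),
    pattern_recipe("cross", rotation = 0, uid = "cross_plus"),
    pattern_recipe("cross", rotation = 45, uid = "cross_diag"),
    rev4,
    pattern_recipe("mirror", base = rev4, uid = "bars_axial_a_rev"),
    spiral,
    pattern_recipe("mirror", base = spiral, uid = "spiral_ccw"),
    rev6,
    pattern_recipe("mirror", base = rev6, uid = "bars_axial_b_rev"),
    pattern_recipe("octagon", rotation = 0, uid = "octagon_ring"),
    pattern_recipe("octagon", rotation = 22.5, uid = "octagon_ring_rot")
  )
  sweep17 <- seq(-200L, 200L, by = 25L)
  exps <- list(
    list(id = "gratings", cs = "grating_horizontal",
         cor = "grating_horizontal", inc = "grating_vertical",
         offsets = sweep17, bee_pct = 67),
    list(id = "sectors", cs = "sectors4", cor = "sectors4",
         inc = "sectors4_rot45", offsets = sweep17, bee_pct = NA),
    list(id = "crosses", cs = "cross_plus", cor = "cross_plus",
         inc = "cross_diag", offsets = sweep17, bee_pct = NA),
    list(id = "reversal_a", cs = "bars_axial_a", cor = "bars_axial_a",
         inc = "bars_axial_a_rev", offsets = sweep17, bee_pct = 62),
    list(id = "spirals", cs = "spiral_cw", cor = "spiral_cw",
         inc = "spiral_ccw", offsets = sweep17, bee_pct = 53.7),
    list(id = "reversal_b", cs = "bars_axial_b", cor = "bars_axial_b",
         inc = "bars_axial_b_rev", offsets = sweep17, bee_pct = 65),
    list(id = "octagons", cs = "octagon_ring", cor = "octagon_ring",
         inc = "octagon_ring_rot", offsets = sweep17, bee_pct = 56.4)
  )
  new_study("discrimination_set1", recipes, exps)
}

# per-quadrant bar orientations of the two generalization training sets
# (canonical quadrant order dorsal_left, ventral_left, dorsal_right,
# ventral_right); set B is set A rotated by 90 degrees in every quadrant
GEN_ORIENT_A <- c(45, 90, 0, 135)
GEN_ORIENT_B <- (GEN_ORIENT_A + 90) %% 180

gen_variants <- function() list(
  list(counts = c(1, 1, 1, 1), bar_length = 56, bar_width = 10),
  list(counts = c(2, 2, 2, 2), bar_length = 56, bar_width = 10),
  list(counts = c(1, 2, 1, 2), bar_length = 56, bar_width = 10),
  list(counts = c(2, 1, 2, 1), bar_length = 56, bar_width = 10),
  list(counts = c(1, 1, 1, 1), bar_length = 70, bar_width = 14),
  list(counts = c(2, 2, 2, 2), bar_length = 44, bar_width = 8,
       spacing = 24)
)

#' The generalization suite: quadrant-bar training sets and test batches
#'
#' Two training sets of six quadrant-bar patterns (set B carries each
#' quadrant's bars rotated by 90 degrees relative to set A). Batch (i)
#' tests simple generalization to three novel pattern-pair styles whose
#' correct member keeps the trained per-quadrant orientations; batch
#' (iv) tests the original layout against its left/right reversal, with
#' reciprocal training included by enumeration; a checkerboard
#' distractor pair represents the final batch. All patterns are
#' presented centred.
#'
#' @return A `study_file`.
#' @export
study_generalization <- function() {
  qr <- function(uid, orientations, v)
    do.call(pattern_recipe,
            c(list("quadrant_bars", orientations = orientations, uid = uid),
              v))
  vars <- gen_variants()
  trainA <- lapply(seq_along(vars), function(i)
    qr(sprintf("setA_%d", i), GEN_ORIENT_A, vars[[i]]))
  trainB <- lapply(seq_along(vars), function(i)
    qr(sprintf("setB_%d", i), GEN_ORIENT_B, vars[[i]]))
  styles <- list(
    list(counts = c(3, 3, 3, 3), bar_length = 40, bar_width = 8),
    list(counts = c(1, 1, 1, 1), bar_length = 64, bar_width = 16),
    list(counts = c(2, 2, 2, 2), bar_length = 60, bar_width = 6,
         spacing = 16)
  )
  tests <- list()
  for (i in seq_along(styles)) {
    tests[[length(tests) + 1]] <-
      qr(sprintf("novelA_%d", i), GEN_ORIENT_A, styles[[i]])
    tests[[length(tests) + 1]] <-
      qr(sprintf("novelB_%d", i), GEN_ORIENT_B, styles[[i]])
  }
  proto_style <- list(counts = c(1, 1, 1, 1), bar_length = 60,
                      bar_width = 12)
  # the left/right reversal swaps each quadrant's bars to the opposite
  # eye while preserving their orientations (quadrant order is DL, VL,
  # DR, VR, so the eye swap is the permutation 3,4,1,2)
  eyeswap <- c(3, 4, 1, 2)
  extras <- list(
    qr("protoA", GEN_ORIENT_A, proto_style),
    qr("protoB", GEN_ORIENT_B, proto_style),
    qr("protoA_rev", GEN_ORIENT_A[eyeswap], proto_style),
    qr("protoB_rev", GEN_ORIENT_B[eyeswap], proto_style),
    pattern_recipe("checkerboard", check_size = 25, uid = "checker25")
  )
  setA <- sprintf("setA_%d", seq_along(vars))
  setB <- sprintf("setB_%d", seq_along(vars))
  exps <- c(
    lapply(1:3, function(i)
      list(id = sprintf("simple_generalization_%d", i),
           cs_set = setA, reciprocal_set = setB,
           cor = sprintf("novelA_%d", i), inc = sprintf("novelB_%d", i),
           bee_pct = c(72, 68, 70)[i])),
    list(
      # reciprocally trained bees face their own set's original layout
      # and its reversal, not the role swap of the set-A pair
      list(id = "original_vs_reversal",
           cs_set = setA, reciprocal_set = setB,
           cor = "protoA", inc = "protoA_rev",
           reciprocal_cor = "protoB", reciprocal_inc = "protoB_rev",
           bee_pct = 69),
      list(id = "original_vs_checkerboard",
           cs_set = setA, reciprocal_set = setB,
           cor = "protoA", inc = "checker25",
           reciprocal_cor = "protoB", reciprocal_inc = "checker25",
           bee_pct = 65)
    )
  )
  new_study("generalization_set2", c(trainA, trainB, tests, extras), exps)
}

#' The cross-pattern suite
#'
#' (a) a 90 degree plus cross against its 45 degree rotation -- the pair
#' honeybees surprisingly fail; (b) a narrow 22.5 degree cross against
#' its 90 degree rotation -- discriminated by bees and both models.
#'
#' @return A `study_file`.
#' @export
study_crosses <- function() {
  recipes <- list(
    pattern_recipe("cross", rotation = 0, uid = "cross90_0"),
    pattern_recipe("cross", rotation = 45, uid = "cross90_45"),
    pattern_recipe("cross", rotation = 0, opening = 22.5,
                   uid = "cross22_0"),
    pattern_recipe("cross", rotation = 90, opening = 22.5,
                   uid = "cross22_90")
  )
  exps <- list(
    list(id = "cross90_vs_rot45", cs = "cross90_0", cor = "cross90_0",
         inc = "cross90_45", bee_pct = 50),
    list(id = "cross22_vs_rot90", cs = "cross22_0", cor = "cross22_0",
         inc = "cross22_90", bee_pct = 75)
  )
  new_study("cross_patterns", recipes, exps)
}
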