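#' Experiment orchestration
#'
#' An experiment presents a (CS+, TS_COR, TS_INC) pattern triplet to a
#' Kenyon cell population model and scores it by the Kenyon cell
#' similarity ratio over repeated noisy trials. The rewarded CS+ is
#' always processed in the centre of the 300 x 150 field of view; test
#' stimuli may be horizontally offset. Performance percent is 100 times
#' the mean KCSR.
#'
#' @name experiments
NULL

#' Experiment specification
#'
#' @param id Experiment identifier.
#' @param cs CS+ pattern UID (a set of UIDs for generalization runs).
#' @param cor,inc Test stimulus UIDs (correct / incorrect).
#' @param model `"DISTINCT"` or `"MERGED"`.
#' @param n_trials Simulation trials (default 1000).
#' @param offset Horizontal test-stimulus offset in pixels (default 0).
#' @param bee_pct Optional published honeybee percent-correct, carried
#'   as metadata only.
#' @return A list of class `"experiment_spec"`.
#' @export
experiment_spec <- function(id, cs, cor, inc, model = "DISTINCT",
                            n_trials = 1000L, offset = 0L,
                            bee_pct = NA_real_) {
  stopifnot(n_trials >= 1)
  if (length(cs) == 1 && (cs == cor) + (cs == inc) + (cor == inc) > 1)
    stop("the three triplet roles must name distinct stimuli ",
         "(CS+ may equal TS_COR for discrimination runs)")
  if (cor == inc) stop("TS_COR and TS_INC must differ")
  structure(list(id = id, cs = cs, cor = cor, inc = inc,
                 model = toupper(model), n_trials = as.integer(n_trials),
                 offset = as.integer(offset), bee_pct = bee_pct),
            class = "experiment_spec")
}

# resolve a UID to a rendered 150x150 tile from a pattern library
# (entries may be stimulus_image tiles or pattern_recipe objects)
resolve_tile <- function(uid, patterns) {
  obj <- patterns[[uid]]
  if (is.null(obj)) stop("unresolvable pattern UID: ", uid)
  if (inherits(obj, "pattern_recipe")) {
    img <- make_pattern(obj)
    img$uid <- uid
    img
  } else if (inherits(obj, "stimulus_image")) obj
  else stop("pattern library entry '", uid, "' is neither a recipe nor ",
            "a stimulus_image")
}

# LOSN vector of a tile composited at a horizontal offset (memoised via
# the preprocess cache)
losn_at_offset <- function(uid, patterns, offset, config) {
  frame <- composite_offset(resolve_tile(uid, patterns), offset)
  losn_vector(preprocess(frame, config), config)
}

# KCSR trial engine: chunked activation sampling for the three patterns
kcsr_trials <- function(losn_cs, losn_cor, losn_inc, pop, n_trials,
                        config) {
  chunk <- max(1L, as.integer(4e6 %/% pop$size))
  out <- numeric(n_trials)
  done <- 0L
  while (done < n_trials) {
    nt <- min(chunk, n_trials - done)
    a_cs <- activation_matrix(pop, losn_cs, nt, config)
    a_cor <- activation_matrix(pop, losn_cor, nt, config)
    a_inc <- activation_matrix(pop, losn_inc, nt, config)
    e_cor <- sqrt(.colSums(a_cs != a_cor, pop$size, nt))
    e_inc <- sqrt(.colSums(a_cs != a_inc, pop$size, nt))
    tot <- e_cor + e_inc
    out[done + seq_len(nt)] <- ifelse(tot > 0, 1 - e_cor / tot, 0.5)
    done <- done + nt
  }
  out
}

summarise_trials <- function(trials, id, model, offset, bee_pct = NA_real_,
                             seed = NA_integer_) {
  structure(list(id = id, model = model, offset = offset,
                 n_trials = length(trials), trials = trials,
                 mean = mean(trials), sd = stats::sd(trials),
                 min = min(trials), max = max(trials),
                 performance = 100 * mean(trials),
                 bee_pct = bee_pct, seed = seed),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result '%s' %s offset %+d px: %d trials>\n",
              x$id, x$model, x$offset, x$n_trials))
  cat(sprintf("  KCSR mean %.4f (sd %.4f, min %.4f, max %.4f)\n",
              x$mean, if (is.na(x$sd)) 0 else x$sd, x$min, x$max))
  cat(sprintf("  performance %.1f%%%s\n", x$performance,
              if (!is.na(x$bee_pct))
                sprintf("  (honeybee %.1f%%)", x$bee_pct) else ""))
  invisible(x)
}

#' Run a single simulation trial
#'
#' One noisy Kenyon cell activation per pattern, one KCSR.
#'
#' @param spec An [experiment_spec()].
#' @param patterns Named pattern library (UID -> recipe or tile).
#' @param config A [beekc_config()].
#' @param pop Optional prebuilt `kc_population` matching `spec$model`.
#' @return The trial's KCSR (numeric scalar).
#' @export
run_trial <- function(spec, patterns, config = beekc_config(),
                      pop = NULL) {
  stopifnot(inherits(spec, "experiment_spec"), length(spec$cs) == 1)
  if (is.null(pop))
    pop <- build_population(spec$model, copies = config$copies_per_config)
  l_cs <- losn_at_offset(spec$cs, patterns, 0L, config)
  l_cor <- losn_at_offset(spec$cor, patterns, spec$offset, config)
  l_inc <- losn_at_offset(spec$inc, patterns, spec$offset, config)
  kcsr_trials(l_cs, l_cor, l_inc, pop, 1L, config)
}

#' Run a full experiment
#'
#' Repeats the triplet simulation `spec$n_trials` times and aggregates
#' the per-trial KCSRs. CS+ is presented centred; test stimuli at
#' `spec$offset`.
#'
#' @inheritParams run_trial
#' @param seed Optional integer; seeds the RNG for a reproducible run.
#' @return An `experiment_result` (mean/sd/min/max KCSR, performance %).
#' @export
run_experiment <- function(spec, patterns, config = beekc_config(),
                           pop = NULL, seed = NULL) {
  stopifnot(inherits(spec, "experiment_spec"), length(spec$cs) == 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pop))
    pop <- build_population(spec$model, copies = config$copies_per_config)
  l_cs <- losn_at_offset(spec$cs, patterns, 0L, config)
  l_cor <- losn_at_offset(spec$cor, patterns, spec$offset, config)
  l_inc <- losn_at_offset(spec$inc, patterns, spec$offset, config)
  trials <- kcsr_trials(l_cs, l_cor, l_inc, pop, spec$n_trials, config)
  summarise_trials(trials, spec$id, spec$model, spec$offset, spec$bee_pct,
                   if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Run a generalization test with full triplet enumeration
#'
#' Every pattern of the rewarded training set serves as CS+ against the
#' fixed test pair; patterns of the reciprocal training set (bees trained
#' with the roles of the two sets exchanged) serve as CS+ against their
#' according test pair, which defaults to the role-swapped `(inc, cor)`.
#' Each triplet runs `n_trials` times; all triplets are weighted equally
#' and their KCSRs pooled into the overall result.
#'
#' @param cs_set Character vector of CS+ UIDs (the rewarded training
#'   set).
#' @param cor,inc Test pair UIDs for `cs_set`.
#' @param reciprocal_set UIDs of the reciprocal training set (optional).
#' @param reciprocal_cor,reciprocal_inc Test pair for the reciprocal
#'   set; defaults to the role-swapped `(inc, cor)`.
#' @param model `"DISTINCT"` or `"MERGED"`.
#' @param patterns Named pattern library.
#' @param n_trials Trials per triplet.
#' @param config A [beekc_config()].
#' @param seed Optional integer seed.
#' @param id Result identifier.
#' @param bee_pct Metadata only.
#' @return An `experiment_result` over all pooled trials, with the
#'   per-triplet results in `$triplets`.
#' @export
run_generalization <- function(cs_set, cor, inc, reciprocal_set = NULL,
                               reciprocal_cor = inc, reciprocal_inc = cor,
                               model = "DISTINCT", patterns,
                               n_trials = 1000L,
                               config = beekc_config(), seed = NULL,
                               id = "generalization",
                               bee_pct = NA_real_) {
  if (!length(cs_set)) stop("empty CS+ pattern set")
  if (!is.null(seed)) set.seed(seed)
  pop <- build_population(model, copies = config$copies_per_config)
  triplets <- c(lapply(cs_set, function(u) c(u, cor, inc)),
                lapply(reciprocal_set, function(u)
                  c(u, reciprocal_cor, reciprocal_inc)))
  results <- lapply(triplets, function(tr) {
    l <- lapply(tr, losn_at_offset, patterns = patterns, offset = 0L,
                config = config)
    trials <- kcsr_trials(l[[1]], l[[2]], l[[3]], pop, n_trials, config)
    summarise_trials(trials, paste(tr, collapse = " | "), model, 0L)
  })
  pooled <- summarise_trials(unlist(lapply(results, `[[`, "trials")),
                             id, model, 0L, bee_pct,
                             if (is.null(seed)) NA_integer_
                             else as.integer(seed))
  pooled$triplets <- results
  pooled
}

#' Horizontal offset sweep
#'
#' Runs one experiment per offset: CS+ stays centred, both test stimuli
#' are composited at the offset. The canonical protocol uses 17 offsets,
#' -200..+200 px in 25 px steps.
#'
#' @param cs,cor,inc Pattern UIDs.
#' @param model `"DISTINCT"` or `"MERGED"`.
#' @param patterns Named pattern library.
#' @param offsets Integer offsets in pixels.
#' @param n_trials Trials per offset.
#' @param config A [beekc_config()].
#' @param seed Optional base seed; offset k runs at `seed + k`.
#' @param id Experiment identifier stem.
#' @param bee_pct Metadata only.
#' @return A list of `experiment_result`, one per offset, in order.
#' @export
run_offset_sweep <- function(cs, cor, inc, model = "DISTINCT", patterns,
                             offsets = seq(-200L, 200L, by = 25L),
                             n_trials = 1000L, config = beekc_config(),
                             seed = NULL, id = "sweep",
                             bee_pct = NA_real_) {
  pop <- build_population(model, copies = config$copies_per_config)
  lapply(seq_along(offsets), function(k) {
    sp <- experiment_spec(id, cs, cor, inc, model, n_trials, offsets[k],
                          bee_pct)
    run_experiment(sp, patterns, config, pop,
                   seed = if (is.null(seed)) NULL else seed + k)
  })
}

#' Collect experiment results into a results table
#'
#' @param results A list of `experiment_result` objects.
#' @return A data frame with one row per result: `experiment_id`,
#'   `model`, `offset_px`, `n_trials`, `kcsr_mean`, `kcsr_sd`,
#'   `kcsr_min`, `kcsr_max`, `performance_pct`, `bee_pct`, `seed`.
#' @export
results_table <- function(results) {
  if (inherits(results, "experiment_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r)
    data.frame(experiment_id = r$id, model = r$model, offset_px = r$offset,
               n_trials = r$n_trials, kcsr_mean = r$mean,
               kcsr_sd = if (is.na(r$sd)) 0 else r$sd,
               kcsr_min = r$min, kcsr_max = r$max,
               performance_pct = r$performance, bee_pct = r$bee_pct,
               seed = r$seed)))
}

#' Write a results table to CSV
#' @param results List of `experiment_result` or a results data frame.
#' @param path Output file.
#' @export
write_results <- function(results, path) {
  df <- if (is.data.frame(results)) results else results_table(results)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
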