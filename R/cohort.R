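#' Latin-hypercube sample of subject parameter sets
#'
#' Draws `n` parameter vectors by Latin hypercube sampling, each parameter
#' independently stratified into `n` equal-width strata of
#' `[nominal * (1 - spread), nominal * (1 + spread)]` with one draw per
#' stratum, randomly permuted across parameters.
#'
#' @param n number of parameter sets.
#' @param nominal a [subject_params()] object of nominal values.
#' @param spread half-width of the sampling interval as a fraction of the
#'   nominal value (default 0.70).
#' @return Data frame with `n` rows and one column per parameter (see
#'   [subject_param_names()]).
#' @export
lhs_sample <- function(n, nominal = subject_params(), spread = 0.70) {
  stopifnot(n >= 1, spread > 0, spread < 1)
  nm <- subject_param_names()
  u <- lhs::randomLHS(n, length(nm))
  lo <- unlist(nominal)[nm] * (1 - spread)
  hi <- unlist(nominal)[nm] * (1 + spread)
  out <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(out) <- nm
  as.data.frame(out)
}

#' Baseline (resting) vital signs of a subject
#'
#' The surrogate's steady state at zero perturbation is `(HR0, SBP0)`; a
#' short settling simulation (5 min, no bleeding) is still run so that the
#' baseline remains correct if the surrogate dynamics change.
#'
#' @param params a [subject_params()] object.
#' @param settle settling simulation length (min).
#' @return Named numeric vector `c(hr, sbp)`.
#' @export
baseline_vitals <- function(params, settle = 5) {
  tr <- simulate_vitals(params, sim_input(bleed_rate = 0, t1 = 0,
                                          horizon = settle))
  n <- length(tr$hr)
  c(hr = tr$hr[n], sbp = tr$sbp[n])
}

#' Stage-1 filter: healthy initial range
#'
#' Keeps subjects whose baseline vitals satisfy 60 < HR < 100 beats/min
#' (excluding bradycardia and tachycardia) and 100 < SBP < 140 mmHg
#' (excluding hypotension and hypertension), with strict inequalities.
#'
#' @param pop data frame of parameter sets (rows) as from [lhs_sample()].
#' @return The kept rows, with `baseline_hr` and `baseline_sbp` columns
#'   appended.
#' @export
stage1_filter <- function(pop) {
  base <- t(vapply(seq_len(nrow(pop)),
                   function(i) baseline_vitals(as_subject_params(pop[i, ])),
                   numeric(2)))
  pop$baseline_hr <- base[, 1]
  pop$baseline_sbp <- base[, 2]
  keep <- pop$baseline_hr > 60 & pop$baseline_hr < 100 &
    pop$baseline_sbp > 100 & pop$baseline_sbp < 140
  pop[keep, , drop = FALSE]
}

#' Stage-2 filter: simulability at the hemorrhage extremes
#'
#' Simulates every subject under the five pentagon-vertex hemorrhage
#' scenarios (no residual bleeding, no infusion, 90-min horizon) and keeps
#' subjects for which all five runs complete, stay within the physiological
#' range (40--200 beats/min, 40--260 mmHg), and show no vital-sign
#' oscillations.
#'
#' @param pop stage-1 output.
#' @param vertices scenario matrix, by default [pentagon_vertices()].
#' @return The kept rows.
#' @export
stage2_filter <- function(pop, vertices = pentagon_vertices()) {
  ok <- vapply(seq_len(nrow(pop)), function(i) {
    p <- as_subject_params(pop[i, ])
    for (v in seq_len(nrow(vertices))) {
      Tb <- vertices[v, 1]; V <- vertices[v, 2]
      tr <- simulate_vitals(p, sim_input(bleed_rate = V / Tb, t1 = Tb,
                                         horizon = 90))
      if (!tr$completed || !tr$in_physiological_range ||
          isTRUE(tr$oscillatory)) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  pop[ok, , drop = FALSE]
}

#' Stage-3 filter: symptomatic at the start of resuscitation
#'
#' Assigns each subject one hemorrhage scenario sampled from the admissible
#' pentagon and an event timeline, simulates to `t2`, and keeps subjects
#' whose vitals at `t2` violate the healthy target range (HR > 100 beats/min
#' or SBP < 100 mmHg) -- casualties inside the target range would not be
#' treated and are discarded.
#'
#' @param pop stage-2 output.
#' @return List of casualty stubs: each a list with `params`, `baseline`,
#'   `hemorrhage` (one-row data frame), and `times`.
#' @export
stage3_filter <- function(pop) {
  out <- list()
  for (i in seq_len(nrow(pop))) {
    spec <- sample_hemorrhage(1)
    times <- sample_event_times(spec$T_b)
    p <- as_subject_params(pop[i, ])
    tr <- simulate_vitals(p, sim_input(bleed_rate = spec$rate, t1 = spec$T_b,
                                       horizon = times$t2))
    n <- length(tr$hr)
    if (!tr$completed) next
    if (is_restored(tr$hr[n], tr$sbp[n])) next  # healthy at t2: no treatment
    out[[length(out) + 1L]] <- list(
      params = p,
      baseline = c(hr = pop$baseline_hr[i], sbp = pop$baseline_sbp[i]),
      hemorrhage = spec,
      times = times)
  }
  out
}

#' Generate the four ground-truth treatment trajectories for a casualty
#'
#' @param casualty a casualty stub from [stage3_filter()].
#' @param f_nc residual bleeding fraction (0 for the controlled scenario).
#' @return List of four `vitals_trajectory` objects indexed by option id.
#' @export
casualty_trajectories <- function(casualty, f_nc = 0) {
  lapply(1:4, function(opt) {
    inp <- sim_input(bleed_rate = casualty$hemorrhage$rate,
                     t1 = casualty$hemorrhage$T_b, f_nc = f_nc,
                     infusion = infusion_schedule(opt, casualty$times),
                     horizon = casualty$times$t3)
    simulate_vitals(casualty$params, inp)
  })
}

#' Build a down-selected casualty cohort
#'
#' Runs the full three-stage funnel: Latin-hypercube sampling of candidate
#' subjects around the nominal parameters, stage-1 healthy-baseline
#' screening, stage-2 simulability screening at the five hemorrhage-region
#' vertices, and stage-3 retention of casualties symptomatic at `t2`.
#' Sampling rounds repeat until at least `n_f` casualties are available;
#' the pool is then randomly deselected down to exactly `n_f`, folds are
#' assigned by random permutation into 5 equal groups, and the four
#' ground-truth treatment trajectories are generated per casualty.
#'
#' @param n_f target cohort size; must be divisible by 5 (default 160).
#' @param pool_size candidate parameter sets per sampling round (default
#'   5000).
#' @param spread Latin-hypercube spread fraction (default 0.70).
#' @param max_rounds sampling rounds before giving up.
#' @param nominal nominal [subject_params()].
#' @return Object of class `cohort`: list with `casualties` (each carrying
#'   `id`, `params`, `baseline`, `hemorrhage`, `times`, `trajectories`),
#'   `n_f`, `fold` (integer vector, 1..5), `attrition` (per-round stage
#'   counts), and `config`.
#' @examples
#' \donttest{
#' set.seed(1)
#' coh <- build_cohort(n_f = 10, pool_size = 600)
#' length(coh$casualties)
#' }
#' @export
build_cohort <- function(n_f = 160, pool_size = 5000, spread = 0.70,
                         max_rounds = 20, nominal = subject_params()) {
  if (n_f %% 5 != 0) stop("n_f must be divisible by 5")
  stubs <- list()
  attrition <- data.frame(round = integer(), sampled = integer(),
                          stage1 = integer(), stage2 = integer(),
                          stage3 = integer())
  round_i <- 0L
  while (length(stubs) < n_f) {
    round_i <- round_i + 1L
    if (round_i > max_rounds) {
      stop(sprintf(paste0("pool exhausted after %d rounds: %d of %d ",
                          "casualties; attrition: %s"),
                   max_rounds, length(stubs), n_f,
                   paste(utils::capture.output(print(attrition)),
                         collapse = "\n")))
    }
    pop <- lhs_sample(pool_size, nominal = nominal, spread = spread)
    s1 <- stage1_filter(pop)
    s2 <- stage2_filter(s1)
    s3 <- stage3_filter(s2)
    attrition <- rbind(attrition,
                       data.frame(round = round_i, sampled = pool_size,
                                  stage1 = nrow(s1), stage2 = nrow(s2),
                                  stage3 = length(s3)))
    stubs <- c(stubs, s3)
  }
  keep <- sort(sample.int(length(stubs), n_f))
  stubs <- stubs[keep]
  for (i in seq_along(stubs)) {
    stubs[[i]]$id <- i
    stubs[[i]]$trajectories <- casualty_trajectories(stubs[[i]])
  }
  fold <- sample(rep(1:5, each = n_f / 5))
  structure(list(casualties = stubs, n_f = n_f, fold = fold,
                 attrition = attrition,
                 config = list(pool_size = pool_size, spread = spread,
                               nominal = unclass(nominal))),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d casualties, %d trajectories, 5 folds of %d\n",
              x$n_f, 4L * x$n_f, x$n_f / 5L))
  invisible(x)
}

#' Observed pre-treatment monitoring window of a casualty
#'
#' The 10 minutes of measured vitals immediately before `t2` (minutes
#' `t2-10 .. t2-1`), with zero infusion. Identical across treatment options
#' since no fluid is given before `t2`.
#'
#' @param casualty a cohort casualty.
#' @param len window length in minutes (default 10).
#' @return Matrix with `len` rows and columns `u` (L/h), `hr`, `sbp`.
#' @export
warmup_window <- function(casualty, len = 10) {
  tr <- casualty$trajectories[[1]]
  t2 <- casualty$times$t2
  idx <- which(tr$times %in% (t2 - len):(t2 - 1))
  cbind(u = numeric(length(idx)), hr = tr$hr[idx], sbp = tr$sbp[idx])
}

#' Measured vitals of a casualty at a given minute
#'
#' @param casualty a cohort casualty.
#' @param option_id ground-truth trajectory to read.
#' @param minute minute on the trajectory grid.
#' @return Named vector `c(hr, sbp)`.
#' @export
vitals_at <- function(casualty, option_id, minute) {
  tr <- casualty$trajectories[[option_id]]
  i <- match(minute, tr$times)
  c(hr = unname(tr$hr[i]), sbp = unname(tr$sbp[i]))
}

#' Serialize / load a cohort as JSON + per-trajectory CSV files
#'
#' Writes `cohort.json` (subjects, scenarios, folds, attrition, config) and
#' one `traj_<id>_opt<k>.csv` per (casualty, option) into `dir`, plus a
#' `manifest.json` of stage attrition counts.
#'
#' @param cohort a [build_cohort()] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    n_f = cohort$n_f,
    fold = cohort$fold,
    config = cohort$config,
    casualties = lapply(cohort$casualties, function(cs) {
      list(id = cs$id, params = unclass(cs$params),
           baseline = as.list(cs$baseline),
           hemorrhage = as.list(cs$hemorrhage),
           times = cs$times)
    }))
  jsonlite::write_json(meta, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(cohort$attrition, file.path(dir, "manifest.json"),
                       digits = NA)
  for (cs in cohort$casualties) {
    for (opt in 1:4) {
      write_trajectory(cs$trajectories[[opt]],
                       file.path(dir, sprintf("traj_%03d_opt%d.csv",
                                              cs$id, opt)))
    }
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"),
                              simplifyVector = TRUE, simplifyDataFrame = FALSE)
  attrition <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                   simplifyVector = TRUE)
  casualties <- lapply(meta$casualties, function(cs) {
    cs$params <- as_subject_params(cs$params)
    cs$baseline <- unlist(cs$baseline)
    cs$hemorrhage <- as.data.frame(cs$hemorrhage)
    cs$trajectories <- lapply(1:4, function(opt) {
      read_trajectory(file.path(dir, sprintf("traj_%03d_opt%d.csv",
                                             cs$id, opt)))
    })
    cs
  })
  structure(list(casualties = casualties, n_f = meta$n_f,
                 fold = unlist(meta$fold), attrition = as.data.frame(attrition),
                 config = meta$config),
            class = "cohort")
}
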