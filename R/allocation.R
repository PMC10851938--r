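#' Healthy target range test
#'
#' A casualty counts as restored when HR <= 100 beats/min AND
#' SBP >= 100 mmHg (inclusive bounds, the two-step transfusion guideline's
#' target range).
#'
#' @param hr,sbp vitals (vectorized).
#' @return Logical vector.
#' @examples
#' is_restored(95, 105)   # TRUE
#' is_restored(95, 90)    # FALSE: SBP outside
#' is_restored(100, 100)  # TRUE: bounds inclusive
#' @export
is_restored <- function(hr, sbp) {
  hr <= 100 & sbp >= 100
}

# Read restored status at t3 of a casualty's stored ground-truth trajectory.
restored_at_t3 <- function(casualty, option_id) {
  v <- vitals_at(casualty, option_id, casualty$times$t3)
  is_restored(v["hr"], v["sbp"])
}

#' Ground-truth fluid need of a casualty
#'
#' Scans the four stored ground-truth trajectories and returns the
#' minimum-unit option whose vitals at `t3` are restored. The 1-unit tie
#' between options 2 (late unit) and 3 (early unit) is broken toward option
#' 3 (fluid earlier).
#'
#' @param casualty a cohort casualty with all four trajectories.
#' @return List with `units` (0, 1, 2, or `NA` when no option restores,
#'   i.e. unrestorable) and `option` (the chosen option id, `NA` if
#'   unrestorable).
#' @export
oracle_needs <- function(casualty) {
  if (length(casualty$trajectories) != 4 ||
      any(vapply(casualty$trajectories, is.null, logical(1)))) {
    stop("casualty is missing ground-truth trajectories")
  }
  restored <- vapply(1:4, function(o) restored_at_t3(casualty, o), logical(1))
  if (restored[1]) return(list(units = 0L, option = 1L))
  if (restored[3]) return(list(units = 1L, option = 3L))
  if (restored[2]) return(list(units = 1L, option = 2L))
  if (restored[4]) return(list(units = 2L, option = 4L))
  list(units = NA_integer_, option = NA_integer_)
}

# Initialize an empty decision table for a group of casualties.
empty_decisions <- function(group) {
  data.frame(id = vapply(group, `[[`, numeric(1), "id"),
             option = 1L, units_used = 0L, restored = NA)
}

finish_decisions <- function(decisions, group) {
  decisions$restored <- vapply(seq_along(group), function(i) {
    restored_at_t3(group[[i]], decisions$option[i])
  }, logical(1))
  decisions
}

#' Oracle (ground-truth-based) allocation under a unit budget
#'
#' Casualties needing 0 units and unrestorable casualties receive nothing.
#' Casualties needing 1 unit are served in cohort order until the budget is
#' exhausted, then casualties needing 2 units are served while at least 2
#' units remain; a stranded final unit is not given to a 2-need casualty.
#'
#' @param group list of casualties (e.g. one fold of a cohort).
#' @param budget available fluid units (>= 0).
#' @param needs optional precomputed list of [oracle_needs()] results.
#' @return Data frame of decisions: `id`, `option`, `units_used`,
#'   `restored` (evaluated on the ground truth of the realized schedule).
#' @export
oracle_allocate <- function(group, budget, needs = NULL) {
  stopifnot(budget >= 0)
  if (is.null(needs)) needs <- lapply(group, oracle_needs)
  dec <- empty_decisions(group)
  remaining <- budget
  for (i in seq_along(group)) {  # 1-need first, cohort order
    nd <- needs[[i]]
    if (!is.na(nd$units) && nd$units == 1L && remaining >= 1) {
      dec$option[i] <- nd$option
      dec$units_used[i] <- 1L
      remaining <- remaining - 1
    }
  }
  for (i in seq_along(group)) {  # then 2-need while 2 units remain
    nd <- needs[[i]]
    if (!is.na(nd$units) && nd$units == 2L && remaining >= 2) {
      dec$option[i] <- nd$option
      dec$units_used[i] <- 2L
      remaining <- remaining - 2
    }
  }
  finish_decisions(dec, group)
}

#' Two-step vital-sign threshold (Vampire-rule) allocation
#'
#' Stage 1, in cohort order: every casualty outside the target range at `t2`
#' receives 1 unit for the first 30-min block while the budget lasts. Stage
#' 2, in cohort order: every casualty (treated or not) whose ground-truth
#' vitals under the realized first block are still outside the target range
#' at `t2 + 30` receives 1 further unit while the budget lasts, capped at 2
#' units per casualty. All first-stage units are committed before any
#' second-stage unit.
#'
#' @inheritParams oracle_allocate
#' @return Decision data frame as in [oracle_allocate()].
#' @export
vampire_allocate <- function(group, budget) {
  stopifnot(budget >= 0)
  dec <- empty_decisions(group)
  remaining <- budget
  first <- integer(length(group))
  for (i in seq_along(group)) {
    v <- vitals_at(group[[i]], 1L, group[[i]]$times$t2)
    if (!is_restored(v["hr"], v["sbp"]) && remaining >= 1) {
      first[i] <- 1L
      remaining <- remaining - 1
    }
  }
  second <- integer(length(group))
  for (i in seq_along(group)) {
    opt_sofar <- option_from_blocks(first[i], 0L)
    v <- vitals_at(group[[i]], opt_sofar, group[[i]]$times$t2 + 30)
    if (!is_restored(v["hr"], v["sbp"]) && remaining >= 1) {
      second[i] <- 1L
      remaining <- remaining - 1
    }
  }
  dec$option <- option_from_blocks(first, second)
  dec$units_used <- first + second
  finish_decisions(dec, group)
}

#' Predicted outcomes needed by the AI allocator
#'
#' For each casualty: `stage1`, a 4 x 2 matrix of predicted `(hr, sbp)` at
#' `t3` for the four treatment options (10-min warm-up, 60-min closed-loop
#' rollout); and `stage2`, a 2 x 2 x 2 array indexed by
#' `[first block unit + 1, second block unit + 1, hr/sbp]` of predicted `t3`
#' vitals from the 40-min reassessment warm-up (10 observed pre-treatment
#' minutes plus 30 minutes under the realized first block) and a 30-min
#' rollout under the candidate second block.
#'
#' With `predictor = perfect_predictor()` the table is filled with the
#' ground-truth endpoints, which collapses the AI allocator onto the oracle.
#'
#' @param group list of casualties.
#' @param predictor a `gru_predictor`, `gru_ensemble`, or
#'   [perfect_predictor()].
#' @return List (one element per casualty) of lists with `stage1` and
#'   `stage2`.
#' @export
ai_forecast_table <- function(group, predictor) {
  lapply(group, function(cs) forecast_casualty(predictor, cs))
}

#' Ground-truth stand-in predictor
#'
#' A predictor whose forecasts are the stored ground-truth endpoints;
#' substituting it for a trained forecaster makes [ai_allocate()] reproduce
#' [oracle_allocate()] exactly.
#'
#' @return Object of class `perfect_predictor`.
#' @export
perfect_predictor <- function() {
  structure(list(), class = "perfect_predictor")
}

forecast_casualty <- function(predictor, casualty) {
  UseMethod("forecast_casualty")
}

#' @export
forecast_casualty.perfect_predictor <- function(predictor, casualty) {
  t3 <- casualty$times$t3
  stage1 <- t(vapply(1:4, function(o) vitals_at(casualty, o, t3), numeric(2)))
  colnames(stage1) <- c("hr", "sbp")
  stage2 <- array(NA_real_, c(2, 2, 2), dimnames = list(NULL, NULL,
                                                        c("hr", "sbp")))
  for (fb in 0:1) {
    for (sb in 0:1) {
      v <- vitals_at(casualty, option_from_blocks(fb, sb), t3)
      stage2[fb + 1, sb + 1, ] <- v
    }
  }
  list(stage1 = stage1, stage2 = stage2)
}

#' @export
forecast_casualty.default <- function(predictor, casualty) {
  t2 <- casualty$times$t2
  warm <- warmup_window(casualty)
  init <- vitals_at(casualty, 1L, t2)
  stage1 <- matrix(NA_real_, 4, 2, dimnames = list(NULL, c("hr", "sbp")))
  st0 <- NULL
  for (o in 1:4) {
    sched <- treatment_schedule(o)
    u <- rep(sched$block_rates, each = 30)
    pr <- predict_outcome(predictor,
                          list(warm = warm, init = init, u = u))
    stage1[o, ] <- c(pr$hr[60], pr$sbp[60])
  }
  stage2 <- array(NA_real_, c(2, 2, 2), dimnames = list(NULL, NULL,
                                                        c("hr", "sbp")))
  for (fb in 0:1) {
    opt_sofar <- option_from_blocks(fb, 0L)
    tr <- casualty$trajectories[[opt_sofar]]
    idx <- match((t2 - 10):(t2 + 29), tr$times)
    u_obs <- c(numeric(10), rep(fb * UNIT_RATE_LPH, 30))
    warm40 <- cbind(u = u_obs, hr = tr$hr[idx], sbp = tr$sbp[idx])
    init30 <- vitals_at(casualty, opt_sofar, t2 + 30)
    for (sb in 0:1) {
      u2 <- rep(sb * UNIT_RATE_LPH, 30)
      pr <- predict_outcome(predictor,
                            list(warm = warm40, init = init30, u = u2))
      stage2[fb + 1, sb + 1, ] <- c(pr$hr[30], pr$sbp[30])
    }
  }
  list(stage1 = stage1, stage2 = stage2)
}

#' AI-predictive allocation under a unit budget
#'
#' Stage 1: each casualty's predicted need is the least-unit treatment whose
#' predicted `t3` vitals are restored (1-unit tie broken toward the early
#' unit; unrestorable if none). Budgeted service order matches
#' [oracle_allocate()]: predicted 1-need casualties first, then predicted
#' 2-need casualties while two units remain (the second unit is reserved).
#' Stage 2: every casualty scheduled any fluid is reassessed at `t2 + 30`
#' from the 40-min observed window; the final block receives 0 or 1 unit,
#' whichever least amount of fluid is predicted to restore. A released
#' reserved unit returns to the pool and may serve later stage-2 requests in
#' cohort order. Outcomes are evaluated on the ground truth of the realized
#' schedules.
#'
#' @inheritParams oracle_allocate
#' @param predictor predictor used when `forecasts` is not supplied; must be
#'   the held-out model for this group's fold.
#' @param forecasts optional precomputed [ai_forecast_table()] (reusable
#'   across budgets).
#' @return Decision data frame as in [oracle_allocate()].
#' @export
ai_allocate <- function(group, budget, predictor = NULL, forecasts = NULL) {
  stopifnot(budget >= 0)
  if (is.null(forecasts)) {
    if (is.null(predictor)) stop("missing fold predictor for AI allocation")
    forecasts <- ai_forecast_table(group, predictor)
  }
  n <- length(group)
  pred_need <- integer(n); pred_opt <- integer(n)
  for (i in seq_len(n)) {
    s1 <- forecasts[[i]]$stage1
    ok <- is_restored(s1[, "hr"], s1[, "sbp"])
    if (ok[1]) { pred_need[i] <- 0L; pred_opt[i] <- 1L }
    else if (ok[3]) { pred_need[i] <- 1L; pred_opt[i] <- 3L }
    else if (ok[2]) { pred_need[i] <- 1L; pred_opt[i] <- 2L }
    else if (ok[4]) { pred_need[i] <- 2L; pred_opt[i] <- 4L }
    else { pred_need[i] <- NA_integer_; pred_opt[i] <- 1L }
  }
  # stage-1 budgeting: 1-need first, then 2-need while 2 units remain
  scheduled <- integer(n)  # scheduled option after stage-1 budgeting
  scheduled[] <- 1L
  committed <- integer(n)  # units committed (given now + reserved)
  remaining <- budget
  for (i in seq_len(n)) {
    if (!is.na(pred_need[i]) && pred_need[i] == 1L && remaining >= 1) {
      scheduled[i] <- pred_opt[i]
      committed[i] <- 1L
      remaining <- remaining - 1
    }
  }
  for (i in seq_len(n)) {
    if (!is.na(pred_need[i]) && pred_need[i] == 2L && remaining >= 2) {
      scheduled[i] <- 4L
      committed[i] <- 2L
      remaining <- remaining - 2
    }
  }
  # stage 2: reassess everyone scheduled any fluid, in cohort order
  first <- as.integer(scheduled %in% c(3L, 4L))
  second <- integer(n)
  for (i in seq_len(n)) {
    if (scheduled[i] == 1L) next
    s2 <- forecasts[[i]]$stage2
    ok0 <- is_restored(s2[first[i] + 1, 1, "hr"], s2[first[i] + 1, 1, "sbp"])
    ok1 <- is_restored(s2[first[i] + 1, 2, "hr"], s2[first[i] + 1, 2, "sbp"])
    want <- if (ok0) 0L else if (ok1) 1L else 0L
    reserved <- committed[i] - first[i]  # 1 if a second-block unit is held
    if (want == 1L) {
      if (reserved >= 1L) {
        second[i] <- 1L
      } else if (remaining >= 1) {  # option-3 casualty asking for an extra
        second[i] <- 1L
        remaining <- remaining - 1
      }
    } else if (reserved >= 1L) {
      remaining <- remaining + 1  # release the held unit back to the pool
    }
  }
  dec <- empty_decisions(group)
  dec$option <- option_from_blocks(first, second)
  dec$units_used <- first + second
  finish_decisions(dec, group)
}

#' Excess fluid use of a decision set
#'
#' Units given beyond each casualty's ground-truth need, summed over the
#' group; unrestorable and 0-need casualties have need 0.
#'
#' @param decisions a decision data frame.
#' @param group the casualty list the decisions refer to.
#' @param needs optional precomputed [oracle_needs()] list.
#' @return Total excess units (integer).
#' @export
excessive_use <- function(decisions, group, needs = NULL) {
  if (is.null(needs)) needs <- lapply(group, oracle_needs)
  need_units <- vapply(needs, function(nd) {
    if (is.na(nd$units)) 0L else nd$units
  }, integer(1))
  sum(pmax(0L, decisions$units_used - need_units))
}

#' Relative fluid-utilization efficiency
#'
#' \deqn{R = (N_A / U_A) / (N_V / U_V)} -- restored casualties per unit for
#' the AI allocation relative to the threshold-rule allocation. Defined only
#' when both methods used at least one unit.
#'
#' @param n_a,u_a restored count and units used by the AI allocation.
#' @param n_v,u_v restored count and units used by the threshold rule.
#' @return `R`, or `NA` when undefined (`u_a` or `u_v` zero, or `n_v` zero).
#' @examples
#' relative_efficiency(28, 20, 22, 32)  # ~2.036
#' @export
relative_efficiency <- function(n_a, u_a, n_v, u_v) {
  if (u_a < 1 || u_v < 1 || n_v == 0) return(NA_real_)
  (n_a / u_a) / (n_v / u_v)
}

#' Budget sweep over the three allocation policies (Analysis 2)
#'
#' For every cohort fold (group of `n_f / 5` casualties) and every budget,
#' runs the oracle, AI, and threshold-rule allocators and records restored
#' counts, units used, and excess fluid.
#'
#' @param cohort a [build_cohort()] cohort.
#' @param predictors list of 5 held-out fold predictors (e.g.
#'   `nested_cv(...)$predictors`), or a single [perfect_predictor()].
#' @param budgets integer vector of available unit counts (default `0:42`).
#' @return Object of class `budget_sweep`: `results` (tidy data frame with
#'   columns `budget`, `method`, `group`, `restored`, `units_used`,
#'   `excess`) and `summary` (per budget and method: mean and 2 SE across
#'   groups, plus the AI/Vampire restored ratio and `R` from the pooled
#'   counts, using the convention ratio = 1 at budget 0).
#' @export
run_analysis2 <- function(cohort, predictors, budgets = 0:42) {
  groups <- lapply(1:5, function(f) {
    cohort$casualties[cohort$fold == f]
  })
  if (inherits(predictors, "perfect_predictor")) {
    predictors <- rep(list(predictors), 5)
  }
  res <- NULL
  for (g in 1:5) {
    group <- groups[[g]]
    needs <- lapply(group, oracle_needs)
    fc <- ai_forecast_table(group, predictors[[g]])
    for (b in budgets) {
      dec_o <- oracle_allocate(group, b, needs = needs)
      dec_a <- ai_allocate(group, b, forecasts = fc)
      dec_v <- vampire_allocate(group, b)
      for (m in c("oracle", "ai", "vampire")) {
        dec <- switch(m, oracle = dec_o, ai = dec_a, vampire = dec_v)
        res <- rbind(res, data.frame(
          budget = b, method = m, group = g,
          restored = sum(dec$restored),
          units_used = sum(dec$units_used),
          excess = excessive_use(dec, group, needs = needs)))
      }
    }
  }
  agg <- stats::aggregate(cbind(restored, units_used, excess) ~
                            budget + method, data = res, FUN = mean)
  se2 <- stats::aggregate(cbind(restored, units_used, excess) ~
                            budget + method, data = res,
                          FUN = function(x) 2 * stats::sd(x) / sqrt(length(x)))
  names(se2)[3:5] <- paste0(names(se2)[3:5], "_2se")
  summary <- merge(agg, se2, by = c("budget", "method"))
  structure(list(results = res, summary = summary, budgets = budgets),
            class = "budget_sweep")
}

#' Restored-fraction and efficiency ratios across group sizes (Analysis 3)
#'
#' Splits each fold's casualties, in cohort order, into subgroups of the
#' requested sizes, allocates with the AI and threshold-rule methods at each
#' budget, and reports the mean and SD across subgroups of the AI/Vampire
#' restored-count ratio and of the relative efficiency `R`. Budget-0 cells
#' are 1.00 by convention; other cells with an undefined ratio (threshold
#' rule restoring nobody, or either method using no fluid for `R`) are
#' dropped from the mean and counted in `n_undefined`.
#'
#' @param cohort a [build_cohort()] cohort.
#' @param predictors as in [run_analysis2()].
#' @param group_sizes subgroup sizes; each must divide `n_f / 5`.
#' @param budgets available unit counts.
#' @return Data frame with columns `group_size`, `budget`,
#'   `restored_ratio_mean`, `restored_ratio_sd`, `R_mean`, `R_sd`,
#'   `n_groups`, `n_undefined_ratio`, `n_undefined_R`.
#' @export
run_analysis3 <- function(cohort, predictors,
                          group_sizes = c(32, 16, 8, 4), budgets = 0:42) {
  per_fold <- cohort$n_f / 5
  if (any(per_fold %% group_sizes != 0)) {
    stop("every group size must divide n_f / 5 = ", per_fold)
  }
  if (inherits(predictors, "perfect_predictor")) {
    predictors <- rep(list(predictors), 5)
  }
  folds <- lapply(1:5, function(f) cohort$casualties[cohort$fold == f])
  fc_folds <- lapply(1:5, function(f) ai_forecast_table(folds[[f]],
                                                        predictors[[f]]))
  out <- NULL
  for (gs in group_sizes) {
    subgroups <- list()
    sub_fc <- list()
    for (f in 1:5) {
      splits <- split(seq_len(per_fold), ceiling(seq_len(per_fold) / gs))
      for (sp in splits) {
        subgroups[[length(subgroups) + 1L]] <- folds[[f]][sp]
        sub_fc[[length(sub_fc) + 1L]] <- fc_folds[[f]][sp]
      }
    }
    for (b in budgets) {
      ratios <- numeric(0); Rs <- numeric(0)
      n_und_ratio <- 0L; n_und_R <- 0L
      for (k in seq_along(subgroups)) {
        if (b == 0) { ratios <- c(ratios, 1); Rs <- c(Rs, 1); next }
        dec_a <- ai_allocate(subgroups[[k]], b, forecasts = sub_fc[[k]])
        dec_v <- vampire_allocate(subgroups[[k]], b)
        n_a <- sum(dec_a$restored); u_a <- sum(dec_a$units_used)
        n_v <- sum(dec_v$restored); u_v <- sum(dec_v$units_used)
        if (n_v == 0) n_und_ratio <- n_und_ratio + 1L
        else ratios <- c(ratios, n_a / n_v)
        R <- relative_efficiency(n_a, u_a, n_v, u_v)
        if (is.na(R)) n_und_R <- n_und_R + 1L else Rs <- c(Rs, R)
      }
      out <- rbind(out, data.frame(
        group_size = gs, budget = b,
        restored_ratio_mean = if (length(ratios)) mean(ratios) else NA_real_,
        restored_ratio_sd = if (length(ratios) > 1) stats::sd(ratios)
                            else NA_real_,
        R_mean = if (length(Rs)) mean(Rs) else NA_real_,
        R_sd = if (length(Rs) > 1) stats::sd(Rs) else NA_real_,
        n_groups = length(subgroups),
        n_undefined_ratio = n_und_ratio, n_undefined_R = n_und_R))
    }
  }
  out
}
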