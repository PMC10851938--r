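#' Residual-bleeding trajectory generation
#'
#' Re-simulates every casualty under its own hemorrhage scenario and event
#' timeline, but with a fraction `f_nc` of the bleeding rate persisting
#' after tourniquet application (non-compressible bleeding), under each of
#' the four treatment options. Runs that fail to complete or leave the
#' physiological range are dropped.
#'
#' @param cohort a [build_cohort()] cohort.
#' @param fractions residual fractions of the bleeding rate (default
#'   `c(0.10, 0.20, 0.30, 0.40, 0.50)`).
#' @param options treatment options to apply (default all four).
#' @return Data-frame-like list: `runs`, a list of records with `id`,
#'   `option`, `f_nc`, and the simulated `trajectory`; and `n_candidates`,
#'   the number attempted before completion filtering.
#' @export
generate_ncb_trajectories <- function(cohort,
                                      fractions = c(0.1, 0.2, 0.3, 0.4, 0.5),
                                      options = 1:4) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  runs <- list()
  n_cand <- 0L
  for (cs in cohort$casualties) {
    for (f in fractions) {
      for (opt in options) {
        n_cand <- n_cand + 1L
        inp <- sim_input(bleed_rate = cs$hemorrhage$rate,
                         t1 = cs$hemorrhage$T_b, f_nc = f,
                         infusion = infusion_schedule(opt, cs$times),
                         horizon = cs$times$t3)
        tr <- simulate_vitals(cs$params, inp)
        if (!tr$completed || !tr$in_physiological_range) next
        runs[[length(runs) + 1L]] <- list(id = cs$id, option = opt,
                                          f_nc = f, trajectory = tr)
      }
    }
  }
  list(runs = runs, n_candidates = n_cand)
}

#' Prediction-error feature of one monitored trajectory
#'
#' Warm-up on the trajectory's own 10 minutes of measured vitals before
#' `t2` (which, under residual bleeding, still reflect ongoing volume loss),
#' closed-loop rollout to `t3` under the realized infusion schedule, and the
#' measured-minus-predicted differences at `t3`.
#'
#' @param trajectory a `vitals_trajectory` (controlled or residual-bleeding
#'   run of the casualty).
#' @param predictor the casualty's held-out fold predictor (or
#'   [perfect_predictor()] applied to controlled runs).
#' @param times the casualty's event timeline.
#' @param option_id the realized treatment option.
#' @return Named vector `c(d_hr, d_sbp)`: ground truth minus prediction at
#'   `t3` (beats/min, mmHg).
#' @export
extract_features <- function(trajectory, predictor, times, option_id) {
  t2 <- times$t2
  idx_w <- match((t2 - 10):(t2 - 1), trajectory$times)
  warm <- cbind(u = numeric(10), hr = trajectory$hr[idx_w],
                sbp = trajectory$sbp[idx_w])
  i2 <- match(t2, trajectory$times)
  init <- c(trajectory$hr[i2], trajectory$sbp[i2])
  u <- rep(treatment_schedule(option_id)$block_rates, each = 30)
  pr <- predict_outcome(predictor, list(warm = warm, init = init, u = u))
  i3 <- match(times$t3, trajectory$times)
  c(d_hr = trajectory$hr[i3] - pr$hr[60],
    d_sbp = trajectory$sbp[i3] - pr$sbp[60])
}

#' Feature table for controlled and residual-bleeding trajectories
#'
#' Extracts `(d_hr, d_sbp)` prediction-error features at `t3` for all
#' stored controlled trajectories (label `controlled`) and all completed
#' residual-bleeding runs (label `ncb`), each scored by its casualty's
#' held-out fold predictor.
#'
#' @param cohort a [build_cohort()] cohort.
#' @param predictors list of 5 fold predictors, or a single predictor used
#'   for every fold.
#' @param ncb result of [generate_ncb_trajectories()].
#' @return Data frame with columns `d_hr`, `d_sbp`, `label` (factor),
#'   `id`, `option`, `f_nc`.
#' @export
ncb_feature_table <- function(cohort, predictors, ncb) {
  if (!is.list(predictors) || inherits(predictors, c("gru_predictor",
                                                     "gru_ensemble",
                                                     "perfect_predictor"))) {
    predictors <- rep(list(predictors), 5)
  }
  by_id <- stats::setNames(cohort$casualties,
                           vapply(cohort$casualties, `[[`, numeric(1), "id"))
  pred_of <- function(id) predictors[[cohort$fold[match(id, names(by_id))]]]
  rows <- list()
  for (cs in cohort$casualties) {
    pd <- pred_of(cs$id)
    for (opt in 1:4) {
      ft <- extract_features(cs$trajectories[[opt]], pd, cs$times, opt)
      rows[[length(rows) + 1L]] <- data.frame(
        d_hr = ft["d_hr"], d_sbp = ft["d_sbp"], label = "controlled",
        id = cs$id, option = opt, f_nc = 0)
    }
  }
  for (run in ncb$runs) {
    cs <- by_id[[as.character(run$id)]]
    ft <- extract_features(run$trajectory, pred_of(run$id), cs$times,
                           run$option)
    rows[[length(rows) + 1L]] <- data.frame(
      d_hr = ft["d_hr"], d_sbp = ft["d_sbp"], label = "ncb",
      id = run$id, option = run$option, f_nc = run$f_nc)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$label <- factor(out$label, levels = c("controlled", "ncb"))
  out
}

#' Class-weighted linear SVM for residual-bleeding detection
#'
#' Fits a linear support vector machine on the 2-D prediction-error feature
#' space with per-class weights inversely proportional to class size, so
#' both bleeding scenarios contribute equally to the objective. Reports
#' per-class accuracy on the full training pool and, as an additional
#' diagnostic, under a seeded 5-fold split.
#'
#' @param features data frame from [ncb_feature_table()] (columns `d_hr`,
#'   `d_sbp`, `label`).
#' @param cost SVM regularization constant (default 1).
#' @param cv_seed seed for the diagnostic cross-validated accuracy.
#' @return Object of class `ncb_classifier`: the fitted `e1071::svm` model,
#'   `class_counts`, `class_weights`, `accuracy` (per class, percent, on
#'   the pool), `cv_accuracy` (per class, percent, 5-fold), and `boundary`
#'   (weight vector `w` and intercept `b` of the decision function
#'   `w . x + b`).
#' @export
fit_ncb_svm <- function(features, cost = 1, cv_seed = 1) {
  stopifnot(all(c("d_hr", "d_sbp", "label") %in% names(features)))
  counts <- table(features$label)
  if (any(counts == 0) || length(counts) < 2) {
    stop("both classes must be present to fit the classifier")
  }
  wts <- as.numeric(sum(counts) / (2 * counts))
  names(wts) <- names(counts)
  fit <- e1071::svm(label ~ d_hr + d_sbp, data = features,
                    kernel = "linear", cost = cost, class.weights = wts,
                    scale = FALSE)
  pred <- stats::predict(fit, features)
  acc <- vapply(names(counts), function(cl) {
    sel <- features$label == cl
    100 * mean(pred[sel] == cl)
  }, numeric(1))
  # diagnostic: seeded 5-fold cross-validated per-class accuracy
  set.seed(cv_seed)
  fold <- sample(rep(1:5, length.out = nrow(features)))
  cv_pred <- factor(rep(NA, nrow(features)), levels = levels(features$label))
  for (f in 1:5) {
    tr <- features[fold != f, ]
    cw <- table(tr$label)
    w_f <- as.numeric(sum(cw) / (2 * cw)); names(w_f) <- names(cw)
    m <- e1071::svm(label ~ d_hr + d_sbp, data = tr, kernel = "linear",
                    cost = cost, class.weights = w_f, scale = FALSE)
    cv_pred[fold == f] <- stats::predict(m, features[fold == f, ])
  }
  cv_acc <- vapply(names(counts), function(cl) {
    sel <- features$label == cl
    100 * mean(cv_pred[sel] == cl)
  }, numeric(1))
  w <- colSums(fit$coefs[, 1] * fit$SV)
  structure(list(model = fit, class_counts = counts, class_weights = wts,
                 accuracy = acc, cv_accuracy = cv_acc,
                 boundary = list(w = w, b = -fit$rho)),
            class = "ncb_classifier")
}

#' @export
print.ncb_classifier <- function(x, ...) {
  cat("<ncb_classifier> linear SVM, per-class pool accuracy (%):\n")
  print(round(x$accuracy, 1))
  cat(sprintf("boundary: %.4f * d_hr + %.4f * d_sbp + %.4f = 0\n",
              x$boundary$w[1], x$boundary$w[2], x$boundary$b))
  invisible(x)
}
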