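#' Forecaster configuration
#'
#' Settings for the recurrent vital-sign forecaster. The network consumes,
#' at each minute, the fluid infusion rate `u_f(t)` (L/h), HR(t) and SBP(t),
#' and emits the predicted HR and SBP for the next minute. Inputs and
#' outputs are scaled by fixed normalization factors: 150 beats/min for HR,
#' 110 mmHg for SBP (the ranges seen in simulation), and the single-unit
#' infusion rate of 1.10 L/h for `u_f`.
#'
#' @param hidden nodes per layer (feedforward and recurrent).
#' @param warmup_len observed minutes consumed before forecasting (10).
#' @param rollout_len forecast horizon in minutes (60).
#' @param hr_norm,sbp_norm,u_norm normalization factors.
#' @param lr Adam learning rate.
#' @param epochs maximum training epochs.
#' @param batch_size trajectories per gradient step.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param tf_frac fraction of the epoch budget run teacher-forced before
#'   switching to free-running (closed-loop) training.
#' @return Object of class `gru_config`.
#' @export
gru_config <- function(hidden = 512, warmup_len = 10, rollout_len = 60,
                       hr_norm = 150, sbp_norm = 110, u_norm = 1.10,
                       lr = 1e-3, epochs = 500, batch_size = 32,
                       patience = 25, tf_frac = 0.25) {
  stopifnot(hidden >= 1, warmup_len >= 1, rollout_len >= 1,
            hr_norm > 0, sbp_norm > 0, u_norm > 0)
  structure(list(hidden = as.integer(hidden),
                 warmup_len = as.integer(warmup_len),
                 rollout_len = as.integer(rollout_len),
                 hr_norm = hr_norm, sbp_norm = sbp_norm, u_norm = u_norm,
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), tf_frac = tf_frac),
            class = "gru_config")
}

# Glorot-uniform weight matrix
glorot <- function(nout, nin) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nout * nin, -lim, lim), nout, nin)
}

#' Initialize forecaster weights
#'
#' Architecture: input(3) -> feedforward (tanh) -> gated recurrent unit ->
#' feedforward (tanh) -> linear output(2). Weights are Glorot-uniform,
#' biases zero; drawn from the current RNG stream.
#'
#' @param config a [gru_config()].
#' @return Object of class `gru_predictor` with untrained weights.
#' @export
init_predictor <- function(config = gru_config()) {
  H <- config$hidden
  W <- list(W1 = glorot(H, 3), b1 = numeric(H),
            Wz = glorot(H, H), Uz = glorot(H, H), bz = numeric(H),
            Wr = glorot(H, H), Ur = glorot(H, H), br = numeric(H),
            Wn = glorot(H, H), Un = glorot(H, H), bn = numeric(H),
            W2 = glorot(H, H), b2 = numeric(H),
            W3 = glorot(2, H), b3 = numeric(2))
  structure(list(weights = W, config = config, history = NULL,
                 provenance = NULL),
            class = "gru_predictor")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# One network step on a batch. x: 3 x B normalized inputs; h: H x B hidden.
# Returns y (2 x B, normalized), new h, and (optionally) the cache needed
# for backpropagation.
net_step <- function(W, x, h, cache = FALSE) {
  a1 <- tanh(W$W1 %*% x + W$b1)
  z <- sigmoid(W$Wz %*% a1 + W$Uz %*% h + W$bz)
  r <- sigmoid(W$Wr %*% a1 + W$Ur %*% h + W$br)
  n <- tanh(W$Wn %*% a1 + W$Un %*% (r * h) + W$bn)
  h_new <- (1 - z) * n + z * h
  a2 <- tanh(W$W2 %*% h_new + W$b2)
  y <- W$W3 %*% a2 + W$b3
  out <- list(y = y, h = h_new)
  if (cache) {
    out$cache <- list(x = x, h_prev = h, a1 = a1, z = z, r = r, n = n,
                      h = h_new, a2 = a2)
  }
  out
}

# Backward through one step. dy: 2 x B, dh_next: H x B. Accumulates into
# gradient environment `g` (same names as weights). Returns list(dh, dx).
net_step_backward <- function(W, cc, dy, dh_next, g) {
  da2 <- crossprod(W$W3, dy)
  g$W3 <- g$W3 + tcrossprod(dy, cc$a2)
  g$b3 <- g$b3 + rowSums(dy)
  dpre2 <- da2 * (1 - cc$a2^2)
  g$W2 <- g$W2 + tcrossprod(dpre2, cc$h)
  g$b2 <- g$b2 + rowSums(dpre2)
  dh <- crossprod(W$W2, dpre2) + dh_next

  dz <- dh * (cc$h_prev - cc$n)
  dn <- dh * (1 - cc$z)
  dh_prev <- dh * cc$z

  dn_pre <- dn * (1 - cc$n^2)
  g$Wn <- g$Wn + tcrossprod(dn_pre, cc$a1)
  g$Un <- g$Un + tcrossprod(dn_pre, cc$r * cc$h_prev)
  g$bn <- g$bn + rowSums(dn_pre)
  drh <- crossprod(W$Un, dn_pre)
  dr <- drh * cc$h_prev
  dh_prev <- dh_prev + drh * cc$r

  dz_pre <- dz * cc$z * (1 - cc$z)
  g$Wz <- g$Wz + tcrossprod(dz_pre, cc$a1)
  g$Uz <- g$Uz + tcrossprod(dz_pre, cc$h_prev)
  g$bz <- g$bz + rowSums(dz_pre)
  dh_prev <- dh_prev + crossprod(W$Uz, dz_pre)

  dr_pre <- dr * cc$r * (1 - cc$r)
  g$Wr <- g$Wr + tcrossprod(dr_pre, cc$a1)
  g$Ur <- g$Ur + tcrossprod(dr_pre, cc$h_prev)
  g$br <- g$br + rowSums(dr_pre)
  dh_prev <- dh_prev + crossprod(W$Ur, dr_pre)

  da1 <- crossprod(W$Wz, dz_pre) + crossprod(W$Wr, dr_pre) +
    crossprod(W$Wn, dn_pre)
  da1_pre <- da1 * (1 - cc$a1^2)
  g$W1 <- g$W1 + tcrossprod(da1_pre, cc$x)
  g$b1 <- g$b1 + rowSums(da1_pre)
  dx <- crossprod(W$W1, da1_pre)
  list(dh = dh_prev, dx = dx)
}

#' Single forecaster step
#'
#' Consumes one minute of (infusion rate, HR, SBP) and returns the updated
#' hidden state with the de-normalized prediction for the next minute. A
#' pure function of its arguments.
#'
#' @param predictor a `gru_predictor`.
#' @param state hidden-state vector (length `hidden`), e.g. from
#'   [gru_warmup()]; use `NULL` for the zero initial state.
#' @param u_f infusion rate (L/h).
#' @param hr,sbp current measured or fed-back vitals.
#' @return List with `state`, `hr_hat`, `sbp_hat`.
#' @export
forward_step <- function(predictor, state, u_f, hr, sbp) {
  cfg <- predictor$config
  if (!all(is.finite(c(u_f, hr, sbp)))) stop("non-finite forecaster input")
  if (is.null(state)) state <- numeric(cfg$hidden)
  x <- matrix(c(u_f / cfg$u_norm, hr / cfg$hr_norm, sbp / cfg$sbp_norm), 3, 1)
  st <- net_step(predictor$weights, x, matrix(state, ncol = 1))
  list(state = as.numeric(st$h),
       hr_hat = st$y[1, 1] * cfg$hr_norm,
       sbp_hat = st$y[2, 1] * cfg$sbp_norm)
}

#' Teacher-forced warm-up on an observed window
#'
#' Consumes the observed `(u_f, hr, sbp)` window minute by minute to update
#' the hidden state; predictions made during warm-up are discarded.
#'
#' @param predictor a `gru_predictor`.
#' @param window matrix with columns `u`, `hr`, `sbp` (one row per minute).
#' @return Hidden-state vector.
#' @export
gru_warmup <- function(predictor, window) {
  if (is.null(dim(window)) || nrow(window) < 1) stop("empty warm-up window")
  cfg <- predictor$config
  h <- matrix(0, cfg$hidden, 1)
  W <- predictor$weights
  for (t in seq_len(nrow(window))) {
    x <- matrix(c(window[t, 1] / cfg$u_norm, window[t, 2] / cfg$hr_norm,
                  window[t, 3] / cfg$sbp_norm), 3, 1)
    h <- net_step(W, x, h)$h
  }
  as.numeric(h)
}

#' Closed-loop rollout under an infusion schedule
#'
#' Starting from a warmed-up hidden state and the last measured vitals, the
#' forecaster repeatedly consumes the scheduled infusion rate together with
#' its own previous prediction, producing a minute-indexed forecast.
#'
#' @param predictor a `gru_predictor`.
#' @param state hidden state from [gru_warmup()].
#' @param u_schedule per-minute infusion rates (L/h), one per forecast step.
#' @param init_hr,init_sbp measured vitals at the last observed minute (the
#'   first step's fed-back values).
#' @return Data frame with columns `hr`, `sbp`, `length(u_schedule)` rows.
#' @export
gru_rollout <- function(predictor, state, u_schedule, init_hr, init_sbp) {
  cfg <- predictor$config
  W <- predictor$weights
  Tn <- length(u_schedule)
  h <- matrix(state, ncol = 1)
  prev <- c(init_hr / cfg$hr_norm, init_sbp / cfg$sbp_norm)
  hr <- numeric(Tn); sbp <- numeric(Tn)
  for (t in seq_len(Tn)) {
    x <- matrix(c(u_schedule[t] / cfg$u_norm, prev), 3, 1)
    st <- net_step(W, x, h)
    h <- st$h
    prev <- st$y[, 1]
    hr[t] <- prev[1] * cfg$hr_norm
    sbp[t] <- prev[2] * cfg$sbp_norm
  }
  data.frame(hr = hr, sbp = sbp)
}

#' Normalized prediction error over the forecast horizon
#'
#' \deqn{\epsilon = \frac{1}{T}\sum_{t=1}^{T}
#'   \left[\left(\frac{\hat{HR}(t)-HR(t)}{150}\right)^2 +
#'         \left(\frac{\hat{SBP}(t)-SBP(t)}{110}\right)^2\right]}
#' with `T = 60` in the standard setting.
#'
#' @param pred,truth data frames (or matrices) with columns `hr` and `sbp`
#'   of equal length.
#' @param hr_norm,sbp_norm normalization factors.
#' @return Dimensionless scalar error.
#' @examples
#' p <- data.frame(hr = rep(115, 60), sbp = rep(100, 60))
#' y <- data.frame(hr = rep(100, 60), sbp = rep(100, 60))
#' epsilon_loss(p, y)  # (15/150)^2 = 0.01
#' @export
epsilon_loss <- function(pred, truth, hr_norm = 150, sbp_norm = 110) {
  pred <- as.data.frame(pred); truth <- as.data.frame(truth)
  if (nrow(pred) != nrow(truth)) stop("prediction/truth length mismatch")
  mean(((pred$hr - truth$hr) / hr_norm)^2 +
         ((pred$sbp - truth$sbp) / sbp_norm)^2)
}

#' Root-mean-square forecast errors for HR and SBP
#'
#' @inheritParams epsilon_loss
#' @return Named vector `c(delta_h, delta_s)` in beats/min and mmHg.
#' @export
rmse_errors <- function(pred, truth) {
  pred <- as.data.frame(pred); truth <- as.data.frame(truth)
  if (nrow(pred) != nrow(truth)) stop("prediction/truth length mismatch")
  c(delta_h = sqrt(mean((pred$hr - truth$hr)^2)),
    delta_s = sqrt(mean((pred$sbp - truth$sbp)^2)))
}

#' Training samples from cohort trajectories
#'
#' Each of the four ground-truth trajectories of each requested casualty
#' becomes one sample: the 10-min pre-treatment window, the measured vitals
#' at `t2`, the 60 per-minute scheduled infusion rates, and the 60-min
#' target vitals.
#'
#' @param cohort a [build_cohort()] cohort.
#' @param ids casualty ids to include.
#' @return List of samples (lists with `warm`, `init`, `u`, `tgt`, `id`,
#'   `option`).
#' @export
trajectory_samples <- function(cohort, ids) {
  out <- list()
  for (cs in cohort$casualties) {
    if (!(cs$id %in% ids)) next
    t2 <- cs$times$t2
    warm <- warmup_window(cs)
    for (opt in 1:4) {
      sched <- treatment_schedule(opt)
      u <- rep(sched$block_rates, each = 30)
      tr <- cs$trajectories[[opt]]
      idx <- match((t2 + 1):(t2 + 60), tr$times)
      i2 <- match(t2, tr$times)
      out[[length(out) + 1L]] <- list(
        warm = warm,
        init = c(tr$hr[i2], tr$sbp[i2]),
        u = u,
        tgt = cbind(hr = tr$hr[idx], sbp = tr$sbp[idx]),
        id = cs$id, option = opt)
    }
  }
  out
}

# Pack samples into normalized arrays for batched training.
prep_samples <- function(samples, cfg) {
  N <- length(samples)
  Tw <- nrow(samples[[1]]$warm)
  Tr <- length(samples[[1]]$u)
  WX <- array(0, c(3, Tw, N))
  INIT <- matrix(0, 2, N)
  U <- matrix(0, Tr, N)
  TGT <- array(0, c(2, Tr, N))
  for (i in seq_len(N)) {
    s <- samples[[i]]
    WX[1, , i] <- s$warm[, 1] / cfg$u_norm
    WX[2, , i] <- s$warm[, 2] / cfg$hr_norm
    WX[3, , i] <- s$warm[, 3] / cfg$sbp_norm
    INIT[, i] <- s$init / c(cfg$hr_norm, cfg$sbp_norm)
    U[, i] <- s$u / cfg$u_norm
    TGT[1, , i] <- s$tgt[, 1] / cfg$hr_norm
    TGT[2, , i] <- s$tgt[, 2] / cfg$sbp_norm
  }
  list(WX = WX, INIT = INIT, U = U, TGT = TGT, N = N, Tw = Tw, Tr = Tr)
}

# Forward pass (optionally with caches and gradient) over a batch given by
# index vector `sel`. Returns mean epsilon; with grad=TRUE also gradients.
batch_pass <- function(W, D, sel, cfg, teacher = FALSE, grad = FALSE) {
  B <- length(sel)
  H <- cfg$hidden
  Tw <- D$Tw; Tr <- D$Tr
  h <- matrix(0, H, B)
  warm_cache <- if (grad) vector("list", Tw) else NULL
  for (t in seq_len(Tw)) {
    x <- matrix(D$WX[, t, sel], nrow = 3)
    st <- net_step(W, x, h, cache = grad)
    h <- st$h
    if (grad) warm_cache[[t]] <- st$cache
  }
  roll_cache <- if (grad) vector("list", Tr) else NULL
  Y <- array(0, c(2, Tr, B))
  prev <- matrix(D$INIT[, sel], nrow = 2)
  for (t in seq_len(Tr)) {
    x <- rbind(D$U[t, sel], prev)
    st <- net_step(W, x, h, cache = grad)
    h <- st$h
    Y[, t, ] <- st$y
    if (grad) roll_cache[[t]] <- st$cache
    prev <- if (teacher) matrix(D$TGT[, t, sel], nrow = 2) else st$y
  }
  RES <- Y - D$TGT[, , sel, drop = FALSE]
  # per-sample mean over time of (hr_err^2 + sbp_err^2)
  eps_per <- vapply(seq_len(B),
                    function(b) mean(colSums(matrix(RES[, , b], nrow = 2)^2)),
                    numeric(1))
  eps <- mean(eps_per)
  if (!grad) return(list(eps = eps, eps_per = eps_per, Y = Y))

  g <- new.env()
  for (nm in names(W)) assign(nm, W[[nm]] * 0, envir = g)
  dh <- matrix(0, H, B)
  dy_feedback <- matrix(0, 2, B)
  for (t in rev(seq_len(Tr))) {
    dy <- (2 / (Tr * B)) * matrix(RES[, t, ], nrow = 2) + dy_feedback
    bk <- net_step_backward(W, roll_cache[[t]], dy, dh, g)
    dh <- bk$dh
    dy_feedback <- if (!teacher && t > 1) {
      matrix(bk$dx[2:3, ], nrow = 2)
    } else matrix(0, 2, B)
  }
  zero2 <- matrix(0, 2, B)
  for (t in rev(seq_len(Tw))) {
    bk <- net_step_backward(W, warm_cache[[t]], zero2, dh, g)
    dh <- bk$dh
  }
  grads <- mget(names(W), envir = g)
  list(eps = eps, eps_per = eps_per, Y = Y, grads = grads)
}

#' Evaluate a predictor on a sample set
#'
#' Free-running (closed-loop) evaluation; returns the mean normalized error
#' and pooled RMSEs over all samples and forecast minutes.
#'
#' @param predictor a `gru_predictor` or `gru_ensemble`.
#' @param samples list from [trajectory_samples()].
#' @return List with `epsilon`, `delta_h`, `delta_s`, and per-sample errors
#'   `eps_per`.
#' @export
evaluate_predictor <- function(predictor, samples) {
  cfg <- predictor$config
  preds <- lapply(samples, function(s) predict_outcome(predictor, s))
  se_h <- 0; se_s <- 0; n <- 0
  eps_per <- numeric(length(samples))
  for (i in seq_along(samples)) {
    tgt <- samples[[i]]$tgt
    pr <- preds[[i]]
    eps_per[i] <- epsilon_loss(pr, data.frame(hr = tgt[, 1], sbp = tgt[, 2]),
                               cfg$hr_norm, cfg$sbp_norm)
    se_h <- se_h + sum((pr$hr - tgt[, 1])^2)
    se_s <- se_s + sum((pr$sbp - tgt[, 2])^2)
    n <- n + nrow(tgt)
  }
  list(epsilon = mean(eps_per), delta_h = sqrt(se_h / n),
       delta_s = sqrt(se_s / n), eps_per = eps_per)
}

#' Forecast one sample's 60-min outcome
#'
#' Warm-up on the sample's observed window followed by a closed-loop rollout
#' under its infusion schedule. For ensembles, members roll out
#' independently and the forecasts are averaged.
#'
#' @param predictor a `gru_predictor` or `gru_ensemble`.
#' @param sample a [trajectory_samples()] element (fields `warm`, `init`,
#'   `u`).
#' @return Data frame with columns `hr`, `sbp`.
#' @export
predict_outcome <- function(predictor, sample) {
  UseMethod("predict_outcome")
}

#' @export
predict_outcome.gru_predictor <- function(predictor, sample) {
  st <- gru_warmup(predictor, sample$warm)
  gru_rollout(predictor, st, sample$u, sample$init[1], sample$init[2])
}

#' @export
predict_outcome.gru_ensemble <- function(predictor, sample) {
  preds <- lapply(predictor$members, predict_outcome, sample = sample)
  Reduce(`+`, preds) / length(preds)
}

# Free-running batched evaluation: epsilon plus pooled RMSEs in physical
# units, equivalent to evaluate_predictor() for a single network.
batch_errors <- function(W, D, cfg) {
  out <- batch_pass(W, D, seq_len(D$N), cfg)
  RES <- out$Y - D$TGT
  list(epsilon = out$eps,
       delta_h = sqrt(mean(RES[1, , ]^2)) * cfg$hr_norm,
       delta_s = sqrt(mean(RES[2, , ]^2)) * cfg$sbp_norm)
}

adam_update <- function(W, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  st$t <- st$t + 1
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (nm in names(W)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    W[[nm]] <- W[[nm]] - lr * (st$m[[nm]] / c1) /
      (sqrt(st$v[[nm]] / c2) + eps)
  }
  W
}

#' Train the forecaster on one training/validation split
#'
#' Minimizes the mean normalized error over the training trajectories by
#' Adam with backpropagation through the full closed-loop rollout. The first
#' `tf_frac` of the epoch budget runs teacher-forced (scheduled inputs are
#' the measured vitals) as a stabilizer, after which training is
#' free-running. Early stopping monitors the free-running validation error;
#' the weights of the best validation epoch are kept. Deterministic given
#' `seed`.
#'
#' @param train_samples,val_samples sample lists from
#'   [trajectory_samples()]; the underlying casualty sets must be disjoint.
#' @param config a [gru_config()].
#' @param seed integer seed for initialization and batch shuffling.
#' @param provenance optional list recorded on the result (e.g. fold ids).
#' @return A trained `gru_predictor` with `history` (per-epoch data frame)
#'   and `provenance`.
#' @export
train_fold <- function(train_samples, val_samples, config = gru_config(),
                       seed = 1, provenance = NULL) {
  set.seed(seed)
  pred <- init_predictor(config)
  W <- pred$weights
  Dtr <- prep_samples(train_samples, config)
  Dva <- prep_samples(val_samples, config)
  st <- new.env()
  st$t <- 0
  st$m <- lapply(W, function(w) w * 0)
  st$v <- lapply(W, function(w) w * 0)
  n_tf <- ceiling(config$tf_frac * config$epochs)
  best_val <- Inf; best_W <- W; best_epoch <- 0L; wait <- 0L
  hist <- data.frame(epoch = integer(), train_eps = numeric(),
                     val_eps = numeric(), teacher_forced = logical())
  all_idx <- seq_len(Dtr$N)
  for (ep in seq_len(config$epochs)) {
    teacher <- ep <= n_tf
    ord <- sample(all_idx)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tr_eps <- 0
    for (b in batches) {
      out <- batch_pass(W, Dtr, b, config, teacher = teacher, grad = TRUE)
      if (!is.finite(out$eps)) {
        cond <- structure(class = c("hemotriage_divergence", "error",
                                    "condition"),
                          list(message = "training diverged (non-finite loss)",
                               call = sys.call(), history = hist))
        stop(cond)
      }
      W <- adam_update(W, out$grads, st, config$lr)
      tr_eps <- tr_eps + out$eps * length(b)
    }
    tr_eps <- tr_eps / Dtr$N
    val_eps <- batch_pass(W, Dva, seq_len(Dva$N), config)$eps
    hist <- rbind(hist, data.frame(epoch = ep, train_eps = tr_eps,
                                   val_eps = val_eps,
                                   teacher_forced = teacher))
    if (!teacher) {  # select only among free-running epochs
      if (val_eps < best_val - 1e-12) {
        best_val <- val_eps; best_W <- W; best_epoch <- ep; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    } else {
      best_val <- Inf  # reset when switching regimes
    }
  }
  if (!is.finite(best_val)) { best_W <- W; best_epoch <- nrow(hist) }
  pred$weights <- best_W
  pred$history <- hist
  pred$best_epoch <- best_epoch
  pred$provenance <- provenance
  pred
}

#' 5-fold nested cross-validation of the forecaster
#'
#' For each outer (test) fold, the validation fold rotates over the four
#' remaining folds while the other three train -- 20 fits per hidden size.
#' The hidden size with the lowest mean validation error over the 20 fits is
#' selected, and each outer fold's test predictor is the equal-weight
#' forecast ensemble of its four inner fits at the selected size.
#'
#' @param cohort a [build_cohort()] cohort with 5 folds.
#' @param config a [gru_config()]; its `hidden` field is overridden by the
#'   grid.
#' @param hidden_grid candidate hidden sizes (default `c(128, 256, 512)`).
#' @param seed base seed; per-fit seeds are derived from it.
#' @return Object of class `nested_cv`: `predictors` (5 `gru_ensemble`s,
#'   one per fold), `fits` (per-fit train/validation report),
#'   `test_report` (per-fold test errors), `selected_hidden`, `n_fits`.
#' @export
nested_cv <- function(cohort, config = gru_config(),
                      hidden_grid = c(128, 256, 512), seed = 1) {
  if (length(unique(cohort$fold)) != 5) stop("cohort must have 5 folds")
  ids <- vapply(cohort$casualties, `[[`, numeric(1), "id")
  fold_ids <- lapply(1:5, function(f) ids[cohort$fold == f])
  samples_of <- lapply(1:5, function(f) trajectory_samples(cohort,
                                                           fold_ids[[f]]))
  splits <- list()
  for (o in 1:5) {
    for (v in setdiff(1:5, o)) {
      splits[[length(splits) + 1L]] <- list(outer = o, inner = v,
                                            train = setdiff(1:5, c(o, v)))
    }
  }
  fits <- list()
  report <- NULL
  k <- 0L
  for (Hn in hidden_grid) {
    cfg_h <- config; cfg_h$hidden <- as.integer(Hn)
    for (sp in splits) {
      k <- k + 1L
      tr_s <- do.call(c, samples_of[sp$train])
      va_s <- samples_of[[sp$inner]]
      fit <- train_fold(tr_s, va_s, cfg_h,
                        seed = (seed * 101 + k) %% .Machine$integer.max,
                        provenance = list(outer = sp$outer, inner = sp$inner,
                                          train = sp$train, hidden = Hn))
      tr_err <- batch_errors(fit$weights, prep_samples(tr_s, cfg_h), cfg_h)
      va_err <- batch_errors(fit$weights, prep_samples(va_s, cfg_h), cfg_h)
      fits[[k]] <- fit
      report <- rbind(report, data.frame(
        fit = k, hidden = Hn, outer = sp$outer, inner = sp$inner,
        train_eps = tr_err$epsilon, val_eps = va_err$epsilon,
        train_delta_h = tr_err$delta_h, train_delta_s = tr_err$delta_s,
        val_delta_h = va_err$delta_h, val_delta_s = va_err$delta_s))
    }
  }
  mean_val <- tapply(report$val_eps, report$hidden, mean)
  selected <- as.numeric(names(mean_val)[which.min(mean_val)])
  predictors <- vector("list", 5)
  for (o in 1:5) {
    members <- fits[report$hidden == selected & report$outer == o]
    predictors[[o]] <- structure(
      list(members = members, config = members[[1]]$config,
           provenance = list(outer = o, hidden = selected)),
      class = "gru_ensemble")
  }
  test_report <- NULL
  for (o in 1:5) {
    te <- evaluate_predictor(predictors[[o]], samples_of[[o]])
    test_report <- rbind(test_report, data.frame(
      fold = o, test_eps = te$epsilon, test_delta_h = te$delta_h,
      test_delta_s = te$delta_s))
  }
  structure(list(predictors = predictors, fits = report,
                 test_report = test_report, selected_hidden = selected,
                 n_fits = sum(report$hidden == selected),
                 mean_val_eps = mean_val, fold_ids = fold_ids),
            class = "nested_cv")
}

#' Audit a nested cross-validation for test-set leakage
#'
#' Verifies that every test casualty is absent from the training and
#' validation folds of its own fold's predictor.
#'
#' @param cv a [nested_cv()] result.
#' @param cohort the cohort it was fitted on.
#' @return `TRUE` invisibly; errors on leakage.
#' @export
audit_leakage <- function(cv, cohort) {
  ids <- vapply(cohort$casualties, `[[`, numeric(1), "id")
  for (o in 1:5) {
    test_ids <- ids[cohort$fold == o]
    for (m in cv$predictors[[o]]$members) {
      used_folds <- c(m$provenance$train, m$provenance$inner)
      if (o %in% used_folds) stop("fold leakage: outer fold used in fit")
      used_ids <- ids[cohort$fold %in% used_folds]
      if (length(intersect(test_ids, used_ids)) > 0) {
        stop("casualty leakage between test and train/validation sets")
      }
    }
  }
  invisible(TRUE)
}
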