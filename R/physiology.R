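#' Physiological parameters of a virtual subject
#'
#' Constructs the parameter vector of the surrogate cardiovascular model for
#' one virtual individual. The surrogate is a lumped first-order model: blood
#' volume obeys a mass balance over bleeding, transcapillary refill, and
#' infusion, and heart rate (HR) and systolic blood pressure (SBP) relax with
#' first-order kinetics toward piecewise-linear targets driven by the
#' fractional volume deficit.
#'
#' @param V0 baseline blood volume (L).
#' @param HR0 baseline heart rate (beats/min).
#' @param SBP0 baseline systolic blood pressure (mmHg).
#' @param g_hr HR gain (beats/min per unit fractional deficit).
#' @param a_sbp compensated SBP slope (mmHg per unit deficit), acting below
#'   the breakpoint `d_c`.
#' @param b_sbp decompensated SBP slope (mmHg per unit deficit), acting above
#'   `d_c`.
#' @param d_c compensation breakpoint as a fractional deficit, in (0, 0.5).
#' @param tau_hr,tau_sbp first-order response time constants (min).
#' @param k_r transcapillary refill rate constant (1/min).
#'
#' @return An object of class `subject_params` (named list of the ten
#'   parameters).
#' @examples
#' p <- subject_params()
#' p$HR0
#' @export
subject_params <- function(V0 = 5.0, HR0 = 75, SBP0 = 120, g_hr = 250,
                           a_sbp = 40, b_sbp = 250, d_c = 0.15,
                           tau_hr = 3, tau_sbp = 3, k_r = 0.004) {
  p <- list(V0 = V0, HR0 = HR0, SBP0 = SBP0, g_hr = g_hr, a_sbp = a_sbp,
            b_sbp = b_sbp, d_c = d_c, tau_hr = tau_hr, tau_sbp = tau_sbp,
            k_r = k_r)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all subject parameters must be finite and > 0")
  }
  if (d_c >= 0.5) stop("d_c must lie in (0, 0.5)")
  structure(p, class = "subject_params")
}

#' Names of the subject parameters
#'
#' @return Character vector of the ten parameter names, in canonical order.
#' @export
subject_param_names <- function() {
  c("V0", "HR0", "SBP0", "g_hr", "a_sbp", "b_sbp", "d_c",
    "tau_hr", "tau_sbp", "k_r")
}

#' Coerce a named numeric vector or one-row data frame to `subject_params`
#'
#' @param x named numeric vector, list, or one-row data frame containing the
#'   ten parameters named as in [subject_param_names()].
#' @return A `subject_params` object.
#' @export
as_subject_params <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- as.list(x)
  }
  x <- as.list(x)[subject_param_names()]
  do.call(subject_params, lapply(x, as.numeric))
}

#' Simulation input: hemorrhage, tourniquet, residual bleeding, infusion
#'
#' @param bleed_rate constant hemorrhage rate over `[0, t1]` (L/min).
#' @param t1 tourniquet application time (min).
#' @param f_nc residual (non-compressible) fraction of `bleed_rate`
#'   persisting after `t1`, in `[0, 1]`.
#' @param infusion piecewise-constant infusion schedule: data frame with
#'   columns `start`, `end` (min) and `rate` (L/h); segments must not
#'   overlap. `NULL` means no infusion.
#' @param horizon total simulated duration (min, integer).
#' @param step internal integration step (min); must divide 1 exactly.
#'
#' @return An object of class `sim_input`.
#' @export
sim_input <- function(bleed_rate, t1, f_nc = 0, infusion = NULL,
                      horizon, step = 0.1) {
  if (bleed_rate < 0) stop("bleed_rate must be >= 0")
  if (f_nc < 0 || f_nc > 1) stop("f_nc must lie in [0, 1]")
  n_sub <- 1 / step
  if (abs(n_sub - round(n_sub)) > 1e-9) stop("step must divide 1.0")
  if (horizon < 1 || horizon != round(horizon)) {
    stop("horizon must be a positive whole number of minutes")
  }
  if (!is.null(infusion)) {
    stopifnot(is.data.frame(infusion),
              all(c("start", "end", "rate") %in% names(infusion)))
    infusion <- infusion[order(infusion$start), , drop = FALSE]
    if (any(infusion$rate < 0)) stop("infusion rates must be >= 0")
    if (any(infusion$end <= infusion$start)) {
      stop("infusion segments must have end > start")
    }
    if (nrow(infusion) > 1 &&
        any(infusion$start[-1] < infusion$end[-nrow(infusion)] - 1e-9)) {
      stop("infusion segments must not overlap")
    }
    if (max(infusion$end) > horizon) stop("horizon must cover the infusion")
  }
  structure(list(bleed_rate = bleed_rate, t1 = t1, f_nc = f_nc,
                 infusion = infusion, horizon = as.integer(horizon),
                 step = step),
            class = "sim_input")
}

# Infusion rate u(t) in L/h on a vector of times (left-continuous blocks:
# a segment [start, end) applies at t in [start, end)).
infusion_rate_at <- function(infusion, t) {
  u <- numeric(length(t))
  if (is.null(infusion)) return(u)
  for (i in seq_len(nrow(infusion))) {
    sel <- t >= infusion$start[i] - 1e-12 & t < infusion$end[i] - 1e-12
    u[sel] <- infusion$rate[i]
  }
  u
}

#' Simulate vital-sign trajectories for one subject
#'
#' Integrates the surrogate model with a fixed-step explicit Euler scheme and
#' reports the state on the integer-minute grid `0..horizon`. The governing
#' equations are
#' \deqn{dV/dt = -b(t) + k_r (V_0 - V) + u(t)/60,}
#' with \eqn{b(t) = } `bleed_rate` for \eqn{t < t_1} and
#' `f_nc * bleed_rate` afterwards, deficit
#' \eqn{d = \max(0, (V_0 - V)/V_0)}, targets
#' \eqn{HR^* = HR_0 + g_{hr} d} and
#' \eqn{SBP^* = SBP_0 - a_{sbp}\min(d, d_c) - b_{sbp}\max(0, d - d_c)},
#' and first-order relaxation of HR and SBP toward those targets with time
#' constants `tau_hr`, `tau_sbp`. HR and SBP are never clamped;
#' out-of-range excursions are only flagged.
#'
#' @param params a [subject_params()] object.
#' @param input a [sim_input()] object; `horizon` must cover any infusion.
#'
#' @return An object of class `vitals_trajectory`: list with integer `times`
#'   (min), numeric `hr`, `sbp`, `volume` series, and flags `completed`
#'   (integration finished with finite, non-negative volume),
#'   `in_physiological_range` (40 <= HR <= 200 and 40 <= SBP <= 260 at every
#'   reported minute), and `oscillatory` (see [detect_oscillation()]). The
#'   tourniquet time is kept as attribute `t1`.
#' @examples
#' p <- subject_params()
#' inp <- sim_input(bleed_rate = 0.15, t1 = 10, horizon = 90)
#' tr <- simulate_vitals(p, inp)
#' tr$hr[c(1, 11, 91)]
#' @export
simulate_vitals <- function(params, input) {
  stopifnot(inherits(params, "subject_params"), inherits(input, "sim_input"))
  h <- input$step
  n_sub <- as.integer(round(1 / h))
  horizon <- input$horizon
  n_steps <- horizon * n_sub

  times <- 0:horizon
  hr_out <- numeric(horizon + 1)
  sbp_out <- numeric(horizon + 1)
  vol_out <- numeric(horizon + 1)

  # precompute per-substep exogenous flows
  tgrid <- (0:(n_steps - 1)) * h
  b <- ifelse(tgrid < input$t1 - 1e-12, input$bleed_rate,
              input$f_nc * input$bleed_rate)
  u <- infusion_rate_at(input$infusion, tgrid) / 60  # L/min

  V0 <- params$V0; HR0 <- params$HR0; SBP0 <- params$SBP0
  g_hr <- params$g_hr; a_sbp <- params$a_sbp; b_sbp <- params$b_sbp
  d_c <- params$d_c; inv_th <- 1 / params$tau_hr; inv_ts <- 1 / params$tau_sbp
  k_r <- params$k_r

  V <- V0; HR <- HR0; SBP <- SBP0
  hr_out[1] <- HR; sbp_out[1] <- SBP; vol_out[1] <- V
  completed <- TRUE
  out_idx <- 2L

  for (k in seq_len(n_steps)) {
    dV <- -b[k] + k_r * (V0 - V) + u[k]
    d <- max(0, (V0 - V) / V0)
    hr_t <- HR0 + g_hr * d
    sbp_t <- SBP0 - a_sbp * min(d, d_c) - b_sbp * max(0, d - d_c)
    V <- V + h * dV
    HR <- HR + h * (hr_t - HR) * inv_th
    SBP <- SBP + h * (sbp_t - SBP) * inv_ts
    if (!is.finite(V) || !is.finite(HR) || !is.finite(SBP) || V < 0) {
      completed <- FALSE
      break
    }
    if (k %% n_sub == 0L) {
      hr_out[out_idx] <- HR; sbp_out[out_idx] <- SBP; vol_out[out_idx] <- V
      out_idx <- out_idx + 1L
    }
  }
  if (!completed && out_idx <= horizon + 1L) {
    hr_out[out_idx:(horizon + 1L)] <- NA_real_
    sbp_out[out_idx:(horizon + 1L)] <- NA_real_
    vol_out[out_idx:(horizon + 1L)] <- NA_real_
  }

  in_range <- completed &&
    all(hr_out >= 40 & hr_out <= 200) &&
    all(sbp_out >= 40 & sbp_out <= 260)

  traj <- structure(
    list(times = times, hr = hr_out, sbp = sbp_out, volume = vol_out,
         completed = completed,
         in_physiological_range = isTRUE(in_range),
         oscillatory = NA),
    class = "vitals_trajectory", t1 = input$t1)
  if (completed) {
    traj$oscillatory <- detect_oscillation(traj, settle = input$t1)
  }
  traj
}

#' Flag oscillatory vital-sign trajectories
#'
#' A trajectory is called oscillatory when the HR series after
#' `max(t1, settle)` minutes shows more than 2 local extrema of prominence
#' greater than 2 beats/min. Prominence of an extremum is taken as the
#' smaller absolute difference to the neighbouring extrema (series endpoints
#' counting as extrema).
#'
#' @param traj a completed [simulate_vitals()] trajectory.
#' @param settle minutes to discard before counting extrema (in addition to
#'   the tourniquet time recorded on the trajectory).
#' @return Logical flag.
#' @export
detect_oscillation <- function(traj, settle = 0) {
  stopifnot(inherits(traj, "vitals_trajectory"))
  if (!isTRUE(traj$completed)) stop("trajectory did not complete")
  t_start <- max(attr(traj, "t1"), settle)
  idx <- which(traj$times >= t_start)
  if (length(idx) < 3L) stop("series shorter than the settle window")
  x <- traj$hr[idx]
  dx <- diff(x)
  s <- sign(dx)
  s <- s[s != 0]
  if (length(s) < 2L) return(FALSE)
  # positions of strict local extrema
  d1 <- diff(x)
  ext <- which(d1[-length(d1)] * d1[-1] < 0) + 1L
  if (length(ext) == 0L) return(FALSE)
  anchors <- c(1L, ext, length(x))
  vals <- x[anchors]
  n_prom <- 0L
  for (j in seq_along(ext)) {
    v <- vals[j + 1L]
    prom <- min(abs(v - vals[j]), abs(v - vals[j + 2L]))
    if (prom > 2) n_prom <- n_prom + 1L
  }
  n_prom > 2L
}

#' Write / read a trajectory as CSV plus a JSON sidecar
#'
#' The CSV holds columns `minute`, `hr`, `sbp`, `volume`; the sidecar JSON
#' (same path with extension `.json`) records the flags and, when supplied,
#' the subject parameters and simulation input.
#'
#' @param traj a `vitals_trajectory`.
#' @param path CSV file path.
#' @param params,input optional provenance objects to embed in the sidecar.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, params = NULL, input = NULL) {
  df <- data.frame(minute = traj$times, hr = traj$hr, sbp = traj$sbp,
                   volume = traj$volume)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(completed = traj$completed,
               in_physiological_range = traj$in_physiological_range,
               oscillatory = traj$oscillatory,
               t1 = attr(traj, "t1"))
  if (!is.null(params)) side$params <- unclass(params)
  if (!is.null(input)) {
    side$input <- list(bleed_rate = input$bleed_rate, t1 = input$t1,
                       f_nc = input$f_nc, horizon = input$horizon,
                       step = input$step, infusion = input$infusion)
  }
  jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  structure(list(times = df$minute, hr = df$hr, sbp = df$sbp,
                 volume = df$volume,
                 completed = side$completed,
                 in_physiological_range = side$in_physiological_range,
                 oscillatory = side$oscillatory),
            class = "vitals_trajectory", t1 = side$t1)
}
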