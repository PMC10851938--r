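#' Vertices of the admissible hemorrhage region
#'
#' The admissible (bleeding time, volume loss) region is the pentagon
#' \eqn{\{5 \le T \le 15,\ 0.75 \le V \le 2.0,\ V \le 0.22\,T\}}: Class II/III
#' blood losses of 0.75--2.00 L over 5--15 min, capped at a hemorrhage rate
#' of 0.22 L/min.
#'
#' @return A 5 x 2 matrix with columns `T_b` (min) and `volume_loss` (L),
#'   counterclockwise starting at (5, 0.75).
#' @examples
#' pentagon_vertices()
#' @export
pentagon_vertices <- function() {
  m <- rbind(c(5, 0.75),
             c(15, 0.75),
             c(15, 2.0),
             c(2.0 / 0.22, 2.0),
             c(5, 0.22 * 5))
  colnames(m) <- c("T_b", "volume_loss")
  m
}

#' Sample hemorrhage scenarios uniformly over the admissible pentagon
#'
#' Rejection sampling from the bounding box `[5,15] x [0.75,2]`, accepting
#' points with rate `volume_loss / T_b <= 0.22` L/min. Uses the current R
#' random-number stream; call `set.seed()` for reproducibility.
#'
#' @param n number of scenarios.
#' @return Data frame with columns `T_b` (min), `volume_loss` (L), and
#'   `rate` (L/min).
#' @export
sample_hemorrhage <- function(n = 1) {
  out <- matrix(NA_real_, nrow = 0, ncol = 2)
  while (nrow(out) < n) {
    m <- max(n - nrow(out), 16L)
    Tb <- stats::runif(m, 5, 15)
    V <- stats::runif(m, 0.75, 2.0)
    keep <- V <= 0.22 * Tb
    out <- rbind(out, cbind(Tb[keep], V[keep]))
  }
  out <- out[seq_len(n), , drop = FALSE]
  data.frame(T_b = out[, 1], volume_loss = out[, 2],
             rate = out[, 2] / out[, 1])
}

#' Sample the event timeline for one scenario
#'
#' Events: injury at `t0 = 0`, tourniquet at `t1 = T_b`, infusion start at
#' `t2` drawn uniformly 10--15 min after `t1` and rounded to the whole
#' minute (so that the 10-min observation window and the 60-min rollout
#' align with the minute grid), end of scenario at `t3 = t2 + 60`.
#'
#' @param T_b bleeding time (min), i.e. the tourniquet time.
#' @return List with elements `t0`, `t1`, `t2`, `t3` (min).
#' @export
sample_event_times <- function(T_b) {
  t2 <- round(T_b + stats::runif(1, 10, 15))
  list(t0 = 0, t1 = T_b, t2 = as.integer(t2), t3 = as.integer(t2 + 60))
}

#' Rate of one whole-blood unit infused over 30 minutes
#'
#' One unit of whole blood averages 0.55 L; infused over a 30-min block this
#' is a constant 1.10 L/h.
#' @keywords internal
UNIT_RATE_LPH <- 1.10

#' Volume of one whole-blood unit (L)
#' @keywords internal
UNIT_VOLUME_L <- 0.55

#' The four fluid treatment options
#'
#' Treatments span two consecutive 30-min blocks starting at `t2`, each block
#' infusing 0 or 1 unit (0.55 L at 1.10 L/h): option 1 = (0, 0), option 2 =
#' (0, 1), option 3 = (1, 0), option 4 = (1, 1).
#'
#' @param option_id integer 1..4.
#' @return Object of class `treatment_option`: list with `id`, `block_rates`
#'   (two L/h rates), and `units` (0..2).
#' @examples
#' treatment_schedule(4)$units
#' @export
treatment_schedule <- function(option_id) {
  if (!option_id %in% 1:4) stop("unknown treatment option: ", option_id)
  blocks <- switch(option_id,
                   c(0, 0),
                   c(0, UNIT_RATE_LPH),
                   c(UNIT_RATE_LPH, 0),
                   c(UNIT_RATE_LPH, UNIT_RATE_LPH))
  structure(list(id = as.integer(option_id), block_rates = blocks,
                 units = sum(blocks > 0)),
            class = "treatment_option")
}

#' Map block units to a treatment option id
#'
#' @param first,second 0/1 units in the first and second 30-min block.
#' @return Option id 1..4.
#' @export
option_from_blocks <- function(first, second) {
  as.integer(1 + second + 2 * first)
}

#' Expand a treatment option into an infusion schedule
#'
#' @param option a [treatment_schedule()] object or option id.
#' @param times event times as returned by [sample_event_times()].
#' @return Data frame with columns `start`, `end` (min), `rate` (L/h),
#'   suitable for [sim_input()]; zero-rate blocks are dropped. `NULL` when
#'   no fluid is given.
#' @export
infusion_schedule <- function(option, times) {
  if (is.numeric(option)) option <- treatment_schedule(option)
  starts <- c(times$t2, times$t2 + 30)
  ends <- c(times$t2 + 30, times$t3)
  keep <- option$block_rates > 0
  if (!any(keep)) return(NULL)
  data.frame(start = starts[keep], end = ends[keep],
             rate = option$block_rates[keep])
}

#' Total fluid volume of a treatment option (L)
#'
#' @param option a [treatment_schedule()] object or option id.
#' @return Infused volume in litres.
#' @export
total_infused <- function(option) {
  if (is.numeric(option)) option <- treatment_schedule(option)
  sum(option$block_rates) * 30 / 60
}

#' Area of the admissible pentagon (shoelace formula)
#'
#' @return Area in min x L units.
#' @export
pentagon_area <- function() {
  v <- pentagon_vertices()
  x <- v[, 1]; y <- v[, 2]
  i2 <- c(2:nrow(v), 1)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

#' Point-in-pentagon test for hemorrhage scenarios
#'
#' @param T_b,volume_loss coordinates to test (vectorized).
#' @return Logical vector.
#' @export
in_pentagon <- function(T_b, volume_loss) {
  T_b >= 5 & T_b <= 15 & volume_loss >= 0.75 & volume_loss <= 2.0 &
    volume_loss <= 0.22 * T_b
}
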