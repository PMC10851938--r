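#' Deterministic miniature cohort
#'
#' Runs the full sampling-and-filtering pipeline at reduced scale under a
#' fixed seed, for fast tests and examples.
#'
#' @param seed integer seed.
#' @param n_f cohort size (divisible by 5).
#' @param pool_size candidate parameter sets per sampling round.
#' @return A [build_cohort()] cohort.
#' @export
make_mini_cohort <- function(seed, n_f = 10, pool_size = 800) {
  set.seed(seed)
  build_cohort(n_f = n_f, pool_size = pool_size)
}

# Build a stub trajectory on the full minute grid whose vitals take given
# values at t2, t2+30, and t3 (constant within the three segments).
stub_trajectory <- function(times, v_t2, v_mid, v_end) {
  grid <- 0:times$t3
  hr <- numeric(length(grid)); sbp <- numeric(length(grid))
  seg <- findInterval(grid, c(times$t2 + 30, times$t3)) + 1L
  vals <- rbind(v_t2, v_mid, v_end)
  hr <- vals[seg, 1]
  sbp <- vals[seg, 2]
  structure(list(times = grid, hr = hr, sbp = sbp,
                 volume = rep(5, length(grid)), completed = TRUE,
                 in_physiological_range = TRUE, oscillatory = FALSE),
            class = "vitals_trajectory", t1 = times$t1)
}

#' Cohort-like stub realizing a prescribed needs profile
#'
#' Builds stub casualties whose ground-truth trajectory endpoints realize
#' exactly the given fluid needs, by direct endpoint injection: no
#' simulation is involved, so allocator logic is exercised purely through
#' the trajectory interface. Unhealthy vitals are (130, 80), healthy
#' (90, 110). Every stub is outside the target range at `t2`. At `t2 + 30`,
#' untreated blocks show unhealthy vitals; a treated first block shows
#' healthy mid-course vitals when the casualty needs at most 1 unit.
#'
#' @param needs vector over casualties with entries 0, 1, 2, or `NA`
#'   (unrestorable).
#' @return List of stub casualties usable with the allocation functions.
#' @examples
#' stub <- make_needs_profile(c(0, 1, 1, 2))
#' oracle_allocate(stub, 3)$units_used
#' @export
make_needs_profile <- function(needs) {
  times <- list(t0 = 0, t1 = 10, t2 = 20, t3 = 80)
  bad <- c(130, 80); good <- c(90, 110)
  lapply(seq_along(needs), function(i) {
    nd <- needs[i]
    end_ok <- if (is.na(nd)) c(FALSE, FALSE, FALSE, FALSE)
    else switch(nd + 1L,
                c(TRUE, TRUE, TRUE, TRUE),     # need 0
                c(FALSE, TRUE, TRUE, TRUE),    # need 1
                c(FALSE, FALSE, FALSE, TRUE))  # need 2
    trajectories <- lapply(1:4, function(opt) {
      first_treated <- opt %in% c(3, 4)
      mid <- if (first_treated && !is.na(nd) && nd <= 1) good else bad
      stub_trajectory(times, bad, mid,
                      if (end_ok[opt]) good else bad)
    })
    list(id = i, params = NULL, baseline = c(hr = 75, sbp = 120),
         hemorrhage = data.frame(T_b = 10, volume_loss = 1, rate = 0.1),
         times = times, trajectories = trajectories)
  })
}
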