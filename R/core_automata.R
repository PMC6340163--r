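# Single-cell timed-automaton semantics.
#
# A cell is a three-state oscillator automaton with states
#   F (firing)  -- rapid depolarization,
#   R (refractory) -- plateau/repolarization, cannot be re-excited,
#   A (activity/rest) -- excitable; SAN cells slowly drift to self-excitation,
# a single clock x that advances by one per global step, and per-state guards
# f, r, a.  Transitions are cyclic F -> R -> A -> F with clock reset.
# The step semantics is "increment-then-check": each step the clock is
# incremented, then the guard of the current phase is evaluated, so a phase
# with guard theta lasts exactly ceiling(theta) steps and an isolated cell
# fires every f + r + a steps (for integer timers).

PHASES <- c("F", "R", "A")

# integer codes used by the vectorized engine
.PH_F <- 1L
.PH_R <- 2L
.PH_A <- 3L

#' Per-cell clock guards
#'
#' Bundles the three guard durations of a cell automaton.  `f` and `a` are
#' the firing and activity guards; the refractory guard `r` is drawn once per
#' cell as `r = r0 + r_noise * xi` with `xi ~ U(0, 1)` (see
#' [draw_refractory()]), which models cell-to-cell variability of the
#' action-potential duration.  Clocks are integers, so a fractional `r`
#' yields an effective refractory stay of `ceiling(r)` steps.
#'
#' @param f firing-state guard, in steps (`> 0`).
#' @param r0 baseline refractory guard, in steps (`> 0`).
#' @param a activity-state guard, in steps (`> 0`); the time to
#'   self-excitation for a pacemaker cell.
#' @param r_noise amplitude of the uniform refractory spread, in steps
#'   (`>= 0`).
#' @param r realized refractory guard; defaults to `r0` (no noise applied).
#' @return An object of class `cell_timers`.
#' @examples
#' cell_timers(f = 5, r0 = 70, a = 40)
#' @export
cell_timers <- function(f, r0, a, r_noise = 0, r = r0) {
  if (f <= 0 || r0 <= 0 || a <= 0)
    stop("timer guards `f`, `r0` and `a` must be positive")
  if (r_noise < 0) stop("`r_noise` must be non-negative")
  if (r < r0 || r > r0 + r_noise)
    stop("`r` must lie in [r0, r0 + r_noise]")
  structure(list(f = f, r = r, a = a, r0 = r0, r_noise = r_noise),
            class = "cell_timers")
}

#' @export
print.cell_timers <- function(x, ...) {
  cat(sprintf("cell timers: f = %g, r = %g (r0 = %g, r_noise = %g), a = %g\n",
              x$f, x$r, x$r0, x$r_noise, x$a))
  invisible(x)
}

#' Draw a refractory guard
#'
#' Realizes the per-cell refractory duration `r = r0 + r_noise * xi` from a
#' uniform deviate `xi` in `[0, 1]`.  All arguments are vectorized.
#'
#' @param r0 baseline refractory guard(s), positive.
#' @param r_noise uniform spread amplitude(s), non-negative.
#' @param xi uniform deviate(s) in `[0, 1]`.
#' @return `r0 + r_noise * xi`.
#' @examples
#' draw_refractory(50, 10, 0.37) # 53.7
#' @export
draw_refractory <- function(r0, r_noise, xi) {
  if (any(r0 <= 0)) stop("`r0` must be positive")
  if (any(r_noise < 0)) stop("`r_noise` must be non-negative")
  if (any(xi < 0 | xi > 1)) stop("`xi` must lie in [0, 1]")
  r0 + r_noise * xi
}

#' Interaction thresholds for neighbor stimulation
#'
#' A cell in `R` whose number of firing in-neighbors strictly exceeds `N_R`
#' has its clock halved (prolonging the refractory stay); a cell in `A`
#' whose number of firing in-neighbors strictly exceeds `N_F` is forced to
#' fire.
#'
#' @param N_R refractory-prolongation threshold (non-negative integer).
#' @param N_F forced-firing threshold (non-negative integer).
#' @return An object of class `interaction_thresholds`.
#' @export
interaction_thresholds <- function(N_R = 3, N_F = 0) {
  if (N_R < 0 || N_F < 0) stop("thresholds must be non-negative")
  structure(list(N_R = as.integer(N_R), N_F = as.integer(N_F)),
            class = "interaction_thresholds")
}

#' Intrinsic automaton step
#'
#' Advances an isolated cell by one global step: the clock increments by
#' one, then the guard of the current phase is evaluated and, if met, the
#' cyclic transition fires with clock reset.  The `A -> F` (fire) transition
#' may be refused: when `refuse_draw < p_refuse` the cell stays in `A` and
#' its clock keeps growing past `a`; the refusal is re-tested on every
#' subsequent step while the guard holds.
#'
#' @param phase one of `"F"`, `"R"`, `"A"`.
#' @param x current clock value (non-negative).
#' @param timers a [cell_timers()] object.
#' @param refuse_draw uniform deviate in `[0, 1]` used for the refusal test;
#'   the default `1` never refuses.
#' @param p_refuse probability of refusing an enabled fire transition.
#' @return A list with elements `phase` and `x`.
#' @examples
#' intrinsic_step("A", 38, cell_timers(5, 70, 40)) # time pass
#' intrinsic_step("A", 39, cell_timers(5, 70, 40)) # fires
#' @export
intrinsic_step <- function(phase, x, timers, refuse_draw = 1, p_refuse = 0) {
  if (x < 0) stop("clock `x` must be non-negative")
  if (p_refuse < 0 || p_refuse > 1) stop("`p_refuse` must lie in [0, 1]")
  x1 <- x + 1
  switch(phase,
    "F" = if (x1 >= timers$f) list(phase = "R", x = 0)
          else list(phase = "F", x = x1),
    "R" = if (x1 >= timers$r) list(phase = "A", x = 0)
          else list(phase = "R", x = x1),
    "A" = if (x1 >= timers$a && refuse_draw >= p_refuse)
            list(phase = "F", x = 0)
          else list(phase = "A", x = x1),
    stop("`phase` must be one of \"F\", \"R\", \"A\"")
  )
}

#' Automaton step under neighbor stimulation
#'
#' Applies the neighbor-interaction rules before the intrinsic step, with
#' precedence forced firing > refractory clock halving > intrinsic guard
#' transition > time pass:
#'
#' * phase `A` with `n_firing > N_F`: the cell is forced to fire, `(F, 0)`,
#'   subject to the same refusal test as intrinsic firing;
#' * phase `R` with `n_firing > N_R`: the clock is halved,
#'   `x <- floor(x / 2)`, replacing this step's increment, so the refractory
#'   stay is prolonged;
#' * otherwise the intrinsic step applies unchanged.
#'
#' @inheritParams intrinsic_step
#' @param n_firing number of connected in-neighbors currently in `F`.
#' @param thresholds an [interaction_thresholds()] object.
#' @return A list with elements `phase`, `x` and `fired` (logical; `TRUE`
#'   when the cell entered `F` this step).
#' @examples
#' tm <- cell_timers(5, 50, 1150)
#' interact_step("R", 10, tm, n_firing = 4, interaction_thresholds(N_R = 3))
#' @export
interact_step <- function(phase, x, timers, n_firing,
                          thresholds = interaction_thresholds(),
                          refuse_draw = 1, p_refuse = 0) {
  if (n_firing < 0) stop("`n_firing` must be non-negative")
  if (phase == "A" && n_firing > thresholds$N_F) {
    if (refuse_draw >= p_refuse) return(list(phase = "F", x = 0, fired = TRUE))
    return(list(phase = "A", x = x + 1, fired = FALSE))
  }
  if (phase == "R" && n_firing > thresholds$N_R)
    return(list(phase = "R", x = floor(x / 2), fired = FALSE))
  res <- intrinsic_step(phase, x, timers, refuse_draw, p_refuse)
  res$fired <- phase == "A" && res$phase == "F"
  res
}

#' Intrinsic cycle period
#'
#' The exact firing-to-firing interval of an isolated cell, `f + r + a`.
#' For the sinoatrial node this is the nominal pacing period `T_SAN`.
#'
#' @param timers a [cell_timers()] object.
#' @return Number of steps per cycle.
#' @examples
#' cycle_period(cell_timers(5, 70, 40)) # 115
#' @export
cycle_period <- function(timers) timers$f + timers$r + timers$a

#' Simulate an isolated cell
#'
#' Runs [intrinsic_step()] for `n_steps` steps from `(A, 0)`, drawing one
#' refusal deviate per step from the current RNG stream when
#' `p_refuse > 0`.
#'
#' @inheritParams intrinsic_step
#' @param n_steps number of steps to simulate.
#' @return A list with `phases` (character vector, phase after each step)
#'   and `fire_steps` (steps at which the cell entered `F`).
#' @export
simulate_cell <- function(timers, n_steps, p_refuse = 0) {
  phases <- character(n_steps)
  fire_steps <- integer(0)
  phase <- "A"; x <- 0
  for (t in seq_len(n_steps)) {
    draw <- if (p_refuse > 0 && phase == "A" && x + 1 >= timers$a)
      stats::runif(1) else 1
    st <- intrinsic_step(phase, x, timers, draw, p_refuse)
    if (st$phase == "F" && phase != "F") fire_steps <- c(fire_steps, t)
    phase <- st$phase; x <- st$x
    phases[t] <- phase
  }
  list(phases = phases, fire_steps = fire_steps)
}
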