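# Synchronous global update of the tissue, AVN event detection, RR-series
# extraction, first-front tracking and the refusal-probability random walk.
#
# All cells update simultaneously from a snapshot of the phases at the
# beginning of the step, so the wavefront advances one lattice link per
# step.  Per-step precedence: forced firing > refractory clock halving >
# intrinsic guard transition > time pass.  The RNG is consumed in a fixed
# order within each step (random-walk deviates first, then one refusal
# deviate per fire-enabled cell in row-major order), which makes runs
# bit-reproducible from the seed.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulation configuration
#'
#' Aggregates the lattice, region geometry, per-role timers, interaction
#' thresholds and run-control parameters of a tissue simulation.
#'
#' @param lattice a [lattice_spec()].
#' @param regions a [node_regions()] for the same lattice size.
#' @param timers named list of per-role [cell_timers()]; see
#'   [default_timers()].
#' @param N_R,N_F interaction thresholds (strict `>` comparison); see
#'   [interaction_thresholds()].
#' @param p_refuse probability that a cell refuses an enabled fire
#'   transition, in `[0, 1]`.
#' @param refuse_roles roles the refusal applies to (default: all).
#' @param refuse_mode `"episode"` (default: one refusal draw per
#'   excitation attempt, so a passing wavefront tests each cell once) or
#'   `"step"` (the draw is re-taken every step while the transition is
#'   enabled).
#' @param total_steps number of global steps to simulate.
#' @param transient_beats number of leading RR intervals discarded before
#'   rhythm analysis.
#' @param seed integer seed making the run reproducible.
#' @param stop_after_events optional early-stop: end the run once this many
#'   AVN events have been recorded.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(lattice = lattice_spec(),
                       regions = node_regions(lattice$L),
                       timers = default_timers(),
                       N_R = 3, N_F = 0,
                       p_refuse = 0,
                       refuse_roles = c("SAN", "ATRIAL", "AVN"),
                       refuse_mode = c("episode", "step"),
                       total_steps = 5000,
                       transient_beats = 10,
                       seed = NULL,
                       stop_after_events = NULL) {
  refuse_mode <- match.arg(refuse_mode)
  if (total_steps <= 0) stop("`total_steps` must be positive")
  if (transient_beats < 0) stop("`transient_beats` must be non-negative")
  if (p_refuse < 0 || p_refuse > 1) stop("`p_refuse` must lie in [0, 1]")
  if (!all(refuse_roles %in% c("SAN", "ATRIAL", "AVN")))
    stop("unknown role in `refuse_roles`")
  structure(list(lattice = lattice, regions = regions, timers = timers,
                 N_R = N_R, N_F = N_F, p_refuse = p_refuse,
                 refuse_roles = refuse_roles, refuse_mode = refuse_mode,
                 total_steps = as.integer(total_steps),
                 transient_beats = as.integer(transient_beats),
                 seed = seed, stop_after_events = stop_after_events),
            class = "sim_config")
}

#' Random-walk specification for the refusal probability
#'
#' Between tissue steps, `p_refuse` attempts a move of size `eps` with
#' probability `p_walk`; the sign is chosen at random and a move leaving
#' the interval `[0, z]` is rejected (the value stays put, it is not
#' clamped).
#'
#' @param p_walk per-step move probability in `[0, 1]`.
#' @param eps step size (`> 0`).
#' @param z upper bound of the admissible interval `[0, z]`.
#' @return An object of class `walk_spec`.
#' @export
walk_spec <- function(p_walk = 0.001, eps = 0.05, z = 0.45) {
  if (p_walk < 0 || p_walk > 1) stop("`p_walk` must lie in [0, 1]")
  if (eps <= 0) stop("`eps` must be positive")
  if (z <= 0 || z > 1) stop("`z` must lie in (0, 1]")
  structure(list(p_walk = p_walk, eps = eps, z = z), class = "walk_spec")
}

#' One random-walk update of the refusal probability
#'
#' @param p current value, in `[0, z]`.
#' @param walk a [walk_spec()].
#' @param zeta uniform deviate in `[0, 1]` deciding whether a move is
#'   attempted.
#' @param sign move direction, `+1` or `-1`.
#' @return The updated value; unchanged when no move is attempted or the
#'   attempted move leaves `[0, z]`.
#' @examples
#' walk_refuse(0.44, walk_spec(eps = 0.05, z = 0.45), zeta = 0, sign = +1)
#' @export
walk_refuse <- function(p, walk, zeta, sign) {
  if (zeta < walk$p_walk) {
    cand <- p + sign * walk$eps
    if (cand >= 0 && cand <= walk$z) return(cand)
  }
  p
}

#' Run a refusal-probability random walk on its own
#'
#' Convenience driver used to study the walk in isolation: draws the
#' per-step deviates from the current RNG stream and iterates
#' [walk_refuse()].
#'
#' @param n_steps number of steps.
#' @param walk a [walk_spec()].
#' @param p0 starting value.
#' @return Numeric vector of length `n_steps` with the value after each
#'   step.
#' @export
run_refuse_walk <- function(n_steps, walk, p0 = 0) {
  zeta <- stats::runif(n_steps)
  sgn <- sample(c(-1, 1), n_steps, replace = TRUE)
  out <- numeric(n_steps)
  cur <- p0
  for (t in seq_len(n_steps)) {
    cur <- walk_refuse(cur, walk, zeta[t], sgn[t])
    out[t] <- cur
  }
  out
}

#' Edge-triggered AVN event detection
#'
#' An event is registered on the first step the simultaneous AVN firing
#' count reaches `k` while the detector is armed; the detector then
#' disarms until the count drops below `k`, so a single wavefront cannot
#' register multiple events.
#'
#' @param counts integer vector of per-step AVN firing counts.
#' @param k simultaneous-firing threshold (`avn_k`).
#' @return Integer vector of event steps (1-based).
#' @examples
#' detect_avn_event(c(0, 1, 3, 4, 3, 1, 0, 3), k = 3) # steps 3 and 8
#' @export
detect_avn_event <- function(counts, k) {
  armed <- TRUE
  ev <- integer(0)
  for (t in seq_along(counts)) {
    if (armed && counts[t] >= k) {
      ev[length(ev) + 1L] <- t
      armed <- FALSE
    } else if (!armed && counts[t] < k) {
      armed <- TRUE
    }
  }
  ev
}

# One synchronous update of all cells.  `nF` counting and all transitions
# use the phase snapshot taken at the beginning of the step.
#
# Refusal modes:
#  * "episode": one Bernoulli draw per excitation attempt, taken at the
#    onset of the enabling condition (a new supra-threshold stimulus while
#    in A, or the clock crossing the activity guard); a refused cell stays
#    silent until the next onset.  One wavefront passage therefore tests a
#    cell exactly once.
#  * "step": the draw is re-taken every step while the fire transition is
#    enabled, as in the single-cell `intrinsic_step()` driver.
.step_cells <- function(phase, clock, block, stimA_prev, adj, gflat, n,
                        seqn, N_R, N_F, p_refuse, refusable, refuse_mode) {
  firing <- phase == .PH_F
  nF <- if (any(firing)) as.vector(adj %*% firing) else 0
  x1 <- clock + 1
  guard <- gflat[(phase - 1L) * n + seqn]
  met <- x1 >= guard
  isA <- phase == .PH_A
  isR <- phase == .PH_R
  stim <- nF > N_F
  forced <- isA & stim
  halve <- isR & nF > N_R
  enabled <- forced | (isA & met)
  stimA <- isA & stim
  if (p_refuse > 0) {
    if (refuse_mode == "step") {
      idx <- which(enabled & refusable)
      if (length(idx)) {
        refused <- stats::runif(length(idx)) < p_refuse
        enabled[idx[refused]] <- FALSE
      }
    } else {
      onset <- (stimA & !stimA_prev) | (isA & met & clock < guard)
      idx <- which(onset & refusable)
      if (length(idx)) block[idx] <- stats::runif(length(idx)) < p_refuse
      enabled <- enabled & !block
    }
  }
  toR <- (phase == .PH_F) & met
  toA <- isR & met & !halve
  newp <- phase
  newc <- x1
  newp[toR] <- .PH_R; newc[toR] <- 0
  newc[halve] <- floor(clock[halve] / 2) # replaces this step's increment
  newp[toA] <- .PH_A; newc[toA] <- 0
  newp[enabled] <- .PH_F; newc[enabled] <- 0
  block[newp != phase] <- FALSE # a transition ends the episode
  list(phase = newp, clock = newc, block = block, stimA = stimA)
}

#' Advance a tissue state by one global step
#'
#' Synchronous update: phases are snapshotted, each cell counts its firing
#' in-neighbors from the snapshot, then [interact_step()]/[intrinsic_step()]
#' semantics are applied per cell and committed simultaneously.  Refusal
#' deviates, when needed, are drawn from the current RNG stream in
#' row-major cell order.
#'
#' @param state list with integer `phase` codes (1 = F, 2 = R, 3 = A),
#'   numeric `clock`, and (for refusal bookkeeping) logical `block` and
#'   `stimA`, one entry per cell; see [initial_state()].
#' @param tissue a [build_tissue()] result.
#' @param N_R,N_F interaction thresholds.
#' @param p_refuse refusal probability applied this step.
#' @param refuse_roles roles subject to refusal.
#' @param refuse_mode `"episode"` (one refusal draw per excitation
#'   attempt, taken at stimulus onset or guard crossing) or `"step"`
#'   (re-drawn every step while the transition is enabled).
#' @return The updated state list.
#' @export
step_tissue <- function(state, tissue, N_R = 3, N_F = 0, p_refuse = 0,
                        refuse_roles = c("SAN", "ATRIAL", "AVN"),
                        refuse_mode = c("episode", "step")) {
  refuse_mode <- match.arg(refuse_mode)
  n <- tissue$n
  gflat <- c(tissue$timers$f, tissue$timers$r, tissue$timers$a)
  .step_cells(state$phase, state$clock,
              state$block %||% logical(n), state$stimA %||% logical(n),
              tissue$adj, gflat, n, seq_len(n),
              N_R, N_F, p_refuse, tissue$roles %in% refuse_roles,
              refuse_mode)
}

#' Initial tissue state
#'
#' All cells start at rest, `(A, x = 0)`, so the SAN fires first in unison
#' after `a_SAN` steps.  With `randomize_san = TRUE` the SAN clocks are
#' instead drawn uniformly from `[0, a)` to exercise the node's
#' self-organization.
#'
#' @param tissue a `tissue` object.
#' @param randomize_san randomize SAN clocks (consumes RNG).
#' @return A state list with `phase` and `clock`.
#' @export
initial_state <- function(tissue, randomize_san = FALSE) {
  phase <- rep.int(.PH_A, tissue$n)
  clock <- numeric(tissue$n)
  if (randomize_san) {
    san <- which(tissue$roles == "SAN")
    clock[san] <- floor(stats::runif(length(san)) * tissue$timers$a[san])
  }
  list(phase = phase, clock = clock,
       block = logical(tissue$n), stimA = logical(tissue$n))
}

#' Simulate a built tissue
#'
#' Iterates the synchronous update for `total_steps` steps, recording the
#' per-step AVN simultaneous-firing count, AVN excitation events
#' (edge-triggered at `avn_k`), the step the first wavefront reaches the
#' bottom border, and the firing episodes of a reference SAN cell.  When a
#' [walk_spec()] is supplied, `p_refuse` is updated by [walk_refuse()]
#' before every tissue step and its per-step trace is recorded.
#'
#' @param tissue a [build_tissue()] result.
#' @param total_steps number of global steps.
#' @param N_R,N_F interaction thresholds.
#' @param p_refuse refusal probability (the walk's starting value when
#'   `walk` is given).
#' @param refuse_roles roles subject to refusal.
#' @param avn_k simultaneous-firing count defining an AVN event; defaults
#'   to the tissue's region setting.
#' @param walk optional [walk_spec()].
#' @param randomize_san see [initial_state()].
#' @param stop_after_events optional early stop once this many events have
#'   been seen (the run continues until the first front has also reached
#'   the bottom border, so the first-front observables are complete).
#' @return An object of class `sim_result` with `avn_events`, `rr`
#'   (inter-event step counts), `t_bottom_first`, `t_avn_first`,
#'   `san_fires`, `avn_counts`, `p_refuse_trace` (or `NULL`) and
#'   `steps_run`.
#' @export
simulate_tissue <- function(tissue, total_steps,
                            N_R = 3, N_F = 0, p_refuse = 0,
                            refuse_roles = c("SAN", "ATRIAL", "AVN"),
                            refuse_mode = c("episode", "step"),
                            avn_k = NULL, walk = NULL,
                            randomize_san = FALSE,
                            stop_after_events = NULL) {
  refuse_mode <- match.arg(refuse_mode)
  n <- tissue$n
  seqn <- seq_len(n)
  avn_k <- avn_k %||% tissue$regions$avn_k
  gflat <- c(tissue$timers$f, tissue$timers$r, tissue$timers$a)
  refusable <- tissue$roles %in% refuse_roles
  st <- initial_state(tissue, randomize_san)
  avn_idx <- which(tissue$roles == "AVN")
  bottom_idx <- which(tissue$row == tissue$L)
  san_ref <- which(tissue$roles == "SAN")[1L]

  p_cur <- p_refuse
  trace <- if (!is.null(walk)) numeric(total_steps) else NULL
  avn_counts <- integer(total_steps)
  events <- integer(0)
  armed <- TRUE
  t_bottom <- NA_integer_
  san_fires <- integer(0)
  t_end <- 0L

  for (t in seq_len(total_steps)) {
    if (!is.null(walk)) {
      p_cur <- walk_refuse(p_cur, walk, stats::runif(1L),
                           sample(c(-1, 1), 1L))
      trace[t] <- p_cur
    }
    prev_san <- st$phase[san_ref]
    st <- .step_cells(st$phase, st$clock, st$block, st$stimA,
                      tissue$adj, gflat, n, seqn,
                      N_R, N_F, p_cur, refusable, refuse_mode)
    if (prev_san != .PH_F && st$phase[san_ref] == .PH_F)
      san_fires[length(san_fires) + 1L] <- t
    cnt <- sum(st$phase[avn_idx] == .PH_F)
    avn_counts[t] <- cnt
    if (armed && cnt >= avn_k) {
      events[length(events) + 1L] <- t
      armed <- FALSE
    } else if (!armed && cnt < avn_k) {
      armed <- TRUE
    }
    if (is.na(t_bottom) && any(st$phase[bottom_idx] == .PH_F))
      t_bottom <- t
    t_end <- t
    if (!is.null(stop_after_events) && length(events) >= stop_after_events &&
        !is.na(t_bottom))
      break
  }
  avn_counts <- avn_counts[seq_len(t_end)]
  if (!is.null(trace)) trace <- trace[seq_len(t_end)]

  structure(list(avn_events = events,
                 rr = if (length(events) >= 2) diff(events) else integer(0),
                 t_bottom_first = t_bottom,
                 t_avn_first = if (length(events)) events[1L]
                               else NA_integer_,
                 san_fires = san_fires,
                 avn_counts = avn_counts,
                 p_refuse_trace = trace,
                 avn_k = avn_k,
                 steps_run = t_end,
                 final_state = st),
            class = "sim_result")
}

#' Build and simulate a tissue from a configuration
#'
#' Seeds the RNG, builds the network and runs the simulation; the
#' combination `(config, seed)` determines the result bit-for-bit.
#'
#' @param config a [sim_config()].
#' @param walk optional [walk_spec()] driving `p_refuse`.
#' @param keep_tissue retain the built tissue in the result (set `FALSE`
#'   in large sweeps to save memory).
#' @param randomize_san see [initial_state()].
#' @return A `sim_result` augmented with `config`, `walk`, `seed`,
#'   `tissue` (optional) and the nominal SAN period `t_san`.
#' @export
run_sim <- function(config, walk = NULL, keep_tissue = TRUE,
                    randomize_san = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  tissue <- build_tissue(config$lattice, config$regions, config$timers)
  res <- simulate_tissue(tissue, config$total_steps,
                         N_R = config$N_R, N_F = config$N_F,
                         p_refuse = config$p_refuse,
                         refuse_roles = config$refuse_roles,
                         refuse_mode = config$refuse_mode %||% "episode",
                         walk = walk, randomize_san = randomize_san,
                         stop_after_events = config$stop_after_events)
  res$config <- config
  res$walk <- walk
  res$seed <- config$seed
  res$t_san <- cycle_period(config$timers$SAN)
  if (keep_tissue) res$tissue <- tissue
  res$final_state <- NULL
  res
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim result: %d steps, %d AVN events", x$steps_run,
              length(x$avn_events)))
  if (length(x$rr))
    cat(sprintf(", mean RR = %.1f steps", mean(x$rr)))
  cat("\n")
  invisible(x)
}

#' RR series after transient removal
#'
#' Drops the leading `transient_beats` RR intervals (self-organization of
#' the first wavefronts) before rhythm analysis.
#'
#' @param result a `sim_result`.
#' @param transient_beats number of leading intervals to discard; defaults
#'   to the run configuration's value (or 10).
#' @return Numeric vector of RR intervals in steps.
#' @export
analysis_rr <- function(result,
                        transient_beats = result$config$transient_beats
                          %||% 10) {
  rr <- result$rr
  if (transient_beats > 0 && length(rr) > 0)
    rr <- rr[-seq_len(min(transient_beats, length(rr)))]
  rr
}

#' Scale RR intervals from steps to milliseconds
#'
#' One automaton step corresponds to about 7 ms, which maps the nominal
#' SAN period of 115 steps onto an 805 ms beat, in the range of resting
#' human RR intervals.
#'
#' @param rr RR intervals in steps.
#' @param factor milliseconds per step.
#' @return RR intervals in milliseconds.
#' @examples
#' scale_rr(c(115, 115)) # 805 805
#' @export
scale_rr <- function(rr, factor = 7) {
  if (factor <= 0) stop("`factor` must be positive")
  rr * factor
}
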