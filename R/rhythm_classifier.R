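# Limit-state classification of RR series, phase-diagram sweeps over
# (p_H = p_L, p_refuse), and the wavefront-velocity metric.

#' Rhythm labels
#'
#' The five limit states a run can be assigned: `normal` (stable sinus
#' rhythm at the SAN period), `san_arrhythmia` (doubled beats from
#' re-entry circulating around the SAN), `lost_normal` (sinus rhythm with
#' missed beats), `lost_arrhythmia` (both shortened and missed beats,
#' including fibrillation-like states), and `dead` (most excitations lost).
#'
#' @return Character vector of the five labels.
#' @export
rhythm_labels <- function() {
  c("normal", "san_arrhythmia", "lost_normal", "lost_arrhythmia", "dead")
}

#' Classifier thresholds
#'
#' All thresholds are expressed relative to the nominal SAN period
#' `T_SAN`.  A healthy human increment above 200 ms on a mean beat of
#' 800 ms is physiologically questionable, hence the normal-rhythm span
#' bound of `200/800 = 0.25` SAN periods.  A rhythm whose mean RR exceeds
#' `dead_mean_mult` SAN periods (default 3, i.e. more than two thirds of
#' the SAN excitations lost) is dead.
#'
#' @param normal_span_frac bound on `(max RR - min RR) / T_SAN` for the
#'   normal rhythm.
#' @param dead_mean_mult multiple of `T_SAN` above which the mean RR marks
#'   a dead rhythm.
#' @param short_beat_frac RR below this fraction of `T_SAN` marks an
#'   arrhythmic doubled beat.
#' @param missed_beat_frac RR above this fraction of `T_SAN` marks a
#'   missed beat.
#' @param mean_tol relative tolerance for `mean(RR)` to approximate
#'   `T_SAN` in the normal rule.
#' @return An object of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(normal_span_frac = 0.25,
                                  dead_mean_mult = 3,
                                  short_beat_frac = 0.75,
                                  missed_beat_frac = 1.25,
                                  mean_tol = 0.10) {
  if (!(short_beat_frac > 0 && short_beat_frac < 1 &&
        missed_beat_frac > 1 && dead_mean_mult > missed_beat_frac))
    stop("need 0 < short_beat_frac < 1 < missed_beat_frac < dead_mean_mult")
  if (normal_span_frac <= 0 || mean_tol < 0)
    stop("`normal_span_frac` must be positive and `mean_tol` non-negative")
  structure(list(normal_span_frac = normal_span_frac,
                 dead_mean_mult = dead_mean_mult,
                 short_beat_frac = short_beat_frac,
                 missed_beat_frac = missed_beat_frac,
                 mean_tol = mean_tol),
            class = "classifier_thresholds")
}

#' Classify a limit state from an RR series
#'
#' Decision cascade (transient assumed already removed):
#'
#' 1. empty series or `mean(RR) > dead_mean_mult * T_SAN` -> `dead`;
#' 2. `max(RR) - min(RR) < normal_span_frac * T_SAN` and
#'    `|mean(RR)/T_SAN - 1| <= mean_tol` -> `normal`;
#' 3. otherwise, shortened beats only (`RR < short_beat_frac * T_SAN`) ->
#'    `san_arrhythmia`; missed beats only
#'    (`RR > missed_beat_frac * T_SAN`) -> `lost_normal`; both ->
#'    `lost_arrhythmia`; neither (wide but bounded) -> `normal`.
#'
#' The cascade is scale invariant: rescaling `rr` and `t_san` by a common
#' factor does not change the label.
#'
#' @param rr RR series (steps or ms), transient removed.
#' @param t_san nominal SAN period on the same scale as `rr`.
#' @param thr a [classifier_thresholds()] object.
#' @return One of [rhythm_labels()].
#' @examples
#' classify_rhythm(rep(115, 20), t_san = 115) # "normal"
#' classify_rhythm(rep(0.5 * 115, 20), t_san = 115) # "san_arrhythmia"
#' @export
classify_rhythm <- function(rr, t_san, thr = classifier_thresholds()) {
  if (t_san <= 0) stop("`t_san` must be positive")
  if (length(rr) == 0) return("dead")
  m <- mean(rr)
  if (m > thr$dead_mean_mult * t_san) return("dead")
  span <- max(rr) - min(rr)
  if (span < thr$normal_span_frac * t_san &&
      abs(m / t_san - 1) <= thr$mean_tol) return("normal")
  has_short <- any(rr < thr$short_beat_frac * t_san)
  has_missed <- any(rr > thr$missed_beat_frac * t_san)
  if (has_short && has_missed) return("lost_arrhythmia")
  if (has_short) return("san_arrhythmia")
  if (has_missed) return("lost_normal")
  "normal"
}

#' Phase-diagram sweep over connectivity and refusal probability
#'
#' For each grid point `(p_H = p_L, p_refuse)` runs `reps` independently
#' seeded realizations, classifies each limit state and tabulates label
#' frequencies.  Seeds are derived deterministically from `seed`.
#'
#' @param p_hl numeric vector of transversal connection densities
#'   (`p_H = p_L`).
#' @param p_refuse numeric vector of refusal probabilities.
#' @param reps realizations per grid cell.
#' @param base a [sim_config()] providing all other parameters (timers
#'   carry the `r_noise` choice; the default uses `r_noise = 10`).
#' @param thr a [classifier_thresholds()].
#' @param seed base seed for the realization seeds.
#' @return A long-format `data.frame` of class `state_table` with columns
#'   `p_hl`, `p_refuse`, `label`, `prob`, `n`; the attribute `"modal"`
#'   holds the most-probable label per grid cell.
#' @export
phase_sweep <- function(p_hl, p_refuse, reps = 10,
                        base = sim_config(),
                        thr = classifier_thresholds(),
                        seed = 1L) {
  if (reps < 1) stop("`reps` must be at least 1")
  labels <- rhythm_labels()
  t_san <- cycle_period(base$timers$SAN)
  rows <- list()
  modal <- list()
  counter <- 0L
  for (d in p_hl) {
    for (q in p_refuse) {
      tab <- stats::setNames(numeric(length(labels)), labels)
      for (rep in seq_len(reps)) {
        counter <- counter + 1L
        cfg <- base
        cfg$lattice$p_H <- d
        cfg$lattice$p_L <- d
        cfg$p_refuse <- q
        cfg$seed <- as.integer(seed) + counter
        res <- run_sim(cfg, keep_tissue = FALSE)
        lab <- classify_rhythm(analysis_rr(res), t_san, thr)
        tab[lab] <- tab[lab] + 1
      }
      prob <- tab / reps
      rows[[length(rows) + 1L]] <-
        data.frame(p_hl = d, p_refuse = q, label = labels,
                   prob = as.numeric(prob), n = reps)
      modal[[length(modal) + 1L]] <-
        data.frame(p_hl = d, p_refuse = q,
                   label = labels[which.max(prob)],
                   prob = max(prob))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "modal") <- do.call(rbind, modal)
  class(out) <- c("state_table", "data.frame")
  out
}

#' Write a state table as long-format CSV
#'
#' @param table a [phase_sweep()] result.
#' @param path output CSV path; the most-probable-label table is written
#'   alongside with suffix `_modal.csv`.
#' @return `path`, invisibly.
#' @export
write_state_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  modal <- attr(table, "modal")
  if (!is.null(modal))
    utils::write.csv(modal, sub("\\.csv$", "_modal.csv", path),
                     row.names = FALSE)
  invisible(path)
}

#' Wavefront-velocity metric
#'
#' Mean, over independently seeded realizations, of the signed difference
#' between the step of the first AVN excitation event and the step the
#' first wavefront reaches the bottom border.  Because all cells are
#' vertically connected, the first front reaches the bottom in the fastest
#' way possible for the current dynamics; the larger the difference, the
#' slower the effective propagation toward the AVN.
#'
#' @param config a [sim_config()]; its `seed` (or 1) seeds the first
#'   realization and subsequent realizations increment it.
#' @param reps number of realizations.
#' @return A list with `mean` (mean signed difference), `diffs` (per
#'   realization), `n_excluded` (realizations without an AVN event or a
#'   bottom arrival, excluded from the mean).
#' @export
velocity_metric <- function(config, reps = 10) {
  seed0 <- as.integer(config$seed %||% 1L)
  diffs <- numeric(0)
  n_excluded <- 0L
  for (i in seq_len(reps)) {
    cfg <- config
    cfg$seed <- seed0 + i - 1L
    cfg$stop_after_events <- 1L
    res <- run_sim(cfg, keep_tissue = FALSE)
    if (is.na(res$t_avn_first) || is.na(res$t_bottom_first)) {
      n_excluded <- n_excluded + 1L
    } else {
      diffs[length(diffs) + 1L] <- res$t_avn_first - res$t_bottom_first
    }
  }
  list(mean = if (length(diffs)) mean(diffs) else NA_real_,
       diffs = diffs, n_excluded = n_excluded)
}
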