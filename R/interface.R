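# Configuration documents, synthetic RR fixtures and run manifests.

.CONFIG_SCHEMA <- list(
  lattice = c("L", "p_V", "p_H", "p_L"),
  regions = c("san_rows", "san_cols", "avn_rows", "avn_cols",
              "san_exit_fraction", "san_conn_prob", "avn_k"),
  timers = c("san", "atrial", "avn"),
  dynamics = c("N_R", "N_F", "p_refuse", "refuse_roles", "refuse_mode",
               "total_steps", "transient_beats", "seed"),
  walk = c("enabled", "p_walk", "eps", "z"),
  classifier = c("normal_span_frac", "dead_mean_mult", "short_beat_frac",
                 "missed_beat_frac", "mean_tol")
)
.TIMER_KEYS <- c("f", "r0", "a", "r_noise")

.config_error <- function(...) {
  stop(errorCondition(sprintf(...),
                      class = c("atriasim_config_error", "error")))
}

.check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    .config_error("unknown key(s) in `%s`: %s", where,
                  paste(extra, collapse = ", "))
}

.as_range <- function(x) {
  # a 2-element [from, to] pair or an explicit index vector
  x <- as.integer(x)
  if (length(x) == 2 && x[2] >= x[1]) x[1]:x[2] else x
}

#' Parse a simulation configuration document
#'
#' Reads a flat sectioned YAML document (or an equivalent nested list),
#' validates every key and range, fills defaults, and rejects unknown
#' keys.  Sections: `lattice`, `regions`, `timers` (sub-sections `san`,
#' `atrial`, `avn` with keys `f`, `r0`, `a`, `r_noise`), `dynamics`,
#' `walk`, `classifier`.  Region rows/columns may be given as
#' `[from, to]` pairs.
#'
#' @param x a file path to a YAML document, or a nested list.
#' @return A list with elements `config` (a [sim_config()]), `walk` (a
#'   [walk_spec()] or `NULL`), `thresholds` (a
#'   [classifier_thresholds()]).
#' @examples
#' parse_config(list(dynamics = list(p_refuse = 0.1, seed = 7)))
#' @export
parse_config <- function(x = list()) {
  doc <- if (is.character(x)) yaml::read_yaml(x) else x
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) .config_error("configuration must be a mapping")
  .check_keys(doc, names(.CONFIG_SCHEMA), "document root")
  for (sec in names(.CONFIG_SCHEMA))
    .check_keys(doc[[sec]], .CONFIG_SCHEMA[[sec]], sec)

  lat <- doc$lattice
  lattice <- tryCatch(
    lattice_spec(L = lat$L %||% 100, p_V = lat$p_V %||% 1,
                 p_H = lat$p_H %||% 0.5, p_L = lat$p_L %||% 0.5),
    error = function(e) .config_error("lattice: %s", conditionMessage(e)))

  tim <- doc$timers
  role_tm <- function(sub, default) {
    .check_keys(sub, .TIMER_KEYS, "timers")
    tryCatch(
      cell_timers(f = sub$f %||% default$f,
                  r0 = sub$r0 %||% default$r0,
                  a = sub$a %||% default$a,
                  r_noise = sub$r_noise %||% default$r_noise),
      error = function(e) .config_error("timers: %s", conditionMessage(e)))
  }
  defaults <- default_timers()
  timers <- list(SAN = role_tm(tim$san, defaults$SAN),
                 ATRIAL = role_tm(tim$atrial, defaults$ATRIAL),
                 AVN = role_tm(tim$avn, defaults$AVN))

  reg <- doc$regions
  reg_args <- list(L = lattice$L)
  if (!is.null(reg$san_rows)) reg_args$san_rows <- .as_range(reg$san_rows)
  if (!is.null(reg$san_cols)) reg_args$san_cols <- .as_range(reg$san_cols)
  if (!is.null(reg$avn_rows)) reg_args$avn_rows <- .as_range(reg$avn_rows)
  if (!is.null(reg$avn_cols)) reg_args$avn_cols <- .as_range(reg$avn_cols)
  for (k in c("san_exit_fraction", "san_conn_prob", "avn_k"))
    if (!is.null(reg[[k]])) reg_args[[k]] <- reg[[k]]
  regions <- tryCatch(do.call(node_regions, reg_args),
                      error = function(e)
                        .config_error("regions: %s", conditionMessage(e)))

  dyn <- doc$dynamics
  config <- tryCatch(
    sim_config(lattice = lattice, regions = regions, timers = timers,
               N_R = dyn$N_R %||% 3, N_F = dyn$N_F %||% 0,
               p_refuse = dyn$p_refuse %||% 0,
               refuse_roles = dyn$refuse_roles %||%
                 c("SAN", "ATRIAL", "AVN"),
               refuse_mode = dyn$refuse_mode %||% "episode",
               total_steps = dyn$total_steps %||% 5000,
               transient_beats = dyn$transient_beats %||% 10,
               seed = dyn$seed),
    error = function(e) .config_error("dynamics: %s", conditionMessage(e)))

  wk <- doc$walk
  walk <- NULL
  if (!is.null(wk) && isTRUE(wk$enabled %||% TRUE)) {
    walk <- tryCatch(
      walk_spec(p_walk = wk$p_walk %||% 0.001, eps = wk$eps %||% 0.05,
                z = wk$z %||% 0.45),
      error = function(e) .config_error("walk: %s", conditionMessage(e)))
  }

  cl <- doc$classifier
  thresholds <- tryCatch(
    classifier_thresholds(
      normal_span_frac = cl$normal_span_frac %||% 0.25,
      dead_mean_mult = cl$dead_mean_mult %||% 3,
      short_beat_frac = cl$short_beat_frac %||% 0.75,
      missed_beat_frac = cl$missed_beat_frac %||% 1.25,
      mean_tol = cl$mean_tol %||% 0.10),
    error = function(e) .config_error("classifier: %s",
                                      conditionMessage(e)))

  list(config = config, walk = walk, thresholds = thresholds)
}

#' Generate a synthetic annotated RR series
#'
#' Produces a reproducible RR series with a controlled increment
#' structure (per-beat quantized jitter around a base interval) and
#' planted artifact runs, for exercising the editing and pattern-matrix
#' pipeline.
#'
#' @param n number of beats.
#' @param base baseline RR interval in ms.
#' @param jitter_quanta per-beat jitter amplitude in recording quanta;
#'   `0` yields a constant series.
#' @param resolution ms per quantum.
#' @param artifact_starts,artifact_lengths positions and lengths of
#'   planted non-normal runs.
#' @param seed optional integer seed.
#' @return An [annotated_rr()] with artifact beats labelled
#'   `"artifact"`.
#' @export
gen_synthetic_rr <- function(n = 2000, base = 800, jitter_quanta = 2,
                             resolution = 8,
                             artifact_starts = integer(0),
                             artifact_lengths = integer(0),
                             seed = NULL) {
  if (length(artifact_starts) != length(artifact_lengths))
    stop("artifact starts and lengths must have the same length")
  if (!is.null(seed)) set.seed(seed)
  jit <- if (jitter_quanta > 0)
    sample.int(2 * jitter_quanta + 1, n, replace = TRUE) -
      jitter_quanta - 1L
  else rep.int(0L, n)
  rr <- base + resolution * jit
  labels <- rep("normal", n)
  for (k in seq_along(artifact_starts)) {
    idx <- artifact_starts[k]:(artifact_starts[k] +
                                 artifact_lengths[k] - 1L)
    if (min(idx) < 1 || max(idx) > n)
      stop("artifact run outside the series")
    # ectopic-like alternation: short coupling then compensatory pause
    rr[idx] <- base * rep_len(c(0.55, 1.6), length(idx))
    labels[idx] <- "artifact"
  }
  annotated_rr(rr, labels, resolution)
}

#' Write a run manifest
#'
#' Records the full configuration, seed, package version, timestamp and
#' output inventory of a run as JSON, sufficient to reproduce the run
#' exactly.
#'
#' @param path output JSON path.
#' @param config a [sim_config()].
#' @param walk optional [walk_spec()].
#' @param seed the seed used.
#' @param files character vector of output files produced.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, walk = NULL, seed = NULL,
                           files = character(0)) {
  doc <- list(tool = "atriasim",
              version = as.character(utils::packageVersion("atriasim")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed %||% config$seed,
              config = .config_as_list(config),
              walk = if (!is.null(walk)) unclass(walk),
              files = files)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), path)
  invisible(path)
}

.config_as_list <- function(config) {
  list(lattice = unclass(config$lattice),
       regions = unclass(config$regions),
       timers = lapply(config$timers, unclass),
       dynamics = list(N_R = config$N_R, N_F = config$N_F,
                       p_refuse = config$p_refuse,
                       refuse_roles = config$refuse_roles,
                       refuse_mode = config$refuse_mode,
                       total_steps = config$total_steps,
                       transient_beats = config$transient_beats,
                       seed = config$seed))
}

#' Reload a configuration from a run manifest
#'
#' @param path manifest JSON path.
#' @return As [parse_config()]: list with `config`, `walk`, `thresholds`.
#' @export
read_manifest <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- doc$config
  parsed <- parse_config(list(
    lattice = cfg$lattice,
    regions = cfg$regions,
    timers = list(san = cfg$timers$SAN[.TIMER_KEYS],
                  atrial = cfg$timers$ATRIAL[.TIMER_KEYS],
                  avn = cfg$timers$AVN[.TIMER_KEYS]),
    dynamics = cfg$dynamics,
    walk = if (!is.null(doc$walk)) c(doc$walk, list(enabled = TRUE))))
  parsed
}
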