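# RR-series editing (Holter normal-to-normal protocol) and the joint
# probability matrix of consecutive RR increments.

#' Annotated RR series
#'
#' An RR-interval series in milliseconds with a per-beat annotation
#' (`"normal"` for verified sinus beats, anything else for artifacts or
#' non-sinus beats) and the recording quantum (8 ms for a 128 Hz Holter).
#'
#' @param rr positive RR intervals in ms.
#' @param labels per-beat annotations, same length as `rr`.
#' @param resolution ms per recording quantum.
#' @return An object of class `annotated_rr`.
#' @export
annotated_rr <- function(rr, labels = rep("normal", length(rr)),
                         resolution = 8) {
  if (any(rr <= 0)) stop("RR intervals must be positive")
  if (length(labels) != length(rr))
    stop("`labels` must have the same length as `rr`")
  structure(list(rr = as.numeric(rr), labels = as.character(labels),
                 resolution = resolution),
            class = "annotated_rr")
}

#' @export
print.annotated_rr <- function(x, ...) {
  cat(sprintf("annotated RR series: %d beats (%d normal), %g ms resolution\n",
              length(x$rr), sum(x$labels == "normal"), x$resolution))
  invisible(x)
}

#' Edit an annotated RR series to a normal-to-normal series
#'
#' Applies the Holter editing protocol: each run of consecutive non-normal
#' beats shorter than `max_patch` is replaced, beat by beat, by the median
#' of the last seven beats of the edited series before the run; runs of
#' length `>= max_patch` are deleted and the junction recorded.  A
#' patchable run that is not preceded by at least seven edited beats is
#' deleted instead (and logged).  The output is truncated to `target_len`
#' beats from the start.
#'
#' Increment pairs must not be formed across deletion junctions;
#' [pattern_from_rr()] honors the returned `junctions`.
#'
#' @param series an [annotated_rr()] object, or a numeric RR vector.
#' @param labels per-beat annotations when `series` is a bare vector.
#' @param max_patch runs shorter than this are patched (strict `<`),
#'   longer ones deleted.
#' @param target_len maximum output length; `NULL` keeps everything.
#' @return An object of class `cleaned_rr`: list with `rr` (edited
#'   series), `junctions` (0-based positions after which a deletion
#'   occurred, i.e. between `rr[j]` and `rr[j + 1]`), and `log` (a
#'   `data.frame` of edits: action, input start, run length, patch value).
#' @examples
#' s <- annotated_rr(c(800, 790, 810, 805, 795, 800, 790, 400, 400),
#'                   c(rep("normal", 7), "artifact", "artifact"))
#' clean_rr(s)$rr # the two artifacts become 800
#' @export
clean_rr <- function(series, labels = NULL, max_patch = 5,
                     target_len = 20000) {
  if (inherits(series, "annotated_rr")) {
    rr <- series$rr
    labels <- series$labels
  } else {
    rr <- as.numeric(series)
    labels <- labels %||% rep("normal", length(rr))
  }
  if (length(labels) != length(rr))
    stop("`labels` must have the same length as `rr`")
  normal <- labels == "normal"
  runs <- rle(normal)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- numeric(0)
  junctions <- integer(0)
  log_rows <- list()
  add_log <- function(action, start, len, value = NA_real_) {
    log_rows[[length(log_rows) + 1L]] <<-
      data.frame(action = action, start = start, length = len,
                 value = value)
  }
  for (k in seq_along(runs$lengths)) {
    idx <- starts[k]:ends[k]
    if (runs$values[k]) {
      out <- c(out, rr[idx])
    } else {
      len <- runs$lengths[k]
      if (len < max_patch && length(out) >= 7) {
        med <- stats::median(out[(length(out) - 6):length(out)])
        out <- c(out, rep(med, len))
        add_log("patch", starts[k], len, med)
      } else {
        if (length(out) > 0 &&
            (length(junctions) == 0 ||
             junctions[length(junctions)] != length(out)))
          junctions <- c(junctions, length(out))
        add_log(if (len < max_patch) "delete_short_prefix" else "delete",
                starts[k], len)
      }
    }
  }
  if (!is.null(target_len) && length(out) > target_len) {
    out <- out[seq_len(target_len)]
    junctions <- junctions[junctions < target_len]
  }
  junctions <- junctions[junctions < length(out)]
  structure(list(rr = out, junctions = junctions,
                 log = if (length(log_rows)) do.call(rbind, log_rows)
                       else data.frame(action = character(0),
                                       start = integer(0),
                                       length = integer(0),
                                       value = numeric(0))),
            class = "cleaned_rr")
}

#' RR increments
#'
#' First difference of consecutive RR intervals,
#' `dRR[k] = RR[k] - RR[k - 1]`.  Accelerations are negative,
#' decelerations positive.
#'
#' @param rr RR series of length at least 2.
#' @return Numeric vector of length `length(rr) - 1`.
#' @examples
#' rr_increments(c(800, 808, 800)) # 8 -8
#' @export
rr_increments <- function(rr) {
  if (length(rr) < 2) stop("need at least two RR intervals")
  diff(rr)
}

#' Joint probability matrix of consecutive RR increments
#'
#' Bins each increment on a grid of half-open bins `[c - w/2, c + w/2)`
#' centered at multiples of `bin_width` (symmetric about 0 and auto-sized
#' to the data range), counts overlapping consecutive pairs
#' `(dRR[k], dRR[k + 1])` and normalizes by the number of pairs.
#'
#' @param drr increment series ([rr_increments()]).
#' @param bin_width bin width in the units of `drr` (8 ms for Holter
#'   recordings, 7 ms for model output scaled by [scale_rr()], 1 for raw
#'   step counts).
#' @param segments optional integer vector, same length as `drr`; pairs
#'   spanning a segment change are not counted (used to avoid pairing
#'   across deletion junctions).
#' @return A matrix of class `pattern_matrix` with bin centers as
#'   dimnames; rows index `dRR[k]`, columns `dRR[k + 1]`.  Attributes
#'   `bin_width` and `n_pairs`.
#' @examples
#' pattern_matrix(c(8, -8, 8, -8), bin_width = 8)
#' @export
pattern_matrix <- function(drr, bin_width = 8, segments = NULL) {
  if (length(drr) < 2) stop("need at least two increments to form a pair")
  if (bin_width <= 0) stop("`bin_width` must be positive")
  idx <- floor(drr / bin_width + 0.5)
  i1 <- idx[-length(idx)]
  i2 <- idx[-1]
  if (!is.null(segments)) {
    if (length(segments) != length(drr))
      stop("`segments` must match `drr` in length")
    keep <- segments[-length(segments)] == segments[-1]
    i1 <- i1[keep]
    i2 <- i2[keep]
  }
  if (length(i1) == 0) stop("no admissible increment pairs")
  lim <- max(abs(c(i1, i2)))
  lv <- seq.int(-lim, lim)
  tab <- table(factor(i1, levels = lv), factor(i2, levels = lv))
  P <- unclass(tab) / length(i1)
  dimnames(P) <- list(drr_i = lv * bin_width, drr_j = lv * bin_width)
  structure(P, class = c("pattern_matrix", "matrix"),
            bin_width = bin_width, n_pairs = length(i1))
}

#' @export
print.pattern_matrix <- function(x, ...) {
  cat(sprintf("RR-increment pattern matrix: %d x %d bins (width %g), %d pairs\n",
              nrow(x), ncol(x), attr(x, "bin_width"), attr(x, "n_pairs")))
  cat(sprintf("  mass at origin: %.3f\n",
              x[as.character(0), as.character(0)]))
  invisible(x)
}

#' Pattern matrix straight from an edited RR series
#'
#' Convenience pipeline: computes increments within the segments delimited
#' by deletion junctions and forms pairs only within segments.
#'
#' @param rr RR series (e.g. `clean_rr(...)$rr` or a simulated series
#'   scaled by [scale_rr()]).
#' @param bin_width see [pattern_matrix()].
#' @param junctions 0-based deletion junction positions as returned by
#'   [clean_rr()].
#' @return A `pattern_matrix`.
#' @export
pattern_from_rr <- function(rr, bin_width = 8, junctions = integer(0)) {
  if (length(rr) < 3) stop("need at least three beats")
  seg_beat <- findInterval(seq_along(rr) - 1L, junctions) # segment per beat
  drr <- diff(rr)
  valid <- seg_beat[-1] == seg_beat[-length(seg_beat)]
  pattern_matrix(drr[valid], bin_width = bin_width,
                 segments = seg_beat[-1][valid])
}

#' Off-origin probability mass of a pattern matrix
#'
#' Total probability outside the central `(0, 0)` bin; a plain stationary
#' rhythm concentrates all mass at the origin, while refusal-driven
#' missed and doubled beats create off-origin peaks.
#'
#' @param P a [pattern_matrix()].
#' @return A probability in `[0, 1]`.
#' @export
off_origin_mass <- function(P) {
  1 - P[as.character(0), as.character(0)]
}

#' Read / write RR series CSV
#'
#' Two-column CSV (`rr_ms`, `label`).
#'
#' @param series an [annotated_rr()].
#' @param path file path.
#' @return `read_rr_csv` returns an `annotated_rr`; `write_rr_csv` the
#'   path, invisibly.
#' @export
write_rr_csv <- function(series, path) {
  utils::write.csv(data.frame(rr_ms = series$rr, label = series$labels),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rr_csv
#' @param resolution recording quantum passed to [annotated_rr()].
#' @export
read_rr_csv <- function(path, resolution = 8) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("rr_ms", "label") %in% names(df)))
    stop("RR CSV must have columns `rr_ms` and `label`")
  annotated_rr(df$rr_ms, df$label, resolution)
}

#' Write a pattern matrix as CSV with bin-center headers
#'
#' @param P a [pattern_matrix()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_pattern_csv <- function(P, path) {
  df <- as.data.frame(unclass(P))
  names(df) <- colnames(P)
  df <- cbind(drr_i = rownames(P), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
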