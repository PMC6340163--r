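# Stochastic lattice construction: SAN and AVN regions embedded in an
# L x L atrial lattice with direction-dependent random connectivity.
#
# Coordinate convention: cells are indexed (row, col), row 1 at the top,
# row L the bottom border; cell id = (row - 1) * L + col (row-major).

#' Lattice connectivity specification
#'
#' Each unordered pair of atrial lattice neighbors is linked independently
#' with a probability depending on the direction class: `p_V` for vertical
#' (N/S) neighbors, `p_H` for horizontal (E/W), `p_L` for lateral
#' (diagonal NE/NW/SE/SW) neighbors.  Vertical links are always present in
#' the reference configuration (`p_V = 1`); lowering `p_H = p_L` emulates
#' the loss of transversal coupling caused by collagen deposition.
#'
#' @param L linear lattice size (cells per side, `>= 10`).
#' @param p_V,p_H,p_L connection probabilities in `[0, 1]`.
#' @return An object of class `lattice_spec`.
#' @export
lattice_spec <- function(L = 100, p_V = 1, p_H = 0.5, p_L = 0.5) {
  if (L < 10) stop("`L` must be at least 10")
  p <- c(p_V, p_H, p_L)
  if (any(p < 0 | p > 1))
    stop("connection probabilities must lie in [0, 1]")
  structure(list(L = as.integer(L), p_V = p_V, p_H = p_H, p_L = p_L),
            class = "lattice_spec")
}

#' SAN and AVN region geometry
#'
#' The SAN is an elongated rectangle in the upper-left part of the lattice;
#' the AVN is a small block centered on the bottom border.  SAN cells never
#' receive edges from outside the node; excitation leaves the SAN only
#' through a random subset (`san_exit_fraction`) of the SAN cells that
#' border non-SAN tissue.  Boundary-crossing links are drawn with the
#' ordinary direction-class probabilities but kept one-way (SAN to
#' atrium) and only from the exit subset.  An AVN excitation event is
#' registered when at
#' least `avn_k` AVN cells fire simultaneously.
#'
#' @param L lattice size the regions are validated against.
#' @param san_rows,san_cols row/column index ranges of the SAN rectangle.
#' @param avn_rows,avn_cols row/column index ranges of the AVN block; the
#'   default is a 2 x 4 block (8 cells) centered on the bottom row.
#' @param san_exit_fraction fraction of bordering SAN cells able to
#'   transmit to the atrium (`0 <` fraction `<= 1`); the count is rounded
#'   to the nearest integer.
#' @param san_conn_prob common probability for SAN-internal links of every
#'   direction class (the node's internal wiring is loose but direction
#'   free).
#' @param avn_k simultaneous-firing count defining an AVN excitation event.
#' @return An object of class `node_regions`.
#' @export
node_regions <- function(L = 100,
                         san_rows = 11:30, san_cols = 3:6,
                         avn_rows = (L - 1):L,
                         avn_cols = (floor(L / 2) - 1):(floor(L / 2) + 2),
                         san_exit_fraction = 0.5,
                         san_conn_prob = 1,
                         avn_k = 3) {
  rng_ok <- function(idx) length(idx) > 0 && min(idx) >= 1 && max(idx) <= L
  if (!rng_ok(san_rows) || !rng_ok(san_cols) ||
      !rng_ok(avn_rows) || !rng_ok(avn_cols))
    stop("region rectangles must be non-empty and lie inside the lattice")
  if (length(intersect(san_rows, avn_rows)) > 0 &&
      length(intersect(san_cols, avn_cols)) > 0)
    stop("SAN and AVN rectangles must be disjoint")
  if (san_exit_fraction <= 0 || san_exit_fraction > 1)
    stop("`san_exit_fraction` must lie in (0, 1]")
  if (san_conn_prob < 0 || san_conn_prob > 1)
    stop("`san_conn_prob` must lie in [0, 1]")
  n_avn <- length(avn_rows) * length(avn_cols)
  if (avn_k < 1 || avn_k > n_avn)
    stop("`avn_k` must lie between 1 and the AVN cell count")
  structure(list(san_rows = as.integer(san_rows),
                 san_cols = as.integer(san_cols),
                 avn_rows = as.integer(avn_rows),
                 avn_cols = as.integer(avn_cols),
                 san_exit_fraction = san_exit_fraction,
                 san_conn_prob = san_conn_prob,
                 avn_k = as.integer(avn_k)),
            class = "node_regions")
}

#' Default per-role timers
#'
#' SAN cells are self-exciting with `f = 5`, `r = 70`, `a = 40`
#' (`T_SAN = 115` steps, about 805 ms at 7 ms per step).  Atrial and AVN
#' cells share `f = 5`, `r0 = 50` with a uniform refractory spread
#' `r_noise` (default 10, i.e. up to 20% relative variation), and an
#' activity guard of ten SAN periods so that they never self-fire in
#' practice and wait to be excited by a neighbor.
#'
#' @param atrial_r_noise refractory spread for atrial and AVN cells, in
#'   steps; set to `0` for identical cells.
#' @return A named list of [cell_timers()] with entries `SAN`, `ATRIAL`,
#'   `AVN`.
#' @export
default_timers <- function(atrial_r_noise = 10) {
  t_san <- 5 + 70 + 40
  list(SAN    = cell_timers(f = 5, r0 = 70, a = 40, r_noise = 0),
       ATRIAL = cell_timers(f = 5, r0 = 50, a = 10 * t_san,
                            r_noise = atrial_r_noise),
       AVN    = cell_timers(f = 5, r0 = 50, a = 10 * t_san,
                            r_noise = atrial_r_noise))
}

# offsets of the 8-neighborhood
.NBR_OFFSETS <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                      dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Build a stochastic tissue network
#'
#' Constructs the lattice adjacency, assigns roles (SAN / ATRIAL / AVN) and
#' draws per-cell refractory guards.  Atrial (and AVN) neighbor pairs are
#' linked symmetrically and independently with the direction-class
#' probabilities of `lattice`; SAN-internal pairs are linked with
#' `regions$san_conn_prob` for every direction class; SAN-to-atrium edges
#' are strictly one-way and exist only from the randomly chosen exit subset
#' of bordering SAN cells, so the SAN cannot read signals from outside.
#' The lattice boundary is open: border cells simply lack the missing
#' neighbors.
#'
#' The RNG is consumed in a fixed order (per-cell refractory deviates in
#' row-major order, then edge coins per direction class V, H, SE, SW, then
#' the exit-cell sample), so a fixed `seed` reproduces the network exactly.
#'
#' @param lattice a [lattice_spec()].
#' @param regions a [node_regions()] for the same `L`.
#' @param timers named list of [cell_timers()] per role, as from
#'   [default_timers()].
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return An object of class `tissue`: a list with `L`, `n`, `row`, `col`,
#'   `roles`, sparse in-adjacency `adj` (`adj[j, i] = 1` when cell `j`
#'   reads the firing of cell `i`), per-cell `timers` (`f`, `r`, `a`,
#'   `r0`, `r_noise`), `exit_ids`, and the input specifications.
#' @export
build_tissue <- function(lattice = lattice_spec(),
                         regions = node_regions(lattice$L),
                         timers = default_timers(),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- lattice$L
  n <- L * L
  cell_id <- function(r, c) (r - 1L) * L + c
  row <- rep(seq_len(L), each = L)
  col <- rep.int(seq_len(L), L)

  roles <- rep.int("ATRIAL", n)
  san_ids <- as.vector(outer(regions$san_rows, regions$san_cols, cell_id))
  avn_ids <- as.vector(outer(regions$avn_rows, regions$avn_cols, cell_id))
  if (max(regions$san_rows) >= min(regions$avn_rows) - 1 &&
      length(intersect(san_ids, avn_ids)) > 0)
    stop("SAN and AVN regions overlap")
  roles[san_ids] <- "SAN"
  roles[avn_ids] <- "AVN"

  # per-cell timers; one uniform deviate per cell in row-major order
  xi <- stats::runif(n)
  f <- r0 <- a <- rn <- numeric(n)
  for (role in c("SAN", "ATRIAL", "AVN")) {
    w <- roles == role
    tm <- timers[[role]]
    f[w] <- tm$f; r0[w] <- tm$r0; a[w] <- tm$a; rn[w] <- tm$r_noise
  }
  r <- draw_refractory(r0, rn, xi)

  # candidate neighbor pairs per direction class (i < j in id order);
  # SAN-internal pairs use the common san_conn_prob, SAN/atrium boundary
  # pairs use the ordinary class probability but are resolved after the
  # exit subset is drawn
  is_san <- roles == "SAN"
  keep_pairs <- function(i, j, p_base) {
    p <- rep.int(p_base, length(i))
    p[is_san[i] & is_san[j]] <- regions$san_conn_prob
    u <- stats::runif(length(i))
    keep <- u < p
    list(i = i[keep], j = j[keep])
  }
  vi <- which(row < L)
  hi <- which(col < L)
  d1 <- which(row < L & col < L)
  d2 <- which(row < L & col > 1L)
  ev <- keep_pairs(vi, vi + L, lattice$p_V)
  eh <- keep_pairs(hi, hi + 1L, lattice$p_H)
  e1 <- keep_pairs(d1, d1 + L + 1L, lattice$p_L) # SE
  e2 <- keep_pairs(d2, d2 + L - 1L, lattice$p_L) # SW

  # SAN exit cells: half (san_exit_fraction) of the SAN cells that have at
  # least one non-SAN lattice neighbor are able to transmit to the atrium
  nbr_ids <- function(ids) {
    res <- vector("list", nrow(.NBR_OFFSETS))
    for (k in seq_len(nrow(.NBR_OFFSETS))) {
      nr <- row[ids] + .NBR_OFFSETS[k, 1L]
      nc <- col[ids] + .NBR_OFFSETS[k, 2L]
      ok <- nr >= 1 & nr <= L & nc >= 1 & nc <= L
      res[[k]] <- cbind(from = ids[ok], to = cell_id(nr[ok], nc[ok]))
    }
    do.call(rbind, res)
  }
  san_nbrs <- nbr_ids(san_ids)
  cross <- san_nbrs[!is_san[san_nbrs[, "to"]], , drop = FALSE]
  border_ids <- sort(unique(cross[, "from"]))
  n_exit <- max(1L, round(regions$san_exit_fraction * length(border_ids)))
  exit_ids <- sort(border_ids[sample.int(length(border_ids), n_exit)])

  # assemble directed edges: atrial pairs symmetric; boundary pairs only
  # SAN -> atrium and only from exit cells; SAN never reads the atrium
  from <- c(ev$i, ev$j, eh$i, eh$j, e1$i, e1$j, e2$i, e2$j)
  to <- c(ev$j, ev$i, eh$j, eh$i, e1$j, e1$i, e2$j, e2$i)
  cross_edge <- is_san[from] != is_san[to]
  drop <- (cross_edge & !is_san[from]) |
    (cross_edge & is_san[from] & !(from %in% exit_ids))
  from <- from[!drop]
  to <- to[!drop]
  adj <- Matrix::sparseMatrix(i = to, j = from, x = 1, dims = c(n, n))

  structure(list(L = L, n = n, row = row, col = col, roles = roles,
                 adj = adj,
                 timers = list(f = f, r = r, a = a, r0 = r0, r_noise = rn),
                 exit_ids = exit_ids, border_ids = border_ids,
                 lattice = lattice, regions = regions, seed = seed),
            class = "tissue")
}

#' @export
print.tissue <- function(x, ...) {
  cat(sprintf(
    "tissue: %d x %d lattice (%d cells: %d SAN, %d AVN), %d directed edges\n",
    x$L, x$L, x$n, sum(x$roles == "SAN"), sum(x$roles == "AVN"),
    Matrix::nnzero(x$adj)))
  cat(sprintf("  p_V = %g, p_H = %g, p_L = %g; %d SAN exit cells\n",
              x$lattice$p_V, x$lattice$p_H, x$lattice$p_L,
              length(x$exit_ids)))
  invisible(x)
}

#' Expected neighbor count
#'
#' Closed-form mean in-degree of an interior atrial cell,
#' `2 (p_V + p_H) + 4 p_L`.
#'
#' @param lattice a [lattice_spec()].
#' @return Expected number of connected neighbors.
#' @examples
#' mean_degree(lattice_spec(p_V = 1, p_H = 0.5, p_L = 0.5)) # 5
#' @export
mean_degree <- function(lattice) {
  2 * (lattice$p_V + lattice$p_H) + 4 * lattice$p_L
}

#' Empirical mean neighbor count
#'
#' Average in-degree over interior atrial cells whose full 8-neighborhood
#' is atrial (cells on the boundary or adjacent to the SAN/AVN regions are
#' excluded, since their wiring follows different rules).
#'
#' @param tissue a [build_tissue()] result.
#' @return Mean in-degree (a single number).
#' @export
empirical_degree <- function(tissue) {
  L <- tissue$L
  ok <- tissue$roles == "ATRIAL" &
    tissue$row > 1L & tissue$row < L & tissue$col > 1L & tissue$col < L
  idx <- which(ok)
  for (k in seq_len(nrow(.NBR_OFFSETS))) {
    nbr <- (tissue$row[idx] + .NBR_OFFSETS[k, 1L] - 1L) * L +
      tissue$col[idx] + .NBR_OFFSETS[k, 2L]
    idx <- idx[tissue$roles[nbr] == "ATRIAL"]
  }
  deg <- Matrix::rowSums(tissue$adj)
  mean(deg[idx])
}

#' Serialize a tissue to JSON
#'
#' Writes roles, directed edges, per-cell timers and the generating seed so
#' that a network realization can be replayed exactly.
#'
#' @param tissue a `tissue` object.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
tissue_to_json <- function(tissue, path = NULL) {
  edges <- Matrix::summary(tissue$adj)
  doc <- list(L = tissue$L,
              roles = tissue$roles,
              edges = list(from = edges$j, to = edges$i),
              timers = tissue$timers,
              exit_ids = tissue$exit_ids,
              border_ids = tissue$border_ids,
              lattice = unclass(tissue$lattice),
              regions = unclass(tissue$regions),
              seed = tissue$seed)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Rebuild a tissue from JSON
#'
#' @param x a JSON string or a path to a JSON file written by
#'   [tissue_to_json()].
#' @return A `tissue` object.
#' @export
tissue_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x)
  L <- as.integer(doc$L)
  n <- L * L
  adj <- Matrix::sparseMatrix(i = doc$edges$to, j = doc$edges$from, x = 1,
                              dims = c(n, n))
  lat <- do.call(lattice_spec, doc$lattice)
  reg <- do.call(node_regions, c(list(L = L),
                                 doc$regions[setdiff(names(doc$regions),
                                                     character(0))]))
  structure(list(L = L, n = n,
                 row = rep(seq_len(L), each = L),
                 col = rep.int(seq_len(L), L),
                 roles = doc$roles, adj = adj,
                 timers = lapply(doc$timers, as.numeric),
                 exit_ids = as.integer(doc$exit_ids),
                 border_ids = as.integer(doc$border_ids),
                 lattice = lat, regions = reg,
                 seed = if (is.null(doc$seed)) NULL else as.integer(doc$seed)),
            class = "tissue")
}
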