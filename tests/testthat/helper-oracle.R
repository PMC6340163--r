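# Independent reference implementations used as oracles.

# In-neighbor lists of a tissue (cell j reads the cells in nbrs[[j]]).
in_neighbor_lists <- function(tissue) {
  ed <- Matrix::summary(tissue$adj)
  split(ed$j, factor(ed$i, levels = seq_len(tissue$n)))
}

# Straightforward per-cell synchronous update, written directly from the
# transition rules (character phases, explicit loops); deterministic
# dynamics only (p_refuse = 0).
oracle_step <- function(ph, x, nbrs, f, r, a, N_R = 3, N_F = 0) {
  n <- length(ph)
  nF <- integer(n)
  for (j in seq_len(n)) nF[j] <- sum(ph[nbrs[[j]]] == "F")
  newph <- ph
  newx <- x
  for (j in seq_len(n)) {
    if (ph[j] == "A" && nF[j] > N_F) {
      newph[j] <- "F"; newx[j] <- 0
    } else if (ph[j] == "R" && nF[j] > N_R) {
      newx[j] <- floor(x[j] / 2)
    } else {
      x1 <- x[j] + 1
      g <- switch(ph[j], F = f[j], R = r[j], A = a[j])
      if (x1 >= g) {
        newph[j] <- switch(ph[j], F = "R", R = "A", A = "F")
        newx[j] <- 0
      } else {
        newx[j] <- x1
      }
    }
  }
  list(ph = newph, x = newx)
}

# Breadth-first arrival-time oracle for the first wavefront: all SAN cells
# fire simultaneously at step a_SAN and excitation crosses one directed
# edge per step.
bfs_arrival <- function(tissue) {
  g <- igraph::graph_from_adjacency_matrix(Matrix::t(tissue$adj) > 0,
                                           mode = "directed")
  san <- which(tissue$roles == "SAN")
  d <- igraph::distances(g, v = san, mode = "out")
  a_san <- tissue$timers$a[san[1]]
  a_san + apply(d, 2, min)
}

# First step at which >= k AVN cells are simultaneously in F, given their
# arrival steps and the firing duration f (a cell is in F during
# [arrival, arrival + f - 1]).
bfs_first_avn_event <- function(arrivals, f, k) {
  arrivals <- arrivals[is.finite(arrivals)]
  if (length(arrivals) < k) return(NA_real_)
  cand <- sort(unique(arrivals))
  for (t in cand) {
    if (sum(arrivals <= t & t <= arrivals + f - 1) >= k) return(t)
  }
  NA_real_
}
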