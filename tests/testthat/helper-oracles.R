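# Brute-force reference implementations used as independent oracles.

# low-level move/census entry points (not part of the public interface)
cpp_propose_pivot <- polyclust:::cpp_propose_pivot
cpp_propose_local <- polyclust:::cpp_propose_local

# all-pairs coordinate collision check on an integer coordinate matrix
oracle_has_collision <- function(coords) {
  anyDuplicated(as.data.frame(coords)) > 0
}

# chain connectivity: squared bond lengths restricted to {1, 2}
oracle_chain_connected <- function(coords) {
  if (nrow(coords) < 2) return(TRUE)
  d2 <- rowSums((coords[-1, , drop = FALSE] -
                   coords[-nrow(coords), , drop = FALSE])^2)
  all(d2 %in% c(1, 2))
}

# breadth-first flood fill with 8-connectivity on an occupancy matrix;
# returns a label matrix (0 = empty)
oracle_flood_fill <- function(occ) {
  nr <- nrow(occ)
  nc <- ncol(occ)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!occ[r0, c0] || lab[r0, c0] != 0L) next
    cur <- cur + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- cur
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr
        c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            occ[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# union-find over binders: connected by shared node or by bridge bond
oracle_census <- function(node, bonds) {
  nb <- length(node)
  parent <- seq_len(nb)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  unite <- function(a, b) parent[find(a)] <<- find(b)
  for (v in unique(node[node > 0])) {
    at <- which(node == v)
    if (length(at) > 1) for (i in at[-1]) unite(at[1], i)
  }
  if (nrow(bonds)) for (k in seq_len(nrow(bonds)))
    unite(bonds[k, 1], bonds[k, 2])
  roots <- vapply(seq_len(nb), find, integer(1))
  roots[node == 0] <- NA_integer_
  # relabel consecutively in order of first appearance
  match(roots, unique(roots[!is.na(roots)]))
}

# exhaustive nearest-centre distance
oracle_nearest <- function(points, centres) {
  vapply(points, function(p) min(abs(centres - p)), numeric(1))
}

# naive O(n*m) any-overlap counts for 0-based half-open intervals
oracle_overlap_counts <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    sum(subject$chrom == query$chrom[i] &
          subject$start < query$end[i] &
          subject$end > query$start[i])
  }, integer(1))
}

# random sparse occupancy matrix for cluster-calling tests
random_grid <- function(nr, nc, p, seed) {
  set.seed(seed)
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

# random bound-binder state on a small polymer, for census tests
random_state <- function(seed) {
  set.seed(seed)
  p <- sim_params(n_nodes = 20, N_endog = 12, k_a_endog = 0.05,
                  k_d_endog = 0.05, k_join = 0.3, k_break = 0.05,
                  n_steps = 10)
  st <- new_sim_state(p, seed = seed)
  for (i in 1:30) {
    st <- binding_step(st, p)
    st <- bridging_step(st, p)
  }
  st
}
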