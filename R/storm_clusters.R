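#' Build or read a single-molecule localization table
#'
#' A localization table holds one row per detected switching event with
#' nanometre coordinates, an imaging channel label and a cell identifier.
#'
#' @param x,y coordinates in nm.
#' @param channel channel label (recycled).
#' @param cell_id cell label (recycled).
#' @return A data frame of class `localization_table` with columns `x_nm`,
#'   `y_nm`, `channel`, `cell_id`.
#' @export
localization_table <- function(x, y, channel = "ch1", cell_id = "cell1") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) && (any(!is.finite(x)) || any(!is.finite(y))))
    stop("coordinates must be finite")
  df <- data.frame(x_nm = as.numeric(x), y_nm = as.numeric(y),
                   channel = rep_len(as.character(channel), length(x)),
                   cell_id = rep_len(as.character(cell_id), length(x)),
                   stringsAsFactors = FALSE)
  class(df) <- c("localization_table", "data.frame")
  df
}

#' @rdname localization_table
#' @param path delimited text file with header columns `x_nm`, `y_nm` and
#'   optionally `channel`, `cell_id`.
#' @param sep field separator.
#' @export
read_localizations <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("x_nm", "y_nm") %in% names(df)))
    stop("localization file needs x_nm and y_nm columns")
  localization_table(df$x_nm, df$y_nm,
                     if ("channel" %in% names(df)) df$channel else "ch1",
                     if ("cell_id" %in% names(df)) df$cell_id else "cell1")
}

#' Adaptive bin size for cluster calling
#'
#' Bin edge length adapted to the localization density of a cell:
#' `15 nm * sqrt(n_avg / n_cell)`, clamped to the \[10, 30\] nm range. Cells
#' with more localizations than the cohort average get finer bins.
#'
#' @param n_cell localizations detected in this cell.
#' @param n_avg average localizations per cell over the cohort.
#' @param base base bin size in nm (default 15).
#' @param range allowed bin-size range in nm (default `c(10, 30)`).
#' @return Bin edge length in nm.
#' @export
adaptive_bin_size <- function(n_cell, n_avg, base = 15,
                              range = c(10, 30)) {
  if (any(n_cell <= 0) || any(n_avg <= 0))
    stop("localization counts must be positive")
  raw <- base * sqrt(n_avg / n_cell)
  pmin(pmax(raw, range[1]), range[2])
}

#' Rasterize localizations onto a square bin grid
#'
#' Assigns each localization to exactly one half-open bin via
#' `floor((coord - origin) / bin_size)`; points exactly on a bin boundary
#' fall into the higher-index bin. The default origin is the minimum
#' coordinate.
#'
#' @param table a [localization_table()] (or data frame with `x_nm`,
#'   `y_nm`).
#' @param bin_size bin edge length in nm.
#' @param origin optional `c(x0, y0)` grid origin in nm.
#' @param dims optional `c(nx, ny)` grid dimensions (bins).
#' @return A `bin_grid`: list with `counts` (nx x ny integer matrix, x as
#'   rows), `bin_size`, `origin`.
#' @export
rasterize <- function(table, bin_size, origin = NULL, dims = NULL) {
  if (bin_size <= 0) stop("bin_size must be positive")
  x <- table$x_nm
  y <- table$y_nm
  if (is.null(origin)) origin <- c(min(x), min(y))
  ix <- floor((x - origin[1]) / bin_size)
  iy <- floor((y - origin[2]) / bin_size)
  if (any(ix < 0) || any(iy < 0))
    stop("localizations fall below the grid origin")
  if (is.null(dims)) dims <- c(max(ix) + 1L, max(iy) + 1L)
  if (any(ix >= dims[1]) || any(iy >= dims[2]))
    stop("localizations fall outside the grid")
  lin <- ix + dims[1] * iy + 1L
  counts <- matrix(tabulate(lin, nbins = dims[1] * dims[2]),
                   nrow = dims[1], ncol = dims[2])
  structure(list(counts = counts, bin_size = bin_size, origin = origin),
            class = "bin_grid")
}

#' Call clusters as 8-connected components of non-empty bins
#'
#' Any connected set of non-empty bins surrounded by empty bins is one
#' cluster, including isolated single bins; bins that are edge-adjacent or
#' diagonal count as connected.
#'
#' @param grid a `bin_grid` from [rasterize()].
#' @return A `cluster_set`: list with `clusters` (data frame `cluster_id`,
#'   `n_bins`, `n_localizations`, `diameter`), `membership` (cluster label
#'   per non-empty bin), `bins` (linear indices of non-empty bins into the
#'   count matrix) and `bin_size`.
#' @export
call_clusters <- function(grid) {
  counts <- grid$counts
  nr <- nrow(counts)
  nc <- ncol(counts)
  idx <- which(counts > 0)
  if (length(idx) == 0) {
    return(structure(list(
      clusters = data.frame(cluster_id = integer(0), n_bins = integer(0),
                            n_localizations = integer(0),
                            diameter = numeric(0)),
      membership = integer(0), bins = integer(0),
      bin_size = grid$bin_size), class = "cluster_set"))
  }
  r <- (idx - 1L) %% nr
  cc <- (idx - 1L) %/% nr
  # connect each non-empty bin to its E, S, SE, SW neighbours (the other
  # four directions are covered symmetrically)
  ed <- list()
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + off[1]
    c2 <- cc + off[2]
    ok <- r2 >= 0L & r2 < nr & c2 >= 0L & c2 < nc
    to <- match(r2[ok] + nr * c2[ok] + 1L, idx)
    keep <- !is.na(to)
    if (any(keep))
      ed[[length(ed) + 1L]] <- cbind(which(ok)[keep], to[keep])
  }
  if (length(ed)) {
    g <- igraph::graph_from_edgelist(do.call(rbind, ed), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_along(idx)
  }
  nl <- as.vector(tapply(counts[idx], memb, sum))
  nb <- as.vector(table(memb))
  clusters <- data.frame(cluster_id = seq_along(nb), n_bins = as.integer(nb),
                         n_localizations = as.integer(nl),
                         diameter = cluster_diameter(as.integer(nb),
                                                     grid$bin_size))
  structure(list(clusters = clusters, membership = as.integer(memb),
                 bins = idx, bin_size = grid$bin_size),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters, %d localizations, bin %.1f nm\n",
              nrow(x$clusters), sum(x$clusters$n_localizations), x$bin_size))
  invisible(x)
}

#' Cluster diameter from bin count
#'
#' Equivalent-square edge: `bin_size * sqrt(n_bins)`. A single occupied bin
#' therefore has diameter `bin_size`. Alternative estimators (e.g.
#' equivalent-circle, `2 * bin_size * sqrt(n_bins / pi)`) differ by a
#' constant factor.
#'
#' @param n_bins number of member bins (>= 1).
#' @param bin_size bin edge length in nm.
#' @return Diameter(s) in nm.
#' @export
cluster_diameter <- function(n_bins, bin_size) {
  if (any(n_bins < 1)) stop("n_bins must be >= 1")
  bin_size * sqrt(n_bins)
}

#' Localization-weighted cluster size distribution
#'
#' Each cluster is weighted by the number of localizations it contains, so
#' the distribution describes the fraction of total localizations found in
#' clusters of a given diameter. The weighted median is the smallest
#' diameter at which the cumulative localization weight reaches one half.
#'
#' @param clusters a `cluster_set` or its `clusters` data frame.
#' @param breaks histogram break specification passed to [hist()]
#'   (default `"Sturges"`).
#' @return List with `diameter`, `weight` (normalized localization weight
#'   per cluster, sorted by diameter), `histogram` (a `histogram` object of
#'   diameters weighted by localizations) and `weighted_median` (nm).
#' @export
weighted_size_distribution <- function(clusters, breaks = "Sturges") {
  df <- if (inherits(clusters, "cluster_set")) clusters$clusters else clusters
  if (nrow(df) == 0) stop("empty cluster set")
  o <- order(df$diameter)
  d <- df$diameter[o]
  w <- df$n_localizations[o] / sum(df$n_localizations)
  med <- d[which(cumsum(w) >= 0.5)[1]]
  h <- graphics::hist(rep(d, times = df$n_localizations[o]), breaks = breaks,
                      plot = FALSE)
  h$density <- h$counts / sum(h$counts)
  list(diameter = d, weight = w, histogram = h, weighted_median = med)
}

#' Count clusters above a diameter threshold
#'
#' @param clusters a `cluster_set` or its `clusters` data frame.
#' @param threshold diameter threshold in nm (default 30, the resolution
#'   limit below which single bins are not interpretable as clusters).
#' @return Number of clusters with diameter strictly above `threshold`.
#' @export
count_clusters_above <- function(clusters, threshold = 30) {
  df <- if (inherits(clusters, "cluster_set")) clusters$clusters else clusters
  sum(df$diameter > threshold)
}

#' Two-channel colocalization by cluster overlap
#'
#' Both channels are binned on a shared fixed grid (15 nm by default) and
#' clustered independently. Single-bin clusters (below the resolution
#' limit) are excluded. Clusters from the two channels that share at least
#' one bin are colocalized; each channel's colocalization fraction is the
#' number of localizations in colocalized clusters divided by the
#' localizations in all its multi-bin clusters.
#'
#' @param table_a,table_b [localization_table()]s for the two channels.
#' @param bin_size shared bin size in nm (default 15).
#' @return List with `frac_a`, `frac_b` (fractions in \[0, 1\], `NA` with a
#'   warning when a channel has no multi-bin cluster), and the two
#'   `cluster_set`s.
#' @export
colocalization <- function(table_a, table_b, bin_size = 15) {
  if (nrow(table_a) == 0 || nrow(table_b) == 0)
    stop("both channels must contain localizations")
  origin <- c(min(table_a$x_nm, table_b$x_nm),
              min(table_a$y_nm, table_b$y_nm))
  dims <- c(floor(max(table_a$x_nm, table_b$x_nm) - origin[1]) %/% bin_size + 1L,
            floor(max(table_a$y_nm, table_b$y_nm) - origin[2]) %/% bin_size + 1L)
  ga <- rasterize(table_a, bin_size, origin = origin, dims = dims)
  gb <- rasterize(table_b, bin_size, origin = origin, dims = dims)
  ca <- call_clusters(ga)
  cb <- call_clusters(gb)
  frac <- function(self, other) {
    multi <- self$clusters$cluster_id[self$clusters$n_bins > 1]
    if (length(multi) == 0) {
      warning("channel has no multi-bin clusters; fraction undefined")
      return(NA_real_)
    }
    keep <- self$membership %in% multi
    other_multi <- other$clusters$cluster_id[other$clusters$n_bins > 1]
    other_bins <- other$bins[other$membership %in% other_multi]
    shared <- self$bins[keep] %in% other_bins
    coloc_ids <- unique(self$membership[keep][shared])
    in_multi <- self$clusters$cluster_id %in% multi
    in_coloc <- self$clusters$cluster_id %in% coloc_ids
    sum(self$clusters$n_localizations[in_coloc]) /
      sum(self$clusters$n_localizations[in_multi])
  }
  list(frac_a = frac(ca, cb), frac_b = frac(cb, ca),
       clusters_a = ca, clusters_b = cb)
}

#' Per-cell cluster calling with adaptive bins
#'
#' Runs the full single-channel pipeline: for each cell, the bin size is
#' adapted to that cell's localization count relative to the cohort average
#' ([adaptive_bin_size()]), localizations are rasterized and clusters
#' called.
#'
#' @param table a [localization_table()] with `cell_id` labels.
#' @param n_avg cohort-average localizations per cell; computed from the
#'   table's `cell_id` groups when `NULL`.
#' @return List with `per_cell` (named list of `cluster_set`s),
#'   `bin_sizes` (nm per cell) and `clusters` (combined data frame with a
#'   `cell_id` column).
#' @export
storm_cluster_cells <- function(table, n_avg = NULL) {
  cells <- split(table, table$cell_id)
  if (is.null(n_avg)) n_avg <- mean(vapply(cells, nrow, integer(1)))
  per_cell <- list()
  bin_sizes <- numeric(0)
  for (cid in names(cells)) {
    b <- adaptive_bin_size(nrow(cells[[cid]]), n_avg)
    per_cell[[cid]] <- call_clusters(rasterize(cells[[cid]], b))
    bin_sizes[cid] <- b
  }
  comb <- do.call(rbind, lapply(names(per_cell), function(cid) {
    df <- per_cell[[cid]]$clusters
    if (nrow(df)) cbind(cell_id = cid, df) else NULL
  }))
  list(per_cell = per_cell, bin_sizes = bin_sizes, clusters = comb)
}

# two-sample Kolmogorov-Smirnov distance between localization-weighted
# diameter distributions
.weighted_ks <- function(d1, w1, d2, w2) {
  grid <- sort(unique(c(d1, d2)))
  f1 <- stats::stepfun(sort(d1), c(0, cumsum(w1[order(d1)]) / sum(w1)))
  f2 <- stats::stepfun(sort(d2), c(0, cumsum(w2[order(d2)]) / sum(w2)))
  max(abs(f1(grid) - f2(grid)))
}

#' Robustness of the size distribution to 50% subsampling
#'
#' Randomly splits the localizations in half, reruns the full cluster
#' pipeline on each half and on the full table, and scores the divergence
#' between the resulting localization-weighted diameter distributions with
#' a two-sample Kolmogorov-Smirnov distance. Small distances indicate that
#' called cluster sizes are not an artifact of localization density.
#'
#' @param table a [localization_table()].
#' @param seed random seed for the split.
#' @param bin_size bin size in nm (default 15; halving every cell of a
#'   cohort halves the cohort average too, so the adaptive rule returns the
#'   same bin size for the halves as for the full data).
#' @return List with `half1`, `half2`, `full` (each a
#'   [weighted_size_distribution()] result), `ks_half_vs_full` (the larger
#'   of the two half-versus-full KS distances) and `ks_between_halves`.
#' @export
subsample_robustness <- function(table, seed = 1L, bin_size = 15) {
  if (nrow(table) < 2) stop("need at least 2 localizations")
  set.seed(seed)
  n <- nrow(table)
  pick <- sample.int(n, floor(n / 2))
  run <- function(tab) {
    weighted_size_distribution(call_clusters(rasterize(tab, bin_size)))
  }
  h1 <- run(table[pick, , drop = FALSE])
  h2 <- run(table[-pick, , drop = FALSE])
  full <- run(table)
  k1 <- .weighted_ks(h1$diameter, h1$weight, full$diameter, full$weight)
  k2 <- .weighted_ks(h2$diameter, h2$weight, full$diameter, full$weight)
  list(half1 = h1, half2 = h2, full = full,
       ks_half_vs_full = max(k1, k2),
       ks_between_halves = .weighted_ks(h1$diameter, h1$weight,
                                        h2$diameter, h2$weight))
}
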