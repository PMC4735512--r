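#' Parameters for the synthetic STORM localization generator
#'
#' Defaults emulate the phenomenology of Polycomb protein clusters in
#' cultured Drosophila cell nuclei: a few hundred clusters per nucleus with
#' diameters spanning roughly 30-700 nm (log-uniform), molecule content
#' scaling with the third power of diameter, several switching events
#' (localizations) per dye molecule, localization jitter at the imaging
#' precision, and a sparse non-specific background.
#'
#' @param nucleus_diameter_nm imaged nuclear section diameter (default
#'   7000 nm, a typical S2-cell nucleus).
#' @param n_clusters planted clusters (default 200, matching the observed
#'   order of hundreds per cell).
#' @param diameter_range_nm log-uniform bounds for planted diameters.
#' @param molecules_per_30nm molecule count of a 30 nm cluster; a cluster
#'   of diameter d holds `round(molecules_per_30nm * (d/30)^3)` molecules.
#' @param loc_per_molecule_mean mean localizations per molecule (geometric
#'   blinking model, support >= 1).
#' @param jitter_sd_nm Gaussian localization jitter (per axis).
#' @param background_per_um2 uniform background localization density.
#' @param shared_fraction for two-channel data: fraction of clusters that
#'   emit in both channels.
#' @param placement_margin_nm minimum edge-to-edge gap between planted
#'   clusters. Planted objects must stay resolvable as distinct clusters
#'   under the measurement model, so the default (100 nm) exceeds twice the
#'   3-sigma jitter spill plus two 15-nm bins.
#' @param seed random seed.
#' @return A list of class `loc_gen_params`.
#' @export
loc_gen_params <- function(nucleus_diameter_nm = 7000, n_clusters = 200,
                           diameter_range_nm = c(30, 700),
                           molecules_per_30nm = 3,
                           loc_per_molecule_mean = 4,
                           jitter_sd_nm = 10, background_per_um2 = 2,
                           shared_fraction = 0.5,
                           placement_margin_nm = 100, seed = 1L) {
  stopifnot(nucleus_diameter_nm > 0, n_clusters >= 1,
            all(diameter_range_nm > 0),
            diameter_range_nm[1] <= diameter_range_nm[2],
            molecules_per_30nm > 0, loc_per_molecule_mean >= 1,
            jitter_sd_nm >= 0, background_per_um2 >= 0,
            shared_fraction >= 0, shared_fraction <= 1)
  structure(as.list(environment()), class = "loc_gen_params")
}

# dart-throwing placement, largest cluster first; guarantees planted
# clusters do not touch, so the planted truth is well defined
.place_clusters <- function(d, R, margin, max_tries = 20000) {
  o <- order(d, decreasing = TRUE)
  n <- length(d)
  x <- numeric(n)
  y <- numeric(n)
  for (k in seq_len(n)) {
    i <- o[k]
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      rr <- (R - d[i] / 2) * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      cx <- rr * cos(th)
      cy <- rr * sin(th)
      prev <- o[seq_len(k - 1)]
      if (k == 1 ||
          all((cx - x[prev])^2 + (cy - y[prev])^2 >
              ((d[i] + d[prev]) / 2 + margin)^2)) {
        x[i] <- cx
        y[i] <- cy
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place cluster ", i,
           "; reduce n_clusters or enlarge the nucleus")
  }
  cbind(x = x, y = y)
}

# molecule positions and blinking for one cluster
.emit_cluster <- function(cx, cy, diam, n_mol, loc_mean, jitter) {
  rr <- (diam / 2) * sqrt(stats::runif(n_mol))
  th <- stats::runif(n_mol, 0, 2 * pi)
  mx <- cx + rr * cos(th)
  my <- cy + rr * sin(th)
  k <- 1L + stats::rgeom(n_mol, prob = 1 / loc_mean)
  x <- rep(mx, k) + stats::rnorm(sum(k), 0, jitter)
  y <- rep(my, k) + stats::rnorm(sum(k), 0, jitter)
  list(x = x, y = y, n_loc = sum(k))
}

#' Generate a synthetic localization table with planted clusters
#'
#' Clusters are placed without mutual overlap in a circular nuclear
#' section; each cluster's molecules are scattered uniformly in its disc,
#' each molecule emits a geometric number of localizations with Gaussian
#' jitter, and a uniform background is added. The truth record carries the
#' planted centres, diameters and realized localization counts, sufficient
#' to score recovery of the localization-weighted size distribution.
#'
#' @param params a [loc_gen_params()].
#' @param cell_id label written into the table.
#' @param channel channel label.
#' @return List with `table` (a [localization_table()]), `truth` (data
#'   frame `cluster_id`, `x`, `y`, `diameter`, `n_molecules`,
#'   `n_localizations`) and `weighted_median_diameter` (the planted
#'   localization-weighted median).
#' @export
gen_localizations <- function(params, cell_id = "cell1", channel = "ch1") {
  stopifnot(inherits(params, "loc_gen_params"))
  set.seed(params$seed)
  .gen_localizations_impl(params, cell_id, channel)
}

.gen_localizations_impl <- function(params, cell_id, channel) {
  R <- params$nucleus_diameter_nm / 2
  d <- exp(stats::runif(params$n_clusters,
                        log(params$diameter_range_nm[1]),
                        log(params$diameter_range_nm[2])))
  centers <- .place_clusters(d, R, params$placement_margin_nm)
  n_mol <- pmax(1L, as.integer(round(params$molecules_per_30nm *
                                       (d / 30)^3)))
  xs <- list()
  ys <- list()
  n_loc <- integer(params$n_clusters)
  for (i in seq_len(params$n_clusters)) {
    em <- .emit_cluster(centers[i, 1], centers[i, 2], d[i], n_mol[i],
                        params$loc_per_molecule_mean, params$jitter_sd_nm)
    xs[[i]] <- em$x
    ys[[i]] <- em$y
    n_loc[i] <- em$n_loc
  }
  area_um2 <- pi * (R / 1000)^2
  n_bg <- stats::rpois(1, params$background_per_um2 * area_um2)
  if (n_bg > 0) {
    rr <- R * sqrt(stats::runif(n_bg))
    th <- stats::runif(n_bg, 0, 2 * pi)
    xs[[length(xs) + 1]] <- rr * cos(th)
    ys[[length(ys) + 1]] <- rr * sin(th)
  }
  truth <- data.frame(cluster_id = seq_len(params$n_clusters),
                      x = centers[, 1], y = centers[, 2], diameter = d,
                      n_molecules = n_mol, n_localizations = n_loc)
  o <- order(truth$diameter)
  wm <- truth$diameter[o][
    which(cumsum(truth$n_localizations[o]) / sum(truth$n_localizations)
          >= 0.5)[1]]
  list(table = localization_table(unlist(xs), unlist(ys), channel, cell_id),
       truth = truth, weighted_median_diameter = wm)
}

#' Generate paired two-channel localization tables
#'
#' A fraction `shared_fraction` of the planted clusters emit in both
#' channels (independent blinking per channel from the same molecule
#' disc); the remaining clusters alternate between channel-exclusive A and
#' B. Background is drawn independently per channel.
#'
#' @param params a [loc_gen_params()].
#' @param cell_id cell label.
#' @return List with `table_a`, `table_b`, `truth` (per-cluster channels),
#'   and `planted_fraction_a`, `planted_fraction_b`: the planted fraction
#'   of cluster localizations sitting in shared clusters, per channel.
#' @export
gen_two_channel <- function(params, cell_id = "cell1") {
  stopifnot(inherits(params, "loc_gen_params"))
  set.seed(params$seed)
  R <- params$nucleus_diameter_nm / 2
  n <- params$n_clusters
  d <- exp(stats::runif(n, log(params$diameter_range_nm[1]),
                        log(params$diameter_range_nm[2])))
  centers <- .place_clusters(d, R, params$placement_margin_nm)
  n_mol <- pmax(1L, as.integer(round(params$molecules_per_30nm *
                                       (d / 30)^3)))
  n_shared <- round(params$shared_fraction * n)
  grp <- rep("shared", n)
  if (n_shared < n)
    grp[(n_shared + 1):n] <- rep(c("a_only", "b_only"),
                                 length.out = n - n_shared)
  grp <- sample(grp)
  emit <- function(i) .emit_cluster(centers[i, 1], centers[i, 2], d[i],
                                    n_mol[i], params$loc_per_molecule_mean,
                                    params$jitter_sd_nm)
  xa <- list(); ya <- list(); xb <- list(); yb <- list()
  loc_a <- numeric(n)
  loc_b <- numeric(n)
  for (i in seq_len(n)) {
    if (grp[i] %in% c("shared", "a_only")) {
      em <- emit(i)
      xa[[length(xa) + 1]] <- em$x
      ya[[length(ya) + 1]] <- em$y
      loc_a[i] <- em$n_loc
    }
    if (grp[i] %in% c("shared", "b_only")) {
      em <- emit(i)
      xb[[length(xb) + 1]] <- em$x
      yb[[length(yb) + 1]] <- em$y
      loc_b[i] <- em$n_loc
    }
  }
  bg <- function() {
    area_um2 <- pi * (R / 1000)^2
    n_bg <- stats::rpois(1, params$background_per_um2 * area_um2)
    rr <- R * sqrt(stats::runif(n_bg))
    th <- stats::runif(n_bg, 0, 2 * pi)
    list(x = rr * cos(th), y = rr * sin(th))
  }
  b1 <- bg()
  b2 <- bg()
  truth <- data.frame(cluster_id = seq_len(n), x = centers[, 1],
                      y = centers[, 2], diameter = d, group = grp,
                      loc_a = loc_a, loc_b = loc_b)
  list(table_a = localization_table(c(unlist(xa), b1$x),
                                    c(unlist(ya), b1$y), "chA", cell_id),
       table_b = localization_table(c(unlist(xb), b2$x),
                                    c(unlist(yb), b2$y), "chB", cell_id),
       truth = truth,
       planted_fraction_a = sum(loc_a[grp == "shared"]) / sum(loc_a),
       planted_fraction_b = sum(loc_b[grp == "shared"]) / sum(loc_b))
}

#' Generate a restriction-fragment map
#'
#' Contiguous fragments tiling `[offset, offset + chrom_length)` with
#' geometric lengths (mean 256 bp, the expected spacing of a 4-cutter such
#' as NlaIII); the last fragment is truncated so total length is conserved.
#'
#' @param chrom_length region length in bp.
#' @param mean_fragment_bp mean fragment length (default 256).
#' @param chrom chromosome name.
#' @param offset start coordinate of the first fragment (0-based).
#' @param seed random seed.
#' @return Data frame with `chrom`, `start`, `end`, sorted and
#'   non-overlapping.
#' @export
gen_fragment_map <- function(chrom_length, mean_fragment_bp = 256,
                             chrom = "chr3R", offset = 0, seed = 1L) {
  stopifnot(chrom_length > 0, mean_fragment_bp >= 1)
  set.seed(seed)
  n_guess <- ceiling(2 * chrom_length / mean_fragment_bp) + 10
  lens <- 1L + stats::rgeom(n_guess, prob = 1 / mean_fragment_bp)
  while (sum(lens) < chrom_length)
    lens <- c(lens, 1L + stats::rgeom(n_guess, prob = 1 / mean_fragment_bp))
  cs <- cumsum(lens)
  k <- which(cs >= chrom_length)[1]
  lens <- lens[seq_len(k)]
  cs <- cs[seq_len(k)]
  ends <- pmin(cs, chrom_length)
  starts <- c(0, ends[-k])
  data.frame(chrom = chrom, start = offset + starts, end = offset + ends)
}

#' Parameters for the synthetic 4C-seq track generator
#'
#' Defaults emulate a 4C viewpoint inside the BX-C: a fragment map over the
#' normalization region, a power-law contact decay away from the
#' viewpoint, enrichment at planted protein-binding peaks, negative
#' binomial replicate noise, and a planted contact depletion of the far
#' region in the test condition.
#'
#' @param scheme a [region_scheme()]; the fragment map spans its
#'   normalization region and the depletion region is the far side of its
#'   near/far boundary.
#' @param mean_fragment_bp mean restriction-fragment length.
#' @param decay_exponent power-law exponent of contact decay (> 0).
#' @param decay_scale_bp distance scale of the decay.
#' @param n_peaks planted binding-site peaks inside the BX-C.
#' @param peak_width_bp peak width.
#' @param peak_enrichment fold enrichment of contacts at peak fragments.
#' @param depletion_factor factor in (0, 1] multiplying far-region contact
#'   intensity in the test condition (1 = null data).
#' @param peak_depletion_factor factor in (0, 1] multiplying contact
#'   intensity at peak-overlapping fragments in the test condition, so
#'   contact losses concentrate around binding sites (default 1 = off;
#'   set below 1 to plant peak-proximal losses).
#' @param reads_per_sample expected sequencing depth per sample.
#' @param nb_size negative binomial size (overdispersion) parameter.
#' @param conditions names of control and test conditions.
#' @param n_replicates replicates per condition.
#' @param seed random seed.
#' @return A list of class `fourc_gen_params`.
#' @export
fourc_gen_params <- function(scheme = region_scheme(),
                             mean_fragment_bp = 256,
                             decay_exponent = 1.0, decay_scale_bp = 2000,
                             n_peaks = 10, peak_width_bp = 500,
                             peak_enrichment = 3,
                             depletion_factor = 0.5,
                             peak_depletion_factor = 1,
                             reads_per_sample = 5e5, nb_size = 10,
                             conditions = c(control = "S2",
                                            test = "PhML"),
                             n_replicates = 2, seed = 1L) {
  stopifnot(decay_exponent > 0, depletion_factor > 0, depletion_factor <= 1,
            peak_depletion_factor > 0, peak_depletion_factor <= 1,
            nb_size > 0, n_replicates >= 1)
  structure(as.list(environment()), class = "fourc_gen_params")
}

#' Generate synthetic 4C-seq count tracks with planted structure
#'
#' Builds a restriction-fragment map over the scheme's normalization
#' region, plants peaks inside the BX-C, and draws negative binomial read
#' counts whose expectation decays with distance from the viewpoint and is
#' enriched at peaks. In the test condition the far region's expected
#' counts are multiplied by `depletion_factor`. Each sample is scaled to
#' the same expected depth, mimicking equal sequencing effort.
#'
#' @param params a [fourc_gen_params()].
#' @return List with `track` (a [fragment_track()] with
#'   `condition.replicate` columns), `scheme`, `peaks` (planted peak
#'   intervals) and `truth` (depletion region, factor, viewpoint).
#' @export
gen_4c_tracks <- function(params) {
  stopifnot(inherits(params, "fourc_gen_params"))
  set.seed(params$seed)
  sc <- params$scheme
  span <- sc$norm_region
  frags <- gen_fragment_map(span[2] - span[1], params$mean_fragment_bp,
                            chrom = sc$chrom, offset = span[1],
                            seed = sample.int(.Machine$integer.max, 1))
  mid <- (frags$start + frags$end) / 2
  vp_mid <- mean(sc$viewpoint)
  w <- (1 + abs(mid - vp_mid) / params$decay_scale_bp)^(-params$decay_exponent)

  # planted peaks inside the BX-C, away from the viewpoint mask
  ok <- FALSE
  while (!ok) {
    pk_start <- sort(round(stats::runif(params$n_peaks, sc$bxc[1],
                                        sc$bxc[2] - params$peak_width_bp)))
    ok <- all(diff(pk_start) > 2 * params$peak_width_bp)
  }
  peaks <- data.frame(chrom = sc$chrom, start = pk_start,
                      end = pk_start + params$peak_width_bp)
  on_peak <- GenomicRanges::countOverlaps(.df_to_gr(frags),
                                          .df_to_gr(peaks)) > 0
  w[on_peak] <- w[on_peak] * params$peak_enrichment

  # far region = opposite side of the boundary from the viewpoint
  vp_near_right <- vp_mid >= sc$boundary
  far <- if (vp_near_right) mid < sc$boundary & mid >= sc$bxc[1]
         else mid >= sc$boundary & mid < sc$bxc[2]
  w_test <- w
  w_test[far] <- w_test[far] * params$depletion_factor
  w_test[on_peak] <- w_test[on_peak] * params$peak_depletion_factor

  draw <- function(wv) {
    mu <- params$reads_per_sample * wv / sum(wv)
    stats::rnbinom(length(mu), size = params$nb_size, mu = mu)
  }
  cols <- list()
  for (rep_i in seq_len(params$n_replicates))
    cols[[paste0(params$conditions[["control"]], ".", rep_i)]] <- draw(w)
  for (rep_i in seq_len(params$n_replicates))
    cols[[paste0(params$conditions[["test"]], ".", rep_i)]] <- draw(w_test)
  counts <- do.call(cbind, cols)
  list(track = fragment_track(frags, counts), scheme = sc, peaks = peaks,
       truth = list(far_region_is_left = vp_near_right,
                    far_index = far, on_peak = on_peak,
                    depletion_factor = params$depletion_factor,
                    peak_depletion_factor = params$peak_depletion_factor,
                    viewpoint_mid = vp_mid))
}

#' Generate a contact set with a planted peak-overlap rate
#'
#' Places `round(frac_on_peaks * n_contacts)` contact intervals centred on
#' randomly chosen peak centres and the remainder uniformly in `span`
#' rejecting any peak overlap, so the planted fraction of peak-overlapping
#' contacts is exact.
#'
#' @param n_contacts number of contacts.
#' @param peaks peak data frame.
#' @param frac_on_peaks planted overlap fraction.
#' @param span `c(lo, hi)` placement range (0-based).
#' @param chrom chromosome.
#' @param width_range contact width bounds in bp.
#' @param seed random seed.
#' @return Data frame of contact intervals.
#' @export
gen_contacts <- function(n_contacts, peaks, frac_on_peaks = 0.6,
                         span, chrom = "chr3R",
                         width_range = c(2000, 10000), seed = 1L) {
  set.seed(seed)
  n_on <- round(frac_on_peaks * n_contacts)
  widths <- round(stats::runif(n_contacts, width_range[1], width_range[2]))
  centres_pk <- (peaks$start + peaks$end) / 2
  ctr <- numeric(n_contacts)
  if (n_on > 0)
    ctr[seq_len(n_on)] <- sample(centres_pk, n_on, replace = TRUE)
  pk_gr <- .df_to_gr(peaks)
  i <- n_on + 1
  while (i <= n_contacts) {
    cand <- round(stats::runif(1, span[1] + widths[i] / 2,
                               span[2] - widths[i] / 2))
    test <- data.frame(chrom = chrom, start = cand - widths[i] / 2,
                       end = cand + widths[i] / 2)
    if (sum(GenomicRanges::countOverlaps(.df_to_gr(test), pk_gr)) == 0) {
      ctr[i] <- cand
      i <- i + 1
    }
  }
  data.frame(chrom = chrom, start = round(ctr - widths / 2),
             end = round(ctr + widths / 2))
}
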