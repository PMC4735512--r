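#' Restriction-fragment count track
#'
#' Container for 4C-seq signal: an ordered set of non-overlapping
#' restriction fragments (0-based, half-open coordinates) and a matrix of
#' read counts with one column per sample.
#'
#' @param fragments data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), sorted and non-overlapping per chromosome.
#' @param counts numeric matrix, `nrow(fragments)` rows; column names are
#'   sample labels.
#' @param samples optional data frame with columns `sample`, `condition`,
#'   `replicate` describing the count columns; parsed from
#'   `"condition.replicate"` column names when `NULL`.
#' @return A list of class `fragment_track` with elements `fragments`,
#'   `counts`, `samples` and an `excluded` logical vector (all `FALSE`
#'   until [mask_viewpoint()] is applied).
#' @export
fragment_track <- function(fragments, counts, samples = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(fragments)))
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(fragments))
    stop("counts must have one row per fragment")
  if (any(counts < 0)) stop("counts must be non-negative")
  o <- order(fragments$chrom, fragments$start)
  fragments <- fragments[o, c("chrom", "start", "end")]
  counts <- counts[o, , drop = FALSE]
  for (ch in unique(fragments$chrom)) {
    f <- fragments[fragments$chrom == ch, ]
    if (nrow(f) > 1 && any(f$start[-1] < f$end[-nrow(f)]))
      stop("fragments overlap on ", ch)
  }
  if (is.null(samples)) {
    parts <- strsplit(colnames(counts), ".", fixed = TRUE)
    samples <- data.frame(
      sample = colnames(counts),
      condition = vapply(parts, `[`, "", 1),
      replicate = vapply(parts, function(p)
        if (length(p) > 1) p[2] else "1", ""))
  }
  structure(list(fragments = fragments, counts = counts, samples = samples,
                 excluded = rep(FALSE, nrow(fragments))),
            class = "fragment_track")
}

#' @export
print.fragment_track <- function(x, ...) {
  cat(sprintf("fragment_track: %d fragments, %d sample(s) [%s]\n",
              nrow(x$fragments), ncol(x$counts),
              paste(colnames(x$counts), collapse = ", ")))
  invisible(x)
}

# 0-based half-open data frame -> GRanges (1-based closed)
.df_to_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1, df$end))
}

#' Genomic region scheme for the BX-C 4C analysis
#'
#' Bundles the fixed genomic landmarks of the analysis: the normalization
#' region around the Bithorax complex, the viewpoint interval, the boundary
#' separating "near" from "far" contacts, the BX-C bounds used for window
#' tiling, and the neighbourhood margin for long-range contact
#' partitioning. Input coordinates follow the 1-based printed convention
#' and are converted to 0-based half-open internally.
#'
#' Default landmarks (chr3R, dm3): normalization region
#' 12367359-12885749; BX-C bounds 12480479-12821577; near/far boundary
#' 12681222 (the iab-3/iab-4 boundary, used for the Abd-B and Fab-6
#' viewpoints; use 12598911, the bxd transcript start, for the Ubx
#' viewpoint).
#'
#' @param chrom chromosome name.
#' @param norm_region `c(start, end)` of the normalization region (1-based
#'   inclusive).
#' @param viewpoint `c(start, end)` of the viewpoint fragment.
#' @param boundary near/far boundary position.
#' @param bxc `c(start, end)` BX-C bounds.
#' @param viewpoint_margin bp masked on each side of the viewpoint.
#' @param neighbourhood_margin bp defining the BX-C neighbourhood for
#'   long-range contacts.
#' @return A list of class `region_scheme` (coordinates 0-based half-open).
#' @export
region_scheme <- function(chrom = "chr3R",
                          norm_region = c(12367359, 12885749),
                          viewpoint = c(12749000, 12753000),
                          boundary = 12681222,
                          bxc = c(12480479, 12821577),
                          viewpoint_margin = 5000,
                          neighbourhood_margin = 2e6) {
  if (boundary < bxc[1] || boundary > bxc[2])
    stop("near/far boundary must lie within the BX-C bounds")
  if (viewpoint_margin <= 0 || neighbourhood_margin <= 0)
    stop("margins must be positive")
  structure(list(chrom = chrom,
                 norm_region = c(norm_region[1] - 1, norm_region[2]),
                 viewpoint = c(viewpoint[1] - 1, viewpoint[2]),
                 boundary = boundary - 1,
                 bxc = c(bxc[1] - 1, bxc[2]),
                 viewpoint_margin = viewpoint_margin,
                 neighbourhood_margin = neighbourhood_margin),
            class = "region_scheme")
}

.in_region <- function(fragments, chrom, lo, hi) {
  fragments$chrom == chrom & fragments$start < hi & fragments$end > lo
}

#' Normalize samples over the reference region
#'
#' Scales each sample so that its total reads inside the normalization
#' region equal a common constant; within-sample relative values are
#' preserved.
#'
#' @param track a [fragment_track()].
#' @param scheme a [region_scheme()].
#' @param constant common post-normalization in-region total (default 1e6;
#'   downstream ratios are scale-free).
#' @return The normalized track.
#' @export
normalize_track <- function(track, scheme, constant = 1e6) {
  inr <- .in_region(track$fragments, scheme$chrom,
                    scheme$norm_region[1], scheme$norm_region[2])
  if (!any(inr)) stop("no fragments in the normalization region")
  totals <- colSums(track$counts[inr, , drop = FALSE])
  if (any(totals == 0))
    stop("sample(s) with zero reads in the normalization region: ",
         paste(colnames(track$counts)[totals == 0], collapse = ", "))
  track$counts <- sweep(track$counts, 2, constant / totals, `*`)
  track
}

#' Running-mean smoothing in fragment space
#'
#' Replaces each fragment's value with the mean over a window of
#' `window` fragments centred on it (default 3). Windows are truncated at
#' the track ends.
#'
#' @param track a [fragment_track()].
#' @param window odd window width in fragments.
#' @return The smoothed track.
#' @export
smooth_running_mean <- function(track, window = 3) {
  if (window < 1 || window %% 2 != 1) stop("window must be odd and >= 1")
  k <- (window - 1) / 2
  smooth1 <- function(v) {
    n <- length(v)
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - k, 1)
    hi <- pmin(seq_len(n) + k, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  for (ch in unique(track$fragments$chrom)) {
    i <- which(track$fragments$chrom == ch)
    track$counts[i, ] <- apply(track$counts[i, , drop = FALSE], 2, smooth1)
  }
  track
}

#' Mask fragments around the viewpoint
#'
#' Flags fragments overlapping the viewpoint extended by `margin` bp on
#' each side (any-overlap rule) as excluded from downstream statistics.
#'
#' @param track a [fragment_track()].
#' @param scheme a [region_scheme()].
#' @param margin bp masked on each side (defaults to the scheme's
#'   `viewpoint_margin`, 5 kb).
#' @return The track with its `excluded` flags updated.
#' @export
mask_viewpoint <- function(track, scheme, margin = scheme$viewpoint_margin) {
  lo <- scheme$viewpoint[1] - margin
  hi <- scheme$viewpoint[2] + margin
  track$excluded <- track$excluded |
    .in_region(track$fragments, scheme$chrom, lo, hi)
  track
}

#' Average replicate columns per condition
#'
#' @param track a [fragment_track()].
#' @return A track whose count columns are condition means.
#' @export
average_replicates <- function(track) {
  conds <- unique(track$samples$condition)
  m <- vapply(conds, function(cd) {
    rowMeans(track$counts[, track$samples$condition == cd, drop = FALSE])
  }, numeric(nrow(track$counts)))
  m <- matrix(m, nrow = nrow(track$counts),
              dimnames = list(NULL, conds))
  track$counts <- m
  track$samples <- data.frame(sample = conds, condition = conds,
                              replicate = "mean")
  track
}

#' Contact-change ratio track (test / control - 1)
#'
#' Divides the test condition's (replicate-averaged, normalized) values by
#' the control's and subtracts 1, so increased contact frequencies are
#' positive and decreased ones negative. Fragments with a zero control
#' value are flagged undefined (`NA`), never infinite.
#'
#' @param test_track,control_track [fragment_track()]s sharing the same
#'   fragment map, each with a single count column (see
#'   [average_replicates()]).
#' @return Data frame with `chrom`, `start`, `end`, `ratio` (test/control
#'   - 1, `NA` where undefined) and `excluded` (viewpoint mask of either
#'   input).
#' @export
ratio_minus_one <- function(test_track, control_track) {
  if (!identical(test_track$fragments, control_track$fragments))
    stop("tracks must share the same fragment map")
  if (ncol(test_track$counts) != 1 || ncol(control_track$counts) != 1)
    stop("tracks must be replicate-averaged to a single column each")
  ctrl <- control_track$counts[, 1]
  ratio <- ifelse(ctrl == 0, NA_real_,
                  test_track$counts[, 1] / ctrl - 1)
  out <- cbind(test_track$fragments,
               data.frame(ratio = ratio,
                          excluded = test_track$excluded |
                            control_track$excluded))
  class(out) <- c("ratio_track", "data.frame")
  out
}

#' Near/far contact summary with group comparison
#'
#' Splits each viewpoint's retained BX-C fragments into "near" (the side of
#' the boundary containing the viewpoint) and "far" regions, reports the
#' mean contact-change ratio per (viewpoint, region), and compares the
#' pooled near and far values with a two-tailed two-sample t-test. The
#' normality of each group is checked with an Anderson-Darling test; if
#' either group violates normality (p < 0.05) an exact Wilcoxon rank-sum
#' test is used instead.
#'
#' @param ratio_tracks a single [ratio_minus_one()] result or a named list
#'   of them (one per viewpoint).
#' @param schemes a [region_scheme()] or list of them matching
#'   `ratio_tracks`.
#' @return List with `means` (data frame `viewpoint`, `region`, `mean`,
#'   `n_fragments`), `p_value`, `method`, `normality_p` and the underlying
#'   `htest`.
#' @export
near_far_summary <- function(ratio_tracks, schemes) {
  if (inherits(ratio_tracks, "ratio_track"))
    ratio_tracks <- list(vp1 = ratio_tracks)
  if (inherits(schemes, "region_scheme"))
    schemes <- rep(list(schemes), length(ratio_tracks))
  near_vals <- list()
  far_vals <- list()
  means <- list()
  for (i in seq_along(ratio_tracks)) {
    rt <- ratio_tracks[[i]]
    sc <- schemes[[i]]
    vp_mid <- mean(sc$viewpoint)
    mid <- (rt$start + rt$end) / 2
    keep <- !rt$excluded & !is.na(rt$ratio) & rt$chrom == sc$chrom &
      mid >= sc$bxc[1] & mid < sc$bxc[2]
    near_side <- if (vp_mid >= sc$boundary) mid >= sc$boundary
                 else mid < sc$boundary
    nv <- rt$ratio[keep & near_side]
    fv <- rt$ratio[keep & !near_side]
    if (length(nv) == 0 || length(fv) == 0)
      stop("viewpoint ", i, ": a region has no retained fragments")
    vp_name <- if (!is.null(names(ratio_tracks)))
      names(ratio_tracks)[i] else paste0("vp", i)
    means[[i]] <- data.frame(viewpoint = vp_name,
                             region = c("near", "far"),
                             mean = c(mean(nv), mean(fv)),
                             n_fragments = c(length(nv), length(fv)))
    near_vals[[i]] <- nv
    far_vals[[i]] <- fv
  }
  near <- unlist(near_vals)
  far <- unlist(far_vals)
  out <- list(means = do.call(rbind, means))
  if (length(near) < 2 || length(far) < 2) {
    warning("too few fragments for a group comparison; test skipped")
    out$p_value <- NA_real_
    out$method <- "none"
    return(out)
  }
  if (stats::sd(near) == 0 && stats::sd(far) == 0 &&
      mean(near) == mean(far)) {
    # identical constant groups (e.g. test track equal to control)
    out$p_value <- 1
    out$method <- "degenerate"
    return(out)
  }
  ad_p <- function(v) {
    if (length(v) < 8 || stats::sd(v) == 0) return(NA_real_)
    nortest::ad.test(v)$p.value
  }
  normality_p <- c(near = ad_p(near), far = ad_p(far))
  normal_ok <- all(is.na(normality_p) | normality_p >= 0.05)
  if (normal_ok) {
    ht <- stats::t.test(near, far, alternative = "two.sided")
    method <- "t.test"
  } else {
    # exact null distribution only where it is computable; the normal
    # approximation is indistinguishable at larger n
    ht <- stats::wilcox.test(near, far, alternative = "two.sided",
                             exact = length(near) <= 50 &&
                               length(far) <= 50)
    method <- "wilcoxon"
  }
  out$p_value <- ht$p.value
  out$method <- method
  out$normality_p <- normality_p
  out$htest <- ht
  out
}

#' Flag windows with changed interaction rates
#'
#' Tiles the BX-C into disjoint `window_bp` windows and computes, per
#' window, the mean replicate-averaged test/control ratio over overlapping
#' retained fragments. Windows with ratio below `1 - threshold` are flagged
#' "decreased" (interaction reduced by more than the threshold), above
#' `1 + threshold` "increased", otherwise "unchanged".
#'
#' @param test_track,control_track normalized [fragment_track()]s (with
#'   replicates; they are averaged internally).
#' @param scheme a [region_scheme()].
#' @param window_bp window width (default 200).
#' @param threshold fractional change required (default 0.5, i.e. >50%).
#' @return Data frame with `chrom`, `start`, `end`, `mid`, `ratio`, `flag`
#'   (`NA` ratio where a window has no informative fragment).
#' @export
flag_changed_windows <- function(test_track, control_track, scheme,
                                 window_bp = 200, threshold = 0.5) {
  ta <- average_replicates(test_track)
  ca <- average_replicates(control_track)
  ctrl <- ca$counts[, 1]
  ratio <- ifelse(ctrl == 0, NA_real_, ta$counts[, 1] / ctrl)
  ratio[ta$excluded | ca$excluded] <- NA_real_
  fr <- ta$fragments
  starts <- seq(scheme$bxc[1], scheme$bxc[2] - 1, by = window_bp)
  ends <- pmin(starts + window_bp, scheme$bxc[2])
  wr <- vapply(seq_along(starts), function(i) {
    ov <- fr$chrom == scheme$chrom & fr$start < ends[i] & fr$end > starts[i]
    v <- ratio[ov]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  flag <- rep(NA_character_, length(wr))
  flag[!is.na(wr) & wr < 1 - threshold] <- "decreased"
  flag[!is.na(wr) & wr > 1 + threshold] <- "increased"
  flag[!is.na(wr) & is.na(flag)] <- "unchanged"
  data.frame(chrom = scheme$chrom, start = starts, end = ends,
             mid = (starts + ends) / 2, ratio = wr, flag = flag)
}

#' Distance from changed windows to the nearest binding-site peak
#'
#' Measures, for every flagged window midpoint, the distance to the centre
#' of the nearest peak (all peaks are candidates regardless of height) and
#' compares mean distances between changed (`"decreased"` and/or
#' `"increased"`) and unchanged windows with a t-test.
#'
#' @param windows output of [flag_changed_windows()].
#' @param peaks data frame of peak intervals (`chrom`, `start`, `end`,
#'   0-based half-open); centres are interval midpoints.
#' @param changed which flags count as changed (default both).
#' @param alternative t-test alternative, `"two.sided"` by default; use
#'   `"less"` to test that changed windows are closer to peaks.
#' @return List with `distances` (windows plus `distance` column),
#'   `group_means`, `p_value` and the `htest`.
#' @export
distance_to_nearest_peak <- function(windows, peaks,
                                     changed = c("decreased", "increased"),
                                     alternative = "two.sided") {
  windows <- windows[!is.na(windows$flag), , drop = FALSE]
  centres <- (peaks$start + peaks$end) / 2
  dist1 <- function(chrom, mid) {
    cand <- centres[peaks$chrom == chrom]
    if (length(cand) == 0)
      stop("no peaks on chromosome ", chrom)
    min(abs(cand - mid))
  }
  windows$distance <- vapply(seq_len(nrow(windows)), function(i)
    dist1(windows$chrom[i], windows$mid[i]), numeric(1))
  is_changed <- windows$flag %in% changed
  gm <- data.frame(group = c("changed", "unchanged"),
                   mean_distance = c(mean(windows$distance[is_changed]),
                                     mean(windows$distance[!is_changed])),
                   n = c(sum(is_changed), sum(!is_changed)))
  out <- list(distances = windows, group_means = gm)
  if (sum(is_changed) >= 2 && sum(!is_changed) >= 2) {
    ht <- stats::t.test(windows$distance[is_changed],
                        windows$distance[!is_changed],
                        alternative = alternative)
    out$p_value <- ht$p.value
    out$htest <- ht
  } else {
    warning("too few windows in a group; test skipped")
    out$p_value <- NA_real_
  }
  out
}

#' Count restriction fragments per contact interval
#'
#' Converts merged significant-contact windows to restriction-fragment
#' counts: the number of fragments each contact overlaps (any-overlap
#' rule).
#'
#' @param contacts data frame of contact intervals (`chrom`, `start`,
#'   `end`, 0-based half-open).
#' @param fragments restriction-fragment map data frame (same convention).
#' @return Integer vector, one count per contact.
#' @export
contacts_to_fragment_counts <- function(contacts, fragments) {
  if (nrow(contacts) == 0) return(integer(0))
  suppressWarnings(
    GenomicRanges::countOverlaps(.df_to_gr(contacts), .df_to_gr(fragments)))
}

#' Mean contact size per condition, normalized to a control
#'
#' @param contact_sets named list of contact data frames, one per
#'   condition.
#' @param fragments restriction-fragment map.
#' @param control name of the control condition.
#' @return Data frame with `condition`, `mean_fragments`,
#'   `normalized` (mean fragments per contact divided by the control's).
#' @export
summarize_contact_sizes <- function(contact_sets, fragments,
                                    control = names(contact_sets)[1]) {
  mf <- vapply(contact_sets, function(ct)
    mean(contacts_to_fragment_counts(ct, fragments)), numeric(1))
  data.frame(condition = names(contact_sets), mean_fragments = mf,
             normalized = mf / mf[[control]], row.names = NULL)
}

#' Partition long-range contacts into neighbourhood and distal sets
#'
#' Contacts overlapping the BX-C are excluded; the remainder are classified
#' by gap distance from the BX-C border: within the neighbourhood margin
#' (2 Mb by default) or more distal. Contacts on other chromosomes are
#' labelled `"other"`.
#'
#' @param contacts contact data frame.
#' @param scheme a [region_scheme()].
#' @return The contacts with a `zone` column
#'   (`"inside"`, `"neighbourhood"`, `"distal"`, `"other"`).
#' @export
partition_contacts <- function(contacts, scheme) {
  zone <- rep("other", nrow(contacts))
  on_chr <- contacts$chrom == scheme$chrom
  lo <- scheme$bxc[1]
  hi <- scheme$bxc[2]
  inside <- on_chr & contacts$start < hi & contacts$end > lo
  gap <- ifelse(contacts$end <= lo, lo - contacts$end,
                ifelse(contacts$start >= hi, contacts$start - hi, 0))
  zone[on_chr & inside] <- "inside"
  zone[on_chr & !inside & gap <= scheme$neighbourhood_margin] <-
    "neighbourhood"
  zone[on_chr & !inside & gap > scheme$neighbourhood_margin] <- "distal"
  contacts$zone <- zone
  contacts
}

#' Fraction of contacts overlapping at least one peak
#'
#' @param contacts contact data frame.
#' @param peaks peak data frame.
#' @return Fraction in \[0, 1\] of contact intervals overlapping >= 1 peak
#'   (any-overlap rule).
#' @export
peak_overlap_fraction <- function(contacts, peaks) {
  if (nrow(contacts) == 0) stop("empty contact set")
  if (nrow(peaks) == 0) return(0)
  mean(suppressWarnings(
    GenomicRanges::countOverlaps(.df_to_gr(contacts), .df_to_gr(peaks))) > 0)
}

#' Read / write BED-style interval files
#'
#' Thin wrappers around `rtracklayer::import()` / `export()` returning the
#' package's 0-based half-open data-frame convention.
#'
#' @param path file path.
#' @return `read_bed()`: data frame with `chrom`, `start`, `end` (plus
#'   `name`/`score` when present).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$name)) df$name <- mc$name
  if (!is.null(mc$score)) df$score <- mc$score
  df
}

#' @rdname read_bed
#' @param df interval data frame (`chrom`, `start`, `end`).
#' @export
write_bed <- function(df, path) {
  gr <- .df_to_gr(df)
  if (!is.null(df$name)) S4Vectors::mcols(gr)$name <- df$name
  if (!is.null(df$score)) S4Vectors::mcols(gr)$score <- df$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' End-to-end ratio track from raw counts
#'
#' Convenience pipeline: normalize over the reference region, optionally
#' smooth with a 3-fragment running mean, mask the viewpoint, average
#' replicates per condition and form the test/control - 1 ratio.
#'
#' Smoothing is applied for display tracks; for the near/far inference the
#' unsmoothed ratios are preferred because the running mean induces serial
#' correlation between neighbouring fragments.
#'
#' @param track a [fragment_track()] containing both conditions.
#' @param test,control condition names.
#' @param scheme a [region_scheme()].
#' @param smooth apply the running mean before the ratio (default `FALSE`).
#' @param window running-mean width in fragments.
#' @return A [ratio_minus_one()] data frame.
#' @export
fourc_ratio_track <- function(track, test, control, scheme,
                              smooth = FALSE, window = 3) {
  tr <- normalize_track(track, scheme)
  if (smooth) tr <- smooth_running_mean(tr, window)
  tr <- mask_viewpoint(tr, scheme)
  avg <- average_replicates(tr)
  pick <- function(cond) {
    t2 <- avg
    t2$counts <- avg$counts[, cond, drop = FALSE]
    t2$samples <- avg$samples[avg$samples$condition == cond, ]
    t2
  }
  ratio_minus_one(pick(test), pick(control))
}
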