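#' Pairwise haplotype p-distances over an interval set
#'
#' Mismatch proportion per callable bp between phased haplotypes, computed
#' over the union of the supplied intervals.  Only variant sites can
#' mismatch; the denominator is the interval length minus, per pair, the
#' sites missing in either haplotype (invariant positions are assumed
#' callable).  Unphased heterozygous sites are dropped with a message.
#'
#' @param gm a [genotype_matrix()].
#' @param haps haplotype ids (`<sample>.<1|2>`, see [hap_ids()]).
#' @param intervals data frame of non-overlapping intervals.
#' @return symmetric numeric matrix of distances; an entry is NA when a
#'   pair has no comparable site support (zero comparable bp).
#' @export
hap_distances <- function(gm, haps, intervals) {
  validate_intervals(intervals)
  total_bp <- interval_bp(intervals)
  if (total_bp <= 0) .stopf("empty interval set")
  keep <- logical(n_sites(gm))
  for (ct in unique(intervals$contig)) {
    sel <- gm$contig == ct
    hit <- IRanges::overlapsAny(
      IRanges::IRanges(gm$pos[sel] + 1L, gm$pos[sel] + 1L),
      .ir(intervals[intervals$contig == ct, , drop = FALSE]))
    keep[sel] <- hit
  }
  H <- hap_alleles(gm, unique(hap_sample(haps)))[keep, haps, drop = FALSE]
  .dist_from_hapmat(H, total_bp)
}

.dist_from_hapmat <- function(H, total_bp) {
  k <- ncol(H)
  D <- matrix(0, k, k, dimnames = list(colnames(H), colnames(H)))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      cmp <- !is.na(H[, i]) & !is.na(H[, j])
      denom <- total_bp - sum(!cmp)
      D[i, j] <- D[j, i] <-
        if (denom <= 0) NA_real_ else sum(H[cmp, i] != H[cmp, j]) / denom
    }
  }
  D
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via [ape::nj()]); negative branch lengths are
#' clamped to 0 with a message.  On additive distances NJ recovers the
#' generating tree exactly.
#'
#' @param dm symmetric distance matrix with labels; all entries defined.
#' @param clamp_negative clamp negative branch lengths to 0 (default TRUE).
#' @return an [ape] `phylo` tree.
#' @export
nj_tree <- function(dm, clamp_negative = TRUE) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) .stopf("NJ needs >= 3 labels")
  if (anyNA(dm)) .stopf("distance matrix has undefined entries")
  tr <- ape::nj(stats::as.dist(dm))
  if (clamp_negative && any(tr$edge.length < 0)) {
    .msg(sum(tr$edge.length < 0), " negative branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' NJ haplotype tree with bootstrap support
#'
#' Builds the p-distance NJ tree of a set of phased haplotypes over an
#' interval set and, optionally, attaches per-branch support from
#' bootstrapping the variant sites (the invariant denominator is kept
#' fixed).
#'
#' @inheritParams hap_distances
#' @param n_boot bootstrap replicates (0 = none).
#' @return a `phylo` tree; with bootstrap, node labels hold support counts
#'   out of `n_boot`.
#' @export
hap_tree <- function(gm, haps, intervals, n_boot = 0) {
  validate_intervals(intervals)
  total_bp <- interval_bp(intervals)
  keep <- logical(n_sites(gm))
  for (ct in unique(intervals$contig)) {
    sel <- gm$contig == ct
    keep[sel] <- IRanges::overlapsAny(
      IRanges::IRanges(gm$pos[sel] + 1L, gm$pos[sel] + 1L),
      .ir(intervals[intervals$contig == ct, , drop = FALSE]))
  }
  H <- hap_alleles(gm, unique(hap_sample(haps)))[keep, haps, drop = FALSE]
  tr <- nj_tree(.dist_from_hapmat(H, total_bp))
  if (n_boot > 0L) {
    boots <- lapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(H), nrow(H), replace = TRUE)
      nj_tree(.dist_from_hapmat(H[idx, , drop = FALSE], total_bp))
    })
    supp <- ape::prop.clades(tr, boots, rooted = FALSE)
    tr$node.label <- supp
  }
  tr
}

#' Molecular-clock parameters
#'
#' @param mu mutation rate per bp per generation (default 1.26e-8).
#' @param g generation interval in years (default 6).
#' @return list of class `clock_params`.
#' @export
clock_params <- function(mu = 1.26e-8, g = 6) {
  stopifnot(is.numeric(mu), mu > 0, is.numeric(g), g > 0)
  structure(list(mu = mu, g = g), class = "clock_params")
}

#' Date an admixture pulse from net tract-donor divergence
#'
#' Converts the mean divergence between introgressed recipient tracts and
#' the donor panel into a time, assuming divergence accrues at `2*mu` per
#' generation.  The ancestral-polymorphism correction is selectable:
#' `"ancestral"` (default) subtracts the full within-donor diversity — the
#' tract lineages were drawn from the donor gene pool, whose modern
#' within-panel diversity estimates the shared ancestral component of
#' `d_cross` — giving `d_net = d_cross - d_within_donor`; `"da"` is the
#' classical net-divergence correction
#' `d_cross - d_within_donor/2 - pi_tracts/2`; `"none"` uses `d_cross`
#' as-is.  `d_net` is floored at 0 (a warning reports tracts
#' indistinguishable from the donor).  With a per-interval table, a
#' bootstrap over intervals (resampled with replacement, bp-weighted)
#' yields a percentile confidence interval.
#'
#' @param d_cross mean recipient-tract-vs-donor distance (per bp).
#' @param d_within_donor mean donor-donor distance (per bp; default 0).
#' @param pi_tracts mean pairwise diversity among the recipient tract
#'   haplotypes (per bp; used by `correction = "da"`; default 0).
#' @param clock a [clock_params()].
#' @param correction one of `"ancestral"`, `"da"`, `"none"`.
#' @param per_interval optional data frame with one row per interval and
#'   columns `bp`, `d_cross`, and (as needed) `d_within_donor`, `pi_tracts`;
#'   used for the bootstrap CI.
#' @param n_boot bootstrap replicates (default 1000).
#' @param conf CI level (default 0.95).
#' @return list of class `clock_date`: `generations`, `years`, `d_net`,
#'   `correction`, and `ci_years` when a bootstrap was possible.
#' @export
clock_date <- function(d_cross, d_within_donor = 0, pi_tracts = 0,
                       clock = clock_params(),
                       correction = c("ancestral", "da", "none"),
                       per_interval = NULL, n_boot = 1000, conf = 0.95) {
  correction <- match.arg(correction)
  stopifnot(d_cross >= 0, d_within_donor >= 0, pi_tracts >= 0)
  net <- function(dc, dw, pt) switch(correction,
    ancestral = dc - dw,
    da = dc - dw / 2 - pt / 2,
    none = dc)
  d_net <- max(0, net(d_cross, d_within_donor, pi_tracts))
  if (d_net == 0 && d_cross > 0)
    warning("net divergence is 0: tracts indistinguishable from donor",
            call. = FALSE)
  gen <- d_net / (2 * clock$mu)
  out <- list(generations = gen, years = gen * clock$g, d_net = d_net,
              correction = correction, clock = clock)
  if (!is.null(per_interval) && nrow(per_interval) > 1L) {
    stopifnot(all(c("bp", "d_cross") %in% names(per_interval)))
    dw <- per_interval$d_within_donor %||% rep(0, nrow(per_interval))
    pt <- per_interval$pi_tracts %||% rep(0, nrow(per_interval))
    w <- per_interval$bp
    boots <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(nrow(per_interval), nrow(per_interval), replace = TRUE)
      dn <- max(0, net(stats::weighted.mean(per_interval$d_cross[i], w[i]),
                       stats::weighted.mean(dw[i], w[i]),
                       stats::weighted.mean(pt[i], w[i])))
      dn / (2 * clock$mu) * clock$g
    }, numeric(1L))
    a <- (1 - conf) / 2
    out$ci_years <- stats::quantile(boots, c(a, 1 - a), names = FALSE)
    out$conf <- conf
  }
  class(out) <- "clock_date"
  out
}

#' @export
print.clock_date <- function(x, ...) {
  cat(sprintf("admixture date: %.0f generations = %.0f years (d_net %.3g, %s correction)\n",
              x$generations, x$years, x$d_net, x$correction))
  if (!is.null(x$ci_years))
    cat(sprintf("  %d%% CI: %.0f - %.0f years\n", round(100 * x$conf),
                x$ci_years[1L], x$ci_years[2L]))
  invisible(x)
}

#' Date introgression from called segments
#'
#' For each segment (one carrier haplotype over one interval) computes the
#' mean distance to the donor haplotypes (`d_cross`), the mean donor-donor
#' distance over the same interval (`d_within_donor`) and, where other
#' carriers overlap, the mean pairwise diversity among carrier haplotypes
#' (`pi_tracts`); aggregates bp-weighted and dates the pulse with
#' [clock_date()], bootstrapping over segments.
#'
#' @param gm a [genotype_matrix()].
#' @param segments data frame with `contig`, `start`, `end`, `carrier`
#'   (haplotype ids) — called segments or known truth tracts.
#' @param donor character vector of donor sample ids.
#' @param trim_bp erode each segment by this many bp on both ends before
#'   measuring (default 0).  Window-quantised segment calls overhang the
#'   true tract by up to a window at each boundary, and even a fraction of
#'   a percent of non-tract bp — diverged from the donor at the species
#'   level — inflates the net divergence several-fold; trimming one window
#'   width removes that contamination.  Segments shorter than
#'   `2 * trim_bp` are dropped.
#' @inheritParams clock_date
#' @return a [clock_date()] result with the aggregated inputs attached.
#' @export
date_segments <- function(gm, segments, donor, clock = clock_params(),
                          correction = c("ancestral", "da", "none"),
                          trim_bp = 0, n_boot = 1000, conf = 0.95) {
  correction <- match.arg(correction)
  validate_intervals(segments)
  if (trim_bp > 0) {
    segments$start <- segments$start + trim_bp
    segments$end <- segments$end - trim_bp
    segments <- segments[segments$end > segments$start, , drop = FALSE]
  }
  if (nrow(segments) == 0L) .stopf("no segments to date")
  donor_haps <- hap_ids(donor)
  all_haps <- unique(c(segments$carrier, donor_haps))
  H <- hap_alleles(gm, unique(hap_sample(all_haps)))[, all_haps, drop = FALSE]
  dpairs <- which(upper.tri(diag(length(donor_haps))), arr.ind = TRUE)

  # mismatch proportion of two haplotype columns over sites idx / bp
  pdist <- function(i, j, idx, bp) {
    x <- H[idx, i]; y <- H[idx, j]
    cmp <- !is.na(x) & !is.na(y)
    denom <- bp - sum(!cmp)
    if (denom <= 0) NA_real_ else sum(x[cmp] != y[cmp]) / denom
  }
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, , drop = FALSE]
    idx <- which(gm$contig == seg$contig)
    idx <- idx[.pos_in_window(gm$pos[idx], seg$start, seg$end)]
    bp <- seg$end - seg$start
    d_cross <- mean(vapply(donor_haps, pdist, numeric(1L),
                           i = seg$carrier, idx = idx, bp = bp), na.rm = TRUE)
    d_within <- mean(vapply(seq_len(nrow(dpairs)), function(k)
      pdist(donor_haps[dpairs[k, 1L]], donor_haps[dpairs[k, 2L]], idx, bp),
      numeric(1L)), na.rm = TRUE)
    # tract-tract diversity only over the parts where other carriers'
    # segments actually overlap this one
    over <- which(segments$contig == seg$contig &
                    segments$carrier != seg$carrier &
                    segments$start < seg$end & segments$end > seg$start)
    pt <- NA_real_
    if (length(over)) {
      pt <- mean(vapply(over, function(jj) {
        s <- max(seg$start, segments$start[jj])
        e <- min(seg$end, segments$end[jj])
        jidx <- idx[gm$pos[idx] >= s & gm$pos[idx] < e]
        pdist(seg$carrier, segments$carrier[jj], jidx, e - s)
      }, numeric(1L)), na.rm = TRUE)
    }
    data.frame(bp = bp, d_cross = d_cross, d_within_donor = d_within,
               pi_tracts = pt)
  })
  per_interval <- do.call(rbind, rows)
  ok <- !is.na(per_interval$d_cross) & !is.na(per_interval$d_within_donor)
  per_interval <- per_interval[ok, , drop = FALSE]
  pt_all <- per_interval$pi_tracts
  pt_mean <- if (all(is.na(pt_all))) 0 else
    stats::weighted.mean(pt_all, per_interval$bp, na.rm = TRUE)
  per_interval$pi_tracts[is.na(per_interval$pi_tracts)] <- pt_mean
  out <- clock_date(
    stats::weighted.mean(per_interval$d_cross, per_interval$bp),
    stats::weighted.mean(per_interval$d_within_donor, per_interval$bp),
    pt_mean, clock = clock, correction = correction,
    per_interval = per_interval, n_boot = n_boot, conf = conf)
  out$per_interval <- per_interval
  out
}

#' Cross-coalescence-rate curve
#'
#' @param time numeric vector of time points, strictly increasing from the
#'   present into the past (generations unless you supply years).
#' @param ccr relative cross-coalescence rate at each time point.
#' @return data frame of class `ccr_curve`.
#' @export
ccr_curve <- function(time, ccr) {
  stopifnot(length(time) == length(ccr), length(time) >= 2L,
            !is.unsorted(time, strictly = TRUE))
  structure(data.frame(time = time, ccr = ccr), class = c("ccr_curve", "data.frame"))
}

#' Read a cross-coalescence curve from TSV
#' @param path two-column TSV (time, rate), with or without header.
#' @export
read_ccr <- function(path) {
  first <- readLines(path, n = 1L)
  header <- !grepl("^[0-9.eE+-]+\\s", first)
  d <- utils::read.table(path, sep = "\t", header = header)
  ccr_curve(d[[1L]], d[[2L]])
}

#' Threshold crossing time of a cross-coalescence curve
#'
#' Scans from the present into the past and returns the first time the
#' curve crosses the threshold, locating it by linear interpolation between
#' the bracketing points.  The first raw grid point at or beyond the
#' threshold is reported alongside.  Thresholds 0.25 and 0.75 around the
#' conventional 0.5 point give a divergence-time range.
#'
#' @param curve a [ccr_curve()].
#' @param threshold crossing level (default 0.5).
#' @param clock optional [clock_params()]; when given, times are taken as
#'   generations and also returned in years.
#' @return list: `time` (interpolated), `raw_time` (first grid point past
#'   the threshold), `status` (`"ok"` or `"no_crossing"`), and `years` /
#'   `raw_years` when a clock is given.
#' @export
ccr_crossing <- function(curve, threshold = 0.5, clock = NULL) {
  v <- curve$ccr - threshold
  out <- list(time = NA_real_, raw_time = NA_real_, status = "no_crossing")
  hit <- which(v == 0)
  brk <- which(v[-length(v)] * v[-1L] < 0)
  if (length(hit) && (!length(brk) || hit[1L] <= brk[1L])) {
    out$time <- curve$time[hit[1L]]
    out$raw_time <- curve$time[hit[1L]]
    out$status <- "ok"
  } else if (length(brk)) {
    i <- brk[1L]
    out$time <- curve$time[i] +
      (threshold - curve$ccr[i]) / (curve$ccr[i + 1L] - curve$ccr[i]) *
      (curve$time[i + 1L] - curve$time[i])
    out$raw_time <- curve$time[i + 1L]
    out$status <- "ok"
  }
  if (!is.null(clock) && out$status == "ok") {
    out$years <- out$time * clock$g
    out$raw_years <- out$raw_time * clock$g
  }
  out
}
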