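#' Tile contigs into (sliding) windows
#'
#' With `step = size` the windows partition each contig; with `step < size`
#' they slide and overlap.  The final window of a contig is truncated at the
#' contig end and flagged `partial` rather than dropped, so terminal
#' statistics are length-normalised instead of lost.
#'
#' @param contig_lengths named numeric vector of contig lengths (bp).
#' @param size window size in bp (default 5000).
#' @param step step between window starts, `0 < step <= size`
#'   (default `size`).
#' @return data frame of windows: `contig`, `start`, `end` (0-based
#'   half-open), `partial`.
#' @export
make_windows <- function(contig_lengths, size = 5000, step = size) {
  stopifnot(size > 0, step > 0)
  if (step > size) .stopf("step (%g) must not exceed window size (%g)", step, size)
  out <- lapply(names(contig_lengths), function(ct) {
    len <- contig_lengths[[ct]]
    starts <- seq(0, max(len - 1, 0), by = step)
    ends <- pmin(starts + size, len)
    data.frame(contig = ct, start = starts, end = ends,
               partial = ends - starts < size, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# indices of sorted positions falling in [start, end)
.pos_in_window <- function(pos, start, end) {
  if (length(pos) == 0L) return(integer())
  i1 <- findInterval(start - 0.5, pos) + 1L
  i2 <- findInterval(end - 0.5, pos)
  if (i2 < i1) integer() else i1:i2
}

# per-site frequency of the diagnostic allele among a set of samples
.diag_site_freq <- function(gm, das, samples) {
  idx <- match(paste(das$contig, das$pos), paste(gm$contig, gm$pos))
  if (anyNA(idx)) .stopf("%d diagnostic site(s) not present in the callset",
                         sum(is.na(idx)))
  dos <- dosages(gm)[idx, samples, drop = FALSE]
  ac <- rowSums(dos, na.rm = TRUE)
  an <- 2L * rowSums(!is.na(dos))
  f_alt <- ifelse(an > 0L, ac / an, NA_real_)
  list(idx = idx, freq = ifelse(das$allele == "alt", f_alt, 1 - f_alt))
}

# per-haplotype indicator of carrying the diagnostic allele (sites x haps)
.diag_hap_carry <- function(gm, das, samples) {
  idx <- match(paste(das$contig, das$pos), paste(gm$contig, gm$pos))
  if (anyNA(idx)) .stopf("%d diagnostic site(s) not present in the callset",
                         sum(is.na(idx)))
  H <- hap_alleles(gm, samples)[idx, , drop = FALSE]
  want <- ifelse(das$allele == "alt", 1L, 0L)
  carry <- H == want
  storage.mode(carry) <- "double"
  carry
}

#' Sliding-window diagnostic-allele scan
#'
#' For each window, averages the diagnostic-allele frequency in the recipient
#' target over the diagnostic sites the window contains.  In `sample` mode
#' the target is the recipient panel (frequency over observed allele copies);
#' in `haplotype` mode each recipient haplotype is scanned separately and the
#' per-site value is the 0/1 indicator of carrying the diagnostic allele,
#' so the window mean is the fraction of diagnostic sites carried.  Windows
#' with no informative site are reported with `n_sites = 0` and `NA` mean,
#' never dropped.  A second, contrasting allele set (e.g. recipient-lineage
#' diagnostic alleles) can be supplied as `control_das`.
#'
#' @param gm a [genotype_matrix()].
#' @param das a `diagnostic_alleles` data frame (see
#'   [find_diagnostic_alleles()]).
#' @param recipient character vector of recipient sample ids.
#' @param windows data frame from [make_windows()].
#' @param mode `"haplotype"` (requires phase) or `"sample"`.
#' @param control_das optional second `diagnostic_alleles` set.
#' @return data frame with one row per window (`sample` mode) or per window
#'   and haplotype (`haplotype` mode): `contig`, `start`, `end`, `carrier`,
#'   `n_sites`, `mean_freq`, and `n_control`/`mean_control_freq` when
#'   `control_das` is given.  Class `window_scan`.
#' @export
window_scan <- function(gm, das, recipient, windows,
                        mode = c("haplotype", "sample"), control_das = NULL) {
  mode <- match.arg(mode)
  if (nrow(das) == 0L) .stopf("empty diagnostic-allele set")
  validate_intervals(windows)

  scan_one <- function(d) {
    # values: sites x carriers matrix of per-site values on d's sites
    if (mode == "sample") {
      sf <- .diag_site_freq(gm, d, recipient)
      vals <- matrix(sf$freq, ncol = 1L,
                     dimnames = list(NULL, "recipient"))
      gpos <- gm$pos[sf$idx]; gct <- gm$contig[sf$idx]
    } else {
      vals <- .diag_hap_carry(gm, d, recipient)
      idx <- match(paste(d$contig, d$pos), paste(gm$contig, gm$pos))
      gpos <- gm$pos[idx]; gct <- gm$contig[idx]
    }
    res_n <- matrix(0L, nrow = nrow(windows), ncol = ncol(vals))
    res_m <- matrix(NA_real_, nrow = nrow(windows), ncol = ncol(vals))
    for (ct in unique(windows$contig)) {
      wsel <- which(windows$contig == ct)
      ssel <- which(gct == ct)
      p <- gpos[ssel]
      for (w in wsel) {
        j <- .pos_in_window(p, windows$start[w], windows$end[w])
        if (length(j) == 0L) next
        v <- vals[ssel[j], , drop = FALSE]
        res_n[w, ] <- colSums(!is.na(v))
        res_m[w, ] <- ifelse(res_n[w, ] > 0L, colMeans(v, na.rm = TRUE), NA_real_)
      }
    }
    list(n = res_n, m = res_m, carriers = colnames(vals))
  }

  main <- scan_one(das)
  k <- length(main$carriers)
  out <- data.frame(
    contig = rep(windows$contig, k), start = rep(windows$start, k),
    end = rep(windows$end, k),
    carrier = rep(main$carriers, each = nrow(windows)),
    n_sites = as.vector(main$n), mean_freq = as.vector(main$m),
    stringsAsFactors = FALSE)
  if (!is.null(control_das) && nrow(control_das) > 0L) {
    ctl <- scan_one(control_das)
    out$n_control <- as.vector(ctl$n)
    out$mean_control_freq <- as.vector(ctl$m)
  }
  class(out) <- c("window_scan", class(out))
  out
}

#' Windowed nucleotide diversity
#'
#' Computes pi per window for one panel as
#' `sum_sites 2*p*(1-p) * n/(n-1) / L`, where `p` is the observed
#' alt-allele frequency, `n` the number of observed allele copies at the
#' site (sites with `n < 2` are skipped) and `L` the window's callable
#' length (the window length when no mask is given).  Equivalent to the
#' average pairwise difference per callable bp.
#'
#' @param gm a [genotype_matrix()].
#' @param panel character vector of sample ids.
#' @param windows data frame from [make_windows()].
#' @param mask optional [callable_mask()]; fully masked windows get `NA`.
#' @return the `windows` data frame with `n_sites`, `callable` and `pi`
#'   columns added.
#' @export
window_pi <- function(gm, panel, windows, mask = NULL) {
  validate_intervals(windows)
  dos <- dosages(gm)[, panel, drop = FALSE]
  ac <- rowSums(dos, na.rm = TRUE)
  an <- 2L * rowSums(!is.na(dos))
  p <- ifelse(an > 0L, ac / an, NA_real_)
  term <- ifelse(an >= 2L, 2 * p * (1 - p) * an / (an - 1L), NA_real_)
  out <- windows
  out$n_sites <- 0L
  out$callable <- out$end - out$start
  out$pi <- NA_real_
  for (ct in unique(windows$contig)) {
    wsel <- which(windows$contig == ct)
    ssel <- which(gm$contig == ct)
    pp <- gm$pos[ssel]
    msk <- if (is.null(mask)) NULL else mask[mask$contig == ct, , drop = FALSE]
    for (w in wsel) {
      if (!is.null(msk)) {
        ir <- IRanges::restrict(.ir(msk), start = windows$start[w] + 1L,
                                end = windows$end[w])
        out$callable[w] <- sum(IRanges::width(ir))
      }
      if (out$callable[w] <= 0) { out$callable[w] <- 0; next }
      j <- .pos_in_window(pp, windows$start[w], windows$end[w])
      if (!is.null(msk) && length(j)) {
        inmask <- IRanges::overlapsAny(
          IRanges::IRanges(pp[j] + 1L, pp[j] + 1L), .ir(msk))
        j <- j[inmask]
      }
      t <- term[ssel[j]]
      t <- t[!is.na(t)]
      out$n_sites[w] <- length(t)
      out$pi[w] <- sum(t) / out$callable[w]
    }
  }
  out
}

#' Call introgressed segments from a window scan
#'
#' Deterministic run-length caller over tiling windows: a window qualifies
#' when its mean diagnostic-allele frequency is defined and
#' `>= freq_threshold` with at least `min_support_sites` informative sites.
#' Runs of qualifying windows, in which up to `max_merge_gap_windows`
#' consecutive non-qualifying (failing or empty) windows are bridged, are
#' reported as merged half-open segments when they contain at least
#' `min_consecutive_windows` qualifying windows.
#'
#' @param ws a `window_scan` data frame (tiling windows, `step = size`).
#' @param freq_threshold window qualification threshold; 0.5 by default
#'   (a haplotype either carries the donor tract or it does not).
#' @param min_support_sites minimum informative sites per qualifying window.
#' @param min_consecutive_windows minimum qualifying windows per segment.
#' @param max_merge_gap_windows maximum run of non-qualifying windows
#'   bridged inside a segment.
#' @return data frame of class `introgressed_segments`: `contig`, `start`,
#'   `end`, `carrier`, `n_windows`, `support` (sum of informative sites over
#'   qualifying windows), `mean_freq` (site-weighted over qualifying
#'   windows).
#' @export
call_segments <- function(ws, freq_threshold = 0.5, min_support_sites = 2,
                          min_consecutive_windows = 2,
                          max_merge_gap_windows = 1) {
  stopifnot(.is_prob(freq_threshold), .is_count(min_support_sites),
            .is_count(min_consecutive_windows), min_consecutive_windows >= 1,
            .is_count(max_merge_gap_windows))
  pieces <- list()
  for (key in unique(paste(ws$carrier, ws$contig, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    d <- ws[ws$carrier == parts[1L] & ws$contig == parts[2L], , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    q <- !is.na(d$mean_freq) & d$mean_freq >= freq_threshold &
      d$n_sites >= min_support_sites
    qi <- which(q)
    if (length(qi) == 0L) next
    grp <- cumsum(c(1L, diff(qi) - 1L > max_merge_gap_windows))
    for (g in split(qi, grp)) {
      if (length(g) < min_consecutive_windows) next
      sel <- d[g, , drop = FALSE]
      pieces[[length(pieces) + 1L]] <- data.frame(
        contig = parts[2L], start = d$start[g[1L]], end = d$end[g[length(g)]],
        carrier = parts[1L], n_windows = length(g),
        support = sum(sel$n_sites),
        mean_freq = sum(sel$mean_freq * sel$n_sites) / sum(sel$n_sites),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, pieces) %||%
    data.frame(contig = character(), start = numeric(), end = numeric(),
               carrier = character(), n_windows = integer(),
               support = numeric(), mean_freq = numeric())
  out <- .sort_intervals(out)
  rownames(out) <- NULL
  class(out) <- c("introgressed_segments", class(out))
  out
}

#' Intervals shared by a minimum number of carriers
#'
#' Sweeps over segment endpoints and returns the sorted, non-overlapping
#' genomic intervals covered by segments of at least `min_carriers` distinct
#' carriers (each carrier counts once per bp).
#'
#' @param segments data frame with `contig`, `start`, `end`, `carrier`.
#' @param min_carriers minimum number of distinct carriers (default 2).
#' @return data frame of intervals with a `carriers`-at-minimum guarantee.
#' @export
shared_filter <- function(segments, min_carriers = 2) {
  stopifnot(.is_count(min_carriers), min_carriers >= 1)
  validate_intervals(segments)
  if (nrow(segments) == 0L)
    return(data.frame(contig = character(), start = numeric(),
                      end = numeric()))
  out <- .per_contig(segments, function(d) {
    wid <- max(d$end)
    per_carrier <- lapply(split(d, d$carrier), function(x)
      IRanges::reduce(.ir(x)))
    cov <- Reduce(`+`, lapply(per_carrier, IRanges::coverage, width = wid))
    sl <- IRanges::slice(cov, lower = min_carriers, rangesOnly = TRUE)
    .from_ir(sl, d$contig[1L])
  })
  out <- .sort_intervals(out)
  rownames(out) <- NULL
  out
}

#' Per-genome introgressed fraction
#'
#' Clips segments to the callable mask and reports, per genome, the
#' fraction of callable sequence covered by introgressed segments.  In
#' haplotype mode a genome's numerator is the summed segment bp of its two
#' haplotypes divided by 2 (diploid normalisation); in sample mode it is the
#' segment bp of the sample.  The group summary gives mean and standard
#' error (sd/sqrt(n), n-1 denominator) over genomes.
#'
#' @param segments an `introgressed_segments` data frame (carriers are
#'   haplotype ids `<sample>.<1|2>` in haplotype mode, sample ids otherwise).
#' @param callable a [callable_mask()].
#' @param samples character vector of all genomes to report (genomes with no
#'   segments get fraction 0).
#' @param mode `"haplotype"` or `"sample"`, matching the segment carriers.
#' @return list with `per_genome` (data frame: sample, bp, fraction),
#'   `mean`, `se` and `callable_bp`.
#' @export
genome_fraction <- function(segments, callable, samples,
                            mode = c("haplotype", "sample")) {
  mode <- match.arg(mode)
  total <- interval_bp(callable)
  if (total <= 0) .stopf("callable mask has zero length")
  bp <- stats::setNames(numeric(length(samples)), samples)
  if (nrow(segments)) {
    segs <- clip_intervals(segments, callable)
    for (carrier in unique(segs$carrier)) {
      smp <- if (mode == "haplotype") hap_sample(carrier) else carrier
      if (!smp %in% samples)
        .stopf("segment carrier '%s' not among the reported samples", carrier)
      d <- segs[segs$carrier == carrier, , drop = FALSE]
      bp[smp] <- bp[smp] + interval_bp(d)  # haplotypes don't self-overlap
    }
  }
  denom <- if (mode == "haplotype") 2 * total else total
  frac <- bp / denom
  per_genome <- data.frame(sample = samples, bp = as.numeric(bp),
                           fraction = as.numeric(frac), row.names = NULL)
  se <- if (length(samples) > 1L) stats::sd(frac) / sqrt(length(samples)) else 0
  list(per_genome = per_genome, mean = mean(frac), se = se,
       callable_bp = total)
}

#' Plot a window scan
#'
#' Dot plot of per-window mean donor-diagnostic allele frequency (and the
#' control frequency, when present) along one contig.
#'
#' @param ws a `window_scan` data frame.
#' @param carrier which carrier to plot (default: the first).
#' @param ... passed to [graphics::plot()].
#' @export
plot_window_scan <- function(ws, carrier = ws$carrier[1L], ...) {
  d <- ws[ws$carrier == carrier, , drop = FALSE]
  mid <- (d$start + d$end) / 2
  graphics::plot(mid, d$mean_freq, pch = 16, cex = 0.4, col = "blue4",
                 ylim = c(0, 1), xlab = paste0(d$contig[1L], " position (bp)"),
                 ylab = "mean allele frequency", ...)
  if ("mean_control_freq" %in% names(d))
    graphics::points(mid, d$mean_control_freq, pch = 16, cex = 0.4,
                     col = "firebrick")
  invisible(d)
}
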