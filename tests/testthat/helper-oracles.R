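# Fixture builders and independent brute-force oracles used across tests.

# random genotype matrix on one contig
rand_gm <- function(n_sites = 50, n_samples = 6, miss = 0.1, phased = TRUE,
                    contig_len = 1e5, contig = "chr1") {
  pos <- sort(sample.int(contig_len, n_sites)) - 1L
  a1 <- matrix(sample(0:1, n_sites * n_samples, replace = TRUE), n_sites)
  a2 <- matrix(sample(0:1, n_sites * n_samples, replace = TRUE), n_sites)
  if (miss > 0) {
    m <- matrix(runif(n_sites * n_samples) < miss, n_sites)
    a1[m] <- NA_integer_; a2[m] <- NA_integer_
  }
  storage.mode(a1) <- storage.mode(a2) <- "integer"
  ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  genotype_matrix(rep(contig, n_sites), pos, ref, alt, a1, a2,
                  matrix(phased, n_sites, n_samples),
                  paste0("S", seq_len(n_samples)),
                  stats::setNames(contig_len, contig))
}

# site-by-site reimplementation of the diagnostic-allele rule
oracle_diag <- function(gm, panels, min_donor_carriers = 1,
                        max_exclusion_freq = 0, max_missing_per_panel = 1) {
  dos <- dosages(gm)
  ex <- grep("^exclusion_", names(panels), value = TRUE)
  hits <- list()
  for (s in seq_len(n_sites(gm))) {
    dd <- dos[s, panels$donor]
    panel_freq <- function(ids, allele) {
      d <- dos[s, ids]
      an <- 2 * sum(!is.na(d))
      if (an == 0) return(NA_real_)
      ac <- sum(d, na.rm = TRUE)
      if (allele == "alt") ac / an else 1 - ac / an
    }
    if (mean(is.na(dd)) > max_missing_per_panel) next
    skip <- FALSE
    for (e in ex) {
      de <- dos[s, panels[[e]]]
      if (mean(is.na(de)) > max_missing_per_panel || all(is.na(de))) skip <- TRUE
    }
    if (skip || all(is.na(dd))) next
    for (allele in c("alt", "ref")) {
      car <- if (allele == "alt") sum(dd >= 1, na.rm = TRUE) else
        sum(dd <= 1, na.rm = TRUE)
      if (car < min_donor_carriers) next
      ok <- TRUE
      for (e in ex)
        if (!(panel_freq(panels[[e]], allele) <= max_exclusion_freq)) ok <- FALSE
      if (ok) hits[[length(hits) + 1L]] <-
          data.frame(site = s, allele = allele, carriers = car)
    }
  }
  do.call(rbind, hits)
}

# direct set-algebra Venn over per-panel presence sets
oracle_venn <- function(gm, panels) {
  dos <- dosages(gm)
  pres <- lapply(panels, function(ids)
    which(rowSums(dos[, ids, drop = FALSE], na.rm = TRUE) >= 1))
  sites <- sort(unique(unlist(pres)))
  pat <- vapply(sites, function(s)
    paste(vapply(pres, function(p) s %in% p, logical(1L)), collapse = ","), "")
  table(pat)
}

# per-window recomputation from scratch
oracle_window_scan <- function(values, vpos, windows) {
  t(vapply(seq_len(nrow(windows)), function(w) {
    sel <- vpos >= windows$start[w] & vpos < windows$end[w]
    v <- values[sel]
    v <- v[!is.na(v)]
    c(n = length(v), m = if (length(v)) mean(v) else NA_real_)
  }, c(n = 0, m = 0)))
}

# exhaustive pair scanner over a qualify vector: a window is covered by a
# segment iff it lies between two qualifying windows whose stretch contains
# >= min_consec qualifying windows and no internal gap > max_gap
oracle_runs <- function(q, min_consec, max_gap) {
  n <- length(q)
  covered <- rep(FALSE, n)
  for (i in which(q)) for (j in which(q)) {
    if (j < i) next
    seg <- q[i:j]
    r <- rle(seg)
    gap <- max(c(0L, r$lengths[!r$values]))
    if (gap > max_gap || sum(seg) < min_consec) next
    covered[i:j] <- TRUE
  }
  covered
}

# per-bp coverage counting for shared intervals (small coordinates only)
oracle_shared <- function(segments, min_carriers, len) {
  cov <- integer(len)
  for (h in unique(segments$carrier)) {
    hit <- rep(FALSE, len)
    d <- segments[segments$carrier == h, , drop = FALSE]
    for (i in seq_len(nrow(d)))
      hit[(d$start[i] + 1L):d$end[i]] <- TRUE
    cov <- cov + hit
  }
  which(cov >= min_carriers) - 1L  # 0-based covered bp
}

# bp set covered by intervals (0-based)
bp_set <- function(x) {
  if (nrow(x) == 0L) return(integer())
  unlist(lapply(seq_len(nrow(x)), function(i) seq(x$start[i], x$end[i] - 1L)))
}

# naive leave-one-out weighted jackknife, transcribed independently
oracle_jackknife_se <- function(num, den, w) {
  g <- length(num)
  theta <- sum(num) / sum(den)
  loo <- vapply(seq_len(g), function(j) sum(num[-j]) / sum(den[-j]), 0)
  n <- sum(w)
  hj <- n / w
  theta_J <- g * theta - sum((1 - w / n) * loo)
  ps <- hj * theta - (hj - 1) * loo
  sqrt(mean((ps - theta_J)^2 / (hj - 1)))
}

# pairwise-difference average oracle for pi
oracle_pi <- function(hapmat, L) {
  k <- ncol(hapmat)
  tot <- 0; np <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    cmp <- !is.na(hapmat[, i]) & !is.na(hapmat[, j])
    tot <- tot + sum(hapmat[cmp, i] != hapmat[cmp, j])
    np <- np + 1
  }
  tot / np / L
}

# direct per-site haplotype distance loop
oracle_hapdist <- function(H, bp) {
  k <- ncol(H)
  D <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    mm <- 0; inc <- 0
    for (s in seq_len(nrow(H))) {
      if (is.na(H[s, i]) || is.na(H[s, j])) inc <- inc + 1
      else if (H[s, i] != H[s, j]) mm <- mm + 1
    }
    D[i, j] <- mm / (bp - inc)
  }
  D
}
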