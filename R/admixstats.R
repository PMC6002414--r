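#' Per-site allele frequencies for a set of panels
#'
#' Frequencies refer to the ALT allele throughout, computed from observed
#' allele copies only (no imputation); `p` is NA where a panel has no
#' observed copies at a site.
#'
#' @param gm a [genotype_matrix()].
#' @param panels named list mapping role names to sample-id vectors.
#' @return list with matrices `p` (frequency) and `n` (observed copies),
#'   one column per role, plus `contig` and `pos` vectors.
#' @export
site_freqs <- function(gm, panels) {
  p <- matrix(NA_real_, n_sites(gm), length(panels),
              dimnames = list(NULL, names(panels)))
  n <- matrix(0L, n_sites(gm), length(panels),
              dimnames = list(NULL, names(panels)))
  for (j in seq_along(panels)) {
    cnt <- .panel_counts(gm, panels[[j]])
    n[, j] <- cnt$an
    p[, j] <- ifelse(cnt$an > 0L, cnt$ac / cnt$an, NA_real_)
  }
  list(p = p, n = n, contig = gm$contig, pos = gm$pos)
}

#' Assign sites to contiguous physical blocks
#'
#' Blocks are `block_size_bp` tiles of each contig; no block spans contigs.
#' Returned ids are consecutive integers in genome order.
#'
#' @param contig,pos site coordinates (sorted, 0-based).
#' @param block_size_bp block size in bp (default 5 Mb).
#' @return integer vector of block ids (1-based).
#' @export
assign_blocks <- function(contig, pos, block_size_bp = 5e6) {
  stopifnot(block_size_bp > 0)
  key <- paste(contig, floor(pos / block_size_bp), sep = "\r")
  match(key, unique(key))
}

#' Weighted delete-one-block jackknife
#'
#' Combines per-block numerators and denominators of a ratio statistic
#' `sum(num)/sum(den)` and computes the weighted jackknife standard error
#' (Busing-type formula) over leave-one-block-out estimates, with block
#' weights defaulting to the denominators (site counts for mean-type
#' statistics).
#'
#' @param num,den numeric vectors of per-block numerator and denominator
#'   sums.
#' @param weights per-block weights (default `den`).
#' @return object of class `jackknife_stat`: `estimate`, `se`, `z`,
#'   `n_blocks`, `weights`.  When all leave-one-out estimates agree the SE
#'   is 0 and `z` is reported as signed infinity with a warning.
#' @export
block_jackknife <- function(num, den, weights = NULL) {
  stopifnot(length(num) == length(den))
  weights <- weights %||% den
  keep <- weights > 0 & den != 0
  num <- num[keep]; den <- den[keep]; weights <- weights[keep]
  g <- length(num)
  if (g < 2L) .stopf("block jackknife needs >= 2 blocks with data")
  tot_n <- sum(num); tot_d <- sum(den); n <- sum(weights)
  est <- tot_n / tot_d
  loo <- (tot_n - num) / (tot_d - den)
  h <- n / weights
  # weighted jackknife (Busing et al. 1999)
  theta_dot <- g * est - sum((1 - weights / n) * loo)
  tau <- h * est - (h - 1) * loo
  var_j <- sum((tau - theta_dot)^2 / (h - 1)) / g
  se <- sqrt(var_j)
  if (se == 0) {
    warning("jackknife SE is 0; Z reported as signed infinity", call. = FALSE)
    z <- sign(est) * Inf
    if (est == 0) z <- NaN
  } else z <- est / se
  structure(list(estimate = est, se = se, z = z, n_blocks = g,
                 weights = weights), class = "jackknife_stat")
}

#' @export
print.jackknife_stat <- function(x, ...) {
  cat(sprintf("estimate %.6g  SE %.3g  Z %.2f  (%d blocks)\n",
              x$estimate, x$se, x$z, x$n_blocks))
  invisible(x)
}

# shared site bookkeeping for f3/D: frequencies, block ids, site skipping
.freq_blocks <- function(gm, panels, roles, block_size_bp) {
  use <- panels[roles]
  if (any(vapply(use, is.null, logical(1L))))
    .stopf("missing panel role(s): %s",
           paste(roles[vapply(use, is.null, logical(1L))], collapse = ", "))
  sf <- site_freqs(gm, use)
  ok <- rowSums(is.na(sf$p)) == 0L
  n_skip <- sum(!ok)
  if (n_skip) .msg(n_skip, " site(s) skipped (a required panel entirely missing)")
  blk <- assign_blocks(sf$contig, sf$pos, block_size_bp)
  list(p = sf$p[ok, , drop = FALSE], n = sf$n[ok, , drop = FALSE],
       blk = blk[ok], n_used = sum(ok), n_skipped = n_skip)
}

#' f3 admixture statistic
#'
#' `f3(C; A, B) = mean over sites of (c-a)(c-b)`, with an optional
#' finite-sample correction `c(1-c)/(n_C - 1)` subtracted per site
#' (heterozygosity bias of the target's sample frequency).  A significantly
#' negative f3 indicates that the target C is admixed between populations
#' related to A and B.  Standard errors come from the weighted
#' delete-one-block jackknife over physical blocks.
#'
#' @param gm a [genotype_matrix()].
#' @param panels named list of sample-id vectors.
#' @param target,source_a,source_b role names in `panels`.
#' @param block_size_bp jackknife block size (default 5 Mb).
#' @param bias_correct subtract the target heterozygosity correction
#'   (default TRUE; sites where the target has fewer than 2 observed copies
#'   are then skipped).
#' @return a [block_jackknife()] result with `n_sites` added.
#' @export
f3_stat <- function(gm, panels, target, source_a, source_b,
                    block_size_bp = 5e6, bias_correct = TRUE) {
  fb <- .freq_blocks(gm, panels, c(target, source_a, source_b), block_size_bp)
  cc <- fb$p[, 1L]; a <- fb$p[, 2L]; b <- fb$p[, 3L]
  nc <- fb$n[, 1L]
  term <- (cc - a) * (cc - b)
  if (bias_correct) {
    ok <- nc >= 2L
    term <- (term - cc * (1 - cc) / (nc - 1))[ok]
    blk <- fb$blk[ok]
  } else blk <- fb$blk
  num <- tapply(term, blk, sum)
  den <- tapply(rep(1, length(term)), blk, sum)
  out <- block_jackknife(as.numeric(num), as.numeric(den))
  out$n_sites <- length(term)
  out$statistic <- sprintf("f3(%s; %s, %s)", target, source_a, source_b)
  out
}

#' Outgroup-f3 shared-drift statistic
#'
#' `f3(O; A, X)` with the outgroup as target and no bias correction:
#' measures shared drift between A and X since their common ancestor with O
#' and is used for ranking affinity, not for hypothesis tests.
#'
#' @inheritParams f3_stat
#' @param outgroup,pop_a,pop_x role names in `panels`.
#' @return a [block_jackknife()] result with `n_sites` added.
#' @export
outgroup_f3 <- function(gm, panels, outgroup, pop_a, pop_x,
                        block_size_bp = 5e6) {
  f3_stat(gm, panels, target = outgroup, source_a = pop_a, source_b = pop_x,
          block_size_bp = block_size_bp, bias_correct = FALSE)
}

#' ABBA-BABA D statistic
#'
#' For the topology (((P1, P2), P3), O),
#' `D = sum(ABBA - BABA) / sum(ABBA + BABA)` with
#' `ABBA = (1-p1) p2 p3 (1-pO)` and `BABA = p1 (1-p2) p3 (1-pO)`, where the
#' per-site terms are symmetrised over the arbitrary choice of which allele
#' the frequencies refer to (each site contributes the average of the term
#' computed with `p` and with `1-p`).  The symmetrised numerator and
#' denominator reduce to `(p2-p1)(p3-pO)` and
#' `(p1+p2-2 p1 p2)(p3+pO-2 p3 pO)`, so no ancestral polarisation is
#' needed and the statistic is invariant under a global allele relabeling;
#' with a polarising outgroup (`pO = 0`) it coincides term-by-term with the
#' plain ABBA/BABA counts.  D > 0 indicates excess allele sharing between
#' P2 and P3.  SE and Z come from the weighted block jackknife with
#' per-block site counts as weights.
#'
#' @inheritParams f3_stat
#' @param p1,p2,p3,outgroup role names in `panels`.
#' @return a [block_jackknife()] result with `n_sites` and `status`
#'   (`"ok"` or `"undefined"` when the overall denominator is 0) added.
#' @export
d_stat <- function(gm, panels, p1, p2, p3, outgroup, block_size_bp = 5e6) {
  fb <- .freq_blocks(gm, panels, c(p1, p2, p3, outgroup), block_size_bp)
  q1 <- fb$p[, 1L]; q2 <- fb$p[, 2L]; q3 <- fb$p[, 3L]; qo <- fb$p[, 4L]
  # allele-labeling-symmetrised ABBA/BABA terms (halves of the classical
  # (p2-p1)(p3-pO) numerator and heterozygosity-product denominator)
  num_site <- (q2 - q1) * (q3 - qo)
  den_site <- (q1 + q2 - 2 * q1 * q2) * (q3 + qo - 2 * q3 * qo)
  abba <- (den_site + num_site) / 2
  baba <- (den_site - num_site) / 2
  if (sum(abba + baba) == 0) {
    out <- structure(list(estimate = NA_real_, se = NA_real_, z = NA_real_,
                          n_blocks = 0L, weights = numeric()),
                     class = "jackknife_stat")
    out$status <- "undefined"
    out$n_sites <- fb$n_used
    return(out)
  }
  num <- as.numeric(tapply(abba - baba, fb$blk, sum))
  den <- as.numeric(tapply(abba + baba, fb$blk, sum))
  cnt <- as.numeric(tapply(rep(1, length(abba)), fb$blk, sum))
  out <- block_jackknife(num, den, weights = cnt)
  out$n_sites <- fb$n_used
  out$status <- "ok"
  out$statistic <- sprintf("D(%s, %s; %s, %s)", p1, p2, p3, outgroup)
  out
}
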