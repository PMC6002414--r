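#' Parameters of the synthetic introgression scenario
#'
#' The generator emulates the history the scan machinery targets: an
#' outgroup (buffalo analogue), a donor species (banteng/yak analogue) that
#' split from the cattle ancestor long before domestication, one taurine-like
#' exclusion panel, a pair of sister recipient-side populations
#' (Indian-indicine-like `exclusion_2` and the recipient), and a recent
#' admixture pulse placing donor tracts of exponential length into a
#' fraction `f` of recipient haplotypes.  Split times default to the
#' cattle-like history on a 6-year generation: outgroup 5e5 gen (~3 Mya),
#' donor 2.5e5 gen (~1.5 Mya), taurine-indicine 5e4 gen (~300 kya), sister
#' indicine split 7.5e3 gen (~45 kya), pulse 500 gen (~3 kya).
#'
#' Sequence variation is built from layers: per-branch fixed substitutions
#' (Poisson with rate mu x branch length x bp), stationary within-population
#' polymorphism, and shared ancestral polymorphism whose per-population
#' frequencies drift apart (Beta around a common ancestral frequency) —
#' the source of incomplete lineage sorting.  Donor tracts copy alleles
#' drawn from the donor gene pool at its population frequencies, then
#' accumulate Poisson(2 mu t_adm bp) new mutations per tract (both the
#' tract lineage and the donor lineage it is later compared with diverge
#' for t_adm generations).  Infinite sites: duplicate positions are
#' dropped.
#'
#' @param contig contig name.
#' @param contig_length contig length in bp (default 10 Mb, desk scale).
#' @param mu mutation rate per bp per generation.
#' @param L_mean mean tract length in bp (default 200 kb, the expected
#'   tract scale of a ~500-generation-old pulse at ~1 cM/Mb).
#' @param t_out,t_donor,t_excl,t_sisters,t_adm split/admixture times in
#'   generations, `t_out > t_donor > t_excl > t_sisters > t_adm > 0`.
#' @param f fraction of each recipient haplotype's genome replaced by donor
#'   tracts (admixture pulse size).
#' @param n_donor,n_recipient,n_exclusion_1,n_exclusion_2,n_outgroup panel
#'   sizes in diploids.
#' @param pi_donor,pi_recipient,pi_exclusion_1,pi_exclusion_2,pi_outgroup
#'   stationary within-population diversity (per bp).
#' @param pi_anc_sisters,pi_anc_cattle,pi_anc_bos,pi_root shared ancestral
#'   polymorphism levels (per bp).
#' @param drift_sisters,drift_cattle,drift_bos,drift_root Beta concentration
#'   of post-split frequency drift for the shared layers (smaller = more
#'   drift).
#' @param missing_rate per-genotype missing probability (default 0; the
#'   pipeline consumes filtered calls).
#' @param seed mandatory RNG seed.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(contig = "chr1", contig_length = 1e7, mu = 1.26e-8,
                       L_mean = 2e5,
                       t_out = 5e5, t_donor = 2.5e5, t_excl = 5e4,
                       t_sisters = 7.5e3, t_adm = 500,
                       f = 0.03,
                       n_donor = 4, n_recipient = 10, n_exclusion_1 = 6,
                       n_exclusion_2 = 6, n_outgroup = 2,
                       pi_donor = 6e-4, pi_recipient = 1.2e-3,
                       pi_exclusion_1 = 1e-3, pi_exclusion_2 = 1e-3,
                       pi_outgroup = 8e-4,
                       pi_anc_sisters = 8e-4, pi_anc_cattle = 6e-4,
                       pi_anc_bos = 5e-4, pi_root = 4e-4,
                       drift_sisters = 30, drift_cattle = 10,
                       drift_bos = 5, drift_root = 5,
                       missing_rate = 0, seed) {
  if (missing(seed)) .stopf("sim_params(): a seed is mandatory")
  p <- as.list(environment())
  stopifnot(p$contig_length >= 1e4, p$mu > 0, p$L_mean > 0,
            .is_prob(p$f), .is_prob(p$missing_rate))
  if (!(p$t_out > p$t_donor && p$t_donor > p$t_excl &&
        p$t_excl > p$t_sisters && p$t_sisters > p$t_adm && p$t_adm > 0))
    .stopf("need t_out > t_donor > t_excl > t_sisters > t_adm > 0")
  for (nm in grep("^n_", names(p), value = TRUE))
    if (!.is_count(p[[nm]]) || p[[nm]] < 1) .stopf("%s must be >= 1", nm)
  structure(p, class = "sim_params")
}

.sim_pops <- function(p) {
  sizes <- c(donor = p$n_donor, recipient = p$n_recipient,
             exclusion_1 = p$n_exclusion_1, exclusion_2 = p$n_exclusion_2,
             outgroup = p$n_outgroup)
  prefix <- c(donor = "DON", recipient = "RCP", exclusion_1 = "EX1",
              exclusion_2 = "EX2", outgroup = "OUT")
  samples <- unlist(lapply(names(sizes), function(r)
    paste0(prefix[[r]], seq_len(sizes[[r]]))), use.names = FALSE)
  roles <- rep(names(sizes), sizes)
  hap_cols <- split(seq_len(2L * length(samples)),
                    rep(roles, each = 2L))[names(sizes)]
  list(sizes = sizes, samples = samples, roles = roles, hap_cols = hap_cols,
       n_haps = 2L * length(samples))
}

#' Panel configuration matching [simulate_introgression()] output
#' @param params a [sim_params()].
#' @return a [panel_config()].
#' @export
sim_panels <- function(params) {
  pops <- .sim_pops(params)
  ids <- split(pops$samples, pops$roles)
  panel_config(ids[names(pops$sizes)])
}

# one alternating exponential renewal draw of tract intervals on [0, len)
.draw_tracts <- function(len, L_mean, f) {
  if (f <= 0) return(cbind(start = numeric(), end = numeric()))
  if (f >= 1) return(cbind(start = 0, end = len))
  gap_mean <- L_mean * (1 - f) / f
  pos <- 0
  in_tract <- stats::runif(1L) < f
  starts <- ends <- numeric()
  while (pos < len) {
    seg <- stats::rexp(1L, rate = 1 / (if (in_tract) L_mean else gap_mean))
    if (in_tract) {
      starts <- c(starts, pos)
      ends <- c(ends, min(pos + seg, len))
    }
    pos <- pos + seg
    in_tract <- !in_tract
  }
  s <- floor(starts); e <- ceiling(pmin(ends, len))
  keep <- e > s
  cbind(start = s[keep], end = e[keep])
}

#' Simulate a structured callset with a known introgression pulse
#'
#' Generates phased haplotypes for the five panels of [sim_params()] under
#' the layered approximation described there, plants donor tracts into the
#' recipient, and returns both the callset and the exact truth.
#' Fully reproducible from `params$seed`.
#'
#' @param params a [sim_params()].
#' @return list with `genotypes` (a [genotype_matrix()]), `truth` (class
#'   `sim_truth`: `tracts` data frame with carrier haplotype ids, per-hap
#'   `realized_fraction`, overall `fraction`, `params`), and `panels`
#'   (a [panel_config()]).
#' @export
simulate_introgression <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)
  pops <- .sim_pops(p)
  L <- p$contig_length
  nh <- pops$n_haps
  eps <- 1e-9

  pos_l <- list(); mat_l <- list(); fp_l <- list()
  add_layer <- function(pos, hapmat, founder_p) {
    k <- length(pos_l) + 1L
    pos_l[[k]] <<- pos; mat_l[[k]] <<- hapmat; fp_l[[k]] <<- founder_p
  }
  blank <- function(S) matrix(FALSE, S, nh)

  poly_private <- function(role, pi) {
    S <- stats::rpois(1L, 4 * pi * L)
    if (S == 0L) return(invisible())
    pr <- pmin(pmax(stats::rbeta(S, 0.5, 0.5), eps), 1 - eps)
    m <- blank(S)
    cols <- pops$hap_cols[[role]]
    m[, cols] <- stats::runif(S * length(cols)) < pr
    add_layer(sample.int(L, S, replace = TRUE), m,
              if (role == "donor") pr else numeric(S))
  }
  poly_shared <- function(roles, pi, nu) {
    S <- stats::rpois(1L, 4 * pi * L)
    if (S == 0L) return(invisible())
    p0 <- pmin(pmax(stats::rbeta(S, 0.5, 0.5), eps), 1 - eps)
    m <- blank(S)
    fp <- numeric(S)
    for (role in roles) {
      pp <- stats::rbeta(S, p0 * nu, (1 - p0) * nu)
      pp <- pmin(pmax(pp, 0), 1)
      cols <- pops$hap_cols[[role]]
      m[, cols] <- stats::runif(S * length(cols)) < pp
      if (role == "donor") fp <- pp
    }
    add_layer(sample.int(L, S, replace = TRUE), m, fp)
  }
  fixed_branch <- function(roles, t_len) {
    S <- stats::rpois(1L, p$mu * t_len * L)
    if (S == 0L) return(invisible())
    m <- blank(S)
    for (role in roles) m[, pops$hap_cols[[role]]] <- TRUE
    add_layer(sample.int(L, S, replace = TRUE), m,
              if ("donor" %in% roles) rep(1, S) else numeric(S))
  }

  # branch substitutions
  fixed_branch("outgroup", p$t_out)
  fixed_branch(c("donor", "exclusion_1", "exclusion_2", "recipient"),
               p$t_out - p$t_donor)
  fixed_branch("donor", p$t_donor)
  fixed_branch(c("exclusion_1", "exclusion_2", "recipient"),
               p$t_donor - p$t_excl)
  fixed_branch("exclusion_1", p$t_excl)
  fixed_branch(c("exclusion_2", "recipient"), p$t_excl - p$t_sisters)
  fixed_branch("exclusion_2", p$t_sisters)
  fixed_branch("recipient", p$t_sisters)
  # stationary within-population polymorphism
  poly_private("donor", p$pi_donor)
  poly_private("recipient", p$pi_recipient)
  poly_private("exclusion_1", p$pi_exclusion_1)
  poly_private("exclusion_2", p$pi_exclusion_2)
  poly_private("outgroup", p$pi_outgroup)
  # shared ancestral polymorphism (ILS)
  poly_shared(c("exclusion_2", "recipient"), p$pi_anc_sisters, p$drift_sisters)
  poly_shared(c("exclusion_1", "exclusion_2", "recipient"),
              p$pi_anc_cattle, p$drift_cattle)
  poly_shared(c("donor", "exclusion_1", "exclusion_2", "recipient"),
              p$pi_anc_bos, p$drift_bos)
  poly_shared(names(pops$sizes), p$pi_root, p$drift_root)

  pos <- unlist(pos_l, use.names = FALSE)
  hap <- do.call(rbind, mat_l)
  founder_p <- unlist(fp_l, use.names = FALSE)
  ord <- order(pos)
  pos <- pos[ord]; hap <- hap[ord, , drop = FALSE]; founder_p <- founder_p[ord]
  dup <- duplicated(pos)
  pos <- pos[!dup]; hap <- hap[!dup, , drop = FALSE]; founder_p <- founder_p[!dup]
  pos0 <- pos - 1L  # 0-based

  # admixture pulse: plant donor tracts into recipient haplotypes
  rcp_cols <- pops$hap_cols$recipient
  rcp_haps <- hap_ids(pops$samples[pops$roles == "recipient"])
  if (p$f > 0 && length(rcp_cols) == 0L)
    .stopf("f > 0 with zero recipient haplotypes")
  tract_rows <- list()
  new_pos <- list(); new_col <- list()
  for (k in seq_along(rcp_cols)) {
    tr <- .draw_tracts(L, p$L_mean, p$f)
    if (nrow(tr)) {
      tract_rows[[length(tract_rows) + 1L]] <- data.frame(
        contig = p$contig, start = tr[, "start"], end = tr[, "end"],
        carrier = rcp_haps[k], stringsAsFactors = FALSE)
      for (t in seq_len(nrow(tr))) {
        s <- tr[t, "start"]; e <- tr[t, "end"]
        in_tr <- which(pos0 >= s & pos0 < e)
        if (length(in_tr))
          hap[in_tr, rcp_cols[k]] <-
            stats::runif(length(in_tr)) < founder_p[in_tr]
        m <- stats::rpois(1L, 2 * p$mu * p$t_adm * (e - s))
        if (m > 0L) {
          new_pos[[length(new_pos) + 1L]] <- s + sample.int(e - s, m, replace = TRUE) - 1L
          new_col[[length(new_col) + 1L]] <- rep(rcp_cols[k], m)
        }
      }
    }
  }
  if (length(new_pos)) {
    np <- unlist(new_pos); ncl <- unlist(new_col)
    fresh <- !(np + 1L) %in% pos & !duplicated(np)
    np <- np[fresh]; ncl <- ncl[fresh]
    if (length(np)) {
      add <- matrix(FALSE, length(np), nh)
      add[cbind(seq_along(np), ncl)] <- TRUE
      pos0 <- c(pos0, np)
      hap <- rbind(hap, add)
      ord <- order(pos0)
      pos0 <- pos0[ord]; hap <- hap[ord, , drop = FALSE]
    }
  }

  # polarity bookkeeping: drop monomorphic sites, assign bases
  der <- rowSums(hap)
  keep <- der > 0L & der < nh
  pos0 <- pos0[keep]; hap <- hap[keep, , drop = FALSE]
  S <- length(pos0)
  bases <- c("A", "C", "G", "T")
  ri <- sample.int(4L, S, replace = TRUE)
  ref <- bases[ri]
  alt <- bases[(ri - 1L + sample.int(3L, S, replace = TRUE)) %% 4L + 1L]

  a1 <- matrix(0L, S, length(pops$samples))
  a2 <- matrix(0L, S, length(pops$samples))
  odd <- seq(1L, nh, by = 2L)
  a1[] <- hap[, odd]
  a2[] <- hap[, odd + 1L]
  storage.mode(a1) <- storage.mode(a2) <- "integer"
  if (p$missing_rate > 0) {
    mis <- matrix(stats::runif(S * ncol(a1)) < p$missing_rate, S)
    a1[mis] <- NA_integer_; a2[mis] <- NA_integer_
  }
  gm <- genotype_matrix(rep(p$contig, S), pos0, ref, alt, a1, a2,
                        matrix(TRUE, S, ncol(a1)), pops$samples,
                        stats::setNames(L, p$contig))

  tracts <- do.call(rbind, tract_rows) %||%
    data.frame(contig = character(), start = numeric(), end = numeric(),
               carrier = character(), stringsAsFactors = FALSE)
  realized <- vapply(rcp_haps, function(h)
    sum(tracts$end[tracts$carrier == h] - tracts$start[tracts$carrier == h]) / L,
    numeric(1L))
  truth <- structure(list(tracts = tracts,
                          realized_fraction = realized,
                          fraction = mean(realized),
                          params = p), class = "sim_truth")
  list(genotypes = gm, truth = truth, panels = sim_panels(p))
}

#' Write simulation truth to BED + JSON
#'
#' @param truth a `sim_truth`.
#' @param bed_path BED output for the tracts (4th column: carrier).
#' @param json_path JSON output for parameters and realized fractions.
#' @export
write_sim_truth <- function(truth, bed_path, json_path) {
  write_bed(truth$tracts, bed_path, extra_columns = "carrier")
  par <- truth$params
  class(par) <- NULL
  jsonlite::write_json(list(params = par,
                            realized_fraction = as.list(truth$realized_fraction),
                            fraction = truth$fraction),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(truth)
}

#' Compare called segments with simulated truth
#'
#' Interval-arithmetic comparison per carrier haplotype: per-bp precision,
#' recall and F1; relative error of the estimated genome-wide introgressed
#' fraction; and the fraction of truth tracts detected by a call with at
#' least 50% reciprocal overlap from the same carrier.
#'
#' @param calls data frame with `contig`, `start`, `end`, `carrier`.
#' @param truth a `sim_truth` from [simulate_introgression()].
#' @return list: `precision` (NA when there are no calls), `recall`, `f1`,
#'   `called_fraction`, `true_fraction`, `fraction_error` (relative),
#'   `detection_rate`, and the raw bp counts.
#' @export
evaluate_calls <- function(calls, truth) {
  stopifnot(inherits(truth, "sim_truth"))
  p <- truth$params
  tr <- truth$tracts
  carriers <- union(unique(calls$carrier), unique(tr$carrier))
  tp <- fp <- fn <- 0
  for (h in carriers) {
    ci <- calls[calls$carrier == h, , drop = FALSE]
    ti <- tr[tr$carrier == h, , drop = FALSE]
    cir <- IRanges::reduce(.ir(ci)); tir <- IRanges::reduce(.ir(ti))
    ov <- sum(IRanges::width(IRanges::intersect(cir, tir)))
    tp <- tp + ov
    fp <- fp + sum(IRanges::width(cir)) - ov
    fn <- fn + sum(IRanges::width(tir)) - ov
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  hap_bp <- 2 * p$n_recipient * p$contig_length
  called_fraction <- sum(calls$end - calls$start) / hap_bp
  true_fraction <- sum(tr$end - tr$start) / hap_bp
  fraction_error <- if (true_fraction > 0)
    (called_fraction - true_fraction) / true_fraction else NA_real_
  detected <- 0L
  if (nrow(tr)) {
    for (i in seq_len(nrow(tr))) {
      ci <- calls[calls$carrier == tr$carrier[i] &
                    calls$contig == tr$contig[i], , drop = FALSE]
      if (nrow(ci) == 0L) next
      ov <- pmin(ci$end, tr$end[i]) - pmax(ci$start, tr$start[i])
      len_t <- tr$end[i] - tr$start[i]
      if (any(ov >= 0.5 * len_t & ov >= 0.5 * (ci$end - ci$start)))
        detected <- detected + 1L
    }
  }
  list(precision = precision, recall = recall, f1 = f1,
       called_fraction = called_fraction, true_fraction = true_fraction,
       fraction_error = fraction_error,
       detection_rate = if (nrow(tr)) detected / nrow(tr) else NA_real_,
       tp_bp = tp, fp_bp = fp, fn_bp = fn)
}

#' Graft admixed target samples onto a callset
#'
#' Builds `n` synthetic diploid samples whose first haplotype is drawn from
#' panel A and second from panel B (a 50/50 two-way mix), appends them to
#' the genotype matrix, and returns the extended matrix plus the new sample
#' ids.  Used to exercise the admixture-f3 test on a target of known mixed
#' ancestry.
#'
#' @param gm a [genotype_matrix()].
#' @param panel_a,panel_b character vectors of source sample ids.
#' @param n number of mixed samples to create.
#' @param prefix sample-id prefix for the mixtures.
#' @return list `gm` (extended matrix) and `samples` (new ids).
#' @export
mix_panels <- function(gm, panel_a, panel_b, n, prefix = "MIX") {
  stopifnot(n >= 1)
  ha <- hap_alleles(gm, panel_a)
  hb <- hap_alleles(gm, panel_b)
  ids <- paste0(prefix, seq_len(n))
  a1 <- gm$a1; a2 <- gm$a2; ph <- gm$phased
  for (i in seq_len(n)) {
    c1 <- ha[, sample.int(ncol(ha), 1L)]
    c2 <- hb[, sample.int(ncol(hb), 1L)]
    a1 <- cbind(a1, c1); a2 <- cbind(a2, c2)
    ph <- cbind(ph, TRUE)
  }
  # a mixed genotype is missing where either source haplotype is undefined
  mis <- is.na(a1) | is.na(a2)
  a1[mis] <- NA_integer_; a2[mis] <- NA_integer_
  dimnames(a1) <- dimnames(a2) <- dimnames(ph) <- NULL
  list(gm = genotype_matrix(gm$contig, gm$pos, gm$ref, gm$alt, a1, a2, ph,
                            c(gm$samples, ids), gm$contig_lengths),
       samples = ids)
}
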