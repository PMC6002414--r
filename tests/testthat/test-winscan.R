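test_that("make_windows tiles contigs, keeps flagged partial tails", {
  w <- make_windows(c(chr1 = 12000), size = 5000)
  expect_equal(w$start, c(0, 5000, 10000))
  expect_equal(w$end, c(5000, 10000, 12000))
  expect_equal(w$partial, c(FALSE, FALSE, TRUE))
  # step = size: a disjoint partition covering the contig
  expect_equal(sum(w$end - w$start), 12000)
  expect_error(make_windows(c(c1 = 100), size = 10, step = 20))
})

test_that("sliding windows cover each bp the expected number of times", {
  set.seed(41)
  for (rep in 1:10) {
    len <- sample(2000:9000, 1)
    size <- sample(c(500, 1000), 1)
    step <- sample(c(size, size / 2, size / 5), 1)
    w <- make_windows(c(k = len), size = size, step = step)
    cov <- integer(len)
    for (i in seq_len(nrow(w)))
      cov[(w$start[i] + 1):w$end[i]] <- cov[(w$start[i] + 1):w$end[i]] + 1L
    expect_true(all(cov >= 1))
    # interior coverage equals size/step; edges are boundary-adjusted
    interior <- cov[(size + 1):(len - size)]
    expect_true(all(interior == size / step))
  }
})

test_that("window scan means and counts match brute-force recomputation", {
  set.seed(42)
  gm <- rand_gm(n_sites = 200, n_samples = 20, miss = 0.1, contig_len = 2e4)
  panels <- panel_config(donor = paste0("S", 1:5),
                         recipient = paste0("S", 6:15),
                         exclusion_1 = paste0("S", 16:20))
  das <- suppressWarnings(find_diagnostic_alleles(gm, panels,
                                                  max_exclusion_freq = 0.2))
  expect_gt(nrow(das), 5)
  w <- make_windows(c(chr1 = 2e4), size = 1000)
  # sample mode
  ws <- window_scan(gm, das, panels$recipient, w, mode = "sample")
  sf <- vapply(seq_len(nrow(das)), function(k) {
    s <- match(das$pos[k], gm$pos)
    d <- dosages(gm)[s, panels$recipient]
    an <- 2 * sum(!is.na(d))
    f <- sum(d, na.rm = TRUE) / an
    if (das$allele[k] == "alt") f else 1 - f
  }, 0)
  orc <- oracle_window_scan(sf, das$pos, w)
  expect_equal(ws$n_sites, unname(orc[, "n"]))
  expect_equal(ws$mean_freq, unname(orc[, "m"]))
  # haplotype mode, one haplotype at a time
  wh <- window_scan(gm, das, panels$recipient, w, mode = "haplotype")
  H <- hap_alleles(gm, panels$recipient)
  for (h in sample(colnames(H), 3)) {
    idx <- match(das$pos, gm$pos)
    carry <- as.numeric(H[idx, h] == ifelse(das$allele == "alt", 1L, 0L))
    orc_h <- oracle_window_scan(carry, das$pos, w)
    sel <- wh$carrier == h
    expect_equal(wh$n_sites[sel], unname(orc_h[, "n"]))
    expect_equal(wh$mean_freq[sel], unname(orc_h[, "m"]))
  }
  # windows with no diagnostic sites are reported undefined, not dropped
  expect_equal(nrow(ws), nrow(w))
  empty <- ws$n_sites == 0
  if (any(empty)) expect_true(all(is.na(ws$mean_freq[empty])))
})

test_that("window pi closed forms and pairwise-average oracle agree", {
  # two haplotypes differing at 3 of 1000 callable bp -> pi = 0.003
  a1 <- matrix(0L, 3, 1); a2 <- matrix(1L, 3, 1)
  gm <- genotype_matrix(rep("c", 3), c(10L, 20L, 30L), rep("A", 3),
                        rep("T", 3), a1, a2, matrix(TRUE, 3, 1), "s1",
                        c(c = 1000))
  w <- make_windows(c(c = 1000), size = 1000)
  out <- window_pi(gm, "s1", w)
  expect_equal(out$pi, 0.003)
  # monomorphic window -> 0
  gm0 <- genotype_matrix("c", 10L, "A", "T", matrix(1L, 1, 2),
                         matrix(1L, 1, 2), matrix(TRUE, 1, 2),
                         c("s1", "s2"), c(c = 1000))
  expect_equal(window_pi(gm0, c("s1", "s2"), w)$pi, 0)
  # random window equals the average over all haplotype pairs
  set.seed(43)
  gm2 <- rand_gm(n_sites = 60, n_samples = 6, miss = 0, contig_len = 5000)
  w2 <- make_windows(c(chr1 = 5000), size = 5000)
  out2 <- window_pi(gm2, gm2$samples, w2)
  expect_equal(out2$pi, oracle_pi(hap_alleles(gm2), 5000))
})

test_that("window pi is invariant to sample order and allele relabeling", {
  set.seed(44)
  gm <- rand_gm(n_sites = 80, n_samples = 6, miss = 0.1, contig_len = 4000)
  w <- make_windows(c(chr1 = 4000), size = 2000)
  p1 <- window_pi(gm, gm$samples, w)$pi
  p2 <- window_pi(gm, rev(gm$samples), w)$pi
  expect_equal(p1, p2)
  flip <- genotype_matrix(gm$contig, gm$pos, gm$alt, gm$ref,
                          1L - gm$a1, 1L - gm$a2, gm$phased, gm$samples,
                          gm$contig_lengths)
  expect_equal(window_pi(flip, flip$samples, w)$pi, p1)
})

test_that("segment caller handles runs, minima and gaps as documented", {
  mk_ws <- function(freq, n = 10) data.frame(
    contig = "c", start = seq_along(freq) * 5000 - 5000,
    end = seq_along(freq) * 5000, carrier = "h1",
    n_sites = ifelse(is.na(freq), 0L, n), mean_freq = freq)
  # run of 3 qualifying windows -> one 15-kb segment
  seg <- call_segments(mk_ws(c(NA, 0.9, 0.8, 0.9, NA)),
                       min_consecutive_windows = 2,
                       max_merge_gap_windows = 0)
  expect_equal(nrow(seg), 1L)
  expect_equal(c(seg$start, seg$end), c(5000, 20000))
  expect_equal(seg$n_windows, 3L)
  # single qualifying window with min_consecutive = 2 -> nothing
  expect_equal(nrow(call_segments(mk_ws(c(NA, 0.9, NA, NA)),
                                  min_consecutive_windows = 2)), 0L)
  # a one-window gap is bridged when allowed
  seg2 <- call_segments(mk_ws(c(0.9, NA, 0.9)), min_consecutive_windows = 2,
                        max_merge_gap_windows = 1)
  expect_equal(nrow(seg2), 1L)
  expect_equal(c(seg2$start, seg2$end), c(0, 15000))
  seg3 <- call_segments(mk_ws(c(0.9, NA, 0.9)), min_consecutive_windows = 2,
                        max_merge_gap_windows = 0)
  expect_equal(nrow(seg3), 0L)
})

test_that("segment caller matches the exhaustive run oracle", {
  set.seed(45)
  for (rep in 1:30) {
    nw <- 30
    freq <- ifelse(runif(nw) < 0.3, NA, runif(nw))
    ns <- sample(0:5, nw, replace = TRUE)
    ws <- data.frame(contig = "c", start = (0:(nw - 1)) * 100,
                     end = (1:nw) * 100, carrier = "h",
                     n_sites = ns, mean_freq = freq)
    mc <- sample(1:3, 1); mg <- sample(0:2, 1); mss <- sample(0:3, 1)
    seg <- call_segments(ws, freq_threshold = 0.5, min_support_sites = mss,
                         min_consecutive_windows = mc,
                         max_merge_gap_windows = mg)
    q <- !is.na(freq) & freq >= 0.5 & ns >= mss
    covered <- oracle_runs(q, mc, mg)
    called <- rep(FALSE, nw)
    for (i in seq_len(nrow(seg)))
      called[(seg$start[i] / 100 + 1):(seg$end[i] / 100)] <- TRUE
    expect_equal(called, covered)
  }
})

test_that("lowering the frequency threshold never removes a called bp", {
  set.seed(46)
  nw <- 40
  freq <- ifelse(runif(nw) < 0.2, NA, runif(nw))
  ws <- data.frame(contig = "c", start = (0:(nw - 1)) * 100,
                   end = (1:nw) * 100, carrier = "h",
                   n_sites = 5L, mean_freq = freq)
  cover_at <- function(t) bp_set(call_segments(ws, freq_threshold = t,
                                               min_support_sites = 0,
                                               min_consecutive_windows = 1,
                                               max_merge_gap_windows = 1))
  for (t in c(0.8, 0.5, 0.2))
    expect_true(all(cover_at(t + 0.2) %in% cover_at(t)))
})

test_that("shared_filter equals per-bp coverage counting", {
  # two identical segments from two haplotypes
  segs <- data.frame(contig = "c", start = c(100, 100), end = c(300, 300),
                     carrier = c("h1", "h2"))
  sh <- shared_filter(segs, 2)
  expect_equal(sh, data.frame(contig = "c", start = 100, end = 300),
               ignore_attr = TRUE)
  # one carrier only -> empty at min 2
  expect_equal(nrow(shared_filter(segs[1L, ], 2)), 0L)
  # random sets vs per-bp oracle; min 1 equals the union
  set.seed(47)
  for (rep in 1:10) {
    n <- 20
    start <- sample.int(900, n)
    segs <- data.frame(contig = "c", start = start,
                       end = start + sample.int(80, n),
                       carrier = sample(paste0("h", 1:5), n, replace = TRUE))
    for (mc in 1:3) {
      sh <- shared_filter(segs, mc)
      expect_equal(bp_set(sh), oracle_shared(segs, mc, 1000))
    }
    u <- shared_filter(segs, 1)
    expect_equal(interval_bp(u), interval_bp(segs))
  }
})

test_that("genome fraction arithmetic and group summary", {
  mask <- callable_mask(contig_lengths = c(c = 2.5e9))
  # 75 Mb across the two haplotypes of one genome on 2.5 Gb -> 1.5%
  segs <- data.frame(contig = "c", start = c(0, 0), end = c(50e6, 25e6),
                     carrier = c("g1.1", "g1.2"))
  fr <- genome_fraction(segs, mask, "g1", mode = "haplotype")
  expect_equal(fr$per_genome$fraction, 0.015)
  # a single sample-level 75 Mb on 2.5 Gb -> 3%
  segs2 <- data.frame(contig = "c", start = 0, end = 75e6, carrier = "g1")
  fr2 <- genome_fraction(segs2, mask, "g1", mode = "sample")
  expect_equal(fr2$per_genome$fraction, 0.03)
  # no segments -> fraction 0, SE 0
  fr0 <- genome_fraction(segs[0, ], mask, c("g1", "g2"))
  expect_equal(fr0$mean, 0)
  expect_equal(fr0$se, 0)
  # SE uses sd/sqrt(n)
  segs3 <- data.frame(contig = "c", start = c(0, 0), end = c(10e6, 30e6),
                      carrier = c("g1.1", "g2.1"))
  fr3 <- genome_fraction(segs3, mask, c("g1", "g2"), mode = "haplotype")
  expect_equal(fr3$se, stats::sd(fr3$per_genome$fraction) / sqrt(2))
})
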