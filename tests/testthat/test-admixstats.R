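# genotype matrix with prescribed per-panel allele frequencies: each panel
# hap draws Bernoulli(p) at every site
freq_gm <- function(p_list, n_dip = 4, pos = NULL) {
  S <- length(p_list[[1L]])
  cols <- list()
  samples <- character()
  for (r in names(p_list)) {
    for (i in seq_len(n_dip)) {
      cols[[length(cols) + 1L]] <- cbind(
        rbinom(S, 1L, p_list[[r]]), rbinom(S, 1L, p_list[[r]]))
      samples <- c(samples, paste0(r, i))
    }
  }
  M <- do.call(cbind, cols)
  a1 <- M[, seq(1, ncol(M), 2), drop = FALSE]
  a2 <- M[, seq(2, ncol(M), 2), drop = FALSE]
  storage.mode(a1) <- storage.mode(a2) <- "integer"
  if (is.null(pos)) pos <- seq_len(S) * 100L
  genotype_matrix(rep("chr1", S), pos, rep("A", S), rep("T", S), a1, a2,
                  matrix(TRUE, S, ncol(a1)), samples)
}

panels_for <- function(gm, roles) {
  lapply(stats::setNames(roles, roles), function(r)
    gm$samples[startsWith(gm$samples, r)])
}

test_that("block assignment is floor(pos/size) per contig", {
  b <- assign_blocks(rep("c", 3), c(1e6, 4e6, 6e6), 5e6)
  expect_equal(b, c(1L, 1L, 2L))
  # a short contig gets a single block; contigs never share blocks
  b2 <- assign_blocks(c("a", "a", "b"), c(0, 4e6, 0), 5e6)
  expect_equal(b2, c(1L, 1L, 2L))
  set.seed(51)
  pos <- sort(sample.int(1e8, 500))
  b3 <- assign_blocks(rep("z", 500), pos, 7e6)
  expect_equal(b3, match(pos %/% 7e6, unique(pos %/% 7e6)))
})

test_that("two equal blocks give the closed-form jackknife SE", {
  jk <- block_jackknife(c(2, 6), c(10, 10))
  d1 <- 6 / 10; d2 <- 2 / 10  # leave-one-out estimates
  expect_equal(jk$se, abs(d1 - d2) / 2)
  expect_equal(jk$estimate, 0.4)
  # identical blocks: SE 0, flagged, Z infinite
  expect_warning(jk0 <- block_jackknife(c(3, 3), c(10, 10)), "SE is 0")
  expect_equal(jk0$se, 0)
  expect_true(is.infinite(jk0$z) && jk0$z > 0)
})

test_that("jackknife SE matches an independent transcription on random data", {
  set.seed(52)
  for (rep in 1:25) {
    g <- sample(3:30, 1)
    num <- rnorm(g)
    den <- rpois(g, 40) + 1
    w <- if (runif(1) < 0.5) den else rpois(g, 20) + 1
    jk <- block_jackknife(num, den, weights = w)
    expect_equal(jk$se, oracle_jackknife_se(num, den, w))
    expect_equal(jk$z, jk$estimate / jk$se)
  }
})

test_that("jackknife SE converges to the analytic SE on iid blocks", {
  set.seed(53)
  g <- 1000
  x <- rnorm(g, mean = 2, sd = 3)
  jk <- block_jackknife(x, rep(1, g))
  analytic <- stats::sd(x) / sqrt(g)
  expect_lt(abs(jk$se - analytic) / analytic, 0.10)
})

test_that("f3 site terms follow the definition", {
  set.seed(54)
  # target duplicates source A -> estimate 0 without correction
  p <- runif(60, 0.1, 0.9)
  gm <- freq_gm(list(C = p, B = runif(60)))
  panels <- panels_for(gm, c("C", "B"))
  panels$A <- panels$C
  f3 <- suppressWarnings(f3_stat(gm, panels, "C", "A", "B",
                                 block_size_bp = 1000, bias_correct = FALSE))
  expect_equal(f3$estimate, 0)  # degenerate: every site term is 0
  # single site with known frequencies: term (c-a)(c-b) = -0.25
  gm1 <- genotype_matrix("c", 0L, "A", "T",
                         matrix(c(0L, 1L, 0L), 1), matrix(c(0L, 1L, 1L), 1),
                         matrix(TRUE, 1, 3), c("A1", "B1", "C1"))
  sf <- site_freqs(gm1, list(A = "A1", B = "B1", C = "C1"))
  cc <- sf$p[, "C"]; aa <- sf$p[, "A"]; bb <- sf$p[, "B"]
  expect_equal(unname((cc - aa) * (cc - bb)), -0.25)
})

test_that("f3 with bias correction is non-negative for an unadmixed target", {
  set.seed(55)
  reps <- vapply(1:40, function(r) {
    p0 <- rbeta(400, 0.8, 0.8)
    drift <- function(nu) pmin(pmax(rbeta(400, p0 * nu, (1 - p0) * nu),
                                    1e-9), 1 - 1e-9)
    gm <- freq_gm(list(C = drift(20), A = drift(20), B = drift(5)), n_dip = 5)
    f3_stat(gm, panels_for(gm, c("C", "A", "B")), "C", "A", "B",
            block_size_bp = 2000)$estimate
  }, 0)
  expect_gt(mean(reps), -2 * stats::sd(reps) / sqrt(length(reps)))
})

test_that("f3 of a 50/50 mixed target is significantly negative", {
  set.seed(56)
  p0 <- rbeta(5000, 0.5, 0.5)
  a <- pmin(pmax(rbeta(5000, p0 * 2, (1 - p0) * 2), 0), 1)
  b <- pmin(pmax(rbeta(5000, p0 * 2, (1 - p0) * 2), 0), 1)
  gm <- freq_gm(list(A = a, B = b), n_dip = 5)
  mixed <- mix_panels(gm, panels_for(gm, "A")$A, panels_for(gm, "B")$B, 5)
  panels <- panels_for(gm, c("A", "B"))
  panels$C <- mixed$samples
  f3 <- f3_stat(mixed$gm, panels, "C", "A", "B", block_size_bp = 1e4)
  expect_lt(f3$estimate, 0)
  expect_lt(f3$z, -3)
})

test_that("outgroup-f3 ranks affinity and is 0 for X = O", {
  set.seed(57)
  p0 <- rbeta(2000, 0.5, 0.5)
  near <- pmin(pmax(rbeta(2000, p0 * 50, (1 - p0) * 50), 0), 1)
  far <- pmin(pmax(rbeta(2000, p0 * 3, (1 - p0) * 3), 0), 1)
  o <- pmin(pmax(rbeta(2000, p0 * 3, (1 - p0) * 3), 0), 1)
  gm <- freq_gm(list(A = near, N = near, F = far, O = o), n_dip = 4)
  panels <- panels_for(gm, c("A", "N", "F", "O"))
  fn <- outgroup_f3(gm, panels, "O", "A", "N", block_size_bp = 5000)
  ff <- outgroup_f3(gm, panels, "O", "A", "F", block_size_bp = 5000)
  expect_gt(fn$estimate, ff$estimate)  # closer pop shares more drift
  # X = O: no drift shared beyond the outgroup (SE degenerates to 0)
  panels$X <- panels$O
  fo <- suppressWarnings(outgroup_f3(gm, panels, "O", "A", "X",
                                     block_size_bp = 5000))
  expect_equal(fo$estimate, 0)
})

test_that("D statistic closed forms, antisymmetry and label invariance", {
  # p1 = p2 at every site -> D = 0 exactly
  set.seed(58)
  p <- runif(100, 0.2, 0.8)
  gm <- freq_gm(list(X = p, Y = runif(100), O = runif(100, 0, 0.3)))
  panels <- panels_for(gm, c("X", "Y", "O"))
  panels$P1 <- panels$X; panels$P2 <- panels$X
  d0 <- suppressWarnings(d_stat(gm, panels, "P1", "P2", "Y", "O",
                                block_size_bp = 2000))
  expect_equal(d0$estimate, 0)
  # single pure-ABBA site -> D = 1
  gm1 <- genotype_matrix(rep("c", 2), c(0L, 10L), rep("A", 2), rep("T", 2),
                         matrix(c(0L, 0L, 1L, 1L, 1L, 1L, 0L, 0L), 2),
                         matrix(c(0L, 0L, 1L, 1L, 1L, 1L, 0L, 0L), 2),
                         matrix(TRUE, 2, 4), c("p1", "p2", "p3", "og"))
  d1 <- suppressWarnings(d_stat(gm1, list(p1 = "p1", p2 = "p2", p3 = "p3",
                                          og = "og"),
                                "p1", "p2", "p3", "og", block_size_bp = 5))
  expect_equal(d1$estimate, 1)
  # antisymmetry under P1 <-> P2
  set.seed(59)
  p0 <- rbeta(3000, 0.5, 0.5)
  mk <- function(nu) pmin(pmax(rbeta(3000, p0 * nu, (1 - p0) * nu), 0), 1)
  gm2 <- freq_gm(list(A = mk(8), B = mk(8), C = mk(3), O = mk(3)), n_dip = 3)
  panels2 <- panels_for(gm2, c("A", "B", "C", "O"))
  dab <- d_stat(gm2, panels2, "A", "B", "C", "O", block_size_bp = 1e4)
  dba <- d_stat(gm2, panels2, "B", "A", "C", "O", block_size_bp = 1e4)
  expect_equal(dab$estimate, -dba$estimate)
  expect_equal(abs(dab$z), abs(dba$z))
  # invariance under global allele relabeling
  flip <- genotype_matrix(gm2$contig, gm2$pos, gm2$alt, gm2$ref,
                          1L - gm2$a1, 1L - gm2$a2, gm2$phased, gm2$samples)
  dflip <- d_stat(flip, panels2, "A", "B", "C", "O", block_size_bp = 1e4)
  expect_equal(dflip$estimate, dab$estimate)
})

test_that("f3/D match a direct per-site loop on random data", {
  set.seed(60)
  gm <- rand_gm(n_sites = 150, n_samples = 12, miss = 0.1, contig_len = 5e4)
  panels <- list(w = paste0("S", 1:3), x = paste0("S", 4:6),
                 y = paste0("S", 7:9), z = paste0("S", 10:12))
  sf <- site_freqs(gm, panels)
  ok <- rowSums(is.na(sf$p)) == 0
  p <- sf$p[ok, , drop = FALSE]; nn <- sf$n[ok, , drop = FALSE]
  # f3(w; x, y) with correction
  use <- nn[, "w"] >= 2
  terms <- ((p[, "w"] - p[, "x"]) * (p[, "w"] - p[, "y"]) -
              p[, "w"] * (1 - p[, "w"]) / (nn[, "w"] - 1))[use]
  f3 <- suppressMessages(f3_stat(gm, panels, "w", "x", "y",
                                 block_size_bp = 5e3))
  expect_equal(f3$estimate, mean(terms))
  # D(w, x; y, z): ABBA/BABA terms averaged over both allele labelings
  term <- function(p1, p2, p3, po) {
    list(abba = (1 - p1) * p2 * p3 * (1 - po),
         baba = p1 * (1 - p2) * p3 * (1 - po))
  }
  tp <- term(p[, "w"], p[, "x"], p[, "y"], p[, "z"])
  tq <- term(1 - p[, "w"], 1 - p[, "x"], 1 - p[, "y"], 1 - p[, "z"])
  num <- (tp$abba - tp$baba + tq$abba - tq$baba) / 2
  den <- (tp$abba + tp$baba + tq$abba + tq$baba) / 2
  d <- suppressMessages(d_stat(gm, panels, "w", "x", "y", "z",
                               block_size_bp = 5e3))
  expect_equal(d$estimate, sum(num) / sum(den))
})
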