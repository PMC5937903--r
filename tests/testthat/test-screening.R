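test_that("q-values reproduce the step-up formula and its oracle", {
  # hand computation: pi0 = 1, m = 4, all tail minima collapse to 0.04
  q <- qvalues(c(0.01, 0.02, 0.03, 0.04), pi0 = 1)
  expect_equal(as.numeric(q), rep(0.04, 4))
  # all p = 1: q = pi0 <= 1
  q1 <- qvalues(rep(1, 150))
  expect_true(all(q1 == attr(q1, "pi0")))
  expect_lte(attr(q1, "pi0"), 1)
  # random vectors match the brute-force min-over-tail scan element-wise
  for (s in 1:5) {
    set.seed(s)
    p <- runif(80)
    expect_equal(as.numeric(qvalues(p, pi0 = 1)), brute_qvalues(p, 1),
                 tolerance = 1e-12)
    expect_equal(as.numeric(qvalues(p, pi0 = 1)),
                 p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
  # with an estimated pi0 the scan must use the same pi0
  set.seed(9)
  p <- c(runif(300)^2, runif(200))    # enriched near zero
  qv <- qvalues(p)
  expect_lt(attr(qv, "pi0"), 1)
  expect_equal(as.numeric(qv), brute_qvalues(p, attr(qv, "pi0")),
               tolerance = 1e-12)
  expect_error(qvalues(c(0.5, 1.2)), "invalid input")
  expect_error(qvalues(c(0.5, NA)), "invalid input")
})

test_that("q-values are monotone in p and fall back to pi0 = 1 for short vectors", {
  set.seed(4)
  p <- sort(runif(200))
  q <- qvalues(p)
  expect_true(all(diff(q) >= -1e-15))
  short <- qvalues(runif(50))
  expect_equal(attr(short, "pi0"), 1)
})

test_that("screen returns empty results for empty inputs, with a reason", {
  d <- generate_design(3, 5, seed = 1)
  m <- generate_proteome(d, n_catalogue = 0, mean_detected_per_plex = 0,
                         sd_detected_per_plex = 0, seed = 1)
  tt <- truth_table(b0 = -2, sigma_B = 0.2, sigma_e = 0.5)
  tc <- generate_carotenoids(m, list(a = tt), d, seed = 2)
  scr <- screen_analyte("a", m, tc)
  expect_equal(nrow(scr$audit), 0)
  expect_equal(nrow(scr$hits), 0)
  # all samples below detection: screen skipped with a message
  tt2 <- truth_table(b0 = -2, sigma_B = 0.2, sigma_e = 0.5,
                     detection_limit = 1e6)
  tc2 <- generate_carotenoids(m, list(a = tt2), d, seed = 2)
  expect_message(scr2 <- screen_analyte("a", m, tc2), "no detectable")
  expect_equal(scr2$n_response, 0)
})

test_that("a planted signal attains the smallest q in almost every replicate", {
  # 1 true protein (slope 1) among 99 nulls at the study's scale
  wins <- 0L
  for (rep in 1:100) {
    set.seed(4000 + rep)
    g <- rep(1:72, each = 7)
    n <- length(g)
    P <- matrix(rnorm(n * 100), n, 100,
                dimnames = list(sprintf("S%03d", 1:n), sprintf("P%03d", 1:100)))
    y <- 2^(0.5 + P[, 1] + rnorm(72, 0, 0.3)[g] + rnorm(n, 0, 0.5))
    m <- abundance_matrix(P, setNames(g, rownames(P)))
    tc <- make_ctab(matrix(y, n, 1, dimnames = list(rownames(P), "a")))
    scr <- screen_analyte("a", m, tc)
    if (scr$audit$protein_id[1] == "P001") wins <- wins + 1L
  }
  expect_gte(wins, 95)
})

test_that("an all-null screen is calibrated at the 5% level", {
  set.seed(77)
  g <- rep(1:40, each = 7)
  n <- length(g)
  P <- matrix(rnorm(n * 200), n, 200,
              dimnames = list(sprintf("S%03d", 1:n), sprintf("P%03d", 1:200)))
  y <- 2^(rnorm(40, 0, 0.3)[g] + rnorm(n, 0, 0.6))
  m <- abundance_matrix(P, setNames(g, rownames(P)))
  tc <- make_ctab(matrix(y, n, 1, dimnames = list(rownames(P), "a")))
  scr <- screen_analyte("a", m, tc)
  frac <- mean(scr$audit$p < 0.05)
  band <- 1.96 * sqrt(0.05 * 0.95 / 200)
  expect_gt(frac, 0.05 - band)
  expect_lt(frac, 0.05 + band)
})

test_that("screen output is nested across q thresholds and ordered by q", {
  set.seed(55)
  d <- generate_design(20, 7, seed = 5)
  m <- generate_proteome(d, n_catalogue = 40, mean_detected_per_plex = 40,
                         sd_detected_per_plex = 0, seed = 6)
  tt <- truth_table(b0 = -3, slopes = c(PROT00001 = 0.9, PROT00002 = -0.9),
                    sigma_B = 0.3, sigma_e = 0.6)
  tc <- generate_carotenoids(m, list(a = tt), d, seed = 7)
  lo <- screen_analyte("a", m, tc, q_threshold = 0.01)
  hi <- screen_analyte("a", m, tc, q_threshold = 0.10)
  expect_true(all(lo$hits$protein_id %in% hi$hits$protein_id))
  expect_true(!is.unsorted(hi$hits$q))
  expect_identical(hi$audit[!is.na(hi$audit$q) & hi$audit$q < 0.10, ]$protein_id,
                   hi$hits$protein_id)
  # audit completeness: every fitted-or-skipped protein is accounted for
  expect_equal(nrow(hi$audit) + nrow(hi$skipped), ncol(m$values))
  # R2 = r^2 and sign(r) = sign(b1) on every emitted record
  expect_equal(hi$audit$R2, hi$audit$r^2, tolerance = 1e-12)
  expect_true(all(sign(hi$audit$r) == sign(hi$audit$b1_raw)))
})

test_that("carotenoid correlations use pairwise-complete data with Fisher-z p-values", {
  y1 <- c(1, 2, 3, 4, 5, 6)
  conc <- cbind(a = 2^y1, b = 2^(-y1), c = 2^c(2, 1, 4, 3, 7, 5))
  rownames(conc) <- paste0("s", 1:6)
  below <- matrix(FALSE, 6, 3, dimnames = dimnames(conc))
  below[5:6, "c"] <- TRUE      # missingness pattern for pair (a, c)
  cc <- carotenoid_correlations(make_ctab(conc, below))
  expect_equal(diag(cc$r), c(a = 1, b = 1, c = 1))
  expect_equal(cc$r["a", "b"], -1)
  expect_equal(cc$r, t(cc$r))
  # hand computation on the 4 intersecting samples of (a, c)
  expect_equal(cc$n["a", "c"], 4)
  expect_equal(cc$r["a", "c"], cor(y1[1:4], c(2, 1, 4, 3)))
  z <- atanh(cc$r["a", "c"]) * sqrt(4 - 3)
  expect_equal(cc$p["a", "c"], 2 * pnorm(-abs(z)))
  # a pair with < 3 complete samples is flagged missing
  below2 <- below; below2[3:6, "c"] <- TRUE
  cc2 <- carotenoid_correlations(make_ctab(conc, below2))
  expect_true(is.na(cc2$r["a", "c"]))
})

test_that("protein correlate matrix matches direct Pearson computation and ordering", {
  ids <- paste0("s", 1:30)
  set.seed(8)
  A <- rnorm(30)
  v <- cbind(P1 = A, P2 = A, P3 = -A + rnorm(30, 0, 0.2), P4 = rnorm(30))
  rownames(v) <- ids
  m <- abundance_matrix(v, setNames(rep(1:5, each = 6), ids))
  rec <- data.frame(protein_id = c("P1", "P2", "P3", "P4"),
                    gene_symbol = c("G1", "G2", "G3", "G4"),
                    q = c(0.001, 0.01, 0.02, 0.2),
                    p = c(0.0001, 0.001, 0.002, 0.1),
                    b1_raw = c(0.5, 0.4, -0.6, 0.1))
  pm <- proteome_correlation_matrix(rec, m, q_cut = 0.05)
  # q = 0.2 excluded; positives (G1, G2) by ascending q, then negative G3
  expect_identical(rownames(pm), c("G1", "G2", "G3"))
  expect_equal(diag(pm), setNames(rep(1, 3), c("G1", "G2", "G3")))
  expect_equal(pm["G1", "G2"], 1)           # duplicated columns
  expect_equal(pm["G1", "G3"], cor(A, v[, "P3"]))
  expect_equal(pm, t(pm))
})
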