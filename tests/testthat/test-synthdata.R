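test_that("plex design lays out analytic and QC slots as specified", {
  d <- generate_design(72, 7, seed = 1)
  expect_equal(sum(!d$is_qc), 504)
  expect_equal(attr(d, "n_plexes"), 72)
  expect_equal(sum(d$is_qc), 72)
  expect_equal(sort(unique(d$plex)), 1:72)                # contiguous
  expect_true(all(tapply(!d$is_qc, d$plex, sum) == 7))
  expect_true(all(tapply(d$is_qc, d$plex, sum) == 1))     # one QC each

  tiny <- generate_design(1, 2, seed = 5)
  expect_equal(sum(!tiny$is_qc), 2)
  expect_equal(unique(tiny$plex), 1)

  expect_identical(generate_design(6, 4, seed = 7), generate_design(6, 4, seed = 7))
  expect_error(generate_design(0, 7), "invalid design")
  expect_error(generate_design(3, 1), "invalid design")

  sub <- generate_design(72, 7, seed = 2, n_analytic = 500)
  expect_equal(sum(!sub$is_qc), 500)
  expect_true(all(tapply(!sub$is_qc, sub$plex, sum) >= 1))
})

test_that("proteome generator honours detection structure and centering", {
  d <- generate_design(5, 7, seed = 1)
  # forced full detection: no missing values, within-plex medians all zero
  m <- generate_proteome(d, n_catalogue = 40, mean_detected_per_plex = 40,
                         sd_detected_per_plex = 0, seed = 2)
  expect_false(anyNA(m$values))
  for (r in 1:5) {
    rows <- names(m$plex)[m$plex == r & !m$is_qc]
    meds <- apply(m$values[rows, , drop = FALSE], 2, median)
    expect_true(all(abs(meds) < 1e-12))
  }
  # empty catalogue keeps the sample index
  e <- generate_proteome(d, n_catalogue = 0, mean_detected_per_plex = 0,
                         sd_detected_per_plex = 0, seed = 1)
  expect_equal(dim(e$values), c(nrow(d), 0L))
  expect_equal(rownames(e$values), d$sample_id)
  expect_error(generate_proteome(d, n_catalogue = 10,
                                 mean_detected_per_plex = 20),
               "invalid parameters")
  # determinism
  m2 <- generate_proteome(d, n_catalogue = 40, mean_detected_per_plex = 20,
                          sd_detected_per_plex = 4, seed = 9)
  m3 <- generate_proteome(d, n_catalogue = 40, mean_detected_per_plex = 20,
                          sd_detected_per_plex = 4, seed = 9)
  expect_identical(m2, m3)
})

test_that("per-plex detected counts track the stated mean within Monte-Carlo error", {
  d <- generate_design(72, 7, seed = 3)
  m <- generate_proteome(d, n_catalogue = 4705, mean_detected_per_plex = 589,
                         sd_detected_per_plex = 65, seed = 4)
  counts <- sapply(1:72, function(r) {
    rows <- which(m$plex == r)
    sum(colSums(!is.na(m$values[rows, , drop = FALSE])) > 0)
  })
  se <- 65 / sqrt(72)
  expect_lt(abs(mean(counts) - 589), 2 * se)
})

test_that("missingness operates at the plex level", {
  d <- generate_design(6, 5, seed = 2)
  m <- generate_proteome(d, n_catalogue = 30, mean_detected_per_plex = 12,
                         sd_detected_per_plex = 3, seed = 3)
  for (r in 1:6) {
    rows <- which(m$plex == r)
    nas <- colSums(is.na(m$values[rows, , drop = FALSE]))
    expect_true(all(nas == 0 | nas == length(rows)))
  }
})

test_that("carotenoid generator reproduces the mixed-model law exactly when noise-free", {
  d <- generate_design(4, 5, seed = 1)
  m <- generate_proteome(d, n_catalogue = 10, mean_detected_per_plex = 10,
                         sd_detected_per_plex = 0, seed = 2)
  # all slopes zero, no noise: log2 concentration == b0 everywhere
  tt0 <- truth_table(b0 = -2, sigma_B = 0, sigma_e = 0)
  t0 <- generate_carotenoids(m, list(a = tt0), d, seed = 1)
  expect_true(all(abs(log2(t0$concentrations[, "a"]) + 2) < 1e-12))
  # unit slope, no noise: log2 concentration - b0 equals that protein's value
  tt1 <- truth_table(b0 = -2, slopes = c(PROT00003 = 1),
                     sigma_B = 0, sigma_e = 0)
  t1 <- generate_carotenoids(m, list(a = tt1), d, seed = 1)
  an <- d$sample_id[!d$is_qc]
  expect_equal(unname(log2(t1$concentrations[an, "a"]) + 2),
               unname(m$values[an, "PROT00003"]), tolerance = 1e-12)
  expect_error(
    generate_carotenoids(m, list(a = truth_table(0, c(NOPE = 1))), d),
    "unknown protein")
})

test_that("generated log2 variance decomposes as b1^2 Var(P) + sigma_B^2 + sigma_e^2", {
  d <- generate_design(80, 7, seed = 5)
  m <- generate_proteome(d, n_catalogue = 5, mean_detected_per_plex = 5,
                         sd_detected_per_plex = 0, abundance_sd = 1, seed = 6)
  tt <- truth_table(b0 = 0, slopes = c(PROT00001 = 0.8),
                    sigma_B = 0.5, sigma_e = 0.7)
  tc <- generate_carotenoids(m, list(a = tt), d, seed = 7)
  an <- d$sample_id[!d$is_qc]
  v_obs <- var(log2(tc$concentrations[an, "a"]))
  v_exp <- 0.8^2 * var(m$values[an, "PROT00001"]) + 0.5^2 + 0.7^2
  expect_lt(abs(v_obs - v_exp) / v_exp, 0.15)   # n = 560 Monte-Carlo slack
})

test_that("censoring is flagged, retained, and monotone in the detection limit", {
  d <- generate_design(10, 7, seed = 8)
  m <- generate_proteome(d, n_catalogue = 3, mean_detected_per_plex = 3,
                         sd_detected_per_plex = 0, seed = 9)
  lims <- c(0.005, 0.02, 0.08, 0.3)
  detectable <- sapply(lims, function(L) {
    tt <- truth_table(b0 = log2(0.06), sigma_B = 0.3, sigma_e = 0.9,
                      detection_limit = L)
    tc <- generate_carotenoids(m, list(a = tt), d, seed = 10)
    expect_false(anyNA(tc$concentrations[, "a"]))  # values retained
    sum(!tc$below_lod[, "a"])
  })
  expect_true(all(diff(detectable) <= 0))  # higher limit, fewer detectable
  # flags align with the limit exactly
  tt <- truth_table(b0 = log2(0.06), sigma_B = 0.3, sigma_e = 0.9,
                    detection_limit = 0.05)
  tc <- generate_carotenoids(m, list(a = tt), d, seed = 11)
  expect_identical(unname(tc$below_lod[, "a"]),
                   unname(tc$concentrations[, "a"] < 0.05))
})

test_that("default truths reproduce the survey's detectable fractions", {
  truths <- default_truths()
  expect_named(truths, carotenoid_reference$analyte)
  set.seed(42)
  for (i in seq_len(nrow(carotenoid_reference))) {
    tt <- truths[[i]]
    y <- rnorm(2e5, tt$b0, sqrt(tt$sigma_B^2 + tt$sigma_e^2))
    p_emp <- mean(2^y >= tt$detection_limit)
    expect_lt(abs(p_emp - carotenoid_reference$n_detect[i] / 500), 0.01)
    expect_lt(abs(median(2^y) - carotenoid_reference$median[i]),
              0.05 * carotenoid_reference$median[i] + 1e-3)
  }
})
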