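#' Reference marginals for the five plasma carotenoids
#'
#' Published survey statistics for plasma carotenoids (umol/L) in 500
#' school-aged children from rural Nepal, used as the default stated world
#' of the synthetic generator: per-analyte median, interquartile range and
#' the number of samples (of 500) with detectable concentration. On the
#' log2 scale the generator treats each analyte as normal with mean
#' `log2(median)` and SD `log2(q3/q1) / 1.349`, and places the detection
#' limit at the quantile that reproduces the printed detectable count.
#'
#' @format data.frame with columns `analyte`, `n_detect`, `median`, `q1`,
#'   `q3`.
#' @export
carotenoid_reference <- data.frame(
  analyte  = c("beta-carotene", "lutein/zeaxanthin", "beta-cryptoxanthin",
               "alpha-carotene", "lycopene"),
  n_detect = c(497L, 500L, 500L, 481L, 171L),
  median   = c(0.10, 0.34, 0.06, 0.01, 0.02),
  q1       = c(0.06, 0.25, 0.04, 0.01, 0.01),
  q3       = c(0.19, 0.48, 0.12, 0.02, 0.03),
  stringsAsFactors = FALSE
)

#' Plex design: samples allocated to multiplexed experiments
#'
#' Lays out `n_plexes` iTRAQ-style experiments, each carrying
#' `samples_per_plex` study samples plus one pooled quality-control (QC)
#' channel. QC slots mirror the laboratory 8-plex layout but are flagged and
#' excluded from every analytic output. The default dimensions reproduce
#' the emulated study: 72 plexes x 7 study samples = 504 analytic slots, of
#' which the study used 500; pass `n_analytic = 500` to subsample slots at
#' random (each plex always keeps at least one study sample).
#'
#' @param n_plexes number of plexes (>= 1).
#' @param samples_per_plex study samples per plex (>= 2), QC not counted.
#' @param seed integer seed; only consumed when `n_analytic` subsamples.
#' @param n_analytic optional total number of analytic samples to retain.
#' @return A `plex_design`: data.frame with columns `sample_id`, `plex`
#'   (integer, contiguous from 1) and `is_qc`.
#' @export
generate_design <- function(n_plexes, samples_per_plex, seed = 1L,
                            n_analytic = NULL) {
  if (n_plexes < 1 || samples_per_plex < 2)
    stop("invalid design: need n_plexes >= 1 and samples_per_plex >= 2")
  set.seed(seed)
  plex <- rep(seq_len(n_plexes), each = samples_per_plex)
  d <- data.frame(
    sample_id = sprintf("S%04d", seq_along(plex)),
    plex = plex, is_qc = FALSE, stringsAsFactors = FALSE)
  qc <- data.frame(sample_id = sprintf("QC%03d", seq_len(n_plexes)),
                   plex = seq_len(n_plexes), is_qc = TRUE,
                   stringsAsFactors = FALSE)
  if (!is.null(n_analytic)) {
    if (n_analytic > nrow(d) || n_analytic < n_plexes)
      stop("invalid design: n_analytic must lie in [n_plexes, n_plexes*samples_per_plex]")
    keep <- unlist(lapply(split(seq_len(nrow(d)), d$plex), function(i)
      i[sample.int(length(i), 1L)]))            # guarantee >=1 per plex
    pool <- setdiff(seq_len(nrow(d)), keep)
    keep <- sort(c(keep, sample(pool, n_analytic - length(keep))))
    d <- d[keep, , drop = FALSE]
  }
  out <- rbind(d, qc)
  out <- out[order(out$plex, out$is_qc, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("plex_design", "data.frame"),
            n_plexes = n_plexes)
}

#' @export
print.plex_design <- function(x, ...) {
  cat(sprintf("Plex design: %d plexes, %d analytic samples, %d QC slots\n",
              attr(x, "n_plexes"), sum(!x$is_qc), sum(x$is_qc)))
  invisible(x)
}

#' Simulate a plex-structured protein abundance matrix
#'
#' Emulates multiplexed proteome quantification: each plex detects a random
#' subset of a protein catalogue (count drawn as a rounded normal with the
#' stated mean and SD, truncated to `[1, n_catalogue]`; defaults 589 +/- 65
#' of 4705, the emulated study's per-plex yield), and a protein undetected
#' in a plex is missing for all of that plex's samples. Detected values are
#' drawn normal on the log2 scale and then referenced to the within-plex
#' per-protein median over study samples, so every per-protein within-plex
#' median is 0 — the relative-abundance convention of iTRAQ reporter-ion
#' data.
#'
#' @param design a [generate_design()] layout.
#' @param n_catalogue size of the protein catalogue (0 gives an empty
#'   matrix that keeps the sample index).
#' @param mean_detected_per_plex,sd_detected_per_plex detected-count
#'   distribution per plex.
#' @param abundance_sd SD of raw log2 abundance draws.
#' @param seed integer seed.
#' @param force_detect protein ids always detected in every plex (useful
#'   when planting ground-truth slopes that must be observed everywhere).
#' @return An `abundance_matrix`: list with `values` (samples x proteins,
#'   NA = undetected), `plex` and `is_qc` (named by sample), and `meta`
#'   (protein_id, gene_symbol, accession).
#' @export
generate_proteome <- function(design, n_catalogue = 4705L,
                              mean_detected_per_plex = 589,
                              sd_detected_per_plex = 65,
                              abundance_sd = 1, seed = 1L,
                              force_detect = character()) {
  stopifnot(inherits(design, "plex_design"))
  if (mean_detected_per_plex > n_catalogue)
    stop("invalid parameters: mean_detected_per_plex exceeds n_catalogue")
  if (abundance_sd <= 0) stop("invalid parameters: abundance_sd must be > 0")
  set.seed(seed)
  ids <- if (n_catalogue > 0) sprintf("PROT%05d", seq_len(n_catalogue))
         else character()
  meta <- data.frame(
    protein_id = ids,
    gene_symbol = if (n_catalogue > 0) sprintf("GENE%05d", seq_len(n_catalogue)) else character(),
    accession = if (n_catalogue > 0)
      sprintf("%09d", sample.int(999999999L, n_catalogue)) else character(),
    stringsAsFactors = FALSE)
  vals <- matrix(NA_real_, nrow = nrow(design), ncol = n_catalogue,
                 dimnames = list(design$sample_id, ids))
  if (n_catalogue > 0) {
    bad <- setdiff(force_detect, ids)
    if (length(bad)) stop("unknown protein in force_detect: ",
                          paste(bad, collapse = ", "))
    n_plexes <- attr(design, "n_plexes")
    d_r <- round(stats::rnorm(n_plexes, mean_detected_per_plex,
                              sd_detected_per_plex))
    d_r <- pmin(pmax(d_r, max(1L, length(force_detect))), n_catalogue)
    for (r in seq_len(n_plexes)) {
      rows <- which(design$plex == r)
      extra <- sample(setdiff(ids, force_detect),
                      d_r[r] - length(force_detect))
      det <- c(force_detect, extra)
      vals[rows, det] <- stats::rnorm(length(rows) * length(det),
                                      0, abundance_sd)
    }
  }
  m <- structure(list(values = vals,
                      plex = stats::setNames(design$plex, design$sample_id),
                      is_qc = stats::setNames(design$is_qc, design$sample_id),
                      meta = meta),
                 class = "abundance_matrix")
  median_center(m)
}

#' @export
print.abundance_matrix <- function(x, ...) {
  v <- x$values[!x$is_qc, , drop = FALSE]
  cat(sprintf("Abundance matrix: %d analytic samples (+%d QC) x %d proteins; %.1f%% missing\n",
              nrow(v), sum(x$is_qc), ncol(v),
              if (length(v)) 100 * mean(is.na(v)) else 0))
  invisible(x)
}

#' Ground truth for one synthetic carotenoid analyte
#'
#' Describes the generative law of one analyte's log2 concentration:
#' intercept `b0` (log2 umol/L), per-protein slopes (zero for proteins not
#' listed), plex random-intercept SD `sigma_B`, residual SD `sigma_e`, and
#' the assay detection limit (umol/L) below which a generated concentration
#' is flagged.
#'
#' @param b0 intercept, log2 umol/L.
#' @param slopes named numeric vector, protein_id -> raw slope.
#' @param sigma_B plex random-effect SD (>= 0).
#' @param sigma_e residual SD (>= 0; zero gives a noise-free generative
#'   check, though a fitted model always reports a positive residual
#'   variance).
#' @param detection_limit assay detection limit, umol/L (> 0).
#' @return object of class `truth_table`.
#' @export
truth_table <- function(b0, slopes = numeric(), sigma_B = 0.3,
                        sigma_e = 0.9, detection_limit = 1e-4) {
  stopifnot(sigma_B >= 0, sigma_e >= 0, detection_limit > 0)
  if (length(slopes) && is.null(names(slopes)))
    stop("slopes must be named by protein_id")
  structure(list(b0 = b0, slopes = slopes, sigma_B = sigma_B,
                 sigma_e = sigma_e, detection_limit = detection_limit),
            class = "truth_table")
}

#' Default per-analyte truths matching the published survey marginals
#'
#' Builds one [truth_table()] per analyte in [carotenoid_reference]: null
#' slopes, total log2-scale variance from the printed IQR, 10% of that
#' variance assigned to the plex random intercept (a modest batch-effect
#' share; the survey does not report one), and the detection limit at the
#' log-normal quantile reproducing the printed detectable fraction (for
#' analytes detected in all samples the limit is placed 6 SD below the
#' mean, i.e. effectively never censoring).
#'
#' @param icc share of log2-scale variance given to the plex intercept.
#' @param n_total survey denominator for the detectable fraction.
#' @return named list of `truth_table`s.
#' @export
default_truths <- function(icc = 0.10, n_total = 500L) {
  ref <- carotenoid_reference
  out <- lapply(seq_len(nrow(ref)), function(i) {
    mu <- log2(ref$median[i])
    sd_tot <- log2(ref$q3[i] / ref$q1[i]) / (2 * stats::qnorm(0.75))
    p_det <- ref$n_detect[i] / n_total
    lod <- if (p_det >= 1) 2^(mu - 6 * sd_tot)
           else 2^(mu + sd_tot * stats::qnorm(1 - p_det))
    truth_table(b0 = mu, sigma_B = sqrt(icc) * sd_tot,
                sigma_e = sqrt(1 - icc) * sd_tot, detection_limit = lod)
  })
  stats::setNames(out, ref$analyte)
}

#' Generate carotenoid concentrations from the mixed-model law
#'
#' For each analyte draws \deqn{N_{rk} = b_0 + \sum_j b_{1j} P_{jk} + B_r +
#' \varepsilon_k} on the log2 scale, with `B_r ~ N(0, sigma_B^2)` per plex
#' and `eps ~ N(0, sigma_e^2)` per sample, then exponentiates to umol/L and
#' flags concentrations below the detection limit. Below-limit values are
#' retained with a flag; exclusion happens downstream in
#' [prepare_response()]. Samples in which a slope-carrying protein is
#' undetected get a missing concentration (the model is then undefined for
#' them).
#'
#' @param abundance an [generate_proteome()] matrix (QC rows are skipped).
#' @param truth a [truth_table()] or named list of them (names = analytes);
#'   default [default_truths()].
#' @param design the [generate_design()] layout.
#' @param seed integer seed.
#' @return A `carotenoid_table`: list with `concentrations` (analytic
#'   samples x analytes, umol/L), `below_lod` (logical, same shape) and
#'   `analytes`.
#' @export
generate_carotenoids <- function(abundance, truth = default_truths(),
                                 design, seed = 1L) {
  stopifnot(inherits(abundance, "abundance_matrix"),
            inherits(design, "plex_design"))
  if (inherits(truth, "truth_table")) truth <- list(analyte = truth)
  set.seed(seed)
  an <- design[!design$is_qc, , drop = FALSE]
  n_plexes <- attr(design, "n_plexes")
  conc <- matrix(NA_real_, nrow(an), length(truth),
                 dimnames = list(an$sample_id, names(truth)))
  lod <- matrix(FALSE, nrow(an), length(truth),
                dimnames = dimnames(conc))
  for (j in seq_along(truth)) {
    tt <- truth[[j]]
    stopifnot(inherits(tt, "truth_table"))
    y <- rep(tt$b0, nrow(an))
    if (length(tt$slopes)) {
      missing_prot <- setdiff(names(tt$slopes), colnames(abundance$values))
      if (length(missing_prot))
        stop("unknown protein in truth slopes: ",
             paste(missing_prot, collapse = ", "))
      P <- abundance$values[an$sample_id, names(tt$slopes), drop = FALSE]
      y <- y + as.vector(P %*% tt$slopes)   # NA propagates when undetected
    }
    B <- stats::rnorm(n_plexes, 0, tt$sigma_B)
    y <- y + B[an$plex] + stats::rnorm(nrow(an), 0, tt$sigma_e)
    conc[, j] <- 2^y
    lod[, j] <- !is.na(y) & conc[, j] < tt$detection_limit
  }
  structure(list(concentrations = conc, below_lod = lod,
                 analytes = names(truth)),
            class = "carotenoid_table")
}

#' @export
print.carotenoid_table <- function(x, ...) {
  cat(sprintf("Carotenoid table: %d samples x %d analytes\n",
              nrow(x$concentrations), length(x$analytes)))
  for (a in x$analytes)
    cat(sprintf("  %-20s detectable %d/%d\n", a,
                sum(!x$below_lod[, a] & !is.na(x$concentrations[, a])),
                nrow(x$concentrations)))
  invisible(x)
}
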