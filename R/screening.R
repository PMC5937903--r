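#' Storey q-values for false discovery rate control
#'
#' Converts a vector of p-values into q-values
#' \deqn{q_{(i)} = \hat\pi_0 \min_{j \ge i} \frac{m\,p_{(j)}}{j}}
#' clipped to \[0, 1\]. The null proportion \eqn{\hat\pi_0} is estimated by
#' the Storey-Tibshirani smoother: \eqn{\hat\pi_0(\lambda) = \#\{p >
#' \lambda\} / (m(1-\lambda))} over \eqn{\lambda = 0.05, 0.10, \dots, 0.95},
#' smoothed by a natural cubic spline (df = 3) and read off at the largest
#' \eqn{\lambda}. When fewer than 100 p-values are supplied, or the
#' smoother yields a value outside (0, 1\], the estimate falls back to
#' \eqn{\hat\pi_0 = 1}, at which point the q-values coincide with the
#' Benjamini-Hochberg step-up adjustment. Ranking by q never contradicts
#' ranking by p.
#'
#' @param p numeric p-values in \[0, 1\].
#' @param pi0 optional fixed null proportion; overrides estimation
#'   (e.g. `pi0 = 1` forces BH equivalence).
#' @return numeric q-values, same order as `p`; the `pi0` used is attached
#'   as an attribute.
#' @export
qvalues <- function(p, pi0 = NULL) {
  if (length(p) == 0L) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("invalid input: p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) pi0 <- estimate_pi0(p)
  o <- order(p)
  q <- pi0 * m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))          # min over the upper tail
  q <- pmin(pmax(q, 0), 1)
  out <- numeric(m)
  out[o] <- q
  attr(out, "pi0") <- pi0
  out
}

# Storey-Tibshirani pi0 smoother with conservative fallback.
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  if (m < 100L) return(1)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  pi0 <- tryCatch({
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    stats::predict(fit, x = max(lambda))$y
  }, error = function(e) NA_real_)
  if (is.na(pi0) || pi0 <= 0 || pi0 > 1) 1 else pi0
}

#' Proteome-wide screen of one carotenoid
#'
#' Fits one random-intercept model per eligible protein (log2 analyte
#' concentration on log2 relative abundance, plex as random intercept),
#' derives the Wald p-value, BLUP-based r and R^2 and the percent-change
#' effect, computes q-values over the full vector of per-protein p-values,
#' and returns the records passing `q < q_threshold` sorted by ascending q
#' then p. The complete unfiltered table is kept for audit, as are skip
#' reasons for proteins below the data floors.
#'
#' @param analyte analyte name in `carotenoids`.
#' @param abundance an `abundance_matrix`, already detection-filtered.
#' @param carotenoids a `carotenoid_table`.
#' @param q_threshold report threshold on the q-value (default 0.10).
#' @param min_n,min_groups per-protein data floors passed to [relme()].
#' @param pi0 optional fixed null proportion for [qvalues()].
#' @return object of class `carot_screen`: list with `hits` (records with
#'   q < threshold), `audit` (every fitted protein), `skipped`
#'   (protein, reason), `analyte`, `n_response`, `pi0`.
#' @export
screen_analyte <- function(analyte, abundance, carotenoids,
                           q_threshold = 0.10, min_n = 10L,
                           min_groups = 2L, pi0 = NULL) {
  stopifnot(inherits(abundance, "abundance_matrix"),
            inherits(carotenoids, "carotenoid_table"),
            q_threshold > 0, q_threshold < 1)
  resp <- prepare_response(carotenoids, analyte)
  empty <- data.frame(gene_symbol = character(), accession = character(),
                      protein_id = character(), n = integer(),
                      r = numeric(), R2 = numeric(), p = numeric(),
                      q = numeric(), b1_pct = numeric(), b1_raw = numeric(),
                      stringsAsFactors = FALSE)
  if (length(resp$log2_conc) == 0L) {
    message("screen skipped for ", analyte, ": no detectable samples")
    return(structure(list(hits = empty, audit = empty,
                          skipped = data.frame(protein_id = character(),
                                               reason = character()),
                          analyte = analyte, n_response = 0L, pi0 = NA_real_),
                     class = "carot_screen"))
  }
  samp <- intersect(names(resp$log2_conc),
                    rownames(abundance$values)[!abundance$is_qc])
  yv <- resp$log2_conc[samp]
  gx <- abundance$plex[samp]
  prots <- colnames(abundance$values)
  rows <- vector("list", length(prots))
  skipped <- list()
  meta <- abundance$meta
  mi <- match(prots, meta$protein_id)
  for (j in seq_along(prots)) {
    xv <- abundance$values[samp, prots[j]]
    rec <- tryCatch({
      fit <- relme(xv, yv, gx, min_n = min_n, min_groups = min_groups)
      st <- association_stats(fit)
      data.frame(gene_symbol = meta$gene_symbol[mi[j]],
                 accession = meta$accession[mi[j]],
                 protein_id = prots[j], n = fit$n_obs,
                 r = st$r, R2 = st$R2, p = wald_p(fit), q = NA_real_,
                 b1_pct = percent_change(fit$b1), b1_raw = fit$b1,
                 stringsAsFactors = FALSE)
    }, relme_error = function(e) {
      skipped[[length(skipped) + 1L]] <<-
        data.frame(protein_id = prots[j], reason = conditionMessage(e),
                   stringsAsFactors = FALSE)
      NULL
    })
    rows[[j]] <- rec
  }
  audit <- do.call(rbind, rows)
  if (is.null(audit)) audit <- empty
  skipped <- if (length(skipped)) do.call(rbind, skipped)
             else data.frame(protein_id = character(), reason = character())
  pi0_used <- NA_real_
  if (nrow(audit)) {
    qv <- qvalues(audit$p, pi0 = pi0)
    pi0_used <- attr(qv, "pi0")
    audit$q <- as.numeric(qv)
    audit <- audit[order(audit$q, audit$p), , drop = FALSE]
    rownames(audit) <- NULL
  }
  hits <- audit[!is.na(audit$q) & audit$q < q_threshold, , drop = FALSE]
  rownames(hits) <- NULL
  structure(list(hits = hits, audit = audit, skipped = skipped,
                 analyte = analyte, n_response = length(resp$log2_conc),
                 pi0 = pi0_used),
            class = "carot_screen")
}

#' @export
print.carot_screen <- function(x, ...) {
  cat(sprintf("Screen of %s: %d proteins fitted, %d skipped, %d hits (pi0 = %s)\n",
              x$analyte, nrow(x$audit), nrow(x$skipped), nrow(x$hits),
              format(x$pi0, digits = 3)))
  if (nrow(x$hits)) {
    show <- x$hits[, c("gene_symbol", "n", "r", "R2", "p", "q", "b1_pct")]
    show$r <- round(show$r, 2); show$R2 <- round(show$R2, 2)
    show$p <- signif(show$p, 3); show$q <- signif(show$q, 3)
    show$b1_pct <- round(show$b1_pct, 1)
    print(utils::head(show, 20), row.names = FALSE)
    if (nrow(x$hits) > 20) cat("  ...\n")
  }
  invisible(x)
}

#' Pairwise-complete correlations between carotenoids
#'
#' Pearson correlations of log2 concentrations across analytes using, for
#' each pair, every sample in which both analytes are detectable. Two-sided
#' p-values come from the large-sample normal approximation of the Fisher
#' z-transformed correlation. Pairs with fewer than 3 complete samples are
#' flagged missing.
#'
#' @param t a `carotenoid_table` with >= 2 analytes.
#' @return list of symmetric analyte x analyte matrices `r`, `n`, `p`
#'   (class `carot_cor`).
#' @export
carotenoid_correlations <- function(t) {
  stopifnot(inherits(t, "carotenoid_table"))
  a <- t$analytes
  if (length(a) < 2L) stop("need at least 2 analytes")
  lg <- log2(t$concentrations)
  lg[t$below_lod | is.na(t$concentrations)] <- NA
  k <- length(a)
  r <- diag(1, k); n <- matrix(NA_integer_, k, k); p <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(n) <- dimnames(p) <- list(a, a)
  diag(n) <- colSums(!is.na(lg))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- !is.na(lg[, i]) & !is.na(lg[, j])
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) < 3L) { r[i, j] <- r[j, i] <- NA_real_; next }
    rij <- stats::cor(lg[ok, i], lg[ok, j])
    r[i, j] <- r[j, i] <- rij
    z <- atanh(min(max(rij, -1 + 1e-15), 1 - 1e-15)) * sqrt(sum(ok) - 3)
    p[i, j] <- p[j, i] <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(r = r, n = n, p = p), class = "carot_cor")
}

#' @export
print.carot_cor <- function(x, digits = 2, ...) {
  cat("Pairwise-complete carotenoid correlations (log2 scale):\n")
  print(round(x$r, digits))
  invisible(x)
}

#' Protein-protein correlation matrix of an analyte's hits
#'
#' Restricts an analyte's association records to `q < q_cut` and computes
#' pairwise Pearson correlations of the proteins' log2 relative abundances
#' over shared non-missing analytic samples. Rows/columns list the
#' positively associated proteins first (ascending q), then the negative
#' ones, mirroring the conventional display of a correlate heatmap.
#'
#' @param records audit or hit data.frame from [screen_analyte()].
#' @param abundance the `abundance_matrix` the screen ran on.
#' @param q_cut stricter q threshold for inclusion (default 0.05).
#' @return correlation matrix with unit diagonal; pairs with < 3 shared
#'   samples are NA. Row order is attached via dimnames (gene symbols).
#' @export
proteome_correlation_matrix <- function(records, abundance, q_cut = 0.05) {
  stopifnot(inherits(abundance, "abundance_matrix"))
  sel <- records[!is.na(records$q) & records$q < q_cut, , drop = FALSE]
  pos <- sel[sel$b1_raw >= 0, , drop = FALSE]
  neg <- sel[sel$b1_raw < 0, , drop = FALSE]
  sel <- rbind(pos[order(pos$q, pos$p), , drop = FALSE],
               neg[order(neg$q, neg$p), , drop = FALSE])
  ids <- sel$protein_id
  v <- abundance$values[!abundance$is_qc, ids, drop = FALSE]
  k <- length(ids)
  m <- diag(1, k)
  dimnames(m) <- list(sel$gene_symbol, sel$gene_symbol)
  if (k >= 2) for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- !is.na(v[, i]) & !is.na(v[, j])
    m[i, j] <- m[j, i] <- if (sum(ok) < 3L) NA_real_
                          else stats::cor(v[ok, i], v[ok, j])
  }
  m
}
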