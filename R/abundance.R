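#' Construct an abundance matrix container
#'
#' @param values samples x proteins numeric matrix of log2 relative
#'   abundance, NA = undetected; rownames are sample ids.
#' @param plex named integer vector, sample_id -> plex index.
#' @param is_qc named logical vector, sample_id -> pooled-QC flag; defaults
#'   to all-FALSE.
#' @param meta data.frame(protein_id, gene_symbol, accession); minimal
#'   metadata is synthesized from column names when absent.
#' @export
abundance_matrix <- function(values, plex, is_qc = NULL, meta = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  plex <- plex[rownames(values)]
  if (anyNA(plex)) stop("every sample needs a plex assignment")
  if (is.null(is_qc))
    is_qc <- stats::setNames(rep(FALSE, nrow(values)), rownames(values))
  if (is.null(meta))
    meta <- data.frame(protein_id = colnames(values),
                       gene_symbol = colnames(values),
                       accession = colnames(values),
                       stringsAsFactors = FALSE)
  if (any(!is.finite(values[!is.na(values)])))
    stop("abundance values must be finite or NA")
  structure(list(values = values, plex = plex,
                 is_qc = is_qc[rownames(values)], meta = meta),
            class = "abundance_matrix")
}

#' Per-protein detection counts over analytic samples
#'
#' @param m an `abundance_matrix`.
#' @return named integer vector: number of non-missing analytic (non-QC)
#'   samples per protein.
#' @export
detection_counts <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  v <- m$values[!m$is_qc, , drop = FALSE]
  colSums(!is.na(v))
}

#' Within-plex median centering of log2 abundances
#'
#' References every protein to its within-plex median: for each (protein,
#' plex) cell the median of the protein's non-missing values within that
#' plex is subtracted, so the per-protein within-plex median of the output
#' is 0. This is the relative-abundance convention for multiplexed
#' reporter-ion data, where only within-plex contrasts are meaningful. The
#' operation is idempotent. Even-count medians use the midpoint convention.
#'
#' @param m an `abundance_matrix` holding log2-scale values.
#' @param include_qc should QC channels enter the median? Default FALSE
#'   (medians over study samples only); the centering is applied to all
#'   rows either way.
#' @return the centered `abundance_matrix`.
#' @export
median_center <- function(m, include_qc = FALSE) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (ncol(m$values) == 0L) return(m)
  for (r in unique(m$plex)) {
    rows <- which(m$plex == r)
    med_rows <- if (include_qc) rows else rows[!m$is_qc[rows]]
    if (length(med_rows) == 0L) next
    med <- apply(m$values[med_rows, , drop = FALSE], 2, stats::median,
                 na.rm = TRUE)
    med[is.na(med)] <- 0   # protein absent from the whole plex: no shift
    m$values[rows, ] <- sweep(m$values[rows, , drop = FALSE], 2, med)
  }
  m
}

#' Detection-prevalence filter
#'
#' Retains exactly the proteins detected in strictly more than
#' `min_fraction` of the analytic samples — the screen's eligibility rule
#' (e.g. >10% of 500 samples means n > 50, so a protein at n = 50 is
#' dropped and n = 51 kept).
#'
#' @param m an `abundance_matrix`.
#' @param total_samples denominator for the fraction; defaults to the
#'   number of analytic samples in `m`.
#' @param min_fraction detection fraction that must be strictly exceeded.
#' @return the filtered `abundance_matrix` (metadata subset accordingly).
#' @export
filter_detection <- function(m, total_samples = NULL, min_fraction = 0.10) {
  stopifnot(inherits(m, "abundance_matrix"),
            min_fraction >= 0, min_fraction < 1)
  if (is.null(total_samples)) total_samples <- sum(!m$is_qc)
  keep <- detection_counts(m) > min_fraction * total_samples
  m$values <- m$values[, keep, drop = FALSE]
  m$meta <- m$meta[m$meta$protein_id %in% colnames(m$values), , drop = FALSE]
  m
}

#' Prepare the log2 carotenoid response for one analyte
#'
#' Returns log2 concentrations for the samples with a detectable
#' measurement; samples flagged below the detection limit (or missing) are
#' excluded, not imputed, and their ids are reported.
#'
#' @param t a `carotenoid_table`.
#' @param analyte analyte name.
#' @return list with `log2_conc` (named numeric), `excluded` (sample ids)
#'   and `analyte`.
#' @export
prepare_response <- function(t, analyte) {
  stopifnot(inherits(t, "carotenoid_table"))
  if (!analyte %in% t$analytes)
    stop("unknown analyte: ", analyte)
  conc <- t$concentrations[, analyte]
  flag <- t$below_lod[, analyte]
  usable <- !is.na(conc) & !flag
  if (any(conc[usable] <= 0))
    stop("data integrity: non-positive concentration without below-LOD flag")
  list(log2_conc = log2(conc[usable]),
       excluded = rownames(t$concentrations)[!usable],
       analyte = analyte)
}
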