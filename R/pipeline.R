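#' Pipeline configuration
#'
#' A run configuration is a plain named list; [default_config()] gives the
#' stated-world defaults (72 plexes x 7 study samples + QC, 4705-protein
#' catalogue with 589 +/- 65 detected per plex, the five survey analytes,
#' the >10% detection filter, q < 0.10 reporting and q < 0.05 for the
#' correlate matrix). [read_config()] loads overrides from a plain
#' `key: value` file (DCF format); list-valued fields are comma-separated,
#' planted truth is written `analyte|protein=slope` entries.
#'
#' @param path DCF file of overrides.
#' @param ... direct overrides by name.
#' @return named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    n_plexes = 72L, samples_per_plex = 7L, n_analytic = 500L,
    n_catalogue = 4705L, mean_detected_per_plex = 589,
    sd_detected_per_plex = 65, abundance_sd = 1,
    analytes = carotenoid_reference$analyte,
    icc = 0.10,
    min_fraction = 0.10, q_threshold = 0.10, q_cut_matrix = 0.05,
    min_n = 10L, min_groups = 2L,
    pi0_policy = "smoother",      # or "fixed1"
    planted = character(),        # e.g. "beta-carotene|PROT00001=0.5"
    seed = 20180515L %% .Machine$integer.max,
    data_dir = "carot_data", out_dir = "carot_out")
  ov <- list(...)
  cfg[names(ov)] <- ov
  validate_config(cfg)
}

#' @rdname default_config
#' @export
read_config <- function(path, ...) {
  if (!file.exists(path)) stop("configuration error: no such file: ", path)
  d <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  num <- c("n_plexes", "samples_per_plex", "n_analytic", "n_catalogue",
           "mean_detected_per_plex", "sd_detected_per_plex", "abundance_sd",
           "icc", "min_fraction", "q_threshold", "q_cut_matrix", "min_n",
           "min_groups", "seed")
  for (k in intersect(names(d), num)) d[[k]] <- as.numeric(d[[k]])
  for (k in intersect(names(d), c("analytes", "planted")))
    d[[k]] <- trimws(strsplit(d[[k]], ",")[[1]])
  do.call(default_config, c(d, list(...)))
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(min_fraction >= 0, min_fraction < 1,
              q_threshold > 0, q_threshold < 1,
              q_cut_matrix > 0, q_cut_matrix < 1,
              icc >= 0, icc < 1, seed == as.integer(seed))
  })
  structure(cfg, class = "run_config")
}

parse_planted <- function(planted) {
  # "analyte|protein=slope" -> list(analyte = c(protein = slope, ...))
  out <- list()
  for (s in planted) {
    m <- regmatches(s, regexec("^([^|]+)\\|([^=]+)=(-?[0-9.eE+-]+)$", s))[[1]]
    if (length(m) != 4) stop("cannot parse planted truth entry: ", s)
    out[[m[2]]] <- c(out[[m[2]]], stats::setNames(as.numeric(m[4]), m[3]))
  }
  out
}

#' Simulate a full dataset to disk
#'
#' Generates design, proteome and carotenoids under the configuration's
#' stated world and writes the TSV dataset plus a JSON manifest echoing the
#' seed and parameters. Deterministic: the same config yields byte-identical
#' files.
#'
#' @param config a `run_config` (see [default_config()]).
#' @return named vector of written paths, invisibly.
#' @export
run_simulate <- function(config = default_config()) {
  cfg <- validate_config(config)
  slots <- cfg$n_plexes * cfg$samples_per_plex
  sub <- !is.null(cfg$n_analytic) && cfg$n_analytic > 0 &&
    cfg$n_analytic < slots   # only subsample when it is a reduction
  design <- generate_design(cfg$n_plexes, cfg$samples_per_plex,
                            seed = cfg$seed,
                            n_analytic = if (sub) cfg$n_analytic else NULL)
  planted <- parse_planted(cfg$planted)
  force_detect <- unique(unlist(lapply(planted, names)))
  m <- generate_proteome(design, n_catalogue = cfg$n_catalogue,
                         mean_detected_per_plex = cfg$mean_detected_per_plex,
                         sd_detected_per_plex = cfg$sd_detected_per_plex,
                         abundance_sd = cfg$abundance_sd,
                         seed = cfg$seed + 1L,
                         force_detect = force_detect %||% character())
  truth <- default_truths(icc = cfg$icc)[cfg$analytes]
  for (a in names(planted)) {
    if (!a %in% names(truth)) stop("planted truth names unknown analyte: ", a)
    truth[[a]]$slopes <- planted[[a]]
  }
  t <- generate_carotenoids(m, truth, design, seed = cfg$seed + 2L)
  paths <- write_dataset(m, t, design, truth, cfg$data_dir)
  manifest <- file.path(cfg$data_dir, "manifest.json")
  jsonlite::write_json(c(list(created_by = "carotscreen::run_simulate"),
                         unclass(cfg)),
                       manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full screen over a simulated or supplied dataset
#'
#' Reads the TSV dataset from `config$data_dir`, re-applies within-plex
#' median centering (idempotent if the data were already centered), applies
#' the detection-prevalence filter, then screens every analyte: one
#' association table per analyte (a formatted TSV mirroring the published
#' table layout plus a full-precision `_full` audit TSV), the analyte
#' correlation matrix, a protein-protein correlate matrix per analyte with
#' >= 2 records at `q < q_cut_matrix`, and a log of skips with reasons.
#'
#' @param config a `run_config`.
#' @return list of `carot_screen` objects by analyte (invisibly); side
#'   effect: files under `config$out_dir`.
#' @export
run_screen <- function(config = default_config()) {
  cfg <- validate_config(config)
  ds <- read_dataset(cfg$data_dir)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "screen.log")
  logf <- file(log_path, open = "wt"); on.exit(close(logf))
  logline <- function(...) writeLines(sprintf(...), logf)
  logline("seed: %d", as.integer(cfg$seed))

  m <- median_center(ds$abundance)
  n_total <- sum(!m$is_qc)
  m <- filter_detection(m, total_samples = n_total,
                        min_fraction = cfg$min_fraction)
  logline("proteins passing >%g%% detection filter of %d samples: %d",
          100 * cfg$min_fraction, n_total, ncol(m$values))

  pi0 <- if (identical(cfg$pi0_policy, "fixed1")) 1 else NULL
  results <- list()
  for (a in intersect(cfg$analytes, ds$carotenoids$analytes)) {
    scr <- screen_analyte(a, m, ds$carotenoids,
                          q_threshold = cfg$q_threshold,
                          min_n = cfg$min_n, min_groups = cfg$min_groups,
                          pi0 = pi0)
    results[[a]] <- scr
    tag <- sanitize_name(a)
    if (scr$n_response == 0L) {
      logline("%s: all samples below detection limit; screen skipped", a)
      next
    }
    for (i in seq_len(nrow(scr$skipped)))
      logline("%s: %s skipped (%s)", a, scr$skipped$protein_id[i],
              scr$skipped$reason[i])
    logline("%s: fitted %d proteins, %d at q < %g (pi0 = %.3f)",
            a, nrow(scr$audit), nrow(scr$hits), cfg$q_threshold, scr$pi0)
    write_association_tsv(scr$hits,
      file.path(cfg$out_dir, paste0("associations_", tag, ".tsv")))
    write_association_tsv(scr$audit,
      file.path(cfg$out_dir, paste0("associations_", tag, "_full.tsv")),
      formatted = FALSE)
    pm <- proteome_correlation_matrix(scr$audit, m,
                                      q_cut = cfg$q_cut_matrix)
    if (nrow(pm) >= 2)
      write_matrix_tsv(pm, file.path(cfg$out_dir,
                                     paste0("protein_cor_", tag, ".tsv")))
  }
  if (length(ds$carotenoids$analytes) >= 2) {
    cc <- carotenoid_correlations(ds$carotenoids)
    write_matrix_tsv(cc$r, file.path(cfg$out_dir, "carotenoid_cor.tsv"))
    write_matrix_tsv(cc$p, file.path(cfg$out_dir, "carotenoid_cor_p.tsv"))
  } else {
    logline("analyte correlation matrix skipped: fewer than 2 analytes")
  }
  invisible(results)
}

sanitize_name <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

# Formatted table mirrors the published layout: r and R2 to 2 decimals,
# p and q in scientific notation, b1 as percent to 1 decimal. The _full
# variant keeps full precision for machines.
write_association_tsv <- function(d, path, formatted = TRUE) {
  out <- data.frame(
    gene_name = d$gene_symbol, gene_symbol = d$gene_symbol, n = d$n,
    r = if (formatted) sprintf("%.2f", d$r) else fmt_num(d$r),
    R2 = if (formatted) sprintf("%.2f", d$R2) else fmt_num(d$R2),
    p = if (formatted) sprintf("%.2e", d$p) else fmt_num(d$p),
    q = if (formatted) sprintf("%.2e", d$q) else fmt_num(d$q),
    b1 = if (formatted) sprintf("%.1f", d$b1_pct) else fmt_num(d$b1_pct),
    accession = d$accession, stringsAsFactors = FALSE)
  if (!formatted) out$b1_raw <- fmt_num(d$b1_raw)
  if (!formatted) out$protein_id <- d$protein_id
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_association_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, na.strings = "")
}
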