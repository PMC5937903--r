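# TSV dialects shared by the generator and the pipeline: first column
# sample_id, header row of protein/analyte identifiers, empty cell = NA.
# Doubles are serialized with %.17g so write-then-read is exact.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- fmt_num(m[, j])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path, what = "numeric") {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", na.strings = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  storage.mode(m) <- what
  m
}

#' Write / read the generated dataset as delimited text
#'
#' Serializes an `abundance_matrix` plus its plex map, a
#' `carotenoid_table` (concentrations and the below-detection flags as two
#' aligned TSVs), and a truth table. All files are plain TSV with a header
#' row; missing values are empty cells; numeric cells round-trip exactly.
#'
#' @param m,t,design,truth the objects produced by the `generate_*`
#'   functions.
#' @param dir output directory (created if needed).
#' @return named character vector of the file paths, invisibly.
#' @export
write_dataset <- function(m, t, design, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(abundance = file.path(dir, "abundance.tsv"),
             plexmap = file.path(dir, "plexmap.tsv"),
             meta = file.path(dir, "protein_meta.tsv"),
             carotenoids = file.path(dir, "carotenoids.tsv"),
             below_lod = file.path(dir, "carotenoids_lod.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_matrix_tsv(m$values, paths["abundance"])
  utils::write.table(
    data.frame(sample_id = names(m$plex), plex = as.integer(m$plex),
               is_qc = m$is_qc[names(m$plex)]),
    paths["plexmap"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(m$meta, paths["meta"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_matrix_tsv(t$concentrations, paths["carotenoids"])
  write_matrix_tsv(t$below_lod * 1L, paths["below_lod"])
  if (inherits(truth, "truth_table")) truth <- list(analyte = truth)
  tr <- do.call(rbind, lapply(names(truth), function(a) {
    tt <- truth[[a]]
    sl <- tt$slopes
    data.frame(analyte = a,
               protein_id = if (length(sl)) names(sl) else NA_character_,
               slope = if (length(sl)) unname(sl) else NA_real_,
               b0 = tt$b0, sigma_B = tt$sigma_B, sigma_e = tt$sigma_e,
               detection_limit = tt$detection_limit,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tr, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  vals <- read_matrix_tsv(file.path(dir, "abundance.tsv"))
  if (!file.exists(file.path(dir, "plexmap.tsv")))
    stop("configuration error: plex map file missing")
  pm <- utils::read.delim(file.path(dir, "plexmap.tsv"))
  meta_path <- file.path(dir, "protein_meta.tsv")
  meta <- if (file.exists(meta_path))
    utils::read.delim(meta_path, colClasses = "character") else NULL
  m <- abundance_matrix(vals,
                        plex = stats::setNames(pm$plex, pm$sample_id),
                        is_qc = stats::setNames(pm$is_qc, pm$sample_id),
                        meta = meta)
  conc <- read_matrix_tsv(file.path(dir, "carotenoids.tsv"))
  lod <- read_matrix_tsv(file.path(dir, "carotenoids_lod.tsv")) > 0
  lod[is.na(lod)] <- FALSE
  t <- structure(list(concentrations = conc, below_lod = lod,
                      analytes = colnames(conc)),
                 class = "carotenoid_table")
  tr <- utils::read.delim(file.path(dir, "truth.tsv"), na.strings = "NA")
  truth <- lapply(split(tr, tr$analyte), function(d) {
    sl <- d$slope[!is.na(d$protein_id)]
    names(sl) <- d$protein_id[!is.na(d$protein_id)]
    truth_table(b0 = d$b0[1], slopes = sl, sigma_B = d$sigma_B[1],
                sigma_e = d$sigma_e[1], detection_limit = d$detection_limit[1])
  })
  list(abundance = m, carotenoids = t, truth = truth)
}
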