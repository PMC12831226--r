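# File formats: gzip/plain TSV matrices (CpGs x samples, first column "cpg"),
# TSV metadata/annotation, gzip TSV EWAS summary statistics, BED or lead-TSV
# loci, JSON reports, YAML or JSON run configs. All readers/writers
# round-trip: write(read(x)) == x.

open_conn <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a measurement matrix as (gzip) TSV
#'
#' Stored transposed relative to the in-memory layout: rows are CpGs, columns
#' samples, first column `cpg`. A `.gz` suffix selects gzip compression.
#'
#' @param mat Samples x CpGs numeric matrix with dimnames.
#' @param path Output path (`.tsv` or `.tsv.gz`).
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(cpg = colnames(mat), t(mat), check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- open_conn(path, "wt")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a measurement matrix written by [write_matrix_tsv()]
#'
#' @param path TSV or gzip TSV with first column `cpg` and one column per
#'   sample.
#' @return Samples x CpGs numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- open_conn(path, "rt")
  on.exit(close(con))
  df <- tryCatch(utils::read.delim(con, check.names = FALSE,
                                   stringsAsFactors = FALSE),
                 error = function(e)
                   stop("malformed matrix file ", path, ": ",
                        conditionMessage(e)))
  if (names(df)[1] != "cpg") stop("malformed matrix file ", path,
                                  ": first column must be 'cpg' (line 1)")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("malformed matrix file ", path,
                           ": non-numeric entries")
  out <- t(m)
  colnames(out) <- df$cpg
  out
}

#' @rdname write_matrix_tsv
#' @param df Data frame to write as plain TSV (metadata, annotation,
#'   association tables).
#' @export
write_table_tsv <- function(df, path) {
  con <- open_conn(path, "wt")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_matrix_tsv
#' @return For `read_table_tsv`, a data frame.
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- open_conn(path, "rt")
  on.exit(close(con))
  utils::read.delim(con, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write EWAS summary statistics (fixed column order, gzip TSV)
#'
#' Columns: `cpg, chrom, pos, effect, se, t, p, n`.
#' @param res An `ewas_result`.
#' @param path Output path, conventionally `ewas.tsv.gz`.
#' @export
write_ewas_tsv <- function(res, path) {
  cols <- c("cpg", "chrom", "pos", "effect", "se", "t", "p", "n")
  write_table_tsv(as.data.frame(res)[, cols], path)
}

#' Read EWAS summary statistics written by [write_ewas_tsv()]
#' @param path Input path.
#' @return An `ewas_result` data frame.
#' @export
read_ewas_tsv <- function(path) {
  df <- read_table_tsv(path)
  need <- c("cpg", "chrom", "pos", "effect", "se", "t", "p", "n")
  if (!all(need %in% names(df)))
    stop("malformed EWAS file ", path, ": missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  class(df) <- c("ewas_result", "data.frame")
  df
}

#' Read GWAS loci from BED or lead-position TSV
#'
#' BED input (`.bed`, 0-based half-open) is converted to 1-based inclusive
#' coordinates (`start + 1`, `end`); the lead position is taken as the
#' window midpoint. TSV input must have columns `chrom`, `pos` (1-based
#' leads) and windows are derived as lead +- `window`.
#'
#' @param path BED or TSV file.
#' @param window Half-width for TSV leads, default 100000.
#' @return A [loci_set()].
#' @export
read_loci <- function(path, window = 100000) {
  if (grepl("\\.bed$", path)) {
    raw <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(raw) < 3) stop("malformed BED file ", path)
    start1 <- raw[[2]] + 1L                 # 0-based half-open -> 1-based incl.
    end1 <- raw[[3]]
    out <- data.frame(chrom = raw[[1]],
                      pos = as.integer(floor((start1 + end1) / 2)),
                      name = if (ncol(raw) >= 4) raw[[4]]
                             else paste0("locus", seq_len(nrow(raw))),
                      start = as.integer(start1), end = as.integer(end1),
                      stringsAsFactors = FALSE)
    structure(out, class = c("loci_set", "data.frame"))
  } else {
    df <- read_table_tsv(path)
    if (!all(c("chrom", "pos") %in% names(df)))
      stop("lead TSV must have columns chrom, pos: ", path)
    loci_set(df, window = window)
  }
}

#' Write loci as 6-column BED plus a lead-position TSV
#'
#' The BED uses 0-based half-open windows (`start - 1`, `end`); the TSV the
#' 1-based leads.
#' @param loci A [loci_set()].
#' @param bed_path,tsv_path Output paths.
#' @export
write_loci <- function(loci, bed_path, tsv_path = NULL) {
  bed <- data.frame(chrom = loci$chrom, start = loci$start - 1L,
                    end = loci$end, name = loci$name, score = 0,
                    strand = ".")
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(tsv_path))
    write_table_tsv(loci[, c("chrom", "pos", "name")], tsv_path)
  invisible(bed_path)
}

#' Write a simulated or loaded tissue dataset to a directory
#'
#' Emits `beta.tsv.gz`, `detection_p.tsv.gz`, `bead_count.tsv.gz`,
#' `samples.tsv`, `probes.tsv` under `dir`.
#' @param ds A [methylation_dataset()].
#' @param dir Output directory (created if needed).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(ds$beta, file.path(dir, "beta.tsv.gz"))
  if (!is.null(ds$detection_p))
    write_matrix_tsv(ds$detection_p, file.path(dir, "detection_p.tsv.gz"))
  if (!is.null(ds$bead_count))
    write_matrix_tsv(ds$bead_count, file.path(dir, "bead_count.tsv.gz"))
  write_table_tsv(ds$samples, file.path(dir, "samples.tsv"))
  write_table_tsv(ds$probes, file.path(dir, "probes.tsv"))
  invisible(dir)
}

#' Read a tissue dataset directory written by [write_dataset()]
#' @param dir Dataset directory.
#' @return A [methylation_dataset()].
#' @export
read_dataset <- function(dir) {
  beta <- read_matrix_tsv(file.path(dir, "beta.tsv.gz"))
  dp <- file.path(dir, "detection_p.tsv.gz")
  bc <- file.path(dir, "bead_count.tsv.gz")
  methylation_dataset(
    beta,
    samples = read_table_tsv(file.path(dir, "samples.tsv")),
    probes = read_table_tsv(file.path(dir, "probes.tsv")),
    detection_p = if (file.exists(dp)) read_matrix_tsv(dp),
    bead_count = if (file.exists(bc)) {
      m <- read_matrix_tsv(bc); storage.mode(m) <- "integer"; m
    })
}

#' Read a run configuration from YAML or JSON
#' @param path `.yaml`/`.yml` or `.json` file of [run_config()] fields.
#' @return The parsed list (validated by [run_config()]).
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.(ya?ml)$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

#' Write a JSON report or object
#' @param x Object serializable by jsonlite.
#' @param path Output path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
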