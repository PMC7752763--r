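.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
}

.read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

.write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1L] <- id_col
  .write_tsv(df, path)
}

.read_matrix_tsv <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write a synthetic dataset to plain-text fixtures
#'
#' Emits one contig FASTA per time point (contigs detected in MG or MT data
#' at that date; host contigs are present throughout), tab-separated tables
#' for CRISPR elements, binning, depth and predictor flags, the ground truth
#' as JSON, and a manifest with MD5 checksums of every file. Re-reading with
#' [read_fixtures()] reproduces the dataset.
#'
#' @param dataset a `synthetic_community`.
#' @param out_dir output directory (created if needed).
#' @return the manifest (invisibly): list with `files` (named md5 vector),
#'   `n_timepoints` and `n_contigs`.
#' @export
write_fixtures <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "synthetic_community"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- character(0)
  date_ids <- .iso_date(dataset$dates)
  for (i in seq_along(date_ids)) {
    present <- dataset$depth_mg[, i] > 0 | dataset$depth_mt[, i] > 0
    fa <- Biostrings::DNAStringSet(dataset$contigs[present])
    p <- file.path(out_dir, sprintf("contigs_%s.fasta", date_ids[i]))
    Biostrings::writeXStringSet(fa, p)
    paths <- c(paths, p)
  }
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    .write_tsv(df, p)
    paths <<- c(paths, p)
  }
  tsv(dataset$elements, "elements.tsv")
  tsv(dataset$contig2mag, "contig_mag.tsv")
  tsv(dataset$mag2rmag, "mag_rmag.tsv")
  tsv(dataset$rmag2family, "rmag_family.tsv")
  tsv(dataset$flags, "predictor_flags.tsv")
  tsv(data.frame(sample = date_ids, date = date_ids), "sample_dates.tsv")
  p <- file.path(out_dir, "depth_mg.tsv")
  .write_matrix_tsv(dataset$depth_mg, p, "contig"); paths <- c(paths, p)
  p <- file.path(out_dir, "depth_mt.tsv")
  .write_matrix_tsv(dataset$depth_mt, p, "contig"); paths <- c(paths, p)
  p <- file.path(out_dir, "all_contigs.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(dataset$contigs), p)
  paths <- c(paths, p)
  p <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(dataset$ground_truth, p, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  paths <- c(paths, p)
  p <- file.path(out_dir, "config.json")
  cfgj <- dataset$config
  cfgj$start_date <- .iso_date(cfgj$start_date)
  jsonlite::write_json(unclass(cfgj), p, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths <- c(paths, p)

  manifest <- list(
    files = as.list(setNames(unname(tools::md5sum(paths)), basename(paths))),
    n_timepoints = length(date_ids),
    n_contigs = length(dataset$contigs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read fixtures back into a synthetic dataset
#'
#' @param dir directory written by [write_fixtures()].
#' @return a `synthetic_community` equal to the one written (the `config`
#'   element is restored from JSON; the ground truth keeps its structure,
#'   with data.frame components restored).
#' @export
read_fixtures <- function(dir) {
  stopifnot(dir.exists(dir))
  fa <- Biostrings::readDNAStringSet(file.path(dir, "all_contigs.fasta"))
  contigs <- setNames(as.character(fa), names(fa))
  elements <- .read_tsv(file.path(dir, "elements.tsv"),
                        colClasses = c(sample = "character"))
  depth_mg <- .read_matrix_tsv(file.path(dir, "depth_mg.tsv"))
  depth_mt <- .read_matrix_tsv(file.path(dir, "depth_mt.tsv"))
  dates <- as.Date(.read_tsv(file.path(dir, "sample_dates.tsv"))$date)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  cfg$start_date <- as.Date(cfg$start_date)
  if (!is.null(cfg$planted_event_table) &&
      length(cfg$planted_event_table) == 0L) {
    cfg$planted_event_table <- NULL
  }
  cfg <- structure(cfg, class = "sim_config")
  structure(list(
    contigs = contigs,
    elements = elements,
    contig2mag = .read_tsv(file.path(dir, "contig_mag.tsv")),
    mag2rmag = .read_tsv(file.path(dir, "mag_rmag.tsv")),
    rmag2family = .read_tsv(file.path(dir, "rmag_family.tsv")),
    depth_mg = depth_mg,
    depth_mt = depth_mt,
    flags = .read_tsv(file.path(dir, "predictor_flags.tsv")),
    dates = dates,
    ground_truth = gt,
    config = cfg), class = "synthetic_community")
}

#' Validate pipeline input fixtures
#'
#' Schema and cross-reference checks on a fixture directory: required files,
#' ISO-8601 dates, element-table columns, depth-table/FASTA contig
#' cross-references and parseable FASTA.
#'
#' @param dir fixture directory.
#' @return character vector of violations (empty when valid).
#' @export
validate_inputs <- function(dir) {
  v <- character(0)
  need <- c("elements.tsv", "contig_mag.tsv", "mag_rmag.tsv",
            "rmag_family.tsv", "predictor_flags.tsv", "sample_dates.tsv",
            "depth_mg.tsv", "depth_mt.tsv", "all_contigs.fasta")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    return(paste("missing file:", missing))
  }
  fa <- tryCatch(
    Biostrings::readDNAStringSet(file.path(dir, "all_contigs.fasta")),
    error = function(e) NULL)
  if (is.null(fa)) {
    v <- c(v, "all_contigs.fasta: not parseable as FASTA")
  }
  dates <- .read_tsv(file.path(dir, "sample_dates.tsv"))
  bad_dates <- dates$date[!grepl("^\\d{4}-\\d{2}-\\d{2}$", dates$date)]
  if (length(bad_dates)) {
    v <- c(v, paste0("sample_dates.tsv: non-ISO-8601 date '", bad_dates, "'"))
  }
  el <- .read_tsv(file.path(dir, "elements.tsv"))
  need_cols <- c("element_id", "kind", "sequence", "sample", "contig",
                 "coverage")
  miss_cols <- setdiff(need_cols, names(el))
  if (length(miss_cols)) {
    v <- c(v, paste0("elements.tsv: missing column '", miss_cols, "'"))
  }
  dm <- .read_matrix_tsv(file.path(dir, "depth_mg.tsv"))
  if (!is.null(fa)) {
    orphan <- setdiff(rownames(dm), names(fa))
    if (length(orphan)) {
      v <- c(v, paste0("depth_mg.tsv: contig '", head(orphan, 5L),
                       "' absent from FASTA"))
    }
  }
  v
}
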