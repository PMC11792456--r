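#' Read an OTU count table
#'
#' Reads a taxa-by-sample count table into the wide tibble layout used
#' throughout the package: a character `otu_id` column followed by one
#' non-negative integer column per sample.
#'
#' @param path Path to the table on disk.
#' @param format `"tsv"` (first column = OTU id, remaining columns = samples)
#'   or `"biom"` (BIOM JSON flavour, read via the biomformat package).
#' @return A tibble with columns `otu_id` and one integer column per sample.
#' @export
read_otu_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File does not exist: ", path))
  if (format == "tsv") {
    raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      colClasses = "character")
    if (ncol(raw) < 2) abort("OTU table needs an id column and at least one sample column.")
    ids <- raw[[1]]
    counts <- raw[, -1, drop = FALSE]
    num <- suppressWarnings(lapply(counts, as.numeric))
    bad <- names(counts)[vapply(num, function(x) any(is.na(x)), logical(1))]
    if (length(bad) > 0) {
      abort(paste0("Non-numeric counts in sample column(s): ",
                   paste(bad, collapse = ", ")))
    }
    out <- tibble(otu_id = ids)
    for (s in names(counts)) out[[s]] <- num[[s]]
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("Reading BIOM files requires the 'biomformat' package.")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    out <- tibble(otu_id = rownames(m))
    for (s in colnames(m)) out[[s]] <- as.numeric(m[, s])
  }
  validate_otu_table(out)
}

#' Validate an OTU table tibble
#'
#' Checks the structural invariants every downstream analysis assumes:
#' unique OTU and sample identifiers, non-negative integer counts, and at
#' least one OTU and two samples.
#'
#' @param otu A wide OTU tibble (`otu_id` + sample count columns).
#' @return The validated tibble, invisibly unchanged (counts coerced to
#'   integer-valued doubles).
#' @export
validate_otu_table <- function(otu) {
  otu <- as_tibble(otu)
  if (!"otu_id" %in% names(otu)) names(otu)[1] <- "otu_id"
  otu$otu_id <- as.character(otu$otu_id)
  dup_o <- unique(otu$otu_id[duplicated(otu$otu_id)])
  if (length(dup_o) > 0) {
    abort(paste0("Duplicate OTU id(s): ", paste(dup_o, collapse = ", ")))
  }
  samples <- setdiff(names(otu), "otu_id")
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s) > 0) {
    abort(paste0("Duplicate sample id(s): ", paste(dup_s, collapse = ", ")))
  }
  if (length(samples) < 2) abort("OTU table needs at least 2 samples.")
  if (nrow(otu) < 1) abort("OTU table needs at least 1 OTU.")
  for (s in samples) {
    x <- otu[[s]]
    if (!is.numeric(x)) abort(paste0("Sample '", s, "' has non-numeric counts."))
    if (any(!is.finite(x))) abort(paste0("Sample '", s, "' has non-finite counts."))
    if (any(x < 0)) abort(paste0("Sample '", s, "' has negative counts."))
    if (any(x != round(x))) abort(paste0("Sample '", s, "' has non-integer counts."))
  }
  otu
}

#' Write an OTU table to TSV
#'
#' @param otu A wide OTU tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(otu, path) {
  otu <- validate_otu_table(otu)
  write.table(otu, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the count matrix from an OTU tibble
#'
#' @param otu A wide OTU tibble.
#' @return A numeric matrix, OTUs in rows (named), samples in columns.
#' @export
otu_counts <- function(otu) {
  otu <- validate_otu_table(otu)
  m <- as.matrix(otu[, setdiff(names(otu), "otu_id"), drop = FALSE])
  rownames(m) <- otu$otu_id
  m
}

#' Sample identifiers of an OTU tibble
#' @param otu A wide OTU tibble.
#' @return Character vector of sample ids in column order.
#' @export
otu_samples <- function(otu) setdiff(names(otu), "otu_id")

#' Per-sample relative abundances
#'
#' @param otu A wide OTU tibble.
#' @return A tibble of the same shape with each sample column scaled to sum 1.
#' @export
relative_abundance <- function(otu) {
  m <- otu_counts(otu)
  tot <- colSums(m)
  if (any(tot == 0)) {
    abort(paste0("Sample(s) with zero total reads: ",
                 paste(colnames(m)[tot == 0], collapse = ", ")))
  }
  m <- sweep(m, 2, tot, "/")
  out <- tibble(otu_id = rownames(m))
  for (s in colnames(m)) out[[s]] <- m[, s]
  out
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `site`, `season`, `replicate`, `latitude`,
#' `longitude` in a comma- or tab-separated file (delimiter sniffed from the
#' header line).
#'
#' @param path Path to the metadata file.
#' @return A tibble with typed columns.
#' @export
read_metadata <- function(path) {
  df <- read_delim_sniff(path)
  validate_metadata(df)
}

#' Validate sample metadata
#'
#' @param metadata Data frame of per-sample records.
#' @param otu Optional OTU tibble to cross-check sample ids against.
#' @return The validated metadata tibble.
#' @export
validate_metadata <- function(metadata, otu = NULL) {
  metadata <- as_tibble(metadata)
  req <- c("sample_id", "site", "season", "replicate", "latitude", "longitude")
  missing_cols <- setdiff(req, names(metadata))
  if (length(missing_cols) > 0) {
    abort(paste0("Metadata is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  metadata$sample_id <- as.character(metadata$sample_id)
  metadata$replicate <- as.integer(metadata$replicate)
  metadata$latitude <- as.numeric(metadata$latitude)
  metadata$longitude <- as.numeric(metadata$longitude)
  if (anyDuplicated(metadata$sample_id)) abort("Duplicate sample_id in metadata.")
  bad_lat <- metadata$sample_id[!is.na(metadata$latitude) &
                                  abs(metadata$latitude) > 90]
  if (length(bad_lat) > 0) {
    abort(paste0("Latitude out of [-90, 90] for: ", paste(bad_lat, collapse = ", ")))
  }
  bad_lon <- metadata$sample_id[!is.na(metadata$longitude) &
                                  abs(metadata$longitude) > 180]
  if (length(bad_lon) > 0) {
    abort(paste0("Longitude out of [-180, 180] for: ", paste(bad_lon, collapse = ", ")))
  }
  if (!is.null(otu)) check_sample_match(metadata$sample_id, otu_samples(otu), "metadata")
  metadata
}

#' Read an environmental table
#'
#' Expects `sample_id` plus the measured water-quality variables; the
#' canonical columns are `WT` (deg C), `pH`, `DO` (mg/L), `SD` (m, Secchi
#' transparency), `Chl_a` (mg/m3), `TN`, `TP`, `NH4_N`, `COD_Cr`, `COD_Mn`
#' (all mg/L).
#'
#' @param path Path to the CSV/TSV file.
#' @return A typed tibble.
#' @export
read_env <- function(path) {
  df <- read_delim_sniff(path)
  validate_env(df)
}

#' Validate an environmental table
#'
#' @param env Data frame of per-sample environmental measurements.
#' @param otu Optional OTU tibble to cross-check sample ids against.
#' @return The validated env tibble.
#' @export
validate_env <- function(env, otu = NULL) {
  env <- as_tibble(env)
  if (!"sample_id" %in% names(env)) abort("Env table is missing column: sample_id")
  env$sample_id <- as.character(env$sample_id)
  if (anyDuplicated(env$sample_id)) abort("Duplicate sample_id in env table.")
  for (v in setdiff(names(env), "sample_id")) env[[v]] <- as.numeric(env[[v]])
  if (!is.null(otu)) check_sample_match(env$sample_id, otu_samples(otu), "env table")
  env
}

env_variables <- function(env) setdiff(names(env), "sample_id")

check_sample_match <- function(have, need, what) {
  missing_ids <- setdiff(need, have)
  if (length(missing_ids) > 0) {
    abort(paste0("Sample id(s) in OTU table but absent from ", what, ": ",
                 paste(missing_ids, collapse = ", ")))
  }
  invisible(TRUE)
}

read_delim_sniff <- function(path) {
  if (!file.exists(path)) abort(paste0("File does not exist: ", path))
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  as_tibble(read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                       stringsAsFactors = FALSE))
}
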