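#' @name specimen_records
#' @title Specimen-level isotope measurement tables
#'
#' @description
#' The canonical data container of the package is a `specimen_records` data
#' frame: one row per skeletal-tissue measurement of one individual, with
#' columns
#'
#' \describe{
#'   \item{specimen_id}{opaque individual label (character)}
#'   \item{species}{binomial string}
#'   \item{family}{one of `"arvicolid"`, `"murid"`, `"other"`}
#'   \item{tissue}{one of `"incisor"`, `"M1"`, `"M2"`, `"M3"`, `"bone"`}
#'   \item{side}{optional: `"left"`, `"right"`, `"both"`, `"unknown"` or `NA`}
#'   \item{d18O_co3}{per mil vs VSMOW, structural carbonate (may be `NA`)}
#'   \item{d18O_po4}{per mil vs VSMOW, phosphate (may be `NA`)}
#'   \item{d13C}{per mil vs VPDB (may be `NA`)}
#'   \item{age_class}{optional: `"juvenile"`, `"adult"`, `"unknown"` or `NA`}
#' }
#'
#' Every row must carry at least one isotope value; `(specimen_id, tissue)`
#' pairs must be unique.  Values outside the sanity windows (delta18O in
#' \[0, 50\] per mil, delta13C in \[-40, 10\] per mil) are *flagged* in the
#' `flag` column, never dropped: exclusion is always an explicit caller
#' decision.  Missing values are `NA`, never sentinel numbers.
NULL

rodiso_tissues <- c("incisor", "M1", "M2", "M3", "bone")
rodiso_families <- c("arvicolid", "murid", "other")
rodiso_sides <- c("left", "right", "both", "unknown")
rodiso_age_classes <- c("juvenile", "adult", "unknown")
rodiso_variables <- c("d18O_co3", "d18O_po4", "d13C")

# canonical CSV column order (External Interfaces contract)
rodiso_schema <- c("specimen_id", "species", "family", "tissue", "side",
                   "d18O_co3", "d18O_po4", "d13C", "age_class")

#' Construct and validate a specimen_records table
#'
#' @param df data frame with at least the columns `specimen_id`, `species`,
#'   `family`, `tissue` and one of `d18O_co3`, `d18O_po4`, `d13C`.  Missing
#'   optional columns (`side`, `age_class`, absent isotope columns) are added
#'   as `NA`.
#' @param strict logical; if `TRUE`, sanity-window violations are an error
#'   instead of a flag.
#' @return the validated data frame with class `specimen_records` and a
#'   character `flag` column (empty string when clean).
#' @export
specimen_records <- function(df, strict = FALSE) {
  stopifnot(is.data.frame(df))
  need <- c("specimen_id", "species", "family", "tissue")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    rodiso_stop("rodiso_format_error",
                paste0("missing required column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  for (col in setdiff(rodiso_schema, names(df))) {
    df[[col]] <- if (col %in% rodiso_variables) NA_real_ else NA_character_
  }
  df <- df[, rodiso_schema]
  df$specimen_id <- as.character(df$specimen_id)
  df$species <- as.character(df$species)
  for (col in rodiso_variables) df[[col]] <- as.numeric(df[[col]])

  bad_fam <- !df$family %in% rodiso_families
  if (any(bad_fam)) {
    rodiso_stop("rodiso_format_error",
                paste0("unknown family value(s): ",
                       paste(unique(df$family[bad_fam]), collapse = ", ")))
  }
  bad_tis <- !df$tissue %in% rodiso_tissues
  if (any(bad_tis)) {
    rodiso_stop("rodiso_format_error",
                paste0("unknown tissue value(s): ",
                       paste(unique(df$tissue[bad_tis]), collapse = ", ")))
  }
  ok_opt <- function(x, levels) is.na(x) | x %in% levels
  if (!all(ok_opt(df$side, rodiso_sides))) {
    rodiso_stop("rodiso_format_error", "invalid side value(s)")
  }
  if (!all(ok_opt(df$age_class, rodiso_age_classes))) {
    rodiso_stop("rodiso_format_error", "invalid age_class value(s)")
  }

  no_value <- is.na(df$d18O_co3) & is.na(df$d18O_po4) & is.na(df$d13C)
  if (any(no_value)) {
    rodiso_stop("rodiso_format_error",
                paste0("record(s) with no isotope value: ",
                       paste(df$specimen_id[no_value], df$tissue[no_value],
                             sep = "/", collapse = ", ")))
  }
  key <- paste(df$specimen_id, df$tissue, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    rodiso_stop("rodiso_format_error",
                paste0("duplicate (specimen_id, tissue) pair: ",
                       gsub("\r", "/", dup)))
  }

  flag <- character(nrow(df))
  out18 <- function(x) !is.na(x) & (x < 0 | x > 50)
  out13 <- !is.na(df$d13C) & (df$d13C < -40 | df$d13C > 10)
  flag[out18(df$d18O_co3)] <- paste0(flag[out18(df$d18O_co3)],
                                     "d18O_co3 outside [0,50];")
  flag[out18(df$d18O_po4)] <- paste0(flag[out18(df$d18O_po4)],
                                     "d18O_po4 outside [0,50];")
  flag[out13] <- paste0(flag[out13], "d13C outside [-40,10];")
  if (strict && any(nzchar(flag))) {
    rodiso_stop("rodiso_sanity_error",
                paste0("isotope value(s) outside sanity window in record(s): ",
                       paste(df$specimen_id[nzchar(flag)], collapse = ", ")))
  }
  df$flag <- flag
  rownames(df) <- NULL
  class(df) <- c("specimen_records", "data.frame")
  df
}

#' Read a specimen dataset from canonical CSV
#'
#' UTF-8 comma-separated values with header
#' `specimen_id,species,family,tissue,side,d18O_co3,d18O_po4,d13C,age_class`;
#' empty string means missing; `.` decimal point.
#'
#' @param path path to a CSV file.
#' @param strict logical, passed to [specimen_records()]; also makes sanity
#'   flags an error.
#' @return a `specimen_records` data frame.
#' @export
read_dataset <- function(path, strict = FALSE) {
  if (!file.exists(path)) {
    rodiso_stop("rodiso_io_error", paste0("file not found: ", path))
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         fileEncoding = "UTF-8", check.names = FALSE)
  missing_cols <- setdiff(rodiso_schema, names(raw))
  if (length(missing_cols)) {
    rodiso_stop("rodiso_format_error",
                paste0("malformed header in ", basename(path),
                       ": missing column(s) ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0L) {
    rodiso_warn("rodiso_empty_warning",
                paste0("empty dataset read from ", basename(path)))
    empty <- raw
    for (col in rodiso_variables) empty[[col]] <- numeric(0)
    empty$flag <- character(0)
    class(empty) <- c("specimen_records", "data.frame")
    return(empty)
  }
  for (col in c("side", "age_class")) raw[[col]][!nzchar(raw[[col]])] <- NA
  for (col in rodiso_variables) {
    txt <- raw[[col]]
    txt[!nzchar(txt)] <- NA
    num <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & is.na(num))
    if (length(bad)) {
      rodiso_stop("rodiso_format_error",
                  paste0("unparseable numeric in column ", col, ", line ",
                         bad[1] + 1L, " of ", basename(path), ": '",
                         txt[bad[1]], "'"))
    }
    raw[[col]] <- num
  }
  specimen_records(raw, strict = strict)
}

#' Write a specimen dataset to canonical CSV
#'
#' Inverse of [read_dataset()]: comma delimiter, `.` decimal, UTF-8, LF line
#' endings, empty string for missing.  `write_dataset(read_dataset(p), p2)`
#' is byte-identical to `p` for canonical files.
#'
#' @param records a `specimen_records` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(records, path) {
  stopifnot(inherits(records, "specimen_records"))
  out <- as.data.frame(records)[, rodiso_schema, drop = FALSE]
  for (col in rodiso_variables) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), "", vapply(v, format, "", digits = 15))
  }
  for (col in c("side", "age_class")) {
    out[[col]][is.na(out[[col]])] <- ""
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(rodiso_schema, collapse = ","), con, sep = "\n")
  if (nrow(out)) {
    lines <- do.call(paste, c(unname(as.list(out)), sep = ","))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' @export
print.specimen_records <- function(x, ...) {
  cat("<specimen_records> ", nrow(x), " record(s), ",
      length(unique(x$specimen_id)), " specimen(s), ",
      length(unique(x$species)), " species\n", sep = "")
  n_flag <- sum(nzchar(x$flag))
  if (n_flag) cat("  ", n_flag, " flagged record(s)\n", sep = "")
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ... ", nrow(x) - 10L, " more row(s)\n", sep = "")
  invisible(x)
}
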