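#' Construct a spectra table
#'
#' A spectra table holds one sensor's absorbance matrix (samples in rows,
#' wavenumbers in columns) together with its sample labels and wavenumber
#' axis. Wavenumber order is normalized to ascending so that every
#' downstream operation can rely on a single convention.
#'
#' @param sample_ids character vector of unique sample labels, one per row.
#' @param wavenumbers numeric vector of strictly monotone wavenumbers
#'   (cm^-1); a descending axis is accepted and reversed.
#' @param absorbance numeric matrix, `length(sample_ids)` rows by
#'   `length(wavenumbers)` columns, all values finite.
#' @param sensor_name single string tagging the sensor (e.g. `"NIR"`).
#' @return An object of class `spectra_table` with fields `sample_ids`,
#'   `wavenumbers` (ascending), `absorbance` and `sensor_name`.
#' @examples
#' st <- spectra_table(c("a", "b"), c(1000, 1004),
#'                     matrix(1:4 / 10, 2, 2), "NIR")
#' dim(st$absorbance)
#' @export
spectra_table <- function(sample_ids, wavenumbers, absorbance, sensor_name) {
  sample_ids <- as.character(sample_ids)
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  if (length(sensor_name) != 1L || !nzchar(sensor_name))
    stop("'sensor_name' must be a single non-empty string")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (length(wavenumbers) < 2L)
    stop("need at least 2 wavenumbers, got ", length(wavenumbers))
  if (anyNA(wavenumbers) || any(!is.finite(wavenumbers)))
    stop("wavenumbers must be finite")
  d <- diff(wavenumbers)
  if (all(d < 0)) {            # descending axis: flip to ascending
    wavenumbers <- rev(wavenumbers)
    absorbance <- absorbance[, rev(seq_len(ncol(absorbance))), drop = FALSE]
  } else if (!all(d > 0)) {
    stop("wavenumbers must be strictly monotone")
  }
  if (nrow(absorbance) != length(sample_ids))
    stop("absorbance has ", nrow(absorbance), " rows but there are ",
         length(sample_ids), " sample ids")
  if (ncol(absorbance) != length(wavenumbers))
    stop("absorbance has ", ncol(absorbance), " columns but there are ",
         length(wavenumbers), " wavenumbers")
  if (any(!is.finite(absorbance)))
    stop("absorbance contains non-finite values")
  dimnames(absorbance) <- NULL
  structure(list(sample_ids = sample_ids, wavenumbers = wavenumbers,
                 absorbance = absorbance, sensor_name = sensor_name),
            class = "spectra_table")
}

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf("<spectra_table> sensor %s: %d samples x %d wavenumbers (%g-%g cm^-1)\n",
              x$sensor_name, length(x$sample_ids), length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' Construct a reference-concentration vector
#'
#' @param sample_ids character vector of unique sample labels.
#' @param concentration numeric vector of analyte contents (% w/w), same
#'   length as `sample_ids`, finite and non-negative.
#' @return An object of class `reference_values`.
#' @export
reference_values <- function(sample_ids, concentration) {
  sample_ids <- as.character(sample_ids)
  concentration <- as.numeric(concentration)
  if (length(sample_ids) != length(concentration))
    stop("sample_ids and concentration differ in length")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (any(!is.finite(concentration)))
    stop("concentrations must be finite")
  if (any(concentration < 0))
    stop("concentrations must be >= 0")
  structure(list(sample_ids = sample_ids, concentration = concentration),
            class = "reference_values")
}

#' @export
print.reference_values <- function(x, ...) {
  cat(sprintf("<reference_values> %d samples, %.4g-%.4g %% w/w\n",
              length(x$sample_ids), min(x$concentration), max(x$concentration)))
  invisible(x)
}

# full-precision number formatting so write -> read is bit-exact
.fmt_num <- function(x) formatC(x, digits = 17, format = "g", width = -1)

.split_csv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path)
  strsplit(lines, ",", fixed = TRUE)
}

.parse_num <- function(s) suppressWarnings(as.numeric(trimws(s)))

#' Read a spectra table from delimited text
#'
#' Expects a comma-separated table whose first row carries the wavenumber
#' axis (first header cell is an arbitrary label), first column the sample
#' ids, and body the absorbance values. The wavenumber axis may be written
#' in descending order; columns are reordered to ascending on read.
#'
#' @param path path to the CSV file.
#' @param sensor_name sensor tag to attach to the returned table.
#' @return A [spectra_table()].
#' @seealso [write_spectra_table()]
#' @export
read_spectra_table <- function(path, sensor_name) {
  rows <- .split_csv_lines(path)
  header <- rows[[1]]
  if (length(header) < 3L)
    stop("header of ", path, " must contain at least 2 wavenumbers")
  wn <- .parse_num(header[-1])
  bad <- which(is.na(wn))
  if (length(bad))
    stop("non-numeric wavenumber in header column ", bad[1] + 1L,
         " of ", path, ": '", header[bad[1] + 1L], "'")
  body <- rows[-1]
  if (length(body) == 0L) stop("no sample rows in ", path)
  n <- length(body)
  ids <- character(n)
  mat <- matrix(NA_real_, n, length(wn))
  for (i in seq_len(n)) {
    r <- body[[i]]
    if (length(r) != length(header))
      stop("row ", i + 1L, " of ", path, " has ", length(r),
           " fields, expected ", length(header))
    ids[i] <- trimws(r[1])
    vals <- .parse_num(r[-1])
    bad <- which(is.na(vals))
    if (length(bad))
      stop("non-numeric absorbance at row ", i + 1L, ", column ",
           bad[1] + 1L, " of ", path, ": '", r[bad[1] + 1L], "'")
    mat[i, ] <- vals
  }
  spectra_table(ids, wn, mat, sensor_name)
}

#' Write a spectra table as delimited text
#'
#' Values are written at 17 significant digits so that
#' `read_spectra_table(write_spectra_table(x))` reproduces `x` exactly.
#'
#' @param x a [spectra_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(x, path) {
  stopifnot(inherits(x, "spectra_table"))
  header <- paste(c("sample_id", .fmt_num(x$wavenumbers)), collapse = ",")
  body <- vapply(seq_along(x$sample_ids), function(i)
    paste(c(x$sample_ids[i], .fmt_num(x$absorbance[i, ])), collapse = ","),
    character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read reference concentrations from a two-column CSV
#'
#' Columns are sample id and concentration (% w/w). A header line is
#' skipped automatically when its concentration field is non-numeric.
#'
#' @param path path to the CSV file.
#' @return A [reference_values()] object, sample order preserved.
#' @export
read_reference <- function(path) {
  rows <- .split_csv_lines(path)
  if (any(lengths(rows) != 2L)) {
    i <- which(lengths(rows) != 2L)[1]
    stop("row ", i, " of ", path, " has ", lengths(rows)[i],
         " fields, expected 2")
  }
  if (is.na(.parse_num(rows[[1]][2]))) rows <- rows[-1]  # header line
  if (length(rows) == 0L) stop("no data rows in ", path)
  ids <- vapply(rows, function(r) trimws(r[1]), character(1))
  conc <- vapply(rows, function(r) .parse_num(r[2]), numeric(1))
  bad <- which(is.na(conc))
  if (length(bad))
    stop("non-numeric concentration at row ", bad[1], " of ", path)
  reference_values(ids, conc)
}

#' Write reference concentrations
#' @param x a [reference_values()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(x, path) {
  stopifnot(inherits(x, "reference_values"))
  writeLines(c("sample_id,concentration",
               paste(x$sample_ids, .fmt_num(x$concentration), sep = ",")),
             path)
  invisible(path)
}

# Align two id vectors; error spelling out any mismatch. Returns the index
# of `ids` within `ref_ids` so matrices can be reordered by sample id.
.match_ids <- function(ids, ref_ids, what = "sample ids") {
  miss <- setdiff(ref_ids, ids)
  extra <- setdiff(ids, ref_ids)
  if (length(miss) || length(extra))
    stop("mismatched ", what,
         if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")))
  match(ref_ids, ids)
}
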