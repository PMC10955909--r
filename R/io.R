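#' Read an insertion-loss spectrum from delimited text
#'
#' Parses a two-column text file (`wavelength_nm`, `il_db`), comma- or
#' tab-delimited, with optional `#`-prefixed metadata header lines of the
#' form `# key: value`. Rows are sorted by wavelength on read.
#'
#' @param path file path.
#' @param dialect delimiter: `"auto"` (default), `"comma"` or `"tab"`.
#' @return A [tfbg_spectrum]; the dialect used is recorded in `meta$dialect`.
#' @export
read_spectrum <- function(path, dialect = c("auto", "comma", "tab")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  meta <- parse_meta_header(lines)
  body <- grep("^\\s*#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("no data rows in ", path)
  sep <- resolve_dialect(body[1], dialect)
  # drop a non-numeric header row if present
  first <- strsplit(body[1], sep, fixed = TRUE)[[1]]
  if (suppressWarnings(anyNA(as.numeric(first[1])))) body <- body[-1]
  n <- length(body)
  wl <- numeric(n); il <- numeric(n)
  for (i in seq_len(n)) {
    fields <- strsplit(body[i], sep, fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2 || anyNA(vals[1:2]))
      stop("malformed spectrum row at data line ", i, " of ", path,
           ": '", body[i], "'")
    wl[i] <- vals[1]; il[i] <- vals[2]
  }
  o <- order(wl)
  wl <- wl[o]; il <- il[o]
  if (anyDuplicated(wl))
    stop("duplicate wavelengths in ", path)
  meta$dialect <- if (sep == ",") "comma" else "tab"
  tfbg_spectrum(wl, il, meta)
}

#' Write an insertion-loss spectrum to delimited text
#'
#' Inverse of [read_spectrum]: metadata is serialized as `# key: value`
#' header lines, then rows `wavelength_nm,il_db` at full double precision so
#' the round trip is lossless.
#'
#' @param spectrum a [tfbg_spectrum].
#' @param path output file path.
#' @param sep field separator, `","` or `"\t"`.
#' @return The path, invisibly.
#' @export
write_spectrum <- function(spectrum, path, sep = ",") {
  stopifnot(inherits(spectrum, "tfbg_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_meta_header(spectrum$meta), con)
  writeLines(sprintf("wavelength_nm%sil_db", sep), con)
  writeLines(paste(format_full(spectrum$wavelengths_nm),
                   format_full(spectrum$il_db), sep = sep), con)
  invisible(path)
}

#' Read a Jones-matrix spectrum from delimited text
#'
#' Nine columns: wavelength then real/imaginary parts of J00, J01, J10, J11
#' (row-major), i.e. `wavelength_nm, re_j00, im_j00, re_j01, im_j01, re_j10,
#' im_j10, re_j11, im_j11`.
#'
#' @param path file path.
#' @return A [jones_spectrum].
#' @export
read_jones <- function(path) {
  lines <- readLines(path)
  body <- grep("^\\s*#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("no data rows in ", path)
  sep <- resolve_dialect(body[1], "auto")
  first <- strsplit(body[1], sep, fixed = TRUE)[[1]]
  if (suppressWarnings(anyNA(as.numeric(first[1])))) body <- body[-1]
  n <- length(body)
  m <- matrix(NA_real_, n, 9)
  for (i in seq_len(n)) {
    vals <- suppressWarnings(as.numeric(strsplit(body[i], sep, fixed = TRUE)[[1]]))
    if (length(vals) != 9 || anyNA(vals))
      stop("Jones row at data line ", i, " of ", path,
           " must have 9 numeric columns")
    m[i, ] <- vals
  }
  o <- order(m[, 1])
  m <- m[o, , drop = FALSE]
  J <- array(complex(real = 0), dim = c(n, 2, 2))
  J[, 1, 1] <- complex(real = m[, 2], imaginary = m[, 3])
  J[, 1, 2] <- complex(real = m[, 4], imaginary = m[, 5])
  J[, 2, 1] <- complex(real = m[, 6], imaginary = m[, 7])
  J[, 2, 2] <- complex(real = m[, 8], imaginary = m[, 9])
  jones_spectrum(m[, 1], J)
}

#' Write a Jones-matrix spectrum to delimited text
#'
#' @param jones a [jones_spectrum].
#' @param path output file path.
#' @param sep field separator.
#' @return The path, invisibly.
#' @export
write_jones <- function(jones, path, sep = ",") {
  stopifnot(inherits(jones, "tfbg_jones"))
  J <- jones$matrices
  cols <- cbind(jones$wavelengths_nm,
                Re(J[, 1, 1]), Im(J[, 1, 1]), Re(J[, 1, 2]), Im(J[, 1, 2]),
                Re(J[, 2, 1]), Im(J[, 2, 1]), Re(J[, 2, 2]), Im(J[, 2, 2]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("wavelength_nm", "re_j00", "im_j00", "re_j01", "im_j01",
                     "re_j10", "im_j10", "re_j11", "im_j11"), collapse = sep),
             con)
  writeLines(apply(cols, 1, function(r) paste(format_full(r), collapse = sep)),
             con)
  invisible(path)
}

#' Write a dataset manifest and its spectra to a directory
#'
#' The manifest is a JSON file listing one entry per record
#' (`file`, `fiber_id`, `ri_riu`, `pol_index`, `alpha_deg`, `eps_deg`,
#' `is_water_reference`) plus the generator provenance.
#'
#' @param dataset a [refractometry_dataset].
#' @param dir output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "tfbg_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- vector("list", length(dataset$records))
  for (i in seq_along(dataset$records)) {
    r <- dataset$records[[i]]
    fn <- sprintf("spectrum_f%02d_n%06.0f_p%02d.csv",
                  r$fiber_id, round(r$ri_riu * 1e5), r$pol_index)
    write_spectrum(r$spectrum, file.path(dir, fn))
    entries[[i]] <- list(
      file = fn, fiber_id = r$fiber_id, ri_riu = r$ri_riu,
      pol_index = r$pol_index,
      alpha_deg = if (is.null(r$pol)) NA else r$pol$alpha_rad * 180 / pi,
      eps_deg = if (is.null(r$pol)) NA else r$pol$eps_rad * 180 / pi,
      is_water_reference = r$is_water_reference)
  }
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(records = entries, provenance = dataset$manifest),
                       manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest_path)
}

#' Read a dataset written by [write_dataset]
#'
#' @param manifest_path path to `manifest.json`.
#' @return A [refractometry_dataset].
#' @export
read_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path)
  man <- jsonlite::read_json(manifest_path)
  dir <- dirname(manifest_path)
  records <- lapply(man$records, function(e) {
    pol <- if (!is.null(e$alpha_deg) && !is.na(e$alpha_deg))
      pol_state(e$alpha_deg * pi / 180, e$eps_deg * pi / 180) else NULL
    labeled_spectrum(read_spectrum(file.path(dir, e$file)),
                     fiber_id = e$fiber_id, ri_riu = e$ri_riu,
                     pol_index = e$pol_index,
                     is_water_reference = isTRUE(e$is_water_reference),
                     pol = pol)
  })
  refractometry_dataset(records, manifest = man$provenance)
}

# full-precision decimal formatting (17 significant digits round-trips doubles)
format_full <- function(x) {
  formatC(x, digits = 17, format = "g")
}

parse_meta_header <- function(lines) {
  hdr <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    h <- sub("^\\s*#\\s*", "", h)
    kv <- regmatches(h, regexec("^([^:]+):\\s*(.*)$", h))[[1]]
    if (length(kv) == 3) {
      val <- kv[3]
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(kv[2])]] <- if (!is.na(num)) num else val
    }
  }
  meta
}

format_meta_header <- function(meta) {
  if (!length(meta)) return(character())
  keep <- vapply(meta, function(v) is.atomic(v) && length(v) == 1, TRUE)
  meta <- meta[keep]
  vapply(names(meta), function(k) {
    v <- meta[[k]]
    if (is.numeric(v)) v <- format_full(v)
    sprintf("# %s: %s", k, v)
  }, "")
}

resolve_dialect <- function(sample_row, dialect) {
  switch(dialect,
         comma = ",",
         tab = "\t",
         auto = if (grepl("\t", sample_row)) "\t" else ",")
}
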