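#' Write a spectrum to delimited text
#'
#' Two columns (wavenumber, intensity), tab separated, with a comment
#' header. The de facto spectroscopy interchange format.
#'
#' @param wavenumbers,intensities numeric vectors of equal length
#' @param path output file
#' @export
write_spectrum <- function(wavenumbers, intensities, path) {
  stopifnot(length(wavenumbers) == length(intensities))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# wavenumber_cm-1\tintensity", con)
  writeLines(paste(format(wavenumbers, digits = 17),
                   format(intensities, digits = 17), sep = "\t"), con)
  invisible(path)
}

#' Read a spectrum from delimited text
#'
#' Accepts two-column numeric text with `#`-prefixed comment lines and a
#' delimiter auto-detected among comma, tab and whitespace. Non-numeric or
#' non-finite rows and a non-monotone axis are rejected with line-numbered
#' diagnostics. If `axis` is given, the file's axis must match it exactly.
#'
#' @param path input file
#' @param axis optional [spectral_axis] to validate against
#' @return list with `wavenumbers` and `intensities`
#' @export
read_spectrum <- function(path, axis = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop(path, ": no data lines")
  delim <- if (grepl(",", lines[1])) "," else "[\t ]+"
  parts <- strsplit(trimws(lines), delim)
  wn <- numeric(length(parts)); y <- numeric(length(parts))
  for (i in seq_along(parts)) {
    v <- suppressWarnings(as.numeric(parts[[i]]))
    if (length(v) < 2L || anyNA(v) || !all(is.finite(v)))
      stop(path, " line ", lineno[i], ": not a finite two-column numeric row: ",
           lines[i])
    wn[i] <- v[1]; y[i] <- v[2]
  }
  if (any(diff(wn) <= 0)) {
    bad <- which(diff(wn) <= 0)[1]
    stop(path, " line ", lineno[bad + 1L],
         ": wavenumber axis not strictly increasing")
  }
  if (!is.null(axis)) {
    if (length(wn) != axis$channel_count ||
        max(abs(wn - axis$wavenumbers)) > 1e-6)
      stop(path, ": spectrum axis does not match the library axis ",
           "(resampling between mismatched axes is not supported)")
  }
  list(wavenumbers = wn, intensities = y)
}

#' Write a spectral library to structured text
#'
#' JSON document carrying the axis, flavor labels, intensity arrays and the
#' background -- the same canonical serialization that [library_hash()]
#' digests, so a written library re-reads to an identical hash.
#'
#' @param library a [spectral_library]
#' @param path output file
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "spectral_library"))
  writeLines(library_json(library), path)
  invisible(path)
}

#' Read a spectral library written by [write_library()]
#'
#' @param path input file
#' @return a [spectral_library]
#' @export
read_library <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version) || doc$schema_version != "1.0")
    stop("unsupported library schema version: ",
         doc$schema_version %||% "<missing>")
  wn <- as.numeric(doc$wavenumbers)
  ax <- structure(list(wavenumbers = wn, channel_count = length(wn)),
                  class = "spectral_axis")
  flavors <- lapply(seq_along(doc$labels), function(i) {
    ints <- if (is.matrix(doc$flavors)) doc$flavors[i, ] else doc$flavors[[i]]
    structure(list(label = doc$labels[i], intensities = as.numeric(ints)),
              class = "reference_spectrum")
  })
  lib <- structure(list(
    axis = ax, flavors = flavors,
    background = structure(list(intensities = as.numeric(doc$background)),
                           class = "background_spectrum"),
    condition_number = NA_real_), class = "spectral_library")
  sv <- svd(flavor_matrix(lib), nu = 0, nv = 0)$d
  lib$condition_number <- sv[1] / sv[length(sv)]
  lib
}

#' Export a library as a delimited table
#'
#' Column 1 = wavenumber, one column per flavor, last column = background.
#'
#' @param library a [spectral_library]
#' @param path output file
#' @export
export_library_table <- function(library, path) {
  df <- data.frame(wavenumber = library$axis$wavenumbers,
                   flavor_matrix(library),
                   background = library$background$intensities,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a reliability table to structured text
#'
#' JSON with a schema version and full provenance (seed, replicate count,
#' noise sweep, library hash). Rows are written sorted by SRI bin center
#' (canonical form) and round-trip losslessly through [read_table()].
#'
#' @param table a `reliability_table`, or a list of them
#' @param path output file
#' @export
write_table <- function(table, path) {
  tabs <- if (inherits(table, "reliability_table")) list(table) else table
  stopifnot(all(vapply(tabs, inherits, logical(1), "reliability_table")))
  doc <- list(schema_version = "1.0",
              tables = lapply(tabs, function(tb) {
                rows <- tb$rows[order(tb$rows$sri), , drop = FALSE]
                list(mixture_ratio = tb$mixture_ratio,
                     confidence = tb$confidence,
                     rows = as.list(rows),
                     min_sri_for = as.list(tb$min_sri_for),
                     provenance = tb$provenance)
              }))
  writeLines(jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE,
                              pretty = TRUE, na = "null"), path)
  invisible(path)
}

#' Read reliability tables written by [write_table()]
#'
#' @param path input file
#' @return list of `reliability_table` objects
#' @export
read_table <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$schema_version) || doc$schema_version != "1.0")
    stop("unsupported reliability-table schema version: ",
         doc$schema_version %||% "<missing>",
         "; regenerate the table with this package version")
  lapply(doc$tables, function(tb) {
    rows <- as.data.frame(lapply(tb$rows, function(col)
      vapply(col, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
             numeric(1))))
    prov <- tb$provenance
    prov$noise_sweep <- as.numeric(unlist(prov$noise_sweep))
    min_sri <- vapply(tb$min_sri_for,
                      function(v) if (is.null(v)) NA_real_ else as.numeric(v),
                      numeric(1))
    structure(list(schema_version = "1.0",
                   mixture_ratio = as.numeric(tb$mixture_ratio),
                   confidence = as.numeric(tb$confidence),
                   rows = rows,
                   min_sri_for = min_sri,
                   provenance = prov),
              class = "reliability_table")
  })
}

#' Read a run configuration
#'
#' JSON configuration with a closed schema: unknown keys are rejected with
#' a clear message so a typo cannot silently fall back to a default.
#'
#' @param path JSON file
#' @return named list of configuration values
#' @export
read_config <- function(path) {
  known <- c("schema_version", "seed", "library", "out", "flavors",
             "channels", "concentrations", "background_scale", "noise_sigma",
             "reps", "ratios", "noise_grid", "confidence", "error_bound",
             "bin_width", "min_count")
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         "; known keys are: ", paste(known, collapse = ", "))
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
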