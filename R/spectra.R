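# reflectance-spectrum container and plumbing

#' Construct a spectrum set
#'
#' A spectrum set holds measurements on a shared wavelength grid: a numeric
#' grid `wl` (nm, strictly increasing), a matrix `refl` with one column per
#' measurement, and a metadata data frame with one row per column
#' (`species`, `individual`, `replicate`).
#'
#' @param wl numeric wavelengths in nm, strictly increasing.
#' @param refl numeric matrix, `length(wl)` rows, one column per measurement.
#'   Negative values are clipped to 0.
#' @param meta data frame with columns `species`, `individual` and
#'   optionally `replicate` (defaults to NA).
#' @return object of class `spectrum_set`.
#' @export
spectrum_set <- function(wl, refl, meta) {
  wl <- as.numeric(wl)
  refl <- as.matrix(refl)
  if (any(diff(wl) <= 0)) stop("wavelengths must be strictly increasing",
                               call. = FALSE)
  if (nrow(refl) != length(wl)) stop("refl rows must match wl", call. = FALSE)
  if (nrow(meta) != ncol(refl)) stop("meta rows must match spectra",
                                     call. = FALSE)
  if (!all(c("species", "individual") %in% names(meta))) {
    stop("meta needs columns species, individual", call. = FALSE)
  }
  if (is.null(meta$replicate)) meta$replicate <- NA_character_
  refl[refl < 0] <- 0
  first <- c("species", "individual", "replicate")
  meta <- meta[, c(first, setdiff(names(meta), first)), drop = FALSE]
  rownames(meta) <- NULL
  structure(list(wl = wl, refl = unname(refl), meta = meta),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum set: %d spectra, %d species, %g-%g nm (%d samples)>\n",
              ncol(x$refl), length(unique(x$meta$species)),
              min(x$wl), max(x$wl), length(x$wl)))
  invisible(x)
}

n_spectra <- function(set) ncol(set$refl)

#' Subset a spectrum set by metadata
#'
#' @param set a [spectrum_set].
#' @param keep logical or integer index over spectra (columns).
#' @return a [spectrum_set].
#' @export
subset_spectra <- function(set, keep) {
  spectrum_set(set$wl, set$refl[, keep, drop = FALSE],
               set$meta[keep, , drop = FALSE])
}

#' Read a wide spectra CSV
#'
#' First column `wl_nm`; remaining columns named
#' `<species>__<individual>[__<replicate>]`. With `percent = TRUE` values
#' are divided by 100.
#'
#' @param path CSV path.
#' @param percent logical; values are percent reflectance.
#' @return a [spectrum_set].
#' @export
read_spectra <- function(path, percent = FALSE) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "wl_nm") stop("first column must be wl_nm", call. = FALSE)
  wl <- df[[1]]
  refl <- as.matrix(df[, -1, drop = FALSE])
  if (percent) refl <- refl / 100
  meta <- parse_spectra_names(colnames(refl))
  spectrum_set(wl, refl, meta)
}

parse_spectra_names <- function(nm) {
  parts <- strsplit(nm, "__", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad)) {
    stop(sprintf("spectra column '%s' is not <species>__<individual>[__<replicate>]",
                 nm[which(bad)[1]]), call. = FALSE)
  }
  data.frame(
    species = vapply(parts, `[`, "", 1L),
    individual = vapply(parts, `[`, "", 2L),
    replicate = vapply(parts, function(p) if (length(p) >= 3L) p[3] else NA_character_, ""),
    stringsAsFactors = FALSE
  )
}

#' Write a spectrum set as a wide CSV
#'
#' @param set a [spectrum_set].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path) {
  nm <- ifelse(is.na(set$meta$replicate),
               paste(set$meta$species, set$meta$individual, sep = "__"),
               paste(set$meta$species, set$meta$individual,
                     set$meta$replicate, sep = "__"))
  df <- data.frame(wl_nm = set$wl, check.names = FALSE)
  df[nm] <- as.data.frame(set$refl)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample spectra onto a wavelength grid
#'
#' Linear interpolation onto `grid`; negative interpolated values are
#' clipped to 0. The grid must lie inside the span of the measured
#' wavelengths up to `tol` nm (no extrapolation).
#'
#' @param set a [spectrum_set] (or a list with `wl` and `refl`).
#' @param grid target wavelengths (nm).
#' @param tol allowed extrapolation at the ends, in nm.
#' @return a [spectrum_set] on `grid`.
#' @export
resample_spectra <- function(set, grid, tol = 0) {
  grid <- as.numeric(grid)
  if (min(grid) < min(set$wl) - tol || max(grid) > max(set$wl) + tol) {
    stop("grid extends beyond the measured wavelength span", call. = FALSE)
  }
  refl <- apply(set$refl, 2, function(v) {
    approx(set$wl, v, xout = grid, rule = 2)$y
  })
  refl <- matrix(refl, nrow = length(grid))
  refl[refl < 0] <- 0
  spectrum_set(grid, refl, set$meta)
}

#' Average replicate measurements per individual
#'
#' Pointwise mean of all replicate spectra sharing (species, individual);
#' used for sheath measurements taken in duplicate.
#'
#' @param set a [spectrum_set].
#' @return a [spectrum_set] with one spectrum per individual and
#'   `replicate = NA`.
#' @export
average_replicates <- function(set) {
  key <- paste(set$meta$species, set$meta$individual, sep = "\r")
  keys <- unique(key)
  refl <- vapply(keys, function(k) {
    rowMeans(set$refl[, key == k, drop = FALSE])
  }, numeric(length(set$wl)))
  refl <- matrix(refl, nrow = length(set$wl))
  first <- match(keys, key)
  meta <- set$meta[first, , drop = FALSE]
  meta$replicate <- NA_character_
  rownames(meta) <- NULL
  spectrum_set(set$wl, refl, meta)
}
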