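# geographic mosaic of host availability: hulls, overlaps, bootstrap summary

#' Read an occurrence CSV
#'
#' Expected columns `species,x,y` and optionally `source`. With
#' `lonlat = TRUE` the x/y columns are interpreted as lon/lat degrees and
#' pre-projected with [project_lonlat()].
#'
#' @param path CSV file path.
#' @param lonlat logical; apply the equirectangular pre-projection.
#' @return a data frame with columns `species`, `x`, `y` (and `source` when
#'   present).
#' @export
read_occurrences <- function(path, lonlat = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "x", "y")
  if (!all(need %in% names(df))) {
    stop("occurrence CSV must have columns species,x,y", call. = FALSE)
  }
  if (!all(is.finite(df$x)) || !all(is.finite(df$y))) {
    stop("non-finite coordinates in occurrence CSV", call. = FALSE)
  }
  if (any(!nzchar(df$species))) stop("empty species labels", call. = FALSE)
  if (lonlat) {
    xy <- project_lonlat(df$x, df$y)
    df$x <- xy[, 1]
    df$y <- xy[, 2]
  }
  df
}

#' Bootstrap mean and one-sided upper percentile bound
#'
#' Nonparametric bootstrap of the mean of a vector of proportions: resample
#' with replacement, take the mean, and report the arithmetic mean of the
#' data together with the `conf` percentile of the bootstrap distribution of
#' resampled means (one-sided upper bound). An upper bound below 1 indicates
#' that no single host covers the full herbivore range.
#'
#' @param values numeric vector (here: per-host overlap proportions).
#' @param n_boot number of bootstrap resamples.
#' @param conf confidence level for the upper percentile bound.
#' @param seed integer seed for the resampling.
#' @return list with `mean`, `upper`, `n_boot`, `conf`.
#' @export
bootstrap_mean_upper_ci <- function(values, n_boot = 10000, conf = 0.95,
                                    seed = 1) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("no values to bootstrap", call. = FALSE)
  stopifnot_scalar_number(n_boot, "n_boot", lower = 1)
  stopifnot_scalar_number(conf, "conf", lower = 0, upper = 1, strict = TRUE)
  n <- length(values)
  boot_means <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    rowMeans(matrix(values[idx], nrow = n_boot))
  })
  list(mean = mean(values),
       upper = as.numeric(quantile(boot_means, conf, type = 7)),
       n_boot = as.integer(n_boot), conf = conf)
}

#' Host-use fractions from co-occurrence
#'
#' For each host, the number of times it was recorded as used by the
#' herbivore out of the number of times a host record falls within `radius`
#' of a herbivore record (co-occurrence). Hosts that never co-occur are
#' flagged and reported as 0/0.
#'
#' @param occurrences occurrence data frame (`species`, `x`, `y`).
#' @param herbivore species label of the herbivore.
#' @param usage data frame (`host`, `x`, `y`) of records where the herbivore
#'   was captured on a host.
#' @param radius co-occurrence radius in planar units.
#' @return data frame with columns `host`, `used`, `co_occurring`,
#'   `fraction`, `undefined`.
#' @export
host_use_fractions <- function(occurrences, herbivore, usage, radius) {
  stopifnot_scalar_number(radius, "radius", lower = 0)
  ins <- occurrences[occurrences$species == herbivore, c("x", "y")]
  hosts <- sort(unique(c(
    setdiff(unique(occurrences$species), herbivore),
    unique(usage$host)
  )))
  out <- lapply(hosts, function(h) {
    hp <- occurrences[occurrences$species == h, c("x", "y")]
    co <- 0L
    if (nrow(hp) > 0L && nrow(ins) > 0L) {
      d2 <- outer(hp$x, ins$x, "-")^2 + outer(hp$y, ins$y, "-")^2
      co <- sum(apply(d2, 1, min) <= radius^2 + 1e-12)
    }
    used <- sum(usage$host == h)
    data.frame(host = h, used = used, co_occurring = co,
               fraction = if (co > 0L) min(used, co) / co else 0,
               undefined = co == 0L, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mosaic report: host-range overlap analysis
#'
#' Applies the host-inclusion rule (a host must have at least
#' `min_records` capture records to count), computes the convex-hull range
#' of the herbivore and of every included host, the directional overlap of
#' each host's hull with the herbivore hull, the symmetric overlap matrix
#' among hosts, and a bootstrap mean with one-sided upper confidence bound
#' over the per-host overlaps.
#'
#' @param occurrences occurrence data frame (`species`, `x`, `y`).
#' @param herbivore herbivore species label.
#' @param hosts character vector of candidate host labels.
#' @param host_records optional named integer vector of capture counts per
#'   host used for the inclusion rule; defaults to the occurrence counts.
#' @param min_records minimum capture records for a host to be included
#'   (default 2: "more than one").
#' @param n_boot,conf,seed bootstrap settings, see
#'   [bootstrap_mean_upper_ci()].
#' @return an object of class `mosaic_report`: list with `herbivore_hull`,
#'   `host_hulls`, `overlap` (data frame host, o), `symmetric` (matrix),
#'   `bootstrap`, `included_hosts`, `excluded_hosts`.
#' @export
mosaic_report <- function(occurrences, herbivore, hosts,
                          host_records = NULL, min_records = 2,
                          n_boot = 10000, conf = 0.95, seed = 1) {
  ins <- occurrences[occurrences$species == herbivore, c("x", "y")]
  if (nrow(ins) < 3L) stop("herbivore needs >= 3 records", call. = FALSE)
  herb_hull <- tryCatch(convex_hull(ins),
                        error = function(e) stop(sprintf(
                          "degenerate hull for '%s'", herbivore), call. = FALSE))

  counts <- if (is.null(host_records)) {
    table(factor(occurrences$species, levels = hosts))
  } else {
    host_records[hosts]
  }
  included <- hosts[as.integer(counts) >= min_records]
  excluded <- setdiff(hosts, included)

  host_hulls <- lapply(included, function(h) {
    hp <- occurrences[occurrences$species == h, c("x", "y")]
    tryCatch(convex_hull(hp),
             error = function(e) stop(sprintf("degenerate hull for '%s'", h),
                                      call. = FALSE))
  })
  names(host_hulls) <- included

  o <- vapply(host_hulls, function(hh) directional_overlap(herb_hull, hh),
              numeric(1))
  overlap <- data.frame(host = included, o = as.numeric(o),
                        stringsAsFactors = FALSE)

  k <- length(included)
  sym <- matrix(1, k, k, dimnames = list(included, included))
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        s <- symmetric_overlap(host_hulls[[i]], host_hulls[[j]])
        sym[i, j] <- s
        sym[j, i] <- s
      }
    }
  }

  boot <- bootstrap_mean_upper_ci(overlap$o, n_boot = n_boot, conf = conf,
                                  seed = seed)
  structure(list(herbivore = herbivore, herbivore_hull = herb_hull,
                 host_hulls = host_hulls, overlap = overlap,
                 symmetric = sym, bootstrap = boot,
                 included_hosts = included, excluded_hosts = excluded),
            class = "mosaic_report")
}

#' @export
print.mosaic_report <- function(x, ...) {
  cat(sprintf("Host-range mosaic for '%s' (%d hosts included, %d excluded)\n",
              x$herbivore, length(x$included_hosts), length(x$excluded_hosts)))
  df <- x$overlap
  df$o <- round(df$o, 3)
  print(df, row.names = FALSE)
  cat(sprintf("bootstrap mean overlap %.3f, upper %d%% bound %.3f (n_boot = %d)\n",
              x$bootstrap$mean, round(100 * x$bootstrap$conf),
              x$bootstrap$upper, x$bootstrap$n_boot))
  invisible(x)
}
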