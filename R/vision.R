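# receptor-noise-limited visual modelling
#
# Pipeline: reflectance R(lambda) -> quantum catches Q_i under illuminant
# I(lambda) -> von Kries normalization against the adapting background ->
# log-contrasts Delta f_i -> receptor-noise-limited distance Delta S in
# just-noticeable differences (JNDs). Delta S ~ 1 is the discrimination
# threshold.

# CIE standard illuminant D65, relative spectral power at 10 nm (300-700 nm).
# Only the relative shape matters here: the illuminant is renormalized to
# unit mean on the working grid, and von Kries adaptation removes overall
# intensity.
d65_wl <- seq(300, 700, by = 10)
d65_power <- c(
  0.0341, 3.2945, 20.2360, 37.0535, 39.9488, 44.9117, 46.6383, 52.0891,
  49.9755, 54.6482, 82.7549, 91.4860, 93.4318, 86.6823, 104.8650, 117.0080,
  117.8120, 114.8610, 115.9230, 108.8110, 109.3540, 107.8020, 104.7900,
  107.6890, 104.4050, 104.0460, 100.0000, 96.3342, 95.7880, 88.6856,
  90.0062, 89.5991, 87.6987, 83.2886, 83.6992, 80.0268, 80.2146, 82.2778,
  78.2842, 69.7213, 71.6091
)

#' Construct a receptor-noise-limited visual system
#'
#' Defines the receptor set, noise model, illuminant and adapting background
#' used by [delta_S()]. The default is a synthetic stand-in for the average
#' violet-sensitive (VS) avian phenotype: four Gaussian-template receptors
#' with peak sensitivities at 416, 478, 542 and 607 nm, relative densities
#' 1:2:2:4, the most abundant (long-wavelength) receptor as the noise
#' reference with Weber fraction 0.1, D65 daylight and an ideal (flat)
#' adapting background. Real measured sensitivity curves can be supplied via
#' `sensitivities`.
#'
#' @param lambda_max peak wavelengths (nm) of the Gaussian receptor
#'   templates; ignored when `sensitivities` is given.
#' @param sigma Gaussian template width (nm).
#' @param sensitivities optional matrix (length(grid) x n receptors) of
#'   spectral sensitivities on `grid`; overrides the templates.
#' @param densities relative receptor densities, one per receptor, > 0.
#' @param weber Weber fraction of the reference receptor.
#' @param reference index of the reference receptor; default the most
#'   abundant.
#' @param illuminant `"D65"`, or a list with `wl` and `power` vectors.
#' @param background `"ideal"` (flat) or a reflectance vector on `grid`.
#' @param grid working wavelength grid (nm); all spectra are resampled onto
#'   it before any computation.
#' @return object of class `visual_system`.
#' @export
visual_system <- function(lambda_max = c(416, 478, 542, 607), sigma = 40,
                          sensitivities = NULL,
                          densities = c(1, 2, 2, 4), weber = 0.1,
                          reference = NULL,
                          illuminant = "D65", background = "ideal",
                          grid = 300:700) {
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing",
                                 call. = FALSE)
  if (is.null(sensitivities)) {
    S <- vapply(lambda_max, function(lm) exp(-((grid - lm)^2) / (2 * sigma^2)),
                numeric(length(grid)))
  } else {
    S <- as.matrix(sensitivities)
    if (nrow(S) != length(grid)) stop("sensitivities must be on `grid`",
                                      call. = FALSE)
  }
  nrec <- ncol(S)
  if (nrec < 2L || nrec > 4L) stop("2-4 receptors supported", call. = FALSE)
  if (any(S < 0)) stop("sensitivities must be non-negative", call. = FALSE)
  if (length(densities) != nrec || any(densities <= 0)) {
    stop("densities must be positive, one per receptor", call. = FALSE)
  }
  stopifnot_scalar_number(weber, "weber", lower = 0, strict = TRUE)
  reference <- reference %||% which.max(densities)

  if (identical(illuminant, "D65")) {
    illum <- approx(d65_wl, d65_power, xout = grid, rule = 2)$y
  } else {
    illum <- approx(illuminant$wl, illuminant$power, xout = grid, rule = 2)$y
  }
  illum <- illum / mean(illum)

  if (!identical(background, "ideal")) {
    background <- as.numeric(background)
    if (length(background) != length(grid)) {
      stop("background reflectance must be on `grid`", call. = FALSE)
    }
  }
  structure(list(grid = grid, S = S, densities = densities, weber = weber,
                 reference = as.integer(reference), illuminant = illum,
                 background = background,
                 labels = paste0("r", seq_len(nrec))),
            class = "visual_system")
}

#' @export
print.visual_system <- function(x, ...) {
  cat(sprintf("<visual system: %d receptors, Weber %.3g (reference %d), %g-%g nm>\n",
              ncol(x$S), x$weber, x$reference, min(x$grid), max(x$grid)))
  invisible(x)
}

# trapezoid weights for the working grid
trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  w[1] <- (x[2] - x[1]) / 2
  w[n] <- (x[n] - x[n - 1]) / 2
  if (n > 2L) w[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  w
}

#' Quantum catches
#'
#' Receptor quantum catches `Q_i = integral R(l) I(l) S_i(l) dl` by
#' trapezoidal quadrature on the working grid.
#'
#' @param refl reflectance vector on `vs$grid`, or a matrix with one column
#'   per spectrum.
#' @param vs a [visual_system].
#' @return matrix of catches, one row per spectrum, one column per receptor.
#' @export
quantum_catch <- function(refl, vs) {
  refl <- as.matrix(refl)
  if (nrow(refl) != length(vs$grid)) {
    stop("reflectance must be on the visual system's grid", call. = FALSE)
  }
  w <- trapz_weights(vs$grid)
  t(refl * (w * vs$illuminant)) %*% vs$S
}

background_catch <- function(vs) {
  w <- trapz_weights(vs$grid)
  if (identical(vs$background, "ideal")) {
    as.numeric((w * vs$illuminant) %*% vs$S)
  } else {
    as.numeric((w * vs$illuminant * vs$background) %*% vs$S)
  }
}

#' von Kries normalized catches
#'
#' `q_i = Q_i / Q_i(background)`; the adapting background cancels overall
#' illuminant intensity.
#'
#' @param Q catch matrix from [quantum_catch()].
#' @param vs a [visual_system].
#' @return matrix of normalized catches.
#' @export
von_kries <- function(Q, vs) {
  Qb <- background_catch(vs)
  if (any(Qb <= 0)) stop("receptor sees no light", call. = FALSE)
  sweep(as.matrix(Q), 2, Qb, "/")
}

#' Receptor noise
#'
#' `e_i = w * sqrt(eta_ref / eta_i)` where `w` is the Weber fraction of the
#' reference receptor and `eta` the relative densities, so `e_ref = w`.
#'
#' @param vs a [visual_system].
#' @return numeric vector of per-receptor noise values.
#' @export
receptor_noise <- function(vs) {
  vs$weber * sqrt(vs$densities[vs$reference] / vs$densities)
}

# receptor-noise-limited distance from log catch contrasts df and noise e,
# general quadratic form for 2-4 receptors:
#   dS^2 = sum_{j<k} (prod of e over the other receptors)^2 (df_j - df_k)^2
#          / sum over (n-1)-subsets of (prod e in subset)^2
rnl_distance <- function(df, e) {
  n <- length(e)
  pairs <- utils::combn(n, 2)
  num <- 0
  for (p in seq_len(ncol(pairs))) {
    j <- pairs[1, p]; k <- pairs[2, p]
    others <- setdiff(seq_len(n), c(j, k))
    w <- if (length(others)) prod(e[others])^2 else 1
    num <- num + w * (df[j] - df[k])^2
  }
  subs <- utils::combn(n, n - 1L)
  den <- sum(apply(subs, 2, function(s) prod(e[s])^2))
  sqrt(num / den)
}

#' Chromatic JND distance between two spectra
#'
#' The receptor-noise-limited distance Delta S between two reflectance
#' spectra under a visual system. With log catch contrasts
#' `df_i = ln q_i(a) - ln q_i(b)` and receptor noise `e_i`, the dichromat
#' distance is `|df_1 - df_2| / sqrt(e_1^2 + e_2^2)`; tri- and tetrachromat
#' distances use the standard quadratic forms of the receptor-noise model.
#'
#' @param a,b reflectance vectors on `vs$grid`.
#' @param vs a [visual_system].
#' @return Delta S in JNDs (non-negative).
#' @export
delta_S <- function(a, b, vs) {
  q <- von_kries(quantum_catch(cbind(a, b), vs), vs)
  if (any(q <= 0)) stop("non-positive normalized catch (log undefined)",
                        call. = FALSE)
  df <- log(q[1, ]) - log(q[2, ])
  rnl_distance(df, receptor_noise(vs))
}

# vectorized: JNDs from one spectrum to every column of a matrix
delta_S_to_set <- function(a, refl, vs) {
  q <- von_kries(quantum_catch(cbind(a, refl), vs), vs)
  if (any(q <= 0)) stop("non-positive normalized catch (log undefined)",
                        call. = FALSE)
  lf <- log(q)
  e <- receptor_noise(vs)
  n <- length(e)
  pairs <- utils::combn(n, 2)
  subs <- utils::combn(n, n - 1L)
  den <- sum(apply(subs, 2, function(s) prod(e[s])^2))
  df <- sweep(lf[-1, , drop = FALSE], 2, lf[1, ], "-")
  num <- 0
  for (p in seq_len(ncol(pairs))) {
    j <- pairs[1, p]; k <- pairs[2, p]
    others <- setdiff(seq_len(n), c(j, k))
    w <- if (length(others)) prod(e[others])^2 else 1
    num <- num + w * (df[, j] - df[, k])^2
  }
  sqrt(num / den)
}

#' Minimum JND distance to a cluster of spectra
#'
#' The colour-match score of an insect against a plant species: the minimum
#' Delta S between the insect's spectrum and any sheath measurement in the
#' species' cluster.
#'
#' @param insect reflectance vector on `vs$grid`.
#' @param cluster a [spectrum_set] (on the same grid) of sheath spectra.
#' @param vs a [visual_system].
#' @return minimum Delta S in JNDs.
#' @export
min_delta_S <- function(insect, cluster, vs) {
  if (n_spectra(cluster) < 1L) stop("empty cluster", call. = FALSE)
  min(delta_S_to_set(insect, cluster$refl, vs))
}

#' JND colour-match table for host/non-host comparisons
#'
#' For each population-pair comparison, scores every insect originating from
#' either species against both sheath clusters: one row for the match to its
#' own host's cluster and one for the alternative host.
#'
#' @param insects a [spectrum_set] of insect spectra; `meta$species` is the
#'   host of origin. An optional `meta$sex` column is carried through.
#' @param clusters named list of [spectrum_set] sheath clusters (replicates
#'   already averaged), one per plant species.
#' @param comparisons list of character pairs `c(originA, originB)`,
#'   optionally named (e.g. low/moderate/high overlap).
#' @param vs a [visual_system].
#' @return data frame of class `delta_s_table` with columns `comparison`,
#'   `individual`, `sex`, `origin`, `target`, `role` (host/alternative) and
#'   `deltaS`.
#' @export
match_table <- function(insects, clusters, comparisons, vs) {
  for (cmp in comparisons) {
    missing <- setdiff(cmp, names(clusters))
    if (length(missing)) {
      stop(sprintf("no sheath cluster for species '%s'", missing[1]),
           call. = FALSE)
    }
  }
  nm <- names(comparisons) %||% rep(NA_character_, length(comparisons))
  if (is.null(names(comparisons))) {
    nm <- vapply(comparisons, paste, "", collapse = "_vs_")
  }
  sex <- insects$meta$sex %||% rep(NA_character_, n_spectra(insects))
  rows <- list()
  for (ci in seq_along(comparisons)) {
    cmp <- comparisons[[ci]]
    for (origin in cmp) {
      alt <- setdiff(cmp, origin)
      idx <- which(insects$meta$species == origin)
      for (i in idx) {
        spec <- insects$refl[, i]
        for (target in c(origin, alt)) {
          rows[[length(rows) + 1L]] <- data.frame(
            comparison = nm[ci],
            individual = insects$meta$individual[i],
            sex = sex[i], origin = origin, target = target,
            role = if (target == origin) "host" else "alternative",
            deltaS = min_delta_S(spec, clusters[[target]], vs),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("delta_s_table", class(out))
  out
}
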