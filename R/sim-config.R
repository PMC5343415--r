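# simulation configuration: the study conditions for all generators

#' Convert an ellipse range specification to a convex polygon
#'
#' Generating ranges are convex polygons; ellipses are represented by a
#' regular polygonal approximation so that analytic overlaps of generating
#' ranges are available in closed (polygonal) form.
#'
#' @param center numeric (x, y).
#' @param radii numeric (a, b) semi-axes.
#' @param angle rotation in degrees.
#' @param n number of vertices.
#' @return a [convex_polygon].
#' @export
ellipse_polygon <- function(center, radii, angle = 0, n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  a <- angle * pi / 180
  x <- radii[1] * cos(th)
  y <- radii[2] * sin(th)
  v <- cbind(center[1] + x * cos(a) - y * sin(a),
             center[2] + x * sin(a) + y * cos(a))
  convex_polygon(v)
}

default_species_ranges <- function() {
  # a heterogeneous mosaic: one herbivore range and 11 host ranges with
  # overlaps from near-disjoint to near-complete, mimicking a regional flora
  # in which no single host spans the whole herbivore range
  list(
    C_uncinatus     = ellipse_polygon(c(5.0, 5.0), c(4.5, 3.2), 15),
    W_incurvata     = ellipse_polygon(c(2.2, 6.3), c(2.0, 1.6), -20),
    W_teres         = ellipse_polygon(c(4.6, 5.4), c(4.0, 2.9), 12),
    M_digitata      = ellipse_polygon(c(7.6, 3.4), c(1.5, 1.1), 30),
    M_spathulata    = ellipse_polygon(c(6.4, 6.6), c(1.7, 1.2), 0),
    H_aristatus     = ellipse_polygon(c(7.2, 3.8), c(2.2, 1.5), 20),
    H_synchroolepis = ellipse_polygon(c(3.4, 3.0), c(1.2, 0.9), 0),
    E_nuda          = ellipse_polygon(c(6.0, 7.0), c(1.4, 1.0), -15),
    E_stokoei       = ellipse_polygon(c(8.8, 5.8), c(1.0, 0.8), 0),
    E_muirii        = ellipse_polygon(c(1.6, 3.8), c(1.3, 1.0), 10),
    E_fistulosa     = ellipse_polygon(c(4.8, 8.0), c(1.6, 1.0), 0),
    E_filacea       = ellipse_polygon(c(5.2, 4.6), c(3.8, 2.8), 8)
  )
}

default_morph_cells <- function(populations) {
  # sex- and host-structured body dimensions (mm): females broader than
  # males; the population on the thicker-culmed host broader-bodied
  expand <- expand.grid(population = populations, sex = c("F", "M"),
                        stringsAsFactors = FALSE)
  base_w <- ifelse(expand$population == populations[1], 1.85, 2.25)
  expand$width_mean <- base_w + ifelse(expand$sex == "F", 0.15, -0.15)
  expand$width_sd <- 0.12
  expand$elytron_mean <- ifelse(expand$sex == "F", 7.4, 6.6)
  expand$elytron_sd <- 0.35
  expand$n <- 45L
  expand
}

default_spectra_groups <- function() {
  # sheath cluster sizes follow the measured design; insect groups match
  # their host's sheath colour (offset on the reflectance scale)
  sheaths <- data.frame(
    species = c("W_incurvata", "M_digitata", "H_aristatus", "M_spathulata",
                "E_nuda"),
    role = "sheath",
    n = c(18L, 15L, 12L, 10L, 11L),
    offset = c(0.10, -0.08, -0.02, 0.04, -0.14),
    stringsAsFactors = FALSE)
  insects <- data.frame(
    species = sheaths$species, role = "insect", n = 30L,
    offset = sheaths$offset, stringsAsFactors = FALSE)
  rbind(sheaths, insects)
}

#' Simulation configuration
#'
#' Bundles every generator parameter: the occurrence mosaic (region and
#' per-species generating ranges), the host-choice design (marginal choice
#' probabilities per population-by-sex cell, the logit-scale individual
#' intercept s.d. that induces within-individual correlation, observation
#' times, individuals per cell), morphometric cell means/s.d.s, and the
#' spectral model (wavelength grid, base curve, per-group reflectance
#' offsets, noise, replicate count). Identical config and seed give
#' bit-identical outputs.
#'
#' Defaults emulate the field design: ~44 herbivore records against 11 host
#' ranges with heterogeneous overlap; two populations of 90 individuals
#' (45 per sex) observed at 12, 15, 18, 21 and 24 h; sheath clusters of
#' 18/15/12/10/11 plants measured in duplicate.
#'
#' @param seed master integer seed; per-generator streams are derived by
#'   fixed offsets.
#' @param species_ranges named list of [convex_polygon] generating ranges
#'   (use [ellipse_polygon()] for elliptical ranges).
#' @param points_per_species named integer vector of record counts.
#' @param choice list: `populations` (character), `p` (matrix populations x
#'   sexes of marginal choice probabilities in (0,1), dimnames required),
#'   `sigma_indiv` (logit-scale intercept s.d. >= 0), `times` (hours),
#'   `n_per_cell` (individuals per population x sex cell).
#' @param morph data frame of morphometric cells: `population`, `sex`,
#'   `width_mean`, `width_sd`, `elytron_mean`, `elytron_sd`, `n`.
#' @param spectra list: `wl` (nm grid, strictly increasing), `base`
#'   (logistic-ramp + optional Gaussian-bump parameters: `low`, `high`,
#'   `mid`, `rate`, `bump_center`, `bump_height`, `bump_sd`), `groups`
#'   (data frame `species`, `role` insect/sheath, `n`, `offset`),
#'   `noise_sd` (reflectance-scale s.d. >= 0), `replicates` (per sheath).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       species_ranges = default_species_ranges(),
                       points_per_species = NULL,
                       choice = NULL, morph = NULL, spectra = NULL) {
  stopifnot_scalar_number(seed, "seed")
  if (is.null(points_per_species)) {
    points_per_species <- setNames(
      c(44L, rep(60L, length(species_ranges) - 1L)), names(species_ranges))
  }
  if (is.null(names(points_per_species)) ||
      !all(names(points_per_species) %in% names(species_ranges))) {
    stop("points_per_species must be named after species_ranges",
         call. = FALSE)
  }
  if (any(points_per_species < 0)) stop("counts must be >= 0", call. = FALSE)

  if (is.null(choice)) {
    pops <- c("M_digitata", "W_incurvata")
    p <- matrix(c(0.45, 0.35, 0.25, 0.15), 2, 2,
                dimnames = list(pops, c("F", "M")))
    choice <- list(populations = pops, p = p, sigma_indiv = 1.2,
                   times = c(12, 15, 18, 21, 24), n_per_cell = 45L)
  }
  if (!all(choice$p >= 0 & choice$p <= 1)) {
    stop("choice probabilities must be in [0,1]", call. = FALSE)
  }
  stopifnot_scalar_number(choice$sigma_indiv, "sigma_indiv", lower = 0)
  if (length(choice$times) < 1L) stop("need >= 1 time point", call. = FALSE)
  if (length(choice$populations) < 1L) stop("need >= 1 population",
                                            call. = FALSE)

  if (is.null(morph)) morph <- default_morph_cells(choice$populations)
  if (any(morph$width_mean <= 0) || any(morph$elytron_mean <= 0)) {
    stop("cell means must be > 0", call. = FALSE)
  }
  if (any(morph$width_sd < 0) || any(morph$elytron_sd < 0) ||
      any(morph$n < 0)) {
    stop("s.d.s and counts must be >= 0", call. = FALSE)
  }

  if (is.null(spectra)) {
    spectra <- list(
      wl = seq(300, 700, by = 1),
      base = list(low = 0.08, high = 0.55, mid = 560, rate = 0.025,
                  bump_center = 450, bump_height = 0.05, bump_sd = 25),
      groups = default_spectra_groups(),
      noise_sd = 0.02, replicates = 2L)
  }
  if (any(diff(spectra$wl) <= 0)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  stopifnot_scalar_number(spectra$noise_sd, "noise_sd", lower = 0)

  structure(list(seed = as.integer(seed), species_ranges = species_ranges,
                 points_per_species = points_per_species, choice = choice,
                 morph = morph, spectra = spectra),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim config: seed %d; %d species ranges; %d population(s) x %d time",
    " points; %d morph cells; %d spectral groups>\n"),
    x$seed, length(x$species_ranges), length(x$choice$populations),
    length(x$choice$times), nrow(x$morph), nrow(x$spectra$groups)))
  invisible(x)
}
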