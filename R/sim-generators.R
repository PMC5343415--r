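# seeded generators emulating the statistical structure of the field data
#
# One master seed lives in the config; each generator draws from its own
# stream derived by a fixed offset, so modules stay reproducible and
# independent of each other.

seed_offset <- c(occurrences = 101L, choice = 202L, morph = 303L,
                 spectra = 404L)

#' Generate occurrence records from the configured species ranges
#'
#' Uniform points inside each species' generating polygon, sampled by
#' rejection from the polygon's bounding box. Species with zero requested
#' points are absent from the output.
#'
#' @param config a [sim_config].
#' @return occurrence data frame (`species`, `x`, `y`).
#' @export
gen_occurrences <- function(config) {
  with_seed(config$seed + seed_offset[["occurrences"]], {
    out <- list()
    for (sp in names(config$species_ranges)) {
      n <- config$points_per_species[[sp]] %||% 0L
      if (n == 0L) next
      poly <- config$species_ranges[[sp]]
      if (polygon_area(poly) <= 0) {
        stop(sprintf("degenerate range for '%s'", sp), call. = FALSE)
      }
      v <- poly$vertices
      bb <- c(min(v[, 1]), max(v[, 1]), min(v[, 2]), max(v[, 2]))
      pts <- matrix(numeric(0), ncol = 2)
      while (nrow(pts) < n) {
        m <- max(2L * (n - nrow(pts)), 32L)
        cand <- cbind(runif(m, bb[1], bb[2]), runif(m, bb[3], bb[4]))
        cand <- cand[points_in_polygon(poly, cand), , drop = FALSE]
        pts <- rbind(pts, cand)
      }
      pts <- pts[seq_len(n), , drop = FALSE]
      out[[sp]] <- data.frame(species = sp, x = pts[, 1], y = pts[, 2],
                              stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    df
  })
}

#' Marginal probability of a logit-normal random-intercept model
#'
#' `E[plogis(b0 + sigma Z)]` with `Z ~ N(0,1)` by Gauss-Hermite quadrature.
#'
#' @param b0 conditional (subject-level) logit intercept.
#' @param sigma intercept s.d. on the logit scale.
#' @param nodes quadrature nodes.
#' @return marginal probability.
#' @export
logit_normal_marginal <- function(b0, sigma, nodes = 40) {
  if (sigma == 0) return(plogis(b0))
  gh <- pracma::gaussHermite(nodes)
  sum(gh$w * plogis(b0 + sigma * sqrt(2) * gh$x)) / sqrt(pi)
}

#' Conditional intercept matching a target marginal probability
#'
#' Solves `E[plogis(b0 + sigma Z)] = p` for `b0`. The generator specifies
#' MARGINAL probabilities (what a GEE estimates), so recovery tests compare
#' like with like.
#'
#' @param p target marginal probability in (0,1).
#' @param sigma logit-scale intercept s.d.
#' @return conditional intercept `b0`.
#' @export
solve_conditional_intercept <- function(p, sigma) {
  if (sigma == 0) return(qlogis(p))
  uniroot(function(b) logit_normal_marginal(b, sigma) - p,
          interval = qlogis(p) + c(-1, 1) * (5 + 5 * sigma),
          tol = 1e-10)$root
}

#' Intraclass correlation of repeated binary choices
#'
#' For the logit-normal model, the correlation between two choices of the
#' same individual: `(E[p(Z)^2] - p^2) / (p (1 - p))`.
#'
#' @param p marginal probability.
#' @param sigma logit-scale intercept s.d.
#' @return ICC in \[0, 1).
#' @export
logit_normal_icc <- function(p, sigma) {
  if (sigma == 0) return(0)
  b0 <- solve_conditional_intercept(p, sigma)
  gh <- pracma::gaussHermite(60)
  ep2 <- sum(gh$w * plogis(b0 + sigma * sqrt(2) * gh$x)^2) / sqrt(pi)
  (ep2 - p^2) / (p * (1 - p))
}

#' Logit-scale intercept s.d. giving a target ICC
#'
#' Inverse of [logit_normal_icc()] in `sigma` (at fixed marginal `p`).
#'
#' @param p marginal probability.
#' @param icc target intraclass correlation in \[0, 1).
#' @return `sigma`.
#' @export
sigma_for_icc <- function(p, icc) {
  if (icc <= 0) return(0)
  uniroot(function(s) logit_normal_icc(p, s) - icc, interval = c(1e-6, 20),
          tol = 1e-8)$root
}

#' Generate repeated binary host-choice trials
#'
#' One binary record per individual and time point. Each individual draws a
#' normal intercept on the logit scale (s.d. `sigma_indiv`) around the
#' conditional intercept solved so that the cell's MARGINAL choice
#' probability equals the configured value; repeated choices are then
#' conditionally independent Bernoulli draws, which induces exchangeable
#' within-individual correlation.
#'
#' @param config a [sim_config].
#' @return data frame (`individual`, `population`, `sex`, `time_h`,
#'   `choice`).
#' @export
gen_choice_trials <- function(config) {
  ch <- config$choice
  sexes <- colnames(ch$p) %||% c("F", "M")
  with_seed(config$seed + seed_offset[["choice"]], {
    rows <- list()
    counter <- 0L
    for (pop in ch$populations) {
      for (sx in sexes) {
        p <- ch$p[pop, sx]
        n <- if (length(ch$n_per_cell) == 1L) ch$n_per_cell
             else ch$n_per_cell[pop, sx]
        if (n == 0L) next
        if (p >= 1 - 1e-12 || p <= 1e-12) {
          probs <- matrix(round(p), n, length(ch$times))
        } else {
          b0 <- solve_conditional_intercept(p, ch$sigma_indiv)
          z <- rnorm(n)
          probs <- matrix(plogis(b0 + ch$sigma_indiv * z), n,
                          length(ch$times))
        }
        ids <- sprintf("ind%05d", counter + seq_len(n))
        counter <- counter + n
        choices <- matrix(rbinom(length(probs), 1, probs), nrow = n)
        rows[[length(rows) + 1L]] <- data.frame(
          individual = rep(ids, times = length(ch$times)),
          population = pop, sex = sx,
          time_h = rep(ch$times, each = n),
          choice = as.integer(choices),
          stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    df <- df[order(df$individual, df$time_h), ]
    rownames(df) <- NULL
    df
  })
}

#' Generate morphometric records
#'
#' Normal draws per population-by-sex cell (truncated at 0 by resampling)
#' for body width and elytron length.
#'
#' @param config a [sim_config].
#' @return data frame (`individual`, `population`, `sex`, `width_mm`,
#'   `elytron_mm`).
#' @export
gen_morphometrics <- function(config) {
  cells <- config$morph
  with_seed(config$seed + seed_offset[["morph"]], {
    rows <- list()
    counter <- 0L
    for (i in seq_len(nrow(cells))) {
      n <- cells$n[i]
      if (n == 0L) next
      ids <- sprintf("morph%05d", counter + seq_len(n))
      counter <- counter + n
      rows[[length(rows) + 1L]] <- data.frame(
        individual = ids,
        population = cells$population[i], sex = cells$sex[i],
        width_mm = rtruncnorm_pos(n, cells$width_mean[i], cells$width_sd[i]),
        elytron_mm = rtruncnorm_pos(n, cells$elytron_mean[i],
                                    cells$elytron_sd[i]),
        stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    df
  })
}

# positive-truncated normal by resampling (means here are many s.d.s above
# zero, so resampling is essentially never triggered)
rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- x <= 0
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x <= 0
  }
  x
}

# smooth plant-like base reflectance: logistic ramp + optional Gaussian bump
base_curve <- function(wl, b) {
  y <- b$low + (b$high - b$low) * plogis(b$rate * (wl - b$mid))
  if (!is.null(b$bump_center) && (b$bump_height %||% 0) != 0) {
    y <- y + b$bump_height * exp(-(wl - b$bump_center)^2 / (2 * b$bump_sd^2))
  }
  y
}

#' Generate reflectance spectra
#'
#' Every spectrum is the configured base curve plus its group's reflectance
#' offset plus i.i.d. Gaussian noise on the reflectance scale, clipped to
#' \[0, 1\]. Insect groups yield one spectrum per individual (with sexes
#' assigned alternately); sheath groups yield `replicates` spectra per
#' plant, mirroring duplicate field measurements.
#'
#' @param config a [sim_config].
#' @return a [spectrum_set]; insect spectra carry a `sex` metadata column.
#' @export
gen_spectra <- function(config) {
  sp <- config$spectra
  base <- base_curve(sp$wl, sp$base)
  with_seed(config$seed + seed_offset[["spectra"]], {
    cols <- list()
    meta <- list()
    insect_counter <- 0L
    for (i in seq_len(nrow(sp$groups))) {
      g <- sp$groups[i, ]
      if (g$n == 0L) next
      reps <- if (g$role == "sheath") sp$replicates else 1L
      for (ind in seq_len(g$n)) {
        # dialect: sheath spectra always carry a replicate label; insect
        # individual ids start with the sex letter (F/M, assigned
        # alternately) and are numbered globally so ids are unique across
        # origin groups
        sex <- if (g$role == "insect") c("F", "M")[1L + ind %% 2L]
               else NA_character_
        if (g$role == "insect") insect_counter <- insect_counter + 1L
        ind_id <- if (g$role == "insect") {
          sprintf("%s%04d", sex, insect_counter)
        } else {
          sprintf("s%03d", ind)
        }
        for (r in seq_len(reps)) {
          y <- base + g$offset + rnorm(length(sp$wl), 0, sp$noise_sd)
          cols[[length(cols) + 1L]] <- pmin(pmax(y, 0), 1)
          meta[[length(meta) + 1L]] <- data.frame(
            species = g$species, individual = ind_id,
            replicate = if (g$role == "sheath") sprintf("r%d", r)
                        else NA_character_,
            role = g$role, sex = sex, stringsAsFactors = FALSE)
        }
      }
    }
    spectrum_set(sp$wl, do.call(cbind, cols), do.call(rbind, meta))
  })
}
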