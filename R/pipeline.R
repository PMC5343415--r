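# end-to-end orchestration: mosaic -> vision -> preference -> groupstats

fnv1a32 <- function(txt) {
  # small stable content hash for provenance (config hash)
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte since b < 256
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b %% 256)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Simulate a full three-comparison study
#'
#' Builds the four inputs of the end-to-end analysis for the standard
#' design: three population-pair comparisons labelled by their hosts'
#' range overlap (low, moderate, high), each with its own host-choice
#' experiment and morphometric sample, plus one shared spectral data set
#' (five sheath clusters and five insect origin groups) and the occurrence
#' mosaic. Which comparisons carry true divergence (in preference, body
#' width and colour matching simultaneously) is controlled by `effects`;
#' the default places divergence in the low- and moderate-overlap
#' comparisons only.
#'
#' @param seed master seed.
#' @param effects named logical vector over `c("low","moderate","high")`.
#' @param n_per_cell individuals per population-by-sex cell in the choice
#'   experiments (2 cells per population).
#' @param icc within-individual correlation of repeated choices.
#' @param p_effect marginal choice probability for the reference host in
#'   its own population when an effect is present (the other population
#'   gets `1 - p_effect`; both get 0.5 when absent).
#' @return list with `occurrences`, `trials`, `morph`, `spectra`
#'   (a [spectrum_set]) and `comparisons` (the comparison definitions).
#' @export
sim_study <- function(seed = 1,
                      effects = c(low = TRUE, moderate = TRUE, high = FALSE),
                      n_per_cell = 45L, icc = 0.3, p_effect = 0.7) {
  comparisons <- list(
    low = list(name = "low", populations = c("M_digitata", "W_incurvata"),
               reference_host = "M_digitata",
               sheaths = c("M_digitata", "W_incurvata")),
    moderate = list(name = "moderate",
                    populations = c("M_spathulata", "E_nuda"),
                    reference_host = "M_spathulata",
                    sheaths = c("M_spathulata", "E_nuda")),
    high = list(name = "high", populations = c("M_digitata", "H_aristatus"),
                reference_host = "M_digitata",
                sheaths = c("M_digitata", "H_aristatus")))

  sigma <- sigma_for_icc(0.5, icc)
  trials <- list()
  morph <- list()
  for (ci in seq_along(comparisons)) {
    cmp <- comparisons[[ci]]
    eff <- isTRUE(effects[[cmp$name]])
    pops <- cmp$populations
    p_ref <- if (eff) p_effect else 0.5
    p_alt <- if (eff) 1 - p_effect else 0.5
    p <- matrix(c(p_ref, p_alt, p_ref, p_alt), 2, 2,
                dimnames = list(pops, c("F", "M")))
    cells <- default_morph_cells(pops)
    if (!eff) {
      # same width distribution in both populations
      cells$width_mean <- 2.05 + ifelse(cells$sex == "F", 0.15, -0.15)
    }
    cells$n <- n_per_cell
    cfg <- sim_config(
      seed = seed + 1000L * ci,
      choice = list(populations = pops, p = p, sigma_indiv = sigma,
                    times = c(12, 15, 18, 21, 24), n_per_cell = n_per_cell),
      morph = cells)
    tr <- gen_choice_trials(cfg)
    tr$individual <- paste(cmp$name, tr$individual, sep = "_")
    tr$comparison <- cmp$name
    mo <- gen_morphometrics(cfg)
    mo$individual <- paste(cmp$name, mo$individual, sep = "_")
    mo$comparison <- cmp$name
    trials[[ci]] <- tr
    morph[[ci]] <- mo
  }

  # spectral offsets: insects sit on their own host's sheath colour where
  # the comparison carries a colour effect; where it does not, both insect
  # groups share the reference population's colour (parallel match profiles)
  sheath_off <- c(W_incurvata = 0.10, M_digitata = -0.08, H_aristatus = -0.02,
                  M_spathulata = 0.04, E_nuda = -0.14)
  insect_off <- sheath_off
  for (cmp in comparisons) {
    if (!isTRUE(effects[[cmp$name]])) {
      insect_off[cmp$populations] <- insect_off[cmp$reference_host]
    }
  }
  groups <- rbind(
    data.frame(species = names(sheath_off), role = "sheath",
               n = c(18L, 15L, 12L, 10L, 11L),
               offset = as.numeric(sheath_off), stringsAsFactors = FALSE),
    data.frame(species = names(insect_off), role = "insect", n = 30L,
               offset = as.numeric(insect_off), stringsAsFactors = FALSE))
  scfg <- sim_config(seed = seed, spectra = list(
    wl = seq(300, 700, by = 1),
    base = list(low = 0.08, high = 0.55, mid = 560, rate = 0.025,
                bump_center = 450, bump_height = 0.05, bump_sd = 25),
    groups = groups, noise_sd = 0.02, replicates = 2L))

  occ <- gen_occurrences(sim_config(seed = seed))
  list(occurrences = occ,
       trials = do.call(rbind, trials),
       morph = do.call(rbind, morph),
       spectra = gen_spectra(scfg),
       comparisons = comparisons)
}

default_run_config <- function() {
  list(version = 1L, seed = 1L, herbivore = "C_uncinatus", hosts = NULL,
       min_records = 2L, n_boot = 10000L, conf = 0.95,
       link = "logit", corstr = "exchangeable", ss_type = "II",
       vision = list(lambda_max = c(416, 478, 542, 607),
                     densities = c(1, 2, 2, 4), weber = 0.1,
                     grid = c(300, 700, 1)),
       comparisons = NULL, inputs = NULL, data = NULL, out_dir = NULL)
}

load_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- default_run_config()
  cfg[names(config)] <- config
  if (is.null(cfg$comparisons)) stop("config needs comparisons", call. = FALSE)
  names(cfg$comparisons) <- vapply(cfg$comparisons, function(x) x$name, "")
  cfg
}

load_inputs <- function(cfg) {
  if (!is.null(cfg$data)) return(cfg$data)
  if (is.null(cfg$inputs)) stop("config needs inputs or data", call. = FALSE)
  list(occurrences = read_occurrences(cfg$inputs$occurrences,
                                      lonlat = isTRUE(cfg$lonlat)),
       trials = read_trials(cfg$inputs$trials),
       morph = read_morph(cfg$inputs$morph),
       spectra = read_spectra(cfg$inputs$spectra,
                              percent = isTRUE(cfg$percent)))
}

#' Validate pipeline inputs
#'
#' Schema and cross-reference checks; problems are returned as a character
#' vector of issues, never raised. An empty vector means clean inputs.
#'
#' @param config run configuration (list or YAML path), see
#'   [run_pipeline()].
#' @return character vector of issues.
#' @export
validate_inputs <- function(config) {
  cfg <- tryCatch(load_run_config(config), error = function(e) e)
  if (inherits(cfg, "error")) return(conditionMessage(cfg))
  issues <- character(0)
  data <- tryCatch(load_inputs(cfg), error = function(e) e)
  if (inherits(data, "error")) return(conditionMessage(data))

  tr <- data$trials
  if (!all(tr$choice %in% c(0, 1))) issues <- c(issues, "non-binary choice values")
  pop_per_ind <- tapply(tr$population, tr$individual,
                        function(x) length(unique(x)))
  if (any(pop_per_ind > 1L)) {
    issues <- c(issues, "individual in multiple populations")
  }
  sex_per_ind <- tapply(tr$sex, tr$individual, function(x) length(unique(x)))
  if (any(sex_per_ind > 1L)) issues <- c(issues, "individual with multiple sexes")

  occ <- data$occurrences
  if (sum(occ$species == cfg$herbivore) < 3L) {
    issues <- c(issues, sprintf("fewer than 3 records for herbivore '%s'",
                                cfg$herbivore))
  }
  sp <- data$spectra
  g <- cfg$vision$grid
  if (min(sp$wl) > g[1] || max(sp$wl) < g[2]) {
    issues <- c(issues, "spectra do not span the visual-system grid")
  }
  sheaths <- unique(sp$meta$species[!is.na(sp$meta$replicate)])
  for (cmp in cfg$comparisons) {
    if (!all(cmp$populations %in% tr$population)) {
      issues <- c(issues, sprintf("comparison '%s': population missing from trials",
                                  cmp$name))
    }
    if (!all(cmp$sheaths %in% sheaths)) {
      issues <- c(issues, sprintf("comparison '%s': sheath cluster missing from spectra",
                                  cmp$name))
    }
  }
  if (any(data$morph$width_mm <= 0) || any(data$morph$elytron_mm <= 0)) {
    issues <- c(issues, "non-positive morphometric measurements")
  }
  issues
}

#' Run the end-to-end analysis
#'
#' Executes all stages from one configuration: the host-range mosaic, the
#' JND colour-match table with split-plot ANOVAs per sex, the GEE
#' preference analysis with Wald tests, back-transformed cell means,
#' preference calls and Hedges' d, and the morphometric ANOVAs with Tukey
#' post hocs. Results are returned as a report object and, when `out_dir`
#' is set, written as CSV/JSON files. Deterministic given the seed (the
#' bootstrap is the only random stage).
#'
#' Configuration fields (list or YAML path): `inputs` (paths to
#' `occurrences`, `trials`, `morph`, `spectra` CSVs) or `data` (the same
#' four objects in memory); `herbivore`; optional `hosts` (default: all
#' other species in the occurrence file); `min_records`; `n_boot`, `conf`,
#' `seed`; `link`, `corstr`, `ss_type`; `vision` (lambda_max, densities,
#' weber, grid as c(from, to, step)); `comparisons` — a list of
#' `list(name, populations, reference_host, sheaths)`; `out_dir`.
#'
#' Divergence is declared per comparison when the population Wald test has
#' p < 0.05 (preference) and when the origin-by-species interaction has
#' p < 0.05 in both sexes (colour).
#'
#' @param config list or YAML path.
#' @return object of class `pipeline_report`.
#' @export
run_pipeline <- function(config) {
  cfg <- load_run_config(config)
  data <- load_inputs(cfg)
  issues <- validate_inputs(cfg)
  report <- list(provenance = list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("mosaicadapt")),
    config_hash = fnv1a32(paste(deparse(cfg[setdiff(names(cfg), "data")]),
                                collapse = "\n")),
    timestamp = format(Sys.time(), tz = "UTC")))
  report$issues <- issues
  errors <- list()

  # --- mosaic -------------------------------------------------------------
  mosaic <- tryCatch({
    hosts <- cfg$hosts %||%
      setdiff(unique(data$occurrences$species), cfg$herbivore)
    mosaic_report(data$occurrences, cfg$herbivore, hosts,
                  min_records = cfg$min_records, n_boot = cfg$n_boot,
                  conf = cfg$conf, seed = cfg$seed)
  }, error = function(e) {
    errors[["mosaic"]] <<- conditionMessage(e)
    NULL
  })
  report$mosaic <- mosaic

  # --- vision -------------------------------------------------------------
  deltas <- tryCatch({
    vsn <- cfg$vision
    grid <- seq(vsn$grid[1], vsn$grid[2], by = vsn$grid[3])
    vs <- visual_system(lambda_max = vsn$lambda_max,
                        densities = vsn$densities, weber = vsn$weber,
                        grid = grid)
    sp <- resample_spectra(data$spectra, grid)
    is_sheath <- !is.na(sp$meta$replicate)
    sheaths <- average_replicates(subset_spectra(sp, is_sheath))
    clusters <- lapply(split(seq_len(n_spectra(sheaths)),
                             sheaths$meta$species),
                       function(ix) subset_spectra(sheaths, ix))
    insects <- subset_spectra(sp, !is_sheath)
    if (is.null(insects$meta$sex)) {
      lead <- substr(insects$meta$individual, 1, 1)
      insects$meta$sex <- ifelse(lead %in% c("F", "M"), lead, NA_character_)
    }
    cmp_pairs <- lapply(cfg$comparisons, function(x) x$sheaths)
    match_table(insects, clusters, cmp_pairs, vs)
  }, error = function(e) {
    errors[["vision"]] <<- conditionMessage(e)
    NULL
  })
  report$deltas <- deltas

  # --- per-comparison analyses --------------------------------------------
  report$comparisons <- lapply(cfg$comparisons, function(cmp) {
    res <- list(name = cmp$name, populations = cmp$populations,
                reference_host = cmp$reference_host)

    res$preference <- tryCatch({
      tr <- if (!is.null(data$trials$comparison)) {
        data$trials[data$trials$comparison == cmp$name, ]
      } else {
        data$trials[data$trials$population %in% cmp$populations, ]
      }
      tr$population <- factor(tr$population,
                              levels = c(cmp$reference_host,
                                         setdiff(cmp$populations,
                                                 cmp$reference_host)))
      fit <- fit_gee(tr, link = cfg$link, corstr = cfg$corstr)
      mm <- marginal_means(fit, tr, conf = cfg$conf)
      wald <- lapply(setNames(nm = fit$term_labels),
                     function(t) wald_term_test(fit, t))
      list(fit = fit, wald = wald, means = mm,
           effect_size = population_effect_size(mm))
    }, error = function(e) {
      errors[[paste0("preference_", cmp$name)]] <<- conditionMessage(e)
      NULL
    })

    res$morph <- tryCatch({
      mo <- if (!is.null(data$morph$comparison)) {
        data$morph[data$morph$comparison == cmp$name, ]
      } else {
        data$morph[data$morph$population %in% cmp$populations, ]
      }
      mo <- add_stockiness(mo)
      list(width = anova_two_way(mo, "width", ss_type = cfg$ss_type),
           stockiness = anova_two_way(mo, "stockiness", ss_type = cfg$ss_type),
           tukey_width = tukey_hsd(mo, "width", by = "cell"))
    }, error = function(e) {
      errors[[paste0("morph_", cmp$name)]] <<- conditionMessage(e)
      NULL
    })

    res$colour <- tryCatch({
      if (is.null(report$deltas)) stop("vision stage failed")
      ds <- report$deltas[report$deltas$comparison ==
                            paste(cmp$sheaths, collapse = "_vs_") |
                            report$deltas$comparison == cmp$name, ]
      sexes <- sort(unique(ds$sex[!is.na(ds$sex)]))
      if (length(sexes) == 0L) sexes <- NA_character_
      per_sex <- lapply(setNames(nm = sexes), function(sx) {
        sub <- if (is.na(sx)) ds else ds[ds$sex == sx, ]
        rm_anova_2x2(sub)
      })
      per_sex
    }, error = function(e) {
      errors[[paste0("colour_", cmp$name)]] <<- conditionMessage(e)
      NULL
    })

    pref_p <- if (!is.null(res$preference)) {
      res$preference$wald$population$p
    } else NA_real_
    colour_ps <- if (!is.null(res$colour)) {
      vapply(res$colour, function(a) {
        as.data.frame(a)[a$term == "origin:species", "p"]
      }, numeric(1))
    } else NA_real_
    res$divergence <- list(
      preference = isTRUE(pref_p < 0.05),
      colour = all(!is.na(colour_ps)) && all(colour_ps < 0.05),
      preference_p = pref_p, colour_p = colour_ps)
    res
  })
  report$errors <- errors

  class(report) <- "pipeline_report"
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  if (length(x$issues)) cat("input issues:", paste(x$issues, collapse = "; "), "\n")
  if (!is.null(x$mosaic)) {
    cat(sprintf("mosaic: mean host overlap %.3f (upper bound %.3f)\n",
                x$mosaic$bootstrap$mean, x$mosaic$bootstrap$upper))
  }
  for (cmp in x$comparisons) {
    d <- cmp$divergence
    cat(sprintf("%s: preference Wald p = %.3g [%s]; colour interaction %s [%s]\n",
                cmp$name, d$preference_p,
                if (d$preference) "divergent" else "ns",
                paste(sprintf("%.3g", d$colour_p), collapse = "/"),
                if (d$colour) "divergent" else "ns"))
  }
  if (length(x$errors)) {
    cat("stage errors:\n")
    for (nm in names(x$errors)) cat(" ", nm, ":", x$errors[[nm]], "\n")
  }
  invisible(x)
}

report_json <- function(report) {
  per_cmp <- lapply(report$comparisons, function(cmp) {
    list(
      populations = cmp$populations,
      reference_host = cmp$reference_host,
      preference = if (!is.null(cmp$preference)) list(
        coefficients = as.list(coef(cmp$preference$fit)),
        alpha = cmp$preference$fit$alpha,
        wald = lapply(cmp$preference$wald, function(w) w[c("wald", "df", "p")]),
        means = cmp$preference$means,
        hedges_d = cmp$preference$effect_size$d,
        hedges_d_var = cmp$preference$effect_size$var),
      morph = if (!is.null(cmp$morph)) list(
        width = as.data.frame(cmp$morph$width),
        stockiness = as.data.frame(cmp$morph$stockiness)),
      colour = if (!is.null(cmp$colour)) {
        lapply(cmp$colour, as.data.frame)
      },
      divergence = cmp$divergence)
  })
  list(provenance = report$provenance, issues = report$issues,
       mosaic = if (!is.null(report$mosaic)) list(
         overlap = report$mosaic$overlap,
         bootstrap = report$mosaic$bootstrap,
         included_hosts = report$mosaic$included_hosts,
         excluded_hosts = report$mosaic$excluded_hosts),
       comparisons = per_cmp,
       errors = report$errors)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_json(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$mosaic)) {
    write.csv(report$mosaic$overlap, file.path(out_dir, "overlap.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(report$mosaic$symmetric),
              file.path(out_dir, "symmetric_overlap.csv"))
  }
  if (!is.null(report$deltas)) {
    write.csv(as.data.frame(report$deltas), file.path(out_dir, "deltas.csv"),
              row.names = FALSE)
  }
  invisible(out_dir)
}
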