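# fixed-effects ANOVAs, Tukey post hocs, and the split-plot colour test

#' Derive stockiness from a morphometric table
#'
#' Stockiness is body width divided by elytron length, a size-standardized
#' shape measure.
#'
#' @param morph data frame with columns `width_mm`, `elytron_mm`.
#' @return `morph` with a `stockiness` column added.
#' @export
add_stockiness <- function(morph) {
  if (any(morph$width_mm <= 0) || any(morph$elytron_mm <= 0)) {
    stop("widths and elytron lengths must be positive", call. = FALSE)
  }
  morph$stockiness <- morph$width_mm / morph$elytron_mm
  morph
}

#' Two-way fixed-effects ANOVA on a morphometric response
#'
#' Least-squares ANOVA with host population and sex as factors. Sums of
#' squares are Type II by default (marginal, respecting marginality), which
#' equals sequential SS for balanced data; Type I and III are available.
#' Zero-variance (degenerate) data return F = 0, p = 1 with a flag rather
#' than an error.
#'
#' @param morph data frame with `population`, `sex` and the response column.
#' @param response `"width"` (column `width_mm`) or `"stockiness"` (derived
#'   if absent).
#' @param include_interaction include the population x sex interaction.
#' @param ss_type `"II"` (default), `"I"` or `"III"`.
#' @return data frame of class `anova_table` with columns `term`, `SS`,
#'   `df`, `F`, `p` and attribute `degenerate`.
#' @export
anova_two_way <- function(morph, response = c("width", "stockiness"),
                          include_interaction = FALSE,
                          ss_type = c("II", "I", "III")) {
  response <- match.arg(response)
  ss_type <- match.arg(ss_type)
  if (response == "stockiness" && is.null(morph$stockiness)) {
    morph <- add_stockiness(morph)
  }
  ycol <- if (response == "width") "width_mm" else "stockiness"
  df <- data.frame(y = morph[[ycol]],
                   population = factor(morph$population),
                   sex = factor(morph$sex))
  # factors collapsed to one level drop out: the model reduces to one-way
  facs <- c("population", "sex")[c(nlevels(df$population), nlevels(df$sex)) > 1L]
  if (length(facs) == 0L) stop("need >= 2 levels in some factor", call. = FALSE)
  if (include_interaction && length(facs) == 2L &&
      any(table(df$population, df$sex) == 0L)) {
    stop("empty cell with interaction requested", call. = FALSE)
  }
  rhs <- paste(facs, collapse = if (include_interaction) " * " else " + ")
  fml <- stats::as.formula(paste("y ~", rhs))

  if (var(df$y) == 0) {
    terms <- c(facs,
               if (include_interaction && length(facs) == 2L) "population:sex",
               "Residuals")
    out <- data.frame(term = terms, SS = 0,
                      df = c(rep(1L, length(terms) - 1L),
                             nrow(df) - length(terms)),
                      F = c(rep(0, length(terms) - 1L), NA),
                      p = c(rep(1, length(terms) - 1L), NA))
    class(out) <- c("anova_table", class(out))
    attr(out, "degenerate") <- TRUE
    return(out)
  }

  fit <- stats::lm(fml, data = df)
  if (ss_type == "I") {
    a <- stats::anova(fit)
    out <- data.frame(term = rownames(a), SS = a$`Sum Sq`, df = a$Df,
                      F = a$`F value`, p = a$`Pr(>F)`)
  } else {
    a <- car::Anova(fit, type = ss_type)
    out <- data.frame(term = rownames(a), SS = a$`Sum Sq`, df = a$Df,
                      F = a$`F value`, p = a$`Pr(>F)`)
  }
  rownames(out) <- NULL
  class(out) <- c("anova_table", class(out))
  attr(out, "degenerate") <- FALSE
  out
}

#' @export
print.anova_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$SS <- signif(y$SS, 5)
  y$F <- signif(y$F, 5)
  y$p <- signif(y$p, 4)
  print(y, row.names = FALSE)
  if (isTRUE(attr(x, "degenerate"))) cat("(degenerate zero-variance data)\n")
  invisible(x)
}

#' Tukey-Kramer post hoc comparisons with compact letter display
#'
#' Pairwise comparisons of all population-by-sex cells (or any single
#' grouping) using the studentized-range distribution:
#' `q = |m_a - m_b| / sqrt(MS_resid (1/n_a + 1/n_b) / 2)`, with adjusted p
#' from `ptukey` at (k groups, residual df). Groups not sharing a letter in
#' the compact letter display differ at the given alpha.
#'
#' @param morph data frame with `population`, `sex` and the response column.
#' @param response `"width"` or `"stockiness"`.
#' @param by `"cell"` (population x sex, default), `"population"` or
#'   `"sex"`.
#' @param alpha significance level for the letter display.
#' @return list of class `tukey_table`: `pairs` data frame (`group1`,
#'   `group2`, `diff`, `q`, `p_adj`), `letters` named character vector,
#'   `ms_resid`, `df_resid`.
#' @export
tukey_hsd <- function(morph, response = c("width", "stockiness"),
                      by = c("cell", "population", "sex"), alpha = 0.05) {
  response <- match.arg(response)
  by <- match.arg(by)
  if (response == "stockiness" && is.null(morph$stockiness)) {
    morph <- add_stockiness(morph)
  }
  y <- morph[[if (response == "width") "width_mm" else "stockiness"]]
  g <- switch(by,
              cell = factor(paste(morph$population, morph$sex, sep = ":")),
              population = factor(morph$population),
              sex = factor(morph$sex))
  if (any(table(g) < 1L)) stop("empty group", call. = FALSE)
  k <- nlevels(g)
  if (k < 2L) stop("need >= 2 groups", call. = FALSE)
  n <- tapply(y, g, length)
  m <- tapply(y, g, mean)
  df_resid <- length(y) - k
  ms_resid <- sum((y - m[g])^2) / df_resid

  combs <- utils::combn(levels(g), 2)
  pairs <- data.frame(group1 = combs[1, ], group2 = combs[2, ],
                      stringsAsFactors = FALSE)
  pairs$diff <- m[pairs$group1] - m[pairs$group2]
  if (ms_resid == 0) {
    pairs$q <- ifelse(pairs$diff == 0, 0, Inf)
    pairs$p_adj <- ifelse(pairs$diff == 0, 1, 0)
  } else {
    pairs$q <- abs(pairs$diff) /
      sqrt(ms_resid * (1 / n[pairs$group1] + 1 / n[pairs$group2]) / 2)
    pairs$p_adj <- ptukey(pairs$q, k, df_resid, lower.tail = FALSE)
  }
  rownames(pairs) <- NULL
  letters_out <- compact_letters(levels(g), pairs, alpha)
  structure(list(pairs = pairs, letters = letters_out,
                 ms_resid = ms_resid, df_resid = df_resid),
            class = "tukey_table")
}

#' @export
print.tukey_table <- function(x, ...) {
  p <- x$pairs
  p$diff <- signif(p$diff, 4)
  p$q <- signif(p$q, 4)
  p$p_adj <- signif(p$p_adj, 4)
  print(p, row.names = FALSE)
  cat("letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = "  "), "\n")
  invisible(x)
}

# insert-and-absorb compact letter display: groups in the same column are
# not significantly different; columns become letters
compact_letters <- function(groups, pairs, alpha) {
  cols <- list(groups)
  sig <- pairs[pairs$p_adj < alpha, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$group1[i]; b <- sig$group2[i]
    newcols <- list()
    for (col in cols) {
      if (a %in% col && b %in% col) {
        newcols <- c(newcols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else {
        newcols <- c(newcols, list(col))
      }
    }
    # absorb columns contained in (or duplicating) another
    keep <- rep(TRUE, length(newcols))
    for (u in seq_along(newcols)) {
      for (v in seq_along(newcols)) {
        if (u == v || !keep[u] || !keep[v]) next
        if (all(newcols[[u]] %in% newcols[[v]]) &&
            (length(newcols[[u]]) < length(newcols[[v]]) ||
             (length(newcols[[u]]) == length(newcols[[v]]) && u > v))) {
          keep[u] <- FALSE
          break
        }
      }
    }
    cols <- newcols[keep]
  }
  out <- setNames(rep("", length(groups)), groups)
  for (ci in seq_along(cols)) {
    lab <- letters[ci]
    for (gname in cols[[ci]]) out[gname] <- paste0(out[gname], lab)
  }
  out
}

#' 2x2 split-plot repeated-measures ANOVA on colour-match scores
#'
#' Each insect carries two JND scores (match to its own host's sheaths and
#' to the alternative host's); population origin is the between-subjects
#' factor and target plant species the within-subjects factor, with
#' individual as the random stratum. The between factor is tested against
#' subject-within-group error; the within factor and the origin x species
#' interaction against the species x subject residual. A significant
#' interaction is the local-adaptation signal. Group sizes may differ.
#'
#' @param ds a [match_table()] result (or any data frame with `individual`,
#'   `origin`, `target`, `deltaS`), already restricted to one comparison and
#'   one sex if desired.
#' @return data frame of class `rm_anova_table` with rows `origin`
#'   (between), `species` (within), `origin:species` (interaction) and the
#'   two error strata; columns `term`, `SS`, `df`, `F`, `p`; attribute
#'   `degenerate`.
#' @export
rm_anova_2x2 <- function(ds) {
  need <- c("individual", "origin", "target", "deltaS")
  if (!all(need %in% names(ds))) stop("missing columns", call. = FALSE)
  targets <- sort(unique(ds$target))
  if (length(targets) != 2L) stop("within factor must have 2 levels",
                                  call. = FALSE)
  counts <- table(ds$individual)
  if (any(counts != 2L)) {
    stop(sprintf("individual '%s' does not have exactly 2 rows",
                 names(counts)[counts != 2L][1]), call. = FALSE)
  }
  wide <- merge(
    ds[ds$target == targets[1], c("individual", "origin", "deltaS")],
    ds[ds$target == targets[2], c("individual", "deltaS")],
    by = "individual", suffixes = c("_1", "_2"))
  if (nrow(wide) != length(counts)) {
    bad <- names(counts)[!(names(counts) %in% wide$individual)][1]
    stop(sprintf("individual '%s' does not have one row per target species",
                 bad), call. = FALSE)
  }
  g <- factor(wide$origin)
  G <- nlevels(g)
  if (G < 2L || any(table(g) < 2L)) {
    stop("need >= 2 individuals per origin", call. = FALSE)
  }
  N <- nrow(wide)
  m <- (wide$deltaS_1 + wide$deltaS_2) / 2   # subject means
  d <- wide$deltaS_2 - wide$deltaS_1         # within-subject contrasts

  if (var(c(wide$deltaS_1, wide$deltaS_2)) == 0) {
    out <- data.frame(
      term = c("origin", "subject(origin)", "species", "origin:species",
               "species:subject"),
      SS = 0, df = c(G - 1L, N - G, 1L, G - 1L, N - G),
      F = c(0, NA, 0, 0, NA), p = c(1, NA, 1, 1, NA))
    class(out) <- c("rm_anova_table", class(out))
    attr(out, "degenerate") <- TRUE
    attr(out, "targets") <- targets
    return(out)
  }

  gm <- tapply(m, g, mean)
  ng <- as.numeric(table(g))
  mbar <- mean(m)
  # between-subjects stratum (original units: x2 for the 2 repeats)
  ss_origin <- 2 * sum(ng * (gm - mbar)^2)
  ss_subj <- 2 * sum((m - gm[g])^2)
  df_origin <- G - 1L
  df_subj <- N - G
  F_origin <- (ss_origin / df_origin) / (ss_subj / df_subj)

  # within-subjects stratum via the difference scores (x1/2 back to y units)
  dg <- tapply(d, g, mean)
  dbar <- mean(d)
  ss_species <- N * dbar^2 / 2
  ss_inter <- sum(ng * (dg - dbar)^2) / 2
  ss_werr <- sum((d - dg[g])^2) / 2
  df_werr <- N - G
  F_species <- (ss_species / 1) / (ss_werr / df_werr)
  F_inter <- (ss_inter / (G - 1L)) / (ss_werr / df_werr)

  out <- data.frame(
    term = c("origin", "subject(origin)", "species", "origin:species",
             "species:subject"),
    SS = c(ss_origin, ss_subj, ss_species, ss_inter, ss_werr),
    df = c(df_origin, df_subj, 1L, G - 1L, df_werr),
    F = c(F_origin, NA, F_species, F_inter, NA),
    p = c(pf(F_origin, df_origin, df_subj, lower.tail = FALSE), NA,
          pf(F_species, 1, df_werr, lower.tail = FALSE),
          pf(F_inter, G - 1L, df_werr, lower.tail = FALSE), NA))
  class(out) <- c("rm_anova_table", class(out))
  attr(out, "degenerate") <- FALSE
  attr(out, "targets") <- targets
  out
}

#' @export
print.rm_anova_table <- function(x, ...) {
  cat("Split-plot repeated-measures ANOVA",
      if (!is.null(attr(x, "targets"))) {
        sprintf("(within levels: %s)", paste(attr(x, "targets"),
                                             collapse = " vs "))
      }, "\n")
  y <- as.data.frame(x)
  y$SS <- signif(y$SS, 5)
  y$F <- signif(y$F, 5)
  y$p <- signif(y$p, 4)
  print(y, row.names = FALSE)
  if (isTRUE(attr(x, "degenerate"))) cat("(degenerate zero-variance data)\n")
  invisible(x)
}

#' Median culm thickness per species and position
#'
#' @param culm data frame with `species`, `position` (apex/base),
#'   `thickness_mm`.
#' @return data frame `species`, `position`, `median_mm`, `n`.
#' @export
summarize_culm <- function(culm) {
  if (!all(culm$position %in% c("apex", "base"))) {
    stop("position must be apex or base", call. = FALSE)
  }
  agg <- aggregate(thickness_mm ~ species + position, data = culm, median)
  cnt <- aggregate(thickness_mm ~ species + position, data = culm, length)
  out <- merge(agg, cnt, by = c("species", "position"),
               suffixes = c("", "_n"))
  names(out)[3:4] <- c("median_mm", "n")
  out[order(out$species, out$position), ]
}
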