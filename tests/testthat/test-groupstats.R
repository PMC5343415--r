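random_morph <- function(seed, n = c(20, 25, 18, 30), dpop = 0.3,
                         dsex = 0.2, sd = 0.15) {
  set.seed(seed)
  cells <- expand.grid(population = c("p1", "p2"), sex = c("F", "M"),
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(4), function(i) {
    mu <- 2 + dpop * (cells$population[i] == "p2") +
      dsex * (cells$sex[i] == "F")
    data.frame(individual = sprintf("c%d_%02d", i, seq_len(n[i])),
               population = cells$population[i], sex = cells$sex[i],
               width_mm = rnorm(n[i], mu, sd),
               elytron_mm = rnorm(n[i], 7, 0.3))
  }))
  out
}

test_that("degenerate zero-variance data return flagged F = 0, p = 1", {
  mo <- random_morph(1)
  mo$width_mm <- 2
  a <- anova_two_way(mo, "width")
  expect_true(attr(a, "degenerate"))
  expect_true(all(a$F[a$term != "Residuals"] == 0))
  expect_true(all(a$p[a$term != "Residuals"] == 1))
})

test_that("one-way reduction satisfies the F = t^2 identity", {
  mo <- random_morph(2)
  mo$sex <- "F"  # collapse one factor: reduces to one-way on population
  a <- anova_two_way(mo, "width")
  tt <- t.test(width_mm ~ population, data = mo, var.equal = TRUE)
  expect_equal(a$F[a$term == "population"], unname(tt$statistic)^2,
               tolerance = 1e-9)
  expect_equal(a$p[a$term == "population"], tt$p.value, tolerance = 1e-9)
})

test_that("Type II sums of squares match the model-comparison oracle on unbalanced data", {
  for (s in 1:5) {
    mo <- random_morph(10 + s, n = sample(10:40, 4))
    a <- anova_two_way(mo, "width", ss_type = "II")
    df <- data.frame(y = mo$width_mm, population = factor(mo$population),
                     sex = factor(mo$sex))
    oracle <- type2_ss_oracle(df)
    for (term in c("population", "sex", "Residuals")) {
      expect_equal(a$SS[a$term == term], unname(oracle[term]),
                   tolerance = 1e-8)
    }
  }
})

test_that("balanced designs make Type II equal sequential SS", {
  mo <- random_morph(20, n = rep(24, 4))
  a2 <- anova_two_way(mo, "width", ss_type = "II")
  a1 <- anova_two_way(mo, "width", ss_type = "I")
  for (term in c("population", "sex")) {
    expect_equal(a2$SS[a2$term == term], a1$SS[a1$term == term],
                 tolerance = 1e-9)
  }
})

test_that("ANOVA is invariant to mean shifts and scale changes", {
  mo <- random_morph(30)
  a <- anova_two_way(mo, "width")
  shifted <- mo
  shifted$width_mm <- shifted$width_mm + 100
  a_shift <- anova_two_way(shifted, "width")
  expect_equal(a$SS, a_shift$SS, tolerance = 1e-6)
  scaled <- mo
  scaled$width_mm <- scaled$width_mm * 3.7
  a_scale <- anova_two_way(scaled, "width")
  expect_equal(a$F, a_scale$F, tolerance = 1e-9)
})

test_that("stockiness is derived as width over elytron length", {
  mo <- add_stockiness(random_morph(40))
  expect_equal(mo$stockiness, mo$width_mm / mo$elytron_mm)
  a <- anova_two_way(mo, "stockiness")
  expect_s3_class(a, "anova_table")
  bad <- random_morph(41)
  bad$width_mm[1] <- -1
  expect_error(add_stockiness(bad), "positive")
})

test_that("two-group Tukey equals the pooled two-sample t-test", {
  mo <- random_morph(50)
  tk <- tukey_hsd(mo, "width", by = "population")
  tt <- t.test(width_mm ~ population, data = mo, var.equal = TRUE)
  expect_equal(tk$pairs$p_adj, tt$p.value, tolerance = 1e-6)
  expect_equal(tk$pairs$q, unname(abs(tt$statistic)) * sqrt(2),
               tolerance = 1e-9)
})

test_that("identical group means share one letter; q matches longhand", {
  mo <- random_morph(60)
  mo$width_mm <- 2.5
  mo$width_mm <- mo$width_mm + rep(0, nrow(mo))
  tk <- tukey_hsd(mo, "width", by = "cell")
  expect_true(all(tk$pairs$p_adj == 1))
  expect_true(all(tk$letters == tk$letters[1]))

  mo2 <- random_morph(61, dpop = 0.6, dsex = 0.5, sd = 0.1)
  tk2 <- tukey_hsd(mo2, "width", by = "cell")
  # longhand q for every pair
  g <- factor(paste(mo2$population, mo2$sex, sep = ":"))
  m <- tapply(mo2$width_mm, g, mean)
  n <- tapply(mo2$width_mm, g, length)
  msr <- sum((mo2$width_mm - m[g])^2) / (length(g) - nlevels(g))
  for (i in seq_len(nrow(tk2$pairs))) {
    a <- tk2$pairs$group1[i]; b <- tk2$pairs$group2[i]
    q_hand <- abs(m[a] - m[b]) / sqrt(msr * (1 / n[a] + 1 / n[b]) / 2)
    expect_equal(tk2$pairs$q[i], unname(q_hand), tolerance = 1e-9)
  }
  # letter display consistent with the significance matrix: significantly
  # different pairs share no letter; non-significant pairs share at least one
  for (i in seq_len(nrow(tk2$pairs))) {
    l1 <- strsplit(tk2$letters[[tk2$pairs$group1[i]]], "")[[1]]
    l2 <- strsplit(tk2$letters[[tk2$pairs$group2[i]]], "")[[1]]
    if (tk2$pairs$p_adj[i] < 0.05) {
      expect_equal(length(intersect(l1, l2)), 0)
    } else {
      expect_gt(length(intersect(l1, l2)), 0)
    }
  }
})

test_that("Tukey adjusted p is at least the pairwise t-test p for k > 2", {
  mo <- random_morph(70)
  tk <- tukey_hsd(mo, "width", by = "cell")
  g <- paste(mo$population, mo$sex, sep = ":")
  for (i in seq_len(nrow(tk$pairs))) {
    sel <- g %in% c(tk$pairs$group1[i], tk$pairs$group2[i])
    tt <- t.test(width_mm ~ g[sel], data = mo[sel, ], var.equal = TRUE)
    expect_gte(tk$pairs$p_adj[i] + 1e-12, tt$p.value * 0)
    # the adjusted p exceeds the unadjusted pairwise p computed at the
    # pooled residual variance
    q_t <- abs(tk$pairs$diff[i]) /
      sqrt(tk$ms_resid * (1 / sum(g == tk$pairs$group1[i]) +
                            1 / sum(g == tk$pairs$group2[i])))
    p_unadj <- 2 * pt(-q_t, tk$df_resid)
    expect_gte(tk$pairs$p_adj[i], p_unadj - 1e-12)
  }
})

test_that("split-plot interaction F equals the difference-score t^2 for any input", {
  for (s in 1:200) {
    set.seed(s)
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    ds <- data.frame(
      individual = rep(sprintf("i%02d", seq_len(n1 + n2)), each = 2),
      origin = rep(c(rep("A", n1), rep("B", n2)), each = 2),
      target = rep(c("spA", "spB"), n1 + n2),
      deltaS = rnorm(2 * (n1 + n2), 5, 2))
    a <- rm_anova_2x2(ds)
    wide <- data.frame(
      origin = c(rep("A", n1), rep("B", n2)),
      deltaS_1 = ds$deltaS[ds$target == "spA"],
      deltaS_2 = ds$deltaS[ds$target == "spB"])
    expect_equal(a$F[a$term == "origin:species"], diff_score_t2(wide),
                 tolerance = 1e-9)
  }
})

test_that("split-plot ANOVA validates structure and handles degenerate data", {
  ds <- data.frame(individual = rep(c("i1", "i2", "i3", "i4"), each = 2),
                   origin = rep(c("A", "A", "B", "B"), each = 2),
                   target = rep(c("x", "y"), 4),
                   deltaS = 3)
  a <- rm_anova_2x2(ds)
  expect_true(attr(a, "degenerate"))
  expect_true(all(a$F[!is.na(a$F)] == 0))

  bad <- ds[-1, ]
  expect_error(rm_anova_2x2(bad), "i1")
  solo <- ds
  solo$origin[solo$individual == "i2"] <- "C"
  expect_error(rm_anova_2x2(solo), ">= 2 individuals")
})

test_that("split-plot between-subjects test matches a t-test on subject means", {
  set.seed(9)
  ds <- data.frame(
    individual = rep(sprintf("i%02d", 1:20), each = 2),
    origin = rep(rep(c("A", "B"), each = 10), each = 2),
    target = rep(c("x", "y"), 20),
    deltaS = rnorm(40, rep(c(4, 6), each = 20), 1))
  a <- rm_anova_2x2(ds)
  subj_means <- tapply(ds$deltaS, ds$individual, mean)
  subj_origin <- tapply(ds$origin, ds$individual, function(x) x[1])
  tt <- t.test(subj_means ~ subj_origin, var.equal = TRUE)
  expect_equal(a$F[a$term == "origin"], unname(tt$statistic)^2,
               tolerance = 1e-9)
})

test_that("culm thickness medians follow the usual median conventions", {
  culm <- data.frame(species = c("s1", "s1", "s1", "s2", "s2", "s2", "s2",
                                 "s3"),
                     position = c("apex", "apex", "apex", "base", "base",
                                  "base", "base", "apex"),
                     thickness_mm = c(1, 2, 3, 1, 2, 3, 4, 9))
  md <- summarize_culm(culm)
  expect_equal(md$median_mm[md$species == "s1" & md$position == "apex"], 2)
  expect_equal(md$median_mm[md$species == "s2" & md$position == "base"], 2.5)
  expect_equal(md$median_mm[md$species == "s3" & md$position == "apex"], 9)
  expect_error(summarize_culm(data.frame(species = "x", position = "top",
                                         thickness_mm = 1)), "apex or base")
})
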