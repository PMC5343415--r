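# independent oracles used by the tests; deliberately coded by different
# routes than the package implementation

# O(n^3)-flavoured convex hull: an input point is a hull vertex iff some
# directed edge through it has every other point strictly on one side
brute_force_hull <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dx <- pts[j, 1] - pts[i, 1]
      dy <- pts[j, 2] - pts[i, 2]
      s <- dx * (pts[, 2] - pts[i, 2]) - dy * (pts[, 1] - pts[i, 1])
      s <- s[-c(i, j)]
      if (all(s <= 1e-12) || all(s >= -1e-12)) {
        on_hull[i] <- TRUE
        break
      }
    }
  }
  v <- pts[on_hull, , drop = FALSE]
  # order counter-clockwise around the centroid
  ctr <- colMeans(v)
  v[order(atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])), , drop = FALSE]
}

# Monte-Carlo rejection estimate of a convex polygon's area
mc_polygon_area <- function(poly, n_draws = 1e6, seed = 1) {
  v <- poly$vertices
  bb <- c(min(v[, 1]), max(v[, 1]), min(v[, 2]), max(v[, 2]))
  set.seed(seed)
  pts <- cbind(runif(n_draws, bb[1], bb[2]), runif(n_draws, bb[3], bb[4]))
  mean(points_in_polygon(poly, pts)) * (bb[2] - bb[1]) * (bb[4] - bb[3])
}

# plain-loop percentile bootstrap of the mean (second implementation)
loop_bootstrap_upper <- function(values, n_boot, conf, seed) {
  set.seed(seed)
  means <- numeric(n_boot)
  n <- length(values)
  for (b in seq_len(n_boot)) {
    means[b] <- mean(values[sample.int(n, n, replace = TRUE)])
  }
  as.numeric(quantile(means, conf, type = 7))
}

# longhand tetrachromat receptor-noise distance, written out term by term
longhand_tetra_dS <- function(f1, f2, e) {
  df <- f1 - f2
  num <- (e[3] * e[4])^2 * (df[1] - df[2])^2 +
         (e[2] * e[4])^2 * (df[1] - df[3])^2 +
         (e[2] * e[3])^2 * (df[1] - df[4])^2 +
         (e[1] * e[4])^2 * (df[2] - df[3])^2 +
         (e[1] * e[3])^2 * (df[2] - df[4])^2 +
         (e[1] * e[2])^2 * (df[3] - df[4])^2
  den <- (e[1] * e[2] * e[3])^2 + (e[1] * e[2] * e[4])^2 +
         (e[1] * e[3] * e[4])^2 + (e[2] * e[3] * e[4])^2
  sqrt(num / den)
}

# logit-normal quantities by adaptive quadrature (stats::integrate), not
# Gauss-Hermite
integrate_marginal_p <- function(b0, sigma) {
  integrate(function(z) plogis(b0 + sigma * z) * dnorm(z),
            -Inf, Inf, rel.tol = 1e-10)$value
}
integrate_icc <- function(b0, sigma) {
  p <- integrate_marginal_p(b0, sigma)
  ep2 <- integrate(function(z) plogis(b0 + sigma * z)^2 * dnorm(z),
                   -Inf, Inf, rel.tol = 1e-10)$value
  (ep2 - p^2) / (p * (1 - p))
}

# Type II sums of squares by explicit model comparison (full vs reduced RSS)
type2_ss_oracle <- function(df) {
  rss <- function(fml) sum(stats::resid(stats::lm(fml, data = df))^2)
  c(population = rss(y ~ sex) - rss(y ~ population + sex),
    sex = rss(y ~ population) - rss(y ~ population + sex),
    Residuals = rss(y ~ population + sex))
}

# pooled two-sample t on within-subject difference scores: the exact oracle
# for the 2x2 split-plot interaction
diff_score_t2 <- function(wide) {
  d <- wide$deltaS_2 - wide$deltaS_1
  tt <- t.test(d ~ wide$origin, var.equal = TRUE)
  unname(tt$statistic^2)
}

# small two-population choice config used across tests
make_choice_config <- function(seed, p1 = 0.5, p2 = 0.5, sigma = 1,
                               n_per_cell = 20L,
                               times = c(12, 15, 18, 21, 24)) {
  pops <- c("popA", "popB")
  p <- matrix(c(p1, p2, p1, p2), 2, 2, dimnames = list(pops, c("F", "M")))
  sim_config(seed = seed,
             choice = list(populations = pops, p = p, sigma_indiv = sigma,
                           times = times, n_per_cell = n_per_cell))
}

unit_square_polygon <- function(side = 1) {
  convex_polygon(rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)))
}
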