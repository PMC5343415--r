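# seeded random spectra on the working grid: smooth positive reflectances
random_spectra <- function(n, grid = 300:700, seed = 1) {
  set.seed(seed)
  sapply(seq_len(n), function(i) {
    mid <- runif(1, 400, 600)
    lo <- runif(1, 0.05, 0.3)
    hi <- runif(1, 0.3, 0.9)
    lo + (hi - lo) * plogis(runif(1, 0.01, 0.05) * (grid - mid))
  })
}

test_that("spectrum resampling is linear interpolation with no extrapolation", {
  wl <- seq(300, 700, 10)
  set1 <- spectrum_set(wl, cbind(seq_along(wl), rep(0.4, length(wl))),
                       data.frame(species = "s", individual = c("a", "b")))
  # identity on the original grid
  same <- resample_spectra(set1, wl)
  expect_equal(same$refl, set1$refl)
  # constant stays constant, ramp hits exact midpoints
  mid <- wl[-length(wl)] + 5
  rs <- resample_spectra(set1, mid)
  expect_equal(rs$refl[, 2], rep(0.4, length(mid)))
  expect_equal(rs$refl[, 1], seq_along(wl)[-length(wl)] + 0.5)
  expect_error(resample_spectra(set1, seq(200, 700, 10)), "span")
})

test_that("replicate averaging is a pointwise mean per individual", {
  wl <- 300:310
  refl <- cbind(rep(0.2, 11), rep(0.4, 11), rep(0.5, 11))
  meta <- data.frame(species = "p", individual = c("i1", "i1", "i2"),
                     replicate = c("r1", "r2", "r1"))
  avg <- average_replicates(spectrum_set(wl, refl, meta))
  expect_equal(ncol(avg$refl), 2)
  expect_equal(avg$refl[, 1], rep(0.3, 11))
  expect_equal(avg$refl[, 2], rep(0.5, 11))
  expect_true(all(is.na(avg$meta$replicate)))
})

test_that("quantum catches reduce to sensitivity integrals and refine with the grid", {
  grid <- 300:700
  flat_illum <- list(wl = c(300, 700), power = c(1, 1))
  vs <- visual_system(illuminant = flat_illum, grid = grid)
  # zero reflectance gives zero catch
  expect_equal(as.numeric(quantum_catch(rep(0, length(grid)), vs)),
               rep(0, 4))
  # unit reflectance under a flat illuminant: catch = integral of S
  Q <- quantum_catch(rep(1, length(grid)), vs)
  w <- diff(range(grid)) / (length(grid) - 1)
  for (i in 1:4) {
    s <- vs$S[, i]
    trap <- sum((s[-1] + s[-length(s)]) / 2) * w
    expect_equal(Q[1, i], trap, tolerance = 1e-12)
  }
  # 1 nm quadrature agrees with a 0.01 nm reference quadrature
  fine <- seq(300, 700, 0.01)
  sens_fine <- exp(-((fine - 500)^2) / (2 * 40^2))
  ref <- sum((sens_fine[-1] + sens_fine[-length(fine)]) / 2) * 0.01
  vs1 <- visual_system(lambda_max = c(500, 600), densities = c(1, 1),
                       illuminant = flat_illum, grid = grid)
  Q1 <- quantum_catch(rep(1, length(grid)), vs1)[1, 1]
  expect_lt(abs(Q1 - ref) / ref, 1e-6)
})

test_that("von Kries adaptation normalizes to the background and cancels intensity", {
  grid <- 300:700
  vs <- visual_system(grid = grid)
  # ideal background, unit reflectance: q = 1
  q <- von_kries(quantum_catch(rep(1, length(grid)), vs), vs)
  expect_equal(as.numeric(q), rep(1, 4), tolerance = 1e-12)
  # stimulus equal to a reflective background: q = 1
  bg <- 0.3 + 0.2 * plogis(0.03 * (grid - 500))
  vs_bg <- visual_system(grid = grid, background = bg)
  qbg <- von_kries(quantum_catch(bg, vs_bg), vs_bg)
  expect_equal(as.numeric(qbg), rep(1, 4), tolerance = 1e-12)
  # halving the illuminant leaves q unchanged
  vs_half <- vs
  vs_half$illuminant <- vs$illuminant / 2
  r <- random_spectra(1, grid, seed = 3)
  expect_equal(as.numeric(von_kries(quantum_catch(r, vs_half), vs_half)),
               as.numeric(von_kries(quantum_catch(r, vs), vs)),
               tolerance = 1e-12)
})

test_that("receptor noise follows the square-root density law", {
  vs_eq <- visual_system(densities = c(1, 1, 1, 1), weber = 0.07)
  expect_equal(receptor_noise(vs_eq), rep(0.07, 4))
  vs <- visual_system(densities = c(1, 2, 2, 4), weber = 0.1)
  expect_equal(receptor_noise(vs),
               c(0.2, 0.1 * sqrt(2), 0.1 * sqrt(2), 0.1))
  vs2 <- visual_system(lambda_max = c(450, 550), densities = c(4, 1),
                       weber = 0.1, reference = 2)
  expect_equal(receptor_noise(vs2), c(0.05, 0.1))
})

test_that("JND distance is a pseudometric and invariant to illuminant scaling", {
  grid <- 300:700
  vs <- visual_system(grid = grid)
  spectra <- random_spectra(100, grid, seed = 10)
  set.seed(11)
  for (k in 1:100) {
    a <- spectra[, k]
    b <- spectra[, sample(100, 1)]
    expect_equal(delta_S(a, a, vs), 0, tolerance = 1e-12)
    expect_equal(delta_S(a, b, vs), delta_S(b, a, vs), tolerance = 1e-12)
    expect_gte(delta_S(a, b, vs), 0)
  }
  # scaling the illuminant by k > 0 changes nothing (von Kries cancels it)
  a <- spectra[, 1]; b <- spectra[, 2]
  base <- delta_S(a, b, vs)
  for (k in c(1e-3, 7, 1e4)) {
    vsk <- vs
    vsk$illuminant <- vs$illuminant * k
    expect_equal(delta_S(a, b, vsk), base, tolerance = 1e-9)
  }
})

test_that("dichromat closed form agrees with the general quadratic form", {
  grid <- 300:700
  vs2 <- visual_system(lambda_max = c(450, 560), densities = c(1, 3),
                       weber = 0.08, grid = grid)
  e <- receptor_noise(vs2)
  spectra <- random_spectra(40, grid, seed = 21)
  for (k in seq(1, 39, 2)) {
    a <- spectra[, k]; b <- spectra[, k + 1]
    q <- von_kries(quantum_catch(cbind(a, b), vs2), vs2)
    df <- log(q[1, ]) - log(q[2, ])
    closed <- abs(df[1] - df[2]) / sqrt(e[1]^2 + e[2]^2)
    expect_equal(delta_S(a, b, vs2), closed, tolerance = 1e-9)
  }
})

test_that("tetrachromat distance matches the longhand expansion", {
  grid <- 300:700
  vs <- visual_system(densities = c(1, 2, 3, 5), weber = 0.12, grid = grid)
  e <- receptor_noise(vs)
  spectra <- random_spectra(100, grid, seed = 33)
  for (k in 1:50) {
    a <- spectra[, k]; b <- spectra[, 101 - k]
    q <- von_kries(quantum_catch(cbind(a, b), vs), vs)
    oracle <- longhand_tetra_dS(log(q[1, ]), log(q[2, ]), e)
    expect_equal(delta_S(a, b, vs), oracle, tolerance = 1e-9)
  }
})

test_that("tetrachromat distance approaches the dichromat limit as e3, e4 grow", {
  f1 <- c(0.21, -0.05, 0.13, 0.02)
  f2 <- c(0.02, 0.11, -0.04, 0.4)
  e12 <- c(0.1, 0.15)
  dichromat <- abs((f1[1] - f2[1]) - (f1[2] - f2[2])) / sqrt(sum(e12^2))
  rnl <- mosaicadapt:::rnl_distance
  for (big in c(1e3, 1e6)) {
    d4 <- rnl(f1 - f2, c(e12, big, big))
    expect_equal(d4, dichromat, tolerance = 10 / big)
  }
})

test_that("minimum cluster distance equals the exhaustive pairwise minimum", {
  grid <- 300:700
  vs <- visual_system(grid = grid)
  cluster_refl <- random_spectra(15, grid, seed = 44)
  cluster <- spectrum_set(grid, cluster_refl,
                          data.frame(species = "p",
                                     individual = sprintf("s%02d", 1:15)))
  insect <- random_spectra(1, grid, seed = 45)[, 1]
  exhaustive <- min(vapply(1:15, function(j) {
    delta_S(insect, cluster_refl[, j], vs)
  }, numeric(1)))
  expect_equal(min_delta_S(insect, cluster, vs), exhaustive,
               tolerance = 1e-12)
  # own spectrum in the cluster: minimum 0; singleton: pairwise distance
  own <- spectrum_set(grid, cbind(cluster_refl, insect),
                      data.frame(species = "p",
                                 individual = sprintf("s%02d", 1:16)))
  expect_equal(min_delta_S(insect, own, vs), 0)
  singleton <- subset_spectra(cluster, 1)
  expect_equal(min_delta_S(insect, singleton, vs),
               delta_S(insect, cluster_refl[, 1], vs))
  expect_error(min_delta_S(insect, subset_spectra(cluster, integer(0)), vs),
               "empty")
})

test_that("match tables have host/alternative rows and reflect generated matching", {
  grid <- seq(300, 700, 2)
  vs <- visual_system(grid = grid)
  # generator-controlled ordering: insects sit on their own host's colour
  groups <- rbind(
    data.frame(species = c("hostA", "hostB"), role = "sheath", n = 8L,
               offset = c(0.12, -0.12)),
    data.frame(species = c("hostA", "hostB"), role = "insect", n = 10L,
               offset = c(0.12, -0.12)))
  cfg <- sim_config(seed = 15, spectra = list(
    wl = grid,
    base = list(low = 0.15, high = 0.5, mid = 550, rate = 0.02,
                bump_center = NULL, bump_height = 0, bump_sd = 20),
    groups = groups, noise_sd = 0.02, replicates = 2L))
  sp <- gen_spectra(cfg)
  sheath <- !is.na(sp$meta$replicate)
  clusters <- lapply(split(seq_len(sum(sheath)),
                           sp$meta$species[sheath]), function(ix) {
    subset_spectra(subset_spectra(sp, sheath), ix)
  })
  clusters <- lapply(clusters, average_replicates)
  insects <- subset_spectra(sp, !sheath)
  mt <- match_table(insects, clusters, list(c("hostA", "hostB")), vs)
  expect_equal(nrow(mt), 2 * n_spectra(insects))
  expect_setequal(unique(mt$role), c("host", "alternative"))
  # every insect has exactly one host row and one alternative row
  expect_true(all(table(mt$individual, mt$role) == 1))
  for (orig in c("hostA", "hostB")) {
    sub <- mt[mt$origin == orig, ]
    expect_lt(mean(sub$deltaS[sub$role == "host"]),
              mean(sub$deltaS[sub$role == "alternative"]))
  }
  expect_error(match_table(insects, clusters["hostA"],
                           list(c("hostA", "hostB")), vs), "hostB")
})
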