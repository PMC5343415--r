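# marginal binomial regression for repeated binary host choices
#
# Generalized estimating equations with an exchangeable working correlation:
# each individual is observed at several time points and its repeated
# choices share one within-individual correlation alpha. Inference uses the
# robust (sandwich) covariance, so conclusions do not depend on the working
# correlation being right.

#' Fit a binomial GEE to repeated host-choice trials
#'
#' Fits the marginal model `choice ~ population + sex + time_h` (terms
#' configurable) by iteratively reweighted Fisher scoring on the
#' generalized estimating equations. The working covariance for individual
#' i is `V_i = phi * A_i^(1/2) R(alpha) A_i^(1/2)` with `A_i` the binomial
#' variance and `R` exchangeable (or identity); `alpha` is the moment
#' estimator over within-individual Pearson-residual pairs and `phi` the
#' mean squared Pearson residual. The reported covariance is the robust
#' sandwich `B^-1 M B^-1`.
#'
#' @param trials data frame with columns `individual`, `population`, `sex`,
#'   `time_h`, `choice` (0/1, 1 = reference host chosen).
#' @param terms character vector of regressors among `population`, `sex`,
#'   `time_h`; time enters as a linear covariate in hours.
#' @param link `"logit"` (default) or `"log"`.
#' @param corstr `"exchangeable"` (default) or `"independence"`.
#' @param tol convergence tolerance on `max |delta beta|`.
#' @param max_iter maximum Fisher-scoring iterations.
#' @return object of class `gee_fit` with elements `coefficients`,
#'   `robust_cov`, `naive_cov`, `alpha`, `phi`, `link`, `corstr`,
#'   `converged`, `iterations`, plus design bookkeeping used by
#'   [marginal_means()] and [wald_term_test()].
#' @export
fit_gee <- function(trials, terms = c("population", "sex", "time_h"),
                    link = c("logit", "log"),
                    corstr = c("exchangeable", "independence"),
                    tol = 1e-8, max_iter = 100) {
  link <- match.arg(link)
  corstr <- match.arg(corstr)
  need <- c("individual", "choice", terms)
  if (!all(need %in% names(trials))) {
    stop("trials is missing required columns", call. = FALSE)
  }
  trials <- trials[complete.cases(trials[, need]), , drop = FALSE]
  if ("population" %in% terms && length(unique(trials$population)) < 2L) {
    stop("need >= 2 populations", call. = FALSE)
  }
  y <- as.numeric(trials$choice)
  if (!all(y %in% c(0, 1))) stop("choice must be binary 0/1", call. = FALSE)

  fml <- stats::as.formula(paste("choice ~", paste(terms, collapse = " + ")))
  df <- trials
  for (tt in intersect(terms, c("population", "sex"))) df[[tt]] <- factor(df[[tt]])
  mf <- stats::model.frame(fml, df)
  X <- stats::model.matrix(fml, mf)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("singular design", call. = FALSE)
  id <- factor(trials$individual, levels = unique(trials$individual))
  idx_list <- split(seq_along(y), id)
  N <- length(y)

  linkinv <- if (link == "logit") plogis else function(eta) pmin(exp(eta), 1 - 1e-10)
  mu_eta <- if (link == "logit") function(mu) mu * (1 - mu) else function(mu) mu

  # initialize from the independence (GLM) fit
  beta <- tryCatch({
    fam <- binomial(link = link)
    suppressWarnings(glm.fit(X, y, family = fam)$coefficients)
  }, error = function(e) {
    b <- numeric(p)
    b[1] <- if (link == "logit") qlogis(mean(pmin(pmax(y, 0.01), 0.99)))
            else log(max(mean(y), 0.01))
    b
  })
  if (any(!is.finite(beta))) beta[!is.finite(beta)] <- 0

  alpha <- 0
  phi <- 1
  converged <- FALSE
  iter <- 0
  eps <- 1e-10
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- linkinv(eta)
    mu <- pmin(pmax(mu, eps), 1 - eps)
    a <- mu * (1 - mu)            # binomial variance
    d <- mu_eta(mu)               # d mu / d eta
    r <- (y - mu) / sqrt(a)       # Pearson residuals

    phi <- sum(r^2) / (N - p)
    if (corstr == "exchangeable") {
      s_cross <- 0
      n_pairs <- 0
      for (ix in idx_list) {
        ni <- length(ix)
        if (ni > 1L) {
          ri <- r[ix]
          s_cross <- s_cross + (sum(ri)^2 - sum(ri^2)) / 2
          n_pairs <- n_pairs + ni * (ni - 1) / 2
        }
      }
      alpha <- if (n_pairs > p) s_cross / (phi * (n_pairs - p)) else 0
      nmax <- max(lengths(idx_list))
      alpha <- min(max(alpha, -1 / max(nmax - 1, 1) + 1e-6), 1 - 1e-6)
    }

    # scoring update; exchangeable R^-1 in closed form:
    # R^-1 = (I - alpha/(1+(ni-1)alpha) J) / (1-alpha)
    B <- matrix(0, p, p)
    U <- numeric(p)
    for (ix in idx_list) {
      ni <- length(ix)
      Di <- X[ix, , drop = FALSE] * d[ix]
      si <- sqrt(a[ix])
      resid <- y[ix] - mu[ix]
      if (corstr == "independence" || ni == 1L || alpha == 0) {
        W <- Di / (phi * a[ix])
        B <- B + crossprod(W, Di)
        U <- U + drop(crossprod(W, resid))
      } else {
        Z <- Di / si                 # A^(-1/2) D
        u <- resid / si              # A^(-1/2) (y - mu)
        c1 <- 1 / (1 - alpha)
        c2 <- alpha / ((1 - alpha) * (1 + (ni - 1) * alpha))
        RinvZ <- c1 * Z - c2 * matrix(colSums(Z), ni, p, byrow = TRUE)
        B <- B + crossprod(Z, RinvZ) / phi
        U <- U + drop(crossprod(RinvZ, u)) / phi
      }
    }
    delta <- solve(B, U)
    beta <- beta + delta
    if (max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("GEE did not converge within max_iter; estimates returned")
  }

  # final quantities at the converged beta
  eta <- drop(X %*% beta)
  mu <- pmin(pmax(linkinv(eta), eps), 1 - eps)
  a <- mu * (1 - mu)
  d <- mu_eta(mu)
  B <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (ix in idx_list) {
    ni <- length(ix)
    Di <- X[ix, , drop = FALSE] * d[ix]
    si <- sqrt(a[ix])
    resid <- y[ix] - mu[ix]
    if (corstr == "independence" || ni == 1L || alpha == 0) {
      WD <- Di / (phi * a[ix])
      B <- B + crossprod(WD, Di)
      g <- drop(crossprod(WD, resid))
    } else {
      Z <- Di / si
      u <- resid / si
      c1 <- 1 / (1 - alpha)
      c2 <- alpha / ((1 - alpha) * (1 + (ni - 1) * alpha))
      RinvZ <- c1 * Z - c2 * matrix(colSums(Z), ni, p, byrow = TRUE)
      B <- B + crossprod(Z, RinvZ) / phi
      g <- drop(crossprod(RinvZ, u)) / phi
    }
    M <- M + tcrossprod(g)
  }
  Binv <- solve(B)
  robust <- Binv %*% M %*% Binv
  robust <- (robust + t(robust)) / 2

  structure(list(
    coefficients = setNames(drop(beta), colnames(X)),
    robust_cov = robust, naive_cov = Binv,
    alpha = if (corstr == "exchangeable") alpha else 0, phi = phi,
    link = link, corstr = corstr, converged = converged, iterations = iter,
    formula = fml, terms = terms, assign = attr(X, "assign"),
    term_labels = attr(stats::terms(fml), "term.labels"),
    xlevels = stats::.getXlevels(stats::terms(fml), mf),
    n_obs = N, n_clusters = length(idx_list),
    time_values = if ("time_h" %in% terms) sort(unique(trials$time_h)) else NULL
  ), class = "gee_fit")
}

#' @export
coef.gee_fit <- function(object, ...) object$coefficients

#' @export
vcov.gee_fit <- function(object, ...) object$robust_cov

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("Binomial GEE (%s link, %s working correlation)\n",
              x$link, x$corstr))
  cat(sprintf("%d observations in %d individuals; alpha = %.3f, phi = %.3f%s\n",
              x$n_obs, x$n_clusters, x$alpha, x$phi,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.gee_fit <- function(object, ...) {
  se <- sqrt(diag(object$robust_cov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Robust SE` = se,
               z = z, `Pr(>|z|)` = 2 * pnorm(-abs(z)))
  out <- list(fit = object, coefficients = tab)
  class(out) <- "summary.gee_fit"
  out
}

#' @export
print.summary.gee_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients (robust inference):\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  invisible(x)
}

#' Wald test of a model term
#'
#' Joint chi-squared test of all coefficients belonging to one term, using
#' the robust covariance: `W = (L b)' (L V L')^-1 (L b)` with `L` the
#' selector of the term's coefficients.
#'
#' @param fit a fitted model from [fit_gee()].
#' @param term term label, e.g. `"population"`.
#' @return list with `wald`, `df`, `p`.
#' @export
wald_term_test <- function(fit, term) {
  ti <- match(term, fit$term_labels)
  if (is.na(ti)) stop(sprintf("term '%s' not in fit", term), call. = FALSE)
  sel <- which(fit$assign == ti)
  if (length(sel) == 0L) stop("rank-deficient term selection", call. = FALSE)
  b <- fit$coefficients[sel]
  V <- fit$robust_cov[sel, sel, drop = FALSE]
  W <- drop(t(b) %*% solve(V, b))
  df <- length(sel)
  list(wald = W, df = df, p = pchisq(W, df, lower.tail = FALSE))
}

#' Back-transformed marginal means per population and sex
#'
#' For each population-by-sex cell the linear predictor is averaged over the
#' design's observation times, a 95% Wald interval is formed on the link
#' scale using the robust covariance, and estimate and bounds are
#' back-transformed to the 0-1 preference scale.
#'
#' @param fit a fitted model from [fit_gee()].
#' @param trials the trials data frame the fit was computed from (used for
#'   cell sample sizes).
#' @param conf confidence level.
#' @return data frame of class `marginal_means` with columns `population`,
#'   `sex`, `mean`, `lower`, `upper`, `n`, and a preference `call` column
#'   from [preference_call()].
#' @export
marginal_means <- function(fit, trials, conf = 0.95) {
  zq <- qnorm(1 - (1 - conf) / 2)
  pops <- fit$xlevels$population %||% unique(trials$population)
  sexes <- fit$xlevels$sex %||% unique(trials$sex)
  tbar <- if (!is.null(fit$time_values)) mean(fit$time_values) else 0
  linkinv <- if (fit$link == "logit") plogis else function(x) pmin(exp(x), 1)

  rows <- list()
  for (pop in pops) {
    for (sx in sexes) {
      nd <- data.frame(population = factor(pop, levels = fit$xlevels$population),
                       sex = factor(sx, levels = fit$xlevels$sex),
                       time_h = tbar)
      Xr <- stats::model.matrix(stats::delete.response(stats::terms(fit$formula)),
                                nd, xlev = fit$xlevels)
      eta <- drop(Xr %*% fit$coefficients)
      se <- sqrt(drop(Xr %*% fit$robust_cov %*% t(Xr)))
      n <- length(unique(trials$individual[trials$population == pop &
                                             trials$sex == sx]))
      rows[[length(rows) + 1L]] <- data.frame(
        population = pop, sex = sx,
        mean = linkinv(eta), lower = linkinv(eta - zq * se),
        upper = linkinv(eta + zq * se), n = n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$call <- vapply(seq_len(nrow(out)), function(i) {
    preference_call(out[i, ])
  }, "")
  class(out) <- c("marginal_means", class(out))
  out
}

#' Preference call from a back-transformed confidence interval
#'
#' A preference is inferred only when the 95% interval excludes 0.5: lower
#' bound above 0.5 means the reference host is preferred, upper bound below
#' 0.5 means the alternative is preferred, otherwise no preference.
#'
#' @param cell one row of a [marginal_means] table (needs `lower`, `upper`).
#' @return one of `"prefers reference"`, `"prefers alternative"`,
#'   `"no preference"`.
#' @export
preference_call <- function(cell) {
  if (cell$lower > 0.5) "prefers reference"
  else if (cell$upper < 0.5) "prefers alternative"
  else "no preference"
}

#' Hedges' d standardized mean difference
#'
#' Bias-corrected standardized mean difference
#' `d = J (m1 - m2) / s_pooled`, with
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2))` and the
#' small-sample correction `J = 1 - 3 / (4 (n1+n2-2) - 1)`; sampling
#' variance `var(d) = (n1+n2)/(n1 n2) + d^2 / (2 (n1+n2))`.
#'
#' @param mean1,mean2 group means.
#' @param sd1,sd2 group standard deviations (>= 0, not both 0).
#' @param n1,n2 group sizes (>= 2).
#' @return list with `d`, `var`, `n1`, `n2`.
#' @export
hedges_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("negative sd", call. = FALSE)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) stop("zero pooled sd", call. = FALSE)
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  d <- J * (mean1 - mean2) / sp
  list(d = d, var = (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)),
       n1 = n1, n2 = n2)
}

#' Hedges' d for the population effect from GEE cell means
#'
#' Collapses the marginal-means table to one preference probability per
#' population (individual-weighted average over sexes), plugs in the
#' binomial standard deviation `sqrt(p (1 - p))` at the cell mean, and
#' computes [hedges_d()] with the per-population individual counts.
#'
#' @param mm a [marginal_means] table with exactly two populations.
#' @return list with `d`, `var`, `populations`.
#' @export
population_effect_size <- function(mm) {
  pops <- unique(mm$population)
  if (length(pops) != 2L) stop("expected exactly two populations", call. = FALSE)
  stat <- lapply(pops, function(pp) {
    rows <- mm[mm$population == pp, ]
    p <- sum(rows$mean * rows$n) / sum(rows$n)
    list(p = p, sd = sqrt(p * (1 - p)), n = sum(rows$n))
  })
  es <- hedges_d(stat[[1]]$p, stat[[1]]$sd, stat[[1]]$n,
                 stat[[2]]$p, stat[[2]]$sd, stat[[2]]$n)
  list(d = es$d, var = es$var, populations = pops)
}
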