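#' Composition data for one cell type across samples
#'
#' @param gestational_week integer weeks, one per sample.
#' @param n_type count of the focal cell type in each sample.
#' @param n_total total QC-passing cells in each sample.
#' @return data.frame of class `composition_data`.
#' @export
composition_data <- function(gestational_week, n_type, n_total) {
  if (length(gestational_week) < 3) stop("need >= 3 samples")
  if (any(n_type < 0 | n_type > n_total)) stop("need 0 <= n_type <= n_total")
  df <- data.frame(gestational_week = as.numeric(gestational_week),
                   n_type = as.numeric(n_type), n_total = as.numeric(n_total))
  class(df) <- c("composition_data", class(df))
  df
}

# Standardized design matrix for a trend family. Centering/scaling constants
# can be supplied (so LOO refits can predict at a held-out week).
comp_design <- function(t, family, ref = NULL) {
  if (is.null(ref)) {
    u <- t - mean(t)
    ref <- list(center = mean(t),
                s1 = if (length(unique(t)) > 1) sd(u) else 1,
                m2 = mean(u^2),
                s2 = if (length(unique(t)) > 2) sd(u^2) else 1)
    if (ref$s1 == 0) ref$s1 <- 1
    if (ref$s2 == 0) ref$s2 <- 1
  }
  u <- t - ref$center
  X <- switch(family,
    constant = cbind(intercept = rep(1, length(t))),
    linear = cbind(intercept = 1, t1 = u / ref$s1),
    quadratic = cbind(intercept = 1, t1 = u / ref$s1,
                      t2 = (u^2 - ref$m2) / ref$s2),
    stop("unknown family: ", family))
  attr(X, "ref") <- ref
  X
}

# Newton optimization of the binomial-logit MAP with N(0, prior_sd^2)
# coefficient priors. Convex; convergence is certain up to tolerance.
comp_map <- function(X, y, n, prior_sd, max_iter = 100, tol = 1e-10) {
  p_dim <- ncol(X)
  beta <- rep(0, p_dim)
  lambda <- 1 / prior_sd^2
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- invlogit(eta)
    g <- drop(crossprod(X, y - n * p)) - lambda * beta
    W <- n * p * (1 - p)
    H <- crossprod(X, X * W) + diag(lambda, p_dim)
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  if (it == max_iter && max(abs(step)) >= 1e-6)
    stop("composition fit did not converge: max |step| = ", max(abs(step)))
  eta <- drop(X %*% beta)
  p <- invlogit(eta)
  H <- crossprod(X, X * (n * p * (1 - p))) + diag(lambda, p_dim)
  list(beta = beta, vcov = solve(H), iter = it)
}

#' Fit a logit-binomial composition trend
#'
#' Models per-sample counts of one cell type (out of the sample total) as
#' binomial with a logit-linear predictor that is constant, linear or
#' quadratic in gestational week. The covariate is centered and scaled to
#' unit SD before a zero-centered normal prior with standard deviation
#' `prior_sd` is applied to every coefficient; the fit is the posterior
#' mode (MAP) and uncertainty comes from the Laplace approximation around
#' it, propagated through the inverse logit for the 95% prediction band.
#'
#' @param data a [composition_data()] (or data.frame with its columns).
#' @param family `"constant"`, `"linear"` or `"quadratic"`.
#' @param prior_sd prior standard deviation (default 2.5).
#' @param gw_grid weeks at which to evaluate the fitted curve.
#' @return object of class `composition_fit` with elements `family`,
#'   `coefficients` (standardized scale), `coefficients_raw` (polynomial in
#'   centered week), `vcov`, `curve` (week, p, lower, upper), `loo_score`
#'   (filled by [select_model()]), `data`.
#' @export
fit_composition <- function(data, family = c("constant", "linear", "quadratic"),
                            prior_sd = 2.5, gw_grid = NULL) {
  family <- match.arg(family)
  data <- as.data.frame(data)
  if (nrow(data) < 3) stop("need >= 3 samples")
  if (any(data$n_type < 0 | data$n_type > data$n_total))
    stop("need 0 <= n_type <= n_total")
  t <- data$gestational_week
  if (family == "quadratic" && length(unique(t)) < 4)
    warning("quadratic trend with fewer than 4 distinct weeks")
  X <- comp_design(t, family)
  ref <- attr(X, "ref")
  fit <- comp_map(X, data$n_type, data$n_total, prior_sd)

  beta <- fit$beta
  raw <- switch(family,
    constant = c(beta[1]),
    linear = c(beta[1], beta[2] / ref$s1),
    quadratic = c(beta[1] - beta[3] * ref$m2 / ref$s2,
                  beta[2] / ref$s1, beta[3] / ref$s2))
  names(raw) <- c("b0", "b1", "b2")[seq_along(raw)]

  if (is.null(gw_grid)) gw_grid <- seq(min(t), max(t), length.out = 50)
  Xg <- comp_design(gw_grid, family, ref = ref)
  eta <- drop(Xg %*% beta)
  se <- sqrt(rowSums((Xg %*% fit$vcov) * Xg))
  curve <- data.frame(week = gw_grid, p = invlogit(eta),
                      lower = invlogit(eta - 1.96 * se),
                      upper = invlogit(eta + 1.96 * se))

  out <- list(family = family, coefficients = setNames(beta, colnames(X)),
              coefficients_raw = raw, vcov = fit$vcov, prior_sd = prior_sd,
              ref = ref, curve = curve, data = data, loo_score = NA_real_,
              n_iter = fit$iter)
  class(out) <- "composition_fit"
  out
}

#' @export
print.composition_fit <- function(x, ...) {
  cat("composition_fit (", x$family, " trend in gestational week)\n", sep = "")
  cat("  coefficients (centered-week scale):",
      paste(sprintf("%s=%.4f", names(x$coefficients_raw), x$coefficients_raw),
            collapse = ", "), "\n")
  if (!is.na(x$loo_score)) cat("  LOO score:", format(x$loo_score), "\n")
  invisible(x)
}

#' @export
summary.composition_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- data.frame(estimate = object$coefficients, se = se,
                    z = object$coefficients / se)
  cat("Binomial composition trend (", object$family,
      "), logit link, N(0, ", object$prior_sd, ") prior on standardized",
      " coefficients\n", sep = "")
  print(tab)
  invisible(tab)
}

#' @export
coef.composition_fit <- function(object, scale = c("raw", "standardized"), ...) {
  scale <- match.arg(scale)
  if (scale == "raw") object$coefficients_raw else object$coefficients
}

#' @export
predict.composition_fit <- function(object, newdata = NULL,
                                    type = c("response", "link"), ...) {
  type <- match.arg(type)
  weeks <- if (is.null(newdata)) object$data$gestational_week
           else if (is.data.frame(newdata)) newdata$gestational_week else newdata
  X <- comp_design(weeks, object$family, ref = object$ref)
  eta <- drop(X %*% object$coefficients)
  if (type == "response") invlogit(eta) else eta
}

#' @export
plot.composition_fit <- function(x, ...) {
  d <- x$data
  plot(d$gestational_week, d$n_type / d$n_total,
       xlab = "gestational week", ylab = "proportion",
       ylim = range(0, x$curve$upper, d$n_type / d$n_total), ...)
  graphics::lines(x$curve$week, x$curve$p)
  graphics::lines(x$curve$week, x$curve$lower, lty = 2)
  graphics::lines(x$curve$week, x$curve$upper, lty = 2)
  invisible(x)
}

#' @export
residuals.composition_fit <- function(object, ...) {
  d <- object$data
  p <- predict(object, d$gestational_week)
  (d$n_type - d$n_total * p) / sqrt(d$n_total * p * (1 - p))
}

#' @export
simulate.composition_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$data
  p <- predict(object, d$gestational_week)
  out <- replicate(nsim, rbinom(nrow(d), d$n_total, p))
  as.data.frame(out)
}

# Exact leave-one-out log predictive scores (pointwise): refit on each n-1
# subset and evaluate the held-out binomial log density at the subset MAP.
comp_loo <- function(data, family, prior_sd = 2.5) {
  n <- nrow(data)
  lpd <- numeric(n)
  for (i in seq_len(n)) {
    sub <- data[-i, , drop = FALSE]
    X <- comp_design(sub$gestational_week, family)
    ref <- attr(X, "ref")
    fit <- comp_map(X, sub$n_type, sub$n_total, prior_sd)
    Xi <- comp_design(data$gestational_week[i], family, ref = ref)
    p_i <- invlogit(drop(Xi %*% fit$beta))
    lpd[i] <- dbinom(data$n_type[i], data$n_total[i], p_i, log = TRUE)
  }
  lpd
}

#' Select the composition trend family by leave-one-out cross-validation
#'
#' Fits constant, linear and quadratic logit-binomial trends and scores
#' each by exact leave-one-out: every sample is held out in turn, the model
#' refit on the remainder, and the held-out binomial log predictive density
#' accumulated. Families are compared from simple to complex: a more
#' complex family is preferred only when its LOO advantage exceeds
#' `se_margin` standard errors of the pointwise LOO difference (the usual
#' reading of a LOO comparison table), so that near-ties resolve toward
#' the simpler trend. A family whose LOO refits fail is disqualified with
#' a warning.
#'
#' @param data a [composition_data()].
#' @param prior_sd prior standard deviation.
#' @param se_margin required LOO advantage in SE units of the pointwise
#'   difference (0 reduces to "highest sum wins").
#' @param gw_grid optional curve grid passed to [fit_composition()].
#' @return object of class `composition_select`: `best` (family name),
#'   `fit` (the selected [fit_composition()] object), `fits` (all three),
#'   `loo_scores`, `loo_pointwise`.
#' @export
select_model <- function(data, prior_sd = 2.5, se_margin = 1, gw_grid = NULL) {
  data <- as.data.frame(data)
  if (nrow(data) < 3) stop("need >= 3 samples")
  fams <- c("constant", "linear", "quadratic")
  fits <- list(); loo <- setNames(rep(NA_real_, 3), fams)
  pw <- list()
  for (f in fams) {
    fits[[f]] <- suppressWarnings(fit_composition(data, f, prior_sd, gw_grid))
    pw[[f]] <- tryCatch(comp_loo(data, f, prior_sd), error = function(e) {
      warning("LOO refit failed for family ", f, ": ", conditionMessage(e))
      NULL
    })
    loo[f] <- if (is.null(pw[[f]])) NA_real_ else sum(pw[[f]])
    fits[[f]]$loo_score <- loo[f]
  }
  if (all(is.na(loo))) stop("all families disqualified")
  best <- NULL
  for (f in fams) {
    if (is.na(loo[f])) next
    if (is.null(best)) { best <- f; next }
    d <- pw[[f]] - pw[[best]]
    se <- sd(d) * sqrt(length(d))
    if (sum(d) > se_margin * se) best <- f
  }
  out <- list(best = best, fit = fits[[best]], fits = fits, loo_scores = loo,
              loo_pointwise = pw, se_margin = se_margin)
  class(out) <- "composition_select"
  out
}

#' @export
print.composition_select <- function(x, ...) {
  cat("composition_select: best family =", x$best, "\n  LOO scores:",
      paste(sprintf("%s=%.3f", names(x$loo_scores), x$loo_scores),
            collapse = ", "), "\n")
  invisible(x)
}
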