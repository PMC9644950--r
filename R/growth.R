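#' Body-mass anchors for linear age interpolation
#'
#' During the near-linear phase of early growth, the age of an individual of
#' unknown age can be linearly interpolated from its body mass between two
#' individuals of known age (typically day 1 and day 42). Anchors must be
#' strictly increasing in both age and mass.
#'
#' @param ages anchor ages in days (strictly increasing).
#' @param masses body masses in g at those ages (strictly increasing).
#' @return An object of class `mass_age_anchors`.
#' @export
mass_age_anchors <- function(ages, masses) {
  if (length(ages) != length(masses) || length(ages) < 2)
    stop("need at least two (age, mass) anchor pairs")
  if (any(diff(ages) <= 0)) stop("anchor ages must be strictly increasing")
  if (any(diff(masses) <= 0))
    stop("anchor masses must be strictly increasing over the window")
  structure(list(ages = as.numeric(ages), masses = as.numeric(masses)),
            class = "mass_age_anchors")
}

#' Interpolate age from body mass
#'
#' Linear map from body mass to age between the bracketing anchors. Masses
#' outside the anchored window raise an error — no extrapolation, since the
#' linear-growth assumption only holds inside it.
#'
#' @param mass body mass in g (vectorised).
#' @param anchors a [mass_age_anchors()].
#' @return age in days.
#' @examples
#' a <- mass_age_anchors(c(1, 42), c(55, 2300))
#' interpolate_age(55, a)               # 1 day
#' interpolate_age((55 + 2300) / 2, a)  # 21.5 days
#' @export
interpolate_age <- function(mass, anchors) {
  stopifnot(inherits(anchors, "mass_age_anchors"))
  lo <- anchors$masses[1]
  hi <- anchors$masses[length(anchors$masses)]
  if (any(mass < lo) || any(mass > hi))
    stop("out of range: mass outside the anchored window; no extrapolation")
  stats::approx(anchors$masses, anchors$ages, xout = mass)$y
}

#' Age class labels
#'
#' Juvenile up to full size (42 days), sub-adult up to maturity (6 months),
#' adult beyond; pheasants are still growing at all sampled ages and are
#' always classed juvenile.
#'
#' @param age_days numeric age in days.
#' @param species `"duck"` or `"pheasant"`.
#' @return character vector of `"juvenile"`, `"sub-adult"`, `"adult"`.
#' @export
age_class <- function(age_days, species = "duck") {
  species <- match.arg(species, c("duck", "pheasant"))
  if (species == "pheasant") return(rep("juvenile", length(age_days)))
  ifelse(age_days <= 42, "juvenile",
         ifelse(age_days <= 182.5, "sub-adult", "adult"))
}

#' Fit a Gompertz growth curve
#'
#' Fits `y(t) = A * exp(-b * exp(-k * t))` by nonlinear least squares
#' (Levenberg–Marquardt) with multi-start initialisation: `A` starts at
#' 1.05 x max(y), `k` from a log-linearised regression of
#' `log(log(A0 / y))` on `t`, `b` from the first observation, plus jittered
#' restarts; the best converged fit by residual sum of squares is kept.
#' `A` is the asymptotic size, `b` a dimensionless shape parameter and `k`
#' the rate constant (1/day). The inflection (age of maximum growth rate)
#' is `t* = log(b) / k` with maximum rate `A * k / e`.
#'
#' @param ages sampling ages, days; at least 4 distinct values.
#' @param sizes measured sizes (mm); must be positive.
#' @param weights optional least-squares weights.
#' @param n_starts number of jittered restarts.
#' @return An object of class `gompertz_fit` with components `coefficients`
#'   (`A`, `b`, `k`), `vcov`, `t_infl`, `max_rate`, `fitted`, `residuals`,
#'   `data`, and the underlying `nls` object. Methods: `print`, `summary`,
#'   `coef`, `predict` (with delta-method confidence bands), `plot`,
#'   `residuals`.
#' @examples
#' t <- seq(0, 60, by = 4)
#' y <- 100 * exp(-4 * exp(-0.1 * t))
#' fit <- fit_gompertz(t, y)
#' coef(fit)
#' @export
fit_gompertz <- function(ages, sizes, weights = NULL, n_starts = 10) {
  ok <- complete.cases(ages, sizes)
  t <- as.numeric(ages[ok]); y <- as.numeric(sizes[ok])
  if (length(unique(t)) < 4)
    stop("invalid argument: need at least 4 distinct ages")
  if (any(y <= 0)) stop("invalid argument: sizes must be positive")
  w <- if (is.null(weights)) rep(1, length(y)) else weights[ok]

  if (sd(y) < 1e-10 * max(abs(y)))
    stop("fit failure: constant-size data, growth curve is degenerate")

  A0 <- 1.05 * max(y)
  # log-linearised init: log(log(A0/y)) = log(b) - k t
  zz <- log(pmax(log(A0 / y), 1e-8))
  ini_lm <- lm(zz ~ t)
  k0 <- max(1e-4, -coef(ini_lm)[[2]])
  b0 <- max(1e-3, -log(y[which.min(t)] / A0) * exp(k0 * min(t)))

  starts <- list(c(A = A0, b = b0, k = k0))
  with_private_seed(42L, {
    for (i in seq_len(n_starts - 1)) {
      starts[[i + 1]] <- c(A = A0 * exp(rnorm(1, 0, 0.1)),
                           b = b0 * exp(rnorm(1, 0, 0.35)),
                           k = k0 * exp(rnorm(1, 0, 0.35)))
    }
  })

  dat <- data.frame(t = t, y = y)
  best <- NULL; best_rss <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-b * exp(-k * t)), data = dat,
                        start = as.list(st), weights = w,
                        lower = c(1e-8, 1e-8, 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * residuals(fit)^2)
    if (rss < best_rss) { best_rss <- rss; best <- fit }
  }
  if (is.null(best))
    stop("fit failure: Gompertz fit did not converge from any start")

  cf <- coef(best)
  if (cf[["k"]] < 1e-6)
    warning("degenerate fit: rate constant k is approximately 0 (flat data)")
  vc <- tryCatch(vcov(best), error = function(e)
    matrix(NA_real_, 3, 3, dimnames = list(names(cf), names(cf))))
  structure(list(
    coefficients = cf, vcov = vc,
    t_infl = log(cf[["b"]]) / cf[["k"]],
    max_rate = cf[["A"]] * cf[["k"]] / exp(1),
    fitted = fitted(best), residuals = residuals(best),
    rss = best_rss, data = dat, nls = best
  ), class = "gompertz_fit")
}

#' @export
coef.gompertz_fit <- function(object, ...) object$coefficients

#' @export
vcov.gompertz_fit <- function(object, ...) object$vcov

#' @export
residuals.gompertz_fit <- function(object, ...) object$residuals

#' @export
print.gompertz_fit <- function(x, ...) {
  cf <- coef(x)
  cat("Gompertz growth curve  y(t) = A exp(-b exp(-k t))\n")
  cat(sprintf("  A = %.4g   b = %.4g   k = %.4g /day\n",
              cf[["A"]], cf[["b"]], cf[["k"]]))
  cat(sprintf("  inflection at %.2f days, maximum rate %.4g per day\n",
              x$t_infl, x$max_rate))
  invisible(x)
}

#' @export
summary.gompertz_fit <- function(object, ...) {
  cf <- coef(object)
  se <- sqrt(diag(object$vcov))
  tab <- cbind(Estimate = cf, `Std. Error` = se)
  cat("Gompertz growth curve fit\n\nParameters:\n")
  printCoefmat(tab)
  cat(sprintf("\nInflection age t* = ln(b)/k = %.3f days\n", object$t_infl))
  cat(sprintf("Maximum growth rate A k / e = %.4f per day\n", object$max_rate))
  cat(sprintf("Residual sum of squares: %.4g on %d observations\n",
              object$rss, nrow(object$data)))
  invisible(object)
}

# gradient of y(t) wrt (A, b, k)
gompertz_grad <- function(cf, t) {
  A <- cf[["A"]]; b <- cf[["b"]]; k <- cf[["k"]]
  ekt <- exp(-k * t)
  core <- exp(-b * ekt)
  cbind(A = core, b = -A * core * ekt, k = A * core * b * t * ekt)
}

#' @export
#' @rdname fit_gompertz
#' @param object,newdata a `gompertz_fit` and a data.frame with column `t`
#'   (or a numeric vector of ages) at which to predict.
#' @param interval `"none"` or `"confidence"` (95 percent pointwise band by
#'   first-order error propagation).
#' @param ... unused.
predict.gompertz_fit <- function(object, newdata = NULL, interval = "none",
                                 ...) {
  t <- if (is.null(newdata)) object$data$t
  else if (is.data.frame(newdata)) newdata$t else as.numeric(newdata)
  cf <- coef(object)
  yhat <- cf[["A"]] * exp(-cf[["b"]] * exp(-cf[["k"]] * t))
  if (identical(interval, "none")) return(yhat)
  G <- gompertz_grad(cf, t)
  se <- sqrt(pmax(0, rowSums((G %*% object$vcov) * G)))
  zc <- qnorm(0.975)
  cbind(fit = yhat, lwr = yhat - zc * se, upr = yhat + zc * se)
}

#' @export
#' @rdname fit_gompertz
#' @param x a `gompertz_fit`.
plot.gompertz_fit <- function(x, ...) {
  tt <- seq(min(x$data$t), max(x$data$t), length.out = 200)
  pr <- predict(x, tt, interval = "confidence")
  graphics::plot(x$data$t, x$data$y, xlab = "age (days)", ylab = "size",
                 main = "Gompertz growth curve", ...)
  graphics::polygon(c(tt, rev(tt)), c(pr[, "lwr"], rev(pr[, "upr"])),
                    col = grDevices::adjustcolor("steelblue", 0.25),
                    border = NA)
  graphics::lines(tt, pr[, "fit"], col = "steelblue", lwd = 2)
  invisible(x)
}

#' Growth rate from a Gompertz fit
#'
#' The growth rate is the first differential of the fitted Gompertz model:
#' `y'(t) = A b k exp(-k t) exp(-b exp(-k t))`, maximal at the inflection
#' age `t* = log(b)/k` where it equals `A k / e`.
#'
#' @param fit a `gompertz_fit`, or a named vector with `A`, `b`, `k`.
#' @param t ages in days (vectorised).
#' @return growth rate in size units per day.
#' @export
growth_rate <- function(fit, t) {
  cf <- if (inherits(fit, "gompertz_fit")) coef(fit) else fit
  A <- cf[["A"]]; b <- cf[["b"]]; k <- cf[["k"]]
  A * b * k * exp(-k * t) * exp(-b * exp(-k * t))
}

#' Pearson correlation with two-sided test
#'
#' Product-moment correlation for unbounded responses (canal thickness,
#' cortical thickness, diameters), with the standard t-based two-sided
#' p-value.
#'
#' @param x,y numeric vectors, n >= 3, non-zero variance.
#' @return list with `r`, `p.value`, `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("invalid argument: need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}
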