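#' Pearson correlation test
#'
#' \code{t = r sqrt(df/(1 - r^2))} with \code{df = n - 2} and a two-sided
#' p-value.
#'
#' @param x,y numeric vectors of equal length (n >= 3), finite values.
#' @return list: r, t, p, df, n.
#' @export
pearsonTest <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop("need >= 3 paired values")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  r <- stats::cor(x, y)
  df <- length(x) - 2
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, t = t, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
       df = df, n = length(x))
}

# Wrap a fitted lm into the package's result shape.
wrapLm <- function(fit, candidates = NULL, path = NULL) {
  s <- summary(fit)
  fstat <- s$fstatistic
  structure(list(
    coefficients = as.data.frame(s$coefficients),
    r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared,
    f_statistic = if (!is.null(fstat)) unname(fstat[1]) else NA_real_,
    f_df = if (!is.null(fstat)) unname(fstat[2:3]) else c(NA, NA),
    f_p = if (!is.null(fstat))
      stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE) else NA_real_,
    aic = stats::AIC(fit),
    n = length(fit$residuals),
    selected = setdiff(names(stats::coef(fit)), "(Intercept)"),
    candidates = candidates,
    path = path,
    model = fit), class = "RegressionResult")
}

#' @export
print.RegressionResult <- function(x, ...) {
  cat("RegressionResult (n =", x$n, ")\n")
  print(round(x$coefficients, 4))
  cat(sprintf("R^2 = %.3f, F = %.2f on (%d, %d) df, P = %.3g, AIC = %.2f\n",
              x$r_squared, x$f_statistic, x$f_df[1], x$f_df[2], x$f_p, x$aic))
  if (!is.null(x$candidates))
    cat("selected:", paste(x$selected, collapse = ", "), "| dropped:",
        paste(setdiff(x$candidates, x$selected), collapse = ", "), "\n")
  invisible(x)
}

#' Ordinary least squares fit
#'
#' Gaussian-likelihood AIC (the \code{stats::AIC} convention,
#' \code{n log(RSS/n) + 2(p + 2) + n(log 2 pi + 1)}) is reported so that
#' AIC levels are comparable across nested fits on the same response; only
#' differences matter for selection.
#'
#' @param y response vector.
#' @param X data.frame or matrix of explanatory variables (no intercept
#'   column; one is added).
#' @return object of class \code{"RegressionResult"}: coefficient table,
#'   R^2, F statistic with df, AIC, n, and the underlying \code{lm} fit.
#' @export
olsFit <- function(y, X) {
  X <- as.data.frame(X)
  if (nrow(X) != length(y)) stop("y and X must align")
  if (length(y) <= ncol(X) + 1) stop("need n > number of parameters")
  dat <- cbind(.y = y, X)
  fit <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  wrapLm(fit, candidates = colnames(X))
}

#' Stepwise AIC variable selection
#'
#' Greedy add/drop minimizing AIC via \code{stats::step}, starting from the
#' full model. Default direction "backward" (the selected/dropped structure
#' of the monitoring study's analysis); "both" matches \code{step}'s
#' default behaviour.
#'
#' @param y response vector.
#' @param X data.frame or matrix of candidate explanatory variables.
#' @param direction "backward" or "both".
#' @return \code{"RegressionResult"} for the selected model, with the
#'   selection path (a data.frame of steps and AIC values) in \code{$path}.
#' @export
stepwiseAIC <- function(y, X, direction = c("backward", "both")) {
  direction <- match.arg(direction)
  full <- olsFit(y, X)
  # step() re-evaluates the lm call in this frame, so the data must be here
  dat <- cbind(.y = y, as.data.frame(X))
  fullFit <- stats::lm(.y ~ ., data = dat)
  sel <- stats::step(fullFit, direction = direction, trace = 0)
  path <- sel$anova
  out <- wrapLm(sel, candidates = colnames(as.data.frame(X)),
                path = data.frame(step = as.character(path$Step),
                                  aic_step = path$AIC))
  out$aic_full <- full$aic
  out
}
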