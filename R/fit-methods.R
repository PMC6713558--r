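#' @export
print.gvs_fit <- function(x, digits = 3, ...) {
  cat("Full-grid least-squares fit (", x$family, " family), ",
      attr(x$series, "measure"), ", ", x$n, " points\n", sep = "")
  print(round(x$coefficients, digits))
  cat("RSS: ", format(x$rss, digits = 4),
      "   variance explained: ",
      if (is.na(x$r.squared)) "NA" else
        paste0(format(100 * x$r.squared, digits = 4), "%"),
      "\n", sep = "")
  invisible(x)
}

#' @export
coef.gvs_fit <- function(object, ...) object$coefficients

#' @export
fitted.gvs_fit <- function(object, ...) object$fitted.values

#' @export
residuals.gvs_fit <- function(object, ...) object$residuals

#' Predict from a grid least-squares fit
#'
#' @param object A `gvs_fit`.
#' @param newdata New stimulation intensities (mA): a numeric vector or a
#'   data frame with an `intensity_mA` column. Defaults to the fitted series.
#' @param ... Unused.
#' @return Predicted response in degrees, in the order of `newdata`.
#' @export
predict.gvs_fit <- function(object, newdata = NULL, ...) {
  V <- if (is.null(newdata)) {
    object$series$intensity_mA
  } else if (is.data.frame(newdata)) {
    if (is.null(newdata$intensity_mA)) {
      stop("newdata needs an 'intensity_mA' column", call. = FALSE)
    }
    newdata$intensity_mA
  } else {
    as.numeric(newdata)
  }
  cf <- object$coefficients
  model_predict(object$family, cf[["a"]],
                if (family_has_b(object$family)) cf[["b"]], V)
}

#' @export
summary.gvs_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.gvs_fit")
}

#' @export
print.summary.gvs_fit <- function(x, ...) {
  f <- x$fit
  g <- f$grid
  print(f)
  a_unit <- if (f$family == "exp") "mA" else "deg/mA"
  b_role <- if (f$family == "exp") "asymptote (deg)" else "intercept (deg)"
  cat("  a: ", a_unit, ", grid [", g$a_min, ", ", g$a_max, "] step ",
      g$a_step, "\n", sep = "")
  if (family_has_b(f$family)) {
    cat("  b: ", b_role, ", grid [", g$b_min, ", ", g$b_max, "] step ",
        g$b_step, "\n", sep = "")
  }
  cat("Residuals:\n")
  print(summary(f$residuals))
  invisible(x)
}

#' Plot a fitted series
#'
#' Observed bilateral means with standard-error bars and the fitted curve on
#' a dense intensity sweep.
#'
#' @param x A `gvs_fit`.
#' @param v_step Curve evaluation step, mA.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.gvs_fit <- function(x, v_step = 0.01, ...) {
  s <- x$series
  v <- seq(0, max(s$intensity_mA), by = v_step)
  ylim <- range(0, s$mean_deg + s$sem_deg, predict(x, v))
  graphics::plot(s$intensity_mA, s$mean_deg, pch = 16, ylim = ylim,
                 xlab = "stimulation intensity (mA)",
                 ylab = paste(attr(s, "measure"), "(deg)"),
                 main = paste0(x$family, " fit"), ...)
  has_sem <- s$sem_deg > 0
  if (any(has_sem)) {
    graphics::arrows(s$intensity_mA[has_sem],
                     s$mean_deg[has_sem] - s$sem_deg[has_sem],
                     s$intensity_mA[has_sem],
                     s$mean_deg[has_sem] + s$sem_deg[has_sem],
                     angle = 90, code = 3, length = 0.03)
  }
  graphics::lines(v, predict(x, v), lty = 2)
  invisible(x)
}

#' Simulate synthetic studies from a fitted model
#'
#' Uses the fitted curve as the generative truth and the fitted series'
#' intensities and measure as the design; see [simulate_study()] for the
#' noise model.
#'
#' @param object A `gvs_fit`.
#' @param nsim Number of synthetic study tables.
#' @param seed Base seed; table `r` uses `seed + r - 1`. Drawn from the
#'   current RNG when `NULL`.
#' @param n_per_cell,noise_sd,polarity_asymmetry Passed to [synth_config()].
#' @param ... Unused.
#' @return A list of `nsim` study tables.
#' @export
simulate.gvs_fit <- function(object, nsim = 1, seed = NULL,
                             n_per_cell = 7, noise_sd = 0.5,
                             polarity_asymmetry = 0, ...) {
  cf <- as.list(coef(object))
  cfg <- synth_config(family = object$family, a = cf$a, b = cf$b,
                      intensities = object$series$intensity_mA,
                      n_per_cell = n_per_cell, noise_sd = noise_sd,
                      polarity_asymmetry = polarity_asymmetry,
                      measure = attr(object$series, "measure"))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max %/% 2L, 1L)
  lapply(seq_len(nsim), function(r) simulate_study(cfg, seed = seed + r - 1L))
}
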