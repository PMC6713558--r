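#' Parameter grid specification
#'
#' Describes the rectangular, inclusive parameter grid explored by
#' [gvs_fit()]: `a` runs over `a_min + k * a_step` up to `a_max`, and likewise
#' `b` when the family has a second parameter. Bounds are nonnegative; both
#' endpoints are candidates (upper-bound solutions are legitimate constrained
#' optima, and one of the published best fits sits exactly on its grid's
#' upper bound).
#'
#' @param a_min,a_max,a_step Bounds and resolution for `a`.
#' @param b_min,b_max,b_step Bounds and resolution for `b`; omit all three for
#'   the directly proportional family.
#' @return A `grid_spec`.
#' @seealso [default_grid()]
#' @export
grid_spec <- function(a_min, a_max, a_step,
                      b_min = NULL, b_max = NULL, b_step = NULL) {
  chk <- function(lo, hi, step, name) {
    stopifnot(is.numeric(lo), is.numeric(hi), is.numeric(step))
    if (lo < 0 || hi < lo) {
      stop("grid bounds for ", name,
           " must satisfy 0 <= min <= max", call. = FALSE)
    }
    if (step <= 0) stop("grid step for ", name, " must be positive",
                        call. = FALSE)
  }
  chk(a_min, a_max, a_step, "a")
  has_b <- !is.null(b_min) || !is.null(b_max) || !is.null(b_step)
  if (has_b) {
    if (is.null(b_min) || is.null(b_max) || is.null(b_step)) {
      stop("specify all of b_min, b_max, b_step or none", call. = FALSE)
    }
    chk(b_min, b_max, b_step, "b")
  }
  structure(list(a_min = a_min, a_max = a_max, a_step = a_step,
                 b_min = if (has_b) b_min, b_max = if (has_b) b_max,
                 b_step = if (has_b) b_step),
            class = "grid_spec")
}

#' Default parameter grids
#'
#' The grids used for the published reanalysis: both linear families explore
#' `[0, 3.5]` at resolution 0.0005 per parameter; the exponential explores
#' `[0, 7]` at resolution 0.001 for both the rate constant and the asymptote
#' (the rate grid effectively starts at 0.001, since `a = 0` is outside the
#' exponential's domain).
#'
#' @param family Model family label.
#' @return A [grid_spec()].
#' @export
default_grid <- function(family) {
  switch(match_family(family),
         `lin-prop` = grid_spec(0, 3.5, 5e-4),
         lin = grid_spec(0, 3.5, 5e-4, 0, 3.5, 5e-4),
         exp = grid_spec(0, 7, 1e-3, 0, 7, 1e-3))
}

# inclusive grid values min + k*step; the 1e-9 guard keeps the upper endpoint
# despite floating-point division
grid_values <- function(lo, hi, step) {
  lo + step * (0:floor((hi - lo) / step + 1e-9))
}

# Exhaustive scan of rss(a, b) = q0(a) - 2*b*q1(a) + b^2*q2(a) over the full
# (a, b) grid, blocked along a to bound memory. Both two-parameter families
# are linear in b, so this expansion evaluates the identical RSS a per-point
# loop would, for every candidate pair. Two passes: global minimum, then the
# lexicographically smallest (a, b) within `tol` of it (column-major order is
# a-major, b-minor, which is exactly lexicographic order).
scan_grid_quadratic <- function(a_vals, b_vals, q0, q1, q2,
                                tol = 1e-12, surface = FALSE,
                                block_size = 1024L) {
  nb <- length(b_vals)
  bsq <- b_vals^2
  blocks <- split(seq_along(a_vals),
                  ceiling(seq_along(a_vals) / block_size))
  block_rss <- function(j) {
    rep(q0[j], each = nb) - 2 * outer(b_vals, q1[j]) + outer(bsq, q2[j])
  }
  if (surface) {
    R <- do.call(cbind, lapply(blocks, block_rss))
    gmin <- min(R)
    k <- which(R <= gmin + tol)[1L]
    col <- (k - 1L) %/% nb + 1L
    row <- k - (col - 1L) * nb
    return(list(a = a_vals[col], b = b_vals[row], rss = R[k],
                surface = list(a = a_vals, b = b_vals, rss = R)))
  }
  gmin <- Inf
  for (j in blocks) gmin <- min(gmin, min(block_rss(j)))
  for (j in blocks) {
    R <- block_rss(j)
    k <- which(R <= gmin + tol)
    if (length(k)) {
      k <- k[1L]
      col <- (k - 1L) %/% nb + 1L
      row <- k - (col - 1L) * nb
      return(list(a = a_vals[j[col]], b = b_vals[row], rss = R[k],
                  surface = NULL))
    }
  }
  stop("internal error: grid minimum not found on rescan") # nocov
}

#' Constrained full-grid least-squares model fit
#'
#' Fits one dose-response family to a bilaterally averaged response series by
#' exhaustive least squares over a nonnegative parameter grid: the residual
#' sum of squares `sum((mean_i - f(V_i))^2)` is evaluated at every candidate
#' parameter combination and the grid point minimising it is returned. The
#' fit is unweighted -- neither cell sample sizes nor standard deviations
#' enter -- and constrained to the grid, so optima may legitimately sit on a
#' boundary (an intercept pinned at 0, or an asymptote at the grid maximum).
#' Ties within `1e-12` of the minimum resolve to the lexicographically
#' smallest `(a, b)` for cross-platform determinism.
#'
#' The evaluation is vectorised in blocks along the `a` axis, exploiting the
#' fact that both two-parameter families are linear in `b`; the default
#' exponential grid (about 49 million candidate pairs) completes in seconds.
#'
#' @param series A [measure_series][average_bilateral] (or data frame with
#'   columns `intensity_mA`, `mean_deg`).
#' @param family `"lin"`, `"lin-prop"`, or `"exp"` (see [model_predict()]).
#' @param grid A [grid_spec()]; defaults to the published resolution for the
#'   family. For the exponential, candidates with `a = 0` are skipped.
#' @param surface If `TRUE`, keep the dense RSS surface (a `length(b)` by
#'   `length(a)` matrix, plus axis values) for heatmap rendering. Only
#'   sensible for coarse grids; the default grids would need tens of
#'   gigabytes.
#' @param block_size Number of `a`-columns evaluated per block.
#' @return An object of class `gvs_fit`: a list with components `family`,
#'   `coefficients` (named `a`, and `b` when the family has one), `rss`,
#'   `r.squared` (`1 - RSS/TSS` with TSS about the series mean, uniformly
#'   across families, including the no-intercept ones), `grid`, `series`,
#'   `fitted.values`, `residuals`, `surface` (or `NULL`), `n`, `call`.
#'   Methods: `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
#'   `plot`, `simulate`.
#' @examples
#' torsion <- average_bilateral(zink1998_table(), "torsion")
#' # a coarse grid for a quick look; default_grid("exp") reproduces the
#' # published three-decimal estimates
#' fit <- gvs_fit(torsion, "exp", grid_spec(0, 7, 0.01, 0, 7, 0.01))
#' coef(fit)
#' @export
gvs_fit <- function(series, family = c("lin", "lin-prop", "exp"),
                    grid = default_grid(family), surface = FALSE,
                    block_size = 1024L) {
  family <- match_family(if (is.character(family)) family[1L] else family)
  series <- as_measure_series(series,
                              measure = attr(series, "measure") %||% "ocular_torsion")
  V <- series$intensity_mA
  Tm <- series$mean_deg
  if (length(V) == 0L) stop("empty series", call. = FALSE)
  if (!inherits(grid, "grid_spec")) stop("grid must be a grid_spec",
                                         call. = FALSE)
  needs_b <- family_has_b(family)
  if (needs_b && is.null(grid$b_min)) {
    stop("family '", family, "' needs a b grid", call. = FALSE)
  }

  a_vals <- grid_values(grid$a_min, grid$a_max, grid$a_step)
  if (family == "exp") a_vals <- a_vals[a_vals > 0]
  if (length(a_vals) == 0L) stop("grid contains no candidate points",
                                 call. = FALSE)

  Svv <- sum(V^2); Svt <- sum(V * Tm); Ctt <- sum(Tm^2)
  if (family == "lin-prop") {
    rss_a <- Ctt - 2 * a_vals * Svt + a_vals^2 * Svv
    gmin <- min(rss_a)
    i <- which(rss_a <= gmin + 1e-12)[1L]
    best <- list(a = a_vals[i], b = NULL,
                 surface = if (surface) list(a = a_vals, b = NULL, rss = rss_a))
  } else {
    b_vals <- grid_values(grid$b_min, grid$b_max, grid$b_step)
    if (family == "lin") {
      q0 <- Ctt - 2 * a_vals * Svt + a_vals^2 * Svv  # sum r^2, r = T - aV
      q1 <- sum(Tm) - a_vals * sum(V)                # sum r
      q2 <- rep.int(length(V), length(a_vals))
    } else {
      G <- 1 - exp(-outer(V, 1 / a_vals))
      q0 <- rep.int(Ctt, length(a_vals))
      q1 <- as.vector(crossprod(G, Tm))
      q2 <- colSums(G * G)
    }
    best <- scan_grid_quadratic(a_vals, b_vals, q0, q1, q2,
                                surface = surface, block_size = block_size)
  }

  coefs <- c(a = best$a, if (needs_b) c(b = best$b))
  fit_vals <- model_predict(family, best$a, best$b, V)
  res <- Tm - fit_vals
  rss <- sum(res^2)
  tss <- sum((Tm - mean(Tm))^2)
  structure(list(family = family,
                 coefficients = coefs,
                 rss = rss,
                 r.squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 grid = grid,
                 series = series,
                 fitted.values = fit_vals,
                 residuals = res,
                 surface = best$surface,
                 n = length(V),
                 call = match.call()),
            class = "gvs_fit")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Variance explained by a fitted (or hypothesised) model
#'
#' `1 - RSS/TSS`, with the total sum of squares taken about the series mean
#' for every family -- including the no-intercept ones, where other
#' conventions exist; this uniform convention is what the published
#' percentages use. Can be negative for fits worse than the series mean.
#'
#' @param object A `gvs_fit`, or a list with elements `family`, `a` and
#'   optionally `b` describing candidate parameters.
#' @param series Series to evaluate against; defaults to the one embedded in
#'   a `gvs_fit`.
#' @return Fraction of variance explained (not a percentage).
#' @export
variance_explained <- function(object, series = NULL) {
  if (inherits(object, "gvs_fit")) {
    pars <- as.list(coef(object))
    pars$family <- object$family
    series <- series %||% object$series
  } else if (is.list(object) && !is.null(object$family)) {
    pars <- object
  } else {
    stop("object must be a gvs_fit or a list(family=, a=, b=)", call. = FALSE)
  }
  series <- as_measure_series(series)
  if (nrow(series) < 2L) {
    stop("variance explained needs at least two points", call. = FALSE)
  }
  Tm <- series$mean_deg
  tss <- sum((Tm - mean(Tm))^2)
  if (tss <= 0) {
    stop("variance undefined: series has no spread about its mean",
         call. = FALSE)
  }
  pred <- model_predict(pars$family, pars$a, pars$b, series$intensity_mA)
  1 - sum((Tm - pred)^2) / tss
}

#' Closed-form least-squares oracle
#'
#' Textbook unconstrained ordinary least squares for the two linear families,
#' kept deliberately independent of the grid search so the two routes can
#' validate each other: through the origin, `slope = sum(V*T) / sum(V^2)`;
#' with an intercept, the usual centred formulas. Unlike [gvs_fit()] the
#' result is not constrained to nonnegative parameters -- a negative
#' unconstrained intercept is precisely what explains a grid solution pinned
#' at `b = 0`.
#'
#' @param series A measure series or compatible data frame.
#' @param intercept If `FALSE`, fit through the origin.
#' @return A list with `slope` and `intercept` (`NULL` when `intercept =
#'   FALSE`).
#' @examples
#' ols_fit(average_bilateral(zink1998_table(), "tilt"))  # intercept < 0
#' @export
ols_fit <- function(series, intercept = TRUE) {
  series <- as_measure_series(series)
  V <- series$intensity_mA
  Tm <- series$mean_deg
  if (!intercept) {
    if (sum(V^2) == 0) stop("degenerate design: all intensities zero",
                            call. = FALSE)
    return(list(slope = sum(V * Tm) / sum(V^2), intercept = NULL))
  }
  if (length(V) < 2L) {
    stop("need at least two points to estimate an intercept", call. = FALSE)
  }
  sxx <- sum((V - mean(V))^2)
  if (sxx == 0) stop("degenerate design: all intensities equal", call. = FALSE)
  slope <- sum((V - mean(V)) * (Tm - mean(Tm))) / sxx
  list(slope = slope, intercept = mean(Tm) - slope * mean(V))
}
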