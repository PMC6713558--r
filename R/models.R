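# The three candidate dose-response families. Labels follow the usual
# shorthand: "lin" (free intercept), "lin-prop" (directly proportional,
# i.e. constrained through the origin), "exp" (saturating exponential).
.gvs_families <- c("lin", "lin-prop", "exp")

#' Resolve a model family label
#'
#' Accepts `"lin"`/`"linear"`, `"lin-prop"`/`"proportional"`, and
#' `"exp"`/`"exponential"`.
#' @keywords internal
#' @noRd
match_family <- function(family) {
  stopifnot(is.character(family), length(family) >= 1L)
  family <- family[1L]
  out <- switch(family,
                lin = , linear = "lin",
                `lin-prop` = , proportional = , `directly_proportional` = "lin-prop",
                exp = , exponential = "exp",
                NA_character_)
  if (is.na(out)) {
    stop("unknown model family '", family, "'; expected one of ",
         paste(.gvs_families, collapse = ", "), call. = FALSE)
  }
  out
}

# TRUE when the family carries a second parameter b
family_has_b <- function(family) family %in% c("lin", "exp")

#' Evaluate a dose-response model
#'
#' Pure prediction for the three candidate families describing an ocular
#' response (degrees of rotation) as a function of stimulation current `V`
#' (mA):
#'
#' * `"lin"`: `a * V + b` — slope `a` (deg/mA) and free intercept `b` (deg);
#' * `"lin-prop"`: `a * V` — directly proportional, zero response at zero
#'   stimulation;
#' * `"exp"`: `b * (1 - exp(-V / a))` — saturating exponential, where `a` (mA)
#'   is a rate constant (smaller values mean a steeper initial rise) and `b`
#'   (deg) the asymptote the response can never exceed.
#'
#' Note that the units of `a` differ between families: degrees per mA for the
#' two linear families, mA for the exponential. All parameters are
#' constrained nonnegative (the unsigned-magnitude convention); the
#' exponential additionally requires `a > 0`, since its `a = 0` limit is
#' discontinuous at `V = 0` and division by zero otherwise.
#'
#' @param family Model family (see above; long synonyms accepted).
#' @param a Slope (deg/mA) for linear families, rate constant (mA) for the
#'   exponential. Scalar, nonnegative.
#' @param b Intercept (deg) for `"lin"`, asymptote (deg) for `"exp"`; must be
#'   `NULL` (or `NA`) for `"lin-prop"`.
#' @param V Stimulation intensity or vector of intensities, mA, `>= 0`.
#' @return Predicted response in degrees, same shape and order as `V`.
#' @examples
#' model_predict("lin", a = 0.483, b = 0.913, V = 0)
#' model_predict("exp", a = 1, b = 2, V = 1)   # 2 * (1 - exp(-1))
#' @export
model_predict <- function(family, a, b = NULL, V) {
  family <- match_family(family)
  stopifnot(is.numeric(a), length(a) == 1L, is.numeric(V))
  if (anyNA(V) || any(V < 0)) {
    stop("stimulation intensities V must be nonnegative", call. = FALSE)
  }
  if (is.na(a) || a < 0) stop("parameter a must be nonnegative", call. = FALSE)
  if (length(b) == 1L && is.na(b)) b <- NULL

  if (family == "lin-prop") {
    if (!is.null(b)) {
      stop("the directly proportional family has no b parameter", call. = FALSE)
    }
    return(a * V)
  }
  if (is.null(b) || !is.numeric(b) || length(b) != 1L || is.na(b) || b < 0) {
    stop("family '", family, "' needs a scalar nonnegative b parameter",
         call. = FALSE)
  }
  switch(family,
         lin = a * V + b,
         exp = {
           if (a == 0) {
             stop("the exponential rate constant a must be strictly positive",
                  call. = FALSE)
           }
           b * (1 - exp(-V / a))
         })
}
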