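#' Configuration for a synthetic stimulation study
#'
#' Describes the generative model behind a synthetic two-polarity study for
#' one measure: a true dose-response curve, the stimulation intensities, the
#' per-cell subject count, between-subject Gaussian noise, and an optional
#' polarity asymmetry. The defaults mirror the structure of the Zink et al.
#' (1998) design the pipeline was built around (torsion-like occupancy at
#' eight intensities, seven subjects per cell, noise of 0.5 degrees).
#'
#' @param family,a,b Generative truth, as in [model_predict()].
#' @param intensities Stimulation intensities, mA, strictly positive.
#' @param n_per_cell Subjects per (intensity, polarity) cell; scalar or one
#'   value per intensity.
#' @param noise_sd Between-subject standard deviation, degrees, `>= 0`.
#' @param polarity_asymmetry Additive offset (degrees) between the two
#'   stimulation arms: the left-anodal cell mean is shifted by `+asym/2` and
#'   the right-anodal by `-asym/2`, leaving the bilateral average unchanged
#'   in expectation.
#' @param measure Measure label attached to the generated cells.
#' @return A `synth_config`.
#' @seealso [simulate_study()], [recovery_experiment()]
#' @export
synth_config <- function(family, a, b = NULL,
                         intensities = c(1, 1.5, 2, 3, 4, 5, 6, 7),
                         n_per_cell = 7, noise_sd = 0.5,
                         polarity_asymmetry = 0,
                         measure = "ocular_torsion") {
  family <- match_family(family)
  measure <- match_measure(measure)
  stopifnot(is.numeric(intensities), length(intensities) >= 1L,
            is.numeric(noise_sd), length(noise_sd) == 1L,
            is.numeric(polarity_asymmetry), length(polarity_asymmetry) == 1L)
  if (any(intensities <= 0)) {
    stop("intensities must be strictly positive", call. = FALSE)
  }
  intensities <- sort(unique(intensities))
  n_per_cell <- rep_len(as.integer(n_per_cell), length(intensities))
  if (any(n_per_cell < 1L)) stop("n_per_cell must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  # validates the parameter set against the family's domain
  model_predict(family, a, b, intensities)
  structure(list(family = family, a = a, b = b,
                 intensities = intensities, n_per_cell = n_per_cell,
                 noise_sd = noise_sd,
                 polarity_asymmetry = polarity_asymmetry,
                 measure = measure),
            class = "synth_config")
}

#' Simulate a synthetic study table
#'
#' Draws a complete two-polarity summary table with the statistical structure
#' the analysis assumes. For each (intensity, polarity) cell, `n_per_cell`
#' per-subject magnitudes are drawn as
#' `|truth(V) + polarity offset + N(0, noise_sd)|` -- the absolute value
#' keeps the unsigned-magnitude convention -- and summarised into the cell's
#' mean, standard deviation, minimum, maximum and count. Cells are generated
#' in a fixed order (config order, then intensity ascending, left arm before
#' right) from a single stream seeded once per table, so an identical
#' seed and configuration always reproduce the identical table.
#'
#' @param config A [synth_config()], or a list of them (one per measure) to
#'   build a multi-measure table.
#' @param seed Integer seed for the table's pseudo-random stream.
#' @return A `study_table` that satisfies all table invariants and feeds
#'   directly into [average_bilateral()].
#' @examples
#' cfg <- synth_config("exp", a = 3.722, b = 4.714)
#' tab <- simulate_study(cfg, seed = 1)
#' average_bilateral(tab, "torsion")
#' @export
simulate_study <- function(config, seed) {
  if (inherits(config, "synth_config")) config <- list(config)
  if (!length(config) || !all(vapply(config, inherits, TRUE, "synth_config"))) {
    stop("config must be a synth_config or a list of synth_config",
         call. = FALSE)
  }
  measures <- vapply(config, `[[`, "", "measure")
  if (anyDuplicated(measures)) {
    stop("one synth_config per measure", call. = FALSE)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed))

  rows <- list()
  for (cfg in config) {
    mu <- model_predict(cfg$family, cfg$a, cfg$b, cfg$intensities)
    for (i in seq_along(cfg$intensities)) {
      for (pol in .gvs_polarities) {
        off <- cfg$polarity_asymmetry / 2 *
          (if (pol == "left_anodal") 1 else -1)
        vals <- abs(mu[i] + off + stats::rnorm(cfg$n_per_cell[i],
                                               0, cfg$noise_sd))
        rows[[length(rows) + 1L]] <- data.frame(
          intensity_mA = cfg$intensities[i], polarity = pol,
          measure = cfg$measure,
          mean_deg = mean(vals),
          sd_deg = if (length(vals) > 1L) stats::sd(vals) else 0,
          min_deg = min(vals), max_deg = max(vals),
          n = cfg$n_per_cell[i])
      }
    }
  }
  validate_study_table(do.call(rbind, rows))
}

#' Parameter-recovery experiment
#'
#' Quantifies how well the full pipeline (simulate a study table, average the
#' two stimulation arms, grid-fit a model family) recovers known generative
#' parameters. Replicate `r` seeds its table with `seed + r`, so the whole
#' experiment is reproducible from a single integer.
#'
#' @param config A single-measure [synth_config()] holding the truth.
#' @param n_replicates Number of simulated studies.
#' @param family Family fitted to each replicate; defaults to the generative
#'   family, but deliberate misspecification is allowed (truth columns are
#'   `NA` then).
#' @param grid [grid_spec()] for the fits. The default is the family's
#'   published grid; pass a coarser one for large simulation studies.
#' @param seed Base seed.
#' @return A `gvs_recovery` data frame with one row per fitted parameter:
#'   `parameter`, `truth`, `mean_estimate`, `bias`, `mae`, `rmse` (the last
#'   three relative to `truth` when available). The per-replicate estimates
#'   are attached as attribute `"estimates"`.
#' @examples
#' cfg <- synth_config("lin-prop", a = 0.672, noise_sd = 0.2)
#' recovery_experiment(cfg, n_replicates = 20,
#'                     grid = grid_spec(0, 3.5, 0.005), seed = 7)
#' @export
recovery_experiment <- function(config, n_replicates,
                                family = config$family,
                                grid = default_grid(family), seed = 1L) {
  stopifnot(inherits(config, "synth_config"),
            is.numeric(n_replicates), n_replicates >= 1)
  family <- match_family(family)
  par_names <- c("a", if (family_has_b(family)) "b")
  est <- matrix(NA_real_, nrow = n_replicates, ncol = length(par_names),
                dimnames = list(NULL, par_names))
  for (r in seq_len(n_replicates)) {
    fit <- tryCatch({
      tab <- simulate_study(config, seed = seed + r)
      gvs_fit(average_bilateral(tab, config$measure), family, grid)
    }, error = function(e) {
      stop("replicate ", r, ": ", conditionMessage(e), call. = FALSE)
    })
    est[r, ] <- coef(fit)[par_names]
  }
  same_family <- identical(family, config$family)
  truth <- if (same_family) {
    c(a = config$a, if (family_has_b(family)) c(b = config$b))[par_names]
  } else {
    stats::setNames(rep(NA_real_, length(par_names)), par_names)
  }
  err <- sweep(est, 2L, truth)
  out <- data.frame(parameter = par_names,
                    truth = as.numeric(truth),
                    mean_estimate = colMeans(est),
                    bias = colMeans(err),
                    mae = colMeans(abs(err)),
                    rmse = sqrt(colMeans(err^2)),
                    row.names = NULL)
  structure(out, estimates = est, n_replicates = n_replicates,
            family = family, class = c("gvs_recovery", "data.frame"))
}

#' @export
print.gvs_recovery <- function(x, digits = 4, ...) {
  cat("Parameter recovery: ", attr(x, "family"), " family, ",
      attr(x, "n_replicates"), " replicates\n", sep = "")
  print.data.frame(cbind(x["parameter"],
                         round(x[-1L], digits)), row.names = FALSE)
  invisible(x)
}
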