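#' End-to-end model-comparison reanalysis
#'
#' Runs the complete analysis on a two-measure study table: derives the
#' bilaterally averaged torsion and tilt series, fits all three model
#' families to each by full-grid least squares, computes variance explained,
#' collects the observed torsion--tilt pairs at the intensities where both
#' measures were recorded, and evaluates the three torsion--tilt model
#' combinations on a dense intensity sweep. The whole computation is
#' deterministic in the table and grids, and never mutates its input.
#'
#' Because no printed metric ranks the torsion--tilt combinations, the report
#' operationalises their fit as the summed squared Euclidean distance, in the
#' (torsion, tilt) plane, between each combination's curve and the observed
#' pairs at the shared intensities (`combo_rss`). On the packaged table this
#' ranks exp--lin best and lin--lin worst.
#'
#' @param table A `study_table` containing both measures; defaults to the
#'   packaged Zink et al. (1998) table.
#' @param grids Named list of [grid_spec()] overrides per family
#'   (`"lin"`, `"lin-prop"`, `"exp"`); unnamed families use [default_grid()].
#' @param surface Keep dense RSS surfaces on each fit (coarse grids only).
#' @param curve_step Intensity step (mA) for the torsion--tilt curves.
#' @return A `gvs_reanalysis` object: list with `table`, `series` (per
#'   measure), `fits` (per measure, per family), `pairs` (observed
#'   torsion--tilt points with standard errors), `curves` (per combination),
#'   `combo_rss` (named, ascending = better), and `grids`.
#' @examples
#' \donttest{
#' rep <- run_reanalysis()   # full published grids; takes a few seconds
#' print(rep)
#' }
#' @export
run_reanalysis <- function(table = zink1998_table(), grids = list(),
                           surface = FALSE, curve_step = 0.01) {
  table <- validate_study_table(table)
  stopifnot(is.list(grids))
  full <- list()
  for (fam in .gvs_families) full[[fam]] <- grids[[fam]] %||% default_grid(fam)

  series <- lapply(stats::setNames(nm = .gvs_measures), function(m) {
    average_bilateral(table, m)
  })
  fits <- lapply(series, function(s) {
    lapply(stats::setNames(nm = .gvs_families), function(fam) {
      gvs_fit(s, fam, grid = full[[fam]], surface = surface)
    })
  })

  shared <- intersect(series$ocular_torsion$intensity_mA,
                      series$visual_tilt$intensity_mA)
  st <- series$ocular_torsion
  sv <- series$visual_tilt
  it <- match(shared, st$intensity_mA)
  iv <- match(shared, sv$intensity_mA)
  pairs <- data.frame(intensity_mA = shared,
                      torsion_deg = st$mean_deg[it],
                      torsion_sem = st$sem_deg[it],
                      tilt_deg = sv$mean_deg[iv],
                      tilt_sem = sv$sem_deg[iv])

  combos <- list(
    "lin-lin" = c(torsion = "lin-prop", tilt = "lin-prop"),
    "exp-exp" = c(torsion = "exp", tilt = "exp"),
    "exp-lin" = c(torsion = "exp", tilt = "lin-prop"))
  v_max <- if (length(shared)) max(shared) else max(st$intensity_mA)
  curves <- lapply(combos, function(cb) {
    torsion_tilt_curves(fits$ocular_torsion[[cb[["torsion"]]]],
                        fits$visual_tilt[[cb[["tilt"]]]],
                        v_max = v_max, step = curve_step)
  })
  combo_rss <- vapply(combos, function(cb) {
    ft <- fits$ocular_torsion[[cb[["torsion"]]]]
    fv <- fits$visual_tilt[[cb[["tilt"]]]]
    sum((pairs$torsion_deg - predict(ft, pairs$intensity_mA))^2 +
          (pairs$tilt_deg - predict(fv, pairs$intensity_mA))^2)
  }, numeric(1L))

  structure(list(table = table, series = series, fits = fits,
                 pairs = pairs, curves = curves,
                 combo_rss = sort(combo_rss), grids = full),
            class = "gvs_reanalysis")
}

#' Paired torsion and tilt curves over a shared intensity sweep
#'
#' Evaluates two already-fitted dose-response curves on the same dense
#' intensity grid and pairs them point-by-point, so visual tilt can be read
#' as a function of ocular torsion under identical stimulation. No fitting
#' occurs here.
#'
#' @param fit_torsion,fit_tilt `gvs_fit` objects.
#' @param v_max Upper end of the sweep, mA (swept from 0).
#' @param step Sweep resolution, mA.
#' @return Data frame with `intensity_mA`, `torsion_deg`, `tilt_deg`.
#' @export
torsion_tilt_curves <- function(fit_torsion, fit_tilt, v_max, step = 0.01) {
  stopifnot(inherits(fit_torsion, "gvs_fit"), inherits(fit_tilt, "gvs_fit"),
            is.numeric(v_max), v_max > 0, step > 0)
  v <- seq(0, v_max, by = step)
  data.frame(intensity_mA = v,
             torsion_deg = predict(fit_torsion, v),
             tilt_deg = predict(fit_tilt, v))
}

#' Flat results table of a reanalysis
#'
#' One row per (measure, family) fit: parameters, residual sum of squares,
#' variance explained, and the explored grid, ready for CSV export.
#'
#' @param report A `gvs_reanalysis`.
#' @return A data frame with columns `measure`, `family`, `a`, `b`, `rss`,
#'   `r_squared`, `a_min`, `a_max`, `a_step`, `b_min`, `b_max`, `b_step`.
#' @export
fit_table <- function(report) {
  stopifnot(inherits(report, "gvs_reanalysis"))
  rows <- list()
  for (m in names(report$fits)) {
    for (fam in names(report$fits[[m]])) {
      f <- report$fits[[m]][[fam]]
      g <- f$grid
      cf <- coef(f)
      rows[[length(rows) + 1L]] <- data.frame(
        measure = m, family = fam,
        a = cf[["a"]], b = if ("b" %in% names(cf)) cf[["b"]] else NA_real_,
        rss = f$rss, r_squared = f$r.squared,
        a_min = g$a_min, a_max = g$a_max, a_step = g$a_step,
        b_min = g$b_min %||% NA_real_, b_max = g$b_max %||% NA_real_,
        b_step = g$b_step %||% NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.gvs_reanalysis <- function(x, ...) {
  ft <- fit_table(x)
  cat("Model comparison: grid least-squares fits\n\n")
  show <- data.frame(measure = ft$measure, family = ft$family,
                     a = round(ft$a, 3), b = round(ft$b, 3),
                     rss = round(ft$rss, 4),
                     var_explained = paste0(round(100 * ft$r_squared), "%"))
  print(show, row.names = FALSE)
  cat("\nTorsion-tilt combinations, RSS over", nrow(x$pairs),
      "observed pairs (best first):\n")
  print(round(x$combo_rss, 4))
  invisible(x)
}

#' Render the reanalysis figures
#'
#' Writes three PNG files into `out_dir`:
#' \describe{
#'   \item{`rss_surfaces.png`}{Residual-sum-of-squares landscapes per family
#'     and measure (lighter is better), with the best fit circled. Surfaces
#'     are evaluated on a display grid of `surface_points` steps per axis
#'     spanning the fit's grid; the marked optimum is the full-resolution
#'     one from the report.}
#'   \item{`fits_with_data.png`}{Both averaged series with standard-error
#'     shading, overlaid with the proportional (dotted) and exponential
#'     (dashed) fits.}
#'   \item{`torsion_vs_tilt.png`}{Visual tilt against ocular torsion:
#'     observed pairs with standard-error bars and the three model
#'     combinations.}
#' }
#'
#' @param report A `gvs_reanalysis`.
#' @param out_dir Output directory; created if needed.
#' @param surface_points Display-surface resolution per axis.
#' @param width,height,res Passed to [grDevices::png()].
#' @return Invisibly, the paths of the three files written.
#' @export
render_figures <- function(report, out_dir, surface_points = 121,
                           width = 1800, height = 1400, res = 150) {
  stopifnot(inherits(report, "gvs_reanalysis"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory '", out_dir, "'", call. = FALSE)
  }
  paths <- file.path(out_dir, c("rss_surfaces.png", "fits_with_data.png",
                                "torsion_vs_tilt.png"))

  coarse <- function(g) {
    astep <- (g$a_max - g$a_min) / (surface_points - 1)
    if (is.null(g$b_min)) grid_spec(g$a_min, g$a_max, astep)
    else grid_spec(g$a_min, g$a_max, astep,
                   g$b_min, g$b_max, (g$b_max - g$b_min) / (surface_points - 1))
  }
  pal <- grDevices::hcl.colors(64, "Grays")  # light = low RSS = better

  grDevices::png(paths[1L], width = width, height = height * 1.4, res = res)
  graphics::par(mfrow = c(3, 2), mar = c(4, 4, 2.5, 1))
  for (fam in .gvs_families) {
    for (m in .gvs_measures) {
      f <- report$fits[[m]][[fam]]
      cf <- gvs_fit(f$series, fam, grid = coarse(f$grid), surface = TRUE)
      sf <- cf$surface
      ttl <- paste0(fam, " — ", m)
      if (fam == "lin-prop") {
        graphics::plot(sf$a, sf$rss, type = "l", xlab = "a (deg/mA)",
                       ylab = "RSS", main = ttl)
        graphics::points(coef(f)[["a"]], f$rss, col = "magenta", cex = 1.5)
      } else {
        graphics::image(sf$a, sf$b, t(sf$rss), col = rev(pal),
                        xlab = if (fam == "exp") "a (mA)" else "a (deg/mA)",
                        ylab = if (fam == "exp") "b (deg)" else "b (deg)",
                        main = ttl)
        graphics::points(coef(f)[["a"]], coef(f)[["b"]],
                         col = "magenta", cex = 1.5, lwd = 2)
      }
    }
  }
  grDevices::dev.off()

  grDevices::png(paths[2L], width = width, height = height, res = res)
  cols <- c(ocular_torsion = "#3366BB", visual_tilt = "#DDAA33")
  v <- seq(0, max(report$series$ocular_torsion$intensity_mA), by = 0.01)
  ylim <- c(0, max(vapply(report$series, function(s)
    max(s$mean_deg + s$sem_deg), numeric(1L))))
  graphics::plot(NA, xlim = c(0, max(v)), ylim = ylim,
                 xlab = "galvanic vestibular stimulation (mA)",
                 ylab = "rotation (deg)",
                 main = "Averaged data with model fits")
  for (m in .gvs_measures) {
    s <- report$series[[m]]
    graphics::polygon(c(s$intensity_mA, rev(s$intensity_mA)),
                      c(s$mean_deg - s$sem_deg, rev(s$mean_deg + s$sem_deg)),
                      col = grDevices::adjustcolor(cols[[m]], 0.2),
                      border = NA)
    graphics::lines(s$intensity_mA, s$mean_deg, col = cols[[m]], lwd = 2)
    graphics::lines(v, predict(report$fits[[m]][["lin-prop"]], v),
                    col = cols[[m]], lty = 3)
    graphics::lines(v, predict(report$fits[[m]][["exp"]], v),
                    col = cols[[m]], lty = 2)
  }
  graphics::legend("topleft", bty = "n",
                   legend = c("ocular torsion", "visual tilt",
                              "proportional fit", "exponential fit"),
                   col = c(cols, "grey30", "grey30"),
                   lty = c(1, 1, 3, 2), lwd = c(2, 2, 1, 1))
  grDevices::dev.off()

  grDevices::png(paths[3L], width = width, height = height, res = res)
  p <- report$pairs
  lty <- c("lin-lin" = 3, "exp-exp" = 2, "exp-lin" = 4)
  xlim <- c(0, max(p$torsion_deg + p$torsion_sem,
                   vapply(report$curves, function(cv) max(cv$torsion_deg),
                          numeric(1L))))
  ylim <- c(0, max(p$tilt_deg + p$tilt_sem,
                   vapply(report$curves, function(cv) max(cv$tilt_deg),
                          numeric(1L))))
  graphics::plot(p$torsion_deg, p$tilt_deg, pch = 16, xlim = xlim,
                 ylim = ylim, xlab = "ocular torsion (deg)",
                 ylab = "visual tilt (deg)",
                 main = "Visual tilt as a function of ocular torsion")
  graphics::arrows(p$torsion_deg, p$tilt_deg - p$tilt_sem,
                   p$torsion_deg, p$tilt_deg + p$tilt_sem,
                   angle = 90, code = 3, length = 0.03)
  graphics::arrows(p$torsion_deg - p$torsion_sem, p$tilt_deg,
                   p$torsion_deg + p$torsion_sem, p$tilt_deg,
                   angle = 90, code = 3, length = 0.03)
  for (nm in names(report$curves)) {
    cv <- report$curves[[nm]]
    graphics::lines(cv$torsion_deg, cv$tilt_deg, lty = lty[[nm]])
  }
  graphics::legend("topleft", bty = "n", legend = names(lty), lty = lty)
  grDevices::dev.off()

  invisible(paths)
}
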