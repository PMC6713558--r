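# shared fixtures and independent oracles for the test suite

make_series <- function(V, Tm, sem = 0, measure = "ocular_torsion") {
  as_measure_series(data.frame(intensity_mA = V, mean_deg = Tm,
                               sem_deg = sem), measure = measure)
}

# deliberately naive exhaustive search: evaluates the model point by point
# through model_predict() and scans every (a, b) combination with a loop.
# Independent of gvs_fit's vectorised evaluation; only usable on coarse grids.
brute_force_fit <- function(series, family, grid) {
  a_vals <- grid$a_min + grid$a_step *
    (0:floor((grid$a_max - grid$a_min) / grid$a_step + 1e-9))
  if (family == "exp") a_vals <- a_vals[a_vals > 0]
  b_vals <- if (is.null(grid$b_min)) NA_real_ else {
    grid$b_min + grid$b_step *
      (0:floor((grid$b_max - grid$b_min) / grid$b_step + 1e-9))
  }
  best <- list(rss = Inf)
  for (a in a_vals) {
    for (b in b_vals) {
      pred <- model_predict(family, a, if (!is.na(b)) b,
                            series$intensity_mA)
      rss <- sum((series$mean_deg - pred)^2)
      if (rss < best$rss - 1e-12) best <- list(a = a, b = b, rss = rss)
    }
  }
  best
}

# coarse grids used wherever the published resolution is not itself under test
coarse_grids <- list(
  "lin"      = grid_spec(0, 3.5, 0.005, 0, 3.5, 0.005),
  "lin-prop" = grid_spec(0, 3.5, 0.005),
  "exp"      = grid_spec(0, 7, 0.01, 0, 7, 0.01))
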