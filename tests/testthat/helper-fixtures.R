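# shared fixtures, built in code

# a clean linear trace: deflection = slope_mm_per_kPa * pressure
linear_trace <- function(slope = 0.025, r_i = 0.05, n = 40, p_max = 1.2,
                         specimen = "s1", region = "RV", group = "control") {
  p <- seq(0, p_max, length.out = n)
  aspiration_trace(time = p / 0.4, pressure = p, deflection = slope * p,
                   r_i = r_i, specimen = specimen, region = region,
                   group = group)
}

# deterministic lightweight cohort table: group means with fixed spread
toy_cohort <- function(means, n = 5, spread = 0.1, range = 0.4) {
  rows <- list()
  dev <- seq(-1, 1, length.out = n) * spread
  for (rg in names(means)) {
    for (g in names(means[[rg]])) {
      m <- means[[rg]][[g]]
      rows[[length(rows) + 1L]] <- data.frame(
        specimen = paste0(g, "_", rg, "_", seq_len(n)),
        region = rg, group = g, range = range,
        value = m * (1 + dev), stringsAsFactors = FALSE)
    }
  }
  cohort_table(do.call(rbind, rows))
}

# small geometry for fast finite-element checks
fast_geom <- function() group_presets()$control_RV$geom

fe_refine_fast <- 0.7
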