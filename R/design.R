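#' Simplex-centroid mixture blends
#'
#' The seven blends of the three-component simplex-centroid design: the three
#' pure-lipid vertices, the three 50/50 binary blends, and the ternary
#' centroid.
#'
#' @return data frame with columns `cw`, `gb`, `gds`, seven rows.
#' @export
simplex_centroid <- function() {
  data.frame(
    cw  = c(0, 0, 1, 0, 0.5, 0.5, 1 / 3),
    gb  = c(0, 1, 0, 0.5, 0, 0.5, 1 / 3),
    gds = c(1, 0, 0, 0.5, 0.5, 0, 1 / 3))
}

#' Factorial grid over the process factors
#'
#' Full Cartesian product of surfactant-ratio and ultrasound-time levels, in
#' lexicographic order (ultrasound time varying slowest).
#'
#' @param p80_levels percentages of polysorbate 80 in the surfactant couple,
#'   each in \[0, 100\].
#' @param us_levels ultrasound times in minutes, each in \[1, 10\].
#' @return data frame with columns `p80_pct`, `us_time_min`.
#' @export
process_grid <- function(p80_levels, us_levels) {
  if (any(p80_levels < 0 | p80_levels > 100))
    stop_config("p80 levels outside the 0-100% variation domain")
  if (any(us_levels < 1 | us_levels > 10))
    stop_config("ultrasound levels outside the 1-10 min variation domain")
  g <- expand.grid(p80_pct = sort(p80_levels), us_time_min = sort(us_levels),
                   KEEP.OUT.ATTRS = FALSE)
  rownames(g) <- NULL
  g
}

#' Cross mixture blends with process settings
#'
#' Every blend is run at every process setting; the mixture-process crossed
#' design with `nrow(blends) * nrow(settings)` runs. Run ids are consecutive
#' integers in setting-major order (all blends at the first setting, then the
#' next), matching the layout of the packaged study.
#'
#' @param blends data frame of mixture proportions (`cw`, `gb`, `gds`).
#' @param settings data frame of process settings (`p80_pct`, `us_time_min`).
#' @param provenance label stored on the design.
#' @param seed optional seed stored on the design (for selected subsets).
#' @return an `sln_design` data frame of run conditions.
#' @export
cross_design <- function(blends, settings, provenance = "full_cross", seed = NULL) {
  if (!nrow(blends) || !nrow(settings)) stop_config("blends and settings must be non-empty")
  i <- rep(seq_len(nrow(settings)), each = nrow(blends))
  j <- rep(seq_len(nrow(blends)), times = nrow(settings))
  runs <- cbind(settings[i, , drop = FALSE], blends[j, , drop = FALSE])
  runs <- data.frame(run_id = as.character(seq_len(nrow(runs))), runs,
                     row.names = NULL, check.names = FALSE)
  validate_conditions(runs)
  structure(runs, class = c("sln_design", "sln_study", "data.frame"),
            provenance = provenance, seed = seed)
}

#' Code process factors onto \[-1, 1\]
#'
#' Affine map sending the midpoint of each variation domain to 0 and the
#' endpoints to -1 and +1: `x1 = (p80 - 50)/50`, `x2 = (us - 5.5)/4.5`.
#' Mixture proportions are never coded; they enter models raw.
#'
#' @param p80_pct,us_time_min process factor values.
#' @param extrapolate allow values outside the variation domains.
#' @return data frame with coded columns `x1`, `x2`.
#' @export
code_process <- function(p80_pct, us_time_min, extrapolate = FALSE) {
  if (!extrapolate &&
      (any(p80_pct < 0 | p80_pct > 100) || any(us_time_min < 1 | us_time_min > 10)))
    stop_config("process setting outside the variation domains (set extrapolate = TRUE to override)")
  data.frame(x1 = (p80_pct - 50) / 50, x2 = (us_time_min - 5.5) / 4.5)
}
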