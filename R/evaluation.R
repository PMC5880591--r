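# Evaluation: local per-beam/per-point deviations against the TPS, plan
# summaries, thresholds and sensitivity checks.

#' Local percent deviation
#'
#' `100 * (d_recon - d_tps) / d_tps`: negative when the reconstructed dose
#' is smaller than the planned dose.
#'
#' @param d_recon reconstructed dose (Gy).
#' @param d_tps TPS reference dose (Gy, > 0).
#' @return deviation in percent (vectorized).
#' @export
#' @examples
#' local_deviation(0.944, 1) # -5.6
local_deviation <- function(d_recon, d_tps) {
  if (any(!is.na(d_tps) & d_tps <= 0)) {
    ed_stop("epidose_undefined_reference",
            "local deviation is undefined for d_tps <= 0; flag the point instead")
  }
  100 * (d_recon - d_tps) / d_tps
}

#' Per-point summary of per-beam deviations
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' per-beam local deviations at each point, over non-excluded beams only,
#' plus the total-dose deviation computed from the summed doses. The
#' total-dose deviation equals the TPS-dose-weighted mean of the per-beam
#' deviations, so a single total figure is reported; it is listed separately
#' from the unweighted mean because a passing mean can hide individual beams
#' outside the threshold.
#'
#' @param rows data frame with columns `poi`, `dose`, `d_tps`, `deviation`
#'   and logical `excluded` (e.g. from [evaluate_plan()]'s per-beam table).
#' @param allow_empty if `TRUE`, a point whose beams are all excluded yields
#'   an `NA` row instead of an error (used when re-flagging whole reports).
#' @return data frame per point: `poi`, `mean_dev`, `sd_dev`, `total_dev`,
#'   `n_used`, `n_excluded`.
#' @export
#' @examples
#' rows <- data.frame(poi = "iso", dose = c(0.99, 1, 1.01),
#'                    d_tps = 1, deviation = c(-1, 0, 1), excluded = FALSE)
#' plan_summary(rows) # mean 0, sd 1
plan_summary <- function(rows, allow_empty = FALSE) {
  stopifnot(all(c("poi", "dose", "d_tps", "deviation") %in% names(rows)))
  if (is.null(rows$excluded)) rows$excluded <- FALSE
  out <- lapply(split(rows, rows$poi), function(d) {
    use <- d[!d$excluded & !is.na(d$deviation), ]
    def <- !is.na(d$d_tps) & d$d_tps > 0
    if (nrow(use) == 0) {
      if (!allow_empty) {
        ed_stop("epidose_empty_summary",
                sprintf("all beams excluded at point '%s'; no summary possible",
                        d$poi[1]))
      }
      return(data.frame(poi = d$poi[1], mean_dev = NA_real_, sd_dev = NA_real_,
                        total_dev = if (any(def))
                          local_deviation(sum(d$dose[def]), sum(d$d_tps[def]))
                        else NA_real_,
                        n_used = 0L, n_excluded = sum(d$excluded)))
    }
    data.frame(poi = d$poi[1],
               mean_dev = mean(use$deviation),
               sd_dev = if (nrow(use) > 1) sd(use$deviation) else 0,
               total_dev = local_deviation(sum(d$dose[def]), sum(d$d_tps[def])),
               n_used = nrow(use), n_excluded = sum(d$excluded))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Apply notification thresholds and low-dose exclusion
#'
#' Per-point fail when the absolute total-dose deviation exceeds
#' `plan_threshold`; per-beam warn when an individual beam deviates by more
#' than `beam_threshold`; beams contributing less than `low_dose_frac` of
#' the point's total TPS dose are labelled low-dose and excluded from
#' pass/fail (local deviations in low-dose regions are dominated by small
#' absolute differences and are not suitable evaluation points).
#'
#' @param report a `deviation_report` from [evaluate_plan()], or a list with
#'   `per_beam` and `per_poi` data frames of the same shape.
#' @param plan_threshold per-point total-dose threshold in percent.
#' @param beam_threshold per-beam threshold in percent.
#' @param low_dose_frac minimum fraction of the point's TPS dose a beam must
#'   contribute to be scored.
#' @return the report with updated `flag`/`excluded` columns and per-point
#'   `status` (`"pass"`/`"fail"`).
#' @export
flag_deviations <- function(report, plan_threshold = 5, beam_threshold = 8,
                            low_dose_frac = 0.10) {
  chk_num(plan_threshold, "plan_threshold", positive = TRUE)
  chk_num(beam_threshold, "beam_threshold", positive = TRUE)
  chk_num(low_dose_frac, "low_dose_frac", nonneg = TRUE)
  pb <- report$per_beam
  tot_tps <- tapply(pb$d_tps, pb$poi, sum)
  frac <- pb$d_tps / as.numeric(tot_tps[pb$poi])
  lowdose <- !is.na(frac) & frac < low_dose_frac
  undef <- is.na(pb$d_tps) | pb$d_tps <= 0
  pb$excluded <- lowdose | undef | !pb$infield
  pb$flag <- ifelse(undef, "undefined",
                    ifelse(lowdose | !pb$infield, "low-dose",
                           ifelse(abs(pb$deviation) > beam_threshold,
                                  "warn", "pass")))
  report$per_beam <- pb
  report$per_poi <- plan_summary(pb, allow_empty = TRUE)
  report$per_poi$status <- ifelse(report$per_poi$n_used == 0, "excluded",
                                  ifelse(abs(report$per_poi$total_dev) > plan_threshold,
                                         "fail", "pass"))
  report$thresholds <- list(plan = plan_threshold, beam = beam_threshold,
                            low_dose_frac = low_dose_frac)
  class(report) <- "deviation_report"
  report
}

#' Full deviation report for a reconstructed plan
#'
#' Computes per-beam local deviations from a [reconstruct_plan()] result and
#' applies [flag_deviations()].
#'
#' @param recon a `reconstructed_dose`.
#' @inheritParams flag_deviations
#' @return an object of class `deviation_report` with `per_beam` and
#'   `per_poi` data frames.
#' @export
evaluate_plan <- function(recon, plan_threshold = 5, beam_threshold = 8,
                          low_dose_frac = 0.10) {
  stopifnot(inherits(recon, "reconstructed_dose"))
  pb <- recon$per_beam
  if (all(is.na(pb$d_tps))) {
    ed_stop("epidose_undefined_reference",
            "no TPS reference doses attached to the reconstruction")
  }
  ok <- !is.na(pb$d_tps) & pb$d_tps > 0
  pb$deviation <- NA_real_
  pb$deviation[ok] <- local_deviation(pb$dose[ok], pb$d_tps[ok])
  flag_deviations(list(per_beam = pb), plan_threshold, beam_threshold,
                  low_dose_frac)
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("<deviation_report> thresholds: plan %g%%, beam %g%%, low-dose < %g of TPS total\n",
              x$thresholds$plan, x$thresholds$beam, x$thresholds$low_dose_frac))
  pp <- x$per_poi
  pp$mean_dev <- sprintf("%+.2f%%", pp$mean_dev)
  pp$sd_dev <- sprintf("%.2f", pp$sd_dev)
  pp$total_dev <- sprintf("%+.2f%%", pp$total_dev)
  print(pp, row.names = FALSE)
  invisible(x)
}

#' Predicted deviation under an MU delivery scaling
#'
#' Compounds a plan's baseline systematic deviation multiplicatively with a
#' delivered-MU scale factor: `100 * (mu_scale * (1 + baseline / 100) - 1)`.
#' With a zero baseline this reduces to the pure MU linearity
#' `100 * (mu_scale - 1)`.
#'
#' @param baseline_mean_dev baseline mean deviation in percent.
#' @param mu_scale delivered-over-planned MU ratio (> 0).
#' @return predicted mean deviation in percent.
#' @export
#' @examples
#' mu_sensitivity(-0.6, 0.95) # -5.57, i.e. -5.6 at one decimal
mu_sensitivity <- function(baseline_mean_dev, mu_scale) {
  chk_num(mu_scale, "mu_scale", positive = TRUE)
  chk_num(baseline_mean_dev, "baseline_mean_dev")
  100 * (mu_scale * (1 + baseline_mean_dev / 100) - 1)
}

#' Automatic high-dose evaluation points
#'
#' Draws `n` distinct voxels uniformly (seeded, reproducible) from the
#' region receiving at least `high_dose_frac` of the maximum dose on the
#' grid - a dose-level stand-in for the prescription target volume when no
#' structure set is available.
#'
#' @param dose_grid a `dose_grid` (see [compute_dose_grid()]) or a list with
#'   axis vectors `x`, `y`, `z` and a 3-D `dose` array.
#' @param n number of points to draw.
#' @param high_dose_frac dose threshold as a fraction of the grid maximum.
#' @param seed integer seed making the draw reproducible.
#' @return list of `n` [point_of_interest()]s with role `"target"`.
#' @export
auto_poi_sample <- function(dose_grid, n = 20, high_dose_frac = 0.90, seed) {
  chk_num(n, "n", positive = TRUE)
  chk_num(high_dose_frac, "high_dose_frac", positive = TRUE)
  d <- dose_grid$dose
  dmax <- max(d, na.rm = TRUE)
  qual <- which(!is.na(d) & d >= high_dose_frac * dmax)
  if (length(qual) < n) {
    ed_stop("epidose_too_few_voxels",
            sprintf("only %d voxels at or above %.0f%% of the maximum dose (need %d); try a lower high_dose_frac",
                    length(qual), 100 * high_dose_frac, n))
  }
  if (!missing(seed) && !is.null(seed)) set.seed(seed)
  pick <- sample(qual, n)
  idx <- arrayInd(pick, dim(d))
  lapply(seq_len(n), function(i) {
    point_of_interest(sprintf("auto%02d", i),
                      c(dose_grid$x[idx[i, 1]], dose_grid$y[idx[i, 2]],
                        dose_grid$z[idx[i, 3]]),
                      role = "target")
  })
}
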