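#' SPR conversion factor for anatomical-change scenarios
#'
#' The mean stopping-power ratio of the tissue affected by the Bragg-peak
#' shift, obtained as the ratio of the known WET of the introduced slab to
#' the calculated geometric range shift: `SPR = s_wet_slab / s_geom_calc`.
#' Both inputs follow the pullback-positive sign convention, so a physical
#' configuration always yields a positive factor; inputs of opposite sign
#' are rejected.
#'
#' @param s_wet_slab Known WET of the introduced slab (mm).
#' @param s_geom_calc Calculated (spot-median) geometric range shift (mm).
#' @return The dimensionless SPR factor.
#' @examples
#' spr_delta_r(5.0, 4.8)  # 1.0417
#' @export
spr_delta_r <- function(s_wet_slab, s_geom_calc) {
  if (any(s_geom_calc == 0)) abort("calculated geometric shift must be nonzero")
  if (any(s_wet_slab * s_geom_calc < 0)) {
    abort("slab WET and calculated shift must have the same sign")
  }
  s_wet_slab / s_geom_calc
}

#' Convert a geometric range shift to a WET range shift
#'
#' Geometric shifts measured by PGI depend on the stopping power of the
#' tissue the beam stops in; multiplying by a mean SPR converts them to
#' water-equivalent shifts comparable with RP. For anatomical-change (AC)
#' scenarios the factor is the slab-calibrated [spr_delta_r()]; for
#' setup-error (SE) scenarios, where the Bragg peaks sit in homogeneous
#' brain tissue, the brain mean SPR (1.04) is used.
#'
#' @param s_geom Measured geometric shift(s), mm.
#' @param mode `"AC"` or `"SE"`.
#' @param spr_factor The [spr_delta_r()] value (required for AC mode).
#' @param spr_brain Mean SPR of the brain region.
#' @return WET shift(s), mm.
#' @examples
#' geom_to_wet(1.0, mode = "SE")  # 1.04
#' @export
geom_to_wet <- function(s_geom, mode = c("AC", "SE"), spr_factor = NULL,
                        spr_brain = 1.04) {
  mode <- match.arg(mode)
  if (mode == "AC") {
    if (is.null(spr_factor)) abort("AC mode needs the spr_factor from spr_delta_r()")
    s_geom * spr_factor
  } else {
    s_geom * spr_brain
  }
}

#' Summarize the repeated shift measurements of each spot
#'
#' Per spot: the median M over the repeats (the per-spot measurement), the
#' unbiased variance over the repeats, and the inverse-variance weight
#' `w = 1 / max(var, var_floor)`. Flagged or missing repeats are dropped;
#' spots with fewer than two valid repeats are flagged out (`NA` summary).
#' The variance floor keeps the weights defined when repeats agree exactly
#' (as in noise-free runs).
#'
#' @param shifts A tibble with columns `spot_id`, `repeat`, a shift column
#'   named by `value`, and `flag`.
#' @param value Name of the shift column to summarize.
#' @param var_floor Variance floor (mm^2).
#' @return A tibble: `spot_id`, `n_valid`, `m_mm`, `var_mm2`, `w`.
#' @export
summarize_spots <- function(shifts, value = "shift_wet_mm",
                            var_floor = 1e-4) {
  stopifnot(var_floor > 0)
  v <- rlang::sym(value)
  shifts |>
    group_by(.data$spot_id) |>
    summarise(
      n_total = dplyr::n(),
      n_valid = sum(.data$flag == "ok" & !is.na(!!v)),
      m_mm = median((!!v)[.data$flag == "ok"], na.rm = TRUE),
      var_mm2 = var((!!v)[.data$flag == "ok"], na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(
      ## a deliberate single-delivery run keeps its spots (variance hits
      ## the floor); with repeated deliveries at least two valid repeats
      ## are required, otherwise the spot is flagged out
      ok = .data$n_valid >= pmin(2L, .data$n_total) & .data$n_valid >= 1L,
      m_mm = ifelse(.data$ok, .data$m_mm, NA_real_),
      var_mm2 = dplyr::case_when(!.data$ok ~ NA_real_,
                                 .data$n_valid < 2 ~ 0,
                                 TRUE ~ .data$var_mm2),
      w = 1 / pmax(.data$var_mm2, var_floor)
    ) |>
    select(-"ok", -"n_total")
}

#' Inverse-variance weighted accuracy and precision of a scenario
#'
#' Implements the weighted scenario statistics: the weighted mean of the
#' per-spot medians
#' \deqn{\hat\mu = \sum_i w_i M_i / \sum_i w_i,}
#' the weighted variance
#' \deqn{\hat\sigma^2 = \frac{\sum_i w_i}{(\sum_i w_i)^2 - \sum_i w_i^2}
#'   \sum_i w_i (M_i - \hat\mu)^2,}
#' which reduces to the unbiased sample variance for equal weights, and the
#' accuracy \eqn{A = \hat\mu - G} against the ground truth G.
#'
#' @param summaries The [summarize_spots()] tibble (flagged-out spots are
#'   dropped).
#' @param g Ground-truth shift G (mm).
#' @return A one-row tibble: `n`, `mu_hat_mm`, `sigma2_hat_mm2`,
#'   `sigma_hat_mm`, `g_mm`, `accuracy_mm`.
#' @examples
#' s <- tibble::tibble(spot_id = 1:2, n_valid = 10,
#'                     m_mm = c(2, 4), var_mm2 = 1, w = 1)
#' weighted_stats(s, g = 0)  # mu 3, sigma2 2, A 3
#' @export
weighted_stats <- function(summaries, g) {
  s <- summaries[!is.na(summaries$m_mm) & !is.na(summaries$w), ]
  n <- nrow(s)
  if (n < 2) abort("need at least two valid spots for weighted statistics")
  sw <- sum(s$w); sw2 <- sum(s$w^2)
  mu <- sum(s$w * s$m_mm) / sw
  sigma2 <- sw / (sw^2 - sw2) * sum(s$w * (s$m_mm - mu)^2)
  tibble(n = n, mu_hat_mm = mu, sigma2_hat_mm2 = sigma2,
         sigma_hat_mm = sqrt(sigma2), g_mm = g, accuracy_mm = mu - g)
}

#' Boxplot statistics with the 1.5 IQR outlier rule
#'
#' Median, quartiles, whiskers at the most extreme values within 1.5 times
#' the interquartile range of the box, and the outliers beyond them -- the
#' convention of the per-scenario shift boxplots.
#'
#' @param values Numeric vector.
#' @return A list: `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `outliers`.
#' @export
iqr_box_stats <- function(values) {
  values <- values[!is.na(values)]
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  inside <- values >= q[1] - 1.5 * iqr & values <= q[3] + 1.5 * iqr
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = min(values[inside]), whisker_hi = max(values[inside]),
       outliers = sort(values[!inside]))
}
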