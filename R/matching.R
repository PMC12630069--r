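## Core least-squares translation fit.
##
## Finds the displacement t of `meas` relative to `ref` along +x
## (distal-positive): t minimizing sum over the window points xw of
## (meas(xw) - ref(xw - t))^2, where ref is linearly interpolated. Coarse
## grid search (`coarse` mm steps over +/- `search` mm, ties broken toward
## the smallest |t|), then either parabolic refinement through the three
## points around the minimum or a fine grid of step `fine`.
.lsq_shift <- function(x, ref, meas, win_x, search = 15, coarse = 0.1,
                       refine = c("parabola", "grid"), fine = 0.01,
                       domain = c("linear", "log")) {
  refine <- match.arg(refine)
  domain <- match.arg(domain)
  ## cubic-spline resampling of both curves: both are smooth detector
  ## responses, and linear interpolation of the sampled grid would bias
  ## off-node shifts
  rf <- stats::splinefun(x, ref, method = "natural")
  mf <- stats::splinefun(x, meas, method = "natural")
  wlo <- min(win_x); whi <- max(win_x)
  win_f <- seq(wlo, whi, length.out = max(4 * length(win_x), 40))
  mw <- mf(win_f)
  shifts <- seq(-search, search, by = coarse)
  if (domain == "log") {
    ## log domain: an amplitude factor becomes an additive offset, and
    ## multiplicative detector noise becomes additive and homoscedastic,
    ## so the noise contribution to the expected misfit is independent of
    ## the trial shift (no noise-induced bias of the minimum)
    eps <- 1e-6 * max(abs(mw))
    lmw <- log(pmax(mw, eps))
    scaled_ssd <- function(rv) {
      d <- log(pmax(rv, eps)) - lmw
      colSums(d^2) - colSums(d)^2 / length(lmw)
    }
  } else {
    ## linear domain: residual after fitting the optimal amplitude per
    ## trial shift, so that small normalization differences between the
    ## curves cannot masquerade as a translation. (A free baseline is
    ## deliberately NOT fitted: on the nearly monotone fall-off window an
    ## offset is almost collinear with a translation, and the extra
    ## degree of freedom amplifies counting noise. Baseline equality is
    ## instead ensured by the translation-equivariant background
    ## estimate of the profile preparation.)
    scaled_ssd <- function(rv) {
      num <- colSums(rv * mw)
      pmax(0, sum(mw^2) - num^2 / colSums(rv^2))
    }
  }
  rv <- matrix(rf(outer(win_f, shifts, "-")), nrow = length(win_f))
  ssd <- scaled_ssd(rv)
  best <- order(ssd, abs(shifts))[1]
  if (best == 1L || best == length(shifts)) {
    return(list(shift_mm = shifts[best], ssd = ssd[best], flag = "boundary"))
  }
  fs <- seq(shifts[best] - coarse, shifts[best] + coarse, by = fine)
  rv <- matrix(rf(outer(win_f, fs, "-")), nrow = length(win_f))
  fssd <- scaled_ssd(rv)
  fbest <- order(fssd, abs(fs))[1]
  t_hat <- fs[fbest]
  if (refine == "parabola" && fbest > 1 && fbest < length(fs)) {
    ## parabolic sub-grid refinement on the fine grid
    y3 <- fssd[(fbest - 1):(fbest + 1)]
    denom <- y3[1] - 2 * y3[2] + y3[3]
    if (denom > 0) t_hat <- t_hat + fine * 0.5 * (y3[1] - y3[3]) / denom
  }
  list(shift_mm = t_hat, ssd = ssd[best], flag = "ok")
}

## Distal crossing of `level` beyond index `from` on (x, y); linear
## interpolation. NA if the curve never crosses the level.
.distal_crossing <- function(x, y, level, from = which.max(y)) {
  n <- length(y)
  if (from >= n) return(NA_real_)
  idx <- seq(from, n)
  below <- which(y[idx] < level)
  if (!length(below)) return(NA_real_)
  j <- idx[below[1]]
  if (j == from) return(x[j])
  approx(c(y[j], y[j - 1]), c(x[j], x[j - 1]), xout = level,
         ties = "ordered")$y   # bracket ordered ascending in y
}

## Background-subtract and plateau-normalize a PGI profile. Background is
## the median over a fixed-length window starting bg_offset beyond the
## profile's own fall-off; anchoring the window on the fall-off (rather
## than running to the field-of-view edge) makes the preparation
## translation-equivariant, so any residual emission-tail leakage into
## the background estimate is identical for reference and measurement
## and cancels in the match. The plateau level is the profile maximum
## after subtraction (the prompt-gamma profile has no Bragg peak, so its
## maximum sits on the plateau).
.pgi_prep <- function(x, counts, bg_offset = 20, bg_len = 15) {
  x_half <- .distal_crossing(x, counts, min(counts) +
                               0.5 * (max(counts) - min(counts)))
  bg <- 0
  if (!is.na(x_half)) {
    tail_bins <- x > x_half + bg_offset & x <= x_half + bg_offset + bg_len
    if (sum(tail_bins) >= 3) bg <- median(counts[tail_bins])
  }
  p <- counts - bg
  if (max(p) <= 0) return(NULL)
  top <- mean(p[p >= 0.9 * max(p)])  # robust plateau level under noise
  p / top
}

#' PGI matching configuration
#'
#' @param window_hi,window_lo Fractions of the plateau level bounding the
#'   fall-off window on the reference profile.
#' @param search_mm Half-width of the shift search window (mm).
#' @param coarse_mm Coarse grid step (mm).
#' @param bg_offset_mm Distance beyond the fall-off from which the
#'   background is estimated (mm).
#' @return A list of matcher settings.
#' @export
pgi_match_config <- function(window_hi = 0.8, window_lo = 0.2,
                             search_mm = 15, coarse_mm = 0.1,
                             bg_offset_mm = 20) {
  list(window_hi = window_hi, window_lo = window_lo, search_mm = search_mm,
       coarse_mm = coarse_mm, bg_offset_mm = bg_offset_mm)
}

#' Least-squares fall-off match of two PGI profiles
#'
#' Both profiles are background-subtracted and normalized to their plateau
#' level; the fall-off window is defined on the reference as the region
#' between the distal crossings of `window_hi` and `window_lo` of the
#' plateau, then the measured profile is matched to the reference by a
#' least-squares translation fit (coarse 0.1 mm grid search, 0.01 mm fine
#' grid, parabolic sub-grid refinement).
#'
#' The returned shift is the raw displacement of the measured fall-off
#' along the beam axis: positive = distal (range increase). Pipelines
#' report the sign-flipped value (positive = range pullback / WET added);
#' see the package help page.
#'
#' @param x Common bin-center grid of both profiles (mm).
#' @param ref,meas Reference and measured count vectors on `x`.
#' @param cfg A [pgi_match_config()].
#' @return A list with `shift_mm`, `ssd`, and a `flag`: `"ok"`,
#'   `"no_falloff"` (no fall-off detected inside the grid), or
#'   `"boundary"` (fit at the search-window edge).
#' @export
match_profile_shift <- function(x, ref, meas, cfg = pgi_match_config()) {
  failed <- list(shift_mm = NA_real_, ssd = NA_real_, flag = "no_falloff")
  r <- .pgi_prep(x, ref, cfg$bg_offset_mm)
  m <- .pgi_prep(x, meas, cfg$bg_offset_mm)
  if (is.null(r) || is.null(m)) return(failed)
  x_hi <- .distal_crossing(x, r, cfg$window_hi)
  x_lo <- .distal_crossing(x, r, cfg$window_lo)
  ## require a usable fall-off window width; the core resamples it finely
  if (is.na(x_hi) || is.na(x_lo) || x_lo - x_hi < 2) return(failed)
  .lsq_shift(x, r, m, c(x_hi, x_lo), search = cfg$search_mm,
             coarse = cfg$coarse_mm, refine = "parabola")
}

#' RP matching configuration
#'
#' @param window_prox Fractional drop below the peak bounding the window on
#'   the proximal side (0.25 = window starts where the reference reaches
#'   75% of its peak, proximal of the peak).
#' @param window_dist Fraction of the peak at which the window ends on the
#'   distal side.
#' @param search_mm Half-width of the shift search (mm).
#' @param coarse_mm,fine_mm Coarse and fine grid steps (mm).
#' @return A list of matcher settings.
#' @export
rp_match_config <- function(window_prox = 0.25, window_dist = 0.10,
                            search_mm = 15, coarse_mm = 0.1,
                            fine_mm = 0.01) {
  list(window_prox = window_prox, window_dist = window_dist,
       search_mm = search_mm, coarse_mm = coarse_mm, fine_mm = fine_mm)
}

#' Least-squares alignment of two MLIC depth-dose curves
#'
#' Both curves are area-normalized; the matching window is anchored on the
#' distal edge of the reference curve, from the proximal `1 - window_prox`
#' peak-fraction crossing to the distal `window_dist` crossing, and the
#' optimal translation is found by a coarse 0.1 mm grid search refined on a
#' 0.01 mm grid. The least-squares misfit is evaluated in log-dose space
#' with a free offset absorbing any residual amplitude factor; under the
#' detector's multiplicative noise the log transform makes the noise
#' additive and homoscedastic, so it cannot bias the fitted shift.
#'
#' The reported shift is sign-flipped relative to the raw distal-positive
#' displacement of the measured curve, so that WET added upstream of the
#' detector (which reduces the residual range) appears as a positive
#' range shift -- the convention of all summary tables.
#'
#' @param ref,meas Reference and measured `idd_curves` dose vectors on the
#'   common channel grid, or single columns thereof.
#' @param depth_mm Channel-center depth grid (mm).
#' @param cfg An [rp_match_config()].
#' @return A list with `shift_wet_mm` (positive = WET added), `ssd`, and a
#'   `flag`: `"ok"`, `"clipped"` (peak or window at the detector
#'   boundary), or `"boundary"` (fit at the search edge).
#' @export
match_idd_shift <- function(ref, meas, depth_mm = mlic_depth_grid(),
                            cfg = rp_match_config()) {
  failed <- function(flag) list(shift_wet_mm = NA_real_, ssd = NA_real_,
                                flag = flag)
  if (anyNA(ref) || anyNA(meas)) return(failed("clipped"))
  r <- ref / sum(ref)
  m <- meas / sum(meas)
  pk <- which.max(r)
  if (pk <= 2 || pk >= length(r) - 2) return(failed("clipped"))
  ## proximal window bound: last crossing of (1 - window_prox) * peak
  ## before the peak
  lev_p <- (1 - cfg$window_prox) * r[pk]
  pre <- which(r[seq_len(pk)] < lev_p)
  if (!length(pre)) return(failed("clipped"))
  j <- max(pre)
  d_lo <- approx(r[j:(j + 1)], depth_mm[j:(j + 1)], xout = lev_p,
                 ties = "ordered")$y
  d_hi <- .distal_crossing(depth_mm, r, cfg$window_dist * r[pk], from = pk)
  if (is.na(d_hi)) return(failed("clipped"))
  win_x <- depth_mm[depth_mm >= d_lo & depth_mm <= d_hi]
  if (length(win_x) < 4) return(failed("clipped"))
  fit <- .lsq_shift(depth_mm, r, m, win_x, search = cfg$search_mm,
                    coarse = cfg$coarse_mm, refine = "grid",
                    fine = cfg$fine_mm, domain = "log")
  list(shift_wet_mm = -fit$shift_mm, ssd = fit$ssd, flag = fit$flag)
}
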