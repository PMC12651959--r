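#' Two-component baseline fraction profile
#'
#' Builds a discrete mRNA distribution over gradient fractions as a mixture of
#' a light (monosome-region) and a heavy (polysome-region) component, each a
#' Gaussian bump discretised at the integer fraction numbers. This is the
#' baseline shape used by [simulate_experiment()]: real sucrose-gradient
#' distributions of a single transcript typically show a monosome peak and a
#' polysome peak whose relative weight reflects translational engagement.
#'
#' @param n_fractions Number of collected fractions (default 20).
#' @param light_peak Fraction number of the light/monosome peak.
#' @param heavy_peak Fraction number of the heavy/polysome peak.
#' @param heavy_weight Mixing weight of the heavy component, in `[0, 1]`.
#' @param peak_width Standard deviation of each component, in fraction units.
#'
#' @return Numeric vector of length `n_fractions`, non-negative, summing to 1.
#' @examples
#' w <- bimodal_profile()
#' sum(w)
#' @export
bimodal_profile <- function(n_fractions = 20, light_peak = 5, heavy_peak = 12,
                            heavy_weight = 0.5, peak_width = 1.5) {
  stopifnot(n_fractions >= 2, heavy_weight >= 0, heavy_weight <= 1,
            peak_width > 0)
  f <- seq_len(n_fractions)
  w <- (1 - heavy_weight) * dnorm(f, light_peak, peak_width) +
    heavy_weight * dnorm(f, heavy_peak, peak_width)
  w / sum(w)
}

# signal-weighted mean fraction of a weight vector restricted to a window
window_fw <- function(weights, window) {
  idx <- window[1]:window[2]
  sum(idx * weights[idx]) / sum(weights[idx])
}

check_window <- function(window, n_fractions) {
  if (length(window) != 2 || anyNA(window) || window[1] > window[2] ||
      window[1] < 1 || window[2] > n_fractions) {
    abort(sprintf("`window` must be an increasing pair within 1..%d", n_fractions))
  }
  as.integer(window)
}

#' Shift a fraction profile toward heavier fractions by a target amount
#'
#' Deterministically reallocates mass within the analysis window so that the
#' window-restricted weighted mean fraction (F_W) of the returned profile
#' equals the input's F_W plus `delta`. For a positive `delta`, mass is moved
#' from the lightest occupied window fractions to the heaviest window fraction
#' (the final donor fraction is split fractionally, so the target is hit
#' exactly); a negative `delta` mirrors this toward the lightest window
#' fraction. Weights outside the window are untouched, and the total mass
#' inside the window is preserved, so percentage distributions remain
#' comparable.
#'
#' @param weights Non-negative weight vector indexed by fraction number.
#' @param delta Target change of the window F_W, in fraction units.
#' @param window Inclusive analysis window, length-2 integer vector.
#'
#' @return A weight vector of the same length whose window F_W equals the
#'   input F_W + `delta` (to ~1e-12).
#' @examples
#' w <- rep(0, 20); w[9] <- 1
#' apply_shift(w, 7, window = c(2, 16))  # all mass ends at fraction 16
#' @export
apply_shift <- function(weights, delta, window = c(2, 16)) {
  stopifnot(is.numeric(weights), is.numeric(delta), length(delta) == 1)
  window <- check_window(window, length(weights))
  if (any(weights < 0) || anyNA(weights)) {
    abort("`weights` must be non-negative and non-missing")
  }
  idx <- window[1]:window[2]
  if (sum(weights[idx]) <= 0) {
    abort("`weights` must carry positive mass inside the window")
  }
  w <- as.numeric(weights)
  total <- sum(w[idx])
  fw0 <- window_fw(w, window)
  target <- fw0 + delta
  tol <- 1e-9
  if (target > window[2] + tol || target < window[1] - tol) {
    abort(sprintf(
      "target F_W %.6g is outside the window [%d, %d]: shift unreachable",
      target, window[1], window[2]
    ))
  }
  if (delta == 0) return(w)
  if (delta > 0) {
    dest <- window[2]
    donors <- idx[idx < dest]            # lightest first
  } else {
    dest <- window[1]
    donors <- rev(idx[idx > dest])       # heaviest first
  }
  deficit <- abs(delta) * total          # mass x distance still to move
  for (a in donors) {
    if (w[a] <= 0) next
    gain <- w[a] * abs(dest - a)
    if (gain <= deficit) {
      w[dest] <- w[dest] + w[a]
      w[a] <- 0
      deficit <- deficit - gain
    } else {
      m <- deficit / abs(dest - a)
      w[a] <- w[a] - m
      w[dest] <- w[dest] + m
      deficit <- 0
      break
    }
    if (deficit <= 0) break
  }
  if (deficit > tol * total) {
    abort("shift unreachable: window mass exhausted before reaching target F_W")
  }
  w
}
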