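#' Discretised bone deposition front (height field)
#'
#' The growing bone domain is represented by a single-valued height field
#' x = h(y, t): for each lateral bin the position of the deposition front
#' along the main growth direction x. The lateral coordinate y is periodic
#' with period `L_y`. The default bin width (2.5 um) is well below the
#' secretion kernel width iota = 15 um.
#'
#' @param L_y Domain width, mm.
#' @param dy Requested bin width, mm; adjusted so that `L_y` is an integer
#'   number of bins.
#' @param h0 Initial front position (scalar or per-bin vector), mm.
#' @return Object of class `height_field` with fields `n_bins`, `dy`, `h`,
#'   `y` (bin centres), `L_y`, `t`.
#' @export
height_field <- function(L_y, dy = 2.5e-3, h0 = 0) {
  n_bins <- max(2L, as.integer(round(L_y / dy)))
  dy <- L_y / n_bins
  h <- rep_len(as.numeric(h0), n_bins)
  if (any(!is.finite(h)) || any(h < 0)) stop("h must be non-negative and finite")
  structure(list(n_bins = n_bins, dy = dy, h = h,
                 y = (seq_len(n_bins) - 0.5) * dy, L_y = L_y, t = 0),
            class = "height_field")
}

#' Apply one secretion event to the front
#'
#' Each secreting osteoblast at lateral position y adds a periodic-wrapped
#' Gaussian bump of standard deviation `iota` and peak height `eta * dt` to
#' the height field. The kernel is truncated at 5 iota and renormalised so
#' that each osteoblast deposits exactly `kappa_form * dt` of bone volume
#' (volume conservation holds exactly in discrete form).
#'
#' @param surface A `height_field`.
#' @param y_pos Lateral positions of the secreting osteoblasts, mm, in
#'   `[0, L_y)`.
#' @param dt Time step, day.
#' @param params A `bone_params` (supplies `eta`, `iota`).
#' @return The updated `height_field` (with `t` advanced by `dt`).
#' @export
deposit <- function(surface, y_pos, dt, params) {
  if (dt <= 0) stop("dt must be positive")
  n <- length(y_pos)
  if (n == 0) {
    surface$t <- surface$t + dt
    return(surface)
  }
  if (any(y_pos < 0 | y_pos >= surface$L_y)) stop("positions must lie in [0, L_y)")
  dy <- surface$dy
  nb <- surface$n_bins
  iota <- params$iota
  m <- ceiling(5 * iota / dy)
  offs <- -m:m
  i0 <- floor(y_pos / dy)                         # 0-based nearest-left bin
  # lateral distance from each osteoblast to candidate bin centres
  d <- outer(i0, offs, function(a, j) (a + j + 0.5) * dy) - y_pos
  w <- exp(-d^2 / (2 * iota^2))
  # renormalise: sum of weights must equal sqrt(2*pi)*iota/dy exactly so the
  # added volume is N * kappa_form * dt independent of sub-bin offsets
  w <- w * (sqrt(2 * pi) * iota / dy) / rowSums(w)
  idx <- (outer(i0, offs, `+`) %% nb) + 1L
  add <- rowsum(as.vector(params$eta * dt * w), as.vector(idx))
  h <- surface$h
  ii <- as.integer(rownames(add))
  h[ii] <- h[ii] + add[, 1]
  surface$h <- h
  surface$t <- surface$t + dt
  surface
}

#' Deposited bone volume
#'
#' @param surface A `height_field`.
#' @param L_z Projected slice thickness, mm.
#' @return Volume `L_z * sum(h) * dy`, mm^3.
#' @export
deposited_volume <- function(surface, L_z) {
  L_z * sum(surface$h) * surface$dy
}

#' Interpolated front position at lateral coordinate y
#'
#' Linear interpolation of the height field between adjacent bin centres,
#' periodic in y.
#'
#' @param surface A `height_field`.
#' @param y Lateral coordinates, mm (any real; wrapped into `[0, L_y)`).
#' @return Front positions x, mm.
#' @export
surface_x_at <- function(surface, y) {
  y <- y %% surface$L_y
  u <- y / surface$dy - 0.5
  i <- floor(u)
  frac <- u - i
  nb <- surface$n_bins
  i0 <- (as.integer(i) %% nb) + 1L
  i1 <- (as.integer(i + 1) %% nb) + 1L
  surface$h[i0] * (1 - frac) + surface$h[i1] * frac
}

#' Front speed from a surface time series
#'
#' Least-squares slope of the spatial mean front position against time.
#'
#' @param t Times, day (length >= 2).
#' @param h_mean Spatially averaged front positions, mm.
#' @return Front speed, mm/day.
#' @export
front_speed <- function(t, h_mean) {
  if (length(t) < 2 || length(t) != length(h_mean)) {
    stop("need >= 2 (t, h_mean) points")
  }
  tc <- t - mean(t)
  sum(tc * (h_mean - mean(h_mean))) / sum(tc^2)
}
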