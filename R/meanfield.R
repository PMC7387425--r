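#' Calibrate the degree-independent (null) model
#'
#' In the traveling-wave regime the osteocyte density generated at the front
#' is `q = D * p_bar / v_wave`, so the terminal differentiation rate follows
#' by inversion: `D_hat = q_target * v_wave / p_bar`. The dendrite growth
#' rate is then fixed by requiring a stationary mean osteoblast degree of 1:
#' the degree-gain rate is `c = alpha * q * L_z * pi * beta^2` (Gaussian
#' pairwise kernel integrated over the half-space of buried osteocytes at
#' projected density `q * L_z`), and for the null model the stationary mean
#' degree is `c / D_hat`, hence `alpha_hat = D_hat / (q_target * L_z * pi *
#' beta^2)`.
#'
#' @param q_target Target osteocyte number density, 1/mm^3.
#' @param p_bar Osteoblast surface density, 1/mm^2.
#' @param v_wave Front speed, mm/day.
#' @param beta Dendrite kernel width, mm.
#' @param L_z Projected thickness, mm.
#' @return List with `D_hat` and `alpha_hat` (1/day).
#' @examples
#' calibrate_null(2.375e4, 6e3, 6.560348e-4, 0.025, 0.04)
#' @export
calibrate_null <- function(q_target, p_bar, v_wave, beta, L_z) {
  args <- c(q_target = q_target, p_bar = p_bar, v_wave = v_wave,
            beta = beta, L_z = L_z)
  if (any(!is.finite(args)) || any(args <= 0)) {
    stop("all calibration inputs must be positive")
  }
  D_hat <- q_target * v_wave / p_bar
  list(D_hat = D_hat, alpha_hat = D_hat / (q_target * L_z * pi * beta^2))
}

#' Calibrate the switch model
#'
#' Fixes the network-independent rate `lambda_` and solves for the increment
#' `gamma` and dendrite growth rate `alpha` such that the traveling-wave
#' steady state reproduces the healthy targets: osteocyte density `q_target`
#' and mean osteoblast degree 1. With mean degree 1 the stationary osteoblast
#' degree distribution is geometric with `P(0) = 1/2`, so the
#' degree-weighted density balance gives `lambda_ + gamma/2 = D_hat` with
#' `D_hat = q_target * v_wave / p_bar`, i.e. `gamma = 2 * (D_hat -
#' lambda_)`. The required degree-gain rate is `c = lambda_ + gamma` (mean-1
#' geometric is stationary iff gain equals the removal rate of connected
#' osteoblasts), hence `alpha = (lambda_ + gamma) / (q_target * L_z * pi *
#' beta^2)`. `lambda_ < D_hat` yields an excitatory increment (gamma > 0),
#' `lambda_ > D_hat` an inhibitory one (gamma < 0).
#'
#' @param lambda_ Network-independent differentiation rate, 1/day.
#' @param q_target,p_bar,v_wave,beta,L_z As in [calibrate_null()].
#' @return List with `gamma`, `alpha`, `c` (the gain rate) and `D_hat`.
#' @examples
#' cal <- calibrate_null(2.375e4, 6e3, 6.560348e-4, 0.025, 0.04)
#' calibrate_switch(cal$D_hat / 2, 2.375e4, 6e3, 6.560348e-4, 0.025, 0.04)
#' @export
calibrate_switch <- function(lambda_, q_target, p_bar, v_wave, beta, L_z) {
  if (!is.finite(lambda_) || lambda_ <= 0) stop("lambda_ must be positive")
  nul <- calibrate_null(q_target, p_bar, v_wave, beta, L_z)
  gamma <- 2 * (nul$D_hat - lambda_)
  if (lambda_ + gamma < 0) {
    stop("calibration violates rate positivity: lambda_ + gamma = ",
         format(lambda_ + gamma), " < 0")
  }
  cc <- lambda_ + gamma
  list(gamma = gamma, alpha = cc / (q_target * L_z * pi * beta^2),
       c = cc, D_hat = nul$D_hat)
}

# stationary degree distribution of the gain-c / removal-D_k chain with
# re-injection at k = 0: v_k = v_{k-1} * c / (c + D_k), normalised
.stationary_pk <- function(c_gain, model, k_max) {
  if (c_gain <= 0) return(c(1, rep(0, k_max)))
  D <- diff_rate(model, 0:k_max)
  v <- numeric(k_max + 1)
  v[1] <- 1
  for (k in seq_len(k_max)) v[k + 1] <- v[k] * c_gain / (c_gain + D[k + 1])
  v / sum(v)
}

#' Traveling-wave steady state
#'
#' Solves the self-consistent fixed point of the mean-field theory in the
#' steadily advancing frame: the osteoblast degree-gain rate satisfies
#' `c = alpha * L_z * pi * beta^2 * q` with
#' `q = mean_rate(model, pk(c)) * p_bar / v_wave`, where `pk(c)` is the
#' stationary degree distribution of the gain-c / removal-D_k chain
#' (geometric for the null and switch models). Solved by damped fixed-point
#' iteration (damping 0.5, tolerance 1e-12, at most 1e4 iterations).
#'
#' @param params A validated `bone_params`.
#' @param model Optional `diff_model` overriding the one implied by
#'   `params`.
#' @param k_max Degree-space truncation (default 40 for the cumulative
#'   model, 25 otherwise).
#' @return Object of class `traveling_wave` with fields `q_bar` (1/mm^3),
#'   `v_wave` (mm/day), `k_ob`, `k_ot` (mean degrees), `M_bar` (dendrite
#'   density `q_bar * k_ot / 2`, 1/mm^3), `c` (gain rate, 1/day), `pk_ob`
#'   (osteoblast degree distribution) and the model.
#' @examples
#' steady_state(bone_params())  # q_bar ~ 2.375e4, k_ob ~ 1, k_ot ~ 2
#' @export
steady_state <- function(params, model = NULL, k_max = NULL) {
  viol <- validate_params(params)
  if (length(viol)) stop("invalid parameters: ", paste(viol, collapse = "; "))
  if (is.null(model)) model <- .model_from_params(params)
  if (is.null(k_max)) k_max <- if (model$name == "cumulative") 40L else 25L
  b <- .derive_basic(params)
  A <- params$alpha * b$c_coeff     # c = A * q
  pref <- params$p_bar / b$v_wave   # q = mean_rate * pref
  if (params$alpha == 0) {
    q <- model$lambda_ * pref
    pk <- c(1, rep(0, k_max))
    return(structure(list(q_bar = q, v_wave = b$v_wave, k_ob = 0, k_ot = 0,
                          M_bar = 0, c = 0, pk_ob = pk, model = model),
                     class = "traveling_wave"))
  }
  cc <- A * model$lambda_ * pref
  conv <- FALSE
  for (it in seq_len(1e4)) {
    pk <- .stationary_pk(cc, model, k_max)
    q <- mean_rate(model, pk) * pref
    c_new <- A * q
    if (abs(c_new - cc) <= 1e-12 * max(cc, 1e-300)) {
      cc <- c_new
      conv <- TRUE
      break
    }
    cc <- 0.5 * cc + 0.5 * c_new
  }
  if (!conv) stop("steady-state fixed point did not converge in 1e4 iterations")
  pk <- .stationary_pk(cc, model, k_max)
  q <- mean_rate(model, pk) * pref
  k_ob <- sum((0:k_max) * pk)
  k_ot <- 2 * cc * params$p_bar / (b$v_wave * q)
  structure(list(q_bar = q, v_wave = b$v_wave, k_ob = k_ob, k_ot = k_ot,
                 M_bar = q * k_ot / 2, c = cc, pk_ob = pk, model = model),
            class = "traveling_wave")
}

#' @export
print.traveling_wave <- function(x, ...) {
  cat(sprintf(
    paste0("Traveling-wave steady state (model '%s'):\n",
           "  q = %.4g /mm^3, v = %.4g um/day, <k>Ob = %.4g, <k>Ot = %.4g,",
           " M = %.4g /mm^3, c = %.4g /day\n"),
    x$model$name, x$q_bar, x$v_wave * 1e3, x$k_ob, x$k_ot, x$M_bar, x$c))
  invisible(x)
}

#' Stationary osteoblast degree distribution (geometric form)
#'
#' For the null and switch models the stationary osteoblast degree
#' distribution is geometric with ratio `s = c / (c + lambda_ + gamma)`
#' (for the null model `gamma = 0` and `lambda_` is the single rate D-hat):
#' `P(k) = (1 - s) s^k`. Other models have non-geometric stationary
#' distributions; request histograms from [transient_solve()] instead.
#'
#' @param summary A `traveling_wave` from [steady_state()].
#' @param k_max Length of the returned pmf minus one.
#' @return List with `s` (geometric ratio) and `pmf` (vector over
#'   k = 0..k_max, summing to 1 up to the truncated tail).
#' @export
degree_distribution <- function(summary, k_max = 50L) {
  model <- summary$model
  if (!model$name %in% c("null", "switch")) {
    stop("degree distribution is geometric only for the null and switch ",
         "models; use transient_solve() histograms for '", model$name, "'")
  }
  if (summary$c == 0) {
    return(list(s = 0, pmf = c(1, rep(0, k_max))))
  }
  rem <- model$lambda_ + if (model$name == "switch") model$gamma else 0
  s <- summary$c / (summary$c + rem)
  pmf <- (1 - s) * s^(0:k_max)
  list(s = s, pmf = pmf / sum(pmf))
}

#' Transient solution of the truncated degree hierarchy
#'
#' Integrates, in the frame of the advancing front `x_f(t) = v_wave * t`,
#' the coupled hierarchy for the surface densities `v_k(t)` of degree-k
#' osteoblasts,
#' `dv_k/dt = c(t) (v_{k-1} - v_k) - D_k v_k + R(t) [k = 0]`, with
#' `R(t) = sum_k D_k v_k` (burial rate; re-injection at degree 0 keeps
#' `sum_k v_k = p_bar` exactly), and for the osteocytes created at the front
#' at rate `R(t)` with the degree distribution of differentiating
#' osteoblasts. A buried cohort at depth `d` behind the front keeps gaining
#' degree at rate `g(d) = alpha * p_bar * L_z * sqrt(2*pi) * beta *
#' exp(-d^2/(2*beta^2))` (a Poisson thinning, so its degree distribution is
#' the burial distribution convolved with a Poisson of mean equal to the
#' integrated gain). The gain rate closes the loop through
#' `c(t) = alpha * L_z * sqrt(2*pi) * beta * integral q(x)
#' exp(-(x_f - x)^2/(2*beta^2)) dx` over the deposited region.
#'
#' Initial condition: `v_k(0) = p_bar [k = 0]`, no osteocytes (fresh cement
#' line). Explicit midpoint integration with adaptive sub-stepping keeps the
#' largest per-substep transition probability below 0.05; the truncation
#' tail is monitored and an error instructs a larger `k_max` if it grows
#' beyond `1e-6 * p_bar`.
#'
#' @param params A validated `bone_params`.
#' @param model Optional `diff_model` override.
#' @param k_max Degree truncation for osteoblasts (>= 10).
#' @param T Integration horizon, day (defaults to `params$T`).
#' @param dt_mf Base time step, day.
#' @param record_every Output thinning interval, day.
#' @return Object of class `hierarchy_solution`: `times`, `v` (matrix,
#'   time x degree), `k_ob_t`, `x` (cohort burial positions `v_wave *
#'   times`), `q_x` (osteocyte density profile, 1/mm^3), `w` (osteocyte
#'   degree distributions by cohort at the final time), `k_ot_x` (cohort
#'   mean final degrees), `R_t` (burial rate), `c_t` (gain rate), plus
#'   `v_wave` and the model.
#' @examples
#' \donttest{
#' hs <- transient_solve(bone_params(), T = 400)
#' range(hs$q_x)  # constant profile for the null model
#' }
#' @export
transient_solve <- function(params, model = NULL, k_max = 25L, T = params$T,
                            dt_mf = 0.1, record_every = 1) {
  viol <- validate_params(params)
  if (length(viol)) stop("invalid parameters: ", paste(viol, collapse = "; "))
  if (k_max < 10L) stop("k_max must be >= 10")
  if (is.null(model)) model <- .model_from_params(params)
  b <- .derive_basic(params)
  p_bar <- params$p_bar
  vw <- b$v_wave
  beta <- params$beta
  D <- diff_rate(model, 0:k_max)
  nsteps <- as.integer(round(T / dt_mf))
  every <- max(1L, as.integer(round(record_every / dt_mf)))

  # gain-rate kernel over burial-time lag: c_i = gcoef * sum_l K[l] * R[i-l] * dt
  gcoef <- params$alpha * params$L_z * sqrt(2 * pi) * beta
  lag_max <- min(nsteps, as.integer(ceiling(5 * beta / (vw * dt_mf))))
  K <- exp(-((seq_len(lag_max) - 0.5) * vw * dt_mf)^2 / (2 * beta^2))

  v <- c(p_bar, rep(0, k_max))
  R_hist <- numeric(nsteps)
  c_hist <- numeric(nsteps)
  nrec <- nsteps %/% every
  times <- numeric(nrec)
  v_rec <- matrix(0, nrec, k_max + 1)
  mean0_rec <- numeric(nrec)  # mean degree at burial, per recorded cohort
  d0_rec <- matrix(0, nrec, k_max + 1)
  r <- 0L

  deriv <- function(v, cc) {
    R <- sum(D * v)
    gain_out <- cc * v
    gain_out[k_max + 1] <- 0  # no flux past the truncation (conservative)
    dv <- c(0, gain_out[1:k_max]) - gain_out - D * v
    dv[1] <- dv[1] + R
    list(dv = dv, R = R)
  }

  for (i in seq_len(nsteps)) {
    nl <- min(i - 1L, lag_max)
    cc <- if (nl > 0) {
      gcoef * dt_mf * sum(K[seq_len(nl)] * R_hist[i - seq_len(nl)])
    } else 0
    # adaptive sub-stepping: keep max total per-substep probability < 0.05
    rate_max <- cc + max(D)
    nsub <- max(1L, as.integer(ceiling(rate_max * dt_mf / 0.05)))
    h <- dt_mf / nsub
    for (s in seq_len(nsub)) {
      d1 <- deriv(v, cc)
      d2 <- deriv(v + 0.5 * h * d1$dv, cc)
      v <- v + h * d2$dv
    }
    fin <- deriv(v, cc)
    R_hist[i] <- fin$R
    c_hist[i] <- cc
    if (v[k_max + 1] > 1e-6 * p_bar) {
      stop("degree-truncation tail mass v_kmax = ", format(v[k_max + 1]),
           " exceeds 1e-6 * p_bar; increase k_max")
    }
    if (i %% every == 0L) {
      r <- r + 1L
      times[r] <- i * dt_mf
      v_rec[r, ] <- v
      d0 <- D * v
      d0 <- if (sum(d0) > 0) d0 / sum(d0) else c(1, rep(0, k_max))
      d0_rec[r, ] <- d0
      mean0_rec[r] <- sum((0:k_max) * d0)
    }
  }

  # post-burial Poisson gain for each recorded cohort, integrated to time T:
  # G = alpha * p_bar * L_z * 2*pi*beta^2 * (Phi(d_max/beta) - 1/2) / v_wave
  d_end <- vw * (T - times)
  G <- params$alpha * p_bar * params$L_z * 2 * pi * beta^2 *
    (stats::pnorm(d_end / beta) - 0.5) / vw
  kot_max <- k_max + as.integer(ceiling(max(G) + 10 * sqrt(max(G, 1))))
  w <- matrix(0, nrec, kot_max + 1)
  for (r in seq_len(nrec)) {
    pois <- stats::dpois(0:(kot_max - k_max), G[r])
    w[r, ] <- pmax(stats::convolve(d0_rec[r, ], rev(pois), type = "open"), 0)
  }
  R_rec <- R_hist[seq_len(nsteps) %% every == 0L]
  q_x <- R_rec / vw

  structure(list(
    times = times, v = v_rec, k_ob_t = as.vector(v_rec %*% (0:k_max)) / p_bar,
    x = vw * times, q_x = q_x, w = w,
    k_ot_x = mean0_rec + G, R_t = R_rec,
    c_t = c_hist[seq_len(nsteps) %% every == 0L],
    v_wave = vw, k_max = k_max, model = model, params = params
  ), class = "hierarchy_solution")
}

#' @export
print.hierarchy_solution <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf(
    paste0("Hierarchy solution to t = %g d (%d records, k_max = %d):\n",
           "  final q = %.4g /mm^3, <k>Ob = %.4g, earliest-cohort <k>Ot = %.4g\n"),
    x$times[n], n, x$k_max, x$q_x[n], x$k_ob_t[n], x$k_ot_x[1]))
  invisible(x)
}
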