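#' Network and density observables
#'
#' Computes the standard observables on a simulation trajectory (or a raw
#' state): the time-averaged mean osteoblast degree, and for the osteocytes
#' buried inside the time window the mean degree, the number density and the
#' dendrite density `M = q * k_ot / 2`.
#'
#' For a trajectory, the osteocyte density is `count / (L_y * L_z * dx)`
#' where `dx` is the front advance across the window (window attribution is
#' by burial time, matching the mean-field's front-generated density). For a
#' raw state the whole deposited volume is used, so the window must cover
#' the full history for `q` to be meaningful.
#'
#' Osteocyte degrees are taken from the final state: osteocytes buried close
#' to the end of the run are still gaining connections, so for final-degree
#' statistics end the window at least ~`4*beta/v_wave` days (about 150 d at
#' defaults) before the end of the run.
#'
#' @param x An `abm_trajectory` or `abm_state`.
#' @param window Length-2 numeric, burial-time window in days.
#' @return Object of class `network_summary`: `k_ob_mean`, `k_ot_mean`, `q`
#'   (1/mm^3), `M` (1/mm^3), `n_osteocytes`, degree histograms `hist_ob`,
#'   `hist_ot`, and the window.
#' @export
network_summary <- function(x, window = c(0, Inf)) {
  if (inherits(x, "abm_trajectory")) {
    s <- x$summary
    w <- c(max(window[1], 0), min(window[2], max(s$t)))
    if (w[2] <= w[1]) stop("empty window")
    in_w <- s$t >= w[1] & s$t <= w[2]
    if (!any(in_w)) stop("empty window")
    k_ob <- mean(s$k_ob_mean[in_w])
    st <- x$final_state
    h_at <- function(tt) {
      if (tt <= 0) return(0)
      stats::approx(c(0, s$t), c(0, s$h_mean), xout = tt, rule = 2)$y
    }
    dx <- h_at(w[2]) - h_at(w[1])
    params <- x$params
    vol <- params$L_y * params$L_z * dx
    hist_ob <- tabulate(st$ob$degree + 1L)
  } else if (inherits(x, "abm_state")) {
    st <- x
    w <- c(max(window[1], 0), min(window[2], st$t))
    k_ob <- mean(st$ob$degree)
    vol <- deposited_volume(st$surface, st$L_z)
    hist_ob <- tabulate(st$ob$degree + 1L)
  } else {
    stop("x must be an abm_trajectory or abm_state")
  }
  sel <- st$ot$buried_t >= w[1] & st$ot$buried_t <= w[2]
  n_ot <- sum(sel)
  degs <- st$ot$degree[sel]
  k_ot <- if (n_ot) mean(degs) else 0
  q <- if (vol > 0) n_ot / vol else 0
  structure(list(
    k_ob_mean = k_ob, k_ot_mean = k_ot, q = q, M = q * k_ot / 2,
    n_osteocytes = n_ot, hist_ob = hist_ob,
    hist_ot = if (n_ot) tabulate(degs + 1L) else integer(0),
    window = w
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Network summary over [%g, %g] d: <k>Ob = %.3g, <k>Ot = %.3g, ",
           "q = %.4g /mm^3, M = %.4g /mm^3 (%d osteocytes)\n"),
    x$window[1], x$window[2], x$k_ob_mean, x$k_ot_mean, x$q, x$M,
    x$n_osteocytes))
  invisible(x)
}

#' Fraction of osteoblasts buried per depth of growth
#'
#' In the steady regime the probability that a given osteoblast terminally
#' differentiates while the front advances by `depth` is
#' `1 - exp(-D * depth / v_wave)`. At the calibrated healthy rates and a
#' 5 um depth this is about 1 in 50.
#'
#' @param D Terminal differentiation rate, 1/day.
#' @param v_wave Front speed, mm/day.
#' @param depth Depth of growth, mm.
#' @return List with `fraction` and its reciprocal `one_in`.
#' @examples
#' burial_fraction(2.5968e-3, 6.5603e-4, 5e-3)
#' @export
burial_fraction <- function(D, v_wave, depth) {
  if (D < 0 || v_wave <= 0 || depth < 0) stop("inputs must be positive")
  f <- 1 - exp(-D * depth / v_wave)
  list(fraction = f, one_in = if (f > 0) 1 / f else Inf)
}

#' Parameter-sensitivity sign table
#'
#' For the calibrated switch model (excitatory: `lambda_` at half the null
#' differentiation rate; inhibitory: 1.5 times it), perturbs one parameter
#' at a time by `factor` (no recalibration), recomputes the traveling-wave
#' steady state, and records the sign of the relative change of each of
#' `q`, `v_wave`, `k_ob`, `k_ot` and `M` with a 0.5% dead-band (changes
#' smaller than the dead-band count as invariant, "-").
#'
#' `gamma` may be negative; "increasing" it means increasing the signed
#' value by the same relative magnitude, `gamma + (factor - 1) * |gamma|`
#' (equal to `gamma * factor` when positive). Scaling the magnitude of a
#' negative `gamma` instead would flip the predicted density response and is
#' degenerate at factor 1.5 for the inhibitory calibration.
#'
#' @param base_params A `bone_params` carrying the general (non-calibrated)
#'   parameters; its model fields are ignored.
#' @param model_config `"excitatory"` or `"inhibitory"`.
#' @param factor Perturbation factor (> 1).
#' @param dead_band Relative dead-band for the "no change" call.
#' @return Object of class `sensitivity_report`: a data.frame with one row
#'   per perturbed parameter (`eta`, `p_bar`, `kappa_diff`, `lambda_`,
#'   `gamma`, `alpha`) and sign columns `q`, `v`, `k_ob`, `k_ot`, `M`, each
#'   in `{"up", "down", "-"}`.
#' @export
sensitivity_table <- function(base_params, model_config = c("excitatory", "inhibitory"),
                              factor = 1.5, dead_band = 5e-3) {
  model_config <- match.arg(model_config)
  if (factor <= 1) stop("factor must be > 1")
  b <- .derive_basic(base_params)
  nul <- calibrate_null(base_params$q_target, base_params$p_bar, b$v_wave,
                        base_params$beta, base_params$L_z)
  lam <- if (model_config == "excitatory") nul$D_hat / 2 else 3 * nul$D_hat / 2
  cal <- calibrate_switch(lam, base_params$q_target, base_params$p_bar,
                          b$v_wave, base_params$beta, base_params$L_z)
  params <- base_params
  params$model_name <- "switch"
  params$lambda_ <- lam
  params$gamma <- cal$gamma
  params$alpha <- cal$alpha

  obs <- function(p) {
    sw <- steady_state(p)
    c(q = sw$q_bar, v = sw$v_wave, k_ob = sw$k_ob, k_ot = sw$k_ot, M = sw$M_bar)
  }
  base <- obs(params)
  rows <- c("eta", "p_bar", "kappa_diff", "lambda_", "gamma", "alpha")
  out <- data.frame(parameter = rows, q = NA, v = NA, k_ob = NA, k_ot = NA,
                    M = NA, stringsAsFactors = FALSE)
  for (i in seq_along(rows)) {
    p2 <- params
    f <- rows[i]
    p2[[f]] <- if (f == "gamma") p2$gamma + (factor - 1) * abs(p2$gamma)
               else p2[[f]] * factor
    viol <- validate_params(p2)
    if (length(viol)) {
      stop("perturbation of ", f, " violates rate positivity: ",
           paste(viol, collapse = "; "))
    }
    rel <- obs(p2) / base - 1
    out[i, 2:6] <- ifelse(abs(rel) < dead_band, "-",
                          ifelse(rel > 0, "up", "down"))
  }
  structure(out, class = c("sensitivity_report", "data.frame"),
            model_config = model_config, factor = factor)
}

#' @export
print.sensitivity_report <- function(x, ...) {
  arrows <- function(v) ifelse(v == "up", "↑", ifelse(v == "down", "↓", "−"))
  df <- as.data.frame(x)
  df[2:6] <- lapply(df[2:6], arrows)
  cat(sprintf("Sensitivity signs (%s switch configuration, factor %g):\n",
              attr(x, "model_config"), attr(x, "factor")))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Compare simulation statistics against the mean-field steady state
#'
#' Computes z-scores of the steady-window simulated `q`, `k_ob`, `k_ot` and
#' front speed against the traveling-wave reference, using the across-seed
#' standard error when several trajectories are given (or within-run
#' block/Poisson errors for a single trajectory). The steady window must
#' span at least 180 simulated days. Osteocyte degrees are only compared
#' for cohorts buried at least `kot_margin` days before the end of the run
#' (later cohorts are still gaining connections).
#'
#' @param trajectories An `abm_trajectory`, a list of them (one per seed),
#'   or a data.frame of per-seed statistics with columns `q`, `k_ob`,
#'   `k_ot`, `v_wave`.
#' @param summary A `traveling_wave` reference from [steady_state()].
#' @param window Steady time window, days.
#' @param kot_margin Days excluded at the end of the window for osteocyte
#'   degrees.
#' @return Data.frame with columns `stat`, `sim`, `ref`, `se`, `z`, `pass`
#'   (|z| < 3).
#' @export
compare_sim_meanfield <- function(trajectories, summary, window = c(365, Inf),
                                  kot_margin = 200) {
  if (inherits(trajectories, "abm_trajectory")) trajectories <- list(trajectories)
  if (is.data.frame(trajectories)) {
    per <- trajectories
  } else {
    per <- do.call(rbind, lapply(trajectories, function(tr) {
      Tend <- max(tr$summary$t)
      w <- c(window[1], min(window[2], Tend))
      if (w[2] - w[1] < 180) stop("steady window must span >= 180 days")
      ns <- network_summary(tr, w)
      nk <- network_summary(tr, c(w[1], max(w[1] + 1, w[2] - kot_margin)))
      data.frame(q = ns$q, k_ob = ns$k_ob_mean, k_ot = nk$k_ot_mean,
                 v_wave = front_speed(tr$summary$t, tr$summary$h_mean),
                 n_ot = ns$n_osteocytes, n_kot = nk$n_osteocytes)
    }))
  }
  refs <- c(q = summary$q_bar, k_ob = summary$k_ob, k_ot = summary$k_ot,
            v_wave = summary$v_wave)
  n <- nrow(per)
  out <- lapply(names(refs), function(stat) {
    vals <- per[[stat]]
    m <- mean(vals)
    se <- if (n >= 2) {
      stats::sd(vals) / sqrt(n)
    } else if (stat == "q" && !is.null(per$n_ot)) {
      m / sqrt(max(per$n_ot, 1))
    } else if (stat == "k_ot" && !is.null(per$n_kot)) {
      m / sqrt(max(per$n_kot, 1))
    } else {
      abs(m) * 0.05
    }
    dev <- m - refs[[stat]]
    z <- if (se > 0) dev / se else if (abs(dev) <= 1e-9 * abs(refs[[stat]])) 0 else sign(dev) * Inf
    data.frame(stat = stat, sim = m, ref = refs[[stat]], se = se, z = z,
               pass = abs(z) < 3)
  })
  do.call(rbind, out)
}

#' Goodness of fit of osteoblast degrees to the geometric law
#'
#' Pools the recorded osteoblast degree snapshots inside the window and
#' tests them against a geometric distribution (ratio estimated from the
#' pooled mean, `s = m / (1 + m)`) with a chi-squared statistic. Because an
#' osteoblast's degree decorrelates only on the burial timescale, daily
#' snapshots of the same cell are far from independent: the statistic is
#' computed at an effective sample size equal to the number of distinct
#' osteoblasts observed in the window, not the raw pooled count (which must
#' still be at least `min_pool`).
#'
#' @param traj An `abm_trajectory`.
#' @param window Time window, days.
#' @param min_pool Minimum raw pooled observation count.
#' @return List of class `gof_geometric`: `statistic`, `df`, `p_value`,
#'   `s_hat`, `n_pooled`, `n_eff`.
#' @export
gof_geometric_degrees <- function(traj, window = c(365, Inf), min_pool = 5000) {
  s <- traj$summary
  rows <- which(s$t >= window[1] & s$t <= window[2])
  if (!length(rows)) stop("empty window")
  degs <- as.vector(traj$snap_degrees[rows, , drop = FALSE])
  n_pool <- length(degs)
  if (n_pool < min_pool) {
    stop("only ", n_pool, " pooled observations; need >= ", min_pool)
  }
  n_eff <- length(unique(as.vector(traj$snap_ids[rows, , drop = FALSE])))
  m <- mean(degs)
  s_hat <- m / (1 + m)
  obs <- tabulate(degs + 1L, nbins = max(degs) + 1L) * (n_eff / n_pool)
  expd <- n_eff * (1 - s_hat) * s_hat^(0:(length(obs) - 1))
  # merge the tail so every expected count is >= 5
  keep <- which(cumsum(rev(expd)) >= 5)
  cut <- length(expd) - (if (length(keep)) keep[1] else length(expd)) + 1L
  cut <- max(cut, 2L)
  o <- c(obs[seq_len(cut - 1)], sum(obs[cut:length(obs)]))
  e <- c(expd[seq_len(cut - 1)], n_eff - sum(expd[seq_len(cut - 1)]))
  stat <- sum((o - e)^2 / e)
  df <- length(o) - 2L
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 s_hat = s_hat, n_pooled = n_pool, n_eff = n_eff),
            class = "gof_geometric")
}

#' @export
print.gof_geometric <- function(x, ...) {
  cat(sprintf(
    "Geometric GOF: X2 = %.3g on %d df, p = %.3g (s = %.3g; %d obs, n_eff = %d)\n",
    x$statistic, x$df, x$p_value, x$s_hat, x$n_pooled, x$n_eff))
  invisible(x)
}
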