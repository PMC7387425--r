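#' Initialise an agent-based simulation state
#'
#' Starting condition: flat surface at x = 0 (fresh cement line, no
#' pre-existing network), `n_osteoblasts = round(p_bar * L_y * L_z)`
#' degree-0 osteoblasts at uniform-random lateral positions, no osteocytes
#' and no edges. Seeds the RNG from `params$seed`.
#'
#' @param params A validated `bone_params`.
#' @return Object of class `abm_state` with fields `t`, `surface`
#'   (`height_field`), `ob` (osteoblast vectors: `id`, `y`, `degree`,
#'   `born_t`), `ot` (osteocyte vectors: `id`, `x`, `y`, `buried_t`,
#'   `degree`), `edges` (`src`, `dst`, `t`), `next_id`, and cumulative event
#'   `counters`.
#' @export
abm_init <- function(params) {
  viol <- validate_params(params)
  if (length(viol)) stop("invalid parameters: ", paste(viol, collapse = "; "))
  set.seed(params$seed)
  b <- .derive_basic(params)
  n <- b$n_osteoblasts
  structure(list(
    t = 0,
    surface = height_field(params$L_y),
    ob = list(id = seq_len(n), y = stats::runif(n, 0, params$L_y),
              degree = integer(n), born_t = numeric(n)),
    ot = list(id = integer(0), x = numeric(0), y = numeric(0),
              buried_t = numeric(0), degree = integer(0)),
    edges = list(src = integer(0), dst = integer(0), t = numeric(0)),
    next_id = n + 1L,
    counters = c(connections = 0L, burials = 0L),
    model = .model_from_params(params),
    derived = b,
    L_z = params$L_z
  ), class = "abm_state")
}

#' Advance the simulation by one fixed time step
#'
#' Event order within a step: (iv) lateral diffusion of disconnected
#' (degree-0) osteoblasts, y <- y + Normal(0, 2*kappa_diff*dt) wrapped
#' periodically; (iii) dendrite growth, each osteoblast-osteocyte pair
#' connects with probability `1 - exp(-alpha * exp(-r^2/(2*beta^2)) * dt)`
#' where r is the Euclidean distance in the projected (x, y) plane from the
#' osteoblast's surface position to the osteocyte; (ii) terminal
#' differentiation, each osteoblast buries with probability
#' `1 - exp(-D_k * dt)`, becoming an osteocyte at its current surface
#' position and retaining all its edges, and (v) is immediately replaced by
#' a new degree-0 osteoblast at the same lateral position (constant
#' osteoblast count); (i) bone secretion via [deposit()]. Connection
#' candidates are restricted to osteocytes within 4*beta of the front
#' (kernel tail mass < 4e-4).
#'
#' A stability precondition requires every single-event probability per step
#' to stay below 0.05; violating rates raise an error naming the rate.
#'
#' @param state An `abm_state`.
#' @param params The `bone_params` used to create it.
#' @param dt Time step, day (defaults to `params$dt`).
#' @return The advanced `abm_state`.
#' @export
abm_step <- function(state, params, dt = params$dt) {
  dm <- state$model
  beta <- params$beta
  L_y <- params$L_y
  ob <- state$ob
  ot <- state$ot
  n <- length(ob$id)
  t_new <- state$t + dt

  # stability bound: max single-event probability per step < 0.05
  if (params$alpha * dt >= 0.05) {
    stop("stability bound violated: connection rate alpha*dt = ",
         format(params$alpha * dt), " >= 0.05")
  }
  dmax <- diff_rate(dm, max(ob$degree))
  if (dmax * dt >= 0.05) {
    stop("stability bound violated: differentiation rate D_k*dt = ",
         format(dmax * dt), " >= 0.05")
  }

  # (iv) migration of disconnected pre-osteoblasts
  mig <- which(ob$degree == 0L)
  if (length(mig)) {
    ob$y[mig] <- (ob$y[mig] +
      stats::rnorm(length(mig), 0, sqrt(2 * params$kappa_diff * dt))) %% L_y
  }
  surf_x <- surface_x_at(state$surface, ob$y)

  # (iii) dendrite growth: pairwise Gaussian-kernel connection events
  if (length(ot$id) && params$alpha > 0) {
    act <- which(ot$x >= min(state$surface$h) - 4 * beta)
    if (length(act)) {
      dx <- outer(ot$x[act], surf_x, `-`)
      dyv <- abs(outer(ot$y[act], ob$y, `-`))
      dyv <- pmin(dyv, L_y - dyv)
      pcon <- 1 - exp(-params$alpha * exp(-(dx^2 + dyv^2) / (2 * beta^2)) * dt)
      hit <- which(matrix(stats::runif(length(pcon)), nrow(pcon)) < pcon,
                   arr.ind = TRUE)
      if (nrow(hit)) {
        oti <- act[hit[, 1]]
        obi <- hit[, 2]
        state$edges$src <- c(state$edges$src, ob$id[obi])
        state$edges$dst <- c(state$edges$dst, ot$id[oti])
        state$edges$t <- c(state$edges$t, rep(t_new, nrow(hit)))
        ob$degree <- ob$degree + tabulate(obi, n)
        ot$degree <- ot$degree + tabulate(oti, length(ot$id))
        state$counters["connections"] <- state$counters["connections"] + nrow(hit)
      }
    }
  }

  # (ii) terminal differentiation + (v) one-for-one replacement
  pdiff <- 1 - exp(-diff_rate(dm, ob$degree) * dt)
  bury <- which(stats::runif(n) < pdiff)
  if (length(bury)) {
    ot$id <- c(ot$id, ob$id[bury])
    ot$x <- c(ot$x, surf_x[bury])
    ot$y <- c(ot$y, ob$y[bury])
    ot$buried_t <- c(ot$buried_t, rep(t_new, length(bury)))
    ot$degree <- c(ot$degree, ob$degree[bury])
    ob$id[bury] <- state$next_id + seq_along(bury) - 1L
    state$next_id <- state$next_id + length(bury)
    ob$degree[bury] <- 0L
    ob$born_t[bury] <- t_new
    state$counters["burials"] <- state$counters["burials"] + length(bury)
  }

  # (i) bone secretion by all surface osteoblasts
  state$surface <- deposit(state$surface, ob$y, dt, params)

  state$ob <- ob
  state$ot <- ot
  state$t <- t_new
  state
}

#' Run a full simulation
#'
#' Executes `round(T/dt)` fixed time steps from the standard initial
#' condition and records per-interval summaries: time, mean front position,
#' osteocyte and edge counts, mean osteoblast degree, cumulative event
#' counts, plus per-snapshot osteoblast ids and degrees (used for degree
#' histograms and goodness-of-fit tests). Reproducible given
#' `params$seed`.
#'
#' @param params A validated `bone_params`.
#' @param record_every Recording interval, day; must be a multiple of `dt`.
#' @param record_surface If `TRUE`, keep a copy of the height field at each
#'   recording time (list `surfaces`).
#' @return Object of class `abm_trajectory` with `summary` (data.frame),
#'   `snap_ids` / `snap_degrees` (matrices, one row per record),
#'   `final_state`, `params`, `derived`.
#' @examples
#' \donttest{
#' tr <- abm_run(bone_params(T = 30, seed = 1))
#' tail(tr$summary, 3)
#' }
#' @export
abm_run <- function(params, record_every = 1, record_surface = FALSE) {
  state <- abm_init(params)
  dt <- params$dt
  nsteps <- as.integer(round(params$T / dt))
  every <- as.integer(round(record_every / dt))
  if (abs(every * dt - record_every) > 1e-9) {
    stop("record_every must be a multiple of dt")
  }
  nrec <- nsteps %/% every
  n <- length(state$ob$id)
  summ <- data.frame(t = numeric(nrec), h_mean = numeric(nrec),
                     n_osteocytes = integer(nrec), n_edges = integer(nrec),
                     k_ob_mean = numeric(nrec), connections = integer(nrec),
                     burials = integer(nrec))
  snap_ids <- matrix(0L, nrec, n)
  snap_degs <- matrix(0L, nrec, n)
  surfaces <- if (record_surface) vector("list", nrec) else NULL
  r <- 0L
  for (s in seq_len(nsteps)) {
    state <- abm_step(state, params, dt)
    if (s %% every == 0L) {
      r <- r + 1L
      summ$t[r] <- state$t
      summ$h_mean[r] <- mean(state$surface$h)
      summ$n_osteocytes[r] <- length(state$ot$id)
      summ$n_edges[r] <- length(state$edges$src)
      summ$k_ob_mean[r] <- mean(state$ob$degree)
      summ$connections[r] <- state$counters["connections"]
      summ$burials[r] <- state$counters["burials"]
      snap_ids[r, ] <- state$ob$id
      snap_degs[r, ] <- state$ob$degree
      if (record_surface) surfaces[[r]] <- state$surface
    }
  }
  structure(list(summary = summ, snap_ids = snap_ids, snap_degrees = snap_degs,
                 surfaces = surfaces, final_state = state, params = params,
                 derived = state$derived),
            class = "abm_trajectory")
}

#' @export
print.abm_state <- function(x, ...) {
  cat(sprintf(
    "ABM state at t = %g d: %d osteoblasts, %d osteocytes, %d edges, <h> = %.4g mm\n",
    x$t, length(x$ob$id), length(x$ot$id), length(x$edges$src),
    mean(x$surface$h)))
  invisible(x)
}

#' @export
print.abm_trajectory <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "ABM trajectory: %d records to t = %g d; final: %d osteocytes, %d edges\n",
    nrow(s), s$t[nrow(s)], s$n_osteocytes[nrow(s)], s$n_edges[nrow(s)]))
  invisible(x)
}
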