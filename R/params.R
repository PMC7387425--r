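#' Model parameters for osteocyte network formation
#'
#' Constructs and validates the full parameter set of the bone-growth model.
#' All lengths are in mm, all times in days; micrometres appear only in
#' reporting. Defaults are the healthy-bone literature values; the three
#' model-dependent rates (`lambda_`, `gamma`, `alpha`) default to the
#' calibrated values for the selected differentiation model (null model:
#' `lambda_` plays the role of the degree-independent rate D-hat and
#' `gamma = 0`; switch model: the excitatory configuration with
#' `lambda_` equal to half the null rate).
#'
#' @param eta Per-osteoblast secretion-rate amplitude (peak normal speed of
#'   the secretion bump), mm/day.
#' @param iota Secretion kernel width (Gaussian s.d. in the lateral
#'   coordinate), mm.
#' @param beta Dendrite connection kernel width (Gaussian s.d. in pairwise
#'   distance), mm.
#' @param alpha Dendrite growth scale: peak pairwise connection rate, 1/day.
#'   `NULL` selects the calibrated value for `model_name`.
#' @param kappa_diff Surface diffusion constant of disconnected
#'   pre-osteoblasts, mm^2/day.
#' @param L_y Lateral domain width (periodic), mm.
#' @param L_z Projected slice thickness (typical osteocyte spacing), mm.
#' @param p_bar Osteoblast surface density, 1/mm^2.
#' @param lambda_ Network-independent differentiation rate, 1/day. `NULL`
#'   selects the calibrated value for `model_name`.
#' @param gamma Network-dependent differentiation increment, 1/day; may be
#'   negative (inhibitory). `NULL` selects the calibrated value.
#' @param model_name One of `"null"`, `"switch"`, `"cumulative"`,
#'   `"diminishing"`.
#' @param dt Simulation time step, day.
#' @param T Simulation horizon, day.
#' @param seed RNG seed (integer).
#' @param q_target Healthy osteocyte number density used for default
#'   calibration, 1/mm^3.
#'
#' @return An object of class `bone_params` (named list of the above).
#' @examples
#' p <- bone_params()
#' derive_constants(p)$v_wave * 1e3  # front speed in um/day, ~0.656
#' @export
bone_params <- function(eta = 7.27e-5,
                        iota = 15e-3,
                        beta = 25e-3,
                        alpha = NULL,
                        kappa_diff = 4.5e-5,
                        L_y = 0.5,
                        L_z = 0.04,
                        p_bar = 6e3,
                        lambda_ = NULL,
                        gamma = NULL,
                        model_name = "null",
                        dt = 0.25,
                        T = 730,
                        seed = 1L,
                        q_target = 2.375e4) {
  model_name <- match.arg(model_name, c("null", "switch", "cumulative", "diminishing"))
  # closed-form healthy calibration used only to fill unspecified rate defaults
  kform <- sqrt(2 * pi) * eta * iota * L_z
  v_wave <- kform * p_bar
  D_hat <- q_target * v_wave / p_bar
  ccoef <- L_z * pi * beta^2
  if (model_name == "null") {
    if (is.null(lambda_)) lambda_ <- D_hat
    if (is.null(gamma)) gamma <- 0
    if (is.null(alpha)) alpha <- D_hat / (q_target * ccoef)
  } else if (model_name == "switch") {
    if (is.null(lambda_)) lambda_ <- D_hat / 2
    if (is.null(gamma)) gamma <- 2 * (D_hat - lambda_)
    if (is.null(alpha)) alpha <- (lambda_ + gamma) / (q_target * ccoef)
  } else {
    if (is.null(lambda_) || is.null(gamma) || is.null(alpha)) {
      stop("lambda_, gamma and alpha must be given explicitly for the '",
           model_name, "' model (no printed calibration exists)")
    }
  }
  p <- structure(list(
    eta = eta, iota = iota, beta = beta, alpha = alpha,
    kappa_diff = kappa_diff, L_y = L_y, L_z = L_z, p_bar = p_bar,
    lambda_ = lambda_, gamma = gamma, model_name = model_name,
    dt = dt, T = T, seed = as.integer(seed), q_target = q_target
  ), class = "bone_params")
  viol <- validate_params(p)
  if (length(viol)) stop("invalid parameters: ", paste(viol, collapse = "; "))
  p
}

#' Validate a parameter set
#'
#' Reporting operation: returns a character vector of violated constraints
#' (empty when the parameter set is valid). Checked constraints: all lengths,
#' rates and densities non-negative (`gamma` may be negative); positivity of
#' the differentiation rate for every degree (`lambda_ > 0` and
#' `lambda_ + f(k) >= 0` for all k >= 1 under the selected model);
#' `dt > 0` and `T >= dt`.
#'
#' @param params A `bone_params` object (or a plain named list with the same
#'   fields).
#' @return Character vector of violations, empty iff valid.
#' @export
validate_params <- function(params) {
  v <- character(0)
  nn <- c("eta", "iota", "beta", "alpha", "kappa_diff",
          "L_y", "L_z", "p_bar", "q_target")
  for (f in nn) {
    x <- params[[f]]
    if (is.null(x) || !is.finite(x) || x < 0) v <- c(v, paste0(f, ">=0"))
  }
  for (f in c("L_y", "L_z", "p_bar", "eta", "iota", "beta")) {
    x <- params[[f]]
    if (!is.null(x) && is.finite(x) && x == 0) v <- c(v, paste0(f, ">0"))
  }
  if (!is.finite(params$lambda_) || params$lambda_ <= 0) v <- c(v, "lambda_>0")
  if (!is.finite(params$gamma)) v <- c(v, "gamma finite")
  # lambda + f(k) >= 0 for all k >= 1 (prevents negative differentiation rates)
  if (is.finite(params$lambda_) && is.finite(params$gamma)) {
    lam <- params$lambda_; gam <- params$gamma
    bad <- switch(params$model_name,
      null = FALSE,
      switch = lam + gam < 0,      # f(k) = gamma for all k >= 1
      cumulative = gam < 0,        # f(k) = gamma*k fails at large k
      diminishing = lam + gam < 0  # f(k) = gamma/k, worst case k = 1
    )
    if (isTRUE(bad)) v <- c(v, "lambda_+f(k)<0")
  }
  if (!is.finite(params$dt) || params$dt <= 0) v <- c(v, "dt>0")
  if (!is.finite(params$T) || params$T < params$dt) v <- c(v, "T>=dt")
  v
}

# kinematic constants that do not require solving the steady state
.derive_basic <- function(params) {
  kappa_form <- sqrt(2 * pi) * params$eta * params$iota * params$L_z
  v_wave <- kappa_form * params$p_bar
  list(
    kappa_form = kappa_form,                       # mm^3/day per osteoblast
    v_wave = v_wave,                               # mm/day
    n_osteoblasts = max(1L, as.integer(round(params$p_bar * params$L_y * params$L_z))),
    c_coeff = params$L_z * pi * params$beta^2      # mm^3; gain rate c = alpha*q*c_coeff
  )
}

#' Derive kinematic and network constants from parameters
#'
#' Computes the per-osteoblast volumetric deposition rate
#' `kappa_form = sqrt(2*pi) * eta * iota * L_z` (the integral of the Gaussian
#' secretion bump over the lateral coordinate times the slice thickness), the
#' steady front speed `v_wave = kappa_form * p_bar`, the integer agent count
#' `n_osteoblasts = round(p_bar * L_y * L_z)`, the connection-gain coefficient
#' `c_coeff = L_z * pi * beta^2` (so the osteoblast degree-gain rate is
#' `c = alpha * q * c_coeff`), and the projected osteocyte areal density
#' `sigma_ot_target = q * L_z` at the model's own traveling-wave steady state.
#'
#' @param params A validated `bone_params` object.
#' @return An object of class `derived_constants` with fields `kappa_form`
#'   (mm^3/day), `v_wave` (mm/day), `n_osteoblasts`, `c_coeff` (mm^3),
#'   `sigma_ot_target` (1/mm^2).
#' @examples
#' dc <- derive_constants(bone_params())
#' dc$kappa_form  # ~1.093e-7 mm^3/day
#' @export
derive_constants <- function(params) {
  viol <- validate_params(params)
  if (length(viol)) stop("invalid parameters: ", paste(viol, collapse = "; "))
  b <- .derive_basic(params)
  sw <- steady_state(params)
  structure(c(b, list(sigma_ot_target = sw$q_bar * params$L_z)),
            class = "derived_constants")
}

#' @export
print.bone_params <- function(x, ...) {
  cat("Bone formation model parameters (mm, day):\n")
  flds <- setdiff(names(x), "model_name")
  for (f in flds) cat(sprintf("  %-11s %g\n", f, x[[f]]))
  cat(sprintf("  %-11s %s\n", "model_name", x$model_name))
  invisible(x)
}

.param_fields <- c("eta", "iota", "beta", "alpha", "kappa_diff", "L_y", "L_z",
                   "p_bar", "lambda_", "gamma", "model_name", "dt", "T",
                   "seed", "q_target")

#' Read model parameters from a flat key/value config file
#'
#' The config is a DCF (`key: value`) document whose keys are named exactly
#' as the `bone_params` fields. Unspecified keys take the defaults (including
#' model-dependent calibrated rates); unknown keys are an error. An example
#' config ships in `system.file("extdata", "healthy_null.dcf",
#' package = "osteonet")`.
#'
#' @param path Path to the config file.
#' @return A validated `bone_params` object.
#' @seealso [write_config()]
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  m <- read.dcf(path)
  if (nrow(m) == 0) return(bone_params())
  if (nrow(m) != 1) stop("config must contain exactly one record: ", path)
  keys <- colnames(m)
  unknown <- setdiff(keys, .param_fields)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  args <- list()
  for (k in keys) {
    val <- m[1, k]
    args[[k]] <- if (k == "model_name") as.character(val) else as.numeric(val)
  }
  do.call(bone_params, args)
}

#' Write model parameters to a flat key/value config file
#'
#' @param params A `bone_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  vals <- vapply(.param_fields, function(f) {
    if (f == "model_name") params[[f]] else format(params[[f]], digits = 17)
  }, character(1))
  m <- matrix(vals, nrow = 1, dimnames = list(NULL, .param_fields))
  write.dcf(m, file = path)
  invisible(path)
}
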