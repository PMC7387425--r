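#' Degree-dependent osteoblast terminal-differentiation models
#'
#' Builds the rate family D_k giving the probability per unit time that a
#' surface osteoblast with k network connections terminally differentiates
#' into an osteocyte. The shipped forms are
#' \describe{
#'   \item{null}{D_k = lambda_ for all k (degree-independent; `lambda_`
#'     plays the role of the single rate D-hat and `gamma` is unused).}
#'   \item{switch}{D_0 = lambda_, D_k = lambda_ + gamma for k >= 1
#'     (any connection flips the switch; gamma > 0 excitatory,
#'     gamma < 0 inhibitory).}
#'   \item{cumulative}{D_0 = lambda_, D_k = lambda_ + gamma*k (contribution
#'     proportional to the number of connections).}
#'   \item{diminishing}{D_0 = lambda_, D_k = lambda_ + gamma/k.}
#'   \item{custom}{D_0 = lambda_, D_k = lambda_ + f(k) for a user-supplied
#'     vectorised function `f`.}
#' }
#' Rates must be non-negative for every k; this is checked at evaluation.
#'
#' @param name Model name; one of `"null"`, `"switch"`, `"cumulative"`,
#'   `"diminishing"`, `"custom"`.
#' @param lambda_ Base (network-independent) rate, 1/day; must be positive.
#' @param gamma Network contribution scale, 1/day; may be negative.
#' @param f For `name = "custom"`, a vectorised function of k (k >= 1)
#'   returning the network contribution, 1/day.
#' @return Object of class `diff_model`.
#' @examples
#' m <- differentiation_model("switch", lambda_ = 1.295e-3, gamma = 2.59e-3)
#' diff_rate(m, 0:3)
#' @export
differentiation_model <- function(name, lambda_, gamma = 0, f = NULL) {
  name <- match.arg(name, c("null", "switch", "cumulative", "diminishing", "custom"))
  if (!is.finite(lambda_) || lambda_ <= 0) stop("lambda_ must be positive")
  if (name == "custom") {
    if (!is.function(f)) stop("custom model requires a function f(k)")
  } else if (!is.finite(gamma)) stop("gamma must be finite")
  structure(list(name = name, lambda_ = lambda_, gamma = gamma, f = f),
            class = "diff_model")
}

# internal: model from a bone_params object
.model_from_params <- function(params) {
  differentiation_model(params$model_name, params$lambda_, params$gamma)
}

#' Differentiation rate at degree k
#'
#' @param model A `diff_model`.
#' @param k Vector of non-negative integer degrees.
#' @return Rates in 1/day, one per element of `k`.
#' @export
diff_rate <- function(model, k) {
  if (any(k < 0) || any(k != floor(k))) stop("k must be non-negative integers")
  lam <- model$lambda_
  gam <- model$gamma
  r <- switch(model$name,
    null = rep(lam, length(k)),
    switch = ifelse(k == 0, lam, lam + gam),
    cumulative = ifelse(k == 0, lam, lam + gam * k),
    diminishing = ifelse(k == 0, lam, lam + gam / k),
    custom = ifelse(k == 0, lam, lam + ifelse(k >= 1, model$f(pmax(k, 1)), 0))
  )
  if (any(r < 0)) {
    stop("negative differentiation rate at k = ",
         paste(k[r < 0], collapse = ","), " (model '", model$name, "')")
  }
  r
}

#' Mean differentiation rate under a degree distribution
#'
#' Computes `sum_k D_k P(k)`, the population mean rate that enters the
#' osteocyte-density balance at the deposition front.
#'
#' @param model A `diff_model`.
#' @param pk Probability vector over k = 0, 1, ..., length(pk) - 1; must sum
#'   to 1 within 1e-9.
#' @return Mean rate, 1/day.
#' @export
mean_rate <- function(model, pk) {
  if (abs(sum(pk) - 1) > 1e-9) {
    stop("degree distribution does not sum to 1 (got ", format(sum(pk)), ")")
  }
  if (any(pk < 0)) stop("degree distribution has negative mass")
  sum(diff_rate(model, seq_along(pk) - 1L) * pk)
}

#' @export
print.diff_model <- function(x, ...) {
  cat(sprintf("Differentiation model '%s': lambda = %g /day, gamma = %g /day\n",
              x$name, x$lambda_, x$gamma))
  invisible(x)
}
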