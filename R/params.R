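# ClaDS scalar parameters and the lognormal rate-inheritance kernel.
#
# The process starts with a birth rate lambda0 at the crown. At every birth
# event the two daughter lineages draw new birth rates
#   log(lambda_child) ~ Normal(log(alpha_lambda * lambda_parent), sigma_lambda^2).
# Death rates follow one of three modes:
#   turnover  — mu = epsilon * lambda on every lineage (ClaDS2-style);
#   lognormal — mu inherited like lambda, with mu0, alpha_mu, sigma_mu;
#   none      — mu = 0 everywhere (ClaDS0, pure birth).
# rho is the probability that an extant species is sampled at present.

PARAM_NAMES <- c("lambda0", "alpha_lambda", "sigma_lambda",
                 "epsilon", "mu0", "alpha_mu", "sigma_mu", "rho")

#' ClaDS model parameters
#'
#' Bundles the scalar parameters of the ClaDS birth-death process together
#' with the set of parameters the inference estimates. The constructor
#' enforces the identifiability rule: at least one of `rho`, `lambda0`, and
#' the death-rate anchor (`epsilon` in turnover mode, `mu0` in lognormal
#' mode) must be fixed. With `death_mode = "none"` the death rate is
#' structurally fixed at zero, which satisfies the rule.
#'
#' @param lambda0 birth rate at the root (per unit time, > 0).
#' @param alpha_lambda birth-rate trend at splits (> 0; values < 1 shrink
#'   rates toward the tips, > 1 inflate them).
#' @param sigma_lambda log-scale standard deviation of the birth-rate
#'   inheritance kernel (>= 0; 0 degenerates to deterministic inheritance).
#' @param death_mode `"turnover"`, `"lognormal"` or `"none"`.
#' @param epsilon turnover mu/lambda, constant across lineages (turnover
#'   mode only).
#' @param mu0,alpha_mu,sigma_mu death-rate analogues of
#'   `lambda0`/`alpha_lambda`/`sigma_lambda` (lognormal mode only).
#' @param rho extant sampling probability in (0, 1].
#' @param estimate character vector naming the parameters the MCMC should
#'   estimate; everything else is fixed.
#' @return an object of class `clads_params`.
#' @examples
#' p <- clads_params(lambda0 = 0.14, alpha_lambda = 0.69, sigma_lambda = 0.9,
#'                   death_mode = "turnover", epsilon = 0.61, rho = 0.98,
#'                   estimate = c("lambda0", "alpha_lambda", "sigma_lambda",
#'                                "epsilon"))
#' @export
clads_params <- function(lambda0 = 0.1, alpha_lambda = 1, sigma_lambda = 0,
                         death_mode = c("turnover", "lognormal", "none"),
                         epsilon = 0, mu0 = 0, alpha_mu = 1, sigma_mu = 0,
                         rho = 1, estimate = character()) {
  death_mode <- match.arg(death_mode)
  stopifnot(lambda0 > 0, alpha_lambda > 0, sigma_lambda >= 0,
            rho > 0, rho <= 1)
  if (death_mode == "turnover") stopifnot(epsilon >= 0)
  if (death_mode == "lognormal")
    stopifnot(mu0 > 0, alpha_mu > 0, sigma_mu >= 0)
  bad <- setdiff(estimate, PARAM_NAMES)
  if (length(bad)) stop("unknown parameters in `estimate`: ",
                        paste(bad, collapse = ", "))
  p <- structure(
    list(lambda0 = lambda0, alpha_lambda = alpha_lambda,
         sigma_lambda = sigma_lambda, death_mode = death_mode,
         epsilon = epsilon, mu0 = mu0, alpha_mu = alpha_mu,
         sigma_mu = sigma_mu, rho = rho, estimate = estimate),
    class = "clads_params")
  check_identifiability(p)
  p
}

#' @export
print.clads_params <- function(x, ...) {
  cat(sprintf(
    "clads_params: lambda0=%.4g alpha_lambda=%.4g sigma_lambda=%.4g\n",
    x$lambda0, x$alpha_lambda, x$sigma_lambda))
  cat(switch(x$death_mode,
    turnover = sprintf("  death: turnover, epsilon=%.4g\n", x$epsilon),
    lognormal = sprintf("  death: lognormal, mu0=%.4g alpha_mu=%.4g sigma_mu=%.4g\n",
                        x$mu0, x$alpha_mu, x$sigma_mu),
    none = "  death: none (pure birth)\n"))
  cat(sprintf("  rho=%.4g; estimated: %s\n", x$rho,
              if (length(x$estimate)) paste(x$estimate, collapse = ", ")
              else "(none)"))
  invisible(x)
}

check_identifiability <- function(params) {
  est <- params$estimate
  fixed <- function(nm) !(nm %in% est)
  death_anchor_fixed <- switch(params$death_mode,
    turnover = fixed("epsilon"),
    lognormal = fixed("mu0"),
    none = TRUE)
  if (!(fixed("rho") || fixed("lambda0") || death_anchor_fixed))
    stop("identifiability: at least one of rho, lambda0, and mu0 or epsilon ",
         "has to be fixed")
  invisible(params)
}

# effective death rate at the root, by mode
root_rates <- function(params) {
  mu <- switch(params$death_mode,
               turnover = params$epsilon * params$lambda0,
               lognormal = params$mu0,
               none = 0)
  c(birth = params$lambda0, death = mu)
}

#' Mean rate variation at birth
#'
#' The expected multiplicative change in birth rate across a speciation
#' event, `m = alpha * exp(sigma^2 / 2)` (the mean of the inheritance
#' lognormal relative to the parent rate). Values above 1 indicate a trend
#' of increasing rates from the root toward the tips.
#'
#' @param alpha trend parameter (> 0).
#' @param sigma log-scale standard deviation (>= 0).
#' @return `alpha * exp(sigma^2 / 2)`.
#' @examples
#' mean_rate_variation(0.69, 0.90)  # ~1.03: slight increasing trend
#' @export
mean_rate_variation <- function(alpha, sigma) {
  stopifnot(alpha > 0, sigma >= 0)
  alpha * exp(sigma^2 / 2)
}

#' Lognormal inheritance log-density
#'
#' Log-density of a child rate under the ClaDS inheritance kernel: lognormal
#' with log-location `log(alpha * parent_rate)` and log-scale `sigma`.
#' `sigma = 0` is a point mass, not a density, and is rejected here; callers
#' treat that case as a hard constraint.
#'
#' @param child_rate,parent_rate positive rates.
#' @param alpha trend parameter.
#' @param sigma log-scale standard deviation (> 0).
#' @return the log-density (vectorised over rates).
#' @export
inheritance_log_density <- function(child_rate, parent_rate, alpha, sigma) {
  if (sigma <= 0)
    stop("sigma = 0 is a point mass; treat as a constraint, not a density")
  if (any(child_rate <= 0) || any(parent_rate <= 0))
    stop("rates must be positive")
  stats::dlnorm(child_rate, meanlog = log(alpha * parent_rate),
                sdlog = sigma, log = TRUE)
}

# tolerance for the sigma = 0 deterministic-inheritance constraint
.SIGMA0_TOL <- 1e-12

# log-density (or constraint check) of drawing rates (lam, mu) from
# ancestral rates under `params`; returns -Inf on constraint violation.
# Vectorised over lam/mu.
rate_draw_log_density <- function(lam, mu, anc_birth, anc_death, params) {
  if (params$sigma_lambda > 0) {
    ll <- sum(stats::dlnorm(lam, log(params$alpha_lambda * anc_birth),
                            params$sigma_lambda, log = TRUE))
  } else {
    target <- params$alpha_lambda * anc_birth
    if (any(abs(lam - target) > .SIGMA0_TOL * pmax(target, 1)))
      return(-Inf)
    ll <- 0
  }
  if (params$death_mode == "lognormal") {
    if (params$sigma_mu > 0) {
      ll <- ll + sum(stats::dlnorm(mu, log(params$alpha_mu * anc_death),
                                   params$sigma_mu, log = TRUE))
    } else {
      target <- params$alpha_mu * anc_death
      if (any(abs(mu - target) > .SIGMA0_TOL * pmax(target, 1)))
        return(-Inf)
    }
  }
  ll
}

# draw n (lam, mu) pairs from the inheritance kernel
draw_rates <- function(n, anc_birth, anc_death, params) {
  lam <- if (params$sigma_lambda > 0)
    stats::rlnorm(n, log(params$alpha_lambda * anc_birth),
                  params$sigma_lambda)
  else rep(params$alpha_lambda * anc_birth, n)
  mu <- switch(params$death_mode,
    turnover = params$epsilon * lam,
    lognormal = if (params$sigma_mu > 0)
        stats::rlnorm(n, log(params$alpha_mu * anc_death), params$sigma_mu)
      else rep(params$alpha_mu * anc_death, n),
    none = rep(0, n))
  list(birth = lam, death = mu)
}

#' Sample daughter rates at a birth event
#'
#' Draws the two daughter lineages' birth (and death) rates from the parent
#' rates under the ClaDS inheritance kernel. Uses R's global random number
#' stream; seed with [set.seed()] for reproducibility.
#'
#' @param parent named vector `c(birth =, death =)` of parent rates.
#' @param params a [clads_params()] object.
#' @return list of two named rate vectors, one per daughter.
#' @examples
#' p <- clads_params(sigma_lambda = 0, alpha_lambda = 0.9,
#'                   death_mode = "none")
#' sample_child_rates(c(birth = 0.1, death = 0), p)  # both daughters 0.09
#' @export
sample_child_rates <- function(parent, params) {
  if (parent[["birth"]] <= 0) stop("parent birth rate must be positive")
  d <- draw_rates(2L, parent[["birth"]], parent[["death"]], params)
  list(c(birth = d$birth[1L], death = d$death[1L]),
       c(birth = d$birth[2L], death = d$death[2L]))
}
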