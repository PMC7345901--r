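#' Random-energy model of a binding interface
#'
#' In a random-energy picture of antibody-antigen binding, an interface of
#' `r` noncovalent bonds with per-bond coupling-energy fluctuation
#' `delta_e2` has Gaussian-distributed binding free energy with mean
#' `mean_dg` and variance `r * delta_e2`. A progenitor with `r = 0` bonds
#' is degenerate: its probability of interaction is zero everywhere except
#' at the mean.
#'
#' @param r Number of noncovalent bonds, integer >= 0.
#' @param delta_e2 Per-bond coupling-energy fluctuation variance, > 0.
#' @param mean_dg Centre of the energy distribution.
#' @return An object of class `random_energy_model`.
#' @examples
#' m <- random_energy_model(r = 3, delta_e2 = 0.5)
#' energy_pdf(m, 0)
#' @export
random_energy_model <- function(r, delta_e2, mean_dg = 0) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r < 0) {
    stop("`r` must be a single value >= 0")
  }
  if (!is.numeric(delta_e2) || length(delta_e2) != 1L ||
      !is.finite(delta_e2) || delta_e2 <= 0) {
    stop("`delta_e2` must be a single value > 0")
  }
  structure(list(r = r, delta_e2 = delta_e2, mean_dg = mean_dg),
            class = "random_energy_model")
}

#' Gaussian density of binding free energy under a random-energy model
#'
#' @param model A [random_energy_model].
#' @param dg Energy value(s) at which to evaluate the density.
#' @return The normal density with mean `mean_dg` and variance
#'   `r * delta_e2`. For the degenerate `r = 0` model the density is 0 at
#'   every `dg != mean_dg` (and `Inf` at the mean), with a warning flagging
#'   the degenerate case.
#' @export
energy_pdf <- function(model, dg) {
  stopifnot(inherits(model, "random_energy_model"))
  if (model$r == 0) {
    warning("degenerate model: r = 0 bonds, zero interaction probability")
    return(ifelse(dg == model$mean_dg, Inf, 0))
  }
  dnorm(dg, mean = model$mean_dg, sd = sqrt(model$r * model$delta_e2))
}

#' Double-Pareto model of system equilibrium constants
#'
#' The distribution of the system equilibrium constant K_sys that results
#' from exponential sampling of random-energy Gaussians: the number of
#' bonds (hence the Gaussian variance of the dimensionless log-affinity) is
#' itself exponentially distributed with rate `lam`, with per-unit-`r`
#' variance `2/lam`. The resulting log-affinity is Laplace(0, 1/lam), i.e.
#' K_sys follows a symmetric double-Pareto (log-Laplace) law whose upper
#' tail decays as `k^-(1+lam)`: the power-law degree exponent of the
#' antibody network is `lam + 1`.
#'
#' @param lam Exponential rate of decrease of antigen availabilities, > 0.
#' @return An object of class `double_pareto_model`.
#' @examples
#' m <- double_pareto_model(1.618034)
#' ksys_pdf_closed(m, c(0.5, 1, 10))
#' @export
double_pareto_model <- function(lam) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0) {
    stop("`lam` must be a single value > 0")
  }
  structure(list(lam = lam), class = "double_pareto_model")
}

as_dp_model <- function(model) {
  if (inherits(model, "double_pareto_model")) return(model)
  double_pareto_model(model)
}

#' Sample system equilibrium constants
#'
#' Draws from the exponential-sampling construction: for each draw the bond
#' count `r ~ Exponential(rate = lam)`, then the dimensionless log-affinity
#' `x | r ~ Normal(0, variance = r * 2/lam)`, and `K_sys = exp(x)`.
#' Marginally `log(K_sys)` is Laplace(0, scale 1/lam), so the sample median
#' is 1 and half the mass lies above 1.
#'
#' @param model A [double_pareto_model] (or a rate `lam`).
#' @param n Number of draws, >= 1.
#' @param seed Optional integer seed. When supplied, the draw is
#'   reproducible and the caller's RNG state is left untouched.
#' @return Numeric vector of `n` positive K_sys values.
#' @examples
#' k <- sample_ksys(double_pareto_model(2), 1000, seed = 1)
#' median(k) # ~1
#' @export
sample_ksys <- function(model, n, seed = NULL) {
  model <- as_dp_model(model)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1) {
    stop("`n` must be >= 1")
  }
  n <- as.integer(n)
  with_seed(seed, {
    r <- rexp(n, rate = model$lam)
    x <- rnorm(n, mean = 0, sd = sqrt(2 * r / model$lam))
    exp(x)
  })
}

#' Closed-form double-Pareto density of K_sys
#'
#' `f(k) = (lam/2) * k^(-1-lam)` for `k >= 1` and
#' `f(k) = (lam/2) * k^(lam-1)` for `0 < k < 1` (the symmetric lower
#' branch of the double-Pareto law). The density integrates to 1 with mass
#' 1/2 on each side of the mode at k = 1.
#'
#' @inheritParams sample_ksys
#' @param k Positive K_sys value(s).
#' @return Density value(s).
#' @export
ksys_pdf_closed <- function(model, k) {
  model <- as_dp_model(model)
  if (!is.numeric(k) || any(!is.finite(k)) || any(k <= 0)) {
    stop("`k` must be finite and > 0")
  }
  lam <- model$lam
  ifelse(k >= 1, lam / 2 * k^(-1 - lam), lam / 2 * k^(lam - 1))
}

#' Closed-form double-Pareto distribution function of K_sys
#'
#' @inheritParams ksys_pdf_closed
#' @return `P(K_sys <= k)`.
#' @export
ksys_cdf_closed <- function(model, k) {
  model <- as_dp_model(model)
  if (!is.numeric(k) || any(!is.finite(k)) || any(k <= 0)) {
    stop("`k` must be finite and > 0")
  }
  lam <- model$lam
  ifelse(k >= 1, 1 - 0.5 * k^(-lam), 0.5 * k^lam)
}

#' Double-Pareto density by quadrature over the bond-count mixture
#'
#' Evaluates the mixture integral directly: the density of K_sys is
#' `integral over r of  lam * exp(-lam r) * LogNormal(k; 0, r * 2/lam) dr`,
#' computed by adaptive quadrature. Agrees with [ksys_pdf_closed] to high
#' relative accuracy; provided as an independent route to the same law.
#'
#' @inheritParams ksys_pdf_closed
#' @param rel_tol Relative tolerance passed to [stats::integrate].
#' @return Density value(s).
#' @export
ksys_pdf_quadrature <- function(model, k, rel_tol = 1e-10) {
  model <- as_dp_model(model)
  if (!is.numeric(k) || any(!is.finite(k)) || any(k <= 0)) {
    stop("`k` must be finite and > 0")
  }
  lam <- model$lam
  vapply(k, function(kk) {
    res <- tryCatch(
      integrate(
        function(r) lam * exp(-lam * r) * dlnorm(kk, 0, sqrt(2 * r / lam)),
        lower = 0, upper = Inf, rel.tol = rel_tol, abs.tol = 0,
        subdivisions = 500L
      ),
      error = function(e) {
        stop("quadrature failed at k = ", kk, ": ", conditionMessage(e))
      }
    )
    res$value
  }, numeric(1))
}

#' Hill (maximum-likelihood Pareto) tail-exponent estimate
#'
#' Fits the exponent of a power-law tail `f(v) ~ v^-alpha` to the sample
#' values above a cutoff, using the continuous-Pareto maximum-likelihood
#' (Hill) estimator `alpha = 1 + n / sum(log(v_i / k_min))` with asymptotic
#' standard error `(alpha - 1)/sqrt(n)`.
#'
#' @param values Positive sample values.
#' @param k_min Lower cutoff; only values strictly above it enter the fit.
#'   Defaults to the sample minimum (so a constant sample is rejected as
#'   having no tail).
#' @return An object of class `tail_fit` with fields `alpha`, `k_min`,
#'   `n_tail` and `stderr`.
#' @examples
#' v <- 1 / runif(1000)^(1 / 1.5) # Pareto, alpha = 2.5
#' fit_tail_exponent(v, k_min = 1)
#' @export
fit_tail_exponent <- function(values, k_min = min(values)) {
  if (!is.numeric(values) || length(values) == 0L) {
    stop("`values` must be a non-empty numeric vector")
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("`values` must be finite and > 0")
  }
  tail <- values[values > k_min]
  n <- length(tail)
  if (n < 10L) {
    stop("insufficient data: need at least 10 values above k_min, got ", n)
  }
  s <- sum(log(tail / k_min))
  if (!is.finite(s) || s <= 0) stop("zero log-spread above k_min")
  alpha <- 1 + n / s
  structure(
    list(alpha = alpha, k_min = k_min, n_tail = n,
         stderr = (alpha - 1) / sqrt(n)),
    class = "tail_fit"
  )
}

#' @export
print.tail_fit <- function(x, ...) {
  cat(sprintf("tail_fit: alpha = %.4f (se %.4f), k_min = %g, n_tail = %d\n",
              x$alpha, x$stderr, x$k_min, x$n_tail))
  invisible(x)
}
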