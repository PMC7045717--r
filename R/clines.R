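#' Geographic cline models
#'
#' Sigmoid allele-frequency clines along a one-dimensional transect: a
#' central tanh sigmoid of width `w` (inverse of the maximum slope) around
#' centre `c`, optional independent exponential tails starting `deltaL` /
#' `deltaR` away from the centre with steepness `tauL` / `tauR`, and free
#' scaling between minimum and maximum frequencies `pmin`, `pmax`. This is
#' the Szymura-Barton tail family used throughout hybrid-zone analysis.
#'
#' @param centre cline centre c (km)
#' @param width cline width w > 0 (km)
#' @param pmin,pmax frequency bounds in \[0, 1\], `pmin <= pmax`
#' @param deltaL,deltaR tail start distances >= 0 (km)
#' @param tauL,tauR tail steepness parameters in \[0, 1\]
#' @param increasing if FALSE the cline decreases with x (mirror image)
#' @param tails if FALSE the cline is the pure scaled sigmoid and the tail
#'   parameters are ignored; note that with tails on, the tail expression
#'   governs everything beyond `c - deltaL` / `c + deltaR`, so `delta = 0`
#'   means an all-tail flank, not a plain sigmoid
#' @return an object of class `cline_model`
#' @export
cline_model <- function(centre, width, pmin = 0, pmax = 1,
                        deltaL = 0, tauL = 1, deltaR = 0, tauR = 1,
                        increasing = TRUE, tails = FALSE) {
  stopifnot(width > 0, pmin >= 0, pmax <= 1, pmin <= pmax,
            deltaL >= 0, deltaR >= 0,
            tauL >= 0, tauL <= 1, tauR >= 0, tauR <= 1)
  structure(list(centre = centre, width = width, pmin = pmin, pmax = pmax,
                 deltaL = deltaL, tauL = tauL, deltaR = deltaR, tauR = tauR,
                 increasing = increasing, tails = tails, fit = NULL),
            class = "cline_model")
}

#' @export
print.cline_model <- function(x, ...) {
  cat(sprintf(
    "<cline_model> centre %.2f km, width %.2f km, p in [%.3f, %.3f]%s\n",
    x$centre, x$width, x$pmin, x$pmax,
    if (x$increasing) "" else " (decreasing)"))
  if (!is.null(x$fit)) {
    cat(sprintf("  logLik %.2f%s\n", x$fit$loglik,
                if (x$fit$degenerate) " [degenerate fit]" else ""))
  }
  invisible(x)
}

#' Predict cline frequencies
#'
#' The unscaled shape is `y(x) = (1 + tanh(2 (x - c) / w)) / 2` inside
#' `[c - deltaL, c + deltaR]`; to the left of the left tail junction,
#' `y(x) = y(c - deltaL) * exp(4 tauL (x - c + deltaL) / w)`, and to the
#' right, `y(x) = 1 - (1 - y(c + deltaR)) * exp(-4 tauR (x - c - deltaR) /
#' w)`. The prediction is `p(x) = pmin + (pmax - pmin) * y(x)`; both tails
#' join the sigmoid continuously by construction.
#'
#' @param model a [cline_model()]
#' @param x distances (km)
#' @return p(x), numeric in `[pmin, pmax]`
#' @export
cline_predict <- function(model, x) {
  if (model$width <= 0) stop("cline width must be positive")
  u <- x - model$centre
  if (!model$increasing) u <- -u
  y <- (1 + tanh(2 * u / model$width)) / 2
  if (isTRUE(model$tails)) {
    left <- u < -model$deltaL
    if (any(left)) {
      yL <- (1 + tanh(-2 * model$deltaL / model$width)) / 2
      y[left] <- yL * exp(4 * model$tauL * (u[left] + model$deltaL) /
                            model$width)
    }
    right <- u > model$deltaR
    if (any(right)) {
      yR <- (1 + tanh(2 * model$deltaR / model$width)) / 2
      y[right] <- 1 - (1 - yR) * exp(-4 * model$tauR *
                                       (u[right] - model$deltaR) /
                                       model$width)
    }
  }
  model$pmin + (model$pmax - model$pmin) * y
}

# parameter transform: unconstrained theta <-> cline parameters.
# theta = (c, log w, logit pmin, logit fmax, [log dL, logit tL, log dR,
# logit tR]) with pmax = pmin + (1 - pmin) * plogis(fmax).
theta_to_model <- function(theta, increasing, tails) {
  pmin <- stats::plogis(theta[3])
  pmax <- pmin + (1 - pmin) * stats::plogis(theta[4])
  if (tails) {
    cline_model(theta[1], exp(theta[2]), pmin, pmax,
                deltaL = exp(theta[5]), tauL = stats::plogis(theta[6]),
                deltaR = exp(theta[7]), tauR = stats::plogis(theta[8]),
                increasing = increasing, tails = TRUE)
  } else {
    cline_model(theta[1], exp(theta[2]), pmin, pmax,
                increasing = increasing)
  }
}

# multi-start bounded MLE + optional Metropolis MCMC for credible intervals
fit_cline_engine <- function(x, loglik_fn, opts) {
  o <- list(tails = FALSE, n_starts = 20, ci = FALSE,
            mcmc_burn = 1e4, mcmc_chain = 1e5, seed = NULL)
  o[names(opts)] <- opts
  if (!is.null(o$seed)) set.seed(o$seed)
  span <- diff(range(x))
  npar <- if (o$tails) 8L else 4L
  lower <- c(min(x) - span, log(span / 200), -8, -8,
             if (o$tails) c(log(span * 1e-3), -8, log(span * 1e-3), -8))
  upper <- c(max(x) + span, log(span * 4), 8, 8,
             if (o$tails) c(log(span * 2), 8, log(span * 2), 8))
  obj <- function(theta, increasing) {
    m <- theta_to_model(theta, increasing, o$tails)
    -loglik_fn(m)
  }
  best <- NULL
  for (increasing in c(TRUE, FALSE)) {
    for (s in seq_len(o$n_starts)) {
      init <- c(stats::runif(1, min(x), max(x)),
                log(stats::runif(1, span / 20, span)),
                stats::rnorm(1, -2, 1), stats::rnorm(1, 2, 1),
                if (o$tails) c(log(span / 4), 0, log(span / 4), 0) +
                  stats::rnorm(4, 0, 0.5))
      fit <- tryCatch(
        stats::optim(init, obj, increasing = increasing,
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = 500)),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      if (is.null(best) || fit$value < best$value) {
        best <- fit
        best$increasing <- increasing
      }
    }
  }
  if (is.null(best)) stop("cline fit failed from every start")
  model <- theta_to_model(best$par, best$increasing, o$tails)
  ci <- NULL
  accept <- NA_real_
  if (o$ci) {
    # random-walk Metropolis on theta; proposal scale tuned during burn-in
    # towards 20-40% acceptance
    theta <- best$par
    sc <- rep(0.1, npar)
    ll <- -best$value
    keep <- matrix(NA_real_, o$mcmc_chain %/% 10L, npar)
    acc <- 0L; tries <- 0L
    for (it in seq_len(o$mcmc_burn + o$mcmc_chain)) {
      prop <- theta + stats::rnorm(npar, 0, sc)
      if (all(prop >= lower & prop <= upper)) {
        llp <- -obj(prop, best$increasing)
        tries <- tries + 1L
        if (log(stats::runif(1)) < llp - ll) {
          theta <- prop; ll <- llp; acc <- acc + 1L
        }
      } else tries <- tries + 1L
      if (it <= o$mcmc_burn && it %% 200L == 0L && tries > 0L) {
        rate <- acc / tries
        if (rate < 0.2) sc <- sc * 0.8
        if (rate > 0.4) sc <- sc * 1.25
        acc <- 0L; tries <- 0L
      }
      if (it > o$mcmc_burn && (it - o$mcmc_burn) %% 10L == 0L) {
        keep[(it - o$mcmc_burn) %/% 10L, ] <- theta
      }
    }
    accept <- acc / max(tries, 1L)
    draws <- apply(keep, 1, function(th) {
      m <- theta_to_model(th, best$increasing, o$tails)
      c(centre = m$centre, width = m$width, pmin = m$pmin, pmax = m$pmax)
    })
    ci <- apply(draws, 1, stats::quantile, probs = c(0.025, 0.975))
  }
  model$fit <- list(loglik = -best$value, convergence = best$convergence,
                    ci = ci, accept = accept, degenerate = FALSE)
  model
}

#' Fit a geographic cline to per-site allele counts
#'
#' Maximum-likelihood fit of the cline model to binomial allele counts:
#' `hits_i ~ Binomial(n_copies_i, p(x_i))`. The optimiser is multi-start
#' bounded L-BFGS-B on transformed parameters (20 starts by default);
#' orientation is resolved by fitting both an increasing and a decreasing
#' cline and keeping the better likelihood. Credible intervals, when
#' requested (`opts$ci = TRUE`), come from a random-walk Metropolis chain
#' (default burn-in 1e4, chain 1e5, proposal scales tuned to 20-40%
#' acceptance).
#'
#' @param site_distances numeric vector of site positions (km), finite
#' @param allele_counts data.frame with columns `hits` and `n_copies`
#' @param opts list: `tails` (fit exponential tails; default FALSE),
#'   `n_starts`, `ci`, `mcmc_burn`, `mcmc_chain`, `seed`
#' @return a fitted [cline_model()]; `$fit` holds the log-likelihood and CI.
#'   An input with identical frequencies at every site yields a fit flagged
#'   `degenerate`.
#' @export
fit_cline <- function(site_distances, allele_counts, opts = list()) {
  x <- site_distances
  stopifnot(all(is.finite(x)), length(x) >= 4,
            nrow(allele_counts) == length(x))
  hits <- allele_counts$hits
  n <- allele_counts$n_copies
  stopifnot(all(hits >= 0), all(hits <= n))
  loglik_fn <- function(m) {
    p <- pmin(pmax(cline_predict(m, x), 1e-9), 1 - 1e-9)
    sum(stats::dbinom(hits, n, p, log = TRUE))
  }
  model <- fit_cline_engine(x, loglik_fn, opts)
  if (length(unique(hits / n)) == 1) model$fit$degenerate <- TRUE
  model
}

#' Fit a cline to mean ancestry per site
#'
#' Same geometry as [fit_cline()], with a Gaussian likelihood on site means:
#' each site contributes `dnorm(mean Q, p(x), se)` with `se = sd / sqrt(n)`;
#' sites with fewer than 3 individuals borrow the pooled within-site sd.
#'
#' @param site_distances numeric vector of site positions (km)
#' @param q_values list of numeric vectors: per-site individual ancestry
#'   fractions (>= 2 individuals at >= 4 sites)
#' @param opts as in [fit_cline()]
#' @return a fitted [cline_model()]
#' @export
fit_ancestry_cline <- function(site_distances, q_values, opts = list()) {
  x <- site_distances
  stopifnot(all(is.finite(x)), length(x) >= 4,
            length(q_values) == length(x))
  ns <- lengths(q_values)
  stopifnot(all(ns >= 2))
  mu <- vapply(q_values, mean, numeric(1))
  sds <- vapply(q_values, stats::sd, numeric(1))
  pooled <- sqrt(sum(sds^2 * (ns - 1)) / sum(ns - 1))
  sds[ns < 3] <- pooled
  se <- pmax(sds / sqrt(ns), 1e-4)
  loglik_fn <- function(m) {
    sum(stats::dnorm(mu, cline_predict(m, x), se, log = TRUE))
  }
  model <- fit_cline_engine(x, loglik_fn, opts)
  if (diff(range(mu)) < 1e-12) model$fit$degenerate <- TRUE
  model
}
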