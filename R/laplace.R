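# Nested Laplace approximation for the latent Gaussian NMA models.
#
# The latent field alpha (internal component parametrization, diagonal
# prior precision) is approximated by a Gaussian at its conditional mode
# for fixed hyperparameters theta = log-variances; the hyperparameter
# posterior is the standard Laplace expression explored on a small grid
# (or central composite design); latent marginals are mixtures of the
# per-point Gaussian conditionals; DIC is estimated by sampling the
# mixture.

GA_GRAD_TOL <- 1e-8
GA_MAX_ITER <- 100L
FD_STEP <- 1e-4       # finite-difference step on the log-variance scale
DIC_SEED <- 20180116L

# ---------------------------------------------------------------------------
# Model context: everything the engine needs, built once per fit.

nma_context <- function(spec, net) {
  stopifnot(inherits(spec, "nma_model_spec"), inherits(net, "nma_network"))
  if (net$family != spec$family)
    abort_config(sprintf("network family (%s) does not match spec (%s)",
                         net$family, spec$family))
  dropped <- character()
  if (kind_has_beta(spec$model_kind)) {
    net <- drop_missing_covariate(net)
    dropped <- net$dropped_studies
  }
  cat <- enumerate_designs(net)
  layout <- build_layout(net, cat, spec$model_kind, spec$reference)
  asm <- build_assembly(net, layout, cat)
  if (spec$kappa_pinned) {
    keep <- layout$components$class != "kappa"
    layout$components <- layout$components[keep, , drop = FALSE]
    layout$report <- layout$report[, keep, drop = FALSE]
    layout$ncomp <- sum(keep)
    asm$X <- asm$X[, keep, drop = FALSE]
  }
  theta_names <- c(if (spec$has_tau) "log_tau2",
                   if (spec$has_kappa) "log_kappa2")
  list(spec = spec, net = net, cat = cat, layout = layout, asm = asm,
       theta_names = theta_names, q = length(theta_names),
       dropped_studies = dropped)
}

hp_from_theta <- function(ctx, theta) {
  hp <- list()
  if (ctx$spec$has_tau) hp$tau <- exp(theta[["log_tau2"]] / 2)
  if (ctx$spec$has_kappa) hp$kappa <- exp(theta[["log_kappa2"]] / 2)
  hp
}

theta_from_hp <- function(ctx, hp) {
  th <- c(if (ctx$spec$has_tau) log_tau2 = 2 * log(hp$tau),
          if (ctx$spec$has_kappa) log_kappa2 = 2 * log(hp$kappa))
  setNames(th, ctx$theta_names)
}

# log prior of theta: uniform on the sd scale transformed with the exact
# Jacobian d(sd)/d(theta) = sd / 2.
log_prior_theta <- function(ctx, theta) {
  spec <- ctx$spec
  lp <- 0
  bounds <- list(log_tau2 = spec$tau_prior, log_kappa2 = spec$kappa_prior)
  for (nm in ctx$theta_names) {
    s <- exp(theta[[nm]] / 2)
    b <- bounds[[nm]]
    if (s < b[1] || s > b[2]) return(-Inf)
    lp <- lp + log(s / 2) - log(b[2] - b[1])
  }
  lp
}

# ---------------------------------------------------------------------------
# Gaussian approximation of the latent field at fixed hyperparameters.

ga_at <- function(ctx, theta, start = NULL) {
  asm <- ctx$asm
  X <- asm$X
  P <- ncol(X)
  hp <- hp_from_theta(ctx, theta)
  prec <- comp_precisions(ctx$layout, ctx$spec, hp)
  lprior_const <- -0.5 * sum(log(2 * pi / prec))
  f_of <- function(alpha, eta) {
    loglik_parts(asm, eta, deriv = FALSE)$ll +
      lprior_const - 0.5 * sum(prec * alpha^2)
  }
  alpha <- start %||% numeric(P)
  eta <- drop(X %*% alpha)
  f <- f_of(alpha, eta)
  iter <- 0L
  repeat {
    parts <- loglik_parts(asm, eta)
    grad <- drop(crossprod(X, parts$u)) - prec * alpha
    gnorm <- max(abs(grad))
    if (gnorm < GA_GRAD_TOL || iter >= GA_MAX_ITER) break
    sw <- sqrt(parts$w)
    H <- crossprod(X * sw)
    diag(H) <- diag(H) + prec
    R <- tryCatch(chol(H), error = function(e)
      stop(sprintf("singular curvature at theta = (%s)",
                   paste(signif(theta, 4), collapse = ", ")),
           call. = FALSE))
    delta <- backsolve(R, backsolve(R, grad, transpose = TRUE))
    step <- 1
    repeat {
      alpha_new <- alpha + step * delta
      eta_new <- drop(X %*% alpha_new)
      f_new <- f_of(alpha_new, eta_new)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      step <- step / 2
      if (step < 1e-10)
        stop(sprintf(
          "latent Newton iteration failed to improve (iteration %d, |grad| = %.3g)",
          iter, gnorm), call. = FALSE)
    }
    alpha <- alpha_new; eta <- eta_new; f <- f_new
    iter <- iter + 1L
  }
  if (max(abs(grad)) >= GA_GRAD_TOL)
    stop(sprintf(
      "latent mode search did not converge in %d iterations (|grad| = %.3g)",
      iter, max(abs(grad))), call. = FALSE)
  parts <- loglik_parts(asm, eta)
  sw <- sqrt(parts$w)
  H <- crossprod(X * sw)
  diag(H) <- diag(H) + prec
  R <- chol(H)
  logdet <- 2 * sum(log(diag(R)))
  log_ptilde <- f + log_prior_theta(ctx, theta) +
    (P / 2) * log(2 * pi) - 0.5 * logdet
  structure(list(theta = theta, hp = hp, mode = alpha, chol = R,
                 logdet = logdet, f_mode = f, log_ptilde = log_ptilde,
                 iterations = iter, grad_norm = max(abs(grad)),
                 prec = prec),
            class = "nma_gaussian_approx")
}

#' Gaussian approximation of the latent field at fixed hyperparameters
#'
#' Runs damped Newton (Fisher-scoring) iterations on the latent log
#' posterior until the gradient max-norm falls below `1e-8`, and returns
#' the mode, the Cholesky factor of the precision at the mode, and the
#' Laplace approximation of the unnormalized hyperparameter log posterior
#' at this point.
#'
#' @param spec an [nma_model_spec()].
#' @param net an [nma_network()].
#' @param hp list with `tau` and/or `kappa` (standard deviations) as the
#'   model kind requires; ignored for the fixed-effect kind.
#' @param start optional latent starting vector.
#' @return Object of class `nma_gaussian_approx` with elements `mode`,
#'   `chol` (upper Cholesky factor of the precision), `log_ptilde`,
#'   `iterations` and `grad_norm`.
#' @export
gaussian_approximation <- function(spec, net, hp = list(), start = NULL) {
  ctx <- nma_context(spec, net)
  theta <- if (ctx$q) theta_from_hp(ctx, hp) else
    setNames(numeric(0), character(0))
  if (ctx$q && !is.finite(log_prior_theta(ctx, theta)))
    abort_validation("hyperparameters outside the prior support")
  ga_at(ctx, theta, start)
}

# Cached evaluation of log ptilde(theta | y) with warm-started modes.
make_logdens <- function(ctx) {
  cache <- new.env(parent = emptyenv())
  cache$last_mode <- NULL
  key <- function(theta) paste(sprintf("%.12g", theta), collapse = ",")
  ld <- function(theta, want_ga = FALSE) {
    theta <- setNames(as.numeric(theta), ctx$theta_names)
    if (!is.finite(log_prior_theta(ctx, theta)))
      return(if (want_ga) NULL else -Inf)
    k <- key(theta)
    ga <- cache[[k]] %||% {
      g <- ga_at(ctx, theta, start = cache$last_mode)
      cache$last_mode <- g$mode
      assign(k, g, envir = cache)
      g
    }
    if (want_ga) ga else ga$log_ptilde
  }
  ld
}

#' Locate the mode of the hyperparameter posterior
#'
#' Maximizes the Laplace-approximated log posterior of the
#' hyperparameters on the internal log-variance scale (golden-section
#' search for one hyperparameter; Nelder-Mead polished by quasi-Newton for
#' two) and computes the curvature at the mode by central finite
#' differences.
#'
#' @inheritParams gaussian_approximation
#' @return Object of class `nma_hyper_opt`: `theta_mode`, `hp_mode`
#'   (tau/kappa at the mode), `value`, `hessian` (negative curvature of
#'   the log density), `Sigma` (its inverse), and the evaluator `logdens`.
#' @export
optimize_hyper <- function(spec, net) {
  ctx <- nma_context(spec, net)
  optimize_hyper_ctx(ctx)
}

optimize_hyper_ctx <- function(ctx) {
  if (ctx$q == 0L)
    abort_config("model has no hyperparameters (fixed-effect kind)")
  ld <- make_logdens(ctx)
  spec <- ctx$spec
  bounds <- list(log_tau2 = spec$tau_prior, log_kappa2 = spec$kappa_prior)
  lower <- vapply(ctx$theta_names, function(nm)
    max(2 * log(max(bounds[[nm]][1], 1e-6)), -27), 0)
  upper <- vapply(ctx$theta_names, function(nm)
    2 * log(bounds[[nm]][2]), 0)
  if (ctx$q == 1L) {
    op <- optimize(function(t) ld(t), lower = lower, upper = upper,
                   maximum = TRUE, tol = 1e-7)
    theta_mode <- setNames(op$maximum, ctx$theta_names)
    value <- op$objective
  } else {
    theta0 <- pmin(pmax(setNames(rep(2 * log(0.5), ctx$q),
                                 ctx$theta_names), lower + 0.5), upper - 0.5)
    nm <- optim(theta0, function(t) ld(t), method = "Nelder-Mead",
                control = list(fnscale = -1, maxit = 500,
                               reltol = 1e-12))
    bf <- tryCatch(
      optim(nm$par, function(t) ld(t), method = "BFGS",
            control = list(fnscale = -1, maxit = 100, reltol = 1e-12)),
      error = function(e) nm)
    best <- if (bf$value >= nm$value) bf else nm
    theta_mode <- setNames(best$par, ctx$theta_names)
    value <- best$value
  }
  at_bound <- theta_mode <= lower + 2 * FD_STEP |
    theta_mode >= upper - 2 * FD_STEP
  if (any(at_bound))
    warning("hyperparameter posterior mode lies at the prior boundary; ",
            "the density is (nearly) flat in the likelihood and the ",
            "posterior is prior-dominated", call. = FALSE)
  fd_center <- pmin(pmax(theta_mode, lower + 2 * FD_STEP),
                    upper - 2 * FD_STEP)
  H <- fd_hessian(function(t) ld(t), fd_center, FD_STEP)
  H <- -H   # curvature of -log density (precision)
  ev <- eigen(H, symmetric = TRUE)
  # curvature floor: a flat (prior-dominated) density still gets a grid
  # scale commensurate with the prior support on the log-variance scale
  floor_val <- max((4 / max(upper - lower))^2, 1e-4)
  if (any(ev$values <= floor_val)) {
    if (any(ev$values <= 0))
      warning("hyper-posterior curvature not positive definite at the ",
              "mode; regularizing", call. = FALSE)
    ev$values <- pmax(ev$values, floor_val)
    H <- ev$vectors %*% diag(ev$values, ctx$q) %*% t(ev$vectors)
  }
  Sigma <- ev$vectors %*% diag(1 / ev$values, ctx$q) %*% t(ev$vectors)
  structure(list(theta_mode = theta_mode,
                 hp_mode = hp_from_theta(ctx, theta_mode),
                 value = value, hessian = H, Sigma = Sigma,
                 eig = ev, logdens = ld, ctx = ctx, q = ctx$q,
                 lower = lower, upper = upper),
            class = "nma_hyper_opt")
}

fd_hessian <- function(f, x, h) {
  q <- length(x)
  H <- matrix(0, q, q)
  f0 <- f(x)
  sh <- function(i, s) {
    y <- x; y[i] <- y[i] + s * h; y
  }
  for (i in seq_len(q)) {
    H[i, i] <- (f(sh(i, 1)) - 2 * f0 + f(sh(i, -1))) / h^2
    if (i < q) for (j in (i + 1):q) {
      yi <- function(si, sj) {
        y <- x; y[i] <- y[i] + si * h; y[j] <- y[j] + sj * h; f(y)
      }
      H[i, j] <- H[j, i] <-
        (yi(1, 1) - yi(1, -1) - yi(-1, 1) + yi(-1, -1)) / (4 * h^2)
    }
  }
  H
}

#' Lay out integration points for the hyperparameter posterior
#'
#' `strategy = "grid"` builds an axis-aligned lattice in standardized
#' coordinates (eigen-decomposition of the curvature), expanding each axis
#' in steps of `step` posterior standard deviations until the log density
#' has dropped by more than `cutoff`, and keeps lattice points within the
#' cutoff.  `strategy = "ccd"` places a central composite design (center,
#' axial and factorial points on a sphere) with weights matched so the
#' rule integrates constants and second moments of a Gaussian exactly.
#'
#' @param opt an [optimize_hyper()] result.
#' @param strategy `"grid"` (default, the reference rule) or `"ccd"`.
#' @param step grid resolution in posterior standard deviations.
#' @param cutoff log-density drop at which the grid stops expanding.
#' @param f0 scaling of the CCD sphere radius `f0 * sqrt(q)`.
#' @param max_steps cap on the number of grid steps per direction (a
#'   degenerate, flat density triggers the cap with a warning).
#' @return Object of class `nma_hyper_grid`: `theta` (points), `logdens`,
#'   `weights` (normalized), `delta` (raw quadrature weights), `gas` (the
#'   per-point Gaussian approximations) and `log_mlik` (log normalizing
#'   constant of the Laplace-approximated hyper posterior).
#' @export
explore_hyper <- function(opt, strategy = c("grid", "ccd"), step = 0.5,
                          cutoff = 6, f0 = 1.1, max_steps = 50L) {
  stopifnot(inherits(opt, "nma_hyper_opt"))
  strategy <- match.arg(strategy)
  q <- opt$q
  ld <- opt$logdens
  A <- opt$eig$vectors %*% diag(1 / sqrt(opt$eig$values), q)
  logdetA <- sum(log(1 / sqrt(opt$eig$values)))
  theta_of <- function(z) drop(opt$theta_mode + A %*% z)
  ld0 <- opt$value

  if (strategy == "grid") {
    extent <- function(dir_vec) {
      k <- 0L
      while (k < max_steps) {
        v <- ld(theta_of((k + 1L) * step * dir_vec))
        if (!is.finite(v) || v < ld0 - cutoff) break
        k <- k + 1L
      }
      if (k >= max_steps)
        warning("hyper grid extent capped; density is very flat",
                call. = FALSE)
      k
    }
    ranges <- lapply(seq_len(q), function(i) {
      e <- numeric(q); e[i] <- 1
      (-extent(-e)):extent(e)
    })
    zg <- as.matrix(expand.grid(lapply(ranges, function(r) r * step)))
    lds <- apply(zg, 1L, function(z) ld(theta_of(z)))
    keep <- is.finite(lds) & lds >= ld0 - cutoff
    zg <- zg[keep, , drop = FALSE]
    lds <- lds[keep]
    delta <- rep(step^q, nrow(zg))
  } else {
    if (q == 1L) {
      zg <- matrix(c(0, f0, -f0), ncol = 1)
      r2 <- f0^2
      n_sat <- 2L
      S <- 2 * r2
    } else {
      r <- f0 * sqrt(q)
      axial <- do.call(rbind, lapply(seq_len(q), function(i) {
        e <- matrix(0, 2, q); e[1, i] <- r; e[2, i] <- -r; e
      }))
      fac <- as.matrix(expand.grid(rep(list(c(-f0, f0)), q)))
      zg <- rbind(matrix(0, 1, q), axial, fac)
      r2 <- r^2
      n_sat <- nrow(zg) - 1L
      S <- 2 * r2 + 2^q * r2 / q
    }
    p0 <- (2 * pi)^(-q / 2)
    p1 <- p0 * exp(-r2 / 2)
    w1 <- 1 / (p1 * S)
    w0 <- (1 - n_sat * w1 * p1) / p0
    delta <- c(w0, rep(w1, n_sat))
    lds <- apply(zg, 1L, function(z) ld(theta_of(z)))
    keep <- is.finite(lds)
    zg <- zg[keep, , drop = FALSE]; lds <- lds[keep]
    delta <- delta[keep]
  }

  w <- delta * exp(lds - max(lds))
  log_mlik <- max(lds) + log(sum(w)) + logdetA
  weights <- w / sum(w)
  theta <- t(apply(zg, 1L, theta_of))
  if (q == 1L) theta <- matrix(theta, ncol = 1)
  colnames(theta) <- opt$ctx$theta_names
  gas <- lapply(seq_len(nrow(theta)), function(j)
    ld(theta[j, ], want_ga = TRUE))
  structure(list(theta = theta, z = zg, logdens = lds, delta = delta,
                 weights = weights, gas = gas, opt = opt,
                 strategy = strategy, step = step, cutoff = cutoff,
                 log_mlik = log_mlik),
            class = "nma_hyper_grid")
}

# Single-point "grid" for the fixed-effect kind.
degenerate_grid <- function(ctx) {
  ga <- ga_at(ctx, setNames(numeric(0), character(0)))
  structure(list(theta = matrix(numeric(0), 1, 0), z = NULL,
                 logdens = ga$log_ptilde, delta = 1, weights = 1,
                 gas = list(ga), opt = NULL, strategy = "none",
                 log_mlik = ga$log_ptilde),
            class = "nma_hyper_grid")
}

# ---------------------------------------------------------------------------
# Marginals.

# Conditional Gaussian moments of a linear functional at each grid point.
mixture_moments <- function(row, grid) {
  m <- vapply(grid$gas, function(g) sum(row * g$mode), 0)
  v <- vapply(grid$gas, function(g) {
    u <- backsolve(g$chol, row, transpose = TRUE)
    sum(u^2)
  }, 0)
  list(m = m, v = v, w = grid$weights)
}

new_marginal <- function(x, density, mean, sd, quantiles) {
  structure(list(x = x, density = density, mean = mean, sd = sd,
                 quantiles = quantiles), class = "nma_marginal")
}

#' @export
print.nma_marginal <- function(x, ...) {
  cat(sprintf(
    "nma_marginal: mean %.4g, sd %.4g, median %.4g, 95%% CI [%.4g, %.4g]\n",
    x$mean, x$sd, x$quantiles[["50%"]], x$quantiles[["2.5%"]],
    x$quantiles[["97.5%"]]))
  invisible(x)
}

QUANTS <- c(0.025, 0.25, 0.5, 0.75, 0.975)

gaussian_mixture_marginal <- function(m, v, w, n_grid = 1001L) {
  mean <- sum(w * m)
  var <- sum(w * (v + m^2)) - mean^2
  if (all(v < 1e-12) && var < 1e-12) {
    qs <- setNames(rep(mean, length(QUANTS)),
                   paste0(100 * QUANTS, "%"))
    return(new_marginal(mean, NA_real_, mean, 0, qs))
  }
  s <- sqrt(v)
  lo <- min(m - 6 * s); hi <- max(m + 6 * s)
  x <- seq(lo, hi, length.out = n_grid)
  dens <- rowSums(vapply(seq_along(w), function(j)
    w[j] * dnorm(x, m[j], s[j]), x))
  # renormalize the gridded density (trapezoid)
  z <- sum((dens[-1] + dens[-n_grid]) / 2 * diff(x))
  dens <- dens / z
  cdf <- rowSums(vapply(seq_along(w), function(j)
    w[j] * pnorm(x, m[j], s[j]), x))
  qs <- setNames(approx(cdf, x, QUANTS, ties = "ordered", rule = 2)$y,
                 paste0(100 * QUANTS, "%"))
  new_marginal(x, dens, mean, sqrt(max(var, 0)), qs)
}

#' Posterior marginal of one latent parameter (or linear functional)
#'
#' Mixes, over the hyperparameter integration points, the Gaussian
#' conditional marginal of a linear functional of the latent field,
#' weighted by the normalized hyper-posterior weights.
#'
#' @param slot a reported parameter name (row of the layout's report map)
#'   or a numeric coefficient vector over the internal components.
#' @param grid an [explore_hyper()] grid.
#' @param layout the model layout (required when `slot` is a name).
#' @return Object of class `nma_marginal`: a `(value, density)` grid with
#'   summary functionals `mean`, `sd` and `quantiles`.
#' @export
latent_marginal <- function(slot, grid, layout = NULL) {
  stopifnot(inherits(grid, "nma_hyper_grid"))
  row <- if (is.character(slot)) {
    stopifnot(inherits(layout, "nma_layout"))
    report_row(layout, slot)
  } else slot
  mm <- mixture_moments(row, grid)
  gaussian_mixture_marginal(mm$m, mm$v, mm$w)
}

#' Posterior marginal of a hyperparameter on the standard-deviation scale
#'
#' The lattice of hyper-posterior evaluations is marginalized over the
#' other hyperparameter (via a pivoted-Cholesky standardization in which
#' the target coordinate depends on a single lattice axis), interpolated,
#' and transformed from the internal log-variance scale to the
#' standard-deviation scale with the exact Jacobian.
#'
#' @param which `"tau"` or `"kappa"`.
#' @param grid an [explore_hyper()] grid.
#' @param step,cutoff lattice resolution and stopping rule for the
#'   marginalization lattice.
#' @return An `nma_marginal` on the sd scale.
#' @export
hyper_marginal <- function(which = c("tau", "kappa"), grid,
                           step = 0.4, cutoff = 8) {
  which <- match.arg(which)
  stopifnot(inherits(grid, "nma_hyper_grid"))
  opt <- grid$opt
  if (is.null(opt)) abort_config("fixed-effect fit has no hyperparameters")
  ctx <- opt$ctx
  target <- switch(which, tau = "log_tau2", kappa = "log_kappa2")
  if (!target %in% ctx$theta_names)
    abort_config(sprintf("model has no %s hyperparameter", which))
  ti <- match(target, ctx$theta_names)
  q <- opt$q
  ld <- opt$logdens
  if (q == 1L) {
    # profile over the single axis with the grid's own lattice spacing
    h <- sqrt(opt$Sigma[1, 1]) * step
    ks <- axis_range(function(k) ld(opt$theta_mode + k * h),
                     cutoff, opt$value)
    th <- opt$theta_mode + ks * h
    lds <- vapply(th, function(t) ld(t), 0)
    return(theta_density_to_sd(th, lds))
  }
  # order target first; lower-triangular standardization makes the target
  # depend on lattice axis 1 only, so the marginal is a sum over axis 2
  ord <- c(ti, setdiff(seq_len(q), ti))
  Sig <- opt$Sigma[ord, ord, drop = FALSE]
  L <- t(chol(Sig))
  mode <- opt$theta_mode[ord]
  theta_of <- function(z) {
    th <- mode + drop(L %*% z)
    setNames(th[order(ord)], ctx$theta_names)
  }
  ld_z <- function(z1, z2) ld(theta_of(c(z1, z2) * step))
  k1 <- axis_range(function(k) ld_z(k, 0), cutoff, opt$value)
  masses <- vapply(k1, function(k) {
    k2 <- axis_range(function(j) ld_z(k, j), cutoff, ld_z(k, 0))
    lds <- vapply(k2, function(j) ld_z(k, j), 0)
    mx <- max(lds)
    mx + log(sum(exp(lds - mx)))
  }, 0)
  th <- mode[1] + k1 * step * L[1, 1]
  theta_density_to_sd(th, masses)
}

# Integer offsets k (sorted) around 0 for which the evaluated log density
# stays within `cutoff` of `value0`.
axis_range <- function(ev, cutoff, value0, max_steps = 60L) {
  one_side <- function(s) {
    k <- 0L
    while (k < max_steps) {
      v <- ev(s * (k + 1L))
      if (!is.finite(v) || v < value0 - cutoff) break
      k <- k + 1L
    }
    k
  }
  (-one_side(-1L)):one_side(1L)
}

# Unnormalized log density on an increasing theta grid -> normalized
# marginal on the sd scale.
theta_density_to_sd <- function(theta, ldens, n_fine = 601L) {
  o <- order(theta)
  theta <- theta[o]; ldens <- ldens[o]
  if (length(theta) == 1L) {
    s <- exp(theta / 2)
    qs <- setNames(rep(s, length(QUANTS)), paste0(100 * QUANTS, "%"))
    return(new_marginal(s, NA_real_, s, 0, qs))
  }
  fine <- seq(min(theta), max(theta), length.out = n_fine)
  lf <- spline(theta, ldens, xout = fine)$y
  s <- exp(fine / 2)                      # sd scale
  dens <- exp(lf - max(lf)) * 2 / s       # p_sd = p_theta * |dtheta/dsd|
  z <- sum((dens[-1] + dens[-n_fine]) / 2 * diff(s))
  dens <- dens / z
  cdf <- c(0, cumsum((dens[-1] + dens[-n_fine]) / 2 * diff(s)))
  cdf <- cdf / cdf[n_fine]
  mean <- sum((dens[-1] * s[-1] + dens[-n_fine] * s[-n_fine]) / 2 * diff(s))
  m2 <- sum((dens[-1] * s[-1]^2 + dens[-n_fine] * s[-n_fine]^2) / 2 *
              diff(s))
  qs <- setNames(approx(cdf, s, QUANTS, ties = "ordered", rule = 2)$y,
                 paste0(100 * QUANTS, "%"))
  new_marginal(s, dens, mean, sqrt(max(m2 - mean^2, 0)), qs)
}

# ---------------------------------------------------------------------------
# DIC.

# Posterior mean deviance by importance-corrected sampling of the
# mixture-of-Gaussians approximation: draws from each grid point's
# Gaussian conditional are reweighted by the exact latent posterior over
# the Gaussian proposal (self-normalized within each point), which removes
# the bias a purely Gaussian conditional leaves in E[deviance] for
# non-Gaussian likelihoods; the normal-identity family has weight 1
# everywhere.
compute_dic <- function(grid, ctx, ndraws = 4000L, seed = DIC_SEED) {
  X <- ctx$asm$X
  dev_of <- function(alpha)
    -2 * loglik_parts(ctx$asm, drop(X %*% alpha), deriv = FALSE)$ll
  f_of <- function(alpha, prec)
    loglik_parts(ctx$asm, drop(X %*% alpha), deriv = FALSE)$ll +
    sum(dnorm(alpha, 0, sqrt(1 / prec), log = TRUE))
  res <- with_preserved_seed(seed, {
    dbar <- 0; abar <- 0; wtot <- 0; ntot <- 0L
    for (j in seq_along(grid$gas)) {
      Wj <- grid$weights[j]
      if (Wj < 1e-5) next
      g <- grid$gas[[j]]
      nj <- max(30L, as.integer(round(ndraws * Wj)))
      P <- length(g$mode)
      Z <- matrix(rnorm(P * nj), P)
      A <- g$mode + backsolve(g$chol, Z)
      lq <- -0.5 * colSums(Z^2) + 0.5 * g$logdet - P / 2 * log(2 * pi)
      lf <- apply(A, 2L, f_of, prec = g$prec)
      lw <- lf - lq
      w <- exp(lw - max(lw))
      w <- w / sum(w)
      D <- apply(A, 2L, dev_of)
      dbar <- dbar + Wj * sum(w * D)
      abar <- abar + Wj * drop(A %*% w)
      wtot <- wtot + Wj
      ntot <- ntot + nj
    }
    list(dbar = dbar / wtot, abar = abar / wtot, ntot = ntot)
  })
  dhat <- dev_of(res$abar)
  pd <- res$dbar - dhat
  list(dic = res$dbar + pd, pd = pd, dbar = res$dbar, dhat = dhat,
       ndraws = res$ntot, seed = seed)
}

#' Deviance information criterion of a fitted model
#'
#' `DIC = Dbar + pD` with `pD = Dbar - D(posterior mean of alpha)`.  The
#' posterior mean deviance `Dbar` is estimated from draws of the
#' mixture-of-Gaussians posterior approximation (fixed seed, so repeated
#' fits are bit-identical).  The deviance is the full `-2 log p(y|alpha)`
#' including normalizing constants, for all three families.
#'
#' @param fit an [nma_fit()] result.
#' @return List with `dic`, `pd`, `dbar`, `dhat`.
#' @export
nma_dic <- function(fit) {
  stopifnot(inherits(fit, "nma_fit"))
  fit$dic
}

# ---------------------------------------------------------------------------
# Top-level fit.

#' Fit an NMA model
#'
#' Dispatches the fixed-effect kind to a single Gaussian approximation (no
#' hyperparameter integration) and all random-effects kinds to the full
#' nested pipeline: hyper-posterior mode search, grid (or CCD)
#' exploration, mixture marginals for every reported latent parameter,
#' hyperparameter marginals on the sd scale, and DIC.  With
#' `engine = "mcmc"` the same model is instead fitted by the
#' Metropolis-within-Gibbs sampler (see [sample_posterior()]) and
#' summarized from the chains.
#'
#' @param spec an [nma_model_spec()].
#' @param net an [nma_network()].
#' @param engine `"laplace"` (default) or `"mcmc"`.
#' @param strategy,step,cutoff hyper-grid options, see [explore_hyper()].
#' @param laplace_marginals if `TRUE`, recompute each reported latent
#'   marginal with a per-slot nested Laplace correction instead of the
#'   Gaussian conditional (slower; the Gaussian conditional is the
#'   default and the reference for tests).
#' @param dic_draws,dic_seed mixture-sampling settings for `Dbar`.
#' @param mcmc list of sampler settings (`iterations`, `burnin`, `thin`,
#'   `chains`, `seed`) overriding the defaults of [sample_posterior()].
#' @return Object of class `nma_fit` with elements `summary` (data frame:
#'   parameter, type, mean, sd, 2.5%, 25%, 50%, 75%, 97.5%), `marginals`,
#'   `hyper_marginals`, `dic`, `layout`, `designs`, `spec`, plus engine
#'   details.
#' @examples
#' net <- make_toy_fixture("toy_s23")
#' fit <- nma_fit(nma_model_spec("consistency", "binomial"), net)
#' fit$summary[fit$summary$type == "d", ]
#' @export
nma_fit <- function(spec, net, engine = c("laplace", "mcmc"),
                    strategy = c("grid", "ccd"), step = 0.5, cutoff = 6,
                    laplace_marginals = FALSE,
                    dic_draws = 4000L, dic_seed = DIC_SEED,
                    mcmc = list()) {
  engine <- match.arg(engine)
  strategy <- match.arg(strategy)
  t0 <- proc.time()[["elapsed"]]
  if (engine == "mcmc")
    return(mcmc_fit(spec, net, mcmc, t0))
  ctx <- nma_context(spec, net)
  if (ctx$q == 0L) {
    grid <- degenerate_grid(ctx)
    opt <- NULL
  } else {
    opt <- optimize_hyper_ctx(ctx)
    grid <- explore_hyper(opt, strategy, step = step, cutoff = cutoff)
  }
  layout <- ctx$layout
  marg_fun <- if (laplace_marginals)
    function(nm) laplace_latent_marginal(report_row(layout, nm), grid, ctx)
  else
    function(nm) latent_marginal(report_row(layout, nm), grid)
  marginals <- setNames(lapply(layout$par$name, marg_fun),
                        layout$par$name)
  hyper_marginals <- list()
  if (spec$has_tau) hyper_marginals$tau <- hyper_marginal("tau", grid)
  if (spec$has_kappa)
    hyper_marginals$kappa <- hyper_marginal("kappa", grid)
  dic <- compute_dic(grid, ctx, ndraws = dic_draws, seed = dic_seed)

  srow <- function(nm, type, mg)
    data.frame(parameter = nm, type = type, mean = mg$mean, sd = mg$sd,
               `2.5%` = mg$quantiles[["2.5%"]],
               `25%` = mg$quantiles[["25%"]],
               `50%` = mg$quantiles[["50%"]],
               `75%` = mg$quantiles[["75%"]],
               `97.5%` = mg$quantiles[["97.5%"]],
               check.names = FALSE)
  summ <- do.call(rbind, c(
    Map(srow, layout$par$name, layout$par$type, marginals),
    Map(srow, names(hyper_marginals),
        names(hyper_marginals), hyper_marginals)))
  rownames(summ) <- NULL

  structure(list(spec = spec, net = ctx$net, layout = layout,
                 designs = ctx$cat, engine = "laplace",
                 strategy = grid$strategy, grid = grid, opt = opt,
                 ctx = ctx,
                 marginals = marginals, hyper_marginals = hyper_marginals,
                 dic = dic, summary = summ,
                 dropped_studies = ctx$dropped_studies,
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "nma_fit")
}

#' @export
print.nma_fit <- function(x, ...) {
  cat(sprintf("nma_fit: %s model (%s), engine %s, %d trials\n",
              x$spec$model_kind, family_label(x$spec$family), x$engine,
              x$net$S))
  keep <- x$summary$type %in% c("d", "beta", "tau", "kappa")
  print(x$summary[keep, c("parameter", "mean", "sd", "2.5%", "50%",
                          "97.5%")],
        row.names = FALSE, digits = 3)
  if (!is.null(x$dic))
    cat(sprintf("DIC %.2f (pD %.2f, mean deviance %.2f)\n",
                x$dic$dic, x$dic$pd, x$dic$dbar))
  cat(sprintf("elapsed: %.1f s\n", x$elapsed))
  invisible(x)
}

#' Posterior marginal of an arbitrary treatment contrast
#'
#' Uses the consistency algebra d\[t1,tk\] = d\[ref,tk\] - d\[ref,t1\] to
#' form the functional's coefficient row and mixes its Gaussian
#' conditionals over the stored hyper grid, so functional summaries obey
#' the basic-parameter algebra by construction.
#'
#' @param fit a Laplace-engine [nma_fit()].
#' @param t1,tk treatments (effect of `tk` relative to `t1`).
#' @return An `nma_marginal`.
#' @export
contrast_marginal <- function(fit, t1, tk) {
  stopifnot(inherits(fit, "nma_fit"))
  if (fit$engine != "laplace")
    abort_config("contrast_marginal needs a Laplace-engine fit")
  co <- contrast_coefficients(t1, tk, fit$layout)
  row <- numeric(fit$layout$ncomp)
  names(row) <- fit$layout$components$name
  row[names(co)] <- co
  latent_marginal(row, fit$grid)
}

# ---------------------------------------------------------------------------
# Optional per-slot nested Laplace correction of latent marginals.

# log p(c'alpha = x | theta, y) by a constrained Laplace approximation:
# maximize the latent log posterior subject to c'alpha = x, and correct by
# the restricted log determinant  log det(Q) + log(c' Q^-1 c).
constrained_laplace <- function(ctx, ga, row, x) {
  asm <- ctx$asm
  X <- asm$X
  prec <- ga$prec
  alpha <- ga$mode + row * (x - sum(row * ga$mode)) / sum(row * row)
  f_of <- function(alpha, eta)
    loglik_parts(asm, eta, deriv = FALSE)$ll - 0.5 * sum(prec * alpha^2)
  eta <- drop(X %*% alpha)
  f <- f_of(alpha, eta)
  for (it in 1:50) {
    parts <- loglik_parts(asm, eta)
    grad <- drop(crossprod(X, parts$u)) - prec * alpha
    sw <- sqrt(parts$w)
    H <- crossprod(X * sw)
    diag(H) <- diag(H) + prec
    R <- chol(H)
    solveH <- function(b) backsolve(R, backsolve(R, b, transpose = TRUE))
    Hg <- solveH(grad)
    Hc <- solveH(row)
    lambda <- sum(row * Hg) / sum(row * Hc)
    delta <- Hg - Hc * lambda
    step <- 1
    repeat {
      a_new <- alpha + step * delta
      e_new <- drop(X %*% a_new)
      f_new <- f_of(a_new, e_new)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      step <- step / 2
      if (step < 1e-10) break
    }
    moved <- max(abs(a_new - alpha))
    alpha <- a_new; eta <- e_new; f <- f_new
    if (moved < 1e-10 || max(abs(delta)) < 1e-10) break
  }
  parts <- loglik_parts(asm, eta)
  sw <- sqrt(parts$w)
  H <- crossprod(X * sw)
  diag(H) <- diag(H) + prec
  R <- chol(H)
  logdet <- 2 * sum(log(diag(R)))
  u <- backsolve(R, row, transpose = TRUE)
  f - 0.5 * (logdet + log(sum(u^2)))
}

laplace_latent_marginal <- function(row, grid, ctx, n_x = 25L) {
  mm <- mixture_moments(row, grid)
  if (all(mm$v < 1e-12))
    return(gaussian_mixture_marginal(mm$m, mm$v, mm$w))
  s <- sqrt(mm$v)
  lo <- min(mm$m - 5 * s); hi <- max(mm$m + 5 * s)
  xs <- seq(lo, hi, length.out = n_x)
  dens <- numeric(n_x)
  for (j in seq_along(grid$gas)) {
    if (grid$weights[j] < 1e-8) next
    lp <- vapply(xs, function(x)
      constrained_laplace(ctx, grid$gas[[j]], row, x), 0)
    pj <- exp(lp - max(lp))
    zj <- sum((pj[-1] + pj[-n_x]) / 2 * diff(xs))
    dens <- dens + grid$weights[j] * pj / zj
  }
  z <- sum((dens[-1] + dens[-n_x]) / 2 * diff(xs))
  dens <- dens / z
  # summaries from the corrected grid density
  fine <- seq(lo, hi, length.out = 801L)
  df <- spline(xs, dens, xout = fine)$y
  df[df < 0] <- 0
  zf <- sum((df[-1] + df[-801L]) / 2 * diff(fine))
  df <- df / zf
  cdf <- c(0, cumsum((df[-1] + df[-801L]) / 2 * diff(fine)))
  cdf <- cdf / cdf[length(cdf)]
  mean <- sum((df[-1] * fine[-1] + df[-801L] * fine[-801L]) / 2 *
                diff(fine))
  m2 <- sum((df[-1] * fine[-1]^2 + df[-801L] * fine[-801L]^2) / 2 *
              diff(fine))
  qs <- setNames(approx(cdf, fine, QUANTS, ties = "ordered", rule = 2)$y,
                 paste0(100 * QUANTS, "%"))
  new_marginal(fine, df, mean, sqrt(max(m2 - mean^2, 0)), qs)
}
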