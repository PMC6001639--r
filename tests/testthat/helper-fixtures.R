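# Shared fixtures and independent oracles, all built in code.

smoking_path <- function()
  system.file("extdata", "smoking.csv", package = "nmalgm")

smoking_net <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- read_arm_table(smoking_path(), "binomial")
    cache
  }
})

# Two-treatment / three-treatment simulated test networks.
small_consistency_topology <- function(seed, tau = 0.3, n = 200L,
                                       d = c(0, -0.6, -1)) {
  list(designs = list(list(treatments = c(1, 2), n_trials = 3),
                      list(treatments = c(1, 3), n_trials = 2),
                      list(treatments = c(1, 2, 3), n_trials = 1)),
       family = "binomial", n = n, d = d, tau = tau, seed = seed)
}

normal_topology <- function(seed, tau = 0.25, kappa = 0) {
  list(designs = list(list(treatments = c(1, 2), n_trials = 3),
                      list(treatments = c(1, 3), n_trials = 2),
                      list(treatments = c(1, 2, 3), n_trials = 1)),
       family = "normal", n = 40L, arm_sd = 1,
       d = c(0, -0.5, 0.4), tau = tau, kappa = kappa, seed = seed)
}

# Precision vector of the internal components, recomputed from the layout
# description (independent of the engine's own helper).
layout_precisions <- function(layout, spec, tau = NULL, kappa = NULL) {
  cls <- layout$components$class
  mult <- layout$components$mult
  p <- numeric(nrow(layout$components))
  p[cls == "fixed"] <- 1 / spec$prior_fixed_sd^2
  if (any(cls == "tau")) p[cls == "tau"] <- mult[cls == "tau"] / tau^2
  if (any(cls == "kappa"))
    p[cls == "kappa"] <- mult[cls == "kappa"] / kappa^2
  p
}

# Direct linear-mixed-model computation for the normal-identity family:
# marginal likelihood y ~ N(0, X P^-1 X' + V) plus the hyper prior on the
# internal log-variance scale (uniform on sd, Jacobian sd/2).  For a
# Gaussian likelihood the Laplace approximation is exact, so the engine's
# log ptilde must equal this up to floating-point error.
oracle_normal_logpost <- function(spec, net, tau, kappa = NULL) {
  cat <- enumerate_designs(net)
  layout <- build_layout(net, cat, spec$model_kind, spec$reference)
  asm <- build_assembly(net, layout, cat)
  p <- layout_precisions(layout, spec, tau, kappa)
  V <- diag(asm$scale2, nrow(asm$X))
  S <- asm$X %*% diag(1 / p, length(p)) %*% t(asm$X) + V
  R <- chol(S)
  y <- asm$y
  z <- backsolve(R, y, transpose = TRUE)
  lml <- -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(R))) +
                   sum(z^2))
  lp <- 0
  add_prior <- function(s, b) log(s / 2) - log(b[2] - b[1])
  if (spec$has_tau) lp <- lp + add_prior(tau, spec$tau_prior)
  if (spec$has_kappa) lp <- lp + add_prior(kappa, spec$kappa_prior)
  lml + lp
}

# GLS posterior moments of the latent field for the normal family at
# fixed hyperparameters (exact conjugate result).
oracle_normal_latent <- function(spec, net, tau, kappa = NULL) {
  cat <- enumerate_designs(net)
  layout <- build_layout(net, cat, spec$model_kind, spec$reference)
  asm <- build_assembly(net, layout, cat)
  p <- layout_precisions(layout, spec, tau, kappa)
  W <- diag(1 / asm$scale2, nrow(asm$X))
  Q <- t(asm$X) %*% W %*% asm$X + diag(p, length(p))
  mean <- solve(Q, t(asm$X) %*% W %*% asm$y)
  list(mean = drop(mean), cov = solve(Q), layout = layout)
}

expect_tabulated <- function(fit, parameter) {
  s <- fit$summary
  expect_true(parameter %in% s$parameter)
  s[s$parameter == parameter, , drop = FALSE]
}

fit_stat <- function(fit, parameter, col = "50%") {
  s <- fit$summary
  s[s$parameter == parameter, col]
}
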