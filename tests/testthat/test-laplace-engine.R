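test_that("normal-identity family makes the Laplace approximation exact", {
  net <- simulate_network(normal_topology(5))
  spec <- nma_model_spec("consistency", "normal")
  for (tau in c(0.1, 0.3, 1.2)) {
    ga <- gaussian_approximation(spec, net, list(tau = tau))
    expect_equal(ga$log_ptilde, oracle_normal_logpost(spec, net, tau),
                 tolerance = 1e-9)
  }
  # latent conditional moments equal the GLS solution
  orc <- oracle_normal_latent(spec, net, 0.3)
  ga <- gaussian_approximation(spec, net, list(tau = 0.3))
  expect_equal(ga$mode, orc$mean, tolerance = 1e-8,
               ignore_attr = TRUE)
  Qinv <- chol2inv(ga$chol)
  expect_equal(Qinv, orc$cov, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("binomial latent mode matches a brute-force optimizer", {
  net <- make_toy_fixture("toy_s23")
  spec <- nma_model_spec("consistency", "binomial")
  cat <- enumerate_designs(net)
  lay <- build_layout(net, cat, "consistency")
  asm <- build_assembly(net, lay, cat)
  p <- layout_precisions(lay, spec, tau = 0.4)
  negpost <- function(a)
    -(log_likelihood(net, linear_predictor(a, asm)) -
        0.5 * sum(p * a^2))
  op <- optim(numeric(lay$ncomp), negpost, method = "BFGS",
              control = list(maxit = 1000, reltol = 1e-14))
  ga <- gaussian_approximation(spec, net, list(tau = 0.4))
  expect_equal(ga$mode, op$par, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("starting at the mode is a fixed point of the Newton iteration", {
  net <- make_toy_fixture("toy_s23")
  spec <- nma_model_spec("consistency", "binomial")
  ga <- gaussian_approximation(spec, net, list(tau = 0.4))
  ga2 <- gaussian_approximation(spec, net, list(tau = 0.4),
                                start = ga$mode)
  expect_equal(ga2$iterations, 0L)
  expect_identical(ga2$mode, ga$mode)
})

test_that("hyper optimization rejects the fixed-effect kind and finds tau", {
  net <- simulate_network(normal_topology(17, tau = 0.25))
  expect_error(optimize_hyper(nma_model_spec("fixed", "normal"), net),
               "no hyperparameters")
  opt <- optimize_hyper(nma_model_spec("consistency", "normal"), net)
  # exact-case cross-check: the mode maximizes the oracle log posterior
  spec <- nma_model_spec("consistency", "normal")
  f <- function(th) oracle_normal_logpost(spec, net, exp(th / 2))
  th_star <- optimize(f, c(-10, 3), maximum = TRUE, tol = 1e-9)$maximum
  expect_equal(unname(opt$theta_mode), th_star, tolerance = 1e-3)
})

test_that("grid and CCD exploration integrate consistently", {
  # stub with an exactly quadratic log density (standard Gaussian in two
  # standardized coordinates): the CCD weights are constructed to match
  # a Gaussian's normalization and second moments, so grid and CCD must
  # agree there, and the grid must be a symmetric lattice
  quad_opt <- function(q) {
    structure(list(
      theta_mode = setNames(numeric(q), letters[seq_len(q)]),
      value = 0, q = q,
      hessian = diag(q), Sigma = diag(q),
      eig = eigen(diag(q), symmetric = TRUE),
      logdens = function(theta, want_ga = FALSE) {
        if (want_ga) return(list(mode = theta, chol = diag(q),
                                 logdet = 0))
        -0.5 * sum(theta^2)
      },
      ctx = list(theta_names = letters[seq_len(q)]),
      lower = rep(-Inf, q), upper = rep(Inf, q)),
      class = "nma_hyper_opt")
  }
  opt1 <- quad_opt(1)
  grid <- explore_hyper(opt1, "grid", cutoff = 15)
  expect_true(all(abs(sort(grid$z) + rev(sort(grid$z))) < 1e-12))
  ccd <- explore_hyper(opt1, "ccd")
  expect_equal(nrow(ccd$theta), 3L)  # q = 1: center + 2 axial
  moments <- function(g)
    c(sum(g$weights * g$theta[, 1]), sum(g$weights * g$theta[, 1]^2))
  expect_equal(moments(ccd), moments(grid), tolerance = 0.01)
  expect_equal(moments(ccd), c(0, 1), tolerance = 0.01)

  opt2 <- quad_opt(2)
  ccd2 <- explore_hyper(opt2, "ccd")
  expect_equal(nrow(ccd2$theta), 9L)  # center + 4 axial + 4 factorial
  grid2 <- explore_hyper(opt2, "grid", cutoff = 15)
  m2 <- function(g) vapply(1:2, function(i)
    sum(g$weights * g$theta[, i]^2), 0)
  expect_equal(m2(ccd2), c(1, 1), tolerance = 0.01)
  expect_equal(m2(grid2), c(1, 1), tolerance = 0.01)
  expect_equal(sum(ccd2$weights), 1)
  # both strategies run on a real model and produce normalized weights
  net <- simulate_network(normal_topology(23, tau = 0.3))
  opt <- optimize_hyper(nma_model_spec("consistency", "normal"), net)
  for (s in c("grid", "ccd")) {
    g <- explore_hyper(opt, s)
    expect_equal(sum(g$weights), 1)
    expect_true(all(g$weights > 0))
  }
})

test_that("marginal densities are normalized and summarized coherently", {
  net <- smoking_net()
  fit <- nma_fit(nma_model_spec("jackson", "binomial"), net)
  for (nm in c("d[1,2]", "d[1,3]", "omega[1,1,3]")) {
    m <- fit$marginals[[nm]]
    z <- sum((m$density[-1] + m$density[-length(m$density)]) / 2 *
               diff(m$x))
    expect_equal(z, 1, tolerance = 1e-6)
    expect_true(all(m$density >= 0))
    expect_lte(m$quantiles[["2.5%"]], m$quantiles[["50%"]])
    expect_lte(m$quantiles[["50%"]], m$quantiles[["97.5%"]])
  }
  for (h in names(fit$hyper_marginals)) {
    m <- fit$hyper_marginals[[h]]
    z <- sum((m$density[-1] + m$density[-length(m$density)]) / 2 *
               diff(m$x))
    expect_equal(z, 1, tolerance = 1e-6)
  }
})

test_that("mixture marginals reduce to their Gaussian components", {
  # single-point grid: exactly the Gaussian conditional
  fake_ga <- function(mode) {
    structure(list(mode = mode, chol = diag(2), logdet = 0),
              class = "nma_gaussian_approx")
  }
  grid1 <- structure(list(gas = list(fake_ga(c(1, 0))), weights = 1),
                     class = "nma_hyper_grid")
  m <- latent_marginal(c(1, 0), grid1)
  expect_equal(m$mean, 1)
  expect_equal(m$sd, 1, tolerance = 1e-12)
  expect_equal(m$density, dnorm(m$x, 1, 1), tolerance = 1e-6)
  # two symmetric components mix to mean zero
  grid2 <- structure(list(gas = list(fake_ga(c(-1, 0)), fake_ga(c(1, 0))),
                          weights = c(0.5, 0.5)),
                     class = "nma_hyper_grid")
  m2 <- latent_marginal(c(1, 0), grid2)
  expect_equal(m2$mean, 0, tolerance = 1e-12)
  expect_equal(m2$quantiles[["50%"]], 0, tolerance = 1e-6)
})

test_that("functional contrasts obey the basic-parameter algebra", {
  net <- smoking_net()
  fit <- nma_fit(nma_model_spec("consistency", "binomial"), net)
  m23 <- contrast_marginal(fit, 2, 3)
  expect_equal(m23$mean,
               fit$marginals[["d[1,3]"]]$mean -
                 fit$marginals[["d[1,2]"]]$mean,
               tolerance = 1e-10)
})

test_that("repeated fits are bit-identical", {
  net <- make_toy_fixture("toy_s23")
  f1 <- nma_fit(nma_model_spec("consistency", "binomial"), net)
  f2 <- nma_fit(nma_model_spec("consistency", "binomial"), net)
  expect_identical(f1$summary, f2$summary)
  expect_identical(f1$dic, f2$dic)
})

test_that("fixed-effect fit matches the logistic-regression profile", {
  arms <- data.frame(study = "a", treatment = c(1, 2),
                     events = c(12, 29), n = c(100, 100))
  net <- nma_network(arms, "binomial")
  fit <- nma_fit(nma_model_spec("fixed", "binomial"), net)
  gl <- stats::glm(cbind(events, n - events) ~ factor(treatment),
                   family = stats::binomial(), data = arms)
  expect_equal(fit_stat(fit, "d[1,2]", "mean"),
               unname(coef(gl)[2]), tolerance = 0.01)
  expect_equal(fit_stat(fit, "d[1,2]", "sd"),
               unname(sqrt(diag(vcov(gl)))[2]), tolerance = 0.01)
  expect_equal(fit$dic$pd, 2, tolerance = 0.15)
})

test_that("all five model kinds fit end to end on covariate data", {
  ts <- small_consistency_topology(41)
  ts$beta <- 0.1
  ts$covariate <- TRUE
  net <- simulate_network(ts)
  for (kind in c("fixed", "consistency", "jackson",
                 "metareg-consistency", "metareg-jackson")) {
    fit <- nma_fit(nma_model_spec(kind, "binomial"), net)
    expect_s3_class(fit, "nma_fit")
    expect_true(all(is.finite(fit$summary$mean)))
    expect_true(is.finite(fit$dic$dic))
    has_beta <- grepl("^metareg", kind)
    expect_equal("beta" %in% fit$summary$parameter, has_beta)
  }
})

test_that("the per-slot Laplace correction agrees with the exact case", {
  # normal family: the Gaussian conditional is exact, so the corrected
  # marginal must reproduce it
  net <- simulate_network(normal_topology(53, tau = 0.3))
  spec <- nma_model_spec("consistency", "normal")
  f_g <- nma_fit(spec, net)
  f_l <- nma_fit(spec, net, laplace_marginals = TRUE)
  for (nm in c("d[1,2]", "d[1,3]")) {
    # agreement to the resolution of the correction's evaluation grid
    expect_lt(abs(f_l$marginals[[nm]]$mean - f_g$marginals[[nm]]$mean),
              5e-3)
    expect_lt(abs(f_l$marginals[[nm]]$quantiles[["50%"]] -
                    f_g$marginals[[nm]]$quantiles[["50%"]]), 5e-3)
  }
  # binomial toy: runs and stays close to the Gaussian-conditional median
  netb <- make_toy_fixture("toy_s23")
  fb_g <- nma_fit(nma_model_spec("consistency", "binomial"), netb)
  fb_l <- nma_fit(nma_model_spec("consistency", "binomial"), netb,
                  laplace_marginals = TRUE)
  expect_equal(fb_l$marginals[["d[1,2]"]]$quantiles[["50%"]],
               fb_g$marginals[["d[1,2]"]]$quantiles[["50%"]],
               tolerance = 0.05)
})
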