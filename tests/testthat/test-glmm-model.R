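test_that("compound-symmetric covariance has the stated entries", {
  expect_equal(cs_covariance(2, 2), matrix(c(4, 2, 2, 4), 2))
  expect_equal(cs_covariance(0.7, 1), matrix(0.49))
  ev <- eigen(cs_covariance(1, 3), symmetric = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("shared + idiosyncratic decomposition reproduces the covariance", {
  for (p in 1:5) {
    dec <- cs_decompose(p)
    expect_equal(nrow(dec), if (p == 1) 1L else p + 1L)
    expect_equal(nmalgm:::cs_implied_covariance(1.3, p),
                 cs_covariance(1.3, p))
  }
})

test_that("linear predictor implements the model-kind structure", {
  net <- make_toy_fixture("toy_s23")
  cat <- enumerate_designs(net)
  lay_f <- build_layout(net, cat, "fixed")
  asm_f <- build_assembly(net, lay_f, cat)
  alpha <- seq_len(lay_f$ncomp) / 10
  names(alpha) <- lay_f$components$name
  eta <- linear_predictor(alpha, asm_f)
  # baseline arm of each trial is just mu_i; the toy baseline is always 1
  base_rows <- which(asm_f$arms$baseline)
  for (r in base_rows) {
    s <- asm_f$arms$study[r]
    expect_equal(eta[r], alpha[[sprintf("mu[%s]", s)]])
  }
  # non-baseline arm: mu + d[1,t]
  r23 <- which(!asm_f$arms$baseline & asm_f$arms$treatment == 3)[1]
  s <- asm_f$arms$study[r23]
  expect_equal(eta[r23],
               alpha[[sprintf("mu[%s]", s)]] + alpha[["d[1,3]"]])
  expect_equal(linear_predictor(numeric(lay_f$ncomp), asm_f),
               rep(0, nrow(net$arms)))
  expect_error(linear_predictor(numeric(3), asm_f), "length")
})

test_that("meta-regression interaction cancels between non-reference arms", {
  # trial with baseline 2 and arm 3: its beta coefficient must be zero,
  # so the d[2,3] contrast does not involve the interaction at all
  arms <- rbind(
    data.frame(study = "a", treatment = c(1, 2), events = c(4, 8),
               n = c(50, 50), covariate = 10),
    data.frame(study = "b", treatment = c(2, 3), events = c(6, 9),
               n = c(40, 40), covariate = 30),
    data.frame(study = "c", treatment = c(1, 3), events = c(3, 7),
               n = c(30, 30), covariate = 20))
  net <- nma_network(arms, "binomial")
  cat <- enumerate_designs(net)
  lay <- build_layout(net, cat, "metareg-consistency")
  asm <- build_assembly(net, lay, cat)
  b_col <- asm$X[, "beta"]
  rows_b <- which(asm$arms$study == "b")
  expect_equal(b_col[rows_b], c(0, 0))
  # trial with baseline 1 (the reference) keeps the centered covariate
  rows_a <- which(asm$arms$study == "a")
  expect_equal(b_col[rows_a], c(0, 10 - net$covariate_mean))
  # perturbing beta leaves every within-trial contrast of non-reference
  # treatments unchanged
  alpha0 <- numeric(lay$ncomp)
  alpha1 <- alpha0
  alpha1[which(lay$components$name == "beta")] <- 2.7
  e0 <- linear_predictor(alpha0, asm)
  e1 <- linear_predictor(alpha1, asm)
  expect_equal(diff(e1[rows_b]), diff(e0[rows_b]))
})

test_that("arm log-likelihoods match closed forms", {
  bin <- nma_network(data.frame(study = "a", treatment = 1:2,
                                events = c(5, 0), n = c(10, 8)),
                     "binomial")
  expect_equal(log_likelihood(bin, c(0, -20)),
               log(choose(10, 5)) + 10 * log(0.5) +
                 8 * log1p(-plogis(-20)))
  nor <- nma_network(data.frame(study = "a", treatment = 1:2,
                                mean = c(1.2, 0.4), sd = c(2, 2),
                                n = c(16, 16)), "normal")
  se <- 2 / sqrt(16)
  expect_equal(log_likelihood(nor, c(1.2, 0.4)),
               -2 * log(se * sqrt(2 * pi)))
  poi <- nma_network(data.frame(study = "a", treatment = 1:2,
                                count = c(0, 3), exposure = c(5, 5)),
                     "poisson")
  expect_equal(log_likelihood(poi, c(0.3, 0)),
               -5 * exp(0.3) + dpois(3, 5, log = TRUE))
  expect_error(log_likelihood(poi, c(Inf, 0)), "non-finite")
})

test_that("likelihood is invariant to arm and trial ordering", {
  net <- simulate_network(small_consistency_topology(21))
  set.seed(31)
  eta <- rnorm(nrow(net$arms))
  perm <- sample(nrow(net$arms))
  net2 <- nma_network(net$arms[perm, ], "binomial")
  # realign eta with the reordered arms
  key <- paste(net$arms$study, net$arms$treatment)
  key2 <- paste(net2$arms$study, net2$arms$treatment)
  expect_equal(log_likelihood(net2, eta[match(key2, key)]),
               log_likelihood(net, eta))
})

test_that("hyper priors are uniform on the sd scale with hard support", {
  spec <- nma_model_spec("jackson", "binomial")
  expect_equal(log_prior_hyper(list(tau = 1, kappa = 2), spec),
               2 * log(1 / 5))
  expect_identical(log_prior_hyper(list(tau = 5.4, kappa = 1), spec),
                   -Inf)
  stroke_like <- nma_model_spec("jackson", "binomial",
                                tau_prior = c(0, 2),
                                kappa_prior = c(0, 2))
  expect_equal(log_prior_hyper(list(tau = 1.9, kappa = 0.1), stroke_like),
               2 * log(1 / 2))
  expect_identical(log_prior_hyper(list(tau = 2.5, kappa = 1),
                                   stroke_like), -Inf)
})

test_that("latent prior combines fixed-effect and decomposed components", {
  net <- make_toy_fixture("toy_s23")
  spec <- nma_model_spec("consistency", "binomial")
  lay <- build_layout(net, enumerate_designs(net), "consistency")
  alpha <- numeric(lay$ncomp)
  hp <- list(tau = 0.5)
  p <- layout_precisions(lay, spec, tau = 0.5)
  expect_equal(log_prior_latent(alpha, hp, spec, lay),
               sum(dnorm(0, 0, sqrt(1 / p), log = TRUE)))
})

test_that("pinning kappa to zero reduces the Jackson predictor to consistency", {
  spec_c <- nma_model_spec("consistency", "binomial")
  spec_j0 <- nma_model_spec("jackson", "binomial",
                            kappa_prior = c(0, 0))
  expect_true(spec_j0$kappa_pinned)
  net <- make_toy_fixture("toy_s23")
  ctx_c <- nmalgm:::nma_context(spec_c, net)
  ctx_j <- nmalgm:::nma_context(spec_j0, net)
  # after dropping the omega columns, the component spaces coincide
  expect_equal(ctx_j$asm$X[, ctx_c$layout$components$name],
               ctx_c$asm$X)
})
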