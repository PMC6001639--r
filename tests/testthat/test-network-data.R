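test_that("reading the smoking table recovers its known shape", {
  net <- smoking_net()
  expect_s3_class(net, "nma_network")
  expect_equal(net$S, 24L)
  expect_equal(net$T, 4L)
  arms_per_trial <- table(net$arms$study)
  expect_equal(sum(arms_per_trial == 3), 2L)   # two 3-arm trials
  expect_equal(nrow(net$arms), 50L)
  cat <- enumerate_designs(net)
  expect_equal(nrow(cat$designs), 8L)
  expect_equal(nrow(cat$omega_slots), 10L)
})

test_that("a minimal two-arm file parses and validates", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("study,treatment,responders,sampleSize",
               "a,1,3,20", "a,2,9,25"), f)
  net <- read_arm_table(f, "binomial")
  expect_equal(net$S, 1L)
  expect_equal(net$T, 2L)
  expect_equal(net$arms$events, c(3L, 9L))
})

test_that("column mapping is configurable and tab separation detected", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("id\ttrt\tr\tN", "s1\t1\t3\t20", "s1\t2\t9\t25"), f)
  net <- read_arm_table(f, "binomial",
                        column_map = list(study = "id", treatment = "trt",
                                          events = "r", n = "N"))
  expect_equal(net$arms$n, c(20L, 25L))
  err <- tryCatch(read_arm_table(f, "binomial"), error = identity)
  expect_s3_class(err, "nmalgm_config_error")
  expect_match(conditionMessage(err), "'study'")
})

test_that("validation rejects malformed arm tables with named rows", {
  base <- data.frame(study = c("a", "a"), treatment = c(1, 2),
                     events = c(3, 9), n = c(20, 25))
  bad <- base; bad$events[2] <- 30
  err <- tryCatch(nma_network(bad, "binomial"), error = identity)
  expect_s3_class(err, "nmalgm_validation_error")
  expect_match(conditionMessage(err), "row 2")
  one_arm <- base[1, ]
  expect_error(nma_network(one_arm, "binomial"), "single arm")
  dup <- base; dup$treatment[2] <- 1
  expect_error(nma_network(dup, "binomial"), "duplicated treatment")
  cont <- data.frame(study = c("a", "a"), treatment = c(1, 2),
                     mean = c(0, 1), sd = c(1, -1), n = c(10, 10))
  expect_error(nma_network(cont, "normal"), "standard deviation")
})

test_that("a disconnected comparison graph warns but still loads", {
  arms <- data.frame(study = c("a", "a", "b", "b"),
                     treatment = c(1, 2, 3, 4),
                     events = c(1, 2, 3, 4), n = rep(20, 4))
  expect_warning(nma_network(arms, "binomial"), "not connected")
})

test_that("design identity is the treatment set, invariant to ordering", {
  net <- simulate_network(small_consistency_topology(11))
  cat1 <- enumerate_designs(net)
  # shuffle arms and trials
  set.seed(99)
  arms <- net$arms[sample(nrow(net$arms)), ]
  net2 <- nma_network(arms, "binomial")
  cat2 <- enumerate_designs(net2)
  expect_equal(nrow(cat1$designs), nrow(cat2$designs))
  expect_equal(nrow(cat1$omega_slots), nrow(cat2$omega_slots))
  expect_setequal(cat1$designs$treatments, cat2$designs$treatments)
  # per design: slots = |treatment set| - 1
  sizes <- lengths(cat1$treatment_sets)
  slots <- table(factor(cat1$omega_slots$design_id,
                        seq_along(cat1$treatment_sets)))
  expect_equal(as.integer(slots), as.integer(sizes) - 1L)
})

test_that("trials with missing covariate are dropped for meta-regression", {
  arms <- do.call(rbind, lapply(1:4, function(i)
    data.frame(study = sprintf("s%d", i), treatment = c(1, 1 + i %% 3 + 1),
               events = c(5, 8), n = c(50, 50),
               covariate = if (i == 3) NA_real_ else 60 + i)))
  net <- nma_network(arms, "binomial")
  expect_equal(net$S, 4L)
  red <- drop_missing_covariate(net)
  expect_equal(red$S, 3L)
  expect_equal(red$dropped_studies, "s3")
  expect_equal(red$covariate_mean, mean(c(61, 62, 64)))
  # the 3-trial remainder is saturated, so the heterogeneity posterior is
  # prior-dominated and the engine says so
  expect_warning(
    fit <- nma_fit(nma_model_spec("metareg-consistency", "binomial"),
                   red),
    "prior boundary|prior-dominated")
  expect_equal(fit$net$S, 3L)
})

test_that("contrast coefficients follow the basic-parameter algebra", {
  net <- make_toy_fixture("toy_s23")
  layout <- build_layout(net, enumerate_designs(net), "consistency")
  co <- contrast_coefficients(2, 3, layout)
  expect_equal(co[["d[1,3]"]], 1)
  expect_equal(co[["d[1,2]"]], -1)
  co1 <- contrast_coefficients(1, 3, layout)
  expect_equal(co1[["d[1,3]"]], 1)
  expect_equal(co1[["d[1,2]"]], 0)
  expect_error(contrast_coefficients(2, 2, layout), "degenerate")
  expect_error(contrast_coefficients(1, 9, layout), "not in network")
})

test_that("latent dimension follows the model-kind slot count", {
  toy <- make_toy_fixture("toy_s23")
  cat <- enumerate_designs(toy)
  # 3 mu + 2 d + 4 gamma + 4 omega
  expect_equal(build_layout(toy, cat, "jackson")$dim, 13L)
  expect_equal(build_layout(toy, cat, "fixed")$dim, toy$S + toy$T - 1L)

  smoking <- smoking_net()
  scat <- enumerate_designs(smoking)
  lay <- build_layout(smoking, scat, "jackson")
  expect_equal(lay$dim, 24L + 3L + 26L + 10L)
  expect_equal(length(lay$gamma_idx), nrow(smoking$arms) - smoking$S)
  # relabeling the reference changes slot names, not the dimension
  lay2 <- build_layout(smoking, scat, "jackson", reference = 3)
  expect_equal(lay2$dim, lay$dim)
  expect_false(identical(lay2$d_names, lay$d_names))
  expect_error(build_layout(toy, cat, "jackson", reference = 7),
               "not in network")
})
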