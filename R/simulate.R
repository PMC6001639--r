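# Simulation of arm-level networks from the generative NMA models.

#' Simulate an arm-level network from the NMA generative model
#'
#' Draws a network from the same hierarchy the engines fit: trial
#' baselines mu_i from a dispersed normal, relative effects d[t1,tk] from
#' the basic parameters, heterogeneity contrasts per trial from
#' [cs_covariance()] with sd `tau`, inconsistency contrasts drawn *once
#' per design* (the defining feature of design-level inconsistency) with
#' sd `kappa`, an optional constant covariate interaction `beta`, and arm
#' outcomes from the chosen family.
#'
#' @param topology list describing the network and truth:
#'   \describe{
#'     \item{designs}{list of `list(treatments =, n_trials =)` entries.}
#'     \item{family}{endpoint family (default `"binomial"`).}
#'     \item{d}{named or positional vector of true basic parameters
#'       d\[1,t\] for every treatment (`d[1] = 0`).}
#'     \item{tau, kappa, beta}{true standard deviations / coefficient
#'       (defaults 0).}
#'     \item{n}{per-arm sample size (binomial/normal; default 100).}
#'     \item{exposure}{per-arm exposure (poisson; default 10).}
#'     \item{arm_sd}{true within-arm sd for the normal family (default 1).}
#'     \item{mu_sd}{sd of the baseline draw (default 1).}
#'     \item{covariate_sd}{sd of the mean-zero trial covariate drawn when
#'       `beta` is nonzero or `covariate = TRUE` (default 1).}
#'     \item{seed}{optional seed; when given the run is reproducible and
#'       the caller's RNG state is untouched.}
#'   }
#' @return An [nma_network()] with attribute `truth`: the drawn `mu`,
#'   `gamma`, `omega`, the true `d`, `tau`, `kappa`, `beta` and trial
#'   covariates.
#' @examples
#' ts <- list(designs = list(list(treatments = c(1, 2), n_trials = 4)),
#'            d = c(0, -0.5), tau = 0.3, seed = 1)
#' net <- simulate_network(ts)
#' attr(net, "truth")$d
#' @export
simulate_network <- function(topology) {
  ts <- topology
  if (is.null(ts$designs) || !length(ts$designs))
    abort_config("topology needs at least one design")
  run <- function() simulate_network_impl(ts)
  if (!is.null(ts$seed)) with_preserved_seed(ts$seed, run()) else run()
}

simulate_network_impl <- function(ts) {
  # exact [[-indexing: `$` would partial-match (e.g. ts$d -> ts$designs)
  family <- normalize_family(ts[["family"]] %||% "binomial")
  treatments <- sort(unique(unlist(lapply(ts[["designs"]], `[[`,
                                          "treatments"))))
  d <- ts[["d"]] %||% setNames(rep(0, length(treatments)), treatments)
  if (is.null(names(d))) names(d) <- treatments
  tau <- ts[["tau"]] %||% 0
  kappa <- ts[["kappa"]] %||% 0
  beta <- ts[["beta"]] %||% 0
  use_cov <- isTRUE(ts[["covariate"]]) || beta != 0
  n_arm <- ts[["n"]] %||% 100L
  exposure <- ts[["exposure"]] %||% 10
  arm_sd <- ts[["arm_sd"]] %||% 1
  mu_sd <- ts[["mu_sd"]] %||% 1
  cov_sd <- ts[["covariate_sd"]] %||% 1

  d_of <- function(t1, tk) d[[as.character(tk)]] - d[[as.character(t1)]]
  draw_cs <- function(sd, p) {
    if (sd == 0) return(rep(0, p))
    if (p == 1L) return(rnorm(1, 0, sd))
    a <- rnorm(1, 0, sd / sqrt(2))
    a + rnorm(p, 0, sd / sqrt(2))
  }

  rows <- list()
  truth <- list(d = d, tau = tau, kappa = kappa, beta = beta,
                mu = numeric(), covariate = numeric(), gamma = list(),
                omega = list())
  s_id <- 0L
  for (di in seq_along(ts$designs)) {
    set <- sort(ts$designs[[di]]$treatments)
    p <- length(set) - 1L
    om <- draw_cs(kappa, p)   # one draw per design, shared by its trials
    truth$omega[[paste(set, collapse = "+")]] <- om
    for (r in seq_len(ts$designs[[di]]$n_trials)) {
      s_id <- s_id + 1L
      study <- sprintf("s%02d", s_id)
      mu <- rnorm(1, 0, mu_sd)
      x <- if (use_cov) rnorm(1, 0, cov_sd) else NA_real_
      gam <- draw_cs(tau, p)
      truth$mu[study] <- mu
      truth$covariate[study] <- x
      truth$gamma[[study]] <- gam
      # interaction is defined against reference treatment 1, so it
      # cancels from contrasts of trials whose baseline is not 1
      cov_term <- if (use_cov) vapply(seq_len(p), function(k)
        x * beta * ((set[k + 1] != 1) - (set[1] != 1)), 0) else 0
      eta <- c(mu, mu + vapply(seq_len(p), function(k)
        d_of(set[1], set[k + 1]), 0) + gam + om + cov_term)
      arm <- data.frame(study = study, treatment = set)
      if (family == "binomial") {
        arm$events <- rbinom(p + 1L, n_arm, plogis(eta))
        arm$n <- n_arm
      } else if (family == "normal") {
        arm$mean <- rnorm(p + 1L, eta, arm_sd / sqrt(n_arm))
        arm$sd <- arm_sd
        arm$n <- n_arm
      } else {
        arm$count <- rpois(p + 1L, exposure * exp(eta))
        arm$exposure <- exposure
      }
      if (use_cov) arm$covariate <- x
      rows[[s_id]] <- arm
    }
  }
  net <- nma_network(do.call(rbind, rows), family)
  attr(net, "truth") <- truth
  net
}

#' Deterministic toy networks
#'
#' Small fixtures with fixed topology and seeded simulated outcomes:
#' `"toy_s23"` is the classic worked inconsistency example (one 3-arm
#' trial with treatments 1,2,3 plus two 2-arm trials 1v2 and 1v3: three
#' designs, four inconsistency slots); `"smoking_like"` matches the shape
#' of the 24-trial smoking-cessation network (4 treatments, two 3-arm
#' trials, 8 designs); `"diabetes_like"` matches the 26-trial diabetes
#' network (10 treatments, one 3-arm trial, 16 designs, continuous
#' endpoints).
#'
#' @param name fixture name.
#' @return An [nma_network()] with simulated outcomes and a `truth`
#'   attribute.
#' @export
make_toy_fixture <- function(name = c("toy_s23", "smoking_like",
                                      "diabetes_like")) {
  name <- match.arg(name)
  des <- function(tr, k) list(treatments = tr, n_trials = k)
  ts <- switch(name,
    toy_s23 = list(
      designs = list(des(c(1, 2, 3), 1), des(c(1, 2), 1),
                     des(c(1, 3), 1)),
      family = "binomial", n = 100L,
      d = c(0, -0.5, -1), tau = 0.3, kappa = 0.1, seed = 230101L),
    smoking_like = list(
      designs = list(des(c(1, 3, 4), 1), des(c(2, 3, 4), 1),
                     des(c(1, 2), 3), des(c(1, 3), 14), des(c(1, 4), 1),
                     des(c(2, 3), 1), des(c(2, 4), 1), des(c(3, 4), 2)),
      family = "binomial", n = 200L,
      d = c(0, 0.5, 0.8, 1.1), tau = 0.8, kappa = 0.4, seed = 420202L),
    diabetes_like = list(
      designs = list(des(c(1, 2, 5), 1), des(c(1, 2), 3),
                     des(c(1, 3), 6), des(c(1, 4), 4), des(c(2, 4), 1),
                     des(c(3, 4), 1), des(c(2, 3), 1), des(c(3, 7), 1),
                     des(c(5, 7), 1), des(c(1, 5), 1), des(c(1, 8), 1),
                     des(c(1, 9), 1), des(c(2, 7), 1), des(c(1, 6), 1),
                     des(c(2, 9), 1), des(c(1, 10), 1)),
      family = "normal", n = 50L, arm_sd = 1.2,
      d = c(0, -1, -1.2, -1, -0.8, -0.9, 0.2, -0.6, -0.7, -0.9),
      tau = 0.33, kappa = 0.12, seed = 260303L))
  simulate_network(ts)
}

#' Write a simulated network (and its truth) to disk
#'
#' The arm table is written in the same delimited long format
#' [read_arm_table()] reads; the truth record as JSON.
#'
#' @param net a simulated [nma_network()] with a `truth` attribute.
#' @param data_path CSV output path for the arm table.
#' @param truth_path optional JSON output path for the truth record.
#' @export
write_network <- function(net, data_path, truth_path = NULL) {
  stopifnot(inherits(net, "nma_network"))
  arms <- net$arms
  map <- default_column_map(net$family)
  out_names <- names(arms)
  for (canon in names(map)) {
    out_names[out_names == canon] <- map[[canon]]
  }
  names(arms) <- out_names
  write.table(arms, data_path, sep = ",", quote = FALSE,
              row.names = FALSE)
  if (!is.null(truth_path)) {
    truth <- attr(net, "truth")
    if (!is.null(truth))
      jsonlite::write_json(truth, truth_path, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
  }
  invisible(data_path)
}
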