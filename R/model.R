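# GLMM assembly: model specification, compound-symmetric random-effect
# structures, the per-arm linear predictor, likelihood families, priors.

#' Specify an NMA model
#'
#' @param model_kind one of `"fixed"`, `"consistency"`, `"jackson"`,
#'   `"metareg-consistency"`, `"metareg-jackson"`.
#' @param endpoint_family `"binomial"`, `"normal"` or `"poisson"`.
#' @param reference reference treatment defining the basic parameters
#'   d\[ref,t\] (and, for meta-regression, the treatment against which the
#'   constant covariate-by-treatment interaction is defined).
#' @param prior_fixed_sd prior standard deviation of the independent
#'   mean-zero normal priors on mu, d and beta; default `sqrt(1000)`.
#' @param tau_prior,kappa_prior bounds `c(lower, upper)` of the uniform
#'   prior on the heterogeneity / inconsistency standard deviation.
#'   `kappa_prior = c(0, 0)` pins the inconsistency variance to zero, which
#'   reduces a Jackson kind to the corresponding consistency kind.
#' @return An object of class `nma_model_spec`.
#' @examples
#' nma_model_spec("jackson", "binomial")
#' @export
nma_model_spec <- function(model_kind = "consistency",
                           endpoint_family = "binomial",
                           reference = 1L,
                           prior_fixed_sd = sqrt(1000),
                           tau_prior = c(0, 5),
                           kappa_prior = c(0, 5)) {
  model_kind <- match.arg(model_kind, MODEL_KINDS)
  family <- normalize_family(endpoint_family)
  check_bounds <- function(b, what) {
    if (length(b) != 2 || !all(is.finite(b)) || b[1] < 0 || b[2] < b[1])
      abort_config(sprintf(
        "%s must be c(lower, upper) with upper >= lower >= 0", what))
  }
  check_bounds(tau_prior, "tau_prior")
  check_bounds(kappa_prior, "kappa_prior")
  if (!is.finite(prior_fixed_sd) || prior_fixed_sd <= 0)
    abort_config("prior_fixed_sd must be positive")
  has_kappa <- kind_has_omega(model_kind) && kappa_prior[2] > 0
  structure(list(model_kind = model_kind,
                 family = family,
                 reference = as.integer(reference),
                 prior_fixed_sd = prior_fixed_sd,
                 tau_prior = tau_prior,
                 kappa_prior = kappa_prior,
                 has_tau = kind_has_gamma(model_kind),
                 has_kappa = has_kappa,
                 kappa_pinned = kind_has_omega(model_kind) && !has_kappa),
            class = "nma_model_spec")
}

#' @export
print.nma_model_spec <- function(x, ...) {
  cat(sprintf("nma_model_spec: %s model, %s, reference treatment %d\n",
              x$model_kind, family_label(x$family), x$reference))
  cat(sprintf("  priors: fixed effects N(0, %.4g^2)", x$prior_fixed_sd))
  if (x$has_tau)
    cat(sprintf("; tau ~ U[%g, %g]", x$tau_prior[1], x$tau_prior[2]))
  if (x$has_kappa)
    cat(sprintf("; kappa ~ U[%g, %g]", x$kappa_prior[1], x$kappa_prior[2]))
  if (x$kappa_pinned) cat("; kappa pinned at 0")
  cat("\n")
  invisible(x)
}

#' Serialize / deserialize a model specification
#'
#' @param spec an [nma_model_spec()].
#' @return `spec_to_list()` returns a plain list suitable for YAML/JSON;
#'   `spec_from_list()` rebuilds the spec from such a list.
#' @export
spec_to_list <- function(spec) {
  list(kind = spec$model_kind, family = spec$family,
       reference = spec$reference,
       prior_fixed_sd = spec$prior_fixed_sd,
       tau_prior = spec$tau_prior, kappa_prior = spec$kappa_prior)
}

#' @rdname spec_to_list
#' @param x a list as produced by `spec_to_list()` (unknown keys rejected).
#' @export
spec_from_list <- function(x) {
  known <- c("kind", "family", "reference", "prior_fixed_sd",
             "tau_prior", "kappa_prior")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    abort_config(sprintf("unknown model config key(s): %s",
                         paste(unknown, collapse = ", ")))
  nma_model_spec(model_kind = x$kind %||% "consistency",
                 endpoint_family = x$family %||% "binomial",
                 reference = x$reference %||% 1L,
                 prior_fixed_sd = x$prior_fixed_sd %||% sqrt(1000),
                 tau_prior = unlist(x$tau_prior %||% c(0, 5)),
                 kappa_prior = unlist(x$kappa_prior %||% c(0, 5)))
}

#' Homogeneous compound-symmetric covariance matrix
#'
#' The Higgins-Whitehead structure for the contrasts of one multi-arm
#' trial (heterogeneity, variance `sd^2`) and for the inconsistency slots
#' of one design: diagonal `sd^2`, off-diagonal `sd^2 / 2`.
#'
#' @param sd standard deviation (tau or kappa).
#' @param dim number of contrasts (arms - 1, or design size - 1).
#' @return A `dim` x `dim` positive-definite matrix.
#' @examples
#' cs_covariance(2, 2)
#' @export
cs_covariance <- function(sd, dim) {
  stopifnot(sd > 0, dim >= 1)
  m <- matrix(sd^2 / 2, dim, dim)
  diag(m) <- sd^2
  m
}

#' Shared + idiosyncratic decomposition of a compound-symmetric effect
#'
#' A vector with covariance [cs_covariance()] can be written exactly as
#' `effect_k = a + b_k` with independent `a, b_k ~ N(0, sd^2 / 2)`: the
#' shared component induces the `sd^2/2` covariance and the idiosyncratic
#' one tops the variance up to `sd^2`.  For a single contrast (`dim = 1`)
#' one component with the full variance suffices.  This decomposition is
#' what makes the latent prior precision diagonal in both engines.
#'
#' @param dim number of contrasts in the group.
#' @return Data frame with one row per internal component: `component`
#'   (`"shared"`, `"idio"` or `"single"`), `contrast` (which contrast the
#'   component loads on, `NA` for the shared one) and `var_factor` (the
#'   component variance as a multiple of `sd^2`).
#' @examples
#' cs_decompose(2)   # 3-arm trial: shared + two idiosyncratic components
#' @export
cs_decompose <- function(dim) {
  stopifnot(dim >= 1)
  if (dim == 1L)
    return(data.frame(component = "single", contrast = 1L, var_factor = 1))
  rbind(data.frame(component = "shared", contrast = NA_integer_,
                   var_factor = 0.5),
        data.frame(component = "idio", contrast = seq_len(dim),
                   var_factor = 0.5))
}

# Covariance over a group's contrasts implied by cs_decompose; used in
# tests to confirm exact equality with cs_covariance.
cs_implied_covariance <- function(sd, dim) {
  dec <- cs_decompose(dim)
  L <- matrix(0, dim, nrow(dec))
  for (j in seq_len(nrow(dec)))
    if (dec$component[j] == "shared") L[, j] <- 1 else
      L[dec$contrast[j], j] <- 1
  L %*% diag(dec$var_factor * sd^2, nrow(dec)) %*% t(L)
}

#' Assemble the per-arm predictor of an NMA model
#'
#' Builds the incidence matrix `X` mapping the internal latent components
#' to the per-arm linear predictor: a baseline arm touches only its trial
#' effect mu; a non-baseline arm adds the contrast coefficients of
#' d\[t1,tk\] over the basic parameters, its heterogeneity components, its
#' design's inconsistency components (Jackson kinds) and the centered
#' covariate times the interaction coefficient (meta-regression kinds,
#' with coefficient `(x - xbar) * (1[tk != ref] - 1[t1 != ref])` so that
#' contrasts between two non-reference treatments are free of beta).
#'
#' @param net an [nma_network()].
#' @param layout an [build_layout()] layout (its model kind decides which
#'   blocks are present).
#' @param cat design catalogue; recomputed when `NULL`.
#' @return List of class `nma_assembly`: `X` (arms x components), `arms`
#'   (bookkeeping data frame with `study`, `treatment`, `baseline`), and
#'   the outcome vectors `y`, `size`, `scale2` used by the likelihood
#'   (`size` is `n` or exposure; `scale2` the known variance `sd^2/n` of a
#'   normal arm mean).
#' @export
build_assembly <- function(net, layout, cat = NULL) {
  stopifnot(inherits(net, "nma_network"), inherits(layout, "nma_layout"))
  kind <- layout$model_kind
  if (is.null(cat) && kind_has_omega(kind)) cat <- enumerate_designs(net)
  A <- net$arms
  N <- nrow(A)
  X <- matrix(0, N, layout$ncomp,
              dimnames = list(NULL, layout$components$name))
  ref <- layout$reference
  xbar <- net$covariate_mean
  baseline <- logical(N)
  idx <- split(seq_len(N), factor(A$study, net$studies))
  for (s in net$studies) {
    rows <- idx[[s]]
    tr <- A$treatment[rows]
    t1 <- tr[1L]
    baseline[rows[1L]] <- TRUE
    X[rows, sprintf("mu[%s]", s)] <- 1
    p <- length(tr) - 1L
    for (k in 2:length(tr)) {
      r <- rows[k]; tk <- tr[k]
      if (tk != ref) X[r, sprintf("d[%d,%d]", ref, tk)] <- 1
      if (t1 != ref) X[r, sprintf("d[%d,%d]", ref, t1)] <- -1
      if (kind_has_gamma(kind)) {
        if (p == 1L) X[r, sprintf("gamma.c[%s]", s)] <- 1
        else {
          X[r, sprintf("gamma.a[%s]", s)] <- 1
          X[r, sprintf("gamma.b[%s,%d]", s, tk)] <- 1
        }
      }
      if (kind_has_omega(kind)) {
        d <- cat$trial_design[[s]]
        set <- cat$treatment_sets[[d]]
        if (length(set) == 2L) X[r, sprintf("omega.c[%d]", d)] <- 1
        else {
          X[r, sprintf("omega.a[%d]", d)] <- 1
          X[r, sprintf("omega.b[%d,%d]", d, tk)] <- 1
        }
      }
      if (kind_has_beta(kind)) {
        x <- A$covariate[r]
        X[r, "beta"] <- (x - xbar) *
          ((tk != ref) - (t1 != ref))
      }
    }
  }
  fam <- net$family
  out <- list(X = X,
              arms = data.frame(study = A$study, treatment = A$treatment,
                                baseline = baseline),
              family = fam)
  if (fam == "binomial") {
    out$y <- A$events; out$size <- A$n; out$scale2 <- rep(NA_real_, N)
  } else if (fam == "normal") {
    out$y <- A$mean; out$size <- A$n; out$scale2 <- A$sd^2 / A$n
  } else {
    out$y <- A$count; out$size <- A$exposure
    out$scale2 <- rep(NA_real_, N)
  }
  class(out) <- "nma_assembly"
  out
}

#' Evaluate the per-arm linear predictor
#'
#' @param alpha latent component vector (length `ncol(assembly$X)`).
#' @param assembly an [build_assembly()] object.
#' @return Numeric vector with one linear-predictor value per arm.
#' @export
linear_predictor <- function(alpha, assembly) {
  stopifnot(inherits(assembly, "nma_assembly"))
  if (length(alpha) != ncol(assembly$X))
    abort_validation(sprintf(
      "latent vector has length %d; assembly expects %d",
      length(alpha), ncol(assembly$X)))
  drop(assembly$X %*% alpha)
}

# Full log-likelihood (normalizing constants included) plus its first and
# negated second derivative w.r.t. eta, as used by the Newton iterations.
loglik_parts <- function(assembly, eta, deriv = TRUE) {
  if (any(!is.finite(eta)))
    abort_validation("non-finite linear predictor")
  fam <- assembly$family
  y <- assembly$y
  if (fam == "binomial") {
    n <- assembly$size
    pi <- plogis(eta)
    ll <- sum(dbinom(y, n, pi, log = TRUE))
    if (!deriv) return(list(ll = ll))
    list(ll = ll, u = y - n * pi, w = n * pi * (1 - pi))
  } else if (fam == "normal") {
    v <- assembly$scale2
    ll <- sum(dnorm(y, eta, sqrt(v), log = TRUE))
    if (!deriv) return(list(ll = ll))
    list(ll = ll, u = (y - eta) / v, w = 1 / v)
  } else {
    lambda <- assembly$size * exp(eta)
    ll <- sum(dpois(y, lambda, log = TRUE))
    if (!deriv) return(list(ll = ll))
    list(ll = ll, u = y - lambda, w = lambda)
  }
}

#' Arm-based log-likelihood of a network at a given linear predictor
#'
#' Binomial arms use `pi = plogis(eta)`, normal arms model the arm mean
#' with known standard error `sd/sqrt(n)`, Poisson arms use rate
#' `exposure * exp(eta)`.  Normalizing constants are included.
#'
#' @param net an [nma_network()].
#' @param eta per-arm linear predictor (in arm order of `net$arms`).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(net, eta) {
  stopifnot(inherits(net, "nma_network"))
  if (length(eta) != nrow(net$arms))
    abort_validation("eta length does not match the number of arms")
  asm <- list(family = net$family)
  A <- net$arms
  if (net$family == "binomial") {
    asm$y <- A$events; asm$size <- A$n
  } else if (net$family == "normal") {
    asm$y <- A$mean; asm$scale2 <- A$sd^2 / A$n
  } else {
    asm$y <- A$count; asm$size <- A$exposure
  }
  loglik_parts(asm, eta, deriv = FALSE)$ll
}

# Per-component prior precision at given hyperparameters.
comp_precisions <- function(layout, spec, hp) {
  cls <- layout$components$class
  mult <- layout$components$mult
  p <- numeric(layout$ncomp)
  p[cls == "fixed"] <- 1 / spec$prior_fixed_sd^2
  if (any(cls == "tau")) {
    if (is.null(hp$tau)) abort_validation("tau required but not supplied")
    p[cls == "tau"] <- mult[cls == "tau"] / hp$tau^2
  }
  if (any(cls == "kappa")) {
    if (is.null(hp$kappa))
      abort_validation("kappa required but not supplied")
    p[cls == "kappa"] <- mult[cls == "kappa"] / hp$kappa^2
  }
  p
}

#' Log prior density of the latent components and of the hyperparameters
#'
#' The latent prior is mean-zero Gaussian: `prior_fixed_sd` for mu, d and
#' beta, and the [cs_decompose()] component variances (`tau^2/2` or
#' `tau^2`, resp. kappa) for the random effects.  The hyperparameter prior
#' is uniform on the standard-deviation scale.
#'
#' @param alpha latent component vector.
#' @param hp list with elements `tau` and/or `kappa`.
#' @param spec an [nma_model_spec()].
#' @param layout an [build_layout()] layout.
#' @return Scalar log density (`-Inf` outside the prior support).
#' @export
log_prior_latent <- function(alpha, hp, spec, layout) {
  p <- comp_precisions(layout, spec, hp)
  sum(dnorm(alpha, 0, sqrt(1 / p), log = TRUE))
}

#' @rdname log_prior_latent
#' @export
log_prior_hyper <- function(hp, spec) {
  lp <- 0
  if (spec$has_tau) {
    b <- spec$tau_prior
    if (is.null(hp$tau) || hp$tau < b[1] || hp$tau > b[2]) return(-Inf)
    lp <- lp - log(b[2] - b[1])
  }
  if (spec$has_kappa) {
    b <- spec$kappa_prior
    if (is.null(hp$kappa) || hp$kappa < b[1] || hp$kappa > b[2])
      return(-Inf)
    lp <- lp - log(b[2] - b[1])
  }
  lp
}
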