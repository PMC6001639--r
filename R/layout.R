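# Latent parameter layout: mapping model symbols (mu, d_b, beta, gamma,
# omega) onto one latent vector.
#
# Internally the compound-symmetric random effects are stored in a
# decomposed "shared + idiosyncratic" parametrization (see cs_decompose),
# which makes the latent prior precision diagonal.  The layout therefore
# distinguishes the *reported* parameters (mu, d_b, beta, one gamma per
# non-baseline arm, one omega per inconsistency slot) from the *internal
# components*; the `report` matrix maps components to reported parameters.

MODEL_KINDS <- c("fixed", "consistency", "jackson",
                 "metareg-consistency", "metareg-jackson")

kind_has_gamma <- function(kind) kind != "fixed"
kind_has_omega <- function(kind) kind %in% c("jackson", "metareg-jackson")
kind_has_beta  <- function(kind) startsWith(kind, "metareg")

#' Coefficients of a treatment contrast over the basic parameters
#'
#' Every relative effect in a consistent network is a linear combination of
#' the basic parameters d\[ref,t\]: d\[t1,tk\] = d\[ref,tk\] - d\[ref,t1\],
#' with the reference slot contributing 0.
#'
#' @param t1,tk treatments to contrast (effect of `tk` relative to `t1`).
#' @param layout an [build_layout()] object.
#' @return Named numeric vector over the basic-parameter slots (length
#'   `T - 1`), zero except for the +1/-1 coefficients.
#' @examples
#' net <- make_toy_fixture("toy_s23")
#' layout <- build_layout(net, enumerate_designs(net), "consistency")
#' contrast_coefficients(2, 3, layout)
#' @export
contrast_coefficients <- function(t1, tk, layout) {
  stopifnot(inherits(layout, "nma_layout"))
  if (t1 == tk)
    abort_validation("degenerate contrast: t1 == tk")
  for (t in c(t1, tk))
    if (!t %in% layout$treatments)
      abort_validation(sprintf("treatment %s not in network", t))
  co <- setNames(numeric(length(layout$d_names)), layout$d_names)
  ref <- layout$reference
  if (tk != ref) co[sprintf("d[%d,%d]", ref, tk)] <- 1
  if (t1 != ref) co[sprintf("d[%d,%d]", ref, t1)] <- -1
  co
}

#' Lay out the latent vector of an NMA model
#'
#' Builds the index map from model symbols to the latent vector: one
#' baseline effect mu per trial, `T - 1` basic parameters d\[ref,t\], an
#' optional interaction coefficient beta, one heterogeneity effect gamma
#' per non-baseline arm (all random-effects kinds), and one inconsistency
#' effect omega per design slot (Jackson kinds).  The reported latent
#' dimension is `S + (T-1) + [beta] + sum(arms_i - 1) + n_omega_slots`.
#'
#' @param net an [nma_network()].
#' @param cat design catalogue from [enumerate_designs()] (required for
#'   Jackson kinds; recomputed when `NULL`).
#' @param model_kind one of `"fixed"`, `"consistency"`, `"jackson"`,
#'   `"metareg-consistency"`, `"metareg-jackson"`.
#' @param reference reference treatment for the basic parameters.
#' @return An object of class `nma_layout` with, among others, `dim` (the
#'   reported latent dimension), `par` (data frame describing the reported
#'   parameters), `components` (data frame describing the internal
#'   components and their precision class: `fixed`, `tau` or `kappa`),
#'   `report` (matrix mapping internal components to reported parameters)
#'   and index vectors `mu_idx`, `d_idx`, `beta_idx`, `gamma_idx`,
#'   `omega_idx` into the reported rows.
#' @export
build_layout <- function(net, cat = NULL, model_kind = "consistency",
                         reference = 1L) {
  stopifnot(inherits(net, "nma_network"))
  model_kind <- match.arg(model_kind, MODEL_KINDS)
  reference <- as.integer(reference)
  if (!reference %in% net$treatments)
    abort_validation(sprintf("reference treatment %d not in network",
                             reference))
  if (kind_has_beta(model_kind) && !net$has_covariate)
    abort_config("meta-regression requested but no covariate in the data")
  if (is.null(cat)) cat <- enumerate_designs(net)

  par <- list()     # reported parameters
  comp <- list()    # internal components
  rmap <- list()    # per reported parameter: internal component names + coefs

  add_par <- function(name, type, comps, coefs = rep(1, length(comps))) {
    par[[length(par) + 1L]] <<- data.frame(name = name, type = type)
    rmap[[name]] <<- list(comps = comps, coefs = coefs)
  }
  add_comp <- function(name, class, mult) {
    comp[[length(comp) + 1L]] <<-
      data.frame(name = name, class = class, mult = mult)
  }

  for (s in net$studies) {
    nm <- sprintf("mu[%s]", s)
    add_comp(nm, "fixed", 1)
    add_par(nm, "mu", nm)
  }
  d_names <- sprintf("d[%d,%d]", reference,
                     setdiff(net$treatments, reference))
  for (nm in d_names) {
    add_comp(nm, "fixed", 1)
    add_par(nm, "d", nm)
  }
  if (kind_has_beta(model_kind)) {
    add_comp("beta", "fixed", 1)
    add_par("beta", "beta", "beta")
  }

  per_trial <- split(net$arms$treatment, factor(net$arms$study, net$studies))
  if (kind_has_gamma(model_kind)) {
    for (s in net$studies) {
      tr <- per_trial[[s]]
      p <- length(tr) - 1L
      if (p == 1L) {
        cn <- sprintf("gamma.c[%s]", s)
        add_comp(cn, "tau", 1)
        add_par(sprintf("gamma[%s,%d,%d]", s, tr[1L], tr[2L]),
                "gamma", cn)
      } else {
        shared <- sprintf("gamma.a[%s]", s)
        add_comp(shared, "tau", 2)
        for (k in 2:length(tr)) {
          idio <- sprintf("gamma.b[%s,%d]", s, tr[k])
          add_comp(idio, "tau", 2)
          add_par(sprintf("gamma[%s,%d,%d]", s, tr[1L], tr[k]),
                  "gamma", c(shared, idio))
        }
      }
    }
  }
  if (kind_has_omega(model_kind)) {
    for (d in seq_along(cat$treatment_sets)) {
      set <- cat$treatment_sets[[d]]
      p <- length(set) - 1L
      if (p == 1L) {
        cn <- sprintf("omega.c[%d]", d)
        add_comp(cn, "kappa", 1)
        add_par(sprintf("omega[%d,%d,%d]", d, set[1L], set[2L]),
                "omega", cn)
      } else {
        shared <- sprintf("omega.a[%d]", d)
        add_comp(shared, "kappa", 2)
        for (k in 2:length(set)) {
          idio <- sprintf("omega.b[%d,%d]", d, set[k])
          add_comp(idio, "kappa", 2)
          add_par(sprintf("omega[%d,%d,%d]", d, set[1L], set[k]),
                  "omega", c(shared, idio))
        }
      }
    }
  }

  par <- do.call(rbind, par)
  comp <- do.call(rbind, comp)
  report <- matrix(0, nrow(par), nrow(comp),
                   dimnames = list(par$name, comp$name))
  for (nm in par$name) {
    m <- rmap[[nm]]
    report[nm, m$comps] <- m$coefs
  }

  structure(list(model_kind = model_kind,
                 reference = reference,
                 treatments = net$treatments,
                 studies = net$studies,
                 d_names = d_names,
                 par = par,
                 components = comp,
                 report = report,
                 dim = nrow(par),
                 ncomp = nrow(comp),
                 mu_idx = which(par$type == "mu"),
                 d_idx = which(par$type == "d"),
                 beta_idx = which(par$type == "beta"),
                 gamma_idx = which(par$type == "gamma"),
                 omega_idx = which(par$type == "omega")),
            class = "nma_layout")
}

#' @export
print.nma_layout <- function(x, ...) {
  cat(sprintf(paste0("nma_layout (%s, reference %d): dim %d ",
                     "(%d mu, %d d, %d beta, %d gamma, %d omega); ",
                     "%d internal components\n"),
              x$model_kind, x$reference, x$dim,
              length(x$mu_idx), length(x$d_idx), length(x$beta_idx),
              length(x$gamma_idx), length(x$omega_idx), x$ncomp))
  invisible(x)
}

# Row over internal components for a reported parameter or an arbitrary
# linear functional of the basic parameters.
report_row <- function(layout, name) {
  layout$report[name, , drop = TRUE]
}
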