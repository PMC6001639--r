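# Arm-level network data: reading, validation, design enumeration.

FAMILIES <- c("binomial", "normal", "poisson")

normalize_family <- function(endpoint_family) {
  x <- match.arg(tolower(endpoint_family),
                 c(FAMILIES, "binomial-logit", "normal-identity",
                   "poisson-log"))
  sub("-.*$", "", x)
}

family_label <- function(family) {
  switch(family,
         binomial = "binomial (logit link)",
         normal   = "normal (identity link)",
         poisson  = "Poisson (log link)")
}

payload_columns <- function(family) {
  switch(family,
         binomial = c("events", "n"),
         normal   = c("mean", "sd", "n"),
         poisson  = c("count", "exposure"))
}

default_column_map <- function(family) {
  base <- list(study = "study", treatment = "treatment")
  c(base, switch(family,
                 binomial = list(events = "responders", n = "sampleSize"),
                 normal   = list(mean = "mean", sd = "std.dev",
                                 n = "sampleSize"),
                 poisson  = list(count = "responders",
                                 exposure = "exposure")))
}

#' Construct a validated arm-level NMA network
#'
#' An `nma_network` holds one row per trial arm with the outcome payload of
#' one endpoint family: `(events, n)` for dichotomous, `(mean, sd, n)` for
#' continuous, `(count, exposure)` for count data, plus an optional
#' trial-level covariate.  Within each trial, arms are ordered so that the
#' lowest-numbered treatment comes first and acts as the trial baseline.
#'
#' @param arms data frame with columns `study`, `treatment`, the payload
#'   columns of `endpoint_family`, and optionally `covariate`.
#' @param endpoint_family `"binomial"`, `"normal"` or `"poisson"` (the
#'   long forms `"binomial-logit"` etc. are accepted).
#' @return An object of class `nma_network`: a list with elements `arms`
#'   (canonical data frame), `family`, `S` (number of trials), `T` (number
#'   of distinct treatments), `treatments`, `has_covariate` and
#'   `covariate_mean` (mean over trials with a non-missing covariate).
#' @examples
#' arms <- data.frame(study = c("s1", "s1"), treatment = c(1, 2),
#'                    events = c(5, 9), n = c(50, 50))
#' net <- nma_network(arms, "binomial")
#' @export
nma_network <- function(arms, endpoint_family) {
  family <- normalize_family(endpoint_family)
  arms <- as.data.frame(arms)
  need <- c("study", "treatment", payload_columns(family))
  missing_cols <- setdiff(need, names(arms))
  if (length(missing_cols))
    abort_config(sprintf("missing column(s) for %s data: %s",
                         family, paste(missing_cols, collapse = ", ")))
  has_cov <- "covariate" %in% names(arms) &&
    any(!is.na(arms$covariate))
  arms <- arms[, c(need, if (has_cov) "covariate")]
  arms$study <- as.character(arms$study)
  if (any(is.na(arms$study)))
    abort_validation("missing study identifier")
  tr <- arms$treatment
  if (any(is.na(tr)) || any(tr != round(tr)) || any(tr < 1))
    abort_validation("treatment ids must be positive integers")
  arms$treatment <- as.integer(round(tr))

  bad_row <- function(cond, what) {
    if (any(cond, na.rm = TRUE) || anyNA(cond)) {
      i <- which(cond | is.na(cond))[1L]
      abort_validation(sprintf(
        "%s in row %d (study %s, treatment %d)", what, i,
        arms$study[i], arms$treatment[i]))
    }
  }
  if (family == "binomial") {
    bad_row(!(arms$n >= 1 & arms$n == round(arms$n)),
            "sample size must be a positive integer")
    bad_row(!(arms$events >= 0 & arms$events == round(arms$events)),
            "event count must be a non-negative integer")
    bad_row(!(arms$events <= arms$n), "events exceed sample size")
  } else if (family == "normal") {
    bad_row(!is.finite(arms$mean), "non-finite arm mean")
    bad_row(!(arms$sd > 0), "standard deviation must be positive")
    bad_row(!(arms$n >= 1), "sample size must be positive")
  } else {
    bad_row(!(arms$count >= 0 & arms$count == round(arms$count)),
            "event count must be a non-negative integer")
    bad_row(!(arms$exposure > 0), "exposure must be positive")
  }

  # Preserve trial order of first appearance; baseline = lowest treatment.
  study_order <- unique(arms$study)
  arms <- arms[order(match(arms$study, study_order), arms$treatment), ,
               drop = FALSE]
  rownames(arms) <- NULL

  per_trial <- split(arms$treatment, factor(arms$study, study_order))
  n_arms <- lengths(per_trial)
  if (any(n_arms < 2))
    abort_validation(sprintf("trial(s) with a single arm: %s",
                             paste(names(per_trial)[n_arms < 2],
                                   collapse = ", ")))
  dup <- vapply(per_trial, anyDuplicated, 0L) > 0L
  if (any(dup))
    abort_validation(sprintf("duplicated treatment within trial(s): %s",
                             paste(names(per_trial)[dup], collapse = ", ")))
  if (has_cov) {
    cv <- split(arms$covariate, factor(arms$study, study_order))
    varies <- vapply(cv, function(x) length(unique(x)) > 1L, TRUE)
    if (any(varies))
      abort_validation(sprintf(
        "covariate varies within trial(s): %s",
        paste(names(cv)[varies], collapse = ", ")))
  }

  treatments <- sort(unique(arms$treatment))
  if (!network_connected(per_trial, treatments))
    warning("treatment comparison graph is not connected; ",
            "contrasts across components are not estimable from the data",
            call. = FALSE)

  covariate_mean <- NA_real_
  if (has_cov) {
    per_trial_cov <- vapply(split(arms$covariate,
                                  factor(arms$study, study_order)),
                            function(x) x[1L], 0)
    covariate_mean <- mean(per_trial_cov, na.rm = TRUE)
  }

  structure(list(arms = arms,
                 family = family,
                 S = length(study_order),
                 T = length(treatments),
                 studies = study_order,
                 treatments = treatments,
                 has_covariate = has_cov,
                 covariate_mean = covariate_mean),
            class = "nma_network")
}

# Union-find connectivity over the treatment comparison graph.
network_connected <- function(per_trial, treatments) {
  parent <- seq_along(treatments)
  idx <- function(t) match(t, treatments)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (tr in per_trial) {
    a <- idx(tr[1L])
    for (t in tr[-1L]) {
      ra <- find(a); rb <- find(idx(t))
      if (ra != rb) parent[rb] <- ra
    }
  }
  length(unique(vapply(seq_along(treatments), find, 0L))) == 1L
}

#' @export
print.nma_network <- function(x, ...) {
  cat(sprintf("nma_network: %d trials, %d treatments, %d arms; %s\n",
              x$S, x$T, nrow(x$arms), family_label(x$family)))
  if (x$has_covariate)
    cat(sprintf("  trial-level covariate present (mean %.4g over %d trials)\n",
                x$covariate_mean,
                sum(!is.na(trial_covariates(x)))))
  invisible(x)
}

# Covariate value per trial (NA when absent), in trial order.
trial_covariates <- function(net) {
  if (!net$has_covariate) return(rep(NA_real_, net$S))
  vapply(split(net$arms$covariate, factor(net$arms$study, net$studies)),
         function(x) x[1L], 0)
}

#' Read an arm-level NMA dataset from delimited text
#'
#' Reads long-format data (one row per trial arm) from a comma- or
#' tab-delimited file with a header.  Column names are configurable through
#' `column_map`; defaults follow common supplementary-table conventions:
#' dichotomous `study, treatment, responders, sampleSize`; continuous
#' `study, treatment, mean, std.dev, sampleSize`; count
#' `study, treatment, responders, exposure`.
#'
#' @param path file path.
#' @param endpoint_family endpoint family, see [nma_network()].
#' @param column_map named list overriding the default file-column names;
#'   recognized keys are `study`, `treatment`, `events`, `n`, `mean`, `sd`,
#'   `count`, `exposure` and `covariate`.  Supply `covariate` to read a
#'   trial-level covariate column.
#' @return An [nma_network()].
#' @export
read_arm_table <- function(path, endpoint_family, column_map = list()) {
  family <- normalize_family(endpoint_family)
  if (!file.exists(path))
    abort_config(sprintf("data file not found: %s", path))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
  map <- default_column_map(family)
  unknown <- setdiff(names(column_map), c(names(map), "covariate"))
  if (length(unknown))
    abort_config(sprintf("unknown column_map key(s): %s",
                         paste(unknown, collapse = ", ")))
  map[names(column_map)] <- column_map
  canon <- c("study", "treatment", payload_columns(family),
             if (!is.null(map$covariate)) "covariate")
  out <- list()
  for (col in canon) {
    src <- map[[col]]
    if (!src %in% names(raw))
      abort_config(sprintf("column '%s' (mapped from '%s') not found in %s",
                           src, col, path))
    out[[col]] <- raw[[src]]
  }
  nma_network(as.data.frame(out, stringsAsFactors = FALSE), family)
}

#' Drop trials with a missing covariate value
#'
#' Network meta-regression needs a covariate value for every trial; trials
#' without one are removed and the covariate mean is recomputed over the
#' retained trials.  The removed study labels are recorded in the
#' `dropped_studies` element.
#'
#' @param net an [nma_network()].
#' @return The reduced network (equal to `net` when nothing is missing).
#' @export
drop_missing_covariate <- function(net) {
  stopifnot(inherits(net, "nma_network"))
  if (!net$has_covariate)
    abort_config("network has no covariate column")
  cov <- trial_covariates(net)
  drop <- net$studies[is.na(cov)]
  if (!length(drop)) {
    net$dropped_studies <- character()
    return(net)
  }
  keep <- !(net$arms$study %in% drop)
  out <- nma_network(net$arms[keep, , drop = FALSE], net$family)
  out$dropped_studies <- drop
  out
}

#' Enumerate the designs of a network
#'
#' A *design* is the set of treatments compared in a trial; trials whose
#' treatment sets are identical share a design.  Each design carries
#' `|design| - 1` slots for design-specific inconsistency random effects,
#' one per contrast of a non-baseline treatment against the design baseline
#' (the lowest-numbered treatment in the set).
#'
#' @param net an [nma_network()].
#' @return An object of class `nma_designs`: list with `designs` (data
#'   frame: `design_id`, `treatments` as a `+`-separated string,
#'   `n_trials`), `trial_design` (named integer vector: study ->
#'   design_id), `treatment_sets` (list of integer vectors) and
#'   `omega_slots` (data frame: `design_id`, `t_base`, `t_k`, `name`).
#' @examples
#' net <- make_toy_fixture("toy_s23")
#' enumerate_designs(net)
#' @export
enumerate_designs <- function(net) {
  stopifnot(inherits(net, "nma_network"))
  per_trial <- split(net$arms$treatment,
                     factor(net$arms$study, net$studies))
  keys <- vapply(per_trial, function(t) paste(sort(t), collapse = "+"), "")
  first <- !duplicated(keys)
  design_keys <- keys[first]
  trial_design <- setNames(match(keys, design_keys), net$studies)
  sets <- lapply(strsplit(design_keys, "+", fixed = TRUE), as.integer)
  slots <- do.call(rbind, lapply(seq_along(sets), function(d) {
    s <- sets[[d]]
    data.frame(design_id = d, t_base = s[1L], t_k = s[-1L])
  }))
  slots$name <- sprintf("omega[%d,%d,%d]",
                        slots$design_id, slots$t_base, slots$t_k)
  structure(list(
    designs = data.frame(design_id = seq_along(sets),
                         treatments = design_keys,
                         n_trials = as.integer(table(factor(
                           trial_design, seq_along(sets))))),
    trial_design = trial_design,
    treatment_sets = sets,
    omega_slots = slots), class = "nma_designs")
}

#' @export
print.nma_designs <- function(x, ...) {
  cat(sprintf("nma_designs: %d designs, %d inconsistency slots\n",
              nrow(x$designs), nrow(x$omega_slots)))
  print(x$designs, row.names = FALSE)
  invisible(x)
}

#' Write a design catalogue as delimited text
#'
#' @param cat an [enumerate_designs()] catalogue.
#' @param path output file path (tab-separated).
#' @export
write_designs <- function(cat, path) {
  stopifnot(inherits(cat, "nma_designs"))
  write.table(cat$designs, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
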