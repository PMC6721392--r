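# Synthetic-cohort generator. Each continuous variable is drawn from a
# normal distribution restricted to its plausible range by inverse-CDF
# sampling; the location of the underlying normal is calibrated so that the
# mean of the RESTRICTED distribution equals the configured group mean.
# Naive truncation would bias means wherever a bound sits within a few SD of
# the target (e.g. Ptau in mixed dementia, bounded at 0).

.truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- pnorm(b) - pnorm(a)
  mu + sd * (dnorm(a) - dnorm(b)) / z
}

# Location mu of N(mu, sd) such that the [lo, hi]-truncated mean equals
# `target`. Monotone in mu, so a bracketed root always exists when
# lo < target < hi.
.calibrate_location <- function(target, sd, lo, hi) {
  if (sd == 0) return(target)
  if (!is.finite(lo) && !is.finite(hi)) return(target)
  f <- function(mu) .truncnorm_mean(mu, sd, lo, hi) - target
  lower <- target - 8 * sd
  upper <- target + 8 * sd
  uniroot(f, lower = lower, upper = upper, tol = 1e-10)$root
}

# Inverse-CDF draw from N(mu, sd) restricted to [lo, hi]; consumes exactly n
# uniforms, which keeps the RNG stream length fixed and runs deterministic.
.rtruncnorm <- function(n, mu, sd, lo, hi) {
  if (sd == 0) return(rep(mu, n))
  pa <- pnorm(lo, mu, sd)
  pb <- pnorm(hi, mu, sd)
  if (pb - pa < 1e-12) {
    abort("requested distribution has negligible mass inside its bounds",
          class = "mixstrat_input_error")
  }
  qnorm(runif(n, pa, pb), mu, sd)
}

# Draws n records from the current RNG stream (no reseeding); fixed variable
# order so generation is reproducible.
.draw_group <- function(params, n) {
  cont <- lapply(.continuous_vars, function(v) {
    b <- .variable_bounds[[v]]
    mu <- .calibrate_location(params$means[[v]], params$sds[[v]], b[1], b[2])
    .rtruncnorm(n, mu, params$sds[[v]], b[1], b[2])
  })
  names(cont) <- .continuous_vars
  bin <- lapply(.binary_vars, function(v) runif(n) < params$probs[[v]])
  names(bin) <- .binary_vars
  tibble(
    patient_id = if (n > 0) sprintf("%s-%04d", params$label, seq_len(n)) else character(),
    biological_label = rep(params$label, n),
    clinical_label = rep(params$label, n),
    !!!cont,
    !!!bin
  )
}

#' Generate synthetic patient records for one diagnostic group
#'
#' Draws `n` independent records from the group's generative model: each
#' continuous variable from a range-restricted normal whose restricted mean
#' equals the configured mean, each binary clinical sign from a Bernoulli.
#' Variables are generated independently within a group (no published
#' covariances; see the methods vignette). `biological_label` and
#' `clinical_label` are both set to the group label; clinical-label
#' perturbation happens at the cohort level ([generate_cohort()]).
#'
#' @param params A [group_params()] object.
#' @param n Number of records (>= 0).
#' @param seed Integer seed; the same `(params, n, seed)` always yields an
#'   identical table. The caller's RNG state is left untouched.
#' @return Tibble with one row per record: `patient_id`, `biological_label`,
#'   `clinical_label`, the thirteen continuous variables and four logical
#'   sign flags.
#' @examples
#' g <- generate_group(default_group_params()$MX, 5, seed = 1)
#' g$ptau
#' @export
generate_group <- function(params, n, seed) {
  if (!inherits(params, "group_params")) {
    abort("`params` must be a group_params object", class = "mixstrat_input_error")
  }
  if (!(is.numeric(n) && length(n) == 1L && is.finite(n) && n >= 0 &&
        n == as.integer(n))) {
    abort("`n` must be a single non-negative integer", class = "mixstrat_input_error")
  }
  if (!(is.numeric(seed) && length(seed) == 1L && is.finite(seed))) {
    abort("`seed` must be a single finite integer", class = "mixstrat_input_error")
  }
  withr::with_seed(as.integer(seed), .draw_group(params, as.integer(n)))
}

#' Default clinical-label confusion matrix
#'
#' Row-stochastic matrix giving P(clinical label | biological label). The
#' default is the identity except for the mixed-dementia row: patients whose
#' biology is dual-pathology are frequently called AD or SIVD in the clinic,
#' so biological MX maps to clinical SIVD/AD/MX with probabilities
#' 0.27/0.36/0.37. These values are a documented choice that makes the
#' expected clinical margins of a cohort at the published biological group
#' sizes approximate the published clinical counts; they are not fitted.
#'
#' @return Square numeric matrix over [diagnosis_labels()], rows biological,
#'   columns clinical, each row summing to 1.
#' @export
default_confusion_matrix <- function() {
  labs <- diagnosis_labels()
  m <- diag(length(labs))
  dimnames(m) <- list(biological = labs, clinical = labs)
  m["MX", ] <- 0
  m["MX", c("SIVD", "AD", "MX")] <- c(0.27, 0.36, 0.37)
  m
}

#' Cohort-level generator configuration
#'
#' @param sizes Named non-negative integer vector of per-group sizes; names
#'   must be a subset of [diagnosis_labels()] (absent groups count 0). The
#'   default is the published biological distribution of the 147-patient
#'   cohort (SIVD 53, AD 25, MX 22, MI 18, LA 29) plus 25 controls (control
#'   count unpublished; package default).
#' @param seed Integer seed driving the whole cohort draw.
#' @param confusion Row-stochastic confusion matrix over
#'   [diagnosis_labels()]; see [default_confusion_matrix()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(sizes = c(SIVD = 53, AD = 25, MX = 22, MI = 18,
                                    LA = 29, CONTROL = 25),
                          seed = 1L,
                          confusion = default_confusion_matrix()) {
  labs <- diagnosis_labels()
  if (is.null(names(sizes)) || !all(names(sizes) %in% labs)) {
    abort("`sizes` must be named by diagnosis labels", class = "mixstrat_input_error")
  }
  if (any(!is.finite(sizes)) || any(sizes < 0) || any(sizes != as.integer(sizes))) {
    abort("`sizes` must be non-negative integers", class = "mixstrat_input_error")
  }
  full <- setNames(integer(length(labs)), labs)
  full[names(sizes)] <- as.integer(sizes)
  if (sum(full) == 0) {
    abort("total cohort size must be > 0", class = "mixstrat_input_error")
  }
  if (!(is.numeric(seed) && length(seed) == 1L && is.finite(seed))) {
    abort("`seed` must be a single finite integer", class = "mixstrat_input_error")
  }
  if (!is.matrix(confusion) || !identical(dim(confusion), c(length(labs), length(labs))) ||
      !identical(rownames(confusion), labs) || !identical(colnames(confusion), labs)) {
    abort("`confusion` must be a square matrix with diagnosis labels on both dimensions",
          class = "mixstrat_input_error")
  }
  if (any(confusion < 0) || any(abs(rowSums(confusion) - 1) > 1e-9)) {
    abort("each confusion row must be non-negative and sum to 1 (tol 1e-9)",
          class = "mixstrat_input_error")
  }
  structure(
    list(sizes = full, seed = as.integer(seed), confusion = confusion),
    class = "cohort_config"
  )
}

#' Generate a full synthetic cohort
#'
#' Concatenates per-group draws in the canonical label order, then perturbs
#' each record's `clinical_label` by sampling from the confusion row of its
#' biological label. With the identity confusion matrix clinical and
#' biological labels coincide. Deterministic given the config seed.
#'
#' @param config A [cohort_config()].
#' @param params Named list of [group_params()], one per requested group;
#'   defaults to [default_group_params()].
#' @return Tibble of patient records (see [generate_group()]).
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 42))
#' table(cohort$biological_label)
#' @export
generate_cohort <- function(config, params = default_group_params()) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be a cohort_config object", class = "mixstrat_input_error")
  }
  labs <- diagnosis_labels()
  wanted <- labs[config$sizes[labs] > 0]
  missing <- wanted[!wanted %in% names(params)]
  if (length(missing)) {
    abort(
      paste0("no group parameters supplied for requested group(s): ",
             paste(missing, collapse = ", ")),
      class = "mixstrat_config_error"
    )
  }
  withr::with_seed(config$seed, {
    parts <- lapply(wanted, function(lab) {
      n <- config$sizes[[lab]]
      df <- .draw_group(params[[lab]], n)
      df$clinical_label <- sample(
        colnames(config$confusion), n, replace = TRUE,
        prob = config$confusion[lab, ]
      )
      df
    })
    dplyr::bind_rows(parts)
  })
}
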