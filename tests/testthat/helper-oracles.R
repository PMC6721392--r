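# Independent oracles and fixture builders used across the suite. These are
# deliberately brute-force and share no code with the implementation paths
# they check.

# Exact two-sided Mann-Whitney p-value by enumeration of all C(n, n1) rank
# assignments (no ties assumed). U is oriented to the first sample.
mw_exact_oracle <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n, n1)
  u_null <- apply(splits, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  p <- 2 * min(mean(u_null <= u_obs), mean(u_null >= u_obs))
  list(u = u_obs, p = min(p, 1))
}

# Tie-corrected Kruskal-Wallis H by the brute-force rank formula.
kw_brute_oracle <- function(samples) {
  x <- unlist(samples)
  n <- length(x)
  r <- rank(x)
  sizes <- lengths(samples)
  idx <- split(seq_len(n), rep(seq_along(samples), sizes))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(idx, function(i) sum(r[i])^2 / length(i), 0)) -
    3 * (n + 1)
  t_counts <- table(x)
  correction <- 1 - sum(t_counts^3 - t_counts) / (n^3 - n)
  h / correction
}

# Exhaustive Hamming-distance minimizer over the sign-matrix columns, with
# the same MX > SIVD > AD > LA tie precedence the matcher documents.
hamming_oracle <- function(fv_row, fm) {
  d <- vapply(colnames(fm), function(l) sum(fm[, l] != fv_row), 0)
  precedence <- c("MX", "SIVD", "AD", "LA")
  cand <- names(d)[d == min(d)]
  precedence[precedence %in% cand][1]
}

# Default parameters made nearly deterministic: SDs scaled down tenfold and
# the infarct flag exact (1 for MI, 0 elsewhere). Used for recovery checks,
# which are properties of this configuration, not of the published cohort.
well_separated_params <- function(sd_scale = 0.1) {
  params <- default_group_params()
  lapply(params, function(p) {
    p$sds <- p$sds * sd_scale
    p$probs[["infarct"]] <- if (p$label == "MI") 1 else 0
    p
  })
}

# A random but valid group_params object for property tests.
random_group_params <- function(label = "SIVD") {
  means <- c(
    age = runif(1, 50, 85), t_memory = runif(1, 25, 60),
    t_executive = runif(1, 25, 60), t_attention = runif(1, 25, 60),
    t_language = runif(1, 25, 60), t_speed = runif(1, 25, 60),
    md_z = runif(1, -1, 4), ptau = runif(1, 20, 150),
    ab_ratio = runif(1, 0.03, 0.15), mmp1 = runif(1, 5, 40),
    mmp3 = runif(1, 5, 40), mmp10 = runif(1, 30, 120),
    albumin_index = runif(1, 3, 10)
  )
  sds <- c(
    age = runif(1, 1, 15), t_memory = runif(1, 1, 15),
    t_executive = runif(1, 1, 15), t_attention = runif(1, 1, 15),
    t_language = runif(1, 1, 15), t_speed = runif(1, 1, 15),
    md_z = runif(1, 0.1, 2.5), ptau = runif(1, 5, 60),
    ab_ratio = runif(1, 0.005, 0.03), mmp1 = runif(1, 1, 25),
    mmp3 = runif(1, 1, 15), mmp10 = runif(1, 5, 70),
    albumin_index = runif(1, 0.5, 3)
  )
  probs <- c(
    wmh_present = runif(1), hyperreflexia = runif(1),
    imbalance = runif(1), infarct = runif(1)
  )
  group_params(label, means, sds, probs)
}

# One archetypal record per feature-matrix column, numerically at the
# correct side of every default cut.
archetype_record <- function(label) {
  th <- default_thresholds()
  fm <- default_feature_matrix()
  sig <- fm[, label]
  tibble::tibble(
    hyperreflexia = sig[["hyperreflexia"]],
    imbalance = sig[["imbalance"]],
    t_executive = if (sig[["executive_deficit"]]) 30 else 50,
    t_memory = if (sig[["memory_deficit"]]) 30 else 50,
    wmh_present = sig[["wmh_flair"]],
    md_z = if (sig[["md_dti_high"]]) 3 else 0.5,
    ab_ratio = if (sig[["amyloid_positive"]]) 0.05 else 0.10,
    ptau = if (sig[["ptau_positive"]]) 120 else 45,
    albumin_index = if (sig[["albumin_index_high"]]) 9 else 5,
    infarct = FALSE
  )
}
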