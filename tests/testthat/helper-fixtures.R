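# shared fixtures and independent oracles, built in code at test time

# intake profile table where every scorer field is present; values default to
# a benign mid-range profile and can be overridden per column
make_profiles <- function(n, sex = rep(c("male", "female"), length.out = n), ...) {
  base <- tibble::tibble(
    participant_id = sprintf("T%03d", seq_len(n)),
    sex = sex
  )
  for (f in dietspan::intake_fields()$field) base[[f]] <- rep(1, n)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# profile rows hitting the best / worst anchor of every AHEI component
ahei_best_profile <- function(sex = "male") {
  make_profiles(1, sex = sex,
    vegetables = 5, fruits = 4, whole_grains = 95, ssb = 0, fruit_juice = 0,
    nuts = 1, legumes = 0.5, red_meat = 0, processed_meat = 0,
    trans_fat_pct = 0.4, n3_mg = 300, pufa_pct = 11, sodium_mg = 1000,
    alcohol_g = 10)
}
ahei_worst_profile <- function(sex = "male") {
  make_profiles(1, sex = sex,
    vegetables = 0, fruits = 0, whole_grains = 0, ssb = 1.2, fruit_juice = 0.5,
    nuts = 0, legumes = 0, red_meat = 1.2, processed_meat = 0.8,
    trans_fat_pct = 5, n3_mg = 0, pufa_pct = 1.5, sodium_mg = 4000,
    alcohol_g = 60)
}

# cohort of n profiles ranked against ONE index's component directions:
# participant r is ranked r-th best on every component of that spec, so r = n
# attains the index maximum and r = 1 the minimum. Directions conflict across
# indices (fish is beneficial in AMED, animal-food in hPDI), so the fixture is
# per-spec by construction.
ranked_profiles <- function(spec, n = 10, sex = rep("male", n)) {
  p <- make_profiles(n, sex = sex)
  r <- seq_len(n)
  comps <- spec$components
  for (i in seq_len(nrow(comps))) {
    val <- if (comps$direction[i] == "lower") (n + 1 - r) * 1.0 else r * 1.0
    for (f in comps$fields[[i]]) p[[f]] <- val
  }
  p
}

# independent average-rank computation by explicit counting (no rank())
oracle_avg_rank <- function(v) {
  vapply(seq_along(v), function(i) {
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }, numeric(1))
}

# brute-force quantile points: average rank -> ceiling(k * rank / n)
oracle_quantile_points <- function(v, k = 5, reverse = FALSE) {
  r <- oracle_avg_rank(v)
  g <- ceiling(k * r / length(v))
  if (reverse) g <- k + 1 - g
  as.integer(g)
}

# brute-force re-implementation of a quintile-ruled scoring spec (rank and
# sum with explicit loops), used as the oracle for AMED/hPDI/DASH/DRRD
oracle_score_quintile_index <- function(profiles, spec) {
  comps <- spec$components
  total <- numeric(nrow(profiles))
  for (i in seq_len(nrow(comps))) {
    v <- rowSums(as.matrix(profiles[comps$fields[[i]]]))
    rev <- comps$direction[i] == "lower"
    pts <- numeric(nrow(profiles))
    if (isTRUE(comps$sex_specific[i])) {
      for (s in unique(profiles$sex)) {
        idx <- profiles$sex == s
        pts[idx] <- oracle_quantile_points(v[idx], 5, rev)
      }
    } else {
      pts <- oracle_quantile_points(v, 5, rev)
    }
    total <- total + pts
  }
  total
}

# small cached synthetic cohort shared across tests
test_cohort <- local({
  cache <- NULL
  function(n = 4000, seed = 42L, ...) {
    key <- paste(n, seed, length(list(...)))
    if (is.null(cache) || !identical(attr(cache, "key"), key)) {
      co <- dietspan::generate_cohort(
        dietspan::simulation_params(n_participants = n, seed = seed, ...))
      cache <<- dietspan::build_analysis_cohort(co)
      attr(cache, "key") <<- key
    }
    cache
  }
})

# lightweight null survival data for calibration-style tests
null_cox_data <- function(n = 600) {
  sex <- sample(c("male", "female"), n, TRUE)
  score <- rnorm(n, 50, 10)
  t <- rexp(n, 0.08)
  tibble::tibble(
    participant_id = sprintf("N%04d", seq_len(n)),
    sex = sex, age = runif(n, 45, 70),
    score = score,
    score_q = dietspan::quintile_rank(score),
    prs_tertile = factor(sample(c("low", "intermediate", "high"), n, TRUE),
                         levels = c("low", "intermediate", "high")),
    time_years = pmin(t, 5), event = t <= 5
  )
}
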