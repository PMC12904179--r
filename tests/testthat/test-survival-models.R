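# exponential two-group data with a closed-form rate-ratio oracle
exp_two_group <- function(n = 6000, rate0 = 0.05, hr = 2, censor = 8, seed = 3) {
  withr::with_seed(seed, {
    g <- rep(0:1, length.out = n)
    t <- rexp(n, rate0 * ifelse(g == 1, hr, 1))
    tibble::tibble(
      participant_id = sprintf("e%05d", seq_len(n)),
      group = g, age = runif(n, 50, 60), sex = sample(c("male", "female"), n, TRUE),
      time_years = pmin(t, censor), event = t <= censor
    )
  })
}

test_that("the Cox HR matches the events/person-years ratio oracle on exponential data", {
  d <- exp_two_group()
  # closed form: rate ratio of (events / person-years) between groups
  oracle <- with(d, (sum(event[group == 1]) / sum(time_years[group == 1])) /
                   (sum(event[group == 0]) / sum(time_years[group == 0])))
  fit <- fit_cox(d, model_spec("group", "continuous", "model1",
                               drop_covariates = c("age", "sex")))
  expect_equal(fit$levels$hr[1], oracle, tolerance = 0.02)
  expect_equal(fit$levels$hr[1], 2, tolerance = 0.1)
})

test_that("a known per-SD effect is recovered without material bias", {
  hrs <- vapply(1:5, function(s) {
    co <- generate_cohort(simulation_params(
      n_participants = 10000, seed = 100 + s,
      log_hr_per_sd_diet = log(0.85), log_hr_per_sd_prs = 0,
      intake_params = default_intake_params()[1:2, ]))
    d <- co$participants
    fit_cox(d, model_spec("diet_factor", "per_sd", "model1"))$levels$hr[1]
  }, numeric(1))
  expect_equal(mean(hrs), 0.85, tolerance = 0.02)
})

test_that("quintile fits carry events, person-years, reference HR 1, and CI order", {
  b <- test_cohort(n = 4000, seed = 42)
  hs <- fit_cox(b$data, model_spec("drrd", "quintile", "model2"))
  expect_equal(hs$levels$hr[1], 1)
  expect_equal(sum(hs$levels$n), nrow(b$data))
  expect_equal(sum(hs$levels$person_years), sum(b$data$time_years))
  expect_true(all(hs$levels$lo <= hs$levels$hr & hs$levels$hr <= hs$levels$hi))
  expect_true(all(hs$levels$hr > 0))
  expect_s3_class(tidy(hs), "tbl_df")
  expect_equal(nrow(tidy(hs)), 5)
  g <- glance(hs)
  expect_equal(g$n_events, sum(b$data$event))
  expect_false(is.na(g$p_trend))
})

test_that("zero events in a level produce an actionable error", {
  d <- exp_two_group(n = 300, censor = 8)
  d$drrd <- runif(300); d$drrd_q <- quintile_rank(d$drrd)
  d$event[d$drrd_q == 3] <- FALSE
  expect_error(
    fit_cox(d, model_spec("drrd", "quintile", "model1",
                          drop_covariates = c("age", "sex"))),
    "merge levels|Zero events")
})

test_that("median coding in the trend test matches brute-force quintile medians", {
  b <- test_cohort(n = 4000, seed = 42)
  tr <- trend_test(b$data, "amed", covariates = "model1")
  for (q in 1:5) {
    expect_equal(tr$coding$median_score[tr$coding$q == q],
                 median(b$data$amed[b$data$amed_q == q]))
  }
  expect_true(tr$p >= 0 && tr$p <= 1)
  # a strong monotone effect drives the trend p towards zero
  d <- exp_two_group(n = 4000, seed = 9)
  d$score <- -log(d$time_years + 0.01) + rnorm(4000, 0, 0.3)
  d$score_q <- quintile_rank(d$score)
  tr2 <- trend_test(d, "score", covariates = "model1")
  expect_lt(tr2$p, 1e-6)
})

test_that("the restricted cubic basis matches the textbook formula at the knots", {
  knots <- c(1, 4, 9)
  x <- c(0.5, 1, 2, 4, 6, 9, 11)
  b <- rcs_basis(x, knots)
  # independent evaluation of the published formula
  plus3 <- function(u) ifelse(u > 0, u^3, 0)
  expected_nl <- (plus3(x - 1) - plus3(x - 4) * (9 - 1) / (9 - 4) +
                    plus3(x - 9) * (4 - 1) / (9 - 4)) / (9 - 1)^2
  expect_equal(unname(b[, "nl1"]), expected_nl)
  expect_equal(unname(b[, "lin"]), x)
  # linearity beyond the boundary knots: second differences vanish
  xr <- seq(10, 20, by = 1)
  nl <- rcs_basis(xr, knots)[, "nl1"]
  expect_equal(diff(nl, differences = 2), rep(0, length(xr) - 2),
               tolerance = 1e-10)
  expect_error(rcs_basis(x, c(1, 2)), "at least 3")
  expect_error(rcs_basis(x, c(3, 2, 1)), "increasing")
})

test_that("spline dose-response is flat with CI covering 0 under the null", {
  d <- null_cox_data(2500)
  sp <- spline_dose_response(d, "score", covariates = "model1")
  expect_true(all(sp$curve$lo <= 0 & sp$curve$hi >= 0))
  expect_equal(sp$knots, unname(quantile(d$score, c(0.1, 0.5, 0.9))))
  # the curve is exactly 0 at the reference value
  atref <- sp$curve$log_hr[which.min(abs(sp$curve$score - sp$ref_value))]
  expect_lt(abs(atref), 0.02)
  expect_true(sp$p_nonlinear >= 0 && sp$p_nonlinear <= 1)
})

test_that("HRs are invariant to time rescaling and covariate shifts", {
  b <- test_cohort(n = 4000, seed = 42)
  base <- fit_cox(b$data, model_spec("dash", "per_sd", "model1"))
  scaled <- b$data; scaled$time_years <- scaled$time_years * 3.7
  expect_equal(fit_cox(scaled, model_spec("dash", "per_sd", "model1"))$levels$hr,
               base$levels$hr, tolerance = 1e-8)
  shifted <- b$data; shifted$age <- shifted$age + 100
  expect_equal(fit_cox(shifted, model_spec("dash", "per_sd", "model1"))$levels$hr,
               base$levels$hr, tolerance = 1e-6)
})

test_that("RERI identities hold exactly at the point estimates", {
  # pure multiplicative interaction
  expect_equal(reri(0.8, 0.7, 0.8 * 0.7), 0.8 * 0.7 - 0.8 - 0.7 + 1)
  # pure additive: hr11 = hr10 + hr01 - 1 gives RERI 0
  expect_equal(reri(0.8, 0.7, 0.8 + 0.7 - 1), 0)
  b <- test_cohort(n = 4000, seed = 42)
  ia <- interaction_analysis(b$data, "drrd", strata_fits = FALSE)
  h <- ia$joint_hrs$hr
  expect_equal(ia$reri$estimate, h[3] - h[1] - h[2] + 1)
  expect_true(ia$reri$lo <= ia$reri$estimate & ia$reri$estimate <= ia$reri$hi)
  expect_true(ia$p_multiplicative >= 0 && ia$p_multiplicative <= 1)
})

test_that("the joint classification yields 15 cells with the stated reference", {
  b <- test_cohort(n = 4000, seed = 42)
  jg <- joint_groups(b$data, "amed")
  expect_equal(nrow(jg$levels), 15)
  expect_equal(jg$levels$level[1], "Q1:low")
  expect_equal(jg$levels$hr[1], 1)
  known <- sum(!is.na(b$data$prs_tertile) & b$data$prs_tertile != "unknown")
  expect_equal(sum(jg$levels$n), known)
})

test_that("stratified analysis reduces to the plain fit in a single stratum", {
  b <- test_cohort(n = 4000, seed = 42)
  d <- b$data
  d$onegrp <- "all"
  st <- stratified_analysis(d, "hpdi", "onegrp", covariates = "model1")
  ref <- fit_cox(d, model_spec("hpdi", "per_sd", "model1",
                               drop_covariates = "onegrp"))
  expect_equal(st$strata$hr, ref$levels$hr, tolerance = 1e-8)
  # by-sex stratification returns one row per sex plus an interaction p
  st2 <- stratified_analysis(d, "hpdi", "sex", covariates = "model1")
  expect_equal(sort(st2$strata$stratum), c("female", "male"))
  expect_true(st2$p_interaction >= 0 && st2$p_interaction <= 1)
  d_empty <- d
  d_empty$modx <- ifelse(seq_len(nrow(d_empty)) <= 3, "rare", "common")
  d_empty$event[d_empty$modx == "rare"] <- FALSE
  expect_error(stratified_analysis(d_empty, "hpdi", "modx", "model1"),
               "no data or no events")
})

test_that("food-group effects are per-SD with coherent correlations", {
  b <- test_cohort(n = 4000, seed = 42)
  d <- dplyr::left_join(b$data,
                        dplyr::select(b$profiles, participant_id, fiber_g,
                                      red_meat, vegetables),
                        by = "participant_id")
  fe <- food_group_effects(d, c("fiber_g", "red_meat", "vegetables"),
                           covariates = "model1")
  expect_equal(nrow(fe$effects), 3)
  expect_equal(fe$effects$sd, vapply(c("fiber_g", "red_meat", "vegetables"),
                                     function(v) sd(d[[v]]), numeric(1)),
               ignore_attr = TRUE)
  expect_equal(dim(fe$correlations), c(3, 5))
  # a food equal to a monotone transform of a score correlates at |rho| = 1
  d$fake_food <- 2 * d$dash + 7
  fe2 <- food_group_effects(d, "fake_food", covariates = "model1")
  expect_equal(unname(fe2$correlations["fake_food", "dash"]), 1)
})

test_that("leave-one-out substitution recovers coefficient differences", {
  # three foods with known log-HRs; total intake held fixed in the model
  withr::with_seed(77, {
    n <- 8000
    a <- rnorm(n); b_ <- rnorm(n); c_ <- rnorm(n)
    lp <- 0.3 * a + 0.1 * b_ - 0.2 * c_
    t <- rexp(n, 0.05 * exp(lp))
    d <- tibble::tibble(
      participant_id = sprintf("s%05d", 1:n),
      food_a = a, food_b = b_, food_c = c_,
      energy_kcal = 2000 + 50 * (a + b_ + c_) + rnorm(n, 0, 10),
      age = runif(n, 50, 60), sex = sample(c("male", "female"), n, TRUE),
      time_years = pmin(t, 10), event = t <= 10
    )
  })
  lo <- leave_one_out_substitution(d, c("food_a", "food_b", "food_c"),
                                   covariates = "model1")
  expect_equal(dim(lo$hr_matrix), c(3, 3))
  # with total intake fixed, the substitution estimate is the difference of
  # the true log-HRs: replacing food_c (-0.2) by food_a (+0.3) gives +0.5
  expect_equal(log(lo$hr_matrix["food_c", "food_a"]), 0.5, tolerance = 0.1)
  expect_equal(log(lo$hr_matrix["food_a", "food_b"]), 0.1 - 0.3, tolerance = 0.1)
  # equal true effects substitute to a null HR: a vs b differs by 0.2, b vs a
  # by -0.2, and the matrix diagonal-free structure is antisymmetric in logs
  expect_equal(log(lo$hr_matrix["food_b", "food_a"]),
               -log(lo$hr_matrix["food_a", "food_b"]), tolerance = 0.2)
  expect_error(leave_one_out_substitution(d, c("food_a", "nope")), "nope")
  expect_error(leave_one_out_substitution(d, "food_a"), "at least two")
})

test_that("cause-specific fits censor competing deaths and validate labels", {
  b <- test_cohort(n = 4000, seed = 42)
  d <- b$data
  expect_error(cause_specific_fit(d, "plague", model_spec("ahei", "per_sd")),
               "plague")
  single <- d
  single$cause[single$event] <- "cancer"
  all_cause <- fit_cox(single, model_spec("ahei", "per_sd", "model1"))
  cs <- cause_specific_fit(single, "cancer", model_spec("ahei", "per_sd", "model1"))
  expect_equal(cs$levels$hr, all_cause$levels$hr)
  cs2 <- cause_specific_fit(d, "cancer", model_spec("ahei", "per_sd", "model1"))
  expect_lt(cs2$levels$n_events[1], sum(d$event))
})

test_that("proportional-hazards diagnostics run as a delegated check", {
  b <- test_cohort(n = 4000, seed = 42)
  hs <- fit_cox(b$data, model_spec("amed", "per_sd", "model1"))
  z <- ph_diagnostic(hs)
  expect_true(all(c("term", "p") %in% names(z)))
})
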