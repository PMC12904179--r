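flat_life_table <- function(q = 0.02, sexes = "male", ages = 45:100) {
  tidyr::expand_grid(sex = sexes, age = ages) |>
    dplyr::mutate(qx = q)
}

two_group_prev <- function(p = c(0.5, 0.5), sexes = "male") {
  tidyr::expand_grid(sex = sexes, group = c("ref", "exp")) |>
    dplyr::mutate(age_band = "45-100",
                  prevalence = rep(p, length(sexes)))
}

test_that("all-unit hazard ratios reproduce the population table exactly", {
  lt <- generate_population_life_table(ages = 45:100)
  prev <- two_group_prev(sexes = c("male", "female"))
  hrs <- tidyr::expand_grid(sex = c("male", "female"),
                            group = c("ref", "exp")) |>
    dplyr::mutate(hr = 1)
  gq <- reference_hazard(lt, prev, hrs)
  merged <- dplyr::left_join(gq, lt, by = c("sex", "age"))
  expect_equal(merged$qx_group, merged$qx, tolerance = 1e-12)
})

test_that("the two-group constant-hazard case matches the algebra oracle", {
  lt <- flat_life_table(q = 1 - exp(-0.01))  # rate exactly 0.01
  hrs <- tibble::tibble(sex = "male", group = c("ref", "exp"), hr = c(1, 2))
  gq <- reference_hazard(lt, two_group_prev(), hrs)
  expect_equal(unique(gq$m_ref), 0.01 / 1.5, tolerance = 1e-12)
  # marginal conservation at every age: sum_g p_g m_g = m
  chk <- gq |>
    dplyr::mutate(m_g = -log(1 - qx_group)) |>
    dplyr::group_by(age) |>
    dplyr::summarise(m_marg = sum(prevalence * m_g))
  expect_true(all(abs(chk$m_marg - 0.01) < 1e-9))
})

test_that("invalid prevalence and exploding probabilities are rejected", {
  lt <- flat_life_table(0.02)
  hrs <- tibble::tibble(sex = "male", group = c("ref", "exp"), hr = c(1, 2))
  bad_prev <- two_group_prev(p = c(0.6, 0.6))
  expect_error(reference_hazard(lt, bad_prev, hrs), "sum to 1")
  # rate-scale conversion keeps probabilities below 1 even for extreme HRs —
  # the reason HRs are applied to m = -ln(1-q), not to q directly
  big <- tibble::tibble(sex = "male", group = c("ref", "exp"), hr = c(1, 2000))
  gq <- reference_hazard(flat_life_table(0.4), two_group_prev(), big)
  expect_true(all(gq$qx_group < 1))
  expect_error(reference_hazard(flat_life_table(1.0), two_group_prev(), big),
               "strictly in")
})

test_that("life expectancy obeys its boundary and closed-form cases", {
  ages <- 45:100
  # everyone dies in the first year: half-year credit only
  expect_equal(life_expectancy(rep(1, 56), ages), 0.5)
  # nobody dies before the table closes
  expect_equal(life_expectancy(rep(0, 56), ages), 56)  # 101 - 45
  # constant hazard: geometric-series closed form
  q <- 0.02
  s <- cumprod(c(1, rep(1 - q, 55)))
  closed <- sum(s * (1 - q / 2))
  expect_equal(life_expectancy(rep(q, 56), ages), closed, tolerance = 1e-9)
  expect_error(life_expectancy(rep(q, 3), c(45, 46, 48)), "Gap")
  # open-ended terminal interval adds survivors' expected remaining years
  le_open <- life_expectancy(rep(q, 56), ages, open_terminal = TRUE)
  expect_gt(le_open, closed)
})

test_that("years gained is an antisymmetric difference, positive for protective HRs", {
  expect_equal(years_gained(38.2, 38.2), 0)
  expect_equal(years_gained(40, 38), -years_gained(38, 40))
  lt <- flat_life_table(0.02)
  hrs <- tibble::tibble(sex = "male", group = c("ref", "exp"), hr = c(1, 0.8))
  gq <- reference_hazard(lt, two_group_prev(), hrs)
  le <- gq |>
    dplyr::group_by(group) |>
    dplyr::summarise(le = life_expectancy(qx_group, age))
  gain <- le$le[le$group == "exp"] - le$le[le$group == "ref"]
  expect_gt(gain, 0)
})

test_that("life expectancy is strictly decreasing in the hazard ratio", {
  lt <- flat_life_table(0.02)
  les <- vapply(c(0.7, 0.9, 1, 1.3, 1.8), function(h) {
    hrs <- tibble::tibble(sex = "male", group = c("ref", "exp"), hr = c(1, h))
    gq <- reference_hazard(lt, two_group_prev(), hrs)
    d <- gq[gq$group == "exp", ]
    life_expectancy(d$qx_group, d$age)
  }, numeric(1))
  expect_true(all(diff(les) < 0))
})

test_that("the full engine returns reference gains of zero and start-age monotonicity", {
  lt <- generate_population_life_table(ages = 0:100)
  hrs <- tidyr::expand_grid(sex = c("male", "female"),
                            group = paste0("Q", 1:5)) |>
    dplyr::mutate(hr = rep(c(1, 0.9, 0.85, 0.8, 0.75), 2),
                  lo = hr * 0.85, hi = hr / 0.85) |>
    dplyr::mutate(lo = ifelse(group == "Q1", 1, lo),
                  hi = ifelse(group == "Q1", 1, hi))
  prev <- tidyr::expand_grid(sex = c("male", "female"),
                             age_band = c("45-54", "55-64", "65-100"),
                             group = paste0("Q", 1:5)) |>
    dplyr::mutate(prevalence = 0.2)
  le <- run_life_expectancy(hrs, lt, prev, reference = "Q1",
                            start_ages = c(45, 50, 55, 60),
                            n_draws = 200, seed = 5)
  expect_equal(nrow(le), 2 * 5 * 4)
  ref_rows <- le[le$group == "Q1", ]
  expect_true(all(ref_rows$gain == 0))
  for (s in c("male", "female")) {
    for (g in paste0("Q", 1:5)) {
      sub <- le[le$sex == s & le$group == g, ]
      expect_true(all(diff(sub$le[order(sub$start_age)]) < 0))
    }
  }
  # protective groups gain life expectancy, with CI bounds bracketing
  q5 <- le[le$group == "Q5", ]
  expect_true(all(q5$gain > 0))
  expect_true(all(q5$gain_lo <= q5$gain & q5$gain <= q5$gain_hi))
})

test_that("Monte Carlo intervals are deterministic, degenerate at width zero, and stable", {
  lt <- flat_life_table(0.02)
  hrs <- tibble::tibble(sex = "male", group = c("ref", "exp"),
                        hr = c(1, 0.8), lo = c(1, 0.8), hi = c(1, 0.8))
  prev <- two_group_prev()
  le0 <- run_life_expectancy(hrs, lt, prev, reference = "ref",
                             start_ages = 45, n_draws = 150, seed = 9)
  # degenerate CIs collapse to the point estimate
  expect_equal(le0$gain_lo, le0$gain)
  expect_equal(le0$gain_hi, le0$gain)
  hrs$lo[2] <- 0.7; hrs$hi[2] <- 0.92
  a <- run_life_expectancy(hrs, lt, prev, reference = "ref", start_ages = 45,
                           n_draws = 150, seed = 9)
  b <- run_life_expectancy(hrs, lt, prev, reference = "ref", start_ages = 45,
                           n_draws = 150, seed = 9)
  expect_identical(a$gain_lo, b$gain_lo)
  big <- run_life_expectancy(hrs, lt, prev, reference = "ref", start_ages = 45,
                             n_draws = 600, seed = 9)
  exp_row <- function(x) x[x$group == "exp", ]
  expect_equal(exp_row(a)$gain_lo, exp_row(big)$gain_lo, tolerance = 0.15)
  expect_warning(
    run_life_expectancy(hrs, lt, prev, reference = "ref", start_ages = 45,
                        n_draws = 50, seed = 9),
    "unstable")
})

test_that("cohort prevalence tables cover every group in every band and sum to 1", {
  b <- test_cohort(n = 2500, seed = 33)
  d <- b$data
  d$grp <- paste0("Q", d$dash_q)
  prev <- prevalence_from_cohort(d, "grp")
  sums <- prev |>
    dplyr::group_by(sex, age_band) |>
    dplyr::summarise(s = sum(prevalence), n = dplyr::n(), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
  expect_true(all(sums$n == 5))
})
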