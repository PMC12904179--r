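test_that("shipped specs close their declared ranges structurally", {
  specs <- default_scoring_specs()
  declared <- list(ahei = c(0, 110), amed = c(10, 50), hpdi = c(17, 85),
                   dash = c(8, 40), drrd = c(9, 45))
  for (nm in names(declared)) {
    expect_equal(specs[[nm]]$range, declared[[nm]])
    expect_equal(sum(specs[[nm]]$components$min_points), declared[[nm]][1])
    expect_equal(sum(specs[[nm]]$components$max_points), declared[[nm]][2])
  }
  expect_equal(nrow(specs$ahei$components), 11)
  expect_equal(nrow(specs$amed$components), 10)
  expect_equal(nrow(specs$hpdi$components), 17)
  expect_equal(nrow(specs$dash$components), 8)
  expect_equal(nrow(specs$drrd$components), 9)
  # a spec whose component extremes do not close the range is rejected
  broken <- specs$dash$components
  broken$max_points[1] <- 6
  expect_error(scoring_spec("dash", broken, c(8, 40)), "close the declared range")
})

test_that("AHEI hits 110 at the best anchors, 0 at the worst, 5 halfway", {
  expect_equal(score_ahei(ahei_best_profile("male"))$score, 110)
  expect_equal(score_ahei(ahei_best_profile("female"))$score, 110)
  expect_equal(score_ahei(ahei_worst_profile("male"))$score, 0)
  half <- ahei_worst_profile("male")
  half$vegetables <- 2.5  # halfway between the 0 and 5 servings anchors
  expect_equal(score_ahei(half)$score, 5)
  # sex-specific whole-grain anchor: 75 g/day is best for women, not for men
  wg <- ahei_worst_profile("female"); wg$whole_grains <- 75
  expect_equal(score_ahei(wg)$score, 10)
  wg_m <- ahei_worst_profile("male"); wg_m$whole_grains <- 75
  expect_equal(score_ahei(wg_m)$score, 10 * 75 / 90)
  expect_error(score_ahei(dplyr::select(ahei_best_profile(), -vegetables)),
               "vegetables")
})

test_that("alcohol is scored by a tent with a nondrinker shelf", {
  p <- ahei_worst_profile("female")
  comp <- function(g) {
    p$alcohol_g <- g
    attr(score_ahei(p), "components")$alcohol
  }
  expect_equal(comp(0), 2.5)
  expect_equal(comp(14), 10)   # inside the optimal band
  expect_equal(comp(35), 0)    # at the upper anchor
  expect_equal(comp(28), 10 * (35 - 28) / (35 - 21))
  expect_gt(comp(3.5), 2.5)    # rising limb
})

test_that("quintile-ruled indices reach their extremes on a ranked cohort", {
  specs <- default_scoring_specs()
  declared <- list(amed = c(10, 50), hpdi = c(17, 85),
                   dash = c(8, 40), drrd = c(9, 45))
  for (nm in names(declared)) {
    p <- ranked_profiles(specs[[nm]], 10, sex = rep("male", 10))
    sc <- score_index(p, specs[[nm]])$score
    expect_equal(range(sc), declared[[nm]], info = nm)
    # the uniformly best-ranked participant holds the maximum
    expect_equal(sc[10], declared[[nm]][2], info = nm)
    expect_equal(sc[1], declared[[nm]][1], info = nm)
  }
})

test_that("every scorer matches the brute-force rank-and-sum oracle exactly", {
  withr::with_seed(123, {
    prof <- make_profiles(200, sex = sample(c("male", "female"), 200, TRUE))
    for (f in dietspan::intake_fields()$field) {
      prof[[f]] <- stats::rlnorm(200, 0, 0.6)
    }
  })
  specs <- default_scoring_specs()
  for (nm in c("amed", "hpdi", "dash", "drrd")) {
    expect_equal(score_index(prof, specs[[nm]])$score,
                 oracle_score_quintile_index(prof, specs[[nm]]),
                 info = nm)
  }
  # AHEI oracle: independent per-component interpolation
  ahei_oracle <- local({
    cl <- function(x) pmin(pmax(x, 0), 1)
    men <- prof$sex == "male"
    wg_best <- ifelse(men, 90, 75)
    alc_hi <- ifelse(men, 28, 21); alc_up <- ifelse(men, 49, 35)
    alc <- prof$alcohol_g
    alc_pts <- ifelse(alc >= 7 & alc <= alc_hi, 10,
               ifelse(alc < 7, 2.5 + 7.5 * alc / 7,
                      pmax(0, 10 * (alc_up - alc) / (alc_up - alc_hi))))
    10 * (cl(prof$vegetables / 5) + cl(prof$fruits / 4) +
            cl(prof$whole_grains / wg_best) +
            cl(1 - (prof$ssb + prof$fruit_juice)) +
            cl(prof$nuts + prof$legumes) +
            cl(1 - (prof$red_meat + prof$processed_meat) / 1.5) +
            cl((4 - prof$trans_fat_pct) / 3.5) +
            cl(prof$n3_mg / 250) + cl((prof$pufa_pct - 2) / 8) +
            cl((3400 - prof$sodium_mg) / 2300)) + alc_pts
  })
  expect_equal(score_ahei(prof)$score, ahei_oracle)
})

test_that("AMED quintiles are sex-specific and insulated across sexes", {
  withr::with_seed(7, {
    prof <- make_profiles(120, sex = rep(c("male", "female"), each = 60))
    for (f in dietspan::intake_fields()$field) {
      prof[[f]] <- stats::rlnorm(120, 0, 0.5)
    }
  })
  before <- score_amed(prof)$score
  shuffled <- prof
  fem <- which(prof$sex == "female")
  withr::with_seed(8, perm <- sample(fem))
  for (f in dietspan::intake_fields()$field) {
    shuffled[[f]][fem] <- prof[[f]][perm]
  }
  after <- score_amed(shuffled)$score
  expect_equal(after[prof$sex == "male"], before[prof$sex == "male"])
  expect_false(all(after[fem] == before[fem]))
})

test_that("raising a beneficial intake never lowers that participant's score", {
  withr::with_seed(42, {
    prof <- make_profiles(50, sex = rep("male", 50))
    for (f in dietspan::intake_fields()$field) {
      prof[[f]] <- stats::rlnorm(50, 0, 0.5)
    }
  })
  for (idx in c("dash", "drrd")) {
    base <- score_index(prof, default_scoring_specs(idx))$score
    bumped <- prof
    bumped$fruits[17] <- max(prof$fruits) * 2
    new <- score_index(bumped, default_scoring_specs(idx))$score
    expect_gte(new[17], base[17])
  }
  base <- score_ahei(prof)$score
  bumped <- prof; bumped$vegetables[3] <- prof$vegetables[3] + 1
  expect_gte(score_ahei(bumped)$score[3], base[3])
})

test_that("alcohol-free variants shrink the declared ranges", {
  expect_equal(spec_without_alcohol(default_scoring_specs("ahei"))$range, c(0, 100))
  expect_equal(spec_without_alcohol(default_scoring_specs("amed"))$range, c(9, 45))
  expect_error(spec_without_alcohol(default_scoring_specs("dash")), "no alcohol")
  best <- ahei_best_profile("male")
  expect_equal(score_without_alcohol(best, "ahei")$score, 100)
  worst <- ahei_worst_profile("male")
  expect_equal(score_without_alcohol(worst, "ahei")$score, 0)
  spec_na <- spec_without_alcohol(default_scoring_specs("amed"))
  p <- ranked_profiles(spec_na, 10)
  expect_equal(range(score_index(p, spec_na)$score), c(9, 45))
})

test_that("score correlations are symmetric with unit diagonal and signed bounds", {
  b <- test_cohort(n = 2500, seed = 33)
  m <- score_correlations(b$data)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 5))
  expect_true(all(m >= -1 & m <= 1))
  # a score against its own negation is exactly -1
  toy <- tibble::tibble(a = rnorm(30), b = NA)
  toy$b <- -toy$a
  expect_equal(unname(score_correlations(toy, indices = c("a", "b"))[1, 2]), -1)
})
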