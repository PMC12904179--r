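#' Decompose population mortality into exposure-group mortality
#'
#' Hazard ratios act on rates, not probabilities, so annual death
#' probabilities are first converted to rates `m = -ln(1 - q)`. At each age
#' the reference-group rate solves the marginal constraint
#' `m_ref = m / sum_g p_g * HR_g`; each group's rate is `HR_g * m_ref` and
#' its probability `q_g = 1 - exp(-HR_g * m_ref)`. The prevalence-weighted
#' group rates reproduce the population rate exactly at every age.
#' Ten-year prevalence bands are expanded to single years by piecewise-
#' constant interpolation.
#'
#' @param life_table Tibble `sex`, `age`, `qx` in (0,1), single-year ages.
#' @param prevalence Tibble `sex`, `age_band` (e.g. `"45-54"`), `group`,
#'   `prevalence`; per (sex, band) the proportions must sum to 1 and every
#'   group must appear.
#' @param hrs Tibble `sex`, `group`, `hr` (reference group `hr = 1`).
#' @return Tibble `sex`, `age`, `group`, `prevalence`, `m_ref`, `qx_group`.
#' @export
reference_hazard <- function(life_table, prevalence, hrs) {
  stop_missing_fields(life_table, c("sex", "age", "qx"), "life table")
  stop_missing_fields(prevalence, c("sex", "age_band", "group", "prevalence"),
                      "prevalence table")
  stop_missing_fields(hrs, c("sex", "group", "hr"), "hazard-ratio table")
  if (any(life_table$qx <= 0 | life_table$qx >= 1)) {
    abort("Life-table qx must lie strictly in (0, 1).")
  }
  bad <- prevalence |>
    group_by(.data$sex, .data$age_band) |>
    summarise(s = sum(.data$prevalence), .groups = "drop") |>
    filter(abs(.data$s - 1) > 1e-9)
  if (nrow(bad)) {
    abort(paste0("Prevalence does not sum to 1 for ", bad$sex[1], " band ",
                 bad$age_band[1], " (sum ", signif(bad$s[1], 6), ")."))
  }
  bands <- prevalence |>
    tidyr::separate_wider_delim("age_band", "-", names = c("band_lo", "band_hi"),
                                cols_remove = FALSE) |>
    mutate(band_lo = as.numeric(.data$band_lo), band_hi = as.numeric(.data$band_hi))

  expanded <- life_table |>
    dplyr::inner_join(bands, by = "sex", relationship = "many-to-many") |>
    filter(.data$age >= .data$band_lo, .data$age <= .data$band_hi) |>
    dplyr::select("sex", "age", "qx", "group", "prevalence")
  missing_ages <- life_table |>
    dplyr::anti_join(distinct(expanded, .data$sex, .data$age), by = c("sex", "age"))
  if (nrow(missing_ages)) {
    # ages outside every band inherit the nearest band's prevalence
    nearest <- missing_ages |>
      dplyr::inner_join(bands, by = "sex", relationship = "many-to-many") |>
      mutate(dist = pmin(abs(.data$age - .data$band_lo),
                         abs(.data$age - .data$band_hi))) |>
      group_by(.data$sex, .data$age) |>
      filter(.data$dist == min(.data$dist)) |>
      ungroup() |>
      dplyr::select("sex", "age", "qx", "group", "prevalence")
    expanded <- bind_rows(expanded, nearest)
  }

  out <- expanded |>
    dplyr::inner_join(hrs, by = c("sex", "group")) |>
    group_by(.data$sex, .data$age) |>
    mutate(
      m = -log(1 - .data$qx),
      m_ref = .data$m / sum(.data$prevalence * .data$hr),
      qx_group = 1 - exp(-.data$hr * .data$m_ref)
    ) |>
    ungroup()
  if (any(out$qx_group >= 1)) {
    bad <- out[out$qx_group >= 1, ][1, ]
    abort(paste0("Scaled death probability reaches 1 (sex ", bad$sex,
                 ", age ", bad$age, ", group ", bad$group, ")."))
  }
  dplyr::select(out, "sex", "age", "group", "prevalence", "m_ref", "qx_group")
}

#' Period life expectancy from single-year death probabilities
#'
#' `S(a)` multiplies survival from the start age; each year lived
#' contributes `S(a) * (1 - q(a)/2)` — survivors a full year, decedents a
#' half year. The table closes at the last supplied age (100 by
#' convention); optionally an open-ended terminal interval `e = 1/m` is
#' added for survivors at the close.
#'
#' @param qx Numeric vector of annual death probabilities for contiguous
#'   single-year ages `start_age, start_age + 1, ...`.
#' @param ages Integer ages matching `qx`.
#' @param start_age First age of the table (must be `ages[1]`).
#' @param open_terminal Add `S * 1/m` beyond the final age.
#' @return Life expectancy in years at `start_age`.
#' @export
life_expectancy <- function(qx, ages, start_age = ages[1], open_terminal = FALSE) {
  if (length(qx) != length(ages)) abort("`qx` and `ages` lengths differ.")
  if (any(diff(ages) != 1)) abort("Gap in ages: single-year contiguous ages required.")
  if (ages[1] != start_age) abort("`start_age` must be the first supplied age.")
  surv <- cumprod(c(1, 1 - qx[-length(qx)]))
  le <- sum(surv * (1 - qx / 2))
  if (open_terminal) {
    s_end <- surv[length(surv)] * (1 - qx[length(qx)])
    m_end <- -log(1 - qx[length(qx)])
    le <- le + s_end / m_end
  }
  le
}

#' Years of life gained relative to a reference group
#'
#' @param le_group,le_reference Life expectancies in years.
#' @return Simple difference (antisymmetric under swap).
#' @export
years_gained <- function(le_group, le_reference) le_group - le_reference

le_by_group <- function(group_qx, start_age, open_terminal = FALSE) {
  group_qx |>
    filter(.data$age >= start_age) |>
    group_by(.data$sex, .data$group) |>
    arrange(.data$age, .by_group = TRUE) |>
    summarise(le = life_expectancy(.data$qx_group, .data$age, start_age,
                                   open_terminal),
              .groups = "drop")
}

#' Life expectancy and years gained across exposure groups
#'
#' Full engine: decomposes the population life table into group-specific
#' mortality via [reference_hazard()], computes life expectancy at each
#' requested start age, takes differences to the reference group, and
#' attaches Monte Carlo percentile confidence intervals that propagate the
#' hazard-ratio uncertainty (log-HRs drawn independently per group from the
#' normal distributions implied by each CI; the reference group is fixed
#' at 1).
#'
#' @param hrs Tibble `sex`, `group`, `hr`, `lo`, `hi` (reference `hr = 1`
#'   with `lo = hi = 1`).
#' @param life_table Population life table (`sex`, `age`, `qx`).
#' @param prevalence Prevalence table (`sex`, `age_band`, `group`,
#'   `prevalence`).
#' @param reference Name of the reference group.
#' @param start_ages Integer start ages.
#' @param n_draws Monte Carlo draws for the CIs (0 skips the CIs).
#' @param seed Seed for the draws.
#' @param open_terminal Passed to [life_expectancy()].
#' @return Tibble of class `le_estimates`: one row per (sex, group,
#'   start_age) with `le`, `le_lo`, `le_hi`, `gain`, `gain_lo`, `gain_hi`.
#' @export
run_life_expectancy <- function(hrs, life_table, prevalence,
                                reference,
                                start_ages = c(45, 50, 55, 60),
                                n_draws = 1000, seed = 1L,
                                open_terminal = FALSE) {
  stop_missing_fields(hrs, c("sex", "group", "hr"), "hazard-ratio table")
  if (!reference %in% hrs$group) {
    abort(paste0("Reference group '", reference, "' absent from `hrs`."))
  }
  if (n_draws > 0 && n_draws < 100) {
    warn("Fewer than 100 Monte Carlo draws: confidence intervals will be unstable.")
  }
  point <- purrr::map_dfr(start_ages, function(sa) {
    gq <- reference_hazard(life_table, prevalence, hrs)
    le <- le_by_group(gq, sa, open_terminal)
    ref <- le |> filter(.data$group == reference) |>
      dplyr::select("sex", le_ref = "le")
    le |>
      left_join(ref, by = "sex") |>
      mutate(start_age = sa, gain = years_gained(.data$le, .data$le_ref)) |>
      dplyr::select("sex", "group", "start_age", "le", "gain")
  })

  if (n_draws > 0) {
    if (!all(c("lo", "hi") %in% names(hrs))) {
      abort("Monte Carlo CIs need `lo` and `hi` columns in `hrs`.")
    }
    # vectorized across draws: per sex, prevalence matrix P (ages x groups),
    # drawn HR matrix H (groups x draws), marginal rates m (ages);
    # denom = P H, m_ref = m / denom, q_g = 1 - exp(-H_g m_ref)
    base <- reference_hazard(life_table, prevalence, hrs)
    ci <- with_stream_seed(seed, "le_mc", purrr::map_dfr(
      unique(hrs$sex), function(s) {
      hs <- dplyr::filter(hrs, .data$sex == s) |> arrange(.data$group)
      groups <- hs$group
      bs <- base |> filter(.data$sex == s) |> arrange(.data$group, .data$age)
      ages <- sort(unique(bs$age))
      P <- matrix(bs$prevalence, nrow = length(ages),
                  dimnames = list(ages, groups))
      lt_s <- life_table |> filter(.data$sex == s) |> arrange(.data$age)
      m <- -log(1 - lt_s$qx[match(ages, lt_s$age)])
      se <- (log(hs$hi) - log(hs$lo)) / (2 * qnorm(0.975))
      H <- matrix(
        exp(rnorm(length(groups) * n_draws, log(hs$hr), se)),
        nrow = length(groups), dimnames = list(groups, NULL)
      )
      H[groups == reference, ] <- 1
      Mref <- (m / (P %*% H))                       # ages x draws
      le_draws <- purrr::map(setNames(groups, groups), function(g) {
        Q <- 1 - exp(-sweep(Mref, 2, H[g, ], "*"))  # ages x draws
        vapply(start_ages, function(sa) {
          idx <- which(ages >= sa)
          Qs <- Q[idx, , drop = FALSE]
          k <- nrow(Qs)
          S <- rbind(rep(1, ncol(Qs)),
                     apply(1 - Qs[-k, , drop = FALSE], 2, cumprod))
          le <- colSums(S * (1 - Qs / 2))
          if (open_terminal) {
            le <- le + S[k, ] * (1 - Qs[k, ]) / (-log(1 - Qs[k, ]))
          }
          le
        }, numeric(ncol(Q)))                        # draws x start_ages
      })
      purrr::map_dfr(groups, function(g) {
        purrr::map_dfr(seq_along(start_ages), function(i) {
          le_g <- le_draws[[g]][, i]
          gain_g <- le_g - le_draws[[reference]][, i]
          tibble(
            sex = s, group = g, start_age = start_ages[i],
            le_lo = unname(quantile(le_g, 0.025)),
            le_hi = unname(quantile(le_g, 0.975)),
            gain_lo = unname(quantile(gain_g, 0.025)),
            gain_hi = unname(quantile(gain_g, 0.975))
          )
        })
      })
    }))
    point <- left_join(point, ci, by = c("sex", "group", "start_age"))
  }
  structure(
    point |> dplyr::relocate(dplyr::any_of(
      c("sex", "group", "start_age", "le", "le_lo", "le_hi",
        "gain", "gain_lo", "gain_hi"))),
    class = c("le_estimates", class(point)),
    n_draws = n_draws, reference = reference, seed = seed
  )
}

#' Empirical exposure prevalence by sex and 10-year age band
#'
#' @param data Analysis cohort tibble with `sex`, `age`, and the group
#'   column.
#' @param group_col Name of the exposure-group column.
#' @param band_width Band width in years (10 by convention).
#' @return Prevalence tibble suitable for [reference_hazard()]; every group
#'   appears in every band (zero where unobserved).
#' @export
prevalence_from_cohort <- function(data, group_col, band_width = 10) {
  stop_missing_fields(data, c("sex", "age", group_col), "analysis cohort")
  lo <- floor(min(data$age) / band_width) * band_width
  dat <- data |>
    mutate(
      band_lo = pmax(lo, floor(.data$age / band_width) * band_width),
      age_band = paste0(.data$band_lo, "-", .data$band_lo + band_width - 1),
      group = as.character(.data[[group_col]])
    )
  dat |>
    count(.data$sex, .data$age_band, .data$group) |>
    group_by(.data$sex, .data$age_band) |>
    tidyr::complete(group = unique(dat$group), fill = list(n = 0L)) |>
    mutate(prevalence = .data$n / sum(.data$n)) |>
    ungroup() |>
    dplyr::select("sex", "age_band", "group", "prevalence")
}
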