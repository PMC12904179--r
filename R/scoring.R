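resolve_anchor <- function(anchor, sex) {
  if (is.list(anchor)) {
    stop_missing_fields(anchor, unique(sex), "sex-specific anchor")
    unlist(anchor[sex], use.names = FALSE)
  } else {
    rep(anchor, length(sex))
  }
}

component_value <- function(profiles, fields) {
  stop_missing_fields(profiles, fields, "intake profile")
  if (length(fields) == 1) return(profiles[[fields]])
  rowSums(as.matrix(profiles[fields]))
}

score_one_component <- function(profiles, comp) {
  x <- component_value(profiles, comp$fields[[1]])
  if (anyNA(x)) {
    abort(paste0("Component '", comp$component, "' has missing intake values."))
  }
  sex <- profiles$sex
  anch <- comp$anchors[[1]]
  switch(comp$rule,
    absolute = {
      worst <- resolve_anchor(anch$worst, sex)
      best <- resolve_anchor(anch$best, sex)
      comp$min_points + anchor_points(x, worst, best,
                                      max_points = comp$max_points - comp$min_points)
    },
    tent = {
      tent_points(x,
        zero_pts = anch$zero_pts,
        opt_lo = resolve_anchor(anch$opt_lo, sex),
        opt_hi = resolve_anchor(anch$opt_hi, sex),
        upper = resolve_anchor(anch$upper, sex),
        max_points = comp$max_points
      )
    },
    quintile = as.numeric(quintile_rank(
      x,
      sex = if (comp$sex_specific) sex else NULL,
      reverse = comp$direction == "lower",
      n_groups = 5L
    )),
    abort(paste0("Unknown rule '", comp$rule, "'."))
  )
}

#' Score a cohort of intake profiles against one dietary index
#'
#' Cohort-level scoring: quintile-rule components are ranked against the
#' cohort distribution (sex-specific where the spec says so), absolute and
#' tent components are scored per participant against their anchors. The
#' per-component point breakdown is attached as the `"components"` attribute.
#'
#' @param profiles Tibble of averaged intake profiles: `participant_id`,
#'   `sex` (`"male"`/`"female"`), and the intake fields the spec needs.
#' @param spec A [scoring_spec()]; defaults to the shipped definition.
#' @return Tibble with `participant_id` and `score`; attribute `"components"`
#'   holds the per-component points, attribute `"range"` the declared range.
#' @export
score_index <- function(profiles, spec) {
  stopifnot(inherits(spec, "scoring_spec"))
  stop_missing_fields(profiles, c("participant_id", "sex"), "intake profile")
  pts <- purrr::map(seq_len(nrow(spec$components)), function(i) {
    score_one_component(profiles, spec$components[i, ])
  })
  names(pts) <- spec$components$component
  breakdown <- tibble::as_tibble(pts)
  total <- rowSums(as.matrix(breakdown))
  out <- tibble(participant_id = profiles$participant_id, score = total)
  attr(out, "components") <- dplyr::bind_cols(
    tibble(participant_id = profiles$participant_id), breakdown
  )
  attr(out, "range") <- spec$range
  attr(out, "index") <- spec$index
  out
}

#' @rdname score_index
#' @export
score_ahei <- function(profiles, spec = default_scoring_specs("ahei")) {
  score_index(profiles, spec)
}

#' @rdname score_index
#' @export
score_amed <- function(profiles, spec = default_scoring_specs("amed")) {
  score_index(profiles, spec)
}

#' @rdname score_index
#' @export
score_hpdi <- function(profiles, spec = default_scoring_specs("hpdi")) {
  score_index(profiles, spec)
}

#' @rdname score_index
#' @export
score_dash <- function(profiles, spec = default_scoring_specs("dash")) {
  score_index(profiles, spec)
}

#' @rdname score_index
#' @export
score_drrd <- function(profiles, spec = default_scoring_specs("drrd")) {
  score_index(profiles, spec)
}

#' Compute all five dietary pattern scores plus cohort quintile labels
#'
#' @param profiles Averaged intake profiles (see [score_index()]).
#' @param specs Named list of `scoring_spec`s; defaults to the shipped five.
#' @return Tibble with `participant_id`, one score column per index, and one
#'   `<index>_q` quintile-label column per index (1 = lowest score).
#' @export
score_diet <- function(profiles, specs = default_scoring_specs()) {
  out <- tibble(participant_id = profiles$participant_id)
  for (nm in names(specs)) {
    sc <- score_index(profiles, specs[[nm]])
    out[[nm]] <- sc$score
    out[[paste0(nm, "_q")]] <- quintile_rank(sc$score, n_groups = 5L)
  }
  out
}

#' Score an index with the alcohol component removed
#'
#' @param profiles Averaged intake profiles.
#' @param index `"ahei"` or `"amed"`.
#' @return As [score_index()]; the attached range reflects the dropped
#'   component (AHEI 0-100, AMED 9-45).
#' @export
score_without_alcohol <- function(profiles, index = c("ahei", "amed")) {
  index <- match.arg(index)
  score_index(profiles, spec_without_alcohol(default_scoring_specs(index)))
}

#' Spearman rank-correlation matrix between dietary scores
#'
#' @param scores Tibble of per-participant scores (output of [score_diet()]);
#'   only the score columns named in `indices` are used.
#' @param indices Character vector of score column names.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
score_correlations <- function(scores,
                               indices = c("ahei", "amed", "hpdi", "dash", "drrd")) {
  stop_missing_fields(scores, indices, "scores table")
  stats::cor(as.matrix(scores[indices]), method = "spearman")
}
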