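#' Longevity polygenic risk score as a weighted allele sum
#'
#' `prs_i = sum_j beta_j * dosage_ij`, where the dosage is the effect-allele
#' count (0-2, fractional allowed for imputed genotypes) and each weight is
#' the years of life gained per effect allele. The score is kept on its
#' natural years scale — no standardization — and a higher value means a
#' greater genetic predisposition to longevity. Effect-allele orientation is
#' the weight table's responsibility; dosage columns are never flipped.
#'
#' @param dosages Tibble: `participant_id` plus one column per SNP, values in
#'   `[0, 2]`. Column names must match `weights$snp_id` exactly.
#' @param weights Tibble with `snp_id`, `effect_allele`, `weight` (finite,
#'   no duplicate ids).
#' @param tertiles Attach tertile labels (low/intermediate/high).
#' @return Tibble with `participant_id`, `prs`, and (optionally)
#'   `prs_tertile`.
#' @export
compute_prs <- function(dosages, weights, tertiles = TRUE) {
  stop_missing_fields(weights, c("snp_id", "effect_allele", "weight"), "weight table")
  if (anyDuplicated(weights$snp_id)) abort("Duplicate snp_id in weight table.")
  if (any(!is.finite(weights$weight))) abort("Non-finite weight in weight table.")
  snp_cols <- setdiff(names(dosages), "participant_id")
  unmatched <- c(setdiff(snp_cols, weights$snp_id), setdiff(weights$snp_id, snp_cols))
  if (length(unmatched)) {
    abort(paste0("SNP columns and weight rows do not match: ",
                 paste(unmatched, collapse = ", ")))
  }
  m <- as.matrix(dosages[weights$snp_id])
  if (any(m < 0 | m > 2, na.rm = TRUE)) {
    abort("Dosage outside [0, 2] detected.")
  }
  out <- tibble(
    participant_id = dosages$participant_id,
    prs = as.numeric(m %*% weights$weight)
  )
  if (tertiles) out$prs_tertile <- prs_tertiles(out$prs)
  out
}

#' Cut polygenic scores at the empirical tertiles
#'
#' Ranks with average-rank tie handling, then maps rank to thirds by
#' `ceiling(3 * rank / n)` — the same tie rule the dietary quintiles use —
#' so tied values always share a label.
#'
#' @param prs Numeric vector.
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @export
prs_tertiles <- function(prs) {
  if (length(unique(prs)) < 3) {
    abort("Degenerate polygenic score distribution: fewer than 3 distinct values.")
  }
  g <- quintile_rank(prs, n_groups = 3L)
  factor(c("low", "intermediate", "high")[g],
         levels = c("low", "intermediate", "high"))
}
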