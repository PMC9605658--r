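#' Deauville 5-point score for a follow-up scan
#'
#' Grades residual uptake against the mediastinal blood pool and the liver:
#' DS 1 = no residual uptake; DS 2 = residual <= mediastinum; DS 3 = above
#' mediastinum but <= liver; DS 4 = moderately above liver; DS 5 = markedly
#' above liver (quantified as more than `ds5_factor` x liver SUVmean,
#' default 2) or any new lesion. The visual "moderate vs marked" boundary has
#' no universal numeric definition, so `ds5_factor` is configurable.
#'
#' @param residual_suvmax maximum residual SUV over the scan's lesion masks;
#'   `NA` or 0 means no residual uptake.
#' @param mediastinum_mean,liver_mean reference SUVmeans (> 0, with
#'   mediastinum < liver).
#' @param new_lesions logical: any new site of disease (forces DS 5).
#' @param ds5_factor multiplier on `liver_mean` separating DS 4 from DS 5.
#' @return an object of class `deauville_score`: list with `ds` (integer
#'   1-5) and the basis values used.
#' @export
assign_deauville <- function(residual_suvmax, mediastinum_mean, liver_mean,
                             new_lesions = FALSE, ds5_factor = 2.0) {
  if (!is.finite(mediastinum_mean) || !is.finite(liver_mean) ||
      mediastinum_mean <= 0 || liver_mean <= 0)
    stop("reference SUVmeans must be positive and finite")
  if (mediastinum_mean >= liver_mean)
    stop("mediastinal blood pool mean must be below the liver mean")
  no_residual <- is.na(residual_suvmax) || residual_suvmax <= 0
  ds <- if (new_lesions) 5L
  else if (no_residual) 1L
  else if (residual_suvmax <= mediastinum_mean) 2L
  else if (residual_suvmax <= liver_mean) 3L
  else if (residual_suvmax <= ds5_factor * liver_mean) 4L
  else 5L
  structure(list(ds = ds,
                 residual_suvmax = if (no_residual) NA_real_ else residual_suvmax,
                 mediastinum_mean = mediastinum_mean,
                 liver_mean = liver_mean,
                 new_lesion_flag = isTRUE(new_lesions),
                 ds5_factor = ds5_factor),
            class = "deauville_score")
}

#' @export
print.deauville_score <- function(x, ...) {
  cat(sprintf("<deauville_score> DS %d (residual %.3g, mediastinum %.3g, liver %.3g)\n",
              x$ds, x$residual_suvmax, x$mediastinum_mean, x$liver_mean))
  invisible(x)
}

#' Dichotomize a Deauville score for the regression stage
#'
#' For a cut level `s`, `outcome = "at_most"` (default) codes achieving
#' `DS <= s` as 1 — the monotone "adequate response at this stringency"
#' reading; `outcome = "exactly"` codes `DS == s` as 1. Both readings of the
#' per-column binarization are exposed because published table semantics of
#' "DS 2 / DS 3 / DS 4 / DS 5" columns are often ambiguous.
#'
#' @param ds a `deauville_score` or an integer vector of scores 1-5.
#' @param cut integer cut level in 2..5.
#' @param outcome `"at_most"` or `"exactly"`.
#' @return integer 0/1 (vectorized over `ds`).
#' @export
dichotomize_deauville <- function(ds, cut, outcome = c("at_most", "exactly")) {
  outcome <- match.arg(outcome)
  if (inherits(ds, "deauville_score")) ds <- ds$ds
  stopifnot(cut %in% 2:5, all(is.na(ds) | ds %in% 1:5))
  if (outcome == "at_most") as.integer(ds <= cut) else as.integer(ds == cut)
}
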