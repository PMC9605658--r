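#' Pearson correlation with linear regression fit
#'
#' Pairwise-complete Pearson correlation (rho) with its two-sided t-test
#' p-value (`t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df, the
#' classical test computed by [stats::cor.test()]) plus the ordinary
#' least-squares slope and intercept of `y` on `x`. Pairs with a missing
#' value in either argument are dropped listwise. Zero variance in either
#' argument leaves rho undefined (`NA`), reported rather than erroring.
#'
#' @param x,y paired numeric vectors.
#' @return list: `rho`, `p`, `slope`, `intercept`, `n`.
#' @export
pearson_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("pearson_regression needs at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, slope = NA_real_,
                intercept = NA_real_, n = n))
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  list(rho = unname(ct$estimate), p = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n = n)
}

#' Bland-Altman agreement between two methods
#'
#' Differences are taken as `x - y` in the argument order given. Returns the
#' bias (mean difference), the sample SD of the differences (n - 1
#' denominator) and limits of agreement `bias +/- loa_multiplier * sd`
#' (1.96 by convention; the raw `+/- 1 SD` lines some plots show correspond
#' to `loa_multiplier = 1`).
#'
#' @param x,y paired numeric vectors (method A, method B).
#' @param loa_multiplier multiplier for the limits of agreement.
#' @return list: `bias`, `sd`, `loa_low`, `loa_high`, `n`, and the per-pair
#'   `means` and `diffs` for plotting.
#' @export
bland_altman <- function(x, y, loa_multiplier = 1.96) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("bland_altman needs at least 2 complete pairs")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd = s,
       loa_low = bias - loa_multiplier * s,
       loa_high = bias + loa_multiplier * s,
       n = length(d), means = (x + y) / 2, diffs = d)
}

#' Univariable logistic regression with Wald inference
#'
#' Fits `outcome ~ predictor` by maximum likelihood ([stats::glm()],
#' binomial/logit) and reports the coefficient, the odds ratio per unit with
#' its Wald 95% CI (`exp(coef +/- 1.96 * SE)`) and two-sided p-value, plus
#' the same quantities per SD of the predictor (useful when the predictor is
#' a large-range volume, where the per-unit OR rounds to 1). Complete or
#' quasi-separation is detected (non-convergence, or |coef| exploding on the
#' standardized scale) and flagged `converged = FALSE`, never silently
#' dropped.
#'
#' @param outcome 0/1 vector (both classes present, n >= 10).
#' @param predictor numeric vector.
#' @return an object of class `logistic_fit`: list with `coef`, `se`, `or_`,
#'   `ci95`, `p`, `coef_per_sd`, `or_per_sd`, `ci95_per_sd`, `converged`,
#'   `n`, `events`.
#' @export
logistic_fit <- function(outcome, predictor) {
  ok <- is.finite(outcome) & is.finite(predictor)
  outcome <- outcome[ok]; predictor <- predictor[ok]
  if (!all(outcome %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(outcome)) < 2L)
    stop("outcome has a single class; logistic fit undefined")
  if (length(outcome) < 10L) stop("logistic_fit needs n >= 10")
  sdx <- stats::sd(predictor)
  fit <- suppressWarnings(
    stats::glm(outcome ~ predictor, family = stats::binomial()))
  sm <- summary(fit)
  co <- sm$coefficients["predictor", ]
  b <- unname(co["Estimate"]); se <- unname(co["Std. Error"])
  p <- unname(co["Pr(>|z|)"])
  converged <- fit$converged && is.finite(b) && abs(b * sdx) < 15
  structure(list(
    coef = b, se = se, or_ = exp(b),
    ci95 = exp(b + c(-1, 1) * 1.96 * se), p = p,
    coef_per_sd = b * sdx, or_per_sd = exp(b * sdx),
    ci95_per_sd = exp(b * sdx + c(-1, 1) * 1.96 * se * sdx),
    converged = converged,
    n = length(outcome), events = sum(outcome)),
    class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit> OR %.3g (95%% CI %.3g-%.3g), p = %.3g, n = %d (%d events)%s\n",
    x$or_, x$ci95[1], x$ci95[2], x$p, x$n, x$events,
    if (!x$converged) " [NOT converged / separation]" else ""))
  invisible(x)
}

# The six method pairs in their conventional printed order.
method_pairs <- function() {
  list(c("v25", "v41"), c("v25", "am"), c("v25", "vliver"),
       c("am", "vliver"), c("v41", "am"), c("v41", "vliver"))
}

agreement_parameters <- c("suvmean", "mtv_ml", "tlg")

# Wide table of one parameter: rows = patients, columns = methods.
reshape_param <- function(records, param, tp) {
  sub <- records[records$timepoint == tp, c("patient_id", "method", param)]
  stats::reshape(sub, idvar = "patient_id", timevar = "method",
                 direction = "wide")
}

# Per-patient percent changes from PET1 for one parameter and method.
delta_table <- function(records, param, follow_tp) {
  base <- records[records$timepoint == "PET1", ]
  fol <- records[records$timepoint == follow_tp, ]
  key_b <- paste(base$patient_id, base$method)
  key_f <- paste(fol$patient_id, fol$method)
  m <- match(key_f, key_b)
  delta <- if (nrow(fol)) mapply(percent_change, base[[param]][m],
                                 fol[[param]]) else numeric(0)
  data.frame(patient_id = fol$patient_id, method = fol$method,
             delta = delta, stringsAsFactors = FALSE)
}

#' Pairwise method-agreement battery
#'
#' For every method pair, parameter (SUVmean, MTV, TLG) and column (absolute
#' values at each timepoint, plus percent changes from baseline to each
#' follow-up) computes the Pearson/regression statistics and the
#' Bland-Altman bias and limits of agreement across patients. Cells with
#' fewer than 3 complete pairs, or with zero variance, are reported with
#' `NA` statistics and a reason, never dropped silently. A
#' Benjamini-Hochberg adjusted p-value column is appended for reference; no
#' significance flag uses it.
#'
#' @param records long-format scan records: one row per patient x timepoint
#'   x method with columns `patient_id`, `timepoint`, `method`, `suvmean`,
#'   `mtv_ml`, `tlg` (output of [aggregate_scan()] / the pipeline).
#' @param timepoints absolute-value columns to include.
#' @param deltas follow-up timepoints for percent-change columns.
#' @param loa_multiplier passed to [bland_altman()].
#' @return data.frame with one row per pair x parameter x column:
#'   `pair`, `method_a`, `method_b`, `parameter`, `column`, `n`, `rho`, `p`,
#'   `slope`, `intercept`, `bias`, `sd`, `loa_low`, `loa_high`, `note`,
#'   `p_bh`.
#' @export
run_agreement_battery <- function(records,
                                  timepoints = c("PET1", "PET2", "PET3"),
                                  deltas = c("PET2", "PET3"),
                                  loa_multiplier = 1.96) {
  timepoints <- intersect(timepoints, unique(records$timepoint))
  cols <- c(timepoints, paste0("d", intersect(deltas, timepoints)))
  rows <- list()
  for (param in agreement_parameters) {
    for (col in cols) {
      if (startsWith(col, "d")) {
        dt <- delta_table(records, param, sub("^d", "", col))
        wide <- stats::reshape(dt, idvar = "patient_id", timevar = "method",
                               direction = "wide")
        prefix <- "delta."
      } else {
        wide <- reshape_param(records, param, col)
        prefix <- paste0(param, ".")
      }
      for (pair in method_pairs()) {
        a <- wide[[paste0(prefix, pair[1])]]
        b <- wide[[paste0(prefix, pair[2])]]
        ok <- if (is.null(a) || is.null(b)) logical(0) else
          is.finite(a) & is.finite(b)
        n_ok <- sum(ok)
        row <- data.frame(
          pair = paste(pair[1], "vs", pair[2]),
          method_a = pair[1], method_b = pair[2],
          parameter = param, column = col, n = n_ok,
          rho = NA_real_, p = NA_real_, slope = NA_real_,
          intercept = NA_real_, bias = NA_real_, sd = NA_real_,
          loa_low = NA_real_, loa_high = NA_real_, note = "",
          stringsAsFactors = FALSE)
        if (n_ok < 3L) {
          row$note <- "fewer than 3 complete pairs"
        } else {
          pr <- pearson_regression(a[ok], b[ok])
          ba <- bland_altman(a[ok], b[ok], loa_multiplier = loa_multiplier)
          row$rho <- pr$rho; row$p <- pr$p
          row$slope <- pr$slope; row$intercept <- pr$intercept
          row$bias <- ba$bias; row$sd <- ba$sd
          row$loa_low <- ba$loa_low; row$loa_high <- ba$loa_high
          if (is.na(pr$rho)) row$note <- "zero variance"
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Deauville-outcome logistic regression battery
#'
#' For each method x parameter, regresses the dichotomized end-of-therapy
#' Deauville outcome (one column per cut DS 2..5) on the baseline absolute
#' value and on the baseline-to-interim percent change. Cells where the fit
#' is impossible (single-class outcome, zero-variance predictor, too few
#' patients) are reported with a reason, mirroring the "-" cells of
#' published tables; separation is flagged via `converged`.
#'
#' @param records long-format scan records (as for
#'   [run_agreement_battery()]) whose `ds` column carries the PET3 Deauville
#'   score (any row of the patient may carry it; the maximum non-missing
#'   value per patient at the `ds_timepoint` is used).
#' @param parameters metric columns to use as predictors.
#' @param cuts Deauville cut levels.
#' @param outcome passed to [dichotomize_deauville()].
#' @param ds_timepoint timepoint whose `ds` column is the outcome.
#' @param delta_from interim timepoint for the percent-change predictors.
#' @return data.frame: one row per method x parameter x variant
#'   (absolute/delta) x cut, with `p`, `or_`, `ci_low`, `ci_high`,
#'   `or_per_sd`, `ci_low_per_sd`, `ci_high_per_sd`, `converged`, `n`,
#'   `events`, `note`.
#' @export
run_ds_regression <- function(records, parameters = agreement_parameters,
                              cuts = 2:5,
                              outcome = c("at_most", "exactly"),
                              ds_timepoint = "PET3", delta_from = "PET2") {
  outcome <- match.arg(outcome)
  ds_rows <- records[records$timepoint == ds_timepoint & !is.na(records$ds), ]
  ds_by_patient <- tapply(ds_rows$ds, ds_rows$patient_id, max)
  methods <- unique(records$method)
  rows <- list()
  for (method in methods) {
    for (param in parameters) {
      base <- records[records$timepoint == "PET1" & records$method == method, ]
      preds <- list(
        absolute = stats::setNames(base[[param]], base$patient_id))
      dt <- delta_table(records[records$method == method, ], param, delta_from)
      preds$delta <- stats::setNames(dt$delta, dt$patient_id)
      for (variant in names(preds)) {
        pred <- preds[[variant]]
        ds <- ds_by_patient[names(pred)]
        for (cut in cuts) {
          y <- dichotomize_deauville(as.integer(ds), cut, outcome = outcome)
          row <- data.frame(method = method, parameter = param,
                            variant = variant, cut = cut,
                            p = NA_real_, or_ = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            or_per_sd = NA_real_,
                            ci_low_per_sd = NA_real_,
                            ci_high_per_sd = NA_real_,
                            converged = NA, n = NA_integer_,
                            events = NA_integer_, note = "",
                            stringsAsFactors = FALSE)
          ok <- is.finite(y) & is.finite(pred)
          if (sum(ok) < 10L) {
            row$note <- "fewer than 10 complete observations"
          } else if (length(unique(y[ok])) < 2L) {
            row$note <- "single-class outcome"
          } else if (stats::sd(pred[ok]) == 0) {
            row$note <- "zero-variance predictor"
          } else {
            f <- logistic_fit(y[ok], pred[ok])
            row$p <- f$p; row$or_ <- f$or_
            row$ci_low <- f$ci95[1]; row$ci_high <- f$ci95[2]
            row$or_per_sd <- f$or_per_sd
            row$ci_low_per_sd <- f$ci95_per_sd[1]
            row$ci_high_per_sd <- f$ci95_per_sd[2]
            row$converged <- f$converged
            row$n <- f$n; row$events <- f$events
            if (!f$converged) row$note <- "separation / non-convergence"
          }
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  do.call(rbind, rows)
}
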