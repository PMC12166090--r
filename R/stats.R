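#' Build the time-to-recurrence endpoint
#'
#' Applies the follow-up cutoff (60 months by default): times are truncated
#' at the cutoff and any event occurring after it is recoded as censored at
#' the cutoff, since clinical data across cohorts is heterogeneous beyond
#' five years.
#'
#' @param frame data frame with follow-up and event columns.
#' @param cfg a [pipeline_config()].
#' @param time_col,event_col column names of follow-up months and the event
#'   indicator (0/1).
#' @return `frame` with columns `ttr_months` and `ttr_event` appended.
#' @export
build_ttr <- function(frame, cfg = pipeline_config(),
                      time_col = "followup_months", event_col = "event") {
  cfg <- as_config(cfg)
  t <- frame[[time_col]]
  e <- frame[[event_col]]
  if (is.null(t) || is.null(e))
    stop("missing follow-up or event column", call. = FALSE)
  if (any(t < 0, na.rm = TRUE))
    stop("negative follow-up time", call. = FALSE)
  if (!all(e %in% c(0, 1, NA)))
    stop("event indicator must be 0/1", call. = FALSE)
  cut <- cfg$followup_cutoff_months
  frame$ttr_months <- pmin(t, cut)
  frame$ttr_event <- as.integer(ifelse(t > cut, 0L, e))
  frame
}

#' Log-transform immune scores for survival modelling
#'
#' Lymphocyte and eosinophil scores are replaced by `log(1 + max(x, 0))` so
#' they scale linearly in the Cox model; `log1p` (rather than a raw log) is
#' used because normalized scores can be zero, and the floor at zero guards
#' against normalized values slightly below the stage-II 5th percentile.
#' The IEL ratio is left untransformed.
#'
#' @param frame data frame with score columns.
#' @param score_cols columns to transform (defaults to the six
#'   lymphocyte/eosinophil scores present).
#' @return `frame` with the named columns transformed.
#' @export
transform_scores <- function(frame,
                             score_cols = intersect(
                               c("LymF", "LymC", "LymA",
                                 "EosF", "EosC", "EosA"), names(frame))) {
  for (sc in score_cols) frame[[sc]] <- log1p(pmax(frame[[sc]], 0))
  frame
}

#' Spearman rank-correlation matrix
#'
#' Pairwise Spearman correlations between score columns, with p-values;
#' rank correlation is used to ignore scale differences between scores.
#' Entries with fewer than 3 complete pairs are `NA`.
#'
#' @param frame data frame.
#' @param score_cols columns to correlate.
#' @return List with matrices `rho`, `p` and `n`.
#' @export
correlation_matrix <- function(frame, score_cols = intersect(SCORE_COLS,
                                                             names(frame))) {
  k <- length(score_cols)
  rho <- p <- n <- matrix(NA_real_, k, k,
                          dimnames = list(score_cols, score_cols))
  for (i in seq_len(k)) {
    rho[i, i] <- 1; p[i, i] <- 0
    n[i, i] <- sum(!is.na(frame[[score_cols[i]]]))
    for (j in seq_len(k)) {
      if (j <= i) next
      x <- frame[[score_cols[i]]]; y <- frame[[score_cols[j]]]
      ok <- !is.na(x) & !is.na(y)
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) >= 3L) {
        ct <- suppressWarnings(
          stats::cor.test(x[ok], y[ok], method = "spearman"))
        rho[i, j] <- rho[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      }
    }
  }
  list(rho = rho, p = p, n = n)
}

#' Kendall tau-B association with an ordinal covariate
#'
#' @param score numeric score vector.
#' @param ordinal ordinal covariate (ordered factor or numeric codes).
#' @return List with `tau` (tau-B, tie-corrected) and `p` (tie-corrected
#'   normal approximation).
#' @export
ordinal_association <- function(score, ordinal) {
  ord <- if (is.factor(ordinal)) as.integer(ordinal) else as.numeric(ordinal)
  ok <- !is.na(score) & !is.na(ord)
  if (sum(ok) < 3L) return(list(tau = NA_real_, p = NA_real_))
  ct <- suppressWarnings(
    stats::cor.test(score[ok], ord[ok], method = "kendall"))
  list(tau = unname(ct$estimate), p = ct$p.value)
}

#' Mann-Whitney U comparisons across groups
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) tests for every pair of
#' category levels. No multiple-testing correction is applied; conclusions
#' are drawn per individual comparison.
#'
#' @param score numeric score vector.
#' @param group categorical covariate.
#' @return Data frame `group1`, `group2`, `n1`, `n2`, `p`.
#' @export
group_compare <- function(score, group) {
  group <- as.factor(group)
  lev <- levels(droplevels(group[!is.na(score) & !is.na(group)]))
  if (length(lev) < 2L)
    stop("need at least two non-empty groups", call. = FALSE)
  rows <- list()
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (j <= i) next
    x <- score[group == lev[i] & !is.na(score)]
    y <- score[group == lev[j] & !is.na(score)]
    if (!length(x) || !length(y))
      stop("empty group in comparison", call. = FALSE)
    pv <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    rows[[length(rows) + 1L]] <-
      data.frame(group1 = lev[i], group2 = lev[j], n1 = length(x),
                 n2 = length(y), p = pv, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Kaplan-Meier quartile analysis
#'
#' Splits a continuous score into quartiles with cut points computed on the
#' full cohort (so subgroup plots share the same quartile definition), then
#' fits KM curves per quartile on the requested subset and reports per
#' quartile a Wald p-value against the lowest quartile from a single
#' univariate Cox model on the quartile indicators.
#'
#' @param score numeric score over the full cohort.
#' @param time,event survival endpoint (e.g. from [build_ttr()]).
#' @param subset optional logical vector selecting the analysis subset;
#'   quartile cuts always come from the full cohort.
#' @param score_name label used in messages.
#' @return An object of class `km_quartiles` with the `survfit` object, the
#'   quartile factor, Wald p-values (`NA` for quartiles empty in the
#'   subset) and the underlying Cox fit.
#' @export
km_quartiles <- function(score, time, event, subset = NULL,
                         score_name = deparse(substitute(score))) {
  cuts <- quantile(score, probs = c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
  if (anyDuplicated(cuts) || any(!is.finite(cuts)))
    stop(sprintf("cannot split '%s' into quartiles: ties or constant values",
                 score_name), call. = FALSE)
  q <- cut(score, breaks = c(-Inf, cuts, Inf),
           labels = c("Q1", "Q2", "Q3", "Q4"))
  if (is.null(subset)) subset <- rep(TRUE, length(score))
  keep <- subset & !is.na(q) & !is.na(time) & !is.na(event)
  qs <- factor(q[keep], levels = c("Q1", "Q2", "Q3", "Q4"))
  srv <- survival::Surv(time[keep], event[keep])
  fit_km <- survival::survfit(srv ~ qs)
  present <- levels(droplevels(qs))
  wald <- setNames(rep(NA_real_, 3), c("Q2", "Q3", "Q4"))
  cox <- NULL
  if (length(present) >= 2L && "Q1" %in% present) {
    cox <- survival::coxph(srv ~ droplevels(qs), ties = "efron")
    s <- summary(cox)$coefficients
    for (qq in c("Q2", "Q3", "Q4")) {
      row <- grep(qq, rownames(s))
      if (length(row) == 1L) wald[qq] <- s[row, "Pr(>|z|)"]
    }
  }
  structure(list(survfit = fit_km, quartile = qs, cuts = cuts,
                 wald_p = wald, cox = cox, score_name = score_name,
                 n = sum(keep), events = sum(event[keep])),
            class = "km_quartiles")
}

#' @export
print.km_quartiles <- function(x, ...) {
  cat(sprintf("<km_quartiles> %s: n=%d, events=%d\n", x$score_name, x$n,
              x$events))
  cat("  quartile cuts:", paste(signif(x$cuts, 4), collapse = ", "), "\n")
  cat("  Wald p vs Q1:",
      paste(names(x$wald_p), signif(x$wald_p, 3), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.km_quartiles <- function(x, ...) {
  plot(x$survfit, col = 1:4, xlab = "months", ylab = "recurrence-free",
       main = x$score_name, ...)
  graphics::legend("bottomleft", legend = levels(x$quartile), col = 1:4,
                   lty = 1, bty = "n")
  invisible(x)
}

#' Fit a Cox proportional-hazards model
#'
#' Formula interface over the partial-likelihood fit with Efron tie
#' handling. Rows with missing values in modelled columns are dropped
#' (complete-case, count recorded); a warning is raised below 10 events.
#' Hazard ratios with 95% confidence intervals and Wald p-values are
#' tabulated per covariate, together with the log-likelihood, the
#' likelihood-ratio test, `AIC = 2k - 2 logLik`, and a
#' proportional-hazards diagnostic (score test on scaled Schoenfeld
#' residuals).
#'
#' @param formula model formula whose left side is a
#'   [survival::Surv()] object, e.g. `Surv(ttr_months, ttr_event) ~ EosF +
#'   age`.
#' @param data data frame.
#' @return An object of class `cox_fit`: the coefficient table (`$table`),
#'   `$loglik`, `$lrt_p`, `$aic`, `$n`, `$events`, `$n_dropped`, `$zph`,
#'   and the underlying `survival::coxph` fit (`$fit`).
#' @export
cox_fit <- function(formula, data) {
  # make bare Surv() in user formulas resolve without attaching survival
  environment(formula) <- list2env(list(Surv = survival::Surv),
                                   parent = environment(formula))
  vars <- intersect(all.vars(formula), names(data))
  complete <- stats::complete.cases(data[, vars, drop = FALSE])
  n_dropped <- sum(!complete)
  dat <- data[complete, , drop = FALSE]
  fit <- withCallingHandlers(
    survival::coxph(formula, data = dat, ties = "efron", x = TRUE),
    warning = function(w) {
      if (grepl("did not converge|out of iterations", conditionMessage(w)))
        stop("Cox fit did not converge: ", conditionMessage(w),
             call. = FALSE)
      invokeRestart("muffleWarning")
    })
  # monotone-likelihood / separation: a coefficient running off to infinity
  if (any(abs(stats::coef(fit)) > 15, na.rm = TRUE))
    stop("Cox fit failed: apparent separation (a coefficient diverges)",
         call. = FALSE)
  s <- summary(fit)
  events <- s$nevent
  if (events < 10)
    warning(sprintf("only %d events; estimates may be unstable", events),
            call. = FALSE)
  co <- s$coefficients
  ci <- s$conf.int
  tab <- data.frame(term = rownames(co), hr = unname(co[, "exp(coef)"]),
                    ci_low = unname(ci[, "lower .95"]),
                    ci_high = unname(ci[, "upper .95"]),
                    p = unname(co[, "Pr(>|z|)"]),
                    stringsAsFactors = FALSE)
  zph <- tryCatch(survival::cox.zph(fit), error = function(e) NULL)
  structure(list(table = tab, loglik = fit$loglik[2],
                 lrt_p = unname(s$logtest["pvalue"]),
                 aic = stats::AIC(fit), n = s$n, events = events,
                 n_dropped = n_dropped,
                 zph = zph, fit = fit,
                 subset_id = sort(rownames(dat)),
                 formula = formula),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<cox_fit> n=%d, events=%d (%d rows dropped), AIC=%.1f\n",
              x$n, x$events, x$n_dropped, x$aic))
  tab <- x$table
  tab$hr <- signif(tab$hr, digits)
  tab$ci_low <- signif(tab$ci_low, digits)
  tab$ci_high <- signif(tab$ci_high, digits)
  tab$p <- signif(tab$p, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cox_fit <- function(object, ...) summary(object$fit, ...)

#' @export
coef.cox_fit <- function(object, ...) coef(object$fit)

#' Rank Cox models by AIC
#'
#' Models must be fitted on the identical patient subset, otherwise their
#' likelihoods (and hence AICs) are not comparable and an error is raised.
#'
#' @param fits named list of [cox_fit()] objects.
#' @return Data frame `model`, `k`, `loglik`, `aic`, `delta_aic` in
#'   ascending AIC order.
#' @export
model_compare <- function(fits) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, logical(1),
                                           "cox_fit")))
  ids <- lapply(fits, `[[`, "subset_id")
  if (length(fits) > 1L &&
      !all(vapply(ids[-1], identical, logical(1), ids[[1]])))
    stop("models were fitted on different subsets; AIC not comparable",
         call. = FALSE)
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model", seq_along(fits))
  out <- data.frame(model = nm,
                    k = vapply(fits, function(f) length(coef(f$fit)),
                               numeric(1)),
                    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                    aic = vapply(fits, `[[`, numeric(1), "aic"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$aic), , drop = FALSE]
  out$delta_aic <- out$aic - out$aic[1]
  rownames(out) <- NULL
  out
}
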