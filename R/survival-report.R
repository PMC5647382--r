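#' Kaplan-Meier estimate per subgroup
#'
#' Product-limit estimator of progression-free survival over the distinct
#' event times of each group, with Greenwood standard errors. Subjects
#' censored at an event time are handled by the standard convention
#' (censored after the events at that time).
#'
#' @param records data.frame with columns `time_months` (or `time`),
#'   `event` (1 = event, 0 = censored) and `group`.
#' @return a list of class `km_estimate`: `table` (data.frame `group`,
#'   `time`, `n_risk`, `n_event`, `surv`, `std_err`) and the underlying
#'   `survival::survfit` object as `fit`.
#' @export
km_estimate <- function(records) {
  rec <- normalize_survival(records)
  if (any(rec$time < 0)) stop("negative survival times")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = rec)
  strata <- if (is.null(fit$strata)) setNames(length(fit$time),
                                              unique(rec$group))
            else fit$strata
  grp <- rep(sub("^group=", "", names(strata)), strata)
  tab <- data.frame(group = grp,
                    time = fit$time,
                    n_risk = fit$n.risk,
                    n_event = fit$n.event,
                    surv = fit$surv,
                    std_err = fit$std.err * fit$surv,  # Greenwood, surv scale
                    stringsAsFactors = FALSE)
  out <- list(table = tab, fit = fit)
  class(out) <- "km_estimate"
  out
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("km_estimate:\n")
  print(head(x$table, 20L), row.names = FALSE)
  invisible(x)
}

#' Read a Kaplan-Meier curve at a time point
#'
#' Right-continuous step-function convention: the survival probability at
#' `t` is the estimate after all events at times `<= t`.
#'
#' @param km a [km_estimate()].
#' @param time time point (months).
#' @return named numeric vector, one survival probability per group.
#' @export
km_at <- function(km, time) {
  vapply(split(km$table, km$table$group), function(g) {
    idx <- which(g$time <= time)
    if (!length(idx)) 1 else g$surv[max(idx)]
  }, 0)
}

#' K-group log-rank test
#'
#' Standard log-rank comparison of survival between groups: at each
#' distinct event time the observed events per group are compared with
#' their hypergeometric expectation given the at-risk sets; the resulting
#' chi-square statistic has `k - 1` degrees of freedom. Supports both the
#' four-subgroup comparison and two-group contrasts such as Grp4 vs rest
#' (pass a collapsed `grouping`).
#'
#' @param records data.frame as in [km_estimate()].
#' @param grouping optional replacement grouping vector (e.g.
#'   `ifelse(g == "Grp4", "Grp4", "other")`).
#' @return a list of class `logrank_result`: `chisq`, `df`, `p_value`,
#'   `observed` and `expected` per group, `n` per group.
#' @export
logrank_test <- function(records, grouping = NULL) {
  rec <- normalize_survival(records)
  if (!is.null(grouping)) rec$group <- as.character(grouping)
  if (length(unique(rec$group)) < 2L)
    stop("log-rank test requires at least two groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = rec)
  groups <- sub("^group=", "", names(sd$n))
  k <- length(sd$n)
  p <- pchisq(sd$chisq, df = k - 1L, lower.tail = FALSE)
  out <- list(chisq = unname(sd$chisq),
              df = k - 1L,
              p_value = p,
              observed = setNames(as.numeric(sd$obs), groups),
              expected = setNames(as.numeric(sd$exp), groups),
              n = setNames(as.numeric(sd$n), groups))
  class(out) <- "logrank_result"
  out
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chisq = %.3f on %d df, p = %.4g\n",
              x$chisq, x$df, x$p_value))
  df <- data.frame(group = names(x$n), n = x$n, observed = x$observed,
                   expected = round(x$expected, 2))
  print(df, row.names = FALSE)
  invisible(x)
}

normalize_survival <- function(records) {
  time <- records$time_months %||% records$time
  if (is.null(time)) stop("records need a 'time_months' (or 'time') column")
  if (is.null(records$event) || is.null(records$group))
    stop("records need 'event' and 'group' columns")
  if (!all(records$event %in% c(0, 1))) stop("'event' must be 0/1")
  data.frame(time = as.numeric(time),
             event = as.integer(records$event),
             group = as.character(records$group),
             stringsAsFactors = FALSE)
}

#' Cohort composition and outcome report
#'
#' Tabulates subgroup frequencies among classifiable samples, the QC
#' disposition breakdown of all calls, and (when survival records are
#' supplied) the 5-year progression-free survival per subgroup read from
#' the Kaplan-Meier curve at 60 months.
#'
#' @param calls data.frame from [classify_cohort()] (needs `sample_id`,
#'   `call`, `qc_code`), or a vector of subgroup calls.
#' @param survival optional survival data.frame as in [km_estimate()];
#'   matched to `calls` by `sample_id` when available, and its `group`
#'   column is replaced by the classified calls.
#' @param pfs_months horizon for the survival read-out.
#' @return a list of class `cohort_report`: `frequencies` (classifiable
#'   subgroup counts and percentages), `dispositions` (call/QC tallies
#'   over all samples), `n_total`, `n_classified` and optionally
#'   `pfs` (per-group survival at `pfs_months`).
#' @export
cohort_report <- function(calls, survival = NULL, pfs_months = 60) {
  if (!is.data.frame(calls))
    calls <- data.frame(sample_id = names(calls) %||%
                          sprintf("S%03d", seq_along(calls)),
                        call = as.character(calls),
                        qc_code = ifelse(as.character(calls) %in%
                                           c("NC", "FAIL"), "OTHER", "PASS"),
                        stringsAsFactors = FALSE)
  n_total <- nrow(calls)
  classified <- !(calls$call %in% c("NC", "FAIL"))
  freq <- table(calls$call[classified])
  frequencies <- data.frame(group = names(freq),
                            n = as.integer(freq),
                            percent = 100 * as.integer(freq) /
                              max(sum(classified), 1L),
                            stringsAsFactors = FALSE)
  dispositions <- table(calls$qc_code)
  pfs <- NULL
  if (!is.null(survival) && any(classified)) {
    surv <- survival
    idx <- match(calls$sample_id[classified], surv$sample_id)
    if (!anyNA(idx)) {
      surv <- surv[idx, , drop = FALSE]
      surv$group <- calls$call[classified]
      pfs <- km_at(km_estimate(surv), pfs_months)
    }
  }
  out <- list(frequencies = frequencies,
              dispositions = dispositions,
              n_total = n_total,
              n_classified = sum(classified),
              pfs = pfs,
              pfs_months = pfs_months)
  class(out) <- "cohort_report"
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("cohort_report: %d samples, %d classified (%.0f%%)\n",
              x$n_total, x$n_classified,
              100 * x$n_classified / max(x$n_total, 1L)))
  print(x$frequencies, row.names = FALSE)
  if (!is.null(x$pfs)) {
    cat(sprintf("%g-month PFS by subgroup:\n", x$pfs_months))
    print(round(x$pfs, 3))
  }
  invisible(x)
}
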