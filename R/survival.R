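#' Quartile (or half) stratification of a continuous variable
#'
#' Cut points are the empirical 25/50/75 percentiles (linear-interpolation
#' quantiles, R type 7); values equal to a cut point go to the lower group so
#' assignment is deterministic under ties.
#'
#' @param values Named numeric vector (names = sample ids), n >= 8 for
#'   quartiles, n >= 4 for halves.
#' @param n_groups 4 (quartiles, default) or 2 (median split).
#' @return data.frame `sample`, `group` (factor Q1..Q4 or low/high);
#'   attribute `cut_points`.
#' @export
quartile_groups <- function(values, n_groups = 4) {
  stopifnot(n_groups %in% c(2L, 4L))
  if (is.null(names(values))) stop("values must be named by sample id")
  values <- values[is.finite(values)]
  n_min <- 2L * n_groups
  if (length(values) < n_min)
    stop("need >= ", n_min, " samples for ", n_groups, "-group stratification, got ",
         length(values))
  if (max(values) == min(values))
    stop("values are constant; no stratification possible")
  probs <- seq_len(n_groups - 1L) / n_groups
  cuts <- stats::quantile(values, probs = probs, type = 7, names = FALSE)
  labels <- if (n_groups == 4L) c("Q1", "Q2", "Q3", "Q4") else c("low", "high")
  # right-closed intervals: a value equal to a cut point falls in the lower group
  grp <- cut(values, breaks = c(-Inf, cuts, Inf), labels = labels, right = TRUE)
  out <- data.frame(sample = names(values), group = grp,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "cut_points") <- cuts
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over [survival::survfit()] returning the stepwise survival
#' curve: S(0) = 1, steps only at event times, censored-only times reduce the
#' risk set without a step.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators, 1 = death, 0 = censored.
#' @return data.frame `time`, `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("km_estimate: empty input")
  stopifnot(length(times) == length(events))
  if (any(times < 0)) stop("times must be >= 0")
  if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Mantel-Haenszel log-rank test across k groups
#'
#' Unweighted log-rank via [survival::survdiff()]; the chi-square statistic
#' has k - 1 degrees of freedom. For the quartile overall-survival screen,
#' k = 4 and the resulting p-value is the per-transcript OS criterion
#' consumed by [evaluate_criteria()].
#'
#' @param groups Group labels (factor or character), >= 2 nonempty groups.
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 death, 0 censored); >= 1 event required.
#' @return list `chisq`, `df`, `p_value`, `n`, `obs`, `exp` (per-group
#'   observed and expected event counts).
#' @export
logrank_test <- function(groups, times, events) {
  stopifnot(length(groups) == length(times), length(times) == length(events))
  keep <- !is.na(groups) & is.finite(times) & !is.na(events)
  if (sum(events[keep]) < 1)
    stop("log-rank requires >= 1 event among samples with group labels")
  groups <- factor(groups[keep]); times <- times[keep]; events <- events[keep]
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("log-rank requires >= 2 nonempty groups")
  sd_fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1L
  list(chisq = unname(sd_fit$chisq), df = df,
       p_value = stats::pchisq(sd_fit$chisq, df = df, lower.tail = FALSE),
       n = length(times), obs = sd_fit$obs, exp = sd_fit$exp)
}

#' Quartile log-rank screen of one transcript against overall survival
#'
#' Stratifies tumor samples by expression quartiles of the transcript and
#' tests survival differences across the four groups. Samples without
#' survival data are excluded (with a message from [survival_samples()]).
#'
#' @param cohort An `lnc_cohort`.
#' @param transcript Transcript identifier (row of the matrix).
#' @param n_groups 4 (quartiles, default) or 2 (median split).
#' @return list `stratification` (see [quartile_groups()]), `test`
#'   (see [logrank_test()]).
#' @export
os_quartile_test <- function(cohort, transcript, n_groups = 4) {
  if (!transcript %in% rownames(cohort$expr))
    stop("transcript not in expression matrix: ", transcript)
  ids <- survival_samples(cohort)
  vals <- cohort$expr[transcript, ids]
  names(vals) <- ids
  strat <- quartile_groups(vals, n_groups = n_groups)
  cl <- cohort$clinical[match(strat$sample, cohort$clinical$sample), ]
  test <- logrank_test(strat$group, cl$os_time, cl$os_event)
  list(stratification = strat, test = test)
}

#' Two-group comparison of expression by recurrence status
#'
#' Wilcoxon rank-sum test of a transcript's expression between tumors with
#' and without recurrence, the comparison used for recurrence boxplots.
#'
#' @param cohort An `lnc_cohort`.
#' @param transcript Transcript identifier.
#' @return list `p_value`, `n_no`, `n_yes`, `median_no`, `median_yes`.
#' @export
recurrence_test <- function(cohort, transcript) {
  if (!transcript %in% rownames(cohort$expr))
    stop("transcript not in expression matrix: ", transcript)
  cl <- cohort$clinical
  keep <- cl$tissue == "tumor" & !is.na(cl$recurrence)
  if (sum(keep) < 4L) stop("need >= 4 tumors with recurrence status")
  x <- cohort$expr[transcript, cl$sample[keep]]
  rec <- cl$recurrence[keep]
  if (length(unique(rec)) < 2L) stop("recurrence status has a single level")
  wt <- stats::wilcox.test(x[rec == "yes"], x[rec == "no"], exact = FALSE)
  list(p_value = wt$p.value, n_no = sum(rec == "no"), n_yes = sum(rec == "yes"),
       median_no = stats::median(x[rec == "no"]),
       median_yes = stats::median(x[rec == "yes"]))
}
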