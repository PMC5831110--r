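#' Summarize cohort composition and data availability
#'
#' For every clinical field, reports how many patients have a value and
#' what percent of the cohort that is; for categorical fields, the count
#' and percent of *available* patients at each level. Percents are rounded
#' half-up to one decimal; an integer (prose-style) form is included.
#'
#' @param clin a `clinical_table` data.frame.
#' @param fields columns to summarize (default: all except `sample_id`).
#' @return data.frame: `field`, `level` (NA for the availability row),
#'   `n`, `pct` (one decimal), `pct_int`.
#' @export
summarize_cohort <- function(clin, fields = setdiff(colnames(clin), "sample_id")) {
  total <- nrow(clin)
  rows <- list()
  for (f in fields) {
    x <- clin[[f]]
    avail <- !is.na(x) & !(is.character(x) & !nzchar(as.character(x)))
    n_av <- sum(avail)
    raw_av <- if (total > 0) 100 * n_av / total else 0
    rows[[length(rows) + 1L]] <- data.frame(
      field = f, level = NA_character_, n = n_av,
      pct = round_half_up(raw_av, 1),
      pct_int = round_half_up(raw_av, 0), stringsAsFactors = FALSE)
    if (is.character(x) || is.factor(x) || is.logical(x)) {
      lv <- table(x[avail])
      for (l in names(lv)) {
        raw <- if (n_av > 0) 100 * lv[[l]] / n_av else 0
        rows[[length(rows) + 1L]] <- data.frame(
          field = f, level = l, n = lv[[l]],
          pct = round_half_up(raw, 1),
          pct_int = round_half_up(raw, 0), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis rank-sum comparison of expression across groups
#'
#' Midrank-based H with tie correction and a chi-square reference on
#' `groups - 1` degrees of freedom.
#'
#' @param values numeric vector.
#' @param groups group labels aligned to `values`.
#' @return list: `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) == 0)) {
    stop("empty group(s): ",
         paste(levels(groups)[table(groups) == 0], collapse = ", "), call. = FALSE)
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Dichotomize expression into high/low groups
#'
#' Default rule is a median split: values strictly above the cut-point are
#' "high", everything else (including ties at the cut) is "low". Other
#' quantile cut-points can be selected (e.g. `q = 2/3` for a top-tertile
#' "high" group).
#'
#' @param values numeric vector (>= 2 finite values, not all identical).
#' @param q quantile defining the cut-point (default 0.5, the median).
#' @return character vector of "high"/"low" labels aligned to `values`.
#' @export
dichotomize_expression <- function(values, q = 0.5) {
  v <- values[is.finite(values)]
  if (length(v) < 2) stop("need at least 2 finite values", call. = FALSE)
  if (length(unique(v)) == 1) stop("all values identical; no split possible", call. = FALSE)
  cut <- stats::quantile(v, probs = q, names = FALSE, type = 7)
  ifelse(values > cut, "high", "low")
}

#' Kaplan-Meier product-limit estimator
#'
#' @param times nonnegative follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return data.frame of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` — the right-continuous step function
#'   `S(t) = prod_(t_i <= t) (1 - d_i / n_i)`.
#' @export
km_estimator <- function(times, events) {
  if (any(times < 0)) stop("negative survival time", call. = FALSE)
  stopifnot(length(times) == length(events), all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#' @param km a `km_curve`.
#' @param t times at which to evaluate the step function.
#' @return survival probabilities (1 before the first event).
#' @export
km_surv_at <- function(km, t) {
  ev <- km[km$n_event > 0, , drop = FALSE]
  vapply(t, function(tt) {
    i <- which(ev$time <= tt)
    if (!length(i)) 1 else ev$surv[max(i)]
  }, numeric(1))
}

#' Log-rank test and O/E hazard ratio between two groups
#'
#' Standard log-rank accounting over shared risk sets: per-group observed
#' and expected event counts, chi-square `(O1 - E1)^2 / V`, and the
#' log-rank-style hazard ratio `HR = (O1/E1) / (O2/E2)` with confidence
#' interval `exp(log HR +/- z * sqrt(1/E1 + 1/E2))`.
#'
#' @param times follow-up times.
#' @param events event indicators (1 = event).
#' @param groups two-level group labels; the first level (alphabetical,
#'   or factor level order) is the HR numerator.
#' @param conf_level confidence level for the HR interval.
#' @return list of class `survival_comparison`: `groups`, `O`, `E`,
#'   `chisq`, `p`, `hr`, `ci_low`, `ci_high`, `n`.
#' @export
logrank_hr <- function(times, events, groups, conf_level = 0.95) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("logrank_hr compares exactly 2 groups", call. = FALSE)
  if (sum(events) < 1) stop("no events in the pooled data", call. = FALSE)
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ groups)
  O <- sd_$obs
  E <- sd_$exp
  if (any(E == 0)) stop("zero expected events in a group", call. = FALSE)
  V <- if (is.matrix(sd_$var)) sd_$var[1, 1] else sd_$var[1]
  chisq <- (O[1] - E[1])^2 / V
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  hr <- (O[1] / E[1]) / (O[2] / E[2])
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- zq * sqrt(1 / E[1] + 1 / E[2])
  structure(list(groups = levels(groups), O = unname(O), E = unname(E),
                 chisq = unname(chisq), p = unname(p), hr = unname(hr),
                 ci_low = unname(exp(log(hr) - half)),
                 ci_high = unname(exp(log(hr) + half)),
                 n = as.vector(table(groups))),
            class = "survival_comparison")
}

#' Survival comparison within strata
#'
#' Runs [logrank_hr()] between the two levels of `group_col` separately
#' inside every combination of the stratifying columns (e.g. treatment
#' arm by cell-of-origin, mirroring expression-stratified per-arm
#' analyses).
#'
#' @param clin `clinical_table` with `time`, `event`, the grouping column
#'   and the strata columns.
#' @param group_col name of the two-level column compared (e.g.
#'   `"arm"` or `"expr_group"`).
#' @param strata_cols character vector of stratifying columns (may be
#'   empty).
#' @return data.frame: one row per stratum with n, O/E per group, HR, CI
#'   bounds, chi-square and p; strata where the comparison is undefined
#'   (one group absent or no events) are skipped.
#' @export
compare_survival <- function(clin, group_col, strata_cols = character(0)) {
  strat <- if (length(strata_cols)) {
    interaction(clin[strata_cols], drop = TRUE, sep = " / ")
  } else {
    factor(rep("all", nrow(clin)))
  }
  rows <- list()
  for (s in levels(strat)) {
    sub <- clin[strat == s, , drop = FALSE]
    g <- factor(sub[[group_col]])
    if (nlevels(droplevels(g)) != 2 || sum(sub$event) < 1) next
    cmp <- try(logrank_hr(sub$time, sub$event, droplevels(g)), silent = TRUE)
    if (inherits(cmp, "try-error")) next
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = s, group1 = cmp$groups[1], group2 = cmp$groups[2],
      n1 = cmp$n[1], n2 = cmp$n[2], O1 = cmp$O[1], E1 = cmp$E[1],
      O2 = cmp$O[2], E2 = cmp$E[2], hr = cmp$hr, ci_low = cmp$ci_low,
      ci_high = cmp$ci_high, chisq = cmp$chisq, p = cmp$p,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stratum = character(0))
  rownames(out) <- NULL
  out
}
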