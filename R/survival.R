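#' Split samples at the median of a gene's expression
#'
#' Samples at or above the median (even-n median = mean of the two central
#' order statistics) are "high", the rest "low"; ties at the median go to
#' "high". Missing values are dropped with a warning; a degenerate split
#' (one empty group) is flagged with a warning rather than an error.
#'
#' @param x Named numeric vector of per-sample expression.
#' @return Named character vector of "high"/"low" labels (NAs removed).
#' @export
median_split <- function(x) {
  if (any(is.na(x))) {
    warning(sum(is.na(x)), " missing value(s) dropped", call. = FALSE)
    x <- x[!is.na(x)]
  }
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  g <- ifelse(x >= stats::median(x), "high", "low")
  if (length(unique(g)) < 2)
    warning("degenerate median split: one group is empty", call. = FALSE)
  g
}

#' Kaplan-Meier product-limit curve
#'
#' \eqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} over distinct event times
#' \eqn{t_i}; right-continuous and nonincreasing with \eqn{S(0) = 1}.
#' Censored subjects leave the risk set after their censoring time.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators (1 = event observed).
#' @param group Optional group labels; curves are computed per group.
#' @return data.frame: `group`, `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_curve <- function(time, event, group = NULL) {
  stopifnot(all(time > 0), all(event %in% c(0, 1)))
  if (is.null(group)) group <- rep("all", length(time))
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(unique(group), length(s$time)) else
    sub("^group=", "", as.character(s$strata))
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, surv = s$surv, row.names = NULL)
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed minus expected events in one
#' group and the hypergeometric variance are accumulated;
#' \eqn{\chi^2 = (\sum O - E)^2 / \sum V} on 1 degree of freedom.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @param group Two-level group labels.
#' @return List: `chi2`, `p`. Both NA (with a warning) when no usable event
#'   times exist.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  if (sum(event) < 1) stop("need at least one event", call. = FALSE)
  sd_fit <- tryCatch(
    survival::survdiff(survival::Surv(time, event) ~ group),
    error = function(e) NULL
  )
  if (is.null(sd_fit) || !is.finite(sd_fit$chisq)) {
    warning("log-rank statistic undefined (zero total variance)",
            call. = FALSE)
    return(list(chi2 = NA_real_, p = NA_real_))
  }
  chi2 <- unname(sd_fit$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit on a binary expression group
#'
#' Partial-likelihood fit with Breslow tie handling. Reports the hazard
#' ratio of "high" vs "low", a 95% normal-approximation Wald confidence
#' interval, the two-sided Wald p-value, and the hazard elevation as a
#' percentage, `100 * (hr - 1)` (an HR of 1.181 is an 18.1% elevation).
#' Monotone likelihoods (complete separation) are flagged rather than
#' silently reported.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators (>= 1 event required).
#' @param covariate Group labels ("high"/"low") or, with
#'   `continuous = TRUE`, a numeric expression vector.
#' @param continuous Use the covariate as continuous instead of binary.
#' @return List of class `"cox_fit"`: `beta`, `se`, `hr`, `ci_low`,
#'   `ci_high`, `p`, `percent_risk`, `score_chi2` (score test at beta = 0),
#'   `flagged`.
#' @export
cox_fit <- function(time, event, covariate, continuous = FALSE) {
  if (sum(event) < 1) stop("need at least one event", call. = FALSE)
  x <- if (continuous) as.numeric(covariate) else
    as.numeric(covariate == "high")
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|converge|out of iterations", conditionMessage(w)))
        flagged <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(beta) || abs(beta) > 15) flagged <- TRUE
  z <- stats::qnorm(0.975)
  hr <- exp(beta)
  structure(list(
    beta = beta, se = se, hr = hr,
    ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
    p = 2 * stats::pnorm(-abs(beta / se)),
    percent_risk = 100 * (hr - 1),
    score_chi2 = unname(fit$score),
    flagged = flagged
  ), class = "cox_fit")
}

#' Hazard ratio as percent hazard elevation
#' @param hr Hazard ratio (> 0).
#' @return `100 * (hr - 1)`.
#' @export
hr_to_percent <- function(hr) 100 * (hr - 1)

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit: HR = %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
              x$hr, x$ci_low, x$ci_high, x$p))
  cat(sprintf("  hazard elevation: %+.1f%%%s\n", x$percent_risk,
              if (x$flagged) "  [flagged: monotone likelihood]" else ""))
  invisible(x)
}

#' Survival validation of a candidate ranking
#'
#' For each candidate gene: median split of its cohort expression, log-rank
#' test between the high and low groups, and a Cox proportional-hazards fit
#' on the group indicator. Candidates absent from the cohort are skipped
#' with a warning.
#'
#' @param ranking Candidate table from [prioritize_genes()].
#' @param expr Genes x samples cohort matrix.
#' @param surv data.frame with `sample_id`, `time_days`, `event`.
#' @param continuous Fit the Cox model on continuous expression instead of
#'   the median-split group.
#' @return data.frame, one row per validated candidate: rank, gene, hr and
#'   CI, percent hazard elevation, Wald and log-rank p-values, flag.
#' @export
validate_candidates <- function(ranking, expr, surv, continuous = FALSE) {
  empty <- data.frame(rank = integer(), gene_id = character(),
                      hr = numeric(), ci_low = numeric(),
                      ci_high = numeric(), percent_risk = numeric(),
                      wald_p = numeric(), logrank_p = numeric(),
                      flagged = logical())
  if (nrow(ranking) == 0) return(empty)
  surv <- surv[match(colnames(expr), surv$sample_id), , drop = FALSE]
  rows <- vector("list", nrow(ranking))
  for (i in seq_len(nrow(ranking))) {
    g <- ranking$gene_id[i]
    if (!g %in% rownames(expr)) {
      warning("candidate ", g, " absent from cohort; skipped", call. = FALSE)
      next
    }
    grp <- median_split(expr[g, ])
    lr <- logrank_test(surv$time_days, surv$event, grp)
    cf <- cox_fit(surv$time_days, surv$event,
                  if (continuous) expr[g, ] else grp,
                  continuous = continuous)
    rows[[i]] <- data.frame(rank = ranking$rank[i], gene_id = g,
                            hr = cf$hr, ci_low = cf$ci_low,
                            ci_high = cf$ci_high,
                            percent_risk = cf$percent_risk,
                            wald_p = cf$p, logrank_p = lr$p,
                            flagged = cf$flagged)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else `rownames<-`(out, NULL)
}
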