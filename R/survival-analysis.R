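#' Cox proportional-hazards fit
#'
#' Fits a Cox model of overall survival on one or more continuous
#' covariates, with Efron handling of tied event times (the default of the
#' survival ecosystem). Exposes the coefficient vector with standard errors,
#' hazard ratios and Wald 95% confidence intervals, per-covariate Wald
#' p-values, the global likelihood-ratio chi-square p, the partial
#' log-likelihood and AIC = -2 loglik + 2k.
#'
#' @param clin a \code{clinical_table}.
#' @param covariates numeric vector (univariate) or matrix/data.frame
#'   (samples x covariates); sample alignment is by name/rowname when
#'   present, otherwise by position.
#' @param ties tie-handling method, \code{"efron"} (default) or
#'   \code{"breslow"}.
#' @return A \code{cox_fit}: list with \code{covariates}, \code{beta},
#'   \code{se}, \code{hr}, \code{ci95} (matrix lower/upper), \code{p}
#'   (Wald, per covariate), \code{p_global} (LR), \code{loglik}, \code{n},
#'   \code{n_events}, \code{aic}.
#' @export
cox_fit <- function(clin, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (is.vector(covariates) && is.numeric(covariates))
    covariates <- matrix(covariates, ncol = 1L,
                         dimnames = list(names(covariates), "score"))
  covariates <- as.matrix(covariates)
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  if (!is.null(rownames(covariates))) {
    miss <- setdiff(clin$sample_id, rownames(covariates))
    if (length(miss)) stopf("covariates missing for sample(s): %s",
                            paste(utils::head(miss, 5), collapse = ", "))
    covariates <- covariates[clin$sample_id, , drop = FALSE]
  } else if (nrow(covariates) != nrow(clin)) {
    stopf("unnamed covariates must match the clinical table length")
  }
  if (any(!is.finite(covariates))) stopf("covariates must be finite")
  if (sum(clin$event) < 2L) stopf("need at least 2 events")
  const <- apply(covariates, 2L, function(v) stats::sd(v) == 0)
  if (any(const))
    stopf("constant covariate(s) carry no information: %s",
          paste(colnames(covariates)[const], collapse = ", "))

  df <- data.frame(time = clin$time, event = clin$event, covariates,
                   check.names = FALSE)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(sprintf("`%s`", colnames(covariates)),
                                       collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = ties,
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 100))
  beta <- stats::coef(fit)
  if (any(!is.finite(beta)) || any(abs(beta) > 20))
    stopf("monotone likelihood: a covariate perfectly separates event order")
  se <- sqrt(diag(fit$var))
  hr <- exp(beta)
  ci95 <- cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se))
  p_wald <- 2 * stats::pnorm(-abs(beta / se))
  lr <- 2 * (fit$loglik[2L] - fit$loglik[1L])
  p_global <- stats::pchisq(lr, df = length(beta), lower.tail = FALSE)
  structure(list(covariates = colnames(covariates),
                 beta = beta, se = se, hr = hr, ci95 = ci95,
                 p = p_wald, p_global = p_global,
                 loglik = fit$loglik[2L], loglik_null = fit$loglik[1L],
                 n = nrow(clin), n_events = sum(clin$event),
                 aic = -2 * fit$loglik[2L] + 2 * length(beta),
                 ties = ties),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit (%s ties): n = %d, events = %d, loglik = %.4f, AIC = %.4f\n",
              x$ties, x$n, x$n_events, x$loglik, x$aic))
  print(data.frame(covariate = x$covariates, beta = x$beta, hr = x$hr,
                   lower95 = x$ci95[, "lower"], upper95 = x$ci95[, "upper"],
                   p = x$p, row.names = NULL))
  invisible(x)
}

#' Log-rank test for survival differences between groups
#'
#' Standard log-rank chi-square with (g - 1) degrees of freedom comparing
#' Kaplan-Meier survival across groups.
#'
#' @param clin a \code{clinical_table}.
#' @param groups group labels aligned with \code{clin} (by name when named);
#'   at least 2 non-empty groups.
#' @return List with \code{statistic}, \code{df} and \code{p}.
#' @export
logrank_test <- function(clin, groups) {
  if (!is.null(names(groups))) {
    miss <- setdiff(clin$sample_id, names(groups))
    if (length(miss)) stopf("groups missing for sample(s): %s",
                            paste(utils::head(miss, 5), collapse = ", "))
    groups <- groups[clin$sample_id]
  } else if (length(groups) != nrow(clin)) {
    stopf("unnamed groups must match the clinical table length")
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stopf("need at least 2 groups")
  df <- data.frame(time = clin$time, event = clin$event, group = groups)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  stat <- sd$chisq
  dof <- nlevels(groups) - 1L
  list(statistic = unname(stat), df = dof,
       p = stats::pchisq(stat, dof, lower.tail = FALSE))
}

#' Cross-validated optimal Kaplan-Meier cutpoint
#'
#' Chooses the score cutpoint that best separates survival, guarding against
#' overfitting by k-fold cross validation: samples are partitioned into
#' event-stratified folds (seeded) and each candidate cutpoint — a grid of
#' score quantiles between the 20th and 80th percentile — is evaluated by
#' the mean log-rank statistic over the k training splits. The maximizer
#' (ties resolved toward the cutpoint nearest the median score) is then
#' applied to the full cohort for the final stratification and log-rank
#' test. Candidates leaving either group below \code{min_group_frac} of the
#' cohort are skipped.
#'
#' @param clin a \code{clinical_table}.
#' @param score named numeric per-sample score.
#' @param folds number of folds (default 5); requires n >= 5 * folds.
#' @param grid_probs quantile grid for candidates.
#' @param seed integer RNG seed for the fold assignment.
#' @param min_group_frac minimum group size as a fraction of n.
#' @return A \code{cutpoint_result}: list with \code{cutpoint},
#'   \code{groups} ("high"/"low" per sample), \code{statistic}, \code{p} and
#'   a \code{cv} record (folds, grid, per-candidate mean statistics).
#' @export
cv_optimal_cutpoint <- function(clin, score, folds = 5,
                                grid_probs = seq(0.2, 0.8, by = 0.05),
                                seed = 1, min_group_frac = 0.10) {
  n <- nrow(clin)
  if (n < 5 * folds) stopf("need at least %d samples for %d-fold CV", 5 * folds, folds)
  if (!is.null(names(score))) score <- score[clin$sample_id]
  if (length(score) != n) stopf("score must cover every clinical sample")
  if (stats::sd(score) == 0) stopf("constant score admits no cutpoint")
  min_group <- ceiling(min_group_frac * n)

  fold_id <- integer(n)
  with_seed(seed, {
    for (ev in c(0L, 1L)) {
      idx <- which(clin$event == ev)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })

  candidates <- unique(unname(stats::quantile(score, grid_probs, type = 7)))
  mean_stat <- rep(NA_real_, length(candidates))
  for (ci in seq_along(candidates)) {
    cut <- candidates[ci]
    hi <- score > cut
    if (sum(hi) < min_group || sum(!hi) < min_group) next
    stats_f <- numeric(folds)
    ok <- TRUE
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (length(unique(hi[tr])) < 2L) { ok <- FALSE; break }
      lt <- tryCatch(
        logrank_test(clin[tr, , drop = FALSE],
                     ifelse(hi[tr], "high", "low"))$statistic,
        error = function(e) NA_real_)
      if (is.na(lt)) { ok <- FALSE; break }
      stats_f[f] <- lt
    }
    if (ok) mean_stat[ci] <- mean(stats_f)
  }
  if (all(is.na(mean_stat))) stopf("no candidate cutpoint admits valid groups")
  best <- which(mean_stat == max(mean_stat, na.rm = TRUE))
  if (length(best) > 1L) {
    med <- stats::median(score)
    best <- best[which.min(abs(candidates[best] - med))]
  }
  cut <- candidates[best]
  groups <- stats::setNames(ifelse(score > cut, "high", "low"), clin$sample_id)
  lt <- logrank_test(clin, groups)
  structure(list(cutpoint = cut, groups = groups,
                 statistic = lt$statistic, p = lt$p,
                 cv = list(folds = folds, fold_id = fold_id,
                           candidates = candidates, mean_stat = mean_stat,
                           seed = seed)),
            class = "cutpoint_result")
}

#' Combined score of two signatures
#'
#' Per-sample sum of the z-scaled enrichment scores of two signatures
#' (the "combination model" summing scaled enrichment scores).
#'
#' @param scores a \code{\link{score_signatures}} table.
#' @param sig_a,sig_b signature names present in \code{scores}.
#' @return Named numeric vector (mean exactly 0 by construction).
#' @export
combined_score <- function(scores, sig_a, sig_b) {
  pick <- function(nm) {
    sub <- scores[scores$signature == nm, , drop = FALSE]
    if (!nrow(sub)) stopf("signature '%s' not found in the score table", nm)
    stats::setNames(sub$es_scaled, sub$sample_id)
  }
  a <- pick(sig_a); b <- pick(sig_b)
  if (length(a) < 2L) stopf("combined score undefined for cohorts of size < 2")
  if (!identical(sort(names(a)), sort(names(b))))
    stopf("signatures were scored on different cohorts")
  a + b[names(a)]
}

#' AIC difference between two Cox fits
#'
#' dAIC = AIC(a) - AIC(b); negative values favor model a. The fits must come
#' from the same cohort (same n and event count).
#'
#' @param fit_a,fit_b \code{cox_fit} objects.
#' @return The AIC difference (numeric scalar).
#' @export
compare_aic <- function(fit_a, fit_b) {
  if (fit_a$n != fit_b$n || fit_a$n_events != fit_b$n_events)
    stopf("fits come from mismatched cohorts (n or event count differ)")
  fit_a$aic - fit_b$aic
}

#' Forest-plot table across cohort fits
#'
#' Tabulates hazard ratio, confidence interval, p-value and the
#' enabled/disabled/neutral prognostic flag (via
#' \code{\link{classify_cohort}}) for a set of univariate cohort fits — the
#' data behind a forest plot.
#'
#' @param fits named list of \code{cox_fit} objects (names = cohort ids).
#' @return data.frame: cohort, n, n_events, hr, ci_lower, ci_upper, p, class.
#' @export
forest_table <- function(fits) {
  if (!length(fits)) stopf("need at least one fit")
  if (is.null(names(fits))) names(fits) <- paste0("cohort", seq_along(fits))
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    cls <- classify_cohort(f, cohort = nm)
    data.frame(cohort = nm, n = f$n, n_events = f$n_events,
               hr = unname(f$hr[1L]),
               ci_lower = unname(f$ci95[1L, "lower"]),
               ci_upper = unname(f$ci95[1L, "upper"]),
               p = cls$p, class = cls$class, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
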