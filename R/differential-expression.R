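#' Moderated-t differential expression between two sample groups
#'
#' Two-group differential expression with empirical-Bayes variance
#' moderation. Per feature g, the log2 fold-change is the mean difference
#' (high minus low) and the pooled residual variance s_g^2 has
#' d_g = n1 + n2 - 2 degrees of freedom. A scaled inverse-chi-square prior
#' (d0, s0^2) is estimated by the method of moments on log s_g^2 (closed-form
#' moment matching via digamma/trigamma), the posterior variance is the
#' precision-weighted blend
#' \deqn{\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g),}
#' and the moderated t is log2fc / (\eqn{\tilde{s}_g} c) with
#' c = sqrt(1/n1 + 1/n2), referred to a t distribution on d0 + d_g degrees of
#' freedom. When all features share the same sample variance the shrinkage
#' target equals that variance and the statistic reduces to the ordinary
#' pooled two-sample t.
#'
#' @param m an \code{expr_matrix}.
#' @param group_high,group_low disjoint character vectors of sample ids, each
#'   of size >= 2 (conventionally the ICR_high and ICR_low tiers).
#' @return A data.frame (one row per feature): \code{feature_id},
#'   \code{log2fc}, \code{t_mod}, \code{p}, \code{q} (BH), \code{direction}
#'   (\code{up}/\code{down}), plus attributes \code{d0} and \code{s0_sq}.
#' @export
moderated_t <- function(m, group_high, group_low) {
  group_high <- as.character(group_high); group_low <- as.character(group_low)
  if (length(intersect(group_high, group_low)))
    stopf("groups must be disjoint")
  if (length(group_high) < 2L || length(group_low) < 2L)
    stopf("each group needs at least 2 samples")
  miss <- setdiff(c(group_high, group_low), m$sample_ids)
  if (length(miss)) stopf("samples not in matrix: %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  xh <- m$values[group_high, , drop = FALSE]
  xl <- m$values[group_low, , drop = FALSE]
  n1 <- nrow(xh); n2 <- nrow(xl)
  mh <- colMeans(xh); ml <- colMeans(xl)
  lfc <- mh - ml
  v1 <- apply(xh, 2L, stats::var); v2 <- apply(xl, 2L, stats::var)
  d_g <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d_g
  cfac <- sqrt(1 / n1 + 1 / n2)

  zero <- s2 <= 0
  if (any(zero)) {
    floor_val <- if (all(zero)) 1e-8 else min(s2[!zero])
    msgf("moderated_t: %d zero-variance feature(s), variance floored", sum(zero))
    s2[zero] <- floor_val
  }

  prior <- squeeze_var_prior(s2, d_g)
  d0 <- prior$d0; s0_sq <- prior$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
    else (d0 * s0_sq + d_g * s2) / (d0 + d_g)
  t_mod <- lfc / (sqrt(s2_post) * cfac)
  df_total <- d0 + d_g
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  # degenerate rows: identical groups with zero variance carry no evidence
  p[zero & lfc == 0] <- 1
  t_mod[zero & lfc == 0] <- 0
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  out <- data.frame(feature_id = m$feature_ids, log2fc = unname(lfc),
                    t_mod = unname(t_mod), p = unname(p),
                    q = bh_adjust(unname(p)),
                    direction = ifelse(lfc >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  attr(out, "df_total") <- df_total
  out
}

# Method-of-moments fit of the scaled inverse-chi-square variance prior on the
# log sample variances: e_g = log s_g^2 - digamma(d_g/2) + log(d_g/2) has mean
# log s0^2 + digamma(d0/2) - log(d0/2) and excess variance trigamma(d0/2).
squeeze_var_prior <- function(s2, d_g) {
  z <- log(s2)
  e <- z - digamma(d_g / 2) + log(d_g / 2)
  emean <- mean(e)
  n <- length(e)
  if (n < 2L) return(list(d0 = Inf, s0_sq = exp(emean)))
  evar <- sum((e - emean)^2) / (n - 1L) - trigamma(d_g / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread in log s^2: variances look exchangeable, point prior
    d0 <- Inf
    s0_sq <- mean(s2)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control:
#' q_i = min over j with p_(j) >= p_(i) of min(1, n p_(j) / j). Wraps
#' \code{\link[stats]{p.adjust}} with input validation; adjusted values are
#' monotone in p and idempotent.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return Vector of BH-adjusted q-values (empty input gives empty output).
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stopf("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Filter differential-expression results to immune-related lncRNAs
#'
#' Keeps features with q below \code{q_max} and |log2FC| above
#' \code{lfc_min} (two-sided, so both up- and down-regulated lncRNAs pass,
#' matching the convention under which both directions are reported for
#' "log2FC > 1").
#'
#' @param results data.frame from \code{\link{moderated_t}}.
#' @param q_max FDR threshold (default 0.05).
#' @param lfc_min absolute log2 fold-change threshold (default 1).
#' @return The filtered data.frame, ordered by q then |log2fc| descending,
#'   with attribute \code{counts} = c(up, down).
#' @export
filter_ir_lncrnas <- function(results, q_max = 0.05, lfc_min = 1.0) {
  keep <- results$q < q_max & abs(results$log2fc) > lfc_min
  out <- results[keep, , drop = FALSE]
  out <- out[order(out$q, -abs(out$log2fc), out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  counts <- c(up = sum(out$direction == "up"),
              down = sum(out$direction == "down"))
  msgf("filter_ir_lncrnas: %d kept (%d up, %d down) of %d at q < %g, |log2FC| > %g",
       nrow(out), counts[["up"]], counts[["down"]], nrow(results), q_max, lfc_min)
  attr(out, "counts") <- counts
  out
}
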