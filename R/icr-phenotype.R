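#' Consensus clustering of samples on an ICR gene module
#'
#' Calls tumor immune phenotypes by resampling-based consensus clustering of
#' the ICR submatrix: for each candidate k, repeated subsamples of
#' \code{ceiling(p_item * n)} samples are clustered by Ward-linkage
#' agglomerative hierarchical clustering (Ward.D2, Euclidean distance on the
#' per-gene z-scored ICR submatrix), and the consensus matrix records for
#' every sample pair the fraction of co-clusterings among co-samplings. Final
#' labels come from complete-linkage clustering of (1 - consensus); k is
#' chosen by the Calinski-Harabasz criterion (\code{\link{select_k}}).
#' Clusters are ranked by mean ICR expression into tiers: \code{ICR_high}
#' (immune hot) down to \code{ICR_low} (immune cold), with medium tier(s) in
#' between.
#'
#' @param m an \code{expr_matrix} containing the ICR genes.
#' @param icr_set a \code{gene_set}; members absent from \code{m} are logged,
#'   at least 5 must be present.
#' @param k_range integer vector of candidate cluster numbers (values >= 2).
#' @param reps number of subsampling repeats (production default 5000; small
#'   values suffice for well-separated data).
#' @param p_item subsampling fraction per repeat.
#' @param seed integer RNG seed.
#' @return A \code{consensus_result}: list with \code{consensus_matrix} (for
#'   the selected k), \code{consensus_by_k}, \code{k_selected}, \code{labels},
#'   \code{tier} (named factors per sample) and \code{ch_by_k}.
#' @export
consensus_cluster <- function(m, icr_set, k_range = 2:5, reps = 5000,
                              p_item = 0.8, seed = 1) {
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L)) {
    msgf("consensus_cluster: excluding k < 2 from k_range")
    k_range <- k_range[k_range >= 2L]
  }
  if (length(k_range) < 1L) stopf("k_range must contain at least one k >= 2")
  if (reps < 1L) stopf("`reps` must be >= 1")
  genes <- intersect(icr_set$members, m$feature_ids)
  missing <- setdiff(icr_set$members, m$feature_ids)
  if (length(missing))
    msgf("consensus_cluster: %d ICR gene(s) absent from the matrix", length(missing))
  if (length(genes) < 5L)
    stopf("fewer than 5 ICR genes found in the expression matrix")
  n <- nrow(m$values)
  if (n < max(k_range) + 1L)
    stopf("need more than max(k_range) samples (n = %d)", n)

  sub <- m$values[, genes, drop = FALSE]
  z <- scale(sub)                      # per-gene z-score for cluster geometry
  z[, attr(z, "scaled:scale") == 0] <- 0

  n_sub <- ceiling(p_item * n)
  conn <- lapply(k_range, function(k) matrix(0, n, n))
  names(conn) <- as.character(k_range)
  co_sampled <- matrix(0, n, n)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      idx <- sort(sample.int(n, n_sub))
      co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
      hc <- stats::hclust(stats::dist(z[idx, , drop = FALSE]), method = "ward.D2")
      for (k in k_range) {
        lab <- stats::cutree(hc, k)
        for (cl in unique(lab)) {
          mem <- idx[lab == cl]
          conn[[as.character(k)]][mem, mem] <-
            conn[[as.character(k)]][mem, mem] + 1
        }
      }
    }
  })
  consensus_by_k <- lapply(conn, function(cm) {
    out <- cm / pmax(co_sampled, 1)
    out[co_sampled == 0] <- 0
    diag(out)[diag(co_sampled) > 0] <- 1
    dimnames(out) <- list(m$sample_ids, m$sample_ids)
    out
  })

  labels_by_k <- lapply(seq_along(k_range), function(i) {
    hc <- stats::hclust(stats::as.dist(1 - consensus_by_k[[i]]), method = "complete")
    stats::cutree(hc, k_range[i])
  })
  names(labels_by_k) <- as.character(k_range)

  k_sel <- select_k(sub, labels_by_k)
  ch_by_k <- attr(k_sel, "ch_by_k")
  k_selected <- as.integer(k_sel)
  labels <- labels_by_k[[as.character(k_selected)]]

  # tiers ranked by descending cluster mean ICR expression
  cl_means <- tapply(rowMeans(sub), labels, mean)
  rank_order <- order(cl_means, decreasing = TRUE)   # cluster ids, high first
  tier_names <- if (k_selected == 2L) c("ICR_high", "ICR_low")
    else if (k_selected == 3L) c("ICR_high", "ICR_medium", "ICR_low")
    else c("ICR_high", paste0("ICR_medium", seq_len(k_selected - 2L)), "ICR_low")
  tier_of_cluster <- stats::setNames(tier_names,
                                     names(cl_means)[rank_order])
  tier <- factor(tier_of_cluster[as.character(labels)], levels = tier_names)
  names(tier) <- m$sample_ids
  names(labels) <- m$sample_ids

  structure(list(consensus_matrix = consensus_by_k[[as.character(k_selected)]],
                 consensus_by_k = consensus_by_k,
                 k_selected = k_selected, labels = labels, tier = tier,
                 ch_by_k = ch_by_k,
                 genes_used = genes, reps = reps, p_item = p_item, seed = seed),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: k = %d over %d samples (%d ICR genes, %d reps)\n",
              x$k_selected, length(x$labels), length(x$genes_used), x$reps))
  print(table(x$tier))
  invisible(x)
}

# Calinski-Harabasz index: between/within dispersion ratio scaled by df.
calinski_harabasz <- function(data, labels) {
  data <- as.matrix(data)
  n <- nrow(data); k <- length(unique(labels))
  if (k < 2L || k >= n) return(NA_real_)
  centroid <- colMeans(data)
  B <- 0; W <- 0
  for (cl in unique(labels)) {
    rows <- data[labels == cl, , drop = FALSE]
    cm <- colMeans(rows)
    B <- B + nrow(rows) * sum((cm - centroid)^2)
    W <- W + sum(sweep(rows, 2L, cm)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Select the number of clusters by the Calinski-Harabasz criterion
#'
#' Computes CH(k) = [B(k)/(k-1)] / [W(k)/(n-k)] on \code{data} for each
#' candidate labelling and returns the k that maximizes it (ties go to the
#' smallest k). Candidates with an empty cluster or undefined CH (k < 2) are
#' skipped with a message.
#'
#' @param data numeric matrix (samples x features) the labels refer to,
#'   typically the ICR submatrix.
#' @param labels_by_k named list of per-sample label vectors, names the k
#'   values.
#' @return The selected k (integer), with attribute \code{ch_by_k}.
#' @export
select_k <- function(data, labels_by_k) {
  ks <- as.integer(names(labels_by_k))
  if (length(ks) < 1L) stopf("need at least one candidate k")
  ch <- vapply(seq_along(ks), function(i) {
    lab <- labels_by_k[[i]]
    if (length(unique(lab)) != ks[i]) {
      msgf("select_k: k = %d skipped (empty cluster)", ks[i])
      return(NA_real_)
    }
    if (ks[i] < 2L) {
      msgf("select_k: k = %d skipped (CH undefined)", ks[i])
      return(NA_real_)
    }
    calinski_harabasz(data, lab)
  }, numeric(1))
  if (all(is.na(ch))) stopf("no candidate k admits a Calinski-Harabasz value")
  best <- ks[which(ch == max(ch, na.rm = TRUE))]
  out <- min(best)
  attr(out, "ch_by_k") <- stats::setNames(ch, ks)
  out
}

#' Classify a cohort as ICR enabled / disabled / neutral
#'
#' Applies the prognostic-direction rule to a continuous-score univariate Cox
#' fit: \code{enabled} if HR < 1 with p < 0.05 (immune activation protective),
#' \code{disabled} if HR > 1 with p < 0.05, otherwise \code{neutral}.
#'
#' @param fit a \code{cox_fit} from a single continuous covariate, or any
#'   object with elements \code{hr} and \code{p}.
#' @param cohort optional cohort id carried through.
#' @return A one-row data.frame: cohort, class, hr, p.
#' @export
classify_cohort <- function(fit, cohort = NA_character_) {
  hr <- fit$hr[1L]
  p <- if (!is.null(fit$p_global)) fit$p_global else fit$p[1L]
  cls <- if (is.na(hr) || is.na(p)) "neutral"
    else if (hr < 1 && p < 0.05) "enabled"
    else if (hr > 1 && p < 0.05) "disabled"
    else "neutral"
  data.frame(cohort = cohort, class = cls, hr = unname(hr), p = unname(p),
             stringsAsFactors = FALSE)
}
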