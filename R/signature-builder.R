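#' Spearman correlation of lncRNAs against an immune checkpoint panel
#'
#' Average-rank Spearman correlation between every lncRNA (rows) and every
#' checkpoint gene (columns) over shared samples, with two-sided p-values
#' from the t approximation t = rho sqrt((n-2)/(1-rho^2)). The heatmap
#' orders follow the convention of ordering columns by the (signed) sum of
#' their correlations and rows by the absolute value of their correlation
#' sums.
#'
#' @param lnc \code{expr_matrix} of lncRNAs.
#' @param chk \code{expr_matrix} of checkpoint genes (same samples).
#' @return A \code{checkpoint_correlation}: list with \code{rho} (lncRNAs x
#'   checkpoints), \code{p}, \code{row_order}, \code{col_order}, \code{n}.
#' @export
spearman_matrix <- function(lnc, chk) {
  if (!identical(lnc$sample_ids, chk$sample_ids))
    stopf("matrices must share identical sample sets/order")
  n <- nrow(lnc$values)
  if (n < 3L) stopf("need at least 3 shared samples")
  drop_zero <- function(m, label) {
    sds <- apply(m$values, 2L, stats::sd)
    if (any(sds == 0)) {
      msgf("spearman_matrix: excluding %d zero-variance %s feature(s)",
           sum(sds == 0), label)
      return(expr_matrix(m$values[, sds > 0, drop = FALSE],
                         m$feature_class[sds > 0]))
    }
    m
  }
  lnc <- drop_zero(lnc, "lncRNA"); chk <- drop_zero(chk, "checkpoint")
  rho <- stats::cor(lnc$values, chk$values, method = "spearman")
  rho_c <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
  tstat <- rho_c * sqrt((n - 2) / (1 - rho_c^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  col_order <- order(colSums(rho), decreasing = TRUE)
  row_order <- order(abs(rowSums(rho)), decreasing = TRUE)
  structure(list(rho = rho, p = p, row_order = row_order,
                 col_order = col_order, n = n),
            class = "checkpoint_correlation")
}

#' @export
print.checkpoint_correlation <- function(x, ...) {
  cat(sprintf("checkpoint_correlation: %d lncRNAs x %d checkpoints (n = %d)\n",
              nrow(x$rho), ncol(x$rho), x$n))
  invisible(x)
}

#' lncRNA signature container
#'
#' @param name signature name.
#' @param members unique member lncRNA ids.
#' @param derivation list recording criterion and parameters so the
#'   derivation is reproducible.
#' @return An object of class \code{lnc_signature}.
#' @export
lnc_signature <- function(name, members, derivation = list()) {
  members <- unique(as.character(members))
  structure(list(name = name, members = members, derivation = derivation),
            class = "lnc_signature")
}

#' @export
print.lnc_signature <- function(x, ...) {
  cat(sprintf("signature '%s': %d member(s)\n", x$name, length(x$members)))
  invisible(x)
}

#' Top-k ir-lncRNAs by differential-expression strength
#'
#' Takes the k strongest differentially expressed ir-lncRNAs, ordered by
#' ascending adjusted p, ties by descending |log2FC|, remaining ties by id
#' (all deterministic). With k = 20 this is the "20-ICRlncRNA"-style
#' signature.
#'
#' @param de filtered data.frame from \code{\link{filter_ir_lncrnas}}.
#' @param k signature size (default 20); if fewer features are available all
#'   are returned with a warning.
#' @return A \code{lnc_signature}.
#' @export
top_icr_signature <- function(de, k = 20) {
  ord <- order(de$q, -abs(de$log2fc), de$feature_id)
  if (nrow(de) < k) {
    warnf("top_icr_signature: only %d feature(s) available (k = %d)", nrow(de), k)
    k <- nrow(de)
  }
  ids <- de$feature_id[ord][seq_len(k)]
  lnc_signature(sprintf("%d-ICRlncRNA", k), ids,
            list(criterion = "ascending q, then descending |log2fc|, then id",
                 k = k, n_candidates = nrow(de)))
}

#' Top-k ir-lncRNAs by checkpoint association
#'
#' Ranks candidate lncRNAs by the signed row-sum of their Spearman
#' correlations with the checkpoint panel (descending; ties by id) and takes
#' the top k — the "20-ICPlncRNA"-style signature. Set \code{use_abs} to rank
#' by the absolute row-sum instead.
#'
#' @param corr a \code{checkpoint_correlation}.
#' @param candidates character vector of candidate lncRNA ids (subset of the
#'   correlation rows).
#' @param k signature size (default 20).
#' @param use_abs rank by |row sum| instead of the signed sum.
#' @return A \code{lnc_signature}.
#' @export
top_icp_signature <- function(corr, candidates, k = 20, use_abs = FALSE) {
  candidates <- as.character(candidates)
  miss <- setdiff(candidates, rownames(corr$rho))
  if (length(miss)) stopf("candidate(s) absent from correlation rows: %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  sums <- rowSums(corr$rho[candidates, , drop = FALSE])
  key <- if (use_abs) abs(sums) else sums
  if (all(key == 0))
    warnf("top_icp_signature: all correlation sums are zero; ranking is uninformative")
  ord <- order(-key, candidates)
  if (length(candidates) < k) {
    warnf("top_icp_signature: only %d candidate(s) available (k = %d)",
          length(candidates), k)
    k <- length(candidates)
  }
  ids <- candidates[ord][seq_len(k)]
  lnc_signature(sprintf("%d-ICPlncRNA", k), ids,
            list(criterion = if (use_abs) "descending |sum rho|, then id"
                             else "descending sum rho, then id",
                 k = k, n_candidates = length(candidates)))
}

#' Intersect two signatures
#'
#' The id-sorted set intersection; with the DE-derived and checkpoint-derived
#' signatures this yields the minimal shared ir-lncRNA signature. An empty
#' intersection is returned with a warning (downstream scoring refuses empty
#' sets).
#'
#' @param a,b \code{lnc_signature} objects.
#' @return A \code{lnc_signature} whose derivation records both parents.
#' @export
intersect_signatures <- function(a, b) {
  members <- sort(intersect(a$members, b$members))
  if (!length(members))
    warnf("intersect_signatures: '%s' and '%s' share no members", a$name, b$name)
  lnc_signature(sprintf("%s_x_%s", a$name, b$name), members,
            list(criterion = "set intersection, id-sorted",
                 parents = c(a$name, b$name),
                 parent_sizes = c(length(a$members), length(b$members))))
}
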