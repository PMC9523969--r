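#' Build a coding--non-coding (CNC) co-expression network
#'
#' Correlates every feature pair (coding-lncRNA, coding-coding and
#' lncRNA-lncRNA) across shared samples and keeps an undirected edge wherever
#' |correlation| >= \code{r_min}, weighted by |correlation|. The transition
#' operator W for network propagation is the column-normalized weight matrix;
#' nodes left without any edge receive a self-loop so every column remains
#' stochastic without teleporting mass to the whole graph.
#'
#' @param coding,lnc \code{expr_matrix} objects over an identical sample set
#'   and order.
#' @param r_min absolute-correlation edge threshold (default 0.5).
#' @param method correlation method, \code{"pearson"} (default) or
#'   \code{"spearman"}.
#' @return A \code{cnc_network}: list with \code{nodes}, \code{node_class},
#'   \code{adjacency} (weights) and \code{transition} (column-stochastic W).
#' @export
build_cnc_network <- function(coding, lnc, r_min = 0.5,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!identical(coding$sample_ids, lnc$sample_ids))
    stopf("coding and lncRNA matrices must share identical sample sets/order")
  if (nrow(coding$values) < 3L) stopf("need at least 3 shared samples")
  x <- cbind(coding$values, lnc$values)
  cls <- c(coding$feature_class, lnc$feature_class)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    msgf("build_cnc_network: excluding %d zero-variance feature(s)", sum(sds == 0))
    x <- x[, sds > 0, drop = FALSE]
    cls <- cls[sds > 0]
  }
  A <- abs(stats::cor(x, method = method))
  A[A < r_min] <- 0
  diag(A) <- 0
  cnc_network(A, cls)
}

#' Construct a CNC network from an adjacency (weight) matrix
#'
#' @param adjacency symmetric non-negative weight matrix with dimnames; zero
#'   means no edge.
#' @param node_class named character vector, \code{"coding"}/\code{"lncRNA"}
#'   per node.
#' @return A \code{cnc_network}.
#' @export
cnc_network <- function(adjacency, node_class) {
  if (!isSymmetric(unname(adjacency))) stopf("adjacency must be symmetric")
  if (any(adjacency < 0)) stopf("edge weights must be non-negative")
  if (any(diag(adjacency) != 0)) stopf("self-edges are not allowed")
  node_class <- rep_len(as.character(node_class), ncol(adjacency))
  names(node_class) <- colnames(adjacency)
  A <- adjacency
  isolated <- colSums(A) == 0
  if (any(isolated)) diag(A)[isolated] <- 1   # self-loop keeps W stochastic
  W <- sweep(A, 2L, colSums(A), "/")
  structure(list(nodes = colnames(adjacency), node_class = node_class,
                 adjacency = adjacency, transition = W),
            class = "cnc_network")
}

#' @export
print.cnc_network <- function(x, ...) {
  n_edge <- sum(x$adjacency[upper.tri(x$adjacency)] > 0)
  tab <- table(factor(x$node_class, levels = c("coding", "lncRNA")))
  cat(sprintf("cnc_network: %d nodes (%d coding, %d lncRNA), %d edges\n",
              length(x$nodes), tab[["coding"]], tab[["lncRNA"]], n_edge))
  invisible(x)
}

#' Read / write a CNC network edge list
#'
#' Edge-list TSV with columns \code{node_a}, \code{node_b}, \code{weight};
#' node classes are supplied separately (coding vs lncRNA cannot be inferred
#' from the list itself).
#'
#' @param path TSV path.
#' @param node_class named character vector of classes covering every node in
#'   the file.
#' @return A \code{cnc_network}.
#' @export
read_edge_list <- function(path, node_class) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("node_a", "node_b", "weight")
  if (!all(need %in% names(df)))
    stopf("edge list must have columns: %s", paste(need, collapse = ", "))
  nodes <- sort(unique(c(df$node_a, df$node_b)))
  miss <- setdiff(nodes, names(node_class))
  if (length(miss)) stopf("no class given for node(s): %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  A[cbind(df$node_a, df$node_b)] <- df$weight
  A[cbind(df$node_b, df$node_a)] <- df$weight
  diag(A) <- 0
  cnc_network(A, node_class[nodes])
}

#' @rdname read_edge_list
#' @param net a \code{cnc_network} to write.
#' @export
write_edge_list <- function(net, path) {
  idx <- which(upper.tri(net$adjacency) & net$adjacency > 0, arr.ind = TRUE)
  df <- data.frame(node_a = net$nodes[idx[, 1L]],
                   node_b = net$nodes[idx[, 2L]],
                   weight = net$adjacency[idx],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Random walk with restart over a CNC network
#'
#' Iterates p <- (1 - r) W p + r p0 from a uniform distribution p0 over the
#' seed nodes until the L1 change drops below \code{tol}. The fixed point is
#' the restart-smoothed stationary distribution; each node's mass is its
#' "walkscore", measuring network proximity to the seed set. Since W is
#' column-stochastic and the seed vector sums to one, walkscores always sum
#' to one.
#'
#' @param net a \code{cnc_network}.
#' @param seeds character vector of seed node ids (typically the ir-lncRNAs);
#'   absent seeds are dropped with a message, all absent is an error.
#' @param restart_r restart probability in (0, 1]; default 0.7.
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap (error on non-convergence).
#' @param seed_weights optional non-negative weights for the seed vector
#'   (e.g. |log2FC|); default uniform.
#' @return A data.frame (\code{walkscore_table}): \code{node}, \code{class},
#'   \code{walkscore}, and \code{rank} among coding nodes (descending
#'   walkscore, ties by id); attribute \code{restart_r}.
#' @export
rwr <- function(net, seeds, restart_r = 0.7, tol = 1e-10, max_iter = 10000,
                seed_weights = NULL) {
  if (!length(seeds)) stopf("seed set is empty")
  if (!(restart_r > 0 && restart_r <= 1)) stopf("restart_r must lie in (0, 1]")
  present <- seeds %in% net$nodes
  if (!all(present))
    msgf("rwr: dropping %d seed(s) absent from the network", sum(!present))
  seeds <- seeds[present]
  if (!length(seeds)) stopf("no seed is present in the network")
  p0 <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  if (is.null(seed_weights)) {
    p0[seeds] <- 1 / length(seeds)
  } else {
    w <- rep_len(as.numeric(seed_weights), length(seeds))
    if (any(w < 0) || sum(w) <= 0) stopf("seed weights must be non-negative, not all zero")
    p0[seeds] <- w / sum(w)
  }
  W <- net$transition
  p <- p0
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    p_new <- (1 - restart_r) * as.numeric(W %*% p) + restart_r * p0
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) stopf("rwr did not converge in %d iterations", max_iter)
  names(p) <- net$nodes
  out <- data.frame(node = net$nodes, class = unname(net$node_class),
                    walkscore = unname(p), stringsAsFactors = FALSE)
  coding <- out$class == "coding"
  rk <- integer(nrow(out)); rk[] <- NA_integer_
  ord <- order(-out$walkscore[coding], out$node[coding])
  rk[which(coding)[ord]] <- seq_len(sum(coding))
  out$rank <- rk
  attr(out, "restart_r") <- restart_r
  attr(out, "n_seeds") <- length(seeds)
  class(out) <- c("walkscore_table", "data.frame")
  out
}

#' Select proxy protein-coding genes by walkscore cutoff
#'
#' Coding nodes with walkscore at or above the cutoff, in descending
#' walkscore order (ties broken lexicographically by id). The default 0.01
#' is a stringent criterion that, on a transcriptome-scale network, retains
#' roughly the top percent of protein-coding genes.
#'
#' @param ws a \code{walkscore_table} from \code{\link{rwr}}.
#' @param cutoff minimum walkscore (default 0.01).
#' @return Character vector of selected coding gene ids (possibly empty,
#'   logged).
#' @export
select_proxy_genes <- function(ws, cutoff = 0.01) {
  cand <- ws[ws$class == "coding" & ws$walkscore >= cutoff, , drop = FALSE]
  cand <- cand[order(-cand$walkscore, cand$node), , drop = FALSE]
  if (!nrow(cand)) msgf("select_proxy_genes: no coding gene reaches walkscore >= %g", cutoff)
  cand$node
}
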