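#' Single-sample gene set enrichment scores (ssGSEA)
#'
#' Rank-based running-sum enrichment in the Barbie style: within each sample,
#' features are ranked by descending expression (average ranks for ties) and
#' the enrichment score is
#' \deqn{ES = \sum_i [P_{in}^w(i) - P_{out}(i)],}
#' where the in-set running fraction weights each member by its expression
#' rank raised to \code{alpha} and the out-of-set fraction rises uniformly.
#' No final normalization by feature count is applied. Being rank-based, the
#' score is invariant to strictly increasing transforms of a sample's values.
#'
#' @param m an \code{expr_matrix}.
#' @param set a \code{gene_set}; its overlap with the features must be a
#'   non-empty strict subset. Missing members are logged.
#' @param alpha rank-weighting exponent (default 0.25).
#' @return Named numeric vector of enrichment scores, one per sample.
#' @export
ssgsea <- function(m, set, alpha = 0.25) {
  members <- intersect(set$members, m$feature_ids)
  miss <- setdiff(set$members, m$feature_ids)
  if (length(miss))
    msgf("ssgsea('%s'): %d member(s) absent from the matrix", set$name, length(miss))
  n_feat <- ncol(m$values)
  if (!length(members)) stopf("gene set '%s' has no member in the matrix", set$name)
  if (length(members) >= n_feat)
    stopf("gene set '%s' covers all features; enrichment undefined", set$name)
  in_set <- m$feature_ids %in% members
  apply_fun <- function(vals) {
    r <- rank(vals, ties.method = "average")
    ord <- order(-r, m$feature_ids)       # descending expression, ties by id
    in_ord <- in_set[ord]
    w <- r[ord]^alpha
    w[!in_ord] <- 0
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!in_ord) / (n_feat - length(members))
    sum(p_in - p_out)
  }
  es <- apply(m$values, 1L, apply_fun)
  stats::setNames(as.numeric(es), m$sample_ids)
}

#' Score a collection of signatures on a cohort
#'
#' Applies \code{\link{ssgsea}} per signature and z-scales the scores across
#' the cohort (mean 0, sd 1 per signature when n >= 2).
#'
#' @param m an \code{expr_matrix}.
#' @param sets named list of \code{gene_set}s.
#' @param alpha rank-weighting exponent passed to \code{\link{ssgsea}}.
#' @return A long data.frame: \code{sample_id}, \code{signature}, \code{es},
#'   \code{es_scaled}.
#' @export
score_signatures <- function(m, sets, alpha = 0.25) {
  if (is.null(names(sets)))
    names(sets) <- vapply(sets, `[[`, character(1), "name")
  rows <- lapply(names(sets), function(nm) {
    es <- ssgsea(m, sets[[nm]], alpha = alpha)
    scl <- if (length(es) >= 2 && stats::sd(es) > 0) as.numeric(scale(es)) else es * 0
    data.frame(sample_id = names(es), signature = nm, es = unname(es),
               es_scaled = scl, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "variant") <- "barbie_running_sum_unnormalized"
  out
}

#' ESTIMATE-style stromal and immune infiltration scores
#'
#' Per-sample ssGSEA enrichment of a stromal and an immune gene set, plus
#' their sum as the combined infiltration score.
#'
#' @param m an \code{expr_matrix}.
#' @param stromal_set,immune_set \code{gene_set}s.
#' @param alpha rank-weighting exponent.
#' @return A data.frame: \code{sample_id}, \code{stromal}, \code{immune},
#'   \code{combined}.
#' @export
estimate_style_scores <- function(m, stromal_set, immune_set, alpha = 0.25) {
  stromal <- ssgsea(m, stromal_set, alpha = alpha)
  immune <- ssgsea(m, immune_set, alpha = alpha)
  data.frame(sample_id = names(stromal), stromal = unname(stromal),
             immune = unname(immune), combined = unname(stromal + immune),
             stringsAsFactors = FALSE)
}

# Walkscore-weighted KS-like running-sum statistic over ranked coding genes:
# in-pathway steps rise proportionally to walkscore, out-of-pathway steps
# uniformly; the statistic is the maximum deviation.
ks_walk_stat <- function(ws_sorted, in_path) {
  w <- ws_sorted
  w[!in_path] <- 0
  tot_in <- sum(w)
  if (tot_in <= 0) {   # all member walkscores zero: fall back to uniform steps
    w[in_path] <- 1
    tot_in <- sum(w)
  }
  p_in <- cumsum(w) / tot_in
  p_out <- cumsum(!in_path) / sum(!in_path)
  max(p_in - p_out)
}

#' KS-like permutation test for pathway enrichment in walkscores
#'
#' Tests whether a pathway's coding genes concentrate at the top of the
#' walkscore ranking. The observed statistic is the maximum deviation of the
#' walkscore-weighted running sum (in-pathway steps proportional to
#' walkscore, out-of-pathway steps uniform) over coding genes ranked by
#' descending walkscore. The null is built by relabeling pathway membership
#' \code{B} times; \eqn{p = (1 + \#\{null \ge obs\}) / (B + 1)}, so p is
#' never below 1/(B+1).
#'
#' @param ws a \code{walkscore_table}.
#' @param pathway a \code{gene_set}; must overlap the coding nodes but not
#'   cover them all.
#' @param B number of permutations (default 1000).
#' @param seed integer RNG seed.
#' @return One-row data.frame: \code{pathway}, \code{statistic}, \code{p},
#'   \code{n_overlap}.
#' @export
ks_pathway_enrichment <- function(ws, pathway, B = 1000, seed = 1) {
  coding <- ws[ws$class == "coding", , drop = FALSE]
  coding <- coding[order(-coding$walkscore, coding$node), , drop = FALSE]
  in_path <- coding$node %in% pathway$members
  n_overlap <- sum(in_path)
  if (n_overlap == 0L) stopf("pathway '%s' has no overlap with coding nodes", pathway$name)
  if (n_overlap == nrow(coding))
    stopf("pathway '%s' covers every coding node", pathway$name)
  obs <- ks_walk_stat(coding$walkscore, in_path)
  null <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      ks_walk_stat(coding$walkscore, sample(in_path))
    }, numeric(1))
  })
  p <- (1 + sum(null >= obs)) / (B + 1)
  data.frame(pathway = pathway$name, statistic = obs, p = p,
             n_overlap = n_overlap, stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric probability of observing at least the overlap
#' between a selected gene list and a pathway within a finite universe
#' (classical ORA as used by pathway-database portals).
#'
#' @param list character vector of selected ids; must be a subset of
#'   \code{universe} and non-empty.
#' @param pathway a \code{gene_set}; its intersection with the universe must
#'   be non-empty.
#' @param universe character vector of background ids (conventionally every
#'   coding node of the CNC network).
#' @return One-row data.frame: \code{pathway}, \code{p}, \code{n_overlap},
#'   \code{n_list}, \code{n_pathway}, \code{n_universe}.
#' @export
ora_hypergeometric <- function(list, pathway, universe) {
  list <- unique(as.character(list)); universe <- unique(as.character(universe))
  if (!length(list)) stopf("selected list is empty")
  if (length(setdiff(list, universe)))
    stopf("selected list must be a subset of the universe")
  in_uni <- intersect(pathway$members, universe)
  if (!length(in_uni)) stopf("pathway '%s' has no member in the universe", pathway$name)
  k <- length(intersect(list, in_uni))
  m_size <- length(in_uni); n_size <- length(universe) - m_size
  p <- stats::phyper(k - 1, m_size, n_size, length(list), lower.tail = FALSE)
  data.frame(pathway = pathway$name, p = p, n_overlap = k,
             n_list = length(list), n_pathway = m_size,
             n_universe = length(universe), stringsAsFactors = FALSE)
}

#' Enrichment of a pathway collection over a walkscore ranking
#'
#' Runs either the KS-like permutation test on the full walkscore ranking or
#' hypergeometric ORA of the walkscore-selected proxy list against each
#' pathway, BH-adjusts across pathways, and (optionally) annotates each
#' pathway with the fraction of up-/down-regulated genes among its overlap
#' with a differential-expression table.
#'
#' @param ws a \code{walkscore_table}.
#' @param pathways named list of \code{gene_set}s.
#' @param mode \code{"ks"} or \code{"ora"}.
#' @param cutoff walkscore cutoff defining the selected list in ORA mode.
#' @param B,seed permutation count and seed for KS mode.
#' @param de optional \code{moderated_t} result for direction summaries.
#' @return data.frame with one row per pathway, including \code{q} (BH) and,
#'   when \code{de} is given, \code{frac_up}/\code{frac_down}.
#' @export
enrich_pathways <- function(ws, pathways, mode = c("ks", "ora"), cutoff = 0.01,
                            B = 1000, seed = 1, de = NULL) {
  mode <- match.arg(mode)
  universe <- ws$node[ws$class == "coding"]
  rows <- if (mode == "ks") {
    seeds <- derive_seeds(seed, length(pathways))
    lapply(seq_along(pathways), function(i)
      ks_pathway_enrichment(ws, pathways[[i]], B = B, seed = seeds[i]))
  } else {
    sel <- select_proxy_genes(ws, cutoff = cutoff)
    lapply(pathways, function(pw) ora_hypergeometric(sel, pw, universe))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- bh_adjust(out$p)
  if (!is.null(de)) {
    dirs <- t(vapply(pathways, function(pw) {
      hit <- de[de$feature_id %in% pw$members, , drop = FALSE]
      if (!nrow(hit)) return(c(frac_up = NA_real_, frac_down = NA_real_))
      c(frac_up = mean(hit$direction == "up"),
        frac_down = mean(hit$direction == "down"))
    }, numeric(2)))
    out$frac_up <- dirs[, "frac_up"]; out$frac_down <- dirs[, "frac_down"]
  }
  out
}
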