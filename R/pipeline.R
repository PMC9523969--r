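#' Default pipeline parameters
#'
#' Central defaults for every stage of the discovery workflow; any element
#' can be overridden through the config passed to
#' \code{\link{run_discovery}} / \code{\link{run_validation}}.
#'
#' Two profile choices differ from the bare function defaults, for reasons
#' worked out in the methods vignette: \code{restart_r = 0.3}, because with
#' a walkscore vector normalized to total mass one over a seed set of size
#' |S|, no non-seed node can exceed (1/|S|)(1-r)/(2-r), so the stringent
#' walkscore cutoff of 0.01 is attainable for moderate seed sets only when
#' r <= 1/3; and \code{r_min = 0.7}, placing the co-expression edge
#' threshold above the correlation level induced by shared phenotype
#' membership so that CNC edges reflect direct lncRNA-gene coupling rather
#' than module co-regulation.
#'
#' @return Named list of parameters.
#' @export
pipeline_defaults <- function() {
  list(k_range = 2:5, reps = 5000, p_item = 0.8,       # consensus clustering
       q_max = 0.05, lfc_min = 1.0,                    # ir-lncRNA filter
       r_min = 0.7, cor_method = "pearson",            # CNC network
       restart_r = 0.3, walkscore_cutoff = 0.01,       # propagation
       alpha = 0.25,                                   # ssGSEA
       k_signature = 20,                               # signature sizes
       folds = 5, min_group_frac = 0.10,               # CV cutpoint
       seed = 1)
}

resolve_input <- function(x, loader, what) {
  if (is.null(x)) stopf("config is missing required input: %s", what)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stopf("%s file not found: %s", what, x)
    return(loader(x))
  }
  x
}

validate_config <- function(config) {
  # fail fast on missing files before any computation starts
  for (nm in intersect(names(config),
                       c("expr_coding", "expr_lncrna", "clinical", "icr_gmt",
                         "checkpoint_gmt", "pathway_gmt", "network_edges"))) {
    x <- config[[nm]]
    if (is.character(x) && length(x) == 1L && !file.exists(x))
      stopf("config file does not exist: %s = %s", nm, x)
  }
  invisible(config)
}

write_stage_table <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Run the full ir-lncRNA signature discovery workflow
#'
#' Orchestrates the six discovery stages on one cohort:
#' \enumerate{
#'   \item immune-phenotype calling: consensus clustering of the ICR module,
#'     Calinski-Harabasz k selection, tier assignment;
#'   \item moderated-t differential expression of lncRNAs between the
#'     ICR_high and ICR_low tiers and the ir-lncRNA filter;
#'   \item CNC network construction (or a prebuilt edge list) and random
#'     walk with restart from the ir-lncRNA seeds; proxy-gene selection;
#'   \item pathway enrichment of the walkscore ranking (when pathway sets
#'     are supplied);
#'   \item signature derivation: top-k by DE, top-k by checkpoint
#'     correlation, and their intersection;
#'   \item survival evaluation: ssGSEA scoring of ICR and each signature,
#'     univariate Cox fits, the combined ICR + minimal-signature model, AIC
#'     comparison, cross-validated KM cutpoint and the cohort
#'     enabled/disabled/neutral call.
#' }
#' Every intermediate table is returned and, when \code{out_dir} is given,
#' written as TSV/JSON together with a run manifest (parameters, seeds,
#' input hashes, per-stage feature counts).
#'
#' @param config list with inputs (\code{expr_coding}, \code{expr_lncrna}:
#'   paths or \code{expr_matrix}; \code{clinical}: path or
#'   \code{clinical_table}; \code{icr_gmt}, \code{checkpoint_gmt}: paths or
#'   \code{gene_set}s; optional \code{pathway_gmt}, \code{network_edges})
#'   and any overrides of \code{\link{pipeline_defaults}} under
#'   \code{params}.
#' @param out_dir optional artifact directory.
#' @return A list with every stage result (\code{phenotype}, \code{de},
#'   \code{ir_lncrnas}, \code{network}, \code{walkscores}, \code{proxies},
#'   \code{enrichment}, \code{correlation}, \code{signatures},
#'   \code{scores}, \code{fits}, \code{combined_fit}, \code{daic},
#'   \code{cutpoint}, \code{cohort_class}, \code{manifest}).
#' @export
run_discovery <- function(config, out_dir = NULL) {
  validate_config(config)
  params <- utils::modifyList(pipeline_defaults(), config$params %||% list())
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(params$seed, 4L)
  counts <- list()

  coding <- resolve_input(config$expr_coding,
                          function(p) read_expression(p, "coding"), "expr_coding")
  lnc <- resolve_input(config$expr_lncrna,
                       function(p) read_expression(p, "lncRNA"), "expr_lncrna")
  clin <- resolve_input(config$clinical, read_clinical, "clinical")
  icr_set <- resolve_input(config$icr_gmt, function(p) read_gmt(p)[[1L]], "icr_gmt")
  chk_set <- resolve_input(config$checkpoint_gmt,
                           function(p) read_gmt(p)[[1L]], "checkpoint_gmt")
  pathways <- if (!is.null(config$pathway_gmt))
    resolve_input(config$pathway_gmt, read_gmt, "pathway_gmt") else NULL

  # stage 1: immune phenotype
  phen <- consensus_cluster(coding, icr_set, k_range = params$k_range,
                            reps = params$reps, p_item = params$p_item,
                            seed = seeds[1L])
  high <- names(phen$tier)[phen$tier == "ICR_high"]
  low <- names(phen$tier)[phen$tier == "ICR_low"]
  counts$icr_high <- length(high); counts$icr_low <- length(low)
  msgf("stage icr_phenotype: k = %d (%d ICR_high, %d ICR_low)",
       phen$k_selected, length(high), length(low))
  write_stage_table(data.frame(sample_id = names(phen$tier),
                               cluster = unname(phen$labels),
                               tier = as.character(phen$tier)),
                    out_dir, "clusters.tsv")

  # stage 2: differential lncRNA expression (ICR_medium samples excluded)
  de <- moderated_t(lnc, high, low)
  irl <- filter_ir_lncrnas(de, q_max = params$q_max, lfc_min = params$lfc_min)
  counts$de_lncrnas <- nrow(irl)
  if (!nrow(irl)) stopf("stage differential_expression: no ir-lncRNA passes the filter")
  write_stage_table(de, out_dir, "de.tsv")
  write_stage_table(irl, out_dir, "ir_lncrnas.tsv")

  # stage 3: CNC network + propagation
  net <- if (!is.null(config$network_edges)) {
    cls <- c(coding$feature_class, lnc$feature_class)
    resolve_input(config$network_edges,
                  function(p) read_edge_list(p, cls), "network_edges")
  } else {
    build_cnc_network(coding, lnc, r_min = params$r_min,
                      method = params$cor_method)
  }
  ws <- rwr(net, irl$feature_id, restart_r = params$restart_r)
  proxies <- select_proxy_genes(ws, cutoff = params$walkscore_cutoff)
  counts$seed_lncrnas <- sum(irl$feature_id %in% net$nodes)
  counts$proxy_genes <- length(proxies)
  msgf("stage network_propagation: %d seed(s), %d proxy gene(s)",
       counts$seed_lncrnas, counts$proxy_genes)
  write_stage_table(ws, out_dir, "walkscores.tsv")

  # stage 4: pathway enrichment (optional)
  enr <- NULL
  if (!is.null(pathways) && length(pathways)) {
    enr <- enrich_pathways(ws, pathways, mode = "ks", B = 1000,
                           seed = seeds[2L], de = de)
    write_stage_table(enr, out_dir, "pathway_enrichment.tsv")
  }

  # stage 5: signature derivation
  chk_ids <- intersect(chk_set$members, coding$feature_ids)
  if (length(chk_ids) < 2L) stopf("fewer than 2 checkpoint genes in the matrix")
  corr <- spearman_matrix(
    expr_matrix(lnc$values[, irl$feature_id, drop = FALSE],
                lnc$feature_class[irl$feature_id]),
    expr_matrix(coding$values[, chk_ids, drop = FALSE],
                coding$feature_class[chk_ids]))
  sig_icr <- top_icr_signature(irl, k = params$k_signature)
  sig_icp <- top_icp_signature(corr, rownames(corr$rho), k = params$k_signature)
  sig_min <- intersect_signatures(sig_icr, sig_icp)
  counts$signature_sizes <- c(length(sig_icr$members), length(sig_icp$members),
                              length(sig_min$members))
  msgf("stage signature_builder: sizes %s",
       paste(counts$signature_sizes, collapse = "/"))

  # stage 6: survival evaluation
  all_expr <- bind_features(coding, lnc)
  sets <- list(ICR = icr_set)
  sets[[sig_icr$name]] <- gene_set(sig_icr$name, sig_icr$members)
  sets[[sig_icp$name]] <- gene_set(sig_icp$name, sig_icp$members)
  if (length(sig_min$members))
    sets[[sig_min$name]] <- gene_set(sig_min$name, sig_min$members)
  scores <- score_signatures(all_expr, sets, alpha = params$alpha)
  fits <- lapply(names(sets), function(nm) {
    sc <- scores[scores$signature == nm, ]
    cox_fit(clin, stats::setNames(sc$es, sc$sample_id))
  })
  names(fits) <- names(sets)
  comb_fit <- daic <- cutpt <- NULL
  if (length(sig_min$members)) {
    comb <- combined_score(scores, "ICR", sig_min$name)
    comb_fit <- cox_fit(clin, comb)
    daic <- compare_aic(fits[[sig_min$name]], fits[["ICR"]])
    sc_min <- scores[scores$signature == sig_min$name, ]
    cutpt <- cv_optimal_cutpoint(clin, stats::setNames(sc_min$es, sc_min$sample_id),
                                 folds = params$folds, seed = seeds[3L],
                                 min_group_frac = params$min_group_frac)
  }
  cls <- classify_cohort(fits[["ICR"]], cohort = config$cohort_id %||% "discovery")
  write_stage_table(scores, out_dir, "scores.tsv")
  write_stage_table(forest_table(fits), out_dir, "fits.tsv")

  manifest <- list(
    stages = c("icr_phenotype", "differential_expression",
               "network_propagation", "gene_set_scoring",
               "signature_builder", "survival_analysis"),
    params = params, stage_seeds = seeds, counts = counts,
    input_hashes = input_hashes(config))
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)

  list(phenotype = phen, de = de, ir_lncrnas = irl, network = net,
       walkscores = ws, proxies = proxies, enrichment = enr,
       correlation = corr,
       signatures = list(icr = sig_icr, icp = sig_icp, minimal = sig_min),
       scores = scores, fits = fits, combined_fit = comb_fit, daic = daic,
       cutpoint = cutpt, cohort_class = cls, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

input_hashes <- function(config) {
  paths <- Filter(function(x) is.character(x) && length(x) == 1L && file.exists(x),
                  config[intersect(names(config),
                                   c("expr_coding", "expr_lncrna", "clinical",
                                     "icr_gmt", "checkpoint_gmt", "pathway_gmt",
                                     "network_edges"))])
  if (!length(paths)) return(list())
  lapply(paths, function(p) unname(tools::md5sum(p)))
}

#' Validate derived signatures across cohorts
#'
#' For each validation cohort: ssGSEA scores for the ICR module and every
#' supplied signature, univariate Cox fits on the continuous scores, the
#' combined ICR + last-signature model, AIC comparison against ICR, the
#' cross-validated KM cutpoint for the first signature, and the
#' enabled/disabled/neutral flag per score. Signatures with no member
#' present in a cohort are skipped for that cohort with a message.
#'
#' @param cohorts named list; each element a list with \code{expr}
#'   (\code{expr_matrix} or list \code{coding}/\code{lncrna} of paths or
#'   matrices) and \code{clinical}.
#' @param signatures named list of \code{signature} or \code{gene_set}
#'   objects to evaluate.
#' @param icr_set the ICR \code{gene_set}.
#' @param params overrides of \code{\link{pipeline_defaults}}.
#' @return List with \code{forest} (merged per-cohort, per-score table) and
#'   \code{fits} (nested list).
#' @export
run_validation <- function(cohorts, signatures, icr_set, params = list()) {
  params <- utils::modifyList(pipeline_defaults(), params)
  if (is.null(names(cohorts))) names(cohorts) <- paste0("cohort", seq_along(cohorts))
  all_rows <- list(); all_fits <- list()
  for (nm in names(cohorts)) {
    co <- cohorts[[nm]]
    expr <- if (inherits(co$expr, "expr_matrix")) co$expr
      else bind_features(resolve_input(co$expr$coding,
                                       function(p) read_expression(p, "coding"),
                                       "coding expression"),
                         resolve_input(co$expr$lncrna,
                                       function(p) read_expression(p, "lncRNA"),
                                       "lncRNA expression"))
    clin <- resolve_input(co$clinical, read_clinical, "clinical")
    sets <- list(ICR = icr_set)
    for (sg in names(signatures)) {
      mem <- intersect(signatures[[sg]]$members, expr$feature_ids)
      if (!length(mem)) {
        msgf("run_validation: cohort %s lacks all members of '%s'; skipped", nm, sg)
        next
      }
      sets[[sg]] <- gene_set(sg, mem)
    }
    scores <- score_signatures(expr, sets, alpha = params$alpha)
    fits <- lapply(names(sets), function(s) {
      sc <- scores[scores$signature == s, ]
      cox_fit(clin, stats::setNames(sc$es, sc$sample_id))
    })
    names(fits) <- names(sets)
    ft <- forest_table(fits)
    ft$cohort <- nm
    ft$score <- names(fits)
    all_rows[[nm]] <- ft
    all_fits[[nm]] <- fits
  }
  forest <- do.call(rbind, all_rows)
  rownames(forest) <- NULL
  list(forest = forest, fits = all_fits)
}
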