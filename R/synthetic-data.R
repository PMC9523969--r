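#' Specification of a synthetic immuno-oncology cohort
#'
#' Describes a cohort in which a latent binary immune phenotype (hot vs cold)
#' drives: (i) coordinated up-regulation of an ICR gene module and an immune
#' checkpoint panel, (ii) differential expression of a planted set of
#' immune-related lncRNAs (ir-lncRNAs) with configurable sign split, (iii)
#' proxy protein-coding genes that are noisy linear functions of single
#' planted lncRNAs (so co-expression network edges form), and (iv) overall
#' survival whose log-hazard is proportional to the standardized mean ICR
#' expression. All remaining features are phenotype-independent noise.
#'
#' Expression is Gaussian on the log2 scale, emulating quantile-normalized
#' log-expression matrices; there is no raw-count layer. The up:down split of
#' the planted lncRNAs defaults to 17:23, mirroring at reduced scale the
#' preponderance of down-regulated ir-lncRNAs seen in immune-hot breast
#' tumors.
#'
#' @param n_samples number of samples.
#' @param n_coding,n_lncrna number of coding / lncRNA features.
#' @param n_icr_genes size of the planted ICR module (default 20).
#' @param n_up,n_down planted ir-lncRNAs up-/down-regulated in hot samples;
#'   their sum is the total number of planted ir-lncRNAs.
#' @param n_proxy_coding coding genes coupled to planted lncRNAs.
#' @param n_checkpoints immune checkpoint genes (shift with phenotype).
#' @param hot_fraction expected fraction of immune-hot samples, in (0,1).
#' @param de_effect log2 fold-change magnitude of planted effects.
#' @param noise_sd residual SD on the log2 scale.
#' @param hazard_coef log-hazard per unit standardized mean ICR expression
#'   (negative = immune-hot protective, i.e. an "ICR enabled" cohort).
#' @param censor_rate target censoring proportion, in [0,1).
#' @param seed integer RNG seed.
#' @return A \code{cohort_spec} list.
#' @export
cohort_spec <- function(n_samples = 300, n_coding = 500, n_lncrna = 200,
                        n_icr_genes = 20, n_up = 17, n_down = 23,
                        n_proxy_coding = 30, n_checkpoints = 30,
                        hot_fraction = 0.5, de_effect = 2, noise_sd = 1,
                        hazard_coef = -0.7, censor_rate = 0.3, seed = 1) {
  spec <- list(n_samples = n_samples, n_coding = n_coding, n_lncrna = n_lncrna,
               n_icr_genes = n_icr_genes, n_up = n_up, n_down = n_down,
               n_ir_lncrna = n_up + n_down,
               n_proxy_coding = n_proxy_coding, n_checkpoints = n_checkpoints,
               hot_fraction = hot_fraction, de_effect = de_effect,
               noise_sd = noise_sd, hazard_coef = hazard_coef,
               censor_rate = censor_rate, seed = as.integer(seed))
  counts <- c("n_samples", "n_coding", "n_lncrna", "n_icr_genes", "n_up",
              "n_down", "n_proxy_coding", "n_checkpoints")
  for (nm in counts)
    if (!is_count(spec[[nm]])) stopf("`%s` must be a non-negative integer", nm)
  if (spec$n_samples <= 0) stopf("`n_samples` must be positive")
  if (!(hot_fraction > 0 && hot_fraction < 1))
    stopf("`hot_fraction` must lie in (0,1)")
  if (censor_rate < 0 || censor_rate >= 1)
    stopf("`censor_rate` must lie in [0,1)")
  if (spec$n_icr_genes + spec$n_checkpoints + spec$n_proxy_coding > spec$n_coding)
    stopf("planted coding sets exceed `n_coding` (they must be disjoint)")
  if (spec$n_ir_lncrna > spec$n_lncrna)
    stopf("planted ir-lncRNAs exceed `n_lncrna`")
  structure(spec, class = "cohort_spec")
}

# Administrative censoring window achieving an expected censoring proportion:
# with C the window and U ~ Unif(0, C), P(censored_i) = min(T_i, C)/C, so the
# expected rate is f(C) = mean(pmin(T, C))/C, decreasing in C. Solve by
# bisection.
censor_window <- function(times, rate, tol = 1e-6) {
  if (rate <= 0) return(Inf)
  f <- function(C) mean(pmin(times, C)) / C
  lo <- min(times[times > 0], 1e-6)
  hi <- max(times) * 2
  while (f(hi) > rate) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > rate) lo <- mid else hi <- mid
    if (hi - lo < tol * hi) break
  }
  (lo + hi) / 2
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws expression, survival and a ground-truth record per the spec in
#' \code{\link{cohort_spec}}. Two independent RNG sub-streams (expression,
#' survival) are derived from the master seed so that changing survival
#' parameters leaves the expression draw untouched; identical specs and seeds
#' give bit-identical cohorts.
#'
#' @param spec a \code{cohort_spec}.
#' @return A list with elements
#'   \describe{
#'     \item{expression}{\code{expr_matrix}, coding + lncRNA features.}
#'     \item{clinical}{\code{clinical_table} (time in days).}
#'     \item{truth}{ground-truth record: latent phenotype, planted id lists
#'       with sign, proxy pairings, true hazard coefficient.}
#'     \item{sets}{named list of \code{gene_set}s (ICR module, checkpoint
#'       panel, planted lncRNA/proxy sets) for downstream use.}
#'   }
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  seeds <- derive_seeds(spec$seed, 2L)

  sample_ids <- sprintf("S%04d", seq_len(spec$n_samples))
  coding_ids <- sprintf("PCG%04d", seq_len(spec$n_coding))
  lnc_ids <- if (spec$n_lncrna > 0) sprintf("LNC%04d", seq_len(spec$n_lncrna)) else character(0)

  icr_ids <- coding_ids[seq_len(spec$n_icr_genes)]
  chk_ids <- coding_ids[spec$n_icr_genes + seq_len(spec$n_checkpoints)]
  proxy_ids <- coding_ids[spec$n_icr_genes + spec$n_checkpoints +
                            seq_len(spec$n_proxy_coding)]
  up_ids <- lnc_ids[seq_len(spec$n_up)]
  down_ids <- lnc_ids[spec$n_up + seq_len(spec$n_down)]
  planted_lnc <- c(up_ids, down_ids)

  # --- expression block ------------------------------------------------------
  expr <- with_seed(seeds[1L], {
    hot <- stats::rbinom(spec$n_samples, 1L, spec$hot_fraction)
    n_feat <- spec$n_coding + spec$n_lncrna
    baseline <- stats::runif(n_feat, 4, 8)
    feat_ids <- c(coding_ids, lnc_ids)
    x <- matrix(stats::rnorm(spec$n_samples * n_feat, sd = spec$noise_sd),
                nrow = spec$n_samples, ncol = n_feat,
                dimnames = list(sample_ids, feat_ids))
    x <- sweep(x, 2L, baseline, "+")
    shift_up <- c(icr_ids, chk_ids, up_ids)
    if (length(shift_up))
      x[, shift_up] <- x[, shift_up] + spec$de_effect * hot
    if (length(down_ids))
      x[, down_ids] <- x[, down_ids] - spec$de_effect * hot
    # proxy coding genes: noisy linear images of single planted lncRNAs
    proxy_map <- character(0)
    if (spec$n_proxy_coding > 0) {
      if (!length(planted_lnc))
        stopf("proxy genes requested but no planted ir-lncRNAs to couple to")
      partner <- planted_lnc[((seq_len(spec$n_proxy_coding) - 1L) %%
                                length(planted_lnc)) + 1L]
      slope <- sample(c(-1, 1), spec$n_proxy_coding, replace = TRUE) *
        stats::runif(spec$n_proxy_coding, 0.7, 1.0)
      eps_sd <- 0.5 * max(spec$noise_sd, 1e-8)
      for (j in seq_len(spec$n_proxy_coding)) {
        x[, proxy_ids[j]] <- baseline[match(proxy_ids[j], feat_ids)] +
          slope[j] * (x[, partner[j]] - mean(x[, partner[j]])) +
          stats::rnorm(spec$n_samples, sd = eps_sd)
      }
      proxy_map <- stats::setNames(partner, proxy_ids)
    }
    list(x = x, hot = hot, proxy_map = proxy_map)
  })

  # --- survival block --------------------------------------------------------
  icr_mean <- rowMeans(expr$x[, icr_ids, drop = FALSE])
  icr_score <- as.numeric(scale(icr_mean))
  surv <- with_seed(seeds[2L], {
    lambda0 <- log(2) / 1095   # baseline median survival ~ 3 years (days)
    rate <- lambda0 * exp(spec$hazard_coef * icr_score)
    t_event <- stats::rexp(spec$n_samples, rate = rate)
    C <- censor_window(t_event, spec$censor_rate)
    u <- if (is.finite(C)) stats::runif(spec$n_samples, 0, C) else rep(Inf, spec$n_samples)
    event <- as.integer(t_event <= u)
    list(time = pmin(t_event, u), event = event, window = C)
  })

  fclass <- c(rep("coding", spec$n_coding), rep("lncRNA", spec$n_lncrna))
  truth <- list(
    latent_phenotype = stats::setNames(ifelse(expr$hot == 1L, "hot", "cold"),
                                       sample_ids),
    planted_ir_lncrnas = data.frame(
      id = planted_lnc,
      sign = rep(c(1L, -1L), c(spec$n_up, spec$n_down)),
      stringsAsFactors = FALSE),
    planted_proxies = data.frame(id = names(expr$proxy_map),
                                 partner = unname(expr$proxy_map),
                                 stringsAsFactors = FALSE),
    icr_genes = icr_ids, checkpoints = chk_ids,
    true_hazard_coef = spec$hazard_coef,
    censor_window = surv$window)

  sets <- list(
    icr = gene_set("ICR", icr_ids, "planted ICR immune-activation module"),
    checkpoints = gene_set("checkpoints", chk_ids, "planted checkpoint panel"))
  if (length(planted_lnc))
    sets$planted_ir_lncrna <- gene_set("planted_ir_lncrna", planted_lnc,
                                       "planted differential lncRNAs")
  if (length(truth$planted_proxies$id))
    sets$planted_proxies <- gene_set("planted_proxies", truth$planted_proxies$id,
                                     "coding genes coupled to planted lncRNAs")

  list(expression = expr_matrix(expr$x, fclass),
       clinical = clinical_table(sample_ids, surv$time, surv$event),
       truth = truth, sets = sets, spec = spec)
}

#' Write a synthetic cohort to disk as plain-text fixtures
#'
#' Writes the coding and lncRNA expression matrices (features x samples TSV),
#' the clinical table, a GMT of the planted gene sets and the ground truth as
#' JSON, such that everything round-trips losslessly through the readers.
#'
#' @param cohort result of \code{\link{generate_cohort}}.
#' @param dir output directory (created if needed).
#' @return Named character vector of the file paths written.
#' @export
write_fixture <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stopf("cannot create directory %s", dir)
  paths <- c(
    coding = file.path(dir, "expression_coding.tsv"),
    lncrna = file.path(dir, "expression_lncrna.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    gmt = file.path(dir, "planted_sets.gmt"),
    truth = file.path(dir, "ground_truth.json"))
  write_expression(subset_class(cohort$expression, "coding"), paths[["coding"]])
  write_expression(subset_class(cohort$expression, "lncRNA"), paths[["lncrna"]])
  write_clinical(cohort$clinical, paths[["clinical"]])
  write_gmt(cohort$sets, paths[["gmt"]])
  truth <- cohort$truth
  truth$latent_phenotype <- as.list(truth$latent_phenotype)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
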