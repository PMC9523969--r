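# Shared fixture builders; everything is generated in code at test time.

# A small cohort that keeps every planted structure but runs fast.
small_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_samples = 120, n_coding = 150, n_lncrna = 80,
         n_icr_genes = 20, n_up = 8, n_down = 12, n_proxy_coding = 10,
         n_checkpoints = 15, hot_fraction = 0.5, de_effect = 2,
         noise_sd = 1, hazard_coef = -0.7, censor_rate = 0.3, seed = seed),
    list(...))
  do.call(cohort_spec, args)
}

small_cohort <- function(seed = 1, ...) generate_cohort(small_spec(seed, ...))

# Tiny expression matrix from a plain numeric matrix (samples x features).
ex_matrix <- function(x, class = "coding") {
  if (is.null(rownames(x))) rownames(x) <- sprintf("s%02d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%02d", seq_len(ncol(x)))
  expr_matrix(x, class)
}

# Independent brute-force ssGSEA oracle: explicit per-position loop over the
# descending-expression ordering, kept deliberately different in style from
# the package's vectorized implementation.
ssgsea_oracle <- function(vals, ids, members, alpha = 0.25) {
  r <- rank(vals, ties.method = "average")
  ord <- order(-r, ids)
  n <- length(vals)
  in_set <- ids[ord] %in% members
  denom_in <- sum(r[ord][in_set]^alpha)
  n_out <- n - sum(in_set)
  es <- 0; run_in <- 0; run_out <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) run_in <- run_in + r[ord][i]^alpha / denom_in
    else run_out <- run_out + 1 / n_out
    es <- es + (run_in - run_out)
  }
  unname(es)
}

# Independent two-group log-rank oracle (O-E / hypergeometric variance form).
logrank_oracle <- function(time, event, g1) {
  stopifnot(is.logical(g1))
  O1 <- 0; E1 <- 0; V <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    n_j <- sum(at_risk); n1_j <- sum(at_risk & g1)
    d_j <- sum(time == tt & event == 1)
    d1_j <- sum(time == tt & event == 1 & g1)
    O1 <- O1 + d1_j
    E1 <- E1 + d_j * n1_j / n_j
    if (n_j > 1)
      V <- V + d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
  }
  (O1 - E1)^2 / V
}

# Dense linear-solve RWR oracle: p = r (I - (1-r) W)^-1 p0.
rwr_oracle <- function(W, p0, r) {
  as.numeric(r * solve(diag(nrow(W)) - (1 - r) * W, p0))
}

# Exponential survival cohort with a known log-hazard coefficient.
sim_exp_cohort <- function(n = 200, beta = 0, seed = 1, censor_q = 0.7,
                           binary = FALSE) {
  withr::with_seed(seed, {
    x <- if (binary) rep(c(0, 1), length.out = n) else rnorm(n)
    t_event <- rexp(n, rate = 0.01 * exp(beta * x))
    cens <- runif(n, 0, quantile(t_event, censor_q) * 2)
  })
  clin <- clinical_table(sprintf("s%04d", 1:n), pmin(t_event, cens),
                         as.integer(t_event <= cens))
  list(clin = clin, x = setNames(x, clin$sample_id))
}
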