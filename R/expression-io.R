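#' Expression matrix container
#'
#' A light S3 container for a log2-scale expression matrix. In memory the
#' orientation is always samples x features; on disk files are written
#' features x samples (TANRIC-style, first column the feature id, header the
#' sample ids). Each feature carries a class label, \code{"coding"} or
#' \code{"lncRNA"}, so mixed matrices can be subset by biotype.
#'
#' @param values numeric matrix, samples x features, with complete dimnames.
#' @param feature_class character scalar or vector giving the class of each
#'   feature (\code{"coding"} or \code{"lncRNA"}).
#' @return An object of class \code{expr_matrix}: a list with elements
#'   \code{values}, \code{feature_class} (named by feature), \code{sample_ids}
#'   and \code{feature_ids}.
#' @export
expr_matrix <- function(values, feature_class) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix (samples x features)")
  if (nrow(values) > 0 && is.null(rownames(values)))
    stopf("`values` must carry sample (row) names")
  if (ncol(values) > 0 && is.null(colnames(values)))
    stopf("`values` must carry feature (column) names")
  if (ncol(values) == 0 && is.null(colnames(values)))
    colnames(values) <- character(0)
  if (nrow(values) == 0 && is.null(rownames(values)))
    rownames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stopf("duplicate sample ids")
  if (anyDuplicated(colnames(values)))
    stopf("duplicate feature ids")
  if (any(!is.finite(values)))
    stopf("expression values must be finite (no NA/NaN/Inf)")
  feature_class <- rep_len(as.character(feature_class), ncol(values))
  bad <- setdiff(unique(feature_class), c("coding", "lncRNA"))
  if (length(bad) && ncol(values) > 0)
    stopf("unknown feature class: %s", paste(bad, collapse = ", "))
  names(feature_class) <- colnames(values)
  structure(
    list(values = values, feature_class = feature_class,
         sample_ids = rownames(values), feature_ids = colnames(values)),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  tab <- table(factor(x$feature_class, levels = c("coding", "lncRNA")))
  cat(sprintf("expr_matrix: %d samples x %d features (%d coding, %d lncRNA)\n",
              nrow(x$values), ncol(x$values), tab[["coding"]], tab[["lncRNA"]]))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by feature class
#'
#' @param m an \code{expr_matrix}.
#' @param class \code{"coding"} or \code{"lncRNA"}.
#' @return An \code{expr_matrix} restricted to features of the given class.
#' @export
subset_class <- function(m, class = c("coding", "lncRNA")) {
  class <- match.arg(class)
  keep <- names(m$feature_class)[m$feature_class == class]
  expr_matrix(m$values[, keep, drop = FALSE],
              m$feature_class[keep])
}

#' Combine two expression matrices over the same samples
#'
#' @param a,b \code{expr_matrix} objects sharing the same sample set.
#' @return A single \code{expr_matrix} with the features of both.
#' @export
bind_features <- function(a, b) {
  if (!identical(a$sample_ids, b$sample_ids))
    stopf("matrices must share an identical sample set and order")
  expr_matrix(cbind(a$values, b$values), c(a$feature_class, b$feature_class))
}

#' Read an expression matrix from a features x samples TSV
#'
#' The on-disk layout is features x samples: the first column holds feature
#' ids, the header the sample ids. Gzip-compressed files are read
#' transparently. Duplicate feature ids and non-numeric cells are rejected.
#'
#' @param path path to a TSV (optionally .gz).
#' @param feature_class class to declare for all features in the file.
#' @param na_policy \code{"error"} (default) rejects missing values;
#'   \code{"drop"} removes features containing any missing value, with a
#'   message.
#' @return An \code{expr_matrix} (samples x features in memory).
#' @export
read_expression <- function(path, feature_class = c("coding", "lncRNA"),
                            na_policy = c("error", "drop")) {
  feature_class <- match.arg(feature_class)
  na_policy <- match.arg(na_policy)
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stopf("malformed header in %s", path)
  ids <- as.character(df[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stopf("duplicate feature id(s) in %s: %s", path,
          paste(utils::head(dup, 5), collapse = ", "))
  vals <- df[, -1L, drop = FALSE]
  num <- vapply(vals, is.numeric, logical(1))
  if (nrow(vals) > 0 && !all(num))
    stopf("non-numeric cells in column(s): %s",
          paste(names(vals)[!num], collapse = ", "))
  x <- if (nrow(vals) == 0) {
    matrix(numeric(0), nrow = ncol(vals), ncol = 0,
           dimnames = list(names(vals), character(0)))
  } else {
    t(as.matrix(vals))         # -> samples x features
  }
  colnames(x) <- ids
  if (anyNA(x)) {
    if (na_policy == "error")
      stopf("missing values in %s (use na_policy = \"drop\" to remove features)",
            path)
    bad <- colnames(x)[colSums(is.na(x)) > 0]
    msgf("dropping %d feature(s) with missing values", length(bad))
    x <- x[, setdiff(colnames(x), bad), drop = FALSE]
  }
  expr_matrix(x, feature_class)
}

#' Write an expression matrix as a features x samples TSV
#'
#' @param m an \code{expr_matrix}.
#' @param path output path.
#' @param id_column header name for the feature-id column.
#' @export
write_expression <- function(m, path, id_column = "feature_id") {
  out <- data.frame(id = m$feature_ids,
                    t(m$values), check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[1L] <- id_column
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Clinical survival table
#'
#' @param sample_id character vector of unique sample ids.
#' @param time non-negative follow-up times (days).
#' @param event event indicator, 1 = death, 0 = censored.
#' @return A \code{data.frame} of class \code{clinical_table}.
#' @export
clinical_table <- function(sample_id, time, event) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stopf("duplicate sample ids in clinical table")
  time <- as.numeric(time); event <- as.integer(event)
  if (any(!is.finite(time)) || any(time < 0)) stopf("times must be finite and >= 0")
  if (!all(event %in% c(0L, 1L))) stopf("event must be 0/1")
  structure(data.frame(sample_id = sample_id, time = time, event = event,
                       stringsAsFactors = FALSE),
            class = c("clinical_table", "data.frame"))
}

#' Read a clinical table (sample_id, time, event) from TSV
#' @param path path to TSV.
#' @return A \code{clinical_table}.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df)))
    stopf("clinical table must have columns: %s", paste(need, collapse = ", "))
  clinical_table(df$sample_id, df$time, df$event)
}

#' Write a clinical table to TSV
#' @param clin a \code{clinical_table}.
#' @param path output path.
#' @export
write_clinical <- function(clin, path) {
  utils::write.table(clin, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample to the same empirical distribution: after
#' normalization each sample's sorted value vector equals the per-rank mean
#' across samples, with ties resolved by averaging the tied rank means
#' (the classical microarray quantile normalization). Delegates to
#' \code{\link[limma]{normalizeQuantiles}}.
#'
#' @param m an \code{expr_matrix} with at least 2 samples. A single-sample
#'   matrix is returned unchanged with a warning.
#' @return The normalized \code{expr_matrix}.
#' @export
quantile_normalize <- function(m) {
  if (nrow(m$values) < 2L) {
    warnf("quantile_normalize: single sample, returning input unchanged")
    return(m)
  }
  norm <- limma::normalizeQuantiles(t(m$values), ties = TRUE)  # features x samples
  out <- t(norm)
  dimnames(out) <- dimnames(m$values)
  expr_matrix(out, m$feature_class)
}

#' Gene set container
#'
#' @param name set name.
#' @param members character vector of member ids (deduplicated).
#' @param description free-text description.
#' @return An object of class \code{gene_set}.
#' @export
gene_set <- function(name, members, description = "") {
  members <- as.character(members)
  if (anyDuplicated(members)) {
    warnf("gene set '%s': %d duplicated member(s) removed",
          name, sum(duplicated(members)))
    members <- unique(members)
  }
  if (!length(members)) stopf("gene set '%s' is empty", name)
  structure(list(name = as.character(name), description = as.character(description),
                 members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s' (%d members)\n", x$name, length(x$members)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' \code{name<TAB>description<TAB>member...}. Lines with fewer than three
#' fields are an error; duplicated members are removed with a warning.
#'
#' @param path path to a GMT file (optionally .gz).
#' @return A named list of \code{gene_set} objects (empty list for an empty
#'   file).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stopf("GMT line %d has %d field(s); need name, description and >= 1 member",
            i, length(fields))
    gene_set(fields[1L], fields[-(1:2)], fields[2L])
  })
  stats::setNames(sets, vapply(sets, `[[`, character(1), "name"))
}

#' Write gene sets to a GMT file
#' @param sets a list of \code{gene_set} objects.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    desc <- if (nzchar(s$description)) s$description else "na"
    paste(c(s$name, desc, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
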