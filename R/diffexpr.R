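# Differential expression and seed selection. A plain pooled-variance linear
# model (two-sample t, or one-way ANOVA for multi-group factors) on
# log2-scale values; genes pass into the seed set under combined p-value and
# |logFC| cutoffs. Paired, block, time-series and nested designs are not
# supported and are rejected up front.

#' Two-group differential expression
#'
#' Per gene, computes `logFC = mean(group_b) - mean(group_a)` on the log2
#' scale and a two-sided p-value from the pooled-variance two-sample t
#' statistic with `n_a + n_b - 2` degrees of freedom, followed by
#' Benjamini-Hochberg adjustment across genes. Missing values are ignored
#' per gene; a gene is dropped from the comparison when either group retains
#' fewer than 2 observed values.
#'
#' @param ds A log2-scale `expression_dataset` (see [normalize_expression()]).
#' @param factor_name Name of the factor (one `#CLASS` row) to compare on.
#' @param group_a,group_b Labels within that factor; logFC is
#'   `group_b - group_a`.
#' @return A `de_result` data frame: `gene`, `logFC`, `p_value`,
#'   `p_adjusted`, sorted by `p_value`.
#' @export
differential_expression <- function(ds, factor_name, group_a, group_b) {
  stopifnot(inherits(ds, "expression_dataset"))
  labels <- get_factor(ds, factor_name)
  for (g in c(group_a, group_b)) {
    if (sum(labels == g) < 2L) {
      stop(sprintf("group '%s' has fewer than 2 samples", g), call. = FALSE)
    }
  }
  va <- ds$values[, labels == group_a, drop = FALSE]
  vb <- ds$values[, labels == group_b, drop = FALSE]
  na <- rowSums(!is.na(va))
  nb <- rowSums(!is.na(vb))
  ok <- na >= 2L & nb >= 2L
  if (any(!ok)) {
    message(sum(!ok), " gene(s) dropped: fewer than 2 observed values in a group")
  }
  va <- va[ok, , drop = FALSE]; vb <- vb[ok, , drop = FALSE]
  na <- na[ok]; nb <- nb[ok]
  ma <- rowMeans(va, na.rm = TRUE)
  mb <- rowMeans(vb, na.rm = TRUE)
  ssa <- rowSums((va - ma)^2, na.rm = TRUE)
  ssb <- rowSums((vb - mb)^2, na.rm = TRUE)
  df <- na + nb - 2
  s2 <- (ssa + ssb) / df
  se <- sqrt(s2 * (1 / na + 1 / nb))
  logfc <- mb - ma
  tstat <- logfc / se
  p <- 2 * pt(-abs(tstat), df)
  zero_var <- se == 0
  if (any(zero_var)) {
    p[zero_var & logfc == 0] <- 1
    if (any(zero_var & logfc != 0)) {
      warning(sum(zero_var & logfc != 0),
              " gene(s) with zero pooled variance but nonzero logFC; ",
              "p reported as the smallest representable value", call. = FALSE)
      p[zero_var & logfc != 0] <- .Machine$double.xmin
    }
  }
  new_de_result(rownames(ds$values)[ok], logfc, p)
}

#' One-way multi-group differential expression
#'
#' Classic equal-variance one-way ANOVA F-test across all labels of a
#' factor; the reported `logFC` is the log2 range of group means (largest
#' minus smallest).
#'
#' @inheritParams differential_expression
#' @return A `de_result` data frame (see [differential_expression()]).
#' @export
differential_expression_multi <- function(ds, factor_name) {
  stopifnot(inherits(ds, "expression_dataset"))
  labels <- get_factor(ds, factor_name)
  groups <- unique(labels)
  if (length(groups) < 2L) stop("factor has fewer than 2 groups", call. = FALSE)
  if (any(table(labels) < 2L)) stop("every group needs at least 2 samples", call. = FALSE)
  v <- ds$values
  ok <- rep(TRUE, nrow(v))
  gm <- matrix(NA_real_, nrow(v), length(groups))
  ssw <- numeric(nrow(v)); nobs <- numeric(nrow(v))
  ssb <- numeric(nrow(v))
  for (j in seq_along(groups)) {
    vg <- v[, labels == groups[j], drop = FALSE]
    ng <- rowSums(!is.na(vg))
    ok <- ok & ng >= 2L
    gm[, j] <- rowMeans(vg, na.rm = TRUE)
    ssw <- ssw + rowSums((vg - gm[, j])^2, na.rm = TRUE)
    nobs <- nobs + ng
  }
  if (any(!ok)) message(sum(!ok), " gene(s) dropped: fewer than 2 observed values in a group")
  grand <- rowSums(v, na.rm = TRUE) / nobs
  for (j in seq_along(groups)) {
    ng <- rowSums(!is.na(v[, labels == groups[j], drop = FALSE]))
    ssb <- ssb + ng * (gm[, j] - grand)^2
  }
  df1 <- length(groups) - 1L
  df2 <- nobs - length(groups)
  fstat <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  p[ssw == 0 & ssb == 0] <- 1
  logfc <- apply(gm, 1L, max) - apply(gm, 1L, min)
  new_de_result(rownames(v)[ok], logfc[ok], p[ok])
}

get_factor <- function(ds, factor_name) {
  if (is.null(factor_name)) factor_name <- names(ds$factors)[1L]
  if (!factor_name %in% names(ds$factors)) {
    stop(sprintf("unknown factor '%s' (available: %s)", factor_name,
                 paste(names(ds$factors), collapse = ", ")), call. = FALSE)
  }
  ds$factors[[factor_name]]
}

new_de_result <- function(gene, logfc, p) {
  res <- data.frame(gene = gene, logFC = unname(logfc), p_value = unname(p),
                    p_adjusted = unname(p.adjust(p, method = "BH")),
                    stringsAsFactors = FALSE)
  res <- res[order(res$p_value, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("de_result", "data.frame")
  res
}

#' Select seed genes by combined p-value and fold-change cutoffs
#'
#' @param de A `de_result`.
#' @param p_cutoff Significance threshold on the chosen p-value.
#' @param fc_cutoff Nonnegative threshold on |logFC|.
#' @param use_adjusted Use the BH-adjusted p-value (default) rather than the
#'   raw one.
#' @return A single-dataset `seed_set`: named numeric vector of signed logFC
#'   values wrapped with a mode flag.
#' @export
select_seeds <- function(de, p_cutoff = 0.05, fc_cutoff = 1, use_adjusted = TRUE) {
  stopifnot(is.finite(p_cutoff), is.finite(fc_cutoff), fc_cutoff >= 0)
  p <- if (use_adjusted) de$p_adjusted else de$p_value
  keep <- p <= p_cutoff & abs(de$logFC) >= fc_cutoff
  if (!any(keep)) warning("no genes pass the cutoffs; seed set is empty", call. = FALSE)
  new_seed_set(setNames(de$logFC[keep], de$gene[keep]), mode = "single")
}

new_seed_set <- function(values, mode = c("single", "multi")) {
  mode <- match.arg(mode)
  structure(list(values = values, mode = mode), class = "seed_set")
}

#' Build a seed set directly from a gene list
#'
#' For gene/protein-list uploads without expression data: optional fold
#' changes default to 0.
#'
#' @param genes Character vector of gene IDs.
#' @param fc Optional numeric fold changes, recycled to `length(genes)`.
#' @return A single-dataset `seed_set`.
#' @export
seed_set_from_list <- function(genes, fc = 0) {
  new_seed_set(setNames(rep_len(as.numeric(fc), length(genes)),
                        trimws(genes)), mode = "single")
}

#' Read a gene/protein list file into a seed set
#'
#' Tab-delimited, one gene per row, optional second column of fold changes;
#' `#` comment lines skipped.
#'
#' @param path Path to the list file.
#' @return A single-dataset `seed_set`.
#' @export
read_seed_list <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  if (!any(keep)) stop("empty gene list: '", path, "'", call. = FALSE)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  genes <- vapply(fields, function(f) trimws(f[[1L]]), "")
  fc <- vapply(fields, function(f) {
    if (length(f) >= 2L) suppressWarnings(as.numeric(trimws(f[[2L]]))) else 0
  }, 0.0)
  fc[is.na(fc)] <- 0
  new_seed_set(setNames(fc, genes), mode = "single")
}

#' Merge seed sets from multiple datasets
#'
#' In meta-analysis mode each gene's value becomes the number of datasets in
#' which it was identified as significant.
#'
#' @param sets List of at least two single-dataset `seed_set`s.
#' @return A multi-dataset `seed_set` whose values are significance counts.
#' @export
merge_seed_sets <- function(sets) {
  stopifnot(length(sets) >= 2L,
            all(vapply(sets, inherits, TRUE, "seed_set")))
  counts <- table(unlist(lapply(sets, function(s) unique(names(s$values)))))
  new_seed_set(setNames(as.numeric(counts), names(counts)), mode = "multi")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("Seed set (%s mode): %d genes\n", x$mode, length(x$values)))
  invisible(x)
}
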