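# Expression upload handling: the #CLASS-annotated tab-delimited matrix format
# (genes/probes in rows, samples in columns, one factor per #CLASS row),
# probe-to-gene collapsing, and log2 / log2-CPM normalization.

#' Parse a #CLASS-annotated expression matrix
#'
#' Reads a tab-delimited expression file with features in rows and samples in
#' columns. Every row starting `#CLASS` defines one experimental factor:
#' `#CLASS:disease` names the factor `disease`; a bare `#CLASS` row is named
#' `CLASS`. An optional header row of sample names is auto-detected (all
#' non-numeric fields). Empty or `NA` cells are recorded as missing; any other
#' non-numeric body cell is an error. `.zip` uploads are decompressed first.
#'
#' @param path Path to the text file (or a `.zip` containing one).
#' @param data_kind `"intensity"` (microarray-style, possibly already on log
#'   scale) or `"counts"` (RNA-seq read counts, nonnegative).
#' @return An `expression_dataset`: list with `values` (numeric matrix,
#'   features x samples), `factors` (named list of per-sample label vectors)
#'   and `data_kind`.
#' @export
parse_expression <- function(path, data_kind = c("intensity", "counts")) {
  data_kind <- match.arg(data_kind)
  if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    exdir <- tempfile("unzipped")
    files <- unzip(path, exdir = exdir)
    if (length(files) == 0L) stop("empty zip archive: '", path, "'", call. = FALSE)
    path <- files[1L]
  }
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  is_class <- startsWith(lines, "#CLASS")
  is_comment <- startsWith(lines, "#") & !is_class
  class_idx <- intersect(nonblank, which(is_class))
  body_idx <- setdiff(nonblank, which(is_class | is_comment))
  if (length(class_idx) == 0L) {
    stop("no #CLASS row found: class labels must be given in a row starting '#CLASS'",
         call. = FALSE)
  }
  if (length(body_idx) == 0L) stop("no data rows found in '", path, "'", call. = FALSE)

  split_row <- function(i) trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1L]])

  first <- split_row(body_idx[1L])
  vals <- suppressWarnings(as.numeric(first[-1L]))
  has_header <- length(first) > 1L && all(is.na(vals)) && all(nzchar(first[-1L]))
  if (has_header) {
    sample_ids <- first[-1L]
    body_idx <- body_idx[-1L]
    if (length(body_idx) == 0L) stop("no data rows found in '", path, "'", call. = FALSE)
  } else {
    sample_ids <- NULL
  }
  n_samples <- if (has_header) length(sample_ids) else length(first) - 1L
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n_samples))

  factors <- list()
  for (i in class_idx) {
    f <- split_row(i)
    nm <- sub("^#CLASS:?", "", f[1L])
    if (!nzchar(nm)) nm <- "CLASS"
    labels <- f[-1L]
    if (length(labels) != n_samples) {
      stop(sprintf("line %d: #CLASS row has %d labels for %d samples",
                   i, length(labels), n_samples), call. = FALSE)
    }
    factors[[length(factors) + 1L]] <- labels
    names(factors)[length(factors)] <- nm
  }
  names(factors) <- make.unique(names(factors))

  feature_ids <- character(length(body_idx))
  values <- matrix(NA_real_, length(body_idx), n_samples,
                   dimnames = list(NULL, sample_ids))
  for (j in seq_along(body_idx)) {
    i <- body_idx[j]
    f <- split_row(i)
    if (length(f) != n_samples + 1L) {
      stop(sprintf("line %d: %d fields where %d expected", i, length(f),
                   n_samples + 1L), call. = FALSE)
    }
    feature_ids[j] <- f[1L]
    cells <- f[-1L]
    missing <- !nzchar(cells) | cells == "NA"
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(num) & !missing)
    if (length(bad) > 0L) {
      stop(sprintf("line %d: non-numeric value '%s' in sample column %d",
                   i, cells[bad[1L]], bad[1L]), call. = FALSE)
    }
    values[j, ] <- num
  }
  rownames(values) <- feature_ids
  if (data_kind == "counts" && any(values < 0, na.rm = TRUE)) {
    stop("count data must be nonnegative", call. = FALSE)
  }
  new_expression_dataset(values, factors, data_kind)
}

new_expression_dataset <- function(values, factors, data_kind) {
  stopifnot(all(lengths(factors) == ncol(values)))
  structure(list(values = values, factors = factors, data_kind = data_kind),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset: %d features x %d samples (%s), factors: %s\n",
              nrow(x$values), ncol(x$values), x$data_kind,
              paste(names(x$factors), collapse = ", ")))
  invisible(x)
}

#' Write an expression dataset in the #CLASS text format
#'
#' @param ds An `expression_dataset`.
#' @param path Output path.
#' @return `ds`, invisibly.
#' @export
write_expression <- function(ds, path) {
  stopifnot(inherits(ds, "expression_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("NAME", colnames(ds$values)), collapse = "\t"), con)
  for (nm in names(ds$factors)) {
    writeLines(paste(c(paste0("#CLASS:", nm), ds$factors[[nm]]), collapse = "\t"),
               con)
  }
  body <- apply(ds$values, 1L, function(v)
    paste(ifelse(is.na(v), "NA", sprintf("%.15g", v)), collapse = "\t"))
  writeLines(paste(rownames(ds$values), body, sep = "\t"), con)
  invisible(ds)
}

#' Collapse probes to genes by averaging
#'
#' Maps row feature IDs to canonical gene IDs through the interactome's ID
#' map; rows mapping to the same gene are replaced by their per-sample
#' arithmetic mean ("average of combined probes"). Unmapped rows are dropped
#' with a logged count.
#'
#' @param ds An `expression_dataset`.
#' @param db An `interaction_db` providing the ID map.
#' @return An `expression_dataset` with one row per canonical gene.
#' @export
collapse_probes <- function(ds, db) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(db, "interaction_db"))
  gene <- unname(db$id_map[rownames(ds$values)])
  keep <- !is.na(gene)
  if (!any(keep)) stop("no feature IDs map to the interactome", call. = FALSE)
  if (any(!keep)) message(sum(!keep), " unmapped feature row(s) dropped")
  v <- ds$values[keep, , drop = FALSE]
  gene <- gene[keep]
  obs <- !is.na(v)
  v0 <- ifelse(obs, v, 0)
  sums <- rowsum(v0, gene)
  counts <- rowsum(obs + 0, gene)
  means <- sums / counts           # NaN where a gene has no observed value
  means[counts == 0] <- NA_real_
  new_expression_dataset(means, ds$factors, ds$data_kind)
}

#' Normalize expression values to the log2 scale
#'
#' Intensity data are log2-transformed unless they already look log-scaled
#' (maximum value below 30; override with `force_log = TRUE`). Count data are
#' converted to log2 counts per million:
#' `log2((count + 0.5) / (library_size + 1) * 1e6)` with the library size
#' taken as the column sum.
#'
#' @param ds An `expression_dataset`.
#' @param force_log Log2-transform intensity data even when the
#'   already-logged heuristic fires.
#' @return An `expression_dataset` on the log2 scale (`data_kind` set to
#'   `"intensity"`).
#' @export
normalize_expression <- function(ds, force_log = FALSE) {
  stopifnot(inherits(ds, "expression_dataset"))
  v <- ds$values
  if (ds$data_kind == "counts") {
    lib <- colSums(v, na.rm = TRUE)
    v <- log2(sweep(v + 0.5, 2L, lib + 1, "/") * 1e6)
  } else {
    if (!force_log && max(v, na.rm = TRUE) < 30) {
      message("intensity data appear already log-scaled (max < 30); not re-transforming")
    } else {
      bad <- which(v <= 0, arr.ind = TRUE)
      if (nrow(bad) > 0L) {
        rn <- if (is.null(rownames(v))) as.character(seq_len(nrow(v))) else rownames(v)
        cn <- if (is.null(colnames(v))) as.character(seq_len(ncol(v))) else colnames(v)
        n_bad <- nrow(bad)
        bad <- bad[seq_len(min(n_bad, 5L)), , drop = FALSE]
        cells <- sprintf("%s/%s", rn[bad[, 1L]], cn[bad[, 2L]])
        stop("cannot log2-transform nonpositive intensities (", n_bad,
             " cell(s), e.g. ", paste(cells, collapse = ", "), ")", call. = FALSE)
      }
      v <- log2(v)
    }
  }
  new_expression_dataset(v, ds$factors, "intensity")
}
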