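#' Expression matrix container
#'
#' A genes-by-samples matrix of log2 expression ratios (M-values) relative to
#' a reference, with an optional matched matrix of p-values and a mask of
#' originally-missing cells. This is the substrate for signature extraction,
#' mode removal and enrichment selection; genes are rows, samples are columns,
#' and both must carry unique identifiers.
#'
#' @param values numeric matrix (genes x samples) with unique rownames
#'   (gene ids) and colnames (sample ids). `NA` entries mark missing data.
#' @param pvalues optional numeric matrix of the same shape and dimnames,
#'   entries in `[0, 1]`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `pvalues` (or `NULL`) and `missing_mask` (logical matrix).
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' em <- expression_matrix(m)
#' dim(em$values)
#' @export
expression_matrix <- function(values, pvalues = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid)) {
    stop("`values` must have rownames (gene ids) and colnames (sample ids)",
         call. = FALSE)
  }
  if (anyDuplicated(gid)) {
    stop("duplicate gene id: ", gid[duplicated(gid)][1], call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample id: ", sid[duplicated(sid)][1], call. = FALSE)
  }
  if (!is.null(pvalues)) {
    if (!is.matrix(pvalues) || !identical(dim(pvalues), dim(values))) {
      stop("`pvalues` must be a matrix with the same shape as `values`",
           call. = FALSE)
    }
    if (!identical(rownames(pvalues), gid) || !identical(colnames(pvalues), sid)) {
      stop("`pvalues` dimnames must match `values`", call. = FALSE)
    }
    rng <- range(pvalues, na.rm = TRUE)
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1)) {
      stop("p-values must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(values = values, pvalues = pvalues, missing_mask = is.na(values)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<expression_matrix> %d genes x %d samples (%d missing%s)\n",
    nrow(x$values), ncol(x$values), sum(x$missing_mask),
    if (is.null(x$pvalues)) "" else ", with p-values"
  ))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Gene and sample identifiers
#'
#' @param x an [expression_matrix] or [cycle_series].
#' @return Character vector of ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Convert an expression matrix to a long tibble
#'
#' @param x an [expression_matrix].
#' @param ... unused.
#' @return A tibble with columns `gene_id`, `sample_id`, `m_value`, and
#'   `p_value` when present.
#' @method tidy expression_matrix
#' @export
tidy.expression_matrix <- function(x, ...) {
  out <- tibble::tibble(
    gene_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    m_value = as.vector(x$values)
  )
  if (!is.null(x$pvalues)) out$p_value <- as.vector(x$pvalues)
  out
}

# -- TSV parsing ------------------------------------------------------------

# Parse the package's TSV dialect by hand so parse failures can be reported
# with line numbers and cell coordinates (readr would silently coerce).
parse_numeric_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("file ", path, " has no data rows", call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  n <- length(sample_ids)
  if (n < 1) stop("file ", path, " has no sample columns", call. = FALSE)
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  widths <- lengths(body)
  # trailing empty fields are dropped by strsplit; pad rows that end in a
  # missing cell, but flag genuinely ragged rows
  bad <- which(widths > n + 1 | widths < 2)
  if (length(bad) > 0) {
    stop("ragged row at line ", bad[1] + 1, " of ", path,
         " (expected ", n + 1, " fields, found ", widths[bad[1]], ")",
         call. = FALSE)
  }
  gid <- vapply(body, `[[`, character(1), 1)
  if (anyDuplicated(gid)) {
    stop("duplicate gene id '", gid[duplicated(gid)][1], "' in ", path,
         call. = FALSE)
  }
  vals <- matrix(NA_real_, length(body), n, dimnames = list(gid, sample_ids))
  for (i in seq_along(body)) {
    cells <- body[[i]][-1]
    length(cells) <- n
    cells[is.na(cells) | cells == "" | cells == "NA"] <- NA_character_
    num <- suppressWarnings(as.numeric(cells))
    bad_cell <- which(is.na(num) & !is.na(cells))
    if (length(bad_cell) > 0) {
      stop("non-numeric value '", cells[bad_cell[1]], "' at line ", i + 1,
           ", column ", bad_cell[1] + 1, " of ", path, call. = FALSE)
    }
    vals[i, ] <- num
  }
  vals
}

format_numeric_tsv <- function(values, path) {
  txt <- matrix("NA", nrow(values), ncol(values))
  ok <- !is.na(values)
  txt[ok] <- formatC(values[ok], format = "g", digits = 10)
  lines <- c(
    paste(c("gene_id", colnames(values)), collapse = "\t"),
    paste(rownames(values), apply(txt, 1, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene ids and whose
#' header row holds sample ids; empty cells or `NA` denote missing values.
#' An optional second file of the same shape supplies per-cell p-values.
#'
#' @param path path to the M-value TSV.
#' @param pvalue_path optional path to a matching p-value TSV.
#' @return An [expression_matrix].
#' @export
read_expression_matrix <- function(path, pvalue_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vals <- parse_numeric_tsv(path)
  pv <- NULL
  if (!is.null(pvalue_path)) {
    if (!file.exists(pvalue_path)) {
      stop("file not found: ", pvalue_path, call. = FALSE)
    }
    pv <- parse_numeric_tsv(pvalue_path)
    if (!identical(dim(pv), dim(vals)) ||
        !identical(dimnames(pv), dimnames(vals))) {
      stop("p-value matrix in ", pvalue_path,
           " does not match the expression matrix ids/shape", call. = FALSE)
    }
  }
  expression_matrix(vals, pvalues = pv)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: values are written with 10
#' significant digits (round-trip accurate to well under 1e-6) and missing
#' cells as `NA`. P-values, when present, go to `pvalue_path`.
#'
#' @param m an [expression_matrix].
#' @param path output TSV path.
#' @param pvalue_path optional output path for the p-value matrix.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, pvalue_path = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  format_numeric_tsv(m$values, path)
  if (!is.null(pvalue_path) && !is.null(m$pvalues)) {
    format_numeric_tsv(m$pvalues, pvalue_path)
  }
  invisible(path)
}

# -- KNN imputation ---------------------------------------------------------

#' Impute missing values by k-nearest-neighbour averaging
#'
#' For each gene (row) with missing entries, the k nearest genes are found by
#' root-mean-square difference over the columns observed in both rows, and
#' each hole is filled with the mean of the values those neighbours carry in
#' that column. Only genes observed in the target column qualify as
#' neighbours for it; if fewer than `k` qualify, the column mean of the
#' observed values is used instead (with a warning). Observed entries are
#' never altered.
#'
#' @param values numeric matrix with `NA` holes; every row must have at least
#'   one observed value.
#' @param k neighbour count (default 10).
#' @return The matrix with all `NA` entries filled.
#' @export
impute_missing <- function(values, k = 10) {
  stopifnot(is.matrix(values), is.numeric(values), k >= 1)
  if (!anyNA(values)) return(values)
  obs <- !is.na(values)
  if (any(rowSums(obs) == 0)) {
    stop("row(s) entirely missing: ",
         paste(head(which(rowSums(obs) == 0), 3), collapse = ", "),
         call. = FALSE)
  }
  out <- values
  holes <- which(rowSums(!obs) > 0)
  fallback_used <- FALSE
  for (i in holes) {
    # RMS distance to every other row over co-observed columns
    d <- rep(Inf, nrow(values))
    for (j in seq_len(nrow(values))) {
      if (j == i) next
      co <- obs[i, ] & obs[j, ]
      if (!any(co)) next
      d[j] <- sqrt(mean((values[i, co] - values[j, co])^2))
    }
    for (col in which(!obs[i, ])) {
      cand <- which(is.finite(d) & obs[, col])
      if (length(cand) < k) {
        out[i, col] <- mean(values[obs[, col], col])
        fallback_used <- TRUE
      } else {
        nn <- cand[order(d[cand], cand)][seq_len(k)]
        out[i, col] <- mean(values[nn, col])
      }
    }
  }
  if (fallback_used) {
    warning("fewer than k = ", k,
            " eligible neighbours for some cells; column mean used",
            call. = FALSE)
  }
  out
}

#' Impute an expression matrix in place
#'
#' Convenience wrapper applying [impute_missing()] to the `values` slot; the
#' original missing mask is retained for provenance.
#'
#' @inheritParams impute_missing
#' @param m an [expression_matrix].
#' @return An [expression_matrix] with no missing values.
#' @export
impute_expression_matrix <- function(m, k = 10) {
  stopifnot(inherits(m, "expression_matrix"))
  mask <- m$missing_mask
  out <- expression_matrix(impute_missing(m$values, k = k), pvalues = m$pvalues)
  out$missing_mask <- mask
  out
}
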