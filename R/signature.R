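#' Extract the recurrent (slow-growth) signature of a compendium
#'
#' Computes the first singular triplet of the genes-by-samples M-value matrix
#' \eqn{M = U S V^T}. The first left-singular vector \eqn{U_1} is the
#' recurrent gene-expression signature shared across slowly growing strains;
#' the first right-singular vector \eqn{V_1} carries its per-sample loading,
#' and \eqn{s_1^2 / \sum_k s_k^2} is the fraction of total variation the mode
#' explains. The signature profile (in M-value units) is the largest-norm
#' column of the rank-1 reconstruction \eqn{M^{(1)} = s_1 U_1 V_1^T}.
#'
#' Singular vectors are sign-ambiguous; the orientation is fixed so that the
#' entry of \eqn{U_1} with the largest absolute value is positive, with
#' \eqn{V_1} and the signature profile following.
#'
#' @param m an [expression_matrix] with no missing values.
#' @param center if `TRUE`, column means are subtracted before decomposition
#'   (classical PCA). Default `FALSE`: the inputs are already log2 ratios
#'   against a common reference.
#' @return An object of class `signature_model` with elements `u1`, `v1`
#'   (named unit vectors), `s1`, `variance_fraction`, `signature_profile`,
#'   `gene_ids`, `sample_ids`, `center`, `sign_rule`.
#' @export
extract_signature <- function(m, center = FALSE) {
  stopifnot(inherits(m, "expression_matrix"))
  x <- m$values
  if (anyNA(x)) {
    stop("matrix has missing values; run impute_expression_matrix() first",
         call. = FALSE)
  }
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("need at least 2 genes and 2 samples", call. = FALSE)
  }
  if (all(x == 0)) stop("all-zero matrix has no signature", call. = FALSE)
  if (center) x <- sweep(x, 2, colMeans(x))
  sv <- svd(x)
  u1 <- sv$u[, 1]
  v1 <- sv$v[, 1]
  s1 <- sv$d[1]
  # deterministic sign: largest-|entry| of u1 positive (first index on ties)
  pivot <- which.max(abs(u1))
  if (u1[pivot] < 0) {
    u1 <- -u1
    v1 <- -v1
  }
  names(u1) <- rownames(m$values)
  names(v1) <- colnames(m$values)
  jstar <- which.max(abs(v1))
  structure(
    list(
      u1 = u1, v1 = v1, s1 = s1,
      variance_fraction = s1^2 / sum(sv$d^2),
      signature_profile = s1 * v1[[jstar]] * u1,
      gene_ids = rownames(m$values), sample_ids = colnames(m$values),
      center = center, sign_rule = "max_abs_u1_positive"
    ),
    class = "signature_model"
  )
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf(
    "<signature_model> %d genes, %d samples; s1 = %.4g, %.1f%% of variance\n",
    length(x$u1), length(x$v1), x$s1, 100 * x$variance_fraction
  ))
  invisible(x)
}

#' Fraction of total variation carried by the first mode
#'
#' @param model a `signature_model` from [extract_signature()].
#' @return \eqn{s_1^2 / \sum_k s_k^2}, in `[0, 1]`.
#' @export
variance_explained <- function(model) {
  stopifnot(inherits(model, "signature_model"))
  model$variance_fraction
}

# align the columns of an expression matrix with a model's gene ids;
# returns the submatrix over shared genes (model order)
align_genes <- function(m, model, min_shared = 1) {
  shared <- intersect(model$gene_ids, rownames(m$values))
  if (length(shared) == 0) {
    stop("no genes shared between matrix and signature model", call. = FALSE)
  }
  if (length(shared) < min_shared) {
    stop("fewer than ", min_shared, " genes shared with the signature model",
         call. = FALSE)
  }
  if (length(shared) < nrow(m$values)) {
    warning(nrow(m$values) - length(shared),
            " gene(s) absent from the signature model were dropped",
            call. = FALSE)
  }
  m$values[shared, , drop = FALSE]
}

#' Per-sample similarity to the slow-growth signature
#'
#' The inner product of each sample's expression profile with the unit gene
#' loading vector \eqn{U_1} — the projection of the profile onto the
#' normalized recurrent profile, proportional to their covariance for
#' centered data. Genes are matched by id; unmatched genes are dropped with
#' a warning.
#'
#' @param m an [expression_matrix].
#' @param model a `signature_model`.
#' @return A tibble with columns `sample_id`, `score` (log2-ratio units).
#' @export
similarity_scores <- function(m, model) {
  stopifnot(inherits(m, "expression_matrix"), inherits(model, "signature_model"))
  x <- align_genes(m, model)
  scores <- drop(crossprod(x, model$u1[rownames(x)]))
  tibble::tibble(sample_id = colnames(x), score = unname(scores))
}

#' Per-sample Pearson correlation with the signature profile
#'
#' Correlates each column of `m` with the model's signature profile over the
#' shared genes. Useful for scanning external profiles (stress time courses,
#' other compendia) for the presence of the slow-growth signature.
#'
#' @inheritParams similarity_scores
#' @return A tibble with columns `sample_id`, `r`.
#' @export
correlate_with_signature <- function(m, model) {
  stopifnot(inherits(m, "expression_matrix"), inherits(model, "signature_model"))
  x <- align_genes(m, model, min_shared = 3)
  sig <- model$signature_profile[rownames(x)]
  tibble::tibble(
    sample_id = colnames(x),
    r = unname(apply(x, 2, stats::cor, y = sig))
  )
}

#' Remove the first singular mode from a compendium
#'
#' Returns the transformed matrix \eqn{M^* = M - s_1 U_1 V_1^T}. Every column
#' of the result is orthogonal to \eqn{U_1}, and
#' \eqn{M^{(1)} + M^*} reconstructs the input exactly. P-values, which belong
#' to the original measurements, are carried through unchanged.
#'
#' @param m the [expression_matrix] the model was extracted from.
#' @param model the matching `signature_model`.
#' @return An [expression_matrix] of the same shape.
#' @export
remove_first_mode <- function(m, model) {
  stopifnot(inherits(m, "expression_matrix"), inherits(model, "signature_model"))
  if (!identical(rownames(m$values), model$gene_ids) ||
      !identical(colnames(m$values), model$sample_ids)) {
    stop("model was not extracted from this matrix (id mismatch)",
         call. = FALSE)
  }
  x <- m$values
  if (model$center) x <- sweep(x, 2, colMeans(x))
  star <- x - model$s1 * tcrossprod(model$u1, model$v1)
  dimnames(star) <- dimnames(m$values)
  expression_matrix(star, pvalues = m$pvalues)
}

#' Remove the signature from a single external profile
#'
#' Gram-Schmidt transformation: over the genes shared with the model, with
#' \eqn{U_1} re-normalized to a unit vector \eqn{\hat u} on that subset, the
#' profile is replaced by
#' \eqn{p' = p - \langle p, \hat u \rangle \hat u}, its component orthogonal
#' to the slow-growth direction. Genes absent from the model pass through
#' unchanged and are listed in the `unmatched` attribute.
#'
#' @param profile named numeric vector of M-values (names are gene ids).
#' @param model a `signature_model`.
#' @return The transformed profile (same names and order), with attribute
#'   `unmatched`.
#' @export
remove_signature_from_profile <- function(profile, model) {
  stopifnot(is.numeric(profile), !is.null(names(profile)),
            inherits(model, "signature_model"))
  shared <- intersect(names(profile), model$gene_ids)
  if (length(shared) == 0) {
    stop("no genes shared with the signature model", call. = FALSE)
  }
  if (length(shared) < 3) {
    stop("need at least 3 genes shared with the signature model", call. = FALSE)
  }
  u <- model$u1[shared]
  u <- u / sqrt(sum(u^2))
  out <- profile
  out[shared] <- profile[shared] - sum(profile[shared] * u) * u
  attr(out, "unmatched") <- setdiff(names(profile), shared)
  out
}

#' Select strains with robust expression changes
#'
#' A strain qualifies when strictly more than `min_transcripts` of its
#' transcripts change more than `fold_threshold`-fold
#' (\eqn{|M| > \log_2} fold) with p below `p_threshold`.
#'
#' @param m an [expression_matrix] carrying p-values.
#' @param fold_threshold fold-change cutoff (default 1.7).
#' @param p_threshold p-value cutoff (default 0.05).
#' @param min_transcripts strains must exceed this count (default 3, so four
#'   qualifying transcripts retain a strain).
#' @return Character vector of qualifying sample ids.
#' @export
robust_strain_filter <- function(m, fold_threshold = 1.7, p_threshold = 0.05,
                                 min_transcripts = 3) {
  stopifnot(inherits(m, "expression_matrix"))
  if (is.null(m$pvalues)) {
    stop("robust_strain_filter() needs a matrix with p-values", call. = FALSE)
  }
  hit <- abs(m$values) > log2(fold_threshold) & m$pvalues < p_threshold
  counts <- colSums(hit, na.rm = TRUE)
  colnames(m$values)[counts > min_transcripts]
}

#' Tidy a signature model
#'
#' @param x a `signature_model`.
#' @param ... unused.
#' @return A tibble of per-gene loadings (`gene_id`, `u1`,
#'   `signature_profile`).
#' @method tidy signature_model
#' @export
tidy.signature_model <- function(x, ...) {
  tibble::tibble(
    gene_id = x$gene_ids,
    u1 = unname(x$u1),
    signature_profile = unname(x$signature_profile)
  )
}

#' @rdname tidy.signature_model
#' @return `glance()`: a one-row tibble with `s1`, `variance_fraction`,
#'   `n_genes`, `n_samples`, `center`.
#' @method glance signature_model
#' @export
glance.signature_model <- function(x, ...) {
  tibble::tibble(
    s1 = x$s1,
    variance_fraction = x$variance_fraction,
    n_genes = length(x$u1),
    n_samples = length(x$v1),
    center = x$center
  )
}

#' Serialize a signature model to JSON
#'
#' @param model a `signature_model`.
#' @param path output path.
#' @return `path` invisibly (write) or a `signature_model` (read).
#' @export
write_signature_model <- function(model, path) {
  stopifnot(inherits(model, "signature_model"))
  jsonlite::write_json(
    list(
      gene_ids = model$gene_ids, u1 = unname(model$u1),
      sample_ids = model$sample_ids, v1 = unname(model$v1),
      s1 = model$s1, variance_fraction = model$variance_fraction,
      signature_profile = unname(model$signature_profile),
      center = model$center, sign_rule = model$sign_rule
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_signature_model
#' @export
read_signature_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      u1 = setNames(j$u1, j$gene_ids),
      v1 = setNames(j$v1, j$sample_ids),
      s1 = j$s1, variance_fraction = j$variance_fraction,
      signature_profile = setNames(j$signature_profile, j$gene_ids),
      gene_ids = j$gene_ids, sample_ids = j$sample_ids,
      center = j$center, sign_rule = j$sign_rule
    ),
    class = "signature_model"
  )
}
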