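#' Cell-cycle time-course container
#'
#' A genes-by-timepoints matrix of M-values (log2 expression changes relative
#' to the first timepoint) sampled along one cell cycle, e.g. an elutriation
#' synchrony experiment. Used as the dictionary of phase-specific profiles in
#' deconvolution.
#'
#' @param values numeric matrix (genes x timepoints) with unique rownames.
#' @param timepoints_min strictly increasing sampling times in minutes,
#'   starting at 0; length must equal `ncol(values)` and be at least 4.
#' @param cycle_duration_min duration of one full cycle in minutes; must be
#'   at least the last timepoint.
#' @return An object of class `cycle_series`.
#' @examples
#' vals <- matrix(rnorm(40), 4, 10,
#'                dimnames = list(paste0("g", 1:4), paste0("t", 1:10)))
#' vals[, 1] <- 0
#' cs <- cycle_series(vals, seq(0, 270, by = 30), 300)
#' @export
cycle_series <- function(values, timepoints_min, cycle_duration_min) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("`values` must have unique rownames (gene ids)", call. = FALSE)
  }
  tp <- as.numeric(timepoints_min)
  if (length(tp) != ncol(values)) {
    stop("length(timepoints_min) must equal ncol(values)", call. = FALSE)
  }
  if (length(tp) < 4) stop("need at least 4 timepoints", call. = FALSE)
  if (tp[1] != 0) stop("first timepoint must be 0", call. = FALSE)
  if (any(diff(tp) <= 0)) {
    stop("timepoints_min must be strictly increasing", call. = FALSE)
  }
  if (cycle_duration_min < tp[length(tp)] || cycle_duration_min <= 0) {
    stop("cycle_duration_min must be positive and cover the last timepoint",
         call. = FALSE)
  }
  colnames(values) <- paste0("t", tp)
  structure(
    list(values = values, timepoints_min = tp,
         cycle_duration_min = as.numeric(cycle_duration_min)),
    class = "cycle_series"
  )
}

#' @export
print.cycle_series <- function(x, ...) {
  cat(sprintf(
    "<cycle_series> %d genes x %d timepoints (0-%g min of a %g-min cycle)\n",
    nrow(x$values), length(x$timepoints_min), max(x$timepoints_min),
    x$cycle_duration_min
  ))
  invisible(x)
}

#' @method tidy cycle_series
#' @export
tidy.cycle_series <- function(x, ...) {
  tibble::tibble(
    gene_id = rep(rownames(x$values), times = ncol(x$values)),
    time_min = rep(x$timepoints_min, each = nrow(x$values)),
    m_value = as.vector(x$values)
  )
}

#' Read / write a cycle series (TSV + JSON sidecar)
#'
#' The matrix travels in the same TSV dialect as expression matrices; the
#' sampling times and cycle duration live in a JSON sidecar
#' (`{"timepoints_min": [...], "cycle_duration_min": ...}`).
#'
#' @param path TSV path.
#' @param meta_path JSON sidecar path; defaults to `path` with a `.json`
#'   extension.
#' @return A [cycle_series] (read) or `path` invisibly (write).
#' @export
read_cycle_series <- function(path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- paste0(sub("\\.tsv$", "", path), ".json")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!file.exists(meta_path)) stop("file not found: ", meta_path, call. = FALSE)
  vals <- parse_numeric_tsv(path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  cycle_series(vals, meta$timepoints_min, meta$cycle_duration_min)
}

#' @rdname read_cycle_series
#' @param series a [cycle_series] to write.
#' @export
write_cycle_series <- function(series, path, meta_path = NULL) {
  stopifnot(inherits(series, "cycle_series"))
  if (is.null(meta_path)) meta_path <- paste0(sub("\\.tsv$", "", path), ".json")
  format_numeric_tsv(series$values, path)
  jsonlite::write_json(
    list(timepoints_min = series$timepoints_min,
         cycle_duration_min = series$cycle_duration_min),
    meta_path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' Each line is `name<TAB>description<TAB>member1<TAB>member2...`; duplicate
#' members within a line are collapsed.
#'
#' @param path GMT file path.
#' @return A named list of character vectors (one per set).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(f) < 3 || length(members) == 0) {
      stop("gene set with no members at line ", i, " of ", path, call. = FALSE)
    }
    sets[[f[1]]] <- members
  }
  sets
}

#' @rdname read_gene_sets
#' @param sets named list of character vectors.
#' @export
write_gene_sets <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", unique(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
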