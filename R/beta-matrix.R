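#' Methylation matrices and related file formats
#'
#' A beta matrix is a numeric matrix with features (genes or probes) in rows
#' and samples in columns. Row and column names carry the identifiers; the
#' orientation is fixed and never auto-detected, because silent transposition
#' is a classic correctness hazard with flat omics files. Values are nominally
#' methylation beta values in [0, 1], but out-of-range values (e.g. M-values)
#' are accepted and merely counted: the heterogeneity score is scale-agnostic.
#'
#' @name beta_matrix
#' @keywords internal
NULL

.default_missing_tokens <- c("NA", "NaN", "")

#' Coerce a matrix-like object to a validated beta matrix
#'
#' @param x numeric matrix (or coercible) with feature row names and sample
#'   column names.
#' @param level either `"gene"` or `"probe"`.
#' @return a numeric matrix of class `beta_matrix` with attributes `level`
#'   and `n_out_of_range` (count of finite entries outside [0, 1]).
#' @export
as_beta_matrix <- function(x, level = c("gene", "probe")) {
  level <- match.arg(level)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("beta matrix must be numeric")
  if (nrow(x) == 0L || ncol(x) == 0L) stop("beta matrix is empty")
  if (is.null(rownames(x))) stop("beta matrix requires feature row names")
  if (is.null(colnames(x))) stop("beta matrix requires sample column names")
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup)) stop("duplicate feature identifier(s): ",
                        paste(unique(dup), collapse = ", "))
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup)) stop("duplicate sample identifier(s): ",
                        paste(unique(dup), collapse = ", "))
  n_oor <- sum(x < 0 | x > 1, na.rm = TRUE)
  structure(x, level = level, n_out_of_range = n_oor,
            class = c("beta_matrix", class(x)))
}

.guess_sep <- function(path, delimiter) {
  switch(delimiter,
         tab = "\t", comma = ",",
         auto = if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t")
}

#' Read a delimited methylation matrix
#'
#' Expects a header row of sample identifiers and a first column of feature
#' identifiers. Cells must parse as numbers or be one of the missing tokens
#' (case-insensitive). Values outside [0, 1] are accepted with a warning.
#'
#' @param path path to a TSV/CSV file.
#' @param delimiter `"auto"` (by extension, default TSV), `"tab"` or `"comma"`.
#' @param level feature level tag, `"gene"` or `"probe"`.
#' @param missing_tokens strings treated as missing values.
#' @return a [as_beta_matrix()] object.
#' @export
read_beta_matrix <- function(path, delimiter = c("auto", "tab", "comma"),
                             level = c("gene", "probe"),
                             missing_tokens = .default_missing_tokens) {
  delimiter <- match.arg(delimiter)
  level <- match.arg(level)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .guess_sep(path, delimiter)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "", na.strings = NULL,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty matrix in ", path)
  feature_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  is_missing <- matrix(trimws(toupper(cells)) %in%
                         unique(toupper(missing_tokens)),
                       nrow = nrow(cells))
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(vals) & !is_missing, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell '%s' at row %d (feature %s), column %d (sample %s)",
                 cells[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
                 feature_ids[bad[1L, 1L]], bad[1L, 2L],
                 sample_ids[bad[1L, 2L]]))
  }
  vals[is_missing] <- NA_real_
  dimnames(vals) <- list(feature_ids, sample_ids)
  out <- as_beta_matrix(vals, level = level)
  if (attr(out, "n_out_of_range") > 0L)
    warning(attr(out, "n_out_of_range"),
            " non-missing value(s) outside [0, 1]; accepted (M-values?)")
  out
}

#' Write a beta matrix as delimited text
#'
#' Values are written with 17 significant digits so that a read/write round
#' trip reproduces doubles exactly.
#'
#' @param x matrix with feature row names and sample column names.
#' @param path output path; `.csv` extension selects comma separation.
#' @export
write_beta_matrix <- function(x, path) {
  x <- as.matrix(x)
  if (nrow(x) == 0L || ncol(x) == 0L) stop("refusing to write an empty matrix")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  .write_numeric_table(x, path, sep, id_header = "feature_id")
}

.fmt_num <- function(v) {
  out <- sprintf("%.17g", v)
  out[is.na(v)] <- "NA"
  out
}

.write_numeric_table <- function(x, path, sep = "\t", id_header = "id") {
  body <- apply(x, 2L, .fmt_num)
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(x))
  lines <- c(paste(c(id_header, colnames(x)), collapse = sep),
             vapply(seq_len(nrow(x)), function(i)
               paste(c(rownames(x)[i], body[i, ]), collapse = sep),
               character(1L)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a probe-to-gene manifest
#'
#' Two-column delimited text (`probe_id`, `gene_id`), one row per
#' probe-to-gene pair. A probe may map to several genes and a gene may
#' receive several probes; probes with no mapping simply do not appear.
#'
#' @param path path to the manifest file.
#' @param delimiter as for [read_beta_matrix()].
#' @return data.frame with columns `probe_id`, `gene_id`.
#' @export
read_probe_manifest <- function(path, delimiter = c("auto", "tab", "comma")) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .guess_sep(path, delimiter)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("manifest needs columns probe_id and gene_id")
  names(df)[1:2] <- c("probe_id", "gene_id")
  df[, 1:2]
}

#' Aggregate a probe-level matrix to gene level
#'
#' Each gene's value in a sample is the unweighted mean of the non-missing
#' values of the probes mapped to it; if every mapped probe is missing, the
#' gene value is missing. Probes mapping to multiple genes contribute to each
#' target; unmapped probes are dropped. Gene rows appear in first-appearance
#' order of the manifest, restricted to genes with at least one probe in the
#' matrix.
#'
#' @param probes a probe-level beta matrix.
#' @param manifest data.frame with columns `probe_id`, `gene_id`
#'   (see [read_probe_manifest()]).
#' @return a gene-level beta matrix.
#' @export
aggregate_probes_to_genes <- function(probes, manifest) {
  if (!identical(attr(probes, "level"), "probe"))
    stop("input matrix is not probe-level")
  manifest <- manifest[manifest$probe_id %in% rownames(probes), , drop = FALSE]
  if (nrow(manifest) == 0L)
    stop("no probe in the matrix maps to any gene")
  genes <- unique(manifest$gene_id)
  vals <- matrix(NA_real_, length(genes), ncol(probes),
                 dimnames = list(genes, colnames(probes)))
  split_probes <- split(manifest$probe_id, factor(manifest$gene_id, levels = genes))
  for (g in genes) {
    sub <- probes[split_probes[[g]], , drop = FALSE]
    m <- colMeans(sub, na.rm = TRUE)
    m[!is.finite(m)] <- NA_real_   # all probes missing for that sample
    vals[g, ] <- m
  }
  as_beta_matrix(vals, level = "gene")
}

#' Read gene sets in GMT format
#'
#' Each line holds a set name, a description, and one or more member genes,
#' tab-separated. Duplicate members within a set are removed with a warning.
#'
#' @param path path to a `.gmt` file.
#' @return object of class `gene_set_collection`: a named list of unique
#'   member vectors, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list(); descs <- character(); n_dup <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 member",
                   i, length(f)))
    nm <- f[1L]
    if (nm %in% names(sets)) stop("duplicate gene set name: ", nm)
    members <- f[-(1:2)]
    n_dup <- n_dup + sum(duplicated(members))
    sets[[nm]] <- unique(members)
    descs[nm] <- f[2L]
  }
  if (n_dup > 0L)
    warning(n_dup, " duplicate member(s) removed within gene set(s)")
  structure(sets, descriptions = descs, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene set collection:", length(x), "set(s)\n")
  sizes <- lengths(x)
  for (nm in utils::head(names(x), 10L))
    cat(sprintf("  %s (%d genes)\n", nm, sizes[[nm]]))
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Read a sample annotation table
#'
#' Delimited text with a mandatory `sample_id` column. If an `event` column
#' is present a `time` column must be too; events must be 0 (censored) or 1,
#' times non-negative.
#'
#' @param path path to the annotation file.
#' @param delimiter as for [read_beta_matrix()].
#' @return a data.frame.
#' @export
read_sample_annotation <- function(path, delimiter = c("auto", "tab", "comma")) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .guess_sep(path, delimiter)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("annotation lacks a sample_id column")
  if ("event" %in% names(df)) {
    if (!"time" %in% names(df))
      stop("annotation has an event column but no time column")
    ev <- df$event[!is.na(df$event)]
    if (!all(ev %in% c(0, 1))) stop("event values must be 0 or 1")
    tm <- df$time[!is.na(df$time)]
    if (any(tm < 0)) stop("negative survival time")
  }
  df
}

#' Write per-sample or per-signature scores
#'
#' Heterogeneity results are written as a three-column table
#' (`sample_id`, `myth_score`, `n_genes_used`); enrichment matrices as
#' signatures-by-samples tables. Full double precision is preserved.
#'
#' @param x a `myth` fit or an `enrichment_matrix`.
#' @param path output path (TSV; `.csv` switches to comma).
#' @export
write_scores <- function(x, path) UseMethod("write_scores")

#' @export
write_scores.myth <- function(x, path) {
  if (!length(x$scores)) stop("refusing to write an empty result")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- c(paste(c("sample_id", "myth_score", "n_genes_used"), collapse = sep),
             paste(names(x$scores), .fmt_num(x$scores),
                   x$n_genes_used, sep = sep))
  writeLines(lines, path)
  invisible(path)
}

#' @export
write_scores.enrichment_matrix <- function(x, path) {
  if (nrow(x) == 0L || ncol(x) == 0L) stop("refusing to write an empty result")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  .write_numeric_table(unclass(x), path, sep, id_header = "signature")
  invisible(path)
}
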