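#' Expression dataset container
#'
#' The container shared by all pipeline stages: a samples-by-features matrix
#' of expression intensities together with per-sample and per-feature
#' metadata and a transform-state marker. Values are arbitrary positive units
#' before transformation and log2 units afterwards.
#'
#' @param values Numeric matrix, rows = samples, columns = features. Row and
#'   column names are taken as sample and feature identifiers when the
#'   corresponding metadata is not supplied.
#' @param sample_meta Data frame with columns `sample_id`, `diagnosis`
#'   (`"AD"`, `"CONTROL"`, or other labels) and optional `age` (years),
#'   `gender` (`"M"`/`"F"`), `cohort`, `group`. Missing optional columns are
#'   filled with `NA`.
#' @param feature_meta Data frame with columns `feature_id` and optional
#'   `gene_symbol`. Defaults to the matrix column names with no symbols.
#' @param transform_state One of `"RAW"`, `"LOG2"`, `"CORRECTED"`.
#'
#' @return An object of class `expr_dataset`.
#' @export
expr_dataset <- function(values, sample_meta, feature_meta = NULL,
                         transform_state = c("RAW", "LOG2", "CORRECTED")) {
  transform_state <- match.arg(transform_state)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix (samples x features)")
  if (is.null(rownames(values)))
    rownames(values) <- sample_meta$sample_id
  if (is.null(colnames(values)))
    colnames(values) <- feature_meta$feature_id
  if (is.null(feature_meta))
    feature_meta <- data.frame(feature_id = colnames(values),
                               gene_symbol = NA_character_,
                               stringsAsFactors = FALSE)
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  feature_meta <- as.data.frame(feature_meta, stringsAsFactors = FALSE)
  sample_meta$age <- if (is.null(sample_meta$age)) NA_real_ else
    as.numeric(sample_meta$age)
  for (col in c("gender", "cohort", "group"))
    if (is.null(sample_meta[[col]])) sample_meta[[col]] <- NA_character_
  if (is.null(feature_meta$gene_symbol)) feature_meta$gene_symbol <- NA_character_

  if (is.null(sample_meta$sample_id) || is.null(sample_meta$diagnosis))
    stopf("sample metadata requires columns `sample_id` and `diagnosis`")
  if (nrow(values) != nrow(sample_meta))
    stopf("matrix has %d samples but metadata has %d rows",
          nrow(values), nrow(sample_meta))
  if (ncol(values) != nrow(feature_meta))
    stopf("matrix has %d features but feature metadata has %d rows",
          ncol(values), nrow(feature_meta))
  dup <- sample_meta$sample_id[duplicated(sample_meta$sample_id)]
  if (length(dup)) stopf("duplicated sample id: %s", dup[1])
  dup <- feature_meta$feature_id[duplicated(feature_meta$feature_id)]
  if (length(dup)) stopf("duplicated feature id: %s", dup[1])
  if (!identical(rownames(values), as.character(sample_meta$sample_id)))
    stopf("matrix row names do not match sample metadata order")
  if (!identical(colnames(values), as.character(feature_meta$feature_id)))
    stopf("matrix column names do not match feature metadata order")
  if (transform_state == "RAW") {
    if (any(values < 0, na.rm = TRUE))
      stopf("RAW dataset contains negative values")
  } else if (any(!is.finite(values)))
    stopf("%s dataset contains non-finite values", transform_state)

  structure(list(values = values, sample_meta = sample_meta,
                 feature_meta = feature_meta,
                 transform_state = transform_state),
            class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  tab <- table(x$sample_meta$diagnosis)
  cat(sprintf("<expr_dataset> %d samples x %d features [%s]\n",
              nrow(x$values), ncol(x$values), x$transform_state))
  cat("  diagnosis:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (any(!is.na(x$sample_meta$cohort)))
    cat("  cohort(s):", paste(unique(stats::na.omit(x$sample_meta$cohort)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

subset_samples <- function(ds, idx) {
  expr_dataset(ds$values[idx, , drop = FALSE],
               ds$sample_meta[idx, , drop = FALSE],
               ds$feature_meta, ds$transform_state)
}

subset_features <- function(ds, idx) {
  expr_dataset(ds$values[, idx, drop = FALSE],
               ds$sample_meta,
               ds$feature_meta[idx, , drop = FALSE],
               ds$transform_state)
}

#' Read an expression matrix and its sample metadata
#'
#' The matrix file is tab-delimited with a header row of feature identifiers
#' and a first column of sample identifiers; the metadata file is
#' tab-delimited and keyed by `sample_id`. Samples present in the matrix but
#' absent from the metadata are an error; metadata rows without a matrix
#' sample are dropped with a warning.
#'
#' @param matrix_path,meta_path Paths to the two tab-delimited files.
#' @param feature_meta_path Optional path to a two-column probe-to-gene map
#'   applied to populate `gene_symbol`.
#' @return An [expr_dataset()] with `transform_state = "RAW"`.
#' @export
read_expression <- function(matrix_path, meta_path, feature_meta_path = NULL) {
  raw <- utils::read.delim(matrix_path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stopf("malformed matrix file: %s", matrix_path)
  sample_ids <- raw[[1L]]
  feat_ids <- colnames(raw)[-1L]
  dup <- feat_ids[duplicated(feat_ids)]
  if (length(dup)) stopf("duplicated feature id in %s: %s", matrix_path, dup[1])
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stopf("duplicated sample id in %s: %s", matrix_path, dup[1])
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num) && !all(is.na(num) == (vals %in% c("NA", "")))) {
    bad <- which(is.na(num) & !(vals %in% c("NA", "")), arr.ind = TRUE)[1, ]
    stopf("non-numeric cell at sample '%s', feature '%s': '%s'",
          sample_ids[bad[1]], feat_ids[bad[2]], vals[bad[1], bad[2]])
  }
  dimnames(num) <- list(sample_ids, feat_ids)

  meta <- utils::read.delim(meta_path, header = TRUE, stringsAsFactors = FALSE)
  if (is.null(meta$sample_id) || is.null(meta$diagnosis))
    stopf("metadata %s requires columns sample_id and diagnosis", meta_path)
  missing <- setdiff(sample_ids, meta$sample_id)
  if (length(missing))
    stopf("samples missing from metadata: %s", paste(missing, collapse = ", "))
  if (!length(intersect(sample_ids, meta$sample_id)))
    stopf("empty intersection of matrix and metadata samples")
  extra <- setdiff(meta$sample_id, sample_ids)
  if (length(extra))
    warnf("dropping %d metadata rows without matrix samples: %s",
          length(extra), paste(utils::head(extra, 5), collapse = ", "))
  meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL

  fmeta <- data.frame(feature_id = feat_ids, gene_symbol = NA_character_,
                      stringsAsFactors = FALSE)
  if (!is.null(feature_meta_path)) {
    map <- read_probe_map(feature_meta_path)
    fmeta$gene_symbol <- unname(map[fmeta$feature_id])
  }
  expr_dataset(num, meta, fmeta, "RAW")
}

#' Write an expression dataset to tab-delimited files
#'
#' Values are written with 17 significant digits so that a read/write/read
#' round trip is bit-exact.
#'
#' @param ds An [expr_dataset()].
#' @param matrix_path,meta_path Output paths.
#' @export
write_expression <- function(ds, matrix_path, meta_path) {
  stopifnot(inherits(ds, "expr_dataset"))
  m <- ds$values
  fmt <- matrix(num_c17(m), nrow = nrow(m), dimnames = dimnames(m))
  out <- cbind(sample_id = rownames(m),
               as.data.frame(fmt, check.names = FALSE, stringsAsFactors = FALSE))
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv_full(ds$sample_meta, meta_path)
  invisible(ds)
}

#' Read a gene-pool list
#'
#' One gene symbol per line; `#` starts a comment; symbols are upper-cased
#' and de-duplicated.
#'
#' @param path Path to the pool file.
#' @param source_label Free-text provenance label stored with the pool.
#' @return An object of class `gene_pool` with elements `symbols` and
#'   `source_label`.
#' @export
read_gene_pool <- function(path, source_label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  sym <- toupper(trimws(lines))
  sym <- unique(sym[nzchar(sym)])
  if (!length(sym)) stopf("gene pool %s is empty after parsing", path)
  gene_pool(sym, source_label)
}

#' @rdname read_gene_pool
#' @param symbols Character vector of gene symbols.
#' @export
gene_pool <- function(symbols, source_label = "user") {
  sym <- unique(toupper(trimws(as.character(symbols))))
  sym <- sym[nzchar(sym) & !is.na(sym)]
  if (!length(sym)) stopf("gene pool is empty")
  structure(list(symbols = sym, source_label = source_label), class = "gene_pool")
}

#' @export
print.gene_pool <- function(x, ...) {
  cat(sprintf("<gene_pool> %d symbols (%s)\n", length(x$symbols), x$source_label))
  invisible(x)
}

#' Read a two-column probe-to-gene map
#'
#' @param path Tab-delimited file, first column feature/probe id, second
#'   column gene symbol.
#' @return Named character vector mapping feature id to gene symbol.
#' @export
read_probe_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stopf("probe map %s needs two columns", path)
  stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

#' Restrict a dataset to selected diagnosis labels
#'
#' Only samples whose diagnosis is in `keep` are retained; the feature set is
#' unchanged. Following the study design, discovery and validation analyses
#' consider AD and control subjects only.
#'
#' @param ds An [expr_dataset()].
#' @param keep Character vector of diagnosis labels to retain.
#' @export
filter_diagnoses <- function(ds, keep = c("AD", "CONTROL")) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (!length(keep)) stopf("`keep` must name at least one diagnosis label")
  idx <- which(ds$sample_meta$diagnosis %in% keep)
  subset_samples(ds, idx)
}

#' Restrict a dataset's features to a knowledge gene pool
#'
#' Keeps exactly the features whose (upper-cased) gene symbol is in the pool.
#' Features with no gene symbol are dropped. Multiple probes mapping to the
#' same pooled gene are all retained as distinct features.
#'
#' @param ds An [expr_dataset()].
#' @param pool A [gene_pool()].
#' @param mapping Optional named character vector (feature id -> gene symbol)
#'   used to populate missing symbols, e.g. from [read_probe_map()].
#' @export
restrict_to_pool <- function(ds, pool, mapping = NULL) {
  stopifnot(inherits(ds, "expr_dataset"), inherits(pool, "gene_pool"))
  sym <- ds$feature_meta$gene_symbol
  if (!is.null(mapping)) {
    fill <- is.na(sym) | !nzchar(sym)
    sym[fill] <- unname(mapping[ds$feature_meta$feature_id[fill]])
  }
  keep <- !is.na(sym) & toupper(sym) %in% pool$symbols
  if (!any(keep)) stopf("pool/dataset intersection empty")
  out <- subset_features(ds, which(keep))
  out$feature_meta$gene_symbol <- sym[keep]
  out
}
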