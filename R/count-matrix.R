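#' Construct a validated count matrix
#'
#' A `count_matrix` is a genes x samples matrix of non-negative integer
#' RNA-seq read counts with unique gene identifiers as row names and unique
#' sample identifiers as column names. All pipeline stages that consume raw
#' counts (the negative-binomial exact test, the simulator, the discovery
#' driver) expect this class; the neural stage consumes a separately scaled
#' copy (see [minmax_scale()]) so that raw integer counts and \[0,1\]-scaled
#' values are never mixed.
#'
#' @param values numeric matrix of non-negative integers, genes in rows.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `colnames(values)`.
#' @return A `count_matrix` object (a base matrix with dimnames and class).
#' @examples
#' m <- count_matrix(matrix(0:5, nrow = 3,
#'                          dimnames = list(paste0("g", 1:3), c("s1", "s2"))))
#' dim(m)
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         sample_ids = colnames(values)) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("count_matrix requires gene and sample identifiers", call. = FALSE)
  }
  rownames(values) <- as.character(gene_ids)
  colnames(values) <- as.character(sample_ids)
  x <- structure(values, class = c("count_matrix", "matrix", "array"))
  validate_count_matrix(x)
}

validate_count_matrix <- function(x) {
  if (anyDuplicated(rownames(x))) {
    stop("duplicate gene ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(x) | x < 0 | x != round(x))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(x))
    stop(sprintf(
      "counts must be non-negative integers; offending cell gene '%s', sample '%s' (value %s)",
      rownames(x)[i[1]], colnames(x)[i[2]], format(x[bad[1]])), call. = FALSE)
  }
  x
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  cat(sprintf("  total counts: %s; median library size: %s\n",
              format(sum(x), big.mark = ","),
              format(stats::median(colSums(x)))))
  invisible(x)
}

#' Read a count matrix from disk
#'
#' Supported formats: `tsv`/`csv` with gene ids in the first column and a
#' header row of sample ids (genes as rows, the transcriptomics convention),
#' and `mtx` MatrixMarket coordinate triplets with companion id files
#' `<path>.genes.txt` and `<path>.samples.txt` (one id per line, rows of the
#' sparse matrix = genes).
#'
#' @param path file to read.
#' @param format one of `"tsv"`, `"csv"`, `"mtx"`; default guessed from the
#'   file extension.
#' @param transpose set `TRUE` when the file stores samples as rows.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, format = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                     stop("cannot guess format from extension of ", path,
                          call. = FALSE))
  }
  format <- match.arg(format, c("tsv", "csv", "mtx"))
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    gf <- paste0(path, ".genes.txt")
    sf <- paste0(path, ".samples.txt")
    if (!file.exists(gf) || !file.exists(sf)) {
      stop("mtx companion id files missing: expected ", gf, " and ", sf,
           call. = FALSE)
    }
    rownames(m) <- readLines(gf)
    colnames(m) <- readLines(sf)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = NA)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) &
                     !is.na(m))
      i <- arrayInd(bad[1], dim(m))
      stop(sprintf("malformed numeric cell at row '%s', column '%s': %s",
                   ids[i[1]], colnames(m)[i[2]], m[bad[1]]), call. = FALSE)
    }
    rownames(m) <- ids
  }
  if (transpose) m <- t(m)
  count_matrix(m)
}

#' Write a count matrix to disk
#'
#' Inverse of [read_count_matrix()]; `read(write(x))` is the identity for
#' every supported format.
#'
#' @param x a [count_matrix()].
#' @param path output file.
#' @param format `"tsv"`, `"csv"` or `"mtx"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, format = NULL) {
  x <- validate_count_matrix(x)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                     stop("cannot guess format from extension of ", path,
                          call. = FALSE))
  }
  format <- match.arg(format, c("tsv", "csv", "mtx"))
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(unclass(x), sparse = TRUE), path)
    writeLines(rownames(x), paste0(path, ".genes.txt"))
    writeLines(colnames(x), paste0(path, ".samples.txt"))
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- data.frame(gene_id = rownames(x), unclass(x),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read or write a binary sample label vector
#'
#' Labels are stored as a two-column TSV (`sample_id`, `label`) with label
#' 0 = normal and 1 = tumor, and represented in memory as a named integer
#' vector.
#'
#' @param path file to read or write.
#' @return `read_labels()` returns a named integer vector of 0/1.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  label_vector(df$sample_id, df$label)
}

#' @rdname read_labels
#' @param labels named 0/1 integer vector as returned by [label_vector()].
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), label = as.integer(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a binary label vector
#'
#' @param sample_ids unique sample identifiers.
#' @param label vector coercible to 0/1 (0 = normal, 1 = tumor).
#' @return Named integer vector.
#' @export
label_vector <- function(sample_ids, label) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in labels", call. = FALSE)
  }
  label <- as.integer(label)
  if (length(label) != length(sample_ids)) {
    stop("one label required per sample", call. = FALSE)
  }
  if (!all(label %in% c(0L, 1L))) {
    stop("labels must be 0 (normal) or 1 (tumor)", call. = FALSE)
  }
  stats::setNames(label, sample_ids)
}

#' Read or write a survival table
#'
#' Three-column TSV keyed by sample id: `sample_id`, `time` (non-negative
#' follow-up, days), `event` (1 = death observed, 0 = censored).
#'
#' @param path file to read or write.
#' @return `read_survival()` returns a data.frame with columns `sample_id`,
#'   `time`, `event`.
#' @export
read_survival <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  survival_table(df$sample_id, df$time, df$event)
}

#' @rdname read_survival
#' @param surv a survival table data.frame.
#' @export
write_survival <- function(surv, path) {
  utils::write.table(surv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a survival table
#'
#' @param sample_ids unique sample identifiers.
#' @param time non-negative follow-up times.
#' @param event 0/1 event indicator (1 = death observed).
#' @return data.frame with columns `sample_id`, `time`, `event`.
#' @export
survival_table <- function(sample_ids, time, event) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  time <- as.numeric(time)
  event <- as.integer(event)
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("survival times must be finite and non-negative", call. = FALSE)
  }
  if (!all(event %in% c(0L, 1L))) {
    stop("event must be 0 (censored) or 1 (death)", call. = FALSE)
  }
  data.frame(sample_id = sample_ids, time = time, event = event,
             stringsAsFactors = FALSE)
}

#' Min-max scale counts to \[0,1\] using training-partition statistics
#'
#' Each gene is mapped linearly so that its minimum and maximum over the
#' *training* samples become 0 and 1; non-training samples are transformed
#' with the same parameters and clipped into \[0,1\]. Genes constant on the
#' training partition map to 0. The decoder of the joint model reconstructs
#' inputs through a Bernoulli (binary cross-entropy) likelihood, which is
#' only meaningful for values in \[0,1\] - hence this transform sits between
#' the integer count stage and the neural stage.
#'
#' @param counts a [count_matrix()] (or plain numeric matrix with dimnames).
#' @param train_samples character vector of sample ids defining the training
#'   partition from which per-gene min/max are computed.
#' @return A `scaled_matrix`: list with `values` (genes x samples in
#'   \[0,1\]), `min`, `max` (per-gene parameters) and `train_samples`.
#' @export
minmax_scale <- function(counts, train_samples = colnames(counts)) {
  m <- unclass(as.matrix(counts))
  train_samples <- as.character(train_samples)
  if (length(train_samples) == 0) {
    stop("training partition is empty", call. = FALSE)
  }
  missing <- setdiff(train_samples, colnames(m))
  if (length(missing)) {
    stop("train samples absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tr <- m[, train_samples, drop = FALSE]
  lo <- apply(tr, 1, min)
  hi <- apply(tr, 1, max)
  scaling <- list(min = lo, max = hi, train_samples = train_samples)
  minmax_apply(scaling, m)
}

#' Apply previously computed min-max parameters
#'
#' Used to scale held-out cohorts with training-derived parameters; applying
#' the transform twice with the same parameters is not meaningful (the
#' parameters describe the count scale), so this is exposed separately from
#' [minmax_scale()].
#'
#' @param scaling a `scaled_matrix` (its parameters are reused) or a list
#'   with `min`, `max` and `train_samples`.
#' @param counts genes x samples matrix to transform.
#' @return A `scaled_matrix`.
#' @export
minmax_apply <- function(scaling, counts) {
  m <- unclass(as.matrix(counts))
  lo <- scaling$min
  hi <- scaling$max
  rng <- hi - lo
  rng[rng == 0] <- 1        # constant genes map to 0
  v <- (m - lo) / rng
  v[v < 0] <- 0
  v[v > 1] <- 1
  structure(list(values = v, min = lo, max = hi,
                 train_samples = scaling$train_samples),
            class = "scaled_matrix")
}

#' @export
print.scaled_matrix <- function(x, ...) {
  cat(sprintf("scaled_matrix: %d genes x %d samples in [0,1] (%d training samples)\n",
              nrow(x$values), ncol(x$values), length(x$train_samples)))
  invisible(x)
}
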