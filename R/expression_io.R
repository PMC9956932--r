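#' Construct an expression matrix
#'
#' Thin validating wrapper around a numeric genes x samples matrix. Gene ids
#' are the row names, sample ids the column names; both must be unique. Raw
#' scale means non-negative counts (integrality is never required, the
#' pipeline log-transforms immediately); log scale carries the base used.
#'
#' @param values numeric matrix, genes in rows (named), samples in columns
#'   (named).
#' @param scale `"raw"` for counts, `"log"` after transformation.
#' @param log_base base of the logarithm when `scale = "log"`.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `scale` and `log_base`.
#' @export
expression_matrix <- function(values, scale = c("raw", "log"),
                              log_base = NA_real_) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("`values` must carry gene ids as rownames and sample ids as colnames")
  dup <- gid[duplicated(gid)]
  if (length(dup))
    stop("format error: duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  if (anyDuplicated(sid))
    stop("format error: duplicate sample id(s)")
  if (!all(is.finite(values)))
    stop("value error: non-finite expression values present")
  if (scale == "raw" && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("value error: negative count at gene '%s', sample '%s'",
                 gid[bad[1L]], sid[bad[2L]]))
  }
  structure(list(values = values, scale = scale, log_base = log_base),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' Gene and sample identifiers of an expression matrix
#' @param x an `expr_matrix`.
#' @return Character vector of ids in matrix order.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Construct a two-strain sample design
#'
#' @param sample_id character vector of unique sample ids.
#' @param strain character vector assigning each sample to a strain; exactly
#'   two distinct labels, each with at least two samples (a sample standard
#'   deviation needs n >= 2).
#' @return An object of class `strain_design`: a data.frame with columns
#'   `sample_id` and `strain`, and attribute `strain_order` giving the two
#'   labels in order of first appearance.
#' @export
strain_design <- function(sample_id, strain) {
  sample_id <- as.character(sample_id)
  strain <- as.character(strain)
  if (length(sample_id) != length(strain))
    stop("design error: sample_id and strain lengths differ")
  if (anyDuplicated(sample_id))
    stop("design error: duplicate sample ids")
  labs <- unique(strain)
  if (length(labs) != 2L)
    stop(sprintf("design error: need exactly 2 strain labels, got %d", length(labs)))
  n_per <- table(strain)
  if (any(n_per < 2L))
    stop("design error: every strain needs at least 2 samples")
  structure(data.frame(sample_id = sample_id, strain = strain,
                       stringsAsFactors = FALSE),
            strain_order = labs, class = c("strain_design", "data.frame"))
}

#' Strain labels of a design, in fixed order
#' @param design a `strain_design`.
#' @export
strain_order <- function(design) attr(design, "strain_order")

#' Read a count matrix from TSV/CSV
#'
#' First column holds gene ids, remaining columns numeric expression values,
#' one sample per column. The delimiter is sniffed from the first line (tab
#' wins over comma) unless given explicitly.
#'
#' @param path file path.
#' @param delimiter field separator; `NULL` to auto-detect.
#' @param header logical; does the first line carry sample ids?
#' @return A raw-scale [expression_matrix()]; row and column order as in the
#'   file.
#' @export
read_counts <- function(path, delimiter = NULL, header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) delimiter <- sniff_delimiter(path)
  tab <- utils::read.table(path, sep = delimiter, header = header,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("format error: need a gene id column plus >= 1 sample column")
  gid <- tab[[1L]]
  dup <- unique(gid[duplicated(gid)])
  if (length(dup))
    stop("format error: duplicate gene id(s): ", paste(dup, collapse = ", "))
  sid <- if (header) colnames(tab)[-1L] else paste0("sample_", seq_len(ncol(tab) - 1L))
  chr <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(chr), dim = dim(chr)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf("value error: non-numeric value '%s' at gene '%s', sample '%s'",
                 chr[i, j], gid[i], sid[j]))
  }
  neg <- which(num < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    i <- neg[1L, 1L]; j <- neg[1L, 2L]
    stop(sprintf("value error: negative count '%s' at gene '%s', sample '%s'",
                 chr[i, j], gid[i], sid[j]))
  }
  dimnames(num) <- list(gid, sid)
  expression_matrix(num, scale = "raw")
}

sniff_delimiter <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Write a count matrix as TSV
#'
#' Inverse of [read_counts()]: gene ids in the first column (`gene_id`
#' header), one sample per remaining column.
#'
#' @param x an `expr_matrix`.
#' @param path output file path.
#' @param delimiter field separator.
#' @export
write_counts <- function(x, path, delimiter = "\t") {
  tab <- data.frame(gene_id = gene_ids(x), x$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a two-column sample design file
#'
#' Two tab- or comma-separated columns: sample id, strain label. A header
#' line `sample_id<sep>strain` is recognized and skipped.
#'
#' @param path file path.
#' @return A [strain_design()].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- sniff_delimiter(path)
  first <- strsplit(readLines(path, n = 1L), delim, fixed = TRUE)[[1L]]
  has_header <- identical(tolower(trimws(first)), c("sample_id", "strain"))
  tab <- utils::read.table(path, sep = delim, header = has_header,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) != 2L) stop("design error: expected 2 columns (sample_id, strain)")
  strain_design(tab[[1L]], tab[[2L]])
}

#' Write a design file
#' @param design a `strain_design`.
#' @param path output file path.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Construct a named gene set
#' @param name label for the set (e.g. the method that produced it).
#' @param members character vector of gene ids; duplicates are dropped.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, members) {
  structure(list(name = as.character(name),
                 members = unique(as.character(members))),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> '%s': %d genes\n", x$name, length(x$members)))
  invisible(x)
}

#' Read a newline-delimited gene list
#'
#' Used to load externally published DE gene lists (e.g. from edgeR, limma,
#' DESeq2 or a t-test) for overlap reporting; those methods are never
#' recomputed here.
#'
#' @param path file path, one gene id per line.
#' @param name name for the resulting set; defaults to the file name.
#' @return A [gene_set()]; duplicates dropped with a message, empty file
#'   yields an empty set with a warning.
#' @export
read_gene_list <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  ids <- trimws(readLines(path))
  ids <- ids[nzchar(ids)]
  n_dup <- sum(duplicated(ids))
  if (n_dup > 0L)
    message(sprintf("read_gene_list: dropped %d duplicate id(s) in '%s'", n_dup, path))
  if (!length(ids))
    warning("read_gene_list: empty gene list file: ", path)
  gene_set(name, ids)
}

#' Write a differential call set as annotated TSV
#'
#' Columns `gene_id`, `batch_index`, `stage` (mean|std) and `label` (-1|-2),
#' preceded by `#key=value` comment lines recording the run parameters. Rows
#' are ordered by batch, then by gene order within the batch, so repeated
#' runs with the same configuration produce byte-identical files.
#'
#' @param calls a `de_calls` object from [run_pipeline()].
#' @param path output file path.
#' @export
write_calls <- function(calls, path) {
  params <- calls_params(calls)
  hdr <- sprintf("#%s=%s", names(params), unlist(params))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- as.data.frame(calls)[order(calls$batch_index,
                                   seq_len(nrow(calls))), , drop = FALSE]
  writeLines(paste(c("gene_id", "batch_index", "stage", "label"), collapse = "\t"), con)
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read back a call file written by [write_calls()]
#'
#' @param path file path.
#' @return A `de_calls` data.frame; the `#key=value` header is returned in
#'   attribute `params` (all values as strings).
#' @export
read_calls <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  kv <- strsplit(sub("^#", "", lines[is_hdr]), "=", fixed = TRUE)
  params <- stats::setNames(
    lapply(kv, function(p) paste(p[-1L], collapse = "=")),
    vapply(kv, `[[`, "", 1L))
  body <- lines[!is_hdr]
  df <- if (length(body) > 1L) {
    utils::read.table(text = body, sep = "\t", header = TRUE,
                      colClasses = c("character", "integer", "character", "integer"),
                      stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(), batch_index = integer(),
               stage = character(), label = integer(),
               stringsAsFactors = FALSE)
  }
  structure(df, params = params, class = c("de_calls", "data.frame"))
}

# flatten the configuration snapshot of a call set into named strings
calls_params <- function(calls) {
  cfg <- attr(calls, "config")
  if (is.null(cfg)) return(list(package = "declust"))
  p <- list(
    package = "declust",
    metric = cfg$metric$name,
    r = cfg$r,
    n_min = cfg$n_min,
    batch_size = cfg$batch_size,
    batch_order = cfg$batch_order,
    std_stage_mode = cfg$std_stage_mode,
    log_base = cfg$log_base,
    std_denominator = "n-1"
  )
  if (cfg$metric$name == "minkowski") p$minkowski_p <- cfg$metric$p
  if (cfg$metric$name == "mahalanobis") p$covariance_mode <- cfg$metric$covariance_mode
  if (cfg$std_stage_mode == "threshold") p$t_std <- cfg$t_std
  if (cfg$batch_order == "shuffle") p$shuffle_seed <- cfg$shuffle_seed
  p
}
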