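#' Expression matrix container
#'
#' A genes x samples matrix of non-negative expression values tagged with the
#' scale it lives on: `"fpkm"` for raw FPKM, `"log2p1"` after the
#' log2(FPKM + 1) transform. The tag guards scale-specific operations
#' (low-expression filtering is only defined on FPKM; the log transform can
#' only be applied once).
#'
#' @param values numeric matrix with unique rownames (gene ids) and unique
#'   colnames (sample ids); all entries finite and >= 0.
#' @param scale `"fpkm"` or `"log2p1"`.
#' @return An `ExpressionMatrix` object.
#' @export
expression_matrix <- function(values, scale = c("fpkm", "log2p1")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry gene ids as rownames and sample ids as colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) stop("duplicate gene id: ", dup[[1L]])
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup)) stop("duplicate sample id: ", dup[[1L]])
  if (any(!is.finite(values))) stop("expression values must all be finite")
  if (any(values < 0)) stop("expression values must be non-negative")
  structure(list(values = values, scale = scale), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Accessors for ExpressionMatrix
#' @param m an `ExpressionMatrix`.
#' @return `expr_values`: the numeric matrix; `gene_ids` / `sample_ids`:
#'   character vectors; `expr_scale`: the scale tag.
#' @export
expr_values <- function(m) m$values

#' @rdname expr_values
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname expr_values
#' @export
sample_ids <- function(m) colnames(m$values)

#' @rdname expr_values
#' @export
expr_scale <- function(m) m$scale

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' Parsing is locale-independent. Duplicate gene ids and negative or
#' non-numeric cells are hard errors with coordinates.
#'
#' @param path TSV file path.
#' @param scale scale tag to stamp on the result (raw files are FPKM).
#' @return An `ExpressionMatrix`.
#' @export
read_expression_matrix <- function(path, scale = "fpkm") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1L), data.table = FALSE)
  if (ncol(dt) < 2L) stop("expression TSV needs a gene id column and >= 1 sample")
  genes <- dt[[1L]]
  dup <- genes[duplicated(genes)]
  if (length(dup)) stop("duplicate gene id in ", path, ": ", dup[[1L]])
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    conv <- matrix(suppressWarnings(as.numeric(vals)), nrow(vals), ncol(vals))
    bad <- which(is.na(conv), arr.ind = TRUE)
    stop(sprintf("non-numeric cell at gene row %d, sample column %d",
                 bad[1L, 1L], bad[1L, 2L]))
  }
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)
    stop(sprintf("missing/non-numeric cell at gene row %d, sample column %d",
                 bad[1L, 1L], bad[1L, 2L]))
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)
    stop(sprintf("negative value at gene row %d, sample column %d",
                 bad[1L, 1L], bad[1L, 2L]))
  }
  rownames(vals) <- genes
  expression_matrix(vals, scale = scale)
}

#' Write an expression matrix as TSV
#'
#' Header row holds sample ids, first column (`gene_id`) the gene ids;
#' `read_expression_matrix` round-trips the values exactly.
#'
#' @param m an `ExpressionMatrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  dt <- data.table::data.table(gene_id = gene_ids(m))
  for (s in sample_ids(m)) dt[[s]] <- expr_values(m)[, s]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
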