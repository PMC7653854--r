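#' Construct a count matrix container
#'
#' Bundles an integer genes x cells count matrix with a per-cell metadata
#' table. The matrix is the unit every pipeline stage consumes; metadata
#' carries at least the donor and FACS compartment (CD38neg/CD38pos) columns
#' used by the enrichment and cell-cycle contrasts.
#'
#' @param values genes x cells matrix of non-negative integer counts
#'   (base matrix or \code{Matrix} sparse matrix) with unique row and
#'   column names.
#' @param cell_meta data.frame with one row per cell, rownames matching
#'   \code{colnames(values)}. Created empty when omitted.
#' @return An object of class \code{count_matrix} with elements
#'   \code{values} and \code{cell_meta}.
#' @export
count_matrix <- function(values, cell_meta = NULL) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("count matrix needs gene (row) and cell (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in count matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate cell ids in count matrix")
  vals <- as.matrix(values)
  if (any(vals < 0)) stop("counts must be non-negative")
  if (any(vals != round(vals))) stop("counts must be integers")
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(row.names = colnames(vals))
  } else {
    cell_meta <- as.data.frame(cell_meta)
    if (!identical(rownames(cell_meta), colnames(vals)))
      stop("cell_meta rownames must match count matrix cell ids")
  }
  structure(list(values = vals, cell_meta = cell_meta),
            class = "count_matrix")
}

#' @method print count_matrix
#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells; meta columns: %s\n",
              nrow(x$values), ncol(x$values),
              paste(names(x$cell_meta), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Construct a gene annotation table
#'
#' Internal coordinate convention is 0-based half-open (BED-like); GTF input
#' is converted on read. Biotype is restricted to \code{coding},
#' \code{lncRNA}, or \code{other}.
#'
#' @param df data.frame with columns gene_id, symbol, chrom, start, end,
#'   strand, biotype (0-based half-open start/end).
#' @return data.frame of class \code{gene_annotation}.
#' @export
gene_annotation <- function(df) {
  need <- c("gene_id", "symbol", "chrom", "start", "end", "strand", "biotype")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("annotation missing columns: ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[, need]
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in annotation")
  if (any(df$start >= df$end)) stop("annotation intervals need start < end")
  bad <- setdiff(unique(df$biotype), c("coding", "lncRNA", "other"))
  if (length(bad)) stop("unknown biotype: ", paste(bad, collapse = ", "))
  rownames(df) <- df$gene_id
  class(df) <- c("gene_annotation", "data.frame")
  df
}
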