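# Readers and writers for the plain-text formats the pipeline touches:
# MTX triplet + id files, dense TSV, GMT gene-set collections, GTF/BED
# annotation, TF-score TSV, YAML config. Readers validate and reject rather
# than coerce; every writer's output is readable by its reader.

#' Read a genes x cells count matrix
#'
#' @param path For \code{format = "tsv"}, a single TSV with gene ids in the
#'   first column and cell ids in the header. For \code{format = "mtx"}, the
#'   path of the MatrixMarket file; row ids are read from
#'   \code{<path>.genes.tsv} and column ids from \code{<path>.cells.tsv}
#'   (one id per line, optional second metadata columns for cells).
#' @param format one of \code{"mtx"}, \code{"tsv"}.
#' @param meta optional path of a cell metadata TSV (rownames in first
#'   column) attached to the result.
#' @return a \code{\link{count_matrix}}.
#' @export
read_matrix <- function(path, format = c("tsv", "mtx"), meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
    vals <- as.matrix(df)
  } else {
    m <- Matrix::readMM(path)
    gf <- paste0(path, ".genes.tsv")
    cf <- paste0(path, ".cells.tsv")
    if (!file.exists(gf) || !file.exists(cf))
      stop("MTX matrix requires companion id files ", gf, " and ", cf)
    genes <- utils::read.delim(gf, header = FALSE)[[1]]
    cells <- utils::read.delim(cf, header = FALSE)[[1]]
    if (length(genes) != nrow(m) || length(cells) != ncol(m))
      stop("id files do not match MTX dimensions")
    vals <- as.matrix(m)
    dimnames(vals) <- list(genes, cells)
  }
  if (any(vals != round(vals)))
    stop("count input contains non-integer values")
  cm <- NULL
  if (!is.null(meta)) {
    cm <- utils::read.delim(meta, row.names = 1, check.names = FALSE)
    cm <- cm[colnames(vals), , drop = FALSE]
  }
  count_matrix(vals, cm)
}

#' Write a count matrix
#'
#' @param x a \code{count_matrix} or plain matrix.
#' @param path output file path.
#' @param format \code{"tsv"} (dense, gene ids in first column) or
#'   \code{"mtx"} (MatrixMarket triplet plus id side files).
#' @return \code{path}, invisibly.
#' @export
write_matrix <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  vals <- if (inherits(x, "count_matrix")) x$values else as.matrix(x)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(vals), vals, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(methods::as(Matrix::Matrix(vals, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(rownames(vals), paste0(path, ".genes.tsv"))
    writeLines(colnames(vals), paste0(path, ".cells.tsv"))
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Wraps the standard GMT parser and validates: duplicate set names are an
#' error, duplicated members within a set are removed with a warning, empty
#' sets are rejected.
#'
#' @param path GMT file (name, description, members... per tab-separated line).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- vapply(strsplit(readLines(path), "\t"), `[`, "", 1L)
  if (anyDuplicated(first))
    stop("duplicate set names in GMT: ",
         paste(unique(first[duplicated(first)]), collapse = ", "))
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, function(s) s[nzchar(s)])
  dup <- vapply(sets, anyDuplicated, 0L) > 0
  if (any(dup)) {
    warning("duplicated members removed in sets: ",
            paste(names(sets)[dup], collapse = ", "))
    sets <- lapply(sets, unique)
  }
  if (any(lengths(sets) == 0))
    stop("empty gene sets: ",
         paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field written for every set.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene annotation from GTF or BED
#'
#' GTF gene-level records (1-based inclusive) are converted to the internal
#' 0-based half-open convention; BED is used unchanged. Biotypes are mapped
#' to \code{coding} / \code{lncRNA} / \code{other}; \code{other} records are
#' dropped with a message giving the count.
#'
#' @param path annotation file.
#' @param format \code{"gtf"} or \code{"bed"}. BED columns are
#'   chrom, start, end, gene_id, score (ignored), strand, and optionally
#'   symbol and biotype.
#' @return a \code{\link{gene_annotation}}.
#' @export
read_annotation <- function(path, format = c("gtf", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "gene"]
    if (is.null(gr$gene_id) || anyNA(gr$gene_id))
      stop("GTF gene records missing gene_id attribute")
    bt <- gr$gene_biotype
    if (is.null(bt)) stop("GTF gene records missing gene_biotype attribute")
    df <- data.frame(
      gene_id = gr$gene_id,
      symbol = if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      # GTF is 1-based inclusive; internal convention 0-based half-open
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      biotype = map_biotype(bt))
  } else {
    bed <- utils::read.delim(path, header = FALSE)
    if (ncol(bed) < 6) stop("BED needs at least 6 columns")
    df <- data.frame(
      gene_id = bed[[4]],
      symbol = if (ncol(bed) >= 7) bed[[7]] else bed[[4]],
      chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
      strand = bed[[6]],
      biotype = if (ncol(bed) >= 8) map_biotype(bed[[8]]) else "coding")
  }
  n_other <- sum(df$biotype == "other")
  if (n_other > 0)
    message(n_other, " records with biotype 'other' excluded")
  gene_annotation(df[df$biotype != "other", ])
}

map_biotype <- function(x) {
  x <- tolower(x)
  out <- rep("other", length(x))
  out[x %in% c("protein_coding", "coding", "mrna")] <- "coding"
  out[x %in% c("lncrna", "lincrna", "long_noncoding", "antisense")] <- "lncRNA"
  out
}

#' Write gene annotation as GTF
#'
#' Internal 0-based half-open coordinates are converted to GTF's 1-based
#' inclusive convention.
#'
#' @param ann a \code{\link{gene_annotation}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_annotation <- function(ann, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand)
  gr$type <- "gene"
  gr$source <- "hspcflow"
  gr$gene_id <- ann$gene_id
  gr$gene_name <- ann$symbol
  gr$gene_biotype <- ifelse(ann$biotype == "coding", "protein_coding",
                            ann$biotype)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a TFs x cells motif-accessibility score matrix
#'
#' @param path TSV with TF ids in the first column, cell ids in the header.
#' @return numeric matrix (TFs x cells).
#' @export
read_tf_scores <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (!all(is.finite(m))) stop("TF score matrix contains non-finite values")
  if (anyDuplicated(rownames(m))) stop("duplicate TF ids")
  m
}

#' @rdname read_tf_scores
#' @param x TFs x cells numeric matrix.
#' @export
write_tf_scores <- function(x, path) {
  df <- data.frame(tf = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
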