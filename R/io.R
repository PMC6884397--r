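#' Write / read a count matrix as TSV + metadata CSV
#'
#' The TSV has a `gene` column plus one integer column per sample; metadata
#' is a CSV with columns sample, condition, tissue, day.
#'
#' @param cm a [count_matrix()].
#' @param counts_tsv,meta_csv output paths.
#' @return invisibly, the paths.
#' @export
write_count_matrix <- function(cm, counts_tsv, meta_csv) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene = rownames(cm$counts), cm$counts, check.names = FALSE)
  write.table(df, counts_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(cm$sample_meta, meta_csv, row.names = FALSE)
  invisible(c(counts_tsv, meta_csv))
}

#' @rdname write_count_matrix
#' @param counts_tsv,meta_csv input paths.
#' @export
read_count_matrix <- function(counts_tsv, meta_csv) {
  df <- read.table(counts_tsv, sep = "\t", header = TRUE, check.names = FALSE)
  meta <- read.csv(meta_csv, check.names = FALSE)
  k <- as.matrix(df[, -1, drop = FALSE])
  rownames(k) <- df$gene
  count_matrix(k[, meta$sample, drop = FALSE], meta)
}

#' Read / write GMT gene-group files
#'
#' One group per line: name, description, then member gene ids, tab
#' separated.
#'
#' @param path GMT file path.
#' @return list of [gene_group()]s.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("read_gmt: line with fewer than 3 fields")
    gene_group(parts[1], parts[-(1:2)], description = parts[2])
  })
}

#' @rdname read_gmt
#' @param groups list of [gene_group()]s.
#' @export
write_gmt <- function(groups, path) {
  lines <- vapply(groups, function(g)
    paste(c(g$name, if (nzchar(g$description)) g$description else "na",
            g$members), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write / read an image stack as multi-page TIFF
#'
#' Planes are written as unsigned 16-bit (intensities on \[0, 1\] scaled to
#' 65535); masks as single-page 0/255 8-bit TIFF.
#'
#' @param stack an `image_stack` or list of matrices on the \[0, 1\] scale.
#' @param path TIFF path.
#' @return invisibly, the path.
#' @export
write_image_stack <- function(stack, path) {
  planes <- if (inherits(stack, "image_stack")) stack$planes else stack
  tiff::writeTIFF(lapply(planes, function(p) pmin(pmax(p, 0), 1)),
                  path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE)
  structure(list(planes = lapply(planes, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    as.matrix(p)
  }), channel = NA_character_, pixel_size_um = NA_real_),
  class = "image_stack")
}

#' @rdname write_image_stack
#' @param mask logical matrix.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                  path, bits.per.sample = 8)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}

#' Write a DE result table as CSV
#'
#' Columns gene, log2fc, p_raw, p_adjusted, mean_expression.
#'
#' @param res a `de_result`.
#' @param path CSV path.
#' @return invisibly, the path.
#' @export
write_de_result <- function(res, path) {
  write.csv(as.data.frame(res), path, row.names = FALSE)
  invisible(path)
}
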