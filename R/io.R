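## Deterministic TSV writer shared by all outputs: no quoting, Unix EOLs,
## full precision. A provenance hash can be stamped as a leading comment.
write_tsv <- function(df, path, hash = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (!is.null(hash)) {
    writeLines(paste0("# config_hash: ", hash), con, sep = "\n")
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a beta matrix (values, annotation, sample sheet)
#'
#' Values go to \code{<prefix>_beta.tsv} (probes x samples, header row of
#' sample ids), the probe annotation to \code{<prefix>_probes.tsv}
#' (BED-like, 0-based positions).
#'
#' @param beta a [beta_matrix()].
#' @param prefix output path prefix.
#' @return the two paths, invisibly.
#' @export
write_beta_matrix <- function(beta, prefix) {
  v <- data.frame(probe_id = beta$annot$probe_id, beta$values,
                  check.names = FALSE, stringsAsFactors = FALSE)
  p1 <- paste0(prefix, "_beta.tsv")
  p2 <- paste0(prefix, "_probes.tsv")
  write_tsv(v, p1)
  write_tsv(beta$annot, p2)
  invisible(c(p1, p2))
}

#' Read a beta matrix written by [write_beta_matrix()]
#'
#' @param prefix path prefix used when writing.
#' @return a [beta_matrix()].
#' @export
read_beta_matrix <- function(prefix) {
  v <- read_tsv(paste0(prefix, "_beta.tsv"))
  an <- read_tsv(paste0(prefix, "_probes.tsv"))
  m <- as.matrix(v[, -1, drop = FALSE])
  rownames(m) <- v$probe_id
  beta_matrix(m, an)
}

#' Write a count matrix (counts and gene annotation)
#'
#' @param counts a [count_matrix()].
#' @param prefix output path prefix (\code{_counts.tsv}, \code{_genes.tsv}).
#' @export
write_count_matrix <- function(counts, prefix) {
  v <- data.frame(gene_id = counts$annot$gene_id, counts$counts,
                  check.names = FALSE, stringsAsFactors = FALSE)
  p1 <- paste0(prefix, "_counts.tsv")
  p2 <- paste0(prefix, "_genes.tsv")
  write_tsv(v, p1)
  write_tsv(counts$annot, p2)
  invisible(c(p1, p2))
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param prefix path prefix used when writing.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(prefix) {
  v <- read_tsv(paste0(prefix, "_counts.tsv"))
  an <- read_tsv(paste0(prefix, "_genes.tsv"))
  m <- as.matrix(v[, -1, drop = FALSE])
  rownames(m) <- v$gene_id
  count_matrix(m, an)
}

#' Write sequences as FASTA
#'
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(unclass(sequences)[seq_along(sequences)])
  names(x) <- names(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write DMPs as a BED file
#'
#' BED6: chrom, start, end (0-based half-open, 1 bp per CpG), name =
#' probe_id, score = round(1000 * |delta-beta|) capped at 1000, strand ".".
#'
#' @param dmps a \code{dmp_result}.
#' @param path output file.
#' @param hash optional provenance hash comment.
#' @export
write_dmp_bed <- function(dmps, path, hash = NULL) {
  bed <- data.frame(
    chrom = dmps$chrom, start = dmps$pos, end = dmps$pos + 1L,
    name = dmps$feature_id,
    score = pmin(1000L, as.integer(round(1000 * abs(dmps$delta_beta)))),
    strand = rep(".", nrow(dmps)), stringsAsFactors = FALSE
  )
  con <- file(path, "wb")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write DMRs as BED6+ with extra columns
#'
#' chrom, start, end, name (placeholder or nearest gene), score =
#' round(1000 * max |delta-beta|) capped, strand ".", then n_cpgs,
#' region_p, direction.
#'
#' @param dmrs a \code{dmr_result}.
#' @param path output file.
#' @param names optional per-region names (default \code{"."}).
#' @param hash optional provenance hash comment.
#' @export
write_dmr_bed <- function(dmrs, path, names = NULL, hash = NULL) {
  bed <- data.frame(
    chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
    name = names %||% rep(".", nrow(dmrs)),
    score = pmin(1000L, as.integer(round(1000 * dmrs$max_abs_delta))),
    strand = rep(".", nrow(dmrs)),
    n_cpgs = dmrs$n_cpgs, region_p = dmrs$region_p,
    direction = dmrs$direction, stringsAsFactors = FALSE
  )
  con <- file(path, "wb")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write a category set as TSV with a JSON provenance column
#'
#' @param cats a \code{category_set}.
#' @param path output file.
#' @param hash optional provenance hash comment.
#' @export
write_category_tsv <- function(cats, path, hash = NULL) {
  prov <- attr(cats, "provenance")
  json <- vapply(cats$feature_id, function(f) {
    rows <- prov[prov$feature_id == f, setdiff(names(prov), "feature_id"),
                 drop = FALSE]
    as.character(jsonlite::toJSON(rows, digits = NA))
  }, character(1))
  df <- as.data.frame(cats)
  df$provenance <- unname(json)
  write_tsv(df, path, hash = hash)
}
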