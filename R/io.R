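#' Read intervals from a BED file
#'
#' BED3/6 via rtracklayer; coordinates are kept in the package's internal
#' 0-based half-open convention (identical to BED, so round-trips are
#' bit-exact).
#'
#' @param path BED file path.
#' @return data.frame \code{chrom}, \code{start}, \code{end} and, when
#'   present, \code{name}, \code{score}, \code{strand}.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  md <- as.data.frame(S4Vectors::mcols(gr))
  if ("name" %in% names(md)) out$name <- md$name
  if ("score" %in% names(md)) out$score <- md$score
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- ifelse(st == "*", ".", st)
  out
}

#' Write intervals to a BED file
#'
#' @param x data.frame with \code{chrom}, \code{start}, \code{end} and
#'   optionally \code{name}, \code{score}, \code{strand}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- data.frame(chrom = x$chrom, start = as.integer(x$start),
                     end = as.integer(x$end))
  if (!is.null(x$name)) {
    cols$name <- x$name
    cols$score <- if (is.null(x$score)) 0 else x$score
    cols$strand <- if (is.null(x$strand)) "." else x$strand
  }
  data.table::fwrite(cols, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports \code{gene} and \code{exon} records, converting the 1-based
#' inclusive GFF3 coordinates to the internal 0-based half-open convention.
#' Subgenome membership is taken from a \code{subgenome} attribute when
#' present, otherwise inferred from the first letter of the chromosome name
#' (\code{A}\* / \code{D}\*).
#'
#' @param path GFF3 file path.
#' @return list with \code{genes} (data.frame \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{subgenome},
#'   \code{is_new_gene}) and \code{exons} (data.frame \code{gene_id},
#'   \code{chrom}, \code{start}, \code{end}).
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  md <- S4Vectors::mcols(gr)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(md$type),
                   stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "."
  is_gene <- df$type == "gene"
  genes <- df[is_gene, c("chrom", "start", "end", "strand")]
  genes$gene_id <- as.character(md$ID[is_gene])
  genes$subgenome <- if (!is.null(md$subgenome)) {
    as.character(md$subgenome[is_gene])
  } else {
    substr(genes$chrom, 1, 1)
  }
  genes$is_new_gene <- if (!is.null(md$is_new_gene)) {
    as.logical(md$is_new_gene[is_gene])
  } else FALSE
  is_exon <- df$type == "exon"
  parent <- md$Parent[is_exon]
  exons <- df[is_exon, c("chrom", "start", "end")]
  exons$gene_id <- vapply(as.list(parent), function(p) as.character(p)[1],
                          character(1))
  exons <- exons[, c("gene_id", "chrom", "start", "end")]
  rownames(genes) <- rownames(exons) <- NULL
  genes <- genes[, c("gene_id", "chrom", "start", "end", "strand",
                     "subgenome", "is_new_gene")]
  list(genes = genes, exons = exons)
}

#' Write gene models as GFF3
#'
#' @param genes,exons gene model tables as returned by [read_gff3_genes()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gff3_genes <- function(genes, exons, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- sprintf("%s\tallostate\tgene\t%d\t%d\t.\t%s\t.\tID=%s;subgenome=%s;is_new_gene=%s",
               genes$chrom, as.integer(genes$start) + 1L,
               as.integer(genes$end), genes$strand,
               genes$gene_id, genes$subgenome,
               tolower(as.character(genes$is_new_gene)))
  e <- sprintf("%s\tallostate\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
               exons$chrom, as.integer(exons$start) + 1L,
               as.integer(exons$end),
               genes$strand[match(exons$gene_id, genes$gene_id)],
               exons$gene_id, seq_len(nrow(exons)), exons$gene_id)
  writeLines(c(g, e), con)
  invisible(path)
}

#' Write a normalized track as bedGraph
#'
#' @param signal normalized signal from [rpkm_normalize()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bedgraph <- function(signal, path) {
  bw <- attr(signal, "bin_width")
  layout <- attr(signal, "layout")
  parts <- lapply(layout$chrom, function(ch) {
    v <- signal[[ch]]
    start <- (seq_along(v) - 1L) * bw
    data.table::data.table(chrom = ch, start = as.integer(start),
                           end = as.integer(pmin(start + bw,
                                                 chrom_length(layout, ch))),
                           value = v)
  })
  data.table::fwrite(data.table::rbindlist(parts), path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bedGraph into a binned track-like signal
#'
#' Expects constant-width bins matching \code{bin_width} (terminal bins may
#' be short).
#'
#' @param path bedGraph path.
#' @param layout a [genome_layout()].
#' @param bin_width bin width in bases.
#' @return named list of per-chromosome numeric vectors with
#'   \code{bin_width}/\code{layout} attributes (same shape as
#'   [rpkm_normalize()] output).
#' @export
read_bedgraph <- function(path, layout, bin_width) {
  bg <- data.table::fread(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  nb <- n_bins(layout, bin_width)
  out <- lapply(layout$chrom, function(ch) numeric(nb[[ch]]))
  names(out) <- layout$chrom
  for (ch in intersect(unique(bg$chrom), layout$chrom)) {
    d <- bg[bg$chrom == ch, ]
    out[[ch]][d$start %/% bin_width + 1L] <- d$value
  }
  attr(out, "bin_width") <- as.integer(bin_width)
  attr(out, "layout") <- layout
  out
}

#' Read a fragment list from TSV/BED3
#'
#' Three columns: chrom, start, end (0-based half-open).
#'
#' @param path file path.
#' @return data.frame \code{chrom}, \code{start}, \code{end}.
#' @export
read_fragments <- function(path) {
  d <- data.table::fread(path, header = FALSE, select = 1:3,
                         col.names = c("chrom", "start", "end"))
  as.data.frame(d)
}
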