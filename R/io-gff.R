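#' Construct a gene model
#'
#' Minimal single-transcript gene model: ordered CDS segments (1-based,
#' inclusive, given in translation order, i.e. descending genomic
#' coordinates on the minus strand) whose total length must be a multiple
#' of three and include the stop codon, so that
#' `protein_length = total_cds / 3 - 1`.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome.
#' @param strand "+" or "-".
#' @param cds data.frame with columns `start`, `end` (genomic, start <= end),
#'   rows in translation order.
#' @param gene_start,gene_end optional gene feature bounds (default CDS span).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, cds,
                       gene_start = NULL, gene_end = NULL) {
  if (!strand %in% c("+", "-"))
    hd_model_error("strand must be '+' or '-'")
  cds <- data.frame(start = as.integer(cds$start), end = as.integer(cds$end))
  if (any(cds$end < cds$start))
    hd_model_error("CDS segment with end < start")
  genomic_order <- order(cds$start)
  expected <- if (strand == "+") genomic_order else rev(genomic_order)
  if (!identical(expected, seq_len(nrow(cds))))
    hd_model_error("CDS segments not in translation order for the given strand")
  starts <- sort(cds$start); ends <- sort(cds$end)
  if (nrow(cds) > 1 && any(starts[-1] <= ends[-nrow(cds)]))
    hd_model_error("overlapping CDS segments")
  total <- sum(cds$end - cds$start + 1L)
  if (total %% 3L != 0L)
    hd_model_error(sprintf("total CDS length %d is not a multiple of 3", total))
  structure(list(gene_id = gene_id, chrom = as.character(chrom),
                 strand = strand, cds = cds,
                 cds_length = total, protein_length = total %/% 3L - 1L,
                 gene_start = as.integer(gene_start %||% min(cds$start)),
                 gene_end = as.integer(gene_end %||% max(cds$end))),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d CDS segment(s), %d aa\n",
              x$gene_id, x$chrom, x$gene_start, x$gene_end, x$strand,
              nrow(x$cds), x$protein_length))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Supports a GFF3 subset with gene, mRNA and CDS features and a single
#' mRNA per gene (CDS may alternatively be parented directly to the gene).
#' CDS segments are assembled in translation order; a total CDS length not
#' divisible by three is a model error.
#'
#' @param path path to a GFF3 file.
#' @return A list of [gene_model()] objects, named by gene id.
#' @export
read_gene_model <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) hd_parse_error(
                   sprintf("%s: GFF3 parse failure: %s", path, conditionMessage(e))))
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p) == 0) NA_character_ else p[[1]], character(1))
  genes <- which(type == "gene")
  if (length(genes) == 0)
    hd_model_error(sprintf("%s: no gene features found", path))
  out <- list()
  for (gi in genes) {
    gid <- ids[gi]
    mrnas <- which(type == "mRNA" & parent == gid)
    if (length(mrnas) > 1)
      hd_model_error(sprintf("gene %s has %d mRNAs; one transcript supported",
                             gid, length(mrnas)))
    parent_id <- if (length(mrnas) == 1) ids[mrnas] else gid
    cds_rows <- which(type == "CDS" & parent == parent_id)
    if (length(cds_rows) == 0)
      hd_model_error(sprintf("gene %s has no CDS features", gid))
    strand <- as.character(BiocGenerics::strand(gr))[gi]
    if (!strand %in% c("+", "-"))
      hd_model_error(sprintf("gene %s has no stranded annotation", gid))
    st <- BiocGenerics::start(gr)[cds_rows]
    en <- BiocGenerics::end(gr)[cds_rows]
    o <- order(st)
    if (strand == "-") o <- rev(o)
    out[[gid]] <- gene_model(gid, as.character(GenomicRanges::seqnames(gr))[gi],
                             strand,
                             data.frame(start = st[o], end = en[o]),
                             gene_start = BiocGenerics::start(gr)[gi],
                             gene_end = BiocGenerics::end(gr)[gi])
  }
  out
}

#' Write gene models to a GFF3 file
#' @param models list of `gene_model` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    lines <- c(lines,
               paste(m$chrom, "hapdeficit", "gene", m$gene_start, m$gene_end,
                     ".", m$strand, ".", sprintf("ID=%s", m$gene_id),
                     sep = "\t"),
               paste(m$chrom, "hapdeficit", "mRNA", m$gene_start, m$gene_end,
                     ".", m$strand, ".",
                     sprintf("ID=%s.t1;Parent=%s", m$gene_id, m$gene_id),
                     sep = "\t"))
    cds <- m$cds[order(m$cds$start), , drop = FALSE]
    phase <- cds_phases(m)
    for (i in seq_len(nrow(cds)))
      lines <- c(lines,
                 paste(m$chrom, "hapdeficit", "CDS", cds$start[i], cds$end[i],
                       ".", m$strand, phase[i],
                       sprintf("ID=%s.cds;Parent=%s.t1", m$gene_id, m$gene_id),
                       sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

# GFF3 phase column per CDS segment, reported in genomic order.
# m$cds rows are already in translation order.
cds_phases <- function(m) {
  len <- m$cds$end - m$cds$start + 1L
  before <- c(0L, cumsum(len)[-length(len)])
  phase_tr <- (3L - before %% 3L) %% 3L
  phase_tr[order(m$cds$start)]
}

#' Read CDS sequences from a FASTA file
#' @param path FASTA path; record names must be gene ids.
#' @return Named character vector of coding-strand CDS sequences.
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write CDS sequences to a FASTA file
#' @param seqs named character vector of CDS sequences.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
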