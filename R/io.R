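# Plain-text interchange: BED genes, bedGraph tracks, TSV tables.

#' Read a BED6 gene annotation
#'
#' @param path BED file (chrom, start, end, name, score, strand).
#' @return data.frame with `chrom`, `start`, `end`, `name`, `strand`
#'   (0-based half-open).
#' @export
read_genes_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = gr$name,
             strand = as.character(GenomicRanges::strand(gr)))
}

#' Write a gene table as BED6
#' @param genes data.frame with `chrom`, `start`, `end`, `name`, `strand`.
#' @param path output BED file.
#' @export
write_genes_bed <- function(genes, path) {
  strand <- ifelse(genes$strand %in% c("+", "-"), genes$strand, "*")
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1, genes$end),
                               strand = strand)
  gr$name <- genes$name
  gr$score <- 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a bedGraph signal track
#' @param path bedGraph file.
#' @return data.frame with `chrom`, `start`, `end`, `value`.
#' @export
read_track_bedgraph <- function(path) {
  gr <- rtracklayer::import.bedGraph(path)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             value = gr$score)
}

#' Write a signal track as bedGraph
#' @param track data.frame with `chrom`, `start`, `end`, `value`.
#' @param path output file.
#' @export
write_track_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + 1, track$end),
                               score = track$value)
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}

#' Read a two-column gene signature TSV (gene, class)
#' @param path TSV with columns `gene`, `class` ("E" or "M").
#' @return an `emt_signature` list.
#' @export
read_signature_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  structure(list(epithelial = df$gene[df$class == "E"],
                 mesenchymal = df$gene[df$class == "M"]),
            class = "emt_signature")
}

#' Write a gene signature as TSV
#' @param sig an `emt_signature`.
#' @param path output file.
#' @export
write_signature_tsv <- function(sig, path) {
  df <- data.frame(gene = c(sig$epithelial, sig$mesenchymal),
                   class = rep(c("E", "M"),
                               c(length(sig$epithelial), length(sig$mesenchymal))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a full synthetic panel to a directory
#'
#' Emits, per sample: contact triplets and the chrom.sizes file, bedGraph
#' histone tracks; plus the gene BED, signature TSV, FPKM TSV, single-cell
#' contact TSV (if supplied), and a JSON ground-truth summary.
#'
#' @param panel an [simulate_panel()] result.
#' @param dir output directory (created if missing).
#' @param sc optional [simulate_single_cells()] result.
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir, sc = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- panel$gen$genome
  writeLines(paste(g$chrom_names, g$chrom_sizes, sep = "\t"),
             file.path(dir, "chrom.sizes"))
  write_genes_bed(panel$gen$genes, file.path(dir, "genes.bed"))
  write_signature_tsv(panel$gen$signature, file.path(dir, "signature.tsv"))
  utils::write.table(data.frame(gene = rownames(panel$omics$fpkm),
                                panel$omics$fpkm, check.names = FALSE),
                     file.path(dir, "fpkm.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in seq_len(panel$spec$n_samples)) {
    id <- panel$spec$sample_ids[s]
    if (!is.null(panel$sims))
      write_contact_matrix(panel$sims[[s]]$cm,
                           file.path(dir, paste0(id, ".triplets.txt")))
    for (mark in names(panel$omics$tracks[[s]]))
      write_track_bedgraph(panel$omics$tracks[[s]][[mark]],
                           file.path(dir, paste0(id, ".", mark, ".bedGraph")))
  }
  if (!is.null(sc))
    utils::write.table(sc$contacts, file.path(dir, "sc_contacts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(
    emt_scores = panel$spec$emt_scores,
    sample_ids = panel$spec$sample_ids,
    flip_genes = panel$gen$genes$name[panel$gen$genes$flip],
    n_tads = nrow(panel$gen$ref_tads$intervals)
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
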