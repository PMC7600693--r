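#' Construct an annotated genome object
#'
#' A genome is an ordered list of protein-coding genes with free-text
#' function labels, a host label and a genome size in base pairs. Gene order
#' (`order_index`, 0-based) is the order genes appear in the source FASTA
#' and is what island detection operates on.
#'
#' @param genome_id single string, unique genome identifier.
#' @param host_label single string, host group (e.g. "human", "chicken").
#' @param size_bp genome size in bases, > 0.
#' @param genes data.frame with columns `gene_id`, `function_label`,
#'   `sequence` (uppercase amino acids, alphabet ACDEFGHIKLMNPQRSTVWY plus X)
#'   and optionally `order_index` (0-based; defaults to row order).
#' @return an object of class `genome`.
#' @export
genome <- function(genome_id, host_label, size_bp, genes) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  if (!is.numeric(size_bp) || size_bp <= 0)
    stop_data("genome '%s': size_bp must be > 0", genome_id)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  req <- c("gene_id", "function_label", "sequence")
  if (!all(req %in% names(genes)))
    stop_data("genome '%s': genes need columns %s", genome_id,
              paste(req, collapse = ", "))
  if (is.null(genes$order_index)) genes$order_index <- seq_len(nrow(genes)) - 1L
  genes <- genes[order(genes$order_index), , drop = FALSE]
  rownames(genes) <- NULL
  if (anyDuplicated(genes$order_index))
    stop_data("genome '%s': duplicated order_index", genome_id)
  if (anyDuplicated(genes$gene_id))
    stop_data("genome '%s': duplicated gene_id", genome_id)
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", genes$sequence) | !nzchar(genes$sequence)
  if (any(bad))
    stop_data("genome '%s': %d gene sequence(s) empty or outside the amino-acid alphabet",
              genome_id, sum(bad))
  structure(list(genome_id = genome_id, host_label = host_label,
                 size_bp = as.numeric(size_bp), genes = genes),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s  host=%s  %.2f Mb  %d genes\n",
              x$genome_id, x$host_label, x$size_bp / 1e6, nrow(x$genes)))
  invisible(x)
}

#' Write genomes as protein FASTA plus a metadata table
#'
#' One FASTA file per genome (`<genome_id>.faa`, headers
#' `geneID|function=<label>`) and a single `genomes.tsv` with columns
#' `genome_id`, `host`, `size_bp`.
#'
#' @param genomes list of [genome()] objects.
#' @param dir output directory, created if needed.
#' @return invisibly, the metadata file path.
#' @export
write_genomes <- function(genomes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in genomes) {
    seqs <- Biostrings::AAStringSet(g$genes$sequence)
    names(seqs) <- paste0(g$genes$gene_id, "|function=", g$genes$function_label)
    Biostrings::writeXStringSet(seqs, file.path(dir, paste0(g$genome_id, ".faa")))
  }
  meta <- data.frame(
    genome_id = vapply(genomes, `[[`, "", "genome_id"),
    host = vapply(genomes, `[[`, "", "host_label"),
    size_bp = vapply(genomes, `[[`, 0, "size_bp"))
  path <- file.path(dir, "genomes.tsv")
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genomes written by [write_genomes()]
#'
#' @param dir directory containing `genomes.tsv` and one `<genome_id>.faa`
#'   protein FASTA per genome.
#' @return list of [genome()] objects, in metadata order.
#' @export
read_genomes <- function(dir) {
  meta <- read.delim(file.path(dir, "genomes.tsv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    seqs <- Biostrings::readAAStringSet(file.path(dir, paste0(meta$genome_id[i], ".faa")))
    hdr <- names(seqs)
    gene_id <- sub("\\|.*$", "", hdr)
    fl <- sub("^.*\\|function=", "", hdr)
    genome(meta$genome_id[i], meta$host[i], meta$size_bp[i],
           data.frame(gene_id = gene_id, function_label = fl,
                      sequence = as.character(seqs)))
  })
}

host_of <- function(genomes) {
  setNames(vapply(genomes, `[[`, "", "host_label"),
           vapply(genomes, `[[`, "", "genome_id"))
}
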