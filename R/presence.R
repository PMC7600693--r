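#' Classify a best-hit similarity into a presence category
#'
#' Categories follow the screening thresholds used throughout the package:
#' a reference gene is `absent` from a genome when its best-hit similarity
#' is below `absent_threshold` (default 50, i.e. unrelated), a
#' `present_recent_transfer` candidate when strictly above
#' `transfer_threshold` (default 99), and `present_divergent` otherwise.
#' The lower bound is inclusive: a similarity of exactly 50 counts as
#' present; a similarity of exactly 99 is still present_divergent.
#'
#' @param similarity numeric vector of percent similarities.
#' @param absent_threshold percent below which a gene is absent (default 50).
#' @param transfer_threshold percent strictly above which a gene is a recent
#'   horizontal-transfer candidate (default 99).
#' @return character vector of categories.
#' @export
presence_category <- function(similarity, absent_threshold = 50,
                              transfer_threshold = 99) {
  stopifnot(absent_threshold > 0, absent_threshold < transfer_threshold,
            transfer_threshold <= 100)
  ifelse(similarity < absent_threshold, "absent",
         ifelse(similarity > transfer_threshold, "present_recent_transfer",
                "present_divergent"))
}

#' Reference-anchored presence/absence matrix
#'
#' Every gene of the reference genome is compared (global alignment percent
#' identity, see [align_similarity()]) against every gene of every other
#' genome; the best hit per genome is kept. The reference's own column is
#' 100 by definition. Each cell is categorised with [presence_category()].
#'
#' @param reference a [genome()] with at least one gene.
#' @param others list of [genome()] objects (the reference may be included;
#'   it is recognised by id).
#' @param absent_threshold,transfer_threshold passed to [presence_category()].
#' @return object of class `presence_matrix`: list with `reference_genome_id`,
#'   `genes` (the reference gene table), `similarity` and `category`
#'   matrices (rows = reference genes, columns = genomes, reference first),
#'   and the thresholds used.
#' @export
build_presence_matrix <- function(reference, others,
                                  absent_threshold = 50,
                                  transfer_threshold = 99) {
  if (nrow(reference$genes) == 0L)
    stop_data("build_presence_matrix: reference genome is empty")
  others <- Filter(function(g) g$genome_id != reference$genome_id, others)
  ids <- c(reference$genome_id, vapply(others, `[[`, "", "genome_id"))
  if (anyDuplicated(ids))
    stop_data("build_presence_matrix: duplicate genome ids")
  ng <- nrow(reference$genes)
  sim <- matrix(NA_real_, ng, length(ids),
                dimnames = list(reference$genes$gene_id, ids))
  sim[, 1L] <- 100
  # pool all subject genes: one alignment call per reference gene
  pool_genome <- unlist(lapply(others, function(g)
    rep(g$genome_id, nrow(g$genes))))
  pool_seq <- unlist(lapply(others, function(g) g$genes$sequence))
  if (length(pool_seq)) {
    for (i in seq_len(ng)) {
      sims <- align_similarity(reference$genes$sequence[i], pool_seq)
      best <- tapply(sims, pool_genome, max)
      sim[i, names(best)] <- best
    }
  }
  cat_ <- presence_category(sim, absent_threshold, transfer_threshold)
  dim(cat_) <- dim(sim); dimnames(cat_) <- dimnames(sim)
  structure(list(reference_genome_id = reference$genome_id,
                 genes = reference$genes,
                 similarity = sim, category = cat_,
                 absent_threshold = absent_threshold,
                 transfer_threshold = transfer_threshold),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("<presence_matrix> reference=%s  %d genes x %d genomes (thresholds %g/%g)\n",
              x$reference_genome_id, nrow(x$similarity), ncol(x$similarity),
              x$absent_threshold, x$transfer_threshold))
  invisible(x)
}

#' Write / read a presence matrix as TSV (cells `similarity:category`)
#'
#' @param pm a `presence_matrix`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_presence_matrix <- function(pm, path) {
  cells <- matrix(paste0(formatC(pm$similarity, format = "fg", digits = 8),
                         ":", pm$category),
                  nrow = nrow(pm$similarity), dimnames = dimnames(pm$similarity))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# reference=%s absent_threshold=%g transfer_threshold=%g",
                     pm$reference_genome_id, pm$absent_threshold,
                     pm$transfer_threshold), con)
  write.table(data.frame(gene_id = rownames(cells), cells, check.names = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Contrast genome sizes between two host groups
#'
#' Reports the min-max genome size per host group and an exact two-sided
#' Mann-Whitney test (see [mann_whitney_exact()]). Host-adapted Bacteroides
#' lineages differ systematically in genome size (chicken-adapted genomes
#' are smaller), which this contrast quantifies.
#'
#' @param genomes list of [genome()] objects spanning exactly two host labels,
#'   each with >= 3 genomes.
#' @return list with `ranges` (data.frame host, n, min_bp, max_bp),
#'   `U`, `p` and `method`. `U` is computed for the alphabetically first
#'   host group.
#' @export
compare_genome_sizes <- function(genomes) {
  hosts <- vapply(genomes, `[[`, "", "host_label")
  sizes <- vapply(genomes, `[[`, 0, "size_bp")
  grp <- split(sizes, hosts)
  if (length(grp) != 2L)
    stop_data("compare_genome_sizes: exactly two host groups required, got %d",
              length(grp))
  if (any(lengths(grp) < 3L))
    stop_data("compare_genome_sizes: each host group needs >= 3 genomes")
  grp <- grp[order(names(grp))]
  mw <- mann_whitney_exact(grp[[1L]], grp[[2L]])
  ranges <- data.frame(host = names(grp), n = lengths(grp),
                       min_bp = vapply(grp, min, 0),
                       max_bp = vapply(grp, max, 0), row.names = NULL)
  list(ranges = ranges, U = mw$U, p = mw$p, method = mw$method)
}
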