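#' Per-protein expression-observation counts from a PSM table
#'
#' `n_expr` for a protein is the number of distinct (strain, condition)
#' cells in which it was detected with at least one peptide spectral match.
#' With 5 strains and 11 conditions (inoculum plus five media at two
#' subcultures) the maximum is 55 — reached only by proteins expressed by
#' every strain in every condition. Proteins never detected get
#' `n_expr = 0`, rendered as "n.e." (not expressed) in reports.
#'
#' @param table data.frame with `protein_id`, `strain`, `condition`, `psm`
#'   (nonnegative integer counts; (protein, strain, condition) unique).
#' @param proteins optional protein ids to report (defaults to those in the
#'   table); ids absent from the table get 0.
#' @return named integer vector, protein id -> n_expr.
#' @export
expression_count <- function(table, proteins = NULL) {
  check_psm(table)
  proteins <- proteins %||% unique(table$protein_id)
  det <- table[table$psm >= 1L, ]
  cells <- unique(det[, c("protein_id", "strain", "condition")])
  n <- table(factor(cells$protein_id, levels = proteins))
  setNames(as.integer(n), proteins)
}

check_psm <- function(table) {
  req <- c("protein_id", "strain", "condition", "psm")
  if (!all(req %in% names(table)))
    stop_data("PSM table needs columns %s", paste(req, collapse = ", "))
  if (any(table$psm < 0)) stop_data("PSM table: negative psm counts")
  if (anyDuplicated(table[, c("protein_id", "strain", "condition")]))
    stop_data("PSM table: duplicated (protein, strain, condition) records")
  invisible(table)
}

#' Relative protein abundance within each strain-condition
#'
#' Within every (strain, condition) cell, a protein's abundance is
#' `100 * psm / total psm` over all proteins in that cell, so abundances
#' sum to 100% per cell. The per-protein mean averages over every
#' strain-condition present in the table, counting the protein as 0 where
#' it was not detected; strain-conditions with zero total PSM are excluded
#' with a warning.
#'
#' @param table a PSM data.frame (see [expression_count()]).
#' @return list with `per_cell` (data.frame `protein_id`, `strain`,
#'   `condition`, `percent`) and `per_protein` (named numeric vector of
#'   mean percent abundance).
#' @export
relative_abundance <- function(table) {
  check_psm(table)
  cell_id <- paste(table$strain, table$condition, sep = "\r")
  totals <- tapply(table$psm, cell_id, sum)
  dead <- names(totals)[totals == 0]
  if (length(dead)) {
    warning(sprintf("relative_abundance: %d strain-condition cell(s) with zero total PSM excluded",
                    length(dead)))
    keep <- !(cell_id %in% dead)
    table <- table[keep, ]; cell_id <- cell_id[keep]
  }
  pct <- 100 * table$psm / as.numeric(totals[cell_id])
  per_cell <- data.frame(protein_id = table$protein_id,
                         strain = table$strain, condition = table$condition,
                         percent = pct)
  n_cells <- length(unique(cell_id))
  sums <- tapply(pct, table$protein_id, sum)
  per_protein <- setNames(as.numeric(sums) / n_cells, names(sums))
  list(per_cell = per_cell, per_protein = per_protein)
}

#' Expression report for a screened gene set
#'
#' Joins a screened gene list (e.g. host-specific genes) against a PSM
#' table: counts how many screen genes were expressed in at least one
#' strain-condition and tabulates each gene's `n_expr` and mean percent
#' abundance, sorted by `n_expr` then mean abundance (both descending,
#' protein id as final tie-break). `n_expr = 0` renders as "n.e.".
#'
#' @param screen_genes nonempty character vector of protein/gene ids.
#' @param table a PSM data.frame; may be empty (zero rows).
#' @return list with `n_expressed`, `n_total` and `summary` (data.frame
#'   `protein_id`, `n_expr`, `n_expr_label`, `mean_abundance_pct`).
#' @export
expressed_gene_report <- function(screen_genes, table) {
  if (!length(screen_genes)) stop_data("expressed_gene_report: empty screen gene list")
  if (nrow(table)) {
    nx <- expression_count(table, proteins = screen_genes)
    ab <- relative_abundance(table)$per_protein
  } else {
    nx <- setNames(integer(length(screen_genes)), screen_genes)
    ab <- numeric()
  }
  mean_ab <- ifelse(screen_genes %in% names(ab), ab[screen_genes], 0)
  summary <- data.frame(protein_id = screen_genes,
                        n_expr = nx[screen_genes],
                        n_expr_label = ifelse(nx[screen_genes] == 0L, "n.e.",
                                              as.character(nx[screen_genes])),
                        mean_abundance_pct = as.numeric(mean_ab))
  summary <- summary[order(-summary$n_expr, -summary$mean_abundance_pct,
                           summary$protein_id), ]
  summary$mean_abundance_pct[summary$n_expr == 0L] <- NA_real_
  rownames(summary) <- NULL
  list(n_expressed = sum(summary$n_expr >= 1L),
       n_total = length(screen_genes), summary = summary)
}

#' Published host-specific gene screen shipped with the package
#'
#' A transcription of a published screen of 29 genes found in all
#' human-adapted *Bacteroides* genomes and absent (<50% amino-acid
#' similarity) from all chicken-adapted genomes, with per-genome percent
#' similarity to the *B. dorei* An41 reference, the expression-observation
#' count (`n_expr`, max 55 = 5 strains x 11 conditions; "n.e." = not
#' expressed) and the mean percent abundance during in vitro growth.
#'
#' @return data.frame with `gene` (function label), one similarity column
#'   per genome (An41 reference first), `n_expr` (integer, NA when not
#'   expressed) and `abundance_pct` (NA when not expressed).
#' @export
host_specific_gene_table <- function() {
  path <- system.file("extdata", "human_specific_genes.tsv", package = "hostadapt")
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#")
  raw$n_expr <- suppressWarnings(as.integer(ifelse(raw$n_expr == "n.e.", NA, raw$n_expr)))
  raw$abundance_pct <- suppressWarnings(as.numeric(ifelse(raw$abundance_pct == "n.e.",
                                                          NA, raw$abundance_pct)))
  raw
}
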