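#' Screening configuration
#'
#' Thresholds and counts shared by the host-specific gene screen, the
#' horizontal-transfer candidate scan and the gene-family contrast.
#'
#' @param absent_threshold percent similarity below which a gene is absent
#'   (unrelated); inclusive presence at exactly this value. Default 50.
#' @param transfer_threshold percent similarity strictly above which genes
#'   count as recent horizontal transfer. Default 99.
#' @param min_carriers smallest carrier-genome count for a transfer
#'   candidate (default 3).
#' @param max_carriers largest carrier count; `NA` (default) means group
#'   size minus one, i.e. the gene must not be in every genome of the group.
#' @param min_family_size keep a gene family only if some genome carries at
#'   least this many members (default 10).
#' @param alpha significance level for family contrasts (default 0.05).
#' @return list of class `screen_config`.
#' @export
screen_config <- function(absent_threshold = 50, transfer_threshold = 99,
                          min_carriers = 3L, max_carriers = NA,
                          min_family_size = 10L, alpha = 0.05) {
  if (!(absent_threshold > 0 && absent_threshold < transfer_threshold &&
        transfer_threshold <= 100))
    stop_data("screen_config: need 0 < absent_threshold < transfer_threshold <= 100")
  min_carriers <- check_count(min_carriers, "min_carriers", min = 2L)
  if (!is.na(max_carriers)) {
    max_carriers <- check_count(max_carriers, "max_carriers", min = 2L)
    if (max_carriers < min_carriers)
      stop_data("screen_config: max_carriers < min_carriers")
  }
  structure(list(absent_threshold = absent_threshold,
                 transfer_threshold = transfer_threshold,
                 min_carriers = min_carriers, max_carriers = max_carriers,
                 min_family_size = check_count(min_family_size, "min_family_size", 1L),
                 alpha = alpha),
            class = "screen_config")
}

#' Host-specific genes from a presence matrix
#'
#' A reference gene is specific to the in-group host when it is present
#' (best-hit similarity >= `absent_threshold`, inclusive) in every in-group
#' genome and absent (< `absent_threshold`) from every out-group genome.
#' The reference genome must belong to the in-group.
#'
#' @param matrix a `presence_matrix` from [build_presence_matrix()].
#' @param host_labels named character vector, genome id -> host label.
#' @param in_group,out_group host labels to contrast.
#' @param config a [screen_config()].
#' @return character vector of reference gene ids, in reference gene order.
#' @export
screen_host_specific <- function(matrix, host_labels, in_group, out_group,
                                 config = screen_config()) {
  ids <- colnames(matrix$similarity)
  if (!all(ids %in% names(host_labels)))
    stop_data("screen_host_specific: host label missing for some genomes")
  hl <- host_labels[ids]
  in_ids <- ids[hl == in_group]
  out_ids <- ids[hl == out_group]
  if (!length(in_ids) || !length(out_ids))
    stop_data("screen_host_specific: host group '%s' has zero genomes",
              if (length(in_ids)) out_group else in_group)
  if (!(matrix$reference_genome_id %in% in_ids))
    stop_data("screen_host_specific: reference genome must belong to the in-group")
  thr <- config$absent_threshold
  sim <- matrix$similarity
  keep <- rowSums(sim[, in_ids, drop = FALSE] >= thr) == length(in_ids) &
    rowSums(sim[, out_ids, drop = FALSE] < thr) == length(out_ids)
  rownames(sim)[keep]
}

#' Species-specific marker genes for PCR assay design
#'
#' Target genes whose best-hit similarity in every other genome falls below
#' `absent_threshold` — genes unique to the target species, the candidates
#' from which species-specific qPCR primer pairs are designed.
#'
#' @param target a [genome()].
#' @param others nonempty list of [genome()] objects.
#' @param config a [screen_config()].
#' @return character vector of target gene ids in gene order.
#' @export
find_marker_genes <- function(target, others, config = screen_config()) {
  if (nrow(target$genes) == 0L) stop_data("find_marker_genes: empty target genome")
  if (!length(others)) stop_data("find_marker_genes: `others` must be nonempty")
  others <- Filter(function(g) g$genome_id != target$genome_id, others)
  if (!length(others)) stop_data("find_marker_genes: `others` must be nonempty")
  keep <- vapply(seq_len(nrow(target$genes)), function(i) {
    all(vapply(others, function(g) best_hit(target$genes[i, ], g)$similarity, 0) <
          config$absent_threshold)
  }, TRUE)
  target$genes$gene_id[keep]
}

#' Recent horizontal-transfer candidates within one host group
#'
#' Scans all genes of the group's genomes for near-identical copies shared
#' across genomes: genes are clustered by single linkage over pairwise
#' similarity strictly above `transfer_threshold`, and a cluster is reported
#' when its distinct carrier-genome count k satisfies
#' `min_carriers <= k <= max_carriers` (default max: group size - 1, so a
#' gene present in every genome of the group is core, not transferred).
#'
#' Candidate gene pairs are pre-screened by shared exact 12-mers before
#' alignment; two sequences above 99% identity over biologically sized
#' proteins always share such a seed, so the prefilter only prunes pairs
#' that could not pass the threshold.
#'
#' @param genomes list of [genome()] objects from a single host group.
#' @param config a [screen_config()].
#' @return data.frame with one row per candidate cluster: `candidate_id`,
#'   `representative_gene_id`, `n_carriers`, `min_pairwise_similarity`,
#'   `carrier_genome_ids` (list-column), `members` (list-column of
#'   data.frames genome_id/gene_id/order_index).
#' @export
detect_recent_transfer <- function(genomes, config = screen_config()) {
  if (length(genomes) < config$min_carriers + 1L)
    stop_data("detect_recent_transfer: need >= min_carriers + 1 genomes")
  max_carriers <- if (is.na(config$max_carriers)) length(genomes) - 1L
                  else config$max_carriers
  pool <- do.call(rbind, lapply(genomes, function(g)
    data.frame(genome_id = g$genome_id, gene_id = g$genes$gene_id,
               order_index = g$genes$order_index, sequence = g$genes$sequence)))
  n <- nrow(pool)
  pairs <- kmer_candidate_pairs(pool$sequence, pool$genome_id, k = 12L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  sims <- if (nrow(pairs))
    align_similarity_pairs(pool$sequence[pairs$i], pool$sequence[pairs$j])
  else numeric()
  hit <- sims > config$transfer_threshold
  es <- cbind(pairs$i[hit], pairs$j[hit], sims[hit])
  for (r in seq_len(nrow(es)))
    parent[find(as.integer(es[r, 1L]))] <- find(as.integer(es[r, 2L]))
  comp <- vapply(seq_len(n), find, numeric(1))
  out <- list()
  for (cid in unique(comp[duplicated(comp)])) {
    members <- which(comp == cid)
    if (length(members) < 2L) next
    carriers <- unique(pool$genome_id[members])
    k <- length(carriers)
    if (k < config$min_carriers || k > max_carriers) next
    minsim <- min(es[es[, 1L] %in% members & es[, 2L] %in% members, 3L])
    members <- members[order(pool$genome_id[members], pool$order_index[members])]
    out[[length(out) + 1L]] <- data.frame(
      candidate_id = sprintf("tc%03d", length(out) + 1L),
      representative_gene_id = pool$gene_id[members[1L]],
      n_carriers = k, min_pairwise_similarity = minsim,
      carrier_genome_ids = I(list(sort(carriers))),
      members = I(list(pool[members, c("genome_id", "gene_id", "order_index")])))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(candidate_id = character(), representative_gene_id = character(),
               n_carriers = integer(), min_pairwise_similarity = numeric(),
               carrier_genome_ids = I(list()), members = I(list()))
  rownames(res) <- NULL
  res
}

# indices of cross-genome gene pairs sharing at least one exact k-mer
kmer_candidate_pairs <- function(seqs, genome_ids, k = 12L) {
  idx <- new.env(parent = emptyenv())
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    L <- nchar(s)
    if (L < k) next
    kmers <- unique(substring(s, 1:(L - k + 1L), k:L))
    for (km in kmers) idx[[km]] <- c(idx[[km]], i)
  }
  seen <- new.env(parent = emptyenv())
  ii <- integer(); jj <- integer()
  for (km in ls(idx)) {
    hits <- idx[[km]]
    if (length(hits) < 2L) next
    for (p in combn(hits, 2L, simplify = FALSE)) {
      if (genome_ids[p[1]] == genome_ids[p[2]]) next
      key <- paste(p, collapse = "_")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      ii <- c(ii, p[1]); jj <- c(jj, p[2])
    }
  }
  data.frame(i = ii, j = jj)
}

#' Conserved syntenic islands among transfer candidates
#'
#' Transfer candidates sharing an identical carrier-genome set are tested
#' for synteny: members occupying consecutive `order_index` positions in
#' every carrier genome (whole-run reversal allowed) are merged into
#' maximal runs; runs of length >= 2 are reported as genomic islands.
#' Candidates in no run stay island-free. The output is a partition — no
#' candidate belongs to two islands.
#'
#' @param candidates data.frame from [detect_recent_transfer()].
#' @param genomes the genomes the candidates were detected in (unused
#'   beyond validation; positions travel with the candidates).
#' @return data.frame with `island_id`, `length`, `carrier_genome_ids`
#'   (list-column) and `member_candidate_ids` / `member_gene_ids`
#'   (list-columns, ordered along the first carrier).
#' @export
detect_islands <- function(candidates, genomes) {
  empty <- data.frame(island_id = character(), length = integer(),
                      carrier_genome_ids = I(list()),
                      member_candidate_ids = I(list()),
                      member_gene_ids = I(list()))
  if (!nrow(candidates)) return(empty)
  known <- unlist(lapply(genomes, function(g) g$genes$gene_id))
  for (m in candidates$members)
    if (!all(m$gene_id %in% known))
      stop_data("detect_islands: candidate references genes not in the supplied genomes")
  key <- vapply(candidates$carrier_genome_ids, paste, "", collapse = "|")
  out <- list()
  for (kset in unique(key)) {
    grp <- which(key == kset)
    if (length(grp) < 2L) next
    carriers <- candidates$carrier_genome_ids[[grp[1L]]]
    # candidate x carrier position matrix (first member per carrier)
    pos <- sapply(grp, function(i) {
      m <- candidates$members[[i]]
      vapply(carriers, function(cg) m$order_index[m$genome_id == cg][1L], 0)
    })
    pos <- matrix(pos, nrow = length(carriers))  # carriers x candidates
    adj <- matrix(FALSE, length(grp), length(grp))
    for (a in seq_along(grp)) for (b in seq_along(grp)) if (a < b)
      adj[a, b] <- adj[b, a] <- all(abs(pos[, a] - pos[, b]) == 1)
    comp <- components_from_adjacency(adj)
    for (cc in unique(comp)) {
      run <- which(comp == cc)
      if (length(run) < 2L) next
      # verify contiguity in every carrier
      contiguous <- all(apply(pos[, run, drop = FALSE], 1L, function(p)
        length(p) == diff(range(p)) + 1L))
      if (!contiguous) next
      ord <- run[order(pos[1L, run])]
      out[[length(out) + 1L]] <- data.frame(
        island_id = sprintf("island%02d", length(out) + 1L),
        length = length(ord),
        carrier_genome_ids = I(list(carriers)),
        member_candidate_ids = I(list(candidates$candidate_id[grp[ord]])),
        member_gene_ids = I(list(candidates$representative_gene_id[grp[ord]])))
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  res
}

components_from_adjacency <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i]) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v]) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Gene-family count contrast between host groups
#'
#' Genes are grouped into families by normalised function label
#' (case-folded, whitespace-collapsed); families in which no genome reaches
#' `min_family_size` members are dropped (configurable to require the
#' minimum in every genome). Retained families are contrasted across the
#' two host groups with the exact Mann-Whitney test.
#'
#' @param genomes list of [genome()] objects spanning two host groups.
#' @param config a [screen_config()].
#' @param require_in_every_genome if TRUE the family-size filter must hold
#'   in every genome rather than at least one (default FALSE).
#' @return data.frame with `family_label`, per-group medians, `U`, `p`,
#'   `significant`, and a list-column `counts` (named per-genome counts).
#' @export
gene_family_counts <- function(genomes, config = screen_config(),
                               require_in_every_genome = FALSE) {
  hosts <- host_of(genomes)
  if (length(unique(hosts)) != 2L)
    stop_data("gene_family_counts: exactly two host groups required")
  if (any(vapply(genomes, function(g)
    any(is.na(g$genes$function_label) | !nzchar(g$genes$function_label)), TRUE)))
    stop_data("gene_family_counts: genomes with missing function labels")
  norm <- function(x) gsub("\\s+", " ", trimws(tolower(x)))
  counts <- lapply(genomes, function(g) table(norm(g$genes$function_label)))
  fams <- sort(unique(unlist(lapply(counts, names))))
  cnt <- sapply(counts, function(tb) {
    v <- as.integer(tb[fams]); v[is.na(v)] <- 0L; v
  })
  cnt <- matrix(cnt, nrow = length(fams),
                dimnames = list(fams, names(hosts)))
  keep <- if (require_in_every_genome) apply(cnt, 1L, min) >= config$min_family_size
          else apply(cnt, 1L, max) >= config$min_family_size
  cnt <- cnt[keep, , drop = FALSE]
  grp_names <- sort(unique(hosts))
  out <- lapply(rownames(cnt), function(f) {
    g1 <- cnt[f, hosts == grp_names[1L]]
    g2 <- cnt[f, hosts == grp_names[2L]]
    mw <- mann_whitney_exact(g1, g2)
    df <- data.frame(family_label = f,
                     median_1 = median(g1), median_2 = median(g2),
                     U = mw$U, p = mw$p, significant = mw$p < config$alpha,
                     counts = I(list(cnt[f, ])))
    names(df)[2:3] <- paste0("median_", grp_names)
    df
  })
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(family_label = character())
  rownames(res) <- NULL
  res
}
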