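#' Configuration for the synthetic genome generator
#'
#' Defaults emulate the study design the package targets: two host groups
#' of seven annotated genomes each (human- and chicken-adapted lineages),
#' a conserved core of shared gene families, five planted host-A-specific
#' gene families, and eight near-identical horizontally transferred genes
#' in three group-B carriers of which five form a syntenic island.
#'
#' Divergence is substitution-only over the 20-letter amino-acid alphabet,
#' so planted similarity relationships are analytically controllable:
#' two gene copies drawn at divergence d from a common ancestor are
#' roughly `100 (1-d)^2` percent identical. `within_group_divergence` must
#' keep that expectation at or above 50%, and `between_group_divergence`
#' (applied on top, to the out-group remnants of planted specific families)
#' must push the cross-group expectation below 50%.
#'
#' @param n_group_a,n_group_b genomes per host group (defaults 7 and 7).
#' @param genes_per_genome number of shared core gene families (default 30).
#' @param gene_length_aa length range in residues, `c(min, max)` (default
#'   60-100).
#' @param within_group_divergence substituted-residue fraction per copy
#'   from its family ancestor (default 0.08, ~85% pairwise identity).
#' @param between_group_divergence extra divergence of group-B remnants of
#'   group-A-specific families (default 0.7, ~25% cross-group identity).
#' @param n_planted_specific_a planted group-A-specific families (default 5).
#' @param n_planted_transfer planted near-identical transfer genes
#'   (default 8), of which the first `island_length` form the island.
#' @param transfer_carrier_count group-B genomes carrying the transfer
#'   genes (default 3; must be a strict subset, at most `n_group_b - 1`).
#' @param island_length consecutive transfer genes forming the island
#'   (default 5).
#' @param seed integer seed; all randomness flows from it.
#' @return list of class `genome_sim_config`.
#' @export
genome_sim_config <- function(n_group_a = 7L, n_group_b = 7L,
                              genes_per_genome = 30L,
                              gene_length_aa = c(60L, 100L),
                              within_group_divergence = 0.08,
                              between_group_divergence = 0.7,
                              n_planted_specific_a = 5L,
                              n_planted_transfer = 8L,
                              transfer_carrier_count = 3L,
                              island_length = 5L,
                              seed = 1L) {
  cfg <- list(n_group_a = check_count(n_group_a, "n_group_a", 1L),
              n_group_b = check_count(n_group_b, "n_group_b", 1L),
              genes_per_genome = check_count(genes_per_genome, "genes_per_genome", 1L),
              gene_length_aa = gene_length_aa,
              within_group_divergence = within_group_divergence,
              between_group_divergence = between_group_divergence,
              n_planted_specific_a = check_count(n_planted_specific_a, "n_planted_specific_a"),
              n_planted_transfer = check_count(n_planted_transfer, "n_planted_transfer"),
              transfer_carrier_count = check_count(transfer_carrier_count, "transfer_carrier_count"),
              island_length = check_count(island_length, "island_length", 2L),
              seed = check_count(seed, "seed"))
  if (length(gene_length_aa) != 2L || gene_length_aa[1] < 20L ||
      gene_length_aa[2] < gene_length_aa[1])
    stop_data("configuration error: `gene_length_aa` must be c(min, max) with min >= 20")
  d <- within_group_divergence
  if (!is.numeric(d) || d < 0 || d >= 1 || (1 - d)^2 < 0.5)
    stop_data("configuration error: `within_group_divergence` must keep expected similarity >= 50%%")
  b <- between_group_divergence
  if (!is.numeric(b) || b <= 0 || b > 1 || (1 - b) * (1 - d)^2 >= 0.5)
    stop_data("configuration error: `between_group_divergence` must push cross-group similarity < 50%%")
  if (cfg$n_planted_transfer > 0) {
    if (cfg$transfer_carrier_count < 3L || cfg$transfer_carrier_count > cfg$n_group_b - 1L)
      stop_data("configuration error: `transfer_carrier_count` must be in [3, n_group_b - 1]")
    if (cfg$island_length > cfg$n_planted_transfer)
      stop_data("configuration error: `island_length` exceeds `n_planted_transfer`")
  }
  structure(cfg, class = "genome_sim_config")
}

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE), collapse = "")

# substitute exactly round(d * L) positions, each to a different residue
mutate_protein <- function(seq, d) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_sub <- round(d * length(ch))
  if (n_sub == 0L) return(seq)
  pos <- sample(length(ch), n_sub)
  ch[pos] <- vapply(ch[pos], function(a) sample(setdiff(AA20, a), 1L), "")
  paste(ch, collapse = "")
}

TRANSFER_LABELS <- c("putative macrolide efflux pump",
                     "lincosamide nucleotidyltransferase LinA",
                     "acetyltransferase GNAT family",
                     "mobile element hypothetical protein",
                     "mobilization protein",
                     "retron-type RNA-directed DNA polymerase",
                     "quaternary ammonium compound-resistance protein SugE",
                     "Kup system potassium uptake protein")

#' Simulate annotated genomes with planted host-adaptation signals
#'
#' Emits `n_group_a` group-A ("human") and `n_group_b` group-B ("chicken")
#' genomes. Each genome carries one copy of every core family at
#' within-group divergence from the family ancestor (so every best-hit
#' similarity stays at or above 50%). Planted group-A-specific families are
#' intact in every group-A genome but present only as heavily diverged
#' remnants (below 50% similarity) in group B. Planted transfer genes are
#' verbatim copies in exactly `transfer_carrier_count` group-B genomes;
#' the first `island_length` of them occupy consecutive positions in every
#' carrier (a conserved genomic island), the rest are scattered so that no
#' two planted genes are ever adjacent. Genome sizes are drawn from the
#' contrasting ranges typical of the two lineages (group A 4.23-6.70 Mb,
#' group B 3.43-4.46 Mb).
#'
#' @param config a [genome_sim_config()].
#' @return list with `genomes` (list of [genome()]) and `truth`: a list with
#'   `specific_gene_ids` (ids in the first group-A genome, the default
#'   screening reference), `specific_gene_ids_by_genome`,
#'   `transfer_families` (one character vector of member gene ids per
#'   planted transfer gene), `island_gene_ids` (subset of transfer families
#'   forming the island), `island_spans` (data.frame genome_id/start/end,
#'   0-based inclusive), `carrier_genome_ids` and `true_config`.
#' @export
simulate_genomes <- function(config = genome_sim_config()) {
  stopifnot(inherits(config, "genome_sim_config"))
  with_seed(config$seed, {
    lens <- function(n) sample(seq(config$gene_length_aa[1], config$gene_length_aa[2]), n, replace = TRUE)
    n_core <- config$genes_per_genome
    core_anc <- vapply(lens(n_core), random_protein, "")
    core_lab <- sprintf("conserved protein family %02d", seq_len(n_core))
    n_spec <- config$n_planted_specific_a
    spec_anc <- if (n_spec) vapply(lens(n_spec), random_protein, "") else character()
    spec_lab <- if (n_spec) sprintf("group A specific protein %02d", seq_len(n_spec)) else character()
    # group-B remnant ancestors of the specific families
    spec_anc_b <- vapply(spec_anc, mutate_protein, "", d = config$between_group_divergence)
    n_tr <- config$n_planted_transfer
    tr_seq <- if (n_tr) vapply(lens(n_tr), random_protein, "") else character()
    tr_lab <- if (n_tr) rep_len(TRANSFER_LABELS, n_tr) else character()

    a_ids <- sprintf("A%02d", seq_len(config$n_group_a))
    b_ids <- sprintf("B%02d", seq_len(config$n_group_b))
    carriers <- if (n_tr > 0) sort(sample(b_ids, config$transfer_carrier_count))
                else character()
    d <- config$within_group_divergence

    spec_ids_by_genome <- list()
    island_spans <- list()
    transfer_members <- replicate(n_tr, character(), simplify = FALSE)

    build <- function(gid, host) {
      is_a <- host == "human"
      is_carrier <- gid %in% carriers
      seqs <- c(vapply(core_anc, mutate_protein, "", d = d),
                if (is_a) vapply(spec_anc, mutate_protein, "", d = d)
                else vapply(spec_anc_b, mutate_protein, "", d = d))
      labs <- c(core_lab,
                if (is_a) spec_lab else paste(spec_lab, "(diverged remnant)"))
      kind <- c(rep("core", n_core), rep(if (is_a) "specific" else "remnant", n_spec))
      fam <- c(seq_len(n_core), if (n_spec) n_core + seq_len(n_spec) else integer())
      n_slots <- length(seqs) + if (is_carrier) n_tr else 0L
      if (is_carrier) {
        placed <- place_planted(n_slots, config$island_length, n_tr - config$island_length)
        slot_kind <- rep("bg", n_slots)
        slot_kind[placed$island] <- "island"
        slot_kind[placed$scattered] <- "scatter"
        ord <- integer(n_slots)
        bg <- sample(which(slot_kind == "bg"))  # shuffle background order
        tr_slots <- c(placed$island, placed$scattered)
        seq_out <- character(n_slots); lab_out <- character(n_slots)
        kind_out <- character(n_slots); fam_out <- integer(n_slots)
        seq_out[bg] <- seqs; lab_out[bg] <- labs
        kind_out[bg] <- kind; fam_out[bg] <- fam
        seq_out[tr_slots] <- tr_seq; lab_out[tr_slots] <- tr_lab
        kind_out[tr_slots] <- "transfer"
        fam_out[tr_slots] <- n_core + n_spec + seq_len(n_tr)
        seqs <- seq_out; labs <- lab_out; kind <- kind_out; fam <- fam_out
        island_slots <- placed$island
      } else {
        perm <- sample(n_slots)
        seqs <- seqs[perm]; labs <- labs[perm]; kind <- kind[perm]; fam <- fam[perm]
        island_slots <- integer()
      }
      ids <- sprintf("%s_g%03d", gid, seq_len(n_slots))
      if (is_a)
        spec_ids_by_genome[[gid]] <<- ids[kind == "specific"][order(fam[kind == "specific"])]
      if (is_carrier && n_tr) {
        for (j in seq_len(n_tr)) {
          slot <- which(fam == n_core + n_spec + j & kind == "transfer")
          transfer_members[[j]] <<- c(transfer_members[[j]], ids[slot])
        }
        island_spans[[gid]] <<- data.frame(genome_id = gid,
                                           start = min(island_slots) - 1L,
                                           end = max(island_slots) - 1L)
      }
      size <- if (is_a) runif(1, 4.23e6, 6.70e6) else runif(1, 3.43e6, 4.46e6)
      genome(gid, host, round(size),
             data.frame(gene_id = ids, function_label = labs, sequence = seqs))
    }
    genomes <- c(lapply(a_ids, build, host = "human"),
                 lapply(b_ids, build, host = "chicken"))
    island_fams <- seq_len(min(config$island_length, n_tr))
    truth <- list(
      specific_gene_ids = spec_ids_by_genome[[a_ids[1L]]] %||% character(),
      specific_gene_ids_by_genome = spec_ids_by_genome,
      transfer_families = transfer_members,
      island_gene_ids = unlist(transfer_members[island_fams]) %||% character(),
      island_spans = if (length(island_spans)) do.call(rbind, unname(island_spans))
                     else data.frame(genome_id = character(), start = integer(), end = integer()),
      carrier_genome_ids = carriers,
      true_config = config)
    list(genomes = genomes, truth = truth)
  })
}

# choose island block + scattered singleton positions so that no two planted
# slots are adjacent; returns 1-based slot indices
place_planted <- function(n_slots, island_len, n_scatter) {
  repeat {
    start <- sample(n_slots - island_len + 1L, 1L)
    island <- start:(start + island_len - 1L)
    blocked <- unique(pmax(1L, pmin(n_slots, c(island, min(island) - 1L, max(island) + 1L))))
    scattered <- integer()
    free <- setdiff(seq_len(n_slots), blocked)
    ok <- TRUE
    for (i in seq_len(n_scatter)) {
      if (!length(free)) { ok <- FALSE; break }
      p <- if (length(free) == 1L) free else sample(free, 1L)
      scattered <- c(scattered, p)
      free <- setdiff(free, c(p - 1L, p, p + 1L))
    }
    if (ok) return(list(island = island, scattered = sort(scattered)))
  }
}

#' Configuration for the qPCR Ct-table simulator
#'
#' The measurement model inverts the delta-Ct quantification: for a species
#' at true abundance p percent of total bacterial DNA,
#' `Ct_species = baseline_16s_ct - log2(p / 100) + noise`, while the 16S
#' reference assay reads `baseline_16s_ct + noise`; noise is independent
#' Gaussian per replicate (the package's model for duplicate qPCR scatter).
#' With zero noise the delta-Ct formula recovers `true_abundance_pct`
#' exactly.
#'
#' @param n_samples_per_host samples per host group (default 20).
#' @param species_names species assays (default "sp_human", "sp_chicken").
#' @param true_abundance_pct named list host -> named numeric vector
#'   species -> percent. Default: a 100-fold reciprocal contrast (10% vs
#'   0.1%) between human and chicken hosts for the two species.
#' @param ct_noise_sd replicate noise in Ct cycles (default 0.3).
#' @param baseline_16s_ct reference-assay Ct (default 15).
#' @param n_replicates qPCR replicates per assay (default 2, duplicate PCR).
#' @param seed integer seed.
#' @return list of class `qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(n_samples_per_host = 20L,
                            species_names = c("sp_human", "sp_chicken"),
                            true_abundance_pct = list(
                              human = c(sp_human = 10, sp_chicken = 0.1),
                              chicken = c(sp_human = 0.1, sp_chicken = 10)),
                            ct_noise_sd = 0.3, baseline_16s_ct = 15,
                            n_replicates = 2L, seed = 1L) {
  if (!is.numeric(ct_noise_sd) || ct_noise_sd < 0)
    stop_data("configuration error: `ct_noise_sd` must be >= 0")
  pcts <- unlist(true_abundance_pct)
  if (!length(pcts) || any(pcts <= 0 | pcts > 100))
    stop_data("configuration error: `true_abundance_pct` values must be in (0, 100]")
  for (h in names(true_abundance_pct))
    if (!all(species_names %in% names(true_abundance_pct[[h]])))
      stop_data("configuration error: `true_abundance_pct` lacks some species for host '%s'", h)
  structure(list(n_samples_per_host = check_count(n_samples_per_host, "n_samples_per_host", 1L),
                 species_names = species_names,
                 true_abundance_pct = true_abundance_pct,
                 ct_noise_sd = ct_noise_sd, baseline_16s_ct = baseline_16s_ct,
                 n_replicates = check_count(n_replicates, "n_replicates", 1L),
                 seed = check_count(seed, "seed")),
            class = "qpcr_sim_config")
}

#' Simulate a replicate qPCR Ct table with known true abundances
#'
#' @param config a [qpcr_sim_config()].
#' @return list with `ct_table` (data.frame `sample_id`, `host`, `assay`,
#'   `replicate`, `ct`, `censored`) and `truth` (the configured
#'   `true_abundance_pct`). Every sample carries the "16S" reference assay.
#' @export
simulate_ct_table <- function(config = qpcr_sim_config()) {
  stopifnot(inherits(config, "qpcr_sim_config"))
  with_seed(config$seed, {
    rows <- list()
    for (h in names(config$true_abundance_pct)) {
      for (s in seq_len(config$n_samples_per_host)) {
        sid <- sprintf("%s_s%02d", h, s)
        add <- function(assay, base_ct) {
          ct <- base_ct + rnorm(config$n_replicates, 0, config$ct_noise_sd)
          rows[[length(rows) + 1L]] <<- data.frame(
            sample_id = sid, host = h, assay = assay,
            replicate = seq_len(config$n_replicates), ct = ct, censored = FALSE)
        }
        add("16S", config$baseline_16s_ct)
        for (sp in config$species_names)
          add(sp, config$baseline_16s_ct -
                log2(config$true_abundance_pct[[h]][[sp]] / 100))
      }
    }
    list(ct_table = do.call(rbind, rows), truth = config$true_abundance_pct)
  })
}

#' Simulate a sparse PSM count table
#'
#' Each (protein, strain, condition) cell is zero with probability
#' `sparsity`, else `1 + Poisson(mean_psm - 1)` so every detected cell has
#' at least one spectral match. With `sparsity = 0` every protein is
#' observed in every strain-condition cell.
#'
#' @param n_proteins number of proteins.
#' @param strains character vector of strain ids (default 5 strains).
#' @param conditions character vector of condition ids; default the in
#'   vitro design of an inoculum plus five media sampled at two
#'   subcultures (11 conditions).
#' @param sparsity probability a cell is zero, in \[0, 1).
#' @param seed integer seed.
#' @param mean_psm mean PSM count of detected cells (default 20).
#' @return data.frame `protein_id`, `strain`, `condition`, `psm`.
#' @export
simulate_psm_table <- function(n_proteins, strains = sprintf("strain%d", 1:5),
                               conditions = default_conditions(),
                               sparsity = 0.3, seed = 1L, mean_psm = 20) {
  if (!is.numeric(sparsity) || sparsity < 0 || sparsity >= 1)
    stop_data("configuration error: `sparsity` must be in [0, 1)")
  n_proteins <- check_count(n_proteins, "n_proteins", 1L)
  with_seed(seed, {
    grid <- expand.grid(protein_id = sprintf("prot%03d", seq_len(n_proteins)),
                        strain = strains, condition = conditions,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    zero <- runif(nrow(grid)) < sparsity
    grid$psm <- ifelse(zero, 0L, 1L + rpois(nrow(grid), max(mean_psm - 1, 0)))
    grid
  })
}

#' Default in vitro condition set: inoculum + 5 media x 2 subcultures
#' @return character vector of 11 condition ids.
#' @export
default_conditions <- function() {
  media <- c("BHI", "mucin", "cellulose", "starch", "pectin")
  c("inoculum", paste0(rep(media, each = 2L), c("_sub1", "_sub4")))
}
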