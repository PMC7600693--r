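test_that("genome simulation is seed-deterministic and books the planted truth", {
  cfg <- genome_sim_config(seed = 3)
  s1 <- simulate_genomes(cfg)
  s2 <- simulate_genomes(cfg)
  expect_identical(s1, s2)
  expect_length(s1$genomes, cfg$n_group_a + cfg$n_group_b)
  expect_length(s1$truth$specific_gene_ids, cfg$n_planted_specific_a)
  expect_length(s1$truth$transfer_families, cfg$n_planted_transfer)
  expect_length(s1$truth$carrier_genome_ids, cfg$transfer_carrier_count)
  # every truth id exists in the emitted genomes
  all_ids <- unlist(lapply(s1$genomes, function(g) g$genes$gene_id))
  expect_true(all(unlist(s1$truth$transfer_families) %in% all_ids))
  expect_true(all(s1$truth$specific_gene_ids %in% all_ids))
  # island spans are consecutive within gene-order bounds, one per carrier
  sp <- s1$truth$island_spans
  expect_setequal(sp$genome_id, s1$truth$carrier_genome_ids)
  expect_true(all(sp$end - sp$start + 1L == cfg$island_length))
  for (i in seq_len(nrow(sp))) {
    g <- s1$genomes[[which(vapply(s1$genomes, `[[`, "", "genome_id") == sp$genome_id[i])]]
    expect_true(sp$start[i] >= 0 && sp$end[i] < nrow(g$genes))
  }
})

test_that("planted similarity structure respects the 50% and 99% thresholds", {
  sim <- simulate_genomes(genome_sim_config(seed = 5, n_group_a = 3, n_group_b = 4,
                                            genes_per_genome = 8,
                                            n_planted_specific_a = 2,
                                            n_planted_transfer = 5,
                                            island_length = 5,
                                            transfer_carrier_count = 3))
  hosts <- vapply(sim$genomes, `[[`, "", "host_label")
  a <- sim$genomes[hosts == "human"]
  b <- sim$genomes[hosts == "chicken"]
  ref <- a[[1]]
  spec <- sim$truth$specific_gene_ids
  for (gid in spec) {
    seq_ <- ref$genes$sequence[ref$genes$gene_id == gid]
    within <- vapply(a[-1], function(g) best_hit(list(gene_id = gid, sequence = seq_), g)$similarity, 0)
    across <- vapply(b, function(g) best_hit(list(gene_id = gid, sequence = seq_), g)$similarity, 0)
    expect_true(all(within >= 50))
    expect_true(all(across < 50))
  }
  # transfer copies are mutually >99% similar in exactly the carrier genomes
  fam <- sim$truth$transfer_families[[1]]
  carriers <- sub("_g.*", "", fam)
  expect_setequal(carriers, sim$truth$carrier_genome_ids)
})

test_that("degenerate divergences give all-identical or configuration errors", {
  z <- simulate_genomes(genome_sim_config(seed = 1, n_group_a = 2, n_group_b = 4,
                                          genes_per_genome = 4,
                                          within_group_divergence = 0,
                                          n_planted_specific_a = 0,
                                          n_planted_transfer = 0))
  # zero divergence: every cross-genome best hit of a core gene is 100
  ref <- z$genomes[[1]]
  sims <- vapply(z$genomes[-1], function(g)
    best_hit(ref$genes[1, ], g)$similarity, 0)
  expect_true(all(sims == 100))

  expect_error(genome_sim_config(within_group_divergence = 0.5), "within_group_divergence")
  expect_error(genome_sim_config(between_group_divergence = 0.05), "between_group_divergence")
  expect_error(genome_sim_config(transfer_carrier_count = 7, n_group_b = 7),
               "transfer_carrier_count")
  expect_error(genome_sim_config(island_length = 1), "island_length")
})

test_that("Ct simulation inverts exactly without noise and is deterministic", {
  cfg <- qpcr_sim_config(ct_noise_sd = 0, n_samples_per_host = 2, seed = 9)
  s1 <- simulate_ct_table(cfg)
  expect_identical(s1, simulate_ct_table(cfg))
  ab <- quantify_abundance(s1$ct_table)
  for (i in seq_len(nrow(ab))) {
    truth <- s1$truth[[ab$host[i]]][[ab$species[i]]]
    expect_equal(ab$percent[i], truth, tolerance = 1e-9)
  }
  # 100% truth means species Ct equals the 16S Ct; 25% lags by 2 cycles
  cfg2 <- qpcr_sim_config(ct_noise_sd = 0, n_samples_per_host = 1,
                          species_names = c("s1", "s2"),
                          true_abundance_pct = list(h = c(s1 = 100, s2 = 25)),
                          seed = 1)
  ct <- simulate_ct_table(cfg2)$ct_table
  ref_ct <- ct$ct[ct$assay == "16S"][1]
  expect_equal(ct$ct[ct$assay == "s1"][1], ref_ct)
  expect_equal(ct$ct[ct$assay == "s2"][1], ref_ct + 2)

  expect_error(qpcr_sim_config(ct_noise_sd = -1), "ct_noise_sd")
  expect_error(qpcr_sim_config(true_abundance_pct = list(h = c(sp_human = 0, sp_chicken = 1))),
               "true_abundance_pct")
})

test_that("PSM simulation matches its sparsity contract and is deterministic", {
  full <- simulate_psm_table(10, sparsity = 0, seed = 2)
  expect_true(all(full$psm >= 1))
  nx <- expression_count(full)
  expect_true(all(nx == length(unique(full$strain)) * length(unique(full$condition))))

  sparse <- simulate_psm_table(40, sparsity = 0.95, seed = 2)
  expect_identical(sparse, simulate_psm_table(40, sparsity = 0.95, seed = 2))
  expect_equal(mean(sparse$psm == 0), 0.95, tolerance = 0.02)
  # at high sparsity most proteins are silent in most cells
  expect_gt(mean(expression_count(sparse) < 10), 0.9)

  expect_error(simulate_psm_table(10, sparsity = 1), "sparsity")
})
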