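# small two-host fixture: 3 human (reference first) + 3 chicken genomes,
# 4 core families everywhere, gene "R1_g05" human-specific
make_screen_fixture <- function() {
  set.seed(51)
  core <- replicate(4, rand_seq(60))
  spec <- rand_seq(60)
  mk <- function(id, host, with_spec) {
    seqs <- vapply(core, sub_seq, "", n = 5)
    if (with_spec) seqs <- c(seqs, sub_seq(spec, 5))
    toy_genome(id, host, seqs)
  }
  genomes <- c(lapply(sprintf("H%d", 1:3), mk, host = "human", with_spec = TRUE),
               lapply(sprintf("C%d", 1:3), mk, host = "chicken", with_spec = FALSE))
  genomes[[1]]$genome_id <- "R1"
  genomes[[1]]$genes$gene_id <- sub("^H1", "R1", genomes[[1]]$genes$gene_id)
  genomes
}

test_that("host-specific screen keeps in-group-present, out-group-absent rows only", {
  genomes <- make_screen_fixture()
  hosts <- setNames(vapply(genomes, `[[`, "", "host_label"),
                    vapply(genomes, `[[`, "", "genome_id"))
  pm <- build_presence_matrix(genomes[[1]], genomes)
  got <- screen_host_specific(pm, hosts, "human", "chicken")
  expect_identical(got, "R1_g05")

  # the published screen pattern: high in-group similarities, all out-group
  # cells below 50 -> selected; present everywhere -> not selected
  fake <- pm
  fake$similarity["R1_g01", ] <- c(100, 84.23, 84.02, 30, 20, 25)
  fake$similarity["R1_g02", ] <- c(100, 84, 84, 60, 55, 70)
  got2 <- screen_host_specific(fake, hosts, "human", "chicken")
  expect_true("R1_g01" %in% got2)
  expect_false("R1_g02" %in% got2)

  expect_error(screen_host_specific(pm, hosts, "human", "pig"), "zero genomes")
  expect_error(screen_host_specific(pm, hosts, "chicken", "human"), "in-group")
})

test_that("raising the absence threshold only shrinks the host-specific in-group condition", {
  genomes <- make_screen_fixture()
  hosts <- setNames(vapply(genomes, `[[`, "", "host_label"),
                    vapply(genomes, `[[`, "", "genome_id"))
  pm <- build_presence_matrix(genomes[[1]], genomes)
  in_ids <- names(hosts)[hosts == "human"]
  for (thr in c(40, 50, 60, 75)) {
    got <- screen_host_specific(pm, hosts, "human", "chicken",
                                screen_config(absent_threshold = thr))
    # every selected row satisfies the definition at this threshold
    for (g in got) {
      expect_true(all(pm$similarity[g, in_ids] >= thr))
      expect_true(all(pm$similarity[g, setdiff(colnames(pm$similarity), in_ids)] < thr))
    }
  }
})

test_that("marker-gene search returns exactly the genes unique to the target", {
  set.seed(61)
  shared <- replicate(3, rand_seq(50))
  unique3 <- replicate(3, rand_seq(50))
  target <- toy_genome("T", "human", c(shared, unique3))
  others <- lapply(1:4, function(i)
    toy_genome(sprintf("O%d", i), "human", vapply(shared, sub_seq, "", n = 4)))
  got <- find_marker_genes(target, others)
  expect_setequal(got, c("T_g04", "T_g05", "T_g06"))

  # copying a candidate into one other genome at 100% removes it
  others2 <- others
  others2[[1]] <- toy_genome("O1", "human", c(vapply(shared, sub_seq, "", n = 4), unique3[1]))
  expect_setequal(find_marker_genes(target, others2), c("T_g05", "T_g06"))
  expect_error(find_marker_genes(target, list()), "nonempty")
})

# 7 genomes; `carried` genes placed (consecutively if island) in a carrier subset
make_transfer_fixture <- function(n_genomes = 7, carriers = 1:4, n_island = 0,
                                  n_scatter = 1, divergence = 0) {
  set.seed(71)
  bg <- replicate(6, rand_seq(60))
  planted <- replicate(n_island + n_scatter, rand_seq(60))
  lapply(seq_len(n_genomes), function(i) {
    seqs <- vapply(bg, function(s) rand_seq(60), "")  # unrelated background
    labs <- sprintf("bg %d", seq_along(seqs))
    if (i %in% carriers && length(planted)) {
      pl <- vapply(planted, function(s) if (divergence > 0) sub_seq(s, divergence) else s, "")
      isl <- seq_len(n_island)
      # island block at positions 3..(2+n_island); scattered at the end
      seqs <- append(seqs, pl[isl], after = 2)
      if (n_scatter) seqs <- c(seqs, pl[n_island + seq_len(n_scatter)])
      labs <- sprintf("gene %d", seq_along(seqs))
    }
    toy_genome(sprintf("G%d", i), "chicken", seqs, labels = labs)
  })
}

test_that("transfer candidates require >99% identity in a strict carrier subset", {
  gs <- make_transfer_fixture(carriers = 1:4, n_island = 0, n_scatter = 1)
  cands <- detect_recent_transfer(gs)
  expect_equal(nrow(cands), 1)
  expect_equal(cands$n_carriers, 4)
  expect_setequal(cands$carrier_genome_ids[[1]], sprintf("G%d", 1:4))
  expect_gte(cands$min_pairwise_similarity, 99)

  # present in all 7 genomes: core, not transfer
  all7 <- make_transfer_fixture(carriers = 1:7, n_island = 0, n_scatter = 1)
  expect_equal(nrow(detect_recent_transfer(all7)), 0)

  # 95% mutual similarity stays below the transfer threshold
  div <- make_transfer_fixture(carriers = 1:4, n_island = 0, n_scatter = 1,
                               divergence = 3)  # 3/60 subs per copy ~ 90-95%
  expect_equal(nrow(detect_recent_transfer(div)), 0)
})

test_that("islands are maximal consecutive runs shared by identical carrier sets", {
  gs <- make_transfer_fixture(carriers = c(2, 4, 6), n_island = 5, n_scatter = 1)
  cands <- detect_recent_transfer(gs)
  expect_equal(nrow(cands), 6)
  isl <- detect_islands(cands, gs)
  expect_equal(nrow(isl), 1)
  expect_equal(isl$length, 5)
  expect_setequal(isl$carrier_genome_ids[[1]], c("G2", "G4", "G6"))
  # partition: island members + the scattered singleton account for all candidates
  expect_length(unlist(isl$member_candidate_ids), 5)
  expect_length(unique(unlist(isl$member_candidate_ids)), 5)

  # shuffling the run in one carrier destroys the island
  gs2 <- gs
  g4 <- gs2[[4]]
  isl_rows <- 3:7  # island block positions in the fixture
  perm <- c(isl_rows[c(2, 4, 1, 5, 3)])
  g4$genes$sequence[isl_rows] <- g4$genes$sequence[perm]
  gs2[[4]] <- g4
  cands2 <- detect_recent_transfer(gs2)
  isl2 <- detect_islands(cands2, gs2)
  expect_equal(nrow(isl2), 0)

  expect_equal(nrow(detect_islands(cands[0, ], gs)), 0)
})

test_that("gene-family contrast drops small families and flags planted count differences", {
  mk <- function(id, host, n_big) {
    labs <- c(rep("ABC Transporter", n_big), rep(" abc  transporter ", 2),
              rep("rare family", 3), sprintf("unique %d", 1:3))
    toy_genome(id, host, replicate(length(labs), rand_seq(25)), labels = labs)
  }
  genomes <- c(lapply(sprintf("H%d", 1:7), mk, host = "human", n_big = 18),
               lapply(sprintf("C%d", 1:7), mk, host = "chicken", n_big = 8))
  res <- gene_family_counts(genomes)
  # label normalisation folds case and whitespace into one family
  expect_true("abc transporter" %in% res$family_label)
  expect_false("rare family" %in% res$family_label)          # max count 3 < 10
  big <- res[res$family_label == "abc transporter", ]
  expect_true(big$significant)                               # 20 vs 10 per genome
  expect_lt(big$p, 0.05)

  # identical counts in every genome: p = 1, not significant
  same <- c(lapply(sprintf("H%d", 1:3), mk, host = "human", n_big = 10),
            lapply(sprintf("C%d", 1:3), mk, host = "chicken", n_big = 10))
  res2 <- gene_family_counts(same)
  expect_equal(res2$p[res2$family_label == "abc transporter"], 1)
  expect_false(any(res2$significant))
})
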