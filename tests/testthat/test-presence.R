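test_that("presence categories have an inclusive 50 and exclusive 99 boundary", {
  expect_identical(presence_category(c(49.999, 50, 99, 99.001, 100)),
                   c("absent", "present_divergent", "present_divergent",
                     "present_recent_transfer", "present_recent_transfer"))
  expect_error(presence_category(50, absent_threshold = 99, transfer_threshold = 50))
})

test_that("presence matrix has an all-100 reference column and oracle-consistent cells", {
  set.seed(31)
  core <- replicate(4, rand_seq(60))
  ref <- toy_genome("R1", "human", core)
  g2 <- toy_genome("G2", "human", c(sub_seq(core[1], 6), sub_seq(core[2], 6),
                                    rand_seq(60), rand_seq(60)))
  pm <- build_presence_matrix(ref, list(ref, g2))
  expect_equal(unname(pm$similarity[, "R1"]), rep(100, 4))
  expect_identical(unname(pm$category[, "R1"]), rep("present_recent_transfer", 4))
  # each cell equals the exhaustive best over pairwise alignments
  for (i in 1:4) {
    sims <- vapply(g2$genes$sequence, function(s) align_similarity(core[i], s), 0)
    expect_equal(unname(pm$similarity[i, "G2"]), max(sims))
  }
  expect_error(build_presence_matrix(ref, list(g2, g2)), "duplicate")
})

test_that("fast identity equals the explicit terminal-trim column count", {
  # the alignment accessors used in production vs direct column bookkeeping
  set.seed(8)
  for (i in 1:10) {
    a <- rand_seq(sample(30:80, 1))
    b <- if (i %% 2) sub_seq(a, sample(0:15, 1)) else rand_seq(sample(30:80, 1))
    b <- substr(b, 1, max(25, nchar(b) - sample(0:10, 1)))
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = hostadapt:::.blosum62(),
      gapOpening = 11, gapExtension = 1)
    slow <- hostadapt:::percent_identity_cols(
      as.character(Biostrings::alignedPattern(pa)),
      as.character(Biostrings::alignedSubject(pa)))
    expect_equal(align_similarity(a, b), slow, tolerance = 1e-12)
  }
})

test_that("genome size contrast reports group ranges and the exact U test", {
  # published ranges: chicken-adapted 3.43-4.46 Mb vs human-adapted 4.23-6.70 Mb;
  # seven genomes per group spread across each range (synthetic within-range sizes)
  chicken <- seq(3.43e6, 4.46e6, length.out = 7)
  human <- seq(4.23e6, 6.70e6, length.out = 7)
  gs <- c(lapply(seq_along(chicken), function(i)
            toy_genome(sprintf("C%d", i), "chicken", rand_seq(30, seed = i),
                       size = chicken[i])),
          lapply(seq_along(human), function(i)
            toy_genome(sprintf("H%d", i), "human", rand_seq(30, seed = 100 + i),
                       size = human[i])))
  res <- compare_genome_sizes(gs)
  expect_equal(res$ranges$min_bp, c(3.43e6, 4.23e6))
  expect_equal(res$ranges$max_bp, c(4.46e6, 6.70e6))
  # chicken group (first alphabetically) sits low: U well below the null mean
  expect_lt(res$U, 7 * 7 / 2)
  expect_lt(res$p, 0.05)
  expect_identical(res$method, "exact")

  # identical size lists: p = 1
  same <- c(lapply(1:3, function(i) toy_genome(sprintf("A%d", i), "a", rand_seq(20, seed = i), size = 4e6)),
            lapply(1:3, function(i) toy_genome(sprintf("B%d", i), "b", rand_seq(20, seed = 9 + i), size = 4e6)))
  expect_equal(compare_genome_sizes(same)$p, 1)

  # fully separated toy lists give U = 0
  toy <- c(lapply(1:3, function(i) toy_genome(sprintf("A%d", i), "a", rand_seq(20, seed = i), size = i)),
           lapply(1:3, function(i) toy_genome(sprintf("B%d", i), "b", rand_seq(20, seed = 9 + i), size = 3 + i)))
  expect_equal(compare_genome_sizes(toy)$U, 0)
  expect_error(compare_genome_sizes(toy[1:3]), "two host groups")
})

test_that("presence matrix round-trips through its TSV rendering", {
  set.seed(41)
  ref <- toy_genome("R1", "human", replicate(3, rand_seq(40)))
  g2 <- toy_genome("G2", "chicken", c(sub_seq(ref$genes$sequence[1], 4), rand_seq(40)))
  pm <- build_presence_matrix(ref, list(g2))
  path <- tempfile(fileext = ".tsv")
  write_presence_matrix(pm, path)
  lines <- readLines(path)
  expect_match(lines[1], "reference=R1")
  body <- read.delim(text = lines[-1], check.names = FALSE)
  expect_equal(nrow(body), 3)
  expect_match(body$G2[1], ":present_")
})
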