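# shared fixture builders (all generated in code, seeded)

AA <- c("A","R","N","D","C","Q","E","G","H","I",
        "L","K","M","F","P","S","T","W","Y","V")

rand_seq <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA, len, replace = TRUE), collapse = "")
}

# substitute exactly n positions of seq, each to a different residue
sub_seq <- function(seq, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), n)
  ch[pos] <- vapply(ch[pos], function(a) sample(setdiff(AA, a), 1L), "")
  paste(ch, collapse = "")
}

toy_genome <- function(id, host, seqs, labels = NULL, size = 4e6) {
  labels <- labels %||% sprintf("protein %02d", seq_along(seqs))
  genome(id, host, size,
         data.frame(gene_id = sprintf("%s_g%02d", id, seq_along(seqs)),
                    function_label = labels, sequence = seqs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force O(n!) alignment-free oracles ----------------------------------

# exact two-sided Mann-Whitney p by full enumeration (midranks)
oracle_mw <- function(x, y) {
  nx <- length(x); N <- nx + length(y)
  r <- rank(c(x, y))
  mu <- nx * (N - nx) / 2
  U <- function(sel) sum(r[sel]) - nx * (nx + 1) / 2
  u0 <- U(seq_len(nx))
  Us <- apply(combn(N, nx), 2, U)
  list(U = u0, p = mean(abs(Us - mu) >= abs(u0 - mu) - 1e-9))
}

# exact Kruskal-Wallis permutation p by enumerating all group assignments
oracle_kw <- function(groups) {
  x <- unlist(groups); sizes <- lengths(groups); N <- length(x)
  r <- rank(x)
  H_of <- function(lab) {
    rbar <- tapply(r, lab, mean)
    n_i <- lengths(split(r, lab))
    H <- 12 / (N * (N + 1)) * sum(n_i * (rbar - (N + 1) / 2)^2)
    tt <- table(r); corr <- 1 - sum(tt^3 - tt) / (N^3 - N)
    if (corr <= 0) 0 else H / corr
  }
  lab0 <- rep(seq_along(groups), sizes)
  h0 <- H_of(lab0)
  perms <- unique(combinat_perms(lab0))
  hs <- apply(perms, 1, H_of)
  list(H = h0, p = mean(hs >= h0 - 1e-9))
}

# all distinct permutations of a label multiset (rows)
combinat_perms <- function(lab) {
  if (length(lab) == 1L) return(matrix(lab, 1L))
  out <- list()
  for (v in unique(lab)) {
    rest <- lab[-match(v, lab)]
    sub <- combinat_perms(rest)
    out[[length(out) + 1L]] <- cbind(v, sub)
  }
  unique(do.call(rbind, out))
}
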