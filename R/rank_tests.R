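#' Kruskal-Wallis rank test with exact and Monte-Carlo permutation options
#'
#' Computes the tie-corrected Kruskal-Wallis H statistic. The p-value comes
#' from the chi-square limiting distribution when every group has at least
#' 5 observations, otherwise from the permutation distribution of H under
#' relabelling: exhaustive enumeration when the number of distinct
#' group assignments is at most `max_enum`, else seeded Monte Carlo.
#' `p_method` overrides the automatic choice.
#'
#' @param groups list of >= 2 nonempty numeric vectors.
#' @param p_method one of "auto", "chisq", "exact", "monte-carlo".
#' @param n_perm Monte-Carlo permutation count (default 10000).
#' @param seed seed for the Monte-Carlo path (local RNG state only).
#' @param max_enum largest number of assignments enumerated exhaustively.
#' @return list with `H`, `p`, `df`, and `method` ("chisq", "exact" or
#'   "monte-carlo").
#' @export
kruskal_wallis <- function(groups, p_method = c("auto", "chisq", "exact", "monte-carlo"),
                           n_perm = 10000L, seed = 1L, max_enum = 2e5) {
  p_method <- match.arg(p_method)
  groups <- check_groups(groups, "kruskal_wallis")
  x <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  k <- length(groups)
  N <- length(x)
  if (length(unique(x)) == 1L)
    return(list(H = 0, p = 1, df = k - 1L, method = "degenerate"))
  r <- rank(x)
  H <- kw_H(r, rep.int(seq_len(k), sizes), sizes, N)
  n_assign <- exp(lgamma(N + 1) - sum(lgamma(sizes + 1)))
  if (p_method == "auto")
    p_method <- if (all(sizes >= 5L)) "chisq"
                else if (n_assign <= max_enum) "exact" else "monte-carlo"
  if (p_method == "exact" && n_assign > 20 * max_enum)
    stop_data("kruskal_wallis: %.3g assignments is too many to enumerate", n_assign)
  p <- switch(p_method,
    chisq = pchisq(H, df = k - 1L, lower.tail = FALSE),
    exact = {
      Hs <- apply(assignments(N, sizes), 2L, function(g) kw_H(r, g, sizes, N))
      mean(Hs >= H - 1e-9)
    },
    `monte-carlo` = with_seed(seed, {
      Hs <- replicate(n_perm, kw_H(r, sample(rep.int(seq_len(k), sizes)), sizes, N))
      mean(Hs >= H - 1e-9)
    })
  )
  list(H = H, p = p, df = k - 1L, method = p_method)
}

# tie-corrected H for ranks r under group labels g
kw_H <- function(r, g, sizes, N) {
  rbar <- tapply(r, g, mean)
  H <- 12 / (N * (N + 1)) * sum(sizes * (rbar - (N + 1) / 2)^2)
  tie <- tie_sum(r)
  denom <- 1 - tie / (N^3 - N)
  if (denom <= 0) 0 else H / denom
}

tie_sum <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

# all distinct assignments of N items to groups of the given sizes;
# columns are group-label vectors of length N
assignments <- function(N, sizes) {
  k <- length(sizes)
  res <- vector("list", 0L)
  rec <- function(idx, lab, g) {
    if (g == k) {
      lab[idx] <- k
      res[[length(res) + 1L]] <<- lab
      return(invisible(NULL))
    }
    cmb <- combn(length(idx), sizes[g])
    for (j in seq_len(ncol(cmb))) {
      take <- cmb[, j]
      lab2 <- lab
      lab2[idx[take]] <- g
      rec(idx[-take], lab2, g + 1L)
    }
  }
  rec(seq_len(N), integer(N), 1L)
  do.call(cbind, res)
}

check_groups <- function(groups, fn) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_data("%s: need a list of >= 2 groups", fn)
  if (any(lengths(groups) == 0L))
    stop_data("%s: every group must be nonempty", fn)
  lapply(groups, function(g) {
    g <- as.numeric(g)
    if (anyNA(g)) stop_data("%s: NA observations not allowed", fn)
    g
  })
}

#' Dunn's post hoc test on pooled tie-corrected ranks
#'
#' For every pair of groups, the standardised difference of mean pooled
#' ranks with the usual tie correction; raw two-sided normal p-values are
#' adjusted for multiple comparisons (default Holm).
#'
#' @param groups named or unnamed list of >= 2 nonempty numeric vectors.
#' @param adjustment a [stats::p.adjust()] method name (default "holm").
#' @return data.frame with `group1`, `group2`, `z`, `p_raw`, `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, adjustment = "holm") {
  groups <- check_groups(groups, "dunn_posthoc")
  nms <- names(groups) %||% as.character(seq_along(groups))
  if (is.null(names(groups))) names(groups) <- nms
  x <- unlist(groups, use.names = FALSE)
  g <- rep.int(nms, lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)[nms]
  sizes <- lengths(groups)
  var_term <- N * (N + 1) / 12 - tie_sum(r) / (12 * (N - 1))
  pairs <- combn(nms, 2L)
  res <- apply(pairs, 2L, function(pr) {
    sig <- sqrt(var_term * (1 / sizes[[pr[1]]] + 1 / sizes[[pr[2]]]))
    z <- if (sig == 0) 0 else (rbar[[pr[1]]] - rbar[[pr[2]]]) / sig
    c(z = z, p_raw = min(1, 2 * pnorm(-abs(z))))
  })
  out <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                    z = res["z", ], p_raw = res["p_raw", ])
  out$p_adjusted <- p.adjust(out$p_raw, method = adjustment)
  out
}

#' Exact two-sided Mann-Whitney U test
#'
#' U is computed from mid-ranks (so ties are handled identically in the
#' observed and permuted statistics). When `n_x + n_y <= enum_limit`
#' (default 16) the two-sided p-value is exact: the proportion of all
#' `choose(n, n_x)` relabellings whose U is at least as far from the null
#' mean `n_x n_y / 2` as the observed U. Larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y nonempty numeric samples.
#' @param enum_limit largest total sample size for exact enumeration.
#' @return list with `U` (for `x`), `p` (two-sided) and `method`
#'   ("exact" or "normal").
#' @export
mann_whitney_exact <- function(x, y, enum_limit = 16L) {
  if (!length(x) || !length(y) || anyNA(c(x, y)))
    stop_data("mann_whitney_exact: both samples must be nonempty without NA")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (N <= enum_limit) {
    sel <- combn(N, nx)
    Rsum <- colSums(matrix(r[sel], nrow = nx))
    Us <- Rsum - nx * (nx + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    tie <- tie_sum(r)
    sig <- sqrt(nx * ny / 12 * ((N + 1) - tie / (N * (N - 1))))
    if (sig == 0) return(list(U = U, p = 1, method = "normal"))
    z <- (U - mu - sign(U - mu) * 0.5) / sig
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(U = U, p = p, method = method)
}
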