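## Network-level weighted-bipartite metrics.

metric_value <- function(name, value, A, notes = "") {
  structure(list(name = name, value = value,
                 matrix_shape = c(n_plants = nrow(A), n_ants = ncol(A)),
                 notes = notes),
            class = "metric_value")
}

#' @export
print.metric_value <- function(x, ...) {
  cat(sprintf("<metric_value> %s = %.4f  (%d x %d matrix)%s\n", x$name,
              x$value, x$matrix_shape[1L], x$matrix_shape[2L],
              if (nzchar(x$notes)) paste0("  [", x$notes, "]") else ""))
  invisible(x)
}

#' @export
as.double.metric_value <- function(x, ...) x$value

check_two_by_two <- function(A, what) {
  if (nrow(A) < 2L || ncol(A) < 2L) {
    stop_undefined_metric(paste0(what, " is undefined on a single-row or ",
                                 "single-column matrix (",
                                 nrow(A), " x ", ncol(A), ")"))
  }
}

shannon <- function(v) {
  p <- v[v > 0]
  -sum(p * log(p))
}

## ------------------------------------------------------------- H2' -------

#' Complementary specialization H2'
#'
#' Network-level specialization derived from the two-dimensional Shannon
#' entropy of the interaction-frequency distribution. With `p_ij = a_ij / F`,
#' `H2 = -sum p_ij log p_ij` is rescaled between the minimum and maximum
#' entropies attainable by integer matrices with the observed row and column
#' totals: `H2' = (H2max - H2) / (H2max - H2min)`. Values near 0 indicate
#' generalization (cells near the margin-product expectation), values near 1
#' perfect specialization.
#'
#' Bounds are exact (margin-constrained enumeration) for small matrices
#' (total at most 12 and at most 16 cells) and otherwise use greedy heuristic
#' fills: units steered towards the independence expectation for `H2max`,
#' mass concentrated on as few cells as the margins allow for `H2min`. On
#' pathological margins the heuristic bounds can differ slightly from the
#' exact optima.
#'
#' @param A A [layer_matrix()] or non-negative count matrix, at least 2 x 2.
#' @return A `metric_value` with `name = "H2"`.
#' @export
h2prime <- function(A) {
  M <- as_count_matrix(A)
  check_two_by_two(M, "H2'")
  F_tot <- sum(M)
  if (F_tot <= 0) stop_undefined_metric("H2' undefined on an all-zero matrix")
  H2 <- shannon(M / F_tot)
  b <- h2_entropy_bounds(rowSums(M), colSums(M))
  if (b$max - b$min < 1e-12) {
    return(metric_value("H2", 0, M, "degenerate margins: H2max = H2min"))
  }
  val <- (b$max - H2) / (b$max - b$min)
  metric_value("H2", min(1, max(0, val)), M,
               if (b$exact) "exact entropy bounds" else "heuristic entropy bounds")
}

h2_entropy_bounds <- function(r, cc) {
  F_tot <- sum(r)
  if (F_tot <= 12 && length(r) * length(cc) <= 16L) {
    ents <- entropy_range_exact(r, cc)
    list(min = ents[1L], max = ents[2L], exact = TRUE)
  } else {
    list(min = h2min_heuristic(r, cc), max = h2max_heuristic(r, cc),
         exact = FALSE)
  }
}

## exact min/max entropy over all non-negative integer matrices with the
## given margins (recursive cell-by-cell enumeration; guarded by caller)
entropy_range_exact <- function(r, cc) {
  n <- length(r); m <- length(cc)
  F_tot <- sum(r)
  lo <- Inf; hi <- -Inf
  cells <- numeric(n * m)
  rec <- function(i, j, rr, ccr, plogp) {
    if (i > n) {
      h <- -plogp
      if (h < lo) lo <<- h
      if (h > hi) hi <<- h
      return(invisible())
    }
    ni <- if (j == m) i + 1L else i
    nj <- if (j == m) 1L else j + 1L
    # remaining column capacity in this row after cell j
    rest <- if (j < m) sum(ccr[(j + 1L):m]) else 0
    vmin <- max(0, rr[i] - rest)
    vmax <- min(rr[i], ccr[j])
    for (v in vmin:vmax) {
      contrib <- if (v > 0) (v / F_tot) * log(v / F_tot) else 0
      rr2 <- rr; rr2[i] <- rr2[i] - v
      cc2 <- ccr; cc2[j] <- cc2[j] - v
      rec(ni, nj, rr2, cc2, plogp + contrib)
    }
  }
  rec(1L, 1L, r, cc, 0)
  c(lo, hi)
}

## greedy fill towards the independence expectation r_i c_j / F; allocates
## one unit at a time to the feasible cell farthest below its expectation
h2max_heuristic <- function(r, cc) {
  n <- length(r); m <- length(cc)
  F_tot <- sum(r)
  e <- as.vector(outer(r, cc) / F_tot)   # expectation, column-major
  a <- numeric(n * m)
  d <- e                                 # e - a, masked -Inf when infeasible
  rr <- r; ccr <- cc
  row_of <- rep.int(seq_len(n), m)
  col_of <- rep(seq_len(m), each = n)
  for (t in seq_len(F_tot)) {
    k <- which.max(d)
    i <- row_of[k]; j <- col_of[k]
    a[k] <- a[k] + 1
    d[k] <- d[k] - 1
    rr[i] <- rr[i] - 1
    ccr[j] <- ccr[j] - 1
    if (rr[i] == 0) d[row_of == i] <- -Inf
    if (ccr[j] == 0) d[col_of == j] <- -Inf
  }
  shannon(a / F_tot)
}

## greedy concentration: repeatedly place min(max row rest, max col rest)
## into the cell joining the fullest row and column
h2min_heuristic <- function(r, cc) {
  F_tot <- sum(r)
  rr <- r; ccr <- cc
  vals <- numeric(0)
  repeat {
    i <- which.max(rr); j <- which.max(ccr)
    v <- min(rr[i], ccr[j])
    if (v <= 0) break
    vals <- c(vals, v)
    rr[i] <- rr[i] - v
    ccr[j] <- ccr[j] - v
  }
  shannon(vals / F_tot)
}

## ----------------------------------------------------------- WNODF -------

#' Weighted nestedness (WNODF)
#'
#' Nestedness based on overlap and decreasing fill in the weighted matrix.
#' Rows are ordered by decreasing row totals (ties keep label order), columns
#' likewise. For an ordered row pair (i above j): the pair contributes 0 when
#' the totals do not decrease (`r_i <= r_j`), otherwise
#' `100 * #{k : 0 < a_jk < a_ik} / #{k : a_jk > 0}`. Column pairs are scored
#' symmetrically, and WNODF is the mean over all row and column pairs, in
#' `[0, 100]`.
#'
#' @param A A [layer_matrix()] or count matrix, at least 2 x 2.
#' @return A `metric_value` with `name = "WNODF"`.
#' @export
wnodf <- function(A) {
  M <- as_count_matrix(A)
  check_two_by_two(M, "WNODF")
  val <- (sum(wnodf_pair_scores(M)) + sum(wnodf_pair_scores(t(M)))) /
    (choose(nrow(M), 2) + choose(ncol(M), 2))
  metric_value("WNODF", val, M)
}

## vector of contributions over ordered row pairs of M
wnodf_pair_scores <- function(M) {
  tot <- rowSums(M)
  ord <- order(-tot)          # stable: ties keep original label order
  M <- M[ord, , drop = FALSE]
  tot <- tot[ord]
  n <- nrow(M)
  scores <- numeric(choose(n, 2))
  s <- 0L
  for (i in seq_len(n - 1L)) {
    Ai <- M[i, ]
    for (j in (i + 1L):n) {
      s <- s + 1L
      if (tot[i] <= tot[j]) next
      Aj <- M[j, ]
      pos <- Aj > 0
      scores[s] <- 100 * sum(pos & Aj < Ai) / sum(pos)
    }
  }
  scores
}

## ------------------------------------------------------ Morisita-Horn ----

#' Morisita-Horn niche overlap
#'
#' Pairwise overlap between the relative resource-use distributions of guild
#' members: for two members with relative-use vectors `p` and `q`,
#' `C = 2 sum(p q) / (sum(p^2) + sum(q^2))`, in `[0, 1]`. The network value
#' is the unweighted mean of `C` over all pairs in the guild (columns for
#' ants, rows for plants).
#'
#' @param A A [layer_matrix()] or count matrix.
#' @param guild `"ants"` (columns, default) or `"plants"` (rows).
#' @return A `metric_value` with `name = "Horn"`.
#' @export
horn_overlap <- function(A, guild = c("ants", "plants")) {
  guild <- match.arg(guild)
  M <- as_count_matrix(A)
  V <- if (guild == "ants") M else t(M)
  if (ncol(V) < 2L) {
    stop_undefined_metric(paste0("Morisita-Horn overlap needs >= 2 ", guild))
  }
  P <- sweep(V, 2L, colSums(V), "/")
  num <- 2 * crossprod(P)
  ss <- colSums(P^2)
  C <- num / outer(ss, ss, "+")
  metric_value("Horn", mean(C[upper.tri(C)]), M, paste0("guild=", guild))
}

#' Pairwise Morisita-Horn overlap between two use vectors
#'
#' @param x,y Non-negative use counts of equal length.
#' @return Overlap in `[0, 1]`.
#' @export
horn_pair <- function(x, y) {
  p <- x / sum(x); q <- y / sum(y)
  2 * sum(p * q) / (sum(p^2) + sum(q^2))
}

## ----------------------------------------------------------- degree ------

#' Degree centrality of every species
#'
#' Binary degree: the number of distinct partners (positive cells) of each
#' species, unweighted by interaction frequency.
#'
#' @param A A [layer_matrix()] or count matrix.
#' @return List with named integer vectors `plants` and `ants`.
#' @export
degree_centrality <- function(A) {
  M <- as_count_matrix(A)
  list(plants = rowSums(M > 0), ants = colSums(M > 0))
}
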