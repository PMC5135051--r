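# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles with naive loops/enumeration so they share
# no code path with the package implementation.

# all non-negative integer vectors of length m summing to s, each component
# bounded by cap[i]
compositions_capped <- function(s, cap) {
  m <- length(cap)
  if (m == 1L) {
    if (s <= cap[1L]) return(list(s)) else return(list())
  }
  out <- list()
  for (v in 0:min(s, cap[1L])) {
    for (rest in compositions_capped(s - v, cap[-1L])) {
      out[[length(out) + 1L]] <- c(v, rest)
    }
  }
  out
}

# all matrices with the exact margins (row-by-row composition recursion)
enumerate_margin_tables <- function(r, cc) {
  n <- length(r)
  build <- function(i, remaining_c) {
    if (i > n) return(list(matrix(numeric(0), 0, length(cc))))
    rows <- compositions_capped(r[i], remaining_c)
    out <- list()
    for (row in rows) {
      for (tail in build(i + 1L, remaining_c - row)) {
        out[[length(out) + 1L]] <- rbind(row, tail, deparse.level = 0)
      }
    }
    out
  }
  build(1L, cc)
}

table_entropy <- function(M) {
  p <- M[M > 0] / sum(M)
  -sum(p * log(p))
}

# enumeration-based H2' (memoised per margin signature)
.h2_oracle_cache <- new.env(parent = emptyenv())
oracle_h2prime <- function(M) {
  r <- rowSums(M); cc <- colSums(M)
  key <- paste(c(r, NA, cc), collapse = ",")
  if (is.null(.h2_oracle_cache[[key]])) {
    ents <- vapply(enumerate_margin_tables(r, cc), table_entropy, numeric(1))
    .h2_oracle_cache[[key]] <- c(min(ents), max(ents))
  }
  b <- .h2_oracle_cache[[key]]
  H2 <- table_entropy(M)
  if (b[2L] - b[1L] < 1e-12) return(0)
  (b[2L] - H2) / (b[2L] - b[1L])
}

# direct pair-by-pair WNODF
oracle_wnodf <- function(M) {
  score_rows <- function(M) {
    tot <- rowSums(M)
    ord <- order(tot, decreasing = TRUE)   # stable for ties
    M <- M[ord, , drop = FALSE]; tot <- tot[ord]
    vals <- c()
    for (i in seq_len(nrow(M) - 1L)) for (j in (i + 1L):nrow(M)) {
      if (tot[i] <= tot[j]) {
        vals <- c(vals, 0)
      } else {
        num <- 0; den <- 0
        for (k in seq_len(ncol(M))) {
          if (M[j, k] > 0) {
            den <- den + 1
            if (M[j, k] < M[i, k]) num <- num + 1
          }
        }
        vals <- c(vals, 100 * num / den)
      }
    }
    vals
  }
  mean(c(score_rows(M), score_rows(t(M))))
}

# unweighted mean pairwise Morisita-Horn over columns
oracle_horn_ants <- function(M) {
  m <- ncol(M)
  vals <- c()
  for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
    p <- M[, a] / sum(M[, a]); q <- M[, b] / sum(M[, b])
    vals <- c(vals, 2 * sum(p * q) / (sum(p^2) + sum(q^2)))
  }
  mean(vals)
}

# direct modularity formula
oracle_Q <- function(M, assignment) {
  F_tot <- sum(M)
  r <- rowSums(M); cc <- colSums(M)
  q <- 0
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    if (assignment[rownames(M)[i]] == assignment[colnames(M)[j]]) {
      q <- q + M[i, j] / F_tot - r[i] * cc[j] / F_tot^2
    }
  }
  unname(q)
}

# all set partitions of n elements as restricted-growth strings
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L)) {
      rec(c(prefix, lab), max(maxlab, lab))
    }
  }
  rec(integer(0), 0L)
  out
}

# exhaustive maximum-modularity search
oracle_best_Q <- function(M) {
  species <- c(rownames(M), colnames(M))
  best <- -Inf
  for (p in enumerate_partitions(length(species))) {
    q <- oracle_Q(M, stats::setNames(p, species))
    if (q > best) best <- q
  }
  best
}

# all permutations of 1..n (rows of a matrix)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# random count matrix with no zero row/column
random_count_matrix <- function(n, m, total, labels = TRUE) {
  repeat {
    M <- matrix(stats::rmultinom(1, total, rep(1, n * m)), n, m)
    if (all(rowSums(M) > 0) && all(colSums(M) > 0)) break
  }
  if (labels) dimnames(M) <- list(sprintf("P%02d", 1:n), sprintf("A%02d", 1:m))
  M
}

# reproduce the package's master-seed -> child-seed derivation
with_seed_oracle <- function(seed, k) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)[k]
}

# strip layer attributes/class for raw matrix comparison
unclass_mat <- function(M) {
  M <- as.matrix(M)
  attr(M, "resource") <- NULL
  attr(M, "sites") <- NULL
  class(M) <- NULL
  storage.mode(M) <- "double"
  M
}

# attach generic species labels to a raw count matrix
provisional_label <- function(M) {
  dimnames(M) <- list(sprintf("P%02d", seq_len(nrow(M))),
                      sprintf("A%02d", seq_len(ncol(M))))
  M
}

named_layer <- function(M, resource = "EFN") {
  if (is.null(rownames(M))) {
    dimnames(M) <- list(sprintf("P%02d", seq_len(nrow(M))),
                        sprintf("A%02d", seq_len(ncol(M))))
  }
  layer_matrix(M, resource = resource)
}

# small deterministic event table used across tests
toy_events <- function() {
  data.frame(
    site_id = c("S1", "S1", "S2"),
    plot_id = c("p1", "p1", "p2"),
    season = c("Jan", "Jan", "Apr"),
    plant_sp = c("P1", "P1", "P2"),
    ant_sp = c("A1", "A1", "A2"),
    resource = c("EFN", "EFN", "EFN"),
    workers = c(1L, 2L, 1L),
    stringsAsFactors = FALSE
  )
}
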