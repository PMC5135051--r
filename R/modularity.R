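## Weighted bipartite modularity (Barber-style bipartite Newman modularity
## for weighted graphs) maximised by simulated annealing, with best-of-N
## restarts. The quality function lives on plant-ant pairs only:
##   Q = sum_ij [ a_ij/F - r_i c_j / F^2 ] delta(module_i, module_j).

#' Modularity of a given partition
#'
#' Evaluates the weighted bipartite modularity
#' `Q = sum_ij (a_ij/F - r_i c_j/F^2) * delta(m_i, m_j)` for an explicit
#' module assignment. The all-in-one partition always scores exactly 0.
#'
#' @param A A [layer_matrix()] or count matrix.
#' @param partition Named vector (names = all row and column species of `A`)
#'   giving a module id per species, or a `module_partition`.
#' @return Numeric `Q`.
#' @export
modularity_Q <- function(A, partition) {
  M <- as_count_matrix(A)
  if (inherits(partition, "module_partition")) partition <- partition$assignment
  species <- c(rownames(M), colnames(M))
  if (!all(species %in% names(partition))) {
    stop_validation("partition must assign every plant and ant of the matrix")
  }
  mp <- partition[rownames(M)]
  ma <- partition[colnames(M)]
  F_tot <- sum(M)
  B <- M / F_tot - outer(rowSums(M), colSums(M)) / F_tot^2
  sum(B * outer(mp, ma, "=="))
}

#' Annealing configuration for modularity search
#'
#' @param t0_factor Initial temperature as a multiple of the matrix total
#'   `F` (default 0.02).
#' @param cooling Geometric cooling factor per move (default 0.99).
#' @param patience_factor Moves without improvement before stopping, as a
#'   multiple of the species count (default 50).
#' @param max_steps Hard cap on annealing moves (default 2e5).
#' @return A list of class `quanbimo_config`.
#' @export
quanbimo_config <- function(t0_factor = 0.02, cooling = 0.99,
                            patience_factor = 50, max_steps = 2e5) {
  structure(list(t0_factor = t0_factor, cooling = cooling,
                 patience_factor = patience_factor,
                 max_steps = as.integer(max_steps)),
            class = "quanbimo_config")
}

#' Fit modules by simulated annealing
#'
#' Single annealing run: every species starts in its own module; moves
#' reassign one species, merge two modules, or split one module, under a
#' geometric cooling schedule. The number of modules is free. The best
#' partition visited is returned; if it scores below the trivial all-in-one
#' partition (Q = 0), the trivial partition is returned instead, so the
#' fitted Q is never negative.
#'
#' @param A A [layer_matrix()] or count matrix, at least 2 x 2.
#' @param config A [quanbimo_config()].
#' @param seed Integer seed (optional; runs use the current RNG stream when
#'   `NULL`).
#' @return A `module_partition`: list with `assignment` (named vector over
#'   all species), `Q`, `n_modules`, `seed`, `iterations`.
#' @export
quanbimo_fit <- function(A, config = quanbimo_config(), seed = NULL) {
  M <- as_count_matrix(A)
  check_two_by_two(M, "modularity")
  F_tot <- sum(M)
  B <- M / F_tot - outer(rowSums(M), colSums(M)) / F_tot^2
  S <- nrow(M) + ncol(M)
  fit <- with_seed(seed, anneal_modules_cpp(
    B,
    t0 = config$t0_factor * F_tot,
    cooling = config$cooling,
    patience = as.integer(ceiling(config$patience_factor * S)),
    max_steps = config$max_steps
  ))
  if (fit$Q < 0) {
    assignment <- setNames(rep(1L, S), c(rownames(M), colnames(M)))
    Q <- 0
  } else {
    raw <- c(fit$mp, fit$ma)
    assignment <- setNames(match(raw, unique(raw)),
                           c(rownames(M), colnames(M)))
    Q <- fit$Q
  }
  structure(list(assignment = assignment, Q = Q,
                 n_modules = length(unique(assignment)),
                 seed = seed, iterations = fit$steps),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> Q = %.4f  modules = %d  species = %d\n",
              x$Q, x$n_modules, length(x$assignment)))
  invisible(x)
}

#' Best-of-N modularity search
#'
#' Repeats [quanbimo_fit()] with independently spawned restart seeds and
#' keeps the partition with the highest Q. With a fixed `seed` the restart
#' seed stream is deterministic, so the best-of value is monotone
#' non-decreasing in `n_iter`.
#'
#' @param A A [layer_matrix()] or count matrix.
#' @param n_iter Number of independent annealing restarts (default 1000).
#' @param config A [quanbimo_config()].
#' @param seed Master seed spawning per-restart seeds.
#' @return The best `module_partition` found; `$n_iter` records the restarts.
#' @export
best_of <- function(A, n_iter = 1000, config = quanbimo_config(),
                    seed = NULL) {
  stopifnot(n_iter >= 1)
  seeds <- with_seed(seed, spawn_seeds(n_iter))
  best <- NULL
  for (s in seeds) {
    fit <- quanbimo_fit(A, config, seed = s)
    if (is.null(best) || fit$Q > best$Q) best <- fit
  }
  best$n_iter <- n_iter
  best$seed <- seed
  best
}

#' Normalized mutual information between two partitions
#'
#' Agreement between two module assignments over the same species, in
#' `[0, 1]` (1 = identical up to relabeling). Uses arithmetic-mean
#' normalization; defined as 1 when both partitions are single-module.
#'
#' @param a,b Module assignments: named vectors (matched by name when both
#'   are named) or equal-length vectors.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    stopifnot(setequal(names(a), names(b)))
    b <- b[names(a)]
  }
  stopifnot(length(a) == length(b))
  n <- length(a)
  tab <- table(a, b) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  Ha <- shannon(pa); Hb <- shannon(pb)
  if (Ha + Hb == 0) return(1)
  mi <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb)) {
    if (tab[i, j] > 0) mi <- mi + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
  }
  unname(2 * mi / (Ha + Hb))
}
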