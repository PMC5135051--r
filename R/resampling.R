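## Fixed-margin (Patefield) null models, metric significance, standardized
## modularity, and the Monte-Carlo pairwise layer comparison.

metric_num <- function(x) {
  if (inherits(x, "metric_value")) x$value
  else if (inherits(x, "module_partition")) x$Q
  else as.numeric(x)
}

#' Draw fixed-margin random matrices (Patefield null model)
#'
#' Samples non-negative integer matrices with exactly the given row and
#' column totals from the independence-conditional (multiple
#' hypergeometric) distribution, via Patefield's (1981) sequential
#' allocation algorithm as implemented in [stats::r2dtable()].
#'
#' @param margins_r Integer vector of row totals.
#' @param margins_c Integer vector of column totals (same sum).
#' @param n Number of draws.
#' @param seed Optional seed.
#' @return A single matrix when `n = 1`, otherwise a list of matrices.
#' @export
patefield_sample <- function(margins_r, margins_c, n = 1, seed = NULL) {
  margins_r <- as.integer(round(margins_r))
  margins_c <- as.integer(round(margins_c))
  if (sum(margins_r) != sum(margins_c) || sum(margins_r) <= 0) {
    stop_validation("row and column margins must be positive and sum equal")
  }
  draws <- with_seed(seed, fixed_margin_tables(n, margins_r, margins_c))
  if (n == 1) draws[[1L]] else draws
}

## r2dtable requires >= 2 rows and columns; single-row/column tables are
## fully determined by the opposite margin
fixed_margin_tables <- function(n, r, cc) {
  if (length(r) == 1L) {
    return(replicate(n, matrix(cc, 1L), simplify = FALSE))
  }
  if (length(cc) == 1L) {
    return(replicate(n, matrix(r, ncol = 1L), simplify = FALSE))
  }
  r2dtable(n, r, cc)
}

null_draws_like <- function(A, n) {
  M <- as_count_matrix(A)
  draws <- fixed_margin_tables(n, as.integer(rowSums(M)),
                               as.integer(colSums(M)))
  lapply(draws, function(d) {
    dimnames(d) <- dimnames(M)
    d
  })
}

## pseudocount p-value: (1 + #{null at least as extreme}) / (N + 1)
null_p_value <- function(observed, nulls, sidedness) {
  eps <- 1e-12
  extreme <- switch(
    sidedness,
    greater = nulls >= observed - eps,
    less = nulls <= observed + eps,
    `two-sided` = {
      center <- mean(nulls)
      abs(nulls - center) >= abs(observed - center) - eps
    }
  )
  (1 + sum(extreme)) / (length(nulls) + 1)
}

#' Null-model significance of a network metric
#'
#' Computes the metric on `n_null` fixed-margin randomizations of the matrix
#' and reports a pseudocount Monte-Carlo p-value,
#' `p = (1 + #{null at least as extreme}) / (n_valid + 1)`. Two-sided
#' extremeness is measured as distance from the null mean. Null draws on
#' which the metric is undefined are excluded and counted.
#'
#' @param A A [layer_matrix()] or count matrix.
#' @param metric_fn Function mapping a matrix to a `metric_value` or number.
#' @param n_null Number of null draws (default 999).
#' @param sidedness `"greater"`, `"less"`, or `"two-sided"`.
#' @param seed Optional seed.
#' @return A `metric_report`: observed value, null vector, p-value,
#'   null summary, exclusion count.
#' @export
metric_significance <- function(A, metric_fn, n_null = 999,
                                sidedness = c("greater", "less", "two-sided"),
                                seed = NULL) {
  sidedness <- match.arg(sidedness)
  observed <- metric_num(metric_fn(A))
  with_seed(seed, {
    draws <- null_draws_like(A, n_null)
    nulls <- vapply(draws, function(d) {
      tryCatch(metric_num(metric_fn(d)),
               antnets_undefined_metric = function(e) NA_real_)
    }, numeric(1))
  })
  excluded <- sum(is.na(nulls))
  nulls <- nulls[!is.na(nulls)]
  structure(list(observed = observed, null_values = nulls,
                 p_value = null_p_value(observed, nulls, sidedness),
                 n_null = n_null, n_excluded = excluded,
                 sidedness = sidedness, seed = seed,
                 null_mean = mean(nulls), null_sd = sd(nulls)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> observed = %.4f  null = %.4f +/- %.4f  P = %.4g (%s, N = %d%s)\n",
    x$observed, x$null_mean, x$null_sd, x$p_value, x$sidedness,
    length(x$null_values),
    if (x$n_excluded > 0) paste0(", ", x$n_excluded, " excluded") else ""))
  invisible(x)
}

#' Standardized modularity
#'
#' How many null standard deviations the observed modularity lies above the
#' mean modularity of fixed-margin randomizations, each maximised with the
#' same best-of-restarts search. Values of 2 or more are flagged
#' significant.
#'
#' @param A A [layer_matrix()] or count matrix.
#' @param n_null Number of null draws (default 1000).
#' @param n_iter Annealing restarts per matrix (observed and null alike).
#' @param config A [quanbimo_config()].
#' @param seed Optional master seed.
#' @return A `standardized_Q` list: `z`, `Q_obs`, `null_mean`, `null_sd`,
#'   `significant`, `degenerate`.
#' @export
standardized_Q <- function(A, n_null = 1000, n_iter = 10,
                           config = quanbimo_config(), seed = NULL) {
  res <- with_seed(seed, {
    seeds <- spawn_seeds(n_null + 1L)
    obs <- best_of(A, n_iter = n_iter, config = config, seed = seeds[1L])
    draws <- null_draws_like(A, n_null)
    q_null <- vapply(seq_len(n_null), function(k) {
      best_of(draws[[k]], n_iter = n_iter, config = config,
              seed = seeds[k + 1L])$Q
    }, numeric(1))
    list(obs = obs, q_null = q_null)
  })
  mu <- mean(res$q_null); sdev <- sd(res$q_null)
  degenerate <- !is.finite(sdev) || sdev < 1e-12
  if (degenerate) {
    warning("degenerate null: all null modularity values identical")
  }
  z <- if (degenerate) NA_real_ else (res$obs$Q - mu) / sdev
  structure(list(z = z, Q_obs = res$obs$Q, partition = res$obs,
                 null_mean = mu, null_sd = sdev, n_null = n_null,
                 significant = isTRUE(z >= 2), degenerate = degenerate,
                 seed = seed),
            class = "standardized_Q")
}

#' @export
print.standardized_Q <- function(x, ...) {
  cat(sprintf(
    "<standardized_Q> Q = %.4f  null = %.4f +/- %.4f  st.Q = %s%s\n",
    x$Q_obs, x$null_mean, x$null_sd,
    if (x$degenerate) "NA (degenerate null)" else sprintf("%.2f", x$z),
    if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Monte-Carlo comparison of a metric between two layers
#'
#' Tests whether the observed metric difference between two layers is lower
#' or higher than expected by chance: each layer is randomized with its own
#' fixed-margin null model, the metric difference is recomputed on each of
#' the `n` paired draws, and a two-sided pseudocount p-value is reported
#' (distance from the null-difference mean).
#'
#' @param A,B Two [layer_matrix()] objects (or count matrices).
#' @param metric_fn Function mapping a matrix to a `metric_value` or number.
#' @param n Number of randomizations (default 999).
#' @param alpha Decision level (default 0.05).
#' @param seed Optional seed.
#' @return A `layer_comparison`: `observed_diff` = metric(A) - metric(B),
#'   null differences, p-value, decision flag.
#' @export
layer_difference_test <- function(A, B, metric_fn, n = 999, alpha = 0.05,
                                  seed = NULL) {
  value_a <- metric_num(metric_fn(A))
  value_b <- metric_num(metric_fn(B))
  observed <- value_a - value_b
  with_seed(seed, {
    draws_a <- null_draws_like(A, n)
    draws_b <- null_draws_like(B, n)
    diffs <- vapply(seq_len(n), function(k) {
      na <- tryCatch(metric_num(metric_fn(draws_a[[k]])),
                     antnets_undefined_metric = function(e) NA_real_)
      nb <- tryCatch(metric_num(metric_fn(draws_b[[k]])),
                     antnets_undefined_metric = function(e) NA_real_)
      na - nb
    }, numeric(1))
  })
  excluded <- sum(is.na(diffs))
  diffs <- diffs[!is.na(diffs)]
  p <- null_p_value(observed, diffs, "two-sided")
  structure(list(layer_a = attr(A, "resource"), layer_b = attr(B, "resource"),
                 value_a = value_a, value_b = value_b,
                 observed_diff = observed, null_diffs = diffs,
                 p_value = p, n = n, n_excluded = excluded,
                 significant = p <= alpha, alpha = alpha, seed = seed),
            class = "layer_comparison")
}

#' @export
print.layer_comparison <- function(x, ...) {
  cat(sprintf(
    "<layer_comparison> %s (%.4f) vs %s (%.4f): diff = %.4f, P = %.4g%s\n",
    x$layer_a %||% "A", x$value_a, x$layer_b %||% "B", x$value_b,
    x$observed_diff, x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
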