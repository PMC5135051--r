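## Per-site descriptors, Poisson GLM comparisons, degree cores, PERMANOVA
## on core composition, and NMDS ordination.

#' Per-site network descriptors
#'
#' Size (number of interacting species, plants + ants), richness (number of
#' distinct interacting species pairs) and frequency (number of events) of
#' one site-level layer.
#'
#' @param events Validated event data.frame.
#' @param resource One of [resource_types()], or `NULL` for all events.
#' @param site Site id.
#' @return One-row data.frame: `site_id, resource, size, richness,
#'   frequency, empty`.
#' @export
site_descriptors <- function(events, resource = NULL, site) {
  events <- validate_events(events)
  if (!site %in% events$site_id) {
    stop_validation(paste0("site '", site, "' not present in events"))
  }
  L <- tryCatch(build_layer(events, resource, sites = site),
                antnets_empty_layer = function(e) NULL)
  res_lab <- if (is.null(resource)) "multilayer" else resource
  if (is.null(L)) {
    return(data.frame(site_id = site, resource = res_lab, size = 0L,
                      richness = 0L, frequency = 0L, empty = TRUE))
  }
  data.frame(site_id = site, resource = res_lab,
             size = nrow(L) + ncol(L),
             richness = sum(L > 0),
             frequency = sum(L),
             empty = FALSE)
}

#' Descriptor table over sites and resource types
#'
#' @param events Validated event data.frame.
#' @param resources Resource types to include (default: EFN, flower,
#'   trophobiont, matching the descriptor analysis that drops the sparse
#'   fruit layer and the visit background).
#' @return Data.frame with one row per site x resource.
#' @export
descriptor_table <- function(events,
                             resources = c("EFN", "flower", "trophobiont")) {
  events <- validate_events(events)
  sites <- sort_species(events$site_id)
  do.call(rbind, lapply(resources, function(res) {
    do.call(rbind, lapply(sites, function(s) {
      site_descriptors(events, res, s)
    }))
  }))
}

#' Poisson GLM test of a descriptor against resource type
#'
#' Fits a log-link Poisson GLM of the chosen count descriptor on resource
#' type and compares it with the intercept-only model by analysis of
#' deviance (chi-squared on `levels - 1` df).
#'
#' @param descriptors Data.frame from [descriptor_table()] (columns
#'   `resource` and the response).
#' @param response `"size"`, `"richness"`, or `"frequency"`.
#' @return List: `deviance` (deviance difference), `df`, `p_value`,
#'   `model` (the fitted GLM).
#' @export
poisson_glm_test <- function(descriptors,
                             response = c("size", "richness", "frequency")) {
  response <- match.arg(response)
  y <- descriptors[[response]]
  if (any(y != floor(y)) || any(y < 0)) {
    stop_validation("Poisson GLM response must be non-negative integers")
  }
  if (length(unique(descriptors$resource)) < 2L) {
    stop_validation("need at least two resource levels")
  }
  dat <- data.frame(y = y, resource = factor(descriptors$resource))
  fit <- glm(y ~ resource, family = poisson(), data = dat)
  fit0 <- glm(y ~ 1, family = poisson(), data = dat)
  dev <- fit0$deviance - fit$deviance
  df <- fit0$df.residual - fit$df.residual
  list(deviance = dev, df = df,
       p_value = pchisq(dev, df, lower.tail = FALSE), model = fit)
}

## ------------------------------------------------------------ cores ------

#' Extract the core of high-degree species
#'
#' Core species are those whose binary degree exceeds the network-average
#' degree (strictly greater). By default the threshold is the mean degree
#' pooled over both guilds; `per_guild = TRUE` applies within-guild means
#' instead.
#'
#' @param A A [layer_matrix()] or count matrix.
#' @param per_guild Use separate plant and ant thresholds (default FALSE).
#' @return A `core_set`: named degree vectors `core_plants`, `core_ants`
#'   (members only), the `threshold`(s), and matrix provenance.
#' @export
extract_core <- function(A, per_guild = FALSE) {
  deg <- degree_centrality(A)
  if (per_guild) {
    thr_p <- mean(deg$plants); thr_a <- mean(deg$ants)
  } else {
    thr_p <- thr_a <- mean(c(deg$plants, deg$ants))
  }
  structure(list(
    core_plants = deg$plants[deg$plants > thr_p],
    core_ants = deg$ants[deg$ants > thr_a],
    threshold = if (per_guild) c(plants = thr_p, ants = thr_a)
                else c(pooled = thr_p),
    resource = attr(A, "resource"),
    sites = attr(A, "sites")
  ), class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("<core_set> %s: %d core ants, %d core plants (threshold %s)\n",
              x$resource %||% "?", length(x$core_ants),
              length(x$core_plants),
              paste(sprintf("%.2f", x$threshold), collapse = "/")))
  invisible(x)
}

#' Per-site, per-resource core sets
#'
#' Builds each site-level resource layer and extracts its degree core.
#' Site-resource combinations with no events are skipped.
#'
#' @param events Validated event data.frame.
#' @param resources Resource types (default EFN, flower, trophobiont).
#' @param per_guild Passed to [extract_core()].
#' @return List of `core_set` objects, each tagged with `site_id`.
#' @export
site_cores <- function(events, resources = c("EFN", "flower", "trophobiont"),
                       per_guild = FALSE) {
  events <- validate_events(events)
  sites <- sort_species(events$site_id)
  cores <- list()
  for (res in resources) {
    for (s in sites) {
      L <- tryCatch(build_layer(events, res, sites = s),
                    antnets_empty_layer = function(e) NULL)
      if (is.null(L)) next
      cs <- extract_core(L, per_guild = per_guild)
      cs$site_id <- s
      cores[[length(cores) + 1L]] <- cs
    }
  }
  cores
}

core_incidence <- function(cores, guild = c("ants", "plants"),
                           weighted = FALSE) {
  guild <- match.arg(guild)
  field <- if (guild == "ants") "core_ants" else "core_plants"
  keep <- vapply(cores, function(cs) length(cs[[field]]) > 0, logical(1))
  cores <- cores[keep]
  if (length(cores) == 0L) stop_validation("all cores are empty")
  species <- sort_species(unlist(lapply(cores, function(cs) names(cs[[field]]))))
  X <- matrix(0, length(cores), length(species),
              dimnames = list(NULL, species))
  for (k in seq_along(cores)) {
    v <- cores[[k]][[field]]
    X[k, names(v)] <- if (weighted) v else 1
  }
  groups <- vapply(cores, function(cs) cs$resource %||% NA_character_,
                   character(1))
  sites <- vapply(cores, function(cs) cs$site_id %||% NA_character_,
                  character(1))
  list(X = X, groups = factor(groups), sites = sites, n_dropped = sum(!keep))
}

## -------------------------------------------------------- PERMANOVA ------

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance (Anderson 2001): the
#' total sum of squared distances is partitioned into between- and
#' within-group components, `pseudo_F = (SS_b/(a-1)) / (SS_w/(n-a))`,
#' `R2 = SS_b/SS_total`, with a p-value from free permutation of the
#' observations. Passing an explicit permutation matrix (rows =
#' permutations, typically all `n!` of them including the identity) yields
#' the exhaustive-enumeration p-value.
#'
#' @param d A `dist` or symmetric distance matrix.
#' @param groups Grouping factor, one level set per observation.
#' @param n_perm Number of random permutations (default 999).
#' @param seed Optional seed.
#' @param permutations Optional integer matrix of explicit permutations.
#' @return A `permanova_result`: `pseudo_F`, `R2`, `p_value`, `df`,
#'   `n_perm`, `distance` attribute carried from `d` if present.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL,
                      permutations = NULL) {
  D <- as.matrix(d)
  n <- nrow(D)
  groups <- factor(groups)
  if (length(groups) != n) stop_validation("one group label per observation")
  a <- nlevels(groups)
  if (a < 2L) stop_antnets("need at least two groups", "antnets_degenerate_design")
  if (any(table(groups) < 1L)) stop_antnets("empty group", "antnets_degenerate_design")
  D2 <- D^2
  ss_total <- sum(D2[upper.tri(D2)]) / n
  ss_within_of <- function(g) {
    s <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1L) {
        s <- s + sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / length(idx)
      }
    }
    s
  }
  f_of <- function(g) {
    ssw <- ss_within_of(g)
    ssb <- ss_total - ssw
    (ssb / (a - 1)) / (ssw / (n - a))
  }
  ssw <- ss_within_of(groups)
  ssb <- ss_total - ssw
  pseudo_F <- (ssb / (a - 1)) / (ssw / (n - a))
  R2 <- ssb / ss_total
  eps <- 1e-12
  if (!is.null(permutations)) {
    Fs <- apply(permutations, 1L, function(p) f_of(groups[p]))
    p_value <- mean(Fs >= pseudo_F - eps)
    n_perm <- nrow(permutations)
  } else {
    Fs <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
      f_of(groups[sample.int(n)])
    }, numeric(1)))
    p_value <- (1 + sum(Fs >= pseudo_F - eps)) / (n_perm + 1)
  }
  structure(list(pseudo_F = pseudo_F, R2 = R2, p_value = p_value,
                 df = c(between = a - 1L, within = n - a),
                 n_perm = n_perm, n = n, seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "<permanova_result> pseudo-F(%d, %d) = %.3f  R2 = %.3f  p = %.4g (n = %d, %d permutations)\n",
    x$df["between"], x$df["within"], x$pseudo_F, x$R2, x$p_value, x$n,
    x$n_perm))
  invisible(x)
}

#' PERMANOVA on core composition across resource layers
#'
#' Builds a (site x resource) incidence table of core membership for one
#' guild, computes pairwise distances (Jaccard on presence/absence by
#' default, Bray-Curtis on degree-weighted incidence as an alternative) and
#' tests the resource grouping with [permanova()]. Site-resource cores that
#' are empty for the guild are dropped (they carry no composition); the
#' dropped count is reported.
#'
#' @param cores List of `core_set` objects from [site_cores()].
#' @param guild `"ants"` or `"plants"`.
#' @param distance `"jaccard"` (binary) or `"bray"` (degree-weighted).
#' @param n_perm Permutations (default 999).
#' @param seed Optional seed.
#' @return A `permanova_result` with extra fields `guild`, `distance`,
#'   `n_dropped`, and the incidence table as `incidence`.
#' @export
core_similarity_permanova <- function(cores, guild = c("ants", "plants"),
                                      distance = c("jaccard", "bray"),
                                      n_perm = 999, seed = NULL) {
  guild <- match.arg(guild)
  distance <- match.arg(distance)
  inc <- core_incidence(cores, guild, weighted = distance == "bray")
  if (nlevels(droplevels(inc$groups)) < 2L || nrow(inc$X) < 3L) {
    stop_antnets("fewer than two resource groups with non-empty cores",
                 "antnets_degenerate_design")
  }
  d <- vegan::vegdist(inc$X, method = distance,
                      binary = distance == "jaccard")
  res <- permanova(d, droplevels(inc$groups), n_perm = n_perm, seed = seed)
  res$guild <- guild
  res$distance <- distance
  res$n_dropped <- inc$n_dropped
  res$incidence <- inc$X
  res$groups <- droplevels(inc$groups)
  res$sites <- inc$sites
  res
}

## ------------------------------------------------------------ NMDS -------

#' Nonmetric multidimensional scaling
#'
#' Best-of-starts NMDS minimising Kruskal stress-1 (via
#' [vegan::monoMDS()], global model, primary tie treatment): one metric
#' start from classical scaling plus `n_starts - 1` random configurations.
#' Coordinates of the best solution are centered.
#'
#' @param d A `dist` or symmetric distance matrix (at least 3 points).
#' @param k Target dimensionality (default 2).
#' @param n_starts Number of starts (default 20).
#' @param seed Optional seed.
#' @param y0 Optional extra starting configuration (n x k matrix).
#' @return An `nmds_fit`: `points` (n x k, centered), `stress`, `k`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, seed = NULL, y0 = NULL) {
  d <- as.dist(d)
  n <- attr(d, "Size")
  if (n < 3L) stop_validation("NMDS needs at least 3 points")
  if (all(d == 0)) stop_antnets("all distances are zero", "antnets_degenerate_design")
  best <- with_seed(seed, {
    starts <- list()
    cm <- tryCatch(cmdscale(d, k = k), error = function(e) NULL)
    if (!is.null(cm)) {
      if (ncol(cm) < k) cm <- cbind(cm, matrix(0, n, k - ncol(cm)))
      starts[[1L]] <- cm
    }
    if (!is.null(y0)) starts[[length(starts) + 1L]] <- as.matrix(y0)
    while (length(starts) < n_starts) {
      starts[[length(starts) + 1L]] <- matrix(rnorm(n * k), n, k)
    }
    fits <- lapply(starts, function(y) {
      suppressWarnings(vegan::monoMDS(d, y = y, k = k, model = "global"))
    })
    fits[[which.min(vapply(fits, function(f) f$stress, numeric(1)))]]
  })
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  colnames(pts) <- paste0("NMDS", seq_len(k))
  structure(list(points = pts, stress = best$stress, k = k,
                 n_starts = n_starts, seed = seed),
            class = "nmds_fit")
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf("<nmds_fit> k = %d  stress = %.4f  (%d points, %d starts)\n",
              x$k, x$stress, nrow(x$points), x$n_starts))
  invisible(x)
}
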