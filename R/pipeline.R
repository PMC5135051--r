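## End-to-end orchestration: layers, metrics with null-model significance,
## pairwise layer comparisons, descriptors + GLMs, cores + PERMANOVA + NMDS,
## and machine-readable report output.

#' Pipeline configuration
#'
#' Defaults mirror the reported analysis protocol (999 null draws for
#' metric significance and layer comparisons, 1000 modularity values for
#' standardized Q, 1000 annealing restarts, 999 permutations). `fast = TRUE`
#' switches to reduced counts (99 / 50 / 3) suitable for routine checks and
#' continuous testing.
#'
#' @param n_null Null draws for metric significance and layer comparisons.
#' @param n_null_q Null draws for standardized modularity.
#' @param q_restarts Annealing restarts per modularity search.
#' @param q_config A [quanbimo_config()].
#' @param n_perm PERMANOVA permutations.
#' @param nmds_starts NMDS starts.
#' @param alpha Decision level.
#' @param include_fruit Include the fruit layer in pairwise comparisons
#'   (default FALSE: it is typically too small to compare reliably).
#' @param core_distance `"jaccard"` or `"bray"` for core composition.
#' @param seed Master seed of the whole run.
#' @param fast Use reduced resampling counts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_null = if (fast) 99 else 999,
                            n_null_q = if (fast) 50 else 1000,
                            q_restarts = if (fast) 3 else 1000,
                            q_config = quanbimo_config(),
                            n_perm = 999,
                            nmds_starts = 20,
                            alpha = 0.05,
                            include_fruit = FALSE,
                            core_distance = "jaccard",
                            seed = 1,
                            fast = FALSE) {
  structure(list(n_null = n_null, n_null_q = n_null_q,
                 q_restarts = q_restarts, q_config = q_config,
                 n_perm = n_perm, nmds_starts = nmds_starts, alpha = alpha,
                 include_fruit = include_fruit,
                 core_distance = core_distance, seed = seed, fast = fast),
            class = "pipeline_config")
}

#' Run the full multilayer analysis pipeline
#'
#' Builds all resource layers and the pooled multilayer matrix; computes
#' H2', WNODF and Morisita-Horn overlap with fixed-margin null significance
#' and modularity with standardized Q for every usable matrix; compares the
#' reward layers pairwise with the Monte-Carlo difference test; fits the
#' Poisson GLMs of per-site descriptors; extracts per-site degree cores and
#' tests their composition across layers with PERMANOVA, ordinating with
#' NMDS. The whole run is a pure function of `(events, config)`.
#'
#' @param events Validated event data.frame (or a path to an events CSV).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for `report.json` and CSV
#'   tables.
#' @return A `pipeline_report` list.
#' @export
run_pipeline <- function(events, config = pipeline_config(),
                         out_dir = NULL) {
  if (is.character(events)) events <- read_events(events)
  events <- validate_events(events)
  seeds <- with_seed(config$seed, spawn_seeds(20000))
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    seeds[si]
  }

  ml <- build_multilayer(events)
  mats <- c(list(multilayer = ml$pooled),
            Filter(Negate(is.null), ml$layers))

  ## Table-1 analogue: metrics + significance per matrix
  metrics <- list()
  for (nm in names(mats)) {
    M <- mats[[nm]]
    if (nrow(M) < 2L || ncol(M) < 2L) next
    h2 <- metric_significance(M, h2prime, config$n_null, "greater",
                              seed = next_seed())
    wn <- metric_significance(M, wnodf, config$n_null, "greater",
                              seed = next_seed())
    ho <- metric_significance(M, horn_overlap, config$n_null, "two-sided",
                              seed = next_seed())
    sq <- standardized_Q(M, n_null = config$n_null_q,
                         n_iter = config$q_restarts,
                         config = config$q_config, seed = next_seed())
    metrics[[nm]] <- list(network = nm, n_plants = nrow(M),
                          n_ants = ncol(M), events = sum(M),
                          H2 = h2, WNODF = wn, Horn = ho, Q = sq)
  }

  ## Table-2 analogue: pairwise comparisons among reward layers
  cmp_layers <- c("EFN", "trophobiont", "flower")
  if (config$include_fruit) cmp_layers <- c(cmp_layers, "fruit")
  cmp_layers <- cmp_layers[vapply(cmp_layers, function(l) {
    !is.null(ml$layers[[l]]) && nrow(ml$layers[[l]]) >= 2 &&
      ncol(ml$layers[[l]]) >= 2
  }, logical(1))]
  q_metric <- function(m) best_of(m, n_iter = config$q_restarts,
                                  config = config$q_config,
                                  seed = next_seed())$Q
  metric_fns <- list(Q = q_metric, WNODF = wnodf, H2 = h2prime,
                     Horn = horn_overlap)
  comparisons <- list()
  if (length(cmp_layers) >= 2L) {
    pairs <- utils::combn(cmp_layers, 2, simplify = FALSE)
    for (pr in pairs) {
      for (mn in names(metric_fns)) {
        cmp <- layer_difference_test(ml$layers[[pr[1L]]], ml$layers[[pr[2L]]],
                                     metric_fns[[mn]], n = config$n_null,
                                     alpha = config$alpha,
                                     seed = next_seed())
        cmp$metric <- mn
        comparisons[[paste(pr[1L], pr[2L], mn, sep = "_")]] <- cmp
      }
    }
  }

  ## descriptors + Poisson GLMs
  descriptors <- descriptor_table(events)
  glms <- lapply(setNames(nm = c("size", "richness", "frequency")),
                 function(resp) poisson_glm_test(descriptors, resp))

  ## cores + PERMANOVA + NMDS
  cores <- site_cores(events)
  core_tests <- list()
  ordinations <- list()
  for (guild in c("ants", "plants")) {
    core_tests[[guild]] <- tryCatch(
      core_similarity_permanova(cores, guild,
                                distance = config$core_distance,
                                n_perm = config$n_perm,
                                seed = next_seed()),
      antnets_degenerate_design = function(e) NULL)
    pt <- core_tests[[guild]]
    if (!is.null(pt) && nrow(pt$incidence) >= 3L) {
      d <- vegan::vegdist(pt$incidence, method = config$core_distance,
                          binary = config$core_distance == "jaccard")
      ordinations[[guild]] <- tryCatch(
        nmds(d, k = 2, n_starts = config$nmds_starts, seed = next_seed()),
        antnets_degenerate_design = function(e) NULL,
        antnets_validation_error = function(e) NULL)
    }
  }

  report <- structure(list(
    community = list(
      n_events = nrow(events),
      n_sites = length(unique(events$site_id)),
      n_plants = length(unique(events$plant_sp)),
      n_ants = length(unique(events$ant_sp)),
      layer_mix = as.list(table(factor(events$resource,
                                       resource_types())) / nrow(events)),
      top5_ant_share = top_ant_share(events, 5)
    ),
    metrics = metrics, comparisons = comparisons,
    descriptors = descriptors, glms = glms,
    cores = cores, core_tests = core_tests, ordinations = ordinations,
    config = config
  ), class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

top_ant_share <- function(events, k) {
  tab <- sort(table(events$ant_sp), decreasing = TRUE)
  sum(tab[seq_len(min(k, length(tab)))]) / nrow(events)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  %d events | %d sites | %d plants x %d ants\n",
              x$community$n_events, x$community$n_sites,
              x$community$n_plants, x$community$n_ants))
  cat(sprintf("  %-12s %6s %8s %7s %7s %7s\n",
              "network", "H2'", "WNODF", "Horn", "Q", "st.Q"))
  for (m in x$metrics) {
    cat(sprintf("  %-12s %6.3f %8.2f %7.3f %7.3f %7s\n", m$network,
                m$H2$observed, m$WNODF$observed, m$Horn$observed, m$Q$Q_obs,
                if (m$Q$degenerate) "NA" else sprintf("%.2f", m$Q$z)))
  }
  for (g in names(x$core_tests)) {
    pt <- x$core_tests[[g]]
    if (!is.null(pt)) {
      cat(sprintf("  core %-7s PERMANOVA R2 = %.3f, p = %.4g\n",
                  g, pt$R2, pt$p_value))
    }
  }
  invisible(x)
}

## ------------------------------------------------------ report output ----

report_to_json_list <- function(report) {
  num <- function(x) unname(as.numeric(x))
  metrics <- lapply(report$metrics, function(m) {
    list(network = m$network, n_plants = m$n_plants, n_ants = m$n_ants,
         events = m$events,
         H2 = num(m$H2$observed), P_H2 = num(m$H2$p_value),
         WNODF = num(m$WNODF$observed), P_WNODF = num(m$WNODF$p_value),
         Horn = num(m$Horn$observed), P_Horn = num(m$Horn$p_value),
         Q = num(m$Q$Q_obs),
         st_Q = if (m$Q$degenerate) NULL else num(m$Q$z),
         Q_null_mean = num(m$Q$null_mean), Q_null_sd = num(m$Q$null_sd))
  })
  comparisons <- lapply(report$comparisons, function(cmp) {
    list(metric = cmp$metric, layer_a = cmp$layer_a, layer_b = cmp$layer_b,
         value_a = num(cmp$value_a), value_b = num(cmp$value_b),
         observed_diff = num(cmp$observed_diff),
         p_value = num(cmp$p_value), significant = cmp$significant)
  })
  glms <- lapply(report$glms, function(g) {
    list(deviance = num(g$deviance), df = g$df, p_value = num(g$p_value))
  })
  core_tests <- lapply(report$core_tests, function(pt) {
    if (is.null(pt)) return(NULL)
    list(pseudo_F = num(pt$pseudo_F), R2 = num(pt$R2),
         p_value = num(pt$p_value), n = pt$n, n_perm = pt$n_perm,
         distance = pt$distance, n_dropped = pt$n_dropped)
  })
  ordinations <- lapply(report$ordinations, function(o) {
    if (is.null(o)) return(NULL)
    list(stress = num(o$stress), k = o$k,
         points = apply(unname(o$points), 1L, num, simplify = FALSE))
  })
  list(community = report$community, metrics = metrics,
       comparisons = comparisons, glms = glms, core_tests = core_tests,
       ordinations = ordinations,
       config = list(n_null = report$config$n_null,
                     n_null_q = report$config$n_null_q,
                     q_restarts = report$config$q_restarts,
                     n_perm = report$config$n_perm,
                     seed = report$config$seed))
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` plus CSV tables (metrics, comparisons, descriptors,
#' core membership, PERMANOVA summaries, NMDS coordinates) into `out_dir`.
#' Output is deterministic: no timestamps or absolute paths are embedded.
#'
#' @param report A `pipeline_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_to_json_list(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  mt <- do.call(rbind, lapply(report$metrics, function(m) {
    data.frame(network = m$network, n_plants = m$n_plants,
               n_ants = m$n_ants, events = m$events,
               H2 = m$H2$observed, P_H2 = m$H2$p_value,
               WNODF = m$WNODF$observed, P_WNODF = m$WNODF$p_value,
               Horn = m$Horn$observed, P_Horn = m$Horn$p_value,
               Q = m$Q$Q_obs,
               st_Q = if (m$Q$degenerate) NA_real_ else m$Q$z)
  }))
  write.csv(mt, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  if (length(report$comparisons)) {
    ct <- do.call(rbind, lapply(report$comparisons, function(cmp) {
      data.frame(metric = cmp$metric, layer_a = cmp$layer_a,
                 layer_b = cmp$layer_b, value_a = cmp$value_a,
                 value_b = cmp$value_b, observed_diff = cmp$observed_diff,
                 p_value = cmp$p_value, significant = cmp$significant)
    }))
    write.csv(ct, file.path(out_dir, "comparisons.csv"), row.names = FALSE)
  }
  write.csv(report$descriptors, file.path(out_dir, "descriptors.csv"),
            row.names = FALSE)
  core_rows <- do.call(rbind, lapply(report$cores, function(cs) {
    rbind(
      if (length(cs$core_ants))
        data.frame(site_id = cs$site_id, resource = cs$resource,
                   guild = "ants", species = names(cs$core_ants),
                   degree = unname(cs$core_ants)),
      if (length(cs$core_plants))
        data.frame(site_id = cs$site_id, resource = cs$resource,
                   guild = "plants", species = names(cs$core_plants),
                   degree = unname(cs$core_plants))
    )
  }))
  if (!is.null(core_rows)) {
    write.csv(core_rows, file.path(out_dir, "cores.csv"), row.names = FALSE)
  }
  pt_rows <- do.call(rbind, lapply(names(report$core_tests), function(g) {
    pt <- report$core_tests[[g]]
    if (is.null(pt)) return(NULL)
    data.frame(guild = g, pseudo_F = pt$pseudo_F, R2 = pt$R2,
               p_value = pt$p_value, n = pt$n, n_perm = pt$n_perm,
               distance = pt$distance, n_dropped = pt$n_dropped)
  }))
  if (!is.null(pt_rows)) {
    write.csv(pt_rows, file.path(out_dir, "permanova.csv"), row.names = FALSE)
  }
  for (g in names(report$ordinations)) {
    o <- report$ordinations[[g]]
    if (is.null(o)) next
    pt <- report$core_tests[[g]]
    df <- data.frame(site_id = pt$sites, resource = as.character(pt$groups),
                     o$points)
    write.csv(df, file.path(out_dir, paste0("nmds_", g, ".csv")),
              row.names = FALSE)
  }
  invisible(out_dir)
}
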