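## Synthetic multi-site, multilayer community generator with planted,
## recoverable structure. Defaults emulate the scale of the field study the
## pipeline is designed around: 7 sites, 78 plant and 30 ant species, 795
## events with mix 66% visit / 20% EFN / 8% flower / 5% trophobiont /
## 1% fruit, strongly skewed ant frequencies, a small shared ant core, and
## layer-specific plant cores.

#' Generator configuration
#'
#' @param n_sites,n_plants,n_ants Community dimensions.
#' @param total_events Total number of interaction events emitted.
#' @param layer_mix Named probability vector over [resource_types()].
#' @param abundance_sigma Log-normal sigma of the species weights (larger =
#'   more skewed frequencies).
#' @param specialization Trait-matching strength (>= 0), acting as the
#'   inverse bandwidth of a Gaussian kernel on latent traits: pair
#'   propensity is damped by
#'   `exp(-((specialization * mult_layer)^2 / 2) * (trait_p - trait_a)^2)`.
#'   Near 0 all pairings are equally likely; large values concentrate each
#'   plant on its trait-matched ants.
#' @param layer_spec_mult Named per-layer multipliers of `specialization`
#'   (visits are a weakly specialized background; trophobionts the most
#'   specialized layer).
#' @param n_planted_modules Number of planted modules per layer (0 = none;
#'   modules are trait-aligned bands shared by both guilds).
#' @param module_bonus Within-module propensity multiplier when modules are
#'   planted.
#' @param core_ants_shared Number of ants boosted in every layer (the
#'   planted shared core). Core ants forage as massively recruiting
#'   generalists: their weight is multiplied by `core_boost` and their
#'   trait-matching sensitivity is attenuated by `core_matching`, so the
#'   same few species stay central in every layer.
#' @param core_boost Weight multiplier for core species.
#' @param core_matching Fraction of trait-matching sensitivity retained by
#'   core ants (small = broad generalist foraging).
#' @param plant_core_disjoint Plant layer-cores disjoint across EFN, flower
#'   and trophobiont layers (TRUE) or shared (FALSE).
#' @param plant_core_size Plants boosted per resource layer.
#' @param fruit_ants Number of ant species able to appear in the sparse
#'   fruit layer.
#' @param site_presence Probability a plant species occurs at a site.
#' @param provision Named probability that a plant species offers each
#'   reward type (every plant can be visited). Layer-core plants always
#'   provide their layer's reward; providing none zeroes the plant's weight
#'   in that layer. Defaults emulate communities where the reward layers
#'   are carried by largely different plant subsets.
#' @param seed Integer seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_sites = 7, n_plants = 78, n_ants = 30,
                             total_events = 795,
                             layer_mix = c(EFN = 0.20, flower = 0.08,
                                           fruit = 0.01, trophobiont = 0.05,
                                           visit = 0.66),
                             abundance_sigma = 0.8,
                             specialization = 6,
                             layer_spec_mult = c(EFN = 1, flower = 2,
                                                 fruit = 2, trophobiont = 4,
                                                 visit = 0.5),
                             n_planted_modules = 0,
                             module_bonus = 3,
                             core_ants_shared = 3,
                             core_boost = 4,
                             core_matching = 0.1,
                             plant_core_disjoint = TRUE,
                             plant_core_size = 6,
                             fruit_ants = 4,
                             site_presence = 0.7,
                             provision = c(EFN = 0.22, flower = 0.29,
                                           fruit = 0.05, trophobiont = 0.23,
                                           visit = 1),
                             seed = NULL) {
  cfg <- list(n_sites = n_sites, n_plants = n_plants, n_ants = n_ants,
              total_events = total_events, layer_mix = layer_mix,
              abundance_sigma = abundance_sigma,
              specialization = specialization,
              layer_spec_mult = layer_spec_mult,
              n_planted_modules = n_planted_modules,
              module_bonus = module_bonus,
              core_ants_shared = core_ants_shared, core_boost = core_boost,
              core_matching = core_matching,
              plant_core_disjoint = plant_core_disjoint,
              plant_core_size = plant_core_size, fruit_ants = fruit_ants,
              site_presence = site_presence, provision = provision,
              seed = seed)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$total_events <= 0) stop_validation("total_events must be positive")
  if (!setequal(names(cfg$layer_mix), resource_types())) {
    stop_validation("layer_mix must be named over the five resource types")
  }
  if (abs(sum(cfg$layer_mix) - 1) > 1e-8) {
    stop_validation("layer_mix must sum to 1")
  }
  if (cfg$n_planted_modules > min(cfg$n_plants, cfg$n_ants)) {
    stop_validation("more planted modules than species")
  }
  if (cfg$specialization < 0) stop_validation("specialization must be >= 0")
  if (!setequal(names(cfg$provision), resource_types()) ||
      any(cfg$provision < 0 | cfg$provision > 1)) {
    stop_validation("provision must be probabilities named over the five resource types")
  }
  n_layer_cores <- if (cfg$plant_core_disjoint) 3L else 1L
  if (cfg$plant_core_size * n_layer_cores > cfg$n_plants) {
    stop_validation("plant cores larger than the plant pool")
  }
  invisible(cfg)
}

#' Generate a synthetic event table with known ground truth
#'
#' Species weights are log-normal; the propensity of a (site, plant, ant,
#' resource) event is proportional to site weight x plant presence x plant
#' weight x ant weight x a Gaussian trait-matching kernel (bandwidth set by
#' the specialization knob and a per-layer multiplier) x planted module and
#' core bonuses; events are a single multinomial allocation of
#' `total_events` over that propensity array. Worker counts are
#' `1 + geometric`, inflated for core ants. With a fixed seed the emitted
#' table is identical across calls.
#'
#' @param config A [generator_config()].
#' @return List with `events` (validated data.frame) and `truth` (planted
#'   structure: weights, traits, core identities, module bands, site
#'   weights, presence matrix).
#' @export
generate_events <- function(config = generator_config()) {
  validate_generator_config(config)
  with_seed(config$seed, {
    n_p <- config$n_plants; n_a <- config$n_ants; n_s <- config$n_sites
    plants <- sprintf("P%03d", seq_len(n_p))
    ants <- sprintf("A%02d", seq_len(n_a))
    sites <- sprintf("S%d", seq_len(n_s))

    trait_p <- runif(n_p)
    trait_a <- runif(n_a)
    w_p <- rlnorm(n_p, 0, config$abundance_sigma)
    w_a <- rlnorm(n_a, 0, config$abundance_sigma)
    names(w_p) <- plants; names(w_a) <- ants

    core_ants <- character(0)
    if (config$core_ants_shared > 0) {
      core_ants <- ants[order(-w_a)][seq_len(config$core_ants_shared)]
      w_a[core_ants] <- w_a[core_ants] * config$core_boost
    }

    reward_layers <- c("EFN", "flower", "trophobiont")
    plant_cores <- list()
    if (config$plant_core_size > 0) {
      if (config$plant_core_disjoint) {
        pool <- sample(plants)
        for (k in seq_along(reward_layers)) {
          plant_cores[[reward_layers[k]]] <-
            pool[((k - 1) * config$plant_core_size + 1):(k * config$plant_core_size)]
        }
      } else {
        shared <- sample(plants, config$plant_core_size)
        for (res in reward_layers) plant_cores[[res]] <- shared
      }
    }

    modules_p <- modules_a <- NULL
    if (config$n_planted_modules > 1) {
      k <- config$n_planted_modules
      modules_p <- setNames(ceiling(rank(trait_p, ties.method = "first") / n_p * k), plants)
      modules_a <- setNames(ceiling(rank(trait_a, ties.method = "first") / n_a * k), ants)
    }

    fruit_set <- ants[order(-w_a)][seq_len(min(config$fruit_ants, n_a))]

    # which plants offer which reward (visits reach every plant)
    provides <- sapply(resource_types(), function(res) {
      rbinom(n_p, 1, config$provision[[res]]) == 1
    })
    rownames(provides) <- plants
    for (res in names(plant_cores)) provides[plant_cores[[res]], res] <- TRUE

    site_w <- rgamma(n_s, 2, 1)
    site_w <- site_w / sum(site_w)
    presence <- matrix(rbinom(n_s * n_p, 1, config$site_presence), n_s, n_p,
                       dimnames = list(sites, plants))
    # every plant occurs somewhere
    absent <- which(colSums(presence) == 0)
    for (i in absent) presence[sample.int(n_s, 1), i] <- 1

    kernel_base <- outer(trait_p, trait_a, function(x, y) (x - y)^2)
    prob <- array(0, dim = c(n_s, n_p, n_a, 5),
                  dimnames = list(sites, plants, ants, resource_types()))
    for (res in resource_types()) {
      # Gaussian trait-matching kernel with bandwidth 1/(spec * multiplier):
      # specialization ~0 is flat, large values approach one-partner matching
      beta <- (config$specialization * config$layer_spec_mult[[res]])^2 / 2
      K <- exp(-beta * kernel_base)
      # core ants recruit massively and forage broadly: their kernel keeps
      # only a fraction core_matching of the inverse bandwidth
      beta_core <- (config$specialization * config$layer_spec_mult[[res]] *
                      config$core_matching)^2 / 2
      K[, ants %in% core_ants] <-
        exp(-beta_core * kernel_base[, ants %in% core_ants])
      W <- outer(w_p * provides[, res], w_a) * K
      if (res %in% names(plant_cores)) {
        W[plant_cores[[res]], ] <- W[plant_cores[[res]], ] * config$core_boost
      }
      if (!is.null(modules_p)) {
        same <- outer(modules_p, modules_a, "==")
        W <- W * ifelse(same, config$module_bonus, 1)
      }
      if (res == "fruit") W[, setdiff(ants, fruit_set)] <- 0
      for (s in seq_len(n_s)) {
        prob[s, , , res] <- site_w[s] * presence[s, ] * W
      }
      # normalize each layer's mass so realized shares follow layer_mix
      tot <- sum(prob[, , , res])
      if (tot > 0) prob[, , , res] <- prob[, , , res] / tot *
          config$layer_mix[[res]]
    }

    counts <- rmultinom(1, config$total_events, as.vector(prob))[, 1L]
    idx <- which(counts > 0)
    reps <- counts[idx]
    coords <- arrayInd(idx, dim(prob))
    n_ev <- sum(reps)
    site_v <- rep(sites[coords[, 1L]], reps)
    plant_v <- rep(plants[coords[, 2L]], reps)
    ant_v <- rep(ants[coords[, 3L]], reps)
    res_v <- rep(resource_types()[coords[, 4L]], reps)
    is_core <- ant_v %in% core_ants
    workers <- 1L + rgeom(n_ev, ifelse(is_core, 0.25, 0.5))
    events <- data.frame(
      site_id = site_v,
      plot_id = paste0(site_v, "-p", sample.int(5, n_ev, replace = TRUE)),
      season = sample(c("Jan", "Apr", "Jul", "Oct"), n_ev, replace = TRUE),
      plant_sp = plant_v,
      ant_sp = ant_v,
      resource = res_v,
      workers = workers,
      stringsAsFactors = FALSE
    )
    truth <- list(core_ants = core_ants, plant_cores = plant_cores,
                  plant_weights = w_p, ant_weights = w_a,
                  plant_traits = setNames(trait_p, plants),
                  ant_traits = setNames(trait_a, ants),
                  modules_plants = modules_p, modules_ants = modules_a,
                  fruit_ants = fruit_set, site_weights = setNames(site_w, sites),
                  presence = presence, provides = provides, config = config)
    list(events = validate_events(events), truth = truth)
  })
}

#' Planted modular count matrix
#'
#' Rows and columns are assigned round-robin to `k` modules; within-module
#' cells have propensity `1 - noise`, between-module cells
#' `noise / (k - 1)`, and `total` events are allocated by one multinomial
#' draw. At `noise = 0` the matrix is exactly block-diagonal; at
#' `noise = (k - 1)/k` all cells are equiprobable (independence limit).
#' All-zero rows/columns are dropped (with their assignments).
#'
#' @param n_rows,n_cols Matrix dimensions.
#' @param k Number of planted modules.
#' @param noise Between-module leakage in `[0, 1)`.
#' @param total Total count.
#' @param seed Optional seed.
#' @return List with `matrix` (a [layer_matrix()]) and `assignment` (named
#'   module vector over the surviving species).
#' @export
planted_modular_matrix <- function(n_rows, n_cols, k, noise, total,
                                   seed = NULL) {
  if (k > min(n_rows, n_cols)) stop_validation("more modules than rows/columns")
  if (noise < 0 || noise >= 1) stop_validation("noise must be in [0, 1)")
  rn <- sprintf("R%02d", seq_len(n_rows))
  cn <- sprintf("C%02d", seq_len(n_cols))
  mod_r <- ((seq_len(n_rows) - 1L) %% k) + 1L
  mod_c <- ((seq_len(n_cols) - 1L) %% k) + 1L
  same <- outer(mod_r, mod_c, "==")
  W <- ifelse(same, 1 - noise, if (k > 1) noise / (k - 1) else 0)
  counts <- with_seed(seed, rmultinom(1, total, as.vector(W)))
  M <- matrix(counts, n_rows, n_cols, dimnames = list(rn, cn))
  keep_r <- rowSums(M) > 0; keep_c <- colSums(M) > 0
  M <- M[keep_r, keep_c, drop = FALSE]
  assignment <- c(setNames(mod_r[keep_r], rn[keep_r]),
                  setNames(mod_c[keep_c], cn[keep_c]))
  list(matrix = layer_matrix(M, resource = "synthetic"),
       assignment = assignment)
}

#' Planted nested count matrix
#'
#' Cell propensity decays geometrically away from the top-left corner
#' (`decay^(i + j)`), optionally restricted to a strict upper-left
#' triangular support, and `total` events are allocated multinomially.
#' Small `decay` and triangular support produce strongly nested weighted
#' matrices; `decay` near 1 without thresholding produces a near-uniform
#' full matrix with little nestedness.
#'
#' @param n_rows,n_cols Matrix dimensions.
#' @param decay Geometric decay in `(0, 1)`.
#' @param total Total count.
#' @param seed Optional seed.
#' @param triangular Restrict support to the upper-left triangle (default
#'   TRUE).
#' @return A [layer_matrix()] (all-zero rows/columns dropped).
#' @export
planted_nested_matrix <- function(n_rows, n_cols, decay, total, seed = NULL,
                                  triangular = TRUE) {
  if (decay <= 0 || decay >= 1) stop_validation("decay must be in (0, 1)")
  i <- seq_len(n_rows) - 1L
  j <- seq_len(n_cols) - 1L
  W <- outer(i, j, function(a, b) decay^(a + b))
  if (triangular) {
    W[outer(i / n_rows, j / n_cols, "+") >= 1] <- 0
  }
  counts <- with_seed(seed, rmultinom(1, total, as.vector(W)))
  M <- matrix(counts, n_rows, n_cols,
              dimnames = list(sprintf("R%02d", seq_len(n_rows)),
                              sprintf("C%02d", seq_len(n_cols))))
  M <- M[rowSums(M) > 0, colSums(M) > 0, drop = FALSE]
  layer_matrix(M, resource = "synthetic")
}
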