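#' Configuration of the synthetic soil-community generator
#'
#' The generator emulates the mesocosm design: two soil systems (NCF, NOF),
#' a heavy-tailed (lognormal) species-abundance distribution in which a
#' fraction of a percent of OTUs carries tens of percent of the reads,
#' multinomial read sampling at fixed depth (post-rarefaction data are
#' depth-equalized by construction), and four replicates per design cell.
#'
#' @param n_otus number of OTUs in the species pool (>= 10).
#' @param depth reads per sample (>= 100; default 10,000; the mesocosm data
#'   were rarefied to 67,899).
#' @param lognormal_mu,lognormal_sigma parameters of the lognormal
#'   species-abundance distribution (log scale); with the default pool of
#'   20,000 OTUs, sigma = 2.5 reproduces the observed partitioning of the
#'   mesocosm soils at the study depth: ~0.1-0.2% of observed OTUs abundant
#'   carrying ~20-30% of reads, ~90% rare carrying ~20%.
#' @param n_replicates samples per design cell.
#' @param seed integer seed; all generator draws derive from it.
#' @return A `community_config` list.
#' @export
community_config <- function(n_otus = 20000, depth = 10000,
                             lognormal_mu = 0, lognormal_sigma = 2.5,
                             n_replicates = 4, seed = 1L) {
  if (n_otus < 10) stop("n_otus must be >= 10")
  if (depth < 100) stop("depth must be >= 100")
  if (lognormal_sigma <= 0) stop("lognormal_sigma must be positive")
  structure(list(n_otus = n_otus, depth = depth,
                 lognormal_mu = lognormal_mu,
                 lognormal_sigma = lognormal_sigma,
                 n_replicates = n_replicates, seed = as.integer(seed)),
            class = "community_config")
}

#' Disturbance scenario acting on a synthetic community
#'
#' A disturbance shifts the true proportions of whole taxon groups by
#' log-fold effects (with per-OTU lognormal jitter so OTU-level tests have
#' heterogeneous signal), optionally time-modulated so the perturbation
#' decays along an impulse-response curve, and can inject NEW OTUs (ids
#' absent from the initial pool) carrying a configured share of the reads.
#'
#' @param treatment one of AMB, DR, FL, FR, HE.
#' @param category_effects named numeric vector of log-fold multipliers for
#'   the groups "abundant", "common", "rare" (missing groups default to 0),
#'   or a groups x timepoints matrix (columns R0, R2, R40, R170).
#' @param new_otu_fraction target relative abundance of invading OTUs at R0
#'   (in `[0, 1)`); by default the invaders persist at that share.
#' @param new_mass_by_time optional length-4 vector of invader shares per
#'   timepoint, overriding the persistent default.
#' @param trajectory_params optional `stability_params`; when supplied, the
#'   vector effects are modulated over timepoints by the magnitude of the
#'   impulse-response curve at model times 1..4 (relative to time 1).
#' @param time_profile length-4 modulation of vector effects over
#'   R0/R2/R40/R170 when no `trajectory_params` is given (default constant).
#' @param effect_jitter_sd sd of the per-OTU lognormal jitter on effects.
#' @param n_new_otus number of distinct invading OTUs.
#' @return A `disturbance_scenario` list.
#' @export
disturbance_scenario <- function(treatment,
                                 category_effects = c(abundant = 0,
                                                      common = 0, rare = 0),
                                 new_otu_fraction = 0,
                                 new_mass_by_time = NULL,
                                 trajectory_params = NULL,
                                 time_profile = rep(1, 4),
                                 effect_jitter_sd = 0.3,
                                 n_new_otus = 100) {
  treatment <- match.arg(treatment, TREATMENTS)
  post_tp <- setdiff(TIMEPOINTS, "initial")
  if (is.matrix(category_effects)) {
    eff <- category_effects
    if (is.null(colnames(eff))) colnames(eff) <- post_tp
  } else {
    bad <- setdiff(names(category_effects), TAXON_GROUPS)
    if (length(bad))
      stop("unknown taxon category in scenario: ", paste(bad, collapse = ", "))
    base <- stats::setNames(rep(0, 3), TAXON_GROUPS)
    base[names(category_effects)] <- category_effects
    modulation <- if (!is.null(trajectory_params)) {
      x <- impulse_response(1:4, trajectory_params)
      abs(x) / max(abs(x[1]), 1e-12)
    } else time_profile
    eff <- outer(base, modulation)
    colnames(eff) <- post_tp
  }
  bad <- setdiff(rownames(eff), TAXON_GROUPS)
  if (length(bad))
    stop("unknown taxon category in scenario: ", paste(bad, collapse = ", "))
  if (new_otu_fraction < 0 || new_otu_fraction >= 1)
    stop("new_otu_fraction must be in [0, 1)")
  if (is.null(new_mass_by_time))
    new_mass_by_time <- rep(new_otu_fraction, 4)
  if (treatment == "AMB" && (any(eff != 0) || any(new_mass_by_time != 0)))
    stop("AMB scenario must have zero effects and no invading OTUs")
  structure(list(treatment = treatment, effects = eff,
                 new_otu_fraction = new_otu_fraction,
                 new_mass_by_time = stats::setNames(new_mass_by_time, post_tp),
                 effect_jitter_sd = effect_jitter_sd,
                 n_new_otus = n_new_otus),
            class = "disturbance_scenario")
}

#' Default disturbance scenarios emulating the mesocosm treatments
#'
#' Ambient is a true null. Heat and flooding are the strong disturbances:
#' they suppress abundant taxa, favor rare taxa and inject invading OTUs at
#' about 20% and 10% relative abundance respectively, persisting through
#' recovery (a community shifted to a new equilibrium). Drought and
#' freeze-thaw are weaker, invader-free, and their effects decay over the
#' recovery period (a community relaxing back toward its initial state).
#'
#' @return Named list of `disturbance_scenario` objects, one per treatment.
#' @export
default_scenarios <- function() {
  list(
    AMB = disturbance_scenario("AMB"),
    DR = disturbance_scenario("DR",
      category_effects = c(abundant = -0.5, rare = 0.5),
      time_profile = c(1, 0.8, 0.5, 0.2)),
    FL = disturbance_scenario("FL",
      category_effects = c(abundant = -1.2, rare = 1.0),
      new_otu_fraction = 0.10,
      time_profile = c(1, 1, 0.9, 0.8)),
    FR = disturbance_scenario("FR",
      category_effects = c(abundant = -0.3, rare = 0.3),
      time_profile = c(1, 0.8, 0.5, 0.2)),
    HE = disturbance_scenario("HE",
      category_effects = c(abundant = -2.0, common = -0.3, rare = 1.5),
      new_otu_fraction = 0.20,
      time_profile = c(1, 1, 0.9, 0.8)))
}

# taxon group each OTU as the downstream analysis will see it: classified
# from the observed initial samples (OTUs unobserved at this depth are
# rare-by-definition and may bloom into detectable NEW-like taxa)
observed_group <- function(initial_table, soil) {
  a <- classify_taxa(relative_abundance(initial_table), soil = soil)
  g <- taxon_group(a$category)
  stats::setNames(g, names(a$category))
}

#' Generate initial (pre-disturbance) communities for both soil systems
#'
#' Draws one set of true OTU proportions per soil from the configured
#' lognormal species-abundance distribution (shared across that soil's
#' initial replicates) and samples each replicate's reads multinomially at
#' fixed depth.
#'
#' @param config a [community_config()].
#' @return An `initial_community` list: `tables` (one `otu_table` per
#'   soil), `true_props` (one named proportion vector per soil), `config`.
#' @export
generate_initial_community <- function(config) {
  stopifnot(inherits(config, "community_config"))
  otu_ids <- sprintf("OTU_%05d", seq_len(config$n_otus))
  out <- withr_seed(config$seed, {
    lapply(stats::setNames(SOILS, SOILS), function(soil) {
      w <- stats::rlnorm(config$n_otus, config$lognormal_mu,
                         config$lognormal_sigma)
      p <- stats::setNames(w / sum(w), otu_ids)
      counts <- stats::rmultinom(config$n_replicates, config$depth, p)
      colnames(counts) <- make_sample_id(soil, NA, "initial",
                                         seq_len(config$n_replicates))
      rownames(counts) <- otu_ids
      md <- data.frame(sample_id = colnames(counts), soil = soil,
                       treatment = "AMB", timepoint = "initial",
                       replicate = seq_len(config$n_replicates))
      list(table = otu_table(counts, md), true_props = p)
    })
  })
  structure(list(tables = lapply(out, `[[`, "table"),
                 true_props = lapply(out, `[[`, "true_props"),
                 config = config),
            class = "initial_community")
}

#' Simulate the full disturbance-recovery sample layout
#'
#' Applies each scenario to both soils' true proportions at every recovery
#' timepoint: taxon-group log-fold effects (with per-OTU jitter) perturb the
#' initial proportions, invading OTUs take their configured share of the
#' community, and reads are drawn multinomially at the configured depth.
#' Effects act on the groups the downstream analysis will recover: each
#' OTU's group comes from classifying the soil's observed initial samples,
#' so OTUs below the detection limit count as rare and can bloom into
#' newly detected taxa after disturbance.
#' The result contains the initial samples plus every treatment x timepoint
#' x replicate cell, with fully populated metadata.
#'
#' @param initial an `initial_community` from [generate_initial_community()].
#' @param scenarios list of `disturbance_scenario`s covering all five
#'   treatments (default [default_scenarios()]).
#' @param config the [community_config()] (defaults to the one stored in
#'   `initial`).
#' @return A single `otu_table` holding all samples of both soils.
#' @export
simulate_disturbance_series <- function(initial, scenarios = default_scenarios(),
                                        config = initial$config) {
  stopifnot(inherits(initial, "initial_community"))
  have <- vapply(scenarios, `[[`, "", "treatment")
  missing_tr <- setdiff(TREATMENTS, have)
  if (length(missing_tr))
    stop("scenarios must cover all treatments; missing: ",
         paste(missing_tr, collapse = ", "))
  post_tp <- setdiff(TIMEPOINTS, "initial")
  count_blocks <- list()
  md_blocks <- list()
  all_new_ids <- character(0)
  withr_seed(config$seed + 1000L, {
    for (soil in SOILS) {
      p0 <- initial$true_props[[soil]]
      grp <- observed_group(initial$tables[[soil]], soil)[names(p0)]
      for (sc in scenarios) {
        tr <- sc$treatment
        jitter <- exp(stats::rnorm(length(p0), 0, sc$effect_jitter_sd))
        new_ids <- if (max(sc$new_mass_by_time) > 0)
          sprintf("NEW_%s_%s_%03d", soil, tr, seq_len(sc$n_new_otus))
        else character(0)
        new_w <- if (length(new_ids)) stats::rgamma(length(new_ids), 1) else numeric(0)
        all_new_ids <- union(all_new_ids, new_ids)
        for (tp in post_tp) {
          lfc <- sc$effects[grp, tp] * jitter
          p <- p0 * exp(lfc)
          p <- p / sum(p)
          new_mass <- sc$new_mass_by_time[tp]
          full_p <- c(p * (1 - new_mass),
                      if (length(new_ids)) new_mass * new_w / sum(new_w))
          names(full_p) <- c(names(p0), new_ids)
          counts <- stats::rmultinom(config$n_replicates, config$depth, full_p)
          rownames(counts) <- names(full_p)
          ids <- make_sample_id(soil, tr, tp, seq_len(config$n_replicates))
          colnames(counts) <- ids
          count_blocks[[length(count_blocks) + 1L]] <- counts
          md_blocks[[length(md_blocks) + 1L]] <-
            data.frame(sample_id = ids, soil = soil, treatment = tr,
                       timepoint = tp,
                       replicate = seq_len(config$n_replicates))
        }
      }
    }
  })
  otu_ids <- c(names(initial$true_props[[1]]), sort(all_new_ids))
  blocks <- c(lapply(initial$tables, `[[`, "counts"), count_blocks)
  mats <- lapply(blocks, function(b) {
    m <- matrix(0, length(otu_ids), ncol(b),
                dimnames = list(otu_ids, colnames(b)))
    m[rownames(b), ] <- b
    m
  })
  full <- do.call(cbind, mats)
  md <- rbind(do.call(rbind, lapply(initial$tables, `[[`, "metadata")),
              do.call(rbind, md_blocks))
  rownames(md) <- NULL
  otu_table(full, md)
}
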