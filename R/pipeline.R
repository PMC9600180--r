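#' Configuration of an end-to-end pipeline run
#'
#' Exactly one of `counts_path`/`metadata_path` (real data) or `synthetic`
#' (a [community_config()], optionally with `scenarios`) must be supplied.
#'
#' @param counts_path,metadata_path input files for [read_otu_table()].
#' @param synthetic a `community_config` for a synthetic run.
#' @param scenarios disturbance scenarios for a synthetic run.
#' @param th classification [thresholds()].
#' @param rarefy_depth rarefaction depth (`NULL` = rarefy to the minimum
#'   sample total; `NA` = skip rarefaction, e.g. for already-equalized
#'   synthetic tables).
#' @param seed master seed; stage seeds are derived from it.
#' @param n_perm PERMANOVA permutations.
#' @param stability a [fit_config()] for the recovery-model fits.
#' @param fit_treatments treatments to fit (ambient is a null series and is
#'   not fitted by default).
#' @param lfc_prior_sd see [nb_wald_test()].
#' @param out_dir directory for tidy TSV outputs (`NULL` = don't write).
#' @return A `run_config` list.
#' @export
run_config <- function(counts_path = NULL, metadata_path = NULL,
                       synthetic = NULL, scenarios = default_scenarios(),
                       th = thresholds(), rarefy_depth = NA, seed = 1L,
                       n_perm = 999, stability = fit_config(),
                       fit_treatments = c("DR", "FL", "FR", "HE"),
                       lfc_prior_sd = 2, out_dir = NULL) {
  if (is.null(synthetic) == is.null(counts_path))
    stop("supply exactly one of {counts_path+metadata_path, synthetic}")
  structure(list(counts_path = counts_path, metadata_path = metadata_path,
                 synthetic = synthetic, scenarios = scenarios, th = th,
                 rarefy_depth = rarefy_depth, seed = as.integer(seed),
                 n_perm = n_perm, stability = stability,
                 fit_treatments = fit_treatments,
                 lfc_prior_sd = lfc_prior_sd, out_dir = out_dir),
            class = "run_config")
}

#' Run the full disturbance-recovery analysis pipeline
#'
#' Executes, in order: data loading (or synthetic generation), optional
#' rarefaction, taxon classification and category flux, per-group Shannon
#' diversity and log response ratios, beta-diversity statistics (PCoA,
#' PERMANOVA, per-sample dissimilarity to initial, SIMPER per treatment),
#' negative-binomial responsive-OTU detection per soil x treatment x
#' timepoint contrast, Bayesian stability-model fits per soil x taxon
#' group x treatment, and the rare:abundant-ratio regressions. Writes tidy
#' TSVs plus a run log when `out_dir` is set. All randomness derives from
#' `cfg$seed`, so a re-run with the same config reproduces every output.
#'
#' @param cfg a [run_config()].
#' @param stages character vector to run a subset of
#'   c("classify", "diversity", "beta", "da", "stability", "regression").
#' @return List of stage results (see the individual stage functions).
#' @export
run_pipeline <- function(cfg, stages = c("classify", "diversity", "beta",
                                         "da", "stability", "regression")) {
  res <- list(config = cfg)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  # ---- load or generate ----
  res$table <- step("input", {
    if (!is.null(cfg$synthetic)) {
      ini <- generate_initial_community(cfg$synthetic)
      simulate_disturbance_series(ini, cfg$scenarios, cfg$synthetic)
    } else {
      read_otu_table(cfg$counts_path, cfg$metadata_path)
    }
  })
  if (!is.null(cfg$rarefy_depth) && !is.na(cfg$rarefy_depth))
    res$table <- step("rarefy",
                      rarefy(res$table, cfg$rarefy_depth, seed = cfg$seed + 1L))
  rel_all <- relative_abundance(res$table)
  # ---- classification, per soil ----
  res$assignment <- step("classify", {
    lapply(stats::setNames(SOILS, SOILS), function(soil) {
      sel <- rel_all$metadata$soil == soil
      ini <- subset_samples(rel_all, samples = sel &
                              is_initial(rel_all$metadata))
      a <- classify_taxa(ini, cfg$th, soil = soil)
      # OTUs absent from this soil's initial samples but present in the
      # full table keep their NEW label by construction of classify_taxa
      a
    })
  })
  if ("classify" %in% stages) {
    res$flux <- step("classify", {
      lapply(stats::setNames(SOILS, SOILS), function(soil) {
        sel <- rel_all$metadata$soil == soil
        category_abundance_flux(subset_samples(rel_all, sel),
                                res$assignment[[soil]])
      })
    })
  }
  # ---- diversity + LRR per soil x group ----
  if ("diversity" %in% stages) {
    res$diversity <- step("diversity", {
      do.call(rbind, lapply(SOILS, function(soil) {
        sel <- res$table$metadata$soil == soil
        tab <- subset_samples(res$table, sel)
        do.call(rbind, lapply(TAXON_GROUPS, function(g)
          shannon(tab, res$assignment[[soil]], g)))
      }))
    })
    res$lrr <- step("diversity", {
      do.call(rbind, lapply(split(res$diversity, res$diversity$group),
                            log_response_ratio))
    })
    rownames(res$lrr) <- NULL
  }
  # ---- beta structure per soil x group ----
  if ("beta" %in% stages) {
    res$beta <- step("beta", {
      lapply(stats::setNames(SOILS, SOILS), function(soil) {
        sel <- rel_all$metadata$soil == soil
        rel <- subset_samples(rel_all, sel)
        out <- lapply(stats::setNames(TAXON_GROUPS, TAXON_GROUPS),
                      function(g) {
          otus <- intersect(group_otus(res$assignment[[soil]], g),
                            rownames(rel$proportions))
          sub <- subset_samples(rel, otus = otus)
          keep <- colSums(sub$proportions) > 0
          sub <- subset_samples(sub, keep)
          sub$proportions <- sweep(sub$proportions, 2,
                                   colSums(sub$proportions), "/")
          d <- bray_curtis(sub)
          post <- !is_initial(sub$metadata)
          list(pcoa = pcoa(d),
               permanova = permanova(
                 d[post, post],
                 sub$metadata[post, c("treatment", "timepoint")],
                 n_perm = cfg$n_perm, seed = cfg$seed + 2L),
               dissimilarity = dissimilarity_to_initial(sub))
        })
        out$simper <- simper_by_treatment(rel, res$assignment[[soil]])
        out
      })
    })
  }
  # ---- differential abundance per soil x treatment x timepoint ----
  if ("da" %in% stages) {
    res$da <- step("da", da_all_contrasts(res$table, res$assignment,
                                          lfc_prior_sd = cfg$lfc_prior_sd))
  }
  # ---- stability-landscape fits per soil x group x treatment ----
  if ("stability" %in% stages) {
    res$stability <- step("stability", {
      div <- res$diversity
      if (is.null(div)) stop("stability stage needs the diversity stage")
      fits <- list()
      for (soil in SOILS) {
        for (g in c("abundant", "rare")) {
          base <- div$H[div$soil == soil & div$group == g &
                          div$timepoint == "initial"]
          for (tr in cfg$fit_treatments) {
            key <- paste(soil, g, tr, sep = ".")
            traj <- diversity_trajectory(div, soil, g, tr,
                                         cfg$stability$time_map)
            if (is.null(traj)) next
            fits[[key]] <- fit_stability_model(traj, cfg$stability)
          }
        }
      }
      fits
    })
    res$stability_summary <- do.call(rbind, lapply(names(res$stability),
      function(k) {
        parts <- strsplit(k, ".", fixed = TRUE)[[1]]
        s <- posterior_summary(res$stability[[k]])
        data.frame(soil = parts[1], group = parts[2], treatment = parts[3],
                   s, skewness_A = attr(s, "skewness_A"), row.names = NULL)
      }))
  }
  # ---- equilibrium regressions ----
  if ("regression" %in% stages) {
    res$regression <- step("regression", {
      ratios <- do.call(rbind, lapply(SOILS, function(soil) {
        sel <- rel_all$metadata$soil == soil
        ratio_rare_abundant(subset_samples(rel_all, sel),
                            res$assignment[[soil]])
      }))
      diss <- dissimilarity_to_initial(rel_all)
      m <- merge(ratios, diss[, c("sample_id", "dissimilarity")],
                 by = "sample_id")
      m <- m[m$timepoint != "initial", ]
      # heat sits on its own scale and is regressed separately
      he <- m$treatment == "HE"
      by_tr <- ratio_dissimilarity_regression(m$ratio, m$dissimilarity,
                                              m$treatment)
      by_soil <- ratio_dissimilarity_regression(
        m$ratio[!he], m$dissimilarity[!he], m$soil[!he])
      by_soil$group <- paste0(by_soil$group, "_nonHE")
      rbind(cbind(metric = "treatment", by_tr),
            cbind(metric = "soil", by_soil))
    })
  }
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(res, cfg$out_dir)
  res
}

# trajectory of Shannon displacement from the initial-mean baseline for one
# soil x taxon group x treatment; replicate x time matrix on model time
diversity_trajectory <- function(div, soil, group, treatment, time_map) {
  base <- div$H[div$soil == soil & div$group == group &
                  div$timepoint == "initial"]
  base <- base[is.finite(base)]
  if (!length(base)) return(NULL)
  baseline <- mean(base)
  sel <- div$soil == soil & div$group == group &
    (div$treatment == treatment | div$timepoint == "initial")
  d <- div[sel & is.finite(div$H), ]
  tps <- intersect(names(time_map), unique(d$timepoint))
  if (length(tps) < 3) return(NULL)
  reps <- sort(unique(d$replicate))
  disp <- matrix(NA_real_, length(reps), length(tps),
                 dimnames = list(reps, tps))
  for (i in seq_len(nrow(d)))
    disp[as.character(d$replicate[i]), d$timepoint[i]] <- d$H[i] - baseline
  if (anyNA(disp)) disp[is.na(disp)] <- 0
  structure(list(times = unname(time_map[tps]), displacements = disp,
                 sigma_true = NA, params_true = NULL),
            class = "trajectory_data")
}

# SIMPER of initial vs each treatment x timepoint cell, with taxon-group
# percentage contributions
simper_by_treatment <- function(rel, assignment) {
  md <- rel$metadata
  cells <- unique(md[!is_initial(md), c("treatment", "timepoint")])
  do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- is_initial(md) |
      (md$treatment == cells$treatment[i] & md$timepoint == cells$timepoint[i])
    sub <- subset_samples(rel, sel)
    grp <- ifelse(is_initial(sub$metadata), "initial", "disturbed")
    s <- simper(sub, grp, assignment)
    data.frame(treatment = cells$treatment[i], timepoint = cells$timepoint[i],
               s$per_group, overall = s$overall, row.names = NULL)
  }))
}

# all pairwise timepoint-vs-initial Wald contrasts within soil x treatment
da_all_contrasts <- function(table, assignments, lfc_prior_sd = 2,
                             timepoints = c("R0", "R2", "R40", "R170")) {
  md <- table$metadata
  out <- list()
  for (soil in SOILS) {
    for (tr in setdiff(unique(md$treatment), NA)) {
      sel <- md$soil == soil &
        (is_initial(md) | (md$treatment == tr & md$timepoint %in% timepoints))
      if (sum(sel & !is_initial(md)) == 0) next
      sub <- subset_samples(table, sel)
      smd <- sub$metadata
      state <- estimate_dispersions(
        sub, groups = ifelse(is_initial(smd), "initial", smd$timepoint))
      for (tp in intersect(timepoints, unique(smd$timepoint))) {
        grp <- factor(ifelse(is_initial(smd), "initial",
                             ifelse(smd$timepoint == tp, tp, NA)),
                      levels = c("initial", tp))
        key <- paste(soil, tr, tp, sep = ".")
        r <- nb_wald_test(sub, state, grp, lfc_prior_sd = lfc_prior_sd,
                          contrast_id = key)
        r$soil <- soil; r$treatment <- tr; r$timepoint <- tp
        out[[key]] <- r
      }
    }
  }
  out
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name)
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  for (soil in names(res$assignment))
    w(data.frame(otu_id = names(res$assignment[[soil]]$category),
                 category = unname(res$assignment[[soil]]$category)),
      paste0("assignment_", soil, ".tsv"))
  if (!is.null(res$flux))
    for (soil in names(res$flux)) {
      w(res$flux[[soil]]$shares, paste0("category_shares_", soil, ".tsv"))
      w(res$flux[[soil]]$flows, paste0("category_flows_", soil, ".tsv"))
    }
  if (!is.null(res$diversity)) w(res$diversity, "diversity.tsv")
  if (!is.null(res$lrr)) w(res$lrr, "lrr.tsv")
  if (!is.null(res$beta))
    for (soil in names(res$beta)) {
      w(res$beta[[soil]]$simper, paste0("simper_", soil, ".tsv"))
      for (g in TAXON_GROUPS) {
        w(as.data.frame(res$beta[[soil]][[g]]$permanova),
          paste0("permanova_", soil, "_", g, ".tsv"))
        w(res$beta[[soil]][[g]]$dissimilarity,
          paste0("dissimilarity_", soil, "_", g, ".tsv"))
      }
    }
  if (!is.null(res$da))
    w(do.call(rbind, res$da), "da_results.tsv")
  if (!is.null(res$stability_summary))
    w(res$stability_summary, "stability_summary.tsv")
  if (!is.null(res$regression)) w(res$regression, "regressions.tsv")
  log <- c(paste("run at:", format(Sys.time())),
           paste("R version:", R.version.string),
           paste("seed:", res$config$seed),
           paste("n_perm:", res$config$n_perm))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(res)
}
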