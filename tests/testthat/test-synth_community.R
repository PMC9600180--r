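small_cfg <- function(seed = 1, ...) {
  community_config(n_otus = 400, depth = 4000, seed = seed, ...)
}

test_that("initial communities conserve depth and are seed-deterministic", {
  cfg <- small_cfg(seed = 3)
  ini1 <- generate_initial_community(cfg)
  ini2 <- generate_initial_community(cfg)
  expect_identical(ini1$tables$NCF$counts, ini2$tables$NCF$counts)
  expect_identical(ini1$true_props, ini2$true_props)
  for (soil in c("NCF", "NOF"))
    expect_equal(unname(colSums(ini1$tables[[soil]]$counts)),
                 rep(4000, 4))
  ini3 <- generate_initial_community(small_cfg(seed = 4))
  expect_false(identical(ini1$tables$NCF$counts, ini3$tables$NCF$counts))
  expect_error(community_config(n_otus = 5), "n_otus")
  expect_error(community_config(depth = 10), "depth")
  expect_error(community_config(lognormal_sigma = 0), "sigma")
})

test_that("the disturbance series has the full layout and conserves depth", {
  cfg <- small_cfg(seed = 5)
  ini <- generate_initial_community(cfg)
  tab <- simulate_disturbance_series(ini, default_scenarios(), cfg)
  md <- tab$metadata
  # 2 soils x (4 initial + 5 treatments x 4 timepoints x 4 replicates)
  expect_equal(ncol(tab$counts), 2 * (4 + 5 * 4 * 4))
  expect_equal(unname(colSums(tab$counts)), rep(4000, ncol(tab$counts)))
  expect_true(all(!is.na(md$soil) & !is.na(md$treatment) &
                    !is.na(md$timepoint) & !is.na(md$replicate)))
  cells <- table(md$soil, md$treatment, md$timepoint)
  expect_true(all(cells[, c("DR", "FL", "FR", "HE"),
                        c("R0", "R2", "R40", "R170")] == 4))
  # determinism
  tab2 <- simulate_disturbance_series(ini, default_scenarios(), cfg)
  expect_identical(tab$counts, tab2$counts)
  # missing treatment errors
  expect_error(simulate_disturbance_series(ini, default_scenarios()[1:3], cfg),
               "missing")
})

test_that("scenarios reject unknown categories and non-null ambient settings", {
  expect_error(disturbance_scenario("DR", category_effects = c(weird = 1)),
               "unknown taxon category")
  expect_error(disturbance_scenario("AMB",
                                    category_effects = c(abundant = -1)),
               "AMB")
  expect_error(disturbance_scenario("DR", new_otu_fraction = 1.2), "fraction")
})

test_that("invading OTUs reach their configured share at R0", {
  shares <- sapply(1:20, function(seed) {
    cfg <- small_cfg(seed = seed)
    ini <- generate_initial_community(cfg)
    sc <- default_scenarios()
    sc$HE <- disturbance_scenario("HE", new_otu_fraction = 0.2)
    tab <- simulate_disturbance_series(ini, sc, cfg)
    rel <- relative_abundance(tab)
    sel <- rel$metadata$soil == "NCF" & rel$metadata$treatment == "HE" &
      rel$metadata$timepoint == "R0"
    new_rows <- grepl("^NEW_NCF_HE", rownames(rel$proportions))
    mean(colSums(rel$proportions[new_rows, sel, drop = FALSE]))
  })
  expect_equal(mean(shares), 0.2, tolerance = 0.01)
})

test_that("suppressing abundant taxa lowers their share at R0; ambient is flat", {
  diffs_he <- c(); diffs_amb <- c()
  for (seed in 1:10) {
    cfg <- small_cfg(seed = seed)
    ini <- generate_initial_community(cfg)
    tab <- simulate_disturbance_series(ini, default_scenarios(), cfg)
    rel <- relative_abundance(tab)
    md <- rel$metadata
    ncf <- subset_samples(rel, md$soil == "NCF")
    a <- classify_taxa(subset_samples(ncf, ncf$metadata$timepoint == "initial"))
    fx <- category_abundance_flux(ncf, a)
    sh <- fx$shares
    ab0 <- sh$share[sh$timepoint == "initial" & sh$group == "abundant"][1]
    diffs_he <- c(diffs_he,
                  sh$share[sh$treatment == "HE" & sh$timepoint == "R0" &
                             sh$group == "abundant"] - ab0)
    diffs_amb <- c(diffs_amb,
                   sh$share[sh$treatment == "AMB" & sh$timepoint == "R170" &
                              sh$group == "abundant"] - ab0)
  }
  expect_true(all(diffs_he < 0))            # strong suppression, every seed
  expect_lt(abs(mean(diffs_amb)), 0.02)     # null scenario drifts only by noise
})

test_that("generated data reproduce the study-like OTU partitioning", {
  fr <- sapply(1:20, function(seed) {
    cfg <- community_config(n_otus = 20000, depth = 67899, seed = seed)
    ini <- generate_initial_community(cfg)
    rel <- relative_abundance(ini$tables$NCF)
    a <- classify_taxa(rel)
    obs <- names(a$category)[a$category != "NEW"]
    c(abundant = mean(a$category[obs] %in% c("AAT", "CAT")),
      rare = mean(a$category[obs] %in% c("ART", "CRT")))
  })
  expect_true(all(fr["abundant", ] < 0.01))
  expect_true(all(fr["rare", ] > 0.85))
  # desk-scale default config still keeps abundant taxa well under 1% of OTUs
  cfg <- community_config(seed = 1)
  ini <- generate_initial_community(cfg)
  a <- classify_taxa(relative_abundance(ini$tables$NOF))
  obs <- names(a$category)[a$category != "NEW"]
  expect_lt(mean(a$category[obs] %in% c("AAT", "CAT")), 0.01)
})
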