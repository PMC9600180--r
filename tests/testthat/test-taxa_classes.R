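test_that("relative abundance is column-stochastic and errors on empty samples", {
  tab <- toy_table()
  rel <- relative_abundance(tab)
  expect_equal(unname(colSums(rel$proportions)), rep(1, ncol(tab$counts)))
  m <- matrix(c(2, 2, 1, 3), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  md <- data.frame(sample_id = c("s1", "s2"), soil = "NCF", treatment = "AMB",
                   timepoint = "initial", replicate = 1:2)
  r <- relative_abundance(otu_table(m, md))
  expect_equal(unname(r$proportions[, "s1"]), c(0.5, 0.5))
  expect_equal(unname(r$proportions[, "s2"]), c(0.25, 0.75))
  m0 <- m; m0[, "s2"] <- 0
  expect_error(relative_abundance(otu_table(m0, md)), "s2")
})

test_that("threshold predicates force the category of archetypal OTUs", {
  p <- rbind(aat  = c(0.02, 0.02),
             art  = c(5e-5, 5e-5),
             crt  = c(5e-5, 5e-4),
             cat_ = c(2e-4, 0.015),
             crat = c(5e-5, 0.015),
             mt   = c(5e-4, 5e-3),
             new  = c(0, 0))
  # columns need not sum to 1 for the predicate logic; pad with a filler OTU
  p <- rbind(p, filler = 1 - colSums(p))
  a <- classify_taxa(make_rel(p))
  expect_equal(unname(a$category[c("aat", "art", "crt", "cat_", "crat", "new")]),
               c("AAT", "ART", "CRT", "CAT", "CRAT", "NEW"))
  # exact 0.01% boundary is moderate-side, exact 1% is abundant-side
  pb <- rbind(atcut = c(1e-4, 1e-4), abcut = c(1e-2, 1e-2))
  pb <- rbind(pb, filler = 1 - colSums(pb))
  ab <- classify_taxa(make_rel(pb))
  expect_equal(unname(ab$category["atcut"]), "MT")
  expect_equal(unname(ab$category["abcut"]), "AAT")
})

test_that("classification matches a brute-force predicate enumerator", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    k <- sample(2:5, 1)
    p <- matrix(10^runif(n * k, -6, -0.3), n, k)
    p[sample(length(p), n)] <- 0   # sprinkle zeros
    p <- sweep(p, 2, colSums(p), "/")
    rownames(p) <- paste0("o", seq_len(n))
    a <- classify_taxa(make_rel(p))
    expect_identical(unname(a$category), unname(classify_oracle(p)))
  }
})

test_that("labels partition all OTUs and counts are bookkept", {
  tab <- toy_table(seed = 3)
  rel <- relative_abundance(tab)
  ini <- subset_samples(rel, rel$metadata$soil == "NCF" &
                          rel$metadata$timepoint == "initial")
  a <- classify_taxa(ini)
  expect_length(a$category, nrow(tab$counts))
  expect_true(all(a$category %in% c("AAT", "CAT", "MT", "CRT", "ART",
                                    "CRAT", "NEW")))
  expect_equal(sum(table(a$category)), nrow(tab$counts))
})

test_that("classification is scale-invariant and monotone in the abundant cutoff", {
  tab <- toy_table(seed = 5)
  ini_sel <- tab$metadata$soil == "NCF" & tab$metadata$timepoint == "initial"
  rel <- subset_samples(relative_abundance(tab), ini_sel)
  a1 <- classify_taxa(rel)
  # scaling counts per sample leaves proportions, hence labels, unchanged
  tab2 <- tab
  tab2$counts <- tab2$counts * 7
  a2 <- classify_taxa(subset_samples(relative_abundance(tab2), ini_sel))
  expect_identical(a1$category, a2$category)
  n_ab <- function(cut) {
    a <- classify_taxa(rel, thresholds(abundant_cutoff = cut))
    sum(a$category %in% c("AAT", "CAT"))
  }
  cuts <- c(0.002, 0.005, 0.01, 0.02, 0.05)
  expect_true(all(diff(sapply(cuts, n_ab)) <= 0))
})

test_that("classify_taxa rejects mixed soils and non-initial samples", {
  tab <- toy_table()
  rel <- relative_abundance(tab)
  expect_error(classify_taxa(subset_samples(rel, rel$metadata$soil == "NCF")),
               "initial")
  ini <- subset_samples(rel, rel$metadata$timepoint == "initial")
  expect_error(classify_taxa(ini), "single soil")
})

test_that("category flux yields unit shares, empty flows on one timepoint", {
  tab <- toy_table(seed = 7)
  sel <- tab$metadata$soil == "NCF"
  rel <- subset_samples(relative_abundance(tab), sel)
  ini <- subset_samples(rel, rel$metadata$timepoint == "initial")
  a <- classify_taxa(ini)
  fx1 <- category_abundance_flux(ini, a)
  expect_equal(nrow(fx1$flows), 0)
  sums <- tapply(fx1$shares$share,
                 paste(fx1$shares$treatment, fx1$shares$timepoint), sum)
  expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-9)
  fx <- category_abundance_flux(rel, a)
  expect_true(nrow(fx$flows) > 0)
  expect_equal(fx$flows$delta, fx$flows$share_to - fx$flows$share_from)
  # unassigned OTU is an error
  a2 <- a
  a2$category <- a2$category[-1]
  expect_error(category_abundance_flux(rel, a2), "assignment")
})
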