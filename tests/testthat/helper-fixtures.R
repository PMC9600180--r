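# fixtures and independent oracles, all built in code

# wrap a proportions matrix as a rel_abundance with initial-sample metadata
make_rel <- function(p, soil = "NCF", timepoint = "initial",
                     treatment = "AMB") {
  if (is.null(colnames(p))) colnames(p) <- paste0("s", seq_len(ncol(p)))
  if (is.null(rownames(p))) rownames(p) <- paste0("otu", seq_len(nrow(p)))
  md <- data.frame(sample_id = colnames(p), soil = soil,
                   treatment = treatment, timepoint = timepoint,
                   replicate = seq_len(ncol(p)))
  structure(list(proportions = p, metadata = md), class = "rel_abundance")
}

# small deterministic count table: 2 soils x initial+2 timepoints
toy_table <- function(seed = 1, n_otus = 60, depth = 2000) {
  set.seed(seed)
  ids <- sprintf("otu%03d", seq_len(n_otus))
  cells <- expand.grid(soil = c("NCF", "NOF"), timepoint = c("initial", "R0"),
                       replicate = 1:3, stringsAsFactors = FALSE)
  p <- exp(rnorm(n_otus, 0, 2)); p <- p / sum(p)
  counts <- sapply(seq_len(nrow(cells)), function(i)
    rmultinom(1, depth, p)[, 1])
  rownames(counts) <- ids
  md <- data.frame(sample_id = paste(cells$soil, cells$timepoint,
                                     cells$replicate, sep = "_"),
                   soil = cells$soil, treatment = "AMB",
                   timepoint = cells$timepoint, replicate = cells$replicate)
  colnames(counts) <- md$sample_id
  otu_table(counts, md)
}

# brute-force classifier: literal enumeration of the six predicates per OTU
classify_oracle <- function(p, lo = 1e-4, hi = 1e-2) {
  apply(p, 1, function(v) {
    if (all(v == 0)) return("NEW")
    if (all(v >= hi)) return("AAT")
    if (any(v >= hi) && any(v < lo)) return("CRAT")
    if (any(v >= hi) && all(v >= lo)) return("CAT")
    if (all(v < lo)) return("ART")
    if (any(v < lo)) return("CRT")
    "MT"
  })
}

# brute-force Bray-Curtis between two columns
bc_pair <- function(x, y) sum(abs(x - y)) / sum(x + y)

# brute-force SIMPER: explicit pair loop, independent of the implementation
simper_oracle <- function(m, g1, g2) {
  contrib <- numeric(nrow(m))
  np <- 0
  for (i in g1) for (j in g2) {
    contrib <- contrib + abs(m[, i] - m[, j]) / sum(m[, i] + m[, j])
    np <- np + 1
  }
  contrib / np
}

# exhaustive-permutation PERMANOVA p for a one-factor design
permanova_exact_p <- function(d, groups) {
  n <- nrow(d)
  perms <- gtools_permutations(n)
  f0 <- permanova(d, data.frame(g = groups), n_perm = 1, seed = 1)$statistic[1]
  fs <- apply(perms, 1, function(pm)
    permanova(d[pm, pm], data.frame(g = groups), n_perm = 1,
              seed = 1)$statistic[1])
  mean(fs >= f0 - 1e-12)
}

# all permutations of 1..n (n small)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(setdiff(seq_len(n), k)[sub], nrow(sub)))
  }))
}
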