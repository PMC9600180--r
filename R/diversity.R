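#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample's reads without replacement to a common depth
#' (multivariate hypergeometric draw per sample), removing sequencing-depth
#' bias before diversity calculations.
#'
#' @param table an `otu_table`; every sample total must be >= `depth`.
#' @param depth target reads per sample.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return A rarefied `otu_table` whose columns all sum to `depth`.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  totals <- colSums(table$counts)
  shallow <- colnames(table$counts)[totals < depth]
  if (length(shallow))
    stop("samples shallower than depth ", depth, ": ",
         paste(shallow, collapse = ", "))
  counts <- table$counts
  out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  withr_seed(seed, {
    for (j in seq_len(ncol(counts))) {
      out[, j] <- rmvhyper(counts[, j], depth)
    }
  })
  otu_table(out, table$metadata)
}

# one multivariate-hypergeometric draw: k reads from the urn given by counts,
# via the sequential conditional hypergeometric decomposition
rmvhyper <- function(counts, k) {
  n <- length(counts)
  res <- numeric(n)
  remaining <- sum(counts)
  idx <- which(counts > 0)
  for (i in idx) {
    if (k <= 0) break
    ci <- counts[i]
    if (remaining == ci) {
      res[i] <- k
      k <- 0
    } else {
      x <- stats::rhyper(1, ci, remaining - ci, k)
      res[i] <- x
      k <- k - x
    }
    remaining <- remaining - ci
  }
  res
}

# run code under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Shannon diversity of taxon-group subcommunities
#'
#' Restricts each sample to the OTUs of a taxon group, renormalizes within
#' the subset and computes H = -sum p_i ln p_i (natural log). A sample in
#' which the group has no reads yields `NA` (H is undefined there, not 0).
#'
#' @param table a rarefied `otu_table` (or a `rel_abundance`).
#' @param assignment optional `category_assignment`; omit to use all OTUs.
#' @param group one of "abundant", "common", "rare", or "all".
#' @param crat_group see [taxon_group()].
#' @return data.frame: sample_id, group, H, richness, plus the metadata.
#' @export
shannon <- function(table, assignment = NULL, group = "all",
                    crat_group = "rare") {
  m <- if (inherits(table, "rel_abundance")) table$proportions else table$counts
  if (group != "all") {
    if (is.null(assignment)) stop("group subsetting needs an assignment")
    keep <- intersect(group_otus(assignment, group, crat_group), rownames(m))
    m <- m[keep, , drop = FALSE]
  }
  H <- apply(m, 2, shannon_index)
  rich <- colSums(m > 0)
  data.frame(sample_id = colnames(m), group = group, H = H,
             richness = rich, table$metadata, row.names = NULL)
}

#' Shannon index of a single abundance vector
#'
#' @param x non-negative counts or proportions.
#' @return H in natural-log units; `NA` if `x` has no positive entries.
#' @export
shannon_index <- function(x) {
  x <- x[x > 0]
  if (!length(x)) return(NA_real_)
  p <- x / sum(x)
  -sum(p * log(p))
}

#' Pairwise log response ratios of Shannon diversity against initial samples
#'
#' For every post-disturbance sample, LRR = ln(H_sample / H_initial) against
#' each same-soil initial replicate (the full cross), or against the
#' replicate mean (`pairing = "mean"`). Pairs with non-positive or missing H
#' are skipped with a warning.
#'
#' @param div a data.frame from [shannon()] (one group).
#' @param pairing "all_pairs" (default) or "mean".
#' @return data.frame: sample_id, initial_id, soil, treatment, timepoint,
#'   replicate, group, lrr.
#' @export
log_response_ratio <- function(div, pairing = c("all_pairs", "mean")) {
  pairing <- match.arg(pairing)
  ini <- div[div$timepoint == "initial", , drop = FALSE]
  post <- div[div$timepoint != "initial", , drop = FALSE]
  if (!nrow(ini)) stop("no initial samples in diversity table")
  bad <- !is.finite(div$H) | div$H <= 0
  if (any(bad)) {
    warning(sum(bad), " sample(s) with undefined or zero H skipped")
    ini <- ini[!(!is.finite(ini$H) | ini$H <= 0), , drop = FALSE]
    post <- post[!(!is.finite(post$H) | post$H <= 0), , drop = FALSE]
  }
  if (pairing == "mean") {
    mH <- tapply(ini$H, ini$soil, mean)
    out <- post
    out$initial_id <- "initial_mean"
    out$lrr <- log(post$H / mH[post$soil])
    return(out[, c("sample_id", "initial_id", "soil", "treatment",
                   "timepoint", "replicate", "group", "lrr")])
  }
  pieces <- lapply(seq_len(nrow(post)), function(i) {
    same <- ini[ini$soil == post$soil[i], , drop = FALSE]
    data.frame(sample_id = post$sample_id[i], initial_id = same$sample_id,
               soil = post$soil[i], treatment = post$treatment[i],
               timepoint = post$timepoint[i], replicate = post$replicate[i],
               group = post$group[i], lrr = log(post$H[i] / same$H),
               row.names = NULL)
  })
  do.call(rbind, pieces)
}
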