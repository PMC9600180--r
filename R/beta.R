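#' Bray-Curtis dissimilarity matrix
#'
#' BC(x, y) = sum_i |x_i - y_i| / sum_i (x_i + y_i), computed between every
#' pair of samples.
#'
#' @param rel a `rel_abundance` (or any non-negative OTU-by-sample matrix).
#' @return A symmetric numeric matrix with zero diagonal, class `bc_dist`,
#'   with the sample metadata attached as an attribute when available.
#' @export
bray_curtis <- function(rel) {
  m <- if (inherits(rel, "rel_abundance")) rel$proportions else
    if (inherits(rel, "otu_table")) rel$counts else as.matrix(rel)
  if (any(m < 0)) stop("negative entries in abundance matrix")
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  tot <- colSums(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- sum(abs(m[, i] - m[, j]))
      den <- tot[i] + tot[j]
      d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
    }
  }
  md <- if (is.list(rel) && !is.null(rel$metadata)) rel$metadata else NULL
  structure(d, class = c("bc_dist", "matrix"), metadata = md)
}

#' Principal-coordinate analysis (classical metric scaling)
#'
#' Double-centers the squared-distance (Gower) matrix, eigendecomposes it and
#' scales eigenvectors by the square root of their eigenvalues. Negative
#' eigenvalues are retained in the output but their axes are excluded from
#' the coordinates; an optional Lingoes correction adds a constant to the
#' squared off-diagonal distances to make the matrix Euclidean-embeddable.
#'
#' @param d symmetric distance matrix (e.g. from [bray_curtis()]).
#' @param correction "none" (default) or "lingoes".
#' @return List: `points` (samples x positive axes, columns `PCo1`, ...),
#'   `eigenvalues` (all, decreasing), `prop_explained` (per positive axis,
#'   relative to the sum of positive eigenvalues).
#' @export
pcoa <- function(d, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  d <- unclass(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(d)
  G <- gower_center(d^2)
  ev <- eigen(G, symmetric = TRUE)
  if (correction == "lingoes" && min(ev$values) < -1e-8) {
    c2 <- -min(ev$values)
    d2 <- d^2 + 2 * c2
    diag(d2) <- 0
    G <- gower_center(d2)
    ev <- eigen(G, symmetric = TRUE)
  }
  lambda <- ev$values
  pos <- which(lambda > max(lambda) * 1e-10 & lambda > 0)
  pts <- ev$vectors[, pos, drop = FALSE] %*% diag(sqrt(lambda[pos]), length(pos))
  dimnames(pts) <- list(rownames(d), paste0("PCo", seq_along(pos)))
  list(points = pts, eigenvalues = lambda,
       prop_explained = lambda[pos] / sum(lambda[pos]))
}

gower_center <- function(d2) {
  n <- nrow(d2)
  J <- diag(n) - matrix(1 / n, n, n)
  -0.5 * J %*% d2 %*% J
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the squared-distance variation among model terms (sequential,
#' Type-I sums of squares via the trace of projected Gower matrices), with
#' significance from free permutation of sample labels. The p-value counts
#' the observed statistic: p = (1 + #{F* >= F}) / (1 + n_perm).
#'
#' @param d distance matrix.
#' @param terms data.frame of factors (one column per model term, in the
#'   order they should enter the model), rows aligned with `d`.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return data.frame of class `permanova_result`: term, df, SS, R2,
#'   statistic (pseudo-F), p; includes Residual and Total rows. Attributes
#'   `n_perm` and `seed`.
#' @export
permanova <- function(d, terms, n_perm = 999, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  d <- unclass(d)
  n <- nrow(d)
  terms <- as.data.frame(terms)
  terms[] <- lapply(terms, function(x) factor(as.character(x)))
  stopifnot(nrow(terms) == n)
  G <- gower_center(d^2)
  # cumulative hat matrices: intercept, then + term1, + term2, ...
  hats <- vector("list", ncol(terms) + 1)
  hats[[1]] <- matrix(1 / n, n, n)
  dfs <- integer(ncol(terms))
  for (k in seq_len(ncol(terms))) {
    X <- stats::model.matrix(~ ., data = terms[, seq_len(k), drop = FALSE])
    hats[[k + 1]] <- X %*% solve(crossprod(X)) %*% t(X)
    dfs[k] <- qr(X)$rank - qr(if (k == 1) matrix(1, n, 1) else
      stats::model.matrix(~ ., data = terms[, seq_len(k - 1), drop = FALSE]))$rank
  }
  H_full <- hats[[length(hats)]]
  ss_total <- sum(diag(G))
  ss_terms <- vapply(seq_len(ncol(terms)), function(k)
    sum((hats[[k + 1]] - hats[[k]]) * G), numeric(1))
  ss_res <- sum((diag(n) - H_full) * G)
  df_res <- n - qr(H_full)$rank
  f_obs <- (ss_terms / dfs) / (ss_res / df_res)
  # permutation distribution: permuting labels = permuting rows/cols of G
  exceed <- numeric(length(f_obs))
  withr_seed(seed, {
    for (b in seq_len(n_perm)) {
      pm <- sample.int(n)
      Gp <- G[pm, pm]
      ssp <- vapply(seq_len(ncol(terms)), function(k)
        sum((hats[[k + 1]] - hats[[k]]) * Gp), numeric(1))
      ssr <- sum((diag(n) - H_full) * Gp)
      fp <- (ssp / dfs) / (ssr / df_res)
      exceed <- exceed + (fp >= f_obs - 1e-12)
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  res <- data.frame(
    term = c(names(terms), "Residual", "Total"),
    df = c(dfs, df_res, n - 1),
    SS = c(ss_terms, ss_res, ss_total),
    R2 = c(ss_terms, ss_res, ss_total) / ss_total,
    statistic = c(f_obs, NA, NA),
    p = c(p, NA, NA))
  structure(res, class = c("permanova_result", "data.frame"),
            n_perm = n_perm, seed = seed)
}

#' Similarity-percentage (SIMPER) decomposition of Bray-Curtis dissimilarity
#'
#' Attributes the mean between-group Bray-Curtis dissimilarity to individual
#' OTUs: contribution_i = mean over all between-group sample pairs of
#' |x_i - y_i| / sum_k (x_k + y_k). Per-OTU contributions sum to the mean
#' between-group dissimilarity; taxon-group contributions are expressed as
#' percentages of that total.
#'
#' @param rel a `rel_abundance` (or non-negative matrix).
#' @param groups two-level factor over samples (e.g. initial vs a
#'   treatment x timepoint cell).
#' @param assignment optional `category_assignment` for the per-taxon-group
#'   summary.
#' @param crat_group see [taxon_group()].
#' @return List: `per_otu` (otu_id, contribution, pct), `overall` (mean
#'   between-group BC), and when an assignment is given `per_group`
#'   (group, contribution, pct summing to 100).
#' @export
simper <- function(rel, groups, assignment = NULL, crat_group = "rare") {
  m <- if (inherits(rel, "rel_abundance")) rel$proportions else as.matrix(rel)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("simper needs exactly two groups")
  idx1 <- which(groups == levels(groups)[1])
  idx2 <- which(groups == levels(groups)[2])
  if (!length(idx1) || !length(idx2)) stop("both groups must have samples")
  contrib <- numeric(nrow(m))
  tot <- colSums(m)
  npair <- 0L
  for (i in idx1) {
    for (j in idx2) {
      contrib <- contrib + abs(m[, i] - m[, j]) / (tot[i] + tot[j])
      npair <- npair + 1L
    }
  }
  contrib <- contrib / npair
  overall <- sum(contrib)
  per_otu <- data.frame(otu_id = rownames(m), contribution = contrib,
                        pct = 100 * contrib / overall, row.names = NULL)
  out <- list(per_otu = per_otu, overall = overall,
              groups = levels(groups))
  if (!is.null(assignment)) {
    grp <- taxon_group(assignment$category[rownames(m)], crat_group)
    agg <- rowsum(contrib, grp)
    out$per_group <- data.frame(group = rownames(agg),
                                contribution = agg[, 1],
                                pct = 100 * agg[, 1] / overall,
                                row.names = NULL)
  }
  out
}

#' Per-sample Bray-Curtis dissimilarity to the initial community
#'
#' For each sample, the mean Bray-Curtis dissimilarity to every same-soil
#' initial replicate; an initial sample is compared with its peers only
#' (the self-pair is excluded).
#'
#' @param rel a `rel_abundance` including initial samples.
#' @return data.frame: sample metadata plus `dissimilarity`.
#' @export
dissimilarity_to_initial <- function(rel) {
  md <- rel$metadata
  d <- bray_curtis(rel)
  out <- md
  out$dissimilarity <- NA_real_
  for (i in seq_len(nrow(md))) {
    ref <- which(md$soil == md$soil[i] & md$timepoint == "initial")
    if (!length(ref))
      stop("no initial samples for soil ", md$soil[i])
    ref <- setdiff(ref, i)
    out$dissimilarity[i] <- mean(d[i, ref])
  }
  out
}
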