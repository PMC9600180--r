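#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the reference profile is the per-OTU
#' geometric mean over rows with no zero count; each sample's factor is the
#' median ratio of its counts to the reference, normalized so the factors
#' have geometric mean 1.
#'
#' @param table an `otu_table` or count matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(table) {
  m <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  logm <- log(m)
  allpos <- rowSums(m > 0) == ncol(m)
  if (any(allpos)) {
    logref <- rowMeans(logm[allpos, , drop = FALSE])
    sf <- apply(logm[allpos, , drop = FALSE], 2,
                function(lc) exp(stats::median(lc - logref)))
  } else {
    warning("no OTU observed in every sample; using positive counts only")
    logref <- rowMeans(replace(logm, !is.finite(logm), NA), na.rm = TRUE)
    sf <- apply(logm, 2, function(lc) {
      ok <- is.finite(lc) & is.finite(logref)
      exp(stats::median(lc[ok] - logref[ok]))
    })
  }
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(m)
  sf
}

#' Method-of-moments dispersion estimates with empirical-Bayes shrinkage
#'
#' Estimates a per-OTU negative-binomial dispersion alpha (variance =
#' mu + alpha mu^2) from normalized counts: a pooled within-group moment
#' estimate, then a mean-dispersion trend alpha(mu) = a0 + a1/mu fitted
#' across OTUs, and log-normal shrinkage of each estimate toward the trend
#' with a weight set by the ratio of sampling to between-OTU variance.
#'
#' @param table an `otu_table` or count matrix.
#' @param sf size factors (default [size_factors()]).
#' @param groups factor over samples; within-group replication (>= 2 per
#'   level) supplies the variance estimate.
#' @param shrink multiplier on the shrinkage weight; 0 = none, `Inf` pins
#'   every dispersion to the trend.
#' @param min_disp floor on dispersion estimates.
#' @return `nb_model_state` list: `size_factors`, `dispersion` (shrunk),
#'   `dispersion_raw`, `trend`, `base_mean`, `excluded` (all-zero OTU ids).
#' @export
estimate_dispersions <- function(table, sf = NULL, groups, shrink = 1,
                                 min_disp = 1e-8) {
  m <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  if (is.null(sf)) sf <- size_factors(m)
  groups <- factor(groups)
  if (any(table(groups) < 2)) stop("need >= 2 replicates per group")
  q <- sweep(m, 2, sf, "/")
  excluded <- rownames(m)[rowSums(m) == 0]
  base_mean <- rowMeans(q)
  G <- nlevels(groups)
  n <- ncol(m)
  # pooled within-group residual variance per OTU
  resid2 <- q * 0
  for (g in levels(groups)) {
    sel <- groups == g
    resid2[, sel] <- (q[, sel, drop = FALSE] -
                        rowMeans(q[, sel, drop = FALSE]))^2
  }
  s2 <- rowSums(resid2) / (n - G)
  raw <- pmax((s2 - base_mean) / base_mean^2, min_disp)
  raw[base_mean == 0] <- NA
  # parametric trend a0 + a1/mu, fitted on informative OTUs
  use <- is.finite(raw) & base_mean > 0.5 & raw > min_disp * 1.01
  if (sum(use) >= 10) {
    fit <- stats::lm(raw[use] ~ I(1 / base_mean[use]))
    a0 <- max(stats::coef(fit)[1], min_disp)
    a1 <- max(stats::coef(fit)[2], 0)
  } else {
    a0 <- stats::median(raw, na.rm = TRUE)
    a1 <- 0
  }
  trend <- pmax(a0 + a1 / base_mean, min_disp)
  # log-normal EB: weight from the delta-method sampling variance of the
  # log-dispersion moment estimate vs the robust spread of log residuals
  # around the trend (floored estimates excluded: they carry no spread
  # information, only the censoring artifact)
  lres <- log(raw) - log(trend)
  informative <- is.finite(lres) & raw > min_disp * 1.01 & base_mean > 0.5
  df <- max(n - G, 1)
  sv <- (2 / df) * ((1 / base_mean + trend) / trend)^2
  samp_var <- stats::median(sv[informative], na.rm = TRUE)
  if (!is.finite(samp_var)) samp_var <- 2 / df
  spread <- if (sum(informative) >= 10)
    stats::mad(lres[informative])^2 else stats::var(lres, na.rm = TRUE)
  prior_var <- max(spread - samp_var, 0.01)
  w <- if (is.infinite(shrink)) 1 else
    pmin(shrink * samp_var / (samp_var + prior_var), 1)
  disp <- exp((1 - w) * log(raw) + w * log(trend))
  disp <- pmax(disp, min_disp)
  structure(list(size_factors = sf, dispersion = disp, dispersion_raw = raw,
                 trend = trend, base_mean = base_mean, excluded = excluded,
                 groups = groups),
            class = "nb_model_state")
}

# NB log-link GLM for one OTU against a two-level design, by IRLS with
# fixed dispersion; optional ridge (zero-centered normal prior) on the
# group coefficient. Returns c(b0, b1, se1) on the natural-log scale.
nb_glm_fit <- function(y, x, offset, alpha, prior_prec = 0, max_iter = 50L) {
  b <- c(log(max(mean(y / exp(offset)), 1e-8)), 0)
  X <- cbind(1, x)
  for (it in seq_len(max_iter)) {
    eta <- offset + X %*% b
    mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
    w <- as.vector(mu / (1 + alpha * mu))
    z <- eta - offset + (y - mu) / mu
    XtWX <- crossprod(X, X * w)
    XtWX[2, 2] <- XtWX[2, 2] + prior_prec
    b_new <- tryCatch(solve(XtWX, crossprod(X, w * z)),
                      error = function(e) b)
    if (max(abs(b_new - b)) < 1e-8) { b <- b_new; break }
    b <- b_new
  }
  eta <- offset + X %*% b
  mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
  w <- as.vector(mu / (1 + alpha * mu))
  XtWX <- crossprod(X, X * w)
  XtWX[2, 2] <- XtWX[2, 2] + prior_prec
  cov <- tryCatch(solve(XtWX), error = function(e) matrix(NA, 2, 2))
  c(b0 = b[1], b1 = b[2], se1 = sqrt(cov[2, 2]))
}

#' Negative-binomial Wald test between two sample groups
#'
#' Fits, per OTU, a log-link negative-binomial GLM with a group indicator
#' (offset = log size factor, dispersion fixed from the model state) by
#' iteratively reweighted least squares; reports the Wald z = LFC/SE with a
#' two-sided normal p-value, and a shrunken log2 fold change from refitting
#' under a zero-centered normal prior on the group coefficient.
#'
#' @param table an `otu_table` or count matrix.
#' @param state an `nb_model_state` from [estimate_dispersions()].
#' @param groups two-level factor over samples (`NA` columns are dropped);
#'   the fold change is level 2 vs level 1.
#' @param lfc_prior_sd prior sd of the group coefficient (natural-log
#'   scale) used for the shrunken estimate.
#' @param contrast_id label stored on the result.
#' @return `da_result` data.frame: otu_id, base_mean, lfc (log2), lfc_shrunk
#'   (log2), se (log2), stat, pvalue, qvalue, flag.
#' @export
nb_wald_test <- function(table, state, groups, lfc_prior_sd = 2,
                         contrast_id = NA_character_) {
  m <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  groups <- factor(groups)
  keep <- !is.na(groups)
  m <- m[, keep, drop = FALSE]
  groups <- droplevels(groups[keep])
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  sf <- state$size_factors[colnames(m)]
  x <- as.numeric(groups == levels(groups)[2])
  offset <- log(sf)
  testable <- setdiff(rownames(m), state$excluded)
  testable <- testable[rowSums(m[testable, , drop = FALSE]) > 0]
  res <- data.frame(otu_id = rownames(m), base_mean = state$base_mean[rownames(m)],
                    lfc = NA_real_, lfc_shrunk = NA_real_, se = NA_real_,
                    stat = NA_real_, pvalue = NA_real_, qvalue = NA_real_,
                    flag = "", row.names = NULL, stringsAsFactors = FALSE)
  ln2 <- log(2)
  for (id in testable) {
    y <- m[id, ]
    i <- match(id, res$otu_id)
    if (sum(y[x == 0]) == 0 || sum(y[x == 1]) == 0) {
      # all-zero group: Wald machinery degenerate, flagged, not called
      res$pvalue[i] <- 1
      res$flag[i] <- "zero_group"
      fit_s <- nb_glm_fit(y, x, offset, state$dispersion[id],
                          prior_prec = 1 / lfc_prior_sd^2)
      res$lfc_shrunk[i] <- fit_s[["b1"]] / ln2
      next
    }
    fit <- nb_glm_fit(y, x, offset, state$dispersion[id])
    fit_s <- nb_glm_fit(y, x, offset, state$dispersion[id],
                        prior_prec = 1 / lfc_prior_sd^2)
    res$lfc[i] <- fit[["b1"]] / ln2
    res$lfc_shrunk[i] <- fit_s[["b1"]] / ln2
    res$se[i] <- fit[["se1"]] / ln2
    res$stat[i] <- fit[["b1"]] / fit[["se1"]]
    res$pvalue[i] <- 2 * stats::pnorm(-abs(res$stat[i]))
  }
  ok <- !is.na(res$pvalue)
  res$qvalue[ok] <- bh_adjust(res$pvalue[ok])
  attr(res, "contrast") <- contrast_id
  class(res) <- c("da_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' q_(i) = min over j >= i of min(1, m/j * p_(j)), enforcing monotone
#' non-decreasing q in p-rank.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(n / (n:1) * p[o]))
  q[order(o)]
}

#' Filter disturbance-responsive OTUs and summarize by taxon group
#'
#' Keeps OTUs with q < `alpha` and |log2 fold change| > `lfc_cut` (shrunken
#' LFC by default), splits them into up/down by sign, and tallies counts and
#' mean absolute fold change per taxon group.
#'
#' @param res a `da_result` (or an already-filtered output of this function).
#' @param assignment a `category_assignment` covering the OTUs.
#' @param alpha FDR threshold (default 0.05).
#' @param lfc_cut log2 fold-change threshold (default 1).
#' @param use_shrunk filter on the shrunken LFC (default) or the raw one.
#' @param crat_group see [taxon_group()].
#' @return List: `table` (the filtered rows, with `group` and `direction`),
#'   `summary` (group x direction counts and mean |log2 FC|).
#' @export
responsive_otus <- function(res, assignment, alpha = 0.05, lfc_cut = 1,
                            use_shrunk = TRUE, crat_group = "rare") {
  lfc <- if (use_shrunk) res$lfc_shrunk else res$lfc
  keep <- !is.na(res$qvalue) & res$qvalue < alpha &
    !is.na(lfc) & abs(lfc) > lfc_cut
  tab <- res[keep, , drop = FALSE]
  lfc <- lfc[keep]
  tab$group <- taxon_group(assignment$category[tab$otu_id], crat_group)
  tab$direction <- ifelse(lfc > 0, "up", "down")
  cells <- expand.grid(group = TAXON_GROUPS, direction = c("up", "down"),
                       stringsAsFactors = FALSE)
  summary <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- tab$group == cells$group[i] & tab$direction == cells$direction[i]
    data.frame(group = cells$group[i], direction = cells$direction[i],
               n = sum(sel),
               mean_abs_lfc = if (any(sel)) mean(abs(lfc[sel])) else NA_real_)
  }))
  list(table = tab, summary = summary)
}
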