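#' Per-sample ratio of rare to abundant relative abundance
#'
#' (summed rare-group proportions, including NEW OTUs) / (summed
#' abundant-group proportions). Samples whose abundant share is zero are
#' dropped with a warning (the ratio is undefined there).
#'
#' @param rel a `rel_abundance`.
#' @param assignment a `category_assignment` covering the OTUs.
#' @param crat_group see [taxon_group()].
#' @return data.frame: sample metadata plus `ratio`.
#' @export
ratio_rare_abundant <- function(rel, assignment, crat_group = "rare") {
  p <- rel$proportions
  grp <- taxon_group(assignment$category[rownames(p)], crat_group)
  rare_share <- colSums(p[grp == "rare", , drop = FALSE])
  ab_share <- colSums(p[grp == "abundant", , drop = FALSE])
  out <- rel$metadata
  out$ratio <- rare_share / ab_share
  if (any(ab_share == 0)) {
    warning("zero abundant share in sample(s): ",
            paste(out$sample_id[ab_share == 0], collapse = ", "))
    out <- out[ab_share > 0, , drop = FALSE]
  }
  out
}

#' Linear regressions of community dissimilarity on the rare:abundant ratio
#'
#' Ordinary least squares of overall-community Bray-Curtis dissimilarity
#' from the initial state on the rare:abundant abundance ratio, fitted
#' separately per grouping level (e.g. per treatment across soils, or per
#' soil across treatments; heat is usually analyzed on its own because its
#' values sit on a different scale).
#'
#' @param ratios numeric vector (e.g. `ratio` from [ratio_rare_abundant()]).
#' @param dissimilarities numeric vector aligned with `ratios` (e.g. from
#'   [dissimilarity_to_initial()]).
#' @param grouping factor aligned with `ratios`; one regression per level.
#' @return data.frame of class `regression_result`: group, slope,
#'   intercept, r2, pvalue (two-sided slope t-test), n.
#' @export
ratio_dissimilarity_regression <- function(ratios, dissimilarities, grouping) {
  stopifnot(length(ratios) == length(dissimilarities),
            length(ratios) == length(grouping))
  grouping <- factor(grouping)
  res <- do.call(rbind, lapply(levels(grouping), function(g) {
    sel <- grouping == g & is.finite(ratios) & is.finite(dissimilarities)
    x <- ratios[sel]; y <- dissimilarities[sel]
    if (length(x) < 3) stop("group ", g, " has fewer than 3 paired values")
    if (stats::var(x) == 0) stop("zero variance in ratios for group ", g)
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    data.frame(group = g, slope = stats::coef(fit)[2],
               intercept = stats::coef(fit)[1],
               r2 = sm$r.squared,
               pvalue = sm$coefficients[2, 4],
               n = length(x), row.names = NULL)
  }))
  class(res) <- c("regression_result", "data.frame")
  res
}
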