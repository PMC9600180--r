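#' Abundance-category vocabulary
#'
#' OTUs are binned by their relative abundance across the initial (pre-
#' disturbance) samples of one soil system: always abundant (AAT, >= 1% in
#' every initial sample), conditionally abundant (CAT, >= 0.01% everywhere
#' and >= 1% somewhere), moderate (MT, within [0.01%, 1%) everywhere),
#' always rare (ART, < 0.01% everywhere), conditionally rare (CRT, < 0.01%
#' somewhere, never >= 1%), conditionally rare and abundant (CRAT, spanning
#' < 0.01% to >= 1%), and NEW (absent from every initial sample, treated as
#' rare). For abundant-vs-rare contrasts the groups are abundant = AAT+CAT,
#' common = MT, rare = ART+CRT+NEW (CRAT grouped with rare by default,
#' configurable).
#' @name taxon-categories
NULL

CATEGORIES <- c("AAT", "CAT", "MT", "CRT", "ART", "CRAT", "NEW")
TAXON_GROUPS <- c("abundant", "common", "rare")

#' Abundance thresholds for the rare/abundant classification
#'
#' @param rare_cutoff proportion below which an OTU counts as rare in a
#'   sample (default 1e-4, i.e. 0.01%).
#' @param abundant_cutoff proportion at or above which an OTU counts as
#'   abundant in a sample (default 1e-2, i.e. 1%).
#' @return A `thresholds` list.
#' @export
thresholds <- function(rare_cutoff = 1e-4, abundant_cutoff = 1e-2) {
  if (!(rare_cutoff > 0 && rare_cutoff < abundant_cutoff && abundant_cutoff < 1))
    stop("need 0 < rare_cutoff < abundant_cutoff < 1")
  structure(list(rare_cutoff = rare_cutoff, abundant_cutoff = abundant_cutoff),
            class = "thresholds")
}

#' Convert counts to per-sample relative abundances
#'
#' Each sample column is divided by its total read count.
#'
#' @param table an `otu_table`.
#' @return A `rel_abundance` object: column-stochastic `proportions` matrix
#'   plus the aligned metadata.
#' @export
relative_abundance <- function(table) {
  totals <- colSums(table$counts)
  zero <- colnames(table$counts)[totals == 0]
  if (length(zero))
    stop("all-zero sample(s): ", paste(zero, collapse = ", "))
  p <- sweep(table$counts, 2, totals, "/")
  structure(list(proportions = p, metadata = table$metadata),
            class = "rel_abundance")
}

#' Classify OTUs into abundance categories from initial samples
#'
#' Applies the six threshold predicates over the initial samples of one soil
#' system. OTUs present in the table but absent (zero) from every initial
#' sample are labelled `NEW`; they enter the rare group downstream.
#'
#' @param initial_rel a `rel_abundance` restricted to initial-timepoint
#'   samples of a single soil system.
#' @param th a `thresholds` object.
#' @param soil soil-system id recorded on the result (defaults to the one
#'   soil present in the metadata).
#' @return A `category_assignment`: named character vector `category` over
#'   all OTU ids, plus the thresholds and soil used.
#' @export
classify_taxa <- function(initial_rel, th = thresholds(), soil = NULL) {
  md <- initial_rel$metadata
  if (any(md$timepoint != "initial"))
    stop("classify_taxa expects only initial-timepoint samples")
  if (is.null(soil)) {
    soil <- unique(md$soil)
    if (length(soil) != 1)
      stop("initial_rel must contain a single soil system")
  }
  p <- initial_rel$proportions
  lo <- th$rare_cutoff
  hi <- th$abundant_cutoff
  # per-OTU predicates across the initial replicates
  all_hi   <- rowSums(p >= hi) == ncol(p)
  some_hi  <- rowSums(p >= hi) > 0
  all_mid  <- rowSums(p >= lo) == ncol(p)   # never drops below the rare cutoff
  all_lo   <- rowSums(p < lo) == ncol(p)
  some_lo  <- rowSums(p < lo) > 0
  absent   <- rowSums(p > 0) == 0
  cat <- character(nrow(p))
  cat[absent]                            <- "NEW"
  cat[!absent & all_hi]                  <- "AAT"
  cat[!absent & !all_hi & some_hi & all_mid] <- "CAT"
  cat[!absent & some_hi & some_lo]       <- "CRAT"
  cat[!absent & !some_hi & all_lo]       <- "ART"
  cat[!absent & !some_hi & some_lo & !all_lo] <- "CRT"
  cat[!absent & !some_hi & all_mid]      <- "MT"
  names(cat) <- rownames(p)
  stopifnot(all(cat %in% CATEGORIES))
  structure(list(category = cat, thresholds = th, soil = soil),
            class = "category_assignment")
}

#' Map categories onto the abundant/common/rare dichotomy
#'
#' @param categories character vector of category labels.
#' @param crat_group group for CRAT OTUs when they occur ("rare" by default).
#' @return Character vector over `TAXON_GROUPS`.
#' @export
taxon_group <- function(categories, crat_group = c("rare", "abundant", "common")) {
  crat_group <- match.arg(crat_group)
  map <- c(AAT = "abundant", CAT = "abundant", MT = "common",
           ART = "rare", CRT = "rare", NEW = "rare", CRAT = crat_group)
  unname(map[categories])
}

#' OTU ids belonging to a taxon group
#'
#' @param assignment a `category_assignment`.
#' @param group one of "abundant", "common", "rare".
#' @param crat_group see [taxon_group()].
#' @return Character vector of OTU ids.
#' @export
group_otus <- function(assignment, group, crat_group = "rare") {
  group <- match.arg(group, TAXON_GROUPS)
  names(assignment$category)[taxon_group(assignment$category, crat_group) == group]
}

#' Category-level abundance flux across treatments and timepoints
#'
#' Computes, for each treatment x timepoint cell, the replicate-mean summed
#' relative abundance of the abundant, common and rare groups (with the NEW
#' share also reported on its own, inside rare), and the per-group flow edges
#' between consecutive timepoints that a Sankey plot would draw.
#'
#' @param rel a `rel_abundance` covering one soil system (any timepoints).
#' @param assignment the soil's `category_assignment`; must cover every OTU.
#' @param crat_group see [taxon_group()].
#' @return List with `shares` (long data.frame: treatment, timepoint, group,
#'   share, new_share) and `flows` (data.frame of consecutive-timepoint
#'   edges: treatment, from, to, group, share_from, share_to, delta).
#' @export
category_abundance_flux <- function(rel, assignment, crat_group = "rare") {
  p <- rel$proportions
  unassigned <- setdiff(rownames(p), names(assignment$category))
  if (length(unassigned))
    stop("OTUs without category assignment: ",
         paste(utils::head(unassigned, 5), collapse = ", "))
  grp <- taxon_group(assignment$category[rownames(p)], crat_group)
  md <- rel$metadata
  # per-sample summed share of each group
  share_mat <- rowsum(p, grp)                       # groups x samples
  new_share <- colSums(p[assignment$category[rownames(p)] == "NEW", ,
                         drop = FALSE])
  cells <- unique(md[, c("treatment", "timepoint")])
  shares <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- md$treatment == cells$treatment[i] & md$timepoint == cells$timepoint[i]
    data.frame(treatment = cells$treatment[i], timepoint = cells$timepoint[i],
               group = rownames(share_mat),
               share = rowMeans(share_mat[, sel, drop = FALSE]),
               new_share = ifelse(rownames(share_mat) == "rare",
                                  mean(new_share[sel]), 0),
               row.names = NULL)
  }))
  tp_order <- intersect(TIMEPOINTS, unique(md$timepoint))
  flows <- NULL
  if (length(tp_order) > 1) {
    treatments <- setdiff(unique(md$treatment), NA)
    for (tr in treatments) {
      tps <- tp_order[tp_order %in%
                        c("initial", md$timepoint[md$treatment == tr])]
      if (length(tps) < 2) next
      for (k in seq_len(length(tps) - 1)) {
        from <- tps[k]; to <- tps[k + 1]
        s_from <- shares[shares$timepoint == from &
                           (shares$treatment == tr | from == "initial"), ]
        s_to <- shares[shares$treatment == tr & shares$timepoint == to, ]
        m <- merge(s_from[, c("group", "share")], s_to[, c("group", "share")],
                   by = "group", suffixes = c("_from", "_to"))
        flows <- rbind(flows, data.frame(treatment = tr, from = from, to = to,
                                         m, row.names = NULL))
      }
    }
    if (!is.null(flows)) flows$delta <- flows$share_to - flows$share_from
  }
  if (is.null(flows))
    flows <- data.frame(treatment = character(), from = character(),
                        to = character(), group = character(),
                        share_from = numeric(), share_to = numeric(),
                        delta = numeric())
  list(shares = shares, flows = flows)
}
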