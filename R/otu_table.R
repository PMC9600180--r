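#' @keywords internal
"_PACKAGE"

# Design vocabulary of the mesocosm layout: two long-term fertilization
# regimes (NCF chemical, NOF organic), five disturbance treatments and five
# sampling occasions (initial = pre-disturbance, R0/R2/R40/R170 = days of
# recovery after the 80-day disturbance window).
SOILS      <- c("NCF", "NOF")
TREATMENTS <- c("AMB", "DR", "FL", "FR", "HE")
TIMEPOINTS <- c("initial", "R0", "R2", "R40", "R170")

#' OTU count table with aligned sample metadata
#'
#' Lightweight container for an integer OTU-by-sample count matrix plus its
#' sample metadata. Columns of `counts` and rows of `metadata` are matched
#' one-to-one by sample id.
#'
#' @param counts integer matrix, OTUs in rows (rownames = OTU ids), samples
#'   in columns (colnames = sample ids).
#' @param metadata data.frame with columns `sample_id`, `soil`, `treatment`,
#'   `timepoint`, `replicate`; one row per sample, in any order.
#' @return An object of class `otu_table`.
#' @export
otu_table <- function(counts, metadata) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique OTU ids as rownames")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("counts must have unique sample ids as colnames")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max in sums
  req <- c("sample_id", "soil", "treatment", "timepoint", "replicate")
  miss <- setdiff(req, names(metadata))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id)) stop("duplicate sample_id in metadata")
  unmatched <- setdiff(colnames(counts), metadata$sample_id)
  if (length(unmatched))
    stop("samples missing from metadata: ", paste(unmatched, collapse = ", "))
  extra <- setdiff(metadata$sample_id, colnames(counts))
  if (length(extra))
    stop("metadata rows without a counts column: ", paste(extra, collapse = ", "))
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(counts = counts, metadata = metadata), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples\n", nrow(x$counts), ncol(x$counts)))
  cat("soils:      ", paste(sort(unique(x$metadata$soil)), collapse = " "), "\n")
  cat("treatments: ", paste(sort(unique(x$metadata$treatment)), collapse = " "), "\n")
  cat("timepoints: ", paste(intersect(TIMEPOINTS, unique(x$metadata$timepoint)),
                            collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Subset an OTU table by samples and/or OTUs
#'
#' @param x an `otu_table` or `rel_abundance` object.
#' @param samples logical/integer/character index into samples.
#' @param otus logical/integer/character index into OTUs.
#' @return Object of the same class restricted to the selection.
#' @export
subset_samples <- function(x, samples = NULL, otus = NULL) {
  mat_name <- if (inherits(x, "rel_abundance")) "proportions" else "counts"
  m <- x[[mat_name]]
  if (!is.null(otus)) m <- m[otus, , drop = FALSE]
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  md <- x$metadata[match(colnames(m), x$metadata$sample_id), , drop = FALSE]
  rownames(md) <- NULL
  out <- x
  out[[mat_name]] <- m
  out$metadata <- md
  out
}

#' Read an OTU table and metadata from tab-separated files
#'
#' The counts file is a tab-separated matrix whose first column holds OTU ids
#' and whose header holds sample ids; the metadata file is tab-separated with
#' columns `sample_id`, `soil`, `treatment`, `timepoint`, `replicate`.
#' A JSON BIOM file may be given instead of the TSV matrix (requires the
#' biomformat package).
#'
#' @param counts_path path to the count matrix (TSV) or BIOM (JSON) file.
#' @param metadata_path path to the metadata TSV.
#' @return An `otu_table`.
#' @export
read_otu_table <- function(counts_path, metadata_path) {
  if (!file.exists(counts_path)) stop("counts file not found: ", counts_path)
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)
  if (grepl("\\.biom$", counts_path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the biomformat package")
    b <- biomformat::read_biom(counts_path)
    counts <- as.matrix(biomformat::biom_data(b))
  } else {
    df <- utils::read.delim(counts_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- df[[1]]
  }
  if (any(counts != round(counts)))
    stop("non-integer counts in ", counts_path)
  metadata <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  otu_table(counts, metadata)
}

#' Write an OTU table (and metadata) as tab-separated files
#'
#' @param x an `otu_table`.
#' @param counts_path output path for the count matrix TSV.
#' @param metadata_path optional output path for the metadata TSV.
#' @return Invisibly, `x`.
#' @export
write_otu_table <- function(x, counts_path, metadata_path = NULL) {
  df <- data.frame(otu_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(metadata_path))
    utils::write.table(x$metadata, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(x)
}

# sample-id convention: soil_treatment_timepoint_replicate; initial samples
# are soil_initial_<rep> (no treatment: they precede the disturbance).
make_sample_id <- function(soil, treatment, timepoint, replicate) {
  n <- max(length(soil), length(treatment), length(timepoint),
           length(replicate))
  soil <- rep_len(soil, n); treatment <- rep_len(treatment, n)
  timepoint <- rep_len(timepoint, n); replicate <- rep_len(replicate, n)
  ifelse(timepoint == "initial",
         paste(soil, "initial", replicate, sep = "_"),
         paste(soil, treatment, timepoint, replicate, sep = "_"))
}

is_initial <- function(metadata) metadata$timepoint == "initial"
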