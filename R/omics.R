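#' Average replicate log-ratios per gene
#'
#' First step of the transcriptome selection procedure: the arithmetic
#' mean of each gene's normalized log-ratios (condition vs reference)
#' over the experimental replicates, ignoring missing values.  Genes
#' with no finite value at all are dropped with a warning.
#'
#' @param x a data frame with a `gene_id` column and one numeric column
#'   per replicate, or a numeric matrix with gene ids as row names.
#' @return tibble: `gene_id`, `mean_log_ratio`, `n_used`.
#' @export
average_log_ratio <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort("matrix input needs gene ids as rownames")
    x <- bind_cols(tibble(gene_id = rownames(x)), as_tibble(x))
  }
  x <- as_tibble(x)
  if (!"gene_id" %in% names(x)) abort("`x` needs a `gene_id` column")
  reps <- setdiff(names(x), "gene_id")
  if (length(reps) < 1) abort("need at least one replicate column")
  mat <- as.matrix(x[reps])
  storage.mode(mat) <- "double"
  n_used <- rowSums(is.finite(mat))
  means <- rowSums(mat * is.finite(mat), na.rm = TRUE) / n_used
  drop <- n_used == 0
  if (any(drop)) {
    warn(paste0("genes with no finite log-ratio dropped: ",
                comma(x$gene_id[drop])))
  }
  tibble(gene_id = x$gene_id, mean_log_ratio = means,
         n_used = as.integer(n_used))[!drop, ]
}

#' Select differentially expressed genes by z-score
#'
#' Standardizes the per-gene mean log-ratios across genes,
#' `z_g = (mean_g - grand_mean) / sigma`, with `sigma` the
#' denominator-`N` (population) standard deviation, and selects the
#' genes with `z` strictly greater than the threshold (one-sided upward;
#' the default 1.65 corresponds to roughly the upper 5% of a standard
#' normal).
#'
#' @param means output of [average_log_ratio()] (or any data frame with
#'   `gene_id` and `mean_log_ratio`), or a named numeric vector.
#' @param threshold z-score cut-off.
#' @return a `"selection_result"` tibble: `gene_id`, `mean_log_ratio`,
#'   `z`, `selected`; attributes `threshold`, `grand_mean`, `sigma`.
#' @seealso [selected_genes()]
#' @export
zscore_select <- function(means, threshold = 1.65) {
  if (is.numeric(means)) {
    if (is.null(names(means))) abort("vector input must be named by gene id")
    means <- tibble(gene_id = names(means), mean_log_ratio = unname(means))
  }
  means <- as_tibble(means)
  if (!all(c("gene_id", "mean_log_ratio") %in% names(means))) {
    abort("`means` needs columns `gene_id` and `mean_log_ratio`")
  }
  m <- means$mean_log_ratio
  grand <- mean(m)
  sigma <- sqrt(mean((m - grand)^2))
  if (sigma == 0 || length(m) < 2) {
    warn("log-ratio means carry no dispersion; nothing selected")
    z <- rep(NA_real_, length(m))
    sel <- rep(FALSE, length(m))
  } else {
    z <- (m - grand) / sigma
    sel <- z > threshold
  }
  out <- tibble(gene_id = means$gene_id, mean_log_ratio = m,
                z = z, selected = sel)
  attr(out, "threshold") <- threshold
  attr(out, "grand_mean") <- grand
  attr(out, "sigma") <- sigma
  class(out) <- c("selection_result", class(out))
  out
}

#' Genes selected by [zscore_select()]
#'
#' @param selection a `"selection_result"`.
#' @return character vector of selected gene ids.
#' @export
selected_genes <- function(selection) {
  stopifnot(inherits(selection, "selection_result"))
  selection$gene_id[selection$selected]
}

#' Merge transcriptome and proteome evidence into a benchmark set
#'
#' Union of the genes supported by either technology; the size of the
#' two-technology overlap is recorded (and messaged) because it
#' quantifies how complementary the channels are.
#'
#' @param transcriptome character vector of selected genes, or a
#'   `"selection_result"`.
#' @param proteome character vector of protein-coding genes detected, or
#'   an [omics_gene_set()].
#' @param quiet suppress the overlap message.
#' @return an [omics_gene_set()] labelled `"benchmark"` (enzymes carried
#'   over from the proteome set, if any) with attribute `overlap`.
#' @export
merge_benchmark <- function(transcriptome, proteome, quiet = FALSE) {
  tg <- if (inherits(transcriptome, "selection_result")) {
    selected_genes(transcriptome)
  } else {
    unique(as.character(transcriptome))
  }
  enz <- character(0)
  if (inherits(proteome, "omics_gene_set")) {
    enz <- proteome$enzymes
    pg <- proteome$genes
  } else {
    pg <- unique(as.character(proteome))
  }
  overlap <- length(intersect(tg, pg))
  if (!quiet) {
    inform(paste0("merge_benchmark: ", length(tg), " transcriptome + ",
                  length(pg), " proteome genes, overlap ", overlap,
                  ", union ", length(union(tg, pg))))
  }
  out <- omics_gene_set("benchmark", genes = union(tg, pg), enzymes = enz)
  attr(out, "overlap") <- overlap
  out
}
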