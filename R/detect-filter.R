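#' Aggregate feature detection flags to gene-level calls
#'
#' AFE emits the detection flag per feature; a microRNA is called detected
#' on an array when the chosen fraction of its features carries the flag.
#' The default rule is a simple majority (at least half the features);
#' \code{"any"} and \code{"all"} are available because the vendor's own
#' gene-level aggregation is unpublished.
#'
#' @param tables List of [feature_table()] objects.
#' @param design The array design.
#' @param rule \code{"majority"}, \code{"any"} or \code{"all"}.
#' @param majority_fraction Feature fraction required under
#'   \code{"majority"} (default 0.5, compared with \code{>=}).
#' @return Gene x array binary (0/1) matrix.
#' @export
gene_flags <- function(tables, design,
                       rule = c("majority", "any", "all"),
                       majority_fraction = 0.5) {
  rule <- match.arg(rule)
  genes <- design$gene_ids
  out <- matrix(0L, nrow = length(genes), ncol = length(tables),
                dimnames = list(genes,
                                vapply(tables, `[[`, character(1L),
                                       "array_id")))
  for (j in seq_along(tables)) {
    f <- tables[[j]]$features
    f <- f[!f$is_control & f$gene_id %in% genes, ]
    frac <- tapply(f$is_gene_detected, factor(f$gene_id, levels = genes),
                   mean)
    out[, j] <- switch(rule,
                       majority = as.integer(frac >= majority_fraction),
                       any = as.integer(frac > 0),
                       all = as.integer(frac == 1))
  }
  out
}

#' Filter microRNAs expressed in at least one experimental group
#'
#' A microRNA is kept when, in at least one group, the fraction of arrays
#' on which it is called detected reaches \code{min_fraction}.  The default
#' (1.0: detected on every replicate of some group) is the strictest
#' reading of "expressed in at least one experimental group"; the fraction
#' is configurable because the original rule is unpublished.  Control
#' entries never survive the filter.
#'
#' @param m Gene x array [expression_matrix()] (any scale).
#' @param flags Gene x array binary matrix from [gene_flags()].
#' @param groups Named character vector, array id -> group label, covering
#'   every array of \code{m}.
#' @param min_fraction Required within-group detection fraction, in
#'   \code{(0, 1]}.
#' @return List with \code{matrix} (the filtered expression matrix) and
#'   \code{calls}, a per-gene audit data frame (per-group detection plus
#'   the kept flag).
#' @export
filter_expressed <- function(m, flags, groups, min_fraction = 1.0) {
  if (!(min_fraction > 0 && min_fraction <= 1))
    stop("min_fraction must be in (0, 1]")
  stopifnot(all(colnames(m) %in% names(groups)),
            all(colnames(m) %in% colnames(flags)))
  genes <- intersect(rownames(m), rownames(flags))
  genes <- genes[!.is_control_name(genes)]
  fl <- flags[genes, colnames(m), drop = FALSE]
  grp <- groups[colnames(m)]
  per_group <- vapply(unique(grp), function(g)
    rowMeans(fl[, grp == g, drop = FALSE]) >= min_fraction,
    logical(length(genes)))
  if (is.null(dim(per_group)))
    per_group <- matrix(per_group, ncol = length(unique(grp)),
                        dimnames = list(genes, unique(grp)))
  kept <- rowSums(per_group) > 0
  calls <- data.frame(gene_id = genes, per_group, kept = kept,
                      row.names = NULL, check.names = FALSE,
                      stringsAsFactors = FALSE)
  out <- m[genes[kept], , drop = FALSE]
  list(matrix = out, calls = calls)
}
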