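#' Collapse replicate features to probe-level data
#'
#' Each distinct probe is spotted several times per array; per the
#' processing order (after normalization and log2 transformation) the
#' replicate features are collapsed to their median, yielding 1--4 probe
#' measures per microRNA per array.
#'
#' @param features Feature x array matrix from [assemble_features()] (log2
#'   scale), carrying \code{probe_id}/\code{gene_id} row attributes.
#' @param design An array design ([infer_design()] or [make_design()]).
#' @return A \code{"ProbeMatrix"}: probe x array matrix with a
#'   \code{gene_of} attribute.
#' @export
collapse_replicates <- function(features, design) {
  probe <- attr(features, "probe_id")
  if (is.null(probe)) probe <- rownames(features)
  if (is.null(probe)) stop("feature matrix lacks probe labels")
  zero <- design$replicates_per_probe == 0L
  if (any(zero))
    stop("probe(s) with zero replicates in design: ",
         paste(names(design$replicates_per_probe)[zero], collapse = ", "))
  probes <- names(design$replicates_per_probe)
  idx <- split(seq_along(probe), factor(probe, levels = probes))
  vals <- t(vapply(idx, function(i) {
    if (length(i) == 1L) features[i, ] else
      apply(features[i, , drop = FALSE], 2L, stats::median)
  }, numeric(ncol(features))))
  gene <- design$gene_of[probes]
  o <- order(gene, probes)
  pm <- vals[o, , drop = FALSE]
  rownames(pm) <- probes[o]
  colnames(pm) <- colnames(features)
  structure(pm, gene_of = gene[o], scale = "log2",
            class = c("ProbeMatrix", "matrix", "array"))
}

#' @export
print.ProbeMatrix <- function(x, ...) {
  cat("ProbeMatrix: ", nrow(x), " probes x ", ncol(x), " arrays (",
      length(unique(attr(x, "gene_of"))), " genes)\n", sep = "")
  invisible(x)
}

#' Tukey median polish of a two-way table
#'
#' Fits the additive decomposition \code{value = overall + row_effect +
#' col_effect + residual} by alternately sweeping row and column medians
#' out of the residuals (rows first), stopping when the relative change in
#' the sum of absolute residuals falls below \code{eps} or after
#' \code{maxiter} sweeps.  Residuals are recomputed against the fit at the
#' end so the reconstruction identity holds exactly.
#'
#' @param m Numeric probe x array matrix, all finite.
#' @param eps Relative convergence tolerance on the sum of absolute
#'   residuals (default 0.01).
#' @param maxiter Maximum full sweeps (default 10).
#' @return A list of class \code{"MedianPolishFit"} with components
#'   \code{overall}, \code{row_effects}, \code{col_effects},
#'   \code{residuals}, \code{iterations}, \code{converged}.
#' @export
median_polish <- function(m, eps = 0.01, maxiter = 10L) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (!all(is.finite(m))) stop("non-finite values in median_polish input")
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(nr >= 1L, nc >= 1L)
  z <- m
  t0 <- 0
  r <- numeric(nr); cc <- numeric(nc)
  oldsum <- 0
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxiter)) {
    rdelta <- apply(z, 1L, stats::median)
    z <- z - rdelta
    r <- r + rdelta
    delta <- stats::median(cc)
    cc <- cc - delta
    t0 <- t0 + delta
    cdelta <- apply(z, 2L, stats::median)
    z <- sweep(z, 2L, cdelta)
    cc <- cc + cdelta
    delta <- stats::median(r)
    r <- r - delta
    t0 <- t0 + delta
    newsum <- sum(abs(z))
    converged <- newsum == 0 || abs(newsum - oldsum) < eps * newsum
    if (converged) break
    oldsum <- newsum
  }
  resid <- m - (t0 + outer(r, cc, "+"))  # identity exact by construction
  structure(list(overall = t0,
                 row_effects = stats::setNames(r, rownames(m)),
                 col_effects = stats::setNames(cc, colnames(m)),
                 residuals = resid,
                 iterations = iter,
                 converged = converged),
            class = "MedianPolishFit")
}

#' Summarize probe-level data into one microRNA signal per array
#'
#' For each microRNA, fits the additive model \code{log2 signal =
#' expression + probe effect + error} to its probe x array submatrix by
#' [median_polish()]; the per-array expression estimate is
#' \code{overall + col_effect}, treating probe affinities as nuisance.
#' MicroRNAs measured by a single probe pass through unchanged.
#'
#' @param pm A [collapse_replicates()] probe matrix on the log2 scale.
#' @param design The array design.
#' @param method Label stored on the result.
#' @return An [expression_matrix()] on the log2 scale.
#' @export
rma_summarize <- function(pm, design, method = "norRMA") {
  gene_of <- attr(pm, "gene_of")
  if (is.null(gene_of)) gene_of <- design$gene_of[rownames(pm)]
  miss <- setdiff(design$gene_ids, unique(gene_of))
  if (length(miss))
    stop("gene(s) in design absent from probe matrix: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  genes <- design$gene_ids
  out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(pm),
                dimnames = list(genes, colnames(pm)))
  idx <- split(seq_len(nrow(pm)), factor(gene_of, levels = genes))
  for (g in seq_along(genes)) {
    sub <- pm[idx[[g]], , drop = FALSE]
    if (nrow(sub) == 1L) {
      out[g, ] <- sub[1L, ]
    } else {
      fit <- median_polish(sub)
      out[g, ] <- fit$overall + fit$col_effects
    }
  }
  expression_matrix(out, scale = "log2", method = method)
}

#' Options for the vendor-style total gene signal
#'
#' @param robust_average \code{"median"} (default) or
#'   \code{"outlier_trimmed_mean"} (drop values beyond 1.5 x IQR from the
#'   quartiles, then mean).  The vendor's own robust-average rule is
#'   proprietary; the median is deterministic and documented.
#' @return A list of class \code{"TgsOptions"}.
#' @export
tgs_options <- function(robust_average = c("median",
                                           "outlier_trimmed_mean")) {
  robust_average <- match.arg(robust_average)
  structure(list(robust_average = robust_average), class = "TgsOptions")
}

.robust_avg <- function(v, kind) {
  if (kind == "median" || length(v) < 4L) return(stats::median(v))
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7L)
  iqr <- q[2L] - q[1L]
  keep <- v >= q[1L] - 1.5 * iqr & v <= q[2L] + 1.5 * iqr
  mean(v[keep])
}

#' Compute the vendor-style total gene signal (TGS)
#'
#' Per probe, the total probe signal is the robust average of the
#' background-subtracted replicate-feature signals times the number of
#' replicates; the per-microRNA TGS is the sum of its probes' total probe
#' signals.  Values are on the linear scale and may be negative, since
#' background-subtracted inputs can be.
#'
#' @param tables List of [feature_table()] objects.
#' @param design The array design.
#' @param opts A [tgs_options()] object.
#' @return An [expression_matrix()] (linear scale, method
#'   \code{"TGS_raw"}).
#' @export
compute_tgs <- function(tables, design, opts = tgs_options()) {
  stopifnot(inherits(opts, "TgsOptions"))
  fm <- assemble_features(tables, design, channel = "bgsub")
  probe <- attr(fm, "probe_id")
  probes <- names(design$replicates_per_probe)
  idx <- split(seq_along(probe), factor(probe, levels = probes))
  tps <- t(vapply(seq_along(probes), function(i) {
    v <- fm[idx[[i]], , drop = FALSE]
    apply(v, 2L, .robust_avg, kind = opts$robust_average) * nrow(v)
  }, numeric(ncol(fm))))
  gene <- design$gene_of[probes]
  tgs <- rowsum(tps, group = gene, reorder = TRUE)
  tgs <- tgs[design$gene_ids, , drop = FALSE]
  colnames(tgs) <- colnames(fm)
  expression_matrix(tgs, scale = "linear", method = "TGS_raw")
}

#' Run a full preprocessing route
#'
#' The four processed signals:
#' \describe{
#'   \item{nor75}{TGS, positivity offset, per-array 75th-percentile
#'     scaling, log2.}
#'   \item{norQ}{TGS, positivity offset, quantile normalization, log2.}
#'   \item{norRMA}{raw mean signals, quantile normalization, log2,
#'     replicate-median collapse, median-polish summarization.}
#'   \item{norRMAbg}{as norRMA but with exponential+normal background
#'     correction of the mean signals first (per array, experimental
#'     features only).}
#' }
#'
#' @param tables List of [feature_table()] objects (>= 2 arrays).
#' @param method One of \code{"nor75"}, \code{"norQ"}, \code{"norRMA"},
#'   \code{"norRMAbg"}.
#' @param design Optional design; inferred from the tables if omitted.
#' @param opts TGS options for the nor75/norQ routes.
#' @param bg Optional list of [bg_params()] (one per array, in table
#'   order) for the norRMAbg route; estimated per array from the
#'   experimental features when \code{NULL}.
#' @return An [expression_matrix()] on the log2 scale, tagged with the
#'   method.  Background parameter fits (norRMAbg) are attached as
#'   attribute \code{"bg_params"}.
#' @export
process_arrays <- function(tables,
                           method = c("nor75", "norQ", "norRMA",
                                      "norRMAbg"),
                           design = NULL, opts = tgs_options(),
                           bg = NULL) {
  method <- match.arg(method)
  stopifnot(length(tables) >= 2L)
  if (is.null(design)) design <- infer_design(tables)
  if (method %in% c("nor75", "norQ")) {
    tgs <- compute_tgs(tables, design, opts)
    m <- shift_positive(unclass(tgs))
    m <- if (method == "nor75") scale_to_percentile75(m)
    else quantile_normalize(m)
    return(expression_matrix(log2_transform(m), scale = "log2",
                             method = method))
  }
  fm <- assemble_features(tables, design, channel = "mean")
  bgp <- NULL
  if (method == "norRMAbg") {
    if (!is.null(bg)) stopifnot(length(bg) == ncol(fm))
    bgp <- vector("list", ncol(fm))
    names(bgp) <- colnames(fm)
    for (j in seq_len(ncol(fm))) {
      bgp[[j]] <- if (is.null(bg)) estimate_bg_params(fm[, j]) else bg[[j]]
      fm[, j] <- correct_background(fm[, j], bgp[[j]])
    }
  }
  qn <- quantile_normalize(fm)
  attributes(qn)[c("probe_id", "gene_id")] <-
    attributes(fm)[c("probe_id", "gene_id")]
  lg <- log2_transform(qn)
  attributes(lg)[c("probe_id", "gene_id")] <-
    attributes(fm)[c("probe_id", "gene_id")]
  pm <- collapse_replicates(lg, design)
  em <- rma_summarize(pm, design, method = method)
  attr(em, "bg_params") <- bgp
  em
}
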