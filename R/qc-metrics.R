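#' Replicate precision: per-gene mean and SD within biological groups
#'
#' For every microRNA and every biological group, computes the mean and the
#' sample SD (n-1 denominator) of the log2 expression values across that
#' group's arrays.  Precision profiles are computed per group because
#' biological replicates exist only within a group.
#'
#' @param m Gene x array matrix on the log2 scale.
#' @param groups Named character vector mapping array id to group label.
#' @return A list of \code{"SdProfile"} data frames (columns
#'   \code{gene_id}, \code{mean_log2}, \code{sd_log2}, \code{group}), one
#'   per group.
#' @export
replicate_sd <- function(m, groups) {
  stopifnot(!is.null(colnames(m)), all(colnames(m) %in% names(groups)))
  groups <- groups[colnames(m)]
  out <- lapply(unique(groups), function(g) {
    cols <- which(groups == g)
    if (length(cols) < 2L)
      stop("group '", g, "' has fewer than 2 arrays; SD undefined")
    sub <- m[, cols, drop = FALSE]
    df <- data.frame(gene_id = rownames(m),
                     mean_log2 = rowMeans(sub),
                     sd_log2 = apply(sub, 1L, stats::sd),
                     group = g,
                     row.names = NULL,
                     stringsAsFactors = FALSE)
    class(df) <- c("SdProfile", "data.frame")
    df
  })
  names(out) <- unique(groups)
  out
}

#' Fit a natural-cubic-spline trend of SD against mean intensity
#'
#' Least-squares fit of per-gene replicate SD on a natural cubic spline
#' basis in the per-gene mean log2 intensity.  The default 5 knots are
#' placed at the 1/6, 2/6, ..., 5/6 quantiles of the mean intensities; the
#' outer two serve as boundary knots, beyond which the fit is linear
#' (natural boundary conditions).
#'
#' @param profile An \code{"SdProfile"} data frame from [replicate_sd()]
#'   (or any data frame with \code{mean_log2} and \code{sd_log2}).
#' @param n_knots Total number of knots (default 5).
#' @return A list of class \code{"SplineTrend"}: \code{knots},
#'   \code{coefficients}, and \code{fitted} (a 100-point \code{(x, y)}
#'   grid spanning the x range).
#' @export
fit_sd_trend <- function(profile, n_knots = 5L) {
  x <- profile$mean_log2
  y <- profile$sd_log2
  stopifnot(length(x) >= n_knots + 2L, n_knots >= 3L)
  if (diff(range(x)) <= 0) stop("mean intensities are degenerate")
  probs <- seq_len(n_knots) / (n_knots + 1L)
  kn <- stats::quantile(x, probs, names = FALSE, type = 7L)
  if (anyDuplicated(kn)) stop("degenerate (tied) knot positions")
  basis <- splines::ns(x, knots = kn[-c(1L, n_knots)],
                       Boundary.knots = kn[c(1L, n_knots)])
  fit <- stats::lm.fit(cbind(1, basis), y)
  grid <- seq(min(x), max(x), length.out = 100L)
  gb <- splines::ns(grid, knots = kn[-c(1L, n_knots)],
                    Boundary.knots = kn[c(1L, n_knots)])
  yhat <- drop(cbind(1, gb) %*% fit$coefficients)
  structure(list(knots = kn,
                 coefficients = fit$coefficients,
                 fitted = data.frame(x = grid, y = yhat),
                 group = if (!is.null(profile$group))
                   profile$group[[1L]] else NA_character_),
            class = "SplineTrend")
}

#' Relative log expression (RLE) statistics
#'
#' RLE measures how far each array's signal for a microRNA sits from that
#' microRNA's median across all arrays:
#' \code{rle[i, j] = m[i, j] - median_j(m[i, ])}.  Well-normalized arrays
#' give per-array RLE distributions centered on zero with comparable
#' spread.
#'
#' @param m Gene x array matrix on the log2 scale (>= 2 arrays).
#' @return A list of class \code{"RleSummary"} with \code{rle_matrix} and
#'   \code{summary}, a per-array data frame of the five-number summary
#'   (min, Q1, median, Q3, max; type-7 quantiles).
#' @export
rle_stats <- function(m) {
  stopifnot(is.matrix(m), ncol(m) >= 2L)
  med <- apply(m, 1L, stats::median)
  r <- m - med
  s <- t(apply(r, 2L, stats::quantile,
               probs = c(0, 0.25, 0.5, 0.75, 1), type = 7L))
  summ <- data.frame(array_id = colnames(m),
                     min = s[, 1L], q1 = s[, 2L], median = s[, 3L],
                     q3 = s[, 4L], max = s[, 5L],
                     row.names = NULL, stringsAsFactors = FALSE)
  structure(list(rle_matrix = r, summary = summ), class = "RleSummary")
}

#' @export
print.RleSummary <- function(x, ...) {
  cat("RleSummary:", nrow(x$rle_matrix), "genes x",
      ncol(x$rle_matrix), "arrays\n")
  print(x$summary, digits = 3L)
  invisible(x)
}

#' Compare preprocessing methods on replicate precision and RLE
#'
#' Runs [process_arrays()] for each requested method on a common set of
#' arrays, then computes SD profiles, spline trends and RLE summaries on
#' the shared gene set.
#'
#' @param tables List of [feature_table()] objects.
#' @param groups Named character vector, array id -> group label.
#' @param methods Character vector of processing routes (>= 2).
#' @param design Optional design; inferred if omitted.
#' @return A list of class \code{"MethodComparison"}: per-method bundles
#'   (\code{expr}, \code{sd_profiles}, \code{trends}, \code{rle}) plus
#'   \code{sd_table}, a tidy long-format data frame (method, gene, group,
#'   mean, SD).
#' @export
compare_methods <- function(tables, groups,
                            methods = c("nor75", "norQ", "norRMA",
                                        "norRMAbg"),
                            design = NULL) {
  stopifnot(length(methods) >= 2L)
  if (is.null(design)) design <- infer_design(tables)
  per <- lapply(methods, function(mth) {
    em <- process_arrays(tables, method = mth, design = design)
    prof <- replicate_sd(em, groups)
    trends <- lapply(prof, fit_sd_trend)
    list(expr = em, sd_profiles = prof, trends = trends,
         rle = rle_stats(unclass(em)))
  })
  names(per) <- methods
  sd_table <- do.call(rbind, lapply(methods, function(mth) {
    df <- do.call(rbind, per[[mth]]$sd_profiles)
    df$method <- mth
    rownames(df) <- NULL
    df[c("method", "gene_id", "group", "mean_log2", "sd_log2")]
  }))
  structure(c(per, list(sd_table = sd_table)),
            class = "MethodComparison")
}

#' Plot fitted SD-vs-mean spline trends
#'
#' @param trends Named list of \code{"SplineTrend"} objects (e.g. one per
#'   method).
#' @param ... Passed to \code{matplot}-style base graphics.
#' @export
plot_sd_trend <- function(trends, ...) {
  xs <- lapply(trends, function(t) t$fitted$x)
  ys <- lapply(trends, function(t) t$fitted$y)
  graphics::plot(NA, xlim = range(unlist(xs)), ylim = range(0, unlist(ys)),
                 xlab = "mean log2 intensity", ylab = "replicate SD (log2)",
                 ...)
  for (i in seq_along(trends))
    graphics::lines(xs[[i]], ys[[i]], col = i, lwd = 2)
  graphics::legend("topright", legend = names(trends), col = seq_along(trends),
                   lwd = 2, bty = "n")
  invisible(NULL)
}

#' RLE boxplots per array
#'
#' @param x An \code{"RleSummary"}.
#' @param ... Passed to \code{boxplot}.
#' @export
plot_rle <- function(x, ...) {
  stopifnot(inherits(x, "RleSummary"))
  graphics::boxplot(x$rle_matrix, las = 2L, outline = FALSE,
                    ylab = "relative log expression", ...)
  graphics::abline(h = 0, lty = 2L)
  invisible(NULL)
}
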