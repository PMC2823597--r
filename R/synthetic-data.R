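#' Build the Human microRNA Microarray v2.0-style design
#'
#' Constructs an [infer_design()]-compatible design in which each microRNA
#' is interrogated by 1--4 distinct oligonucleotide probes whose features
#' together total \code{features_per_gene} spots.  The default composition
#' mirrors the v2.0 layout: 362 microRNAs with 2 oligos, 45 with 3, 390
#' with 4 and 2 with a single oligo, each microRNA replicated 16 times.
#' Features are split across a gene's oligos as evenly as possible
#' (2 oligos -> 8+8, 3 -> 6+5+5, 4 -> 4x4, 1 -> 16).
#'
#' @param spec Two-column matrix-like of (n_genes, n_distinct_oligos)
#'   pairs; default \code{cbind(c(362,45,390,2), c(2,3,4,1))}.
#' @param features_per_gene Spots per microRNA (default 16).
#' @return An \code{"ArrayDesign"}.
#' @export
make_design <- function(spec = cbind(n_genes = c(362L, 45L, 390L, 2L),
                                     n_oligos = c(2L, 3L, 4L, 1L)),
                        features_per_gene = 16L) {
  spec <- as.matrix(spec)
  stopifnot(ncol(spec) == 2L, all(spec > 0), features_per_gene >= 1L)
  if (any(spec[, 2L] > features_per_gene))
    stop("features_per_gene (", features_per_gene,
         ") must be >= the number of distinct oligos per gene")
  n_genes <- sum(spec[, 1L])
  wid <- nchar(as.character(n_genes))
  gene_ids <- sprintf(paste0("mir-%0", wid, "d"), seq_len(n_genes))
  oligos <- rep(spec[, 2L], spec[, 1L])

  probes_per_gene <- vector("list", n_genes)
  names(probes_per_gene) <- gene_ids
  rep_counts <- integer(0)
  gene_of <- character(0)
  for (i in seq_len(n_genes)) {
    k <- oligos[[i]]
    base <- features_per_gene %/% k
    extra <- features_per_gene %% k
    counts <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
    pid <- sprintf("%s_p%d", gene_ids[[i]], seq_len(k))
    probes_per_gene[[i]] <- pid
    rep_counts <- c(rep_counts, stats::setNames(counts, pid))
    gene_of <- c(gene_of, stats::setNames(rep(gene_ids[[i]], k), pid))
  }
  structure(list(gene_ids = gene_ids,
                 probes_per_gene = probes_per_gene,
                 replicates_per_probe = rep_counts,
                 gene_of = gene_of),
            class = "ArrayDesign")
}

#' Simulation settings for synthetic AFE experiments
#'
#' Collects the parameters of the generative intensity model used by
#' [simulate_experiment()].  The observed mean signal of a feature is
#' \deqn{S = c \cdot 2^{\theta_{g,G} + \phi_p + \epsilon} + Y,\qquad
#'       Y \sim N(\mu_b, \sigma_b^2)\ \mathrm{truncated\ at\ }0,}
#' where \eqn{\theta} is the true log2 microRNA expression per group,
#' \eqn{\phi_p \sim N(0, \code{probe_affinity_sd}^2)} a probe affinity fixed
#' across arrays, \eqn{\epsilon \sim N(0, \code{noise_sd}^2)} per-feature
#' noise, and \eqn{c = \code{exp_rate_scale}} converts log2 expression to
#' fluorescence units.  The background-subtracted signal is
#' \code{mean_signal - bg_mu} and may be negative.
#'
#' @param n_arrays_per_group Arrays (biological replicates) per group.
#' @param groups Group labels.
#' @param design An [make_design()] result.
#' @param theta Optional gene x group matrix of true log2 expression; drawn
#'   if \code{NULL} (baseline \eqn{N(4, 2^2)} per gene, with a fraction
#'   \code{frac_de} of genes shifted in the second and later groups by
#'   \eqn{N(0, \code{de_sd}^2)}).
#' @param frac_de Fraction of genes differentially expressed between groups.
#' @param de_sd SD (log2 units) of the between-group shifts.
#' @param probe_affinity_sd SD (log2 units) of probe affinities.
#' @param noise_sd SD (log2 units) of per-feature noise.
#' @param bg_mu,bg_sigma Mean and SD (fluorescence units) of the additive
#'   normal background.
#' @param exp_rate_scale Linear-scale multiplier for the true signal.
#' @param detected_threshold A gene is flagged detected on an array when the
#'   median of its feature mean signals exceeds this value; the default,
#'   \code{bg_mu + 3 * bg_sigma}, is a conventional three-sigma call
#'   against background.
#' @param seed Integer seed; identical configs and seeds give bit-identical
#'   output.
#' @return A list of class \code{"SimulationConfig"}.
#' @export
simulation_config <- function(n_arrays_per_group = 4L,
                              groups = c("MSC", "Fib"),
                              design = make_design(),
                              theta = NULL,
                              frac_de = 0.2,
                              de_sd = 1.5,
                              probe_affinity_sd = 0.5,
                              noise_sd = 0.25,
                              bg_mu = 50,
                              bg_sigma = 10,
                              exp_rate_scale = 1,
                              detected_threshold = bg_mu + 3 * bg_sigma,
                              seed = 1L) {
  stopifnot(n_arrays_per_group >= 1L, length(groups) >= 1L,
            probe_affinity_sd >= 0, noise_sd >= 0, bg_sigma >= 0,
            exp_rate_scale > 0, frac_de >= 0, frac_de <= 1)
  structure(as.list(environment()), class = "SimulationConfig")
}

#' Simulate a multi-array AFE experiment
#'
#' Draws true expression, probe affinities and noise under the model of
#' [simulation_config()], appends positive and negative control features,
#' and returns one [feature_table()] per array together with the ground
#' truth needed for recovery tests.
#'
#' Controls comprise 20 negative-control probes at pure background and 4
#' positive-control targets each interrogated by 4 probes repeated 5 times;
#' all carry a nonzero control type.
#'
#' @param cfg A [simulation_config()].
#' @return List with \code{tables} (list of FeatureTable), \code{truth}
#'   (list with \code{theta}, \code{phi}, \code{group_of}) and \code{design}.
#' @export
simulate_experiment <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  design <- cfg$design
  genes <- design$gene_ids
  ng <- length(genes)
  probes <- names(design$replicates_per_probe)

  theta <- cfg$theta
  if (is.null(theta)) {
    base <- stats::rnorm(ng, mean = 4, sd = 2)
    theta <- matrix(base, nrow = ng, ncol = length(cfg$groups),
                    dimnames = list(genes, cfg$groups))
    if (length(cfg$groups) > 1L && cfg$frac_de > 0) {
      de <- stats::runif(ng) < cfg$frac_de
      for (j in seq_along(cfg$groups)[-1L])
        theta[de, j] <- theta[de, j] + stats::rnorm(sum(de), 0, cfg$de_sd)
    }
  } else {
    theta <- as.matrix(theta)
    stopifnot(nrow(theta) == ng, ncol(theta) == length(cfg$groups))
    dimnames(theta) <- list(genes, cfg$groups)
  }
  phi <- stats::setNames(stats::rnorm(length(probes), 0,
                                      cfg$probe_affinity_sd), probes)

  # expand design to a feature skeleton shared by all arrays
  feat_probe <- rep(probes, design$replicates_per_probe)
  feat_gene <- design$gene_of[feat_probe]
  nfe <- length(feat_probe)

  ctl <- .control_skeleton()
  ntot <- nfe + nrow(ctl)
  rows <- ((seq_len(ntot) - 1L) %/% 100L) + 1L
  cols <- ((seq_len(ntot) - 1L) %% 100L) + 1L

  group_of <- rep(cfg$groups, each = cfg$n_arrays_per_group)
  array_ids <- paste0(group_of, "_rep",
                      rep(seq_len(cfg$n_arrays_per_group),
                          times = length(cfg$groups)))
  gidx <- match(feat_gene, genes)

  rtruncnorm0 <- function(n, mean, sd) {
    if (sd == 0) return(rep(mean, n))
    pmax(stats::rnorm(n, mean, sd), 0)
  }

  tables <- vector("list", length(array_ids))
  names(tables) <- array_ids
  for (a in seq_along(array_ids)) {
    g <- group_of[[a]]
    eps <- if (cfg$noise_sd > 0) stats::rnorm(nfe, 0, cfg$noise_sd) else 0
    x <- cfg$exp_rate_scale * 2^(theta[cbind(gidx, match(g, cfg$groups))] +
                                   phi[feat_probe] + eps)
    y <- rtruncnorm0(nfe, cfg$bg_mu, cfg$bg_sigma)
    mean_sig <- x + y

    det <- tapply(mean_sig, feat_gene, stats::median)[feat_gene] >
      cfg$detected_threshold

    ctl_x <- ifelse(ctl$positive, 2^10, 0)
    ctl_mean <- ctl_x + rtruncnorm0(nrow(ctl), cfg$bg_mu, cfg$bg_sigma)

    features <- data.frame(
      probe_id = c(feat_probe, ctl$probe_id),
      gene_id = c(feat_gene, ctl$gene_id),
      mean_signal = c(mean_sig, ctl_mean),
      bgsub_signal = c(mean_sig, ctl_mean) - cfg$bg_mu,
      control_type = c(rep(0L, nfe), ctl$control_type),
      is_gene_detected = c(as.integer(det), ifelse(ctl$positive, 1L, 0L)),
      row = rows, col = cols,
      stringsAsFactors = FALSE
    )
    tables[[a]] <- feature_table(array_ids[[a]], features,
                                 metadata = c(Protocol = "synthetic-v2.0",
                                              Seed = as.character(cfg$seed)))
  }
  list(tables = tables,
       truth = list(theta = theta, phi = phi,
                    group_of = stats::setNames(group_of, array_ids)),
       design = design)
}

# 20 negative-control probes (5 replicates each) plus 4 positive-control
# targets x 4 probes x 5 replicates.
.control_skeleton <- function() {
  neg <- data.frame(
    probe_id = rep(sprintf("NC_probe%02d", 1:20), each = 5L),
    gene_id = rep(sprintf("NegativeControl_%02d", 1:20), each = 5L),
    control_type = -1L, positive = FALSE, stringsAsFactors = FALSE)
  pos_target <- rep(sprintf("PC_target%d", 1:4), each = 4L * 5L)
  pos_probe <- rep(sprintf("PC_target%d_p%d",
                           rep(1:4, each = 4L), rep(1:4, times = 4L)),
                   each = 5L)
  pos <- data.frame(probe_id = pos_probe, gene_id = pos_target,
                    control_type = 1L, positive = TRUE,
                    stringsAsFactors = FALSE)
  rbind(neg, pos)
}

#' Write a feature table as an AFE-dialect text file
#'
#' Emits either the native three-block AFE shape (\code{TYPE} lines,
#' FEPARAMS metadata block, FEATURES block, \code{*} separators) or a plain
#' single-header TSV; both are accepted by [read_afe()] and round-trip the
#' record content exactly.  A \code{.gz} suffix on \code{path} gzips the
#' output.
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @param dialect \code{"blocks"} or \code{"plain"}.
#' @export
write_afe <- function(table, path, dialect = c("blocks", "plain")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "FeatureTable"))
  f <- table$features
  fmt_num <- function(v) formatC(v, format = "g", digits = 17L)
  cols <- .afe_default_cols
  body_cells <- cbind(f$probe_id, f$gene_id, fmt_num(f$mean_signal),
                      fmt_num(f$bgsub_signal), f$control_type,
                      f$is_gene_detected, f$row, f$col)
  body <- apply(body_cells, 1L, paste, collapse = "\t")
  hdr <- paste(unname(cols), collapse = "\t")
  lines <- if (dialect == "plain") {
    c(hdr, body)
  } else {
    meta_cols <- names(table$metadata)
    meta <- if (length(meta_cols)) {
      c(paste(c("TYPE", rep("text", length(meta_cols))), collapse = "\t"),
        paste(c("FEPARAMS", meta_cols), collapse = "\t"),
        paste(c("DATA", unname(table$metadata)), collapse = "\t"),
        "*")
    } else character()
    c(meta,
      paste(c("TYPE", rep("text", length(cols))), collapse = "\t"),
      paste(c("FEATURES", unname(cols)), collapse = "\t"),
      paste("DATA", body, sep = "\t"),
      "*")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
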