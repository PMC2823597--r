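# Default mapping from internal field names to the AFE v9.5 column vocabulary.
# Matching in read_afe() is case-insensitive.
.afe_default_cols <- c(
  probe_id         = "ProbeName",
  gene_id          = "SystematicName",
  mean_signal      = "gMeanSignal",
  bgsub_signal     = "gBGSubSignal",
  control_type     = "ControlType",
  is_gene_detected = "gIsGeneDetected",
  row              = "Row",
  col              = "Col"
)

# Gene-id prefixes treated as controls even when ControlType == 0.
.control_prefixes <- c("NegativeControl", "DarkCorner", "BrightCorner",
                       "NC_", "PC_", "SCorner", "GE_BrightCorner")

#' Construct a per-array feature table
#'
#' A \code{FeatureTable} holds the parsed content of one Agilent Feature
#' Extraction (AFE) export: one row per physical spot (feature) with probe
#' and microRNA identifiers, the raw mean signal, the background-subtracted
#' signal, the control type and the detection flag.
#'
#' @param array_id Character scalar naming the array.
#' @param features \code{data.frame} with columns \code{probe_id},
#'   \code{gene_id}, \code{mean_signal}, \code{bgsub_signal},
#'   \code{control_type}, \code{is_gene_detected}, \code{row}, \code{col}.
#' @param metadata Named character vector of header fields (scanner,
#'   protocol, ...); may be empty.
#'
#' @return An object of class \code{"FeatureTable"}.
#' @export
feature_table <- function(array_id, features, metadata = character()) {
  stopifnot(is.character(array_id), length(array_id) == 1L)
  required <- names(.afe_default_cols)
  missing <- setdiff(required, names(features))
  if (length(missing))
    stop("feature table is missing field(s): ", paste(missing, collapse = ", "))
  features <- as.data.frame(features)[required]
  features$probe_id <- as.character(features$probe_id)
  features$gene_id <- as.character(features$gene_id)
  for (f in c("mean_signal", "bgsub_signal"))
    features[[f]] <- as.numeric(features[[f]])
  for (f in c("control_type", "is_gene_detected", "row", "col"))
    features[[f]] <- as.integer(features[[f]])
  num <- features[c("mean_signal", "bgsub_signal", "control_type",
                    "is_gene_detected", "row", "col")]
  if (any(!vapply(num, function(v) all(is.finite(v)), logical(1L))))
    stop("missing or non-finite numeric cells in feature table '", array_id,
         "' (dense AFE exports expected; refusing to impute)")
  if (!all(features$is_gene_detected %in% c(0L, 1L)))
    stop("is_gene_detected must be 0 or 1")
  if (any(features$mean_signal < 0))
    stop("mean_signal must be non-negative")
  key <- paste(features$probe_id, features$row, features$col)
  if (anyDuplicated(key))
    stop("duplicate (probe, row, col) features in array '", array_id, "': ",
         paste(utils::head(key[duplicated(key)], 3L), collapse = "; "))
  # belt-and-braces: control-named genes are controls even if ControlType == 0
  ctl_name <- .is_control_name(features$gene_id)
  features$is_control <- features$control_type != 0L | ctl_name
  if (!any(!features$is_control))
    stop("no experimental (ControlType == 0) features in array '", array_id, "'")
  structure(list(array_id = array_id, features = features,
                 metadata = metadata),
            class = "FeatureTable")
}

.is_control_name <- function(gene_id) {
  hit <- rep(FALSE, length(gene_id))
  for (p in .control_prefixes) hit <- hit | startsWith(gene_id, p)
  hit
}

#' @export
print.FeatureTable <- function(x, ...) {
  n <- nrow(x$features)
  ne <- sum(!x$features$is_control)
  cat("FeatureTable '", x$array_id, "': ", n, " features (",
      ne, " experimental, ", n - ne, " control)\n", sep = "")
  invisible(x)
}

#' Read an Agilent Feature Extraction text file
#'
#' Parses either the native three-block AFE export (FEPARAMS / STATS /
#' FEATURES, each block introduced by a \code{TYPE} line and closed by a
#' \code{*} line) or a plain single-header tab-separated file.  The dialect
#' is detected from the first token of the file.  Gzip-compressed files are
#' read transparently.
#'
#' @param path Path to the \code{.txt} (or \code{.txt.gz}) file.
#' @param array_id Array name; defaults to the file name without extension.
#' @param col_map Named character vector mapping internal field names to
#'   column names in the file; defaults to the AFE v9.5 vocabulary
#'   (ProbeName, SystematicName, gMeanSignal, gBGSubSignal, ControlType,
#'   gIsGeneDetected, Row, Col).  Matching is case-insensitive.
#'
#' @return A [feature_table()] object.  Control features are retained and
#'   flagged (column \code{is_control}); they are excluded from
#'   normalization and summarization downstream.
#' @export
read_afe <- function(path, array_id = NULL,
                     col_map = .afe_default_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(array_id)) {
    array_id <- sub("\\.gz$", "", basename(path))
    array_id <- sub("\\.[^.]*$", "", array_id)
  }
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)
  first_tok <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]][1L]
  if (identical(first_tok, "TYPE")) {
    parsed <- .parse_afe_blocks(lines)
  } else {
    parsed <- list(features = utils::read.delim(text = lines,
                                                check.names = FALSE,
                                                stringsAsFactors = FALSE),
                   metadata = character())
  }
  feats <- parsed$features
  if (!nrow(feats)) stop("empty FEATURES block in ", path)
  lc <- tolower(names(feats))
  idx <- match(tolower(col_map), lc)
  if (anyNA(idx))
    stop("AFE file ", path, " is missing required column(s): ",
         paste(col_map[is.na(idx)], collapse = ", "))
  out <- feats[idx]
  names(out) <- names(col_map)
  feature_table(array_id, out, parsed$metadata)
}

# Split a three-block AFE export into FEATURES data and FEPARAMS metadata.
.parse_afe_blocks <- function(lines) {
  brk <- c(which(lines == "*"), length(lines) + 1L)
  start <- 1L
  features <- NULL
  metadata <- character()
  for (b in brk) {
    block <- lines[start:(b - 1L)]
    start <- b + 1L
    block <- block[nzchar(block)]
    if (length(block) < 2L) next
    hdr <- strsplit(block[[2L]], "\t", fixed = TRUE)[[1L]]
    body <- block[-(1:2)]
    name <- hdr[1L]
    cols <- hdr[-1L]
    if (identical(name, "FEATURES")) {
      df <- utils::read.delim(text = body, header = FALSE,
                              stringsAsFactors = FALSE)
      df <- df[-1L]                      # drop the leading DATA token
      names(df) <- cols
      features <- df
    } else if (identical(name, "FEPARAMS") && length(body)) {
      vals <- strsplit(body[[1L]], "\t", fixed = TRUE)[[1L]][-1L]
      length(vals) <- length(cols)
      metadata <- c(metadata, stats::setNames(as.character(vals), cols))
    }
    if (start > length(lines)) break
  }
  if (is.null(features)) stop("no FEATURES block found")
  list(features = features, metadata = metadata)
}

#' Infer the probe-to-gene array design from feature tables
#'
#' Derives the shared layout (gene list, probes per gene, replicate features
#' per probe) from the experimental features of a set of arrays.  All arrays
#' must carry the identical layout.
#'
#' @param tables List of [feature_table()] objects.
#' @return An \code{"ArrayDesign"}: list with \code{gene_ids}
#'   (lexicographically ordered), \code{probes_per_gene} (gene ->
#'   character vector of probe ids), \code{replicates_per_probe} (named
#'   integer), and \code{gene_of} (probe -> gene lookup).
#' @export
infer_design <- function(tables) {
  stopifnot(length(tables) >= 1L)
  layout_of <- function(tb) {
    f <- tb$features[!tb$features$is_control, c("probe_id", "gene_id")]
    f <- f[order(f$probe_id, f$gene_id), ]
    rownames(f) <- NULL
    f
  }
  ref <- layout_of(tables[[1L]])
  for (tb in tables[-1L]) {
    cur <- layout_of(tb)
    if (!identical(ref, cur)) {
      bad <- union(setdiff(unique(ref$probe_id), unique(cur$probe_id)),
                   setdiff(unique(cur$probe_id), unique(ref$probe_id)))
      stop("array layouts differ between '", tables[[1L]]$array_id,
           "' and '", tb$array_id, "'; offending probes: ",
           paste(utils::head(bad, 5L), collapse = ", "),
           if (length(bad) > 5L) ", ..." else "")
    }
  }
  g_of_p <- tapply(ref$gene_id, ref$probe_id, function(g) unique(g))
  if (any(lengths(g_of_p) != 1L))
    stop("probe(s) mapped to multiple genes: ",
         paste(names(g_of_p)[lengths(g_of_p) != 1L], collapse = ", "))
  gene_of <- vapply(g_of_p, `[[`, character(1L), 1L)
  reps <- table(ref$probe_id)
  replicates_per_probe <- stats::setNames(as.integer(reps), names(reps))
  gene_ids <- sort(unique(ref$gene_id))
  probes_per_gene <- lapply(stats::setNames(gene_ids, gene_ids), function(g)
    sort(names(gene_of)[gene_of == g]))
  structure(list(gene_ids = gene_ids,
                 probes_per_gene = probes_per_gene,
                 replicates_per_probe = replicates_per_probe,
                 gene_of = gene_of),
            class = "ArrayDesign")
}

#' @export
print.ArrayDesign <- function(x, ...) {
  tot <- sum(x$replicates_per_probe)
  cat("ArrayDesign: ", length(x$gene_ids), " genes, ",
      length(x$replicates_per_probe), " probes, ", tot, " features\n",
      sep = "")
  invisible(x)
}

#' Assemble a feature-level signal matrix across arrays
#'
#' Stacks one signal channel from several arrays into a feature x array
#' matrix.  Replicate features stay as separate rows (collapsing to probes
#' happens in [collapse_replicates()]); rows are ordered deterministically
#' by (gene, probe, replicate position) and columns follow the input table
#' order.  Values are carried over bit-exactly.
#'
#' @param tables List of [feature_table()] objects.
#' @param design An [infer_design()] result.
#' @param channel \code{"bgsub"} for the background-subtracted signal or
#'   \code{"mean"} for the raw mean signal.
#' @return Numeric matrix with attributes \code{probe_id} and
#'   \code{gene_id} (one entry per row).
#' @export
assemble_features <- function(tables, design,
                              channel = c("bgsub", "mean")) {
  channel <- match.arg(channel)
  stopifnot(length(tables) >= 2L)
  field <- if (channel == "bgsub") "bgsub_signal" else "mean_signal"
  cols <- lapply(tables, function(tb) {
    f <- tb$features[!tb$features$is_control, ]
    miss <- setdiff(names(design$replicates_per_probe), unique(f$probe_id))
    if (length(miss))
      stop("array '", tb$array_id, "' lacks probe(s) present in design: ",
           paste(utils::head(miss, 5L), collapse = ", "))
    o <- order(design$gene_of[f$probe_id], f$probe_id, f$row, f$col)
    f <- f[o, ]
    list(vals = f[[field]], probe = f$probe_id)
  })
  probe <- cols[[1L]]$probe
  m <- matrix(unlist(lapply(cols, `[[`, "vals")), nrow = length(probe))
  colnames(m) <- vapply(tables, `[[`, character(1L), "array_id")
  rownames(m) <- probe
  attr(m, "probe_id") <- probe
  attr(m, "gene_id") <- unname(design$gene_of[probe])
  m
}

#' Construct an expression matrix (gene x array)
#'
#' @param values Numeric matrix, one row per gene, one column per array.
#' @param scale \code{"linear"} or \code{"log2"}.
#' @param method Label of the processing route that produced the values
#'   (\code{TGS_raw}, \code{nor75}, \code{norQ}, \code{norRMA},
#'   \code{norRMAbg}).
#' @return An \code{"ExpressionMatrix"} (a matrix with \code{scale} and
#'   \code{method} attributes).
#' @export
expression_matrix <- function(values, scale = c("linear", "log2"),
                              method = "TGS_raw") {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  structure(values, scale = scale, method = method,
            class = c("ExpressionMatrix", "matrix", "array"))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix (", attr(x, "method"), ", ", attr(x, "scale"),
      " scale): ", nrow(x), " genes x ", ncol(x), " arrays\n", sep = "")
  invisible(x)
}

#' Write an expression or probe matrix to tab-separated text
#'
#' First column holds row ids, the header row holds array ids; numbers are
#' written at full double precision so [read_matrix()] recovers them
#' losslessly.
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_name Header label for the id column.
#' @export
write_matrix <- function(m, path, id_name = "id") {
  if (!is.matrix(m) || nrow(m) == 0L || ncol(m) == 0L)
    stop("refusing to write an empty matrix")
  hdr <- paste(c(id_name, colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i],
            formatC(m[i, ], format = "g", digits = 17L)), collapse = "\t"),
    character(1L))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a matrix written by [write_matrix()]
#' @param path Input path.
#' @return Numeric matrix with row and column names.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[-1L])
  rownames(m) <- as.character(df[[1L]])
  m
}
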