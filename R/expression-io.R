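#' Construct a time-series expression dataset
#'
#' Container for one or more independent time series measured over a common
#' gene set, as produced by the DREAM in-silico challenges: each series is a
#' timepoints x genes matrix, and all series share the same genes in the same
#' order. Series are treated as independent experiments: lagged regulator ->
#' target sample pairs never cross a series boundary.
#'
#' @param series a matrix (single series) or list of matrices, each
#'   timepoints x genes. Column names, if present, must agree across series.
#' @param gene_ids character vector of gene names; defaults to the column
#'   names of the first series.
#' @param time_stamps optional list of numeric time vectors, one per series.
#' @param normalized logical; `TRUE` when values are already on the
#'   min-max-normalized `[0, 1]` scale.
#' @return an object of class `expression_dataset` with fields `gene_ids`,
#'   `series`, `time_stamps` and `normalized`.
#' @seealso [read_timeseries()], [minmax_normalize()], [lagged_pairs()]
#' @export
expression_dataset <- function(series, gene_ids = NULL, time_stamps = NULL,
                               normalized = FALSE) {
  if (is.matrix(series)) series <- list(series)
  if (!is.list(series) || !length(series) || !all(vapply(series, is.matrix, TRUE)))
    stop("'series' must be a matrix or a non-empty list of matrices")
  if (is.null(gene_ids)) gene_ids <- colnames(series[[1L]])
  if (is.null(gene_ids))
    stop("gene names are required (column names or 'gene_ids')")
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene names: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  for (i in seq_along(series)) {
    m <- series[[i]]
    if (ncol(m) != length(gene_ids))
      stop("series ", i, " has ", ncol(m), " genes; expected ", length(gene_ids))
    if (!is.null(colnames(m)) && !identical(colnames(m), gene_ids))
      stop("series ", i, " gene order differs from 'gene_ids'")
    if (nrow(m) < 3L)
      stop("series ", i, " has ", nrow(m),
           " timepoints; at least 3 are required for lagged prediction")
    storage.mode(m) <- "double"
    colnames(m) <- gene_ids
    series[[i]] <- m
  }
  if (is.null(time_stamps))
    time_stamps <- lapply(series, function(m) seq_len(nrow(m)) - 1)
  if (length(time_stamps) != length(series))
    stop("'time_stamps' must have one vector per series")
  structure(list(gene_ids = gene_ids, series = series,
                 time_stamps = lapply(time_stamps, as.numeric),
                 normalized = isTRUE(normalized)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  tp <- vapply(x$series, nrow, 1L)
  cat("expression_dataset: ", length(x$gene_ids), " genes, ",
      length(x$series), " series (",
      paste(tp, collapse = ", "), " timepoints), ",
      if (x$normalized) "normalized" else "raw", " values\n", sep = "")
  invisible(x)
}

#' Number of genes / series / timepoints in a dataset
#'
#' @param ds an `expression_dataset`.
#' @return `n_genes()` and `n_series()` return single integers;
#'   `n_timepoints()` an integer vector, one entry per series.
#' @export
n_genes <- function(ds) length(ds$gene_ids)

#' @rdname n_genes
#' @export
n_series <- function(ds) length(ds$series)

#' @rdname n_genes
#' @export
n_timepoints <- function(ds) vapply(ds$series, nrow, 1L)

#' Read DREAM-style time-series expression data
#'
#' Parses the tab-separated DREAM challenge layout: a header line
#' `Time<TAB>gene1<TAB>...<TAB>geneN` followed by numeric rows. A file may
#' stack several independent time series; blocks are delimited by a blank
#' line, by a repeated header line, or (under `dialect = "time-reset"`) by a
#' non-increasing jump in the `Time` column.
#'
#' @param path file path.
#' @param dialect `"header-per-block"` (default; blank lines and repeated
#'   headers delimit series) or `"time-reset"` (additionally split wherever
#'   the time stamp fails to increase).
#' @return an [expression_dataset()] (with `normalized = FALSE`).
#' @export
read_timeseries <- function(path, dialect = c("header-per-block", "time-reset")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)
  header <- NULL
  blocks <- list()
  cur <- list()   # list of numeric rows
  cur_lines <- integer()
  flush <- function() {
    if (length(cur)) blocks[[length(blocks) + 1L]] <<- list(rows = cur, lines = cur_lines)
    cur <<- list(); cur_lines <<- integer()
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) { flush(); next }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (toupper(trimws(f[1L])) == "TIME") {
      if (is.null(header)) {
        header <- trimws(f)
      } else if (!identical(trimws(f), header)) {
        stop("line ", i, ": header differs from the first header")
      }
      flush()
      next
    }
    if (is.null(header)) stop("line ", i, ": data before any 'Time' header")
    if (length(f) != length(header))
      stop("line ", i, ": ragged row (", length(f), " fields, expected ",
           length(header), ")")
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) stop("line ", i, ": non-numeric value")
    cur[[length(cur) + 1L]] <- v
    cur_lines <- c(cur_lines, i)
  }
  flush()
  if (!length(blocks)) stop("no data rows in ", path)
  genes <- header[-1L]
  if (anyDuplicated(genes))
    stop("duplicate gene names in header: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  # assemble, optionally splitting blocks on time resets
  series <- list(); stamps <- list()
  for (b in blocks) {
    m <- do.call(rbind, b$rows)
    t_col <- m[, 1L]
    if (dialect == "time-reset" && nrow(m) > 1L) {
      brk <- which(diff(t_col) <= 0)
      starts <- c(1L, brk + 1L); ends <- c(brk, nrow(m))
    } else {
      starts <- 1L; ends <- nrow(m)
    }
    for (k in seq_along(starts)) {
      idx <- starts[k]:ends[k]
      series[[length(series) + 1L]] <- m[idx, -1L, drop = FALSE]
      stamps[[length(stamps) + 1L]] <- t_col[idx]
    }
  }
  short <- which(vapply(series, nrow, 1L) < 3L)
  if (length(short))
    stop("series ", paste(short, collapse = ", "),
         " have fewer than 3 timepoints")
  series <- lapply(series, function(m) { colnames(m) <- genes; m })
  expression_dataset(series, gene_ids = genes, time_stamps = stamps)
}

#' Write an expression dataset in DREAM layout
#'
#' One header line, numeric rows, one blank line between consecutive series.
#' Values are written with 15 significant digits so a write/read round trip
#' reproduces them to at least 12 significant digits.
#'
#' @param ds an [expression_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ds, path) {
  con <- file(path, "w"); on.exit(close(con))
  header <- paste(c("Time", ds$gene_ids), collapse = "\t")
  for (s in seq_along(ds$series)) {
    if (s > 1L) writeLines("", con)
    writeLines(header, con)
    m <- cbind(ds$time_stamps[[s]], ds$series[[s]])
    writeLines(apply(m, 1L, function(r)
      paste(sprintf("%.15g", r), collapse = "\t")), con)
  }
  invisible(path)
}

#' Min-max normalize expression per gene
#'
#' Rescales every gene to `[0, 1]` with `(v - min) / (max - min)`, pooling
#' all series of the dataset for the per-gene minimum and maximum. A gene
#' that is constant across the pooled dataset is mapped to all zeros and
#' reported with a warning rather than an error, so pipelines survive
#' degenerate simulated inputs.
#'
#' @param ds an [expression_dataset()]. Normalizing is idempotent: a dataset
#'   already flagged as normalized is returned unchanged.
#' @return the normalized dataset; genes mapped to zero because they were
#'   constant are recorded in `attr(, "constant_genes")`.
#' @export
minmax_normalize <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ds$normalized) return(ds)
  pooled <- do.call(rbind, ds$series)
  lo <- apply(pooled, 2L, min)
  hi <- apply(pooled, 2L, max)
  const <- hi <= lo
  if (any(const))
    warning("constant gene(s) mapped to 0 under normalization: ",
            paste(ds$gene_ids[const], collapse = ", "))
  rng <- ifelse(const, 1, hi - lo)
  ds$series <- lapply(ds$series, function(m) {
    out <- sweep(sweep(m, 2L, ifelse(const, 0, lo), "-"), 2L, rng, "/")
    out[, const] <- 0
    out
  })
  ds$normalized <- TRUE
  attr(ds, "constant_genes") <- ds$gene_ids[const]
  ds
}

#' Lagged regulator/target sample pairs
#'
#' Collects, within each series, the pairs (regulator value at t, target
#' value at t+1) and concatenates them over all series. Pairs never straddle
#' a boundary between two independent series, so the sample size is
#' `sum(T_s - 1)` over series.
#'
#' @param ds an [expression_dataset()].
#' @param regulator,target gene names.
#' @return an object of class `lagged_pairs`: list with `x` (regulator at t),
#'   `y` (target at t+1), `n`, and the gene names.
#' @export
lagged_pairs <- function(ds, regulator, target) {
  stopifnot(inherits(ds, "expression_dataset"))
  ir <- match(regulator, ds$gene_ids)
  it <- match(target, ds$gene_ids)
  if (is.na(ir)) stop("unknown gene: ", regulator)
  if (is.na(it)) stop("unknown gene: ", target)
  xs <- lapply(ds$series, function(m) m[-nrow(m), ir])
  ys <- lapply(ds$series, function(m) m[-1L, it])
  x <- unlist(xs, use.names = FALSE)
  y <- unlist(ys, use.names = FALSE)
  structure(list(x = x, y = y, n = length(x),
                 regulator = regulator, target = target),
            class = "lagged_pairs")
}

#' @export
print.lagged_pairs <- function(x, ...) {
  cat("lagged_pairs: ", x$regulator, " (t) -> ", x$target, " (t+1), n = ",
      x$n, "\n", sep = "")
  invisible(x)
}

#' Read a gold-standard edge list
#'
#' Accepts the DREAM convention `regulator<TAB>target<TAB>label` with labels
#' in {0, 1}, or a two-column list (implicit label 1). Edges are the pairs
#' labelled 1. Self-loops are dropped with a warning (self-regulation is
#' outside the model's scope).
#'
#' @param path file path.
#' @param gene_universe character vector; every gene named in the file must
#'   belong to it.
#' @return object of class `gold_standard`: list with `edges` (two-column
#'   character matrix, zero rows allowed) and `gene_universe`.
#' @export
read_goldstandard <- function(path, gene_universe) {
  gene_universe <- as.character(gene_universe)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  edges <- matrix(character(), 0L, 2L)
  for (i in seq_along(lines)) {
    f <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]])
    if (!length(f) %in% c(2L, 3L))
      stop("line ", i, ": expected 2 or 3 tab-separated fields")
    lab <- if (length(f) == 3L) f[3L] else "1"
    if (!lab %in% c("0", "1"))
      stop("line ", i, ": label must be 0 or 1, got '", lab, "'")
    miss <- setdiff(f[1:2], gene_universe)
    if (length(miss))
      stop("line ", i, ": gene(s) outside the declared universe: ",
           paste(miss, collapse = ", "))
    if (lab == "1") {
      if (f[1L] == f[2L]) {
        warning("line ", i, ": self-loop ", f[1L], " -> ", f[2L], " dropped")
      } else {
        edges <- rbind(edges, f[1:2])
      }
    }
  }
  dimnames(edges) <- list(NULL, c("regulator", "target"))
  edges <- unique(edges)
  structure(list(edges = edges, gene_universe = gene_universe),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("gold_standard: ", nrow(x$edges), " edges over ",
      length(x$gene_universe), " genes\n", sep = "")
  invisible(x)
}

#' Write a gold-standard edge list (three-column DREAM convention)
#'
#' @param gs a `gold_standard` object (or a two-column character matrix).
#' @param path output file path.
#' @param complete if `TRUE`, also write the absent non-self pairs with
#'   label 0, as the DREAM files do.
#' @return `path`, invisibly.
#' @export
write_goldstandard <- function(gs, path, complete = FALSE) {
  edges <- if (inherits(gs, "gold_standard")) gs$edges else gs
  rows <- character()
  if (nrow(edges))
    rows <- paste(edges[, 1L], edges[, 2L], "1", sep = "\t")
  if (complete) {
    stopifnot(inherits(gs, "gold_standard"))
    u <- gs$gene_universe
    all_pairs <- expand.grid(regulator = u, target = u,
                             stringsAsFactors = FALSE)
    all_pairs <- all_pairs[all_pairs$regulator != all_pairs$target, ]
    key <- paste(all_pairs$regulator, all_pairs$target)
    pos <- paste(edges[, 1L], edges[, 2L])
    neg <- all_pairs[!key %in% pos, ]
    rows <- c(rows, paste(neg$regulator, neg$target, "0", sep = "\t"))
  }
  writeLines(rows, path)
  invisible(path)
}
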