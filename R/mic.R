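#' Grid-size bound for the MIC search
#'
#' The maximal grid area searched at sample size `n` is `B(n) =
#' floor(n^alpha)`, with a floor of 4 so the minimal 2x2 grid is always
#' admissible. `alpha = 0.6` is the published MINE default.
#'
#' @param n sample size.
#' @param alpha grid-bound exponent.
#' @return integer grid-area bound.
#' @export
mic_grid_bound <- function(n, alpha = 0.6) {
  max(4L, as.integer(floor(n^alpha)))
}

.as_xy <- function(sample) {
  if (inherits(sample, "lagged_pairs")) return(list(x = sample$x, y = sample$y))
  if (is.list(sample) && all(c("x", "y") %in% names(sample)))
    return(list(x = as.numeric(sample$x), y = as.numeric(sample$y)))
  stop("'sample' must be a lagged_pairs object or a list with x and y")
}

#' Maximal information coefficient of a lagged sample
#'
#' Normalized maximal mutual information over axis-aligned grids whose area
#' (columns x rows) does not exceed `B(n) = floor(n^alpha)`: each grid's
#' mutual information is divided by `log2(min(columns, rows))` and the
#' maximum over grid shapes and placements is taken. Placement search uses
#' the ApproxMaxMI heuristic: one axis is equipartitioned (ties never
#' split), the other is partitioned optimally by dynamic programming over
#' value clumps, and both orientations are tried. When an axis has at most
#' `min(B(n), exhaustive_max)` distinct values, all of its partitions are
#' enumerated instead of the single equipartition, which makes the search
#' exact on heavily tied axes.
#'
#' @param sample a [lagged_pairs()] object, or a list with numeric `x`, `y`.
#' @param alpha grid-bound exponent, see [mic_grid_bound()].
#' @param C clump factor: the optimized axis is limited to `C` times the
#'   maximal column count of superclumps (MINE default 15).
#' @param grid_strict if `TRUE`, require grid area strictly below `B(n)`
#'   instead of the conventional `<=`.
#' @param exhaustive_max axis-cardinality cutoff for the exhaustive-partition
#'   refinement.
#' @return a score in `[0, 1]`. A constant variable yields 0 with a warning.
#' @export
mic <- function(sample, alpha = 0.6, C = 15L, grid_strict = FALSE,
                exhaustive_max = 6L) {
  s <- .as_xy(sample)
  n <- length(s$x)
  if (length(s$y) != n) stop("x and y must have equal length")
  if (n < 4L) stop("MIC needs at least 4 sample pairs, got ", n)
  if (anyNA(s$x) || anyNA(s$y)) stop("missing values in sample")
  if (min(s$x) == max(s$x) || min(s$y) == max(s$y)) {
    warning("constant variable: MIC set to 0")
    return(0)
  }
  B <- mic_grid_bound(n, alpha)
  mic_approx_cpp(s$x, s$y, B, as.integer(C), as.integer(exhaustive_max),
                 isTRUE(grid_strict))
}

#' Exhaustive-grid MIC oracle for small samples
#'
#' Enumerates every pair of axis partitions built from cut points between
#' consecutive distinct sorted values (ties never split), with at least two
#' parts per axis and grid area at most `B(n)`, and returns the exact
#' maximum of normalized mutual information. Feasible for `n <= 25` only;
#' intended as an independent reference for [mic()].
#'
#' @inheritParams mic
#' @param B optional explicit grid-area bound overriding `floor(n^alpha)`.
#' @return exact maximal normalized mutual information in `[0, 1]`.
#' @export
mic_bruteforce_oracle <- function(sample, alpha = 0.6, B = NULL,
                                  grid_strict = FALSE) {
  s <- .as_xy(sample)
  n <- length(s$x)
  if (n > 25L) stop("brute-force enumeration is limited to n <= 25, got ", n)
  if (n < 4L) stop("MIC needs at least 4 sample pairs, got ", n)
  if (min(s$x) == max(s$x) || min(s$y) == max(s$y)) {
    warning("constant variable: MIC set to 0")
    return(0)
  }
  if (is.null(B)) B <- mic_grid_bound(n, alpha)
  Beff <- if (isTRUE(grid_strict)) B - 1L else B
  rx <- match(s$x, sort(unique(s$x)))  # dense ranks
  ry <- match(s$y, sort(unique(s$y)))
  dx <- max(rx); dy <- max(ry)

  cuts_of <- function(d, parts) {
    if (parts == 1L) return(list(integer()))
    if (d - 1L < parts - 1L) return(list())
    m <- utils::combn(d - 1L, parts - 1L)
    lapply(seq_len(ncol(m)), function(j) m[, j])
  }
  assign_part <- function(rank, cuts) findInterval(rank - 1L, cuts) + 1L

  best <- 0
  for (l in 2:max(2L, Beff %/% 2L)) {
    for (r in 2:max(2L, Beff %/% l)) {
      if (l * r > Beff) next
      col_parts <- cuts_of(dx, l)
      row_parts <- cuts_of(dy, r)
      if (!length(col_parts) || !length(row_parts)) next
      denom <- log2(min(l, r))
      for (cc in col_parts) {
        ci <- assign_part(rx, cc)
        for (rr in row_parts) {
          yi <- assign_part(ry, rr)
          joint <- tabulate(ci + l * (yi - 1L), nbins = l * r)
          p <- joint[joint > 0] / n
          hj <- -sum(p * log2(p))
          pc <- tabulate(ci, nbins = l) / n
          pr <- tabulate(yi, nbins = r) / n
          hx <- -sum(pc[pc > 0] * log2(pc[pc > 0]))
          hy <- -sum(pr[pr > 0] * log2(pr[pr > 0]))
          val <- (hx + hy - hj) / denom
          if (val > best) best <- val
        }
      }
    }
  }
  min(1, max(0, best))
}

#' Lagged MIC matrix over all ordered gene pairs
#'
#' For every ordered pair (regulator, target) with regulator != target,
#' computes [mic()] on the lagged sample (regulator at t, target at t+1).
#' The lag makes the matrix asymmetric by construction; the diagonal is
#' undefined (`NA`) and never consulted downstream, since self-regulation
#' is outside the model's scope.
#'
#' @param ds a normalized [expression_dataset()].
#' @inheritParams mic
#' @return object of class `mic_matrix`: list with `gene_ids`, `scores`
#'   (regulator x target matrix, `NA` diagonal), `alpha`, `C`.
#' @export
mic_matrix <- function(ds, alpha = 0.6, C = 15L, grid_strict = FALSE) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!ds$normalized)
    stop("normalize the dataset first (minmax_normalize)")
  g <- ds$gene_ids
  ng <- length(g)
  # lagged slices, computed once per gene
  heads <- lapply(seq_len(ng), function(i)
    unlist(lapply(ds$series, function(m) m[-nrow(m), i]), use.names = FALSE))
  tails <- lapply(seq_len(ng), function(i)
    unlist(lapply(ds$series, function(m) m[-1L, i]), use.names = FALSE))
  scores <- matrix(NA_real_, ng, ng, dimnames = list(g, g))
  for (i in seq_len(ng)) {
    for (j in seq_len(ng)) {
      if (i == j) next
      sc <- tryCatch(
        mic(list(x = heads[[i]], y = tails[[j]]), alpha = alpha, C = C,
            grid_strict = grid_strict),
        error = function(e) stop("MIC failed for pair ", g[i], " -> ", g[j],
                                 ": ", conditionMessage(e)))
      scores[i, j] <- sc
    }
  }
  structure(list(gene_ids = g, scores = scores, alpha = alpha, C = C),
            class = "mic_matrix")
}

#' @export
print.mic_matrix <- function(x, ...) {
  cat("mic_matrix: ", length(x$gene_ids), " genes, alpha = ", x$alpha,
      ", C = ", x$C, "\n", sep = "")
  invisible(x)
}

#' Candidate regulators for one target gene
#'
#' Screens the MIC scores into a target: under `mode = "mean"` the threshold
#' is the arithmetic mean of the n-1 incoming scores (the low-burden default
#' of the method); under `mode = "fixed"` it is a user-supplied value.
#' Candidates are the genes scoring at or above the threshold (inclusive
#' comparison, which keeps mean mode non-empty), sorted by descending score
#' with ties broken by gene order.
#'
#' @param m a [mic_matrix()].
#' @param target gene name.
#' @param mode `"mean"` or `"fixed"`.
#' @param fixed_value threshold for `mode = "fixed"`.
#' @return object of class `candidate_set`: list with `target`, `genes`,
#'   `scores`, `threshold_used`, `threshold_mode`.
#' @export
candidate_set <- function(m, target, mode = c("mean", "fixed"),
                          fixed_value = NULL) {
  stopifnot(inherits(m, "mic_matrix"))
  mode <- match.arg(mode)
  it <- match(target, m$gene_ids)
  if (is.na(it)) stop("unknown target gene: ", target)
  incoming <- m$scores[, it]
  incoming <- incoming[-it]
  thr <- switch(mode,
    mean = mean(incoming),
    fixed = {
      if (is.null(fixed_value))
        stop("mode = 'fixed' requires 'fixed_value'")
      as.numeric(fixed_value)
    })
  keep <- which(incoming >= thr)
  ord <- keep[order(-incoming[keep], keep)]
  structure(list(target = target,
                 genes = names(incoming)[ord],
                 scores = unname(incoming[ord]),
                 threshold_used = thr,
                 threshold_mode = mode),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("candidate_set for ", x$target, ": ", length(x$genes),
      " genes at threshold ", format(x$threshold_used, digits = 4),
      " (", x$threshold_mode, ")\n", sep = "")
  invisible(x)
}

#' Write / read a MIC matrix as TSV
#'
#' Regulator rows, target columns, empty diagonal; for reproducibility
#' audits of the screening stage.
#'
#' @param m a [mic_matrix()].
#' @param path file path.
#' @return `path` (write) or a `mic_matrix` (read).
#' @export
write_mic_matrix <- function(m, path) {
  stopifnot(inherits(m, "mic_matrix"))
  g <- m$gene_ids
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("regulator", g), collapse = "\t"), con)
  for (i in seq_along(g)) {
    vals <- ifelse(is.na(m$scores[i, ]), "",
                   sprintf("%.15g", m$scores[i, ]))
    writeLines(paste(c(g[i], vals), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_mic_matrix
#' @param alpha,C parameters recorded on the reconstructed object.
#' @export
read_mic_matrix <- function(path, alpha = 0.6, C = 15L) {
  lines <- readLines(path, warn = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  g <- header[-1L]
  scores <- matrix(NA_real_, length(g), length(g), dimnames = list(g, g))
  for (i in seq_along(g)) {
    f <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1L]]
    v <- suppressWarnings(as.numeric(f[-1L]))
    scores[i, ] <- c(v, rep(NA_real_, length(g) - length(v)))
  }
  structure(list(gene_ids = g, scores = scores, alpha = alpha, C = C),
            class = "mic_matrix")
}
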