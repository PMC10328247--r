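#' Assemble per-target selections into a signed directed network
#'
#' Takes the union of per-target selected regulators. Self-loops never
#' occur by construction; duplicate (regulator, target) entries are resolved
#' to the occurrence with the lower residual score, with a warning when the
#' duplicates carry conflicting signs.
#'
#' @param selections a `regulator_selection` data frame, or a list of them
#'   (one per target).
#' @param gene_universe ordered character vector of all gene names.
#' @return an object of class `grn`: list with `edges` (data frame
#'   `regulator`, `target`, `sign`, `rs`, `nrs`, `mic`) and `gene_universe`.
#' @export
assemble_network <- function(selections, gene_universe) {
  gene_universe <- as.character(gene_universe)
  if (is.data.frame(selections)) selections <- list(selections)
  edges <- do.call(rbind, lapply(selections, as.data.frame))
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(regulator = character(), target = character(),
                        sign = character(), rs = numeric(), nrs = numeric(),
                        mic = numeric(), stringsAsFactors = FALSE)
  } else {
    bad <- setdiff(unique(c(edges$regulator, edges$target)), gene_universe)
    if (length(bad))
      stop("selection references genes outside the universe: ",
           paste(bad, collapse = ", "))
    if (any(edges$regulator == edges$target))
      stop("self-loop in selections")
    key <- paste(edges$regulator, edges$target, sep = "\r")
    if (anyDuplicated(key)) {
      edges <- edges[order(edges$rs), , drop = FALSE]
      key <- paste(edges$regulator, edges$target, sep = "\r")
      dup <- duplicated(key)
      conflict <- vapply(split(edges$sign, key),
                         function(s) length(unique(s)) > 1L, TRUE)
      if (any(conflict))
        warning("conflicting signs for ",
                paste(gsub("\r", " -> ", names(conflict)[conflict]),
                      collapse = ", "),
                "; keeping the lower-rs sign")
      edges <- edges[!dup, , drop = FALSE]
    }
    rownames(edges) <- NULL
  }
  structure(list(edges = edges, gene_universe = gene_universe),
            class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat("grn: ", nrow(x$edges), " signed edges over ",
      length(x$gene_universe), " genes (",
      sum(x$edges$sign == "+"), " activating, ",
      sum(x$edges$sign == "-"), " repressing)\n", sep = "")
  invisible(x)
}

#' Write / read an inferred network as TSV
#'
#' Columns: `regulator`, `target`, `sign`, `rs`, `nrs`, `mic`.
#'
#' @param net a [assemble_network()] result.
#' @param path file path.
#' @return `path` (write) or a `grn` (read).
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "grn"))
  e <- net$edges
  lines <- c("regulator\ttarget\tsign\trs\tnrs\tmic",
             if (nrow(e)) paste(e$regulator, e$target, e$sign,
                                sprintf("%.15g", e$rs),
                                sprintf("%.15g", e$nrs),
                                sprintf("%.15g", e$mic), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_network
#' @param gene_universe gene universe attached to the reconstructed network.
#' @export
read_network <- function(path, gene_universe) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[[1L]], "regulator"))
    stop("not a network file (missing header): ", path)
  body <- lines[-1L]
  if (length(body)) {
    f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    num <- function(v) { v[v == "NA"] <- NA_character_; as.numeric(v) }
    edges <- data.frame(regulator = f[, 1L], target = f[, 2L],
                        sign = f[, 3L], rs = num(f[, 4L]),
                        nrs = num(f[, 5L]), mic = num(f[, 6L]),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(regulator = character(), target = character(),
                        sign = character(), rs = numeric(), nrs = numeric(),
                        mic = numeric(), stringsAsFactors = FALSE)
  }
  assemble_network(edges, gene_universe)
}

#' Confusion counts against a gold standard
#'
#' Compares the predicted edge set with the reference over all `n(n-1)`
#' ordered non-self gene pairs (self-regulation is excluded from the
#' universe). The comparison is directed but unsigned, as DREAM gold
#' standards carry no signs.
#'
#' @param net a `grn`.
#' @param gold a [read_goldstandard()] result (or a `planted_network`).
#' @return named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion <- function(net, gold) {
  stopifnot(inherits(net, "grn"))
  gedges <- if (inherits(gold, "planted_network")) {
    as.matrix(gold$edges[, c("regulator", "target")])
  } else gold$edges
  guniv <- if (inherits(gold, "planted_network")) gold$gene_ids
           else gold$gene_universe
  if (!setequal(net$gene_universe, guniv))
    stop("gene universe mismatch between network and gold standard")
  n <- length(net$gene_universe)
  pred <- unique(paste(net$edges$regulator, net$edges$target, sep = "\r"))
  truth <- unique(paste(gedges[, 1L], gedges[, 2L], sep = "\r"))
  tp <- sum(pred %in% truth)
  fp <- length(pred) - tp
  fn <- length(truth) - tp
  tn <- n * (n - 1L) - tp - fp - fn
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Topology metrics from confusion counts
#'
#' Precision, true/false positive rates, specificity, F-score, SS_mean,
#' Matthews correlation coefficient and structural accuracy
#' `(TP+TN)/(TP+FP+TN+FN)`. SS_mean combines sensitivity and specificity;
#' the harmonic mean is the default, with geometric and arithmetic variants
#' selectable since the literature does not fix the formula. Ratios with a
#' zero denominator are reported as 0 and listed in the `zero_denominator`
#' field.
#'
#' @param counts named vector with `tp`, `fp`, `tn`, `fn` (as from
#'   [confusion()]).
#' @param ss_mean_type `"harmonic"`, `"geometric"` or `"arithmetic"`.
#' @return an object of class `evaluation_report`.
#' @export
network_metrics <- function(counts,
                            ss_mean_type = c("harmonic", "geometric",
                                             "arithmetic")) {
  ss_mean_type <- match.arg(ss_mean_type)
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  if (any(c(tp, fp, tn, fn) < 0)) stop("negative confusion counts")
  total <- tp + fp + tn + fn
  if (total <= 0) stop("all confusion counts are zero")
  flags <- character()
  ratio <- function(num, den, name) {
    if (den <= 0) { flags <<- c(flags, name); return(0) }
    num / den
  }
  precision <- ratio(tp, tp + fp, "precision")
  tpr <- ratio(tp, tp + fn, "tpr")
  fpr <- ratio(fp, fp + tn, "fpr")
  specificity <- 1 - fpr
  f_score <- ratio(2 * precision * tpr, precision + tpr, "f_score")
  ss_mean <- switch(ss_mean_type,
    harmonic = ratio(2 * tpr * specificity, tpr + specificity, "ss_mean"),
    geometric = sqrt(tpr * specificity),
    arithmetic = (tpr + specificity) / 2)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den <= 0) { flags <- c(flags, "mcc"); 0 } else
    (tp * tn - fp * fn) / mcc_den
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 precision = precision, tpr = tpr, fpr = fpr,
                 specificity = specificity, f_score = f_score,
                 ss_mean = ss_mean, ss_mean_type = ss_mean_type, mcc = mcc,
                 structural_accuracy = (tp + tn) / total,
                 zero_denominator = flags),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report (tp ", x$tp, ", fp ", x$fp, ", tn ", x$tn,
      ", fn ", x$fn, ")\n", sep = "")
  for (f in c("precision", "tpr", "fpr", "specificity", "f_score",
              "ss_mean", "mcc", "structural_accuracy"))
    cat(sprintf("  %-20s %.4f\n", f, x[[f]]))
  if (length(x$zero_denominator))
    cat("  zero denominators:", paste(x$zero_denominator, collapse = ", "),
        "\n")
  invisible(x)
}

#' Evaluate an inferred network against a gold standard
#'
#' Convenience wrapper: [confusion()] followed by [network_metrics()].
#'
#' @inheritParams confusion
#' @inheritParams network_metrics
#' @return an `evaluation_report`.
#' @export
evaluate_network <- function(net, gold,
                             ss_mean_type = c("harmonic", "geometric",
                                              "arithmetic")) {
  network_metrics(confusion(net, gold), ss_mean_type = match.arg(ss_mean_type))
}

#' Sign accuracy on correctly recovered edges
#'
#' Among predicted edges that are true (directed, unsigned match against a
#' signed reference), the fraction whose predicted sign matches the planted
#' sign. `NA` when no true edge was recovered.
#'
#' @param net a `grn`.
#' @param truth a `planted_network` (signed reference).
#' @return fraction in `[0, 1]`, or `NA`.
#' @export
signed_accuracy <- function(net, truth) {
  stopifnot(inherits(net, "grn"), inherits(truth, "planted_network"))
  tkey <- paste(truth$edges$regulator, truth$edges$target, sep = "\r")
  pkey <- paste(net$edges$regulator, net$edges$target, sep = "\r")
  hit <- pkey %in% tkey
  if (!any(hit)) return(NA_real_)
  mean(net$edges$sign[hit] ==
         truth$edges$sign[match(pkey[hit], tkey)])
}

#' Combinatorial reduction of the pair search
#'
#' The classical fuzzy model scores, for each of `n` targets, every ordered
#' activator-repressor pair drawn from the remaining `n - 1` genes:
#' `n (n-1) (n-2)` triplets. With MIC screening the count is `sum over
#' targets of m_g (m_g - 1)` for candidate-set sizes `m_g`. Returns the
#' percentage reduction `100 (1 - screened / classical)`.
#'
#' @param m_sizes integer vector of per-target candidate-set sizes.
#' @param n total number of genes (`>= 3`).
#' @return reduction percentage in `[0, 100]`.
#' @export
combinatorial_reduction <- function(m_sizes, n) {
  if (n < 3L) stop("n must be at least 3")
  classical <- as.numeric(n) * (n - 1) * (n - 2)
  screened <- sum(as.numeric(m_sizes) * (m_sizes - 1))
  100 * (1 - screened / classical)
}
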