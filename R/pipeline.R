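#' Run the full two-stage inference pipeline
#'
#' Wires the stages end to end: per-gene min-max normalization (skipped when
#' the dataset is already normalized), lagged MIC matrix, per-target
#' candidate screening, fuzzy scoring of every ordered activator-repressor
#' candidate pair, residual-score selection, and assembly into a signed
#' directed network. The pipeline contains no unseeded randomness: identical
#' inputs and settings give identical networks.
#'
#' @param ds an [expression_dataset()] (raw or normalized).
#' @param mic_mode `"mean"` (per-target average MIC threshold, the
#'   low-burden default) or `"fixed"`.
#' @param mic_threshold threshold value for `mic_mode = "fixed"`.
#' @param selection `"nrs_threshold"` (keep pairs with normalized residual
#'   score at or below `nrs_threshold`) or `"top_k"` (keep the `k`
#'   lowest-residual pairs per target, the mode used for larger networks).
#' @param nrs_threshold normalized residual-score threshold (default 0.05).
#' @param top_k pair count for `selection = "top_k"`.
#' @param rrs include the regulatory relationship strength in the fuzzy
#'   effects; `FALSE` reproduces the classical-model ablation.
#' @param cfg a [fuzzy_config()].
#' @param alpha,C MIC search parameters, see [mic()].
#' @return a `grn`; `attr(, "log")` holds a `run_log` with per-target
#'   candidate-set sizes and thresholds, pair counts, the
#'   combinatorial-reduction percentage and the fuzzy-configuration hash.
#' @export
infer_grn <- function(ds, mic_mode = c("mean", "fixed"),
                      mic_threshold = NULL,
                      selection = c("nrs_threshold", "top_k"),
                      nrs_threshold = 0.05, top_k = NULL, rrs = TRUE,
                      cfg = fuzzy_config(), alpha = 0.6, C = 15L) {
  stopifnot(inherits(ds, "expression_dataset"))
  mic_mode <- match.arg(mic_mode)
  selection <- match.arg(selection)
  if (selection == "nrs_threshold" &&
      (nrs_threshold < 0 || nrs_threshold > 1))
    stop("nrs_threshold must lie in [0, 1]")
  if (!ds$normalized) ds <- minmax_normalize(ds)
  m <- mic_matrix(ds, alpha = alpha, C = C)
  genes <- ds$gene_ids
  selections <- vector("list", length(genes))
  cand_sizes <- integer(length(genes))
  thresholds <- numeric(length(genes))
  pair_counts <- integer(length(genes))
  no_regulator <- character()
  for (g in seq_along(genes)) {
    cand <- candidate_set(m, genes[g], mode = mic_mode,
                          fixed_value = mic_threshold)
    cand_sizes[g] <- length(cand$genes)
    thresholds[g] <- cand$threshold_used
    scores <- suppressMessages(
      score_all_pairs(ds, m, genes[g], cand, cfg = cfg, rrs = rrs))
    pair_counts[g] <- nrow(scores)
    if (!nrow(scores)) {
      no_regulator <- c(no_regulator, genes[g])
      next
    }
    selections[[g]] <- select_regulators(
      scores, mode = selection, nrs_threshold = nrs_threshold, k = top_k,
      mic = m)
  }
  net <- assemble_network(selections[!vapply(selections, is.null, TRUE)],
                          gene_universe = genes)
  log <- structure(list(
    targets = genes, candidate_sizes = cand_sizes,
    mic_thresholds = thresholds, mic_mode = mic_mode,
    pair_counts = pair_counts, selection = selection,
    nrs_threshold = if (selection == "nrs_threshold") nrs_threshold else NA,
    top_k = if (selection == "top_k") top_k else NA,
    rrs = rrs, no_regulator = no_regulator,
    combinatorial_reduction = combinatorial_reduction(cand_sizes,
                                                      length(genes)),
    fuzzy_config_hash = fuzzy_config_hash(cfg)),
    class = "run_log")
  attr(net, "log") <- log
  attr(net, "mic_matrix") <- m
  net
}

#' @export
print.run_log <- function(x, ...) {
  cat("run_log: MIC mode ", x$mic_mode, ", selection ", x$selection,
      if (x$selection == "nrs_threshold")
        paste0(" (nrs <= ", x$nrs_threshold, ")")
      else paste0(" (k = ", x$top_k, ")"),
      ", RRS ", if (x$rrs) "on" else "off", "\n", sep = "")
  cat("  candidate sizes: ", paste(x$candidate_sizes, collapse = " "), "\n",
      "  pair counts:     ", paste(x$pair_counts, collapse = " "), "\n",
      "  combinatorial reduction: ",
      sprintf("%.2f%%", x$combinatorial_reduction), "\n",
      "  fuzzy config md5: ", x$fuzzy_config_hash, "\n", sep = "")
  if (length(x$no_regulator))
    cat("  targets with no inferable regulators:",
        paste(x$no_regulator, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a fuzzy configuration as a flat key-value file
#'
#' One `key = value` line per setting: triangle vertices per level
#' (comma-separated), rule-matrix cells as `rule.<activator>.<repressor>`,
#' resolution and firing epsilon. The shipped default file
#' (`system.file("extdata", "fuzzy-default.conf", package = "fuzzygrn")`)
#' reproduces [fuzzy_config()]'s defaults.
#'
#' @param cfg a [fuzzy_config()].
#' @param path file path.
#' @return `path` (write) / a `fuzzy_config` (read).
#' @export
write_fuzzy_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "fuzzy_config"))
  fmt <- function(v) paste(sprintf("%.15g", v), collapse = ",")
  lines <- c(
    vapply(rownames(cfg$input_levels), function(l)
      paste0("input.", l, " = ", fmt(cfg$input_levels[l, ])), ""),
    vapply(rownames(cfg$output_levels), function(l)
      paste0("output.", l, " = ", fmt(cfg$output_levels[l, ])), ""),
    unlist(lapply(rownames(cfg$rule_matrix), function(a)
      vapply(colnames(cfg$rule_matrix), function(r)
        paste0("rule.", a, ".", r, " = ", cfg$rule_matrix[a, r]), ""))),
    paste0("defuzz_resolution = ", sprintf("%.15g", cfg$defuzz_resolution)),
    paste0("firing_epsilon = ", sprintf("%.15g", cfg$firing_epsilon)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fuzzy_config
#' @export
read_fuzzy_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, function(p) trimws(p[[1L]]), "")
  vals <- vapply(kv, function(p) trimws(paste(p[-1L], collapse = "=")), "")
  getv <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) stop("missing key in fuzzy config: ", key)
    vals[[i]]
  }
  nums <- function(key) as.numeric(strsplit(getv(key), ",")[[1L]])
  inp <- t(vapply(c("Low", "Medium", "High"),
                  function(l) nums(paste0("input.", l)), numeric(3L)))
  outp <- t(vapply(c("VL", "L", "Med", "H", "VH"),
                   function(l) nums(paste0("output.", l)), numeric(3L)))
  colnames(inp) <- colnames(outp) <- c("a", "b", "c")
  rules <- matrix("", 3L, 3L,
                  dimnames = list(activator = c("Low", "Medium", "High"),
                                  repressor = c("Low", "Medium", "High")))
  for (a in rownames(rules)) for (r in colnames(rules))
    rules[a, r] <- getv(paste0("rule.", a, ".", r))
  fuzzy_config(input_levels = inp, output_levels = outp,
               rule_matrix = rules,
               defuzz_resolution = as.numeric(getv("defuzz_resolution")),
               firing_epsilon = as.numeric(getv("firing_epsilon")))
}

#' MD5 hash of a fuzzy configuration
#'
#' Canonical serialization hashed with MD5, so run logs identify exactly
#' which membership functions and rule matrix produced a network.
#'
#' @param cfg a [fuzzy_config()].
#' @return hex digest string.
#' @export
fuzzy_config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".conf")
  on.exit(unlink(tmp))
  write_fuzzy_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}
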