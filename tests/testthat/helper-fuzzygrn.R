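# Fixture builders shared across the test files. Everything is generated in
# code; no binary fixtures.

# DREAM-style TSV with `blocks` stacked series of `timepoints` rows over
# `genes` named columns, values from a deterministic RNG.
write_dream_file <- function(path, genes = 10L, timepoints = 21L,
                             blocks = 5L, header_per_block = TRUE,
                             blank_between = FALSE, seed = 1L) {
  set.seed(seed)
  gene_ids <- sprintf("G%d", seq_len(genes))
  header <- paste(c("Time", gene_ids), collapse = "\t")
  lines <- character()
  for (b in seq_len(blocks)) {
    if (b > 1L && blank_between) lines <- c(lines, "")
    if (b == 1L || header_per_block) lines <- c(lines, header)
    m <- matrix(round(runif(timepoints * genes), 6), timepoints, genes)
    rows <- paste(seq_len(timepoints) - 1L,
                  apply(m, 1L, paste, collapse = "\t"), sep = "\t")
    lines <- c(lines, rows)
  }
  writeLines(lines, path)
  path
}

# Small in-memory dataset with named gene columns.
make_dataset <- function(..., normalized = FALSE) {
  series <- list(...)
  expression_dataset(series, normalized = normalized)
}

# mic_matrix object with hand-set scores, for screening/scoring tests.
manual_mic_matrix <- function(scores) {
  g <- rownames(scores)
  diag(scores) <- NA_real_
  structure(list(gene_ids = g, scores = scores, alpha = 0.6, C = 15L),
            class = "mic_matrix")
}

# Planted network object from an explicit signed edge list.
manual_planted <- function(gene_ids, regulator, target, sign) {
  structure(list(gene_ids = gene_ids,
                 edges = data.frame(regulator = regulator, target = target,
                                    sign = sign, stringsAsFactors = FALSE)),
            class = "planted_network")
}

# grn object from an explicit edge list over a universe.
manual_grn <- function(gene_universe, regulator = character(),
                       target = character(), sign = NULL) {
  n <- length(regulator)
  edges <- data.frame(regulator = regulator, target = target,
                      sign = if (is.null(sign)) rep("+", n) else sign,
                      rs = rep(0, n), nrs = rep(0, n), mic = rep(NA_real_, n),
                      stringsAsFactors = FALSE)
  assemble_network(edges, gene_universe)
}

# gold_standard object from an explicit pair list.
manual_gold <- function(gene_universe, regulator = character(),
                        target = character()) {
  edges <- cbind(regulator = regulator, target = target)
  if (!length(regulator)) edges <- matrix(character(), 0L, 2L,
    dimnames = list(NULL, c("regulator", "target")))
  structure(list(edges = edges, gene_universe = gene_universe),
            class = "gold_standard")
}
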