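# Planted signed networks and simulated DREAM-style time series, so the
# whole pipeline can be validated end to end without external downloads.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a planted signed regulatory network
#'
#' Every target gene is assigned `density` regulators drawn uniformly
#' without replacement from the other genes; drawn slots alternate roles,
#' activator first, so `density = 2` plants exactly one activator and one
#' repressor per target (the default study condition) and `density = 0`
#' plants an empty network.
#'
#' @param n_genes number of genes (`>= 3`).
#' @param density regulators per target, `0 <= density <= n_genes - 1`.
#' @param seed integer seed for reproducibility; the caller's RNG state is
#'   left untouched.
#' @param gene_ids optional gene names (default `G1..Gn`).
#' @return object of class `planted_network`: list with `gene_ids` and
#'   `edges` (data frame `regulator`, `target`, `sign`).
#' @export
generate_network <- function(n_genes, density = 2L, seed = NULL,
                             gene_ids = NULL) {
  if (n_genes < 3L) stop("n_genes must be at least 3")
  if (density < 0L || density > n_genes - 1L)
    stop("density must be between 0 and n_genes - 1")
  if (is.null(gene_ids)) gene_ids <- sprintf("G%d", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes)
  edges <- .with_seed(seed, {
    rows <- list()
    for (t in seq_len(n_genes)) {
      if (density == 0L) next
      pool <- gene_ids[-t]
      regs <- sample(pool, density)
      sign <- rep(c("+", "-"), length.out = density)
      rows[[t]] <- data.frame(regulator = regs, target = gene_ids[t],
                              sign = sign, stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(regulator = character(), target = character(),
                 sign = character(), stringsAsFactors = FALSE)
  })
  rownames(edges) <- NULL
  structure(list(gene_ids = gene_ids, edges = edges),
            class = "planted_network")
}

#' @export
print.planted_network <- function(x, ...) {
  cat("planted_network: ", length(x$gene_ids), " genes, ", nrow(x$edges),
      " signed edges\n", sep = "")
  invisible(x)
}

#' Convert a planted network to an (unsigned) gold standard
#'
#' @param net a `planted_network`.
#' @return a `gold_standard` usable with [confusion()].
#' @export
as_goldstandard <- function(net) {
  stopifnot(inherits(net, "planted_network"))
  edges <- as.matrix(net$edges[, c("regulator", "target"), drop = FALSE])
  dimnames(edges) <- list(NULL, c("regulator", "target"))
  structure(list(edges = edges, gene_universe = net$gene_ids),
            class = "gold_standard")
}

#' Simulate DREAM-style time series from a planted network
#'
#' Initial values are Uniform(0, 1) per gene per series. From the second
#' timepoint on, each regulated gene takes the defuzzified fuzzy-rulebase
#' prediction from its activator and repressor values at the previous
#' timepoint (a missing role enters as 0), plus Gaussian noise, clipped to
#' `[0, 1]`; if a role has several planted regulators their mean expression
#' is used. Unregulated genes follow a mean-reverting noisy walk. Values are
#' therefore already on the `[0, 1]` scale and the returned dataset is
#' flagged `normalized = TRUE` (the normalized-concentration convention of
#' DREAM data); edge recovery on these data is well posed by construction
#' since the inference engine assumes the same generative rulebase.
#'
#' The alternative `dynamics = "linear"` mode replaces the fuzzy map by
#' `clip(w_act * a - w_rep * r + bias)` and exists to probe robustness when
#' the fuzzy model is misspecified for the data.
#'
#' @param net a [generate_network()] result.
#' @param timepoints timepoints per series (`>= 3`; DREAM series use 21).
#' @param series number of independent series (DREAM uses 5).
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer seed; caller's RNG state is left untouched.
#' @param dynamics `"fuzzy"` (default) or `"linear"`.
#' @param cfg the [fuzzy_config()] acting as ground-truth dynamics.
#' @param init optional list (one `timepoints==1` row start per series) or
#'   matrix `series x n_genes` of initial values, overriding the uniform
#'   draws.
#' @param linear_weights named vector `c(act, rep, bias)` for the linear
#'   mode.
#' @param walk list with `theta` (mean-reversion rate), `mu` (long-run
#'   level) and `sd` (innovation sd) for unregulated genes.
#' @return an [expression_dataset()] with `normalized = TRUE`.
#' @export
simulate_expression <- function(net, timepoints = 21L, series = 5L,
                                noise_sd = 0.02, seed = NULL,
                                dynamics = c("fuzzy", "linear"),
                                cfg = fuzzy_config(), init = NULL,
                                linear_weights = c(act = 0.9, rep = 0.9,
                                                   bias = 0.5),
                                walk = list(theta = 0.2, mu = 0.5,
                                            sd = 0.1)) {
  stopifnot(inherits(net, "planted_network"))
  dynamics <- match.arg(dynamics)
  if (timepoints < 3L) stop("at least 3 timepoints are required")
  if (series < 1L) stop("at least 1 series is required")
  genes <- net$gene_ids
  ng <- length(genes)
  acts <- lapply(genes, function(g)
    net$edges$regulator[net$edges$target == g & net$edges$sign == "+"])
  reps <- lapply(genes, function(g)
    net$edges$regulator[net$edges$target == g & net$edges$sign == "-"])
  regulated <- which(lengths(acts) + lengths(reps) > 0L)
  free <- setdiff(seq_len(ng), regulated)
  ai <- lapply(acts, match, table = genes)
  ri <- lapply(reps, match, table = genes)
  clip01 <- function(v) pmin(1, pmax(0, v))

  out <- .with_seed(seed, {
    lapply(seq_len(series), function(s) {
      m <- matrix(NA_real_, timepoints, ng, dimnames = list(NULL, genes))
      m[1L, ] <- if (is.null(init)) stats::runif(ng) else {
        v <- if (is.matrix(init)) init[s, ] else init[[s]]
        stopifnot(length(v) == ng)
        as.numeric(v)
      }
      for (t in 2:timepoints) {
        prev <- m[t - 1L, ]
        if (length(regulated)) {
          a <- vapply(regulated, function(g)
            if (length(ai[[g]])) mean(prev[ai[[g]]]) else 0, numeric(1L))
          r <- vapply(regulated, function(g)
            if (length(ri[[g]])) mean(prev[ri[[g]]]) else 0, numeric(1L))
          base <- if (dynamics == "fuzzy") {
            .fuzzy_predict(a, r, cfg)$pred
          } else {
            clip01(linear_weights[["act"]] * a -
                   linear_weights[["rep"]] * r + linear_weights[["bias"]])
          }
          noise <- if (noise_sd > 0)
            stats::rnorm(length(regulated), 0, noise_sd) else 0
          m[t, regulated] <- clip01(base + noise)
        }
        if (length(free)) {
          drift <- prev[free] + walk$theta * (walk$mu - prev[free])
          m[t, free] <- clip01(drift + stats::rnorm(length(free), 0,
                                                    walk$sd))
        }
      }
      m
    })
  })
  expression_dataset(out, gene_ids = genes,
                     time_stamps = rep(list(seq_len(timepoints) - 1),
                                       series),
                     normalized = TRUE)
}
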