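# Mamdani-style activator-repressor fuzzy model: fuzzify regulatory effects
# into three input levels, fire a 3x3 rulebase onto five output levels,
# aggregate by bounded sum, defuzzify by centroid.

.tri_mf <- function(x, v) {
  a <- v[1L]; b <- v[2L]; c <- v[3L]
  up <- if (b > a) (x - a) / (b - a) else as.numeric(x >= b)
  dn <- if (c > b) (c - x) / (c - b) else as.numeric(x <= b)
  pmax(0, pmin(up, dn, 1))
}

.default_input_levels <- function() {
  m <- rbind(Low = c(0, 0, 0.5), Medium = c(0, 0.5, 1), High = c(0.5, 1, 1))
  colnames(m) <- c("a", "b", "c")
  m
}

.default_output_levels <- function() {
  m <- rbind(VL = c(0, 0, 0.25), L = c(0, 0.25, 0.5),
             Med = c(0.25, 0.5, 0.75), H = c(0.5, 0.75, 1),
             VH = c(0.75, 1, 1))
  colnames(m) <- c("a", "b", "c")
  m
}

.default_rule_matrix <- function() {
  matrix(c("Med", "L",   "VL",
           "H",   "Med", "L",
           "VH",  "H",   "Med"),
         nrow = 3L, byrow = TRUE,
         dimnames = list(activator = c("Low", "Medium", "High"),
                         repressor = c("Low", "Medium", "High")))
}

#' Fuzzy model configuration
#'
#' Defines the whole fuzzy inference system: three triangular input levels
#' (Low, Medium, High) on the normalized regulatory-effect axis `[0, 1]`,
#' five triangular output levels (VL, L, Med, H, VH) on the target
#' expression axis, the 3x3 activator-by-repressor rule matrix, the
#' defuzzification universe step and the firing-strength cutoff.
#'
#' The default input vertices `Low (0, 0, 0.5)`, `Medium (0, 0.5, 1)`,
#' `High (0.5, 1, 1)` form a partition of unity (memberships sum to one
#' everywhere), the output levels are five uniform triangles on `[0, 1]`,
#' and the default rule matrix is the unique monotone, antisymmetric
#' completion of the anchor rule "activator High AND repressor Low ->
#' target Very High": output level is non-decreasing in the activator level
#' and non-increasing in the repressor level.
#'
#' @param input_levels 3x3 numeric matrix of triangle vertices (rows Low,
#'   Medium, High; columns a, b, c).
#' @param output_levels 5x3 numeric matrix (rows VL, L, Med, H, VH).
#' @param rule_matrix 3x3 character matrix (activator rows Low/Medium/High,
#'   repressor columns likewise) with entries among the output level names.
#' @param defuzz_resolution universe step for centroid defuzzification.
#' @param firing_epsilon minimal firing strength counted as "fired".
#' @return an object of class `fuzzy_config`.
#' @export
fuzzy_config <- function(input_levels = .default_input_levels(),
                         output_levels = .default_output_levels(),
                         rule_matrix = .default_rule_matrix(),
                         defuzz_resolution = 0.001,
                         firing_epsilon = 1e-9) {
  input_levels <- as.matrix(input_levels)
  output_levels <- as.matrix(output_levels)
  stopifnot(nrow(input_levels) == 3L, ncol(input_levels) == 3L,
            nrow(output_levels) == 5L, ncol(output_levels) == 3L,
            is.matrix(rule_matrix), all(dim(rule_matrix) == 3L),
            defuzz_resolution > 0, defuzz_resolution <= 0.1,
            firing_epsilon >= 0)
  if (is.null(rownames(input_levels)))
    rownames(input_levels) <- c("Low", "Medium", "High")
  if (is.null(rownames(output_levels)))
    rownames(output_levels) <- c("VL", "L", "Med", "H", "VH")
  out_names <- rownames(output_levels)
  if (!all(rule_matrix %in% out_names))
    stop("rule_matrix entries must be output level names: ",
         paste(out_names, collapse = ", "))
  lev <- matrix(match(rule_matrix, out_names), 3L, 3L)
  if (any(apply(lev, 2L, diff) < 0))
    stop("rule_matrix must be non-decreasing in the activator level")
  if (any(apply(lev, 1L, diff) > 0))
    stop("rule_matrix must be non-increasing in the repressor level")

  h <- defuzz_resolution
  universe <- seq(h / 2, 1 - h / 2, by = h)  # midpoint rule
  out_mf <- t(apply(output_levels, 1L, .tri_mf, x = universe))
  # per-rule output membership rows, rule order column-major in
  # (activator level, repressor level)
  rule_idx <- as.vector(lev)
  structure(list(input_levels = input_levels,
                 output_levels = output_levels,
                 rule_matrix = rule_matrix,
                 defuzz_resolution = h,
                 firing_epsilon = firing_epsilon,
                 .universe = universe,
                 .rule_out_mf = out_mf[rule_idx, , drop = FALSE]),
            class = "fuzzy_config")
}

#' @export
print.fuzzy_config <- function(x, ...) {
  cat("fuzzy_config: 3 input levels, ", nrow(x$output_levels),
      " output levels, step ", x$defuzz_resolution, "\n", sep = "")
  print(x$rule_matrix)
  invisible(x)
}

.memberships <- function(x, levels) {
  vapply(seq_len(nrow(levels)),
         function(i) .tri_mf(x, levels[i, ]),
         numeric(length(x)))
}

#' Fuzzify a normalized regulatory effect
#'
#' Evaluates the three input membership functions at `x`. With the default
#' configuration the three memberships always sum to one (partition of
#' unity), e.g. an effect of 0.4 fuzzifies to Low 0.2, Medium 0.8, High 0.
#'
#' @param x normalized regulatory effect(s) in `[0, 1]`.
#' @param cfg a [fuzzy_config()].
#' @return for scalar `x` a named numeric triple (Low, Medium, High); for a
#'   vector, a matrix with one row per value.
#' @export
input_membership <- function(x, cfg = fuzzy_config()) {
  if (any(x < 0 | x > 1)) stop("regulatory effect outside [0, 1]")
  m <- .memberships(x, cfg$input_levels)
  m <- matrix(m, nrow = length(x),
              dimnames = list(NULL, rownames(cfg$input_levels)))
  if (length(x) == 1L) m[1L, ] else m
}

#' Regulatory effect of one candidate regulator
#'
#' Multiplies the regulator's normalized expression trajectory by the
#' regulatory relationship strength (its MIC score with respect to the
#' target), then min-max normalizes the product over the regulator's pooled
#' timepoints. Because min-max normalization is scale invariant, the result
#' of this single-regulator form does not depend on the (positive) MIC
#' value; MIC magnitudes matter when the activator's and repressor's raw
#' effects of a pair are normalized over a common pool, which is what
#' [score_pair()] does internally.
#'
#' @param expr numeric vector of normalized expression values (all series
#'   pooled).
#' @param mic_score MIC of the regulator with respect to the target, in
#'   `[0, 1]`.
#' @param normalize min-max normalize the raw product (default `TRUE`).
#' @return per-timepoint normalized regulatory effect in `[0, 1]`.
#' @export
regulatory_effect <- function(expr, mic_score, normalize = TRUE) {
  stopifnot(mic_score >= 0, mic_score <= 1)
  raw <- mic_score * expr
  if (!normalize) return(raw)
  lo <- min(raw); hi <- max(raw)
  if (hi <= lo) {
    warning("constant regulatory effect mapped to 0")
    return(rep(0, length(raw)))
  }
  (raw - lo) / (hi - lo)
}

# Batched rule firing + prediction for vectors of activator/repressor
# effects. Returns the defuzzified predictions, the P x 9 firing matrix
# (rules in column-major (activator level, repressor level) order) and a
# no-fire indicator.
.fuzzy_predict <- function(act_eff, rep_eff, cfg) {
  P <- length(act_eff)
  A <- matrix(.memberships(act_eff, cfg$input_levels), nrow = P)
  R <- matrix(.memberships(rep_eff, cfg$input_levels), nrow = P)
  fir <- matrix(0, P, 9L)
  k <- 0L
  for (j in 1:3) for (i in 1:3) {
    k <- k + 1L
    fir[, k] <- pmin(A[, i], R[, j])
  }
  O <- cfg$.rule_out_mf
  npts <- ncol(O)
  agg <- matrix(0, P, npts)
  for (k in 1:9) {
    agg <- agg + pmin(matrix(fir[, k], P, npts),
                      matrix(O[k, ], P, npts, byrow = TRUE))
  }
  agg[agg > 1] <- 1                      # bounded sum
  den <- rowSums(agg)
  no_fire <- den <= 0
  pred <- as.vector(agg %*% cfg$.universe)
  pred[!no_fire] <- pred[!no_fire] / den[!no_fire]
  pred[no_fire] <- 0.5
  list(pred = pred, firing = fir, no_fire = no_fire, agg = agg)
}

#' Fire the rulebase for one activator/repressor effect pair
#'
#' Computes the nine rule firing strengths (Mamdani min of the two input
#' memberships), clips each rule's output membership at its firing strength
#' and aggregates by bounded sum: `aggregate(y) = min(1, sum of clipped
#' memberships)`.
#'
#' @param act_effect,rep_effect normalized regulatory effects in `[0, 1]`.
#' @param cfg a [fuzzy_config()].
#' @return list with `aggregate` (membership values over the discretized
#'   output universe), `firing` (3x3 matrix, activator level rows by
#'   repressor level columns) and `universe`.
#' @export
infer_target_level <- function(act_effect, rep_effect, cfg = fuzzy_config()) {
  stopifnot(length(act_effect) == 1L, length(rep_effect) == 1L,
            act_effect >= 0, act_effect <= 1,
            rep_effect >= 0, rep_effect <= 1)
  out <- .fuzzy_predict(act_effect, rep_effect, cfg)
  firing <- matrix(out$firing[1L, ], 3L, 3L,
                   dimnames = dimnames(cfg$rule_matrix))
  list(aggregate = out$agg[1L, ], firing = firing, universe = cfg$.universe)
}

#' Centroid defuzzification
#'
#' Centroid of the aggregated output membership over the discretized
#' universe (midpoint-rule sums). An identically zero aggregate cannot arise
#' under the default configuration (the input partition of unity guarantees
#' some rule always fires); should it occur, 0.5 is returned and flagged via
#' the `"no_fire"` attribute.
#'
#' @param aggregate membership values over the universe, as returned by
#'   [infer_target_level()] (the list itself is also accepted).
#' @param cfg a [fuzzy_config()].
#' @return crisp value in `[0, 1]`.
#' @export
defuzzify <- function(aggregate, cfg = fuzzy_config()) {
  if (is.list(aggregate)) aggregate <- aggregate$aggregate
  if (length(aggregate) != length(cfg$.universe))
    stop("aggregate length does not match the configured universe")
  den <- sum(aggregate)
  if (den <= 0) {
    out <- 0.5
    attr(out, "no_fire") <- TRUE
    return(out)
  }
  sum(cfg$.universe * aggregate) / den
}

# Joint pair-pool effects: raw effect = MIC x expression per regulator,
# min-max normalized over the two regulators' pooled raw values so that
# relative regulatory strengths matter. rrs = FALSE is the classical-model
# effect: the (already dataset-normalized) expression used directly.
.pair_effects <- function(act_expr, rep_expr, mic_a, mic_r, rrs = TRUE) {
  if (!rrs) return(list(act = act_expr, rep = rep_expr))
  raw_a <- mic_a * act_expr
  raw_r <- mic_r * rep_expr
  lo <- min(raw_a, raw_r); hi <- max(raw_a, raw_r)
  if (hi <= lo) {
    warning("constant regulatory effects mapped to 0")
    return(list(act = rep(0, length(raw_a)), rep = rep(0, length(raw_r))))
  }
  list(act = (raw_a - lo) / (hi - lo), rep = (raw_r - lo) / (hi - lo))
}

#' Score one (activator, repressor, target) triplet
#'
#' Predicts the target trajectory from the pair's regulatory effects: for
#' every timepoint t >= 2 of every series, the effects at t-1 are fuzzified,
#' the rulebase fired, and the aggregate defuzzified into a predicted
#' expression value. The triplet is scored by `rs = mse * variance`, where
#' `mse` is the mean squared prediction error over all predicted points and
#' `variance` is the population variance of the nine per-rule firing counts
#' (a rule counts as fired at a timepoint when its strength exceeds
#' `firing_epsilon`). Low variance means the rules are evenly exercised, so
#' an even, accurate triplet scores best.
#'
#' With `rrs = TRUE` the effects are MIC-weighted expressions min-max
#' normalized over the pair's common pool; with `rrs = FALSE` (ablation,
#' classical model) the normalized expressions are used directly.
#'
#' @param ds a normalized [expression_dataset()].
#' @param m a [mic_matrix()] for `ds`.
#' @param target,activator,repressor distinct gene names.
#' @param cfg a [fuzzy_config()].
#' @param rrs include the regulatory relationship strength (default `TRUE`).
#' @return object of class `pair_score`: list with `target`, `activator`,
#'   `repressor`, `predicted` (list per series; first timepoint `NA`),
#'   `mse`, `firing_counts` (3x3), `variance`, `rs`, `nrs` (`NA` until
#'   normalized by [score_all_pairs()]), `no_fire_events`.
#' @export
score_pair <- function(ds, m, target, activator, repressor,
                       cfg = fuzzy_config(), rrs = TRUE) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(m, "mic_matrix"))
  if (!ds$normalized) stop("normalize the dataset first (minmax_normalize)")
  genes <- c(target = target, activator = activator, repressor = repressor)
  if (anyDuplicated(genes)) stop("target, activator and repressor must be distinct")
  idx <- match(genes, ds$gene_ids)
  if (anyNA(idx)) stop("unknown gene(s): ",
                       paste(genes[is.na(idx)], collapse = ", "))
  mic_a <- m$scores[activator, target]
  mic_r <- m$scores[repressor, target]

  act_expr <- unlist(lapply(ds$series, function(s) s[, activator]),
                     use.names = FALSE)
  rep_expr <- unlist(lapply(ds$series, function(s) s[, repressor]),
                     use.names = FALSE)
  eff <- .pair_effects(act_expr, rep_expr, mic_a, mic_r, rrs = rrs)

  tp <- vapply(ds$series, nrow, 1L)
  ends <- cumsum(tp)
  starts <- ends - tp + 1L
  # indices of t-1 (inputs) and t (predicted) within the pooled trajectory
  in_idx <- unlist(lapply(seq_along(tp),
                          function(s) starts[s]:(ends[s] - 1L)))
  out_idx <- in_idx + 1L

  fp <- .fuzzy_predict(eff$act[in_idx], eff$rep[in_idx], cfg)
  actual <- unlist(lapply(ds$series, function(s) s[-1L, target]),
                   use.names = FALSE)
  mse <- mean((actual - fp$pred)^2)
  counts <- colSums(fp$firing > cfg$firing_epsilon)
  variance <- mean((counts - mean(counts))^2)  # population variance over 9
  predicted <- vector("list", length(tp))
  off <- 0L
  for (s in seq_along(tp)) {
    predicted[[s]] <- c(NA_real_, fp$pred[off + seq_len(tp[s] - 1L)])
    off <- off + tp[s] - 1L
  }
  structure(list(target = target, activator = activator,
                 repressor = repressor, predicted = predicted, mse = mse,
                 firing_counts = matrix(counts, 3L, 3L,
                                        dimnames = dimnames(cfg$rule_matrix)),
                 variance = variance, rs = mse * variance, nrs = NA_real_,
                 no_fire_events = sum(fp$no_fire)),
            class = "pair_score")
}

#' @export
print.pair_score <- function(x, ...) {
  cat("pair_score: ", x$activator, " (+) / ", x$repressor, " (-) -> ",
      x$target, "; mse = ", format(x$mse, digits = 4), ", variance = ",
      format(x$variance, digits = 4), ", rs = ", format(x$rs, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Score every ordered activator-repressor pair for a target
#'
#' Evaluates [score_pair()] on all ordered pairs (a, r), a != r, from the
#' candidate set, then min-max normalizes the residual scores within the
#' target (`nrs`): the best pair gets 0, the worst 1; if all residual scores
#' are equal, all `nrs` are 0. A candidate set with fewer than two genes
#' yields an empty result with a message (the target has no inferable
#' regulators) rather than an error.
#'
#' @param ds a normalized [expression_dataset()].
#' @param m a [mic_matrix()].
#' @param target target gene name.
#' @param cand a [candidate_set()] for `target` (the target itself is never
#'   paired).
#' @param cfg a [fuzzy_config()].
#' @param rrs see [score_pair()].
#' @return a data frame of class `pair_scores` with columns `target`,
#'   `activator`, `repressor`, `mse`, `variance`, `rs`, `nrs`; the full
#'   `pair_score` objects are kept in `attr(, "details")`.
#' @export
score_all_pairs <- function(ds, m, target, cand, cfg = fuzzy_config(),
                            rrs = TRUE) {
  stopifnot(inherits(cand, "candidate_set"))
  genes <- setdiff(cand$genes, target)
  empty <- data.frame(target = character(), activator = character(),
                      repressor = character(), mse = numeric(),
                      variance = numeric(), rs = numeric(), nrs = numeric(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("pair_scores", "data.frame")
  if (length(genes) < 2L) {
    message("target ", target, ": fewer than 2 candidates, no pairs scored")
    attr(empty, "details") <- list()
    attr(empty, "gene_ids") <- m$gene_ids
    return(empty)
  }
  pairs <- expand.grid(activator = genes, repressor = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$activator != pairs$repressor, , drop = FALSE]
  details <- vector("list", nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    details[[p]] <- score_pair(ds, m, target,
                               activator = pairs$activator[p],
                               repressor = pairs$repressor[p],
                               cfg = cfg, rrs = rrs)
  }
  rs <- vapply(details, `[[`, numeric(1L), "rs")
  lo <- min(rs); hi <- max(rs)
  nrs <- if (hi > lo) (rs - lo) / (hi - lo) else rep(0, length(rs))
  for (p in seq_along(details)) details[[p]]$nrs <- nrs[p]
  out <- data.frame(target = target, activator = pairs$activator,
                    repressor = pairs$repressor,
                    mse = vapply(details, `[[`, numeric(1L), "mse"),
                    variance = vapply(details, `[[`, numeric(1L), "variance"),
                    rs = rs, nrs = nrs, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("pair_scores", "data.frame")
  attr(out, "details") <- details
  attr(out, "gene_ids") <- m$gene_ids
  out
}

#' Select signed regulators from scored pairs
#'
#' Keeps the best pairs either by normalized residual score (`nrs <=
#' nrs_threshold`) or as the `k` pairs with smallest raw residual score
#' (ties broken by activator then repressor gene order). Kept pairs emit
#' signed edges: activator -> target with sign `+`, repressor -> target with
#' sign `-`. One gene acts in one role per target: a gene appearing in both
#' roles among the kept pairs is resolved to the role it plays in its
#' lowest-rs kept pair.
#'
#' @param scores a `pair_scores` data frame from [score_all_pairs()].
#' @param mode `"nrs_threshold"` or `"top_k"`.
#' @param nrs_threshold threshold in `[0, 1]` for `mode = "nrs_threshold"`.
#' @param k pair count for `mode = "top_k"`.
#' @param mic optional [mic_matrix()] used to annotate edges with the
#'   regulator's MIC score.
#' @return a data frame of class `regulator_selection` with columns
#'   `regulator`, `target`, `sign`, `rs`, `nrs`, `mic`.
#' @export
select_regulators <- function(scores, mode = c("nrs_threshold", "top_k"),
                              nrs_threshold = NULL, k = NULL, mic = NULL) {
  mode <- match.arg(mode)
  empty <- data.frame(regulator = character(), target = character(),
                      sign = character(), rs = numeric(), nrs = numeric(),
                      mic = numeric(), stringsAsFactors = FALSE)
  class(empty) <- c("regulator_selection", "data.frame")
  if (!nrow(scores)) return(empty)
  gene_ids <- attr(scores, "gene_ids")
  if (mode == "nrs_threshold") {
    if (is.null(nrs_threshold)) stop("mode 'nrs_threshold' requires a value")
    kept <- scores[scores$nrs <= nrs_threshold, , drop = FALSE]
  } else {
    if (is.null(k)) stop("mode 'top_k' requires 'k'")
    ai <- match(scores$activator, gene_ids)
    ri <- match(scores$repressor, gene_ids)
    ord <- order(scores$rs, ai, ri)
    kept <- scores[ord[seq_len(min(k, nrow(scores)))], , drop = FALSE]
  }
  if (!nrow(kept)) return(empty)
  # long form: one row per (gene, role) occurrence in a kept pair
  long <- rbind(
    data.frame(regulator = kept$activator, target = kept$target, sign = "+",
               rs = kept$rs, nrs = kept$nrs, stringsAsFactors = FALSE),
    data.frame(regulator = kept$repressor, target = kept$target, sign = "-",
               rs = kept$rs, nrs = kept$nrs, stringsAsFactors = FALSE))
  # one role per gene: lowest-rs occurrence wins; '+' first on exact ties
  long <- long[order(long$rs, long$sign != "+"), , drop = FALSE]
  long <- long[!duplicated(long$regulator), , drop = FALSE]
  long$mic <- if (!is.null(mic)) {
    mapply(function(r, t) mic$scores[r, t], long$regulator, long$target)
  } else NA_real_
  rownames(long) <- NULL
  class(long) <- c("regulator_selection", "data.frame")
  long
}
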