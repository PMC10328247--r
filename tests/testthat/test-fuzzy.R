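cfg <- fuzzy_config()

test_that("input fuzzification matches the three-triangle partition", {
  expect_equal(input_membership(0.4, cfg),
               c(Low = 0.2, Medium = 0.8, High = 0))
  expect_equal(input_membership(0, cfg), c(Low = 1, Medium = 0, High = 0))
  expect_equal(input_membership(0.5, cfg), c(Low = 0, Medium = 1, High = 0))
  expect_equal(input_membership(1, cfg), c(Low = 0, Medium = 0, High = 1))
  expect_equal(input_membership(0.75, cfg),
               c(Low = 0, Medium = 0.5, High = 0.5))
  expect_error(input_membership(1.2, cfg), "outside")
  expect_error(input_membership(-0.1, cfg), "outside")
})

test_that("input memberships form a partition of unity", {
  grid <- seq(0, 1, length.out = 1001L)
  sums <- rowSums(input_membership(grid, cfg))
  expect_lt(max(abs(sums - 1)), 1e-12)
})

test_that("configuration validation rejects non-monotone rulebases", {
  bad <- matrix(
    c("VH", "L", "VL", "H", "Med", "L", "Med", "H", "Med"), 3L, 3L,
    byrow = TRUE,
    dimnames = list(activator = c("Low", "Medium", "High"),
                    repressor = c("Low", "Medium", "High")))
  expect_error(fuzzy_config(rule_matrix = bad), "non-decreasing")
  expect_error(fuzzy_config(rule_matrix = matrix("Nope", 3, 3)),
               "output level names")
  expect_equal(cfg$rule_matrix["High", "Low"], "VH")
})

test_that("regulatory effect is the min-max-normalized MIC-weighted level", {
  expect_equal(regulatory_effect(c(0, 0.5, 1), 0.8), c(0, 0.5, 1))
  expect_equal(regulatory_effect(c(0, 0.5, 1), 0.8, normalize = FALSE),
               c(0, 0.4, 0.8))
  expect_warning(z <- regulatory_effect(c(0.3, 0.7, 1), 0), "constant")
  expect_equal(z, c(0, 0, 0))
  # scale cancellation: any positive MIC gives the same normalized series
  expr <- c(0.1, 0.4, 0.9, 0.2)
  expect_equal(regulatory_effect(expr, 0.3), regulatory_effect(expr, 0.9))
})

test_that("rule firing follows Mamdani min with bounded-sum aggregation", {
  r <- infer_target_level(1, 0, cfg)       # the anchor rule
  expect_equal(sum(r$firing > 0), 1L)
  expect_equal(r$firing["High", "Low"], 1)
  expect_equal(defuzzify(r, cfg), (0.75 + 1 + 1) / 3,
               tolerance = cfg$defuzz_resolution)

  r2 <- infer_target_level(0.5, 0.5, cfg)  # single vertex rule
  expect_equal(sum(r2$firing > 0), 1L)
  expect_equal(r2$firing["Medium", "Medium"], 1)
  expect_equal(defuzzify(r2, cfg), 0.5, tolerance = 1e-9)

  # 0.4/0.4 fires four rules at min over {0.2, 0.8} x {0.2, 0.8}
  r3 <- infer_target_level(0.4, 0.4, cfg)
  expect_equal(unname(r3$firing[c("Low", "Medium"), c("Low", "Medium")]),
               matrix(c(0.2, 0.2, 0.2, 0.8), 2L, 2L))
  expect_equal(sum(r3$firing > 0), 4L)
})

test_that("centroid defuzzification: symmetry, fallback, resolution", {
  u <- cfg$.universe
  symm <- pmax(0, 1 - 4 * abs(u - 0.5))       # triangle centred at 0.5
  expect_equal(defuzzify(symm, cfg), 0.5, tolerance = 1e-9)
  zero <- numeric(length(u))
  v <- defuzzify(zero, cfg)
  expect_equal(as.numeric(v), 0.5)
  expect_true(isTRUE(attr(v, "no_fire")))
  expect_error(defuzzify(c(0, 1), cfg), "universe")
})

test_that("defuzzified output is monotone in the activator effect", {
  for (rep_eff in c(0, 0.3, 0.7, 1)) {
    outs <- vapply(seq(0, 1, by = 0.05), function(a)
      defuzzify(infer_target_level(a, rep_eff, cfg), cfg), numeric(1L))
    expect_true(all(diff(outs) >= -1e-9))
  }
})

test_that("swapping activator and repressor mirrors the output around 0.5", {
  set.seed(1)
  for (i in 1:25) {
    a <- runif(1); r <- runif(1)
    s <- defuzzify(infer_target_level(a, r, cfg), cfg) +
         defuzzify(infer_target_level(r, a, cfg), cfg)
    expect_equal(s, 1, tolerance = 2 * cfg$defuzz_resolution)
  }
})

test_that("no rule ever fails to fire under the default configuration", {
  set.seed(2)
  a <- runif(200); r <- runif(200)
  preds <- fuzzygrn:::.fuzzy_predict(a, r, cfg)
  expect_equal(sum(preds$no_fire), 0L)
  expect_true(all(rowSums(preds$firing) > 0))
})

test_that("pair scoring computes mse, firing variance and rs = mse * variance", {
  # rrs = FALSE uses expression directly, so predictions are hand-checkable
  ds <- make_dataset(cbind(ACT = c(1, 1, 0.5), REP = c(0, 0, 0.5),
                           TGT = c(0.2, 0.5, 0.7)), normalized = TRUE)
  sc <- matrix(0.5, 3L, 3L, dimnames = list(c("ACT", "REP", "TGT"),
                                            c("ACT", "REP", "TGT")))
  m <- manual_mic_matrix(sc)
  ps <- score_pair(ds, m, target = "TGT", activator = "ACT",
                   repressor = "REP", cfg = cfg, rrs = FALSE)
  vh <- defuzzify(infer_target_level(1, 0, cfg), cfg)
  expect_equal(ps$mse, ((0.5 - vh)^2 + (0.7 - vh)^2) / 2, tolerance = 1e-12)
  expect_equal(ps$predicted[[1L]], c(NA, vh, vh))
  counts <- as.vector(ps$firing_counts)
  expect_equal(ps$variance, mean((counts - mean(counts))^2))
  expect_equal(ps$rs, ps$mse * ps$variance)
  expect_equal(ps$no_fire_events, 0L)
  expect_error(score_pair(ds, m, "TGT", "ACT", "ACT"), "distinct")
})

test_that("a perfectly predicted target has zero residual score", {
  net <- manual_planted(c("A", "R", "T"),
                        regulator = c("A", "R"), target = c("T", "T"),
                        sign = c("+", "-"))
  ds <- simulate_expression(net, timepoints = 9L, series = 2L,
                            noise_sd = 0, seed = 5)
  m <- mic_matrix(ds)
  ps <- score_pair(ds, m, "T", "A", "R", cfg = cfg, rrs = FALSE)
  expect_lt(ps$mse, 1e-20)
  expect_equal(ps$rs, 0)
})

test_that("all ordered candidate pairs are scored and nrs spans [0, 1]", {
  set.seed(6)
  genes <- sprintf("G%d", 1:5)
  mk <- function(tp) {
    m <- matrix(runif(tp * 5), tp, 5); colnames(m) <- genes; m
  }
  ds <- minmax_normalize(expression_dataset(list(mk(10L))))
  m <- mic_matrix(ds)
  cand <- structure(list(target = "G5", genes = c("G1", "G2", "G3"),
                         scores = c(0.9, 0.8, 0.7), threshold_used = 0.5,
                         threshold_mode = "fixed"),
                    class = "candidate_set")
  scores <- score_all_pairs(ds, m, "G5", cand, cfg = cfg)
  expect_equal(nrow(scores), 3L * 2L)          # m(m-1) ordered pairs
  expect_equal(min(scores$nrs), 0)
  expect_equal(max(scores$nrs), 1)
  expect_equal(scores$nrs[which.min(scores$rs)], 0)
  expect_equal(scores$nrs[which.max(scores$rs)], 1)

  single <- structure(list(target = "G5", genes = "G1", scores = 0.9,
                           threshold_used = 0.5, threshold_mode = "fixed"),
                      class = "candidate_set")
  expect_message(empty <- score_all_pairs(ds, m, "G5", single, cfg = cfg),
                 "fewer than 2")
  expect_equal(nrow(empty), 0L)
})

test_that("nrs ordering is invariant to rescaling the residual scores", {
  rs <- c(0.4, 0.1, 0.9, 0.3)
  nrs <- (rs - min(rs)) / (max(rs) - min(rs))
  rs2 <- 17 * rs
  nrs2 <- (rs2 - min(rs2)) / (max(rs2) - min(rs2))
  expect_equal(order(nrs), order(nrs2))
  expect_equal(nrs, nrs2, tolerance = 1e-12)
})

test_that("regulator selection thresholds, ranks and resolves roles", {
  scores <- data.frame(
    target = "T",
    activator = c("A", "B", "C"),
    repressor = c("B", "C", "A"),
    mse = c(1, 2, 5) * 1e-3, variance = 1,
    rs = c(0.001, 0.002, 0.005),
    nrs = c(0, 0.02, 0.5), stringsAsFactors = FALSE)
  class(scores) <- c("pair_scores", "data.frame")
  attr(scores, "gene_ids") <- c("A", "B", "C", "T")

  sel <- select_regulators(scores, mode = "nrs_threshold",
                           nrs_threshold = 0.03)
  # pairs (A,B) and (B,C) kept; B appears as repressor (rs 0.001) and
  # activator (rs 0.002): the lower-rs occurrence wins
  expect_setequal(sel$regulator, c("A", "B", "C"))
  expect_equal(sel$sign[sel$regulator == "A"], "+")
  expect_equal(sel$sign[sel$regulator == "B"], "-")
  expect_equal(sel$sign[sel$regulator == "C"], "-")

  topk <- select_regulators(scores, mode = "top_k", k = 2L)
  expect_setequal(topk$regulator, c("A", "B", "C"))
  expect_error(select_regulators(scores, mode = "top_k"), "requires")
  expect_error(select_regulators(scores, mode = "nrs_threshold"), "requires")

  # top_k keeps exactly k pairs even among many
  big <- scores[rep(1:3, 4), ]
  big$rs <- seq_len(nrow(big)) / 100
  big$activator <- sprintf("A%d", seq_len(nrow(big)))
  big$repressor <- sprintf("R%d", seq_len(nrow(big)))
  class(big) <- c("pair_scores", "data.frame")
  attr(big, "gene_ids") <- c(big$activator, big$repressor, "T")
  topk2 <- select_regulators(big, mode = "top_k", k = 10L)
  # 10 kept pairs emit one activator and one repressor each, all distinct
  expect_equal(nrow(topk2), 20L)
})

test_that("fuzzy configurations serialize to flat key-value files", {
  f <- withr::local_tempfile(fileext = ".conf")
  write_fuzzy_config(cfg, f)
  back <- read_fuzzy_config(f)
  expect_equal(back$input_levels, cfg$input_levels)
  expect_equal(back$output_levels, cfg$output_levels)
  expect_equal(back$rule_matrix, cfg$rule_matrix)
  expect_identical(fuzzy_config_hash(back), fuzzy_config_hash(cfg))

  shipped <- system.file("extdata", "fuzzy-default.conf",
                         package = "fuzzygrn")
  expect_true(nzchar(shipped))
  expect_identical(fuzzy_config_hash(read_fuzzy_config(shipped)),
                   fuzzy_config_hash(cfg))
})
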