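test_that("network assembly unions selections and resolves duplicates", {
  u <- c("A", "B", "C", "T1", "T2")
  s1 <- data.frame(regulator = c("A", "B"), target = "T1",
                   sign = c("+", "-"), rs = c(0.1, 0.2), nrs = 0,
                   mic = NA_real_, stringsAsFactors = FALSE)
  s2 <- data.frame(regulator = c("A", "C"), target = "T2",
                   sign = c("+", "-"), rs = c(0.3, 0.4), nrs = 0,
                   mic = NA_real_, stringsAsFactors = FALSE)
  net <- assemble_network(list(s1, s2), u)
  expect_equal(nrow(net$edges), 4L)

  # duplicate edge with equal sign: single edge, minimum rs kept
  dup <- rbind(s1, within(s1, rs <- rs + 1)[1L, ])
  net2 <- assemble_network(dup, u)
  expect_equal(nrow(net2$edges), 2L)
  expect_equal(net2$edges$rs[net2$edges$regulator == "A"], 0.1)

  # conflicting signs: lower-rs occurrence wins, with a warning
  con <- rbind(s1, data.frame(regulator = "A", target = "T1", sign = "-",
                              rs = 0.9, nrs = 0, mic = NA_real_))
  expect_warning(net3 <- assemble_network(con, u), "conflicting signs")
  expect_equal(net3$edges$sign[net3$edges$regulator == "A"], "+")

  expect_error(assemble_network(
    data.frame(regulator = "Z", target = "T1", sign = "+", rs = 0, nrs = 0,
               mic = NA_real_), u), "outside the universe")
})

test_that("confusion counts cover the ordered non-self pair universe", {
  u <- c("G1", "G2", "G3")
  gold <- manual_gold(u, c("G1", "G2"), c("G2", "G3"))
  perfect <- manual_grn(u, c("G1", "G2"), c("G2", "G3"))
  expect_equal(confusion(perfect, gold),
               c(tp = 2L, fp = 0L, tn = 4L, fn = 0L))

  empty <- manual_grn(u)
  expect_equal(confusion(empty, gold),
               c(tp = 0L, fp = 0L, tn = 4L, fn = 2L))

  # counts always partition n(n-1)
  cc <- confusion(manual_grn(u, "G3", "G1"), gold)
  expect_equal(sum(cc), 6L)
  expect_error(confusion(manual_grn(c("G1", "G2"), "G1", "G2"), gold),
               "universe mismatch")
})

test_that("confusion counts are invariant to gene reordering", {
  u <- sprintf("G%d", 1:6)
  set.seed(1)
  gold <- manual_gold(u, sprintf("G%d", 1:4), sprintf("G%d", c(2, 3, 5, 6)))
  net <- manual_grn(u, sprintf("G%d", c(1, 3, 6)), sprintf("G%d", c(2, 5, 1)))
  ref <- confusion(net, gold)
  perm <- sample(u)
  gold2 <- manual_gold(perm, gold$edges[, 1L], gold$edges[, 2L])
  net2 <- manual_grn(perm, net$edges$regulator, net$edges$target,
                     net$edges$sign)
  expect_equal(confusion(net2, gold2), ref)
})

test_that("metric arithmetic matches the SOS-network reference counts", {
  # 8 genes (56 ordered pairs), 9 known regulations, 6 recovered, 8 false
  counts <- c(tp = 6L, fp = 8L, tn = 39L, fn = 3L)
  rep <- network_metrics(counts)
  expect_equal(rep$precision, 6 / 14, tolerance = 1e-12)
  expect_equal(rep$tpr, 6 / 9, tolerance = 1e-12)
  expect_equal(rep$f_score, 0.5217, tolerance = 1e-3)
  expect_equal(rep$precision, 0.4286, tolerance = 1e-3)
  expect_equal(rep$tpr, 0.6667, tolerance = 1e-3)
  expect_equal(rep$structural_accuracy, 45 / 56, tolerance = 1e-12)
  expect_equal(rep$fpr, 8 / 47, tolerance = 1e-12)
  expect_equal(rep$ss_mean,
               2 * (6 / 9) * (39 / 47) / ((6 / 9) + (39 / 47)),
               tolerance = 1e-12)
})

test_that("perfect and degenerate predictions hit metric extremes", {
  perfect <- network_metrics(c(tp = 9L, fp = 0L, tn = 47L, fn = 0L))
  for (f in c("precision", "tpr", "specificity", "f_score", "ss_mean",
              "mcc", "structural_accuracy"))
    expect_equal(perfect[[f]], 1)
  expect_equal(perfect$fpr, 0)

  # gold standard evaluated against itself is all ones
  u <- sprintf("G%d", 1:5)
  gold <- manual_gold(u, c("G1", "G2", "G4"), c("G2", "G3", "G5"))
  self <- manual_grn(u, gold$edges[, 1L], gold$edges[, 2L])
  rep <- network_metrics(confusion(self, gold))
  expect_equal(rep$f_score, 1)
  expect_equal(rep$mcc, 1)

  # zero-denominator ratios are flagged, not NaN
  nothing <- network_metrics(c(tp = 0L, fp = 0L, tn = 50L, fn = 6L))
  expect_equal(nothing$precision, 0)
  expect_true("precision" %in% nothing$zero_denominator)
  expect_error(network_metrics(c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)),
               "zero")
})

test_that("random predictions with matched marginals give mcc near zero", {
  u <- sprintf("G%d", 1:8)
  pairs <- expand.grid(r = u, t = u, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$r != pairs$t, ]
  set.seed(42)
  gidx <- sample(nrow(pairs), 9L)
  gold <- manual_gold(u, pairs$r[gidx], pairs$t[gidx])
  mccs <- replicate(300, {
    pidx <- sample(nrow(pairs), 9L)
    net <- manual_grn(u, pairs$r[pidx], pairs$t[pidx])
    network_metrics(confusion(net, gold))$mcc
  })
  expect_lt(abs(mean(mccs)), 0.05)
})

test_that("ss_mean variants are selectable", {
  counts <- c(tp = 6L, fp = 8L, tn = 39L, fn = 3L)
  tpr <- 6 / 9; spec <- 39 / 47
  expect_equal(network_metrics(counts, "geometric")$ss_mean,
               sqrt(tpr * spec))
  expect_equal(network_metrics(counts, "arithmetic")$ss_mean,
               (tpr + spec) / 2)
})

test_that("combinatorial reduction follows the screened/classical ratio", {
  # no filtering: every target keeps all n-1 genes
  expect_equal(combinatorial_reduction(rep(9L, 10L), 10L), 0)
  # empty or singleton candidate sets: full reduction
  expect_equal(combinatorial_reduction(rep(0L, 10L), 10L), 100)
  expect_equal(combinatorial_reduction(rep(1L, 10L), 10L), 100)
  # screened 50-gene case
  expect_equal(combinatorial_reduction(rep(15L, 50L), 50L),
               100 * (1 - 50 * 15 * 14 / (50 * 49 * 48)),
               tolerance = 1e-12)
  expect_equal(combinatorial_reduction(rep(15L, 50L), 50L), 91.07,
               tolerance = 1e-3)
  expect_error(combinatorial_reduction(1L, 2L), "at least 3")

  # always within [0, 100]
  set.seed(3)
  for (i in 1:20) {
    n <- sample(3:40, 1L)
    m <- sample(0:(n - 1L), n, replace = TRUE)
    v <- combinatorial_reduction(m, n)
    expect_gte(v, 0); expect_lte(v, 100)
  }
})

test_that("signed accuracy scores recovered-edge signs only", {
  truth <- manual_planted(c("A", "B", "T"),
                          regulator = c("A", "B"), target = c("T", "T"),
                          sign = c("+", "-"))
  net <- manual_grn(c("A", "B", "T"), c("A", "B", "T"), c("T", "T", "A"),
                    sign = c("+", "+", "-"))
  # A->T correct sign, B->T wrong sign, T->A not a true edge
  expect_equal(signed_accuracy(net, truth), 0.5)
  expect_true(is.na(signed_accuracy(manual_grn(c("A", "B", "T")), truth)))
})

test_that("networks round trip through TSV", {
  u <- c("A", "B", "T")
  net <- manual_grn(u, c("A", "B"), c("T", "T"), sign = c("+", "-"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f)
  back <- read_network(f, u)
  expect_equal(back$edges$regulator, net$edges$regulator)
  expect_equal(back$edges$sign, net$edges$sign)
  empty <- manual_grn(u)
  write_network(empty, f)
  expect_equal(nrow(read_network(f, u)$edges), 0L)
})
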