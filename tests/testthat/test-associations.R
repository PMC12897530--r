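test_that("behavior summaries are per-participant channel means", {
  b <- validate_behavior(make_behavior_fixture())
  s <- behavior_summaries(b)
  expect_equal(s$participant_id, c("S1", "S2"))
  expect_equal(s$ave_attractiveness, c(mean(c(2, 5, 7)), mean(c(1, 1, 9))))
  expect_equal(s$ave_amount, c(mean(c(0, 300, 1300)), mean(c(100, 0, 700))))
  # constant responder and extreme amounts
  cb <- validate_behavior(data.frame(
    participant_id = "K", group = "HC", partner_id = c("A", "B"),
    attractiveness = 5, trustworthiness = 5, amount = c(0, 1300)))
  sk <- behavior_summaries(cb)
  expect_equal(sk$ave_attractiveness, 5)
  expect_equal(sk$ave_amount, 650)
  expect_error(behavior_summaries(b[0, ]), "empty")
})

test_that("BH adjustment equals the hand step-up procedure", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(17)
  for (i in 1:25) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    # q is monotone in p-rank
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("correlation screen recovers exact and rank relationships", {
  x <- data.frame(participant_id = sprintf("S%d", 1:8),
                  v = c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.9))
  y <- data.frame(participant_id = sprintf("S%d", 1:8),
                  lin = 2 * c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.9) + 1,
                  dec = exp(-c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.9)))
  pe <- correlate(x, y, method = "pearson")
  expect_equal(pe$r[pe$y_name == "lin"], 1, tolerance = 1e-12)
  expect_lt(pe$p[pe$y_name == "lin"], 1e-12)
  sp <- correlate(x, y, method = "spearman")
  expect_equal(sp$r[sp$y_name == "dec"], -1, tolerance = 1e-12)
  # six-point fixture against the textbook formula
  xv <- c(1, 2, 4, 5, 7, 11); yv <- c(2, 1, 5, 8, 6, 13)
  hand_r <- sum((xv - mean(xv)) * (yv - mean(yv))) /
    sqrt(sum((xv - mean(xv))^2) * sum((yv - mean(yv))^2))
  got <- correlate(data.frame(participant_id = 1:6, xv = xv),
                   data.frame(participant_id = 1:6, yv = yv))
  expect_equal(got$r, hand_r, tolerance = 1e-12)
  # p-values match the stats::cor.test t-approximation
  ct <- cor.test(xv, yv)
  expect_equal(got$p, ct$p.value, tolerance = 1e-10)
})

test_that("spearman screening is invariant to monotone transforms", {
  set.seed(19)
  x <- data.frame(participant_id = 1:20, v = rnorm(20))
  y0 <- rnorm(20)
  for (f in list(identity, function(z) exp(z), function(z) z^3)) {
    y <- data.frame(participant_id = 1:20, m = f(y0))
    out <- correlate(x, y, method = "spearman")
    base <- correlate(x, data.frame(participant_id = 1:20, m = y0),
                      method = "spearman")
    expect_equal(out$r, base$r, tolerance = 1e-12)
    expect_equal(out$p, base$p, tolerance = 1e-12)
  }
})

test_that("missing values drop pairwise and small overlap is excluded from FDR", {
  x <- data.frame(participant_id = 1:10, v = c(1:9, NA))
  y <- data.frame(participant_id = 1:10,
                  ok = c(2 * (1:9) + rnorm(9, sd = 0.1), 5),
                  sparse = c(1, 2, NA, NA, NA, NA, NA, NA, NA, NA))
  out <- correlate(x, y)
  expect_equal(out$n[out$y_name == "ok"], 9L)
  expect_true(is.na(out$r[out$y_name == "sparse"]))
  expect_true(is.na(out$q[out$y_name == "sparse"]))
  # the FDR family is only the testable pairs
  expect_equal(out$q[out$y_name == "ok"], out$p[out$y_name == "ok"])
  expect_error(correlate(x[1:2, ], y[1:2, ]), "overlapping")
})

test_that("group comparisons match their reference procedures", {
  vals <- c(3.2, 4.1, 2.5, 5.0, 1.1, 1.9, 0.7, 2.2)
  grp <- rep(c("HC", "MDD"), each = 4)
  # exact Mann-Whitney equals exhaustive enumeration over all 70 splits
  mw <- group_compare(vals, grp, test = "mann_whitney_u")
  expect_equal(mw$p_value, oracle_ranksum_exact_p(vals[1:4], vals[5:8]),
               tolerance = 1e-12)
  # the same procedure under its other name
  wr <- group_compare(vals, grp, test = "wilcoxon_rank_sum")
  expect_equal(wr$p_value, mw$p_value)
  expect_equal(wr$statistic, mw$statistic)
  # against stats::wilcox.test on an untied fixture
  ht <- wilcox.test(vals[1:4], vals[5:8], exact = TRUE)
  expect_equal(mw$p_value, ht$p.value, tolerance = 1e-12)
  expect_equal(mw$statistic, unname(ht$statistic))
  # Welch separates near-degenerate groups
  set.seed(23)
  w <- group_compare(c(rnorm(4, 0, 1e-3), rnorm(4, 1, 1e-3)),
                     grp, test = "welch_t")
  expect_lt(w$p_value, 1e-3)
  # identical multisets show no separation
  same <- rep(c(5, 6, 7, 8), 2)
  expect_gte(group_compare(same, grp, "mann_whitney_u")$p_value, 0.99)
  expect_gte(group_compare(same, grp, "welch_t")$p_value, 0.99)
  expect_error(group_compare(vals[1:5], grp[1:5]), "two groups|2 members")
  expect_error(group_compare(rep(1, 8), grp, "welch_t"), "degenerate")
})

test_that("per-partner evaluation tests count significant partners", {
  set.seed(29)
  g <- setNames(rep(c("HC", "MDD"), each = 20), sprintf("S%02d", 1:40))
  E <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(names(g), sprintf("P%d", 1:6)))
  # plant a strong shift on partners 1-3
  E[21:40, 1:3] <- E[21:40, 1:3] - 3
  out <- per_partner_evaluation_test(E, g)
  expect_equal(out$n_partners, 6)
  expect_true(all(out$per_partner$p[1:3] < 0.001))
  expect_equal(out$n_significant, sum(out$per_partner$p < 0.05))
  expect_equal(out$cumulative, sort(out$per_partner$p))
  # single-partner input
  one <- per_partner_evaluation_test(E[, 1, drop = FALSE], g)
  expect_equal(nrow(one$per_partner), 1)
  expect_error(per_partner_evaluation_test({E[1, 1] <- NA; E}, g),
               "every participant")
})

test_that("planted group offsets make most partners significant", {
  # offset of two between-participant evaluation SDs (the spread the
  # per-partner comparison sees; ~1.25 under the default cohort)
  spec <- cohort_spec(mdd_w_o_offset = -2.5)
  co <- generate_cohort(spec, seed = 31)
  g <- setNames(as.character(co$truth$group), co$truth$participant_id)
  out <- per_partner_evaluation_test(co$evaluations, g)
  expect_gt(out$n_significant / out$n_partners, 0.8)
})

test_that("heatmap clustering places identical columns adjacently", {
  set.seed(37)
  x <- data.frame(participant_id = 1:30, p1 = rnorm(30), p2 = rnorm(30),
                  p3 = rnorm(30))
  base <- rnorm(30)
  y <- data.frame(participant_id = 1:30,
                  mA = base + rnorm(30, sd = 0.01),
                  mB = rnorm(30),
                  mC = base + rnorm(30, sd = 0.01),
                  mD = rnorm(30))
  assoc <- correlate(x, y)
  out <- cluster_heatmap_export(assoc)
  ord <- out$col_order
  expect_equal(abs(which(ord == "mA") - which(ord == "mC")), 1)
  expect_equal(sort(rownames(out$matrix)), c("p1", "p2", "p3"))
  # missing correlations are refused with advice
  broken <- assoc; broken$r[1] <- NA
  expect_error(cluster_heatmap_export(broken), "pairwise-complete")
  # 1x1 screen passes through trivially
  tiny <- correlate(x[, 1:2], y[, 1:2])
  t1 <- cluster_heatmap_export(tiny)
  expect_equal(dim(t1$matrix), c(1, 1))
})

test_that("clustered export writes an ordered matrix CSV", {
  set.seed(38)
  x <- data.frame(participant_id = 1:20, p1 = rnorm(20), p2 = rnorm(20),
                  p3 = rnorm(20))
  y <- data.frame(participant_id = 1:20, m1 = rnorm(20), m2 = rnorm(20),
                  m3 = rnorm(20))
  path <- withr::local_tempfile(fileext = ".csv")
  out <- cluster_heatmap_export(correlate(x, y), path)
  back <- read.csv(path, check.names = FALSE)
  expect_equal(back$x_name, rownames(out$matrix))
  expect_equal(unname(as.matrix(back[, -1])), unname(out$matrix),
               tolerance = 1e-12)
})
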