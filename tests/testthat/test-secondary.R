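test_that("ddCT fold changes follow the closed form", {
  # ddCT = 0 -> fold 1; ddCT = 1 -> fold 0.5
  qpcr <- rbind(
    data.frame(sample_id = "cal1", sirna_id = "untreated",
               role = "calibrator", technical_rep = 1:3,
               LDLR = 24, GAPDH = 17, ACTB = 16),
    data.frame(sample_id = "t0", sirna_id = "s0", role = "test",
               technical_rep = 1:3, LDLR = 24, GAPDH = 17, ACTB = 16),
    data.frame(sample_id = "t1", sirna_id = "s1", role = "test",
               technical_rep = 1:3, LDLR = 25, GAPDH = 17, ACTB = 16))
  fc <- ddct_fold_change(qpcr, housekeeper = "GAPDH")
  expect_equal(fc$fold_change[fc$sirna_id == "s0"], 1)
  expect_equal(fc$fold_change[fc$sirna_id == "s1"], 0.5)
  # plate offset on all CTs of a sample cancels
  qpcr2 <- qpcr
  t1 <- qpcr2$sample_id == "t1"
  qpcr2[t1, c("LDLR", "GAPDH", "ACTB")] <-
    qpcr2[t1, c("LDLR", "GAPDH", "ACTB")] + 3.7
  fc2 <- ddct_fold_change(qpcr2, housekeeper = "GAPDH")
  expect_equal(fc2$fold_change, fc$fold_change, tolerance = 1e-12)
  # technical triplicates are averaged on the CT scale
  qpcr3 <- qpcr
  qpcr3$LDLR[qpcr3$sample_id == "t1"] <- c(24, 25, 26)
  expect_equal(ddct_fold_change(qpcr3, housekeeper = "GAPDH")$fold_change[3],
               0.5)
  expect_error(ddct_fold_change(qpcr[, -5], housekeeper = "GAPDH"),
               "missing CT")
})

test_that("enzymatic calls require both the 2-sd and both t-test criteria", {
  ctl <- c(99.9, 100, 100.1)
  # identical means: n.s.
  expect_equal(enzymatic_call(c(99.8, 100, 100.2), ctl, ctl)$direction,
               "n.s.")
  # strong shift, tight controls: called with matching sign
  up <- enzymatic_call(c(119, 120, 121), ctl, c(99.8, 100.1, 100.3))
  expect_equal(up$direction, "+")
  dn <- enzymatic_call(c(79, 80, 81), ctl, c(99.8, 100.1, 100.3))
  expect_equal(dn$direction, "-")
  # beyond 2 sd of pooled controls, but the mock t-test fails -> n.s.
  mock_wide <- c(80, 100, 120)
  r <- c(125, 126, 127)
  pooled <- c(ctl, mock_wide)
  expect_gt(abs(mean(r) - mean(pooled)), 2 * sd(pooled))
  call <- enzymatic_call(r, ctl, mock_wide)
  expect_equal(call$direction, "n.s.")
  expect_gt(call$p_values[2], 0.05)
  expect_error(enzymatic_call(c(1, 2), ctl, ctl), ">= 3")
  expect_error(enzymatic_call(c(1, 2, 3), numeric(0), ctl), "control")
})

test_that("enzymatic recovery on simulated shifts is sign-correct", {
  ok <- sapply(1:20, function(s) {
    des <- data.frame(sirna_id = "sA", true_chol_fold = 0.7)
    tabs <- simulate_secondary_tables(des, n_replicates = 6,
                                      enzymatic_noise_sd = 0.04, seed = s)
    enz <- tabs$enzymatic
    call <- enzymatic_call(enz$reading[enz$sirna_id == "sA"],
                           enz$reading[enz$role == "negative_control"],
                           enz$reading[enz$role == "mock"], "sA")
    call$direction == "-"
  })
  expect_gte(mean(ok), 0.9)
})

test_that("HuH7 validation applies cell-count, CI and replica-p rules", {
  ctl <- c(-0.2, 0.1, -0.1, 0.2, 0)
  # all replicas under 50 cells: untestable, not n.s.
  u <- huh7_fc_call(c(2, 2, 2), c(40, 30, 49), ctl, c(0.001, 0.001, 0.001))
  expect_equal(u$direction, "untestable")
  # strong deviation, enough cells, two significant replicas: called
  call <- huh7_fc_call(c(2.1, 1.9, 2.0), c(120, 200, 55), ctl,
                       c(0.003, 0.01, 0.2), "sX")
  expect_equal(call$direction, "+")
  # only one significant replica: n.s. (conjunction)
  ns <- huh7_fc_call(c(2.1, 1.9, 2.0), c(120, 200, 55), ctl,
                     c(0.003, 0.2, 0.3))
  expect_equal(ns$direction, "n.s.")
  # inside the control confidence interval: n.s.
  inside <- huh7_fc_call(c(0.01, -0.01, 0), c(120, 200, 55), ctl,
                         c(0.001, 0.001, 0.001))
  expect_equal(inside$direction, "n.s.")
  # replicas below 50 cells are excluded from the significance count
  excl <- huh7_fc_call(c(2, 2, 2), c(120, 40, 55), ctl,
                       c(0.001, 0.001, 0.2))
  expect_equal(excl$direction, "n.s.")
})

test_that("LDLR mRNA calls need both housekeepers and four t-tests", {
  des <- data.frame(sirna_id = "sKD", true_mrna_fold = 1 / 3)
  ok <- sapply(1:20, function(s) {
    tabs <- simulate_secondary_tables(des, ct_noise_sd = 0.08, seed = s)
    fg <- ddct_fold_change(tabs$qpcr, housekeeper = "GAPDH")
    fa <- ddct_fold_change(tabs$qpcr, housekeeper = "ACTB")
    ldlr_mrna_call(fg, fa, "sKD")$direction == "-"
  })
  expect_gte(mean(ok), 0.9)
  tabs <- simulate_secondary_tables(des, ct_noise_sd = 0, seed = 1)
  fg <- ddct_fold_change(tabs$qpcr, housekeeper = "GAPDH")
  fa <- ddct_fold_change(tabs$qpcr, housekeeper = "ACTB")
  # null siRNA: n.s.; absent siRNA: untestable
  null_tab <- transform(fg, fold_change = 1)
  expect_equal(ldlr_mrna_call(null_tab, transform(fa, fold_change = 1),
                              "sKD")$direction, "n.s.")
  expect_equal(ldlr_mrna_call(fg, fa, "sAbsent")$direction, "untestable")
})

test_that("densitometry normalizes within gels and is scale-invariant", {
  des <- data.frame(sirna_id = "sP", true_protein_fold = 0.5)
  tabs <- simulate_secondary_tables(des, density_noise_sd = 0.03, seed = 3)
  nd <- normalize_densitometry(tabs$western)
  # control lanes average to 1 on each gel by construction
  ctl_mean <- tapply(nd$norm_ldlr[nd$role == "control"],
                     nd$gel_id[nd$role == "control"], mean)
  expect_equal(as.vector(ctl_mean), rep(1, length(ctl_mean)),
               tolerance = 1e-12)
  # rescaling one gel's lanes leaves normalized values unchanged
  w2 <- tabs$western
  g1 <- w2$gel_id == w2$gel_id[1]
  w2$density_ldlr[g1] <- w2$density_ldlr[g1] * 37
  w2$density_tubulin[g1] <- w2$density_tubulin[g1] * 37
  nd2 <- normalize_densitometry(w2)
  expect_equal(nd2$norm_ldlr, nd$norm_ldlr, tolerance = 1e-12)
  expect_equal(nd2$norm_ldlr_tub, nd$norm_ldlr_tub, tolerance = 1e-12)
})

test_that("LDLR protein calls recover planted reductions", {
  ok <- sapply(1:20, function(s) {
    des <- data.frame(sirna_id = "sP", true_protein_fold = 0.5)
    tabs <- simulate_secondary_tables(des, density_noise_sd = 0.04,
                                      seed = s)
    ldlr_protein_call(tabs$western, "sP")$direction == "-"
  })
  expect_gte(mean(ok), 0.9)
  # a lane equal to the control average is n.s.
  des <- data.frame(sirna_id = "sN", true_protein_fold = 1)
  tabs <- simulate_secondary_tables(des, density_noise_sd = 0.05, seed = 2)
  expect_equal(ldlr_protein_call(tabs$western, "sN")$direction, "n.s.")
  expect_equal(ldlr_protein_call(tabs$western, "sAbsent")$direction,
               "untestable")
})

test_that("transfection classes follow the 97th-percentile / 4-fold rule", {
  set.seed(13)
  mock <- data.frame(gfp_total = runif(200, 0, 100))
  thr <- unname(quantile(mock$gfp_total, 0.97))
  cells <- data.frame(gfp_total = c(0.5 * thr, 2 * thr, 5 * thr))
  cl <- classify_transfection(cells, mock)
  expect_equal(cl$transfection_class,
               c("untransfected", "intermediate", "transfected"))
  expect_equal(attr(cl, "gfp_threshold"), thr)
  expect_error(classify_transfection(cells, mock[1:10, , drop = FALSE]),
               "50")
})

test_that("overexpression effects recover planted filipin ratios", {
  des <- data.frame(sirna_id = "cA", true_fc_ratio = 2)
  tabs <- simulate_secondary_tables(des, cell_noise_sd = 0.15, seed = 4)
  ovx <- tabs$overexpression
  mock <- ovx[ovx$construct == "mock", ]
  cons <- classify_transfection(ovx[ovx$construct == "cA", ], mock)
  eff <- overexpression_fc_effect(cons, mock, gene = "cA")
  expect_equal(eff$status, "ok")
  expect_lt(abs(eff$ratio_vs_untransfected - 2), 0.25)
  expect_equal(eff$stars, "***")
  expect_equal(eff$n_significant, 4)
  # identical distributions: ratio near 1, no stars
  des0 <- data.frame(sirna_id = "c0", true_fc_ratio = 1)
  tabs0 <- simulate_secondary_tables(des0, seed = 5)
  ovx0 <- tabs0$overexpression
  mock0 <- ovx0[ovx0$construct == "mock", ]
  cons0 <- classify_transfection(ovx0[ovx0$construct == "c0", ], mock0)
  eff0 <- overexpression_fc_effect(cons0, mock0, gene = "c0")
  expect_lt(abs(eff0$ratio_vs_untransfected - 1), 0.15)
  expect_equal(eff0$stars, "")
})

test_that("concentration-dependent effects give a positive trend slope", {
  ok <- sapply(1:10, function(s) {
    set.seed(s)
    n <- 600
    gfp <- rlnorm(n, log(50), 0.4)
    tf <- seq_len(n) %% 3 == 0
    gfp[tf] <- gfp[tf] * 300
    fil <- 100 + 0.05 * gfp + rnorm(n, 0, 30)
    cells <- data.frame(replicate = rep(1:3, each = n / 3),
                        gfp_total = gfp, filipin_total = fil)
    mock <- data.frame(replicate = rep(1:3, each = 50),
                       filipin_total = rnorm(150, 100, 30))
    cl <- classify_transfection(cells, rlnorm(200, log(50), 0.4))
    overexpression_fc_effect(cl, mock)$trend_slope > 0
  })
  expect_gte(mean(ok), 0.9)
})

test_that("secondary criteria are conjunctive: ablation only adds calls", {
  # relaxing the alpha of the t-tests can only turn n.s. into a call
  set.seed(14)
  for (i in 1:20) {
    r <- rnorm(4, 100 + sample(c(-1, 1), 1) * runif(1, 0, 15), 3)
    ctl <- rnorm(5, 100, 3); mock <- rnorm(5, 100, 3)
    strict <- enzymatic_call(r, ctl, mock, alpha = 0.05)
    loose <- enzymatic_call(r, ctl, mock, alpha = 1)
    if (strict$direction != "n.s.")
      expect_equal(loose$direction, strict$direction)
  }
})

test_that("null secondary tables stay below a 5% call rate", {
  calls <- sapply(1:25, function(s) {
    des <- data.frame(sirna_id = "s0")
    tabs <- simulate_secondary_tables(des, seed = s)
    enz <- tabs$enzymatic
    e <- enzymatic_call(enz$reading[enz$sirna_id == "s0"],
                        enz$reading[enz$role == "negative_control"],
                        enz$reading[enz$role == "mock"])
    fg <- ddct_fold_change(tabs$qpcr, housekeeper = "GAPDH")
    fa <- ddct_fold_change(tabs$qpcr, housekeeper = "ACTB")
    m <- ldlr_mrna_call(fg, fa, "s0")
    w <- ldlr_protein_call(tabs$western, "s0")
    c(e$direction, m$direction, w$direction) != "n.s."
  })
  expect_lte(mean(calls), 0.05)
})

test_that("call matrix encodes one- and two-siRNA validation symbols", {
  mapdf <- data.frame(sirna_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
                      gene = c("A", "A", "B", "C", "C", "D"))
  calls <- list(
    secondary_call("s1", "enzymatic", "-"),
    secondary_call("s2", "enzymatic", "-"),
    secondary_call("s3", "enzymatic", "+"),
    secondary_call("s4", "enzymatic", "+"),
    secondary_call("s5", "enzymatic", "-"),
    secondary_call("s6", "enzymatic", "n.s."))
  m <- secondary_call_matrix(calls, mapdf)
  expect_equal(m["A", "enzymatic"], "-")
  expect_equal(m["B", "enzymatic"], "(+)")
  expect_equal(m["C", "enzymatic"], "-/+")
  expect_equal(m["D", "enzymatic"], "n.s.")
})
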