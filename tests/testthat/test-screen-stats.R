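test_that("deviation value follows the control-anchored formula", {
  # controls {1, 3}: mean 2, mean absolute deviation 1 -> (6 - 2)/(2*1) = 2
  expect_equal(deviation_value(6, c(1, 3)), 2)
  expect_equal(deviation_value(2, c(1, 3)), 0)
  # oddness: reflecting the siRNA mean about the control mean negates it
  set.seed(1)
  for (i in 1:20) {
    ctl <- rnorm(16); m <- rnorm(1)
    d1 <- deviation_value(m, ctl)
    d2 <- deviation_value(2 * mean(ctl) - m, ctl)
    expect_equal(d1, -d2, tolerance = 1e-12)
  }
  expect_error(deviation_value(1, c(2, 2)), "degenerate")
  expect_error(deviation_value(1, 2), ">= 2")
})

test_that("deviation values are invariant to intensity rescaling", {
  set.seed(2)
  for (i in 1:20) {
    ctl <- rlnorm(16); m <- rlnorm(1); c0 <- runif(1, 0.1, 10)
    expect_equal(deviation_value(m, ctl),
                 deviation_value(c0 * m, c0 * ctl), tolerance = 1e-12)
    expect_equal(deviation_value(m, ctl, error = "sd"),
                 deviation_value(c0 * m, c0 * ctl, error = "sd"),
                 tolerance = 1e-12)
  }
})

test_that("deviation is strictly monotone in the siRNA mean", {
  ctl <- c(0.8, 1, 1.2, 1.1)
  x <- seq(0.5, 2, length.out = 30)
  d <- sapply(x, deviation_value, control_means = ctl)
  expect_true(all(diff(d) > 0))
})

test_that("negative controls are centred to zero by construction", {
  scr <- demo_scored_screen(seed = 3)
  rd <- scr$scored$replicate_deviations
  neg <- rd[rd$role == "negative_control", ]
  cen <- aggregate(deviation ~ parameter + replicate + region, neg, mean)
  # within each replicate and region the control deviations average to 0
  expect_lt(max(abs(cen$deviation)), 1e-10)
})

test_that("replicate deviations average arithmetically", {
  base <- data.frame(position_id = "p", sirna_id = "s", role = "candidate",
                     region = 3, assay = "fc", parameter = "total")
  tab <- rbind(transform(base, replicate = 1, deviation = -1),
               transform(base, replicate = 2, deviation = 0),
               transform(base, replicate = 3, deviation = 1))
  expect_equal(aggregate_deviations(tab)$mean_deviation, 0)
  expect_equal(aggregate_deviations(tab[1, ])$mean_deviation, -1)
  set.seed(4)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    d <- rnorm(k)
    tab <- do.call(rbind, lapply(seq_len(k), function(r)
      transform(base, replicate = r, deviation = d[r])))
    expect_equal(aggregate_deviations(tab)$mean_deviation, mean(d),
                 tolerance = 1e-12)
  }
})

test_that("effector thresholds implement the 3-SEM control envelope", {
  # construct explicitly: two control positions, 9 replicates each, with
  # per-position means -0.2 and 0.1 and overall sd 0.3
  set.seed(5)
  mkvals <- function(m) {
    x <- rnorm(9); x <- (x - mean(x)) / sd(x)  # mean 0, sd 1
    m + x * 0.3
  }
  v1 <- mkvals(-0.2); v2 <- mkvals(0.1)
  allv <- c(v1, v2)
  s_all <- sd(allv)
  tab <- data.frame(position_id = rep(c("c1", "c2"), each = 9),
                    parameter = "total", assay = "fc",
                    deviation = allv)
  th <- effector_thresholds(tab, n_replicates = 9)
  expect_equal(th$sem, s_all / 3, tolerance = 1e-12)
  expect_equal(th$lower, -0.2 - 3 * s_all / 3, tolerance = 1e-12)
  expect_equal(th$upper, 0.1 + 3 * s_all / 3, tolerance = 1e-12)
  # identical controls at 0 with spread s -> symmetric +/- 3 s / sqrt(n)
  x <- rep(c(-0.1, 0.1), 8)
  tab2 <- data.frame(position_id = rep(c("c1", "c2"), each = 8),
                     parameter = "total", assay = "fc", deviation = x)
  th2 <- effector_thresholds(tab2, n_replicates = 4)
  expect_equal(th2$upper, 3 * sd(x) / 2, tolerance = 1e-12)
  expect_equal(th2$lower, -3 * sd(x) / 2, tolerance = 1e-12)
  expect_error(effector_thresholds(transform(tab2, deviation = 0)),
               "degenerate")
})

test_that("published thresholds classify reported deviations", {
  th <- published_thresholds()
  ldl2 <- th[th$screen == "GWAS2" & th$assay == "ldl", ]
  expect_equal(c(ldl2$lower, ldl2$upper), c(-0.55, 1.02))
  dev <- data.frame(sirna_id = c("s224006", "s226084", "sNull", "sEdge"),
                    mean_deviation = c(-1.47, 1.32, 0.10, 1.02))
  calls <- call_effector_sirnas(dev, ldl2, parameter = NULL, roles = NULL)
  calls <- calls[match(dev$sirna_id, calls$sirna_id), ]
  expect_equal(calls$direction,
               c("decrease", "increase", "none", "none"))  # boundary: none
})

test_that("missing deviations are called none with a missing flag", {
  dev <- data.frame(sirna_id = "sX", mean_deviation = NA_real_)
  call <- call_effector_sirnas(dev, data.frame(lower = -1, upper = 1),
                               parameter = NULL, roles = NULL)
  expect_equal(call$direction, "none")
  expect_true(call$missing)
})

test_that("two independent effector siRNAs make a gene a hit", {
  calls <- data.frame(
    sirna_id = c("s224006", "s224007", "s6", "sA", "sB1", "sB2", "sB3",
                 "sB4", "sC"),
    gene = c("LDLR", "LDLR", "LDLR", "SOLO", "B", "B", "B", "B", "C"),
    assay = "ldl",
    direction = c("decrease", "decrease", "decrease", "decrease",
                  "increase", rep("none", 3), "none"))
  hits <- call_hit_genes(calls)
  expect_true(hits$is_hit[hits$gene == "LDLR"])
  expect_equal(hits$supporting_sirnas[hits$gene == "LDLR"],
               "s224006,s224007,s6")
  expect_true(hits$direction_consistent[hits$gene == "LDLR"])
  expect_false(hits$is_hit[hits$gene == "B"])   # 1 effector of 4
  expect_false(hits$is_hit[hits$gene == "SOLO"])
  expect_true(hits$untestable_by_rule[hits$gene == "SOLO"])
  # two effectors in *different* assays do not make a hit
  calls2 <- data.frame(sirna_id = c("sD1", "sD2"), gene = "D",
                       assay = c("ldl", "fc"), direction = "increase")
  expect_false(call_hit_genes(calls2)$is_hit)
})

test_that("validation rate reproduces reported arithmetic", {
  mkcalls <- function(ids, dirs) data.frame(sirna_id = ids, direction = dirs)
  s1 <- mkcalls(sprintf("s%02d", 1:63), rep("increase", 63))
  s2 <- mkcalls(sprintf("s%02d", 1:63),
                c(rep("increase", 30), rep("none", 33)))
  vr <- validation_rate(s1, s2)
  expect_equal(vr$n_effectors_s1, 63)
  expect_equal(vr$n_validated, 30)
  expect_equal(vr$rate, 48)
  expect_equal(validation_rate(s1, s1)$rate, 100)
  s3 <- mkcalls(sprintf("s%02d", 1:63), rep("none", 63))
  expect_equal(validation_rate(s1, s3)$rate, 0)
  expect_true(is.na(validation_rate(s3, s1)$rate))
})

test_that("region normalization removes multiplicative edge effects", {
  r1_means <- sapply(1:5, function(s) {
    cands <- demo_candidates(40)
    lay <- make_plate_layout("plate_384", cands,
                             controls = control_spec(n_negative = 16,
                                                     n_mock = 8), seed = s)
    sc <- scene_spec(n_cells = 120, edge_effect = c(0.85, 0.95, 1))
    sim <- simulate_screen(lay, n_replicates = 3, scene = sc, seed = s + 70)
    summ <- summarize_replicates(sim$cells, lay)
    with_reg <- suppressWarnings(score_deviations(summ,
                                                  region_normalize = TRUE))
    without <- score_deviations(summ, region_normalize = FALSE)
    r1 <- function(sc_) {
      d <- sc_$deviations
      mean(d$mean_deviation[d$role == "candidate" & d$region == 1 &
                              d$parameter == "total"])
    }
    c(with_reg = r1(with_reg), without = r1(without))
  })
  expect_lt(abs(mean(r1_means["with_reg", ])), 0.5)
  expect_lt(mean(r1_means["without", ]), -0.5)  # uncorrected edge wells low
})

test_that("region and plate normalization agree on uniform plates", {
  diffs <- sapply(1:5, function(s) {
    cands <- demo_candidates(20)
    lay <- make_plate_layout("plate_384", cands,
                             controls = control_spec(n_negative = 16,
                                                     n_mock = 8),
                             seed = s)
    sc <- scene_spec(n_cells = 120, edge_effect = c(1, 1, 1))
    sim <- simulate_screen(lay, n_replicates = 3, scene = sc, seed = s + 50)
    summ <- summarize_replicates(sim$cells, lay)
    a <- suppressWarnings(score_deviations(summ, region_normalize = TRUE))
    b <- score_deviations(summ, region_normalize = FALSE)
    da <- a$deviations[a$deviations$parameter == "total", ]
    db <- b$deviations[b$deviations$parameter == "total", ]
    m <- merge(da, db, by = "position_id")
    mean(abs(m$mean_deviation.x - m$mean_deviation.y))
  })
  expect_lt(median(diffs), 0.5)
})

test_that("Shapiro-Wilk control check is calibrated and has power", {
  set.seed(8)
  p_norm <- replicate(60, control_normality_check(rnorm(100))$p_value)
  expect_gt(mean(p_norm > 0.01), 0.9)
  p_lnorm <- replicate(60,
                       control_normality_check(rlnorm(100, sdlog = 1))$p_value)
  expect_gt(mean(p_lnorm < 0.01), 0.95)
  qq <- control_normality_check(rnorm(50))$qq_points
  expect_equal(nrow(qq), 50)
  expect_true(all(diff(qq$sample) >= 0))
  expect_error(control_normality_check(c(1, 2)), ">= 3")
  expect_error(control_normality_check(rep(1, 10)), "degenerate")
})

test_that("parameter correlations match the closed-form estimator", {
  set.seed(9)
  for (i in 1:10) {
    m <- matrix(rnorm(40 * 5), 40, 5,
                dimnames = list(NULL, paste0("p", 1:5)))
    cc <- parameter_correlations(m)
    brute <- function(x, y) {
      sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    }
    for (a in 1:5) for (b in 1:5)
      expect_equal(cc[a, b], brute(m[, a], m[, b]), tolerance = 1e-12)
  }
  m <- cbind(x = rnorm(10), y = 0)
  m[, "y"] <- -m[, "x"]
  cc <- parameter_correlations(m)
  expect_equal(unname(diag(cc)), c(1, 1))
  expect_equal(cc["x", "y"], -1)
})

test_that("empirical FDR uses the add-one two-sided rule and BH", {
  ctl <- seq(-1, 1, length.out = 100)
  dev <- data.frame(sirna_id = c("far", "mid"), mean_deviation = c(5, 0))
  fdr <- empirical_fdr(dev, ctl)
  expect_equal(fdr$p_empirical[1], 2 / 101, tolerance = 1e-12)
  expect_gt(fdr$p_empirical[2], 0.95)
  expect_error(empirical_fdr(dev, 1:5), ">= 10")
  # BH adjustment matches a brute-force step-up on random p-vectors
  set.seed(10)
  for (i in 1:30) {
    p <- runif(sample(5:40, 1))
    bh <- p.adjust(p, "BH")
    n <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    brute <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
    expect_equal(bh, brute, tolerance = 1e-12)
  }
})

test_that("control positions scored as candidates stay within thresholds", {
  n_called <- sapply(1:8, function(s) {
    scr <- demo_scored_screen(seed = s)
    cc <- call_effector_sirnas(scr$scored$deviations, scr$thresholds,
                               roles = c("negative_control", "mock"))
    sum(cc$direction != "none")
  })
  expect_gte(mean(n_called == 0), 0.95)
})
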