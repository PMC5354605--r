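# Normalization, ratios, isolate averaging, classification, replicate
# intersection, hub fraction, and the sga_score fitting surface.

test_that("normalize_plate divides by the midpoint median of retained sizes", {
  p <- toy_plate()  # 100 200 300 400 -> median 250
  np <- normalize_plate(p)
  expect_equal(as.vector(np$values), c(0.4, 0.8, 1.2, 1.6))
  expect_equal(np$median_size, 250)
  expect_equal(median(np$values[np$flags == ""]), 1, tolerance = 1e-12)
  # scale invariance
  np2 <- normalize_plate(toy_plate(c(100, 200, 300, 400) * 7.3))
  expect_equal(np2$values, np$values)
  # one flagged position: median over the remaining three
  fl <- matrix(c("", "dead_pin", "", ""), 2, 2)
  np3 <- normalize_plate(toy_plate(flags = fl))
  expect_equal(as.vector(np3$values), c(100, NA, 300, 400) / 300)
  # zero sizes are excluded the same way
  np4 <- normalize_plate(toy_plate(c(100, 0, 300, 400)))
  expect_equal(as.vector(np4$values), c(100, NA, 300, 400) / 300)
  expect_error(normalize_plate(toy_plate(c(0, 0, 0, 0))), "no retained")
})

test_that("compute_ratios divides query by control and records failure reasons", {
  g <- matrix(c("g1", "g2", "g3", "g4"), 2, 2)
  q <- normalize_plate(toy_plate(c(60, 200, 300, 400), genes = g))
  c_ <- normalize_plate(toy_plate(c(100, 200, 300, 400), genes = g))
  r <- compute_ratios(q, c_)
  expect_equal(unname(r["g1"]), (60 / 250) / (100 / 250))
  # missing control -> missing ratio with reason
  cm <- normalize_plate(toy_plate(c(0, 200, 300, 400), genes = g))
  r2 <- compute_ratios(q, cm)
  expect_true(is.na(r2["g1"]))
  expect_equal(unname(attr(r2, "reasons")["g1"]), "missing_control")
  # control floor
  cf <- normalize_plate(toy_plate(c(1, 200, 300, 400), genes = g))
  r3 <- compute_ratios(q, cf, control_floor = 0.05)
  expect_true(is.na(r3["g1"]))
  expect_equal(unname(attr(r3, "reasons")["g1"]), "control_below_floor")
  # layout mismatch
  g2 <- matrix(c("g1", "g2", "g4", "g3"), 2, 2)
  expect_error(compute_ratios(q, normalize_plate(toy_plate(genes = g2))),
               "layout mismatch")
})

test_that("mean_over_isolates averages defined ratios and drops sparse genes", {
  m <- rbind(gA = c(0.70, 0.75, 0.80, 0.75),
             gB = c(0.70, NA, 0.80, NA),
             gC = c(NA, NA, NA, 0.9),
             gD = c(NA, NA, NA, NA))
  out <- mean_over_isolates(m, min_isolates = 2)
  expect_equal(out$mean_ratio[out$gene == "gA"], 0.75)
  expect_equal(out$mean_ratio[out$gene == "gB"], 0.75)
  expect_equal(out$n_used, c(4L, 2L, 1L, 0L))
  expect_equal(out$dropped, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(out$reason, c(NA, NA, "too_few_isolates", "no_ratio"))
})

test_that("classification uses strict thresholds and partitions the ratio axis", {
  calls <- classify_interactions(c(0.79, 0.80, 1.00, 1.20, 1.21))
  expect_equal(as.character(calls),
               c("negative", "none", "none", "none", "positive"))
  expect_error(classify_interactions(1, low = 1.2, high = 0.8), "thresholds")
  # monotone in the ratio: calls ordered negative -> none -> positive
  x <- sort(runif(200, 0.5, 1.6))
  cl <- as.integer(classify_interactions(x))
  expect_true(all(diff(cl) >= 0))
})

test_that("replicate intersection keeps same-sign calls and flags discordance", {
  r1 <- data.frame(gene = c("a", "b", "c", "d"),
                   call = factor(c("negative", "negative", "positive", "none"),
                                 c("negative", "none", "positive")))
  r2 <- data.frame(gene = c("a", "b", "c", "d"),
                   call = factor(c("negative", "none", "negative", "negative"),
                                 c("negative", "none", "positive")))
  out <- intersect_replicates(list(r1, r2))
  expect_equal(out$gene, "a")
  expect_equal(out$call, "negative")
  expect_equal(attr(out, "discordant"), "c")
  expect_error(intersect_replicates(list(r1)), ">= 2 replicates")
  # idempotent and order-invariant
  expect_equal(as.data.frame(intersect_replicates(list(r2, r1))),
               as.data.frame(out))
  expect_equal(as.data.frame(intersect_replicates(list(r1, r2, r2))),
               as.data.frame(out))
})

test_that("hub_fraction truncates the percentage to one decimal", {
  res <- hub_fraction(sprintf("g%03d", 1:131), sprintf("g%03d", 1:39))
  expect_equal(res$n_in_hub, 39)
  expect_equal(res$percent, 29.7)  # 29.77... truncated, not rounded
  expect_equal(hub_fraction(c("a", "b"), "zz")$percent, 0)
  expect_equal(hub_fraction(sprintf("g%d", 1:131),
                            sprintf("g%d", 1:131))$percent, 100)
  expect_error(hub_fraction(character(0), "a"), "empty")
})

test_that("sga_score matches a hand-coded recomputation on a 16-gene screen", {
  cfg <- toy_screen_config(noise_cv = 0.25, plate_scale_sd = 0.15,
                           interaction_fractions = c(negative = 0.125,
                                                     positive = 0.125),
                           seed = 314)
  s <- simulate_screen(cfg)
  fit <- sga_score(s)

  # independent brute-force recomputation, plain R on the raw tables
  brute <- lapply(1:2, function(r) {
    ratio_mat <- sapply(1:2, function(i) {
      q <- s$plates[[sprintf("r%d_i%d_query_p1", r, i)]]
      c_ <- s$plates[[sprintf("r%d_i%d_control_p1", r, i)]]
      qn <- q$sizes / median(q$sizes[q$sizes > 0 & q$flags == ""])
      cn <- c_$sizes / median(c_$sizes[c_$sizes > 0 & c_$flags == ""])
      rt <- as.vector(qn / cn)
      names(rt) <- as.vector(q$genes)
      rt[sort(names(rt))]
    })
    mr <- rowMeans(ratio_mat)
    call <- ifelse(mr < 0.8, "negative", ifelse(mr > 1.2, "positive", "none"))
    list(mean = mr, call = call)
  })
  for (r in 1:2) {
    sc <- fit$scores[[r]]
    expect_equal(setNames(sc$mean_ratio, sc$gene), brute[[r]]$mean)
    expect_equal(setNames(as.character(sc$call), sc$gene), brute[[r]]$call)
  }
  both <- intersect(names(which(brute[[1]]$call != "none")),
                    names(which(brute[[2]]$call != "none")))
  both <- both[brute[[1]]$call[both] == brute[[2]]$call[both]]
  expect_setequal(fit$robust$gene, both)
})

test_that("single-plate scale changes never alter downstream calls", {
  cfg <- toy_screen_config(noise_cv = 0.15, seed = 77,
                           interaction_fractions = c(negative = 0.125,
                                                     positive = 0))
  s <- simulate_screen(cfg)
  fit1 <- sga_score(s)
  s$plates$r1_i2_query_p1$sizes <- s$plates$r1_i2_query_p1$sizes * 11.7
  fit2 <- sga_score(s)
  expect_equal(fit1$scores, fit2$scores)
  expect_equal(as.data.frame(fit1$robust), as.data.frame(fit2$robust))
})

test_that("sga_screen methods expose ratios and calls coherently", {
  s <- simulate_screen(toy_screen_config(
    noise_cv = 0.1, seed = 5,
    interaction_fractions = c(negative = 0.125, positive = 0.125)))
  fit <- sga_score(s)
  cm <- coef(fit)
  expect_equal(dim(cm), c(16L, 2L))
  expect_true(all(cm > 0))
  expect_output(print(fit), "robust")
  expect_output(summary(fit), "replicate1")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
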