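# Synthetic screen generator: determinism, generative model, truth table.

test_that("screen generation is deterministic and carries a consistent truth table", {
  cfg <- toy_screen_config(interaction_fractions = c(negative = 0.125, positive = 0.125),
                           noise_cv = 0.1)
  s1 <- simulate_screen(cfg)
  s2 <- simulate_screen(cfg)
  expect_identical(s1$plates, s2$plates)
  expect_identical(s1$truth, s2$truth)
  # category is consistent with epsilon, epsilon > 0
  expect_true(all(s1$truth$epsilon > 0))
  expect_identical(s1$truth$category,
                   ifelse(s1$truth$epsilon < 1, "negative",
                          ifelse(s1$truth$epsilon > 1, "positive", "none")))
  expect_equal(sum(s1$truth$category == "negative"), 2)
  expect_equal(sum(s1$truth$category == "positive"), 2)
  # control plates never carry the planted effect: zero noise => query/control
  # raw size ratio equals epsilon exactly (same plate up to a scalar)
  cfg0 <- toy_screen_config(interaction_fractions = c(negative = 0.125, positive = 0),
                            effect_magnitudes = c(negative = 0.5, positive = 1.5))
  s0 <- simulate_screen(cfg0)
  q <- s0$plates$r1_i1_query_p1$sizes / s0$plates$r1_i1_control_p1$sizes
  eps <- setNames(s0$truth$epsilon, s0$truth$gene)
  expect_equal(as.vector(q / eps[s0$plates$r1_i1_query_p1$genes]),
               rep(mean(q / eps[s0$plates$r1_i1_query_p1$genes]), 16))
})

test_that("a planted effect propagates exactly through normalization at zero noise", {
  # 4-gene toy, constant baseline: the affected gene's post-normalization
  # ratio equals its planted epsilon on every isolate of every replicate
  cfg <- screen_config(n_genes = 4, rows = 2, cols = 2, n_isolates = 2,
                       n_replicates = 2, base_size_cv = 0, noise_cv = 0,
                       plate_scale_sd = 0.2, edge_effect = 1,
                       interaction_fractions = c(negative = 0.25, positive = 0),
                       effect_magnitudes = c(negative = 0.5, positive = 1.5),
                       seed = 2)
  s <- simulate_screen(cfg)
  hit <- s$truth$gene[s$truth$category == "negative"]
  expect_length(hit, 1)
  for (r in 1:2) for (i in 1:2) {
    ratios <- compute_ratios(
      normalize_plate(s$plates[[sprintf("r%d_i%d_query_p1", r, i)]]),
      normalize_plate(s$plates[[sprintf("r%d_i%d_control_p1", r, i)]]))
    expect_equal(unname(ratios[hit]), 0.5)
    expect_equal(unname(ratios[setdiff(names(ratios), hit)]), rep(1, 3))
  }
})

test_that("no effects, no noise, no edge boost yields unit ratios everywhere", {
  s <- simulate_screen(toy_screen_config())
  ratios <- compute_ratios(normalize_plate(s$plates$r1_i1_query_p1),
                           normalize_plate(s$plates$r1_i1_control_p1))
  expect_equal(as.numeric(ratios), rep(1, 16))
})

test_that("plates differing only in scale conserve log-size structure", {
  # zero noise: two plates of the same isolate/role pair are exact scalar
  # multiples, so log sizes shift by a constant with zero spread
  s <- simulate_screen(toy_screen_config(plate_scale_sd = 0.3))
  lr <- log(s$plates$r1_i1_query_p1$sizes) - log(s$plates$r2_i1_query_p1$sizes)
  expect_equal(sd(as.vector(lr)), 0)
  expect_equal(mean(lr), log(s$plates$r1_i1_query_p1$sizes[1] /
                               s$plates$r2_i1_query_p1$sizes[1]))
})

test_that("edge positions get the configured multiplicative boost", {
  cfg <- toy_screen_config(rows = 6L, cols = 6L, n_genes = 36L,
                           base_size_cv = 0, edge_effect = 1.25)
  s <- simulate_screen(cfg)
  sz <- s$plates$r1_i1_query_p1$sizes
  expect_equal(sz[1, 1] / sz[3, 3], 1.25)
  expect_equal(sz[2, 4] / sz[3, 3], 1.25)  # second ring is still edge
  expect_equal(sz[3, 4] / sz[3, 3], 1)
})

test_that("config validation rejects impossible screens", {
  expect_error(screen_config(n_genes = 5, rows = 2, cols = 2, n_plates = 1),
               "grid too small")
  expect_error(screen_config(interaction_fractions = c(0.6, 0.6)), "fractions")
  expect_error(screen_config(noise_cv = -1), "noise_cv")
  # multi-plate layout covers a library larger than one 1536 plate
  cfg <- screen_config(n_genes = 2000)
  expect_equal(cfg$n_plates, 2L)
})

test_that("colony tables round-trip through TSV unchanged", {
  s <- simulate_screen(toy_screen_config(noise_cv = 0.2,
                                         dropout_prob = 0.1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_plate_tsv(s$plates, path)
  back <- read_plate_tsv(path)
  expect_setequal(names(back), names(s$plates))
  for (nm in names(s$plates)) {
    expect_equal(back[[nm]]$sizes, s$plates[[nm]]$sizes, tolerance = 1e-12)
    expect_identical(back[[nm]]$genes, s$plates[[nm]]$genes)
    expect_identical(back[[nm]]$flags, s$plates[[nm]]$flags)
    expect_identical(back[[nm]]$array_role, s$plates[[nm]]$array_role)
  }
})
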