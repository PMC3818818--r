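test_that("generators are deterministic per seed and leave the RNG untouched", {
  plan <- generator_plan(seed = 7)
  set.seed(123)
  before <- .Random.seed
  a <- gen_ct_timecourse(plan)
  expect_identical(.Random.seed, before)
  b <- gen_ct_timecourse(plan)
  expect_identical(a, b)
  c <- gen_ct_timecourse(generator_plan(seed = 8))
  expect_false(identical(a$ct, c$ct))
})

test_that("a noise-free, gap-free table round-trips to the planned fold changes", {
  plan <- generator_plan(noise_sd = 0, missing_rate = 0, seed = 3)
  ct <- gen_ct_timecourse(plan)
  fc <- ddct_fold_change(ct, plan$reference_gene, "control")
  common <- intersect(rownames(fc), rownames(plan$profiles))
  expect_identical(sort(common), sort(rownames(plan$profiles)))
  expect_equal(unclass(fc[common, colnames(plan$profiles)]),
               unclass(plan$profiles[common, ]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("plans implying out-of-range Cts are rejected with the gene named", {
  plan <- generator_plan(noise_sd = 0, missing_rate = 0)
  plan$profiles["TRAF1", 2] <- 2^40
  expect_error(gen_ct_timecourse(plan), "TRAF1")
})

test_that("missingness is injected at roughly the planned rate", {
  plan <- generator_plan(missing_rate = 0.2, seed = 11)
  ct <- gen_ct_timecourse(plan)
  ct <- ct[ct$gene != plan$reference_gene, ]
  cellna <- tapply(is.na(ct$ct), paste(ct$gene, ct$condition, ct$time_min), all)
  rate <- mean(cellna)
  expect_gt(rate, 0.1)
  expect_lt(rate, 0.3)
})

test_that("planted two-cluster structure is reassembled by the pipeline", {
  # two well-separated response groups (>= 4 SD on the Z scale after the
  # row transform), Ct noise 0.25 cycles; UPGMA cut at 2 must recover the
  # planted assignment in >= 90% of genes across 20 seeds
  agreements <- vapply(1:20, function(seed) {
    plan <- generator_plan(noise_sd = 0.25, missing_rate = 0, seed = seed)
    genes <- rownames(plan$profiles)
    half <- seq_len(floor(length(genes) / 2))
    planted <- ifelse(seq_along(genes) %in% half, "up", "down")
    cols <- plan$columns
    late <- cols$time_min >= 360
    plan$profiles[] <- 1
    plan$profiles[planted == "up", late] <- 16
    plan$profiles[planted == "down", late] <- 1 / 16
    plan$profiles[, cols$condition == "control" & cols$time_min == 0] <- 1
    ct <- gen_ct_timecourse(plan)
    z <- zscore_transform(ddct_fold_change(ct, plan$reference_gene, "control"))
    tree <- cluster_average_linkage(z)
    cut2 <- stats::cutree(stats::as.hclust(tree), k = 2)
    tab <- table(cut2, planted[match(names(cut2), genes)])
    best <- max(sum(diag(tab)), sum(tab[1, 2] + tab[2, 1]))
    best / length(genes)
  }, numeric(1))
  expect_gte(mean(agreements >= 0.9), 0.9)
  expect_gte(min(agreements), 0.75)
})

test_that("noisy p52 trajectories stay on the clean mean within 3 SD", {
  p <- default_params()
  a <- gen_noisy_trajectory(p, c(120, 90), 0.05, seed = 1)
  b <- gen_noisy_trajectory(p, c(120, 90), 0.05, seed = 2)
  expect_false(identical(a$p52, b$p52))
  expect_identical(a$clean, b$clean)
  z <- (a$p52 - a$clean) / (0.05 * a$clean)
  z <- z[is.finite(z)]
  expect_lt(max(abs(mean(z))), 3 / sqrt(length(z)) * 3)
  zero <- gen_noisy_trajectory(p, c(120, 90), 0, seed = 5)
  expect_identical(zero$p52, zero$clean)
  expect_error(gen_noisy_trajectory(p, c(120, 90), -0.1), ">= 0")
  expect_error(gen_noisy_trajectory(p, c(121, 90), 0.05), "lattice")
})

test_that("seeded dilution series fit cleanly at realistic noise", {
  r2 <- vapply(1:20, function(seed) {
    d <- gen_dilution_series(-3.32, 30, noise_sd = 0.05, seed = seed)
    fit_standard_curve(d)$r_squared
  }, numeric(1))
  expect_true(all(r2 > 0.99))
  expect_error(gen_dilution_series(-3.3, 30, masses_ng = numeric(0)), "empty")
  expect_error(gen_dilution_series(-3.3, 30, masses_ng = c(-1, 10)), "> 0")
})
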