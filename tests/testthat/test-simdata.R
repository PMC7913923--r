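test_that("null design in the Poisson limit reproduces the target mean", {
  d <- sim_design(group_names = "g", group_sizes = 1000, n_mirnas = 1,
                  baseline_log2_mean = log2(100), baseline_log2_sd = 0,
                  dispersion = 1e6, library_size_range = c(1e6, 1e6),
                  seed = 11)
  sim <- simulate_count_matrix(d)
  x <- as.numeric(sim$counts$counts[1, ])
  se <- sqrt(100 / 1000)  # Poisson SE of the mean
  expect_lt(abs(mean(x) - 100), 3 * se)
  expect_true(all(x == round(x)) && all(x >= 0))
  expect_equal(unname(sim$counts$mirna_mapped_total),
               unname(colSums(sim$counts$counts)))
})

test_that("a planted log2 effect yields the expected group-mean ratio", {
  d <- sim_design(group_names = c("A", "B"), group_sizes = c(200, 200),
                  n_mirnas = 1, baseline_log2_mean = 7, baseline_log2_sd = 0,
                  dispersion = 10, library_size_range = c(1e6, 1e6),
                  effect_table = list(marker = c(B = 2)), seed = 21)
  sim <- simulate_count_matrix(d)
  x <- sim$counts$counts["marker", ]
  ratio <- mean(x[sim$meta$group == "B"]) / mean(x[sim$meta$group == "A"])
  # Monte-Carlo band around 2^2 = 4 at NB size 10, n = 200 per group
  expect_gt(ratio, 3.5)
  expect_lt(ratio, 4.6)
})

test_that("count simulation is deterministic under a fixed seed and validates inputs", {
  d <- default_rat_design("sequencing", n_mirnas = 50, seed = 5)
  s1 <- simulate_count_matrix(d)
  s2 <- simulate_count_matrix(d)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$meta, s2$meta)
  expect_error(sim_design("g", 0, 5), "group sizes")
  expect_error(sim_design("g", 3, 5, dispersion = -1), "dispersion")
  expect_error(sim_design("g", 3, 1,
                          effect_table = list(a = c(g = 1), b = c(g = 1))),
               "effect miRNAs")
})

test_that("Cq simulation honors planted effects, noiselessness and hemolysis flags", {
  meta <- toy_meta(c(s1 = "A", s2 = "A", s3 = "B"))
  assays <- c("target", "miR-28-3p", "miR-23a", "miR-451")

  null_cq <- simulate_cq_table(meta, assays, noise_sd = 0, seed = 1)
  rel <- delta_ct_relative(null_cq)
  for (a in setdiff(assays, "miR-28-3p")) {
    expect_equal(var(rel$value[rel$assay == a]), 0)
  }

  eff_cq <- simulate_cq_table(meta, assays,
                              effects = list(target = c(B = 3)),
                              noise_sd = 0, seed = 1)
  rel <- delta_ct_relative(eff_cq)
  v <- rel[rel$assay == "target", ]
  expect_equal(v$value[v$sample_id == "s3"] / v$value[v$sample_id == "s1"], 8)

  hem_cq <- simulate_cq_table(meta, assays, hemolyzed = "s2", seed = 2)
  d <- assess_dcq(hem_cq)
  expect_true(d$delta_cq[d$sample_id == "s2"] > 5)

  expect_error(simulate_cq_table(meta, c("target", "miR-23a", "miR-451")),
               "reference")
  expect_error(simulate_cq_table(meta, c("target", "miR-28-3p")),
               "hemolysis pair")
})

test_that("ddPCR simulation follows Poisson occupancy and validates inputs", {
  # empty well: no positives, all amplitudes below the threshold
  w0 <- simulate_ddpcr_wells(c(S = 0), n_droplets = 2000, replicates = 1,
                             keep_amplitudes = TRUE, seed = 3)[[1]]
  expect_true(all(w0$amplitudes < w0$threshold))
  expect_equal(quantify_well(w0), 0)

  # copies = n * ln(2) gives expected positive fraction 1/2
  n <- 10000
  w <- simulate_ddpcr_wells(c(S = n * log(2)), n_droplets = n,
                            replicates = 1, seed = 4)[[1]]
  ci <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(w$n_positive, ci[1])
  expect_lte(w$n_positive, ci[2])

  expect_error(simulate_ddpcr_wells(c(S = -1)), "non-negative")
  expect_error(simulate_ddpcr_wells(c(S = 1), n_droplets = 0), "n_droplets")
  expect_error(simulate_ddpcr_wells(c(S = 1), replicates = 0), "replicates")
})

test_that("simulate/quantify round-trip recovers the planted copy number", {
  wells <- simulate_ddpcr_wells(c(S = 19.2), n_droplets = 15000,
                                replicates = 500, seed = 11)
  recovered <- vapply(wells, quantify_well, numeric(1))
  expect_gt(mean(recovered), 18.5)
  expect_lt(mean(recovered), 19.9)
})

test_that("log-normal copy-number simulation hits the geometric group means", {
  sim <- simulate_copy_numbers(c(lo = 5, hi = 20), c(lo = 400, hi = 400),
                               log_sd = 0.3, seed = 9)
  gm <- tapply(log(sim$copies), sim$meta$group, mean)
  expect_lt(abs(gm[["lo"]] - log(5)), 3 * 0.3 / sqrt(400))
  expect_lt(abs(gm[["hi"]] - log(20)), 3 * 0.3 / sqrt(400))
})
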