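test_that("haplotype generator plants exactly the requested site classes", {
  cfg <- seq_sim_config(length = 400, n_fixed_diff = 3, n_shared_poly = 2,
                        seed = 12)
  sim <- simulate_haplotypes(cfg)
  expect_equal(sim$aln$length, 400L)
  expect_equal(length(sim$aln), 12L)
  cl <- classify_sites(complete_deletion(sim$aln),
                       split_by_arrangement(sim$aln))
  expect_equal(cl$fixed_diff, 3L)
  expect_equal(cl$shared, 2L)
  expect_equal(cl$sp1_sf2, 0L)
  expect_equal(cl$sp2_sf1, 0L)
  expect_equal(cl$monomorphic, 395L)

  # truth records the realised classes column by column
  expect_equal(sum(sim$truth$classes == "fixed_diff"), 3L)
  expect_equal(sum(sim$truth$classes == "shared"), 2L)

  # zero-variation config: two identical monomorphic populations
  sim0 <- simulate_haplotypes(seq_sim_config(length = 100, seed = 3))
  cl0 <- classify_sites(complete_deletion(sim0$aln),
                        split_by_arrangement(sim0$aln))
  expect_equal(cl0$monomorphic, 100L)

  # fixed differences only: Hw = 0, so Fst is exactly 1
  simf <- simulate_haplotypes(seq_sim_config(length = 400, n_fixed_diff = 100,
                                             seed = 9))
  expect_equal(hudson_fst(complete_deletion(simf$aln),
                          split_by_arrangement(simf$aln)), 1)

  expect_error(seq_sim_config(length = 10, n_fixed_diff = 11), "capacity")
})

test_that("gap columns are planted and then excluded by complete deletion", {
  sim <- simulate_haplotypes(seq_sim_config(length = 200, n_fixed_diff = 5,
                                            gap_columns = 7, seed = 44))
  clean <- complete_deletion(sim$aln)
  expect_equal(clean$length, 193L)
  cl <- classify_sites(clean, split_by_arrangement(clean))
  expect_equal(cl$fixed_diff, 5L)
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- seq_sim_config(length = 150, n_fixed_diff = 2, n_shared_poly = 1,
                        gap_columns = 1, seed = 77)
  expect_identical(simulate_haplotypes(cfg), simulate_haplotypes(cfg))
  expect_identical(simulate_promoter(seed = 5), simulate_promoter(seed = 5))
  cfg_ct <- expr_sim_config(sex_effect = 0.5, seed = 77)
  expect_identical(simulate_ct_data(cfg_ct), simulate_ct_data(cfg_ct))
  # different seed, different draw
  expect_false(identical(simulate_promoter(seed = 5)$sequence,
                         simulate_promoter(seed = 6)$sequence))
})

test_that("promoter generator recovers its planted elements exactly", {
  pr <- simulate_promoter(seed = 1)
  expect_equal(nchar(pr$sequence), 550L)
  expect_equal(pr$tss, 291L)
  hse <- scan_hse(pr$sequence)
  expect_equal(hse$unit_count, c(3L, 4L, 4L, 3L))
  expect_equal(nrow(scan_gaga(pr$sequence)), 3L)
  want <- pr$truth[pr$truth$kind == "HSE", c("start", "end", "unit_count")]
  rownames(want) <- NULL
  expect_equal(hse[, c("start", "end", "unit_count")], want)

  # an empty layout yields a sequence no scanner fires on
  empty <- simulate_promoter(list(upstream = 100L, downstream = 50L,
                                  elements = list()), seed = 8)
  expect_equal(nrow(scan_hse(empty$sequence)), 0L)
  expect_equal(nrow(scan_gaga(empty$sequence)), 0L)
  expect_equal(nrow(scan_are(empty$sequence)), 0L)
  expect_equal(nrow(scan_tata(empty$sequence)), 0L)

  # overlapping planted elements are a configuration error
  bad <- list(upstream = 100L, downstream = 0L,
              elements = list(list(kind = "GAGA_PLUS", start = 10L),
                              list(kind = "GAGA_MINUS", start = 12L)))
  expect_error(simulate_promoter(bad, seed = 1), "overlap")
})

test_that("Ct generator realises the nested design with planted effects", {
  cfg <- expr_sim_config(sex_effect = 2, sd_line = 0, sd_error = 0,
                         sd_tech = 0, n_missing = 0, seed = 10)
  sim <- simulate_ct_data(cfg)
  obs <- aggregate_ct(sim$ct)
  expect_equal(nrow(obs), 72L)
  # noiseless: female and male delta-CT differ by exactly the planted effect
  expect_equal(mean(obs$delta_ct[obs$sex == "M"]) -
                 mean(obs$delta_ct[obs$sex == "F"]), 2)
  # per-replicate truth matches the emitted data
  expect_equal(sort(unique(round(obs$delta_ct, 10))),
               sort(unique(round(sim$truth$design$true_dct, 10))))

  # the default design drops 5 of 72 biological replicates (67 analysed)
  sim67 <- simulate_ct_data(expr_sim_config(seed = 11))
  expect_equal(sim67$truth$n_observations, 67L)
  expect_equal(nrow(aggregate_ct(sim67$ct)), 67L)
  expect_equal(length(sim67$truth$dropped_rows), 5L)

  # all variation off: the ANOVA correctly refuses the degenerate data
  cfg0 <- expr_sim_config(sd_line = 0, sd_error = 0, sd_tech = 0,
                          n_missing = 0, seed = 1)
  expect_error(fit_nested_anova(aggregate_ct(simulate_ct_data(cfg0)$ct)),
               "degenerate")

  expect_error(expr_sim_config(sd_error = -1), "standard deviations")
})

test_that("emitted Ct tables round-trip through the reader", {
  sim <- simulate_ct_data(expr_sim_config(seed = 21))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ct_table(sim$ct, path)
  back <- read_ct_table(path)
  expect_equal(nrow(back), nrow(sim$ct))
  expect_equal(back$ct, sim$ct$ct, tolerance = 1e-12)
  expect_equal(back$gene, sim$ct$gene)
})
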