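ct_rows <- function(line, arr, sex, bio, gene, cts) {
  data.frame(line_id = line, arrangement = arr, sex = sex, bio_rep = bio,
             tech_rep = seq_along(cts), gene = gene, ct = cts,
             stringsAsFactors = FALSE)
}

test_that("technical replicates average into delta-CT and 2^-dCT", {
  rec <- rbind(ct_rows("l1", "OST", "F", 1, "target", c(25, 25, 25)),
               ct_rows("l1", "OST", "F", 1, "reference", c(20, 20, 20)))
  obs <- aggregate_ct(rec)
  expect_equal(obs$delta_ct, 5)
  expect_equal(obs$rel_expr, 0.03125)

  # dCT = 0 means equal expression to the reference
  rec0 <- rbind(ct_rows("l1", "OST", "F", 1, "target", c(20, 20)),
                ct_rows("l1", "OST", "F", 1, "reference", c(20, 20)))
  expect_equal(aggregate_ct(rec0)$rel_expr, 1)

  # uneven technical replication: means per gene, then the difference
  rec2 <- rbind(ct_rows("l1", "OST", "F", 1, "target", c(24.8, 25.2)),
                ct_rows("l1", "OST", "F", 1, "reference", 20.0))
  expect_equal(aggregate_ct(rec2)$delta_ct, 5)
  expect_equal(aggregate_ct(rec2)$rel_expr, 2^-5)

  # permutation-invariance over technical replicate order
  rec3 <- rec[sample(nrow(rec)), ]
  expect_equal(aggregate_ct(rec3), obs)

  # a biological replicate without its reference gene cannot be normalised
  expect_error(aggregate_ct(ct_rows("l2", "OST", "M", 1, "target", 25)),
               "missing reference.*l2")
})

test_that("nested ANOVA matches the closed-form balanced oracle", {
  cfg <- expr_sim_config(arrangement_effect = 0.2, sex_effect = 0.4,
                         interaction_effect = 0.1, sd_line = 0.15,
                         sd_error = 0.01, sd_tech = 0, n_missing = 0,
                         seed = 314)
  obs <- aggregate_ct(simulate_ct_data(cfg)$ct)
  expect_equal(nrow(obs), 72L)
  fit <- fit_nested_anova(obs)
  oracle <- oracle_balanced_ss(obs)
  for (tm in c("arrangement", "line", "sex", "interaction", "error")) {
    got <- fit$ss[fit$term == tm]
    expect_equal(got, oracle[[tm]], tolerance = 1e-10, info = tm)
  }
  # balanced data: Type III coincides with the sequential decomposition
  expect_equal(fit$df, c(1L, 10L, 1L, 1L, 58L))
  expect_equal(sum(fit$df), nrow(obs) - 1L)
})

test_that("unbalanced Type III SS agree with an independent lm route", {
  sim <- simulate_ct_data(expr_sim_config(sex_effect = 0.5, seed = 88))
  obs <- aggregate_ct(sim$ct)
  expect_equal(nrow(obs), 67L)
  fit <- fit_nested_anova(obs)
  expect_equal(sum(fit$df), 66L)

  # cross-check line/sex/interaction Type III SS against car::Anova on an
  # lm with sum-to-zero contrasts (the nested arrangement term is aliased
  # in that parameterisation, so it is covered by the balanced oracle above)
  df <- data.frame(y = obs$rel_expr, arr = factor(obs$arrangement),
                   sx = factor(obs$sex), ln = factor(obs$line_id))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  m <- stats::lm(y ~ arr + arr/ln + sx + arr:sx, data = df)
  A <- suppressWarnings(car::Anova(m, type = 3, singular.ok = TRUE))
  expect_equal(fit$ss[fit$term == "line"], A["arr:ln", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(fit$ss[fit$term == "sex"], A["sx", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(fit$ss[fit$term == "interaction"], A["arr:sx", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(fit$ss[fit$term == "error"], A["Residuals", "Sum Sq"],
               tolerance = 1e-8)

  # F denominators: arrangement over the line MS, everything else over error
  ms <- setNames(fit$ms, fit$term); f <- setNames(fit$f, fit$term)
  expect_equal(f[["arrangement"]], ms[["arrangement"]] / ms[["line"]])
  expect_equal(f[["sex"]], ms[["sex"]] / ms[["error"]])
})

test_that("degenerate and ill-posed designs are rejected", {
  rec <- rbind(ct_rows("l1", "OST", "F", 1, "target", 25),
               ct_rows("l1", "OST", "F", 1, "reference", 20),
               ct_rows("l2", "O347", "M", 1, "target", 25),
               ct_rows("l2", "O347", "M", 1, "reference", 20))
  obs <- aggregate_ct(rec)
  expect_error(fit_nested_anova(obs), "degenerate|zero variance")

  sim <- simulate_ct_data(expr_sim_config(n_missing = 0, seed = 2))
  obs2 <- aggregate_ct(sim$ct)
  obs2$arrangement <- "OST"
  expect_error(fit_nested_anova(obs2), "2 arrangements")
})

test_that("permutation p-values respect the counting rule and the seed", {
  sim <- simulate_ct_data(expr_sim_config(sex_effect = 1, seed = 5))
  obs <- aggregate_ct(sim$ct)
  pa <- permutation_anova(obs, n_permutations = 99, seed = 1)
  pp <- pa$p_permutation[!is.na(pa$p_permutation)]
  expect_true(all(pp >= 1 / 100 & pp <= 1))
  pa2 <- permutation_anova(obs, n_permutations = 99, seed = 1)
  expect_identical(as.data.frame(pa), as.data.frame(pa2))
  pa3 <- permutation_anova(obs, n_permutations = 99, seed = 2)
  expect_false(identical(pa$p_permutation, pa3$p_permutation))
  expect_error(permutation_anova(obs, n_permutations = 0), "n_permutations")
})

test_that("permutation p converges to parametric p on normal data", {
  cfg <- expr_sim_config(sex_effect = 0.08, sd_line = 0.02, sd_error = 0.05,
                         sd_tech = 0, n_missing = 0,
                         effect_scale = "rel_expr", seed = 404)
  obs <- aggregate_ct(simulate_ct_data(cfg)$ct)
  pa <- permutation_anova(obs, n_permutations = 9999, seed = 10)
  for (tm in c("line", "sex", "interaction")) {
    p_par <- pa$p_parametric[pa$term == tm]
    p_perm <- pa$p_permutation[pa$term == tm]
    se <- sqrt(p_par * (1 - p_par) / 9999)
    expect_lt(abs(p_perm - p_par), 3 * se + 1e-3, label = tm)
  }
})

test_that("reference-gene homogeneity check runs ANOVA and Levene variants", {
  grp <- function(line, arr, sex, cts)
    ct_rows(line, arr, sex, 1, "reference", cts)
  # identical within-group spread, different means: F large, Levene W = 0
  rec <- rbind(grp("l1", "OST", "F", c(1, 2, 3)),
               grp("l2", "OST", "M", c(11, 12, 13)),
               grp("l3", "O347", "F", c(21, 22, 23)),
               grp("l4", "O347", "M", c(31, 32, 33)))
  chk <- reference_gene_check(rec)
  expect_gt(chk$anova_f, 100)
  expect_equal(chk$levene_w_median, 0)
  expect_equal(chk$levene_w_mean, 0)
  expect_equal(unname(chk$group_means),
               c(22, 2, 32, 12))                # alphabetical group order

  # identical groups: F = 0, p = 1
  rec2 <- rbind(grp("l1", "OST", "F", c(1, 2, 3)),
                grp("l2", "OST", "M", c(1, 2, 3)),
                grp("l3", "O347", "F", c(1, 2, 3)),
                grp("l4", "O347", "M", c(1, 2, 3)))
  chk2 <- reference_gene_check(rec2)
  expect_equal(chk2$anova_f, 0)
  expect_equal(chk2$anova_p, 1)

  # its type-I error is nominal on homogeneous simulated groups
  set.seed(606)
  rej <- mean(replicate(400, {
    recs <- rbind(grp("l1", "OST", "F", rnorm(8, 20, 0.5)),
                  grp("l2", "OST", "M", rnorm(8, 20, 0.5)),
                  grp("l3", "O347", "F", rnorm(8, 20, 0.5)),
                  grp("l4", "O347", "M", rnorm(8, 20, 0.5)))
    reference_gene_check(recs)$anova_p <= 0.05
  }))
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 400)
  expect_gte(rej, ci[1]); expect_lte(rej, ci[2])

  expect_error(reference_gene_check(rec[rec$gene == "target", ]), "reference")
})
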