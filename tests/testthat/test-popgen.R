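worked_aln <- function() {
  make_aln(c("AAAA", "AAAT", "TTTA", "TTTT"))
}
worked_split <- function() pop_split(c("s1", "s2"), c("s3", "s4"))

test_that("complete deletion removes exactly the gap/N-bearing columns", {
  aln <- make_aln(c("ACGTACGTAC", "ACGTACGTAC"))
  clean <- complete_deletion(aln)
  expect_identical(clean$seq, aln$seq)          # no gaps: identity
  expect_equal(attr(clean, "analysed_sites"), 10L)

  aln2 <- make_aln(c("AC-TACGTAC", "ACGTACGNAC"))
  clean2 <- complete_deletion(aln2)
  expect_equal(clean2$length, 8L)               # columns 3 and 8 removed

  # columns gapped only in excluded sequences survive the restriction
  aln3 <- make_aln(c("ACGT", "ACGT", "-CGT"), n_pop1 = 2)
  expect_equal(complete_deletion(aln3, c("s1", "s2"))$length, 4L)
  expect_equal(complete_deletion(aln3)$length, 3L)

  expect_error(complete_deletion(make_aln(c("-A", "A-"))), "degenerate")
})

test_that("site classes partition the columns into the five classes", {
  # hand enumeration: col1/2 monomorphic, col3 fixed, col4 pop1-exclusive
  aln <- make_aln(c("ACGT", "ACGA", "ACTT", "ACTT"))
  cl <- classify_sites(aln, worked_split())
  expect_equal(cl$monomorphic, 2L)
  expect_equal(cl$fixed_diff, 1L)
  expect_equal(cl$sp1_sf2, 1L)
  expect_equal(cl$sp2_sf1, 0L)
  expect_equal(cl$shared, 0L)

  # symmetric polymorphism is shared
  cl2 <- classify_sites(make_aln(c("AT", "AA", "AT", "AA")), worked_split())
  expect_equal(cl2$shared, 1L)
  expect_equal(cl2$monomorphic, 1L)

  expect_error(classify_sites(make_aln(c("A-", "AA", "AA", "AA")),
                              worked_split()), "gap")

  # partition identity on random alignments, including multi-allelic sites
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(4:6, 1)
    aln_r <- make_aln(random_alignment(n, sample(5:30, 1)), n_pop1 = 2)
    sp <- pop_split(paste0("s", 1:2), paste0("s", 3:n))
    cl_r <- classify_sites(aln_r, sp)
    expect_equal(cl_r$sp1_sf2 + cl_r$sp2_sf1 + cl_r$shared + cl_r$fixed_diff +
                   cl_r$monomorphic, cl_r$analysed_sites)
  }
})

test_that("pairwise difference matrix equals the per-site double loop", {
  expect_true(all(pairwise_diff_matrix(make_aln(c("ACGT", "ACGT"))) == 0))
  expect_equal(pairwise_diff_matrix(make_aln(c("AAAA", "TTTT")))[1, 2], 4L)
  set.seed(5)
  seqs <- random_alignment(6, 100)
  d <- pairwise_diff_matrix(make_aln(seqs))
  for (i in 1:6) for (j in 1:6)
    expect_equal(d[i, j], oracle_hamming(seqs[i], seqs[j]))
  expect_identical(d, t(d))
})

test_that("Dxy, Fst and Snn reproduce the worked haplotype example", {
  aln <- worked_aln(); sp <- worked_split()
  # 4 cross pairs differ at 3+4+4+3 = 14 sites over 4 columns
  expect_equal(dxy(aln, sp), 14 / 16)
  # Hw = 0.25, Hb = 0.875
  expect_equal(hudson_fst(aln, sp), 1 - 2 / 7)
  expect_equal(snn(aln, sp), 1)

  # identical populations: dxy 0, fst undefined
  same <- make_aln(c("ACGT", "ACGT", "ACGT", "ACGT"))
  expect_equal(dxy(same, worked_split()), 0)
  expect_error(hudson_fst(same, worked_split()), "undefined")

  # maximal differentiation: Hw = 0 and Hb > 0 give Fst exactly 1
  fixed <- make_aln(c("AAAA", "AAAA", "TTTT", "TTTT"))
  expect_equal(hudson_fst(fixed, worked_split()), 1)

  # all-identical alignment: every other sequence ties as nearest neighbour
  expect_equal(snn(same, worked_split()), 1 / 3)
})

test_that("swapping population labels leaves all statistics invariant", {
  set.seed(17)
  for (rep in 1:20) {
    seqs <- random_alignment(6, 25)
    aln <- make_aln(seqs, n_pop1 = 3)
    sp <- pop_split(paste0("s", 1:3), paste0("s", 4:6))
    sp_rev <- pop_split(paste0("s", 4:6), paste0("s", 1:3))
    expect_equal(dxy(aln, sp), dxy(aln, sp_rev))
    expect_equal(snn(aln, sp), snn(aln, sp_rev))
    cl <- classify_sites(aln, sp); cl_rev <- classify_sites(aln, sp_rev)
    expect_equal(cl$sp1_sf2, cl_rev$sp2_sf1)
    expect_equal(cl$shared, cl_rev$shared)
    if (dxy(aln, sp) > 0)
      expect_equal(hudson_fst(aln, sp), hudson_fst(aln, sp_rev))
  }
})

test_that("duplicated identical populations give non-positive Fst", {
  set.seed(31)
  for (rep in 1:10) {
    half <- random_alignment(3, 20)
    aln <- make_aln(c(half, half), n_pop1 = 3)
    sp <- pop_split(paste0("s", 1:3), paste0("s", 4:6))
    if (dxy(aln, sp) > 0) expect_lte(hudson_fst(aln, sp), 0)
  }
})

test_that("Snn permutation p matches exhaustive label enumeration", {
  aln <- worked_aln(); sp <- worked_split()
  # exact null: 2 of the 6 distinct 2/2 assignments reproduce Snn = 1
  exact <- oracle_snn_exact_p(aln$seq, 1:2, 3:4)
  expect_equal(exact, 2 / 6)
  res <- snn_permutation_test(aln, sp, n_permutations = 3000, seed = 21)
  expect_equal(res$snn, 1)
  expect_lt(abs(res$p - exact), 0.03)
  expect_gte(res$p, 1 / 3001)

  # reproducible given the seed
  res2 <- snn_permutation_test(aln, sp, n_permutations = 3000, seed = 21)
  expect_identical(res, res2)
  expect_error(snn_permutation_test(aln, sp, n_permutations = 0), "n_permutations")
})

test_that("Snn permutation p-values are uniform under the null", {
  # long sequences keep nearest-neighbour distance ties rare; with short
  # regions the tie rule makes the test conservative, not anti-conservative
  set.seed(2024)
  ps <- replicate(400, {
    aln <- make_aln(random_alignment(12, 500), n_pop1 = 6)
    sp <- pop_split(paste0("s", 1:6), paste0("s", 7:12))
    snn_permutation_test(aln, sp, n_permutations = 99)$p
  })
  rej <- mean(ps <= 0.05)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 400)
  expect_gte(rej, ci[1] - 1e-9)
  expect_lte(rej, ci[2] + 1e-9)
  # KS sanity check against uniformity (discrete p makes this approximate)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("differentiation table assembles per-copy and combined rows", {
  simA <- simulate_haplotypes(seq_sim_config(length = 300, n_fixed_diff = 4,
                                             n_excl_poly_pop1 = 3,
                                             n_shared_poly = 1, seed = 401))
  simB <- simulate_haplotypes(seq_sim_config(length = 300, n_fixed_diff = 1,
                                             n_excl_poly_pop2 = 2,
                                             gap_columns = 2, seed = 402))
  simA$aln$meta$gene_copy <- "A"; simB$aln$meta$gene_copy <- "B"
  # same line ids across copies so concatenation can join them
  simB$aln$meta$line_id <- simA$aln$meta$line_id
  tab <- differentiation_table(
    list(list(aln = simA$aln, region = "five_prime", copy = "A"),
         list(aln = simB$aln, region = "five_prime", copy = "B")),
    n_permutations = 200, seed = 7)
  expect_equal(nrow(tab), 3L)
  expect_setequal(tab$copy, c("A", "B", "concatenated"))
  a_row <- tab[tab$copy == "A", ]
  expect_equal(a_row$fixed_diff, 4L)
  expect_equal(a_row$sp1_sf2, 3L)
  expect_equal(a_row$shared, 1L)
  b_row <- tab[tab$copy == "B", ]
  expect_equal(b_row$analysed_sites, 298L)      # 2 gap columns excluded
  conc <- tab[tab$copy == "concatenated", ]
  # concatenation joins A and B per line before gap deletion
  expect_equal(conc$analysed_sites, a_row$analysed_sites + b_row$analysed_sites)
  expect_equal(conc$fixed_diff, a_row$fixed_diff + b_row$fixed_diff)
  expect_true(all(tab$snn_p >= 1 / 201 & tab$snn_p <= 1))

  # determinism: same seed, same table
  tab2 <- differentiation_table(
    list(list(aln = simA$aln, region = "five_prime", copy = "A"),
         list(aln = simB$aln, region = "five_prime", copy = "B")),
    n_permutations = 200, seed = 7)
  expect_identical(tab, tab2)
})
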