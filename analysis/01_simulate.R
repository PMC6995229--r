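#!/usr/bin/env Rscript
# Generates the synthetic study inputs used by the downstream analysis
# scripts: promoter and 3'UTR sequences for 6 cold-climate (OST) and 6
# warm-climate (O347) isochromosomal lines x 2 hsp70 gene copies, haplotype
# alignments with planted between-arrangement site classes, and a qPCR Ct
# dataset under the nested expression model (67 of 72 biological replicates,
# 1-cycle female-biased sex effect). Everything is seeded and written as
# plain text under results/synthetic/.

suppressPackageStartupMessages(library(hspreg))
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260101L

lines <- c(paste0("OST_", 1:6), paste0("O347_", 1:6))
arr <- rep(c("OST", "O347"), each = 6)

# --- promoters: identical element layout (4 HSEs 3/4/4/3, 3 GAGA, TATA) ----
for (copy in c("A", "B")) {
  seqs <- vapply(seq_along(lines), function(k)
    simulate_promoter(seed = seed + match(copy, c("A", "B")) * 100 + k)$sequence,
    character(1))
  names(seqs) <- lines
  aln <- aligned_set(seqs, line_id = lines, arrangement = arr,
                     gene_copy = copy)
  write_fasta_alignment(aln, file.path(out, paste0("five_prime_", copy, ".fasta")))
  utils::write.csv(aln$meta, file.path(out, paste0("five_prime_", copy, "_meta.csv")),
                   row.names = FALSE, quote = FALSE)
}
cat("wrote promoter alignments (TSS at column 291)\n")

# --- 3'UTRs: copy A modally 2 AREs (1 in OST_1/OST_6), copy B modally 1
#     (2 in OST_4, whose UTR is longer) --------------------------------------
utr_layout <- function(n_are, len = 200L) {
  list(upstream = 0L, downstream = len,
       elements = lapply(c(40L, 120L, 170L)[seq_len(n_are)],
                         function(s) list(kind = "ARE", start = s)))
}
n_are_A <- ifelse(lines %in% c("OST_1", "OST_6"), 1L, 2L)
n_are_B <- ifelse(lines == "OST_4", 2L, 1L)
for (copy in c("A", "B")) {
  n_are <- if (copy == "A") n_are_A else n_are_B
  seqs <- vapply(seq_along(lines), function(k) {
    len <- if (copy == "B" && lines[k] == "OST_4") 381L else 200L
    simulate_promoter(utr_layout(n_are[k], len), seed = seed + 500 + k +
                        match(copy, c("A", "B")) * 50)$sequence
  }, character(1))
  # pad the one longer UTR with gaps so the set aligns
  width <- max(nchar(seqs))
  seqs <- vapply(seqs, function(s)
    paste0(s, strrep("-", width - nchar(s))), character(1))
  names(seqs) <- lines
  aln <- aligned_set(seqs, line_id = lines, arrangement = arr,
                     gene_copy = copy)
  write_fasta_alignment(aln, file.path(out, paste0("three_prime_", copy, ".fasta")))
}
cat("wrote 3'UTR alignments; ARE exceptions: OST_1/OST_6 (A), OST_4 (B)\n")

# --- haplotype alignments with planted site-class structure -----------------
# counts echo the per-copy 5' structure reported for the real lines
simA <- simulate_haplotypes(seq_sim_config(
  length = 550, n_excl_poly_pop1 = 13, n_excl_poly_pop2 = 3,
  n_shared_poly = 2, gap_columns = 4, seed = seed + 900))
write_fasta_alignment(simA$aln, file.path(out, "haplotypes_5p_A.fasta"))
utils::write.csv(simA$aln$meta, file.path(out, "haplotypes_meta.csv"),
                 row.names = FALSE, quote = FALSE)
jsonlite::write_json(simA$truth[c("classes", "variable_columns")],
                     file.path(out, "haplotypes_5p_A_truth.json"))
simB <- simulate_haplotypes(seq_sim_config(
  length = 550, n_excl_poly_pop1 = 10, n_excl_poly_pop2 = 2,
  n_shared_poly = 2, gap_columns = 4, seed = seed + 901))
simB$aln$meta$line_id <- simA$aln$meta$line_id
write_fasta_alignment(simB$aln, file.path(out, "haplotypes_5p_B.fasta"))
cat("wrote haplotype alignments with planted site classes\n")

# --- Ct dataset: 67 of 72 replicates, 1-cycle sex effect --------------------
ct_sim <- simulate_ct_data(expr_sim_config(sex_effect = 1, sd_error = 0.3,
                                           seed = seed + 950))
write_ct_table(ct_sim$ct, file.path(out, "ct_data.csv"))
cat("wrote Ct dataset:", ct_sim$truth$n_observations,
    "biological replicates analysed\n")
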