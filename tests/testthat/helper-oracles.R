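# Independent oracles used across the suite. These deliberately re-derive
# every statistic with naive explicit loops over characters/pairs, sharing
# no code with the package implementation.

# build an hsp_aln from bare strings with a half/half arrangement split
make_aln <- function(seqs, n_pop1 = floor(length(seqs) / 2)) {
  ids <- paste0("s", seq_along(seqs))
  names(seqs) <- ids
  n2 <- length(seqs) - n_pop1
  aligned_set(seqs, line_id = ids,
              arrangement = c(rep("OST", n_pop1), rep("O347", n2)))
}

random_alignment <- function(n, L, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, L, replace = TRUE), collapse = ""), character(1))
}

oracle_hamming <- function(s1, s2) {
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  d <- 0L
  for (k in seq_along(c1)) if (c1[k] != c2[k]) d <- d + 1L
  d
}

oracle_dxy <- function(seqs, idx1, idx2) {
  L <- nchar(seqs[[1]])
  tot <- 0
  for (i in idx1) for (j in idx2) tot <- tot + oracle_hamming(seqs[i], seqs[j])
  tot / (length(idx1) * length(idx2) * L)
}

oracle_within <- function(seqs, idx) {
  L <- nchar(seqs[[1]])
  tot <- 0; np <- 0
  for (i in seq_along(idx)) for (j in seq_along(idx)) {
    if (j > i) { tot <- tot + oracle_hamming(seqs[idx[i]], seqs[idx[j]]); np <- np + 1 }
  }
  tot / np / L
}

oracle_fst <- function(seqs, idx1, idx2) {
  hb <- oracle_dxy(seqs, idx1, idx2)
  hw <- (oracle_within(seqs, idx1) + oracle_within(seqs, idx2)) / 2
  1 - hw / hb
}

oracle_snn <- function(seqs, idx1, idx2) {
  idx <- c(idx1, idx2)
  lab <- c(rep(1, length(idx1)), rep(2, length(idx2)))
  xs <- numeric(length(idx))
  for (i in seq_along(idx)) {
    dists <- numeric(0); labs <- numeric(0)
    for (j in seq_along(idx)) {
      if (i == j) next
      dists <- c(dists, oracle_hamming(seqs[idx[i]], seqs[idx[j]]))
      labs <- c(labs, lab[j])
    }
    nn <- labs[dists == min(dists)]
    xs[i] <- sum(nn == lab[i]) / length(nn)
  }
  mean(xs)
}

# exact Snn permutation p over all label assignments (small n only)
oracle_snn_exact_p <- function(seqs, idx1, idx2) {
  idx <- c(idx1, idx2)
  obs <- oracle_snn(seqs, idx1, idx2)
  combos <- utils::combn(length(idx), length(idx1))
  vals <- apply(combos, 2, function(take)
    oracle_snn(seqs, idx[take], idx[-take]))
  mean(vals >= obs - 1e-12)
}

# brute-force HSE finder: enumerate every (start, units) window, validate
# with an explicit pentamer loop, keep left/right-maximal runs, greedy
# non-overlapping from the left
oracle_hse <- function(seq, min_units = 3) {
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  valid <- function(start, units, first) {
    core <- first
    for (u in seq_len(units)) {
      p <- start + 5 * (u - 1)
      if (p + 4 > L) return(FALSE)
      if (paste(chars[(p + 1):(p + 3)], collapse = "") != core) return(FALSE)
      core <- if (core == "GAA") "TTC" else "GAA"
    }
    TRUE
  }
  runs <- NULL
  for (start in seq_len(L)) {
    for (first in c("GAA", "TTC")) {
      units <- 0
      while (valid(start, units + 1, first)) units <- units + 1
      if (units >= min_units) {
        prev <- if (first == "GAA") "TTC" else "GAA"
        left_ext <- start - 5 >= 1 && valid(start - 5, 1, prev)
        if (!left_ext)
          runs <- rbind(runs, data.frame(start = start,
                                         end = start + 5 * units - 1,
                                         unit_count = units))
      }
    }
  }
  if (is.null(runs)) return(data.frame(start = integer(), end = integer(),
                                       unit_count = integer()))
  runs <- unique(runs[order(runs$start, -runs$unit_count), ])
  keep <- NULL; last_end <- 0
  for (r in seq_len(nrow(runs))) {
    if (runs$start[r] > last_end) { keep <- c(keep, r); last_end <- runs$end[r] }
  }
  out <- runs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# closed-form balanced-design sums of squares for the nested model
# (2 arrangements x l lines x 2 sexes x r replicates, complete data)
oracle_balanced_ss <- function(obs, response = "rel_expr") {
  y <- obs[[response]]
  g <- mean(y)
  arr <- obs$arrangement; line <- obs$line_id; sex <- obs$sex
  ss_a <- sum(tapply(y, arr, function(v) length(v) * (mean(v) - g)^2))
  ss_l <- 0
  for (a in unique(arr)) {
    ya <- y[arr == a]; la <- line[arr == a]
    ma <- mean(ya)
    ss_l <- ss_l + sum(tapply(ya, la, function(v) length(v) * (mean(v) - ma)^2))
  }
  ss_s <- sum(tapply(y, sex, function(v) length(v) * (mean(v) - g)^2))
  ss_as <- 0
  for (a in unique(arr)) for (s in unique(sex)) {
    cellv <- y[arr == a & sex == s]
    ss_as <- ss_as + length(cellv) *
      (mean(cellv) - mean(y[arr == a]) - mean(y[sex == s]) + g)^2
  }
  ss_tot <- sum((y - g)^2)
  list(arrangement = ss_a, line = ss_l, sex = ss_s, interaction = ss_as,
       error = ss_tot - ss_a - ss_l - ss_s - ss_as)
}

# default 3'UTR layouts: hsp70A carries two AREs in most lines (one in the
# 1st and 6th cold-climate lines); hsp70B one ARE (two in the 4th
# cold-climate line, whose UTR is longer)
utr_layout <- function(n_are, length = 200L) {
  starts <- c(40L, 120L, 170L)[seq_len(n_are)]
  list(upstream = 0L, downstream = as.integer(length),
       elements = lapply(starts, function(s) list(kind = "ARE", start = s)))
}
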