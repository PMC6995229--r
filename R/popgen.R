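#' Define a two-population split of an alignment
#'
#' @param pop1_ids,pop2_ids disjoint, non-empty id vectors (in the hsp70
#'   study: pop1 = OST lines, pop2 = O347 lines).
#' @return list of class `pop_split`.
#' @export
pop_split <- function(pop1_ids, pop2_ids) {
  if (!length(pop1_ids) || !length(pop2_ids))
    stop("both populations must be non-empty", call. = FALSE)
  if (length(intersect(pop1_ids, pop2_ids)))
    stop("populations must be disjoint", call. = FALSE)
  structure(list(pop1 = as.character(pop1_ids), pop2 = as.character(pop2_ids)),
            class = "pop_split")
}

#' Split an alignment into populations by arrangement metadata
#'
#' @param aln an `hsp_aln` whose metadata carries arrangement labels.
#' @param pop1,pop2 arrangement levels forming the two populations.
#' @return a [pop_split()].
#' @export
split_by_arrangement <- function(aln, pop1 = "OST", pop2 = "O347") {
  pop_split(aln$ids[aln$meta$arrangement == pop1],
            aln$ids[aln$meta$arrangement == pop2])
}

#' Remove gapped columns (complete deletion)
#'
#' Restricts the alignment to `ids` (default: all sequences) and removes
#' every column in which any retained sequence carries a gap (`-`) or an
#' ambiguous base (`N`). Columns gapped only in sequences outside `ids`
#' survive, which maximises analysed sites per comparison; pass all ids for
#' strict whole-alignment deletion.
#'
#' @param aln an `hsp_aln`.
#' @param ids sequences to retain (default all).
#' @return gap-free `hsp_aln` with attribute `analysed_sites`.
#' @export
complete_deletion <- function(aln, ids = aln$ids) {
  sub <- subset_aln(aln, ids)
  m <- aln_matrix(sub)
  keep <- colSums(m == "-" | m == "N") == 0L
  if (!any(keep))
    stop("degenerate alignment: every column contains a gap or N", call. = FALSE)
  out <- aln_from_matrix(m[, keep, drop = FALSE], sub$meta)
  attr(out, "analysed_sites") <- sum(keep)
  out
}

#' Classify alignment columns by within-population variability
#'
#' Each gap-free column falls in exactly one class: `monomorphic` (one
#' allele overall), `fixed_diff` (each population monomorphic for different
#' alleles), `shared` (polymorphic within both populations), `sp1_sf2`
#' (polymorphic in pop1 only) or `sp2_sf1` (polymorphic in pop2 only).
#' Multi-allelic columns are classified by the same
#' polymorphic-in-which-population rule.
#'
#' @param aln gap-free `hsp_aln` (run [complete_deletion()] first).
#' @param split a [pop_split()].
#' @return list of class `site_class_counts` with the five counts,
#'   `analysed_sites`, and `classes` (the per-column class vector).
#' @export
classify_sites <- function(aln, split) {
  m <- aln_matrix(aln)
  if (any(m == "-" | m == "N"))
    stop("alignment contains gaps or N; run complete_deletion() first",
         call. = FALSE)
  m1 <- m[split$pop1, , drop = FALSE]
  m2 <- m[split$pop2, , drop = FALSE]
  classes <- vapply(seq_len(ncol(m)), function(j) {
    a1 <- unique(m1[, j]); a2 <- unique(m2[, j])
    p1 <- length(a1) > 1L; p2 <- length(a2) > 1L
    if (p1 && p2) "shared"
    else if (p1) "sp1_sf2"
    else if (p2) "sp2_sf1"
    else if (a1 == a2) "monomorphic"
    else "fixed_diff"
  }, character(1))
  counts <- list(
    sp1_sf2 = sum(classes == "sp1_sf2"),
    sp2_sf1 = sum(classes == "sp2_sf1"),
    shared = sum(classes == "shared"),
    fixed_diff = sum(classes == "fixed_diff"),
    monomorphic = sum(classes == "monomorphic"),
    analysed_sites = ncol(m),
    classes = classes
  )
  structure(counts, class = "site_class_counts")
}

#' Pairwise Hamming-distance matrix of an alignment
#'
#' @param aln gap-free `hsp_aln`.
#' @return symmetric integer matrix of per-pair differing sites, zero
#'   diagonal, dimnames = sequence ids.
#' @export
pairwise_diff_matrix <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  }
  d
}

#' Average pairwise divergence between populations (Dxy)
#'
#' Mean number of nucleotide substitutions per site between populations:
#' the average Hamming distance over all cross-population sequence pairs,
#' divided by the number of analysed sites.
#'
#' @param aln gap-free `hsp_aln`.
#' @param split a [pop_split()].
#' @return non-negative real (per-site).
#' @export
dxy <- function(aln, split) {
  d <- pairwise_diff_matrix(aln)
  dxy_from_matrix(d, split, aln$length)
}

dxy_from_matrix <- function(d, split, L) {
  if (L == 0L) stop("degenerate alignment: zero analysed sites", call. = FALSE)
  mean(d[split$pop1, split$pop2, drop = FALSE]) / L
}

within_pi <- function(d, ids, L) {
  n <- length(ids)
  if (n < 2L) stop("within-population diversity needs >= 2 sequences",
                   call. = FALSE)
  sub <- d[ids, ids, drop = FALSE]
  sum(sub[upper.tri(sub)]) / (n * (n - 1L) / 2) / L
}

#' Hudson's Fst from mean within- and between-population diversity
#'
#' `Fst = 1 - Hw/Hb`, where `Hb` is [dxy()] and `Hw` is the mean of the two
#' within-population mean pairwise per-site diversities. With equal sample
#' sizes (the study design: 6 vs 6 lines) weighted and unweighted means
#' coincide; set `weighted = TRUE` to weight each population by its number
#' of sequence pairs.
#'
#' @param aln gap-free `hsp_aln`.
#' @param split a [pop_split()] with >= 2 sequences per population.
#' @param weighted weight within-population diversities by pair counts.
#' @return real <= 1 (negative values possible for undifferentiated samples).
#' @export
hudson_fst <- function(aln, split, weighted = FALSE) {
  d <- pairwise_diff_matrix(aln)
  hudson_fst_from_matrix(d, split, aln$length, weighted)
}

hudson_fst_from_matrix <- function(d, split, L, weighted = FALSE) {
  hb <- dxy_from_matrix(d, split, L)
  if (hb == 0)
    stop("Fst undefined: between-population diversity is zero", call. = FALSE)
  h1 <- within_pi(d, split$pop1, L)
  h2 <- within_pi(d, split$pop2, L)
  hw <- if (weighted) {
    w1 <- choose(length(split$pop1), 2); w2 <- choose(length(split$pop2), 2)
    (w1 * h1 + w2 * h2) / (w1 + w2)
  } else (h1 + h2) / 2
  1 - hw / hb
}

#' Hudson's nearest-neighbour statistic (Snn)
#'
#' For each sequence, the fraction of its nearest neighbours (sequences at
#' minimal Hamming distance, excluding itself; all ties included) that
#' belong to its own population; Snn is the mean of these fractions. Values
#' near 1 indicate strong population structure; with no structure the
#' expectation is roughly the own-population share of the sample.
#'
#' @param aln gap-free `hsp_aln`.
#' @param split a [pop_split()]; total sample size >= 3.
#' @return real in `[0, 1]`.
#' @export
snn <- function(aln, split) {
  d <- pairwise_diff_matrix(aln)
  ids <- c(split$pop1, split$pop2)
  snn_from_matrix(d[ids, ids, drop = FALSE],
                  c(rep(1L, length(split$pop1)), rep(2L, length(split$pop2))))
}

snn_from_matrix <- function(d, labels) {
  n <- nrow(d)
  if (n < 3L) stop("Snn needs at least 3 sequences", call. = FALSE)
  x <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    nn <- which(di == min(di))
    own <- labels[-i][nn] == labels[i]
    mean(own)
  }, numeric(1))
  mean(x)
}

#' Permutation test for Snn
#'
#' Population labels are permuted uniformly at random preserving group
#' sizes; `p = (# permuted Snn >= observed + 1) / (n_permutations + 1)`,
#' so the smallest attainable p is `1/(n_permutations+1)`.
#'
#' @inheritParams snn
#' @param n_permutations number of random label permutations (default 1000).
#' @param seed integer seed; the test is reproducible given the seed.
#' @return list with `snn` (observed), `p`, `n_permutations`.
#' @export
snn_permutation_test <- function(aln, split, n_permutations = 1000L,
                                 seed = NULL) {
  if (n_permutations < 1L)
    stop("n_permutations must be >= 1", call. = FALSE)
  d <- pairwise_diff_matrix(aln)
  ids <- c(split$pop1, split$pop2)
  d <- d[ids, ids, drop = FALSE]
  labels <- c(rep(1L, length(split$pop1)), rep(2L, length(split$pop2)))
  obs <- snn_from_matrix(d, labels)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_permutations)) {
    perm <- sample(labels)
    if (snn_from_matrix(d, perm) >= obs - 1e-12) hits <- hits + 1L
  }
  list(snn = obs, p = (hits + 1L) / (n_permutations + 1L),
       n_permutations = as.integer(n_permutations))
}

#' Differentiation table across regulatory regions
#'
#' One row per (region, gene copy): site-class counts, Dxy, Hudson's Fst,
#' and Snn with its permutation P — the per-region summary of
#' between-arrangement differentiation. A concatenated row per region joins
#' each line's A and B sequences end-to-end before gap removal (default
#' `conc_scheme = "concatenate"`; `"pool"` instead analyses A and B
#' sequences side by side as 2n haplotypes per arrangement).
#'
#' @param regions list of entries, each a list with elements `aln` (an
#'   `hsp_aln` whose metadata carries `arrangement` and `gene_copy`),
#'   `region` (e.g. `"five_prime"`), and optionally `copy` (default from
#'   metadata).
#' @param n_permutations permutations for the Snn test per row.
#' @param seed integer seed.
#' @param conc_scheme `"concatenate"` (default), `"pool"`, or `"none"` to
#'   skip the combined row.
#' @param weighted_fst passed to [hudson_fst()].
#' @return data.frame with columns `region`, `copy`, `sp1_sf2`, `sp2_sf1`,
#'   `shared`, `fixed_diff`, `analysed_sites`, `dxy`, `fst`, `snn`, `snn_p`,
#'   `n_permutations`.
#' @export
differentiation_table <- function(regions, n_permutations = 1000L, seed = NULL,
                                  conc_scheme = c("concatenate", "pool", "none"),
                                  weighted_fst = FALSE) {
  conc_scheme <- match.arg(conc_scheme)
  if (!is.null(seed)) set.seed(seed)
  by_region <- split(regions, vapply(regions, `[[`, character(1), "region"))
  rows <- list()
  for (region in names(by_region)) {
    entries <- by_region[[region]]
    for (e in entries) {
      copy <- if (!is.null(e$copy)) e$copy else
        unique(stats::na.omit(e$aln$meta$gene_copy))[1]
      rows[[length(rows) + 1L]] <-
        diff_row(e$aln, region, copy, n_permutations, weighted_fst)
    }
    if (conc_scheme != "none" && length(entries) >= 2L) {
      comb <- combine_copies(lapply(entries, `[[`, "aln"), conc_scheme)
      rows[[length(rows) + 1L]] <-
        diff_row(comb, region, "concatenated", n_permutations, weighted_fst)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

diff_row <- function(aln, region, copy, n_permutations, weighted_fst) {
  clean <- complete_deletion(aln)
  split <- split_by_arrangement(clean)
  cnt <- classify_sites(clean, split)
  d <- pairwise_diff_matrix(clean)
  perm <- snn_permutation_test(clean, split, n_permutations)
  data.frame(
    region = region, copy = copy,
    sp1_sf2 = cnt$sp1_sf2, sp2_sf1 = cnt$sp2_sf1, shared = cnt$shared,
    fixed_diff = cnt$fixed_diff, analysed_sites = cnt$analysed_sites,
    dxy = dxy_from_matrix(d, split, clean$length),
    fst = hudson_fst_from_matrix(d, split, clean$length, weighted_fst),
    snn = perm$snn, snn_p = perm$p, n_permutations = perm$n_permutations,
    stringsAsFactors = FALSE
  )
}

# combine per-copy alignments of one region into a single hsp_aln, either by
# concatenating each line's copies end-to-end or by pooling all sequences
combine_copies <- function(alns, scheme) {
  if (scheme == "pool") {
    ids <- unlist(lapply(alns, function(a)
      paste(a$ids, a$meta$gene_copy, sep = "_")))
    seqs <- unlist(lapply(alns, function(a) unname(a$seq)))
    names(seqs) <- ids
    # pooled sequences must share length; pad is not attempted
    if (length(unique(nchar(seqs))) != 1L)
      stop("pooling requires equal alignment lengths across copies",
           call. = FALSE)
    meta <- do.call(rbind, lapply(alns, `[[`, "meta"))
    return(aligned_set(seqs, line_id = meta$line_id,
                       arrangement = meta$arrangement, gene_copy = NA))
  }
  # concatenate: join by line_id, in the order of the first alignment
  base <- alns[[1L]]
  lines <- base$meta$line_id
  seqs <- character(length(lines)); names(seqs) <- lines
  arr <- base$meta$arrangement
  for (k in seq_along(lines)) {
    parts <- vapply(alns, function(a) {
      hit <- which(a$meta$line_id == lines[k])
      if (length(hit) != 1L)
        stop("concatenation requires exactly one sequence per line per copy; line ",
             lines[k], call. = FALSE)
      unname(a$seq[hit])
    }, character(1))
    seqs[k] <- paste(parts, collapse = "")
  }
  aligned_set(seqs, line_id = lines, arrangement = arr, gene_copy = NA)
}
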