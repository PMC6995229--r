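#' Configuration for synthetic haplotype alignments
#'
#' @param n_pop1,n_pop2 sequences per population (default 6 and 6, the
#'   study's isochromosomal line counts per arrangement).
#' @param length alignment length in bp (default 550, the size of the
#'   proximal 5' region sequenced per line).
#' @param n_fixed_diff,n_excl_poly_pop1,n_excl_poly_pop2,n_shared_poly
#'   planted counts of fixed differences, exclusive polymorphisms and
#'   shared polymorphisms.
#' @param gap_columns number of columns carrying a gap in >= 1 sequence.
#' @param seed integer seed.
#' @return list of class `seq_sim_config`.
#' @export
seq_sim_config <- function(n_pop1 = 6L, n_pop2 = 6L, length = 550L,
                           n_fixed_diff = 0L, n_excl_poly_pop1 = 0L,
                           n_excl_poly_pop2 = 0L, n_shared_poly = 0L,
                           gap_columns = 0L, seed = 1L) {
  cfg <- list(n_pop1 = as.integer(n_pop1), n_pop2 = as.integer(n_pop2),
              length = as.integer(length),
              n_fixed_diff = as.integer(n_fixed_diff),
              n_excl_poly_pop1 = as.integer(n_excl_poly_pop1),
              n_excl_poly_pop2 = as.integer(n_excl_poly_pop2),
              n_shared_poly = as.integer(n_shared_poly),
              gap_columns = as.integer(gap_columns), seed = as.integer(seed))
  n_var <- cfg$n_fixed_diff + cfg$n_excl_poly_pop1 + cfg$n_excl_poly_pop2 +
    cfg$n_shared_poly + cfg$gap_columns
  if (n_var > cfg$length)
    stop("capacity error: planted sites (", n_var, ") exceed length (",
         cfg$length, ")", call. = FALSE)
  if (any(unlist(cfg) < 0)) stop("all counts must be >= 0", call. = FALSE)
  structure(cfg, class = "seq_sim_config")
}

# background base sampler that avoids spontaneous motif cores: the assembled
# string is rejected while it contains a >=3-unit GAA/TTC alternating run,
# GAGAG, CTCTC, ATTTA, or a TATAWAWR match, so planted truth stays unambiguous
background_clean <- function(s) {
  nrow(scan_hse(s, min_units = 3L)) == 0L &&
    !grepl("GAGAG", s, fixed = TRUE) && !grepl("CTCTC", s, fixed = TRUE) &&
    !grepl("ATTTA", s, fixed = TRUE) && !grepl("TATA[AT]A[AT][AG]", s)
}

random_background <- function(length, max_tries = 200L) {
  for (t in seq_len(max_tries)) {
    s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
    if (background_clean(s)) return(s)
  }
  stop("could not draw a motif-free background in ", max_tries, " tries",
       call. = FALSE)
}

other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)

#' Generate a haplotype alignment with planted site classes
#'
#' Builds a two-population alignment whose columns realise exactly the
#' requested numbers of fixed differences, exclusive polymorphisms (minor
#' allele on a random proper subset of one population), shared
#' polymorphisms (segregating in both populations) and gap-bearing columns;
#' all remaining columns are monomorphic. The background sequence is
#' motif-free (see the rejection rule in the generator), so planted-truth
#' comparisons with the site classifier and motif scanners are exact.
#'
#' @param cfg a [seq_sim_config()].
#' @return list with `aln` (an `hsp_aln`; pop1 lines are arrangement `OST`,
#'   pop2 `O347`) and `truth` (planted per-column classes, site indices and
#'   the config).
#' @export
simulate_haplotypes <- function(cfg) {
  stopifnot(inherits(cfg, "seq_sim_config"))
  set.seed(cfg$seed)
  bg <- strsplit(random_background(cfg$length), "", fixed = TRUE)[[1]]
  n1 <- cfg$n_pop1; n2 <- cfg$n_pop2; n <- n1 + n2
  m <- matrix(rep(bg, each = n), nrow = n)

  n_var <- cfg$n_fixed_diff + cfg$n_excl_poly_pop1 + cfg$n_excl_poly_pop2 +
    cfg$n_shared_poly + cfg$gap_columns
  cols <- sample(cfg$length, n_var)
  classes <- rep("monomorphic", cfg$length)
  idx <- 0L
  take <- function(k) { out <- cols[idx + seq_len(k)]; idx <<- idx + k; out }

  pop1 <- seq_len(n1); pop2 <- n1 + seq_len(n2)
  for (j in take(cfg$n_fixed_diff)) {
    m[pop2, j] <- other_base(bg[j]); classes[j] <- "fixed_diff"
  }
  subset_prop <- function(ids) {          # random proper non-empty subset
    k <- sample(length(ids) - 1L, 1L)
    sample(ids, k)
  }
  for (j in take(cfg$n_excl_poly_pop1)) {
    m[subset_prop(pop1), j] <- other_base(bg[j]); classes[j] <- "sp1_sf2"
  }
  for (j in take(cfg$n_excl_poly_pop2)) {
    m[subset_prop(pop2), j] <- other_base(bg[j]); classes[j] <- "sp2_sf1"
  }
  for (j in take(cfg$n_shared_poly)) {
    alt <- other_base(bg[j])
    m[subset_prop(pop1), j] <- alt
    m[subset_prop(pop2), j] <- alt
    classes[j] <- "shared"
  }
  for (j in take(cfg$gap_columns)) {
    m[sample(n, sample(n - 1L, 1L)), j] <- "-"; classes[j] <- "gapped"
  }

  ids <- c(paste0("ST_", seq_len(n1)), paste0("W_", seq_len(n2)))
  rownames(m) <- ids
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- ids
  aln <- aligned_set(seqs,
                     line_id = ids,
                     arrangement = c(rep("OST", n1), rep("O347", n2)),
                     gene_copy = NA)
  truth <- list(classes = classes, variable_columns = sort(cols),
                config = unclass(cfg))
  list(aln = aln, truth = truth)
}

# assemble one HSE of `units` pentamers; flanking n positions random
hse_string <- function(units, start_core = sample(c("GAA", "TTC"), 1L)) {
  core <- start_core
  out <- character(units)
  for (u in seq_len(units)) {
    out[u] <- paste0(sample(c("A", "C", "G", "T"), 1L), core,
                     sample(c("A", "C", "G", "T"), 1L))
    core <- if (core == "GAA") "TTC" else "GAA"
  }
  paste(out, collapse = "")
}

#' Default promoter layout
#'
#' The element layout observed on the hsp70 proximal promoters of all 12
#' isochromosomal lines: four HSEs with 3, 4, 4 and 3 pentamer units from
#' distal to proximal, three GAGA sites (two G+ `GAGAG`, one G- `CTCTC`)
#' and a TATA box, all upstream of the TSS.
#'
#' @param upstream bases upstream of the TSS (default 290).
#' @param downstream bases downstream of the TSS (default 260).
#' @return list usable as `planted_motifs`/layout in [simulate_promoter()].
#' @export
promoter_layout_default <- function(upstream = 290L, downstream = 260L) {
  list(
    upstream = as.integer(upstream), downstream = as.integer(downstream),
    elements = list(
      list(kind = "HSE", start = 21L, unit_count = 3L),
      list(kind = "HSE", start = 61L, unit_count = 4L),
      list(kind = "GAGA_PLUS", start = 105L),
      list(kind = "HSE", start = 131L, unit_count = 4L),
      list(kind = "GAGA_MINUS", start = 171L),
      list(kind = "HSE", start = 201L, unit_count = 3L),
      list(kind = "GAGA_PLUS", start = 231L),
      list(kind = "TATA", start = 256L)
    )
  )
}

#' Generate a promoter sequence with planted regulatory elements
#'
#' Elements are synthesised from their definitions — HSE pentamer cores
#' alternate with random flanking bases, GAGA sites are literal
#' `GAGAG`/`CTCTC`, the TATA box is a consensus instance (`TATAAATA`) — and
#' spliced into a motif-free background at the layout positions. The
#' assembled sequence is re-scanned and resampled until recovery equals the
#' planted truth, so junctions cannot create or destroy elements.
#'
#' @param layout element layout as from [promoter_layout_default()];
#'   positions are 1-based on the full sequence, which has
#'   `upstream + downstream` bases with the TSS at `upstream + 1`.
#' @param seed integer seed.
#' @param max_tries resampling budget for junction-safe assembly.
#' @return list with `sequence`, `tss` (ungapped TSS position) and `truth`
#'   (data.frame of planted annotations: `kind`, `start`, `end`,
#'   `unit_count`).
#' @export
simulate_promoter <- function(layout = promoter_layout_default(), seed = 1L,
                              max_tries = 50L) {
  set.seed(seed)
  L <- layout$upstream + layout$downstream
  for (t in seq_len(max_tries)) {
    chars <- strsplit(random_background(L), "", fixed = TRUE)[[1]]
    truth <- empty_annotation()
    ok <- TRUE
    for (el in layout$elements) {
      s <- switch(el$kind,
                  HSE = hse_string(el$unit_count),
                  GAGA_PLUS = "GAGAG",
                  GAGA_MINUS = "CTCTC",
                  TATA = "TATAAATA",
                  ARE = "ATTTA",
                  stop("unknown element kind: ", el$kind, call. = FALSE))
      end <- el$start + nchar(s) - 1L
      if (end > L) stop("element extends past sequence end", call. = FALSE)
      if (nrow(truth) && any(el$start <= truth$end + 1L & end >= truth$start - 1L)) {
        stop("config error: planted elements overlap or abut", call. = FALSE)
      }
      chars[el$start:end] <- strsplit(s, "", fixed = TRUE)[[1]]
      truth <- rbind(truth, data.frame(
        kind = el$kind, start = el$start, end = end,
        unit_count = if (el$kind == "HSE") el$unit_count else 0L,
        stringsAsFactors = FALSE))
    }
    seq <- paste(chars, collapse = "")
    truth <- truth[order(truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    if (promoter_recovery_ok(seq, truth)) {
      return(list(sequence = seq, tss = layout$upstream + 1L, truth = truth))
    }
  }
  stop("could not assemble a junction-safe promoter in ", max_tries, " tries",
       call. = FALSE)
}

# scanner recovery must equal the planted truth (ARE/GAGA/HSE exact; TATA
# hits allowed only at planted TATA positions)
promoter_recovery_ok <- function(seq, truth) {
  got <- rbind(scan_hse(seq), scan_gaga(seq), scan_are(seq))
  want <- truth[truth$kind %in% c("HSE", "GAGA_PLUS", "GAGA_MINUS", "ARE"), ,
                drop = FALSE]
  # GAGA/ARE truth spans are the literal 5-mers; TATA is 8 bp and checked
  # separately since the consensus can also match at non-planted offsets
  got <- got[order(got$start), c("kind", "start", "end", "unit_count")]
  want <- want[order(want$start), c("kind", "start", "end", "unit_count")]
  rownames(got) <- rownames(want) <- NULL
  if (!identical(got, want)) return(FALSE)
  tata <- scan_tata(seq)
  planted_tata <- truth$start[truth$kind == "TATA"]
  nrow(tata) == length(planted_tata) && all(tata$start %in% planted_tata)
}

#' Configuration for synthetic qPCR Ct datasets
#'
#' Defaults reproduce the study design: 2 arrangements x 6 isochromosomal
#' lines x 2 sexes x 3 biological replicates (72 planned observations) x 3
#' technical replicates, with 5 biological replicates missing at random
#' (67 analysed), and effect/variance values on the Ct cycle scale.
#'
#' @param n_lines_per_arrangement,n_bio_reps,n_tech_reps design sizes.
#' @param grand_mean_dct mean delta-CT in cycles (default 12.5, a typical
#'   basal hsp70-vs-rp49 offset giving rel_expr of order 1e-4, the scale of
#'   the study's mean squares).
#' @param arrangement_effect,sex_effect,interaction_effect effect sizes in
#'   cycles (difference between the two factor levels; default 0). A
#'   positive `sex_effect` lowers female delta-CT by that many cycles
#'   relative to males, i.e. raises female relative expression, the
#'   direction observed in basal hsp70 data; a positive
#'   `arrangement_effect` raises OST delta-CT relative to O347.
#' @param sd_line,sd_error,sd_tech line, residual and technical-replicate
#'   standard deviations in cycles.
#' @param reference_ct_mean,reference_sd reference-gene Ct distribution,
#'   independent of the design factors.
#' @param n_missing biological replicates removed completely at random
#'   (default 5, emulating 67 of 72 analysed samples).
#' @param effect_scale `"dct"` (default: effects and noise on the Ct scale,
#'   making rel_expr log-normal) or `"rel_expr"` (normal, homoscedastic
#'   effects directly on the 2^-dCT scale).
#' @param seed integer seed.
#' @return list of class `expr_sim_config`.
#' @export
expr_sim_config <- function(n_lines_per_arrangement = 6L, n_bio_reps = 3L,
                            n_tech_reps = 3L, grand_mean_dct = 12.5,
                            arrangement_effect = 0, sex_effect = 0,
                            interaction_effect = 0, sd_line = 0.15,
                            sd_error = 0.3, sd_tech = 0.1,
                            reference_ct_mean = 20, reference_sd = 0.5,
                            n_missing = 5L,
                            effect_scale = c("dct", "rel_expr"),
                            seed = 1L) {
  effect_scale <- match.arg(effect_scale)
  cfg <- list(n_lines_per_arrangement = as.integer(n_lines_per_arrangement),
              n_bio_reps = as.integer(n_bio_reps),
              n_tech_reps = as.integer(n_tech_reps),
              grand_mean_dct = grand_mean_dct,
              arrangement_effect = arrangement_effect,
              sex_effect = sex_effect,
              interaction_effect = interaction_effect,
              sd_line = sd_line, sd_error = sd_error, sd_tech = sd_tech,
              reference_ct_mean = reference_ct_mean,
              reference_sd = reference_sd,
              n_missing = as.integer(n_missing),
              effect_scale = effect_scale, seed = as.integer(seed))
  if (any(c(cfg$sd_line, cfg$sd_error, cfg$sd_tech, cfg$reference_sd) < 0))
    stop("standard deviations must be >= 0", call. = FALSE)
  if (cfg$n_lines_per_arrangement < 2L || cfg$n_bio_reps < 1L ||
      cfg$n_tech_reps < 1L)
    stop("design sizes too small", call. = FALSE)
  structure(cfg, class = "expr_sim_config")
}

#' Generate a synthetic qPCR Ct dataset under the nested model
#'
#' Simulates `delta_ct = grand_mean + arrangement + line(arrangement) + sex
#' + arrangement:sex + error` (line effects zero-mean normal), then emits
#' raw technical-replicate Ct rows for both target and reference genes such
#' that the per-replicate expected delta-CT equals the simulated value.
#' Effects are halved into +/- deviations so `*_effect` is the difference
#' between the two levels of each factor.
#'
#' @param cfg an [expr_sim_config()].
#' @return list with `ct` (raw Ct data.frame, schema of [read_ct_table()])
#'   and `truth` (realised line effects, per-replicate true delta-CT,
#'   dropped replicates, the config).
#' @export
simulate_ct_data <- function(cfg) {
  stopifnot(inherits(cfg, "expr_sim_config"))
  set.seed(cfg$seed)
  arr <- c("OST", "O347")
  nl <- cfg$n_lines_per_arrangement
  lines <- data.frame(
    arrangement = rep(arr, each = nl),
    line_id = c(paste0("ST", seq_len(nl)), paste0("W", seq_len(nl))),
    line_effect = stats::rnorm(2L * nl, 0, cfg$sd_line),
    stringsAsFactors = FALSE
  )
  design <- expand.grid(bio_rep = seq_len(cfg$n_bio_reps), sex = c("F", "M"),
                        line_id = lines$line_id, stringsAsFactors = FALSE)
  design <- merge(design, lines, by = "line_id", sort = FALSE)
  a_sign <- ifelse(design$arrangement == "OST", +0.5, -0.5)
  s_sign <- ifelse(design$sex == "F", -0.5, +0.5)

  if (cfg$effect_scale == "dct") {
    design$true_dct <- cfg$grand_mean_dct +
      a_sign * cfg$arrangement_effect + design$line_effect +
      s_sign * cfg$sex_effect + (2 * a_sign) * (2 * s_sign) *
      cfg$interaction_effect / 2 +
      stats::rnorm(nrow(design), 0, cfg$sd_error)
  } else {
    base_rel <- 2^(-cfg$grand_mean_dct)
    rel <- base_rel * (1 +
      a_sign * cfg$arrangement_effect + design$line_effect +
      s_sign * cfg$sex_effect + (2 * a_sign) * (2 * s_sign) *
      cfg$interaction_effect / 2 +
      stats::rnorm(nrow(design), 0, cfg$sd_error))
    if (any(rel <= 0))
      stop("rel_expr-scale simulation produced non-positive expression; ",
           "reduce effects or sd_error", call. = FALSE)
    design$true_dct <- -log2(rel)
  }

  dropped <- integer(0)
  if (cfg$n_missing > 0L) {
    if (cfg$n_missing >= nrow(design))
      stop("n_missing leaves no observations", call. = FALSE)
    dropped <- sort(sample(nrow(design), cfg$n_missing))
  }
  kept <- setdiff(seq_len(nrow(design)), dropped)

  empty_cells <- with(design[kept, ],
                      sum(table(line_id, sex) == 0L))
  rows <- vector("list", length(kept))
  for (k in seq_along(kept)) {
    r <- design[kept[k], ]
    ref_base <- stats::rnorm(1L, cfg$reference_ct_mean, cfg$reference_sd)
    tech <- seq_len(cfg$n_tech_reps)
    rows[[k]] <- rbind(
      data.frame(line = r$line_id, arrangement = r$arrangement, sex = r$sex,
                 bio_rep = r$bio_rep, tech_rep = tech, gene = "target",
                 ct = ref_base + r$true_dct +
                   stats::rnorm(cfg$n_tech_reps, 0, cfg$sd_tech)),
      data.frame(line = r$line_id, arrangement = r$arrangement, sex = r$sex,
                 bio_rep = r$bio_rep, tech_rep = tech, gene = "reference",
                 ct = ref_base + stats::rnorm(cfg$n_tech_reps, 0, cfg$sd_tech))
    )
  }
  ct <- do.call(rbind, rows)
  names(ct)[names(ct) == "line"] <- "line_id"
  ct$gene <- as.character(ct$gene)
  truth <- list(lines = lines, design = design, dropped_rows = dropped,
                n_observations = length(kept),
                empty_cell_warning = empty_cells > 0L,
                config = unclass(cfg))
  list(ct = ct[, c("line_id", "arrangement", "sex", "bio_rep", "tech_rep",
                   "gene", "ct")],
       truth = truth)
}
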