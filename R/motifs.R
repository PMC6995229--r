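#' Scan a sequence for heat-shock elements (HSEs)
#'
#' An HSE is a run of at least `min_units` contiguous 5-bp units whose core
#' triplet (positions 2-4 of each pentamer) alternates between `GAA` and
#' `TTC` — the binding footprint of one heat-shock factor monomer per unit.
#' Positions 1 and 5 of each pentamer are unconstrained (`nGAAn`/`nTTCn`);
#' either core may start the run. Reported runs are maximal (not extendable
#' by another valid unit on either side) and non-overlapping (greedy from
#' the left).
#'
#' @param sequence ungapped DNA string (`A C G T N`; `N` never matches a core).
#' @param min_units minimum number of pentamer units per element (default 3).
#' @param max_core_mismatch total mismatches tolerated in the cores of one
#'   run (default 0, i.e. exact alternation). Exploratory use only.
#' @return data.frame of annotations with columns `kind`, `start`, `end`
#'   (1-based inclusive), `unit_count`, sorted by `start`. Zero rows if no
#'   element is found.
#' @examples
#' scan_hse("cGAAtcTTCgaGAAc")   # one element of 3 units
#' @export
scan_hse <- function(sequence, min_units = 3L, max_core_mismatch = 0L) {
  seq <- check_ungapped(sequence)
  if (min_units < 2L) stop("min_units must be >= 2", call. = FALSE)
  L <- nchar(seq)
  if (L < 5L * min_units) return(empty_annotation())
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]

  core_mm <- function(pos, core) {   # mismatches of chars[pos+1..pos+3] vs core
    sum(chars[pos + 1:3] != strsplit(core, "")[[1]])
  }
  # run length (and mismatch use) starting at p with first core `first`
  run_from <- function(p, first) {
    units <- 0L; mm_used <- 0L
    core <- first
    q <- p
    while (q + 4L <= L) {
      mm <- core_mm(q, core)
      if (mm_used + mm > max_core_mismatch) break
      mm_used <- mm_used + mm
      units <- units + 1L
      q <- q + 5L
      core <- if (core == "GAA") "TTC" else "GAA"
    }
    units
  }
  extendable_left <- function(p, first) {
    if (p - 5L < 1L) return(FALSE)
    prev_core <- if (first == "GAA") "TTC" else "GAA"
    max_core_mismatch == 0L && core_mm(p - 5L, prev_core) == 0L
  }

  hits <- empty_annotation()
  last_end <- 0L
  p <- 1L
  while (p + 5L * min_units - 1L <= L + 0L) {
    if (p <= last_end) { p <- p + 1L; next }
    best_units <- 0L; best_first <- NULL
    for (first in c("GAA", "TTC")) {
      u <- run_from(p, first)
      if (u >= min_units && !extendable_left(p, first) && u > best_units) {
        best_units <- u; best_first <- first
      }
    }
    if (best_units > 0L) {
      end <- p + 5L * best_units - 1L
      hits <- rbind(hits, data.frame(
        kind = "HSE", start = p, end = end, unit_count = best_units,
        stringsAsFactors = FALSE))
      last_end <- end
      p <- end + 1L
    } else {
      p <- p + 1L
    }
  }
  hits
}

empty_annotation <- function() {
  data.frame(kind = character(), start = integer(), end = integer(),
             unit_count = integer(), stringsAsFactors = FALSE)
}

check_ungapped <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- gsub("U", "T", toupper(sequence))
  if (grepl("-", seq, fixed = TRUE))
    stop("sequence contains gap characters; de-gap before scanning", call. = FALSE)
  if (grepl("[^ACGTN]", seq))
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  seq
}

#' Scan for a fixed motif (all occurrences, overlaps included)
#'
#' @param sequence ungapped DNA string.
#' @param motif literal motif (length >= 4), e.g. `"GAGAG"` or `"ATTTA"`.
#' @param kind annotation label to attach to each hit.
#' @return annotation data.frame (`kind`, `start`, `end` 1-based inclusive,
#'   `unit_count = 0`), sorted by start; overlapping hits all reported.
#' @export
scan_fixed_motif <- function(sequence, motif, kind = motif) {
  seq <- check_ungapped(sequence)
  motif <- toupper(motif)
  if (nchar(motif) < 4L) stop("motif length must be >= 4", call. = FALSE)
  k <- nchar(motif)
  L <- nchar(seq)
  if (L < k) return(empty_annotation())
  starts <- which(vapply(seq_len(L - k + 1L),
                         function(p) substr(seq, p, p + k - 1L) == motif,
                         logical(1)))
  if (!length(starts)) return(empty_annotation())
  data.frame(kind = kind, start = starts, end = starts + k - 1L,
             unit_count = 0L, stringsAsFactors = FALSE)
}

#' Scan for GAGA-factor binding sites
#'
#' Reports `GAGAG` occurrences as `GAGA_PLUS` (sense, G+) and `CTCTC` as
#' `GAGA_MINUS` (antisense, G-).
#'
#' @inheritParams scan_fixed_motif
#' @return annotation data.frame sorted by start.
#' @export
scan_gaga <- function(sequence) {
  out <- rbind(scan_fixed_motif(sequence, "GAGAG", "GAGA_PLUS"),
               scan_fixed_motif(sequence, "CTCTC", "GAGA_MINUS"))
  out[order(out$start), , drop = FALSE]
}

#' Scan for AU-rich elements (AREs)
#'
#' A single `AUUUA` pentamer, scanned on the DNA sense strand as `ATTTA`
#' (inputs are genomic, not mRNA). Overlapping pentamers are all reported.
#'
#' @inheritParams scan_fixed_motif
#' @return annotation data.frame sorted by start.
#' @export
scan_are <- function(sequence) {
  scan_fixed_motif(sequence, "ATTTA", "ARE")
}

#' Scan for TATA boxes
#'
#' Matches the consensus `TATAWAWR` (IUPAC: W = A/T, R = A/G). Used only
#' to annotate promoter diagrams, not for promoter-activity prediction.
#'
#' @inheritParams scan_fixed_motif
#' @return annotation data.frame sorted by start.
#' @export
scan_tata <- function(sequence) {
  seq <- check_ungapped(sequence)
  m <- gregexpr("(?=(TATA[AT]A[AT][AG]))", seq, perl = TRUE)[[1]]
  if (m[1L] == -1L) return(empty_annotation())
  starts <- as.integer(m)
  data.frame(kind = "TATA", start = starts, end = starts + 7L,
             unit_count = 0L, stringsAsFactors = FALSE)
}

#' Annotate every sequence of an alignment with regulatory elements
#'
#' Each sequence is de-gapped and scanned with all element scanners (HSE,
#' GAGA, TATA, ARE). Coordinates are reported on the ungapped sequence
#' (1-based inclusive) and relative to the transcription start site, where
#' +1 is the TSS, -1 the base immediately upstream, and position 0 does not
#' exist.
#'
#' @param aln an `hsp_aln` alignment.
#' @param tss_column 1-based alignment column of the TSS (must not be a gap
#'   column for a sequence to receive TSS-relative coordinates).
#' @param scanners character subset of `c("HSE","GAGA","TATA","ARE")`.
#' @return data.frame with one row per annotation per sequence: `id`,
#'   `kind`, `start`, `end`, `unit_count`, `tss_relative_start`.
#' @export
annotate_region <- function(aln, tss_column,
                            scanners = c("HSE", "GAGA", "TATA", "ARE")) {
  stopifnot(inherits(aln, "hsp_aln"))
  if (tss_column < 1L || tss_column > aln$length)
    stop("tss_column outside alignment (1..", aln$length, ")", call. = FALSE)
  out <- list()
  for (id in aln$ids) {
    s <- aln$seq[[id]]
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    keep <- chars != "-"
    ungapped <- paste(chars[keep], collapse = "")
    # ungapped position of the TSS alignment column (next non-gap if gapped)
    tss_u <- sum(keep[seq_len(tss_column)])
    if (!keep[tss_column]) tss_u <- tss_u + 1L
    ann <- empty_annotation()
    if ("HSE" %in% scanners) ann <- rbind(ann, scan_hse(ungapped))
    if ("GAGA" %in% scanners) ann <- rbind(ann, scan_gaga(ungapped))
    if ("TATA" %in% scanners) ann <- rbind(ann, scan_tata(ungapped))
    if ("ARE" %in% scanners) ann <- rbind(ann, scan_are(ungapped))
    if (nrow(ann)) {
      ann <- ann[order(ann$start), , drop = FALSE]
      ann$id <- id
      ann$tss_relative_start <- tss_relative(ann$start, tss_u)
      out[[id]] <- ann[, c("id", "kind", "start", "end", "unit_count",
                           "tss_relative_start")]
    }
  }
  if (!length(out))
    return(data.frame(id = character(), kind = character(), start = integer(),
                      end = integer(), unit_count = integer(),
                      tss_relative_start = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map ungapped positions to TSS-relative coordinates (and back)
#'
#' TSS-relative coordinates skip 0: the TSS is +1 and the base upstream is
#' -1. The mapping is a bijection on positive positions.
#'
#' @param pos ungapped 1-based positions.
#' @param tss ungapped 1-based position of the TSS.
#' @return integer vector of TSS-relative coordinates.
#' @export
tss_relative <- function(pos, tss) {
  ifelse(pos >= tss, pos - tss + 1L, pos - tss)
}

#' @rdname tss_relative
#' @param rel TSS-relative coordinates (non-zero integers).
#' @export
tss_absolute <- function(rel, tss) {
  if (any(rel == 0L)) stop("TSS-relative coordinate 0 does not exist", call. = FALSE)
  ifelse(rel > 0L, rel + tss - 1L, rel + tss)
}

#' Write annotations as BED
#'
#' BED uses 0-based half-open coordinates; the package's user-facing tables
#' are 1-based inclusive, so `start` is shifted down by one.
#'
#' @param ann annotation data.frame from [annotate_region()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
annotations_to_bed <- function(ann, path) {
  bed <- data.frame(chrom = ann$id, start = ann$start - 1L, end = ann$end,
                    name = ifelse(ann$unit_count > 0,
                                  paste0(ann$kind, "_u", ann$unit_count),
                                  ann$kind))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse-complement a DNA string
#' @param x DNA string (IUPAC codes allowed).
#' @return reverse complement as a string.
#' @export
revcomp <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(toupper(x), "")[[1]]), collapse = ""))
}

# does primer (exact bases) match template starting at pos? template may
# carry IUPAC degeneracy; a template code matches if its set contains the base
primer_matches_at <- function(tchars, primer_chars, pos) {
  n <- length(primer_chars)
  for (k in seq_len(n)) {
    set <- IUPAC_SETS[[tchars[pos + k - 1L]]]
    if (is.null(set) || !(primer_chars[k] %in% set)) return(FALSE)
  }
  TRUE
}

primer_sites <- function(tchars, primer) {
  pc <- strsplit(toupper(primer), "")[[1]]
  L <- length(tchars); n <- length(pc)
  if (L < n) return(integer())
  which(vapply(seq_len(L - n + 1L),
               function(p) primer_matches_at(tchars, pc, p), logical(1)))
}

#' Predict a PCR amplicon from a primer pair
#'
#' Exact-match in-silico PCR: the forward primer must match the template
#' sense strand, and the reverse complement of the reverse primer must match
#' downstream of it. Degenerate IUPAC codes in the template match any base
#' they encode. The product spans from the first base of the forward site to
#' the last base of the reverse site.
#'
#' @param template DNA string (IUPAC codes allowed).
#' @param fwd_primer,rev_primer primer sequences, written 5'->3'.
#' @return list with `fwd_start`, `rev_end` (1-based inclusive template
#'   coordinates), `length` (bp) and `product_sequence`.
#' @export
in_silico_pcr <- function(template, fwd_primer, rev_primer) {
  tmpl <- gsub("U", "T", toupper(template))
  if (grepl("-", tmpl, fixed = TRUE))
    stop("template contains gap characters", call. = FALSE)
  tchars <- strsplit(tmpl, "")[[1]]
  f_sites <- primer_sites(tchars, fwd_primer)
  r_sites <- primer_sites(tchars, revcomp(rev_primer))
  nf <- nchar(fwd_primer); nr <- nchar(rev_primer)
  prods <- list()
  for (f in f_sites) for (r in r_sites) {
    r_end <- r + nr - 1L
    if (r >= f + nf)           # reverse site strictly downstream of fwd site
      prods[[length(prods) + 1L]] <- c(fwd_start = f, rev_end = r_end)
  }
  if (!length(prods))
    stop("no amplicon: primer pair does not define a product on this template",
         call. = FALSE)
  prods <- unique(do.call(rbind, prods))
  if (nrow(prods) > 1L)
    stop("ambiguous PCR: multiple products of lengths ",
         paste(prods[, "rev_end"] - prods[, "fwd_start"] + 1L, collapse = ", "),
         " bp", call. = FALSE)
  f <- prods[1L, "fwd_start"]; e <- prods[1L, "rev_end"]
  list(fwd_start = unname(f), rev_end = unname(e),
       length = unname(e - f + 1L),
       product_sequence = substr(tmpl, f, e))
}
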