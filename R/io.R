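#' Construct an aligned haplotype set
#'
#' Container for a gap-aware multiple sequence alignment with per-sequence
#' metadata (isochromosomal line, chromosomal arrangement, hsp70 gene copy).
#' Sequences are stored upper-case with RNA `U` normalised to `T`; the
#' allowed alphabet is `A C G T N -`.
#'
#' @param sequences named character vector of aligned sequences (names are
#'   sequence ids, unique and non-empty). All sequences must share one length.
#' @param line_id character vector, one per sequence (recycled if length 1).
#' @param arrangement arrangement labels; normalised to one of
#'   `"OST"`, `"O347"`, `"OTHER"` (see [normalize_arrangement()]).
#' @param gene_copy gene copy labels; normalised to `"A"`, `"B"` or `NA`.
#' @return An object of class `hsp_aln`: a list with elements `ids`,
#'   `seq` (named character), `meta` (data.frame with `id`, `line_id`,
#'   `arrangement`, `gene_copy`) and `length` (alignment columns).
#' @export
aligned_set <- function(sequences, line_id = NA_character_,
                        arrangement = "OTHER", gene_copy = NA_character_) {
  if (length(sequences) < 2L)
    stop("an alignment needs at least 2 sequences", call. = FALSE)
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids))
    stop("every sequence needs a non-empty id", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicated sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- normalize_sequence(sequences)
  lens <- nchar(seqs)
  if (any(lens == 0L)) stop("empty sequence: ", ids[lens == 0L][1L], call. = FALSE)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "),
         call. = FALSE)
  meta <- data.frame(
    id = ids,
    line_id = as.character(rep_len(line_id, length(ids))),
    arrangement = normalize_arrangement(rep_len(arrangement, length(ids))),
    gene_copy = normalize_gene_copy(rep_len(gene_copy, length(ids))),
    stringsAsFactors = FALSE
  )
  structure(
    list(ids = ids, seq = seqs, meta = meta, length = unname(lens[1L])),
    class = "hsp_aln"
  )
}

#' @export
print.hsp_aln <- function(x, ...) {
  cat("<hsp_aln> ", length(x$ids), " sequences x ", x$length, " columns\n", sep = "")
  tab <- table(x$meta$arrangement)
  cat("  arrangements:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.hsp_aln <- function(x) length(x$ids)

# upper-case, U->T, then validate against the alignment alphabet
normalize_sequence <- function(sequences) {
  seqs <- chartr("u", "T", toupper(sequences))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- regexpr("[^ACGTN-]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid character '%s' in sequence '%s' at column %d",
                 substr(seqs[i], bad[i], bad[i]),
                 if (is.null(names(seqs))) as.character(i) else names(seqs)[i],
                 bad[i]), call. = FALSE)
  }
  seqs
}

#' Normalise arrangement labels
#'
#' Maps the spellings found in metadata files (`O_ST`, `ost`, `O3+4+7`,
#' `O_3+4+7`, `o347`, ...) onto the canonical levels `OST` (cold-climate
#' standard), `O347` (warm-climate O3+4+7) and `OTHER`.
#'
#' @param x character vector of labels.
#' @return character vector over `{"OST","O347","OTHER"}`.
#' @export
normalize_arrangement <- function(x) {
  key <- gsub("[^A-Z0-9]", "", toupper(as.character(x)))
  out <- rep("OTHER", length(x))
  out[key %in% c("OST", "ST")] <- "OST"
  out[key %in% c("O347", "347", "O347X")] <- "O347"
  out[is.na(x)] <- "OTHER"
  out
}

normalize_gene_copy <- function(x) {
  key <- toupper(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[key %in% c("A", "HSP70A")] <- "A"
  out[key %in% c("B", "HSP70B")] <- "B"
  out
}

normalize_sex <- function(x) {
  key <- toupper(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[key %in% c("F", "FEMALE", "FEMALES")] <- "F"
  out[key %in% c("M", "MALE", "MALES")] <- "M"
  if (anyNA(out))
    stop("unrecognised sex label: ", paste(unique(x[is.na(out)]), collapse = ", "),
         call. = FALSE)
  out
}

#' Read a FASTA multiple sequence alignment
#'
#' Reads a (wrapped or unwrapped) multi-record FASTA file into an
#' [aligned_set()]. Per-sequence metadata is joined from a sidecar table by
#' id; ids absent from the table fall back to pipe-delimited headers of the
#' form `id|line|arrangement|copy`, and otherwise get `arrangement = "OTHER"`
#' and `gene_copy = NA`.
#'
#' @param path FASTA file path.
#' @param metadata optional data.frame with columns `id`, `line_id`,
#'   `arrangement`, `gene_copy` (or a path to a CSV with those columns).
#' @return An `hsp_aln` object.
#' @export
read_fasta_alignment <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- tryCatch(
    seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE),
    error = function(e) stop("not parseable as FASTA: ", path, " (",
                             conditionMessage(e), ")", call. = FALSE)
  )
  if (length(recs) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- vapply(recs, function(r) as.character(r)[1L], character(1))
  full_ids <- vapply(recs, function(r) attr(r, "name"), character(1))
  names(seqs) <- full_ids

  if (is.character(metadata) && length(metadata) == 1L)
    metadata <- utils::read.csv(metadata, stringsAsFactors = FALSE)

  n <- length(seqs)
  line_id <- rep(NA_character_, n); arr <- rep("OTHER", n); copy <- rep(NA_character_, n)
  ids <- full_ids

  # fallback: header-encoded metadata "id|line|arrangement|copy"
  piped <- grepl("|", full_ids, fixed = TRUE)
  if (any(piped)) {
    parts <- strsplit(full_ids[piped], "|", fixed = TRUE)
    ids[piped] <- vapply(parts, `[`, character(1), 1L)
    line_id[piped] <- vapply(parts, function(p) if (length(p) >= 2) p[2L] else NA_character_, character(1))
    arr[piped] <- vapply(parts, function(p) if (length(p) >= 3) p[3L] else "OTHER", character(1))
    copy[piped] <- vapply(parts, function(p) if (length(p) >= 4) p[4L] else NA_character_, character(1))
  }
  if (!is.null(metadata)) {
    need <- c("id", "line_id", "arrangement", "gene_copy")
    if (!all(need %in% names(metadata)))
      stop("metadata must have columns: ", paste(need, collapse = ", "), call. = FALSE)
    hit <- match(ids, metadata$id)
    got <- !is.na(hit)
    line_id[got] <- as.character(metadata$line_id[hit[got]])
    arr[got] <- as.character(metadata$arrangement[hit[got]])
    copy[got] <- as.character(metadata$gene_copy[hit[got]])
  }
  names(seqs) <- ids
  aligned_set(seqs, line_id = line_id, arrangement = arr, gene_copy = copy)
}

#' Write an alignment back to FASTA
#'
#' Inverse of [read_fasta_alignment()]: sequences and record order round-trip
#' exactly. Metadata is not encoded in headers; write it separately with
#' [utils::write.csv()] if needed.
#'
#' @param aln an `hsp_aln` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "hsp_aln"))
  seqinr::write.fasta(as.list(unname(aln$seq)), names = aln$ids,
                      file.out = path, nbchar = 70)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' Reads a delimited text file of raw quantification-cycle values, one row
#' per technical replicate per gene, and validates it against the expected
#' schema. Required header columns: `line`, `arrangement`, `sex`, `bio_rep`,
#' `tech_rep`, `gene`, `ct`. `sex` is normalised to `F`/`M`; `gene` to
#' `target` (hsp70) / `reference` (rp49).
#'
#' @param path CSV/TSV file path (delimiter sniffed from the header line).
#' @return data.frame of validated Ct records with columns `line_id`,
#'   `arrangement`, `sex`, `bio_rep`, `tech_rep`, `gene`, `ct`.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character")
  need <- c("line", "arrangement", "sex", "bio_rep", "tech_rep", "gene", "ct")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("Ct table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  ct <- suppressWarnings(as.numeric(raw$ct))
  bad <- which(is.na(ct) | !is.finite(ct))
  if (length(bad))
    stop(sprintf("non-numeric or non-finite ct value '%s' at data row %d",
                 raw$ct[bad[1L]], bad[1L]), call. = FALSE)
  if (any(ct <= 0))
    stop("ct values must be positive cycles (row ",
         which(ct <= 0)[1L], ")", call. = FALSE)
  out <- data.frame(
    line_id = as.character(raw$line),
    arrangement = normalize_arrangement(raw$arrangement),
    sex = normalize_sex(raw$sex),
    bio_rep = as.integer(raw$bio_rep),
    tech_rep = as.integer(raw$tech_rep),
    gene = normalize_gene(raw$gene),
    ct = ct,
    stringsAsFactors = FALSE
  )
  if (any(out$bio_rep < 1L) || any(out$tech_rep < 1L) ||
      anyNA(out$bio_rep) || anyNA(out$tech_rep))
    stop("bio_rep and tech_rep must be integers >= 1", call. = FALSE)
  out
}

normalize_gene <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[key %in% c("target", "hsp70")] <- "target"
  out[key %in% c("reference", "rp49", "ref")] <- "reference"
  if (anyNA(out))
    stop("unrecognised gene label: ", paste(unique(x[is.na(out)]), collapse = ", "),
         call. = FALSE)
  out
}

#' Write a Ct table
#'
#' @param ct data.frame in the schema returned by [read_ct_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path) {
  out <- data.frame(line = ct$line_id, arrangement = ct$arrangement,
                    sex = ct$sex, bio_rep = ct$bio_rep, tech_rep = ct$tech_rep,
                    gene = ct$gene, ct = ct$ct)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# restrict an hsp_aln to a subset of ids, preserving order of `ids`
subset_aln <- function(aln, ids) {
  stopifnot(inherits(aln, "hsp_aln"))
  miss <- setdiff(ids, aln$ids)
  if (length(miss)) stop("ids not in alignment: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  hit <- match(ids, aln$ids)
  structure(
    list(ids = aln$ids[hit], seq = aln$seq[hit],
         meta = aln$meta[hit, , drop = FALSE], length = aln$length),
    class = "hsp_aln"
  )
}

# alignment as an n x L character matrix (rownames = ids)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

# rebuild an hsp_aln from a character matrix plus existing metadata
aln_from_matrix <- function(m, meta) {
  if (ncol(m) == 0L)
    stop("degenerate alignment: no columns survive gap removal", call. = FALSE)
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- rownames(m)
  structure(
    list(ids = rownames(m), seq = seqs, meta = meta, length = ncol(m)),
    class = "hsp_aln"
  )
}
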