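#' Run the full regulatory-region and expression analysis
#'
#' Orchestrates annotate -> differentiate -> ANOVA from one configuration
#' and writes the consolidated outputs: a per-sequence element annotation
#' table and BED file, a differentiation table (one row per region x gene
#' copy plus a combined row), the nested ANOVA table with parametric and
#' permutation P values, a reference-gene homogeneity summary, and a run
#' manifest recording seeds and parameters.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{alignments}{list of entries, each with `fasta`, `region`
#'       (`"five_prime"`/`"three_prime"`), optional `copy`, `tss_column`,
#'       and optional `metadata` CSV path.}
#'     \item{ct_table}{path to the raw Ct CSV.}
#'     \item{popgen_permutations}{Snn permutations (default 1000).}
#'     \item{anova_permutations}{ANOVA permutations per stage (default 9999).}
#'     \item{seed}{integer seed (default 1).}
#'     \item{out_dir}{output directory.}
#'   }
#' @return invisibly, a list with the computed tables and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop("config needs out_dir", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  n_pop_perm <- as.integer(config$popgen_permutations %||% 1000L)
  n_anova_perm <- as.integer(config$anova_permutations %||% 9999L)
  failed_marker <- file.path(out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)),
                 failed_marker)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  result <- list()

  if (!is.null(config$alignments)) {
    alns <- stage("read_alignments", lapply(config$alignments, function(a) {
      list(aln = read_fasta_alignment(a$fasta, a$metadata),
           region = a$region, copy = a$copy, tss_column = a$tss_column)
    }))
    ann <- stage("annotate", {
      tabs <- lapply(alns, function(a) {
        if (is.null(a$tss_column)) return(NULL)
        t <- annotate_region(a$aln, a$tss_column)
        if (nrow(t)) { t$region <- a$region; t$copy <- a$copy %||% NA }
        t
      })
      do.call(rbind, tabs[!vapply(tabs, is.null, logical(1))])
    })
    if (!is.null(ann) && nrow(ann)) {
      utils::write.table(ann, file.path(out_dir, "annotations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      annotations_to_bed(ann, file.path(out_dir, "annotations.bed"))
      result$annotations <- ann
    }
    diff_tab <- stage("differentiation", differentiation_table(
      lapply(alns, function(a) list(aln = a$aln, region = a$region,
                                    copy = a$copy)),
      n_permutations = n_pop_perm, seed = seed))
    utils::write.table(diff_tab, file.path(out_dir, "differentiation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(diff_tab, file.path(out_dir, "differentiation.json"),
                         auto_unbox = TRUE, digits = NA)
    result$differentiation <- diff_tab
  }

  if (!is.null(config$ct_table)) {
    ct <- stage("read_ct", read_ct_table(config$ct_table))
    obs <- stage("aggregate_ct", aggregate_ct(ct))
    anova_tab <- stage("anova", permutation_anova(
      obs, n_permutations = n_anova_perm, seed = seed))
    utils::write.table(as.data.frame(anova_tab),
                       file.path(out_dir, "anova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    refchk <- stage("reference_gene_check", reference_gene_check(ct))
    jsonlite::write_json(refchk, file.path(out_dir, "reference_gene.json"),
                         auto_unbox = TRUE, digits = NA)
    result$anova <- anova_tab
    result$reference_gene <- refchk
    result$observations <- obs
  }

  manifest <- list(
    seed = seed, popgen_permutations = n_pop_perm,
    anova_permutations = n_anova_perm,
    package_version = as.character(utils::packageVersion("hspreg")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  result$manifest <- manifest
  result$out_dir <- out_dir
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
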