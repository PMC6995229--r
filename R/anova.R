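#' Aggregate technical replicates and transform to relative expression
#'
#' For each biological replicate (line x sex x bio_rep), technical
#' replicates are averaged per gene, `delta_ct = mean(target Ct) -
#' mean(reference Ct)`, and relative expression follows the comparative CT
#' method, `rel_expr = 2^(-delta_ct)`.
#'
#' @param records Ct data.frame in the schema of [read_ct_table()].
#' @return data.frame of observations: `line_id`, `arrangement`, `sex`,
#'   `bio_rep`, `delta_ct`, `rel_expr`; one row per biological replicate.
#' @export
aggregate_ct <- function(records) {
  key <- interaction(records$line_id, records$sex, records$bio_rep,
                     drop = TRUE, sep = "/")
  out <- lapply(split(records, key), function(g) {
    tc <- g$ct[g$gene == "target"]
    rc <- g$ct[g$gene == "reference"]
    if (!length(tc) || !length(rc))
      stop("unpaired biological replicate (missing ",
           if (length(tc)) "reference" else "target", " gene): line ",
           g$line_id[1L], ", sex ", g$sex[1L], ", bio_rep ", g$bio_rep[1L],
           call. = FALSE)
    dct <- mean(tc) - mean(rc)
    data.frame(line_id = g$line_id[1L], arrangement = g$arrangement[1L],
               sex = g$sex[1L], bio_rep = g$bio_rep[1L],
               delta_ct = dct, rel_expr = 2^(-dct), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$arrangement, out$line_id, out$sex, out$bio_rep), ]
  rownames(out) <- NULL
  out
}

# ---- model-matrix machinery -------------------------------------------------
#
# Model: y = mu + A_i + L_j(i) + S_k + AS_ik + e, with A and S fixed (2 levels
# each), L random and nested within A. Sum-to-zero contrasts throughout; sums
# of squares are Type III (RSS of the model without the term minus RSS of the
# full model), which reduces to the sequential decomposition when the design
# is balanced. F denominators: arrangement over the line MS; line, sex and
# interaction over the error MS.

# sum-to-zero contrast columns for the lines of one arrangement
nested_line_columns <- function(line_f, arr_f) {
  cols <- NULL
  for (a in levels(arr_f)) {
    lines_a <- sort(unique(as.character(line_f[arr_f == a])))
    if (length(lines_a) < 2L)
      stop("design error: fewer than 2 lines in arrangement ", a, call. = FALSE)
    for (l in lines_a[-length(lines_a)]) {
      v <- numeric(length(line_f))
      v[arr_f == a & line_f == l] <- 1
      v[arr_f == a & line_f == lines_a[length(lines_a)]] <- -1
      cols <- cbind(cols, v)
    }
  }
  cols
}

# build the design pieces once; arrangement/sex coded +/-1 (contr.sum)
build_design <- function(obs) {
  arr_f <- factor(obs$arrangement)
  sex_f <- factor(obs$sex)
  line_f <- factor(obs$line_id)
  if (nlevels(arr_f) != 2L) stop("design error: need exactly 2 arrangements",
                                 call. = FALSE)
  if (nlevels(sex_f) != 2L) stop("design error: need exactly 2 sexes",
                                 call. = FALSE)
  a <- ifelse(arr_f == levels(arr_f)[1L], 1, -1)
  s <- ifelse(sex_f == levels(sex_f)[1L], 1, -1)
  Lcols <- nested_line_columns(line_f, arr_f)
  list(
    n = nrow(obs), a = a, s = s, Lcols = Lcols,
    arr_f = arr_f, sex_f = sex_f, line_f = line_f,
    df = c(arrangement = 1L,
           line = ncol(Lcols),
           sex = 1L,
           interaction = 1L)
  )
}

design_matrix <- function(d, drop = NULL) {
  blocks <- list(intercept = matrix(1, d$n, 1L),
                 arrangement = matrix(d$a, ncol = 1L),
                 line = d$Lcols,
                 sex = matrix(d$s, ncol = 1L),
                 interaction = matrix(d$a * d$s, ncol = 1L))
  if (!is.null(drop)) blocks[[drop]] <- NULL
  do.call(cbind, blocks)
}

rss_of <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

# orthonormal basis of the column space (for fast batched projections)
ortho_basis <- function(X) {
  q <- qr(X)
  qr.Q(q)[, seq_len(q$rank), drop = FALSE]
}

#' Fit the nested arrangement/line/sex ANOVA
#'
#' Least-squares decomposition for the model
#' `y = mu + arrangement + line(arrangement) + sex + arrangement:sex + error`
#' with sum-to-zero contrasts and Type III sums of squares (robust to the
#' unbalanced designs that arise when biological replicates are lost).
#' Because line is a random effect nested in arrangement, the arrangement F
#' uses the line mean square as its denominator; line, sex and the
#' interaction are tested over the error mean square.
#'
#' @param obs observation data.frame from [aggregate_ct()] (or a synthetic
#'   equivalent) with columns `line_id`, `arrangement`, `sex` and the
#'   response.
#' @param response which response to analyse: relative expression
#'   (`"rel_expr"`, the comparative-CT transform, default) or `"delta_ct"`.
#' @return object of class `hsp_anova`: a data.frame with one row per term
#'   (`arrangement`, `line`, `sex`, `interaction`, `error`) and columns
#'   `df`, `ss`, `ms`, `f`, `p_parametric`, plus attributes used by
#'   [permutation_anova()].
#' @export
fit_nested_anova <- function(obs, response = c("rel_expr", "delta_ct")) {
  response <- match.arg(response)
  y <- obs[[response]]
  if (stats::var(y) == 0)
    stop("degenerate data: response has zero variance", call. = FALSE)
  d <- build_design(obs)
  X_full <- design_matrix(d)
  rss_full <- rss_of(X_full, y)
  df_error <- d$n - qr(X_full)$rank
  if (df_error < 1L) stop("design error: no residual degrees of freedom",
                          call. = FALSE)
  ms_error <- rss_full / df_error
  if (ms_error <= .Machine$double.eps * mean(y)^2)
    stop("degenerate data: zero error mean square", call. = FALSE)

  terms <- c("arrangement", "line", "sex", "interaction")
  ss <- vapply(terms, function(tm) rss_of(design_matrix(d, drop = tm), y) - rss_full,
               numeric(1))
  df <- d$df[terms]
  ms <- ss / df
  denom_ms <- c(arrangement = unname(ms["line"]), line = ms_error,
                sex = ms_error, interaction = ms_error)
  denom_df <- c(arrangement = unname(df["line"]), line = df_error,
                sex = df_error, interaction = df_error)
  f <- ms / denom_ms
  p <- stats::pf(f, df, denom_df, lower.tail = FALSE)

  tab <- data.frame(
    term = c(terms, "error"),
    df = c(unname(df), df_error),
    ss = c(unname(ss), rss_full),
    ms = c(unname(ms), ms_error),
    f = c(unname(f), NA_real_),
    p_parametric = c(unname(p), NA_real_),
    stringsAsFactors = FALSE
  )
  structure(tab, class = c("hsp_anova", "data.frame"),
            design = d, response = response, y = y)
}

#' @export
print.hsp_anova <- function(x, ...) {
  cat("Nested ANOVA (Type III, sum-to-zero contrasts); response:",
      attr(x, "response"), "\n")
  print.data.frame(format(as.data.frame(x), digits = 4), row.names = FALSE)
  invisible(x)
}

# ---- four-stage restricted permutation test ---------------------------------

# derive one sub-seed per stage so each stage is independently reproducible
stage_seeds <- function(seed) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, 4L)
}

perm_pvalue <- function(perm_f, obs_f, n) {
  (sum(perm_f >= obs_f - 1e-12) + 1L) / (n + 1L)
}

# batched Type III SS for a term with a FIXED design: columns of Y are
# permuted responses; returns the permuted F values for that term
batched_term_f <- function(Q_full, Q_red, Y, df_term, n, rank_full,
                           denom = c("error", "line"), Q_red_line = NULL,
                           df_line = NULL) {
  denom <- match.arg(denom)
  yy <- colSums(Y^2)
  fit_full <- colSums((crossprod(Q_full, Y))^2)
  rss_full <- yy - fit_full
  ss_term <- (yy - colSums((crossprod(Q_red, Y))^2)) - rss_full
  ms_term <- ss_term / df_term
  if (denom == "error") {
    ms_den <- rss_full / (n - rank_full)
  } else {
    ss_line <- (yy - colSums((crossprod(Q_red_line, Y))^2)) - rss_full
    ms_den <- ss_line / df_line
  }
  ms_term / ms_den
}

#' Four-stage restricted permutation test for the nested ANOVA
#'
#' Each term's F statistic is recalibrated under a permutation scheme that
#' respects the model structure: (1) line — observations shuffled among
#' lines within each arrangement; (2) arrangement — whole lines, with all
#' their observations, reassigned to arrangements preserving group sizes;
#' (3) sex — sex labels shuffled within each line; (4) interaction —
#' observations shuffled across the four arrangement x sex cells. For each
#' term, `p = (# permuted F >= observed F + 1) / (n_permutations + 1)`, so
#' the observed allocation counts as one of the `n_permutations + 1` values.
#'
#' @inheritParams fit_nested_anova
#' @param n_permutations random allocations per stage (default 9999, giving
#'   10000 F values per term including the observed one).
#' @param seed integer seed; one sub-seed is drawn per stage so stages are
#'   independently reproducible.
#' @param sex_scheme `"within_line"` (default; preserves the nuisance line
#'   structure) or `"global"` sex-label exchange.
#' @param interaction_scheme `"cells"` (default; free shuffling across the
#'   four arrangement x sex cells) or `"freedman_lane"` (permutation of
#'   residuals from the additive model).
#' @return the `hsp_anova` table with an extra column `p_permutation`.
#' @export
permutation_anova <- function(obs, n_permutations = 9999L, seed = NULL,
                              response = c("rel_expr", "delta_ct"),
                              sex_scheme = c("within_line", "global"),
                              interaction_scheme = c("cells", "freedman_lane")) {
  response <- match.arg(response)
  sex_scheme <- match.arg(sex_scheme)
  interaction_scheme <- match.arg(interaction_scheme)
  if (n_permutations < 1L) stop("n_permutations must be >= 1", call. = FALSE)
  fit <- fit_nested_anova(obs, response)
  d <- attr(fit, "design")
  y <- attr(fit, "y")
  n <- d$n
  B <- as.integer(n_permutations)
  seeds <- if (is.null(seed)) sample.int(.Machine$integer.max - 1L, 4L) else
    stage_seeds(seed)
  obs_f <- stats::setNames(fit$f[match(c("arrangement", "line", "sex",
                                         "interaction"), fit$term)],
                           c("arrangement", "line", "sex", "interaction"))

  X_full <- design_matrix(d)
  rank_full <- qr(X_full)$rank
  Q_full <- ortho_basis(X_full)
  Q_no_line <- ortho_basis(design_matrix(d, drop = "line"))
  Q_no_sex <- ortho_basis(design_matrix(d, drop = "sex"))
  Q_no_int <- ortho_basis(design_matrix(d, drop = "interaction"))

  # -- stage 1: line term; permute y among observations within arrangement --
  set.seed(seeds[1L])
  Y <- replicate(B, {
    yp <- y
    for (a in levels(d$arr_f)) {
      idx <- which(d$arr_f == a)
      yp[idx] <- y[sample(idx)]
    }
    yp
  })
  f_line <- batched_term_f(Q_full, Q_no_line, Y, d$df[["line"]], n, rank_full)
  p_line <- perm_pvalue(f_line, obs_f[["line"]], B)

  # -- stage 3: sex term; exchange sex labels (= permute y) within line ------
  set.seed(seeds[3L])
  Y <- replicate(B, {
    yp <- y
    if (sex_scheme == "within_line") {
      for (l in levels(d$line_f)) {
        idx <- which(d$line_f == l)
        yp[idx] <- y[sample(idx)]
      }
    } else yp <- y[sample(n)]
    yp
  })
  f_sex <- batched_term_f(Q_full, Q_no_sex, Y, d$df[["sex"]], n, rank_full)
  p_sex <- perm_pvalue(f_sex, obs_f[["sex"]], B)

  # -- stage 4: interaction; shuffle across the 4 arrangement x sex cells ----
  set.seed(seeds[4L])
  if (interaction_scheme == "cells") {
    Y <- replicate(B, y[sample(n)])
  } else {
    # Freedman-Lane: permute residuals of the model without the interaction
    X_add <- design_matrix(d, drop = "interaction")
    fit_add <- stats::lm.fit(X_add, y)
    Y <- replicate(B, fit_add$fitted.values + fit_add$residuals[sample(n)])
  }
  f_int <- batched_term_f(Q_full, Q_no_int, Y, d$df[["interaction"]], n,
                          rank_full)
  p_int <- perm_pvalue(f_int, obs_f[["interaction"]], B)

  # -- stage 2: arrangement; reassign whole lines to arrangements ------------
  # all design columns are constant within line x sex cells, so weighted
  # least squares on cell means gives identical SS differences at a fraction
  # of the cost; repeated assignments (there are only choose(n_lines, n1)
  # distinct ones) are cached
  set.seed(seeds[2L])
  cell <- interaction(d$line_f, d$sex_f, drop = TRUE)
  n_c <- as.vector(table(cell))
  ybar_c <- as.vector(tapply(y, cell, mean))
  w <- sqrt(n_c)
  yw <- w * ybar_c
  cell_line <- factor(vapply(split(as.character(d$line_f), cell), `[`,
                             character(1), 1L), levels = levels(d$line_f))
  cell_s <- vapply(split(d$s, cell), `[`, numeric(1), 1L)
  lines <- levels(d$line_f)
  arr_of_line <- vapply(lines, function(l)
    as.character(d$arr_f[d$line_f == l][1L]), character(1))
  sizes <- table(arr_of_line)
  arr_levels <- names(sizes)
  one_c <- rep(1, nlevels(cell))
  f_arr_of <- function(arr_line) {
    new_arr <- factor(arr_line[as.character(cell_line)], levels = arr_levels)
    a <- ifelse(new_arr == arr_levels[1L], 1, -1)
    Lcols <- nested_line_columns(cell_line, new_arr)
    Xf <- w * cbind(one_c, a, Lcols, cell_s, a * cell_s)
    rssf <- rss_of(Xf, yw)
    ss_arr <- rss_of(w * cbind(one_c, Lcols, cell_s, a * cell_s), yw) - rssf
    ss_line <- rss_of(w * cbind(one_c, a, cell_s, a * cell_s), yw) - rssf
    (ss_arr / 1) / (ss_line / d$df[["line"]])
  }
  cache <- new.env(parent = emptyenv())
  f_arr <- vapply(seq_len(B), function(b) {
    arr_line <- stats::setNames(sample(rep(arr_levels, sizes)), lines)
    key <- paste(arr_line, collapse = "")
    got <- cache[[key]]
    if (is.null(got)) {
      got <- f_arr_of(arr_line)
      cache[[key]] <- got
    }
    got
  }, numeric(1))
  p_arr <- perm_pvalue(f_arr, obs_f[["arrangement"]], B)

  fit$p_permutation <- NA_real_
  fit$p_permutation[match(c("arrangement", "line", "sex", "interaction"),
                          fit$term)] <- c(p_arr, p_line, p_sex, p_int)
  attr(fit, "n_permutations") <- B
  attr(fit, "stage_seeds") <- seeds
  fit
}

#' Reference-gene homogeneity check
#'
#' Tests whether the housekeeping (reference) gene is expressed equally
#' across the four sex x arrangement groups: one-way ANOVA on raw Ct values
#' plus Levene's homogeneity-of-variance test (both the Brown-Forsythe
#' median-centred and the mean-centred variants).
#'
#' @param records Ct data.frame (schema of [read_ct_table()]); only
#'   `gene == "reference"` rows are used.
#' @return list with `group_means` (named, 4 groups), `anova_f`, `anova_p`,
#'   `levene_w_median`, `levene_p_median`, `levene_w_mean`, `levene_p_mean`,
#'   `n_per_group`.
#' @export
reference_gene_check <- function(records) {
  ref <- records[records$gene == "reference", , drop = FALSE]
  if (!nrow(ref)) stop("no reference-gene rows in input", call. = FALSE)
  grp <- factor(paste(ref$sex, ref$arrangement, sep = "_"))
  if (nlevels(grp) != 4L)
    stop("design error: expected 4 sex x arrangement groups, found ",
         nlevels(grp), call. = FALSE)
  if (any(table(grp) < 2L))
    stop("design error: every group needs >= 2 observations", call. = FALSE)
  fit <- stats::lm(ct ~ grp, data = data.frame(ct = ref$ct, grp = grp))
  an <- stats::anova(fit)
  lev_med <- car::leveneTest(ref$ct, grp, center = stats::median)
  lev_mean <- car::leveneTest(ref$ct, grp, center = mean)
  gm <- tapply(ref$ct, grp, mean)
  list(
    group_means = stats::setNames(as.numeric(gm), names(gm)),
    n_per_group = as.integer(table(grp)),
    anova_f = an[["F value"]][1L],
    anova_p = an[["Pr(>F)"]][1L],
    levene_w_median = lev_med[["F value"]][1L],
    levene_p_median = lev_med[["Pr(>F)"]][1L],
    levene_w_mean = lev_mean[["F value"]][1L],
    levene_p_mean = lev_mean[["Pr(>F)"]][1L]
  )
}
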