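#' Per-line mutation-class summary and class-by-line count matrix
#'
#' Tabulates derived-mutation annotations into the canonical class-by-line
#' matrix (intergenic / intron / coding synonymous / coding nonsynonymous /
#' coding other), computes per-line derived totals, coding totals,
#' protein-changing counts and radical counts, and joins the per-line
#' adaptive-step and fitness estimates.
#'
#' @param annotations Output of [annotate_variants()] including a `line_id`
#'   column, one row per derived mutation.
#' @param step_table data.frame `line_id`, `treatment`, `steps`, `fitness`
#'   (see [evolved_step_table()]); lines absent from it get `NA` steps.
#' @param lines Optional character vector fixing line order (defaults to the
#'   step table order, then any extra lines seen in the annotations).
#' @return list with:
#'   * `line_summary`: one row per line (`line_id`, `treatment`, class
#'     counts, `total`, `coding_total`, `protein_changing`, `radical`,
#'     `steps`, `fitness`);
#'   * `class_matrix`: integer matrix, classes x lines, plus an
#'     `all_mutations` row;
#'   * `treatment_pct`: class percentages within each treatment's total.
#' @export
summarize_lines <- function(annotations, step_table = NULL, lines = NULL) {
  classes <- mutation_classes()
  if (is.null(lines)) {
    lines <- unique(c(if (!is.null(step_table)) step_table$line_id,
                      unique(annotations$line_id)))
  }
  counts <- matrix(0L, nrow = length(classes), ncol = length(lines),
                   dimnames = list(classes, lines))
  if (nrow(annotations) > 0L) {
    tab <- table(factor(annotations$mclass, levels = classes),
                 factor(annotations$line_id, levels = lines))
    counts[] <- as.integer(tab)
  }
  total <- colSums(counts)
  coding <- colSums(counts[c("coding_synonymous", "coding_nonsynonymous",
                             "coding_other"), , drop = FALSE])
  protch <- colSums(counts[c("coding_nonsynonymous", "coding_other"),
                           , drop = FALSE])
  radical <- vapply(lines, function(l) {
    a <- annotations[annotations$line_id == l, , drop = FALSE]
    sum(a$severity == "radical")
  }, numeric(1L))

  ls <- data.frame(line_id = lines, t(counts), total = as.integer(total),
                   coding_total = as.integer(coding),
                   protein_changing = as.integer(protch),
                   radical = as.integer(radical),
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(step_table)) {
    ls <- merge(ls, step_table, by = "line_id", all.x = TRUE, sort = FALSE)
  } else {
    ls$treatment <- treatment_from_id(lines)
    ls$steps <- NA_real_; ls$fitness <- NA_real_
  }
  ls <- ls[match(lines, ls$line_id), , drop = FALSE]
  rownames(ls) <- NULL

  cm <- rbind(counts, all_mutations = as.integer(total))
  trts <- unique(ls$treatment[!is.na(ls$treatment)])
  pct <- sapply(trts, function(tr) {
    sel <- ls$line_id[!is.na(ls$treatment) & ls$treatment == tr]
    cs <- rowSums(counts[, sel, drop = FALSE])
    100 * cs / sum(cs)
  })
  list(line_summary = ls, class_matrix = cm, treatment_pct = pct)
}

# fallback treatment labels from trailing S/L in the line id
treatment_from_id <- function(ids) {
  tr <- toupper(substring(ids, nchar(ids)))
  ifelse(tr %in% c("S", "L"), tr, NA_character_)
}

#' Round half away from zero at a given number of decimals
#'
#' Conventional "printed precision" rounding (2.125 -> 2.13 at two
#' decimals), unlike [round()]'s round-half-even under floating point.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Mean and standard error
#'
#' SE uses the n-1 sample standard deviation over sqrt(n).
#'
#' @param values Numeric vector, no NAs.
#' @return list with `mean`, `se` (NA for n = 1) and `n`.
#' @examples
#' mean_se(c(31, 18, 11, 21, 10, 12, 22, 19))  # 18.0, SE 2.48
#' @export
mean_se <- function(values) {
  n <- length(values)
  if (n == 0L) stop("no values")
  list(mean = mean(values),
       se = if (n >= 2L) sd(values) / sqrt(n) else NA_real_,
       n = n)
}

#' Ratio of mean mutation count to mean adaptive-step number
#'
#' @param mean_mutations,mean_steps Means; `mean_steps` must be positive.
#' @return The ratio.
#' @examples
#' step_ratio(18.0, 2.13)  # 8.45
#' @export
step_ratio <- function(mean_mutations, mean_steps) {
  if (!is.finite(mean_steps) || mean_steps <= 0) {
    stop("mean_steps must be positive")
  }
  mean_mutations / mean_steps
}

#' Pearson correlation with Student-t significance
#'
#' Computes R and the two-tailed p-value from `t = R sqrt(n-2) / sqrt(1-R^2)`
#' on n-2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, non-zero variance.
#' @return list with `R`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance: correlation undefined")
  R <- cor(x, y)
  if (abs(R) >= 1) {
    p <- 0
  } else {
    t <- R * sqrt(n - 2) / sqrt(1 - R^2)
    p <- 2 * pt(-abs(t), df = n - 2)
  }
  list(R = R, p = p, n = n)
}

#' Leave-one-out correlation screen for influential lines
#'
#' Recomputes [pearson_with_p()] excluding each line in turn, flagging lines
#' whose exclusion changes significance at `alpha` relative to the full-data
#' correlation.
#'
#' @param x,y Numeric vectors (n >= 4).
#' @param line_ids Labels for the observations.
#' @param alpha Significance threshold used for the change flag (default
#'   0.05).
#' @return data.frame with `excluded`, `R`, `p`, `n`,
#'   `significance_changed`.
#' @export
leave_one_out <- function(x, y, line_ids = seq_along(x), alpha = 0.05) {
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations")
  full <- pearson_with_p(x, y)
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    r <- pearson_with_p(x[-i], y[-i])
    data.frame(excluded = as.character(line_ids[i]), R = r$R, p = r$p,
               n = r$n, stringsAsFactors = FALSE)
  }))
  out$significance_changed <- (out$p < alpha) != (full$p < alpha)
  rownames(out) <- NULL
  out
}

#' One-tailed F-test comparing group variances
#'
#' F is the larger variance over the smaller; the one-tailed p comes from
#' the F distribution with the corresponding degrees of freedom.
#'
#' @param group_a,group_b Numeric vectors, each n >= 2.
#' @return list with `var_a`, `var_b`, `F`, `df`, `p`.
#' @export
variance_f_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values")
  }
  va <- var(group_a); vb <- var(group_b)
  if (min(va, vb) == 0) stop("zero variance in one group")
  if (va >= vb) {
    f <- va / vb; df <- c(length(group_a) - 1L, length(group_b) - 1L)
  } else {
    f <- vb / va; df <- c(length(group_b) - 1L, length(group_a) - 1L)
  }
  list(var_a = va, var_b = vb, F = f, df = df,
       p = pf(f, df[1L], df[2L], lower.tail = FALSE))
}

#' One-tailed treatment contrast on per-line mutation proportions
#'
#' Computes a per-line proportion — the synonymous share of coding SNPs
#' (`synonymous / (synonymous + nonsynonymous)`) or the putatively neutral
#' share of all mutations (`(intergenic + intron + synonymous) / total`) —
#' and compares small- vs large-population lines with a one-tailed t-test
#' under the alternative S > L (Welch's unequal-variance form by default).
#'
#' @param line_summary The `line_summary` data.frame from
#'   [summarize_lines()].
#' @param kind `"synonymous_of_coding_snps"` or `"putatively_neutral"`.
#' @param pooled Use the pooled-variance t instead of Welch (default FALSE).
#' @return list with `mean_S`, `se_S`, `mean_L`, `se_L`, `t`, `df`, `p`
#'   (one-tailed), and `excluded_lines` (zero-denominator lines).
#' @export
proportion_contrast <- function(line_summary,
                                kind = c("synonymous_of_coding_snps",
                                         "putatively_neutral"),
                                pooled = FALSE) {
  kind <- match.arg(kind)
  ls <- line_summary
  denom <- switch(kind,
    synonymous_of_coding_snps =
      ls$coding_synonymous + ls$coding_nonsynonymous,
    putatively_neutral = ls$total)
  num <- switch(kind,
    synonymous_of_coding_snps = ls$coding_synonymous,
    putatively_neutral = ls$intergenic + ls$intron + ls$coding_synonymous)
  excluded <- ls$line_id[denom == 0]
  if (length(excluded) > 0L) {
    warning("lines excluded (zero denominator): ",
            paste(excluded, collapse = ", "))
  }
  keep <- denom > 0
  prop <- num[keep] / denom[keep]
  tr <- ls$treatment[keep]
  s <- prop[tr == "S"]; l <- prop[tr == "L"]
  if (length(s) < 2L || length(l) < 2L) stop("need >= 2 lines per treatment")
  ms <- mean_se(s); ml <- mean_se(l)
  if (pooled) {
    sp2 <- ((length(s) - 1) * var(s) + (length(l) - 1) * var(l)) /
      (length(s) + length(l) - 2)
    t <- (ms$mean - ml$mean) / sqrt(sp2 * (1 / length(s) + 1 / length(l)))
    df <- length(s) + length(l) - 2
  } else {
    vs <- var(s) / length(s); vl <- var(l) / length(l)
    t <- (ms$mean - ml$mean) / sqrt(vs + vl)
    df <- (vs + vl)^2 / (vs^2 / (length(s) - 1) + vl^2 / (length(l) - 1))
  }
  list(mean_S = ms$mean, se_S = ms$se, mean_L = ml$mean, se_L = ml$se,
       t = t, df = df, p = pt(t, df, lower.tail = FALSE),
       excluded_lines = as.character(excluded))
}

#' Substitution rate per nucleotide per generation
#'
#' @param total_mutations Total derived mutations across lines.
#' @param callable_genome_bp Callable reference length in bp.
#' @param generations Generations of selection.
#' @param n_lines Number of evolved lines.
#' @param per_chromosome Optional data.frame `chrom`, `mutations`,
#'   `callable_bp` for a per-chromosome breakdown.
#' @return list with `rate` and optionally `per_chromosome` rates.
#' @examples
#' substitution_rate(144, 29.67e6, 800, 8)$rate  # ~7.58e-10
#' @export
substitution_rate <- function(total_mutations, callable_genome_bp,
                              generations, n_lines, per_chromosome = NULL) {
  if (callable_genome_bp <= 0 || generations <= 0 || n_lines <= 0) {
    stop("callable_genome_bp, generations and n_lines must be positive")
  }
  out <- list(rate = total_mutations /
                (callable_genome_bp * generations * n_lines))
  if (!is.null(per_chromosome)) {
    pc <- per_chromosome
    pc$rate <- pc$mutations / (pc$callable_bp * generations * n_lines)
    out$per_chromosome <- pc
  }
  out
}

#' Goodness-of-fit test of the coding share of mutations
#'
#' One-degree-of-freedom chi-square of the observed (coding, noncoding)
#' split against an expected coding fraction (for the study system, the
#' approximate coding share of the genome).
#'
#' @param observed_coding Number of coding mutations.
#' @param total Total mutations.
#' @param expected_coding_fraction Expected coding share, in (0, 1).
#' @return list with `proportion`, `chi2`, `p`.
#' @export
coding_fraction_test <- function(observed_coding, total,
                                 expected_coding_fraction) {
  if (observed_coding > total) stop("observed_coding exceeds total")
  if (expected_coding_fraction <= 0 || expected_coding_fraction >= 1) {
    stop("expected_coding_fraction must be in (0, 1)")
  }
  e1 <- total * expected_coding_fraction
  e2 <- total - e1
  chi2 <- (observed_coding - e1)^2 / e1 + ((total - observed_coding) - e2)^2 / e2
  list(proportion = observed_coding / total, chi2 = chi2,
       p = pchisq(chi2, df = 1L, lower.tail = FALSE))
}
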