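#' Per-line derived-mutation class counts for the eight-line study cohort
#'
#' The published class-by-line count matrix for the eight evolved
#' *A. nidulans* lines (four small-bottleneck "S" lines, four
#' large-bottleneck "L" lines): 144 derived mutations split into intergenic,
#' intron, coding synonymous, coding nonsynonymous and coding "other"
#' (codon indel / stop gained / frame-shift). Used as the default planting
#' scheme of [sim_config()] so the synthetic cohort reproduces the study's
#' per-line mutation spectrum.
#'
#' @return An integer matrix with mutation classes as rows and line ids as
#'   columns.
#' @examples
#' colSums(evolved_line_counts())  # per-line totals, 144 overall
#' @export
evolved_line_counts <- function() {
  m <- matrix(
    c(14, 6, 5, 6, 3, 4, 10, 9,   # intergenic
      1, 1, 0, 1, 0, 1, 0, 0,     # intron
      5, 1, 4, 7, 3, 1, 4, 3,     # coding, synonymous
      9, 10, 0, 6, 4, 5, 7, 6,    # coding, nonsynonymous
      2, 0, 2, 1, 0, 1, 1, 1),    # coding, other
    nrow = 5L, byrow = TRUE,
    dimnames = list(
      c("intergenic", "intron", "coding_synonymous",
        "coding_nonsynonymous", "coding_other"),
      c("9S", "16S", "25S", "42S", "8L", "37L", "45L", "59L")
    )
  )
  storage.mode(m) <- "integer"
  m
}

#' Adaptive-step and fitness table for the eight-line study cohort
#'
#' Per-line estimates of the number of adaptive steps taken during the
#' selection experiment (maximum-likelihood estimates from fitness
#' trajectories, an *input* to this package, never recomputed here) together
#' with a relative mycelial growth-rate value per line.
#'
#' The step values (integers between one and three, mean 2.13, SE 0.30) are a
#' reconstruction: they are the unique assignment of steps in \{1,2,3\} to
#' lines that is simultaneously consistent with the study's published
#' summary statistics and its step-vs-mutation-count correlations (R = 0.562
#' over all eight lines; R = 0.884 excluding outlier line 25S; R = 0.181
#' within S lines; R = 0.966 within L lines). The fitness column is a
#' synthetic stand-in on a relative growth-rate scale, back-solved only to
#' approximate the reported step-vs-growth-rate correlation; do not treat it
#' as measured data.
#'
#' @return A data.frame with columns `line_id`, `treatment` ("S"/"L"),
#'   `steps` and `fitness`.
#' @examples
#' mean_se(evolved_step_table()$steps)  # 2.13 (SE 0.30) after rounding
#' @export
evolved_step_table <- function() {
  data.frame(
    line_id = c("9S", "16S", "25S", "42S", "8L", "37L", "45L", "59L"),
    treatment = rep(c("S", "L"), each = 4L),
    steps = c(3, 2, 3, 3, 1, 1, 2, 2),
    fitness = c(0.863, 0.784, 0.881, 0.837, 0.750, 0.876, 0.794, 0.832),
    stringsAsFactors = FALSE
  )
}

# canonical class labels, in reporting order
mutation_classes <- function() {
  c("intergenic", "intron", "coding_synonymous",
    "coding_nonsynonymous", "coding_other")
}
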