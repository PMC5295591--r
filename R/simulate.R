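#' Configuration for a synthetic evolve-and-resequence cohort
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the study conditions this package targets: one haploid ancestor and eight
#' evolved lines (four small-bottleneck "S", four large-bottleneck "L"), 800
#' generations, derived mutations planted with the published per-line class
#' counts ([evolved_line_counts()], 144 in total, 87 of them genic), a
#' 22-gene pathway subset receiving exactly two hits, 1196 ancestral
#' variants (740 SNPs + 456 indels) against the reference, mean coverage 83x
#' in 1 kb bins, and a GO-Slim table whose per-namespace annotation coverage
#' matches the study's (57/56/54% missing). The toy genome is scaled down
#' (eight 400 kb chromosomes, 1000 genes, ~50% coding) so an end-to-end run
#' stays fast while keeping the full per-line mutation density.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_chromosomes,chromosome_length,n_genes,coding_fraction Genome
#'   geometry; placement fails with an explicit error when infeasible.
#' @param lines data.frame `line_id`, `treatment`.
#' @param line_class_counts Class-by-line integer matrix of derived
#'   mutations to plant (rows as in [mutation_classes()]); `NULL` samples
#'   counts instead.
#' @param mutations_per_line list(mean, dispersion) for the negative-binomial
#'   per-line totals used when `line_class_counts` is `NULL`.
#' @param class_mix Class proportions used when sampling (must sum to 1).
#' @param n_utr5_hits,n_promoter_hits How many intergenic-class mutations to
#'   place inside 5'-UTRs / within the promoter window upstream of a TSS.
#' @param planted_subset_size,subset_hit_count Size of the designated
#'   pathway gene subset and the exact number of derived mutations planted
#'   in it.
#' @param ancestral_snps,ancestral_indels Pre-experiment variants shared by
#'   the ancestor and every line.
#' @param callers Pseudo-caller identifiers (>= 2).
#' @param caller_fp_per_mb,caller_fn_rate Named per-caller error rates:
#'   spurious calls per Mb and the probability of missing a true variant.
#' @param coverage_mean,coverage_bin Background mean read depth and bin
#'   width (bp).
#' @param planted_coverage_events data.frame `line_id` (a line id or
#'   `"all"`), `chrom`, `start`, `end` (0-based half-open), `fold`; `NULL`
#'   auto-plants shared absent regions covering `shared_absent_fraction` of
#'   the genome plus one line-private deletion and one duplication.
#' @param shared_absent_fraction Genome share of auto-planted regions absent
#'   from every sample (default 0.017).
#' @param step_table Per-line steps/fitness table
#'   (default [evolved_step_table()]).
#' @param go_missing Named per-namespace fractions of genes lacking GO
#'   annotation.
#' @param go_terms_per_namespace Number of GO-Slim terms per namespace.
#' @param planted_term list(term_id, term_name, namespace, fold,
#'   background_frequency): a term whose carriers are oversampled among
#'   mutated genes by `fold`, planting a detectable enrichment.
#' @param generations Generations of selection (default 800).
#' @param promoter_window Promoter tag window in bp (default 100).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 8L,
                       chromosome_length = 400000L,
                       n_genes = 1000L,
                       coding_fraction = 0.5,
                       lines = NULL,
                       line_class_counts = evolved_line_counts(),
                       mutations_per_line = list(mean = 18, dispersion = 8),
                       class_mix = NULL,
                       n_utr5_hits = 5L,
                       n_promoter_hits = 8L,
                       planted_subset_size = 22L,
                       subset_hit_count = 2L,
                       ancestral_snps = 740L,
                       ancestral_indels = 456L,
                       callers = c("mpileup", "varscan", "pindel"),
                       caller_fp_per_mb = NULL,
                       caller_fn_rate = NULL,
                       coverage_mean = 83,
                       coverage_bin = 1000L,
                       planted_coverage_events = NULL,
                       shared_absent_fraction = 0.017,
                       step_table = evolved_step_table(),
                       go_missing = c(cellular_component = 0.57,
                                      biological_process = 0.56,
                                      molecular_function = 0.54),
                       go_terms_per_namespace = 15L,
                       planted_term = list(term_id = "GO:0006950",
                                           term_name = "response to stress",
                                           namespace = "biological_process",
                                           fold = 2.1,
                                           background_frequency = 0.12),
                       generations = 800L,
                       promoter_window = 100L) {
  if (is.null(lines)) {
    lines <- if (!is.null(line_class_counts)) {
      data.frame(line_id = colnames(line_class_counts),
                 treatment = treatment_from_id(colnames(line_class_counts)),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(line_id = c("9S", "16S", "25S", "42S", "8L", "37L", "45L",
                             "59L"),
                 treatment = rep(c("S", "L"), each = 4L),
                 stringsAsFactors = FALSE)
    }
  }
  if (is.null(class_mix)) {
    class_mix <- c(intergenic = 57, intron = 4, coding_synonymous = 28,
                   coding_nonsynonymous = 47, coding_other = 8) / 144
  }
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix must sum to 1")
  if (!all(names(class_mix) %in% mutation_classes())) {
    stop("class_mix names must be the canonical mutation classes")
  }
  if (length(callers) < 2L) stop("need at least 2 pseudo-callers")
  if (is.null(caller_fp_per_mb)) {
    caller_fp_per_mb <- setNames(rep(0.5, length(callers)), callers)
  }
  if (is.null(caller_fn_rate)) {
    caller_fn_rate <- setNames(rep(0.05, length(callers)), callers)
  }
  if (!is.null(line_class_counts)) {
    if (!identical(sort(rownames(line_class_counts)),
                   sort(mutation_classes()))) {
      stop("line_class_counts rows must be the canonical mutation classes")
    }
    if (!identical(colnames(line_class_counts), lines$line_id)) {
      stop("line_class_counts columns must match the line ids")
    }
  }
  if (subset_hit_count > planted_subset_size) {
    stop("subset_hit_count cannot exceed the subset size")
  }
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              n_genes = as.integer(n_genes), coding_fraction = coding_fraction,
              lines = lines, line_class_counts = line_class_counts,
              mutations_per_line = mutations_per_line, class_mix = class_mix,
              n_utr5_hits = as.integer(n_utr5_hits),
              n_promoter_hits = as.integer(n_promoter_hits),
              planted_subset_size = as.integer(planted_subset_size),
              subset_hit_count = as.integer(subset_hit_count),
              ancestral_snps = as.integer(ancestral_snps),
              ancestral_indels = as.integer(ancestral_indels),
              callers = callers, caller_fp_per_mb = caller_fp_per_mb,
              caller_fn_rate = caller_fn_rate,
              coverage_mean = coverage_mean,
              coverage_bin = as.integer(coverage_bin),
              planted_coverage_events = planted_coverage_events,
              shared_absent_fraction = shared_absent_fraction,
              step_table = step_table, go_missing = go_missing,
              go_terms_per_namespace = as.integer(go_terms_per_namespace),
              planted_term = planted_term,
              generations = as.integer(generations),
              promoter_window = as.integer(promoter_window))
  class(cfg) <- "sim_config"
  cfg
}

MIN_GENE_GAP <- 300L   # bp between genes; leaves room for promoter windows
MIN_CDS <- 150L

#' Generate a synthetic reference: sequences plus gene models
#'
#' Places `n_genes` non-overlapping, single-transcript gene models (explicit
#' 5'-UTR, CDS split by introns at codon boundaries, 3'-UTR) on random
#' chromosome sequences, tuning per-gene CDS lengths so the realized coding
#' fraction matches the configured one. CDS sequence is built from sense
#' codons ending in a stop, so any codon is safely mutable.
#'
#' @param config A [sim_config()].
#' @return A reference bundle: list with `seqs` (named DNAStringSet),
#'   `genes` (`gene_id`, `chrom`, `strand`, `start`, `end`, `tss`) and
#'   `features` (`gene_id`, `chrom`, `strand`, `type`, `start`, `end`;
#'   1-based inclusive).
#' @export
generate_reference <- function(config) {
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  L <- config$chromosome_length
  bases <- c("A", "C", "G", "T")
  seq_chars <- lapply(chroms, function(ch) sample(bases, L, replace = TRUE))
  names(seq_chars) <- chroms

  genes <- NULL; features <- NULL
  n <- config$n_genes
  if (n > 0L) {
    total_len <- config$n_chromosomes * as.numeric(L)
    target_cds <- config$coding_fraction * total_len
    mean_cds <- target_cds / n
    if (mean_cds < MIN_CDS) {
      stop("infeasible geometry: per-gene CDS below ", MIN_CDS, " bp")
    }
    cds_len <- 3L * pmax(MIN_CDS %/% 3L,
                         round(mean_cds / 3 * runif(n, 0.75, 1.25)))
    delta <- round((target_cds - sum(cds_len)) / 3)
    if (abs(delta) > 0) {
      step <- sign(delta) * 3L
      take <- abs(delta) %% n
      per <- (abs(delta) %/% n) * step
      cds_len <- pmax(MIN_CDS, cds_len + per +
                        c(rep(step, take), rep(0L, n - take)))
    }
    n_exons <- sample(1:3, n, replace = TRUE, prob = c(0.45, 0.35, 0.20))
    utr5_len <- sample(50:150, n, replace = TRUE)
    utr3_len <- sample(50:150, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)

    # split each CDS into exon chunks at codon boundaries
    chunks <- lapply(seq_len(n), function(i) {
      k <- n_exons[i]; ncod <- cds_len[i] %/% 3L
      if (k == 1L || ncod < 3L * k) return(cds_len[i])
      cuts <- sort(sample(seq_len(ncod - 1L), k - 1L))
      diff(c(0L, cuts, ncod)) * 3L
    })
    intron_lens <- lapply(seq_len(n), function(i) {
      k <- length(chunks[[i]])
      if (k < 2L) integer(0) else sample(60:90, k - 1L, replace = TRUE)
    })
    span <- utr5_len + utr3_len + cds_len +
      vapply(intron_lens, sum, numeric(1L))

    # distribute genes evenly over chromosomes, random gaps >= MIN_GENE_GAP
    per_chrom <- rep(n %/% config$n_chromosomes, config$n_chromosomes)
    extra <- n %% config$n_chromosomes
    if (extra > 0L) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
    idx_split <- split(seq_len(n), rep(seq_len(config$n_chromosomes), per_chrom))

    sense_codons <- names(Biostrings::GENETIC_CODE)[
      Biostrings::GENETIC_CODE != "*"]

    gene_rows <- vector("list", n); feat_rows <- vector("list", n)
    gi <- 0L
    for (ci in seq_along(chroms)) {
      ids <- idx_split[[ci]]
      if (length(ids) == 0L) next
      need <- sum(span[ids]) + (length(ids) + 1L) * MIN_GENE_GAP
      if (need > L) {
        stop("infeasible geometry: cannot place ", length(ids),
             " genes on a ", L, " bp chromosome")
      }
      slack <- L - sum(span[ids]) - (length(ids) + 1L) * MIN_GENE_GAP
      w <- runif(length(ids) + 1L)
      extras <- floor(slack * w / sum(w))
      gaps <- MIN_GENE_GAP + extras
      cursor <- 0L
      for (j in seq_along(ids)) {
        i <- ids[j]; gi <- gi + 1L
        gstart <- cursor + gaps[j] + 1L
        gend <- gstart + span[i] - 1L
        cursor <- gend
        gid <- sprintf("gene%04d", gi)
        fr <- gene_segments(gid, chroms[ci], strand[i], gstart, utr5_len[i],
                            chunks[[i]], intron_lens[[i]], utr3_len[i])
        feat_rows[[gi]] <- fr
        gene_rows[[gi]] <- data.frame(
          gene_id = gid, chrom = chroms[ci], strand = strand[i],
          start = gstart, end = gend,
          tss = if (strand[i] == "+") gstart else gend,
          stringsAsFactors = FALSE)
        # write coding sequence into the chromosome
        ncod <- cds_len[i] %/% 3L
        coding <- c(sample(sense_codons, ncod - 1L, replace = TRUE), "TAA")
        cod_chars <- strsplit(paste(coding, collapse = ""), "", fixed = TRUE)[[1L]]
        if (strand[i] == "-") {
          cod_chars <- rev(unname(complement_base(cod_chars)))
        }
        cds_iv <- fr[fr$type == "CDS", , drop = FALSE]
        cds_iv <- cds_iv[order(cds_iv$start), , drop = FALSE]
        off <- 0L
        for (r in seq_len(nrow(cds_iv))) {
          wdt <- cds_iv$end[r] - cds_iv$start[r] + 1L
          seq_chars[[chroms[ci]]][cds_iv$start[r]:cds_iv$end[r]] <-
            cod_chars[(off + 1L):(off + wdt)]
          off <- off + wdt
        }
      }
    }
    genes <- do.call(rbind, gene_rows)
    features <- do.call(rbind, feat_rows)
    rownames(genes) <- rownames(features) <- NULL
  } else {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        strand = character(), start = integer(),
                        end = integer(), tss = integer(),
                        stringsAsFactors = FALSE)
    features <- data.frame(gene_id = character(), chrom = character(),
                           strand = character(), type = character(),
                           start = integer(), end = integer(),
                           stringsAsFactors = FALSE)
  }
  seqs <- Biostrings::DNAStringSet(vapply(seq_chars, paste, character(1L),
                                          collapse = ""))
  names(seqs) <- chroms
  list(seqs = seqs, genes = genes, features = features)
}

# genomic-ascending feature intervals for one gene
gene_segments <- function(gid, chrom, strand, gstart, u5, cds_chunks,
                          introns, u3) {
  # transcription order: 5'UTR, cds1, intron1, cds2, ..., cdsk, 3'UTR
  k <- length(cds_chunks)
  widths <- u5; types <- "five_prime_UTR"
  for (j in seq_len(k)) {
    widths <- c(widths, cds_chunks[j]); types <- c(types, "CDS")
    if (j < k) { widths <- c(widths, introns[j]); types <- c(types, "intron") }
  }
  widths <- c(widths, u3); types <- c(types, "three_prime_UTR")
  if (strand == "-") {           # genomic-ascending = reverse of transcript
    widths <- rev(widths); types <- rev(types)
  }
  widths <- as.integer(widths)
  ends <- gstart - 1L + cumsum(widths)
  starts <- ends - widths + 1L
  seg <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                    type = types, start = starts, end = ends,
                    stringsAsFactors = FALSE)
  # exons: contiguous non-intron stretches
  nonint <- seg[seg$type != "intron", , drop = FALSE]
  nonint <- nonint[order(nonint$start), , drop = FALSE]
  ex_start <- nonint$start[1L]; ex <- NULL
  for (r in seq_len(nrow(nonint))) {
    if (r < nrow(nonint) && nonint$start[r + 1L] == nonint$end[r] + 1L) next
    ex <- rbind(ex, data.frame(gene_id = gid, chrom = chrom, strand = strand,
                               type = "exon", start = ex_start,
                               end = nonint$end[r], stringsAsFactors = FALSE))
    if (r < nrow(nonint)) ex_start <- nonint$start[r + 1L]
  }
  rbind(seg[seg$type != "intron", , drop = FALSE], ex)
}
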