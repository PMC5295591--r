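# Readers/writers for the standard formats (FASTA, GFF3, VCF, BED, TSV) and
# the end-to-end pipeline driver. VCF coordinates are 1-based; BED and
# coverage intervals are 0-based half-open.

#' Write a variant table as VCF
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` and
#'   optionally `depth`, `quality`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  v <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  gr <- GenomicRanges::GRanges(v$chrom,
                               IRanges::IRanges(v$pos, width = nchar(v$ref)))
  qual <- if (!is.null(v$quality)) as.numeric(v$quality) else rep(50, nrow(v))
  fx <- S4Vectors::DataFrame(REF = Biostrings::DNAStringSet(v$ref),
                             ALT = as(as.list(v$alt), "CharacterList"),
                             QUAL = qual,
                             FILTER = rep("PASS", nrow(v)))
  vcf <- suppressWarnings(VariantAnnotation::VCF(rowRanges = gr, fixed = fx))
  h <- VariantAnnotation::header(vcf)
  VariantAnnotation::meta(h) <- IRanges::DataFrameList(
    fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                      row.names = "fileformat"))
  VariantAnnotation::info(h) <- S4Vectors::DataFrame(
    Number = "1", Type = "Integer", Description = "Read depth",
    row.names = "DP")
  suppressWarnings({
    VariantAnnotation::header(vcf) <- h
    VariantAnnotation::info(vcf)$DP <-
      if (!is.null(v$depth)) as.integer(v$depth) else rep(NA_integer_, nrow(v))
    VariantAnnotation::writeVcf(vcf, path)
  })
  invisible(path)
}

#' Read a VCF into the pipeline's variant table
#'
#' @param path VCF file.
#' @param line_id,caller_id Labels attached to every record.
#' @return data.frame `line_id`, `caller_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `kind`, `depth`, `quality`.
#' @export
read_variants_vcf <- function(path, line_id = NA_character_,
                              caller_id = NA_character_) {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- vapply(VariantAnnotation::alt(vcf), function(a)
    as.character(a)[1L], character(1L))
  dp <- VariantAnnotation::info(vcf)$DP
  if (is.null(dp)) dp <- rep(NA_integer_, length(rr))
  ref <- as.character(VariantAnnotation::ref(vcf))
  df <- data.frame(
    line_id = line_id, caller_id = caller_id,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr), ref = ref, alt = alt,
    kind = variant_kind(ref, alt),
    depth = as.integer(dp),
    quality = as.numeric(rr$QUAL),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Write gene models as GFF3
#'
#' Emits one `gene` row per gene plus its `exon`, `CDS`, `five_prime_UTR`
#' and `three_prime_UTR` children.
#'
#' @param reference Reference bundle (`genes` + `features`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(reference, path) {
  g <- reference$genes; f <- reference$features
  gr_g <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                                 strand = g$strand)
  gr_g$type <- "gene"; gr_g$ID <- g$gene_id
  gr_g$Parent <- as(vector("list", nrow(g)), "CharacterList")
  gr_f <- GenomicRanges::GRanges(f$chrom, IRanges::IRanges(f$start, f$end),
                                 strand = f$strand)
  gr_f$type <- f$type
  gr_f$ID <- paste0(f$gene_id, ".", tolower(f$type), seq_len(nrow(f)))
  gr_f$Parent <- as(as.list(f$gene_id), "CharacterList")
  gr <- c(gr_g, gr_f)
  gr <- gr[order(GenomicRanges::seqnames(gr), GenomicRanges::start(gr))]
  suppressWarnings(rtracklayer::export(gr, path, format = "gff3"))
  invisible(path)
}

#' Read gene models from GFF3 into a reference-bundle annotation
#'
#' @param path GFF3 file with `gene` rows and `exon`/`CDS`/UTR children
#'   carrying `Parent` attributes.
#' @return list with `genes` and `features` data.frames (see
#'   [generate_reference()]).
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  is_gene <- type == "gene"
  genes <- data.frame(
    gene_id = as.character(gr$ID[is_gene]),
    chrom = as.character(GenomicRanges::seqnames(gr)[is_gene]),
    strand = as.character(GenomicRanges::strand(gr)[is_gene]),
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  feat <- gr[!is_gene]
  parent <- vapply(feat$Parent, function(p)
    if (length(p) > 0L) p[[1L]] else NA_character_, character(1L))
  features <- data.frame(
    gene_id = parent,
    chrom = as.character(GenomicRanges::seqnames(feat)),
    strand = as.character(GenomicRanges::strand(feat)),
    type = as.character(feat$type),
    start = GenomicRanges::start(feat),
    end = GenomicRanges::end(feat),
    stringsAsFactors = FALSE)
  list(genes = genes, features = features)
}

#' Write / read binned coverage as BED-style TSV
#'
#' Columns: chrom, start, end (0-based half-open), mean depth.
#'
#' @param track A `coverage_track`.
#' @param path File path.
#' @return `path` invisibly, or a `coverage_track`.
#' @export
write_coverage_bed <- function(track, path) {
  write.table(track$bins[, c("chrom", "start", "end", "mean_depth")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_coverage_bed
#' @param line_id Label for the track read back.
#' @export
read_coverage_bed <- function(path, line_id = NA_character_) {
  b <- read.delim(path, header = FALSE,
                  col.names = c("chrom", "start", "end", "mean_depth"))
  coverage_track(b, line_id = line_id)
}

#' Write a complete synthetic cohort to disk
#'
#' Produces `reference.fa`, `genes.gff3`, `go_slim.tsv`, `steps.tsv`,
#' `vcf/<line>_<caller>.vcf` (ancestor included), `coverage/<line>.bed` and
#' `ground_truth.json` under `dir`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "vcf"), showWarnings = FALSE)
  dir.create(file.path(dir, "coverage"), showWarnings = FALSE)
  Biostrings::writeXStringSet(cohort$reference$seqs,
                              file.path(dir, "reference.fa"))
  write_gene_models_gff3(cohort$reference, file.path(dir, "genes.gff3"))
  write.table(cohort$go_table, file.path(dir, "go_slim.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$step_table, file.path(dir, "steps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  calls <- cohort$calls
  for (s in unique(calls$line_id)) {
    for (cal in unique(calls$caller_id)) {
      sub <- calls[calls$line_id == s & calls$caller_id == cal, , drop = FALSE]
      write_variants_vcf(sub, file.path(dir, "vcf",
                                        paste0(s, "_", cal, ".vcf")))
    }
  }
  for (s in names(cohort$coverage$tracks)) {
    write_coverage_bed(cohort$coverage$tracks[[s]],
                       file.path(dir, "coverage", paste0(s, ".bed")))
  }
  truth <- cohort$truth
  truth$coverage_events <- cohort$coverage$events
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return list with `reference` (seqs + gene models), `go_table`,
#'   `step_table`, `calls` and `tracks` — the same shapes
#'   [simulate_cohort()] produces in memory.
#' @export
read_cohort <- function(dir) {
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "reference.fa"))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gm <- read_gene_models_gff3(file.path(dir, "genes.gff3"))
  reference <- list(seqs = seqs, genes = gm$genes, features = gm$features)
  go_table <- read.delim(file.path(dir, "go_slim.tsv"),
                         stringsAsFactors = FALSE)
  step_table <- read.delim(file.path(dir, "steps.tsv"),
                           stringsAsFactors = FALSE)
  vcfs <- list.files(file.path(dir, "vcf"), pattern = "\\.vcf$",
                     full.names = TRUE)
  calls <- do.call(rbind, lapply(vcfs, function(f) {
    nm <- sub("\\.vcf$", "", basename(f))
    parts <- strsplit(nm, "_")[[1L]]
    read_variants_vcf(f, line_id = paste(head(parts, -1L), collapse = "_"),
                      caller_id = tail(parts, 1L))
  }))
  beds <- list.files(file.path(dir, "coverage"), pattern = "\\.bed$",
                     full.names = TRUE)
  tracks <- lapply(beds, function(f)
    read_coverage_bed(f, line_id = sub("\\.bed$", "", basename(f))))
  names(tracks) <- sub("\\.bed$", "", basename(beds))
  list(reference = reference, go_table = go_table, step_table = step_table,
       calls = calls, tracks = tracks)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates (or accepts) a cohort, then chains consensus verification,
#' ancestral/derived partitioning, mutation annotation, coverage scanning,
#' GO-Slim enrichment, the pathway-subset parallelism probability and the
#' adaptive-walk comparison statistics into one report. All stages use the
#' configured defaults (2-of-3 caller agreement, depth 3, coverage
#' thresholds 1.8x/0.20x with 500 bp minimum length and 200 bp merge gap,
#' 5% term representation, 1.2 fold, FDR 0.15, 100 bp promoter window).
#'
#' @param config A [sim_config()]; ignored when `cohort` is given.
#' @param cohort Optional pre-built [simulate_cohort()] result.
#' @param dir Optional directory: the cohort is written there and read back
#'   through the on-disk formats before analysis.
#' @param min_callers,depth_min Consensus thresholds.
#' @param mask Optional low-quality mask (BED-convention data.frame).
#' @param expected_coding_fraction Expected coding share for the
#'   goodness-of-fit test (defaults to the configured coding fraction).
#' @return A `compwalk_report` list with the per-stage results.
#' @export
run_all <- function(config = sim_config(), cohort = NULL, dir = NULL,
                    min_callers = 2L, depth_min = 3L, mask = NULL,
                    expected_coding_fraction = NULL) {
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  config <- cohort$config
  if (!is.null(dir)) {
    write_cohort(cohort, dir)
    disk <- read_cohort(dir)
    calls <- disk$calls
    reference <- disk$reference
    tracks <- disk$tracks
    go_table <- disk$go_table
    step_table <- disk$step_table
  } else {
    calls <- cohort$calls
    reference <- cohort$reference
    tracks <- cohort$coverage$tracks
    go_table <- cohort$go_table
    step_table <- cohort$step_table
  }

  consensus <- cross_verify(calls, min_callers = min_callers,
                            depth_min = depth_min,
                            known_chroms = names(reference$seqs))
  masked <- mask_regions(consensus, mask)
  part <- partition_ancestral_derived(masked$variants)
  annotations <- annotate_variants(part$derived, reference,
                                   promoter_window = config$promoter_window)

  regions <- lapply(tracks, call_regions)
  low_regions <- lapply(regions, function(r)
    r[r$direction == "low", , drop = FALSE])
  genome_length <- sum(as.numeric(Biostrings::width(reference$seqs)))
  shared_absent <- summarize_masked_fraction(low_regions, genome_length)

  genic <- annotations[annotations$mclass != "intergenic", , drop = FALSE]
  query <- unique(genic$gene_id[!is.na(genic$gene_id)])
  enrichment <- if (length(query) > 0L) {
    go_enrich(query, go_table, universe = reference$genes$gene_id)
  } else {
    NULL
  }
  go_coverage <- annotation_coverage_report(query, go_table)
  subset_genes <- cohort$truth$subset_genes
  k_obs <- sum(genic$gene_id %in% subset_genes, na.rm = TRUE)
  subset_prob <- subset_hit_probability(length(subset_genes),
                                        nrow(reference$genes),
                                        nrow(genic), k_obs)

  summary <- summarize_lines(annotations, step_table)
  ls <- summary$line_summary
  stats <- adaptive_walk_report(ls, genome_length, config$generations)
  ecf <- if (is.null(expected_coding_fraction)) config$coding_fraction else
    expected_coding_fraction
  stats$coding_fraction <- coding_fraction_test(sum(ls$coding_total),
                                                sum(ls$total), ecf)

  report <- list(config = config, consensus = consensus,
                 n_masked = masked$n_masked, partition = part,
                 annotations = annotations, coverage_regions = regions,
                 shared_absent = shared_absent, enrichment = enrichment,
                 go_coverage = go_coverage, subset_probability = subset_prob,
                 summary = summary, stats = stats)
  class(report) <- "compwalk_report"
  report
}

# the step-number comparison block shared by run_all() and the examples
adaptive_walk_report <- function(ls, callable_bp, generations) {
  out <- list()
  out$total <- mean_se(ls$total)
  out$coding <- mean_se(ls$coding_total)
  out$protein_changing <- mean_se(ls$protein_changing)
  out$radical <- mean_se(ls$radical)
  have_steps <- !any(is.na(ls$steps))
  if (have_steps) {
    out$steps <- mean_se(ls$steps)
    # ratios are quoted against the step mean at printed precision (2 dp,
    # half-up so e.g. 2.125 -> 2.13)
    ms <- round_half_up(out$steps$mean, 2)
    out$ratio_total <- step_ratio(out$total$mean, ms)
    out$ratio_coding <- step_ratio(out$coding$mean, ms)
    out$ratio_protein_changing <- step_ratio(out$protein_changing$mean, ms)
    out$cor_total_steps <- pearson_with_p(ls$steps, ls$total)
    out$loo_total_steps <- leave_one_out(ls$steps, ls$total, ls$line_id)
  } else {
    out$steps_note <- "step table missing; ratio and correlation skipped"
  }
  s <- ls$total[ls$treatment == "S"]; l <- ls$total[ls$treatment == "L"]
  if (length(s) >= 2L && length(l) >= 2L) {
    out$variance_test <- variance_f_test(s, l)
    out$synonymous_contrast <-
      proportion_contrast(ls, "synonymous_of_coding_snps")
    out$neutral_contrast <- proportion_contrast(ls, "putatively_neutral")
  }
  out$substitution_rate <- substitution_rate(sum(ls$total), callable_bp,
                                             generations, nrow(ls))
  out
}

#' @export
print.compwalk_report <- function(x, ...) {
  fm <- function(v, d = 2) formatC(round_half_up(v, d), digits = d,
                                   format = "f")
  cat("== compwalk pipeline report ==\n")
  cat("consensus variants retained:", nrow(x$consensus),
      "| masked:", x$n_masked, "\n")
  cat("ancestral:", nrow(x$partition$ancestral),
      "| derived:", nrow(x$partition$derived),
      "| ambiguous:", nrow(x$partition$ambiguous), "\n")
  cat("\nderived mutation classes x lines:\n")
  print(x$summary$class_matrix)
  st <- x$stats
  cat("\nmean mutations per line: ", fm(st$total$mean, 2), " (SE ",
      fm(st$total$se, 2), ")\n", sep = "")
  if (!is.null(st[["steps"]])) {
    cat("mean adaptive steps:     ", fm(st$steps$mean, 2), " (SE ",
        fm(st$steps$se, 2), ")\n", sep = "")
    cat("mutations per step: total ", fm(st$ratio_total, 2), ", coding ",
        fm(st$ratio_coding, 2), ", protein-changing ",
        fm(st$ratio_protein_changing, 2), "\n", sep = "")
    cat("steps vs total mutations: R = ", fm(st$cor_total_steps$R, 3),
        ", p = ", fm(st$cor_total_steps$p, 4), "\n", sep = "")
  }
  if (!is.null(st$variance_test)) {
    cat("S vs L variance: ", fm(st$variance_test$var_a, 1), " / ",
        fm(st$variance_test$var_b, 1), " (one-tailed F p = ",
        fm(st$variance_test$p, 3), ")\n", sep = "")
  }
  cat("substitution rate: ", format(st$substitution_rate$rate, digits = 3),
      " per nucleotide per generation\n", sep = "")
  cat("coding share: ", fm(100 * st$coding_fraction$proportion, 1),
      "% (chi2 = ", fm(st$coding_fraction$chi2, 2), ", p = ",
      fm(st$coding_fraction$p, 3), ")\n", sep = "")
  cat("shared absent coverage: ", format(x$shared_absent$total_bp,
                                         big.mark = ","), " bp (",
      fm(100 * x$shared_absent$fraction, 2), "% of genome)\n", sep = "")
  if (!is.null(x$enrichment)) {
    fl <- x$enrichment[x$enrichment$flagged_overrepresented, , drop = FALSE]
    cat("flagged GO-Slim terms: ", nrow(fl), "\n", sep = "")
    if (nrow(fl) > 0L) {
      print(fl[, c("namespace", "term_id", "observed", "expected", "fold",
                   "p_one_tailed", "q_bh")], digits = 3, row.names = FALSE)
    }
  }
  sp <- x$subset_probability
  cat("pathway subset: ", sp$k, "/", sp$n, " genic mutations in ", sp$m,
      " of ", sp$G, " genes; P = ", format(sp$probability, digits = 3),
      "\n", sep = "")
  invisible(x)
}
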