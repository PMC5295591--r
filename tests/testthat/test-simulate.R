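# Synthetic-cohort generator: geometry, determinism, planting fidelity,
# pseudo-caller error model and coverage planting.

tiny_config <- function(seed = 3, ...) {
  sim_config(seed = seed, n_chromosomes = 2L, chromosome_length = 120000L,
             n_genes = 40L, planted_subset_size = 6L,
             ancestral_snps = 40L, ancestral_indels = 20L,
             caller_fp_per_mb = c(mpileup = 0, varscan = 0, pindel = 0),
             caller_fn_rate = c(mpileup = 0, varscan = 0, pindel = 0),
             shared_absent_fraction = 0.01, ...)
}

test_that("reference geometry honours the configured coding fraction", {
  ref <- generate_reference(tiny_config())
  cds <- ref$features[ref$features$type == "CDS", ]
  frac <- sum(cds$end - cds$start + 1) / (2 * 120000)
  expect_gt(frac, 0.48)
  expect_lt(frac, 0.52)
  # every gene: strand, TSS, at least one exon, non-overlapping
  expect_true(all(ref$genes$strand %in% c("+", "-")))
  expect_true(all(table(ref$features$gene_id[ref$features$type == "exon"]) >= 1))
  g <- ref$genes[order(ref$genes$chrom, ref$genes$start), ]
  same <- g$chrom[-1] == g$chrom[-nrow(g)]
  expect_true(all(g$start[-1][same] > g$end[-nrow(g)][same]))
  # CDS lengths are codon-complete
  cdslen <- tapply(cds$end - cds$start + 1, cds$gene_id, sum)
  expect_true(all(cdslen %% 3 == 0))
})

test_that("zero genes still yields a sequence; infeasible geometry errors", {
  cfg <- tiny_config()
  cfg$n_genes <- 0L
  ref <- generate_reference(cfg)
  expect_equal(nrow(ref$genes), 0L)
  expect_equal(length(ref$seqs), 2L)
  expect_error(generate_reference(
    sim_config(n_chromosomes = 1L, chromosome_length = 10000L,
               n_genes = 200L, coding_fraction = 0.5)),
    "infeasible")
})

test_that("identical seeds give byte-identical cohort outputs", {
  co1 <- simulate_cohort(tiny_config(seed = 11))
  co2 <- simulate_cohort(tiny_config(seed = 11))
  expect_identical(as.character(co1$reference$seqs),
                   as.character(co2$reference$seqs))
  expect_identical(co1$truth$mutations, co2$truth$mutations)
  expect_identical(co1$calls, co2$calls)
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(co1, d1); write_cohort(co2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  co3 <- simulate_cohort(tiny_config(seed = 12))
  expect_false(identical(co1$truth$mutations, co3$truth$mutations))
})

test_that("planted class counts are realized exactly and subset hits are exact", {
  co <- table1_cohort()
  got <- table(factor(co$truth$mutations$class, levels = mutation_classes()),
               factor(co$truth$mutations$line_id,
                      levels = co$config$lines$line_id))
  expect_equal(unname(as.matrix(got)), unname(evolved_line_counts()))
  hits <- co$truth$mutations[co$truth$mutations$subset_hit, ]
  expect_equal(nrow(hits), 2L)
  expect_true(all(hits$gene_id %in% co$truth$subset_genes))
  expect_equal(length(unique(hits$gene_id)), 2L)
  expect_equal(length(unique(hits$line_id)), 2L)
  other_genic <- co$truth$mutations[!co$truth$mutations$subset_hit &
                                      co$truth$mutations$class != "intergenic", ]
  expect_false(any(other_genic$gene_id %in% co$truth$subset_genes))
})

test_that("sampled class counts follow the configured multinomial mix", {
  mix <- c(intergenic = 31, intron = 3, coding_synonymous = 17,
           coding_nonsynonymous = 25, coding_other = 5) / 81
  cfg <- sim_config(seed = 5, n_chromosomes = 2L, chromosome_length = 300000L,
                    n_genes = 220L, line_class_counts = NULL,
                    mutations_per_line = list(mean = 120, dispersion = 50),
                    class_mix = mix, n_utr5_hits = 0L, n_promoter_hits = 0L,
                    planted_subset_size = 6L, subset_hit_count = 2L,
                    ancestral_snps = 0L, ancestral_indels = 0L,
                    caller_fp_per_mb = c(mpileup = 0, varscan = 0, pindel = 0),
                    caller_fn_rate = c(mpileup = 0, varscan = 0, pindel = 0))
  ref <- generate_reference(cfg)
  truth <- plant_mutations(cfg, ref)
  n <- nrow(truth$mutations)
  expect_gt(n, 500)
  obs <- table(factor(truth$mutations$class,
                      levels = names(mix)))[names(mix)] / n
  se <- sqrt(mix * (1 - mix) / n)
  expect_true(all(abs(obs - mix) <= 3.2 * se))
})

test_that("all-intergenic mix never overlaps genes; intron demand needs introns", {
  cfg <- tiny_config()
  cfg$line_class_counts <- NULL
  cfg$class_mix <- c(intergenic = 1, intron = 0, coding_synonymous = 0,
                     coding_nonsynonymous = 0, coding_other = 0)
  cfg$mutations_per_line <- list(mean = 10, dispersion = 10)
  cfg$n_utr5_hits <- 0L; cfg$n_promoter_hits <- 0L
  cfg$subset_hit_count <- 0L
  ref <- generate_reference(cfg)
  truth <- plant_mutations(cfg, ref)
  g <- ref$genes
  overlaps <- vapply(seq_len(nrow(truth$mutations)), function(i) {
    m <- truth$mutations[i, ]
    any(g$chrom == m$chrom & g$start <= m$pos & g$end >= m$pos)
  }, logical(1L))
  expect_false(any(overlaps))

  # strip multi-exon genes, then ask for intron mutations
  ref1 <- ref
  single <- names(which(table(
    ref$features$gene_id[ref$features$type == "exon"]) == 1L))
  ref1$genes <- ref$genes[ref$genes$gene_id %in% single, ]
  ref1$features <- ref$features[ref$features$gene_id %in% single, ]
  cfg1 <- tiny_config()
  cfg1$line_class_counts <- NULL
  cfg1$class_mix <- c(intergenic = 0, intron = 1, coding_synonymous = 0,
                      coding_nonsynonymous = 0, coding_other = 0)
  cfg1$mutations_per_line <- list(mean = 5, dispersion = 10)
  cfg1$subset_hit_count <- 0L
  expect_error(plant_mutations(cfg1, ref1), "no introns")
})

test_that("noise-free callers reproduce the exact truth; ancestral shared", {
  co <- table1_cohort()
  truth_key <- function(df) sort(paste(df$chrom, df$pos, df$ref, df$alt))
  anc <- co$truth$ancestral
  for (cal in co$config$callers) {
    k <- co$calls[co$calls$line_id == "ancestor" &
                    co$calls$caller_id == cal, ]
    expect_identical(truth_key(k), truth_key(anc))
  }
  one <- co$calls[co$calls$caller_id == "mpileup" & co$calls$line_id == "9S", ]
  expected <- rbind(anc[, c("chrom", "pos", "ref", "alt")],
                    co$truth$mutations[co$truth$mutations$line_id == "9S",
                                       c("chrom", "pos", "ref", "alt")])
  expect_identical(truth_key(one), truth_key(expected))
  # an ancestral variant appears in the ancestor and every line VCF
  v <- anc[1, ]
  for (l in c("ancestor", co$config$lines$line_id)) {
    k <- co$calls[co$calls$line_id == l & co$calls$caller_id == "varscan", ]
    expect_true(any(k$chrom == v$chrom & k$pos == v$pos & k$alt == v$alt))
  }
})

test_that("independent caller dropout multiplies: fn 0.5 x 2 callers ~ 25%", {
  cfg <- sim_config(seed = 9, n_chromosomes = 1L, chromosome_length = 150000L,
                    n_genes = 10L, planted_subset_size = 2L,
                    subset_hit_count = 0L,
                    line_class_counts = NULL,
                    mutations_per_line = list(mean = 0, dispersion = 1),
                    n_utr5_hits = 0L, n_promoter_hits = 0L,
                    ancestral_snps = 800L, ancestral_indels = 0L,
                    callers = c("a", "b"),
                    caller_fp_per_mb = c(a = 0, b = 0),
                    caller_fn_rate = c(a = 0.5, b = 0.5))
  co <- simulate_cohort(cfg)
  anc_calls <- co$calls[co$calls$line_id == "ancestor", ]
  both <- cross_verify(anc_calls, min_callers = 2L, depth_min = 0L)
  p_hat <- nrow(both) / 800
  expect_lt(abs(p_hat - 0.25), 3 * sqrt(0.25 * 0.75 / 800))
})

test_that("planted coverage events shape the emitted tracks", {
  cfg <- tiny_config()
  cfg$planted_coverage_events <- data.frame(
    line_id = c("9S", "16S"), chrom = "chr1",
    start = c(20000, 50000), end = c(25000, 52000), fold = c(0, 2),
    stringsAsFactors = FALSE)
  cfg$shared_absent_fraction <- 0
  co <- simulate_cohort(cfg)
  b9 <- co$coverage$tracks[["9S"]]$bins
  del <- b9[b9$chrom == "chr1" & b9$start >= 20000 & b9$end <= 25000, ]
  expect_equal(nrow(del), 5L)
  expect_true(all(del$mean_depth == 0))
  b16 <- co$coverage$tracks[["16S"]]$bins
  dup <- b16[b16$chrom == "chr1" & b16$start >= 50000 & b16$end <= 52000, ]
  expect_equal(nrow(dup), 2L)
  expect_lt(abs(mean(dup$mean_depth) - 166), 40)
  # a clean line shows no bins beyond thresholds
  b8 <- co$coverage$tracks[["8L"]]$bins
  fold <- b8$mean_depth / co$coverage$tracks[["8L"]]$genome_mean
  expect_false(any(fold > 1.8 | fold < 0.20))
  # overlapping events on one line are rejected
  cfg$planted_coverage_events <- data.frame(
    line_id = "9S", chrom = "chr1", start = c(1000, 1500),
    end = c(2000, 2500), fold = c(0, 0), stringsAsFactors = FALSE)
  expect_error(emit_coverage_tracks(cfg, co$reference), "overlap")
})

test_that("planted enrichment bias lifts the term's share of mutated genes", {
  co <- table1_cohort()
  pt <- co$config$planted_term
  carriers <- unique(co$go_table$gene_id[co$go_table$term_id == pt$term_id])
  genic <- co$truth$mutations[co$truth$mutations$class != "intergenic", ]
  q <- unique(genic$gene_id)
  bg_f <- mean(co$reference$genes$gene_id %in% carriers)
  expect_gt(mean(q %in% carriers), bg_f)   # oversampled above background
})
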