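# Shared fixtures: a noise-free cohort planted with the published per-line
# class counts, brute-force oracles, and small constructors. Everything is
# generated in code at test time.

.fixture_cache <- new.env(parent = emptyenv())

noise_free_config <- function(seed = 42) {
  sim_config(seed = seed, n_chromosomes = 2L, chromosome_length = 200000L,
             n_genes = 80L, planted_subset_size = 10L,
             caller_fp_per_mb = c(mpileup = 0, varscan = 0, pindel = 0),
             caller_fn_rate = c(mpileup = 0, varscan = 0, pindel = 0),
             shared_absent_fraction = 0.017)
}

table1_cohort <- function() {
  if (is.null(.fixture_cache$cohort)) {
    .fixture_cache$cohort <- simulate_cohort(noise_free_config())
  }
  .fixture_cache$cohort
}

# consensus -> partition -> annotation -> per-line summary, memoized
table1_pipeline <- function() {
  if (is.null(.fixture_cache$pipeline)) {
    co <- table1_cohort()
    consensus <- cross_verify(co$calls, min_callers = 2L, depth_min = 3L)
    part <- partition_ancestral_derived(consensus)
    ann <- annotate_variants(part$derived, co$reference)
    summ <- summarize_lines(ann, evolved_step_table())
    .fixture_cache$pipeline <- list(cohort = co, consensus = consensus,
                                    partition = part, annotations = ann,
                                    summary = summ)
  }
  .fixture_cache$pipeline
}

# ---- brute-force oracles -----------------------------------------------------

# exhaustive set-intersection consensus: loop over every distinct variant
oracle_consensus <- function(calls, min_callers, depth_min = 0) {
  key <- paste(calls$line_id, calls$chrom, calls$pos, calls$ref, calls$alt)
  out <- character(0)
  for (k in unique(key)) {
    rows <- calls[key == k, , drop = FALSE]
    if (length(unique(rows$caller_id)) >= min_callers &&
        max(rows$depth) >= depth_min) {
      out <- c(out, k)
    }
  }
  sort(out)
}

# exhaustive run/merge scan: every flagged bin starts as its own region,
# then any two same-direction regions within merge_gap are merged until no
# pair qualifies
oracle_regions <- function(track, high = 1.8, low = 0.20, min_length = 500,
                           merge_gap = 200) {
  gm <- track$genome_mean
  b <- track$bins
  fold <- b$mean_depth / gm
  dirn <- ifelse(fold > high, "high", ifelse(fold < low, "low", "none"))
  regs <- b[dirn != "none", c("chrom", "start", "end"), drop = FALSE]
  regs$direction <- dirn[dirn != "none"]
  repeat {
    merged <- FALSE
    if (nrow(regs) >= 2L) {
      for (i in seq_len(nrow(regs) - 1L)) {
        for (j in (i + 1L):nrow(regs)) {
          if (regs$chrom[i] == regs$chrom[j] &&
              regs$direction[i] == regs$direction[j]) {
            gap_lo <- min(regs$end[i], regs$end[j])
            gap_hi <- max(regs$start[i], regs$start[j])
            gap <- gap_hi - gap_lo
            # merging never jumps across another flagged region in the gap
            blocked <- any(vapply(seq_len(nrow(regs)), function(k) {
              k != i && k != j && regs$chrom[k] == regs$chrom[i] &&
                regs$end[k] > gap_lo && regs$start[k] < gap_hi
            }, logical(1L)))
            if (gap <= merge_gap && !blocked) {
              regs$start[i] <- min(regs$start[i], regs$start[j])
              regs$end[i] <- max(regs$end[i], regs$end[j])
              regs <- regs[-j, , drop = FALSE]
              merged <- TRUE
              break
            }
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  regs <- regs[(regs$end - regs$start) > min_length, , drop = FALSE]
  regs <- regs[order(regs$chrom, regs$start), , drop = FALSE]
  rownames(regs) <- NULL
  regs
}

random_track <- function(seed) {
  set.seed(seed)
  n <- sample(50:250, 1L)
  state <- sample(c("bg", "high", "low"), n, replace = TRUE,
                  prob = c(0.8, 0.1, 0.1))
  depth <- ifelse(state == "bg", 100, ifelse(state == "high",
                                             sample(c(190, 300, 500), n, TRUE),
                                             sample(c(0, 5, 15), n, TRUE)))
  bins <- data.frame(chrom = sample(c("chrA", "chrB"), n, TRUE),
                     start = NA_real_, end = NA_real_, mean_depth = depth)
  bins <- bins[order(bins$chrom), , drop = FALSE]
  for (ch in unique(bins$chrom)) {
    k <- sum(bins$chrom == ch)
    bins$start[bins$chrom == ch] <- (seq_len(k) - 1L) * 1000
    bins$end[bins$chrom == ch] <- seq_len(k) * 1000
  }
  coverage_track(bins, line_id = "x", genome_mean = 100)
}

# ---- strand-flip transform ---------------------------------------------------

revcomp_reference <- function(reference) {
  lens <- setNames(Biostrings::width(reference$seqs),
                   names(reference$seqs))
  seqs <- Biostrings::reverseComplement(reference$seqs)
  flip <- function(df) {
    L <- lens[df$chrom]
    s <- L - df$end + 1L
    e <- L - df$start + 1L
    df$start <- as.integer(s); df$end <- as.integer(e)
    df$strand <- ifelse(df$strand == "+", "-", "+")
    df
  }
  genes <- flip(reference$genes)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  list(seqs = seqs, genes = genes, features = flip(reference$features))
}

revcomp_snps <- function(variants, reference) {
  lens <- setNames(Biostrings::width(reference$seqs),
                   names(reference$seqs))
  stopifnot(all(variants$kind == "SNP"))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  variants$pos <- as.integer(lens[variants$chrom] - variants$pos + 1L)
  variants$ref <- unname(comp[variants$ref])
  variants$alt <- unname(comp[variants$alt])
  variants
}

# hand-built micro reference: one + strand and one - strand gene with known
# codons, the minus-strand gene split by an intron at a codon boundary
micro_reference <- function() {
  # plus gene: 5'UTR [11,20], CDS [21,32] = ATG GCT AAA TAA, 3'UTR [33,42]
  plus_cds <- "ATGGCTAAATAA"
  # minus gene: transcript CDS = ATG TCT GGG TAA, split 6|6 by intron;
  # genomic (revcomp, ascending) = revcomp(GGGTAA) intron revcomp(ATGTCT)
  minus_cds <- "ATGTCTGGGTAA"
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  seq <- paste0(
    strrep("C", 10),                  #   1-10  intergenic
    strrep("A", 10),                  #  11-20  utr5(+)
    plus_cds,                         #  21-32  CDS(+)
    strrep("G", 10),                  #  33-42  utr3(+)
    strrep("C", 58),                  #  43-100 intergenic
    strrep("A", 10),                  # 101-110 utr3(-)
    rc(substr(minus_cds, 7, 12)),     # 111-116 CDS(-) second coding half
    strrep("T", 8),                   # 117-124 intron(-)
    rc(substr(minus_cds, 1, 6)),      # 125-130 CDS(-) first coding half
    strrep("G", 10),                  # 131-140 utr5(-)
    strrep("C", 60))                  # 141-200 intergenic
  genes <- data.frame(
    gene_id = c("gplus", "gminus"), chrom = "chr1",
    strand = c("+", "-"), start = c(11L, 101L), end = c(42L, 140L),
    tss = c(11L, 140L), stringsAsFactors = FALSE)
  features <- data.frame(
    gene_id = c("gplus", "gplus", "gplus", "gplus",
                "gminus", "gminus", "gminus", "gminus", "gminus", "gminus"),
    chrom = "chr1",
    strand = c(rep("+", 4L), rep("-", 6L)),
    type = c("five_prime_UTR", "CDS", "three_prime_UTR", "exon",
             "three_prime_UTR", "CDS", "CDS", "five_prime_UTR",
             "exon", "exon"),
    start = c(11L, 21L, 33L, 11L, 101L, 111L, 125L, 131L, 101L, 125L),
    end = c(20L, 32L, 42L, 42L, 110L, 116L, 130L, 140L, 116L, 140L),
    stringsAsFactors = FALSE)
  list(seqs = Biostrings::DNAStringSet(c(chr1 = seq)), genes = genes,
       features = features)
}

snp <- function(chrom, pos, ref, alt, line_id = "l1") {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             kind = "SNP", line_id = line_id, stringsAsFactors = FALSE)
}

# universe + GO table at roughly the study's scale (10667 genes, ~44%
# annotated in the tested namespace, 15 terms, planted term at 12%)
make_go_table <- function(seed, n_genes = 10667, planted_freq = 0.12) {
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  ann <- sample(genes, round(0.44 * n_genes))
  nt <- 15L
  ids <- sprintf("GO:BP%04d", seq_len(nt))
  # GO-Slim terms are broad by construction: keep every term common enough
  # that 2x2 expected counts stay well away from zero
  extra <- lapply(seq_along(ann), function(i)
    sample.int(nt - 1L, 1L + (runif(1) < 0.4),
               prob = 1 / sqrt(seq_len(nt - 1L))) + 1L)
  df <- data.frame(gene_id = rep(ann, lengths(extra)),
                   namespace = "biological_process",
                   term_id = ids[unlist(extra)],
                   term_name = ids[unlist(extra)], stringsAsFactors = FALSE)
  carriers <- sample(ann, round(planted_freq * length(ann)))
  df <- rbind(df, data.frame(gene_id = carriers,
                             namespace = "biological_process",
                             term_id = ids[1L], term_name = ids[1L],
                             stringsAsFactors = FALSE))
  list(go = unique(df), universe = genes, planted = ids[1L])
}
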