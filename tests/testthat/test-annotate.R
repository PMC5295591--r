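# Mutation classification: genetic-code handling on both strands, the
# amino-acid severity scheme, regulatory tagging and the candidate filter.

test_that("the residue scheme partitions all 20 amino acids into 6 classes", {
  s <- aa_class_scheme()
  expect_equal(length(s), 20L)
  expect_equal(length(unique(s)), 6L)
  expect_setequal(names(s)[s == "hydrophilic_uncharged"], c("S", "N", "T", "Q"))
  expect_setequal(names(s)[s == "aliphatic_uncharged"],
                  c("A", "G", "V", "L", "I"))
  expect_setequal(names(s)[s == "nonpolar_uncharged"], c("C", "M", "P"))
  expect_setequal(names(s)[s == "acidic"], c("D", "E"))
  expect_setequal(names(s)[s == "basic"], c("K", "R", "H"))
  expect_setequal(names(s)[s == "aromatic"], c("F", "Y", "W"))
})

test_that("severity calls match the scheme and are symmetric", {
  expect_equal(classify_aa_change("K", "N"), "radical")
  expect_equal(classify_aa_change("Q", "P"), "radical")
  expect_equal(classify_aa_change("S", "F"), "radical")
  expect_equal(classify_aa_change("T", "I"), "radical")
  expect_equal(classify_aa_change("S", "T"), "conservative")
  expect_equal(classify_aa_change("D", "E"), "conservative")
  s <- aa_class_scheme()
  set.seed(1)
  for (i in 1:40) {
    pair <- sample(names(s), 2L)
    expect_equal(classify_aa_change(pair[1], pair[2]),
                 classify_aa_change(pair[2], pair[1]))
  }
  expect_error(classify_aa_change("B", "A"), "unsupported")
  expect_error(classify_aa_change("K", "*"), "unsupported")
})

# micro reference: + gene CDS ATG GCT AAA TAA at 21..32,
#                  - gene CDS ATG TCT GGG TAA split across 125..130 / 111..116
test_that("coding SNPs translate correctly on the plus strand", {
  ref <- micro_reference()
  # codon 2 GCT -> GCC: synonymous (A)
  a <- annotate_variants(snp("chr1", 26, "T", "C"), ref)
  expect_equal(a$mclass, "coding_synonymous")
  expect_equal(a$severity, "not_applicable")
  # codon 3 AAA -> AAC: K -> N, radical
  a <- annotate_variants(snp("chr1", 29, "A", "C"), ref)
  expect_equal(a$mclass, "coding_nonsynonymous")
  expect_equal(a$aa_from, "K"); expect_equal(a$aa_to, "N")
  expect_equal(a$severity, "radical")
  expect_equal(a$aa_pos, 3L)
  # codon 3 AAA -> TAA: premature stop, "coding other", radical
  a <- annotate_variants(snp("chr1", 27, "A", "T"), ref)
  expect_equal(a$mclass, "coding_other")
  expect_equal(a$severity, "radical")
})

test_that("coding SNPs translate correctly on the minus strand", {
  ref <- micro_reference()
  # minus CDS codon 2 TCT; its genomic third base is position 125 (= A on
  # the plus strand); A->G genomic is T->C on the transcript: TCT -> TCC (S)
  a <- annotate_variants(snp("chr1", 125, "A", "G"), ref)
  expect_equal(a$mclass, "coding_synonymous")
  # codon 3 GGG at genomic 114..116; G->C at transcript position 1 means
  # plus-strand base 116 C->G: GGG -> CGG (G -> R, radical)
  a <- annotate_variants(snp("chr1", 116, "C", "G"), ref)
  expect_equal(a$mclass, "coding_nonsynonymous")
  expect_equal(a$aa_from, "G"); expect_equal(a$aa_to, "R")
  expect_equal(a$severity, "radical")
  # intron of the minus gene
  a <- annotate_variants(snp("chr1", 120, "T", "A"), ref)
  expect_equal(a$mclass, "intron")
  expect_equal(a$gene_id, "gminus")
})

test_that("indels in CDS are 'coding other' and radical; UTRs are intergenic", {
  ref <- micro_reference()
  del1 <- data.frame(chrom = "chr1", pos = 24L, ref = "GC", alt = "G",
                     kind = "deletion", stringsAsFactors = FALSE)
  a <- annotate_variants(del1, ref)
  expect_equal(a$mclass, "coding_other")
  expect_equal(a$severity, "radical")
  ins3 <- data.frame(chrom = "chr1", pos = 24L, ref = "G", alt = "GAAT",
                     kind = "insertion", stringsAsFactors = FALSE)
  a <- annotate_variants(ins3, ref)
  expect_equal(a$mclass, "coding_other")   # in-frame codon insertion
  # 3'-UTR position: intergenic class, no tag
  a <- annotate_variants(snp("chr1", 35, "G", "A"), ref)
  expect_equal(a$mclass, "intergenic")
  expect_equal(a$regulatory_tag, "none")
})

test_that("regulatory tags: 5'-UTR, promoter window, strand-aware distance", {
  ref <- micro_reference()
  # inside the + gene 5'UTR
  a <- annotate_variants(snp("chr1", 15, "A", "G"), ref)
  expect_equal(a$mclass, "intergenic")
  expect_equal(a$regulatory_tag, "utr5")
  expect_equal(a$gene_id, "gplus")
  # 5 bp upstream of the + TSS (pos 6, TSS 11)
  a <- annotate_variants(snp("chr1", 6, "C", "T"), ref)
  expect_equal(a$regulatory_tag, "promoter")
  expect_equal(a$gene_id, "gplus")
  # upstream of the - TSS (TSS 140, upstream means larger coordinates)
  a <- annotate_variants(snp("chr1", 170, "C", "T"), ref)
  expect_equal(a$regulatory_tag, "promoter")
  expect_equal(a$gene_id, "gminus")
  # beyond the window
  t <- tag_regulatory(snp("chr1", 6, "C", "T"), ref, window_bp = 3L)
  expect_equal(t$regulatory_tag, "none")
})

test_that("every derived variant gets exactly one class; counts add up", {
  p <- table1_pipeline()
  ann <- p$annotations
  expect_true(all(ann$mclass %in% mutation_classes()))
  expect_equal(nrow(ann), 144L)
  expect_equal(sum(p$summary$class_matrix["all_mutations", ]), 144L)
  expect_equal(colSums(p$summary$class_matrix[mutation_classes(), ]),
               p$summary$class_matrix["all_mutations", ])
})

test_that("annotation recovers planted classes, severities and tags exactly", {
  co <- table1_cohort()
  truth <- co$truth$mutations
  ann <- annotate_variants(truth, co$reference)
  expect_equal(ann$mclass, truth$class)
  expect_equal(ann$severity, truth$severity)
  expect_equal(ann$regulatory_tag, truth$regulatory_tag)
  expect_equal(sum(ann$regulatory_tag == "utr5"), 5L)
  expect_equal(sum(ann$regulatory_tag == "promoter"), 8L)
  genic <- ann$mclass != "intergenic"
  expect_equal(ann$gene_id[genic], truth$gene_id[genic])
})

test_that("classification is invariant under reverse-complementation", {
  co <- table1_cohort()
  snps <- co$truth$mutations[co$truth$mutations$kind == "SNP", ]
  fwd <- annotate_variants(snps, co$reference)
  rc_ref <- revcomp_reference(co$reference)
  rc_snps <- revcomp_snps(snps, co$reference)
  rev <- annotate_variants(rc_snps, rc_ref)
  expect_equal(rev$mclass, fwd$mclass)
  expect_equal(rev$severity, fwd$severity)
  expect_equal(rev$aa_from, fwd$aa_from)
  expect_equal(rev$aa_to, fwd$aa_to)
  expect_equal(rev$regulatory_tag, fwd$regulatory_tag)
})

test_that("two-step candidate filter: protein-changing, then the interval", {
  co <- table1_cohort()
  ref <- co$reference
  g <- ref$genes[ref$genes$chrom == "chr1", ]
  g <- g[order(g$start), ]
  interval <- list(chrom = "chr1", start = g$start[1], end = g$end[12])
  # synthetic ancestor annotations: 390 protein-changing variants over many
  # genes, some inside the interval, plus non-protein-changing decoys
  set.seed(8)
  prot_genes <- sample(ref$genes$gene_id, 60, replace = TRUE)
  ann <- data.frame(
    chrom = ref$genes$chrom[match(prot_genes, ref$genes$gene_id)],
    pos = ref$genes$start[match(prot_genes, ref$genes$gene_id)] + 5L,
    mclass = sample(c("coding_nonsynonymous", "coding_other"), 60, TRUE),
    gene_id = prot_genes, stringsAsFactors = FALSE)
  decoys <- data.frame(chrom = "chr1", pos = 1:20, mclass = "intergenic",
                       gene_id = NA_character_, stringsAsFactors = FALSE)
  out <- filter_resistance_candidates(rbind(ann, decoys), ref, interval)
  expect_true(all(out$mclass %in% c("coding_nonsynonymous", "coding_other")))
  expect_true(all(out$gene_id %in% g$gene_id[1:12]))
  want <- unique(prot_genes[prot_genes %in% g$gene_id[1:12]])
  expect_setequal(unique(out$gene_id), want)
  expect_false(is.unsorted(out$pos))
  # no protein-changing variants -> empty result
  empty <- filter_resistance_candidates(decoys, ref, interval)
  expect_equal(nrow(empty), 0L)
  expect_error(filter_resistance_candidates(ann, ref,
                                            list(chrom = "chrX", start = 1,
                                                 end = 10)), "unknown")
})
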