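# Mutation planting, GO-table synthesis, pseudo-caller and coverage emission
# for the synthetic cohort. All ground truth is recorded alongside.

#' Plant derived mutations with known ground truth
#'
#' Realizes the configured class-by-line counts as concrete variants on the
#' synthetic reference: intergenic SNPs (optionally inside 5'-UTRs or
#' promoter windows), intronic SNPs, codon-aware synonymous and
#' nonsynonymous SNPs, and "coding other" events (frame-shift indels,
#' in-frame codon indels, stop gains). Exactly `subset_hit_count` mutations
#' are placed in the designated pathway subset (in distinct genes and
#' lines); all other genic mutations avoid subset genes. When a GO table
#' with a planted term is supplied, carriers of that term are oversampled
#' among mutated genes by the configured fold, planting a detectable
#' functional enrichment. Ancestral (pre-experiment) variants shared by the
#' ancestor and every line are planted at positions clear of the derived
#' set.
#'
#' @param config A [sim_config()].
#' @param reference Output of [generate_reference()].
#' @param go_table Optional output of [simulate_go_table()] for the
#'   planted-term bias.
#' @return A ground-truth list: `mutations` (one row per derived mutation
#'   with true class, gene, amino-acid change, severity, regulatory tag and
#'   subset flag), `ancestral`, `subset_genes`, `counts` (the realized
#'   class-by-line matrix).
#' @export
plant_mutations <- function(config, reference, go_table = NULL) {
  set.seed(config$seed + 2L)
  idx <- build_annotation_index(reference)
  classes <- mutation_classes()
  lines <- config$lines$line_id

  counts <- config$line_class_counts
  if (is.null(counts)) {
    totals <- rnbinom(length(lines), size = config$mutations_per_line$dispersion,
                      mu = config$mutations_per_line$mean)
    counts <- vapply(totals, function(tt)
      as.integer(rmultinom(1L, tt, config$class_mix[classes])),
      integer(length(classes)))
    dimnames(counts) <- list(classes, lines)
  } else {
    counts <- counts[classes, lines, drop = FALSE]
  }

  all_genes <- reference$genes$gene_id
  intron_genes <- unique(idx$introns$gene_id)
  if (sum(counts["intron", ]) > 0L && length(intron_genes) == 0L) {
    stop("intron mutations requested but gene models have no introns")
  }
  n_subset <- min(config$planted_subset_size, length(all_genes))
  subset_genes <- if (n_subset > 0L) sample(all_genes, n_subset) else character(0)

  term_genes <- character(0)
  pt <- config$planted_term
  if (!is.null(go_table) && !is.null(pt)) {
    term_genes <- unique(go_table$gene_id[go_table$term_id == pt$term_id &
                                            go_table$namespace == pt$namespace])
  }

  # assign the forced subset hits to distinct lines with nonsynonymous quota
  k <- config$subset_hit_count
  forced <- data.frame(line_id = character(0), gene_id = character(0))
  if (k > 0L) {
    if (length(subset_genes) < k) stop("subset smaller than subset_hit_count")
    cand_lines <- lines[counts["coding_nonsynonymous", ] > 0L]
    if (length(cand_lines) < k) {
      stop("not enough lines with nonsynonymous quota for the subset hits")
    }
    forced <- data.frame(line_id = sample(cand_lines, k),
                         gene_id = sample(subset_genes, k),
                         stringsAsFactors = FALSE)
  }

  # distribute the special intergenic placements (5'-UTR / promoter) over
  # lines in proportion to their intergenic quota
  interg_quota <- counts["intergenic", ]
  special <- c(rep("utr5", config$n_utr5_hits),
               rep("promoter", config$n_promoter_hits))
  if (length(special) > sum(interg_quota)) {
    stop("more utr5/promoter hits requested than intergenic mutations")
  }
  slot_lines <- rep(lines, interg_quota)
  special_assign <- if (length(special) > 0L) {
    data.frame(line_id = sample(slot_lines, length(special)),
               what = special, stringsAsFactors = FALSE)
  } else {
    data.frame(line_id = character(0), what = character(0))
  }

  interg_space <- intergenic_space(reference, config$promoter_window)
  ordinary_pool <- setdiff(all_genes, subset_genes)
  fold <- if (!is.null(pt)) pt$fold else 1
  pool_w <- ifelse(ordinary_pool %in% term_genes,
                   term_weight(fold, mean(ordinary_pool %in% term_genes)), 1)

  rows <- list(); ri <- 0L
  for (l in lines) {
    used <- new.env(parent = emptyenv())
    n_int <- counts["intron", l]; n_syn <- counts["coding_synonymous", l]
    n_non <- counts["coding_nonsynonymous", l]
    n_oth <- counts["coding_other", l]; n_ig <- counts["intergenic", l]
    fgenes <- forced$gene_id[forced$line_id == l]
    n_non_ord <- n_non - length(fgenes)

    # choose distinct target genes for this line
    ipool <- intersect(ordinary_pool, intron_genes)
    if (n_int > length(ipool)) stop("not enough intron-bearing genes")
    g_int <- if (n_int > 0L) sample(ipool, n_int,
      prob = pool_w[match(ipool, ordinary_pool)]) else character(0)
    rest_pool <- setdiff(ordinary_pool, g_int)
    n_rest <- n_syn + n_non_ord + n_oth
    if (n_rest > length(rest_pool)) stop("not enough genes for genic mutations")
    g_rest <- if (n_rest > 0L) sample(rest_pool, n_rest,
      prob = pool_w[match(rest_pool, ordinary_pool)]) else character(0)
    g_syn <- head(g_rest, n_syn)
    g_non <- c(fgenes, g_rest[seq_len(n_non_ord) + n_syn])
    g_oth <- tail(g_rest, n_oth)

    add <- function(v) { ri <<- ri + 1L; rows[[ri]] <<- v }
    for (g in g_int) add(synth_intron_snp(idx, g, l, used))
    for (g in g_syn) add(synth_codon_snp(idx, g, l, "synonymous", used))
    for (g in g_non) {
      v <- synth_codon_snp(idx, g, l, "nonsynonymous", used)
      v$subset_hit <- g %in% fgenes
      add(v)
    }
    for (g in g_oth) add(synth_coding_other(idx, g, l, used))
    sp <- special_assign$what[special_assign$line_id == l]
    n_plain <- n_ig - length(sp)
    for (w in sp) {
      if (w == "utr5") add(synth_utr5_snp(idx, reference, l, used))
      else add(synth_promoter_snp(idx, reference, l, config$promoter_window,
                                  used))
    }
    for (j in seq_len(n_plain)) {
      add(synth_intergenic_snp(idx, interg_space, l, used))
    }
  }
  mutations <- do.call(rbind, rows)
  if (is.null(mutations)) {
    mutations <- data.frame(line_id = character(), chrom = character(),
                            pos = integer(), ref = character(),
                            alt = character(), kind = character(),
                            class = character(), gene_id = character(),
                            aa_pos = integer(), aa_from = character(),
                            aa_to = character(), severity = character(),
                            regulatory_tag = character(),
                            subset_hit = logical(), stringsAsFactors = FALSE)
  } else {
    mutations$subset_hit[is.na(mutations$subset_hit)] <- FALSE
    rownames(mutations) <- NULL
  }

  ancestral <- plant_ancestral(config, reference, mutations)
  list(mutations = mutations, ancestral = ancestral,
       subset_genes = subset_genes, counts = counts)
}

# ---- placement helpers ------------------------------------------------------

# sampling weight for term carriers so their realized share among sampled
# genes is `fold` times their background frequency f:
# w f / (w f + (1 - f)) = fold * f  =>  w = fold (1 - f) / (1 - fold f)
term_weight <- function(fold, f) {
  if (fold * f >= 1) return(1e6)   # saturated: take carriers almost surely
  fold * (1 - f) / (1 - fold * f)
}

BASES <- c("A", "C", "G", "T")

claim_pos <- function(used, chrom, pos, span = 1L) {
  keys <- paste0(chrom, ":", pos:(pos + span - 1L))
  if (any(vapply(keys, function(k) !is.null(used[[k]]), logical(1L)))) {
    return(FALSE)
  }
  for (k in keys) used[[k]] <- TRUE
  TRUE
}

mut_row <- function(line_id, chrom, pos, ref, alt, kind, class, gene_id = NA,
                    aa_pos = NA, aa_from = NA, aa_to = NA,
                    severity = "not_applicable", regulatory_tag = "none") {
  data.frame(line_id = line_id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, kind = kind, class = class,
             gene_id = as.character(gene_id), aa_pos = as.integer(aa_pos),
             aa_from = as.character(aa_from), aa_to = as.character(aa_to),
             severity = severity, regulatory_tag = regulatory_tag,
             subset_hit = NA, stringsAsFactors = FALSE)
}

# genomic intervals more than promoter_window away from any gene
intergenic_space <- function(reference, promoter_window) {
  lens <- setNames(Biostrings::width(reference$seqs), names(reference$seqs))
  si <- GenomeInfoDb::Seqinfo(names(lens), lens)
  if (nrow(reference$genes) == 0L) {
    gr <- GenomicRanges::GRanges(names(lens), IRanges::IRanges(1L, lens),
                                 seqinfo = si)
    return(gr)
  }
  g <- reference$genes
  pad <- promoter_window + 1L
  occ <- GenomicRanges::GRanges(g$chrom,
                                IRanges::IRanges(pmax(1L, g$start - pad),
                                                 pmin(lens[g$chrom], g$end + pad)),
                                seqinfo = si)
  sp <- GenomicRanges::gaps(GenomicRanges::reduce(occ))
  sp[GenomicRanges::strand(sp) == "*"]   # gaps() also emits +/- placeholders
}

sample_from_space <- function(space) {
  w <- GenomicRanges::width(space)
  i <- sample.int(length(space), 1L, prob = w)
  list(chrom = as.character(GenomicRanges::seqnames(space)[i]),
       pos = GenomicRanges::start(space)[i] +
         sample.int(GenomicRanges::width(space)[i], 1L) - 1L)
}

snp_alt <- function(ref) sample(setdiff(BASES, ref), 1L)

synth_intergenic_snp <- function(idx, space, line_id, used) {
  for (try in 1:200) {
    p <- sample_from_space(space)
    if (!claim_pos(used, p$chrom, p$pos)) next
    ref <- idx$chrseq[[p$chrom]][p$pos]
    return(mut_row(line_id, p$chrom, p$pos, ref, snp_alt(ref), "SNP",
                   "intergenic"))
  }
  stop("could not place intergenic SNP")
}

synth_utr5_snp <- function(idx, reference, line_id, used) {
  u <- idx$utr5
  if (nrow(u) == 0L) stop("no 5'-UTRs available")
  for (try in 1:200) {
    r <- u[sample.int(nrow(u), 1L), ]
    pos <- r$start + sample.int(r$end - r$start + 1L, 1L) - 1L
    if (!claim_pos(used, r$chrom, pos)) next
    ref <- idx$chrseq[[r$chrom]][pos]
    return(mut_row(line_id, r$chrom, pos, ref, snp_alt(ref), "SNP",
                   "intergenic", gene_id = r$gene_id,
                   regulatory_tag = "utr5"))
  }
  stop("could not place 5'-UTR SNP")
}

synth_promoter_snp <- function(idx, reference, line_id, window, used) {
  g <- reference$genes
  lens <- setNames(Biostrings::width(reference$seqs), names(reference$seqs))
  for (try in 1:500) {
    r <- g[sample.int(nrow(g), 1L), ]
    d <- sample.int(window, 1L)
    pos <- if (r$strand == "+") r$tss - d else r$tss + d
    if (pos < 1L || pos > lens[r$chrom]) next
    # the gap between genes exceeds the window, so this is intergenic;
    # still ensure it is not nearer to a neighbouring TSS
    other <- g[g$chrom == r$chrom & g$gene_id != r$gene_id, , drop = FALSE]
    if (nrow(other) > 0L) {
      dd <- ifelse(other$strand == "+", other$tss - pos, pos - other$tss)
      if (any(dd > 0 & dd < d)) next
      if (any(pos >= other$start & pos <= other$end)) next
    }
    if (!claim_pos(used, r$chrom, pos)) next
    ref <- idx$chrseq[[r$chrom]][pos]
    return(mut_row(line_id, r$chrom, pos, ref, snp_alt(ref), "SNP",
                   "intergenic", gene_id = r$gene_id,
                   regulatory_tag = "promoter"))
  }
  stop("could not place promoter SNP")
}

synth_intron_snp <- function(idx, gene, line_id, used) {
  iv <- idx$introns[idx$introns$gene_id == gene, , drop = FALSE]
  if (nrow(iv) == 0L) stop("gene has no introns: ", gene)
  for (try in 1:200) {
    r <- iv[sample.int(nrow(iv), 1L), ]
    pos <- r$start + sample.int(r$end - r$start + 1L, 1L) - 1L
    if (!claim_pos(used, r$chrom, pos)) next
    ref <- idx$chrseq[[r$chrom]][pos]
    return(mut_row(line_id, r$chrom, pos, ref, snp_alt(ref), "SNP", "intron",
                   gene_id = gene))
  }
  stop("could not place intron SNP")
}

# enumerate the 9 single-base substitutions of a sense codon and return the
# subset matching the requested effect
codon_substitutions <- function(codon) {
  aa0 <- translate_codon(codon)
  out <- list()
  for (o in 1:3) {
    for (b in setdiff(BASES, codon[o])) {
      alt <- codon; alt[o] <- b
      aa1 <- translate_codon(alt)
      eff <- if (aa1 == aa0) "synonymous"
             else if (aa1 == "*") "stop_gain" else "nonsynonymous"
      out[[length(out) + 1L]] <- list(offset = o, base = b, aa_from = aa0,
                                      aa_to = aa1, effect = eff)
    }
  }
  out
}

synth_codon_snp <- function(idx, gene, line_id, effect, used,
                            class = c(synonymous = "coding_synonymous",
                                      nonsynonymous = "coding_nonsynonymous",
                                      stop_gain = "coding_other")[effect]) {
  map <- cds_map(idx, gene)
  ncod <- length(map$pos) %/% 3L
  for (try in 1:300) {
    ci <- sample.int(ncod - 1L, 1L)        # spare the terminal stop codon
    cod <- codon_at(idx, map, (ci - 1L) * 3L + 1L)
    subs <- codon_substitutions(cod$codon)
    subs <- Filter(function(s) s$effect == effect, subs)
    if (length(subs) == 0L) next
    s <- subs[[sample.int(length(subs), 1L)]]
    gpos <- cod$gpos[s$offset]
    if (!claim_pos(used, map$chrom, gpos)) next
    ref <- idx$chrseq[[map$chrom]][gpos]
    alt <- if (map$strand == "-") unname(complement_base(s$base)) else s$base
    sev <- switch(effect,
                  synonymous = "not_applicable",
                  stop_gain = "radical",
                  nonsynonymous = classify_aa_change(s$aa_from, s$aa_to))
    return(mut_row(line_id, map$chrom, gpos, ref, alt, "SNP", class,
                   gene_id = gene, aa_pos = ci, aa_from = s$aa_from,
                   aa_to = s$aa_to, severity = sev))
  }
  stop("could not place ", effect, " SNP in gene ", gene)
}

synth_coding_other <- function(idx, gene, line_id, used) {
  subtype <- sample(c("frameshift", "codon_indel", "stop_gain"), 1L,
                    prob = c(0.5, 0.25, 0.25))
  if (subtype == "stop_gain") {
    return(synth_codon_snp(idx, gene, line_id, "stop_gain", used))
  }
  map <- cds_map(idx, gene)
  cds <- idx$cds[idx$cds$gene_id == gene, , drop = FALSE]
  len <- if (subtype == "frameshift") sample(c(1L, 2L, 4L), 1L,
                                             prob = c(0.6, 0.3, 0.1)) else 3L
  insertion <- runif(1) < 0.5
  for (try in 1:300) {
    r <- cds[sample.int(nrow(cds), 1L), ]
    if (insertion) {
      # anchored insertion strictly inside the CDS interval, clear of the
      # terminal stop codon
      lo <- r$start; hi <- r$end - 1L
      if (map$strand == "+" && r$end == max(cds$end)) hi <- r$end - 4L
      if (map$strand == "-" && r$start == min(cds$start)) lo <- r$start + 3L
      if (hi < lo) next
      pos <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      if (!claim_pos(used, r$chrom, pos, span = 2L)) next
      anchor <- idx$chrseq[[r$chrom]][pos]
      ins <- paste(sample(BASES, len, replace = TRUE), collapse = "")
      return(mut_row(line_id, r$chrom, pos, anchor, paste0(anchor, ins),
                     "insertion", "coding_other", gene_id = gene,
                     severity = "radical"))
    } else {
      lo <- r$start; hi <- r$end - len + 1L
      if (map$strand == "+" && r$end == max(cds$end)) hi <- r$end - len - 2L
      if (map$strand == "-" && r$start == min(cds$start)) lo <- r$start + 3L
      if (hi < lo) next
      d <- lo + sample.int(hi - lo + 1L, 1L) - 1L   # first deleted base
      pos <- d - 1L
      if (pos < 1L) next
      if (!claim_pos(used, r$chrom, pos, span = len + 1L)) next
      ref <- paste(idx$chrseq[[r$chrom]][pos:(pos + len)], collapse = "")
      alt <- idx$chrseq[[r$chrom]][pos]
      return(mut_row(line_id, r$chrom, pos, ref, alt, "deletion",
                     "coding_other", gene_id = gene, severity = "radical"))
    }
  }
  stop("could not place coding indel in gene ", gene)
}

# ancestral (pre-experiment) variants, clear of all derived positions
plant_ancestral <- function(config, reference, mutations) {
  lens <- setNames(Biostrings::width(reference$seqs), names(reference$seqs))
  n_snp <- config$ancestral_snps; n_ind <- config$ancestral_indels
  n <- n_snp + n_ind
  if (n == 0L) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), kind = character(),
                      stringsAsFactors = FALSE))
  }
  chrseq <- lapply(as.character(reference$seqs), function(s)
    strsplit(s, "", fixed = TRUE)[[1L]])
  avoid <- new.env(parent = emptyenv())
  if (nrow(mutations) > 0L) {
    for (i in seq_len(nrow(mutations))) {
      span <- max(nchar(mutations$ref[i]), 2L) + 12L
      for (p in (mutations$pos[i] - 12L):(mutations$pos[i] + span)) {
        avoid[[paste0(mutations$chrom[i], ":", p)]] <- TRUE
      }
    }
  }
  kinds <- c(rep("SNP", n_snp), rep("indel", n_ind))
  rows <- vector("list", n)
  total <- sum(as.numeric(lens))
  for (i in seq_len(n)) {
    for (try in 1:500) {
      chrom <- sample(names(lens), 1L, prob = lens)
      pos <- sample.int(lens[[chrom]] - 10L, 1L)
      if (!claim_pos(avoid, chrom, pos, span = 8L)) next
      if (kinds[i] == "SNP") {
        ref <- chrseq[[chrom]][pos]
        rows[[i]] <- data.frame(chrom = chrom, pos = pos, ref = ref,
                                alt = snp_alt(ref), kind = "SNP",
                                stringsAsFactors = FALSE)
      } else if (runif(1) < 0.5) {  # deletion
        len <- sample.int(6L, 1L)
        ref <- paste(chrseq[[chrom]][pos:(pos + len)], collapse = "")
        rows[[i]] <- data.frame(chrom = chrom, pos = pos, ref = ref,
                                alt = chrseq[[chrom]][pos], kind = "deletion",
                                stringsAsFactors = FALSE)
      } else {                      # insertion
        len <- sample.int(6L, 1L)
        anchor <- chrseq[[chrom]][pos]
        rows[[i]] <- data.frame(chrom = chrom, pos = pos, ref = anchor,
                                alt = paste0(anchor,
                                             paste(sample(BASES, len,
                                                          replace = TRUE),
                                                   collapse = "")),
                                kind = "insertion", stringsAsFactors = FALSE)
      }
      break
    }
    if (is.null(rows[[i]])) stop("could not place ancestral variant")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthesize a gene-to-GO-Slim annotation table
#'
#' Assigns high-level terms to genes per namespace, leaving the configured
#' fraction of genes unannotated, with skewed (rank-weighted) term
#' frequencies. The planted term of `config$planted_term` is given a
#' controlled background frequency so enrichment against it is well defined.
#'
#' @param config A [sim_config()].
#' @param reference Output of [generate_reference()].
#' @return data.frame `gene_id`, `namespace`, `term_id`, `term_name`.
#' @export
simulate_go_table <- function(config, reference) {
  set.seed(config$seed + 1L)
  genes <- reference$genes$gene_id
  nt <- config$go_terms_per_namespace
  pt <- config$planted_term
  rows <- list()
  for (ns in names(config$go_missing)) {
    miss <- config$go_missing[[ns]]
    ann <- sample(genes, round((1 - miss) * length(genes)))
    abbr <- toupper(substr(gsub("(^|_)(\\w)", "\\2", ns), 1L, 2L))
    ids <- sprintf("GO:%s%04d", abbr, seq_len(nt))
    nms <- paste(gsub("_", " ", ns), "term", seq_len(nt))
    # Slim terms are broad, high-level categories: keep frequencies flat-ish
    w <- 1 / sqrt(seq_len(nt))
    n_terms <- 1L + (runif(length(ann)) < 0.4)
    gene_terms <- lapply(seq_along(ann), function(i)
      sample.int(nt, n_terms[i], prob = w))
    df <- data.frame(
      gene_id = rep(ann, n_terms),
      namespace = ns,
      term_id = ids[unlist(gene_terms)],
      term_name = nms[unlist(gene_terms)],
      stringsAsFactors = FALSE)
    if (!is.null(pt) && ns == pt$namespace) {
      carriers <- sample(ann, round(pt$background_frequency * length(ann)))
      if (length(carriers) > 0L) {
        df <- rbind(df, data.frame(gene_id = carriers, namespace = ns,
                                   term_id = pt$term_id,
                                   term_name = pt$term_name,
                                   stringsAsFactors = FALSE))
      }
    }
    rows[[ns]] <- unique(df)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sample a query gene list with an optional planted term bias
#'
#' Draws `n_query` distinct genes from the universe; genes carrying
#' `planted_term` (looked up in `go_table`) are oversampled by `fold`,
#' emulating a mutated-gene list enriched for one functional class. With
#' `fold = 1` the draw is uniform (a null cohort).
#'
#' @param go_table data.frame as from [simulate_go_table()].
#' @param universe Character vector of all gene ids.
#' @param n_query Number of genes to draw.
#' @param planted_term,namespace Term to bias toward (NULL for none).
#' @param fold Sampling weight multiplier for carriers.
#' @return Character vector of gene ids.
#' @export
simulate_query_genes <- function(go_table, universe, n_query,
                                 planted_term = NULL,
                                 namespace = "biological_process",
                                 fold = 1) {
  w <- rep(1, length(universe))
  if (!is.null(planted_term)) {
    carriers <- unique(go_table$gene_id[go_table$term_id == planted_term &
                                          go_table$namespace == namespace])
    is_c <- universe %in% carriers
    w[is_c] <- term_weight(fold, mean(is_c))
  }
  sample(universe, n_query, prob = w)
}

#' Emit per-(line, caller) variant calls with configurable error rates
#'
#' The truth of each evolved line is its derived set plus every ancestral
#' variant; the ancestor carries the ancestral set only. Each pseudo-caller
#' independently misses a true variant with its false-negative rate and adds
#' spurious SNPs at its false-positive rate per Mb. Depths are Poisson
#' around the configured coverage mean.
#'
#' @param truth Output of [plant_mutations()].
#' @param reference Output of [generate_reference()].
#' @param config A [sim_config()].
#' @return data.frame of raw calls (`line_id` including `"ancestor"`,
#'   `caller_id`, `chrom`, `pos`, `ref`, `alt`, `kind`, `depth`, `quality`)
#'   ready for [cross_verify()].
#' @export
emit_caller_vcfs <- function(truth, reference, config) {
  set.seed(config$seed + 3L)
  lens <- setNames(Biostrings::width(reference$seqs), names(reference$seqs))
  genome_mb <- sum(as.numeric(lens)) / 1e6
  chrseq <- lapply(as.character(reference$seqs), function(s)
    strsplit(s, "", fixed = TRUE)[[1L]])
  cols <- c("chrom", "pos", "ref", "alt", "kind")
  line_truth <- c(
    list(ancestor = truth$ancestral[, cols, drop = FALSE]),
    setNames(lapply(config$lines$line_id, function(l) {
      rbind(truth$ancestral[, cols, drop = FALSE],
            truth$mutations[truth$mutations$line_id == l, cols, drop = FALSE])
    }), config$lines$line_id))

  out <- list()
  for (sample_id in names(line_truth)) {
    tv <- line_truth[[sample_id]]
    for (cal in config$callers) {
      fn <- config$caller_fn_rate[[cal]]
      keep <- if (nrow(tv) > 0L) runif(nrow(tv)) >= fn else logical(0)
      calls <- tv[keep, , drop = FALSE]
      n_fp <- rpois(1L, config$caller_fp_per_mb[[cal]] * genome_mb)
      if (n_fp > 0L) {
        chroms <- sample(names(lens), n_fp, replace = TRUE, prob = lens)
        pos <- vapply(chroms, function(ch) sample.int(lens[[ch]], 1L),
                      integer(1L))
        ref <- mapply(function(ch, p) chrseq[[ch]][p], chroms, pos)
        alt <- vapply(ref, snp_alt, character(1L))
        calls <- rbind(calls, data.frame(chrom = chroms, pos = pos, ref = ref,
                                         alt = alt, kind = "SNP",
                                         stringsAsFactors = FALSE))
      }
      if (nrow(calls) > 0L) {
        calls$line_id <- sample_id
        calls$caller_id <- cal
        calls$depth <- rpois(nrow(calls), config$coverage_mean)
        calls$quality <- round(runif(nrow(calls), 30, 60))
        out[[paste(sample_id, cal)]] <- calls
      }
    }
  }
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  calls[, c("line_id", "caller_id", "chrom", "pos", "ref", "alt", "kind",
            "depth", "quality")]
}

#' Emit binned coverage tracks with planted anomalies
#'
#' Background bin depths are Poisson around the configured mean; planted
#' events scale the Poisson mean by their fold over their interval (weighted
#' by overlap for partial bins). Events with `line_id = "all"` apply to the
#' ancestor and every line, emulating sequence absent from all samples
#' relative to the reference assembly. When no events are configured, shared
#' absent regions covering `shared_absent_fraction` of the genome are
#' auto-planted (clear of all planted variants), plus one line-private
#' deletion and one duplication.
#'
#' @param config A [sim_config()].
#' @param reference Output of [generate_reference()].
#' @param truth Output of [plant_mutations()] (positions to avoid when
#'   auto-planting).
#' @return list with `tracks` (named list of `coverage_track`, ancestor
#'   included) and `events` (the planted events, 0-based half-open).
#' @export
emit_coverage_tracks <- function(config, reference, truth = NULL) {
  set.seed(config$seed + 4L)
  lens <- setNames(Biostrings::width(reference$seqs), names(reference$seqs))
  events <- config$planted_coverage_events
  if (is.null(events)) events <- auto_coverage_events(config, lens, truth)
  validate_coverage_events(events, lens, config$lines$line_id)

  samples <- c("ancestor", config$lines$line_id)
  bw <- config$coverage_bin
  tracks <- lapply(samples, function(s) {
    ev <- events[events$line_id %in% c("all", s), , drop = FALSE]
    bins <- do.call(rbind, lapply(names(lens), function(ch) {
      starts <- seq(0L, lens[[ch]] - 1L, by = bw)
      ends <- pmin(starts + bw, lens[[ch]])
      lambda <- rep(config$coverage_mean, length(starts))
      eh <- ev[ev$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(eh))) {
        ov <- pmin(ends, eh$end[i]) - pmax(starts, eh$start[i])
        ov <- pmax(ov, 0) / (ends - starts)
        lambda <- lambda * (1 - ov + ov * eh$fold[i])
      }
      data.frame(chrom = ch, start = starts, end = ends,
                 mean_depth = rpois(length(starts), lambda),
                 partial = (ends - starts) < bw, stringsAsFactors = FALSE)
    }))
    rownames(bins) <- NULL
    coverage_track(bins, line_id = s,
                   genome_mean = sum(bins$mean_depth *
                                       (bins$end - bins$start)) /
                     sum(bins$end - bins$start))
  })
  names(tracks) <- samples
  list(tracks = tracks, events = events)
}

auto_coverage_events <- function(config, lens, truth) {
  bw <- config$coverage_bin
  total_bp <- round(config$shared_absent_fraction * sum(as.numeric(lens)))
  ev <- list()
  if (total_bp > 0) {
    # whole-bin-aligned regions of >= 2 bins so the scan recovers them fully
    sizes <- pmax(2L * bw, round(total_bp * c(0.6, 0.3, 0.1) / bw) * bw)
    while (length(sizes) > 1L && sum(sizes) > total_bp + bw) {
      sizes <- sizes[-length(sizes)]
    }
    # keep the planted derived mutations out of zero-coverage regions;
    # ancestral variants are genome-wide background and are not coupled to
    # the coverage layer
    vpos <- if (!is.null(truth)) {
      data.frame(chrom = truth$mutations$chrom, pos = truth$mutations$pos)
    } else {
      data.frame(chrom = character(), pos = integer())
    }
    for (sz in sizes[sizes > 0]) {
      for (try in 1:200) {
        ch <- sample(names(lens), 1L, prob = lens)
        if (lens[[ch]] <= sz + 2L * bw) next
        st <- sample.int((lens[[ch]] - sz) %/% bw - 1L, 1L) * bw
        hit <- vpos$chrom == ch & vpos$pos > st & vpos$pos <= st + sz
        over <- vapply(ev, function(e)
          e$chrom == ch && st < e$end && st + sz > e$start, logical(1L))
        # keep clear of the fixed line-private events planted below
        if (ch == names(lens)[1L] && st < 35000 && st + sz > 8000) next
        if (any(hit) || any(over)) next
        ev[[length(ev) + 1L]] <- data.frame(line_id = "all", chrom = ch,
                                            start = st, end = st + sz,
                                            fold = 0, stringsAsFactors = FALSE)
        break
      }
    }
  }
  if (length(config$lines$line_id) >= 2L) {
    ch <- names(lens)[1L]
    ev[[length(ev) + 1L]] <- data.frame(
      line_id = config$lines$line_id[1L], chrom = ch,
      start = 10000, end = 15000, fold = 0, stringsAsFactors = FALSE)
    ev[[length(ev) + 1L]] <- data.frame(
      line_id = config$lines$line_id[2L], chrom = ch,
      start = 30000, end = 33000, fold = 2, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, ev)
  if (is.null(out)) {
    out <- data.frame(line_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), fold = numeric(),
                      stringsAsFactors = FALSE)
  }
  out
}

validate_coverage_events <- function(events, lens, line_ids) {
  if (nrow(events) == 0L) return(invisible(TRUE))
  bad <- !events$line_id %in% c("all", line_ids)
  if (any(bad)) stop("coverage event for unknown line: ",
                     paste(unique(events$line_id[bad]), collapse = ", "))
  if (any(!events$chrom %in% names(lens)) ||
      any(events$start < 0) || any(events$end > lens[events$chrom])) {
    stop("coverage event outside chromosome bounds")
  }
  for (l in line_ids) {
    e <- events[events$line_id %in% c("all", l), , drop = FALSE]
    e <- e[order(e$chrom, e$start), , drop = FALSE]
    if (nrow(e) > 1L) {
      same <- e$chrom[-1L] == e$chrom[-nrow(e)]
      if (any(same & e$start[-1L] < e$end[-nrow(e)])) {
        stop("overlapping coverage events planted for line ", l)
      }
    }
  }
  invisible(TRUE)
}

#' Simulate a complete synthetic cohort
#'
#' Chains [generate_reference()], [simulate_go_table()],
#' [plant_mutations()], [emit_caller_vcfs()] and [emit_coverage_tracks()]
#' into one in-memory cohort with full ground truth. Identical configs
#' (including the seed) produce identical cohorts.
#'
#' @param config A [sim_config()].
#' @return A `compwalk_cohort`: list with `config`, `reference`, `go_table`,
#'   `truth`, `calls`, `coverage` (tracks + events) and `step_table`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  reference <- generate_reference(config)
  go_table <- simulate_go_table(config, reference)
  truth <- plant_mutations(config, reference, go_table)
  calls <- emit_caller_vcfs(truth, reference, config)
  coverage <- emit_coverage_tracks(config, reference, truth)
  cohort <- list(config = config, reference = reference, go_table = go_table,
                 truth = truth, calls = calls, coverage = coverage,
                 step_table = config$step_table)
  class(cohort) <- "compwalk_cohort"
  cohort
}

#' @export
print.compwalk_cohort <- function(x, ...) {
  cat("Synthetic evolve-and-resequence cohort\n")
  cat("  genome: ", x$config$n_chromosomes, " chromosome(s) x ",
      x$config$chromosome_length, " bp, ", nrow(x$reference$genes),
      " genes\n", sep = "")
  cat("  lines:  ", paste(x$config$lines$line_id, collapse = ", "), "\n",
      sep = "")
  cat("  derived mutations planted: ", nrow(x$truth$mutations),
      "; ancestral variants: ", nrow(x$truth$ancestral), "\n", sep = "")
  cat("  callers: ", paste(x$config$callers, collapse = ", "), "\n", sep = "")
  invisible(x)
}
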