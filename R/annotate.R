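#' Physicochemical amino-acid classification scheme
#'
#' Partitions the twenty standard residues into six classes: hydrophilic
#' uncharged (S, N, T, Q), aliphatic uncharged (A, G, V, L, I), nonpolar
#' uncharged (C, M, P), acidic (D, E), basic (K, R, H) and aromatic
#' (F, Y, W). Replacements within a class are conservative, replacements
#' across classes are radical.
#'
#' @return Named character vector mapping residue letter to class label.
#' @export
aa_class_scheme <- function() {
  c(S = "hydrophilic_uncharged", N = "hydrophilic_uncharged",
    T = "hydrophilic_uncharged", Q = "hydrophilic_uncharged",
    A = "aliphatic_uncharged", G = "aliphatic_uncharged",
    V = "aliphatic_uncharged", L = "aliphatic_uncharged",
    I = "aliphatic_uncharged",
    C = "nonpolar_uncharged", M = "nonpolar_uncharged",
    P = "nonpolar_uncharged",
    D = "acidic", E = "acidic",
    K = "basic", R = "basic", H = "basic",
    F = "aromatic", Y = "aromatic", W = "aromatic")
}

#' Classify an amino-acid replacement as conservative or radical
#'
#' @param from,to Single-letter codes of the original and replacement residue.
#' @param scheme Residue-to-class map, by default [aa_class_scheme()].
#' @return `"conservative"` if both residues fall in the same physicochemical
#'   class, `"radical"` otherwise.
#' @examples
#' classify_aa_change("K", "N")  # radical (basic vs hydrophilic uncharged)
#' classify_aa_change("S", "T")  # conservative
#' @export
classify_aa_change <- function(from, to, scheme = aa_class_scheme()) {
  stopifnot(length(from) == 1L, length(to) == 1L)
  if (!from %in% names(scheme) || !to %in% names(scheme)) {
    stop("unsupported residue letter: ",
         paste(setdiff(c(from, to), names(scheme)), collapse = ", "))
  }
  if (scheme[[from]] == scheme[[to]]) "conservative" else "radical"
}

# ---- gene-model helpers ----------------------------------------------------

# Intron intervals of one gene: gaps between its exons.
gene_introns <- function(features) {
  ex <- features[features$type == "exon", , drop = FALSE]
  out <- lapply(split(ex, ex$gene_id), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2L) return(NULL)
    data.frame(gene_id = e$gene_id[1L], chrom = e$chrom[1L],
               strand = e$strand[1L],
               start = head(e$end, -1L) + 1L, end = tail(e$start, -1L) - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

feature_granges <- function(df) {
  if (nrow(df) == 0L) {
    return(GenomicRanges::GRanges())
  }
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  gr$gene_id <- df$gene_id
  gr
}

# Prebuilt overlap index over a reference bundle; avoids rebuilding GRanges
# per variant. Chromosome sequences cached as plain character vectors.
build_annotation_index <- function(reference) {
  feats <- reference$features
  cds <- feats[feats$type == "CDS", , drop = FALSE]
  utr5 <- feats[feats$type == "five_prime_UTR", , drop = FALSE]
  introns <- gene_introns(feats)
  chrseq <- lapply(as.character(reference$seqs), function(s)
    strsplit(s, "", fixed = TRUE)[[1L]])
  list(
    cds = cds, utr5 = utr5, introns = introns,
    gr_cds = feature_granges(cds),
    gr_utr5 = feature_granges(utr5),
    gr_intron = feature_granges(introns),
    genes = reference$genes,
    chrseq = chrseq,
    cds_maps = new.env(parent = emptyenv())
  )
}

# Map of one gene's CDS: genomic positions in translation order (5'->3' of
# the mRNA), so position i of the vector is coding position i.
cds_map <- function(idx, gene_id) {
  cached <- idx$cds_maps[[gene_id]]
  if (!is.null(cached)) return(cached)
  cd <- idx$cds[idx$cds$gene_id == gene_id, , drop = FALSE]
  if (nrow(cd) == 0L) stop("gene has no CDS: ", gene_id)
  cd <- cd[order(cd$start), , drop = FALSE]
  pos <- unlist(lapply(seq_len(nrow(cd)), function(i) cd$start[i]:cd$end[i]),
                use.names = FALSE)
  strand <- cd$strand[1L]
  if (strand == "-") pos <- rev(pos)
  if (length(pos) %% 3L != 0L) {
    stop("incomplete CDS (length not a multiple of 3) for gene ", gene_id)
  }
  m <- list(pos = pos, chrom = cd$chrom[1L], strand = strand)
  idx$cds_maps[[gene_id]] <- m
  m
}

complement_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]
}

# Reference codon (mRNA sense) containing coding position cpos, plus the
# offset of cpos within it.
codon_at <- function(idx, map, cpos) {
  ci <- (cpos - 1L) %/% 3L
  offs <- (cpos - 1L) %% 3L + 1L
  gpos <- map$pos[(ci * 3L + 1L):(ci * 3L + 3L)]
  bases <- idx$chrseq[[map$chrom]][gpos]
  if (map$strand == "-") bases <- unname(complement_base(bases))
  list(codon = bases, offset = offs, index = ci + 1L, gpos = gpos)
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[paste(codon, collapse = "")])
}

#' Classify derived variants by genomic context and protein effect
#'
#' Assigns each variant exactly one mutation class: `intergenic` (including
#' untranslated regions), `intron`, `coding_synonymous`,
#' `coding_nonsynonymous` or `coding_other` (frame-shift, in-frame codon
#' indel, stop gained or stop lost). Coding SNPs are translated through the
#' standard genetic code with strand handling; nonsynonymous changes receive
#' a conservative/radical severity from [classify_aa_change()], and all
#' `coding_other` events are radical. Intergenic variants are screened for
#' regulatory context with [tag_regulatory()].
#'
#' A variant overlapping a CDS boundary is classified by the affected CDS
#' base if there is one, otherwise as intron/intergenic. For anchored VCF
#' indels, the affected footprint is the deleted bases (`pos+1 ...`) or the
#' insertion point.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `kind` (`"SNP"`, `"insertion"`, `"deletion"`); extra columns such
#'   as `line_id` are carried through.
#' @param reference A reference bundle as produced by [generate_reference()]
#'   or [read_cohort()]: a list with `seqs` (DNAStringSet), `genes` and
#'   `features` data.frames.
#' @param promoter_window Width in bp of the upstream window used for the
#'   promoter tag (default 100).
#' @return The input data.frame with columns `mclass`, `gene_id`, `aa_pos`,
#'   `aa_from`, `aa_to`, `severity` (`"conservative"`, `"radical"` or
#'   `"not_applicable"`) and `regulatory_tag` (`"none"`, `"utr5"`,
#'   `"promoter"`) appended.
#' @export
annotate_variants <- function(variants, reference, promoter_window = 100L) {
  idx <- build_annotation_index(reference)
  n <- nrow(variants)
  mclass <- character(n); gene_id <- rep(NA_character_, n)
  aa_pos <- rep(NA_integer_, n)
  aa_from <- rep(NA_character_, n); aa_to <- rep(NA_character_, n)
  severity <- rep("not_applicable", n)
  regulatory_tag <- rep("none", n)

  if (n == 0L) {
    out <- variants
    out$mclass <- character(0); out$gene_id <- character(0)
    out$aa_pos <- integer(0); out$aa_from <- character(0)
    out$aa_to <- character(0); out$severity <- character(0)
    out$regulatory_tag <- character(0)
    return(out)
  }

  chrlens <- setNames(Biostrings::width(reference$seqs),
                      names(reference$seqs))
  if (any(!variants$chrom %in% names(chrlens))) {
    stop("variant on unknown chromosome: ",
         paste(unique(setdiff(variants$chrom, names(chrlens))), collapse = ", "))
  }
  foot <- variant_footprint(variants)
  gr_var <- GenomicRanges::GRanges(variants$chrom,
                                   IRanges::IRanges(foot$start, foot$end))
  hit_cds <- GenomicRanges::findOverlaps(gr_var, idx$gr_cds, select = "first")
  hit_int <- GenomicRanges::findOverlaps(gr_var, idx$gr_intron, select = "first")

  for (i in seq_len(n)) {
    kind <- variants$kind[i]
    if (!is.na(hit_cds[i])) {
      gid <- idx$gr_cds$gene_id[hit_cds[i]]
      gene_id[i] <- gid
      if (kind == "SNP") {
        map <- cds_map(idx, gid)
        cpos <- match(variants$pos[i], map$pos)
        cod <- codon_at(idx, map, cpos)
        alt_b <- variants$alt[i]
        if (map$strand == "-") alt_b <- unname(complement_base(alt_b))
        alt_codon <- cod$codon
        alt_codon[cod$offset] <- alt_b
        aa1 <- translate_codon(cod$codon)
        aa2 <- translate_codon(alt_codon)
        if (identical(aa1, aa2)) {
          mclass[i] <- "coding_synonymous"
        } else if (aa1 == "*" || aa2 == "*") {
          mclass[i] <- "coding_other"   # stop gained / stop lost
          severity[i] <- "radical"
          aa_pos[i] <- cod$index; aa_from[i] <- aa1; aa_to[i] <- aa2
        } else {
          mclass[i] <- "coding_nonsynonymous"
          severity[i] <- classify_aa_change(aa1, aa2)
          aa_pos[i] <- cod$index; aa_from[i] <- aa1; aa_to[i] <- aa2
        }
      } else {
        # frame-shift or in-frame codon indel: radical by definition
        mclass[i] <- "coding_other"
        severity[i] <- "radical"
      }
    } else if (!is.na(hit_int[i])) {
      mclass[i] <- "intron"
      gene_id[i] <- idx$gr_intron$gene_id[hit_int[i]]
    } else {
      mclass[i] <- "intergenic"
    }
  }

  inter <- which(mclass == "intergenic")
  if (length(inter) > 0L) {
    tags <- tag_regulatory(variants[inter, , drop = FALSE], reference,
                           window_bp = promoter_window)
    regulatory_tag[inter] <- tags$regulatory_tag
    gene_id[inter] <- ifelse(tags$regulatory_tag == "none",
                             NA_character_, tags$gene_id)
  }

  out <- variants
  out$mclass <- mclass
  out$gene_id <- gene_id
  out$aa_pos <- aa_pos
  out$aa_from <- aa_from
  out$aa_to <- aa_to
  out$severity <- severity
  out$regulatory_tag <- regulatory_tag
  out
}

# 1-based inclusive genomic footprint of each variant.
variant_footprint <- function(variants) {
  start <- variants$pos
  end <- variants$pos
  del <- variants$kind == "deletion"
  ins <- variants$kind == "insertion"
  # anchored representation: deleted bases follow the anchor base
  start[del] <- variants$pos[del] + 1L
  end[del] <- variants$pos[del] + nchar(variants$ref[del]) - 1L
  end[ins] <- variants$pos[ins] + 1L   # insertion point spans the two flanks
  list(start = start, end = end)
}

#' Tag intergenic/UTR variants as 5'-UTR or promoter candidates
#'
#' A variant is tagged `utr5` if it lies inside an annotated 5'-UTR, and
#' `promoter` if it lies within `window_bp` bases upstream (strand-aware) of
#' a transcription start site; otherwise `none`. A variant upstream of two
#' genes is assigned to the nearer TSS.
#'
#' @param variants data.frame with `chrom` and `pos`.
#' @param reference Reference bundle (see [annotate_variants()]).
#' @param window_bp Upstream window size in bp (default 100).
#' @return data.frame with columns `regulatory_tag` and `gene_id`.
#' @export
tag_regulatory <- function(variants, reference, window_bp = 100L) {
  feats <- reference$features
  genes <- reference$genes
  n <- nrow(variants)
  tag <- rep("none", n); gid <- rep(NA_character_, n)
  if (n == 0L) return(data.frame(regulatory_tag = tag, gene_id = gid))

  utr5 <- feats[feats$type == "five_prime_UTR", , drop = FALSE]
  if (nrow(utr5) > 0L) {
    gr_u <- feature_granges(utr5)
    gr_v <- GenomicRanges::GRanges(variants$chrom,
                                   IRanges::IRanges(variants$pos, variants$pos))
    hit <- GenomicRanges::findOverlaps(gr_v, gr_u, select = "first")
    tag[!is.na(hit)] <- "utr5"
    gid[!is.na(hit)] <- gr_u$gene_id[hit[!is.na(hit)]]
  }

  rest <- which(tag == "none")
  for (i in rest) {
    g <- genes[genes$chrom == variants$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    # strand-aware distance from the variant to each TSS, upstream side only
    d <- ifelse(g$strand == "+", g$tss - variants$pos[i],
                variants$pos[i] - g$tss)
    ok <- d > 0 & d <= window_bp
    if (any(ok)) {
      j <- which(ok)[which.min(d[ok])]
      tag[i] <- "promoter"
      gid[i] <- g$gene_id[j]
    }
  }
  data.frame(regulatory_tag = tag, gene_id = gid, stringsAsFactors = FALSE)
}

#' Two-step filter for resistance-candidate genes
#'
#' Step one retains only protein-changing variants (`coding_nonsynonymous`
#' or `coding_other`); step two intersects the affected genes with a genetic
#' mapping interval (for the study system, the region between the centromere
#' and the cys2 marker on linkage group III, supplied here as explicit
#' coordinates). Intended for the ancestor-vs-reference variant set when
#' searching for the resistance determinant.
#'
#' @param annotations Output of [annotate_variants()].
#' @param reference Reference bundle (gene coordinates).
#' @param interval list or vector with `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @return data.frame of candidate genes (one row per gene/variant pair)
#'   ordered by position, with the annotation columns attached.
#' @export
filter_resistance_candidates <- function(annotations, reference, interval) {
  chrom <- as.character(interval[["chrom"]])
  start <- as.numeric(interval[["start"]]); end <- as.numeric(interval[["end"]])
  if (!chrom %in% unique(reference$genes$chrom)) {
    stop("interval on unknown chromosome: ", chrom)
  }
  prot <- annotations[annotations$mclass %in%
                        c("coding_nonsynonymous", "coding_other"), , drop = FALSE]
  if (nrow(prot) == 0L) return(prot)
  g <- reference$genes
  g <- g[g$chrom == chrom & g$start <= end & g$end >= start, , drop = FALSE]
  out <- prot[prot$gene_id %in% g$gene_id, , drop = FALSE]
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
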