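#' Reduce a variant to its minimal (normalized) allele representation
#'
#' Callers emit the same indel with different padding; before cross-caller
#' comparison every variant is reduced to a minimal representation by
#' trimming the common allele suffix, then the common prefix (keeping one
#' anchor base for indels, per VCF convention), adjusting `pos` accordingly.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @return The data.frame with `pos`, `ref`, `alt` normalized and `kind`
#'   recomputed.
#' @export
normalize_variants <- function(variants) {
  n <- nrow(variants)
  if (n == 0L) return(variants)
  pos <- variants$pos; ref <- variants$ref; alt <- variants$alt
  for (i in seq_len(n)) {
    r <- strsplit(ref[i], "", fixed = TRUE)[[1L]]
    a <- strsplit(alt[i], "", fixed = TRUE)[[1L]]
    # trim common suffix
    while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]; a <- a[-length(a)]
    }
    # trim common prefix, keeping an anchor when lengths differ
    minlen <- if (length(r) == length(a)) 1L else 2L
    while (length(r) >= minlen && length(a) >= minlen && r[1L] == a[1L] &&
           (length(r) > 1L || length(a) > 1L)) {
      r <- r[-1L]; a <- a[-1L]; pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = ""); alt[i] <- paste(a, collapse = "")
  }
  variants$pos <- pos; variants$ref <- ref; variants$alt <- alt
  variants$kind <- variant_kind(ref, alt)
  variants
}

variant_kind <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}

#' Cross-verify variants across callers
#'
#' A variant is retained for a line when it is called identically (same
#' chromosome, position and alleles after normalization) by at least
#' `min_callers` callers and its depth reaches `depth_min`. Optionally,
#' indels may additionally be accepted from a single dedicated indel caller,
#' and SNPs may be required to carry a minimum posterior probability when
#' the input provides one (a `posterior` column).
#'
#' @param calls data.frame of raw calls with columns `line_id`, `caller_id`,
#'   `chrom`, `pos`, `ref`, `alt`, and optionally `depth`, `posterior`.
#' @param min_callers Minimum number of agreeing callers (default 2).
#' @param depth_min Minimum read depth (default 3); the depth of a consensus
#'   variant is the maximum across its supporting callers.
#' @param snp_posterior_min If non-NULL and a `posterior` column is present,
#'   SNPs must exceed this posterior in at least one caller.
#' @param indel_solo_caller Optional caller id whose indel calls are accepted
#'   without cross-caller support.
#' @param known_chroms Optional character vector; calls on other chromosomes
#'   raise an error.
#' @return data.frame of consensus variants: `line_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `kind`, `n_callers`, `callers` (comma-separated), `depth`.
#' @export
cross_verify <- function(calls, min_callers = 2L, depth_min = 3L,
                         snp_posterior_min = NULL, indel_solo_caller = NULL,
                         known_chroms = NULL) {
  stopifnot(min_callers >= 1L)
  if (!is.null(known_chroms) && any(!calls$chrom %in% known_chroms)) {
    stop("calls reference unknown chromosomes: ",
         paste(unique(setdiff(calls$chrom, known_chroms)), collapse = ", "))
  }
  if (nrow(calls) == 0L) {
    return(data.frame(line_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      kind = character(), n_callers = integer(),
                      callers = character(), depth = numeric(),
                      stringsAsFactors = FALSE))
  }
  calls <- normalize_variants(calls)
  if (is.null(calls$depth)) calls$depth <- NA_real_
  key <- paste(calls$line_id, calls$chrom, calls$pos, calls$ref, calls$alt,
               sep = "\r")
  grp <- split(seq_len(nrow(calls)), key)
  rows <- lapply(grp, function(ii) {
    callers <- unique(calls$caller_id[ii])
    kind <- variant_kind(calls$ref[ii[1L]], calls$alt[ii[1L]])
    keep <- length(callers) >= min_callers ||
      (!is.null(indel_solo_caller) && kind != "SNP" &&
         indel_solo_caller %in% callers)
    if (!keep) return(NULL)
    depth <- suppressWarnings(max(calls$depth[ii], na.rm = TRUE))
    if (is.finite(depth) && depth < depth_min) return(NULL)
    if (!is.null(snp_posterior_min) && kind == "SNP" &&
        !is.null(calls$posterior)) {
      post <- suppressWarnings(max(calls$posterior[ii], na.rm = TRUE))
      if (is.finite(post) && post <= snp_posterior_min) return(NULL)
    }
    data.frame(line_id = calls$line_id[ii[1L]], chrom = calls$chrom[ii[1L]],
               pos = calls$pos[ii[1L]], ref = calls$ref[ii[1L]],
               alt = calls$alt[ii[1L]], kind = kind,
               n_callers = length(callers),
               callers = paste(sort(callers), collapse = ","),
               depth = if (is.finite(depth)) depth else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(line_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      kind = character(), n_callers = integer(),
                      callers = character(), depth = numeric(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$line_id, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove variants falling in masked (low-quality) regions
#'
#' @param variants data.frame with `chrom` and `pos` (1-based).
#' @param mask data.frame of intervals `chrom`, `start`, `end` in BED
#'   convention (0-based half-open).
#' @return list with `variants` (the survivors) and `n_masked`.
#' @export
mask_regions <- function(variants, mask) {
  if (is.null(mask) || nrow(mask) == 0L) {
    return(list(variants = variants, n_masked = 0L))
  }
  if (any(mask$start > mask$end)) stop("malformed mask interval: start > end")
  gr_m <- GenomicRanges::GRanges(mask$chrom,
                                 IRanges::IRanges(mask$start + 1L, mask$end))
  gr_v <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos, variants$pos))
  hit <- IRanges::overlapsAny(gr_v, gr_m)
  list(variants = variants[!hit, , drop = FALSE], n_masked = sum(hit))
}

#' Partition consensus variants into ancestral and derived sets
#'
#' Variants shared by the ancestor and all evolved lines were present before
#' the experiment (ancestral); variants absent from the ancestor but present
#' in at least one evolved line arose during selection (derived). Variants
#' present in the ancestor but missing from some evolved lines are reported
#' separately as ambiguous, never silently merged.
#'
#' @param consensus Output of [cross_verify()] covering the ancestor and all
#'   evolved lines.
#' @param ancestor_id Line identifier of the ancestor (default `"ancestor"`).
#' @return list with data.frames `derived` (per-line), `ancestral` and
#'   `ambiguous` (both deduplicated across lines).
#' @export
partition_ancestral_derived <- function(consensus, ancestor_id = "ancestor") {
  lines <- setdiff(unique(consensus$line_id), ancestor_id)
  if (length(lines) == 0L) stop("no evolved lines present")
  vkey <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = "\r")
  anc <- consensus[consensus$line_id == ancestor_id, , drop = FALSE]
  anc_keys <- vkey(anc)
  line_keys <- lapply(lines, function(l)
    vkey(consensus[consensus$line_id == l, , drop = FALSE]))
  names(line_keys) <- lines

  in_all <- anc_keys[vapply(anc_keys, function(k)
    all(vapply(line_keys, function(lk) k %in% lk, logical(1L))), logical(1L))]
  ancestral <- anc[anc_keys %in% in_all, , drop = FALSE]
  ambiguous <- anc[!anc_keys %in% in_all, , drop = FALSE]

  ev <- consensus[consensus$line_id != ancestor_id, , drop = FALSE]
  derived <- ev[!vkey(ev) %in% anc_keys, , drop = FALSE]
  rownames(ancestral) <- rownames(ambiguous) <- rownames(derived) <- NULL
  list(derived = derived, ancestral = ancestral, ambiguous = ambiguous)
}
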