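#' Bin per-base depth into fixed-width intervals
#'
#' @param depth data.frame of per-base depth with columns `chrom`, `pos`
#'   (1-based) and `depth`; every base of each chromosome must be present.
#' @param bin_width Bin width in bp (default 1000). Terminal bins may be
#'   shorter and are flagged `partial`.
#' @param line_id Optional label stored on the track.
#' @return A `coverage_track`: list with `line_id`, `bins` (data.frame
#'   `chrom`, `start`, `end` in 0-based half-open convention, `mean_depth`,
#'   `partial`) and `genome_mean` (mean depth over all bases).
#' @export
bin_coverage <- function(depth, bin_width = 1000L, line_id = NA_character_) {
  if (is.null(depth) || nrow(depth) == 0L) stop("empty depth input")
  bins <- do.call(rbind, lapply(split(depth, depth$chrom), function(d) {
    d <- d[order(d$pos), , drop = FALSE]
    L <- max(d$pos)
    bin <- (d$pos - 1L) %/% bin_width
    mu <- tapply(d$depth, bin, mean)
    b <- as.integer(names(mu))
    start <- b * bin_width
    end <- pmin(start + bin_width, L)
    data.frame(chrom = d$chrom[1L], start = start, end = end,
               mean_depth = as.numeric(mu),
               partial = (end - start) < bin_width,
               stringsAsFactors = FALSE)
  }))
  rownames(bins) <- NULL
  track <- list(line_id = line_id, bins = bins,
                genome_mean = mean(depth$depth))
  class(track) <- "coverage_track"
  track
}

#' Build a coverage track from already-binned depth
#'
#' @param bins data.frame `chrom`, `start`, `end` (0-based half-open),
#'   `mean_depth`.
#' @param line_id Optional label.
#' @param genome_mean Genome-wide mean depth; by default recomputed as the
#'   length-weighted mean of the bins.
#' @return A `coverage_track` (see [bin_coverage()]).
#' @export
coverage_track <- function(bins, line_id = NA_character_, genome_mean = NULL) {
  w <- bins$end - bins$start
  if (is.null(genome_mean)) genome_mean <- sum(bins$mean_depth * w) / sum(w)
  bins$partial <- if (is.null(bins$partial)) w < max(w) else bins$partial
  track <- list(line_id = line_id, bins = bins, genome_mean = genome_mean)
  class(track) <- "coverage_track"
  track
}

#' Call regions of anomalously high or low coverage
#'
#' Bins with mean depth strictly above `high_threshold` times, or strictly
#' below `low_threshold` times, the genome mean are flagged; maximal runs of
#' same-direction flagged bins become candidate regions; same-direction
#' candidates separated by at most `merge_gap` bp are collapsed; candidates
#' whose length does not exceed `min_length` are discarded. Regions never
#' span chromosomes, high and low regions are never merged with each other,
#' and a merge never jumps across an intervening flagged region of the
#' opposite direction. When per-base depth is supplied, candidate boundaries
#' are first
#' refined to the outermost beyond-threshold base within the flanking bins
#' (so the gap rule operates at base resolution); by default regions are
#' reported at bin resolution.
#'
#' @param track A `coverage_track`.
#' @param high_threshold,low_threshold Fold-of-mean cutoffs (defaults 1.8 and
#'   0.20; ties are not flagged).
#' @param min_length Minimum region length in bp, exclusive (default 500).
#' @param merge_gap Maximum gap collapsed between same-direction regions
#'   (default 200).
#' @param depth Optional per-base depth data.frame (`chrom`, `pos`, `depth`)
#'   enabling boundary refinement.
#' @return data.frame of regions: `line_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `direction` (`"high"`/`"low"`), `fold_of_mean`,
#'   `length`.
#' @export
call_regions <- function(track, high_threshold = 1.8, low_threshold = 0.20,
                         min_length = 500L, merge_gap = 200L, depth = NULL) {
  if (low_threshold >= high_threshold) {
    stop("low_threshold must be below high_threshold")
  }
  if (!is.finite(track$genome_mean) || track$genome_mean <= 0) {
    stop("genome mean depth must be positive")
  }
  gm <- track$genome_mean
  bins <- track$bins
  fold <- bins$mean_depth / gm
  dir <- ifelse(fold > high_threshold, "high",
                ifelse(fold < low_threshold, "low", "none"))

  regions <- list()
  for (chr in unique(bins$chrom)) {
    sel <- bins$chrom == chr
    b <- bins[sel, , drop = FALSE]
    d <- dir[sel]
    o <- order(b$start); b <- b[o, , drop = FALSE]; d <- d[o]
    r <- rle(d)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    cand <- data.frame(start = b$start[starts], end = b$end[ends],
                       direction = r$values, stringsAsFactors = FALSE)
    cand <- cand[cand$direction != "none", , drop = FALSE]
    if (nrow(cand) == 0L) next
    if (!is.null(depth)) {
      cand <- refine_boundaries(cand, depth[depth$chrom == chr, , drop = FALSE],
                                gm, high_threshold, low_threshold,
                                bin_width = max(b$end - b$start))
    }
    cand <- merge_candidates(cand, merge_gap)
    cand <- cand[(cand$end - cand$start) > min_length, , drop = FALSE]
    if (nrow(cand) == 0L) next
    cand$chrom <- chr
    # fold of mean over the region, from the overlapped bins (length-weighted)
    cand$fold_of_mean <- vapply(seq_len(nrow(cand)), function(i) {
      ov <- pmin(b$end, cand$end[i]) - pmax(b$start, cand$start[i])
      ov[ov < 0] <- 0
      sum(b$mean_depth * ov) / sum(ov) / gm
    }, numeric(1L))
    regions[[chr]] <- cand
  }
  out <- do.call(rbind, regions)
  if (is.null(out)) {
    out <- data.frame(start = numeric(), end = numeric(),
                      direction = character(), chrom = character(),
                      fold_of_mean = numeric(), stringsAsFactors = FALSE)
  }
  out$length <- out$end - out$start
  out$line_id <- rep(track$line_id, nrow(out))
  out <- out[, c("line_id", "chrom", "start", "end", "direction",
                 "fold_of_mean", "length")]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# collapse same-direction candidates separated by <= merge_gap
merge_candidates <- function(cand, merge_gap) {
  if (nrow(cand) < 2L) return(cand)
  cand <- cand[order(cand$start), , drop = FALSE]
  out <- cand[1L, , drop = FALSE]
  for (i in 2L:nrow(cand)) {
    j <- nrow(out)
    if (cand$direction[i] == out$direction[j] &&
        cand$start[i] - out$end[j] <= merge_gap) {
      out$end[j] <- max(out$end[j], cand$end[i])
    } else {
      out <- rbind(out, cand[i, , drop = FALSE])
    }
  }
  out
}

# extend candidate edges to the outermost contiguous beyond-threshold base
# within the flanking bin, and trim edges whose outer bases are within range
refine_boundaries <- function(cand, depth, gm, high, low, bin_width) {
  if (nrow(depth) == 0L) return(cand)
  depth <- depth[order(depth$pos), , drop = FALSE]
  dv <- depth$depth
  L <- nrow(depth)
  beyond <- function(x, direction) {
    if (direction == "high") x / gm > high else x / gm < low
  }
  for (i in seq_len(nrow(cand))) {
    dirn <- cand$direction[i]
    s <- cand$start[i] + 1L   # 1-based first base
    e <- cand$end[i]          # 1-based last base
    # trim inward while edge bases are not beyond threshold
    while (s <= e && !beyond(dv[s], dirn)) s <- s + 1L
    while (e >= s && !beyond(dv[e], dirn)) e <- e - 1L
    if (s > e) { cand$start[i] <- NA; next }
    # extend outward through contiguous beyond-threshold bases (flanking bins)
    smin <- max(1L, s - bin_width); emax <- min(L, e + bin_width)
    while (s - 1L >= smin && beyond(dv[s - 1L], dirn)) s <- s - 1L
    while (e + 1L <= emax && beyond(dv[e + 1L], dirn)) e <- e + 1L
    cand$start[i] <- s - 1L
    cand$end[i] <- e
  }
  cand[!is.na(cand$start), , drop = FALSE]
}

#' Total extent of coverage regions shared by every line
#'
#' Intersects region sets across all supplied lines (for example regions of
#' missing coverage present in the ancestor and every evolved line, which
#' indicate sequence absent relative to the reference assembly rather than
#' derived events) and reports their genomic footprint.
#'
#' @param region_list list of region data.frames (one per line, ancestor
#'   included), as returned by [call_regions()].
#' @param genome_length Total reference length in bp.
#' @return list with `total_bp` and `fraction` of the genome.
#' @export
summarize_masked_fraction <- function(region_list, genome_length) {
  if (length(region_list) == 0L) return(list(total_bp = 0, fraction = 0))
  grs <- lapply(region_list, function(r) {
    if (nrow(r) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(
      GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$start + 1L, r$end)))
  })
  shared <- Reduce(GenomicRanges::intersect, grs)
  total <- sum(as.numeric(GenomicRanges::width(shared)))
  list(total_bp = total, fraction = total / genome_length)
}
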