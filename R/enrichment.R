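#' GO-Slim overrepresentation test for a mutated-gene list
#'
#' For each namespace, terms carried by fewer than `min_representation` of
#' the annotated query genes are dropped, each remaining term is tested with
#' a one-tailed 2x2 chi-square (query vs rest-of-genome, term vs not-term),
#' and Benjamini-Hochberg correction is applied across the retained terms of
#' the namespace. A term is flagged overrepresented when its BH q-value is
#' within `fdr` and its observed/expected fold reaches `fold_min`.
#'
#' The background is, by default, the annotated genes of the universe
#' excluding the query ("rest of the genome"); set
#' `background = "include_query"` to test against the whole annotated
#' universe. The one-tailed p-value is the directional halving of the 1-df
#' two-tailed chi-square p (p/2 when fold > 1, else 1 - p/2).
#'
#' @param query_genes Character vector of mutated gene ids.
#' @param go_table data.frame `gene_id`, `namespace`, `term_id`, `term_name`
#'   (one row per gene/term pair); genes absent from the table are treated
#'   as unannotated.
#' @param universe Character vector of all gene ids in the genome. Query
#'   genes missing from the universe are dropped with a warning.
#' @param min_representation Minimum share of annotated query genes carrying
#'   a term for it to be tested (default 0.05).
#' @param fold_min Minimum observed/expected fold to flag (default 1.2).
#' @param fdr Benjamini-Hochberg level (default 0.15).
#' @param background `"exclude_query"` (default) or `"include_query"`.
#' @param yates Apply Yates continuity correction (default FALSE).
#' @return data.frame with one row per namespace/term: `namespace`,
#'   `term_id`, `term_name`, `observed`, `query_annotated`, `expected`,
#'   `fold`, `chi2`, `p_one_tailed`, `q_bh`, `flagged_overrepresented`;
#'   sorted by q then decreasing fold within namespace.
#' @export
go_enrich <- function(query_genes, go_table, universe,
                      min_representation = 0.05, fold_min = 1.2, fdr = 0.15,
                      background = c("exclude_query", "include_query"),
                      yates = FALSE) {
  background <- match.arg(background)
  query_genes <- unique(query_genes)
  if (length(query_genes) == 0L) stop("empty query gene list")
  if (length(universe) == 0L) stop("empty gene universe")
  missing <- setdiff(query_genes, universe)
  if (length(missing) > 0L) {
    warning(length(missing), " query gene(s) absent from universe; excluded")
    query_genes <- intersect(query_genes, universe)
  }

  res <- lapply(unique(go_table$namespace), function(ns) {
    tab <- go_table[go_table$namespace == ns, , drop = FALSE]
    annotated <- unique(tab$gene_id)
    q_ann <- intersect(query_genes, annotated)
    nq <- length(q_ann)
    if (nq == 0L) return(NULL)
    bg <- if (background == "exclude_query") {
      setdiff(annotated, query_genes)
    } else {
      annotated
    }
    nb <- length(bg)
    terms <- unique(tab[, c("term_id", "term_name")])
    rows <- lapply(seq_len(nrow(terms)), function(i) {
      tg <- unique(tab$gene_id[tab$term_id == terms$term_id[i]])
      obs <- length(intersect(q_ann, tg))
      if (obs / nq < min_representation) return(NULL)
      bg_with <- length(intersect(bg, tg))
      expected <- nq * bg_with / nb
      fold <- if (expected > 0) obs / expected else NA_real_
      m <- matrix(c(obs, nq - obs, bg_with, nb - bg_with), nrow = 2L)
      chi <- suppressWarnings(chisq.test(m, correct = yates))
      p2 <- chi$p.value
      p1 <- if (!is.na(fold) && fold > 1) p2 / 2 else 1 - p2 / 2
      data.frame(namespace = ns, term_id = terms$term_id[i],
                 term_name = terms$term_name[i], observed = obs,
                 query_annotated = nq, expected = expected, fold = fold,
                 chi2 = unname(chi$statistic), p_one_tailed = p1,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) return(NULL)
    out$q_bh <- p.adjust(out$p_one_tailed, method = "BH")
    out$flagged_overrepresented <- out$q_bh <= fdr &
      !is.na(out$fold) & out$fold >= fold_min
    out[order(out$q_bh, -out$fold), , drop = FALSE]
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(namespace = character(), term_id = character(),
                      term_name = character(), observed = integer(),
                      query_annotated = integer(), expected = numeric(),
                      fold = numeric(), chi2 = numeric(),
                      p_one_tailed = numeric(), q_bh = numeric(),
                      flagged_overrepresented = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Probability that mutations hit a designated gene subset
#'
#' For a pathway of `m` genes among `G` protein-coding genes and `n` genic
#' mutations placed uniformly at random, `specific_hit` mode returns the
#' probability that `k` designated mutations fall inside the subset while
#' the remaining `n - k` fall outside: `(m/G)^k * (1 - m/G)^(n-k)`.
#' `binomial_tail` mode returns the conventional tail probability
#' `P(X >= k)` for `X ~ Binomial(n, m/G)`, which is never smaller for
#' `k >= 1`.
#'
#' @param m Subset (pathway) size in genes.
#' @param G Number of protein-coding genes in the genome.
#' @param n Number of genic mutations observed.
#' @param k Number of mutations observed inside the subset.
#' @param mode `"specific_hit"` (default) or `"binomial_tail"`.
#' @return list with `m`, `G`, `n`, `k`, `mode` and `probability`.
#' @examples
#' subset_hit_probability(22, 10667, 87, 2)$probability  # ~3.57e-6
#' @export
subset_hit_probability <- function(m, G, n, k,
                                   mode = c("specific_hit", "binomial_tail")) {
  mode <- match.arg(mode)
  if (!(m > 0 && m <= G)) stop("require 0 < m <= G")
  if (!(k >= 0 && k <= n)) stop("require 0 <= k <= n")
  p <- m / G
  prob <- switch(mode,
    specific_hit = p^k * (1 - p)^(n - k),
    binomial_tail = pbinom(k - 1, n, p, lower.tail = FALSE))
  list(m = m, G = G, n = n, k = k, mode = mode, probability = prob)
}

#' Fraction of query genes lacking GO annotation, per namespace
#'
#' @param query_genes Character vector of gene ids.
#' @param go_table data.frame `gene_id`, `namespace`, `term_id`, `term_name`.
#' @return data.frame with `namespace`, `n_query`, `n_annotated`,
#'   `missing_fraction` (NA when the query is empty).
#' @export
annotation_coverage_report <- function(query_genes, go_table) {
  query_genes <- unique(query_genes)
  nq <- length(query_genes)
  ns <- unique(go_table$namespace)
  out <- do.call(rbind, lapply(ns, function(s) {
    ann <- unique(go_table$gene_id[go_table$namespace == s])
    na <- length(intersect(query_genes, ann))
    data.frame(namespace = s, n_query = nq, n_annotated = na,
               missing_fraction = if (nq > 0L) 1 - na / nq else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
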