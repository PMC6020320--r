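#' Hypergeometric over-representation of one gene set
#'
#' Upper-tail hypergeometric test of the overlap between a query gene list
#' and a gene set, against a fixed background:
#' `p = sum_{i >= k} C(K, i) C(N-K, n-i) / C(N, n)` with `N` background
#' genes, `K` set members in the background, `n` query genes and `k`
#' overlap.
#'
#' @param query character vector of query genes (must be a subset of the
#'   background).
#' @param gene_set character vector; intersected with the background before
#'   testing.
#' @param background character vector of all eligible genes (non-empty).
#' @return list with `overlap` (k), `set_size_in_background` (K),
#'   `query_size` (n), `background_size` (N), `p_value`.
#' @export
hypergeomOverrep <- function(query, gene_set, background) {
  background <- unique(background)
  if (!length(background)) stop("empty background")
  query <- unique(query)
  if (!all(query %in% background))
    stop("query genes missing from the background: ",
         paste(head(setdiff(query, background), 5), collapse = ", "))
  set_bg <- intersect(unique(gene_set), background)
  k <- length(intersect(query, set_bg))
  K <- length(set_bg)
  n <- length(query)
  N <- length(background)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(overlap = k, set_size_in_background = K, query_size = n,
       background_size = N, p_value = p)
}

#' Gene-set enrichment of selected modules
#'
#' Tests every gene set against every selected module's gene list with
#' [hypergeomOverrep()], applying BH across sets within each module. The
#' background is the set of genes that entered the network. Sets with fewer
#' than `min_set_size` members after background intersection are skipped.
#'
#' @param labels module labels (named by gene) from a [ModuleSet-class].
#' @param modules character vector of module names to test (e.g. from
#'   [selectTraitModules()]).
#' @param gene_sets named list of character vectors (e.g. from
#'   [readGmt()]).
#' @param background background gene ids; defaults to all labelled genes.
#' @param fdr q-value threshold used for the `significant` flag.
#' @param min_set_size minimum in-background set size (default 3).
#' @return data.frame: module, set_name, overlap, set_size_in_background,
#'   query_size, background_size, p_value, q_value, significant.
#' @export
enrichModules <- function(labels, modules, gene_sets,
                          background = names(labels), fdr = 0.05,
                          min_set_size = 3) {
  background <- unique(background)
  rows <- list()
  for (m in modules) {
    query <- intersect(names(labels)[labels == m], background)
    res <- lapply(names(gene_sets), function(s) {
      h <- hypergeomOverrep(query, gene_sets[[s]], background)
      if (h$set_size_in_background < min_set_size) return(NULL)
      data.frame(module = m, set_name = s, overlap = h$overlap,
                 set_size_in_background = h$set_size_in_background,
                 query_size = h$query_size,
                 background_size = h$background_size,
                 p_value = h$p_value, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    if (is.null(res)) next
    res$q_value <- bhFdr(res$p_value)
    rows[[m]] <- res
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(module = character(), set_name = character(),
                      overlap = integer(), set_size_in_background = integer(),
                      query_size = integer(), background_size = integer(),
                      p_value = numeric(), q_value = numeric(),
                      significant = logical()))
  rownames(out) <- NULL
  out$significant <- out$q_value <= fdr
  out
}
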