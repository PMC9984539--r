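#' Read a GMT pathway annotation
#'
#' Parses the standard gene-set format (one set per line: id, description,
#' then member gene ids, tab-separated).
#'
#' @param path GMT file path.
#' @param background optional gene universe; defaults to the union of all
#'   set members.
#' @return object of class `pathway_annotation`: `sets` (named list of gene
#'   id vectors), `descriptions`, `background`.
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty annotation")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "",
                 character(1))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  pathway_annotation(sets, background = background,
                     descriptions = stats::setNames(desc, ids))
}

#' Construct a pathway annotation
#'
#' @param sets named list: pathway id -> character vector of gene ids.
#' @param background gene universe; defaults to the union of the sets. Every
#'   pathway gene must belong to it.
#' @param descriptions optional named descriptions.
#' @return a `pathway_annotation`.
#' @export
pathway_annotation <- function(sets, background = NULL, descriptions = NULL) {
  if (!length(sets) || is.null(names(sets)))
    stop("`sets` must be a non-empty named list")
  sets <- lapply(sets, unique)
  if (is.null(background)) background <- unique(unlist(sets))
  stray <- setdiff(unique(unlist(sets)), background)
  if (length(stray))
    stop("pathway gene(s) outside the background: ",
         paste(utils::head(stray, 5), collapse = ", "))
  structure(list(sets = sets, background = unique(background),
                 descriptions = descriptions),
            class = "pathway_annotation")
}

#' Pathway enrichment with FDR and minimum-Bayes-factor screening
#'
#' One-sided Fisher exact test (hypergeometric upper tail) of a gene list
#' against each pathway, Benjamini-Hochberg correction across pathways, and
#' a minimum Bayes factor computed from each p-value via the
#' Sellke-Bayarri-Berger bound `1 / (-e * p * ln p)` for `p < 1/e` (else 1).
#' A pathway is called enriched when `q < alpha` and the minimum Bayes
#' factor exceeds `bf_min` ("p < 0.05, FDR corrected; Bayes factor > 3").
#'
#' @param gene_list character vector of query gene ids; genes outside the
#'   background are dropped with a warning.
#' @param annotation a [pathway_annotation()].
#' @param alpha FDR level, default 0.05.
#' @param bf_min minimum-Bayes-factor threshold, default 3.
#' @return data.frame `(pathway_id, pathway_size, overlap, expected,
#'   p_fisher, q_bh, min_bayes_factor, enriched)`.
#' @export
enrich_pathways <- function(gene_list, annotation, alpha = 0.05, bf_min = 3) {
  if (!inherits(annotation, "pathway_annotation"))
    stop("`annotation` must be a pathway_annotation")
  bg <- annotation$background
  gene_list <- unique(gene_list)
  outside <- setdiff(gene_list, bg)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the background dropped",
                    length(outside)))
    gene_list <- intersect(gene_list, bg)
  }
  N <- length(bg); nq <- length(gene_list)
  ids <- names(annotation$sets)
  K <- vapply(annotation$sets, length, integer(1))
  overlap <- vapply(annotation$sets,
                    function(s) length(intersect(s, gene_list)), integer(1))
  # upper tail P(X >= overlap), X ~ Hypergeom(N, K, nq)
  p <- stats::phyper(overlap - 1L, K, N - K, nq, lower.tail = FALSE)
  q <- bh_fdr(p)
  data.frame(pathway_id = ids,
             pathway_size = unname(K),
             overlap = unname(overlap),
             expected = unname(nq * K / N),
             p_fisher = unname(p),
             q_bh = unname(q),
             min_bayes_factor = unname(min_bayes_factor(p)),
             enriched = unname(q < alpha & min_bayes_factor(p) > bf_min),
             stringsAsFactors = FALSE)
}

#' Minimum Bayes factor from a p-value
#'
#' Sellke-Bayarri-Berger lower bound on the Bayes factor against the null:
#' `1 / (-e * p * ln p)` for `p < 1/e`, else 1. Monotone decreasing in p on
#' (0, 1/e).
#'
#' @param p p-values in `[0, 1]`.
#' @return Bayes-factor bounds (>= 1).
#' @export
min_bayes_factor <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  out <- rep(1, length(p))
  lo <- !is.na(p) & p > 0 & p < exp(-1)
  out[lo] <- 1 / (-exp(1) * p[lo] * log(p[lo]))
  out[!is.na(p) & p == 0] <- Inf
  out
}

#' Cross-reference enriched pathway sets across omic layers
#'
#' @param sets named list (>= 2) of enriched pathway id vectors (e.g.
#'   metabolome, proteome, transcriptome).
#' @return list with `common` (pathways present in every set) and
#'   `pairwise` (matrix of pairwise intersection counts). Order-independent.
#' @examples
#' cross_reference(list(a = c("A", "B", "C"), b = c("B", "C", "D"),
#'                      c = "C"))$common   # "C"
#' @export
cross_reference <- function(sets) {
  if (length(sets) < 2L || is.null(names(sets)))
    stop("need >= 2 named sets")
  sets <- lapply(sets, unique)
  common <- sort(Reduce(intersect, sets))
  k <- length(sets)
  pw <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k))
    for (j in seq_len(k))
      pw[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  list(common = common, pairwise = pw)
}
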