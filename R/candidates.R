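#' Build a RankedGeneLists object from per-setting tables
#'
#' @param lists Named list of data.frames, each with columns \code{gene},
#'   \code{direction} and (optionally) \code{statistic}, already ordered.
#' @param k List-size cap (defaults to the longest list).
#' @return A \linkS4class{RankedGeneLists}.
#' @export
rankedGeneLists <- function(lists, k = max(vapply(lists, nrow, 0L))) {
  lists <- lapply(lists, S4Vectors::DataFrame)
  new("RankedGeneLists", lists = lists, k = as.integer(k))
}

#' Dual-direction top-k candidate list for one exposure setting
#'
#' Acute mode mirrors the published top-50 structure: the k/2 genes with
#' the largest composite trend score (up) followed by the k/2 with the
#' smallest (down). Chronic mode returns the k genes with smallest
#' p-value, keeping their directions. Boundary ties are broken by the
#' statistic and then by gene symbol, so output is deterministic.
#'
#' @param trend A \linkS4class{TrendResult}.
#' @param k List size (must be even in acute mode, and <= the number of
#'   genes).
#' @param setting Label for the resulting list (e.g.
#'   \code{"bleomycin_acute"}).
#' @return A \linkS4class{RankedGeneLists} holding one list.
#' @export
topKLists <- function(trend, k = 50, setting = "setting") {
  stopifnot(is(trend, "TrendResult"))
  tab <- trend@table
  if (k > nrow(tab)) stop("k exceeds the number of genes")
  if (trend@mode == "acute") {
    if (k %% 2 != 0) stop("k must be even in acute mode")
    up <- tab[order(-tab$sigma_Z, tab$gene), ][seq_len(k / 2), ]
    dn <- tab[order(tab$sigma_Z, tab$gene), ][seq_len(k / 2), ]
    out <- S4Vectors::DataFrame(
      gene = c(up$gene, dn$gene),
      direction = c(rep("up", k / 2), rep("down", k / 2)),
      statistic = c(up$sigma_Z, dn$sigma_Z))
    if (anyDuplicated(out$gene))
      stop("k too large: up and down halves overlap")
  } else {
    sel <- tab[order(tab$p_value, tab$gene), ][seq_len(k), ]
    out <- S4Vectors::DataFrame(gene = sel$gene, direction = sel$direction,
                                statistic = sel$p_value)
  }
  lists <- list(out)
  names(lists) <- setting
  new("RankedGeneLists", lists = lists, k = as.integer(k))
}

#' Combine RankedGeneLists objects across settings
#'
#' @param ... \linkS4class{RankedGeneLists} objects with distinct setting
#'   names.
#' @return A single \linkS4class{RankedGeneLists}.
#' @export
combineGeneLists <- function(...) {
  objs <- list(...)
  stopifnot(all(vapply(objs, is, TRUE, "RankedGeneLists")))
  lists <- do.call(c, lapply(objs, function(o) o@lists))
  if (anyDuplicated(names(lists))) stop("duplicate setting names")
  new("RankedGeneLists", lists = lists,
      k = max(vapply(objs, function(o) o@k, 0L)))
}

#' Multi-setting overlap (Venn) candidate selection
#'
#' Counts, for every gene appearing in at least one per-setting top list,
#' how many lists contain it; the candidate set comprises the genes whose
#' membership count reaches the threshold \code{m} (a >=-threshold: a gene
#' present in all lists also qualifies). Pairwise intersection sizes are
#' reported for all list pairs.
#'
#' @param lists A \linkS4class{RankedGeneLists} with at least 2 lists.
#' @param m Minimum membership count, \code{2 <= m <= } number of lists
#'   (default 3, the three-of-four selection rule).
#' @return An \linkS4class{OverlapReport}.
#' @examples
#' a <- data.frame(gene = c("X", "Y"), direction = "up")
#' b <- data.frame(gene = c("Y", "Z"), direction = "up")
#' r <- overlapSelect(rankedGeneLists(list(s1 = a, s2 = b)), m = 2)
#' candidateSet(r)  # "Y"
#' @export
overlapSelect <- function(lists, m = 3) {
  stopifnot(is(lists, "RankedGeneLists"))
  ll <- lists@lists
  if (length(ll) < 2L) stop("need at least 2 lists")
  if (any(vapply(ll, nrow, 0L) == 0L)) stop("empty list input")
  if (m > length(ll)) stop("m cannot exceed the number of lists")
  genes <- sort(unique(unlist(lapply(ll, function(l) l$gene))))
  member <- vapply(ll, function(l) genes %in% l$gene,
                   logical(length(genes)))
  member <- matrix(member, nrow = length(genes),
                   dimnames = list(genes, names(ll)))
  count <- rowSums(member)
  tab <- S4Vectors::DataFrame(gene = genes, member, count = count,
                              check.names = FALSE)
  pairwise <- crossprod(member)
  new("OverlapReport", membership = tab,
      candidates = genes[count >= m], m = as.integer(m),
      pairwise = pairwise)
}

#' Direction concordance of overlap genes across member settings
#'
#' For each gene in the overlap report, checks whether its direction flag
#' agrees across all lists that contain it. A gene present in a single
#' list is concordant by convention. (The published candidates are not all
#' concordant: a gene can rise under acute exposure yet fall under
#' chronic exposure.)
#'
#' @param report An \linkS4class{OverlapReport}.
#' @param lists The \linkS4class{RankedGeneLists} the report was built
#'   from.
#' @return data.frame with columns \code{gene}, \code{n_settings},
#'   \code{directions} (comma-collapsed unique flags), \code{concordant}.
#' @export
directionConcordance <- function(report, lists) {
  stopifnot(is(report, "OverlapReport"), is(lists, "RankedGeneLists"))
  ll <- lists@lists
  genes <- report@membership$gene
  res <- lapply(genes, function(g) {
    dirs <- unlist(lapply(ll, function(l) l$direction[l$gene == g]))
    data.frame(gene = g, n_settings = length(dirs),
               directions = paste(unique(dirs), collapse = ","),
               concordant = length(unique(dirs)) <= 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
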