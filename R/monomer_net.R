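#' Harvest complete, phased monomers of one family from reads
#'
#' Each read is locally aligned (both strands) to the family consensus
#' tiled head-to-tail; every complete monomer copy — an alignment segment
#' spanning one full consensus period strictly inside the read — is
#' excised, oriented to the consensus strand, and projected onto consensus
#' coordinates (star alignment: per consensus position, the aligned read
#' base, `-` for a deletion; read insertions are dropped). Partial
#' flanking copies are discarded, and phasing to consensus position 0
#' guarantees rotations never create artificial haplotypes.
#'
#' @param rs A `read_set`.
#' @param family_consensus Consensus monomer (shorter than the reads).
#' @param min_identity Minimum alignment identity for a copy to count.
#' @param k Prescreen k-mer size.
#' @return Data frame of monomers: `sequence` (raw excised), `aligned`
#'   (consensus-length projection), `source_read`, `source_library`.
#' @export
harvest_monomers <- function(rs, family_consensus, min_identity = 0.8,
                             k = 11L) {
  rul <- nchar(family_consensus)
  if (!length(rs)) {
    return(data.frame(sequence = character(0), aligned = character(0),
                      source_read = character(0),
                      source_library = character(0)))
  }
  if (rul >= min(nchar(rs$seq))) {
    stop("consensus longer than the reads; family not harvestable")
  }
  rl_max <- max(nchar(rs$seq))
  tiles <- ceiling(rl_max / rul) + 2L
  tiled <- strrep(family_consensus, tiles)
  kk <- min(k, rul)
  refs <- cpp_kmer_sets(strrep(family_consensus, 2L), kk)
  km <- cpp_kmer_match(rs$seq, kk, refs)
  lib <- .read_library(rs)
  out <- list()
  for (i in which(km[, 1] > 0)) {
    best <- NULL; used <- rs$seq[i]
    for (s in c(rs$seq[i], revcomp(rs$seq[i]))) {
      al <- cpp_align_local(s, tiled, keep_path = TRUE)
      if (is.null(best) || al$score > best$score) { best <- al; used <- s }
    }
    if (is.null(best) || best$alen == 0) next
    if (best$matches / best$alen < min_identity) next
    chars <- strsplit(used, "")[[1]]
    # map consensus positions (mod rul) to aligned read bases
    bpos <- best$b_pos; apos <- best$a_pos
    covered <- bpos[bpos > 0]
    if (!length(covered)) next
    first_copy <- (min(covered) - 1L) %/% rul
    last_copy <- (max(covered) - 1L) %/% rul
    for (cp in first_copy:last_copy) {
      lo <- cp * rul + 1L; hi <- (cp + 1L) * rul
      # complete copy: consensus endpoints aligned (not clipped)
      sel <- which(bpos >= lo & bpos <= hi & bpos > 0)
      if (!length(sel)) next
      cov <- bpos[sel]
      if (min(cov) != lo || max(cov) != hi) next
      cols <- which((bpos >= lo & bpos <= hi) | (bpos == 0 &
                    seq_along(bpos) > min(sel) & seq_along(bpos) < max(sel)))
      proj <- rep("-", rul)
      for (ci in cols) {
        if (bpos[ci] > 0) {
          proj[bpos[ci] - lo + 1L] <-
            if (apos[ci] > 0) chars[apos[ci]] else "-"
        }
      }
      rpos <- apos[cols]; rpos <- rpos[rpos > 0]
      raw <- paste(chars[min(rpos):max(rpos)], collapse = "")
      out[[length(out) + 1L]] <- data.frame(
        sequence = raw, aligned = paste(proj, collapse = ""),
        source_read = rs$id[i], source_library = lib[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(sequence = character(0), aligned = character(0),
                      source_read = character(0),
                      source_library = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Collapse monomers into haplotypes with per-sex counts
#'
#' Exact-sequence grouping over the phased (consensus-projected) monomer
#' sequences; counts are kept per source library. Singletons — haplotypes
#' seen exactly once across both libraries pooled — are discarded when
#' `drop_singletons` is set.
#'
#' @param monomers Output of [harvest_monomers()].
#' @param drop_singletons Remove total-count-1 haplotypes.
#' @return Data frame: `sequence`, `count_female`, `count_male`, `total`,
#'   sorted by decreasing total then sequence.
#' @export
collapse_haplotypes <- function(monomers, drop_singletons = TRUE) {
  if (!nrow(monomers)) {
    return(data.frame(sequence = character(0), count_female = integer(0),
                      count_male = integer(0), total = integer(0)))
  }
  key <- monomers$aligned
  cf <- tapply(monomers$source_library == "female", key, sum)
  cm <- tapply(monomers$source_library == "male", key, sum)
  out <- data.frame(sequence = names(cf),
                    count_female = as.integer(cf),
                    count_male = as.integer(cm[names(cf)]),
                    stringsAsFactors = FALSE)
  out$total <- out$count_female + out$count_male
  if (drop_singletons) out <- out[out$total >= 2L, , drop = FALSE]
  out <- out[order(-out$total, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mutational steps between two aligned haplotypes
#'
#' Hamming distance over the star-aligned (equal-length) sequences; gap
#' characters count as a fifth state.
#'
#' @param a,b Aligned haplotype sequences of equal length.
#' @return Integer number of differing columns.
#' @export
pairwise_steps <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("haplotypes are not aligned (unequal length)")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' All pairwise mutational steps among haplotypes
#'
#' @param haplotypes Haplotype data frame from [collapse_haplotypes()], or
#'   a character vector of aligned sequences.
#' @return Symmetric integer matrix of Hamming distances.
#' @export
pairwise_steps_matrix <- function(haplotypes) {
  seqs <- if (is.data.frame(haplotypes)) haplotypes$sequence else haplotypes
  n <- length(seqs)
  chars <- do.call(rbind, strsplit(seqs, ""))
  d <- matrix(0L, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- sum(chars[i, ] != chars[j, ])
      }
    }
  }
  d
}

#' Minimum spanning tree over haplotype distances
#'
#' Kruskal's algorithm with deterministic, abundance-aware tie-breaking:
#' among equal-weight edges, the edge whose endpoints carry the higher
#' total haplotype count is added first (then the higher minimum count,
#' then lexicographic node order), in the spirit of goeBURST. The result
#' is a spanning tree of minimal total weight; the tie rule only selects
#' among co-optimal trees.
#'
#' @param haplotypes Haplotype data frame ([collapse_haplotypes()]).
#' @param distances Optional symmetric distance matrix (defaults to
#'   [pairwise_steps_matrix()] of the haplotypes).
#' @return A `haplotype_graph`: `nodes` (haplotype table with `id`),
#'   `edges` (`from`, `to`, `steps`), `tree_flag = TRUE`.
#' @export
build_mst <- function(haplotypes, distances = NULL) {
  n <- nrow(haplotypes)
  stopifnot(n >= 1)
  if (is.null(distances)) distances <- pairwise_steps_matrix(haplotypes)
  stopifnot(nrow(distances) == n, ncol(distances) == n,
            all(diag(distances) == 0),
            isTRUE(all.equal(distances, t(distances))))
  nodes <- haplotypes
  nodes$id <- seq_len(n)
  tot <- if (!is.null(haplotypes$total)) haplotypes$total else rep(1L, n)
  if (n == 1L) {
    return(structure(list(nodes = nodes,
                          edges = data.frame(from = integer(0),
                                             to = integer(0),
                                             steps = integer(0)),
                          tree_flag = TRUE),
                     class = "haplotype_graph"))
  }
  idx <- which(upper.tri(distances), arr.ind = TRUE)
  ed <- data.frame(from = idx[, 1], to = idx[, 2],
                   steps = distances[idx])
  ord <- order(ed$steps,
               -pmax(tot[ed$from], tot[ed$to]),
               -pmin(tot[ed$from], tot[ed$to]),
               ed$from, ed$to)
  ed <- ed[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  picked <- logical(nrow(ed))
  taken <- 0L
  for (e in seq_len(nrow(ed))) {
    ra <- find(ed$from[e]); rb <- find(ed$to[e])
    if (ra != rb) {
      parent[ra] <- rb
      picked[e] <- TRUE
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  edges <- ed[picked, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, tree_flag = TRUE),
            class = "haplotype_graph")
}

#' @exportS3Method base::print
print.haplotype_graph <- function(x, ...) {
  cat(sprintf("haplotype_graph: %d haplotypes, %d edges, total weight %d\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$steps)))
  invisible(x)
}

#' Convert a haplotype graph to igraph
#'
#' Node attributes: `size` (total count), `count_female`, `count_male`;
#' edge attribute `weight` = mutational steps.
#'
#' @param graph A `haplotype_graph`.
#' @return An igraph object.
#' @export
as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = nrow(graph$nodes), directed = FALSE)
  tot <- if (!is.null(graph$nodes$total)) graph$nodes$total
         else rep(1L, nrow(graph$nodes))
  g <- igraph::set_vertex_attr(g, "name", value = paste0("h", graph$nodes$id))
  g <- igraph::set_vertex_attr(g, "size", value = tot)
  if (!is.null(graph$nodes$count_female)) {
    g <- igraph::set_vertex_attr(g, "count_female",
                                 value = graph$nodes$count_female)
    g <- igraph::set_vertex_attr(g, "count_male",
                                 value = graph$nodes$count_male)
  }
  if (nrow(graph$edges)) {
    g <- igraph::add_edges(g, rbind(graph$edges$from, graph$edges$to),
                           weight = graph$edges$steps)
  }
  g
}

#' Export a haplotype graph as GraphML and DOT
#'
#' Node size is proportional to total haplotype count and per-sex counts
#' are carried as attributes, so viewers can recreate the female/male
#' coloring of haplotype network figures.
#'
#' @param graph A `haplotype_graph`.
#' @param graphml_path,dot_path Output paths (either may be `NULL`).
#' @return Named vector of written paths, invisibly.
#' @export
export_graph <- function(graph, graphml_path = NULL, dot_path = NULL) {
  g <- as_igraph(graph)
  written <- character(0)
  if (!is.null(graphml_path)) {
    igraph::write_graph(g, graphml_path, format = "graphml")
    written <- c(written, graphml = graphml_path)
  }
  if (!is.null(dot_path)) {
    igraph::write_graph(g, dot_path, format = "dot")
    written <- c(written, dot = dot_path)
  }
  invisible(written)
}
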