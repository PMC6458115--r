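#' Quality-trim reads with a sliding window and a length floor
#'
#' Scans each read 5'->3' with a window of `window` bases and truncates the
#' read just before the first window whose mean quality falls below
#' `min_mean_q`. Reads shorter than `min_len` after trimming are dropped;
#' when the set carries `/1` `/2` mate suffixes, pairs are dropped together
#' if either mate fails.
#'
#' @param rs A `read_set` with Phred+33 quality strings.
#' @param window Window width in bases.
#' @param min_mean_q Minimum mean window quality.
#' @param min_len Minimum retained read length.
#' @return The filtered `read_set`.
#' @export
quality_filter_reads <- function(rs, window = 4L, min_mean_q = 20,
                                 min_len = 250L) {
  stopifnot(window >= 1)
  n <- length(rs)
  if (!n) return(rs)
  keep_len <- integer(n)
  for (i in seq_len(n)) {
    q <- utf8ToInt(rs$qual[i]) - 33L
    L <- length(q)
    if (L < window) {
      keep_len[i] <- if (mean(q) >= min_mean_q) L else 0L
      next
    }
    cs <- cumsum(q)
    wmean <- (cs[window:L] - c(0, cs)[1:(L - window + 1L)]) / window
    bad <- which(wmean < min_mean_q)
    keep_len[i] <- if (length(bad)) bad[1L] - 1L else L
  }
  ok <- keep_len >= min_len
  # drop mates together
  base_id <- sub("/[12]$", "", rs$id)
  if (anyDuplicated(base_id)) {
    bad_pairs <- unique(base_id[!ok])
    ok <- ok & !(base_id %in% bad_pairs)
  }
  out <- subset_reads(rs, which(ok))
  out$seq <- substr(out$seq, 1L, keep_len[ok])
  out$qual <- substr(out$qual, 1L, keep_len[ok])
  if (!is.null(rs$library)) out$library <- rs$library[ok]
  out
}

#' Uniformly sample reads without replacement
#'
#' @param rs A `read_set`.
#' @param n Sample size (`n <= length(rs)`).
#' @param seed Integer seed.
#' @return A `read_set` of `n` reads.
#' @export
sample_reads <- function(rs, n, seed = 1L) {
  if (n > length(rs)) stop("insufficient reads: asked ", n, " of ", length(rs))
  set.seed(seed)
  idx <- if (n == 0L) integer(0) else sort(sample.int(length(rs), n))
  out <- subset_reads(rs, idx)
  if (!is.null(rs$library)) out$library <- rs$library[idx]
  out
}

#' Cluster reads by shared canonical k-mer content
#'
#' Builds a read-similarity graph with an edge between two reads when the
#' number of distinct canonical k-mers they share is at least
#' `min_kmer_share` of the smaller of their k-mer sets (canonical k-mers
#' make the graph strand-symmetric). Connected components of size at least
#' `min_cluster_size` are returned, each with a consensus contig obtained
#' by majority vote over cluster members locally aligned to the cluster
#' medoid read.
#'
#' Reads whose k-mers are essentially private to themselves (fewer than
#' `min_kmer_share` of their k-mers seen in any other read) cannot take
#' part in a qualifying edge and are excluded before the quadratic step,
#' which keeps the graph construction linear in practice.
#'
#' Components are triaged for satellite-like structure before the
#' consensus step: a read made of tandem copies of a monomer carries at
#' most about one monomer's worth of distinct k-mers, far below the
#' k-mer diversity of a single-copy read, so clusters whose members have
#' median relative k-mer diversity above `max_kmer_diversity` (e.g.
#' overlapping single-copy reads at higher coverage) are discarded. This
#' quantitative triage plays the role of the visual cluster-shape
#' inspection used in graph-based repeat explorers.
#'
#' @param rs A `read_set`.
#' @param min_kmer_share Minimum shared-k-mer fraction for an edge.
#' @param k K-mer size (<= 15).
#' @param min_cluster_size Minimum component size to report.
#' @param max_consensus_members Members used for the consensus vote.
#' @param max_kmer_diversity Maximum median distinct-k-mer fraction of a
#'   cluster's reads for it to count as satellite-like.
#' @return List of `read_cluster` objects (fields `member_read_ids`,
#'   `consensus_contig`, `size`).
#' @export
cluster_reads <- function(rs, min_kmer_share = 0.2, k = 13L,
                          min_cluster_size = 5L,
                          max_consensus_members = 40L,
                          max_kmer_diversity = 0.85) {
  n <- length(rs)
  if (!n) return(list())
  stopifnot(k <= min(nchar(rs$seq)))
  sets <- cpp_kmer_sets(rs$seq, k)
  sizes <- lengths(sets)
  all_km <- unlist(sets, use.names = FALSE)
  km_levels <- unique(all_km)
  km_idx <- match(all_km, km_levels)
  df <- tabulate(km_idx, length(km_levels)) # document frequency per k-mer
  read_of <- rep.int(seq_len(n), sizes)
  shared_df <- df[km_idx] >= 2L
  n_shareable <- tabulate(read_of[shared_df], n)
  cand <- which(n_shareable >= pmax(1, 0.75 * min_kmer_share * sizes))
  if (length(cand) < min_cluster_size) return(list())
  keep_entry <- read_of %in% cand & shared_df
  inc <- Matrix::sparseMatrix(
    i = match(read_of[keep_entry], cand),
    j = km_idx[keep_entry], x = 1,
    dims = c(length(cand), length(km_levels)))
  shared <- Matrix::tcrossprod(inc)
  tri <- Matrix::which(shared > 0, arr.ind = TRUE)
  tri <- tri[tri[, 1] < tri[, 2], , drop = FALSE]
  if (!nrow(tri)) return(list())
  sc <- shared[tri]
  mins <- pmin(sizes[cand[tri[, 1]]], sizes[cand[tri[, 2]]])
  edge <- sc / mins >= min_kmer_share
  if (!any(edge)) return(list())
  g <- igraph::graph_from_edgelist(
    cbind(tri[edge, 1], tri[edge, 2]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(cand) - igraph::vcount(g)))
  comp <- igraph::components(g)
  out <- list()
  for (ci in which(comp$csize >= min_cluster_size)) {
    members <- cand[comp$membership == ci]
    rel_div <- sizes[members] / (nchar(rs$seq[members]) - k + 1L)
    if (stats::median(rel_div) > max_kmer_diversity) next
    # medoid: member with the largest normalized in-cluster k-mer share;
    # normalizing by the member's own set size demotes array-edge reads
    # whose background tail would otherwise pollute the consensus
    mi <- match(members, cand)
    tot_share <- Matrix::rowSums(shared[mi, mi, drop = FALSE])
    norm_share <- tot_share / sizes[members]
    medoid <- members[which.max(norm_share)]
    vote_members <- members[order(-norm_share)]
    vote_members <- utils::head(vote_members, max_consensus_members)
    consensus <- .cluster_consensus(rs$seq[medoid], rs$seq[vote_members])
    out[[length(out) + 1L]] <- structure(
      list(member_read_ids = rs$id[members],
           consensus_contig = consensus,
           size = length(members)),
      class = "read_cluster")
  }
  out[order(-vapply(out, `[[`, integer(1), "size"))]
}

# Majority-vote consensus over cluster members aligned to an anchor read.
.cluster_consensus <- function(anchor, members) {
  L <- nchar(anchor)
  votes <- matrix(0L, 4L, L, dimnames = list(DNA_BASES, NULL))
  for (m in members) {
    best <- NULL; used <- m
    for (s in c(m, revcomp(m))) {
      al <- cpp_align_local(s, anchor, keep_path = TRUE)
      if (is.null(best) || al$score > best$score) { best <- al; used <- s }
    }
    pair <- best$a_pos > 0 & best$b_pos > 0
    if (!any(pair)) next
    mb <- strsplit(used, "")[[1]]
    bases <- mb[best$a_pos[pair]]
    cols <- best$b_pos[pair]
    ok <- bases %in% DNA_BASES
    idx <- cbind(match(bases[ok], DNA_BASES), cols[ok])
    for (r in seq_len(nrow(idx))) {
      votes[idx[r, 1], idx[r, 2]] <- votes[idx[r, 1], idx[r, 2]] + 1L
    }
  }
  anchor_chars <- strsplit(anchor, "")[[1]]
  out <- vapply(seq_len(L), function(j) {
    if (sum(votes[, j]) == 0L) anchor_chars[j]
    else DNA_BASES[which.max(votes[, j])]
  }, character(1))
  paste(out, collapse = "")
}

#' Detect the tandem period of a contig by lag self-match
#'
#' For each lag `L` up to half the contig length, computes the fraction of
#' positions where the contig matches itself shifted by `L`. The smallest
#' lag reaching `min_match_fraction` is taken as the period; among lags
#' within 10\% of that candidate, the one maximizing the match fraction
#' wins (guards against off-by-noise lags). The monomer consensus is the
#' per-column majority over the lag-phased columns.
#'
#' @param contig DNA string (>= 20 nt).
#' @param min_match_fraction Minimum self-match fraction at the period.
#' @return A `tandem_call` (fields `contig`, `period`,
#'   `match_fraction_at_period`, `monomer_consensus`) or `NULL` when no lag
#'   qualifies.
#' @export
detect_tandem_period <- function(contig, min_match_fraction = 0.7) {
  n <- nchar(contig)
  stopifnot(n >= 20)
  x <- strsplit(contig, "")[[1]]
  max_lag <- n %/% 2L
  frac <- vapply(seq_len(max_lag), function(L) {
    mean(x[seq_len(n - L)] == x[(L + 1L):n])
  }, numeric(1))
  ok <- which(frac >= min_match_fraction)
  if (!length(ok)) return(NULL)
  cand <- ok[1L]
  near <- ok[abs(ok - cand) <= ceiling(0.1 * cand)]
  period <- near[which.max(frac[near])]
  cols <- ((seq_len(n) - 1L) %% period) + 1L
  monomer <- vapply(seq_len(period), function(j) {
    names(which.max(table(factor(x[cols == j], levels = DNA_BASES))))
  }, character(1))
  structure(list(contig = contig, period = period,
                 match_fraction_at_period = frac[period],
                 monomer_consensus = paste(monomer, collapse = "")),
            class = "tandem_call")
}

#' Remove reads matching a catalog of satellite monomers
#'
#' A read is masked (removed) when it aligns locally, on either strand, to
#' any catalog monomer tiled to circular completeness, with identity at
#' least `min_identity` over at least half the read. A canonical-k-mer
#' prescreen keeps the alignment step proportional to the number of
#' satellite-like reads.
#'
#' @param rs A `read_set`.
#' @param catalog Character vector of monomer consensus sequences.
#' @param min_identity Identity threshold for masking.
#' @param k Prescreen k-mer size.
#' @return The surviving `read_set`.
#' @export
mask_reads <- function(rs, catalog, min_identity = 0.8, k = 11L) {
  if (!length(catalog)) return(rs)
  if (!length(rs)) return(rs)
  tiled <- vapply(catalog, .tile_monomer, character(1),
                  target = max(nchar(rs$seq)))
  refs <- cpp_kmer_sets(tiled, k)
  hits <- cpp_kmer_match(rs$seq, k, refs)
  cand <- which(Matrix::rowSums(hits) > 0)
  masked <- logical(length(rs))
  for (i in cand) {
    rd <- rs$seq[i]
    half <- nchar(rd) / 2
    for (j in which(hits[i, ] > 0)) {
      for (s in c(rd, revcomp(rd))) {
        al <- cpp_align_local(s, tiled[j])
        if (al$alen > 0 && al$n_pairs >= half &&
            al$matches / al$alen >= min_identity) {
          masked[i] <- TRUE
          break
        }
      }
      if (masked[i]) break
    }
  }
  out <- subset_reads(rs, which(!masked))
  if (!is.null(rs$library)) out$library <- rs$library[!masked]
  out
}

# Tile a monomer head-to-tail so a read can align across copy junctions.
.tile_monomer <- function(m, target) {
  reps <- max(2L, ceiling(target / nchar(m)) + 1L)
  strrep(m, reps)
}

#' Iterative satellite discovery loop
#'
#' Joins the two libraries and repeats: sample reads from the unmasked
#' pool, cluster, detect tandem periods, add novel monomers to the catalog
#' (novel = below `dedup_identity` circular identity to every known
#' monomer), then mask the whole pool with the updated catalog. Round 1
#' samples `round0_n` reads per library; round 2 doubles the sample; later
#' rounds keep it constant. The loop ends when a round contributes no new
#' monomer or after `max_rounds`.
#'
#' @param female,male `read_set` libraries.
#' @param round0_n Reads sampled per library in round 1.
#' @param max_rounds Maximum number of rounds.
#' @param seed Integer seed (per-round sampling seeds are derived from it).
#' @param min_kmer_share,k,min_cluster_size Clustering parameters, see
#'   [cluster_reads()].
#' @param min_match_fraction Tandem-period threshold, see
#'   [detect_tandem_period()].
#' @param mask_identity Masking identity threshold, see [mask_reads()].
#' @param dedup_identity Circular identity above which a candidate monomer
#'   is considered already discovered.
#' @return Data frame of discovered monomers: `monomer`, `period`,
#'   `match_fraction`, `round`, `cluster_size`; the final unmasked pool is
#'   attached as attribute `"final_pool"` and a per-round log as
#'   attribute `"log"`.
#' @export
run_discovery_loop <- function(female, male, round0_n, max_rounds = 8L,
                               seed = 1L,
                               min_kmer_share = 0.2, k = 13L,
                               min_cluster_size = 5L,
                               min_match_fraction = 0.7,
                               mask_identity = 0.8,
                               dedup_identity = 0.8) {
  stopifnot(round0_n <= length(female), round0_n <= length(male))
  pool <- join_reads(female, male)
  calls <- data.frame(monomer = character(0), period = integer(0),
                      match_fraction = numeric(0), round = integer(0),
                      cluster_size = integer(0))
  log <- data.frame(round = integer(0), sampled = integer(0),
                    clusters = integer(0), new_calls = integer(0),
                    pool_size = integer(0))
  for (r in seq_len(max_rounds)) {
    n_per_lib <- if (r == 1L) round0_n else 2L * round0_n
    n_sample <- min(2L * n_per_lib, length(pool))
    smp <- sample_reads(pool, n_sample, seed = stage_seed(seed, r))
    clusters <- cluster_reads(smp, min_kmer_share, k, min_cluster_size)
    new_this_round <- 0L
    for (cl in clusters) {
      tc <- detect_tandem_period(cl$consensus_contig, min_match_fraction)
      if (is.null(tc)) next
      mono <- tc$monomer_consensus
      known <- nrow(calls) > 0 && any(vapply(calls$monomer, function(m) {
        circular_identity(mono, m) >= dedup_identity
      }, logical(1)))
      if (!known) {
        calls <- rbind(calls, data.frame(
          monomer = mono, period = tc$period,
          match_fraction = tc$match_fraction_at_period, round = r,
          cluster_size = cl$size))
        new_this_round <- new_this_round + 1L
      }
    }
    log <- rbind(log, data.frame(round = r, sampled = n_sample,
                                 clusters = length(clusters),
                                 new_calls = new_this_round,
                                 pool_size = length(pool)))
    if (new_this_round == 0L) break
    pool <- mask_reads(pool, calls$monomer, mask_identity)
    if (length(pool) < min_cluster_size) break
  }
  rownames(calls) <- NULL
  attr(calls, "final_pool") <- pool
  attr(calls, "log") <- log
  calls
}
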