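#' Downsample two libraries to equal size
#'
#' Comparative abundance between libraries of unequal depth requires equal
#' read numbers; both libraries are downsampled to `n` (default: the size
#' of the smaller library).
#'
#' @param female,male `read_set` libraries.
#' @param n Sample size, or `"min"` for the smaller library's size.
#' @param seed Integer seed.
#' @return List with downsampled `female` and `male` read sets.
#' @export
subsample_equal <- function(female, male, n = "min", seed = 1L) {
  if (identical(n, "min")) n <- min(length(female), length(male))
  if (n > length(female) || n > length(male)) {
    stop("n exceeds a library size")
  }
  list(female = sample_reads(female, n, seed = stage_seed(seed, 1L)),
       male = sample_reads(male, n, seed = stage_seed(seed, 2L)))
}

#' Align reads to a satellite catalog
#'
#' For each read, finds the best-scoring local alignment to any catalog
#' variant (either strand; variants are tiled head-to-tail so alignments
#' cross copy junctions, making the search circular-aware). The single
#' best hit wins its read segment; flanking segments long enough to hold
#' another hit are re-aligned (up to two extra passes), so hits never
#' overlap and abundance is not double-counted. Substitutions in each hit
#' are classified as transitions (A/G, C/T) or transversions for the
#' Kimura 2-parameter divergence downstream. Hits shorter than `min_len`
#' aligned bases or below `min_identity` are discarded.
#'
#' @param rs A `read_set`.
#' @param catalog Named character vector of variant consensus sequences,
#'   or a [build_catalog()] result (family representatives are used).
#' @param families Optional character vector mapping each catalog entry to
#'   a family id (defaults to the entry names).
#' @param min_identity Minimum alignment identity.
#' @param min_len Minimum aligned bases per hit.
#' @param k Prescreen k-mer size.
#' @return Data frame of hits: `read_id`, `library`, `family_id`,
#'   `variant_id`, `aligned_nt`, `matches`, `transitions`, `transversions`,
#'   `identity`, `k2p` (per-hit Kimura 2-parameter distance).
#' @export
align_to_catalog <- function(rs, catalog, families = NULL,
                             min_identity = 0.7, min_len = 20L, k = 13L) {
  if (inherits(catalog, "list") && !is.null(catalog$families)) {
    fam <- catalog$families
    catalog <- setNames(fam$consensus, fam$family_id)
  }
  if (!length(catalog)) stop("catalog must be non-empty")
  vids <- names(catalog)
  if (is.null(vids)) vids <- sprintf("var%03d", seq_along(catalog))
  if (is.null(families)) families <- vids
  empty <- data.frame(read_id = character(0), library = character(0),
                      family_id = character(0), variant_id = character(0),
                      aligned_nt = integer(0), matches = integer(0),
                      transitions = integer(0), transversions = integer(0),
                      identity = numeric(0), k2p = numeric(0))
  if (!length(rs)) return(empty)
  rl_max <- max(nchar(rs$seq))
  tiled <- vapply(unname(catalog), .tile_monomer, character(1),
                  target = rl_max)
  kk <- min(k, min(nchar(catalog)))
  refs <- cpp_kmer_sets(vapply(unname(catalog), strrep, character(1), 2L), kk)
  km <- cpp_kmer_match(rs$seq, kk, refs)
  lib <- .read_library(rs)
  rows <- vector("list", 256L); nr <- 0L
  add_row <- function(df) {
    nr <<- nr + 1L
    if (nr > length(rows)) rows <<- c(rows, vector("list", length(rows)))
    rows[[nr]] <<- df
  }
  score_segment <- function(seg, cand) {
    best <- NULL; best_j <- NA
    for (j in cand) {
      for (s in c(seg, revcomp(seg))) {
        al <- cpp_align_local(s, tiled[j])
        if (is.null(best) || al$score > best$score) {
          best <- al; best_j <- j
          best$rc <- !identical(s, seg)
        }
      }
    }
    list(al = best, j = best_j)
  }
  for (i in which(Matrix::rowSums(km) > 0)) {
    cand <- which(km[i, ] > 0)
    segments <- list(rs$seq[i]); depth <- 0L
    while (length(segments) && depth < 3L) {
      depth <- depth + 1L
      next_segments <- list()
      for (seg in segments) {
        if (nchar(seg) < min_len) next
        hit <- score_segment(seg, cand)
        al <- hit$al
        if (is.null(al) || al$n_pairs < min_len) next
        ident <- al$matches / al$alen
        if (ident < min_identity) next
        P <- al$transitions / al$n_pairs
        Q <- al$transversions / al$n_pairs
        add_row(data.frame(
          read_id = rs$id[i], library = lib[i],
          family_id = families[hit$j], variant_id = vids[hit$j],
          aligned_nt = al$n_pairs, matches = al$matches,
          transitions = al$transitions, transversions = al$transversions,
          identity = ident,
          k2p = kimura2p(P, Q, warn = FALSE),
          stringsAsFactors = FALSE))
        # unaligned flanks may contain a different family
        a1 <- al$a_start; a2 <- al$a_end
        if (al$rc) {
          w <- nchar(seg)
          tmp <- a1; a1 <- w - a2 + 1L; a2 <- w - tmp + 1L
        }
        if (a1 - 1L >= 2L * min_len) {
          next_segments <- c(next_segments, substr(seg, 1L, a1 - 1L))
        }
        if (nchar(seg) - a2 >= 2L * min_len) {
          next_segments <- c(next_segments, substr(seg, a2 + 1L, nchar(seg)))
        }
      }
      segments <- next_segments
    }
  }
  if (!nr) return(empty)
  out <- do.call(rbind, rows[seq_len(nr)])
  rownames(out) <- NULL
  out
}

#' Per-family abundance as a nucleotide fraction of the library
#'
#' Abundance of a family = aligned nucleotides attributed to that family
#' divided by the total nucleotides in the library (sum of read lengths).
#'
#' @param hits Hit data frame from [align_to_catalog()].
#' @param rs The `read_set` the hits were computed on.
#' @param family_ids Optional families to report (defaults to those in
#'   `hits`; pass a catalog's family ids to get explicit zeros).
#' @return Named numeric vector of abundance fractions.
#' @export
abundance <- function(hits, rs, family_ids = NULL) {
  if (!length(rs)) stop("empty library")
  total_nt <- sum(nchar(rs$seq))
  if (is.null(family_ids)) family_ids <- sort(unique(hits$family_id))
  out <- setNames(numeric(length(family_ids)), family_ids)
  if (nrow(hits)) {
    agg <- tapply(hits$aligned_nt, hits$family_id, sum)
    out[names(agg)[names(agg) %in% family_ids]] <-
      agg[names(agg) %in% family_ids] / total_nt
  }
  out
}

#' Kimura 2-parameter distance
#'
#' `K = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`, with `P` the transition
#' and `Q` the transversion proportion over aligned bases. Returns `NA`
#' (saturation) when the log domain is violated.
#'
#' @param P Transition proportion.
#' @param Q Transversion proportion.
#' @param warn Warn on saturation.
#' @return Distance (substitutions per site), `NA_real_` if saturated.
#' @export
kimura2p <- function(P, Q, warn = TRUE) {
  stopifnot(length(P) == length(Q))
  w <- 1 - 2 * P - Q
  v <- 1 - 2 * Q
  bad <- w <= 0 | v <= 0
  if (any(bad) && warn) warning("Kimura 2-parameter distance saturated")
  k <- rep(NA_real_, length(P))
  ok <- !bad
  k[ok] <- -0.5 * log(w[ok] * sqrt(v[ok]))
  k
}

#' Family divergence: aligned-nt-weighted mean Kimura distance, in percent
#'
#' @param hits Hits of one family (saturated hits are dropped).
#' @return Divergence percentage, or `NA` when the family has no hits
#'   (printed as missing for families absent from a library).
#' @export
family_divergence <- function(hits) {
  ok <- !is.na(hits$k2p)
  if (!nrow(hits) || !any(ok)) return(NA_real_)
  100 * weighted.mean(hits$k2p[ok], hits$aligned_nt[ok])
}

#' Repeat landscape: abundance binned by Kimura divergence
#'
#' Each hit contributes `aligned_nt / library nt` to the bin containing
#' its Kimura 2-parameter percentage. Bins therefore sum exactly to the
#' family abundance.
#'
#' @param hits Hit data frame from [align_to_catalog()].
#' @param rs The `read_set` the hits were computed on.
#' @param bin_width Bin width in divergence percent.
#' @param max_bin Highest bin lower bound to report.
#' @return A `repeat_landscape` data frame: `family_id`, `bin_lower`,
#'   `value`, with attribute `bin_width`.
#' @export
build_landscape <- function(hits, rs, bin_width = 1, max_bin = 50) {
  stopifnot(bin_width > 0)
  total_nt <- sum(nchar(rs$seq))
  fams <- sort(unique(hits$family_id))
  bins <- seq(0, max_bin, by = bin_width)
  if (!length(fams)) {
    return(structure(data.frame(family_id = character(0),
                                bin_lower = numeric(0), value = numeric(0)),
                     bin_width = bin_width,
                     class = c("repeat_landscape", "data.frame")))
  }
  grid <- expand.grid(bin_lower = bins, family_id = fams,
                      stringsAsFactors = FALSE)[, 2:1]
  grid$value <- 0
  if (nrow(hits)) {
    k2p_pct <- pmin(100 * hits$k2p, max_bin + bin_width / 2)
    k2p_pct[is.na(k2p_pct)] <- max_bin
    bl <- pmin(floor(k2p_pct / bin_width) * bin_width, max_bin)
    contrib <- hits$aligned_nt / total_nt
    key <- paste(hits$family_id, bl)
    agg <- tapply(contrib, key, sum)
    gkey <- paste(grid$family_id, grid$bin_lower)
    m <- match(names(agg), gkey)
    grid$value[m[!is.na(m)]] <- agg[!is.na(m)]
  }
  structure(grid, bin_width = bin_width, class = c("repeat_landscape",
                                                   class(grid)))
}

#' Subtractive (female minus male) repeat landscape
#'
#' Per-bin difference of two landscapes on the same bin grid; positive
#' values flag divergence classes over-represented in the female library,
#' the signature of W-linked accumulation.
#'
#' @param female,male `repeat_landscape` objects with equal `bin_width`.
#' @return Signed landscape data frame (same shape, `value` = F - M).
#' @export
subtract_landscapes <- function(female, male) {
  bwf <- attr(female, "bin_width"); bwm <- attr(male, "bin_width")
  if (!isTRUE(all.equal(bwf, bwm))) stop("mismatched bin widths")
  fams <- sort(unique(c(female$family_id, male$family_id)))
  bins <- sort(unique(c(female$bin_lower, male$bin_lower)))
  grid <- expand.grid(bin_lower = bins, family_id = fams,
                      stringsAsFactors = FALSE)[, 2:1]
  key <- function(d) paste(d$family_id, d$bin_lower)
  gk <- key(grid)
  fv <- setNames(female$value, key(female))
  mv <- setNames(male$value, key(male))
  grid$value <- ifelse(is.na(fv[gk]), 0, fv[gk]) -
    ifelse(is.na(mv[gk]), 0, mv[gk])
  structure(grid, bin_width = bwf,
            class = c("repeat_landscape", "data.frame"))
}

#' Female/male abundance ratio
#'
#' The F/M ratio of a family; values well above 1 indicate accumulation in
#' the female (ZW) genome, the expected signature of W-linkage. Families
#' absent from the male library get `Inf` (the absent-in-male flag, which
#' sorts above every finite ratio); families absent from both get `NaN`.
#'
#' @param abundance_female,abundance_male Non-negative abundances.
#' @return Numeric vector of ratios (`Inf` = absent in male).
#' @export
fm_ratio <- function(abundance_female, abundance_male) {
  stopifnot(all(abundance_female >= 0), all(abundance_male >= 0))
  ifelse(abundance_male > 0, abundance_female / abundance_male,
         ifelse(abundance_female > 0, Inf, NaN))
}

#' Rank W-chromosome candidate families by F/M ratio
#'
#' Descending F/M ratio with absent-in-male families first (ordered among
#' themselves by female abundance), mirroring how candidate tables place
#' the female-exclusive families at the top.
#'
#' @param records Data frame with `family_id`, `abundance_female`,
#'   `fm_ratio` (and any other columns, carried through).
#' @param top_k Number of candidates to return.
#' @return The top `top_k` rows in rank order.
#' @export
rank_candidates <- function(records, top_k) {
  stopifnot(nrow(records) >= 1)
  if (top_k <= 0) stop("top_k must be positive")
  r <- records$fm_ratio
  r[is.nan(r)] <- -Inf
  ord <- order(-is.infinite(r) * (r > 0),
               ifelse(is.infinite(r) & r > 0, -records$abundance_female, 0),
               -ifelse(is.finite(r), r, 0),
               -records$abundance_female,
               records$family_id)
  utils::head(records[ord, , drop = FALSE], top_k)
}

#' Full per-family abundance/divergence table for two libraries
#'
#' Runs [align_to_catalog()] on both libraries (already subsampled to equal
#' size), then assembles the per-family summary: abundances, divergences,
#' and F/M ratio, in decreasing F/M order.
#'
#' @param female,male Equal-size `read_set` libraries.
#' @param catalog Named character vector of family consensus sequences or
#'   a [build_catalog()] result.
#' @param ... Passed to [align_to_catalog()].
#' @return List with `table` (the per-family data frame), `hits_female`,
#'   `hits_male`.
#' @export
abundance_table <- function(female, male, catalog, ...) {
  if (inherits(catalog, "list") && !is.null(catalog$families)) {
    catalog <- setNames(catalog$families$consensus,
                        catalog$families$family_id)
  }
  hf <- align_to_catalog(female, catalog, ...)
  hm <- align_to_catalog(male, catalog, ...)
  fams <- names(catalog)
  ab_f <- abundance(hf, female, fams)
  ab_m <- abundance(hm, male, fams)
  div_f <- vapply(fams, function(f) {
    family_divergence(hf[hf$family_id == f, , drop = FALSE])
  }, numeric(1))
  div_m <- vapply(fams, function(f) {
    family_divergence(hm[hm$family_id == f, , drop = FALSE])
  }, numeric(1))
  tab <- data.frame(family_id = fams, rul = nchar(catalog),
                    at_content = at_content(unname(catalog)),
                    abundance_female = unname(ab_f),
                    abundance_male = unname(ab_m),
                    divergence_female = unname(div_f),
                    divergence_male = unname(div_m),
                    fm_ratio = fm_ratio(unname(ab_f), unname(ab_m)),
                    stringsAsFactors = FALSE)
  tab <- rank_candidates(tab, nrow(tab))
  list(table = tab, hits_female = hf, hits_male = hm)
}
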