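# Shared synthetic scenarios. Monomers are drawn mutually dissimilar
# (<70% circular identity) so planted families are unambiguous.

draw_dissimilar_monomers <- function(lengths, seed) {
  set.seed(seed)
  monomers <- character(0)
  for (L in lengths) {
    repeat {
      m <- random_dna(L)
      if (!length(monomers) ||
          max(vapply(monomers, function(x) circular_identity(m, x),
                     numeric(1))) < 0.7) break
    }
    monomers <- c(monomers, m)
  }
  monomers
}

# Five-family ZW scenario: four autosomal families of decreasing abundance
# plus one W-linked family. `fractions` are approximate genome fractions.
make_family_specs <- function(monomers, background, fractions,
                              linkages = c("autosomal", "autosomal",
                                           "autosomal", "autosomal", "W"),
                              sub_rate = 0.02) {
  stopifnot(length(monomers) == length(fractions))
  lapply(seq_along(monomers), function(i) {
    copies <- max(1L, round(fractions[i] * background / nchar(monomers[i])))
    family_spec(sprintf("fam%02d", i), monomers[i],
                copies_female = copies,
                copies_male = if (linkages[i] == "W") 0L
                              else if (linkages[i] == "Z") 2L * copies
                              else copies,
                n_arrays = max(1L, min(3L, copies %/% 10L)),
                per_copy_substitution_rate = sub_rate,
                linkage = linkages[i])
  })
}

# independent per-read sliding-window quality trim (oracle for
# quality_filter_reads): position-by-position re-scan
oracle_window_trim <- function(qual, window, min_q) {
  q <- utf8ToInt(qual) - 33L
  L <- length(q)
  if (L < window) return(if (mean(q) >= min_q) L else 0L)
  for (s in seq_len(L - window + 1L)) {
    if (mean(q[s:(s + window - 1L)]) < min_q) return(s - 1L)
  }
  L
}

# decode a Pruefer sequence into the edge list of a labelled tree on n nodes
pruefer_decode <- function(pr, n) {
  degree <- rep(1L, n)
  for (v in pr) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  ptr <- 0L
  for (v in pr) {
    leaf <- which(degree == 1L)[1L]
    ptr <- ptr + 1L
    edges[ptr, ] <- c(leaf, v)
    degree[leaf] <- 0L
    degree[v] <- degree[v] - 1L
  }
  last <- which(degree == 1L)
  edges[n - 1L, ] <- last
  edges
}

# exhaustive minimum spanning weight over all labelled trees (Cayley)
oracle_min_spanning_weight <- function(d) {
  n <- nrow(d)
  if (n == 1L) return(0)
  if (n == 2L) return(d[1, 2])
  prs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  for (r in seq_len(nrow(prs))) {
    e <- pruefer_decode(prs[r, ], n)
    w <- sum(d[e])
    if (w < best) best <- w
  }
  best
}
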