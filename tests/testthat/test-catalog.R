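# independent oracle: alignment identity maximized over every explicit
# rotation of the partner and both strands, with the same scores as the
# implementation but a separate R dynamic program (no doubling trick);
# the shorter sequence aligns globally, the partner contributes free end
# gaps whose uncovered length is charged to the alignment length
oracle_rotation_identity <- function(a, b, match = 1, mismatch = -2,
                                     gap = -3) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  na <- nchar(a); nb <- nchar(b)
  av <- strsplit(a, "")[[1]]
  best <- 0
  rots <- function(x) {
    xx <- paste0(x, x)
    vapply(seq_len(nchar(x)),
           function(i) substr(xx, i, i + nchar(x) - 1L), character(1))
  }
  best_score <- -Inf
  for (bb in c(rots(b), rots(revcomp(b)))) {
    bv <- strsplit(bb, "")[[1]]
    S <- matrix(0, na + 1, nb + 1)
    M <- matrix(0L, na + 1, nb + 1) # matches on best path
    L <- matrix(0L, na + 1, nb + 1) # internal alignment columns
    B <- matrix(0L, na + 1, nb + 1) # partner positions consumed
    S[, 1] <- gap * (0:na); L[, 1] <- 0:na
    for (i in 2:(na + 1)) {
      for (j in 2:(nb + 1)) {
        m <- av[i - 1] == bv[j - 1]
        cand <- c(S[i - 1, j - 1] + if (m) match else mismatch,
                  S[i - 1, j] + gap, S[i, j - 1] + gap)
        k <- which.max(cand)
        S[i, j] <- cand[k]
        if (k == 1) {
          M[i, j] <- M[i - 1, j - 1] + m
          L[i, j] <- L[i - 1, j - 1] + 1L
          B[i, j] <- B[i - 1, j - 1] + 1L
        } else if (k == 2) {
          M[i, j] <- M[i - 1, j]; L[i, j] <- L[i - 1, j] + 1L
          B[i, j] <- B[i - 1, j]
        } else {
          M[i, j] <- M[i, j - 1]; L[i, j] <- L[i, j - 1] + 1L
          B[i, j] <- B[i, j - 1] + 1L
        }
      }
    }
    for (j in 1:(nb + 1)) { # free suffix of the partner
      len <- L[na + 1, j] + (nb - B[na + 1, j])
      if (len == 0) next
      # same selection rule as the implementation: maximize the alignment
      # score; identity reported for the best-scoring alignment
      if (S[na + 1, j] > best_score ||
          (S[na + 1, j] == best_score && M[na + 1, j] / len > best)) {
        if (S[na + 1, j] > best_score) best <- M[na + 1, j] / len
        else best <- max(best, M[na + 1, j] / len)
        best_score <- S[na + 1, j]
      }
    }
  }
  best
}

test_that("circular identity is exact on identity, rotation and strand", {
  expect_equal(circular_identity("ACGTACGTAC", "ACGTACGTAC"), 1.0)
  expect_equal(circular_identity("ACGTACGT", "GTACGTAC"), 1.0)
  expect_equal(circular_identity("AACCG", revcomp("AACCG")), 1.0)
})

test_that("circular identity counts substitutions as constructed", {
  set.seed(10)
  m <- random_dna(50)
  chars <- strsplit(m, "")[[1]]
  pos <- sample(50, 5)
  for (p in pos) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  expect_equal(circular_identity(m, paste(chars, collapse = "")), 0.90)
})

test_that("circular identity matches the exhaustive rotation-strand oracle", {
  set.seed(12)
  monomers <- vapply(1:8, function(i) random_dna(sample(12:30, 1)),
                     character(1))
  # include a rotated mutant so related pairs are covered too
  monomers[2] <- paste0(substr(monomers[1], 6, nchar(monomers[1])),
                        substr(monomers[1], 1, 5))
  for (i in 1:7) {
    for (j in (i + 1):8) {
      a <- monomers[i]; b <- monomers[j]
      expect_equal(circular_identity(a, b), oracle_rotation_identity(a, b),
                   tolerance = 0.05)
    }
  }
})

test_that("canonical monomer is the lexicographic minimum and idempotent", {
  expect_equal(canonical_monomer("GAT"),
               min(c("GAT", "ATG", "TGA", "ATC", "TCA", "CAT")))
  expect_equal(canonical_monomer("GAT"), "ATC")
  expect_equal(canonical_monomer("AAA"), "AAA")
  set.seed(14)
  for (i in 1:20) {
    m <- random_dna(sample(5:40, 1))
    cm <- canonical_monomer(m)
    expect_equal(canonical_monomer(cm), cm)
    # invariant to rotation and strand of the input
    rot <- paste0(substr(m, 3, nchar(m)), substr(m, 1, 2))
    expect_equal(canonical_monomer(rot), cm)
    expect_equal(canonical_monomer(revcomp(m)), cm)
  }
})

test_that("hierarchy groups by single linkage at nested thresholds", {
  set.seed(16)
  a <- random_dna(60)
  mutate_n <- function(x, n) {
    chars <- strsplit(x, "")[[1]]
    pos <- sample(length(chars), n)
    for (p in pos) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
    paste(chars, collapse = "")
  }
  near <- mutate_n(a, 2)        # ~97%: same variant
  b <- mutate_n(a, 9)           # ~85%: same family, different variant
  c_ <- mutate_n(b, 9)          # ~85% to b, ~72% to a: single linkage chain
  far <- draw_dissimilar_monomers(55, seed = 17) # unrelated
  short <- "ACGGTCAGATTGCATCC" # 17 nt: identity vs 60-mers capped at ~0.28
  h <- group_hierarchy(c(v1 = a, v2 = near, v3 = b, v4 = c_, v5 = far,
                         v6 = short))
  idm <- attr(h, "identity")
  expect_gt(idm[1, 2], 0.95)
  expect_gt(idm[1, 3], 0.80)
  expect_gt(idm[3, 4], 0.80)
  expect_lt(idm[1, 4], 0.80) # a-c below threshold, linked via b
  expect_equal(h$variant_group[1], h$variant_group[2])
  expect_equal(length(unique(h$family_group[1:4])), 1)
  # an unrelated monomer never joins the family
  expect_false(h$family_group[5] == h$family_group[1])
  # a monomer with an incompatible repeat unit length falls below even the
  # superfamily threshold (identity is capped by the length ratio)
  expect_lt(idm[1, 6], 0.40)
  expect_false(h$sf_group[6] == h$sf_group[1])
})

test_that("the three partitions are strictly nested on random inputs", {
  set.seed(18)
  pool <- c(draw_dissimilar_monomers(c(30, 40, 50), seed = 19))
  monomers <- unlist(lapply(pool, function(m) {
    chars <- strsplit(m, "")[[1]]
    mut <- function(n) {
      cc <- chars
      pos <- sample(length(cc), n)
      for (p in pos) cc[p] <- setdiff(c("A", "C", "G", "T"), cc[p])[1]
      paste(cc, collapse = "")
    }
    c(m, mut(1), mut(ceiling(nchar(m) * 0.1)))
  }))
  h <- group_hierarchy(monomers)
  nested <- function(fine, coarse) {
    all(vapply(split(coarse, fine),
               function(x) length(unique(x)) == 1, logical(1)))
  }
  expect_true(nested(h$variant_group, h$family_group))
  expect_true(nested(h$family_group, h$sf_group))
})

test_that("the hierarchy is invariant to rotating or reverse-complementing inputs", {
  set.seed(20)
  monomers <- unlist(lapply(draw_dissimilar_monomers(c(30, 42), seed = 21),
                            function(m) {
    chars <- strsplit(m, "")[[1]]
    p <- sample(length(chars), 2)
    for (q in p) chars[q] <- setdiff(c("A", "C", "G", "T"), chars[q])[1]
    c(m, paste(chars, collapse = ""))
  }))
  h1 <- group_hierarchy(monomers)
  perturbed <- monomers
  perturbed[2] <- paste0(substr(monomers[2], 8, nchar(monomers[2])),
                         substr(monomers[2], 1, 7))
  perturbed[3] <- revcomp(monomers[3])
  h2 <- group_hierarchy(perturbed)
  relabel <- function(x) match(x, unique(x))
  expect_equal(relabel(h1$family_group), relabel(h2$family_group))
  expect_equal(relabel(h1$sf_group), relabel(h2$sf_group))
  expect_equal(relabel(h1$variant_group), relabel(h2$variant_group))
})

test_that("catalog names rank families by female abundance with stable ties", {
  fams <- data.frame(family_group = 1:2, rul = c(53L, 72L),
                     abundance_female = c(0.25, 0.12),
                     abundance_male = c(0.1, 0.1),
                     consensus = c("A", "C"))
  named <- assign_names(fams, prefix = "X")
  expect_equal(named$family_id, c("XSat001-53", "XSat002-72"))
  single <- assign_names(fams[1, ], prefix = "X")
  expect_equal(single$family_id, "XSat001-53")
  # permutation invariance
  named2 <- assign_names(fams[2:1, ], prefix = "X")
  expect_equal(named2$family_id, named$family_id)
  expect_error(assign_names(rbind(fams, fams[1, ]), prefix = "X"),
               "duplicate")
})
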