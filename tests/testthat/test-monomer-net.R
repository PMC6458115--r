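test_that("harvest excises complete phased monomers from tandem reads", {
  mono <- "ACGGTCAGATTGCATCCAGTTAGGACTTCGAACGGTTACCAGGTAATCGA" # 50 nt
  # phase 0: the read is exactly 5 complete copies
  rs <- read_set("r1", strrep(mono, 5), library_label = "female")
  m <- harvest_monomers(rs, mono)
  expect_equal(nrow(m), 5)
  expect_true(all(m$aligned == mono))
  expect_true(all(m$sequence == mono))
  # shifted phase: first and last copies are clipped, 4 complete remain
  shifted <- substr(strrep(mono, 6), 11, 10 + 250)
  m2 <- harvest_monomers(read_set("r2", shifted, library_label = "male"),
                         mono)
  expect_equal(nrow(m2), 4)
  expect_true(all(m2$aligned == mono))
  # reverse-strand read comes back in consensus orientation
  m3 <- harvest_monomers(read_set("r3", revcomp(strrep(mono, 5)),
                                  library_label = "female"), mono)
  expect_equal(nrow(m3), 5)
  expect_true(all(m3$aligned == mono))
  # unrelated read yields nothing
  set.seed(31)
  m4 <- harvest_monomers(read_set("r4", random_dna(250),
                                  library_label = "female"), mono)
  expect_equal(nrow(m4), 0)
  # a consensus longer than the reads cannot be harvested
  expect_error(harvest_monomers(rs, strrep(mono, 6)), "longer")
})

test_that("haplotype collapse keeps per-sex counts and drops singletons", {
  mono <- strrep("ACGGT", 8)
  mut <- sub("A", "G", mono)
  m <- data.frame(
    sequence = c(mono, mono, mono, mut),
    aligned = c(mono, mono, mono, mut),
    source_read = sprintf("r%d", 1:4),
    source_library = c("female", "female", "male", "female"))
  haps <- collapse_haplotypes(m, drop_singletons = TRUE)
  expect_equal(nrow(haps), 1)
  expect_equal(haps$count_female, 2)
  expect_equal(haps$count_male, 1)
  haps2 <- collapse_haplotypes(m, drop_singletons = FALSE)
  expect_equal(nrow(haps2), 2)
  # count conservation before filtering
  expect_equal(sum(haps2$total), nrow(m))
})

test_that("planted haplotype frequencies survive collapse", {
  base <- strrep("ACGGTCAGAT", 4)
  mutate_at <- function(x, pos) {
    chars <- strsplit(x, "")[[1]]
    chars[pos] <- setdiff(c("A", "C", "G", "T"), chars[pos])[1]
    paste(chars, collapse = "")
  }
  haps_true <- c(base, mutate_at(base, 3), mutate_at(base, 7),
                 mutate_at(base, 11), mutate_at(base, 17))
  counts <- c(10, 8, 4, 2, 1)
  m <- data.frame(sequence = rep(haps_true, counts),
                  aligned = rep(haps_true, counts),
                  source_read = sprintf("r%02d", seq_len(sum(counts))),
                  source_library = "female")
  haps <- collapse_haplotypes(m, drop_singletons = TRUE)
  expect_equal(nrow(haps), 4)
  expect_equal(haps$total, c(10, 8, 4, 2))
})

test_that("pairwise steps is a Hamming distance with gaps as a fifth state", {
  expect_equal(pairwise_steps("ACGT", "ACGT"), 0)
  expect_equal(pairwise_steps("ACGT", "ACTT"), 1)
  expect_equal(pairwise_steps("AC-T", "ACTT"), 1)
  expect_error(pairwise_steps("ACG", "ACGT"), "aligned")
  set.seed(33)
  for (i in 1:20) {
    a <- random_dna(30); b <- random_dna(30)
    recount <- sum(mapply(function(x, y) x != y,
                          strsplit(a, "")[[1]], strsplit(b, "")[[1]]))
    expect_equal(pairwise_steps(a, b), recount)
  }
})

test_that("two haplotypes connect by a single edge of their distance", {
  haps <- data.frame(sequence = c("ACGT", "ACTT"), count_female = c(3L, 2L),
                     count_male = c(1L, 0L), total = c(4L, 2L))
  g <- build_mst(haps)
  expect_true(g$tree_flag)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$steps, 1)
})

test_that("the documented 4-node tie case resolves to minimal weight", {
  d <- matrix(c(0, 1, 1, 3,
                1, 0, 2, 2,
                1, 2, 0, 2,
                3, 2, 2, 0), 4, 4, byrow = TRUE)
  haps <- data.frame(sequence = c("A", "B", "C", "D"),
                     count_female = c(5L, 1L, 1L, 1L),
                     count_male = c(0L, 0L, 0L, 0L),
                     total = c(5L, 1L, 1L, 1L))
  g <- build_mst(haps, d)
  expect_equal(sum(g$edges$steps), 4)
  expect_equal(oracle_min_spanning_weight(d), 4)
})

test_that("a strict star topology yields exactly the star tree", {
  k <- 5
  d <- matrix(2L, k + 1, k + 1)
  d[1, ] <- d[, 1] <- 1L
  diag(d) <- 0L
  haps <- data.frame(sequence = letters[1:(k + 1)],
                     count_female = rep(1L, k + 1),
                     count_male = rep(0L, k + 1),
                     total = c(10L, rep(1L, k)))
  g <- build_mst(haps, d)
  expect_equal(sum(g$edges$steps), k)
  expect_true(all(g$edges$from == 1 | g$edges$to == 1))
})

test_that("MST weight equals exhaustive enumeration on small random cases", {
  set.seed(35)
  for (trial in 1:25) {
    n <- sample(2:6, 1)
    d <- matrix(0L, n, n)
    d[upper.tri(d)] <- sample(1:9, n * (n - 1) / 2, replace = TRUE)
    d <- d + t(d)
    haps <- data.frame(sequence = letters[1:n],
                       count_female = sample(0:5, n, replace = TRUE),
                       count_male = sample(0:5, n, replace = TRUE))
    haps$total <- haps$count_female + haps$count_male
    g <- build_mst(haps, d)
    expect_equal(nrow(g$edges), n - 1)
    expect_equal(sum(g$edges$steps), oracle_min_spanning_weight(d))
  }
})

test_that("female-only haplotypes cluster together on the tree", {
  base <- strrep("ACGGTCAGATCCTGA", 3) # 45 nt
  mutate_at <- function(x, pos) {
    chars <- strsplit(x, "")[[1]]
    for (p in pos) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
    paste(chars, collapse = "")
  }
  ok <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    p <- sample(45, 7)
    shared <- c(base, mutate_at(base, p[1]), mutate_at(base, p[2]))
    w_core <- mutate_at(base, p[3:5])
    w_haps <- c(w_core, mutate_at(w_core, p[6]), mutate_at(w_core, p[7]))
    m <- data.frame(
      sequence = c(rep(shared, c(12, 6, 4)), rep(w_haps, c(8, 3, 2))),
      aligned = c(rep(shared, c(12, 6, 4)), rep(w_haps, c(8, 3, 2))),
      source_read = sprintf("r%03d", 1:35),
      source_library = c(rep(c("female", "male"), 11),
                         rep("female", 13)))
    haps <- collapse_haplotypes(m)
    g <- build_mst(haps)
    w_nodes <- which(haps$count_male == 0)
    sub <- igraph::induced_subgraph(as_igraph(g), w_nodes)
    if (igraph::components(sub)$no == 1) ok <- ok + 1L
  }
  expect_gte(ok, 9)
})

test_that("graph export round-trips through GraphML with attributes intact", {
  haps <- data.frame(sequence = c("ACGT", "ACTT", "GCTT"),
                     count_female = c(4L, 2L, 0L),
                     count_male = c(1L, 0L, 2L))
  haps$total <- haps$count_female + haps$count_male
  g <- build_mst(haps)
  gml <- tempfile(fileext = ".graphml")
  dot <- tempfile(fileext = ".dot")
  export_graph(g, gml, dot)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), 3)
  expect_equal(igraph::ecount(back), 2)
  expect_equal(sort(igraph::V(back)$size), sort(haps$total))
  expect_equal(sum(igraph::V(back)$size), sum(haps$total))
  expect_equal(sum(igraph::E(back)$weight), sum(g$edges$steps))
  expect_true(file.exists(dot) && file.size(dot) > 0)
  # empty graph (single node, no edges) still exports a valid document
  single <- build_mst(haps[1, , drop = FALSE])
  gml1 <- tempfile(fileext = ".graphml")
  export_graph(single, gml1)
  back1 <- igraph::read_graph(gml1, format = "graphml")
  expect_equal(igraph::vcount(back1), 1)
  expect_equal(igraph::ecount(back1), 0)
})
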