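test_that("equal-size subsampling follows the min rule deterministically", {
  big <- read_set(sprintf("f%04d", 1:1000),
                  rep(strrep("ACGT", 25), 1000), library_label = "female")
  small <- read_set(sprintf("m%03d", 1:600),
                    rep(strrep("TGCA", 25), 600), library_label = "male")
  eq <- subsample_equal(big, small, n = "min", seed = 4)
  expect_equal(length(eq$female), 600)
  expect_equal(length(eq$male), 600)
  eq2 <- subsample_equal(big, small, n = "min", seed = 4)
  expect_identical(eq$female$id, eq2$female$id)
  eq0 <- subsample_equal(big, small, n = 0, seed = 4)
  expect_equal(length(eq0$female), 0)
  expect_error(subsample_equal(big, small, n = 700), "exceeds")
})

test_that("catalog alignment classifies substitutions and covers tandem reads", {
  mono <- "ACGGTCAGATTGCATCCAGTTAGGACTTCGAACGGTTACCAGGTAATCGA" # 50 nt
  read <- strrep(mono, 5)
  rs <- read_set("r1", read, library_label = "female")
  hits <- align_to_catalog(rs, c(fam1 = mono))
  expect_equal(nrow(hits), 1)
  expect_gte(hits$aligned_nt, 245)
  expect_equal(hits$transitions, 0)
  expect_equal(hits$transversions, 0)
  expect_equal(hits$identity, 1)
  expect_equal(hits$k2p, 0)

  # single interior A->G transition (terminal mismatches would be clipped
  # by the local alignment, so mutate mid-read)
  stopifnot(substr(read, 101, 101) == "A")
  read2 <- read; substr(read2, 101, 101) <- "G"
  hits2 <- align_to_catalog(read_set("r2", read2,
                                     library_label = "female"),
                            c(fam1 = mono))
  expect_equal(hits2$transitions, 1)
  expect_equal(hits2$transversions, 0)

  read3 <- read; substr(read3, 101, 101) <- "T" # interior A->T transversion
  hits3 <- align_to_catalog(read_set("r3", read3,
                                     library_label = "female"),
                            c(fam1 = mono))
  expect_equal(hits3$transitions, 0)
  expect_equal(hits3$transversions, 1)
})

test_that("abundance is aligned nucleotides over library nucleotides", {
  rs <- read_set(sprintf("r%02d", 1:10), rep(strrep("ACGT", 62), 10)[1:10],
                 library_label = "female")
  rs$seq <- rep(strrep("A", 250), 10)
  hits <- data.frame(read_id = c("r01", "r02"), family_id = "f1",
                     aligned_nt = c(100L, 100L))
  expect_equal(unname(abundance(hits, rs)), 200 / 2500)
  expect_equal(unname(abundance(hits[0, ], rs, "f1")), 0)
  expect_error(abundance(hits, read_set(character(0), character(0),
                                        character(0))), "empty")
})

test_that("Kimura two-parameter distance matches its closed form", {
  expect_identical(kimura2p(0, 0), 0)
  expect_equal(kimura2p(0.2, 0.1), -0.5 * log(0.5 * sqrt(0.8)),
               tolerance = 1e-12)
  expect_gt(kimura2p(0.1, 0), kimura2p(0.05, 0))
  expect_warning(res <- kimura2p(0.5, 0.2), "saturated")
  expect_true(is.na(res))
})

test_that("family divergence is the aligned-nt-weighted Kimura mean", {
  h0 <- data.frame(aligned_nt = c(100, 100), k2p = c(0, 0))
  expect_equal(family_divergence(h0), 0)
  h <- data.frame(aligned_nt = c(100, 100), k2p = c(0.10, 0.20))
  expect_equal(family_divergence(h), 15)
  hw <- data.frame(aligned_nt = c(300, 100), k2p = c(0.10, 0.20))
  expect_equal(family_divergence(hw), 12.5)
  expect_true(is.na(family_divergence(h[0, ])))
})

test_that("landscapes bin abundance by divergence and conserve totals", {
  rs <- read_set(sprintf("r%02d", 1:10), rep(strrep("A", 250), 10),
                 library_label = "female")
  hits <- data.frame(read_id = c("r01", "r02", "r03"),
                     family_id = c("f1", "f1", "f2"),
                     aligned_nt = c(100L, 150L, 200L),
                     k2p = c(0.001, 0.052, 0.121))
  ls <- build_landscape(hits, rs, bin_width = 1)
  expect_equal(sum(ls$value[ls$family_id == "f1"]),
               unname(abundance(hits, rs)["f1"]), tolerance = 1e-12)
  expect_equal(ls$value[ls$family_id == "f1" & ls$bin_lower == 0],
               100 / 2500)
  expect_equal(ls$value[ls$family_id == "f1" & ls$bin_lower == 5],
               150 / 2500)
  expect_equal(ls$value[ls$family_id == "f2" & ls$bin_lower == 12],
               200 / 2500)
  empty <- build_landscape(hits[0, ], rs)
  expect_equal(sum(empty$value), 0)
})

test_that("subtractive landscapes are female minus male per bin", {
  rs <- read_set(sprintf("r%02d", 1:10), rep(strrep("A", 250), 10),
                 library_label = "female")
  hf <- data.frame(read_id = "r01", family_id = "w1",
                   aligned_nt = 200L, k2p = 0.03)
  hm <- hf[0, ]
  lf <- build_landscape(hf, rs)
  lm <- build_landscape(hm, rs)
  sub <- subtract_landscapes(lf, lf)
  expect_true(all(sub$value == 0))
  subw <- subtract_landscapes(lf, lm)
  expect_true(all(subw$value >= 0))
  expect_equal(sum(subw$value), unname(abundance(hf, rs)["w1"]))
  # oracle: direct per-bin recomputation from the two hit lists
  hm2 <- data.frame(read_id = "r02", family_id = "w1",
                    aligned_nt = 120L, k2p = 0.031)
  s2 <- subtract_landscapes(lf, build_landscape(hm2, rs))
  expect_equal(s2$value[s2$bin_lower == 3], (200 - 120) / 2500)
  bad <- build_landscape(hf, rs, bin_width = 2)
  expect_error(subtract_landscapes(lf, bad), "bin width")
})

test_that("F/M ratios reproduce the published worked examples", {
  tab <- candidate_families()
  sel <- c("MmaSat009-53", "MmaSat017-72", "MmaSat058-71", "MmaSat061-33",
           "MmaSat111-33", "MmaSat098-37")
  d <- tab[match(sel, tab$family), ]
  r <- fm_ratio(d$abundance_female, d$abundance_male)
  # printed abundances carry 6 decimals: agreement to >= 4 significant figures
  expect_equal(r, d$fm_ratio_printed, tolerance = 2e-4)
  expect_identical(fm_ratio(0.1, 0), Inf)
  expect_true(is.nan(fm_ratio(0, 0)))
})

test_that("candidate ranking reproduces the published table order", {
  tab <- candidate_families()
  rec <- data.frame(family_id = tab$family,
                    abundance_female = tab$abundance_female,
                    fm_ratio = ifelse(is.na(tab$abundance_male), Inf,
                                      tab$abundance_female /
                                        tab$abundance_male))
  set.seed(3)
  shuffled <- rec[sample(nrow(rec)), ]
  ranked <- rank_candidates(shuffled, 31)
  # absent-in-male families first (by female abundance), then F/M descending
  expect_equal(ranked$family_id, tab$family)
  top1 <- rank_candidates(shuffled, 1)
  expect_equal(top1$family_id, "MmaSat155-71")
  expect_error(rank_candidates(rec, 0), "positive")
})

test_that("per-family aligned fractions track planted truth on a small pool", {
  monos <- draw_dissimilar_monomers(c(50, 60), seed = 23)
  specs <- list(
    family_spec("a", monos[1], 160, 160, n_arrays = 2,
                per_copy_substitution_rate = 0.02),
    family_spec("w", monos[2], 70, 0, n_arrays = 1,
                per_copy_substitution_rate = 0.02, linkage = "W"))
  g <- plant_satellites(specs, 300000, seed = 9)
  sim <- simulate_reads(g, read_sim_config(n_read_pairs = 4000,
                                           per_base_error_rate = 0.001,
                                           seed = 10))
  res <- abundance_table(sim$female, sim$male,
                         setNames(g$monomers, names(g$monomers)))
  tab <- res$table
  truth <- g$truth
  for (fam in truth$family_id) {
    tf <- truth$true_fraction_female[truth$family_id == fam]
    ef <- tab$abundance_female[tab$family_id == fam]
    # three binomial SDs at fragment resolution
    expect_lt(abs(ef - tf), 3 * sqrt(tf * (1 - tf) / 4000) + 0.0005)
  }
  expect_identical(tab$fm_ratio[tab$family_id == "w"], Inf)
  expect_true(is.na(tab$divergence_male[tab$family_id == "w"]))
})
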