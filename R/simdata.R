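#' Specify a planted satellite family
#'
#' Defines one tandem-repeat family for the synthetic ZW/ZZ genome pair:
#' its monomer, per-sex copy numbers, how many separate arrays the copies
#' are split across, per-copy mutation rates, and its linkage class.
#' W-linked families are female-only (`copies_male` must be 0), emulating
#' satellites restricted to the female-limited W chromosome.
#'
#' @param family_id Unique family label.
#' @param monomer Monomer sequence (5-2000 nt, A/C/G/T only).
#' @param copies_female,copies_male Tandem copy counts per sex.
#' @param n_arrays Number of separate arrays the copies are split across.
#' @param per_copy_substitution_rate Per-base substitution probability
#'   applied independently to each planted copy (models array divergence).
#' @param indel_rate Per-base indel probability per copy. Default 0 keeps
#'   the nucleotide bookkeeping of the truth table exact.
#' @param linkage One of `"autosomal"`, `"Z"`, `"W"`.
#' @return A `family_spec` list.
#' @export
family_spec <- function(family_id, monomer, copies_female, copies_male,
                        n_arrays = 1L,
                        per_copy_substitution_rate = 0,
                        indel_rate = 0,
                        linkage = c("autosomal", "Z", "W")) {
  linkage <- match.arg(linkage)
  .assert_dna(monomer, "monomer")
  if (nchar(monomer) < 5 || nchar(monomer) > 2000) {
    stop("monomer length must be in 5..2000 nt")
  }
  if (linkage == "W" && copies_male != 0) {
    stop("W-linked family must have copies_male = 0")
  }
  stopifnot(copies_female >= 0, copies_male >= 0, n_arrays >= 1,
            per_copy_substitution_rate >= 0, per_copy_substitution_rate < 1,
            indel_rate >= 0, indel_rate < 1)
  structure(list(family_id = family_id, monomer = toupper(monomer),
                 copies_female = as.integer(copies_female),
                 copies_male = as.integer(copies_male),
                 n_arrays = as.integer(n_arrays),
                 per_copy_substitution_rate = per_copy_substitution_rate,
                 indel_rate = indel_rate, linkage = linkage),
            class = "family_spec")
}

# Mutate one satellite copy: i.i.d. substitutions with a configurable
# transition:transversion ratio, optional i.i.d. indels (single-base).
.mutate_copy <- function(chars, sub_rate, indel_rate, ts_tv_ratio) {
  n <- length(chars)
  if (sub_rate > 0) {
    nmut <- rbinom(1L, n, sub_rate)
    if (nmut > 0) {
      pos <- sample.int(n, nmut)
      p_ts <- ts_tv_ratio / (ts_tv_ratio + 1)
      for (p in pos) {
        b <- chars[p]
        if (runif(1) < p_ts) {
          chars[p] <- switch(b, A = "G", G = "A", C = "T", T = "C")
        } else {
          tv <- switch(b, A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))
          chars[p] <- tv[sample.int(2L, 1L)]
        }
      }
    }
  }
  if (indel_rate > 0) {
    nind <- rbinom(1L, length(chars), indel_rate)
    if (nind > 0) {
      for (k in seq_len(nind)) {
        p <- sample.int(length(chars), 1L)
        if (runif(1) < 0.5 && length(chars) > 1L) {
          chars <- chars[-p]
        } else {
          chars <- append(chars, sample(DNA_BASES, 1L), after = p)
        }
      }
    }
  }
  chars
}

# Build all arrays for one family in one sex; returns list of array strings.
.build_arrays <- function(spec, copies, ts_tv_ratio) {
  if (copies == 0L) return(character(0))
  n_arrays <- min(spec$n_arrays, copies)
  sizes <- diff(floor(seq(0, copies, length.out = n_arrays + 1L)))
  mono <- strsplit(spec$monomer, "")[[1]]
  vapply(sizes, function(sz) {
    cps <- vapply(seq_len(sz), function(i) {
      paste(.mutate_copy(mono, spec$per_copy_substitution_rate,
                         spec$indel_rate, ts_tv_ratio), collapse = "")
    }, character(1))
    paste(cps, collapse = "")
  }, character(1))
}

#' Plant satellite arrays into synthetic female and male genomes
#'
#' Generates one random background sequence per sex and inserts, at uniform
#' random non-overlapping positions, head-to-tail tandem arrays for each
#' family. Each copy is mutated independently at the family's substitution
#' and indel rates (transition:transversion ratio `ts_tv_ratio`, default 2,
#' so planted divergence is recoverable with the Kimura 2-parameter
#' estimator). The truth table records planted nucleotide fractions
#' computed from the actual post-mutation array lengths.
#'
#' @param specs List of [family_spec()] objects.
#' @param background_length_per_sex Background (single-copy) length per sex.
#' @param seed Integer seed; fully determines the output.
#' @param ts_tv_ratio Transition:transversion ratio of the mutation model.
#' @return A `genome_pair`: `female_sequences` and `male_sequences`
#'   (character vectors, one chromosome-like string each),
#'   `arrays` (data frame of planted array coordinates per sex, 0-based
#'   half-open) and `truth` (data frame with per-family planted fractions
#'   and the true F/M ratio, `Inf` for W-linked families).
#' @export
plant_satellites <- function(specs, background_length_per_sex, seed = 1L,
                             ts_tv_ratio = 2) {
  if (!length(specs)) stop("specs must be non-empty")
  if (inherits(specs, "family_spec")) specs <- list(specs)
  ids <- vapply(specs, `[[`, character(1), "family_id")
  if (anyDuplicated(ids)) stop("duplicate family_id")
  for (s in specs) .assert_dna(s$monomer, paste0("monomer of ", s$family_id))
  total_sat <- sum(vapply(specs, function(s) {
    nchar(s$monomer) * max(s$copies_female, s$copies_male)
  }, numeric(1)))
  if (total_sat >= background_length_per_sex) {
    stop("total satellite length must be smaller than the background")
  }
  set.seed(seed)
  sexes <- c("female", "male")
  seqs <- list(); coords <- list()
  for (sex in sexes) {
    arrays <- list(); fam_of_array <- character(0)
    for (s in specs) {
      copies <- if (sex == "female") s$copies_female else s$copies_male
      arr <- .build_arrays(s, copies, ts_tv_ratio)
      if (length(arr)) {
        arrays <- c(arrays, as.list(arr))
        fam_of_array <- c(fam_of_array, rep(s$family_id, length(arr)))
      }
    }
    bg <- random_dna(background_length_per_sex)
    k <- length(arrays)
    if (k) {
      # insertion points into the background; insertion cannot overlap
      cut <- sort(sample.int(background_length_per_sex - 1L, k))
      ord <- sample.int(k) # shuffle which array goes to which cut point
      arrays <- arrays[ord]; fam_of_array <- fam_of_array[ord]
      pieces <- character(2L * k + 1L)
      starts <- integer(k); ends <- integer(k)
      prev <- 0L; offset <- 0L
      for (i in seq_len(k)) {
        pieces[2L * i - 1L] <- substr(bg, prev + 1L, cut[i])
        a <- arrays[[i]]
        pieces[2L * i] <- a
        starts[i] <- cut[i] + offset          # 0-based start
        ends[i] <- starts[i] + nchar(a)       # half-open end
        offset <- offset + nchar(a)
        prev <- cut[i]
      }
      pieces[2L * k + 1L] <- substr(bg, prev + 1L, background_length_per_sex)
      seqs[[sex]] <- paste(pieces, collapse = "")
      coords[[sex]] <- data.frame(
        sex = sex, family_id = fam_of_array, start = starts, end = ends,
        stringsAsFactors = FALSE)
    } else {
      seqs[[sex]] <- bg
      coords[[sex]] <- data.frame(sex = character(0), family_id = character(0),
                                  start = integer(0), end = integer(0))
    }
  }
  arrays_df <- do.call(rbind, coords)
  rownames(arrays_df) <- NULL
  tot <- vapply(sexes, function(s) nchar(seqs[[s]]), numeric(1))
  truth <- do.call(rbind, lapply(specs, function(s) {
    pf <- sum(with(arrays_df,
                   (end - start)[sex == "female" & family_id == s$family_id]))
    pm <- sum(with(arrays_df,
                   (end - start)[sex == "male" & family_id == s$family_id]))
    ff <- pf / tot[["female"]]; fm <- pm / tot[["male"]]
    data.frame(family_id = s$family_id, linkage = s$linkage,
               monomer_length = nchar(s$monomer),
               planted_nt_female = pf, planted_nt_male = pm,
               true_fraction_female = ff, true_fraction_male = fm,
               fm_ratio = if (fm > 0) ff / fm else if (ff > 0) Inf else NaN,
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  structure(list(female_sequences = seqs[["female"]],
                 male_sequences = seqs[["male"]],
                 arrays = arrays_df, truth = truth,
                 monomers = setNames(
                   vapply(specs, `[[`, character(1), "monomer"), ids)),
            class = "genome_pair")
}

#' Read simulator configuration
#'
#' @param read_length Read length in nt (default 250, MiSeq-like).
#' @param paired Emit read pairs (second mate reverse-complemented).
#' @param insert_mean,insert_sd Insert size distribution (nt).
#' @param n_read_pairs Number of read pairs per library.
#' @param per_base_error_rate Uniform substitution error probability.
#' @param seed Integer seed; fully determines the output.
#' @return A `read_sim_config` list.
#' @export
read_sim_config <- function(read_length = 250L, paired = TRUE,
                            insert_mean = 500L, insert_sd = 25L,
                            n_read_pairs = 1000L,
                            per_base_error_rate = 0.001, seed = 1L) {
  stopifnot(read_length >= 1, insert_mean >= read_length, insert_sd >= 0,
            n_read_pairs >= 0, per_base_error_rate >= 0,
            per_base_error_rate < 1)
  structure(list(read_length = as.integer(read_length), paired = paired,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 n_read_pairs = as.integer(n_read_pairs),
                 per_base_error_rate = per_base_error_rate,
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

.add_errors <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  L <- nchar(seqs)
  nerr <- rbinom(length(seqs), L, rate)
  idx <- which(nerr > 0)
  for (i in idx) {
    chars <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(L[i], nerr[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

# Simulate one library from one genome (a character vector of sequences).
.simulate_library <- function(genome_seqs, cfg, label) {
  lens <- nchar(genome_seqs)
  if (any(lens <= cfg$insert_mean)) {
    stop("genome sequences must be longer than insert_mean")
  }
  n <- cfg$n_read_pairs
  rl <- cfg$read_length
  if (n == 0L) {
    return(list(
      r1 = read_set(character(0), character(0), character(0), label),
      r2 = read_set(character(0), character(0), character(0), label)))
  }
  seq_idx <- sample.int(length(genome_seqs), n, replace = TRUE,
                        prob = lens / sum(lens))
  ins <- pmax(rl, round(rnorm(n, cfg$insert_mean, cfg$insert_sd)))
  ins <- pmin(ins, lens[seq_idx])
  start <- vapply(seq_len(n), function(i) {
    sample.int(lens[seq_idx[i]] - ins[i] + 1L, 1L)
  }, integer(1))
  r1 <- substring(genome_seqs[seq_idx], start, start + rl - 1L)
  e2 <- start + ins - 1L
  r2 <- revcomp(substring(genome_seqs[seq_idx], e2 - rl + 1L, e2))
  r1 <- .add_errors(r1, cfg$per_base_error_rate)
  r2 <- .add_errors(r2, cfg$per_base_error_rate)
  qual <- strrep("?", rl) # constant Q30
  ids <- sprintf("sim_%s_%06d", label, seq_len(n))
  orig1 <- data.frame(seq_index = seq_idx, start = start - 1L,
                      end = start + rl - 1L, strand = "+")
  orig2 <- data.frame(seq_index = seq_idx, start = e2 - rl,
                      end = e2, strand = "-")
  list(r1 = read_set(paste0(ids, "/1"), r1, rep(qual, n), label, orig1),
       r2 = read_set(paste0(ids, "/2"), r2, rep(qual, n), label, orig2))
}

#' Simulate paired-end reads from a synthetic genome pair
#'
#' Uniform fragment sampling; the second mate is the reverse complement of
#' the fragment end. Substitution errors are applied at
#' `per_base_error_rate`; qualities are constant Q30. Deterministic under
#' the config seed.
#'
#' @param genome A `genome_pair` from [plant_satellites()].
#' @param cfg A [read_sim_config()].
#' @return List with `female` and `male`, each a `read_set` containing both
#'   mates (ids suffixed `/1`, `/2`), plus mate-separated sets in
#'   `female_pairs` / `male_pairs`.
#' @export
simulate_reads <- function(genome, cfg) {
  stopifnot(inherits(genome, "genome_pair"), inherits(cfg, "read_sim_config"))
  set.seed(cfg$seed)
  fem <- .simulate_library(genome$female_sequences, cfg, "female")
  mal <- .simulate_library(genome$male_sequences, cfg, "male")
  list(female = join_pair(fem$r1, fem$r2, "female"),
       male = join_pair(mal$r1, mal$r2, "male"),
       female_pairs = fem, male_pairs = mal)
}

# interleave two mate sets into one library-labelled read_set
join_pair <- function(r1, r2, label) {
  read_set(c(r1$id, r2$id), c(r1$seq, r2$seq), c(r1$qual, r2$qual), label,
           if (!is.null(r1$origin)) rbind(r1$origin, r2$origin))
}

#' Fraction of simulated read nucleotides originating inside planted arrays
#'
#' Truth-aware helper: intersects simulated read origin coordinates with the
#' planted array coordinates of one sex (optionally one family).
#'
#' @param rs A simulated `read_set` with an `origin` component.
#' @param genome The `genome_pair` the reads were simulated from.
#' @param sex `"female"` or `"male"`.
#' @param family_id Optional family restriction.
#' @return Fraction in `[0,1]` of read nucleotides overlapping arrays.
#' @export
read_satellite_fraction <- function(rs, genome, sex, family_id = NULL) {
  stopifnot(!is.null(rs$origin))
  arr <- genome$arrays[genome$arrays$sex == sex, , drop = FALSE]
  if (!is.null(family_id)) arr <- arr[arr$family_id %in% family_id, , drop = FALSE]
  if (!nrow(arr)) return(0)
  ov <- numeric(length(rs))
  for (i in seq_len(nrow(arr))) {
    ov <- ov + pmax(0, pmin(rs$origin$end, arr$end[i]) -
                       pmax(rs$origin$start, arr$start[i]))
  }
  sum(ov) / sum(rs$origin$end - rs$origin$start)
}

#' Write simulation outputs (FASTQ pairs, truth TSV, monomer FASTA)
#'
#' @param sim Output of [simulate_reads()].
#' @param genome The `genome_pair`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written file paths, invisibly.
#' @export
write_simulation <- function(sim, genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    female_1 = file.path(dir, "female_1.fastq"),
    female_2 = file.path(dir, "female_2.fastq"),
    male_1 = file.path(dir, "male_1.fastq"),
    male_2 = file.path(dir, "male_2.fastq"),
    truth = file.path(dir, "truth.tsv"),
    monomers = file.path(dir, "monomers.fasta"))
  write_fastq(sim$female_pairs$r1, paths[["female_1"]])
  write_fastq(sim$female_pairs$r2, paths[["female_2"]])
  write_fastq(sim$male_pairs$r1, paths[["male_1"]])
  write_fastq(sim$male_pairs$r2, paths[["male_2"]])
  write.table(genome$truth, paths[["truth"]], sep = "\t", row.names = FALSE,
              quote = FALSE)
  write_fasta(genome$monomers, paths[["monomers"]])
  invisible(paths)
}
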