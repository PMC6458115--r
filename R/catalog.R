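#' Circular, strand-aware sequence identity between two monomers
#'
#' Tandem-repeat monomers are circular (any rotation is the same repeat)
#' and strandless. The shorter sequence is aligned globally against every
#' rotation of the longer one, on both strands, with free end gaps in the
#' partner; identity is `matches / alignment length`, where the alignment
#' length also charges the part of the partner the alignment leaves
#' uncovered, so unequal repeat unit lengths are penalized rather than
#' ignored. The best-scoring alignment over all rotations and strands is
#' reported. For sequences beyond `max_exact` nucleotides the explicit
#' rotation scan (cubic in length) is replaced by a single fit alignment
#' against the doubled partner, a close approximation of the same
#' quantity.
#'
#' @param a,b DNA strings (non-empty).
#' @param max_exact Length cap for the exact rotation scan.
#' @return Identity fraction in `[0,1]`.
#' @export
circular_identity <- function(a, b, max_exact = 400L) {
  stopifnot(nzchar(a), nzchar(b))
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  if (nchar(b) <= max_exact) {
    return(cpp_rotation_identity(a, b))
  }
  best <- 0
  for (s in c(b, revcomp(b))) {
    al <- cpp_align_fit(a, strrep(s, 2L))
    if (al$alen > 0) {
      b_span <- al$b_end - al$b_start + 1L
      alen_eff <- al$alen + max(0L, nchar(b) - b_span)
      best <- max(best, al$matches / alen_eff)
    }
  }
  min(1, best)
}

#' Canonical representative of a monomer
#'
#' The lexicographically smallest string among all rotations of the
#' monomer and of its reverse complement. Idempotent; stable across input
#' rotation and strand, so catalogs built from different read orientations
#' deduplicate identically.
#'
#' @param m DNA string (non-empty).
#' @return The canonical rotation/strand string.
#' @export
canonical_monomer <- function(m) {
  stopifnot(nzchar(m))
  n <- nchar(m)
  rots <- function(x) {
    xx <- strrep(x, 2L)
    vapply(seq_len(n), function(i) substr(xx, i, i + n - 1L), character(1))
  }
  min(c(rots(m), rots(revcomp(m))))
}

#' A+T content of a sequence
#'
#' @param x DNA string(s).
#' @return Fraction(s) of A or T bases.
#' @export
at_content <- function(x) {
  (nchar(gsub("[^AT]", "", x))) / nchar(x)
}

#' Group monomers into variants, families and superfamilies
#'
#' Single-linkage connected components of the pairwise circular-identity
#' graph at three nested thresholds: sequences above the variant threshold
#' collapse into one variant, variants above the family threshold into one
#' family, families above the superfamily threshold into one superfamily.
#' Because an identity above a higher threshold is also above every lower
#' one, the three partitions are strictly nested.
#'
#' @param monomers Character vector of monomer consensus sequences
#'   (optionally named; names become variant ids).
#' @param thresholds Named numeric vector
#'   `c(variant = 0.95, family = 0.80, superfamily = 0.40)`.
#' @return A `sat_hierarchy` data frame: `variant_id`, `consensus`, `rul`,
#'   `at_content`, `variant_group`, `family_group`, `sf_group` (integer
#'   component labels). The identity matrix is attached as attribute
#'   `"identity"`.
#' @export
group_hierarchy <- function(monomers,
                            thresholds = c(variant = 0.95, family = 0.80,
                                           superfamily = 0.40)) {
  stopifnot(length(monomers) >= 1)
  n <- length(monomers)
  ids <- names(monomers)
  if (is.null(ids)) ids <- sprintf("var%03d", seq_len(n))
  idm <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        idm[i, j] <- idm[j, i] <- circular_identity(monomers[[i]], monomers[[j]])
      }
    }
  }
  comp_at <- function(thr) {
    g <- igraph::graph_from_adjacency_matrix(idm > thr, mode = "undirected",
                                             diag = FALSE)
    igraph::components(g)$membership
  }
  out <- data.frame(
    variant_id = ids, consensus = unname(unlist(monomers)),
    rul = nchar(unname(unlist(monomers))),
    at_content = at_content(unname(unlist(monomers))),
    variant_group = comp_at(thresholds[["variant"]]),
    family_group = comp_at(thresholds[["family"]]),
    sf_group = comp_at(thresholds[["superfamily"]]),
    stringsAsFactors = FALSE)
  attr(out, "identity") <- idm
  class(out) <- c("sat_hierarchy", class(out))
  out
}

#' Assign catalog names ordered by female abundance
#'
#' Families are ranked by decreasing abundance in the female library and
#' named `<prefix>SatNNN-RUL`, where `NNN` is the zero-padded rank and
#' `RUL` the repeat unit length of the family's representative (most
#' abundant) variant. Ties are broken by male abundance, then by the
#' representative consensus lexicographically, so names are deterministic
#' under input permutation.
#'
#' @param families Data frame with one row per family: `family_group`,
#'   `rul` (representative RUL), `abundance_female`, `abundance_male`,
#'   and optionally `consensus` of the representative variant.
#' @param prefix Catalog prefix (species tag).
#' @param pad Zero-padding width of the rank.
#' @return `families` with a `family_id` column (`<prefix>SatNNN-RUL`),
#'   sorted by rank.
#' @export
assign_names <- function(families, prefix = "X", pad = 3L) {
  stopifnot(!is.null(families$abundance_female))
  if (anyDuplicated(families$family_group)) stop("duplicate family rows")
  cons <- if (!is.null(families$consensus)) families$consensus else ""
  ord <- order(-families$abundance_female,
               -if (!is.null(families$abundance_male))
                 families$abundance_male else rep(0, nrow(families)),
               cons)
  families <- families[ord, , drop = FALSE]
  families$family_id <- sprintf("%sSat%0*d-%d", prefix, pad,
                                seq_len(nrow(families)), families$rul)
  rownames(families) <- NULL
  families
}

#' Build a named catalog from a hierarchy and per-variant abundances
#'
#' Aggregates a [group_hierarchy()] table to family level (representative =
#' most abundant variant), names families with [assign_names()], and
#' returns both levels.
#'
#' @param hierarchy A `sat_hierarchy`.
#' @param abundance_female,abundance_male Numeric vectors parallel to the
#'   hierarchy rows (per-variant abundances). Defaults rank by RUL when
#'   absent.
#' @param prefix,pad Passed to [assign_names()].
#' @return List with `families` (named family table) and `variants`
#'   (hierarchy with `family_id` filled in).
#' @export
build_catalog <- function(hierarchy, abundance_female = NULL,
                          abundance_male = NULL, prefix = "X", pad = 3L) {
  n <- nrow(hierarchy)
  if (is.null(abundance_female)) abundance_female <- rep(0, n)
  if (is.null(abundance_male)) abundance_male <- rep(0, n)
  h <- hierarchy
  h$abundance_female <- abundance_female
  h$abundance_male <- abundance_male
  fam <- do.call(rbind, lapply(split(h, h$family_group), function(d) {
    rep_i <- which.max(d$abundance_female + d$abundance_male)
    if (all(d$abundance_female == 0)) rep_i <- which.max(d$rul)
    data.frame(family_group = d$family_group[1],
               sf_group = d$sf_group[1],
               n_variants = nrow(d),
               consensus = d$consensus[rep_i],
               rul = d$rul[rep_i],
               at_content = d$at_content[rep_i],
               abundance_female = sum(d$abundance_female),
               abundance_male = sum(d$abundance_male),
               stringsAsFactors = FALSE)
  }))
  fam <- assign_names(fam, prefix = prefix, pad = pad)
  h$family_id <- fam$family_id[match(h$family_group, fam$family_group)]
  list(families = fam, variants = h)
}

#' Write a catalog to FASTA
#'
#' Headers carry superfamily and variant count:
#' `>XSat001-53 sf=1 variants=3`.
#'
#' @param catalog Output of [build_catalog()].
#' @param path FASTA path.
#' @return `path`, invisibly.
#' @export
write_catalog_fasta <- function(catalog, path) {
  fam <- catalog$families
  seqs <- setNames(fam$consensus,
                   sprintf("%s sf=%d variants=%d", fam$family_id,
                           fam$sf_group, fam$n_variants))
  write_fasta(seqs, path)
}
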