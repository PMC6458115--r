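#' Call sex from quick-FISH interphase spot counts
#'
#' With a probe mix targeting one autosomal satellite locus (two signals
#' per cell) plus one W-linked satellite (a third signal in ZW females),
#' informative cells show exactly 2 (male) or 3 (female) spots. Cells with
#' other counts (signal dropout or overlap) are excluded from the
#' denominator but reported. The call is `female` when the fraction of
#' informative cells with 3 spots reaches `majority`, `male` when the
#' 2-spot fraction does, otherwise `ambiguous`.
#'
#' @param counts Integer vector of per-cell spot counts for one specimen.
#' @param min_cells Minimum number of informative cells required.
#' @param majority Majority fraction required for a call.
#' @param max_count Sanity cap on per-cell counts.
#' @return List: `call` (`"female"`, `"male"`, `"ambiguous"`), `n_cells`,
#'   `n_informative`, `frac2`, `frac3`, `reason`.
#' @export
call_sex_quickfish <- function(counts, min_cells = 20L, majority = 0.8,
                               max_count = 6L) {
  stopifnot(length(counts) >= 1, all(counts >= 0), all(counts <= max_count))
  informative <- counts[counts %in% c(2L, 3L)]
  n_inf <- length(informative)
  if (length(counts) < min_cells || n_inf < min_cells) {
    return(list(call = "ambiguous", n_cells = length(counts),
                n_informative = n_inf, frac2 = NA_real_, frac3 = NA_real_,
                reason = sprintf("fewer than %d informative cells",
                                 min_cells)))
  }
  frac3 <- mean(informative == 3L)
  frac2 <- 1 - frac3
  call <- if (frac3 >= majority) "female"
          else if (frac2 >= majority) "male"
          else "ambiguous"
  list(call = call, n_cells = length(counts), n_informative = n_inf,
       frac2 = frac2, frac3 = frac3,
       reason = if (call == "ambiguous") "no majority" else NA_character_)
}

#' Quick-FISH calls for a table of specimens
#'
#' @param table Data frame with columns `specimen` and `count` (one row
#'   per cell).
#' @param ... Passed to [call_sex_quickfish()].
#' @return Data frame: `specimen`, `call`, `n_cells`, `n_informative`,
#'   `frac3`.
#' @export
quickfish_calls <- function(table, ...) {
  stopifnot(all(c("specimen", "count") %in% names(table)))
  res <- lapply(split(table$count, table$specimen), call_sex_quickfish, ...)
  data.frame(specimen = names(res),
             call = vapply(res, `[[`, character(1), "call"),
             n_cells = vapply(res, `[[`, integer(1), "n_cells"),
             n_informative = vapply(res, `[[`, integer(1), "n_informative"),
             frac3 = vapply(res, `[[`, numeric(1), "frac3"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Delta-Ct relative quantification for one qPCR record
#'
#' `dCt = mean(Ct_target) - mean(Ct_reference)` against a single-copy
#' reference gene; relative quantity `RQ = efficiency^(-dCt)` (default
#' efficiency 2, i.e. perfect doubling per cycle). The SEM of `dCt` is
#' propagated as `sqrt(SEM_target^2 + SEM_reference^2)`. Replicates whose
#' range exceeds `max_replicate_range` cycles are inconsistent; a record
#' with an inconsistent channel is rejected.
#'
#' @param ct_target,ct_reference Numeric replicate vectors (>= 2 values
#'   each, Ct in (0, 45)).
#' @param max_replicate_range Maximum within-channel replicate range.
#' @param efficiency Amplification efficiency factor per cycle.
#' @return List: `delta_ct`, `sem`, `rq`, `ok`, `reason`.
#' @export
delta_ct_rq <- function(ct_target, ct_reference,
                        max_replicate_range = 0.5, efficiency = 2) {
  stopifnot(length(ct_target) >= 1, length(ct_reference) >= 1,
            all(ct_target > 0), all(ct_target < 45),
            all(ct_reference > 0), all(ct_reference < 45))
  rng <- function(x) diff(range(x))
  if (rng(ct_target) > max_replicate_range ||
      rng(ct_reference) > max_replicate_range) {
    return(list(delta_ct = NA_real_, sem = NA_real_, rq = NA_real_,
                ok = FALSE, reason = "inconsistent replicate Ct values"))
  }
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  dct <- mean(ct_target) - mean(ct_reference)
  list(delta_ct = dct,
       sem = sqrt(sem(ct_target)^2 + sem(ct_reference)^2),
       rq = efficiency^(-dct), ok = TRUE, reason = NA_character_)
}

#' Call sex from qPCR relative quantification of a W-linked satellite
#'
#' Specimens with RQ of the W-linked target above `threshold_rq` are
#' called female. When no threshold is given, it is derived from
#' calibration records of known sex as the geometric midpoint between the
#' female and male RQ geometric means (both sexes must be represented).
#'
#' @param records List of records, each a list with `specimen`,
#'   `ct_target`, `ct_reference`, and optionally `sex_label` (calibration).
#' @param threshold_rq Optional fixed decision threshold.
#' @param ... Passed to [delta_ct_rq()].
#' @return Data frame: `specimen`, `delta_ct`, `rq`, `call` (`"female"`,
#'   `"male"`, `"ambiguous"`, or `"rejected"`), plus the threshold used as
#'   attribute `"threshold_rq"`.
#' @export
call_sex_qpcr <- function(records, threshold_rq = NULL, ...) {
  stopifnot(length(records) >= 1)
  rqs <- lapply(records, function(r) delta_ct_rq(r$ct_target,
                                                 r$ct_reference, ...))
  rq_val <- vapply(rqs, `[[`, numeric(1), "rq")
  labels <- vapply(records, function(r) {
    if (is.null(r$sex_label)) NA_character_ else r$sex_label
  }, character(1))
  if (is.null(threshold_rq)) {
    ok <- !is.na(rq_val)
    f <- rq_val[ok & labels %in% "female"]
    m <- rq_val[ok & labels %in% "male"]
    if (!length(f) || !length(m)) {
      stop("no threshold_rq and calibration lacks one of the sexes")
    }
    threshold_rq <- exp((mean(log(f)) + mean(log(m))) / 2)
  }
  call <- ifelse(is.na(rq_val), "rejected",
                 ifelse(rq_val > threshold_rq, "female",
                        ifelse(rq_val < threshold_rq, "male", "ambiguous")))
  out <- data.frame(
    specimen = vapply(records, function(r) as.character(r$specimen),
                      character(1)),
    delta_ct = vapply(rqs, `[[`, numeric(1), "delta_ct"),
    rq = rq_val, call = call, stringsAsFactors = FALSE)
  attr(out, "threshold_rq") <- threshold_rq
  out
}

#' Mann-Whitney U test (midranks, exact by enumeration for small samples)
#'
#' `U = min(U_a, U_b)` computed from midranks. For `n_a + n_b <= 12` the
#' two-sided p-value is exact: all assignments of the pooled observations
#' to the two groups are enumerated and `p = P(U <= U_obs)` (the min-U
#' statistic is inherently two-sided). Larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b Numeric vectors (non-empty).
#' @return A `test_result` list: `statistic_name = "U"`,
#'   `statistic_value`, `p_value`, `group_sizes`, `method`.
#' @export
mann_whitney_u <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  rk <- rank(pooled)
  ua <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  ub <- na * nb - ua
  u <- min(ua, ub)
  if (n <= 12) {
    combs <- combn(n, na)
    us <- apply(combs, 2, function(ix) {
      uu <- sum(rk[ix]) - na * (na + 1) / 2
      min(uu, na * nb - uu)
    })
    p <- mean(us <= u + 1e-9)
    method <- "exact enumeration"
  } else {
    mu <- na * nb / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * (n + 1 - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sigma
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
    method <- "normal approximation with tie correction"
  }
  structure(list(statistic_name = "U", statistic_value = u, p_value = p,
                 group_sizes = c(na, nb), method = method),
            class = "test_result")
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper with input validation; delegates to the standard
#' implementation in `stats`.
#'
#' @param x Numeric vector, `3 <= n <= 5000`, not constant.
#' @return A `test_result` list.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3 || length(x) > 5000) stop("n must be in 3..5000")
  if (length(unique(x)) == 1L) stop("constant vector")
  ht <- shapiro.test(x)
  structure(list(statistic_name = "W", statistic_value = unname(ht$statistic),
                 p_value = ht$p.value, group_sizes = length(x),
                 method = ht$method),
            class = "test_result")
}

#' Kruskal-Wallis rank-sum test
#'
#' H with tie correction and a chi-square p-value on k-1 degrees of
#' freedom (delegates to `stats::kruskal.test`). All-identical
#' observations give `H = 0`, `p = 1`.
#'
#' @param groups List of non-empty numeric vectors (>= 2 groups).
#' @return A `test_result` list.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 1))
  values <- unlist(groups)
  if (length(unique(values)) == 1L) {
    return(structure(list(statistic_name = "H", statistic_value = 0,
                          p_value = 1, group_sizes = lengths(groups),
                          method = "Kruskal-Wallis rank sum test"),
                     class = "test_result"))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- kruskal.test(values, g)
  structure(list(statistic_name = "H",
                 statistic_value = unname(ht$statistic),
                 p_value = ht$p.value, group_sizes = lengths(groups),
                 method = ht$method),
            class = "test_result")
}

#' @exportS3Method base::print
print.test_result <- function(x, ...) {
  cat(sprintf("%s = %.4g, P = %.4g (n = %s; %s)\n", x$statistic_name,
              x$statistic_value, x$p_value,
              paste(x$group_sizes, collapse = "/"), x$method))
  invisible(x)
}
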