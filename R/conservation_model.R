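# Random-association conservation model for splice-site hexanucleotides.
#
# The null model: under mutual evolutionary independence of neighbouring
# positions, the chance that a group of nucleotides is conserved in both
# species is the product of the per-position conservation values of its
# component nucleotides. Observed (actual) frequencies of whole patterns are
# compared against this product with exact one-tailed binomial tests.

#' Random conservation of one base at one position
#'
#' Probability that the same base occupies a position in both species by
#' random association: the product of the two species' frequencies.
#'
#' @param freq_a,freq_b Base frequencies in species A and B, in `[0, 1]`.
#' @return `freq_a * freq_b`.
#' @examples
#' random_position_conservation(0.597, 0.570)  # 0.3403
#' @export
random_position_conservation <- function(freq_a, freq_b) {
  if (any(freq_a < 0 | freq_a > 1 | freq_b < 0 | freq_b > 1)) {
    stop("frequencies must lie in [0, 1]")
  }
  freq_a * freq_b
}

#' Actual conservation of one base at one position
#'
#' Fraction of couples carrying `base` at hexanucleotide position `position`
#' in both species.
#'
#' @param hex_pairs A `hex_pairs` data frame from [extract_hexes()].
#' @param end `"five_prime"` or `"three_prime"`.
#' @param position Hexanucleotide position (must be variable for the end:
#'   3--6 at 5', 1--4 at 3').
#' @param base One of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return A fraction in `[0, 1]`.
#' @export
actual_position_conservation <- function(hex_pairs, end, position, base) {
  hp <- hex_subset(hex_pairs, end)
  if (!(position %in% variable_positions(end))) {
    stop("position ", position, " is not variable at the ", end, " end")
  }
  if (!(base %in% BASES)) stop("base must be one of A, C, G, T")
  a <- substr(hp$hex_a, position, position)
  b <- substr(hp$hex_b, position, position)
  mean(a == base & b == base)
}

#' Per-position, per-base conservation table
#'
#' For each variable position and base at the given end: the base frequency
#' in each species, the random conservation (product of the two), the actual
#' conservation (both species carry the base), and an exact one-tailed
#' binomial p-value for actual vs random (upper tail when actual exceeds
#' random, lower tail otherwise).
#'
#' @param hex_pairs A `hex_pairs` data frame.
#' @param end `"five_prime"` or `"three_prime"`.
#' @return A `conservation_table` data frame with columns `position`,
#'   `base`, `freq_a`, `freq_b`, `random_cons`, `actual_cons`, `p_value`;
#'   attributes `end`, `n` and `totals` (per-position sums of random and
#'   actual conservation; the actual total equals the cross-species identity
#'   fraction at that position).
#' @export
conservation_table <- function(hex_pairs, end) {
  hp <- hex_subset(hex_pairs, end)
  n <- nrow(hp)
  ma <- hex_matrix(hp$hex_a)
  mb <- hex_matrix(hp$hex_b)
  pos <- variable_positions(end)
  rows <- expand.grid(base = BASES, position = pos,
                      stringsAsFactors = FALSE)[, 2:1]
  freq_a <- freq_b <- actual <- numeric(nrow(rows))
  k_act <- integer(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    p <- rows$position[i]
    b <- rows$base[i]
    in_a <- ma[, p] == b
    in_b <- mb[, p] == b
    freq_a[i] <- mean(in_a)
    freq_b[i] <- mean(in_b)
    k_act[i] <- sum(in_a & in_b)
    actual[i] <- k_act[i] / n
  }
  random <- random_position_conservation(freq_a, freq_b)
  pval <- vapply(seq_len(nrow(rows)), function(i) {
    binomial_tail_test(k_act[i], n, random[i],
                       tail = if (actual[i] > random[i]) "upper" else "lower")
  }, numeric(1L))
  out <- data.frame(
    position = rows$position, base = rows$base,
    freq_a = freq_a, freq_b = freq_b,
    random_cons = random, actual_cons = actual, p_value = pval,
    stringsAsFactors = FALSE
  )
  totals <- data.frame(
    position = pos,
    random_total = as.numeric(tapply(random, rows$position, sum)),
    actual_total = as.numeric(tapply(actual, rows$position, sum))
  )
  structure(out, end = end, n = n, totals = totals,
            class = c("conservation_table", "data.frame"))
}

# ---- motif patterns --------------------------------------------------------

#' Validate a wildcard hexanucleotide pattern
#'
#' Patterns are six characters over `{A,C,G,T,x}`: `x` is a wildcard, allowed
#' only at the variable positions. A 5' pattern fixes positions 1--2 to `GT`,
#' a 3' pattern fixes positions 5--6 to `AG`, and at least one variable
#' position must be fixed. Bifunctional `GT..AG` patterns need an explicit
#' `end`.
#'
#' @param pattern A 6-character pattern string, e.g. `"GTGAGx"`, `"TTxxAG"`.
#' @param end `"five_prime"`, `"three_prime"`, or `NULL` to infer from the
#'   invariant dinucleotides.
#' @return A `motif_pattern` list with elements `pattern`, `end`, `chars`,
#'   `fixed_variable` (indices of fixed variable positions).
#' @export
motif_pattern <- function(pattern, end = NULL) {
  if (length(pattern) != 1L || nchar(pattern) != 6L) {
    stop("pattern must be a single 6-character string")
  }
  chars <- strsplit(pattern, "")[[1]]
  if (!all(chars %in% c(BASES, "x"))) {
    stop("pattern characters must be A, C, G, T or x")
  }
  has_gt <- identical(chars[1:2], c("G", "T"))
  has_ag <- identical(chars[5:6], c("A", "G"))
  if (is.null(end)) {
    if (has_gt && has_ag) {
      stop("pattern ", pattern, " is bifunctional (GT..AG); specify end")
    }
    if (has_gt) end <- "five_prime"
    else if (has_ag) end <- "three_prime"
    else stop("pattern ", pattern,
              " fixes neither the GT nor the AG invariant dinucleotide")
  }
  end <- match_end(end)
  inv <- if (end == "five_prime") 1:2 else 5:6
  inv_chars <- if (end == "five_prime") c("G", "T") else c("A", "G")
  if (!identical(chars[inv], inv_chars)) {
    stop("a ", end, " pattern must fix positions ", inv[1], "-", inv[2],
         " to ", paste(inv_chars, collapse = ""))
  }
  varpos <- variable_positions(end)
  fixed_var <- varpos[chars[varpos] != "x"]
  if (length(fixed_var) == 0L) {
    stop("pattern must fix at least one variable position")
  }
  list(pattern = pattern, end = end, chars = chars,
       fixed_variable = fixed_var)
}

#' Random probability of a wildcard pattern under the independence null
#'
#' The product, over the pattern's fixed variable positions, of the actual
#' per-position conservation of the fixed base; invariant positions
#' contribute a factor of 1.
#'
#' @param pattern A pattern string or [motif_pattern()] object.
#' @param conservation A `conservation_table` (e.g. from
#'   [conservation_table()] or [reference_conservation()]) covering every
#'   fixed variable position/base of the pattern.
#' @param end Passed to [motif_pattern()] when `pattern` is a string.
#' @return The null conservation probability as a fraction.
#' @examples
#' ref <- reference_conservation("five_prime")
#' motif_random_probability("GTAAGT", ref)  # 0.1481...
#' motif_random_probability("GTAAGx", ref)  # 0.3265...
#' @export
motif_random_probability <- function(pattern, conservation, end = NULL) {
  pat <- if (is.list(pattern)) pattern else motif_pattern(pattern, end)
  stopifnot(inherits(conservation, "conservation_table"))
  if (!identical(attr(conservation, "end"), pat$end)) {
    stop("conservation table is for the ", attr(conservation, "end"),
         " end but the pattern is ", pat$end)
  }
  prob <- 1
  for (p in pat$fixed_variable) {
    hit <- conservation$position == p & conservation$base == pat$chars[p]
    if (!any(hit)) {
      stop("conservation table has no entry for position ", p, ", base ",
           pat$chars[p])
    }
    prob <- prob * conservation$actual_cons[hit][1L]
  }
  prob
}

#' Actual frequency of a wildcard pattern
#'
#' Fraction of couples where both species' hexanucleotides match the pattern
#' at every fixed (non-wildcard) position. Matching both species at a fixed
#' position implies cross-species identity there.
#'
#' @param hex_pairs A `hex_pairs` data frame.
#' @param pattern A pattern string or [motif_pattern()] object.
#' @param end Passed to [motif_pattern()] when `pattern` is a string.
#' @return A fraction in `[0, 1]`.
#' @export
motif_actual_frequency <- function(hex_pairs, pattern, end = NULL) {
  pat <- if (is.list(pattern)) pattern else motif_pattern(pattern, end)
  hp <- hex_subset(hex_pairs, pat$end)
  ma <- hex_matrix(hp$hex_a)
  mb <- hex_matrix(hp$hex_b)
  ok <- rep(TRUE, nrow(hp))
  for (p in which(pat$chars != "x")) {
    ok <- ok & ma[, p] == pat$chars[p] & mb[, p] == pat$chars[p]
  }
  mean(ok)
}

#' Binomial standard deviation on the count scale
#'
#' @param n Number of trials.
#' @param p Success probability.
#' @return `sqrt(n * p * (1 - p))`, in count units.
#' @examples
#' binomial_sd(216, 0.2070)  # 5.95
#' @export
binomial_sd <- function(n, p) {
  if (n < 1) stop("n must be >= 1")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  sqrt(n * p * (1 - p))
}

#' Exact one-tailed binomial test
#'
#' Upper tail: `P(X >= k)`; lower tail: `P(X <= k)` for
#' `X ~ Binomial(n, p0)`. The observed value is included in the tail.
#' Degenerate nulls (`p0` of 0 or 1) return 1 when the observation is the
#' only consistent outcome and 0 otherwise.
#'
#' @param k Observed count, `0 <= k <= n`.
#' @param n Number of trials.
#' @param p0 Null success probability.
#' @param tail `"upper"` or `"lower"`.
#' @return The tail probability.
#' @export
binomial_tail_test <- function(k, n, p0, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n")
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  if (p0 == 0) {
    return(if (tail == "upper") as.numeric(k == 0) else 1)
  }
  if (p0 == 1) {
    return(if (tail == "upper") 1 else as.numeric(k == n))
  }
  if (tail == "upper") {
    stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  } else {
    stats::pbinom(k, n, p0)
  }
}

#' Enumerate all wildcard patterns for one end
#'
#' All patterns with 1 to 4 fixed variable positions:
#' `sum(choose(4, k) * 4^k) = 624` per end.
#'
#' @param end `"five_prime"` or `"three_prime"`.
#' @return Character vector of 624 pattern strings.
#' @export
enumerate_motif_patterns <- function(end) {
  end <- match_end(end)
  varpos <- variable_positions(end)
  template <- if (end == "five_prime") {
    c("G", "T", "x", "x", "x", "x")
  } else {
    c("x", "x", "x", "x", "A", "G")
  }
  pats <- character(0L)
  for (k in 1:4) {
    sets <- utils::combn(varpos, k)
    assign_grid <- as.matrix(expand.grid(rep(list(BASES), k),
                                         stringsAsFactors = FALSE))
    for (j in seq_len(ncol(sets))) {
      for (r in seq_len(nrow(assign_grid))) {
        chars <- template
        chars[sets[, j]] <- assign_grid[r, ]
        pats <- c(pats, paste(chars, collapse = ""))
      }
    }
  }
  pats
}

#' Scan all wildcard patterns for over/under-representation
#'
#' For every pattern with 1--4 fixed variable positions at the given end,
#' compares the observed conserved-pattern count against the
#' random-association null probability (product of per-position actual
#' conservation values) with an exact one-tailed binomial test: upper tail
#' when the observed frequency exceeds the null, lower tail otherwise. A
#' Benjamini-Hochberg adjusted p-value column is emitted alongside the raw
#' p-values as a modern extension; the `flagged` column uses the raw p.
#'
#' @param hex_pairs A `hex_pairs` data frame.
#' @param end `"five_prime"` or `"three_prime"`.
#' @param conservation Optional `conservation_table` supplying the
#'   per-position actual conservation values; computed from `hex_pairs` when
#'   `NULL`.
#' @param alpha Significance level for flagging (default 0.05).
#' @return A `motif_scan` data frame sorted by p-value with columns
#'   `pattern`, `n_fixed`, `random_prob`, `sd_counts`, `actual_freq`,
#'   `k_obs`, `excess`, `direction`, `p_value`, `p_bh`, `flagged`;
#'   attributes `end`, `n`, `alpha`.
#' @export
motif_scan <- function(hex_pairs, end, conservation = NULL, alpha = 0.05) {
  hp <- hex_subset(hex_pairs, end)
  n <- nrow(hp)
  if (is.null(conservation)) conservation <- conservation_table(hex_pairs, end)
  stopifnot(inherits(conservation, "conservation_table"))
  varpos <- variable_positions(end)
  # actual conservation lookup: 6 positions x 4 bases (NA off the variable set)
  lookup <- matrix(NA_real_, nrow = 6L, ncol = 4L,
                   dimnames = list(NULL, BASES))
  for (i in seq_len(nrow(conservation))) {
    lookup[conservation$position[i], conservation$base[i]] <-
      conservation$actual_cons[i]
  }
  ma <- hex_matrix(hp$hex_a)
  mb <- hex_matrix(hp$hex_b)
  pats <- enumerate_motif_patterns(end)
  pm <- hex_matrix(pats)
  np <- length(pats)
  random <- numeric(np)
  k_obs <- integer(np)
  n_fixed <- integer(np)
  for (i in seq_len(np)) {
    chars <- pm[i, ]
    fixed_var <- varpos[chars[varpos] != "x"]
    n_fixed[i] <- length(fixed_var)
    prob <- 1
    ok <- rep(TRUE, n)
    for (p in fixed_var) {
      b <- chars[p]
      prob <- prob * lookup[p, b]
      ok <- ok & ma[, p] == b & mb[, p] == b
    }
    random[i] <- prob
    k_obs[i] <- sum(ok)
  }
  actual <- k_obs / n
  excess <- actual - random
  direction <- ifelse(excess > 0, "over", "under")
  pval <- vapply(seq_len(np), function(i) {
    binomial_tail_test(k_obs[i], n, random[i],
                       tail = if (excess[i] > 0) "upper" else "lower")
  }, numeric(1L))
  out <- data.frame(
    pattern = pats, n_fixed = n_fixed,
    random_prob = random, sd_counts = binomial_sd(n, random),
    actual_freq = actual, k_obs = k_obs, excess = excess,
    direction = direction, p_value = pval,
    p_bh = stats::p.adjust(pval, method = "BH"),
    flagged = pval <= alpha,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_value, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, end = end, n = n, alpha = alpha,
            class = c("motif_scan", "data.frame"))
}

#' Between-species composition test
#'
#' One-tailed exact binomial comparison of the two species' counts of some
#' feature (e.g. a base at one hexanucleotide position): the larger count is
#' tested against the other species' proportion as the null.
#'
#' @param count_a,count_b Observed counts in species A and B.
#' @param n Number of couples.
#' @return A one-tailed p-value; `>= 0.5` when the counts are equal.
#' @export
species_composition_test <- function(count_a, count_b, n) {
  if (count_a > n || count_b > n || count_a < 0 || count_b < 0) {
    stop("counts must lie in [0, n]")
  }
  k <- max(count_a, count_b)
  p0 <- min(count_a, count_b) / n
  binomial_tail_test(k, n, p0, tail = "upper")
}

#' Write a conservation table as a TSV
#'
#' @param conservation A [conservation_table()] result.
#' @param path Output TSV path.
#' @return Invisibly, the written data frame.
#' @export
write_conservation_tsv <- function(conservation, path) {
  out <- data.frame(
    position    = conservation$position,
    base        = conservation$base,
    freq_a      = sprintf("%.4f", conservation$freq_a),
    freq_b      = sprintf("%.4f", conservation$freq_b),
    random_cons = sprintf("%.4f", conservation$random_cons),
    actual_cons = sprintf("%.4f", conservation$actual_cons),
    p_value     = sprintf("%.4g", conservation$p_value),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write a motif scan as a TSV
#'
#' @param scan A [motif_scan()] result.
#' @param path Output TSV path.
#' @return Invisibly, the written data frame.
#' @export
write_motif_scan_tsv <- function(scan, path) {
  out <- data.frame(
    pattern    = scan$pattern,
    random_pct = sprintf("%.2f", 100 * scan$random_prob),
    sd_counts  = sprintf("%.2f", scan$sd_counts),
    actual_pct = sprintf("%.2f", 100 * scan$actual_freq),
    excess_pct = sprintf("%.2f", 100 * scan$excess),
    p_value    = sprintf("%.4g", scan$p_value),
    direction  = scan$direction,
    flagged    = scan$flagged,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
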