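# Per-position cross-species identity profiles over the intron ends.
#
# Coordinate convention: five_prime position p is the p-th intron nucleotide;
# three_prime position p is the p-th nucleotide counting backwards from the
# intron's last nucleotide (position 1 is the final G of the terminal AG).
# All positions are 1-based.

#' Per-position identity profile over an intron end
#'
#' For each position `p` in `1..window`, the fraction of couples whose two
#' sequences carry the same base at that position. Couples shorter than `p`
#' (in either species) are excluded from both numerator and denominator at
#' that position; positions where either member carries `N` count as
#' non-identical but stay in the denominator.
#'
#' @param pairs An `intron_pairs` data frame.
#' @param end `"five_prime"` or `"three_prime"`.
#' @param window Number of positions to profile (default 50).
#' @return An `identity_profile` data frame with columns `position`,
#'   `identity`, `denominator` and attributes `end` and `window`.
#' @export
identity_profile <- function(pairs, end = c("five_prime", "three_prime"),
                             window = 50L) {
  end <- match_end(end)
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be >= 1")
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) == 0L) stop("pairs must be non-empty")
  minlen <- pmin(pairs$len_a, pairs$len_b)
  identity <- numeric(window)
  denom <- integer(window)
  for (p in seq_len(window)) {
    ok <- minlen >= p
    if (end == "five_prime") {
      pa <- rep(p, nrow(pairs))
      pb <- pa
    } else {
      pa <- pairs$len_a - p + 1L
      pb <- pairs$len_b - p + 1L
    }
    a <- substr(pairs$seq_a, pa, pa)
    b <- substr(pairs$seq_b, pb, pb)
    same <- ok & a == b & a != "N" & b != "N"
    denom[p] <- sum(ok)
    identity[p] <- if (denom[p] > 0L) sum(same) / denom[p] else NA_real_
  }
  structure(
    data.frame(position = seq_len(window), identity = identity,
               denominator = denom),
    end = end, window = window,
    class = c("identity_profile", "data.frame")
  )
}

#' Unweighted mean identity over a plateau of positions
#'
#' @param profile An [identity_profile()] result.
#' @param from_pos,to_pos 1-based closed position range inside the profile's
#'   window. Defaults 7--50 match the intron-body plateau beyond the end
#'   hexanucleotide.
#' @return The arithmetic mean of `identity[from_pos..to_pos]`.
#' @export
plateau_mean <- function(profile, from_pos = 7L, to_pos = 50L) {
  stopifnot(inherits(profile, "identity_profile"))
  window <- attr(profile, "window")
  if (from_pos < 1L || to_pos > window || from_pos > to_pos) {
    stop("positions must satisfy 1 <= from_pos <= to_pos <= window (",
         window, ")")
  }
  mean(profile$identity[from_pos:to_pos])
}

#' Write an identity profile as a TSV
#'
#' @param profile An [identity_profile()] result.
#' @param path Output TSV path.
#' @return Invisibly, the written data frame.
#' @export
write_identity_tsv <- function(profile, path) {
  out <- data.frame(
    end         = attr(profile, "end"),
    position    = profile$position,
    identity    = sprintf("%.4f", profile$identity),
    denominator = profile$denominator,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
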