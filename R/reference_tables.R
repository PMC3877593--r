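# Bundled reference statistics for the intron-end hexanucleotides of 216
# orthologous mouse/human cytokine-receptor intron couples. These are
# published summary values (per-position base composition, random and actual
# cross-species conservation, and the most frequent hexanucleotides) used as
# (i) printed-precision inputs for the random-association arithmetic and
# (ii) defaults for the synthetic-data generator.

.ref_cons_5 <- function() {
  # hex positions 3..6 (the four variable positions after the invariant GT);
  # percentages as printed: mouse, human, random conservation, actual
  # conservation, per base A/C/G/T
  data.frame(
    position = rep(3:6, each = 4L),
    base     = rep(BASES, times = 4L),
    pct_a    = c(59.7, 1.9, 37.0, 1.4,
                 82.4, 2.8, 6.9, 7.9,
                 7.9, 1.4, 85.2, 5.5,
                 21.8, 11.6, 16.6, 50.0),
    pct_b    = c(57.5, 2.3, 38.4, 2.3,
                 81.0, 2.8, 8.3, 7.9,
                 7.4, 1.8, 84.3, 6.5,
                 24.1, 7.4, 19.9, 48.6),
    random_pct = c(34.03, 0.04, 14.21, 0.03,
                   66.74, 0.08, 0.57, 0.62,
                   0.58, 0.03, 71.82, 0.36,
                   5.25, 0.86, 3.30, 24.30),
    actual_pct = c(50.93, 1.85, 30.09, 1.39,
                   77.78, 2.31, 4.17, 6.02,
                   6.48, 0.93, 82.41, 3.70,
                   16.20, 3.70, 8.33, 45.37),
    stringsAsFactors = FALSE
  )
}

.ref_cons_3 <- function() {
  # hex positions 1..4 (the four variable positions before the invariant AG)
  data.frame(
    position = rep(1:4, each = 4L),
    base     = rep(BASES, times = 4L),
    pct_a    = c(5.1, 35.2, 8.3, 51.4,
                 7.9, 25.9, 8.3, 57.9,
                 27.3, 27.3, 19.9, 25.5,
                 7.4, 63.0, 0.0, 29.6),
    pct_b    = c(5.6, 33.8, 4.6, 56.0,
                 9.3, 22.2, 8.3, 60.2,
                 26.9, 29.1, 21.3, 22.7,
                 7.0, 59.7, 0.0, 33.3),
    random_pct = c(0.29, 11.9, 0.38, 28.78,
                   0.73, 5.75, 0.69, 34.86,
                   7.34, 7.94, 4.24, 5.79,
                   0.52, 37.6, 0.00, 9.86),
    actual_pct = c(2.31, 23.61, 3.70, 42.59,
                   5.09, 13.89, 5.09, 48.61,
                   17.13, 16.67, 9.26, 16.67,
                   6.02, 50.46, 0.00, 20.83),
    stringsAsFactors = FALSE
  )
}

#' Reference per-position conservation table for mouse/human intron ends
#'
#' Published per-position summary statistics for the initial and terminal
#' hexanucleotides of 216 orthologous mouse/human cytokine-receptor intron
#' couples: base frequency in each species, the random-association
#' conservation (product of the two species' frequencies) and the actual
#' cross-species conservation, all as fractions at printed precision.
#'
#' These values serve as desk-checkable inputs for
#' [motif_random_probability()] and as conservation defaults for
#' [generator_config()]. Positions are hexanucleotide positions counted
#' left-to-right: 3--6 for the 5' end (after the invariant GT), 1--4 for the
#' 3' end (before the invariant AG).
#'
#' @param end `"five_prime"` or `"three_prime"`.
#' @return A `conservation_table` data frame with columns `position`, `base`,
#'   `freq_a`, `freq_b`, `random_cons`, `actual_cons`, with attributes `end`,
#'   `n` (216) and `totals` (per-position sums of random and actual
#'   conservation).
#' @examples
#' ref <- reference_conservation("five_prime")
#' subset(ref, position == 3 & base == "A")$actual_cons  # 0.5093
#' @export
reference_conservation <- function(end = c("five_prime", "three_prime")) {
  end <- match_end(end)
  raw <- if (end == "five_prime") .ref_cons_5() else .ref_cons_3()
  out <- data.frame(
    position    = raw$position,
    base        = raw$base,
    freq_a      = raw$pct_a / 100,
    freq_b      = raw$pct_b / 100,
    random_cons = raw$random_pct / 100,
    actual_cons = raw$actual_pct / 100,
    stringsAsFactors = FALSE
  )
  totals <- data.frame(
    position     = sort(unique(out$position)),
    random_total = tapply(out$random_cons, out$position, sum),
    actual_total = tapply(out$actual_cons, out$position, sum),
    row.names    = NULL
  )
  # keep printed per-position totals where the published table rounds them
  # (e.g. 5' position 6 actual total printed 73.6, not the 73.60 column sum)
  printed_actual <- if (end == "five_prime") {
    c(0.8426, 0.9028, 0.9352, 0.736)
  } else {
    c(0.7221, 0.7268, 0.5973, 0.7731)
  }
  totals$actual_total <- printed_actual
  structure(out,
            end = end, n = 216L, totals = totals, source = "reference",
            class = c("conservation_table", "data.frame"))
}

#' Reference hexanucleotide usage for mouse/human intron ends
#'
#' The most frequent initial and terminal hexanucleotides of the 216
#' orthologous mouse/human cytokine-receptor intron couples, as
#' species-averaged fractions. The listed rows cover 64.5% (5') and 36.8%
#' (3') of the observed mass; [generator_config()] spreads the remaining
#' probability uniformly over the other canonical hexanucleotides.
#'
#' @param end `"five_prime"` or `"three_prime"`.
#' @return Named numeric vector of fractions (names are hexanucleotides).
#' @examples
#' reference_hex_usage("five_prime")["GTGAGT"]  # 0.185
#' @export
reference_hex_usage <- function(end = c("five_prime", "three_prime")) {
  end <- match_end(end)
  if (end == "five_prime") {
    c(GTGAGT = 0.185, GTAAGT = 0.181, GTAAGA = 0.088, GTGAGA = 0.056,
      GTGAGG = 0.056, GTAAGG = 0.044, GTAAGC = 0.035)
  } else {
    c(TTTCAG = 0.069, CTGCAG = 0.063, TTTTAG = 0.056, TTGCAG = 0.053,
      TTCTAG = 0.049, CCACAG = 0.039, TTCCAG = 0.039)
  }
}
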