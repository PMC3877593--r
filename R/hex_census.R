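# Hexanucleotide censuses: extraction of the initial/terminal hexanucleotides
# of each couple, per-species usage tables, per-position base composition,
# mismatch-count distributions, and the bifunctional (GT....AG) classification.

#' Extract end hexanucleotides from intron pairs
#'
#' The initial hexanucleotide is the intron's first six nucleotides, the
#' terminal hexanucleotide its last six (both indexed left-to-right h1..h6).
#' `n_mismatch` is the Hamming distance between the two species'
#' hexanucleotides restricted to the variable positions (3--6 at the 5' end,
#' 1--4 at the 3' end).
#'
#' @param pairs An `intron_pairs` data frame with all lengths >= 12.
#' @return A `hex_pairs` data frame with two rows per couple (one per end)
#'   and columns `gene_id`, `intron_index`, `end`, `hex_a`, `hex_b`,
#'   `n_mismatch`.
#' @export
extract_hexes <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  if (any(pairs$len_a < 12L | pairs$len_b < 12L)) {
    stop("all introns must be at least 12 nt so the two hexanucleotides ",
         "are disjoint; run filter_pairs() first")
  }
  hex5_a <- substr(pairs$seq_a, 1L, 6L)
  hex5_b <- substr(pairs$seq_b, 1L, 6L)
  hex3_a <- substr(pairs$seq_a, pairs$len_a - 5L, pairs$len_a)
  hex3_b <- substr(pairs$seq_b, pairs$len_b - 5L, pairs$len_b)
  mism <- function(a, b, positions) {
    ma <- hex_matrix(a)
    mb <- hex_matrix(b)
    rowSums(ma[, positions, drop = FALSE] != mb[, positions, drop = FALSE])
  }
  out <- rbind(
    data.frame(gene_id = pairs$gene_id, intron_index = pairs$intron_index,
               end = "five_prime", hex_a = hex5_a, hex_b = hex5_b,
               n_mismatch = mism(hex5_a, hex5_b, 3:6),
               stringsAsFactors = FALSE),
    data.frame(gene_id = pairs$gene_id, intron_index = pairs$intron_index,
               end = "three_prime", hex_a = hex3_a, hex_b = hex3_b,
               n_mismatch = mism(hex3_a, hex3_b, 1:4),
               stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  class(out) <- c("hex_pairs", "data.frame")
  out
}

hex_subset <- function(hex_pairs, end) {
  end <- match_end(end)
  hp <- hex_pairs[hex_pairs$end == end, , drop = FALSE]
  if (nrow(hp) == 0L) stop("no hexanucleotide pairs for end ", end)
  hp
}

#' Per-species hexanucleotide frequency table
#'
#' Tabulates how often each distinct hexanucleotide appears at the given end
#' in each species, as counts and percentages of the number of couples,
#' sorted by decreasing species-averaged percentage. Distinct-hexanucleotide
#' counts per species and cumulatively over both are attached as attributes.
#'
#' @param hex_pairs A `hex_pairs` data frame from [extract_hexes()].
#' @param end `"five_prime"` or `"three_prime"`.
#' @return A data frame with columns `sequence`, `count_a`, `count_b`,
#'   `pct_a`, `pct_b`, `mean_pct`; attributes `n`, `n_distinct_a`,
#'   `n_distinct_b`, `n_distinct_total`.
#' @export
hex_frequency_table <- function(hex_pairs, end) {
  hp <- hex_subset(hex_pairs, end)
  n <- nrow(hp)
  levels <- sort(unique(c(hp$hex_a, hp$hex_b)))
  ca <- table(factor(hp$hex_a, levels = levels))
  cb <- table(factor(hp$hex_b, levels = levels))
  out <- data.frame(
    sequence = levels,
    count_a  = as.integer(ca),
    count_b  = as.integer(cb),
    stringsAsFactors = FALSE
  )
  out$pct_a <- 100 * out$count_a / n
  out$pct_b <- 100 * out$count_b / n
  out$mean_pct <- (out$pct_a + out$pct_b) / 2
  out <- out[order(-out$mean_pct, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n = n,
            n_distinct_a = sum(out$count_a > 0L),
            n_distinct_b = sum(out$count_b > 0L),
            n_distinct_total = length(levels))
}

#' Per-position base composition of one species' hexanucleotides
#'
#' Fraction of couples whose hexanucleotide for the chosen species carries
#' each base at each variable position. Rows (positions) sum to 1.
#'
#' @param hex_pairs A `hex_pairs` data frame.
#' @param end `"five_prime"` or `"three_prime"`.
#' @param species `"a"` or `"b"`.
#' @return A 4 x 4 numeric matrix, rows named by hexanucleotide position,
#'   columns `A`, `C`, `G`, `T`.
#' @export
position_composition <- function(hex_pairs, end, species = c("a", "b")) {
  species <- match.arg(species)
  hp <- hex_subset(hex_pairs, end)
  m <- hex_matrix(if (species == "a") hp$hex_a else hp$hex_b)
  pos <- variable_positions(end)
  out <- t(vapply(pos, function(p) {
    tab <- table(factor(m[, p], levels = BASES))
    as.numeric(tab) / nrow(m)
  }, numeric(4L)))
  dimnames(out) <- list(as.character(pos), BASES)
  out
}

#' Mismatch-count distribution between orthologous hexanucleotides
#'
#' Histogram (fractions over 0..4 changed variable positions) and mean number
#' of changes per hexanucleotide couple.
#'
#' @param hex_pairs A `hex_pairs` data frame.
#' @param end `"five_prime"` or `"three_prime"`.
#' @return A list with `histogram` (named fractions for 0..4, summing to 1)
#'   and `mean` (mean mismatches per couple).
#' @export
mismatch_distribution <- function(hex_pairs, end) {
  hp <- hex_subset(hex_pairs, end)
  tab <- table(factor(hp$n_mismatch, levels = 0:4))
  hist <- as.numeric(tab) / nrow(hp)
  names(hist) <- 0:4
  list(histogram = hist, mean = sum(as.numeric(names(hist)) * hist))
}

#' Classify the sixteen bifunctional GT....AG hexanucleotides
#'
#' A hexanucleotide of the form `GT..AG` could in principle act as either a
#' 5' or a 3' splice site. Each of the 16 such sequences is classified by
#' where it was observed (in either species): `five_only`, `three_only`,
#' `both`, or `unused`.
#'
#' @param hex_pairs_5,hex_pairs_3 `hex_pairs` data frames (or one combined
#'   frame passed to both arguments) holding the initial and terminal
#'   hexanucleotide observations.
#' @return A data frame with 16 rows: `hexanucleotide`, `status`.
#' @export
bifunctional_classification <- function(hex_pairs_5, hex_pairs_3 = hex_pairs_5) {
  grid <- expand.grid(h4 = BASES, h3 = BASES, stringsAsFactors = FALSE)
  hexes <- sort(paste0("GT", grid$h3, grid$h4, "AG"))
  seen_at <- function(hp, end) {
    rows <- hp[hp$end == end, , drop = FALSE]  # empty census is legitimate
    unique(c(rows$hex_a, rows$hex_b))
  }
  seen5 <- seen_at(hex_pairs_5, "five_prime")
  seen3 <- seen_at(hex_pairs_3, "three_prime")
  in5 <- hexes %in% seen5
  in3 <- hexes %in% seen3
  status <- ifelse(in5 & in3, "both",
                   ifelse(in5, "five_only",
                          ifelse(in3, "three_only", "unused")))
  data.frame(hexanucleotide = hexes, status = status,
             stringsAsFactors = FALSE)
}

#' Write a hexanucleotide frequency table as a TSV
#'
#' @param freq A [hex_frequency_table()] result.
#' @param path Output TSV path.
#' @return Invisibly, the written data frame.
#' @export
write_frequency_tsv <- function(freq, path) {
  out <- data.frame(
    sequence = freq$sequence,
    pct_a    = sprintf("%.1f", freq$pct_a),
    pct_b    = sprintf("%.1f", freq$pct_b),
    mean_pct = sprintf("%.1f", freq$mean_pct),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write per-position base composition (both species) as a TSV
#'
#' @param hex_pairs A `hex_pairs` data frame.
#' @param end `"five_prime"` or `"three_prime"`.
#' @param path Output TSV path.
#' @return Invisibly, the written data frame.
#' @export
write_composition_tsv <- function(hex_pairs, end, path) {
  ca <- position_composition(hex_pairs, end, "a")
  cb <- position_composition(hex_pairs, end, "b")
  pos <- variable_positions(end)
  out <- data.frame(
    position = rep(pos, each = 4L),
    base     = rep(BASES, times = length(pos)),
    pct_a    = sprintf("%.2f", 100 * as.vector(t(ca))),
    pct_b    = sprintf("%.2f", 100 * as.vector(t(cb))),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
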