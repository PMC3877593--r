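# Ungapped antiparallel Watson-Crick complementarity between the U1 snRNA 5'
# element (written ACTTAC in DNA alphabet) and the 5' splice-site region.
# The region scored is the last three exonic nucleotides plus the intron's
# initial hexanucleotide; register 0 places the U1 element across the
# hexanucleotide, negative registers slide it into the exon tail.

U1_DEFAULT <- "ACTTAC"

# Antiparallel pairing template: 5'ss position i pairs U1 position 7-i, so
# matching the hexanucleotide against the reverse complement of the U1
# element position-wise is equivalent. ACTTAC -> GTAAGT.
u1_pairing_template <- function(u1 = U1_DEFAULT) {
  if (nchar(u1) != 6L || !is_dna(u1, allow_n = FALSE)) {
    stop("the U1 element must be a 6-mer over A, C, G, T")
  }
  rev(strsplit(chartr("ACGT", "TGCA", u1), "")[[1]])
}

#' Watson-Crick match vector between a 5' splice site and U1 (register 0)
#'
#' Position `i` of the hexanucleotide (5'->3') is matched iff it is the
#' Watson-Crick complement of U1 position `7 - i` (antiparallel pairing).
#' With the default element `ACTTAC` this amounts to position-wise identity
#' with the template `GTAAGT`. G.T wobble pairs are not matches unless
#' `wobble = TRUE`.
#'
#' @param five_ss_hex The intron's initial hexanucleotide (6-mer, ACGT).
#' @param u1 The U1 snRNA 5' element in DNA alphabet (default `"ACTTAC"`).
#' @param wobble Also count G.U (G.T in DNA space) wobble pairs as matches
#'   (default `FALSE`).
#' @return A `u1_match` list: `register_shift` (0), `matches` (6 logicals),
#'   `n_matches`.
#' @examples
#' u1_match_vector("GTAAGT")$n_matches  # 6
#' u1_match_vector("GTTTCG")$n_matches  # 2
#' @export
u1_match_vector <- function(five_ss_hex, u1 = U1_DEFAULT, wobble = FALSE) {
  if (nchar(five_ss_hex) != 6L || !is_dna(five_ss_hex, allow_n = FALSE)) {
    stop("five_ss_hex must be a 6-mer over A, C, G, T")
  }
  tmpl <- u1_pairing_template(u1)
  ss <- strsplit(five_ss_hex, "")[[1]]
  matches <- ss == tmpl
  if (wobble) {
    u1_chars <- rev(strsplit(u1, "")[[1]])  # u1 base facing position i
    matches <- matches |
      (u1_chars == "G" & ss == "T") | (u1_chars == "T" & ss == "G")
  }
  structure(list(register_shift = 0L, matches = matches,
                 n_matches = sum(matches)),
            class = "u1_match")
}

#' Best ungapped U1 pairing register over the 5' splice-site region
#'
#' Assembles the 9-nt window `exon_tail + five_ss_hex` and evaluates the U1
#' element at registers 0 (across the hexanucleotide) down to -3 (shifted
#' three nucleotides into the exon tail), returning the register with the
#' most Watson-Crick matches; ties break toward register 0.
#'
#' @param exon_tail The exon's last three nucleotides (3-mer, ACGT).
#' @param five_ss_hex The intron's initial hexanucleotide (6-mer, ACGT).
#' @param u1 The U1 element (default `"ACTTAC"`).
#' @param wobble Count G.T wobble pairs as matches (default `FALSE`).
#' @return A `u1_match` list: `register_shift` in `-3..0`, `matches`,
#'   `n_matches`, and `aligned` (the 6-mer the element paired against).
#' @export
u1_best_register <- function(exon_tail, five_ss_hex, u1 = U1_DEFAULT,
                             wobble = FALSE) {
  if (nchar(exon_tail) != 3L || !is_dna(exon_tail, allow_n = FALSE)) {
    stop("exon_tail must be a 3-mer over A, C, G, T")
  }
  if (nchar(five_ss_hex) != 6L || !is_dna(five_ss_hex, allow_n = FALSE)) {
    stop("five_ss_hex must be a 6-mer over A, C, G, T")
  }
  window <- paste0(exon_tail, five_ss_hex)
  tmpl <- u1_pairing_template(u1)
  u1_chars <- rev(strsplit(u1, "")[[1]])
  best <- NULL
  for (s in c(0L, -1L, -2L, -3L)) {
    seg <- substr(window, 4L + s, 9L + s)
    ss <- strsplit(seg, "")[[1]]
    matches <- ss == tmpl
    if (wobble) {
      matches <- matches |
        (u1_chars == "G" & ss == "T") | (u1_chars == "T" & ss == "G")
    }
    cand <- list(register_shift = s, matches = matches,
                 n_matches = sum(matches), aligned = seg)
    if (is.null(best) || cand$n_matches > best$n_matches) best <- cand
  }
  structure(best, class = "u1_match")
}

#' Aggregate U1 complementarity over a set of 5' splice sites
#'
#' Per-position match frequencies against the U1 template (register 0), for
#' each species and pooled; the mean match rate over the four variable
#' positions; and the frequency of perfect (6/6) sites. When `exon_tails`
#' are supplied, the fraction of sites whose best ungapped register is
#' shifted into the exon is also reported.
#'
#' @param hex_pairs A `hex_pairs` data frame (its `five_prime` rows are
#'   used).
#' @param exon_tails Optional character vector of 3-mers (one per couple,
#'   applied to both species) enabling the best-register statistic.
#' @param u1 The U1 element (default `"ACTTAC"`).
#' @return A list: `per_position` (data frame of match rates by position),
#'   `mean_variable_a`, `mean_variable_b`, `mean_variable_pooled`,
#'   `perfect_freq_a`, `perfect_freq_b`, `perfect_freq_pooled`, and
#'   `shifted_fraction` (`NA` without `exon_tails`).
#' @export
u1_aggregate <- function(hex_pairs, exon_tails = NULL, u1 = U1_DEFAULT) {
  hp <- hex_subset(hex_pairs, "five_prime")
  tmpl <- u1_pairing_template(u1)
  rate <- function(hexes) {
    m <- hex_matrix(hexes)
    colMeans(m == matrix(tmpl, nrow = nrow(m), ncol = 6L, byrow = TRUE))
  }
  ra <- rate(hp$hex_a)
  rb <- rate(hp$hex_b)
  rp <- rate(c(hp$hex_a, hp$hex_b))
  varpos <- variable_positions("five_prime")
  perfect <- function(hexes) {
    m <- hex_matrix(hexes)
    mean(rowSums(m == matrix(tmpl, nrow = nrow(m), ncol = 6L,
                             byrow = TRUE)) == 6L)
  }
  shifted <- NA_real_
  if (!is.null(exon_tails)) {
    if (length(exon_tails) != nrow(hp)) {
      stop("exon_tails must supply one 3-mer per couple")
    }
    regs <- mapply(function(tail, hex) {
      u1_best_register(tail, hex, u1)$register_shift
    }, rep(exon_tails, 2L), c(hp$hex_a, hp$hex_b))
    shifted <- mean(regs < 0L)
  }
  list(
    per_position = data.frame(position = 1:6, rate_a = ra, rate_b = rb,
                              rate_pooled = rp),
    mean_variable_a = mean(ra[varpos]),
    mean_variable_b = mean(rb[varpos]),
    mean_variable_pooled = mean(rp[varpos]),
    perfect_freq_a = perfect(hp$hex_a),
    perfect_freq_b = perfect(hp$hex_b),
    perfect_freq_pooled = perfect(c(hp$hex_a, hp$hex_b)),
    shifted_fraction = shifted
  )
}
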