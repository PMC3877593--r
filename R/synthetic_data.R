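# Seeded generator of orthologous intron couples with the statistical
# structure the analysis assumes: an ancestral hexanucleotide drawn from a
# usage distribution, independent per-position retention vs mutation in the
# two lineages, intron-body identity plateaus, and an optional
# whole-hexanucleotide retention boost for chosen motifs (creating
# correlated conservation in excess of the random-association null).

#' Generator configuration for synthetic orthologous intron couples
#'
#' Defaults reproduce the summary statistics of the 216 mouse/human
#' cytokine-receptor intron couples bundled with the package: the most
#' frequent hexanucleotides (remaining mass spread uniformly over the other
#' canonical hexanucleotides), per-position cross-species conservation
#' totals, and the three intron-body identity plateaus (55.4% over 5'
#' positions 7--50, 63.1% over 3' positions 7--21, 56.0% over 3' positions
#' 22--50).
#'
#' @param n_pairs Number of couples to generate (default 216).
#' @param seed Integer seed; the full output is reproducible from
#'   `(config, seed)`.
#' @param hex5_usage,hex3_usage Named probability vectors of ancestral
#'   hexanucleotide usage (must sum to <= 1; remainder spread uniformly over
#'   the unlisted canonical hexanucleotides). Set to `NULL` to draw each
#'   variable position independently from `hex5_composition` /
#'   `hex3_composition` instead (a factorized null with no between-position
#'   correlation).
#' @param hex5_composition,hex3_composition 4 x 4 matrices (variable
#'   position x base A,C,G,T) of per-position base probabilities, used when
#'   the corresponding usage map is `NULL`. Default: uniform 0.25.
#' @param per_position_conservation_5,per_position_conservation_3 Four
#'   probabilities each: chance that a variable position retains the
#'   ancestral base in both lineages. Defaults are the reference actual
#'   conservation totals (5': 0.8426, 0.9028, 0.9352, 0.736; 3': 0.7221,
#'   0.7268, 0.5973, 0.7731, hexanucleotide positions left-to-right).
#' @param body_identity_5 Cross-species identity of intron-body positions
#'   outside both end windows (default 0.554).
#' @param body_identity_3_near,body_identity_3_far Identity at positions
#'   7--21 and 22--50 counted from the 3' end (defaults 0.631, 0.560).
#' @param intron_length_range Two integers `(min >= 12, max)`; one length is
#'   drawn per couple and shared by both species (default `c(100, 300)`).
#' @param correlated_motifs Named numeric vector: for ancestors matching the
#'   pattern (name), the whole hexanucleotide is retained intact in both
#'   species with the given extra probability, creating excess conservation
#'   of that motif over the random-association null. Default: none.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_pairs = 216L,
                             seed = 1L,
                             hex5_usage = reference_hex_usage("five_prime"),
                             hex3_usage = reference_hex_usage("three_prime"),
                             hex5_composition = NULL,
                             hex3_composition = NULL,
                             per_position_conservation_5 =
                               c(0.8426, 0.9028, 0.9352, 0.736),
                             per_position_conservation_3 =
                               c(0.7221, 0.7268, 0.5973, 0.7731),
                             body_identity_5 = 0.554,
                             body_identity_3_near = 0.631,
                             body_identity_3_far = 0.560,
                             intron_length_range = c(100L, 300L),
                             correlated_motifs = NULL) {
  n_pairs <- as.integer(n_pairs)
  if (is.na(n_pairs) || n_pairs < 1L) stop("n_pairs must be >= 1")
  probs <- c(per_position_conservation_5, per_position_conservation_3,
             body_identity_5, body_identity_3_near, body_identity_3_far)
  if (any(probs < 0 | probs > 1)) {
    stop("all conservation/identity parameters must lie in [0, 1]")
  }
  if (length(per_position_conservation_5) != 4L ||
      length(per_position_conservation_3) != 4L) {
    stop("per-position conservation needs exactly 4 probabilities per end")
  }
  for (u in list(hex5_usage, hex3_usage)) {
    if (!is.null(u)) {
      if (is.null(names(u)) || any(nchar(names(u)) != 6L)) {
        stop("usage maps must be named by hexanucleotides")
      }
      if (any(u < 0) || sum(u) > 1 + 1e-9) {
        stop("usage probabilities must be non-negative and sum to <= 1")
      }
    }
  }
  intron_length_range <- as.integer(intron_length_range)
  if (length(intron_length_range) != 2L || intron_length_range[1L] < 12L ||
      intron_length_range[2L] < intron_length_range[1L]) {
    stop("intron_length_range must be (min >= 12, max >= min)")
  }
  if (!is.null(correlated_motifs) &&
      (is.null(names(correlated_motifs)) ||
       any(correlated_motifs < 0 | correlated_motifs > 1))) {
    stop("correlated_motifs must be a named vector of probabilities")
  }
  structure(list(
    n_pairs = n_pairs, seed = as.integer(seed),
    hex5_usage = hex5_usage, hex3_usage = hex3_usage,
    hex5_composition = hex5_composition,
    hex3_composition = hex3_composition,
    per_position_conservation_5 = per_position_conservation_5,
    per_position_conservation_3 = per_position_conservation_3,
    body_identity_5 = body_identity_5,
    body_identity_3_near = body_identity_3_near,
    body_identity_3_far = body_identity_3_far,
    intron_length_range = intron_length_range,
    correlated_motifs = correlated_motifs
  ), class = "generator_config")
}

# all 256 canonical hexanucleotides for one end
full_hex_space <- function(end) {
  end <- match_end(end)
  g <- expand.grid(p4 = BASES, p3 = BASES, p2 = BASES, p1 = BASES,
                   stringsAsFactors = FALSE)
  core <- paste0(g$p1, g$p2, g$p3, g$p4)
  if (end == "five_prime") paste0("GT", core) else paste0(core, "AG")
}

# full 256-hex probability vector: listed usage plus uniform remainder
usage_probs <- function(usage, end) {
  space <- full_hex_space(end)
  probs <- setNames(rep(0, length(space)), space)
  if (!all(names(usage) %in% space)) {
    stop("usage map contains non-canonical hexanucleotides for the ",
         end, " end: ",
         paste(setdiff(names(usage), space), collapse = ", "))
  }
  probs[names(usage)] <- usage
  rest <- setdiff(space, names(usage))
  probs[rest] <- (1 - sum(usage)) / length(rest)
  probs
}

draw_ancestors <- function(n, usage, composition, end) {
  varpos <- variable_positions(end)
  if (!is.null(usage)) {
    probs <- usage_probs(usage, end)
    hexes <- sample(names(probs), n, replace = TRUE, prob = probs)
    return(hex_matrix(hexes))
  }
  comp <- composition
  if (is.null(comp)) {
    comp <- matrix(0.25, nrow = 4L, ncol = 4L, dimnames = list(NULL, BASES))
  }
  if (any(abs(rowSums(comp) - 1) > 1e-9)) {
    stop("composition rows must sum to 1")
  }
  m <- matrix("", nrow = n, ncol = 6L)
  if (end == "five_prime") {
    m[, 1L] <- "G"; m[, 2L] <- "T"
  } else {
    m[, 5L] <- "A"; m[, 6L] <- "G"
  }
  for (i in seq_along(varpos)) {
    m[, varpos[i]] <- sample(BASES, n, replace = TRUE, prob = comp[i, ])
  }
  m
}

# uniform draw over the three bases other than `base` (vectorised)
off_base <- function(base) {
  alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                nrow = 3L,
                dimnames = list(NULL, BASES))
  pick <- sample.int(3L, length(base), replace = TRUE)
  alt[cbind(pick, match(base, BASES))]
}

# evolve ancestor hex matrix into the two species; returns list of species
# matrices plus the per-position conservation mask and whole-hex retention
evolve_hexes <- function(anc, end, conservation, motifs) {
  n <- nrow(anc)
  varpos <- variable_positions(end)
  retained <- rep(FALSE, n)
  if (!is.null(motifs)) {
    for (m in seq_along(motifs)) {
      pat <- motif_pattern(names(motifs)[m], end = end)
      hit <- rep(TRUE, n)
      for (p in which(pat$chars != "x")) {
        hit <- hit & anc[, p] == pat$chars[p]
      }
      retained <- retained | (hit & runif(n) < motifs[m])
    }
  }
  a <- anc
  b <- anc
  conserved <- matrix(TRUE, nrow = n, ncol = 4L)
  for (i in seq_along(varpos)) {
    p <- varpos[i]
    keep <- retained | runif(n) < conservation[i]
    conserved[, i] <- keep
    mut <- which(!keep)
    if (length(mut)) {
      # a fair coin picks which lineage keeps the ancestral base; the other
      # is forced onto one of the three alternatives, so cross-species
      # identity at the position fails with certainty
      a_keeps <- runif(length(mut)) < 0.5
      new_base <- off_base(anc[mut, p])
      b[mut[a_keeps], p] <- new_base[a_keeps]
      a[mut[!a_keeps], p] <- new_base[!a_keeps]
    }
  }
  list(a = a, b = b, conserved = conserved, retained = retained)
}

#' Generate synthetic orthologous intron couples
#'
#' For each couple an ancestral initial and terminal hexanucleotide is drawn
#' from the configured usage (or per-position composition); each variable
#' position is retained in both lineages with the configured per-position
#' conservation probability, otherwise one lineage (fair coin) keeps the
#' ancestral base and the other is forced onto a different base, so
#' cross-species identity at the position equals the configured conservation
#' exactly in expectation. Intron-body positions are drawn with the plateau
#' identity of their zone (distance from the 3' end: 7--21 near, 22--50 far,
#' otherwise the 5' body value). Canonical GT/AG dinucleotides are enforced
#' by construction.
#'
#' @param config A [generator_config()].
#' @return A list with `pairs` (an `intron_pairs` data frame) and `truth`
#'   (realized ancestors, conservation masks, whole-hexanucleotide retention
#'   flags, intron lengths, and the config).
#' @export
generate_pairs <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed)
  n <- config$n_pairs
  anc5 <- draw_ancestors(n, config$hex5_usage, config$hex5_composition,
                         "five_prime")
  anc3 <- draw_ancestors(n, config$hex3_usage, config$hex3_composition,
                         "three_prime")
  motifs5 <- motifs3 <- NULL
  if (!is.null(config$correlated_motifs)) {
    ends <- vapply(names(config$correlated_motifs), function(p) {
      # bifunctional patterns default to the 5' end in the generator
      if (substr(p, 1L, 2L) == "GT") "five_prime" else "three_prime"
    }, character(1L))
    motifs5 <- config$correlated_motifs[ends == "five_prime"]
    motifs3 <- config$correlated_motifs[ends == "three_prime"]
    if (!length(motifs5)) motifs5 <- NULL
    if (!length(motifs3)) motifs3 <- NULL
  }
  ev5 <- evolve_hexes(anc5, "five_prime",
                      config$per_position_conservation_5, motifs5)
  ev3 <- evolve_hexes(anc3, "three_prime",
                      config$per_position_conservation_3, motifs3)
  len_choices <- seq(config$intron_length_range[1L],
                     config$intron_length_range[2L])
  lens <- if (length(len_choices) == 1L) rep(len_choices, n) else {
    sample(len_choices, n, replace = TRUE)
  }
  body_len <- lens - 12L
  total <- sum(body_len)
  body_a_chr <- body_b_chr <- character(n)
  if (total > 0L) {
    couple <- factor(rep(seq_len(n), body_len), levels = seq_len(n))
    idx <- sequence(body_len)              # body position 1..(L-12)
    p <- idx + 6L                          # intron position
    d3 <- lens[couple] - p + 1L            # distance from the 3' end
    ident_p <- ifelse(d3 <= 21L, config$body_identity_3_near,
                      ifelse(d3 <= 50L, config$body_identity_3_far,
                             config$body_identity_5))
    base_a <- sample(BASES, total, replace = TRUE)
    same <- runif(total) < ident_p
    base_b <- base_a
    if (any(!same)) base_b[!same] <- off_base(base_a[!same])
    body_a_chr <- vapply(split(base_a, couple), paste, character(1L),
                         collapse = "")
    body_b_chr <- vapply(split(base_b, couple), paste, character(1L),
                         collapse = "")
  }
  collapse_hex <- function(m) apply(m, 1L, paste, collapse = "")
  seq_a <- paste0(collapse_hex(ev5$a), body_a_chr, collapse_hex(ev3$a))
  seq_b <- paste0(collapse_hex(ev5$b), body_b_chr, collapse_hex(ev3$b))
  pairs <- new_intron_pairs(data.frame(
    gene_id      = sprintf("g%04d", seq_len(n)),
    intron_index = 1L,
    seq_a        = seq_a,
    seq_b        = seq_b,
    len_a        = lens,
    len_b        = lens,
    canonical_a  = TRUE,
    canonical_b  = TRUE,
    stringsAsFactors = FALSE
  ))
  truth <- list(
    ancestor_hex5 = collapse_hex(anc5),
    ancestor_hex3 = collapse_hex(anc3),
    conserved_5 = ev5$conserved, conserved_3 = ev3$conserved,
    retained_5 = ev5$retained, retained_3 = ev3$retained,
    lengths = lens, config = config
  )
  list(pairs = pairs, truth = truth)
}

#' Generate a canonical/variant transcript fixture with a known event
#'
#' Builds a canonical transcript on a synthetic gene axis and a variant
#' carrying exactly one catalogued splice event, together with the event
#' [classify_variant()] must report.
#'
#' @param kind `"exon_skipping"`, `"alt_3ss"` or `"alt_5ss"`.
#' @param n_exons Number of canonical exons (default 8).
#' @param exon_lengths Exon lengths, recycled to `n_exons` (default 120).
#' @param intron_length Intron length between exons (default 300).
#' @param exon_index First (or only) exon affected (default 4).
#' @param exon_to Last skipped exon for multi-exon skipping (default
#'   `exon_index`).
#' @param offset Signed splice-site offset in nucleotides for the `alt_*`
#'   kinds (negative = upstream; default -18).
#' @param gene_id Gene identifier (default `"geneX"`).
#' @return A list with `canonical`, `variant` (both
#'   `transcript_structure`) and `expected` (one-row event data frame).
#' @export
generate_transcript_fixture <- function(kind = c("exon_skipping", "alt_3ss",
                                                 "alt_5ss"),
                                        n_exons = 8L, exon_lengths = 120L,
                                        intron_length = 300L,
                                        exon_index = 4L, exon_to = exon_index,
                                        offset = -18L, gene_id = "geneX") {
  kind <- match.arg(kind)
  exon_lengths <- rep_len(as.integer(exon_lengths), n_exons)
  starts <- integer(n_exons)
  starts[1L] <- 1L
  for (i in seq_len(n_exons - 1L)) {
    starts[i + 1L] <- starts[i] + exon_lengths[i] + intron_length
  }
  ce <- data.frame(start = starts, end = starts + exon_lengths - 1L)
  canonical <- transcript_structure("canonical", gene_id, ce)
  if (kind == "exon_skipping") {
    if (exon_index < 1L || exon_to > n_exons || exon_index > exon_to) {
      stop("invalid skipped-exon range")
    }
    ve <- ce[-(exon_index:exon_to), , drop = FALSE]
    dlen <- -sum(exon_lengths[exon_index:exon_to])
    expected <- data.frame(kind = "exon_skipping", exon_from = exon_index,
                           exon_to = exon_to, offset_nt = NA_integer_,
                           length_change_nt = dlen,
                           frame_preserved = dlen %% 3L == 0L,
                           stringsAsFactors = FALSE)
  } else {
    offset <- as.integer(offset)
    if (offset == 0L) stop("offset must be non-zero for alternative sites")
    ve <- ce
    if (kind == "alt_3ss") {
      new_start <- ce$start[exon_index] + offset
      prev_end <- if (exon_index > 1L) ce$end[exon_index - 1L] else 0L
      if (new_start <= prev_end || new_start > ce$end[exon_index]) {
        stop("offset places the acceptor outside the intron/exon geometry")
      }
      ve$start[exon_index] <- new_start
      expected <- data.frame(kind = "alt_3ss", exon_from = exon_index,
                             exon_to = exon_index, offset_nt = offset,
                             length_change_nt = -offset,
                             frame_preserved = (-offset) %% 3L == 0L,
                             stringsAsFactors = FALSE)
    } else {
      new_end <- ce$end[exon_index] + offset
      next_start <- if (exon_index < n_exons) ce$start[exon_index + 1L]
                    else new_end + 1L
      if (new_end < ce$start[exon_index] || new_end >= next_start) {
        stop("offset places the donor outside the intron/exon geometry")
      }
      ve$end[exon_index] <- new_end
      expected <- data.frame(kind = "alt_5ss", exon_from = exon_index,
                             exon_to = exon_index, offset_nt = offset,
                             length_change_nt = offset,
                             frame_preserved = offset %% 3L == 0L,
                             stringsAsFactors = FALSE)
    }
  }
  variant <- transcript_structure("variant", gene_id, ve)
  list(canonical = canonical, variant = variant, expected = expected)
}
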