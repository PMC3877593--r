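# Reading, validating, pairing and writing orthologous intron sequences.
#
# Intron sequences arrive as two FASTA files (one per species), already
# oriented 5'->3' on the mRNA sense strand, plus a TSV manifest that pairs a
# sequence ID in each file under a (gene_id, intron_index) key. Pairs are
# held as a plain data frame (class "intron_pairs") with one row per couple.

#' Analysis configuration
#'
#' Bundles the few knobs shared across the pipeline: the expected number of
#' couples, the window over which positional identity is profiled, the
#' significance level for motif tests, and whether non-canonical (non GT--AG)
#' couples are dropped.
#'
#' @param n_pairs_expected Expected number of intron couples (the reference
#'   study size is 216); informational only.
#' @param window Number of positions profiled from each intron end
#'   (default 50).
#' @param alpha Significance level for one-tailed binomial tests
#'   (default 0.05).
#' @param require_canonical Drop couples whose introns do not start with GT
#'   and end with AG in both species (default `TRUE`).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(n_pairs_expected = 216L, window = 50L,
                            alpha = 0.05, require_canonical = TRUE) {
  window <- as.integer(window)
  if (is.na(window) || window < 6L) stop("window must be an integer >= 6")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1")
  }
  structure(
    list(n_pairs_expected = as.integer(n_pairs_expected), window = window,
         alpha = alpha, require_canonical = isTRUE(require_canonical)),
    class = "analysis_config"
  )
}

new_intron_pairs <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("intron_pairs", "data.frame")
  df
}

# first whitespace-delimited token of a FASTA header
fasta_ids <- function(x) sub("\\s.*$", "", names(x))

#' Read orthologous intron pairs from two FASTA files and a manifest
#'
#' The manifest is a TSV with header columns `gene_id`, `intron_index`,
#' `id_a`, `id_b`; each row names one intron couple by its sequence ID in
#' each species' FASTA. Sequences are uppercased, RNA `U` is converted to
#' `T`, and canonical flags (starts `GT`, ends `AG`) are recomputed from the
#' sequence.
#'
#' @param fasta_a,fasta_b Paths to the species A and species B FASTA files.
#' @param manifest Path to the pairing manifest TSV.
#' @return An `intron_pairs` data frame with one row per manifest row, in
#'   manifest order, and columns `gene_id`, `intron_index`, `seq_a`, `seq_b`,
#'   `len_a`, `len_b`, `canonical_a`, `canonical_b`.
#' @seealso [filter_pairs()], [write_ortholog_pairs()]
#' @export
read_ortholog_pairs <- function(fasta_a, fasta_b, manifest) {
  for (f in c(fasta_a, fasta_b, manifest)) {
    if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  }
  man <- utils::read.delim(manifest, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("gene_id", "intron_index", "id_a", "id_b")
  missing <- setdiff(required, names(man))
  if (length(missing)) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  man$intron_index <- as.integer(man$intron_index)
  if (anyNA(man$intron_index) || any(man$intron_index < 1L)) {
    stop("manifest intron_index must be integers >= 1", call. = FALSE)
  }
  key <- paste(man$gene_id, man$intron_index)
  if (anyDuplicated(key)) {
    stop("duplicate (gene_id, intron_index) in manifest: ",
         key[duplicated(key)][1L], call. = FALSE)
  }
  # BStringSet so RNA/lowercase/ambiguity input survives until normalisation
  sa <- Biostrings::readBStringSet(fasta_a)
  sb <- Biostrings::readBStringSet(fasta_b)
  names(sa) <- fasta_ids(sa)
  names(sb) <- fasta_ids(sb)
  resolve <- function(ids, set, which_file) {
    absent <- !(ids %in% names(set))
    if (any(absent)) {
      row <- which(absent)[1L]
      stop("manifest row ", row, " references ID \"", ids[row],
           "\" absent from ", which_file, call. = FALSE)
    }
    as.character(set[ids])
  }
  seq_a <- normalize_dna(resolve(man$id_a, sa, fasta_a), "species A sequence")
  seq_b <- normalize_dna(resolve(man$id_b, sb, fasta_b), "species B sequence")
  new_intron_pairs(data.frame(
    gene_id      = man$gene_id,
    intron_index = man$intron_index,
    seq_a        = seq_a,
    seq_b        = seq_b,
    len_a        = nchar(seq_a),
    len_b        = nchar(seq_b),
    canonical_a  = startsWith(seq_a, "GT") & endsWith(seq_a, "AG"),
    canonical_b  = startsWith(seq_b, "GT") & endsWith(seq_b, "AG"),
    stringsAsFactors = FALSE
  ))
}

#' Filter intron pairs for downstream analysis
#'
#' Drops couples that are too short for disjoint end hexanucleotides
#' (length < 12 in either species), carry an ambiguous base (`N`) inside
#' either hexanucleotide, or fail the canonical GT--AG check (when
#' `require_canonical`). Each drop is reported with its reason.
#'
#' @param pairs An `intron_pairs` data frame.
#' @param config An [analysis_config()].
#' @return The retained subset, an `intron_pairs` data frame. An empty
#'   result is an error, because the downstream statistics are undefined.
#' @export
filter_pairs <- function(pairs, config = analysis_config()) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) == 0L) stop("no intron pairs to filter", call. = FALSE)
  hex_ok <- function(seq, len) {
    is_dna(substr(seq, 1L, 6L), allow_n = FALSE) &
      is_dna(substr(seq, len - 5L, len), allow_n = FALSE)
  }
  too_short <- pairs$len_a < 12L | pairs$len_b < 12L
  ambiguous <- !too_short &
    !(hex_ok(pairs$seq_a, pairs$len_a) & hex_ok(pairs$seq_b, pairs$len_b))
  noncanon <- if (config$require_canonical) {
    !(pairs$canonical_a & pairs$canonical_b)
  } else {
    rep(FALSE, nrow(pairs))
  }
  drop <- too_short | ambiguous | noncanon
  if (any(drop)) {
    reason <- ifelse(too_short, "length < 12",
                     ifelse(ambiguous, "N inside a hexanucleotide",
                            "non-canonical (not GT...AG)"))
    for (i in which(drop)) {
      message("dropping ", pairs$gene_id[i], " intron ",
              pairs$intron_index[i], ": ", reason[i])
    }
  }
  kept <- pairs[!drop, , drop = FALSE]
  if (nrow(kept) == 0L) {
    stop("all intron pairs were dropped; downstream statistics undefined",
         call. = FALSE)
  }
  new_intron_pairs(kept)
}

#' Write an intron pair set as two FASTA files plus a manifest
#'
#' Inverse of [read_ortholog_pairs()]: sequence IDs are formed as
#' `<gene_id>.<intron_index>` in both files.
#'
#' @param pairs An `intron_pairs` data frame.
#' @param fasta_a,fasta_b,manifest Output paths.
#' @return Invisibly, a named list of the three paths.
#' @export
write_ortholog_pairs <- function(pairs, fasta_a, fasta_b, manifest) {
  stopifnot(is.data.frame(pairs), nrow(pairs) > 0L)
  ids <- paste0(pairs$gene_id, ".", pairs$intron_index)
  sa <- Biostrings::DNAStringSet(setNames(pairs$seq_a, ids))
  sb <- Biostrings::DNAStringSet(setNames(pairs$seq_b, ids))
  Biostrings::writeXStringSet(sa, fasta_a)
  Biostrings::writeXStringSet(sb, fasta_b)
  man <- data.frame(gene_id = pairs$gene_id,
                    intron_index = pairs$intron_index,
                    id_a = ids, id_b = ids, stringsAsFactors = FALSE)
  utils::write.table(man, manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fasta_a = fasta_a, fasta_b = fasta_b, manifest = manifest))
}

#' Write the per-couple hexanucleotide summary TSV
#'
#' One row per couple: the two end hexanucleotides in each species, the
#' canonical flags and the intron lengths.
#'
#' @param pairs An `intron_pairs` data frame (all lengths >= 12).
#' @param path Output TSV path.
#' @return Invisibly, the written data frame.
#' @export
write_pairs_tsv <- function(pairs, path) {
  out <- data.frame(
    gene_id      = pairs$gene_id,
    intron_index = pairs$intron_index,
    hex5_a       = substr(pairs$seq_a, 1L, 6L),
    hex5_b       = substr(pairs$seq_b, 1L, 6L),
    hex3_a       = substr(pairs$seq_a, pairs$len_a - 5L, pairs$len_a),
    hex3_b       = substr(pairs$seq_b, pairs$len_b - 5L, pairs$len_b),
    canonical_a  = pairs$canonical_a,
    canonical_b  = pairs$canonical_b,
    len_a        = pairs$len_a,
    len_b        = pairs$len_b,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
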