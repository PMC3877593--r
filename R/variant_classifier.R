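# Classification of transcript variants against canonical transcript
# structures: exon skipping (a constitutive 3' splice site is silenced and
# the downstream exon dropped), alternative 3'/5' splice sites with signed
# nucleotide offsets, and reading-frame preservation. Coordinates are
# 1-based closed intervals on the gene axis (sense strand).

#' Construct a transcript structure
#'
#' @param transcript_id,gene_id Identifiers.
#' @param exons Data frame with columns `start`, `end`: ordered, 1-based
#'   closed, strictly increasing, non-overlapping exon intervals on the gene
#'   axis.
#' @param hex5,hex3 Optional character vectors of splice-site
#'   hexanucleotides flanking each intron (length `nrow(exons) - 1`): the 5'
#'   site after each internal exon and the 3' site before each following
#'   exon. Attached to events when available; not required for
#'   classification.
#' @return A `transcript_structure` list.
#' @export
transcript_structure <- function(transcript_id, gene_id, exons,
                                 hex5 = NULL, hex3 = NULL) {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  if (nrow(exons) == 0L) stop("exons must be non-empty")
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$start > exons$end)) stop("exon start must not exceed end")
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    stop("exons must be disjoint and strictly increasing")
  }
  n_introns <- nrow(exons) - 1L
  for (h in list(hex5, hex3)) {
    if (!is.null(h) && length(h) != n_introns) {
      stop("splice-site hexanucleotide annotations must have one entry per ",
           "intron (", n_introns, ")")
    }
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 exons = exons, hex5 = hex5, hex3 = hex3),
            class = "transcript_structure")
}

#' Read transcript structures from a TSV or a GFF3 subset
#'
#' The TSV format has columns `transcript_id`, `gene_id` (optional, defaults
#' to the transcript ID), `exon_index`, `start`, `end`. The GFF3 subset uses
#' `exon` features grouped by their `Parent` (mRNA) attribute, with the gene
#' taken from the mRNA's own `Parent` when present.
#'
#' @param path Input file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"gff3"`.
#' @return Named list of `transcript_structure` objects.
#' @export
read_transcript_structures <- function(path,
                                       format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
              else "tsv"
  }
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("transcript_id", "start", "end")
    if (!all(need %in% names(tab))) {
      stop("transcript TSV needs columns transcript_id, start, end")
    }
    if (is.null(tab$gene_id)) tab$gene_id <- tab$transcript_id
  } else {
    gr <- rtracklayer::import(path)
    df <- as.data.frame(gr)
    ex <- df[df$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0L) stop("no exon features in ", path)
    parent <- vapply(ex$Parent, function(p) as.character(p)[1L],
                     character(1L))
    mrna <- df[df$type == "mRNA", , drop = FALSE]
    gene_of <- setNames(
      vapply(seq_len(nrow(mrna)), function(i) {
        g <- as.character(mrna$Parent[[i]])
        if (length(g)) g[1L] else as.character(mrna$ID[i])
      }, character(1L)),
      as.character(mrna$ID)
    )
    tab <- data.frame(transcript_id = parent,
                      gene_id = ifelse(parent %in% names(gene_of),
                                       gene_of[parent], parent),
                      start = ex$start, end = ex$end,
                      stringsAsFactors = FALSE)
  }
  lapply(split(tab, tab$transcript_id), function(d) {
    transcript_structure(d$transcript_id[1L], d$gene_id[1L],
                         d[, c("start", "end")])
  })
}

empty_events <- function() {
  data.frame(kind = character(), exon_from = integer(),
             exon_to = integer(), offset_nt = integer(),
             length_change_nt = integer(), frame_preserved = logical(),
             stringsAsFactors = FALSE)
}

#' Classify a variant transcript against its canonical structure
#'
#' Canonical exons with no overlapping variant exon become `exon_skipping`
#' events (consecutive absences merged, length change the negated sum of the
#' skipped exon lengths). A variant exon sharing one boundary with a
#' canonical exon but differing at the other becomes `alt_3ss` (acceptor /
#' left boundary differs) or `alt_5ss` (donor / right boundary differs),
#' with a signed offset (negative = upstream shift of the splice site).
#' Variant exons that overlap no canonical exon, overlap several, or differ
#' at both boundaries are reported as `unrecognized`, never silently
#' dropped. Every event carries `frame_preserved`
#' (`length_change_nt %% 3 == 0`).
#'
#' @param canonical,variant `transcript_structure` objects on the same gene
#'   axis.
#' @return A `variant_events` data frame in genomic order with columns
#'   `kind`, `exon_from`, `exon_to`, `offset_nt`, `length_change_nt`,
#'   `frame_preserved`, plus `gene_id` and `variant_id`.
#' @export
classify_variant <- function(canonical, variant) {
  stopifnot(inherits(canonical, "transcript_structure"),
            inherits(variant, "transcript_structure"))
  if (!identical(canonical$gene_id, variant$gene_id)) {
    stop("canonical and variant must lie on the same gene axis (gene_id ",
         canonical$gene_id, " vs ", variant$gene_id, ")")
  }
  ce <- canonical$exons
  ve <- variant$exons
  nc <- nrow(ce)
  covered <- logical(nc)
  events <- empty_events()
  add <- function(kind, from, to, offset, dlen) {
    rbind(events, data.frame(
      kind = kind, exon_from = from, exon_to = to,
      offset_nt = offset, length_change_nt = dlen,
      frame_preserved = if (is.na(dlen)) NA else dlen %% 3L == 0L,
      stringsAsFactors = FALSE))
  }
  for (j in seq_len(nrow(ve))) {
    hit <- which(ve$start[j] <= ce$end & ve$end[j] >= ce$start)
    covered[hit] <- TRUE
    if (length(hit) == 1L) {
      d_left <- ve$start[j] - ce$start[hit]
      d_right <- ve$end[j] - ce$end[hit]
      if (d_left == 0L && d_right == 0L) next
      if (d_left != 0L && d_right == 0L) {
        events <- add("alt_3ss", hit, hit, d_left, -d_left)
      } else if (d_left == 0L && d_right != 0L) {
        events <- add("alt_5ss", hit, hit, d_right, d_right)
      } else {
        events <- add("unrecognized", hit, hit, NA_integer_, NA_integer_)
      }
    } else {
      # novel inclusion (no overlap) or a fusion spanning several canonical
      # exons: outside the catalogued event types
      from <- if (length(hit)) min(hit) else NA_integer_
      to <- if (length(hit)) max(hit) else NA_integer_
      events <- add("unrecognized", from, to, NA_integer_, NA_integer_)
    }
  }
  if (any(!covered)) {
    runs <- rle(!covered)
    stop_at <- cumsum(runs$lengths)
    start_at <- stop_at - runs$lengths + 1L
    for (r in which(runs$values)) {
      from <- start_at[r]
      to <- stop_at[r]
      dlen <- -sum(ce$end[from:to] - ce$start[from:to] + 1L)
      events <- add("exon_skipping", from, to, NA_integer_, dlen)
    }
  }
  ord <- order(ifelse(is.na(events$exon_from), nc + 1L, events$exon_from),
               events$kind)
  events <- events[ord, , drop = FALSE]
  rownames(events) <- NULL
  events$gene_id <- rep(canonical$gene_id, nrow(events))
  events$variant_id <- rep(variant$transcript_id, nrow(events))
  class(events) <- c("variant_events", "data.frame")
  events
}

#' Fraction of variable splice sites across many variant classifications
#'
#' A canonical 3' splice site is variable if any variant silences it (exon
#' skipping of its downstream exon) or replaces it (`alt_3ss`); a canonical
#' 5' site is variable if any variant replaces it (`alt_5ss`). Sites hit by
#' several variants count once (unique canonical sites).
#'
#' @param events A `variant_events` data frame (or rbind of several).
#' @param n_5ss,n_3ss Total numbers of canonical 5' and 3' splice sites.
#' @return A list with `frac_5ss` and `frac_3ss`.
#' @export
variability_summary <- function(events, n_5ss, n_3ss) {
  sites3 <- character(0L)
  sites5 <- character(0L)
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      kind <- events$kind[i]
      g <- events$gene_id[i]
      if (kind == "exon_skipping") {
        sites3 <- c(sites3, paste(g, events$exon_from[i]:events$exon_to[i]))
      } else if (kind == "alt_3ss") {
        sites3 <- c(sites3, paste(g, events$exon_from[i]))
      } else if (kind == "alt_5ss") {
        sites5 <- c(sites5, paste(g, events$exon_from[i]))
      }
    }
  }
  n3 <- length(unique(sites3))
  n5 <- length(unique(sites5))
  if (n5 > n_5ss || n3 > n_3ss) {
    stop("site totals are smaller than the number of distinct variable sites")
  }
  list(frac_5ss = if (n_5ss > 0) n5 / n_5ss else 0,
       frac_3ss = if (n_3ss > 0) n3 / n_3ss else 0)
}

#' Write variant events as a TSV
#'
#' @param events A `variant_events` data frame.
#' @param path Output TSV path.
#' @return Invisibly, the written data frame.
#' @export
write_variant_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(events)
}
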