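# End-to-end orchestration: read and filter intron couples, run every
# analysis stage, and write publication-style TSV tables plus a
# machine-readable report.json. Outputs use fixed float formatting and stable sort orders so
# re-running on identical inputs is byte-identical.

#' Simulate a dataset to disk
#'
#' Generates synthetic orthologous intron couples and writes them in the
#' same FASTA x2 + manifest format [read_ortholog_pairs()] consumes, plus
#' the generator ground truth as JSON.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [generator_config()].
#' @return Invisibly, a named list of the written paths.
#' @export
simulate_dataset <- function(out_dir, config = generator_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_pairs(config)
  paths <- write_ortholog_pairs(
    sim$pairs,
    fasta_a = file.path(out_dir, "species_a.fasta"),
    fasta_b = file.path(out_dir, "species_b.fasta"),
    manifest = file.path(out_dir, "manifest.tsv")
  )
  truth_path <- file.path(out_dir, "truth.json")
  truth <- sim$truth
  truth$conserved_5 <- NULL  # large masks are reproducible from the seed
  truth$conserved_3 <- NULL
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(c(paths, list(truth = truth_path)))
}

#' Run the full splice-site conservation pipeline
#'
#' Executes identity profiling, the hexanucleotide census, the
#' random-association conservation model with the motif scan, U1 pairing
#' aggregation and (when transcript pairs are supplied) variant
#' classification, writing one TSV per table plus `report.json` under
#' `out_dir`.
#'
#' @param fasta_a,fasta_b,manifest Input paths for [read_ortholog_pairs()].
#' @param out_dir Output directory (created if missing).
#' @param config An [analysis_config()].
#' @param ends Which intron ends to analyse (default both).
#' @param transcript_pairs Optional list of `list(canonical=, variant=)`
#'   `transcript_structure` pairs for variant classification.
#' @return Invisibly, the report list (also written as `report.json`).
#' @export
run_pipeline <- function(fasta_a, fasta_b, manifest, out_dir,
                         config = analysis_config(),
                         ends = c("five_prime", "three_prime"),
                         transcript_pairs = NULL) {
  ends <- match.arg(ends, END_LEVELS, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  pairs <- stage("intron_io", {
    filter_pairs(read_ortholog_pairs(fasta_a, fasta_b, manifest), config)
  })
  write_pairs_tsv(pairs, file.path(out_dir, "pairs.tsv"))
  hexes <- stage("hex_census", extract_hexes(pairs))
  report <- list(
    config = unclass(config),
    n_couples = nrow(pairs),
    outputs = list(pairs = "pairs.tsv")  # paths relative to out_dir
  )
  for (end in ends) {
    tag <- if (end == "five_prime") "5prime" else "3prime"
    prof <- stage(paste0("positional_identity_", tag), {
      identity_profile(pairs, end, config$window)
    })
    write_identity_tsv(prof, file.path(out_dir,
                                       paste0("identity_", tag, ".tsv")))
    freq <- hex_frequency_table(hexes, end)
    write_frequency_tsv(freq, file.path(out_dir,
                                        paste0("hex_frequency_", tag,
                                               ".tsv")))
    write_composition_tsv(hexes, end,
                          file.path(out_dir,
                                    paste0("composition_", tag, ".tsv")))
    cons <- stage(paste0("conservation_", tag),
                  conservation_table(hexes, end))
    write_conservation_tsv(cons, file.path(out_dir,
                                           paste0("conservation_", tag,
                                                  ".tsv")))
    scan <- stage(paste0("motif_scan_", tag), {
      motif_scan(hexes, end, cons, config$alpha)
    })
    write_motif_scan_tsv(scan, file.path(out_dir,
                                         paste0("motif_scan_", tag, ".tsv")))
    mism <- mismatch_distribution(hexes, end)
    plateaus <- if (end == "five_prime") {
      list(body = plateau_mean(prof, 7L, min(50L, config$window)))
    } else {
      list(near = plateau_mean(prof, 7L, min(21L, config$window)),
           far = if (config$window >= 22L) {
             plateau_mean(prof, 22L, min(50L, config$window))
           } else NULL)
    }
    report[[end]] <- list(
      n_distinct_a = attr(freq, "n_distinct_a"),
      n_distinct_b = attr(freq, "n_distinct_b"),
      n_distinct_total = attr(freq, "n_distinct_total"),
      mean_mismatches = mism$mean,
      identical_fraction = mism$histogram[["0"]],
      plateau_means = plateaus,
      flagged_motifs = scan$pattern[scan$flagged]
    )
  }
  if ("five_prime" %in% ends) {
    u1 <- stage("u1_pairing", u1_aggregate(hexes))
    report$u1 <- list(
      mean_variable_pooled = u1$mean_variable_pooled,
      perfect_freq_a = u1$perfect_freq_a,
      perfect_freq_b = u1$perfect_freq_b
    )
  }
  if (all(END_LEVELS %in% ends)) {
    bif <- bifunctional_classification(hexes)
    utils::write.table(bif, file.path(out_dir, "bifunctional.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$bifunctional = as.list(table(bif$status))
  }
  if (!is.null(transcript_pairs)) {
    events <- stage("variant_classifier", {
      do.call(rbind, lapply(transcript_pairs, function(tp) {
        classify_variant(tp$canonical, tp$variant)
      }))
    })
    write_variant_events_tsv(events, file.path(out_dir, "variants.tsv"))
    report$variants <- list(n_events = nrow(events),
                            kinds = as.list(table(events$kind)))
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 8, force = TRUE)
  invisible(report)
}
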