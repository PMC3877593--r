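# Shared fixtures and independent oracles for the test suite.

# Build an intron_pairs data frame directly from sequence vectors,
# recomputing the derived fields the reader would set.
pairs_from_seqs <- function(seq_a, seq_b,
                            gene_id = sprintf("g%03d", seq_along(seq_a)),
                            intron_index = 1L) {
  df <- data.frame(
    gene_id = gene_id,
    intron_index = rep_len(intron_index, length(seq_a)),
    seq_a = seq_a, seq_b = seq_b,
    len_a = nchar(seq_a), len_b = nchar(seq_b),
    canonical_a = startsWith(seq_a, "GT") & endsWith(seq_a, "AG"),
    canonical_b = startsWith(seq_b, "GT") & endsWith(seq_b, "AG"),
    stringsAsFactors = FALSE
  )
  class(df) <- c("intron_pairs", "data.frame")
  df
}

# Pad a 5' hex and a 3' hex into a full canonical intron of length >= 12.
intron_seq <- function(hex5 = "GTAAGT", hex3 = "TTTCAG", body = "") {
  paste0(hex5, body, hex3)
}

# Write a tiny FASTA/manifest trio to tempdir; returns the three paths.
write_fixture_files <- function(seq_a, seq_b, ids_a = names(seq_a),
                                ids_b = names(seq_b),
                                gene_id = sprintf("G%d", seq_along(seq_a)),
                                intron_index = 1L) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  fa <- file.path(dir, "a.fasta")
  fb <- file.path(dir, "b.fasta")
  mf <- file.path(dir, "manifest.tsv")
  writeLines(as.vector(rbind(paste0(">", ids_a), unname(seq_a))), fa)
  writeLines(as.vector(rbind(paste0(">", ids_b), unname(seq_b))), fb)
  man <- data.frame(gene_id = gene_id,
                    intron_index = rep_len(intron_index, length(seq_a)),
                    id_a = ids_a, id_b = ids_b)
  utils::write.table(man, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta_a = fa, fasta_b = fb, manifest = mf)
}

# Independent brute-force binomial tail: direct choose()/power summation.
brute_binomial_tail <- function(k, n, p0, tail) {
  js <- if (tail == "upper") k:n else 0:k
  sum(choose(n, js) * p0^js * (1 - p0)^(n - js))
}

# Independent motif-frequency oracle: regex matching on both species.
brute_motif_frequency <- function(hex_a, hex_b, pattern) {
  rx <- paste0("^", gsub("x", ".", pattern), "$")
  mean(grepl(rx, hex_a) & grepl(rx, hex_b))
}

# Independent U1 register oracle: brute-force complement count at one shift.
brute_u1_count <- function(window9, u1, shift) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  seg <- strsplit(substr(window9, 4 + shift, 9 + shift), "")[[1]]
  u1c <- strsplit(u1, "")[[1]]
  # antiparallel: segment position i faces u1 position 7 - i
  sum(vapply(1:6, function(i) comp[[u1c[7 - i]]] == seg[i], logical(1)))
}

# Per-position base composition matrix matching the reference mouse values,
# used by simulations that need a realistic factorized 5' composition.
realistic_comp5 <- function() {
  m <- matrix(c(0.597, 0.019, 0.370, 0.014,
                0.824, 0.028, 0.069, 0.079,
                0.079, 0.014, 0.852, 0.055,
                0.218, 0.116, 0.166, 0.500),
              nrow = 4, byrow = TRUE,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m / rowSums(m)
}
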