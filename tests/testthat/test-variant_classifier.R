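test_that("transcript_structure validates exon geometry", {
  good <- transcript_structure("t1", "g1",
                               data.frame(start = c(1, 100), end = c(50, 150)))
  expect_s3_class(good, "transcript_structure")
  expect_error(transcript_structure("t1", "g1",
                                    data.frame(start = 10, end = 5)),
               "start")
  expect_error(transcript_structure("t1", "g1",
                                    data.frame(start = c(1, 40),
                                               end = c(50, 90))),
               "disjoint")
  expect_error(transcript_structure("t1", "g1",
                                    data.frame(start = numeric(),
                                               end = numeric())),
               "non-empty")
})

test_that("identical structures yield no events", {
  fx <- generate_transcript_fixture("exon_skipping")
  expect_equal(nrow(classify_variant(fx$canonical, fx$canonical)), 0L)
})

test_that("a missing internal exon is reported as frame-aware skipping", {
  fx <- generate_transcript_fixture("exon_skipping", n_exons = 8,
                                    exon_lengths = c(90, 90, 90, 216,
                                                     90, 90, 90, 90),
                                    exon_index = 4)
  ev <- classify_variant(fx$canonical, fx$variant)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "exon_skipping")
  expect_equal(ev$exon_from, 4L)
  expect_equal(ev$length_change_nt, -216L)
  expect_true(ev$frame_preserved)
  expect_equal(ev[names(fx$expected)], fx$expected,
               ignore_attr = "class")
})

test_that("consecutive skipped exons merge into one ranged event", {
  fx <- generate_transcript_fixture("exon_skipping", n_exons = 8,
                                    exon_index = 2, exon_to = 4)
  ev <- classify_variant(fx$canonical, fx$variant)
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$exon_from, ev$exon_to), c(2L, 4L))
  expect_equal(ev$length_change_nt, -3L * 120L)
  expect_true(ev$frame_preserved)
})

test_that("boundary shifts classify as alternative 3'/5' sites with offsets", {
  fx3 <- generate_transcript_fixture("alt_3ss", exon_index = 7,
                                     offset = -18)
  ev3 <- classify_variant(fx3$canonical, fx3$variant)
  expect_equal(ev3$kind, "alt_3ss")
  expect_equal(ev3$offset_nt, -18L)
  expect_equal(ev3$length_change_nt, 18L)  # 18-nt longer exon
  expect_true(ev3$frame_preserved)

  fx5 <- generate_transcript_fixture("alt_5ss", exon_index = 7,
                                     offset = -12)
  ev5 <- classify_variant(fx5$canonical, fx5$variant)
  expect_equal(ev5$kind, "alt_5ss")
  expect_equal(ev5$offset_nt, -12L)
  expect_equal(ev5$length_change_nt, -12L)
  expect_true(ev5$frame_preserved)
})

test_that("frame preservation tracks offset mod 3 exhaustively", {
  for (off in setdiff(-30:30, 0)) {
    fx <- generate_transcript_fixture("alt_3ss", offset = off)
    ev <- classify_variant(fx$canonical, fx$variant)
    expect_equal(ev$frame_preserved, off %% 3 == 0)
    expect_equal(ev$length_change_nt, -off)
  }
})

test_that("total length change decomposes over events", {
  fx_a <- generate_transcript_fixture("exon_skipping", exon_index = 3)
  ve <- fx_a$variant$exons
  ve$end[5] <- ve$end[5] + 9  # add an alt_5ss on top of the skip
  variant <- transcript_structure("v2", "geneX", ve)
  ev <- classify_variant(fx_a$canonical, variant)
  expect_equal(sort(ev$kind), c("alt_5ss", "exon_skipping"))
  total <- function(ts) sum(ts$exons$end - ts$exons$start + 1)
  expect_equal(sum(ev$length_change_nt),
               total(variant) - total(fx_a$canonical))
})

test_that("uncatalogued shapes surface as unrecognized, never dropped", {
  fx <- generate_transcript_fixture("exon_skipping")
  # novel exon in an intron: overlaps nothing
  ve <- rbind(fx$canonical$exons,
              data.frame(start = 200, end = 260))
  variant <- transcript_structure("vX", "geneX", ve)
  ev <- classify_variant(fx$canonical, variant)
  expect_true("unrecognized" %in% ev$kind)
  # both boundaries shifted on one exon
  ve2 <- fx$canonical$exons
  ve2$start[4] <- ve2$start[4] - 6
  ve2$end[4] <- ve2$end[4] + 6
  ev2 <- classify_variant(fx$canonical,
                          transcript_structure("vY", "geneX", ve2))
  expect_equal(ev2$kind, "unrecognized")
  # swapping canonical/variant turns skipping into an unrecognized
  # inclusion, not a mislabel
  ev3 <- classify_variant(fx$variant, fx$canonical)
  expect_false("exon_skipping" %in% ev3$kind)
  expect_true("unrecognized" %in% ev3$kind)
})

test_that("classification requires a shared gene axis", {
  a <- transcript_structure("t1", "g1", data.frame(start = 1, end = 50))
  b <- transcript_structure("t2", "g2", data.frame(start = 1, end = 50))
  expect_error(classify_variant(a, b), "gene axis")
})

test_that("variability summary counts unique canonical sites", {
  expect_equal(variability_summary(classify_variant(
    generate_transcript_fixture("alt_3ss")$canonical,
    generate_transcript_fixture("alt_3ss")$canonical), 12, 10),
    list(frac_5ss = 0, frac_3ss = 0))

  fx_skip <- generate_transcript_fixture("exon_skipping", exon_index = 4)
  fx_alt <- generate_transcript_fixture("alt_3ss", exon_index = 6)
  ev <- rbind(classify_variant(fx_skip$canonical, fx_skip$variant),
              classify_variant(fx_alt$canonical, fx_alt$variant))
  s <- variability_summary(ev, n_5ss = 12, n_3ss = 10)
  expect_equal(s$frac_5ss, 0)
  expect_equal(s$frac_3ss, 0.2)

  # the same site hit by two variants counts once
  ev_dup <- rbind(classify_variant(fx_alt$canonical, fx_alt$variant),
                  classify_variant(fx_alt$canonical, fx_alt$variant))
  expect_equal(variability_summary(ev_dup, 12, 10)$frac_3ss, 0.1)
  expect_error(variability_summary(ev, n_5ss = 12, n_3ss = 0), "totals")
})

test_that("transcript structures round-trip through TSV and GFF3", {
  fx <- generate_transcript_fixture("alt_3ss")
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "tx.tsv")
  tab <- rbind(
    data.frame(transcript_id = "canonical", gene_id = "geneX",
               exon_index = seq_len(nrow(fx$canonical$exons)),
               fx$canonical$exons),
    data.frame(transcript_id = "variant", gene_id = "geneX",
               exon_index = seq_len(nrow(fx$variant$exons)),
               fx$variant$exons)
  )
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  ts <- read_transcript_structures(tsv)
  expect_equal(ts$canonical$exons, fx$canonical$exons)
  ev <- classify_variant(ts$canonical, ts$variant)
  expect_equal(ev$kind, "alt_3ss")

  gff <- file.path(dir, "tx.gff3")
  lines <- c("##gff-version 3",
             "chr1\tsrc\tgene\t1\t5000\t.\t+\t.\tID=geneX",
             "chr1\tsrc\tmRNA\t1\t5000\t.\t+\t.\tID=canonical;Parent=geneX",
             paste0("chr1\tsrc\texon\t", fx$canonical$exons$start, "\t",
                    fx$canonical$exons$end, "\t.\t+\t.\tParent=canonical"),
             "chr1\tsrc\tmRNA\t1\t5000\t.\t+\t.\tID=variant;Parent=geneX",
             paste0("chr1\tsrc\texon\t", fx$variant$exons$start, "\t",
                    fx$variant$exons$end, "\t.\t+\t.\tParent=variant"))
  writeLines(lines, gff)
  tg <- read_transcript_structures(gff)
  expect_equal(tg$canonical$exons, fx$canonical$exons)
  expect_equal(tg$canonical$gene_id, "geneX")
  ev2 <- classify_variant(tg$canonical, tg$variant)
  expect_equal(ev2$kind, "alt_3ss")
})
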