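ipr_row <- function(id = "p1", analysis = "Pfam", sig = "PF00931",
                    start = 180, stop = 460, score = "2.1E-45") {
  paste(id, "md5", "500", analysis, sig, "some description", start, stop,
        score, "T", "01-01-2026", sep = "\t")
}

test_that("InterProScan rows map onto canonical motifs via the signature map", {
  h <- parse_interproscan_tsv(c(ipr_row(),
                                ipr_row(id = "p2", analysis = "SMART",
                                        sig = "SM00369", start = 30,
                                        stop = 90)))
  expect_equal(nrow(h), 2)
  p1 <- h[h$protein_id == "p1", ]
  expect_equal(p1$motif, "NB-ARC")
  expect_equal(p1$source, "Pfam")
  expect_equal(c(p1$start, p1$end), c(180L, 460L))
  expect_equal(h$motif[h$protein_id == "p2"], "LRR")
  expect_equal(h$source[h$protein_id == "p2"], "SMART")

  expect_equal(nrow(parse_interproscan_tsv(character(0))), 0)

  # unknown signatures never abort: they land in UNMAPPED
  u <- parse_interproscan_tsv(ipr_row(sig = "PF99999"))
  expect_equal(u$motif, "UNMAPPED")
})

test_that("malformed InterProScan rows honour the strict/skip policy", {
  bad <- c(ipr_row(), "p2\tonly\tthree")
  expect_error(parse_interproscan_tsv(bad), "line 2")
  expect_warning(h <- parse_interproscan_tsv(bad, on_error = "skip"),
                 "skipped 1")
  expect_equal(nrow(h), 1)
  expect_error(parse_interproscan_tsv(ipr_row(start = "abc")), "line 1")
})

test_that("pfam_scan parsing strips version suffixes and orders by start", {
  txt <- c("# pfam_scan.pl output",
           "p1  300  520  295  525  PF00931.23  NB-ARC  Domain  1 250 250 310.2 1.2e-55 1 CL0023",
           "p1   20   80   18   85  PF13855.9   LRR_8   Repeat  1  60  60  40.1 3.0e-09 1 CL0022")
  h <- parse_pfamscan(txt)
  expect_equal(nrow(h), 2)
  expect_equal(h$signature_id, c("PF13855", "PF00931"))  # ordered by start
  expect_equal(h$motif, c("LRR", "NB-ARC"))
  expect_equal(h$source, rep("pfam_scan", 2))
  expect_equal(h$score, c(3.0e-09, 1.2e-55))
  expect_error(parse_pfamscan("p1 x 520 295 525 PF00931.23 N D 1 2 3 4 1e-5 1 CL"),
               "line 1")
})

test_that("Phobius short format yields one TM hit per membrane segment", {
  hdr <- "SEQENCE ID                     TM SP PREDICTION"
  h1 <- parse_phobius(c(hdr, "p0  1  0 o514-537i"))
  expect_equal(nrow(h1), 1)
  expect_equal(c(h1$start, h1$end), c(514L, 537L))

  h <- parse_phobius(c(hdr, "p1  2  0 i10-30o514-537i"))
  expect_equal(nrow(h), 2)
  expect_equal(h$motif, rep("TM", 2))
  expect_equal(h$start, c(10L, 514L))
  expect_equal(h$end, c(30L, 537L))

  expect_equal(nrow(parse_phobius(c(hdr, "p2  0  0 i"))), 0)

  # TM count cross-checked against a brute-force span count
  topo <- "i5-25o60-80i120-140o"
  n_spans <- length(gregexpr("[0-9]+-[0-9]+", topo)[[1]])
  h3 <- parse_phobius(c(hdr, sprintf("p3  %d  0 %s", n_spans, topo)))
  expect_equal(nrow(h3), 3)

  # declared TM count disagreeing with the topology is a row error
  expect_error(parse_phobius(c(hdr, "p4  5  0 i5-25o")), "line 2")
})

test_that("Phobius signal peptides become UNMAPPED hits; long format parses", {
  hdr <- "SEQENCE ID                     TM SP PREDICTION"
  h <- parse_phobius(c(hdr, "p1  1  Y n8-27c31/32o512-530i"))
  expect_equal(sort(h$motif), c("TM", "UNMAPPED"))
  sp <- h[h$motif == "UNMAPPED", ]
  expect_equal(c(sp$start, sp$end), c(1L, 31L))
  tm <- h[h$motif == "TM", ]
  expect_equal(c(tm$start, tm$end), c(512L, 530L))

  long <- c("ID   p9", "FT   SIGNAL        1     22",
            "FT   TRANSMEM    200    221", "//")
  h2 <- parse_phobius(long)
  expect_equal(h2$motif[h2$signature_id == "TRANSMEM"], "TM")
  expect_equal(h2$start[h2$signature_id == "TRANSMEM"], 200L)
  expect_true(all(h2$protein_id == "p9"))
})

test_that("coiled-coil segment tables parse and reject bad probabilities", {
  h <- parse_coils_segments("p1 10 38 0.97")
  expect_equal(h$motif, "CC")
  expect_equal(h$source, "coils")
  expect_equal(c(h$start, h$end), c(10L, 38L))
  expect_equal(h$score, 0.97)
  expect_error(parse_coils_segments("p1 10 38 1.2"), "outside")
  expect_equal(nrow(parse_coils_segments(character(0))), 0)
})

test_that("merge_evidence deduplicates, keeps empty proteins, counts hits", {
  a <- domain_hits("p1", "NB-ARC", "Pfam", "PF00931", 180L, 460L, 1e-40)
  b <- domain_hits("p1", "NB-ARC", "Pfam", "PF00931", 180L, 460L, 1e-40)
  es <- merge_evidence(a, b, lengths = c(p1 = 500L))
  expect_equal(nrow(es$hits), 1)

  lens <- c(a = 300L, b = 300L, c = 300L)
  es2 <- merge_evidence(domain_hits(c("a", "b"), "LRR", "Pfam", "PF13855",
                                    c(1L, 5L), c(60L, 70L)),
                        lengths = lens)
  expect_equal(es2$proteins, c("a", "b", "c"))
  expect_equal(sum(es2$hits$protein_id == "c"), 0)

  # 3 lists totalling 10 distinct hits over 4 proteins
  l1 <- domain_hits(c("w", "w", "x"), "LRR", "Pfam", "PF13855",
                    c(1L, 80L, 1L), c(60L, 140L, 60L))
  l2 <- domain_hits(c("y", "y", "y"), "TM", "phobius", "TRANSMEM",
                    c(10L, 50L, 90L), c(30L, 70L, 110L))
  l3 <- domain_hits(c("z", "z", "x", "w"), "CC", "coils", "COILS",
                    c(5L, 40L, 100L, 200L), c(33L, 68L, 128L, 228L))
  es3 <- merge_evidence(l1, l2, l3)
  expect_equal(length(es3$proteins), 4)
  expect_equal(nrow(es3$hits), 10)
})

test_that("hits beyond the known protein length warn and are flagged", {
  h <- domain_hits("p1", "LRR", "Pfam", "PF13855", 90L, 160L)
  expect_warning(es <- merge_evidence(h, lengths = c(p1 = 100L)), "clamped")
  expect_true(es$hits$clamped)
})

test_that("the domain table round-trips an evidence set identically", {
  es <- make_evidence(list(
    list("p1", "NB-ARC", "pfam_scan", "PF00931", 200L, 450L),
    list("p1", "CC", "coils", "COILS", 8L, 40L),
    list("p2", "TM", "phobius", "TRANSMEM", 300L, 321L)),
    lengths = c(p1 = 500L, p2 = 400L))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_domain_table(es, path)
  back <- merge_evidence(read_domain_table(path),
                         lengths = es$lengths)
  expect_identical(back$hits, es$hits)
  expect_identical(back$proteins, es$proteins)
})

test_that("parsers are deterministic: same bytes give identical hit lists", {
  lines <- c(ipr_row(), ipr_row(id = "p0", analysis = "Gene3D",
                                sig = "G3DSA:3.80.10.10", start = 5,
                                stop = 60))
  expect_identical(parse_interproscan_tsv(lines),
                   parse_interproscan_tsv(rev(lines)[c(2, 1)]))
  expect_identical(parse_interproscan_tsv(lines),
                   parse_interproscan_tsv(lines))
})
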