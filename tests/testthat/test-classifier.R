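test_that("modes activate the documented source sets", {
  q <- rga_mode("quick")
  d <- rga_mode("deep")
  expect_setequal(q$active_sources,
                  c("Pfam", "Gene3D", "pfam_scan", "phobius", "coils"))
  expect_setequal(d$active_sources,
                  c(q$active_sources, "SMART", "Superfamily"))
  f <- rga_mode("free", sources = c("Panther", "phobius"))
  expect_setequal(f$active_sources, c("Panther", "phobius"))
  expect_error(rga_mode("free"), "non-empty")
  expect_error(rga_mode("free", sources = "NotADB"), "unknown source")
})

test_that("mode_filter keeps dedicated channels and drops inactive sources", {
  es <- make_evidence(list(
    list("p1", "LRR", "SMART", "SM00369", 10L, 80L),
    list("p1", "NB-ARC", "pfam_scan", "PF00931", 200L, 450L),
    list("p1", "TM", "phobius", "TRANSMEM", 470L, 491L),
    list("p1", "CC", "coils", "COILS", 1L, 30L)))
  q <- mode_filter(es, rga_mode("quick"))
  expect_false("SMART" %in% q$hits$source)          # LRR hit removed
  expect_setequal(q$hits$source, c("pfam_scan", "phobius", "coils"))
  d <- mode_filter(es, rga_mode("deep"))
  expect_true("SMART" %in% d$hits$source)           # same hit retained
  expect_equal(nrow(d$hits), 4)
})

test_that("flags are pure presence summaries; UNMAPPED sets nothing", {
  h <- domain_hits(rep("p", 4), c("NB-ARC", "LRR", "CC", "UNMAPPED"),
                   c("Pfam", "Pfam", "coils", "phobius"),
                   c("PF00931", "PF13855", "COILS", "SIGNAL"),
                   c(100L, 500L, 1L, 1L), c(400L, 580L, 30L, 25L))
  f <- flags_from_evidence(h)
  expect_equal(f, c(nb = TRUE, tir = FALSE, cc = TRUE, lrr = TRUE,
                    lysm = FALSE, kinase = FALSE, tm = FALSE))
  expect_equal(flags_from_evidence(domain_hits()),
               c(nb = FALSE, tir = FALSE, cc = FALSE, lrr = FALSE,
                 lysm = FALSE, kinase = FALSE, tm = FALSE))
  # duplicates do not matter: presence only
  dup <- domain_hits(rep("p", 3), "TM", "phobius", "TRANSMEM",
                     c(10L, 60L, 110L), c(30L, 80L, 130L))
  expect_true(flags_from_evidence(dup)[["tm"]])
})

test_that("named architectures classify to their documented classes", {
  expect_equal(classify_flags(nb = TRUE, cc = TRUE, lrr = TRUE), "CNL")
  expect_equal(classify_flags(tir = TRUE, cc = TRUE), "OTHER")
  expect_equal(classify_flags(tir = TRUE, cc = TRUE, nb = TRUE), "OTHER")
  expect_equal(classify_flags(tir = TRUE, nb = TRUE, lrr = TRUE), "TNL")
  expect_equal(classify_flags(tir = TRUE, nb = TRUE), "TN")
  expect_equal(classify_flags(tir = TRUE), "TX")
  expect_equal(classify_flags(tir = TRUE, lrr = TRUE, tm = TRUE), "TX")
  expect_equal(classify_flags(nb = TRUE, cc = TRUE), "CN")
  expect_equal(classify_flags(nb = TRUE, lrr = TRUE), "NL")
  expect_equal(classify_flags(nb = TRUE), "NBS")
  expect_equal(classify_flags(tm = TRUE, kinase = TRUE, lrr = TRUE), "RLK")
  expect_equal(classify_flags(tm = TRUE, kinase = TRUE, lysm = TRUE), "RLK")
  expect_equal(classify_flags(tm = TRUE, lysm = TRUE), "RLP")
  expect_equal(classify_flags(tm = TRUE, lrr = TRUE), "RLP")
  expect_equal(classify_flags(tm = TRUE, cc = TRUE), "TMCC")
  expect_equal(classify_flags(), "NONRGA")
  expect_equal(classify_flags(lrr = TRUE), "NONRGA")
})

test_that("classification is total and matches the oracle on all 128 combos", {
  g <- flag_grid()
  got <- classify_flags(g$nb, g$tir, g$cc, g$lrr, g$lysm, g$kinase, g$tm)
  want <- vapply(seq_len(nrow(g)), function(i)
    oracle_classify(g$nb[i], g$tir[i], g$cc[i], g$lrr[i], g$lysm[i],
                    g$kinase[i], g$tm[i]), character(1))
  expect_identical(got, want)
  expect_true(all(got %in% RGA_CLASSES))
})

test_that("NB-ARC or TIR always wins over the membrane branch", {
  g <- flag_grid()
  got <- classify_flags(g$nb, g$tir, g$cc, g$lrr, g$lysm, g$kinase, g$tm)
  nbs_branch <- g$nb | g$tir
  expect_false(any(got[nbs_branch] %in% c("RLP", "RLK", "TMCC")))
})

test_that("relaxing strict_rlk lets TM + kinase qualify without ectodomain", {
  expect_equal(classify_flags(tm = TRUE, kinase = TRUE), "NONRGA")
  expect_equal(classify_flags(tm = TRUE, kinase = TRUE, cc = TRUE), "TMCC")
  expect_equal(classify_flags(tm = TRUE, kinase = TRUE, strict_rlk = FALSE),
               "RLK")
  g <- flag_grid()
  got <- classify_flags(g$nb, g$tir, g$cc, g$lrr, g$lysm, g$kinase, g$tm,
                        strict_rlk = FALSE)
  want <- vapply(seq_len(nrow(g)), function(i)
    oracle_classify(g$nb[i], g$tir[i], g$cc[i], g$lrr[i], g$lysm[i],
                    g$kinase[i], g$tm[i], strict_rlk = FALSE), character(1))
  expect_identical(got, want)
})

test_that("family labels are a fixed function of the class", {
  expect_equal(rga_family(c("CNL", "TNL", "CN", "TN", "NL", "NBS", "TX",
                            "OTHER")),
               rep("NBS-encoding", 8))
  expect_equal(rga_family(c("RLP", "RLK", "TMCC", "NONRGA")),
               c("RLP", "RLK", "TM-CC", "none"))
  expect_error(rga_family("XYZ"))
})

test_that("classify_all composes flags and tree over a whole evidence set", {
  es <- make_evidence(list(
    list("cnl", "CC", "coils", "COILS", 1L, 30L),
    list("cnl", "NB-ARC", "pfam_scan", "PF00931", 200L, 450L),
    list("cnl", "LRR", "Pfam", "PF13855", 500L, 580L),
    list("rlk", "LRR", "Pfam", "PF13855", 30L, 250L),
    list("rlk", "TM", "phobius", "TRANSMEM", 300L, 321L),
    list("rlk", "KINASE", "Pfam", "PF00069", 350L, 600L)),
    lengths = c(cnl = 600L, rlk = 650L, none = 200L))
  out <- classify_all(es)
  expect_equal(out$protein_id, c("cnl", "rlk", "none"))
  expect_equal(out$class, c("CNL", "RLK", "NONRGA"))
  expect_equal(out$family, c("NBS-encoding", "RLK", "none"))
  expect_equal(out$domains[1], "CC;NB-ARC;LRR")
  expect_equal(out$domains[3], "")

  empty <- classify_all(merge_evidence())
  expect_equal(nrow(empty), 0)
})

test_that("quick/deep divergence: Superfamily-only LRR flips NBS to NL", {
  es <- make_evidence(list(
    list("p", "NB-ARC", "pfam_scan", "PF00931", 200L, 450L),
    list("p", "LRR", "Superfamily", "SSF52058", 500L, 580L)),
    lengths = c(p = 600L))
  expect_equal(classify_all(es, rga_mode("quick"))$class, "NBS")
  expect_equal(classify_all(es, rga_mode("deep"))$class, "NL")
})

test_that("deep-mode flags are a per-protein superset of quick-mode flags", {
  set.seed(31)
  srcs <- c("Pfam", "Gene3D", "SMART", "Superfamily", "pfam_scan",
            "phobius", "coils")
  motifs <- c("NB-ARC", "TIR", "CC", "LRR", "LysM", "KINASE", "TM")
  for (rep_i in 1:20) {
    n <- sample(1:6, 1)
    triples <- lapply(seq_len(n), function(j) {
      s <- sample(srcs, 1)
      m <- if (s == "coils") "CC" else if (s == "phobius") "TM"
           else sample(motifs, 1)
      list("p", m, s, "SIG", j * 10L, j * 10L + 40L)
    })
    es <- make_evidence(triples)
    fq <- flags_from_evidence(mode_filter(es, rga_mode("quick"))$hits)
    fd <- flags_from_evidence(mode_filter(es, rga_mode("deep"))$hits)
    expect_true(all(fd[fq]))   # every quick flag survives in deep
  }
})
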