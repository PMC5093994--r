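# Independent oracles, kept deliberately separate in structure from the
# implementation they check.

# Decision-tree oracle: a nested if/else reading of the classification
# figure (branch by branch), as opposed to the implementation's flat
# ordered-rule evaluator.
oracle_classify <- function(nb, tir, cc, lrr, lysm, kinase, tm,
                            strict_rlk = TRUE) {
  if (tir) {
    if (cc) return("OTHER")
    if (nb) return(if (lrr) "TNL" else "TN")
    return("TX")
  }
  if (nb) {
    if (cc && lrr) return("CNL")
    if (cc) return("CN")
    if (lrr) return("NL")
    return("NBS")
  }
  if (tm) {
    ecto <- lrr || lysm
    if (kinase && (ecto || !strict_rlk)) return("RLK")
    if (ecto) return("RLP")
    if (cc) return("TMCC")
  }
  "NONRGA"
}

# All 128 flag combinations.
flag_grid <- function() {
  g <- expand.grid(nb = c(FALSE, TRUE), tir = c(FALSE, TRUE),
                   cc = c(FALSE, TRUE), lrr = c(FALSE, TRUE),
                   lysm = c(FALSE, TRUE), kinase = c(FALSE, TRUE),
                   tm = c(FALSE, TRUE))
  g
}

# Exhaustive window x frame enumeration of the coiled-coil score: for every
# window placement and every heptad frame compute the weighted geometric
# mean directly, then take each residue's max over covering windows.
oracle_coils_score <- function(sequence, params) {
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  L <- length(res)
  W <- params$window
  if (L < W) return(numeric(L))
  tab <- params$propensity_table
  w <- params$position_weights
  best <- rep(-Inf, L)
  for (s in seq_len(L - W + 1)) {
    for (f in 0:6) {
      num <- 0; den <- 0
      for (k in 0:(W - 1)) {
        hp <- ((f + k) %% 7) + 1
        r <- res[s + k]
        p <- if (!r %in% rownames(tab)) {
          stopifnot(r == "X"); 1
        } else tab[r, hp]
        num <- num + w[hp] * log(p)
        den <- den + w[hp]
      }
      ws <- num / den
      cover <- s:(s + W - 1)
      best[cover] <- pmax(best[cover], ws)
    }
  }
  exp(best)
}

# Toy propensity table: three informative residues (L core, E/K outer), a
# strongly anti-coil filler (G and everything else), X neutral.
toy_coils_table <- function() {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y", "X")
  m <- matrix(0.2, nrow = length(aa), ncol = 7,
              dimnames = list(aa, letters[1:7]))
  m["L", ] <- c(4.0, 0.25, 0.25, 4.0, 0.25, 0.25, 0.25)
  m["E", ] <- c(0.3, 1.2, 1.2, 0.3, 1.2, 1.2, 1.2)
  m["K", ] <- c(0.3, 1.2, 1.2, 0.3, 1.2, 1.2, 1.2)
  m["X", ] <- 1
  m
}

toy_coils_params <- function(...) {
  coils_params(propensity_table = toy_coils_table(), window = 14L,
               gaussian_cc = c(1.6, 0.08), gaussian_gl = c(0.9, 0.15),
               prob_threshold = 0.9, min_segment_len = 7L, ...)
}

# Ideal toy heptads: L at a and d, E/K outside.
toy_heptads <- function(n) strrep("LEKLEKE", n)

# Brute-force per-(chrom, bin, family) histogram used against
# distribution_table.
oracle_histogram <- function(classification, genes, bin_size,
                             id_map = strip_transcript_suffix) {
  rga <- classification[classification$class != "NONRGA", , drop = FALSE]
  counts <- list()
  seen_gene <- character(0)
  # precedence collapse, replicated longhand
  rga <- rga[order(match(rga$class, RGA_CLASSES)), , drop = FALSE]
  unplaced <- 0L
  for (i in seq_len(nrow(rga))) {
    g <- id_map(rga$protein_id[i])
    if (g %in% seen_gene) next
    seen_gene <- c(seen_gene, g)
    j <- match(g, genes$gene_id)
    if (is.na(j)) { unplaced <- unplaced + 1L; next }
    key <- paste(genes$chrom[j], floor(genes$start[j] / bin_size) * bin_size,
                 rga$family[i], sep = "\r")
    counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
  }
  list(counts = counts, unplaced = unplaced)
}

# Compare a distribution_table result against the oracle histogram.
expect_matches_histogram <- function(dist, classification, genes, bin_size) {
  oracle <- oracle_histogram(classification, genes, bin_size)
  tab <- dist$table
  keys <- paste(tab$chrom, tab$bin_start, tab$family, sep = "\r")
  expect_setequal(keys, names(oracle$counts))
  for (i in seq_len(nrow(tab)))
    expect_identical(tab$count[i], oracle$counts[[keys[i]]])
  expect_identical(dist$unplaced, oracle$unplaced)
}

# A tiny evidence set built from explicit (protein, motif, source) triples.
make_evidence <- function(triples, lengths = NULL) {
  hits <- do.call(rbind, lapply(triples, function(tr)
    domain_hits(tr[[1]], tr[[2]], tr[[3]],
                if (length(tr) >= 4) tr[[4]] else "SIG",
                if (length(tr) >= 5) tr[[5]] else 1L,
                if (length(tr) >= 6) tr[[6]] else 50L)))
  merge_evidence(hits, lengths = lengths)
}
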