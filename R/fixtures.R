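# Synthetic proteomes with planted RGA architectures, plus matched
# detector-output files in every dialect the parsers accept. The generator
# is first-class, tested code: it lets the whole pipeline run offline with
# known ground truth.

# Heptad repeat used for planted coiled-coil regions: hydrophobic L at the
# core positions a and d, charged/polar elsewhere, so the built-in scorer
# (not only the emitted segment table) can recognize them.
CC_HEPTAD <- "LEKLQEE"
TM_STRETCH <- "ILVFILVFILVFILVFILVFI"

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

# Minimal protein length that accommodates each class's domain layout.
class_min_len <- c(OTHER = 260, TNL = 600, TN = 520, TX = 260, CNL = 600,
                   CN = 520, NL = 600, NBS = 520, RLK = 650, RLP = 400,
                   TMCC = 300, NONRGA = 150)

# Domain layout archetypes: CC near the N-terminus, TIR then the central
# NB-ARC, LRRs C-terminal; for membrane classes an N-terminal ectodomain,
# a TM anchor and (RLK) an intracellular kinase toward the C-terminus.
# `channel` is the detector whose output file carries the motif.
plant_layout <- function(class, L, ecto = c("LRR", "LysM")) {
  ecto <- match.arg(ecto)
  row <- function(motif, start, end, channel)
    data.frame(motif = motif, start = as.integer(start),
               end = as.integer(end), channel = channel,
               stringsAsFactors = FALSE)
  d <- list()
  if (class %in% c("OTHER", "CNL", "CN", "TMCC"))
    d <- c(d, list(row("CC", 8, 35, "coils")))
  if (class %in% c("OTHER", "TNL", "TN", "TX"))
    d <- c(d, list(row("TIR", 50, 200, "interproscan")))
  if (class %in% c("TNL", "TN", "CNL", "CN", "NL", "NBS"))
    d <- c(d, list(row("NB-ARC", 220, 470, "pfam_scan")))
  if (class %in% c("TNL", "CNL", "NL"))
    d <- c(d, list(row("LRR", L - 110, L - 20, "interproscan")))
  if (class %in% c("RLK", "RLP"))
    d <- c(d, list(row(ecto, 30, if (ecto == "LRR") 250 else 75,
                       "interproscan")))
  if (class == "RLK")
    d <- c(d, list(row("TM", L - 330, L - 310, "phobius"),
                   row("KINASE", L - 290, L - 50, "interproscan")))
  if (class %in% c("RLP", "TMCC"))
    d <- c(d, list(row("TM", L - 80, L - 60, "phobius")))
  do.call(rbind, c(d, list(row(character(0), integer(0), integer(0),
                               character(0)))))
}

# Deterministic largest-remainder allocation of n among proportions `mix`
# (ties broken by class order).
allocate_counts <- function(n, mix) {
  raw <- n * mix
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    extra <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic proteome with planted RGA architectures
#'
#' Builds `n` proteins whose domain content realizes a chosen mix of RGA
#' classes, with gene models tiled over three synthetic chromosomes.
#' Domains are placed non-overlapping in the order of their class archetype
#' (CC near the N-terminus, NB-ARC central, LRRs C-terminal, TM near the
#' C-terminus for membrane classes); planted coiled-coil regions are
#' written as heptad repeats so the built-in scorer can also find them.
#' RLP/RLK ectodomains alternate deterministically between LRR and LysM.
#' Each planted architecture is verified at generation time to classify to
#' its planted class. Output is fully reproducible under a fixed seed.
#'
#' @param n Number of proteins, >= 1.
#' @param class_mix Named numeric vector of proportions over [RGA_CLASSES]
#'   (must sum to 1 within 1e-9; missing classes count as 0). Default:
#'   uniform over all 12 classes.
#' @param seed Integer RNG seed.
#' @param out_dir Optional directory; when given, writes `proteins.fasta`,
#'   `genes.gff3` and `truth.tsv` there.
#' @return A list of class `rga_truth`: `sequences` (named character),
#'   `truth` (one row per protein: protein_id, gene_id, class, family,
#'   length, chrom, gene_start, gene_end, strand), `domains` (planted
#'   domains: protein_id, motif, start, end, channel), and `files` (paths,
#'   when written).
#' @examples
#' tr <- generate_synthetic_set(24, seed = 42)
#' table(tr$truth$class)
#' @export
generate_synthetic_set <- function(n, class_mix = NULL, seed = 1,
                                   out_dir = NULL) {
  stopifnot(n >= 1)
  if (is.null(class_mix))
    class_mix <- stats::setNames(rep(1 / length(RGA_CLASSES),
                                     length(RGA_CLASSES)), RGA_CLASSES)
  bad <- setdiff(names(class_mix), RGA_CLASSES)
  if (length(bad) > 0)
    stop("unknown class label(s) in class_mix: ", paste(bad, collapse = ", "))
  mix <- stats::setNames(rep(0, length(RGA_CLASSES)), RGA_CLASSES)
  mix[names(class_mix)] <- class_mix
  if (abs(sum(mix) - 1) > 1e-9)
    stop("class_mix proportions must sum to 1 (got ", sum(mix), ")")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  counts <- allocate_counts(n, mix)
  classes <- rep(RGA_CLASSES, counts)

  seqs <- character(n)
  truth_rows <- vector("list", n)
  dom_rows <- vector("list", n)
  chrom_offset <- c(chr1 = 0, chr2 = 0, chr3 = 0)
  ids <- sprintf("g%05d", seq_len(n))

  for (i in seq_len(n)) {
    cls <- classes[i]
    L <- max(class_min_len[[cls]], sample(150:1500, 1))
    ecto <- if (i %% 2 == 0) "LRR" else "LysM"
    dom <- plant_layout(cls, L, ecto = ecto)

    res <- sample(AA20, L, replace = TRUE)
    for (j in seq_len(nrow(dom))) {
      if (dom$motif[j] == "CC") {
        span <- dom$start[j]:dom$end[j]
        res[span] <- strsplit(strrep(CC_HEPTAD, ceiling(length(span) / 7)),
                              "")[[1]][seq_along(span)]
      } else if (dom$motif[j] == "TM") {
        span <- dom$start[j]:dom$end[j]
        res[span] <- strsplit(strrep(TM_STRETCH, ceiling(length(span) / 21)),
                              "")[[1]][seq_along(span)]
      }
    }
    seqs[i] <- paste(res, collapse = "")

    m <- dom$motif
    got <- classify_flags(nb = "NB-ARC" %in% m, tir = "TIR" %in% m,
                          cc = "CC" %in% m, lrr = "LRR" %in% m,
                          lysm = "LysM" %in% m, kinase = "KINASE" %in% m,
                          tm = "TM" %in% m)
    if (got != cls)
      stop("internal error: planted architecture for ", cls,
           " classifies as ", got)

    chrom <- paste0("chr", (i - 1) %% 3 + 1)
    glen <- 3 * L
    gstart <- chrom_offset[[chrom]] + 1
    chrom_offset[[chrom]] <- chrom_offset[[chrom]] + glen + 5000
    pid <- paste0(ids[i], ".1")
    truth_rows[[i]] <- data.frame(
      protein_id = pid, gene_id = ids[i], class = cls,
      family = rga_family(cls), length = L, chrom = chrom,
      gene_start = gstart, gene_end = gstart + glen - 1,
      strand = if (i %% 2 == 0) "-" else "+", stringsAsFactors = FALSE)
    if (nrow(dom) > 0) {
      dom$protein_id <- pid
      dom_rows[[i]] <- dom[, c("protein_id", "motif", "start", "end",
                               "channel")]
    }
  }

  truth <- do.call(rbind, truth_rows)
  domains <- do.call(rbind, c(Filter(Negate(is.null), dom_rows),
                              list(data.frame(protein_id = character(0),
                                              motif = character(0),
                                              start = integer(0),
                                              end = integer(0),
                                              channel = character(0),
                                              stringsAsFactors = FALSE))))
  rownames(truth) <- rownames(domains) <- NULL
  names(seqs) <- truth$protein_id

  out <- structure(list(sequences = seqs, truth = truth, domains = domains,
                        files = NULL), class = "rga_truth")
  if (!is.null(out_dir)) out <- write_truth_files(out, out_dir)
  out
}

write_truth_files <- function(truth_set, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(out_dir, "proteins.fasta")
  aa <- Biostrings::AAStringSet(truth_set$sequences)
  Biostrings::writeXStringSet(aa, fa)

  gff <- file.path(out_dir, "genes.gff3")
  t <- truth_set$truth
  gene_lines <- sprintf("%s\trgascan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                        t$chrom, t$gene_start, t$gene_end, t$strand,
                        t$gene_id)
  mrna_lines <- sprintf("%s\trgascan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                        t$chrom, t$gene_start, t$gene_end, t$strand,
                        t$protein_id, t$gene_id)
  ord <- order(t$chrom, t$gene_start, method = "radix")
  writeLines(c("##gff-version 3",
               as.vector(rbind(gene_lines[ord], mrna_lines[ord]))), gff)

  tt <- file.path(out_dir, "truth.tsv")
  utils::write.table(t, tt, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_set$files <- c(fasta = fa, gff = gff, truth = tt)
  truth_set
}

# Signature emitted for each InterProScan-channel motif, per source.
ipr_signature <- function(motif, source) {
  if (motif == "LRR")
    return(switch(source, Pfam = "PF13855", SMART = "SM00369",
                  Superfamily = "SSF52058", Gene3D = "G3DSA:3.80.10.10",
                  stop("no LRR signature for source ", source)))
  switch(motif, LysM = "PF01476", KINASE = "PF00069", TIR = "PF01582",
         stop("unexpected InterProScan-channel motif ", motif))
}

#' Emit detector-output files matching a synthetic truth set
#'
#' Writes, into `out_dir`, evidence files in every dialect the parsers
#' accept, consistent with the planted domains and routed through the
#' channel each detector owns: NB-ARC rows via pfam_scan, TM spans via
#' Phobius (short format), CC segments via the 4-column coiled-coil table,
#' and LRR/LysM/kinase/TIR rows via InterProScan TSV. Every planted RGA
#' receives a qualifying BLAST hit (E-value 1e-50); planted non-RGAs
#' alternate between no hit and a weak 1e-3 hit, both far from the 1e-5
#' prefilter boundary.
#'
#' @param truth_set An `rga_truth` from [generate_synthetic_set()].
#' @param out_dir Output directory (the pipeline's `evidence_dir`).
#' @param lrr_source InterProScan member database attributed to LRR rows
#'   (`Pfam` by default; set `Superfamily` or `SMART` to produce evidence
#'   visible only in deep mode — the quick/deep NBS-vs-NL divergence).
#' @return Named vector of the five file paths, invisibly.
#' @export
emit_detector_outputs <- function(truth_set, out_dir, lrr_source = "Pfam") {
  stopifnot(inherits(truth_set, "rga_truth"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t <- truth_set$truth
  d <- truth_set$domains
  lens <- stats::setNames(t$length, t$protein_id)

  ## InterProScan TSV
  ipr <- d[d$channel == "interproscan", , drop = FALSE]
  src <- ifelse(ipr$motif == "LRR", lrr_source, "Pfam")
  sig <- mapply(ipr_signature, ipr$motif, src)
  ipr_lines <- sprintf(
    "%s\t-\t%d\t%s\t%s\t%s domain\t%d\t%d\t%s\tT\t01-01-2026",
    ipr$protein_id, lens[ipr$protein_id], src, sig, ipr$motif,
    ipr$start, ipr$end, "1.0E-20")
  ipr_path <- file.path(out_dir, "interproscan.tsv")
  writeLines(ipr_lines, ipr_path)

  ## pfam_scan (NB-ARC channel)
  pf <- d[d$channel == "pfam_scan", , drop = FALSE]
  pf_lines <- c(
    "# pfam_scan.pl,  run at fixture-generation time",
    "# <seq id> <alignment start> <alignment end> <envelope start> <envelope end> <hmm acc> <hmm name> <type> <hmm start> <hmm end> <hmm length> <bit score> <E-value> <significance> <clan>",
    sprintf("%s %6d %6d %6d %6d PF00931.23 NB-ARC Domain 1 250 250 320.5 1e-60 1 CL0023",
            pf$protein_id, pf$start, pf$end, pf$start, pf$end))
  pf_path <- file.path(out_dir, "pfamscan.txt")
  writeLines(pf_lines, pf_path)

  ## Phobius short format (TM channel); every protein gets a row
  tm <- d[d$channel == "phobius", , drop = FALSE]
  topo <- vapply(t$protein_id, function(p) {
    spans <- tm[tm$protein_id == p, , drop = FALSE]
    if (nrow(spans) == 0) return("i")
    sides <- rep(c("o", "i"), length.out = nrow(spans))
    paste0("i", paste0(spans$start, "-", spans$end, sides, collapse = ""))
  }, character(1))
  ntm <- vapply(t$protein_id,
                function(p) sum(tm$protein_id == p), integer(1))
  ph_lines <- c("SEQENCE ID                     TM SP PREDICTION",
                sprintf("%-30s %2d  0 %s", t$protein_id, ntm, topo))
  ph_path <- file.path(out_dir, "phobius.txt")
  writeLines(ph_lines, ph_path)

  ## coiled-coil segment table (CC channel)
  cc <- d[d$channel == "coils", , drop = FALSE]
  cc_path <- file.path(out_dir, "coils.tsv")
  writeLines(sprintf("%s\t%d\t%d\t0.970", cc$protein_id, cc$start, cc$end),
             cc_path)

  ## BLAST tabular (prefilter channel)
  is_rga <- t$class != "NONRGA"
  bl_lines <- character(0)
  nonrga_idx <- 0
  for (i in seq_len(nrow(t))) {
    if (is_rga[i]) {
      bl_lines <- c(bl_lines, sprintf(
        "%s\tRGADB_0001\t45.0\t210\t100\t3\t1\t210\t1\t210\t1e-50\t200",
        t$protein_id[i]))
    } else {
      nonrga_idx <- nonrga_idx + 1
      if (nonrga_idx %% 2 == 0)   # alternate: weak hit / no hit at all
        bl_lines <- c(bl_lines, sprintf(
          "%s\tRGADB_0002\t25.0\t80\t55\t2\t1\t80\t1\t80\t1e-3\t35",
          t$protein_id[i]))
    }
  }
  bl_path <- file.path(out_dir, "blast.tsv")
  writeLines(bl_lines, bl_path)

  invisible(c(interproscan = ipr_path, pfamscan = pf_path,
              phobius = ph_path, coils = cc_path, blast = bl_path))
}
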