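# Per-chromosome distribution of RGA families, the table behind
# chromosome-level distribution plots.

#' Read gene models from GFF3 or GTF
#'
#' Genes are located via `gene` features; when a file carries none (some
#' GTFs), the span of grouped transcript/exon features (by `gene_id`, or
#' GFF3 `Parent`) is used instead.
#'
#' @param path GFF3 or GTF file (format detected by `rtracklayer::import`).
#' @return A data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive genomic coordinates), `strand` (`+`, `-` or `.`).
#' @export
read_gene_models <- function(path) {
  g <- rtracklayer::import(path)
  type <- as.character(g$type)
  if (any(type == "gene")) {
    g <- g[type == "gene"]
    id <- if (!is.null(g$ID)) as.character(g$ID)
          else if (!is.null(g$gene_id)) as.character(g$gene_id)
          else as.character(seq_along(g))
    return(data.frame(gene_id = id,
                      chrom = as.character(GenomicRanges::seqnames(g)),
                      start = GenomicRanges::start(g),
                      end = GenomicRanges::end(g),
                      strand = as.character(GenomicRanges::strand(g)),
                      stringsAsFactors = FALSE))
  }
  key <- if (!is.null(g$gene_id)) as.character(g$gene_id)
         else if (!is.null(g$Parent))
           vapply(as.list(g$Parent),
                  function(p) if (length(p)) as.character(p[1]) else NA_character_,
                  character(1))
         else stop("cannot locate genes: no 'gene' features and no ",
                   "gene_id/Parent attributes in ", path)
  keep <- !is.na(key)
  g <- g[keep]; key <- key[keep]
  sp <- S4Vectors::split(g, key)
  rng <- unlist(range(sp))
  data.frame(gene_id = names(rng),
             chrom = as.character(GenomicRanges::seqnames(rng)),
             start = GenomicRanges::start(rng),
             end = GenomicRanges::end(rng),
             strand = as.character(GenomicRanges::strand(rng)),
             stringsAsFactors = FALSE)
}

#' Default protein-to-gene id mapping
#'
#' Strips one trailing transcript suffix of the form `.n` or `-n`
#' (`gene0001.1` -> `gene0001`). Pass any other function as `id_map` where
#' a different convention applies.
#'
#' @param protein_id Character vector.
#' @return Character vector of gene ids.
#' @export
strip_transcript_suffix <- function(protein_id) {
  sub("[.-][0-9]+$", "", protein_id)
}

#' Binned per-chromosome distribution of RGA families
#'
#' Counts RGA genes per (chromosome, bin, family). Proteins are collapsed to
#' genes via `id_map`; when several transcripts of one gene classify
#' differently, the gene takes the class that fires earliest in the decision
#' tree ([RGA_CLASSES] order). Non-RGA proteins are excluded. Bins are
#' half-open `[i*bin_size, (i+1)*bin_size)` over the gene start coordinate.
#'
#' RGA genes whose id cannot be resolved against `genes` are excluded from
#' the table and counted in the returned `unplaced` tally (with a warning).
#'
#' @param classification A classification table from [classify_all()] /
#'   [run_pipeline()].
#' @param genes Gene models from [read_gene_models()].
#' @param bin_size Bin width in bp. Default 1 Mb.
#' @param id_map Function mapping protein ids to gene ids; default
#'   [strip_transcript_suffix()].
#' @return A list with `table` (data.frame: `chrom`, `bin_start`, `bin_end`,
#'   `family`, `count`, sorted) and `unplaced` (number of RGA genes with no
#'   gene model).
#' @export
distribution_table <- function(classification, genes, bin_size = 1e6,
                               id_map = strip_transcript_suffix) {
  stopifnot(bin_size > 0)
  rga <- classification[classification$class != "NONRGA", , drop = FALSE]
  empty <- data.frame(chrom = character(0), bin_start = numeric(0),
                      bin_end = numeric(0), family = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
  if (nrow(rga) == 0) return(list(table = empty, unplaced = 0L))

  gene_key <- id_map(rga$protein_id)
  # transcript -> gene collapse by decision-tree precedence
  prec <- match(rga$class, RGA_CLASSES)
  ord <- order(gene_key, prec, method = "radix")
  rga <- rga[ord, , drop = FALSE]; gene_key <- gene_key[ord]
  first <- !duplicated(gene_key)
  rga <- rga[first, , drop = FALSE]; gene_key <- gene_key[first]

  gi <- match(gene_key, genes$gene_id)
  unplaced <- sum(is.na(gi))
  if (unplaced > 0)
    warning(unplaced, " RGA gene(s) not found in the gene models; ",
            "excluded from the distribution table")
  placed <- !is.na(gi)
  if (!any(placed)) return(list(table = empty, unplaced = unplaced))
  gm <- genes[gi[placed], , drop = FALSE]
  fam <- rga$family[placed]
  bin <- floor(gm$start / bin_size)
  agg <- stats::aggregate(
    list(count = rep(1L, nrow(gm))),
    by = list(chrom = gm$chrom, bin_start = bin * bin_size, family = fam),
    FUN = sum)
  agg$bin_end <- agg$bin_start + bin_size
  agg <- agg[order(agg$chrom, agg$bin_start, agg$family, method = "radix"),
             c("chrom", "bin_start", "bin_end", "family", "count")]
  rownames(agg) <- NULL
  list(table = agg, unplaced = unplaced)
}
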