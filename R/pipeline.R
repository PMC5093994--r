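# End-to-end orchestration: prefilter -> evidence acquisition -> mode
# filtering -> classification -> plain-text exports. Heavy stages operate on
# deterministic contiguous chunks of the input so results are byte-identical
# for any worker count.

EVIDENCE_FILES <- c(blast = "blast.tsv", interproscan = "interproscan.tsv",
                    pfamscan = "pfamscan.txt", phobius = "phobius.txt",
                    coils = "coils.tsv")

#' Pipeline configuration
#'
#' @param protein_fasta Protein FASTA of the proteome to analyse (required).
#' @param gff Optional companion GFF3/GTF gene annotation; enables the
#'   per-chromosome distribution table.
#' @param evalue_cutoff BLASTP prefilter E-value cutoff, > 0. Default 1e-5.
#' @param mode An [rga_mode()]; default quick.
#' @param workers Number of chunks the inputs are partitioned into, >= 1.
#'   Results are identical for any value.
#' @param output_dir Directory for the plain-text exports; `NULL` skips
#'   writing.
#' @param evidence_dir Directory of pre-computed detector outputs, named
#'   `blast.tsv`, `interproscan.tsv`, `pfamscan.txt`, `phobius.txt`,
#'   `coils.tsv` (any subset; a missing `coils.tsv` triggers the built-in
#'   coiled-coil scanner).
#' @param adapters Named list of external-tool command templates (e.g.
#'   `blastp = "blastp -query {input} -db rgadb -outfmt 6 -out {output}"`),
#'   used when the corresponding evidence file is absent.
#' @param skip_prefilter Classify every input protein, bypassing the BLASTP
#'   prefilter.
#' @param bin_size Distribution-table bin width in bp. Default 1 Mb.
#' @param strict_rlk See [classify_flags()].
#' @param coils_params Parameters for the built-in coiled-coil scanner.
#' @param signature_map A signature map; default the shipped one.
#' @param id_map Protein-to-gene id mapping function; default
#'   [strip_transcript_suffix()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(protein_fasta, gff = NULL, evalue_cutoff = 1e-5,
                            mode = rga_mode("quick"), workers = 1L,
                            output_dir = NULL, evidence_dir = NULL,
                            adapters = list(), skip_prefilter = FALSE,
                            bin_size = 1e6, strict_rlk = TRUE,
                            coils_params = rgascan::coils_params(),
                            signature_map = load_signature_map(),
                            id_map = strip_transcript_suffix) {
  stopifnot(is.numeric(evalue_cutoff), evalue_cutoff > 0,
            inherits(mode, "rga_mode"), workers >= 1)
  structure(list(protein_fasta = protein_fasta, gff = gff,
                 evalue_cutoff = evalue_cutoff, mode = mode,
                 workers = as.integer(workers), output_dir = output_dir,
                 evidence_dir = evidence_dir, adapters = adapters,
                 skip_prefilter = isTRUE(skip_prefilter),
                 bin_size = bin_size, strict_rlk = isTRUE(strict_rlk),
                 coils_params = coils_params, signature_map = signature_map,
                 id_map = id_map),
            class = "pipeline_config")
}

#' Partition ids into balanced, contiguous, order-preserving chunks
#'
#' Chunk sizes differ by at most one and concatenating the chunks
#' reproduces the input order exactly — the contract that makes chunked
#' (parallel) execution deterministic. When `k` exceeds the number of ids,
#' the surplus chunks are empty.
#'
#' @param ids Vector (usually protein ids in input order).
#' @param k Number of chunks, >= 1.
#' @return A list of `k` vectors.
#' @examples
#' lengths(chunk_inputs(letters[1:10], 3))   # 4 3 3
#' @export
chunk_inputs <- function(ids, k) {
  k <- as.integer(k)
  stopifnot(k >= 1)
  n <- length(ids)
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  lapply(seq_len(k), function(i)
    if (sizes[i] == 0) ids[0] else ids[starts[i]:ends[i]])
}

run_adapter <- function(template, input, output) {
  cmd <- gsub("{input}", input, template, fixed = TRUE)
  cmd <- gsub("{output}", output, cmd, fixed = TRUE)
  status <- system(cmd)
  if (status != 0) stop("adapter command failed (exit ", status, "): ", cmd)
  output
}

evidence_path <- function(config, channel) {
  if (is.null(config$evidence_dir)) return(NULL)
  p <- file.path(config$evidence_dir, EVIDENCE_FILES[[channel]])
  if (file.exists(p)) p else NULL
}

subset_evidence <- function(evidence, ids) {
  keep <- intersect(ids, evidence$proteins)
  hits <- evidence$hits[evidence$hits$protein_id %in% keep, , drop = FALSE]
  rownames(hits) <- NULL
  structure(list(proteins = keep, lengths = evidence$lengths[keep],
                 hits = hits), class = "evidence_set")
}

#' Run the full RGA prediction pipeline
#'
#' Executes the prefilter (unless skipped), acquires domain evidence from
#' pre-computed detector outputs in `evidence_dir` (or via configured
#' adapters; the built-in coiled-coil scanner fills in when no coiled-coil
#' segment file is supplied), applies the mode's source filter, classifies
#' every retained protein through the decision tree, and writes all
#' plain-text exports. Classification runs over [chunk_inputs()] partitions
#' merged in input order, so outputs are byte-identical for any `workers`
#' value.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `rga_result`: `classification` (one row per
#'   retained protein), `summary` ([rga_summary()]), `evidence` (the
#'   mode-unfiltered `evidence_set`), `retained` ids, `distribution`
#'   (when a GFF was supplied) and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seqs <- tryCatch(Biostrings::readAAStringSet(config$protein_fasta),
                   error = function(e)
                     stop("cannot read protein FASTA '",
                          config$protein_fasta, "': ", conditionMessage(e)))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ids <- names(seqs)
  lens <- stats::setNames(Biostrings::width(seqs), ids)

  ## 1. prefilter
  if (config$skip_prefilter) {
    retained <- ids
  } else {
    bl <- evidence_path(config, "blast")
    if (is.null(bl) && !is.null(config$adapters$blastp)) {
      bl <- tempfile(fileext = ".blast.tsv")
      run_adapter(config$adapters$blastp, config$protein_fasta, bl)
    }
    if (is.null(bl))
      stop("prefilter needs a BLAST tabular file in evidence_dir or a ",
           "blastp adapter; use skip_prefilter to classify everything")
    hits <- parse_blast_tabular(bl)
    res <- filter_candidates(hits, cutoff = config$evalue_cutoff,
                             total = length(ids))
    retained <- ids[ids %in% res$retained]  # input order
  }

  ## 2. evidence acquisition
  hit_lists <- list()
  for (channel in c("interproscan", "pfamscan", "phobius")) {
    p <- evidence_path(config, channel)
    if (is.null(p) && !is.null(config$adapters[[channel]])) {
      p <- tempfile()
      run_adapter(config$adapters[[channel]], config$protein_fasta, p)
    }
    if (is.null(p)) {
      if (!is.null(config$evidence_dir))
        warning("no ", EVIDENCE_FILES[[channel]], " in evidence_dir; ",
                "classification proceeds without that channel")
      next
    }
    hit_lists[[channel]] <- switch(channel,
      interproscan = parse_interproscan_tsv(p, map = config$signature_map),
      pfamscan = parse_pfamscan(p, map = config$signature_map),
      phobius = parse_phobius(p))
  }
  cp <- evidence_path(config, "coils")
  hit_lists$coils <- if (!is.null(cp)) parse_coils_segments(cp)
                     else scan_coils(seqs[retained], config$coils_params)

  evidence <- merge_evidence(hit_lists, lengths = lens[retained])
  evidence <- subset_evidence(evidence, retained)

  ## 3. chunked classification, merged in input order
  chunks <- chunk_inputs(retained, config$workers)
  parts <- lapply(chunks, function(chunk) {
    if (length(chunk) == 0) return(NULL)
    classify_all(subset_evidence(evidence, chunk), mode = config$mode,
                 strict_rlk = config$strict_rlk)
  })
  classification <- do.call(rbind, c(Filter(Negate(is.null), parts),
                                     list(classify_all(
                                       subset_evidence(evidence, character(0)),
                                       mode = config$mode))))
  rownames(classification) <- NULL

  ## 4. summaries and exports
  summary <- rga_summary(classification, total_input = length(ids),
                         retained = length(retained))
  dist <- NULL
  if (!is.null(config$gff)) {
    genes <- read_gene_models(config$gff)
    dist <- distribution_table(classification, genes,
                               bin_size = config$bin_size,
                               id_map = config$id_map)
  }
  result <- structure(list(classification = classification, summary = summary,
                           evidence = evidence, retained = retained,
                           distribution = dist, config = config),
                      class = "rga_result")
  if (!is.null(config$output_dir))
    export_results(result, seqs, config$output_dir)
  result
}

#' Summary counts of a classification
#'
#' @param classification A classification table from [classify_all()].
#' @param total_input Number of proteins in the input proteome.
#' @param retained Number retained by the prefilter (= number classified).
#' @return A list of class `rga_summary`: `class_counts` (all 12 labels),
#'   `family_counts` (the four RGA families plus `none`), `total_input`,
#'   `retained`.
#' @export
rga_summary <- function(classification, total_input = nrow(classification),
                        retained = nrow(classification)) {
  cls <- factor(classification$class, levels = RGA_CLASSES)
  fam <- factor(classification$family, levels = c(RGA_FAMILIES, "none"))
  structure(list(class_counts = table(cls), family_counts = table(fam),
                 total_input = total_input, retained = retained),
            class = "rga_summary")
}

#' @export
print.rga_summary <- function(x, ...) {
  cat("RGA prediction summary\n")
  cat("  input proteins:   ", x$total_input, "\n", sep = "")
  cat("  after prefilter:  ", x$retained, "\n", sep = "")
  nz <- x$class_counts[x$class_counts > 0]
  cat("  classes:          ",
      if (length(nz)) paste(names(nz), nz, sep = "=", collapse = " ")
      else "(none)", "\n", sep = "")
  fam <- x$family_counts
  cat("  families:         ",
      paste(names(fam), as.integer(fam), sep = "=", collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Export pipeline results as plain-text files
#'
#' Writes, into `out_dir`: `RGA_candidates.tsv` (all non-NONRGA proteins
#' with class, family and domain string), per-family id lists
#' (`NBS.ids.txt`, `RLP.ids.txt`, `RLK.ids.txt`, `TMCC.ids.txt`),
#' per-family FASTA subsets, the unified `domains.tsv` evidence table,
#' `summary.tsv`, and `distribution.tsv` when a GFF was supplied. All
#' outputs are tab-separated with stable column order and line endings;
#' re-running on identical inputs reproduces byte-identical files.
#'
#' @param result An `rga_result` from [run_pipeline()].
#' @param sequences The input `AAStringSet` (for the FASTA subsets).
#' @param out_dir Output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
export_results <- function(result, sequences, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  probe <- file.path(out_dir, ".write_test")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("output directory is not writable: ", out_dir)
  unlink(probe)

  cl <- result$classification
  rga <- cl[cl$class != "NONRGA", , drop = FALSE]
  utils::write.table(rga[, c("protein_id", "class", "family", "domains")],
                     file.path(out_dir, "RGA_candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  fam_files <- c("NBS-encoding" = "NBS", "RLP" = "RLP", "RLK" = "RLK",
                 "TM-CC" = "TMCC")
  for (fam in names(fam_files)) {
    ids <- rga$protein_id[rga$family == fam]
    stem <- file.path(out_dir, fam_files[[fam]])
    write_id_list(ids, paste0(stem, ".ids.txt"))
    Biostrings::writeXStringSet(sequences[intersect(names(sequences), ids)],
                                paste0(stem, ".fasta"))
  }

  write_domain_table(result$evidence, file.path(out_dir, "domains.tsv"))

  s <- result$summary
  kv <- c(total_input = s$total_input, retained = s$retained,
          stats::setNames(as.integer(s$class_counts),
                          paste0("class.", names(s$class_counts))),
          stats::setNames(as.integer(s$family_counts),
                          paste0("family.", names(s$family_counts))))
  if (!is.null(result$distribution))
    kv <- c(kv, unplaced = result$distribution$unplaced)
  writeLines(paste(names(kv), kv, sep = "\t"),
             file.path(out_dir, "summary.tsv"))

  if (!is.null(result$distribution))
    utils::write.table(result$distribution$table,
                       file.path(out_dir, "distribution.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
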