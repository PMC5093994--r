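#' Load a signature-to-motif map
#'
#' A signature map translates raw detector signatures (Pfam/SMART/Gene3D/
#' Superfamily accessions and the like) into the canonical motif vocabulary
#' ([RGA_MOTIFS]). The map is total: any signature it does not know maps to
#' `UNMAPPED`, never to an error. Two structural rules sit outside the file:
#' hits from source `coils` are always `CC`, and Phobius transmembrane spans
#' are labelled `TM` at parse time.
#'
#' @param path Path to a 3-column tab-separated file
#'   (`signature`, `motif`, `sources`), `#` comments allowed. `sources` is a
#'   comma-separated list of evidence sources the row applies to, or `"*"`
#'   for any. Defaults to the map shipped with the package.
#' @return A data.frame of class `signature_map` with columns
#'   `signature`, `motif`, `sources`.
#' @examples
#' map <- load_signature_map()
#' map_motif("PF00931.23", "Pfam", map)   # "NB-ARC"
#' map_motif("PF99999", "Pfam", map)      # "UNMAPPED"
#' @export
load_signature_map <- function(path = system.file("extdata", "signature_map.tsv",
                                                  package = "rgascan")) {
  map <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                           col.names = c("signature", "motif", "sources"),
                           colClasses = "character", quote = "",
                           stringsAsFactors = FALSE)
  bad <- setdiff(map$motif, RGA_MOTIFS)
  if (length(bad) > 0)
    stop("signature map assigns unknown motif label(s): ",
         paste(bad, collapse = ", "))
  map$signature <- toupper(map$signature)
  class(map) <- c("signature_map", class(map))
  map
}

strip_version <- function(acc) sub("\\.[0-9]+$", "", acc)

#' Map raw signature accessions to canonical motifs
#'
#' Version suffixes (`PF00931.23` -> `PF00931`) are stripped before lookup so
#' the map is Pfam-release independent; matching is case-insensitive. A
#' source-restricted row only applies to hits from the listed sources.
#'
#' @param signature Character vector of raw accessions.
#' @param source Character vector (recycled) of evidence sources.
#' @param map A `signature_map` from [load_signature_map()].
#' @return Character vector of canonical motif labels; unknown signatures map
#'   to `"UNMAPPED"`.
#' @export
map_motif <- function(signature, source, map = load_signature_map()) {
  if (length(signature) == 0) return(character(0))
  source <- rep_len(source, length(signature))
  acc <- toupper(strip_version(signature))
  motif <- rep("UNMAPPED", length(acc))
  # coils is a structural channel: every segment is a coiled coil
  motif[source == "coils"] <- "CC"
  cand <- which(acc %in% map$signature & source != "coils")
  for (i in cand) {
    rows <- which(map$signature == acc[i])
    for (r in rows) {
      ok <- identical(map$sources[r], "*") ||
        source[i] %in% strsplit(map$sources[r], ",", fixed = TRUE)[[1]]
      if (ok) {
        motif[i] <- map$motif[r]
        break
      }
    }
  }
  motif
}
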