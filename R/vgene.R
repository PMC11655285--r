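#' Read a germline V-segment reference from FASTA
#'
#' Record ids are gene names (e.g. `IGHV3-23*01`); sequences are amino-acid
#' germline V-region segments.
#'
#' @param path FASTA file path.
#' @param chain_class `"LIGHT"` or `"HEAVY"`.
#' @param species Species label of the reference.
#' @return A `v_reference`: data frame with columns `gene` and `sequence`
#'   plus attributes `chain_class` and `species`.
#' @export
read_v_reference <- function(path, chain_class, species = NA_character_) {
  aa <- Biostrings::readAAStringSet(path)
  ref <- v_reference(sub(" .*$", "", names(aa)), as.character(aa),
                     chain_class, species)
  ref
}

#' @rdname read_v_reference
#' @param genes Character vector of gene names (must be unique).
#' @param sequences Character vector of amino-acid sequences.
#' @export
v_reference <- function(genes, sequences, chain_class,
                        species = NA_character_) {
  stopifnot(length(genes) == length(sequences), !anyDuplicated(genes),
            all(nzchar(sequences)))
  structure(data.frame(gene = genes, sequence = toupper(sequences),
                       stringsAsFactors = FALSE),
            chain_class = chain_class, species = species,
            class = c("v_reference", "data.frame"))
}

#' Germline family from a V gene name
#'
#' The family is the gene-name prefix up to the first `-` or `*` (e.g.
#' `"IGHV3-23*01"` gives `"IGHV3"`). Names without a recognizable
#' `IG[HKL]V<number>` prefix map to `"other"`.
#'
#' @param gene Character vector of gene names.
#' @return Character vector of family names.
#' @export
v_gene_family <- function(gene) {
  fam <- sub("[-*].*$", "", gene)
  ok <- grepl("^IG[HKL]V[0-9]+$", fam)
  fam[!ok] <- "other"
  fam
}

#' Best-hit germline V-segment assignment
#'
#' Scores a chain against every reference entry with local (Smith-Waterman)
#' alignment and returns the highest-scoring gene; ties are broken by the
#' lexicographically smallest gene name, so the result does not depend on
#' reference order. This is a generic best-hit scorer over a user-supplied
#' germline set, not a framework-aware annotator; assignments produced by an
#' external annotation tool can be imported instead with
#' [read_v_assignments()].
#'
#' @param seqs Character vector of chain sequences.
#' @param reference A [v_reference()].
#' @param substitution_matrix Name of the substitution matrix (default
#'   `"BLOSUM62"`).
#' @param gap_opening,gap_extension Gap penalties (defaults 11 and 1).
#' @return A data frame with columns `gene`, `score` and `family`, one row
#'   per query.
#' @export
assign_v_gene <- function(seqs, reference,
                          substitution_matrix = "BLOSUM62",
                          gap_opening = 11, gap_extension = 1) {
  if (is.null(reference) || nrow(reference) == 0L)
    stop("empty V reference", call. = FALSE)
  if (any(!nzchar(seqs)))
    stop("empty query sequence", call. = FALSE)
  mat <- get(utils::data(list = substitution_matrix,
                         package = "Biostrings",
                         envir = environment()))
  out <- data.frame(gene = character(length(seqs)),
                    score = numeric(length(seqs)),
                    family = character(length(seqs)),
                    stringsAsFactors = FALSE)
  ord <- order(reference$gene)
  genes <- reference$gene[ord]
  rseqs <- reference$sequence[ord]
  for (i in seq_along(seqs)) {
    scores <- vapply(rseqs, function(rs) {
      Biostrings::pairwiseAlignment(
        Biostrings::AAString(seqs[i]), Biostrings::AAString(rs),
        type = "local", substitutionMatrix = mat,
        gapOpening = gap_opening, gapExtension = gap_extension,
        scoreOnly = TRUE)
    }, numeric(1), USE.NAMES = FALSE)
    best <- which.max(scores)  # first max over name-sorted genes = tie rule
    out$gene[i] <- genes[best]
    out$score[i] <- scores[best]
  }
  out$family <- v_gene_family(out$gene)
  out
}

#' Import best-hit assignments from an external annotation tool
#'
#' Reads a tab-separated best-hit table (columns: query id, gene name,
#' score; a header line is detected and skipped) such as a summarized
#' tabular output of a germline annotation tool, as an alternative to
#' [assign_v_gene()].
#'
#' @param path TSV file path.
#' @return A data frame with columns `query`, `gene`, `score`, `family`.
#' @export
read_v_assignments <- function(path) {
  d <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (nrow(d) > 0L && suppressWarnings(is.na(as.numeric(d[1, 3]))))
    d <- d[-1, , drop = FALSE]
  out <- data.frame(query = d[[1]], gene = d[[2]],
                    score = as.numeric(d[[3]]), stringsAsFactors = FALSE)
  out$family <- v_gene_family(out$gene)
  rownames(out) <- NULL
  out
}

#' Tally germline family frequencies over seven IGHV clusters
#'
#' Bins assignments into the seven phylogenetic IGHV families (IGHV1..IGHV7)
#' plus an `other` overflow bin and reports counts and percentages.
#'
#' @param families Character vector of family names (e.g. the `family`
#'   column of [assign_v_gene()]).
#' @param bins Bin names (default `IGHV1`..`IGHV7`).
#' @return A data frame with columns `family`, `count`, `percent` (percent
#'   of total; 0 when the input is empty) and attribute `total`.
#' @export
tally_cluster_frequencies <- function(families,
                                      bins = paste0("IGHV", 1:7)) {
  fam <- ifelse(families %in% bins, families, "other")
  lv <- c(bins, "other")
  counts <- as.integer(table(factor(fam, levels = lv)))
  total <- length(fam)
  pct <- if (total > 0L) 100 * counts / total else rep(0, length(lv))
  structure(data.frame(family = lv, count = counts, percent = pct,
                       stringsAsFactors = FALSE),
            total = total)
}

#' Annotate a collection with V-segment assignments
#'
#' Adds `v_light`/`v_heavy` (gene names) and `v_light_family`/
#' `v_heavy_family` columns; existing columns are untouched and
#' re-annotation overwrites identically.
#'
#' @param pairs A pair table or record table with `light_seq`/`heavy_seq`.
#' @param light_reference,heavy_reference [v_reference()] objects for each
#'   chain class present.
#' @param ... Passed to [assign_v_gene()].
#' @return `pairs` with the four annotation columns added.
#' @export
annotate_collection <- function(pairs, light_reference, heavy_reference,
                                ...) {
  if (nrow(pairs) == 0L) {
    pairs$v_light <- character(0); pairs$v_heavy <- character(0)
    pairs$v_light_family <- character(0)
    pairs$v_heavy_family <- character(0)
    return(pairs)
  }
  if (is.null(light_reference) || is.null(heavy_reference))
    stop("a V reference is required for each chain class present",
         call. = FALSE)
  al <- assign_v_gene(pairs$light_seq, light_reference, ...)
  ah <- assign_v_gene(pairs$heavy_seq, heavy_reference, ...)
  pairs$v_light <- al$gene
  pairs$v_heavy <- ah$gene
  pairs$v_light_family <- al$family
  pairs$v_heavy_family <- ah$family
  pairs
}
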