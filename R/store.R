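#' Stable content-derived antibody identifier
#'
#' The identifier is the SHA-256 hex digest of a canonical string built from
#' the species and the two chain sequences. The canonical form joins the
#' three fields with `"|"` (UTF-8), which keeps distinct field splits from
#' colliding; `legacy_concat = TRUE` reproduces bare concatenation without a
#' separator instead.
#'
#' @param species Character vector of species names.
#' @param light_seq,heavy_seq Character vectors of uppercase chain
#'   sequences.
#' @param legacy_concat Use bare concatenation (no separator).
#' @return Character vector of 64-character lowercase hex ids.
#' @export
#' @examples
#' antibody_id("Homo sapiens", "DIQMTQSP", "EVQLVESG")
antibody_id <- function(species, light_seq, heavy_seq,
                        legacy_concat = FALSE) {
  if (any(!nzchar(species)) || any(!nzchar(light_seq)) ||
      any(!nzchar(heavy_seq)))
    stop("species and both sequences must be non-empty", call. = FALSE)
  canon <- if (legacy_concat)
    paste0(species, toupper(light_seq), toupper(heavy_seq))
  else
    paste(species, toupper(light_seq), toupper(heavy_seq), sep = "|")
  vapply(canon, function(x)
    digest::digest(x, algo = "sha256", serialize = FALSE),
    character(1), USE.NAMES = FALSE)
}

pair_identity <- function(pairs) {
  antibody_id(pairs$species, pairs$light_seq, pairs$heavy_seq)
}

#' Finalize a merged collection into identified records
#'
#' Attaches the SHA-256 id to every pair, verifies id uniqueness (a
#' duplicate id would mean the merge stage failed to deduplicate) and sorts
#' the collection by id for canonical, diff-stable output.
#'
#' @param pairs A merge-form pair table (see [merge_collections()]).
#' @param legacy_concat Passed to [antibody_id()].
#' @return A record table: `id`, `species`, `light_seq`, `heavy_seq`,
#'   `light_header`, `heavy_header`, `sources` (list column, sorted tags)
#'   and any annotation columns, sorted by `id`.
#' @export
finalize_records <- function(pairs, legacy_concat = FALSE) {
  if (nrow(pairs) == 0L) {
    out <- cbind(data.frame(id = character(0)), pairs)
    return(out)
  }
  id <- antibody_id(pairs$species, pairs$light_seq, pairs$heavy_seq,
                    legacy_concat = legacy_concat)
  if (anyDuplicated(id))
    stop("duplicate antibody id in final collection; ",
         "merge-stage uniqueness violated", call. = FALSE)
  out <- cbind(data.frame(id = id, stringsAsFactors = FALSE), pairs)
  if (is.null(out$sources)) out$sources <- I(pair_sources(pairs))
  out$sources <- I(lapply(out$sources, function(s) sort(unique(s))))
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collection statistics
#'
#' @param records A record table (see [finalize_records()]).
#' @return A list: `antibody_count`, `sequence_count` (exactly twice the
#'   antibody count), `unique_sequence_count` (distinct chain strings across
#'   both sides), `per_species` and `per_source` (named integer vectors;
#'   a multi-source antibody counts once per source).
#' @export
collection_stats <- function(records) {
  n <- nrow(records)
  chains <- c(records$light_seq, records$heavy_seq)
  per_species <- if (n > 0L) {
    tab <- table(records$species)
    stats::setNames(as.integer(tab), names(tab))
  } else integer(0)
  srcs <- if (n > 0L && !is.null(records$sources)) unlist(records$sources)
          else character(0)
  per_source <- if (length(srcs)) {
    tab <- table(srcs)
    stats::setNames(as.integer(tab), names(tab))
  } else integer(0)
  list(antibody_count = n,
       sequence_count = 2L * n,
       unique_sequence_count = length(unique(chains)),
       per_species = per_species,
       per_source = per_source)
}

#' Export a collection
#'
#' `"jsonl"` writes one JSON record per line (round-trips with
#' [read_jsonl()]); `"paired-fasta"` writes two index-synchronized FASTA
#' files with the record id as first header token on both sides.
#'
#' @param records A record table (see [finalize_records()]).
#' @param path Output path; for `"paired-fasta"` the stem, producing
#'   `<stem>_light.fasta` and `<stem>_heavy.fasta`.
#' @param format `"jsonl"` or `"paired-fasta"`.
#' @return The written path(s), invisibly.
#' @export
export_collection <- function(records, path, format = c("jsonl",
                                                        "paired-fasta")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    cols <- intersect(c("id", "species", "light_seq", "heavy_seq",
                        "light_header", "heavy_header", "sources",
                        "v_light", "v_heavy", "v_light_family",
                        "v_heavy_family"), names(records))
    write_jsonl(records[, cols, drop = FALSE], path)
    invisible(path)
  } else {
    lp <- paste0(path, "_light.fasta")
    hp <- paste0(path, "_heavy.fasta")
    write_paired_fasta(records, lp, hp)
    invisible(c(lp, hp))
  }
}
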