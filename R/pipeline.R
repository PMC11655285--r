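#' Build a non-redundant collection from per-source records
#'
#' End-to-end driver chaining every stage: per source and species,
#' [ingest_source()] (species filter, chain classification, grouping,
#' containment pruning), [pair_all()] (four-strategy pairing cascade) and
#' [standardize_pairs()] (label correction, variable-region trimming, length
#' filter); then [merge_collections()] across sources (containment
#' deduplication, longest-common-substring resolution, ambiguity clustering,
#' cross-species removal), optional V-segment annotation, and
#' [finalize_records()] (SHA-256 ids, canonical order).
#'
#' @param sources Named list mapping a source tag to a record table (from
#'   [parse_source_fasta()]) or to a FASTA file path.
#' @param species Character vector of species to extract (each must be
#'   configured in `config$species_keywords`).
#' @param config A [keyword_config()].
#' @param patterns A [pattern_set()].
#' @param bounds A [length_bounds()].
#' @param reference Optional reference pair set for pairing strategy S3
#'   (data frame with `light_seq`, `heavy_seq`).
#' @param decisions Optional decisions table for pairing strategy S4 (see
#'   [read_decisions()]).
#' @param light_reference,heavy_reference Optional [v_reference()] objects;
#'   when both are given the final collection is annotated with best-hit
#'   V-segment assignments.
#' @param legacy_concat Passed to [antibody_id()].
#' @return A list with:
#'   `records` (final identified collection), `clusters` (ambiguous-pair
#'   tables), `report` (merge accounting), `stats` ([collection_stats()]),
#'   `strategy_counts` (summed over sources), `pairings` (per-source pair
#'   tables with strategy attribution), `unpaired`, `ingest_reports`,
#'   `outcomes` (standardization outcome log),
#'   `cross_species_removed`.
#' @export
build_collection <- function(sources, species, config = keyword_config(),
                             patterns = pattern_set(),
                             bounds = length_bounds(),
                             reference = NULL, decisions = NULL,
                             light_reference = NULL, heavy_reference = NULL,
                             legacy_concat = FALSE) {
  stopifnot(length(sources) > 0L, !is.null(names(sources)),
            all(nzchar(names(sources))))
  merge_input <- list()
  pairings <- list()
  ingest_reports <- list()
  outcomes <- list()
  unpaired <- list()
  strategy_counts <- c(S1 = 0L, S2 = 0L, S3 = 0L, S4 = 0L)
  for (tag in names(sources)) {
    recs <- sources[[tag]]
    if (is.character(recs))
      recs <- parse_source_fasta(recs, source_tag = tag)
    for (sp in species) {
      ing <- ingest_source(recs, sp, config)
      pr <- pair_all(ing$groups, config, reference = reference,
                     decisions = decisions, species = sp)
      std <- standardize_pairs(pr$pairs, patterns, bounds)
      key <- paste0(tag, "/", sp)
      ingest_reports[[key]] <- ing$report
      pairings[[key]] <- pr$pairs
      outcomes[[key]] <- std$outcomes
      unpaired[[key]] <- pr$unpaired
      strategy_counts <- strategy_counts + pr$strategy_counts
      if (nrow(std$pairs) > 0L)
        merge_input[[key]] <- prepare_for_merge(std$pairs, tag)
    }
  }
  if (length(merge_input) == 0L) {
    empty <- prepare_for_merge(
      cbind(empty_pairs(), data.frame(species = character(0))), "none")
    mg <- list(pairs = empty, clusters = list(),
               cross_species_removed = empty,
               report = c(input_count = 0L, duplicates_collapsed = 0L,
                          ambiguous_pair_count = 0L, cluster_count = 0L,
                          cross_species_removed = 0L, retained_count = 0L))
  } else {
    mg <- merge_collections(merge_input, patterns, bounds)
  }
  final <- mg$pairs
  if (!is.null(light_reference) && !is.null(heavy_reference))
    final <- annotate_collection(final, light_reference, heavy_reference)
  records <- finalize_records(final, legacy_concat = legacy_concat)
  list(records = records,
       clusters = mg$clusters,
       report = mg$report,
       stats = collection_stats(records),
       strategy_counts = strategy_counts,
       pairings = pairings,
       unpaired = do.call(rbind, c(unpaired, list(make.row.names = FALSE))),
       ingest_reports = ingest_reports,
       outcomes = do.call(rbind, c(outcomes, list(make.row.names = FALSE))),
       cross_species_removed = mg$cross_species_removed)
}

#' Run the pipeline on a generated fixture
#'
#' Convenience wrapper: builds the collection from a [generate_fixture()]
#' result using the fixture's own reference pairs and decisions.
#'
#' @param fixture A [generate_fixture()] result.
#' @param ... Passed on to [build_collection()].
#' @return As [build_collection()].
#' @export
build_fixture_collection <- function(fixture, ...) {
  sources <- lapply(fixture$sources, function(df) {
    out <- parse_header_fields(df$raw_header)
    out$sequence <- df$sequence
    out
  })
  for (tag in names(sources)) sources[[tag]]$source_tag <- tag
  species <- unique(fixture$truth$retained$species)
  if (length(species) == 0L)
    species <- names(fixture$truth$config$species_mix)
  build_collection(sources, species = species,
                   reference = fixture$reference,
                   decisions = fixture$decisions, ...)
}

pair_key <- function(species, light, heavy) {
  paste(species, light, heavy, sep = "\r")
}

#' Check pipeline output against fixture ground truth
#'
#' Compares the retained pair set (species, both chains, source sets),
#' the ambiguity clusters (as sets of chain pairs), the planted discards
#' (by reason), and the per-strategy group attribution.
#'
#' @param result A [build_collection()] result.
#' @param truth The `truth` element of a [generate_fixture()] result.
#' @return A list with `ok` (logical) and `mismatches` (character vector
#'   describing every disagreement; empty when `ok`).
#' @export
verify_against_truth <- function(result, truth) {
  mism <- character(0)
  got <- pair_key(result$records$species, result$records$light_seq,
                  result$records$heavy_seq)
  want <- pair_key(truth$retained$species, truth$retained$light_seq,
                   truth$retained$heavy_seq)
  for (k in setdiff(want, got))
    mism <- c(mism, paste0("missing retained pair: ",
                           substr(gsub("\r", " | ", k), 1, 60), "..."))
  for (k in setdiff(got, want))
    mism <- c(mism, paste0("unexpected retained pair: ",
                           substr(gsub("\r", " | ", k), 1, 60), "..."))
  common <- intersect(want, got)
  src_want <- truth$retained$sources[match(common, want)]
  src_got <- result$records$sources[match(common, got)]
  for (i in seq_along(common)) {
    if (!setequal(src_want[[i]], src_got[[i]]))
      mism <- c(mism, paste0("source set mismatch for a retained pair: ",
                             "expected {",
                             paste(src_want[[i]], collapse = ","),
                             "} got {",
                             paste(src_got[[i]], collapse = ","), "}"))
  }
  canon_cluster <- function(cl)
    paste(sort(pair_key(cl$species, cl$light_seq, cl$heavy_seq)),
          collapse = "\n")
  want_cl <- sort(vapply(truth$clusters, canon_cluster, character(1)))
  got_cl <- sort(vapply(result$clusters, canon_cluster, character(1)))
  if (!identical(want_cl, got_cl))
    mism <- c(mism, paste0("cluster sets differ: expected ",
                           length(want_cl), " cluster(s), got ",
                           length(got_cl),
                           "; memberships match = ",
                           setequal(want_cl, got_cl)))
  # discards: every planted discard must appear with the matching reason
  disc <- truth$discards
  for (i in seq_len(nrow(disc))) {
    hdr <- disc$raw_header[i]; why <- disc$reason[i]
    found <- switch(
      why,
      "irrelevant keyword" = ,
      "no chain keyword" = ,
      "contained" = {
        rep <- do.call(rbind, c(result$ingest_reports,
                                list(make.row.names = FALSE)))
        any(rep$raw_header == hdr &
              startsWith(rep$reason, substr(why, 1, 9)))
      },
      "unpaired" = {
        gid <- sub("_.*$", "", sub("\\|.*$", "", hdr))
        any(result$unpaired$group_id == gid)
      },
      "DISCARDED_LENGTH" = {
        gid <- sub("_\\*$", "", hdr)
        any(result$outcomes$group_id == gid &
              result$outcomes$action == "DISCARDED_LENGTH")
      },
      "DISCARDED_NO_PATTERN" = {
        gid <- sub("_\\*$", "", hdr)
        any(result$outcomes$group_id == gid &
              result$outcomes$action == "DISCARDED_NO_PATTERN")
      },
      FALSE)
    if (!isTRUE(found))
      mism <- c(mism, paste0("planted discard not reported (", why, "): ",
                             hdr))
  }
  # strategy attribution per group
  all_pairs <- do.call(rbind, c(result$pairings,
                                list(make.row.names = FALSE)))
  for (s in names(truth$strategy_groups)) {
    for (gid in truth$strategy_groups[[s]]) {
      att <- unique(all_pairs$strategy[all_pairs$group_id == gid])
      if (!identical(att, s))
        mism <- c(mism, paste0("group ", gid, ": expected strategy ", s,
                               ", attributed ",
                               paste(att, collapse = "/")))
    }
  }
  list(ok = length(mism) == 0L, mismatches = mism)
}
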