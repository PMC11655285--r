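#' Longest common substring of a set of sequences
#'
#' The longest string occurring contiguously in every input. Ties are broken
#' by the earliest occurrence in the shortest input. Returns `""` when the
#' inputs share no common substring.
#'
#' @param seqs Character vector (length >= 1).
#' @return A single string.
#' @export
#' @examples
#' longest_common_substring(c("AWIDPEIB", "AWIDEIB"))
longest_common_substring <- function(seqs) {
  stopifnot(length(seqs) >= 1L)
  if (length(seqs) == 1L) return(seqs)
  s0 <- seqs[which.min(nchar(seqs))]
  others <- seqs[-which.min(nchar(seqs))]
  n0 <- nchar(s0)
  for (len in seq.int(n0, 1L)) {
    for (start in seq_len(n0 - len + 1L)) {
      cand <- substr(s0, start, start + len - 1L)
      if (all(vapply(others, grepl, logical(1), pattern = cand,
                     fixed = TRUE, USE.NAMES = FALSE)))
        return(cand)
    }
  }
  ""
}

#' Merge sequence variants that diverge only at their termini
#'
#' Databases sometimes hold near-identical chains that differ only in a few
#' terminal residues (e.g. alternative J-segment ends). Such variants are
#' reconciled by taking the longest common substring (LCS) of the set: the
#' merge succeeds iff every variant equals `prefix + LCS + suffix` with both
#' the prefix and suffix at most `max_trim` residues, i.e. the divergence is
#' strictly terminal. Internal divergence (an insertion or deletion in the
#' middle) makes the LCS lose one whole flank and the merge fails.
#'
#' @param variants Character vector of sequence variants.
#' @param max_trim Maximum number of terminal residues a variant may carry
#'   beyond the LCS (default 10); prevents merging barely-related chains.
#' @return The merged sequence (the LCS), or `NA_character_` when the
#'   divergence is not terminal. A single variant is returned unchanged.
#' @export
#' @examples
#' resolve_terminal_divergence(c("DIQMABCVTVSS", "DIQMABCVTVVS"))
#' resolve_terminal_divergence(c("AWIDPEIB", "AWIDEIB"))  # internal: NA
resolve_terminal_divergence <- function(variants, max_trim = 10L) {
  variants <- unique(variants)
  if (length(variants) == 1L) return(variants)
  lcs <- longest_common_substring(variants)
  if (nchar(lcs) == 0L) return(NA_character_)
  ok <- vapply(variants, function(v) {
    hits <- gregexpr(lcs, v, fixed = TRUE)[[1]]
    if (hits[1] < 0L) return(FALSE)
    any(vapply(as.integer(hits), function(p) {
      (p - 1L) <= max_trim &&
        (nchar(v) - (p + nchar(lcs) - 1L)) <= max_trim
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  if (all(ok)) lcs else NA_character_
}

#' Attach provenance and convert standardized pairs to merge form
#'
#' Serializes each raw chain header with the source tag (see
#' [serialize_merged_header()]) and initializes the per-pair `sources` list.
#'
#' @param pairs A standardized pair table (from [standardize_pairs()]).
#' @param source_tag Provenance label of the source the pairs came from.
#' @return A merge-form pair table: `species`, `light_seq`, `heavy_seq`,
#'   `light_header`, `heavy_header` (serialized), `sources` (list column).
#' @export
prepare_for_merge <- function(pairs, source_tag) {
  out <- data.frame(
    species = pairs$species,
    light_seq = pairs$light_seq, heavy_seq = pairs$heavy_seq,
    light_header = vapply(pairs$light_header, serialize_merged_header,
                          character(1), source_tags = source_tag,
                          USE.NAMES = FALSE),
    heavy_header = vapply(pairs$heavy_header, serialize_merged_header,
                          character(1), source_tags = source_tag,
                          USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  out$sources <- I(rep(list(source_tag), nrow(pairs)))
  out
}

pair_sources <- function(pairs) {
  mapply(function(lh, hh) {
    unique(c(parse_merged_header(lh)$source_tag,
             parse_merged_header(hh)$source_tag))
  }, pairs$light_header, pairs$heavy_header,
  SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Merge two antibody pairs related by sequence containment
#'
#' Two pairs of the same species are mergeable iff on *both* sides the
#' sequences are equal or one contains the other; the merged pair keeps the
#' longer sequence of each side, concatenates the provenance headers
#' (A then B) and unions the source sets. Pairs whose chains differ
#' internally on either side are not mergeable.
#'
#' @param a,b Single-row merge-form pair tables (see [prepare_for_merge()]).
#' @return The merged single-row pair table, or `NULL` when not mergeable.
#' @export
merge_two_pairs <- function(a, b) {
  if (a$species != b$species) return(NULL)
  if (!seq_related(a$light_seq, b$light_seq)) return(NULL)
  if (!seq_related(a$heavy_seq, b$heavy_seq)) return(NULL)
  out <- a
  if (nchar(b$light_seq) > nchar(a$light_seq)) out$light_seq <- b$light_seq
  if (nchar(b$heavy_seq) > nchar(a$heavy_seq)) out$heavy_seq <- b$heavy_seq
  out$light_header <- paste(a$light_header, b$light_header, sep = "|||")
  out$heavy_header <- paste(a$heavy_header, b$heavy_header, sep = "|||")
  out$sources <- I(list(unique(c(a$sources[[1]], b$sources[[1]]))))
  out
}

#' Gather chain-sharing pairs into ambiguity clusters
#'
#' Builds an undirected graph with antibody pairs as nodes and an edge
#' whenever two pairs of the same species share an identical chain sequence
#' (on any side); with `containment_edges = TRUE`, same-side containment
#' also creates an edge. Connected components of two or more pairs are
#' clusters of ambiguous antibodies (the true pairing cannot be decided
#' automatically) and are excluded from the collection; singletons are
#' retained.
#'
#' @param pairs A merge-form pair table.
#' @param containment_edges Also link pairs whose same-side sequences are in
#'   a containment relation (default `FALSE`).
#' @return A list with `retained` (singleton pairs), `clusters` (list of
#'   pair tables, each one cluster) and `membership` (integer vector: 0 for
#'   retained, else cluster index).
#' @export
build_ambiguity_clusters <- function(pairs, containment_edges = FALSE) {
  n <- nrow(pairs)
  if (n == 0L)
    return(list(retained = pairs, clusters = list(),
                membership = integer(0)))
  edges <- integer(0)
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq.int(i + 1L, n)) {
      if (pairs$species[i] != pairs$species[j]) next
      share <-
        pairs$light_seq[i] == pairs$light_seq[j] ||
        pairs$heavy_seq[i] == pairs$heavy_seq[j] ||
        pairs$light_seq[i] == pairs$heavy_seq[j] ||
        pairs$heavy_seq[i] == pairs$light_seq[j]
      if (!share && containment_edges) {
        share <- seq_related(pairs$light_seq[i], pairs$light_seq[j]) ||
          seq_related(pairs$heavy_seq[i], pairs$heavy_seq[j])
      }
      if (share) edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges) > 0L) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  sizes <- comp$csize[comp$membership]
  amb_comp <- sort(unique(comp$membership[sizes >= 2L]))
  membership <- integer(n)
  clusters <- vector("list", length(amb_comp))
  for (k in seq_along(amb_comp)) {
    idx <- which(comp$membership == amb_comp[k])
    membership[idx] <- k
    cl <- pairs[idx, , drop = FALSE]
    rownames(cl) <- NULL
    clusters[[k]] <- cl
  }
  retained <- pairs[membership == 0L, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, clusters = clusters, membership = membership)
}

#' Remove chain sequences duplicated across species
#'
#' A chain sequence occurring in antibodies of two different species (e.g. a
#' humanized antibody deposited under both the mouse and the human entry)
#' cannot be attributed; every antibody containing such a sequence is
#' removed, in every species.
#'
#' @param pairs A merge-form pair table (any mix of species).
#' @return A list with `retained`, `removed` (pair tables) and
#'   `offending_sequences` (character vector).
#' @export
remove_cross_species_duplicates <- function(pairs) {
  n <- nrow(pairs)
  if (n == 0L)
    return(list(retained = pairs, removed = pairs[0, , drop = FALSE],
                offending_sequences = character(0)))
  chains <- data.frame(
    seq = c(pairs$light_seq, pairs$heavy_seq),
    species = rep(pairs$species, 2L), stringsAsFactors = FALSE)
  nsp <- tapply(chains$species, chains$seq,
                function(s) length(unique(s)))
  offending <- names(nsp)[nsp >= 2L]
  hit <- pairs$light_seq %in% offending | pairs$heavy_seq %in% offending
  retained <- pairs[!hit, , drop = FALSE]
  removed <- pairs[hit, , drop = FALSE]
  rownames(retained) <- rownames(removed) <- NULL
  list(retained = retained, removed = removed,
       offending_sequences = offending)
}

containment_fixed_point <- function(pairs) {
  # exhaustive pairwise containment merging until no merge fires
  absorbed <- 0L
  repeat {
    n <- nrow(pairs)
    merged_any <- FALSE
    i <- 1L
    while (i < nrow(pairs)) {
      j <- i + 1L
      while (j <= nrow(pairs)) {
        m <- merge_two_pairs(pairs[i, , drop = FALSE],
                             pairs[j, , drop = FALSE])
        if (!is.null(m)) {
          for (cn in c("species", "light_seq", "heavy_seq",
                       "light_header", "heavy_header"))
            pairs[[cn]][i] <- m[[cn]]
          pairs$sources[[i]] <- m$sources[[1]]
          pairs <- pairs[-j, , drop = FALSE]
          absorbed <- absorbed + 1L
          merged_any <- TRUE
        } else {
          j <- j + 1L
        }
      }
      i <- i + 1L
    }
    if (!merged_any) break
  }
  rownames(pairs) <- NULL
  list(pairs = pairs, absorbed = absorbed)
}

merge_component <- function(cl, patterns, bounds, max_trim) {
  # attempt terminal-divergence resolution of one chain-sharing component
  ml <- resolve_terminal_divergence(unique(cl$light_seq), max_trim)
  mh <- resolve_terminal_divergence(unique(cl$heavy_seq), max_trim)
  if (is.na(ml) || is.na(mh)) return(NULL)
  lt <- trim_to_variable_region(ml, "LIGHT", patterns)
  ht <- trim_to_variable_region(mh, "HEAVY", patterns)
  if (is.na(lt) || is.na(ht)) return(NULL)
  cand <- data.frame(species = cl$species[1], light_seq = lt,
                     heavy_seq = ht, stringsAsFactors = FALSE)
  if (!length_filter(cand, bounds)) return(NULL)
  out <- cl[1, , drop = FALSE]
  out$light_seq <- lt
  out$heavy_seq <- ht
  out$light_header <- paste(cl$light_header, collapse = "|||")
  out$heavy_header <- paste(cl$heavy_header, collapse = "|||")
  out$sources <- I(list(unique(unlist(cl$sources))))
  rownames(out) <- NULL
  out
}

#' Merge per-source collections into one non-redundant collection
#'
#' The merge runs in four stages, per species:
#' 1. exhaustive pairwise containment merging to a fixed point
#'    ([merge_two_pairs()]);
#' 2. chain-sharing components (identical or contained chains on one side)
#'    are resolved by longest-common-substring merging of their variants
#'    ([resolve_terminal_divergence()]); a merged antibody must re-pass
#'    standardization (trimming and length bounds) to be retained;
#' 3. components that cannot be resolved become ambiguity clusters and are
#'    excluded ([build_ambiguity_clusters()] semantics);
#' 4. chain sequences shared across species cause removal of every antibody
#'    containing them ([remove_cross_species_duplicates()]).
#'
#' @param pairs A merge-form pair table pooling every source (rbind of
#'   [prepare_for_merge()] outputs), or a list of such tables.
#' @param patterns A [pattern_set()] for re-standardizing LCS-merged chains.
#' @param bounds A [length_bounds()].
#' @param max_trim Terminal-trim cap for LCS resolution (default 10).
#' @return A list with `pairs` (the final collection), `clusters` (list of
#'   ambiguous-pair tables), `cross_species_removed` (pair table) and
#'   `report` (named integer vector: `input_count`, `duplicates_collapsed`,
#'   `ambiguous_pair_count`, `cluster_count`, `cross_species_removed`,
#'   `retained_count`; the accounting balances exactly).
#' @export
merge_collections <- function(pairs, patterns = pattern_set(),
                              bounds = length_bounds(), max_trim = 10L) {
  if (is.data.frame(pairs)) pairs <- list(pairs)
  pool <- do.call(rbind, pairs)
  rownames(pool) <- NULL
  n_in <- nrow(pool)
  collapsed <- 0L
  retained <- pool[0, , drop = FALSE]
  clusters <- list()
  for (sp in unique(pool$species)) {
    sub <- pool[pool$species == sp, , drop = FALSE]
    fp <- containment_fixed_point(sub)
    collapsed <- collapsed + fp$absorbed
    cc <- build_ambiguity_clusters(fp$pairs, containment_edges = TRUE)
    retained <- rbind(retained, cc$retained)
    for (cl in cc$clusters) {
      m <- merge_component(cl, patterns, bounds, max_trim)
      if (!is.null(m)) {
        collapsed <- collapsed + nrow(cl) - 1L
        retained <- rbind(retained, m)
      } else {
        clusters[[length(clusters) + 1L]] <- cl
      }
    }
  }
  cs <- remove_cross_species_duplicates(retained)
  retained <- cs$retained
  rownames(retained) <- NULL
  amb <- if (length(clusters)) sum(vapply(clusters, nrow, integer(1)))
         else 0L
  report <- c(input_count = n_in,
              duplicates_collapsed = collapsed,
              ambiguous_pair_count = amb,
              cluster_count = length(clusters),
              cross_species_removed = nrow(cs$removed),
              retained_count = nrow(retained))
  stopifnot(report[["input_count"]] ==
              report[["retained_count"]] + report[["duplicates_collapsed"]] +
              report[["ambiguous_pair_count"]] +
              report[["cross_species_removed"]])
  list(pairs = retained, clusters = clusters,
       cross_species_removed = cs$removed, report = report)
}
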