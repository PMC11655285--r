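motif_occurrences <- function(seq, motifs) {
  # start positions of every occurrence of every motif
  unlist(lapply(motifs, function(m) {
    hits <- gregexpr(m, seq, fixed = TRUE)[[1]]
    if (hits[1] < 0L) integer(0) else as.integer(hits)
  }), use.names = FALSE)
}

start_evidence <- function(seq, patterns) {
  # which chain classes have a start motif occurring in the sequence
  c(LIGHT = length(motif_occurrences(seq, patterns$light_starts)) > 0L,
    HEAVY = length(motif_occurrences(seq, patterns$heavy_starts)) > 0L)
}

#' Correct swapped light/heavy labels on a pair
#'
#' Headers occasionally annotate the light chain as heavy and vice versa.
#' The slots of a pair are exchanged only on both-sided sequence evidence:
#' the light-slot sequence contains heavy start motifs and no light start
#' motif, while the heavy-slot sequence contains light start motifs and no
#' heavy start motif. One-sided or mixed evidence leaves the pair unchanged
#' (with a warning), so that a single spurious motif never flips a pair.
#'
#' @param pairs A pair table (from [pair_all()]).
#' @param patterns A [pattern_set()].
#' @return The pair table with slots exchanged where warranted and a logical
#'   `swapped` column recording the corrections.
#' @export
correct_swapped_labels <- function(pairs, patterns) {
  stopifnot(inherits(patterns, "pattern_set"))
  n <- nrow(pairs)
  pairs$swapped <- rep(FALSE, n)
  for (i in seq_len(n)) {
    le <- start_evidence(pairs$light_seq[i], patterns)
    he <- start_evidence(pairs$heavy_seq[i], patterns)
    if (le[["HEAVY"]] && !le[["LIGHT"]] && he[["LIGHT"]] && !he[["HEAVY"]]) {
      tmp_seq <- pairs$light_seq[i]
      pairs$light_seq[i] <- pairs$heavy_seq[i]
      pairs$heavy_seq[i] <- tmp_seq
      tmp_h <- pairs$light_header[i]
      pairs$light_header[i] <- pairs$heavy_header[i]
      pairs$heavy_header[i] <- tmp_h
      if (!is.null(pairs$light_member)) {
        tmp_m <- pairs$light_member[i]
        pairs$light_member[i] <- pairs$heavy_member[i]
        pairs$heavy_member[i] <- tmp_m
      }
      pairs$swapped[i] <- TRUE
    } else if (xor(le[["HEAVY"]] && !le[["LIGHT"]],
                   he[["LIGHT"]] && !he[["HEAVY"]])) {
      warning("one-sided label-swap evidence for pair ",
              pairs$group_id[i], "; left unchanged", call. = FALSE)
    }
  }
  pairs
}

#' Trim a chain to its variable region
#'
#' Among all substrings that begin at an occurrence of a start motif of the
#' chain's class and end at the final residue of an occurrence of an end
#' motif of that class, returns the longest (ties broken by leftmost start).
#' Returns `NA` when no start motif precedes an end motif, which both
#' standardizes records to the variable region and weeds out records that
#' are not antibody chains at all.
#'
#' @param seq Character vector of uppercase amino-acid sequences.
#' @param chain_class `"LIGHT"` or `"HEAVY"`.
#' @param patterns A [pattern_set()].
#' @return Character vector of trimmed sequences (`NA` where no motif-bounded
#'   region exists).
#' @export
trim_to_variable_region <- function(seq, chain_class, patterns) {
  stopifnot(inherits(patterns, "pattern_set"),
            chain_class %in% c("LIGHT", "HEAVY"))
  starts_m <- if (chain_class == "LIGHT") patterns$light_starts
              else patterns$heavy_starts
  ends_m <- if (chain_class == "LIGHT") patterns$light_ends
            else patterns$heavy_ends
  vapply(seq, function(s) {
    st <- motif_occurrences(s, starts_m)
    if (length(st) == 0L) return(NA_character_)
    # end position = final residue of an end-motif occurrence
    en <- unlist(lapply(ends_m, function(m) {
      hits <- gregexpr(m, s, fixed = TRUE)[[1]]
      if (hits[1] < 0L) integer(0) else as.integer(hits) + nchar(m) - 1L
    }), use.names = FALSE)
    if (length(en) == 0L) return(NA_character_)
    best_len <- 0L; best_start <- NA_integer_; best_end <- NA_integer_
    for (a in sort(unique(st))) {
      ok <- en[en >= a]
      if (length(ok) == 0L) next
      b <- max(ok)
      len <- b - a + 1L
      if (len > best_len) { best_len <- len; best_start <- a; best_end <- b }
    }
    if (best_len == 0L) return(NA_character_)
    substr(s, best_start, best_end)
  }, character(1), USE.NAMES = FALSE)
}

#' Length filter on trimmed pairs
#'
#' A pair is kept iff both trimmed chains are within the inclusive bounds;
#' a pair with any chain shorter than `min_len` or longer than `max_len`
#' amino acids is discarded.
#'
#' @param pairs A pair table with `light_seq` and `heavy_seq`.
#' @param bounds A [length_bounds()].
#' @return Logical vector, `TRUE` where the pair is kept.
#' @export
length_filter <- function(pairs, bounds = length_bounds()) {
  stopifnot(inherits(bounds, "length_bounds"))
  ll <- nchar(pairs$light_seq); hl <- nchar(pairs$heavy_seq)
  ll >= bounds$min_len & ll <= bounds$max_len &
    hl >= bounds$min_len & hl <= bounds$max_len
}

#' Standardize paired chains to variable regions
#'
#' Runs, in order: label-swap correction, variable-region trimming of both
#' chains, and the length filter. Every input pair yields exactly one
#' outcome row; discarded pairs are absent from the returned pair table but
#' present in the outcome log.
#'
#' @param pairs A pair table (from [pair_all()]).
#' @param patterns A [pattern_set()].
#' @param bounds A [length_bounds()].
#' @return A list with `pairs` (retained, trimmed pairs) and `outcomes`
#'   (data frame: `group_id`, `action` in `KEPT`/`SWAPPED`/
#'   `DISCARDED_NO_PATTERN`/`DISCARDED_LENGTH`, `details`). A swapped then
#'   retained pair reports `SWAPPED`; trimming is implied for every retained
#'   pair.
#' @export
standardize_pairs <- function(pairs, patterns = pattern_set(),
                              bounds = length_bounds()) {
  n <- nrow(pairs)
  if (n == 0L) {
    return(list(pairs = pairs,
                outcomes = data.frame(group_id = character(0),
                                      action = character(0),
                                      details = character(0))))
  }
  pairs <- correct_swapped_labels(pairs, patterns)
  lt <- trim_to_variable_region(pairs$light_seq, "LIGHT", patterns)
  ht <- trim_to_variable_region(pairs$heavy_seq, "HEAVY", patterns)
  action <- ifelse(pairs$swapped, "SWAPPED", "KEPT")
  details <- rep("", n)
  no_pat <- is.na(lt) | is.na(ht)
  action[no_pat] <- "DISCARDED_NO_PATTERN"
  details[no_pat] <- paste0(
    ifelse(is.na(lt[no_pat]), "light: no motif-bounded region; ", ""),
    ifelse(is.na(ht[no_pat]), "heavy: no motif-bounded region", ""))
  pairs$light_seq[!no_pat] <- lt[!no_pat]
  pairs$heavy_seq[!no_pat] <- ht[!no_pat]
  ok_len <- length_filter(pairs, bounds)
  bad_len <- !no_pat & !ok_len
  action[bad_len] <- "DISCARDED_LENGTH"
  details[bad_len] <- paste0("light ", nchar(pairs$light_seq[bad_len]),
                             " aa, heavy ", nchar(pairs$heavy_seq[bad_len]),
                             " aa outside [", bounds$min_len, ", ",
                             bounds$max_len, "]")
  outcomes <- data.frame(group_id = pairs$group_id, action = action,
                         details = details, stringsAsFactors = FALSE)
  keep <- !no_pat & ok_len
  kept <- pairs[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(pairs = kept, outcomes = outcomes)
}
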