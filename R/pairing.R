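#' Normalize a header description for containment comparison
#'
#' Lowercases, removes any parenthesized group consisting solely of
#' light/heavy keyword tokens (e.g. `"(kappa)"`), removes the remaining
#' light/heavy keyword tokens on word boundaries, collapses repeated
#' whitespace and trims. Two chains of one antibody typically differ in
#' their description only by such tokens, so after normalization one
#' description is contained in the other.
#'
#' @param description Character vector of header descriptions.
#' @param config A [keyword_config()].
#' @return Normalized character vector.
#' @export
#' @examples
#' normalize_header("CB3s Fab light chain (kappa)", keyword_config())
normalize_header <- function(description, config) {
  stopifnot(inherits(config, "keyword_config"))
  kws <- c(config$light_keywords, config$heavy_keywords)
  x <- tolower(description)
  kw_alt <- paste(kws, collapse = "|")
  # parenthesized groups made only of chain keywords
  x <- gsub(paste0("\\(\\s*(?:(?:", kw_alt, ")[\\s,/]*)+\\)"), " ", x,
            perl = TRUE)
  for (kw in kws)
    x <- gsub(paste0("\\b", kw, "\\b"), " ", x, perl = TRUE)
  x <- gsub("\\s+", " ", x, perl = TRUE)
  trimws(x)
}

empty_pairs <- function() {
  data.frame(group_id = character(0), strategy = character(0),
             light_member = character(0), heavy_member = character(0),
             light_header = character(0), heavy_header = character(0),
             light_seq = character(0), heavy_seq = character(0),
             stringsAsFactors = FALSE)
}

make_pair <- function(group, li, hi, strategy) {
  data.frame(group_id = group$group_id[li], strategy = strategy,
             light_member = group$member_id[li],
             heavy_member = group$member_id[hi],
             light_header = group$raw_header[li],
             heavy_header = group$raw_header[hi],
             light_seq = group$sequence[li],
             heavy_seq = group$sequence[hi],
             stringsAsFactors = FALSE)
}

#' Pairing strategy 1: header containment modulo chain keywords
#'
#' A light and a heavy member are paired when, after [normalize_header()],
#' one description is a substring of the other. Matching is greedy in input
#' order (each light member, in order, takes the first unused matching heavy
#' member), and each member is used at most once.
#'
#' @param group A chain group (record table with `chain_class`).
#' @param config A [keyword_config()].
#' @return A list with `pairs` (pair rows, strategy `"S1"`) and `leftover`
#'   (the unpaired remainder of the group).
#' @export
pair_strategy1 <- function(group, config) {
  pairs <- empty_pairs()
  if (nrow(group) == 0L) return(list(pairs = pairs, leftover = group))
  norm <- normalize_header(group$description, config)
  lights <- which(group$chain_class == "LIGHT")
  heavies <- which(group$chain_class == "HEAVY")
  used <- rep(FALSE, nrow(group))
  for (li in lights) {
    for (hi in heavies) {
      if (used[hi]) next
      a <- norm[li]; b <- norm[hi]
      if (grepl(a, b, fixed = TRUE) || grepl(b, a, fixed = TRUE)) {
        pairs <- rbind(pairs, make_pair(group, li, hi, "S1"))
        used[li] <- used[hi] <- TRUE
        break
      }
    }
  }
  list(pairs = pairs, leftover = group[!used, , drop = FALSE])
}

#' Pairing strategy 2: two-member groups
#'
#' Fires only when the (leftover) group has exactly two members, one
#' classified `LIGHT` and one `HEAVY`; they are then paired.
#'
#' @inheritParams pair_strategy1
#' @return As [pair_strategy1()], strategy `"S2"`.
#' @export
pair_strategy2 <- function(group) {
  pairs <- empty_pairs()
  if (nrow(group) == 2L && setequal(group$chain_class, c("LIGHT", "HEAVY")) &&
      group$chain_class[1] != group$chain_class[2]) {
    li <- which(group$chain_class == "LIGHT")
    hi <- which(group$chain_class == "HEAVY")
    pairs <- make_pair(group, li, hi, "S2")
    return(list(pairs = pairs, leftover = group[0, , drop = FALSE]))
  }
  list(pairs = pairs, leftover = group)
}

seq_related <- function(a, b) {
  a == b || grepl(a, b, fixed = TRUE) || grepl(b, a, fixed = TRUE)
}

#' Pairing strategy 3: sequence evidence from previously paired antibodies
#'
#' Two members are paired when one member's sequence is equal to, contained
#' in or containing a reference light chain while the other stands in the
#' same relation to that reference pair's heavy chain. Chain classes from
#' headers are bypassed: the member matching the reference light is assigned
#' the light slot, which rescues records whose headers are mislabeled. The
#' first matching reference pair wins; each member is used at most once.
#'
#' @inheritParams pair_strategy1
#' @param reference A reference pair set: data frame with columns
#'   `light_seq` and `heavy_seq` (uppercase), e.g. from a previous run's
#'   collection.
#' @return As [pair_strategy1()], strategy `"S3"`.
#' @export
pair_strategy3 <- function(group, reference) {
  pairs <- empty_pairs()
  n <- nrow(group)
  if (n < 2L || is.null(reference) || nrow(reference) == 0L)
    return(list(pairs = pairs, leftover = group))
  used <- rep(FALSE, n)
  for (i in seq_len(n - 1L)) {
    if (used[i]) next
    for (j in seq.int(i + 1L, n)) {
      if (used[i] || used[j]) next
      si <- group$sequence[i]; sj <- group$sequence[j]
      done <- FALSE
      for (r in seq_len(nrow(reference))) {
        rl <- reference$light_seq[r]; rh <- reference$heavy_seq[r]
        if (seq_related(si, rl) && seq_related(sj, rh)) {
          pairs <- rbind(pairs, make_pair(group, i, j, "S3"))
          done <- TRUE
        } else if (seq_related(sj, rl) && seq_related(si, rh)) {
          pairs <- rbind(pairs, make_pair(group, j, i, "S3"))
          done <- TRUE
        }
        if (done) { used[i] <- used[j] <- TRUE; break }
      }
      if (done) break
    }
  }
  list(pairs = pairs, leftover = group[!used, , drop = FALSE])
}

#' Pairing strategy 4: curated pairing decisions
#'
#' Applies reviewer decisions to the groups no automatic strategy resolved.
#' A decision names a group, a light member and a heavy member, with verdict
#' `"pair"` (form the pair) or `"skip"` (mark the group resolved with no
#' pair). The pipeline is non-interactive: unresolved groups are reported,
#' never guessed.
#'
#' @inheritParams pair_strategy1
#' @param decisions Data frame with columns `group_id`, `light_member`,
#'   `heavy_member`, `verdict`, e.g. from [read_decisions()].
#' @return As [pair_strategy1()], strategy `"S4"`.
#' @export
pair_strategy4 <- function(group, decisions) {
  pairs <- empty_pairs()
  if (nrow(group) == 0L || is.null(decisions) || nrow(decisions) == 0L)
    return(list(pairs = pairs, leftover = group))
  gid <- group$group_id[1]
  dec <- decisions[decisions$group_id == gid, , drop = FALSE]
  used <- rep(FALSE, nrow(group))
  for (d in seq_len(nrow(dec))) {
    if (identical(dec$verdict[d], "skip")) {
      return(list(pairs = pairs, leftover = group[0, , drop = FALSE],
                  skipped = TRUE))
    }
    li <- which(group$member_id == dec$light_member[d] & !used)
    hi <- which(group$member_id == dec$heavy_member[d] & !used)
    if (length(li) == 0L || length(hi) == 0L)
      stop("decision for group ", gid, " names a missing member (",
           dec$light_member[d], " / ", dec$heavy_member[d], ")",
           call. = FALSE)
    li <- li[1]; hi <- hi[1]
    pairs <- rbind(pairs, make_pair(group, li, hi, "S4"))
    used[li] <- used[hi] <- TRUE
  }
  list(pairs = pairs, leftover = group[!used, , drop = FALSE])
}

#' Read a pairing decisions table
#'
#' Tab-separated with header columns `group_id`, `light_member`,
#' `heavy_member`, `verdict` (`pair` or `skip`).
#'
#' @param path Path to the TSV file.
#' @return A data frame of decisions.
#' @export
read_decisions <- function(path) {
  d <- utils::read.delim(path, colClasses = "character")
  need <- c("group_id", "light_member", "heavy_member", "verdict")
  if (!all(need %in% names(d)))
    stop("decisions file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  d
}

#' Pair all chain groups with the four-strategy cascade
#'
#' Strategies are applied per group in fixed precedence: header containment
#' (S1), then two-member groups (S2) on the S1 leftover, then sequence
#' evidence against previously paired antibodies (S3), then curated
#' decisions (S4). Each member joins at most one pair, and the strategy
#' attributed to a pair is the lowest-numbered one that produced it.
#'
#' @param groups Named list of chain groups (from [ingest_source()]).
#' @param config A [keyword_config()].
#' @param reference Optional reference pair set for S3.
#' @param decisions Optional decisions table for S4.
#' @param species Species label attached to the resulting pairs.
#' @return A list with `pairs` (pair table with a `species` column),
#'   `unpaired` (data frame `group_id`, `member_id`, `reason`), and
#'   `strategy_counts` (named integer vector over S1..S4).
#' @export
pair_all <- function(groups, config, reference = NULL, decisions = NULL,
                     species = NA_character_) {
  all_pairs <- list()
  unpaired <- data.frame(group_id = character(0), member_id = character(0),
                         reason = character(0), stringsAsFactors = FALSE)
  for (g in groups) {
    s1 <- pair_strategy1(g, config)
    s2 <- pair_strategy2(s1$leftover)
    s3 <- pair_strategy3(s2$leftover, reference)
    s4 <- pair_strategy4(s3$leftover, decisions)
    all_pairs[[length(all_pairs) + 1L]] <-
      rbind(s1$pairs, s2$pairs, s3$pairs, s4$pairs)
    left <- s4$leftover
    if (nrow(left) > 0L) {
      unpaired <- rbind(unpaired, data.frame(
        group_id = left$group_id, member_id = left$member_id,
        reason = "no strategy resolved this member",
        stringsAsFactors = FALSE))
    }
  }
  pairs <- if (length(all_pairs)) do.call(rbind, all_pairs)
           else empty_pairs()
  rownames(pairs) <- NULL
  if (nrow(pairs) > 0L) pairs$species <- species
  else pairs$species <- character(0)
  counts <- vapply(paste0("S", 1:4),
                   function(s) sum(pairs$strategy == s), integer(1))
  list(pairs = pairs, unpaired = unpaired, strategy_counts = counts)
}
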