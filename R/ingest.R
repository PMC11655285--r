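kw_match <- function(text, keywords, substring = FALSE) {
  if (length(keywords) == 0L) return(rep(FALSE, length(text)))
  text <- tolower(text)
  hit <- rep(FALSE, length(text))
  for (kw in keywords) {
    if (substring) {
      hit <- hit | grepl(kw, text, fixed = TRUE)
    } else {
      hit <- hit | grepl(paste0("\\b", kw, "\\b"), text, perl = TRUE)
    }
  }
  hit
}

#' Classify a chain record from its header description
#'
#' Classification is keyword-driven and case-insensitive on whole words (word
#' boundaries, so "prothrombin" does not match "thrombin"; set
#' `substring_match = TRUE` in the config for raw substring behavior).
#' Irrelevant keywords are checked first and dominate: a description matching
#' one is `"DISCARD"` even if chain keywords also match. Otherwise light
#' keywords win over heavy keywords, and a description matching neither is
#' `"UNKNOWN"`.
#'
#' @param description Character vector of header descriptions.
#' @param config A [keyword_config()].
#' @return Character vector with values `"LIGHT"`, `"HEAVY"`, `"UNKNOWN"` or
#'   `"DISCARD"`.
#' @export
#' @examples
#' cfg <- keyword_config()
#' classify_chain(c("CB3s Fab light chain (kappa)",
#'                  "IGG1 ANTIBODY (variable heavy chain)",
#'                  "prothrombin antigen complex", ""), cfg)
classify_chain <- function(description, config) {
  stopifnot(inherits(config, "keyword_config"))
  ss <- config$substring_match
  out <- rep("UNKNOWN", length(description))
  out[kw_match(description, config$heavy_keywords, ss)] <- "HEAVY"
  out[kw_match(description, config$light_keywords, ss)] <- "LIGHT"
  out[kw_match(description, config$irrelevant_keywords, ss)] <- "DISCARD"
  out
}

#' Restrict records to one species
#'
#' A record is retained when its parsed species name or its raw header
#' matches any of the configured keywords for `species` (case-insensitive),
#' or when its parsed taxon id equals the configured taxon id.
#'
#' @param records A record table from [parse_source_fasta()].
#' @param species A species name configured in `config$species_keywords`.
#' @param config A [keyword_config()].
#' @return The retained subset of `records`.
#' @export
filter_species <- function(records, species, config) {
  stopifnot(inherits(config, "keyword_config"))
  kws <- config$species_keywords[[species]]
  if (is.null(kws))
    stop("species not configured in species_keywords: ", species,
         call. = FALSE)
  ss <- config$substring_match
  keep <- kw_match(records$species_name, kws, ss) |
    kw_match(records$raw_header, kws, ss)
  taxid <- config$species_taxids[species]
  if (!is.na(taxid))
    keep <- keep | (!is.na(records$taxon_id) & records$taxon_id == taxid)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify, filter and group records of one source
#'
#' Applies [classify_chain()], drops `DISCARD` records, optionally drops
#' `UNKNOWN` records (the default; disable with `drop_unknown = FALSE` to let
#' sequence-evidence pairing attempt them), and splits the remainder into
#' chain groups by `group_id`, preserving input order within each group.
#'
#' @inheritParams filter_species
#' @param drop_unknown Drop records whose class is `UNKNOWN` (default
#'   `TRUE`).
#' @return A list with `groups` (named list of record tables, each with an
#'   added `chain_class` column) and `report` (a data frame of dropped
#'   records with columns `raw_header`, `class`, `action`, `reason`).
#' @export
group_by_id <- function(records, config, drop_unknown = TRUE) {
  records$chain_class <- classify_chain(records$description, config)
  drop <- records$chain_class == "DISCARD" |
    (drop_unknown & records$chain_class == "UNKNOWN")
  report <- data.frame(
    raw_header = records$raw_header[drop],
    class = records$chain_class[drop],
    action = rep("dropped", sum(drop)),
    reason = ifelse(records$chain_class[drop] == "DISCARD",
                    "irrelevant keyword", "no chain keyword"),
    stringsAsFactors = FALSE)
  kept <- records[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  groups <- if (nrow(kept) == 0L) list()
            else split(kept, factor(kept$group_id, unique(kept$group_id)))
  list(groups = groups, report = report)
}

#' Remove within-group contained sequences
#'
#' Within one chain group, a member whose sequence is a strict substring of a
#' same-class member's sequence is discarded (the smallest sequence loses);
#' for exact duplicates the first-encountered member is kept. Containment is
#' checked within a chain class only, so a short light chain contained in a
#' long heavy chain by chance is not pruned. The operation is idempotent and
#' order-stable (the output is a subsequence of the input).
#'
#' @param group A record table with a `chain_class` column.
#' @return The pruned record table.
#' @export
prune_contained <- function(group) {
  n <- nrow(group)
  if (n <= 1L) return(group)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (group$chain_class[i] != group$chain_class[j]) next
      si <- group$sequence[i]; sj <- group$sequence[j]
      if (si == sj) {
        if (j < i) keep[i] <- FALSE
      } else if (nchar(si) < nchar(sj) && grepl(si, sj, fixed = TRUE)) {
        keep[i] <- FALSE
      }
    }
  }
  out <- group[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full per-source ingest stage
#'
#' Convenience wrapper: [filter_species()], then [group_by_id()], then
#' [prune_contained()] on every group.
#'
#' @inheritParams filter_species
#' @inheritParams group_by_id
#' @return As [group_by_id()], with groups pruned; the report also lists
#'   records pruned by containment (`reason = "contained in larger
#'   same-class sequence"`).
#' @export
ingest_source <- function(records, species, config, drop_unknown = TRUE) {
  records <- filter_species(records, species, config)
  gb <- group_by_id(records, config, drop_unknown)
  pruned <- lapply(gb$groups, prune_contained)
  extra <- do.call(rbind, lapply(names(gb$groups), function(g) {
    gone <- setdiff(gb$groups[[g]]$raw_header, pruned[[g]]$raw_header)
    if (length(gone) == 0L) return(NULL)
    data.frame(raw_header = gone, class = "", action = "dropped",
               reason = "contained in larger same-class sequence",
               stringsAsFactors = FALSE)
  }))
  report <- rbind(gb$report, extra)
  list(groups = pruned, report = report, species = species)
}
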