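#' Keyword configuration for chain classification and species filtering
#'
#' Bundles the keyword lists used to classify FASTA records from their header
#' descriptions and to restrict a source to one species. Matching is
#' case-insensitive and, by default, on whole words (see [classify_chain()]).
#'
#' @param light_keywords Character vector of words marking a light chain.
#' @param heavy_keywords Character vector of words marking a heavy chain.
#'   The defaults cover the five heavy-chain isotype class names.
#' @param irrelevant_keywords Character vector of words marking a record as
#'   not an antibody chain (antigens, co-crystallized proteins, ...). These
#'   take precedence over the chain keywords. The default list is short and
#'   meant to be extended per source.
#' @param species_keywords Named list mapping a species name to the words that
#'   identify it in free-text headers.
#' @param species_taxids Named integer vector mapping a species name to its
#'   NCBI taxon id; a record whose parsed taxon id matches is retained even if
#'   no keyword matches.
#' @param substring_match Logical; if `TRUE`, keywords match as raw substrings
#'   instead of whole words.
#'
#' @return An object of class `keyword_config` (a list with the fields above,
#'   all keywords lowercased).
#' @export
#' @examples
#' cfg <- keyword_config()
#' classify_chain("CB3s Fab light chain (kappa)", cfg)
keyword_config <- function(light_keywords = c("light", "kappa", "lambda"),
                           heavy_keywords = c("heavy", "alpha", "gamma",
                                              "delta", "epsilon", "mu"),
                           irrelevant_keywords = c("thrombin", "antigen",
                                                   "subcomponent", "albumin",
                                                   "lysozyme", "receptor"),
                           species_keywords = list(
                             "Homo sapiens" = c("homo", "sapiens"),
                             "Mus musculus" = c("mus", "musculus")),
                           species_taxids = c("Homo sapiens" = 9606L,
                                              "Mus musculus" = 10090L),
                           substring_match = FALSE) {
  light_keywords <- tolower(light_keywords)
  heavy_keywords <- tolower(heavy_keywords)
  if (length(intersect(light_keywords, heavy_keywords)) > 0L)
    stop("light and heavy keyword lists must be disjoint", call. = FALSE)
  structure(list(
    light_keywords = light_keywords,
    heavy_keywords = heavy_keywords,
    irrelevant_keywords = tolower(irrelevant_keywords),
    species_keywords = lapply(species_keywords, tolower),
    species_taxids = species_taxids,
    substring_match = isTRUE(substring_match)
  ), class = "keyword_config")
}

#' Variable-region boundary motifs
#'
#' Start and end amino-acid motifs delimiting antibody variable regions, per
#' chain class. Retained chains must begin at an occurrence of a start motif
#' of their class and end at the final residue of an occurrence of an end
#' motif of their class (see [trim_to_variable_region()]).
#'
#' The default lists are illustrative, not a published reference set: a few
#' common germline V-segment starting patterns and J-segment ending patterns,
#' sufficient for the shipped fixtures. Production use should supply curated
#' lists (e.g. derived from IMGT germline references) via a YAML/JSON file and
#' [read_pattern_set()].
#'
#' @param light_starts,heavy_starts,light_ends,heavy_ends Character vectors of
#'   uppercase amino-acid motifs, each at least 3 residues long.
#'
#' @return An object of class `pattern_set`.
#' @export
#' @examples
#' ps <- pattern_set()
#' seq <- paste0("GSHM", ps$light_starts[1], "ARNDCQEG", ps$light_ends[1], "HH")
#' trim_to_variable_region(seq, "LIGHT", ps)
pattern_set <- function(light_starts = c("DIQM", "EIVL", "QSVL", "DIVM"),
                        heavy_starts = c("EVQL", "QVQL", "QVHL", "QMQL"),
                        light_ends = c("VEIK", "VELK", "VLG", "LEIK"),
                        heavy_ends = c("VTVSS", "VTVVS", "VTVF", "VTV")) {
  ps <- list(light_starts = toupper(light_starts),
             heavy_starts = toupper(heavy_starts),
             light_ends = toupper(light_ends),
             heavy_ends = toupper(heavy_ends))
  for (nm in names(ps)) {
    if (length(ps[[nm]]) == 0L)
      stop("pattern list '", nm, "' must be non-empty", call. = FALSE)
    if (any(nchar(ps[[nm]]) < 3L))
      stop("motifs in '", nm, "' must be at least 3 residues long",
           call. = FALSE)
    if (any(!grepl("^[A-Z]+$", ps[[nm]])))
      stop("motifs in '", nm, "' must be uppercase amino-acid strings",
           call. = FALSE)
  }
  structure(ps, class = "pattern_set")
}

#' Variable-region length bounds
#'
#' Inclusive bounds on trimmed chain length; pairs with any chain shorter than
#' `min_len` or longer than `max_len` amino acids are discarded.
#'
#' @param min_len,max_len Integer bounds in amino acids.
#' @return An object of class `length_bounds`.
#' @export
length_bounds <- function(min_len = 80L, max_len = 150L) {
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (is.na(min_len) || is.na(max_len) || min_len <= 0L || min_len > max_len)
    stop("invalid length bounds: need 0 < min_len <= max_len", call. = FALSE)
  structure(list(min_len = min_len, max_len = max_len),
            class = "length_bounds")
}

config_read_file <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read configuration objects from YAML or JSON files
#'
#' Field names mirror the corresponding constructor arguments; absent fields
#' fall back to the constructor defaults.
#'
#' @param path Path to a `.yaml`, `.yml` or `.json` file.
#' @return A `keyword_config`, `pattern_set` or `length_bounds` object.
#' @export
read_keyword_config <- function(path) {
  raw <- config_read_file(path)
  if (!is.null(raw$species_taxids))
    raw$species_taxids <- unlist(raw$species_taxids)
  do.call(keyword_config, raw)
}

#' @rdname read_keyword_config
#' @export
read_pattern_set <- function(path) {
  do.call(pattern_set, config_read_file(path))
}

#' @rdname read_keyword_config
#' @export
read_length_bounds <- function(path) {
  do.call(length_bounds, config_read_file(path))
}
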