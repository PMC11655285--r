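#' Parse a FASTA header into structured fields
#'
#' The default `"structured-pipe"` dialect expects headers of the form
#' `GROUPID_MEMBER|description|Species (taxid)`: the header is split on `|`
#' into three fields (extra `|` fields are appended to the description), and
#' the first field is split on its last underscore into group and member ids.
#' A trailing parenthesized integer in the species field is parsed as the
#' NCBI taxon id. Headers that do not match fall back to free-text parsing:
#' the group id is the first whitespace/underscore-delimited token and the
#' remainder becomes the description.
#'
#' @param header Character vector of raw FASTA headers (without the `>`).
#' @param dialect Header dialect name; `"structured-pipe"` (default) or
#'   `"free-text"`.
#' @return A data frame with columns `group_id`, `member_id`, `description`,
#'   `species_name`, `taxon_id` (integer, `NA` when absent) and `raw_header`.
#' @export
#' @examples
#' parse_header_fields("8AON_3|Light chain|Homo sapiens (9606)")
parse_header_fields <- function(header, dialect = "structured-pipe") {
  if (!dialect %in% c("structured-pipe", "free-text"))
    stop("unknown header dialect: ", dialect, call. = FALSE)
  n <- length(header)
  out <- data.frame(group_id = character(n), member_id = character(n),
                    description = character(n), species_name = character(n),
                    taxon_id = rep(NA_integer_, n), raw_header = header,
                    stringsAsFactors = FALSE)
  for (i in seq_along(header)) {
    h <- trimws(header[i])
    parts <- strsplit(h, "|", fixed = TRUE)[[1]]
    structured <- dialect == "structured-pipe" && length(parts) >= 3L
    if (structured) {
      idf <- parts[1]
      us <- regexpr("_[^_]*$", idf)
      if (us > 0L) {
        out$group_id[i] <- substr(idf, 1L, us - 1L)
        out$member_id[i] <- substr(idf, us + 1L, nchar(idf))
      } else {
        out$group_id[i] <- idf
      }
      # extra pipe fields join the description; species is the last field
      out$description[i] <- paste(parts[2:(length(parts) - 1L)],
                                  collapse = "|")
      sp <- trimws(parts[length(parts)])
      m <- regexpr("\\(\\s*(\\d+)\\s*\\)\\s*$", sp)
      if (m > 0L) {
        tax <- regmatches(sp, m)
        out$taxon_id[i] <- as.integer(gsub("[^0-9]", "", tax))
        sp <- trimws(substr(sp, 1L, m - 1L))
      }
      out$species_name[i] <- sp
      if (out$group_id[i] == "") structured <- FALSE
    }
    if (!structured) {
      tok <- regexpr("[\\s_]", h, perl = TRUE)
      if (tok > 0L) {
        out$group_id[i] <- substr(h, 1L, tok - 1L)
        out$description[i] <- trimws(substr(h, tok + 1L, nchar(h)))
      } else {
        out$group_id[i] <- h
      }
      out$member_id[i] <- ""
      out$species_name[i] <- ""
      out$taxon_id[i] <- NA_integer_
    }
  }
  out
}

#' Read a source FASTA file into a table of chain records
#'
#' Reads protein FASTA (any line wrapping) and parses each header with the
#' given dialect. Sequences are uppercased and terminal stop characters
#' (`*`) are stripped. Records with an empty sequence are skipped with a
#' warning rather than silently dropped.
#'
#' @param path Path to a FASTA file, or a character vector of FASTA text
#'   lines.
#' @param source_tag Short provenance label for this source (e.g. `"PDB"`);
#'   must not contain `;` or `|`.
#' @inheritParams parse_header_fields
#' @return A data frame of records: the header fields of
#'   [parse_header_fields()] plus `sequence` and `source_tag`.
#' @export
parse_source_fasta <- function(path, source_tag,
                               dialect = "structured-pipe") {
  stopifnot(is.character(source_tag), length(source_tag) == 1L,
            nzchar(source_tag))
  if (grepl("[;|]", source_tag))
    stop("source_tag must not contain ';' or '|'", call. = FALSE)
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
           else as.character(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(cbind(parse_header_fields(character(0), dialect),
                 sequence = character(0), source_tag = character(0)))
  }
  if (!startsWith(trimws(lines[1]), ">"))
    stop("malformed FASTA: sequence data before first header at line 1",
         call. = FALSE)
  is_hdr <- startsWith(trimws(lines), ">")
  rec <- cumsum(is_hdr)
  headers <- sub("^>", "", trimws(lines[is_hdr]))
  seqs <- vapply(split(lines[!is_hdr], rec[!is_hdr]), paste,
                 character(1), collapse = "")
  sequence <- character(length(headers))
  sequence[as.integer(names(seqs))] <- seqs
  sequence <- toupper(gsub("[*\\s]+", "", sequence, perl = TRUE))
  out <- parse_header_fields(headers, dialect)
  out$sequence <- sequence
  out$source_tag <- source_tag
  empty <- !nzchar(out$sequence)
  if (any(empty)) {
    warning(sum(empty), " record(s) with empty sequence skipped: ",
            paste(utils::head(out$raw_header[empty], 3L), collapse = ", "),
            call. = FALSE)
    out <- out[!empty, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

fasta_wrap <- function(seq, width = 80L) {
  vapply(seq, function(s) {
    n <- nchar(s)
    starts <- seq.int(1L, max(n, 1L), by = width)
    paste(substring(s, starts, pmin(starts + width - 1L, n)),
          collapse = "\n")
  }, character(1), USE.NAMES = FALSE)
}

write_fasta <- function(headers, seqs, path, width = 80L) {
  stopifnot(length(headers) == length(seqs))
  txt <- if (length(headers) == 0L) character(0)
         else paste0(">", headers, "\n", fasta_wrap(seqs, width))
  writeLines(txt, path)
  invisible(path)
}

#' Write and read paired FASTA files
#'
#' A paired collection is stored as two FASTA files, one with every light
#' chain and one with every heavy chain, index-synchronized: record *i* of
#' both files belongs to the same antibody and shares the same identifier as
#' first header token.
#'
#' @param pairs A pair table as produced by [merge_collections()] or
#'   [standardize_pairs()]: a data frame with columns `species`, `light_seq`,
#'   `heavy_seq`, `light_header`, `heavy_header` (and optionally `id`).
#' @param light_path,heavy_path Output/input file paths.
#' @return `write_paired_fasta()` returns the two paths invisibly;
#'   `read_paired_fasta()` returns a pair table.
#' @export
write_paired_fasta <- function(pairs, light_path, heavy_path) {
  if (nrow(pairs) == 0L) {
    write_fasta(character(0), character(0), light_path)
    write_fasta(character(0), character(0), heavy_path)
    return(invisible(c(light_path, heavy_path)))
  }
  ids <- if (!is.null(pairs$id)) pairs$id else pair_identity(pairs)
  sp <- gsub(" ", "_", pairs$species, fixed = TRUE)
  lh <- paste0(ids, " ", sp, " ", pairs$light_header)
  hh <- paste0(ids, " ", sp, " ", pairs$heavy_header)
  write_fasta(lh, pairs$light_seq, light_path)
  write_fasta(hh, pairs$heavy_seq, heavy_path)
  invisible(c(light_path, heavy_path))
}

#' @rdname write_paired_fasta
#' @export
read_paired_fasta <- function(light_path, heavy_path) {
  rd <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L)
      return(data.frame(id = character(0), species = character(0),
                        header = character(0), seq = character(0)))
    is_hdr <- startsWith(trimws(lines), ">")
    rec <- cumsum(is_hdr)
    headers <- sub("^>", "", trimws(lines[is_hdr]))
    seqs <- vapply(split(lines[!is_hdr], rec[!is_hdr]), paste,
                   character(1), collapse = "")
    sq <- character(length(headers))
    sq[as.integer(names(seqs))] <- seqs
    id <- sub(" .*$", "", headers)
    rest <- sub("^[^ ]+ ", "", headers)
    # species is underscore-encoded as the second token
    species <- gsub("_", " ", sub(" .*$", "", rest), fixed = TRUE)
    header <- sub("^[^ ]+ ", "", rest)
    data.frame(id = id, species = species, header = header,
               seq = toupper(gsub("\\s", "", sq)), stringsAsFactors = FALSE)
  }
  l <- rd(light_path); h <- rd(heavy_path)
  if (nrow(l) != nrow(h))
    stop("paired FASTA files have different record counts (",
         nrow(l), " vs ", nrow(h), ")", call. = FALSE)
  if (!all(l$id == h$id))
    stop("paired FASTA files are not index-synchronized", call. = FALSE)
  out <- data.frame(species = l$species,
                    light_seq = l$seq, heavy_seq = h$seq,
                    light_header = l$header, heavy_header = h$header,
                    stringsAsFactors = FALSE)
  out$id <- l$id
  out
}

#' Serialize and parse merged provenance headers
#'
#' When antibodies from several sources are merged, the original FASTA
#' headers are all retained: each raw header is suffixed with `;` and its
#' source tag, and entries are joined with the three-pipe separator `|||`.
#' Parsing a serialized header recovers the list of (header, source) pairs
#' exactly.
#'
#' @param headers Character vector of raw headers.
#' @param source_tags Character vector of source tags, recycled to the length
#'   of `headers`.
#' @return `serialize_merged_header()` returns a single string;
#'   `parse_merged_header()` returns a data frame with columns `raw_header`
#'   and `source_tag`.
#' @export
#' @examples
#' serialize_merged_header(c("h1", "h2"), c("PDB", "IMGT"))
serialize_merged_header <- function(headers, source_tags) {
  stopifnot(length(headers) >= 1L)
  source_tags <- rep_len(source_tags, length(headers))
  if (any(grepl("|||", headers, fixed = TRUE)))
    stop("raw header contains the reserved '|||' separator", call. = FALSE)
  if (any(grepl("[;|]", source_tags)))
    stop("source tags must not contain ';' or '|'", call. = FALSE)
  paste(paste0(headers, ";", source_tags), collapse = "|||")
}

#' @rdname serialize_merged_header
#' @param merged A serialized merged header string.
#' @export
parse_merged_header <- function(merged) {
  stopifnot(is.character(merged), length(merged) == 1L)
  entries <- strsplit(merged, "|||", fixed = TRUE)[[1]]
  sc <- regexpr(";[^;]*$", entries)
  if (any(sc < 0L))
    stop("malformed merged header entry (missing ';source' suffix)",
         call. = FALSE)
  data.frame(raw_header = substr(entries, 1L, sc - 1L),
             source_tag = substr(entries, sc + 1L, nchar(entries)),
             stringsAsFactors = FALSE)
}

#' Source tags recorded in a merged header
#'
#' @param merged A serialized merged header string (or vector of them).
#' @return A list of character vectors of unique source tags, in first
#'   appearance order.
#' @export
header_sources <- function(merged) {
  lapply(merged, function(m) unique(parse_merged_header(m)$source_tag))
}

#' Read and write JSON Lines record streams
#'
#' One JSON object per line; round-tripping a data frame of records is the
#' identity. List columns (such as `sources`) are written as JSON arrays.
#'
#' @param records A data frame.
#' @param path File path.
#' @return `write_jsonl()` returns `path` invisibly; `read_jsonl()` returns a
#'   data frame (zero rows for an empty file).
#' @export
write_jsonl <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(records) > 0L) {
    for (i in seq_len(nrow(records))) {
      row <- lapply(records[i, , drop = FALSE], function(col) {
        v <- if (is.list(col)) col[[1]] else col
        v
      })
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, null = "null",
                                  na = "null", digits = NA), con)
    }
  }
  invisible(path)
}

#' @rdname write_jsonl
#' @param list_cols Character vector of column names to keep as list columns
#'   on read (columns whose JSON value is an array).
#' @export
read_jsonl <- function(path, list_cols = "sources") {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(data.frame())
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rows[[i]] <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
      error = function(e) stop("malformed JSON at line ", i, ": ",
                               conditionMessage(e), call. = FALSE))
  }
  cols <- names(rows[[1]])
  out <- lapply(cols, function(cn) {
    vals <- lapply(rows, function(r) {
      v <- r[[cn]]
      if (is.null(v)) NA else v
    })
    if (cn %in% list_cols) I(lapply(vals, as.character))
    else unlist(lapply(vals, function(v) v[1]))
  })
  names(out) <- cols
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  names(df) <- cols
  df
}
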