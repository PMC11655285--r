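#' Configuration of a synthetic multi-source fixture
#'
#' Describes a collection of planted antibodies and the redundancy/ambiguity
#' phenomena layered on top of them: cross-source duplication, sequence
#' containment, terminal and internal divergence between chain variants,
#' ambiguous chain-sharing triples, swapped chain labels, contaminant
#' records and out-of-bounds chains. Generation is fully deterministic under
#' a fixed seed.
#'
#' @param seed Integer master seed.
#' @param n_antibodies Number of planted clean antibodies.
#' @param n_sources Number of sources the records are spread over.
#' @param overlap_fraction Fraction of antibodies emitted identically in a
#'   second source.
#' @param containment_fraction Fraction of antibodies whose second-source
#'   copy is a truncated (contained) variant; these antibodies also carry a
#'   within-group contained duplicate member exercising ingest pruning.
#' @param terminal_divergence_count Number of variant families (three pairs
#'   sharing a light chain, heavy chains diverging only at the C terminus)
#'   that the merge stage must reconcile by longest common substring.
#' @param internal_divergence_count Number of pair duos sharing a light
#'   chain whose heavy chains differ by an interior deletion; these are
#'   unresolvable and must end up in ambiguity clusters.
#' @param ambiguous_triple_count Number of chained chain-sharing triples
#'   (L1/H1, L1/H2, L3/H2), each of which must form one ambiguity cluster.
#' @param swap_label_count Number of antibodies whose two records carry
#'   exchanged light/heavy descriptions.
#' @param contaminant_count Number of non-antibody records with irrelevant
#'   descriptions.
#' @param short_long_count Number of antibodies with one chain outside the
#'   length bounds (alternating too short / too long).
#' @param cross_species_count Number of antibody duos planted in two
#'   species with an identical light chain; all involved antibodies must be
#'   removed.
#' @param species_mix Named numeric vector of species proportions.
#' @param strategy_counts Named integer vector: how many antibodies are
#'   styled so that only pairing strategy S2, S3 or S4 can resolve them
#'   (every other group is S1-style).
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L, n_antibodies = 50L, n_sources = 2L,
                           overlap_fraction = 0.3,
                           containment_fraction = 0.2,
                           terminal_divergence_count = 2L,
                           internal_divergence_count = 1L,
                           ambiguous_triple_count = 1L,
                           swap_label_count = 1L,
                           contaminant_count = 2L,
                           short_long_count = 2L,
                           cross_species_count = 0L,
                           species_mix = c("Homo sapiens" = 0.8,
                                           "Mus musculus" = 0.2),
                           strategy_counts = c(S2 = 3L, S3 = 2L, S4 = 2L)) {
  cfg <- list(seed = as.integer(seed), n_antibodies = as.integer(n_antibodies),
              n_sources = as.integer(n_sources),
              overlap_fraction = overlap_fraction,
              containment_fraction = containment_fraction,
              terminal_divergence_count = as.integer(terminal_divergence_count),
              internal_divergence_count = as.integer(internal_divergence_count),
              ambiguous_triple_count = as.integer(ambiguous_triple_count),
              swap_label_count = as.integer(swap_label_count),
              contaminant_count = as.integer(contaminant_count),
              short_long_count = as.integer(short_long_count),
              cross_species_count = as.integer(cross_species_count),
              species_mix = species_mix,
              strategy_counts = strategy_counts)
  if (any(unlist(cfg[4:5]) < 0) || any(unlist(cfg[6:12]) < 0))
    stop("fixture counts and fractions must be non-negative", call. = FALSE)
  if (cfg$overlap_fraction > 1 || cfg$containment_fraction > 1)
    stop("fractions must be in [0, 1]", call. = FALSE)
  consumed <- sum(cfg$strategy_counts) + cfg$swap_label_count +
    cfg$short_long_count + cfg$terminal_divergence_count +
    cfg$internal_divergence_count
  if (consumed > cfg$n_antibodies)
    stop("infeasible fixture config: planted phenomena (", consumed,
         ") exceed n_antibodies (", cfg$n_antibodies, ")", call. = FALSE)
  structure(cfg, class = "fixture_config")
}

# residues that occur in no default boundary motif, so random cores can
# never create a spurious motif occurrence
CORE_ALPHABET <- setdiff(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                         c("V", "Q", "L"))

rand_core <- function(n) {
  paste(sample(CORE_ALPHABET, n, replace = TRUE), collapse = "")
}

species_taxid_label <- function(species) {
  tax <- c("Homo sapiens" = 9606L, "Mus musculus" = 10090L)[species]
  ifelse(is.na(tax), species, paste0(species, " (", tax, ")"))
}

fx_header <- function(gid, member, desc, species) {
  paste0(gid, "_", member, "|", desc, "|", species_taxid_label(species))
}

#' Generate a seeded multi-source fixture with ground truth
#'
#' Synthesizes per-source FASTA files of antibody chain records (plus a
#' reference pair set for strategy S3 and a decisions table for S4) together
#' with the machine-readable ground truth the pipeline output can be checked
#' against. Chains are built as start motif + random core + end motif using
#' the default [pattern_set()]; cores are drawn from residues that occur in
#' no motif, so planted boundaries are unambiguous.
#'
#' @param config A [fixture_config()].
#' @param dir Optional directory; when given, the fixture is written to disk
#'   (`<tag>.fasta` per source, `reference_pairs.jsonl`, `decisions.tsv`,
#'   `truth.json`).
#' @return A list: `sources` (named list of record tables), `fasta` (named
#'   list of FASTA text), `reference`, `decisions`, `truth` (list with
#'   `retained`, `clusters`, `discards`, `strategy_groups`, `config`).
#' @export
generate_fixture <- function(config = fixture_config(), dir = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  ps <- pattern_set()
  n <- config$n_antibodies
  nsrc <- config$n_sources
  tags <- paste0("DB", seq_len(nsrc))

  # per-antibody species from the mix (block allocation)
  counts <- diff(c(0, round(cumsum(config$species_mix) * n)))
  species <- rep(names(config$species_mix), counts)[seq_len(n)]

  # stream 1: clean chain sequences
  set.seed(config$seed + 1L)
  make_light <- function(total) {
    s <- sample(ps$light_starts, 1L); e <- sample(ps$light_ends, 1L)
    paste0(s, rand_core(total - nchar(s) - nchar(e)), e)
  }
  make_heavy <- function(total, end = NULL) {
    s <- sample(ps$heavy_starts, 1L)
    e <- if (is.null(end)) sample(c("VTVSS", "VTVVS"), 1L) else end
    paste0(s, rand_core(total - nchar(s) - nchar(e)), e)
  }
  lights <- vapply(sample(95:125, n, replace = TRUE), make_light,
                   character(1))
  heavies <- vapply(sample(100:130, n, replace = TRUE), make_heavy,
                    character(1))

  # index allocation: phenomena occupy disjoint blocks of 1..n
  sc <- config$strategy_counts
  cursor <- 0L
  take <- function(k) {
    if (k == 0L) return(integer(0))
    out <- seq.int(cursor + 1L, cursor + k); cursor <<- cursor + k; out
  }
  idx_s2 <- take(sc[["S2"]]); idx_s3 <- take(sc[["S3"]])
  idx_s4 <- take(sc[["S4"]]); idx_swap <- take(config$swap_label_count)
  idx_sl <- take(config$short_long_count)
  idx_term <- take(config$terminal_divergence_count)
  idx_int <- take(config$internal_divergence_count)
  idx_plain <- if (cursor < n) seq.int(cursor + 1L, n) else integer(0)
  n_overlap <- min(round(config$overlap_fraction * n), length(idx_plain))
  idx_overlap <- idx_plain[seq_len(n_overlap)]
  rest <- setdiff(idx_plain, idx_overlap)
  n_contain <- min(round(config$containment_fraction * n), length(rest))
  idx_contain <- rest[seq_len(n_contain)]

  # stream 2: phenomenon-specific sequence edits
  set.seed(config$seed + 2L)
  for (i in idx_sl) {                      # alternately too short / too long
    if (i %% 2L == 0L) lights[i] <- make_light(sample(40:60, 1L))
    else heavies[i] <- make_heavy(sample(160:180, 1L))
  }
  for (i in idx_term)                      # families need the VTVSS end
    heavies[i] <- make_heavy(sample(100:130, 1L), end = "VTVSS")
  for (i in idx_contain) {                 # light with an inner start motif
    s <- sample(ps$light_starts, 1L); s2 <- sample(ps$light_starts, 1L)
    e <- sample(ps$light_ends, 1L)
    lights[i] <- paste0(s, rand_core(40L), s2, rand_core(82L), e)
  }

  names(tags) <- tags
  recs <- stats::setNames(rep(list(list()), nsrc), tags)
  add_rec <- function(src, gid, member, desc, sp, seq) {
    recs[[src]][[length(recs[[src]]) + 1L]] <<-
      data.frame(raw_header = fx_header(gid, member, desc, sp),
                 sequence = seq, stringsAsFactors = FALSE)
  }
  truth_strategy <- list(S1 = character(0), S2 = character(0),
                         S3 = character(0), S4 = character(0))
  discards <- data.frame(raw_header = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  add_discard <- function(hdr, reason)
    discards <<- rbind(discards, data.frame(raw_header = hdr,
                                            reason = reason,
                                            stringsAsFactors = FALSE))

  home <- (seq_len(n) - 1L) %% nsrc + 1L   # primary source per antibody
  gids <- sprintf("G%03d", seq_len(n))
  names_ab <- sprintf("ab%03d", seq_len(n))

  # stream 3: S3 reference pairs = exact copies of the planted chains
  set.seed(config$seed + 3L)
  reference <- data.frame(light_seq = lights[idx_s3],
                          heavy_seq = heavies[idx_s3],
                          label = sprintf("ref-%s", gids[idx_s3]),
                          stringsAsFactors = FALSE)
  decisions <- data.frame(group_id = gids[idx_s4],
                          light_member = rep("1", length(idx_s4)),
                          heavy_member = rep("2", length(idx_s4)),
                          verdict = rep("pair", length(idx_s4)),
                          stringsAsFactors = FALSE)

  for (i in seq_len(n)) {
    src <- tags[home[i]]; gid <- gids[i]; nm <- names_ab[i]; sp <- species[i]
    if (i %in% idx_s2) {
      add_rec(src, gid, "2", paste(nm, "BCR light chain"), sp, lights[i])
      add_rec(src, gid, "1", paste(nm, "heavy chain (VH and CH1 domains)"),
              sp, heavies[i])
      truth_strategy$S2 <- c(truth_strategy$S2, gid)
    } else if (i %in% idx_s3) {
      # both records mislabeled heavy; only sequence evidence can pair them
      add_rec(src, gid, "2", paste(nm, "Fab HEAVY CHAIN"), sp, heavies[i])
      add_rec(src, gid, "3", paste(nm, "Fab HEAVY CHAIN"), sp, lights[i])
      truth_strategy$S3 <- c(truth_strategy$S3, gid)
    } else if (i %in% idx_s4) {
      add_rec(src, gid, "1", paste0(nm, " IGG1 ANTIBODY (light chain)"),
              sp, lights[i])
      add_rec(src, gid, "2",
              paste0(nm, " IGG1 ANTIBODY (variable heavy chain)"),
              sp, heavies[i])
      const_seq <- rand_core(100L)
      add_rec(src, gid, "3",
              paste0(nm, " IGG1 ANTIBODY (constant heavy chain)"),
              sp, const_seq)
      add_discard(fx_header(gid, "3",
                            paste0(nm, " IGG1 ANTIBODY (constant heavy chain)"),
                            sp), "unpaired")
      truth_strategy$S4 <- c(truth_strategy$S4, gid)
    } else if (i %in% idx_swap) {
      # descriptions exchanged between the two records
      add_rec(src, gid, "1", paste(nm, "heavy chain"), sp, lights[i])
      add_rec(src, gid, "2", paste(nm, "light chain (kappa)"), sp, heavies[i])
      truth_strategy$S1 <- c(truth_strategy$S1, gid)
    } else {
      add_rec(src, gid, "1", paste(nm, "light chain (kappa)"), sp, lights[i])
      add_rec(src, gid, "2", paste(nm, "heavy chain"), sp, heavies[i])
      truth_strategy$S1 <- c(truth_strategy$S1, gid)
    }
  }

  for (i in idx_sl) {
    add_discard(paste0(gids[i], "_*"), "DISCARDED_LENGTH")
  }

  # cross-source duplicates and contained copies (S1-styled extra groups)
  for (i in idx_overlap) {
    src2 <- tags[home[i] %% nsrc + 1L]
    gid2 <- sprintf("O%03d", i); nm <- names_ab[i]; sp <- species[i]
    add_rec(src2, gid2, "1", paste(nm, "light chain (kappa)"), sp, lights[i])
    add_rec(src2, gid2, "2", paste(nm, "heavy chain"), sp, heavies[i])
    truth_strategy$S1 <- c(truth_strategy$S1, gid2)
  }
  for (i in idx_contain) {
    src2 <- tags[home[i] %% nsrc + 1L]
    gid2 <- sprintf("C%03d", i); nm <- names_ab[i]; sp <- species[i]
    inner <- substr(lights[i], 45L, nchar(lights[i]))  # from inner motif
    add_rec(src2, gid2, "1", paste(nm, "light chain (kappa)"), sp, inner)
    add_rec(src2, gid2, "2", paste(nm, "heavy chain"), sp, heavies[i])
    truth_strategy$S1 <- c(truth_strategy$S1, gid2)
    # plus a within-group truncated duplicate exercising ingest pruning
    dup <- substr(lights[i], 1L, nchar(lights[i]) - 3L)
    hdr <- fx_header(gids[i], "9", paste(nm, "light chain copy"), sp)
    recs[[tags[home[i]]]][[length(recs[[tags[home[i]]]]) + 1L]] <-
      data.frame(raw_header = hdr, sequence = dup, stringsAsFactors = FALSE)
    add_discard(hdr, "contained")
  }

  # stream 4: terminal-divergence variants (resolved by LCS at merge)
  set.seed(config$seed + 4L)
  truth_retained <- data.frame(species = species, light_seq = lights,
                               heavy_seq = heavies, stringsAsFactors = FALSE)
  truth_retained$sources <- I(lapply(seq_len(n), function(i) {
    s <- tags[home[i]]
    if (i %in% c(idx_overlap, idx_contain))
      s <- c(s, tags[home[i] %% nsrc + 1L])
    sort(unname(s))
  }))
  for (i in idx_term) {
    stem <- substr(heavies[i], 1L, nchar(heavies[i]) - 2L)  # ...VTV
    variants <- paste0(stem, c("VS", "F"))                  # VTVVS, VTVF
    for (k in 1:2) {
      src2 <- tags[(home[i] + k - 1L) %% nsrc + 1L]
      gid2 <- sprintf("V%03d%s", i, letters[k]); sp <- species[i]
      nm <- paste0(names_ab[i], "v", k)
      add_rec(src2, gid2, "1", paste(nm, "light chain (kappa)"), sp,
              lights[i])
      add_rec(src2, gid2, "2", paste(nm, "heavy chain"), sp, variants[k])
      truth_strategy$S1 <- c(truth_strategy$S1, gid2)
    }
    # merged family keeps the longest common substring of the heavies
    truth_retained$heavy_seq[i] <- stem
    truth_retained$sources[[i]] <-
      sort(unique(c(truth_retained$sources[[i]],
                    tags[(home[i] + 0:1) %% nsrc + 1L])))
  }

  # stream 5: internal-divergence duos (unresolvable, must cluster)
  set.seed(config$seed + 5L)
  truth_clusters <- list()
  for (i in idx_int) {
    h <- heavies[i]
    cut <- sample(seq.int(30L, nchar(h) - 30L), 1L)
    h2 <- paste0(substr(h, 1L, cut - 1L), substr(h, cut + 1L, nchar(h)))
    src2 <- tags[home[i] %% nsrc + 1L]
    gid2 <- sprintf("I%03d", i); sp <- species[i]
    nm <- paste0(names_ab[i], "x")
    add_rec(src2, gid2, "1", paste(nm, "light chain (kappa)"), sp, lights[i])
    add_rec(src2, gid2, "2", paste(nm, "heavy chain"), sp, h2)
    truth_strategy$S1 <- c(truth_strategy$S1, gid2)
    truth_clusters[[length(truth_clusters) + 1L]] <-
      data.frame(species = sp, light_seq = lights[i],
                 heavy_seq = c(h, h2), stringsAsFactors = FALSE)
  }

  # stream 6: ambiguous chain-sharing triples (extra antibodies)
  set.seed(config$seed + 6L)
  for (k in seq_len(config$ambiguous_triple_count)) {
    sp <- species[1L]
    l1 <- make_light(sample(95:120, 1L)); l3 <- make_light(sample(95:120, 1L))
    h1 <- make_heavy(sample(100:130, 1L)); h2 <- make_heavy(sample(100:130, 1L))
    trio <- list(c(l1, h1), c(l1, h2), c(l3, h2))
    for (m in 1:3) {
      gid <- sprintf("T%02d%s", k, letters[m])
      nm <- paste0("amb", k, letters[m])
      src <- tags[(k + m) %% nsrc + 1L]
      add_rec(src, gid, "1", paste(nm, "light chain (kappa)"), sp,
              trio[[m]][1])
      add_rec(src, gid, "2", paste(nm, "heavy chain"), sp, trio[[m]][2])
      truth_strategy$S1 <- c(truth_strategy$S1, gid)
    }
    truth_clusters[[length(truth_clusters) + 1L]] <-
      data.frame(species = sp,
                 light_seq = c(l1, l1, l3), heavy_seq = c(h1, h2, h2),
                 stringsAsFactors = FALSE)
  }

  # stream 7: contaminant records
  set.seed(config$seed + 7L)
  for (k in seq_len(config$contaminant_count)) {
    gid <- sprintf("X%03d", k)
    desc <- sample(c("serum albumin complex", "prothrombin antigen complex",
                     "complement subcomponent chain"), 1L)
    sp <- species[1L]
    hdr <- fx_header(gid, "1", desc, sp)
    src <- tags[k %% nsrc + 1L]
    recs[[src]][[length(recs[[src]]) + 1L]] <-
      data.frame(raw_header = hdr, sequence = rand_core(90L),
                 stringsAsFactors = FALSE)
    add_discard(hdr, "irrelevant keyword")
  }

  # stream 8: chains duplicated across two species (all must be removed)
  set.seed(config$seed + 8L)
  for (k in seq_len(config$cross_species_count)) {
    spp <- names(config$species_mix)[1:2]
    l <- make_light(sample(95:120, 1L))
    for (m in 1:2) {
      gid <- sprintf("Z%02d%s", k, letters[m])
      nm <- paste0("xsp", k, letters[m])
      h <- make_heavy(sample(100:130, 1L))
      src <- tags[(k + m) %% nsrc + 1L]
      add_rec(src, gid, "1", paste(nm, "light chain (kappa)"), spp[m], l)
      add_rec(src, gid, "2", paste(nm, "heavy chain"), spp[m], h)
      truth_strategy$S1 <- c(truth_strategy$S1, gid)
    }
  }

  # drop planted non-survivors from the expected retained set
  drop_idx <- c(idx_sl, idx_int)
  truth_retained <- truth_retained[setdiff(seq_len(n), drop_idx), ,
                                   drop = FALSE]
  rownames(truth_retained) <- NULL

  source_tables <- lapply(recs, function(rl) {
    df <- do.call(rbind, rl)
    rownames(df) <- NULL
    df
  })
  fasta <- lapply(source_tables, function(df)
    paste0(">", df$raw_header, "\n", fasta_wrap(df$sequence)))

  truth <- list(retained = truth_retained, clusters = truth_clusters,
                discards = discards, strategy_groups = truth_strategy,
                config = unclass(config))
  out <- list(sources = source_tables, fasta = fasta,
              reference = reference, decisions = decisions, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (tag in names(fasta))
      writeLines(fasta[[tag]], file.path(dir, paste0(tag, ".fasta")))
    write_jsonl(reference, file.path(dir, "reference_pairs.jsonl"))
    utils::write.table(decisions, file.path(dir, "decisions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truth_json <- truth
    truth_json$retained$sources <-
      vapply(truth_json$retained$sources, paste, character(1),
             collapse = ";")
    jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}
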