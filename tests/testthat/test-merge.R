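ps <- pattern_set()
core_ab <- setdiff(AA20, c("V", "Q", "L"))

mk_mpair <- function(light, heavy, species = "Homo sapiens", tag = "PDB",
                     hdr = "h") {
  p <- data.frame(species = species, light_seq = light, heavy_seq = heavy,
                  light_header = paste0(hdr, "_l;", tag),
                  heavy_header = paste0(hdr, "_h;", tag),
                  stringsAsFactors = FALSE)
  p$sources <- I(list(tag))
  p
}

test_that("longest_common_substring matches exhaustive enumeration", {
  expect_equal(longest_common_substring(c("AWIDPEIB", "AWIDEIB")), "AWID")
  expect_equal(longest_common_substring("SINGLE"), "SINGLE")
  expect_equal(longest_common_substring(c("ABC", "XYZ")), "")
  set.seed(21)
  for (k in 1:120) {
    nv <- sample(2:4, 1)
    seqs <- replicate(nv, random_seq(sample(5:30, 1), AA20[1:5]))
    got <- longest_common_substring(seqs)
    expect_equal(nchar(got), oracle_lcs_length(seqs),
                 label = paste(seqs, collapse = "/"))
    if (nchar(got) > 0)
      for (s in seqs) expect_true(grepl(got, s, fixed = TRUE))
  }
})

test_that("terminal divergence resolves to the LCS, internal does not", {
  stem <- paste0("EVQL", random_seq(90, core_ab), "VTV")
  fam <- paste0(stem, c("SS", "VS", "F"))
  expect_equal(resolve_terminal_divergence(fam), stem)
  # internal deletion: LCS loses a whole flank
  h <- paste0("EVQL", random_seq(90, core_ab), "VTVSS")
  h2 <- paste0(substr(h, 1, 40), substr(h, 42, nchar(h)))
  expect_true(is.na(resolve_terminal_divergence(c(h, h2))))
  expect_true(is.na(resolve_terminal_divergence(c("AWIDPEIB", "AWIDEIB"),
                                                max_trim = 2)))
  expect_equal(resolve_terminal_divergence("ONLYONE"), "ONLYONE")
  # trim cap: divergence longer than max_trim fails
  long_tail <- paste0(stem, strrep("A", 15))
  expect_true(is.na(resolve_terminal_divergence(c(stem, long_tail),
                                                max_trim = 10)))
  expect_equal(resolve_terminal_divergence(c(stem, long_tail),
                                           max_trim = 20), stem)
})

test_that("merge_two_pairs requires both sides related, keeps the longest", {
  A <- mk_mpair("BCDE", "XYZW", hdr = "a", tag = "PDB")
  B <- mk_mpair("ABCDEF", "XYZW", hdr = "b", tag = "IMGT")
  m <- merge_two_pairs(A, B)
  expect_equal(m$light_seq, "ABCDEF")
  expect_equal(m$heavy_seq, "XYZW")
  expect_equal(m$light_header, "a_l;PDB|||b_l;IMGT")
  expect_setequal(m$sources[[1]], c("PDB", "IMGT"))

  # identical pairs merge with concatenated headers
  m2 <- merge_two_pairs(A, mk_mpair("BCDE", "XYZW", hdr = "c", tag = "OAS"))
  expect_equal(m2$light_seq, "BCDE")
  expect_equal(m2$light_header, "a_l;PDB|||c_l;OAS")

  # internal difference on one side: not mergeable
  C <- mk_mpair("BCDE", "XAZW", hdr = "d")
  expect_null(merge_two_pairs(A, C))
  # different species: not mergeable
  D <- mk_mpair("BCDE", "XYZW", species = "Mus musculus", hdr = "e")
  expect_null(merge_two_pairs(A, D))
})

test_that("ambiguity clusters equal brute-force transitive closure", {
  # chained sharing: (L1,H1), (L1,H2), (L3,H2) form one cluster of 3
  p <- rbind(mk_mpair("L1", "H1", hdr = "a"),
             mk_mpair("L1", "H2", hdr = "b"),
             mk_mpair("L3", "H2", hdr = "c"),
             mk_mpair("L4", "H4", hdr = "d"))
  cc <- build_ambiguity_clusters(p)
  expect_length(cc$clusters, 1L)
  expect_equal(nrow(cc$clusters[[1]]), 3L)
  expect_equal(cc$retained$light_seq, "L4")

  # all-distinct chains: everything retained
  q <- rbind(mk_mpair("A1", "B1"), mk_mpair("A2", "B2"))
  cc2 <- build_ambiguity_clusters(q)
  expect_length(cc2$clusters, 0L)
  expect_equal(nrow(cc2$retained), 2L)

  # randomized comparison with the repeated-pass closure oracle
  set.seed(31)
  for (k in 1:40) {
    n <- sample(5:50, 1)
    # draw chains from a small pool to force sharing
    pool_l <- replicate(max(2, n %/% 2), random_seq(6, AA20[1:6]))
    pool_h <- replicate(max(2, n %/% 2), random_seq(6, AA20[7:12]))
    pr <- do.call(rbind, lapply(seq_len(n), function(i)
      mk_mpair(sample(pool_l, 1), sample(pool_h, 1), hdr = i)))
    got <- build_ambiguity_clusters(pr)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      adj[i, j] <- i != j &&
        (pr$light_seq[i] == pr$light_seq[j] ||
           pr$heavy_seq[i] == pr$heavy_seq[j] ||
           pr$light_seq[i] == pr$heavy_seq[j] ||
           pr$heavy_seq[i] == pr$light_seq[j])
    }
    comp <- oracle_components(adj)
    sizes <- table(comp)
    singletons <- comp %in% as.integer(names(sizes)[sizes == 1])
    expect_equal(nrow(got$retained), sum(singletons))
    expect_length(got$clusters, sum(sizes >= 2))
    # membership partitions agree
    canon <- function(groups) {
      keys <- vapply(groups, function(ix) paste(sort(ix), collapse = ","),
                     character(1), USE.NAMES = FALSE)
      sort(keys)
    }
    want_groups <- split(which(!singletons), comp[!singletons])
    got_groups <- split(which(got$membership > 0),
                        got$membership[got$membership > 0])
    expect_equal(canon(got_groups), canon(want_groups))
  }
})

test_that("cross-species duplicate chains remove all involved antibodies", {
  p <- rbind(mk_mpair("LSHARED", "H1", species = "Mus musculus", hdr = "m"),
             mk_mpair("LSHARED", "H2", species = "Homo sapiens", hdr = "h"),
             mk_mpair("L3", "H3", species = "Homo sapiens", hdr = "x"))
  r <- remove_cross_species_duplicates(p)
  expect_equal(nrow(r$removed), 2L)
  expect_equal(r$retained$light_seq, "L3")
  expect_equal(r$offending_sequences, "LSHARED")

  # disjoint species collections unchanged
  q <- rbind(mk_mpair("A", "B", species = "Mus musculus"),
             mk_mpair("C", "D", species = "Homo sapiens"))
  expect_equal(nrow(remove_cross_species_duplicates(q)$removed), 0L)
})

test_that("merge_collections merges overlap, resolves terminal families,
           isolates ambiguity, and balances its report", {
  set.seed(41)
  l1 <- paste0("DIQM", random_seq(90, core_ab), "VEIK")
  h1 <- paste0("EVQL", random_seq(95, core_ab), "VTVSS")
  l2 <- paste0("EIVL", random_seq(92, core_ab), "VELK")
  h2 <- paste0("QVQL", random_seq(97, core_ab), "VTVSS")
  # terminal family sharing l2
  stem <- substr(h2, 1, nchar(h2) - 2)
  h2b <- paste0(stem, "VS")
  # ambiguous duo sharing a light with internally differing heavies
  l3 <- paste0("QSVL", random_seq(88, core_ab), "VLG")
  h3 <- paste0("QVHL", random_seq(93, core_ab), "VTVSS")
  h3b <- paste0(substr(h3, 1, 40), substr(h3, 42, nchar(h3)))

  src1 <- rbind(mk_mpair(l1, h1, tag = "DB1", hdr = "s1"),
                mk_mpair(l2, h2, tag = "DB1", hdr = "s2"),
                mk_mpair(l3, h3, tag = "DB1", hdr = "s3"))
  src2 <- rbind(mk_mpair(l1, h1, tag = "DB2", hdr = "t1"),
                mk_mpair(l2, h2b, tag = "DB2", hdr = "t2"),
                mk_mpair(l3, h3b, tag = "DB2", hdr = "t3"))
  res <- merge_collections(list(src1, src2), ps, length_bounds())
  expect_equal(unname(res$report["input_count"]), 6L)
  expect_equal(nrow(res$pairs), 2L)
  expect_length(res$clusters, 1L)
  expect_equal(nrow(res$clusters[[1]]), 2L)
  # the shared antibody records both sources
  shared <- res$pairs[res$pairs$light_seq == l1, ]
  expect_setequal(shared$sources[[1]], c("DB1", "DB2"))
  # the terminal family merged to the LCS stem
  fam <- res$pairs[res$pairs$light_seq == l2, ]
  expect_equal(fam$heavy_seq, stem)
  expect_setequal(fam$sources[[1]], c("DB1", "DB2"))
  # accounting balances
  r <- res$report
  expect_equal(unname(r["input_count"]),
               unname(r["retained_count"] + r["duplicates_collapsed"] +
                        r["ambiguous_pair_count"] +
                        r["cross_species_removed"]))

  # idempotence: merging the output is a fixed point
  again <- merge_collections(res$pairs, ps, length_bounds())
  expect_equal(again$pairs$light_seq, res$pairs$light_seq)
  expect_equal(again$pairs$heavy_seq, res$pairs$heavy_seq)
  expect_length(again$clusters, 0L)
  expect_equal(unname(again$report["duplicates_collapsed"]), 0L)

  # order invariance of the retained sequence set
  perm <- merge_collections(list(src2[3:1, ], src1[c(2, 1, 3), ]),
                            ps, length_bounds())
  expect_setequal(paste(perm$pairs$light_seq, perm$pairs$heavy_seq),
                  paste(res$pairs$light_seq, res$pairs$heavy_seq))
})
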