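cfg <- keyword_config()

mk_group <- function(gid, members, descs, classes, seqs,
                     species = "Homo sapiens") {
  data.frame(group_id = gid, member_id = as.character(members),
             raw_header = paste0(gid, "_", members, "|", descs,
                                 "|", species, " (9606)"),
             description = descs, sequence = seqs, chain_class = classes,
             stringsAsFactors = FALSE)
}

test_that("header normalization removes chain keywords and keyword parens", {
  expect_equal(normalize_header("CB3s Fab light chain (kappa)", cfg),
               "cb3s fab chain")
  expect_equal(normalize_header("Heavy chain", cfg), "chain")
  expect_equal(normalize_header("", cfg), "")
  expect_equal(normalize_header("LIGHT  CHAIN   (LAMBDA)", cfg), "chain")
  # parenthesized groups with non-keyword tokens survive token removal
  expect_equal(normalize_header("x (variable heavy chain)", cfg),
               "x (variable chain)")
})

test_that("strategy 1 pairs on normalized header containment, greedily", {
  g <- mk_group("2HFG", 1:2,
                c("CB3s Fab light chain (kappa)", "CB3s Fab heavy chain"),
                c("LIGHT", "HEAVY"),
                c("DIQMAAAA", "EVQLBBBB"))
  r <- pair_strategy1(g, cfg)
  expect_equal(nrow(r$pairs), 1L)
  expect_equal(r$pairs$strategy, "S1")
  expect_equal(r$pairs$light_seq, "DIQMAAAA")
  expect_equal(nrow(r$leftover), 0L)

  only_lights <- mk_group("L", 1:2, rep("light chain", 2),
                          rep("LIGHT", 2), c("AA", "BB"))
  r2 <- pair_strategy1(only_lights, cfg)
  expect_equal(nrow(r2$pairs), 0L)
  expect_equal(nrow(r2$leftover), 2L)

  # 2 lights + 2 heavies with identical normalized descriptions pair
  # in input order
  g3 <- mk_group("M", 1:4,
                 c("ab light chain", "ab light chain",
                   "ab heavy chain", "ab heavy chain"),
                 c("LIGHT", "LIGHT", "HEAVY", "HEAVY"),
                 c("L1", "L2", "H1", "H2"))
  r3 <- pair_strategy1(g3, cfg)
  expect_equal(nrow(r3$pairs), 2L)
  expect_equal(r3$pairs$light_seq, c("L1", "L2"))
  expect_equal(r3$pairs$heavy_seq, c("H1", "H2"))
})

test_that("strategy 2 fires only on two-member light/heavy groups", {
  g <- mk_group("5DRX", c(2, 1),
                c("CLL240 BCR light chain",
                  "CLL240 heavy chain (VH and CH1 domains)"),
                c("LIGHT", "HEAVY"), c("DIQMA", "EVQLB"))
  # S1 cannot resolve these headers
  expect_equal(nrow(pair_strategy1(g, cfg)$pairs), 0L)
  r <- pair_strategy2(g)
  expect_equal(nrow(r$pairs), 1L)
  expect_equal(r$pairs$strategy, "S2")
  expect_equal(r$pairs$light_member, "2")

  g3 <- mk_group("X", 1:3, rep("chain", 3),
                 c("LIGHT", "HEAVY", "HEAVY"), c("A", "B", "C"))
  expect_equal(nrow(pair_strategy2(g3)$pairs), 0L)
  g2h <- mk_group("Y", 1:2, rep("chain", 2), rep("HEAVY", 2), c("A", "B"))
  expect_equal(nrow(pair_strategy2(g2h)$pairs), 0L)
})

test_that("strategy 3 pairs on reference sequence evidence, bypassing
           header classes", {
  ref <- data.frame(light_seq = "DIQMLIGHTSEQ", heavy_seq = "EVQLHEAVYSEQ",
                    stringsAsFactors = FALSE)
  # both members labeled heavy; member 3 carries the light sequence
  g <- mk_group("7URS", 2:3, rep("COV11 Fab HEAVY CHAIN", 2),
                rep("HEAVY", 2), c("EVQLHEAVYSEQ", "DIQMLIGHTSEQ"))
  r <- pair_strategy3(g, ref)
  expect_equal(nrow(r$pairs), 1L)
  expect_equal(r$pairs$strategy, "S3")
  expect_equal(r$pairs$light_member, "3")
  expect_equal(r$pairs$light_seq, "DIQMLIGHTSEQ")

  expect_equal(nrow(pair_strategy3(g, ref[0, ])$pairs), 0L)

  # containment also counts as relation
  g2 <- mk_group("A", 1:2, rep("x", 2), rep("UNKNOWN", 2),
                 c("QMLIGHTSE", "EVQLHEAVYSEQEXT"))
  r2 <- pair_strategy3(g2, ref)
  expect_equal(nrow(r2$pairs), 1L)
  expect_equal(r2$pairs$light_member, "1")

  # one-sided match is not enough
  g3 <- mk_group("B", 1:2, rep("x", 2), rep("UNKNOWN", 2),
                 c("DIQMLIGHTSEQ", "TOTALLYUNRELATED"))
  expect_equal(nrow(pair_strategy3(g3, ref)$pairs), 0L)
})

test_that("strategy 4 applies decisions and reports leftovers", {
  g <- mk_group("1CL7", 1:3,
                c("IGG1 ANTIBODY (light chain)",
                  "IGG1 ANTIBODY (variable heavy chain)",
                  "IGG1 ANTIBODY (constant heavy chain)"),
                c("LIGHT", "HEAVY", "HEAVY"),
                c("DIQMA", "EVQLB", "CONST"))
  dec <- data.frame(group_id = "1CL7", light_member = "1",
                    heavy_member = "2", verdict = "pair",
                    stringsAsFactors = FALSE)
  r <- pair_strategy4(g, dec)
  expect_equal(nrow(r$pairs), 1L)
  expect_equal(r$pairs$strategy, "S4")
  expect_equal(r$leftover$member_id, "3")

  r2 <- pair_strategy4(g, dec[0, ])
  expect_equal(nrow(r2$pairs), 0L)
  expect_equal(nrow(r2$leftover), 3L)

  skip_dec <- data.frame(group_id = "1CL7", light_member = "",
                         heavy_member = "", verdict = "skip",
                         stringsAsFactors = FALSE)
  r3 <- pair_strategy4(g, skip_dec)
  expect_equal(nrow(r3$pairs), 0L)
  expect_equal(nrow(r3$leftover), 0L)

  bad <- data.frame(group_id = "1CL7", light_member = "9",
                    heavy_member = "2", verdict = "pair",
                    stringsAsFactors = FALSE)
  expect_error(pair_strategy4(g, bad), "1CL7")
})

test_that("the cascade attributes each group to the lowest strategy and
           never reuses a member", {
  ref <- data.frame(light_seq = "DIQMREFLIGHT", heavy_seq = "EVQLREFHEAVY",
                    stringsAsFactors = FALSE)
  dec <- data.frame(group_id = "G4", light_member = "1",
                    heavy_member = "2", verdict = "pair",
                    stringsAsFactors = FALSE)
  groups <- list(
    G1 = mk_group("G1", 1:2, c("ab light chain", "ab heavy chain"),
                  c("LIGHT", "HEAVY"), c("L1", "H1")),
    G2 = mk_group("G2", 1:2, c("one BCR light chain", "two heavy chain vh"),
                  c("LIGHT", "HEAVY"), c("L2", "H2")),
    G3 = mk_group("G3", 1:2, rep("Fab HEAVY CHAIN", 2), rep("HEAVY", 2),
                  c("EVQLREFHEAVY", "DIQMREFLIGHT")),
    G4 = mk_group("G4", 1:3, c("a1 (light chain)", "a2 (variable heavy)",
                               "a3 (constant heavy)"),
                  c("LIGHT", "HEAVY", "HEAVY"), c("L4", "H4", "C4")))
  res <- pair_all(groups, cfg, reference = ref, decisions = dec,
                  species = "Homo sapiens")
  expect_equal(unname(res$strategy_counts), c(1L, 1L, 1L, 1L))
  expect_equal(res$pairs$strategy[match(paste0("G", 1:4),
                                        res$pairs$group_id)],
               c("S1", "S2", "S3", "S4"))
  expect_equal(res$unpaired$group_id, "G4")
  # no member appears in two pairs
  keys <- c(paste0(res$pairs$group_id, "_", res$pairs$light_member),
            paste0(res$pairs$group_id, "_", res$pairs$heavy_member))
  expect_equal(anyDuplicated(keys), 0L)

  # a group solvable by S1 and S2 is attributed to S1
  res2 <- pair_all(groups["G1"], cfg)
  expect_equal(res2$pairs$strategy, "S1")
  # determinism: identical input, identical output
  expect_identical(pair_all(groups, cfg, ref, dec, "Homo sapiens"), res)
})
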