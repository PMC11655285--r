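ps <- pattern_set()
core_ab <- setdiff(AA20, c("V", "Q", "L"))

# brute-force oracle: enumerate every (start occurrence, end occurrence)
# span and return the maximal one (leftmost start on ties)
oracle_trim <- function(seq, starts, ends) {
  occ <- function(m) {
    h <- gregexpr(m, seq, fixed = TRUE)[[1]]
    if (h[1] < 0) integer(0) else as.integer(h)
  }
  st <- sort(unique(unlist(lapply(starts, occ))))
  en <- sort(unique(unlist(lapply(ends, function(m)
    occ(m) + nchar(m) - 1L))))
  best <- NA_character_; best_len <- 0L
  for (a in st) for (b in en) {
    if (b < a) next
    if (b - a + 1L > best_len) {
      best_len <- b - a + 1L
      best <- substr(seq, a, b)
    }
  }
  best
}

test_that("label swap correction needs both-sided start-motif evidence", {
  light <- paste0("DIQM", random_seq(80, core_ab), "VEIK")
  heavy <- paste0("EVQL", random_seq(90, core_ab), "VTVSS")
  swapped <- data.frame(group_id = "5TPP", light_seq = heavy,
                        heavy_seq = light,
                        light_header = "a", heavy_header = "b",
                        stringsAsFactors = FALSE)
  out <- correct_swapped_labels(swapped, ps)
  expect_true(out$swapped)
  expect_equal(out$light_seq, light)
  expect_equal(out$heavy_seq, heavy)
  expect_equal(out$light_header, "b")  # headers travel with the sequences

  fine <- data.frame(group_id = "OK", light_seq = light, heavy_seq = heavy,
                     light_header = "a", heavy_header = "b",
                     stringsAsFactors = FALSE)
  out2 <- correct_swapped_labels(fine, ps)
  expect_false(out2$swapped)
  expect_equal(out2$light_seq, light)

  # one-sided evidence: heavy motif in the light slot only -> warn, keep
  oneside <- data.frame(group_id = "W", light_seq = heavy, heavy_seq = heavy,
                        light_header = "a", heavy_header = "b",
                        stringsAsFactors = FALSE)
  expect_warning(out3 <- correct_swapped_labels(oneside, ps), "one-sided")
  expect_false(out3$swapped)
})

test_that("variable-region trimming keeps the longest motif-bounded span", {
  core <- random_seq(80, core_ab)
  s <- paste0("MGWS", "DIQM", core, "VEIK", "HHHH")
  expect_equal(trim_to_variable_region(s, "LIGHT", ps),
               paste0("DIQM", core, "VEIK"))
  # no start motif -> NA
  expect_true(is.na(trim_to_variable_region(
    paste0(random_seq(50, core_ab), "VEIK"), "LIGHT", ps)))
  # no end motif -> NA
  expect_true(is.na(trim_to_variable_region(
    paste0("DIQM", random_seq(50, core_ab)), "LIGHT", ps)))
  # two starts, one end: span from the earlier start (longest)
  s2 <- paste0("DIQM", random_seq(20, core_ab), "EIVL",
               random_seq(30, core_ab), "VLG")
  expect_equal(trim_to_variable_region(s2, "LIGHT", ps), s2)

  # equivalence with the exhaustive span oracle on randomized sequences
  set.seed(11)
  for (k in 1:60) {
    n_chunks <- sample(2:6, 1)
    chunks <- replicate(n_chunks, {
      what <- sample(c("core", "ls", "le", "hs", "he"), 1,
                     prob = c(.4, .15, .15, .15, .15))
      switch(what, core = random_seq(sample(3:25, 1), core_ab),
             ls = sample(ps$light_starts, 1), le = sample(ps$light_ends, 1),
             hs = sample(ps$heavy_starts, 1), he = sample(ps$heavy_ends, 1))
    })
    s3 <- paste(chunks, collapse = "")
    for (cl in c("LIGHT", "HEAVY")) {
      starts <- if (cl == "LIGHT") ps$light_starts else ps$heavy_starts
      ends <- if (cl == "LIGHT") ps$light_ends else ps$heavy_ends
      got <- trim_to_variable_region(s3, cl, ps)
      want <- oracle_trim(s3, starts, ends)
      expect_identical(got, want, label = paste("seq", s3, "class", cl))
      # trimmed output is a substring and trimming is idempotent
      if (!is.na(got)) {
        expect_true(grepl(got, s3, fixed = TRUE))
        expect_identical(trim_to_variable_region(got, cl, ps), got)
      }
    }
  }
})

test_that("length filter is inclusive at both bounds", {
  b <- length_bounds()
  mk <- function(l, h) data.frame(light_seq = strrep("A", l),
                                  heavy_seq = strrep("A", h))
  expect_false(length_filter(mk(79, 120), b))
  expect_true(length_filter(mk(80, 120), b))
  expect_true(length_filter(mk(80, 150), b))
  expect_false(length_filter(mk(120, 151), b))
  expect_false(length_filter(mk(151, 120), b))
})

test_that("standardize_pairs chains swap, trim and filter with one outcome
           per pair", {
  set.seed(5)
  good_l <- paste0("DIQM", random_seq(90, core_ab), "VEIK")
  good_h <- paste0("EVQL", random_seq(100, core_ab), "VTVSS")
  short_l <- paste0("DIQM", random_seq(30, core_ab), "VEIK")
  no_end_h <- paste0("EVQL", random_seq(100, core_ab))
  pairs <- data.frame(
    group_id = c("A", "B", "C", "D"),
    light_seq = c(good_l, good_h, short_l, good_l),
    heavy_seq = c(good_h, good_l, good_h, no_end_h),
    light_header = "lh", heavy_header = "hh",
    light_member = "1", heavy_member = "2",
    stringsAsFactors = FALSE)
  res <- standardize_pairs(pairs, ps, length_bounds())
  expect_equal(nrow(res$outcomes), 4L)
  expect_equal(res$outcomes$action,
               c("KEPT", "SWAPPED", "DISCARDED_LENGTH",
                 "DISCARDED_NO_PATTERN"))
  expect_equal(nrow(res$pairs), 2L)
  # every retained chain starts/ends with a class motif within bounds
  for (i in seq_len(nrow(res$pairs))) {
    expect_true(any(startsWith(res$pairs$light_seq[i], ps$light_starts)))
    expect_true(any(endsWith(res$pairs$light_seq[i], ps$light_ends)))
    expect_true(any(startsWith(res$pairs$heavy_seq[i], ps$heavy_starts)))
    expect_true(any(endsWith(res$pairs$heavy_seq[i], ps$heavy_ends)))
  }
  expect_true(all(length_filter(res$pairs)))
})
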