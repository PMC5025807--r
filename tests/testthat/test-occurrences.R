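test_that("genus canonicalization strips qualifiers, subgenera and case noise", {
  expect_equal(
    canonicalize_genus(c("cf. Allosaurus", "aff.  Camptosaurus",
                         "?Stegosaurus", "Allosaurus (Antrodemus)",
                         "  ALLOSAURUS ", "cf.", "")),
    c("Allosaurus", "Camptosaurus", "Stegosaurus", "Allosaurus",
      "Allosaurus", "", "")
  )
})

test_that("reading drops invalid rows with a counted warning and validates structure", {
  df <- occ_df(genus = c("Aa", "Bb", "Cc", "Dd", ""),
               max_ma = c(150, 150, 150, 147, 150),
               min_ma = c(148, 148, 148, 145, 148))
  df$min_ma[2] <- 151        # inverted range
  df$max_ma[3] <- NA         # non-numeric age
  path <- withr::local_tempfile(fileext = ".csv")
  write_paleodb_csv(df, path)

  expect_warning(occs <- read_occurrence_table(path), "dropped 3")
  expect_s3_class(occs, "occurrence_table")
  expect_equal(nrow(occs), 2L)
  log <- attr(occs, "drop_log")
  expect_equal(unname(log[c("inverted_age", "non_numeric_age", "empty_genus")]),
               c(1L, 1L, 1L))

  # header-only file -> empty table, no error
  empty <- df[0, ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_paleodb_csv(empty, path2)
  expect_equal(nrow(read_occurrence_table(path2)), 0L)

  # duplicate ids -> integrity error; missing column -> format error
  dup <- occ_df(c("Aa", "Bb"))
  dup$occurrence_id <- "same"
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_paleodb_csv(dup, path3)
  expect_error(read_occurrence_table(path3), "integrity")
  raw <- utils::read.csv(path3)
  raw$genus <- NULL
  path4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(raw, path4, row.names = FALSE)
  expect_error(read_occurrence_table(path4), "format error")
})

test_that("written tables round-trip through read bit-exactly", {
  occs <- occ_df(genus = c("Aa", "Bb", "Cc"),
                 collection = c("c1", "c1", "c2"),
                 reference = c("r1", "r1", "r2"),
                 formation = c("F1", "F1", NA),
                 max_ma = c(150.25, 149.5, 151),
                 min_ma = c(148.125, 149.5, 150),
                 realm = c("marine", "nonmarine", "nonmarine"),
                 region = c("Europe", "Asia", "Other"),
                 group = c("Theropoda", NA, "Testudines"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrence_table(occs, path)
  back <- read_occurrence_table(path, identity_column_map())
  expect_equal(as.data.frame(back), as.data.frame(occs),
               ignore_attr = TRUE)
})

test_that("strict containment binning follows the single-bin rule with older-bin ties", {
  sc <- jk_stage_bins()
  occs <- occ_df(genus = c("Aa", "Bb", "Cc"),
                 max_ma = c(150.0, 146.0, 145.0),
                 min_ma = c(148.0, 144.0, 145.0))
  b <- assign_to_bins(occs, sc)
  expect_equal(b$occurrences$bin_name[1], "Tithonian")      # inside
  expect_true(is.na(b$occurrences$bin[2]))                  # spans 145.0
  expect_equal(b$occurrences$bin_name[3], "Tithonian")      # boundary point -> older

  expect_error(assign_to_bins(occs, data.frame()), "configuration error")
})

test_that("binning conserves occurrences and never double-assigns (property)", {
  sc <- make_uniform_bins(200, 140, 6)
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 200
    mid <- runif(n, 141, 199)
    half <- rexp(n, rate = 0.5)
    occs <- occ_df(genus = sample(LETTERS, n, TRUE),
                   max_ma = mid + half, min_ma = pmax(mid - half, 0.1))
    occs$occurrence_id <- sprintf("o%04d", seq_len(n))
    b <- assign_to_bins(occs, sc)
    idx <- b$occurrences$bin
    expect_equal(sum(!is.na(idx)) + sum(is.na(idx)), n)
    ok <- !is.na(idx)
    expect_true(all(occs$max_ma[ok] <= sc$base_ma[idx[ok]] + 1e-9))
    expect_true(all(occs$min_ma[ok] >= sc$top_ma[idx[ok]] - 1e-9))
    # raw diversity never exceeds occurrence count per bin
    tde <- raw_taxonomic_diversity(b)
    obs <- !is.na(tde$value)
    expect_true(all(tde$value[obs] <= tde$n_occurrences[obs]))
  }
})

test_that("realm partitions are disjoint and exhaustive; unknown levels error", {
  occs <- occ_df(genus = letters[1:6],
                 realm = c("marine", "nonmarine", "marine", "nonmarine",
                           "nonmarine", "marine"))
  m <- partition_occurrences(occs, "realm", "marine")
  nm <- partition_occurrences(occs, "realm", "nonmarine")
  expect_equal(nrow(m) + nrow(nm), nrow(occs))
  expect_length(intersect(m$occurrence_id, nm$occurrence_id), 0)
  expect_setequal(c(m$occurrence_id, nm$occurrence_id), occs$occurrence_id)

  expect_error(partition_occurrences(occs, "region", "Atlantis"),
               "configuration error")
  # absent group level -> empty table, not an error
  expect_equal(nrow(partition_occurrences(occs, "group", "Aves")), 0L)
})

test_that("raw diversity counts distinct genera and keeps empty bins NA", {
  sc <- make_uniform_bins(160, 140, 2)
  occs <- occ_df(genus = c("Aa", "Aa", "Bb"),
                 max_ma = 158, min_ma = 155)   # all in the older bin
  tde <- raw_taxonomic_diversity(assign_to_bins(occs, sc))
  expect_equal(tde$value[1], 2L)
  expect_true(is.na(tde$value[2]))   # NA, not 0
  expect_equal(tde$n_occurrences[2], 0L)
})

test_that("sampling proxies count formations/collections by realm with mixed formations in both", {
  sc <- make_uniform_bins(160, 140, 2)
  occs <- occ_df(
    genus = c("Aa", "Bb", "Cc", "Dd"),
    collection = c("c1", "c2", "c3", "c3"),
    reference = "r1",
    formation = c("F1", "F1", "F2", "F2"),
    realm = c("nonmarine", "nonmarine", "marine", "nonmarine"),
    max_ma = 158, min_ma = 155
  )
  px <- sampling_proxies(assign_to_bins(occs, sc))
  # F1 has 2 non-marine collections; F2 holds marine + non-marine -> both tallies
  expect_equal(px$TBF[1], 2L)
  expect_equal(px$TBC[1], 3L)
  expect_equal(px$MBF[1], 1L)
  expect_equal(px$MBC[1], 1L)
  # empty bin -> zero counts (proxies are counts, not diversity)
  expect_equal(unlist(px[2, c("TBF", "TBC", "MBF", "MBC")], use.names = FALSE),
               rep(0L, 4))
})
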