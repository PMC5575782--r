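test_that("residue maps are strictly increasing bijections", {
  aln <- alignment(c(a = "MK--S", b = "MKQSA"))
  rmap <- residue_map(aln)
  expect_equal(map_to_column(rmap, "a", 3L), 5L)
  expect_equal(map_to_column(rmap, "b", 1:5), 1:5)
  expect_equal(map_to_native(rmap, "a", 5L), 3L)
  expect_error(map_to_native(rmap, "a", 3L), "gap")
  expect_error(map_to_column(rmap, "a", 4L), "outside")
  # round trip over the whole domain
  sub <- rmap[rmap$seq_id == "a", ]
  expect_equal(map_to_native(rmap, "a", map_to_column(rmap, "a",
                                                      sub$native_pos)),
               sub$native_pos)
  expect_true(all(diff(sub$column) > 0))
})

test_that("MAP construction groups PTMs by column and conserves records", {
  aln <- alignment(c(
    P1 = "MKSAS-KT",
    P2 = "MKSA-SKT",
    P3 = "M-SASSKT",
    P4 = "MKSASSK-"
  ))
  ptms <- validate_ptms(dplyr::bind_rows(
    make_ptm_row("P1", 3, "S"),          # column 3
    make_ptm_row("P2", 3, "S"),          # column 3
    make_ptm_row("P3", 2, "S"),          # column 3 (gap at col 2)
    make_ptm_row("P1", 5, "S"),          # column 5
    make_ptm_row("P4", 7, "K", "ubiquitination")  # column 7
  ), aln)
  maps <- build_maps(ptms, aln)
  expect_equal(maps$column, c(3L, 5L, 7L))
  expect_equal(maps$n_ptms, c(3L, 1L, 1L))
  expect_equal(sum(purrr::map_int(maps$ptms, nrow)), nrow(ptms))
  # three PTMs on distinct columns -> three MAPs
  three <- dplyr::filter(
    ptms,
    (protein_id == "P1" & native_pos %in% c(3, 5)) | protein_id == "P4"
  )
  expect_equal(nrow(build_maps(three, aln)), 3L)
})

test_that("distinct-triple PTM counting deduplicates and splits by type", {
  twice <- dplyr::bind_rows(make_ptm_row("P1", 100, "S"),
                            make_ptm_row("P1", 100, "S"))
  expect_equal(ptm_count(twice), 1L)
  mixed <- dplyr::bind_rows(make_ptm_row("P1", 100, "S"),
                            make_ptm_row("P1", 100, "S", "ubiquitination"))
  expect_equal(ptm_count(mixed), 2L)
  expect_equal(ptm_count(dplyr::bind_rows(make_ptm_row("P1", 100, "S"),
                                          make_ptm_row("P2", 90, "S"))), 2L)
})

test_that("profile merge preserves both inputs and hits the exhaustive
           optimum on small profiles", {
  a <- alignment(c(q1 = "RGS"))
  b <- alignment(c(s1 = "RGS"))
  merged <- profile_align(a, b)
  expect_equal(n_columns(merged), 3L)
  expect_false(any(grepl("-", merged$seq)))

  a <- alignment(c(q1 = "RGS"))
  b <- alignment(c(s1 = "RAGS"))
  merged <- profile_align(a, b)
  expect_equal(n_columns(merged), 4L)
  expect_equal(strip_allgap_columns(merged, "q1")$seq, "RGS")
  expect_equal(strip_allgap_columns(merged, "s1")$seq, "RAGS")

  sm <- ptmhotspots:::default_submat()
  set.seed(42)
  for (case in 1:10) {
    a <- random_small_profile(sample(1:3, 1), sample(2:6, 1))
    b <- random_small_profile(sample(1:3, 1), sample(2:6, 1))
    merged <- profile_align(a, b)
    S <- naive_colpair_scores(a, b, sm)
    expect_equal(attr(merged, "score"),
                 exhaustive_profile_score(S, -10, -0.5),
                 tolerance = 1e-9)
    # each input recoverable verbatim (modulo its own all-gap columns,
    # which single-row random profiles can contain)
    expect_equal(strip_allgap_columns(merged, a$seq_id)$seq,
                 strip_allgap_columns(a, a$seq_id)$seq)
    expect_equal(strip_allgap_columns(merged, b$seq_id)$seq,
                 strip_allgap_columns(b, b$seq_id)$seq)
  }
})

test_that("profile merge is symmetric up to row order and stable for PTM
           columns", {
  set.seed(7)
  a <- random_small_profile(2, 6, gap_prob = 0)
  b <- random_small_profile(2, 5, gap_prob = 0)
  ab <- profile_align(a, b)
  ba <- profile_align(b, a)
  expect_equal(attr(ab, "score"), attr(ba, "score"), tolerance = 1e-9)
  reordered <- ba[match(ab$seq_id, ba$seq_id), ]
  expect_equal(reordered$seq, ab$seq)

  # a PTM's merged column is consistent with its pre-merge native position
  ptms <- validate_ptms(make_ptm_row(a$seq_id[1], 2,
                                     substr(gsub("-", "", a$seq[1]), 2, 2)),
                        a)
  merged_maps <- build_maps(ptms, ab)
  rmap <- residue_map(ab)
  expect_equal(merged_maps$column,
               map_to_column(rmap, a$seq_id[1], 2L))
})

test_that("profile merge rejects shared ids", {
  a <- alignment(c(x = "RGS"))
  expect_error(profile_align(a, a), "disjoint")
})
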