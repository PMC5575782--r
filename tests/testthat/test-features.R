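test_that("column conservation follows hand counts and flags degenerate
           columns", {
  aln <- alignment(c(a = "SS-", b = "ST-", c = "SA-", d = "S--"))
  cc <- column_conservation(aln, 1:3)
  expect_equal(cc$trc, c(1, 1 / 3, 0))
  expect_equal(cc$pac, c(1, 2 / 3, 0))
  expect_equal(cc$membership, c(1, 0.75, 0))
  expect_equal(cc$degenerate, c(FALSE, FALSE, TRUE))
  expect_error(column_conservation(aln, 9L), "outside")
})

test_that("query-scope conservation ignores non-query rows", {
  aln <- alignment(c(a = "S", b = "S", c = "A", d = "A"),
                   is_query = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(column_conservation(aln, 1L, scope = "query")$pac, 1)
  expect_equal(column_conservation(aln, 1L, scope = "all")$pac, 0.5)
})

test_that("cluster window statistics match the worked layout", {
  # per-column PTM counts [1,0,2,0,3] on columns 1..5
  aln <- alignment(setNames(rep(strrep("S", 5), 6), paste0("p", 1:6)))
  recs <- dplyr::bind_rows(
    make_ptm_row("p1", 1, "S"),
    make_ptm_row("p1", 3, "S"), make_ptm_row("p2", 3, "S"),
    make_ptm_row("p1", 5, "S"), make_ptm_row("p2", 5, "S"),
    make_ptm_row("p3", 5, "S", known = TRUE)
  )
  maps <- build_maps(validate_ptms(recs, aln), aln)
  st <- cluster_window_stats(maps, window = 2L)
  mid <- st[st$column == 3L, ]
  expect_equal(mid$cpc, 6L)   # 1 + 2 + 3, self included
  expect_equal(mid$nc, 2L)    # columns 1 and 5, self excluded
  expect_equal(mid$nkc, 1L)   # column 5 carries known-function evidence
  expect_true(mid$neighbor_known)
})

test_that("window statistics agree with brute-force scan on random layouts", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(3:30, 1)
    cols <- sort(sample.int(200, n))
    pc <- sample.int(8, n, replace = TRUE)
    kf <- runif(n) < 0.3
    w <- sample(0:4, 1)
    maps <- tibble::tibble(
      column = cols, known_function = kf,
      ptms = purrr::map2(seq_len(n), pc, function(i, k) {
        dplyr::bind_rows(lapply(seq_len(k), function(j)
          make_ptm_row(paste0("q", j), i, "S")))
      })
    )
    st <- cluster_window_stats(maps, window = w)
    for (i in seq_len(n)) {
      o <- brute_window_stats(cols, pc, kf, cols[i], w)
      expect_identical(st$cpc[i], as.integer(o$cpc))
      expect_identical(st$nc[i], as.integer(o$nc))
      expect_identical(st$nkc[i], as.integer(o$nkc))
    }
  }
})

test_that("window zero collapses cluster stats onto the MAP itself", {
  aln <- alignment(setNames(rep(strrep("S", 6), 4), paste0("p", 1:4)))
  recs <- dplyr::bind_rows(
    make_ptm_row("p1", 2, "S", known = TRUE), make_ptm_row("p2", 2, "S"),
    make_ptm_row("p1", 3, "S"), make_ptm_row("p1", 5, "S")
  )
  maps <- build_maps(validate_ptms(recs, aln), aln)
  st <- cluster_window_stats(maps, window = 0L)
  expect_equal(st$cpc, st$pc)
  expect_true(all(st$nc == 0L) && all(st$nkc == 0L))
})

test_that("interface residence maps native interface sets to columns", {
  aln <- alignment(c(AtRGS1 = "--SAS", Other = "QQSAS"))
  iface <- tibble::tibble(protein_id = "AtRGS1", native_pos = 3L)  # column 5
  expect_equal(interface_columns(iface, aln), 5L)
  expect_equal(interface_columns(NULL, aln), integer(0))
  expect_error(
    interface_columns(tibble::tibble(protein_id = "nope", native_pos = 1L),
                      aln),
    "unknown protein"
  )
})

test_that("PTM-residue conservation uses the dominant type's acceptor
           class", {
  aln <- alignment(c(a = "S", b = "T", c = "Y", d = "A"))
  phos <- make_ptm_row("a", 1, "S")
  expect_equal(ptm_residue_conservation(phos, aln, 1L), 3 / 4)

  kk <- alignment(c(a = "K", b = "K"))
  ub <- make_ptm_row("a", 1, "K", "ubiquitination")
  expect_equal(ptm_residue_conservation(ub, aln = kk, column = 1L), 1)

  # tie between phospho and ubiquitin resolves to the phospho class
  mixed <- dplyr::bind_rows(make_ptm_row("a", 1, "S"),
                            make_ptm_row("b", 1, "T", "ubiquitination"))
  expect_equal(ptm_residue_conservation(mixed, aln, 1L), 3 / 4)
})

test_that("crosstalk pairs are inclusive at the window boundary", {
  recs <- dplyr::bind_rows(
    make_ptm_row("GmRGS2", 405, "S"),
    make_ptm_row("GmRGS2", 410, "K", "ubiquitination"),
    make_ptm_row("GmRGS2", 416, "K", "ubiquitination"),  # distance 11
    make_ptm_row("Other", 100, "S"),
    make_ptm_row("Other", 106, "K", "ubiquitination")    # distance 6
  )
  ct <- crosstalk_pairs(recs, window = 5L)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$distance, 5L)
  expect_equal(crosstalk_pairs(recs, window = 6L)$distance, c(5L, 11L, 6L)[c(1, 3)])
})

test_that("adding a PTM inside the window never decreases CPC", {
  aln <- alignment(setNames(rep(strrep("S", 9), 5), paste0("p", 1:5)))
  base <- dplyr::bind_rows(make_ptm_row("p1", 4, "S"),
                           make_ptm_row("p1", 6, "S"))
  maps0 <- cluster_window_stats(build_maps(validate_ptms(base, aln), aln), 2L)
  for (extra_pos in 2:6) {
    recs <- dplyr::bind_rows(base, make_ptm_row("p2", extra_pos, "S"))
    maps1 <- cluster_window_stats(build_maps(validate_ptms(recs, aln), aln), 2L)
    expect_gte(maps1$cpc[maps1$column == 4L], maps0$cpc[maps0$column == 4L])
  }
})

test_that("feature assembly produces a complete, consistent table", {
  aln <- read_alignment(fixture_path("rgs_plant_family_synthetic.fasta"))
  ptms <- read_ptm_table(fixture_path("rgs_plant_sites.tsv"), aln)
  maps <- build_maps(ptms, aln)
  fv <- compute_features(maps, aln, window = 2L)
  expect_equal(nrow(fv), nrow(maps))
  expect_true(all(fv$cpc >= fv$pc))
  expect_true(all(fv$nkc <= fv$nc & fv$nc <= 4L))
  expect_true(all(fv$prc >= 0 & fv$prc <= 1))
  expect_true(all(fv$pac <= 1 & fv$membership <= 1))
})
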