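make_point_chain <- function(chain_id, coords, resno = seq_len(nrow(coords))) {
  out <- tibble::tibble(
    chain = chain_id, resno = as.integer(resno), resid = "ALA", elety = "CA",
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  )
  class(out) <- c("structure_chain", class(tibble::tibble()))
  out
}

test_that("interface detection is inclusive at the cutoff", {
  a <- make_point_chain("A", cbind(0, 0, 0))
  near <- make_point_chain("B", cbind(3.99, 0, 0))
  far <- make_point_chain("B", cbind(4.01, 0, 0))
  hit <- detect_interface(a, near, 4.0)
  expect_equal(hit$a$native_pos, 1L)
  expect_equal(hit$b$native_pos, 1L)
  miss <- detect_interface(a, far, 4.0)
  expect_equal(nrow(miss$a), 0L)
  exact <- detect_interface(a, make_point_chain("B", cbind(4, 0, 0)), 4.0)
  expect_equal(exact$a$native_pos, 1L)
  expect_error(detect_interface(a, near, -1), "positive")
})

test_that("interface detection equals the all-pairs brute force on random
           chains", {
  set.seed(5)
  for (rep in 1:5) {
    a <- random_chain(50, box = 25, chain_id = "A")
    b <- random_chain(50, box = 25, chain_id = "B")
    got <- detect_interface(a, b, 4.0)
    want <- brute_interface(a, b, 4.0)
    expect_identical(got$a$native_pos, want$a)
    expect_identical(got$b$native_pos, want$b)
    # symmetry
    swapped <- detect_interface(b, a, 4.0)
    expect_identical(swapped$a$native_pos, want$b)
    expect_identical(swapped$b$native_pos, want$a)
  }
})

test_that("interface sets grow monotonically with the cutoff and are
           rigid-motion invariant", {
  set.seed(9)
  a <- random_chain(40, box = 20, chain_id = "A")
  b <- random_chain(40, box = 20, chain_id = "B")
  sets <- lapply(c(3, 4.5, 6, 8), function(cu)
    detect_interface(a, b, cu)$a$native_pos)
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
  th <- runif(3, 0, 2 * pi)
  R <- matrix(c(cos(th[1]), -sin(th[1]), 0,
                sin(th[1]), cos(th[1]), 0,
                0, 0, 1), 3, 3) %*%
    matrix(c(1, 0, 0,
             0, cos(th[2]), -sin(th[2]),
             0, sin(th[2]), cos(th[2])), 3, 3)
  shift <- c(12.3, -45.6, 7.8)
  rigid <- function(ch) {
    xyz <- t(R %*% t(as.matrix(ch[, c("x", "y", "z")]))) +
      rep(shift, each = nrow(ch))
    ch$x <- xyz[, 1]; ch$y <- xyz[, 2]; ch$z <- xyz[, 3]
    ch
  }
  moved <- detect_interface(rigid(a), rigid(b), 4.0)
  orig <- detect_interface(a, b, 4.0)
  expect_identical(moved$a$native_pos, orig$a$native_pos)
  expect_identical(moved$b$native_pos, orig$b$native_pos)
})

test_that("structure residues map to alignment columns through the member
           sequence", {
  aln <- read_alignment(fixture_path("rgs_plant_family_synthetic.fasta"))
  chain <- read_structure(fixture_path("rgs_complex_synthetic.pdb"), "A")
  mp <- map_structure_to_alignment(chain, aln, "AtRGS1")
  # chain is the exact 284..459 construct: native position == author resno
  expect_equal(mp$native_pos, mp$resno)
  rmap <- residue_map(aln)
  expect_equal(mp$column,
               map_to_column(rmap, "AtRGS1", mp$native_pos))
  # a chain from an unrelated sequence fails the identity threshold
  other <- chain
  set.seed(2)
  other_seq <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                      length(unique(chain$resno)), replace = TRUE)
  other$resid <- bio3d::aa123(other_seq)[match(other$resno,
                                               unique(other$resno))]
  expect_error(map_structure_to_alignment(other, aln, "AtRGS1"),
               "identity")
})

test_that("projection writes bins into B-factors and round-trips", {
  sim <- simulate_structure_pair(n_residues = 10, n_contacts = 0, seed = 3)
  chain <- sim$a
  mapping <- tibble::tibble(resno = 1:10, native_pos = 1:10, column = 1:10)
  scored <- tibble::tibble(column = c(2L, 5L), bin = c(4L, 1L))
  tmp <- withr::local_tempfile(fileext = ".pdb")
  project_scores(chain, mapping, scored, tmp)
  lines <- readLines(tmp)
  atoms <- lines[startsWith(lines, "ATOM")]
  bfac <- as.numeric(substr(atoms, 61, 66))
  resno <- as.integer(substr(atoms, 23, 26))
  expect_equal(bfac[resno == 2], 4.00)
  expect_equal(bfac[resno == 5], 1.00)
  expect_true(all(bfac[!resno %in% c(2, 5)] == 0))
  # regrouping the re-parsed file reproduces the bin assignment
  back <- read_structure(tmp, "A")
  expect_equal(nrow(back), 10L)
})
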