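test_that("12-gon vertices follow the cosine/sine formula on the unit circle", {
  v <- polygon_vertex()
  expect_equal(dim(v), c(12L, 2L))
  expect_equal(sqrt(rowSums(v^2)), rep(1, 12))
  k <- 1:12
  expect_equal(v[, "x"], cos((k - 1) * pi / 6))
  expect_equal(v[, "y"], sin((k - 1) * pi / 6))
  expect_equal(unname(polygon_vertex(1)[1, ]), c(1, 0))
  expect_equal(unname(polygon_vertex(4)[1, ]), c(0, 1))
  expect_equal(unname(polygon_vertex(7)[1, ]), c(-1, 0))
  expect_error(polygon_vertex(13), "1..12")
})

test_that("trajectories are midpoint iterations from the centre", {
  # protein: class of 'A' is vertex 1 = (1, 0) under the default map
  expect_equal(unname(cgr_trajectory("A", "protein")), rbind(c(0.5, 0)))
  expect_equal(unname(cgr_trajectory("AA", "protein")),
               rbind(c(0.5, 0), c(0.75, 0)))
  # RNA: start (0.5, 0.5), A pulls to (0, 0)
  expect_equal(unname(cgr_trajectory("A", "rna")), rbind(c(0.25, 0.25)))
  expect_error(cgr_trajectory("", "rna"), "empty")
})

test_that("segment rules match their stated geometry", {
  expect_identical(segment_index_24(c(0.25, 0)), 1L)   # sector 1, inner
  expect_identical(segment_index_24(c(0.5, 0)), 2L)    # r = 0.5 is outer
  expect_identical(segment_index_24(c(0, 0.6)), 8L)    # 90 deg, sector 4, outer
  expect_identical(segment_index_16(c(0.25, 0.25)), 6L)
  expect_identical(segment_index_16(c(0, 0)), 1L)
  expect_identical(segment_index_16(c(1, 1)), 16L)     # clamped
})

test_that("histograms match an independent per-point classification", {
  # oracle: classify each trajectory point one at a time with scalar
  # geometry (helper-oracles.R), no vectorised indexing
  classify24 <- oracle_classify24
  classify16 <- oracle_classify16
  set.seed(202)
  for (i in 1:100) {
    p <- random_protein(sample(1:80, 1))
    traj <- cgr_trajectory(p, "protein")
    oracle <- tabulate(apply(traj, 1, classify24), 24)
    got <- encode_cgr_protein(p)
    expect_identical(attr(got, "counts"), oracle)
    expect_equal(sum(got), 1)
    expect_equal(sum(attr(got, "counts")), nchar(p))
  }
  for (i in 1:100) {
    r <- random_rna(sample(1:80, 1))
    traj <- cgr_trajectory(r, "rna")
    oracle <- tabulate(apply(traj, 1, classify16), 16)
    got <- encode_cgr_rna(r)
    expect_identical(attr(got, "counts"), oracle)
    expect_equal(sum(got), 1)
  }
})

test_that("trajectories stay inside their geometry and are deterministic", {
  set.seed(303)
  for (i in 1:50) {
    p <- random_protein(sample(1:120, 1))
    traj <- cgr_trajectory(p, "protein")
    expect_true(all(sqrt(rowSums(traj^2)) <= 1 + 1e-12))
    expect_identical(traj, cgr_trajectory(p, "protein"))
    r <- random_rna(sample(1:120, 1))
    trj <- cgr_trajectory(r, "rna")
    expect_true(all(trj >= 0 & trj <= 1))
    expect_identical(trj, cgr_trajectory(r, "rna"))
  }
})

test_that("k-mer-distinguishable sequences get distinct histograms", {
  set.seed(404)
  hits <- 0L
  for (i in 1:20) {
    a <- random_rna(60)
    b <- random_rna(60)
    if (a == b) next
    if (!isTRUE(all.equal(as.numeric(encode_cgr_rna(a)),
                          as.numeric(encode_cgr_rna(b))))) hits <- hits + 1L
  }
  expect_gte(hits, 18L)  # probabilistic smoke test
})

test_that("a custom twelve-group map changes the protein histogram accordingly", {
  # map everything to vertex 1 except C -> 2..12 spread; then a poly-A
  # run converges along the x-axis
  m <- setNames(rep(1L, 20), rpiforest:::AA20)
  m[2:12] <- 2:12  # keep the map surjective
  traj <- cgr_trajectory("AAAAAA", "protein", twelve_map = m)
  expect_true(all(abs(traj[, "y"]) < 1e-12))
  expect_true(all(diff(traj[, "x"]) > 0))
})
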